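#' Write / read a pullback as multi-page TIFF plus JSON sidecar
#'
#' The label masks are stored one frame per TIFF page (8-bit, integer
#' labels 0..4); the calibration, lesion span and per-frame
#' vulnerable-plaque flags go into a JSON sidecar next to the TIFF.
#'
#' @param pullback An [oct_pullback()].
#' @param tiff_path Output TIFF path.
#' @param sidecar_path JSON sidecar path; defaults to the TIFF path with a
#'   `.json` extension.
#' @return `tiff_path`, invisibly.
#' @export
write_pullback <- function(pullback, tiff_path,
                           sidecar_path = paste0(
                             tools::file_path_sans_ext(tiff_path), ".json")) {
  stopifnot(inherits(pullback, "oct_pullback"))
  pages <- lapply(pullback$frames, function(f) f$mask / 255)
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 8L)
  vp <- t(vapply(pullback$frames, function(f) f$vp_flags, logical(5)))
  meta <- list(pixel_size = pullback$calibration$pixel_size,
               frame_pitch = pullback$calibration$frame_pitch,
               lesion_span = pullback$lesion_span,
               vp_flags = as.data.frame(vp))
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(tiff_path)
}

#' @rdname write_pullback
#' @return `read_pullback` returns an [oct_pullback()].
#' @export
read_pullback <- function(tiff_path,
                          sidecar_path = paste0(
                            tools::file_path_sans_ext(tiff_path), ".json")) {
  if (!file.exists(sidecar_path))
    stop("missing JSON sidecar: ", sidecar_path)
  meta <- tryCatch(jsonlite::read_json(sidecar_path, simplifyVector = TRUE),
                   error = function(e)
                     stop("corrupt JSON sidecar '", sidecar_path, "': ",
                          conditionMessage(e), call. = FALSE))
  for (fld in c("pixel_size", "frame_pitch", "lesion_span"))
    if (is.null(meta[[fld]])) stop("sidecar lacks field '", fld, "'")
  pages <- tiff::readTIFF(tiff_path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  vp <- meta$vp_flags
  frames <- lapply(seq_along(pages), function(i) {
    flags <- if (!is.null(vp) && nrow(vp) >= i)
      stats::setNames(as.logical(vp[i, ]), colnames(vp)) else NULL
    oct_frame(pages[[i]], flags)
  })
  oct_pullback(frames,
               oct_calibration(meta$pixel_size, meta$frame_pitch),
               lesion_span = meta$lesion_span)
}

#' Write / read a cohort feature table as CSV
#'
#' Columns carry the display labels of [oct_features()] (plus the outcome
#' column); the reader maps them back to internal keys.
#'
#' @param table Cohort data.frame with feature keys (+ optionally
#'   `outcome`).
#' @param path CSV path.
#' @return `path` invisibly; `read_cohort_csv` returns the data.frame with
#'   internal key names.
#' @export
write_cohort_csv <- function(table, path) {
  out <- as.data.frame(table)
  colnames(out) <- ifelse(colnames(out) == "outcome", "outcome",
                          .key_to_label(colnames(out)))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @param outcome_column Name of the outcome column in the file.
#' @export
read_cohort_csv <- function(path, outcome_column = "outcome") {
  tab <- utils::read.csv(path, check.names = FALSE)
  cn <- colnames(tab)
  if (outcome_column %in% cn) {
    cn[cn == outcome_column] <- "outcome"
  }
  cn <- ifelse(cn == "outcome", "outcome", .label_to_key(cn))
  colnames(tab) <- cn
  tab
}

#' En-face fibrous-cap class map of a lesion
#'
#' Unrolls the lesion into the (angle, pullback position) plane and codes
#' each cell with the cap thickness class on that ray (0 = no cap,
#' 1/2/3 = thickness class).
#'
#' @param profiles List of `oct_ray_profile` (one per frame, e.g. from
#'   [quantify_pullback()]).
#' @param scheme An [fc_class_scheme()].
#' @return Integer matrix frames x rays.
#' @export
enface_class_map <- function(profiles, scheme = fc_class_scheme()) {
  profiles <- profiles[!vapply(profiles, is.null, logical(1))]
  stopifnot(length(profiles) >= 1L)
  t(vapply(profiles, function(p) {
    cl <- fc_class(p$fc_thickness, scheme)
    cl[is.na(cl)] <- 0L
    as.integer(cl)
  }, integer(profiles[[1]]$n_rays)))
}

#' Write an en-face class map as an indexed-color PNG
#'
#' Background black; class 1 green, class 2 light blue, class 3 red
#' (thin to thick cap).
#'
#' @param map Integer matrix from [enface_class_map()].
#' @param path PNG path.
#' @return `path`, invisibly.
#' @export
write_enface_png <- function(map, path) {
  pal <- rbind(c(0, 0, 0), c(0, 0.8, 0), c(0.4, 0.75, 1), c(0.9, 0.1, 0.1))
  img <- array(0, dim = c(nrow(map), ncol(map), 3))
  for (ch in 1:3)
    img[, , ch] <- matrix(pal[map + 1L, ch], nrow(map), ncol(map))
  png::writePNG(img, path)
  invisible(path)
}

# flatten a report for JSON serialization (deterministic field order)
.report_as_list <- function(report) {
  roc <- lapply(report$roc, function(r)
    list(auc = r$auc, ci_low = r$ci_low, ci_high = r$ci_high,
         optimal_cutoff = r$optimal_cutoff,
         sensitivity_at_cutoff = r$sensitivity_at_cutoff,
         specificity_at_cutoff = r$specificity_at_cutoff,
         n_boot = r$n_boot))
  list(config = report$config,
       n = report$n, n_events = report$n_events,
       comparison = report$comparison,
       pruning = list(retained = report$pruning$retained,
                      dropped = report$pruning$dropped,
                      components = report$pruning$components),
       univariate = report$univariate,
       selected = report$selected,
       multivariate = report$multivariate,
       significant = report$significant,
       roc = roc)
}

#' Serialize an analysis report to JSON
#'
#' @param report An `oct_report` from [run_pipeline()].
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "oct_report"))
  js <- jsonlite::toJSON(.report_as_list(report), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Quantify a stored pullback into a one-row feature CSV
#'
#' Reads the TIFF + sidecar, quantifies the lesion, writes the 31-entry
#' feature vector as a one-row CSV with display-label headers, and
#' optionally an en-face class-map PNG.
#'
#' @param tiff_path Mask stack (multi-page TIFF).
#' @param out_csv Output CSV path.
#' @param enface_png Optional output PNG path.
#' @param config An [oct_config()] (supplies `n_rays`).
#' @param sidecar_path JSON sidecar (default: next to the TIFF).
#' @return The lesion feature vector, invisibly.
#' @export
cli_quantify <- function(tiff_path, out_csv, enface_png = NULL,
                         config = oct_config(),
                         sidecar_path = paste0(
                           tools::file_path_sans_ext(tiff_path), ".json")) {
  pb <- read_pullback(tiff_path, sidecar_path)
  q <- quantify_pullback(pb, n_rays = config$n_rays)
  v <- feature_vector(q$lesion)
  out <- as.data.frame(as.list(v))
  colnames(out) <- .key_to_label(names(v))
  utils::write.csv(out, out_csv, row.names = FALSE)
  if (!is.null(enface_png))
    write_enface_png(enface_class_map(q$profiles), enface_png)
  invisible(v)
}

#' Analyze a cohort feature CSV end to end
#'
#' Reads the feature table, runs [run_pipeline()], and writes the report
#' JSON (plus optional ROC-point and correlation-matrix CSVs).
#'
#' @param feature_csv Cohort CSV (display-label or key headers).
#' @param out_json Report output path.
#' @param outcome_column Outcome column name in the CSV.
#' @param config An [oct_config()].
#' @param roc_csv Optional CSV of ROC points of the top feature.
#' @param rho_csv Optional CSV of the Spearman correlation matrix.
#' @return The `oct_report`, invisibly.
#' @export
cli_analyze <- function(feature_csv, out_json, outcome_column = "outcome",
                        config = oct_config(), roc_csv = NULL,
                        rho_csv = NULL) {
  hdr <- colnames(utils::read.csv(feature_csv, nrows = 1,
                                  check.names = FALSE))
  if (!outcome_column %in% hdr)
    stop("outcome column '", outcome_column, "' not found in ", feature_csv)
  tab <- read_cohort_csv(feature_csv, outcome_column)
  rep <- run_pipeline(tab, config)
  report_json(rep, out_json)
  if (!is.null(roc_csv) && length(rep$roc))
    utils::write.csv(rep$roc[[1]]$points, roc_csv, row.names = FALSE)
  if (!is.null(rho_csv))
    utils::write.csv(as.data.frame(rep$pruning$rho), rho_csv,
                     row.names = TRUE)
  invisible(rep)
}

#' Simulate a cohort (and optionally a phantom pullback) to files
#'
#' @param out_csv Cohort CSV output path.
#' @param spec A [cohort_spec()].
#' @param truth_json Optional path for the generative-truth record.
#' @return The simulated cohort, invisibly.
#' @export
cli_simulate <- function(out_csv, spec = cohort_spec(),
                         truth_json = NULL) {
  tab <- simulate_cohort(spec)
  write_cohort_csv(tab, out_csv)
  if (!is.null(truth_json)) {
    tr <- attr(tab, "truth")
    jsonlite::write_json(list(spec = unclass(tr$spec), beta0 = tr$beta0),
                         truth_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(tab)
}
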