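#' Calibration of an IVOCT pullback
#'
#' In-plane pixel size and longitudinal frame pitch, both in millimetres.
#' The frame pitch can be derived from the acquisition settings as
#' `pullback_speed / frame_rate` (e.g. 36 mm/s at 180 fps gives 0.2 mm).
#'
#' @param pixel_size In-plane size of one pixel in mm (isotropic).
#' @param frame_pitch Distance between consecutive frames in mm. If `NULL`,
#'   derived from `pullback_speed / frame_rate`.
#' @param pullback_speed Pullback speed in mm/s (used only when
#'   `frame_pitch` is `NULL`).
#' @param frame_rate Acquisition frame rate in frames/s.
#' @return An object of class `oct_calibration`.
#' @export
#' @examples
#' oct_calibration(0.01)                         # default 0.2 mm pitch
#' oct_calibration(0.02, frame_pitch = 0.1)
oct_calibration <- function(pixel_size, frame_pitch = NULL,
                            pullback_speed = 36, frame_rate = 180) {
  if (is.null(frame_pitch)) frame_pitch <- pullback_speed / frame_rate
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0,
            is.numeric(frame_pitch), length(frame_pitch) == 1L,
            frame_pitch > 0)
  structure(list(pixel_size = pixel_size, frame_pitch = frame_pitch),
            class = "oct_calibration")
}

#' One segmented IVOCT frame
#'
#' A labeled cross-sectional mask plus the frame-level vulnerable-plaque
#' flags. Labels are integers: 0 background, 1 lumen, 2 calcium, 3 lipid,
#' 4 fibrous cap; labels are mutually exclusive per pixel by construction.
#'
#' @param mask Integer matrix of labels in `0:4` (rows are the image y axis,
#'   columns the x axis).
#' @param vp_flags Named logical vector over [oct_vp_flags()]; missing names
#'   default to `FALSE`.
#' @return An object of class `oct_frame`.
#' @export
oct_frame <- function(mask, vp_flags = NULL) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "integer"
  bad <- setdiff(unique(as.vector(mask)), unname(OCT_LABELS))
  if (length(bad))
    stop("mask contains labels outside 0..4: ", paste(bad, collapse = ", "))
  flags <- stats::setNames(rep(FALSE, 5L), oct_vp_flags())
  if (!is.null(vp_flags)) {
    if (is.null(names(vp_flags)) && length(vp_flags) == 5L)
      names(vp_flags) <- oct_vp_flags()
    unknown <- setdiff(names(vp_flags), oct_vp_flags())
    if (length(unknown))
      stop("unknown vulnerable-plaque flag: ", paste(unknown, collapse = ", "))
    flags[names(vp_flags)] <- as.logical(vp_flags)
  }
  structure(list(mask = mask, vp_flags = flags), class = "oct_frame")
}

#' A calibrated pullback of segmented frames
#'
#' @param frames List of [oct_frame()] objects sharing one image size.
#' @param calibration An [oct_calibration()].
#' @param lesion_span Inclusive frame-index range `c(first, last)` of the
#'   lesion (the stented segment). Defaults to the whole pullback.
#' @return An object of class `oct_pullback`.
#' @export
oct_pullback <- function(frames, calibration, lesion_span = NULL) {
  stopifnot(length(frames) >= 1L, inherits(calibration, "oct_calibration"))
  frames <- lapply(frames, function(f) {
    if (inherits(f, "oct_frame")) f else oct_frame(f)
  })
  dims <- vapply(frames, function(f) dim(f$mask), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share the same dimensions")
  if (is.null(lesion_span)) lesion_span <- c(1L, length(frames))
  lesion_span <- as.integer(lesion_span)
  if (length(lesion_span) != 2L || lesion_span[1] < 1L ||
      lesion_span[2] > length(frames) || lesion_span[1] > lesion_span[2])
    stop("lesion_span out of bounds")
  structure(list(frames = frames, calibration = calibration,
                 lesion_span = lesion_span),
            class = "oct_pullback")
}

#' @export
print.oct_pullback <- function(x, ...) {
  d <- dim(x$frames[[1]]$mask)
  cat(sprintf(
    "IVOCT pullback: %d frames of %d x %d px (%.3g mm/px, pitch %.3g mm), lesion frames %d-%d\n",
    length(x$frames), d[1], d[2], x$calibration$pixel_size,
    x$calibration$frame_pitch, x$lesion_span[1], x$lesion_span[2]))
  invisible(x)
}

# pixel centers in mm; column index -> x, row index -> y
.pixel_centers <- function(idx, pixel_size) (idx - 0.5) * pixel_size

#' Center of mass of the lumen
#'
#' Arithmetic mean of the lumen-pixel centers, in mm image coordinates
#' (x along columns, y along rows).
#'
#' @param frame An [oct_frame()] (or a bare label matrix).
#' @param calibration An [oct_calibration()] supplying the pixel size.
#' @return Numeric `c(x, y)` in mm.
#' @export
lumen_centroid <- function(frame, calibration) {
  mask <- if (inherits(frame, "oct_frame")) frame$mask else frame
  idx <- which(mask == OCT_LABELS[["lumen"]], arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("frame has no lumen pixels")
  ps <- calibration$pixel_size
  c(x = mean(.pixel_centers(idx[, "col"], ps)),
    y = mean(.pixel_centers(idx[, "row"], ps)))
}

#' Cast radial rays from the lumen centroid
#'
#' Walks outward from the lumen center of mass along `n_rays` uniformly
#' spaced directions, sampling the label mask at half-pixel steps, and
#' records per ray: the lumen boundary radius (sub-pixel, by linear
#' interpolation between the last in-lumen and first out-of-lumen sample),
#' the inner/outer radial extent of calcium, and the total radial extent of
#' fibrous-cap label, which is the radially measured cap thickness.
#'
#' Angles are measured from the image +x axis (increasing column) towards
#' +y (increasing row); only angular extents enter the feature set, so the
#' origin is a documented convention, not a measurement. If the centroid
#' falls outside the lumen (a non-star-shaped lumen), the frame is flagged
#' with a warning and rays are measured from the centroid regardless.
#'
#' @param frame An [oct_frame()].
#' @param calibration An [oct_calibration()].
#' @param n_rays Number of rays (default 360, i.e. 1 degree sampling;
#'   must be >= 36 and even so diametric chords pair up).
#' @return An object of class `oct_ray_profile`: list with `angles` (deg),
#'   `lumen_radius`, `fc_thickness`, `calcium_inner`, `calcium_outer`
#'   (mm, `NA` where the tissue is absent on that ray), `centroid`, and
#'   `flagged`.
#' @export
cast_rays <- function(frame, calibration, n_rays = 360L) {
  stopifnot(inherits(frame, "oct_frame"),
            inherits(calibration, "oct_calibration"))
  n_rays <- as.integer(n_rays)
  if (n_rays < 36L) stop("n_rays must be >= 36")
  if (n_rays %% 2L != 0L) stop("n_rays must be even")
  mask <- frame$mask
  ps <- calibration$pixel_size
  ctr <- lumen_centroid(frame, calibration)

  nr <- nrow(mask); nc <- ncol(mask)
  # farthest possible radius: distance from centroid to the far corner
  corners_x <- c(0, nc * ps); corners_y <- c(0, nr * ps)
  rmax <- sqrt(max(outer((corners_x - ctr[1])^2, (corners_y - ctr[2])^2, "+")))
  step <- ps / 2
  radii <- seq(step, rmax + step, by = step)
  K <- length(radii)

  theta <- (seq_len(n_rays) - 1L) * (2 * pi / n_rays)
  # sample positions: n_rays x K
  x <- ctr[1] + outer(cos(theta), radii)
  y <- ctr[2] + outer(sin(theta), radii)
  col <- floor(x / ps) + 1
  row <- floor(y / ps) + 1
  inb <- col >= 1 & col <= nc & row >= 1 & row <= nr
  lab <- matrix(OCT_LABELS[["background"]], n_rays, K)
  lab[inb] <- mask[cbind(row[inb], col[inb])]

  ctr_col <- floor(ctr[1] / ps) + 1; ctr_row <- floor(ctr[2] / ps) + 1
  ctr_in_lumen <- ctr_col >= 1 && ctr_col <= nc && ctr_row >= 1 &&
    ctr_row <= nr && mask[ctr_row, ctr_col] == OCT_LABELS[["lumen"]]
  flagged <- !ctr_in_lumen
  if (flagged)
    warning("lumen centroid falls outside the lumen label (non-star-shaped lumen?); rays measured from the centroid regardless")

  in_lumen <- lab == OCT_LABELS[["lumen"]]
  lumen_radius <- numeric(n_rays)
  for (i in seq_len(n_rays)) {
    row_in <- c(ctr_in_lumen, in_lumen[i, ])
    # first lumen -> non-lumen transition walking outward
    trans <- which(row_in[-length(row_in)] & !row_in[-1])
    if (length(trans) == 0L) {
      # never leaves the lumen before the image edge; take the last sample
      lumen_radius[i] <- radii[K]
    } else {
      k <- trans[1]  # sample k-1 (radius index) in lumen, k out
      r_in <- if (k == 1L) 0 else radii[k - 1L]
      lumen_radius[i] <- (r_in + radii[k]) / 2
    }
  }

  extent <- function(which_label) {
    inner <- rep(NA_real_, n_rays); outer_ <- rep(NA_real_, n_rays)
    hit <- lab == which_label
    for (i in seq_len(n_rays)) {
      k <- which(hit[i, ])
      if (length(k)) {
        inner[i] <- radii[k[1]] - step / 2
        outer_[i] <- radii[k[length(k)]] + step / 2
      }
    }
    list(inner = inner, outer = outer_)
  }
  ca <- extent(OCT_LABELS[["calcium"]])
  # cap thickness: total radial coverage of the fibrous-cap label
  fc_n <- rowSums(lab == OCT_LABELS[["fibrous_cap"]])
  fc_thickness <- ifelse(fc_n > 0L, fc_n * step, NA_real_)

  structure(list(angles = theta * 180 / pi,
                 lumen_radius = lumen_radius,
                 fc_thickness = fc_thickness,
                 calcium_inner = ca$inner,
                 calcium_outer = ca$outer,
                 centroid = ctr,
                 n_rays = n_rays,
                 flagged = flagged),
            class = "oct_ray_profile")
}
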