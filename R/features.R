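#' Fibrous-cap thickness classification scheme
#'
#' Caps are stratified into three thickness classes plus their union:
#' class 1, thickness <= `t1_max` (default 65 um, the conventional
#' thin-cap threshold); class 2, strictly between `t1_max` and `t2_max`;
#' class 3, thickness >= `t2_max` (default 150 um); class T, all caps.
#' Values exactly at `t1_max` fall in class 1 and values exactly at
#' `t2_max` in class 3, following the printed inequalities.
#'
#' @param t1_max Upper bound of class 1 in mm (default 0.065).
#' @param t2_max Lower bound of class 3 in mm (default 0.150).
#' @return An object of class `fc_class_scheme`.
#' @export
fc_class_scheme <- function(t1_max = 0.065, t2_max = 0.150) {
  stopifnot(t1_max > 0, t1_max < t2_max)
  structure(list(t1_max = t1_max, t2_max = t2_max), class = "fc_class_scheme")
}

#' Classify cap thicknesses
#' @param thickness Numeric vector of cap thicknesses in mm (`NA` allowed).
#' @param scheme An [fc_class_scheme()].
#' @return Integer vector of classes 1/2/3 (`NA` preserved).
#' @export
fc_class <- function(thickness, scheme = fc_class_scheme()) {
  ifelse(is.na(thickness), NA_integer_,
         ifelse(thickness <= scheme$t1_max, 1L,
                ifelse(thickness >= scheme$t2_max, 3L, 2L)))
}

#' Angular extent of a plaque from ray presence
#'
#' The extent of a tissue around the lumen, measured from the lumen center
#' of mass: the number of rays on which the tissue is present times the
#' angular spacing. Disjoint arcs sum; an empty presence vector gives 0.
#'
#' @param present Logical (or `NA`-coded) vector, one entry per ray.
#' @param n_rays Number of rays (defaults to `length(present)`).
#' @return Extent in degrees, in `[0, 360]`.
#' @export
angular_extent <- function(present, n_rays = length(present)) {
  if (n_rays < 36L) stop("n_rays must be >= 36")
  p <- !is.na(present) & as.logical(present)
  sum(p) * (360 / n_rays)
}

.min_or_na <- function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
.max_or_na <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)

#' Per-frame plaque features
#'
#' Computes the cross-sectional measurements of one frame from its ray
#' profile and label mask: lumen area (pixel count times pixel area),
#' minimum and mean lumen diameter (diametric chords `r(theta) +
#' r(theta+180)`), lumen circumference (`sum r dtheta`), calcium angle /
#' per-ray thickness (outer - inner) / per-ray depth (inner - lumen
#' radius), fibrous-cap angle and minimum thickness, cap cross-sectional
#' area per thickness class (each cap pixel assigned to the class of its
#' nearest ray), and cap arc length per class (`sum r dtheta` over rays of
#' that class).
#'
#' Fields for absent tissue are `NA`-coded.
#'
#' @param profile An `oct_ray_profile` from [cast_rays()].
#' @param frame The [oct_frame()] the profile was cast on.
#' @param calibration An [oct_calibration()].
#' @param scheme An [fc_class_scheme()].
#' @return An object of class `oct_frame_features` (a named list; the
#'   per-class fields `fc_area` and `fc_arc_length` are length-4 vectors
#'   named `"1","2","3","t"`).
#' @export
frame_features <- function(profile, frame, calibration,
                           scheme = fc_class_scheme()) {
  stopifnot(inherits(profile, "oct_ray_profile"), inherits(frame, "oct_frame"))
  ps <- calibration$pixel_size
  n <- profile$n_rays
  dth <- 2 * pi / n
  mask <- frame$mask

  lumen_area <- sum(mask == OCT_LABELS[["lumen"]]) * ps^2
  r <- profile$lumen_radius
  half <- n %/% 2L
  chords <- r[seq_len(half)] + r[seq_len(half) + half]
  lumen_circumference <- sum(r) * dth

  ca_th <- profile$calcium_outer - profile$calcium_inner
  ca_depth <- profile$calcium_inner - r

  fc_t <- profile$fc_thickness
  cls <- fc_class(fc_t, scheme)

  # cap pixels -> nearest ray -> that ray's class
  fc_area <- stats::setNames(numeric(4), c("1", "2", "3", "t"))
  idx <- which(mask == OCT_LABELS[["fibrous_cap"]], arr.ind = TRUE)
  if (nrow(idx) > 0L && any(!is.na(cls))) {
    px <- .pixel_centers(idx[, "col"], ps) - profile$centroid[1]
    py <- .pixel_centers(idx[, "row"], ps) - profile$centroid[2]
    ang <- atan2(py, px) %% (2 * pi)
    ray <- (round(ang / dth) %% n) + 1L
    pix_cls <- cls[ray]
    if (anyNA(pix_cls)) {
      # arc-edge pixels whose nearest ray carries no cap: use the nearest
      # cap-bearing ray (circular distance)
      have <- which(!is.na(cls))
      miss <- which(is.na(pix_cls))
      for (m in miss) {
        d <- abs(have - ray[m])
        d <- pmin(d, n - d)
        pix_cls[m] <- cls[have[which.min(d)]]
      }
    }
    tab <- table(factor(pix_cls, levels = 1:3))
    fc_area[1:3] <- as.numeric(tab) * ps^2
    # left-associated sum so the class-total identity is exact in floats
    fc_area["t"] <- fc_area[[1]] + fc_area[[2]] + fc_area[[3]]
  } else {
    fc_area[] <- if (any(!is.na(fc_t))) 0 else NA_real_
  }

  fc_arc <- stats::setNames(numeric(4), c("1", "2", "3", "t"))
  if (any(!is.na(cls))) {
    for (c3 in 1:3) fc_arc[c3] <- sum(r[which(cls == c3)]) * dth
    fc_arc["t"] <- fc_arc[[1]] + fc_arc[[2]] + fc_arc[[3]]
  } else fc_arc[] <- NA_real_

  structure(list(
    lumen_area = lumen_area,
    lumen_min_diameter = min(chords),
    lumen_mean_diameter = mean(chords),
    lumen_circumference = lumen_circumference,
    calcium_angle = if (all(is.na(ca_th))) NA_real_ else
      angular_extent(!is.na(ca_th), n),
    calcium_max_thickness = .max_or_na(ca_th),
    calcium_min_thickness = .min_or_na(ca_th),
    calcium_max_depth = .max_or_na(ca_depth),
    calcium_min_depth = .min_or_na(ca_depth),
    fc_angle = if (all(is.na(fc_t))) NA_real_ else
      angular_extent(!is.na(fc_t), n),
    fc_min_thickness = .min_or_na(fc_t),
    fc_area = fc_area,
    fc_arc_length = fc_arc
  ), class = "oct_frame_features")
}

#' Aggregate per-frame features to one lesion
#'
#' Lesion length is the frame count times the frame pitch. Lumen metrics
#' are min/mean over frames. Calcium and cap extrema take the per-frame
#' maxima for "max" fields and the per-frame minima for "min" fields, over
#' the frames where the tissue is present (absent frames are skipped, not
#' zero-filled). Cap surface area per class is the en-face area `sum over
#' frames of arc_length(class) * frame_pitch`; cap burden is that surface
#' expressed as a percentage of the total lumen surface area `sum of
#' circumference * frame_pitch`. Vulnerable-plaque flags are any-frame
#' presence.
#'
#' @param per_frame List of [frame_features()] results (lesion frames only).
#' @param calibration An [oct_calibration()].
#' @param vp_flags Logical matrix frames x 5 (columns [oct_vp_flags()]), or
#'   `NULL` for all-absent.
#' @return An object of class `oct_lesion_features`: a named list holding
#'   the 31 features under the keys of [oct_features()].
#' @export
aggregate_lesion <- function(per_frame, calibration, vp_flags = NULL) {
  nf <- length(per_frame)
  if (nf < 1L) stop("at least one lesion frame is required")
  g <- function(fld) vapply(per_frame, function(x) x[[fld]], numeric(1))
  gc4 <- function(fld, cl) vapply(per_frame, function(x) x[[fld]][[cl]],
                                  numeric(1))
  pitch <- calibration$frame_pitch

  lumen_surface <- sum(g("lumen_circumference")) * pitch
  sa <- vapply(c("1", "2", "3"), function(cl) {
    v <- gc4("fc_arc_length", cl)
    sum(v[!is.na(v)]) * pitch
  }, numeric(1))
  sa[["t"]] <- sa[["1"]] + sa[["2"]] + sa[["3"]]
  no_fc <- all(is.na(g("fc_angle")))
  if (no_fc) sa[] <- 0

  if (is.null(vp_flags)) {
    vp <- stats::setNames(rep(FALSE, 5L), oct_vp_flags())
  } else {
    vp_flags <- as.matrix(vp_flags)
    colnames(vp_flags) <- oct_vp_flags()
    vp <- apply(vp_flags, 2, any)
  }

  out <- list(
    lesion_length = nf * pitch,
    min_lumen_area = min(g("lumen_area")),
    avg_lumen_area = mean(g("lumen_area")),
    min_lumen_diameter = min(g("lumen_min_diameter")),
    avg_lumen_diameter = mean(g("lumen_mean_diameter")),
    max_calcium_angle = .max_or_na(g("calcium_angle")),
    min_calcium_angle = .min_or_na(g("calcium_angle")),
    max_calcium_thickness = .max_or_na(g("calcium_max_thickness")),
    min_calcium_thickness = .min_or_na(g("calcium_min_thickness")),
    max_calcium_depth = .max_or_na(g("calcium_max_depth")),
    min_calcium_depth = .min_or_na(g("calcium_min_depth")),
    max_fc_angle = .max_or_na(g("fc_angle")),
    min_fc_angle = .min_or_na(g("fc_angle")),
    min_fc_thickness = .min_or_na(g("fc_min_thickness")),
    max_fc_area_1 = .max_or_na(gc4("fc_area", "1")),
    max_fc_area_2 = .max_or_na(gc4("fc_area", "2")),
    max_fc_area_3 = .max_or_na(gc4("fc_area", "3")),
    max_fc_area_t = .max_or_na(gc4("fc_area", "t")),
    fc_surface_area_1 = sa[["1"]],
    fc_surface_area_2 = sa[["2"]],
    fc_surface_area_3 = sa[["3"]],
    fc_surface_area_t = sa[["t"]],
    fc_burden_1 = 100 * sa[["1"]] / lumen_surface,
    fc_burden_2 = 100 * sa[["2"]] / lumen_surface,
    fc_burden_3 = 100 * sa[["3"]] / lumen_surface,
    fc_burden_t = 100 * sa[["t"]] / lumen_surface,
    microchannel = as.numeric(vp[["microchannel"]]),
    macrophage_infiltration = as.numeric(vp[["macrophage_infiltration"]]),
    cholesterol_crystal = as.numeric(vp[["cholesterol_crystal"]]),
    layered_plaque = as.numeric(vp[["layered_plaque"]]),
    calcium_nodule = as.numeric(vp[["calcium_nodule"]])
  )
  out$lumen_surface_area <- lumen_surface
  structure(out, class = "oct_lesion_features")
}

#' Flatten lesion features into the standard 31-entry vector
#'
#' @param lesion An [aggregate_lesion()] (or [truth_features()]) result.
#' @param labels Use display labels instead of internal keys for names.
#' @return Named numeric vector of length 31 in the standard feature order;
#'   absent-coded values propagate as `NA`.
#' @export
feature_vector <- function(lesion, labels = FALSE) {
  keys <- oct_feature_keys()
  v <- vapply(keys, function(k) {
    x <- lesion[[k]]
    if (is.null(x)) NA_real_ else as.numeric(x)
  }, numeric(1))
  if (labels) names(v) <- .key_to_label(keys)
  v
}

#' Quantify a whole pullback lesion
#'
#' Runs [cast_rays()] and [frame_features()] on every frame of the lesion
#' span and aggregates to lesion level. Frames without any lumen label are
#' skipped for plaque statistics (with a message); they still count toward
#' lesion length, which is defined by the lesion span.
#'
#' @param pullback An [oct_pullback()].
#' @param n_rays Rays per frame (see [cast_rays()]).
#' @param scheme An [fc_class_scheme()].
#' @return List with `lesion` ([aggregate_lesion()] result), `per_frame`
#'   (list of [frame_features()]), `profiles` (list of ray profiles) and
#'   `skipped` (indices of frames without lumen).
#' @export
quantify_pullback <- function(pullback, n_rays = 360L,
                              scheme = fc_class_scheme()) {
  stopifnot(inherits(pullback, "oct_pullback"))
  span <- pullback$lesion_span[1]:pullback$lesion_span[2]
  cal <- pullback$calibration
  profiles <- vector("list", length(span))
  feats <- vector("list", length(span))
  skipped <- integer(0)
  for (j in seq_along(span)) {
    fr <- pullback$frames[[span[j]]]
    if (!any(fr$mask == OCT_LABELS[["lumen"]])) {
      skipped <- c(skipped, span[j])
      next
    }
    profiles[[j]] <- cast_rays(fr, cal, n_rays)
    feats[[j]] <- frame_features(profiles[[j]], fr, cal, scheme)
  }
  if (length(skipped))
    message("skipped ", length(skipped),
            " frame(s) without lumen label: ",
            paste(skipped, collapse = ", "))
  ok <- !vapply(feats, is.null, logical(1))
  if (!any(ok)) stop("no quantifiable frames in the lesion span")
  vp <- t(vapply(pullback$frames[span], function(f) f$vp_flags, logical(5)))
  lesion <- aggregate_lesion(feats[ok], cal, vp)
  # lesion length counts all lesion-span frames, including skipped ones
  lesion$lesion_length <- length(span) * cal$frame_pitch
  list(lesion = lesion, per_frame = feats, profiles = profiles,
       skipped = skipped)
}
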