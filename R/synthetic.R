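#' Specification of a synthetic vessel lesion
#'
#' Describes a vessel phantom in polar coordinates around the lumen center:
#' a lumen radius (constant, or a function of angle in degrees and
#' longitudinal position z in mm), fibrous-cap arcs sitting on the lumen
#' boundary, and calcium arcs at a given depth behind it. The phantom has
#' closed-form feature values ([truth_features()]) and can be rasterized
#' into label masks ([rasterize()]) for round-trip testing.
#'
#' @param n_frames Number of frames in the lesion.
#' @param lumen_radius Lumen radius in mm: a single number or
#'   `function(theta_deg, z_mm)`.
#' @param fc_arcs List of cap arcs, each `list(start, end, thickness)` with
#'   angles in degrees in `[0, 360)` (an arc may wrap through 0) and
#'   thickness in mm either a number or `function(theta_deg)`.
#' @param calcium_arcs List of calcium arcs, each
#'   `list(start, end, thickness, depth)` in degrees / mm.
#' @param vp_flags Logical matrix `n_frames x 5` (columns [oct_vp_flags()])
#'   or `NULL`.
#' @param calibration An [oct_calibration()].
#' @param center_offset Offset `c(dx, dy)` in mm of the lumen center from
#'   the image center (rasterization only); exercises eccentric lumens.
#' @return An object of class `lesion_spec`.
#' @export
#' @examples
#' sp <- lesion_spec(n_frames = 50, lumen_radius = 1.5,
#'                   fc_arcs = list(list(start = 0, end = 90,
#'                                       thickness = 0.1)))
#' truth_features(sp)$fc_surface_area_t   # pi/2 * 1.5 * 10 = 23.56 mm^2
lesion_spec <- function(n_frames, lumen_radius,
                        fc_arcs = list(), calcium_arcs = list(),
                        vp_flags = NULL,
                        calibration = oct_calibration(0.01),
                        center_offset = c(0, 0)) {
  stopifnot(n_frames >= 1L)
  rfn <- if (is.function(lumen_radius)) lumen_radius else {
    stopifnot(lumen_radius > 0)
    function(theta, z) rep(lumen_radius, length(theta))
  }
  norm_arc <- function(a, need_depth) {
    stopifnot(!is.null(a$start), !is.null(a$end))
    if (a$start < 0 || a$start >= 360 || a$end < 0 || a$end > 360)
      stop("arc angles must lie in [0, 360)")
    if (!is.function(a$thickness)) {
      stopifnot(a$thickness > 0)
      th <- a$thickness
      a$thickness <- function(theta) rep(th, length(theta))
    }
    if (need_depth) stopifnot(!is.null(a$depth), a$depth >= 0)
    a
  }
  fc_arcs <- lapply(fc_arcs, norm_arc, need_depth = FALSE)
  calcium_arcs <- lapply(calcium_arcs, norm_arc, need_depth = TRUE)
  .check_arc_overlap(fc_arcs, "fibrous-cap")
  .check_arc_overlap(calcium_arcs, "calcium")
  if (!is.null(vp_flags)) {
    vp_flags <- as.matrix(vp_flags)
    stopifnot(nrow(vp_flags) == n_frames, ncol(vp_flags) == 5L)
    colnames(vp_flags) <- oct_vp_flags()
  }
  structure(list(n_frames = as.integer(n_frames), lumen_radius_fn = rfn,
                 fc_arcs = fc_arcs, calcium_arcs = calcium_arcs,
                 vp_flags = vp_flags, calibration = calibration,
                 center_offset = center_offset),
            class = "lesion_spec")
}

.arc_span <- function(a) {
  s <- (a$end - a$start) %% 360
  if (s == 0) 360 else s
}

# angle membership with wrap-through-zero support
.in_arc <- function(theta, start, end) {
  theta <- theta %% 360
  if (start < end) theta >= start & theta < end
  else theta >= start | theta < end
}

.check_arc_overlap <- function(arcs, what) {
  if (length(arcs) < 2L) return(invisible())
  probe <- seq(0, 359.995, by = 0.005)
  cover <- integer(length(probe))
  for (a in arcs) cover <- cover + .in_arc(probe, a$start, a$end)
  if (any(cover > 1L))
    stop("overlapping ", what, " arcs in lesion_spec")
  invisible()
}

#' Closed-form feature values of a synthetic lesion
#'
#' Evaluates the 31 lesion features analytically (fine angular quadrature
#' of the defining integrals, no rasterization): angles from arc spans,
#' cap arc length per thickness class by classifying the thickness profile
#' on the quadrature grid, cap surface area as `integral of r(theta, z)
#' dtheta x frame_pitch`, burden as percent of the lumen surface
#' `integral r dtheta x pitch`, lumen area as `1/2 integral r^2 dtheta`,
#' cap cross-section area as `1/2 integral (r+t)^2 - r^2 dtheta`.
#'
#' @param spec A [lesion_spec()].
#' @param n_theta Quadrature points over the full circle (default 7200).
#' @return An `oct_lesion_features` object (same shape as
#'   [aggregate_lesion()]).
#' @export
truth_features <- function(spec, n_theta = 7200L) {
  stopifnot(inherits(spec, "lesion_spec"))
  cal <- spec$calibration
  pitch <- cal$frame_pitch
  theta <- (seq_len(n_theta) - 0.5) * (360 / n_theta)   # midpoint rule, deg
  dth <- 2 * pi / n_theta                                # radians
  half <- n_theta %/% 2L
  scheme <- fc_class_scheme()

  zs <- (seq_len(spec$n_frames) - 0.5) * pitch
  lumen_area <- numeric(spec$n_frames)
  min_d <- numeric(spec$n_frames); mean_d <- numeric(spec$n_frames)
  circ <- numeric(spec$n_frames)
  arc_len <- matrix(0, spec$n_frames, 4,
                    dimnames = list(NULL, c("1", "2", "3", "t")))
  fc_area <- matrix(NA_real_, spec$n_frames, 4,
                    dimnames = list(NULL, c("1", "2", "3", "t")))
  fc_min_t <- rep(NA_real_, spec$n_frames)
  fc_angle <- rep(NA_real_, spec$n_frames)

  has_fc <- length(spec$fc_arcs) > 0L
  for (fi in seq_len(spec$n_frames)) {
    r <- spec$lumen_radius_fn(theta, zs[fi])
    lumen_area[fi] <- 0.5 * sum(r^2) * dth
    chords <- r[seq_len(half)] + r[seq_len(half) + half]
    min_d[fi] <- min(chords); mean_d[fi] <- mean(chords)
    circ[fi] <- sum(r) * dth
    if (has_fc) {
      t_prof <- rep(NA_real_, n_theta)
      for (a in spec$fc_arcs) {
        sel <- .in_arc(theta, a$start, a$end)
        t_prof[sel] <- a$thickness(theta[sel])
      }
      cls <- fc_class(t_prof, scheme)
      fc_min_t[fi] <- .min_or_na(t_prof)
      fc_angle[fi] <- sum(!is.na(t_prof)) * (360 / n_theta)
      area_c <- numeric(3)
      for (c3 in 1:3) {
        sel <- which(cls == c3)
        arc_len[fi, c3] <- sum(r[sel]) * dth
        area_c[c3] <- 0.5 * sum((r[sel] + t_prof[sel])^2 - r[sel]^2) * dth
      }
      arc_len[fi, "t"] <- arc_len[fi, 1] + arc_len[fi, 2] + arc_len[fi, 3]
      fc_area[fi, ] <- c(area_c, area_c[1] + area_c[2] + area_c[3])
    }
  }

  ca_angle <- ca_max_t <- ca_min_t <- ca_max_d <- ca_min_d <- NA_real_
  if (length(spec$calcium_arcs)) {
    spans <- vapply(spec$calcium_arcs, .arc_span, numeric(1))
    ths <- vapply(spec$calcium_arcs, function(a) a$thickness(0)[1], numeric(1))
    dps <- vapply(spec$calcium_arcs, function(a) a$depth, numeric(1))
    ca_angle <- sum(spans)
    ca_max_t <- max(ths); ca_min_t <- min(ths)
    ca_max_d <- max(dps); ca_min_d <- min(dps)
  }

  lumen_surface <- sum(circ) * pitch
  sa <- colSums(arc_len) * pitch
  sa[["t"]] <- sa[["1"]] + sa[["2"]] + sa[["3"]]

  vp <- stats::setNames(rep(FALSE, 5L), oct_vp_flags())
  if (!is.null(spec$vp_flags)) vp <- apply(spec$vp_flags, 2, any)

  out <- list(
    lesion_length = spec$n_frames * pitch,
    min_lumen_area = min(lumen_area), avg_lumen_area = mean(lumen_area),
    min_lumen_diameter = min(min_d), avg_lumen_diameter = mean(mean_d),
    max_calcium_angle = ca_angle, min_calcium_angle = ca_angle,
    max_calcium_thickness = ca_max_t, min_calcium_thickness = ca_min_t,
    max_calcium_depth = ca_max_d, min_calcium_depth = ca_min_d,
    max_fc_angle = .max_or_na(fc_angle), min_fc_angle = .min_or_na(fc_angle),
    min_fc_thickness = .min_or_na(fc_min_t),
    max_fc_area_1 = .max_or_na(fc_area[, "1"]),
    max_fc_area_2 = .max_or_na(fc_area[, "2"]),
    max_fc_area_3 = .max_or_na(fc_area[, "3"]),
    max_fc_area_t = .max_or_na(fc_area[, "t"]),
    fc_surface_area_1 = sa[["1"]], fc_surface_area_2 = sa[["2"]],
    fc_surface_area_3 = sa[["3"]], fc_surface_area_t = sa[["t"]],
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

#' Rasterize a synthetic lesion into label masks
#'
#' Renders each frame of the phantom as an integer label image on a square
#' pixel grid (the lumen center sits at the image center plus the spec's
#' offset). Deterministic; pixel membership is decided at the pixel center.
#' Label priority where bands touch: fibrous cap over calcium over
#' background; the lumen region is disjoint by construction.
#'
#' @param spec A [lesion_spec()]; its calibration's `pixel_size` must be
#'   <= 0.02 mm (the imaging resolution regime the phantom emulates).
#' @param margin Background margin around the outermost structure, mm.
#' @return An [oct_pullback()].
#' @export
rasterize <- function(spec, margin = 0.2) {
  stopifnot(inherits(spec, "lesion_spec"))
  cal <- spec$calibration
  ps <- cal$pixel_size
  if (ps > 0.02) stop("pixel_size must be <= 0.02 mm for rasterization")

  probe <- seq(0, 359.9, by = 0.1)
  zs <- (seq_len(spec$n_frames) - 0.5) * cal$frame_pitch
  rmax <- max(vapply(zs, function(z) max(spec$lumen_radius_fn(probe, z)),
                     numeric(1)))
  ext <- rmax
  for (a in spec$fc_arcs)
    ext <- max(ext, rmax + max(a$thickness(probe)))
  for (a in spec$calcium_arcs)
    ext <- max(ext, rmax + a$depth + max(a$thickness(probe)))
  halfw <- ext + margin + max(abs(spec$center_offset))
  npx <- 2L * as.integer(ceiling(halfw / ps))
  if (npx < 8L) stop("image too small to contain the vessel")

  cx <- npx * ps / 2 + spec$center_offset[1]
  cy <- npx * ps / 2 + spec$center_offset[2]
  xs <- .pixel_centers(seq_len(npx), ps)
  dx <- matrix(xs, npx, npx, byrow = TRUE) - cx   # columns -> x
  dy <- matrix(xs, npx, npx, byrow = FALSE) - cy  # rows -> y
  rad <- sqrt(dx^2 + dy^2)
  ang <- (atan2(dy, dx) * 180 / pi) %% 360

  frames <- vector("list", spec$n_frames)
  for (fi in seq_len(spec$n_frames)) {
    r_at <- matrix(spec$lumen_radius_fn(as.vector(ang), zs[fi]), npx, npx)
    m <- matrix(OCT_LABELS[["background"]], npx, npx)
    for (a in spec$calcium_arcs) {
      sel <- .in_arc(ang, a$start, a$end) &
        rad >= r_at + a$depth &
        rad < r_at + a$depth + matrix(a$thickness(as.vector(ang)), npx, npx)
      m[sel] <- OCT_LABELS[["calcium"]]
    }
    for (a in spec$fc_arcs) {
      sel <- .in_arc(ang, a$start, a$end) &
        rad >= r_at &
        rad < r_at + matrix(a$thickness(as.vector(ang)), npx, npx)
      m[sel] <- OCT_LABELS[["fibrous_cap"]]
    }
    m[rad < r_at] <- OCT_LABELS[["lumen"]]
    vp <- if (is.null(spec$vp_flags)) NULL else spec$vp_flags[fi, ]
    frames[[fi]] <- oct_frame(m, vp)
  }
  oct_pullback(frames, cal)
}

#' Specification of a simulated lesion cohort
#'
#' Parameters of the generative model behind [simulate_cohort()]: a latent
#' severity per patient drives a log-normal total fibrous-cap surface area
#' (FCSA-T), a set of correlated plaque features, and a Bernoulli
#' cardiovascular-death outcome through a logistic model on standardized
#' FCSA-T. The defaults mirror the reference study conditions: 104
#' patients, a 23.1% event fraction, and a generative odds ratio of 2.38
#' per standard deviation of FCSA-T.
#'
#' @param n_patients Cohort size (>= 20).
#' @param event_fraction_target Marginal event probability; the intercept
#'   is calibrated so the mean model probability matches it.
#' @param beta_fcsa Log-odds slope per SD of (raw) FCSA-T. The default 2.4
#'   makes FCSA-T discriminate the outcome at AUC of about 0.85, and
#'   implies an odds ratio of roughly 1.8 per mm^2 at the default FCSA
#'   scale. Set it to `log(2.38)` to run parameter-recovery experiments at
#'   the reference multivariate effect size.
#' @param beta0 Intercept; `NULL` (default) calibrates it to the target.
#' @param rho_nuis Latent correlation of the strongly outcome-linked
#'   nuisance plaque features with severity, in `[0, 1)`; weakly linked
#'   features use `rho_nuis / 2`.
#' @param mu_log_fcsa,sigma_log_fcsa Log-normal parameters of FCSA-T
#'   (mm^2); defaults give mean 3.0 mm^2 with SD 3.9 mm^2, the
#'   right-skewed mean >> median pattern seen in diseased cohorts.
#' @param seed Integer seed; every draw is reproducible from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 104L, event_fraction_target = 0.231,
                        beta_fcsa = 2.4, beta0 = NULL,
                        rho_nuis = 0.45, mu_log_fcsa = 0.6,
                        sigma_log_fcsa = 1.0, seed = 1L) {
  stopifnot(n_patients >= 20L, is.finite(beta_fcsa),
            rho_nuis >= 0, rho_nuis < 1,
            event_fraction_target > 0, event_fraction_target < 1)
  structure(list(n_patients = as.integer(n_patients),
                 event_fraction_target = event_fraction_target,
                 beta_fcsa = beta_fcsa, beta0 = beta0,
                 rho_nuis = rho_nuis, mu_log_fcsa = mu_log_fcsa,
                 sigma_log_fcsa = sigma_log_fcsa, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a lesion cohort with a known outcome model
#'
#' Draws `n_patients` lesions. A standard-normal latent severity `s` sets
#' FCSA-T = `exp(mu + sigma * s)` (log-normal, right-skewed); the per-class
#' surface areas split FCSA-T by a patient-level Dirichlet draw so the
#' class conservation `SA-1 + SA-2 + SA-3 = SA-T` holds exactly. The
#' nuisance features follow the tiered association pattern of a real
#' cohort: cap angle, frame cap area, calcium angle/thickness and two of
#' the vulnerable-plaque flags correlate with severity at `rho_nuis`;
#' lesion length and the remaining flags at `rho_nuis / 2`; lumen
#' area/diameter, the minimum-type calcium metrics and minimum cap
#' thickness are null features independent of severity. Burden features
#' are the surface areas normalized by a lumen-surface proxy (with
#' within-pullback profile variability), and the diameters are monotone
#' transforms of the areas, so the redundancy-pruning stage sees
#' near-duplicate features as a real cohort does. The outcome is Bernoulli
#' with `logit(p) = beta0 + beta_fcsa * standardized FCSA-T` (raw scale).
#'
#' @param spec A [cohort_spec()].
#' @return A `data.frame` (class `oct_cohort`) with the 31 feature columns
#'   (keys of [oct_features()]) plus `outcome`; the generative parameters,
#'   calibrated intercept, latent severity, standardized FCSA and event
#'   probabilities are stored in `attr(, "truth")`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  rho <- spec$rho_nuis
  w <- rho / 2
  mixr <- function(s, r) r * s + sqrt(1 - r^2) * stats::rnorm(n)

  s <- stats::rnorm(n)
  fcsa_t <- exp(spec$mu_log_fcsa + spec$sigma_log_fcsa * s)

  # per-class split of the cap: class 2 dominates; class 1 (thin caps) is
  # smallest and most variable
  gdraw <- cbind(stats::rgamma(n, 6), stats::rgamma(n, 120),
                 stats::rgamma(n, 90))
  p_cls <- gdraw / rowSums(gdraw)
  sa <- p_cls * fcsa_t

  max_fc_angle <- pmin(pmax(70 + 45 * mixr(s, rho), 5), 360)
  min_fc_angle <- stats::runif(n, 5, 40)
  max_fc_area_t <- exp(-0.3 + 0.8 * mixr(s, rho))
  max_fc_area <- p_cls * max_fc_area_t

  max_calcium_angle <- pmin(pmax(180 + 75 * mixr(s, rho), 10), 360)
  min_calcium_angle <- stats::runif(n, 5, 35)
  max_calcium_thickness <- pmin(pmax(1.3 + 0.28 * mixr(s, rho), 0.2), 2.5)
  min_calcium_thickness <- pmin(pmax(0.27 + 0.07 * stats::rnorm(n), 0.05), 1)
  max_calcium_depth <- pmin(pmax(0.5 + 0.19 * stats::rnorm(n), 0.02), 1.5)
  min_calcium_depth <- pmin(pmax(0.012 + 0.012 * stats::rnorm(n), 0), 0.2)
  lesion_length <- exp(log(30) + 0.4 * mixr(s, w))

  avg_lumen_area <- exp(log(5.4) + 0.43 * stats::rnorm(n))
  min_lumen_area <- avg_lumen_area * stats::runif(n, 0.25, 0.5)
  avg_lumen_diameter <- 2 * sqrt(avg_lumen_area / pi)
  min_lumen_diameter <- 2 * sqrt(min_lumen_area / pi)
  min_fc_thickness <- pmax(0.03 + 0.02 * stats::rnorm(n), 0.005)

  # lumen surface: cylinder proxy times within-pullback profile variability
  lumen_surface <- pi * avg_lumen_diameter * lesion_length *
    exp(0.35 * stats::rnorm(n))
  burden <- 100 * sa / lumen_surface
  burden_t <- 100 * fcsa_t / lumen_surface

  prev <- list(microchannel = c(0.19, w),
               macrophage_infiltration = c(0.68, w),
               cholesterol_crystal = c(0.28, rho),
               layered_plaque = c(0.11, rho),
               calcium_nodule = c(0.15, w))
  vp <- vapply(prev, function(p)
    as.numeric(mixr(s, p[2]) > stats::qnorm(1 - p[1])), numeric(n))

  z <- as.numeric(scale(fcsa_t))
  beta0 <- spec$beta0
  if (is.null(beta0)) {
    f <- function(b0) mean(stats::plogis(b0 + spec$beta_fcsa * z)) -
      spec$event_fraction_target
    lo <- f(-50); hi <- f(50)
    if (lo > 0 || hi < 0)
      stop("event_fraction_target unattainable under the given coefficients")
    beta0 <- stats::uniroot(f, c(-50, 50), tol = 1e-10)$root
  }
  p_event <- stats::plogis(beta0 + spec$beta_fcsa * z)
  outcome <- stats::rbinom(n, 1L, p_event)

  tab <- data.frame(
    lesion_length = lesion_length,
    min_lumen_area = min_lumen_area, avg_lumen_area = avg_lumen_area,
    min_lumen_diameter = min_lumen_diameter,
    avg_lumen_diameter = avg_lumen_diameter,
    max_calcium_angle = max_calcium_angle,
    min_calcium_angle = min_calcium_angle,
    max_calcium_thickness = max_calcium_thickness,
    min_calcium_thickness = min_calcium_thickness,
    max_calcium_depth = max_calcium_depth,
    min_calcium_depth = min_calcium_depth,
    max_fc_angle = max_fc_angle, min_fc_angle = min_fc_angle,
    min_fc_thickness = min_fc_thickness,
    max_fc_area_1 = max_fc_area[, 1], max_fc_area_2 = max_fc_area[, 2],
    max_fc_area_3 = max_fc_area[, 3], max_fc_area_t = max_fc_area_t,
    fc_surface_area_1 = sa[, 1], fc_surface_area_2 = sa[, 2],
    fc_surface_area_3 = sa[, 3], fc_surface_area_t = fcsa_t,
    fc_burden_1 = burden[, 1], fc_burden_2 = burden[, 2],
    fc_burden_3 = burden[, 3], fc_burden_t = burden_t,
    microchannel = vp[, "microchannel"],
    macrophage_infiltration = vp[, "macrophage_infiltration"],
    cholesterol_crystal = vp[, "cholesterol_crystal"],
    layered_plaque = vp[, "layered_plaque"],
    calcium_nodule = vp[, "calcium_nodule"],
    outcome = outcome
  )
  # SA-1+SA-2+SA-3 must equal SA-T exactly (left-associated float sums)
  tab$fc_surface_area_t <- tab$fc_surface_area_1 + tab$fc_surface_area_2 +
    tab$fc_surface_area_3
  tab$fc_burden_t <- tab$fc_burden_1 + tab$fc_burden_2 + tab$fc_burden_3
  class(tab) <- c("oct_cohort", "data.frame")
  attr(tab, "truth") <- list(spec = spec, beta0 = beta0, severity = s,
                             p_event = p_event,
                             standardized_fcsa = z)
  tab
}
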