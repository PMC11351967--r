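test_that("angular extent counts present rays, arcs sum", {
  expect_equal(angular_extent(rep(TRUE, 360)), 360)
  expect_equal(angular_extent(rep(FALSE, 360)), 0)
  expect_equal(angular_extent(c(rep(TRUE, 45), rep(FALSE, 135),
                                rep(TRUE, 45), rep(FALSE, 135))), 90)
  # NA-coded absence behaves like FALSE
  expect_equal(angular_extent(c(rep(1.5, 90), rep(NA, 270))), 90)
  expect_error(angular_extent(rep(TRUE, 10)), ">= 36")

  # two disjoint rasterized 45-degree wedges measure 90 degrees
  sp <- lesion_spec(n_frames = 1, lumen_radius = 1.5,
                    fc_arcs = list(list(start = 0, end = 45, thickness = 0.1),
                                   list(start = 180, end = 225,
                                        thickness = 0.1)))
  pb <- rasterize(sp)
  prof <- cast_rays(pb$frames[[1]], pb$calibration)
  expect_equal(angular_extent(!is.na(prof$fc_thickness)), 90, tolerance = 0.03)
})

test_that("frame features recover the analytic circle", {
  sp <- lesion_spec(n_frames = 1, lumen_radius = 1.5)
  pb <- rasterize(sp)
  prof <- cast_rays(pb$frames[[1]], pb$calibration)
  ff <- frame_features(prof, pb$frames[[1]], pb$calibration)
  expect_equal(ff$lumen_area, pi * 1.5^2, tolerance = 0.02)
  expect_equal(ff$lumen_min_diameter, 3.0, tolerance = 0.02)
  expect_equal(ff$lumen_mean_diameter, 3.0, tolerance = 0.02)
  expect_equal(ff$lumen_circumference, 2 * pi * 1.5, tolerance = 0.02)
  expect_true(is.na(ff$fc_angle))
  expect_true(is.na(ff$calcium_angle))
})

test_that("a uniform 0.1 mm cap lands entirely in thickness class 2", {
  sp <- lesion_spec(n_frames = 1, lumen_radius = 1.5,
                    fc_arcs = list(list(start = 0, end = 360 - 1e-9,
                                        thickness = 0.1)))
  pb <- rasterize(sp)
  prof <- cast_rays(pb$frames[[1]], pb$calibration)
  ff <- frame_features(prof, pb$frames[[1]], pb$calibration)
  expect_equal(ff$fc_angle, 360)
  expect_equal(unname(ff$fc_area[["1"]]), 0)
  expect_equal(unname(ff$fc_area[["3"]]), 0)
  expect_gt(ff$fc_area[["2"]], 0)
  expect_equal(ff$fc_area[["2"]], pi * (1.6^2 - 1.5^2), tolerance = 0.05)
})

test_that("fc_class honors the printed inclusive boundaries", {
  expect_equal(fc_class(c(0.064, 0.065, 0.0651, 0.149, 0.150, 0.2)),
               c(1L, 1L, 2L, 2L, 3L, 3L))
  expect_true(is.na(fc_class(NA_real_)))
})

test_that("calcium shell phantom yields its thickness, depth and angle", {
  sp <- lesion_spec(n_frames = 1, lumen_radius = 1.5,
                    calcium_arcs = list(list(start = 0, end = 120,
                                             thickness = 0.4, depth = 0.1)))
  pb <- rasterize(sp)
  prof <- cast_rays(pb$frames[[1]], pb$calibration)
  ff <- frame_features(prof, pb$frames[[1]], pb$calibration)
  px2 <- 2 * pb$calibration$pixel_size
  expect_lte(abs(ff$calcium_max_thickness - 0.4), px2)
  expect_lte(abs(ff$calcium_min_thickness - 0.4), px2)
  expect_lte(abs(ff$calcium_max_depth - 0.1), px2)
  expect_lte(abs(ff$calcium_min_depth - 0.1), px2)
  expect_lte(abs(ff$calcium_angle - 120), 2)
})

test_that("lesion aggregation matches the analytic arc phantom", {
  sp <- arc_phantom_spec()
  pb <- rasterize(sp)
  q <- quantify_pullback(pb)
  l <- q$lesion
  expect_equal(l$lesion_length, 10)
  expect_equal(l$fc_surface_area_t, pi / 2 * 1.5 * 10, tolerance = 0.03)
  expect_equal(l$fc_burden_t, 25, tolerance = 1)
  expect_equal(l$max_fc_angle, 90, tolerance = 2)
  expect_true(is.na(l$max_calcium_angle))

  # single frame: lesion length is one frame pitch
  sp1 <- arc_phantom_spec(n_frames = 1)
  l1 <- quantify_pullback(rasterize(sp1))$lesion
  expect_equal(l1$lesion_length, 0.2)
})

test_that("feature vectors keep the 31-entry order and propagate absence", {
  sp <- arc_phantom_spec(n_frames = 2)
  l <- quantify_pullback(rasterize(sp))$lesion
  v <- feature_vector(l)
  expect_identical(names(v), oct_feature_keys())
  expect_length(v, 31)
  # no calcium in the phantom: calcium entries 6-11 are missing
  expect_true(all(is.na(v[6:11])))
  expect_false(anyNA(v[c(1:5, 12:31)]))

  # CSV round trip is the identity
  path <- withr::local_tempfile(fileext = ".csv")
  df <- as.data.frame(as.list(v))
  names(df) <- names(v)
  write_cohort_csv(df, path)
  back <- read_cohort_csv(path)
  expect_equal(unlist(back[1, oct_feature_keys()]), v,
               ignore_attr = TRUE)
})

test_that("aggregates are invariant to frame order and skip absent frames", {
  set.seed(42)
  sp <- lesion_spec(
    n_frames = 4,
    lumen_radius = function(theta, z) 1.2 + 0.1 * sin(z),
    fc_arcs = list(list(start = 20, end = 130, thickness = 0.09)),
    calcium_arcs = list(list(start = 200, end = 260, thickness = 0.3,
                             depth = 0.15)),
    calibration = oct_calibration(0.02))
  pb <- rasterize(sp)
  cal <- pb$calibration
  ff <- lapply(pb$frames, function(f)
    frame_features(cast_rays(f, cal), f, cal))
  a1 <- aggregate_lesion(ff, cal)
  a2 <- aggregate_lesion(rev(ff), cal)
  expect_equal(feature_vector(a1), feature_vector(a2))

  # a lone calcium frame defines both max and min
  ff2 <- lapply(pb$frames, function(f)
    frame_features(cast_rays(f, cal), f, cal))
  expect_equal(a1$max_calcium_angle > 0, TRUE)
  expect_equal(a1$min_calcium_angle, min(vapply(ff2, `[[`, numeric(1),
                                                "calcium_angle")))
})

test_that("thickening a cap moves area between classes, not the total", {
  mk <- function(th) {
    sp <- lesion_spec(n_frames = 1, lumen_radius = 1.5,
                      fc_arcs = list(list(start = 0, end = 90,
                                          thickness = th)),
                      calibration = oct_calibration(0.02))
    quantify_pullback(rasterize(sp))$lesion
  }
  thin <- mk(0.05); mid <- mk(0.1); thick <- mk(0.2)
  expect_gt(thin$fc_surface_area_1, 0)
  expect_equal(thin$fc_surface_area_2 + thin$fc_surface_area_3, 0)
  expect_gt(mid$fc_surface_area_2, 0)
  expect_equal(mid$fc_surface_area_1 + mid$fc_surface_area_3, 0)
  expect_gt(thick$fc_surface_area_3, 0)
  expect_equal(thick$fc_surface_area_1 + thick$fc_surface_area_2, 0)
  # totals agree across thickness (same arc, same lumen radius)
  expect_equal(thin$fc_surface_area_t, thick$fc_surface_area_t,
               tolerance = 0.02)
  # burden stays within [0, 100]
  for (l in list(thin, mid, thick)) {
    expect_gte(l$fc_burden_t, 0)
    expect_lte(l$fc_burden_t, 100)
  }
})

test_that("vulnerable-plaque flags aggregate as any-frame presence", {
  vp <- matrix(FALSE, 3, 5)
  vp[2, 3] <- TRUE   # cholesterol crystal on one frame only
  sp <- lesion_spec(n_frames = 3, lumen_radius = 1.2, vp_flags = vp,
                    calibration = oct_calibration(0.02))
  l <- quantify_pullback(rasterize(sp))$lesion
  expect_equal(l$cholesterol_crystal, 1)
  expect_equal(l$microchannel, 0)
})
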