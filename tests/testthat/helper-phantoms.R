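# Shared fixtures, all generated in code.

# a star-shaped "blob" lumen: smooth random radius profile around a center
blob_mask <- function(seed, npx = 200L, pixel_size = 0.01) {
  set.seed(seed)
  r0 <- runif(1, 0.5, 0.8)
  a <- runif(3, 0, 0.12)
  ph <- runif(3, 0, 2 * pi)
  cx <- npx * pixel_size / 2 + runif(1, -0.1, 0.1)
  cy <- npx * pixel_size / 2 + runif(1, -0.1, 0.1)
  xs <- (seq_len(npx) - 0.5) * pixel_size
  dx <- matrix(xs, npx, npx, byrow = TRUE) - cx
  dy <- matrix(xs, npx, npx, byrow = FALSE) - cy
  th <- atan2(dy, dx)
  rb <- r0 + a[1] * cos(th + ph[1]) + a[2] * cos(2 * th + ph[2]) +
    a[3] * cos(3 * th + ph[3])
  m <- matrix(0L, npx, npx)
  m[sqrt(dx^2 + dy^2) < rb] <- 1L
  m
}

# brute-force pixel-enumeration oracles (explicit loops, no shortcuts)
oracle_centroid <- function(mask, pixel_size) {
  sx <- 0; sy <- 0; k <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] == 1L) {
      sx <- sx + (j - 0.5) * pixel_size
      sy <- sy + (i - 0.5) * pixel_size
      k <- k + 1L
    }
  }
  c(x = sx / k, y = sy / k)
}

oracle_area <- function(mask, pixel_size, label = 1L) {
  k <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] == label) k <- k + 1L
  }
  k * pixel_size^2
}

# angular extent oracle: 1-degree bins touched by any pixel of the label,
# angles measured around the lumen centroid
oracle_angular_extent <- function(mask, pixel_size, label, centroid) {
  hit <- logical(360)
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] == label) {
      ang <- atan2((i - 0.5) * pixel_size - centroid[2],
                   (j - 0.5) * pixel_size - centroid[1]) * 180 / pi
      hit[(floor(ang %% 360)) + 1L] <- TRUE
    }
  }
  sum(hit)
}

# random non-overlapping arcs partitioning a fraction of the circle
random_arcs <- function(n_arcs, thickness_range = c(0.03, 0.3)) {
  starts <- sort(runif(n_arcs, 0, 300))
  arcs <- list()
  for (i in seq_len(n_arcs)) {
    lim <- if (i < n_arcs) starts[i + 1] else 359.9
    span <- runif(1, 10, max(10.1, min(80, lim - starts[i])))
    arcs[[i]] <- list(start = starts[i],
                      end = min(starts[i] + span, lim - 0.5),
                      thickness = runif(1, thickness_range[1],
                                        thickness_range[2]))
  }
  arcs
}

# randomized small phantom for conservation / round-trip batteries
random_phantom <- function(seed, n_frames = 2L, pixel_size = 0.02) {
  set.seed(seed)
  r0 <- runif(1, 1.0, 1.8)
  arcs <- random_arcs(sample(1:3, 1))
  # occasionally ramp the thickness across the arc
  if (runif(1) < 0.5) {
    a <- arcs[[1]]
    t0 <- runif(1, 0.03, 0.08); t1 <- runif(1, 0.12, 0.3)
    arcs[[1]]$thickness <- local({
      s <- a$start; e <- a$end; t0 <- t0; t1 <- t1
      function(theta) t0 + (t1 - t0) * (theta - s) / (e - s)
    })
  }
  lesion_spec(n_frames = n_frames, lumen_radius = r0, fc_arcs = arcs,
              calibration = oct_calibration(pixel_size))
}

# rotate a square mask by +90 degrees in the package's angle convention
rot90_mask <- function(m) t(m)[, nrow(m):1]

# standard 90-degree arc phantom used throughout
arc_phantom_spec <- function(n_frames = 50L, pixel_size = 0.01) {
  lesion_spec(n_frames = n_frames, lumen_radius = 1.5,
              fc_arcs = list(list(start = 0, end = 90, thickness = 0.1)),
              calibration = oct_calibration(pixel_size))
}
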