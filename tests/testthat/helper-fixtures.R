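# Shared fixtures, built once per test run.

# default synthetic shoulder (expensive enough to cache)
.fixture_env <- new.env(parent = emptyenv())

default_gen <- function() {
  if (is.null(.fixture_env$gen)) .fixture_env$gen <- generate_shoulder(shoulder_spec())
  .fixture_env$gen
}

default_measures <- function() {
  if (is.null(.fixture_env$ms))
    .fixture_env$ms <- measure_all(default_gen()$model)
  .fixture_env$ms
}

measures_vec <- function(ms) unlist(as.data.frame(ms))

# canonical landmarks whose frame is the identity at the origin
canonical_landmarks <- function(radius = 14, n = 12) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  scapular_landmarks(glenoid_rim = cbind(0, radius * cos(th), radius * sin(th)),
                     B = c(-100, 0, 0), C = c(-40, -120, 0),
                     AM = c(21, 15, 8), PM = c(21, 5, -14),
                     anterior_witness = c(0, 10, 30), side = "right")
}

canonical_frame <- function() build_frame(canonical_landmarks())

# minimal hand-built shoulder model from axis-aligned boxes (canonical frame)
block_model <- function(acr_x = c(6, 20), acr_y = c(10, 18), acr_z = c(-20, 6),
                        clav_x = c(-40, 10), clav_y = c(19, 29),
                        clav_z = c(-12, 0),
                        hum_center = c(12, -30, -7), hum_r = 24,
                        landmarks = canonical_landmarks()) {
  acr <- box_mesh_test(acr_x, acr_y, acr_z)
  scap <- tri_mesh(acr$vertices, acr$faces,
                   labels = rep("acromion", nrow(acr$vertices)))
  clav <- box_mesh_test(clav_x, clav_y, clav_z)
  clav <- tri_mesh(clav$vertices, clav$faces,
                   labels = rep("distal", nrow(clav$vertices)))
  hum <- sphere_mesh_test(hum_center, hum_r)
  shoulder_model(scap, clav, hum, landmarks, side = "right")
}

box_mesh_test <- function(xlim, ylim, zlim, step = 2) {
  acromion3d:::box_mesh(xlim, ylim, zlim, step = step)
}

sphere_mesh_test <- function(center, radius, n_theta = 16L, n_phi = 24L) {
  acromion3d:::uv_sphere(center, radius, n_theta, n_phi)
}

# independent circle-fit oracle: coarse-to-fine 2D grid search over the
# center (radius = mean distance), minimizing summed squared radial residuals
circle_oracle_2d <- function(xy, span = 5, iters = 4L, grid_n = 21L) {
  ctr <- colMeans(xy)
  for (it in seq_len(iters)) {
    gx <- seq(ctr[1L] - span, ctr[1L] + span, length.out = grid_n)
    gy <- seq(ctr[2L] - span, ctr[2L] + span, length.out = grid_n)
    best <- NULL
    for (cx in gx) for (cy in gy) {
      d <- sqrt((xy[, 1L] - cx)^2 + (xy[, 2L] - cy)^2)
      r <- mean(d)
      sse <- sum((d - r)^2)
      if (is.null(best) || sse < best$sse)
        best <- list(center = c(cx, cy), radius = r, sse = sse)
    }
    ctr <- best$center
    span <- span / (grid_n - 1) * 4
  }
  best
}

# independent plane-fit oracle: direct minimization of squared orthogonal
# distances over spherical normal angles
plane_oracle <- function(points) {
  obj <- function(ang) {
    n <- c(sin(ang[1L]) * cos(ang[2L]), sin(ang[1L]) * sin(ang[2L]),
           cos(ang[1L]))
    d <- points %*% n
    sum((d - mean(d))^2)
  }
  best <- NULL
  for (t0 in seq(0.2, pi - 0.2, length.out = 5))
    for (p0 in seq(0, 2 * pi, length.out = 7)) {
      o <- stats::optim(c(t0, p0), obj, method = "Nelder-Mead")
      if (is.null(best) || o$value < best$value) best <- o
    }
  ang <- best$par
  c(sin(ang[1L]) * cos(ang[2L]), sin(ang[1L]) * sin(ang[2L]), cos(ang[1L]))
}

angle_between_deg <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  acos(pmin(pmax(abs(sum(u * v)), -1), 1)) * 180 / pi
}

scale_model <- function(model, s) {
  acromion3d:::transform_model(model, function(p) p * s)
}

# every edge of a closed mesh appears exactly twice, in opposite directions
expect_watertight <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  fwd <- paste(he[, 1L], he[, 2L])
  rev <- paste(he[, 2L], he[, 1L])
  expect_true(!any(duplicated(fwd)))
  expect_true(all(fwd %in% rev))
}
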