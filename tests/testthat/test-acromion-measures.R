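test_that("find_MLPA returns the lateral apex and applies the tie rule", {
  gen <- default_gen()
  model <- gen$model
  fr <- build_frame(model$landmarks)
  mlpa <- find_MLPA(model, fr)
  expect_equal(mlpa$point, gen$truth$mlpa, tolerance = 1e-9)

  # block acromion: every max-x vertex ties; lowest y then lowest z wins
  m <- block_model()
  frb <- canonical_frame()
  mlpa <- find_MLPA(m, frb)
  expect_equal(mlpa$point, c(20, 10, -20), tolerance = 1e-9)
})

test_that("measure_AHI: construction value, monotonicity, no-overhang flag", {
  fr <- canonical_frame()
  m <- block_model(hum_center = c(12, 10 - 8.1 - 24, -8), hum_r = 24)
  ahi <- measure_AHI(m, fr)
  expect_equal(ahi$value, 8.1, tolerance = 1e-9)
  expect_false(ahi$no_overhang)

  # raising the humeral head by 1 mm shortens the interval by exactly 1 mm
  m2 <- m
  m2$humerus <- rigid_transform(m$humerus, diag(3), c(0, 1, 0))
  expect_equal(measure_AHI(m2, fr)$value, 7.1, tolerance = 1e-9)

  # humeral head entirely anterior of the undersurface z-range
  m3 <- block_model(hum_center = c(12, 10 - 8.1 - 24, 40), hum_r = 24)
  expect_true(measure_AHI(m3, fr)$no_overhang)

  # brute-force oracle: min distance over all undersurface vertices
  acr <- acromion3d:::submesh_by_label(m$scapula, "acromion")
  vn <- vertex_normals(acr)
  under <- acr$vertices[vn[, 2] < -0.2, , drop = FALSE]
  H <- m$humerus$vertices[which.max(m$humerus$vertices[, 2]), ]
  oracle <- min(apply(under, 1, function(p)
    sqrt((p[2] - H[2])^2 + (p[3] - H[3])^2)))
  expect_equal(ahi$value, oracle, tolerance = 1e-12)
})

test_that("measure_AAP: construction value and clamp rule", {
  fr <- canonical_frame()
  m <- block_model(acr_z = c(-20, 6.8), clav_z = c(-12, 0))
  aap <- measure_AAP(m, fr)
  expect_equal(aap$value, 6.8, tolerance = 1e-9)
  expect_false(aap$clamped)

  m2 <- block_model(acr_z = c(-20, -2), clav_z = c(-12, 0))
  aap2 <- measure_AAP(m2, fr)
  expect_equal(aap2$value, 0)
  expect_true(aap2$clamped)
})

test_that("protrusion distance against a tilted line matches the closed form", {
  # line through (0,0) at 30 degrees, probe above it
  t <- seq(-20, 20, by = 1)
  line_pts <- cbind(t * cos(pi / 6), t * sin(pi / 6))
  probe <- c(4, 9)
  got <- acromion3d:::protrusion_vs_line(line_pts, probe,
                                         positive_toward = c(0, 1))
  dir <- c(cos(pi / 6), sin(pi / 6))
  expected <- abs(dir[1] * probe[2] - dir[2] * probe[1])
  expect_equal(got$value, expected, tolerance = 1e-9)
})

test_that("measure_AIP: construction value and clamp rule", {
  fr <- canonical_frame()
  m <- block_model(clav_y = c(19, 29))
  aip <- measure_AIP(m, fr)
  expect_equal(aip$value, 9, tolerance = 1e-9)

  m2 <- block_model(clav_y = c(5, 15))  # clavicle below the acromion
  aip2 <- measure_AIP(m2, fr)
  expect_equal(aip2$value, 0)
  expect_true(aip2$clamped)
})

test_that("measure_AC_angle matches closed forms", {
  fr <- canonical_frame()
  lm <- canonical_landmarks()
  lm$AM <- c(0, 15, 8); lm$PM <- c(0, 5, -14)
  m <- block_model(landmarks = lm)  # MLPA projects to (20, 10) in x-y
  expect_equal(measure_AC_angle(m, fr), 2 * atan(5 / 20) * 180 / pi,
               tolerance = 1e-9)

  lm$AM <- c(10, 20, 8); lm$PM <- c(10, 0, -14)  # symmetric, orthogonal rays
  m <- block_model(landmarks = lm)
  expect_equal(measure_AC_angle(m, fr), 90, tolerance = 1e-9)

  # random configurations vs independent dot-product computation
  set.seed(14)
  for (i in 1:5) {
    am <- c(runif(1, -10, 15), runif(1, 12, 30), 8)
    pm <- c(runif(1, -10, 15), runif(1, -10, 8), -14)
    lm$AM <- am; lm$PM <- pm
    m <- block_model(landmarks = lm)
    v1 <- am[1:2] - c(20, 10); v2 <- pm[1:2] - c(20, 10)
    expected <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    expect_equal(measure_AC_angle(m, fr), expected, tolerance = 1e-9)
  }

  lm$AM <- c(20, 10, 8)  # coincides with the MLPA in projection
  m <- block_model(landmarks = lm)
  expect_error(measure_AC_angle(m, fr), "coincides")
})

test_that("split_acromion partitions at the MLPA plane, boundary anterior", {
  gen <- default_gen()
  model <- gen$model
  fr <- build_frame(model$landmarks)
  sp <- split_acromion(model, fr)
  expect_equal(sum(sp$anterior) + sum(sp$posterior), nrow(sp$local))
  expect_true(all(sp$local[sp$anterior, 3] >= sp$z_cut))
  expect_true(all(sp$local[sp$posterior, 3] < sp$z_cut))
  # the apex vertex sits exactly on the cut plane and goes anterior
  apex <- which.min(abs(sp$local[, 3] - sp$z_cut) +
                    abs(sp$local[, 1] - gen$truth$mlpa[1]))
  expect_true(sp$anterior[apex])
})

test_that("localize_AALP finds the crease border; no lobe means empty", {
  gen <- default_gen()
  model <- gen$model
  fr <- build_frame(model$landmarks)
  sp <- split_acromion(model, fr)
  reg <- localize_AALP(model, fr, split = sp)
  expect_false(reg$empty)
  expect_gte(nrow(reg$border), 3)
  # border points in the anterior half
  expect_true(all(reg$border[, 3] >= sp$z_cut))
  # each detected point within 1 mm of the analytic crease at its height
  h <- shoulder_spec()$thickness
  for (i in seq_len(nrow(reg$border))) {
    t <- (reg$border[i, 2] - 10) / h
    truth <- gen$truth$crease$at(t)
    expect_lt(sqrt(sum((reg$border[i, c(1, 3)] - truth[c(1, 3)])^2)), 1)
  }

  g0 <- generate_shoulder(shoulder_spec(lobe_depth = 0))
  fr0 <- build_frame(g0$model$landmarks)
  reg0 <- localize_AALP(g0$model, fr0)
  expect_true(reg0$empty)
})

test_that("AALP border is stable under tessellation refinement", {
  ms1 <- as.data.frame(measure_all(generate_shoulder(
    shoulder_spec(mesh_step = 1.0))$model))
  ms2 <- as.data.frame(measure_all(generate_shoulder(
    shoulder_spec(mesh_step = 0.55))$model))
  expect_lt(abs(ms1$a - ms2$a), 0.2)
  expect_lt(abs(ms1$b - ms2$b), 0.2)
})

test_that("measure_AALP_params: empty region and similarity scaling", {
  gen <- default_gen()
  ms <- default_measures()
  expect_true(ms$c <= ms$c_plus_d)
  expect_gt(ms$ratio_percent, 0)
  expect_lt(ms$ratio_percent, 100)

  g0 <- generate_shoulder(shoulder_spec(lobe_depth = 0))
  ms0 <- measure_all(g0$model)
  expect_true(is.na(ms0$a) && is.na(ms0$b) && is.na(ms0$ratio_percent))
  expect_true(ms0$flags$aalp_empty)

  s <- 1.3
  ms_s <- measure_all(scale_model(gen$model, s))
  for (p in c("AHI", "AAP", "AIP", "c", "c_plus_d"))
    expect_equal(ms_s[[p]], s * ms[[p]], tolerance = 1e-6)
  expect_equal(ms_s$a, s * ms$a, tolerance = 0.03)
  expect_equal(ms_s$b, s * ms$b, tolerance = 0.03)
  expect_equal(ms_s$AC_angle, ms$AC_angle, tolerance = 1e-6)
  expect_equal(ms_s$ratio_percent, ms$ratio_percent, tolerance = 1e-6)
})

test_that("measure_all returns a complete annotated measurement set", {
  ms <- default_measures()
  expect_s3_class(ms, "measurement_set")
  df <- as.data.frame(ms)
  expect_named(df, c("AHI", "AAP", "AIP", "AC_angle", "a", "b", "c",
                     "c_plus_d", "ratio_percent"))
  expect_true(all(is.finite(unlist(df))))
  expect_false(ms$flags$aalp_empty)
  expect_equal(ms$provenance$glenoid_radius, 14, tolerance = 0.01 * 14)
  expect_output(print(ms), "AC angle")
})
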