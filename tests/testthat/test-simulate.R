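test_that("zero density gives an empty scene; positions stay in the frustum", {
  empty <- simulate_scene(0, 3000, seed = 1)
  expect_equal(nrow(empty), 0)

  cam <- camera_model()
  scene <- simulate_scene(200, 2000, cam, seed = 2)
  expect_gt(nrow(scene), 0)
  tan_h <- tan(cam$hfov_deg / 2 * pi / 180)
  tan_v <- tan(cam$vfov_deg / 2 * pi / 180)
  expect_true(all(scene$z_mm > 0 & scene$z_mm <= 2000))
  expect_true(all(abs(scene$x_mm) <= scene$z_mm * tan_h))
  expect_true(all(abs(scene$y_mm) <= scene$z_mm * tan_v))
  expect_true(all(scene$length_mm >= 31 & scene$length_mm <= 60))
  expect_true(all(scene$orientation_deg > -180 &
                    scene$orientation_deg <= 180))
})

test_that("scene counts are Poisson with mean density times frustum volume", {
  cam <- camera_model()
  vol <- attr(simulate_scene(0, 1000, cam, seed = 1), "frustum_volume_m3")
  lambda <- 100 * vol
  set.seed(55)
  counts <- vapply(1:200, function(i)
    nrow(simulate_scene(100, 1000, cam)), numeric(1))
  se <- sqrt(lambda / 200)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("analytic frustum volume matches rejection-sampled measure", {
  cam <- camera_model()
  r <- 2500
  tan_h <- tan(cam$hfov_deg / 2 * pi / 180)
  tan_v <- tan(cam$vfov_deg / 2 * pi / 180)
  set.seed(77)
  n <- 2e5
  z <- runif(n, 0, r)
  x <- runif(n, -r * tan_h, r * tan_h)
  y <- runif(n, -r * tan_v, r * tan_v)
  inside <- abs(x) <= z * tan_h & abs(y) <= z * tan_v
  box_m3 <- (2 * r * tan_h / 1000) * (2 * r * tan_v / 1000) * (r / 1000)
  mc <- mean(inside) * box_m3
  se <- sd(inside) / sqrt(n) * box_m3
  analytic <- attr(simulate_scene(0, r, cam, seed = 1), "frustum_volume_m3")
  expect_lt(abs(mc - analytic), 3 * se)
})

test_that("projection follows the pinhole model with orientation and axial floor", {
  cam <- camera_model()
  # a median krill at median orientation at the primary-range geometry
  # images at the primary boundary size
  px_at <- function(len_mm, orient_deg, z_mm, axial_frac = 0) {
    scene <- data.frame(x_mm = 0, y_mm = 0, z_mm = z_mm,
                        length_mm = len_mm, orientation_deg = orient_deg,
                        axial_width_mm = axial_frac * len_mm)
    project_to_image(scene, cam)$imaged_length_px
  }
  r <- volume_from_boundary(34.4)$resolvable_range_mm
  expect_equal(px_at(42 / sqrt(2), 0, r), 34.4, tolerance = 1e-6)

  # normal incidence images the full length
  expect_equal(px_at(50, 0, 1000), 50 * 960 / (2 * 1000 * tan(12 * pi / 180)))
  # end-on, only the body width is seen
  expect_equal(px_at(50, 90, 1000, axial_frac = 0.1), px_at(5, 0, 1000),
               tolerance = 1e-9)
  # pinhole scaling: doubling range halves imaged size
  expect_equal(px_at(50, 30, 2000), px_at(50, 30, 1000) / 2)

  expect_error(project_to_image(
    data.frame(x_mm = 0, y_mm = 0, z_mm = -1, length_mm = 10,
               orientation_deg = 0, axial_width_mm = 1), cam),
    "positive")
})

test_that("hard-threshold resolvability is exactly the range indicator", {
  scene <- simulate_scene(100, 3000, seed = 9)
  proj <- project_to_image(scene)
  a <- assign_resolvability(proj, true_r_res_mm = 1500,
                            blur_fraction = 0, logistic_scale_mm = 0)
  expect_equal(a$resolvability == "resolvable", proj$range_mm < 1500)
  expect_true(all(a$subtype %in% c("plain", "none")))
})

test_that("blur contaminates the unresolvable class with large objects", {
  scene <- simulate_scene(150, 3000, seed = 10)
  proj <- project_to_image(scene)
  a <- assign_resolvability(proj, true_r_res_mm = 1500,
                            blur_fraction = 0.1, seed = 10)
  res_px <- a$imaged_length_px[a$resolvability == "resolvable"]
  unres_px <- a$imaged_length_px[a$resolvability == "unresolvable"]
  # size distributions overlap: some unresolvable objects out-size some
  # resolvable ones
  expect_gt(max(unres_px), min(res_px))
  overlap <- mean(unres_px > quantile(res_px, 0.05))
  expect_gt(overlap, 0)
})

test_that("soft boundaries produce mixed calls in the marginal region", {
  scene <- simulate_scene(150, 3000, seed = 12)
  proj <- project_to_image(scene)
  a <- assign_resolvability(proj, true_r_res_mm = 1500,
                            logistic_scale_mm = 200, seed = 12)
  marginal <- proj$range_mm > 1300 & proj$range_mm < 1700
  calls <- a$resolvability[marginal]
  expect_true(all(c("resolvable", "unresolvable") %in% calls))
})

test_that("subtype flags are sampled at the requested rates", {
  scene <- simulate_scene(300, 2000, seed = 14)
  proj <- project_to_image(scene)
  a <- assign_resolvability(proj, true_r_res_mm = 1900, seed = 14,
                            subtype_rates = c(bent = 0.1, partial = 0.05,
                                              axial = 0, motion_blurred = 0))
  res <- as.data.frame(a)[a$resolvability == "resolvable", ]
  expect_equal(mean(res$subtype == "bent"), 0.1, tolerance = 0.5)
  expect_true(all(res$subtype %in% c("plain", "bent", "partial")))
})

test_that("datasets regenerate byte-identically under a fixed seed", {
  s1 <- generate_dataset(40, n_images = 6, true_r_res_mm = 1500, seed = 3)
  s2 <- generate_dataset(40, n_images = 6, true_r_res_mm = 1500, seed = 3)
  expect_identical(as.data.frame(s1$annotations),
                   as.data.frame(s2$annotations))
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_dataset(40, n_images = 6, true_r_res_mm = 1500, seed = 4)
  expect_false(identical(as.data.frame(s1$annotations),
                         as.data.frame(s3$annotations)))
})

test_that("generator bookkeeping matches its analytic frustum volumes", {
  sim <- generate_dataset(48, n_images = 124, true_r_res_mm = 1950, seed = 6)
  ledger <- sim$truth$per_image_counts
  expect_equal(nrow(ledger), 124)
  # mean within-range count ~= density x within-range volume
  lambda <- 48 * sim$truth$within_range_volume_m3
  se <- sqrt(lambda / 124)
  expect_lt(abs(mean(ledger$n_within_range) - lambda), 3 * se)
  # total count ~= density x full frustum volume
  lambda_tot <- 48 * sim$truth$frustum_volume_m3
  expect_lt(abs(mean(ledger$n_total) - lambda_tot),
            3 * sqrt(lambda_tot / 124))
  # the truth ledger serialises to JSON
  p <- tempfile(fileext = ".json")
  write_truth_ledger(sim$truth, p)
  back <- jsonlite::read_json(p)
  expect_equal(back$true_density, 48)
})

test_that("guardrail rejects absurd expected counts", {
  expect_error(simulate_scene(1e9, 1e5, seed = 1), "1e7|exceeds")
})
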