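# Synthetic cohort generator: determinism, geometry, outcome model.

test_that("patient generation is deterministic and response-consistent", {
  cfg <- cohort_config(n_patients = 3, seed = 11)
  p1 <- generate_patient(cfg, 1)
  p2 <- generate_patient(cfg, 1)
  expect_identical(p1$before$volume$data, p2$before$volume$data)
  expect_identical(p1$after$rois$tumor, p2$after$rois$tumor)
  expect_identical(p1$latent_response, p2$latent_response)
  # different index -> different image
  p3 <- generate_patient(cfg, 2)
  expect_false(identical(p1$before$volume$data, p3$before$volume$data))
  # zero response: after equals before exactly (shared noise draws)
  p0 <- generate_patient(cfg, 1, latent_response = 0)
  expect_identical(p0$before$rois$tumor, p0$after$rois$tumor)
  expect_identical(p0$before$volume$data, p0$after$volume$data)
  # positive response shrinks the tumor
  expect_lt(sum(p1$after$rois$tumor), sum(p1$before$rois$tumor))
})

test_that("tumor and bladder volumes match their analytic sizes", {
  cfg <- cohort_config(n_patients = 2, grid_shape = c(40L, 40L, 40L),
                       voxel_spacing = c(1, 1, 1),
                       tumor_radius_range = c(10, 10),
                       tumor_anisotropy = c(1, 1), seed = 21)
  p <- generate_patient(cfg, 1)
  v_sphere <- 4 / 3 * pi * 10^3
  expect_lt(abs(sum(p$before$rois$tumor) - v_sphere) / v_sphere, 0.2)
  # bladder ~1 cm^3 within 20% at the default grid
  cfg2 <- cohort_config(n_patients = 2, seed = 22)
  p2 <- generate_patient(cfg2, 1)
  vox_mm3 <- prod(cfg2$voxel_spacing)
  expect_lt(abs(sum(p2$before$rois$bladder) * vox_mm3 - 1000) / 1000, 0.2)
  # urine is bright and nearly constant
  urine <- p2$before$volume$data[p2$before$rois$bladder]
  expect_gt(mean(urine), 2 * mean(p2$before$volume$data[p2$before$rois$tumor]))
  expect_lt(sd(urine) / mean(urine), 0.05)
})

test_that("oversized tumors fail naming the offending dimension", {
  cfg <- cohort_config(n_patients = 2, grid_shape = c(4L, 40L, 40L),
                       voxel_spacing = c(1, 1, 1),
                       tumor_radius_range = c(10, 10),
                       tumor_anisotropy = c(1, 1), seed = 3)
  expect_error(generate_patient(cfg, 1), "dimension z")
})

test_that("after-tumor volume is non-increasing in latent response", {
  cfg <- cohort_config(n_patients = 2, seed = 31)
  grid <- seq(0, 1, by = 0.25)
  vols <- vapply(grid, function(r)
    sum(generate_patient(cfg, 1, latent_response = r)$after$rois$tumor),
    numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("simulate_survival honors censoring and effect direction", {
  # no censoring: every subject has an event
  o <- simulate_survival(rep(0, 200), 0.05, censor_horizon = Inf,
                         censor_rate = 0, seed = 4)
  expect_equal(mean(o$event), 1)
  expect_true(all(o$time > 0))
  expect_error(simulate_survival(rep(0, 5), -1), "positive")
  expect_error(simulate_survival(c(0, Inf), 0.1), "finite")
  # null scores: concordance with outcomes ~ 0.5
  set.seed(5)
  sc <- rnorm(500)
  o2 <- simulate_survival(rep(0, 500), 0.02, 60, 0.25, seed = 6)
  expect_lt(abs(c_index(sc, o2$time, o2$event)$C - 0.5), 0.05)
  # strong positive coefficient: higher score -> earlier events
  set.seed(7)
  sc3 <- rnorm(400)
  o3 <- simulate_survival(3 * sc3, 0.02, Inf, 0, seed = 8)
  expect_lt(cor(sc3, o3$time, method = "kendall"), 0)
})

test_that("censored fraction matches its analytic expectation", {
  h <- 0.02; H <- 60; cr <- 0.3
  o <- simulate_survival(rep(0, 1000), h, H, cr, seed = 9)
  expected <- (1 - cr) * exp(-h * H) + cr * (1 - exp(-h * H)) / (h * H)
  expect_lt(abs(mean(o$event == 0) - expected), 0.05)
})

test_that("split_cohort gives rounded 2:1 sizes deterministically", {
  ids <- sprintf("P%03d", 1:101)
  sp <- split_cohort(ids, c(2, 1), seed = 10)
  expect_length(sp$training, 67)
  expect_length(sp$validation, 34)
  expect_setequal(c(sp$training, sp$validation), ids)
  expect_length(intersect(sp$training, sp$validation), 0)
  sp2 <- split_cohort(ids, c(2, 1), seed = 10)
  expect_identical(sp, sp2)
  sp3 <- split_cohort(letters[1:3], c(2, 1), seed = 1)
  expect_length(sp3$training, 2)
  expect_length(sp3$validation, 1)
  expect_error(split_cohort("a", c(2, 1)), "at least 2")
})

test_that("generate_cohort outcomes cover every patient and endpoint", {
  cfg <- cohort_config(n_patients = 4, seed = 41,
                       hazard_coefficients = c(latent_response = 1))
  ch <- generate_cohort(cfg)
  oc <- ch$outcomes
  expect_equal(nrow(oc), 4 * 3)
  expect_setequal(unique(oc$endpoint), c("LR", "DM", "DFS"))
  expect_equal(as.integer(table(oc$patient_id)), rep(3L, 4))
  expect_true(all(oc$time > 0))
  expect_true(all(oc$event %in% 0:1))
  # cohort-level determinism
  ch2 <- generate_cohort(cfg)
  expect_identical(ch$outcomes, ch2$outcomes)
  expect_identical(ch$scores, ch2$scores)
})

test_that("feature-driven hazards use the named delta features", {
  cfg <- cohort_config(n_patients = 3, seed = 51)
  ch <- generate_cohort(cfg, keep_images = FALSE)
  expect_equal(dim(ch$delta3d), c(3L, 55L))
  expect_identical(colnames(ch$delta3d), feature_registry())
  expect_error(generate_cohort(
    cohort_config(n_patients = 2, seed = 1,
                  hazard_coefficients = c(NotAFeature = 1))),
    "unknown hazard feature")
})
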