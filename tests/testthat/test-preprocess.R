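# Normalization, quantization, resampling and slice selection.

mk_vol <- function(arr, spacing = c(1, 1, 1)) image_volume(arr, spacing)

test_that("Collewet clip matches hand-computed mean +/- 3 SD bounds", {
  vals <- c(rep(10, 19), 200)            # one genuine > mu + 3 sigma outlier
  arr <- array(vals, c(1, 1, 20))
  mask <- array(TRUE, c(1, 1, 20))
  out <- collewet_normalize(mk_vol(arr), mask)
  mu <- mean(vals)
  s <- sqrt(mean((vals - mu)^2))
  expect_equal(as.numeric(out$data),
               pmin(pmax(vals, mu - 3 * s), mu + 3 * s))
  expect_true(any(out$data != arr))      # the 200 is clipped to the bound
  # constant ROI: unchanged, with a note
  expect_message(cst <- collewet_normalize(mk_vol(array(5, c(2, 2, 2))),
                                           array(TRUE, c(2, 2, 2))),
                 "zero in-mask variance")
  expect_equal(cst$data, array(5, c(2, 2, 2)))
  # in-band values untouched
  v2 <- array(c(1, 2, 3, 4), c(1, 2, 2))
  out2 <- collewet_normalize(mk_vol(v2), array(TRUE, c(1, 2, 2)))
  expect_equal(out2$data, v2)
  # out-of-mask voxels never modified
  m3 <- array(FALSE, c(1, 1, 20)); m3[1, 1, 1:19] <- TRUE
  out3 <- collewet_normalize(mk_vol(arr), m3)
  expect_equal(out3$data[1, 1, 20], 200)
})

test_that("urine normalization rescales to unit bladder mean", {
  arr <- array(100, c(2, 4, 4))
  bl <- array(FALSE, c(2, 4, 4)); bl[1, 1:2, 1:2] <- TRUE
  arr[bl] <- 200
  out <- urine_normalize(mk_vol(arr), bl)
  expect_equal(mean(out$data[bl]), 1)
  expect_equal(out$data[2, 4, 4], 0.5)
  # idempotent after the first pass
  out2 <- urine_normalize(out, bl)
  expect_equal(out2$data, out$data)
  # random volume: in-mask mean is 1 to machine precision
  set.seed(1)
  rnd <- array(runif(32, 50, 300), c(2, 4, 4))
  expect_equal(mean(urine_normalize(mk_vol(rnd), bl)$data[bl]), 1)
  expect_error(urine_normalize(mk_vol(array(-1, c(2, 4, 4))), bl),
               "non-positive")
  expect_error(urine_normalize(mk_vol(arr), array(FALSE, c(2, 4, 4))),
               "empty")
})

test_that("quantization maps the urine mean to the top level", {
  expect_identical(deltarad:::quantize_levels(1.0, 64L), 64L)
  expect_identical(deltarad:::quantize_levels(0.0, 64L), 1L)
  expect_identical(deltarad:::quantize_levels(1 / 128, 64L), 1L)
  expect_identical(deltarad:::quantize_levels(1 / 64, 64L), 1L)
  expect_identical(deltarad:::quantize_levels(1 / 64 + 1e-9, 64L), 2L)
  expect_identical(deltarad:::quantize_levels(2.5, 64L), 64L)
  expect_identical(deltarad:::quantize_levels(-3, 64L), 1L)
  expect_error(deltarad:::quantize_levels(0.5, 1L), "at least 2")
  set.seed(2)
  q <- quantize(mk_vol(array(runif(60, -0.2, 1.4), c(3, 4, 5))),
                array(TRUE, c(3, 4, 5)))
  expect_true(all(q$levels[q$mask] >= 1 & q$levels[q$mask] <= 64))
})

test_that("isotropic resampling preserves constants, identity and volume", {
  set.seed(4)
  arr <- array(runif(4 * 6 * 6), c(4, 6, 6))
  mask <- array(FALSE, c(4, 6, 6)); mask[2:3, 2:5, 2:5] <- TRUE
  # already isotropic 1 mm: identity to interpolation tolerance
  iso <- resample_isotropic_3d(mk_vol(arr), list(tumor = mask))
  expect_equal(dim(iso$volume$data), c(4L, 6L, 6L))
  expect_lt(max(abs(iso$volume$data - arr)), 1e-6)
  expect_identical(iso$masks$tumor, mask)
  # constant stays constant under anisotropic resampling
  cst <- resample_isotropic_3d(mk_vol(array(7, c(4, 6, 6)),
                                      spacing = c(4, 0.5, 0.5)),
                               list(tumor = mask))
  expect_equal(unique(as.numeric(cst$volume$data)), 7)
  # 2 mm input: ~8x the voxel count within rounding
  two <- resample_isotropic_3d(mk_vol(arr, spacing = c(2, 2, 2)),
                               list(tumor = mask))
  expect_equal(dim(two$volume$data), c(8L, 12L, 12L))
  expect_equal(sum(two$masks$tumor), 8 * sum(mask), tolerance = 0.35)
  expect_error(resample_isotropic_3d(mk_vol(arr, spacing = c(0.2, 0.2, 0.2)),
                                     list(tumor = array(FALSE, c(4, 6, 6)))),
               "empty")
})

test_that("largest-slice selection obeys the low-index tie rule", {
  mask <- array(FALSE, c(4, 6, 6))
  mask[1, 1, 1:3] <- TRUE                      # area 3
  mask[2, 1:2, 1:4] <- c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  mask[3, 1, 1:6] <- TRUE; mask[3, 2, 1] <- TRUE  # area 7 (tie with slice 2)
  mask[4, 1, 1:2] <- TRUE                      # area 2
  vol <- mk_vol(array(seq_len(4 * 6 * 6), c(4, 6, 6)))
  sel <- select_largest_slice_2d(vol, mask)
  expect_equal(sel$slice_index, 2L)
  expect_equal(sum(sel$mask), 7)
  # single-slice mask returns that slice
  m1 <- array(FALSE, c(4, 6, 6)); m1[3, 2:4, 2:4] <- TRUE
  expect_equal(select_largest_slice_2d(vol, m1)$slice_index, 3L)
  # ellipsoid: the equatorial slice wins
  co <- ((1:9) - 5)
  d2 <- outer(outer((co / 2)^2, (co / 4)^2, "+"), (co / 4)^2, "+")
  ell <- array(d2 <= 1, c(9, 9, 9))
  v9 <- mk_vol(array(1, c(9, 9, 9)))
  expect_equal(select_largest_slice_2d(v9, ell)$slice_index, 5L)
})

test_that("full preprocessing is scale-invariant and level-idempotent", {
  cfg <- cohort_config(n_patients = 2, seed = 5)
  p <- generate_patient(cfg, 1)
  pre1 <- preprocess_case(p$before$volume, p$before$rois)
  # global intensity rescaling cancels in urine normalization
  k <- 3.7
  vol_k <- image_volume(p$before$volume$data * k, p$before$volume$spacing)
  pre2 <- preprocess_case(vol_k, p$before$rois)
  expect_identical(pre1$q3d$levels, pre2$q3d$levels)
  expect_identical(pre1$q2d$levels, pre2$q2d$levels)
  # in-mask levels always within [1, 64]
  expect_true(all(pre1$q3d$levels[pre1$q3d$mask] %in% 1:64))
  expect_true(all(pre1$q2d$levels[pre1$q2d$mask] %in% 1:64))
  # re-running the chain on the 1 mm normalized output changes no levels
  rois1 <- roi_set(pre1$q3d$mask, pre1$q3d$mask)  # placeholder bladder
  iso <- resample_isotropic_3d(
    image_volume(pre1$q3d$intensities, pre1$q3d$spacing),
    list(tumor = pre1$q3d$mask))
  q_re <- quantize(iso$volume, iso$masks$tumor)
  expect_identical(q_re$levels[q_re$mask], pre1$q3d$levels[pre1$q3d$mask])
})
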