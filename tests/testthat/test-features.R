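# Feature extraction: registry contract, hand-computed examples,
# oracle equivalence and symmetry properties.

test_that("registry partitions the 55 features as 1/8/15/13/13/5", {
  reg <- feature_registry()
  expect_length(reg, 55)
  expect_false(anyDuplicated(reg) > 0)
  counts <- vapply(c("size", "firstorder", "glcm", "glrlm", "glszm",
                     "ngtdm"), function(f) length(feature_registry(f)),
                   integer(1))
  expect_equal(unname(counts), c(1L, 8L, 15L, 13L, 13L, 5L))
  # names used by the published formulas must exist
  expect_true(all(c("Volume", "Int_Energy", "GLCM_Energy",
                    "GLCM_SumAverage", "GLCM_SumVariance",
                    "GLCM_Autocorrelation", "GLRLM_SRLGLE", "GLRLM_LRLGLE",
                    "GLRLM_LRHGLE", "GLSZM_LZLGLE", "GLSZM_LZHGLE",
                    "NGTDM_Coarseness") %in% reg))
})

test_that("roi_size returns voxel count times unit size", {
  m <- array(FALSE, c(2, 3, 3)); m[1:10] <- TRUE
  expect_equal(roi_size(m, c(1, 1, 1), "3D"), 10)
  m2 <- array(TRUE, c(1, 5, 5))
  expect_equal(roi_size(m2, c(1, 1, 1), "2D"), 25)
  expect_error(roi_size(array(FALSE, c(2, 2, 2)), c(1, 1, 1)), "empty")
  # sphere radius 5 mm at 1 mm voxels vs analytic volume
  sph <- {
    co <- (1:13) - 7
    d2 <- outer(outer(co^2, co^2, "+"), co^2, "+")
    array(d2 <= 25, c(13, 13, 13))
  }
  expect_lt(abs(roi_size(sph, c(1, 1, 1), "3D") - 4 / 3 * pi * 125) /
              (4 / 3 * pi * 125), 0.15)
})

test_that("first-order features match hand arithmetic and conventions", {
  fo <- first_order_features(rep(0.5, 9), rep(32L, 9))
  expect_equal(unname(fo[c("Int_Mean", "Int_StdDev", "Int_Energy",
                           "Int_Skewness", "Int_Kurtosis",
                           "Int_Uniformity", "Int_Entropy")]),
               c(0.5, 0, 0.25, 0, 0, 1, 0))
  fo2 <- first_order_features(c(1, 3), c(1L, 3L))
  expect_equal(unname(fo2[c("Int_Mean", "Int_StdDev", "Int_Energy")]),
               c(2, 1, 5))
  expect_length(fo2, 8)
  # sum-mode energy is n times mean-mode
  fo3 <- first_order_features(c(1, 3), c(1L, 3L), energy_mode = "sum")
  expect_equal(unname(fo3["Int_Energy"]), 10)
})

test_that("GLCM on constant and strip ROIs matches closed forms", {
  q <- roi_from_levels(array(3L, c(2, 2, 2)), L = 8)
  g <- glcm_features(q)
  expect_equal(unname(g[c("GLCM_Energy", "GLCM_Contrast",
                          "GLCM_MaximumProbability")]), c(1, 0, 1))
  # alternating strip: only (1,2)/(2,1) cells, each 0.5
  qs <- roi_from_levels(array(c(1L, 2L, 1L, 2L), c(1, 1, 4)), L = 2)
  gs <- glcm_features(qs)
  expect_equal(unname(gs["GLCM_Energy"]), 0.5)
  expect_equal(unname(gs["GLCM_SumAverage"]), 3)
  expect_length(gs, 15)
})

test_that("GLRLM single-direction strip and constant-ROI growth", {
  arr <- array(c(1L, 1L, 2L), c(1, 1, 3))
  cnt <- deltarad:::cpp_glrlm_counts(arr, dim(arr),
                                     matrix(c(0L, 0L, 1L), 1), 2L)
  f <- deltarad:::glrlm_feats_one(cnt[, , 1], 3)
  expect_equal(unname(f["SRE"]), (1 / 4 + 1) / 2)
  expect_equal(unname(f["LRE"]), (4 + 1) / 2)
  # LRE grows like L^2 on a constant row
  lre <- vapply(c(4L, 8L, 16L), function(L) {
    a <- array(1L, c(1, 1, L))
    cn <- deltarad:::cpp_glrlm_counts(a, dim(a), matrix(c(0L, 0L, 1L), 1), 1L)
    unname(deltarad:::glrlm_feats_one(matrix(cn[, , 1], nrow = 1), L)["LRE"])
  }, numeric(1))
  expect_equal(lre, c(16, 64, 256))
  expect_length(glrlm_features(roi_from_levels(arr, 2)), 13)
})

test_that("GLSZM single zone and diagonal connectivity", {
  q <- roi_from_levels(array(2L, c(2, 2, 2)), L = 4)
  g <- glszm_features(q)
  expect_equal(unname(g[c("GLSZM_SAE", "GLSZM_LAE")]), c(1 / 64, 64))
  expect_length(g, 13)
  # 2D checkerboard under 8-connectivity: each level is one zone
  chk <- outer(1:4, 1:4, function(i, j) ((i + j) %% 2) + 1L)
  zones <- deltarad:::cpp_glszm_zones(array(chk, c(1, 4, 4)), c(1L, 4L, 4L),
                                      deltarad:::direction_set("2D"))
  expect_equal(nrow(zones), 2)
  expect_equal(sort(zones[, "size"]), c(8L, 8L))
})

test_that("NGTDM degenerate cap and 3x3 hand case", {
  q <- roi_from_levels(array(5L, c(3, 3, 3)), L = 8)
  g <- ngtdm_features(q)
  expect_equal(unname(g[c("NGTDM_Coarseness", "NGTDM_Contrast")]),
               c(1e6, 0))
  # 3x3 plane, center deviant: s_center = |4 - 1|, each rim voxel sees
  # the center among its neighbors
  m <- matrix(1L, 3, 3); m[2, 2] <- 4L
  arr <- array(m, c(1, 3, 3))
  got <- deltarad:::cpp_ngtdm(arr, c(1L, 3L, 3L), deltarad:::full_neighborhood("2D"), 4L)
  ora <- oracle_ngtdm(arr, deltarad:::full_neighborhood("2D"), 4L)
  expect_equal(got, ora)
  expect_equal(got[4, 2], 3)          # center: |4 - mean(eight 1s)| = 3
  # corner rim voxels: neighbors {1,1,4} -> |1 - 2| = 1; edge rim:
  # {1,1,1,4,1} -> |1 - 8/5| = 0.6
  expect_equal(got[1, 2], 4 * 1 + 4 * 0.6)
})

test_that("texture matrices equal naive enumeration on random ROIs", {
  set.seed(42)
  for (rep in 1:6) {
    dims <- if (rep %% 2) "3D" else "2D"
    shape <- if (dims == "3D") c(4, 5, 4) else c(1, 6, 6)
    arr <- random_roi(shape, L = 5)
    ds <- deltarad:::direction_set(dims)
    glcm <- deltarad:::cpp_glcm_counts(arr, dim(arr), ds, 5L)
    glrlm <- deltarad:::cpp_glrlm_counts(arr, dim(arr), ds, 5L)
    for (d in seq_len(nrow(ds))) {
      expect_equal(glcm[, , d], oracle_glcm(arr, ds[d, ], 5L))
      o <- oracle_glrlm(arr, ds[d, ], 5L)
      expect_equal(glrlm[, seq_len(ncol(o)), d], o)
    }
    zo <- deltarad:::cpp_glszm_zones(arr, dim(arr), ds)
    zo <- zo[order(zo[, 1], zo[, 2]), , drop = FALSE]
    expect_equal(unname(zo[, 1:2, drop = FALSE]),
                 unname(oracle_glszm(arr, deltarad:::full_neighborhood(dims))))
    expect_equal(deltarad:::cpp_ngtdm(arr, dim(arr),
                                      deltarad:::full_neighborhood(dims), 5L),
                 oracle_ngtdm(arr, deltarad:::full_neighborhood(dims), 5L))
  }
})

test_that("GLCM probabilities conserve mass and symmetry per direction", {
  set.seed(7)
  arr <- random_roi(c(5, 5, 5), L = 6)
  cnt <- deltarad:::cpp_glcm_counts(arr, dim(arr), deltarad:::direction_set("3D"), 6L)
  for (d in seq_len(dim(cnt)[3])) {
    M <- cnt[, , d]
    if (sum(M) == 0) next
    P <- M / sum(M)
    expect_equal(sum(P), 1)
    expect_equal(P, t(P))
  }
})

test_that("direction-averaged features are invariant to axis-aligned rotation", {
  set.seed(11)
  arr <- random_roi(c(5, 6, 7), L = 6)
  q1 <- roi_from_levels(arr, 6)
  rot <- aperm(arr, c(1, 3, 2))[, , rev(seq_len(dim(arr)[2]))]  # 90 deg about z
  q2 <- roi_from_levels(rot, 6)
  expect_equal(glcm_features(q1), glcm_features(q2), tolerance = 1e-12)
  expect_equal(glrlm_features(q1), glrlm_features(q2), tolerance = 1e-12)
})

test_that("extract_all returns 55 deterministic named features", {
  set.seed(3)
  arr <- random_roi(c(4, 6, 6), L = 8)
  q <- roi_from_levels(arr, 8)
  f1 <- extract_all(q, "P001", "before")
  f2 <- extract_all(q, "P001", "before")
  expect_length(f1, 55)
  expect_identical(names(f1), feature_registry())
  expect_identical(as.numeric(f1), as.numeric(f2))
  expect_true(all(is.finite(f1)))
  expect_identical(attr(f1, "timepoint"), "before")
})

test_that("NGTDM coarseness increases with texture correlation length", {
  mean_coarse <- vapply(c(0.8, 2, 5), function(cl) {
    vals <- vapply(1:5, function(s) {
      cfg <- cohort_config(n_patients = 2, seed = 100 + s,
                          texture_before = list(correlation_length = cl,
                                                intensity_sd = 0.25))
      p <- generate_patient(cfg, 1, latent_response = 0)
      q <- preprocess_case(p$before$volume, p$before$rois)$q3d
      unname(ngtdm_features(q)["NGTDM_Coarseness"])
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(mean_coarse) > 0))
})
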