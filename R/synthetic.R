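#' Synthetic cohort configuration
#'
#' Describes the simulated world: paired T2-weighted-MRI-like volumes on
#' an anisotropic native grid (default 4 x 0.5 x 0.5 mm), an
#' ellipsoid-like textured tumor whose size shrinks and whose texture
#' homogenizes with a latent treatment response, a ~1 cm^3 bright
#' bladder-urine reference sphere, and proportional-hazards outcomes for
#' the three endpoints (LR, DM, DFS) driven by delta features.
#'
#' Response acts on three knobs: tumor scale factor `1 - 0.5 r`, texture
#' correlation-length multiplier `1 + r`, and intensity-SD multiplier
#' `1 - 0.5 r`, where `r` is the latent response in `[0, 1]`.
#'
#' @param n_patients cohort size (>= 2).
#' @param grid_shape native grid `(nz, ny, nx)` in voxels.
#' @param voxel_spacing native spacing `(z, y, x)` in mm.
#' @param tumor_radius_range min/max baseline tumor radius in mm.
#' @param tumor_anisotropy min/max per-axis semi-axis multiplier (set
#'   `c(1, 1)` for exact spheres).
#' @param texture_before list with `correlation_length` (mm) and
#'   `intensity_sd` (relative to the tumor mean intensity).
#' @param response_distribution `c(a, b)` of the Beta law of the latent
#'   response on `[0, 1]`.
#' @param hazard_coefficients named vector of log-hazard-ratio weights on
#'   standardized 3D delta features (names from [feature_registry()]), or
#'   the single name `"latent_response"` to drive hazards directly from
#'   the latent response.
#' @param baseline_hazard named per-endpoint baseline hazards (1/month).
#' @param censor_horizon administrative censoring horizon (months).
#' @param censor_rate probability of early uniform dropout censoring.
#' @param seed master seed; every patient stream derives from it.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 100L,
                          grid_shape = c(16L, 80L, 80L),
                          voxel_spacing = c(4, 0.5, 0.5),
                          tumor_radius_range = c(8, 15),
                          tumor_anisotropy = c(0.85, 1.15),
                          texture_before = list(correlation_length = 2,
                                                intensity_sd = 0.25),
                          response_distribution = c(2, 2),
                          hazard_coefficients = c(Int_Energy = 1,
                                                  NGTDM_Coarseness = -1),
                          baseline_hazard = c(LR = 0.003, DM = 0.005,
                                              DFS = 0.025),
                          censor_horizon = 60,
                          censor_rate = 0.25,
                          seed = 1L) {
  if (n_patients < 2L) stop("need at least 2 patients")
  if (any(voxel_spacing <= 0)) stop("voxel spacings must be positive")
  if (censor_horizon <= 0) stop("censor horizon must be positive")
  structure(list(n_patients = as.integer(n_patients),
                 grid_shape = as.integer(grid_shape),
                 voxel_spacing = as.numeric(voxel_spacing),
                 tumor_radius_range = as.numeric(tumor_radius_range),
                 tumor_anisotropy = as.numeric(tumor_anisotropy),
                 texture_before = texture_before,
                 response_distribution = as.numeric(response_distribution),
                 hazard_coefficients = hazard_coefficients,
                 baseline_hazard = baseline_hazard,
                 censor_horizon = censor_horizon,
                 censor_rate = censor_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Separable Gaussian smoothing of a (z,y,x) array; sigma per axis in
# voxels.  Edge weights are renormalized so a constant field stays
# constant.
gauss_smooth <- function(arr, sigma) {
  d <- dim(arr)
  for (a in 1:3) {
    if (sigma[a] <= 0 || d[a] == 1L) next
    n <- d[a]
    x <- seq_len(n)
    K <- exp(-outer(x, x, "-")^2 / (2 * sigma[a]^2))
    K <- K / rowSums(K)
    perm <- c(a, setdiff(1:3, a))
    m <- matrix(aperm(arr, perm), nrow = n)
    arr <- aperm(array(K %*% m, dim = d[perm]), order(perm))
  }
  arr
}

# mm coordinates of voxel centers along each axis
axis_coords <- function(shape, spacing)
  lapply(1:3, function(a) (seq_len(shape[a]) - 0.5) * spacing[a])

ellipsoid_mask <- function(shape, spacing, center, semiaxes) {
  co <- axis_coords(shape, spacing)
  uz <- (co[[1]] - center[1]) / semiaxes[1]
  uy <- (co[[2]] - center[2]) / semiaxes[2]
  ux <- (co[[3]] - center[3]) / semiaxes[3]
  d2 <- outer(outer(uz^2, uy^2, "+"), ux^2, "+")
  d2 <= 1
}

#' Generate one synthetic patient
#'
#' Builds the paired before/after volumes and masks for patient `index`.
#' All noise draws are shared between the two timepoints, so a latent
#' response of exactly 0 yields identical before/after images and masks;
#' a positive response shrinks the tumor, lengthens the texture
#' correlation and damps the intensity SD.  Deterministic given
#' `(config$seed, index)`.
#'
#' @param config a [cohort_config].
#' @param index patient index in `1..n_patients`.
#' @param latent_response optional override of the Beta-drawn response.
#' @return a `patient_case`: list with `patient_id`, `before`/`after`
#'   (each `list(volume, rois)`) and `latent_response`.
#' @export
generate_patient <- function(config, index, latent_response = NULL) {
  stopifnot(index >= 1L, index <= config$n_patients)
  shape <- config$grid_shape; sp <- config$voxel_spacing
  extent <- shape * sp
  with_seed(child_seed(config$seed, "patient", index), {
    r <- if (is.null(latent_response))
      rbeta(1, config$response_distribution[1], config$response_distribution[2])
    else latent_response
    radius <- runif(1, config$tumor_radius_range[1], config$tumor_radius_range[2])
    aniso <- runif(3, config$tumor_anisotropy[1], config$tumor_anisotropy[2])
    semi <- radius * aniso
    center <- extent / 2
    margin <- 2  # mm head-room for +/-1 mm ROI translations
    for (a in 1:3) {
      if (semi[a] + margin > extent[a] / 2)
        stop("tumor radius ", round(semi[a], 1), " mm too large for grid ",
             "dimension ", c("z", "y", "x")[a], " (extent ", extent[a], " mm)")
    }
    noise_img <- array(rnorm(prod(shape)), dim = shape)   # background
    noise_tex <- array(rnorm(prod(shape)), dim = shape)   # tumor texture
    noise_bla <- array(rnorm(prod(shape)), dim = shape)   # urine ripple
    # bladder: ~1 cm^3 sphere tucked toward a corner, away from the tumor
    r_bl <- (3 * 1000 / (4 * pi))^(1 / 3)   # 6.20 mm
    bl_center <- pmax(r_bl + 1.5, extent * 0.22)
    bl_center[1] <- max(r_bl + 1.5, extent[1] * 0.15)
    bladder <- ellipsoid_mask(shape, sp, bl_center, rep(r_bl, 3))
    tex <- config$texture_before
    mk_timepoint <- function(scale, sig_mult, sd_mult) {
      tumor <- ellipsoid_mask(shape, sp, center, semi * scale)
      sig_vox <- tex$correlation_length * sig_mult / sp
      field <- gauss_smooth(noise_tex, sig_vox)
      fin <- field[tumor]
      fsd <- sd(fin)
      if (!is.finite(fsd) || fsd == 0) fsd <- 1
      tumor_mean <- 200; urine_mean <- 500
      field <- (field - mean(fin)) / fsd *
        (tex$intensity_sd * sd_mult * tumor_mean)
      img <- 100 + 10 * noise_img
      img[tumor] <- tumor_mean + field[tumor]
      img[bladder] <- urine_mean + 5 * noise_bla[bladder]
      img[img < 1] <- 1
      list(volume = image_volume(img, sp), rois = roi_set(tumor, bladder))
    }
    before <- mk_timepoint(1, 1, 1)
    after <- mk_timepoint(1 - 0.5 * r, 1 + r, 1 - 0.5 * r)
    structure(list(patient_id = sprintf("P%03d", index),
                   before = before, after = after, latent_response = r),
              class = "patient_case")
  })
}

#' Simulate proportional-hazards survival outcomes
#'
#' Event times are exponential with rate `baseline_hazard * exp(score)`;
#' censoring is uniform dropout on `(0, horizon)` with probability
#' `censor_rate`, administrative at `horizon` otherwise.
#'
#' @param scores per-patient linear predictors (finite).
#' @param baseline_hazard events per month (> 0).
#' @param censor_horizon months.
#' @param censor_rate dropout probability in `[0, 1]`.
#' @param seed integer seed.
#' @param patient_id optional ids (default `P001..`).
#' @return data.frame with `patient_id`, `time` (months), `event` (0/1).
#' @export
simulate_survival <- function(scores, baseline_hazard, censor_horizon = Inf,
                              censor_rate = 0, seed = 1L,
                              patient_id = NULL) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (baseline_hazard <= 0) stop("baseline hazard must be positive")
  n <- length(scores)
  if (is.null(patient_id)) patient_id <- sprintf("P%03d", seq_len(n))
  with_seed(seed, {
    t_event <- rexp(n, rate = baseline_hazard * exp(scores))
    dropout <- runif(n) < censor_rate
    t_cens <- ifelse(dropout & is.finite(censor_horizon),
                     runif(n, 0, censor_horizon), censor_horizon)
    data.frame(patient_id = patient_id,
               time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens))
  })
}

#' Split a cohort into training and validation sets
#'
#' Random disjoint exhaustive split at an `a:b` ratio (default 2:1), the
#' training size being the rounded share.
#'
#' @param patient_ids character or integer vector.
#' @param ratio positive integer pair `(a, b)`.
#' @param seed integer seed.
#' @return list with `training` and `validation` id vectors.
#' @export
split_cohort <- function(patient_ids, ratio = c(2, 1), seed = 1L) {
  n <- length(patient_ids)
  if (n < 2L) stop("need at least 2 patients to split")
  if (length(ratio) != 2L || any(ratio <= 0)) stop("ratio must be two positive numbers")
  n_train <- min(max(round(n * ratio[1] / sum(ratio)), 1L), n - 1L)
  with_seed(seed, {
    tr <- sort(sample.int(n, n_train))
    list(training = patient_ids[tr], validation = patient_ids[-tr])
  })
}

#' Generate a full synthetic cohort with outcomes
#'
#' Generates every patient, extracts 3D delta features when the hazard is
#' driven by named features (the default), forms the per-patient linear
#' predictor from standardized delta features, and simulates outcomes for
#' LR, DM and DFS with endpoint-specific baseline hazards.
#'
#' @param config a [cohort_config].
#' @param keep_images keep the image volumes in the result (default TRUE;
#'   set FALSE to save memory once features are extracted).
#' @param levels quantization levels for the internal extraction.
#' @return list with `patients`, `outcomes` (long data.frame with
#'   `endpoint` in LR/DM/DFS), `scores`, `truth` (per-patient latent
#'   response), and `delta3d` (matrix, when features drive the hazard).
#' @export
generate_cohort <- function(config, keep_images = TRUE, levels = 64L) {
  patients <- lapply(seq_len(config$n_patients),
                     function(i) generate_patient(config, i))
  ids <- vapply(patients, `[[`, "", "patient_id")
  resp <- vapply(patients, `[[`, 0, "latent_response")
  hc <- config$hazard_coefficients
  delta3d <- NULL
  if (identical(names(hc), "latent_response")) {
    scores <- hc[[1]] * (resp - mean(resp)) / sd(resp)
  } else {
    feats <- lapply(patients, function(p) {
      qb <- preprocess_case(p$before$volume, p$before$rois, levels)$q3d
      qa <- preprocess_case(p$after$volume, p$after$rois, levels)$q3d
      extract_all(qa, p$patient_id, "after") -
        extract_all(qb, p$patient_id, "before")
    })
    delta3d <- do.call(rbind, feats)
    rownames(delta3d) <- ids
    miss <- setdiff(names(hc), colnames(delta3d))
    if (length(miss)) stop("unknown hazard features: ", paste(miss, collapse = ", "))
    Z <- scale(delta3d[, names(hc), drop = FALSE])
    Z[is.nan(Z)] <- 0
    scores <- as.numeric(Z %*% hc)
  }
  outcomes <- do.call(rbind, lapply(names(config$baseline_hazard), function(ep) {
    o <- simulate_survival(scores, config$baseline_hazard[[ep]],
                           config$censor_horizon, config$censor_rate,
                           seed = child_seed(config$seed, "surv", ep),
                           patient_id = ids)
    cbind(o[1], endpoint = ep, o[2:3])
  }))
  rownames(outcomes) <- NULL
  if (!keep_images) patients <- NULL
  list(patients = patients, outcomes = outcomes, scores = scores,
       truth = data.frame(patient_id = ids, latent_response = resp),
       delta3d = delta3d)
}

#' Simulate a delta-feature matrix with known prognostic structure
#'
#' Feature-level generator for selection experiments: `p` independent
#' standard-normal delta features for `n` patients, of which the first
#' `n_true` carry log-hazard-ratio `beta` each; the rest are pure noise.
#'
#' @param n,p patients and features.
#' @param n_true number of truly prognostic features.
#' @param beta effect size per true feature (log hazard ratio per SD).
#' @param seed integer seed.
#' @return list with `X` (n x p), `scores`, `true_features`.
#' @export
simulate_delta_matrix <- function(n = 200L, p = 22L, n_true = 2L, beta = 1,
                                  seed = 1L) {
  stopifnot(n_true <= p)
  nm <- paste0("F", sprintf("%02d", seq_len(p)))
  with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, nm))
    b <- c(rep(beta, n_true), rep(0, p - n_true))
    list(X = X, scores = as.numeric(X %*% b),
         true_features = nm[seq_len(n_true)])
  })
}
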