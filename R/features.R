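#' Quantized ROI container
#'
#' Couples the quantized gray levels (integers `1..n_levels` inside the
#' mask, 0 outside), the mask, the continuous urine-normalized
#' intensities, and the voxel spacing.  2D ROIs are stored as a
#' single-slice array (`nz = 1`); `dims` selects the displacement sets
#' used by texture features (13 directions / 26-neighborhood in 3D, 4 /
#' 8 in 2D).
#'
#' @param levels integer array `(z, y, x)`, 0 outside the mask.
#' @param mask logical array, same grid.
#' @param intensities numeric array of normalized intensities, same grid.
#' @param spacing voxel spacing `(z, y, x)` in mm.
#' @param n_levels number of quantization levels (default 64).
#' @param dims `"3D"` or `"2D"`.
#' @return object of class `quantized_roi`.
#' @export
quantized_roi <- function(levels, mask, intensities, spacing,
                          n_levels = 64L, dims = c("3D", "2D")) {
  dims <- match.arg(dims)
  mask <- mask != 0
  if (!identical(dim(levels), dim(mask)) ||
      !identical(dim(levels), dim(intensities)))
    stop("levels, mask and intensities must share a grid")
  if (!any(mask)) stop("empty mask")
  inm <- levels[mask]
  if (any(inm < 1L | inm > n_levels))
    stop("in-mask levels must lie in [1, ", n_levels, "]")
  structure(list(levels = levels, mask = mask, intensities = intensities,
                 spacing = as.numeric(spacing), n_levels = as.integer(n_levels),
                 dims = dims),
            class = "quantized_roi")
}

# Crop the level array to the mask bounding box (texture matrices only
# see in-mask voxels, so cropping is exact and much faster).
crop_to_mask <- function(q) {
  w <- which(q$mask, arr.ind = TRUE)
  rng <- apply(w, 2, range)
  arr <- q$levels
  arr[!q$mask] <- 0L
  arr <- arr[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2], rng[1, 3]:rng[2, 3],
             drop = FALSE]
  storage.mode(arr) <- "integer"
  arr
}

#' ROI size
#'
#' Volume (mm^3) of a 3D mask or area (mm^2) of a 2D mask: voxel count
#' times the unit voxel volume/pixel area.
#'
#' @param mask logical array `(z, y, x)`.
#' @param spacing voxel spacing `(z, y, x)` in mm.
#' @param dims `"3D"` (volume) or `"2D"` (in-plane area).
#' @return size in mm^3 (3D) or mm^2 (2D).
#' @export
roi_size <- function(mask, spacing, dims = c("3D", "2D")) {
  dims <- match.arg(dims)
  n <- sum(mask != 0)
  if (n == 0) stop("empty mask")
  unit <- if (dims == "3D") prod(spacing) else prod(spacing[2:3])
  n * unit
}

#' First-order intensity features
#'
#' Eight statistics of the urine-normalized intensities inside the mask.
#' `Int_StdDev` and the moment-based `Int_Skewness` / `Int_Kurtosis`
#' (excess) use population moments; both are defined as 0 for constant
#' input.  `Int_Energy` is the mean of squared normalized intensities
#' (size-invariant; set `energy_mode = "sum"` for the summed variant).
#' `Int_Entropy` (bits) and `Int_Uniformity` are computed on the
#' discrete quantized-level histogram.
#'
#' @param values numeric vector of in-mask normalized intensities.
#' @param levels integer vector of in-mask quantized levels.
#' @param n_levels number of quantization levels.
#' @param energy_mode `"mean"` (default) or `"sum"`.
#' @return named numeric vector of length 8.
#' @export
first_order_features <- function(values, levels, n_levels = 64L,
                                 energy_mode = c("mean", "sum")) {
  energy_mode <- match.arg(energy_mode)
  if (length(values) < 1L) stop("need at least one in-mask value")
  mu <- mean(values)
  s <- sqrt(mean((values - mu)^2))
  skew <- if (s > 0) mean((values - mu)^3) / s^3 else 0
  kurt <- if (s > 0) mean((values - mu)^4) / s^4 - 3 else 0
  energy <- if (energy_mode == "mean") mean(values^2) else sum(values^2)
  p <- tabulate(levels, nbins = n_levels) / length(levels)
  pnz <- p[p > 0]
  setNames(c(mu, median(values), s, skew, kurt, energy,
             -sum(pnz * log2(pnz)), sum(p^2)),
           feature_registry("firstorder"))
}

# Features of one symmetric normalized GLCM.
glcm_feats_one <- function(P) {
  L <- nrow(P)
  nz <- which(P > 0, arr.ind = TRUE)
  p <- P[nz]
  i <- nz[, 1]; j <- nz[, 2]
  mu <- sum(i * p)
  sig2 <- sum((i - mu)^2 * p)
  ks <- i + j
  sumavg <- sum(ks * p)
  kd <- abs(i - j)
  diffavg <- sum(kd * p)
  # p_{x+y} and p_{x-y} entropies need aggregation over equal k
  psum <- rowsum(p, ks); pdiff <- rowsum(p, kd)
  c(Energy = sum(p^2),
    Contrast = sum((i - j)^2 * p),
    Correlation = if (sig2 > 0) sum((i - mu) * (j - mu) * p) / sig2 else 1,
    SumAverage = sumavg,
    SumVariance = sum((ks - sumavg)^2 * p),
    SumEntropy = -sum(psum * log2(psum)),
    Entropy = -sum(p * log2(p)),
    DifferenceVariance = sum((kd - diffavg)^2 * p),
    DifferenceEntropy = -sum(pdiff * log2(pdiff)),
    InverseDifferenceMoment = sum(p / (1 + (i - j)^2)),
    Autocorrelation = sum(i * j * p),
    ClusterShade = sum((ks - 2 * mu)^3 * p),
    ClusterProminence = sum((ks - 2 * mu)^4 * p),
    Dissimilarity = diffavg,
    MaximumProbability = max(p))
}

#' Gray level co-occurrence matrix features
#'
#' Distance-1 symmetric GLCMs are built over the 13 unique 3D (4 in 2D)
#' directions, counting only voxel pairs with both members in-mask; the
#' 15 Haralick-style features are computed per direction and averaged
#' over directions that contain at least one pair.
#'
#' @param q a [quantized_roi].
#' @return named numeric vector of length 15 (`GLCM_*`).
#' @export
glcm_features <- function(q) {
  arr <- crop_to_mask(q)
  dirs <- direction_set(q$dims)
  cnt <- cpp_glcm_counts(arr, dim(arr), dirs, q$n_levels)
  vals <- NULL
  for (d in seq_len(dim(cnt)[3])) {
    M <- cnt[, , d]
    tot <- sum(M)
    if (tot == 0) next
    vals <- rbind(vals, glcm_feats_one(M / tot))
  }
  if (is.null(vals))
    stop("GLCM: no valid in-mask voxel pairs in ROI (", sum(q$mask),
         " voxels)")
  setNames(colMeans(vals), feature_registry("glcm"))
}

glrlm_feats_one <- function(R, n_vox) {
  nz <- which(R > 0, arr.ind = TRUE)
  r <- R[nz]
  i <- nz[, 1]; l <- nz[, 2]
  Nr <- sum(r)
  pr <- r / Nr
  mu_i <- sum(pr * i); mu_l <- sum(pr * l)
  c(SRE = sum(r / l^2) / Nr,
    LRE = sum(r * l^2) / Nr,
    GLN = sum(rowsum(r, i)^2) / Nr,
    RLN = sum(rowsum(r, l)^2) / Nr,
    RunPercentage = Nr / n_vox,
    LGLRE = sum(r / i^2) / Nr,
    HGLRE = sum(r * i^2) / Nr,
    SRLGLE = sum(r / (i^2 * l^2)) / Nr,
    SRHGLE = sum(r * i^2 / l^2) / Nr,
    LRLGLE = sum(r * l^2 / i^2) / Nr,
    LRHGLE = sum(r * i^2 * l^2) / Nr,
    GrayLevelVariance = sum(pr * (i - mu_i)^2),
    RunLengthVariance = sum(pr * (l - mu_l)^2))
}

#' Gray level run length matrix features
#'
#' Runs of equal level along each of the 13 (3D) / 4 (2D) directions,
#' truncated at the mask boundary; the 13 Galloway/extended features are
#' computed per direction and averaged.  Low/high gray level weights are
#' `1/i^2` and `i^2`.
#'
#' @param q a [quantized_roi].
#' @return named numeric vector of length 13 (`GLRLM_*`).
#' @export
glrlm_features <- function(q) {
  arr <- crop_to_mask(q)
  dirs <- direction_set(q$dims)
  cnt <- cpp_glrlm_counts(arr, dim(arr), dirs, q$n_levels)
  n_vox <- sum(q$mask)
  vals <- t(vapply(seq_len(dim(cnt)[3]),
                   function(d) glrlm_feats_one(
                     matrix(cnt[, , d], nrow = q$n_levels), n_vox),
                   numeric(13)))
  setNames(colMeans(vals), feature_registry("glrlm"))
}

#' Gray level size zone matrix features
#'
#' Zones are connected components of equal level under 26-connectivity
#' (3D) or 8-connectivity (2D); a single matrix (no directions) yields
#' the 13 Thibault-style features, with low/high gray level weights
#' `1/i^2` and `i^2`.
#'
#' @param q a [quantized_roi].
#' @return named numeric vector of length 13 (`GLSZM_*`).
#' @export
glszm_features <- function(q) {
  arr <- crop_to_mask(q)
  zones <- cpp_glszm_zones(arr, dim(arr), direction_set(q$dims))
  i <- zones[, "level"]; s <- zones[, "size"]
  Nz <- nrow(zones)
  n_vox <- sum(q$mask)
  pz <- rep(1 / Nz, Nz)
  mu_i <- sum(pz * i); mu_s <- sum(pz * s)
  vals <- c(SAE = sum(1 / s^2) / Nz,
            LAE = sum(s^2) / Nz,
            GLN = sum(rowsum(rep(1, Nz), i)^2) / Nz,
            ZSN = sum(rowsum(rep(1, Nz), s)^2) / Nz,
            ZonePercentage = Nz / n_vox,
            LGLZE = sum(1 / i^2) / Nz,
            HGLZE = sum(i^2) / Nz,
            SALGLE = sum(1 / (i^2 * s^2)) / Nz,
            SAHGLE = sum(i^2 / s^2) / Nz,
            LZLGLE = sum(s^2 / i^2) / Nz,
            LZHGLE = sum(s^2 * i^2) / Nz,
            GrayLevelVariance = sum(pz * (i - mu_i)^2),
            ZoneSizeVariance = sum(pz * (s - mu_s)^2))
  setNames(vals, feature_registry("glszm"))
}

#' Neighborhood gray tone difference matrix features
#'
#' For each level `i`, `s_i` sums the absolute deviation of the level
#' from the mean of its in-mask 26- (3D) / 8- (2D) neighborhood over all
#' voxels of that level having at least one in-mask neighbor.  The five
#' Amadasun-King features are returned; Coarseness is capped at 1e6 when
#' its denominator falls below 1e-6 (uniform ROI).
#'
#' @param q a [quantized_roi].
#' @return named numeric vector of length 5 (`NGTDM_*`).
#' @export
ngtdm_features <- function(q) {
  arr <- crop_to_mask(q)
  m <- cpp_ngtdm(arr, dim(arr), full_neighborhood(q$dims), q$n_levels)
  n_i <- m[, 1]; s_i <- m[, 2]
  N <- sum(n_i)
  if (N == 0) stop("NGTDM: no in-mask voxel has an in-mask neighbor")
  p_i <- n_i / N
  pres <- which(p_i > 0)
  Ng <- length(pres)
  lev <- pres  # level value == index
  ps <- sum(p_i * s_i)
  coarseness <- if (ps < 1e-6) 1e6 else 1 / ps
  if (Ng > 1) {
    ii <- rep(lev, each = Ng); jj <- rep(lev, Ng)
    pii <- p_i[ii]; pjj <- p_i[jj]
    contrast <- sum(pii * pjj * (ii - jj)^2) / (Ng * (Ng - 1)) * sum(s_i) / N
    bden <- sum(abs(ii * pii - jj * pjj))
    busyness <- if (bden > 0) ps / bden else 0
    complexity <- sum(abs(ii - jj) * (pii * s_i[ii] + pjj * s_i[jj]) /
                        (pii + pjj)) / N
    sden <- sum(s_i)
    strength <- if (sden > 0) sum((pii + pjj) * (ii - jj)^2) / sden else 0
  } else {
    contrast <- busyness <- complexity <- strength <- 0
  }
  setNames(c(coarseness, contrast, busyness, complexity, strength),
           feature_registry("ngtdm"))
}

#' Extract the full 55-feature vector from a quantized ROI
#'
#' Concatenates size (1), first-order (8), GLCM (15), GLRLM (13),
#' GLSZM (13) and NGTDM (5) features in registry order.
#'
#' @param q a [quantized_roi].
#' @param patient_id,timepoint optional labels attached as attributes
#'   (`timepoint` one of `"before"`/`"after"`).
#' @inheritParams first_order_features
#' @return a `feature_vector`: named numeric of length 55 with
#'   attributes `dims`, `timepoint`, `patient_id`.
#' @export
extract_all <- function(q, patient_id = NA_character_,
                        timepoint = NA_character_,
                        energy_mode = c("mean", "sum")) {
  energy_mode <- match.arg(energy_mode)
  fam <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(name, " extraction failed: ", conditionMessage(e), call. = FALSE))
  }
  vol <- fam("size", roi_size(q$mask, q$spacing, q$dims))
  fo <- fam("first-order",
            first_order_features(q$intensities[q$mask], q$levels[q$mask],
                                 q$n_levels, energy_mode))
  out <- c(Volume = vol, fo,
           fam("GLCM", glcm_features(q)),
           fam("GLRLM", glrlm_features(q)),
           fam("GLSZM", glszm_features(q)),
           fam("NGTDM", ngtdm_features(q)))
  stopifnot(identical(names(out), feature_registry()))
  structure(out, dims = q$dims, timepoint = timepoint,
            patient_id = patient_id, class = "feature_vector")
}
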