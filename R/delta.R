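#' Delta features
#'
#' Elementwise after-minus-before difference of two feature vectors of
#' the same dimensionality and patient.
#'
#' @param after,before `feature_vector`s (named numerics over the
#'   registry names).
#' @return named numeric `delta_feature_vector` (after - before).
#' @export
delta_features <- function(after, before) {
  miss <- c(setdiff(names(before), names(after)),
            setdiff(names(after), names(before)))
  if (length(miss))
    stop("feature name mismatch: ", paste(unique(miss), collapse = ", "))
  da <- attr(after, "dims"); db <- attr(before, "dims")
  if (!is.null(da) && !is.null(db) && !identical(da, db))
    stop("dimensionality mismatch: ", da, " vs ", db)
  pa <- attr(after, "patient_id"); pb <- attr(before, "patient_id")
  if (!is.null(pa) && !is.null(pb) && !is.na(pa) && !is.na(pb) &&
      !identical(pa, pb))
    stop("patient mismatch: ", pa, " vs ", pb)
  out <- unclass(after)[names(before)] - unclass(before)
  structure(out, dims = da, patient_id = pa, timepoint = "delta",
            class = "delta_feature_vector")
}

# Rigid in-grid shift of a logical mask; errors if any mask voxel would
# leave the grid (callers must pad their grids).
shift_mask <- function(mask, dz = 0L, dy = 0L, dx = 0L) {
  d <- dim(mask)
  w <- which(mask, arr.ind = TRUE)
  w[, 1] <- w[, 1] + dz; w[, 2] <- w[, 2] + dy; w[, 3] <- w[, 3] + dx
  if (any(w < 1L) || any(w[, 1] > d[1]) || any(w[, 2] > d[2]) ||
      any(w[, 3] > d[3]))
    stop("mask translation (", dz, ",", dy, ",", dx, ") exits grid bounds")
  out <- array(FALSE, dim = d)
  out[w] <- TRUE
  out
}

#' Eight translated ROIs
#'
#' All in-plane +/-1 voxel shifts of the mask — `(dy, dx)` over
#' `{-1,0,1}^2` minus the identity — emulating inter-observer contouring
#' variability on the 1 mm isotropic grid.  Craniocaudal shifts are
#' excluded by default so that 2D extraction sees a shifted, not a
#' different, slice; set `include_z = TRUE` for the axial variant.
#'
#' @param mask logical array `(z, y, x)` on a 1 mm grid.
#' @param include_z also shift along z (yields 26 masks).
#' @return list of shifted masks, named `"dy,dx"`, each with the same
#'   voxel count as the input.
#' @export
translated_rois <- function(mask, include_z = FALSE) {
  g <- expand.grid(dz = if (include_z) -1:1 else 0L, dy = -1:1, dx = -1:1)
  g <- g[!(g$dz == 0 & g$dy == 0 & g$dx == 0), ]
  out <- lapply(seq_len(nrow(g)), function(i)
    shift_mask(mask, g$dz[i], g$dy[i], g$dx[i]))
  names(out) <- apply(g, 1, paste, collapse = ",")
  out
}

#' One-way random-effects single-measure ICC
#'
#' ICC(1,1) from the one-way ANOVA decomposition:
#' `(MSB - MSW) / (MSB + (k - 1) MSW)` for `n` subjects measured `k`
#' times.  When every value is identical (degenerate denominator) the
#' result is `NA` with attribute `degenerate = TRUE`, to be treated as
#' non-robust.
#'
#' @param m numeric matrix, subjects in rows, repeats in columns.
#' @return ICC value in `(-Inf, 1]`, or `NA` if degenerate.
#' @export
icc_one_way <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 repeats")
  row_mu <- rowMeans(m)
  grand <- mean(m)
  msb <- k * sum((row_mu - grand)^2) / (n - 1)
  msw <- sum((m - row_mu)^2) / (n * (k - 1))
  denom <- msb + (k - 1) * msw
  if (denom <= 0 || !is.finite(denom))
    return(structure(NA_real_, degenerate = TRUE))
  (msb - msw) / denom
}

#' Two-way random-effects single-measure ICC
#'
#' ICC(2,1), absolute agreement, from the two-way ANOVA decomposition —
#' offered as an alternative when the repeats are treated as fixed
#' raters rather than interchangeable perturbations.
#'
#' @inheritParams icc_one_way
#' @return ICC value, or `NA` if degenerate.
#' @export
icc_two_way <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 repeats")
  row_mu <- rowMeans(m); col_mu <- colMeans(m); grand <- mean(m)
  msr <- k * sum((row_mu - grand)^2) / (n - 1)
  msc <- n * sum((col_mu - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_mu, rep(1, k)) -
                outer(rep(1, n), col_mu) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom <= 0 || !is.finite(denom))
    return(structure(NA_real_, degenerate = TRUE))
  (msr - mse) / denom
}

# Replace the mask of a quantized ROI, keeping its level/intensity grids.
with_mask <- function(q, mask) {
  quantized_roi(q$levels, mask, q$intensities, q$spacing, q$n_levels, q$dims)
}

#' Translated-ROI robustness filter
#'
#' For every patient, timepoint (before/after) and dimensionality
#' (2D/3D), features are extracted from the original ROI and its 8
#' translated copies (9 repeats per subject); ICC(1,1) is computed per
#' feature in each of the four tables, and the robust set is the
#' intersection of the features exceeding `threshold` in all four.
#'
#' @param patients list of `patient_case`s (see [generate_patient()]).
#' @param threshold ICC robustness threshold (default 0.9).
#' @param levels quantization levels.
#' @return an `icc_report`: list with `icc` (feature x 4-table matrix),
#'   `robust_set`, `threshold`, `k` (repeats per subject).
#' @export
robustness_filter <- function(patients, threshold = 0.9, levels = 64L) {
  if (length(patients) < 2L) stop("need >= 2 patients")
  reg <- feature_registry()
  tables <- c("3D.before", "3D.after", "2D.before", "2D.after")
  acc <- lapply(setNames(tables, tables), function(t) list())
  for (p in patients) {
    for (tp in c("before", "after")) {
      prep <- tryCatch(
        preprocess_case(p[[tp]]$volume, p[[tp]]$rois, levels),
        error = function(e) stop("patient ", p$patient_id, " (", tp, "): ",
                                 conditionMessage(e), call. = FALSE))
      for (dm in c("3D", "2D")) {
        q <- if (dm == "3D") prep$q3d else prep$q2d
        masks <- c(list(orig = q$mask), translated_rois(q$mask))
        fmat <- vapply(masks, function(mk)
          as.numeric(extract_all(with_mask(q, mk), p$patient_id, tp)),
          numeric(length(reg)))
        key <- paste(dm, tp, sep = ".")
        acc[[key]][[p$patient_id]] <- fmat  # 55 x 9
      }
    }
  }
  icc <- sapply(tables, function(t) {
    arr <- simplify2array(acc[[t]])               # 55 x 9 x n
    vapply(seq_along(reg), function(f)
      as.numeric(icc_one_way(t(arr[f, , ]))), numeric(1))
  })
  rownames(icc) <- reg
  pass <- !is.na(icc) & icc > threshold
  structure(list(icc = icc, pass = pass,
                 robust_set = reg[rowSums(pass) == length(tables)],
                 threshold = threshold, k = 9L),
            class = "icc_report")
}
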