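#' Rad-score signature container
#'
#' A signature is a sparse linear score over delta features: named
#' coefficients for one endpoint (LR/DM/DFS) and dimensionality (2D/3D),
#' an optional dichotomization cutoff, and a provenance tag
#' (`"fitted"` or `"published"`).
#'
#' @param endpoint one of `"LR"`, `"DM"`, `"DFS"` (or `NA`).
#' @param dims `"2D"` or `"3D"` (or `NA`).
#' @param coefficients named numeric vector; names must belong to the
#'   feature registry when they are registry features.
#' @param cutoff optional numeric cutoff.
#' @param provenance `"fitted"` or `"published"`.
#' @param lambda optional penalty at which the signature was fitted.
#' @return object of class `rad_signature`.
#' @export
rad_signature <- function(endpoint = NA_character_, dims = NA_character_,
                          coefficients = numeric(), cutoff = NULL,
                          provenance = c("fitted", "published"),
                          lambda = NULL) {
  provenance <- match.arg(provenance)
  if (length(coefficients) && is.null(names(coefficients)))
    stop("coefficients must be named")
  structure(list(endpoint = endpoint, dims = dims,
                 coefficients = coefficients, cutoff = cutoff,
                 provenance = provenance, lambda = lambda),
            class = "rad_signature")
}

#' @export
print.rad_signature <- function(x, ...) {
  cat(sprintf("<rad_signature> %s %s (%s), %d term(s)\n",
              x$endpoint, x$dims, x$provenance, length(x$coefficients)))
  for (nm in names(x$coefficients))
    cat(sprintf("  %+.7g x %s\n", x$coefficients[[nm]], nm))
  if (!is.null(x$cutoff)) cat("  cutoff:", format(x$cutoff), "\n")
  invisible(x)
}

# The six published delta-radiomics Rad-score formulas, encoded
# digit-for-digit.
published_coefs <- list(
  LR.3D = c(Volume = -5.9627417e-5,
            Int_Energy = 4.0761146,
            GLCM_Energy = -135.5705805,
            GLCM_SumAverage = 286.7201809,
            GLCM_Autocorrelation = 2.7222298e-3,
            GLSZM_LZLGLE = 0.1212618,
            NGTDM_Coarseness = -263.8275908),
  LR.2D = c(Volume = -3.9078995e-4,
            Int_Energy = 2.4888091,
            GLCM_Energy = -22.2879655,
            GLCM_SumAverage = 432.3870771,
            GLRLM_SRLGLE = -8.7912561,
            NGTDM_Coarseness = -37.6853716),
  DM.3D = c(Int_Energy = 2.0001257,
            GLCM_SumVariance = 9.0766595e-5,
            GLRLM_LRLGLE = -36.4133193,
            GLRLM_LRHGLE = 1.3710706e-4,
            GLSZM_LZHGLE = 2.0565009e-8,
            NGTDM_Coarseness = -108.1326981),
  DM.2D = c(Int_Energy = 0.4580866,
            NGTDM_Coarseness = -45.2277485),
  DFS.3D = c(Int_Energy = 1.6123539,
             GLCM_SumVariance = 7.9686750e-5,
             GLRLM_LRLGLE = -32.6172005,
             GLRLM_LRHGLE = 1.1112033e-4,
             NGTDM_Coarseness = -101.5991090),
  DFS.2D = c(Int_Energy = 0.3188674,
             NGTDM_Coarseness = -44.9766973))

#' Published delta-radiomics signatures
#'
#' Returns one of the six published Rad-score formulas (endpoint in
#' LR/DM/DFS crossed with 2D/3D) as a [rad_signature] with exact
#' coefficients.
#'
#' @param endpoint `"LR"`, `"DM"` or `"DFS"`.
#' @param dims `"2D"` or `"3D"`.
#' @return a [rad_signature] with `provenance = "published"`.
#' @export
published_signature <- function(endpoint, dims) {
  key <- paste(endpoint, dims, sep = ".")
  if (!key %in% names(published_coefs))
    stop("no published signature for (", endpoint, ", ", dims, ")")
  rad_signature(endpoint, dims, published_coefs[[key]],
                provenance = "published")
}

#' Evaluate a Rad score
#'
#' Linear combination of the signature's coefficients with the matching
#' delta-feature values; no intercept.
#'
#' @param sig a [rad_signature].
#' @param delta named numeric delta-feature vector, or a patients x
#'   features matrix with registry column names.
#' @return numeric score (vector of scores for a matrix input).
#' @export
rad_score <- function(sig, delta) {
  cf <- sig$coefficients
  if (is.matrix(delta) || is.data.frame(delta)) {
    delta <- as.matrix(delta)
    miss <- setdiff(names(cf), colnames(delta))
    if (length(miss)) stop("missing delta feature(s): ",
                           paste(miss, collapse = ", "))
    return(as.numeric(delta[, names(cf), drop = FALSE] %*% cf))
  }
  miss <- setdiff(names(cf), names(delta))
  if (length(miss)) stop("missing delta feature(s): ",
                         paste(miss, collapse = ", "))
  sum(cf * as.numeric(delta[names(cf)]))
}

#' LASSO-Cox fit configuration
#'
#' @param n_folds cross-validation folds (default 10).
#' @param seed seed for the stratified fold assignment.
#' @param nlambda points on the log-spaced penalty grid.
#' @param lambda_min_ratio smallest penalty as a fraction of the
#'   all-zero penalty.
#' @param standardize standardize features internally (coefficients are
#'   always reported on the original scale).
#' @return object of class `fit_config`.
#' @export
fit_config <- function(n_folds = 10L, seed = 1L, nlambda = 100L,
                       lambda_min_ratio = 1e-3, standardize = TRUE) {
  if (n_folds < 2L) stop("need >= 2 folds")
  structure(list(n_folds = as.integer(n_folds), seed = as.integer(seed),
                 nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio,
                 standardize = standardize),
            class = "fit_config")
}

# Event-stratified cyclic fold assignment after a seeded shuffle.
stratified_folds <- function(event, n_folds, seed) {
  foldid <- integer(length(event))
  with_seed(seed, {
    for (g in unique(event)) {
      idx <- sample(which(event == g))
      foldid[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  foldid
}

#' Fit a LASSO-Cox delta-radiomics signature
#'
#' L1-penalized Cox partial likelihood over a log-spaced penalty grid;
#' the penalty is chosen by event-stratified k-fold cross-validation at
#' minimum mean partial-likelihood deviance, and the non-zero
#' coefficients are returned on the original feature scale.
#' Deterministic given the seed in `config`.
#'
#' @param X patients x features numeric matrix (no missing values).
#' @param time,event survival outcome (months, 0/1).
#' @param config a [fit_config].
#' @param endpoint,dims labels stored in the result.
#' @param lambda optional fixed penalty; when given, cross-validation is
#'   skipped and the model is solved at this penalty directly.
#' @return a [rad_signature] with `provenance = "fitted"` (possibly with
#'   zero terms when the optimum is the empty model).
#' @export
lasso_cox_fit <- function(X, time, event, config = fit_config(),
                          endpoint = NA_character_, dims = NA_character_,
                          lambda = NULL) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(time) || anyNA(event)) stop("missing values")
  if (sum(event) < 2) stop("need at least 2 events")
  keep <- apply(X, 2, function(col) var(col) > 0)
  if (!all(keep)) {
    warning("dropping constant feature column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  if (ncol(X) < 2L) stop("need at least 2 non-constant features")
  y <- survival::Surv(time, event)
  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(X, y, family = "cox",
                          standardize = config$standardize)
    cf <- as.matrix(coef(fit, s = lambda, exact = FALSE))[, 1]
  } else {
    foldid <- stratified_folds(event, config$n_folds, config$seed)
    cv <- with_seed(config$seed,
      glmnet::cv.glmnet(X, y, family = "cox", foldid = foldid,
                        nlambda = config$nlambda,
                        lambda.min.ratio = config$lambda_min_ratio,
                        standardize = config$standardize))
    lambda <- cv$lambda.min
    cf <- as.matrix(coef(cv, s = "lambda.min"))[, 1]
  }
  cf <- cf[cf != 0]
  rad_signature(endpoint, dims, cf, provenance = "fitted",
                lambda = lambda)
}

#' Optimal Rad-score cutoff by log-rank separation
#'
#' Scans the midpoints between consecutive sorted unique scores,
#' keeping only cutoffs that leave at least `min_group_frac` of patients
#' (and never fewer than 2) on each side, and returns the cutoff
#' maximizing the two-group log-rank chi-square; ties go to the lower
#' cutoff.
#'
#' @param scores numeric Rad scores.
#' @param time,event survival outcome.
#' @param min_group_frac admissibility floor per group (default 0.1).
#' @return list with `cutoff`, `chisq`, `p`.
#' @export
optimal_cutoff <- function(scores, time, event, min_group_frac = 0.1) {
  u <- sort(unique(scores))
  if (length(u) < 2L) stop("all scores identical; no cutoff exists")
  if (sum(event) < 1) stop("need at least one event")
  floor_n <- max(2L, ceiling(min_group_frac * length(scores)))
  cands <- (head(u, -1) + tail(u, -1)) / 2
  best <- NULL
  for (ct in cands) {
    hi <- scores > ct
    if (sum(hi) < floor_n || sum(!hi) < floor_n) next
    sd <- survival::survdiff(survival::Surv(time, event) ~ hi)
    if (is.null(best) || sd$chisq > best$chisq + 1e-12)
      best <- list(cutoff = ct, chisq = sd$chisq,
                   p = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
  }
  if (is.null(best))
    stop("no admissible cutoff: each group must keep >= ", floor_n,
         " patients")
  best
}
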