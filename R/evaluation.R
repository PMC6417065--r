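#' Kaplan-Meier curves and two-group log-rank test
#'
#' @param time,event survival outcome (months, 0/1 with 1 = event).
#' @param group factor-like group labels (exactly 2 distinct values).
#' @return list with `chisq`, `p` (chi-square with 1 df) and `km`
#'   (a `survfit` object with censoring marks).
#' @export
km_logrank <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) stop("need exactly 2 groups")
  if (sum(event) < 1) stop("need at least one event")
  y <- survival::Surv(time, event)
  sd <- survival::survdiff(y ~ group)
  list(chisq = sd$chisq,
       p = pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       km = survival::survfit(y ~ group))
}

#' Cox proportional hazards tables
#'
#' Univariate mode fits one Cox model per covariate; multivariate mode
#' first screens covariates at univariate `p < select_p` and fits the
#' joint model on the survivors (Efron tie handling throughout).
#' Non-convergent or collinear fits are flagged, not fatal.
#'
#' @param X data.frame or matrix of covariates (columns are variables).
#' @param time,event survival outcome.
#' @param mode `"univariate"` or `"multivariate"`.
#' @param select_p univariate screening threshold for multivariate mode.
#' @return data.frame with one row per covariate: `HR`, `lower95`,
#'   `upper95`, `p`, `flag` (empty, `"not_selected"`, `"degenerate"`).
#' @export
cox_fit <- function(X, time, event, mode = c("univariate", "multivariate"),
                    select_p = 0.05) {
  mode <- match.arg(mode)
  X <- as.data.frame(X)
  if (mode == "multivariate" && sum(event) < ncol(X))
    stop("fewer events than covariates in multivariate mode")
  y <- survival::Surv(time, event)
  one_row <- function(fit, nm) {
    s <- summary(fit)
    co <- s$coefficients
    i <- match(nm, rownames(co))
    if (is.na(i) || is.na(co[i, "coef"]))
      return(data.frame(variable = nm, HR = NA, lower95 = NA, upper95 = NA,
                        p = NA, flag = "degenerate"))
    data.frame(variable = nm, HR = unname(exp(co[i, "coef"])),
               lower95 = unname(s$conf.int[i, "lower .95"]),
               upper95 = unname(s$conf.int[i, "upper .95"]),
               p = unname(co[i, ncol(co)]), flag = "")
  }
  safe_fit <- function(fml, dat) {
    ok <- TRUE
    fit <- withCallingHandlers(
      tryCatch(survival::coxph(fml, data = dat, ties = "efron"),
               error = function(e) NULL),
      warning = function(w) {
        if (grepl("converge|infinite|singular", conditionMessage(w)))
          ok <<- FALSE
        invokeRestart("muffleWarning")
      })
    list(fit = fit, ok = ok)
  }
  uni <- do.call(rbind, lapply(names(X), function(nm) {
    dat <- data.frame(y = y, v = X[[nm]])
    sf <- safe_fit(y ~ v, dat)
    if (is.null(sf$fit))
      return(data.frame(variable = nm, HR = NA, lower95 = NA, upper95 = NA,
                        p = NA, flag = "degenerate"))
    r <- one_row(sf$fit, "v")
    r$variable <- nm
    if (!sf$ok) r$flag <- "degenerate"
    r
  }))
  if (mode == "univariate") return(uni)
  sel <- uni$variable[!is.na(uni$p) & uni$p < select_p]
  if (!length(sel)) {
    uni$flag <- ifelse(uni$flag == "", "not_selected", uni$flag)
    return(uni)
  }
  dat <- cbind(data.frame(y = y), X[sel])
  sf <- safe_fit(y ~ ., dat)
  rows <- do.call(rbind, lapply(sel, function(nm) {
    r <- if (is.null(sf$fit))
      data.frame(variable = nm, HR = NA, lower95 = NA, upper95 = NA, p = NA,
                 flag = "degenerate")
    else one_row(sf$fit, nm)
    r$variable <- nm
    if (!is.null(sf$fit) && !sf$ok && r$flag == "") r$flag <- "degenerate"
    r
  }))
  drop <- uni[!uni$variable %in% sel, ]
  if (nrow(drop)) {
    drop$flag <- ifelse(drop$flag == "", "not_selected", drop$flag)
    rows <- rbind(rows, drop)
  }
  rows[match(names(X), rows$variable), , drop = FALSE]
}

#' Harrell's concordance index
#'
#' All usable pairs are event-anchored: `(i, j)` is comparable when
#' subject `i` has an event and either `t_i < t_j`, or `t_i == t_j` with
#' `j` censored.  Concordance credits 1 when the earlier-event subject
#' has the higher score, 0.5 for tied scores.  The standard error comes
#' from the per-subject influence of the underlying U-statistic.
#'
#' @param scores risk scores (higher = higher risk).
#' @param time,event survival outcome.
#' @return list with `C` and `se`.
#' @export
c_index <- function(scores, time, event) {
  n <- length(scores)
  stopifnot(length(time) == n, length(event) == n)
  conc <- comp <- numeric(n)
  for (i in which(event == 1)) {
    usable <- (time > time[i]) | (time == time[i] & event == 0)
    usable[i] <- FALSE
    if (!any(usable)) next
    cr <- (scores[i] > scores[usable]) + 0.5 * (scores[i] == scores[usable])
    conc[i] <- conc[i] + sum(cr)
    comp[i] <- comp[i] + sum(usable)
    conc[usable] <- conc[usable] + cr
    comp[usable] <- comp[usable] + 1
  }
  if (sum(comp) == 0) stop("no comparable pairs")
  C <- sum(conc) / sum(comp)
  # influence-function variance of the ratio estimator
  psi <- conc - C * comp
  se <- 2 * sqrt(sum(psi^2)) / sum(comp)
  list(C = C, se = se)
}

#' Paired bootstrap comparison of two C-indices
#'
#' Resamples patients with replacement, recomputes both concordance
#' indices per replicate, and returns a two-sided p-value from the
#' normal approximation of the bootstrap distribution of `C_A - C_B`.
#'
#' @param scores_a,scores_b two risk scores on the same patients.
#' @param time,event survival outcome.
#' @param n_boot bootstrap replicates (default 1000; < 100 warns).
#' @param seed integer seed.
#' @return list with `delta` (observed `C_A - C_B`), `p`, `C_a`, `C_b`.
#' @export
compare_c <- function(scores_a, scores_b, time, event, n_boot = 1000L,
                      seed = 1L) {
  n <- length(time)
  stopifnot(length(scores_a) == n, length(scores_b) == n)
  if (n_boot < 100L) warning("n_boot < 100 gives an unstable p-value")
  ca <- c_index(scores_a, time, event)$C
  cb <- c_index(scores_b, time, event)$C
  delta <- ca - cb
  ds <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (sum(event[idx]) == 0) return(NA_real_)
    da <- tryCatch(c_index(scores_a[idx], time[idx], event[idx])$C -
                     c_index(scores_b[idx], time[idx], event[idx])$C,
                   error = function(e) NA_real_)
    da
  }, numeric(1)))
  ds <- ds[is.finite(ds)]
  s <- sd(ds)
  p <- if (!is.finite(s) || s == 0) {
    if (abs(delta) < 1e-12) 1 else 0
  } else 2 * pnorm(-abs(delta) / s)
  list(delta = delta, p = p, C_a = ca, C_b = cb)
}

#' AUC and Hosmer-Lemeshow calibration of a risk score
#'
#' The discrimination target is binary event occurrence (censoring times
#' ignored; optionally restrict to subjects followed to `horizon` or
#' with earlier events).  AUC is the rank (Mann-Whitney) statistic.  For
#' calibration the score is first recalibrated through a univariate
#' logistic model, then the Hosmer-Lemeshow chi-square is computed on
#' `g` predicted-probability groups with `g - 2` df.
#'
#' @param scores risk scores.
#' @param event binary event indicators.
#' @param g number of calibration groups (default 10).
#' @return list with `auc`, `hl_chisq`, `hl_df`, `hl_p`.
#' @export
auc_hl <- function(scores, event, g = 10L) {
  event <- as.integer(event)
  n1 <- sum(event == 1); n0 <- sum(event == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[event == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  hl_chisq <- hl_p <- hl_df <- NA_real_
  if (length(event) >= 30) {
    fit <- suppressWarnings(glm(event ~ scores, family = binomial()))
    p <- predict(fit, type = "response")
    br <- unique(quantile(p, probs = seq(0, 1, length.out = g + 1)))
    grp <- cut(p, breaks = br, include.lowest = TRUE)
    O <- tapply(event, grp, sum)
    E <- tapply(p, grp, sum)
    ng <- tapply(p, grp, length)
    keep <- !is.na(O)
    O <- O[keep]; E <- E[keep]; ng <- ng[keep]
    hl_chisq <- sum((O - E)^2 / E + ((ng - O) - (ng - E))^2 / (ng - E))
    hl_df <- length(O) - 2
    hl_p <- if (hl_df > 0) pchisq(hl_chisq, hl_df, lower.tail = FALSE)
            else NA_real_
  }
  list(auc = auc, hl_chisq = hl_chisq, hl_df = hl_df, hl_p = hl_p)
}

#' Pearson correlation and variance inflation factor of two Rad scores
#'
#' Pearson r with Fisher-z 95% confidence interval and t-test p-value,
#' plus `VIF = 1 / (1 - r^2)` for the 2D-vs-3D collinearity check.
#'
#' @param scores_a,scores_b numeric vectors (n >= 3, non-constant, not
#'   perfectly correlated).
#' @return list with `r`, `ci95`, `p`, `vif`.
#' @export
pearson_vif <- function(scores_a, scores_b) {
  if (length(scores_a) < 3L) stop("need n >= 3")
  if (sd(scores_a) == 0 || sd(scores_b) == 0)
    stop("zero variance in a score")
  ct <- cor.test(scores_a, scores_b, method = "pearson")
  r <- unname(ct$estimate)
  if (abs(r) >= 1 - 1e-12) stop("perfect correlation: VIF is unbounded")
  list(r = r, ci95 = as.numeric(ct$conf.int), p = ct$p.value,
       vif = 1 / (1 - r^2))
}
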