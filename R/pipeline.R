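#' Tabular and JSON I/O for pipeline artifacts
#'
#' Feature tables are CSVs with columns `patient_id`, `timepoint`,
#' `dims`, then the 55 registry features; outcome tables have
#' `patient_id`, `endpoint`, `time`, `event`.  Signatures are JSON with
#' full-precision coefficients.
#'
#' @param df data.frame to write.
#' @param path file path.
#' @return readers return the validated data.frame / [rad_signature];
#'   writers return `path` invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_features <- function(df, path) {
  need <- c("patient_id", "timepoint", "dims", feature_registry())
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("feature table missing column(s): ",
                         paste(head(miss, 5), collapse = ", "))
  write.csv(df[need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_features <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  miss <- setdiff(c("patient_id", "timepoint", "dims", feature_registry()),
                  names(df))
  if (length(miss)) stop("malformed feature CSV, missing: ",
                         paste(head(miss, 5), collapse = ", "))
  df
}

#' @rdname pipeline_io
#' @export
write_outcomes <- function(df, path) {
  miss <- setdiff(c("patient_id", "endpoint", "time", "event"), names(df))
  if (length(miss)) stop("outcome table missing column(s): ",
                         paste(miss, collapse = ", "))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_outcomes <- function(path) {
  df <- read.csv(path)
  miss <- setdiff(c("patient_id", "endpoint", "time", "event"), names(df))
  if (length(miss)) stop("malformed outcome CSV, missing: ",
                         paste(miss, collapse = ", "))
  if (any(df$time <= 0)) stop("outcome times must be positive")
  if (!all(df$event %in% 0:1)) stop("events must be 0/1")
  df
}

#' @rdname pipeline_io
#' @param sig a [rad_signature].
#' @export
write_signature <- function(sig, path) {
  jsonlite::write_json(
    list(endpoint = sig$endpoint, dims = sig$dims,
         coefficients = as.list(sig$coefficients),
         cutoff = sig$cutoff, provenance = sig$provenance,
         lambda = sig$lambda),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_signature <- function(path) {
  x <- jsonlite::read_json(path)
  if (is.null(x$coefficients)) stop("malformed signature JSON: no coefficients")
  rad_signature(x$endpoint %||% NA_character_, x$dims %||% NA_character_,
                unlist(x$coefficients), cutoff = x$cutoff,
                provenance = x$provenance %||% "fitted",
                lambda = x$lambda)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline configuration
#'
#' @param out output directory for all stage artifacts.
#' @param cohort a [cohort_config] for the synthetic stage.
#' @param levels quantization levels.
#' @param icc_threshold robustness threshold; `run_robustness = FALSE`
#'   skips the (expensive) translated-ROI stage and treats every feature
#'   as robust.
#' @param run_robustness logical.
#' @param endpoints,dims endpoints and dimensionalities to model.
#' @param split_ratio training:validation ratio.
#' @param signature_source `"fitted"` (LASSO-Cox on the training split)
#'   or `"published"` (score with the encoded published formulas).
#' @param write_volumes write per-patient NIfTI volumes/masks.
#' @param seed pipeline seed (propagated to split and fits).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out, cohort = cohort_config(),
                            levels = 64L, icc_threshold = 0.9,
                            run_robustness = TRUE,
                            endpoints = c("LR", "DM", "DFS"),
                            dims = c("3D", "2D"),
                            split_ratio = c(2, 1),
                            signature_source = c("fitted", "published"),
                            write_volumes = FALSE, seed = 1L) {
  structure(list(out = out, cohort = cohort, levels = as.integer(levels),
                 icc_threshold = icc_threshold,
                 run_robustness = run_robustness,
                 endpoints = endpoints, dims = dims,
                 split_ratio = split_ratio,
                 signature_source = match.arg(signature_source),
                 write_volumes = write_volumes, seed = as.integer(seed)),
            class = "pipeline_config")
}

write_patient_niftis <- function(p, dir) {
  for (tp in c("before", "after")) {
    v <- p[[tp]]$volume; r <- p[[tp]]$rois
    base <- file.path(dir, paste0(p$patient_id, "_", tp))
    write_nifti(v, paste0(base, "_image.nii.gz"))
    write_nifti(r$tumor + 0L, paste0(base, "_tumor.nii.gz"),
                spacing = v$spacing, datatype = "uint8")
    write_nifti(r$bladder + 0L, paste0(base, "_bladder.nii.gz"),
                spacing = v$spacing, datatype = "uint8")
  }
}

#' Run the full delta-radiomics pipeline
#'
#' Executes simulate -> preprocess -> extract -> delta -> robustness ->
#' fit (or published scoring) -> evaluate, writing each stage's artifact
#' into the output directory (`features.csv`, `delta.csv`,
#' `icc_report.json`, `signature_<endpoint>_<dims>.json`,
#' `report.json`, `manifest.json`).  Stage failures raise structured
#' errors naming the stage; artifacts of completed stages are retained.
#'
#' @param cfg a [pipeline_config].
#' @return the output directory, invisibly; the parsed report is
#'   attached as attribute `report`.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))

  cohort <- stage("simulate", generate_cohort(cfg$cohort, levels = cfg$levels))
  write_outcomes(cohort$outcomes, file.path(cfg$out, "outcomes.csv"))
  write.csv(cohort$truth, file.path(cfg$out, "truth.csv"), row.names = FALSE)
  if (cfg$write_volumes) {
    vd <- file.path(cfg$out, "volumes")
    dir.create(vd, showWarnings = FALSE)
    stage("simulate", for (p in cohort$patients) write_patient_niftis(p, vd))
  }

  feats <- stage("extract", {
    rows <- list()
    for (p in cohort$patients) for (tp in c("before", "after")) {
      prep <- preprocess_case(p[[tp]]$volume, p[[tp]]$rois, cfg$levels)
      for (dm in cfg$dims) {
        q <- if (dm == "3D") prep$q3d else prep$q2d
        fv <- extract_all(q, p$patient_id, tp)
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(patient_id = p$patient_id, timepoint = tp,
                           dims = dm), as.data.frame(t(as.numeric(fv))))
      }
    }
    df <- do.call(rbind, rows)
    names(df)[-(1:3)] <- feature_registry()
    df
  })
  write_features(feats, file.path(cfg$out, "features.csv"))

  delta <- stage("delta", {
    rows <- list()
    for (dm in cfg$dims) for (id in unique(feats$patient_id)) {
      b <- feats[feats$patient_id == id & feats$dims == dm &
                   feats$timepoint == "before", feature_registry()]
      a <- feats[feats$patient_id == id & feats$dims == dm &
                   feats$timepoint == "after", feature_registry()]
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(patient_id = id, timepoint = "delta", dims = dm),
              a - b)
    }
    do.call(rbind, rows)
  })
  write_features(delta, file.path(cfg$out, "delta.csv"))

  robust <- stage("robustness", {
    if (cfg$run_robustness) {
      rep <- robustness_filter(cohort$patients, cfg$icc_threshold, cfg$levels)
      jsonlite::write_json(
        list(threshold = rep$threshold, k = rep$k,
             icc = as.data.frame(rep$icc), robust_set = rep$robust_set),
        file.path(cfg$out, "icc_report.json"), auto_unbox = TRUE,
        digits = NA, dataframe = "columns")
      rep$robust_set
    } else feature_registry()
  })

  ids <- unique(delta$patient_id)
  split <- split_cohort(ids, cfg$split_ratio,
                        seed = child_seed(cfg$seed, "split"))
  report <- list(split = split, robust_set = robust, signatures = list())
  for (ep in cfg$endpoints) for (dm in cfg$dims) {
    key <- paste(ep, dm, sep = "_")
    d <- delta[delta$dims == dm, ]
    X <- as.matrix(d[feature_registry()])
    rownames(X) <- d$patient_id
    oc <- cohort$outcomes[cohort$outcomes$endpoint == ep, ]
    oc <- oc[match(d$patient_id, oc$patient_id), ]
    tr <- d$patient_id %in% split$training
    sig <- stage(paste0("fit:", key), {
      if (cfg$signature_source == "published") published_signature(ep, dm)
      else lasso_cox_fit(X[tr, robust, drop = FALSE], oc$time[tr],
                         oc$event[tr],
                         fit_config(seed = child_seed(cfg$seed, "fit", key)),
                         endpoint = ep, dims = dm)
    })
    ev <- stage(paste0("evaluate:", key), {
      if (length(sig$coefficients) == 0) {
        list(empty = TRUE)
      } else {
        sc <- rad_score(sig, X)
        cut <- tryCatch(optimal_cutoff(sc[tr], oc$time[tr], oc$event[tr]),
                        error = function(e) NULL)
        sig$cutoff <- cut$cutoff
        res <- list(empty = FALSE,
                    c_train = c_index(sc[tr], oc$time[tr], oc$event[tr]),
                    c_val = c_index(sc[!tr], oc$time[!tr], oc$event[!tr]))
        if (!is.null(cut)) {
          res$cutoff <- cut$cutoff
          res$logrank_train <- cut[c("chisq", "p")]
          grp_val <- sc[!tr] > cut$cutoff
          if (length(unique(grp_val)) == 2 && sum(oc$event[!tr]) > 0) {
            lr <- km_logrank(oc$time[!tr], oc$event[!tr], grp_val)
            res$logrank_val <- lr[c("chisq", "p")]
          }
        }
        res
      }
    })
    write_signature(sig, file.path(cfg$out, paste0("signature_", key, ".json")))
    report$signatures[[key]] <- ev
  }
  jsonlite::write_json(report, file.path(cfg$out, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest <- list(
    package = "deltarad",
    version = as.character(utils::packageVersion("deltarad")),
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(file.path(cfg$out, "outcomes.csv"))),
    files = list.files(cfg$out, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                       auto_unbox = TRUE)
  structure(invisible(cfg$out), report = report)
}
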