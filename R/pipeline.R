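# End-to-end orchestration: connectome featurisation -> cognitive scores ->
# confound residualization and robust feature filtering -> cross-validated
# penalty selection -> sparse CCA -> permutation mode test -> mode scoring ->
# multivariate thought-pattern regression (overall and per stratum).
# Every stage writes its output as tab-separated text; a JSON manifest
# records paths, per-stage seeds and timings.

#' Pipeline configuration
#'
#' @param cohort A `"synthetic_cohort"` object to analyse, or `NULL`.
#' @param simulate A [cohort_config()]; when `cohort` is `NULL` the pipeline
#'   generates its own input cohort from it.
#' @param out_dir Output directory for all stage artifacts.
#' @param mad_fraction Fraction of edge features retained by the robust
#'   variance filter (default 0.05).
#' @param clip Correlation clipping tolerance for the Fisher transform.
#' @param filter_first Apply the MAD filter before confound residualization
#'   (default `TRUE`); set `FALSE` to residualize all features first.
#' @param grid Penalty search grid, see [default_penalty_grid()].
#' @param k_folds Cross-validation folds for penalty selection.
#' @param penalty Optional fixed penalty fractions `(cx, cy)`; skips the CV
#'   search when supplied.
#' @param K Number of canonical modes to extract and test.
#' @param n_perm Number of permutations for the mode test (>= 1).
#' @param alpha Mode acceptance level.
#' @param tol,max_iter Solver settings.
#' @param schedule Cognitive score schedule, see [default_score_schedule()].
#' @param seed Master seed; per-stage seeds are derived from it
#'   deterministically.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(cohort = NULL, simulate = NULL,
                            out_dir = file.path(tempdir(), "neurocca_run"),
                            mad_fraction = 0.05, clip = 1e-7,
                            filter_first = TRUE,
                            grid = default_penalty_grid(), k_folds = 5L,
                            penalty = NULL, K = 2L, n_perm = 1000L,
                            alpha = 0.05, tol = 1e-6, max_iter = 200L,
                            schedule = default_score_schedule(),
                            seed = 1L) {
  if (is.null(cohort) && is.null(simulate)) {
    stop("supply an input `cohort` or a `simulate` cohort_config")
  }
  if (!is.null(cohort) && !inherits(cohort, "synthetic_cohort")) {
    stop("`cohort` must be a synthetic_cohort")
  }
  if (!is.null(simulate) && !inherits(simulate, "cohort_config")) {
    stop("`simulate` must be a cohort_config")
  }
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1) {
    stop("`n_perm` must be a positive integer")
  }
  if (mad_fraction <= 0 || mad_fraction > 1) {
    stop("`mad_fraction` must lie in (0, 1]")
  }
  if (!is.null(penalty) &&
      (length(penalty) != 2 || any(penalty <= 0) || any(penalty > 1))) {
    stop("`penalty` must be two fractions in (0, 1]")
  }
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  structure(
    list(cohort = cohort, simulate = simulate, out_dir = out_dir,
         mad_fraction = mad_fraction, clip = clip,
         filter_first = filter_first, grid = grid,
         k_folds = as.integer(k_folds), penalty = penalty,
         K = as.integer(K), n_perm = n_perm, alpha = alpha, tol = tol,
         max_iter = as.integer(max_iter), schedule = schedule,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

write_tsv <- function(obj, dir, name, rownames = FALSE) {
  path <- file.path(dir, name)
  utils::write.table(obj, path, sep = "\t", quote = FALSE,
                     row.names = rownames,
                     col.names = if (rownames) NA else TRUE)
  path
}

#' Run the full association pipeline
#'
#' Executes every analysis stage on the configured cohort and writes all
#' intermediates (feature tables, score tables, CV grid, canonical-vector
#' loadings, permutation null distribution, thought-pattern reports) under
#' `config$out_dir`, together with `manifest.json`. A stage failure aborts
#' the run with the stage name; the partial manifest (status `"failed"`) is
#' still written.
#'
#' @param config A [pipeline_config()] object.
#' @return Invisibly, the manifest list (also element `results` with the
#'   in-memory stage objects).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("`config` must be created with pipeline_config()")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- config$out_dir
  manifest <- list(
    package_version = as.character(utils::packageVersion("neurocca")),
    master_seed = config$seed,
    stage_seeds = list(simulate = config$seed,
                       cv = config$seed + 1L,
                       permutation = config$seed + 2L),
    settings = list(mad_fraction = config$mad_fraction, clip = config$clip,
                    filter_first = config$filter_first,
                    k_folds = config$k_folds, K = config$K,
                    n_perm = config$n_perm, alpha = config$alpha,
                    tol = config$tol, max_iter = config$max_iter),
    stages = list(), paths = list(), warnings = list(), timing = list(),
    status = "running"
  )
  results <- list()
  finalize <- function(status) {
    manifest$status <<- status
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        manifest$stages[[name]] <<- "failed"
        finalize("failed")
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }),
      warning = function(w) {
        manifest$warnings[[name]] <<-
          c(manifest$warnings[[name]], conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    manifest$stages[[name]] <<- "ok"
    manifest$timing[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    value
  }

  # --- input cohort -------------------------------------------------------
  cohort <- stage("input", {
    if (!is.null(config$cohort)) config$cohort else {
      cfg <- config$simulate
      cfg$seed <- config$seed
      simulate_cohort(cfg)
    }
  })

  # --- connectome features ------------------------------------------------
  X <- stage("features", {
    feats <- if (!is.null(cohort$connectivity)) cohort$connectivity else
      connectome_features(cohort$roi_timeseries, clip = config$clip)
    manifest$paths$features <- write_tsv(feats, out, "features.tsv",
                                          rownames = TRUE)
    feats
  })

  # --- cognitive scores ---------------------------------------------------
  scores <- stage("scores", {
    sc <- assemble_scores(cohort$raw_task, schedule = config$schedule)
    manifest$paths$scores <- write_tsv(sc, out, "cognitive_scores.tsv",
                                        rownames = TRUE)
    sc
  })

  # --- feature filtering + confound residualization -----------------------
  prep <- stage("prepare", {
    covs <- cohort$covariates
    if (config$filter_first) {
      fs <- mad_filter(X, config$mad_fraction)
      Xf <- residualize_confounds(X[, fs$selected, drop = FALSE], covs)
    } else {
      Xr <- residualize_confounds(X, covs)
      fs <- mad_filter(Xr, config$mad_fraction)
      Xf <- Xr[, fs$selected, drop = FALSE]
    }
    Xs <- standardize_columns(Xf)
    Ys <- standardize_columns(residualize_confounds(scores, covs))
    manifest$paths$selected_features <- write_tsv(
      data.frame(index = fs$selected,
                 label = colnames(X)[fs$selected] %||% fs$selected,
                 mad = fs$mad[fs$selected]),
      out, "selected_features.tsv")
    manifest$paths$x_prepared <- write_tsv(Xs, out, "x_prepared.tsv",
                                            rownames = TRUE)
    manifest$paths$y_prepared <- write_tsv(Ys, out, "y_prepared.tsv",
                                            rownames = TRUE)
    list(x = Xs, y = Ys, selection = fs)
  })

  # --- penalty selection --------------------------------------------------
  penalty <- stage("select", {
    if (!is.null(config$penalty)) {
      manifest$paths$cv_table <- NULL
      results$cv <- NULL
      config$penalty
    } else {
      cv <- scca_cv(prep$x, prep$y, grid = config$grid,
                    k_folds = config$k_folds,
                    seed = config$seed + 1L, tol = config$tol,
                    max_iter = config$max_iter)
      manifest$paths$cv_table <- write_tsv(cv$table, out, "cv_table.tsv")
      results$cv <- cv
      cv$best_penalty
    }
  })
  manifest$selected_penalty <- as.list(stats::setNames(as.numeric(penalty),
                                                       c("cx", "cy")))

  # --- sparse CCA + permutation mode test ---------------------------------
  perm <- stage("permtest", {
    pt <- scca_permtest(prep$x, prep$y, penalty = penalty, K = config$K,
                        n_perm = config$n_perm, alpha = config$alpha,
                        seed = config$seed + 2L, tol = config$tol,
                        max_iter = config$max_iter)
    manifest$paths$loadings_u <- write_tsv(pt$fit$u, out,
                                            "loadings_connectivity.tsv",
                                            rownames = TRUE)
    manifest$paths$loadings_v <- write_tsv(pt$fit$v, out,
                                            "loadings_task.tsv",
                                            rownames = TRUE)
    manifest$paths$null_first_r <- write_tsv(
      data.frame(null_first_r = pt$null_first_r), out, "null_first_r.tsv")
    manifest$paths$mode_test <- write_tsv(
      data.frame(mode = seq_len(config$K), canonical_r = pt$observed_r,
                 p_fwe = pt$p_fwe, accepted = pt$accepted),
      out, "mode_test.tsv")
    pt
  })
  manifest$canonical_r <- as.numeric(perm$observed_r)
  manifest$p_fwe <- as.numeric(perm$p_fwe)
  manifest$accepted_modes <- sum(perm$accepted)

  results$cohort <- cohort
  results$prepared <- prep
  results$permtest <- perm

  if (!any(perm$accepted)) {
    manifest$note <- "no mode passed the permutation test; association stages skipped"
    finalize("ok")
    results$manifest <- manifest
    return(invisible(structure(list(manifest = manifest, results = results),
                               class = "neurocca_run")))
  }

  # --- mode scores + thought-pattern regressions --------------------------
  assoc <- stage("associate", {
    keep <- which(perm$accepted)
    pr <- predict(perm$fit, newx = prep$x, newy = prep$y)
    ms <- mode_score(pr$xu[, keep, drop = FALSE],
                     pr$yv[, keep, drop = FALSE])
    scores_df <- as.data.frame(ms$score)
    names(scores_df) <- paste0("mode", keep, "_score")
    rownames(scores_df) <- cohort$subjects
    manifest$paths$mode_scores <- write_tsv(scores_df, out,
                                             "mode_scores.tsv",
                                             rownames = TRUE)
    predictors <- cbind(scores_df, cohort$covariates)
    items <- standardize_columns(as.matrix(cohort$mdes_overall[mdes_items()]))
    overall <- manova_pillai(items, predictors)
    by_condition <- stratified_patterns(cohort$mdes, predictors,
                                        subjects = cohort$subjects,
                                        by = "condition")
    by_day <- stratified_patterns(cohort$mdes, predictors,
                                  subjects = cohort$subjects, by = "day")

    pattern_table <- function(res, stratum) {
      do.call(rbind, lapply(res$patterns, function(p) {
        data.frame(stratum = stratum, predictor = p$predictor,
                   pillai = p$pillai, f_stat = p$f_stat,
                   df_num = p$df_num, df_den = p$df_den,
                   p_value = p$p_value, eta_sq = p$eta_sq, n = p$n,
                   t(p$coefficients))
      }))
    }
    report <- rbind(
      pattern_table(overall, "overall"),
      do.call(rbind, lapply(names(by_condition), function(lv) {
        pattern_table(by_condition[[lv]], paste0("condition_", lv))
      })),
      do.call(rbind, lapply(names(by_day), function(lv) {
        pattern_table(by_day[[lv]], paste0("day_", lv))
      }))
    )
    manifest$paths$thought_patterns <- write_tsv(report, out,
                                                  "thought_patterns.tsv")

    # ranked-loading summary for the first accepted mode's pattern
    first_pred <- paste0("mode", keep[1], "_score")
    co <- overall$patterns[[first_pred]]$coefficients
    manifest$paths$ranked_loadings <- write_tsv(
      data.frame(item = names(co), coefficient = co,
                 rank = rank(-abs(co)))[order(-abs(co)), ],
      out, "ranked_loadings.tsv")

    # cross-stratum pattern similarity against the overall pattern
    sim <- do.call(rbind, lapply(names(overall$patterns), function(pn) {
      strata <- c(stats::setNames(by_condition,
                                  paste0("condition_",
                                         names(by_condition))),
                  stats::setNames(by_day, paste0("day_", names(by_day))))
      do.call(rbind, lapply(names(strata), function(sn) {
        ps <- pattern_similarity(overall$patterns[[pn]],
                                 strata[[sn]]$patterns[[pn]])
        data.frame(predictor = pn, stratum = sn, r = ps$r, p = ps$p)
      }))
    }))
    manifest$paths$pattern_similarity <- write_tsv(sim, out,
                                                    "pattern_similarity.tsv")
    list(mode_scores = ms, predictors = predictors, overall = overall,
         by_condition = by_condition, by_day = by_day, similarity = sim)
  })
  results$association <- assoc

  finalize("ok")
  results$manifest <- manifest
  invisible(structure(list(manifest = manifest, results = results),
                      class = "neurocca_run"))
}

#' @export
print.neurocca_run <- function(x, ...) {
  m <- x$manifest
  cat("neurocca pipeline run (status:", m$status, ")\n")
  cat("  output:", normalizePath(dirname(m$paths$features %||% ".")), "\n")
  cat("  canonical r:", paste(sprintf("%.3f", m$canonical_r),
                              collapse = ", "), "\n")
  cat("  accepted modes:", m$accepted_modes, "\n")
  if (!is.null(x$results$association)) {
    cat("  overall thought-pattern tests:\n")
    print(x$results$association$overall)
  }
  invisible(x)
}
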