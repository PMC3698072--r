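# Workflow orchestration: run every configured stratified comparison
# (univariate table, stepwise or ensemble model, standardized coefficients,
# LOOCV confusion matrix, five rates) and render report tables in the
# published column layout, with a machine-readable JSON mirror.

#' Run the full classification study
#'
#' For each configured comparison: select the cohort, preprocess
#' (impute -> log2 -> z-score on the full comparison cohort by default),
#' compute the univariate comparison table, select markers (stepwise
#' partial-F by default, or the random-subset ensemble), fit the
#' discriminant model, and evaluate it by leave-one-out cross-validation.
#' A comparison where no feature meets the entry criterion is reported as
#' "NA — no model".  A failing comparison is logged and skipped; the others
#' proceed.
#'
#' @param panel a `cytokine_panel` (or a `synthetic_spec`, which is
#'   generated first).
#' @param comparisons list of comparison definitions; each a list with a
#'   `label`, a pair in `diagnoses` or `sexes`, optional `sex`/`diagnosis`
#'   filters, optional `time_points`, optional `method`
#'   (`"stepwise"` default, or `"ensemble"`), and for the ensemble method
#'   optional `top_k` (default 2).
#' @param preprocess list of overrides for [preprocess_matrix()]
#'   (`impute_value`, `impute_stage`, `sd_type`).
#' @param stepwise_cfg list: `p_enter` (0.05), `p_remove` (0.10).
#' @param ensemble_cfg list: `n_iterations` (500), `subset_size` (5),
#'   `accuracy_threshold` (0.80).
#' @param covariance_mode covariance used for stepwise-selected models
#'   (`"pooled_full"` default; ensemble models always use `"diagonal"`).
#' @param priors `"equal"` or `"proportional"`.
#' @param scale_in_fold leakage-free LOOCV standardization (default FALSE,
#'   matching one-shot preprocessing).
#' @param seed integer seed driving every stochastic step.
#' @param out_dir optional directory; when given, writes
#'   `<label>_univariate.csv`, `report_table.csv` and `report.json`.
#' @return object of class `study_report`: per-comparison results and the
#'   rendered table.
#' @export
run_study <- function(panel, comparisons,
                      preprocess = list(),
                      stepwise_cfg = list(p_enter = 0.05, p_remove = 0.10),
                      ensemble_cfg = list(n_iterations = 500L,
                                          subset_size = 5L,
                                          accuracy_threshold = 0.80),
                      covariance_mode = "pooled_full",
                      priors = "equal",
                      scale_in_fold = FALSE,
                      seed = 1L,
                      out_dir = NULL) {
  if (inherits(panel, "synthetic_spec")) panel <- generate_cohort(panel)$panel
  stopifnot(inherits(panel, "cytokine_panel"))
  results <- vector("list", length(comparisons))
  for (i in seq_along(comparisons)) {
    cmp <- comparisons[[i]]
    label <- cmp$label %||% paste0("comparison_", i)
    res <- tryCatch(
      run_comparison(panel, cmp, preprocess, stepwise_cfg, ensemble_cfg,
                     covariance_mode, priors, scale_in_fold,
                     seed = seed + i),
      error = function(e) {
        warning(sprintf("comparison '%s' failed: %s", label,
                        conditionMessage(e)))
        list(error = conditionMessage(e))
      }
    )
    res$label <- label
    results[[i]] <- res
  }
  names(results) <- vapply(results, `[[`, "", "label")
  report <- structure(list(results = results,
                           table = render_table(results),
                           seed = seed),
                      class = "study_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

run_comparison <- function(panel, cmp, preprocess, stepwise_cfg,
                           ensemble_cfg, covariance_mode, priors,
                           scale_in_fold, seed) {
  sel <- select_cohort(panel,
                       diagnoses = cmp$diagnoses, sexes = cmp$sexes,
                       sex = cmp$sex, diagnosis = cmp$diagnosis,
                       time_points = cmp$time_points %||% TIME_POINTS)
  univariate <- compare_table(panel,
                              diagnoses = cmp$diagnoses, sexes = cmp$sexes,
                              sex = cmp$sex, diagnosis = cmp$diagnosis,
                              time_points = cmp$time_points %||% TIME_POINTS)
  Xl <- do.call(preprocess_matrix,
                c(list(X = sel$X, mask = sel$mask, standardize = FALSE),
                  preprocess[setdiff(names(preprocess), "sd_type")]))
  # constant features carry no class information and cannot be z-scored;
  # dropping them here lets degenerate inputs flow to the "no model" path
  sds <- apply(Xl, 2, stats::sd)
  keep <- is.finite(sds) & sds > 0
  method <- cmp$method %||% "stepwise"
  out <- list(groups = sel$groups, method = method, univariate = univariate,
              n = as.vector(table(sel$y)),
              dropped = colnames(Xl)[!keep])
  if (!any(keep)) {
    out$no_model <- TRUE
    return(out)
  }
  Xp <- zscore(Xl[, keep, drop = FALSE],
               sd_type = preprocess$sd_type %||% "sample")
  if (method == "stepwise") {
    trace <- stepwise(Xp, sel$y,
                      p_enter = stepwise_cfg$p_enter %||% 0.05,
                      p_remove = stepwise_cfg$p_remove %||% 0.10)
    out$trace <- trace
    if (trace$no_model) {
      out$no_model <- TRUE
      return(out)
    }
    feats <- trace$selected
    mode <- covariance_mode
  } else if (method == "ensemble") {
    rk <- ensemble_rank(Xp, sel$y,
                        n_iterations = ensemble_cfg$n_iterations %||% 500L,
                        subset_size = ensemble_cfg$subset_size %||% 5L,
                        accuracy_threshold =
                          ensemble_cfg$accuracy_threshold %||% 0.80,
                        seed = seed)
    out$ranking <- rk
    if (rk$n_passing == 0L) {
      out$no_model <- TRUE
      return(out)
    }
    feats <- rk$ranking$feature[seq_len(cmp$top_k %||% 2L)]
    mode <- "diagonal"
  } else {
    stop("unknown selection method: ", method)
  }
  out$no_model <- FALSE
  out$features <- feats
  out$model <- fit_lda(Xp[, feats, drop = FALSE], sel$y,
                       covariance_mode = mode, priors = priors)
  out$confusion <- loocv(Xp, sel$y, features = feats,
                         covariance_mode = mode, priors = priors,
                         scale_in_fold = scale_in_fold)
  out$metrics <- evaluate_metrics(out$confusion)
  out
}

#' Render study results in the published table layout
#'
#' One block per comparison with columns Model / Stand. coeff. /
#' Assigned `<A>` / Assigned `<B>` / Total / truth label / Accuracy / NPV /
#' PPV / Specificity / Sensitivity.  Multi-feature models occupy one row
#' per feature (counts and rates on the first two rows); a comparison with
#' no model renders a single "NA" row with "NA" rate cells.  Rates are
#' rounded half-up to 2 decimals.
#'
#' @param results list of comparison results from [run_study()] (or a
#'   `study_report`).
#' @return character data frame in the table layout.
#' @export
render_table <- function(results) {
  if (inherits(results, "study_report")) results <- results$results
  cols <- c("Comparison", "Model", "Stand. coeff.", "Assigned A",
            "Assigned B", "Total", "Truth", "Accuracy", "NPV", "PPV",
            "Specificity", "Sensitivity")
  empty <- function() stats::setNames(rep("", length(cols)), cols)
  rows <- list()
  for (res in results) {
    if (!is.null(res$error)) {
      r <- empty()
      r["Comparison"] <- res$label
      r["Model"] <- paste0("ERROR: ", res$error)
      rows[[length(rows) + 1L]] <- r
      next
    }
    A <- res$groups[1]; B <- res$groups[2]
    if (isTRUE(res$no_model)) {
      r <- empty()
      r["Comparison"] <- res$label
      r["Model"] <- "NA"
      r[c("Accuracy", "NPV", "PPV", "Specificity", "Sensitivity")] <- "NA"
      r["Truth"] <- paste("True", A)
      rows[[length(rows) + 1L]] <- r
      next
    }
    k <- res$confusion$counts
    m <- res$metrics
    std <- res$model$standardized
    nfeat <- length(res$features)
    for (j in seq_len(max(nfeat, 2L))) {
      r <- empty()
      if (j == 1L) r["Comparison"] <- res$label
      if (j <= nfeat) {
        r["Model"] <- res$features[j]
        r["Stand. coeff."] <- fmt2(std[j])
      }
      if (j <= 2L) {
        g <- res$groups[j]
        r["Assigned A"] <- as.character(k[g, A])
        r["Assigned B"] <- as.character(k[g, B])
        r["Total"] <- as.character(sum(k[g, ]))
        r["Truth"] <- paste("True", g)
      }
      if (j == 1L) {
        r["Accuracy"] <- fmt2(m$accuracy)
        r["NPV"] <- fmt2(m$npv)
        r["PPV"] <- fmt2(m$ppv)
        r["Specificity"] <- fmt2(m$specificity)
        r["Sensitivity"] <- fmt2(m$sensitivity)
      }
      rows[[length(rows) + 1L]] <- r
    }
  }
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tab) <- cols
  # name the assignment columns after the groups of the first comparison
  first <- Filter(function(r) is.null(r$error) && !is.null(r$groups), results)
  if (length(first)) {
    names(tab)[names(tab) == "Assigned A"] <-
      paste("Assigned", first[[1]]$groups[1])
    names(tab)[names(tab) == "Assigned B"] <-
      paste("Assigned", first[[1]]$groups[2])
  }
  tab
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d comparison(s), seed %d\n",
              length(x$results), x$seed))
  print(x$table, row.names = FALSE)
  invisible(x)
}

# serialize a comparison result to plain lists for the JSON mirror
result_to_json <- function(res) {
  if (!is.null(res$error)) {
    return(list(label = res$label, error = res$error))
  }
  out <- list(label = res$label, groups = res$groups, method = res$method,
              n = res$n, no_model = isTRUE(res$no_model))
  if (!isTRUE(res$no_model)) {
    m <- res$metrics
    out$features <- res$features
    out$B0 <- res$model$B0
    out$B <- res$model$B
    out$standardized <- res$model$standardized
    out$covariance_mode <- res$model$covariance_mode
    out$priors <- res$model$priors
    out$confusion <- res$confusion$counts
    out$metrics <- list(accuracy = m$accuracy, sensitivity = m$sensitivity,
                        specificity = m$specificity, ppv = m$ppv,
                        npv = m$npv)
    out$metrics_2dp <- as.list(m$rounded)
  }
  out
}

#' Write a study report to disk
#'
#' Writes the rendered table (`report_table.csv`), per-comparison
#' univariate tables (`<label>_univariate.csv`) and the machine-readable
#' mirror (`report.json`).  Reruns with an identical configuration and
#' seed produce byte-identical JSON.
#'
#' @param report a `study_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$table, file.path(out_dir, "report_table.csv"),
                     sep = ",", row.names = FALSE, quote = TRUE)
  for (res in report$results) {
    if (!is.null(res$univariate)) {
      utils::write.table(res$univariate,
                         file.path(out_dir,
                                   paste0(gsub("[^A-Za-z0-9_-]", "_",
                                               res$label),
                                          "_univariate.csv")),
                         sep = ",", row.names = FALSE, quote = TRUE)
    }
  }
  js <- lapply(unname(report$results), result_to_json)
  jsonlite::write_json(list(seed = report$seed, comparisons = js),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
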