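#' First coefficient rank that is predictive of survival and sensitivity
#'
#' Walks the features of a coefficient ranking in rank order (1, 2, ...) and
#' returns the first rank whose pathway (i) separates median-split responder
#' classes on the treated patient cohort with log-rank p below `alpha_sig`,
#' and (ii) differs between isogenic sensitive and resistant lines with
#' t-test p below `alpha_sig` in the direction consistent with the sign of
#' its coefficient (a positive coefficient maps high activity to high IC50,
#' so resistant lines should show the higher activity, and vice versa).
#' Returns `NA` when no feature qualifies.
#'
#' @param ranking A `coef_ranking` trained on organoids.
#' @param patient_activity `expr_matrix`, pathways x patients
#'   (z-standardized).
#' @param clinical Clinical table; only rows with `treated == TRUE` are used.
#' @param isogenic_activity `expr_matrix`, pathways x isogenic lines.
#' @param isogenic_labels `"sensitive"`/`"resistant"` labels over the lines.
#' @param alpha_sig Significance level for both criteria (default 0.05).
#' @param require_isogenic Set `FALSE` to relax to the survival criterion
#'   only.
#' @return Integer rank, or `NA_integer_` if none qualifies.
#' @export
best_predictive_rank <- function(ranking, patient_activity, clinical,
                                 isogenic_activity, isogenic_labels,
                                 alpha_sig = 0.05, require_isogenic = TRUE) {
  if (length(ranking$ranks) == 0L) stop("empty ranking")
  treated <- clinical[clinical$treated, , drop = FALSE]
  feats <- names(sort(ranking$ranks))
  for (i in seq_along(feats)) {
    f <- feats[i]
    beta <- ranking$coefficients[[f]]
    if (beta == 0) next  # no direction, cannot qualify
    if (!f %in% rownames(patient_activity)) next
    sc <- score_patients(patient_activity,
                         single_feature_ranking(f, beta), n_top = 1L)
    sc <- tryCatch(median_split(sc), error = function(e) NULL)
    if (is.null(sc)) next
    sub <- merge(treated, sc[, c("patient_id", "cls")], by = "patient_id")
    resp <- sub[sub$cls == "responder", , drop = FALSE]
    nonr <- sub[sub$cls == "non_responder", , drop = FALSE]
    if (nrow(resp) == 0L || nrow(nonr) == 0L) next
    lr <- tryCatch(
      logrank_test(resp$time_days, resp$event, nonr$time_days, nonr$event),
      error = function(e) NULL
    )
    if (is.null(lr) || lr$p >= alpha_sig) next
    if (require_isogenic) {
      if (!f %in% rownames(isogenic_activity)) next
      ic <- isogenic_contrast(isogenic_activity, isogenic_labels, f)
      expected_dir <- if (beta > 0) "resistant" else "sensitive"
      if (ic$p >= alpha_sig || ic$direction != expected_dir) next
    }
    return(i)
  }
  NA_integer_
}

# empirical p of an observed predictive rank against null ranks: fraction of
# iterations whose rank is defined and numerically <= the observed rank
# (rank 1 = best); NA iterations never count; NA observed rank gives p = 1
empirical_rank_p <- function(observed_rank, null_ranks) {
  if (is.na(observed_rank)) return(1)
  sum(!is.na(null_ranks) & null_ranks <= observed_rank) / length(null_ranks)
}

# minimal one-feature ranking for internal scoring
single_feature_ranking <- function(feature, beta) {
  structure(list(model_kind = "ridge", alpha = NA_real_, intercept = 0,
                 coefficients = stats::setNames(beta, feature),
                 ranks = stats::setNames(1L, feature)),
            class = "coef_ranking")
}

#' Random-pathway bootstrap of the biomarker's predictive rank
#'
#' Empirical significance of the observed biomarker's predictive rank
#' against arbitrary feature selection. Per iteration, `k` pathways are
#' drawn uniformly without replacement from the collection, the IC50 model
#' is retrained on their activities, and the best predictive rank
#' ([best_predictive_rank()]) is recorded (`NA` when no pathway of the draw
#' is predictive). The empirical p-value is the fraction of iterations whose
#' rank is defined and at least as good as (numerically no larger than) the
#' observed rank; `NA` iterations never count as successes. An observed rank
#' of `NA` (observed biomarker not predictive) yields an empirical p of 1 by
#' definition and is flagged.
#'
#' @param pathways Character vector of candidate pathway names; all must be
#'   rows of `organoid_activity`.
#' @param k Number of pathways per draw (the number of proximal pathways).
#' @param organoid_activity `expr_matrix` of all candidate pathway
#'   activities on the organoids (z-standardized).
#' @param y Named IC50 vector over the organoids.
#' @param observed_ranking The `coef_ranking` of the observed (proximal)
#'   biomarker set, used to compute the observed rank.
#' @inheritParams best_predictive_rank
#' @param n_iter Number of bootstrap iterations (10,000 at full scale).
#' @param seed Integer seed.
#' @param ... Passed to [fit_model()].
#' @return List of class `bootstrap_summary`: `observed_rank`, `null_ranks`,
#'   `empirical_p`, `p_label` (`"< 1/n_iter"` on zero successes),
#'   `n_absent`, `n_iter`.
#' @export
bootstrap_empirical_p <- function(pathways, k, organoid_activity, y,
                                  observed_ranking, patient_activity,
                                  clinical, isogenic_activity,
                                  isogenic_labels, n_iter = 10000L, seed,
                                  alpha_sig = 0.05, require_isogenic = TRUE,
                                  ...) {
  if (missing(seed)) stop("seed is required")
  if (k > length(pathways)) stop("k (", k, ") exceeds collection size (",
                                 length(pathways), ")")
  miss <- setdiff(pathways, rownames(organoid_activity))
  if (length(miss) > 0L) stop("pathway(s) without organoid activity: ",
                              paste(miss, collapse = ", "))
  observed_rank <- best_predictive_rank(
    observed_ranking, patient_activity, clinical, isogenic_activity,
    isogenic_labels, alpha_sig = alpha_sig,
    require_isogenic = require_isogenic
  )
  set.seed(seed)
  null_ranks <- rep(NA_integer_, n_iter)
  for (i in seq_len(n_iter)) {
    draw <- sample(pathways, k)
    fit <- fit_model(unclass(organoid_activity)[draw, , drop = FALSE], y,
                     seed = seed + i, ...)
    null_ranks[i] <- best_predictive_rank(
      fit, patient_activity, clinical, isogenic_activity, isogenic_labels,
      alpha_sig = alpha_sig, require_isogenic = require_isogenic
    )
  }
  if (is.na(observed_rank)) {
    warning("observed biomarker set is not predictive; empirical p = 1 by ",
            "definition")
  }
  emp <- empirical_rank_p(observed_rank, null_ranks)
  structure(list(observed_rank = observed_rank, null_ranks = null_ranks,
                 empirical_p = emp,
                 p_label = if (!is.na(observed_rank) && emp == 0) {
                   paste0("< ", format(1 / n_iter))
                 } else {
                   format(emp)
                 },
                 n_absent = sum(is.na(null_ranks)), n_iter = n_iter),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat("Random-pathway bootstrap (", x$n_iter, " iterations)\n", sep = "")
  cat("  observed predictive rank:",
      if (is.na(x$observed_rank)) "not available" else x$observed_rank, "\n")
  cat("  iterations with no predictive pathway:", x$n_absent, "\n")
  cat("  empirical p:", x$p_label, "\n")
  invisible(x)
}
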