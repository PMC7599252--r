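#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper over [survival::survfit()] returning the curve as a plain
#' data frame. Censored observations reduce the risk set only; at tied
#' times events are processed before censorings (the standard convention).
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 = death, 0 = censored).
#' @return A `data.frame` with columns `time`, `n_risk`, `n_event`,
#'   `survival` (non-increasing, 1 before the first event).
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("empty input")
  if (length(times) != length(events)) stop("times/events length mismatch")
  if (any(times < 0)) stop("negative time")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard unweighted two-sample log-rank test: chi-square statistic
#' `(O_A - E_A)^2 / Var` with the hypergeometric variance, 1 degree of
#' freedom, two-sided by construction.
#'
#' @param times_a,events_a Follow-up times and event indicators, group A.
#' @param times_b,events_b Same for group B.
#' @return List with `statistic` (chi-square, 1 df) and `p`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0L || length(times_b) == 0L) {
    stop("both groups must be nonempty")
  }
  if (sum(events_a) + sum(events_b) == 0) {
    stop("log-rank undefined with no events")
  }
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  grp <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(statistic = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Survival validation of a responder classification
#'
#' Runs the log-rank test between predicted responders and non-responders on
#' the drug-treated cohort and, as a negative control, on the untreated
#' cohort (whose survival should not depend on a drug-response biomarker).
#' The report states both p-values and Kaplan-Meier curves; it does not
#' enforce any claim about them.
#'
#' @param clinical Clinical `data.frame` (see [read_clinical()]) covering
#'   both cohorts.
#' @param scores_treated `patient_scores` with classes, computed on the
#'   treated cohort.
#' @param scores_untreated `patient_scores` with classes, computed on the
#'   untreated cohort.
#' @return List of class `biomarker_validation` with elements `treated` and
#'   `untreated`, each containing `n_responder`, `n_nonresponder`,
#'   `logrank_chi2`, `p`, `km_responder`, `km_nonresponder`.
#' @export
validate_biomarker <- function(clinical, scores_treated, scores_untreated) {
  one_cohort <- function(scores, treated_flag) {
    sub <- clinical[clinical$treated == treated_flag, , drop = FALSE]
    sub <- merge(sub, scores[, c("patient_id", "cls")], by = "patient_id")
    resp <- sub[sub$cls == "responder", , drop = FALSE]
    nonr <- sub[sub$cls == "non_responder", , drop = FALSE]
    if (nrow(resp) == 0L || nrow(nonr) == 0L) {
      stop("a responder class is empty in the ",
           if (treated_flag) "treated" else "untreated", " cohort")
    }
    lr <- logrank_test(resp$time_days, resp$event, nonr$time_days, nonr$event)
    list(n_responder = nrow(resp), n_nonresponder = nrow(nonr),
         logrank_chi2 = lr$statistic, p = lr$p,
         km_responder = km_estimate(resp$time_days, resp$event),
         km_nonresponder = km_estimate(nonr$time_days, nonr$event))
  }
  structure(list(treated = one_cohort(scores_treated, TRUE),
                 untreated = one_cohort(scores_untreated, FALSE)),
            class = "biomarker_validation")
}

#' @export
print.biomarker_validation <- function(x, ...) {
  for (coh in c("treated", "untreated")) {
    r <- x[[coh]]
    cat(sprintf("%-9s cohort: %d responders vs %d non-responders, log-rank chi2 = %.3f, p = %.4g\n",
                coh, r$n_responder, r$n_nonresponder, r$logrank_chi2, r$p))
  }
  invisible(x)
}

#' Pathway activity contrast in isogenic sensitive/resistant lines
#'
#' Unpaired, two-tailed, pooled-variance two-sample t-test on a named
#' pathway's activity between drug-sensitive and drug-resistant isogenic
#' cell lines, reporting which group has the higher mean.
#'
#' @param activity `expr_matrix`, pathways x cell lines.
#' @param labels Character vector over the columns, values `"sensitive"` or
#'   `"resistant"`; both groups must have at least 2 lines.
#' @param pathway Pathway (row) name to test.
#' @return List with `t`, `df`, `p` (two-sided) and `direction` (which group
#'   has the higher mean: `"sensitive"`, `"resistant"`, or `"none"`).
#' @export
isogenic_contrast <- function(activity, labels, pathway) {
  if (!pathway %in% rownames(activity)) stop("unknown pathway: ", pathway)
  labels <- as.character(labels)
  x <- unclass(activity)[pathway, ]
  sens <- x[labels == "sensitive"]
  res <- x[labels == "resistant"]
  if (length(sens) < 2L || length(res) < 2L) {
    stop("both groups need at least 2 cell lines")
  }
  ht <- stats::t.test(sens, res, var.equal = TRUE)
  dir <- if (mean(sens) > mean(res)) "sensitive"
         else if (mean(res) > mean(sens)) "resistant" else "none"
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       direction = dir)
}

#' Leave-up-to-k-organoids-out robustness of mutation concordance
#'
#' For every k in `0..k_max`, retrains the IC50 model on every subset of
#' organoids with k samples removed, rescores the patients with the top
#' biomarker, reruns the one-sided mutation concordance test, and reports
#' the fraction of subsets whose p-value stays below `alpha_sig`.
#'
#' @param organoid_activity `expr_matrix`, pathways x organoids
#'   (z-standardized).
#' @param y Named IC50 vector over the organoids.
#' @param patient_activity `expr_matrix`, pathways x patients
#'   (z-standardized).
#' @param status Mutation status over patients (logical, named or ordered as
#'   the patient columns).
#' @param k_max Maximum number of organoids removed (default 3).
#' @param alpha_sig Significance level for a subset to count as recovered.
#' @param alternative Direction of the concordance test (see
#'   [mutation_concordance()]).
#' @param cap Hard cap on the number of subsets enumerated per k.
#' @param ... Passed to [fit_model()] (model kind, alpha grid, seed...).
#' @return Named numeric vector: fraction of recovering subsets per k
#'   (`"k0"`, `"k1"`, ...).
#' @export
leave_out_robustness <- function(organoid_activity, y, patient_activity,
                                 status, k_max = 3L, alpha_sig = 0.05,
                                 alternative = "greater", cap = 10000L, ...) {
  n <- ncol(organoid_activity)
  if (n <= k_max + 3L) stop("too few organoids for k_max = ", k_max)
  out <- numeric(k_max + 1L)
  names(out) <- paste0("k", 0:k_max)
  for (k in 0:k_max) {
    n_sub <- choose(n, k)
    if (n_sub > cap) {
      stop("C(", n, ",", k, ") = ", n_sub, " subsets exceeds cap ", cap,
           "; reduce k_max or raise cap")
    }
    subsets <- utils::combn(n, k)
    hit <- 0L
    for (j in seq_len(ncol(subsets))) {
      keep <- setdiff(seq_len(n), subsets[, j])
      fit <- fit_model(unclass(organoid_activity)[, keep, drop = FALSE],
                       y, ...)
      sc <- score_patients(patient_activity, fit, n_top = 1L)
      mc <- mutation_concordance(sc, status, alternative = alternative)
      if (mc$p < alpha_sig) hit <- hit + 1L
    }
    out[k + 1L] <- hit / ncol(subsets)
  }
  out
}
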