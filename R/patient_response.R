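#' Patient drug-resistance scores from organoid-trained coefficients
#'
#' For each patient, the predicted drug-resistance score is the sum over the
#' top-ranked biomarker pathways of the patient's standardized pathway
#' activity times that pathway's organoid-derived regression coefficient:
#' \deqn{Score = \sum_{p=1}^{N} Exp_{patient,p} \times \beta_{preclinical,p}}
#' With `n_top = 1` this is the single-biomarker score. Because the
#' coefficients map activity to IC50, a higher score means higher predicted
#' IC50, i.e. predicted resistance.
#'
#' @param activity Patient `expr_matrix` (pathways x patients), z-standardized
#'   within the patient dataset.
#' @param ranking A `coef_ranking` trained on organoids.
#' @param n_top How many top-ranked pathways to combine (default 1).
#' @return A `data.frame` (class `patient_scores`) with columns `patient_id`,
#'   `score` and (after [median_split()]) `cls`; attribute `n_pathways_used`.
#' @export
score_patients <- function(activity, ranking, n_top = 1L) {
  feats <- top_features(ranking, n_top)
  miss <- setdiff(feats, rownames(activity))
  if (length(miss) > 0L) {
    stop("feature row(s) missing from patient activity: ",
         paste(miss, collapse = ", "))
  }
  beta <- ranking$coefficients[feats]
  sc <- drop(crossprod(unclass(activity)[feats, , drop = FALSE], beta))
  out <- data.frame(patient_id = colnames(activity), score = unname(sc),
                    cls = NA_character_, stringsAsFactors = FALSE)
  attr(out, "n_pathways_used") <- n_top
  class(out) <- c("patient_scores", class(out))
  out
}

#' Median-split responder classification
#'
#' Rank-orders patients by predicted resistance score and splits at the
#' cohort median: patients at or below the median are called responders
#' (lower predicted resistance), patients above it non-responders. The usual
#' midpoint median is used; ties at the median go to the responder class.
#'
#' @param scores A `patient_scores` table from [score_patients()].
#' @return The table with the `cls` column filled
#'   (`"responder"`/`"non_responder"`).
#' @export
median_split <- function(scores) {
  if (nrow(scores) < 2L) stop("need at least 2 patients")
  if (length(unique(scores$score)) == 1L) {
    stop("all scores identical; no separation; cannot split")
  }
  med <- stats::median(scores$score)
  scores$cls <- ifelse(scores$score <= med, "responder", "non_responder")
  scores
}

#' Concordance of predicted resistance with a mutation biomarker
#'
#' One-sided Mann-Whitney U test comparing predicted resistance scores of
#' mutation carriers against wild-type patients. The default alternative
#' `"greater"` tests resistance mutations (mutant scores higher); use
#' `"less"` for sensitizing mutations. The exact p-value is used when the
#' combined sample size is at most `exact_max` and there are no ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction.
#'
#' @param scores A `patient_scores` table.
#' @param status Logical vector (or named logical over `patient_id`): TRUE =
#'   mutant.
#' @param alternative `"greater"` (mutants more resistant) or `"less"`.
#' @param exact_max Combined-size cutoff for the exact test (default 20).
#' @return List with `U` (Mann-Whitney U statistic of the mutant group) and
#'   `p` (one-sided p-value).
#' @export
mutation_concordance <- function(scores, status,
                                 alternative = c("greater", "less"),
                                 exact_max = 20L) {
  alternative <- match.arg(alternative)
  if (!is.null(names(status))) status <- status[scores$patient_id]
  status <- as.logical(status)
  if (length(status) != nrow(scores)) stop("status length mismatch")
  mut <- scores$score[status]
  wt <- scores$score[!status]
  if (length(mut) == 0L || length(wt) == 0L) {
    stop("both mutant and wild-type groups must be nonempty")
  }
  ties <- anyDuplicated(c(mut, wt)) > 0L
  use_exact <- (length(mut) + length(wt)) <= exact_max && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(mut, wt, alternative = alternative,
                       exact = use_exact, correct = !use_exact)
  )
  list(U = unname(ht$statistic), p = ht$p.value)
}
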