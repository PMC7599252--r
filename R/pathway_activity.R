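#' log2(x + 1) transform
#'
#' Standard variance-stabilizing transform for non-negative expression
#' values (e.g. FPKM-UQ).
#'
#' @param m An `expr_matrix` with non-negative values.
#' @return An `expr_matrix` on the `log2p1` scale.
#' @export
log2_plus_one <- function(m) {
  if (any(m < 0)) stop("negative expression value; log2(x+1) needs x >= 0")
  out <- log2(unclass(m) + 1)
  expression_matrix(out, value_scale = "log2p1")
}

#' Single-sample GSEA pathway activity
#'
#' Computes per-sample pathway enrichment the ssGSEA way. Within each sample,
#' genes are ranked by expression (descending; ties broken by descending gene
#' label so results are deterministic) and assigned rank values n..1. For a
#' gene set the enrichment score is the sum, over the ranked gene list, of
#' the difference between the weighted in-set cumulative distribution (rank
#' values raised to `weight`, normalized to sum 1 over in-set genes) and the
#' uniform out-of-set cumulative distribution. Enrichment scores are
#' normalized to NES by dividing by the range (max - min) of all ES values
#' in the call (`normalize = "global"`, the common ssGSEA convention) or by
#' the per-sample ES range (`normalize = "per_sample"`).
#'
#' @param m An `expr_matrix`, genes x samples.
#' @param coll Named list of gene sets; sets with no gene among the matrix
#'   rows are dropped with a warning.
#' @param weight Rank weighting exponent (ssGSEA convention 0.25).
#' @param normalize `"global"` or `"per_sample"` ES-range normalization;
#'   `"none"` returns raw enrichment scores.
#' @return An `expr_matrix` (pathways x samples) on the `nes` scale, with
#'   attributes `weight` and `normalize` recording the provenance.
#' @export
ssgsea_scores <- function(m, coll, weight = 0.25,
                          normalize = c("global", "per_sample", "none")) {
  normalize <- match.arg(normalize)
  if (nrow(m) < 2L) stop("need at least 2 genes per sample")
  present <- vapply(coll, function(s) any(s %in% rownames(m)), logical(1L))
  if (any(!present)) {
    warning("dropping ", sum(!present), " gene set(s) with no gene in the ",
            "expression matrix: ",
            paste(names(coll)[!present], collapse = ", "))
    coll <- coll[present]
  }
  if (length(coll) == 0L) stop("no scorable gene set")
  genes <- rownames(m)
  n <- length(genes)
  es <- matrix(NA_real_, nrow = length(coll), ncol = ncol(m),
               dimnames = list(names(coll), colnames(m)))
  in_set <- lapply(coll, function(s) genes %in% s)  # by original row order
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    if (all(x == 0)) stop("constant-zero sample: ", colnames(m)[j])
    ord <- order(x, genes, decreasing = TRUE, method = "radix")
    rank_val <- as.numeric(n:1)          # top gene gets rank n
    w <- rank_val^weight
    for (k in seq_along(coll)) {
      ins <- in_set[[k]][ord]
      w_in <- w * ins
      p_in <- cumsum(w_in) / sum(w_in)
      p_out <- cumsum(!ins) / (n - sum(ins))
      if (sum(ins) == n) p_out <- rep(0, n)  # degenerate: set covers all genes
      es[k, j] <- sum(p_in - p_out)
    }
  }
  nes <- switch(normalize,
    none = es,
    global = {
      rng <- max(es) - min(es)
      if (rng == 0) stop("degenerate enrichment scores: zero range")
      es / rng
    },
    per_sample = {
      apply(es, 2L, function(col) {
        rng <- max(col) - min(col)
        if (rng == 0) stop("degenerate enrichment scores: zero range")
        col / rng
      })
    }
  )
  out <- expression_matrix(nes, value_scale = "nes")
  attr(out, "weight") <- weight
  attr(out, "normalize") <- normalize
  out
}

#' Per-feature z-score standardization
#'
#' Standardizes every row (gene or pathway) across samples to mean 0 and
#' standard deviation 1, using the population (n) standard deviation.
#' Constant rows carry no information and are dropped with a warning.
#' Standardization is applied within one dataset at a time; organoid and
#' patient matrices are standardized separately.
#'
#' @param m An `expr_matrix` with at least 2 columns.
#' @return An `expr_matrix` on the `zscore` scale.
#' @export
standardize <- function(m) {
  if (ncol(m) < 2L) stop("cannot standardize a single-column matrix")
  x <- unclass(m)
  mu <- rowMeans(x)
  sd_pop <- sqrt(rowMeans((x - mu)^2))
  const <- sd_pop == 0
  if (any(const)) {
    warning("dropping ", sum(const), " constant row(s): ",
            paste(utils::head(rownames(x)[const], 5L), collapse = ", "))
    x <- x[!const, , drop = FALSE]
    mu <- mu[!const]
    sd_pop <- sd_pop[!const]
  }
  if (nrow(x) == 0L) stop("no non-constant row left to standardize")
  out <- (x - mu) / sd_pop
  expression_matrix(out, value_scale = "zscore")
}
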