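# Ridge solve in the "penalty added directly to X'X" parametrization:
# center X and y, beta = (X'X + alpha I)^-1 X'y, intercept from the means.
# Features are z-standardized upstream, so no internal rescaling is done.
ridge_solve <- function(X, y, alpha) {
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2L, xm)
  yc <- y - ym
  p <- ncol(X)
  beta <- drop(solve(crossprod(Xc) + diag(alpha, p), crossprod(Xc, yc)))
  list(beta = beta, intercept = ym - sum(xm * beta))
}

ols_solve <- function(X, y) {
  Xi <- cbind(`(Intercept)` = 1, X)
  if (qr(Xi)$rank < ncol(Xi)) {
    stop("singular design for linear regression; use kind = 'ridge'")
  }
  cf <- qr.coef(qr(Xi), y)
  list(beta = cf[-1L], intercept = cf[[1L]])
}

svr_solve <- function(X, y, cost = 1) {
  fit <- e1071::svm(x = X, y = y, type = "eps-regression", kernel = "linear",
                    cost = cost, scale = FALSE)
  beta <- drop(crossprod(fit$coefs, fit$SV))
  names(beta) <- colnames(X)
  list(beta = beta, intercept = -fit$rho)
}

#' Fit the IC50 regression and rank features by coefficient magnitude
#'
#' Regresses organoid IC50 on the activity of the selected features in one
#' joint multivariate model and ranks features by |coefficient| descending
#' (rank 1 = largest magnitude, the feature's "predictive performance").
#' For `kind = "ridge"` the penalty alpha is chosen by k-fold cross-validated
#' mean squared error over the grid, then the model is refit on all samples.
#'
#' @param X Activity matrix, features x samples (rows z-standardized).
#' @param y Named numeric vector of IC50 values; names must match the
#'   columns of `X`.
#' @param kind `"ridge"` (default), `"linear"` (OLS), or `"svr_linear"`
#'   (epsilon-insensitive linear SVR at C = 1).
#' @param alphas Ridge penalty grid (default 0.1 to 1.0 by 0.1).
#' @param folds Number of CV folds (default 3).
#' @param seed Integer seed for the fold assignment.
#' @param log10_ic50 Regress on log10(IC50) instead of raw IC50.
#' @return An object of class `coef_ranking`: list with `model_kind`,
#'   `alpha` (chosen penalty, ridge only), `intercept`, `coefficients`
#'   (named numeric), and `ranks` (named integer permutation of 1..p; ties
#'   in |coefficient| broken lexicographically by feature name).
#' @export
fit_model <- function(X, y, kind = c("ridge", "linear", "svr_linear"),
                      alphas = seq(0.1, 1.0, by = 0.1), folds = 3L, seed = 1L,
                      log10_ic50 = FALSE) {
  kind <- match.arg(kind)
  X <- as.matrix(unclass(X))
  if (is.null(names(y))) stop("y must be named by sample")
  miss <- setdiff(colnames(X), names(y))
  if (length(miss) > 0L) stop("samples without response: ",
                              paste(miss, collapse = ", "))
  y <- y[colnames(X)]
  if (log10_ic50) y <- log10(y)
  Xt <- t(X)  # samples as observations
  n <- nrow(Xt)
  if (n < folds) stop("n_samples (", n, ") < folds (", folds, ")")

  chosen_alpha <- NA_real_
  if (kind == "ridge") {
    set.seed(seed)
    fold_id <- sample(rep_len(seq_len(folds), n))
    cv_mse <- vapply(alphas, function(a) {
      errs <- numeric(folds)
      for (f in seq_len(folds)) {
        tr <- fold_id != f
        fit <- ridge_solve(Xt[tr, , drop = FALSE], y[tr], a)
        pred <- drop(Xt[!tr, , drop = FALSE] %*% fit$beta) + fit$intercept
        errs[f] <- mean((y[!tr] - pred)^2)
      }
      mean(errs)
    }, numeric(1L))
    chosen_alpha <- alphas[which.min(cv_mse)]
    fit <- ridge_solve(Xt, y, chosen_alpha)
  } else if (kind == "linear") {
    fit <- ols_solve(Xt, y)
  } else {
    fit <- svr_solve(Xt, y)
  }
  beta <- fit$beta
  names(beta) <- rownames(X)
  ranks <- integer(length(beta))
  ord <- order(-abs(beta), names(beta))
  ranks[ord] <- seq_along(beta)
  names(ranks) <- names(beta)
  structure(list(model_kind = kind, alpha = chosen_alpha,
                 intercept = fit$intercept, coefficients = beta,
                 ranks = ranks),
            class = "coef_ranking")
}

#' @export
print.coef_ranking <- function(x, ...) {
  cat("Coefficient ranking (", x$model_kind,
      if (!is.na(x$alpha)) paste0(", alpha = ", x$alpha), ")\n", sep = "")
  ord <- order(x$ranks)
  df <- data.frame(feature = names(x$coefficients)[ord],
                   beta = unname(x$coefficients)[ord],
                   rank = unname(x$ranks)[ord])
  print(utils::head(df, 10L), row.names = FALSE)
  if (length(ord) > 10L) cat("... and", length(ord) - 10L, "more features\n")
  invisible(x)
}

#' Top-ranked features of a coefficient ranking
#' @param ranking A `coef_ranking`.
#' @param n_top How many features.
#' @return Character vector of feature names in rank order.
#' @export
top_features <- function(ranking, n_top = 1L) {
  if (n_top < 1L || n_top > length(ranking$ranks)) {
    stop("n_top must be in [1, ", length(ranking$ranks), "]")
  }
  names(sort(ranking$ranks))[seq_len(n_top)]
}

#' Out-of-sample predictive ability with a train/validation/test split
#'
#' Splits samples into train/validation/test partitions (default 60/10/30),
#' tunes the ridge penalty by validation RMSE (training on the train
#' partition only), refits on the train partition at the chosen alpha, and
#' reports the squared Pearson correlation between observed and predicted
#' IC50 on the test partition. Partition sizes use floor for train and
#' validation, remainder to test.
#'
#' @inheritParams fit_model
#' @param fractions Numeric length-3 vector (train, validation, test)
#'   summing to 1.
#' @return List of class `split_evaluation`: `fractions`, `sizes`,
#'   `chosen_alpha`, `validation_rmse`, `test_r2`, `seed`.
#' @export
evaluate_split <- function(X, y, fractions = c(0.60, 0.10, 0.30),
                           alphas = seq(0.1, 1.0, by = 0.1), seed = 1L,
                           log10_ic50 = FALSE) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8)
  X <- as.matrix(unclass(X))
  y <- y[colnames(X)]
  if (log10_ic50) y <- log10(y)
  n <- ncol(X)
  n_train <- floor(fractions[1L] * n)
  n_val <- floor(fractions[2L] * n)
  n_test <- n - n_train - n_val
  if (min(n_train, n_val, n_test) < 1L) {
    stop("empty partition at n = ", n, ": train ", n_train, ", validation ",
         n_val, ", test ", n_test)
  }
  set.seed(seed)
  perm <- sample.int(n)
  idx_train <- perm[seq_len(n_train)]
  idx_val <- perm[n_train + seq_len(n_val)]
  idx_test <- perm[n_train + n_val + seq_len(n_test)]
  Xt <- t(X)
  rmse <- vapply(alphas, function(a) {
    fit <- ridge_solve(Xt[idx_train, , drop = FALSE], y[idx_train], a)
    pred <- drop(Xt[idx_val, , drop = FALSE] %*% fit$beta) + fit$intercept
    sqrt(mean((y[idx_val] - pred)^2))
  }, numeric(1L))
  best <- which.min(rmse)
  fit <- ridge_solve(Xt[idx_train, , drop = FALSE], y[idx_train], alphas[best])
  pred_test <- drop(Xt[idx_test, , drop = FALSE] %*% fit$beta) + fit$intercept
  r2 <- if (stats::sd(pred_test) == 0 || stats::sd(y[idx_test]) == 0) {
    0
  } else {
    stats::cor(y[idx_test], pred_test)^2
  }
  structure(list(fractions = fractions,
                 sizes = c(train = n_train, validation = n_val, test = n_test),
                 chosen_alpha = alphas[best],
                 validation_rmse = rmse[best],
                 test_r2 = r2, seed = seed),
            class = "split_evaluation")
}

#' Correlation-based gene pre-selection (leave-half-out)
#'
#' Baseline gene-level feature selection: over `n_iter` iterations, half the
#' organoids are held out at random and the Spearman correlation p-value of
#' every gene's expression with IC50 is computed on the retained half. A
#' gene is selected when the mean of its per-iteration p-values is below
#' `p_cut`. Genes constant on any retained half have no defined rank
#' correlation and are excluded with a warning.
#'
#' @param expr `expr_matrix`, genes x organoids.
#' @param y Named numeric IC50 vector over the organoids.
#' @param n_iter Number of leave-half-out iterations.
#' @param p_cut Selection threshold on the mean p-value.
#' @param seed Integer seed.
#' @return Character vector of selected gene names.
#' @export
bolis_select_genes <- function(expr, y, n_iter = 10L, p_cut = 0.05, seed = 1L) {
  X <- as.matrix(unclass(expr))
  y <- y[colnames(X)]
  n <- ncol(X)
  if (n < 4L) stop("need at least 4 organoids")
  set.seed(seed)
  pmat <- matrix(NA_real_, nrow = nrow(X), ncol = n_iter,
                 dimnames = list(rownames(X), NULL))
  for (i in seq_len(n_iter)) {
    hold <- sample.int(n, floor(n / 2))
    keep <- setdiff(seq_len(n), hold)
    if (length(keep) < 4L) stop("fewer than 4 retained samples")
    yk <- y[keep]
    for (g in seq_len(nrow(X))) {
      xg <- X[g, keep]
      if (stats::sd(xg) == 0) next  # left NA; handled below
      pmat[g, i] <- suppressWarnings(
        stats::cor.test(xg, yk, method = "spearman")$p.value
      )
    }
  }
  undefined <- rowSums(is.na(pmat)) > 0L
  if (any(undefined)) {
    warning("excluding ", sum(undefined),
            " gene(s) with undefined rank correlation (constant on a ",
            "retained half)")
  }
  mean_p <- rowMeans(pmat)
  sel <- !undefined & mean_p < p_cut
  rownames(X)[sel]
}
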