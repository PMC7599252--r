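test_that("Kaplan-Meier estimates match hand product-limit arithmetic", {
  km <- km_estimate(c(5, 10), c(1, 0))
  expect_equal(km$survival[km$time == 5], 0.5, tolerance = 1e-9)
  expect_equal(km$survival[km$time == 10], 0.5, tolerance = 1e-9)

  km2 <- km_estimate(c(1, 2), c(1, 1))
  expect_equal(km2$survival, c(0.5, 0), tolerance = 1e-9)

  # all censored: the curve never drops
  km3 <- km_estimate(c(3, 6, 9), c(0, 0, 0))
  expect_true(all(km3$survival == 1))

  # 5-record fixture with a mid-curve censoring: S after t=2 is
  # (1 - 1/5)(1 - 1/3) with the censored record leaving the risk set only
  km4 <- km_estimate(c(1, 1.5, 2, 4, 5), c(1, 0, 1, 1, 1))
  expect_equal(km4$survival[km4$time == 2], (4 / 5) * (2 / 3),
               tolerance = 1e-9)
  expect_true(all(diff(km4$survival) <= 1e-12))
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank matches the hand-tabled O/E statistic and is symmetric", {
  # A: events at 1, 2; B: events at 3, 4. Hand life table:
  # t=1: E_A = 2/4, V = 1/4; t=2: E_A = 1/3, V = 2/9; t=3,4: E_A = V = 0
  # chi2 = (2 - 5/6)^2 / (1/4 + 2/9) = 49/17
  lr <- logrank_test(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
  expect_equal(lr$statistic, 49 / 17, tolerance = 1e-9)
  expect_equal(lr$p, stats::pchisq(49 / 17, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  lr_swap <- logrank_test(c(3, 4), c(1, 1), c(1, 2), c(1, 1))
  expect_equal(lr_swap$statistic, lr$statistic, tolerance = 1e-12)

  # identical groups: no separation
  lr0 <- logrank_test(c(2, 5, 7), c(1, 0, 1), c(2, 5, 7), c(1, 0, 1))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-12)

  # duplicating every record grows the statistic and shrinks p
  lr2 <- logrank_test(rep(c(1, 2), 2), rep(1, 4), rep(c(3, 4), 2), rep(1, 4))
  expect_gt(lr2$statistic, lr$statistic)
  expect_lt(lr2$p, lr$p)

  expect_error(logrank_test(numeric(0), numeric(0), c(1), c(1)), "nonempty")
  expect_error(logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0)), "no events")
})

test_that("biomarker validation reports both cohorts and errors on an empty
           class", {
  set.seed(11)
  n <- 60
  cl <- data.frame(
    patient_id = sprintf("p%03d", 1:(2 * n)),
    time_days = c(stats::rexp(n, rate = c(rep(3 / 365, n / 2),
                                          rep(1 / 365, n / 2))),
                  stats::rexp(n, rate = 1 / 365)),
    event = 1L,
    treated = rep(c(TRUE, FALSE), each = n),
    stringsAsFactors = FALSE
  )
  sc <- function(ids, scores) {
    median_split(data.frame(patient_id = ids, score = scores,
                            cls = NA_character_, stringsAsFactors = FALSE))
  }
  # treated scores track the hazard split; untreated scores are arbitrary
  st <- sc(cl$patient_id[1:n], c(rnorm(n / 2, 3), rnorm(n / 2, -3)))
  su <- sc(cl$patient_id[(n + 1):(2 * n)], rnorm(n))
  rep_out <- validate_biomarker(cl, st, su)
  expect_lt(rep_out$treated$p, 0.05)
  expect_equal(rep_out$treated$n_responder + rep_out$treated$n_nonresponder, n)
  expect_s3_class(rep_out$treated$km_responder, "data.frame")
  expect_true(rep_out$untreated$p > 0.001)  # arbitrary split, usually null

  st_bad <- st
  st_bad$cls <- "responder"
  expect_error(validate_biomarker(cl, st_bad, su), "empty")
})

test_that("the isogenic contrast reproduces the pooled-variance t-test by
           hand", {
  m <- matrix(c(1, 2, 3, 1, 2, 3), nrow = 1)
  dimnames(m) <- list("P1", paste0("l", 1:6))
  act <- expression_matrix(m, value_scale = "zscore")
  labels <- rep(c("sensitive", "resistant"), each = 3)
  ic0 <- isogenic_contrast(act, labels, "P1")
  expect_equal(ic0$t, 0, tolerance = 1e-12)
  expect_equal(ic0$p, 1, tolerance = 1e-12)
  expect_equal(ic0$direction, "none")

  m2 <- matrix(c(2, 3, 4, 0, 1, 2), nrow = 1,
               dimnames = list("P1", paste0("l", 1:6)))
  ic <- isogenic_contrast(expression_matrix(m2, value_scale = "zscore"),
                          labels, "P1")
  # pooled sd = 1, SE = sqrt(2/3), t = 2 / 0.8165
  expect_equal(ic$t, 2 / sqrt(2 / 3), tolerance = 1e-4)
  expect_equal(ic$df, 4)
  expect_equal(ic$direction, "sensitive")
  expect_error(isogenic_contrast(act, c("sensitive", rep("resistant", 5)),
                                 "P1"), "at least 2")
  expect_error(isogenic_contrast(act, labels, "P9"), "unknown pathway")
})

test_that("a planted 2-sd shift is detected in small isogenic groups", {
  hits <- 0
  for (seed in 1:40) {
    set.seed(seed)
    m <- matrix(c(rnorm(3), rnorm(9, mean = -2)), nrow = 1,
                dimnames = list("P1", paste0("l", 1:12)))
    ic <- isogenic_contrast(expression_matrix(m, value_scale = "zscore"),
                            rep(c("sensitive", "resistant"), c(3, 9)), "P1")
    if (ic$p < 0.05 && ic$direction == "sensitive") hits <- hits + 1
  }
  expect_gte(hits, 32)
})

test_that("leave-out robustness enumerates subsets and recovers strong
           signals", {
  set.seed(21)
  n_org <- 12
  n_pat <- 40
  act_driver <- rnorm(n_org)
  org_act <- rbind(P1 = act_driver, P2 = rnorm(n_org))
  colnames(org_act) <- sprintf("o%02d", 1:n_org)
  y <- stats::setNames(10^(-0.9 * act_driver + 0.3 * rnorm(n_org)),
                       colnames(org_act))
  pat_driver <- rnorm(n_pat)
  pat_act <- rbind(P1 = pat_driver, P2 = rnorm(n_pat))
  colnames(pat_act) <- sprintf("p%03d", 1:n_pat)
  # mutants sit in the resistance direction (low P1 activity)
  status <- stats::setNames(pat_driver < stats::quantile(pat_driver, 0.3),
                            colnames(pat_act))
  frac <- leave_out_robustness(
    expression_matrix(org_act, value_scale = "zscore"), y,
    expression_matrix(pat_act, value_scale = "zscore"), status,
    k_max = 2, seed = 1
  )
  expect_named(frac, c("k0", "k1", "k2"))
  expect_true(frac[["k0"]] %in% c(0, 1))
  expect_gte(frac[["k2"]], 0.7)
  expect_error(
    leave_out_robustness(
      expression_matrix(org_act, value_scale = "zscore"), y,
      expression_matrix(pat_act, value_scale = "zscore"), status,
      k_max = 3, cap = 10, seed = 1
    ),
    "cap"
  )
})
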