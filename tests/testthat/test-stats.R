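test_that("Pearson point estimate matches the closed-form sum formula", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.0)
  y <- c(2.0, 3.9, 2.5, 4.8, 5.2)
  n <- 5
  r_closed <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  res <- pearson_with_bootstrap(x, y, n_boot = 200, seed = 1)
  expect_equal(res$r, r_closed, tolerance = 1e-12)
  expect_equal(res$p, cor.test(x, y)$p.value, tolerance = 1e-12)

  ident <- pearson_with_bootstrap(x, x + 0, n_boot = 50, seed = 1)
  expect_equal(ident$r, 1, tolerance = 1e-12)

  expect_error(pearson_with_bootstrap(c(1, 1, 1), y[1:3]), "zero variance")
  expect_error(pearson_with_bootstrap(x[1:2], y[1:2]), "at least 3")
})

test_that("sampling distribution at the design effect size matches r = sqrt(0.26)", {
  set.seed(11)
  sim <- simulate_cor_pvals(41, sqrt(0.26), 1000)
  expect_lt(abs(mean(abs(sim$r)) - sqrt(0.26)), 0.03)
})

test_that("bootstrap CIs are reproducible under a fixed seed and well ordered", {
  set.seed(3)
  for (i in 1:15) {
    n <- sample(8:40, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    a <- pearson_with_bootstrap(x, y, n_boot = 300, seed = 99)
    b <- pearson_with_bootstrap(x, y, n_boot = 300, seed = 99)
    expect_identical(a$ci_low, b$ci_low)
    expect_identical(a$ci_high, b$ci_high)
    expect_true(a$ci_low >= -1 && a$ci_high <= 1)
    expect_lte(a$ci_low, a$ci_high)
  }
})

test_that("significance demands both p < .05 and a CI excluding zero", {
  # hunt for seeds where the two criteria disagree; the flag must then be off
  found <- 0L
  for (s in 1:300) {
    set.seed(s)
    n <- 12
    x <- rnorm(n)
    y <- 0.55 * x + rnorm(n)
    res <- pearson_with_bootstrap(x, y, n_boot = 200, seed = s)
    p_ok <- res$p < 0.05
    ci_ok <- res$ci_low > 0 || res$ci_high < 0
    if (p_ok != ci_ok) {
      found <- found + 1L
      expect_false(res$significant)
    } else {
      expect_identical(res$significant, p_ok && ci_ok)
    }
    if (found >= 3L) break
  }
  expect_gte(found, 1L)
})

test_that("partial correlation: formula agrees with the residual method", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    z <- rnorm(n)
    x <- 0.4 * z + rnorm(n)
    y <- -0.3 * z + rnorm(n)
    res <- partial_pearson(x, y, z, n_boot = 50, seed = 1)
    r_resid <- cor(resid(lm(x ~ z)), resid(lm(y ~ z)))
    expect_equal(res$r, r_resid, tolerance = 1e-10)
  }
})

test_that("an inert covariate leaves the correlation essentially unchanged", {
  set.seed(13)
  n <- 5000
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n)
  z <- rnorm(n)  # independent of both
  plain <- pearson_with_bootstrap(x, y, n_boot = 50, seed = 1)
  adj <- partial_pearson(x, y, z, n_boot = 50, seed = 1)
  expect_lt(abs(adj$r - plain$r), 0.02)
})

test_that("degenerate covariates are handled with warnings", {
  set.seed(2)
  x <- rnorm(20)
  y <- rnorm(20)
  expect_warning(res <- partial_pearson(x, y, x, n_boot = 50, seed = 1),
                 "collinear")
  expect_true(is.na(res$r))
  expect_false(res$significant)
  expect_warning(res2 <- partial_pearson(x, y, rep(1, 20), n_boot = 50,
                                         seed = 1), "zero variance")
  expect_false(res2$partial)
  expect_equal(res2$r, cor(x, y), tolerance = 1e-12)
})

test_that("AUC equals the Mann-Whitney statistic and pROC agrees", {
  skip_if_not_installed("pROC")
  set.seed(19)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    pred <- round(rnorm(n), 2)  # ties likely
    lab <- runif(n) < 0.4
    if (!any(lab) || all(lab)) next
    rr <- roc_analysis(pred, lab)
    x1 <- pred[lab]; x0 <- pred[!lab]
    u <- mean(outer(x1, x0, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(rr$auc, u, tolerance = 1e-12)
    p_auc <- as.numeric(pROC::auc(pROC::roc(lab, pred, direction = "<",
                                            quiet = TRUE)))
    expect_equal(rr$auc, p_auc, tolerance = 1e-12)
    # monotone-transform invariance
    rr_log <- roc_analysis(exp(pred), lab)
    expect_equal(rr_log$auc, rr$auc, tolerance = 1e-12)
  }
})

test_that("a perfectly separating predictor gives AUC 1 and a 100%/100% cutoff", {
  pred <- c(1, 2, 3, 10, 11, 12)
  lab <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  rr <- roc_analysis(pred, lab)
  expect_identical(rr$auc, 1)
  expect_identical(rr$chosen_sensitivity, 1)
  expect_identical(rr$chosen_specificity, 1)
  expect_identical(rr$chosen_cutoff, 10)
  expect_error(roc_analysis(pred, rep(TRUE, 6)), "both outcome classes")
})

test_that("the chosen cutoff maximises sensitivity first, then specificity", {
  pred <- c(1, 2, 3, 4, 5, 6)
  lab <- c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  rr <- roc_analysis(pred, lab)
  expect_identical(rr$chosen_sensitivity, 1)  # all abnormal cases caught
  expect_identical(rr$chosen_cutoff, 2)       # largest threshold with sens 1
  expect_equal(rr$chosen_specificity, 1 / 3)
})

test_that("required sample size reproduces the design value and is monotone", {
  expect_identical(required_sample_size(0.26, 0.80, 0.05), 28L)
  ns <- vapply(c(0.5, 0.7, 0.8, 0.9, 0.95), function(p) {
    required_sample_size(0.26, p, 0.05)
  }, integer(1))
  expect_true(all(diff(ns) >= 0))
  expect_error(required_sample_size(1.2, 0.8, 0.05), "r2")
})

test_that("the Fisher-z sample size agrees with a simulation-based power check", {
  n_formula <- required_sample_size(0.5, 0.80, 0.05)
  set.seed(29)
  power_at <- function(n) mean(simulate_cor_pvals(n, sqrt(0.5), 10000)$p < 0.05)
  cand <- (n_formula - 2):(n_formula + 2)
  pw <- vapply(cand, power_at, numeric(1))
  n_sim <- cand[which(pw >= 0.8)[1]]
  expect_lte(abs(n_formula - n_sim), 1)
})

test_that("run_outcome_analysis composes the elementary operations", {
  sc <- sim_config(n_channels = 2, channel_labels = c("C3", "C4"))
  coh <- simulate_cohort(sc, cohort_config(n_infants = 41, seed = 5))
  res <- run_outcome_analysis(coh, channels = "C4", outcomes = "cognitive",
                              covariate = NULL, n_boot = 200, seed = 10)
  expect_identical(nrow(res$correlations), 1L)
  direct <- pearson_with_bootstrap(coh$power_C4, coh$cognitive,
                                   n_boot = 200, seed = 11)  # seed + row index
  expect_equal(res$correlations$r, direct$r, tolerance = 1e-12)
  expect_identical(res$correlations$ci_low, direct$ci_low)
  expect_identical(res$correlations$significant, direct$significant)
  if (nrow(res$roc) == 1L) {
    rr <- roc_analysis(coh$power_C4, coh$abnormal_cognitive)
    expect_equal(res$roc$auc, rr$auc, tolerance = 1e-12)
    expect_identical(res$roc$cutoff_uv2, rr$chosen_cutoff)
  }
})

test_that("a planted single-channel effect concentrates significance at that channel", {
  sc <- sim_config(n_channels = 3, channel_labels = c("C3", "C4", "O1"))
  hits_c4 <- 0L
  other_sig <- 0L
  other_n <- 0L
  reps <- 12
  for (s in 1:reps) {
    coh <- simulate_cohort(sc, cohort_config(n_infants = 60, effect_r2 = 0.26,
                                             effect_channels = "C4",
                                             seed = 400 + s))
    res <- run_outcome_analysis(coh, outcomes = "cognitive",
                                covariate = NULL, n_boot = 200, seed = s)
    tab <- res$correlations
    hits_c4 <- hits_c4 + tab$significant[tab$channel == "C4"]
    other_sig <- other_sig + sum(tab$significant[tab$channel != "C4"])
    other_n <- other_n + sum(tab$channel != "C4")
  }
  expect_gte(hits_c4, 10L)
  expect_lt(other_sig / other_n, 0.25)
})
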