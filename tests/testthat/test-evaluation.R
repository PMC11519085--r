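test_that("AUC equals brute-force concordance counting", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3)), 1.0)
  # reversing scores mirrors the AUC
  withr::with_seed(31, {
    s <- rnorm(30); y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) == 1) y[1] <- 1 - y[1]
  })
  expect_equal(roc_auc(-s, y), 1 - roc_auc(s, y))
  # random fixtures with ties vs the pairwise-counting oracle
  withr::with_seed(32, {
    for (rep in 1:20) {
      n <- sample(10:40, 1)
      y <- c(0, 1, rbinom(n - 2, 1, 0.5))
      s <- round(runif(n), 1)  # coarse grid forces ties
      expect_equal(roc_auc(s, y), bf_auc(s, y))
    }
  })
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("stratified bootstrap interval brackets the point AUC", {
  y <- rep(c(0, 1), each = 10)
  s_perfect <- c(runif(10, 0, 0.4), runif(10, 0.6, 1))
  ci <- bootstrap_auc_ci(s_perfect, y, B = 50L, seed = 1L)
  expect_equal(unname(ci), c(1, 1))

  withr::with_seed(33, {
    s <- rnorm(40); y2 <- rbinom(40, 1, 0.5); y2[1:2] <- c(0, 1)
  })
  a <- roc_auc(s, y2)
  ci2 <- bootstrap_auc_ci(s, y2, B = 200L, seed = 2L)
  expect_lte(ci2[["lo"]], a)
  expect_gte(ci2[["hi"]], a)

  # oracle equivalence at B = 50: replay the same stratified resampling
  pos <- which(y2 == 1); neg <- which(y2 == 0)
  ref <- withr::with_seed(4L, vapply(1:50, function(b) {
    idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    bf_auc(s[idx], y2[idx])
  }, 0))
  ref_ci <- quantile(ref, c(0.025, 0.975), names = FALSE)
  expect_equal(unname(bootstrap_auc_ci(s, y2, B = 50L, seed = 4L)), ref_ci)
})

test_that("confusion metrics follow their definitions", {
  perfect <- confusion_metrics(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$ppv, 1)
  expect_equal(perfect$npv, 1)

  # TP=3, FP=1, TN=4, FN=2 by construction
  scores <- c(rep(0.9, 3), rep(0.1, 2), rep(0.9, 1), rep(0.1, 4))
  labels <- c(rep(1, 5), rep(0, 5))
  m <- confusion_metrics(scores, labels)
  expect_equal(m$tp, 3L); expect_equal(m$fp, 1L)
  expect_equal(m$tn, 4L); expect_equal(m$fn, 2L)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$npv, 2 / 3)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$tp + m$fp + m$tn + m$fn, m$n)

  # no positive calls: PPV is missing, not zero
  none <- confusion_metrics(c(0.1, 0.2, 0.3, 0.4), c(0, 1, 0, 1))
  expect_true(is.na(none$ppv))
  expect_equal(none$npv, 0.5)
})

test_that("Hosmer-Lemeshow matches a hand-binned tabulation", {
  # probabilities equal to empirical group rates: chi2 = 0, p = 1
  probs <- rep(c(0.2, 0.5, 0.8), each = 10)
  labels <- c(rep(c(1, 0), c(2, 8)), rep(c(1, 0), c(5, 5)),
              rep(c(1, 0), c(8, 2)))
  r <- hosmer_lemeshow(probs, labels, n_groups = 3L)
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)

  # seeded miscalibrated fixture vs the brute-force oracle on the same bins
  withr::with_seed(35, {
    p2 <- runif(200)
    y2 <- rbinom(200, 1, pmin(pmax(p2^2, 0), 1))  # miscalibrated by squaring
  })
  r2 <- hosmer_lemeshow(p2, y2, n_groups = 10L)
  brks <- unique(quantile(p2, seq(0, 1, length.out = 11), type = 7))
  oracle <- bf_hosmer_lemeshow(p2, y2, brks)
  expect_equal(r2$chi2, oracle$chi2)
  expect_equal(r2$df, oracle$df)
  expect_gt(r2$chi2, qchisq(0.95, r2$df))  # the miscalibration is detected

  # heavy ties merge bins and reduce the degrees of freedom
  p3 <- c(rep(0.3, 40), rep(0.6, 40), runif(20))
  y3 <- rbinom(100, 1, p3)
  r3 <- hosmer_lemeshow(p3, y3, n_groups = 10L)
  expect_lt(r3$n_groups_used, 10L)
  expect_equal(r3$df, r3$n_groups_used - 2L)

  expect_error(hosmer_lemeshow(rep(c(0.2, 0.8), 10), rbinom(20, 1, 0.5)),
               "distinct")
})

test_that("decision curves equal brute-force TP/FP tabulation", {
  withr::with_seed(37, {
    probs <- runif(80)
    labels <- rbinom(80, 1, probs)
  })
  curve <- decision_curve(probs, labels)
  for (i in c(1L, 25L, 50L, 75L, 99L)) {
    expect_equal(curve$net_benefit_model[i],
                 bf_net_benefit(probs, labels, curve$threshold[i]))
  }
  expect_true(all(curve$net_benefit_none == 0))
  prev <- mean(labels)
  # treat-all tends to the prevalence as the threshold goes to 0
  low <- decision_curve(probs, labels, thresholds = 1e-6)
  expect_equal(low$net_benefit_all, prev, tolerance = 1e-4)
  # oracle probabilities: no FP/FN, model net benefit = prevalence throughout
  oracle_curve <- decision_curve(as.numeric(labels), labels)
  expect_true(all(abs(oracle_curve$net_benefit_model - prev) < 1e-12))
  # net benefit never exceeds the prevalence
  expect_true(all(curve$net_benefit_model <= prev + 1e-12))
})

test_that("label-independent scores cannot beat the default strategies", {
  # uninformative probabilities have zero expected net benefit at the
  # prevalence threshold; at large n the excess over the better of
  # treat-all/treat-none stays within sampling noise of zero
  withr::with_seed(38, {
    worst <- -Inf
    for (rep in 1:10) {
      n <- 20000
      probs <- runif(n)
      labels <- rbinom(n, 1, 0.4)
      prev <- mean(labels)
      curve <- decision_curve(probs, labels, thresholds = prev)
      excess <- curve$net_benefit_model - max(curve$net_benefit_all, 0)
      worst <- max(worst, excess)
    }
  })
  expect_lte(worst, 0.02)
})

test_that("cohort baseline comparisons use the right tests", {
  # 2x2 gender table: uncorrected Pearson chi-squared
  g <- baseline_comparison(c(54, 37), c(21, 18), "categorical")
  expect_equal(g$test, "chi_squared")
  expect_equal(round(g$p, 3), 0.561)

  lr <- baseline_comparison(c(45, 46), c(19, 20), "categorical")
  expect_equal(round(lr$p, 3), 0.939)

  # proportionally identical cohorts: p = 1
  same <- suppressWarnings(
    baseline_comparison(c(30, 70), c(3, 7), "categorical"))
  expect_equal(same$p, 1)

  # small expected counts warn but do not switch tests
  expect_warning(fh <- baseline_comparison(c(79, 12), c(35, 4), "categorical"),
                 "expected")
  expect_equal(fh$test, "chi_squared")
  f <- baseline_comparison(c(79, 12), c(35, 4), "categorical", exact = TRUE)
  expect_equal(f$test, "fisher")
  expect_equal(f$p, fisher.test(cbind(c(79, 12), c(35, 4)))$p.value)

  # Mann-Whitney is invariant under monotone transforms
  withr::with_seed(39, {
    a <- rnorm(40, 1.99, 0.57)
    b <- rnorm(25, 2.08, 0.53)
  })
  m1 <- baseline_comparison(a, b, "continuous")
  m2 <- baseline_comparison(exp(a), exp(b), "continuous")
  expect_equal(m1$test, "mann_whitney")
  expect_equal(m1$p, m2$p)
  expect_equal(m1$statistic, m2$statistic)

  expect_error(baseline_comparison(numeric(0), c(1, 2), "continuous"),
               "empty")

  tab <- baseline_table(list(
    gender = list(type = "categorical", a = c(54, 37), b = c(21, 18)),
    mwt = list(type = "continuous", a = a, b = b)))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$test, c("chi_squared", "mann_whitney"))
})
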