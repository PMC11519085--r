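test_that("Gaussian naive Bayes pair classifier matches the hand posterior", {
  pairs <- structure(list(
    vectors = matrix(c(-0.1, 0, 0.1, 1.9, 2, 2.1), ncol = 1,
                     dimnames = list(NULL, "v")),
    pair_labels = c(1L, 1L, 1L, 0L, 0L, 0L),
    template_ids = rep("t", 6), sample_ids = paste0("s", 1:6)),
    class = "pair_set")
  clf <- fit_pair_classifier(pairs, "gaussian_nb", seed = 1L)

  # hand posterior: equal priors, class means 0 and 2, equal variances 0.01
  hand_p <- function(x) {
    l1 <- dnorm(x, 0, 0.1); l0 <- dnorm(x, 2, 0.1)
    l1 / (l1 + l0)
  }
  for (x in c(-0.05, 0.4, 1.0, 1.95)) {
    expect_equal(predict_pair_prob(clf, matrix(x)), hand_p(x),
                 tolerance = 1e-9)
  }
  expect_gt(predict_pair_prob(clf, matrix(-0.05)), 0.5)
  expect_lt(predict_pair_prob(clf, matrix(1.95)), 0.5)
})

test_that("duplicate-feature pair vectors train via the variance floor", {
  x <- c(-0.1, 0, 0.1, 1.9, 2, 2.1)
  pairs <- structure(list(
    vectors = cbind(v1 = x, v2 = x),  # perfectly collinear dimensions
    pair_labels = c(1L, 1L, 1L, 0L, 0L, 0L),
    template_ids = rep("t", 6), sample_ids = paste0("s", 1:6)),
    class = "pair_set")
  expect_no_error(clf <- fit_pair_classifier(pairs, "gaussian_nb", 1L))
  p <- predict_pair_prob(clf, cbind(0, 0))
  expect_gt(p, 0.5)

  # constant dimension (zero within-class variance) also engages the floor
  pairs$vectors[, 2] <- 1
  expect_no_error(fit_pair_classifier(pairs, "gaussian_nb", 1L))

  expect_error(fit_pair_classifier(
    structure(list(vectors = matrix(x), pair_labels = rep(1L, 6),
                   template_ids = rep("t", 6), sample_ids = paste0("s", 1:6)),
              class = "pair_set"), "gaussian_nb", 1L),
    "both")
})

test_that("in-package naive Bayes agrees with the stock implementation", {
  withr::with_seed(13, {
    y <- rep(c(0L, 1L), each = 25)
    x <- matrix(rnorm(150), 50, 3)
    x[y == 1L, 1] <- x[y == 1L, 1] + 2
  })
  colnames(x) <- paste0("v", 1:3)
  clf <- fit_binary_classifier(x, y, "gaussian_nb", 1L)
  ref <- e1071::naiveBayes(x, factor(y))
  p_ref <- predict(ref, x, type = "raw")[, "1"]
  expect_equal(predict_prob(clf, x), unname(p_ref), tolerance = 1e-6)
})

test_that("every classifier family fits deterministically and emits probabilities", {
  tab <- make_separable_table(n = 40, d = 3, gap = 4, seed = 21L)
  for (fam in classifier_families()) {
    c1 <- fit_binary_classifier(tab$values, tab$labels, fam, seed = 5L)
    c2 <- fit_binary_classifier(tab$values, tab$labels, fam, seed = 5L)
    p1 <- predict_prob(c1, tab$values)
    p2 <- predict_prob(c2, tab$values)
    expect_identical(p1, p2, info = fam)
    expect_true(all(p1 >= 0 & p1 <= 1), info = fam)
    # the separable direction must be learnable by every family
    expect_gt(bf_auc(p1, tab$labels), 0.9)
  }
})

test_that("vote aggregation follows the template-label evidence rule", {
  v <- aggregate_votes(c(0.8, 0.6, 0.3), c(1, 1, 0))
  expect_equal(v$contributions, c(0.8, 0.6, 0.7))
  expect_equal(v$prob, 0.7)
  expect_equal(v$class, 1L)

  all_one <- suppressWarnings(aggregate_votes(c(1, 1), c(1, 1)))
  expect_equal(all_one$prob, 1)
  expect_equal(all_one$class, 1L)

  # tie at the threshold goes to class 1 under the >= rule
  tie <- aggregate_votes(c(0.5, 0.5), c(1, 0))
  expect_equal(tie$prob, 0.5)
  expect_equal(tie$class, 1L)

  expect_error(aggregate_votes(numeric(0), numeric(0)), "empty")
  expect_error(aggregate_votes(c(0.5, 1.2), c(1, 0)), "outside")
  expect_warning(aggregate_votes(c(0.3, 0.4), c(1, 1)), "single class")
})

test_that("flipping template labels mirrors the vote probability", {
  withr::with_seed(17, {
    for (rep in 1:20) {
      t_n <- sample(2:6, 1)
      labels <- c(0, 1, sample(0:1, t_n - 2, replace = TRUE))
      probs <- round(runif(t_n), 3)
      v <- aggregate_votes(probs, labels)
      v_flip <- aggregate_votes(probs, 1 - labels)
      expect_equal(v_flip$prob, 1 - v$prob)
      if (v$prob != 0.5) expect_equal(v_flip$class, 1L - v$class)
    }
  })
})

test_that("a duplicated template moves the vote by at most 1/T", {
  withr::with_seed(19, {
    for (rep in 1:20) {
      t_n <- sample(2:6, 1)
      labels <- c(0, 1, sample(0:1, t_n - 2, replace = TRUE))
      probs <- runif(t_n)
      j <- sample(t_n, 1)
      v0 <- aggregate_votes(probs, labels)
      v1 <- aggregate_votes(c(probs, probs[j]), c(labels, labels[j]))
      expect_lte(abs(v1$prob - v0$prob), 1 / t_n + 1e-12)
      expect_true(v1$prob >= 0 && v1$prob <= 1)
    }
  })
})

test_that("the fitted pipeline stores its configuration faithfully", {
  tab <- generate_cohort(cohort_spec(n = 60, d_radiomics = 30,
                                     effect_size = 1.2, seed = 31L))
  cfg <- pipeline_config(n_features = 12L, seed = 31L)
  model <- fit_pipeline(tab, config = cfg)
  expect_length(model$selected_features, 12L)
  expect_equal(length(model$templates$ids), 7L)
  p <- predict(model, tab)
  expect_gt(roc_auc(p$prob, tab$labels), 0.5)

  # refits with the same seed serialize byte-identically
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  save_model(model, f1)
  save_model(fit_pipeline(tab, config = cfg), f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(fit_pipeline(tab, config = pipeline_config(n_features = 500L)),
               "survive")
})

test_that("prediction is row-order invariant and handles single samples", {
  tab <- generate_cohort(cohort_spec(n = 50, d_radiomics = 20, seed = 7L))
  model <- fit_pipeline(tab, config = pipeline_config(n_features = 5L,
                                                      seed = 7L))
  p <- predict(model, tab)
  perm <- withr::with_seed(1, sample(50))
  tab2 <- ft_subset(tab, samples = perm)
  p2 <- predict(model, tab2)
  expect_equal(p2$prob[match(p$sample_id, p2$sample_id)], p$prob)

  one <- ft_subset(tab, samples = 1L)
  p1 <- predict(model, one)
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$prob, p$prob[1L])

  dropped <- ft_subset(tab, features = setdiff(tab$feature_names, "rad_001"))
  expect_error(predict(model, dropped), "rad_001")
})

test_that("stratified split reproduces the 91/39 cohort partition", {
  tab <- generate_cohort(cohort_spec(seed = 11L))  # 130 samples, 64 events
  sp <- split_cohort(tab, ratio = 0.7, seed = 11L)
  expect_equal(nrow(sp$train$values), 91L)
  expect_equal(nrow(sp$test$values), 39L)
  expect_equal(sum(sp$train$labels), 45L)
  expect_equal(sum(sp$test$labels), 19L)
  # partition: union is the cohort, intersection empty
  expect_setequal(c(sp$train$sample_ids, sp$test$sample_ids), tab$sample_ids)
  expect_length(intersect(sp$train$sample_ids, sp$test$sample_ids), 0L)
  # different seed: same sizes, different membership
  sp2 <- split_cohort(tab, ratio = 0.7, seed = 12L)
  expect_equal(nrow(sp2$train$values), 91L)
  expect_false(setequal(sp$train$sample_ids, sp2$train$sample_ids))
})

test_that("cross-validation refits everything inside each fold", {
  tab <- generate_cohort(cohort_spec(n = 91, d_radiomics = 30,
                                     prevalence = 45 / 91, seed = 23L))
  cfg <- pipeline_config(n_features = 6L, seed = 23L)
  cv <- crossvalidate(tab, config = cfg, return_details = TRUE)
  expect_equal(sort(cv$folds$n_validation, decreasing = TRUE),
               c(19L, 18L, 18L, 18L, 18L))
  expect_equal(cv$mean_validation_auc, mean(cv$folds$validation_auc))

  # leakage audit: per-fold normalizer statistics come from the training
  # folds only, and templates are training-fold members
  for (d in cv$details) {
    train_tab <- ft_subset(tab, samples = d$train_ids)
    expect_equal(d$normalizer$center,
                 colMeans(train_tab$values)[names(d$normalizer$center)])
    expect_true(all(d$template_ids %in% d$train_ids))
    expect_length(intersect(d$template_ids, d$validation_ids), 0L)
  }
})

test_that("grid optimization ranks configurations reproducibly", {
  tab <- generate_cohort(cohort_spec(n = 60, d_radiomics = 15,
                                     effect_size = 1.5, seed = 41L))
  g1 <- grid_optimize(tab, normalizations = "unit_zero_center",
                      reductions = "pcc", screeners = "anova",
                      n_features_grid = c(2L, 4L),
                      base_config = pipeline_config(seed = 41L))
  expect_equal(nrow(g1$results), 2L)
  expect_true(all(diff(g1$results$cv_validation_auc) <= 0))
  g2 <- grid_optimize(tab, normalizations = "unit_zero_center",
                      reductions = "pcc", screeners = "anova",
                      n_features_grid = c(2L, 4L),
                      base_config = pipeline_config(seed = 41L))
  expect_identical(g1$results, g2$results)

  single <- grid_optimize(tab, normalizations = "zero_center",
                          reductions = "pcc", screeners = "anova",
                          n_features_grid = 3L,
                          base_config = pipeline_config(seed = 41L))
  expect_equal(single$best_config$n_features, 3L)
  expect_s3_class(single$best_model, "trained_pairwise_model")
})

test_that("plain baselines share the interface and nail separable data", {
  tab <- make_separable_table(n = 40, d = 5, gap = 8, seed = 51L)
  cfg <- pipeline_config(normalization = "zero_center", reduction = "none",
                         n_features = 5L, seed = 51L)
  plain <- fit_plain_classifier(tab, config = cfg)
  p <- predict(plain, tab)
  expect_named(p, c("sample_id", "prob", "class"))
  expect_equal(roc_auc(p$prob, tab$labels), 1.0)

  # paired and plain models are benchmarkable side by side
  paired <- fit_pipeline(tab, config = cfg)
  pp <- predict(paired, tab)
  expect_true(roc_auc(pp$prob, tab$labels) > 0.9)
})
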