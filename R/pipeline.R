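#' Fit the full pairwise classification pipeline
#'
#' Executes, on the training table only: normalization, dimensionality
#' reduction (correlation filter or PCA), feature screening, selection of the
#' top-ranked features, template selection, pair construction, and pair
#' classifier fitting. Every data-dependent statistic (normalizer center and
#' scale, kept features, screening ranks, templates) is computed from the
#' training partition and frozen into the returned model; prediction applies
#' the frozen transforms and never refits anything.
#'
#' @param train_table a labeled `feature_table`.
#' @param labels binary outcome per sample (defaults to the table labels).
#' @param config a [pipeline_config()].
#' @param template_strategy forwarded to [select_templates()].
#' @param manual_template_ids forwarded to [select_templates()].
#' @return a `trained_pairwise_model`.
#' @export
fit_pipeline <- function(train_table, labels = train_table$labels,
                         config = pipeline_config(),
                         template_strategy = "medoid",
                         manual_template_ids = NULL) {
  check_two_classes(labels)
  norm <- fit_normalizer(train_table, config$normalization)
  tab <- apply_normalizer(norm, train_table)
  tab$labels <- labels

  reduction <- list(method = config$reduction)
  if (config$reduction == "pcc") {
    kept <- pcc_filter(tab, config$pcc_threshold)
    reduction$kept_features <- kept
    tab <- ft_subset(tab, features = kept)
  } else if (config$reduction == "pca") {
    k <- min(config$n_features, nrow(tab$values) - 1L, ncol(tab$values))
    pr <- pca_reduce(tab, k)
    reduction$center <- pr$center
    reduction$loadings <- pr$loadings
    tab <- pr$table
    tab$labels <- labels
  }

  screening <- screen_features(tab, labels, config$screener,
                               seed = config$seed)
  if (config$n_features > length(screening$features)) {
    stop(sprintf("n_features = %d but only %d features survive reduction",
                 config$n_features, length(screening$features)))
  }
  selected <- screening$features[seq_len(config$n_features)]
  tab_sel <- ft_subset(tab, features = selected)

  templates <- select_templates(tab_sel, labels, config$n_templates,
                                strategy = template_strategy,
                                manual_ids = manual_template_ids,
                                seed = config$seed)
  pairs <- build_pairs(templates, tab_sel, labels, exclude_self = TRUE,
                       abs_difference = config$abs_difference)
  classifier <- fit_pair_classifier(pairs, config$classifier, config$seed)

  structure(
    list(format_version = MODEL_FORMAT_VERSION,
         normalizer = norm,
         reduction = reduction,
         screening = data.frame(feature = screening$features,
                                score = screening$scores,
                                stringsAsFactors = FALSE),
         selected_features = selected,
         templates = templates,
         classifier = classifier,
         threshold = config$threshold,
         config = config),
    class = "trained_pairwise_model")
}

MODEL_FORMAT_VERSION <- "1.0"

#' @export
print.trained_pairwise_model <- function(x, ...) {
  cat(sprintf(
    "trained_pairwise_model: %s pair classifier, %d features, %d templates\n",
    x$classifier$family, length(x$selected_features),
    length(x$templates$ids)))
  cat("features:", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}

# Apply the frozen preprocessing of a trained model to an incoming table.
apply_frozen_preprocessing <- function(model, table) {
  tab <- apply_normalizer(model$normalizer, table)
  if (model$reduction$method == "pcc") {
    tab <- ft_subset(tab, features = model$reduction$kept_features)
  } else if (model$reduction$method == "pca") {
    tab <- pca_transform(model$reduction$center, model$reduction$loadings, tab)
  }
  ft_subset(tab, features = model$selected_features)
}

#' Predict outcome probabilities with a trained pairwise model
#'
#' Each incoming sample is paired with every stored template, the pair
#' classifier scores each pair, and the votes are aggregated into the
#' sample-level probability and class.
#'
#' @param object a `trained_pairwise_model`.
#' @param table a `feature_table` containing all model features.
#' @param ... unused.
#' @return data.frame with `sample_id`, `prob`, `class`, in the row order of
#'   `table`.
#' @export
predict.trained_pairwise_model <- function(object, table, ...) {
  tab <- apply_frozen_preprocessing(object, table)
  pairs <- build_pairs(object$templates, tab, labels = NULL,
                       exclude_self = FALSE,
                       abs_difference = isTRUE(object$config$abs_difference))
  probs <- predict_pair_prob(object$classifier, pairs$vectors)
  tlab <- stats::setNames(object$templates$labels, object$templates$ids)
  out <- aggregate_pair_set(pairs, probs, tlab, object$threshold)
  out[match(table$sample_ids, out$sample_id), , drop = FALSE] |>
    (\(d) {rownames(d) <- NULL; d})()
}

#' Stratified train/test split
#'
#' Splits the cohort by label stratum: within each class the training count
#' is the largest-remainder share of `round(n * ratio)`, and membership is a
#' seeded random draw. A 130-sample cohort with 64 events at ratio 0.7
#' yields 91 training (45 events) and 39 testing (19 events) samples.
#'
#' @param table a labeled `feature_table`.
#' @param labels binary outcome per sample.
#' @param ratio training fraction.
#' @param seed integer seed.
#' @return list with `train` and `test` feature tables.
#' @export
split_cohort <- function(table, labels = table$labels, ratio = 0.7,
                         seed = 1L) {
  check_two_classes(labels)
  n <- length(labels)
  n_train <- round(n * ratio)
  counts <- c(sum(labels == 1L), sum(labels == 0L))
  alloc <- apportion(counts, n_train, min_one = TRUE)
  train_idx <- withr::with_seed(seed, {
    c(sample(which(labels == 1L), alloc[1L]),
      sample(which(labels == 0L), alloc[2L]))
  })
  train_idx <- sort(train_idx)
  tr <- ft_subset(table, samples = train_idx)
  te <- ft_subset(table, samples = setdiff(seq_len(n), train_idx))
  tr$labels <- labels[train_idx]
  te$labels <- labels[setdiff(seq_len(n), train_idx)]
  list(train = tr, test = te)
}

#' Stratified fold assignment
#' @keywords internal
make_folds <- function(labels, k, seed) {
  n <- length(labels)
  fold <- integer(n)
  withr::with_seed(seed, {
    for (cls in sort(unique(labels))) {
      idx <- sample(which(labels == cls))
      sizes <- apportion(rep(1, k), length(idx))
      fold[idx] <- rep(seq_len(k), times = sizes)
    }
  })
  fold
}

#' Cross-validate the pairwise pipeline
#'
#' Stratified k-fold cross-validation in which the *entire* pipeline —
#' normalization, reduction, screening, template selection, pair classifier
#' — is refitted on the k-1 training folds of each split, so no held-out
#' sample ever contributes to a fitted statistic. Per-fold AUC and accuracy
#' are recorded on both the fold-training and the held-out data and averaged.
#'
#' @param train_table a labeled `feature_table`.
#' @param labels binary outcome per sample.
#' @param config a [pipeline_config()].
#' @param return_details also return per-fold fitted normalizer parameters
#'   and membership (used to audit the no-leakage contract).
#' @return list with `folds` (per-fold data.frame), `mean_validation_auc`,
#'   `mean_validation_accuracy`, `mean_train_auc`, `mean_train_accuracy`,
#'   and optionally `details`.
#' @export
crossvalidate <- function(train_table, labels = train_table$labels,
                          config = pipeline_config(),
                          return_details = FALSE) {
  k <- config$cv_folds
  fold <- make_folds(labels, k, config$seed)
  per_class <- table(labels, fold)
  if (any(per_class == 0L)) {
    stop("a fold lacks one outcome class; use fewer folds")
  }
  rows <- vector("list", k)
  details <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- ft_subset(train_table, samples = fold != f)
    te <- ft_subset(train_table, samples = fold == f)
    tr$labels <- labels[fold != f]
    te$labels <- labels[fold == f]
    model <- fit_pipeline(tr, tr$labels, config)
    p_tr <- predict(model, tr)
    p_te <- predict(model, te)
    rows[[f]] <- data.frame(
      fold = f,
      n_train = nrow(tr$values), n_validation = nrow(te$values),
      train_auc = roc_auc(p_tr$prob, tr$labels),
      train_accuracy = mean(p_tr$class == tr$labels),
      validation_auc = roc_auc(p_te$prob, te$labels),
      validation_accuracy = mean(p_te$class == te$labels))
    if (return_details) {
      details[[f]] <- list(train_ids = tr$sample_ids,
                           validation_ids = te$sample_ids,
                           normalizer = model$normalizer,
                           template_ids = model$templates$ids)
    }
  }
  folds <- do.call(rbind, rows)
  out <- list(folds = folds,
              mean_validation_auc = mean(folds$validation_auc),
              mean_validation_accuracy = mean(folds$validation_accuracy),
              mean_train_auc = mean(folds$train_auc),
              mean_train_accuracy = mean(folds$train_accuracy))
  if (return_details) out$details <- details
  out
}

#' Grid search over pipeline scheme combinations
#'
#' Evaluates every combination of normalization scheme, reduction method,
#' screener, feature count and classifier family by mean cross-validation
#' validation AUC; ties are broken by fewer features, then lexicographically
#' by the configuration string. Cells that fail (for example when too few
#' features survive reduction) are recorded as failed rather than aborting
#' the search. The best configuration is refitted on the full training table.
#'
#' @param train_table a labeled `feature_table`.
#' @param labels binary outcome per sample.
#' @param normalizations,reductions,screeners,classifiers character vectors
#'   of scheme values to cross.
#' @param n_features_grid integer vector of feature counts to try.
#' @param base_config a [pipeline_config()] supplying the remaining fields.
#' @param seed integer seed.
#' @return list with `results` (one row per grid cell, ranked), `best_config`
#'   and `best_model`.
#' @export
grid_optimize <- function(train_table, labels = train_table$labels,
                          normalizations = c("unit", "zero_center",
                                             "unit_zero_center"),
                          reductions = c("pcc", "pca"),
                          screeners = c("anova", "rfe", "relief"),
                          n_features_grid = 1:20,
                          classifiers = "gaussian_nb",
                          base_config = pipeline_config(),
                          seed = base_config$seed) {
  grid <- expand.grid(normalization = normalizations,
                      reduction = reductions,
                      screener = screeners,
                      n_features = n_features_grid,
                      classifier = classifiers,
                      stringsAsFactors = FALSE)
  if (nrow(grid) == 0L) stop("empty grid")
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- utils::modifyList(base_config, as.list(grid[i, ]))
    cfg <- do.call(pipeline_config, cfg[names(formals(pipeline_config))])
    cfg$seed <- as.integer(seed)
    cell <- grid[i, ]
    res <- tryCatch({
      cv <- crossvalidate(train_table, labels, cfg)
      model <- fit_pipeline(train_table, labels, cfg)
      p_full <- predict(model, train_table)
      data.frame(cell,
                 cv_train_auc = cv$mean_train_auc,
                 cv_train_accuracy = cv$mean_train_accuracy,
                 cv_validation_auc = cv$mean_validation_auc,
                 cv_validation_accuracy = cv$mean_validation_accuracy,
                 train_auc = roc_auc(p_full$prob, labels),
                 train_accuracy = mean(p_full$class == labels),
                 failed = FALSE, error = "",
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(cell, cv_train_auc = NA_real_, cv_train_accuracy = NA_real_,
                 cv_validation_auc = NA_real_,
                 cv_validation_accuracy = NA_real_,
                 train_auc = NA_real_, train_accuracy = NA_real_,
                 failed = TRUE, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- res
  }
  results <- do.call(rbind, rows)
  cfg_key <- do.call(paste, c(results[c("normalization", "reduction",
                                        "screener", "classifier")],
                              sep = "|"))
  ord <- order(results$failed, -results$cv_validation_auc,
               results$n_features, cfg_key)
  results <- results[ord, , drop = FALSE]
  rownames(results) <- NULL
  if (results$failed[1L]) stop("every grid cell failed")
  best <- results[1L, ]
  best_config <- utils::modifyList(
    base_config,
    list(normalization = best$normalization, reduction = best$reduction,
         screener = best$screener, n_features = best$n_features,
         classifier = best$classifier, seed = as.integer(seed)))
  best_config <- do.call(pipeline_config,
                         best_config[names(formals(pipeline_config))])
  best_model <- fit_pipeline(train_table, labels, best_config)
  list(results = results, best_config = best_config, best_model = best_model)
}

#' Fit a plain (non-pairwise) baseline classifier
#'
#' Applies the same preprocessing chain as [fit_pipeline()] but fits the
#' classifier directly on the processed sample vectors, enabling
#' paired-versus-plain benchmarking with an identical `predict` interface.
#'
#' @inheritParams fit_pipeline
#' @return a `trained_plain_model`.
#' @export
fit_plain_classifier <- function(train_table, labels = train_table$labels,
                                 config = pipeline_config()) {
  check_two_classes(labels)
  norm <- fit_normalizer(train_table, config$normalization)
  tab <- apply_normalizer(norm, train_table)
  tab$labels <- labels
  reduction <- list(method = config$reduction)
  if (config$reduction == "pcc") {
    kept <- pcc_filter(tab, config$pcc_threshold)
    reduction$kept_features <- kept
    tab <- ft_subset(tab, features = kept)
  } else if (config$reduction == "pca") {
    k <- min(config$n_features, nrow(tab$values) - 1L, ncol(tab$values))
    pr <- pca_reduce(tab, k)
    reduction$center <- pr$center
    reduction$loadings <- pr$loadings
    tab <- pr$table
    tab$labels <- labels
  }
  screening <- screen_features(tab, labels, config$screener,
                               seed = config$seed)
  if (config$n_features > length(screening$features)) {
    stop(sprintf("n_features = %d but only %d features survive reduction",
                 config$n_features, length(screening$features)))
  }
  selected <- screening$features[seq_len(config$n_features)]
  tab_sel <- ft_subset(tab, features = selected)
  clf <- fit_binary_classifier(tab_sel$values, labels, config$classifier,
                               config$seed)
  structure(
    list(format_version = MODEL_FORMAT_VERSION, normalizer = norm,
         reduction = reduction, selected_features = selected,
         classifier = clf, threshold = config$threshold, config = config),
    class = "trained_plain_model")
}

#' @export
predict.trained_plain_model <- function(object, table, ...) {
  tab <- apply_frozen_preprocessing(object, table)
  p <- predict_prob(object$classifier, tab$values)
  data.frame(sample_id = tab$sample_ids, prob = p,
             class = as.integer(p >= object$threshold),
             stringsAsFactors = FALSE)
}
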