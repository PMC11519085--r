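#' Supported binary classifier families
#'
#' `gaussian_nb` is the default pair classifier; the remaining families fill
#' out the comparison menu of standard classifiers. All of them emit a
#' calibrated-in-\[0,1\] probability for class 1.
#'
#' @return character vector of family names.
#' @export
classifier_families <- function() {
  c("gaussian_nb", "logistic", "lda", "svm_linear", "svm_rbf", "knn",
    "decision_tree", "random_forest", "adaboost", "gaussian_process")
}

#' Fit a binary classifier on a numeric matrix
#'
#' Shared engine behind the pair classifier and the plain (non-pairwise)
#' baselines. Standard families are delegated to their usual implementations
#' (`stats::glm`, `MASS::lda`, `e1071::svm`, `class::knn`, `rpart`,
#' `randomForest`, `kernlab::gausspr`); Gaussian naive Bayes and a stump
#' AdaBoost are implemented here (naive Bayes needs an explicit variance
#' floor for the near-duplicate feature columns that pair vectors produce,
#' and no AdaBoost implementation is otherwise available). Every fit is
#' deterministic under a fixed seed.
#'
#' @param x numeric matrix, rows = cases.
#' @param y binary 0/1 vector.
#' @param family one of [classifier_families()].
#' @param seed integer seed.
#' @return a `binary_classifier` object usable with [predict_prob()].
#' @export
fit_binary_classifier <- function(x, y, family = "gaussian_nb", seed = 1L) {
  family <- match.arg(family, classifier_families())
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes must be present in y")
  x <- as.matrix(x)
  fit <- withr::with_seed(seed, switch(
    family,
    gaussian_nb = fit_gaussian_nb(x, y),
    logistic = suppressWarnings(
      stats::glm.fit(cbind(1, x), y, family = stats::binomial())$coefficients),
    lda = MASS::lda(x, grouping = factor(y)),
    svm_linear = e1071::svm(x, factor(y), kernel = "linear",
                            probability = TRUE, scale = FALSE),
    svm_rbf = e1071::svm(x, factor(y), kernel = "radial",
                         probability = TRUE, scale = FALSE),
    knn = list(x = x, y = y, k = min(5L, nrow(x) - 1L)),
    decision_tree = rpart::rpart(
      y ~ ., data = data.frame(y = factor(y), x, check.names = FALSE),
      method = "class"),
    random_forest = randomForest::randomForest(x, factor(y), ntree = 200L),
    adaboost = fit_adaboost_stumps(x, y, n_rounds = 50L),
    gaussian_process = suppressMessages(
      kernlab::gausspr(x, factor(y), kernel = "rbfdot"))
  ))
  structure(list(family = family, fit = fit, seed = as.integer(seed),
                 features = colnames(x)),
            class = "binary_classifier")
}

# Gaussian naive Bayes with a variance floor (sklearn-style smoothing:
# 1e-9 times the largest per-feature variance, never below 1e-12).
fit_gaussian_nb <- function(x, y) {
  classes <- c(0L, 1L)
  prior <- vapply(classes, function(k) mean(y == k), 0)
  mu <- lapply(classes, function(k) colMeans(x[y == k, , drop = FALSE]))
  va <- lapply(classes, function(k)
    apply(x[y == k, , drop = FALSE], 2L, stats::var))
  floor_v <- max(1e-9 * max(unlist(va), 0, na.rm = TRUE), 1e-12)
  va <- lapply(va, function(v) {
    v[is.na(v) | v < floor_v] <- floor_v
    v
  })
  list(prior = prior, mean = mu, var = va)
}

predict_gaussian_nb <- function(fit, x) {
  loglik <- vapply(1:2, function(ci) {
    rowSums(stats::dnorm(x, rep(fit$mean[[ci]], each = nrow(x)),
                         rep(sqrt(fit$var[[ci]]), each = nrow(x)),
                         log = TRUE)) + log(fit$prior[ci])
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) loglik <- matrix(loglik, 1L)
  # stable softmax over the two classes
  m <- pmax(loglik[, 1L], loglik[, 2L])
  e0 <- exp(loglik[, 1L] - m); e1 <- exp(loglik[, 2L] - m)
  e1 / (e0 + e1)
}

# AdaBoost.M1 over depth-1 rpart stumps; probability through the usual
# logistic link on the ensemble margin.
fit_adaboost_stumps <- function(x, y, n_rounds = 50L) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  ysgn <- ifelse(y == 1L, 1, -1)
  df <- data.frame(y = factor(y), x, check.names = FALSE)
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    st <- rpart::rpart(y ~ ., data = df, weights = w, method = "class",
                       control = rpart::rpart.control(maxdepth = 1L,
                                                      cp = -1, minsplit = 2L,
                                                      xval = 0L))
    pred <- ifelse(predict(st, df, type = "class") == "1", 1, -1)
    err <- sum(w * (pred != ysgn))
    err <- min(max(err, 1e-10), 1 - 1e-10)
    if (err >= 0.5 && m > 1L) break
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- st
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * ysgn * pred)
    w <- w / sum(w)
  }
  list(stumps = stumps, alphas = alphas)
}

predict_adaboost_stumps <- function(fit, x) {
  df <- data.frame(x, check.names = FALSE)
  score <- rep(0, nrow(x))
  for (m in seq_along(fit$stumps)) {
    pred <- ifelse(predict(fit$stumps[[m]], df, type = "class") == "1", 1, -1)
    score <- score + fit$alphas[m] * pred
  }
  1 / (1 + exp(-2 * score))
}

#' Probability of class 1 from a fitted binary classifier
#'
#' @param object a `binary_classifier`.
#' @param x numeric matrix with the same columns the classifier was fitted on.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_prob <- function(object, x) {
  x <- as.matrix(x)
  if (!is.null(object$features)) colnames(x) <- object$features
  fit <- object$fit
  p <- withr::with_seed(object$seed, switch(
    object$family,
    gaussian_nb = predict_gaussian_nb(fit, x),
    logistic = {
      fit[is.na(fit)] <- 0  # collinear columns dropped by the fit
      eta <- drop(cbind(1, x) %*% fit)
      1 / (1 + exp(-eta))
    },
    lda = predict(fit, x)$posterior[, "1"],
    svm_linear = ,
    svm_rbf = {
      pr <- attr(predict(fit, x, probability = TRUE), "probabilities")
      pr[, "1"]
    },
    knn = {
      pred <- class::knn(fit$x, x, factor(fit$y), k = fit$k, prob = TRUE,
                         use.all = TRUE)
      frac <- attr(pred, "prob")
      ifelse(pred == "1", frac, 1 - frac)
    },
    decision_tree = predict(fit, data.frame(x, check.names = FALSE),
                            type = "prob")[, "1"],
    random_forest = predict(fit, x, type = "prob")[, "1"],
    adaboost = predict_adaboost_stumps(fit, x),
    gaussian_process = kernlab::predict(fit, x,
                                        type = "probabilities")[, "1"]
  ))
  p <- as.numeric(p)
  pmin(pmax(p, 0), 1)
}

#' Fit the pair classifier
#'
#' Fits one of the [classifier_families()] on pair difference vectors, with
#' the positive/negative pair label as the binary target. The fitted object
#' returns the positive-pair probability `P_PP` for new pair vectors (and
#' implicitly `P_NP = 1 - P_PP`).
#'
#' @param pairs a `pair_set` with known pair labels.
#' @param family classifier family; default `"gaussian_nb"`.
#' @param seed integer seed.
#' @return a `pair_classifier`.
#' @export
fit_pair_classifier <- function(pairs, family = "gaussian_nb", seed = 1L) {
  if (is.null(pairs$pair_labels)) stop("pair labels are required for fitting")
  if (length(unique(pairs$pair_labels)) < 2L) {
    stop("both positive and negative pairs are required")
  }
  clf <- fit_binary_classifier(pairs$vectors, pairs$pair_labels, family, seed)
  class(clf) <- c("pair_classifier", class(clf))
  clf
}

#' Positive-pair probabilities for new pair vectors
#' @param classifier a `pair_classifier`.
#' @param vectors matrix of pair difference vectors.
#' @return vector of `P_PP` values in `[0, 1]`.
#' @export
predict_pair_prob <- function(classifier, vectors) {
  predict_prob(classifier, vectors)
}
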