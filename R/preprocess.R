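#' Fit a feature normalizer on training data
#'
#' Three schemes are supported, all fitted per feature on the training
#' partition only and frozen into the model:
#' \describe{
#'   \item{`zero_center`}{`x' = x - mean(x)`}
#'   \item{`unit`}{`x' = x / ||x||`, the per-feature Euclidean norm over the
#'     training samples}
#'   \item{`unit_zero_center`}{`x' = (x - mean(x)) / ||x - mean(x)||`}
#' }
#' A feature whose scale would be zero (constant feature under a centered
#' scheme, all-zero feature under `unit`) gets scale 1 so it maps to all
#' zeros; such features are flagged in the returned object.
#'
#' @param table a `feature_table` with >= 2 samples.
#' @param scheme `"unit"`, `"zero_center"`, or `"unit_zero_center"`.
#' @return a `normalizer_params` object with per-feature `center` and `scale`.
#' @export
fit_normalizer <- function(table, scheme = c("unit_zero_center", "unit",
                                             "zero_center")) {
  scheme <- match.arg(scheme)
  x <- table$values
  if (nrow(x) < 2L) stop("need at least 2 samples to fit a normalizer")
  center <- if (scheme == "unit") rep(0, ncol(x)) else colMeans(x)
  xc <- sweep(x, 2L, center)
  scale <- if (scheme == "zero_center") rep(1, ncol(x)) else
    sqrt(colSums(xc^2))
  degenerate <- scale <= 0
  scale[degenerate] <- 1
  names(center) <- names(scale) <- table$feature_names
  structure(
    list(scheme = scheme, center = center, scale = scale,
         constant_features = table$feature_names[degenerate]),
    class = "normalizer_params")
}

#' Apply fitted normalization parameters to a table
#'
#' @param params a `normalizer_params` from [fit_normalizer()].
#' @param table a `feature_table` containing every feature the normalizer was
#'   fitted on (extra features are an error).
#' @return the transformed `feature_table`.
#' @export
apply_normalizer <- function(params, table) {
  missing <- setdiff(names(params$center), table$feature_names)
  if (length(missing)) stop("missing feature(s): ", paste(missing, collapse = ", "))
  tab <- ft_subset(table, features = names(params$center))
  vals <- sweep(sweep(tab$values, 2L, params$center), 2L, params$scale, "/")
  feature_table(vals, tab$sample_ids, tab$feature_names, tab$feature_kind,
                tab$labels)
}

#' Drop redundant features by pairwise Pearson correlation
#'
#' Greedy first-kept-wins scan: features are visited in table order (or in
#' decreasing `score_hint` order when scores are given); a feature is dropped
#' when its absolute Pearson correlation with any already-kept feature
#' exceeds `threshold`. The result is independent of sample order and
#' idempotent. Mirrors the common radiomics practice of collapsing highly
#' collinear feature families before screening.
#'
#' @param table a `feature_table` with >= 3 samples.
#' @param threshold absolute correlation cutoff in `(0, 1]`.
#' @param score_hint optional named numeric vector; higher-scored features are
#'   visited (and therefore kept) first.
#' @return character vector of kept feature names, in table order.
#' @export
pcc_filter <- function(table, threshold = 0.99, score_hint = NULL) {
  if (nrow(table$values) < 3L) stop("need at least 3 samples for correlation filtering")
  stopifnot(threshold > 0, threshold <= 1)
  feats <- table$feature_names
  ord <- seq_along(feats)
  if (!is.null(score_hint)) {
    s <- score_hint[feats]
    if (any(is.na(s))) stop("score_hint must cover every feature")
    ord <- order(-s, feats)
  }
  cm <- suppressWarnings(stats::cor(table$values))
  cm[is.na(cm)] <- 0  # constant features correlate with nothing
  kept_idx <- integer(0)
  for (j in ord) {
    if (length(kept_idx) == 0L ||
        all(abs(cm[j, kept_idx]) <= threshold)) {
      kept_idx <- c(kept_idx, j)
    }
  }
  feats[sort(kept_idx)]
}

#' Principal component reduction
#'
#' Thin wrapper over [stats::prcomp()] with a fixed sign convention (the
#' largest-magnitude loading of each component is positive) so transforms are
#' reproducible. Components are ordered by explained variance. If the data
#' rank cannot support `n_components`, the count is truncated with a warning.
#'
#' @param table a `feature_table`.
#' @param n_components number of components to keep.
#' @return list with `table` (transformed `feature_table` whose features are
#'   `PC1..PCk`), `loadings` (d x k matrix), `center` (training means), and
#'   `explained_variance_ratio`.
#' @export
pca_reduce <- function(table, n_components) {
  x <- table$values
  max_k <- min(nrow(x) - 1L, ncol(x))
  if (n_components > max_k) stop("n_components exceeds min(n - 1, d)")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-12)
  k <- n_components
  if (k > rank) {
    warning(sprintf("rank %d < requested %d components; truncating", rank, k))
    k <- rank
  }
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- apply(load, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  load <- sweep(load, 2L, flip, "*")
  scores <- sweep(x, 2L, pc$center) %*% load
  colnames(scores) <- paste0("PC", seq_len(k))
  out <- feature_table(scores, table$sample_ids, colnames(scores),
                       "radiomics", table$labels)
  list(table = out, loadings = load, center = pc$center,
       explained_variance_ratio = evr[seq_len(k)])
}

#' @keywords internal
pca_transform <- function(center, loadings, table) {
  missing <- setdiff(rownames(loadings), table$feature_names)
  if (length(missing)) stop("missing feature(s): ", paste(missing, collapse = ", "))
  tab <- ft_subset(table, features = rownames(loadings))
  scores <- sweep(tab$values, 2L, center) %*% loadings
  colnames(scores) <- colnames(loadings)
  feature_table(scores, tab$sample_ids, colnames(scores), "radiomics",
                tab$labels)
}

new_screening_result <- function(features, scores, method) {
  ord <- order(-scores, features)  # descending score, lexicographic ties
  structure(
    list(features = features[ord], scores = scores[ord], method = method),
    class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("screening_result (%s): %d features\n", x$method,
              length(x$features)))
  utils::head(data.frame(feature = x$features, score = x$scores), 10L)
}

#' Export a screening result as a two-column CSV
#' @param result a `screening_result`.
#' @param path output path.
#' @export
write_screening_result <- function(result, path) {
  utils::write.csv(data.frame(feature = result$features, score = result$scores),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

check_two_classes <- function(labels) {
  if (is.null(labels)) stop("labels are required")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
}

#' Rank features by one-way ANOVA F score
#'
#' Per-feature univariate screening: for each feature the one-way F statistic
#' between the two outcome groups, `F = (between-group SS / 1) /
#' (within-group SS / (n - 2))`, equal to the squared pooled-variance
#' two-sample t statistic. Ties are broken lexicographically by feature name.
#'
#' @param table a `feature_table`.
#' @param labels binary outcome per sample (defaults to `table$labels`).
#' @return a `screening_result` ordered by decreasing F.
#' @export
anova_rank <- function(table, labels = table$labels) {
  check_two_classes(labels)
  x <- table$values
  n <- nrow(x)
  if (min(table(labels)) < 2L) stop("each class needs >= 2 samples")
  g1 <- labels == 1
  n1 <- sum(g1); n0 <- n - n1
  m1 <- colMeans(x[g1, , drop = FALSE])
  m0 <- colMeans(x[!g1, , drop = FALSE])
  m <- colMeans(x)
  ss_between <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  ss_within <- colSums(sweep(x[g1, , drop = FALSE], 2L, m1)^2) +
    colSums(sweep(x[!g1, , drop = FALSE], 2L, m0)^2)
  f <- ifelse(ss_within > 0, ss_between / 1 / (ss_within / (n - 2L)),
              ifelse(ss_between > 0, Inf, 0))
  new_screening_result(table$feature_names, as.numeric(f), "anova")
}

#' Rank features by the classic binary Relief weight
#'
#' Kira-Rendell Relief for two classes: for each of `n_iterations` instances
#' sampled without replacement in seeded random order, find the nearest
#' same-class hit and the nearest other-class miss by Euclidean distance over
#' all features, and update each feature weight by
#' `W(f) <- W(f) - diff(f, x, hit)/m + diff(f, x, miss)/m`, with `diff`
#' normalized by the feature's observed range. Features should be on
#' comparable scales beforehand. An instance whose class has no other member
#' has no hit and is skipped with a warning.
#'
#' @param table a `feature_table`.
#' @param labels binary outcome per sample.
#' @param n_iterations number of instances visited; default every sample once.
#' @param seed integer seed for the visiting order.
#' @return a `screening_result` of Relief weights.
#' @export
relief_rank <- function(table, labels = table$labels, n_iterations = NULL,
                        seed = 1L) {
  check_two_classes(labels)
  x <- table$values
  n <- nrow(x)
  if (is.null(n_iterations)) n_iterations <- n
  rng <- apply(x, 2L, function(v) diff(range(v)))
  rng[rng <= 0] <- 1  # constant feature: diff is 0 anyway
  w <- numeric(ncol(x))
  singleton <- names(which(table(labels) < 2L))
  if (length(singleton)) {
    warning("class with a single member: its instance has no hit and is skipped")
  }
  order_idx <- withr::with_seed(seed, {
    rep_len(sample.int(n), n_iterations)
  })
  m_eff <- 0L
  contrib <- matrix(0, 0, ncol(x))
  for (i in order_idx) {
    same <- which(labels == labels[i]); same <- setdiff(same, i)
    if (length(same) == 0L) next
    other <- which(labels != labels[i])
    d2_same <- colSums((t(x[same, , drop = FALSE]) - x[i, ])^2)
    d2_other <- colSums((t(x[other, , drop = FALSE]) - x[i, ])^2)
    hit <- same[which.min(d2_same)]
    miss <- other[which.min(d2_other)]
    w <- w - abs(x[i, ] - x[hit, ]) / rng + abs(x[i, ] - x[miss, ]) / rng
    m_eff <- m_eff + 1L
  }
  if (m_eff > 0L) w <- w / m_eff
  new_screening_result(table$feature_names, as.numeric(w), "relief")
}

#' Rank features by recursive feature elimination
#'
#' Repeatedly fits an L2-regularized (ridge) logistic classifier and
#' eliminates the feature with the smallest absolute coefficient, one per
#' step; the later a feature is eliminated, the higher its rank. A ridge
#' model is used because the naive Bayes pair classifier exposes no
#' coefficient magnitudes to drive elimination.
#'
#' @param table a `feature_table`.
#' @param labels binary outcome per sample.
#' @param lambda ridge penalty passed to [glmnet::glmnet()].
#' @return a `screening_result`; the score is the elimination rank (d for the
#'   last survivor down to 1 for the first feature removed).
#' @export
rfe_rank <- function(table, labels = table$labels, lambda = 1e-2) {
  check_two_classes(labels)
  d <- ncol(table$values)
  remaining <- table$feature_names
  elim_order <- character(0)
  while (length(remaining) > 1L) {
    xm <- table$values[, remaining, drop = FALSE]
    coefs <- tryCatch({
      fit <- glmnet::glmnet(xm, factor(labels), family = "binomial",
                            alpha = 0, lambda = lambda,
                            standardize = FALSE)
      as.numeric(fit$beta)
    }, error = function(e) {
      warning("ridge fit failed (", conditionMessage(e),
              "); falling back to per-feature association")
      abs(stats::cor(xm, labels))
    })
    drop_i <- order(abs(coefs), remaining)[1L]  # smallest |coef|, name tie-break
    elim_order <- c(elim_order, remaining[drop_i])
    remaining <- remaining[-drop_i]
  }
  elim_order <- c(elim_order, remaining)
  rank <- match(table$feature_names, elim_order)  # 1 = first eliminated
  new_screening_result(table$feature_names, as.numeric(rank), "rfe")
}

#' Dispatch to a feature screener by name
#' @param method `"anova"`, `"relief"` or `"rfe"`.
#' @inheritParams anova_rank
#' @param seed seed forwarded to the Relief screener.
#' @return a `screening_result`.
#' @export
screen_features <- function(table, labels = table$labels,
                            method = c("anova", "relief", "rfe"), seed = 1L) {
  method <- match.arg(method)
  switch(method,
         anova = anova_rank(table, labels),
         relief = relief_rank(table, labels, seed = seed),
         rfe = rfe_rank(table, labels))
}
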