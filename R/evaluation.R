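#' Area under the ROC curve
#'
#' Computed with \pkg{pROC}; equals the Mann-Whitney probability that a
#' random event sample scores above a random non-event sample, with 0.5
#' credit for ties.
#'
#' @param scores numeric risk scores (higher = more event-like).
#' @param labels binary outcome per sample.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  check_two_classes(labels)
  as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                 levels = c(0, 1), direction = "<")))
}

#' Stratified percentile bootstrap interval for the AUC
#'
#' Resamples events and non-events separately (so every replicate keeps both
#' classes), recomputes the AUC, and reports the percentile interval.
#'
#' @param scores numeric risk scores.
#' @param labels binary outcome per sample.
#' @param B number of bootstrap replicates.
#' @param level confidence level.
#' @param seed integer seed.
#' @return named vector `c(lo, hi)`.
#' @export
bootstrap_auc_ci <- function(scores, labels, B = 1000L, level = 0.95,
                             seed = 1L) {
  check_two_classes(labels)
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  aucs <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
      roc_auc(scores[idx], labels[idx])
    }, 0)
  })
  alpha <- (1 - level) / 2
  q <- stats::quantile(aucs, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(lo = q[1L], hi = q[2L])
}

#' Threshold-based diagnostic performance
#'
#' Confusion counts and the derived rates at a fixed probability threshold
#' (positive call when `score >= threshold`). PPV/NPV are reported as `NA`
#' (not 0) when no positive/negative calls are made.
#'
#' @param scores predicted probabilities.
#' @param labels binary outcome per sample.
#' @param threshold decision threshold.
#' @return an `evaluation_report` list: `auc`, `accuracy`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `threshold`, `n`, and counts
#'   `tp`/`fp`/`tn`/`fn`.
#' @export
confusion_metrics <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  n <- length(labels)
  structure(
    list(auc = if (length(unique(labels)) == 2L) roc_auc(scores, labels)
         else NA_real_,
         accuracy = (tp + tn) / n,
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
         threshold = threshold, n = n, tp = tp, fp = fp, tn = tn, fn = fn),
    class = "evaluation_report")
}

#' Full evaluation report with bootstrap AUC interval
#'
#' @inheritParams confusion_metrics
#' @inheritParams bootstrap_auc_ci
#' @return an `evaluation_report` including `auc_ci`.
#' @export
evaluate_predictions <- function(scores, labels, threshold = 0.5, B = 1000L,
                                 level = 0.95, seed = 1L) {
  rep <- confusion_metrics(scores, labels, threshold)
  rep$auc_ci <- bootstrap_auc_ci(scores, labels, B, level, seed)
  rep
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("n = %d, threshold = %.3g\n", x$n, x$threshold))
  if (!is.null(x$auc_ci)) {
    cat(sprintf("AUC %.3f (%.3f-%.3f)\n", x$auc, x$auc_ci[1L], x$auc_ci[2L]))
  } else cat(sprintf("AUC %.3f\n", x$auc))
  cat(sprintf("accuracy %.3f  sensitivity %.3f  specificity %.3f\n",
              x$accuracy, x$sensitivity, x$specificity))
  cat(sprintf("PPV %s  NPV %s\n",
              ifelse(is.na(x$ppv), "NA", sprintf("%.3f", x$ppv)),
              ifelse(is.na(x$npv), "NA", sprintf("%.3f", x$npv))))
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups samples into bins by quantiles of predicted risk (bins whose
#' boundaries fall on tied probabilities are merged), then compares observed
#' and expected event counts with
#' `chi2 = sum_g (O_g - E_g)^2 / (E_g (1 - E_g / n_g))` on `g - 2` degrees
#' of freedom.
#'
#' @param probs predicted event probabilities.
#' @param labels binary outcome per sample.
#' @param n_groups requested number of risk groups (default deciles).
#' @return list with `chi2`, `df`, `p`, `n_groups_used`, and the per-group
#'   `table` (n, observed, expected).
#' @export
hosmer_lemeshow <- function(probs, labels, n_groups = 10L) {
  if (length(unique(probs)) < 3L) {
    stop("fewer than 3 distinct probabilities; cannot form risk groups")
  }
  if (length(probs) < 2L * n_groups) {
    warning("fewer than 2 samples per requested group on average")
  }
  qs <- stats::quantile(probs, probs = seq(0, 1, length.out = n_groups + 1L),
                        type = 7)
  brks <- unique(qs)  # tied quantiles merge adjacent bins
  grp <- cut(probs, breaks = brks, include.lowest = TRUE)
  tab <- data.frame(
    n = as.vector(table(grp)),
    observed = as.vector(tapply(labels, grp, sum)),
    expected = as.vector(tapply(probs, grp, sum)))
  tab <- tab[tab$n > 0, , drop = FALSE]
  g <- nrow(tab)
  if (g < 3L) stop("fewer than 3 usable risk groups after merging ties")
  denom <- tab$expected * (1 - tab$expected / tab$n)
  term <- (tab$observed - tab$expected)^2 / denom
  term[denom <= 0] <- 0  # bin with all-0 or all-1 predictions matching exactly
  chi2 <- sum(term)
  df <- g - 2L
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE),
       n_groups_used = g, table = tab)
}

#' Decision curve analysis
#'
#' Net benefit of acting on the model at each threshold probability `p_t`:
#' `NB(p_t) = TP/n - (FP/n) * p_t / (1 - p_t)` with a positive call when
#' `prob >= p_t`; compared against treating everyone
#' (`prevalence - (1 - prevalence) * p_t / (1 - p_t)`) and treating no one
#' (identically zero).
#'
#' @param probs predicted event probabilities.
#' @param labels binary outcome per sample.
#' @param thresholds threshold-probability grid.
#' @return a `dca_curve` data.frame with columns `threshold`,
#'   `net_benefit_model`, `net_benefit_all`, `net_benefit_none`.
#' @export
decision_curve <- function(probs, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  stopifnot(all(thresholds > 0), all(thresholds < 1))
  n <- length(labels)
  prev <- mean(labels)
  rows <- vapply(thresholds, function(pt) {
    pos <- probs >= pt
    tp <- sum(pos & labels == 1L)
    fp <- sum(pos & labels == 0L)
    w <- pt / (1 - pt)
    c(tp / n - fp / n * w, prev - (1 - prev) * w)
  }, numeric(2))
  out <- data.frame(threshold = thresholds,
                    net_benefit_model = rows[1L, ],
                    net_benefit_all = rows[2L, ],
                    net_benefit_none = 0)
  class(out) <- c("dca_curve", class(out))
  out
}

#' Plot a decision curve
#' @param x a `dca_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dca_curve <- function(x, ...) {
  ylim <- range(c(0, x$net_benefit_model, pmax(x$net_benefit_all, -0.05)))
  graphics::plot(x$threshold, x$net_benefit_model, type = "l", lwd = 2,
                 xlab = "Threshold probability", ylab = "Net benefit",
                 ylim = ylim, ...)
  graphics::lines(x$threshold, x$net_benefit_all, lty = 2, col = "grey40")
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", c("model", "treat all", "treat none"),
                   lty = c(1, 2, 3), lwd = c(2, 1, 1),
                   col = c("black", "grey40", "black"), bty = "n")
  invisible(x)
}

#' Compare a baseline characteristic between two cohorts
#'
#' Categorical variables are compared with the Pearson chi-squared test
#' without continuity correction by default (Fisher's exact test by flag;
#' a warning is raised when any expected cell count is below 5, but the test
#' is not switched automatically). Continuous variables are compared with
#' the two-sided Mann-Whitney U test (normal approximation with tie
#' correction).
#'
#' @param cohort_a,cohort_b for `type = "categorical"`, vectors of category
#'   counts (same category order); for `type = "continuous"`, raw
#'   measurement vectors.
#' @param type `"categorical"` or `"continuous"`.
#' @param exact use Fisher's exact test for categorical variables.
#' @return list with `statistic`, `p`, `test`.
#' @export
baseline_comparison <- function(cohort_a, cohort_b,
                                type = c("categorical", "continuous"),
                                exact = FALSE) {
  type <- match.arg(type)
  if (length(cohort_a) == 0L || length(cohort_b) == 0L) stop("empty cohort")
  if (type == "categorical") {
    m <- cbind(cohort_a, cohort_b)
    if (exact) {
      ft <- stats::fisher.test(m)
      list(statistic = NA_real_, p = ft$p.value, test = "fisher")
    } else {
      expected <- outer(rowSums(m), colSums(m)) / sum(m)
      if (any(expected < 5)) {
        warning("expected cell count < 5; consider exact = TRUE")
      }
      ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
      list(statistic = unname(ct$statistic), p = ct$p.value,
           test = "chi_squared")
    }
  } else {
    wt <- stats::wilcox.test(cohort_a, cohort_b, exact = FALSE,
                             correct = FALSE)
    list(statistic = unname(wt$statistic), p = wt$p.value,
         test = "mann_whitney")
  }
}

#' Baseline comparison table for several characteristics
#'
#' Builds a cohort-characteristics comparison in the usual "Table 1" layout:
#' one row per variable with the test used and its p-value.
#'
#' @param variables named list; each element is a list with `type`
#'   (`"categorical"`/`"continuous"`), `a` and `b` (counts or values per
#'   cohort), and optionally `exact = TRUE`.
#' @return data.frame with columns `variable`, `test`, `statistic`, `p`.
#' @export
baseline_table <- function(variables) {
  rows <- lapply(names(variables), function(nm) {
    v <- variables[[nm]]
    res <- baseline_comparison(v$a, v$b, type = v$type,
                               exact = isTRUE(v$exact))
    data.frame(variable = nm, test = res$test,
               statistic = res$statistic, p = res$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
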