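# Small labeled tables and independent brute-force oracles used across the
# module tests and the acceptance suite. Oracles are deliberately written as
# plain loops, independent of the package's vectorized code paths.

make_table <- function(values, labels = NULL, kind = "radiomics") {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  }
  feature_table(values, paste0("s", seq_len(nrow(values))),
                colnames(values), kind, labels)
}

# A linearly separable two-class table: feature f1 carries the classes far
# apart, the rest is seeded noise.
make_separable_table <- function(n = 20L, d = 3L, gap = 10, seed = 1L) {
  withr::with_seed(seed, {
    labels <- rep(c(0L, 1L), length.out = n)
    x <- matrix(rnorm(n * d), n, d)
    x[, 1L] <- x[, 1L] + gap * labels
    make_table(x, labels)
  })
}

# Brute-force voting rule: per-template evidence s_I is the positive-pair
# probability if the template is an event, its complement otherwise; the
# aggregate is the arithmetic mean, class 1 at or above the threshold.
bf_vote <- function(pair_probs, template_labels, threshold = 0.5) {
  s <- numeric(length(pair_probs))
  for (i in seq_along(pair_probs)) {
    if (template_labels[i] == 1) s[i] <- pair_probs[i]
    else s[i] <- 1 - pair_probs[i]
  }
  total <- 0
  for (v in s) total <- total + v
  p <- total / length(s)
  list(prob = p, class = if (p >= threshold) 1L else 0L)
}

# Brute-force AUC: concordant-pair counting with half credit for ties.
bf_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    if (p > q) total <- total + 1
    else if (p == q) total <- total + 0.5
  }
  total / (length(pos) * length(neg))
}

# Brute-force net-benefit tabulation for one threshold.
bf_net_benefit <- function(probs, labels, pt) {
  tp <- 0; fp <- 0
  for (i in seq_along(probs)) {
    if (probs[i] >= pt) {
      if (labels[i] == 1) tp <- tp + 1 else fp <- fp + 1
    }
  }
  n <- length(probs)
  tp / n - fp / n * pt / (1 - pt)
}

# Brute-force Hosmer-Lemeshow tabulation over explicit bins.
bf_hosmer_lemeshow <- function(probs, labels, breaks) {
  grp <- cut(probs, breaks = breaks, include.lowest = TRUE)
  chi2 <- 0; g <- 0
  for (lev in levels(grp)) {
    sel <- grp == lev
    ng <- sum(sel)
    if (ng == 0) next
    o <- sum(labels[sel])
    e <- sum(probs[sel])
    chi2 <- chi2 + (o - e)^2 / (e * (1 - e / ng))
    g <- g + 1
  }
  list(chi2 = chi2, df = g - 2)
}

# ICC(2,1) from an explicit two-way ANOVA fitted with aov().
bf_icc21 <- function(r1, r2) {
  n <- length(r1); k <- 2
  long <- data.frame(y = c(r1, r2),
                     subject = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = long))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
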