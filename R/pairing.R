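#' Largest-remainder apportionment
#'
#' Distributes `total` integer units over groups proportionally to `weights`:
#' each group gets the floor of its exact share, then the leftover units go
#' to the groups with the largest fractional remainders (ties broken by group
#' order). With `min_one = TRUE` every group with positive weight gets at
#' least one unit.
#'
#' @param weights non-negative numeric weights (e.g. class counts).
#' @param total number of units to distribute.
#' @param min_one guarantee at least one unit per positively weighted group.
#' @return integer vector of allocations summing to `total`.
#' @export
apportion <- function(weights, total, min_one = FALSE) {
  stopifnot(total >= 0, all(weights >= 0), sum(weights) > 0)
  exact <- weights / sum(weights) * total
  alloc <- floor(exact)
  rem <- exact - alloc
  leftover <- total - sum(alloc)
  if (leftover > 0) {
    give <- order(-rem, seq_along(rem))[seq_len(leftover)]
    alloc[give] <- alloc[give] + 1L
  }
  if (min_one) {
    while (any(alloc == 0L & weights > 0)) {
      lend <- which.max(alloc)
      need <- which(alloc == 0L & weights > 0)[1L]
      alloc[lend] <- alloc[lend] - 1L
      alloc[need] <- 1L
    }
  }
  as.integer(alloc)
}

#' Select representative template cases
#'
#' Templates are the labeled reference cases every sample is paired against.
#' Per-class counts are proportional to class frequencies (largest-remainder
#' rounding, at least one per class). Strategies:
#' \describe{
#'   \item{`medoid`}{within each class, the samples minimizing the summed
#'     Euclidean distance to all same-class samples (deterministic; ties
#'     broken by sample id).}
#'   \item{`random`}{a seeded random draw per class.}
#'   \item{`manual`}{exactly the ids in `manual_ids` (mirrors expert choice
#'     of representative cases).}
#' }
#'
#' @param table a `feature_table` in the processed feature space.
#' @param labels binary outcome per sample.
#' @param n_templates total number of templates (>= 2).
#' @param strategy `"medoid"`, `"random"`, or `"manual"`.
#' @param manual_ids sample ids used when `strategy = "manual"`.
#' @param seed seed for the random strategy.
#' @return a `template_set`: ids, feature matrix, labels, strategy tag.
#' @export
select_templates <- function(table, labels = table$labels, n_templates = 7L,
                             strategy = c("medoid", "random", "manual"),
                             manual_ids = NULL, seed = 1L) {
  strategy <- match.arg(strategy)
  check_two_classes(labels)
  n_templates <- as.integer(n_templates)
  if (n_templates < 2L) stop("n_templates must be >= 2")
  if (n_templates > nrow(table$values)) stop("n_templates exceeds sample count")
  # canonicalize to sorted-id order so selection ignores row order
  ord <- order(table$sample_ids)
  tab <- ft_subset(table, samples = ord)
  labs <- labels[ord]
  if (strategy == "manual") {
    if (is.null(manual_ids) || length(manual_ids) != n_templates) {
      stop("manual strategy requires exactly n_templates manual_ids")
    }
    idx <- match(manual_ids, tab$sample_ids)
    if (any(is.na(idx))) {
      stop("unknown template id(s): ",
           paste(manual_ids[is.na(idx)], collapse = ", "))
    }
    chosen <- idx
  } else {
    counts <- c(`0` = sum(labs == 0L), `1` = sum(labs == 1L))
    alloc <- stats::setNames(apportion(counts, n_templates, min_one = TRUE),
                             names(counts))
    chosen <- integer(0)
    for (k in c(0L, 1L)) {
      members <- which(labs == k)
      take <- alloc[[as.character(k)]]
      picked <- if (strategy == "medoid") {
        xm <- tab$values[members, , drop = FALSE]
        dsum <- rowSums(as.matrix(stats::dist(xm)))
        members[order(dsum, tab$sample_ids[members])[seq_len(take)]]
      } else {
        withr::with_seed(seed + k, sample(members, take))
      }
      chosen <- c(chosen, picked)
    }
  }
  structure(
    list(ids = tab$sample_ids[chosen],
         values = tab$values[chosen, , drop = FALSE],
         labels = labs[chosen],
         strategy = strategy),
    class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("template_set (%s): %d templates (%d event, %d non-event)\n",
              x$strategy, length(x$ids), sum(x$labels), sum(1 - x$labels)))
  invisible(x)
}

#' Build template-sample pair vectors
#'
#' Every template is paired with every sample; the pair vector is the signed
#' feature-space difference `V = M_I - N_i` (template minus sample), or its
#' absolute value under `abs_difference`. When sample labels are known each
#' pair is labeled positive (1, template and sample share the outcome class)
#' or negative (0, classes differ). Self-pairs (a template paired with its
#' own row) are zero vectors and degenerate perfect positives, so they are
#' excluded from training by default.
#'
#' @param templates a `template_set`.
#' @param table a `feature_table` in the same processed feature space.
#' @param labels optional binary outcome per sample.
#' @param exclude_self drop template-with-itself pairs (matched by sample id).
#' @param abs_difference take `|M_I - N_i|` componentwise.
#' @return a `pair_set`: matrix `vectors` (one row per pair), `pair_labels`
#'   (or NULL), `template_ids`, `sample_ids`.
#' @export
build_pairs <- function(templates, table, labels = table$labels,
                        exclude_self = TRUE, abs_difference = FALSE) {
  if (ncol(templates$values) != ncol(table$values) ||
      !identical(colnames(templates$values), table$feature_names)) {
    stop("feature-space mismatch between templates and table")
  }
  t_n <- length(templates$ids)
  n <- nrow(table$values)
  v_list <- vector("list", t_n)
  for (ti in seq_len(t_n)) {
    v <- sweep(-table$values, 2L, templates$values[ti, ], "+")  # M - N
    v_list[[ti]] <- v
  }
  vectors <- do.call(rbind, v_list)
  if (abs_difference) vectors <- abs(vectors)
  template_ids <- rep(templates$ids, each = n)
  sample_ids <- rep(table$sample_ids, times = t_n)
  pair_labels <- NULL
  if (!is.null(labels)) {
    pair_labels <- as.integer(rep(templates$labels, each = n) ==
                                rep(labels, times = t_n))
  }
  keep <- rep(TRUE, length(template_ids))
  if (exclude_self) keep <- template_ids != sample_ids
  rownames(vectors) <- NULL
  structure(
    list(vectors = vectors[keep, , drop = FALSE],
         pair_labels = pair_labels[keep],
         template_ids = template_ids[keep],
         sample_ids = sample_ids[keep]),
    class = "pair_set")
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("pair_set: %d pairs x %d dims", nrow(x$vectors),
              ncol(x$vectors)))
  if (!is.null(x$pair_labels)) {
    cat(sprintf(" (%d positive, %d negative)", sum(x$pair_labels),
                sum(1 - x$pair_labels)))
  }
  cat("\n")
  invisible(x)
}

#' Export a pair set for inspection
#' @param pairs a `pair_set`.
#' @param path output CSV path.
#' @export
write_pair_set <- function(pairs, path) {
  df <- data.frame(template_id = pairs$template_ids,
                   sample_id = pairs$sample_ids,
                   stringsAsFactors = FALSE)
  if (!is.null(pairs$pair_labels)) df$pair_label <- pairs$pair_labels
  df <- cbind(df, as.data.frame(pairs$vectors))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
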