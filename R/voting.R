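#' Aggregate per-template pair probabilities into a sample-level vote
#'
#' Each template I contributes a sample-level score
#' `s_I = P_PP,I` when the template label `M_I = 1`, and
#' `s_I = 1 - P_PP,I` when `M_I = 0`: a high positive-pair probability
#' against an event template is evidence the sample is an event, and the
#' same probability against a non-event template is evidence it is not.
#' The aggregated probability is the plain average `P = mean(s_I)` and the
#' predicted class is 1 when `P >= threshold` (ties at the threshold go to
#' class 1; the strict-inequality case split leaves the boundary undefined,
#' so the operator is `>=` and configurable via `threshold`).
#'
#' @param pair_probs numeric vector, the positive-pair probability for one
#'   sample against each template.
#' @param template_labels 0/1 label of each template (`M_I`).
#' @param threshold decision threshold on the aggregated probability.
#' @return list with `prob` (aggregated `P`), `class` (0/1), and
#'   `contributions` (the per-template `s_I`).
#' @export
aggregate_votes <- function(pair_probs, template_labels, threshold = 0.5) {
  if (length(pair_probs) == 0L) stop("empty probability list")
  if (length(pair_probs) != length(template_labels)) {
    stop("one probability per template is required")
  }
  if (any(pair_probs < 0 | pair_probs > 1)) stop("probability outside [0, 1]")
  if (!all(template_labels %in% c(0, 1))) stop("template labels must be 0/1")
  if (length(unique(template_labels)) < 2L) {
    warning("templates cover a single class; votes are one-sided")
  }
  s <- ifelse(template_labels == 1, pair_probs, 1 - pair_probs)
  p <- mean(s)
  list(prob = p, class = as.integer(p >= threshold), contributions = s)
}

#' Vote aggregation over a whole pair set
#'
#' Applies [aggregate_votes()] per sample of a scored `pair_set`.
#'
#' @param pairs a `pair_set` (pair rows carry `template_ids`/`sample_ids`).
#' @param pair_probs `P_PP` for every pair row, aligned with `pairs`.
#' @param template_labels named 0/1 vector keyed by template id.
#' @param threshold decision threshold.
#' @return data.frame with columns `sample_id`, `prob`, `class`.
#' @keywords internal
aggregate_pair_set <- function(pairs, pair_probs, template_labels,
                               threshold = 0.5) {
  sample_ids <- unique(pairs$sample_ids)
  res <- lapply(sample_ids, function(sid) {
    rows <- pairs$sample_ids == sid
    v <- aggregate_votes(pair_probs[rows],
                         template_labels[pairs$template_ids[rows]],
                         threshold)
    data.frame(sample_id = sid, prob = v$prob, class = v$class,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
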