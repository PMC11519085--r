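#' Pipeline configuration
#'
#' Bundles every tunable choice of the pairwise modeling pipeline: the
#' normalization scheme, the dimensionality-reduction step, the feature
#' screener and the number of screened features kept, the pair-classifier
#' family, the number of templates, the train/test split ratio, the number of
#' cross-validation folds, and the seed from which all randomness derives.
#'
#' @param normalization one of `"unit"` (divide by the per-feature Euclidean
#'   norm over training samples), `"zero_center"` (subtract the training
#'   mean), or `"unit_zero_center"` (center then divide by the centered norm).
#' @param reduction one of `"pcc"` (drop one of each highly correlated
#'   feature pair), `"pca"`, or `"none"`.
#' @param pcc_threshold absolute Pearson correlation above which the
#'   later-ordered feature of a pair is dropped; in `(0, 1]`.
#' @param screener one of `"anova"`, `"rfe"`, `"relief"`.
#' @param n_features number of top-ranked features kept for modeling.
#' @param classifier pair-classifier family; see [fit_pair_classifier()].
#' @param n_templates number of representative template cases (>= 2).
#' @param split_ratio training fraction for [split_cohort()].
#' @param cv_folds number of cross-validation folds.
#' @param threshold decision threshold on the aggregated vote probability.
#' @param abs_difference use |template - sample| instead of the signed
#'   difference when building pair vectors.
#' @param seed integer seed controlling all randomness.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(normalization = "unit_zero_center",
                            reduction = "pcc",
                            pcc_threshold = 0.99,
                            screener = "anova",
                            n_features = 12L,
                            classifier = "gaussian_nb",
                            n_templates = 7L,
                            split_ratio = 0.7,
                            cv_folds = 5L,
                            threshold = 0.5,
                            abs_difference = FALSE,
                            seed = 1L) {
  normalization <- match.arg(normalization,
                             c("unit", "zero_center", "unit_zero_center"))
  reduction <- match.arg(reduction, c("pcc", "pca", "none"))
  screener <- match.arg(screener, c("anova", "rfe", "relief"))
  classifier <- match.arg(classifier, classifier_families())
  stopifnot(is.numeric(pcc_threshold), length(pcc_threshold) == 1,
            pcc_threshold > 0, pcc_threshold <= 1)
  n_features <- as.integer(n_features)
  if (is.na(n_features) || n_features < 1L) stop("n_features must be >= 1")
  n_templates <- as.integer(n_templates)
  if (is.na(n_templates) || n_templates < 2L) stop("n_templates must be >= 2")
  stopifnot(split_ratio > 0, split_ratio < 1)
  cv_folds <- as.integer(cv_folds)
  if (is.na(cv_folds) || cv_folds < 2L) stop("cv_folds must be >= 2")
  stopifnot(threshold >= 0, threshold <= 1)
  structure(
    list(normalization = normalization, reduction = reduction,
         pcc_threshold = pcc_threshold, screener = screener,
         n_features = n_features, classifier = classifier,
         n_templates = n_templates, split_ratio = split_ratio,
         cv_folds = cv_folds, threshold = threshold,
         abs_difference = abs_difference, seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#'
#' Every field is validated through [pipeline_config()] on read, so an invalid
#' enum value or out-of-range number in the file is a hard error.
#'
#' @param path JSON file path.
#' @return [read_config()] returns a `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}
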