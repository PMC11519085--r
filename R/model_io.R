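#' Save a trained pairwise model as JSON
#'
#' The file carries an explicit `format_version`; the frozen normalizer,
#' reduction parameters, selected features and templates are written as
#' plain JSON at full numeric precision. A Gaussian naive Bayes pair
#' classifier is stored transparently as its priors, means and variances;
#' other classifier families embed their fitted object as a base64 payload.
#' `load_model(save_model(m))` reproduces identical predictions.
#'
#' @param model a `trained_pairwise_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_pairwise_model"))
  clf <- model$classifier
  clf_json <- list(family = clf$family, seed = clf$seed,
                   features = clf$features)
  if (clf$family == "gaussian_nb") {
    clf_json$params <- list(prior = clf$fit$prior,
                            mean0 = clf$fit$mean[[1L]],
                            mean1 = clf$fit$mean[[2L]],
                            var0 = clf$fit$var[[1L]],
                            var1 = clf$fit$var[[2L]])
  } else {
    clf_json$payload <- jsonlite::base64_enc(serialize(clf$fit, NULL))
  }
  red <- model$reduction
  if (!is.null(red$loadings)) {
    red$loadings_features <- rownames(red$loadings)
    red$loadings <- matrix_to_columns(red$loadings)
  }
  obj <- list(
    format_version = model$format_version,
    config = unclass(model$config),
    threshold = model$threshold,
    normalizer = list(scheme = model$normalizer$scheme,
                      features = names(model$normalizer$center),
                      center = unname(model$normalizer$center),
                      scale = unname(model$normalizer$scale),
                      constant_features = model$normalizer$constant_features),
    reduction = red,
    selected_features = model$selected_features,
    screening = model$screening,
    templates = list(ids = model$templates$ids,
                     labels = model$templates$labels,
                     strategy = model$templates$strategy,
                     features = colnames(model$templates$values),
                     values = matrix_to_columns(model$templates$values)),
    classifier = clf_json)
  # I(17) = 17 significant digits, enough for exact double round-trips
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a trained pairwise model from JSON
#'
#' @param path a file written by [save_model()]. A missing or truncated file,
#'   or a `format_version` other than the one this package writes, is a hard
#'   error.
#' @return a `trained_pairwise_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse model file: ",
                                           conditionMessage(e)))
  if (is.null(obj$format_version) ||
      !identical(obj$format_version, MODEL_FORMAT_VERSION)) {
    stop("model format version mismatch: expected ", MODEL_FORMAT_VERSION,
         ", found ", obj$format_version %||% "<missing>")
  }
  config <- do.call(pipeline_config,
                    obj$config[names(formals(pipeline_config))])
  norm <- structure(
    list(scheme = obj$normalizer$scheme,
         center = stats::setNames(obj$normalizer$center,
                                  obj$normalizer$features),
         scale = stats::setNames(obj$normalizer$scale,
                                 obj$normalizer$features),
         constant_features = as.character(obj$normalizer$constant_features %||%
                                            character(0))),
    class = "normalizer_params")
  red <- obj$reduction
  if (!is.null(red$loadings)) {
    lf <- red$loadings_features
    red$loadings <- columns_to_matrix(red$loadings)
    rownames(red$loadings) <- lf
    red$center <- stats::setNames(red$center, lf)
    red$loadings_features <- NULL
  }
  tmpl_vals <- columns_to_matrix(obj$templates$values)
  colnames(tmpl_vals) <- obj$templates$features
  rownames(tmpl_vals) <- obj$templates$ids
  templates <- structure(
    list(ids = obj$templates$ids, values = tmpl_vals,
         labels = as.integer(obj$templates$labels),
         strategy = obj$templates$strategy),
    class = "template_set")
  cj <- obj$classifier
  fit <- if (identical(cj$family, "gaussian_nb")) {
    list(prior = cj$params$prior,
         mean = list(stats::setNames(cj$params$mean0, cj$features),
                     stats::setNames(cj$params$mean1, cj$features)),
         var = list(stats::setNames(cj$params$var0, cj$features),
                    stats::setNames(cj$params$var1, cj$features)))
  } else {
    unserialize(jsonlite::base64_dec(cj$payload))
  }
  classifier <- structure(
    list(family = cj$family, fit = fit, seed = as.integer(cj$seed),
         features = cj$features),
    class = c("pair_classifier", "binary_classifier"))
  structure(
    list(format_version = obj$format_version,
         normalizer = norm,
         reduction = red,
         screening = obj$screening,
         selected_features = obj$selected_features,
         templates = templates,
         classifier = classifier,
         threshold = obj$threshold,
         config = config),
    class = "trained_pairwise_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

matrix_to_columns <- function(m) {
  stats::setNames(lapply(seq_len(ncol(m)), function(j) unname(m[, j])),
                  colnames(m))
}

columns_to_matrix <- function(lst) {
  m <- do.call(cbind, lapply(lst, as.numeric))
  colnames(m) <- names(lst)
  m
}
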