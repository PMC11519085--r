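#' Specification of a synthetic cohort
#'
#' Describes a seeded synthetic cohort with the statistical structure the
#' pipeline assumes: a binary outcome at a fixed prevalence, a large block-
#' correlated set of continuous "radiomics" features of which a few carry a
#' standardized mean shift between the outcome groups, and a small number of
#' clinical covariates (continuous, e.g. wall thickness, or ordinal, e.g.
#' T stage). Defaults emulate an elderly ESCC radiotherapy cohort: 130
#' patients with 49.23% locoregional recurrence, 200 radiomics features in
#' equicorrelated blocks of 10 (within-block correlation 0.8, mirroring
#' highly collinear radiomics feature families), 5 informative features with
#' standardized mean difference 1, one continuous and one 4-level ordinal
#' clinical covariate.
#'
#' @param n number of samples.
#' @param d_radiomics number of radiomics features.
#' @param n_informative number of radiomics features with a class shift.
#' @param effect_size standardized mean difference of informative features.
#' @param block_correlation within-block equicorrelation in `[0, 1)`.
#' @param block_size features per correlated block.
#' @param clinical list describing clinical covariates; each element is
#'   `list(type = "continuous")` or `list(type = "ordinal", levels = k)`,
#'   optionally with `effect` (standardized shift on the latent scale;
#'   default half the radiomics `effect_size`).
#' @param prevalence event fraction in `(0, 1)`; the event count is fixed at
#'   `round(prevalence * n)`, not drawn, so small cohorts are stable.
#' @param seed integer seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n = 130L, d_radiomics = 200L, n_informative = 5L,
                        effect_size = 1.0, block_correlation = 0.8,
                        block_size = 10L,
                        clinical = list(
                          wall_thickness = list(type = "continuous"),
                          t_stage = list(type = "ordinal", levels = 4L)),
                        prevalence = 0.4923, seed = 1L) {
  n <- as.integer(n)
  d_radiomics <- as.integer(d_radiomics)
  n_informative <- as.integer(n_informative)
  if (n_informative > d_radiomics) stop("n_informative exceeds d_radiomics")
  stopifnot(block_correlation >= 0, block_correlation < 1,
            prevalence > 0, prevalence < 1, effect_size >= 0)
  n_event <- round(prevalence * n)
  if (n_event < 2L || n - n_event < 2L) {
    stop("prevalence leaves fewer than 2 samples in a class")
  }
  structure(
    list(n = n, d_radiomics = d_radiomics, n_informative = n_informative,
         effect_size = effect_size, block_correlation = block_correlation,
         block_size = as.integer(block_size), clinical = clinical,
         prevalence = prevalence, seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Labels: exactly `round(prevalence * n)` events, randomly positioned.
#' Radiomics features: equicorrelated Gaussian blocks
#' (`x = sqrt(rho) z_block + sqrt(1 - rho) z_own`, unit marginal variance),
#' with the class-1 mean of the first `n_informative` features shifted by
#' `effect_size`. Continuous clinical covariates are standard Gaussians with
#' their own shift; ordinal covariates discretize a shifted latent Gaussian
#' at its null quantiles (a proportional-odds-style construction). Fully
#' reproducible from the spec seed.
#'
#' @param spec a [cohort_spec()].
#' @return a labeled `feature_table` (radiomics features `rad_001`, ...,
#'   clinical features named as in `spec$clinical`).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n
    n_event <- round(spec$prevalence * n)
    labels <- integer(n)
    labels[sample.int(n, n_event)] <- 1L
    d <- spec$d_radiomics
    rho <- spec$block_correlation
    bs <- spec$block_size
    n_blocks <- ceiling(d / bs)
    block_of <- rep(seq_len(n_blocks), each = bs)[seq_len(d)]
    z_block <- matrix(stats::rnorm(n * n_blocks), n, n_blocks)
    z_own <- matrix(stats::rnorm(n * d), n, d)
    x <- sqrt(rho) * z_block[, block_of, drop = FALSE] +
      sqrt(1 - rho) * z_own
    if (spec$n_informative > 0L && spec$effect_size > 0) {
      idx <- seq_len(spec$n_informative)
      x[labels == 1L, idx] <- x[labels == 1L, idx, drop = FALSE] +
        spec$effect_size
    }
    colnames(x) <- sprintf("rad_%03d", seq_len(d))
    clin <- NULL
    if (length(spec$clinical)) {
      clin <- matrix(0, n, length(spec$clinical),
                     dimnames = list(NULL, names(spec$clinical)))
      for (j in seq_along(spec$clinical)) {
        v <- spec$clinical[[j]]
        eff <- v$effect %||% (spec$effect_size / 2)
        latent <- stats::rnorm(n) + eff * labels
        if (identical(v$type, "ordinal")) {
          k <- v$levels %||% 4L
          cuts <- stats::qnorm(seq_len(k - 1L) / k)  # null-quantile cuts
          clin[, j] <- findInterval(latent, cuts) + 1
        } else {
          clin[, j] <- latent
        }
      }
    }
    vals <- cbind(x, clin)
    kind <- c(rep("radiomics", d), rep("clinical", length(spec$clinical)))
    feature_table(vals, sprintf("s%03d", seq_len(n)), colnames(vals), kind,
                  labels)
  })
}

#' Generate a pair of jittered ellipsoid masks
#'
#' Builds a 3-D binary ellipsoid mask and a boundary-jittered copy: the
#' second mask's center and radii are perturbed by seeded Gaussian noise of
#' magnitude `jitter` (voxels). Expected Dice between the pair decreases as
#' `jitter` grows, emulating inter-observer delineation differences.
#'
#' @param shape integer vector of 3 grid dimensions.
#' @param center ellipsoid center (defaults to the grid center).
#' @param radii ellipsoid radii in voxels (all > 0).
#' @param jitter perturbation magnitude in voxels (0 = identical masks).
#' @param seed integer seed.
#' @return list of two binary 3-D arrays `a` and `b`.
#' @export
generate_mask_pair <- function(shape = c(32L, 32L, 32L),
                               center = (shape + 1) / 2,
                               radii = c(8, 6, 5), jitter = 0, seed = 1L) {
  stopifnot(length(shape) == 3L, length(radii) == 3L, jitter >= 0)
  if (any(radii < 1)) stop("ellipsoid radii must be >= 1 voxel")
  ellipsoid <- function(ctr, rad) {
    g <- expand.grid(x = seq_len(shape[1L]), y = seq_len(shape[2L]),
                     z = seq_len(shape[3L]))
    inside <- ((g$x - ctr[1L]) / rad[1L])^2 + ((g$y - ctr[2L]) / rad[2L])^2 +
      ((g$z - ctr[3L]) / rad[3L])^2 <= 1
    array(inside, dim = shape)
  }
  a <- ellipsoid(center, radii)
  if (sum(a) == 0) stop("ellipsoid contains no voxels on this grid")
  b <- withr::with_seed(seed, {
    ctr2 <- center + stats::rnorm(3L, 0, jitter)
    rad2 <- pmax(radii + stats::rnorm(3L, 0, jitter / 2), 1)
    ellipsoid(ctr2, rad2)
  })
  list(a = a, b = b)
}

#' Write a cohort and its generating spec to disk
#'
#' Emits the standard feature-table CSV plus the spec as JSON alongside.
#'
#' @param spec a [cohort_spec()].
#' @param path output CSV path (the spec goes to `<path>.spec.json`).
#' @return the generated `feature_table`, invisibly.
#' @export
write_cohort <- function(spec, path) {
  tab <- generate_cohort(spec)
  write_feature_table(tab, path)
  jsonlite::write_json(unclass(spec), paste0(path, ".spec.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(tab)
}
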