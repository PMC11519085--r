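#' Dice overlap coefficient between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)` over same-shaped binary arrays. Masks
#' may be given as numeric/logical arrays or as paths to NIfTI files (read
#' with \pkg{RNifti}); any nonzero voxel counts as foreground. Two empty
#' masks are in perfect (if vacuous) agreement, so that case returns 1 with
#' a warning.
#'
#' @param mask_a,mask_b binary arrays of identical shape, or NIfTI paths.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  mask_a <- load_mask(mask_a)
  mask_b <- load_mask(mask_b)
  if (!identical(dim(mask_a), dim(mask_b))) {
    stop("mask shape mismatch: ", paste(dim(mask_a), collapse = "x"), " vs ",
         paste(dim(mask_b), collapse = "x"))
  }
  a <- mask_a != 0
  b <- mask_b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) {
    warning("both masks are empty; returning Dice = 1")
    return(1)
  }
  2 * sum(a & b) / denom
}

load_mask <- function(m) {
  if (is.character(m)) {
    if (!file.exists(m)) stop("mask file not found: ", m)
    m <- RNifti::readNifti(m)
  }
  arr <- as.array(m)
  if (any(is.na(arr))) stop("mask contains missing values")
  arr
}

#' Paired measurements from two readers
#'
#' @param subject_ids subject identifiers.
#' @param reader1,reader2 measurements in the same units, one per subject.
#' @return a `paired_measurements` object.
#' @export
paired_measurements <- function(subject_ids, reader1, reader2) {
  stopifnot(length(reader1) == length(reader2),
            length(subject_ids) == length(reader1))
  if (length(reader1) < 3L) stop("need at least 3 subjects")
  if (any(!is.finite(reader1)) || any(!is.finite(reader2))) {
    stop("measurements must be finite")
  }
  structure(list(subject_ids = as.character(subject_ids),
                 reader1 = as.numeric(reader1),
                 reader2 = as.numeric(reader2)),
            class = "paired_measurements")
}

#' Read paired measurements from CSV
#' @param path CSV with columns `subject`, `reader1`, `reader2`.
#' @return a `paired_measurements` object.
#' @export
read_paired_measurements <- function(path) {
  df <- utils::read.csv(path)
  need <- c("subject", "reader1", "reader2")
  if (!all(need %in% names(df))) {
    stop("CSV must have columns: ", paste(need, collapse = ", "))
  }
  paired_measurements(df$subject, df$reader1, df$reader2)
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single rater (Shrout-Fleiss
#' ICC(2,1)): with n subjects and k raters,
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' where MSR, MSC, MSE are the subject, rater, and residual mean squares of
#' the two-way decomposition. The F statistic is `MSR / MSE` on
#' `(n-1, (n-1)(k-1))` degrees of freedom and the confidence interval uses
#' the Shrout-Fleiss F-distribution bounds with Satterthwaite degrees of
#' freedom.
#'
#' @param pm a [paired_measurements()] object.
#' @param level confidence level.
#' @return list with `icc`, `ci` (lo, hi), `F`, `df1`, `df2`, `p`.
#' @export
icc <- function(pm, level = 0.95) {
  x <- cbind(pm$reader1, pm$reader2)
  n <- nrow(x)
  k <- ncol(x)
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_total <- sum((x - grand)^2)
  if (ss_total <= 0) stop("zero total variance; ICC undefined")
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc_val <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  f <- msr / mse
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  # Shrout & Fleiss interval for ICC(2,1)
  alpha <- 1 - level
  fj <- msc / mse
  a <- k * icc_val / (n * (1 - icc_val))
  b <- 1 + k * icc_val * (n - 1) / (n * (1 - icc_val))
  v <- (a * fj + b)^2 / (a^2 * fj^2 / (k - 1) + b^2 / (n - 1))
  f_l <- stats::qf(1 - alpha / 2, df1 = n - 1, df2 = v)
  f_u <- stats::qf(1 - alpha / 2, df1 = v, df2 = n - 1)
  lo <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc_val, ci = c(lo = lo, hi = hi), F = f, df1 = df1, df2 = df2,
       p = p)
}

#' Agreement summary table for several shape measures
#'
#' One ICC row per measure, in the usual reproducibility-table layout
#' (feature, ICC, CI, F, p).
#'
#' @param measures named list of [paired_measurements()] objects.
#' @param level confidence level.
#' @return data.frame with columns `feature`, `icc`, `ci_lo`, `ci_hi`, `F`,
#'   `p`.
#' @export
agreement_table <- function(measures, level = 0.95) {
  rows <- lapply(names(measures), function(nm) {
    r <- icc(measures[[nm]], level)
    data.frame(feature = nm, icc = r$icc, ci_lo = r$ci[["lo"]],
               ci_hi = r$ci[["hi"]], F = r$F, p = r$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
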