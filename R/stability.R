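## Expression stability: median-of-ratios normalization, CV, geometric mean,
## percentile ranks and the low-expression filter.

#' Median-of-ratios size factors
#'
#' Estimates one positive scaling factor per sample using the median-of-ratios
#' method: for each reference transcript (strictly positive counts in every
#' sample) the ratio of its count in a sample to its geometric mean across
#' samples is formed, and the sample's factor is the median of those ratios.
#' Size factors are only defined up to a common scalar; the gauge is fixed by
#' rescaling them to geometric mean 1, which makes [normalize_counts()] an
#' exact fixed point (re-estimating on a normalized matrix gives all ones).
#'
#' @param counts numeric matrix, transcripts x samples, non-negative.
#' @return named numeric vector of strictly positive factors, one per sample.
#' @examples
#' m <- rbind(a = c(10, 20), b = c(30, 60))
#' size_factors(m) # 1/sqrt(2), sqrt(2)
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    stop("no reference transcripts: every transcript has a zero count in ",
         "at least one sample, so median-of-ratios factors cannot be estimated")
  }
  lc <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(lc)
  logf <- apply(lc, 2L, function(col) stats::median(col - loggeo))
  factors <- exp(logf - mean(logf))
  names(factors) <- colnames(counts)
  factors
}

#' Normalize a count matrix by per-sample size factors
#'
#' Divides each column by its factor. Re-estimating size factors on the
#' result yields all ones, and the operation is idempotent in that sense.
#'
#' @param counts numeric matrix, transcripts x samples.
#' @param factors strictly positive numeric vector, one per sample. Defaults
#'   to [size_factors()] of `counts`.
#' @return matrix of normalized counts with the input dimnames.
#' @export
normalize_counts <- function(counts, factors = size_factors(counts)) {
  counts <- as.matrix(counts)
  if (length(factors) != ncol(counts)) {
    stop("need one size factor per sample: got ", length(factors),
         " factors for ", ncol(counts), " samples")
  }
  if (any(factors <= 0)) stop("size factors must be strictly positive")
  sweep(counts, 2L, factors, "/")
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the arithmetic
#' mean. Undefined (NA) when the mean is zero; such transcripts are excluded
#' from percentile ranking downstream.
#'
#' @param x numeric vector of length >= 2, non-negative.
#' @return a dimensionless non-negative scalar, or NA when the mean is 0.
#' @export
cv <- function(x) {
  if (length(x) < 2L) stop("cv needs at least 2 samples")
  m <- mean(x)
  if (m == 0) return(NA_real_)
  stats::sd(x) / m
}

#' Percentile rank
#'
#' The fraction of values less than or equal to each value, in (0, 1]. Ties
#' are handled by the "<=" counting definition itself. NA values get NA ranks
#' and do not enter the denominator.
#'
#' @param x numeric vector.
#' @return numeric vector of ranks in (0, 1], same length and names as `x`.
#' @export
percentile_rank <- function(x) {
  out <- rep(NA_real_, length(x))
  names(out) <- names(x)
  ok <- !is.na(x)
  if (!any(ok)) return(out)
  out[ok] <- stats::ecdf(x[ok])(x[ok])
  out
}

#' Geometric mean with zero propagation
#'
#' The n-th root of the product of the values; exactly 0 whenever any value
#' is 0 (no pseudocount is added).
#'
#' @param x non-negative numeric vector.
#' @return non-negative scalar.
#' @export
geometric_mean <- function(x) {
  if (any(x < 0)) stop("geometric_mean needs non-negative values")
  if (length(x) == 0L) return(NA_real_)
  if (any(x == 0)) return(0)
  exp(mean(log(x)))
}

#' Low-expression filter
#'
#' A transcript passes iff the arithmetic mean of its raw counts across all
#' samples is at least `threshold` (default 1 read). Applied to raw counts,
#' before normalization.
#'
#' @param raw numeric matrix of raw counts, transcripts x samples.
#' @param threshold minimum mean raw count (default 1).
#' @return logical vector, named by transcript.
#' @export
low_expression_filter <- function(raw, threshold = 1) {
  raw <- as.matrix(raw)
  means <- rowMeans(raw)
  out <- means >= threshold
  names(out) <- rownames(raw)
  out
}

#' Per-transcript stability table
#'
#' Runs the full stability stage on a raw count matrix: size-factor
#' normalization, per-transcript CV and geometric mean of normalized counts,
#' the mean raw count, the low-expression filter, and percentile ranks of CV
#' and geometric mean computed over the transcripts that pass the filter.
#' Transcripts failing the filter are retained in the table with
#' `passes_filter = FALSE` and NA percentiles, so removed-vs-kept comparisons
#' remain possible.
#'
#' @param raw numeric matrix of raw counts, transcripts x samples, with
#'   rownames (transcript ids) and colnames (sample ids).
#' @param metadata optional data.frame with columns `sample`, `tissue`,
#'   `stage` covering every sample; checked, not otherwise used here.
#' @param min_mean_reads low-expression threshold on the mean raw count.
#' @return data.frame with columns `transcript`, `cv`, `cv_percentile`,
#'   `geo_mean`, `geo_mean_percentile`, `mean_raw`, `passes_filter`.
#' @export
stability_table <- function(raw, metadata = NULL, min_mean_reads = 1) {
  raw <- as.matrix(raw)
  if (is.null(rownames(raw))) stop("raw counts need transcript rownames")
  if (anyDuplicated(rownames(raw))) stop("transcript ids must be unique")
  if (any(raw < 0)) stop("counts must be non-negative")
  if (!is.null(metadata)) {
    missing <- setdiff(colnames(raw), metadata$sample)
    if (length(missing)) {
      stop("metadata does not cover samples: ", paste(missing, collapse = ", "))
    }
  }
  norm <- normalize_counts(raw)
  cvs <- apply(norm, 1L, cv)
  geo <- apply(norm, 1L, geometric_mean)
  mean_raw <- rowMeans(raw)
  keep <- low_expression_filter(raw, min_mean_reads)

  cv_rank <- rep(NA_real_, nrow(raw))
  geo_rank <- rep(NA_real_, nrow(raw))
  cv_rank[keep] <- percentile_rank(cvs[keep])
  geo_rank[keep] <- percentile_rank(geo[keep])

  data.frame(
    transcript = rownames(raw),
    cv = unname(cvs),
    cv_percentile = cv_rank,
    geo_mean = unname(geo),
    geo_mean_percentile = geo_rank,
    mean_raw = unname(mean_raw),
    passes_filter = unname(keep),
    stringsAsFactors = FALSE
  )
}
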