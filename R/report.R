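## Reporting: promoter subsampling, CV distributions by promoter class,
## ortholog recovery rates with ANOVA/Tukey, and tertile binning.

#' Uniform random subsample of transcript ids
#'
#' Samples `round(fraction * n)` ids without replacement, deterministically
#' under the seed.
#'
#' @param ids character vector of transcript ids.
#' @param fraction fraction to keep, in (0, 1] (default 0.4).
#' @param seed integer seed.
#' @return character vector subset of `ids`.
#' @export
subsample_transcripts <- function(ids, fraction = 0.4, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (fraction == 1) return(ids)
  set.seed(seed)
  k <- round(fraction * length(ids))
  sort(sample(ids, k))
}

#' CV-percentile distribution per promoter class
#'
#' Joins promoter labels with the stability table on transcript id, keeps
#' filtered transcripts, and tabulates a normalized histogram of
#' `cv_percentile` on `[0, 1]` per class. Densities integrate to 1 for
#' nonempty classes.
#'
#' @param labels label table from [scan_promoters()] (needs `transcript`,
#'   `class`).
#' @param stab stability table from [stability_table()].
#' @param bins number of equal-width bins on `[0, 1]` (default 20).
#' @return list per class with `class`, `n`, `breaks`, `density` and
#'   `mean_percentile`; classes with no members get `n = 0` and are flagged
#'   with `empty = TRUE`.
#' @export
cv_distribution_by_class <- function(labels, stab, bins = 20L) {
  merged <- merge(labels[, c("transcript", "class")],
                  stab[stab$passes_filter,
                       c("transcript", "cv_percentile")],
                  by = "transcript")
  merged <- merged[!is.na(merged$cv_percentile), , drop = FALSE]
  breaks <- seq(0, 1, length.out = bins + 1L)
  out <- lapply(sort(unique(labels$class)), function(cl) {
    x <- merged$cv_percentile[merged$class == cl]
    if (length(x) == 0L) {
      return(list(class = cl, n = 0L, breaks = breaks,
                  density = rep(NA_real_, bins), mean_percentile = NA_real_,
                  empty = TRUE))
    }
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    list(class = cl, n = length(x), breaks = breaks, density = h$density,
         mean_percentile = mean(x), empty = FALSE)
  })
  names(out) <- vapply(out, `[[`, "", "class")
  out
}

#' Ortholog recovery rate per species and gene set
#'
#' The fraction of each query set's members that appear as the query of at
#' least one ortholog-table row for the species.
#'
#' @param sets named list of query transcript id vectors (e.g. uniform,
#'   conditional, random).
#' @param table ortholog table (`query_transcript`, `species`).
#' @param species character vector of target species.
#' @return data.frame with columns `species`, `set`, `rate`.
#' @export
ortholog_recovery <- function(sets, table, species) {
  out <- expand.grid(species = species, set = names(sets),
                     stringsAsFactors = FALSE)
  out$rate <- mapply(function(sp, st) {
    q <- sets[[st]]
    if (length(q) == 0L) return(NA_real_)
    found <- unique(table$query_transcript[table$species == sp])
    mean(q %in% found)
  }, out$species, out$set)
  out
}

#' One-way ANOVA with Tukey HSD across gene sets
#'
#' Treats each species as one observation per gene set and tests whether
#' mean recovery differs between sets, following the ANOVA with Tukey's
#' honestly-significant-difference post hoc.
#'
#' @param rates data.frame from [ortholog_recovery()] (`set`, `rate`).
#' @return list with `F` statistic, `p_value`, and `tukey` (data.frame of
#'   pairwise comparisons: `pair`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
anova_tukey <- function(rates) {
  rates <- rates[!is.na(rates$rate), , drop = FALSE]
  counts <- table(rates$set)
  if (length(counts) < 2L) stop("need at least 2 gene sets")
  if (any(counts < 2L)) {
    stop("degenerate group(s) with < 2 observations: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  rates$set <- factor(rates$set)
  if (all(abs(rates$rate - mean(rates$rate)) <
            1e-12 * max(1, abs(mean(rates$rate))))) {
    ## no variation at all: no effect, and aov's 0/0 F is meaningless
    pairs <- utils::combn(levels(rates$set), 2L,
                          function(p) paste(p[2L], p[1L], sep = "-"))
    return(list(F = 0, p_value = 1,
                tukey = data.frame(pair = pairs, diff = 0, lwr = 0, upr = 0,
                                   p_adj = 1, stringsAsFactors = FALSE)))
  }
  fit <- stats::aov(rate ~ set, data = rates)
  an <- summary(fit)[[1L]]
  tk <- suppressWarnings(stats::TukeyHSD(fit)$set)
  Fv <- an[["F value"]][1L]
  pv <- an[["Pr(>F)"]][1L]
  if (is.nan(Fv)) {  # zero variance within and between: no effect at all
    Fv <- 0; pv <- 1
    tk[, "p adj"][is.nan(tk[, "p adj"])] <- 1
  }
  list(F = Fv, p_value = pv,
       tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          lwr = tk[, "lwr"], upr = tk[, "upr"],
                          p_adj = tk[, "p adj"], row.names = NULL,
                          stringsAsFactors = FALSE))
}

#' Tertile category of a percentile rank
#'
#' low for `[0, 0.33]`, mid for `(0.33, 0.66]`, high for `(0.66, 1]`;
#' boundary values go to the lower bin.
#'
#' @param percentile numeric vector in `[0, 1]`.
#' @return character vector of "low"/"mid"/"high".
#' @export
tertile_bins <- function(percentile) {
  if (any(is.na(percentile)) || any(percentile < 0 | percentile > 1)) {
    stop("percentiles must lie in [0, 1]")
  }
  ifelse(percentile <= 0.33, "low", ifelse(percentile <= 0.66, "mid", "high"))
}
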