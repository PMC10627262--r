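# Independent oracles and tiny fixture builders used across the suite.

# Brute-force PWM scorer: explicit per-offset, per-position summation, no
# shared code with pwm_relative_score().
oracle_pwm_score <- function(weights, seq) {
  bases <- strsplit(seq, "")[[1L]]
  K <- ncol(weights)
  n <- length(bases)
  if (n < K) return(NA_real_)
  lo <- 0; hi <- 0
  for (j in seq_len(K)) {
    lo <- lo + min(weights[, j])
    hi <- hi + max(weights[, j])
  }
  best <- NA_real_
  for (o in seq_len(n - K + 1L)) {
    raw <- 0
    ok <- TRUE
    for (j in seq_len(K)) {
      b <- bases[o + j - 1L]
      if (!b %in% rownames(weights)) { ok <- FALSE; break }
      raw <- raw + weights[b, j]
    }
    if (!ok) next
    rel <- (raw - lo) / (hi - lo)
    if (is.na(best) || rel > best) best <- rel
  }
  unname(best)
}

# Naive windowed substring search: does any listed 8-mer sit fully inside
# the window sequence?
oracle_octamer_present <- function(window_seq, octamers) {
  n <- nchar(window_seq)
  for (oct in octamers) {
    k <- nchar(oct)
    if (n < k) next
    for (o in seq_len(n - k + 1L)) {
      if (substr(window_seq, o, o + k - 1L) == oct) return(TRUE)
    }
  }
  FALSE
}

# Hand-rolled one-way ANOVA F statistic (between/within mean squares).
oracle_anova_F <- function(values, groups) {
  groups <- as.character(groups)
  gm <- mean(values)
  ss_between <- 0; ss_within <- 0
  for (g in unique(groups)) {
    x <- values[groups == g]
    ss_between <- ss_between + length(x) * (mean(x) - gm)^2
    ss_within <- ss_within + sum((x - mean(x))^2)
  }
  df1 <- length(unique(groups)) - 1L
  df2 <- length(values) - length(unique(groups))
  (ss_between / df1) / (ss_within / df2)
}

random_dna <- function(n, gc = 0.36) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_pwm <- function(len = sample(4:10, 1)) {
  w <- matrix(stats::runif(4 * len, -3, 3), 4, len,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  promstab::pwm("rand", w)
}

toy_tree <- "(((sp1,sp2),(sp3,sp4)),((sp5,sp6),(sp7,sp8)));"

# Minimal stability table from named cv / geo_mean vectors.
toy_stab <- function(cv, geo = NULL) {
  geo <- geo %||% stats::setNames(rep(1, length(cv)), names(cv))
  data.frame(transcript = names(cv), cv = unname(cv),
             cv_percentile = unname(promstab::percentile_rank(cv)),
             geo_mean = unname(geo[names(cv)]),
             geo_mean_percentile = unname(promstab::percentile_rank(geo[names(cv)])),
             mean_raw = 10, passes_filter = TRUE, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rank-based AUROC of a score separating two classes (positives should
# score higher).
auroc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
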