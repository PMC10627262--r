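#' @keywords internal
"_PACKAGE"

## Shared small helpers. Coordinate convention used throughout: TSS-relative
## positions have no 0; -1 is the base immediately upstream of the TSS and +1
## is the first transcribed base.

#' Reverse complement of a nucleotide string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors.
#'
#' @param x character vector of A/C/G/T/N strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Derive a child seed from a master seed
#'
#' Deterministically maps a master seed and a stage label to a 31-bit child
#' seed, so every stochastic stage of the pipeline draws from an independent
#' stream while remaining reproducible from a single `--seed`.
#'
#' @param seed integer master seed.
#' @param label character stage label.
#' @return a single integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- utils::head(utf8ToInt(label), 16L)
  acc <- as.numeric(seed) %% 2147483647
  for (k in h) acc <- (acc * 131 + k) %% 2147483647
  as.integer(acc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## integer check tolerant of doubles
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}
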