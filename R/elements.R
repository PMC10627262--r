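## Core promoter element vocabulary shared by the simulator and the scanners.
## Consensus octamers are example sequences for the five screened element
## classes; the shipped PWM and octamer files are synthetic instances built
## around these consensi (real scans take user-supplied motif files).

CORE_ELEMENTS <- c("TATA", "YPatch", "Inr", "CA", "GA")
MOTIF_ELEMENTS <- c("TATA", "YPatch", "Inr")     # PWM motif scan
OCTAMER_ELEMENTS <- c("TATA", "YPatch", "CA", "GA")  # positional octamer scan

#' Consensus octamers used when planting elements
#'
#' One representative 8-mer per element class: an A/T-rich TATA-box, a
#' pyrimidine-rich Y patch, an initiator spanning the TSS, and the CA and GA
#' octamer classes. These are the sequences [simulate_genome()] writes into
#' synthetic promoters and the anchors of the shipped example motif files.
#'
#' @return named character vector of 8-mers.
#' @export
element_consensus <- function() {
  c(TATA = "TATAAATA",
    YPatch = "CTTCTTCC",
    Inr = "TTCAATTC",
    CA = "ACCAATCA",
    GA = "AGGAGAAG")
}

#' Default TSS-relative scan windows
#'
#' Motif-scan windows: TATA (-100, -1), Y patch (-100, +100), Inr (-10, +10).
#' Octamer-scan windows: TATA (-45, -18), Y patch (-50, +50), CA (-35, -1),
#' GA (-35, +75). Positions use the no-zero convention (-1 abuts the TSS,
#' +1 is the first transcribed base).
#'
#' @return list with components `motif` and `octamer`, each a named list of
#'   `c(from, to)` pairs.
#' @export
default_scan_windows <- function() {
  list(
    motif = list(TATA = c(-100L, -1L),
                 YPatch = c(-100L, 100L),
                 Inr = c(-10L, 10L)),
    octamer = list(TATA = c(-45L, -18L),
                   YPatch = c(-50L, 50L),
                   CA = c(-35L, -1L),
                   GA = c(-35L, 75L))
  )
}

## window an element must be planted inside (octamer window where one exists,
## since those are the narrower constraint; motif window for Inr)
element_plant_windows <- function() {
  w <- default_scan_windows()
  list(TATA = w$octamer$TATA, YPatch = w$octamer$YPatch,
       Inr = w$motif$Inr, CA = w$octamer$CA, GA = w$octamer$GA)
}

#' Default TSS-relative planting start per element
#'
#' @return named integer vector of start positions (no-zero convention).
#' @export
default_plant_starts <- function() {
  c(TATA = -31L, YPatch = -30L, Inr = -3L, CA = -20L, GA = 40L)
}

#' Expand a TSS-relative start into the positions of a planted element
#'
#' Returns `len` consecutive TSS-relative positions beginning at `start`,
#' skipping 0 (there is no position 0: -1 abuts the TSS, +1 is the TSS base).
#'
#' @param start TSS-relative start position (nonzero).
#' @param len element length in bases.
#' @return integer vector of length `len`.
#' @export
tss_positions <- function(start, len = 8L) {
  if (start == 0L) stop("TSS-relative position 0 does not exist")
  cand <- seq.int(start, start + len)
  cand <- cand[cand != 0L]
  cand[seq_len(len)]
}

## map TSS-relative positions to genomic coordinates
tss_to_genomic <- function(pos, tss, strand) {
  if (strand == "+") {
    ifelse(pos < 0L, tss + pos, tss + pos - 1L)
  } else {
    ifelse(pos < 0L, tss - pos, tss - pos + 1L)
  }
}
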