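## Core promoter labeling: PWM motif scan in fixed TSS-relative windows with
## a relative-score threshold, positional octamer presence scan, and the
## either-method-positive combination rule.

## TSS-relative position of the i-th base of a window whose realized start
## is `from` (no-zero convention)
rel_position <- function(from, i) {
  p <- from + i - 1L
  if (from < 0L && p >= 0L) p <- p + 1L
  p
}

#' PWM motif scan of one promoter
#'
#' Materializes each element's TSS-relative window with [window_sequence()],
#' scores it with [pwm_relative_score()], and flags the element present when
#' the best relative score strictly exceeds `threshold`. Promoters whose
#' intergenic region is shorter than `min_intergenic` are unscannable: all
#' flags are NA.
#'
#' @param p a [promoter_sequence()].
#' @param pwms named list of [pwm()] objects (typically TATA, YPatch, Inr).
#' @param windows scan windows as in [default_scan_windows()].
#' @param threshold relative-score threshold (default 0.85, strict >).
#' @param min_intergenic minimum intergenic length for scanning (100 bp).
#' @return data.frame with one row per element: `element`, `flag`,
#'   `best_score`, `best_at` (TSS-relative start of the best window).
#' @export
motif_scan <- function(p, pwms, windows = default_scan_windows(),
                       threshold = 0.85, min_intergenic = 100L) {
  els <- names(pwms)
  if (p$intergenic_length < min_intergenic) {
    return(data.frame(element = els, flag = NA, best_score = NA_real_,
                      best_at = NA_integer_, stringsAsFactors = FALSE))
  }
  out <- lapply(els, function(el) {
    w <- windows$motif[[el]]
    if (is.null(w)) stop("no motif window for element ", el)
    s <- window_sequence(p, w[1L], w[2L])
    res <- pwm_relative_score(pwms[[el]], as.character(s))
    at <- if (is.na(res$offset)) NA_integer_ else
      rel_position(attr(s, "from"), res$offset)
    data.frame(element = el, flag = !is.na(res$score) && res$score > threshold,
               best_score = res$score, best_at = at, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Positional octamer scan of one promoter
#'
#' Flags an element present when at least one of its listed 8-mers occurs
#' with all 8 bases inside the element's TSS-relative window. All matches
#' are reported with their TSS-relative starts.
#'
#' @param p a [promoter_sequence()].
#' @param octamers named list of 8-mer character vectors (TATA, YPatch, CA,
#'   GA).
#' @param windows scan windows as in [default_scan_windows()].
#' @param min_intergenic minimum intergenic length for scanning (100 bp).
#' @return data.frame with one row per element: `element`, `flag`, `matches`
#'   (comma-separated `octamer@position`, "" when none).
#' @export
octamer_scan <- function(p, octamers, windows = default_scan_windows(),
                         min_intergenic = 100L) {
  els <- names(octamers)
  if (p$intergenic_length < min_intergenic) {
    return(data.frame(element = els, flag = NA, matches = NA_character_,
                      stringsAsFactors = FALSE))
  }
  out <- lapply(els, function(el) {
    w <- windows$octamer[[el]]
    if (is.null(w)) stop("no octamer window for element ", el)
    s <- window_sequence(p, w[1L], w[2L])
    seq <- as.character(s)
    hits <- character()
    if (nchar(seq) >= 8L) {
      for (oct in octamers[[el]]) {
        m <- gregexpr(oct, seq, fixed = TRUE)[[1L]]
        if (m[1L] != -1L) {
          hits <- c(hits, sprintf("%s@%d", oct,
                                  vapply(as.integer(m), function(o)
                                    rel_position(attr(s, "from"), o), 0L)))
        }
      }
    }
    data.frame(element = el, flag = length(hits) > 0L,
               matches = paste(hits, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Combine motif and octamer flags into a core promoter label
#'
#' An element is present if either method returned a positive result. The
#' promoter class is TATA if the combined TATA flag is true, else YPatch if
#' the combined Y patch flag is true, else Coreless; unscannable promoters
#' (intergenic < 100 bp) are Unscannable regardless of flags.
#'
#' @param motif data.frame from [motif_scan()].
#' @param octamer data.frame from [octamer_scan()].
#' @param scannable logical: was the promoter scannable?
#' @return list with `combined` (named logical per element) and `class`.
#' @export
combine_labels <- function(motif, octamer, scannable = TRUE) {
  els <- union(motif$element, octamer$element)
  combined <- vapply(els, function(el) {
    m <- motif$flag[motif$element == el]
    o <- octamer$flag[octamer$element == el]
    isTRUE(any(c(m, o), na.rm = TRUE))
  }, logical(1L))
  names(combined) <- els
  cls <- if (!scannable) "Unscannable"
         else if (isTRUE(combined["TATA"])) "TATA"
         else if (isTRUE(combined["YPatch"])) "YPatch"
         else "Coreless"
  list(combined = combined, class = cls)
}

#' Label a table of promoters by core promoter type
#'
#' Runs [motif_scan()], [octamer_scan()] and [combine_labels()] over every
#' row of a promoter table.
#'
#' @param promoters data.frame from [extract_promoters()].
#' @param pwms named list of [pwm()] objects.
#' @param octamers named list of octamer vectors.
#' @param windows scan windows (default [default_scan_windows()]).
#' @param threshold motif relative-score threshold (default 0.85).
#' @param min_intergenic minimum intergenic length for scanning (100 bp).
#' @return data.frame with, per transcript: per-element motif flag, best
#'   score and position (`motif_<el>`, `motif_<el>_score`,
#'   `motif_<el>_at`), per-element octamer flag and matches (`oct_<el>`,
#'   `oct_<el>_matches`), combined flags (`comb_<el>`), and `class`
#'   (TATA | YPatch | Coreless | Unscannable).
#' @export
scan_promoters <- function(promoters, pwms, octamers,
                           windows = default_scan_windows(),
                           threshold = 0.85, min_intergenic = 100L) {
  rows <- lapply(seq_len(nrow(promoters)), function(i) {
    p <- as_promoter(promoters[i, , drop = FALSE])
    scannable <- p$intergenic_length >= min_intergenic
    m <- motif_scan(p, pwms, windows, threshold, min_intergenic)
    o <- octamer_scan(p, octamers, windows, min_intergenic)
    lab <- combine_labels(m, o, scannable)
    row <- list(transcript = p$transcript,
                intergenic_length = p$intergenic_length)
    for (j in seq_len(nrow(m))) {
      el <- m$element[j]
      row[[paste0("motif_", el)]] <- m$flag[j]
      row[[paste0("motif_", el, "_score")]] <- m$best_score[j]
      row[[paste0("motif_", el, "_at")]] <- m$best_at[j]
    }
    for (j in seq_len(nrow(o))) {
      el <- o$element[j]
      row[[paste0("oct_", el)]] <- o$flag[j]
      row[[paste0("oct_", el, "_matches")]] <- o$matches[j]
    }
    for (el in names(lab$combined)) {
      row[[paste0("comb_", el)]] <- unname(lab$combined[el])
    }
    row$class <- lab$class
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
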