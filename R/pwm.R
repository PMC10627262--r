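## Position weight matrices: JASPAR-like plain-text parsing, conversion of
## frequency/count matrices to log-odds, and min-max-normalized relative
## scoring of sequences.

#' Construct a position weight matrix
#'
#' @param name element name (e.g. TATA, YPatch, Inr).
#' @param weights 4 x L numeric matrix with rownames A, C, G, T. Matrices
#'   with only non-negative entries are taken as counts/frequencies and
#'   converted to log2 odds against `background`; matrices with negative
#'   entries are taken as log-odds already.
#' @param background nucleotide background for the log-odds conversion
#'   (default uniform).
#' @return object of class `pwm`.
#' @export
pwm <- function(name, weights, background = c(A = .25, C = .25, G = .25, T = .25)) {
  weights <- as.matrix(weights)
  if (is.null(rownames(weights))) rownames(weights) <- c("A", "C", "G", "T")
  weights <- weights[c("A", "C", "G", "T"), , drop = FALSE]
  if (ncol(weights) < 2L) stop("a PWM needs at least 2 positions")
  if (anyNA(weights)) stop("every position needs all four weights")
  if (all(weights >= 0)) {
    freq <- sweep(weights, 2L, colSums(weights), "/")
    if (any(freq == 0)) freq <- sweep(weights + 1e-4, 2L,
                                      colSums(weights + 1e-4), "/")
    bg <- unname(background[c("A", "C", "G", "T")])
    weights <- log2(freq / bg)
  }
  structure(list(name = name, weights = weights), class = "pwm")
}

#' Read a PWM from a JASPAR-like plain-text file
#'
#' Expected layout: a `>name` header line followed by four rows
#' `A [ 5 85 ... ]` (brackets optional), one per nucleotide.
#'
#' @param path file path.
#' @param background nucleotide background passed to [pwm()].
#' @return a `pwm` object.
#' @export
read_pwm <- function(path, background = c(A = .25, C = .25, G = .25, T = .25)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- grep("^>", lines)
  name <- if (length(header)) sub("^>\\s*(\\S+).*", "\\1", lines[header[1L]])
          else tools::file_path_sans_ext(basename(path))
  rows <- grep("^[ACGT]\\b", trimws(lines), value = TRUE)
  if (length(rows) != 4L) stop("PWM file must have one row per nucleotide: ", path)
  parse_row <- function(x) {
    vals <- gsub("[][]", " ", sub("^[ACGT]", "", trimws(x)))
    as.numeric(strsplit(trimws(vals), "\\s+")[[1L]])
  }
  w <- t(vapply(rows, parse_row, parse_row(rows[1L])))
  rownames(w) <- substr(trimws(rows), 1L, 1L)
  pwm(name, w, background)
}

#' Best min-max relative PWM score over a sequence
#'
#' Scores every forward-strand offset of the PWM along the sequence: the raw
#' score is the sum of per-position weights for the window's bases, and the
#' relative score rescales it by the PWM's attainable range,
#' `(raw - min) / (max - min)`, so 1 is the per-position argmax chain and 0
#' the argmin chain. Offsets whose window contains a non-ACGT base are
#' skipped.
#'
#' @param pwm a [pwm()] object.
#' @param seq character sequence.
#' @return list with `score` (best relative score in `[0, 1]`, NA when no
#'   offset is scorable) and `offset` (1-based start of the best window).
#' @export
pwm_relative_score <- function(pwm, seq) {
  W <- pwm$weights
  K <- ncol(W)
  idx <- match(strsplit(seq, "")[[1L]], c("A", "C", "G", "T"))
  n <- length(idx)
  if (n < K) return(list(score = NA_real_, offset = NA_integer_))
  mins <- apply(W, 2L, min)
  maxs <- apply(W, 2L, max)
  lo <- sum(mins); hi <- sum(maxs)
  best <- -Inf; best_off <- NA_integer_
  for (o in seq_len(n - K + 1L)) {
    ids <- idx[o:(o + K - 1L)]
    if (anyNA(ids)) next
    raw <- sum(W[cbind(ids, seq_len(K))])
    rel <- (raw - lo) / (hi - lo)
    if (rel > best) { best <- rel; best_off <- o }
  }
  if (is.infinite(best)) return(list(score = NA_real_, offset = NA_integer_))
  list(score = best, offset = best_off)
}

#' Read an octamer list file
#'
#' One 8-mer per line; blank lines and `#` comments ignored. Any entry whose
#' length is not exactly 8 is a configuration error.
#'
#' @param path file path.
#' @return character vector of 8-mers.
#' @export
read_octamers <- function(path) {
  x <- trimws(readLines(path))
  x <- toupper(x[nzchar(x) & !startsWith(x, "#")])
  bad <- x[nchar(x) != 8L | !grepl("^[ACGT]+$", x)]
  if (length(bad)) {
    stop("malformed octamers in ", path, ": ", paste(bad, collapse = ", "))
  }
  x
}

#' Load the example motif files shipped with the package
#'
#' Returns the synthetic example PWMs (TATA, YPatch, Inr) and octamer lists
#' (TATA, YPatch, CA, GA) bundled under `inst/extdata`. These are built
#' around [element_consensus()] and exist so the pipeline runs end to end on
#' synthetic genomes; scans of real promoters should use motif files from a
#' curated source via `pwm_dir` / `octamer_dir` arguments.
#'
#' @param pwm_dir,octamer_dir directories of PWM and octamer files; default
#'   to the bundled examples.
#' @return list with `pwms` (named list of `pwm`) and `octamers` (named list
#'   of character vectors).
#' @export
load_motif_library <- function(pwm_dir = system.file("extdata", "pwm", package = "promstab"),
                               octamer_dir = system.file("extdata", "octamers", package = "promstab")) {
  pwm_files <- list.files(pwm_dir, pattern = "\\.(pwm|txt)$", full.names = TRUE)
  pwms <- lapply(pwm_files, read_pwm)
  names(pwms) <- vapply(pwms, `[[`, "", "name")
  oct_files <- list.files(octamer_dir, pattern = "\\.txt$", full.names = TRUE)
  octamers <- lapply(oct_files, read_octamers)
  names(octamers) <- tools::file_path_sans_ext(basename(oct_files))
  list(pwms = pwms, octamers = octamers)
}
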