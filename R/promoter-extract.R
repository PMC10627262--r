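## TSS-anchored promoter extraction from GFF3 + FASTA: intergenic upstream
## sequence (to the nearest annotated gene boundary on either strand, capped)
## and annotated 5'UTR, both in transcript orientation.

#' Load transcript models from a GFF3 annotation
#'
#' Transcripts are mRNA features with `Parent` gene attributes; 1-based
#' closed coordinates per the GFF3 standard. When a transcript lacks
#' five_prime_UTR features its UTR is empty (no inference from CDS).
#'
#' @param gff3 path to a GFF3 file, or a GFF3-style features data.frame as
#'   produced by [simulate_genome()].
#' @return list with `transcripts` (transcript, gene, chrom, strand, start,
#'   end), `utr5` (named list of start/end interval data.frames per
#'   transcript) and `genes` (gene, chrom, start, end).
#' @export
transcript_models <- function(gff3) {
  if (is.character(gff3)) {
    gr <- rtracklayer::import(gff3)
    f <- as.data.frame(gr)
    feats <- data.frame(seqid = as.character(f$seqnames), type = as.character(f$type),
                        start = f$start, end = f$end,
                        strand = as.character(f$strand),
                        id = as.character(f$ID %||% NA_character_),
                        parent = vapply(f$Parent, function(p)
                          if (length(p)) as.character(p[[1L]]) else NA_character_, ""),
                        stringsAsFactors = FALSE)
  } else {
    att <- function(a, key) {
      m <- regmatches(a, regexec(paste0(key, "=([^;]+)"), a))
      vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, "")
    }
    feats <- data.frame(seqid = gff3$seqid, type = gff3$type,
                        start = gff3$start, end = gff3$end,
                        strand = gff3$strand,
                        id = att(gff3$attributes, "ID"),
                        parent = att(gff3$attributes, "Parent"),
                        stringsAsFactors = FALSE)
  }
  strip <- function(x) sub("^(gene|transcript|mRNA):", "", x)

  g <- feats[feats$type == "gene", , drop = FALSE]
  genes <- data.frame(gene = strip(g$id), chrom = g$seqid,
                      start = g$start, end = g$end, strand = g$strand,
                      stringsAsFactors = FALSE)
  m <- feats[feats$type == "mRNA", , drop = FALSE]
  if (any(!m$strand %in% c("+", "-"))) {
    stop("transcript with unknown strand: ",
         paste(strip(m$id)[!m$strand %in% c("+", "-")], collapse = ", "))
  }
  transcripts <- data.frame(transcript = strip(m$id), gene = strip(m$parent),
                            chrom = m$seqid, strand = m$strand,
                            start = m$start, end = m$end,
                            stringsAsFactors = FALSE)
  u <- feats[feats$type == "five_prime_UTR", , drop = FALSE]
  utr5 <- lapply(seq_len(nrow(transcripts)), function(i) {
    ui <- u[strip(u$parent) == transcripts$transcript[i], , drop = FALSE]
    data.frame(start = ui$start, end = ui$end)
  })
  names(utr5) <- transcripts$transcript
  list(transcripts = transcripts, utr5 = utr5, genes = genes)
}

#' Transcription start site of a transcript
#'
#' The annotated transcript 5' end: the span start on the plus strand, the
#' span end on the minus strand.
#'
#' @param strand "+" or "-".
#' @param start,end 1-based closed transcript span.
#' @return genomic coordinate of the TSS.
#' @export
find_tss <- function(strand, start, end) {
  if (!strand %in% c("+", "-")) stop("unknown strand: ", strand)
  if (strand == "+") start else end
}

## distance from the TSS to the nearest annotated gene boundary on the 5'
## side (either strand, own gene excluded); chromosome edge truncates
intergenic_distance <- function(tss, strand, chrom, own_gene, genes, chrom_len) {
  g <- genes[genes$chrom == chrom & genes$gene != own_gene, , drop = FALSE]
  if (strand == "+") {
    ends <- g$end[g$end < tss]
    if (length(ends)) tss - max(ends) - 1L else tss - 1L
  } else {
    starts <- g$start[g$start > tss]
    if (length(starts)) min(starts) - tss - 1L else chrom_len - tss
  }
}

#' Extract the upstream intergenic sequence of a transcript
#'
#' Runs from `min(max_len, distance to the nearest upstream gene boundary)`
#' bases upstream of the TSS to the base adjacent to it (position -1), in
#' transcript orientation (reverse-complemented for minus-strand genes) and
#' truncated at the chromosome edge.
#'
#' @param genome named character vector of chromosome sequences.
#' @param tx one-row transcript data.frame (chrom, strand, start, end, gene).
#' @param genes gene table from [transcript_models()].
#' @param max_len upstream cap in bp (default 2000).
#' @return list with `seq` and `intergenic_length`.
#' @export
extract_upstream <- function(genome, tx, genes, max_len = 2000L) {
  chrom_seq <- genome[[tx$chrom]]
  if (is.null(chrom_seq)) stop("genome lacks chromosome ", tx$chrom)
  chrom_len <- nchar(chrom_seq)
  tss <- find_tss(tx$strand, tx$start, tx$end)
  dist <- intergenic_distance(tss, tx$strand, tx$chrom, tx$gene, genes, chrom_len)
  L <- min(max_len, dist)
  if (L <= 0L) return(list(seq = "", intergenic_length = max(dist, 0L)))
  if (tx$strand == "+") {
    s <- substr(chrom_seq, tss - L, tss - 1L)
  } else {
    s <- revcomp(substr(chrom_seq, tss + 1L, tss + L))
  }
  list(seq = s, intergenic_length = dist)
}

#' Extract a transcript's 5'UTR sequence
#'
#' Concatenates the five_prime_UTR intervals in transcript order (ascending
#' genomic order on the plus strand; descending, each reverse-complemented,
#' on the minus strand). Empty string when no UTR is annotated.
#'
#' @param genome named character vector of chromosome sequences.
#' @param tx one-row transcript data.frame.
#' @param utr data.frame of start/end intervals (possibly zero rows).
#' @return character UTR sequence.
#' @export
extract_utr5 <- function(genome, tx, utr) {
  if (is.null(utr) || nrow(utr) == 0L) return("")
  chrom_seq <- genome[[tx$chrom]]
  if (tx$strand == "+") {
    utr <- utr[order(utr$start), , drop = FALSE]
    paste(substr(rep(chrom_seq, nrow(utr)), utr$start, utr$end), collapse = "")
  } else {
    utr <- utr[order(utr$start, decreasing = TRUE), , drop = FALSE]
    paste(vapply(seq_len(nrow(utr)), function(i)
      revcomp(substr(chrom_seq, utr$start[i], utr$end[i])), ""), collapse = "")
  }
}

#' TSS-anchored promoter sequence pair
#'
#' @param transcript transcript id.
#' @param upstream intergenic sequence, 5'->3' in transcript orientation,
#'   ending at position -1.
#' @param utr5 5'UTR sequence starting at position +1.
#' @param intergenic_length full intergenic distance in bp (>= nchar(upstream)
#'   when the upstream cap truncated the sequence).
#' @return object of class `promoter_sequence`.
#' @export
promoter_sequence <- function(transcript, upstream, utr5,
                              intergenic_length = nchar(upstream)) {
  stopifnot(grepl("^[ACGTN]*$", upstream), grepl("^[ACGTN]*$", utr5))
  structure(list(transcript = transcript, upstream = upstream, utr5 = utr5,
                 intergenic_length = as.integer(intergenic_length)),
            class = "promoter_sequence")
}

#' Slice a promoter in TSS-relative coordinates
#'
#' Positions follow the no-zero convention: -1 is the base immediately
#' upstream of the TSS, +1 the first transcribed base. Bases beyond the
#' available upstream or UTR sequence are clipped; the realized bounds are
#' attached as attributes `from` and `to` (NA when the window is empty).
#'
#' @param p a [promoter_sequence()].
#' @param from,to TSS-relative window bounds, `from < to`, neither 0.
#' @return the window sequence (possibly shorter than requested, possibly "").
#' @export
window_sequence <- function(p, from, to) {
  stopifnot(inherits(p, "promoter_sequence"), from != 0L, to != 0L, from < to)
  Lu <- nchar(p$upstream)
  Ld <- nchar(p$utr5)
  up <- ""
  down <- ""
  r_from <- NA_integer_; r_to <- NA_integer_
  if (from <= -1L) {
    a <- max(from, -Lu)
    b <- min(to, -1L)
    if (a <= b) {
      up <- substr(p$upstream, Lu + a + 1L, Lu + b + 1L)
      r_from <- a; r_to <- b
    }
  }
  if (to >= 1L) {
    a <- max(from, 1L)
    b <- min(to, Ld)
    if (a <= b) {
      down <- substr(p$utr5, a, b)
      if (is.na(r_from)) r_from <- a
      r_to <- b
    }
  }
  structure(paste0(up, down), from = r_from, to = r_to)
}

#' Extract promoters for all (or a subsample of) transcripts
#'
#' @param genome named character vector of chromosome sequences (or a FASTA
#'   path).
#' @param annotation GFF3 path or features data.frame (see
#'   [transcript_models()]).
#' @param max_upstream upstream cap in bp.
#' @param subsample_fraction fraction of transcripts to keep (uniformly at
#'   random without replacement; default 1 keeps all).
#' @param seed seed for the subsample.
#' @return data.frame with columns `transcript`, `intergenic_length`,
#'   `upstream_seq`, `utr5_seq`.
#' @export
extract_promoters <- function(genome, annotation, max_upstream = 2000L,
                              subsample_fraction = 1, seed = 1L) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  mod <- transcript_models(annotation)
  tx <- mod$transcripts
  if (subsample_fraction < 1) {
    keep <- subsample_transcripts(tx$transcript, subsample_fraction, seed)
    tx <- tx[tx$transcript %in% keep, , drop = FALSE]
  }
  out <- lapply(seq_len(nrow(tx)), function(i) {
    t1 <- tx[i, , drop = FALSE]
    up <- extract_upstream(genome, t1, mod$genes, max_upstream)
    u5 <- extract_utr5(genome, t1, mod$utr5[[t1$transcript]])
    data.frame(transcript = t1$transcript,
               intergenic_length = up$intergenic_length,
               upstream_seq = up$seq, utr5_seq = u5,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## one-row promoter table entry -> promoter_sequence
as_promoter <- function(row) {
  promoter_sequence(row$transcript, row$upstream_seq, row$utr5_seq,
                    row$intergenic_length)
}
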