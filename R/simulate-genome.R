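## Synthetic genome generator: i.i.d. background at a chosen GC fraction,
## non-overlapping genes on both strands, annotated 5'UTRs, and core promoter
## elements planted at window-correct TSS-relative positions.

#' Specification for a synthetic genome
#'
#' @param n_genes number of genes.
#' @param chrom_length chromosome length in bp, or NULL to size automatically
#'   from the gene layout.
#' @param strand_fraction fraction of genes placed on the minus strand.
#' @param intergenic_spacing `c(min, max)` bp of intergenic gap sampled
#'   uniformly upstream of each gene. The minimum must accommodate the
#'   deepest planted element and the 100 bp scannability rule.
#' @param utr5_length `c(min, max)` bp of annotated 5'UTR per transcript.
#' @param body_length transcript length beyond the 5'UTR.
#' @param gc_background GC fraction of the i.i.d. background sequence
#'   (default 0.36, typical of plant intergenic DNA).
#' @param element_plan data.frame with columns `gene` (1-based index),
#'   `element` (TATA | YPatch | Inr | CA | GA | none) and `start`
#'   (TSS-relative start of the planted 8-mer), or NULL for no planting.
#'   See [default_plant_starts()] for window-correct defaults.
#' @param chrom_name chromosome name.
#' @param seed integer seed; equal specs with equal seeds give byte-identical
#'   output files.
#' @return object of class `genome_spec`.
#' @export
genome_spec <- function(n_genes, chrom_length = NULL, strand_fraction = 0.5,
                        intergenic_spacing = c(150L, 400L),
                        utr5_length = c(60L, 120L), body_length = 300L,
                        gc_background = 0.36, element_plan = NULL,
                        chrom_name = "chr1", seed = 1L) {
  stopifnot(is_count(n_genes), strand_fraction >= 0, strand_fraction <= 1,
            length(intergenic_spacing) == 2L,
            intergenic_spacing[1L] <= intergenic_spacing[2L],
            intergenic_spacing[1L] >= 1L,
            length(utr5_length) == 2L, utr5_length[1L] <= utr5_length[2L],
            gc_background > 0, gc_background < 1)
  if (!is.null(element_plan)) {
    stopifnot(all(c("gene", "element", "start") %in% names(element_plan)))
    bad <- setdiff(element_plan$element, c(CORE_ELEMENTS, "none"))
    if (length(bad)) stop("unknown elements in plan: ", paste(bad, collapse = ", "))
    if (any(element_plan$gene < 1L | element_plan$gene > n_genes)) {
      stop("element_plan references genes outside 1..n_genes")
    }
    plant <- element_plan[element_plan$element != "none", , drop = FALSE]
    win <- element_plant_windows()
    for (i in seq_len(nrow(plant))) {
      pos <- tss_positions(plant$start[i])
      w <- win[[plant$element[i]]]
      if (min(pos) < w[1L] || max(pos) > w[2L]) {
        stop(sprintf("planted %s at %d..%d lies outside its window (%d, %d)",
                     plant$element[i], min(pos), max(pos), w[1L], w[2L]))
      }
    }
  }
  structure(list(n_genes = as.integer(n_genes), chrom_length = chrom_length,
                 strand_fraction = strand_fraction,
                 intergenic_spacing = as.integer(intergenic_spacing),
                 utr5_length = as.integer(utr5_length),
                 body_length = as.integer(body_length),
                 gc_background = gc_background, element_plan = element_plan,
                 chrom_name = chrom_name, seed = as.integer(seed)),
            class = "genome_spec")
}

## i.i.d. background with the requested GC fraction
random_background <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sample(names(p), n, replace = TRUE, prob = p)
}

#' Simulate a genome with planted core promoter elements
#'
#' Lays out non-overlapping genes left to right on one chromosome with
#' uniformly sampled intergenic gaps, draws an i.i.d. background sequence at
#' the requested GC fraction, and overwrites planted element octamers at
#' their TSS-relative positions, reverse-complemented for minus-strand genes.
#' Each gene carries one transcript with a single exon and an annotated
#' 5'UTR beginning at the TSS.
#'
#' @param spec a [genome_spec()].
#' @return object of class `synthetic_genome`: a list with `sequence` (named
#'   character, one chromosome), `features` (GFF3-style data.frame),
#'   `transcripts` (id, gene, chrom, strand, start, end, tss, utr5_length),
#'   `truth` (planted elements: transcript, element, start_rel, end_rel,
#'   octamer) and `spec`.
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  consensus <- element_consensus()

  if (n == 0L) {
    len <- spec$chrom_length %||% 1000L
    seqs <- paste(random_background(len, spec$gc_background), collapse = "")
    names(seqs) <- spec$chrom_name
    empty_tx <- data.frame(transcript = character(), gene = character(),
                           chrom = character(), strand = character(),
                           start = integer(), end = integer(), tss = integer(),
                           utr5_length = integer(), stringsAsFactors = FALSE)
    empty_truth <- data.frame(transcript = character(), element = character(),
                              start_rel = integer(), end_rel = integer(),
                              octamer = character(), stringsAsFactors = FALSE)
    return(structure(list(sequence = seqs,
                          features = gff_features(empty_tx),
                          transcripts = empty_tx, truth = empty_truth,
                          spec = spec),
                     class = "synthetic_genome"))
  }

  gaps <- sample(seq.int(spec$intergenic_spacing[1L], spec$intergenic_spacing[2L]),
                 n + 1L, replace = TRUE)
  utr <- sample(seq.int(spec$utr5_length[1L], spec$utr5_length[2L]),
                n, replace = TRUE)
  tx_len <- utr + spec$body_length
  strand <- ifelse(stats::runif(n) < spec$strand_fraction, "-", "+")

  starts <- integer(n); ends <- integer(n)
  cursor <- 0L
  for (i in seq_len(n)) {
    starts[i] <- cursor + gaps[i] + 1L
    ends[i] <- starts[i] + tx_len[i] - 1L
    cursor <- ends[i]
  }
  needed <- cursor + gaps[n + 1L]
  len <- spec$chrom_length %||% needed
  if (len < needed) {
    stop(sprintf("chrom_length %d cannot fit %d genes with the requested spacing (need %d bp)",
                 len, n, needed))
  }

  bases <- random_background(len, spec$gc_background)
  gene_id <- sprintf("G%04d", seq_len(n))
  tx_id <- paste0(gene_id, ".t1")
  tss <- ifelse(strand == "+", starts, ends)

  truth <- NULL
  plan <- spec$element_plan
  if (!is.null(plan)) {
    plan <- plan[plan$element != "none", , drop = FALSE]
    for (i in seq_len(nrow(plan))) {
      g <- plan$gene[i]
      oct <- consensus[[plan$element[i]]]
      pos <- tss_positions(plan$start[i], nchar(oct))
      gpos <- tss_to_genomic(pos, tss[g], strand[g])
      if (any(gpos < 1L | gpos > len)) {
        stop("planted element falls off the chromosome for gene ", g)
      }
      eb <- strsplit(oct, "")[[1L]]
      if (strand[g] == "-") eb <- chartr("ACGT", "TGCA", eb)
      bases[gpos] <- eb
      truth <- rbind(truth, data.frame(
        transcript = tx_id[g], element = plan$element[i],
        start_rel = min(pos), end_rel = max(pos), octamer = oct,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(truth)) {
    truth <- data.frame(transcript = character(), element = character(),
                        start_rel = integer(), end_rel = integer(),
                        octamer = character(), stringsAsFactors = FALSE)
  }

  seqs <- paste(bases, collapse = "")
  names(seqs) <- spec$chrom_name
  transcripts <- data.frame(
    transcript = tx_id, gene = gene_id, chrom = spec$chrom_name,
    strand = strand, start = starts, end = ends, tss = tss,
    utr5_length = utr, stringsAsFactors = FALSE)

  structure(list(sequence = seqs, features = gff_features(transcripts),
                 transcripts = transcripts, truth = truth, spec = spec),
            class = "synthetic_genome")
}

## GFF3 feature table (1-based closed intervals) for single-exon transcripts
gff_features <- function(tx) {
  if (nrow(tx) == 0L) {
    return(data.frame(seqid = character(), source = character(),
                      type = character(), start = integer(), end = integer(),
                      score = character(), strand = character(),
                      phase = character(), attributes = character(),
                      stringsAsFactors = FALSE))
  }
  utr_start <- ifelse(tx$strand == "+", tx$start, tx$end - tx$utr5_length + 1L)
  utr_end <- ifelse(tx$strand == "+", tx$start + tx$utr5_length - 1L, tx$end)
  row <- function(type, s, e, attr) {
    data.frame(seqid = tx$chrom, source = "promstab", type = type,
               start = s, end = e, score = ".", strand = tx$strand,
               phase = ".", attributes = attr, stringsAsFactors = FALSE)
  }
  feats <- rbind(
    row("gene", tx$start, tx$end, sprintf("ID=gene:%s", tx$gene)),
    row("mRNA", tx$start, tx$end,
        sprintf("ID=transcript:%s;Parent=gene:%s", tx$transcript, tx$gene)),
    row("exon", tx$start, tx$end,
        sprintf("ID=exon:%s.1;Parent=transcript:%s", tx$transcript, tx$transcript)),
    row("five_prime_UTR", utr_start, utr_end,
        sprintf("ID=utr5:%s.1;Parent=transcript:%s", tx$transcript, tx$transcript))
  )
  ## stable order: by start, then a fixed type precedence
  type_rank <- c(gene = 1L, mRNA = 2L, exon = 3L, five_prime_UTR = 4L)
  feats[order(feats$start, type_rank[feats$type]), , drop = FALSE]
}

#' Write a synthetic genome to disk
#'
#' Emits `genome.fa` (60-column FASTA), `annotation.gff3` (GFF3 v3) and
#' `elements_truth.tsv` under `outdir`.
#'
#' @param sim a `synthetic_genome` from [simulate_genome()].
#' @param outdir output directory (created if needed).
#' @return named character vector of the three paths, invisibly.
#' @export
write_genome <- function(sim, outdir) {
  stopifnot(inherits(sim, "synthetic_genome"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(outdir, "genome.fa")
  gff <- file.path(outdir, "annotation.gff3")
  truth <- file.path(outdir, "elements_truth.tsv")
  write_fasta(sim$sequence, fa)
  con <- file(gff, "w")
  writeLines("##gff-version 3", con)
  f <- sim$features
  if (nrow(f)) {
    writeLines(sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
                       f$seqid, f$source, f$type, f$start, f$end, f$score,
                       f$strand, f$phase, f$attributes), con)
  }
  close(con)
  write_tsv(sim$truth, truth)
  invisible(c(fasta = fa, gff3 = gff, truth = truth))
}

#' Reverse-complement a genome and remap its annotation
#'
#' Reverse-complements every chromosome and remaps feature coordinates
#' (`start' = L - end + 1`, strands flipped), yielding an equivalent genome
#' viewed from the opposite strand. Promoter extraction and scanning must be
#' invariant under this transformation.
#'
#' @param sequence named character vector of chromosome sequences.
#' @param features GFF3-style data.frame as produced by [simulate_genome()].
#' @return list with remapped `sequence` and `features`.
#' @export
reverse_complement_genome <- function(sequence, features) {
  lens <- nchar(sequence)
  rc <- revcomp(sequence)
  names(rc) <- names(sequence)
  f <- features
  if (nrow(f)) {
    L <- lens[f$seqid]
    s <- L - f$end + 1L
    e <- L - f$start + 1L
    f$start <- as.integer(s)
    f$end <- as.integer(e)
    f$strand <- ifelse(f$strand == "+", "-", ifelse(f$strand == "-", "+", f$strand))
    type_rank <- c(gene = 1L, mRNA = 2L, exon = 3L, five_prime_UTR = 4L)
    f <- f[order(f$seqid, f$start, type_rank[f$type]), , drop = FALSE]
  }
  list(sequence = rc, features = f)
}
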