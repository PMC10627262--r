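## Synthetic tissue atlas: negative-binomial counts around designed per-gene,
## per-sample means, with per-sample library-size distortion.

#' Specification for a synthetic tissue atlas
#'
#' Emulates a bulk RNA-seq tissue atlas: at least 10 tissue samples spanning
#' at least 2 developmental stages, with each gene designed to be either
#' uniformly expressed (same expected level everywhere) or conditionally
#' expressed (full level in a few tissues, near-zero elsewhere).
#'
#' @param n_tissues number of tissue samples (>= 10).
#' @param n_stages number of developmental stages (>= 2); tissues are
#'   assigned to stages round-robin in the metadata.
#' @param gene_classes character vector, one of "uniform", "conditional" or
#'   "intermediate" per gene. Intermediate genes express at full level in
#'   half of the tissues: their CVs fall between the uniform and conditional
#'   blocks, emulating the continuum of tissue specificity in real atlases.
#' @param expressing_tissues for conditional genes, the number of tissues in
#'   which they express at full level (recycled per conditional gene).
#' @param base_mean expected count scale in expressing samples.
#' @param off_mean expected count in a conditional gene's non-expressing
#'   tissues (default 0.1: near zero, but allowing occasional nonzero draws).
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives the noise-free limit where counts equal
#'   the rounded means.
#' @param library_size_factors per-sample multiplicative distortions, or NULL
#'   to draw them log-normally (sdlog 0.2) at simulation time.
#' @param seed integer seed.
#' @return object of class `atlas_spec`.
#' @export
atlas_spec <- function(n_tissues = 12L, n_stages = 2L, gene_classes,
                       expressing_tissues = 3L, base_mean = 100,
                       off_mean = 0.1, dispersion = 0.05,
                       library_size_factors = NULL, seed = 1L) {
  stopifnot(is_count(n_tissues), n_tissues >= 10L,
            is_count(n_stages), n_stages >= 2L,
            all(gene_classes %in% c("uniform", "conditional", "intermediate")))
  if (base_mean <= 0) stop("base_mean must be positive")
  if (dispersion < 0) stop("dispersion must be non-negative")
  if (!is.null(library_size_factors)) {
    if (length(library_size_factors) != n_tissues) {
      stop("need one library size factor per sample")
    }
    if (any(library_size_factors <= 0)) {
      stop("library size factors must be strictly positive")
    }
  }
  structure(list(n_tissues = as.integer(n_tissues),
                 n_stages = as.integer(n_stages),
                 gene_classes = gene_classes,
                 expressing_tissues = as.integer(expressing_tissues),
                 base_mean = base_mean, off_mean = off_mean,
                 dispersion = dispersion,
                 library_size_factors = library_size_factors,
                 seed = as.integer(seed)),
            class = "atlas_spec")
}

#' Simulate a count atlas with designed uniform and conditional genes
#'
#' Draws negative-binomial counts around per-gene, per-sample means: uniform
#' genes have mean `base_mean` in every sample; conditional genes have mean
#' `base_mean` in their (randomly chosen) expressing tissues and `off_mean`
#' elsewhere. Each sample's means are multiplied by its library size factor
#' before sampling. At `dispersion = 0` counts are the rounded means.
#'
#' @param spec an [atlas_spec()].
#' @param transcript_ids optional transcript ids (default T0001...); length
#'   must match `gene_classes`.
#' @return list with `counts` (matrix, transcripts x samples), `metadata`
#'   (sample, tissue, stage), `truth` (transcript, class, n_expressing),
#'   `size_factors` (the planted distortions) and `spec`.
#' @export
simulate_counts <- function(spec, transcript_ids = NULL) {
  stopifnot(inherits(spec, "atlas_spec"))
  set.seed(spec$seed)
  n_genes <- length(spec$gene_classes)
  ids <- transcript_ids %||% sprintf("T%04d", seq_len(n_genes))
  if (length(ids) != n_genes) stop("transcript_ids length must match gene_classes")
  ns <- spec$n_tissues
  samples <- sprintf("S%02d", seq_len(ns))
  sf <- spec$library_size_factors %||% stats::rlnorm(ns, 0, 0.2)

  mu <- matrix(spec$base_mean, n_genes, ns, dimnames = list(ids, samples))
  n_expr <- rep(ns, n_genes)
  for (g in which(spec$gene_classes != "uniform")) {
    k <- if (spec$gene_classes[g] == "conditional") {
      min(spec$expressing_tissues, ns)
    } else {
      max(1L, ns %/% 2L)   # intermediate: half the tissues
    }
    on <- sample.int(ns, k)
    mu[g, -on] <- spec$off_mean
    n_expr[g] <- k
  }
  mu <- sweep(mu, 2L, sf, "*")

  if (spec$dispersion == 0) {
    counts <- round(mu)
  } else {
    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                    size = 1 / spec$dispersion),
                     n_genes, ns, dimnames = dimnames(mu))
  }

  metadata <- data.frame(
    sample = samples,
    tissue = sprintf("tissue%02d", seq_len(ns)),
    stage = sprintf("stage%d", ((seq_len(ns) - 1L) %% spec$n_stages) + 1L),
    stringsAsFactors = FALSE)
  truth <- data.frame(transcript = ids, class = spec$gene_classes,
                      n_expressing = n_expr, stringsAsFactors = FALSE)
  list(counts = counts, metadata = metadata, truth = truth,
       size_factors = stats::setNames(sf, samples), spec = spec)
}

#' Write a simulated atlas to disk
#'
#' Emits `counts.tsv`, `metadata.tsv`, `class_truth.tsv` and
#' `size_factors_truth.tsv` under `outdir`.
#'
#' @param atlas result of [simulate_counts()].
#' @param outdir output directory.
#' @return named character vector of paths, invisibly.
#' @export
write_atlas <- function(atlas, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(outdir, "counts.tsv"),
             metadata = file.path(outdir, "metadata.tsv"),
             truth = file.path(outdir, "class_truth.tsv"),
             size_factors = file.path(outdir, "size_factors_truth.tsv"))
  write_count_matrix(atlas$counts, paths["counts"])
  write_tsv(atlas$metadata, paths["metadata"])
  write_tsv(atlas$truth, paths["truth"])
  write_tsv(data.frame(sample = names(atlas$size_factors),
                       size_factor = unname(atlas$size_factors),
                       stringsAsFactors = FALSE),
            paths["size_factors"])
  invisible(paths)
}
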