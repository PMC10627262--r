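## End-to-end orchestration: simulate -> stability -> extract -> scan ->
## orthologs -> report, from one config and one master seed, with every
## intermediate artifact written to disk as plain text.

#' Default pipeline configuration
#'
#' Returns the full configuration tree for [run_all()]; any subset can be
#' overridden via a YAML file or a nested list. The defaults describe a
#' desk-scale study: a 200-gene query genome at GC 0.36 with TATA boxes
#' planted in 70% of conditional and 20% of uniform genes, a 12-tissue /
#' 2-stage atlas (negative-binomial, dispersion 0.05), and an 8-species
#' ortholog family of 40 groups (10 switched within one clade, 10 switched
#' across the tree, 20 unswitched) at dispersion 0.02.
#'
#' @return nested list of settings.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    genome = list(n_genes = 200L, gc_background = 0.36, strand_fraction = 0.5,
                  intergenic_spacing = c(150L, 400L), utr5_length = c(60L, 120L),
                  tata_conditional = 0.7, tata_uniform = 0.2,
                  ypatch_other = 0.3),
    atlas = list(n_tissues = 12L, n_stages = 2L, conditional_fraction = 0.5,
                 expressing_tissues = 3L, base_mean = 100, dispersion = 0.05),
    family = list(
      tree = "(((sp1,sp2),(sp3,sp4)),((sp5,sp6),(sp7,sp8)));",
      n_clade = 10L, n_scattered = 10L, n_none = 20L, n_background = 120L,
      n_tissues = 12L, n_stages = 2L, base_mean = 100, dispersion = 0.02,
      expressing_tissues = 3L, scan_promoters = TRUE,
      recovery = list(uniform = 0.9, conditional = 0.5)),
    extract = list(max_upstream = 2000L, subsample_fraction = 1.0),
    scan = list(threshold = 0.85, min_intergenic = 100L),
    orthologs = list(boundary = 0.5, min_switched = 2L,
                     consistency_threshold = 0.5, fraction = 0.05),
    report = list(bins = 20L)
  )
}

## deep-merge user overrides into the defaults
merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror [default_config()]; missing keys keep their defaults.
#'
#' @param path YAML file path.
#' @return full configuration list.
#' @export
read_config <- function(path) {
  merge_config(default_config(), yaml::read_yaml(path))
}

## element plan assigning TATA preferentially to conditional genes, Y patch
## to a fraction of the rest
plan_elements <- function(classes, cfg, seed) {
  set.seed(seed)
  n <- length(classes)
  starts <- default_plant_starts()
  p_tata <- ifelse(classes == "conditional", cfg$tata_conditional, cfg$tata_uniform)
  tata <- stats::runif(n) < p_tata
  ypatch <- !tata & stats::runif(n) < cfg$ypatch_other
  el <- rep("none", n)
  el[tata] <- "TATA"
  el[ypatch] <- "YPatch"
  data.frame(gene = seq_len(n), element = el,
             start = unname(ifelse(el == "none", NA_integer_, starts[el])),
             stringsAsFactors = FALSE)[el != "none" | TRUE, ]
}

## rename the generator's default gene ids to caller-supplied ones
rename_genome_genes <- function(sim, gene_ids) {
  stopifnot(length(gene_ids) == nrow(sim$transcripts))
  old_tx <- sim$transcripts$transcript
  sim$transcripts$gene <- gene_ids
  sim$transcripts$transcript <- paste0(gene_ids, ".t1")
  sim$truth$transcript <- sim$transcripts$transcript[match(sim$truth$transcript, old_tx)]
  sim$features <- gff_features(sim$transcripts)
  sim
}

## one species' worth of genome + atlas + stability + labels
simulate_species_stage <- function(classes, gene_ids, genome_cfg, atlas_cfg,
                                   scan_cfg, extract_cfg, motifs, seed) {
  plan <- plan_elements(classes, genome_cfg, derive_seed(seed, "elements"))
  gspec <- genome_spec(
    n_genes = length(classes),
    strand_fraction = genome_cfg$strand_fraction,
    intergenic_spacing = genome_cfg$intergenic_spacing,
    utr5_length = genome_cfg$utr5_length,
    gc_background = genome_cfg$gc_background,
    element_plan = plan[plan$element != "none", , drop = FALSE],
    seed = derive_seed(seed, "genome"))
  sim <- rename_genome_genes(simulate_genome(gspec), gene_ids)
  aspec <- atlas_spec(n_tissues = atlas_cfg$n_tissues,
                      n_stages = atlas_cfg$n_stages,
                      gene_classes = classes,
                      expressing_tissues = atlas_cfg$expressing_tissues,
                      base_mean = atlas_cfg$base_mean,
                      dispersion = atlas_cfg$dispersion,
                      seed = derive_seed(seed, "atlas"))
  atlas <- simulate_counts(aspec, transcript_ids = sim$transcripts$transcript)
  stab <- stability_table(atlas$counts, atlas$metadata)
  promoters <- extract_promoters(sim$sequence, sim$features,
                                 max_upstream = extract_cfg$max_upstream,
                                 subsample_fraction = extract_cfg$subsample_fraction,
                                 seed = derive_seed(seed, "subsample"))
  labels <- scan_promoters(promoters, motifs$pwms, motifs$octamers,
                           threshold = scan_cfg$threshold,
                           min_intergenic = scan_cfg$min_intergenic)
  list(genome = sim, atlas = atlas, stability = stab,
       promoters = promoters, labels = labels)
}

#' Run the whole pipeline from one configuration
#'
#' Executes simulate, stability, extract, scan, orthologs and report in
#' order, writing every intermediate and final artifact as TSV/JSON under
#' `outdir`. Two runs from the same configuration and seed produce
#' byte-identical outputs.
#'
#' @param config configuration list (see [default_config()]) or a YAML path.
#' @param outdir output directory.
#' @param seed master seed; every stage derives its own stream from it.
#' @param quiet suppress stage messages.
#' @return (invisibly) a list with the in-memory results of every stage.
#' @export
run_all <- function(config = default_config(), outdir, seed = config$seed,
                    quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  cfg <- merge_config(default_config(), config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  motifs <- load_motif_library()

  ## --- query species: genome, atlas, stability, promoters, labels -------
  say("[simulate] query genome + atlas (%d genes)", cfg$genome$n_genes)
  n <- cfg$genome$n_genes
  classes <- rep(c("uniform", "conditional"),
                 times = c(n - round(cfg$atlas$conditional_fraction * n),
                           round(cfg$atlas$conditional_fraction * n)))
  query <- simulate_species_stage(classes, sprintf("G%04d", seq_len(n)),
                                  cfg$genome, cfg$atlas, cfg$scan,
                                  cfg$extract, motifs,
                                  derive_seed(seed, "query"))
  write_genome(query$genome, file.path(outdir, "query"))
  write_atlas(query$atlas, file.path(outdir, "query"))
  write_tsv(query$stability, file.path(outdir, "query", "stability.tsv"))
  write_tsv(query$promoters, file.path(outdir, "query", "promoters.tsv"))
  write_tsv(query$labels, file.path(outdir, "query", "labels.tsv"))

  say("[report] CV distribution by promoter class")
  dist <- cv_distribution_by_class(query$labels, query$stability,
                                   cfg$report$bins)
  sets <- select_gene_sets(query$stability, cfg$orthologs$fraction,
                           seed = derive_seed(seed, "sets"))

  ## --- ortholog family --------------------------------------------------
  say("[simulate] %d-group ortholog family",
      cfg$family$n_clade + cfg$family$n_scattered + cfg$family$n_none)
  plan <- plan_switches(cfg$family$tree, cfg$family$n_clade,
                        cfg$family$n_scattered, cfg$family$n_none,
                        seed = derive_seed(seed, "switch-plan"))
  fspec <- family_spec(cfg$family$tree,
                       n_groups = length(plan$switched),
                       switched = plan$switched,
                       clade_concentrated = plan$clade_concentrated,
                       n_background = cfg$family$n_background,
                       recovery = unlist(cfg$family$recovery),
                       n_tissues = cfg$family$n_tissues,
                       n_stages = cfg$family$n_stages,
                       base_mean = cfg$family$base_mean,
                       dispersion = cfg$family$dispersion,
                       expressing_tissues = cfg$family$expressing_tissues,
                       seed = derive_seed(seed, "family"))
  fam <- simulate_family(fspec)
  write_family(fam, file.path(outdir, "family"))

  say("[stability] per-species stability tables")
  fam_stab <- lapply(fam$atlases, function(a) stability_table(a$counts, a$metadata))
  for (sp in names(fam_stab)) {
    write_tsv(fam_stab[[sp]], file.path(outdir, "family", sp, "stability.tsv"))
  }

  fam_labels <- NULL
  if (isTRUE(cfg$family$scan_promoters)) {
    say("[extract+scan] per-species family promoters")
    fam_labels <- do.call(rbind, lapply(names(fam$atlases), function(sp) {
      a <- fam$atlases[[sp]]
      classes <- a$truth$class
      gene_ids <- sub("\\.t1$", "", a$truth$transcript)
      plan <- plan_elements(classes, cfg$genome,
                            derive_seed(seed, paste0("fam-el-", sp)))
      gspec <- genome_spec(
        n_genes = length(classes),
        strand_fraction = cfg$genome$strand_fraction,
        intergenic_spacing = cfg$genome$intergenic_spacing,
        utr5_length = cfg$genome$utr5_length,
        gc_background = cfg$genome$gc_background,
        element_plan = plan[plan$element != "none", , drop = FALSE],
        chrom_name = paste0(sp, "_chr1"),
        seed = derive_seed(seed, paste0("fam-genome-", sp)))
      sim <- rename_genome_genes(simulate_genome(gspec), gene_ids)
      write_genome(sim, file.path(outdir, "family", sp))
      prom <- extract_promoters(sim$sequence, sim$features,
                                max_upstream = cfg$extract$max_upstream)
      lab <- scan_promoters(prom, motifs$pwms, motifs$octamers,
                            threshold = cfg$scan$threshold,
                            min_intergenic = cfg$scan$min_intergenic)
      write_tsv(lab, file.path(outdir, "family", sp, "labels.tsv"))
      data.frame(species = sp, transcript = lab$transcript,
                 promoter_class = lab$class, stringsAsFactors = FALSE)
    }))
  }

  say("[orthologs] switch cascade")
  cascade <- ortholog_switch_analysis(
    fam$ortholog_table, fam_stab, fam$tree, fspec$query_species,
    boundary = cfg$orthologs$boundary,
    min_switched = cfg$orthologs$min_switched,
    consistency_threshold = cfg$orthologs$consistency_threshold,
    member_counts = fam$member_counts)
  write_tsv(cascade$groups, file.path(outdir, "family", "groups.tsv"))
  write_tsv(cascade$members, file.path(outdir, "family", "members.tsv"))

  say("[report] recovery rates + ANOVA/Tukey")
  qtruth <- fam$truth
  fam_sets <- list(
    uniform = qtruth$query_transcript[qtruth$query_class == "uniform"],
    conditional = qtruth$query_transcript[qtruth$query_class == "conditional"])
  set.seed(derive_seed(seed, "random-set"))
  fam_sets$random <- sample(qtruth$query_transcript,
                            min(lengths(fam_sets[1:2])))
  recovery <- ortholog_recovery(fam_sets, fam$ortholog_table,
                                setdiff(fspec$species, fspec$query_species))
  anova <- anova_tukey(recovery)

  ## per-group report: members with percentiles, tertiles and labels
  members <- cascade$members
  members$cv_tertile <- tertile_bins(members$cv_percentile)
  members$exp_tertile <- tertile_bins(members$geo_mean_percentile)
  if (!is.null(fam_labels)) {
    members$promoter_class <- fam_labels$promoter_class[
      match(paste(members$species, members$transcript),
            paste(fam_labels$species, fam_labels$transcript))]
  }
  retained <- cascade$groups[cascade$groups$retained, , drop = FALSE]
  group_report <- lapply(retained$query_transcript, function(q) {
    m <- members[members$query_transcript == q, , drop = FALSE]
    list(query = q,
         members = m[, setdiff(colnames(m), "query_transcript")],
         switched = m$species[m$switched],
         consistency = retained$consistency[retained$query_transcript == q])
  })

  report <- list(
    class_distribution = dist,
    gene_set_sizes = lengths(sets),
    recovery = recovery,
    anova = anova,
    n_groups = nrow(cascade$groups),
    n_retained = nrow(retained),
    retained_groups = retained$query_transcript,
    groups = group_report)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  write_tsv(recovery, file.path(outdir, "recovery.tsv"))
  say("[done] %d of %d groups retained", nrow(retained), nrow(cascade$groups))
  invisible(list(query = query, class_distribution = dist, sets = sets,
                 family = fam, family_stability = fam_stab,
                 cascade = cascade, recovery = recovery, anova = anova,
                 report = report, config = cfg))
}
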