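## Synthetic ortholog families: one gene per species per group, each species
## with its own simulated tissue atlas, and expression-pattern switches
## (uniform <-> conditional) planted in chosen species sets on a phylogeny.

#' Specification for a synthetic multi-species ortholog family
#'
#' @param tree species phylogeny: an [ape::phylo] object or a Newick string.
#'   Tip labels are the species names.
#' @param n_groups number of orthologous gene groups.
#' @param switched list of length `n_groups`; each entry the character vector
#'   of target species whose group member gets the class opposite to the
#'   query's (may be empty). See [plan_switches()] for a tree-aware builder.
#' @param clade_concentrated logical vector, the designed truth of whether
#'   each group's switched set is concentrated in one clade.
#' @param query_class character vector of the query gene's class per group
#'   ("uniform"/"conditional"); defaults to alternating.
#' @param query_species the query species (default: first tip label).
#' @param n_background filler genes per species atlas anchoring the
#'   CV-percentile scale: equal uniform and conditional blocks plus a
#'   one-sixth intermediate block (genes expressing in half the tissues)
#'   that keeps the 50th percentile strictly between the uniform and
#'   conditional CV ranges.
#' @param duplications optional data.frame (`group`, `species`) planting a
#'   1:many ortholog (a second target gene) for filter testing.
#' @param recovery named numeric: probability that a non-switched target
#'   species has an ortholog row for a group, by query class (default 1 for
#'   both); switched species are always present.
#' @param n_tissues,n_stages,base_mean,dispersion,expressing_tissues atlas
#'   parameters passed to [atlas_spec()] for every species.
#' @param seed integer seed.
#' @return object of class `family_spec`.
#' @export
family_spec <- function(tree, n_groups,
                        switched = vector("list", n_groups),
                        clade_concentrated = logical(n_groups),
                        query_class = NULL, query_species = NULL,
                        n_background = 120L, duplications = NULL,
                        recovery = c(uniform = 1, conditional = 1),
                        n_tissues = 12L, n_stages = 2L, base_mean = 100,
                        dispersion = 0.05, expressing_tissues = 3L,
                        seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), is_count(n_groups),
            length(switched) == n_groups,
            length(clade_concentrated) == n_groups)
  species <- tree$tip.label
  if (anyDuplicated(species)) stop("tree tip labels must be unique")
  query_species <- query_species %||% species[1L]
  if (!query_species %in% species) stop("query_species must be a tree tip")
  for (sw in switched) {
    unknown <- setdiff(sw, species)
    if (length(unknown)) {
      stop("switch plan references unknown species: ",
           paste(unknown, collapse = ", "))
    }
    if (query_species %in% sw) stop("the query species cannot be switched")
  }
  query_class <- query_class %||%
    rep(c("uniform", "conditional"), length.out = n_groups)
  stopifnot(all(query_class %in% c("uniform", "conditional")),
            length(query_class) == n_groups)
  structure(list(tree = tree, species = species, n_groups = as.integer(n_groups),
                 switched = switched,
                 clade_concentrated = as.logical(clade_concentrated),
                 query_class = query_class, query_species = query_species,
                 n_background = as.integer(n_background),
                 duplications = duplications, recovery = recovery,
                 n_tissues = as.integer(n_tissues),
                 n_stages = as.integer(n_stages), base_mean = base_mean,
                 dispersion = dispersion,
                 expressing_tissues = as.integer(expressing_tissues),
                 seed = as.integer(seed)),
            class = "family_spec")
}

#' Plan clade-concentrated and scattered switch sets on a tree
#'
#' Builds a switch plan of `n_clade` groups switched in the two leaves of a
#' cherry (sister pair) not containing the query species, `n_scattered`
#' groups switched in two species whose most recent common ancestor is the
#' root (so the switches are spread across the tree), and `n_none` groups
#' with no switches.
#'
#' @param tree species phylogeny ([ape::phylo] or Newick string).
#' @param n_clade,n_scattered,n_none group counts per category.
#' @param query_species species excluded from switch sets (default first tip).
#' @param seed integer seed.
#' @return list with `switched` (list of species vectors) and
#'   `clade_concentrated` (logical), ordered clade, scattered, none.
#' @export
plan_switches <- function(tree, n_clade, n_scattered, n_none,
                          query_species = NULL, seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  set.seed(seed)
  species <- tree$tip.label
  query_species <- query_species %||% species[1L]
  root <- ape::Ntip(tree) + 1L

  ## cherries: internal nodes with exactly two tip children
  cherries <- list()
  for (node in unique(tree$edge[, 1L])) {
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    if (all(kids <= ape::Ntip(tree)) && length(kids) == 2L) {
      pair <- species[kids]
      if (!query_species %in% pair) cherries[[length(cherries) + 1L]] <- pair
    }
  }
  if (n_clade > 0L && !length(cherries)) {
    stop("tree has no cherry free of the query species")
  }
  ## scattered pairs: MRCA at the root
  others <- setdiff(species, query_species)
  scattered_pairs <- list()
  if (n_scattered > 0L) {
    combs <- utils::combn(others, 2L, simplify = FALSE)
    for (p in combs) {
      if (ape::getMRCA(tree, p) == root) {
        scattered_pairs[[length(scattered_pairs) + 1L]] <- p
      }
    }
    if (!length(scattered_pairs)) stop("tree has no root-spanning pair")
  }

  switched <- c(
    lapply(seq_len(n_clade),
           function(i) cherries[[((i - 1L) %% length(cherries)) + 1L]]),
    lapply(seq_len(n_scattered),
           function(i) scattered_pairs[[((i - 1L) %% length(scattered_pairs)) + 1L]]),
    rep(list(character()), n_none)
  )
  list(switched = switched,
       clade_concentrated = rep(c(TRUE, FALSE, FALSE),
                                c(n_clade, n_scattered, n_none)))
}

#' Simulate a multi-species ortholog family with planted switches
#'
#' For every species a tissue atlas is simulated over the family genes plus
#' background filler genes. In each group, species in the switch set receive
#' the gene class opposite to the query's; everyone else inherits the
#' query's class. The ortholog table links the query transcript to exactly
#' one target gene per species, except where the spec plants 1:many
#' duplications.
#'
#' @param spec a [family_spec()].
#' @return list with `ortholog_table` (query_transcript, species,
#'   target_gene, target_transcript), `atlases` (named list per species, as
#'   [simulate_counts()]), `tree`, `truth` (group, query_transcript,
#'   switched, n_switched, clade_concentrated), `member_counts` (one row per
#'   group x species with gene-tree member counts) and `spec`.
#' @export
simulate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  species <- spec$species
  qs <- spec$query_species
  ng <- spec$n_groups
  set.seed(derive_seed(spec$seed, "family-plan"))

  gene_id <- function(sp, g, suffix = "") sprintf("%s_G%03d%s", sp, g, suffix)
  tx_of <- function(gene) paste0(gene, ".t1")

  ## per-species per-group class
  class_mat <- matrix(rep(spec$query_class, each = length(species)),
                      nrow = length(species),
                      dimnames = list(species, NULL))
  for (g in seq_len(ng)) {
    flip <- spec$switched[[g]]
    opp <- if (spec$query_class[g] == "uniform") "conditional" else "uniform"
    class_mat[flip, g] <- opp
  }

  ## presence of ortholog rows (query species always carries its own gene)
  present <- matrix(TRUE, length(species), ng, dimnames = list(species, NULL))
  for (g in seq_len(ng)) {
    p <- spec$recovery[[spec$query_class[g]]] %||% 1
    for (sp in setdiff(species, c(qs, spec$switched[[g]]))) {
      present[sp, g] <- stats::runif(1) < p
    }
  }

  dup <- spec$duplications
  atlases <- list()
  rows <- list()
  for (sp in species) {
    genes <- character(); classes <- character()
    for (g in seq_len(ng)) {
      if (!present[sp, g]) next
      genes <- c(genes, gene_id(sp, g))
      classes <- c(classes, class_mat[sp, g])
      if (!is.null(dup) && sp != qs &&
          any(dup$group == g & dup$species == sp)) {
        genes <- c(genes, gene_id(sp, g, "b"))
        classes <- c(classes, class_mat[sp, g])
      }
    }
    ## background fillers anchor the CV-percentile scale: mostly uniform and
    ## conditional in equal measure, plus an intermediate block (expressing
    ## in half the tissues) so the 50th percentile falls strictly between
    ## the uniform and conditional CV blocks rather than on their boundary
    nb <- spec$n_background
    n_mid <- round(nb / 6)
    n_uni <- (nb - n_mid + 1L) %/% 2L
    bg_genes <- gene_id(sp, ng + seq_len(nb))
    bg_classes <- rep(c("uniform", "intermediate", "conditional"),
                      c(n_uni, n_mid, nb - n_mid - n_uni))
    all_genes <- c(genes, bg_genes)
    aspec <- atlas_spec(n_tissues = spec$n_tissues, n_stages = spec$n_stages,
                        gene_classes = c(classes, bg_classes),
                        expressing_tissues = spec$expressing_tissues,
                        base_mean = spec$base_mean,
                        dispersion = spec$dispersion,
                        seed = derive_seed(spec$seed, paste0("atlas-", sp)))
    atlases[[sp]] <- simulate_counts(aspec, transcript_ids = tx_of(all_genes))
  }

  for (g in seq_len(ng)) {
    qtx <- tx_of(gene_id(qs, g))
    for (sp in setdiff(species, qs)) {
      if (!present[sp, g]) next
      tg <- gene_id(sp, g)
      rows[[length(rows) + 1L]] <- data.frame(
        query_transcript = qtx, species = sp, target_gene = tg,
        target_transcript = tx_of(tg), stringsAsFactors = FALSE)
      if (!is.null(dup) && any(dup$group == g & dup$species == sp)) {
        tg2 <- gene_id(sp, g, "b")
        rows[[length(rows) + 1L]] <- data.frame(
          query_transcript = qtx, species = sp, target_gene = tg2,
          target_transcript = tx_of(tg2), stringsAsFactors = FALSE)
      }
    }
  }
  ortholog_table <- do.call(rbind, rows)

  truth <- data.frame(
    group = seq_len(ng),
    query_transcript = tx_of(gene_id(qs, seq_len(ng))),
    query_class = spec$query_class,
    switched = vapply(spec$switched, paste, "", collapse = ","),
    n_switched = lengths(spec$switched),
    clade_concentrated = spec$clade_concentrated,
    stringsAsFactors = FALSE)

  member_counts <- do.call(rbind, lapply(seq_len(ng), function(g) {
    sp <- species[present[, g]]
    n <- rep(1L, length(sp))
    if (!is.null(dup)) {
      n[sp %in% dup$species[dup$group == g]] <- 2L
    }
    data.frame(query_transcript = tx_of(gene_id(qs, g)), species = sp,
               n_members = n, stringsAsFactors = FALSE)
  }))

  list(ortholog_table = ortholog_table, atlases = atlases, tree = spec$tree,
       truth = truth, member_counts = member_counts, spec = spec)
}

#' Write a simulated ortholog family to disk
#'
#' Emits `ortholog_table.tsv`, `tree.nwk`, `family_truth.tsv`,
#' `member_counts.tsv` and one atlas directory per species under `outdir`.
#'
#' @param fam result of [simulate_family()].
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_family <- function(fam, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(fam$ortholog_table, file.path(outdir, "ortholog_table.tsv"))
  ape::write.tree(fam$tree, file.path(outdir, "tree.nwk"))
  write_tsv(fam$truth, file.path(outdir, "family_truth.tsv"))
  write_tsv(fam$member_counts, file.path(outdir, "member_counts.tsv"))
  for (sp in names(fam$atlases)) {
    write_atlas(fam$atlases[[sp]], file.path(outdir, sp))
  }
  invisible(outdir)
}
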