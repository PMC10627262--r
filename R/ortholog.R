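## Ortholog expression-switch cascade: CV-rank gene-set selection, transcript
## resolution, 1:many removal, 50th-percentile switch detection, and clade
## consistency on a species phylogeny.

#' Select uniform, conditional and random control gene sets by CV rank
#'
#' From the filtered transcripts of a stability table: the lowest-CV
#' fraction (uniform), the highest-CV fraction (conditional), and an
#' equally sized uniform random control set. Set size is
#' `ceiling(fraction * n)`.
#'
#' @param stab stability table from [stability_table()].
#' @param fraction tail fraction, in (0, 1) (default 0.05).
#' @param seed seed for the random control set.
#' @return list of character vectors `uniform`, `conditional`, `random`.
#' @export
select_gene_sets <- function(stab, fraction = 0.05, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  kept <- stab[stab$passes_filter & !is.na(stab$cv), , drop = FALSE]
  n <- nrow(kept)
  k <- ceiling(fraction * n)
  ord <- order(kept$cv, kept$transcript)
  uniform <- kept$transcript[ord][seq_len(k)]
  conditional <- kept$transcript[rev(ord)][seq_len(k)]
  set.seed(seed)
  random <- sample(kept$transcript, k)
  list(uniform = uniform, conditional = conditional, random = random)
}

#' Pick the highest-expressing transcript of a gene
#'
#' Expression is summarized as the geometric mean of normalized counts
#' (`geo_mean` in the stability table); exact ties break to the
#' lexicographically smaller transcript id.
#'
#' @param candidates transcript ids of one gene.
#' @param stab stability table holding `geo_mean` per transcript.
#' @return the chosen transcript id, or NA when no candidate has data.
#' @export
pick_highest_expressing <- function(candidates, stab) {
  g <- stab$geo_mean[match(candidates, stab$transcript)]
  ok <- !is.na(g)
  if (!any(ok)) return(NA_character_)
  candidates <- candidates[ok]; g <- g[ok]
  candidates[order(-g, candidates)][1L]
}

#' Remove 1:many ortholog pairs
#'
#' For every (query, species) pair matched to more than one target gene,
#' all rows of that pair are removed; the query's rows for other species are
#' retained.
#'
#' @param table ortholog table with columns `query_transcript`, `species`,
#'   `target_gene`.
#' @return the filtered table.
#' @export
drop_multi_orthologs <- function(table) {
  key <- paste(table$query_transcript, table$species, sep = "\r")
  n_genes <- tapply(table$target_gene, key, function(x) length(unique(x)))
  multi <- names(n_genes)[n_genes > 1L]
  table[!key %in% multi, , drop = FALSE]
}

#' Has an ortholog switched expression pattern?
#'
#' TRUE iff the query and target CV percentiles lie on strictly opposite
#' sides of the boundary (default the 50th percentile). A target exactly at
#' the boundary is not a switch.
#'
#' @param query_percentile,target_percentile CV percentile ranks in (0, 1].
#' @param boundary crossing boundary (default 0.5).
#' @return logical.
#' @export
detect_switch <- function(query_percentile, target_percentile, boundary = 0.5) {
  (query_percentile - boundary) * (target_percentile - boundary) < 0
}

#' Keep groups switched in enough species
#'
#' @param groups data.frame with an `n_switched` column.
#' @param min_switched minimum number of switched target species (default 2).
#' @return the retained rows.
#' @export
filter_switch_groups <- function(groups, min_switched = 2L) {
  groups[groups$n_switched >= min_switched, , drop = FALSE]
}

#' Clade consistency of a switched species set
#'
#' Quantifies how concentrated the switched species are within one clade:
#' the number of switched species divided by the number of present species
#' descending from their most recent common ancestor. A singleton set scores
#' 1; an empty set is undefined (NA score, flag FALSE).
#'
#' @param tree species phylogeny ([ape::phylo] or Newick string).
#' @param switched character vector of switched species.
#' @param present character vector of species present in the group
#'   (`switched` must be a subset).
#' @param threshold consistency threshold for the flag (default 0.5).
#' @return list with `score` in `[0, 1]` (or NA) and `consistent` flag.
#' @export
clade_consistency <- function(tree, switched, present, threshold = 0.5) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!all(switched %in% present)) stop("switched species must be present")
  if (!all(present %in% tree$tip.label)) stop("present species must be tree leaves")
  if (length(switched) == 0L) return(list(score = NA_real_, consistent = FALSE))
  if (length(switched) == 1L) return(list(score = 1, consistent = 1 >= threshold))
  mrca <- ape::getMRCA(tree, switched)
  clade_tips <- if (mrca == ape::Ntip(tree) + 1L) tree$tip.label
                else ape::extract.clade(tree, mrca)$tip.label
  denom <- length(intersect(clade_tips, present))
  score <- length(switched) / denom
  list(score = score, consistent = score >= threshold)
}

#' Enforce a 1:1 relationship from gene-tree member counts
#'
#' Species contributing more than one member to the group's gene tree are
#' removed; the group is dropped entirely when fewer than `min_switched`
#' switched species remain.
#'
#' @param members data.frame of group members with columns `species` and
#'   `switched` (logical).
#' @param counts named integer vector of gene-tree member counts per species
#'   (species absent from `counts` are assumed single-copy).
#' @param min_switched minimum surviving switched species (default 2).
#' @return the trimmed members data.frame, or NULL when the group is dropped.
#' @export
enforce_one_to_one <- function(members, counts, min_switched = 2L) {
  n <- unname(counts[members$species])
  n[is.na(n)] <- 1L
  out <- members[n <= 1L, , drop = FALSE]
  if (sum(out$switched) < min_switched) return(NULL)
  out
}

#' Run the full ortholog switch cascade
#'
#' Resolves each (query, species, gene) to its highest-expressing
#' transcript, removes 1:many ortholog pairs, joins CV percentiles from the
#' per-species stability tables, detects expression-pattern switches
#' (crossing the `boundary` percentile), keeps groups switched in at least
#' `min_switched` target species, optionally enforces 1:1 membership from
#' gene-tree member counts, and scores clade consistency on the species
#' tree. Species without expression data for a group are excluded from both
#' the switched and present sets.
#'
#' @param ortholog_table data.frame with `query_transcript`, `species`,
#'   `target_gene` and optionally `target_transcript`.
#' @param stability named list of stability tables, one per species,
#'   including the query species.
#' @param tree species phylogeny ([ape::phylo] or Newick string).
#' @param query_species name of the query species in `stability`.
#' @param boundary switch boundary on the CV percentile (default 0.5).
#' @param min_switched minimum switched target species (default 2).
#' @param consistency_threshold clade-consistency threshold (default 0.5).
#' @param member_counts optional data.frame (`query_transcript`, `species`,
#'   `n_members`) of gene-tree member counts for [enforce_one_to_one()].
#' @return list with `groups` (one row per query: `query_transcript`,
#'   `n_members`, `n_switched`, `switched`, `consistency`, `retained`) and
#'   `members` (per-member detail: species, transcript, percentiles,
#'   switched flag).
#' @export
ortholog_switch_analysis <- function(ortholog_table, stability, tree,
                                     query_species, boundary = 0.5,
                                     min_switched = 2L,
                                     consistency_threshold = 0.5,
                                     member_counts = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(query_species %in% names(stability))

  ## resolve each (query, species, gene) to one transcript
  tab <- ortholog_table
  key <- paste(tab$query_transcript, tab$species, tab$target_gene, sep = "\r")
  resolved <- do.call(rbind, lapply(split(tab, key), function(rows) {
    sp <- rows$species[1L]
    cand <- if (!is.null(rows$target_transcript) &&
                all(!is.na(rows$target_transcript))) {
      unique(rows$target_transcript)
    } else {
      stability[[sp]]$transcript[grepl(paste0("^", rows$target_gene[1L], "\\."),
                                       stability[[sp]]$transcript)]
    }
    tx <- pick_highest_expressing(cand, stability[[sp]])
    data.frame(query_transcript = rows$query_transcript[1L], species = sp,
               target_gene = rows$target_gene[1L], target_transcript = tx,
               stringsAsFactors = FALSE)
  }))
  resolved <- resolved[!is.na(resolved$target_transcript), , drop = FALSE]
  resolved <- drop_multi_orthologs(resolved)

  qstab <- stability[[query_species]]
  members_all <- list(); groups <- list()
  for (q in unique(resolved$query_transcript)) {
    qp <- qstab$cv_percentile[match(q, qstab$transcript)]
    if (is.na(qp)) next
    rows <- resolved[resolved$query_transcript == q, , drop = FALSE]
    mem <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
      sp <- rows$species[i]
      st <- stability[[sp]]
      j <- match(rows$target_transcript[i], st$transcript)
      data.frame(query_transcript = q, species = sp,
                 transcript = rows$target_transcript[i],
                 cv_percentile = if (is.na(j)) NA_real_ else st$cv_percentile[j],
                 geo_mean_percentile = if (is.na(j)) NA_real_ else st$geo_mean_percentile[j],
                 stringsAsFactors = FALSE)
    }))
    mem <- mem[!is.na(mem$cv_percentile), , drop = FALSE]
    if (nrow(mem) == 0L) next
    mem$switched <- detect_switch(qp, mem$cv_percentile, boundary)

    if (!is.null(member_counts)) {
      mc <- member_counts[member_counts$query_transcript == q, , drop = FALSE]
      counts <- stats::setNames(as.integer(mc$n_members), mc$species)
      mem <- enforce_one_to_one(mem, counts, min_switched = 0L) %||% mem[0L, ]
    }
    sw <- mem$species[mem$switched]
    cc <- clade_consistency(tree, sw,
                            union(mem$species, query_species),
                            consistency_threshold)
    groups[[q]] <- data.frame(
      query_transcript = q, query_percentile = qp, n_members = nrow(mem),
      n_switched = length(sw), switched = paste(sort(sw), collapse = ","),
      consistency = cc$score,
      retained = length(sw) >= min_switched && cc$consistent,
      stringsAsFactors = FALSE)
    members_all[[q]] <- mem
  }
  groups <- do.call(rbind, groups)
  rownames(groups) <- NULL
  list(groups = groups, members = do.call(rbind, members_all))
}
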