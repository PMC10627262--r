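test_that("gene-set sizes follow ceiling(fraction * n)", {
  set.seed(10)
  n <- 100
  cvv <- stats::setNames(runif(n), sprintf("t%03d", 1:n))
  stab <- toy_stab(cvv)
  sets <- select_gene_sets(stab, 0.05, seed = 1)
  expect_equal(lengths(sets), c(uniform = 5, conditional = 5, random = 5))
  # uniform = lowest CV, conditional = highest CV
  expect_setequal(sets$uniform, names(sort(cvv))[1:5])
  expect_setequal(sets$conditional, names(sort(cvv, decreasing = TRUE))[1:5])
  # deterministic control set
  expect_identical(sets$random, select_gene_sets(stab, 0.05, seed = 1)$random)
  expect_error(select_gene_sets(stab, 1.5), "fraction")
})

test_that("highest-expressing transcript wins, ties break lexicographically", {
  stab <- toy_stab(c(a.t1 = 0.2, a.t2 = 0.4, b.t1 = 0.1),
                   geo = c(a.t1 = 5, a.t2 = 7.5, b.t1 = 3))
  expect_equal(pick_highest_expressing(c("a.t1", "a.t2"), stab), "a.t2")
  expect_equal(pick_highest_expressing("b.t1", stab), "b.t1")
  stab2 <- toy_stab(c(x.t1 = 0.2, x.t2 = 0.4),
                    geo = c(x.t1 = 5, x.t2 = 5))
  expect_equal(pick_highest_expressing(c("x.t2", "x.t1"), stab2), "x.t1")
  expect_true(is.na(pick_highest_expressing("missing", stab)))
})

test_that("1:many pairs are removed wholesale, other species kept", {
  tab <- data.frame(
    query_transcript = c("q1", "q1", "q1", "q2"),
    species = c("s", "s", "t", "s"),
    target_gene = c("g1", "g2", "g3", "g4"))
  out <- drop_multi_orthologs(tab)
  expect_equal(nrow(out), 2)
  expect_false(any(out$query_transcript == "q1" & out$species == "s"))
  expect_true(any(out$query_transcript == "q1" & out$species == "t"))
  # no duplicates -> unchanged
  expect_equal(drop_multi_orthologs(tab[3:4, ]), tab[3:4, ],
               ignore_attr = TRUE)
})

test_that("a switch strictly crosses the boundary", {
  expect_true(detect_switch(0.03, 0.62))
  expect_true(detect_switch(0.97, 0.40))
  expect_false(detect_switch(0.03, 0.20))
  expect_false(detect_switch(0.03, 0.5))   # exactly at the boundary
  expect_false(detect_switch(0.5, 0.9))
})

test_that("groups need enough switched species to be retained", {
  g <- data.frame(id = 1:3, n_switched = c(1, 2, 0))
  expect_equal(filter_switch_groups(g)$id, 2)
  expect_equal(nrow(filter_switch_groups(g, min_switched = 0)), 3)
})

test_that("clade consistency scores switched concentration on the tree", {
  all8 <- paste0("sp", 1:8)
  # both leaves of a cherry
  cc <- clade_consistency(toy_tree, c("sp3", "sp4"), all8)
  expect_equal(cc$score, 1)
  expect_true(cc$consistent)
  # MRCA spanning the whole 8-species tree
  cc2 <- clade_consistency(toy_tree, c("sp2", "sp7"), all8)
  expect_equal(cc2$score, 0.25)
  expect_false(cc2$consistent)
  # all present species switched
  cc3 <- clade_consistency(toy_tree, all8, all8)
  expect_equal(cc3$score, 1)
  # denominator counts only present species
  cc4 <- clade_consistency(toy_tree, c("sp5", "sp7"), c("sp1", "sp5", "sp7"))
  expect_equal(cc4$score, 1)
  # singleton and empty sets
  expect_equal(clade_consistency(toy_tree, "sp2", all8)$score, 1)
  empty <- clade_consistency(toy_tree, character(), all8)
  expect_true(is.na(empty$score))
  expect_false(empty$consistent)
  expect_error(clade_consistency(toy_tree, "sp9", all8), "present")
})

test_that("1:1 enforcement removes multi-member species and cascades", {
  mem <- data.frame(species = c("s1", "s2", "s3"),
                    switched = c(TRUE, TRUE, FALSE))
  out <- enforce_one_to_one(mem, c(s2 = 2L), min_switched = 1)
  expect_equal(out$species, c("s1", "s3"))
  expect_null(enforce_one_to_one(mem, c(s2 = 2L), min_switched = 2))
  expect_equal(enforce_one_to_one(mem, c(s1 = 1L)), mem)
})

test_that("the cascade recovers planted switches and drops planted duplications", {
  plan <- plan_switches(toy_tree, n_clade = 3, n_scattered = 3, n_none = 4)
  dup <- data.frame(group = 10L, species = "sp3")
  fs <- family_spec(toy_tree, 10, plan$switched, plan$clade_concentrated,
                    n_background = 40, dispersion = 0.02,
                    duplications = dup, seed = 99)
  fam <- simulate_family(fs)
  # planted 1:many duplication -> two rows for (group 10, sp3)
  rows <- fam$ortholog_table[
    fam$ortholog_table$query_transcript == fam$truth$query_transcript[10] &
      fam$ortholog_table$species == "sp3", ]
  expect_equal(nrow(rows), 2)

  stab <- lapply(fam$atlases, function(a) stability_table(a$counts, a$metadata))
  res <- ortholog_switch_analysis(fam$ortholog_table, stab, fam$tree, "sp1",
                                  member_counts = fam$member_counts)
  retained <- res$groups$query_transcript[res$groups$retained]
  expected <- fam$truth$query_transcript[fam$truth$clade_concentrated]
  expect_setequal(retained, expected)
  # the duplicated species is absent from group 10's members
  m10 <- res$members[res$members$query_transcript ==
                       fam$truth$query_transcript[10], ]
  expect_false("sp3" %in% m10$species)
  # retained groups satisfy the contract
  for (q in retained) {
    g <- res$groups[res$groups$query_transcript == q, ]
    expect_gte(g$n_switched, 2)
    expect_gte(g$consistency, 0.5)
    m <- res$members[res$members$query_transcript == q, ]
    expect_false(any(duplicated(m$species)))
  }
})

test_that("unknown species in a switch plan is a reference error", {
  expect_error(family_spec(toy_tree, 1, list(c("spX", "sp2")), TRUE),
               "unknown species")
})
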