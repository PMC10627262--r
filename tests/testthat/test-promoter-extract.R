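test_that("the TSS is the annotated transcript 5' end", {
  expect_equal(find_tss("+", 1001, 2000), 1001)
  expect_equal(find_tss("-", 1001, 2000), 2000)
  expect_error(find_tss(".", 1, 2), "unknown strand")
})

test_that("window_sequence does TSS-relative bookkeeping with no position 0", {
  p <- promoter_sequence("t1", "ACGTT", "GGACC")
  expect_equal(as.character(window_sequence(p, -3, 2)), "GTTGG")
  expect_equal(as.character(window_sequence(p, -5, -1)), "ACGTT")
  expect_equal(as.character(window_sequence(p, 1, 5)), "GGACC")
  # clipping beyond the available sequence
  expect_equal(as.character(window_sequence(p, -100, -1)), "ACGTT")
  expect_equal(as.character(window_sequence(p, 3, 100)), "ACC")
  # empty 5'UTR
  p2 <- promoter_sequence("t2", "ACGTT", "")
  expect_equal(as.character(window_sequence(p2, 1, 10)), "")
  expect_error(window_sequence(p, 0, 5))
  # |window(-k, -1)| <= k with equality iff enough upstream
  for (k in c(2, 5, 9)) {
    w <- window_sequence(p, -k, -1)
    expect_lte(nchar(w), k)
    expect_equal(nchar(w) == k, 5 >= k)
  }
})

test_that("minus-strand two-exon UTR concatenates in transcript order", {
  # 60 bp toy genome; minus-strand transcript at 21..50, TSS = 50,
  # UTR intervals 45..50 and 31..38 (transcript order: 45..50 first)
  set.seed(1)
  chrom <- random_dna(60)
  genome <- c(chrX = chrom)
  tx <- data.frame(transcript = "m1", gene = "g1", chrom = "chrX",
                   strand = "-", start = 21, end = 50)
  utr <- data.frame(start = c(31, 45), end = c(38, 50))
  got <- extract_utr5(genome, tx, utr)
  expected <- paste0(revcomp(substr(chrom, 45, 50)),
                     revcomp(substr(chrom, 31, 38)))
  expect_identical(got, expected)
  # plus strand: ascending genomic order, no revcomp
  tx$strand <- "+"
  got_p <- extract_utr5(genome, tx, utr)
  expect_identical(got_p, paste0(substr(chrom, 31, 38), substr(chrom, 45, 50)))
  # no UTR annotated -> empty string
  expect_identical(extract_utr5(genome, tx, utr[0, ]), "")
})

test_that("upstream extraction measures intergenic distance to the nearest gene", {
  sim <- simulate_genome(genome_spec(12, seed = 21))
  prom <- extract_promoters(sim$sequence, sim$features)
  tx <- sim$transcripts
  for (i in seq_len(nrow(tx))) {
    j <- match(tx$transcript[i], prom$transcript)
    others <- tx[-i, ]
    if (tx$strand[i] == "+") {
      ends <- others$end[others$end < tx$tss[i]]
      expected <- if (length(ends)) tx$tss[i] - max(ends) - 1 else tx$tss[i] - 1
    } else {
      starts <- others$start[others$start > tx$tss[i]]
      expected <- if (length(starts)) min(starts) - tx$tss[i] - 1
                  else nchar(sim$sequence[[1]]) - tx$tss[i]
    }
    expect_equal(prom$intergenic_length[j], expected)
    expect_equal(nchar(prom$upstream_seq[j]), min(2000, expected))
    expect_equal(nchar(prom$utr5_seq[j]), tx$utr5_length[i])
  }
})

test_that("upstream is capped at max_len and truncated at the chromosome edge", {
  set.seed(2)
  chrom <- random_dna(5000)
  genome <- c(c1 = chrom)
  genes <- data.frame(gene = "g1", chrom = "c1", start = 4500, end = 4800,
                      strand = "+")
  tx <- data.frame(transcript = "t1", gene = "g1", chrom = "c1",
                   strand = "+", start = 4500, end = 4800)
  up <- extract_upstream(genome, tx, genes, max_len = 2000)
  expect_equal(up$intergenic_length, 4499)   # to chromosome start
  expect_equal(nchar(up$seq), 2000)          # capped
  expect_identical(up$seq, substr(chrom, 2500, 4499))
  # TSS at position 1 -> empty upstream
  tx1 <- data.frame(transcript = "t2", gene = "g2", chrom = "c1",
                    strand = "+", start = 1, end = 300)
  up1 <- extract_upstream(genome, tx1, genes, 2000)
  expect_equal(up1$intergenic_length, 0)
  expect_identical(up1$seq, "")
})

test_that("planted minus-strand elements appear forward in the extracted upstream", {
  plan <- data.frame(gene = 1:20, element = "TATA", start = -31L)
  sim <- simulate_genome(genome_spec(20, strand_fraction = 1,
                                     element_plan = plan, seed = 13))
  prom <- extract_promoters(sim$sequence, sim$features)
  for (i in seq_len(nrow(prom))) {
    up <- prom$upstream_seq[i]
    L <- nchar(up)
    expect_identical(substr(up, L - 31 + 1, L - 24 + 1), "TATAAATA")
  }
})

test_that("extraction is invariant under genome reverse complementation", {
  plan <- data.frame(gene = c(1:6), element = rep(c("TATA", "Inr"), 3),
                     start = rep(c(-31L, -3L), 3))
  sim <- simulate_genome(genome_spec(6, element_plan = plan, seed = 33))
  rc <- reverse_complement_genome(sim$sequence, sim$features)
  p1 <- extract_promoters(sim$sequence, sim$features)
  p2 <- extract_promoters(rc$sequence, rc$features)
  ord <- order(p1$transcript)
  expect_equal(p1[ord, ], p2[order(p2$transcript), ], ignore_attr = TRUE)
})

test_that("promoter subsampling respects the fraction deterministically", {
  sim <- simulate_genome(genome_spec(10, seed = 3))
  p1 <- extract_promoters(sim$sequence, sim$features,
                          subsample_fraction = 0.4, seed = 5)
  p2 <- extract_promoters(sim$sequence, sim$features,
                          subsample_fraction = 0.4, seed = 5)
  expect_equal(nrow(p1), 4)
  expect_identical(p1, p2)
})
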