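test_that("identical sequences collapse to one haplotype, zero segregating sites", {
  aln <- toy_alignment(rep("ACGTACGT", 4))
  hap <- collapse_haplotypes(aln)
  expect_equal(hap$n_haplotypes, 1L)
  expect_equal(hap$n_segregating_sites, 0L)
  expect_equal(sum(hap$counts), 4L)
})

test_that("hand-enumerated toy alignment: 4 haplotypes at 3 segregating sites", {
  # variants at columns 2, 5, 8 only; three distinct rows
  aln <- toy_alignment(c("AAGTACGA", "ATGTACGA", "AAGTTCGA",
                         "AAGTACGC", "AAGTACGC"))
  hap <- collapse_haplotypes(aln)
  expect_equal(hap$n_haplotypes, 4L)
  expect_equal(hap$n_segregating_sites, 3L)
})

test_that("haplotype collapsing is invariant to sample order and monotone", {
  strings <- c("ACGT", "ACGA", "ACGT", "TCGA", "ACGG")
  aln1 <- toy_alignment(strings)
  set.seed(42)
  perm <- sample(5)
  aln2 <- toy_alignment(strings[perm], ids = paste0("s", perm))
  h1 <- collapse_haplotypes(aln1)
  h2 <- collapse_haplotypes(aln2)
  expect_equal(h1$haplotype_seqs, h2$haplotype_seqs)
  expect_equal(h1$counts, h2$counts)
  # adding samples never decreases the haplotype count
  for (m in 2:5) {
    hm <- collapse_haplotypes(toy_alignment(strings[1:m]))
    expect_gte(hm$n_haplotypes,
               collapse_haplotypes(toy_alignment(strings[1:(m - 1)]))$n_haplotypes)
  }
})

test_that("gene diversity matches the closed form and the pair enumeration", {
  # monomorphic -> 0
  mono <- toy_haplotypes(matrix(c(5L), 1, 1, dimnames = list(NULL, "P1")))
  expect_equal(diversity_stats(mono)$gene_diversity, 0)
  # n = 2 distinct -> 1
  two <- toy_haplotypes(matrix(c(1L, 1L), 2, 1, dimnames = list(NULL, "P1")))
  expect_equal(diversity_stats(two)$gene_diversity, 1)
  # counts (4, 2, 2): H = (8/7)(1 - 0.375)
  h3 <- toy_haplotypes(matrix(c(4L, 2L, 2L), 3, 1, dimnames = list(NULL, "P1")))
  expect_equal(diversity_stats(h3)$gene_diversity, (8 / 7) * (1 - 0.375),
               tolerance = 1e-12)
  # brute force: H equals the fraction of unordered sample pairs that differ
  set.seed(7)
  for (rep in 1:5) {
    counts <- matrix(as.integer(rmultinom(1, sample(4:12, 1), rep(1, 4))),
                     ncol = 1, dimnames = list(NULL, "P1"))
    counts <- counts[counts[, 1] > 0, , drop = FALSE]
    n <- sum(counts)
    if (n < 2) next
    labels <- rep(seq_len(nrow(counts)), counts[, 1])
    pairs <- combn(n, 2)
    frac_diff <- mean(labels[pairs[1, ]] != labels[pairs[2, ]])
    expect_equal(diversity_stats(counts_tab <- toy_haplotypes(counts))$gene_diversity,
                 frac_diff, tolerance = 1e-12)
  }
})

test_that("rarefied allelic richness matches exhaustive subset enumeration", {
  counts <- matrix(c(4L, 2L, 1L), 3, 1, dimnames = list(NULL, "P1"))
  g <- 4
  hap <- toy_haplotypes(counts)
  got <- diversity_stats(hap, rarefaction_size = g)$allelic_richness
  # oracle: average distinct haplotypes over all C(7, 4) subsamples
  labels <- rep(seq_len(3), counts[, 1])
  subs <- combn(7, g)
  oracle <- mean(apply(subs, 2, function(ix) length(unique(labels[ix]))))
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("populations of size one are flagged with undefined diversity", {
  counts <- matrix(c(1L, 0L, 3L, 2L), 2, 2,
                   dimnames = list(NULL, c("P1", "P2")))
  ds <- diversity_stats(counts_tab <- toy_haplotypes(counts),
                        rarefaction_size = 1)
  expect_true(ds$flag_small_n[ds$population == "P1"])
  expect_true(is.na(ds$gene_diversity[ds$population == "P1"]))
})

test_that("differentiation is zero for identical populations, one for fixed differences", {
  same <- toy_haplotypes(matrix(c(3L, 3L, 3L, 3L), 2, 2,
                                dimnames = list(NULL, c("P1", "P2"))))
  d0 <- differentiation_stats(same, variant = "plug_in")
  expect_equal(d0$gst, 0)
  expect_equal(d0$gst_hedrick, 0)
  expect_equal(d0$jost_d, 0)
  # each population fixed for its own haplotype: Hs = 0, Ht = 0.5, D = 1
  fixed <- toy_haplotypes(matrix(c(4L, 0L, 0L, 4L), 2, 2,
                                 dimnames = list(NULL, c("P1", "P2"))))
  d1 <- differentiation_stats(fixed, variant = "plug_in")
  expect_equal(d1$hs, 0)
  expect_equal(d1$ht, 0.5)
  expect_equal(d1$gst, 1)
  expect_equal(d1$jost_d, 1)
})

test_that("both pops monomorphic for the same haplotype give flagged zeros", {
  mono <- toy_haplotypes(matrix(c(4L, 6L), 1, 2,
                                dimnames = list(NULL, c("P1", "P2"))))
  d <- differentiation_stats(mono)
  expect_true(d$flag_monomorphic)
  expect_equal(d$gst, 0)
  expect_equal(d$jost_d, 0)
})

test_that("differentiation matches independent hand evaluation of the formulas", {
  # counts pop1 = (6, 2), pop2 = (1, 7)
  counts <- matrix(c(6L, 2L, 1L, 7L), 2, 2,
                   dimnames = list(NULL, c("P1", "P2")))
  hap <- toy_haplotypes(counts)
  # independent evaluation, written out from the definitions
  p1 <- c(6, 2) / 8; p2 <- c(1, 7) / 8
  hs_plug <- mean(c(1 - sum(p1^2), 1 - sum(p2^2)))
  pbar <- (p1 + p2) / 2
  ht_plug <- 1 - sum(pbar^2)
  gst_p <- (ht_plug - hs_plug) / ht_plug
  gph_p <- gst_p * (1 + hs_plug) / (1 - hs_plug)
  d_p <- 2 * (ht_plug - hs_plug) / (1 - hs_plug)
  got_p <- differentiation_stats(hap, variant = "plug_in")
  expect_equal(got_p$gst, gst_p, tolerance = 1e-12)
  expect_equal(got_p$gst_hedrick, gph_p, tolerance = 1e-12)
  expect_equal(got_p$jost_d, d_p, tolerance = 1e-12)
  # Nei-Chesser corrected: harmonic mean n = 8
  nt <- 2 / (1 / 8 + 1 / 8)
  hs_c <- nt / (nt - 1) * hs_plug
  ht_c <- ht_plug + hs_c / (nt * 2)
  gst_c <- (ht_c - hs_c) / ht_c
  got_c <- differentiation_stats(hap, variant = "nei_chesser")
  expect_equal(got_c$hs, hs_c, tolerance = 1e-12)
  expect_equal(got_c$ht, ht_c, tolerance = 1e-12)
  expect_equal(got_c$gst, gst_c, tolerance = 1e-12)
})

test_that("duplicating a population leaves its pairwise statistics equal", {
  counts <- matrix(c(5L, 3L, 2L, 8L, 5L, 3L), 2, 3,
                   dimnames = list(NULL, c("A", "B", "A2")))
  d <- differentiation_stats(toy_haplotypes(counts))
  ab <- d[d$pop1 == "A" & d$pop2 == "B", ]
  a2b <- d[(d$pop1 == "A2" & d$pop2 == "B") |
             (d$pop1 == "B" & d$pop2 == "A2"), ]
  expect_equal(ab$gst, a2b$gst)
  expect_equal(ab$jost_d, a2b$jost_d)
  # plug-in Gst never exceeds 1
  expect_true(all(differentiation_stats(toy_haplotypes(counts),
                                        variant = "plug_in")$gst <= 1))
})
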