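test_that("identity matching requires Hamming distance zero", {
  A <- toy_gm(a1 = "abab", a2 = "aabb")
  B <- toy_gm(b1 = "abab", b2 = "abaa")
  m <- match_identical_loci(A, B)
  expect_identical(m$id_a, "a1")
  expect_identical(m$id_b, "b1")
  expect_identical(m$n_compared, 4)
  # one differing progeny breaks the match
  expect_identical(nrow(match_identical_loci(toy_gm(x = "abab"),
                                             toy_gm(y = "abaa"))), 0L)
  expect_error(match_identical_loci(A, toy_gm(z = "ab")), "progeny")
})

test_that("matching is symmetric and respects segregation type", {
  A <- toy_gm(a1 = "abab", a2 = "abab", segtype = c("abxaa", "aaxab"))
  B <- toy_gm(b1 = "abab", segtype = "aaxab")
  m_ab <- match_identical_loci(A, B)
  m_ba <- match_identical_loci(B, A)
  expect_identical(m_ab$id_a, "a2")  # same-type only
  expect_identical(m_ba$id_b, "a2")
  expect_identical(nrow(m_ab), nrow(m_ba))
})

test_that("missing-data policies compare co-observed or full vectors", {
  A <- toy_gm(a1 = "ab-b")
  B <- toy_gm(b1 = "abab", b2 = "ab-b")
  co <- match_identical_loci(A, B, policy = "coobserved")
  expect_setequal(co$id_b, c("b1", "b2"))
  expect_identical(co$n_compared[co$id_b == "b1"], 3)
  strict <- match_identical_loci(A, B, policy = "strict")
  expect_identical(strict$id_b, "b2")
})

test_that("many-to-one matches collapse to the first view's locus", {
  A <- toy_gm(a1 = "abab", a2 = "bbbb")
  B <- toy_gm(b1 = "abab", b2 = "abab", b3 = "aaaa")
  matched <- crossval_matched(A, match_identical_loci(A, B))
  expect_identical(matched$markers$id, "a1")
  expect_identical(matched$markers$n_matches, 2L)
})

test_that("binning collapses identical runs within 1 kb on a contig", {
  gm1 <- toy_gm(m1 = "abab", m2 = "abab", m3 = "abab",
                contig = "C1", pos = c(100, 600, 1400))
  b1 <- bin_markers(gm1)
  expect_identical(nrow(b1$representatives$calls), 1L)  # chained gaps
  expect_identical(unique(b1$bins$representative), "m1")

  gm2 <- toy_gm(m1 = "abab", m2 = "abab", contig = "C1",
                pos = c(100, 5000))
  expect_identical(nrow(bin_markers(gm2)$representatives$calls), 2L)

  gm3 <- toy_gm(m1 = "abab", m2 = "bbba", contig = "C1",
                pos = c(100, 200))
  expect_identical(nrow(bin_markers(gm3)$representatives$calls), 2L)

  # representative = fewest missing calls
  gm4 <- toy_gm(m1 = "ab-b", m2 = "abab", contig = "C1",
                pos = c(100, 300))
  expect_identical(bin_markers(gm4)$representatives$markers$id,
                   c("m1", "m2"))  # not identical vectors -> both kept
  gm5 <- toy_gm(m1 = "ab-b", m2 = "ab-b", contig = "C1",
                pos = c(300, 100))
  expect_identical(unique(bin_markers(gm5)$bins$representative), "m2")
})

test_that("binning is idempotent", {
  spec <- chrom_spec(r = rep(0, 9), spacing_bp = 300, contig_bp = 50000)
  gm <- simulate_progeny(spec, 40, seed = 21)
  b1 <- bin_markers(gm)
  b2 <- bin_markers(b1$representatives)
  expect_identical(b1$representatives$markers$id,
                   b2$representatives$markers$id)
})

test_that("venn counts: disjoint sets, subsets, and coded >= nucleotide", {
  A <- toy_gm(a1 = "abab", a2 = "aabb",
              allele_a = c("A", "C"), allele_b = c("G", "T"))
  B <- toy_gm(b1 = "abab", b2 = "bbbb",
              allele_a = c("T", "A"), allele_b = c("C", "G"))
  D <- toy_gm(d1 = "baba", d2 = "abba",
              allele_a = c("A", "A"), allele_b = c("C", "C"))
  vd <- venn_counts(list(A = A, D = D))
  expect_true(all(vd$count == 0))                    # disjoint
  sub <- venn_counts(list(A = A, AB = toy_gm(a1 = "abab", a2 = "aabb",
                                             a3 = "bbbb")))
  expect_identical(sub$count[sub$dataset == "A" & sub$vs == "AB"], 2L)
  coded <- venn_counts(list(A = A, B = B), mode = "coded")
  nt <- venn_counts(list(A = A, B = B), mode = "nucleotide")
  expect_true(all(coded$count >= nt$count))
  # here the labels disagree at every site, so nucleotide matches vanish
  expect_identical(sum(nt$count), 0L)
})

test_that("dual views with zero divergence intersect at the simulator key", {
  spec <- make_parent_spec(n_chrom = 2, markers_per_parent = 4)
  gm <- simulate_progeny(spec, 25, seed = 31)
  dual <- emit_dual_views(gm, drop_p = c(0.2, 0.2), flip_p = 0,
                          lowqual_p = 0, mq_low_p = 0, seed = 31)
  shared <- sum(!is.na(dual$key$locus_D) & !is.na(dual$key$locus_S))
  A <- geno_matrix(dual$views$D$calls,
                   data.frame(id = dual$views$D$loci$locus,
                              segtype = dual$views$D$loci$segtype))
  B <- geno_matrix(dual$views$S$calls,
                   data.frame(id = dual$views$S$loci$locus,
                              segtype = dual$views$S$loci$segtype))
  m <- match_identical_loci(A, B)
  key <- dual$key[!is.na(dual$key$locus_D) & !is.na(dual$key$locus_S), ]
  # every truly shared locus is recovered as a match
  expect_true(all(paste(key$locus_D, key$locus_S) %in%
                    paste(m$id_a, m$id_b)))
  expect_gte(nrow(m), shared)
})
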