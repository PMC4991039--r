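test_that("zero recombination forces co-segregation and r = 0.5 is rejected", {
  spec <- chrom_spec(r = 0)
  gm <- simulate_progeny(spec, n = 150, seed = 3)
  expect_identical(gm$calls[1, ], gm$calls[2, ])
  expect_error(simulate_progeny(chrom_spec(r = 0.5), 10), "0.5")
  expect_error(simulate_progeny(chrom_spec(r = -0.1), 10))
})

test_that("recombinant fraction matches binomial sampling at large n", {
  spec <- chrom_spec(r = 0.30)
  gm <- simulate_progeny(spec, n = 10000, seed = 11)
  rec <- mean(gm$calls[1, ] != gm$calls[2, ])
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(rec - 0.30), 3 * se)
})

test_that("interleaved layouts place composite truth at the requested spacing", {
  spec <- make_parent_spec(n_chrom = 2, markers_per_parent = 5,
                           spacing_cM = 5)
  # same-parent neighbours are two intervals apart
  r13 <- true_rf(spec, "chr01", 1, 3)
  expect_lt(abs(kosambi_distance(r13) - 5), 0.15)
  gm <- simulate_progeny(spec, n = 200, seed = 5)
  expect_identical(unique(table(gm$markers$segtype)), 10L)
})

test_that("degrade applies missingness and errors at the stated rates", {
  spec <- chrom_spec(r = rep(0.1, 999))
  gm <- simulate_progeny(spec, n = 150, seed = 2)
  expect_identical(degrade(gm, 0, 0)$calls, gm$calls)
  expect_true(all(is.na(degrade(gm, 1, 0)$calls)))
  deg <- degrade(gm, 0.05, 0.01, seed = 9)
  mfrac <- mean(is.na(deg$calls))
  expect_lt(abs(mfrac - 0.05), 3 * sqrt(0.05 * 0.95 / length(gm$calls)))
  flipped <- mean(deg$calls != gm$calls, na.rm = TRUE)
  expect_lt(abs(flipped - 0.01), 3 * sqrt(0.01 * 0.99 / sum(!is.na(deg$calls))))
})

test_that("dual views agree exactly under zero divergence and drop works", {
  spec <- make_parent_spec(n_chrom = 2, markers_per_parent = 5)
  gm <- simulate_progeny(spec, n = 30, seed = 4)
  dual <- emit_dual_views(gm, drop_p = c(0, 0), flip_p = 0,
                          lowqual_p = 0, mq_low_p = 0, seed = 4)
  expect_identical(dual$views$D$calls, dual$views$S$calls)
  expect_false(anyNA(dual$key$locus_D))
  dropped <- emit_dual_views(gm, drop_p = c(0, 1), flip_p = 0, seed = 4)
  expect_identical(nrow(dropped$views$S$loci), 0L)
  expect_true(all(is.na(dropped$key$locus_S)))
})

test_that("independent view flips perturb vectors at the predicted rate", {
  spec <- chrom_spec(r = rep(0.2, 999))
  gm <- simulate_progeny(spec, n = 20, seed = 6)
  p <- 0.02
  dual <- emit_dual_views(gm, drop_p = c(0, 0), flip_p = p,
                          lowqual_p = 0, mq_low_p = 0, seed = 6)
  uneq <- mean(vapply(seq_len(1000), function(i)
    any(dual$views$D$calls[i, ] != dual$views$S$calls[i, ]), logical(1)))
  # a call differs when flipped in exactly one view
  expected <- 1 - (1 - 2 * p * (1 - p))^20
  expect_lt(abs(uneq - expected), 3 * sqrt(expected * (1 - expected) / 1000))
})

test_that("identical config and seed reproduce byte-identical VCF output", {
  spec <- make_parent_spec(n_chrom = 1, markers_per_parent = 4)
  gm <- degrade(simulate_progeny(spec, n = 12, seed = 8),
                0.1, 0.01, seed = 8)
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_view_vcf(emit_dual_views(gm, seed = 8)$views$D, f1)
  write_view_vcf(emit_dual_views(gm, seed = 8)$views$D, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed changes the draws
  f3 <- tempfile(fileext = ".vcf")
  write_view_vcf(emit_dual_views(gm, seed = 9)$views$D, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("segregation distortion pushes markers out of the 1:1 ratio", {
  spec <- chrom_spec(r = rep(0.4, 199))
  gm <- simulate_progeny(spec, n = 150, seed = 10, distortion = 1,
                         distortion_strength = 0.4)
  expect_gt(mean(gm$markers$p < 0.01), 0.5)
})

test_that("truth tables round-trip the layout", {
  spec <- make_parent_spec(n_chrom = 2, markers_per_parent = 3)
  gm <- simulate_progeny(spec, n = 10, seed = 1)
  f <- tempfile(fileext = ".tsv")
  write_truth_table(gm, f)
  tt <- read.delim(f)
  expect_identical(nrow(tt), 12L)
  expect_identical(tt$id, gm$markers$id)
  expect_true(all(is.na(tt$r_next[c(6, 12)])))
})
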