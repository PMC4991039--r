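test_that("alignment records are kept exactly per the NM/AS/XS predicate", {
  expect_false(keep_alignment(10, 100, 50))        # edit distance too high
  expect_true(keep_alignment(0, 60, NA))           # all clauses at boundary
  expect_false(keep_alignment(5, 80, 81))          # second-best beats best
  expect_true(keep_alignment(9, 60, 60))           # ties survive
  expect_false(keep_alignment(3, 59, NA))          # best score below 60
  expect_identical(keep_alignment(c(10, 0, 5), c(100, 60, 80),
                                  c(50, NA, 81)),
                   c(FALSE, TRUE, FALSE))
  expect_error(keep_alignment(-1, 80, NA), ">= 0")
})

test_that("parental site discovery enforces MQ >= 20 and DP >= 5 with union merge", {
  sites <- data.frame(id = paste0("s", 1:6),
                      mq = c(30, 30, 19, 25, 20, 50),
                      dp_mother = c(4, 5, 9, 12, 5, 2))
  expect_identical(discover_parental_sites(sites)$id, c("s2", "s4", "s5"))
  # discovered in either parent qualifies; duplicates collapse
  both <- data.frame(id = c("x", "x", "y"), mq = c(40, 40, 40),
                     dp_mother = c(2, 2, 8), dp_father = c(9, 9, NA))
  expect_identical(discover_parental_sites(both)$id, c("x", "y"))
})

test_that("genotype calls honour DP >= 10 and GQ > 50 and the cross model", {
  expect_identical(code_genotypes("0/1", 10, 51), "ab")
  expect_identical(code_genotypes("0/1", 9, 99), NA_character_)
  expect_identical(code_genotypes("0/0", 50, 50), NA_character_)  # GQ must exceed 50
  expect_identical(code_genotypes("0/0", 10, 51, hom_allele = 0L), "aa")
  expect_identical(code_genotypes("1/1", 10, 51, hom_allele = 1L), "aa")
  # homozygous for the allele the homozygous parent lacks: impossible
  expect_identical(code_genotypes("1/1", 30, 99, hom_allele = 0L),
                   NA_character_)
  expect_error(code_genotypes("0/2", 30, 99), "ref/alt")
})

test_that("segregation types follow the parental genotype pattern", {
  expect_identical(classify_segregation("A/C", "A/A"), "abxaa")
  expect_identical(classify_segregation("G/G", "G/T"), "aaxab")
  expect_identical(classify_segregation("A/C", "A/C"), "abxab")
  expect_identical(classify_segregation("T/T", "T/T"), "hom")
  expect_identical(classify_segregation("./.", "A/A"), "untyped")
  expect_identical(classify_segregation(c("A/C", "0/0"), c("A/A", "0/1")),
                   c("abxaa", "aaxab"))
})

test_that("1:1 chi-square matches the df-1 closed form", {
  expect_identical(chi_square_1to1(75, 75)$chisq, 0)
  expect_identical(chi_square_1to1(75, 75)$p, 1)
  r1 <- chi_square_1to1(90, 60)
  expect_equal(r1$chisq, 6.00)
  expect_equal(r1$p, 2 * pnorm(-sqrt(6)), tolerance = 1e-12)  # tail oracle
  expect_equal(round(r1$p, 4), 0.0143)
  r2 <- chi_square_1to1(95, 55)
  expect_equal(r2$chisq, 10.667, tolerance = 1e-3)
  expect_equal(round(r2$p, 5), 0.00109)
  expect_true(is.na(chi_square_1to1(0, 0)$chisq))
  # symmetry, non-negativity, p in (0, 1]
  set.seed(1)
  a <- rpois(50, 70); b <- rpois(50, 70)
  expect_identical(chi_square_1to1(a, b), chi_square_1to1(b, a))
  expect_true(all(chi_square_1to1(a, b)$chisq >= 0))
  expect_true(all(chi_square_1to1(a, b)$p > 0 &
                    chi_square_1to1(a, b)$p <= 1))
})

test_that("marker QC removes distorted, gappy and non-1:1 markers", {
  n <- 150
  mk <- function(n_ab, n_miss, segtype = "abxaa") {
    calls <- c(rep("ab", n_ab), rep(NA, n_miss),
               rep("aa", n - n_ab - n_miss))
    paste(ifelse(is.na(calls), "-", ifelse(calls == "aa", "a", "b")),
          collapse = "")
  }
  gm <- toy_gm(keep_even = mk(75, 0),
               drop_p = mk(55, 0),          # p ~ 0.0011 < .01
               keep_p = mk(60, 0),          # p ~ 0.0143
               keep_missing = mk(60, 15),   # exactly 10 % missing
               drop_missing = mk(62, 16),   # > 10 % missing
               not11 = mk(70, 0, "abxab"),
               segtype = c(rep("abxaa", 5), "abxab"))
  kept <- marker_qc(gm)$markers$id
  expect_setequal(kept, c("keep_even", "keep_p", "keep_missing"))
})

test_that("tightening any threshold never enlarges the retained set", {
  spec <- chrom_spec(r = rep(0.3, 199))
  gm <- degrade(simulate_progeny(spec, 120, seed = 13), 0.08, 0.02,
                seed = 13)
  base <- marker_qc(gm)$markers$id
  tighter <- list(filter_config(max_missing = 0.05),
                  filter_config(min_segregation_p = 0.05))
  for (cfg in tighter)
    expect_true(all(marker_qc(gm, cfg)$markers$id %in% base))
})

test_that("marker tables serialise the coded vectors", {
  gm <- toy_gm(m1 = "ab-a", m2 = "bbaa")
  f <- tempfile(fileext = ".tsv")
  write_marker_table(gm, f)
  tab <- read.delim(f)
  expect_identical(tab$genotypes, c("ab-a", "bbaa"))
})
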