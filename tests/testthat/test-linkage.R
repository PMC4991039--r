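test_that("pair tabulation counts co-observed progeny only", {
  g <- rep(c("aa", "ab"), 75)
  expect_identical(count_pair(g, g)$m, 0L)
  comp <- ifelse(g == "aa", "ab", "aa")
  cp <- count_pair(g, comp)
  expect_identical(cp$m, cp$n)
  gA <- g; gA[1:10] <- NA
  gB <- g; gB[11:15] <- NA
  expect_identical(count_pair(gA, gB)$n, 135L)
  expect_error(count_pair(g, g, segA = "abxaa", segB = "aaxab"),
               "uninformative")
})

test_that("two-point estimates reproduce the testcross closed forms", {
  e1 <- estimate_rf(list(n = 150, m = 45))
  expect_equal(e1$r_hat, 0.30)
  expect_identical(e1$phase, "coupling")
  expect_equal(round(e1$lod, 2), 5.36)

  e2 <- estimate_rf(list(n = 150, m = 75))
  expect_equal(e2$r_hat, 0.5)
  expect_equal(e2$lod, 0)
  expect_identical(e2$phase, "undetermined")

  e3 <- estimate_rf(list(n = 150, m = 105))
  expect_equal(e3$r_hat, 0.30)
  expect_identical(e3$phase, "repulsion")
  expect_equal(round(e3$lod, 2), 5.36)

  e4 <- estimate_rf(list(n = 150, m = 0))
  expect_equal(e4$r_hat, 0)
  expect_equal(e4$lod, 150 * log10(2), tolerance = 1e-12)

  expect_error(estimate_rf(list(n = 0, m = 0)), "undefined")
})

test_that("estimate_rf maximises the binomial likelihood ratio (grid oracle)", {
  grid <- seq(0.0001, 0.5, by = 0.0001)
  ll <- function(n, k, r) (n - k) * log10(2 * (1 - r)) + k * log10(2 * r)
  set.seed(17)
  for (n in sample(5:200, 15)) {
    for (k in unique(c(0, sample(0:floor(n / 2), 4)))) {
      est <- estimate_rf(list(n = n, m = k))
      vals <- ll(n, k, grid)
      if (k == 0) vals <- c(n * log10(2), vals)  # boundary r = 0
      expect_gte(est$lod + 1e-9, max(vals))
      if (k > 0)
        expect_lt(abs(est$r_hat - grid[which.max(vals)]), 1e-4 + 1e-12)
    }
  }
})

test_that("expected LOD matches its closed form and the estimator", {
  expect_equal(round(expected_lod(0.30, 150), 2), 5.36)
  expect_equal(expected_lod(0.5, 37), 0, tolerance = 1e-12)
  expect_equal(round(expected_lod(0.1, 100), 2), 15.98)
  expect_error(expected_lod(0, 100), "0, 0.5")
  # agreement with estimate_rf when observed proportions are exact
  for (r in c(0.1, 0.25, 0.4)) {
    n <- 200
    expect_equal(expected_lod(r, n),
                 estimate_rf(list(n = n, m = n * r))$lod,
                 tolerance = 1e-12)
  }
})

test_that("Kosambi transform and inverse are exact and round-trip", {
  expect_equal(round(kosambi_distance(0.30), 2), 34.66)
  expect_identical(kosambi_distance(0), 0)
  expect_equal(kosambi_distance(0.25), 25 * log(3), tolerance = 1e-12)
  expect_equal(round(kosambi_inverse(34.66), 3), 0.300)
  expect_identical(kosambi_inverse(0), 0)
  expect_equal(round(kosambi_inverse(27.47), 3), 0.250)
  expect_error(kosambi_distance(0.5), "0.5")
  expect_error(kosambi_inverse(-1))
  d <- seq(0, 200, by = 0.5)
  back <- kosambi_distance(kosambi_inverse(d))
  expect_lt(max(abs(back - d) / pmax(d, 1e-12)), 1e-9)
})

test_that("pairwise matrices are symmetric and recover simulated truth", {
  gm <- toy_gm(m1 = "abab", m2 = "abab")
  pm <- pairwise_matrix(gm)
  expect_identical(pm$rf["m1", "m2"], 0)
  expect_equal(pm$lod["m1", "m2"], 4 * log10(2))

  spec <- chrom_spec(r = c(0.05, 0.1, 0.2, 0.3))
  sim <- simulate_progeny(spec, 10000, seed = 23)
  spm <- pairwise_matrix(sim)
  expect_identical(spm$rf, t(spm$rf))
  expect_identical(spm$lod, t(spm$lod))
  for (i in 1:4) for (j in (i + 1):5) {
    r_true <- true_rf(spec, "chr01", i, j)
    se <- sqrt(r_true * (1 - r_true) / 10000)
    expect_lt(abs(spm$rf[i, j] - r_true), 3 * se + 1e-9)
  }
  expect_error(pairwise_matrix(
    toy_gm(a = "ab", b = "ab", segtype = c("abxaa", "aaxab"))), "mixed")
})

test_that("phase matrix tracks coupling versus repulsion", {
  gm <- toy_gm(m1 = "aabb", m2 = "aabb", m3 = "bbaa")
  pm <- pairwise_matrix(gm)
  expect_identical(pm$phase["m1", "m2"], 1)    # coupling
  expect_identical(pm$phase["m1", "m3"], -1)   # repulsion
})
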