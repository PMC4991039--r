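#' Kosambi mapping function
#'
#' Converts a recombination fraction to a map distance,
#' d = 25 ln((1+2r)/(1-2r)) centiMorgans. The Kosambi function partially
#' accounts for crossover interference; it is the distance transform used
#' throughout this package.
#'
#' @param r recombination fraction(s), 0 <= r < 0.5
#' @return map distance(s) in cM
#' @examples
#' kosambi_distance(0.30)  # 34.66 cM
#' @export
kosambi_distance <- function(r) {
  if (any(!is.finite(r)) || any(r < 0) || any(r >= 0.5))
    stop("recombination fraction must lie in [0, 0.5); ",
         "r = 0.5 maps to infinite distance")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse Kosambi mapping function
#'
#' @param d map distance(s) in cM, d >= 0
#' @return recombination fraction(s), r = tanh(2d/100)/2
#' @examples
#' kosambi_inverse(34.66)  # ~0.300
#' @export
kosambi_inverse <- function(d) {
  if (any(!is.finite(d)) || any(d < 0)) stop("distance must be >= 0")
  tanh(2 * d / 100) / 2
}

# base-10 log likelihood ratio of linkage at r_hat = k/n versus r = 0.5,
# under the binomial testcross model; 0*log(0) taken as 0.
testcross_lod <- function(n, k) {
  r <- k / n
  t1 <- ifelse(k == n, 0, (n - k) * log10(2 * (1 - r)))
  t2 <- ifelse(k == 0, 0, k * log10(2 * r))
  t1 + t2
}

#' Expected LOD score for a testcross marker pair
#'
#' The expected two-point LOD for a pair of 1:1-segregating markers with
#' true recombination fraction `r` in `n` progeny:
#' ELOD = n \[ (1-r) log10(2(1-r)) + r log10(2r) \].
#' At r = 0.30 and n = 150 this gives 5.36, the support expected for two
#' moderately linked loci in a family of 150.
#'
#' @param r true recombination fraction, 0 < r <= 0.5
#' @param n number of informative progeny
#' @return the expected LOD score
#' @examples
#' expected_lod(0.30, 150)  # 5.36
#' @export
expected_lod <- function(r, n) {
  if (any(r <= 0) || any(r > 0.5)) stop("r must lie in (0, 0.5]")
  if (any(n < 1)) stop("n must be >= 1")
  n * ((1 - r) * log10(2 * (1 - r)) + r * log10(2 * r))
}

#' Tabulate co-observed genotype classes for a marker pair
#'
#' For two 1:1-segregating markers informative for the same parent there
#' are four combined progeny genotype classes (aa/aa, aa/ab, ab/aa, ab/ab).
#' Counts are taken over progeny with both calls observed. A pair of
#' markers informative for different parents carries no recombination
#' information and is rejected.
#'
#' @param gA,gB coded call vectors (`"aa"`/`"ab"`/`NA`) over the same
#'   progeny ordering
#' @param segA,segB the two markers' segregation types; must be equal
#' @return a `pair_counts` list: `table` (2x2 matrix), `n` co-observed
#'   progeny, `m` off-diagonal (allele-discordant) count
#' @export
count_pair <- function(gA, gB, segA = "abxaa", segB = segA) {
  if (length(gA) != length(gB)) stop("call vectors differ in length")
  if (segA != segB)
    stop("uninformative pairing: markers segregate from different parents")
  obs <- !is.na(gA) & !is.na(gB)
  tab <- matrix(0L, 2, 2, dimnames = list(A = c("aa", "ab"),
                                          B = c("aa", "ab")))
  if (any(obs)) {
    t0 <- table(factor(gA[obs], c("aa", "ab")),
                factor(gB[obs], c("aa", "ab")))
    tab[] <- as.integer(t0)
  }
  structure(list(table = tab, n = sum(tab),
                 m = tab["aa", "ab"] + tab["ab", "aa"]),
            class = "pair_counts")
}

#' Two-point recombination fraction, phase and LOD for a marker pair
#'
#' In pseudo-testcross data the parental linkage phase is unknown, so it is
#' inferred per pair by minimising the recombinant count: with `m`
#' allele-discordant progeny out of `n` co-observed, the pair is in
#' coupling (k = m recombinants) if m <= n - m, else in repulsion
#' (k = n - m). Then r_hat = k/n and
#' LOD = (n-k) log10(2(1-r_hat)) + k log10(2 r_hat), the base-10 likelihood
#' ratio against independence (r = 0.5).
#'
#' @param counts a `pair_counts` object from [count_pair()], or a list with
#'   elements `n` and `m`
#' @return a `pairwise_linkage` list: `r_hat`, `phase` (`"coupling"`,
#'   `"repulsion"` or `"undetermined"` when m = n - m), `lod`, `n`, `k`
#' @examples
#' estimate_rf(list(n = 150, m = 45))  # r_hat 0.30, LOD 5.36
#' @export
estimate_rf <- function(counts) {
  n <- counts$n
  m <- counts$m
  if (is.null(n) || n < 1) stop("no co-observed progeny: undefined pair")
  if (m > n) stop("m cannot exceed n")
  k <- min(m, n - m)
  phase <- if (m < n - m) "coupling" else if (m > n - m) "repulsion"
           else "undetermined"
  structure(list(r_hat = k / n, phase = phase,
                 lod = testcross_lod(n, k), n = n, k = k),
            class = "pairwise_linkage")
}

#' @export
print.pairwise_linkage <- function(x, ...) {
  cat(sprintf("r_hat = %.4f (%s), LOD = %.2f, n = %d\n",
              x$r_hat, x$phase, x$lod, x$n))
  invisible(x)
}

#' All-pairs two-point linkage matrices
#'
#' Computes recombination fraction, LOD, phase and informative-count
#' matrices over all pairs of same-parent markers, vectorised over the
#' coded call matrix. Missing calls are excluded pairwise.
#'
#' @param gm a [geno_matrix()] whose markers all share one segregation type
#'   (see [informative_markers()])
#' @return list of symmetric matrices `rf`, `lod`, `n`, `phase` (+1
#'   coupling, -1 repulsion, 0 undetermined), with marker-id dimnames.
#'   Diagonal: rf 0, lod NA.
#' @export
pairwise_matrix <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (length(unique(gm$markers$segtype)) > 1)
    stop("markers of mixed segregation type: map each parent separately")
  x <- coded01(gm)
  obs <- !is.na(x)
  a <- ifelse(obs, x, 0)          # indicator of "ab"
  b <- ifelse(obs, 1 - x, 0)      # indicator of "aa"
  n <- obs %*% t(obs)
  same <- a %*% t(a) + b %*% t(b)
  m <- n - same
  k <- pmin(m, n - m)
  rf <- ifelse(n > 0, k / n, NA_real_)
  lod <- matrix(NA_real_, nrow(rf), ncol(rf), dimnames = dimnames(rf))
  pos <- n > 0
  lod[pos] <- testcross_lod(n[pos], k[pos])
  phase <- sign(n - 2 * m)        # +1 coupling, -1 repulsion, 0 tie
  diag(lod) <- NA_real_
  diag(rf) <- 0
  ids <- gm$markers$id
  dimnames(rf) <- dimnames(lod) <- dimnames(n) <- dimnames(phase) <-
    list(ids, ids)
  list(rf = rf, lod = lod, n = n, phase = phase)
}

#' Write a square linkage matrix as tab-separated text
#'
#' @param m a matrix from [pairwise_matrix()]
#' @param path output file
#' @export
write_linkage_matrix <- function(m, path) {
  write.table(data.frame(marker = rownames(m), m, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
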