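# small builders used across the suite

# genotype matrix from compact strings: "a" = aa, "b" = ab, "-" = missing
toy_gm <- function(..., segtype = "abxaa", contig = NULL, pos = NULL,
                   allele_a = NULL, allele_b = NULL) {
  strs <- c(...)
  calls <- t(vapply(strsplit(strs, ""), function(ch)
    ifelse(ch == "-", NA_character_, ifelse(ch == "a", "aa", "ab")),
    character(nchar(strs[1]))))
  ids <- names(strs)
  if (is.null(ids)) ids <- sprintf("M%02d", seq_along(strs))
  mk <- data.frame(id = ids, segtype = rep_len(segtype, length(strs)))
  if (!is.null(contig)) mk$contig <- contig
  if (!is.null(pos)) mk$contig_pos <- pos
  if (!is.null(allele_a)) mk$allele_a <- allele_a
  if (!is.null(allele_b)) mk$allele_b <- allele_b
  rownames(calls) <- ids
  geno_matrix(calls, mk)
}

# hand-built single-chromosome layout with explicit per-interval r
chrom_spec <- function(r, segtype = NULL, spacing_bp = 1000,
                       contig_bp = 5000) {
  nm <- length(r) + 1L
  if (is.null(segtype)) segtype <- rep("abxaa", nm)
  pos <- seq_len(nm) * spacing_bp
  ch <- list(n_markers = nm, r = r, segtype = segtype, phys_bp = pos,
             contig = sprintf("C01_%05d", pos %/% contig_bp),
             contig_pos = pos %% contig_bp + 1L)
  structure(list(chr01 = ch), class = "parent_spec")
}

# symmetric random rf matrix in [0, 0.5) with zero diagonal
random_rf <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n, 0, 0.499), n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(sprintf("M%02d", 1:n), sprintf("M%02d", 1:n))
  m
}
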