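#' Filter thresholds for the SNP discovery and genotyping cascade
#'
#' Collects every numeric threshold of the quality-control cascade, with
#' defaults matching the mapping protocol this package implements:
#' alignment records are dropped when the edit distance exceeds 9, the best
#' alignment score is below 60, or a second-best alignment scores higher
#' than the best; candidate SNP sites require site mapping quality >= 20
#' and parental read depth >= 5; individual genotype calls require
#' DP >= 10 and GQ strictly > 50; markers are removed when the 1:1
#' segregation chi-square p-value is below 0.01 or more than 10 % of
#' progeny calls are missing.
#'
#' @param max_edit_distance drop alignments with NM above this
#' @param min_best_score drop alignments with AS below this
#' @param min_site_mq minimum site mapping quality for SNP discovery
#' @param min_discovery_dp minimum parental depth at discovery
#' @param min_genotype_dp minimum per-call depth for genotyping
#' @param min_gq per-call genotype quality must strictly exceed this
#' @param max_missing maximum tolerated missing fraction per marker
#'   (strictly more is removed)
#' @param min_segregation_p markers with 1:1 chi-square p below this are
#'   removed
#' @return a `filter_config` list of thresholds
#' @export
filter_config <- function(max_edit_distance = 9,
                          min_best_score = 60,
                          min_site_mq = 20,
                          min_discovery_dp = 5,
                          min_genotype_dp = 10,
                          min_gq = 50,
                          max_missing = 0.10,
                          min_segregation_p = 0.01) {
  structure(list(max_edit_distance = max_edit_distance,
                 min_best_score = min_best_score,
                 min_site_mq = min_site_mq,
                 min_discovery_dp = min_discovery_dp,
                 min_genotype_dp = min_genotype_dp,
                 min_gq = min_gq,
                 max_missing = max_missing,
                 min_segregation_p = min_segregation_p),
            class = "filter_config")
}

#' Alignment-record filter
#'
#' Decides, per alignment record, whether it survives the mapping filter:
#' a record is dropped iff its edit distance (NM) exceeds the maximum, its
#' best alignment score (AS) is below the minimum, or a second-best
#' alignment score (XS) exceeds the best. An absent second-best score
#' never triggers the last clause.
#'
#' @param edit_distance integer NM tag value(s); must be >= 0
#' @param best_score integer AS tag value(s)
#' @param second_best integer XS tag value(s), `NA` where absent
#' @param cfg a [filter_config()]
#' @return logical vector: `TRUE` = keep
#' @export
keep_alignment <- function(edit_distance, best_score, second_best = NA,
                           cfg = filter_config()) {
  if (any(edit_distance < 0, na.rm = TRUE))
    stop("edit distance must be >= 0")
  n <- max(length(edit_distance), length(best_score), length(second_best))
  second_best <- rep_len(second_best, n)
  drop <- edit_distance > cfg$max_edit_distance |
    best_score < cfg$min_best_score |
    (!is.na(second_best) & second_best > best_score)
  !drop
}

#' Parental SNP site discovery filter
#'
#' Retains candidate SNP sites with site mapping quality >= the MQ
#' threshold and read depth >= the discovery depth threshold in the parent
#' the site was discovered in, then merges ("union") the per-parent site
#' lists, deduplicated by locus id. A site qualifies if discovered in
#' either parent.
#'
#' @param sites data frame with columns `id`, `mq`, and one or both of
#'   `dp_mother`, `dp_father` (per-parent read depth; `NA` = not observed
#'   in that parent)
#' @param cfg a [filter_config()]
#' @return the subset of `sites` passing discovery, deduplicated by `id`
#' @export
discover_parental_sites <- function(sites, cfg = filter_config()) {
  dp_m <- if (is.null(sites$dp_mother)) NA_real_ else sites$dp_mother
  dp_f <- if (is.null(sites$dp_father)) NA_real_ else sites$dp_father
  depth_ok <- (!is.na(dp_m) & dp_m >= cfg$min_discovery_dp) |
              (!is.na(dp_f) & dp_f >= cfg$min_discovery_dp)
  keep <- sites$mq >= cfg$min_site_mq & depth_ok
  out <- sites[keep, , drop = FALSE]
  out[!duplicated(out$id), , drop = FALSE]
}

#' Code one genotype call against DP/GQ thresholds
#'
#' A diploid call is set missing when DP < the genotyping depth threshold
#' or GQ <= the quality threshold (GQ must strictly exceed it). Surviving
#' calls are mapped to the testcross coding relative to the segregating
#' parent: homozygous for the homozygous parent's allele = `"aa"`,
#' heterozygous = `"ab"`. A homozygous call for the allele the homozygous
#' parent does not carry is impossible under the cross and is coded
#' missing; alleles outside the site's ref/alt set are an input error.
#'
#' @param gt diploid call(s) as allele-index strings (`"0/0"`, `"0/1"`,
#'   `"1/1"`, `"./."` or `NA`)
#' @param dp,gq per-call depth and genotype quality
#' @param hom_allele index (0 or 1) of the homozygous parent's allele
#' @param cfg a [filter_config()]
#' @return character vector of coded calls `"aa"`, `"ab"`, `NA`
#' @export
code_genotypes <- function(gt, dp, gq, hom_allele = 0L,
                           cfg = filter_config()) {
  n <- length(gt)
  dp <- rep_len(dp, n); gq <- rep_len(gq, n)
  gt <- gsub("|", "/", gt, fixed = TRUE)
  known <- c("0/0", "0/1", "1/0", "1/1", "./.", NA)
  if (any(!(gt %in% known)))
    stop("genotype with alleles outside the site's ref/alt set: ",
         paste(unique(setdiff(gt, known)), collapse = ", "))
  out <- rep(NA_character_, n)
  pass <- !is.na(dp) & !is.na(gq) &
    dp >= cfg$min_genotype_dp & gq > cfg$min_gq
  het <- gt %in% c("0/1", "1/0")
  hom_aa <- gt == sprintf("%d/%d", hom_allele, hom_allele)
  out[pass & het] <- "ab"
  out[pass & hom_aa] <- "aa"
  # homozygous for the non-shared allele: impossible under the cross
  out
}

#' Classify the segregation type of a SNP from the parental genotypes
#'
#' Markers heterozygous in the mother and homozygous in the father
#' (`abxaa`) segregate 1:1 and map on the maternal map; the reverse
#' (`aaxab`) on the paternal map. Both-heterozygous (`abxab`) markers are
#' fully informative but are not handled by the pseudo-testcross model and
#' are flagged not-mappable; both-homozygous sites are monomorphic in the
#' cross.
#'
#' @param maternal_gt,paternal_gt parental diploid genotypes as
#'   `"X/Y"` allele strings (nucleotides or indices)
#' @return one of `"abxaa"`, `"aaxab"`, `"abxab"`, `"hom"`, `"untyped"`
#' @export
classify_segregation <- function(maternal_gt, paternal_gt) {
  het <- function(g) {
    a <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)
    vapply(a, function(x) {
      if (length(x) != 2 || anyNA(x) || any(x == ".")) NA
      else x[1] != x[2]
    }, logical(1))
  }
  hm <- het(maternal_gt); hf <- het(paternal_gt)
  out <- rep("untyped", length(hm))
  out[!is.na(hm) & !is.na(hf) &  hm & !hf] <- "abxaa"
  out[!is.na(hm) & !is.na(hf) & !hm &  hf] <- "aaxab"
  out[!is.na(hm) & !is.na(hf) &  hm &  hf] <- "abxab"
  out[!is.na(hm) & !is.na(hf) & !hm & !hf] <- "hom"
  out
}

#' Chi-square test of 1:1 Mendelian segregation
#'
#' For a testcross marker with `n_aa` and `n_ab` progeny in the two
#' genotype classes, the goodness-of-fit statistic against the expected
#' 1:1 ratio is X^2 = (n_aa - n_ab)^2 / (n_aa + n_ab) on 1 df (no
#' continuity correction); p is the upper tail.
#'
#' @param n_aa,n_ab class counts (vectorised)
#' @return data frame with columns `chisq` and `p`; both `NA` where
#'   `n_aa + n_ab` = 0 (such markers are dropped)
#' @examples
#' chi_square_1to1(90, 60)   # chisq 6.00, p 0.0143 -> retained at p >= .01
#' chi_square_1to1(95, 55)   # chisq 10.67, p 0.0011 -> removed
#' @export
chi_square_1to1 <- function(n_aa, n_ab) {
  n <- n_aa + n_ab
  chisq <- ifelse(n > 0, (n_aa - n_ab)^2 / n, NA_real_)
  data.frame(chisq = chisq,
             p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Marker-level quality filter
#'
#' Removes markers deviating from the 1:1 Mendelian ratio (p <
#' `min_segregation_p`) or with strictly more than `max_missing` missing
#' genotypes in the progeny, and keeps only 1:1-segregating types
#' (`abxaa`, `aaxab`) for mapping. Markers with no scorable progeny are
#' dropped.
#'
#' @param gm a [geno_matrix()] (chi-square and missing fraction are
#'   recomputed by the constructor)
#' @param cfg a [filter_config()]
#' @return the filtered `geno_matrix`
#' @export
marker_qc <- function(gm, cfg = filter_config()) {
  stopifnot(inherits(gm, "geno_matrix"))
  mk <- gm$markers
  keep <- !is.na(mk$p) & mk$p >= cfg$min_segregation_p &
    mk$miss_frac <= cfg$max_missing &
    mk$segtype %in% c("abxaa", "aaxab")
  subset_markers(gm, keep)
}

#' Write a filtered marker table as tab-separated text
#'
#' One row per marker: locus id, segregation type, chi-square, p, missing
#' fraction, and the coded genotype vector as a compact string
#' (`a` = aa, `b` = ab, `-` = missing).
#'
#' @param gm a [geno_matrix()]
#' @param path output file
#' @export
write_marker_table <- function(gm, path) {
  g <- gm$calls
  code <- matrix("-", nrow(g), ncol(g))
  code[g == "aa"] <- "a"
  code[g == "ab"] <- "b"
  df <- data.frame(id = gm$markers$id, segtype = gm$markers$segtype,
                   chisq = round(gm$markers$chisq, 4),
                   p = signif(gm$markers$p, 4),
                   miss_frac = round(gm$markers$miss_frac, 4),
                   genotypes = apply(code, 1, paste, collapse = ""))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
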