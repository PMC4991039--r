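#' Read a family VCF into a coded genotype matrix
#'
#' Parses a VCF v4.2 file with GT/DP/GQ per sample and site MQ, applies
#' the discovery filter (site MQ and parental depth, see
#' [discover_parental_sites()]), classifies each site's segregation type
#' from the parental genotypes ([classify_segregation()]), and codes every
#' progeny call against the DP/GQ thresholds ([code_genotypes()]). Marker
#' ids are `CONTIG_POS`. No marker-level QC is applied here; run
#' [marker_qc()] on the result.
#'
#' @param path VCF file (plain text or bgzipped)
#' @param maternal,paternal sample names of the two parents
#' @param cfg a [filter_config()]
#' @return a [geno_matrix()] over the progeny (all samples except the two
#'   parents), with `allele_a`/`allele_b` nucleotide columns and the
#'   source `contig`/`contig_pos` in its marker table
#' @export
read_family_vcf <- function(path, maternal = "mother",
                            paternal = "father",
                            cfg = filter_config()) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(fix) == 0) stop("no variant records in ", path)
  samples <- colnames(v@gt)[-1]
  if (!all(c(maternal, paternal) %in% samples))
    stop("parent samples not found in ", path)
  prog <- setdiff(samples, c(maternal, paternal))
  if (length(prog) == 0) stop("no progeny samples in ", path)
  gt <- vcfR::extract.gt(v, "GT")
  dp <- vcfR::extract.gt(v, "DP", as.numeric = TRUE)
  gq <- vcfR::extract.gt(v, "GQ", as.numeric = TRUE)
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(v, "MQ")))
  contig <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  id <- sprintf("%s_%d", contig, pos)

  # discovery: site MQ and read depth in either parent
  disc <- discover_parental_sites(
    data.frame(id = id, mq = ifelse(is.na(mq), 0, mq),
               dp_mother = dp[, maternal], dp_father = dp[, paternal]),
    cfg)
  keep <- id %in% disc$id

  # parental genotypes must themselves pass the genotyping thresholds
  pgt_ok <- function(par) !is.na(dp[, par]) & !is.na(gq[, par]) &
    dp[, par] >= cfg$min_genotype_dp & gq[, par] > cfg$min_gq &
    !is.na(gt[, par]) & !grepl("\\.", gt[, par])
  mat_gt <- ifelse(pgt_ok(maternal), gt[, maternal], NA)
  pat_gt <- ifelse(pgt_ok(paternal), gt[, paternal], NA)
  segtype <- rep("untyped", length(id))
  both <- !is.na(mat_gt) & !is.na(pat_gt)
  segtype[both] <- classify_segregation(mat_gt[both], pat_gt[both])

  # shared allele "a" = the homozygous parent's allele index
  first_allele <- function(g) as.integer(substr(gsub("|", "/", g,
                                                     fixed = TRUE), 1, 1))
  hom_allele <- ifelse(segtype == "abxaa", first_allele(pat_gt),
                ifelse(segtype == "aaxab", first_allele(mat_gt), NA))

  use <- keep & segtype %in% c("abxaa", "aaxab") & !is.na(hom_allele)
  if (!any(use)) stop("no mappable 1:1 sites in ", path)
  calls <- matrix(NA_character_, sum(use), length(prog),
                  dimnames = list(id[use], prog))
  rows <- which(use)
  for (k in seq_along(rows)) {
    i <- rows[k]
    calls[k, ] <- code_genotypes(gt[i, prog], dp[i, prog], gq[i, prog],
                                 hom_allele = hom_allele[i], cfg = cfg)
  }
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  allele_a <- ifelse(hom_allele[use] == 0L, ref[use], alt[use])
  allele_b <- ifelse(hom_allele[use] == 0L, alt[use], ref[use])
  geno_matrix(calls,
              data.frame(id = id[use], segtype = segtype[use],
                         contig = contig[use], contig_pos = pos[use],
                         allele_a = allele_a, allele_b = allele_b))
}
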