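#' Genotype matrix for a pseudo-testcross family
#'
#' The central container: coded genotype calls for a set of SNP markers
#' across the progeny of an F1 cross, together with per-marker metadata.
#' Calls are coded relative to the segregating (heterozygous) parent:
#' `"aa"` (progeny received the shared allele) or `"ab"` (progeny received
#' the alternative allele), with `NA` for missing. Only markers segregating
#' 1:1 — heterozygous in exactly one parent — are mappable.
#'
#' @param calls character matrix, markers x progeny, values `"aa"`, `"ab"`
#'   or `NA`. Row names are taken as marker ids if `markers` lacks an `id`
#'   column.
#' @param markers data frame of per-marker metadata with at least columns
#'   `id` and `segtype` (one of `"abxaa"` maternal-informative, `"aaxab"`
#'   paternal-informative, `"abxab"`, `"hom"`, `"untyped"`). Optional
#'   columns used downstream: `chrom`, `phys_bp`, `contig`, `contig_pos`,
#'   `allele_a`, `allele_b`, `source`.
#' @return An object of class `geno_matrix`: a list with elements `calls`,
#'   `markers` (with `chisq`, `p` and `miss_frac` columns filled in) and
#'   `progeny`.
#' @seealso [marker_qc()], [pairwise_matrix()], [simulate_progeny()]
#' @export
geno_matrix <- function(calls, markers) {
  if (!is.matrix(calls) || !is.character(calls))
    stop("`calls` must be a character matrix")
  bad <- !is.na(calls) & !(calls %in% c("aa", "ab"))
  if (any(bad))
    stop("coded calls must be 'aa', 'ab' or NA; found: ",
         paste(unique(calls[bad]), collapse = ", "))
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  if (is.null(markers$id)) markers$id <- rownames(calls)
  if (is.null(markers$id)) stop("marker ids missing")
  markers$id <- as.character(markers$id)
  if (anyDuplicated(markers$id)) stop("duplicated marker ids")
  if (nrow(markers) != nrow(calls))
    stop("nrow(markers) != nrow(calls)")
  if (is.null(markers$segtype)) markers$segtype <- "abxaa"
  ok_types <- c("abxaa", "aaxab", "abxab", "hom", "untyped")
  if (!all(markers$segtype %in% ok_types))
    stop("segtype must be one of: ", paste(ok_types, collapse = ", "))
  rownames(calls) <- markers$id
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("P%03d", seq_len(ncol(calls)))
  markers$miss_frac <- rowMeans(is.na(calls))
  n_aa <- rowSums(calls == "aa", na.rm = TRUE)
  n_ab <- rowSums(calls == "ab", na.rm = TRUE)
  chi <- chi_square_1to1(n_aa, n_ab)
  markers$chisq <- chi$chisq
  markers$p <- chi$p
  structure(list(calls = calls, markers = markers,
                 progeny = colnames(calls)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  tab <- table(factor(x$markers$segtype,
                      c("abxaa", "aaxab", "abxab", "hom", "untyped")))
  cat("geno_matrix:", nrow(x$calls), "markers x", ncol(x$calls),
      "progeny\n")
  cat("  segregation types:",
      paste(sprintf("%s=%d", names(tab)[tab > 0], tab[tab > 0]),
            collapse = ", "), "\n")
  cat("  mean missing fraction:",
      sprintf("%.3f", mean(x$markers$miss_frac)), "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by marker
#'
#' @param gm a [geno_matrix()]
#' @param keep logical, integer or character index over markers
#' @return a `geno_matrix` restricted to the selected markers
#' @export
subset_markers <- function(gm, keep) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (is.character(keep)) keep <- match(keep, gm$markers$id)
  geno_matrix(gm$calls[keep, , drop = FALSE],
              gm$markers[keep, , drop = FALSE])
}

#' Extract the markers informative for one parent
#'
#' Markers of type `"abxaa"` are heterozygous in the mother and mappable on
#' the maternal map; `"aaxab"` on the paternal map.
#'
#' @param gm a [geno_matrix()]
#' @param parent `"maternal"` or `"paternal"`
#' @return a `geno_matrix` containing only that parent's testcross markers
#' @export
informative_markers <- function(gm, parent = c("maternal", "paternal")) {
  parent <- match.arg(parent)
  type <- if (parent == "maternal") "abxaa" else "aaxab"
  subset_markers(gm, gm$markers$segtype == type)
}

# internal: calls coded 0 (aa) / 1 (ab) / NA, for matrix arithmetic
coded01 <- function(gm) {
  x <- matrix(NA_real_, nrow(gm$calls), ncol(gm$calls),
              dimnames = dimnames(gm$calls))
  x[gm$calls == "aa"] <- 0
  x[gm$calls == "ab"] <- 1
  x
}
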