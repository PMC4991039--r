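#' Assemble ordered linkage groups into a parental map
#'
#' For each ordered group, converts adjacent recombination fractions to
#' Kosambi centiMorgans, accumulates positions from 0 and copies the
#' predicted linkage phase between adjacent markers from the two-point
#' estimates. An adjacent fraction of 0.5 means the ordering produced a
#' broken chain and is an error.
#'
#' @param orders named list of `marker_order` objects (one per group, see
#'   [order_group()])
#' @param pm pairwise matrices from [pairwise_matrix()] (`rf` and `phase`
#'   are used)
#' @param parent_prefix optional single letter prepended to marker names
#'   in reports (maps are conventionally lettered by parent)
#' @return a `linkage_map` data frame: `group`, `rank`, `id`, `r_next`,
#'   `interval_cM`, `cum_cM`, `phase_next`
#' @export
build_map <- function(orders, pm, parent_prefix = "") {
  if (length(orders) == 0)
    stop("no ordered linkage groups to assemble")
  phase_name <- c("repulsion", "undetermined", "coupling")
  rows <- lapply(names(orders), function(gname) {
    o <- orders[[gname]]$order
    n <- length(o)
    if (n == 1)
      return(data.frame(group = gname, rank = 1L,
                        id = paste0(parent_prefix, o), r_next = NA,
                        interval_cM = NA, cum_cM = 0,
                        phase_next = NA))
    r_adj <- pm$rf[cbind(o[-n], o[-1])]
    if (any(r_adj >= 0.5))
      stop("adjacent recombination fraction of 0.5 in group ", gname,
           ": broken chain")
    ph <- phase_name[pm$phase[cbind(o[-n], o[-1])] + 2]
    d <- kosambi_distance(r_adj)
    data.frame(group = gname, rank = seq_len(n),
               id = paste0(parent_prefix, o),
               r_next = c(r_adj, NA),
               interval_cM = c(d, NA),
               cum_cM = c(0, cumsum(d)),
               phase_next = c(ph, NA))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("linkage_map", "data.frame")
  out
}

#' Summary statistics of a linkage map
#'
#' Per-group SNP number and genetic length, plus map totals. The mean
#' adjacent interval is total length / (marker count - group count), the
#' identity under which a 2012-marker, 19-group, 4067.16 cM map has a
#' 2.04 cM mean interval.
#'
#' @param map a `linkage_map` from [build_map()]
#' @return list with `per_group` (data frame: `group`, `n_snp`,
#'   `length_cM`, `max_interval_cM`, `min_interval_cM`) and `totals`
#'   (`n_groups`, `n_snp`, `length_cM`, `mean_interval_cM`,
#'   `max_interval_cM`)
#' @export
map_summary <- function(map) {
  sp <- split(map, map$group)
  per_group <- do.call(rbind, lapply(sp, function(g)
    data.frame(group = g$group[1], n_snp = nrow(g),
               length_cM = round(max(g$cum_cM), 2),
               max_interval_cM = round(suppressWarnings(
                 max(g$interval_cM, na.rm = TRUE)), 2),
               min_interval_cM = round(suppressWarnings(
                 min(g$interval_cM, na.rm = TRUE)), 2))))
  rownames(per_group) <- NULL
  n_groups <- nrow(per_group)
  n_snp <- sum(per_group$n_snp)
  len <- sum(per_group$length_cM)
  list(per_group = per_group,
       totals = list(
         n_groups = n_groups, n_snp = n_snp,
         length_cM = round(len, 2),
         mean_interval_cM = round(len / (n_snp - n_groups), 2),
         max_interval_cM = max(per_group$max_interval_cM)))
}

#' Per-megabase genetic length difference between two homologous groups
#'
#' Contrast of the two parents' genetic lengths for the same chromosome,
#' normalised by physical size: |lenB - lenA| / size, reported to 2
#' decimals. Values above ~3 cM/Mb flag localised recombination-rate
#' differences between the parents (e.g. recombination suppression near a
#' sex-determination region).
#'
#' @param len_a,len_b group lengths in cM on the two maps
#' @param chrom_size_mb physical chromosome size in Mb (> 0)
#' @return cM-per-Mb difference(s), rounded to 2 decimals
#' @export
per_mb_length_difference <- function(len_a, len_b, chrom_size_mb) {
  if (any(chrom_size_mb <= 0)) stop("chromosome size must be positive")
  round(abs(len_b - len_a) / chrom_size_mb, 2)
}

#' Pearson correlations among per-group map statistics
#'
#' Correlates per-linkage-group statistics (e.g. SNP number and genetic
#' length on each parental map, and physical chromosome size) across
#' groups, to 4 decimals.
#'
#' @param stats data frame of aligned per-group statistics (one row per
#'   linkage group, >= 3 rows), numeric columns only
#' @param digits rounding of the reported coefficients
#' @return the correlation matrix
#' @export
group_stat_correlations <- function(stats, digits = 4) {
  stats <- as.data.frame(stats)
  num <- stats[vapply(stats, is.numeric, logical(1))]
  if (nrow(num) < 3) stop("need at least 3 groups for correlations")
  round(cor(as.matrix(num)), digits)
}

#' Genetic-versus-physical collinearity table
#'
#' Joins mapped markers to a physical anchor table (marker id,
#' chromosome, position) and reports, per linkage group, the (physical
#' Mb, genetic cM) point pairs plus the fraction of mapped markers that
#' are anchored and the per-group Spearman rank correlation between
#' genetic and physical position (|rho| = 1 for perfectly collinear
#' groups, the sign depending on group orientation).
#'
#' @param map a `linkage_map` from [build_map()]
#' @param anchors data frame with columns `id`, `chrom`, `bp`
#' @return list with `points` (data frame `id`, `group`, `cum_cM`,
#'   `chrom`, `bp`, `mb`), `n_anchored`, `n_markers`, `anchored_pct` (to
#'   1 decimal), `per_group_rho`
#' @export
collinearity_points <- function(map, anchors) {
  if (is.null(anchors) || nrow(anchors) == 0) {
    warning("no physical anchors supplied: empty collinearity table")
    return(list(points = data.frame(), n_anchored = 0L,
                n_markers = nrow(map), anchored_pct = 0,
                per_group_rho = numeric()))
  }
  hit <- match(map$id, anchors$id)
  points <- data.frame(id = map$id, group = map$group,
                       cum_cM = map$cum_cM,
                       chrom = anchors$chrom[hit],
                       bp = anchors$bp[hit])[!is.na(hit), ]
  points$mb <- points$bp / 1e6
  rho <- vapply(split(points, points$group), function(g)
    if (nrow(g) < 2) NA_real_
    else suppressWarnings(cor(g$cum_cM, g$bp, method = "spearman")),
    numeric(1))
  list(points = points, n_anchored = nrow(points),
       n_markers = nrow(map),
       anchored_pct = round(100 * nrow(points) / nrow(map), 1),
       per_group_rho = rho)
}

#' Per-linkage-group summary of a published poplar F1 map pair
#'
#' Summary statistics of a pair of parent-specific linkage maps from a
#' *Populus deltoides* x *P. simonii* F1 family genotyped by sequencing:
#' for each of the 19 linkage groups, the SNP number and genetic length
#' on the maternal and paternal maps, the number of those SNPs anchored
#' to the *P. trichocarpa* reference genome, and the physical chromosome
#' size. Bundled as a worked real-data example for the reporting
#' functions ([map_summary()] arithmetic, [group_stat_correlations()],
#' [per_mb_length_difference()], anchored fractions).
#'
#' @return data frame with one row per linkage group plus columns
#'   `group`, `snp_maternal`, `anchored_maternal`, `length_maternal_cM`,
#'   `snp_paternal`, `anchored_paternal`, `length_paternal_cM`,
#'   `chrom_size_Mb`
#' @export
poplar_map_summary <- function() {
  read.delim(system.file("extdata", "poplar_f1_map_summary.tsv",
                         package = "ptcmap"),
             stringsAsFactors = FALSE)
}
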