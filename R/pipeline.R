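#' Configuration for an end-to-end simulated mapping run
#'
#' Bundles every knob of the pipeline: simulated family design, noise
#' rates, dual-view divergence, filter thresholds, grouping and ordering
#' settings. Defaults describe a 19-chromosome genome (the *Populus*
#' karyotype) with 20 markers per parent per chromosome at ~5 cM
#' same-parent spacing, a family of 150 progeny, and modest noise.
#'
#' @param n_progeny family size
#' @param n_chrom,markers_per_parent,spacing_cM,spacing_bp,contig_bp
#'   passed to [make_parent_spec()]
#' @param missing_rate,error_rate passed to [degrade()]
#' @param distortion fraction of distorted markers (see
#'   [simulate_progeny()])
#' @param drop_p,flip_p,lowqual_p,mq_low_p passed to [emit_dual_views()]
#' @param filter a [filter_config()]
#' @param lod_threshold LOD grouping threshold, or `NULL` to auto-scan
#'   towards `expected_groups`
#' @param expected_groups target group count for the auto-scan
#' @param restarts ordering restarts per group
#' @param bin_window_bp marker binning window
#' @param seed master seed for every stage
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(n_progeny = 150, n_chrom = 19,
                            markers_per_parent = 20, spacing_cM = 5,
                            spacing_bp = 50000, contig_bp = 5000,
                            missing_rate = 0.05, error_rate = 0.005,
                            distortion = 0,
                            drop_p = c(0.05, 0.05), flip_p = 0.002,
                            lowqual_p = 0.02, mq_low_p = 0.01,
                            filter = filter_config(),
                            lod_threshold = 6, expected_groups = NULL,
                            restarts = 20L, bin_window_bp = 1000,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full simulate-filter-crossvalidate-map pipeline
#'
#' Drives every stage on a simulated family: meiosis simulation,
#' degradation, emission of two reference-view VCFs, VCF re-import and
#' the genotype/marker filter cascade per view, cross-validation of the
#' two views by genotype-vector identity, marker binning, and — per
#' parent — two-point linkage matrices, LOD grouping, minimum-SARF
#' ordering and Kosambi map construction with summaries and a
#' genetic-versus-physical collinearity report against the simulator's
#' true positions.
#'
#' @param config a [pipeline_config()]
#' @param out_dir directory for artifacts (VCFs, truth/marker/match/bin
#'   tables, matrices, groups, maps, summaries, run log); created if
#'   needed. With `NULL`, VCFs go to a temporary directory and nothing
#'   else is written.
#' @return a `ptc_pipeline` list: `truth`, `observed`, `views`, `key`,
#'   per-view filtered matrices, `matches`, `matched`, `bins`, and per
#'   parent (`maternal`, `paternal`): `pm`, `groups`, `orders`, `map`,
#'   `summary`, `collinearity`
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$n_progeny < 1) stop("empty progeny set")
  cfg <- config$filter
  keep_artifacts <- !is.null(out_dir)
  if (keep_artifacts) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  } else out_dir <- tempfile("ptcmap_run_")
  dir.create(out_dir, showWarnings = FALSE)

  spec <- make_parent_spec(config$n_chrom, config$markers_per_parent,
                           config$spacing_cM, config$spacing_bp,
                           config$contig_bp)
  truth <- simulate_progeny(spec, config$n_progeny, seed = config$seed,
                            distortion = config$distortion)
  observed <- degrade(truth, config$missing_rate, config$error_rate,
                      seed = config$seed)
  dual <- emit_dual_views(observed, drop_p = config$drop_p,
                          flip_p = config$flip_p,
                          lowqual_p = config$lowqual_p,
                          mq_low_p = config$mq_low_p,
                          seed = config$seed)
  paths <- list(PD = file.path(out_dir, "view_PD.vcf"),
                PS = file.path(out_dir, "view_PS.vcf"))
  write_view_vcf(dual$views$D, paths$PD)
  write_view_vcf(dual$views$S, paths$PS)

  # per-view import + filter cascade
  filtered <- lapply(paths, function(p)
    marker_qc(read_family_vcf(p, cfg = cfg), cfg))

  # cross-validation: PD is the mapping unit
  matches <- match_identical_loci(filtered$PD, filtered$PS)
  matched <- crossval_matched(filtered$PD, matches)
  binned <- bin_markers(matched, config$bin_window_bp)
  mapped_set <- binned$representatives

  # locus -> true marker key (for truth-anchored reports)
  key_of <- setNames(dual$key$marker_id, dual$key$locus_D)
  anchors <- data.frame(id = truth$markers$id,
                        chrom = truth$markers$chrom,
                        bp = truth$markers$phys_bp)

  one_parent <- function(parent) {
    gm <- informative_markers(mapped_set, parent)
    if (nrow(gm$calls) < 2) stop("too few ", parent, " markers")
    pm <- pairwise_matrix(gm)
    th <- config$lod_threshold
    scan <- NULL
    if (is.null(th)) {
      sel <- select_threshold(pm$lod, config$expected_groups)
      th <- sel$threshold; scan <- sel$scan
    }
    groups <- group_markers(pm$lod, th)
    multi <- groups$groups[lengths(groups$groups) > 1]
    if (length(multi) == 0)
      stop("no multi-marker ", parent, " linkage groups at LOD ", th,
           ": too few cross-validated markers for this design")
    orders <- lapply(multi, function(ids)
      order_group(pm$rf[ids, ids, drop = FALSE],
                  restarts = config$restarts, seed = config$seed))
    map <- build_map(orders, pm,
                     parent_prefix = "")
    truth_ids <- key_of[map$id]
    coll <- collinearity_points(
      within(map, id <- unname(truth_ids)), anchors)
    list(pm = pm, groups = groups, threshold = th, scan = scan,
         orders = orders, map = map, summary = map_summary(map),
         collinearity = coll)
  }
  maternal <- one_parent("maternal")
  paternal <- one_parent("paternal")

  res <- structure(list(config = config, truth = truth,
                        observed = observed, views = dual$views,
                        key = dual$key, vcf_paths = paths,
                        filtered = filtered, matches = matches,
                        matched = matched, bins = binned$bins,
                        mapped_set = mapped_set,
                        maternal = maternal, paternal = paternal),
                   class = "ptc_pipeline")
  if (keep_artifacts) write_pipeline_artifacts(res, out_dir)
  res
}

#' @export
print.ptc_pipeline <- function(x, ...) {
  cat("ptcmap pipeline run (seed ", x$config$seed, ")\n", sep = "")
  cat("  simulated markers:", nrow(x$truth$calls), "x",
      ncol(x$truth$calls), "progeny\n")
  cat("  filtered:", nrow(x$filtered$PD$calls), "(PD) /",
      nrow(x$filtered$PS$calls), "(PS); cross-validated:",
      nrow(x$matched$calls), "; after binning:",
      nrow(x$mapped_set$calls), "\n")
  for (p in c("maternal", "paternal")) {
    tt <- x[[p]]$summary$totals
    cat(sprintf("  %s map: %d groups, %d SNPs, %.2f cM, mean interval %.2f cM\n",
                p, tt$n_groups, tt$n_snp, tt$length_cM,
                tt$mean_interval_cM))
  }
  invisible(x)
}

#' Evaluate order recovery of a pipeline run against simulator truth
#'
#' Maps every ordered group's loci back to the simulator's marker ids via
#' the dual-view key and compares each group's estimated order with the
#' true chromosome order using [order_agreement()] (reversal-invariant;
#' zero-recombination ties excluded). A group spanning markers of more
#' than one true chromosome is reported as not recovered.
#'
#' @param res a `ptc_pipeline` result
#' @param parent `"maternal"` or `"paternal"`
#' @return data frame: `group`, `chrom`, `n_markers`, `discordant`,
#'   `exact`
#' @export
pipeline_order_recovery <- function(res,
                                    parent = c("maternal", "paternal")) {
  parent <- match.arg(parent)
  key_of <- setNames(res$key$marker_id, res$key$locus_D)
  truth_order <- attr(res$truth, "truth")$order
  mk <- res$truth$markers
  pr <- res[[parent]]
  out <- lapply(names(pr$orders), function(g) {
    est_loci <- pr$orders[[g]]$order
    est <- unname(key_of[est_loci])
    chrom <- unique(mk$chrom[match(est, mk$id)])
    if (length(chrom) != 1)
      return(data.frame(group = g, chrom = NA, n_markers = length(est),
                        discordant = NA_integer_, exact = FALSE))
    ref <- intersect(truth_order[[chrom]], est)
    rf <- pr$pm$rf[est_loci, est_loci, drop = FALSE]
    dimnames(rf) <- list(est, est)
    ag <- order_agreement(est, ref, rf)
    data.frame(group = g, chrom = chrom, n_markers = length(est),
               discordant = ag$discordant, exact = ag$exact)
  })
  do.call(rbind, out)
}

# writes every tabular artifact of a finished run
write_pipeline_artifacts <- function(res, out_dir) {
  w <- function(df, f) write.table(df, file.path(out_dir, f),
                                   sep = "\t", quote = FALSE,
                                   row.names = FALSE)
  write_truth_table(res$truth, file.path(out_dir, "truth_markers.tsv"))
  write_marker_table(res$filtered$PD, file.path(out_dir,
                                                "filtered_PD.tsv"))
  write_marker_table(res$filtered$PS, file.path(out_dir,
                                                "filtered_PS.tsv"))
  w(res$matches, "matches.tsv")
  w(res$bins, "bins.tsv")
  for (p in c("maternal", "paternal")) {
    pr <- res[[p]]
    write_linkage_matrix(pr$pm$rf,
                         file.path(out_dir, paste0(p, "_rf.tsv")))
    write_linkage_matrix(pr$pm$lod,
                         file.path(out_dir, paste0(p, "_lod.tsv")))
    w(cbind(pr$groups$assignment, threshold = pr$threshold),
      paste0(p, "_groups.tsv"))
    w(res[[p]]$map, paste0(p, "_map.tsv"))
    w(pr$summary$per_group, paste0(p, "_summary.tsv"))
    w(pr$collinearity$points, paste0(p, "_collinearity.tsv"))
  }
  log <- c(sprintf("seed\t%d", res$config$seed),
           sprintf("n_progeny\t%d", res$config$n_progeny),
           sprintf("lod_threshold_maternal\t%s", res$maternal$threshold),
           sprintf("lod_threshold_paternal\t%s", res$paternal$threshold),
           vapply(names(res$config$filter), function(k)
             sprintf("filter.%s\t%s", k, res$config$filter[[k]]), ""))
  writeLines(log, file.path(out_dir, "run_log.tsv"))
  invisible(out_dir)
}
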