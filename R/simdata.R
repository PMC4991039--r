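#' Run an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so simulator calls are
#' reproducible without disturbing the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic stage-specific child seed below 2^31, derived from the
# master seed and a stage label
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 99991L
  (as.integer(seed) %% 20000000L) * 100L + h %% 100L + h
}

#' Marker layout specification for an F1 pseudo-testcross simulation
#'
#' Builds the true genome model of the cross: chromosomes carrying
#' interleaved maternal-informative (`abxaa`) and paternal-informative
#' (`aaxab`) markers, per-interval true recombination fractions, physical
#' positions and a fragmentation of each chromosome into contigs (mimicking
#' a rough draft assembly).
#'
#' Markers alternate maternal/paternal along each chromosome; the
#' per-interval recombination fraction is chosen so that two consecutive
#' same-parent markers are separated by `spacing_cM` Kosambi centiMorgans
#' (the composite fraction over intervening intervals is
#' r = (1 - prod(1 - 2 r_k))/2 under independent interval recombination).
#'
#' @param n_chrom number of chromosomes
#' @param markers_per_parent markers informative for each parent on each
#'   chromosome (total markers per chromosome is twice this)
#' @param spacing_cM Kosambi map distance between consecutive same-parent
#'   markers
#' @param spacing_bp physical distance between consecutive markers (any
#'   type), base pairs
#' @param contig_bp contig length used to fragment each chromosome
#' @return a `parent_spec` list of chromosome models; each chromosome has
#'   `n_markers`, `r` (length n_markers - 1), `segtype`, `phys_bp`,
#'   `contig`, `contig_pos`
#' @export
make_parent_spec <- function(n_chrom = 19, markers_per_parent = 20,
                             spacing_cM = 5, spacing_bp = 50000,
                             contig_bp = 5000) {
  stopifnot(n_chrom >= 1, markers_per_parent >= 1)
  r_same <- kosambi_inverse(spacing_cM)
  # split one same-parent interval into two equal sub-intervals
  r_half <- (1 - sqrt(1 - 2 * r_same)) / 2
  chroms <- lapply(seq_len(n_chrom), function(cc) {
    nm <- 2L * markers_per_parent
    pos <- seq_len(nm) * spacing_bp
    list(n_markers = nm,
         r = rep(r_half, nm - 1L),
         segtype = rep(c("abxaa", "aaxab"), markers_per_parent),
         phys_bp = pos,
         contig = sprintf("C%02d_%05d", cc, pos %/% contig_bp),
         contig_pos = pos %% contig_bp + 1L)
  })
  names(chroms) <- sprintf("chr%02d", seq_len(n_chrom))
  validate_parent_spec(structure(chroms, class = "parent_spec"))
}

validate_parent_spec <- function(spec) {
  for (ch in spec) {
    if (any(ch$r < 0) || any(ch$r >= 0.5))
      stop("per-interval recombination fractions must lie in [0, 0.5)")
    if (length(ch$r) != ch$n_markers - 1L)
      stop("need one recombination fraction per adjacent marker pair")
    if (any(diff(ch$phys_bp) <= 0))
      stop("physical positions must be strictly increasing")
    if (!all(ch$segtype %in% c("abxaa", "aaxab")))
      stop("segregation type must be abxaa or aaxab")
  }
  spec
}

#' True recombination fraction between two markers of a simulated genome
#'
#' Composite fraction over the intervals between markers `i` and `j` of
#' one chromosome, r = (1 - prod(1 - 2 r_k))/2, under independent
#' per-interval recombination.
#'
#' @param spec a [make_parent_spec()] object
#' @param chrom chromosome name or index
#' @param i,j marker indices on that chromosome
#' @return the true recombination fraction
#' @export
true_rf <- function(spec, chrom, i, j) {
  ch <- spec[[chrom]]
  lo <- min(i, j); hi <- max(i, j)
  if (lo == hi) return(0)
  (1 - prod(1 - 2 * ch$r[lo:(hi - 1L)])) / 2
}

#' Simulate true progeny genotypes of an F1 pseudo-testcross
#'
#' For each progeny and each parent, a transmitted haplotype is simulated
#' along every chromosome: the starting allele is drawn uniformly and
#' switches between adjacent markers independently with the interval's
#' true recombination fraction (no crossover interference). At a
#' maternal-informative (`abxaa`) marker the progeny is `"ab"` when the
#' mother transmits her alternative allele and `"aa"` otherwise; paternal
#' markers are analogous. Parents are simulated error-free and fully
#' genotyped.
#'
#' @param spec a [make_parent_spec()] layout
#' @param n number of progeny (>= 1)
#' @param seed master simulation seed
#' @param distortion fraction of markers subjected to segregation
#'   distortion (local viability selection against the `"ab"` class)
#' @param distortion_strength per-progeny probability that a distorted
#'   marker's `"ab"` call is replaced by `"aa"`
#' @return a [geno_matrix()] of true calls; the attribute `"truth"` holds
#'   the spec, seed and per-chromosome marker order for downstream
#'   validation
#' @export
simulate_progeny <- function(spec, n, seed = 1L, distortion = 0,
                             distortion_strength = 0.3) {
  validate_parent_spec(spec)
  stopifnot(n >= 1, distortion >= 0, distortion <= 1)
  with_seed(child_seed(seed, "meiosis"), {
    per_chrom <- lapply(names(spec), function(cn) {
      ch <- spec[[cn]]
      nm <- ch$n_markers
      transmit <- function() {
        h <- matrix(0L, nm, n)
        h[1, ] <- rbinom(n, 1L, 0.5)
        for (k in seq_len(nm - 1L))
          h[k + 1L, ] <- (h[k, ] + rbinom(n, 1L, ch$r[k])) %% 2L
        h
      }
      hm <- transmit()   # maternal meiosis
      hp <- transmit()   # paternal meiosis
      mat <- ch$segtype == "abxaa"
      h <- hm
      h[!mat, ] <- hp[!mat, ]
      calls <- matrix(ifelse(h == 1L, "ab", "aa"), nm, n)
      ids <- sprintf("%s_m%03d", cn, seq_len(nm))
      list(calls = calls,
           markers = data.frame(id = ids, segtype = ch$segtype,
                                chrom = cn, order_idx = seq_len(nm),
                                phys_bp = ch$phys_bp, contig = ch$contig,
                                contig_pos = ch$contig_pos))
    })
    calls <- do.call(rbind, lapply(per_chrom, `[[`, "calls"))
    markers <- do.call(rbind, lapply(per_chrom, `[[`, "markers"))
    colnames(calls) <- sprintf("P%03d", seq_len(n))
    if (distortion > 0) {
      hit <- runif(nrow(calls)) < distortion
      for (i in which(hit)) {
        ab <- which(calls[i, ] == "ab")
        flip <- ab[runif(length(ab)) < distortion_strength]
        calls[i, flip] <- "aa"
      }
    }
    gm <- geno_matrix(calls, markers)
    attr(gm, "truth") <- list(
      spec = spec, seed = seed, distortion = distortion,
      order = split(markers$id, markers$chrom))
    gm
  })
}

#' Degrade a true genotype matrix with missingness and call errors
#'
#' Each progeny call is independently set missing with probability
#' `missing_rate`; each surviving call is flipped `aa <-> ab` with
#' probability `error_rate`. Marker metadata (and the parental genotypes
#' they encode) are untouched.
#'
#' @param gm a [geno_matrix()] of true calls
#' @param missing_rate,error_rate proportions in \[0, 1\]
#' @param seed seed for the degradation draws
#' @return the degraded `geno_matrix` (truth attribute preserved)
#' @export
degrade <- function(gm, missing_rate = 0.05, error_rate = 0.005,
                    seed = 1L) {
  stopifnot(inherits(gm, "geno_matrix"),
            missing_rate >= 0, missing_rate <= 1,
            error_rate >= 0, error_rate <= 1)
  with_seed(child_seed(seed, "degrade"), {
    calls <- gm$calls
    nc <- length(calls)
    miss <- runif(nc) < missing_rate
    err <- runif(nc) < error_rate
    flip <- !miss & err & !is.na(calls)
    calls[flip] <- ifelse(calls[flip] == "aa", "ab", "aa")
    calls[miss] <- NA_character_
    out <- geno_matrix(calls, gm$markers)
    attr(out, "truth") <- attr(gm, "truth")
    out
  })
}

#' Emit two reference views of one simulated family
#'
#' Emulates calling the same F1 family twice, once against each parent's
#' rough reference assembly. Each view renames loci into view-specific
#' contig coordinates, independently drops loci (divergence between the
#' references), injects independent per-call flips, assigns view-specific
#' ref/alt nucleotides (so nucleotide labels differ between views even
#' where coded genotypes agree), and draws DP/GQ/MQ so that configured
#' fractions of calls and sites fail the genotyping thresholds. A key
#' table records which loci in the two views are the same underlying
#' marker.
#'
#' @param gm the observed [geno_matrix()] (after [degrade()])
#' @param drop_p length-2 probabilities of dropping each locus from the
#'   first/second view
#' @param flip_p per-call probability of an independent view-specific
#'   `aa <-> ab` flip (progeny only)
#' @param lowqual_p fraction of progeny calls given DP/GQ failing the
#'   genotyping thresholds
#' @param mq_low_p fraction of sites given mapping quality below the
#'   discovery threshold
#' @param prefixes two single-letter view prefixes used in contig names
#' @param seed seed for all view-specific draws
#' @return list with `views` (two `sim_view` objects, each with `loci`,
#'   `calls`, `dp`, `gq` and parental fields) and `key` (data frame
#'   mapping marker id to the locus id in each view, `NA` where dropped)
#' @seealso [write_view_vcf()]
#' @export
emit_dual_views <- function(gm, drop_p = c(0.05, 0.05), flip_p = 0.002,
                            lowqual_p = 0.02, mq_low_p = 0.01,
                            prefixes = c("D", "S"), seed = 1L) {
  stopifnot(inherits(gm, "geno_matrix"), length(drop_p) == 2,
            all(drop_p >= 0 & drop_p <= 1), flip_p >= 0, flip_p <= 1)
  nm <- nrow(gm$calls)
  bases <- c("A", "C", "G", "T")
  one_view <- function(vseed, drop, prefix) {
    with_seed(vseed, {
      keep <- runif(nm) >= drop
      mk <- gm$markers[keep, , drop = FALSE]
      calls <- gm$calls[keep, , drop = FALSE]
      nv <- nrow(mk); np <- ncol(calls)
      if (nv == 0)
        return(structure(list(
          loci = data.frame(locus = character(), marker_id = character(),
                            contig = character(), pos = integer(),
                            segtype = character(), allele_a = character(),
                            allele_b = character(), a_is_ref = logical(),
                            mq = integer()),
          calls = calls, dp = calls, gq = calls,
          progeny = colnames(calls),
          parent_dp = integer(), parent_gq = integer()),
          class = "sim_view"))
      # independent view-specific call errors
      flip <- matrix(runif(nv * np) < flip_p, nv, np) & !is.na(calls)
      calls[flip] <- ifelse(calls[flip] == "aa", "ab", "aa")
      # view-specific alleles and coordinates
      allele_a <- sample(bases, nv, replace = TRUE)
      allele_b <- vapply(allele_a,
                         function(a) sample(setdiff(bases, a), 1), "")
      a_is_ref <- runif(nv) < 0.5
      contig <- paste0(prefix, mk$contig)
      locus <- sprintf("%s_%d", contig, mk$contig_pos)
      mq <- ifelse(runif(nv) < mq_low_p,
                   sample(0:19, nv, replace = TRUE), 60L)
      draw_dp <- function(n) 10L + rpois(n, 15)
      draw_gq <- function(n) 51L + sample.int(48L, n, replace = TRUE)
      dp <- matrix(draw_dp(nv * np), nv, np)
      gq <- matrix(draw_gq(nv * np), nv, np)
      low <- matrix(runif(nv * np) < lowqual_p, nv, np)
      # a low-quality call fails depth or quality (or both)
      which_fail <- matrix(sample.int(3L, nv * np, replace = TRUE), nv, np)
      dp[low & which_fail != 2L] <- sample(0:9, sum(low & which_fail != 2L),
                                           replace = TRUE)
      gq[low & which_fail != 1L] <- sample(0:50, sum(low & which_fail != 1L),
                                           replace = TRUE)
      dp[is.na(calls)] <- 0L
      gq[is.na(calls)] <- 0L
      loci <- data.frame(locus = locus, marker_id = mk$id,
                         contig = contig, pos = mk$contig_pos,
                         segtype = mk$segtype,
                         allele_a = allele_a, allele_b = allele_b,
                         a_is_ref = a_is_ref, mq = mq)
      structure(list(loci = loci, calls = calls, dp = dp, gq = gq,
                     progeny = colnames(calls),
                     parent_dp = draw_dp(2L * nv),
                     parent_gq = draw_gq(2L * nv)),
                class = "sim_view")
    })
  }
  v1 <- one_view(child_seed(seed, "view1"), drop_p[1], prefixes[1])
  v2 <- one_view(child_seed(seed, "view2"), drop_p[2], prefixes[2])
  key <- data.frame(marker_id = gm$markers$id)
  key[[paste0("locus_", prefixes[1])]] <-
    v1$loci$locus[match(key$marker_id, v1$loci$marker_id)]
  key[[paste0("locus_", prefixes[2])]] <-
    v2$loci$locus[match(key$marker_id, v2$loci$marker_id)]
  views <- list(v1, v2)
  names(views) <- prefixes
  list(views = views, key = key)
}

#' Write a simulated reference view as a VCF v4.2 file
#'
#' One record per locus, contig-sorted, with GT, DP and GQ per sample
#' (mother, father, then progeny), site mapping quality in INFO/MQ, and
#' 1-based positions. Plain text, byte-identical for identical inputs.
#'
#' @param view a `sim_view` from [emit_dual_views()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_view_vcf <- function(view, path) {
  loci <- view$loci
  ord <- order(loci$contig, loci$pos)
  loci <- loci[ord, , drop = FALSE]
  calls <- view$calls[ord, , drop = FALSE]
  dp <- view$dp[ord, , drop = FALSE]
  gq <- view$gq[ord, , drop = FALSE]
  pdp <- matrix(view$parent_dp, ncol = 2)[ord, , drop = FALSE]
  pgq <- matrix(view$parent_gq, ncol = 2)[ord, , drop = FALSE]
  nv <- nrow(loci)
  ref <- ifelse(loci$a_is_ref, loci$allele_a, loci$allele_b)
  alt <- ifelse(loci$a_is_ref, loci$allele_b, loci$allele_a)
  a_idx <- ifelse(loci$a_is_ref, 0L, 1L)   # index of the shared allele
  b_idx <- 1L - a_idx
  gt_of <- function(code) ifelse(is.na(code), "./.",
    ifelse(code == "aa", sprintf("%d/%d", a_idx, a_idx),
           sprintf("%d/%d", pmin(a_idx, b_idx), pmax(a_idx, b_idx))))
  # parental genotypes implied by the segregation type
  mother <- ifelse(loci$segtype == "abxaa", gt_of(rep("ab", nv)),
                   gt_of(rep("aa", nv)))
  father <- ifelse(loci$segtype == "aaxab", gt_of(rep("ab", nv)),
                   gt_of(rep("aa", nv)))
  fmt_sample <- function(gt, d, q) sprintf("%s:%d:%d", gt, d, q)
  prog_cols <- vapply(seq_along(view$progeny), function(j)
    fmt_sample(gt_of(calls[, j]), dp[, j], gq[, j]),
    character(nv))
  if (is.null(dim(prog_cols)))
    prog_cols <- matrix(prog_cols, nrow = nv)
  body <- paste(loci$contig, loci$pos, loci$locus, ref, alt, ".",
                "PASS", sprintf("MQ=%d", loci$mq), "GT:DP:GQ",
                fmt_sample(mother, pdp[, 1], pgq[, 1]),
                fmt_sample(father, pdp[, 2], pgq[, 2]),
                apply(prog_cols, 1, paste, collapse = "\t"),
                sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ptcmap simulator",
    sprintf("##contig=<ID=%s>", unique(loci$contig)),
    "##INFO=<ID=MQ,Number=1,Type=Integer,Description=\"RMS mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "mother", "father", view$progeny),
          collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the simulation truth tables
#'
#' Tab-separated truth: marker id, chromosome, order index, true
#' recombination fraction to the next marker, physical position, contig
#' and within-contig position.
#'
#' @param gm a simulated [geno_matrix()] carrying a `"truth"` attribute
#' @param path output file
#' @export
write_truth_table <- function(gm, path) {
  truth <- attr(gm, "truth")
  if (is.null(truth)) stop("no truth attribute: not a simulated matrix")
  mk <- gm$markers
  r_next <- unlist(lapply(names(truth$spec), function(cn)
    c(truth$spec[[cn]]$r, NA)), use.names = FALSE)
  df <- data.frame(id = mk$id, chrom = mk$chrom,
                   order_idx = mk$order_idx, r_next = r_next,
                   phys_bp = mk$phys_bp, contig = mk$contig,
                   contig_pos = mk$contig_pos)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
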