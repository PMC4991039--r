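#' Find SNP loci called identically in two reference views
#'
#' Cross-validates two genotype call sets over the same progeny (e.g. the
#' same family called against each parent's rough reference): for every
#' marker in `A`, reports all markers in `B` of the same segregation type
#' whose coded genotype vectors are identical, i.e. whose Hamming distance
#' is zero. Matching is on coded (`aa`/`ab`) vectors, never on nucleotide
#' labels — ref/alt labels differ between references even at the same
#' underlying site.
#'
#' Under the default `"coobserved"` policy, progeny missing in either
#' vector are excluded and equality is required at all co-observed
#' positions; `"strict"` additionally requires identical missingness, so
#' the full vectors must be equal.
#'
#' @param A,B [geno_matrix()] objects coded over the same progeny
#' @param policy missing-data handling, `"coobserved"` (default) or
#'   `"strict"`
#' @param min_overlap minimum number of co-observed progeny for a
#'   comparison to count (guards against vacuous matches)
#' @return data frame with columns `id_a`, `id_b`, `segtype`,
#'   `n_compared`; every reported pair has Hamming distance 0
#' @export
match_identical_loci <- function(A, B,
                                 policy = c("coobserved", "strict"),
                                 min_overlap = 1L) {
  policy <- match.arg(policy)
  stopifnot(inherits(A, "geno_matrix"), inherits(B, "geno_matrix"))
  if (!identical(A$progeny, B$progeny))
    stop("the two datasets are coded over different progeny lists")
  np <- length(A$progeny)
  out <- list()
  for (st in intersect(unique(A$markers$segtype),
                       unique(B$markers$segtype))) {
    ia <- which(A$markers$segtype == st)
    ib <- which(B$markers$segtype == st)
    la <- A$calls[ia, , drop = FALSE]
    lb <- B$calls[ib, , drop = FALSE]
    oa <- !is.na(la); ob <- !is.na(lb)
    n_co <- oa %*% t(ob)
    # count agreeing co-observed positions, level by level (works for
    # coded aa/ab calls and for nucleotide-labelled calls alike)
    same <- matrix(0, nrow(la), nrow(lb))
    for (lev in union(la[oa], lb[ob])) {
      va <- (la == lev) & oa
      vb <- (lb == lev) & ob
      same <- same + va %*% t(vb)
    }
    hit <- (n_co - same) == 0 & n_co >= min_overlap
    if (policy == "strict")
      hit <- hit & (same + (!oa) %*% t(!ob)) == np
    w <- which(hit, arr.ind = TRUE)
    if (nrow(w))
      out[[st]] <- data.frame(id_a = A$markers$id[ia][w[, 1]],
                              id_b = B$markers$id[ib][w[, 2]],
                              segtype = st,
                              n_compared = n_co[w])
  }
  if (!length(out))
    return(data.frame(id_a = character(), id_b = character(),
                      segtype = character(), n_compared = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(match(res$id_a, A$markers$id),
            match(res$id_b, B$markers$id)), , drop = FALSE]
}

#' Keep the cross-validated markers of the first view
#'
#' The first view is the mapping unit: a marker of `A` is retained when it
#' has one or more identical partners in `B` ("each corresponded to one or
#' more SNPs"). Calls are taken from `A`; the number of partners is
#' recorded.
#'
#' @param A the reference view used for mapping
#' @param matches result of [match_identical_loci()]
#' @return a `geno_matrix` of the matched `A` markers with an `n_matches`
#'   column
#' @export
crossval_matched <- function(A, matches) {
  tab <- table(matches$id_a)
  keep <- A$markers$id %in% names(tab)
  out <- subset_markers(A, keep)
  out$markers$n_matches <- as.integer(tab[out$markers$id])
  out
}

#' Collapse co-segregating, physically adjacent markers to one
#' representative
#'
#' Markers with identical coded genotype vectors (complete linkage) are
#' grouped; within a group, runs of markers on the same contig whose
#' adjacent gaps are at most `window_bp` collapse to a single
#' representative. The representative is the member with the fewest
#' missing calls, ties broken by smallest (contig, position). Identity
#' here is exact vector identity (including the missingness pattern), so
#' grouping is well defined.
#'
#' @param gm a [geno_matrix()] whose marker table carries `contig` and
#'   `contig_pos`
#' @param window_bp maximum gap between adjacent markers of a collapsed
#'   run (default 1 kb)
#' @return list with `representatives` (the reduced `geno_matrix`) and
#'   `bins` (data frame mapping every input marker to its representative)
#' @export
bin_markers <- function(gm, window_bp = 1000) {
  stopifnot(inherits(gm, "geno_matrix"))
  mk <- gm$markers
  if (is.null(mk$contig) || is.null(mk$contig_pos))
    stop("binning needs contig and contig_pos marker metadata")
  sig <- apply(gm$calls, 1, function(x)
    paste(ifelse(is.na(x), "-", substr(x, 2, 2)), collapse = ""))
  rep_of <- character(nrow(mk))
  for (g in split(seq_len(nrow(mk)), sig)) {
    o <- g[order(mk$contig[g], mk$contig_pos[g])]
    run_id <- cumsum(c(1, (mk$contig[o][-1] != mk$contig[o][-length(o)]) |
                         diff(mk$contig_pos[o]) > window_bp))
    for (run in split(o, run_id)) {
      nmiss <- rowSums(is.na(gm$calls[run, , drop = FALSE]))
      best <- run[order(nmiss, mk$contig[run], mk$contig_pos[run])][1]
      rep_of[run] <- mk$id[best]
    }
  }
  bins <- data.frame(id = mk$id, representative = rep_of)
  list(representatives = subset_markers(gm, mk$id %in% unique(rep_of)),
       bins = bins)
}

#' Intersection counts of identical loci across call sets
#'
#' For each dataset, counts the loci having at least one identical partner
#' in each other dataset, and in all datasets jointly, under coded
#' (`aa`/`ab`) or nucleotide-labelled comparison. Nucleotide mode recodes
#' each call with the marker's actual alleles (e.g. `A/A`, `A/C`), so
#' loci whose ref/alt labels differ between views stop matching —
#' coded-mode counts are always at least as large.
#'
#' @param datasets named list of [geno_matrix()] objects over the same
#'   progeny
#' @param mode `"coded"` or `"nucleotide"`
#' @param min_overlap passed to the underlying comparisons
#' @return data frame with columns `dataset`, `vs` (another dataset name
#'   or `"all"`), `count`
#' @export
venn_counts <- function(datasets, mode = c("coded", "nucleotide"),
                        min_overlap = 1L) {
  mode <- match.arg(mode)
  if (length(datasets) < 2) stop("need at least two datasets")
  if (is.null(names(datasets)))
    names(datasets) <- paste0("set", seq_along(datasets))
  use <- if (mode == "nucleotide") lapply(datasets, nucleotide_recode)
         else datasets
  has_match <- function(X, Y)  # ids in X with >=1 identical partner in Y
    unique(match_identical_loci(X, Y, min_overlap = min_overlap)$id_a)
  nm <- names(use)
  out <- list()
  for (i in nm) {
    hits <- lapply(setdiff(nm, i), function(j) has_match(use[[i]],
                                                         use[[j]]))
    names(hits) <- setdiff(nm, i)
    for (j in names(hits))
      out[[length(out) + 1]] <- data.frame(dataset = i, vs = j,
                                           count = length(hits[[j]]))
    out[[length(out) + 1]] <- data.frame(dataset = i, vs = "all",
                                         count = length(Reduce(intersect,
                                                               hits)))
  }
  do.call(rbind, out)
}

# recode aa/ab calls as nucleotide genotype strings using the marker's
# allele_a/allele_b labels; the result is a geno_matrix-like comparison
# proxy where differing labels break identity
nucleotide_recode <- function(gm) {
  mk <- gm$markers
  if (is.null(mk$allele_a) || is.null(mk$allele_b))
    stop("nucleotide mode needs allele_a/allele_b marker metadata")
  pair <- function(x, y) {
    s <- ifelse(x <= y, paste0(x, "/", y), paste0(y, "/", x))
    s
  }
  gaa <- pair(mk$allele_a, mk$allele_a)
  gab <- pair(mk$allele_a, mk$allele_b)
  # map each distinct nucleotide genotype string onto a fake aa/ab split
  # per marker is impossible (10 possible strings), so compare via string
  # matrices directly using a light wrapper
  calls <- gm$calls
  out <- matrix(NA_character_, nrow(calls), ncol(calls),
                dimnames = dimnames(calls))
  out[calls == "aa"] <- gaa[row(calls)[calls == "aa" & !is.na(calls)]]
  out[calls == "ab"] <- gab[row(calls)[calls == "ab" & !is.na(calls)]]
  structure(list(calls = out, markers = mk, progeny = gm$progeny),
            class = c("nt_matrix", "geno_matrix"))
}
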