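#' Partition markers into linkage groups at a LOD threshold
#'
#' Places an edge between every marker pair whose two-point LOD is at
#' least `threshold` and takes connected components (single linkage), so
#' every non-singleton group is connected through pairs above the
#' threshold. Groups are labelled deterministically in order of
#' decreasing size, ties broken by the smallest member's position in the
#' matrix.
#'
#' @param lod symmetric LOD matrix with marker-id dimnames (see
#'   [pairwise_matrix()]); `NA` entries are treated as no linkage
#' @param threshold minimum LOD for an edge
#' @return a `linkage_groups` object: list with `groups` (named list of
#'   marker-id vectors), `assignment` (data frame `id`, `group`),
#'   `threshold`
#' @export
group_markers <- function(lod, threshold = 6) {
  stopifnot(is.matrix(lod), nrow(lod) == ncol(lod))
  adj <- !is.na(lod) & lod >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  members <- split(seq_along(comp), comp)
  ord <- order(-lengths(members),
               vapply(members, min, numeric(1)))
  members <- members[ord]
  ids <- rownames(lod)
  groups <- lapply(members, function(ix) ids[ix])
  names(groups) <- sprintf("LG%02d", seq_along(groups))
  assignment <- data.frame(
    id = unlist(groups, use.names = FALSE),
    group = rep(names(groups), lengths(groups)))
  structure(list(groups = groups, assignment = assignment,
                 threshold = threshold),
            class = "linkage_groups")
}

#' @export
print.linkage_groups <- function(x, ...) {
  sz <- lengths(x$groups)
  cat("linkage groups at LOD >=", x$threshold, ":",
      sum(sz > 1), "multi-marker group(s),", sum(sz == 1),
      "singleton(s)\n")
  cat("  sizes:", paste(sz[sz > 1], collapse = ", "), "\n")
  invisible(x)
}

#' Summarise group structure over a range of LOD thresholds
#'
#' @param lod symmetric LOD matrix
#' @param thresholds ascending LOD thresholds to scan
#' @return data frame with columns `threshold`, `n_groups` (multi-marker
#'   groups) and `n_singletons`
#' @seealso [select_threshold()]
#' @export
scan_thresholds <- function(lod, thresholds = 2:20) {
  stopifnot(!is.unsorted(thresholds))
  do.call(rbind, lapply(thresholds, function(th) {
    sz <- lengths(group_markers(lod, th)$groups)
    data.frame(threshold = th, n_groups = sum(sz > 1),
               n_singletons = sum(sz == 1))
  }))
}

#' Pick the LOD threshold recovering a target number of linkage groups
#'
#' Scans thresholds and returns the smallest one whose partition has
#' exactly `expected_groups` multi-marker groups (e.g. 19 for a genome
#' with 19 chromosome pairs); if none does, the threshold whose group
#' count is closest to the target.
#'
#' @param lod symmetric LOD matrix
#' @param expected_groups target number of multi-marker groups
#' @param thresholds candidate thresholds, ascending
#' @return list with `threshold` and the full `scan` table
#' @export
select_threshold <- function(lod, expected_groups, thresholds = 2:20) {
  scan <- scan_thresholds(lod, thresholds)
  exact <- scan$threshold[scan$n_groups == expected_groups]
  th <- if (length(exact)) exact[1]
        else scan$threshold[which.min(abs(scan$n_groups -
                                          expected_groups))]
  list(threshold = th, scan = scan)
}
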