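#' Sum of adjacent recombination fractions of an order
#'
#' The ordering criterion minimised within each linkage group: the sum of
#' estimated recombination fractions between consecutive markers of a
#' candidate order. Reversal-invariant.
#'
#' @param order permutation of matrix indices (or marker ids matching the
#'   dimnames)
#' @param rf symmetric recombination-fraction matrix
#' @return the SARF value
#' @export
sarf <- function(order, rf) {
  if (is.character(order)) order <- match(order, rownames(rf))
  n <- length(order)
  if (any(is.na(order)) || !setequal(order, seq_len(nrow(rf))) ||
      n != nrow(rf))
    stop("`order` must be a permutation of the matrix indices")
  if (n < 2) return(0)
  sum(rf[cbind(order[-n], order[-1])])
}

# all permutations of 1..n as a matrix (n! rows); n kept small by callers
all_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

#' Exhaustive minimum-SARF ordering (test oracle)
#'
#' Searches all permutations (modulo reversal) of a small group for the
#' global minimum sum of adjacent recombination fractions. Intended as an
#' exact oracle for [order_group()]; refuses groups larger than 10.
#'
#' @param rf symmetric recombination-fraction matrix of the group
#' @return a `marker_order` list: `order` (marker ids), `perm` (indices),
#'   `sarf`
#' @export
brute_force_order <- function(rf) {
  n <- nrow(rf)
  if (n > 10) stop("exhaustive search refused for groups larger than 10")
  if (n == 1)
    return(structure(list(order = rownames(rf), perm = 1L, sarf = 0),
                     class = "marker_order"))
  perms <- all_perms(n)
  perms <- perms[perms[, 1] < perms[, n], , drop = FALSE]  # mod reversal
  s <- numeric(nrow(perms))
  for (k in seq_len(n - 1L))
    s <- s + rf[cbind(perms[, k], perms[, k + 1L])]
  best <- perms[which.min(s), ]
  structure(list(order = rownames(rf)[best], perm = best,
                 sarf = min(s)),
            class = "marker_order")
}

# local search on path SARF: best-improvement 2-opt (segment reversal)
# moves interleaved with Or-opt (relocation of segments of length 1-3),
# iterated until neither neighbourhood improves
two_opt <- function(perm, rf) {
  n <- length(perm)
  if (n < 3) return(perm)
  path_sarf <- function(p) sum(rf[cbind(p[-n], p[-1])])
  best_reversal <- function(p) {
    best_delta <- -1e-12
    best_ij <- NULL
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        if (i == 1L && j == n) next  # full reversal changes nothing
        old <- 0; new <- 0
        if (i > 1L) {
          old <- old + rf[p[i - 1L], p[i]]
          new <- new + rf[p[i - 1L], p[j]]
        }
        if (j < n) {
          old <- old + rf[p[j], p[j + 1L]]
          new <- new + rf[p[i], p[j + 1L]]
        }
        delta <- new - old
        if (delta < best_delta) {
          best_delta <- delta
          best_ij <- c(i, j)
        }
      }
    }
    if (is.null(best_ij)) return(NULL)
    p[best_ij[1]:best_ij[2]] <- rev(p[best_ij[1]:best_ij[2]])
    p
  }
  best_relocation <- function(p) {
    s0 <- path_sarf(p)
    best <- NULL
    best_s <- s0 - 1e-12
    for (len in 1:min(3L, n - 1L)) {
      for (i in seq_len(n - len + 1L)) {
        seg <- p[i:(i + len - 1L)]
        rest <- p[-(i:(i + len - 1L))]
        for (at in 0:length(rest)) {
          if (at == i - 1L) next  # unchanged position
          cand <- append(rest, seg, after = at)
          s <- path_sarf(cand)
          if (s < best_s) {
            best_s <- s
            best <- cand
          }
        }
      }
    }
    best
  }
  repeat {
    p2 <- best_reversal(perm)
    if (!is.null(p2)) {
      perm <- p2
      next
    }
    p3 <- best_relocation(perm)
    if (is.null(p3)) return(perm)
    perm <- p3
  }
}

#' Order the markers of a linkage group by minimum SARF
#'
#' Multi-start heuristic: greedy nearest-neighbour chains grown from
#' `restarts` random start markers (the natural input order is always
#' included as one start), each refined by 2-opt segment reversal to a
#' local optimum of the sum of adjacent recombination fractions; the best
#' result over all starts is returned. Deterministic given `seed`. The
#' returned order is canonically oriented (first marker id sorts before
#' the last) and equal-SARF candidates are resolved to the
#' lexicographically smallest oriented permutation.
#'
#' @param rf symmetric recombination-fraction matrix of the group, with
#'   marker-id dimnames
#' @param restarts number of random starts (default `max(20, n)`)
#' @param seed RNG seed for start selection
#' @return a `marker_order` list: `order` (marker ids), `perm` (indices),
#'   `sarf`, `restarts`, `seed`
#' @export
order_group <- function(rf, restarts = max(20L, nrow(rf)), seed = 1L) {
  n <- nrow(rf)
  ids <- rownames(rf)
  if (is.null(ids)) ids <- rownames(rf) <- colnames(rf) <-
      as.character(seq_len(n))
  if (n == 1)
    return(structure(list(order = ids, perm = 1L, sarf = 0,
                          restarts = 0L, seed = seed),
                     class = "marker_order"))
  greedy <- function(start) {
    left <- rep(TRUE, n)
    perm <- integer(n)
    perm[1] <- start
    left[start] <- FALSE
    for (k in seq_len(n - 1L)) {
      cand <- which(left)
      d <- rf[perm[k], cand]
      perm[k + 1L] <- cand[which.min(d)]  # ties -> smallest index
      left[perm[k + 1L]] <- FALSE
    }
    perm
  }
  orient <- function(perm)
    if (ids[perm[1]] > ids[perm[length(perm)]]) rev(perm) else perm
  starts <- with_seed(child_seed(seed, "order"),
                      sample.int(n, min(restarts, n), replace = FALSE))
  cands <- c(list(two_opt(seq_len(n), rf)),
             lapply(starts, function(s) two_opt(greedy(s), rf)))
  s <- vapply(cands, sarf, numeric(1), rf = rf)
  eps <- 1e-12
  best <- which(s <= min(s) + eps)
  oriented <- lapply(cands[best], orient)
  key <- vapply(oriented, function(p) paste(p, collapse = ","), "")
  pick <- oriented[[order(key)[1]]]
  structure(list(order = ids[pick], perm = pick, sarf = min(s),
                 restarts = length(starts), seed = seed),
            class = "marker_order")
}

#' @export
print.marker_order <- function(x, ...) {
  cat("marker order (", length(x$order), " markers), SARF = ",
      sprintf("%.4f", x$sarf), "\n", sep = "")
  invisible(x)
}

#' Agreement between an estimated and a reference marker order
#'
#' Compares two orders modulo reversal by counting discordant marker
#' pairs (Kendall distance), choosing the orientation with fewer
#' discordances. Marker pairs adjacent in the reference order with zero
#' observed recombination between them are genuinely unorderable from the
#' data; when `rf` is supplied such pairs form unordered blocks and
#' discordances within a block are not counted.
#'
#' @param est estimated order (marker ids)
#' @param ref reference (true) order
#' @param rf optional recombination-fraction matrix used to detect
#'   zero-recombination blocks
#' @return list with `discordant` (pair count), `n_pairs`, `exact`
#'   (`TRUE` when no resolvable pair is discordant)
#' @export
order_agreement <- function(est, ref, rf = NULL) {
  stopifnot(setequal(est, ref))
  block <- seq_along(ref)
  if (!is.null(rf)) {
    tied <- rf[cbind(ref[-length(ref)], ref[-1])] == 0
    block <- cumsum(c(1, !tied))
  }
  count_disc <- function(pos) {
    d <- 0L
    n <- length(ref)
    for (i in seq_len(n - 1L))
      for (j in seq((i + 1L), n))
        if (block[i] != block[j] && pos[i] > pos[j]) d <- d + 1L
    d
  }
  pos <- match(ref, est)
  d_fwd <- count_disc(pos)
  d_rev <- count_disc(length(est) + 1L - pos)
  d <- min(d_fwd, d_rev)
  list(discordant = d, n_pairs = choose(length(ref), 2),
       exact = d == 0L)
}
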