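#' Bounded branching search for MCIPP (decision version)
#'
#' Decides whether the instance admits a common pair partition of size at
#' most `k`, and returns one if so. The search is a depth-bounded
#' branching anchored at the minimum element: each node pivots on the
#' tuple attaining the minimum first component over both sides
#' (tie-break: minimum second component) and branches over the pieces
#' that tuple can contribute, jointly subtracted from an opposite-side
#' source tuple; since any input tuple must receive at least one piece
#' of any common partition, enumerating all pieces of one pivot is
#' complete, with no appeal to a structural lemma. (Anchorings that
#' restrict the pivot's pieces -- committing a whole minimum-attaining
#' input tuple, or insisting the minimum component travels in a single
#' piece -- are demonstrably incomplete for pair instances, unlike the
#' integer case of [exact_mcip_fpt()]; see the package vignette.)
#' Candidates are ordered greedy-first -- the whole pivot tuple, then
#' pieces anchored at the componentwise minima, then the rest by
#' decreasing size -- so a cheap greedy descent is the fast path and the
#' full branching only runs when it fails.
#'
#' Tuples common to both sides are moved into the solution up front. A
#' budget below `max(|S|, |T|)` is refused immediately (no partition can
#' be smaller). Pieces sharing a source pair on both sides are merged
#' before returning, and the result is re-validated.
#'
#' @param S,T pair multisets forming a feasible instance.
#' @param k maximum partition size (positive integer).
#' @return an `mcipp_result` with `method = "fpt"`, or `NULL` when no
#'   common partition of size at most `k` exists.
#' @export
#' @examples
#' exact_mcipp_fpt(rbind(c(3, 2)), rbind(c(3, 2)), k = 1)
exact_mcipp_fpt <- function(S, T, k) {
  S <- as_pair_multiset(S); T <- as_pair_multiset(T)
  stop_if_infeasible(S, T)
  if (k < 1L) stop("'k' must be a positive integer")
  k <- as.integer(k)
  b <- mcipp_bounds(S, T)
  if (k < b[["lower"]]) return(NULL)

  Sst <- state_init(S); Tst <- state_init(T)
  pre_pieces <- list()
  repeat {
    hit <- NULL
    for (i in seq_len(nrow(Sst))) {
      j <- which(Tst[, 1L] == Sst[i, 1L] & Tst[, 2L] == Sst[i, 2L])
      if (length(j)) { hit <- c(i, j[1L]); break }
    }
    if (is.null(hit)) break
    stp <- state_dom_step(Sst, Tst, hit[1L], hit[2L])
    pre_pieces[[length(pre_pieces) + 1L]] <- c(stp$piece, stp$so, stp$to)
    Sst <- stp$S; Tst <- stp$T
  }
  budget <- k - length(pre_pieces)
  if (budget < 0L) return(NULL)

  fail_memo <- new.env(parent = emptyenv())
  rec <- function(Sm, Tm, kk) {
    nS <- nrow(Sm); nT <- nrow(Tm)
    if (nS == 0L && nT == 0L) return(list())
    if (kk <= 0L || kk < max(nS, nT)) return(NULL)
    key <- paste(pairs_key(state_pairs(Sm)), pairs_key(state_pairs(Tm)), sep = "#")
    known <- fail_memo[[key]]
    if (!is.null(known) && kk <= known) return(NULL)

    for (br in fpt_branches(Sm, Tm)) {
      pivot_side <- br$side          # side holding the pivot tuple
      i <- br$pivot                  # pivot row on that side
      for (p in br$pieces) {
        if (pivot_side == "S") {
          opp <- which(Tm[, 1L] >= p[1L] & Tm[, 2L] >= p[2L])
          opp <- opp[!duplicated(paste(Tm[opp, 1L], Tm[opp, 2L]))]
          for (j in opp) {
            S2 <- state_replace(Sm, i, Sm[i, 1:2] - p)
            T2 <- state_replace(Tm, j, Tm[j, 1:2] - p)
            sub <- rec(S2, T2, kk - 1L)
            if (!is.null(sub)) return(c(list(c(p, Sm[i, 3L], Tm[j, 3L])), sub))
          }
        } else {
          opp <- which(Sm[, 1L] >= p[1L] & Sm[, 2L] >= p[2L])
          opp <- opp[!duplicated(paste(Sm[opp, 1L], Sm[opp, 2L]))]
          for (j in opp) {
            S2 <- state_replace(Sm, j, Sm[j, 1:2] - p)
            T2 <- state_replace(Tm, i, Tm[i, 1:2] - p)
            sub <- rec(S2, T2, kk - 1L)
            if (!is.null(sub)) return(c(list(c(p, Sm[j, 3L], Tm[i, 3L])), sub))
          }
        }
      }
    }
    fail_memo[[key]] <- max(kk, if (is.null(known)) 0L else known)
    NULL
  }

  sol <- rec(Sst, Tst, budget)
  if (is.null(sol)) return(NULL)
  pm <- do.call(rbind, c(pre_pieces, sol))
  if (is.null(pm)) pm <- matrix(integer(0), ncol = 4L)
  pieces <- pm[, 1:2, drop = FALSE]
  assignment <- data.frame(s = pm[, 3L], t = pm[, 4L])
  merged <- merge_same_source(pieces, assignment)
  if (!validate_pair_partition(S, T, merged$pieces)) {
    stop("internal error: branching search returned an invalid partition")
  }
  new_solve_result(
    partition = merged$pieces, assignment = merged$assignment,
    size = nrow(merged$pieces), method = "fpt",
    lower_bound = b[["lower"]], upper_bound = b[["upper"]]
  )
}

# The single branch set at a node: pivot on the tuple attaining the
# minimum first component over both sides (tie-break: minimum second),
# and enumerate every piece (p1, p2) <= pivot, p != (0,0). Completeness
# needs no lemma: the pivot must receive at least one piece of any
# common partition, and every choice of that piece is explored. Pieces
# are ordered greedy-first: the whole pivot tuple, then the piece
# anchored at the global componentwise minima, then decreasing size.
fpt_branches <- function(Sm, Tm) {
  a <- min(Sm[, 1L], Tm[, 1L])
  d <- min(Sm[, 2L], Tm[, 2L])
  cand_s <- which(Sm[, 1L] == a)
  cand_t <- which(Tm[, 1L] == a)
  side <- "S"; i <- NA_integer_
  best2 <- Inf
  for (r in cand_s) if (Sm[r, 2L] < best2) { best2 <- Sm[r, 2L]; i <- r; side <- "S" }
  for (r in cand_t) if (Tm[r, 2L] < best2) { best2 <- Tm[r, 2L]; i <- r; side <- "T" }
  z <- if (side == "S") Sm[i, 1:2] else Tm[i, 1:2]
  grid <- expand.grid(p1 = 0:z[1L], p2 = 0:z[2L])
  grid <- grid[grid$p1 > 0L | grid$p2 > 0L, , drop = FALSE]
  rank <- -(grid$p1 + grid$p2) - 1000L * (grid$p1 == z[1L] & grid$p2 == z[2L]) -
    500L * (grid$p1 == min(a, z[1L]) & grid$p2 == min(d, z[2L]))
  grid <- grid[order(rank), , drop = FALSE]
  pieces <- lapply(seq_len(nrow(grid)),
                   function(r) c(grid$p1[r], grid$p2[r]))
  list(list(side = side, pivot = i, pieces = pieces))
}

#' Minimum common pair partition (optimization wrapper)
#'
#' Computes a minimum-size common pair partition by the requested method:
#' `"fpt"` runs the bounded branching search with iterative deepening from
#' the certified lower bound `max(|S|, |T|)` up to `|S| + |T|`; `"brute"`
#' uses the independent exhaustive oracle [brute_force_mcipp()];
#' `"heuristic"` returns the (not necessarily optimal) heuristic solution.
#'
#' @param S,T pair multisets forming a feasible instance.
#' @param method one of `"fpt"`, `"brute"`, `"heuristic"`.
#' @return an `mcipp_result`.
#' @export
#' @examples
#' S <- rbind(c(9, 4), c(1, 11), c(6, 3))
#' T <- rbind(c(2, 8), c(12, 1), c(2, 9))
#' mcipp_optimize(S, T, method = "fpt")
mcipp_optimize <- function(S, T, method = c("fpt", "brute", "heuristic")) {
  method <- match.arg(method)
  S <- as_pair_multiset(S); T <- as_pair_multiset(T)
  stop_if_infeasible(S, T)
  if (method == "heuristic") return(heuristic_mcipp(S, T))
  b <- mcipp_bounds(S, T)
  if (method == "brute") {
    br <- brute_force_mcipp(S, T)
    asg <- find_pair_assignment(S, T, br$partition)
    merged <- merge_same_source(br$partition,
                                data.frame(s = asg$s, t = asg$t))
    return(new_solve_result(
      partition = merged$pieces, assignment = merged$assignment,
      size = nrow(merged$pieces), method = "brute",
      lower_bound = b[["lower"]], upper_bound = b[["upper"]]
    ))
  }
  for (k in b[["lower"]]:b[["upper"]]) {
    res <- exact_mcipp_fpt(S, T, k)
    if (!is.null(res)) return(res)
  }
  stop("internal error: no partition found within the certified upper bound")
}

#' Bounded branching search for MCIP (decision version)
#'
#' Decides whether integer multisets `A`, `B` (equal sums) admit a common
#' partition of size at most `k`. Uses the minimum-element property: some
#' optimal solution always contains the smallest element of the combined
#' input as a piece, so each node commits the current global minimum `a`
#' and branches only over which opposite-side element it is subtracted
#' from. Elements common to both sides are emitted directly (they belong
#' to some optimal solution as-is).
#'
#' @param A,B multisets of positive integers with equal sums.
#' @param k maximum partition size (positive integer).
#' @return list with `size`, `partition` (sorted integer vector) and
#'   `method = "fpt"`, or `NULL` when no solution of size at most `k`
#'   exists.
#' @export
#' @examples
#' exact_mcip_fpt(c(2, 5, 5), c(6, 6), k = 4)
exact_mcip_fpt <- function(A, B, k) {
  A <- as_int_multiset(A); B <- as_int_multiset(B)
  if (sum(A) != sum(B)) stop("infeasible MCIP instance: sums differ")
  if (k < 1L) stop("'k' must be a positive integer")
  k <- as.integer(k)

  fail_memo <- new.env(parent = emptyenv())
  rec <- function(Av, Bv, kk) {
    if (!length(Av) && !length(Bv)) return(integer(0))
    if (kk <= 0L || kk < max(length(Av), length(Bv))) return(NULL)
    key <- paste(paste(Av, collapse = ","), paste(Bv, collapse = ","), sep = "|")
    known <- fail_memo[[key]]
    if (!is.null(known) && kk <= known) return(NULL)
    common <- intersect(Av, Bv)
    if (length(common)) {                       # forced: emit a common element
      v <- common[1L]
      sub <- rec(Av[-match(v, Av)], Bv[-match(v, Bv)], kk - 1L)
      if (!is.null(sub)) return(c(v, sub))
    } else {
      a <- min(Av[1L], Bv[1L])                  # global minimum element
      if (length(Av) && Av[1L] == a) {
        from <- Av; other <- Bv; a_in_A <- TRUE
      } else {
        from <- Bv; other <- Av; a_in_A <- FALSE
      }
      for (z in unique(other[other > a])) {
        o2 <- other[-match(z, other)]
        o2 <- sort(c(o2, z - a))
        sub <- if (a_in_A) rec(from[-1L], o2, kk - 1L) else rec(o2, from[-1L], kk - 1L)
        if (!is.null(sub)) return(c(a, sub))
      }
    }
    fail_memo[[key]] <- max(kk, if (is.null(known)) 0L else known)
    NULL
  }

  sol <- rec(A, B, k)
  if (is.null(sol)) return(NULL)
  partition <- sort(sol)
  if (!validate_common_partition(A, B, partition)) {
    stop("internal error: MCIP search returned an invalid partition")
  }
  list(size = length(partition), partition = partition, method = "fpt")
}

#' Minimum common integer partition (optimization wrapper)
#'
#' Iterative deepening over [exact_mcip_fpt()] from `max(|A|, |B|)`
#' upward, or the exhaustive oracle [brute_force_mcip()].
#'
#' @param A,B multisets of positive integers with equal sums.
#' @param method `"fpt"` or `"brute"`.
#' @return list with `size`, `partition`, `method`.
#' @export
mcip_optimize <- function(A, B, method = c("fpt", "brute")) {
  method <- match.arg(method)
  A <- as_int_multiset(A); B <- as_int_multiset(B)
  if (sum(A) != sum(B)) stop("infeasible MCIP instance: sums differ")
  if (method == "brute") return(brute_force_mcip(A, B))
  for (k in max(length(A), length(B)):(length(A) + length(B))) {
    res <- exact_mcip_fpt(A, B, k)
    if (!is.null(res)) return(res)
  }
  stop("internal error: no partition found within the upper bound")
}
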