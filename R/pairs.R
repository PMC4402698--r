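#' Coerce to a pair multiset
#'
#' A pair multiset is the instance side of the Minimum Common Integer Pair
#' Partition (MCIPP) problem: a multiset of 2-tuples of non-negative
#' integers, here represented as a two-column integer matrix with one tuple
#' per row, rows sorted lexicographically. The tuple (0,0) carries no
#' children and is never allowed, in instances or in solutions; tuples with
#' a single zero component are legal.
#'
#' @param x a two-column matrix or data frame of non-negative integers, or
#'   a length-2 vector for a single tuple.
#' @return canonical two-column integer matrix of class `pair_multiset`.
#' @export
#' @examples
#' as_pair_multiset(rbind(c(9, 4), c(1, 11), c(6, 3)))
as_pair_multiset <- function(x) {
  if (inherits(x, "pair_multiset")) return(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x) && length(x) == 2L) x <- matrix(x, ncol = 2L)
  if (!is.matrix(x) || ncol(x) != 2L) {
    stop("a pair multiset needs two columns (one 2-tuple per row)")
  }
  if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    stop("pair multiset entries must be non-negative integers")
  }
  storage.mode(x) <- "integer"
  if (any(x[, 1L] == 0L & x[, 2L] == 0L)) {
    stop("the tuple (0,0) is not allowed in a pair multiset")
  }
  dimnames(x) <- NULL
  x <- x[order(x[, 1L], x[, 2L]), , drop = FALSE]
  class(x) <- c("pair_multiset", class(x))
  x
}

#' @export
print.pair_multiset <- function(x, ...) {
  cat(sprintf("<pair multiset of %d tuple(s); projection sums %d, %d>\n",
              nrow(x), sum(x[, 1L]), sum(x[, 2L])))
  if (nrow(x)) {
    cat(paste0("  <", x[, 1L], ",", x[, 2L], ">", collapse = " "), "\n")
  }
  invisible(x)
}

# strip class, canonical row order
canon_pairs <- function(m) {
  m <- unclass(m)
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

pairs_key <- function(m) {
  m <- canon_pairs(m)
  paste(m[, 1L], m[, 2L], sep = ",", collapse = ";")
}

projection_sums <- function(m) {
  c(sum(m[, 1L]), sum(m[, 2L]))
}

#' Feasibility of an MCIPP instance
#'
#' Two pair multisets admit a common partition only if their first-component
#' sums agree and their second-component sums agree. All solvers assume
#' this condition and reject infeasible instances.
#'
#' @param S,T pair multisets (see [as_pair_multiset()]).
#' @return `TRUE` or `FALSE`.
#' @export
mcipp_feasible <- function(S, T) {
  S <- as_pair_multiset(S); T <- as_pair_multiset(T)
  all(projection_sums(S) == projection_sums(T))
}

stop_if_infeasible <- function(S, T) {
  if (!mcipp_feasible(S, T)) {
    stop("infeasible MCIPP instance: projection sums differ between S and T")
  }
}

#' Dominance classification of two tuples
#'
#' Tuple u = (a,b) dominates v = (c,d) when a >= c and b >= d. Two tuples
#' form a non-dominating pair when they are incomparable componentwise
#' (a > c, b < d or a < c, b > d).
#'
#' @param u,v length-2 non-negative integer vectors.
#' @return one of `"u_dominates"`, `"v_dominates"`, `"both_equal"`,
#'   `"non_dominating"`.
#' @export
#' @examples
#' dominates(c(4, 5), c(2, 4))  # "u_dominates"
#' dominates(c(1, 4), c(2, 3))  # "non_dominating"
dominates <- function(u, v) {
  stopifnot(length(u) == 2L, length(v) == 2L)
  if (u[1L] == v[1L] && u[2L] == v[2L]) return("both_equal")
  if (u[1L] >= v[1L] && u[2L] >= v[2L]) return("u_dominates")
  if (v[1L] >= u[1L] && v[2L] >= u[2L]) return("v_dominates")
  "non_dominating"
}

# index pairs (si, ti) of cross pairs by dominance class, on plain matrices
cross_pairs_classified <- function(S, T) {
  nS <- nrow(S); nT <- nrow(T)
  if (nS == 0L || nT == 0L) {
    return(list(dominating = matrix(integer(0), ncol = 2L),
                non_dominating = matrix(integer(0), ncol = 2L)))
  }
  dom <- list(); nd <- list()
  for (i in seq_len(nS)) {
    for (j in seq_len(nT)) {
      cls <- dominates(S[i, ], T[j, ])
      if (cls == "non_dominating") {
        nd[[length(nd) + 1L]] <- c(i, j)
      } else {
        dom[[length(dom) + 1L]] <- c(i, j)
      }
    }
  }
  list(
    dominating = if (length(dom)) do.call(rbind, dom) else matrix(integer(0), ncol = 2L),
    non_dominating = if (length(nd)) do.call(rbind, nd) else matrix(integer(0), ncol = 2L)
  )
}

#' Enumerate non-dominating cross pairs of an instance
#'
#' @param S,T pair multisets.
#' @return data frame with one row per non-dominating cross pair:
#'   columns `s1`, `s2`, `t1`, `t2` (tuple values), `s_index`,
#'   `t_index` (row indices into the canonical `S` and `T`) and
#'   `eligible` (`FALSE` for degenerate pairs whose exchanged piece would
#'   be `(0,0)`).
#' @export
nondominating_pairs <- function(S, T) {
  S <- as_pair_multiset(S); T <- as_pair_multiset(T)
  cls <- cross_pairs_classified(S, T)
  nd <- cls$non_dominating
  out <- data.frame(
    s1 = S[nd[, 1L], 1L], s2 = S[nd[, 1L], 2L],
    t1 = T[nd[, 2L], 1L], t2 = T[nd[, 2L], 2L],
    s_index = nd[, 1L], t_index = nd[, 2L]
  )
  out$eligible <- !mapply(function(i, j) nondom_piece_zero(S[i, ], T[j, ]),
                          out$s_index, out$t_index)
  out
}

# would the non-dominating split of (s, t) emit the forbidden (0,0) piece?
# (happens for pairs like (x,0) vs (0,y); such pairs are ineligible, and
# whenever no dominating pair exists an eligible one can be shown to exist)
nondom_piece_zero <- function(s, t) {
  if (s[1L] > t[1L]) t[1L] == 0L && s[2L] == 0L else s[1L] == 0L && t[2L] == 0L
}

# locate the first row of m equal to tuple v; error when absent
locate_tuple <- function(m, v, side) {
  hit <- which(m[, 1L] == v[1L] & m[, 2L] == v[2L])
  if (!length(hit)) {
    stop(sprintf("tuple <%d,%d> not found in %s", v[1L], v[2L], side))
  }
  hit[1L]
}

drop_row <- function(m, i) m[-i, , drop = FALSE]

# replace row i by tuple v, dropping it when v == (0,0)
replace_row <- function(m, i, v) {
  if (v[1L] == 0L && v[2L] == 0L) return(drop_row(m, i))
  m[i, ] <- v
  m
}

#' One dominating-partition step
#'
#' For a dominating pair s, t the componentwise minimum (the dominated
#' tuple) is emitted as a solution piece; the dominated tuple is removed
#' from its side and the dominating tuple is replaced by the positive
#' residual obtained by subtraction (removed entirely when s = t).
#'
#' @param S,T pair multisets.
#' @param s,t length-2 tuples, members of `S` and `T` respectively, forming
#'   a dominating pair.
#' @return list with `piece` (the emitted tuple), `S`, `T` (updated sides).
#' @export
#' @examples
#' dominating_step(rbind(c(2, 4)), rbind(c(4, 5)), c(2, 4), c(4, 5))
dominating_step <- function(S, T, s, t) {
  S <- as_pair_multiset(S); T <- as_pair_multiset(T)
  cls <- dominates(s, t)
  if (cls == "non_dominating") {
    stop("dominating_step needs a dominating pair; got a non-dominating one")
  }
  i <- locate_tuple(S, s, "S"); j <- locate_tuple(T, t, "T")
  piece <- pmin(s, t)
  if (cls == "both_equal") {
    S <- drop_row(S, i); T <- drop_row(T, j)
  } else if (cls == "u_dominates") {      # s dominates: t emitted, s keeps residual
    S <- replace_row(S, i, s - t); T <- drop_row(T, j)
  } else {                                # t dominates
    T <- replace_row(T, j, t - s); S <- drop_row(S, i)
  }
  list(piece = as.integer(piece),
       S = as_pair_multiset_allow_empty(S),
       T = as_pair_multiset_allow_empty(T))
}

#' One non-dominating-partition step
#'
#' For a non-dominating pair s, t with (up to swapping roles) s1 > t1 and
#' s2 < t2, the piece (t1, s2) is emitted; s is replaced by
#' (s1 - t1, 0) and t by (0, t2 - s2). The instance stays valid and both
#' projection sums are conserved.
#'
#' @inheritParams dominating_step
#' @return list with `piece`, `S`, `T`.
#' @export
#' @examples
#' nondominating_step(rbind(c(6, 3)), rbind(c(2, 9)), c(6, 3), c(2, 9))
nondominating_step <- function(S, T, s, t) {
  S <- as_pair_multiset(S); T <- as_pair_multiset(T)
  if (dominates(s, t) != "non_dominating") {
    stop("nondominating_step needs a non-dominating pair")
  }
  i <- locate_tuple(S, s, "S"); j <- locate_tuple(T, t, "T")
  if (nondom_piece_zero(s, t)) {
    stop("degenerate non-dominating pair: the exchanged piece would be (0,0)")
  }
  if (s[1L] > t[1L]) {                    # s1 > t1, s2 < t2
    piece <- c(t[1L], s[2L])
    S <- replace_row(S, i, c(s[1L] - t[1L], 0L))
    T <- replace_row(T, j, c(0L, t[2L] - s[2L]))
  } else {                                # s1 < t1, s2 > t2
    piece <- c(s[1L], t[2L])
    S <- replace_row(S, i, c(0L, s[2L] - t[2L]))
    T <- replace_row(T, j, c(t[1L] - s[1L], 0L))
  }
  list(piece = as.integer(piece),
       S = as_pair_multiset_allow_empty(S),
       T = as_pair_multiset_allow_empty(T))
}

# residuals can legitimately empty a side; keep class without re-checking
as_pair_multiset_allow_empty <- function(m) {
  m <- canon_pairs(m)
  storage.mode(m) <- "integer"
  class(m) <- c("pair_multiset", class(m))
  m
}

#' Move common tuples of S and T into the solution
#'
#' A tuple present in both sides (with multiplicity) can always be placed
#' directly in an optimal common partition, so it is stripped from both
#' sides up front. After preprocessing the reduced sides share no tuple.
#'
#' @param S,T pair multisets.
#' @return list with `pieces` (matrix of moved tuples, possibly 0-row),
#'   `S`, `T` (reduced sides).
#' @export
preprocess_common_tuples <- function(S, T) {
  S <- as_pair_multiset(S); T <- as_pair_multiset(T)
  pieces <- matrix(integer(0), ncol = 2L)
  keep_t <- rep(TRUE, nrow(T))
  keep_s <- rep(TRUE, nrow(S))
  for (i in seq_len(nrow(S))) {
    j <- which(keep_t & T[, 1L] == S[i, 1L] & T[, 2L] == S[i, 2L])
    if (length(j)) {
      keep_s[i] <- FALSE
      keep_t[j[1L]] <- FALSE
      pieces <- rbind(pieces, S[i, ])
    }
  }
  list(pieces = pieces,
       S = as_pair_multiset_allow_empty(S[keep_s, , drop = FALSE]),
       T = as_pair_multiset_allow_empty(T[keep_t, , drop = FALSE]))
}

#' Certified size bounds for an MCIPP instance
#'
#' The optimum of a feasible instance is at least `max(|S|, |T|)` (every
#' input tuple needs at least one piece) and the subtraction heuristic
#' never returns more than `|S| + |T|` pieces; together the two bounds
#' certify the heuristic as a factor-2 approximation.
#'
#' @param S,T pair multisets forming a feasible instance.
#' @return named integer vector `c(lower, upper)`.
#' @export
mcipp_bounds <- function(S, T) {
  S <- as_pair_multiset(S); T <- as_pair_multiset(T)
  stop_if_infeasible(S, T)
  c(lower = max(nrow(S), nrow(T)), upper = nrow(S) + nrow(T))
}
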