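# Brute-force reference implementations. These share no search code with
# the heuristic or the bounded branching solvers, so agreement between the
# two routes is a meaningful certificate on small instances. They exist as
# ground truth, not for performance, and refuse inputs above a size cap.

#' Exhaustive minimum common integer partition
#'
#' Enumerates common partitions by recursive piece splitting: the first
#' element of (the canonically sorted) `A` must receive some piece `v`
#' taken jointly from an element `b` of `B`; the search branches over all
#' `(b, v)` choices and recurses on the residual multisets, memoizing the
#' minimum size per residual state. Independent of the minimum-element
#' branching used by [exact_mcip_fpt()].
#'
#' @param A,B multisets of positive integers with equal sums.
#' @param cap refuse instances whose common sum exceeds this (default 40).
#' @param use_memo memoize on residual states (results are identical with
#'   memoization off; the toggle exists so tests can certify that).
#' @return list with `size`, `partition` (sorted integer vector) and
#'   `method = "brute"`.
#' @export
#' @examples
#' brute_force_mcip(c(2, 5, 5), c(6, 6))  # size 4
brute_force_mcip <- function(A, B, cap = 40L, use_memo = TRUE) {
  A <- as_int_multiset(A); B <- as_int_multiset(B)
  if (sum(A) != sum(B)) stop("infeasible MCIP instance: sums differ")
  if (sum(A) > cap) {
    stop("instance sum ", sum(A), " exceeds the oracle cap (", cap,
         "); use exact_mcip_fpt() for larger instances")
  }
  memo <- new.env(parent = emptyenv())
  rec <- function(Av, Bv) {
    if (!length(Av)) return(list(size = 0L, partition = integer(0)))
    key <- paste(paste(Av, collapse = ","), paste(Bv, collapse = ","), sep = "|")
    if (use_memo) {
      hit <- memo[[key]]
      if (!is.null(hit)) return(hit)
    }
    a <- Av[1L]
    best <- NULL
    for (b in unique(Bv)) {
      jB <- match(b, Bv)
      for (v in seq_len(min(a, b))) {
        A2 <- Av[-1L]
        if (a - v > 0L) A2 <- sort(c(A2, a - v))
        B2 <- Bv[-jB]
        if (b - v > 0L) B2 <- sort(c(B2, b - v))
        sub <- rec(A2, B2)
        if (is.null(best) || 1L + sub$size < best$size) {
          best <- list(size = 1L + sub$size, partition = c(v, sub$partition))
        }
      }
    }
    if (use_memo) memo[[key]] <- best
    best
  }
  out <- rec(A, B)
  list(size = out$size, partition = sort(out$partition), method = "brute")
}

#' Exhaustive minimum common integer pair partition
#'
#' Same splitting scheme as [brute_force_mcip()] lifted to 2-tuples: the
#' first tuple of the canonical `S` receives a piece `(v1, v2)` drawn
#' jointly from some tuple of `T`, branching over all tuples and all
#' componentwise piece values (excluding `(0,0)`). The enumeration is
#' depth-bounded and iteratively deepened from `max(|S|, |T|)` (no
#' partition can be smaller) to `|S| + |T|` (one always exists below
#' this), with failed states memoized per budget, so the first budget
#' that succeeds is the exact optimum. Optimal partitions found this way
#' automatically respect the merged normal form (two pieces on one
#' source pair would merge into a smaller partition, which the
#' minimization prefers).
#'
#' @param S,T pair multisets forming a feasible instance.
#' @param cap refuse instances whose projection sums exceed this
#'   (default 25).
#' @param max_side refuse instances with more than this many tuples per
#'   side (default 4).
#' @param use_memo memoize on residual states.
#' @return list with `size`, `partition` (two-column matrix) and
#'   `method = "brute"`.
#' @export
brute_force_mcipp <- function(S, T, cap = 25L, max_side = 4L, use_memo = TRUE) {
  S <- as_pair_multiset(S); T <- as_pair_multiset(T)
  stop_if_infeasible(S, T)
  ps <- projection_sums(S)
  if (any(ps > cap) || nrow(S) > max_side || nrow(T) > max_side) {
    stop("instance exceeds the oracle caps (projection sums <= ", cap,
         ", sides <= ", max_side, " tuples); use exact_mcipp_fpt() instead")
  }
  fail_memo <- new.env(parent = emptyenv())
  rec <- function(Sm, Tm, kk) {
    if (!nrow(Sm)) return(list())
    if (kk < max(nrow(Sm), nrow(Tm))) return(NULL)
    key <- paste(pairs_key(Sm), pairs_key(Tm), sep = "#")
    if (use_memo) {
      known <- fail_memo[[key]]
      if (!is.null(known) && kk <= known) return(NULL)
    }
    s <- Sm[1L, ]
    seen_t <- character(0)
    for (j in seq_len(nrow(Tm))) {
      t <- Tm[j, ]
      tk <- paste(t, collapse = ",")
      if (tk %in% seen_t) next
      seen_t <- c(seen_t, tk)
      for (v1 in min(s[1L], t[1L]):0) {
        for (v2 in min(s[2L], t[2L]):0) {
          if (v1 == 0L && v2 == 0L) next
          piece <- c(v1, v2)
          sub <- rec(shrink_first(Sm, piece), shrink_at(Tm, j, piece), kk - 1L)
          if (!is.null(sub)) return(c(list(piece), sub))
        }
      }
    }
    if (use_memo) {
      known <- fail_memo[[key]]
      fail_memo[[key]] <- max(kk, if (is.null(known)) 0L else known)
    }
    NULL
  }
  out <- NULL
  for (k in max(nrow(S), nrow(T)):(nrow(S) + nrow(T))) {
    out <- rec(canon_pairs(S), canon_pairs(T), k)
    if (!is.null(out)) break
  }
  if (is.null(out)) stop("internal error: oracle found no partition")
  pm <- do.call(rbind, out)
  if (is.null(pm)) pm <- matrix(integer(0), ncol = 2L)
  storage.mode(pm) <- "integer"
  pm <- pm[order(pm[, 1L], pm[, 2L]), , drop = FALSE]
  list(size = nrow(pm), partition = pm, method = "brute")
}

shrink_first <- function(m, piece) {
  r <- m[1L, ] - piece
  m <- m[-1L, , drop = FALSE]
  if (any(r > 0L)) m <- rbind(m, r)
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

shrink_at <- function(m, j, piece) {
  r <- m[j, ] - piece
  m <- m[-j, , drop = FALSE]
  if (any(r > 0L)) m <- rbind(m, r)
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

#' Brute-force pedigree isomorphism with witness
#'
#' Exhaustive backtracking over sex-preserving bijections between the
#' individuals of two pedigrees, pruned by (sex, in-degree, out-degree)
#' classes and incremental edge checking. Returns a witness bijection when
#' the pedigrees are isomorphic. Intended as independent ground truth for
#' small inputs; refuses pedigrees above the size cap.
#'
#' @param p,q [pedigree] objects.
#' @param cap maximum number of individuals per pedigree (default 12).
#' @return named character vector mapping individuals of `p` to
#'   individuals of `q` (a pedigree isomorphism), or `NULL` when the
#'   pedigrees are not isomorphic.
#' @export
pedigree_isomorphic_bruteforce <- function(p, q, cap = 12L) {
  stopifnot(inherits(p, "pedigree"), inherits(q, "pedigree"))
  if (length(p$individuals) > cap || length(q$individuals) > cap) {
    stop("pedigree exceeds the brute-force cap of ", cap,
         " individuals; use monogamous_isomorphic() where applicable")
  }
  if (length(p$individuals) != length(q$individuals)) return(NULL)
  if (nrow(p$edges) != nrow(q$edges)) return(NULL)

  class_of <- function(ped) {
    indeg <- in_degrees(ped); outdeg <- out_degrees(ped)
    paste(ped$sex, indeg, outdeg, sep = "/")
  }
  cp <- stats::setNames(class_of(p), p$individuals)
  cq <- stats::setNames(class_of(q), q$individuals)
  if (!identical(sort(unname(cp)), sort(unname(cq)))) return(NULL)

  adj_p <- edge_set(p); adj_q <- edge_set(q)
  ids_p <- p$individuals[order(cp, p$individuals)]
  n <- length(ids_p)
  mapping <- stats::setNames(rep(NA_character_, n), ids_p)
  used <- character(0)

  consistent <- function(v, w) {
    # all edges of p between v and already-mapped vertices must map to
    # edges of q, and vice versa
    for (u in names(mapping)[!is.na(mapping)]) {
      mu <- mapping[[u]]
      if (edge_in(adj_p, u, v) != edge_in(adj_q, mu, w)) return(FALSE)
      if (edge_in(adj_p, v, u) != edge_in(adj_q, w, mu)) return(FALSE)
    }
    TRUE
  }
  rec <- function(i) {
    if (i > n) return(TRUE)
    v <- ids_p[i]
    for (w in setdiff(names(cq)[cq == cp[[v]]], used)) {
      if (consistent(v, w)) {
        mapping[[v]] <<- w
        used <<- c(used, w)
        if (rec(i + 1L)) return(TRUE)
        mapping[[v]] <<- NA_character_
        used <<- setdiff(used, w)
      }
    }
    FALSE
  }
  if (rec(1L)) mapping[p$individuals] else NULL
}

edge_set <- function(p) {
  if (!nrow(p$edges)) return(character(0))
  paste(p$edges[, 1L], p$edges[, 2L], sep = "\r")
}

edge_in <- function(es, a, b) paste(a, b, sep = "\r") %in% es
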