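# Internal solver state: 3-column integer matrix (a, b, origin), where
# origin is the row index of the original input tuple the row descends
# from. Residuals keep the origin of the tuple they were subtracted from.

state_init <- function(m) {
  cbind(unclass(m), seq_len(nrow(m)))
}

state_pairs <- function(st) st[, 1:2, drop = FALSE]

state_drop <- function(st, i) st[-i, , drop = FALSE]

state_replace <- function(st, i, v) {
  if (v[1L] == 0L && v[2L] == 0L) return(state_drop(st, i))
  st[i, 1:2] <- v
  st
}

# classify cross pairs of a state; returns index-pair matrices
state_classes <- function(Sst, Tst) {
  cross_pairs_classified(state_pairs(Sst), state_pairs(Tst))
}

# lexicographically smallest (s, t) among index pairs `idx`
lex_smallest_pair <- function(Sst, Tst, idx) {
  s1 <- Sst[idx[, 1L], 1L]; s2 <- Sst[idx[, 1L], 2L]
  t1 <- Tst[idx[, 2L], 1L]; t2 <- Tst[idx[, 2L], 2L]
  idx[order(s1, s2, t1, t2)[1L], ]
}

# apply a dominating step at state level; returns list(piece, so, to, S, T)
state_dom_step <- function(Sst, Tst, i, j) {
  s <- Sst[i, 1:2]; t <- Tst[j, 1:2]
  piece <- pmin(s, t)
  so <- Sst[i, 3L]; to <- Tst[j, 3L]
  cls <- dominates(s, t)
  if (cls == "both_equal") {
    Sst <- state_drop(Sst, i); Tst <- state_drop(Tst, j)
  } else if (cls == "u_dominates") {
    Sst <- state_replace(Sst, i, s - t); Tst <- state_drop(Tst, j)
  } else {
    Tst <- state_replace(Tst, j, t - s); Sst <- state_drop(Sst, i)
  }
  list(piece = piece, so = so, to = to, S = Sst, T = Tst)
}

state_nondom_step <- function(Sst, Tst, i, j) {
  s <- Sst[i, 1:2]; t <- Tst[j, 1:2]
  so <- Sst[i, 3L]; to <- Tst[j, 3L]
  if (s[1L] > t[1L]) {
    piece <- c(t[1L], s[2L])
    Sst <- state_replace(Sst, i, c(s[1L] - t[1L], 0L))
    Tst <- state_replace(Tst, j, c(0L, t[2L] - s[2L]))
  } else {
    piece <- c(s[1L], t[2L])
    Sst <- state_replace(Sst, i, c(0L, s[2L] - t[2L]))
    Tst <- state_replace(Tst, j, c(t[1L] - s[1L], 0L))
  }
  list(piece = piece, so = so, to = to, S = Sst, T = Tst)
}

# terminal merge (one side down to <= 1 tuple): the other side's tuples
# are emitted as-is, each assigned to the single remaining opposite tuple
state_terminal <- function(Sst, Tst) {
  pieces <- list()
  if (nrow(Sst) <= 1L && nrow(Tst) <= 1L) {
    if (nrow(Sst) == 1L) {
      pieces[[1L]] <- c(Sst[1L, 1:2], Sst[1L, 3L], Tst[1L, 3L])
    }
  } else if (nrow(Sst) == 1L) {
    for (j in seq_len(nrow(Tst))) {
      pieces[[length(pieces) + 1L]] <- c(Tst[j, 1:2], Sst[1L, 3L], Tst[j, 3L])
    }
  } else {
    for (i in seq_len(nrow(Sst))) {
      pieces[[length(pieces) + 1L]] <- c(Sst[i, 1:2], Sst[i, 3L], Tst[1L, 3L])
    }
  }
  pieces
}

# greedy probe: from (Sst, Tst), apply lexicographically smallest
# dominating steps; TRUE if a terminal state is reached without needing a
# further non-dominating step
probe_dominating_only <- function(Sst, Tst) {
  repeat {
    if (nrow(Sst) <= 1L || nrow(Tst) <= 1L) return(TRUE)
    cls <- state_classes(Sst, Tst)
    if (!nrow(cls$dominating)) return(FALSE)
    ij <- lex_smallest_pair(Sst, Tst, cls$dominating)
    stp <- state_dom_step(Sst, Tst, ij[1L], ij[2L])
    Sst <- stp$S; Tst <- stp$T
  }
}

#' Subtraction heuristic for MCIPP
#'
#' Builds a common pair partition by repeatedly applying
#' dominating-partition steps (emit the dominated tuple, keep the
#' residual); when no dominating pair exists and both sides still hold at
#' least two tuples, a non-dominating starting pair is chosen by brute
#' force among the candidates such that the remainder can be finished with
#' dominating steps alone, and one non-dominating-partition step is
#' applied. When one side is down to a single tuple the opposite side is
#' emitted verbatim (its tuples already sum to the remaining one). The
#' result is a valid common partition of size at most `|S| + |T|`, hence a
#' factor-2 approximation of the optimum.
#'
#' Dominating pairs are selected deterministically (lexicographically
#' smallest `(s, t)`); the correctness of the procedure does not depend on
#' this tie-break.
#'
#' @param S,T pair multisets forming a feasible instance.
#' @param start optional forced first non-dominating pair, a list with
#'   elements `s` and `t` (length-2 tuples, members of `S` and `T`). When
#'   given, the non-dominating-partition step on `(s, t)` is applied
#'   before anything else.
#' @param preprocess move tuples common to `S` and `T` straight into the
#'   solution first (default `TRUE`).
#' @return an object of class `mcipp_result`: list with `partition`
#'   (two-column matrix of pieces), `assignment` (source row in `S` and
#'   `T` per piece), `size`, `method = "heuristic"`, certified
#'   `lower_bound`/`upper_bound`, and `nondom_steps` (number of
#'   non-dominating-partition steps taken).
#' @export
#' @examples
#' S <- rbind(c(9, 4), c(1, 11), c(6, 3))
#' T <- rbind(c(2, 8), c(12, 1), c(2, 9))
#' heuristic_mcipp(S, T, start = list(s = c(6, 3), t = c(2, 9)))
heuristic_mcipp <- function(S, T, start = NULL, preprocess = TRUE) {
  S <- as_pair_multiset(S); T <- as_pair_multiset(T)
  stop_if_infeasible(S, T)
  b <- mcipp_bounds(S, T)
  Sst <- state_init(S); Tst <- state_init(T)
  pieces <- list()   # each element: c(a, b, s_origin, t_origin)
  nondom_steps <- 0L

  emit <- function(stp) {
    pieces[[length(pieces) + 1L]] <<- c(stp$piece, stp$so, stp$to)
    Sst <<- stp$S; Tst <<- stp$T
  }

  if (preprocess) {
    repeat {
      hit <- NULL
      for (i in seq_len(nrow(Sst))) {
        j <- which(Tst[, 1L] == Sst[i, 1L] & Tst[, 2L] == Sst[i, 2L])
        if (length(j)) { hit <- c(i, j[1L]); break }
      }
      if (is.null(hit)) break
      emit(state_dom_step(Sst, Tst, hit[1L], hit[2L]))
    }
  }

  if (!is.null(start)) {
    i <- locate_tuple(state_pairs(Sst), start$s, "S")
    j <- locate_tuple(state_pairs(Tst), start$t, "T")
    if (dominates(start$s, start$t) != "non_dominating") {
      stop("forced start must be a non-dominating pair")
    }
    emit(state_nondom_step(Sst, Tst, i, j))
    nondom_steps <- nondom_steps + 1L
  }

  repeat {
    nS <- nrow(Sst); nT <- nrow(Tst)
    if (nS == 0L && nT == 0L) break
    if (nS <= 1L || nT <= 1L) {
      pieces <- c(pieces, state_terminal(Sst, Tst))
      break
    }
    cls <- state_classes(Sst, Tst)
    if (nrow(cls$dominating)) {
      ij <- lex_smallest_pair(Sst, Tst, cls$dominating)
      emit(state_dom_step(Sst, Tst, ij[1L], ij[2L]))
      next
    }
    # no dominating pair: brute-force a non-dominating start that leads to
    # successive dominating pairs (greedy probe, then exhaustive check);
    # degenerate pairs (piece (0,0)) are never eligible
    nd <- cls$non_dominating
    keep <- vapply(seq_len(nrow(nd)), function(r) {
      !nondom_piece_zero(Sst[nd[r, 1L], 1:2], Tst[nd[r, 2L], 1:2])
    }, logical(1))
    nd <- nd[keep, , drop = FALSE]
    if (!nrow(nd)) stop("internal error: no eligible non-dominating pair")
    chosen <- NULL
    for (r in seq_len(nrow(nd))) {
      stp <- state_nondom_step(Sst, Tst, nd[r, 1L], nd[r, 2L])
      if (probe_dominating_only(stp$S, stp$T)) { chosen <- stp; break }
    }
    if (is.null(chosen)) {
      for (r in seq_len(nrow(nd))) {
        stp <- state_nondom_step(Sst, Tst, nd[r, 1L], nd[r, 2L])
        if (dom_only_completable(state_pairs(stp$S), state_pairs(stp$T))) {
          chosen <- stp; break
        }
      }
    }
    if (is.null(chosen)) {
      stp <- state_nondom_step(Sst, Tst, nd[1L, 1L], nd[1L, 2L])
      chosen <- stp
    }
    emit(chosen)
    nondom_steps <- nondom_steps + 1L
  }

  pm <- do.call(rbind, pieces)
  if (is.null(pm)) pm <- matrix(integer(0), ncol = 4L)
  new_solve_result(
    partition = pm[, 1:2, drop = FALSE],
    assignment = data.frame(s = pm[, 3L], t = pm[, 4L]),
    size = nrow(pm),
    method = "heuristic",
    lower_bound = b[["lower"]], upper_bound = b[["upper"]],
    extra = list(nondom_steps = nondom_steps)
  )
}

#' Exhaustive analysis of heuristic step choices
#'
#' `dom_only_completable()` decides, by exhaustive search over all
#' dominating-partition step choices, whether an instance can be fully
#' decomposed by dominating steps alone (the terminal merge, which needs
#' no further non-dominating split, counts as completion).
#'
#' @param S,T pair multisets forming a feasible instance.
#' @return `TRUE` or `FALSE`.
#' @export
dom_only_completable <- function(S, T) {
  S <- as_pair_multiset(S); T <- as_pair_multiset(T)
  stop_if_infeasible(S, T)
  memo <- new.env(parent = emptyenv())
  rec <- function(Sm, Tm) {
    if (nrow(Sm) <= 1L || nrow(Tm) <= 1L) return(TRUE)
    key <- paste(pairs_key(Sm), pairs_key(Tm), sep = "#")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    memo[[key]] <- FALSE            # guard against revisits while exploring
    cls <- cross_pairs_classified(Sm, Tm)
    res <- FALSE
    dp <- cls$dominating
    for (r in seq_len(nrow(dp))) {
      stp <- state_dom_step(cbind(Sm, 0L), cbind(Tm, 0L), dp[r, 1L], dp[r, 2L])
      if (rec(state_pairs(stp$S), state_pairs(stp$T))) { res <- TRUE; break }
    }
    memo[[key]] <- res
    res
  }
  rec(canon_pairs(S), canon_pairs(T))
}

#' @rdname dom_only_completable
#' @details
#' `best_heuristic_size()` computes, by memoized exhaustive search over
#' all step choices the heuristic could make (dominating steps whenever
#' any dominating pair exists; non-dominating-partition steps only when
#' none does), the minimum partition size the heuristic can achieve.
#' @return `best_heuristic_size()`: an integer.
#' @export
best_heuristic_size <- function(S, T) {
  S <- as_pair_multiset(S); T <- as_pair_multiset(T)
  stop_if_infeasible(S, T)
  memo <- new.env(parent = emptyenv())
  rec <- function(Sm, Tm) {
    nS <- nrow(Sm); nT <- nrow(Tm)
    if (nS == 0L && nT == 0L) return(0L)
    if (nS <= 1L || nT <= 1L) return(max(nS, nT))
    key <- paste(pairs_key(Sm), pairs_key(Tm), sep = "#")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    memo[[key]] <- nS + nT + 1L     # provisional bound against revisits
    cls <- cross_pairs_classified(Sm, Tm)
    moves <- if (nrow(cls$dominating)) {
      list(idx = cls$dominating, fn = state_dom_step)
    } else {
      nd <- cls$non_dominating
      keep <- vapply(seq_len(nrow(nd)), function(r) {
        !nondom_piece_zero(Sm[nd[r, 1L], ], Tm[nd[r, 2L], ])
      }, logical(1))
      list(idx = nd[keep, , drop = FALSE], fn = state_nondom_step)
    }
    best <- Inf
    for (r in seq_len(nrow(moves$idx))) {
      stp <- moves$fn(cbind(Sm, 0L), cbind(Tm, 0L),
                      moves$idx[r, 1L], moves$idx[r, 2L])
      best <- min(best, 1L + rec(state_pairs(stp$S), state_pairs(stp$T)))
    }
    best <- as.integer(best)
    memo[[key]] <- best
    best
  }
  rec(canon_pairs(S), canon_pairs(T))
}

#' Classify the non-dominating starting pairs of an instance
#'
#' For an instance with no dominating cross pair, the heuristic must open
#' with one non-dominating-partition step. This helper classifies every
#' candidate starting pair: whether the remainder after the split can be
#' finished with dominating steps alone (existence over step choices,
#' checked exhaustively), and the best partition size the heuristic can
#' reach from that start under any step choices.
#'
#' @param S,T pair multisets forming a feasible instance.
#' @return data frame with one row per non-dominating cross pair: the
#'   tuple values (`s1`, `s2`, `t1`, `t2`), `dom_completable` (logical)
#'   and `best_size` (integer, includes the opening piece).
#' @export
#' @examples
#' S <- rbind(c(9, 4), c(1, 11), c(6, 3))
#' T <- rbind(c(2, 8), c(12, 1), c(2, 9))
#' mcipp_start_analysis(S, T)
mcipp_start_analysis <- function(S, T) {
  S <- as_pair_multiset(S); T <- as_pair_multiset(T)
  stop_if_infeasible(S, T)
  nd <- nondominating_pairs(S, T)
  nd$dom_completable <- NA
  nd$best_size <- NA_integer_
  for (r in which(nd$eligible)) {
    stp <- nondominating_step(S, T, c(nd$s1[r], nd$s2[r]), c(nd$t1[r], nd$t2[r]))
    nd$dom_completable[r] <- dom_only_completable(stp$S, stp$T)
    nd$best_size[r] <- 1L + best_heuristic_size(stp$S, stp$T)
  }
  nd
}
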