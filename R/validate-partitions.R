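#' Validate a common integer partition
#'
#' `Z` is a common partition of integer multisets `A` and `B` when `Z` can
#' be split into groups summing to the elements of `A` and, independently,
#' into groups summing to the elements of `B`. Feasibility is decided by
#' exhaustive grouping with memoization; this is intended for desk-scale
#' certification, not large instances.
#'
#' @param A,B multisets of positive integers (plain integer vectors).
#' @param Z candidate common partition (vector of positive integers).
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' validate_common_partition(c(5, 8), c(3, 10), c(1, 2, 2, 4, 4))  # TRUE
validate_common_partition <- function(A, B, Z) {
  A <- as_int_multiset(A); B <- as_int_multiset(B); Z <- as_int_multiset(Z)
  if (sum(A) != sum(B) || sum(Z) != sum(A)) return(FALSE)
  can_group_into(Z, A) && can_group_into(Z, B)
}

as_int_multiset <- function(x) {
  x <- as.vector(x, mode = "numeric")
  if (any(is.na(x)) || any(x != round(x)) || any(x < 1)) {
    stop("an integer multiset must contain positive integers only")
  }
  sort(as.integer(x))
}

# can `parts` be split into groups summing exactly to the `targets`?
can_group_into <- function(parts, targets, memo = new.env(parent = emptyenv())) {
  parts <- sort(parts, decreasing = TRUE)
  targets <- sort(targets, decreasing = TRUE)
  if (!length(targets)) return(!length(parts))
  key <- paste(paste(parts, collapse = ","), paste(targets, collapse = ","),
               sep = "|")
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  tgt <- targets[1L]
  res <- FALSE
  for (sub in subsets_summing_to(parts, tgt)) {
    rest <- remove_multiset(parts, parts[sub])
    if (can_group_into(rest, targets[-1L], memo)) { res <- TRUE; break }
  }
  memo[[key]] <- res
  res
}

# index subsets of `parts` (sorted decreasing) summing to `total`,
# skipping duplicate value patterns
subsets_summing_to <- function(parts, total) {
  out <- list()
  n <- length(parts)
  rec <- function(idx, start, remaining) {
    if (remaining == 0L) { out[[length(out) + 1L]] <<- idx; return(invisible()) }
    if (start > n) return(invisible())
    prev <- NA_integer_
    for (i in start:n) {
      v <- parts[i]
      if (v > remaining) next
      if (!is.na(prev) && v == prev) next   # skip equal-value siblings
      prev <- v
      rec(c(idx, i), i + 1L, remaining - v)
    }
    invisible()
  }
  rec(integer(0), 1L, total)
  out
}

remove_multiset <- function(x, drop) {
  for (v in drop) {
    i <- match(v, x)
    x <- x[-i]
  }
  x
}

#' Validate a common pair partition
#'
#' `H` is a common partition of pair multisets `S` and `T` when its first
#' projection is a common partition of the first projections of `S` and
#' `T` grouped tuple-wise, i.e. `H` can be split into groups whose
#' componentwise sums are the tuples of `S`, and independently into groups
#' summing to the tuples of `T`. Decided by exhaustive assignment search.
#'
#' @param S,T pair multisets.
#' @param H candidate partition (pair multiset; zero components allowed,
#'   (0,0) forbidden).
#' @return `TRUE` or `FALSE`.
#' @export
validate_pair_partition <- function(S, T, H) {
  S <- as_pair_multiset(S); T <- as_pair_multiset(T)
  H <- as_pair_multiset(H)
  if (!mcipp_feasible(S, T)) return(FALSE)
  if (!all(projection_sums(H) == projection_sums(S))) return(FALSE)
  !is.null(assign_pieces(H, S)) && !is.null(assign_pieces(H, T))
}

#' Recover a piece-to-source assignment of a common pair partition
#'
#' @param S,T pair multisets.
#' @param H a valid common pair partition of `S` and `T`.
#' @return list with integer vectors `s` and `t`: for each row of the
#'   canonical `H`, the row index of the source tuple in `S` (resp. `T`)
#'   it is assigned to; or `NULL` if `H` is not a common partition.
#' @export
find_pair_assignment <- function(S, T, H) {
  S <- as_pair_multiset(S); T <- as_pair_multiset(T)
  H <- as_pair_multiset(H)
  a_s <- assign_pieces(H, S)
  if (is.null(a_s)) return(NULL)
  a_t <- assign_pieces(H, T)
  if (is.null(a_t)) return(NULL)
  list(s = a_s, t = a_t)
}

# Backtracking assignment of pieces (rows of H) to source tuples (rows of M)
# such that pieces assigned to each source sum componentwise to it.
# Returns per-piece source indices or NULL.
assign_pieces <- function(H, M) {
  nH <- nrow(H); nM <- nrow(M)
  if (nH == 0L) return(if (nM == 0L) integer(0) else NULL)
  ord <- order(-(H[, 1L] + H[, 2L]), -H[, 1L])   # big pieces first
  Ho <- H[ord, , drop = FALSE]
  remaining <- M
  assign <- integer(nH)
  rec <- function(i) {
    if (i > nH) return(all(remaining == 0L))
    piece <- Ho[i, ]
    tried <- character(0)
    for (m in seq_len(nM)) {
      cap <- remaining[m, ]
      key <- paste(cap, collapse = ",")
      if (key %in% tried) next
      if (cap[1L] >= piece[1L] && cap[2L] >= piece[2L]) {
        tried <- c(tried, key)
        remaining[m, ] <<- cap - piece
        assign[i] <<- m
        if (rec(i + 1L)) return(TRUE)
        remaining[m, ] <<- cap
      }
    }
    FALSE
  }
  if (!rec(1L)) return(NULL)
  assign[order(ord)]
}
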