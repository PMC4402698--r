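# Seeded generators. Every generator takes an explicit seed and restores
# nothing: it calls set.seed() itself so the same seed always yields a
# byte-identical object.

#' Generate an MCIPP instance with a planted common partition
#'
#' Draws `n_pieces` random tuples (componentwise uniform on
#' `0:max_value`, rejecting (0,0)), then groups them randomly into
#' `sides[1]` non-empty groups summed to form `S` and, independently, into
#' `sides[2]` groups summed to form `T`. The pieces themselves are then a
#' common partition of `(S, T)`, so the instance is feasible by
#' construction and its optimum is at most `n_pieces`.
#'
#' @param n_pieces number of planted pieces (must be at least
#'   `max(sides)`).
#' @param max_value componentwise maximum piece value (default 6).
#' @param sides integer vector `c(|S|, |T|)` (default `c(2, 2)`).
#' @param seed integer seed.
#' @return list of class `planted_mcipp` with elements `S`, `T`
#'   (pair multisets), `planted` (the pieces, a pair multiset) and `seed`.
#' @export
#' @examples
#' gen_planted_mcipp(4, sides = c(2, 3), seed = 1)
gen_planted_mcipp <- function(n_pieces, max_value = 6L, sides = c(2L, 2L),
                              seed) {
  stopifnot(length(sides) == 2L, all(sides >= 1L), max_value >= 1L)
  if (n_pieces < max(sides)) {
    stop("'n_pieces' must be at least max(sides) so every group is non-empty")
  }
  set.seed(seed)
  pieces <- matrix(0L, nrow = n_pieces, ncol = 2L)
  for (r in seq_len(n_pieces)) {
    repeat {
      v <- sample.int(max_value + 1L, 2L, replace = TRUE) - 1L
      if (any(v > 0L)) { pieces[r, ] <- v; break }
    }
  }
  group_sums <- function(n_groups) {
    grp <- c(sample.int(n_groups), sample.int(n_groups, n_pieces - n_groups,
                                              replace = TRUE))
    grp <- grp[sample.int(n_pieces)]
    cbind(as.integer(tapply(pieces[, 1L], factor(grp, levels = seq_len(n_groups)), sum)),
          as.integer(tapply(pieces[, 2L], factor(grp, levels = seq_len(n_groups)), sum)))
  }
  structure(
    list(S = as_pair_multiset(group_sums(sides[1L])),
         T = as_pair_multiset(group_sums(sides[2L])),
         planted = as_pair_multiset(pieces),
         seed = seed),
    class = "planted_mcipp"
  )
}

#' @export
print.planted_mcipp <- function(x, ...) {
  cat(sprintf("<planted MCIPP instance (seed %s): |S| = %d, |T| = %d, %d planted piece(s)>\n",
              format(x$seed), nrow(x$S), nrow(x$T), nrow(x$planted)))
  invisible(x)
}

#' Generate a random two-generation pedigree
#'
#' Builds `n_families` mating couples and their children. With probability
#' `polygamy_rate` a couple reuses an existing generation-1 individual of
#' the required sex (subject to not duplicating an existing couple), which
#' introduces polygamy; at rate 0 the pedigree is monogamous. Children
#' counts are drawn from `child_dist` (default: 1 plus a geometric with
#' success probability 1/2, i.e. at least one child, two on average) and
#' child sexes are uniform.
#'
#' @param n_families number of couples.
#' @param polygamy_rate probability in `[0, 1]` that a parent slot reuses
#'   an existing generation-1 individual.
#' @param child_dist function of `n` returning `n` child counts, all at
#'   least 1.
#' @param seed integer seed.
#' @return a valid two-generation [pedigree]; the generated family counts
#'   are recorded in the `ground_truth` attribute (a data frame with
#'   columns `i`, `j`, sorted).
#' @export
gen_random_pedigree <- function(n_families, polygamy_rate = 0,
                                child_dist = function(n) 1L + stats::rgeom(n, 0.5),
                                seed) {
  stopifnot(n_families >= 1L, polygamy_rate >= 0, polygamy_rate <= 1)
  set.seed(seed)
  males <- character(0); females <- character(0)
  couples <- character(0)
  edges <- list()
  sex <- character(0)
  fam_i <- integer(n_families); fam_j <- integer(n_families)
  n_kid <- 0L
  for (f in seq_len(n_families)) {
    repeat {
      father <- if (length(males) && stats::runif(1) < polygamy_rate) {
        sample(males, 1L)
      } else NA_character_
      mother <- if (length(females) && stats::runif(1) < polygamy_rate) {
        sample(females, 1L)
      } else NA_character_
      if (is.na(father)) {
        father <- sprintf("M%03d", length(males) + 1L)
      }
      if (is.na(mother)) {
        mother <- sprintf("F%03d", length(females) + 1L)
      }
      if (!(paste(father, mother) %in% couples)) break
    }
    if (!father %in% males) { males <- c(males, father); sex[[father]] <- "male" }
    if (!mother %in% females) { females <- c(females, mother); sex[[mother]] <- "female" }
    couples <- c(couples, paste(father, mother))
    nc <- child_dist(1L)
    if (nc < 1L) stop("'child_dist' must return counts of at least 1")
    for (k in seq_len(nc)) {
      n_kid <- n_kid + 1L
      kid <- sprintf("C%04d", n_kid)
      ks <- sample(c("female", "male"), 1L)
      sex[[kid]] <- ks
      edges[[length(edges) + 1L]] <- c(father, kid)
      edges[[length(edges) + 1L]] <- c(mother, kid)
      if (ks == "female") fam_i[f] <- fam_i[f] + 1L else fam_j[f] <- fam_j[f] + 1L
    }
  }
  p <- pedigree(edges = do.call(rbind, edges), sex = sex)
  gt <- data.frame(i = fam_i, j = fam_j)
  gt <- gt[order(gt$i, gt$j), , drop = FALSE]
  rownames(gt) <- NULL
  attr(p, "ground_truth") <- gt
  p
}

#' Generate a pair of small bipartite graphs
#'
#' Draws a random bipartite graph on `n_u` + `n_v` nodes with edge
#' probability `p_edge` (resampling until no node is isolated). The second
#' graph is either a randomly relabeled copy (`isomorphic = TRUE`) or an
#' edge-perturbed copy verified non-isomorphic by exhaustive search over
#' side-preserving node bijections (`isomorphic = FALSE`; refuses sides
#' larger than `cap`).
#'
#' @param n_u,n_v side sizes.
#' @param p_edge edge probability (default 0.5).
#' @param isomorphic whether the two graphs should be isomorphic.
#' @param seed integer seed.
#' @param cap maximum side size for the non-isomorphism check (default 5).
#' @return list of two graphs, each a list with `U`, `V` (character
#'   vectors) and `edges` (two-column character matrix).
#' @export
gen_bipartite_pair <- function(n_u, n_v, p_edge = 0.5, isomorphic = TRUE,
                               seed, cap = 5L) {
  stopifnot(n_u >= 1L, n_v >= 1L, p_edge > 0, p_edge <= 1)
  if (!isomorphic && (n_u > cap || n_v > cap)) {
    stop("non-isomorphism verification needs side sizes <= ", cap)
  }
  set.seed(seed)
  g1 <- rand_bipartite(n_u, n_v, p_edge, prefix = c("u", "v"))
  if (isomorphic) {
    perm_u <- sample(g1$U); perm_v <- sample(g1$V)
    map <- stats::setNames(c(paste0("x", seq_len(n_u)), paste0("y", seq_len(n_v))),
                           c(perm_u, perm_v))
    e2 <- cbind(map[g1$edges[, 1L]], map[g1$edges[, 2L]])
    dimnames(e2) <- NULL
    g2 <- list(U = sort(unname(map[g1$U])), V = sort(unname(map[g1$V])),
               edges = e2[order(e2[, 1L], e2[, 2L]), , drop = FALSE])
    return(list(g1, g2))
  }
  repeat {
    g2 <- rand_bipartite(n_u, n_v, p_edge, prefix = c("x", "y"))
    if (!bipartite_isomorphic_bruteforce(g1, g2)) return(list(g1, g2))
  }
}

rand_bipartite <- function(n_u, n_v, p_edge, prefix) {
  U <- sprintf("%s%d", prefix[1L], seq_len(n_u))
  V <- sprintf("%s%d", prefix[2L], seq_len(n_v))
  repeat {
    adj <- matrix(stats::runif(n_u * n_v) < p_edge, n_u, n_v)
    if (all(rowSums(adj) > 0) && all(colSums(adj) > 0)) break
  }
  idx <- which(adj, arr.ind = TRUE)
  edges <- cbind(U[idx[, 1L]], V[idx[, 2L]])
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  list(U = U, V = V, edges = edges)
}

#' Brute-force bipartite graph isomorphism
#'
#' Exhaustive search over side-preserving node bijections (U to U, V to
#' V). Used to certify generated non-isomorphic pairs and as an
#' independent oracle for the reduction-pedigree construction.
#'
#' @param g1,g2 bipartite graphs as returned by [gen_bipartite_pair()].
#' @return `TRUE` or `FALSE`.
#' @export
bipartite_isomorphic_bruteforce <- function(g1, g2) {
  if (length(g1$U) != length(g2$U) || length(g1$V) != length(g2$V) ||
      nrow(g1$edges) != nrow(g2$edges)) {
    return(FALSE)
  }
  target <- sort(paste(g2$edges[, 1L], g2$edges[, 2L], sep = "\r"))
  for (pu in permutations_of(g2$U)) {
    mu <- stats::setNames(pu, g1$U)
    for (pv in permutations_of(g2$V)) {
      mv <- stats::setNames(pv, g1$V)
      mapped <- sort(paste(mu[g1$edges[, 1L]], mv[g1$edges[, 2L]], sep = "\r"))
      if (identical(mapped, target)) return(TRUE)
    }
  }
  FALSE
}

permutations_of <- function(x) {
  n <- length(x)
  if (n == 1L) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in permutations_of(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}
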