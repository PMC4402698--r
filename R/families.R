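#' Decompose a two-generation pedigree into mating families
#'
#' A family is a couple (an unordered male/female pair of generation-1
#' individuals sharing at least one child) together with their children;
#' a couple with i daughters and j sons contributes the pair (i, j).
#' Families may share a parent (polygamy) but never a child, and every
#' generation-2 individual belongs to exactly one family, so the family
#' counts conserve children sex-wise.
#'
#' @param p a valid two-generation [pedigree].
#' @return data frame of class `family_multiset` with columns `father`,
#'   `mother`, `i` (daughters), `j` (sons), rows sorted by `(i, j)`; the
#'   children of each family are kept in the `children` attribute.
#' @seealso [family_pairs()], [is_monogamous()]
#' @export
families_of <- function(p) {
  g <- assign_generations(p)
  if (is.null(g) || max(g) != 2L) {
    stop("families_of() requires a two-generation pedigree")
  }
  par_of <- split(p$edges[, "parent"], p$edges[, "child"])
  rows <- list()
  children <- list()
  for (child in names(par_of)) {
    pars <- par_of[[child]]
    father <- pars[p$sex[pars] == "male"]
    mother <- pars[p$sex[pars] == "female"]
    key <- paste(father, mother, sep = "\r")
    if (is.null(rows[[key]])) {
      rows[[key]] <- list(father = father, mother = mother, i = 0L, j = 0L)
      children[[key]] <- character(0)
    }
    if (p$sex[[child]] == "female") {
      rows[[key]]$i <- rows[[key]]$i + 1L
    } else {
      rows[[key]]$j <- rows[[key]]$j + 1L
    }
    children[[key]] <- c(children[[key]], child)
  }
  fam <- data.frame(
    father = vapply(rows, `[[`, "", "father"),
    mother = vapply(rows, `[[`, "", "mother"),
    i = vapply(rows, `[[`, 0L, "i"),
    j = vapply(rows, `[[`, 0L, "j"),
    row.names = NULL
  )
  ord <- order(fam$i, fam$j, fam$father, fam$mother)
  fam <- fam[ord, , drop = FALSE]
  rownames(fam) <- NULL
  attr(fam, "children") <- children[names(rows)[ord]]
  class(fam) <- c("family_multiset", "data.frame")
  fam
}

#' @export
print.family_multiset <- function(x, ...) {
  cat(sprintf("<family multiset: %d family(ies)>\n", nrow(x)))
  cat(" ", paste0("<", x$i, ",", x$j, ">", collapse = " "), "\n")
  invisible(x)
}

#' Family multiset as a pair multiset
#'
#' Extracts the (daughters, sons) count pairs of a family decomposition as
#' a [pair multiset][as_pair_multiset], the form consumed by the MCIPP
#' solvers.
#'
#' @param fam a `family_multiset` from [families_of()], or a pedigree
#'   (decomposed on the fly).
#' @return a `pair_multiset` (two-column integer matrix).
#' @export
family_pairs <- function(fam) {
  if (inherits(fam, "pedigree")) fam <- families_of(fam)
  stopifnot(inherits(fam, "family_multiset"))
  as_pair_multiset(cbind(fam$i, fam$j))
}

#' Test whether a two-generation pedigree is monogamous
#'
#' Monogamy: every generation-1 individual mates with exactly one partner,
#' i.e. appears in exactly one couple.
#'
#' @param p a valid two-generation [pedigree].
#' @return `TRUE` or `FALSE`.
#' @export
is_monogamous <- function(p) {
  fam <- families_of(p)
  !anyDuplicated(fam$father) && !anyDuplicated(fam$mother)
}

#' Exact isomorphism test for monogamous two-generation pedigrees
#'
#' A monogamous two-generation pedigree is a disjoint union of families,
#' so two such pedigrees are isomorphic exactly when their family
#' multisets of (daughters, sons) pairs coincide. The pairs are compared
#' after a two-pass sort (by first component, then within ties by second),
#' giving an O(n log n) test overall. Sexes are not interchangeable: a
#' family with two daughters and one son never matches one with one
#' daughter and two sons.
#'
#' @param p,q valid, monogamous, two-generation [pedigree] objects.
#' @return `TRUE` or `FALSE`.
#' @export
monogamous_isomorphic <- function(p, q) {
  if (!is_monogamous(p) || !is_monogamous(q)) {
    stop("monogamous_isomorphic() requires monogamous pedigrees; ",
         "for general two-generation pedigrees use similarity_mcipp()")
  }
  mp <- sorted_pairs_two_pass(family_pairs(families_of(p)))
  mq <- sorted_pairs_two_pass(family_pairs(families_of(q)))
  identical(mp, mq)
}

# two-pass sort: first by first components, then, within runs of equal
# first components, by second components (radix-style, stable)
sorted_pairs_two_pass <- function(m) {
  m <- unclass(m)
  m <- m[order(m[, 2L]), , drop = FALSE]     # pass 2 key first (stable sort)
  m <- m[order(m[, 1L]), , drop = FALSE]
  dimnames(m) <- NULL
  m
}

#' Build the reduction pedigree of a bipartite graph
#'
#' The gadget behind the hardness of general two-generation pedigree
#' isomorphism: the nodes of `U` become generation-1 males, the nodes of
#' `V` generation-1 females, and every edge (u, v) becomes one new
#' generation-2 female child of the couple (u, v). Every couple of the
#' resulting pedigree has exactly one child and all children are female,
#' so every family is a (1, 0)-family; two bipartite graphs are
#' isomorphic exactly when their reduction pedigrees are.
#'
#' @param U,V character vectors of node names (disjoint).
#' @param edges two-column character matrix of (u, v) edges with
#'   `u` in `U`, `v` in `V`. Every node must occur in at least one edge
#'   (the construction assumes no isolated nodes).
#' @return a valid two-generation [pedigree].
#' @export
#' @examples
#' pedigree_from_bipartite(c("u"), c("v"), rbind(c("u", "v")))
pedigree_from_bipartite <- function(U, V, edges) {
  U <- as.character(U); V <- as.character(V)
  if (length(intersect(U, V))) stop("'U' and 'V' must be disjoint")
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (!is.matrix(edges) || ncol(edges) != 2L) {
    stop("'edges' must be a two-column matrix of (u, v) pairs")
  }
  storage.mode(edges) <- "character"
  if (!all(edges[, 1L] %in% U) || !all(edges[, 2L] %in% V)) {
    stop("every edge must join a node of U to a node of V")
  }
  if (anyDuplicated(paste(edges[, 1L], edges[, 2L], sep = "\r"))) {
    stop("duplicated edge in bipartite graph")
  }
  isolated <- c(setdiff(U, edges[, 1L]), setdiff(V, edges[, 2L]))
  if (length(isolated)) {
    stop("isolated node(s) in bipartite graph: ",
         paste(isolated, collapse = ", "))
  }
  child <- paste0(edges[, 1L], "::", edges[, 2L])
  if (length(intersect(child, c(U, V)))) {
    stop("generated child ids collide with input node names")
  }
  ped_edges <- rbind(cbind(edges[, 1L], child), cbind(edges[, 2L], child))
  sex <- c(
    stats::setNames(rep("male", length(U)), U),
    stats::setNames(rep("female", length(V)), V),
    stats::setNames(rep("female", length(child)), child)
  )
  pedigree(edges = ped_edges, sex = sex)
}

#' Similarity of two general two-generation pedigrees
#'
#' Scores how alike two (possibly polygamous) two-generation pedigrees
#' are by decomposing each into families and computing a minimum common
#' pair partition of the two family multisets: the common partition is a
#' decomposition of both pedigrees' generation-2 individuals into matching
#' sub-families (a generation-1 couple may appear in several
#' sub-families), and the smaller its size, the more similar the
#' pedigrees. The two pedigrees must have equal numbers of generation-2
#' females and of generation-2 males; otherwise no common partition exists
#' and the pedigrees are incomparable under this measure.
#'
#' @param p,q valid two-generation [pedigree] objects.
#' @param method solver passed to [mcipp_optimize()] (`"fpt"`, `"brute"`)
#'   or `"heuristic"` for the factor-2 approximation.
#' @return an `mcipp_result`; its `partition` rows are the matched
#'   sub-family sizes, and the `families_p` / `families_q` entries carry
#'   the two family decompositions.
#' @export
similarity_mcipp <- function(p, q, method = c("heuristic", "fpt", "brute")) {
  method <- match.arg(method)
  fp <- families_of(p); fq <- families_of(q)
  S <- family_pairs(fp); T <- family_pairs(fq)
  if (!mcipp_feasible(S, T)) {
    stop("incomparable pedigrees: generation-2 female and male counts ",
         "must agree between the two pedigrees")
  }
  res <- if (method == "heuristic") heuristic_mcipp(S, T) else
    mcipp_optimize(S, T, method = method)
  res$families_p <- fp
  res$families_q <- fq
  res
}
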