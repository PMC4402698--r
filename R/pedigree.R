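#' Construct a pedigree
#'
#' A pedigree is a directed acyclic graph of sexed individuals in which edges
#' run from parent to child. A well-formed pedigree satisfies four axioms:
#' the graph is acyclic, every individual has in-degree 0 (founder) or 2,
#' the two parents of any child have opposite sexes, and no individual is
#' isolated. The constructor only performs structural coercion; use
#' [validate_pedigree()] to check the axioms (violations are data, not
#' errors).
#'
#' Individual identifiers are opaque strings. Pedigrees are treated as
#' unlabeled for all comparison purposes: no operation compares individuals
#' across two pedigrees by identifier.
#'
#' @param edges two-column character matrix (or data frame) of
#'   (parent, child) pairs; may have zero rows.
#' @param sex named character vector mapping every individual to `"male"` or
#'   `"female"`. Individuals that appear in `sex` but in no edge are kept
#'   (they will be flagged as isolated by the validator).
#' @return an object of class `pedigree`: a list with elements
#'   `individuals` (sorted character vector), `sex` (named character vector)
#'   and `edges` (two-column character matrix, rows sorted).
#' @seealso [validate_pedigree()], [assign_generations()], [read_ped()]
#' @export
#' @examples
#' p <- pedigree(
#'   edges = rbind(c("dad", "kid"), c("mom", "kid")),
#'   sex = c(dad = "male", mom = "female", kid = "female")
#' )
#' validate_pedigree(p)
pedigree <- function(edges, sex) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  }
  if (!is.character(edges)) storage.mode(edges) <- "character"
  if (ncol(edges) != 2L) stop("'edges' must have two columns (parent, child)")
  colnames(edges) <- c("parent", "child")
  if (anyDuplicated(paste(edges[, 1L], edges[, 2L], sep = "\r"))) {
    stop("duplicated edge in pedigree")
  }
  sex <- unlist(sex)
  if (is.null(names(sex)) || any(!nzchar(names(sex)))) {
    stop("'sex' must be a named vector")
  }
  if (anyDuplicated(names(sex))) stop("duplicate individual id in 'sex'")
  sex <- vapply(sex, as_sex, character(1))
  ids <- sort(unique(c(names(sex), as.vector(edges))))
  missing_sex <- setdiff(ids, names(sex))
  if (length(missing_sex)) {
    stop("no sex given for individual(s): ", paste(missing_sex, collapse = ", "))
  }
  sex <- sex[ids]
  ord <- order(edges[, 1L], edges[, 2L])
  edges <- edges[ord, , drop = FALSE]
  structure(
    list(individuals = ids, sex = sex, edges = edges),
    class = "pedigree"
  )
}

# normalise a sex label; accepts male/female, m/f, 1/2
as_sex <- function(x) {
  x <- tolower(as.character(x))
  if (x %in% c("male", "m", "1")) return("male")
  if (x %in% c("female", "f", "2")) return("female")
  stop("invalid sex code: '", x, "'")
}

#' @export
print.pedigree <- function(x, ...) {
  g <- tryCatch(assign_generations(x), error = function(e) NULL)
  cat(sprintf(
    "<pedigree> %d individuals (%d female, %d male), %d edges",
    length(x$individuals), sum(x$sex == "female"), sum(x$sex == "male"),
    nrow(x$edges)
  ), "\n")
  if (!is.null(g)) {
    cat(sprintf("  generational with %d generation(s)\n", max(g)))
  } else {
    cat("  not generational\n")
  }
  invisible(x)
}

#' @export
format.pedigree <- function(x, ...) {
  sprintf("<pedigree: %d individuals, %d edges>",
          length(x$individuals), nrow(x$edges))
}

in_degrees <- function(p) {
  deg <- stats::setNames(integer(length(p$individuals)), p$individuals)
  if (nrow(p$edges)) {
    tab <- table(p$edges[, "child"])
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

out_degrees <- function(p) {
  deg <- stats::setNames(integer(length(p$individuals)), p$individuals)
  if (nrow(p$edges)) {
    tab <- table(p$edges[, "parent"])
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

# Kahn topological sort; returns ordered ids or NULL if a cycle exists
topo_order <- function(p) {
  indeg <- in_degrees(p)
  kids_of <- split(p$edges[, "child"], p$edges[, "parent"])
  queue <- names(indeg)[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    out <- c(out, v)
    for (w in kids_of[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) != length(p$individuals)) NULL else out
}

#' Validate a pedigree against the structural axioms
#'
#' Checks the four axioms: acyclicity, in-degree 0 or 2 for every
#' individual, opposite-sex parents for every child, and no isolated
#' individuals. Violations are reported as data, never raised as errors.
#'
#' @param p a [pedigree] object.
#' @return list of class `pedigree_validation` with elements `ok` (logical)
#'   and `violations` (character vector of human-readable axiom violations,
#'   empty when `ok`).
#' @export
validate_pedigree <- function(p) {
  stopifnot(inherits(p, "pedigree"))
  violations <- character(0)
  if (is.null(topo_order(p))) {
    violations <- c(violations, "cycle: pedigree graph is not acyclic")
  }
  indeg <- in_degrees(p)
  bad_deg <- names(indeg)[!(indeg %in% c(0L, 2L))]
  for (v in bad_deg) {
    violations <- c(violations,
                    sprintf("in-degree %d for individual '%s'", indeg[[v]], v))
  }
  if (nrow(p$edges)) {
    par_of <- split(p$edges[, "parent"], p$edges[, "child"])
    for (child in names(par_of)) {
      pars <- par_of[[child]]
      if (length(pars) == 2L && p$sex[[pars[1L]]] == p$sex[[pars[2L]]]) {
        violations <- c(violations,
                        sprintf("same-sex parents for child '%s'", child))
      }
    }
  }
  outdeg <- out_degrees(p)
  isolated <- names(indeg)[indeg == 0L & outdeg == 0L]
  for (v in isolated) {
    violations <- c(violations, sprintf("isolated individual '%s'", v))
  }
  structure(list(ok = length(violations) == 0L, violations = violations),
            class = "pedigree_validation")
}

#' @export
print.pedigree_validation <- function(x, ...) {
  if (x$ok) {
    cat("ok\n")
  } else {
    cat("invalid pedigree:\n")
    for (v in x$violations) cat("  -", v, "\n")
  }
  invisible(x)
}

#' Assign generation numbers to a pedigree
#'
#' A pedigree is generational when a function g exists with g = 1 on every
#' founder (in-degree 0) and g(child) = g(parent) + 1 along every edge.
#' Inter-generational matings (a couple drawn from different generations)
#' make the constraints inconsistent, in which case no such g exists.
#'
#' @param p a valid [pedigree] (an invalid pedigree is rejected).
#' @return named integer vector mapping each individual to its generation,
#'   or `NULL` if the pedigree is not generational.
#' @export
#' @examples
#' p <- pedigree(
#'   edges = rbind(c("dad", "kid"), c("mom", "kid")),
#'   sex = c(dad = "male", mom = "female", kid = "female")
#' )
#' assign_generations(p)
assign_generations <- function(p) {
  v <- validate_pedigree(p)
  if (!v$ok) {
    stop("invalid pedigree: ", paste(v$violations, collapse = "; "))
  }
  ord <- topo_order(p)
  g <- stats::setNames(rep(NA_integer_, length(p$individuals)), p$individuals)
  indeg <- in_degrees(p)
  par_of <- if (nrow(p$edges)) split(p$edges[, "parent"], p$edges[, "child"]) else list()
  for (v_id in ord) {
    if (indeg[[v_id]] == 0L) {
      g[[v_id]] <- 1L
    } else {
      pg <- g[par_of[[v_id]]]
      if (length(unique(pg)) != 1L) return(NULL)  # parents from different generations
      g[[v_id]] <- pg[[1L]] + 1L
    }
  }
  g
}

#' Test whether a pedigree is a two-generation pedigree
#'
#' @param p a valid [pedigree].
#' @return `TRUE` iff `p` is generational with maximum generation 2.
#' @export
is_two_generation <- function(p) {
  g <- assign_generations(p)
  !is.null(g) && max(g) == 2L
}
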