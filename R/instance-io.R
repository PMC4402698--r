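#' Read and write MCIPP / MCIP instance files
#'
#' A pair-multiset file holds one tuple per line as `i<TAB>j`; an integer
#' multiset file holds one positive integer per line. `#`-prefixed
#' comments and blank lines are skipped. Writers emit canonical
#' (lexicographically sorted) order so files are byte-stable.
#'
#' @param path file path.
#' @return `read_pair_multiset()`: a `pair_multiset`;
#'   `read_int_multiset()`: a sorted integer vector.
#' @name instance-io
NULL

#' @rdname instance-io
#' @export
read_pair_multiset <- function(path) {
  tab <- read_tab_lines(path, 2L)
  if (!nrow(tab)) stop("empty pair multiset file: ", path)
  m <- suppressWarnings(cbind(as.numeric(tab[, 1L]), as.numeric(tab[, 2L])))
  if (any(is.na(m))) stop("non-numeric entry in ", path)
  as_pair_multiset(m)
}

#' @rdname instance-io
#' @param m a pair multiset.
#' @export
write_pair_multiset <- function(m, path) {
  m <- as_pair_multiset(m)
  writeLines(sprintf("%d\t%d", m[, 1L], m[, 2L]), path)
  invisible(path)
}

#' @rdname instance-io
#' @export
read_int_multiset <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty integer multiset file: ", path)
  x <- suppressWarnings(as.numeric(lines))
  if (any(is.na(x))) stop("non-numeric entry in ", path)
  as_int_multiset(x)
}

#' @rdname instance-io
#' @param x an integer multiset.
#' @export
write_int_multiset <- function(x, path) {
  x <- as_int_multiset(x)
  writeLines(sprintf("%d", x), path)
  invisible(path)
}

#' Read a bipartite graph from an edge-list file
#'
#' Lines `u<TAB>v`; the left column forms the node set `U`, the right
#' column `V`.
#'
#' @param path file path.
#' @return list with `U`, `V`, `edges` as used by
#'   [pedigree_from_bipartite()].
#' @export
read_bipartite_edges <- function(path) {
  edges <- read_tab_lines(path, 2L)
  if (!nrow(edges)) stop("empty bipartite edge file: ", path)
  list(U = sort(unique(edges[, 1L])), V = sort(unique(edges[, 2L])),
       edges = edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE])
}
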