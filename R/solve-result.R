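# Construct a solver result. `partition` is a 2-col integer matrix of
# pieces; `assignment` (optional) a data.frame with columns s, t giving the
# source tuple row (in the canonical input S / T) of each piece.
new_solve_result <- function(partition, size, method, lower_bound, upper_bound,
                             assignment = NULL, extra = list()) {
  partition <- canon_with_assignment(partition, assignment)
  res <- c(list(
    partition = partition$pieces,
    assignment = partition$assignment,
    size = as.integer(size),
    method = method,
    lower_bound = as.integer(lower_bound),
    upper_bound = as.integer(upper_bound)
  ), extra)
  class(res) <- "mcipp_result"
  res
}

canon_with_assignment <- function(pieces, assignment) {
  if (!nrow(pieces)) {
    return(list(pieces = matrix(integer(0), ncol = 2L), assignment = assignment))
  }
  storage.mode(pieces) <- "integer"
  dimnames(pieces) <- NULL
  ord <- order(pieces[, 1L], pieces[, 2L])
  list(
    pieces = pieces[ord, , drop = FALSE],
    assignment = if (is.null(assignment)) NULL else assignment[ord, , drop = FALSE]
  )
}

#' @export
print.mcipp_result <- function(x, ...) {
  cat(sprintf("<MCIPP %s solution: %d piece(s); certified bounds [%d, %d]>\n",
              x$method, x$size, x$lower_bound, x$upper_bound))
  if (nrow(x$partition)) {
    cat(" ", paste0("<", x$partition[, 1L], ",", x$partition[, 2L], ">",
                    collapse = " "), "\n")
  }
  invisible(x)
}

# merge pieces sharing the same (s, t) source pair: in an optimal partition
# at most one piece joins any source pair, so merging never hurts and
# restores that normal form after a branching search
merge_same_source <- function(pieces, assignment) {
  if (is.null(assignment) || nrow(pieces) <= 1L) {
    return(list(pieces = pieces, assignment = assignment))
  }
  key <- paste(assignment$s, assignment$t, sep = "|")
  if (!anyDuplicated(key)) return(list(pieces = pieces, assignment = assignment))
  agg1 <- tapply(pieces[, 1L], key, sum)
  agg2 <- tapply(pieces[, 2L], key, sum)
  keys <- names(agg1)
  st <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  list(
    pieces = cbind(as.integer(agg1), as.integer(agg2)),
    assignment = data.frame(s = as.integer(st[, 1L]), t = as.integer(st[, 2L]))
  )
}
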