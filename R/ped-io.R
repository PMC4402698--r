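#' Read a pedigree from a PED-style file
#'
#' The dialect is a minimal subset of the ubiquitous PED convention: four
#' mandatory tab-separated columns per row -- individual id, father id,
#' mother id, sex (1 = male, 2 = female) -- with `"0"` as the
#' missing-parent sentinel and `#`-prefixed comment lines. Both parents
#' must be present or both absent. Referenced parents must have their own
#' rows and the sexes must be consistent (father male, mother female).
#' Isolated individuals (founders that are nobody's parent) are removed
#' with a warning.
#'
#' @param path path to the file.
#' @return a [pedigree].
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path)
  lines <- trimws(lines, which = "right")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty PED file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    stop(sprintf("PED row %d: expected 4 tab-separated fields, got %d",
                 which(nf != 4L)[1L], nf[nf != 4L][1L]))
  }
  tab <- do.call(rbind, fields)
  colnames(tab) <- c("id", "father", "mother", "sex")
  if (anyDuplicated(tab[, "id"])) {
    stop("duplicate individual id: ",
         tab[duplicated(tab[, "id"]), "id"][1L])
  }
  if (any(tab[, "id"] == "0")) stop("'0' is reserved and cannot be an individual id")
  sex <- stats::setNames(vapply(tab[, "sex"], as_sex, character(1)), tab[, "id"])

  has_f <- tab[, "father"] != "0"
  has_m <- tab[, "mother"] != "0"
  if (any(has_f != has_m)) {
    bad <- tab[has_f != has_m, "id"][1L]
    stop("in-degree 1: individual '", bad,
         "' has exactly one parent given (both or neither required)")
  }
  edges <- matrix(character(0), ncol = 2L)
  kids <- tab[has_f, , drop = FALSE]
  if (nrow(kids)) {
    for (col in c("father", "mother")) {
      unknown <- setdiff(kids[, col], tab[, "id"])
      if (length(unknown)) stop("unknown parent id: '", unknown[1L], "'")
    }
    bad_f <- kids[sex[kids[, "father"]] != "male", "father"]
    if (length(bad_f)) stop("sex conflict: father '", bad_f[1L], "' is not male")
    bad_m <- kids[sex[kids[, "mother"]] != "female", "mother"]
    if (length(bad_m)) stop("sex conflict: mother '", bad_m[1L], "' is not female")
    edges <- rbind(
      cbind(kids[, "father"], kids[, "id"]),
      cbind(kids[, "mother"], kids[, "id"])
    )
  }
  referenced <- unique(as.vector(edges))
  isolated <- setdiff(tab[, "id"], referenced)
  if (length(isolated)) {
    warning("removing isolated individual(s): ",
            paste(isolated, collapse = ", "))
    sex <- sex[setdiff(names(sex), isolated)]
  }
  if (!length(sex)) stop("PED file contains only isolated individuals")
  pedigree(edges = edges, sex = sex)
}

#' Write a pedigree to a PED-style file
#'
#' Rows are sorted lexicographically by individual id so that output is
#' byte-stable; `read_ped(write_ped(p))` reproduces `p` exactly.
#'
#' @param p a [pedigree].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(p, path) {
  stopifnot(inherits(p, "pedigree"))
  father <- stats::setNames(rep("0", length(p$individuals)), p$individuals)
  mother <- father
  if (nrow(p$edges)) {
    par_of <- split(p$edges[, "parent"], p$edges[, "child"])
    for (child in names(par_of)) {
      pars <- par_of[[child]]
      for (pa in pars) {
        if (p$sex[[pa]] == "male") father[[child]] <- pa else mother[[child]] <- pa
      }
    }
  }
  ids <- sort(p$individuals)
  rows <- sprintf("%s\t%s\t%s\t%s", ids, father[ids], mother[ids],
                  ifelse(p$sex[ids] == "male", "1", "2"))
  writeLines(rows, path)
  invisible(path)
}

#' Read a pedigree from an edge list plus a sex map
#'
#' Alternative input format: one `parent<TAB>child` line per edge and a
#' second file with `id<TAB>sex` lines (sex coded 1/2 or male/female).
#' `#`-prefixed comments are skipped in both files.
#'
#' @param edge_path path to the edge-list file.
#' @param sex_path path to the sex-map file.
#' @return a [pedigree].
#' @export
read_ped_edges <- function(edge_path, sex_path) {
  edges <- read_tab_lines(edge_path, 2L)
  sexes <- read_tab_lines(sex_path, 2L)
  if (anyDuplicated(sexes[, 1L])) stop("duplicate individual id in sex map")
  sex <- stats::setNames(vapply(sexes[, 2L], as_sex, character(1)), sexes[, 1L])
  pedigree(edges = edges, sex = sex)
}

# shared reader: tab-separated lines with a fixed field count
read_tab_lines <- function(path, nfields) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- trimws(readLines(path), which = "right")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != nfields)) {
    stop(sprintf("%s: expected %d tab-separated fields per line", path, nfields))
  }
  if (!length(fields)) return(matrix(character(0), ncol = nfields))
  do.call(rbind, fields)
}
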