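# Shared fixtures, all built in code.

# couple with i daughters and j sons
make_family_ped <- function(i, j, prefix = "f") {
  sex <- c("male", "female")
  names(sex) <- paste0(prefix, c("_dad", "_mom"))
  edges <- NULL
  for (k in seq_len(i)) {
    id <- sprintf("%s_g%d", prefix, k)
    sex[id] <- "female"
    edges <- rbind(edges, c(names(sex)[1L], id), c(names(sex)[2L], id))
  }
  for (k in seq_len(j)) {
    id <- sprintf("%s_b%d", prefix, k)
    sex[id] <- "male"
    edges <- rbind(edges, c(names(sex)[1L], id), c(names(sex)[2L], id))
  }
  pedigree(edges, sex)
}

# monogamous pedigree realizing a list of (i, j) family sizes
make_families_ped <- function(fams, prefix = "fam") {
  parts <- lapply(seq_along(fams), function(k) {
    make_family_ped(fams[[k]][1L], fams[[k]][2L], sprintf("%s%d", prefix, k))
  })
  edges <- do.call(rbind, lapply(parts, function(p) p$edges))
  sex <- do.call(c, lapply(parts, function(p) p$sex))
  pedigree(edges, sex)
}

# copy of a pedigree under fresh opaque ids
relabel_ped <- function(p, prefix = "z") {
  map <- stats::setNames(sprintf("%s%03d", prefix, seq_along(p$individuals)),
                         sample(p$individuals))
  pedigree(cbind(map[p$edges[, 1L]], map[p$edges[, 2L]]),
           stats::setNames(p$sex, map[names(p$sex)]))
}

# the 3-vs-3 worked pair-partition instance used throughout
worked_S <- function() rbind(c(9L, 4L), c(1L, 11L), c(6L, 3L))
worked_T <- function() rbind(c(2L, 8L), c(12L, 1L), c(2L, 9L))

# a two-generation pedigree with one polygamous parent: families
# <2,0> and <0,1> share the father, plus a separate <1,1> family
mixed_mating_ped <- function() {
  sex <- c(F1 = "male", M1 = "female", M2 = "female",
           c1 = "female", c2 = "female", c3 = "male",
           F2 = "male", M3 = "female", d1 = "female", d2 = "male")
  edges <- rbind(c("F1", "c1"), c("M1", "c1"), c("F1", "c2"), c("M1", "c2"),
                 c("F1", "c3"), c("M2", "c3"),
                 c("F2", "d1"), c("M3", "d1"), c("F2", "d2"), c("M3", "d2"))
  pedigree(edges, sex)
}

# sub-pedigrees of the above: the polygamous left part, the <1,1> right part
polygamous_component_ped <- function() {
  sex <- c(F1 = "male", M1 = "female", M2 = "female",
           c1 = "female", c2 = "female", c3 = "male")
  edges <- rbind(c("F1", "c1"), c("M1", "c1"), c("F1", "c2"), c("M1", "c2"),
                 c("F1", "c3"), c("M2", "c3"))
  pedigree(edges, sex)
}

nuclear_family_ped <- function() make_family_ped(1, 1, "r")

# pedigree with an inter-generational mating (valid but not generational)
intergen_ped <- function() {
  sex <- c(A = "male", B = "female", C = "female", D = "male", E = "female")
  edges <- rbind(c("A", "C"), c("B", "C"), c("D", "E"), c("C", "E"))
  pedigree(edges, sex)
}

expect_valid_partition <- function(S, T, H) {
  expect_true(validate_pair_partition(S, T, H))
}
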