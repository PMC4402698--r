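test_that("family decomposition recovers the worked component examples", {
  left <- families_of(polygamous_component_ped())        # polygamous: shared father
  expect_identical(unclass(family_pairs(left))[, , drop = FALSE],
                   rbind(c(0L, 1L), c(2L, 0L)))
  right <- families_of(nuclear_family_ped())
  expect_identical(unclass(family_pairs(right))[, , drop = FALSE],
                   rbind(c(1L, 1L)))
  expect_identical(unclass(family_pairs(make_family_ped(3, 0)))[, , drop = FALSE],
                   rbind(c(3L, 0L)))
  expect_error(families_of(intergen_ped()), "two-generation")
})

test_that("families partition the second generation and conserve child counts", {
  for (seed in c(31L, 32L, 33L)) {
    p <- gen_random_pedigree(6, polygamy_rate = 0.5, seed = seed)
    fam <- families_of(p)
    g <- assign_generations(p)
    gen2 <- names(g)[g == 2L]
    kids <- unlist(attr(fam, "children"))
    expect_setequal(kids, gen2)               # every child in exactly one family
    expect_identical(length(kids), length(unique(kids)))
    expect_identical(sum(fam$i) + sum(fam$j), length(gen2))
    expect_identical(sum(fam$i), sum(p$sex[gen2] == "female"))
  }
})

test_that("monogamy holds exactly when no parent appears in two couples", {
  expect_true(is_monogamous(nuclear_family_ped()))
  expect_false(is_monogamous(polygamous_component_ped()))
  expect_false(is_monogamous(mixed_mating_ped()))
  expect_true(is_monogamous(make_family_ped(2, 3)))
})

test_that("the family-multiset isomorphism test handles the canonical cases", {
  p <- make_families_ped(list(c(2, 1), c(0, 3)))
  expect_true(monogamous_isomorphic(p, p))
  q <- make_families_ped(list(c(0, 3), c(2, 1)), prefix = "other")
  expect_true(monogamous_isomorphic(p, q))
  # sexes are not interchangeable
  expect_false(monogamous_isomorphic(make_family_ped(2, 1), make_family_ped(1, 2)))
  expect_error(monogamous_isomorphic(polygamous_component_ped(), nuclear_family_ped()),
               "monogamous")
})

test_that("the family-multiset test agrees with the brute-force isomorphism oracle", {
  set.seed(77)
  pool <- list(list(c(1, 1), c(2, 0)), list(c(2, 0), c(1, 1)),
               list(c(1, 1), c(0, 2)), list(c(2, 1)), list(c(1, 2)),
               list(c(1, 0), c(1, 0), c(0, 1)), list(c(2, 2)),
               list(c(1, 0), c(1, 1)))
  for (rep in 1:12) {
    a <- pool[[sample.int(length(pool), 1L)]]
    b <- pool[[sample.int(length(pool), 1L)]]
    p <- make_families_ped(a, prefix = "a")
    q <- relabel_ped(make_families_ped(b, prefix = "b"))
    if (length(p$individuals) > 12 || length(q$individuals) > 12) next
    fast <- monogamous_isomorphic(p, q)
    slow <- !is.null(pedigree_isomorphic_bruteforce(p, q))
    expect_identical(fast, slow)
  }
})

test_that("the bipartite reduction produces all-female single-child families", {
  p <- pedigree_from_bipartite("u", "v", rbind(c("u", "v")))
  expect_identical(length(p$individuals), 3L)
  expect_identical(unclass(family_pairs(p))[, , drop = FALSE], rbind(c(1L, 0L)))

  star <- pedigree_from_bipartite("hub", c("v1", "v2"),
                                  rbind(c("hub", "v1"), c("hub", "v2")))
  expect_identical(length(star$individuals), 5L)
  expect_identical(unclass(family_pairs(star))[, , drop = FALSE],
                   rbind(c(1L, 0L), c(1L, 0L)))
  expect_false(is_monogamous(star))

  for (seed in c(41L, 42L)) {
    gg <- gen_bipartite_pair(2, 3, 0.6, isomorphic = TRUE, seed = seed)
    P <- pedigree_from_bipartite(gg[[1L]]$U, gg[[1L]]$V, gg[[1L]]$edges)
    expect_true(validate_pedigree(P)$ok)
    g <- assign_generations(P)
    expect_identical(max(g), 2L)
    expect_true(all(P$sex[names(g)[g == 2L]] == "female"))
  }

  expect_error(pedigree_from_bipartite(c("u", "lonely"), "v",
                                       rbind(c("u", "v"))),
               "isolated")
})

test_that("bipartite isomorphism transfers to the reduction pedigrees both ways", {
  for (seed in c(51L, 52L, 53L)) {
    gg <- gen_bipartite_pair(2, 3, 0.6, isomorphic = TRUE, seed = seed)
    P1 <- pedigree_from_bipartite(gg[[1L]]$U, gg[[1L]]$V, gg[[1L]]$edges)
    P2 <- pedigree_from_bipartite(gg[[2L]]$U, gg[[2L]]$V, gg[[2L]]$edges)
    expect_false(is.null(pedigree_isomorphic_bruteforce(P1, P2, cap = 14L)))
  }
  for (seed in c(54L, 55L, 56L)) {
    gg <- gen_bipartite_pair(2, 3, 0.6, isomorphic = FALSE, seed = seed)
    P1 <- pedigree_from_bipartite(gg[[1L]]$U, gg[[1L]]$V, gg[[1L]]$edges)
    P2 <- pedigree_from_bipartite(gg[[2L]]$U, gg[[2L]]$V, gg[[2L]]$edges)
    expect_true(is.null(pedigree_isomorphic_bruteforce(P1, P2, cap = 14L)))
  }
})

test_that("pedigree similarity solves MCIPP on the family multisets", {
  p <- mixed_mating_ped()
  res <- similarity_mcipp(p, p, method = "fpt")
  expect_identical(res$size, 3L)              # identical pedigrees: one piece per family
  expect_identical(unclass(res$partition)[, , drop = FALSE],
                   unclass(family_pairs(families_of(p)))[, , drop = FALSE])

  expect_error(similarity_mcipp(make_family_ped(2, 4), make_family_ped(4, 5)),
               "incomparable")

  # planted split: q refines p's families, so a partition of q's size exists
  p2 <- make_families_ped(list(c(2, 2), c(1, 0)), prefix = "whole")
  q2 <- make_families_ped(list(c(2, 0), c(0, 2), c(1, 0)), prefix = "split")
  res2 <- similarity_mcipp(p2, q2, method = "fpt")
  expect_lte(res2$size, 3L)
  expect_valid_partition(family_pairs(families_of(p2)),
                         family_pairs(families_of(q2)), res2$partition)
})
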