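test_that("dominance classification matches the componentwise definition", {
  expect_identical(dominates(c(4, 5), c(2, 4)), "u_dominates")
  expect_identical(dominates(c(2, 4), c(4, 5)), "v_dominates")
  expect_identical(dominates(c(1, 4), c(2, 3)), "non_dominating")
  expect_identical(dominates(c(3, 3), c(3, 3)), "both_equal")
})

test_that("the dominating-partition step subtracts and emits the dominated tuple", {
  stp <- dominating_step(rbind(c(2, 4)), rbind(c(4, 5)), c(2, 4), c(4, 5))
  expect_identical(stp$piece, c(2L, 4L))
  expect_identical(nrow(stp$S), 0L)
  expect_identical(unclass(stp$T)[, , drop = FALSE], rbind(c(2L, 1L)))

  eq <- dominating_step(rbind(c(3, 3)), rbind(c(3, 3)), c(3, 3), c(3, 3))
  expect_identical(eq$piece, c(3L, 3L))
  expect_identical(nrow(eq$S) + nrow(eq$T), 0L)

  expect_error(dominating_step(rbind(c(1, 4)), rbind(c(2, 3)), c(1, 4), c(2, 3)),
               "dominating")
})

test_that("the non-dominating-partition step exchanges coordinates and pads zeros", {
  stp <- nondominating_step(rbind(c(6, 3)), rbind(c(2, 9)), c(6, 3), c(2, 9))
  expect_identical(stp$piece, c(2L, 3L))
  expect_identical(unclass(stp$S)[, , drop = FALSE], rbind(c(4L, 0L)))
  expect_identical(unclass(stp$T)[, , drop = FALSE], rbind(c(0L, 6L)))

  mir <- nondominating_step(rbind(c(1, 4)), rbind(c(2, 3)), c(1, 4), c(2, 3))
  expect_identical(mir$piece, c(1L, 3L))
  expect_identical(unclass(mir$S)[, , drop = FALSE], rbind(c(0L, 1L)))
  expect_identical(unclass(mir$T)[, , drop = FALSE], rbind(c(1L, 0L)))

  expect_error(nondominating_step(rbind(c(2, 4)), rbind(c(4, 5)), c(2, 4), c(4, 5)),
               "non-dominating")
  expect_error(nondominating_step(rbind(c(5, 0)), rbind(c(0, 5)), c(5, 0), c(0, 5)),
               "degenerate")
})

test_that("both step kinds conserve the projection sums on each side", {
  set.seed(91)
  for (rep in 1:25) {
    inst <- gen_planted_mcipp(sample(3:5, 1), max_value = 6,
                              sides = c(sample(2:3, 1), sample(2:3, 1)),
                              seed = 900L + rep)
    S <- inst$S; T <- inst$T
    total <- projection_sums(S)
    emitted <- c(0L, 0L)
    # walk a few random legal steps, checking conservation throughout
    for (step in 1:4) {
      nd <- nondominating_pairs(S, T)
      nd <- nd[nd$eligible, , drop = FALSE]
      cls_all <- expand.grid(i = seq_len(nrow(S)), j = seq_len(nrow(T)))
      doms <- cls_all[mapply(function(i, j) dominates(S[i, ], T[j, ]) != "non_dominating",
                             cls_all$i, cls_all$j), , drop = FALSE]
      if (nrow(doms)) {
        r <- doms[sample.int(nrow(doms), 1L), ]
        stp <- dominating_step(S, T, S[r$i, ], T[r$j, ])
      } else if (nrow(nd)) {
        r <- nd[sample.int(nrow(nd), 1L), ]
        stp <- nondominating_step(S, T, c(r$s1, r$s2), c(r$t1, r$t2))
      } else break
      emitted <- emitted + stp$piece
      S <- stp$S; T <- stp$T
      expect_identical(projection_sums(S) + emitted, total)
      expect_identical(projection_sums(T) + emitted, total)
      if (!nrow(S) || !nrow(T)) break
    }
  }
})

test_that("common-tuple preprocessing strips shared tuples and keeps the optimum", {
  S <- rbind(c(1, 2), c(3, 4))
  pre <- preprocess_common_tuples(S, S)
  expect_identical(nrow(pre$S) + nrow(pre$T), 0L)
  expect_identical(nrow(pre$pieces), 2L)

  pre2 <- preprocess_common_tuples(rbind(c(1, 2), c(3, 4)),
                                   rbind(c(3, 4), c(0, 3)))
  expect_identical(unclass(pre2$pieces)[, , drop = FALSE], rbind(c(3L, 4L)))
  expect_identical(unclass(pre2$S)[, , drop = FALSE], rbind(c(1L, 2L)))
  expect_identical(unclass(pre2$T)[, , drop = FALSE], rbind(c(0L, 3L)))

  for (seed in c(61L, 62L, 63L, 64L)) {
    inst <- gen_planted_mcipp(4, max_value = 3, sides = c(3, 3), seed = seed)
    before <- brute_force_mcipp(inst$S, inst$T)$size
    pre <- preprocess_common_tuples(inst$S, inst$T)
    after <- nrow(pre$pieces) +
      if (nrow(pre$S)) brute_force_mcipp(pre$S, pre$T)$size else 0L
    expect_identical(after, before)
  }
})

test_that("the certified bounds sandwich the optimum and detect infeasibility", {
  S <- worked_S(); T <- worked_T()
  expect_identical(mcipp_bounds(S, T), c(lower = 3L, upper = 6L))
  single <- rbind(c(2, 3))
  expect_identical(mcipp_bounds(single, single), c(lower = 1L, upper = 2L))
  expect_identical(brute_force_mcipp(single, single)$size, 1L)
  expect_error(mcipp_bounds(rbind(c(2, 4)), rbind(c(4, 5))), "infeasible")

  for (seed in c(71L, 72L, 73L)) {
    inst <- gen_planted_mcipp(4, max_value = 4, sides = c(2, 3), seed = seed)
    b <- mcipp_bounds(inst$S, inst$T)
    opt <- brute_force_mcipp(inst$S, inst$T)$size
    expect_gte(opt, b[["lower"]])
    expect_lte(opt, b[["upper"]])
  }
})

test_that("the common-partition validators accept exactly the refining multisets", {
  expect_true(validate_common_partition(c(5, 8), c(3, 10), c(1, 2, 2, 4, 4)))
  expect_true(validate_common_partition(c(5, 8), c(3, 10), c(3, 2, 8)))
  expect_false(validate_common_partition(c(5, 8), c(3, 10), c(1, 1, 11)))
  expect_false(validate_common_partition(c(5, 8), c(3, 9), c(1, 2, 2, 4, 4)))
  A <- c(2, 3, 7)
  expect_true(validate_common_partition(A, A, A))

  S <- worked_S(); T <- worked_T()
  H <- rbind(c(0, 4), c(1, 2), c(1, 7), c(2, 4), c(5, 1), c(7, 0))
  expect_true(validate_pair_partition(S, T, H))
  expect_false(validate_pair_partition(S, T, rbind(c(16, 18))))
  asg <- find_pair_assignment(S, T, H)
  expect_identical(length(asg$s), nrow(H))
  # assigned pieces sum back to their sources
  Sc <- as_pair_multiset(S); Hc <- as_pair_multiset(H)
  for (i in seq_len(nrow(Sc))) {
    expect_identical(colSums(Hc[asg$s == i, , drop = FALSE]),
                     c(Sc[i, 1L], Sc[i, 2L]) + 0)
  }
})
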