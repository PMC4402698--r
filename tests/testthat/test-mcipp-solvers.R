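test_that("the heuristic reproduces the worked run on the 3-vs-3 instance", {
  S <- worked_S(); T <- worked_T()
  res <- heuristic_mcipp(S, T, start = list(s = c(6, 3), t = c(2, 9)))
  expect_identical(res$size, 6L)
  expect_identical(res$nondom_steps, 1L)
  expect_true(validate_pair_partition(S, T, res$partition))
  expect_identical(res$lower_bound, 3L)
  expect_identical(res$upper_bound, 6L)

  free <- heuristic_mcipp(S, T)               # free choice of starting pair
  expect_true(validate_pair_partition(S, T, free$partition))
  expect_identical(free$size, 6L)
  expect_identical(free$nondom_steps, 1L)
})

test_that("the heuristic handles degenerate and trivial shapes", {
  one <- rbind(c(3, 2))
  res <- heuristic_mcipp(one, one)
  expect_identical(res$size, 1L)
  expect_identical(unclass(res$partition)[, , drop = FALSE], rbind(c(3L, 2L)))

  # one side a single tuple: the other side is already the partition
  S <- rbind(c(10, 11))
  T <- rbind(c(2, 2), c(2, 3), c(2, 5), c(4, 1))
  res2 <- heuristic_mcipp(S, T)
  expect_identical(res2$size, 4L)
  expect_true(validate_pair_partition(S, T, res2$partition))

  expect_error(heuristic_mcipp(rbind(c(2, 4)), rbind(c(4, 5))), "infeasible")
  expect_error(heuristic_mcipp(worked_S(), worked_T(),
                               start = list(s = c(9, 4), t = c(9, 4))),
               "not found|non-dominating")
})

test_that("heuristic results stay within the certified sandwich and factor 2", {
  for (seed in 101:160) {
    set.seed(seed)
    sides <- c(sample(1:4, 1), sample(1:4, 1))
    inst <- gen_planted_mcipp(max(sides) + sample(0:2, 1), max_value = 5,
                              sides = sides, seed = seed)
    h <- heuristic_mcipp(inst$S, inst$T)
    expect_true(validate_pair_partition(inst$S, inst$T, h$partition))
    expect_gte(h$size, max(nrow(inst$S), nrow(inst$T)))
    expect_lte(h$size, nrow(inst$S) + nrow(inst$T))
    opt <- brute_force_mcipp(inst$S, inst$T)$size
    expect_lte(h$size, 2L * opt)
  }
})

test_that("after its one non-dominating split on a dominance-free instance the heuristic needs no other", {
  # instances with no dominating cross pair at all and a completable start
  S <- worked_S(); T <- worked_T()
  an <- mcipp_start_analysis(S, T)
  expect_true(any(an$dom_completable, na.rm = TRUE))
  h <- heuristic_mcipp(S, T)
  expect_identical(h$nondom_steps, 1L)
})

test_that("the bounded branching search matches the oracle on the worked instance", {
  S <- worked_S(); T <- worked_T()
  opt <- brute_force_mcipp(S, T)$size
  expect_identical(opt, 6L)
  res <- exact_mcipp_fpt(S, T, k = opt)
  expect_identical(res$size, 6L)
  expect_true(validate_pair_partition(S, T, res$partition))
  expect_null(exact_mcipp_fpt(S, T, k = opt - 1L))
  expect_null(exact_mcipp_fpt(S, T, k = 2L))  # below the size lower bound

  single <- rbind(c(4, 7))
  expect_identical(exact_mcipp_fpt(single, single, k = 1L)$size, 1L)
  expect_error(exact_mcipp_fpt(rbind(c(2, 4)), rbind(c(4, 5)), 3L), "infeasible")
})

test_that("branching answers equal brute-force answers across a seeded grid", {
  for (seed in 201:260) {
    set.seed(seed)
    sides <- c(sample(1:4, 1), sample(1:4, 1))
    inst <- gen_planted_mcipp(max(sides) + sample(0:2, 1),
                              max_value = sample(2:5, 1),
                              sides = sides, seed = seed)
    if (any(projection_sums(inst$S) > 25)) next
    opt <- brute_force_mcipp(inst$S, inst$T)$size
    fpt <- mcipp_optimize(inst$S, inst$T, method = "fpt")
    expect_identical(fpt$size, opt)
    expect_true(validate_pair_partition(inst$S, inst$T, fpt$partition))
    # decision agrees at every budget around the optimum
    if (opt > max(nrow(inst$S), nrow(inst$T))) {
      expect_null(exact_mcipp_fpt(inst$S, inst$T, k = opt - 1L))
    }
    expect_identical(exact_mcipp_fpt(inst$S, inst$T, k = opt + 1L)$size <= opt + 1L,
                     TRUE)
    # no optimal result uses one source pair twice
    key <- paste(fpt$assignment$s, fpt$assignment$t)
    expect_identical(anyDuplicated(key), 0L)
  }
})

test_that("the integer-partition search honors the minimum-element property", {
  res <- exact_mcip_fpt(c(2, 5, 5), c(6, 6), k = 4L)
  expect_identical(res$size, 4L)
  expect_true(validate_common_partition(c(2, 5, 5), c(6, 6), res$partition))
  expect_null(exact_mcip_fpt(c(2, 5, 5), c(6, 6), k = 3L))

  A <- c(3, 4, 9)
  expect_identical(exact_mcip_fpt(A, A, k = 3L)$size, 3L)
  expect_error(exact_mcip_fpt(c(2, 3), c(4, 4), k = 2L), "infeasible")

  for (seed in 301:330) {
    set.seed(seed)
    nA <- sample(2:5, 1); vals <- sample(1:12, nA, replace = TRUE)
    # split the same total differently to get B
    total <- sum(vals)
    nB <- sample(2:5, 1)
    cuts <- sort(sample.int(total - 1L, nB - 1L))
    B <- diff(c(0L, cuts, total))
    if (sum(vals) > 40) next
    opt <- brute_force_mcip(vals, B)$size
    deep <- mcip_optimize(vals, B, method = "fpt")
    expect_identical(deep$size, opt)
    # some optimal solution contains the global minimum element as a piece
    expect_true(min(c(vals, B)) %in% deep$partition)
  }
})

test_that("the optimization wrapper agrees across methods", {
  S <- worked_S(); T <- worked_T()
  expect_identical(mcipp_optimize(S, T, method = "fpt")$size,
                   mcipp_optimize(S, T, method = "brute")$size)
  sameside <- rbind(c(1, 2), c(3, 0), c(2, 2))
  expect_identical(mcipp_optimize(sameside, sameside, method = "fpt")$size, 3L)
  h <- mcipp_optimize(S, T, method = "heuristic")
  expect_identical(h$method, "heuristic")
})

test_that("anchored branching rules are incomplete for pair instances", {
  # forcing a piece into the solution, assigned to a chosen source pair,
  # and solving the remainder exactly gives the best size containing it
  forced_best <- function(S, T, piece) {
    S <- as_pair_multiset(S); T <- as_pair_multiset(T)
    best <- Inf
    for (i in seq_len(nrow(S))) for (j in seq_len(nrow(T))) {
      if (all(S[i, ] >= piece) && all(T[j, ] >= piece)) {
        S2 <- unclass(S); T2 <- unclass(T)
        S2[i, ] <- S2[i, ] - piece; T2[j, ] <- T2[j, ] - piece
        S2 <- S2[rowSums(S2) > 0, , drop = FALSE]
        T2 <- T2[rowSums(T2) > 0, , drop = FALSE]
        sub <- if (nrow(S2)) brute_force_mcipp(S2, T2)$size else 0L
        best <- min(best, 1L + sub)
      }
    }
    best
  }

  # worked 3-vs-3 instance: optimum 6, yet no optimal solution contains
  # the piece joining the two componentwise minima, nor either whole
  # minimum-attaining input tuple (no opposite-side source dominates them)
  S <- worked_S(); T <- worked_T()
  expect_identical(brute_force_mcipp(S, T)$size, 6L)
  expect_equal(forced_best(S, T, c(1L, 1L)), 7)
  expect_equal(forced_best(S, T, c(1L, 11L)), Inf)
  expect_equal(forced_best(S, T, c(12L, 1L)), Inf)

  # second instance: optimum 5 forces the minimum-first tuple <2,6> to
  # split its first component, so even "the minimum component travels in
  # one piece" fails as a branching rule
  S2 <- rbind(c(4L, 3L), c(7L, 5L))
  T2 <- rbind(c(2L, 6L), c(3L, 0L), c(3L, 1L), c(3L, 1L))
  expect_identical(brute_force_mcipp(S2, T2)$size, 5L)
  anchored <- vapply(0:6, function(b) forced_best(S2, T2, c(2L, b)), numeric(1))
  expect_true(all(anchored > 5))
  # the complete pivot branching still reaches the optimum
  expect_identical(mcipp_optimize(S2, T2, method = "fpt")$size, 5L)
})
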