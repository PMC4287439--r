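test_that("spore exchanges are the adjacent-call switches", {
  expect_equal(classify_spore(c("P1", "P1", "P1", "P1")), integer(0))
  expect_equal(classify_spore(c("P1", "P2", "P2", "P2")), 1L)
  expect_equal(classify_spore(c("P1", "P2", "P1", "P2")), c(1L, 2L, 3L))
  expect_null(classify_spore(c("P1", NA, "P2")))
  expect_null(classify_spore(c("P1", "??", "P2")))
  expect_error(classify_spore("P1"), "at least 2")
})

test_that("classify_spore agrees with brute force over all call vectors", {
  for (k in 2:6) {
    grid <- expand.grid(rep(list(c("P1", "P2")), k), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(grid))) {
      calls <- unlist(grid[i, ], use.names = FALSE)
      # oracle: exhaustive pairwise comparison of adjacent markers
      oracle <- which(vapply(seq_len(k - 1),
                             function(j) calls[j] != calls[j + 1], logical(1)))
      expect_equal(classify_spore(calls), oracle)
    }
  }
})

test_that("crossover_tally partitions spores into classes", {
  calls <- rbind(c("P1", "P1", "P1"),   # NCO
                 c("P1", "P2", "P2"),   # single in interval 1
                 c("P1", "P1", "P2"),   # single in interval 2
                 c("P1", "P2", "P1"),   # double
                 c("P2", "P2", "P2"))   # NCO
  tl <- crossover_tally(calls)
  expect_equal(tl$total, 5)
  expect_equal(tl$nco, 2)
  expect_equal(tl$single, c(1L, 1L))
  expect_equal(tl$double, 1)
  expect_equal(tl$triple_plus, 0)
  expect_equal(tl$ambiguous_gc, 1)
  expect_equal(tl$per_interval, c(2L, 2L))
  # class counts sum to the total
  expect_equal(tl$nco + sum(tl$single) + tl$double + tl$triple_plus, tl$total)
  # unknown calls are excluded, with a message
  calls2 <- rbind(calls, c("P1", NA, "P1"))
  expect_message(tl2 <- crossover_tally(calls2), "excluded")
  expect_equal(tl2$total, 5)
})

test_that("tallies are invariant under spore reordering", {
  set.seed(21)
  cfg <- sim_config(seed = 21, interval_cm = c(A = 10, B = 20))
  sp <- simulate_random_spores(cfg, 500)
  calls <- spore_calls(sp)
  t1 <- crossover_tally(calls)
  t2 <- crossover_tally(calls[sample(nrow(calls)), ])
  expect_equal(t1, t2)
})

test_that("expected multiple-crossover percentage is the marginal product", {
  tl <- structure(list(total = 100, per_interval = c(10L, 20L), nco = 72,
                       single = c(8L, 18L), double = 2L, triple_plus = 0L,
                       ambiguous_gc = 2L), class = "crossover_tally")
  expect_equal(expected_multi_co(tl, c(1, 2)), 100 * 0.10 * 0.20)
  expect_equal(expected_multi_co(tl, 1), 10)
  tl$per_interval <- c(0L, 20L)
  expect_equal(expected_multi_co(tl, c(1, 2)), 0)
  # hand-multiplied marginals 6.8% and 5%
  tl$total <- 1000L; tl$per_interval <- c(68L, 50L)
  expect_equal(expected_multi_co(tl, c(1, 2)), 0.34)
  expect_error(expected_multi_co(tl, integer(0)), "nonempty")
  expect_error(expected_multi_co(tl, 5), "out of range")
})

test_that("interference ratio handles its edge cases", {
  expect_equal(interference_ratio(2, 2), 1)
  expect_equal(interference_ratio(1, 2), 0.5)
  expect_warning(r <- interference_ratio(0, 0), "undefined")
  expect_true(is.na(r))
  expect_warning(r2 <- interference_ratio(1, 0), "infinite")
  expect_equal(r2, Inf)
})

test_that("compare_groups recovers constructed fold differences", {
  # build tallies with exact per-interval fractions from explicit calls
  mk_calls <- function(n, n_ex1, n_ex2) {
    rbind(matrix(rep(c("P1", "P2", "P2"), n_ex1), ncol = 3, byrow = TRUE),
          matrix(rep(c("P1", "P1", "P2"), n_ex2), ncol = 3, byrow = TRUE),
          matrix(rep(c("P1", "P1", "P1"), n - n_ex1 - n_ex2),
                 ncol = 3, byrow = TRUE))
  }
  a <- crossover_tally(mk_calls(1000, 300, 150))
  b <- crossover_tally(mk_calls(1000, 100, 50))
  res <- compare_groups(a, b)
  expect_equal(res$ratio, c(3, 3))
  expect_true(all(res$p_value < 0.001))
  same <- compare_groups(a, a)
  expect_equal(same$ratio, c(1, 1))
  expect_true(all(same$p_value > 0.999))
  # disjoint support
  c1 <- crossover_tally(mk_calls(100, 100, 0))
  c2 <- crossover_tally(mk_calls(100, 0, 0))
  expect_lt(compare_groups(c1, c2)$p_value[1], 1e-10)
})
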