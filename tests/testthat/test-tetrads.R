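make_tetrad <- function(genos) {
  tetrad(do.call(rbind, strsplit(genos, "")),
         parent1 = c("A", "B"), parent2 = c("a", "b"))
}

test_that("tetrads are classified PD/NPD/TT by parental configuration", {
  expect_equal(classify_tetrad(make_tetrad(c("AB", "AB", "ab", "ab")), 1:2), "PD")
  expect_equal(classify_tetrad(make_tetrad(c("Ab", "Ab", "aB", "aB")), 1:2), "NPD")
  expect_equal(classify_tetrad(make_tetrad(c("AB", "ab", "Ab", "aB")), 1:2), "TT")
  # 3:1 segregation at the first marker is a gene conversion
  expect_equal(classify_tetrad(make_tetrad(c("AB", "AB", "Ab", "ab")), 1:2), "GC")
})

test_that("classification is invariant to spore order and parent labels", {
  set.seed(5)
  tets <- simulate_tetrads(sim_config(seed = 5, interval_cm = c(AB = 30)), 40)
  for (t in tets) {
    cls <- classify_tetrad(t, 1:2)
    perm <- t
    perm$spores <- t$spores[sample(4), , drop = FALSE]
    expect_equal(classify_tetrad(perm, 1:2), cls)
    swapped <- t
    swapped$parent1 <- t$parent2
    swapped$parent2 <- t$parent1
    expect_equal(classify_tetrad(swapped, 1:2), cls)
  }
})

test_that("tally_tetrads excludes gene-conversion tetrads with a message", {
  tets <- list(make_tetrad(c("AB", "AB", "ab", "ab")),
               make_tetrad(c("AB", "ab", "Ab", "aB")),
               make_tetrad(c("AB", "AB", "Ab", "ab")))
  expect_message(cnt <- tally_tetrads(tets, 1:2), "gene conversion")
  expect_equal(c(cnt$PD, cnt$NPD, cnt$TT), c(1, 0, 1))
  expect_equal(attr(cnt, "gene_conversions"), 1)
})

test_that("every published map distance is reproduced from its counts", {
  tab <- printed_tetrad_table()
  for (i in seq_len(nrow(tab))) {
    cm <- perkins_cm(tetrad_counts(tab$PD[i], tab$NPD[i], tab$TT[i]))
    digits <- if (tab$printed_cm[i] == round(tab$printed_cm[i], 1)) 1 else 2
    expect_equal(round(cm, digits), tab$printed_cm[i],
                 info = paste(tab$strain[i], tab$interval[i]))
  }
})

test_that("percent recombination reproduces the printed values", {
  tab <- printed_tetrad_table()
  for (i in seq_len(nrow(tab))) {
    if (is.na(tab$printed_pct[i])) next  # garbled cell, counts irreconcilable
    pct <- percent_recombination(tetrad_counts(tab$PD[i], tab$NPD[i], tab$TT[i]))
    # 246/0/61 computes 19.87 against a printed 19.8 (rounding direction);
    # all other rows agree at the printed precision
    tol <- if (tab$printed_pct[i] == 19.8) 0.1 else 0.051
    expect_equal(pct, tab$printed_pct[i], tolerance = tol / tab$printed_pct[i],
                 info = paste(tab$strain[i], tab$interval[i]))
  }
  expect_equal(percent_recombination(tetrad_counts(123, 0, 0)), 0)
})

test_that("without NPDs percent recombination is exactly twice the cM", {
  set.seed(9)
  for (rep in 1:10) {
    x <- tetrad_counts(sample(50:300, 1), 0, sample(0:100, 1))
    expect_equal(percent_recombination(x), 2 * perkins_cm(x))
  }
})

test_that("the map-distance standard error matches the published values", {
  expect_equal(perkins_se(tetrad_counts(140, 1, 144)), 1.8, tolerance = 0.05 / 1.8)
  expect_equal(perkins_se(tetrad_counts(167, 2, 139)), 1.9, tolerance = 0.05 / 1.9)
  expect_equal(perkins_se(tetrad_counts(100, 0, 0)), 0)
  # the printed "13.0 +/- 0.13" is a typo: the variance formula gives 1.3
  expect_equal(round(perkins_se(tetrad_counts(224, 0, 79)), 1), 1.3)
  expect_error(perkins_se(tetrad_counts(1, 0, 0)), "more than one")
})

test_that("cM/kb densities match the published table", {
  expect_equal(round(cm_per_kb(1.6, 9.7), 2), 0.16)
  expect_equal(round(cm_per_kb(26.3, 22.5), 1), 1.2)
  expect_equal(cm_per_kb(0, 5), 0)
  expect_error(cm_per_kb(1, 0), "positive")
  tab <- printed_tetrad_table()
  for (i in seq_len(nrow(tab))) {
    if (is.na(tab$printed_cm_kb[i])) next
    d <- cm_per_kb(perkins_cm(tetrad_counts(tab$PD[i], tab$NPD[i], tab$TT[i])),
                   tab$kb[i])
    expect_equal(d, tab$printed_cm_kb[i], tolerance = 0.06,
                 info = paste(tab$strain[i], tab$interval[i]))
  }
})

test_that("chi-square comparison of tetrad tables behaves sensibly", {
  same <- chisq_tetrads(tetrad_counts(200, 10, 90), tetrad_counts(400, 20, 180))
  expect_lt(same$statistic, 1e-10)
  expect_equal(same$p_value, 1, tolerance = 1e-6)
  # reported nonsignificant (p = 0.17) comparison of the two coldspot strains
  res <- chisq_tetrads(tetrad_counts(269, 0, 16), tetrad_counts(243, 0, 8))
  expect_gt(res$p_value, 0.05)
  expect_equal(res$p_value, 0.17, tolerance = 0.1)
  orth <- chisq_tetrads(tetrad_counts(100, 0, 0), tetrad_counts(0, 0, 100))
  expect_lt(orth$p_value, 1e-10)
  expect_error(chisq_tetrads(tetrad_counts(0, 0, 0), tetrad_counts(1, 0, 0)),
               "classified tetrads")
})

test_that("summarize_tetrads assembles the per-interval table", {
  out <- summarize_tetrads(list(tetrad_counts(140, 1, 144, kb = 22.5,
                                              interval = "MAT-kanMX")))
  expect_equal(round(out$cM, 1), 26.3)
  expect_equal(round(out$pct_recombination, 1), 51.2)
  expect_equal(round(out$SE, 1), 1.8)
  expect_equal(round(out$cM_per_kb, 1), 1.2)
})
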