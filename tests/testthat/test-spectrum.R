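test_that("single-base substitutions split into transitions and transversions", {
  bases <- c("A", "C", "G", "T")
  purines <- c("A", "G")
  n_ts <- 0
  for (ref in bases) for (alt in setdiff(bases, ref)) {
    got <- classify_mutation(ref, alt)
    expect_equal(got$class, "substitution")
    # oracle: transition iff both purines or both pyrimidines
    is_ts <- (ref %in% purines) == (alt %in% purines)
    expect_equal(got$subtype, if (is_ts) "transition" else "transversion",
                 info = paste(ref, alt))
    n_ts <- n_ts + is_ts
  }
  expect_equal(n_ts, 4)  # 4 transitions, 8 transversions among the 12 pairs
})

test_that("indels classify by net length change", {
  expect_equal(unlist(classify_mutation("AA", "A")),
               c(class = "frameshift", subtype = "contraction"))
  expect_equal(unlist(classify_mutation("A", "AA")),
               c(class = "frameshift", subtype = "expansion"))
  expect_equal(unlist(classify_mutation("ACGTA", "A")),
               c(class = "frameshift", subtype = "contraction"))
  expect_equal(classify_mutation("ACGT", "A")$class, "in_frame_indel")
  expect_equal(classify_mutation("AC", "GT")$class, "complex")
  expect_error(classify_mutation("A", "A"), "differ")
  expect_error(classify_mutation("A", "X"), "A/C/G/T")
})

test_that("spectrum summaries reproduce the published percentages", {
  # meiosis-like group: 20 frameshifts (15 contractions, 5 expansions),
  # 72 substitutions, 4 complex isolates = 96 isolates
  iso <- sprintf("i%03d", 1:96)
  ref <- c(rep("AA", 15), rep("A", 5), rep("G", 72), rep("G", 4))
  alt <- c(rep("A", 15), rep("AA", 5), rep("A", 72), rep("A", 4))
  rec <- mutation_records(c(iso, iso[93:96]),
                          rep("meiosis", 100),
                          rep(1:4, 25),
                          c(ref, rep("C", 4)),
                          c(alt, rep("T", 4)))
  s <- summarize_spectrum(rec)$meiosis
  expect_equal(s$n_total, 96)
  expect_equal(s$n_frameshift, 20)
  expect_equal(s$pct_frameshift, 21)
  expect_equal(s$n_contraction, 15)
  expect_equal(s$n_expansion, 5)
  expect_equal(s$n_substitution, 72)
  expect_equal(s$n_complex, 4)
  expect_output(print(s), "frameshift")
  # mitosis-like: 8 frameshifts of 80 -> 10%
  rec2 <- mutation_records(sprintf("j%03d", 1:80), rep("mitosis", 80), 1:80,
                           c(rep("AA", 8), rep("G", 72)),
                           c(rep("A", 8), rep("A", 72)))
  s2 <- summarize_spectrum(rec2)$mitosis
  expect_equal(s2$pct_frameshift, 10)
  # single-class input
  s3 <- summarize_spectrum(mutation_records("a", "mitosis", 5, "G", "T"))$mitosis
  expect_equal(s3$pct_substitution, 100)
})

test_that("summary splits always add up to their class totals", {
  set.seed(31)
  rec <- simulate_mutations(sim_config(seed = 31), 400)
  s <- summarize_spectrum(rec)[[1]]
  expect_equal(s$n_transition + s$n_transversion, s$n_substitution)
  expect_equal(s$n_contraction + s$n_expansion, s$n_frameshift)
  expect_equal(s$n_frameshift + s$n_substitution + s$n_complex +
                 s$n_in_frame_indel, s$n_total)
})

test_that("compare_spectra matches the hand-computed chi-square", {
  mk <- function(fs, total) {
    iso <- sprintf("x%03d", 1:total)
    summarize_one <- summarize_spectrum(mutation_records(
      iso, rep("mitosis", total), seq_len(total),
      c(rep("AA", fs), rep("G", total - fs)),
      c(rep("A", fs), rep("A", total - fs))))$mitosis
  }
  a <- mk(8, 80); b <- mk(20, 96)
  res <- compare_spectra(a, b)
  # hand chi-square on the 2x2 [8,72;20,76]; note the published p = 0.02
  # is not recovered by the uncorrected test (p here ~0.050)
  expect_equal(res$statistic, 3.83, tolerance = 0.01)
  expect_equal(res$df, 1)
  same <- compare_spectra(a, a)
  expect_equal(same$p_value, 1, tolerance = 1e-8)
  ext <- compare_spectra(mk(100, 100), mk(0, 100))
  expect_lt(ext$p_value, 1e-10)
  full <- compare_spectra(a, b, full = TRUE)
  expect_equal(full$df, 1)  # complex column all zero -> dropped
})

test_that("positions bin into half-open 200-bp windows", {
  rec <- mutation_records(c("a", "b", "c"), rep("mitosis", 3),
                          c(1, 200, 201), c("G", "G", "G"), c("A", "A", "A"))
  pd <- positional_distribution(rec, orf_length = 1773)
  expect_equal(pd$windows$mitosis[1], 2)  # positions 1 and 200
  expect_equal(pd$windows$mitosis[2], 1)  # position 201
  expect_equal(nrow(pd$windows), 9)
  expect_equal(sum(pd$windows$mitosis), 3)
  # out-of-ORF records are excluded with a message
  rec2 <- mutation_records(c("a", "b"), rep("mitosis", 2), c(5, 2000),
                           c("G", "G"), c("A", "A"))
  expect_message(pd2 <- positional_distribution(rec2, orf_length = 1773),
                 "beyond the ORF")
  expect_equal(sum(pd2$windows$mitosis), 1)
})

test_that("window homogeneity test is calibrated under the null", {
  set.seed(41)
  nonsig <- 0
  for (i in 1:100) {
    pos <- sample.int(1773, 120, replace = TRUE)
    rec <- mutation_records(sprintf("i%03d", 1:120),
                            rep(c("mitosis", "meiosis"), each = 60),
                            pos, rep("G", 120), rep("A", 120))
    p <- positional_distribution(rec, orf_length = 1773)$p_value
    nonsig <- nonsig + (p > 0.05)
  }
  expect_gte(nonsig, 90)
})

test_that("a concentrated group is detected against a uniform one", {
  set.seed(43)
  rec <- mutation_records(sprintf("i%03d", 1:200),
                          rep(c("mitosis", "meiosis"), each = 100),
                          c(sample.int(1773, 100, replace = TRUE),
                            sample.int(200, 100, replace = TRUE)),
                          rep("G", 200), rep("A", 200))
  expect_lt(positional_distribution(rec, orf_length = 1773)$p_value, 0.001)
})

test_that("mutation_records validates its fields", {
  expect_error(mutation_records("a", "mitosis", 0, "G", "A"), ">= 1")
  expect_error(mutation_records("a", "growth", 1, "G", "A"), "phase")
  expect_error(mutation_records("a", "mitosis", 1, "G", "G"), "differ")
})
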