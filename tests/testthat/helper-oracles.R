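# Independent oracle implementations used to cross-check the package.
# Deliberately written as plain loops, sharing no code with R/.

# MSS probabilities by a naive double loop (independent of the package's
# vectorized recursion).
oracle_mss_p <- function(m, r_max) {
  p <- numeric(r_max + 1)
  p[1] <- exp(-m)
  if (r_max >= 1) {
    for (r in 1:r_max) {
      acc <- 0
      for (i in 0:(r - 1)) acc <- acc + p[i + 1] / (r - i + 1)
      p[r + 1] <- (m / r) * acc
    }
  }
  p
}

oracle_loglik <- function(m, counts) {
  p <- oracle_mss_p(m, max(counts))
  sum(log(pmax(p[counts + 1], .Machine$double.xmin)))
}

# Two-stage grid search at final step 1e-4 over (0, upper].
oracle_grid_mle <- function(counts, upper = max(counts) + 2) {
  coarse <- seq(0.01, upper, by = 0.01)
  ll <- vapply(coarse, oracle_loglik, numeric(1), counts = counts)
  center <- coarse[which.max(ll)]
  fine <- seq(max(1e-4, center - 0.02), min(upper, center + 0.02), by = 1e-4)
  llf <- vapply(fine, oracle_loglik, numeric(1), counts = counts)
  fine[which.max(llf)]
}

# Printed per-interval tetrad summary values, frozen from the source table.
# pct NA marks the garbled percent-recombination cell.
printed_tetrad_table <- function() {
  counts <- utils::read.delim(
    system.file("extdata", "tetrad_counts.tsv", package = "meiomut"),
    comment.char = "#", stringsAsFactors = FALSE)
  counts$printed_cm <- c(2.8, 26.3, 1.6, 1.4, 0.59, 2.16, 1.67, 0.24,
                         4.05, 2.45, 1.22, 2.26, 9.93, 13.0, 24.5)
  counts$printed_pct <- c(5.6, 51.2, 3.2, 2.8, 1.2, 4.3, 3.3, 0.5,
                          8.1, 4.9, 2.4, NA, 19.8, 26.1, 46.4)
  # the GRY3276 natMX-MAT density cell prints 0.27 but its own row gives
  # 2.16 cM / 9.7 kb = 0.22; excluded (NA) like the garbled GRY3630 cell
  counts$printed_cm_kb <- c(0.29, 1.2, 0.16, 0.18, 0.32, NA, 0.21, 0.13,
                            0.33, 0.24, 0.66, NA, 0.90, 0.90, 0.98)
  counts
}
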