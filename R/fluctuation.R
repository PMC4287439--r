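# Luria-Delbruck fluctuation analysis: Ma-Sandri-Sarkar maximum likelihood
# estimation of m (mutations per culture) and conversion to a per-division
# mutation rate with Foster-style 95% confidence intervals.

#' Construct a fluctuation experiment
#'
#' Bundles per-culture mutant counts and total viable-cell counts from a set
#' of parallel cultures (a Luria-Delbruck fluctuation test).  Counts are
#' whole-culture equivalents: any dilution or plating-volume scaling must be
#' applied by the caller before construction (plating efficiency is assumed
#' to be 1).
#'
#' @param mutant_count Integer vector, one entry per culture: number of
#'   mutant colonies (e.g. His+ Can-r), scaled to the whole culture.
#' @param total_cells Numeric vector (recycled if length 1): total viable
#'   cells per culture (e.g. His+ colonies), scaled to the whole culture.
#' @param culture_id Optional identifiers, defaults to `1:n`.
#' @param label Free-text label for the experiment (e.g. a strain name).
#' @return An object of class `fluctuation_experiment`: a data frame with
#'   columns `culture_id`, `mutant_count`, `total_cells`.
#' @examples
#' fx <- fluctuation_experiment(c(0, 0, 1, 0, 12), 2e7)
#' mss_mle(fx)
#' @export
fluctuation_experiment <- function(mutant_count, total_cells,
                                   culture_id = seq_along(mutant_count),
                                   label = "") {
  mutant_count <- as.numeric(mutant_count)
  if (length(mutant_count) < 1L) {
    stop("at least one culture is required")
  }
  if (any(!is.finite(mutant_count)) || any(mutant_count < 0) ||
      any(mutant_count != floor(mutant_count))) {
    stop("mutant_count must be finite nonnegative integers")
  }
  total_cells <- rep_len(as.numeric(total_cells), length(mutant_count))
  if (any(!is.finite(total_cells)) || any(total_cells <= 0)) {
    stop("total_cells must be finite and positive")
  }
  if (any(mutant_count > total_cells)) {
    stop("mutant_count cannot exceed total_cells")
  }
  out <- data.frame(culture_id = culture_id,
                    mutant_count = mutant_count,
                    total_cells = total_cells,
                    stringsAsFactors = FALSE)
  attr(out, "label") <- label
  class(out) <- c("fluctuation_experiment", "data.frame")
  out
}

#' Ma-Sandri-Sarkar mutant-count probabilities
#'
#' Probability that a culture contains `r` mutant cells at plating, for
#' `r = 0, ..., r_max`, when the expected number of mutation events per
#' culture is `m`, under the Luria-Delbruck model.  Computed by the MSS
#' recursion
#' \deqn{p_0 = e^{-m}, \qquad
#'       p_r = \frac{m}{r} \sum_{i=0}^{r-1} \frac{p_i}{r - i + 1}.}
#'
#' @param m Expected number of mutations per culture (nonnegative).
#' @param r_max Largest mutant count for which to return a probability.
#' @return Numeric vector of length `r_max + 1`, entry `r + 1` is `p_r`.
#' @examples
#' mss_probabilities(2, 10)
#' @export
mss_probabilities <- function(m, r_max) {
  if (!is.finite(m) || m < 0) stop("m must be a finite nonnegative number")
  r_max <- as.integer(r_max)
  if (r_max < 0) stop("r_max must be nonnegative")
  p <- numeric(r_max + 1L)
  p[1L] <- exp(-m)
  if (r_max >= 1L && m > 0) {
    for (r in seq_len(r_max)) {
      # denominators run r+1, r, ..., 2 as i runs 0..r-1
      p[r + 1L] <- (m / r) * sum(p[seq_len(r)] / seq(r + 1, 2))
    }
  }
  p
}

# Log-likelihood of m for a vector of mutant counts.  Counts above r_cap are
# treated as right-censored (contribute log P(R > r_cap)); this keeps the
# likelihood proper while bounding the O(r^2) recursion on jackpot cultures.
mss_loglik <- function(m, counts, r_cap = 512L) {
  capped <- counts > r_cap
  r_top <- if (any(capped)) r_cap else max(counts)
  p <- mss_probabilities(m, r_top)
  p <- pmax(p, .Machine$double.xmin)
  ll <- sum(log(p[counts[!capped] + 1L]))
  if (any(capped)) {
    tail_mass <- max(1 - sum(p), .Machine$double.xmin)
    ll <- ll + sum(capped) * log(tail_mass)
  }
  ll
}

#' Ma-Sandri-Sarkar maximum-likelihood estimate of m
#'
#' Maximizes the product over cultures of the MSS probabilities
#' \eqn{p_{r_c}(m)} to estimate the expected number of mutation events per
#' culture.  The search is a bounded derivative-free optimization on
#' \eqn{\ln m} over \eqn{[\ln 10^{-6}, \ln(\max r + 10)]}, so the result is
#' deterministic given the inputs.
#'
#' Mutant counts larger than `r_cap` (jackpot cultures) enter the likelihood
#' as right-censored observations, i.e. through \eqn{P(R > r_{cap})}; this is
#' statistically proper and avoids the quadratic cost of the recursion on
#' extreme counts.
#'
#' @param x A `fluctuation_experiment`, or a plain vector of per-culture
#'   mutant counts.
#' @param r_cap Censoring threshold for jackpot counts (default 512).
#' @param tol Convergence tolerance on `ln m` (default 1e-6).
#' @return The MLE `m_hat` (0 when every culture has zero mutants).
#' @examples
#' mss_mle(c(0, 0, 0, 1, 0, 7, 0, 0, 2, 0))
#' @export
mss_mle <- function(x, r_cap = 512L, tol = 1e-6) {
  counts <- if (inherits(x, "fluctuation_experiment")) x$mutant_count else as.numeric(x)
  if (length(counts) < 1L) stop("empty experiment")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("mutant counts must be finite and nonnegative")
  }
  counts <- as.integer(round(counts))
  if (all(counts == 0L)) return(0)
  lo <- log(1e-6)
  hi <- log(max(counts) + 10)
  opt <- stats::optimize(function(lm) mss_loglik(exp(lm), counts, r_cap = r_cap),
                         interval = c(lo, hi), maximum = TRUE, tol = tol)
  exp(opt$maximum)
}

#' Foster 95% confidence interval for m
#'
#' Approximate 95% confidence limits for the MSS-MLE estimate of the expected
#' number of mutations per culture, symmetric on the \eqn{\ln m} scale:
#' \deqn{\sigma_{\ln \hat m} \approx \frac{1.225\, \hat m^{-0.315}}{\sqrt C},
#'       \qquad CI = \exp(\ln \hat m \pm 1.96\, \sigma_{\ln \hat m}),}
#' where `C` is the number of parallel cultures.
#'
#' When `m_hat` is 0 (no mutants observed anywhere) the interval degenerates
#' to `(0, -ln(0.05)/C)`, the one-sided upper bound from the p0 method, and a
#' warning is issued.
#'
#' @param m_hat MSS-MLE estimate of m (nonnegative).
#' @param n_cultures Number of parallel cultures (>= 2).
#' @return Numeric vector `c(low, high)` on the m scale.
#' @examples
#' foster_ci95(2, 18)
#' @export
foster_ci95 <- function(m_hat, n_cultures) {
  if (!is.finite(m_hat) || m_hat < 0) stop("m_hat must be nonnegative")
  n_cultures <- as.integer(n_cultures)
  if (n_cultures < 2L) stop("n_cultures must be at least 2")
  if (m_hat == 0) {
    warning("m_hat is 0; returning degenerate p0-method upper bound")
    return(c(0, -log(0.05) / n_cultures))
  }
  sigma <- 1.225 * m_hat^(-0.315) / sqrt(n_cultures)
  exp(log(m_hat) + c(-1, 1) * 1.96 * sigma)
}

#' Convert m to a per-division mutation rate
#'
#' Divides the expected number of mutations per culture by the number of
#' cells at risk.  The default ("final") convention divides by the final
#' viable population \eqn{N_t}; the "final-ln2" convention divides by
#' \eqn{N_t \ln 2} (the expected number of divisions in the final doubling).
#'
#' @param m_hat Mutations per culture.
#' @param mean_total_cells Mean final viable population per culture (> 0).
#' @param divisor Either `"final"` (rate = m / N) or `"final-ln2"`
#'   (rate = m / (N ln 2)).
#' @return Mutation rate per cell per division.
#' @examples
#' rate_from_m(3.7, 1e7)
#' @export
rate_from_m <- function(m_hat, mean_total_cells,
                        divisor = c("final", "final-ln2")) {
  divisor <- match.arg(divisor)
  if (!is.finite(mean_total_cells) || mean_total_cells <= 0) {
    stop("mean_total_cells must be positive")
  }
  if (!is.finite(m_hat) || m_hat < 0) stop("m_hat must be nonnegative")
  denom <- if (divisor == "final-ln2") mean_total_cells * log(2) else mean_total_cells
  m_hat / denom
}

#' Estimate a mitotic mutation rate from a fluctuation experiment
#'
#' Full MSS-MLE workflow: estimate m, convert it to a per-cell per-division
#' rate using the mean final population, and attach Foster 95% confidence
#' limits (computed on the m scale and divided through by the same
#' population).  A warning is issued when the per-culture final populations
#' are strongly heterogeneous (CV > 0.5), since a single mean divisor is
#' then a coarse summary.
#'
#' @param experiment A [fluctuation_experiment()].
#' @param divisor Rate convention, see [rate_from_m()].
#' @param r_cap Jackpot censoring threshold, see [mss_mle()].
#' @return Object of class `mutation_rate_estimate`: list with `m_hat`,
#'   `rate`, `ci95_low`, `ci95_high`, `n_cultures`, `mean_total_cells`,
#'   `divisor`, `label`.
#' @examples
#' fx <- fluctuation_experiment(c(0, 1, 0, 0, 9, 0, 2, 0, 0, 0), 2e7)
#' estimate_mutation_rate(fx)
#' @export
estimate_mutation_rate <- function(experiment,
                                   divisor = c("final", "final-ln2"),
                                   r_cap = 512L) {
  if (!inherits(experiment, "fluctuation_experiment")) {
    stop("experiment must be a fluctuation_experiment")
  }
  if (nrow(experiment) < 2L) stop("at least 2 cultures are required")
  divisor <- match.arg(divisor)
  nt <- experiment$total_cells
  cv <- stats::sd(nt) / mean(nt)
  if (is.finite(cv) && cv > 0.5) {
    warning(sprintf(
      "final populations are heterogeneous (CV = %.2f); rate uses their mean", cv))
  }
  m_hat <- mss_mle(experiment, r_cap = r_cap)
  n_bar <- mean(nt)
  rate <- rate_from_m(m_hat, n_bar, divisor = divisor)
  ci_m <- if (m_hat > 0) {
    foster_ci95(m_hat, nrow(experiment))
  } else {
    suppressWarnings(foster_ci95(0, nrow(experiment)))
  }
  denom <- if (divisor == "final-ln2") n_bar * log(2) else n_bar
  out <- list(m_hat = m_hat,
              rate = rate,
              ci95_low = ci_m[1] / denom,
              ci95_high = ci_m[2] / denom,
              n_cultures = nrow(experiment),
              mean_total_cells = n_bar,
              divisor = divisor,
              label = attr(experiment, "label"))
  class(out) <- "mutation_rate_estimate"
  out
}

#' @export
print.mutation_rate_estimate <- function(x, ...) {
  cat("Mutation rate estimate (MSS-MLE)\n")
  if (!is.null(x$label) && nzchar(x$label)) cat("  experiment:", x$label, "\n")
  cat(sprintf("  cultures:        %d\n", x$n_cultures))
  cat(sprintf("  m (per culture): %.4g\n", x$m_hat))
  cat(sprintf("  rate:            %.3g per cell per division (divisor: %s)\n",
              x$rate, x$divisor))
  cat(sprintf("  95%% CI:          %.3g - %.3g\n", x$ci95_low, x$ci95_high))
  invisible(x)
}
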