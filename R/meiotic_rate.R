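# Meiotic mutation rate: per-culture subtraction of the pre-sporulation
# (mitotic) mutant frequency from the post-sporulation (meiotic) frequency.
# Because meiosis is a single division, the median of the differences is
# itself a rate per meiosis.

#' Construct matched mitotic/meiotic frequency pairs
#'
#' One row per culture: the mutant frequency measured during mitotic growth
#' (just before transfer to sporulation medium) and the mutant frequency
#' among the spores of the same culture after meiosis.
#'
#' @param mitotic_frequency Mutants per viable cell before sporulation.
#' @param meiotic_frequency Mutants per viable spore after sporulation.
#' @param culture_id Optional identifiers.
#' @return Object of class `meiosis_pairs` (a data frame).
#' @examples
#' meiosis_pairs(c(1e-7, 2e-7), c(6e-7, 9e-7))
#' @export
meiosis_pairs <- function(mitotic_frequency, meiotic_frequency,
                          culture_id = seq_along(mitotic_frequency)) {
  if (length(mitotic_frequency) != length(meiotic_frequency)) {
    stop("frequency vectors must have equal length")
  }
  if (length(mitotic_frequency) < 1L) stop("at least one culture is required")
  ok <- function(f) all(is.finite(f)) && all(f >= 0) && all(f <= 1)
  if (!ok(mitotic_frequency) || !ok(meiotic_frequency)) {
    stop("frequencies must lie in [0, 1]")
  }
  out <- data.frame(culture_id = culture_id,
                    mitotic_frequency = mitotic_frequency,
                    meiotic_frequency = meiotic_frequency,
                    stringsAsFactors = FALSE)
  class(out) <- c("meiosis_pairs", "data.frame")
  out
}

#' Meiotic mutation rate by per-culture frequency subtraction
#'
#' For each culture the mitotic mutant frequency is subtracted from the
#' post-sporulation frequency; the median of the differences over cultures
#' is reported as the mutation rate per meiosis (meiosis being a single
#' division, frequency and rate coincide).  Negative per-culture differences
#' are retained: the median is robust to them and flooring at zero would
#' bias the estimate upward.  A warning is emitted when more than 25% of the
#' differences are negative, since that suggests a measurement problem.
#'
#' @param pairs A [meiosis_pairs()] object.
#' @return Median difference (rate per meiosis).
#' @examples
#' p <- meiosis_pairs(c(1e-7, 1e-7, 1e-7), c(2e-7, 4e-7, 6e-7))
#' meiotic_rate(p)
#' @export
meiotic_rate <- function(pairs) {
  if (!inherits(pairs, "meiosis_pairs")) stop("pairs must be a meiosis_pairs object")
  if (nrow(pairs) < 1L) stop("empty input")
  d <- pairs$meiotic_frequency - pairs$mitotic_frequency
  if (mean(d < 0) > 0.25) {
    warning(sprintf("%.0f%% of per-culture differences are negative",
                    100 * mean(d < 0)))
  }
  stats::median(d)
}

#' Fold change between two rates
#'
#' @param numerator_rate,denominator_rate Per-division rates on the same
#'   scale (e.g. meiotic over mitotic).
#' @return Dimensionless ratio.  In printed summaries the package rounds
#'   fold changes to one decimal, always computed from unrounded rates.
#' @examples
#' fold_change(37e-8, 5.7e-8)
#' @export
fold_change <- function(numerator_rate, denominator_rate) {
  if (any(!is.finite(denominator_rate)) || any(denominator_rate <= 0)) {
    stop("denominator_rate must be positive")
  }
  numerator_rate / denominator_rate
}

#' Two-sample t test on per-culture rate differences
#'
#' Compares two groups of per-culture values (e.g. meiotic-minus-mitotic
#' frequency differences from two strains).  Welch's unequal-variance
#' two-sided test by default; set `var_equal = TRUE` for the pooled-variance
#' variant.
#'
#' @param group_a,group_b Numeric vectors with at least 2 values each.
#' @param var_equal Use the pooled-variance (classical Student) test.
#' @return List with `statistic`, `df`, `p_value`.
#' @examples
#' rate_ttest(rnorm(10), rnorm(10, 2))
#' @export
rate_ttest <- function(group_a, group_b, var_equal = FALSE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 values")
  }
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (isTRUE(all.equal(mean(group_a), mean(group_b)))) {
      # identical constant groups: no evidence of a difference
      return(list(statistic = 0, df = NA_real_, p_value = 1))
    }
    stop("both groups have zero variance")
  }
  tt <- stats::t.test(group_a, group_b, var.equal = var_equal)
  list(statistic = unname(tt$statistic),
       df = unname(tt$parameter),
       p_value = tt$p.value)
}
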