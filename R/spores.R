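# Random-spore analysis: crossover-interval classification of individual
# spores, crossover class tallies (NCO / single / double / triple),
# expected multiple-crossover percentages under independence, and
# interference (observed/expected) ratios.

#' Classify one spore into exchanged intervals
#'
#' Given a spore's ordered parental-origin calls (values `"P1"`/`"P2"`, one
#' per marker along the chromosome), an interval between adjacent markers is
#' called exchanged iff the calls on its two sides differ.  A spore with no
#' exchanges is a non-crossover (NCO).  Note that an apparent exchange can
#' also be produced by a gene conversion of a flanking marker; random-spore
#' data cannot distinguish the two, so multi-exchange spores should be
#' interpreted with the `ambiguous_gc` flag reported by
#' [crossover_tally()] in mind.
#'
#' @param calls Character vector of ordered parental-origin calls
#'   (`"P1"`/`"P2"`), length >= 2.
#' @return Integer vector of exchanged interval indices (interval `i` lies
#'   between markers `i` and `i + 1`); `integer(0)` for an NCO.  Returns
#'   `NULL` if any call is missing/unknown (the spore must be excluded).
#' @examples
#' classify_spore(c("P1", "P2", "P2", "P2"))
#' @export
classify_spore <- function(calls) {
  calls <- as.character(calls)
  if (length(calls) < 2L) stop("need at least 2 markers")
  if (any(is.na(calls)) || !all(calls %in% c("P1", "P2"))) {
    return(NULL)
  }
  which(calls[-length(calls)] != calls[-1L])
}

#' Tally crossover classes over a group of spores
#'
#' Classifies every spore with [classify_spore()] and tallies per-interval
#' exchange counts and crossover classes: NCO, single crossover (per
#' interval), double crossover, and triple-or-more.  Spores with unknown
#' marker calls are excluded (with a message).  Per-interval counts are
#' marginal: a double crossover contributes to both of its intervals.
#'
#' @param calls_matrix Character matrix, one row per spore, one column per
#'   marker (ordered by chromosome position), values `"P1"`/`"P2"`.
#' @return Object of class `crossover_tally`: list with `total` (spores
#'   retained), `per_interval` (marginal exchange counts, length K-1),
#'   `nco`, `single` (per interval), `double`, `triple_plus`, and
#'   `ambiguous_gc` (number of multi-exchange spores, whose exchanges could
#'   also be gene conversions of internal markers).
#' @export
crossover_tally <- function(calls_matrix) {
  calls_matrix <- as.matrix(calls_matrix)
  if (ncol(calls_matrix) < 2L) stop("need at least 2 markers")
  k <- ncol(calls_matrix) - 1L
  classified <- apply(calls_matrix, 1L, classify_spore, simplify = FALSE)
  drop <- vapply(classified, is.null, logical(1))
  if (any(drop)) {
    message(sprintf("%d spore(s) with unknown marker calls excluded", sum(drop)))
    classified <- classified[!drop]
  }
  n_ex <- lengths(classified)
  per_interval <- integer(k)
  for (ex in classified) per_interval[ex] <- per_interval[ex] + 1L
  single <- integer(k)
  for (ex in classified[n_ex == 1L]) single[ex] <- single[ex] + 1L
  out <- list(total = length(classified),
              per_interval = per_interval,
              nco = sum(n_ex == 0L),
              single = single,
              double = sum(n_ex == 2L),
              triple_plus = sum(n_ex >= 3L),
              ambiguous_gc = sum(n_ex >= 2L))
  class(out) <- "crossover_tally"
  out
}

#' Expected multiple-crossover percentage under independence
#'
#' Expected percentage of spores with a simultaneous exchange in every
#' interval of `intervals`, assuming independence between intervals: the
#' product of the marginal exchange fractions, times 100.  Marginal
#' fractions include spores with multiple exchanges by default (each
#' interval's marginal counts every spore exchanged there, whether or not
#' it is also exchanged elsewhere); set `inclusive = FALSE` to use
#' single-crossover counts only.
#'
#' @param tally A [crossover_tally()].
#' @param intervals Integer indices of the intervals (e.g. `c(1, 2)` for a
#'   double crossover across the first two intervals).
#' @param inclusive Include multi-exchange spores in the marginals
#'   (default TRUE).
#' @return Expected percentage (0-100).
#' @export
expected_multi_co <- function(tally, intervals, inclusive = TRUE) {
  if (!inherits(tally, "crossover_tally")) stop("tally must be a crossover_tally")
  intervals <- as.integer(intervals)
  if (length(intervals) < 1L) stop("intervals must be nonempty")
  if (any(intervals < 1L) || any(intervals > length(tally$per_interval))) {
    stop("interval index out of range")
  }
  if (tally$total <= 0) stop("tally has no spores")
  counts <- if (inclusive) tally$per_interval else tally$single
  100 * prod(counts[intervals] / tally$total)
}

#' Crossover interference ratio (observed / expected)
#'
#' Ratio of the observed multiple-crossover percentage to the percentage
#' expected under independence.  Values below 1 indicate positive crossover
#' interference (fewer double crossovers than expected); a ratio near or
#' above 1 indicates loss of interference.
#'
#' @param observed_pct,expected_pct Percentages on the same scale.
#' @return The ratio; `NA` (with a warning) when both are 0, `Inf` (with a
#'   warning) when only the expected is 0.
#' @examples
#' interference_ratio(1.0, 2.0)
#' @export
interference_ratio <- function(observed_pct, expected_pct) {
  if (expected_pct < 0 || observed_pct < 0) stop("percentages must be nonnegative")
  if (expected_pct == 0) {
    if (observed_pct == 0) {
      warning("no crossovers observed or expected; ratio undefined")
      return(NA_real_)
    }
    warning("expected percentage is 0 with observed > 0; ratio is infinite")
    return(Inf)
  }
  observed_pct / expected_pct
}

#' Compare crossover fractions between two spore groups
#'
#' For each interval, reports the marginal exchange fraction in group `a`
#' divided by that in group `b` (e.g. Can-r mutant spores over Can-s
#' non-mutant spores), with a Pearson chi-square test (no continuity
#' correction) on the exchanged / not-exchanged counts.
#'
#' @param a,b [crossover_tally()] objects over the same markers.
#' @return Data frame with one row per interval: `frac_a`, `frac_b`,
#'   `ratio` (NA when `frac_b` is 0), `statistic`, `p_value`.
#' @export
compare_groups <- function(a, b) {
  if (!inherits(a, "crossover_tally") || !inherits(b, "crossover_tally")) {
    stop("a and b must be crossover_tally objects")
  }
  if (length(a$per_interval) != length(b$per_interval)) {
    stop("groups scored over different numbers of intervals")
  }
  if (a$total <= 0 || b$total <= 0) stop("both groups must be nonempty")
  k <- length(a$per_interval)
  frac_a <- a$per_interval / a$total
  frac_b <- b$per_interval / b$total
  stat <- p <- numeric(k)
  for (i in seq_len(k)) {
    tab <- rbind(c(a$per_interval[i], a$total - a$per_interval[i]),
                 c(b$per_interval[i], b$total - b$per_interval[i]))
    if (any(colSums(tab) == 0)) {
      stat[i] <- 0; p[i] <- 1
      next
    }
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(e < 5)) {
      warning(sprintf("interval %d: expected counts below 5; chi-square approximation is coarse", i))
    }
    stat[i] <- sum((tab - e)^2 / e)
    p[i] <- stats::pchisq(stat[i], 1, lower.tail = FALSE)
  }
  data.frame(interval = seq_len(k),
             frac_a = frac_a,
             frac_b = frac_b,
             ratio = ifelse(frac_b > 0, frac_a / frac_b, NA_real_),
             statistic = stat,
             p_value = p)
}
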