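# Tetrad analysis: PD/NPD/TT classification per marker interval, Perkins
# map distances with standard errors, percent recombination, per-kilobase
# densities, and chi-square comparison of tetrad class tables.

#' Construct a tetrad
#'
#' A dissected four-spore ascus with marker calls for each spore, together
#' with the two parental haplotypes that define which allele came from which
#' parent.
#'
#' @param spores 4 x K character matrix of allele calls (rows = spores,
#'   columns = markers, in chromosome order).
#' @param parent1,parent2 Character vectors of length K: the two parental
#'   haplotypes.  Every spore call must match one of the two parental
#'   alleles at that marker.
#' @param markers Marker names (defaults to column names of `spores`).
#' @param id Tetrad identifier.
#' @return Object of class `tetrad`.
#' @examples
#' t <- tetrad(rbind(c("A", "B"), c("A", "B"), c("a", "b"), c("a", "b")),
#'             parent1 = c("A", "B"), parent2 = c("a", "b"))
#' classify_tetrad(t, c(1, 2))
#' @export
tetrad <- function(spores, parent1, parent2, markers = colnames(spores),
                   id = NA_character_) {
  spores <- as.matrix(spores)
  if (nrow(spores) != 4L) stop("a tetrad must have exactly 4 viable spores")
  k <- ncol(spores)
  if (length(parent1) != k || length(parent2) != k) {
    stop("parental haplotypes must cover every marker")
  }
  if (any(parent1 == parent2)) {
    stop("parents must differ at every scored marker")
  }
  for (j in seq_len(k)) {
    if (!all(spores[, j] %in% c(parent1[j], parent2[j]))) {
      stop(sprintf("spore call at marker %d matches neither parental allele", j))
    }
  }
  if (is.null(markers)) markers <- paste0("m", seq_len(k))
  structure(list(spores = spores, parent1 = parent1, parent2 = parent2,
                 markers = markers, id = id),
            class = "tetrad")
}

# TRUE for each marker iff the two parental alleles segregate 2:2.
segregates_2to2 <- function(t) {
  vapply(seq_along(t$markers),
         function(j) sum(t$spores[, j] == t$parent1[j]) == 2L,
         logical(1))
}

#' Classify a tetrad for a two-marker interval
#'
#' Each spore is parental if its two calls match the same parental
#' haplotype, recombinant otherwise.  A tetrad is PD (parental ditype) when
#' all four spores are parental, NPD (non-parental ditype) when all four are
#' recombinant, and TT (tetratype) when two are parental and two
#' recombinant.  Markers that fail 2:2 segregation indicate a gene
#' conversion; such tetrads are flagged `"GC"` and must be excluded from
#' PD/NPD/TT tallies.
#'
#' @param t A [tetrad()].
#' @param interval Length-2 vector of marker names or column indices.
#' @return One of `"PD"`, `"NPD"`, `"TT"`, or `"GC"` (gene-conversion flag
#'   for non-2:2 segregation at either marker).
#' @export
classify_tetrad <- function(t, interval) {
  if (!inherits(t, "tetrad")) stop("t must be a tetrad")
  if (length(interval) != 2L) stop("interval must name exactly 2 markers")
  idx <- if (is.character(interval)) match(interval, t$markers) else as.integer(interval)
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > length(t$markers))) {
    stop("interval markers not found")
  }
  if (!all(segregates_2to2(t)[idx])) return("GC")
  a <- t$spores[, idx[1]]
  b <- t$spores[, idx[2]]
  parental <- (a == t$parent1[idx[1]] & b == t$parent1[idx[2]]) |
              (a == t$parent2[idx[1]] & b == t$parent2[idx[2]])
  n_par <- sum(parental)
  if (n_par == 4L) "PD" else if (n_par == 0L) "NPD" else "TT"
}

#' Tetrad class counts for one interval
#'
#' @param PD,NPD,TT Nonnegative integer counts of parental ditypes,
#'   non-parental ditypes and tetratypes.
#' @param kb Physical length of the interval in kilobases, counting only the
#'   portion with homology between the two parents (heterologous insertions
#'   cannot recombine and are excluded from the length).
#' @param interval Optional label, e.g. `"natMX-MAT"`.
#' @return Object of class `tetrad_counts`.
#' @examples
#' perkins_cm(tetrad_counts(269, 0, 16))
#' @export
tetrad_counts <- function(PD, NPD, TT, kb = NA_real_, interval = NA_character_) {
  cnt <- c(PD, NPD, TT)
  if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != floor(cnt))) {
    stop("PD, NPD and TT must be nonnegative integers")
  }
  structure(list(PD = PD, NPD = NPD, TT = TT, kb = kb, interval = interval),
            class = "tetrad_counts")
}

#' Tally classified tetrads into PD/NPD/TT counts
#'
#' Applies [classify_tetrad()] to a list of tetrads and counts the classes;
#' gene-conversion tetrads (non-2:2 segregation) are excluded from the
#' counts and reported via the `gene_conversions` attribute and a message.
#'
#' @param tetrads List of [tetrad()] objects.
#' @param interval Two marker names/indices.
#' @param kb Homologous physical length of the interval (kb).
#' @return A [tetrad_counts()] with attribute `gene_conversions`.
#' @export
tally_tetrads <- function(tetrads, interval, kb = NA_real_) {
  cls <- vapply(tetrads, classify_tetrad, character(1), interval = interval)
  n_gc <- sum(cls == "GC")
  if (n_gc > 0) {
    message(sprintf("%d tetrad(s) with non-2:2 segregation excluded as gene conversions", n_gc))
  }
  lab <- if (is.character(interval)) paste(interval, collapse = "-") else NA_character_
  out <- tetrad_counts(sum(cls == "PD"), sum(cls == "NPD"), sum(cls == "TT"),
                       kb = kb, interval = lab)
  attr(out, "gene_conversions") <- n_gc
  out
}

as_counts <- function(x) {
  if (inherits(x, "tetrad_counts")) x else stop("expected a tetrad_counts object")
}

#' Perkins map distance
#'
#' The NPD-corrected tetrad map distance
#' \deqn{cM = \frac{100\,(6\,NPD + TT)}{2\,(PD + NPD + TT)}
#'          = \frac{50\,(TT + 6\,NPD)}{PD + NPD + TT}.}
#'
#' @param x A [tetrad_counts()].
#' @return Map distance in centimorgans (unrounded).
#' @examples
#' perkins_cm(tetrad_counts(140, 1, 144))
#' @export
perkins_cm <- function(x) {
  x <- as_counts(x)
  n <- x$PD + x$NPD + x$TT
  if (n <= 0) stop("no classified tetrads")
  50 * (x$TT + 6 * x$NPD) / n
}

#' Percent recombination from tetrad counts
#'
#' Fraction of recombinant spores among all spores: a TT contributes 2/4
#' recombinant spores and an NPD 4/4, so
#' \deqn{\%rec = 100\,(TT + 2\,NPD) / (PD + NPD + TT).}
#'
#' @param x A [tetrad_counts()].
#' @return Percent recombination (unrounded).
#' @examples
#' percent_recombination(tetrad_counts(269, 0, 16))
#' @export
percent_recombination <- function(x) {
  x <- as_counts(x)
  n <- x$PD + x$NPD + x$TT
  if (n <= 0) stop("no classified tetrads")
  100 * (x$TT + 2 * x$NPD) / n
}

#' Standard error of the Perkins map distance
#'
#' Multinomial (Perkins-style) standard error of the map distance:
#' \deqn{SE = \frac{100}{2n} \sqrt{TT + 36\,NPD - (TT + 6\,NPD)^2 / n},
#'       \quad n = PD + NPD + TT.}
#'
#' @param x A [tetrad_counts()] with at least 2 classified tetrads.
#' @return Standard error in centimorgans.
#' @examples
#' perkins_se(tetrad_counts(140, 1, 144))
#' @export
perkins_se <- function(x) {
  x <- as_counts(x)
  n <- x$PD + x$NPD + x$TT
  if (n <= 1) stop("need more than one classified tetrad")
  v <- x$TT + 36 * x$NPD - (x$TT + 6 * x$NPD)^2 / n
  (100 / (2 * n)) * sqrt(max(v, 0))
}

#' Recombination density per kilobase
#'
#' @param cm Map distance in centimorgans.
#' @param kb Physical interval length in kilobases (homologous portion
#'   only; > 0).
#' @return cM/kb.
#' @examples
#' cm_per_kb(26.3, 22.5)
#' @export
cm_per_kb <- function(cm, kb) {
  if (any(!is.finite(kb)) || any(kb <= 0)) stop("kb must be positive")
  cm / kb
}

#' Chi-square comparison of two tetrad class tables
#'
#' Pearson chi-square (no continuity correction) on the 2 x 3 contingency
#' table of PD/NPD/TT counts for two strains.  Columns that are zero in both
#' strains are dropped; if any remaining cell has expected count below 5 the
#' NPD and TT columns are pooled into a single recombinant class, reducing
#' to a 2 x 2 table.
#'
#' @param a,b [tetrad_counts()] objects for the two strains.
#' @return List with `statistic`, `df`, `p_value`, and the `table` actually
#'   tested.
#' @examples
#' chisq_tetrads(tetrad_counts(269, 0, 16), tetrad_counts(243, 0, 8))
#' @export
chisq_tetrads <- function(a, b) {
  a <- as_counts(a); b <- as_counts(b)
  tab <- rbind(a = c(PD = a$PD, NPD = a$NPD, TT = a$TT),
               b = c(PD = b$PD, NPD = b$NPD, TT = b$TT))
  if (any(rowSums(tab) == 0)) stop("each strain needs classified tetrads")
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2L) stop("no variation between classes to test")
  expected <- function(t) outer(rowSums(t), colSums(t)) / sum(t)
  if (ncol(tab) == 3L && any(expected(tab) < 5)) {
    tab <- cbind(PD = tab[, "PD"], rec = tab[, "NPD"] + tab[, "TT"])
  }
  e <- expected(tab)
  if (any(e < 5)) {
    warning("expected counts below 5 after pooling; chi-square approximation is coarse")
  }
  stat <- sum((tab - e)^2 / e)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       table = tab)
}

#' Summarize tetrad counts for a set of intervals
#'
#' Builds the standard per-interval summary: counts, percent recombination,
#' Perkins cM with standard error, and cM/kb where a physical length is
#' known.
#'
#' @param counts_list List of [tetrad_counts()] objects.
#' @return Data frame with one row per interval.
#' @export
summarize_tetrads <- function(counts_list) {
  rows <- lapply(counts_list, function(x) {
    x <- as_counts(x)
    cm <- perkins_cm(x)
    data.frame(interval = x$interval,
               PD = x$PD, NPD = x$NPD, TT = x$TT,
               pct_recombination = percent_recombination(x),
               cM = cm,
               SE = perkins_se(x),
               kb = x$kb,
               cM_per_kb = if (is.finite(x$kb) && x$kb > 0) cm_per_kb(cm, x$kb) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
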