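# Mutation-spectrum classification for a forward-mutation reporter ORF:
# frameshifts (contraction/expansion), base substitutions
# (transition/transversion), complex events, and positional distribution in
# fixed windows along the ORF.

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

valid_seq <- function(x) {
  vapply(strsplit(x, ""), function(ch) all(ch %in% c("A", "C", "G", "T")) || length(ch) == 0L,
         logical(1))
}

#' Construct a table of sequenced mutation records
#'
#' One row per sequenced change.  Positions are 1-based relative to the
#' reporter ORF start codon (the A of ATG is +1).  A deletion is written
#' with the deleted bases in `ref` and the retained prefix (possibly empty)
#' in `alt`; an insertion the other way round.
#'
#' @param isolate_id Identifier of the sequenced isolate; an isolate with
#'   two or more records is classified as a complex event.
#' @param phase `"mitosis"` or `"meiosis"`: the division in which the
#'   mutation arose.
#' @param position 1-based position of the first changed base.
#' @param ref,alt Reference and alternate sequences over A/C/G/T (`alt` may
#'   be empty for a pure deletion); `ref != alt`.
#' @return Object of class `mutation_records` (a data frame).
#' @export
mutation_records <- function(isolate_id, phase, position, ref, alt) {
  n <- length(isolate_id)
  if (length(phase) != n || length(position) != n ||
      length(ref) != n || length(alt) != n) {
    stop("all fields must have equal length")
  }
  phase <- as.character(phase)
  if (!all(phase %in% c("mitosis", "meiosis"))) {
    stop('phase must be "mitosis" or "meiosis"')
  }
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  if (any(!valid_seq(ref)) || any(!valid_seq(alt))) {
    stop("ref and alt must be strings over A/C/G/T")
  }
  if (any(ref == alt)) stop("ref must differ from alt")
  if (any(!is.finite(position)) || any(position < 1)) {
    stop("position must be >= 1")
  }
  out <- data.frame(isolate_id = as.character(isolate_id), phase = phase,
                    position = as.integer(position), ref = ref, alt = alt,
                    stringsAsFactors = FALSE)
  class(out) <- c("mutation_records", "data.frame")
  out
}

#' Classify a single mutation call
#'
#' A change with `nchar(ref) == nchar(alt) == 1` is a base substitution:
#' a transition if purine-to-purine (A<->G) or pyrimidine-to-pyrimidine
#' (C<->T), otherwise a transversion.  A length change not divisible by 3
#' is a frameshift: a contraction on net loss of bases, an expansion on net
#' gain.  In-frame indels (length change a nonzero multiple of 3) are kept
#' as their own class rather than forced into the three summary classes.
#' Equal-length multi-base changes are classified complex.  Isolate-level
#' complexity (>= 2 changes in one isolate) is handled by
#' [summarize_spectrum()], not here.
#'
#' @param ref,alt Character vectors of reference/alternate sequences
#'   (vectorized; `ref != alt` elementwise).
#' @return Data frame with columns `class` (`"substitution"`,
#'   `"frameshift"`, `"in_frame_indel"`, `"complex"`) and `subtype`
#'   (`"transition"`/`"transversion"`, `"contraction"`/`"expansion"`, or
#'   `NA`).
#' @examples
#' classify_mutation("G", "A")   # transition
#' classify_mutation("AA", "A")  # frameshift contraction
#' @export
classify_mutation <- function(ref, alt) {
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  if (length(ref) != length(alt)) stop("ref and alt must have equal length")
  if (any(ref == alt)) stop("ref must differ from alt")
  if (any(!valid_seq(ref)) || any(!valid_seq(alt))) {
    stop("ref and alt must be strings over A/C/G/T")
  }
  d <- nchar(alt) - nchar(ref)
  cls <- sub <- character(length(ref))
  is_snv <- nchar(ref) == 1L & nchar(alt) == 1L
  cls[is_snv] <- "substitution"
  ts <- is_snv & ((ref %in% PURINES & alt %in% PURINES) |
                  (ref %in% PYRIMIDINES & alt %in% PYRIMIDINES))
  sub[is_snv] <- ifelse(ts[is_snv], "transition", "transversion")
  fs <- d != 0L & (d %% 3L) != 0L
  cls[fs] <- "frameshift"
  sub[fs] <- ifelse(d[fs] < 0L, "contraction", "expansion")
  inframe <- d != 0L & !fs
  cls[inframe] <- "in_frame_indel"; sub[inframe] <- NA_character_
  mnv <- d == 0L & !is_snv
  cls[mnv] <- "complex"; sub[mnv] <- NA_character_
  sub[sub == ""] <- NA_character_
  data.frame(class = cls, subtype = sub, stringsAsFactors = FALSE)
}

summarize_one_group <- function(rec) {
  cls <- classify_mutation(rec$ref, rec$alt)
  rec <- cbind(rec, cls)
  per_iso <- split(rec, rec$isolate_id)
  iso_class <- vapply(per_iso, function(d) {
    if (nrow(d) >= 2L) "complex" else d$class[1]
  }, character(1))
  iso_sub <- vapply(per_iso, function(d) {
    if (nrow(d) >= 2L) NA_character_ else d$subtype[1]
  }, character(1))
  n_total <- length(iso_class)
  n_fs <- sum(iso_class == "frameshift")
  n_sub <- sum(iso_class == "substitution")
  n_cx <- sum(iso_class == "complex")
  n_if <- sum(iso_class == "in_frame_indel")
  out <- list(n_total = n_total,
              n_frameshift = n_fs,
              n_contraction = sum(iso_sub == "contraction", na.rm = TRUE),
              n_expansion = sum(iso_sub == "expansion", na.rm = TRUE),
              n_substitution = n_sub,
              n_transition = sum(iso_sub == "transition", na.rm = TRUE),
              n_transversion = sum(iso_sub == "transversion", na.rm = TRUE),
              n_complex = n_cx,
              n_in_frame_indel = n_if,
              pct_frameshift = round(100 * n_fs / n_total),
              pct_substitution = round(100 * n_sub / n_total),
              pct_complex = round(100 * n_cx / n_total))
  class(out) <- "spectrum_summary"
  out
}

#' Summarize a mutation spectrum per phase
#'
#' Classifies every record, collapses records to isolates (an isolate
#' carrying two or more distinct changes counts once, as a complex event),
#' and tallies frameshift (contraction:expansion), base substitution
#' (transition:transversion), complex and in-frame indel classes per phase
#' group, with integer-rounded percentages of the isolate total.
#'
#' @param records A [mutation_records()] table.
#' @return Named list of `spectrum_summary` objects, one per phase present.
#' @export
summarize_spectrum <- function(records) {
  if (!inherits(records, "mutation_records")) {
    stop("records must be a mutation_records table")
  }
  if (nrow(records) < 1L) stop("empty record table")
  lapply(split(records, records$phase), summarize_one_group)
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("Spectrum over %d isolates\n", x$n_total))
  cat(sprintf("  frameshift:   %d/%d (%d%%), contractions:expansions %d:%d\n",
              x$n_frameshift, x$n_total, x$pct_frameshift,
              x$n_contraction, x$n_expansion))
  cat(sprintf("  substitution: %d/%d (%d%%), transitions:transversions %d:%d\n",
              x$n_substitution, x$n_total, x$pct_substitution,
              x$n_transition, x$n_transversion))
  cat(sprintf("  complex:      %d/%d (%d%%)\n", x$n_complex, x$n_total,
              x$pct_complex))
  if (x$n_in_frame_indel > 0) {
    cat(sprintf("  in-frame indel: %d/%d\n", x$n_in_frame_indel, x$n_total))
  }
  invisible(x)
}

#' Chi-square comparison of two mutation spectra
#'
#' By default tests the frameshift versus non-frameshift split between two
#' groups (a 2 x 2 table); `full = TRUE` tests the full frameshift /
#' substitution / complex 2 x 3 table instead.  Pearson chi-square without
#' continuity correction.
#'
#' @param a,b `spectrum_summary` objects (see [summarize_spectrum()]).
#' @param full Test the three-class table instead of frameshift vs rest.
#' @return List with `statistic`, `df`, `p_value`, `table`.
#' @export
compare_spectra <- function(a, b, full = FALSE) {
  if (!inherits(a, "spectrum_summary") || !inherits(b, "spectrum_summary")) {
    stop("a and b must be spectrum_summary objects")
  }
  if (a$n_total <= 0 || b$n_total <= 0) stop("both groups must be nonempty")
  tab <- if (full) {
    rbind(a = c(frameshift = a$n_frameshift, substitution = a$n_substitution,
                complex = a$n_complex),
          b = c(frameshift = b$n_frameshift, substitution = b$n_substitution,
                complex = b$n_complex))
  } else {
    rbind(a = c(frameshift = a$n_frameshift, other = a$n_total - a$n_frameshift),
          b = c(frameshift = b$n_frameshift, other = b$n_total - b$n_frameshift))
  }
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2L) stop("degenerate table: a class margin is zero")
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       table = tab)
}

# Merge adjacent windows until every pooled expected count reaches the
# threshold (greedy: repeatedly merge the window pair with the smallest
# combined total).  `counts` is a groups x windows matrix.
pool_windows <- function(counts, threshold = 5) {
  repeat {
    e <- outer(rowSums(counts), colSums(counts)) / sum(counts)
    if (ncol(counts) <= 2L || all(e >= threshold)) return(counts)
    tot <- colSums(counts)
    j <- which.min(tot[-length(tot)] + tot[-1L])  # adjacent pair to merge
    merged <- counts[, j] + counts[, j + 1L, drop = TRUE]
    counts <- cbind(counts[, seq_len(j - 1L), drop = FALSE],
                    merged,
                    counts[, -seq_len(j + 1L), drop = FALSE])
  }
}

#' Positional distribution of mutations along the reporter ORF
#'
#' Bins mutation positions into fixed half-open windows
#' `[1, w+1), [w+1, 2w+1), ...` along the ORF (the last window may be
#' short) and, when two phase groups are present, tests homogeneity of the
#' window distributions by Pearson chi-square, pooling adjacent windows
#' while any expected count is below 5.  Records beyond the ORF end are
#' excluded with a message.
#'
#' @param records A [mutation_records()] table.
#' @param orf_length Length of the reporter ORF in bp.
#' @param window_bp Window width in bp (default 200).
#' @return List with `windows` (data frame of window bounds and per-phase
#'   counts) and, when both phases are present, `statistic`, `df`,
#'   `p_value` from the homogeneity test (on the pooled table).
#' @export
positional_distribution <- function(records, orf_length, window_bp = 200L) {
  if (!inherits(records, "mutation_records")) {
    stop("records must be a mutation_records table")
  }
  if (orf_length < 1 || window_bp < 1) stop("orf_length and window_bp must be positive")
  off <- records$position > orf_length
  if (any(off)) {
    message(sprintf("%d record(s) beyond the ORF excluded", sum(off)))
    records <- records[!off, , drop = FALSE]
  }
  if (nrow(records) == 0L) stop("no records within the ORF")
  n_win <- ceiling(orf_length / window_bp)
  win <- (records$position - 1L) %/% window_bp + 1L
  phases <- sort(unique(records$phase))
  counts <- t(vapply(phases, function(ph) {
    tabulate(win[records$phase == ph], nbins = n_win)
  }, integer(n_win)))
  rownames(counts) <- phases
  windows <- data.frame(window = seq_len(n_win),
                        start = (seq_len(n_win) - 1L) * window_bp + 1L,
                        end = pmin(seq_len(n_win) * window_bp, orf_length))
  for (ph in phases) windows[[ph]] <- counts[ph, ]
  out <- list(windows = windows)
  if (length(phases) == 2L) {
    keep <- colSums(counts) > 0
    pooled <- pool_windows(counts[, keep, drop = FALSE])
    e <- outer(rowSums(pooled), colSums(pooled)) / sum(pooled)
    stat <- sum((pooled - e)^2 / e)
    df <- (nrow(pooled) - 1) * (ncol(pooled) - 1)
    out$statistic <- stat
    out$df <- df
    out$p_value <- stats::pchisq(stat, df, lower.tail = FALSE)
  }
  out
}
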