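# Tab-separated input/output for every analysis module.  All readers
# expect UTF-8 TSV with a header row; lines starting with '#' are ignored.

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         check.names = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  d
}

#' Read per-culture fluctuation counts
#'
#' TSV with columns `culture_id`, `mutant_count`, `total_cells`, one row
#' per culture, counts already scaled to the whole culture.
#'
#' @param path File path.
#' @param label Experiment label.
#' @return A [fluctuation_experiment()].
#' @export
read_cultures <- function(path, label = basename(path)) {
  d <- read_tsv_checked(path, c("culture_id", "mutant_count", "total_cells"))
  fluctuation_experiment(d$mutant_count, d$total_cells,
                         culture_id = d$culture_id, label = label)
}

#' Write a fluctuation experiment as TSV
#' @param experiment A [fluctuation_experiment()].
#' @param path Output path.
#' @export
write_cultures <- function(experiment, path) {
  utils::write.table(as.data.frame(experiment), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read matched mitotic/meiotic plating counts
#'
#' TSV with columns `culture_id`, `mitotic_mutants`, `mitotic_total`,
#' `meiotic_mutants`, `meiotic_total`; frequencies are computed internally
#' as mutants/total per plating.
#'
#' @param path File path.
#' @return A [meiosis_pairs()] object.
#' @export
read_meiosis_pairs <- function(path) {
  d <- read_tsv_checked(path, c("culture_id", "mitotic_mutants",
                                "mitotic_total", "meiotic_mutants",
                                "meiotic_total"))
  if (any(d$mitotic_total <= 0) || any(d$meiotic_total <= 0)) {
    stop("total counts must be positive")
  }
  meiosis_pairs(d$mitotic_mutants / d$mitotic_total,
                d$meiotic_mutants / d$meiotic_total,
                culture_id = d$culture_id)
}

#' Read an interval/marker configuration file
#'
#' Debian-control-format (DCF) file with fields:
#' \describe{
#'   \item{markers}{comma-separated marker names in chromosome order}
#'   \item{parent1, parent2}{comma-separated parental alleles, one per
#'     marker (for tetrad input) or parental phase labels (for spores)}
#'   \item{kb}{comma-separated homologous physical lengths in kb, one per
#'     interval (optional)}
#' }
#'
#' @param path File path.
#' @return List with `markers`, `parent1`, `parent2`, `kb`.
#' @export
read_marker_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.dcf(path)
  get <- function(field, required = TRUE) {
    if (!field %in% colnames(d)) {
      if (required) stop("config missing field: ", field)
      return(NULL)
    }
    trimws(strsplit(d[1, field], ",")[[1]])
  }
  markers <- get("markers")
  parent1 <- get("parent1", required = FALSE)
  parent2 <- get("parent2", required = FALSE)
  kb <- get("kb", required = FALSE)
  if (!is.null(kb)) kb <- as.numeric(kb)
  for (p in list(parent1, parent2)) {
    if (!is.null(p) && length(p) != length(markers)) {
      stop("parental haplotypes must cover every marker")
    }
  }
  if (!is.null(kb) && length(kb) != length(markers) - 1L) {
    stop("kb must give one length per interval")
  }
  list(markers = markers, parent1 = parent1, parent2 = parent2, kb = kb)
}

#' Read tetrad genotypes
#'
#' TSV with columns `tetrad_id`, `spore_index`, then one column per marker;
#' exactly 4 spore rows per tetrad.  Parental haplotypes and marker order
#' come from the config (see [read_marker_config()]); unknown-phase input
#' is rejected.
#'
#' @param path Genotype TSV path.
#' @param config A list from [read_marker_config()] with `parent1` and
#'   `parent2` set.
#' @return List of [tetrad()] objects.
#' @export
read_tetrads <- function(path, config) {
  if (is.null(config$parent1) || is.null(config$parent2)) {
    stop("config must supply both parental haplotypes (phase is not inferred)")
  }
  d <- read_tsv_checked(path, c("tetrad_id", "spore_index", config$markers))
  lapply(split(d, d$tetrad_id), function(block) {
    block <- block[order(block$spore_index), , drop = FALSE]
    m <- as.matrix(block[, config$markers, drop = FALSE])
    tetrad(m, parent1 = config$parent1, parent2 = config$parent2,
           markers = config$markers, id = as.character(block$tetrad_id[1]))
  })
}

#' Write simulated tetrads as TSV
#' @param tetrads List of [tetrad()] objects.
#' @param path Output path.
#' @export
write_tetrads <- function(tetrads, path) {
  rows <- do.call(rbind, lapply(tetrads, function(t) {
    data.frame(tetrad_id = t$id, spore_index = 1:4, t$spores,
               stringsAsFactors = FALSE, check.names = FALSE)
  }))
  colnames(rows) <- c("tetrad_id", "spore_index", tetrads[[1]]$markers)
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read random-spore genotypes
#'
#' TSV with columns `spore_id`, `canavanine`
#' (`resistant`/`sensitive`), then one parental-origin call column per
#' marker (`P1`/`P2` after phase mapping).  If the config supplies
#' `parent1`/`parent2` allele names, raw allele calls are translated to
#' `P1`/`P2`; otherwise calls must already be `P1`/`P2`.
#'
#' @param path File path.
#' @param config Optional list from [read_marker_config()].
#' @return A `spore_records` data frame.
#' @export
read_spores <- function(path, config = NULL) {
  required <- c("spore_id", "canavanine")
  d <- read_tsv_checked(path, required)
  markers <- if (!is.null(config)) config$markers else setdiff(names(d), required)
  if (!all(markers %in% names(d))) stop("marker columns missing from spore table")
  for (j in seq_along(markers)) {
    col <- as.character(d[[markers[j]]])
    if (!is.null(config) && !is.null(config$parent1)) {
      translated <- ifelse(col == config$parent1[j], "P1",
                           ifelse(col == config$parent2[j], "P2", NA))
      d[[markers[j]]] <- translated
    } else if (!all(col %in% c("P1", "P2", NA))) {
      stop("spore calls must be P1/P2, or supply a phase config")
    }
  }
  class(d) <- c("spore_records", "data.frame")
  attr(d, "markers") <- markers
  d
}

#' Write spore records as TSV
#' @param spores A `spore_records` data frame.
#' @param path Output path.
#' @export
write_spores <- function(spores, path) {
  utils::write.table(as.data.frame(spores), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Extract the marker-call matrix for one spore group
#'
#' @param spores A `spore_records` data frame.
#' @param canavanine Optional filter: `"resistant"` or `"sensitive"`.
#' @return Character matrix of calls suitable for [crossover_tally()].
#' @export
spore_calls <- function(spores, canavanine = NULL) {
  markers <- attr(spores, "markers")
  if (is.null(markers)) markers <- setdiff(names(spores), c("spore_id", "canavanine"))
  if (!is.null(canavanine)) {
    spores <- spores[spores$canavanine == canavanine, , drop = FALSE]
  }
  as.matrix(spores[, markers, drop = FALSE])
}

#' Read sequenced mutation calls
#'
#' TSV with columns `isolate_id`, `phase`, `position`, `ref`, `alt`.  An
#' optional single-sequence FASTA of the reporter ORF is used to validate
#' that each `ref` allele matches the ORF at its position.
#'
#' @param path File path.
#' @param orf_fasta Optional FASTA path for reference validation.
#' @return A [mutation_records()] table.
#' @export
read_mutations <- function(path, orf_fasta = NULL) {
  d <- read_tsv_checked(path, c("isolate_id", "phase", "position", "ref", "alt"))
  d$alt[is.na(d$alt)] <- ""
  rec <- mutation_records(d$isolate_id, d$phase, d$position, d$ref, d$alt)
  if (!is.null(orf_fasta)) {
    orf <- read_single_fasta(orf_fasta)
    for (i in seq_len(nrow(rec))) {
      r <- rec$ref[i]
      if (nchar(r) == 0L) next
      seg <- substr(orf, rec$position[i], rec$position[i] + nchar(r) - 1L)
      if (seg != r) {
        stop(sprintf("record %d: ref '%s' does not match ORF ('%s') at position %d",
                     i, r, seg, rec$position[i]))
      }
    }
  }
  rec
}

#' Write mutation records as TSV
#' @param records A [mutation_records()] table.
#' @param path Output path.
#' @export
write_mutations <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Minimal single-record FASTA reader (uncompressed, one sequence).
read_single_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!startsWith(lines[1], ">")) stop("not a FASTA file: ", path)
  headers <- startsWith(lines, ">")
  if (sum(headers) != 1L) stop("expected exactly one FASTA record")
  toupper(paste(lines[!headers], collapse = ""))
}
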