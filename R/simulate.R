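# Synthetic-data generator: Luria-Delbruck fluctuation cultures, tetrads
# and random spores under per-interval crossover probabilities (optionally
# with interference and mutation-crossover association), and mutation lists
# with a configurable spectrum.  Every generator is reproducible under the
# seed carried in the configuration.

#' Simulation configuration
#'
#' Collects every tunable parameter of the synthetic-data generators with
#' defaults chosen to emulate the wild-type diploid reporter assay:
#' cultures grown from a small inoculum to ~2e8 cells with a mitotic
#' mutation rate of 5.7e-8 per division, 18 parallel cultures, per-interval
#' map distances matching the hotspot insertion strain, and a mutation
#' spectrum matching the sequenced meiotic isolates (21% frameshift with a
#' 3:1 contraction:expansion split, 75% substitution with a 44:31
#' transition:transversion split, 4% complex) over a 1773-bp reporter ORF.
#'
#' @param seed Integer seed; every generator calls `set.seed(seed)` so that
#'   identical configurations yield identical data.
#' @param mutation_rate_per_division Mutation rate per cell per division.
#' @param n_initial,n_final Cells per culture at inoculation and at plating.
#' @param n_cultures Number of parallel cultures.
#' @param interval_cm Named numeric vector of map distances (cM), one per
#'   marker interval in chromosome order.
#' @param interference_strength Nonnegative; 0 disables interference.
#'   Adjacent double crossovers are thinned with probability
#'   `1 - exp(-interference_strength)`.
#' @param meiotic_mutation_prob Probability that a simulated random spore
#'   carries a reporter mutation (is canavanine resistant).  The default
#'   0.5 mirrors the selected sampling design of a random-spore experiment,
#'   where mutant and non-mutant spores are collected to comparable depth
#'   by plating, not in proportion to the in vivo mutant frequency.
#' @param co_association_enrichment Fold increase (>= 1) of every
#'   per-interval crossover probability in spores that carry a mutation.
#' @param spectrum_probs Named probabilities (summing to 1) over mutation
#'   classes `transition`, `transversion`, `fs_contraction`,
#'   `fs_expansion`, `complex`.
#' @param orf_length Reporter ORF length in bp.
#' @return Object of class `sim_config` (a list).
#' @export
sim_config <- function(seed = 1L,
                       mutation_rate_per_division = 5.7e-8,
                       n_initial = 1e4,
                       n_final = 2e8,
                       n_cultures = 18L,
                       interval_cm = c("natMX-MAT" = 2.26,
                                       "MAT-HIS3" = 9.93,
                                       "HIS3-kanMX" = 13.0),
                       interference_strength = 0,
                       meiotic_mutation_prob = 0.5,
                       co_association_enrichment = 1,
                       spectrum_probs = c(transition = 44 / 75 * 72 / 96,
                                          transversion = 31 / 75 * 72 / 96,
                                          fs_contraction = 15 / 96,
                                          fs_expansion = 5 / 96,
                                          complex = 4 / 96),
                       orf_length = 1773L) {
  stopifnot(is.finite(seed),
            mutation_rate_per_division >= 0,
            n_initial > 0, n_final > n_initial,
            n_cultures >= 1,
            all(interval_cm >= 0),
            interference_strength >= 0,
            meiotic_mutation_prob >= 0, meiotic_mutation_prob <= 1,
            co_association_enrichment >= 1,
            all(spectrum_probs >= 0),
            orf_length >= 1)
  if (abs(sum(spectrum_probs) - 1) > 1e-8) {
    stop("spectrum_probs must sum to 1")
  }
  need <- c("transition", "transversion", "fs_contraction", "fs_expansion",
            "complex")
  if (!all(need %in% names(spectrum_probs))) {
    stop("spectrum_probs must name the classes: ", paste(need, collapse = ", "))
  }
  structure(list(seed = as.integer(seed),
                 mutation_rate_per_division = mutation_rate_per_division,
                 n_initial = n_initial,
                 n_final = n_final,
                 n_cultures = as.integer(n_cultures),
                 interval_cm = interval_cm,
                 interference_strength = interference_strength,
                 meiotic_mutation_prob = meiotic_mutation_prob,
                 co_association_enrichment = co_association_enrichment,
                 spectrum_probs = spectrum_probs,
                 orf_length = as.integer(orf_length)),
            class = "sim_config")
}

#' Simulate a Luria-Delbruck fluctuation experiment
#'
#' Each culture grows from `n_initial` to `n_final` cells; mutations arise
#' at `mutation_rate_per_division` per cell born, so the expected number of
#' mutation events per culture is `m = rate x (n_final - n_initial)`.  Two
#' growth models are available:
#'
#' \describe{
#'   \item{`"exponential"` (default)}{Continuous exponential growth: the
#'     number of mutation events is Poisson(m) and each event's final clone
#'     size is drawn from the Luria-Delbruck clone-size law
#'     \eqn{P(K \ge k) = 1/k} (sampled as `floor(1/U)`, truncated at the
#'     attainable clone size `n_final / n_initial`).  This is the process
#'     the MSS likelihood describes, so parameter recovery is unbiased.}
#'   \item{`"synchronous"`}{Deterministic doublings: `G =
#'     ceiling(log2(n_final / n_initial))` generations with Poisson(rate x
#'     cells born) new mutants per generation, each mutant lineage doubling
#'     thereafter.  Cheap and structurally transparent, but clone sizes are
#'     quantized to powers of 2, which biases MSS-MLE recovery downward by
#'     several percent at large m (about -10% at m = 10); retained for
#'     sensitivity analysis, not for estimator validation.}
#' }
#'
#' Both models produce the over-dispersed (jackpot) mutant-count
#' distribution that motivates fluctuation analysis.  A warning is issued
#' when the per-lineage mutation probability `rate x log2(n_final /
#' n_initial)` exceeds 0.1, where the rare-mutation assumptions of the
#' Luria-Delbruck model are strained.
#'
#' @param config A [sim_config()]; uses `seed`,
#'   `mutation_rate_per_division`, `n_initial`, `n_final`, `n_cultures`.
#' @param n_cultures Optional override of `config$n_cultures`.
#' @param growth_model `"exponential"` or `"synchronous"`, see Details.
#' @return A [fluctuation_experiment()].
#' @examples
#' fx <- simulate_fluctuation(sim_config(seed = 7, n_cultures = 12))
#' mss_mle(fx)
#' @export
simulate_fluctuation <- function(config, n_cultures = config$n_cultures,
                                 growth_model = c("exponential", "synchronous")) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  growth_model <- match.arg(growth_model)
  set.seed(config$seed)
  rate <- config$mutation_rate_per_division
  g_real <- log2(config$n_final / config$n_initial)
  if (rate * g_real > 0.1) {
    warning("per-lineage mutation probability exceeds 0.1: Luria-Delbruck assumptions strained")
  }
  if (growth_model == "exponential") {
    m <- rate * (config$n_final - config$n_initial)
    k_max <- config$n_final / config$n_initial
    counts <- vapply(seq_len(n_cultures), function(i) {
      k <- stats::rpois(1L, m)
      if (k == 0L) return(0)
      sum(pmin(floor(1 / stats::runif(k)), k_max))
    }, numeric(1))
  } else {
    g <- max(1L, ceiling(g_real))
    n0 <- config$n_final / 2^g
    births <- n0 * 2^(seq_len(g) - 1L)      # cells born at generation t
    lineage <- 2^(g - seq_len(g))           # final clone size of a gen-t mutant
    counts <- vapply(seq_len(n_cultures), function(i) {
      sum(stats::rpois(g, rate * births) * lineage)
    }, numeric(1))
  }
  counts <- pmin(counts, config$n_final)
  fluctuation_experiment(counts, rep(config$n_final, n_cultures),
                         label = sprintf("simulated (rate=%.3g)", rate))
}

# lambda: expected crossovers per bivalent so that Perkins recovers the
# target map distance (cM = 50 * lambda under no chromatid interference).
cm_to_bivalent_lambda <- function(cm) cm / 50

#' Simulate tetrads under a no-interference crossover model
#'
#' For each meiosis and each marker interval, the number of crossovers on
#' the four-chromatid bundle is Poisson with mean `cM / 50` (so that the
#' Perkins estimate recovers the target distance); each crossover joins one
#' randomly chosen chromatid from each homolog (no chromatid interference)
#' and exchanges their distal segments.  The four resulting chromatids are
#' emitted as spores with parental haplotypes `"P1"`/`"P2"` at every
#' marker.
#'
#' @param config A [sim_config()]; uses `seed` and `interval_cm`.
#' @param n_tetrads Number of meioses to simulate.
#' @return List of [tetrad()] objects.
#' @examples
#' tt <- simulate_tetrads(sim_config(seed = 3, interval_cm = c(AB = 5)), 50)
#' tally_tetrads(tt, c(1, 2))
#' @export
simulate_tetrads <- function(config, n_tetrads) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  set.seed(config$seed)
  cm <- config$interval_cm
  if (any(cm > 50)) {
    warning("interval map distance above 50 cM: Perkins formula saturates")
  }
  k <- length(cm) + 1L  # number of markers
  markers <- if (is.null(names(cm))) paste0("m", seq_len(k)) else {
    unique(unlist(strsplit(names(cm), "-", fixed = TRUE)))
  }
  if (length(markers) != k) markers <- paste0("m", seq_len(k))
  lambda <- cm_to_bivalent_lambda(cm)
  lapply(seq_len(n_tetrads), function(i) {
    # origin[c, j]: which homolog chromatid c carries at marker j
    origin <- matrix(rep(c("P1", "P1", "P2", "P2"), k), nrow = 4L)
    for (j in seq_len(k - 1L)) {
      n_co <- stats::rpois(1L, lambda[j])
      for (co in seq_len(n_co)) {
        a <- sample(1:2, 1L)   # chromatid from homolog 1
        b <- sample(3:4, 1L)   # chromatid from homolog 2
        tail_idx <- (j + 1L):k
        tmp <- origin[a, tail_idx]
        origin[a, tail_idx] <- origin[b, tail_idx]
        origin[b, tail_idx] <- tmp
      }
    }
    colnames(origin) <- markers
    tetrad(origin, parent1 = rep("P1", k), parent2 = rep("P2", k),
           markers = markers, id = sprintf("tetrad%05d", i))
  })
}

# Bernoulli exchange matrix for n spores given per-interval probabilities,
# with pragmatic interference thinning: whenever two adjacent intervals are
# both exchanged, with probability 1 - exp(-strength) one of the two
# exchanges (chosen at random) is removed.
draw_exchanges <- function(n, p, strength) {
  k <- length(p)
  ex <- matrix(stats::runif(n * k) < rep(p, each = n), nrow = n)
  if (strength > 0 && k >= 2L) {
    thin_p <- 1 - exp(-strength)
    for (j in seq_len(k - 1L)) {
      both <- which(ex[, j] & ex[, j + 1L])
      if (length(both)) {
        thin <- both[stats::runif(length(both)) < thin_p]
        drop_first <- stats::runif(length(thin)) < 0.5
        ex[thin[drop_first], j] <- FALSE
        ex[thin[!drop_first], j + 1L] <- FALSE
      }
    }
  }
  ex
}

#' Simulate random spores with optional mutation-crossover association
#'
#' Each spore is drawn from an independent meiosis.  With probability
#' `meiotic_mutation_prob` the spore carries a reporter mutation (is
#' canavanine resistant); in mutant spores every per-interval crossover
#' probability is multiplied by `co_association_enrichment` (capped at 1,
#' with a message when the cap binds).  Baseline per-interval exchange
#' probabilities are `cM / 100` (the recombinant-spore fraction).
#' Interference is a pragmatic thinning of adjacent double crossovers with
#' probability `1 - exp(-interference_strength)`.
#'
#' @param config A [sim_config()]; uses `seed`, `interval_cm`,
#'   `meiotic_mutation_prob`, `co_association_enrichment`,
#'   `interference_strength`.
#' @param n_spores Number of spores.
#' @return Data frame of class `spore_records`: `spore_id`, `canavanine`
#'   (`"resistant"`/`"sensitive"`), and one `"P1"`/`"P2"` call column per
#'   marker.
#' @export
simulate_random_spores <- function(config, n_spores) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  set.seed(config$seed)
  cm <- config$interval_cm
  k <- length(cm) + 1L
  markers <- if (is.null(names(cm))) paste0("m", seq_len(k)) else {
    mk <- unique(unlist(strsplit(names(cm), "-", fixed = TRUE)))
    if (length(mk) == k) mk else paste0("m", seq_len(k))
  }
  p0 <- cm / 100
  p1 <- p0 * config$co_association_enrichment
  if (any(p1 > 1)) {
    message("enriched crossover probabilities capped at 1")
    p1 <- pmin(p1, 1)
  }
  mutant <- stats::runif(n_spores) < config$meiotic_mutation_prob
  ex <- matrix(FALSE, n_spores, k - 1L)
  if (any(!mutant)) {
    ex[!mutant, ] <- draw_exchanges(sum(!mutant), p0, config$interference_strength)
  }
  if (any(mutant)) {
    ex[mutant, ] <- draw_exchanges(sum(mutant), p1, config$interference_strength)
  }
  # parental origin: random starting homolog, switching at each exchange
  start <- sample(c(0L, 1L), n_spores, replace = TRUE)
  cum <- cbind(0L, t(apply(ex, 1L, cumsum)))
  calls <- matrix(ifelse((start + cum) %% 2L == 0L, "P1", "P2"),
                  nrow = n_spores)
  colnames(calls) <- markers
  out <- data.frame(spore_id = sprintf("spore%06d", seq_len(n_spores)),
                    canavanine = ifelse(mutant, "resistant", "sensitive"),
                    calls, stringsAsFactors = FALSE)
  class(out) <- c("spore_records", "data.frame")
  attr(out, "markers") <- markers
  out
}

TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSION_PARTNER_1 <- c(A = "C", G = "C", C = "A", T = "A")
TRANSVERSION_PARTNER_2 <- c(A = "T", G = "T", C = "G", T = "G")

# Vectorized ref/alt generation for a vector of per-record classes.
draw_changes <- function(classes) {
  n <- length(classes)
  base <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  ref <- base
  alt <- character(n)
  i <- classes == "transition"
  alt[i] <- TRANSITION_PARTNER[base[i]]
  i <- classes == "transversion"
  alt[i] <- ifelse(stats::runif(sum(i)) < 0.5,
                   TRANSVERSION_PARTNER_1[base[i]],
                   TRANSVERSION_PARTNER_2[base[i]])
  i <- classes == "fs_contraction"
  ref[i] <- paste0(base[i], base[i]); alt[i] <- base[i]
  i <- classes == "fs_expansion"
  alt[i] <- paste0(base[i], base[i])
  list(ref = ref, alt = alt)
}

#' Simulate sequenced mutation records with a configurable spectrum
#'
#' Draws one mutation class per isolate from `spectrum_probs`; positions
#' are uniform over the reporter ORF.  Transitions/transversions emit a
#' single-base substitution, frameshift contractions/expansions a 1-bp
#' deletion/insertion written against a homopolymer anchor, and complex
#' isolates two independent substitutions at distinct positions (so the
#' isolate is classified complex by [summarize_spectrum()]).
#'
#' @param config A [sim_config()]; uses `seed`, `spectrum_probs`,
#'   `orf_length`.
#' @param n_isolates Number of isolates.
#' @param phase Phase label for the records (`"meiosis"` default).
#' @return A [mutation_records()] table.
#' @export
simulate_mutations <- function(config, n_isolates, phase = "meiosis") {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  set.seed(config$seed)
  probs <- config$spectrum_probs
  classes <- sample(names(probs), n_isolates, replace = TRUE, prob = probs)
  iso <- sprintf("iso%05d", seq_len(n_isolates))
  # complex isolates carry two independent substitutions, all others one record
  n_rec <- ifelse(classes == "complex", 2L, 1L)
  id <- rep(iso, n_rec)
  rec_class <- rep(classes, n_rec)
  is_cx <- rec_class == "complex"
  rec_class[is_cx] <- sample(c("transition", "transversion"), sum(is_cx),
                             replace = TRUE)
  ch <- draw_changes(rec_class)
  pos <- sample.int(config$orf_length, length(id), replace = TRUE)
  # the two changes of a complex isolate must sit at distinct positions
  dup <- c(FALSE, id[-1L] == id[-length(id)] & pos[-1L] == pos[-length(id)])
  pos[dup] <- pos[dup] %% config$orf_length + 1L
  mutation_records(id, rep(phase, length(id)), pos, ch$ref, ch$alt)
}
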