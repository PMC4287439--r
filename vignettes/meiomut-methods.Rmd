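---
title: "Models and methods behind meiomut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind meiomut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiomut)
```

## The scientific problem

During meiosis, budding yeast introduces roughly 160 programmed
double-strand breaks per cell (via Spo11) to initiate recombination.
Because DNA synthesis during break repair is far less accurate than
S-phase replication, the single meiotic division is itself mutagenic: the
"meiotic effect", a 6–21-fold elevation of the forward mutation rate at a
`CAN1 HIS3` reporter, correlated with the local recombination rate
(coldspot versus hotspot).  Quantifying the effect requires four
statistical machines, each of which this package implements and validates
against synthetic data with known ground truth:

1. a **fluctuation-test estimator** for the mitotic (per-division) rate,
2. a **single-division meiotic rate** from matched pre-/post-sporulation
   mutant frequencies,
3. **tetrad and random-spore recombination analysis**, including
   crossover-interference statistics, and
4. a **mutation-spectrum classifier**.

## Mitotic rate: MSS maximum likelihood

A fluctuation test grows `C` parallel cultures from small inocula and
counts mutant colonies in each.  Because a mutation arising early produces
a "jackpot" of descendants, the mutant count `r` is wildly over-dispersed,
and the mean frequency is a poor estimator.  Under the Luria–Delbrück
model the number of mutation *events* per culture is Poisson with mean
`m`, and the count distribution follows the Ma–Sandri–Sarkar recursion

$$p_0 = e^{-m}, \qquad
  p_r = \frac{m}{r}\sum_{i=0}^{r-1}\frac{p_i}{r-i+1}.$$

`mss_mle()` maximizes $\sum_c \log p_{r_c}(m)$ over $\ln m$ with a bounded
derivative-free search (tolerance $10^{-6}$ on $\ln m$), so the estimate
is deterministic.  Numerical choices that matter:

* **Jackpot censoring.** The recursion costs $O(r^2)$, so counts above
  `r_cap` (default 512) enter the likelihood as right-censored
  observations through $P(R > r_{cap})$.  This is a proper likelihood —
  no data are discarded and no bias is introduced — and it bounds the
  cost of extreme jackpots.
* **Boundary at zero.** When every culture has zero mutants the
  likelihood is maximized at `m = 0`, which is returned exactly.
* **Heavy tails.** The distribution's tail mass is $\Theta(m/R)$ (each
  mutation's clone-size law is $P(K \ge k) = 1/k$), so partial sums of
  `mss_probabilities()` approach 1 only at rate $O(1/R)$.  Tests assert
  this analytically correct behavior.

Confidence limits use Foster's approximation, symmetric on the log scale:
$\sigma_{\ln\hat m} \approx 1.225\,\hat m^{-0.315}/\sqrt{C}$, with
$CI_{95} = \exp(\ln\hat m \pm 1.96\sigma)$.  The conversion to a
per-division rate divides by the mean final viable population
(`divisor = "final"`); the $N_t\ln 2$ variant is available because the
divisor convention differs between laboratories.  A warning is emitted
when per-culture populations are heterogeneous (CV > 0.5), since a single
mean divisor then blurs real differences.

## Meiotic rate: per-culture subtraction

Mutants present before sporulation would otherwise be counted as meiotic;
the estimator therefore subtracts, culture by culture, the mitotic mutant
frequency from the post-sporulation spore frequency, and takes the
**median** of the differences.  Meiosis is a single division, so this
median frequency difference is directly a rate per meiosis.  Negative
per-culture differences are retained — the median is robust to them,
while flooring at zero would bias the estimate upward — but a warning
fires when more than a quarter of differences are negative.  Group
comparisons use Welch's two-sided t test by default (`var_equal = TRUE`
restores the pooled-variance variant); the choice is configurable because
the original analyses specify only "a Student's t test".

## Tetrad analysis

For a pair of linked markers each four-spore tetrad is a parental ditype
(PD), non-parental ditype (NPD, requiring a four-strand double crossover)
or tetratype (TT).  Distances use the Perkins formula
$cM = 50(T + 6N)/(P + N + T)$, with the multinomial standard error
$SE = \frac{100}{2n}\sqrt{T + 36N - (T+6N)^2/n}$ and percent
recombination $100(T + 2N)/n$ (the fraction of recombinant spores: 2 of 4
in a TT, 4 of 4 in an NPD).  The last two formulas are not stated in the
source analyses; they were derived to reproduce the published cells and
are documented as such.  With $N = 0$, percent recombination is exactly
twice the map distance — a useful internal consistency check.

Markers failing 2:2 segregation indicate gene conversion; those tetrads
are flagged and excluded from PD/NPD/TT tallies (counted separately), so
published-style totals reflect only classified tetrads.  Strain
comparisons use an uncorrected Pearson chi-square on the 2×3 class table,
pooling NPD into TT when an expected count falls below 5 and dropping
classes absent from both strains.  Physical interval lengths (`kb`) count
only sequence with homology between the parents, since heterologous
insertions cannot recombine.

## Random spores and interference

When mutants are too rare for tetrad dissection, individual spores are
genotyped at ordered markers.  An interval is called *exchanged* when the
parental-origin calls on its two sides differ; a spore with no exchange
is a non-crossover.  A fundamental ambiguity is inherited from the assay:
a gene conversion of an internal marker is indistinguishable from a
double crossover, so every multi-exchange spore carries an
`ambiguous_gc` flag rather than a resolved call.

The expected percentage of simultaneous exchanges in a set of intervals
(under independence) is the product of the marginal exchange fractions —
marginals that by default include multi-exchange spores, matching the
convention of counting doubles in each interval's total.  The
**interference ratio** observed/expected is below 1 under positive
crossover interference and near or above 1 when interference is lost (as
reported for mutant Can-resistant spores).  Mutant/non-mutant group
comparisons report per-interval fraction ratios with uncorrected
chi-square tests on the exchanged/not-exchanged counts.

## Mutation spectra

Single-base changes split into transitions (A↔G, C↔T) and transversions;
length changes not divisible by 3 are frameshifts (contraction on net
loss, expansion on net gain).  Two conventions required decisions:

* **Complex events** are defined at the *isolate* level: an isolate
  carrying two or more distinct changes counts once, as complex.  This
  matches isolate-count denominators (e.g. 80 or 96 sequenced isolates)
  in published summaries, where "complex" is otherwise undefined.
* **In-frame indels** get their own class rather than being forced into
  the three summary classes (none occur in the published totals, but a
  classifier must place them somewhere explicit).

Positional analysis bins positions into half-open 200-bp windows
$[1,201), [201,401), \ldots$ from the ORF start codon (the indel position
is its first changed base) and tests between-group homogeneity by
chi-square, greedily merging adjacent windows while any expected count is
below 5.

Of note: an uncorrected 2×2 chi-square on the published frameshift counts
(8/80 vs 20/96) gives a statistic of 3.83 ($p \approx 0.050$), not the
quoted $p = 0.02$; the original test construction is unstated, so the
tests here assert the statistic, not the quoted p-value.

## The synthetic-data generator

Every estimator is validated by simulate-then-recover tests.  What the
generator emulates, and what it deliberately does not:

* **Fluctuation cultures.** The default growth model is continuous
  exponential growth: Poisson(m) mutation events per culture, each with a
  clone size drawn from the Luria–Delbrück law $P(K \ge k) = 1/k$
  (truncated at the attainable `n_final / n_initial`).  This is exactly
  the process the MSS likelihood describes, and the MLE recovers
  $m \in \{0.5, 2, 10\}$ within 0.4% at $C = 5000$.  A synchronous
  deterministic-doubling model is retained as an option; it is cheap and
  transparent but quantizes clone sizes to powers of 2, which biases the
  MLE downward (about −2% at m = 0.5, −4% at m = 2, −10% at m = 10).  It
  is therefore *not* used for estimator validation — a worked example of
  why generator artifacts must be separated from estimator defects.
* **Tetrads.** Crossovers per interval on the four-chromatid bundle are
  Poisson with mean $cM/50$; each crossover joins one random chromatid
  from each homolog (no chromatid interference) and swaps distal
  segments.  Perkins distances are recovered within binomial error
  (5 ± 1 cM at 1000 tetrads).
* **Random spores.** Per-interval exchange probabilities are $cM/100$;
  spores are mutant with probability `meiotic_mutation_prob`, and mutant
  spores have all probabilities multiplied by
  `co_association_enrichment` (capped at 1).  The default mutation
  probability is 0.5 — *not* the in vivo mutant frequency (~5×10⁻⁷) —
  because it mirrors the selected sampling design: mutant and non-mutant
  spores are plated to comparable depth by selection, so group sizes are
  set by the experimenter.  Interference is a pragmatic thinning: an
  adjacent double crossover is reduced to a single with probability
  $1 - e^{-s}$ for strength $s$; this moves obs/exp below 1 controllably
  but is not a gamma/counting-process interference model.
* **Mutation lists.** Classes are drawn from configurable probabilities
  (defaulting to the published meiotic spectrum: 21% frameshift at 3:1
  contraction:expansion, 75% substitution at 44:31
  transition:transversion, 4% complex) with positions uniform over a
  1773-bp ORF.  Real spectra have context effects (homopolymer runs,
  hotspot motifs) that the generator does not model.

A green recovery test therefore establishes that the estimators are
correct *for data satisfying their own assumptions*; it does not
establish that real cultures grow exponentially without mutant fitness
effects, that chromatid choice is uniform, or that conversions and double
crossovers can be separated.

Determinism: each generator reseeds from `config$seed`, so identical
configurations give byte-identical outputs.

## Known limitations

* Published absolute rates and their confidence intervals cannot be
  reproduced without the raw per-culture counts, which were never
  deposited; parameter-recovery tests on synthetic data stand in.
* No corrections for partial plating, plating efficiency < 1, or mutant
  fitness differences (Lea–Coulson/Drake variants are out of scope).
* Spore-viability and unsporulated-cell carryover corrections are
  assumed to have been handled at the bench.
* Phase (which parent carries which allele) must be supplied; it is
  never inferred from the data.

## A worked example

```{r example}
cfg <- sim_config(seed = 42, mutation_rate_per_division = 5.7e-8,
                  n_cultures = 18)
fx <- simulate_fluctuation(cfg)
estimate_mutation_rate(fx)

cnt <- tetrad_counts(140, 1, 144, kb = 22.5, interval = "MAT-kanMX")
summarize_tetrads(list(cnt))
```
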