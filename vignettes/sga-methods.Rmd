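---
title: "Scoring genetic interactions from high-density colony screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring genetic interactions from high-density colony screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgarray)
```

# The measurement model

A synthetic genetic array (SGA) screen arrays a collection of deletion
strains — here, a wild type (WT), single deletions of a gene panel, and
all constructible pairwise double deletions — as colonies on agar plates
at 384 (16 × 24) or 1,536 (32 × 48) density, grows them to endpoint
under each condition, and quantifies each colony's integrated density
(summed pixel intensity) as a biomass proxy. `sgarray` starts from these
density grids; image acquisition and segmentation are out of scope.

Two systematic artifacts separate raw densities from fitness:

* **Edge effect.** Border colonies face less competition for nutrients
  and grow systematically larger. We index plate positions by their
  *ring*: `ring = min(row-1, col-1, rows-row, cols-col)`, 0 being the
  border. The correction rescales each ring `r <= max_ring` by
  `median(interior) / median(ring r)` (defaults: rings 0 and 1). Median
  ratios are robust to the minority of genuinely sick or jackpot
  colonies on a ring, and the correction is idempotent on clean input.
  Setting `max_ring = -1` disables it.
* **Plate-scale differences.** Conditions and plates differ in overall
  signal. Each colony is divided by the interquartile mean (IQM) of the
  other colonies on its plate: the mean of values lying within
  [Q1, Q3], quartiles by linear interpolation on the sorted sample
  (the "type 7" convention — IQM membership depends on the quartile
  rule, so we fix it explicitly). By default the reference excludes
  *all* technical replicate colonies of the focal strain
  (`exclude = "strain"`), so a strain with a strong phenotype cannot
  drag its own reference; `"colony"` (leave-one-out) and `"none"` (one
  shared plate reference) are provided as dialects. The normalized
  output is invariant to any positive rescaling of a plate.

Normalized values are then expressed relative to WT: each replicate is
divided by the mean of the WT reference colonies pooled over plates of
the same condition and configuration, and per-strain summaries report
the mean, sample standard deviation (n − 1), and replicate count.
Missing colonies stay missing throughout — they are excluded from
reference sets and replicate counts, never imputed or zeroed.

# The interaction statistic

Under the multiplicative null, fitness defects combine independently:
the expected relative growth of a double mutant is the product of its
single mutants' growths, `E = g_a g_b`, with first-order propagated
uncertainty

$$\frac{\sigma(E)}{|E|} \;=\; \sqrt{\left(\frac{\sigma_a}{g_a}\right)^2 +
\left(\frac{\sigma_b}{g_b}\right)^2}.$$

The observed replicates (mean, SD, n) are compared against
(E, σ(E), n_expected) by a Welch two-sample *t* test with
Welch–Satterthwaite degrees of freedom. The propagated σ is computed
from replicate SDs, so `σ(E)/sqrt(n)` matches the standard error of the
product of the two single-mutant means when the replicate counts agree;
we attribute `n_expected = min(n_a, n_b)` to the expectation — the
conservative choice, exposed as an option — since no canonical sample
size exists for a derived quantity.

Two-sided p-values are adjusted by Benjamini–Hochberg over the **whole
record family** (all pairs × all conditions jointly), not per condition:
the screen's discovery claim is over every measurement made. Records
with q ≤ 0.05 (inclusive, one consistent threshold everywhere) are
classified *enhancing* when observed < expected and *suppressing* when
observed > expected. Untestable records — a missing single mutant,
fewer than two replicates on either side, a zero expectation — are
emitted flagged but are excluded from the BH family rather than being
assigned p = 1, which would distort the step-up thresholds.

Tallies follow screening conventions: the deviation magnitude is
`|observed/expected − 1|`, with 20% as the default "strong" cutoff and
`observed/expected < 0.4` marking severe synthetic growth defects;
per-gene counts credit a record to both of its genes.

# The synthetic-data generator

Because colony-level screen data are typically only published through
interactive browsers, the simulator is a first-class module that
emulates the screen design:

* **Fitness truth.** Per-gene single-mutant fitness per condition
  (default 1); a double mutant's true fitness is
  `f_a f_b (1 + ε)` with planted interaction ε (−1 < ε; ε = 0
  elsewhere). WT is 1 under every condition by construction. An
  exclusion list models pairs absent from the collection (empty
  positions).
* **Layouts.** Strains are placed uniformly at random, technical
  replicates kept on one plate, a fixed count of WT reference colonies
  (default 16) scattered on every plate. With two or more
  configurations, the colonies on the outermost ring of configuration 1
  are deliberately reseated on interior positions (ring ≥ 2 where
  capacity allows) in the later configurations, so edge-effect
  correction can be validated by position-swap concordance.
* **Measurement.** `value = plate_scale × edge_factor(ring) × fitness ×
  noise`, with default edge factors 1.25 (ring 0) and 1.10 (ring 1) —
  a border growth advantage of the magnitude seen on high-density
  arrays — and multiplicative lognormal noise with
  `sdlog = sqrt(log(1 + CV²))` and mean 1, because colony densities are
  positive, right-skewed, and their error scales with signal. Default
  CV 10%; CV 0 is bit-reproducible and equals the closed-form product
  model. All randomness flows from one seed.

What the simulator does **not** model: nutrient-diffusion physics and
spatially correlated competition beyond the ring bias, colony-shape and
segmentation artifacts, time-resolved colony growth (endpoint only),
batch effects between plate sets, and non-multiplicative noise such as
pinning failures (missingness is supported but unmodeled). Passing
tests on simulated screens therefore demonstrate the pipeline's
correctness under its own measurement model, not robustness to every
artifact of real plates.

# Statistical behavior under the study conditions

With 4 replicates and 10% measurement CV, the Welch test's variance
estimates carry only ~4 degrees of freedom. Simulation at scale
(20-gene panels, 4 conditions, 10% of pair–condition combinations
planted) shows the consequences:

* **FDR control holds.** The mean false-discovery proportion of
  q ≤ 0.05 calls is well below 0.05 on null screens and on screens with
  a planted-positive arm (the acceptance script measures ~0.008). BH is
  conservative here because the heavy-tailed t null is approximated
  slightly conservatively and discoveries are few.
* **Power at moderate effect sizes is limited.** A planted interaction
  of magnitude |ε| = 0.4 changes growth by 4–5 propagated standard
  errors, but with df ≈ 4 the *estimated* standard errors vary so much
  that the median p-value is only ~0.006, while the adaptive BH
  threshold in a 760-test family with 10% signals sits near 0.005.
  Measured recovery is ~4% at |ε| = 0.4, ~37% at 0.5, ~67% at 0.6.
  High recovery of subtle interactions at this replicate depth requires
  either more replicates, lower plate noise, or a larger fraction of
  true signals (which raises the step-up threshold). This is a real
  property of BH-corrected Welch testing at n = 4, and the package
  reports it rather than masking it.

# Growth kinetics

Liquid-culture curves are summarized by the maximum OD600 amplitude and
the maximum first-order growth rate: the series is smoothed by a
centered moving average (default window 5 points; window 1 differentiates
the raw curve), differentiated by centered finite differences
(one-sided at the ends), and the derivative's maximum and its time are
reported. For a logistic curve of amplitude K and rate r the true
maximum is rK/4 at the midpoint, which the noiseless estimator matches
to < 2% on densely sampled curves.

On noisy curves the achievable accuracy is bounded by a noise floor:
taking the maximum of a differenced moving average inflates the
estimate by roughly `noise_sd / (window × Δt)`. At plate-reader noise
of 0.005–0.01 OD and 15-minute sampling this floor is 0.003–0.008
OD600/h — negligible for vigorous growth but a double-digit relative
error for slow, low-amplitude curves (rK/4 ≈ 0.03 OD/h). The property
tests therefore check 5% relative accuracy *plus* this floor, and the
derivative is taken on the linear OD scale (the literal first-order
derivative); a log-scale specific growth rate would need a different
estimator. Fold changes divide each metric by the WT value per
condition; a zero WT metric yields a flagged `NA`, never infinity.
Replicate curves are maximized per curve first, then averaged.

# Network construction

Edges are the records with q ≤ 0.05 and deviation ≥ 15%, one edge per
(pair, condition); isolated genes remain as nodes. For community
detection and layout, per-condition multi-edges collapse to a weighted
simple graph (weight = number of shared interaction conditions) — genes
are clustered once even if they interact under many conditions, but the
per-condition edges are preserved in exports. Louvain (resolution 1 by
default) maximizes weighted modularity; partitions are deterministic
given a seed, community ids are contiguous from 0, and isolated nodes
form singletons (or one catch-all group, configurable). The
Fruchterman–Reingold layout is seeded and centered on the origin.
GraphML exports carry all edge and node attributes and round-trip
through `import_network()`.

# Genome-scale screen analytics

The **phenocopy filter** marks a strain impaired under a condition when
its normalized growth falls more than z SD (default 2) below that
condition's across-strain mean, and returns strains impaired under
*every* test condition but not under the permissive control — the
signature of a deletion that phenocopies a query mutant's conditional
lethality. Per-condition impaired sets are also returned for
Venn-style reporting of partial overlaps, and a trimmed mean/SD option
guards against heavy screen tails. **Suppressor ranking** orders
strains by absolute growth under a stress among candidates whose growth
under the reference condition passes a gate (default 0.5), so generally
sick strains cannot masquerade as suppressors; a stress/reference ratio
scorer is available as an alternative.

# Numerical and design choices

* Quartiles: type 7 (linear interpolation), documented because IQM
  membership depends on it.
* Sample SD uses n − 1; single-replicate strains get `sd = NA` and are
  untestable; zero-variance degenerate Welch cases return t = 0, p = 1
  for equal means.
* Zero single-mutant growth with nonzero SD has no defined relative
  error; `propagated_sigma()` refuses it, and the calling layer flags
  such records untestable instead.
* Suppressor ties break lexicographically by strain id; community ids
  renumber in first-appearance order — both for reproducibility.
* Problem sizes in the test-suite experiments — 20-gene panels
  (190 pairs), 4 conditions, 200 null screens and 100 recovery
  screens — give Monte-Carlo standard errors of ~0.002 on the FDR
  estimate and ~1.5 percentage points on recovery, adequate for the
  bounds being checked.

# Known limitations

Single-colony (n = 1) strains are excluded from testing rather than
modeled; the multiplicative rule is the only supported null
(no additive or minimum epistasis models, no S-scores); BH assumes the
usual positive-dependence conditions, which position-level correlations
on a plate could in principle violate; and the simulator's noise model
is exchangeable across positions, so the pipeline's behavior under
spatially structured artifacts beyond ring bias is untested.
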