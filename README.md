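# sgarray

Genetic-interaction analysis for synthetic genetic array (SGA) colony
screens of double-deletion strain collections, as used to map epistasis
among *E. coli* small regulatory RNAs (sRNAs) across carbon-source and
nutrient-stress conditions.

## The problem

In an SGA screen, every pairwise double deletion of a gene panel is
arrayed as colonies on high-density agar plates (384 or 1,536 colonies
per plate) under many growth conditions, and colony integrated density
is used as a proxy for fitness. A genetic interaction is a statistically
significant departure of a double mutant's growth from the
**multiplicative rule**: with growth measured relative to wild type
(WT ≡ 1), the null expectation for the double mutant *ΔaΔb* is

```
E[growth(ΔaΔb)] = growth(Δa) × growth(Δb)
```

with the uncertainty of that expectation obtained by propagation of
errors for a product,

```
σ(E) / |E| = sqrt( (σ_a / g_a)² + (σ_b / g_b)² ).
```

Each observed double-mutant growth (mean of 3–4 replicates) is compared
with its expectation by a Welch *t* test (Welch–Satterthwaite degrees of
freedom), p-values are corrected across the whole screen by the
Benjamini–Hochberg step-up procedure, and records with q ≤ 0.05 are
classified **enhancing** (observed < expected; an aggravated growth
defect) or **suppressing** (observed > expected; alleviated growth).

Upstream of the statistics, raw colony densities need two corrections:
colonies on the plate border systematically out-grow interior colonies
(the *edge effect*; corrected per ring by median rescaling), and each
colony is normalized to the interquartile mean (IQM) of the remaining
strains on its plate. Downstream, significant interactions are tallied
(per gene, per condition, deviation histograms) and assembled into a
network whose per-condition edges connect interacting genes, with Louvain
communities and a Fruchterman–Reingold layout.

Because raw screen data of this kind are rarely deposited in a reusable
form, the package includes a first-class simulator that generates colony
arrays with known ground truth — planted single-mutant fitness, planted
interactions, edge-growth bias, and multiplicative lognormal measurement
noise — so every stage of the pipeline is testable end to end. A
growth-kinetics module (maximum OD600 amplitude, maximum first-order
growth rate, fold change vs WT) and genome-scale screen analytics (a
2-SD phenocopy filter with a permissive-condition veto, and suppressor
ranking under stress) round out the toolkit.

## Worked example

Simulate a small two-condition screen of 8 sRNA genes with one planted
strong enhancing interaction (arcZ–csrC on pyruvate, ε = −0.6), then run
the full pipeline:

```r
library(sgarray)

genes   <- c("arcZ", "csrC", "dsrA", "gcvB", "micL", "rprA", "sgrS", "spot42")
planted <- tibble::tibble(gene_a = "arcZ", gene_b = "csrC",
                          condition = "pyruvate", epsilon = -0.6)

cfg     <- sim_config(genes, conditions = c("glucose", "pyruvate"),
                      interactions = planted, noise_cv = 0.05, seed = 101)
strains <- make_strains(genes)
layouts <- make_layouts(strains, plate_format(384),
                        n_replicate_colonies = 4, n_configurations = 2,
                        wt_colonies = 16, seed = 101)
screen  <- simulate_screen(cfg, layouts)

calls <- screen$colonies |>
  normalize_screen(max_ring = 1) |>        # edge correction + IQM scaling
  summarize_growth(wt_id = "WT") |>        # growth relative to WT
  call_interactions(screen$strains)        # multiplicative rule + Welch/BH
calls
#> <sga_interactions> 56 records (56 testable); 1 significant at q <= 0.05 (1 enhancing, 0 suppressing)

tidy(calls) |>
  dplyr::filter(class != "none") |>
  dplyr::select(gene_a, gene_b, condition, observed, expected, q_value, class)
#> # A tibble: 1 × 7
#>   gene_a gene_b condition observed expected       q_value class
#>   <chr>  <chr>  <chr>        <dbl>    <dbl>         <dbl> <chr>
#> 1 arcZ   csrC   pyruvate     0.394     1.02 0.00000000405 enhancing

tally_interactions(calls)
#> <sga_tally> 56 measurements; 1 significant (1.79%)
#>   enhancing:  1 (100.0% of significant)
#>   suppressing: 0 (0.0% of significant)
#>   strong (>20% deviation): 1 (1 enhancing, 0 suppressing)
#>   severe (observed/expected < 0.4): 1
#>   per-gene interactions: mean 1, median 1
```

The 56 records are the 28 gene pairs × 2 conditions. The planted pair is
recovered with observed growth 0.394 against a multiplicative expectation
of 1.02 — a deviation ratio of 0.39, i.e. a severe synthetic growth
defect — and nothing else is called. The interaction network is built
from the classified records:

```r
net <- build_network(calls, min_deviation = 0.15) |>
  detect_communities(seed = 1) |>
  layout_network(seed = 1)
autoplot(net)                        # force-directed map, edges by class
export_network(net, "net.graphml")   # or "tsv"
```

`run_pipeline()` wires all stages together from a YAML config with one
master seed (see `inst/scripts/sga-pipeline.R` for a shell entry point),
and `simulate_growth_curve()` / `summarize_kinetics()` /
`fold_change_table()` cover liquid-culture growth curves.

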