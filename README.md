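# dietswitch

Analysis of acute diet-switch experiments in *Drosophila*: which genes
track the rapid drop in mortality that follows a shift from full to
restricted food?

Dietary restriction (DR) lowers age-specific mortality within a few days
of the diet change, while chronic DR alters hundreds to thousands of
transcripts. The experimental design this package implements separates
the two: three cohorts — **CF** (control food), **RF** (restricted food)
and **SF** (switched CF→RF at day 40) — are expression-profiled at twelve
post-switch time points (2–72 h) while daily deaths are recorded for all
three. Genes whose SF expression *leaves the CF level and reaches the RF
level inside the mortality-switch window* are the candidate mediators.

The package is written for researchers analysing such three-cohort
time-course designs, and ships a fully synthetic replica of the study so
every stage is testable without any download.

## What it computes

**Demography.** Daily life tables with sampling censoring; instantaneous
hazard `ĥ(d) = −ln(1 − D/N)` over a centered window; log-rank tests
(via the survival package); maximum lifespan as the mean death day of the
longest-surviving 10%; and two detectors — the first day with a sustained
`≥ fold` hazard ratio between CF and RF, and the post-switch lag until the
SF hazard joins the RF trajectory.

**Differential expression.** For each gene, two-sided paired *t*-tests
across time-matched points for RF vs CF, SF vs CF and SF vs RF
(replicates averaged within cohort × time), then one Benjamini–Hochberg
correction over the pooled p-values of all genes × all three comparisons.

**Categories.** With `S(c)` = significance of comparison `c` at the FDR
cutoff and `D = S(RF vs CF)`:
I (switching) `D ∧ S(SFvCF) ∧ ¬S(SFvRF)`; II (refractory)
`D ∧ ¬S(SFvCF) ∧ S(SFvRF)`; III (responsive) `D ∧ S(SFvCF) ∧ S(SFvRF)`;
IV (deviating) `¬D ∧ S(SFvCF)`; V nothing significant; VI–VIII
indeterminate classes resolved by the SF late-time position on the CF→RF
gap. Switch-completion times (90% of the gap, sustained) curate the fast
switchers.

**Enrichment & concordance.** Upper-tail hypergeometric
over-representation of up/down gene lists against GMT gene sets with BH
per family, and cross-study direction-concordance summaries (shared genes,
same/opposite percentages, up/down ratios, category cross-tabs).

**Simulators.** `simulate_expression()` plants seven gene archetypes
(null, up/down switching, refractory, responsive, deviating, slow-switch)
with known truth; `simulate_cohorts()` draws Gompertz cohorts
(`h(t) = a·e^{bt}`, restricted-food hazard multiplied by
`dr_hazard_fold`) with the SF hazard converging onto RF over a set lag.

## Worked example

```r
library(dietswitch)

# 500 genes, default archetype mix, 12 time points x 3 replicates x 3 cohorts
sim    <- simulate_expression(expr_sim_config(n_genes = 500, seed = 7))
comp   <- run_comparisons(sim$expr)                    # pooled BH over 1500 tests
assign <- assign_categories(comp, fdr = 0.05,
                            stats = gene_level_stats(sim$expr))
category_counts(assign)
#>   category   n n_up n_down
#> 1        I 101   51     50
#> 2       II  73   28     45
#> 3      III 102   54     48
#> 4       IV  32   15     17
#> 5        V 185    0      0
#> 6       VI   0    0      0
#> 7      VII   2    0      0
#> 8     VIII   5    0      0

fast <- curate_fast_switchers(assign, switch_times(sim$expr), cutoff_h = 8)
lengths(fast)
#> 12 up, 7 down

ev <- simulate_cohorts(cohort_sim_config(seed = 7))$events
hz <- lapply(split(ev, ev$cohort),
             function(e) hazard(build_life_table(e), window = 3))
detect_separation(hz$CF, hz$RF, fold = 1.5, k = 3)          # day 3
detect_convergence(hz$SF, hz$RF, switch_day = 40,
                   tol = 0.25, k = 2)                       # 3 days
round(max_lifespan(ev[ev$cohort == "RF", ]), 1)             # 70.5 days
```

Reading: Category I recovers the 100 planted switching genes (plus one
false positive), split evenly by direction; the halved RF hazard is detectable from day 3
(the simulator applies it from day 1); the switched cohort's hazard joins
the RF trajectory 3 days after the switch, its planted convergence lag;
and restricted food extends maximum lifespan (70.5 vs 62.9 days for CF).

## The analysis workflow

`analysis/` holds the numbered drivers that reproduce the full study on
synthetic data, each a thin narrative over the package functions:

```sh
Rscript analysis/01_simulate.R                 # expression + survival cohorts
Rscript analysis/02_demography.R               # hazards, log-rank, detectors
Rscript analysis/03_differential_expression.R  # paired tests, pooled FDR
Rscript analysis/04_categorize.R               # categories, fast switchers
Rscript analysis/05_enrichment.R               # planted-set GMT demonstration
Rscript analysis/06_concordance.R              # DR-vs-starvation arithmetic
```

Tables land under `results/`; large intermediates (`results/data/`) are
regenerated by `01_simulate.R`. `run_pipeline(run_config(...))` runs the
same stages programmatically (or from a YAML config via
`read_run_config()`), writing a JSON + text report.

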