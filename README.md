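# unresscreen

Detection of unexpectedly resistant (UNRES) cell lines in cell-line
pharmacogenomic screens, and prioritization of the resistance mechanisms
behind them.

## What problem this solves, and for whom

Preclinical screens (GDSC/CTRP-style) pair natural-log IC50 drug responses
with binary cancer-functional-event (CFE) matrices — mutations, recurrent
copy-number segments, methylation states — across hundreds of cancer cell
lines. Covariate-adjusted ANOVA finds CFEs that mark *sensitive*
subpopulations within a cancer type. The clinically interesting exceptions
are cell lines that carry the sensitivity biomarker yet sit among the
non-responders: secondary-resistance candidates of the EGFR-T790M kind.
This package is for computational biologists who want to mine such screens
for resistance biomarkers with explicit, reproducible error control.

## The statistics at its core

* **Association discovery** — per (tissue, drug, CFE): OLS ANOVA
  `lnIC50 ~ msi + medium + growth + cfe` (partial type-II F-test for the
  CFE term) and signed Cohen's
  *d* = (X̄₁ − X̄₂)/s_pooled; retained when p < 0.001 and d < −1, with ≥ 4
  mutant lines and ≤ 50% extrapolated mutant IC50s.
* **UNRES detection** — for the n altered lines, Δσᵢ = σᵢ − σ₀, the change
  in sample SD when the i = 1..min(⌊n/2⌋, 5) highest IC50s are removed;
  significance from B = 10,000 bootstrap resamples of n values from the
  whole within-tissue pool, p = (1 + #{Δσ_boot ≤ Δσ_obs})/(B+1); magnitude
  as the normalized SD decrease −(Δσᵢ − E)/(σ₀ − E), E = null median.
* **Hierarchical FDR** — children (UNRES tests) are BH-adjusted at α = 0.15
  only under significant parents; overall bound
  FDR ≤ ((D + F)/(D + 1))·α·δ, δ = 1. A within-tissue permutation study
  (100×) estimates false-positive counts empirically.
* **Resistance biomarkers** — unique second mutations in the biomarker
  gene, mutually exclusive CFEs (both directions), and Fisher-exact
  enrichment for multi-line cases, filtered against a cancer gene list.
* **Differential essentiality** — on CRISPR gene-effect matrices,
  Δess_g = mean over k comparisons of z-scored per-comparison differences;
  |Δess| > 4 highlights, wt-like classification versus biomarker-wild-type
  lines.

A synthetic-screen generator with planted ground truth
(`sim_config()` / `generate_screen()` / `generate_essentiality()`) makes
every stage testable offline.

## Worked example

```r
library(unresscreen)

cfg <- sim_config(seed = 7)          # 4 tissues x 25 lines, 4 planted associations,
screen <- generate_screen(cfg)       # 1 planted UNRES line each
ana <- analyse_screen(screen$drug_response, screen$cfe, screen$annotations,
                      unres_options(B = 2000, seed = 7))

subset(ana$associations, retained, select = c(tissue, drug, cfe, n_mut, p_value, cohens_d))
#>       tissue   drug   cfe n_mut  p_value cohens_d
#> 1   TISSUE01 DRUG01 CFE01    10 2.61e-08    -3.89
#> 42  TISSUE02 DRUG01 CFE02    10 7.42e-09    -4.24
#> 83  TISSUE03 DRUG01 CFE03    10 5.17e-07    -3.13
#> 124 TISSUE04 DRUG01 CFE04    10 1.84e-11    -5.81
```

All four planted associations are recovered (p-value of the CFE term and
the signed effect size both clear the gates). UNRES detection then flags
the planted resistant line inside each sensitive subpopulation:

```r
subset(ana$unres_cases, selected,
       select = c(tissue, drug, cfe, i, removed_cells, p_adjusted, normalized_sd_decrease))
#>      tissue   drug   cfe i                 removed_cells p_adjusted normalized_sd_decrease
#> 1  TISSUE01 DRUG01 CFE01 1                  TISSUE01_C11     0.0050                  0.516
#> 6  TISSUE02 DRUG01 CFE02 1                  TISSUE02_C13     0.0167                  0.462
#> 11 TISSUE03 DRUG01 CFE03 1                  TISSUE03_C16     0.0050                  0.623
#> 16 TISSUE04 DRUG01 CFE04 1                  TISSUE04_C11     0.1087                  0.254
#> ...                                          (additional i = 2, 3 cases omitted)

unlist(screen$ground_truth$unres)    # the planted truth
#> "TISSUE01_C11" "TISSUE02_C13" "TISSUE03_C16" "TISSUE04_C11"

ana$fdr_bound
#> [1] 0.3692308                      # ((D + F)/(D + 1)) * 0.15 over 20 families
```

Each `removed_cells[1]` is exactly the planted UNRES line; the adjusted
p-values come from the pooled BH pass over all child hypotheses of the
significant parents, and the normalized SD decrease ranks the strength of
each case (> 0.5 is conventionally labeled strong).

## Command line

```sh
Rscript inst/cli/unres-screen simulate --out bundle/ --seed 7
Rscript inst/cli/unres-screen run --config run.cfg --seed 1 --out results/
Rscript inst/cli/unres-screen permute --config run.cfg --out results/
```

`run.cfg` is plain `key = value` text (`bundle = bundle/`, `B = 2000`, any
`unres_options()` name). Exit codes: 0 success, 2 validation error, 1
runtime error. Results are stage-wise TSVs plus a JSON run manifest with
input digests, options and seed.

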