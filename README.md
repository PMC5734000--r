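# careflow

Clinical pathway mining and correlation-network profiling of care
providers, for health-services researchers working with administrative
claims data.

Chronic ischemic heart disease work-up escalates through three care
levels — non-invasive non-imaging tests (**E**: stress ECG), non-invasive
imaging (**NI**: stress echocardiography, SPECT) and invasive procedures
(**I**: coronary angiography, PCI, CABG). Guidelines prescribe E → NI → I,
but real practice varies regionally. `careflow` measures that variation
from a time-stamped per-patient event table:

1. **Episodes.** After merging redundant "phantom" claims rows, an *event
   series* starts at an index event preceded by ≥ 180 event-free days and
   ends at the next > 180-day event-free gap, death, or end of
   observation. Each series gets one of 15 labels — the hyphen-join of
   the categories in order of first appearance (e.g. `E-NI-I`, `I-E`):
   the non-empty ordered selections of distinct elements of {E, NI, I}.
2. **Centers.** Each ZIP area is assigned a dominant de facto care center
   per level by majority vote of its residents' first events of that
   level.
3. **Spectra.** Every center is profiled by its 15-component relative
   frequency vector over series types, plus average series cost (from a
   reimbursement tariff), revascularization rate (share of
   CA-containing series with PCI/CABG within 180 days) and 365-day
   mortality.
4. **Network.** Centers are correlated pairwise (Pearson, n = 15) and
   joined in a complete weighted graph with `w_ij = c_ij + 2` (no
   cutoff). Native Louvain modularity optimization

   `Q = (1/2m) Σ_ij (A_ij − k_i k_j / 2m) δ(c_i, c_j)`

   with 10 seeded random starts and 10 local-moving sweeps per level
   clusters the centers; the same procedure re-runs inside each cluster
   for a three-level hierarchy. Weighted degree and betweenness (edge
   length 1/w) rank "opinion leader" centers.
5. **Reports.** Per-cluster pathway distributions with a pooled column
   (an exact series-count-weighted mean of the cluster columns), pairwise
   percent differences `100·(a−b)/b` with two-sided Fisher exact tests,
   intra-/inter-cluster correlation averages, and a versioned JSON/CSV
   bundle.

Because national reimbursement registers are not public, the package
ships a synthetic register generator with planted regional practice
archetypes and full ground truth, so every stage is testable end to end.

## Worked example

```r
library(careflow)

cfg <- simulation_config(
  n_centers = 12, n_patients = 6000,
  archetype_spectra = separated_archetype_spectra(),  # 3 planted styles
  spectrum_noise = 60, seed = 42
)
reg <- generate_registry(cfg)
analysis <- run_pipeline(reg$events, seed = 42)

analysis
#> <careflow analysis>
#>   6000 series across 12 centers; 3 clusters, Q = 0.0501

dplyr::select(analysis$cluster_summary, cluster, n_series, E, NI, I,
              revasc_rate_pct, mort365_pct, avg_cost_huf)
#> # A tibble: 4 × 8
#>   cluster n_series     E    NI     I revasc_rate_pct mort365_pct avg_cost_huf
#>   <chr>      <dbl> <dbl> <dbl> <dbl>           <dbl>       <dbl>        <dbl>
#> 1 1           2005 30.6   1.05  1.70            3.78        1.35       98568.
#> 2 2           1912  3.03 27.4   2.77            4.11        2.25      115108.
#> 3 3           2083  1.97  2.21 26.2             3.82        3.17      206014.
#> 4 pooled      6000 11.9   9.85 10.6             3.88        2.27      141140.

analysis$correlation_summary
#> # A tibble: 6 × 5
#>   cluster_a cluster_b type  mean_correlation n_pairs
#>       <int>     <int> <chr>            <dbl>   <dbl>
#> 1         1         1 intra            0.946       6
#> 2         1         2 inter           -0.251      16
#> 3         1         3 inter           -0.243      16
#> 4         2         2 intra            0.889       6
#> 5         2         3 inter           -0.218      16
#> 6         3         3 intra            0.933       6
```

The three planted practice styles are recovered exactly (adjusted Rand
index 1.0 against the generator's truth); the E-preferring cluster is the
cheapest and the invasive cluster costs about twice as much per series,
with the highest 365-day mortality — the cost/outcome contrast the
pipeline is designed to expose. `plot_correlation_heatmap(analysis$corr,
analysis$partition)` draws the cluster-blocked red/black/green
correlation heat map; `tidy()` and `glance()` give broom-style views of
the partition; `write_report(analysis, "out/")` writes the JSON/CSV
bundle.

## Package layout

- `R/vocabulary.R` — procedure/category scheme, the 15-type canon,
  tariff and reference tables
- `R/synthetic-registry.R` — simulation config, generator, registry CSV I/O
- `R/event-pipeline.R` — phantom merging, series extraction, classification
- `R/provider-voting.R` — ZIP-level dominant-center voting, department
  aggregation
- `R/spectrum.R` — spectra, costs, revascularization, mortality, direct
  standardization
- `R/network.R`, `R/louvain.R`, `R/centrality.R` — correlation network,
  native modularity/Louvain (hierarchical), centralities and correlation
  summaries
- `R/reporting.R` — cluster tables, pairwise tests, pipeline runner,
  report bundle
- `vignettes/pathway-networks.Rmd` — methods, assumptions, design
  decisions, limitations
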