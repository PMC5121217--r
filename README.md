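# chainelongr

Analysis toolkit for anaerobic **chain-elongation bioreactors** with in-line
membrane extraction. Chain elongation converts short-chain carboxylates
(acetate, n-butyrate) plus an electron donor such as ethanol into
medium-chain carboxylates (MCCs: n-caproate C6, n-caprylate C8) via reverse
β-oxidation. Because the undissociated acids inhibit the microbiome, the
broth is recycled through a hollow-fiber membrane contactor (pertraction)
that continuously strips the hydrophobic acids into an alkaline trap.
`chainelongr` is for bioprocess engineers and microbiome researchers who
need to turn the raw measurements of such a system — broth concentration
time series, cumulative trap amounts, operating-period metadata, and 16S OTU
counts — into the standard performance and community metrics.

Everything is expressed on a **g COD basis** (chemical oxygen demand), the
common currency for reducing equivalents. The core quantities:

- **ThOD**: for C_nH_mO_p, ThOD = 32 (n + m/4 − p/2) g O₂/mol; e.g. 96 for
  ethanol and 352 for n-caprylate.
- **Mass balance per operating period**: production = extraction + washout,
  with extraction M (g COD/d) the OLS slope of the cumulative trap series,
  washout the mean broth concentration × effluent flow; productivity = rate/V,
  flux = rate/A_transfer, yield = MCC productivity / OLR, specificity =
  product COD / total product COD.
- **Pertraction model**: the overall mass transfer coefficient
  k = M / (A_transfer · ΔC_MCCA) (mm/d) is linear in the broth-recycle
  superficial velocity u = Q_recycle / A_cross (m/d); the packaged published
  line is k = 0.24 u + 1.31. Combined with a washout term V·C/HRT it predicts
  MCC production fluxes for any reported reactor/contactor configuration.
- **Microbiome correlation**: relative OTU abundances, a 1% abundance
  screen, Shannon diversity, Bray–Curtis + UPGMA ordering, PCoA, and a
  positive Pearson-correlation gate against MCC productivity using the
  critical value r* = t/√(t² + n − 2) (0.754 at n = 7, α = 0.05 two-sided).
- **Synthetic-data generator**: a forward-Euler COD balance with a planted
  k–u line, planted per-period production rates, and an OTU simulator with a
  planted abundance–productivity correlation — so the entire pipeline is
  testable end to end with no external data.

## Worked example

Simulate a noiseless four-period campaign under the default Phase-II-style
conditions (planted line k = 0.24 u + 1.31), then run the full recovery
pipeline:

```r
library(chainelongr)

sim <- simulate_reactor(simulation_config(noise_cv = 0, seed = 1))
est <- estimate_ku(sim$timeseries, sim$periods)
est$model
#> k-u mass-transfer model (fitted): k = 0.24 u + 1.31  [k mm/d, u m/d]
#>   R-squared: 1.000 (n = 4)

perf <- period_performance(sim$timeseries, sim$periods)
cat(render_period_report(perf)$text, sep = "\n")
#> Period 2: MCC productivity 0.6 g COD/L-d, yield 10%, C8:C6 ratio 0.3
#> Period 3: MCC productivity 1.6 g COD/L-d, yield 27%, C8:C6 ratio 0.5
#> Period 4: MCC productivity 3.9 g COD/L-d, yield 65%, C8:C6 ratio 1.0
#> Period 5: MCC productivity 3.3 g COD/L-d, yield 55%, C8:C6 ratio 0.8
```

The pipeline recovers the planted mass-transfer line exactly, and the
period report reads like an operating summary: in the highest-recycle
period the lumped C6+C8 productivity reaches 3.9 g COD/L-d (65% of the
6 g COD/L-d loading) with equal C8 and C6 production (ratio 1.0).

Cross-study flux prediction from reported operating data alone:

```r
predict_flux(published_ku_model(),
             data.frame(label = "high-recycle period", u_m_d = 207,
                        A_transfer_m2 = 1.4, C_MCCA_undiss_gCOD_L = 0.25,
                        V_L = 4.8, C_MCC_broth_gCOD_L = 1.0, HRT_d = 9.5))
#> # A tibble: 1 × 12
#>   label               predicted_k_mm_d predicted_flux_gCOD_m2_d ...
#> 1 high-recycle period             51.0                     13.1
```

OTU analytics on a simulated community with a planted productivity-tracking
taxon:

```r
otus <- simulate_otu_table(otu_sim_config(seed = 1))
correlate_otus(otus$counts, otus$metadata)   # r, p, significance gate at 0.754
shannon_diversity(otus$counts)               # per-sample Shannon index (base 2)
plot_abundance_heatmap(otus$counts)          # Bray–Curtis/UPGMA-ordered heat map
```

A thin command-line wrapper covers the same pipeline
(`inst/exec/chainelongr`; subcommands `simulate`, `rates`,
`pertraction-fit`, `predict-flux`, `microbiome-corr`, `report`); see
`?cli_run`.

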