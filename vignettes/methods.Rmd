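---
title: "Models and methods in chainelongr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in chainelongr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chainelongr)
```

This vignette is the package's own account of the science it implements:
the COD bookkeeping, the period mass balance, the pertraction mass-transfer
model, the microbiome correlation analysis, and the synthetic-data
generator that ties them together. It also records the numerical and
design choices that were genuinely open, and what the passing tests do and
do not demonstrate about real reactor data.

## COD bookkeeping

All concentrations and rates are carried on a g COD (chemical oxygen
demand) basis so that substrates (ethanol, complex organics) and products
(carboxylates, reduced gases) share one currency of reducing equivalents.
The conversion factor for a compound C~n~H~m~O~p~ is its theoretical
oxygen demand,

$$\mathrm{ThOD} = 32\,(n + m/4 - p/2)\ \text{g O}_2/\text{mol},$$

implemented as a sum of integer products (`32n + 8m − 16p`) so the
registry constants are exact. The packaged registry covers ethanol and the
straight-chain C2–C8 carboxylates (96, 64, 112, 160, 208, 256, 304, 352
g COD/mol); lookups are alias-tolerant (`"C8"`, `"n-caprylate"`,
`"octanoate"` are one species).

Acid speciation uses the Henderson–Hasselbalch form: the undissociated
fraction at broth pH is $1/(1 + 10^{\mathrm{pH} - \mathrm{p}K_a})$. The
pK~a~ defaults (acetic 4.76 … n-caprylic 4.89) are literature values for
the free acids at 25 °C, with no temperature or ionic-strength
correction — adequate at reactor pH 5.2 where the fraction changes by
< 0.01 per 0.01 pK~a~. COD factors are identical for the carboxylate and
the free acid (a proton carries no oxygen demand); molar masses are stored
for the free acids. No solubility constants are implemented: solubility
limits enter the literature only as qualitative context for product
inhibition.

## Period mass balance

Carboxylates leave the bioreactor by exactly two routes: membrane
extraction into the alkaline trap, and washout with the effluent. Per
operating period and species:

- **extraction** M (g COD/d) is the ordinary least-squares slope of the
  cumulative trap amount against time. The reported uncertainty is the
  **slope standard error** (with a t-based 95% CI at n − 2 df). Where a
  spreadsheet LINEST-style "sample standard deviation" is ambiguous
  between the slope SE and the residual SD, the slope SE is the quantity
  a confidence interval on a rate needs, so that is what is implemented.
  Negative fitted slopes are physically impossible for an accumulating
  trap and are returned unclamped with a warning flag, preserving
  diagnosability of sampling problems.
- **washout** is the period-mean broth concentration × effluent flow.
- **production** = extraction + washout (an identity, asserted exactly in
  tests); productivity = production / V; flux = production / A_transfer;
  yield = lumped-MCC productivity / OLR; specificity = a product's
  production over total product production (ethanol is the substrate and
  is excluded from the product pool); the C8:C6 product ratio is on a COD
  basis.

Period windows are `[t_start, t_end]` inclusive of boundary samples; no
transition-day exclusion is applied by default because there is no
principled universal choice — users can pre-filter the series. "MCC"
means lumped C6 + C8 unless C7 is explicitly requested; uneven chains are
reported separately. Reports round rates and ratios to 1 decimal and
percentages to integers (the conventional operating-summary style), while
full precision is retained in the underlying tibbles.

## Pertraction mass transfer

The driving quantity is the broth-recycle **superficial velocity** through
the forward contactor shell, $u = Q_\mathrm{recycle}/A_\mathrm{cross}$
(m/d; defaults A_cross = 1.56 × 10⁻³ m², A_transfer = 1.4 m²). The
**overall mass transfer coefficient** is

$$k = \frac{M_\mathrm{MCCA}}{A_\mathrm{transfer}\,\Delta C_\mathrm{MCCA}},$$

in L m⁻² d⁻¹ ≡ mm/d (1 L over 1 m² is a 1-mm film; the identity is
asserted against a dimensional-analysis oracle in the tests). The gradient
ΔC is the difference in undissociated MCCA concentration between broth and
trap; because the pH-9 trap holds essentially no undissociated acid, the
broth concentration alone is the standard approximation
(`gradient_approximation(..., approximate = TRUE)`), with the exact
difference available.

k is modelled as **linear in u** (turbulence lowers the boundary-layer
resistance), fitted by unweighted OLS with intercept — no weighting
scheme is defensible from period-level summary data. Units are kept as
mm/d against m/d so the packaged published line, k = 0.24 u + 1.31, has
its familiar coefficients; conversion to L m⁻² d⁻¹ at the extraction-rate
boundary is numerically the identity. The fit uses per-period k values
(one M, one mean ΔC per period) rather than per-sample values: the trap
slope is only defined over a window, so a per-sample k would mix
timescales. Extrapolation beyond the fitted u range is permitted — the
model's main use is asking what faster recycle would deliver — but flagged
in the output.

Cross-study **flux prediction** composes the pieces from reported data
alone: predicted extraction `k(u) · A_transfer · C_MCCA,undiss`, predicted
washout `V · C_MCC / HRT`, flux = (extraction + washout)/A_transfer.
`r_squared()` for observed-vs-predicted comparisons uses the **squared
Pearson correlation** convention (a constant prediction scores 0); a
through-origin regression R² would depend on an arbitrary anchoring choice
and is not offered.

## Microbiome–productivity correlation

Counts enter as an OTU-by-sample table. Analyses: per-sample relative
abundance; a 1% abundance screen (an OTU passes if it reaches the
threshold in ≥ 1 sample — inclusive by default, with a strict `>` mode,
since "exceeds 1%" applied to rounded percentages is boundary-ambiguous);
singleton removal; Shannon diversity (base 2 by default, the convention of
the QIIME-era upstream pipelines this table layout comes from; natural log
selectable); Bray–Curtis dissimilarity with average-linkage (UPGMA)
ordering for heat maps (rows sorted lexicographically before clustering so
equal-height merges resolve deterministically); and classical-scaling PCoA
with negative eigenvalues reported, never hidden (Bray–Curtis is a
semimetric). Weighted UniFrac is out of scope — it needs a phylogenetic
tree — so ordination is generic PCoA on whatever dissimilarity is
supplied.

The significance gate for abundance–productivity association is
deliberately **one-directional with a two-sided critical value**: an OTU
is called positively correlated with MCC productivity when its Pearson r
exceeds

$$r^* = \frac{t_{1-\alpha/2,\,n-2}}{\sqrt{t^2_{1-\alpha/2,\,n-2} + n - 2}},$$

which is 0.754 at n = 7, α = 0.05. p-values come from the two-sided
`cor.test` t-transform. No multiple-testing correction is applied by
default (the gate is reported per OTU as a descriptive screen);
Benjamini–Hochberg adjustment is available via `adjust = "BH"`.
Zero-variance abundance vectors yield an explicit `undefined-r` note, not
NaN.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which every pipeline property is verified.

**Reactor series.** The defaults emulate a semi-continuous Phase-II-style
campaign: four periods over days 17–84, V = 4.8 L, HRT 9 d (effluent
≈ 0.53 L/d), OLR 6 g COD/L-d, recycle rate stepped 9 → 86 → 323 → 228 L/d
(superficial velocities ≈ 6–207 m/d), pH 5.2, planted k–u line
(0.24, 1.31). Planted production is piecewise-constant per period, with
lumped MCC productivity rising 0.6 → 3.9 g COD/L-d and the C8:C6 split
rising to 1.0 at the highest recycle rate, plus minor acetate/butyrate
production so specificities are non-trivial. The broth obeys

$$V\,\frac{dC_s}{dt} = P_s - k(u)\,A_\mathrm{transfer}\,f_{u,s}\,C_s - Q_\mathrm{eff}\,C_s,$$

integrated by explicit forward Euler with automatic sub-stepping (the step
is divided so the per-step fractional loss stays below ~20%, and halved
further if a concentration would cross zero). Only the medium-chain acids
are extracted (the hydrophobic solvent takes up short-chain acids far more
slowly; approximated as not at all), and only their undissociated fraction
crosses the membrane. COD conservation — fed = Δbroth + extracted +
washed out — holds to ~1e-15 per period by construction of the discrete
update, and is asserted at 1e-9.

Two choices matter for interpretability:

- **Steady-state initialisation** (default): each period starts at its own
  steady state $C^* = P/(k A f_u + Q_\mathrm{eff})$. Period-average rate
  estimation implicitly assumes quasi-steady operation within a period;
  starting at steady state makes that assumption exactly true, so the
  noiseless pipeline must recover the planted extraction rates, per-period
  k values, and the k–u line to floating-point accuracy (the package's
  central closed-loop oracle, asserted at 1e-6 relative). `"continue"`
  and `"zero"` initialisations are available for studying transients.
- **Mid-interval sampling**: samples sit strictly inside their period
  window, so inclusive window filters never pick up a boundary sample
  belonging to the adjacent period.

Measurement noise is multiplicative Gaussian truncated at zero (GC-like
relative error), CV 5% by default. Each output stream draws from its own
seed (master + 11 for broth, + 23 for trap), so regenerating one stream
never perturbs another; a fixed master seed makes output byte-identical,
and the ambient RNG state is saved and restored.

**OTU tables.** The background community is an independent Dirichlet draw
per sample over a power-law ranked concentration profile (total
concentration 100); counts are multinomial at depth 10⁴ over 7 samples, the
scale of a small 16S time course. The planted OTU's expected proportion is
affine and increasing in the standardised productivity, mixed with
independent Gaussian noise as $\rho z + \sqrt{1-\rho^2}\,\varepsilon$ so
the latent correlation with productivity equals the target ρ (default
0.9). Expected proportions are truncated into [1e-6, 0.95]; if truncation
bites, the correlation actually achieved is reported in the truth record
(`achieved_latent_rho`) rather than failing silently. Across 500 seeds at
ρ = 0.9, n = 7 the mean empirical r sits within ±0.05 of the target
(small-sample Pearson bias plus multinomial attenuation are both well
inside that band at depth 10⁴).

**What passing tests do and do not show.** The generator has no microbial
kinetics (no Monod growth, no thermodynamic feasibility, no product
inhibition feedback), no solvent-phase dynamics, no solids/hydrolysis
pool, and its noise is uncorrelated across time, whereas real GC drift is
not. Recovery of planted parameters therefore validates the *estimators
and their composition* — not the biological assumptions of any particular
reactor. In particular, the linearity of k in u is an empirical operating
correlation, not a derived law; applying it far outside the fitted
velocity range is an extrapolation and is flagged as such.

## Numerical choices and degenerate inputs

- ThOD uses exact integer arithmetic; conversions round-trip at 1e-12.
- OLS slope standard errors use the closed form
  $\sqrt{\hat\sigma^2 / \sum (t_i - \bar t)^2}$ (identical to `summary.lm`
  but silent on perfect fits, which noiseless synthetic data produce
  routinely).
- `fit_ku` requires ≥ 2 distinct velocities (singular otherwise);
  `predict_k` floors predictions at zero.
- A zero concentration gradient makes k undefined and raises an error
  rather than returning infinity; zero OLR with nonzero MCC production
  raises a division error rather than an infinite yield.
- Dendrogram tie-breaks are made deterministic by lexicographic
  pre-sorting; PCoA axes are reported only for positive eigenvalues with
  variance fractions over the positive-eigenvalue sum.
- Problem sizes in the test suite are chosen so the full suite runs in
  seconds: 200-replicate coverage checks for the extraction-slope CI,
  500-seed recovery of the planted OTU correlation, 60-seed null checks.

## Known limitations

- Yield accounting treats the OLR as fully characterised COD; COD of
  biomass/solids is a lumped input, so yields over partially hydrolysed
  substrates are operational, not stoichiometric.
- The semi-continuous feeding cycle is represented by its average flow;
  sub-cycle dynamics (every-2-day feast/famine) are not resolved.
- The flux predictor uses a lumped C6+C8 MCCA concentration; systems
  strongly skewed toward C8 extract more easily than the lumped model
  assumes, so predictions there are conservative.
- The two-film resistance decomposition (shell/membrane/lumen) and
  solvent partition modelling are out of scope; k is strictly an overall
  coefficient.
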