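---
title: "Habitat selection and segregation from transect trapping counts: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat selection and segregation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habseg)
```

## The problem

Two forest rodents — the yellow-necked mouse (*Apodemus flavicollis*, `af`)
and the bank vole (*Clethrionomys glareolus*, `cg`) — co-dominate small-mammal
communities across much of montane Europe. When two species share a
continuous forested landscape, one candidate coexistence mechanism is
*habitat segregation*: systematic divergence in how their local densities
track habitat features. `habseg` implements a complete analysis chain for
testing this from transect live-trapping data:

1. count regressions of per-transect captures on standardised habitat
   covariates, with trapping effort as an offset and survey year as a random
   intercept;
2. AICc multimodel inference over all main-effect predictor subsets;
3. variance partitioning into per-variable partial r², split into
   *contrasting* (opposite or single-species effects) versus *shared*
   (same-sign in both species) habitat features;
4. a partial-r²-weighted Euclidean distance between the two species'
   averaged coefficient vectors, compared between elevation strata with a
   paired deletion jackknife;
5. competitor-augmented models testing interspecific suppression.

The unit of analysis is the transect: a line of 30–40 live traps inside a
homogeneous habitat patch, surveyed in one year, with captures (recaptures
excluded) recorded per species and effort in trap-nights.

## The count model

For transect $i$ in year $t$, species counts are modelled as

$$y_i \sim \text{Poisson}(\mu_i)\quad\text{or}\quad\text{NB2}(\mu_i, \theta),
\qquad
\log \mu_i = \log E_i + \beta_0 + \mathbf{x}_i^\top\boldsymbol\beta + u_{t(i)},$$

with $E_i$ the trap-nights of effort (so $\exp(\beta_0)$ is a baseline
capture rate per trap-night), $\mathbf{x}_i$ the z-scored habitat
covariates, and $u_t \sim N(0, \sigma^2_{\text{year}})$ absorbing
interannual density fluctuations (driven in these forests by masting
cycles). NB2 means $\operatorname{Var}(y) = \mu + \mu^2/\theta$.

`fit_count_model()` maximises the exact marginal likelihood. The year
intercepts are integrated out by adaptive Gauss–Hermite quadrature: each
year's integrand is re-centred at its conditional mode with the Laplace
curvature, and a `nodes`-point Hermite rule (default 15; 1 node is exactly
the Laplace approximation) is applied on that transformed axis. The outer
optimisation runs `nlminb` on $(\boldsymbol\beta, \log\sigma[, \log\theta])$
from deterministic starts (Poisson-GLM coefficients, $\sigma = 0.5$,
$\theta = 1$), so a fit is a pure function of the data. Fixed-effects-only
models use iteratively reweighted least squares directly. The test suite
checks the quadrature against dense trapezoid integration (agreement
$<10^{-4}$ on toy problems, $<10^{-6}$ between 31 and 63 nodes) and the
$\sigma \to 0$ limit against an independently coded IRLS oracle.

**Family and structure decisions** follow a fixed cascade
(`select_family_and_structure()`): fit Poisson; switch to NB2 if the
Pearson $\chi^2/\text{df}$ overdispersion check flags; then drop the year
intercept if its likelihood-ratio test against the fixed model is
non-significant. Because $\sigma = 0$ sits on the parameter boundary, that
test uses the $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ mixture reference
(halving the naive p-value); the plain $\chi^2_1$ reference would be
conservative in the wrong direction for *retaining* the intercept. Every
decision is recorded in a trail the pipeline writes to its run log.

## Model selection and averaging

`enumerate_and_rank()` fits all $2^p$ main-effect subsets (guarded at
$p \le 15$) and ranks by AICc, $\text{AICc} = \text{AIC} +
2k(k+1)/(n-k-1)$, with ties broken by fewer parameters then label. Models
within $\Delta\text{AICc} < 2$ (strict) of the best form the competing set;
Akaike weights $w_i \propto e^{-\Delta_i/2}$ are renormalised within it.
Coefficients are model-averaged in *full* mode by default — a variable
absent from a model contributes 0 before weighting — because reported
averaged-coefficient tables in this literature print exact zeros for
variables outside the competing set; conditional averaging is a flag.
Unconditional standard errors use
$\bar{SE}_v = \sum_i w_i \sqrt{SE_{i,v}^2 + (\beta_{i,v} - \bar\beta_v)^2}$.

The "best model containing only significant predictors" is a reconstruction
(the convention states the outcome, not the algorithm): walk the competing
set from the top and return the first model whose every predictor has
LR-test $p < \alpha$; failing that, backward-eliminate from the top model,
dropping the largest-p predictor each round. The intercept-only model is a
valid terminus and the path is logged so users can audit it.

## Variance partitioning

`model_r2()` is the marginal (fixed-effects) r² on the latent log scale:

$$r^2 = \frac{\operatorname{var}(\mathbf{X}\hat{\boldsymbol\beta})}
{\operatorname{var}(\mathbf{X}\hat{\boldsymbol\beta}) + \hat\sigma^2_{\text{year}} + \sigma^2_{\varepsilon}},$$

with the observation-level variance
$\sigma^2_\varepsilon = \ln(1 + 1/\bar\lambda)$ (Poisson) or
$\ln(1 + 1/\bar\lambda + 1/\hat\theta)$ (NB2), where
$\bar\lambda = \exp(\overline{\eta} + \overline{\log E})$. This is the
lognormal approximation standard in the mixed-model r² literature; the
delta-method variant ($1/\bar\lambda$ instead of $\ln(1+1/\bar\lambda)$) is
available via `method = "delta"` since published analyses rarely state
which their tooling used.

`partial_r2(fit, S)` refits the model without the subset $S$ and reports
the drop in explained variance **measured on the full model's
total-variance denominator**:
$(\operatorname{var}(\mathbf{X}\hat\beta) -
\operatorname{var}(\mathbf{X}_{-S}\hat\beta_{-S}))/(\text{full denominator})$.
A naive difference of two self-normalised r² values is *not* additive even
for orthogonal predictors — the reduced Poisson model cannot absorb the
removed signal into its latent residual term, so its denominator shrinks
and the partials can undershoot the model r² by large margins (we observed
0.2 at $n = 800$). With the common denominator, partials of orthogonal
predictors sum to the model r², $S = \text{all}$ recovers it exactly, and
monotonicity under subset inclusion holds; negatives from finite-sample
refits are floored at 0.

`contrast_partition()` classifies each variable significant in either
species as contrasting (one species only, or both with opposite signs) or
shared (both, same sign) and reports each species' group partial r² and the
contrasting share of its explained variation. `r2_ci()` provides
seed-deterministic parametric-bootstrap percentile intervals (simulate new
year effects and counts from the fitted model, refit, recompute; default
1000 draws; refit failures dropped, >20% failing is an error).

## The segregation distance and its jackknife

For one elevation stratum, each species' habitat response is summarised by
its averaged coefficient vector $\bar{\boldsymbol\beta}$ over the competing
set and per-variable weights $w_v$ equal to the partial r² of $v$ in the
*union model* (all variables appearing in any competing model), proportion
scale. The default distance convention is

$$d = \sqrt{\sum_v \frac{w_{A,v} + w_{C,v}}{2}\,
(\bar\beta_{A,v} - \bar\beta_{C,v})^2},$$

i.e. squared coefficient differences weighted by the species-mean partial
r². The weighting formula behind published distances of this kind is
typically under-specified, so three alternatives are implemented behind the
`convention` flag — per-species-weighted coordinates
($\beta w$), sqrt-weighted coordinates ($\beta\sqrt{w}$), and
stratum-normalised weights — and `distance_from_table()` ingests a printed
coefficient/weight table (censored "<1" entries mapped to the 0.5%
interval midpoint, configurable) and reports the distance under every
convention rather than asserting any one reproduces a printed value.
(Running `distance_from_table()` on the packaged example table — averaged
coefficients and weights reported for the survey this package's replica
design emulates — the default mean-weight convention gives 1.95 (LOW) and
0.72 (HIGH), close to that survey's reported *jackknife mean* distances,
while no implemented convention reproduces its point distances; the tests
only assert that all conventions yield finite positive distances.)

Inference compares LOW ($\le$ 1300 m, the elevation where these forests
shift to spruce dominance) against HIGH (> 1300 m). The paired deletion
jackknife removes, in turn, every combination of one LOW and one HIGH
transect and reruns the whole per-stratum pipeline (re-standardise →
selection → averaging → weights → distance) on the reduced strata, giving
$|LOW|\times|HIGH|$ pairs (1638 for the 42/39 design). Since the strata are
analysed independently, the LOW member of pair $(i,k)$ depends only on $i$;
the implementation therefore computes $|LOW| + |HIGH|$ leave-one-out
pipeline runs and crosses them — numerically identical, ~20× cheaper.
`jackknife_ci_and_test()` reports percentile 95% intervals and a paired
one-sample t of $d_{LOW} - d_{HIGH} > 0$ with $\text{df} = n_{\text{pairs}} - 1$.
That df convention treats deletions as independent samples; jackknife
replicates are not independent, so the t statistic is anti-conservative —
it is reported because it is the convention of this literature, with this
caveat attached.

## What the simulator states, and what a green test establishes

`generate_dataset()` draws habitat covariates with a shared latent site
factor (sites are blocks of adjacent elevations), enforces the pairwise
$|\rho_{\text{Spearman}}| \le 0.6$ screen by rejection for designs of
$\ge 15$ transects (below that the bound is pure sampling noise and is
skipped), then generates counts from exactly the model above.
`generate_study_replica()` fixes the design constants of the emulated
survey: 81 transects in 43 sites, elevations 820–2080 m with exactly 42 at
or below 1300 m, seven survey years with 50 transects in odd and 31 in even
years, opposite-sign defaults on tree cover and moisture, shared positive
response to rocks, and a −1 log-scale depression of odd years standing in
for post-masting density troughs. Values the emulated survey does not state
were fixed once: effort 90–160 trap-nights per transect (30–40 traps run
3–4 nights), baseline capture rate 0.025 per trap-night,
$\sigma_{\text{year}} = 0.35$. Interspecific suppression is generated
sequentially: the first species in `species_order` (vole by default) is
drawn from habitat alone, the second adds $\gamma \cdot z(\text{competitor
rate})$ to its linear predictor; the first species' $\gamma$ is necessarily
inert and documented as such.

The generator reproduces the *statistical structure* the analysis assumes —
not trap-level capture processes, spatial autocorrelation beyond the site
factor, detection differences between species, or the real covariate joint
distribution. A green test therefore establishes that the machinery is
correct and calibrated under the stated model, not that the original
field estimates are reproduced. Accordingly the published coefficient
tables, model r² values (0.12/0.37), jackknife means (1.98/0.72), t = 135.9
and Wilcoxon W statistics — which require the archived field data — are
deliberately never asserted; the in-study arithmetic identities (capture
share 78.7%, contrasting shares 63%/93.6%, 1638 pairs, df 1637) are.

## Numerical choices and degenerate inputs

* Linear predictors are capped at 30 before exponentiation; $\log\sigma$ is
  bounded in $[\log 10^{-6}, \log 50]$ and $\log\theta$ in
  $[\log 10^{-4}, \log 10^{6}]$; marginal likelihoods floor $\sigma$ at
  $10^{-10}$, where the quadrature provably collapses to the GLM
  likelihood.
* Rank-deficient designs error naming the aliased terms; perfectly
  collinear predictors get an infinite VIF plus a fail flag rather than a
  crash; constant predictors are rejected by `zscore()`.
* AICc is undefined at $n \le k + 1$: `aicc()` errors, and fits on such
  tiny n carry `NA` so closed-form MLE checks remain possible.
* Exact Wilcoxon enumeration is used up to $n_1 + n_2 = 12$ without ties;
  otherwise a tie-corrected normal approximation (no continuity
  correction, matching the tie-corrected reference implementation).
* Jackknife deletion refits that fail (e.g. a covariate becoming constant
  in a reduced stratum) are flagged and excluded; more than 5% of pairs
  failing is an error.

## Scale-downs for tractability

Two pipeline defaults trade fidelity for feasible runtimes and are plain
config switches, not silent approximations: `run_config()` uses
fixed-effects fits inside jackknife deletions
(`jackknife_random_intercept = "none"`), and the packaged tests enumerate
4–5 candidate predictors rather than all ten. Setting
`jackknife_random_intercept = "year"` and the full candidate list
reproduces the full-fidelity procedure at minutes-to-hours of compute.

## Known limitations

* Single random intercept only — no crossed/nested random effects, no
  zero-inflated mixture families (the zero-inflation *check* is provided).
* The t test on jackknife pairs inherits the anti-conservative df
  convention discussed above.
* The latent-scale r² depends on the lognormal-vs-delta choice for the
  observation variance; both are provided, neither is canonical.
* The simulator's within-site covariate correlation is a stand-in latent
  factor, not an inference about any real landscape.
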