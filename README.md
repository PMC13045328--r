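# canopyshift

Forest *mesophication* — the drift of fire-adapted, drought-tolerant open
forests toward shade-adapted, fire-intolerant "mesic" communities under
fire suppression — is usually described taxonomically. `canopyshift`
quantifies it functionally and phylogenetically from paired-era resurvey
data: the same forest sites scored in two survey eras, a species-level
functional trait table, and an ultrametric phylogeny.

The package implements the full inference chain for this design:

* **Temporal beta diversity (TBI)** — per-site Bray–Curtis percentage
  difference `(B + C) / (2A + B + C)` decomposed exactly into a
  species-loss share `B/(2A+B+C)` and a species-gain share `C/(2A+B+C)`,
  with Welch/paired tests of gains against losses.
* **Hill-number (q = 1) beta diversity** — taxonomic, functional
  (Rao-distance-based), and phylogenetic (branch-length-based)
  gamma/alpha/beta partitions with bounded [0, 1] overlap similarity, and
  permutation-null **standardized effect sizes** (999 shuffles of species
  identities over traits or tips, frequencies held fixed).
* **Community-weighted means (CWM)** — abundance-weighted trait means per
  site and era, with a within-pair era-swap permutation test (1000 draws,
  add-one two-sided p) and a Wilcoxon signed-rank companion.
* **Trait construction** — hydraulic derivations (K_S, K_L, A_L:A_S),
  osmometry-to-turgor-loss-point conversion, Box-Cox-guided transforms
  with provenance guarding, litter flammability PCA (PC1_fire sign-anchored
  on flame height), Gamma-GLMM variance decomposition across taxonomic
  levels, and bark thickness predicted at a 10 cm reference DBH.
* **Phylogenetic signal** — maximum-likelihood Pagel's lambda with
  analytic profiling and a chi-square LRT against no signal.
* **ZIP phylogenetic GLMMs** — zero-inflated Poisson mixed models of
  site-by-species stem counts with site, species, phylogenetic
  (`sigma^2 * Sigma_phy`), per-trait site-slope, and **nested phylogenetic
  clustering** (`kron(I_m, sigma^2 * Sigma_phy)`) random effects, a global
  zero-inflation probability, Laplace-ML and MCMC backends, WAIC,
  boundary-corrected LRTs, forward trait selection, and the headline
  statistic

  `% reduction = 100 (sigma^2_nested,without − sigma^2_nested,with) / sigma^2_nested,without`

  — how much of the phylogenetic clustering the measured traits explain.
* **Synthetic data** — a first-class generator (pure-birth trees,
  lambda-scaled Brownian traits, the full ZIP generative model with
  directional era-2 turnover) that defines the study conditions every
  stage is tested against.

## Worked example

```r
library(canopyshift)

scenario <- simulation_scenario(seed = 42)   # 19 species x 138 paired sites
sim <- simulate_community_pair(scenario)

# temporal beta diversity with gain/loss partition
tbi <- tbi_table(sim$era1, sim$era2)
mean(tbi$tbi)
compare_gain_loss(tbi)$p_value

# nested phylogenetic clustering: does the trait explain it?
traits <- sim$traits
d_with <- build_design(sim$era1, traits = traits, tree = sim$tree)
d_without <- build_design(sim$era1, tree = sim$tree,
                          terms = c("site", "species", "species_phy", "nested"))
f_with <- fit_pglmm(d_with, seed = 1)
f_without <- fit_pglmm(d_without, seed = 1)
variance_reduction(f_with, f_without)
```

With this seed the run prints a mean TBI of `0.495`, a gain-vs-loss Welch
p of `0.0014` (the generator shifts composition toward high mesophyte
scores, so gains and losses are asymmetric by design), nested clustering
variances of `0.466` (with the trait) against `0.601` (without), and a
variance reduction of `22.4%`: the simulated trait accounts for roughly a
fifth of the phylogenetic clustering, the rest remaining as nested
covariance — the same structure the published Wisconsin analyses report
with their richer trait set (40.8% in the 1950s era, 19.6% in the 2000s).

The numbered scripts under `analysis/` run the same chain as a narrative
workflow (simulate, diversity + SES, CWM shifts, PGLMMs) and write their
tables under `results/`.

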