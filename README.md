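# meadowsucc

Analysis pipeline for grazing-induced community succession in alpine
meadow, built for quadrat-level vegetation/soil surveys of the kind
collected on the Tibetan Plateau under space-for-time substitution
designs: areas with different grazing histories are surveyed once,
quadrats are grouped into succession stages from their community
composition, and plant–soil state is compared across the stages. It is
aimed at grassland ecologists who have (or want to simulate) per-quadrat
species biomass tables plus soil covariates and need the whole chain —
stage assignment, coupling, multifunctionality, inference — reproducible
from one seed.

## What it computes

* **Succession stages** — Ward agglomerative clustering (Euclidean,
  `ward.D2`) of quadrats on functional-group biomass shares plus canopy
  height, cut at *k* stages (default 4) and ordered sedge-dominated →
  toxic-forb-dominated.
* **Community metrics** — species richness *SR*, stage gamma diversity,
  functional-group shares, and Camargo evenness
  *E* = 1 − Σ<sub>i&lt;j</sub> |P<sub>i</sub> − P<sub>j</sub>| / S,
  with P<sub>i</sub> the biomass proportion of species *i* among the *S*
  species present.
* **Plant–soil coupling** — per quadrat, min–max standardized indicators
  (polarity-aware), PCA-derived weights, subsystem integrals S(X) and
  P(Y), coupling degree C = 2√(S·P)/(S+P), coordination T = αS + βP,
  and the coupling coordination degree D = C·T ∈ [0, 1].
* **Ecosystem multifunctionality** — EMF = (1/N) Σ z(x<sub>i</sub>) over
  N = 12 plant and soil functions, with PGI/SCI/SNI sub-indices.
* **Inference** — one-way ANOVA with Tukey HSD letters, simple
  regressions, Mantel permutation tests (with an exact mode for small
  n), correlation matrices, and exact LMG (averaging-over-orderings) R²
  decomposition of relative importance.
* **Synthetic surveys** — a stage-structured generator whose defaults
  encode the published stage compositions (Stage 1 sedges 46% … Stage 4
  toxic forbs 44%), pool sizes 61/55/47/49, and the reported stage
  ordering of soil variables, so the full pipeline is testable without
  field data.

## Worked example

```r
library(meadowsucc)

survey <- generate_survey(generator_config(rng_seed = 2024))
fg     <- templates_fg_map()

stages <- assign_stages(survey, fg)       # Ward clustering + ordering
cp     <- coupling_indices(survey)        # S, P, C, T, D per quadrat
mf     <- multifunctionality(survey)      # PGI, SCI, SNI, EMF

anova_tukey(cp$D, stages$stage)$summary
#>   group     n  mean     sd letters
#> 1 1        28 0.636 0.0372 a
#> 2 2        31 0.564 0.0432 b
#> 3 3        30 0.589 0.0359 b
#> 4 4        31 0.283 0.0677 c

simple_regression(mf$emf, cp$D)
#>   slope intercept r_squared  p_value     n
#> 1 0.296     0.514     0.938 4.76e-73  120
```

Reading this: the recovered Stage 4 has by far the lowest coupling
coordination (mean D = 0.28 vs 0.56–0.64; Tukey letter `c` vs `a`/`b`),
and multifunctionality and coupling rise together (positive slope,
R² = 0.94 on this synthetic survey). Stage gamma diversities here are
61/55/47/49 — the generated pools. The full pipeline, including the
inferential tables and a JSON run manifest, is one call:

```r
run_pipeline(config = analysis_config(rng_seed = 2024), out_dir = "results/run1")
```

A thin CLI wrapper lives in `inst/scripts/meadowsucc.R`
(`simulate` and `run` subcommands).

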