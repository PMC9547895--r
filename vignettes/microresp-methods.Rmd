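---
title: "Methods: null-model response metrics for dietary-intervention microbiome studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: null-model response metrics for dietary-intervention microbiome studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(microresp)
```

# The problem

Gut-microbiome responses to dietary interventions vary strongly between
individuals, and a natural response measure — beta diversity between a
subject's samples before and after the intervention — is confounded by a
purely computational dependence on alpha diversity: sparser, less diverse
communities produce systematically different Bray–Curtis or Aitchison values
even when composition is random. `microresp` implements an analysis chain
that (i) measures this computational dependence, (ii) replaces raw beta
diversity with a null-model statistic that removes it, and (iii) relates the
resulting response to baseline community features, with an honest
machine-learning test of how much of the response is predictable at all.

# The RC~bray~ response metric

For a pair of samples, the observed Bray–Curtis dissimilarity
$BC_{obs} = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)$ is located within a null
distribution obtained by re-assembling both communities many times from the
species pool of a declared *context* table:

1. each null community keeps the sample's observed richness $S$ and read
   depth $N$;
2. $S$ taxa are drawn without replacement with probability proportional to
   their prevalence (occurrence frequency) in the context;
3. each drawn taxon is seeded with one read and the remaining $N - S$ reads
   are drawn with replacement with probability proportional to the taxa's
   mean relative abundance in the context.

With `n_reps` null replicates,

$$RC = 2\,\frac{\#\{BC_{null} < BC_{obs}\} + \tfrac12\,\#\{BC_{null} = BC_{obs}\}}{n_{reps}} - 1 \in [-1, 1].$$

Identical communities score $-1$, maximally distinct ones $+1$, and a pair
that looks exactly as expected under random assembly scores $0$. Splitting
ties at weight one half makes both endpoints attainable. Equality of two
Bray–Curtis values is decided at an absolute tolerance of $10^{-10}$ (the
values are ratios of integers, so true ties are exactly representable and
the tolerance only absorbs floating-point noise).

Because prevalence and mean abundance are context properties, RC values for
the same pair differ slightly across contexts (global, per-intervention,
per-enterotype). `null_model_config()` therefore binds one context table and
a `label` that is carried into every result for provenance. Each pair's
null stream is seeded from the master seed and the *sorted* pair ids, so
`rc_bray(x, y)` and `rc_bray(y, x)` are identical and every value is
reproducible in isolation.

Defaults: `n_reps = 999` (a granularity of 0.002 on the RC scale; at least
99 is enforced). The per-subject response is RC~bray~ between the baseline
and after samples (`rc_bray_pairs()`), and `rescale_rc_to_unit()` maps it to
$[0, 1]$ where a non-negative quantity is needed.

# Diagnosing the computational alpha–beta dependence

`alpha_beta_dependence()` regresses pairwise beta diversity on the pair mean
Shannon index for randomly drawn sample pairs, after one of two
randomisations that destroy all biology while controlling alpha diversity:

* **Randomisation 1** permutes count values across taxa independently per
  sample: the count multiset, depth and Shannon index are preserved
  bit-exactly. Pairwise dissimilarity rises on average because shared taxa
  become rare.
* **Randomisation 2** re-assembles every sample by the same two-step null
  model used inside RC~bray~ (richness and depth preserved exactly; Shannon
  changes slightly). Samples become draws from a common pool, so pairwise
  dissimilarity falls on average.

A significant slope on randomised data is, by construction, a computational
artefact. Bray–Curtis and Aitchison retain such slopes; RC~bray~ does not —
which is the argument for using it as the response metric. The package's
acceptance tests reproduce this qualitative pattern on synthetic data with
500 pairs per regression.

# Enterotyping

`fit_dmm()` fits a $K$-component Dirichlet-multinomial mixture to a
genus-level table by EM. The component densities are full
Dirichlet-multinomials (including the multinomial coefficient, so the
log-likelihood is an honest data log-likelihood); M-steps update each
component's parameter vector by Minka's fixed-point iteration under the
posterior responsibilities, which does not decrease the observed-data
likelihood — the EM trace is checked to be monotone in the tests.

Numerical choices: initialisation is k-means on relative abundances under
the user seed, with initial concentrations $50 \cdot \bar p_k$ floored at
$10^{-4}$; parameters are floored at $10^{-6}$ during fixed-point updates;
convergence is a relative log-likelihood change below `tol` (default
$10^{-8}$), with a warning and best-so-far model after `max_iter`. `K`
defaults to 4, the canonical enterotype count; the model records BIC in
`fit_score` so alternative `K` values can be compared. BIC was chosen as the
selection criterion for its robustness and simplicity; names are component
indices (matching components to published enterotype names requires real
taxon identities and is out of scope).

Classification of new samples (`classify_by_medoid()`) is by smallest
Bray–Curtis dissimilarity, on relative abundances, to the component medoids
(the member minimising summed dissimilarity to its co-members); exact ties
break towards the lowest component index, with a message.

# Community statistics

* **Alpha diversity**: Shannon index in nats on rarefied counts.
  Rarefaction (`rarefy()`) is a single recorded-seed subsample without
  replacement to the dataset minimum depth (a fixed depth is available as an
  argument); it is done once per dataset, not per analysis.
* **AGN** (average gene number per organism): a read-weighted mean of
  per-taxon gene counts from a reference table. Species-resolved taxa match
  species-rank entries, genus-resolved taxa match genus-rank entries, and
  taxa resolved only to family or higher — or with no reference match — are
  excluded; the denominator counts only included reads, and the included
  fraction is reported alongside. AGN is invariant to uniform count
  rescaling. The bundled reference under `inst/extdata` is synthetic (real
  references are built from genome-assembly annotation counts).
* **B:F ratio**: total Bacteroidetes reads over total Firmicutes reads. A
  zero denominator is an error by default (`zero_firmicutes = "inf"` yields
  a sentinel instead; infinities are rejected downstream by the record
  validator, which is why the error default exists).

# Partial-correlation networks

For components $i, j$ of a record table (response, baseline alpha, AGN, B:F,
optionally response potential), the edge weight is the Pearson correlation
of the residuals of two regressions: $i$ on all components except $i, j$,
and $j$ likewise. With `random_effect = "intervention"` both regressions
carry a random intercept per intervention (ML fit; conditional residuals),
which is how pooling across heterogeneous interventions is corrected; with
a single intervention the mixed path reduces to ordinary least squares and
agrees with it numerically. Components are standardised internally — partial
correlations are scale-invariant, so this only aids conditioning. Singular
(collinear) component sets are rejected by a rank check.

Edge p-values come from the Pearson test on the residual pairs with $n - 2$
degrees of freedom, uncorrected for the preceding model fits — a documented
approximation; q-values are Benjamini–Hochberg over the network's edges (one
family per network). Per-taxon response associations
(`taxa_response_association()`) use the same modelling vocabulary: response
on clr-transformed baseline abundance (pseudocount 0.5), optional alpha
adjustment, a random intervention intercept in the pooled and per-enterotype
modes (p-values by Satterthwaite approximation), simple regression per
intervention, and BH within each (mode, stratum) family.

# Response potential

The response potential of a baseline sample is the mean RC~bray~ between it
and a large panel of same-enterotype samples from other individuals,
computed in the shared context of query plus panel. It estimates the
component of the response determined by the initial state alone and needs
only one timepoint per individual. Panels smaller than 300 samples trigger
a warning — the estimate is a mean of noisy $[-1,1]$ values and stabilises
with panel size.

# The machine-learning predictability test

`cv_predict_response()` asks how much of the response is predictable from
baseline composition, and whether the response-potential estimate captures
that predictable component. Per iteration (default 50): subjects split 2:1
into train and test; taxa with zero abundance in more than 30% of the
*training* samples dropped; 10 selection models (300 rounds) fitted on the
training set and their gain importances averaged; the top 30 predictors fed
into the main model (depth 15, 1000 rounds, learning rate 0.3); test
predictions scored as squared Pearson correlation ("caret $R^2$") against
(a) the held-out responses, (b) a per-iteration label-shuffled rerun of the
entire procedure (the random model), and (c) the held-out response-potential
values. Selection and fitting see only training rows, so test information
cannot leak by construction — a property asserted directly in the tests.
Predictors are arcsine-square-root transformed relative abundances.
Constant predictions score 0 by convention; note the measure is sign-blind.

# The synthetic-data generator

`generate_study()` emulates the structure of a paired 16S intervention
cohort with known ground truth:

* **Baseline**: $K = 4$ enterotype-like components; component Dirichlet
  means share a log-normal abundance backbone with 10 component-specific
  driver taxa boosted 25-fold; subject compositions are Dirichlet draws
  (concentration 30) and counts multinomial at uniform depths in
  5000–15000 reads. Taxa carry phylum blocks (Bacteroidetes / Firmicutes /
  other), gene counts increasing with backbone abundance (generalists carry
  more genes) in 1500–8000, and a resolution mix of 85% species / 10% genus
  / 5% family-only (the latter exercising the AGN exclusion rule).
* **After**: each subject's baseline composition is mixed with a fresh draw
  from a *different* random component in proportion
  $w = \mathrm{clip}(0.3 + 0.12 \cdot score, 0, 0.95)$, where $score$ is a
  standardised linear combination of baseline AGN (weight $-1$), Shannon
  alpha ($+1$) and log B:F ($+1$) plus Gaussian noise (sd 0.5). Mixing
  towards another component makes large scores read as enterotype-scale
  shifts, so the realised RC~bray~ spans its range instead of saturating at
  $-1$, and the map from planted score to realised response is monotone.
  With all effects, noise and floor at zero (and count resampling off) the
  after-sample equals the baseline exactly.

The generator does **not** emulate sequencing error, chimeras, phylogeny,
overdispersion beyond the Dirichlet, longitudinal drift, or realistic taxon
co-occurrence; passing tests demonstrate the correctness and sensitivity of
the *procedures* under a controlled data-generating process, not effect
sizes in real cohorts. All randomness flows through one seed.

# Filters and conventions

Samples are kept when their read total strictly exceeds 3000; taxa are kept
when they exceed 20 reads in at least 20 samples (both comparisons strict —
a taxon with 21 reads in exactly 20 samples survives). The clr transform
replaces zeros by 0.5 before taking logs. Counts are always stored as
integers; relative abundances are derived on demand. Outlier samples with
abnormal composition are excluded manually by subsetting — no automatic
rule is implemented.

# Problem sizes in the shipped tests

The test suite exercises the claims at sizes chosen to keep a full run in a
few minutes while leaving all statistical checks well-powered: 999 null
replicates for RC endpoint and enumeration-oracle checks, 99 replicates
(the enforced minimum) inside the 500-pair regression and the 20-replicate
planted-sign study (n = 300 subjects each), n = 400 subjects for
enterotype recovery, n = 150 subjects with 50 CV iterations for the
boosted-tree protocol, and 200 simulated null datasets for FDR calibration.

# Known limitations

* RC~bray~ depends on the declared context; values are comparable only
  within one context, and the package deliberately forces that declaration.
* The residual-correlation p-values ignore the uncertainty of the mixed-model
  fit that produced the residuals.
* The Jaccard metric is computed on presence/absence after rarefaction;
  phylogenetic (UniFrac-family) metrics are out of scope because the data
  model carries no tree.
* The DMM fit is a local EM optimum from a single seeded initialisation;
  for small or poorly separated data, comparing several seeds via
  `fit_score` is advisable.
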