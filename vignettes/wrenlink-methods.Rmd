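---
title: "Methods: linking nestling diet, arthropod availability and nesting performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking nestling diet, arthropod availability and nesting performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrenlink)
```

## The problem this package addresses

Insectivorous birds can be food-limited even where arthropods are abundant,
because the taxa that dominate the environment are not necessarily the taxa
nestlings are fed. `wrenlink` implements a territory-scale analysis chain for
exactly this question, developed around a coastal-sage-scrub system (the
Coastal Cactus Wren, *Campylorhynchus brunneicapillus sandiegensis*): it
links (i) nestling diet characterized by COI metabarcoding of fecal samples,
(ii) arthropod availability resolved by habitat element and stratum, and
(iii) nesting performance, with the territory as the unit of replication.

The package ships a synthetic-study generator that emulates all four data
streams of such a study with known latent structure, so the entire chain is
testable without any field data.

## Diet from COI metabarcoding

OTUs (97%-clustered COI sequence clusters) arrive with candidate
reference-database matches and percent similarities. `assign_taxonomy()`
applies the published operating points for COI identity: a best match at or
above 99.3% similarity supports a species-level assignment, 94.9% genus,
91% family, and 85.9% order; below that the OTU is unresolved and excluded.
The comparisons are inclusive (`>=`): the cutoffs are operating points and an
observation exactly at one qualifies.

When several candidates tie at the best similarity with conflicting
taxonomy, the assignment falls to the deepest rank on which all tied
candidates agree — their lowest common ancestor — still capped by the
threshold rank. Regional overrides apply last; the default rule assigns
family-level Armadillidiidae to *Armadillidium vulgare*, the only
armadillidiid in the study region.

One property worth stating precisely: the cascade is monotone in the *best
match's* similarity (raising it never coarsens the assignment), but it is
not monotone in an arbitrary candidate's similarity — raising a non-best
candidate into an exact tie can engage the LCA rule and legitimately coarsen
the rank. The test suite asserts the former, well-defined form.

Diet composition is summarized per order by frequency of occurrence
(`FO = 100 x` samples containing the order `/` samples with detectable
arthropod DNA — the denominator is positive samples, not all collected
samples), relative read abundance (mean per-sample read share), OTU counts
and minimum species richness. Orders found in more than one positive sample
("more than 1" read strictly, i.e. at least 2) are designated prey;
single-occurrence orders are listed with the reason for exclusion.

## Biomass allometry and aggregation

Counted-and-measured arthropods are converted to biomass with order- or
suborder-level power laws, `mass_mg = a * length_mm^b`. The shipped registry
is an editable table of literature-style defaults — configuration, not
ground truth — and five orders without usable parameters (Raphidoptera,
Archaeognatha, Pseudoscorpionida, Ephemeroptera, Siphonaptera) return a
no-estimate sentinel rather than a number. Hemiptera are parameterized by
suborder (Heteroptera, Auchenorrhyncha, Sternorrhyncha); unknown suborders
fall back to the parent order's entry. Canopy visual-search records are
treated together with vacuum records (a `source` column is retained for
audit).

`aggregate_cells()` reduces record-level biomass in a fixed order: sum
within each (territory x habitat element x stratum x taxon x time block x
block) sample cell, then average across spatial blocks, then total across
time blocks. Cells absent from a block are *missing*, not zero: they are
excluded from the block mean, and `n_blocks` records how many blocks
contributed. The default time reduction totals all five time blocks (both
seasons); both reductions are exposed (`block_mean`, `time_total`) because
the season-wise alternative is equally defensible.

## Marginal means

The default estimator of per-cell mean biomass is the balanced-design cell
mean of the `log(x + 1)`-transformed response, with its standard error. This
is deliberately the estimator contract: under a full-interaction fixed
structure with balanced data, mixed-model estimated marginal means reduce to
exactly these cell means, and that equivalence is what the oracle tests
assert (tolerance 1e-8). `method = "lmm"` fits the mixed model per stratum
and taxon — habitat element x territory fixed effects, random intercepts for
time block and block-in-territory, random terms with zero estimated variance
dropped and the model refitted — and extracts estimated marginal means via
`emmeans`. The log1p scale is used for estimation and hypothesis tests;
territory upscaling consumes raw-scale block means, because the
cover-weighted sum is defined on the arithmetic scale.

## Composition statistics

Bray–Curtis dissimilarity, PERMANOVA and the composition PCA are implemented
in the package (they carry oracle-equivalence tests against brute-force
computations and against `vegan` as an independent cross-check):

- `bray_curtis()` is the plain normalized absolute difference,
  `sum |x - y| / sum (x + y)`, undefined for two all-zero vectors.
- `permanova()` is one-way with Anderson's partitioning of squared
  dissimilarities, unrestricted label permutations (no strata), the upper
  one-sided tail, and `p = (#{F* >= F} + 1) / (n + 1)` with 999 permutations
  by default. The permutation stream is private and seeded; a run is exactly
  reproducible from its seed. The minimal attainable p at 999 permutations
  is 0.001, and the null rejection rate at alpha = 0.05 is calibrated to
  5% in the test suite.
- `pca_composition()` is column-centred, unscaled PCA on row proportions
  (proportions share a scale, so no variance scaling). Axis signs are fixed
  so each axis's largest-magnitude loading is positive, making loadings
  reproducible up to labeling rather than up to sign.

## Territory upscaling

Vegetation cover is consumed as territory-level percent cover per habitat
element. Availability is the cover-weighted sum scaled to a standard area:
`sum_elements (cover%/100) x mean_biomass x area`, with
`standard_area(100) = 31,416` m² (a 100 m circular buffer) as the default
standardization. Bare ground is a focal element with its own sampled
biomass; non-focal cover ("other"/artificial) contributes zero biomass by
definition and its fraction is reported, not imputed. Covers are raw
percentages of mapped area — no renormalization to focal-only cover. This
conversion assumes equal sampling effort per unit cover across elements; it
is crude for structurally dissimilar elements and should be read as a
standardized index, not an absolute density.

`territory_availability()` assembles the per-territory, per-stratum surface:
per-order biomass, the prey total (sum over designated prey orders),
Hymenoptera kept strictly as an independent predictor axis (never a prey
order, since the environmental Hymenoptera here are overwhelmingly a single
invasive ant), and the first two axes of a PCA on relative prey biomass.

## Performance links

`summarize_nesting()` reports means and standard errors (sample SD / sqrt n)
across territories for nest attempts, clutch size, seasonal eggs and
fledglings. Clutch size is the mean of per-territory `eggs / attempts`
ratios — that reading reproduces the packaged table's printed value — with
the pooled ratio also reported since the alternative is plausible.

`relate()` fits territory-level links. The gaussian family (first egg date)
returns the Pearson correlation test with the simple linear fit; the poisson
family (fledgling counts) returns a log-link GLM slope with its Wald p.
Supporting both resolves an ambiguity in how count responses should be
handled: a Poisson error structure cannot "achieve normality of residuals",
so the package exposes gaussian for dates and poisson for counts and lets
the analyst run either. P-values are two-sided and uncorrected for multiple
testing (each result carries a caveat flag); heavy-tailed predictors such as
invasive-ant biomass can be log-transformed via `log_predictor = TRUE`.

`rank_discordance()` pairs each order's diet rank (by FO) with its
availability rank per stratum, computes Spearman's rho with midranks, and
flags high-diet/low-availability orders — the package's summary of the
diet/availability discordance.

## The synthetic-study generator

`generate_study()` draws a complete bundle under `nominal_config()`, which
encodes the field design: 3 sites holding 8 territories (3/2/3), 2 spatial
blocks per territory, 9 habitat elements (8 dominant plants plus bare
ground), canopy and ground strata, 5 time blocks, and 28 diet samples with
detectable arthropod DNA out of 62 collected.

Model choices, each made once:

- **Counts** are negative-binomial per sample cell (`dispersion = 0.7`),
  reflecting the strong overdispersion and single-taxon numerical dominance
  typical of such samples; Poisson is the `dispersion = Inf` special case.
  Default intensities put Hymenoptera (95% invasive ants) at roughly an
  order of magnitude above most prey taxa, Lepidoptera concentrated on a
  subset of shrub canopies, Isopoda on the ground, Orthoptera on grasses.
- **Body lengths** are lognormal per order (e.g. ants small at ~2 mm,
  Lepidoptera larvae large at ~8 mm, sdlog 0.35).
- **Cover** is Dirichlet per territory over the nine elements plus a
  non-focal "other" category, with concentrations shaped like observed
  territory cover (non-native grasses most common; "other" near 10–20%).
  Rows sum to 100 exactly before rounding.
- **Diet** is per-order Bernoulli detection (defaults shaped like an
  insectivore diet: Diptera 0.89, Lepidoptera 0.82, mid-frequency
  Orthoptera/Araneae/Coleoptera/Isopoda, Hymenoptera 0.036) followed by
  multinomial reads over the detected orders' OTUs — the simplest structure
  supporting FO and RRA. The match table spans all similarity bands and
  plants equal-similarity ties to exercise the LCA rule.
- **Nesting**: the latent "Lepidoptera relative availability" of a territory
  is the Lepidoptera share of upscaled prey biomass (strata summed) — the
  same quantity the pipeline later estimates. First egg date is
  `intercept - effect x z(latent) + Normal(0, date_sd)` with defaults
  intercept 100 (Julian), `date_sd` 15 days, effect 10 days/SD; fledglings
  are Poisson with log-mean `1.03 - 0.02 x (date - intercept)`, truncated at
  the egg count. These defaults put simulated dates and fledgling counts in
  the observed ranges (days ~50–130; ~2.8 fledglings at the mean date).
- A single private random stream per bundle, seeded from the configuration;
  the caller's RNG state is never touched, and equal seeds give bit-identical
  bundles.

What the generator does *not* emulate: spatial autocorrelation, continuous
phenology (time is discrete blocks), sequence-level artifacts (reads are
abstract counts), and territory-specific diet sampling effort (samples are
linked to territories uniformly at random). Passing tests on synthetic
bundles therefore demonstrate the correctness of the estimators and the
recoverability of a planted effect under idealized sampling — not the
field-data properties themselves.

## Numerical and design choices

- Similarity ties are exact equalities (within 1e-9); thresholds inclusive.
- FO ranking ties break alphabetically for deterministic reports.
- `standard_area()` rounds to the nearest m² for reporting only; upscaling
  uses the value passed in.
- PERMANOVA p-values can never be 0 by construction; single-group designs
  and groups of one are rejected.
- Zero-variance inputs (constant composition matrices, constant predictors)
  raise typed errors rather than returning NaN.
- All tables are UTF-8 CSV with headers; Julian dates are plain integers;
  the run manifest contains versions, seed and content hashes but no
  timestamps, so reruns are bit-identical.
- Problem sizes in the test suite are chosen to keep the full suite around a
  few minutes: calibration loops use 1000 replicates at the nominal
  8-territory design, recovery uses 100 replicates at 40 territories, and
  oracle checks use instances of at most 10 x 10.

## Known limitations

The cover-to-availability conversion inherits the equal-effort assumption
discussed above. The marginal-mean/LMM equivalence holds exactly only for
balanced designs; with severe imbalance the `lmm` method is the better
estimator and the cell-mean contract no longer applies. Diet metrics are
order-level; within-order variation in prey quality is invisible at this
resolution. Territory-level links rest on 8 observations in the nominal
design and are correlational; the package reports them with raw p-values
and an explicit caveat rather than implying confirmatory strength.
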