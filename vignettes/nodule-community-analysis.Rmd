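---
title: "Methods: community analysis of nodule-field 16S surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community analysis of nodule-field 16S surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodulecomm)
```

This vignette is the package's own account of its methods: the models and
procedures, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the design choices made where the design was
genuinely open. It states no empirical result that the test suite does not
itself compute.

## The study design the package assumes

An abyssal nodule-field survey samples three habitats — the **water
column** (here split into epipelagic 0–200 m, mesopelagic 200–1,000 m,
bathypelagic 1,000–3,000 m and abyssopelagic zones; the zone boundaries are
configurable because survey conventions differ, and some reports use a
300 m epipelagic bound), five **sediment layers** (0–5, 5–6, 6–8, 8–10,
15–18 cm), and the **nodules** — across several study areas, typically
exploration-contract strata plus a protected reference area. The unit of
analysis is the post-clustering OTU count table (OTU × sample, with SILVA
style semicolon lineages); read-level processing (quality filtering,
clustering, taxonomy assignment) is upstream and out of scope.

## Preprocessing rules

Two cleanup rules are applied in a fixed order (lineage filter first; the
order is irrelevant under the row-removal reading below, but it is fixed
and logged):

1. **Decoy lineages.** Bacteria-targeted 16S primers co-amplify
   chloroplast and archaeal sequences. Any OTU whose lineage matches a
   configured case-insensitive substring (defaults `"Chloroplast"`,
   `"Archaea"`) is removed. Substring matching on the full lineage is the
   simplest rule that covers SILVA-style strings, where "Chloroplast"
   appears at class rank.
2. **Blank subtraction.** Every OTU with at least one read in an
   extraction-blank (`habitat = "control"`) sample is removed *entirely*,
   in all samples. We read "subtracting all hits of OTUs found in the
   blank" as removing the OTU, not decrementing counts: a taxon observed in
   a negative control is not trustworthy anywhere, and a single blank read
   against thousands of real reads says nothing about which real reads are
   contamination. A per-count subtraction mode
   (`blank_mode = "subtract_counts"`) exists for sensitivity analysis.

Normalization divides each OTU's count by its sample total. Rarefaction
draws exactly `depth` reads per sample *without replacement* (multivariate
hypergeometric), one draw per sample, with a mandatory logged seed; samples
below the depth are dropped, never padded — the standard practice where a
survey protocol is silent. Alpha diversity is computed on a single rarefied
draw, matching how such surveys report it.

## Diversity and ordination

* **Shannon** uses natural logarithms. Survey reports rarely state the
  base; indices near 7–8 at tens of thousands of OTUs are only consistent
  with nats, so nats is the default and `base` is an argument.
* **Chao-1** uses the bias-corrected form
  `S_obs + F1(F1−1)/(2(F2+1))`, finite when doubletons are absent. The
  classical `S_obs + F1²/(2F2)` is available behind a flag (and itself
  falls back to the corrected form at `F2 = 0`, where it is undefined).
* **Bray-Curtis** is computed on relative abundances via
  `2Σmin(x,y) = Σx + Σy − Σ|x−y|`, so the pairwise work is one Manhattan
  distance; an oracle test checks the naive double loop.
* **nMDS** minimizes Kruskal stress-1 with monotone disparities fitted by
  pooled-adjacent-violators. Tied dissimilarities use the primary (weak)
  approach: within a tied block the configuration distances are pre-sorted,
  so ties impose no constraint. Optimization is steepest descent with
  backtracking; a step is accepted only if the freshly computed stress
  decreases, so stress is monotone over accepted iterations. Default 20
  restarts (first start = classical MDS, rest random), `max_iter = 300`,
  `tol = 1e-6` on relative stress improvement; non-convergence is reported
  via `converged = FALSE`, not an error. These optimizer settings are our
  own: nothing in the survey literature pins them down.
* **PERMANOVA** is the one-way pseudo-F partition of squared
  dissimilarities. Multi-factor reports in this literature are reproduced
  by running one factor at a time; no interaction model is implied by the
  published df patterns, so none is fitted. The permutation p-value uses
  the add-one convention `p = (#{F*≥F}+1)/(B+1)`, which guarantees `p > 0`;
  with `permutations = "exhaustive"` (N ≤ 8) every relabeling is
  enumerated and p is the exact tail proportion (the identity permutation
  plays the role of the +1).
* **Two-way ANOVA** for Shannon indices uses Type II sums of squares via
  nested model comparisons, because field designs are unbalanced and Type
  II is the defensible default when the report says only "two-way ANOVA".
  Tukey HSD on the first factor's marginal means uses the Tukey-Kramer
  studentized-range adjustment with the full-model MSE.

## Habitat-specialization classification

From the presence matrix (detected ⇔ ≥ `min_count` reads in ≥
`min_samples` samples of a stratum; defaults 1 and 1 because surveys give
no detection threshold), OTUs are classified:

* **specialist** — detected in exactly one stratum;
* **generalist** — detected in every stratum of a *core set*. The strict
  core (all strata) yields zero generalists on real surveys of this design,
  because deep sediment layers share nothing with the water column; the
  operative core — all water zones, nodules, and sediment layers above
  6 cm — is therefore the default (`rule_set = "operative"`), and the
  choice is recorded in the classification's attributes;
* **moderate generalist** — detected in ≥ 2 habitats, not a generalist;
* **unclassified** — multi-stratum but single-habitat patterns, which none
  of the three published-style rules covers; forcing them into a class
  silently would misstate the rules, so they are kept visible.

Occupancy is the fraction of non-control *samples* with a detection
(surveys also speak of "sites"; samples are the finer, reproducible unit).
Sequence-contribution percentages are taken over the classified OTUs so
that the four classes sum to 100%.

## The synthetic community generator

The generator exists so every pipeline stage can be tested against planted
truth. Its stated world:

* One sample per (area, stratum, replicate); defaults of 4 areas × 10
  strata × 11 replicates ≈ 440 samples plus one extraction blank — the
  scale of the real survey this design mirrors (447 samples).
* Sequencing depth ~ round(Normal(9694.7, 892.7)) truncated at 1 — the
  reported per-sample mean ± sd is all a survey gives, so Normal is the
  minimal model.
* Latent abundance: per-OTU lognormal base (`abund_mu = 0`,
  `abund_sigma = 1.5`, a typical amplicon abundance spread), ×
  `preference_multiplier` (default 50) in the OTU's preferred strata, ×
  `off_habitat_epsilon` (default 0.01) elsewhere. Specialists prefer one
  stratum; moderate generalists prefer strata in exactly two habitats;
  generalists prefer the operative core set; contaminants ride at leakage
  level everywhere and dominate the blank; decoys carry chloroplast or
  archaeal lineages.
* **Export coupling:** a fraction (default 0.3) of epipelagic specialists
  is additionally seeded onto nodules at `export_scale` (default 0.1)
  times their preferred-stratum abundance — never into sediments —
  emulating vertical export of photic-zone cells that associate with
  nodules. Epipelagic specialists always carry cyanobacterial lineages and
  no other planted bacterial class does, so the photic-zone group is
  identifiable by the `"Cyanobacteria"` lineage pattern after decoy
  removal.
* Counts are one multinomial draw per sample over the normalized latent
  abundances. A Dirichlet-multinomial option (`overdispersion` θ > 0
  multiplies each latent cell by an independent Gamma(1/θ, 1/θ) factor) is
  exposed, default off; it is the standard way to add the per-sample
  biological variation a plain multinomial lacks, and it is what makes
  "exchangeable, independent OTUs" worlds possible for calibration tests.
* The paired eukaryote table shares sample ids with the bacterial table
  (controls excluded); planted pairs copy the bacterial partner's realized
  per-sample latent abundance times `exp(Normal(0, pair_noise_sigma))`;
  the eukaryote draw uses a seed derived as `seed + 1` so the two tables
  are jointly reproducible but not identical streams.

What the generator does **not** emulate: read-level artifacts (chimeras,
clustering errors), taxon-abundance correlations within a sample beyond
compositional closure, spatial autocorrelation between areas, and
abundance-dependent detection bias. A green recovery test therefore
establishes that the *classification logic* inverts the *stated
preference model* — not that the model captures every feature of real
surveys.

Two consequences of compositional closure are worth stating because tests
encode them. First, a planted 16S–18S pair's observed rank correlation
stays somewhat below 1 even at saturating depth and vanishing pair noise,
because the two tables' per-sample totals fluctuate independently; the
pair tests assert strong coupling (ρ > 0.8) rather than the idealized
limit. Second, in habitat-structured communities, OTUs sharing a
preference pattern co-occur without any planted link — the network's FDR
guarantee is therefore stated (and tested) for exchangeable communities
(`preference_multiplier = 1`, overdispersion on), which is the standard
framing for co-occurrence benchmarks; on structured data the network is a
screening tool, as it is in the field.

## Co-occurrence network

No survey in this literature specifies its network method, so the
implementation is a declared reconstruction: Spearman's ρ for every
cross-table OTU pair over shared samples (≥ 8 required), permutation
p-values, Benjamini-Hochberg q over all tested pairs, and retention at
`q ≤ fdr_alpha` and `|ρ| ≥ min_abs_rho`. `min_prevalence = 0.2` excludes
OTUs detected in under 20% of shared samples, because double zeros
manufacture spurious correlation in compositional data. The permutation
null draws one shared set of sample permutations and applies it to the
second table — for each pair this is exactly the permutation-of-one-vector
null, and sharing the permutations lets the whole ρ matrix be computed as
one rank-matrix cross-product per permutation.

One numerical constraint matters in practice: the smallest attainable
permutation p is `1/(B+1)`, and BH at level α over m pairs retains k
discoveries only if their p ≤ αk/m. Screening m = 10,000 pairs for ~20
edges at α = 0.05 therefore needs `B ≥ ~20,000`; with too few permutations
entire seeds return zero edges not because the signal is weak but because
the p-grid is coarser than the BH threshold. The FDR acceptance test uses
B = 19,999 for exactly this reason.

## Calibration and recovery worlds used by the acceptance tests

Where a criterion fixes parameters (leakage 0.01, depth 5,000, multiplier
100 carried over from the noise-free clause; PERMANOVA effect at
multiplier 5 with 10 samples per habitat), those are used as stated. Where
the world is otherwise free, the tests use a compact single-area benchmark
design (3 replicates per stratum) — the configuration a methods paper
would use for a parameter-recovery experiment — chosen once, before
measuring. Under leakage, misclassification is dominated by rare
off-habitat detections of high-abundance specialists, which scales with
the number of off-habitat samples; a recovery benchmark at depth 5,000 is
informative precisely at this compact scale.

## Pipeline determinism

`run_pipeline()` consumes one strict JSON config (unknown keys are
rejected) with exactly one of an `input` block or a `simulate` block.
Every stochastic stage's seed is derived from the global seed by fixed
offsets (+1 rarefaction, +2 nMDS, +3 PERMANOVA, +4 network) and echoed in
`run_report.json`, which contains no wall-clock fields — so a rerun with
the same config is byte-identical, and the determinism test hashes every
artifact. Figures are deliberately out of scope: all pipeline surfaces are
tabular or JSON.

## Known limitations

* The one-way PERMANOVA cannot reproduce multi-factor df patterns from
  reports that never specify their model matrices; factors are tested one
  at a time.
* Chao-1 is reported per sample like the other alpha metrics; some survey
  texts group it with beta diversity, a labeling this package does not
  adopt or resolve.
* The co-occurrence network makes no compositional correction
  (SparCC-style methods are out of scope); its guarantees are stated for
  exchangeable communities.
* Specialist sequence-contribution percentages depend on the detection
  rule; with `min_count = 1` a single stray read reassigns an OTU's class,
  which is why `min_count`/`min_samples` are first-class parameters.
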