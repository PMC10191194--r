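---
title: "Models and methods behind mycoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mycoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycoflux)
```

`mycoflux` analyses ¹³CO₂ pulse-labelling microcosm experiments on
ectomycorrhizal symbioses: how much carbon does a fungal isolate acquire
from its plant host, which growth traits co-vary with that flux, and which
transcripts track it. This vignette is the package's own account of the
models it fits, the defaults it chooses and why, and what its validation
on synthetic data does and does not establish.

## The two-pool isotope mixing model

After a ¹³CO₂ pulse, plant leaves are strongly enriched in ¹³C while
free-living mycelium (FLM) remains at the unlabelled baseline. Carbon in
the extra-radical mycelium (ERM) of a symbiotic plate is modelled as a
two-pool mixture: a fraction `f` of host-derived carbon at the leaf
enrichment level, and `1 − f` of fungus-fixed carbon at the FLM baseline.
Solving the mixture for `f` gives

$$\%C_{symbiosis} = \frac{^{13}C_{ERM} - ^{13}C_{FLM}}
  {^{13}C_{leaf} - ^{13}C_{FLM}} \times 100$$

and scaling by colony composition and size gives the absolute amount
retained in hyphal tissue,

$$C_{symbiosis}\,[\mathrm{mg}] = \frac{\%C_{symbiosis}}{100} \times
  \frac{\%C_{fungal}}{100} \times \text{fungal biomass}\,[\mathrm{mg}].$$

Assumptions worth stating explicitly:

* **Two pools only.** Every ERM carbon atom is either at leaf enrichment
  or at FLM baseline. Isotopic fractionation during transfer and dilution
  of the leaf signal along the transport path are ignored; both would make
  the estimate conservative.
* **Retained carbon.** Respired and exuded carbon never appears in the
  ERM, so `C_symbiosis` is a lower bound on transfer, not a flux.
* **Units.** Both percentages are treated as fractions (divided by 100) so
  the product carries the biomass unit, mg C. The second equation is
  otherwise unit-ambiguous.
* **Pairing.** Each ERM value is paired with the leaf value from the same
  plate (`leaf_pairing = "plate"`), because the plate is the experimental
  unit: its leaf records the labelling its fungus actually saw. Pairing
  against the isolate's mean leaf value is available
  (`leaf_pairing = "isolate_mean"`) and coincides when leaf enrichment is
  homogeneous within an isolate.

Mixing fractions below 0% or above 100% can arise from measurement noise
around an extreme true value. They are flagged but **not clamped**:
truncation would bias isolate means toward the interior.

### Outlier filtering

Atom% values are filtered once (no re-iteration) per isolate × tissue role
with the interquartile-range test: type-7 (linearly interpolated)
quartiles, closed fences `[Q1 − k·IQR, Q3 + k·IQR]`, `k = 1.5`. The closed
fences mean a constant vector loses nothing (IQR = 0 puts every value *on*
the fence). Two consequences of small-sample Tukey fences deserve note:

* With 4–5 replicates of genuinely Gaussian noise, roughly 5–10% of values
  fall outside the fences, so a few clean measurements are sacrificed per
  experiment. That is inherent to the method, not a defect; the filter
  targets gross instrument- or contamination-level errors that would
  otherwise dominate an isolate mean.
* When an ERM value is removed, its plate's pair simply drops out of the
  per-replicate table; an error is raised only for ERM replicates that
  never had a leaf sample in the input, which indicates malformed data
  rather than filtering.

Groups with fewer than 4 values are passed through unfiltered (quartiles
of 3 values carry no outlier information).

## Growth traits

* **Colonization %** = 100 × colonized tips / tips in contact, from
  symbiosis plates.
* **Hyphal density** (mg/cm²) = colony dry biomass / colony area at
  harvest, from fungus-only plates.
* **Radial growth rate** (% area/day): the unit invites two readings, and
  we chose *percent increase relative to the week-2 colony area per day*,
  `100 × (A₄ − A₂)/A₂ / days`, because the week-2 area is the colony state
  at plant contact and the rate is meant as a proxy for growth during
  symbiosis. The alternative normalization by the agar inoculation-block
  area is available (`baseline = "agar_block"`). The day count between
  marking and harvest is nominally 14 and configurable.

### ANOVA, Tukey HSD and compact letters

Per-trait group comparisons use a one-way fixed-effects ANOVA followed by
Tukey's HSD on all pairs (studentized-range based; the Tukey–Kramer
correction applies automatically for unbalanced 4–5-replicate designs).
The pairwise decisions are summarized with the insert-and-absorb compact
letter display: start with one letter column containing all groups; for
each significantly different pair, split every column containing both and
delete columns absorbed by (subsets of) others. By construction, two
groups share a letter iff no significant difference separates them.
Letters are assigned in order of decreasing group mean, so the
largest-mean group reads "a". Group labels may not contain `-`, which
delimits contrast names.

### PCA of trait means

`pca_traits()` works on per-isolate means. Variables are log-transformed
(natural log of value + ε, ε = the variable's smallest positive value ×
10⁻³, so exact zeros — e.g. a near-zero-biomass isolate — stay finite
without distorting the rest of the scale), centered, and by default scaled
to unit variance, because mg, µm and %/day are incommensurate; covariance
PCA is one flag away. Components carry a deterministic sign convention
(largest-magnitude loading positive), so runs are comparable. Variance
fractions always sum to 1 and are checked in the test suite against an
independent eigen-decomposition of the covariance matrix.

### Trait–carbon correlations

`trait_c_correlation()` computes Pearson's r with its two-tailed t-test.
The `paired` flag documents the design: replicate-level pairing is valid
only for traits measured on the same plates as the carbon values
(colonization); traits from fungus-only plates are correlated against
per-isolate means.

## Expression screen

* **Filter.** A transcript is "expressed" if its within-condition mean raw
  count reaches the organism threshold (plant 10, fungus 5) in at least
  one condition. Filtering precedes normalization.
* **Normalization.** Median-of-ratios size factors: per-transcript
  geometric means over transcripts positive in every sample form the
  reference; each sample's factor is the median of its count/reference
  ratios. The estimator is implemented directly (and is checked against
  the DESeq2 implementation in the tests); no dispersion estimation or
  differential testing is involved anywhere in the pipeline — only the
  normalization is needed.
* **Correlation and selection.** Each transcript's normalized counts are
  correlated with per-isolate mean carbon. Default pairing is
  replicate-level (n = isolates × replicates = 27): every count sample is
  paired with its isolate's mean C. This uses all count data; the
  alternative (`mode = "averaged"`, n = 9 condition means) is one argument
  away, and critical values always use the effective n of the chosen mode.
  The top/bottom "percentile" is a count rule: ⌈0.01·n⌉ transcripts per
  tail (247 for n = 24,615; 130 for n = 12,959), with ties broken by input
  order and the reported q0.99/q0.01 being the least extreme selected
  values. Zero-variance transcripts get r = 0, a flag, and are never
  selected. Significance is flagged against
  `r_crit = t*/√(t*² + n − 2)` — the textbook critical-value table in
  closed form.
* **Fold changes and clustering.** Heatmap matrices divide condition means
  of normalized counts by the across-isolate baseline (uninoculated
  control excluded from the baseline but displayed as an extra column) and
  take log₂. A pseudocount of 1 normalized count is added to numerator and
  denominator *only* for transcripts with a zero condition mean, leaving
  typical values untouched. Row/column ordering uses Euclidean distances
  with average linkage (complete linkage by flag); `hclust`'s
  deterministic agglomeration makes leaf orders reproducible.
* **Categories.** Functional-category tallies match annotations against a
  case-insensitive keyword lexicon covering carbohydrate biosynthesis and
  catabolism, defence, growth/cell-cycle, host–fungus interaction,
  signalling, stress, transcription regulation and transport. The default
  keyword lists are this package's own choices and are fully replaceable;
  tallies are reported as integer-rounded percentages and one transcript
  may count toward several categories.

## The synthetic-data generator

The generator exists so that every stage has a recoverable target. It
emulates the study design: 9 isolate conditions plus an uninoculated plant
control, 3 transcriptome replicates per condition, 5 isotope/growth
replicates and 3 FLM plates per isolate, and expressed-set sizes of 24,615
plant and 12,959 fungal transcripts.

Key defaults, chosen once:

* **FLM baseline 1.08 atom%** — the natural ¹³C abundance; leaves after
  labelling sit in 2.5–4.5 atom%, a strong but not saturating enrichment.
  Each isolate receives one labelling level (its plates share a chamber
  pulse); within-isolate spread is measurement noise (SD 0.02 atom% by
  default, zero for exact-inversion checks).
* **True carbon amounts** default to fixed fractions 0.10–0.80 of each
  colony's carbon capacity (%C × biomass, with biomass 0.6–1.3 mg and
  36–42% C, the magnitudes of four-week *Pisolithus* colonies), so mixing
  fractions span a realistic 10–80% gradient and can never exceed 100%.
* **Counts** are negative binomial (dispersion 0.1 — typical RNA-seq
  overdispersion; Poisson at 0) with log-normal base means, uniform
  per-sample size factors in [0.5, 2] (rescaled to geometric mean 1, the
  scale on which median-of-ratios factors are identified), and a tenth of
  transcripts drawn near zero so the expression filter has real work.
  Planted transcripts have log mean expression linear in the standardized
  per-isolate carbon vector with slope ±2 by default — the matched signal
  for a Pearson detector on normalized counts.
* **Reproducibility.** Each data family (isotope, growth, counts,
  annotations) draws from an independent stream derived from the master
  seed, so regenerating one family never perturbs another, and the
  caller's RNG state is restored afterwards.

What the generator does **not** emulate: correlated transcript modules,
isolate-specific dispersions, batch effects, compositional (mRNA-pool)
shifts between conditions, and fungal reads bleeding into control plates.
Recovery results on synthetic data therefore demonstrate correctness of
the arithmetic and sound behaviour under idealized noise — not performance
guarantees on real sequencing data.

## Validation scope and problem sizes

The test suite checks, among others: exact inversion of the mixing model
on noise-free data (≤ 10⁻¹⁰ mg); exact removal of injected gross outliers
over 100 noise-free fixtures; the median-of-ratios hand example
(2,4,6 vs 4,8,12 → 1/√2, √2) and ≤ 1% recovery of known multiplicative
library effects; tail counts 247/24,615 and 130/12,959 against a
brute-force sort; letter displays against the multcomp reference on 50
random fixtures; and ≥ 90% recovery of planted transcripts (effect 2,
dispersion 0.1) with ≤ 2% null contamination over 20 seeds at 25,000
transcripts. Simulation sizes in routine tests are a few hundred to a few
thousand transcripts — large enough for the percentile rule to be
meaningful, small enough that the whole suite runs in well under a minute.

## Known limitations

* The IQR filter is liberal at n = 4–5 (see above); downstream SEs
  reflect the post-filter replicate count.
* The screen's correlation is linear; transcripts responding
  monotonically but non-linearly to carbon rank lower than matched linear
  responders.
* Compact letters become ambiguous displays when many overlapping group
  subsets exist; the pairwise table (`tidy()`) is the authoritative
  record.
* `category_tally()` is keyword matching, not ontology inference;
  annotation vocabularies differing from the lexicon's keywords need a
  custom lexicon.
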