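---
title: "Defining organellar importomes from knockdown proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defining organellar importomes from knockdown proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(importomics)
```

## The measurement model

An importome experiment couples inducible knockdown of an essential
protein-import component (e.g. the pore-forming subunit of an outer
membrane translocase, or the sulfhydryl oxidase of the intermembrane-space
disulfide relay) with quantitative mass spectrometry of the organellar
fraction. Proteins that depend on the targeted machinery are depleted in
induced (+Tet) relative to uninduced (−Tet) cells; co-purifying
contaminants and machinery-independent residents are not. Each biological
replicate yields one heavy/light isotope ratio per protein (SILAC or
dimethyl labelling); replicate designs include a *label switch* — swapping
which condition carries the heavy label — so systematic labelling biases
cancel.

The package models a protein's oriented log2 (+Tet/−Tet) ratio in
replicate $j$ as

$$ y_{ij} = \beta_i + \varepsilon_{ij}, \qquad
   \varepsilon_{ij} \sim N(0, \sigma^2_i), $$

with $\beta_i < 0$ for machinery-dependent proteins and $\beta_i = 0$
otherwise. The per-protein inference is deliberately simple — a mean and a
two-sided one-sample Student $t$-test against 0 with
$\mathrm{df} = n_i - 1$ — because the classification burden is carried not
by the $p$-value but by a data-calibrated ratio threshold (below). No
variance moderation, normalisation or imputation is applied: the search
engine's normalised ratios are taken as given, and an absent ratio means
"not quantified", never "unchanged".

### Orientation and filtering

Raw H/L ratios are oriented at read time: $\log_2(\mathrm{H/L})$ where the
induced condition is heavy, $-\log_2(\mathrm{H/L})$ where it is light.
Zero or negative raw ratios are rejected as corruption rather than
coerced. The default filter demands at least two peptides (one unique) and
quantification in at least two replicates. For gradient-purified organelle
data an optional *single-peptide rescue* admits proteins with one unique
peptide when they are quantified in **all** replicates and identified by
MS/MS spectra (not match-between-runs transfer) in at least two — genuine
low-abundance organellar residents would otherwise be discarded wholesale.
Failing proteins are kept and flagged, never dropped, so downstream
accounting conserves counts.

### Degenerate cases

With $n_i < 2$ the test is undefined and the $p$-value missing. A zero
sample variance yields $p = 1$ when the mean is 0 and $p = 0$ otherwise —
the limit of the $t$ statistic — which keeps volcano plots computable on
quantised toy data.

## The dual-reference F1 threshold scan

The central calibration step asks: *which mean-ratio cutoff best separates
known organellar from known non-organellar proteins in this very
dataset?* Two curated, disjoint reference proteomes are required. For a
candidate threshold $\theta$ the depleted-side confusion counts are

* TP — positive-reference members with mean $\le \theta$,
* FP — negative-reference members with mean $\le \theta$,
* FN — positive-reference members with mean $> \theta$,

and $F_1(\theta)$ is the harmonic mean of precision
$\mathrm{TP}/(\mathrm{TP}+\mathrm{FP})$ and sensitivity
$\mathrm{TP}/(\mathrm{TP}+\mathrm{FN})$. The negative reference is scored
on the mirrored call (mean $> \theta$). Proteins in neither set — the
unlabeled pool actually being classified — never enter the counts. The
positive-curve argmax is $t_2$, the negative-curve argmax $t_1$, and the
adopted threshold is $\min(t_1, t_2)$: the more stringent cut for calling
depletion.

Numerical choices, all of which matter at the margins:

* **Grid.** Thresholds advance in 0.01 steps (configurable), carried at
  the matching decimal precision; comparisons use $\le$ with a $10^{-9}$
  epsilon so a mean equal to a grid value counts as below it despite
  binary-float representation.
* **Start rule.** The default follows the literal protocol: each curve
  starts at the lowest ratio with at least one TP and one FP. This skips
  perfectly separating thresholds (where FP = 0), so a `start_rule =
  "full"` option spans all observed means with precision defined as 1
  when no positive call is made. The default stays literal for
  reproduction of the protocol.
* **Candidates.** Whether the original protocol evaluated the 0.01 grid
  or the observed mean ratios themselves is ambiguous; the grid reading
  is the default and `candidates = "observed"` is available. On dense
  data the two agree to within a few grid steps.
* **Ties.** Equal maximal $F_1$ breaks toward the most negative grid
  value — the conservative choice for importome calling.

## Importome calls

A protein is *imported* iff it passes the filter, its mean log2 ratio is
$\le$ the threshold (boundary included) and its $p$-value is $< 0.05$
(strict); the asymmetry of the gates follows the convention that the
ratio criterion is stated as "less than or equal to" and the significance
criterion as "less than". No multiple-testing correction is applied to
the per-protein $p$-values — the reference-calibrated threshold carries
the specificity, and the false-positive behaviour is checked against the
negative reference instead (the overlap summary). Imported proteins
absent from the positive reference are the *new candidates*;
negative-reference members called imported are flagged with their
membership but retained, since a reference list can itself be wrong.
Experiments without reference proteomes (whole-cell lysates, strong
pathway-specific knockdowns) use fixed fold-change calls instead
(`call_fixed_fold()`, cut at $\pm\log_2(\mathrm{fold})$).

## MIA substrate prediction

Classical substrates of the intermembrane-space disulfide relay are small
proteins with twin Cx3C or twin Cx9C motifs. The scanner finds
occurrences of C, exactly 3 (or 9) non-cysteine residues, C — greedy,
left-to-right, non-overlapping, resuming after each closing cysteine: a
cysteine cannot serve two motifs, because overlapping counting would call
single cysteine runs "twin". A protein is predicted a substrate when its
average mass is strictly below 50 kDa and it carries at least two motifs
*of the same type* (the classical helix–loop–helix arrangement); the
sentence "two or more Cx3C or Cx9C motifs" is ambiguous, so
`count_mode = "total"` provides the cross-type reading. Masses are sums
of average residue masses plus one water (18.0153 Da); `X` contributes
the mean of the twenty standard residues and sequences over 10% `X` are
flagged as unreliable. Domain-similarity substrate lists (from external
Pfam/InterPro searches) are joined from user-supplied ID lists rather
than recomputed.

## Enrichment statistics

Overrepresentation of predicted substrates or annotation terms in a hit
set uses the two-sided Fisher's exact test (all tables as improbable as
the observed one) with Benjamini–Hochberg correction across tested terms.
The background is always *all quantified, filter-passing proteins of the
same experiment*, never the genome — quantifiability is itself biased.
Terms with no hit-set member are not tested, shrinking the correction
family; their count is recorded in the result's metadata. Term lists can
first be reduced to a slim vocabulary by closing each term over its
ancestors and intersecting with the slim set; this is the classic
per-term Fisher approach, not a decorrelating (elim-style) algorithm, and
adjusted p-values are reported alongside raw ones so the family size is
transparent.

## The synthetic-data generator

`simulate_quant_dataset()` emulates exactly the statistical structure the
pipeline assumes: organellar proteins draw a protein-level effect from
$N(\mu_e, \sigma_e^2)$, others sit at 0; replicate ratios add
$N(0, \sigma_r^2)$ noise; cells go missing independently; raw H/L columns
are emitted with label-switched replicates inverted; peptide counts
follow $1 + \mathrm{NB}(\mu, k)$ so single-peptide proteins occur and the
rescue path is exercised; and each class contributes a fixed fraction of
its members to its reference set, leaving an unlabeled pool (the stand-in
for contaminants and unannotated proteins) to be classified. The defaults
— 800 + 800 proteins, 4 replicates with a switch on r2/r4,
$\mu_e = -1.5$, $\sigma_e = 0.5$, $\sigma_r = 0.4$, 5% missing cells, 60%
reference coverage — describe a clearly separated knockdown with
realistic replicate scatter; they were fixed once, as the package's
default study conditions.

What the generator does **not** emulate, and hence what passing tests do
not show about real data: ratio compression, intensity-dependent
missingness, protein–replicate interactions, correlated references,
shared-peptide protein groups, or contaminant populations with
systematic non-zero shifts. Results on real tables depend on the curation
quality of the reference proteomes in a way no simulation can certify.

`simulate_proteome_sequences()` plants two disjoint same-type motifs with
cysteine-free flanks in substrate sequences (linker lengths that would
create accidental cross-type motifs are excluded) and suppresses
cysteines elsewhere, so scanner output can be compared coordinate-exact
against the planted truth.

## Verification strategy and problem sizes

The test suite checks every statistical component against an independent
oracle: the scan against brute-force confusion counting at every grid
point (100 random datasets of up to 200 proteins), Fisher p-values
against exhaustive hypergeometric enumeration (all 2×2 tables with
margins ≤ 12), the $t$-test against `stats::t.test` and against its
nominal type-I error on 10,000 null proteins, BH against its step-up
arithmetic and null false-discovery behaviour, and the motif scanner
against a character-walking reimplementation on 1,000 cysteine-rich
random sequences. Recovery on the default synthetic scenario is compared
with analytic normal-overlap lower bounds (Fréchet-joined ratio-gate and
noncentral-$t$ power terms, averaged over the effect and replicate-count
distributions) minus three Monte-Carlo standard errors, and the chosen
threshold is required to fall between $\mu_e$ and 0 in at least 99 of 100
seeded runs. These sizes keep the full suite around a minute on one core
while leaving each check statistically sharp.

## Known limitations

* The one-sample $t$-test assumes approximately normal log-ratios;
  heavy-tailed contamination inflates $p$-values but is partially
  absorbed by the threshold calibration.
* Reference-set errors propagate directly into $t_1$/$t_2$; the scan has
  no robustness machinery beyond the dual-reference construction itself.
* The fixed 0.01 grid bounds threshold resolution; `candidates =
  "observed"` removes the bound at the cost of a data-dependent
  candidate set.
* Protein groups are treated as atomic accessions; shared-peptide
  ambiguity must be resolved upstream.
* The enrichment module's per-term Fisher tests are not decorrelated
  across the term hierarchy; nested slim terms yield correlated records.
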