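---
title: "Methods: protein-abundance-corrected Kbhb quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: protein-abundance-corrected Kbhb quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbhbatlas)
```

## The problem

A modified peptide's mass-spectrometric intensity is the product of two
biological quantities: the abundance of its parent protein and the
fraction of that protein carrying the modification (the stoichiometry).
In a starvation experiment, where the proteome itself is extensively
remodeled, a site whose raw intensity doubles may simply sit on a protein
whose expression doubled. This package's central computation is the
two-layer normalization that separates these signals, followed by the
descriptive and interpretive layers (landscape, motif, enrichment,
structure) that a site-level study reports.

## The correction model

Let $I_{fs}$ be the linear-scale intensity of feature $f$ in sample $s$.
Both the site table and the proteome are first reduced to *relative*
values by center-scaling,

$$R_{fs} = \frac{I_{fs}}{\overline{I_{f\cdot}}},$$

with the mean taken over the samples where $f$ is valid, so each row of
$R$ averages exactly 1 (asserted exactly in the tests). The corrected
modification level of site $f$ with parent protein $p(f)$ is the
element-wise ratio

$$M_{fs} = \frac{R^{\mathrm{site}}_{fs}}{R^{\mathrm{prot}}_{p(f)s}}.$$

If the site's intensity tracks its parent exactly — pure expression-driven
change — $M$ is constant at 1. A genuine stoichiometry change survives
division. Differential testing then applies Student's pooled-variance t
to $\log_2 M$, with fold change computed as the ratio of linear-scale
group means, and classifies at nominal $p < 0.05$ together with
$|\log_2 \mathrm{FC}| > 0.585$ (1.5-fold). BH-adjusted p values are
reported alongside but do not enter classification; with n = 4 per group
the nominal-p-plus-fold-change rule trades specificity for sensitivity,
and the type-I error of the composite rule is checked by simulation
rather than assumed.

Assumptions worth stating explicitly:

* **Measurement noise is multiplicative and roughly log-normal**, so
  t-testing log2 values is exact under the generator and approximate on
  real data.
* **Equal group variances** (Student rather than Welch). With 4 vs 4
  replicates the pooled test is the conventional choice and is what the
  classification thresholds were calibrated around.
* **The parent protein is correctly assigned.** Rows listing several
  accessions (shared peptides) are assigned to the first listed accession
  with a warning; no razor-protein reassignment is attempted.

## Order of operations

Quantile normalization is applied to the **log2 proteome LFQ matrix
only**; the site table is normalized by center-scale plus parent
correction, not quantile-normalized (a `quantile_normalize_sites` flag
exposes the alternative). The proteome's relative values for the
correction are computed from the quantile-normalized matrix
back-transformed to the linear scale. Missing values are never imputed:
zeros, empty cells and NaN in the input tables all parse as missing, the
≥ 3-of-4 validity filter controls how much missingness reaches the
statistics, and features testable in only one group (≥ 3 valid vs ≤ 1)
are emitted in a separate presence/absence report rather than forced into
the up/down classes.

## Tunable parameters

| Parameter | Default | Units / scale | Rationale |
|---|---|---|---|
| `min_valid` | 3 | replicates | valid in ≥ 3 of 4 replicates in ≥ 1 group |
| `loc_prob_min` | 0.90 | probability | site localization confidence cutoff |
| `min_peptide_len` | 7 | residues | shortest identifiable tryptic peptide |
| `alpha` | 0.05 | probability | nominal significance level |
| `fc_threshold` | 0.585 | log2 | 1.5-fold change, `log2(1.5)` to 3 decimals |
| `distance_cutoff` | 5.0 | Å | heavy-atom contact distance for "near" |
| `conservation_min` | 0.85 | score in [0,1] | high-conservation flag |
| `flank` | 7 | residues | ±7 window, 15-mer centered on K |

Motif extraction defaults (`min_occurrences = 20`, `binomial_p = 1e-6`)
follow the original motif-x conventions and are exposed as arguments.

## The synthetic-data generator

`generate_dataset()` emulates the study design the pipeline targets: two
groups × four biological replicates, per-feature base abundance
$\log_2 I \sim N(25, 2^2)$, multiplicative replicate noise with CV 0.2,
and missingness at 5% (completely at random by default; an
intensity-dependent logistic mode exists because the validity filter only
matters under missingness). Site intensities are built as *the same
per-sample parent-protein draw that populates the proteome table* times a
per-site stoichiometry factor times site-level log-normal noise — the
construction that makes "protein-confounded" sites (constant
stoichiometry on a changing parent) behave exactly as they do in real
data: raw intensities shift with the parent, corrected values do not.

Default proportions mirror the landscape the pipeline is meant to
summarize: ~41% single-site proteins and ~14% with more than five sites;
an 8:1 up:down ratio among true stoichiometry changes
(`frac_sites_up = 0.08`, `frac_sites_down = 0.01`); compartment
probabilities (nucleus 16.9%, cytoplasm 35.9%, mitochondria 14.0%, other
33.2%); and an aspartate planted at the +1 flank of upregulated sites
with probability 0.6. These are presentation defaults, not fitted values:
no per-feature variance estimates exist for the real data, so the CV and
effect sizes are stated assumptions.

Two structural choices deserve their own paragraphs:

* **Direction of protein changes.** Parents of confounded sites shift
  *up* (so confounded sites rise with them), while changed background
  proteins shift *down*, reflecting the predominance of protein
  downregulation under starvation. This matters numerically: if all
  planted protein changes pointed the same way, quantile normalization —
  which forces every sample onto a common distribution — would
  redistribute the net shift onto unchanged proteins and leak a small
  systematic bias into every corrected ratio. With mixed directions the
  simulated proteome is near-balanced and the corrected null is centered.
  On real data with a strongly one-sided proteome, the same mechanism is
  a genuine caveat of quantile normalization, not of the correction.
* **Truth-class disjointness.** Confounded status is assigned at protein
  granularity (whole proteins are flipped until the requested site
  fraction is covered), and true up/down sites are planted only on
  unchanged parents, so the four site classes are mutually exclusive and
  the ledger covers every feature exactly once.

What the generator does **not** emulate: peptide-level interference and
co-isolation, retention-time or batch structure, correlated noise between
the site and proteome runs beyond the shared parent draw, shared/razor
peptide ambiguity, and real sequence composition (flanks are uniform over
the 20 canonical residues except planted motifs). Passing tests therefore
demonstrate that the *computations* are correct and that the correction
removes parent-driven confounding under realistic noise — not that any
particular biological dataset will behave as cleanly.

## Numerical choices

* **Quantile normalization** builds the reference distribution as the
  row-wise mean of each column's empirical quantile function evaluated at
  mid-rank probabilities $(i - 0.5)/n$; columns with unequal numbers of
  missing values are matched by linear interpolation on the quantile
  scale. Ties receive the mean of the reference values at their tied
  ranks. On complete matrices this reduces exactly to
  sort / average / map-back (oracle-tested, and cross-checked against an
  independent implementation).
* **Degenerate t inputs**: zero pooled variance with equal means gives
  t = 0, p = 1; with unequal means the p value is reported as 0 with a
  `degenerate` flag rather than an error, so all-zero/all-present
  patterns surface instead of crashing a batch run.
* **Fisher position tests** are two-sided and exact; padding characters
  from window truncation never count as residues, and positions where
  every foreground window is padded are skipped rather than scored.
* **Conservation** substitutes 1 − normalized Shannon entropy
  (gap-excluded, columns > 50% gaps scored absent, invariant columns
  = 1.0) for maximum-likelihood evolutionary rate estimation. It is a
  monotone, exactly testable proxy on the same [0, 1] scale, and the
  0.85 prioritization cutoff is kept on this scale; rate-based scores
  from external tools can be swapped in wherever a
  `conservation_profile` is accepted.
* **Compartment ties** resolve by the priority mitochondria > nucleus >
  cytoplasm > other, favoring the most specific organelle; the priority
  is an argument.
* **Prioritization ties** order by conservation descending, then minimal
  functional distance ascending.

## Problem sizes

The test suite exercises the statistical properties on simulated studies
of ~2,000 sites on 700 proteins (plus an equal background proteome), the
scale at which the binomial error of a 5% type-I-error check is ± 0.5
percentage points; smaller fixtures (tens of features) carry the exact
oracle comparisons. The `analysis/` drivers use 800 proteins (~2,300
sites). The full suite and the acceptance script each run in well under a
minute of single-core time.

## Known limitations

* The correction consumes proteome and site measurements from the same
  samples; sites whose parent protein was not quantified are excluded
  (reported as `parent-missing`), not rescued.
* Structural classification trusts the input annotations of functional
  and PTM residues and assumes the site table and structure share residue
  numbering (an offset parameter handles tagged constructs).
* Distances against real predicted structures depend on the model and the
  pocket annotation chosen; the packaged geometries are synthetic
  fixtures with planted distances, useful for validating the machinery,
  not biological claims.
* With n = 4 and nominal-p classification, the up/down lists are
  hypothesis-generating; the BH column is provided for readers who want
  FDR-controlled subsets.
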