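---
title: "Profiling mitochondrial targeting signals against their mature sequences: models and methods"
author: "mtsprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling mitochondrial targeting signals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtsprofiler)
```

## The scientific question

Nuclear-encoded mitochondrial matrix proteins are imported via an
N-terminal mitochondrial targeting signal (MTS) that is cleaved on
arrival, leaving the mature protein. MTSs share almost no sequence
homology and vary enormously in length, yet they all traverse the same
conserved import machinery. One explanation for this diversity is that
the MTS is co-adapted to the protein it imports: physicochemical
features of the mature sequence — above all its charge and its
N-terminal composition and structure — constrain what kind of signal
can import it efficiently. `mtsprofiler` implements the statistical
side of that question: given a dataset of species-labelled
(MTS, mature) sequence pairs, it quantifies each part, correlates the
two quantifications within and across species, and compares the
N-terminal structure of mature sequences attached to extreme (shortest
and longest) signals.

## The per-sequence profile

Each sequence (either part) is summarized by 12 variables:

* **length** — residue count, including unknown residues; length is a
  positional property.
* **charge** — modelled net charge at a configurable pH (default 7.5),
  in elementary charges, from a Henderson–Hasselbalch sum over
  ionizable side chains (D, E, C, Y acidic; H, K, R basic) and, by
  default, the free termini:
  $$ q(\mathrm{pH}) = \sum_{b \in \mathrm{basic}} \frac{1}{1 + 10^{\mathrm{pH} - pK_a(b)}} \;-\; \sum_{a \in \mathrm{acidic}} \frac{1}{1 + 10^{pK_a(a) - \mathrm{pH}}}. $$
  Termini are ionized by default for both parts because the mature
  N-terminus is free after cleavage; the flag is configurable.
* **pI** — the pH at which $q$ crosses zero. $q$ is strictly decreasing
  in pH and the termini guarantee a sign change on $(0, 14)$, so the
  root is unique; it is found by bisection on $[0, 14]$ to a tolerance
  of $10^{-3}$ pH units (at most 60 iterations — the interval halves
  well past the tolerance long before that cap).
* **nine group fractions** — the composition of the sequence under a
  nine-group reduced alphabet: non-polar aliphatic (G, A, V, I, L),
  non-polar aromatic (F, W), non-polar cyclic (P), polar
  sulphur-containing (C, M), polar hydroxyl (S, T), polar aromatic (Y),
  polar acidic-amide (N, Q), acidic (D, E) and basic (R, H, K). The
  groups partition the 20-letter code, so the nine fractions sum to 1.

pKa values are a named, auditable text resource. The default set is the
Bjellqvist set (the model behind the ExPASy Compute pI/Mw service, here
with a single generic N-terminal pKa of 7.5); `emboss` and `lehninger`
are shipped as alternatives and user files can add more. The choice of
set shifts absolute charge and pI values slightly but barely moves their
*ranks*, and every downstream statistic in this package is rank-based
(Spearman) or standardized (PCA), so conclusions are robust to it. The
active set name is recorded in the run manifest.

Unknown residues (X, B, Z, U, O, J) cannot be ionized or classified:
they count toward `length` but are excluded from both the numerator and
denominator of composition fractions and contribute zero charge.
Records with more than 5% unknowns in either part are rejected on load
(configurable) because their chemical profile would be unreliable; the
per-record rejection report is kept on the dataset object.

## The statistical layer

**Correlation grids.** For each species, and pooled over all records,
every MTS variable is correlated against every mature variable with
Spearman's rho (product-moment correlation of mid-ranks, so ties are
handled). The two-tailed p-value uses the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom, which is
what general statistics packages report in the per-species range of
n = 35–85; an exact-null option (via `cor.test`) exists for very small
n. Cells are classed by raw p (`p<0.01`, `p<0.05`, `none`) exactly as
the classic presentation of such grids does; a Benjamini–Hochberg
column is written alongside in the long-format output for transparency
but never changes the class. Cells with fewer than 5 complete pairs
(configurable) or zero variance are reported as not computed rather
than aborting the grid. The minimum is enforced at the grid layer;
`spearmanCell` itself computes from n = 3 so that textbook examples
remain reproducible.

**PCA.** Property tables are standardized and the sample correlation
matrix is eigendecomposed, so eigenvalues sum to the number of
(non-constant) variables and percent variance is eigenvalue divided by
variable count. Loadings are reported SPSS-style (eigenvector times the
square root of the eigenvalue, i.e. variable–component correlations),
unrotated. Components with eigenvalue strictly greater than 1 are
retained by default (Kaiser), with a fixed-k alternative. Constant
columns are dropped with a warning. The 12-variable set, including pI,
is used for every PCA; keeping one variable set for the pairwise and
multivariate analyses makes the two directly comparable.

**Windowed analysis.** The influence of the mature N-terminus is probed
with fixed windows counted from the first residue after the cleavage
site, by default residues 1–40 and 41–80. The windowed table correlates
two MTS variables (length, charge) against the acidic-group fraction of
each window. Mature sequences shorter than the window end are excluded
from that window's statistics (`require_full`): a 41–80 window computed
on a 60-residue protein would not measure the same quantity. A
`truncate` policy is available for exploratory use.

**Secondary structure.** Per-residue helix/strand/other states and a
disorder mask are inputs (upstream predictors produce them), never
predicted here. Within each species the k records with the shortest and
the k with the longest MTSs are selected (k = 10 when the species has
at least 80 records, else 5; ties in MTS length break by lexicographic
record id, making the selection deterministic), and their windowed
structure proportions (windows 1–50 and 51–100, truncated) are compared
with a tie-corrected Kruskal–Wallis test. The degenerate all-identical
case, where the tie correction is 0/0, is defined as H = 0, p = 1.

## The synthetic-data generator

The generator exists so that every stage of the pipeline can be
exercised, and its statistical behaviour measured, without any external
data. Its defaults emulate the scale of curated matrix-protein
datasets:

* five species groups of 85/84/56/35/36 records;
* MTS lengths from a shifted negative binomial (minimum 10, mean 45,
  dispersion 2.5, giving a realistic 10–120+ range);
* mature lengths likewise (minimum 60, mean 360, dispersion 3);
* MTS composition drawn from a Dirichlet with means enriched in basic
  (0.25) and hydroxyl (0.19) groups and deficient in acidic residues
  (0.02), concentration 40;
* mature composition near proteome-average means (acidic 0.122, basic
  0.136, …), concentration 60 — at that concentration the acidic
  fraction varies between records with a standard deviation of about
  0.04, matching the between-protein spread seen in real proteomes;
* segmental secondary structure: geometric segment lengths (means
  H = 9, E = 5, L = 7), state frequencies 0.35/0.20/0.45, and a 0.15
  per-segment disorder probability.

**Induced correlations.** Target rank correlations between an MTS
property and a mature property are induced through a Gaussian copula:
each targeted property gets one latent dimension, and a target
Spearman's $\rho_S$ is converted to the latent Pearson correlation with
the closed form $\rho = 2\sin(\pi\rho_S/6)$, so the generator *solves*
for the latent structure rather than approximating it. A `length`
driver maps its uniform to the length quantile; a `frac_g` driver sets
group g's residue count deterministically to `round(L * qbeta(u, ...))`
of its Beta marginal (a deliberate choice: sampling that count
multinomially instead would attenuate the induced correlation by the
within-sequence sampling noise and bias parameter recovery low); a
`charge` driver tilts the basic count up and the acidic count down with
one shared uniform. Undriven groups remain multinomial draws from the
Dirichlet weights. Residue identity within a group is uniform — every
analysis in the package operates on group fractions, so within-group
identity is immaterial.

The default configuration induces MTS length vs mature acidic fraction
at +0.35 and MTS charge vs mature charge at −0.437. Note one honest
attenuation: when the mature acidic group is owned by the
length–acidic target, the mature charge driver can only tilt the basic
group, so the realized charge–charge correlation comes out weaker than
its nominal target (about −0.30 at the default scale). The per-target
recovery is exact when drivers do not compete (the recovery experiment
below measures a mean estimated rho of 0.40 for a 0.40 target).

**What the generator does not emulate** — and hence what passing tests
do not show about real data: amphipathic helix periodicity and
hydrophobic-moment structure in the MTS; cleavage-site motifs;
covariance between a sequence's length and its composition;
phylogenetic dependence between species; and any coupling between
composition and the secondary-structure annotation. The generator
validates the statistical machinery, not the biology.

## Calibration and parameter recovery

Two whole-stack experiments are part of the test suite and the
acceptance script:

* **Recovery** — with a single induced target (MTS length vs mature
  acidic fraction, $\rho_S^* = 0.4$) at n = 300, the rho estimated from
  the generated *sequences* is unbiased. The sampling standard
  deviation of Spearman's rho at this n and effect size is about 0.053,
  which puts the coverage of the ±0.1 band just above 95%; the
  experiment therefore uses 400 seeded replicates so the Monte-Carlo
  error of the coverage estimate (≈1 point) stays below the margin it
  is measuring.
* **Null calibration** — with no induced targets, MTS and mature
  variables are independent, and about 5% of the 144 grid cells should
  reach p < 0.05. Three 300-record runs (432 cells) are pooled.

Problem sizes throughout the suite (296-record default datasets,
300-record experiments, 400 replicates, 100 random 50-mers for the pI
grid oracle) are the package's own choice of scales at which the
statistics are informative while the whole suite stays quick to run.

## Numerical and design decisions

* pI bisection: interval $[0, 14]$, tolerance $10^{-3}$, monotone
  objective, termini always included (they guarantee the sign change).
* Tie-breaks: extreme-group selection orders by (MTS length, record
  id); all outputs are deterministic functions of their inputs, and
  re-running an analysis reproduces the bundle byte for byte.
* Degenerate inputs: empty input files are errors (they usually mean a
  wrong path), not empty datasets; all-identical Kruskal–Wallis groups
  give H = 0, p = 1; constant PCA columns are dropped with a warning;
  failed correlation cells are reported as not-computed, never fatal.
* Pooled grids are computed across all records in addition to the
  per-species grids, because the headline charge–charge association is
  a pooled quantity; both groupings are always emitted.
* The run manifest records every tunable that affects numbers: pKa set,
  pH, termini flag, windows, minimum pair count, retention rule, group
  sizes and record counts.

## Known limitations

* The charge model is a standard Henderson–Hasselbalch independent-site
  model; it ignores electrostatic interactions between sites and
  position-specific terminal pKa refinements, and proprietary tools
  using richer models will differ in absolute values (rank-based
  statistics make the package's conclusions insensitive to this).
* Secondary-structure annotations are trusted as given; prediction
  reliability scores are not modelled.
* The windowed analysis excludes short mature sequences under the
  default policy, so per-window n varies and is reported with every
  correlation.
* The generator's attenuation of competing-driver targets (above) means
  a multi-target default configuration reproduces patterns, not exact
  coefficients, for targets whose drivers share composition groups.
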