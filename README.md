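# mtsprofiler

Physicochemical profiling of N-terminal mitochondrial targeting signals
(MTSs) against the mature sequences they import.

## The problem

Proteins destined for the mitochondrial matrix carry an N-terminal
targeting signal that is cleaved on import. These signals share
essentially no sequence homology and range from ~10 to well over 100
residues, yet all of them negotiate the same conserved import
machinery. A long-standing hypothesis is that this diversity is partly
explained by the cargo: charge and N-terminal properties of the
*mature* part of the precursor constrain what signal can import it.
`mtsprofiler` is for computational biologists who want to test that
kind of hypothesis on a curated dataset of species-labelled
(MTS, mature) pairs — or to study the statistical behaviour of the
analysis itself on fully synthetic data.

## What it computes

Every sequence (either part) is reduced to a 12-variable profile:
length; net charge at pH 7.5 from a Henderson–Hasselbalch pKa model,

> q(pH) = Σ_basic 1 / (1 + 10^(pH − pKa)) − Σ_acidic 1 / (1 + 10^(pKa − pH)),

summed over ionizable side chains (D, E, C, Y; H, K, R) and the free
termini; the isoelectric point (bisection root of q on [0, 14],
tolerance 1e-3); and the fractions of nine physicochemical residue
groups (non-polar aliphatic/aromatic/cyclic, polar
sulphur/hydroxyl/aromatic/acidic-amide, acidic, basic). On top of the
profiles:

* per-species and pooled 12 × 12 **Spearman correlation grids** (MTS
  variables × mature variables) with two-tailed p-values and
  significance classes;
* **PCA** of standardized property tables (correlation-matrix
  eigendecomposition, Kaiser retention, SPSS-style loadings);
* **windowed N-terminal analysis**: MTS length and charge against the
  acidic fraction of mature residues 1–40 and 41–80;
* **secondary-structure comparison** of the mature N-terminus between
  the shortest- and longest-MTS record groups (Kruskal–Wallis on
  helix/strand/disorder proportions over residues 1–50 and 51–100,
  using per-residue annotations supplied as input);
* a **Gaussian-copula synthetic generator** that emulates the species
  structure, length distributions and composition biases of curated
  matrix-protein datasets and can induce chosen rank correlations
  between MTS and mature properties (latent correlation solved from
  the target via rho = 2 sin(pi rho_S / 6)).

## Worked example

```r
library(mtsprofiler)

sim <- generateDataset(generatorConfig(), seed = 42)
ds <- sim$dataset
ds
#> MtsDataset with 296 record(s)
#>   species: Atha=35 Hsap=85 Mmus=84 Osat=36 Scer=56
#>   MTS length: 11-137; mature length: 97-1204
#>   provenance: synthetic (mtsprofiler generator, seed 42)

res <- runFullAnalysis(ds, annotations = sim$annotations)
res$correlations$pooled
#> CorrelationResult [pooled]: 12 x 12 cells (min n = 5)
#>   144 computed, 27 significant (p<0.05 or p<0.01)

round(corRho(res$correlations$pooled)["mts_length", "mature_frac_d"], 3)
#> [1] 0.364

res$pcaMts$Hsap
#> PcaSummary: 12 variables, 6 component(s) retained (kaiser (eigenvalue > 1))
#>   eigenvalues: 3.303 1.838 1.388 1.377 1.115 ...
#>   cumulative variance over retained: 83.89%

sequenceProperties("MLSRAVCGTSRQLAPALGYLGSRQ")[1:3]
#>    length    charge        pI
#> 24.000000  2.466212 10.763611
```

The pooled rank correlation of 0.364 between MTS length and the mature
acidic fraction recovers the 0.35 induced by the default generator
configuration: longer signals attach to more acidic cargo, the central
association the analysis is designed to detect. The per-sequence
profile shows a typical targeting signal: strongly basic (+2.47 e at
pH 7.5, pI 10.76).

With real data, replace the simulated dataset by
`ds <- readDataset("my_dataset.tsv")` (columns `record_id`, `species`,
`gene_id`, `accession`, `mts_seq`, `mature_seq`; `.` for missing
optional fields) and optionally
`ann <- readAnnotations("my_annotations.tsv", ds)`. Passing
`outDir = "results/"` to `runFullAnalysis()` writes the full TSV
bundle (property table, correlation grids, PCA summaries, windowed
table, structure comparison, manifest). A thin command-line wrapper
with `analyze`, `simulate` and `props` subcommands is installed at
`inst/scripts/mts-pipeline.R`.

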