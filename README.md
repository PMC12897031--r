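# kbhbatlas

Downstream analysis of label-free quantitative proteomics with lysine
β-hydroxybutyrylation (Kbhb) enrichment. Kbhb is an acyl modification of
lysine ε-amines derived from the ketone body β-hydroxybutyrate; during
fasting, rising β-HB drives widespread Kbhb remodeling of muscle proteins.
The analytical difficulty is that a Kbhb peptide's intensity confounds two
signals — how much of the parent protein is present, and what fraction of
it is modified. This package implements the full desk-side workflow that
separates them, for proteomics analysts working from MaxQuant-style site
and proteinGroups tables.

## What it computes

For site *f* in sample *s* with intensity *I*\[f,s\] and parent protein
*p(f)*:

1. **Filtering** — keep features with valid intensities in ≥ 3 of 4
   replicates in at least one group; sites additionally need localization
   probability ≥ 0.90 and peptide length ≥ 7.
2. **Proteome normalization** — quantile-normalize log2 LFQ intensities
   across samples.
3. **Center-scale relative quantification** —
   R\[f,s\] = I\[f,s\] / mean_s I\[f,·\] (mean over valid samples), so
   every feature's row averages 1.
4. **Stoichiometry correction** —
   M\[f,s\] = R_site\[f,s\] / R_protein\[p(f),s\]: a protein-abundance-
   normalized modification level. Changes driven purely by protein
   expression cancel; true stoichiometry changes remain.
5. **Differential testing** — Student's pooled t on log2 values; fold
   change as the ratio of linear group means; `up`/`down` at nominal
   p < 0.05 with |log2FC| > 0.585 (1.5-fold); BH-adjusted p reported
   alongside.
6. **Landscape and interpretation** — sites-per-protein density,
   subcellular breakdowns, ±7-residue motif statistics (two-sample Fisher
   position tests and iterative motif-x-style extraction), hypergeometric
   over-representation analysis, and structural prioritization of modified
   lysines by minimal heavy-atom distance to catalytic/cofactor residues
   (5 Å cutoff, four-way classification) combined with entropy-based
   alignment conservation (> 0.85 flags).

A seeded synthetic-data generator produces every input with a ground-truth
ledger (which sites truly change, which are protein-confounded, which
motifs and compartments were planted), so the whole pipeline is testable
end to end.

## Worked example

```r
library(kbhbatlas)
cfg <- generator_config(n_proteins = 400, seed = 1)
res <- run_pipeline(pipeline_config(generator = cfg))
print(res)
#> Kbhb pipeline result
#>   proteome: 800 in -> 800 kept; 800 tested
#>   sites: 1081 in -> 1017 kept -> 1017 corrected; 1010 tested
#>   differential sites: up 80 / down 9
```

1,081 simulated sites pass through filtering (localization and replicate
validity remove 64), correction, and testing; 80 are called up and 9 down,
an asymmetry that mirrors the planted 8:1 up:down ratio. The top
position-specific motif hit among upregulated windows is the planted
aspartate at +1:

```r
res$motif$up[1, c("offset", "residue", "fg_freq", "bg_freq", "p_value")]
#>   offset residue fg_freq    bg_freq      p_value
#> 1      1       D   0.475 0.09439528 2.123584e-16
```

47.5% of upregulated windows carry D at +1 versus 9.4% of all quantified
windows. The numbered scripts under `analysis/` walk the same stages on a
larger simulated study, with commentary, writing their tables under
`results/`.

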