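#!/usr/bin/env Rscript
# Filter and normalize the simulated study read back from its on-disk,
# MaxQuant-style representation.
#
# Proteome: log2 LFQ intensities quantile-normalized across samples.
# Sites: replicate-validity (>=3 of 4 in at least one group), localization
# probability >= 0.90 and peptide length >= 7 filters; center-scale relative
# quantification; division by the parent protein's relative value, which
# separates modification-level change from protein-expression change.

library(kbhbatlas)

in_dir <- "results/simdata"
out_dir <- "results/preprocess"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

dtab <- read.delim(file.path(in_dir, "design.tsv"))
design <- sample_design(dtab$sample, dtab$group)
sites <- read_site_table(file.path(in_dir, "kbhb_sites.tsv"), design)
proteome <- read_protein_table(file.path(in_dir, "protein_groups.tsv"), design)

pre <- preprocess_study(proteome, sites, design)

cat("Proteome:", nrow(proteome), "->", nrow(pre$protein_filter$matrix),
    "after the replicate-validity filter\n")
cat("Sites:", nrow(sites), "->", nrow(pre$site_filter$matrix),
    "after filtering; rejection reasons:\n")
print(table(pre$site_filter$rejected$reason))
cat("Corrected sites:", nrow(pre$corrected$matrix), "(",
    length(pre$corrected$parent_missing), "lost to unquantified parents )\n")

qc <- qc_replicates(pre$proteome_norm, design)
ve <- attr(qc$pca, "var_explained")
cat(sprintf("\nProteome QC: PC1 %.1f%%, PC2 %.1f%% of variance; %d complete features\n",
            100 * ve[1], 100 * ve[2], qc$n_complete_features))
within_r <- qc$correlation[design$group[row(qc$correlation)] ==
                             design$group[col(qc$correlation)]]
cat(sprintf("Within-group Pearson r: %.3f-%.3f\n",
            min(within_r[within_r < 1]), max(within_r[within_r < 1])))

write.table(pre$site_filter$rejected, file.path(out_dir, "rejected_sites.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(site = rownames(pre$corrected$matrix),
                       pre$corrected$matrix, check.names = FALSE),
            file.path(out_dir, "corrected_matrix.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(qc$pca, file.path(out_dir, "qc_pca_proteome.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(round(qc$correlation, 4),
            file.path(out_dir, "qc_pearson_proteome.tsv"),
            sep = "\t", quote = FALSE)
cat("\nWrote", out_dir, "\n")
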