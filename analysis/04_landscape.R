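#!/usr/bin/env Rscript
# Site-landscape, motif and pathway-enrichment summaries of the simulated
# Kbhb atlas: sites-per-protein density, subcellular breakdowns for all /
# up / down site sets, two-sample position-specific residue enrichment and
# iterative motif extraction for the regulated windows, and hypergeometric
# over-representation of regulated parent proteins against the gene sets.

library(kbhbatlas)

in_dir <- "results/simdata"
out_dir <- "results/landscape"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

dtab <- read.delim(file.path(in_dir, "design.tsv"))
design <- sample_design(dtab$sample, dtab$group)
sites <- read_site_table(file.path(in_dir, "kbhb_sites.tsv"), design)
proteome <- read_protein_table(file.path(in_dir, "protein_groups.tsv"), design)
annotation <- read_annotation(file.path(in_dir, "subcellular.tsv"))
gene_sets <- read_gmt(file.path(in_dir, "gene_sets.gmt"))

pre <- preprocess_study(proteome, sites, design)
kept <- pre$site_filter$site_meta
site_diff <- differential_test(pre$corrected$matrix, design)
up_ids <- site_diff$table$feature[site_diff$table$class == "up"]
down_ids <- site_diff$table$feature[site_diff$table$class == "down"]

dens <- site_density(kept)
cat("Sites per protein:\n"); print(dens)

for (scope in c("all", "up", "down")) {
  ids <- switch(scope, all = rownames(kept), up = up_ids, down = down_ids)
  cs <- summarize_compartments(kept[intersect(ids, rownames(kept)), ,
                                    drop = FALSE], annotation, scope)
  cat("\nCompartments (", scope, "):\n", sep = ""); print(cs)
  write.table(cs, file.path(out_dir, paste0("compartments_", scope, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

motif_up <- two_sample_position_test(
  kept[intersect(up_ids, rownames(kept)), "sequence_window"],
  kept$sequence_window, p_max = 1)
cat("\nTop position-specific enrichments in upregulated windows:\n")
print(head(motif_up, 5))

mx <- motif_x_iterative(kept[intersect(up_ids, rownames(kept)),
                             "sequence_window"],
                        kept$sequence_window)
cat("\nmotif-x patterns:",
    if (length(mx)) paste(vapply(mx, `[[`, "", "pattern"), collapse = ", ")
    else "(none)", "\n")

parent_map <- pre$parent_map
universe <- unique(unname(parent_map))
enr <- ora(sites_to_proteins(up_ids, parent_map), universe, gene_sets)
cat("\nORA of upregulated parent proteins:\n")
print(enr[, c("term", "k", "K", "p_value", "p_adjust", "significant")])

write.table(dens, file.path(out_dir, "site_density.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(motif_up, file.path(out_dir, "motif_up.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(enr[, setdiff(names(enr), "members")],
            file.path(out_dir, "ora_up.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nWrote", out_dir, "\n")
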