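#' Pipeline configuration
#'
#' Bundles thresholds and either a simulate-mode generator configuration or
#' a set of input file paths. Exactly one of `generator` / `inputs` must be
#' given.
#'
#' @param generator a [generator_config()] for simulate mode.
#' @param inputs named list of paths for file mode: `site_table`,
#'   `protein_table`, `design` (TSV with sample, group columns), optionally
#'   `fasta`, `annotation`, `gene_sets`, `structures` (named PDB paths).
#' @param alpha,fc_threshold differential thresholds.
#' @param loc_prob_min,min_valid,min_peptide_len filter thresholds.
#' @param distance_cutoff spatial proximity cutoff in Angstrom.
#' @param conservation_min conservation cutoff for prioritization.
#' @param out_dir optional output directory; when set, [run_pipeline()]
#'   writes its tables there.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = NULL, inputs = NULL,
                            alpha = 0.05, fc_threshold = 0.585,
                            loc_prob_min = 0.90, min_valid = 3L,
                            min_peptide_len = 7L,
                            distance_cutoff = 5.0, conservation_min = 0.85,
                            out_dir = NULL) {
  if (is.null(generator) == is.null(inputs))
    stop("exactly one of 'generator' (simulate mode) or 'inputs' ",
         "(file mode) must be supplied")
  for (th in c(alpha, fc_threshold, loc_prob_min, distance_cutoff,
               conservation_min))
    if (!is.numeric(th) || th <= 0) stop("thresholds must be positive")
  structure(list(generator = generator, inputs = inputs, alpha = alpha,
                 fc_threshold = fc_threshold, loc_prob_min = loc_prob_min,
                 min_valid = as.integer(min_valid),
                 min_peptide_len = as.integer(min_peptide_len),
                 distance_cutoff = distance_cutoff,
                 conservation_min = conservation_min, out_dir = out_dir),
            class = "pipeline_config")
}

#' Percentage change between two measurements
#'
#' `100 * (before - after) / before`, reported to one decimal -- e.g. a
#' body-weight drop from 29.3 g to 22.0 g is a 24.9% loss.
#'
#' @param before,after positive reals.
#' @return signed percentage, one decimal.
#' @export
percent_change <- function(before, after) {
  if (!is.numeric(before) || before <= 0) stop("'before' must be > 0")
  round(100 * (before - after) / before, 1)
}

#' Replicate quality control: PCA and Pearson correlation
#'
#' Principal component analysis (centered, unscaled) of the samples over
#' features with complete observations, plus the full sample-sample Pearson
#' correlation matrix on pairwise-complete values. Operates on log2
#' intensities.
#'
#' @param mat linear-scale feature x sample matrix.
#' @param design a [sample_design()].
#' @return list: `pca` (data.frame sample, group, PC1, PC2,
#'   var_explained attribute), `correlation` (sample x sample matrix),
#'   `n_complete_features`.
#' @export
qc_replicates <- function(mat, design) {
  lm2 <- log2(mat)
  complete <- stats::complete.cases(lm2)
  if (sum(complete) < 3L) stop("fewer than 3 complete features for PCA")
  pc <- stats::prcomp(t(lm2[complete, , drop = FALSE]), center = TRUE,
                      scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  pca <- data.frame(sample = design$sample, group = design$group,
                    PC1 = pc$x[design$sample, 1L],
                    PC2 = pc$x[design$sample, 2L])
  attr(pca, "var_explained") <- ve[1:2]
  corr <- stats::cor(lm2, use = "pairwise.complete.obs", method = "pearson")
  list(pca = pca, correlation = corr, n_complete_features = sum(complete))
}

.load_inputs <- function(inputs) {
  dtab <- utils::read.delim(inputs$design, stringsAsFactors = FALSE)
  design <- sample_design(dtab$sample, dtab$group)
  sites <- read_site_table(inputs$site_table, design)
  proteome <- read_protein_table(inputs$protein_table, design)
  annotation <- if (!is.null(inputs$annotation))
    read_annotation(inputs$annotation) else list()
  gene_sets <- if (!is.null(inputs$gene_sets))
    read_gmt(inputs$gene_sets) else list()
  sequences <- if (!is.null(inputs$fasta)) read_fasta(inputs$fasta) else NULL
  list(design = design, sites = sites, proteome = proteome,
       annotation = annotation, gene_sets = gene_sets,
       sequences = sequences, structures = list(), truth = NULL)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input generation or loading; replicate-validity /
#' localization filtering; proteome quantile normalization; center-scale
#' relative quantification; parent-protein correction; differential
#' analysis of proteins and corrected sites; site-landscape summaries
#' (site density, compartments, for all/up/down scopes); two-sample motif
#' enrichment and iterative motif extraction of up- and downregulated
#' windows against all quantified windows; over-representation analysis of
#' up/down parent proteins; structural lysine reports with prioritization;
#' replicate QC (PCA and Pearson correlations); and a run manifest with
#' exact stage row-count bookkeeping.
#'
#' @param config a [pipeline_config()].
#' @return list of class `kbhb_pipeline_result` with elements `data`,
#'   `preprocess`, `protein_diff`, `site_diff`, `site_density`,
#'   `compartments`, `motif`, `enrichment`, `structure`, `qc`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  data <- if (!is.null(config$generator)) {
    .stage("simulate", generate_dataset(config$generator))
  } else {
    .stage("load", .load_inputs(config$inputs))
  }
  design <- data$design

  pre <- .stage("preprocess", preprocess_study(
    data$proteome, data$sites, design, min_valid = config$min_valid,
    loc_prob_min = config$loc_prob_min,
    min_peptide_len = config$min_peptide_len))

  protein_diff <- .stage("differential_proteins", differential_test(
    pre$proteome_norm, design, alpha = config$alpha,
    fc_threshold = config$fc_threshold, min_valid = config$min_valid))
  site_diff <- .stage("differential_sites", differential_test(
    pre$corrected$matrix, design, alpha = config$alpha,
    fc_threshold = config$fc_threshold, min_valid = config$min_valid))

  kept_sites <- pre$site_filter$site_meta
  dens <- .stage("site_density", site_density(kept_sites))

  up_ids <- site_diff$table$feature[site_diff$table$class == "up"]
  down_ids <- site_diff$table$feature[site_diff$table$class == "down"]
  comp <- .stage("compartments", list(
    all = summarize_compartments(kept_sites, data$annotation, "all"),
    up = summarize_compartments(kept_sites[up_ids, , drop = FALSE],
                                data$annotation, "up"),
    down = summarize_compartments(kept_sites[down_ids, , drop = FALSE],
                                  data$annotation, "down")))

  all_windows <- kept_sites$sequence_window
  motif_res <- .stage("motif", list(
    up = two_sample_position_test(kept_sites[up_ids, "sequence_window"],
                                  all_windows, p_max = 1),
    down = two_sample_position_test(kept_sites[down_ids, "sequence_window"],
                                    all_windows, p_max = 1),
    motif_x_up = motif_x_iterative(kept_sites[up_ids, "sequence_window"],
                                   all_windows)))

  enr <- .stage("enrichment", {
    if (length(data$gene_sets) == 0L) list(up = NULL, down = NULL) else {
      parent_map <- pre$parent_map
      universe <- unique(unname(parent_map))
      list(up = ora(sites_to_proteins(up_ids, parent_map), universe,
                    data$gene_sets),
           down = ora(sites_to_proteins(down_ids, parent_map), universe,
                      data$gene_sets))
    }
  })

  struct <- .stage("structure", lapply(data$structures, function(g)
    prioritize(lysine_report(g, cutoff = config$distance_cutoff),
               conservation_min = config$conservation_min)))

  qc <- .stage("qc", list(proteome = qc_replicates(pre$proteome_norm, design),
                          sites = qc_replicates(pre$site_filter$matrix,
                                                design)))

  manifest <- list(
    config = config[setdiff(names(config), "generator")],
    seed = if (!is.null(config$generator)) config$generator$seed else NA,
    stages = list(
      proteins_in = nrow(data$proteome),
      proteins_kept = nrow(pre$protein_filter$matrix),
      proteins_rejected = nrow(pre$protein_filter$rejected),
      sites_in = nrow(data$sites),
      sites_kept = nrow(pre$site_filter$matrix),
      sites_rejected = nrow(pre$site_filter$rejected),
      sites_corrected = nrow(pre$corrected$matrix),
      sites_parent_missing = length(pre$corrected$parent_missing),
      sites_tested = nrow(site_diff$table),
      sites_up = length(up_ids), sites_down = length(down_ids),
      proteins_tested = nrow(protein_diff$table)))

  res <- structure(list(data = data, preprocess = pre,
                        protein_diff = protein_diff, site_diff = site_diff,
                        site_density = dens, compartments = comp,
                        motif = motif_res, enrichment = enr,
                        structure = struct, qc = qc, manifest = manifest),
                   class = "kbhb_pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(res, config$out_dir)
  res
}

#' @export
print.kbhb_pipeline_result <- function(x, ...) {
  st <- x$manifest$stages
  cat("Kbhb pipeline result\n")
  cat("  proteome:", st$proteins_in, "in ->", st$proteins_kept, "kept;",
      st$proteins_tested, "tested\n")
  cat("  sites:", st$sites_in, "in ->", st$sites_kept, "kept ->",
      st$sites_corrected, "corrected;", st$sites_tested, "tested\n")
  cat("  differential sites: up", st$sites_up, "/ down", st$sites_down, "\n")
  invisible(x)
}

#' Write the pipeline result tables to a directory
#' @param result a `kbhb_pipeline_result`.
#' @param dir output directory (created if absent).
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(result$protein_diff$table, "differential_proteins.tsv")
  wt(result$site_diff$table, "differential_sites.tsv")
  wt(result$site_density, "site_density.tsv")
  for (sc in names(result$compartments))
    wt(result$compartments[[sc]], paste0("compartments_", sc, ".tsv"))
  for (sc in c("up", "down"))
    if (nrow(result$motif[[sc]]))
      wt(result$motif[[sc]], paste0("motif_", sc, ".tsv"))
  for (sc in c("up", "down"))
    if (!is.null(result$enrichment[[sc]]))
      wt(result$enrichment[[sc]], paste0("enrichment_", sc, ".tsv"))
  for (nm in names(result$structure))
    wt(result$structure[[nm]], paste0("structure_", nm, ".tsv"))
  wt(result$qc$proteome$pca, "qc_pca_proteome.tsv")
  wt(result$qc$sites$pca, "qc_pca_sites.tsv")
  utils::write.table(result$qc$proteome$correlation,
                     file.path(dir, "qc_pearson_proteome.tsv"),
                     sep = "\t", quote = FALSE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
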