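AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Configuration for the synthetic Kbhb dataset generator
#'
#' Defaults emulate the study design the pipeline targets: two groups
#' (control vs starved) with four biological replicates each, log-normal
#' label-free intensities with a 20% replicate coefficient of variation,
#' ~41% of modified proteins carrying a single site and ~14% more than five,
#' an 8:1 up:down ratio among truly changed sites, and an acidic-residue
#' (D) preference at the +1 flanking position of upregulated sites.
#'
#' @param n_proteins number of Kbhb-modified proteins.
#' @param n_background_proteins extra unmodified proteins present only in the
#'   proteome table (differential-protein truth is planted here).
#' @param sites_per_protein_probs probability vector over site-count bins
#'   `c("1","2","3","4","5",">5")`; must sum to 1.
#' @param n_replicates_per_group biological replicates per group.
#' @param base_intensity_log_mean,base_intensity_log_sd mean and sd of
#'   per-feature base abundance on the log2 scale.
#' @param replicate_cv coefficient of variation of multiplicative
#'   (log-normal) replicate noise, per measurement.
#' @param missing_rate fraction of intensities set missing.
#' @param missing_mode `"mcar"` (completely at random, default) or
#'   `"intensity"` (logistic in log2 intensity: low-abundance values are
#'   more likely to be missing, with the same marginal rate).
#' @param frac_sites_up,frac_sites_down fractions of sites with a true
#'   stoichiometry change (planted on unchanged parents only).
#' @param site_effect_log2fc log2 effect size of true stoichiometry changes.
#' @param frac_proteins_changed fraction of background proteins whose
#'   abundance changes under starvation (downward, reflecting the
#'   predominance of protein downregulation during fasting; parents of
#'   confounded sites change upward).
#' @param protein_effect_log2fc log2 effect size of protein-abundance change.
#' @param frac_confounded_sites fraction of sites whose parent protein
#'   changes while their stoichiometry stays constant; their raw intensities
#'   shift although the modification level does not.
#' @param motif_spec list of planted flanking-sequence motifs, each a list
#'   with elements `class` (site truth class carrying the motif), `offset`
#'   (flank position, -7..7, not 0), `residue`, `prob` (planting probability).
#' @param compartment_probs probability vector over
#'   `c(nucleus, cytoplasm, mitochondria, other)`; must sum to 1.
#' @param frac_low_locprob fraction of sites given localization probability
#'   below 0.9 (exercises the localization filter).
#' @param seed integer seed; identical seeds give bit-identical datasets.
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(n_proteins = 400,
                             n_background_proteins = n_proteins,
                             sites_per_protein_probs = c("1" = 0.41, "2" = 0.20,
                                                         "3" = 0.13, "4" = 0.07,
                                                         "5" = 0.05, ">5" = 0.14),
                             n_replicates_per_group = 4L,
                             base_intensity_log_mean = 25,
                             base_intensity_log_sd = 2,
                             replicate_cv = 0.2,
                             missing_rate = 0.05,
                             missing_mode = c("mcar", "intensity"),
                             frac_sites_up = 0.08,
                             frac_sites_down = 0.01,
                             site_effect_log2fc = 1.0,
                             frac_proteins_changed = 0.10,
                             protein_effect_log2fc = 1.0,
                             frac_confounded_sites = 0.10,
                             motif_spec = list(list(class = "up", offset = 1L,
                                                    residue = "D", prob = 0.6)),
                             compartment_probs = c(nucleus = 0.169,
                                                   cytoplasm = 0.359,
                                                   mitochondria = 0.140,
                                                   other = 0.332),
                             frac_low_locprob = 0.05,
                             seed = 1L) {
  missing_mode <- match.arg(missing_mode)
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_background_proteins = as.integer(n_background_proteins),
              sites_per_protein_probs = sites_per_protein_probs,
              n_replicates_per_group = as.integer(n_replicates_per_group),
              base_intensity_log_mean = base_intensity_log_mean,
              base_intensity_log_sd = base_intensity_log_sd,
              replicate_cv = replicate_cv,
              missing_rate = missing_rate,
              missing_mode = missing_mode,
              frac_sites_up = frac_sites_up,
              frac_sites_down = frac_sites_down,
              site_effect_log2fc = site_effect_log2fc,
              frac_proteins_changed = frac_proteins_changed,
              protein_effect_log2fc = protein_effect_log2fc,
              frac_confounded_sites = frac_confounded_sites,
              motif_spec = motif_spec,
              compartment_probs = compartment_probs,
              frac_low_locprob = frac_low_locprob,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  fr <- c("missing_rate", "frac_sites_up", "frac_sites_down",
          "frac_proteins_changed", "frac_confounded_sites", "frac_low_locprob")
  for (f in fr) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("configuration error: ", f, " must be a fraction in [0,1]")
  }
  for (pv in c("sites_per_protein_probs", "compartment_probs")) {
    p <- cfg[[pv]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("configuration error: ", pv,
           " must be a nonnegative probability vector summing to 1")
  }
  if (cfg$frac_sites_up + cfg$frac_sites_down + cfg$frac_confounded_sites > 1)
    stop("configuration error: site class fractions exceed 1")
  if (cfg$n_proteins < 1L || cfg$n_replicates_per_group < 2L)
    stop("configuration error: need >=1 protein and >=2 replicates per group")
  if (cfg$replicate_cv < 0) stop("configuration error: replicate_cv < 0")
  invisible(TRUE)
}

# log2-scale sd of multiplicative log-normal noise with the given CV
.cv_to_log2_sd <- function(cv) sqrt(log(1 + cv^2)) / log(2)

.draw_site_count <- function(n, probs) {
  bins <- sample(names(probs), n, replace = TRUE, prob = probs)
  vapply(bins, function(b) {
    if (b == ">5") sample(6:10, 1L) else as.integer(b)
  }, integer(1), USE.NAMES = FALSE)
}

#' Generate a synthetic Kbhb study with known ground truth
#'
#' Produces every input the downstream pipeline consumes -- a proteome
#' intensity matrix, a modification-site table, protein sequences,
#' subcellular annotation, gene sets, toy structures -- together with a
#' truth ledger recording each feature's true class.
#'
#' Site intensities are built as the parent protein's per-sample intensity
#' (the same draw that populates the proteome table) times a per-site
#' stoichiometry factor times site-level log-normal replicate noise.
#' "up"/"down" sites change stoichiometry by `site_effect_log2fc` in the
#' starved group; "protein-confounded" sites keep constant stoichiometry on
#' a parent whose abundance shifts by `protein_effect_log2fc`, so their raw
#' site intensities change although the modification level does not.
#'
#' @param config a [generator_config()].
#' @return list of class `kbhb_synthetic_dataset` with elements `proteome`
#'   (linear-scale matrix with NA for missing), `sites` (site records with
#'   intensity columns), `sequences`, `annotation`, `gene_sets`,
#'   `structures`, `design`, `truth`, `config`.
#' @export
generate_dataset <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed)
  nrep <- config$n_replicates_per_group
  design <- sample_design(
    samples = c(paste0("GA_C", seq_len(nrep)), paste0("GA_S", seq_len(nrep))),
    groups = rep(c("control", "starved"), each = nrep))
  starved <- design$group == "starved"
  sd2 <- .cv_to_log2_sd(config$replicate_cv)

  ## --- proteins and site layout -------------------------------------------
  np <- config$n_proteins
  acc <- sprintf("P%04d", seq_len(np))
  site_counts <- .draw_site_count(np, config$sites_per_protein_probs)
  n_sites <- sum(site_counts)
  site_protein <- rep(acc, site_counts)

  nb <- config$n_background_proteins
  bacc <- if (nb > 0) sprintf("B%04d", seq_len(nb)) else character()

  ## --- truth classes -------------------------------------------------------
  # confounded sites: whole proteins are flipped to "changed" until the
  # requested site fraction is covered (protein granularity)
  target_conf <- round(config$frac_confounded_sites * n_sites)
  perm <- sample.int(np)
  csum <- cumsum(site_counts[perm])
  n_changed <- if (target_conf > 0) which(csum >= target_conf)[1L] else 0L
  changed_prot <- acc[perm[seq_len(n_changed)]]
  site_class <- rep("null", n_sites)
  site_class[site_protein %in% changed_prot] <- "protein-confounded"

  free <- which(site_class == "null")
  n_up <- round(config$frac_sites_up * n_sites)
  n_down <- round(config$frac_sites_down * n_sites)
  pick <- sample(free, min(length(free), n_up + n_down))
  site_class[pick[seq_len(min(n_up, length(pick)))]] <- "up"
  if (n_down > 0 && length(pick) > n_up)
    site_class[pick[(n_up + 1L):length(pick)]] <- "down"

  # background protein changes point down, mirroring the predominance of
  # protein downregulation under starvation; parents of confounded sites go
  # up so that raw confounded-site intensities rise with their parent
  changed_bg <- if (nb > 0)
    bacc[sample.int(nb, round(config$frac_proteins_changed * nb))] else character()
  all_acc <- c(acc, bacc)
  prot_class <- rep("null", np + nb)
  prot_class[all_acc %in% changed_prot] <- "up"
  prot_class[all_acc %in% changed_bg] <- "down"

  ## --- sequences, site positions, planted motifs --------------------------
  seqs <- character(np)
  names(seqs) <- acc
  positions <- integer(n_sites)
  motif_rows <- list()
  idx <- 0L
  for (i in seq_len(np)) {
    k <- site_counts[i]
    len <- 15L * k + 40L
    s <- sample(AA20, len, replace = TRUE)
    slots <- seq(10L, len - 10L, by = 15L)
    pos <- sort(sample(slots, k))
    s[pos] <- "K"
    sites_here <- idx + seq_len(k)
    for (j in seq_len(k)) {
      f <- sites_here[j]
      for (ms in config$motif_spec) {
        if (site_class[f] != ms$class) next
        planted <- stats::runif(1) < ms$prob
        at <- pos[j] + ms$offset
        if (planted && at >= 1L && at <= len && !(at %in% pos)) s[at] <- ms$residue
        motif_rows[[length(motif_rows) + 1L]] <-
          data.frame(site_id = paste0(acc[i], "_K", pos[j]),
                     offset = ms$offset, residue = ms$residue,
                     planted = planted, stringsAsFactors = FALSE)
      }
    }
    positions[sites_here] <- pos
    seqs[i] <- paste(s, collapse = "")
    idx <- idx + k
  }
  site_id <- paste0(site_protein, "_K", positions)
  motif_truth <- if (length(motif_rows)) do.call(rbind, motif_rows) else
    data.frame(site_id = character(), offset = integer(),
               residue = character(), planted = logical())

  ## --- intensities ---------------------------------------------------------
  ns <- nrow(design)
  base_log2 <- stats::rnorm(np + nb, config$base_intensity_log_mean,
                            config$base_intensity_log_sd)
  names(base_log2) <- all_acc
  dir <- (prot_class == "up") - (prot_class == "down")
  shift <- outer(dir, starved) * config$protein_effect_log2fc
  prot_log2 <- base_log2 + shift +
    matrix(stats::rnorm((np + nb) * ns, 0, sd2), np + nb, ns)
  dimnames(prot_log2) <- list(all_acc, design$sample)

  stoich <- stats::rnorm(n_sites, -3, 1)
  site_shift <- matrix(0, n_sites, ns)
  site_shift[site_class == "up", starved] <- config$site_effect_log2fc
  site_shift[site_class == "down", starved] <- -config$site_effect_log2fc
  site_log2 <- prot_log2[site_protein, , drop = FALSE] + stoich + site_shift +
    matrix(stats::rnorm(n_sites * ns, 0, sd2), n_sites, ns)
  dimnames(site_log2) <- list(site_id, design$sample)

  proteome <- 2^prot_log2
  site_int <- 2^site_log2

  inject_missing <- function(m) {
    if (config$missing_rate <= 0) return(m)
    if (config$missing_mode == "mcar") {
      miss <- matrix(stats::runif(length(m)) < config$missing_rate,
                     nrow(m), ncol(m))
    } else {
      x <- log2(m)
      z <- (x - stats::median(x)) / stats::sd(x)
      p <- pmin(1, 2 * config$missing_rate * stats::plogis(-2 * z))
      miss <- matrix(stats::runif(length(m)) < p, nrow(m), ncol(m))
    }
    m[miss] <- NA
    m
  }
  proteome <- inject_missing(proteome)
  site_int <- inject_missing(site_int)

  ## --- site record table ---------------------------------------------------
  locp <- 0.9 + 0.1 * stats::runif(n_sites)
  low <- stats::runif(n_sites) < config$frac_low_locprob
  locp[low] <- 0.5 + 0.39 * stats::runif(sum(low))
  windows <- vapply(seq_len(n_sites), function(f)
    extract_window(seqs[[site_protein[f]]], positions[f]), "")
  sites <- data.frame(protein = site_protein, position = positions,
                      localization_prob = round(locp, 4),
                      sequence_window = windows,
                      peptide_length = sample(7:30, n_sites, replace = TRUE),
                      stringsAsFactors = FALSE)
  rownames(sites) <- site_id
  for (s in design$sample) sites[[s]] <- site_int[, s]

  ## --- annotation, gene sets ----------------------------------------------
  comp <- sample(names(config$compartment_probs), np + nb, replace = TRUE,
                 prob = config$compartment_probs)
  names(comp) <- all_acc
  # "other" proteins carry no annotation line; assign_compartment() defaults
  # unannotated proteins to "other"
  annotated <- comp != "other"
  annotation <- as.list(comp[annotated])

  up_parents <- unique(site_protein[site_class == "up"])
  gene_sets <- list()
  if (length(up_parents) >= 3L) {
    gene_sets$PLANTED_UP <- up_parents[seq_len(min(30L, length(up_parents)))]
  }
  for (t in seq_len(5L)) {
    gene_sets[[sprintf("RANDOM_%02d", t)]] <-
      sample(acc, min(20L, np))
  }

  ## --- toy structures ------------------------------------------------------
  structures <- list()
  struct_rows <- list()
  demo <- .demo_structure_spec()
  st <- generate_toy_structure(demo$atoms,
                               kbhb_lysines = demo$kbhb_lysines,
                               functional_residues = demo$functional_residues,
                               ptm_residues = demo$ptm_residues)
  structures$demo <- st
  struct_rows[[1]] <- cbind(structure = "demo", st$distance_ledger)
  structure_truth <- do.call(rbind, struct_rows)

  truth <- list(
    sites = data.frame(site_id = site_id, protein = site_protein,
                       position = positions, class = site_class,
                       stringsAsFactors = FALSE),
    proteins = data.frame(protein = all_acc, class = prot_class,
                          modified = all_acc %in% acc,
                          stringsAsFactors = FALSE),
    motifs = motif_truth,
    compartments = data.frame(protein = all_acc, compartment = comp,
                              stringsAsFactors = FALSE),
    structures = structure_truth)

  structure(list(proteome = proteome, sites = sites, sequences = seqs,
                 annotation = annotation, gene_sets = gene_sets,
                 structures = structures, design = design, truth = truth,
                 config = config),
            class = "kbhb_synthetic_dataset")
}

#' @export
print.kbhb_synthetic_dataset <- function(x, ...) {
  cat("Synthetic Kbhb dataset:", nrow(x$sites), "sites on",
      x$config$n_proteins, "proteins;", nrow(x$proteome),
      "proteome entries;", nrow(x$design), "samples\n")
  cat("Site truth classes:\n")
  print(table(x$truth$sites$class))
  invisible(x)
}

# four lysines spanning the four spatial categories of the lysine report:
# K10 overlaps a PTM residue and sits 3 A from the catalytic residue;
# K20 overlaps a PTM residue, 12 A away; K30 no overlap, 4 A; K40 neither.
.demo_structure_spec <- function() {
  atoms <- data.frame(
    resno = c(10L, 20L, 30L, 40L, 50L, 60L),
    resname = c("LYS", "LYS", "LYS", "LYS", "HIS", "SER"),
    atom = c("NZ", "NZ", "NZ", "NZ", "NE2", "OG"),
    x = c(3, 12, 4, 40, 0, 60),
    y = c(0, 0, 0, 0, 0, 0),
    z = c(0, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE)
  list(atoms = atoms,
       kbhb_lysines = c(10L, 20L, 30L, 40L),
       functional_residues = 50L,
       ptm_residues = c(10L, 20L))
}

#' Generate a toy PDB structure with a planted distance ledger
#'
#' Writes a minimal valid PDB file from the given residue/atom layout,
#' re-reads it through the package's PDB reader, and records the exact
#' pairwise minimal inter-residue distances implied by the coordinates.
#'
#' @param atoms data.frame with columns `resno`, `resname`, `atom`, `x`,
#'   `y`, `z`; one row per atom. Several rows may share a `resno` (one
#'   residue, several atoms) but a residue number may not be reused with a
#'   different residue name.
#' @inheritParams read_pdb
#' @param path where to write the PDB file (default: temp file).
#' @return a `residue_geometry` with extra elements `pdb_path` and
#'   `distance_ledger` (data.frame res_a, res_b, distance in Angstrom).
#' @export
generate_toy_structure <- function(atoms, kbhb_lysines = integer(),
                                   functional_residues = integer(),
                                   ptm_residues = integer(),
                                   path = tempfile(fileext = ".pdb")) {
  stopifnot(all(c("resno", "resname", "atom", "x", "y", "z") %in% names(atoms)))
  if (nrow(atoms) < 1L) stop("need at least one residue")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("coordinates must be finite")
  rid <- unique(atoms[, c("resno", "resname")])
  if (anyDuplicated(rid$resno))
    stop("duplicate residue identifiers with conflicting names")
  .write_pdb_minimal(atoms, path)
  geom <- read_pdb(path, kbhb_lysines, functional_residues, ptm_residues)

  res <- sort(unique(atoms$resno))
  ledger <- if (length(res) >= 2L) {
    pairs <- utils::combn(res, 2L)
    data.frame(res_a = pairs[1L, ], res_b = pairs[2L, ],
               distance = vapply(seq_len(ncol(pairs)), function(i)
                 min_atomic_distance(geom, pairs[1L, i], pairs[2L, i]),
                 numeric(1)))
  } else {
    data.frame(res_a = integer(), res_b = integer(), distance = numeric())
  }
  geom$pdb_path <- path
  geom$distance_ledger <- ledger
  geom
}

# fixed-width ATOM records, single chain A, occupancy/B-factor 1.00/0.00
.write_pdb_minimal <- function(atoms, path) {
  elem <- toupper(substr(gsub("[0-9]", "", atoms$atom), 1L, 1L))
  lines <- sprintf(
    "ATOM  %5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(atoms)), substr(atoms$atom, 1L, 3L),
    substr(atoms$resname, 1L, 3L), atoms$resno,
    atoms$x, atoms$y, atoms$z, elem)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a synthetic dataset to a directory of standard-format files
#'
#' Emits the tab-delimited site and protein tables, FASTA sequences, GMT
#' gene sets, subcellular annotation TSV, toy-structure PDB files, the
#' design table, and the truth ledger as JSON.
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dataset$design
  write_site_table(dataset$sites, file.path(dir, "kbhb_sites.tsv"), d)
  write_protein_table(dataset$proteome, file.path(dir, "protein_groups.tsv"))
  write_fasta(dataset$sequences, file.path(dir, "proteins.fasta"))
  write_gmt(dataset$gene_sets, file.path(dir, "gene_sets.gmt"))
  write_annotation(dataset$annotation, file.path(dir, "subcellular.tsv"))
  utils::write.table(as.data.frame(d), file.path(dir, "design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(dataset$structures)) {
    file.copy(dataset$structures[[nm]]$pdb_path,
              file.path(dir, paste0("structure_", nm, ".pdb")),
              overwrite = TRUE)
  }
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(dir)
}
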