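test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(missing_rate = 1.2), "fraction")
  expect_error(generator_config(frac_sites_up = -0.1), "fraction")
  expect_error(generator_config(
    sites_per_protein_probs = c("1" = 0.5, "2" = 0.6, "3" = 0, "4" = 0,
                                "5" = 0, ">5" = 0)), "summing to 1")
  expect_error(generator_config(compartment_probs = c(nucleus = 0.5,
                                                      cytoplasm = 0.6,
                                                      mitochondria = -0.1,
                                                      other = 0)),
               "probability vector")
  expect_error(generator_config(frac_sites_up = 0.6, frac_sites_down = 0.3,
                                frac_confounded_sites = 0.3), "exceed 1")
})

test_that("identical seeds give bit-identical datasets, different seeds differ", {
  cfg <- generator_config(n_proteins = 40, seed = 11)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$proteome, d2$proteome)
  expect_identical(d1$sites, d2$sites)
  expect_identical(d1$sequences, d2$sequences)
  expect_identical(d1$truth$sites, d2$truth$sites)
  d3 <- generate_dataset(generator_config(n_proteins = 40, seed = 12))
  expect_false(identical(d1$proteome, d3$proteome))
})

test_that("null configuration plants no effects and the ledger covers every feature", {
  cfg <- generator_config(n_proteins = 50, frac_sites_up = 0,
                          frac_sites_down = 0, frac_proteins_changed = 0,
                          frac_confounded_sites = 0, seed = 3)
  d <- generate_dataset(cfg)
  expect_true(all(d$truth$sites$class == "null"))
  expect_true(all(d$truth$proteins$class == "null"))
  # ledger covers each generated feature exactly once
  expect_setequal(d$truth$sites$site_id, rownames(d$sites))
  expect_false(anyDuplicated(d$truth$sites$site_id) > 0)
  expect_setequal(d$truth$proteins$protein, rownames(d$proteome))
})

test_that("confounded sites change in raw intensity but not in stoichiometry", {
  cfg <- generator_config(n_proteins = 250, frac_sites_up = 0,
                          frac_sites_down = 0, frac_confounded_sites = 0.2,
                          site_effect_log2fc = 0, protein_effect_log2fc = 1.0,
                          missing_rate = 0, seed = 5)
  d <- generate_dataset(cfg)
  conf <- d$truth$sites$site_id[d$truth$sites$class == "protein-confounded"]
  expect_gt(length(conf), 50)
  m <- site_intensity_matrix(d$sites, d$design)[conf, ]
  ctrl <- d$design$sample[d$design$group == "control"]
  stv <- d$design$sample[d$design$group == "starved"]
  raw_ratio <- log2(rowMeans(m[, stv]) / rowMeans(m[, ctrl]))
  # raw group-mean log2 ratio tracks the parent-protein effect
  mc_se <- sd(raw_ratio) / sqrt(length(raw_ratio))
  expect_lt(abs(mean(raw_ratio) - 1.0), 4 * mc_se + 0.05)
})

test_that("under the null generator downstream p values are uniform", {
  cfg <- generator_config(n_proteins = 700, frac_sites_up = 0,
                          frac_sites_down = 0, frac_proteins_changed = 0,
                          frac_confounded_sites = 0, seed = 1)
  d <- generate_dataset(cfg)
  pre <- preprocess_study(d$proteome, d$sites, d$design)
  p <- differential_test(pre$corrected$matrix, d$design)$table$p_value
  expect_gt(length(p), 1500)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("toy structures record the exact planted distances", {
  atoms <- data.frame(resno = c(1L, 2L), resname = c("LYS", "GLY"),
                      atom = c("NZ", "CA"),
                      x = c(0, 3), y = c(0, 4), z = c(0, 0))
  st <- generate_toy_structure(atoms, kbhb_lysines = 1L)
  expect_equal(st$distance_ledger$distance, 5.0)
  # one residue: empty ledger
  st1 <- generate_toy_structure(atoms[1, ])
  expect_equal(nrow(st1$distance_ledger), 0L)
  # identical coordinates: distance zero
  atoms0 <- data.frame(resno = c(1L, 2L), resname = c("LYS", "GLY"),
                       atom = c("NZ", "CA"), x = 0, y = 0, z = 0)
  expect_equal(generate_toy_structure(atoms0)$distance_ledger$distance, 0)
  # duplicate residue identifiers with conflicting names rejected
  bad <- data.frame(resno = c(1L, 1L), resname = c("LYS", "GLY"),
                    atom = c("NZ", "CA"), x = c(0, 1), y = 0, z = 0)
  expect_error(generate_toy_structure(bad), "duplicate")
})

test_that("planted motif residues are enriched in the designated class", {
  cfg <- generator_config(n_proteins = 300, seed = 9)
  d <- generate_dataset(cfg)
  up <- d$truth$sites$site_id[d$truth$sites$class == "up"]
  planted <- d$truth$motifs
  expect_true(all(planted$site_id %in% up))
  win_up <- d$sites[up, "sequence_window"]
  frac_D <- mean(substr(win_up, 9, 9) == "D")
  win_all <- d$sites$sequence_window
  frac_D_all <- mean(substr(win_all, 9, 9) == "D")
  expect_gt(frac_D, 0.4)     # planting probability 0.6, minus collisions
  expect_lt(frac_D_all, 0.2) # background stays near 1/20
})

test_that("a dataset round-trips through its on-disk representation", {
  cfg <- generator_config(n_proteins = 25, seed = 21)
  d <- generate_dataset(cfg)
  dir <- tempfile("simdata")
  write_dataset(d, dir)
  sites2 <- read_site_table(file.path(dir, "kbhb_sites.tsv"), d$design)
  expect_equal(nrow(sites2), nrow(d$sites))
  m1 <- site_intensity_matrix(d$sites, d$design)
  m2 <- site_intensity_matrix(sites2, d$design)
  expect_equal(is.na(m1), is.na(m2))
  expect_equal(m1, m2, tolerance = 1e-6)
  prot2 <- read_protein_table(file.path(dir, "protein_groups.tsv"), d$design)
  expect_equal(is.na(d$proteome), is.na(prot2))
  seqs2 <- read_fasta(file.path(dir, "proteins.fasta"))
  expect_identical(seqs2, d$sequences)
  gmt2 <- read_gmt(file.path(dir, "gene_sets.gmt"))
  expect_identical(gmt2, d$gene_sets)
  ann2 <- read_annotation(file.path(dir, "subcellular.tsv"))
  expect_setequal(names(ann2), names(d$annotation))
})
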