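write_tsv_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

test_that("well-formed site tables parse with missingness semantics", {
  design <- tiny_design(2L)
  f <- write_tsv_lines(c(
    paste(c("protein", "position", "localization_prob", "sequence_window",
            design$sample), collapse = "\t"),
    paste(c("P1", "10", "0.95", "AAAAAAAKAAAAAAA", "100", "0", "5", ""),
          collapse = "\t"),
    paste(c("P2", "3", "0.99", "_____CDKGHIKLMN", "200", "NaN", "10", "20"),
          collapse = "\t"),
    paste(c("P3", "8", "1.0", "MNPQRSTKVWYACDE", "1", "2", "3", "4"),
          collapse = "\t")))
  tab <- read_site_table(f, design)
  expect_equal(nrow(tab), 3L)
  # "0", "", "NaN" all parse as missing
  expect_true(is.na(tab[1, "GA_C2"]))
  expect_true(is.na(tab[1, "GA_S2"]))
  expect_true(is.na(tab[2, "GA_C2"]))
  expect_equal(unlist(tab[3, design$sample]), c(1, 2, 3, 4),
               ignore_attr = TRUE)
})

test_that("schema and validation errors name the offending column or row", {
  design <- tiny_design(2L)
  header <- paste(c("protein", "position", "localization_prob",
                    "sequence_window", design$sample), collapse = "\t")
  f <- write_tsv_lines(c(gsub("localization_prob", "locprob", header),
                         paste(c("P1", "10", "0.95", "AAAAAAAKAAAAAAA",
                                 1, 2, 3, 4), collapse = "\t")))
  expect_error(read_site_table(f, design), "localization_prob")
  # localization probability out of range
  f <- write_tsv_lines(c(header,
                         paste(c("P1", "10", "1.2", "AAAAAAAKAAAAAAA",
                                 1, 2, 3, 4), collapse = "\t")))
  expect_error(read_site_table(f, design), "\\[0,1\\].*row")
  # window center must be K
  f <- write_tsv_lines(c(header,
                         paste(c("P1", "10", "0.95", "AAAAAAARAAAAAAA",
                                 1, 2, 3, 4), collapse = "\t")))
  expect_error(read_site_table(f, design), "not K")
  # shared-peptide rows assigned to the first accession with a warning
  f <- write_tsv_lines(c(header,
                         paste(c("P1;P2", "10", "0.95", "AAAAAAAKAAAAAAA",
                                 1, 2, 3, 4), collapse = "\t")))
  expect_warning(tab <- read_site_table(f, design), "first listed")
  expect_equal(tab$protein, "P1")
})

test_that("site tables round-trip losslessly (write then read)", {
  design <- tiny_design(3L)
  set.seed(42)
  n <- 20L
  sites <- data.frame(
    protein = paste0("P", seq_len(n)), position = 8L + seq_len(n),
    localization_prob = round(runif(n, 0.9, 1), 4),
    sequence_window = replicate(n, paste0(
      paste(sample(c(LETTERS[1:10]), 7, replace = TRUE), collapse = ""), "K",
      paste(sample(c(LETTERS[1:10]), 7, replace = TRUE), collapse = ""))),
    stringsAsFactors = FALSE)
  for (s in design$sample) {
    v <- round(2^rnorm(n, 20, 2), 3)
    v[sample.int(n, 3)] <- NA
    sites[[s]] <- v
  }
  rownames(sites) <- paste0(sites$protein, "_K", sites$position)
  f <- tempfile(fileext = ".tsv")
  write_site_table(sites, f, design)
  back <- read_site_table(f, design)
  expect_equal(back$protein, sites$protein)
  expect_equal(back$localization_prob, sites$localization_prob)
  m1 <- site_intensity_matrix(sites, design)
  m2 <- site_intensity_matrix(back, design)
  expect_equal(is.na(m1), is.na(m2))
  expect_equal(m1, m2, tolerance = 1e-9)
})

test_that("FASTA, GMT and annotation readers parse standard content", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">P1 some description", "ACDEFGHIK", ">P2", "MNPQR"), f)
  seqs <- read_fasta(f)
  expect_equal(length(seqs), 2L)
  expect_identical(names(seqs), c("P1", "P2"))
  expect_equal(unname(seqs["P1"]), "ACDEFGHIK")

  g <- tempfile(fileext = ".gmt")
  writeLines(c("TCA\tdesc\tP1\tP2", "GLYCOLYSIS\tdesc\tP2\tP3\tP4"), g)
  sets <- read_gmt(g)
  expect_identical(sets$TCA, c("P1", "P2"))
  expect_equal(length(sets$GLYCOLYSIS), 3L)
  expect_error(read_gmt(write_tsv_lines("ONLY\tTWO")), "fewer than 3")

  a <- tempfile(fileext = ".tsv")
  writeLines(c("protein\tcompartment", "P1\tcytoplasm",
               "P2\tmitochondria;nucleus", "P2\tcytoplasm"), a)
  ann <- read_annotation(a)
  expect_setequal(ann$P1, "cytoplasm")
  expect_setequal(ann$P2, c("mitochondria", "nucleus", "cytoplasm"))
})

test_that("PDB reading returns labelled heavy-atom geometry", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  NZ  LYS A   2       4.000   2.000   3.000  1.00  0.00           N",
    "ATOM      3  H   LYS A   2       4.500   2.000   3.000  1.00  0.00           H",
    "END"), f)
  geom <- read_pdb(f, kbhb_lysines = 2L, functional_residues = 1L)
  expect_s3_class(geom, "residue_geometry")
  expect_equal(nrow(geom$atoms), 2L) # hydrogen discarded
  expect_equal(geom$atoms$x[1], 1.0)
  expect_equal(unlist(geom$atoms[1, c("x", "y", "z")]), c(1, 2, 3),
               ignore_attr = TRUE)
  expect_error(read_pdb(f, kbhb_lysines = 99L), "absent")
})

test_that("sample designs validate their inputs", {
  expect_error(sample_design(c("A", "A"), c("control", "starved")), "unique")
  expect_error(sample_design(c("A", "B"), c("control", "control")),
               "two groups")
  d <- tiny_design()
  expect_equal(nrow(d), 8L)
  expect_equal(d$replicate, rep(1:4, 2))
})
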