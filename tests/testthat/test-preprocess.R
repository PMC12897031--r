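test_that("replicate-validity filter keeps features valid in at least one group", {
  design <- tiny_design()
  m <- tiny_matrix(c(1, 2, 3, NA, NA, NA, NA, NA,   # 3/4 control, 0/4 starved
                     1, NA, NA, NA, 2, 3, NA, NA,   # 1/4 and 2/4
                     1, 2, 3, 4, 5, 6, 7, 8),       # complete
                   c("f1", "f2", "f3"), design)
  res <- filter_features(m, design, min_valid = 3L)
  expect_setequal(rownames(res$matrix), c("f1", "f3"))
  expect_equal(res$rejected$feature, "f2")
  expect_equal(res$rejected$reason, "replicate_validity")
  expect_error(filter_features(m, design, min_valid = 5L), "configuration")
})

test_that("site filters apply localization and length rules with logged reasons", {
  design <- tiny_design()
  m <- tiny_matrix(rep(1, 24), c("s1", "s2", "s3"), design)
  meta <- data.frame(protein = c("P1", "P2", "P3"), position = c(5L, 6L, 7L),
                     localization_prob = c(0.95, 0.85, 0.99),
                     peptide_length = c(12L, 12L, 6L),
                     row.names = c("s1", "s2", "s3"))
  res <- filter_features(m, design, site_meta = meta)
  expect_equal(rownames(res$matrix), "s1")
  expect_equal(res$rejected$reason[res$rejected$feature == "s2"],
               "localization")
  expect_equal(res$rejected$reason[res$rejected$feature == "s3"],
               "peptide_length")
  # bookkeeping is exact
  expect_equal(nrow(res$matrix) + nrow(res$rejected), nrow(m))
  # empty table passes through
  empty <- filter_features(m[0, , drop = FALSE], design)
  expect_equal(nrow(empty$matrix), 0L)
  expect_equal(nrow(empty$rejected), 0L)
})

test_that("quantile normalization matches the sort/average/map-back oracle", {
  design <- tiny_design(1L)
  m <- matrix(c(1, 2, 3, 2, 4, 6), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, 1]), c(1.5, 3.0, 4.5))
  expect_equal(unname(qn[, 2]), c(1.5, 3.0, 4.5))
  # random complete matrices vs oracle
  set.seed(101)
  for (i in 1:5) {
    r <- matrix(rnorm(60), 12, 5, dimnames = list(paste0("f", 1:12), NULL))
    expect_equal(unname(quantile_normalize(r)),
                 unname(oracle_quantile_normalize(r)), tolerance = 1e-12)
  }
  # identical columns unchanged; single column unchanged
  same <- matrix(rep(c(5, 1, 3), 2), ncol = 2)
  expect_equal(quantile_normalize(same), same, ignore_attr = TRUE)
  one <- matrix(c(4, 1, 9), ncol = 1)
  expect_equal(quantile_normalize(one), one, ignore_attr = TRUE)
  # all-missing column rejected
  bad <- matrix(c(1, 2, NA, NA), ncol = 2)
  expect_error(quantile_normalize(bad), "all-missing")
})

test_that("quantile normalization is idempotent and permutation-equivariant", {
  set.seed(7)
  m <- matrix(rnorm(80, 20, 3), 16, 5)
  qn <- quantile_normalize(m)
  expect_equal(quantile_normalize(qn), qn, tolerance = 1e-9)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(quantile_normalize(m[, perm]), qn[, perm], tolerance = 1e-12)
  # ties receive the mean of the reference values at their tied ranks
  mt <- matrix(c(1, 1, 3, 2, 4, 6), ncol = 2)
  qt <- quantile_normalize(mt)
  expect_equal(qt[1, 1], qt[2, 1])
  # reference is (1.5, 2.5, 4.5); tied ranks 1 and 2 average to 2.0
  expect_equal(qt[1, 1], 2.0)
})

test_that("quantile normalization agrees with limma on complete matrices", {
  skip_if_not_installed("limma")
  set.seed(13)
  m <- matrix(2^rnorm(200, 20, 2), 40, 5)
  expect_equal(unname(quantile_normalize(m)),
               unname(limma::normalizeQuantiles(m, ties = TRUE)),
               tolerance = 1e-8)
})

test_that("center-scale gives exact row-mean 1 over valid entries", {
  design <- tiny_design(2L)
  m <- tiny_matrix(c(2, 2, 2, 2,
                     2, 4, 2, 4,
                     2, NA, 4, NA), c("f1", "f2", "f3"), design)
  cs <- center_scale(m)
  expect_equal(unname(cs$matrix["f1", ]), c(1, 1, 1, 1))
  expect_equal(unname(cs$matrix["f2", ]), c(2, 4, 2, 4) / 3)
  expect_equal(unname(cs$matrix["f3", c(1, 3)]), c(2 / 3, 4 / 3))
  expect_true(all(is.na(cs$matrix["f3", c(2, 4)])))
  expect_equal(unname(rowMeans(cs$matrix, na.rm = TRUE)), rep(1, 3),
               tolerance = 1e-12)
  # all-missing rows dropped with a log entry
  m2 <- rbind(m, f4 = NA_real_)
  cs2 <- center_scale(m2)
  expect_equal(cs2$dropped, "f4")
  expect_false("f4" %in% rownames(cs2$matrix))
  expect_error(center_scale(-m), "positive")
})

test_that("parent-protein correction cancels protein-driven change", {
  design <- tiny_design(1L)
  samples <- design$sample
  site_m <- matrix(c(2.0, 0.5, 1.5, 0.5), 2, byrow = TRUE,
                   dimnames = list(c("P1_K5", "P9_K2"), samples))
  prot_m <- matrix(c(1.0, 0.5), 1, dimnames = list("P1", samples))
  site_R <- structure(list(matrix = site_m, provenance = "site",
                           dropped = character()), class = "relquant")
  prot_R <- structure(list(matrix = prot_m, provenance = "protein",
                           dropped = character()), class = "relquant")
  cor <- protein_correct(site_R, prot_R,
                         c(P1_K5 = "P1", P9_K2 = "P9"))
  expect_equal(unname(cor$matrix["P1_K5", ]), c(2.0, 1.0))
  expect_equal(cor$parent_missing, "P9_K2")
  # a site tracking its parent exactly corrects to all 1
  site_R2 <- structure(list(matrix = prot_m, provenance = "site",
                            dropped = character()), class = "relquant")
  rownames(site_R2$matrix) <- "P1_K7"
  cor2 <- protein_correct(site_R2, prot_R, c(P1_K7 = "P1"))
  expect_equal(unname(cor2$matrix[1, ]), c(1, 1))
  # sample mismatch is an alignment error
  prot_bad <- prot_R
  colnames(prot_bad$matrix) <- rev(samples)
  expect_error(protein_correct(site_R, prot_bad, c(P1_K5 = "P1", P9_K2 = "P9")),
               "mismatch")
})

test_that("correction removes confounding on synthetic data but keeps true effects", {
  cfg <- generator_config(n_proteins = 250, frac_sites_up = 0.1,
                          frac_sites_down = 0, site_effect_log2fc = 1.0,
                          frac_confounded_sites = 0.15,
                          protein_effect_log2fc = 1.0, replicate_cv = 0.2,
                          missing_rate = 0, seed = 17)
  d <- generate_dataset(cfg)
  pre <- preprocess_study(d$proteome, d$sites, d$design)
  cl <- setNames(d$truth$sites$class, d$truth$sites$site_id)
  ctrl <- d$design$sample[d$design$group == "control"]
  stv <- d$design$sample[d$design$group == "starved"]
  M <- pre$corrected$matrix
  lfc <- log2(rowMeans(M[, stv], na.rm = TRUE) /
                rowMeans(M[, ctrl], na.rm = TRUE))
  conf <- lfc[cl[names(lfc)] == "protein-confounded"]
  up <- lfc[cl[names(lfc)] == "up"]
  raw <- pre$site_filter$matrix
  raw_lfc <- log2(rowMeans(raw[, stv], na.rm = TRUE) /
                    rowMeans(raw[, ctrl], na.rm = TRUE))
  raw_conf <- raw_lfc[cl[names(raw_lfc)] == "protein-confounded"]
  expect_lt(abs(mean(conf)), 0.1)
  expect_lt(abs(mean(up) - 1.0), 3 * sd(up) / sqrt(length(up)) + 0.05)
  expect_gt(mean(raw_conf), 0.8)
})
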