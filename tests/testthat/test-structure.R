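test_that("minimal atomic distance equals the brute-force atom-pair minimum", {
  st <- line_structure()
  expect_equal(min_atomic_distance(st, 1L, 2L), 5.0)
  expect_equal(min_atomic_distance(st, 1L, 3L), 7.1)
  expect_equal(min_atomic_distance(st, 1L, c(2L, 3L)), 5.0)
  # symmetric in its two residues
  expect_equal(min_atomic_distance(st, 2L, 1L),
               min_atomic_distance(st, 1L, 2L))
  # residue against itself
  expect_equal(min_atomic_distance(st, 1L, 1L), 0.0)
  # empty set: absent, not zero
  expect_true(is.na(min_atomic_distance(st, 1L, integer())))
  # brute force on a multi-atom toy fixture
  atoms <- data.frame(resno = c(1L, 1L, 2L, 2L, 2L),
                      resname = c("LYS", "LYS", "ASP", "ASP", "ASP"),
                      atom = c("CA", "NZ", "CA", "OD1", "OD2"),
                      x = c(0, 1, 4, 3.5, 6), y = c(0, 1, 0, 2, 1),
                      z = c(0, 0, 0, 1, 0))
  st2 <- generate_toy_structure(atoms)
  a <- as.matrix(atoms[atoms$resno == 1, c("x", "y", "z")])
  b <- as.matrix(atoms[atoms$resno == 2, c("x", "y", "z")])
  expect_equal(min_atomic_distance(st2, 1L, 2L), brute_min_dist(a, b),
               tolerance = 1e-6)
})

test_that("lysine classification is total and follows the 5 Angstrom rule", {
  expect_equal(classify_lysine(TRUE, 4.2), "overlap+near")
  expect_equal(classify_lysine(TRUE, 7.0), "overlap-only")
  expect_equal(classify_lysine(TRUE, NA), "overlap-only")
  expect_equal(classify_lysine(FALSE, 3.0), "near-only")
  expect_equal(classify_lysine(FALSE, 8.0), "neither")
  expect_equal(classify_lysine(FALSE, NA), "neither")
  expect_equal(classify_lysine(TRUE, 5.0), "overlap+near")   # boundary: <= 5
  # every (boolean, distance-or-absent) combination maps to one category
  for (ov in c(TRUE, FALSE))
    for (d in list(0, 4.9, 5.0, 5.1, 100, NA_real_)) {
      cat_ <- classify_lysine(ov, d)
      expect_true(cat_ %in% c("overlap+near", "overlap-only",
                              "near-only", "neither"))
    }
})

test_that("conservation scores are entropy-based and map to reference numbering", {
  msa <- c(ref = "KKAR-", s2 = "KRAR-", s3 = "KRA--", s4 = "KKARW",
           s5 = "KRACW", s6 = "KKAGW", s7 = "KRAAW", s8 = "KKATW",
           s9 = "KRAYW", s10 = "KKAVW")
  cp <- conservation_scores(msa, "ref")
  expect_equal(cp$score[1], 1.0)                         # invariant column
  expect_equal(cp$score[2], 1 - log(2) / log(20),        # half K / half R
               tolerance = 1e-12)
  expect_equal(cp$score[5], 1.0)        # invariant among non-gap rows
  expect_true(is.na(cp$ref_position[5])) # reference gap: no residue number
  expect_equal(cp$ref_position[1:4], 1:4)
  # a uniform column over all 20 residues scores 0
  msa20 <- setNames(paste0(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "A"),
                    paste0("s", 1:20))
  cp20 <- conservation_scores(msa20, "s1")
  expect_equal(cp20$score[1], 0, tolerance = 1e-12)
  expect_equal(cp20$score[2], 1)
  # duplicated-sequence alignment scores 1 at every non-gap column
  dup <- setNames(rep("KARW", 5), paste0("d", 1:5))
  expect_true(all(conservation_scores(dup, "d1")$score == 1))
  expect_error(conservation_scores(msa, "nope"), "absent")
  expect_error(conservation_scores(msa[1:2], "ref"), ">= 3")
})

test_that("columns gappier than the cutoff are scored absent", {
  msa <- c(a = "K-", b = "K-", c = "K-", d = "KA")
  cp <- conservation_scores(msa, "a")
  expect_true(is.na(cp$score[2]))   # 75% gaps
  expect_equal(cp$score[1], 1)
})

test_that("lysine reports combine distances, overlap, category and conservation", {
  demo <- kbhbatlas:::.demo_structure_spec()
  st <- generate_toy_structure(demo$atoms, demo$kbhb_lysines,
                               demo$functional_residues, demo$ptm_residues)
  rep_ <- lysine_report(st)
  expect_equal(nrow(rep_), 4L)
  got <- setNames(rep_$category, rep_$residue)
  expect_equal(got[["10"]], "overlap+near")
  expect_equal(got[["20"]], "overlap-only")
  expect_equal(got[["30"]], "near-only")
  expect_equal(got[["40"]], "neither")
  expect_equal(rep_$min_dist_functional[rep_$residue == 10], 3.0)
})

test_that("prioritization flags conserved, functionally proximal lysines", {
  rep_ <- data.frame(residue = c(1L, 2L, 3L, 4L),
                     min_dist_functional = c(3, 4, 2, 3),
                     min_dist_ptm = NA_real_,
                     overlaps_ptm = c(FALSE, FALSE, FALSE, TRUE),
                     category = c("near-only", "near-only", "neither",
                                  "overlap+near"),
                     conservation = c(0.9, 0.9, 0.99, 0.5))
  pr <- prioritize(rep_)
  expect_equal(sum(pr$priority), 2L)        # residues 1 and 2
  # equal conservation: smaller distance ranks first
  flagged <- pr[pr$priority, ]
  expect_equal(flagged$residue, c(1L, 2L))
  expect_false(pr$priority[pr$residue == 3])  # conserved but not proximal
  expect_false(pr$priority[pr$residue == 4])  # proximal but not conserved
  # conservation 0.5 never flagged regardless of category
  expect_equal(sum(prioritize(rep_, conservation_min = 0.85,
                              require_near_or_overlap = FALSE)$priority), 3L)
})
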