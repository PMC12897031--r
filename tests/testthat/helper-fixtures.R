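# shared fixtures for the test suite; everything is generated in code

tiny_design <- function(nrep = 4L) {
  sample_design(c(paste0("GA_C", seq_len(nrep)), paste0("GA_S", seq_len(nrep))),
                rep(c("control", "starved"), each = nrep))
}

# small intensity matrix with named rows/columns
tiny_matrix <- function(values, features, design) {
  matrix(values, nrow = length(features), byrow = TRUE,
         dimnames = list(features, design$sample))
}

# exhaustive hypergeometric enumeration: P[X >= k] by direct combinatorial sum
enum_hyper_upper <- function(k, K, n, N) {
  ks <- k:min(n, K)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# two-sided Fisher exact p by enumeration over all tables with the same
# margins, summing probabilities <= that of the observed table
enum_fisher_two_sided <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; m1 <- a + c; N <- n1 + n2
  support <- max(0L, m1 - n2):min(n1, m1)
  probs <- choose(n1, support) * choose(n2, m1 - support) / choose(N, m1)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# sort / average / map-back quantile normalization for complete matrices
oracle_quantile_normalize <- function(mat) {
  ref <- rowMeans(apply(mat, 2L, sort))
  apply(mat, 2L, function(col) ref[rank(col, ties.method = "average")])
}

# brute-force minimal atom-pair distance between two coordinate sets
brute_min_dist <- function(a, b) {
  min(apply(a, 1L, function(p)
    apply(b, 1L, function(q) sqrt(sum((p - q)^2)))))
}

# toy structure spec used across structure tests: residues on a line
line_structure <- function() {
  atoms <- data.frame(
    resno = c(1L, 2L, 3L),
    resname = c("LYS", "ASP", "GLY"),
    atom = c("NZ", "OD1", "CA"),
    x = c(0, 3, 7.1), y = c(0, 4, 0), z = c(0, 0, 0),
    stringsAsFactors = FALSE)
  generate_toy_structure(atoms, kbhb_lysines = 1L,
                         functional_residues = c(2L, 3L))
}
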