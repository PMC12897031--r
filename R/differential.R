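#' Two-sample pooled-variance (Student) t test
#'
#' Classical equal-variance two-sample t statistic with two-sided p value.
#' Degenerate zero-variance inputs are handled explicitly: equal means give
#' t = 0, p = 1; unequal means with zero pooled variance give p = 0 with a
#' `degenerate` flag.
#'
#' @param a,b numeric vectors (at least 2 values each).
#' @return list: `t`, `df`, `p`, `degenerate`.
#' @export
pooled_t_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("need >= 2 valid values per group")
  df <- na + nb - 2L
  sp2 <- ((na - 1L) * stats::var(a) + (nb - 1L) * stats::var(b)) / df
  dm <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (dm == 0) return(list(t = 0, df = df, p = 1, degenerate = FALSE))
    return(list(t = sign(dm) * Inf, df = df, p = 0, degenerate = TRUE))
  }
  tt <- dm / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df), degenerate = FALSE)
}

#' Significance classification from fold change and p value
#'
#' A feature is `up` when p < `alpha` and log2 fold change > `fc_threshold`,
#' `down` when p < `alpha` and log2 fold change < -`fc_threshold`, and `ns`
#' otherwise. Both comparisons are strict; the default fold-change cutoff
#' 0.585 corresponds to a 1.5-fold change (see [fc_threshold_log2()]).
#'
#' @param log2fc numeric vector of log2 fold changes.
#' @param p numeric vector of p values.
#' @param alpha nominal significance level.
#' @param fc_threshold absolute log2 fold-change cutoff.
#' @return character vector in `{"up","down","ns"}`.
#' @export
classify <- function(log2fc, p, alpha = 0.05, fc_threshold = 0.585) {
  stopifnot(length(log2fc) == length(p))
  out <- rep("ns", length(p))
  out[p < alpha & log2fc > fc_threshold] <- "up"
  out[p < alpha & log2fc < -fc_threshold] <- "down"
  out[is.na(p) | is.na(log2fc)] <- NA_character_
  out
}

#' Log2 fold-change threshold for a given linear fold change
#'
#' @param fold linear fold change (default 1.5).
#' @return `log2(fold)`; `log2(1.5)` rounds to 0.585 at 3 decimals.
#' @export
fc_threshold_log2 <- function(fold = 1.5) log2(fold)

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment (reported alongside the nominal
#' p values; classification uses the nominal p).
#'
#' @param p numeric vector of p values in (0, 1].
#' @return adjusted p values, same length.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Differential abundance analysis of a feature matrix
#'
#' Runs a pooled t test on log2-transformed values per feature, computes
#' fold change as the ratio of linear-scale group means (starved over
#' control), classifies by nominal p and fold-change thresholds, and reports
#' BH-adjusted p values alongside. Features with fewer than 2 valid values
#' in either group are untestable; among them, those with at least
#' `min_valid` valid values in one group and at most 1 in the other are
#' listed in a separate presence/absence report.
#'
#' @param mat linear-scale feature x sample matrix (corrected site values or
#'   normalized protein intensities).
#' @param design a [sample_design()].
#' @param groups length-2 character vector `(reference, treatment)`; fold
#'   change is treatment over reference. Defaults to the design's group
#'   order.
#' @param alpha,fc_threshold classification thresholds.
#' @param min_valid presence/absence cutoff.
#' @return list of class `differential_result`: `table` (data.frame feature,
#'   mean_control, mean_starved, log2fc, t, p_value, bh_adjusted_p, class,
#'   n_control, n_starved, degenerate), `untestable`, `presence_absence`.
#' @export
differential_test <- function(mat, design, groups = design_groups(design),
                              alpha = 0.05, fc_threshold = 0.585,
                              min_valid = 3L) {
  stopifnot(length(groups) == 2L, all(groups %in% design$group))
  ref_cols <- design$sample[design$group == groups[1L]]
  trt_cols <- design$sample[design$group == groups[2L]]
  A <- mat[, ref_cols, drop = FALSE]
  B <- mat[, trt_cols, drop = FALSE]
  nA <- rowSums(!is.na(A)); nB <- rowSums(!is.na(B))
  testable <- nA >= 2L & nB >= 2L

  feats <- rownames(mat)
  rows <- lapply(which(testable), function(i) {
    a <- A[i, ]; b <- B[i, ]
    tt <- pooled_t_test(log2(b[!is.na(b)]), log2(a[!is.na(a)]))
    ma <- mean(a, na.rm = TRUE); mb <- mean(b, na.rm = TRUE)
    data.frame(feature = feats[i], mean_control = ma, mean_starved = mb,
               log2fc = log2(mb / ma), t = tt$t, p_value = tt$p,
               n_control = nA[i], n_starved = nB[i],
               degenerate = tt$degenerate, stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature = character(), mean_control = numeric(),
               mean_starved = numeric(), log2fc = numeric(), t = numeric(),
               p_value = numeric(), n_control = integer(),
               n_starved = integer(), degenerate = logical())
  tab$bh_adjusted_p <- bh_adjust(tab$p_value)
  tab$class <- classify(tab$log2fc, tab$p_value, alpha, fc_threshold)
  tab <- tab[, c("feature", "mean_control", "mean_starved", "log2fc", "t",
                 "p_value", "bh_adjusted_p", "class", "n_control",
                 "n_starved", "degenerate")]
  rownames(tab) <- tab$feature

  untestable <- feats[!testable]
  pa <- feats[(nA >= min_valid & nB <= 1L) | (nB >= min_valid & nA <= 1L)]
  structure(list(table = tab, untestable = untestable,
                 presence_absence = pa,
                 groups = groups, alpha = alpha,
                 fc_threshold = fc_threshold),
            class = "differential_result")
}

#' @export
print.differential_result <- function(x, ...) {
  cl <- table(factor(x$table$class, levels = c("up", "down", "ns")))
  cat("Differential analysis (", x$groups[2L], " vs ", x$groups[1L], "): ",
      nrow(x$table), " features tested; up ", cl[["up"]], ", down ",
      cl[["down"]], ", ns ", cl[["ns"]], "; ", length(x$untestable),
      " untestable (", length(x$presence_absence),
      " presence/absence)\n", sep = "")
  invisible(x)
}
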