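#' Replicate-validity, localization and length filtering
#'
#' Retains features quantified with at least `min_valid` valid (non-missing)
#' intensities in at least one experimental group. For site tables (when
#' `site_meta` is supplied) two further rules apply first: modification
#' localization probability at least `loc_prob_min` and peptide length at
#' least `min_peptide_len`. Every dropped feature is logged with the first
#' rule it failed.
#'
#' @param mat features x samples intensity matrix (NA = missing).
#' @param design a [sample_design()].
#' @param min_valid minimal number of valid values required in one group.
#' @param site_meta optional site record data.frame (rownames matching
#'   `mat`) carrying `localization_prob` and optionally `peptide_length`.
#' @param loc_prob_min localization probability cutoff.
#' @param min_peptide_len minimal peptide length.
#' @return list with `matrix` (kept rows), `rejected` (data.frame feature,
#'   reason), and for site tables `site_meta` subset to kept rows.
#' @export
filter_features <- function(mat, design, min_valid = 3L, site_meta = NULL,
                            loc_prob_min = 0.90, min_peptide_len = 7L) {
  gsizes <- table(design$group)
  if (min_valid > max(gsizes))
    stop("configuration error: min_valid (", min_valid,
         ") exceeds the largest group size (", max(gsizes), ")")
  if (nrow(mat) == 0L) {
    return(list(matrix = mat,
                rejected = data.frame(feature = character(),
                                      reason = character()),
                site_meta = site_meta))
  }
  reason <- rep(NA_character_, nrow(mat))
  feats <- rownames(mat)
  if (!is.null(site_meta)) {
    stopifnot(all(feats %in% rownames(site_meta)))
    sm <- site_meta[feats, , drop = FALSE]
    reason[is.na(reason) & sm$localization_prob < loc_prob_min] <- "localization"
    if (!is.null(sm$peptide_length))
      reason[is.na(reason) & sm$peptide_length < min_peptide_len] <- "peptide_length"
  }
  groups <- design_groups(design)
  valid_by_group <- sapply(groups, function(g) {
    cols <- design$sample[design$group == g]
    rowSums(!is.na(mat[, cols, drop = FALSE]))
  })
  enough <- apply(valid_by_group >= min_valid, 1L, any)
  reason[is.na(reason) & !enough] <- "replicate_validity"

  keep <- is.na(reason)
  rejected <- data.frame(feature = feats[!keep], reason = reason[!keep],
                         stringsAsFactors = FALSE)
  list(matrix = mat[keep, , drop = FALSE],
       rejected = rejected,
       site_meta = if (!is.null(site_meta))
         site_meta[feats[keep], , drop = FALSE] else NULL)
}

#' Quantile normalization of an intensity matrix
#'
#' Forces every column onto a common reference distribution: the row-wise
#' mean of the column-sorted values. After normalization, each column's
#' sorted non-missing values equal that reference and within-column ranks
#' are preserved. Tied values receive the mean of the reference values at
#' their tied ranks. Columns with differing numbers of missing values are
#' matched to the reference by linear interpolation on the quantile scale.
#' Intended for log2-scale proteome LFQ intensities.
#'
#' @param mat numeric matrix (features x samples); NA allowed.
#' @return normalized matrix, same dimensions and NA pattern.
#' @export
quantile_normalize <- function(mat) {
  if (is.null(dim(mat)) || ncol(mat) < 1L) stop("need a matrix with >= 1 column")
  nvalid <- colSums(!is.na(mat))
  if (any(nvalid == 0L))
    stop("all-missing column(s): ",
         paste(colnames(mat)[nvalid == 0L], collapse = ", "))
  n <- nrow(mat)
  grid <- (seq_len(n) - 0.5) / n
  # reference = mean across columns of each column's empirical quantile fn
  ref_cols <- sapply(seq_len(ncol(mat)), function(j) {
    v <- sort(mat[, j], na.last = NA)
    if (length(v) == 1L) rep(v, n)
    else stats::approx((seq_along(v) - 0.5) / length(v), v,
                       xout = grid, rule = 2L)$y
  })
  ref <- rowMeans(ref_cols)
  out <- mat
  for (j in seq_len(ncol(mat))) {
    ok <- !is.na(mat[, j])
    m <- sum(ok)
    r <- rank(mat[ok, j], ties.method = "average")
    out[ok, j] <- stats::approx(grid, ref, xout = (r - 0.5) / m, rule = 2L)$y
  }
  out
}

#' Center-scale relative quantification
#'
#' Converts linear-scale intensities to relative values by dividing each
#' feature's intensity by its mean over valid samples, so every row of the
#' result averages exactly 1 over its valid entries. Rows with no valid
#' value are dropped and logged.
#'
#' @param mat linear-scale intensity matrix, positive where valid.
#' @param provenance `"site"` or `"protein"`, recorded on the result.
#' @return list of class `relquant`: `matrix` (relative values), `provenance`,
#'   `dropped` (character vector of all-missing features).
#' @export
center_scale <- function(mat, provenance = c("site", "protein")) {
  provenance <- match.arg(provenance)
  if (any(mat <= 0, na.rm = TRUE))
    stop("center_scale expects positive linear-scale intensities")
  rm_ <- rowMeans(mat, na.rm = TRUE)
  dropped <- rownames(mat)[!is.finite(rm_)]
  keep <- is.finite(rm_)
  res <- mat[keep, , drop = FALSE] / rm_[keep]
  structure(list(matrix = res, provenance = provenance, dropped = dropped),
            class = "relquant")
}

#' @export
print.relquant <- function(x, ...) {
  cat("Relative quantification (", x$provenance, "): ",
      nrow(x$matrix), " features x ", ncol(x$matrix), " samples; ",
      length(x$dropped), " all-missing row(s) dropped\n", sep = "")
  invisible(x)
}

#' Parent-protein abundance correction of site stoichiometry
#'
#' Divides each site's center-scaled relative value by the relative
#' quantification value of its parent protein in the same sample, yielding a
#' protein-abundance-normalized modification level: changes driven purely by
#' parent-protein expression cancel, changes in modification stoichiometry
#' remain. Sites whose parent protein is absent from the proteome table are
#' marked `parent-missing`, excluded from the corrected matrix, and logged.
#'
#' @param site_R `relquant` of the site table.
#' @param protein_R `relquant` of the proteome.
#' @param parent_map named character vector: site id -> parent accession
#'   (must cover every site row).
#' @return list of class `corrected_sites`: `matrix` (corrected site x
#'   sample values, NA where either input is missing), `parent` (named
#'   vector for corrected sites), `parent_missing` (site ids excluded).
#' @export
protein_correct <- function(site_R, protein_R, parent_map) {
  stopifnot(inherits(site_R, "relquant"), inherits(protein_R, "relquant"))
  sm <- site_R$matrix
  pm <- protein_R$matrix
  if (!identical(colnames(sm), colnames(pm)))
    stop("sample-name mismatch between site and protein tables")
  sites <- rownames(sm)
  if (!all(sites %in% names(parent_map)))
    stop("parent_map must cover every site feature")
  parent <- parent_map[sites]
  has_parent <- parent %in% rownames(pm)
  corrected <- sm[has_parent, , drop = FALSE] /
    pm[parent[has_parent], , drop = FALSE]
  structure(list(matrix = corrected,
                 parent = parent[has_parent],
                 parent_missing = sites[!has_parent]),
            class = "corrected_sites")
}

#' @export
print.corrected_sites <- function(x, ...) {
  cat("Protein-abundance-corrected site table:", nrow(x$matrix), "sites x",
      ncol(x$matrix), "samples;", length(x$parent_missing),
      "site(s) with unquantified parent excluded\n")
  invisible(x)
}

#' Full preprocessing of a synthetic or file-based study
#'
#' Applies the canonical order of operations: replicate-validity (and, for
#' sites, localization/length) filtering of both tables; quantile
#' normalization of the log2 proteome LFQ matrix; center-scale relative
#' quantification of the (back-transformed) proteome and of the linear-scale
#' site intensities; parent-protein correction of the site values.
#'
#' @param proteome linear-scale protein intensity matrix.
#' @param sites site record data.frame with intensity columns.
#' @param design a [sample_design()].
#' @param min_valid,loc_prob_min,min_peptide_len filter settings.
#' @param quantile_normalize_sites also quantile-normalize the site
#'   intensity matrix before center-scaling (default FALSE: the site table
#'   is normalized by center-scale + parent correction only).
#' @return list: `protein_filter`, `site_filter` (filter results),
#'   `proteome_norm` (linear-scale quantile-normalized proteome),
#'   `protein_R`, `site_R` (relquant), `corrected` (corrected_sites),
#'   `parent_map`.
#' @export
preprocess_study <- function(proteome, sites, design, min_valid = 3L,
                             loc_prob_min = 0.90, min_peptide_len = 7L,
                             quantile_normalize_sites = FALSE) {
  pf <- filter_features(proteome, design, min_valid = min_valid)
  smat <- site_intensity_matrix(sites, design)
  sf <- filter_features(smat, design, min_valid = min_valid, site_meta = sites,
                        loc_prob_min = loc_prob_min,
                        min_peptide_len = min_peptide_len)
  prot_norm <- 2^quantile_normalize(log2(pf$matrix))
  protein_R <- center_scale(prot_norm, "protein")
  site_mat <- sf$matrix
  if (quantile_normalize_sites) site_mat <- 2^quantile_normalize(log2(site_mat))
  site_R <- center_scale(site_mat, "site")
  parent_map <- stats::setNames(sf$site_meta$protein, rownames(sf$site_meta))
  corrected <- protein_correct(site_R, protein_R, parent_map)
  list(protein_filter = pf, site_filter = sf, proteome_norm = prot_norm,
       protein_R = protein_R, site_R = site_R, corrected = corrected,
       parent_map = parent_map)
}
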