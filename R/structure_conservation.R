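LYSINE_CATEGORIES <- c("overlap+near", "overlap-only", "near-only", "neither")

.res_coords <- function(geom, resno) {
  at <- geom$atoms[geom$atoms$resno == resno, c("x", "y", "z"), drop = FALSE]
  if (nrow(at) == 0L) stop("residue ", resno, " absent from structure")
  as.matrix(at)
}

#' Minimal atomic distance between a residue and a residue set
#'
#' Minimum Euclidean distance over all heavy-atom pairs between the atoms of
#' `resno` and the atoms of every residue in `residue_set`. An empty set
#' gives `NA` (distance undefined, not 0).
#'
#' @param geom a `residue_geometry`.
#' @param resno residue number of the query residue.
#' @param residue_set integer vector of residue numbers.
#' @return distance in Angstrom, or `NA_real_` for an empty set.
#' @export
min_atomic_distance <- function(geom, resno, residue_set) {
  if (length(residue_set) == 0L) return(NA_real_)
  a <- .res_coords(geom, resno)
  d <- vapply(residue_set, function(r) {
    b <- .res_coords(geom, r)
    # all pairwise distances between the two atom sets
    dd <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
    sqrt(max(0, min(dd)))
  }, numeric(1))
  min(d)
}

#' Four-category spatial classification of a modified lysine
#'
#' Classifies a lysine by whether it coincides with a known-PTM residue and
#' whether it lies within `cutoff` Angstrom of a functional
#' (catalytic/cofactor-binding) residue: `overlap+near`, `overlap-only`,
#' `near-only`, or `neither`. An absent distance (no functional residues)
#' counts as "not near".
#'
#' @param overlaps_ptm logical: the lysine itself is a known-PTM residue.
#' @param min_dist_functional distance in Angstrom, or `NA`.
#' @param cutoff proximity cutoff in Angstrom (default 5).
#' @return one of the four category labels.
#' @export
classify_lysine <- function(overlaps_ptm, min_dist_functional, cutoff = 5.0) {
  near <- !is.na(min_dist_functional) && min_dist_functional <= cutoff
  if (overlaps_ptm && near) "overlap+near"
  else if (overlaps_ptm) "overlap-only"
  else if (near) "near-only"
  else "neither"
}

#' Per-column conservation scores from a multiple sequence alignment
#'
#' Scores each alignment column as 1 minus the Shannon entropy of its
#' residue frequencies normalized by log(20), so an invariant column scores
#' 1 and a column drawing all twenty residues uniformly scores 0. Gaps are
#' excluded from the frequencies; columns with more than 50% gaps are
#' scored `NA`. Scores are mapped to the reference sequence's residue
#' numbering (non-gap reference columns only).
#'
#' @param msa named character vector of aligned sequences (equal width,
#'   `-` for gaps), e.g. from [read_fasta()] on an aligned FASTA.
#' @param reference_id name of the reference sequence.
#' @param max_gap_frac columns gappier than this are scored `NA`.
#' @return data.frame of class `conservation_profile`: column, ref_position
#'   (NA at reference gaps), score.
#' @export
conservation_scores <- function(msa, reference_id, max_gap_frac = 0.5) {
  if (!reference_id %in% names(msa))
    stop("reference sequence '", reference_id, "' absent from alignment")
  if (length(msa) < 3L) stop("need >= 3 aligned sequences")
  widths <- unique(nchar(msa))
  if (length(widths) != 1L) stop("aligned sequences must have equal width")
  m <- do.call(rbind, strsplit(toupper(msa), ""))
  ref <- strsplit(toupper(msa[[reference_id]]), "")[[1]]
  scores <- apply(m, 2L, function(col) {
    res <- col[col %in% AA20]
    gap_frac <- 1 - length(res) / length(col)
    if (gap_frac > max_gap_frac || length(res) == 0L) return(NA_real_)
    f <- table(res) / length(res)
    h <- -sum(f * log(f))
    1 - h / log(20)
  })
  ref_pos <- cumsum(ref != "-")
  ref_pos[ref == "-"] <- NA_integer_
  out <- data.frame(column = seq_len(widths), ref_position = ref_pos,
                    score = scores)
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Structural report for the Kbhb lysines of a structure
#'
#' For every labelled Kbhb lysine, computes the minimal atomic distance to
#' the functional-residue set and to the known-PTM residue set, whether the
#' lysine itself is a known-PTM residue, the four-way spatial category, and
#' (when a conservation profile is supplied) the conservation score at that
#' residue.
#'
#' @param geom a `residue_geometry` with labelled residue sets.
#' @param conservation optional `conservation_profile`; scores are looked
#'   up by `ref_position`.
#' @param cutoff proximity cutoff in Angstrom.
#' @return data.frame of class `lysine_report`: residue, min_dist_functional,
#'   min_dist_ptm, overlaps_ptm, category, conservation.
#' @export
lysine_report <- function(geom, conservation = NULL, cutoff = 5.0) {
  ks <- geom$kbhb_lysines
  rows <- lapply(ks, function(k) {
    df <- min_atomic_distance(geom, k, geom$functional_residues)
    dp <- min_atomic_distance(geom, k, setdiff(geom$ptm_residues, k))
    ov <- k %in% geom$ptm_residues
    cons <- NA_real_
    if (!is.null(conservation)) {
      hit <- conservation$score[match(k, conservation$ref_position)]
      if (length(hit) == 1L) cons <- hit
    }
    data.frame(residue = k, min_dist_functional = df, min_dist_ptm = dp,
               overlaps_ptm = ov,
               category = classify_lysine(ov, df, cutoff),
               conservation = cons, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(residue = integer(), min_dist_functional = numeric(),
               min_dist_ptm = numeric(), overlaps_ptm = logical(),
               category = character(), conservation = numeric())
  class(out) <- c("lysine_report", "data.frame")
  out
}

#' Prioritize modified lysines by conservation and spatial proximity
#'
#' Flags lysines that are both highly conserved (conservation above
#' `conservation_min`) and spatially implicated (category `overlap+near` or
#' `near-only`, i.e. within the distance cutoff of a functional residue;
#' set `require_near_or_overlap = FALSE` to flag on conservation alone).
#' Flagged sites are ranked by conservation (descending), then distance to
#' the nearest functional residue (ascending).
#'
#' @param reports a `lysine_report` (or rbind of several).
#' @param conservation_min conservation cutoff (default 0.85).
#' @param require_near_or_overlap restrict the flag to the two
#'   functional-proximal categories.
#' @return the report with added `priority` flag, flagged rows first in
#'   rank order.
#' @export
prioritize <- function(reports, conservation_min = 0.85,
                       require_near_or_overlap = TRUE) {
  cons_ok <- !is.na(reports$conservation) &
    reports$conservation > conservation_min
  cat_ok <- if (require_near_or_overlap)
    reports$category %in% c("overlap+near", "near-only") else TRUE
  reports$priority <- cons_ok & cat_ok
  ord <- order(!reports$priority, -reports$conservation,
               reports$min_dist_functional)
  out <- reports[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
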