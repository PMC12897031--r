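#' Extract a +/-7 sequence window around a modified lysine
#'
#' Returns the 15-mer centered on the modified residue, padded with `_`
#' where the flank runs past either sequence terminus.
#'
#' @param sequence protein sequence (single string).
#' @param position 1-based residue position of the modified K.
#' @param flank flank width (default 7).
#' @return character string of length `2*flank + 1`.
#' @export
extract_window <- function(sequence, position, flank = 7L) {
  n <- nchar(sequence)
  if (position < 1L || position > n)
    stop("position ", position, " out of range for sequence of length ", n)
  if (substr(sequence, position, position) != "K")
    stop("residue at position ", position, " is not K")
  lo <- position - flank
  hi <- position + flank
  core <- substr(sequence, max(1L, lo), min(n, hi))
  paste0(strrep("_", max(0L, 1L - lo)), core, strrep("_", max(0L, hi - n)))
}

.window_residue_counts <- function(windows, flank = 7L) {
  # matrix of characters: windows x positions
  if (length(windows) == 0L)
    return(matrix(character(), 0L, 2L * flank + 1L))
  do.call(rbind, strsplit(windows, ""))
}

#' Two-sample position-specific residue enrichment
#'
#' For every flanking offset (-flank..+flank, excluding the modified center)
#' and every residue observed there, tests whether the residue is enriched
#' or depleted in the foreground windows relative to the background windows
#' with a two-sided Fisher exact test on the 2x2 presence table. Padding
#' (`_`) never counts as a residue.
#'
#' @param foreground,background character vectors of equal-width windows.
#' @param flank flank width (windows are `2*flank+1` characters).
#' @param p_max report entries with p below this value (set to 1 to return
#'   every tested pair).
#' @return data.frame of class `position_enrichment`: offset, residue,
#'   fg_count, fg_total, fg_freq, bg_count, bg_total, bg_freq, p_value,
#'   direction (`enriched`/`depleted`), sorted by p.
#' @export
two_sample_position_test <- function(foreground, background, flank = 7L,
                                     p_max = 0.05) {
  if (length(background) == 0L) stop("background must be nonempty")
  if (length(foreground) == 0L) {
    warning("empty foreground; no enrichment computed")
    return(.empty_position_enrichment())
  }
  fg <- .window_residue_counts(foreground, flank)
  bg <- .window_residue_counts(background, flank)
  center <- flank + 1L
  rows <- list()
  for (col in seq_len(2L * flank + 1L)) {
    if (col == center) next
    offset <- col - center
    fg_res <- fg[, col]; fg_res <- fg_res[fg_res != "_"]
    bg_res <- bg[, col]; bg_res <- bg_res[bg_res != "_"]
    nf <- length(fg_res); nb <- length(bg_res)
    if (nf == 0L || nb == 0L) next
    for (r in sort(unique(c(fg_res, bg_res)))) {
      k <- sum(fg_res == r); K <- sum(bg_res == r)
      p <- stats::fisher.test(matrix(c(k, nf - k, K, nb - K), 2L, 2L,
                                     byrow = TRUE))$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        offset = offset, residue = r, fg_count = k, fg_total = nf,
        fg_freq = k / nf, bg_count = K, bg_total = nb, bg_freq = K / nb,
        p_value = min(p, 1),
        direction = if (k / nf >= K / nb) "enriched" else "depleted",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (p_max < 1) out <- out[out$p_value < p_max, , drop = FALSE]
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("position_enrichment", "data.frame")
  out
}

.empty_position_enrichment <- function() {
  out <- data.frame(offset = integer(), residue = character(),
                    fg_count = integer(), fg_total = integer(),
                    fg_freq = numeric(), bg_count = integer(),
                    bg_total = integer(), bg_freq = numeric(),
                    p_value = numeric(), direction = character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("position_enrichment", "data.frame")
  out
}

.binom_upper_tail <- function(k, n, p) stats::pbinom(k - 1L, n, p,
                                                     lower.tail = FALSE)

#' Iterative motif extraction (motif-x style)
#'
#' Greedy iterative procedure over aligned modification windows: at each
#' step, for every unfixed (offset, residue) pair, compute the binomial
#' upper-tail probability of observing the foreground count given the
#' background frequency; fix the most significant pair whose count meets
#' `min_occurrences` and whose p is below `binomial_p`; restrict both window
#' sets to matches and repeat. When no pair qualifies, the accumulated
#' pattern is emitted, its matching windows are removed from the original
#' sets, and the search restarts; extraction stops when no first-step pair
#' qualifies.
#'
#' @param foreground,background character vectors of equal-width windows.
#' @param flank flank width.
#' @param min_occurrences minimal foreground count to fix a position.
#' @param binomial_p binomial tail threshold to fix a position.
#' @return list of motifs; each has `pattern` (window-width string, `.` for
#'   unfixed positions, `K` center), `positions` (data.frame offset,
#'   residue, count, p_value), `n_matches`.
#' @export
motif_x_iterative <- function(foreground, background, flank = 7L,
                              min_occurrences = 20L, binomial_p = 1e-6) {
  center <- flank + 1L
  width <- 2L * flank + 1L
  motifs <- list()
  fg <- foreground
  bg <- background
  repeat {
    cur_fg <- fg
    cur_bg <- bg
    fixed <- list()
    repeat {
      if (length(cur_fg) == 0L || length(cur_bg) == 0L) break
      fgm <- .window_residue_counts(cur_fg, flank)
      bgm <- .window_residue_counts(cur_bg, flank)
      best <- NULL
      for (col in seq_len(width)) {
        if (col == center) next
        if (any(vapply(fixed, function(f) f$col == col, logical(1)))) next
        fg_res <- fgm[, col]; fg_res <- fg_res[fg_res != "_"]
        bg_res <- bgm[, col]; bg_res <- bg_res[bg_res != "_"]
        if (length(bg_res) == 0L) next
        for (r in unique(fg_res)) {
          k <- sum(fg_res == r)
          if (k < min_occurrences) next
          p0 <- sum(bg_res == r) / length(bg_res)
          pv <- .binom_upper_tail(k, length(fg_res), p0)
          if (pv < binomial_p && (is.null(best) || pv < best$p)) {
            best <- list(col = col, residue = r, count = k, p = pv)
          }
        }
      }
      if (is.null(best)) break
      fixed[[length(fixed) + 1L]] <- best
      keep_fg <- substr(cur_fg, best$col, best$col) == best$residue
      keep_bg <- substr(cur_bg, best$col, best$col) == best$residue
      cur_fg <- cur_fg[keep_fg]
      cur_bg <- cur_bg[keep_bg]
    }
    if (length(fixed) == 0L) break
    pat <- rep(".", width)
    pat[center] <- "K"
    for (f in fixed) pat[f$col] <- f$residue
    pattern <- paste(pat, collapse = "")
    matches <- vapply(fg, function(w) {
      all(vapply(fixed, function(f)
        substr(w, f$col, f$col) == f$residue, logical(1)))
    }, logical(1))
    motifs[[length(motifs) + 1L]] <- list(
      pattern = pattern,
      positions = data.frame(
        offset = vapply(fixed, function(f) f$col - center, integer(1)),
        residue = vapply(fixed, function(f) f$residue, ""),
        count = vapply(fixed, function(f) f$count, integer(1)),
        p_value = vapply(fixed, function(f) f$p, numeric(1))),
      n_matches = sum(matches))
    fg <- fg[!matches]
    bg_matches <- vapply(bg, function(w) {
      all(vapply(fixed, function(f)
        substr(w, f$col, f$col) == f$residue, logical(1)))
    }, logical(1))
    bg <- bg[!bg_matches]
    if (length(fg) == 0L) break
  }
  motifs
}
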