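#' Sample design: sample-to-group mapping
#'
#' Constructs and validates the experimental design used throughout the
#' pipeline: each mass-spectrometry sample belongs to one of two groups
#' (by convention `control` and `starved`) and carries a replicate index.
#'
#' @param samples character vector of unique sample (column) names.
#' @param groups character vector, same length, group label per sample.
#' @param replicates optional integer vector of replicate indices; defaults
#'   to 1..k within each group.
#' @return a `data.frame` of class `sample_design` with columns
#'   `sample`, `group`, `replicate`.
#' @examples
#' sample_design(c("C1","C2","S1","S2"), c("control","control","starved","starved"))
#' @export
sample_design <- function(samples, groups, replicates = NULL) {
  samples <- as.character(samples)
  groups <- as.character(groups)
  if (length(samples) != length(groups))
    stop("samples and groups must have the same length")
  if (anyDuplicated(samples))
    stop("sample names must be unique")
  if (length(unique(groups)) < 2L)
    stop("design must contain at least two groups")
  if (any(table(groups) == 0L))
    stop("each group must be nonempty")
  if (is.null(replicates)) {
    replicates <- stats::ave(seq_along(samples), groups, FUN = seq_along)
  }
  out <- data.frame(sample = samples, group = groups,
                    replicate = as.integer(replicates),
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_design", "data.frame")
  out
}

#' @export
print.sample_design <- function(x, ...) {
  cat("Sample design:", nrow(x), "samples,",
      length(unique(x$group)), "groups\n")
  NextMethod()
}

design_groups <- function(design) unique(design$group)

# Missing-intensity encodings accepted from MaxQuant-style tables:
# empty cell, "0", "NaN" (MaxQuant writes 0 for absent LFQ values).
.parse_intensity <- function(x) {
  x <- trimws(as.character(x))
  x[x == "" | x == "NaN" | x == "NA"] <- NA
  v <- suppressWarnings(as.numeric(x))
  v[!is.na(v) & v == 0] <- NA
  v
}

#' Read a Kbhb site table
#'
#' Reads a tab-delimited modification-site table in the package dialect:
#' required columns `protein`, `position` (1-based), `localization_prob`,
#' `sequence_window` (15-mer, modified K at position 8, `_`-padded at
#' sequence termini), optionally `peptide_length`, plus one intensity column
#' per sample named in `design`. Intensities of 0, empty, or NaN are parsed
#' as missing. Rows listing several accessions separated by `;` (shared
#' peptides) are assigned to the first accession with a warning.
#'
#' @param path path to the tab-delimited file.
#' @param design a [sample_design()].
#' @return a `data.frame` of site records with an attached numeric intensity
#'   matrix in columns named after the design samples; row names are site
#'   ids `accession_Kposition`.
#' @export
read_site_table <- function(path, design) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("protein", "position", "localization_prob", "sequence_window")
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop("site table is missing required column(s): ",
         paste(miss, collapse = ", "))
  miss_s <- setdiff(design$sample, names(tab))
  if (length(miss_s))
    stop("site table is missing intensity column(s) for sample(s): ",
         paste(miss_s, collapse = ", "))

  prot <- as.character(tab$protein)
  shared <- grepl(";", prot, fixed = TRUE)
  if (any(shared)) {
    warning(sum(shared), " row(s) list multiple accessions; ",
            "assigned to the first listed accession")
    prot[shared] <- vapply(strsplit(prot[shared], ";", fixed = TRUE),
                           `[[`, "", 1L)
  }
  pos <- as.integer(tab$position)
  lp <- as.numeric(tab$localization_prob)
  win <- as.character(tab$sequence_window)

  bad <- which(is.na(pos) | pos < 1L)
  if (length(bad))
    stop("invalid position at row(s): ", paste(bad, collapse = ", "))
  bad <- which(is.na(lp) | lp < 0 | lp > 1)
  if (length(bad))
    stop("localization probability outside [0,1] at row(s): ",
         paste(bad, collapse = ", "))
  bad <- which(nchar(win) != 15L)
  if (length(bad))
    stop("sequence window not 15 residues at row(s): ",
         paste(bad, collapse = ", "))
  bad <- which(substr(win, 8L, 8L) != "K")
  if (length(bad))
    stop("sequence window center is not K at row(s): ",
         paste(bad, collapse = ", "))

  out <- data.frame(protein = prot, position = pos,
                    localization_prob = lp, sequence_window = win,
                    stringsAsFactors = FALSE)
  if ("peptide_length" %in% names(tab))
    out$peptide_length <- as.integer(tab$peptide_length)
  for (s in design$sample) out[[s]] <- .parse_intensity(tab[[s]])
  rownames(out) <- paste0(out$protein, "_K", out$position)
  out
}

#' Write a Kbhb site table
#'
#' Inverse of [read_site_table()]; missing intensities are written as empty
#' cells so that write-then-read preserves missingness.
#'
#' @param sites site record `data.frame` as returned by [read_site_table()].
#' @param path output path.
#' @param design a [sample_design()] naming the intensity columns.
#' @export
write_site_table <- function(sites, path, design) {
  out <- sites
  for (s in design$sample) {
    v <- out[[s]]
    out[[s]] <- ifelse(is.na(v), "",
                       format(v, scientific = FALSE, trim = TRUE, digits = 15))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a proteinGroups-style protein quantification table
#'
#' Required columns: `protein` plus one LFQ intensity column per design
#' sample. Returns a numeric matrix (proteins x samples) with missing values
#' where the file holds 0, empty or NaN.
#'
#' @inheritParams read_site_table
#' @return numeric matrix, rownames = accessions, colnames = samples.
#' @export
read_protein_table <- function(path, design) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"protein" %in% names(tab))
    stop("protein table is missing required column: protein")
  miss_s <- setdiff(design$sample, names(tab))
  if (length(miss_s))
    stop("protein table is missing intensity column(s) for sample(s): ",
         paste(miss_s, collapse = ", "))
  m <- sapply(design$sample, function(s) .parse_intensity(tab[[s]]))
  m <- matrix(as.numeric(m), nrow = nrow(tab),
              dimnames = list(as.character(tab$protein), design$sample))
  if (anyDuplicated(rownames(m))) stop("duplicate protein accessions")
  m
}

#' Write a protein quantification table
#' @param mat proteins x samples numeric matrix.
#' @param path output path.
#' @export
write_protein_table <- function(mat, path) {
  out <- data.frame(protein = rownames(mat), stringsAsFactors = FALSE)
  for (s in colnames(mat)) {
    v <- mat[, s]
    out[[s]] <- ifelse(is.na(v), "",
                       format(v, scientific = FALSE, trim = TRUE, digits = 15))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector; names are the first whitespace-delimited
#'   token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readAAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[[`, "", 1L)
  seqs
}

#' Write sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a PDB-format structure into a residue geometry
#'
#' Consumes ATOM records only (first model, altloc blank or "A", heavy atoms
#' only -- hydrogens discarded) via `bio3d::read.pdb`.
#'
#' @param path PDB file.
#' @param kbhb_lysines,functional_residues,ptm_residues optional integer
#'   residue numbers labelling the modified lysines, the catalytic or
#'   cofactor-binding residues, and residues with known other PTMs.
#' @return object of class `residue_geometry`: a list with `atoms`
#'   (data.frame: chain, resno, resname, elety, x, y, z) and the three
#'   labelled residue sets.
#' @export
read_pdb <- function(path, kbhb_lysines = integer(), functional_residues = integer(),
                     ptm_residues = integer()) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  # drop hydrogens by element symbol when present, else by atom-name prefix
  if (!is.null(at$elesy) && any(nzchar(at$elesy))) {
    at <- at[toupper(trimws(at$elesy)) != "H", , drop = FALSE]
  } else {
    at <- at[!grepl("^H", trimws(at$elety)), , drop = FALSE]
  }
  atoms <- data.frame(chain = at$chain, resno = at$resno, resname = at$resid,
                      elety = at$elety, x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in ", path)
  residue_geometry(atoms, kbhb_lysines, functional_residues, ptm_residues)
}

#' Construct a residue geometry
#'
#' @param atoms data.frame with columns chain, resno, resname, elety, x, y, z.
#' @inheritParams read_pdb
#' @return object of class `residue_geometry`.
#' @export
residue_geometry <- function(atoms, kbhb_lysines = integer(),
                             functional_residues = integer(),
                             ptm_residues = integer()) {
  stopifnot(all(c("resno", "resname", "x", "y", "z") %in% names(atoms)))
  lab <- c(kbhb_lysines, functional_residues, ptm_residues)
  missing_res <- setdiff(lab, atoms$resno)
  if (length(missing_res))
    stop("labelled residue(s) absent from structure: ",
         paste(missing_res, collapse = ", "))
  structure(list(atoms = atoms,
                 kbhb_lysines = as.integer(kbhb_lysines),
                 functional_residues = as.integer(functional_residues),
                 ptm_residues = as.integer(ptm_residues)),
            class = "residue_geometry")
}

#' @export
print.residue_geometry <- function(x, ...) {
  cat("Residue geometry:", nrow(x$atoms), "heavy atoms,",
      length(unique(x$atoms$resno)), "residues;",
      length(x$kbhb_lysines), "Kbhb K,",
      length(x$functional_residues), "functional,",
      length(x$ptm_residues), "PTM residues\n")
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' One set per line: `term<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path GMT file.
#' @return named list of character vectors of member accessions.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(short, collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate GMT term names")
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named descriptions; defaults to the term name.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else nm
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read subcellular annotation
#'
#' Two-column tab-delimited file `accession<TAB>compartment`; a protein may
#' appear on several lines or carry a `;`-separated compartment list.
#'
#' @param path TSV file.
#' @return named list: accession -> character vector of compartments.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("annotation file must have two columns")
  acc <- as.character(tab[[1L]])
  comp <- strsplit(as.character(tab[[2L]]), ";", fixed = TRUE)
  comp <- lapply(comp, trimws)
  split_comp <- split(comp, acc)
  lapply(split_comp, function(x) unique(unlist(x)))
}

#' Write subcellular annotation
#' @param ann named list accession -> compartments.
#' @param path output path.
#' @export
write_annotation <- function(ann, path) {
  df <- data.frame(protein = names(ann),
                   compartment = vapply(ann, paste, "", collapse = ";"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the intensity matrix from a site record table
#' @param sites site records from [read_site_table()] or the generator.
#' @param design a [sample_design()].
#' @return numeric matrix sites x samples, rownames = site ids.
#' @export
site_intensity_matrix <- function(sites, design) {
  m <- as.matrix(sites[, design$sample, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- rownames(sites)
  m
}
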