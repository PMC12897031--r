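SITE_DENSITY_BINS <- c("1", "2", "3", "4", "5", ">5")
COMPARTMENTS <- c("nucleus", "cytoplasm", "mitochondria", "other")

#' Sites-per-protein density summary
#'
#' Counts distinct modified positions per protein and bins proteins by site
#' count into `{1, 2, 3, 4, 5, >5}`. Duplicate (protein, position) pairs are
#' deduplicated with a warning.
#'
#' @param sites data.frame with columns `protein` and `position`.
#' @return data.frame of class `site_density_summary`: bin, count,
#'   percentage (2 decimals; sums to 100 up to rounding).
#' @export
site_density <- function(sites) {
  if (nrow(sites) == 0L) {
    out <- data.frame(bin = SITE_DENSITY_BINS, count = 0L, percentage = 0)
    class(out) <- c("site_density_summary", "data.frame")
    return(out)
  }
  key <- paste(sites$protein, sites$position)
  if (anyDuplicated(key)) {
    warning("duplicate (protein, position) pairs deduplicated")
    sites <- sites[!duplicated(key), , drop = FALSE]
  }
  per_prot <- table(sites$protein)
  bin <- ifelse(per_prot > 5L, ">5", as.character(per_prot))
  counts <- table(factor(bin, levels = SITE_DENSITY_BINS))
  out <- data.frame(bin = SITE_DENSITY_BINS, count = as.integer(counts),
                    percentage = round(100 * as.integer(counts) /
                                         length(per_prot), 2))
  class(out) <- c("site_density_summary", "data.frame")
  out
}

#' Assign a protein to a single subcellular compartment
#'
#' Proteins annotated to several compartments are resolved by a fixed
#' priority (most specific organelle first); unannotated proteins map to
#' `other`.
#'
#' @param protein accession.
#' @param annotation named list accession -> character vector of
#'   compartments (see [read_annotation()]).
#' @param priority resolution order.
#' @return one of `nucleus`, `cytoplasm`, `mitochondria`, `other`.
#' @export
assign_compartment <- function(protein, annotation,
                               priority = c("mitochondria", "nucleus",
                                            "cytoplasm", "other")) {
  ann <- annotation[[protein]]
  if (is.null(ann) || length(ann) == 0L) return("other")
  hit <- priority[priority %in% ann]
  if (length(hit) == 0L) "other" else hit[[1L]]
}

#' Compartment breakdown of a site set
#'
#' Maps each site's parent protein to a compartment and tabulates counts and
#' percentages. `scope` labels the set summarized (all quantified sites, or
#' the up-/down-regulated subsets).
#'
#' @param sites data.frame with a `protein` column (one row per site).
#' @param annotation named list accession -> compartments.
#' @param scope one of `"all"`, `"up"`, `"down"`.
#' @param priority passed to [assign_compartment()].
#' @return data.frame of class `compartment_summary`: compartment, count,
#'   percentage (2 decimals), with attribute `scope`.
#' @export
summarize_compartments <- function(sites, annotation, scope = "all",
                                   priority = c("mitochondria", "nucleus",
                                                "cytoplasm", "other")) {
  stopifnot(scope %in% c("all", "up", "down"))
  if (nrow(sites) == 0L) {
    warning("empty site set for scope '", scope, "'")
    out <- data.frame(compartment = COMPARTMENTS, count = 0L, percentage = 0)
  } else {
    comp <- vapply(sites$protein, assign_compartment, "",
                   annotation = annotation, priority = priority)
    counts <- table(factor(comp, levels = COMPARTMENTS))
    out <- data.frame(compartment = COMPARTMENTS,
                      count = as.integer(counts),
                      percentage = round(100 * as.integer(counts) /
                                           nrow(sites), 2))
  }
  attr(out, "scope") <- scope
  class(out) <- c("compartment_summary", "data.frame")
  out
}
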