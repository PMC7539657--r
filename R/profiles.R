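## Presence/absence matrix assembly and the distance feeding Ward clustering.

#' Build a PresenceMatrix from presence calls
#'
#' Assembles the stacked call table produced by [callFamilies()] into a
#' [PresenceMatrix-class] with deterministic row (family) and column (species)
#' order.  Pairs without a call become 0 with empty provenance.  Duplicate
#' calls for the same (species, family) pair are an error when they conflict;
#' identical duplicates are collapsed.
#'
#' @param calls data.frame with columns \code{species_id, family_id, present,
#'   supporting_proteins} (and optionally \code{evidence}).
#' @param speciesOrder character vector fixing column order; defaults to the
#'   sorted species in \code{calls}.
#' @param familyOrder character vector fixing row order; defaults to the
#'   sorted families in \code{calls}.
#' @param rules optional named list of [GeneFamilyRule-class]; when given,
#'   family category/pathway/mode are attached as \code{rowData} and
#'   \code{familyOrder} defaults to rule order.
#' @param manifest optional species manifest ([readSpeciesManifest()])
#'   attached as \code{colData}; \code{speciesOrder} defaults to its order.
#' @return A validated [PresenceMatrix-class].
#' @export
buildPresenceMatrix <- function(calls, speciesOrder = NULL, familyOrder = NULL,
                                rules = NULL, manifest = NULL) {
  if (is.null(speciesOrder))
    speciesOrder <- if (!is.null(manifest)) rownames(manifest)
      else sort(unique(calls$species_id))
  if (is.null(familyOrder))
    familyOrder <- if (!is.null(rules)) names(rules)
      else sort(unique(calls$family_id))
  if (nrow(calls)) {
    unknownSp <- setdiff(calls$species_id, speciesOrder)
    if (length(unknownSp))
      stop("calls reference species outside the species order: ",
           paste(unknownSp, collapse = ", "))
    unknownFam <- setdiff(calls$family_id, familyOrder)
    if (length(unknownFam))
      stop("calls reference families outside the family order: ",
           paste(unknownFam, collapse = ", "))
    key <- paste(calls$species_id, calls$family_id, sep = "\r")
    if (anyDuplicated(key)) {
      for (k in unique(key[duplicated(key)])) {
        rows <- calls[key == k, c("present", "supporting_proteins")]
        if (nrow(unique(rows)) > 1L)
          stop("conflicting duplicate calls for ", sub("\r", "/", k))
      }
      calls <- calls[!duplicated(key), , drop = FALSE]
    }
  }
  p <- matrix(0L, nrow = length(familyOrder), ncol = length(speciesOrder),
              dimnames = list(familyOrder, speciesOrder))
  v <- matrix("", nrow = length(familyOrder), ncol = length(speciesOrder),
              dimnames = list(familyOrder, speciesOrder))
  if (nrow(calls)) {
    idx <- cbind(match(calls$family_id, familyOrder),
                 match(calls$species_id, speciesOrder))
    p[idx] <- as.integer(calls$present)
    v[idx] <- ifelse(calls$present == 1L, calls$supporting_proteins, "")
  }
  rd <- S4Vectors::DataFrame(row.names = familyOrder)
  if (!is.null(rules)) {
    rs <- rules[familyOrder]
    rd$category <- vapply(rs, function(r) r@category, character(1L))
    rd$pathway_group <- vapply(rs, function(r) r@pathwayGroup, character(1L))
    rd$detection_mode <- vapply(rs, function(r) r@detectionMode, character(1L))
  }
  cd <- if (!is.null(manifest)) manifest[speciesOrder, , drop = FALSE]
    else S4Vectors::DataFrame(row.names = speciesOrder)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(presence = p, provenance = v),
    rowData = rd, colData = cd)
  new("PresenceMatrix", se)
}

#' Per-species gene counts for one family category
#'
#' Column sums of the presence matrix restricted to one category's families
#' (e.g. the number of apoptosis-associated gene families present in each
#' species).
#'
#' @param x a [PresenceMatrix-class] with a \code{category} column in
#'   \code{rowData}.
#' @param category one of [familyCategories()].
#' @param ... unused.
#' @return Named integer vector, species id -> count.
#' @export
setMethod("categoryCounts", "PresenceMatrix", function(x, category, ...) {
  cats <- SummarizedExperiment::rowData(x)$category
  if (is.null(cats)) stop("matrix carries no family category annotation")
  if (!category %in% cats)
    stop(sprintf("unknown or empty category '%s' (available: %s)", category,
                 paste(unique(cats), collapse = ", ")))
  sel <- presence(x)[cats == category, , drop = FALSE]
  counts <- as.integer(colSums(sel))
  names(counts) <- speciesIds(x)
  counts
})

#' Euclidean distance between species' binary profiles
#'
#' Distance between two species is the Euclidean distance between their 0/1
#' family profiles, i.e. the square root of the number of differing cells —
#' the conventional metric fed to Ward variance-minimisation linkage.
#'
#' @param x a [PresenceMatrix-class], or a binary matrix with observations in
#'   rows.
#' @return A [stats::dist] object over species.
#' @export
binaryDistance <- function(x) {
  m <- if (is(x, "PresenceMatrix")) t(presence(x)) else as.matrix(x)
  if (nrow(m) < 2L) stop("need at least 2 species to compute distances")
  if (!all(m %in% c(0, 1))) stop("profiles must be binary (0/1)")
  stats::dist(m, method = "euclidean")
}
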