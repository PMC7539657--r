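## Largest-ortholog-group reduction: a family's homolog-based presence is
## reduced to presence of at least one member of the largest ortholog group
## containing any retrieved protein of that family.  Group size is the total
## protein member count (not species count); ties break to the
## lexicographically smallest group id.  Proteins assigned to no group are
## ignored (orthology pipelines leave singletons unassigned).

#' Select the largest ortholog group for one family
#'
#' Candidate groups are those containing at least one retrieved (species,
#' protein) pair for the family; among them the group with the most members
#' (proteins) is selected, ties broken by lexicographically smallest group id.
#' If no retrieved protein belongs to any group the family is explicitly
#' \emph{unassigned} — a distinct outcome from absence.
#'
#' @param groups ortholog-group data.frame (\code{group_id, species_id,
#'   protein_id}, see [readOrthologGroups()]).
#' @param retrieved data.frame with columns \code{species_id, protein_id}:
#'   the proteins retrieved for the family; must be non-empty.
#' @param familyId family identifier recorded in the result.
#' @return A [FamilyGroupSelection-class].
#' @export
selectLargestGroup <- function(groups, retrieved, familyId = "") {
  stopifnot(nrow(retrieved) >= 1L)
  key <- function(df) paste(df$species_id, df$protein_id, sep = "\r")
  hitGroups <- unique(groups$group_id[key(groups) %in% key(retrieved)])
  if (!length(hitGroups)) {
    return(new("FamilyGroupSelection", familyId = familyId,
               selectedGroupId = NA_character_, groupSize = 0L,
               candidates = data.frame(group_id = character(),
                                       size = integer()),
               status = "unassigned"))
  }
  sizes <- table(groups$group_id)[hitGroups]
  cand <- data.frame(group_id = hitGroups, size = as.integer(sizes),
                     stringsAsFactors = FALSE)
  cand <- cand[order(-cand$size, cand$group_id), , drop = FALSE]
  rownames(cand) <- NULL
  new("FamilyGroupSelection", familyId = familyId,
      selectedGroupId = cand$group_id[1L], groupSize = cand$size[1L],
      candidates = cand, status = "selected")
}

#' Ortholog-based presence from group selections
#'
#' A species is called present (1) iff it contributes at least one member to
#' \emph{any} selected group among the selections passed in — for
#' multi-subfamily categories (e.g. a nuclease family with several seed
#' subfamilies) presence of at least one ortholog suffices.
#'
#' @param selections a [FamilyGroupSelection-class] or list of them (the
#'   subfamily selections of one family category).
#' @param groups ortholog-group data.frame.
#' @param speciesIds character vector of species to score.
#' @return Named integer vector (0/1) over \code{speciesIds}, with attribute
#'   \code{"members"}: named list of supporting protein ids per species.
#' @export
orthologPresence <- function(selections, groups, speciesIds) {
  if (is(selections, "FamilyGroupSelection")) selections <- list(selections)
  chosen <- vapply(selections, function(s) s@selectedGroupId, character(1L))
  chosen <- chosen[!is.na(chosen)]
  sub <- groups[groups$group_id %in% chosen, , drop = FALSE]
  members <- split(sub$protein_id, factor(sub$species_id, levels = speciesIds))
  out <- as.integer(lengths(members) > 0L)
  names(out) <- speciesIds
  attr(out, "members") <- lapply(members, function(p) sort(unique(p)))
  out
}

#' Reduce a homolog-based presence matrix to ortholog-based calls
#'
#' For each family, the retrieved proteins are taken from the matrix
#' provenance, the largest containing ortholog group is selected and presence
#' is re-called from group membership.  When the groups are built from the
#' retrieved proteins themselves, the reduction can only remove presence,
#' never create it.  Families with no presence at all, or whose retrieved
#' proteins fall in no group, yield an all-zero row and are flagged in
#' \code{rowData(..)$ortholog_status}.
#'
#' @param pm a [PresenceMatrix-class] (homolog-based).
#' @param groups ortholog-group data.frame.
#' @return List with \code{matrix}: the ortholog-based
#'   [PresenceMatrix-class], and \code{selections}: named list of
#'   [FamilyGroupSelection-class] per family (NULL for families with no
#'   retrieved proteins).
#' @export
reduceToOrthologs <- function(pm, groups) {
  stopifnot(is(pm, "PresenceMatrix"))
  fams <- familyIds(pm)
  sps <- speciesIds(pm)
  prov <- provenance(pm)
  newP <- matrix(0L, nrow = length(fams), ncol = length(sps),
                 dimnames = dimnames(presence(pm)))
  newV <- matrix("", nrow = length(fams), ncol = length(sps),
                 dimnames = dimnames(prov))
  selections <- setNames(vector("list", length(fams)), fams)
  status <- setNames(rep("no_retrieval", length(fams)), fams)
  for (i in seq_along(fams)) {
    cells <- which(nzchar(prov[i, ]))
    if (!length(cells)) next
    retrieved <- do.call(rbind, lapply(cells, function(j) {
      data.frame(species_id = sps[j],
                 protein_id = strsplit(prov[i, j], ",", fixed = TRUE)[[1L]],
                 stringsAsFactors = FALSE)
    }))
    sel <- selectLargestGroup(groups, retrieved, familyId = fams[i])
    selections[[i]] <- sel
    status[i] <- sel@status
    if (sel@status == "unassigned") next
    pres <- orthologPresence(sel, groups, sps)
    newP[i, ] <- pres
    mem <- attr(pres, "members")
    newV[i, ] <- vapply(sps, function(sp)
      paste(mem[[sp]] %||% character(), collapse = ","), character(1L))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(presence = newP, provenance = newV),
    rowData = SummarizedExperiment::rowData(pm),
    colData = SummarizedExperiment::colData(pm))
  SummarizedExperiment::rowData(se)$ortholog_status <- unname(status)
  list(matrix = new("PresenceMatrix", se), selections = selections)
}
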