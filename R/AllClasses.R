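#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

## Controlled vocabularies -----------------------------------------------------

#' Controlled vocabularies for species metadata and family rules
#'
#' Enumerations used throughout the package: eukaryotic superphyla,
#' mitochondrial phenotype classes (fully aerobic mitochondria, anaerobic
#' mitochondria, hydrogen-producing mitochondria, hydrogenosomes, mitosomes,
#' and the fully amitochondriate state), lifestyle classes (P parasitic,
#' S (ecto)symbiotic, F free-living, M transiently multicellular), gene-family
#' categories and detection modes.
#'
#' @return A character vector of allowed labels.
#' @examples
#' mitoClasses()
#' lifestyleClasses()
#' @export
superphyla <- function() c("AMO", "SAR", "ARC", "EXC", "HAP", "CRYP")

#' @rdname superphyla
#' @export
mitoClasses <- function() {
  c("aerobic", "anaerobic", "hydrogen_producing",
    "hydrogenosome", "mitosome", "amitochondriate")
}

#' @rdname superphyla
#' @export
lifestyleClasses <- function() c("P", "S", "F", "M")

#' @rdname superphyla
#' @export
familyCategories <- function() c("apoptosis", "autophagy", "necrosis")

#' @rdname superphyla
#' @export
detectionModes <- function() c("homology_only", "domain_only", "combined")

## GeneFamilyRule --------------------------------------------------------------

#' GeneFamilyRule: one RCD gene-family definition
#'
#' A gene family is detected by iterative homology search
#' (\code{homology_only}), by a boolean Pfam domain-architecture formula
#' (\code{domain_only}), or by the union of both kinds of evidence
#' (\code{combined}).  The domain expression is stored as a disjunction of
#' conjunctions: a list of character vectors, each vector a set of Pfam
#' accessions that must co-occur on the same protein.
#'
#' @slot familyId short unique family token, e.g. \code{"TSN"}.
#' @slot category one of \code{familyCategories()}.
#' @slot pathwayGroup free-text pathway annotation (may be \code{""}).
#' @slot detectionMode one of \code{detectionModes()}.
#' @slot domainExpr list of character vectors (disjunction of conjunctions);
#'   empty list if and only if \code{detectionMode == "homology_only"}.
#' @slot baitSetId identifier of the bait (seed) sequence set used for
#'   homology search, or \code{""} for domain-only families.
#'
#' @seealso [parseRulesConfig()], [parseRuleExpr()], [callFamily()]
#' @export
setClass("GeneFamilyRule",
  representation(
    familyId = "character",
    category = "character",
    pathwayGroup = "character",
    detectionMode = "character",
    domainExpr = "list",
    baitSetId = "character"
  ),
  prototype(pathwayGroup = "", domainExpr = list(), baitSetId = "")
)

setValidity("GeneFamilyRule", function(object) {
  msg <- character()
  if (length(object@familyId) != 1L || !nzchar(object@familyId))
    msg <- c(msg, "familyId must be a single non-empty string")
  if (!object@category %in% familyCategories())
    msg <- c(msg, sprintf("unknown category '%s'", object@category))
  if (!object@detectionMode %in% detectionModes())
    msg <- c(msg, sprintf("unknown detection mode '%s'", object@detectionMode))
  empty <- length(object@domainExpr) == 0L
  if (empty != (object@detectionMode == "homology_only"))
    msg <- c(msg, "domainExpr must be empty iff detectionMode is 'homology_only'")
  accs <- unlist(object@domainExpr, use.names = FALSE)
  if (length(object@domainExpr) && any(lengths(object@domainExpr) == 0L))
    msg <- c(msg, "domainExpr must not contain empty conjunctions")
  if (length(accs) && !all(grepl("^PF[0-9]{5}$", accs)))
    msg <- c(msg, "all accessions in domainExpr must be normalized Pfam tokens (PFxxxxx)")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneFamilyRule
#'
#' @param familyId,category,pathwayGroup,detectionMode,baitSetId see the
#'   corresponding slots of [GeneFamilyRule-class].
#' @param domainExpr either a list of character vectors (disjunction of
#'   conjunctions) or a single formula string parsed with [parseRuleExpr()].
#' @return A validated \code{GeneFamilyRule}.
#' @examples
#' GeneFamilyRule("TSN", "apoptosis", detectionMode = "combined",
#'                domainExpr = "PF00565 + PF00567", baitSetId = "TSN")
#' @export
GeneFamilyRule <- function(familyId, category, pathwayGroup = "",
                           detectionMode = "combined", domainExpr = list(),
                           baitSetId = "") {
  if (is.character(domainExpr)) {
    domainExpr <- if (length(domainExpr) == 1L && nzchar(trimws(domainExpr)))
      parseRuleExpr(domainExpr) else list()
  }
  new("GeneFamilyRule", familyId = familyId, category = category,
      pathwayGroup = pathwayGroup, detectionMode = detectionMode,
      domainExpr = domainExpr, baitSetId = baitSetId)
}

## ScreenParams ----------------------------------------------------------------

#' ScreenParams: homology-screen cutoff thresholds
#'
#' Defaults follow the standard protist RCD-mining cutoffs: E-value below
#' 1e-5, at least 30 percent identity and at least 80 percent query coverage.
#' The E-value threshold is strict (\code{<}), identity and coverage are
#' inclusive (\code{>=}).
#'
#' @slot eMax maximum E-value (exclusive), default \code{1e-5}.
#' @slot idMin minimum percent identity (inclusive), default \code{30}.
#' @slot covMin minimum query-coverage fraction (inclusive), default
#'   \code{0.80}; coverage is the aligned query span divided by query length.
#' @slot maxRounds maximum number of iterative-search rounds, default 3.
#' @export
setClass("ScreenParams",
  representation(eMax = "numeric", idMin = "numeric",
                 covMin = "numeric", maxRounds = "integer"),
  prototype(eMax = 1e-5, idMin = 30, covMin = 0.80, maxRounds = 3L)
)

setValidity("ScreenParams", function(object) {
  msg <- character()
  if (!(object@eMax > 0)) msg <- c(msg, "eMax must be > 0")
  if (object@idMin < 0 || object@idMin > 100)
    msg <- c(msg, "idMin must lie in [0, 100]")
  if (!(object@covMin > 0 && object@covMin <= 1))
    msg <- c(msg, "covMin must lie in (0, 1]")
  if (object@maxRounds < 1L) msg <- c(msg, "maxRounds must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname ScreenParams-class
#' @param eMax,idMin,covMin,maxRounds see slots.
#' @return A validated \code{ScreenParams} object.
#' @examples
#' ScreenParams()
#' ScreenParams(eMax = 1e-10, idMin = 40)
#' @export
ScreenParams <- function(eMax = 1e-5, idMin = 30, covMin = 0.80, maxRounds = 3L) {
  new("ScreenParams", eMax = eMax, idMin = idMin, covMin = covMin,
      maxRounds = as.integer(maxRounds))
}

## PresenceMatrix --------------------------------------------------------------

#' PresenceMatrix: binary phylogenetic profiles with provenance
#'
#' A \linkS4class{SummarizedExperiment} with gene families as rows and species
#' as columns.  Two assays: \code{"presence"} (0/1 integer) and
#' \code{"provenance"} (comma-joined supporting protein identifiers; empty
#' string iff the cell is 0).  \code{rowData} carries family category and
#' detection metadata; \code{colData} carries the species manifest.
#'
#' @seealso [buildPresenceMatrix()], [categoryCounts()], [binaryDistance()]
#' @export
setClass("PresenceMatrix", contains = "SummarizedExperiment")

setValidity("PresenceMatrix", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("presence", "provenance") %in% an))
    return("assays 'presence' and 'provenance' are required")
  p <- SummarizedExperiment::assay(object, "presence")
  v <- SummarizedExperiment::assay(object, "provenance")
  if (!all(p %in% c(0L, 1L))) msg <- c(msg, "presence cells must be 0 or 1")
  if (!identical(dim(p), dim(v)))
    msg <- c(msg, "presence and provenance assays must have identical shape")
  else if (!all((p == 1L) == nzchar(v)))
    msg <- c(msg, "cell = 1 iff provenance set non-empty is violated")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "family (row) names must be unique and non-NULL")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "species (column) names must be unique and non-NULL")
  if (length(msg)) msg else TRUE
})

## LinkageTree -----------------------------------------------------------------

#' LinkageTree: agglomerative merge sequence from Ward clustering
#'
#' Stores the n-1 merges of an agglomerative clustering in
#' \code{\link[stats]{hclust}} merge convention (negative entries index
#' leaves, positive entries earlier merges), the merge heights, the size of
#' each newly formed cluster, and a leaf display order.
#'
#' @slot merges integer matrix (n-1 x 2), hclust merge convention.
#' @slot heights numeric vector of merge heights (non-decreasing under Ward
#'   on a metric input).
#' @slot sizes integer vector, member count of each newly formed cluster.
#' @slot order integer permutation of 1..n for dendrogram display.
#' @slot labels leaf labels (species identifiers).
#' @seealso [wardLinkage()], [cutLinkage()], [as.hclust.LinkageTree()]
#' @export
setClass("LinkageTree",
  representation(merges = "matrix", heights = "numeric",
                 sizes = "integer", order = "integer", labels = "character")
)

setValidity("LinkageTree", function(object) {
  n <- length(object@labels)
  msg <- character()
  if (nrow(object@merges) != n - 1L || ncol(object@merges) != 2L)
    msg <- c(msg, "merges must be an (n-1) x 2 matrix")
  if (length(object@heights) != n - 1L)
    msg <- c(msg, "heights must have n-1 entries")
  if (length(object@sizes) != n - 1L)
    msg <- c(msg, "sizes must have n-1 entries")
  if (!identical(sort(object@order), seq_len(n)))
    msg <- c(msg, "order must be a permutation of 1..n")
  if (length(msg)) msg else TRUE
})

## GroupComparison -------------------------------------------------------------

#' GroupComparison: two-group Mann-Whitney U comparison
#'
#' Holds the per-group sample sizes, means and sample standard deviations
#' (denominator n-1), the Mann-Whitney U statistic of the first group, and the
#' two-tailed p-value, together with the method used (\code{"exact"} by null
#' enumeration, or \code{"normal_approx"} with tie correction and continuity
#' correction).
#'
#' @slot labelA,labelB group labels.
#' @slot nA,nB sample sizes.
#' @slot meanA,meanB,sdA,sdB group means and sample SDs; for a single-value
#'   group the SD is reported as 0 and flagged.
#' @slot U Mann-Whitney U statistic for group A (0 <= U <= nA*nB).
#' @slot pTwoTailed two-tailed p-value in (0, 1].
#' @slot method \code{"exact"} or \code{"normal_approx"}.
#' @slot flags character vector of data-quality flags (e.g. \code{"sd_undefined_a"}).
#' @seealso [mannWhitneyU()], [groupReport()]
#' @export
setClass("GroupComparison",
  representation(
    labelA = "character", labelB = "character",
    nA = "integer", nB = "integer",
    meanA = "numeric", meanB = "numeric",
    sdA = "numeric", sdB = "numeric",
    U = "numeric", pTwoTailed = "numeric",
    method = "character", flags = "character"
  ),
  prototype(flags = character())
)

setValidity("GroupComparison", function(object) {
  msg <- character()
  if (object@U < 0 || object@U > object@nA * object@nB)
    msg <- c(msg, "U must lie in [0, nA*nB]")
  if (!(object@pTwoTailed > 0 && object@pTwoTailed <= 1))
    msg <- c(msg, "p must lie in (0, 1]")
  if (!object@method %in% c("exact", "normal_approx"))
    msg <- c(msg, "method must be 'exact' or 'normal_approx'")
  if (length(msg)) msg else TRUE
})

## FamilyGroupSelection ---------------------------------------------------------

#' FamilyGroupSelection: largest-ortholog-group choice for one family
#'
#' Records which ortholog group was selected for a gene family (the largest,
#' by total member count, among groups containing at least one retrieved
#' protein; ties broken by lexicographically smallest group id), together with
#' the full candidate list.  A family whose retrieved proteins fall in no
#' group is \code{"unassigned"} — explicitly distinct from absence.
#'
#' @slot familyId gene family identifier.
#' @slot selectedGroupId chosen group id, or \code{NA_character_} if unassigned.
#' @slot groupSize member count of the selected group (0 if unassigned).
#' @slot candidates data.frame with columns \code{group_id}, \code{size}.
#' @slot status \code{"selected"} or \code{"unassigned"}.
#' @seealso [selectLargestGroup()], [orthologPresence()]
#' @export
setClass("FamilyGroupSelection",
  representation(familyId = "character", selectedGroupId = "character",
                 groupSize = "integer", candidates = "data.frame",
                 status = "character")
)

setValidity("FamilyGroupSelection", function(object) {
  if (object@status == "selected") {
    if (is.na(object@selectedGroupId))
      return("selected status requires a group id")
    if (nrow(object@candidates) &&
        object@groupSize < max(object@candidates$size))
      return("selected group must have maximal size among candidates")
  }
  TRUE
})

## SimConfig -------------------------------------------------------------------

#' SimConfig: configuration of the synthetic-data generator
#'
#' Defines planted group structure for the simulator: species counts per
#' group, per-(group, category) presence probabilities, a symmetric flip-noise
#' rate applied after the Bernoulli draw, the number of decoy proteins per
#' proteome, and a mandatory seed.
#'
#' @slot groups named integer vector: group label -> number of species.
#' @slot groupVar manifest column the group labels populate
#'   (\code{"lifestyle"} or \code{"mito_class"}).
#' @slot presenceProb named list: group label -> named numeric vector of
#'   per-category presence probabilities in [0, 1].
#' @slot flipNoise probability of flipping each truth cell, in [0, 1].
#' @slot decoysPerProteome number of decoy proteins fabricated per species.
#' @slot seed integer RNG seed (mandatory).
#' @seealso [simConfig()], [simulateTruth()], [emitEvidence()]
#' @export
setClass("SimConfig",
  representation(groups = "integer", groupVar = "character",
                 presenceProb = "list", flipNoise = "numeric",
                 decoysPerProteome = "integer", seed = "integer")
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (is.null(names(object@groups)) || any(!nzchar(names(object@groups))))
    msg <- c(msg, "groups must be a named integer vector")
  if (any(object@groups < 1L)) msg <- c(msg, "each group needs >= 1 species")
  if (!object@groupVar %in% c("lifestyle", "mito_class"))
    msg <- c(msg, "groupVar must be 'lifestyle' or 'mito_class'")
  probs <- unlist(object@presenceProb, use.names = FALSE)
  if (any(probs < 0 | probs > 1)) msg <- c(msg, "presence probabilities must lie in [0, 1]")
  if (!all(names(object@groups) %in% names(object@presenceProb)))
    msg <- c(msg, "every group needs a presenceProb entry")
  if (object@flipNoise < 0 || object@flipNoise > 1)
    msg <- c(msg, "flipNoise must lie in [0, 1]")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed is mandatory")
  if (length(msg)) msg else TRUE
})
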