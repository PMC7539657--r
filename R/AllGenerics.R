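#' @rdname PresenceMatrix-utils
#' @export
setGeneric("presence", function(x) standardGeneric("presence"))

#' @rdname PresenceMatrix-utils
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname PresenceMatrix-utils
#' @export
setGeneric("speciesIds", function(x) standardGeneric("speciesIds"))

#' @rdname PresenceMatrix-utils
#' @export
setGeneric("familyIds", function(x) standardGeneric("familyIds"))

#' @rdname categoryCounts
#' @export
setGeneric("categoryCounts", function(x, category, ...)
  standardGeneric("categoryCounts"))

#' Accessors for PresenceMatrix objects
#'
#' \code{presence()} returns the binary family-by-species matrix;
#' \code{provenance()} the matching matrix of comma-joined supporting protein
#' ids; \code{speciesIds()} and \code{familyIds()} the column and row names.
#'
#' @param x a [PresenceMatrix-class].
#' @return A matrix or character vector, see details.
#' @name PresenceMatrix-utils
#' @aliases presence provenance speciesIds familyIds
NULL

#' @rdname PresenceMatrix-utils
#' @export
setMethod("presence", "PresenceMatrix", function(x)
  SummarizedExperiment::assay(x, "presence"))

#' @rdname PresenceMatrix-utils
#' @export
setMethod("provenance", "PresenceMatrix", function(x)
  SummarizedExperiment::assay(x, "provenance"))

#' @rdname PresenceMatrix-utils
#' @export
setMethod("speciesIds", "PresenceMatrix", function(x) colnames(x))

#' @rdname PresenceMatrix-utils
#' @export
setMethod("familyIds", "PresenceMatrix", function(x) rownames(x))

## show methods ----------------------------------------------------------------

setMethod("show", "GeneFamilyRule", function(object) {
  expr <- deparseRuleExpr(object@domainExpr)
  cat(sprintf("GeneFamilyRule '%s' [%s/%s]\n  mode: %s\n  expr: %s\n",
              object@familyId, object@category,
              if (nzchar(object@pathwayGroup)) object@pathwayGroup else "-",
              object@detectionMode,
              if (nzchar(expr)) expr else "<homology only>"))
})

setMethod("show", "ScreenParams", function(object) {
  cat(sprintf(
    "ScreenParams: E-value < %g, identity >= %g%%, query coverage >= %g, max %d rounds\n",
    object@eMax, object@idMin, object@covMin, object@maxRounds))
})

setMethod("show", "LinkageTree", function(object) {
  n <- length(object@labels)
  cat(sprintf("LinkageTree: %d leaves, %d merges, heights [%.3g, %.3g]\n",
              n, n - 1L, min(object@heights), max(object@heights)))
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf(
    "GroupComparison: %s (n=%d, %.2f +/- %.2f) vs %s (n=%d, %.2f +/- %.2f)\n  U = %g, two-tailed p = %.4g (%s)\n",
    object@labelA, object@nA, object@meanA, object@sdA,
    object@labelB, object@nB, object@meanB, object@sdB,
    object@U, object@pTwoTailed, object@method))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "FamilyGroupSelection", function(object) {
  cat(sprintf("FamilyGroupSelection '%s': %s\n", object@familyId,
              if (object@status == "selected")
                sprintf("group %s (%d members, %d candidate groups)",
                        object@selectedGroupId, object@groupSize,
                        nrow(object@candidates))
              else "unassigned (no candidate ortholog group)"))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d species in %d %s groups, flip noise %.3g, %d decoys/proteome, seed %d\n",
              sum(object@groups), length(object@groups), object@groupVar,
              object@flipNoise, object@decoysPerProteome, object@seed))
})
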