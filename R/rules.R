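## Boolean domain-architecture formulas: "+" is conjunction (domains that must
## co-occur on the same protein), "/" is disjunction, and "+" binds tighter
## than "/".  A formula therefore parses to a disjunction of conjunctions,
## represented as a list of character vectors of normalized Pfam accessions.

#' Parse a domain-architecture formula
#'
#' Parses formulas in the field's compact notation, e.g.
#' \code{"PF00565 + PF00567"} (both domains on the same protein) or
#' \code{"PF13365 + PF00595 / PF12812"} (either the pair, or PF12812 alone):
#' \code{"+"} binds tighter than \code{"/"}.  Accessions are normalized with
#' [normalizePfam()].
#'
#' @param text formula string.
#' @return List of character vectors (disjunction of conjunctions); each
#'   conjunction's accessions sorted, duplicates removed.
#' @examples
#' parseRuleExpr("PF02265 / PF01223 / PF03265")
#' parseRuleExpr("PF13365 + PF00595 / PF12812")
#' @export
parseRuleExpr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) stop("empty rule expression")
  if (grepl("^\\s*[+/]", text) || grepl("[+/]\\s*$", text))
    stop("dangling operator at the ",
         if (grepl("[+/]\\s*$", text)) "end" else "start",
         " of rule expression: ", text)
  alts <- strsplit(text, "/", fixed = TRUE)[[1L]]
  if (any(!nzchar(trimws(alts))))
    stop("dangling '/' operator in rule expression: ", text)
  out <- lapply(seq_along(alts), function(i) {
    toks <- trimws(strsplit(alts[[i]], "+", fixed = TRUE)[[1L]])
    if (any(!nzchar(toks)))
      stop(sprintf("dangling '+' operator in alternative %d of: %s", i, text))
    bad <- !grepl("^PF[0-9]{5}(\\.[0-9]+)?$", toks)
    if (any(bad))
      stop(sprintf("non-accession token '%s' at alternative %d of: %s",
                   toks[bad][1L], i, text))
    sort(unique(normalizePfam(toks)))
  })
  out
}

#' @rdname parseRuleExpr
#' @param expr a parsed expression (list of character vectors).
#' @return \code{deparseRuleExpr}: the canonical string form, \code{""} for an
#'   empty expression.
#' @export
deparseRuleExpr <- function(expr) {
  if (!length(expr)) return("")
  paste(vapply(expr, paste, character(1L), collapse = " + "), collapse = " / ")
}

#' Evaluate a domain formula against one protein's domain set
#'
#' TRUE iff some alternative's accession set is entirely contained in the
#' protein's accession set (domain co-occurrence on the same protein).
#' Monotone in the domain set: adding accessions never flips TRUE to FALSE.
#'
#' @param expr parsed expression from [parseRuleExpr()].
#' @param domains character vector of Pfam accessions carried by one protein.
#' @return logical scalar.
#' @examples
#' tsn <- parseRuleExpr("PF00565 + PF00567")
#' evaluateProtein(tsn, c("PF00565"))              # FALSE
#' evaluateProtein(tsn, c("PF00565", "PF00567"))   # TRUE
#' @export
evaluateProtein <- function(expr, domains) {
  if (!length(expr)) return(FALSE)
  for (conj in expr) if (all(conj %in% domains)) return(TRUE)
  FALSE
}

## split a species domain table into per-protein accession sets
domainSetsByProtein <- function(domainTable) {
  if (!nrow(domainTable)) return(list())
  split(domainTable$pfam_acc, domainTable$protein_id)
}

#' Call presence of one gene family in one species
#'
#' Applies the family's detection mode: \code{domain_only} scans the species
#' domain table for a protein satisfying the formula; \code{homology_only}
#' requires a non-empty set of kept homologs for the family;
#' \code{combined} is the union (OR) of both evidence channels.  The call
#' records the supporting proteins and which evidence produced them.
#'
#' @param rule a [GeneFamilyRule-class].
#' @param domainTable species domain-scan data.frame (see [readDomainScan()]);
#'   may be empty.  Domain E-values are assumed pre-filtered by the scanner;
#'   an optional ceiling can be applied via \code{domainEMax}.
#' @param homologs character vector of kept homolog protein ids for this
#'   species and family, or \code{NULL} if no homology evidence channel was
#'   run.  For a \code{homology_only} rule \code{NULL} is an error (evidence
#'   unavailable), distinct from an empty vector (evidence ran, nothing kept).
#' @param speciesId species identifier recorded in the call.
#' @param domainEMax optional E-value ceiling re-applied to the domain table
#'   (default \code{Inf}: off).
#' @return A one-row data.frame with columns \code{species_id, family_id,
#'   present, evidence, supporting_proteins} (comma-joined, \code{""} when
#'   absent); evidence is one of \code{"domain"}, \code{"homology"},
#'   \code{"both"}, \code{"none"}.
#' @export
callFamily <- function(rule, domainTable, homologs = NULL, speciesId,
                       domainEMax = Inf) {
  stopifnot(is(rule, "GeneFamilyRule"))
  mode <- rule@detectionMode
  domainSupport <- character()
  if (mode %in% c("domain_only", "combined")) {
    dt <- domainTable
    if (is.finite(domainEMax) && nrow(dt))
      dt <- dt[dt$e_value <= domainEMax, , drop = FALSE]
    sets <- domainSetsByProtein(dt)
    sat <- vapply(sets, function(s) evaluateProtein(rule@domainExpr, s),
                  logical(1L))
    domainSupport <- names(sets)[sat]
  }
  homologSupport <- character()
  if (mode %in% c("homology_only", "combined")) {
    if (mode == "homology_only" && is.null(homologs))
      stop(sprintf(
        "family %s: homology evidence unavailable for species %s (homology_only rule needs a homolog set)",
        rule@familyId, speciesId))
    homologSupport <- unique(as.character(homologs %||% character()))
  }
  support <- sort(unique(c(domainSupport, homologSupport)))
  evidence <- if (!length(support)) "none"
    else if (length(domainSupport) && length(homologSupport)) "both"
    else if (length(domainSupport)) "domain" else "homology"
  data.frame(species_id = speciesId, family_id = rule@familyId,
             present = as.integer(length(support) > 0L),
             evidence = evidence,
             supporting_proteins = paste(support, collapse = ","),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Call every family for every species
#'
#' Convenience driver over [callFamily()]: takes per-species domain tables and
#' per-species, per-family homolog sets and returns the stacked call table.
#'
#' @param rules named list of [GeneFamilyRule-class] objects.
#' @param domainTables named list (by species_id) of domain-scan data.frames.
#' @param homologSets named list (by species_id) of named lists (by family_id)
#'   of kept homolog protein id vectors; missing species/family entries are
#'   treated as empty homolog sets (the homology channel is assumed to have
#'   run for every species passed in).
#' @param speciesIds species to call; defaults to the names of
#'   \code{domainTables}.
#' @param domainEMax see [callFamily()].
#' @return data.frame of calls, one row per (species, family).
#' @export
callFamilies <- function(rules, domainTables, homologSets = list(),
                         speciesIds = names(domainTables), domainEMax = Inf) {
  emptyDomains <- data.frame(protein_id = character(), pfam_acc = character(),
                             env_start = integer(), env_end = integer(),
                             e_value = numeric(), stringsAsFactors = FALSE)
  out <- vector("list", length(speciesIds) * length(rules))
  k <- 0L
  for (sp in speciesIds) {
    dt <- domainTables[[sp]] %||% emptyDomains
    hs <- homologSets[[sp]] %||% list()
    for (rule in rules) {
      k <- k + 1L
      out[[k]] <- callFamily(rule, dt,
                             homologs = hs[[rule@familyId]] %||% character(),
                             speciesId = sp, domainEMax = domainEMax)
    }
  }
  do.call(rbind, out)
}
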