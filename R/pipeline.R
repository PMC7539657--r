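## End-to-end orchestration: screen -> call -> (optional) ortholog reduction
## -> matrix -> cluster -> group statistics, with TSV outputs and a
## machine-readable JSON run report.  The pipeline itself is free of
## randomness: two runs over identical inputs produce byte-identical outputs.

#' Screen, call and assemble a presence matrix from an in-memory bundle
#'
#' The homology channel filters each species' hits with [filterHits()] and
#' assigns kept subjects to families through the bait id convention
#' (\code{bait_<baitSetId>}); the domain channel evaluates every family
#' formula on the species domain table; [callFamilies()] combines the
#' channels per detection mode and [buildPresenceMatrix()] assembles the
#' result.
#'
#' @param bundle evidence bundle (see [emitEvidence()]); must contain
#'   \code{manifest}, \code{hits}, \code{domains}, \code{baitLengths}.
#' @param rules named list of [GeneFamilyRule-class].
#' @param params a [ScreenParams-class].
#' @return List with \code{matrix} (a [PresenceMatrix-class]), \code{calls}
#'   (the call table) and \code{screenStats} (per-species kept/total hits).
#' @export
profileBundle <- function(bundle, rules, params = ScreenParams()) {
  spIds <- rownames(bundle$manifest)
  baitOfFamily <- vapply(rules, function(r)
    if (nzchar(r@baitSetId)) paste0("bait_", r@baitSetId) else NA_character_,
    character(1L))
  homologSets <- list()
  screenStats <- data.frame(species_id = spIds, n_hits = 0L, n_kept = 0L,
                            stringsAsFactors = FALSE)
  for (i in seq_along(spIds)) {
    sp <- spIds[i]
    h <- bundle$hits[[sp]] %||% emptyHits()
    kept <- filterHits(h, bundle$baitLengths, params)
    screenStats$n_hits[i] <- nrow(h)
    screenStats$n_kept[i] <- nrow(kept)
    sets <- list()
    for (fam in names(rules)) {
      b <- baitOfFamily[[fam]]
      if (is.na(b)) next
      sets[[fam]] <- unique(kept$subject_id[kept$query_id == b])
    }
    homologSets[[sp]] <- sets
  }
  calls <- callFamilies(rules, bundle$domains, homologSets, speciesIds = spIds)
  pm <- buildPresenceMatrix(calls, rules = rules, manifest = bundle$manifest)
  list(matrix = pm, calls = calls, screenStats = screenStats)
}

## derive a call-style table (with provenance) back from a matrix
matrixToCalls <- function(pm) {
  p <- presence(pm); v <- provenance(pm)
  data.frame(
    species_id = rep(colnames(p), each = nrow(p)),
    family_id = rep(rownames(p), times = ncol(p)),
    present = as.integer(p),
    supporting_proteins = as.character(v),
    stringsAsFactors = FALSE
  )
}

writePresenceTSV <- function(pm, path) {
  df <- data.frame(family_id = familyIds(pm), presence(pm),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

writeLinkageTSV <- function(tree, path) {
  df <- data.frame(merge_a = tree@merges[, 1L], merge_b = tree@merges[, 2L],
                   height = tree@heights, new_size = tree@sizes)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## cluster one category's species profiles; NULL (with notice) when degenerate
clusterCategory <- function(pm, category, kRange = NULL) {
  cats <- SummarizedExperiment::rowData(pm)$category
  sub <- presence(pm)[cats == category, , drop = FALSE]
  if (ncol(sub) < 3L) return(NULL)
  profiles <- t(sub)
  if (all(stats::dist(profiles) == 0)) return(NULL)
  tree <- wardLinkage(stats::dist(profiles))
  sel <- selectK(tree, profiles, kRange = kRange)
  list(tree = tree, selection = sel)
}

#' Run the full profiling pipeline over an evidence directory
#'
#' Executes screen -> call -> (optional) ortholog reduction -> matrix ->
#' cluster -> group statistics over the directory layout written by
#' [writeEvidenceBundle()] (\code{manifest.tsv}, \code{baits.fasta},
#' \code{hits/<sp>.tsv}, \code{domains/<sp>.tsv}, optionally
#' \code{orthogroups.tsv}).  Homolog-based and ortholog-based matrices are
#' emitted separately.  Any stage failure aborts with the stage name and the
#' offending file.
#'
#' @param evidenceDir input directory.
#' @param rulesPath rule configuration ([parseRulesConfig()] default).
#' @param outDir output directory for TSVs and \code{report.json}.
#' @param params a [ScreenParams-class].
#' @param orthologs logical: run the ortholog reduction if
#'   \code{orthogroups.tsv} exists?  When the file is absent the
#'   ortholog-based outputs are skipped with a notice in the report.
#' @param kRange candidate cluster numbers forwarded to [selectK()].
#' @return The run report (a nested list, also written as
#'   \code{report.json}), invisibly: tool version, parameter echo, per-stage
#'   record counts, per-category group means and comparisons, k_best with the
#'   index table, and md5 checksums of every output file.
#' @export
runAll <- function(evidenceDir, rulesPath = defaultRulesPath(),
                   outDir = file.path(evidenceDir, "out"),
                   params = ScreenParams(), orthologs = TRUE, kRange = NULL) {
  stage <- function(name, file, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed on %s: %s", name, file,
                   conditionMessage(e)), call. = FALSE))
  }
  manifestPath <- file.path(evidenceDir, "manifest.tsv")
  manifest <- stage("manifest", manifestPath, readSpeciesManifest(manifestPath))
  rules <- stage("rules", rulesPath, parseRulesConfig(rulesPath))
  baitsPath <- file.path(evidenceDir, "baits.fasta")
  baitLengths <- if (file.exists(baitsPath))
    stage("baits", baitsPath, readSequenceLengths(baitsPath))
  else stats::setNames(numeric(), character())

  spIds <- rownames(manifest)
  hits <- list(); domains <- list()
  for (sp in spIds) {
    hPath <- file.path(evidenceDir, "hits", paste0(sp, ".tsv"))
    dPath <- file.path(evidenceDir, "domains", paste0(sp, ".tsv"))
    if (!file.exists(dPath))
      stop(sprintf("stage 'read-domains' failed on %s: missing domains file for species %s",
                   dPath, sp), call. = FALSE)
    hits[[sp]] <- if (file.exists(hPath))
      stage("read-hits", hPath, readTabularHits(hPath)) else emptyHits()
    domains[[sp]] <- stage("read-domains", dPath, readDomainScan(dPath))
  }
  bundle <- list(manifest = manifest, hits = hits, domains = domains,
                 baitLengths = baitLengths)
  prof <- stage("screen-call", evidenceDir, profileBundle(bundle, rules, params))
  pmHom <- prof$matrix

  notices <- character()
  orthoPath <- file.path(evidenceDir, "orthogroups.tsv")
  pmOrt <- NULL; selections <- NULL
  if (orthologs && file.exists(orthoPath)) {
    groups <- stage("orthology", orthoPath, readOrthologGroups(orthoPath))
    red <- stage("orthology", orthoPath, reduceToOrthologs(pmHom, groups))
    pmOrt <- red$matrix
    selections <- red$selections
  } else {
    notices <- c(notices,
                 "ortholog groups not provided; ortholog-based outputs skipped")
  }

  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  emit <- function(writer, obj, name) {
    path <- file.path(outDir, name)
    writer(obj, path)
    outputs <<- c(outputs, path)
    path
  }
  emit(writePresenceTSV, pmHom, "presence_homolog.tsv")
  emit(function(obj, path)
    utils::write.table(obj, path, sep = "\t", quote = FALSE,
                       row.names = FALSE),
    prof$calls, "calls_homolog.tsv")
  if (!is.null(pmOrt)) {
    emit(writePresenceTSV, pmOrt, "presence_ortholog.tsv")
    emit(function(obj, path)
      utils::write.table(obj, path, sep = "\t", quote = FALSE,
                         row.names = FALSE),
      matrixToCalls(pmOrt), "calls_ortholog.tsv")
  }

  matrices <- list(homolog = pmHom)
  if (!is.null(pmOrt)) matrices$ortholog <- pmOrt
  cats <- intersect(familyCategories(),
                    unique(SummarizedExperiment::rowData(pmHom)$category))
  clustering <- list(); statsOut <- list(); cmpRows <- list()
  for (mt in names(matrices)) {
    pm <- matrices[[mt]]
    for (category in cats) {
      key <- paste(category, mt, sep = "_")
      counts <- categoryCounts(pm, category)
      cl <- clusterCategory(pm, category, kRange = kRange)
      if (!is.null(cl)) {
        emit(writeLinkageTSV, cl$tree, paste0("linkage_", key, ".tsv"))
        labs <- data.frame(species_id = names(cl$selection$labels),
                           cluster = as.integer(cl$selection$labels))
        emit(function(obj, path)
          utils::write.table(obj, path, sep = "\t", quote = FALSE,
                             row.names = FALSE),
          labs, paste0("clusters_", key, ".tsv"))
        clustering[[key]] <- list(k_best = cl$selection$k_best,
                                  votes = as.list(cl$selection$votes),
                                  index_table = cl$selection$table)
      } else {
        notices <- c(notices, paste0("clustering skipped for ", key,
                                     " (too few species or identical profiles)"))
      }
      reports <- list(
        mito_class = suppressWarnings(
          groupReport(counts, manifest, "mito_class")),
        lifestyle = suppressWarnings(
          groupReport(counts, manifest, "lifestyle"))
      )
      statsOut[[key]] <- lapply(reports, function(r) list(
        groups = r$groups,
        comparisons = lapply(r$comparisons, comparisonToRow)))
      for (grouping in names(reports)) {
        for (nm in names(reports[[grouping]]$comparisons)) {
          row <- comparisonToRow(reports[[grouping]]$comparisons[[nm]])
          row <- cbind(data.frame(category = category, matrix = mt,
                                  grouping = grouping, comparison = nm,
                                  stringsAsFactors = FALSE), row)
          cmpRows[[length(cmpRows) + 1L]] <- row
        }
      }
    }
  }
  if (length(cmpRows))
    emit(function(obj, path)
      utils::write.table(obj, path, sep = "\t", quote = FALSE,
                         row.names = FALSE),
      do.call(rbind, cmpRows), "comparisons.tsv")

  report <- list(
    tool = "rcdProfiler",
    version = as.character(utils::packageVersion("rcdProfiler")),
    params = list(e_max = params@eMax, id_min = params@idMin,
                  cov_min = params@covMin, max_rounds = params@maxRounds),
    stages = list(
      n_species = length(spIds),
      n_families = length(rules),
      screen = prof$screenStats,
      n_calls = nrow(prof$calls),
      ortholog_reduction = !is.null(pmOrt)
    ),
    clustering = clustering,
    statistics = statsOut,
    notices = notices
  )
  reportPath <- file.path(outDir, "report.json")
  checks <- tools::md5sum(outputs)
  report$outputs <- data.frame(file = basename(names(checks)),
                               md5 = unname(checks),
                               stringsAsFactors = FALSE)
  jsonlite::write_json(report, reportPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(report)
}

#' Plot a presence/absence heatmap ordered by the species dendrogram
#'
#' Minimal two-colour heatmap (absence dark, presence copper) with species
#' columns ordered by a Ward dendrogram of the selected category's profiles.
#'
#' @param pm a [PresenceMatrix-class].
#' @param category optional category to restrict the rows to.
#' @return invisibly, the column order used.
#' @export
plotPresence <- function(pm, category = NULL) {
  m <- presence(pm)
  if (!is.null(category)) {
    cats <- SummarizedExperiment::rowData(pm)$category
    m <- m[cats == category, , drop = FALSE]
  }
  ord <- seq_len(ncol(m))
  if (ncol(m) >= 3L && any(stats::dist(t(m)) > 0))
    ord <- wardLinkage(stats::dist(t(m)))@order
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)),
                  t(m[, ord, drop = FALSE]),
                  col = c("grey15", "#B87333"), axes = FALSE,
                  xlab = "species", ylab = "family")
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m)[ord],
                 las = 2, cex.axis = 0.6)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rownames(m),
                 las = 2, cex.axis = 0.6)
  invisible(ord)
}
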