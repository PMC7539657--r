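## Synthetic-data generator: plants a truth presence/absence matrix with
## group structure, then fabricates minimal-sufficient, internally consistent
## evidence (domain tables, homology hits, ortholog groups, FASTA) so that
## running the full pipeline over the emitted bundle recovers the truth
## exactly at zero flip noise.  One protein is fabricated per planted
## presence, plus per-species decoy proteins whose single domains are
## guaranteed (by construction and by rule-engine sweep) to satisfy no rule.

#' Construct a simulation configuration
#'
#' The defaults reproduce the composition of the reference 67-protist study
#' panel: lifestyle groups P = 17, S = 4, F = 31, M = 15; mitochondrial
#' phenotypes 51 aerobic, 2 anaerobic, 2 hydrogen-producing, 6 hydrogenosome,
#' 5 mitosome and 1 amitochondriate, with all diverged phenotypes assigned to
#' parasites (no transiently multicellular taxon carries a diverged
#' mitochondrion).  Default per-category presence probabilities are the
#' reported group mean counts divided by the number of families per category
#' (apoptosis 10, autophagy 12): e.g. parasites 0.38/0.38, free-living
#' 0.66/0.66, transiently multicellular 0.80/0.91, symbionts 0.69/0.74;
#' regulated-necrosis probability is 0 (no homolog was detected in the
#' panel).
#'
#' @param groups named integer vector, group label -> species count.
#' @param groupVar manifest column the groups populate: \code{"lifestyle"}
#'   or \code{"mito_class"}.
#' @param presenceProb named list: group -> named numeric vector over
#'   categories (\code{apoptosis}, \code{autophagy}, \code{necrosis}).
#' @param flipNoise per-cell symmetric flip probability applied after the
#'   Bernoulli draw (default 0).
#' @param decoysPerProteome decoy proteins fabricated per species (default 5).
#' @param seed mandatory integer seed; the generator uses a single seeded RNG
#'   stream per run.
#' @return A validated [SimConfig-class].
#' @export
simConfig <- function(groups = c(P = 17L, S = 4L, F = 31L, M = 15L),
                      groupVar = "lifestyle",
                      presenceProb = list(
                        P = c(apoptosis = 0.38, autophagy = 0.38, necrosis = 0),
                        S = c(apoptosis = 0.69, autophagy = 0.74, necrosis = 0),
                        F = c(apoptosis = 0.66, autophagy = 0.66, necrosis = 0),
                        M = c(apoptosis = 0.80, autophagy = 0.91, necrosis = 0)
                      ),
                      flipNoise = 0, decoysPerProteome = 5L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  new("SimConfig", groups = setNames(as.integer(groups), names(groups)),
      groupVar = groupVar, presenceProb = presenceProb,
      flipNoise = flipNoise, decoysPerProteome = as.integer(decoysPerProteome),
      seed = as.integer(seed))
}

## deterministic mito-class assignment: diverged phenotypes go to parasites
## first (up to the reference panel's 16 diverged + 1 amitochondriate), all
## remaining species are aerobic
divergedCycle <- function() {
  rep(c("hydrogenosome", "mitosome", "anaerobic", "hydrogen_producing",
        "amitochondriate"),
      times = c(6L, 5L, 2L, 2L, 1L))
}

#' Simulate a planted truth matrix and species manifest
#'
#' Per species s in group g and family f of category c, presence is drawn
#' Bernoulli(presenceProb[g, c]) and then flipped with probability
#' \code{flipNoise}.  Deterministic given the config seed.
#'
#' @param config a [SimConfig-class].
#' @param rules named list of [GeneFamilyRule-class]
#'   (default: shipped config).
#' @return List with \code{truth} (binary matrix, families x species) and
#'   \code{manifest} (species [S4Vectors::DataFrame]).
#' @export
simulateTruth <- function(config, rules = parseRulesConfig()) {
  stopifnot(is(config, "SimConfig"))
  set.seed(config@seed)
  nTotal <- sum(config@groups)
  spIds <- sprintf("sp%03d", seq_len(nTotal))
  groupLab <- rep(names(config@groups), times = config@groups)

  if (config@groupVar == "lifestyle") {
    lifestyle <- groupLab
    mito <- rep("aerobic", nTotal)
    par <- which(lifestyle == "P")
    div <- divergedCycle()
    take <- seq_len(min(length(par), length(div)))
    mito[par[take]] <- div[take]
  } else {
    mito <- groupLab
    lifestyle <- rep("F", nTotal)
  }
  manifest <- S4Vectors::DataFrame(
    species_id = spIds,
    taxon_name = sprintf("Synthetic protist %03d", seq_len(nTotal)),
    superphylum = rep_len(superphyla(), nTotal),
    mito_class = mito,
    lifestyle = lifestyle,
    proteome_path = rep("", nTotal),
    row.names = spIds
  )

  famIds <- names(rules)
  cats <- vapply(rules, function(r) r@category, character(1L))
  truth <- matrix(0L, nrow = length(famIds), ncol = nTotal,
                  dimnames = list(famIds, spIds))
  for (j in seq_len(nTotal)) {
    probs <- config@presenceProb[[groupLab[j]]][cats]
    cells <- as.integer(stats::runif(length(famIds)) < probs)
    if (config@flipNoise > 0) {
      flip <- stats::runif(length(famIds)) < config@flipNoise
      cells[flip] <- 1L - cells[flip]
    }
    truth[, j] <- cells
  }
  list(truth = truth, manifest = manifest)
}

## accessions that, alone on a protein, satisfy no rule: partial members of
## multi-domain conjunctions plus a reserved unused range
safeDecoyPool <- function(rules) {
  used <- unique(unlist(lapply(rules, function(r) unlist(r@domainExpr))))
  pool <- c(used, sprintf("PF9%04d", 1:10))
  ok <- vapply(pool, function(a)
    !any(vapply(rules, function(r) evaluateProtein(r@domainExpr, a),
                logical(1L))),
    logical(1L))
  pool[ok]
}

randomProteinSeq <- function(len = 100L) {
  paste(c("M", sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]],
                      len - 1L, replace = TRUE)), collapse = "")
}

#' Fabricate evidence files consistent with a truth matrix
#'
#' For each planted presence one protein is fabricated.  Families with a
#' domain channel get domain-scan rows carrying the full accession set of one
#' randomly chosen alternative of the family's formula; families with a
#' homology channel get a tabular hit from the family bait that clears every
#' screen threshold (identity 90, coverage 1.0, E-value 1e-30); every
#' fabricated protein joins the family's ortholog group.  Absences emit no
#' satisfying evidence.  Decoy proteins carry single accessions verified to
#' satisfy no rule.  Seeded from \code{config@seed + 1} (one stream per run).
#'
#' @param truthSim result of [simulateTruth()] (\code{truth} + \code{manifest}).
#' @param rules named list of [GeneFamilyRule-class].
#' @param config the [SimConfig-class] used for the truth.
#' @return An in-memory evidence bundle: list with \code{manifest},
#'   \code{truth}, \code{hits} and \code{domains} (named lists of per-species
#'   data.frames), \code{orthoGroups}, \code{baitLengths} (named vector),
#'   \code{baitSeqs} and \code{proteinSeqs} (named character vectors).
#' @seealso [writeEvidenceBundle()], [profileBundle()]
#' @export
emitEvidence <- function(truthSim, rules, config) {
  set.seed(config@seed + 1L)
  truth <- truthSim$truth
  manifest <- truthSim$manifest
  spIds <- colnames(truth)
  famIds <- rownames(truth)
  stopifnot(identical(sort(famIds), sort(names(rules))))
  decoyPool <- safeDecoyPool(rules)

  baitIds <- vapply(rules, function(r)
    if (nzchar(r@baitSetId)) paste0("bait_", r@baitSetId) else "",
    character(1L))
  baitLengths <- setNames(rep(100, sum(nzchar(baitIds))),
                          baitIds[nzchar(baitIds)])
  baitSeqs <- vapply(names(baitLengths),
                     function(b) randomProteinSeq(100L), character(1L))

  hits <- list(); domains <- list()
  ortho <- list(); proteinSeqs <- character()
  for (sp in spIds) {
    hRows <- list(); dRows <- list()
    for (fam in famIds) {
      if (truth[fam, sp] != 1L) next
      rule <- rules[[fam]]
      prot <- sprintf("%s|%s_p1", sp, fam)
      proteinSeqs[[prot]] <- randomProteinSeq(100L)
      if (rule@detectionMode %in% c("domain_only", "combined")) {
        alt <- rule@domainExpr[[sample.int(length(rule@domainExpr), 1L)]]
        dRows[[length(dRows) + 1L]] <- data.frame(
          protein_id = prot, pfam_acc = alt,
          env_start = (seq_along(alt) - 1L) * 40L + 5L,
          env_end = (seq_along(alt) - 1L) * 40L + 35L,
          e_value = 1e-30, stringsAsFactors = FALSE)
      }
      if (rule@detectionMode %in% c("homology_only", "combined")) {
        hRows[[length(hRows) + 1L]] <- data.frame(
          query_id = paste0("bait_", rule@baitSetId), subject_id = prot,
          pct_identity = 90, aln_length = 100L, mismatch = 10L, gapopen = 0L,
          q_start = 1L, q_end = 100L, s_start = 1L, s_end = 100L,
          e_value = 1e-30, bit_score = 250, stringsAsFactors = FALSE)
      }
      ortho[[length(ortho) + 1L]] <- data.frame(
        group_id = paste0("OG_", fam), species_id = sp, protein_id = prot,
        stringsAsFactors = FALSE)
    }
    if (config@decoysPerProteome > 0L) {
      for (k in seq_len(config@decoysPerProteome)) {
        prot <- sprintf("%s|decoy_%d", sp, k)
        proteinSeqs[[prot]] <- randomProteinSeq(100L)
        dRows[[length(dRows) + 1L]] <- data.frame(
          protein_id = prot,
          pfam_acc = sample(decoyPool, 1L),
          env_start = 5L, env_end = 60L, e_value = 1e-10,
          stringsAsFactors = FALSE)
      }
    }
    hits[[sp]] <- if (length(hRows)) do.call(rbind, hRows) else emptyHits()
    domains[[sp]] <- if (length(dRows)) do.call(rbind, dRows) else
      data.frame(protein_id = character(), pfam_acc = character(),
                 env_start = integer(), env_end = integer(),
                 e_value = numeric(), stringsAsFactors = FALSE)
  }
  orthoGroups <- if (length(ortho)) do.call(rbind, ortho) else
    data.frame(group_id = character(), species_id = character(),
               protein_id = character(), stringsAsFactors = FALSE)
  list(manifest = manifest, truth = truth, hits = hits, domains = domains,
       orthoGroups = orthoGroups, baitLengths = baitLengths,
       baitSeqs = baitSeqs, proteinSeqs = proteinSeqs)
}

#' Simulate a complete evidence bundle
#'
#' Convenience wrapper: [simulateTruth()] followed by [emitEvidence()].
#'
#' @inheritParams simulateTruth
#' @return An in-memory evidence bundle (see [emitEvidence()]).
#' @export
simulateBundle <- function(config, rules = parseRulesConfig()) {
  emitEvidence(simulateTruth(config, rules), rules, config)
}

#' Write an evidence bundle to a directory
#'
#' Produces the on-disk layout consumed by [runAll()]:
#' \code{manifest.tsv}, \code{truth.tsv}, \code{orthogroups.tsv},
#' \code{baits.fasta}, \code{proteins.fasta}, and per-species
#' \code{hits/<sp>.tsv} and \code{domains/<sp>.tsv}.
#'
#' @param bundle bundle from [simulateBundle()] / [emitEvidence()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeEvidenceBundle <- function(bundle, dir) {
  dir.create(file.path(dir, "hits"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "domains"), showWarnings = FALSE)
  man <- as.data.frame(bundle$manifest)
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truthDf <- data.frame(family_id = rownames(bundle$truth),
                        bundle$truth, check.names = FALSE)
  utils::write.table(truthDf, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$orthoGroups, file.path(dir, "orthogroups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeFasta <- function(seqs, path) {
    set <- Biostrings::AAStringSet(seqs)
    Biostrings::writeXStringSet(set, path)
  }
  writeFasta(bundle$baitSeqs, file.path(dir, "baits.fasta"))
  if (length(bundle$proteinSeqs))
    writeFasta(bundle$proteinSeqs, file.path(dir, "proteins.fasta"))
  for (sp in names(bundle$hits))
    writeTabularHits(bundle$hits[[sp]], file.path(dir, "hits",
                                                  paste0(sp, ".tsv")))
  for (sp in names(bundle$domains)) {
    utils::write.table(bundle$domains[[sp]],
                       file.path(dir, "domains", paste0(sp, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(dir)
}

#' Read a truth matrix written by writeEvidenceBundle
#'
#' @param path path to \code{truth.tsv}.
#' @return Binary integer matrix, families x species.
#' @export
readTruthMatrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$family_id
  m
}
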