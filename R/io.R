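## Readers and writers for every external tabular format plus the
## rule-configuration parser.  All coordinates are 1-based inclusive (BLAST
## convention); Pfam accession version suffixes (".N") are stripped on read.

HITS_COLS <- c("query_id", "subject_id", "pct_identity", "aln_length",
               "mismatch", "gapopen", "q_start", "q_end", "s_start", "s_end",
               "e_value", "bit_score")

#' Normalize Pfam accessions
#'
#' Strips a version suffix (\code{".N"}) and validates the \code{PF} + 5-digit
#' form.
#'
#' @param acc character vector of Pfam accession tokens.
#' @return Character vector of normalized accessions.
#' @examples
#' normalizePfam("PF00656.22")
#' @export
normalizePfam <- function(acc) {
  out <- sub("\\.[0-9]+$", "", acc)
  bad <- !grepl("^PF[0-9]{5}$", out)
  if (any(bad))
    stop("invalid Pfam accession(s): ", paste(unique(acc[bad]), collapse = ", "))
  out
}

#' Read a species manifest
#'
#' Tab-separated file with header columns \code{species_id}, \code{taxon_name},
#' \code{superphylum}, \code{mito_class}, \code{lifestyle},
#' \code{proteome_path}.  Lines starting with \code{#} are comments.
#' Enumerated columns are validated against [superphyla()], [mitoClasses()]
#' and [lifestyleClasses()]; violations are reported with row and column.
#'
#' @param path path to the manifest TSV.
#' @return A [S4Vectors::DataFrame] of species records with rownames =
#'   \code{species_id}.
#' @seealso [simulateBundle()] for generating a synthetic manifest.
#' @export
readSpeciesManifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = "character", stringsAsFactors = FALSE)
  need <- c("species_id", "taxon_name", "superphylum", "mito_class",
            "lifestyle", "proteome_path")
  if (!all(need %in% names(df)))
    stop("manifest is missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df <- df[need]
  if (nrow(df) == 0L) {
    out <- S4Vectors::DataFrame(df)
    return(out)
  }
  checkEnum <- function(column, allowed) {
    bad <- which(!df[[column]] %in% allowed)
    if (length(bad))
      stop(sprintf("manifest row %d: invalid %s '%s' (allowed: %s)",
                   bad[1L], column, df[[column]][bad[1L]],
                   paste(allowed, collapse = ", ")))
  }
  checkEnum("superphylum", superphyla())
  checkEnum("mito_class", mitoClasses())
  checkEnum("lifestyle", lifestyleClasses())
  if (anyDuplicated(df$species_id))
    stop("duplicate species_id in manifest: ",
         df$species_id[duplicated(df$species_id)][1L])
  out <- S4Vectors::DataFrame(df)
  rownames(out) <- df$species_id
  out
}

#' Read and write 12-column tabular homology hits
#'
#' The standard 12-column tab-separated homology dialect
#' (\code{qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore}), no header.  Coordinates are 1-based inclusive; rows with
#' the wrong column count, non-numeric numeric fields, inverted coordinates or
#' negative E-values are rejected with their line number.
#'
#' @param path file path.
#' @return \code{readTabularHits}: a data.frame with typed columns named
#'   \code{query_id, subject_id, pct_identity, aln_length, mismatch, gapopen,
#'   q_start, q_end, s_start, s_end, e_value, bit_score}.
#' @export
readTabularHits <- function(path) {
  if (!file.exists(path)) stop("hits file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(emptyHits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12L)
  if (length(bad))
    stop(sprintf("hits line %d: expected 12 tab-separated columns, found %d",
                 bad[1L], lengths(parts)[bad[1L]]))
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  df <- data.frame(query_id = m[, 1L], subject_id = m[, 2L],
                   stringsAsFactors = FALSE)
  numCols <- c(pct_identity = 3L, aln_length = 4L, mismatch = 5L, gapopen = 6L,
               q_start = 7L, q_end = 8L, s_start = 9L, s_end = 10L,
               e_value = 11L, bit_score = 12L)
  for (nm in names(numCols)) {
    v <- suppressWarnings(as.numeric(m[, numCols[[nm]]]))
    if (anyNA(v))
      stop(sprintf("hits line %d: non-numeric value '%s' in column %s",
                   which(is.na(v))[1L], m[which(is.na(v))[1L], numCols[[nm]]], nm))
    df[[nm]] <- v
  }
  intCols <- c("aln_length", "mismatch", "gapopen",
               "q_start", "q_end", "s_start", "s_end")
  for (nm in intCols) df[[nm]] <- as.integer(df[[nm]])
  bad <- which(df$q_start > df$q_end | df$s_start > df$s_end)
  if (length(bad))
    stop(sprintf("hits line %d: start coordinate exceeds end coordinate", bad[1L]))
  bad <- which(df$e_value < 0)
  if (length(bad))
    stop(sprintf("hits line %d: negative E-value", bad[1L]))
  df
}

emptyHits <- function() {
  df <- data.frame(query_id = character(), subject_id = character(),
                   pct_identity = numeric(), aln_length = integer(),
                   mismatch = integer(), gapopen = integer(),
                   q_start = integer(), q_end = integer(),
                   s_start = integer(), s_end = integer(),
                   e_value = numeric(), bit_score = numeric(),
                   stringsAsFactors = FALSE)
  df
}

#' @rdname readTabularHits
#' @param hits a data.frame as returned by \code{readTabularHits}.
#' @export
writeTabularHits <- function(hits, path) {
  stopifnot(identical(names(hits), HITS_COLS))
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a domain-scan table
#'
#' Parses a whitespace- or tab-separated protein domain scan into typed
#' records.  Because scanner output layouts vary, the caller declares a column
#' mapping instead of the reader guessing; the default mapping matches the
#' five-column layout emitted by [writeEvidenceBundle()]:
#' \code{protein_id pfam_acc env_start env_end e_value}.  Accessions are
#' normalized with [normalizePfam()].  Duplicated identical rows are retained
#' (the result is an interval list, not a set).
#'
#' @param path file path.
#' @param colMap named integer vector mapping the five field names to column
#'   positions.
#' @param header does the file carry a header line to skip?
#' @return data.frame with columns \code{protein_id, pfam_acc, env_start,
#'   env_end, e_value}.
#' @examples
#' tf <- tempfile()
#' writeLines("prot1\tPF00656.22\t10\t150\t1e-30", tf)
#' readDomainScan(tf)
#' @export
readDomainScan <- function(path,
                           colMap = c(protein_id = 1L, pfam_acc = 2L,
                                      env_start = 3L, env_end = 4L,
                                      e_value = 5L),
                           header = FALSE) {
  if (!file.exists(path)) stop("domain-scan file not found: ", path)
  need <- c("protein_id", "pfam_acc", "env_start", "env_end", "e_value")
  if (!all(need %in% names(colMap)))
    stop("colMap must name columns: ", paste(need, collapse = ", "))
  lines <- readLines(path, warn = FALSE)
  if (header && length(lines)) lines <- lines[-1L]
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (!length(lines))
    return(data.frame(protein_id = character(), pfam_acc = character(),
                      env_start = integer(), env_end = integer(),
                      e_value = numeric(), stringsAsFactors = FALSE))
  parts <- strsplit(trimws(lines), "[ \t]+")
  maxCol <- max(colMap)
  short <- which(lengths(parts) < maxCol)
  if (length(short))
    stop(sprintf("domain-scan line %d: fewer than %d columns", short[1L], maxCol))
  pick <- function(i) vapply(parts, `[[`, character(1L), i)
  df <- data.frame(
    protein_id = pick(colMap[["protein_id"]]),
    pfam_acc = normalizePfam(pick(colMap[["pfam_acc"]])),
    env_start = as.integer(pick(colMap[["env_start"]])),
    env_end = as.integer(pick(colMap[["env_end"]])),
    e_value = as.numeric(pick(colMap[["e_value"]])),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$env_start) || anyNA(df$env_end) || anyNA(df$e_value))
    stop("domain scan: non-numeric coordinate or E-value")
  if (any(df$e_value < 0)) stop("domain scan: negative E-value")
  if (any(df$env_start > df$env_end))
    stop("domain scan: envelope start exceeds end")
  df
}

#' Read an ortholog-group membership table
#'
#' Three-column TSV with header \code{group_id species_id protein_id}, one row
#' per group member (the summarized output of an orthology pipeline such as
#' Broccoli).  A (species, protein) pair may belong to at most one group.
#'
#' @param path file path.
#' @return data.frame with columns \code{group_id, species_id, protein_id}.
#' @export
readOrthologGroups <- function(path) {
  if (!file.exists(path)) stop("ortholog-group file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", stringsAsFactors = FALSE)
  need <- c("group_id", "species_id", "protein_id")
  if (!all(need %in% names(df)))
    stop("ortholog table is missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df <- df[need]
  key <- paste(df$species_id, df$protein_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    clash <- key[dup][1L]
    gs <- unique(df$group_id[key == clash])
    if (length(gs) > 1L)
      stop("protein assigned to multiple ortholog groups: ",
           sub("\r", ":", clash))
    df <- df[!dup, , drop = FALSE]
  }
  df
}

#' Parse a gene-family rule configuration
#'
#' The configuration is plain structured text in Debian-control (DCF) layout:
#' one block per family separated by blank lines, with fields \code{family},
#' \code{category}, \code{pathway} (optional), \code{mode}, \code{expr}
#' (omitted for homology-only families) and \code{baits} (optional).  The
#' shipped default configuration (see [defaultRulesPath()]) transcribes the
#' canonical protist RCD gene-family definitions: 10 apoptosis, 12 autophagy
#' and 3 regulated-necrosis families.
#'
#' @param path path to a rule configuration; defaults to the shipped config.
#' @return Named list of [GeneFamilyRule-class] objects, in file order.
#' @examples
#' rules <- parseRulesConfig()
#' rules[["TSN"]]
#' @export
parseRulesConfig <- function(path = defaultRulesPath()) {
  if (!file.exists(path)) stop("rule config not found: ", path)
  blocks <- read.dcf(path, all = FALSE)
  if (!"family" %in% colnames(blocks))
    stop("rule config: every block needs a 'family' field")
  getField <- function(i, nm, default = "") {
    if (nm %in% colnames(blocks) && !is.na(blocks[i, nm]))
      unname(blocks[i, nm])
    else default
  }
  rules <- vector("list", nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    fam <- unname(blocks[i, "family"])
    mode <- getField(i, "mode", "combined")
    exprTxt <- getField(i, "expr")
    expr <- if (nzchar(trimws(exprTxt))) parseRuleExpr(exprTxt) else list()
    rules[[i]] <- GeneFamilyRule(
      familyId = fam,
      category = getField(i, "category"),
      pathwayGroup = getField(i, "pathway"),
      detectionMode = mode,
      domainExpr = expr,
      baitSetId = getField(i, "baits")
    )
  }
  ids <- vapply(rules, function(r) r@familyId, character(1L))
  if (anyDuplicated(ids))
    stop("duplicate family_id in rule config: ", ids[duplicated(ids)][1L])
  names(rules) <- ids
  rules
}

#' @rdname parseRulesConfig
#' @export
defaultRulesPath <- function() {
  system.file("extdata", "rcd_families.cfg", package = "rcdProfiler",
              mustWork = TRUE)
}

#' Sequence lengths from a protein FASTA
#'
#' Convenience lookup used to supply query (bait) lengths to [filterHits()].
#' Sequence names are truncated at the first whitespace.
#'
#' @param path FASTA file.
#' @return Named integer vector of sequence lengths.
#' @export
readSequenceLengths <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  len <- Biostrings::width(seqs)
  names(len) <- sub("\\s.*$", "", names(seqs))
  len
}
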