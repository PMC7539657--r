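## Homology-hit filtering by the mining thresholds and iterative bait
## expansion.  Coverage is computed on the query (bait) sequence as the
## aligned-span fraction (q_end - q_start + 1) / query_length.

#' Filter homology hits by E-value, identity and query coverage
#'
#' Keeps exactly the hits with \code{e_value < eMax}, \code{pct_identity >=
#' idMin} and query coverage \code{(q_end - q_start + 1)/query_length >=
#' covMin}.  Input order is preserved.  The filter is idempotent and monotone:
#' relaxing any threshold never removes a previously kept hit.
#'
#' @param hits data.frame of homology hits (see [readTabularHits()]).
#' @param queryLengths named numeric vector: query id -> residue length; must
#'   cover every query in \code{hits}.
#' @param params a [ScreenParams-class].
#' @return The kept subset of \code{hits}, original order.
#' @examples
#' h <- data.frame(query_id = "b1", subject_id = "p1", pct_identity = 45,
#'                 aln_length = 95L, mismatch = 0L, gapopen = 0L,
#'                 q_start = 1L, q_end = 95L, s_start = 1L, s_end = 95L,
#'                 e_value = 1e-20, bit_score = 200)
#' filterHits(h, c(b1 = 100), ScreenParams())
#' @export
filterHits <- function(hits, queryLengths, params = ScreenParams()) {
  stopifnot(is(params, "ScreenParams"))
  if (!nrow(hits)) return(hits)
  missing <- setdiff(unique(hits$query_id), names(queryLengths))
  if (length(missing))
    stop("missing query length for: ", paste(missing, collapse = ", "))
  qlen <- as.numeric(queryLengths[hits$query_id])
  coverage <- (hits$q_end - hits$q_start + 1) / qlen
  keep <- hits$e_value < params@eMax &
    hits$pct_identity >= params@idMin &
    coverage >= params@covMin
  hits[keep, , drop = FALSE]
}

#' Expand a bait set with the subjects of kept hits
#'
#' @param keptHits filtered hits data.frame.
#' @param currentBaits character vector of current bait protein ids.
#' @return Character vector: \code{currentBaits} united with the subject ids
#'   of \code{keptHits} (always a superset of the input).
#' @export
expandBaits <- function(keptHits, currentBaits) {
  sort(unique(c(currentBaits, keptHits$subject_id)))
}

#' Iterative homology search to a fixed point
#'
#' Repeatedly calls a caller-supplied search function on the current bait set,
#' filters its hits, and expands the baits with kept subjects, stopping when a
#' round adds no new baits or \code{maxRounds} is reached.  The search backend
#' (an external tool wrapper or a test stub) is injected, keeping the core
#' hermetic.
#'
#' @param searchFn function(baits) -> hits data.frame.
#' @param seedBaits character vector of seed bait ids.
#' @param queryLengths named numeric vector covering every bait that can act
#'   as a query.
#' @param params a [ScreenParams-class]; \code{maxRounds} caps the iteration.
#' @return List with \code{baits} (final set, sorted) and \code{log}, a
#'   data.frame with one row per executed round: \code{round, n_hits, n_kept,
#'   n_new_baits}.
#' @export
iterateSearch <- function(searchFn, seedBaits, queryLengths,
                          params = ScreenParams()) {
  stopifnot(is.function(searchFn), length(seedBaits) >= 1L)
  baits <- sort(unique(as.character(seedBaits)))
  log <- data.frame(round = integer(), n_hits = integer(),
                    n_kept = integer(), n_new_baits = integer())
  for (round in seq_len(params@maxRounds)) {
    hits <- tryCatch(searchFn(baits), error = function(e)
      stop(sprintf("search failed in round %d: %s", round, conditionMessage(e)),
           call. = FALSE))
    kept <- filterHits(hits, queryLengths, params)
    grown <- expandBaits(kept, baits)
    nNew <- length(grown) - length(baits)
    log <- rbind(log, data.frame(round = round, n_hits = nrow(hits),
                                 n_kept = nrow(kept), n_new_baits = nNew))
    baits <- grown
    if (nNew == 0L) break
  }
  list(baits = baits, log = log)
}
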