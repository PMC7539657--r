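# Builders for small in-code fixtures and the independent oracles used to
# cross-check the hand-written numerics.

makeHit <- function(query_id = "b1", subject_id = "p1", pct_identity = 50,
                    aln_length = 80L, mismatch = 0L, gapopen = 0L,
                    q_start = 1L, q_end = 80L, s_start = 1L, s_end = 80L,
                    e_value = 1e-20, bit_score = 100) {
  data.frame(query_id = query_id, subject_id = subject_id,
             pct_identity = pct_identity, aln_length = as.integer(aln_length),
             mismatch = as.integer(mismatch), gapopen = as.integer(gapopen),
             q_start = as.integer(q_start), q_end = as.integer(q_end),
             s_start = as.integer(s_start), s_end = as.integer(s_end),
             e_value = e_value, bit_score = bit_score,
             stringsAsFactors = FALSE)
}

randomHits <- function(n, queries = paste0("q", 1:4)) {
  qe <- sample(20:100, n, replace = TRUE)
  data.frame(query_id = sample(queries, n, replace = TRUE),
             subject_id = paste0("s", seq_len(n)),
             pct_identity = round(runif(n, 0, 100), 1),
             aln_length = qe, mismatch = 0L, gapopen = 0L,
             q_start = 1L, q_end = qe,
             s_start = 1L, s_end = qe,
             e_value = 10^runif(n, -30, 1),
             bit_score = round(runif(n, 20, 300), 1),
             stringsAsFactors = FALSE)
}

toyManifestFile <- function(n = 12L) {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(
    species_id = sprintf("tx%02d", 1:n),
    taxon_name = sprintf("Toy taxon %d", 1:n),
    superphylum = rep_len(superphyla(), n),
    mito_class = rep_len(mitoClasses(), n),
    lifestyle = rep_len(lifestyleClasses(), n),
    proteome_path = ""
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# random accession pool used by expression/domain property tests
accPool <- sprintf("PF%05d", 1:30)

randomExpr <- function(maxAlts = 4L, maxConj = 3L) {
  nAlt <- sample.int(maxAlts, 1L)
  lapply(seq_len(nAlt), function(i)
    sort(sample(accPool, sample.int(maxConj, 1L))))
}

# truth-table oracle: explicit double loop with per-accession membership
oracleEvaluate <- function(expr, domains) {
  for (conj in expr) {
    sat <- TRUE
    for (acc in conj) if (!acc %in% domains) { sat <- FALSE; break }
    if (sat) return(TRUE)
  }
  FALSE
}

# brute-force greedy Ward: recomputes the merge cost from cluster centroids
# from scratch at every step (2*na*nb/(na+nb) * squared centroid distance),
# same deterministic tie rule as wardLinkage
oracleWard <- function(pts) {
  n <- nrow(pts)
  members <- lapply(seq_len(n), identity)
  ids <- seq_len(n); code <- -seq_len(n)
  heights <- numeric(0); merges <- NULL
  for (s in seq_len(n - 1L)) {
    act <- which(!vapply(members, is.null, logical(1L)))
    best <- NULL; bd <- Inf
    for (a in act) for (b in act) if (a < b) {
      ca <- colMeans(pts[members[[a]], , drop = FALSE])
      cb <- colMeans(pts[members[[b]], , drop = FALSE])
      na <- length(members[[a]]); nb <- length(members[[b]])
      v <- 2 * na * nb / (na + nb) * sum((ca - cb)^2)
      if (is.null(best) || v < bd - 1e-8 * max(1, bd)) {
        bd <- v; best <- c(a, b)
      } else if (v <= bd + 1e-8 * max(1, bd)) {
        cur <- sort(c(ids[best[1L]], ids[best[2L]]))
        alt <- sort(c(ids[a], ids[b]))
        if (alt[1L] < cur[1L] || (alt[1L] == cur[1L] && alt[2L] < cur[2L])) {
          bd <- min(bd, v); best <- c(a, b)
        }
      }
    }
    a <- best[1L]; b <- best[2L]
    heights <- c(heights, sqrt(bd))
    merges <- rbind(merges, sort(c(code[a], code[b])))
    members[[a]] <- c(members[[a]], members[[b]])
    members[b] <- list(NULL)
    ids[a] <- n + s; code[a] <- s
  }
  list(heights = heights, merges = unname(merges))
}

# exact two-tailed Mann-Whitney p by full enumeration of rank assignments
oracleMWp <- function(x, y) {
  nA <- length(x); nB <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  uObs <- sum(rank(pooled)[seq_len(nA)]) - nA * (nA + 1) / 2
  allRanks <- seq_len(nA + nB)
  us <- apply(combn(nA + nB, nA), 2L, function(sel)
    sum(allRanks[sel]) - nA * (nA + 1) / 2)
  pLow <- mean(us <= uObs); pHigh <- mean(us >= uObs)
  min(1, 2 * min(pLow, pHigh))
}
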