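## Two-tailed Mann-Whitney U comparison of gene-count vectors, with an exact
## p-value by enumeration of the tie-free null distribution for small
## problems and a tie-corrected, continuity-corrected normal approximation
## otherwise.  Group summaries use the sample SD (denominator n-1).

EXACT_LIMIT <- 400  # use exact enumeration when nA*nB <= this and no ties

## exact null distribution of U for tie-free samples: counts[u+1] = number of
## rank arrangements of nA values among nA+nB with U = u
uNullCounts <- function(nA, nB) {
  memo <- new.env(parent = emptyenv())
  rec <- function(n, m) {
    if (n == 0L || m == 0L) return(1)
    key <- paste(n, m)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    a <- c(numeric(m), rec(n - 1L, m))       # largest value is in sample A
    b <- rec(n, m - 1L)                      # largest value is in sample B
    res <- numeric(n * m + 1L)
    res[seq_along(a)] <- a
    res[seq_along(b)] <- res[seq_along(b)] + b
    memo[[key]] <- res
    res
  }
  rec(as.integer(nA), as.integer(nB))
}

sampleSD <- function(v) if (length(v) < 2L) 0 else stats::sd(v)

#' Two-tailed Mann-Whitney U test
#'
#' U is computed from rank sums with midranks for ties.  The two-tailed
#' p-value is exact (by enumeration of the tie-free null distribution of U)
#' when \code{nA*nB <= 400} and the pooled sample has no ties; otherwise a
#' normal approximation with tie correction and a 0.5 continuity correction
#' is used.  Group means and SDs (sample SD, denominator n-1) are reported
#' alongside; a single-value group gets SD 0 with a flag.
#'
#' @param x,y numeric count vectors for the two groups (both non-empty).
#' @param labelA,labelB group labels carried into the result.
#' @param method \code{"auto"} (default), \code{"exact"} or \code{"normal"}.
#'   \code{"exact"} errors if the pooled sample has ties.
#' @return A [GroupComparison-class]; its \code{U} slot is the U statistic of
#'   \code{x} (so \code{U(x,y) + U(y,x) = nA*nB}).
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))   # U = 0, exact p = 0.1
#' @export
mannWhitneyU <- function(x, y, labelA = "A", labelB = "B",
                         method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  x <- as.numeric(x); y <- as.numeric(y)
  nA <- length(x); nB <- length(y); N <- nA + nB
  pooled <- c(x, y)
  ranks <- rank(pooled)
  U <- sum(ranks[seq_len(nA)]) - nA * (nA + 1) / 2
  hasTies <- anyDuplicated(pooled) > 0L

  if (method == "exact" && hasTies)
    stop("exact p-value requires a tie-free pooled sample")
  useExact <- switch(method,
    exact = TRUE,
    normal = FALSE,
    auto = (nA * nB <= EXACT_LIMIT) && !hasTies
  )

  if (useExact) {
    counts <- uNullCounts(nA, nB)
    total <- sum(counts)
    u <- as.integer(round(U))
    pLow <- sum(counts[seq_len(u + 1L)]) / total
    pHigh <- sum(counts[seq(u + 1L, length(counts))]) / total
    p <- min(1, 2 * min(pLow, pHigh))
    meth <- "exact"
  } else {
    mu <- nA * nB / 2
    tieTab <- table(pooled)
    tieTerm <- sum(tieTab^3 - tieTab)
    sigma2 <- (nA * nB / 12) * ((N + 1) - tieTerm / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(0, abs(U - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-z))
    }
    meth <- "normal_approx"
  }

  flags <- character()
  if (nA < 2L) flags <- c(flags, "sd_undefined_a")
  if (nB < 2L) flags <- c(flags, "sd_undefined_b")
  new("GroupComparison",
      labelA = labelA, labelB = labelB, nA = nA, nB = nB,
      meanA = mean(x), meanB = mean(y), sdA = sampleSD(x), sdB = sampleSD(y),
      U = U, pTwoTailed = p, method = meth, flags = flags)
}

comparisonToRow <- function(cmp) {
  data.frame(group_a = cmp@labelA, group_b = cmp@labelB,
             n_a = cmp@nA, n_b = cmp@nB,
             mean_a = cmp@meanA, mean_b = cmp@meanB,
             sd_a = cmp@sdA, sd_b = cmp@sdB,
             U = cmp@U, p_two_tailed = cmp@pTwoTailed,
             method = cmp@method, stringsAsFactors = FALSE)
}

#' Group summary and comparisons of per-species gene counts
#'
#' Summarises a per-species count vector (e.g. number of apoptosis families
#' present) by a metadata grouping and runs the standard comparisons:
#' \describe{
#'   \item{\code{"mito_class"}}{per-phenotype mean +/- SD table, and species
#'     with diverged mitochondria (every non-aerobic class, including the
#'     amitochondriate state) versus species with fully aerobic mitochondria.}
#'   \item{\code{"lifestyle"}}{per-lifestyle table, parasitic (P) versus
#'     non-parasitic (S, F, M), and transiently multicellular (M) versus
#'     free-living (F).}
#'   \item{custom}{a named factor/character partition over the species; all
#'     pairwise level comparisons.}
#' }
#' Groups with no species are excluded with a warning; single-species groups
#' report SD 0 with a flag on the comparison.
#'
#' @param counts named numeric vector, species id -> count.
#' @param metadata species manifest ([readSpeciesManifest()]) with rownames
#'   covering \code{names(counts)}; ignored for a custom partition.
#' @param grouping \code{"mito_class"}, \code{"lifestyle"}, or a named vector
#'   giving a custom partition of the species.
#' @return List with \code{groups} (data.frame: group, n, mean, sd) and
#'   \code{comparisons} (named list of [GroupComparison-class]).
#' @export
groupReport <- function(counts, metadata = NULL, grouping = "lifestyle") {
  sp <- names(counts)
  if (is.null(sp)) stop("counts must be named by species_id")
  if (is.character(grouping) && length(grouping) == 1L &&
      grouping %in% c("mito_class", "lifestyle")) {
    if (is.null(metadata)) stop("metadata required for grouping '", grouping, "'")
    if (!all(sp %in% rownames(metadata)))
      stop("species missing from metadata: ",
           paste(setdiff(sp, rownames(metadata))[1L], collapse = ", "))
    labels <- setNames(as.character(metadata[sp, grouping]), sp)
    levelOrder <- if (grouping == "mito_class") mitoClasses()
      else lifestyleClasses()
  } else {
    labels <- setNames(as.character(grouping)[match(sp, names(grouping))], sp)
    if (anyNA(labels)) stop("custom grouping does not cover all species")
    levelOrder <- sort(unique(labels))
    grouping <- "custom"
  }

  present <- levelOrder[levelOrder %in% labels]
  dropped <- setdiff(levelOrder, present)
  if (length(dropped))
    warning("group(s) with no species excluded: ",
            paste(dropped, collapse = ", "))
  groupValues <- lapply(present, function(g) unname(counts[labels == g]))
  names(groupValues) <- present
  groupTab <- data.frame(
    group = present,
    n = vapply(groupValues, length, integer(1L)),
    mean = vapply(groupValues, mean, numeric(1L)),
    sd = vapply(groupValues, sampleSD, numeric(1L)),
    stringsAsFactors = FALSE
  )

  comparisons <- list()
  addCmp <- function(name, selA, labA, selB, labB) {
    a <- unname(counts[selA]); b <- unname(counts[selB])
    if (!length(a) || !length(b)) return()
    comparisons[[name]] <<- mannWhitneyU(a, b, labelA = labA, labelB = labB)
  }
  if (grouping == "mito_class") {
    addCmp("diverged_vs_aerobic",
           labels != "aerobic", "diverged", labels == "aerobic", "aerobic")
  } else if (grouping == "lifestyle") {
    addCmp("parasitic_vs_nonparasitic",
           labels == "P", "parasitic", labels != "P", "non-parasitic")
    addCmp("multicellular_vs_freeliving",
           labels == "M", "multicellular", labels == "F", "free-living")
  } else {
    if (length(present) >= 2L) {
      prs <- utils::combn(present, 2L)
      for (i in seq_len(ncol(prs))) {
        a <- prs[1L, i]; b <- prs[2L, i]
        addCmp(paste(a, "vs", b, sep = "_"),
               labels == a, a, labels == b, b)
      }
    }
  }
  list(groups = groupTab, comparisons = comparisons)
}
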