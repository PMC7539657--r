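## Ward variance-minimisation linkage, implemented directly via the
## Lance-Williams update on squared distances:
##   d2(k, i+j) = [(n_i+n_k) d2(i,k) + (n_j+n_k) d2(j,k) - n_k d2(i,j)]
##               / (n_i + n_j + n_k)
## Merge heights are sqrt(d2) (the "ward.D2" convention); the merge sequence
## is fully deterministic: among tied pairs the one with the smallest
## (min creation index, max creation index) is merged, leaves indexed 1..n in
## input order and internal nodes n+1, n+2, ... in merge order.

WARD_TIE_TOL <- 1e-8

#' Ward linkage on a distance matrix
#'
#' Agglomerative clustering minimising the within-cluster variance increase at
#' each merge.  Heights are non-decreasing on metric input and match the
#' \code{"ward.D2"} convention (square root of the Lance-Williams squared
#' merge cost).
#'
#' @param d a [stats::dist] object or symmetric numeric matrix with zero
#'   diagonal.
#' @return A [LinkageTree-class].
#' @examples
#' m <- rbind(a = c(0, 0), b = c(0, 1), c = c(10, 0))
#' wardLinkage(dist(m))
#' @export
wardLinkage <- function(d) {
  if (inherits(d, "dist")) {
    labels <- attr(d, "Labels")
    dm <- as.matrix(d)
  } else {
    dm <- as.matrix(d)
    if (!isSymmetric(unname(dm), tol = 1e-10))
      stop("distance matrix must be symmetric")
    labels <- rownames(dm)
  }
  n <- nrow(dm)
  if (n < 2L) stop("need at least 2 observations")
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (any(diag(dm) != 0)) stop("distance matrix must have a zero diagonal")

  D2 <- dm^2
  active <- rep(TRUE, n)
  ids <- seq_len(n)            # creation index of the cluster at each slot
  code <- -seq_len(n)          # hclust merge code of the cluster at each slot
  sizes <- rep(1L, n)
  merges <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  newSizes <- integer(n - 1L)

  for (step in seq_len(n - 1L)) {
    slots <- which(active)
    best <- NULL
    bestD2 <- Inf
    for (ai in seq_len(length(slots) - 1L)) {
      for (aj in seq(ai + 1L, length(slots))) {
        i <- slots[ai]; j <- slots[aj]
        v <- D2[i, j]
        if (is.null(best) || v < bestD2 - WARD_TIE_TOL * max(1, bestD2)) {
          bestD2 <- v
          best <- c(i, j)
        } else if (v <= bestD2 + WARD_TIE_TOL * max(1, bestD2)) {
          # tie: prefer smallest (min id, max id)
          cur <- sort(c(ids[best[1L]], ids[best[2L]]))
          alt <- sort(c(ids[i], ids[j]))
          if (alt[1L] < cur[1L] || (alt[1L] == cur[1L] && alt[2L] < cur[2L])) {
            bestD2 <- min(bestD2, v)
            best <- c(i, j)
          }
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    heights[step] <- sqrt(max(0, D2[i, j]))
    entries <- sort(c(code[i], code[j]))
    merges[step, ] <- entries
    ni <- sizes[i]; nj <- sizes[j]
    newSizes[step] <- ni + nj
    for (k in which(active)) {
      if (k == i || k == j) next
      nk <- sizes[k]
      D2[i, k] <- D2[k, i] <-
        ((ni + nk) * D2[i, k] + (nj + nk) * D2[j, k] - nk * D2[i, j]) /
        (ni + nj + nk)
    }
    active[j] <- FALSE
    sizes[i] <- ni + nj
    ids[i] <- n + step
    code[i] <- step
  }

  new("LinkageTree", merges = merges, heights = heights,
      sizes = newSizes, order = leafOrder(merges, n), labels = labels)
}

## dendrogram leaf order: left-to-right depth-first walk of the merge tree
leafOrder <- function(merges, n) {
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(merges[node, 1L]), walk(merges[node, 2L]))
  }
  as.integer(walk(nrow(merges)))
}

#' Convert a LinkageTree to an hclust object
#'
#' @param x a [LinkageTree-class].
#' @param ... unused.
#' @return A [stats::hclust] object (method \code{"ward.D2"}).
#' @export
as.hclust.LinkageTree <- function(x, ...) {
  structure(list(merge = x@merges, height = x@heights, order = x@order,
                 labels = x@labels, method = "ward.D2",
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

#' Cut a LinkageTree into k flat clusters
#'
#' @param tree a [LinkageTree-class].
#' @param k number of clusters.
#' @return Named integer vector of cluster labels.
#' @export
cutLinkage <- function(tree, k) {
  stopifnot(is(tree, "LinkageTree"))
  stats::cutree(as.hclust.LinkageTree(tree), k = k)
}

## within-cluster sum of squared Euclidean deviations from cluster centroids
clusterWSS <- function(m, labels) {
  sum(vapply(split(seq_len(nrow(m)), labels), function(rows) {
    sub <- m[rows, , drop = FALSE]
    ctr <- colMeans(sub)
    sum(sweep(sub, 2L, ctr)^2)
  }, numeric(1L)))
}

#' Select the number of clusters by a deterministic three-index vote
#'
#' For each candidate k the tree is cut into k flat clusters and three
#' standard indices are computed on the profile matrix: Calinski-Harabasz
#' (maximised), mean silhouette width (maximised) and the
#' within-cluster-sum-of-squares elbow (maximum curvature of the WSS curve).
#' Each index votes for one k; the majority wins, ties going to the smallest
#' voted k.  The full index table is returned so disagreement between indices
#' can be inspected.  If all profiles are identical the result is k = 1 with a
#' warning.
#'
#' @param tree a [LinkageTree-class] over the species.
#' @param x the matrix the tree was built from: a [PresenceMatrix-class] or a
#'   numeric matrix with species in rows (same order as the tree labels).
#' @param kRange candidate cluster numbers; default \code{2:min(8, n-1)}.
#' @return List with \code{k_best}, \code{votes} (named integer vector, one
#'   per index), \code{table} (data.frame k, wss, ch, silhouette,
#'   elbow_score) and \code{labels} (flat clustering at \code{k_best}).
#' @export
selectK <- function(tree, x, kRange = NULL) {
  stopifnot(is(tree, "LinkageTree"))
  m <- if (is(x, "PresenceMatrix")) t(presence(x)) else as.matrix(x)
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 species to select a cluster number")
  stopifnot(n == length(tree@labels))
  if (is.null(kRange)) kRange <- seq(2L, min(8L, n - 1L))
  kRange <- sort(unique(as.integer(kRange)))
  stopifnot(all(kRange >= 2L & kRange <= n - 1L))
  d <- stats::dist(m)
  if (all(d == 0)) {
    warning("all profiles identical; k_best = 1")
    return(list(k_best = 1L, votes = NULL,
                table = data.frame(k = integer(), wss = numeric(),
                                   ch = numeric(), silhouette = numeric(),
                                   elbow_score = numeric()),
                labels = setNames(rep(1L, n), tree@labels)))
  }

  kGrid <- sort(unique(c(1L, kRange, max(kRange) + 1L)))
  cuts <- stats::cutree(as.hclust.LinkageTree(tree), k = kGrid)
  if (is.null(dim(cuts))) cuts <- matrix(cuts, ncol = 1L,
                                         dimnames = list(NULL, kGrid))
  wssAt <- vapply(as.character(kGrid), function(kc)
    clusterWSS(m, cuts[, kc]), numeric(1L))
  names(wssAt) <- as.character(kGrid)

  totSS <- wssAt[["1"]]
  wAt <- function(k) {
    kc <- as.character(k)
    if (kc %in% names(wssAt)) wssAt[[kc]] else NA_real_
  }
  tab <- data.frame(k = kRange, wss = NA_real_, ch = NA_real_,
                    silhouette = NA_real_, elbow_score = NA_real_)
  for (r in seq_along(kRange)) {
    k <- kRange[r]
    labels <- cuts[, as.character(k)]
    w <- wssAt[[as.character(k)]]
    tab$wss[r] <- w
    tab$ch[r] <- ((totSS - w) / (k - 1)) / (w / (n - k))
    sil <- cluster::silhouette(labels, d)
    tab$silhouette[r] <- mean(sil[, "sil_width"])
    wPrev <- wAt(k - 1L)
    wNext <- wAt(k + 1L)
    if (!is.na(wPrev) && !is.na(wNext))
      tab$elbow_score[r] <- (wPrev - w) - (w - wNext)
  }
  votes <- c(
    ch = tab$k[which.max(tab$ch)],
    silhouette = tab$k[which.max(tab$silhouette)],
    elbow = if (all(is.na(tab$elbow_score))) tab$k[1L]
      else tab$k[which.max(tab$elbow_score)]
  )
  counts <- table(votes)
  winners <- as.integer(names(counts)[counts == max(counts)])
  kBest <- min(winners)
  list(k_best = kBest, votes = votes, table = tab,
       labels = cuts[, as.character(kBest)])
}
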