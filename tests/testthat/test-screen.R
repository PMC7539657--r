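test_that("filterHits applies the three thresholds with correct strictness", {
  qlen <- c(b1 = 100)
  params <- ScreenParams()

  kept <- filterHits(makeHit(pct_identity = 45, q_end = 95L, e_value = 1e-20),
                     qlen, params)
  expect_equal(nrow(kept), 1L)

  # identity just below 30 is dropped; exactly 30 is kept (inclusive)
  expect_equal(nrow(filterHits(makeHit(pct_identity = 29.9, q_end = 95L),
                               qlen, params)), 0L)
  expect_equal(nrow(filterHits(makeHit(pct_identity = 30, q_end = 95L),
                               qlen, params)), 1L)

  # coverage exactly 0.8 is kept
  expect_equal(nrow(filterHits(makeHit(q_start = 1L, q_end = 80L),
                               qlen, params)), 1L)
  expect_equal(nrow(filterHits(makeHit(q_start = 1L, q_end = 79L),
                               qlen, params)), 0L)

  # E-value exactly 1e-5 is dropped (strict <)
  expect_equal(nrow(filterHits(makeHit(e_value = 1e-5, q_end = 95L),
                               qlen, params)), 0L)
  expect_equal(nrow(filterHits(makeHit(e_value = 0.99e-5, q_end = 95L),
                               qlen, params)), 1L)

  expect_error(filterHits(makeHit(query_id = "ghost"), qlen, params),
               "missing query length.*ghost")
})

test_that("filterHits equals a naive per-condition scan and is well-behaved", {
  set.seed(21)
  qlen <- setNames(sample(50:200, 4), paste0("q", 1:4))
  params <- ScreenParams()
  for (rep in 1:10) {
    hits <- randomHits(200)
    kept <- filterHits(hits, qlen, params)
    naive <- hits[vapply(seq_len(nrow(hits)), function(i) {
      h <- hits[i, ]
      cov <- (h$q_end - h$q_start + 1) / qlen[[h$query_id]]
      h$e_value < 1e-5 && h$pct_identity >= 30 && cov >= 0.8
    }, logical(1L)), ]
    expect_equal(kept, naive)
    # subset of input, idempotent
    expect_true(all(rownames(kept) %in% rownames(hits)))
    expect_equal(filterHits(kept, qlen, params), kept)
    # monotone: relaxing thresholds keeps every previously kept hit
    relaxed <- filterHits(hits, qlen,
                          ScreenParams(eMax = 1e-3, idMin = 10, covMin = 0.5))
    expect_true(all(rownames(kept) %in% rownames(relaxed)))
  }
})

test_that("bait expansion is a union and reaches fixed points", {
  kept <- makeHit(subject_id = c("n1", "n2"), query_id = c("b1", "b1"))
  expect_setequal(expandBaits(kept, "b1"), c("b1", "n1", "n2"))
  expect_equal(expandBaits(kept[0L, ], c("b1", "b2")), c("b1", "b2"))
  expect_setequal(expandBaits(kept, c("b1", "n1", "n2")), c("b1", "n1", "n2"))
})

test_that("iterative search stops at fixed point or round cap", {
  qlen <- c(a = 100, b = 100, c = 100)
  # chain a -> b -> c: searching {a} finds b, {a,b} finds c
  edges <- list(a = "b", b = "c", c = character())
  searchFn <- function(baits) {
    subj <- unlist(edges[baits], use.names = FALSE)
    if (!length(subj)) return(makeHit()[0L, ])
    makeHit(query_id = rep(baits, lengths(edges[baits])), subject_id = subj,
            pct_identity = 90, q_start = 1L, q_end = 100L, e_value = 1e-30)
  }
  res <- iterateSearch(searchFn, "a", qlen, ScreenParams(maxRounds = 3L))
  expect_equal(res$baits, c("a", "b", "c"))
  expect_equal(nrow(res$log), 3L)  # two growth rounds + one fixed-point round
  expect_true(all(diff(res$log$n_new_baits) <= 0))

  # stub returning hits only for the seed: terminates after round 2
  onceFn <- function(baits) {
    if ("a" %in% baits && !"b" %in% baits)
      makeHit(query_id = "a", subject_id = "b", pct_identity = 90,
              q_end = 100L, e_value = 1e-30)
    else makeHit()[0L, ]
  }
  res <- iterateSearch(onceFn, "a", qlen, ScreenParams(maxRounds = 5L))
  expect_equal(res$baits, c("a", "b"))
  expect_equal(nrow(res$log), 2L)

  # maxRounds 1 executes exactly one round
  res <- iterateSearch(searchFn, "a", qlen, ScreenParams(maxRounds = 1L))
  expect_equal(nrow(res$log), 1L)
  expect_equal(res$baits, c("a", "b"))

  # search failures propagate with round context
  expect_error(
    iterateSearch(function(b) stop("backend down"), "a", qlen),
    "round 1.*backend down")
})

test_that("bait sets grow monotonically on random closed homology graphs", {
  set.seed(31)
  for (rep in 1:10) {
    prots <- paste0("p", 1:8)
    qlen <- setNames(rep(100, 8), prots)
    adj <- lapply(setNames(prots, prots), function(p)
      sample(prots, sample(0:2, 1)))
    searchFn <- function(baits) {
      subj <- unlist(adj[baits], use.names = FALSE)
      if (!length(subj)) return(makeHit()[0L, ])
      makeHit(query_id = rep(baits, lengths(adj[baits])), subject_id = subj,
              pct_identity = 90, q_end = 100L, e_value = 1e-30)
    }
    res <- iterateSearch(searchFn, "p1", qlen, ScreenParams(maxRounds = 10L))
    # oracle: transitive closure of the directed graph from p1
    closure <- "p1"; repeat {
      nxt <- sort(unique(c(closure, unlist(adj[closure]))))
      if (identical(nxt, closure)) break
      closure <- nxt
    }
    expect_equal(res$baits, closure)
  }
})
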