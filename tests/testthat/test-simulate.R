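test_that("planted truth follows the configured probabilities", {
  rules <- parseRulesConfig()

  # presence probability 1, no noise -> all-ones truth
  allOn <- lapply(setNames(nm = c("F", "M")), function(g)
    c(apoptosis = 1, autophagy = 1, necrosis = 1))
  cfg <- simConfig(groups = c(F = 3L, M = 2L), presenceProb = allOn,
                   flipNoise = 0, seed = 1)
  tr <- simulateTruth(cfg, rules)
  expect_true(all(tr$truth == 1L))
  expect_equal(dim(tr$truth), c(25L, 5L))

  # determinism: same seed -> identical outputs
  cfg2 <- simConfig(seed = 99)
  expect_identical(simulateTruth(cfg2, rules), simulateTruth(cfg2, rules))

  # group means land within 3 binomial SDs of expectation
  probs <- list(F = c(apoptosis = 0.9, autophagy = 0.9, necrosis = 0.9),
                M = c(apoptosis = 0.3, autophagy = 0.3, necrosis = 0.3))
  cfg3 <- simConfig(groups = c(F = 20L, M = 20L), presenceProb = probs,
                    flipNoise = 0, seed = 7)
  tr3 <- simulateTruth(cfg3, rules)
  grp <- as.character(tr3$manifest$lifestyle)
  for (g in c("F", "M")) {
    p <- probs[[g]][["apoptosis"]]
    cells <- tr3$truth[1:10, grp == g]   # 10 apoptosis families x 20 species
    n <- length(cells)
    expect_lt(abs(mean(cells) - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("default config mirrors the 67-species study panel", {
  cfg <- simConfig(seed = 3)
  tr <- simulateTruth(cfg)
  man <- tr$manifest
  expect_equal(nrow(man), 67L)
  expect_equal(as.vector(table(factor(man$lifestyle, lifestyleClasses()))),
               c(17L, 4L, 31L, 15L))
  expect_equal(as.vector(table(factor(man$mito_class, mitoClasses()))),
               c(51L, 2L, 2L, 6L, 5L, 1L))
  # no transiently multicellular species carries a diverged mitochondrion
  expect_true(all(man$mito_class[man$lifestyle == "M"] == "aerobic"))
  # all diverged phenotypes sit in parasites
  expect_true(all(man$lifestyle[man$mito_class != "aerobic"] == "P"))
})

test_that("fabricated evidence is minimal-sufficient and rule-consistent", {
  rules <- parseRulesConfig()
  allOn <- lapply(setNames(nm = c("F", "M")), function(g)
    c(apoptosis = 1, autophagy = 1, necrosis = 1))
  cfg <- simConfig(groups = c(F = 2L, M = 2L), presenceProb = allOn,
                   flipNoise = 0, seed = 11)
  bundle <- simulateBundle(cfg, rules)

  # a TSN presence emits one protein carrying BOTH Tudor and SN domains
  sp <- colnames(bundle$truth)[1L]
  dt <- bundle$domains[[sp]]
  sets <- split(dt$pfam_acc, dt$protein_id)
  carriesBoth <- vapply(sets, function(s)
    all(c("PF00565", "PF00567") %in% s), logical(1L))
  expect_equal(sum(carriesBoth), 1L)
  expect_setequal(sets[[which(carriesBoth)]], c("PF00565", "PF00567"))

  # homology-only families emit hits but never domain rows
  mlklProts <- grep("MLKL", dt$protein_id, value = TRUE)
  expect_length(mlklProts, 0L)
  hit <- bundle$hits[[sp]]
  expect_true(any(hit$query_id == "bait_MLKL"))

  # every emitted hit clears every screen threshold
  kept <- filterHits(hit, bundle$baitLengths, ScreenParams())
  expect_equal(nrow(kept), nrow(hit))

  # decoy proteins never satisfy any rule
  decoys <- dt[grepl("decoy", dt$protein_id), ]
  expect_gt(nrow(decoys), 0L)
  for (prot in unique(decoys$protein_id)) {
    doms <- decoys$pfam_acc[decoys$protein_id == prot]
    sat <- vapply(rules, function(r) evaluateProtein(r@domainExpr, doms),
                  logical(1L))
    expect_false(any(sat))
  }
})

test_that("the pipeline round-trips emitted evidence to the truth matrix", {
  rules <- parseRulesConfig()
  cfg <- simConfig(groups = c(F = 8L, P = 8L), seed = 201, flipNoise = 0)
  bundle <- simulateBundle(cfg, rules)
  pm <- profileBundle(bundle, rules)$matrix
  expect_identical(unname(presence(pm)), unname(bundle$truth))
  # column/row ordering is preserved
  expect_equal(colnames(presence(pm)), colnames(bundle$truth))
  expect_equal(rownames(presence(pm)), rownames(bundle$truth))
})

test_that("group-effect recovery and planted contrasts behave as designed", {
  rules <- parseRulesConfig()
  # presence-probability difference of 0.5 between groups, n = 15 + 15,
  # 10-family category: Mann-Whitney rejects at p < 0.01 almost always
  probs <- list(F = c(apoptosis = 0.2, autophagy = 0.5, necrosis = 0),
                M = c(apoptosis = 0.7, autophagy = 0.5, necrosis = 0))
  rej <- 0L
  nRep <- 200L
  for (s in seq_len(nRep)) {
    cfg <- simConfig(groups = c(F = 15L, M = 15L), presenceProb = probs,
                     flipNoise = 0, seed = 5000 + s)
    tr <- simulateTruth(cfg, rules)
    counts <- colSums(tr$truth[1:10, ])
    grp <- as.character(tr$manifest$lifestyle)
    p <- mannWhitneyU(counts[grp == "M"], counts[grp == "F"])@pTwoTailed
    if (p < 0.01) rej <- rej + 1L
  }
  expect_gte(rej / nRep, 0.95)
})
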