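test_that("Mann-Whitney U matches hand examples and symmetry laws", {
  cmp <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp@U, 0)
  expect_equal(cmp@pTwoTailed, 0.1)   # 2 * 1/choose(6,3)
  expect_equal(cmp@method, "exact")

  # identical multisets -> p = 1
  expect_equal(mannWhitneyU(c(1, 2, 2), c(1, 2, 2))@pTwoTailed, 1)

  set.seed(23)
  for (i in 1:20) {
    x <- rnorm(sample(2:8, 1)); y <- rnorm(sample(2:8, 1))
    a <- mannWhitneyU(x, y); b <- mannWhitneyU(y, x)
    expect_equal(a@pTwoTailed, b@pTwoTailed)
    expect_equal(a@U + b@U, length(x) * length(y))
  }
  # U_x + U_y = nA*nB with midranks under heavy ties too
  x <- c(1, 1, 2, 2, 3); y <- c(1, 2, 2, 3, 3, 3)
  expect_equal(mannWhitneyU(x, y)@U + mannWhitneyU(y, x)@U,
               length(x) * length(y))

  expect_error(mannWhitneyU(numeric(), 1:3), "non-empty")
})

test_that("exact p equals full enumeration and wilcox.test on tie-free data", {
  set.seed(24)
  for (i in 1:20) {
    nA <- sample(2:6, 1); nB <- sample(2:6, 1)
    vals <- sample(seq(0.1, 50, by = 0.1), nA + nB)
    x <- vals[seq_len(nA)]; y <- vals[-seq_len(nA)]
    cmp <- mannWhitneyU(x, y)
    expect_equal(cmp@method, "exact")
    expect_equal(cmp@pTwoTailed, oracleMWp(x, y))
    wt <- wilcox.test(x, y, exact = TRUE)
    expect_equal(cmp@pTwoTailed, wt$p.value)
  }
})

test_that("normal approximation agrees with the exact tail near crossover", {
  set.seed(25)
  for (i in 1:10) {
    vals <- sample(1:5000, 40)
    x <- vals[1:20]; y <- vals[21:40]   # nA*nB = 400: the exact/approx boundary
    pe <- mannWhitneyU(x, y, method = "exact")@pTwoTailed
    pa <- mannWhitneyU(x, y, method = "normal")@pTwoTailed
    expect_lt(abs(pe - pa), 0.01)
  }
  expect_error(mannWhitneyU(c(1, 1, 2), c(2, 3, 4), method = "exact"),
               "tie-free")
})

test_that("group report reproduces hand-computed means and comparisons", {
  man <- readSpeciesManifest(toyManifestFile(12L))
  counts <- setNames(c(5, 2, 8, 9, 4, 1, 7, 6, 3, 2, 9, 8), rownames(man))

  rep <- groupReport(counts, man, "lifestyle")
  # toy manifest cycles P,S,F,M so each lifestyle has 3 species
  byHand <- tapply(counts, as.character(man$lifestyle), mean)
  got <- setNames(rep$groups$mean, rep$groups$group)
  expect_equal(unname(got[names(byHand)]), as.vector(byHand))
  expect_named(rep$comparisons,
               c("parasitic_vs_nonparasitic", "multicellular_vs_freeliving"))
  pvn <- rep$comparisons$parasitic_vs_nonparasitic
  expect_equal(pvn@nA, 3L); expect_equal(pvn@nB, 9L)
  expect_equal(pvn@meanA, mean(counts[as.character(man$lifestyle) == "P"]))
  expect_equal(pvn@sdA, sd(counts[as.character(man$lifestyle) == "P"]))

  repM <- groupReport(counts, man, "mito_class")
  dva <- repM$comparisons$diverged_vs_aerobic
  expect_equal(dva@labelA, "diverged")
  expect_equal(dva@nA + dva@nB, 12L)
  expect_equal(dva@nB, sum(man$mito_class == "aerobic"))

  # single-species groups: SD reported as 0 with a flag
  solo <- groupReport(setNames(c(4, 7, 7, 8), rownames(man)[1:4]),
                      grouping = setNames(c("a", "b", "b", "b"),
                                          rownames(man)[1:4]))
  cmp <- solo$comparisons$a_vs_b
  expect_equal(cmp@sdA, 0)
  expect_true("sd_undefined_a" %in% cmp@flags)

  # empty groups are excluded with a warning
  manP <- man[man$lifestyle %in% c("P", "F"), ]
  expect_warning(
    groupReport(counts[rownames(manP)], manP, "lifestyle"),
    "excluded")
})

test_that("custom partitions run all pairwise comparisons", {
  counts <- setNames(c(1, 2, 3, 10, 11, 12, 5, 6), paste0("s", 1:8))
  part <- setNames(rep(c("lo", "hi", "mid"), c(3, 3, 2)), paste0("s", 1:8))
  rep <- groupReport(counts, grouping = part)
  expect_equal(nrow(rep$groups), 3L)
  expect_length(rep$comparisons, 3L)
  expect_equal(rep$comparisons$hi_vs_lo@pTwoTailed, 0.1)
})
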