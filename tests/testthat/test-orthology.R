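groupsFixture <- function() {
  data.frame(
    group_id = c(rep("g1", 5), rep("g2", 7)),
    species_id = c("s1", "s1", "s2", "s3", "s4",
                   "s5", "s5", "s6", "s6", "s7", "s7", "s8"),
    protein_id = paste0("p", 1:12),
    stringsAsFactors = FALSE)
}

test_that("largest-group selection restricts to candidate groups", {
  groups <- groupsFixture()
  # g2 is bigger but contains no retrieved protein -> not a candidate
  retrieved <- data.frame(species_id = c("s1", "s2"),
                          protein_id = c("p1", "p3"))
  sel <- selectLargestGroup(groups, retrieved, "famA")
  expect_equal(sel@selectedGroupId, "g1")
  expect_equal(sel@groupSize, 5L)
  expect_equal(sel@status, "selected")
  expect_equal(nrow(sel@candidates), 1L)

  # single candidate group
  one <- data.frame(species_id = "s5", protein_id = "p6")
  expect_equal(selectLargestGroup(groups, one, "famB")@selectedGroupId, "g2")

  # size ties break to the lexicographically smallest group id
  tied <- data.frame(
    group_id = c("gB", "gB", "gA", "gA"),
    species_id = c("s1", "s2", "s3", "s4"),
    protein_id = c("q1", "q2", "q3", "q4"))
  sel <- selectLargestGroup(tied,
                            data.frame(species_id = c("s1", "s3"),
                                       protein_id = c("q1", "q3")))
  expect_equal(sel@selectedGroupId, "gA")

  # no containing group -> explicit unassigned, distinct from absence
  sel <- selectLargestGroup(groups,
                            data.frame(species_id = "sX", protein_id = "pX"),
                            "famC")
  expect_equal(sel@status, "unassigned")
  expect_true(is.na(sel@selectedGroupId))
})

test_that("ortholog presence scores membership in any selected group", {
  groups <- groupsFixture()
  sel <- selectLargestGroup(groups,
                            data.frame(species_id = "s1", protein_id = "p1"))
  pres <- orthologPresence(sel, groups, paste0("s", 1:8))
  expect_equal(unname(pres[c("s1", "s4")]), c(1L, 1L))
  # species only in the non-selected group score 0
  expect_equal(unname(pres[c("s5", "s8")]), c(0L, 0L))

  # multi-subfamily category: presence in either subfamily's group counts
  sel2 <- selectLargestGroup(groups,
                             data.frame(species_id = "s5", protein_id = "p6"))
  both <- orthologPresence(list(sel, sel2), groups, paste0("s", 1:8))
  expect_equal(sum(both), 8L)
})

test_that("selection is invariant under group listing order", {
  groups <- groupsFixture()
  retrieved <- data.frame(species_id = c("s1", "s5"),
                          protein_id = c("p1", "p6"))
  a <- selectLargestGroup(groups, retrieved)
  b <- selectLargestGroup(groups[sample(nrow(groups)), ], retrieved)
  expect_equal(a@selectedGroupId, b@selectedGroupId)
  expect_equal(a@candidates, b@candidates)
})

test_that("ortholog reduction never creates presence on synthetic bundles", {
  rules <- parseRulesConfig()
  cfg <- simConfig(groups = c(F = 6L, M = 6L), seed = 91, flipNoise = 0)
  bundle <- simulateBundle(cfg, rules)
  pm <- profileBundle(bundle, rules)$matrix
  red <- reduceToOrthologs(pm, bundle$orthoGroups)
  expect_true(all(presence(red$matrix) <= presence(pm)))
  # groups built from the retrieved proteins themselves: reduction is exact
  expect_equal(presence(red$matrix), presence(pm))
  # provenance/presence invariant holds on the reduced object too
  expect_true(validObject(red$matrix))
})

test_that("families with unassigned retrievals yield zero rows, flagged", {
  rules <- parseRulesConfig()
  cfg <- simConfig(groups = c(F = 4L, M = 4L), seed = 17, flipNoise = 0)
  bundle <- simulateBundle(cfg, rules)
  pm <- profileBundle(bundle, rules)$matrix
  # drop one family's group from the table entirely
  fam <- rownames(presence(pm))[which(rowSums(presence(pm)) > 0)[1L]]
  groups <- bundle$orthoGroups
  groups <- groups[groups$group_id != paste0("OG_", fam), ]
  red <- reduceToOrthologs(pm, groups)
  expect_equal(sum(presence(red$matrix)[fam, ]), 0L)
  rd <- SummarizedExperiment::rowData(red$matrix)
  expect_equal(rd[fam, "ortholog_status"], "unassigned")
  expect_equal(red$selections[[fam]]@status, "unassigned")
})
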