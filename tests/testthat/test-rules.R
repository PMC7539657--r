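test_that("formula parsing honours precedence and rejects malformed input", {
  expect_equal(parseRuleExpr("PF00565 + PF00567"),
               list(c("PF00565", "PF00567")))
  expect_equal(parseRuleExpr("PF02265 / PF01223 / PF03265"),
               list("PF02265", "PF01223", "PF03265"))
  # "+" binds tighter than "/"
  expect_equal(parseRuleExpr("PF13365 + PF00595 / PF12812"),
               list(c("PF00595", "PF13365"), "PF12812"))
  expect_error(parseRuleExpr("PF00565 +"), "dangling operator")
  expect_error(parseRuleExpr("PF00565 + + PF00567"), "dangling '\\+'")
  expect_error(parseRuleExpr("PF00565 / / PF00567"), "dangling '/'")
  expect_error(parseRuleExpr("PF00565 + NOTPF"), "non-accession token 'NOTPF'")
})

test_that("parse -> deparse -> parse is the identity on random formulas", {
  set.seed(5)
  for (i in 1:50) {
    expr <- randomExpr()
    expect_equal(parseRuleExpr(deparseRuleExpr(expr)), expr)
  }
})

test_that("protein evaluation equals truth-table oracle and is monotone", {
  tsn <- parseRuleExpr("PF00565 + PF00567")
  expect_false(evaluateProtein(tsn, "PF00565"))
  expect_true(evaluateProtein(tsn, c("PF00565", "PF00567", "PF00001")))

  set.seed(6)
  for (i in 1:300) {
    expr <- randomExpr()
    doms <- sample(accPool, sample(0:8, 1))
    expect_identical(evaluateProtein(expr, doms), oracleEvaluate(expr, doms))
    # adding accessions never flips TRUE -> FALSE
    if (evaluateProtein(expr, doms))
      expect_true(evaluateProtein(expr, c(doms, sample(accPool, 3))))
  }
})

test_that("family calls follow detection modes and record evidence", {
  rules <- parseRulesConfig()
  mc <- rules[["METACASPASE"]]
  dt <- data.frame(protein_id = "p1", pfam_acc = "PF00656",
                   env_start = 10L, env_end = 150L, e_value = 1e-30)
  call <- callFamily(mc, dt, homologs = character(), speciesId = "sp1")
  expect_equal(call$present, 1L)
  expect_equal(call$evidence, "domain")
  expect_equal(call$supporting_proteins, "p1")

  aif <- rules[["AIF_AMID"]]
  emptyDt <- dt[0L, ]
  call <- callFamily(aif, emptyDt, homologs = character(), speciesId = "sp1")
  expect_equal(call$present, 0L)
  expect_equal(call$evidence, "none")

  # homology_only with no homolog channel at all is an explicit error
  expect_error(callFamily(aif, emptyDt, homologs = NULL, speciesId = "sp1"),
               "evidence unavailable")

  # combined mode: homology evidence alone suffices
  tor <- rules[["TOR"]]
  call <- callFamily(tor, emptyDt, homologs = "h1", speciesId = "sp1")
  expect_equal(call$present, 1L)
  expect_equal(call$evidence, "homology")

  # both channels -> evidence "both"
  dtTor <- data.frame(protein_id = "p2", pfam_acc = "PF08771",
                      env_start = 1L, env_end = 50L, e_value = 1e-10)
  call <- callFamily(tor, dtTor, homologs = "h1", speciesId = "sp1")
  expect_equal(call$evidence, "both")
  expect_equal(call$supporting_proteins, "h1,p2")
})

test_that("calls are invariant to protein order and duplicated domain rows", {
  tsn <- parseRulesConfig()[["TSN"]]
  dt <- data.frame(
    protein_id = c("pB", "pB", "pA"),
    pfam_acc = c("PF00565", "PF00567", "PF00565"),
    env_start = 1L, env_end = 50L, e_value = 1e-10)
  base <- callFamily(tsn, dt, homologs = character(), speciesId = "s")
  shuffled <- callFamily(tsn, dt[c(3, 2, 1), ], homologs = character(),
                         speciesId = "s")
  duplicated <- callFamily(tsn, rbind(dt, dt), homologs = character(),
                           speciesId = "s")
  expect_equal(base$supporting_proteins, "pB")
  expect_equal(shuffled, base)
  expect_equal(duplicated, base)
})

test_that("optional per-call E-value ceiling filters domain evidence", {
  mc <- parseRulesConfig()[["METACASPASE"]]
  dt <- data.frame(protein_id = "p1", pfam_acc = "PF00656",
                   env_start = 1L, env_end = 50L, e_value = 1e-3)
  expect_equal(callFamily(mc, dt, character(), "s")$present, 1L)
  expect_equal(
    callFamily(mc, dt, character(), "s", domainEMax = 1e-5)$present, 0L)
})
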