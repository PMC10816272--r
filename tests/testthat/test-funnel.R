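# Comparative elimination, ranking and the orchestrated funnel.

test_that("comparative elimination applies per-receptor rules", {
  rules <- c(HDAC1 = "remove_if_bidentate",
             HDAC6 = "remove_if_bidentate_or_monodentate",
             HDAC8 = "remove_if_bidentate")
  tabs <- list(
    HDAC1 = data.frame(id = c("a", "b"), class = c("none", "bidentate")),
    HDAC6 = data.frame(id = c("a", "c"), class = c("none", "monodentate")),
    HDAC8 = data.frame(id = "d", class = "monodentate"))
  res <- comparativeEliminate(c("a", "b", "c", "d", "e"), tabs, rules)
  # a: clean everywhere; b: bidentate in HDAC1; c: monodentate under the
  # HDAC6 rule; d: monodentate in HDAC8 (allowed); e: absent everywhere
  expect_identical(res$kept, c("a", "d", "e"))
  expect_setequal(res$log$id, c("b", "c"))
  expect_match(res$log$reason[res$log$id == "c"], "HDAC6")
  # unknown receptor in the rules is a configuration error
  expect_error(comparativeEliminate("a", tabs,
                                    c(HDAC4 = "remove_if_bidentate")),
               "HDAC4")
  expect_error(comparativeEliminate("a", tabs, c(HDAC1 = "frobnicate")),
               "unknown elimination rule")
})

test_that("elimination on a planted 20-ligand class table matches hand derivation", {
  set.seed(20)
  ids <- sprintf("Z%02d", 1:20)
  cls <- function() sample(c("bidentate", "monodentate", "none", NA),
                           20, replace = TRUE)
  tab <- data.frame(id = ids, HDAC1 = cls(), HDAC6 = cls(), HDAC8 = cls(),
                    stringsAsFactors = FALSE)
  rules <- c(HDAC1 = "remove_if_bidentate",
             HDAC6 = "remove_if_bidentate_or_monodentate",
             HDAC8 = "remove_if_bidentate")
  tabs <- lapply(c(HDAC1 = "HDAC1", HDAC6 = "HDAC6", HDAC8 = "HDAC8"),
                 function(r) {
                   keep <- !is.na(tab[[r]])
                   data.frame(id = tab$id[keep], class = tab[[r]][keep])
                 })
  res <- comparativeEliminate(ids, tabs, rules)
  handKept <- ids[!(
    (!is.na(tab$HDAC1) & tab$HDAC1 == "bidentate") |
      (!is.na(tab$HDAC6) & tab$HDAC6 %in% c("bidentate", "monodentate")) |
      (!is.na(tab$HDAC8) & tab$HDAC8 == "bidentate"))]
  expect_identical(res$kept, handKept)
})

test_that("ranking sorts ascending with lexicographic tie-break", {
  expect_identical(rankHits(c("A", "B", "C"),
                            c(A = -50, B = -60, C = -40), topK = 1)$id,
                   "B")
  tied <- rankHits(c("B", "A"), c(A = -50, B = -50))
  expect_identical(tied$id, c("A", "B"))
  expect_error(rankHits(c("A", "X"), c(A = -50)), "X")
  # order equals an independent sort oracle on a random table
  set.seed(8)
  ids <- sprintf("M%03d", sample(100))
  sc <- setNames(round(rnorm(100), 2), ids)
  got <- rankHits(ids, sc)$id
  oracle <- names(sort(sc))   # stable sort; resolve ties by name
  df <- data.frame(id = names(sc), s = unname(sc))
  oracle <- df$id[order(df$s, df$id)]
  expect_identical(got, oracle)
})

test_that("the funnel reproduces planted stage counts exactly", {
  pk <- fixturePocket()
  gl <- genLibrary(librarySpec(n = 80, seed = 17), pk)
  cfg <- defaultFunnelConfig()
  cfg$hypothesis <- pk$hypothesis
  rep <- runFunnel(gl$library, cfg, fixtureReceptors(),
                   syntheticBackend(gl$truth, seed = 3), gl$scores)
  tr <- gl$truth
  want <- c(substructure = sum(tr$surv_substructure),
            state = sum(tr$surv_state),
            rule_of_five = sum(tr$surv_ro5),
            pharmacophore = sum(tr$surv_pharmacophore),
            docking_target = sum(tr$surv_docking),
            pose_filter = sum(tr$surv_pose),
            comparative = sum(tr$surv_comparative),
            alerts = sum(tr$surv_alerts),
            ranking = sum(tr$surv_alerts))
  got <- setNames(stageCounts(rep)$nOut, stageCounts(rep)$stage)
  expect_identical(got[names(want)], want)
  # survivor identity, not just counts
  surv <- stageSurvivors(rep)
  expect_setequal(surv$pose_filter, tr$id[tr$surv_pose])
  expect_setequal(surv$alerts, tr$id[tr$surv_alerts])
})

test_that("funnel stage order and audit invariants hold", {
  pk <- fixturePocket()
  gl <- genLibrary(librarySpec(n = 40, seed = 2), pk)
  cfg <- defaultFunnelConfig()
  cfg$hypothesis <- pk$hypothesis
  rep <- runFunnel(gl$library, cfg, fixtureReceptors(),
                   syntheticBackend(gl$truth, seed = 3), gl$scores)
  s <- stageCounts(rep)
  expect_identical(s$stage,
                   c("substructure", "state", "rule_of_five",
                     "pharmacophore", "docking_target", "pose_filter",
                     "comparative", "alerts", "ranking"))
  # telescoping counts and monotone shrinkage
  expect_identical(s$nIn[-1], s$nOut[-nrow(s)])
  expect_true(all(s$nOut <= s$nIn))
  # survivors of stage k are a subset of stage k-1
  surv <- stageSurvivors(rep)
  for (k in 2:length(surv))
    expect_true(all(surv[[k]] %in% surv[[k - 1]]))
  # audit conservation: input = output + removals, per stage
  rm <- removalLog(rep)
  for (k in seq_len(nrow(s)))
    expect_identical(s$nIn[k],
                     s$nOut[k] + sum(rm$stage == s$stage[k]))
  # every removal attributed to exactly one stage
  expect_false(anyDuplicated(rm$id) > 0)
})

test_that("an empty library flows through with all counts zero", {
  pk <- fixturePocket()
  cfg <- defaultFunnelConfig()
  cfg$hypothesis <- pk$hypothesis
  rep <- runFunnel(moleculeLibrary(), cfg, fixtureReceptors(),
                   function(mol, rec) NULL, numeric())
  expect_true(all(stageCounts(rep)$nIn == 0))
  expect_true(all(stageCounts(rep)$nOut == 0))
  expect_identical(nrow(rankingOf(rep)), 0L)
})

test_that("shuffling the library changes no survivor set or ranking", {
  pk <- fixturePocket()
  gl <- genLibrary(librarySpec(n = 40, seed = 6), pk)
  cfg <- defaultFunnelConfig()
  cfg$hypothesis <- pk$hypothesis
  backend <- syntheticBackend(gl$truth, seed = 5)
  rep1 <- runFunnel(gl$library, cfg, fixtureReceptors(), backend,
                    gl$scores)
  set.seed(99)
  shuffled <- gl$library[sample(length(gl$library))]
  rep2 <- runFunnel(shuffled, cfg, fixtureReceptors(), backend, gl$scores)
  s1 <- stageSurvivors(rep1); s2 <- stageSurvivors(rep2)
  for (k in seq_along(s1)) expect_setequal(s1[[k]], s2[[k]])
  expect_identical(rankingOf(rep1), rankingOf(rep2))
})

test_that("two runs under fixed seeds give identical reports", {
  pk <- fixturePocket()
  gl <- genLibrary(librarySpec(n = 40, seed = 4), pk)
  cfg <- defaultFunnelConfig()
  cfg$hypothesis <- pk$hypothesis
  backend <- syntheticBackend(gl$truth, seed = 7)
  rep1 <- runFunnel(gl$library, cfg, fixtureReceptors(), backend, gl$scores)
  rep2 <- runFunnel(gl$library, cfg, fixtureReceptors(), backend, gl$scores)
  expect_identical(stageCounts(rep1), stageCounts(rep2))
  expect_identical(stageSurvivors(rep1), stageSurvivors(rep2))
  expect_identical(rankingOf(rep1), rankingOf(rep2))
})

test_that("configuration errors abort with the offending stage", {
  pk <- fixturePocket()
  gl <- genLibrary(librarySpec(n = 20, seed = 1), pk)
  cfg <- defaultFunnelConfig()
  cfg$hypothesis <- pk$hypothesis
  backend <- syntheticBackend(gl$truth, seed = 1)
  badCfg <- cfg
  badCfg$target <- "HDAC99"
  expect_error(runFunnel(gl$library, badCfg, fixtureReceptors(), backend,
                         gl$scores), "HDAC99")
  noHyp <- cfg
  noHyp$hypothesis <- NULL
  expect_error(runFunnel(gl$library, noHyp, fixtureReceptors(), backend,
                         gl$scores), "pharmacophore")
})

test_that("reports serialize to JSON and CSV", {
  pk <- fixturePocket()
  gl <- genLibrary(librarySpec(n = 40, seed = 12), pk)
  cfg <- defaultFunnelConfig()
  cfg$hypothesis <- pk$hypothesis
  rep <- runFunnel(gl$library, cfg, fixtureReceptors(),
                   syntheticBackend(gl$truth, seed = 2), gl$scores)
  d <- tempfile()
  writeFunnelReport(rep, d)
  js <- jsonlite::read_json(file.path(d, "report.json"),
                            simplifyVector = TRUE)
  expect_identical(js$stages$stage, stageCounts(rep)$stage)
  expect_identical(as.integer(js$stages$nOut), stageCounts(rep)$nOut)
  rm <- read.csv(file.path(d, "removals.csv"))
  expect_identical(names(rm), c("id", "stage", "reason"))
  expect_true(file.exists(file.path(d, "ranking.csv")))
})

test_that("funnel configs round trip through YAML", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("target: HDAC11",
               "antitargets:",
               "  HDAC1: remove_if_bidentate",
               "  HDAC6: remove_if_bidentate_or_monodentate",
               "cutoff: 2.6",
               "maxConformers: 25"), f)
  cfg <- readFunnelConfig(f)
  expect_identical(cfg$target, "HDAC11")
  expect_identical(cfg$maxConformers, 25L)
  expect_identical(unname(cfg$antitargetRules["HDAC6"]),
                   "remove_if_bidentate_or_monodentate")
  expect_identical(cfg$ro5$thresholds$mw, 500)
})
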