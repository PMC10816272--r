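# Receptor loading, chelator identification and zinc-chelation
# classification; mock docking backend.

toyPDB <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

test_that("receptor loading resolves a single zinc and errors otherwise", {
  one <- toyPDB(c(
    "ATOM      1  CA  ALA A   1      11.104   6.134  -6.504  1.00  0.00           C",
    "HETATM    2 ZN    ZN A  99       1.000   2.000   3.000  1.00  0.00          ZN",
    "END"))
  rec <- loadReceptor(one, isoform = "HDAC11")
  expect_equal(rec@zinc, c(1, 2, 3))
  expect_identical(rec@isoform, "HDAC11")
  expect_false("ZN" %in% rec@atoms$elem)
  two <- toyPDB(c(
    "HETATM    1 ZN    ZN A  98       0.000   0.000   0.000  1.00  0.00          ZN",
    "HETATM    2 ZN    ZN A  99       5.000   0.000   0.000  1.00  0.00          ZN",
    "END"))
  expect_error(loadReceptor(two), "found 2")
  # selector narrowing resolves the ambiguity
  rec2 <- loadReceptor(two, zincSelector = list(resno = 99))
  expect_equal(rec2@zinc, c(5, 0, 0))
})

test_that("pocket PDB round trip preserves the planted zinc", {
  pk <- fixturePocket()
  f <- tempfile(fileext = ".pdb")
  writeReceptorPDB(pk$receptor, f)
  back <- loadReceptor(f, isoform = "HDAC11")
  expect_equal(back@zinc, pk$zinc, tolerance = 1e-3)
})

test_that("chelator identification finds the hydroxamate oxygens", {
  m <- moleculeFromSmiles("[O-]N([H])C(=O)c1ccccc1", id = "anion")
  pair <- identifyChelators(m)
  expect_identical(m@atoms$elem[pair], c("O", "O"))
  # carbonyl O is double-bonded to C; hydroxyl O is the charged one
  expect_identical(m@atoms$charge[pair], c(0L, -1L))
  expect_error(identifyChelators(moleculeFromSmiles("NC(=O)c1ccccc1",
                                                    id = "benzamide")),
               "no hydroxamate")
})

test_that("with two hydroxamates the embedding nearer the zinc wins", {
  bis <- moleculeFromSmiles("[O-]N([H])C(=O)CCCC(=O)N([H])[O-]", id = "bis")
  n <- nrow(bis@atoms)
  coords <- matrix(0, n, 3)
  coords[, 1] <- seq(0, by = 1.2, length.out = n)  # stretched along x
  conformers(bis) <- list(coords)
  rec <- new("ReceptorContext", isoform = "X",
             atoms = data.frame(elety = character(), resid = character(),
                                chain = character(), resno = integer(),
                                elem = character(), x = numeric(),
                                y = numeric(), z = numeric()),
             zinc = c(0, 0, 0))
  pairNear <- identifyChelators(bis, rec)
  recFar <- rec
  recFar@zinc <- c(coords[n, 1], 0, 0)
  pairFar <- identifyChelators(bis, recFar)
  expect_false(setequal(pairNear, pairFar))
  midNear <- mean(coords[pairNear, 1])
  midFar <- mean(coords[pairFar, 1])
  expect_lt(midNear, midFar)
  # hand-derived: both embeddings' distances confirm the choice
  expect_lt(abs(midNear - rec@zinc[1]), abs(midFar - rec@zinc[1]))
})

test_that("chelation classes follow the inclusive 2.6 A cutoff", {
  expect_identical(chelationClass(classifyChelation(2.41, 2.17)),
                   "bidentate")
  expect_identical(chelationClass(classifyChelation(2.60, 2.60)),
                   "bidentate")    # boundary passes: removal is 'more than'
  expect_identical(chelationClass(classifyChelation(2.2, 3.4)),
                   "monodentate")
  expect_identical(chelationClass(classifyChelation(5.0, 5.0)), "none")
  expect_identical(chelationClass(classifyChelation(2.6000001, 2.0)),
                   "monodentate")
})

test_that("classification agrees with brute-force recomputation on 1000 random poses", {
  pk <- fixturePocket()
  set.seed(101)
  mol <- pk$template
  pair <- identifyChelators(mol)
  for (i in 1:1000) {
    coords <- matrix(rnorm(nrow(mol@atoms) * 3, sd = 3), ncol = 3)
    pose <- new("DockedPose", ligandId = "r", molecule = mol,
                coords = coords, chelatorPair = pair)
    a <- assessChelation(pose, pk$receptor)
    d1 <- sqrt(sum((coords[pair[1], ] - pk$zinc)^2))
    d2 <- sqrt(sum((coords[pair[2], ] - pk$zinc)^2))
    want <- c("none", "monodentate", "bidentate")[sum(c(d1, d2) <= 2.6) + 1]
    expect_identical(chelationClass(a), want)
    expect_equal(a@dCarbonyl, d1)
    expect_equal(a@dHydroxyl, d2)
  }
})

test_that("assessment is invariant under joint rigid motion of pose and zinc", {
  pk <- fixturePocket()
  mol <- pk$template
  pair <- identifyChelators(mol)
  coords <- conformers(mol)[[1]]
  set.seed(11)
  for (k in 1:10) {
    rig <- randomRigid()
    rec2 <- pk$receptor
    rec2@zinc <- as.vector(rig$R %*% pk$zinc + rig$t)
    pose2 <- new("DockedPose", ligandId = "t", molecule = mol,
                 coords = applyRigid(coords, rig), chelatorPair = pair)
    a0 <- assessChelation(new("DockedPose", ligandId = "t", molecule = mol,
                              coords = coords, chelatorPair = pair),
                          pk$receptor)
    a1 <- assessChelation(pose2, rec2)
    expect_equal(a1@dCarbonyl, a0@dCarbonyl, tolerance = 1e-9)
    expect_equal(a1@dHydroxyl, a0@dHydroxyl, tolerance = 1e-9)
    expect_identical(chelationClass(a1), chelationClass(a0))
  }
})

test_that("raising the cutoff never demotes a pose's class", {
  rank <- c(none = 0, monodentate = 1, bidentate = 2)
  set.seed(3)
  for (k in 1:200) {
    d <- runif(2, 0, 6)
    cls <- vapply(c(1.5, 2.6, 4.0, 7.0), function(cu) {
      chelationClass(classifyChelation(d[1], d[2], cutoff = cu))
    }, character(1))
    expect_true(all(diff(rank[cls]) >= 0))
  }
})

test_that("mock docking realizes the requested mode deterministically", {
  pk <- fixturePocket()
  mol <- pk$template
  p1 <- mockDock(mol, pk$receptor, "chelating", seed = 42)
  expect_identical(chelationClass(assessChelation(p1, pk$receptor)),
                   "bidentate")
  p2 <- mockDock(mol, pk$receptor, "monodentate", seed = 42)
  expect_identical(chelationClass(assessChelation(p2, pk$receptor)),
                   "monodentate")
  p3 <- mockDock(mol, pk$receptor, "nonbinding", seed = 42)
  a3 <- assessChelation(p3, pk$receptor)
  expect_identical(chelationClass(a3), "none")
  expect_gt(min(a3@dCarbonyl, a3@dHydroxyl), 4)
  # bit-identical coordinates under the same seed
  p1b <- mockDock(mol, pk$receptor, "chelating", seed = 42)
  expect_identical(p1@coords, p1b@coords)
  p1c <- mockDock(mol, pk$receptor, "chelating", seed = 43)
  expect_false(identical(p1@coords, p1c@coords))
  # chelating distances within the advertised band
  a1 <- assessChelation(p1, pk$receptor)
  expect_true(all(c(a1@dCarbonyl, a1@dHydroxyl) >= 2.0 - 1e-9))
  expect_true(all(c(a1@dCarbonyl, a1@dHydroxyl) <= 2.3 + 1e-9))
})

test_that("poses round trip through SDF with score and receptor fields", {
  pk <- fixturePocket()
  p <- mockDock(pk$template, pk$receptor, "chelating", seed = 7)
  f <- tempfile(fileext = ".sdf")
  writePoses(list(p), f)
  back <- readPoses(f, pk$receptor)
  expect_length(back, 1)
  expect_identical(back[[1]]@ligandId, p@ligandId)
  expect_equal(back[[1]]@score, p@score, tolerance = 1e-4)
  expect_identical(back[[1]]@receptor, "HDAC11")
  expect_equal(back[[1]]@coords, p@coords, tolerance = 1e-3,
               ignore_attr = TRUE)
  a <- assessChelation(back[[1]], pk$receptor)
  expect_identical(chelationClass(a), "bidentate")
})

test_that("assessments are written in the documented CSV layout", {
  pk <- fixturePocket()
  p <- mockDock(pk$template, pk$receptor, "chelating", seed = 1)
  a <- assessChelation(p, pk$receptor)
  f <- tempfile(fileext = ".csv")
  writeAssessments(list(template = a), "HDAC11", f)
  tab <- read.csv(f)
  expect_identical(names(tab),
                   c("id", "receptor", "d_carbonyl", "d_hydroxyl", "class"))
  expect_identical(tab$class, "bidentate")
})
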