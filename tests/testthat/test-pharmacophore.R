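# Feature perception, hypothesis construction, matching and screening.

test_that("perception finds the four hydroxamate-anion features", {
  pk <- fixturePocket()
  feats <- perceiveFeatures(pk$template)
  expect_true(all(c("acceptor", "donor", "negative", "aromatic") %in%
                    feats$kind))
  # anchors: negative at the anionic O, donor at N, acceptor at carbonyl O
  sc <- attr(pk$template, "scaffold")
  coords <- conformers(pk$template)[[1]]
  neg <- feats[feats$kind == "negative", ][1, ]
  expect_equal(unlist(neg[c("x", "y", "z")]),
               coords[sc$head[["Oh"]], ], ignore_attr = TRUE)
  arom <- feats[feats$kind == "aromatic", ][1, ]
  expect_equal(unlist(arom[c("x", "y", "z")]),
               colMeans(coords[sc$ring, ]), ignore_attr = TRUE)
})

test_that("perception is empty for methane and errors without coordinates", {
  m <- moleculeFromSmiles("C", id = "methane")
  conformers(m) <- list(matrix(0, 1, 3))
  expect_identical(nrow(perceiveFeatures(m)), 0L)
  m2 <- moleculeFromSmiles("CCO", id = "etoh")
  expect_error(perceiveFeatures(m2), "no 3D coordinates")
})

test_that("per-molecule feature counts equal hand enumeration", {
  cases <- list(
    # smiles, expected counts: acceptor, donor, negative, aromatic
    list(s = "O=C(NO)c1ccccc1", acc = 2L, don = 2L, neg = 0L, aro = 1L),
    list(s = "[O-]N([H])C(=O)c1ccccc1", acc = 1L, don = 1L, neg = 1L,
         aro = 1L),
    list(s = "c1ccncc1", acc = 1L, don = 0L, neg = 0L, aro = 1L),
    list(s = "CCOC", acc = 1L, don = 0L, neg = 0L, aro = 0L),
    list(s = "CC(=O)NC", acc = 1L, don = 1L, neg = 0L, aro = 0L))
  for (cs in cases) {
    m <- moleculeFromSmiles(cs$s, id = cs$s)
    conformers(m) <- list(matrix(rnorm(nrow(m@atoms) * 3), ncol = 3))
    f <- perceiveFeatures(m)
    expect_identical(sum(f$kind == "acceptor"), cs$acc, label = cs$s)
    expect_identical(sum(f$kind == "donor"), cs$don, label = cs$s)
    expect_identical(sum(f$kind == "negative"), cs$neg, label = cs$s)
    expect_identical(sum(f$kind == "aromatic"), cs$aro, label = cs$s)
  }
})

test_that("hypothesis built from a pose places features and volumes", {
  pk <- fixturePocket()
  hyp <- pk$hypothesis
  expect_s4_class(hyp, "PharmacophoreHypothesis")
  expect_identical(nrow(hyp@features), 4L)
  expect_setequal(hyp@features$kind,
                  c("acceptor", "donor", "negative", "aromatic"))
  # every excluded volume sits on a protein heavy-atom coordinate
  prot <- pk$receptor@atoms
  prot <- prot[prot$elem != "H", ]
  for (i in seq_len(nrow(hyp@volumes))) {
    d <- min(sqrt((prot$x - hyp@volumes$x[i])^2 +
                    (prot$y - hyp@volumes$y[i])^2 +
                    (prot$z - hyp@volumes$z[i])^2))
    expect_lt(d, 1e-9)
  }
  # a receptor with no atoms in the shell yields features only
  far <- pk$receptor
  far@atoms$x <- far@atoms$x + 100
  hyp0 <- buildHypothesis(pk$template, far)
  expect_identical(nrow(hyp0@volumes), 0L)
  # a pick absent from the ligand is an error naming it
  expect_error(buildHypothesis(pk$template, pk$receptor,
                               picks = c("acceptor", "positive")),
               "positive")
})

test_that("identity and rigidly moved poses match with zero fit RMSD", {
  pk <- fixturePocket()
  hyp <- pk$hypothesis
  res <- matchPharmacophore(pk$template, hyp)
  expect_false(is.null(res))
  expect_lt(res$fitRmsd, 1e-9)
  # rigid translation is removed by the alignment
  shifted <- pk$template
  conformers(shifted) <- list(sweep(conformers(pk$template)[[1]], 2,
                                    c(10, 0, 0), "+"))
  res2 <- matchPharmacophore(shifted, hyp)
  expect_false(is.null(res2))
  expect_lt(res2$fitRmsd, 1e-9)
})

test_that("matching is invariant under arbitrary rigid transforms", {
  pk <- fixturePocket()
  hyp <- pk$hypothesis
  set.seed(42)
  for (k in 1:5) {
    rig <- randomRigid()
    moved <- pk$template
    conformers(moved) <- list(applyRigid(conformers(pk$template)[[1]], rig))
    res <- matchPharmacophore(moved, hyp)
    expect_false(is.null(res))
    expect_lt(res$fitRmsd, 1e-6)
  }
})

test_that("a ligand atom inside an excluded volume is rejected", {
  pk <- fixturePocket()
  hyp <- pk$hypothesis
  # add a volume right on a ligand tail atom position
  coords <- conformers(pk$template)[[1]]
  tailAtom <- coords[nrow(coords), ]
  hyp2 <- hyp
  hyp2@volumes <- rbind(hyp@volumes,
                        data.frame(x = tailAtom[1], y = tailAtom[2],
                                   z = tailAtom[3], radius = 1.2))
  expect_null(matchPharmacophore(pk$template, hyp2))
})

test_that("matcher equals the exhaustive-enumeration oracle", {
  pk <- fixturePocket()
  set.seed(7)
  # toy instances with up to 6 hypothesis features and extra decoys
  for (k in 1:4) {
    mol <- hdacfunnel:::.scaffoldMolecule(paste0("T", k), anionic = TRUE,
                             ortho = c("OMe", "OEt")[k %% 2 + 1],
                             tailLen = k %% 3, nitro = k == 3)
    feats <- perceiveFeatures(mol)
    picks <- feats[feats$kind %in% c("acceptor", "donor", "negative",
                                     "aromatic", "hydrophobic"), ]
    picks <- picks[!duplicated(picks$kind), ]
    picks <- head(picks, 6)
    hyp <- newHypothesis(picks[, c("kind", "x", "y", "z")],
                         tolerance = 1.5)
    # jitter the conformer so the fit is non-trivial
    jit <- mol
    conformers(jit) <- list(conformers(mol)[[1]] +
                              matrix(rnorm(nrow(mol@atoms) * 3, sd = 0.2),
                                     ncol = 3))
    got <- matchPharmacophore(jit, hyp)
    want <- oracleMatch(jit, hyp)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_false(is.null(got))
      expect_equal(got$fitRmsd, want, tolerance = 1e-9)
      # loose theoretical bound on an accepted fit
      expect_lte(got$fitRmsd,
                 max(hyp@features$tolerance) * sqrt(nrow(hyp@features)))
    }
  }
})

test_that("ties between equally good conformers go to the lower index", {
  pk <- fixturePocket()
  mol <- pk$template
  conformers(mol) <- list(conformers(pk$template)[[1]],
                          conformers(pk$template)[[1]])
  res <- matchPharmacophore(mol, pk$hypothesis)
  expect_identical(res$conformer, 1L)
  # maxConformers caps the search
  bad <- conformers(pk$template)[[1]]
  bad[5:10, 3] <- bad[5:10, 3] + 8
  mol2 <- pk$template
  conformers(mol2) <- list(bad, conformers(pk$template)[[1]])
  expect_null(matchPharmacophore(mol2, pk$hypothesis, maxConformers = 1L))
  expect_false(is.null(matchPharmacophore(mol2, pk$hypothesis)))
})

test_that("screening returns exactly the matchers; empty library is empty", {
  pk <- fixturePocket()
  gl <- genLibrary(librarySpec(n = 40, seed = 5), pk)
  eligible <- gl$truth$id[gl$truth$surv_ro5]
  res <- screenPharmacophore(gl$library[eligible], pk$hypothesis)
  expect_setequal(molIds(kept(res)),
                  gl$truth$id[gl$truth$pharmacophore_matcher])
  m <- attr(res, "matches")
  expect_identical(sort(m$id), sort(molIds(kept(res))))
  empty <- screenPharmacophore(moleculeLibrary(), pk$hypothesis)
  expect_length(kept(empty), 0)
  expect_error(matchPharmacophore(pk$template,
                                  newHypothesis(data.frame(
                                    kind = character(), x = numeric(),
                                    y = numeric(), z = numeric())[0, ])))
})

test_that("hypothesis YAML round trip is lossless", {
  pk <- fixturePocket()
  f <- tempfile(fileext = ".yaml")
  writeHypothesis(pk$hypothesis, f)
  back <- readHypothesis(f)
  expect_equal(back@features$x, pk$hypothesis@features$x, tolerance = 1e-9)
  expect_equal(back@volumes$z, pk$hypothesis@volumes$z, tolerance = 1e-9)
  expect_identical(back@requiredCount, pk$hypothesis@requiredCount)
  expect_identical(back@features$kind, pk$hypothesis@features$kind)
})
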