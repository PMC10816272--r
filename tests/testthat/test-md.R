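# Superposition, RMSD/RMSF, distance traces and interaction persistence.

test_that("superposition handles identity, translation and degeneracy", {
  set.seed(1)
  p <- matrix(rnorm(15, sd = 3), 5, 3)
  fit <- superpose(p, p)
  expect_lt(fit$rmsd, 1e-12)
  expect_equal(fit$R, diag(3), tolerance = 1e-9)
  fit2 <- superpose(p, sweep(p, 2, c(4, -2, 7), "+"))
  expect_lt(fit2$rmsd, 1e-12)
  expect_error(superpose(p[1:2, ], p[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(line, line), "collinear")
})

test_that("superposed RMSD matches the rotation-grid oracle to 0.01 A", {
  set.seed(23)
  p <- matrix(rnorm(15, sd = 2.5), 5, 3)   # asymmetric 5-point set
  rig <- randomRigid()
  q <- applyRigid(p, rig)
  # pure rotation+translation: both must find ~0
  expect_lt(superpose(p, q)$rmsd, 1e-9)
  # distorted copy: Kabsch optimum vs exhaustive 2-degree Euler grid
  qd <- q + matrix(rnorm(15, sd = 0.3), 5, 3)
  kab <- superpose(p, qd)$rmsd
  grid <- gridSuperposeRMSD(p, qd)
  expect_lte(kab, grid + 1e-12)   # Kabsch is the optimum
  expect_lt(abs(kab - grid), 0.01)
})

test_that("static trajectories give identically zero RMSD and RMSF", {
  pk <- fixturePocket()
  g <- genTrajectory(pk, trajectorySpec(nFrames = 6, sigma = 0,
                                        persistences = NULL, seed = 3))
  tr <- g$trajectory
  bb <- selectAtoms(tr, "protein_backbone")
  lig <- selectAtoms(tr, "ligand")
  expect_lt(max(rmsdSeries(tr, bb, lig)), 1e-9)
  expect_lt(max(rmsdSeries(tr, bb)), 1e-9)
  expect_lt(max(rmsf(tr, lig, bb)), 1e-9)
  expect_equal(rmsdSeries(tr, bb)[1], 0)
})

test_that("a rigid 2 A ligand displacement gives ligand RMSD of exactly 2", {
  pk <- fixturePocket()
  g <- genTrajectory(pk, trajectorySpec(nFrames = 5, sigma = 0,
                                        persistences = NULL,
                                        drift = c(0, 2, 2, 2, 2),
                                        seed = 1))
  tr <- g$trajectory
  bb <- selectAtoms(tr, "protein_backbone")
  lig <- selectAtoms(tr, "ligand")
  rs <- rmsdSeries(tr, bb, lig)
  expect_equal(rs, c(0, 2, 2, 2, 2), tolerance = 1e-9)
})

test_that("termini exclusion changes the RMSD only when termini move", {
  pk <- fixturePocket()
  g <- genTrajectory(pk, trajectorySpec(nFrames = 20, sigma = 0,
                                        persistences = NULL,
                                        terminiSigma = 1.0,
                                        jitterResno = c(1:14, 321:347),
                                        seed = 5))
  tr <- g$trajectory
  full <- selectAtoms(tr, "protein_backbone")
  core <- selectAtoms(tr, "protein_backbone",
                      excludeResno = c(1:14, 321:347))
  withTermini <- rmsdSeries(tr, full)
  withoutTermini <- rmsdSeries(tr, core)
  expect_gt(max(withTermini), 0.2)
  expect_lt(max(withoutTermini), 1e-9)
  expect_identical(length(core), length(full) - 14L - 27L)
})

test_that("RMSF of isotropic jitter converges to sqrt(3) sigma", {
  pk <- fixturePocket()
  g <- genTrajectory(pk, trajectorySpec(nFrames = 2000, sigma = 0.5,
                                        persistences = NULL, seed = 31))
  tr <- g$trajectory
  bb <- selectAtoms(tr, "protein_backbone")
  vals <- rmsf(tr, bb)
  expect_equal(mean(vals), sqrt(3) * 0.5, tolerance = 0.05)
})

test_that("jittering a single atom moves only that atom's RMSF", {
  pk <- fixturePocket()
  g <- genTrajectory(pk, trajectorySpec(nFrames = 50, sigma = 0,
                                        persistences = NULL, seed = 2))
  tr <- g$trajectory
  bb <- selectAtoms(tr, "protein_backbone")
  lig <- selectAtoms(tr, "ligand")
  target <- lig[5]
  set.seed(77)
  tr@frames <- lapply(tr@frames, function(fr) {
    fr[target, ] <- fr[target, ] + rnorm(3, sd = 0.4)
    fr
  })
  vals <- rmsf(tr, lig, bb)
  expect_gt(vals[5], 0.1)
  expect_lt(max(vals[-5]), 1e-9)
  expect_error(rmsf(newTrajectory(tr@topology, tr@frames[1]), lig),
               "at least two frames")
})

test_that("persistence is exact on planted frame masks", {
  pk <- fixturePocket()
  g <- genTrajectory(pk, trajectorySpec(
    nFrames = 1000, sigma = 0.25,
    persistences = c(salt_bridge_His142 = 1.0, hbond_His143 = 0.68),
    seed = 13))
  tr <- g$trajectory
  expect_equal(persistence(tr, g$specs$salt_bridge_His142), 1.0)
  expect_equal(persistence(tr, g$specs$hbond_His143), 0.680)
  expect_equal(g$truth$fractions[["hbond_His143"]], 0.680)
})

test_that("chelation distance traces recover the mock chelating pose", {
  pk <- fixturePocket()
  g <- genTrajectory(pk, trajectorySpec(nFrames = 50, sigma = 0,
                                        persistences = NULL, seed = 4))
  tr <- g$trajectory
  zn <- selectAtoms(tr, "zinc")
  oc <- g$truth$chelatorIndices[["carbonyl"]]
  spec <- interactionSpec("distance", a = oc, b = zn, distanceCutoff = 2.6)
  expect_equal(persistence(tr, spec), 1.0)
  d <- distanceSeries(tr, oc, zn)
  expect_equal(d, rep(2.41, 50), tolerance = 1e-6)
})

test_that("measures are invariant under a global rigid transform", {
  pk <- fixturePocket()
  g <- genTrajectory(pk, trajectorySpec(
    nFrames = 60, sigma = 0.3,
    persistences = c(hbond_His143 = 0.5), seed = 21))
  tr <- g$trajectory
  set.seed(12)
  rig <- randomRigid()
  tr2 <- tr
  tr2@frames <- lapply(tr@frames, applyRigid, rig = rig)
  bb <- selectAtoms(tr, "protein_backbone")
  lig <- selectAtoms(tr, "ligand")
  expect_equal(rmsdSeries(tr2, bb, lig), rmsdSeries(tr, bb, lig),
               tolerance = 1e-8)
  expect_equal(rmsf(tr2, lig, bb), rmsf(tr, lig, bb), tolerance = 1e-8)
  expect_equal(persistence(tr2, g$specs$hbond_His143),
               persistence(tr, g$specs$hbond_His143))
})

test_that("selectors and selections fail loudly when unresolvable", {
  pk <- fixturePocket()
  g <- genTrajectory(pk, trajectorySpec(nFrames = 3, sigma = 0,
                                        persistences = NULL, seed = 1))
  tr <- g$trajectory
  expect_error(selectAtoms(tr, "protein_backbone",
                           excludeResno = 1:1000), "zero atoms")
  expect_error(persistence(tr, interactionSpec("distance",
                                               a = list(name = "XX"),
                                               b = 1)),
               "resolves to 0")
  expect_error(rmsdSeries(tr, integer(), 1:3), "non-empty")
})

test_that("series and persistence tables are written as documented CSV", {
  f1 <- tempfile(fileext = ".csv")
  writeSeries(c(0.1, 0.2), f1)
  tab <- read.csv(f1)
  expect_identical(names(tab), c("frame", "value"))
  f2 <- tempfile(fileext = ".csv")
  writePersistence(c(salt_bridge = 0.99), f2)
  tab2 <- read.csv(f2)
  expect_identical(names(tab2), c("interaction", "fraction", "percent"))
  expect_equal(tab2$percent, 99)
})
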