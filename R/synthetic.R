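# Deterministic, labelled synthetic inputs: ligand libraries with planted
# stage-by-stage composition, a zinc pocket with a matching pharmacophore
# hypothesis, a mock docking backend driven by planted chelation classes,
# and trajectories realizing planted interaction persistences exactly.

roundHalfUp <- function(x) floor(x + 0.5)

# --- scaffold geometry -----------------------------------------------------
# All scaffolds live in one canonical frame: hydroxamate head near the
# origin, phenyl ring extending toward +x, plane z = 0.  Bond lengths are
# idealized; the graph (bond table), not the geometry, defines chemistry.

.ringCenter <- c(3.796, 0, 0)

# atoms 1..4: hydroxyl O, N, carbonyl C, carbonyl O; atoms 5..10: ring
.headCoords <- rbind(
  c(-1.120, -1.450, 0),   # O (hydroxyl / anionic)
  c( 0.225, -1.169, 0),   # N
  c( 0.900,  0.000, 0),   # C=O carbon
  c( 0.285,  1.065, 0))   # O (carbonyl)

.ringCoords <- t(vapply(c(180, 120, 60, 0, -60, -120), function(a) {
  .ringCenter + 1.396 * c(cos(a * pi / 180), sin(a * pi / 180), 0)
}, numeric(3)))

# Build one scaffold variant as atom/bond tables + coordinates.
# chemotype: "benzohydroxamate" or "benzamide" (the non-hydroxamate filler).
.buildScaffold <- function(chemotype = "benzohydroxamate", anionic = FALSE,
                           ortho = c("OMe", "OEt", "Cl", "none"),
                           tailLen = 0L, nitro = FALSE,
                           chloroTail = FALSE) {
  ortho <- match.arg(ortho)
  atoms <- data.frame(elem = character(), charge = integer(),
                      stringsAsFactors = FALSE)
  coords <- matrix(numeric(), 0, 3)
  bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  addAtom <- function(elem, xyz, charge = 0L) {
    atoms <<- rbind(atoms, data.frame(elem = elem, charge = charge))
    coords <<- rbind(coords, xyz)
    nrow(atoms)
  }
  addBond <- function(a, b, order = 1L) {
    bonds <<- rbind(bonds, data.frame(a1 = a, a2 = b, order = order))
  }
  if (chemotype == "benzohydroxamate") {
    iOh <- addAtom("O", .headCoords[1, ], if (anionic) -1L else 0L)
    iN  <- addAtom("N", .headCoords[2, ])
    iC  <- addAtom("C", .headCoords[3, ])
    iOc <- addAtom("O", .headCoords[4, ])
    addBond(iOh, iN); addBond(iN, iC); addBond(iC, iOc, 2L)
  } else {
    iN  <- addAtom("N", .headCoords[2, ])
    iC  <- addAtom("C", .headCoords[3, ])
    iOc <- addAtom("O", .headCoords[4, ])
    addBond(iN, iC); addBond(iC, iOc, 2L)
    iOh <- NA_integer_
  }
  ringIdx <- integer(6)
  for (k in 1:6) ringIdx[k] <- addAtom("C", .ringCoords[k, ])
  ringOrders <- c(2L, 1L, 2L, 1L, 2L, 1L)
  for (k in 1:6) addBond(ringIdx[k], ringIdx[k %% 6 + 1], ringOrders[k])
  addBond(iC, ringIdx[1])
  radial <- function(k) {
    v <- .ringCoords[k, ] - .ringCenter
    v / sqrt(sum(v^2))
  }
  if (ortho != "none") {
    # ortho substituent on the ring carbon adjacent to the hydroxamate
    base <- .ringCoords[2, ]
    dir <- radial(2)
    if (ortho == "Cl") {
      iCl <- addAtom("Cl", base + 1.74 * dir)
      addBond(ringIdx[2], iCl)
    } else {
      iO <- addAtom("O", base + 1.36 * dir)
      addBond(ringIdx[2], iO)
      iMe <- addAtom("C", base + 1.36 * dir + c(0, 1.43, 0))
      addBond(iO, iMe)
      if (ortho == "OEt") {
        iEt <- addAtom("C", base + 1.36 * dir + c(0.72, 2.70, 0))
        addBond(iMe, iEt)
      }
    }
  }
  if (tailLen > 0L) {
    # aliphatic capping tail in para position, along +x
    prev <- ringIdx[4]
    for (k in seq_len(tailLen)) {
      iT <- addAtom("C", .ringCoords[4, ] +
                      c(1.45 * k, 0.35 * (k %% 2), 0))
      addBond(prev, iT)
      prev <- iT
      if (chloroTail) {
        i1 <- addAtom("Cl", coords[iT, ] + c(0, 1.0, 1.35))
        i2 <- addAtom("Cl", coords[iT, ] + c(0, -1.0, 1.35))
        addBond(iT, i1); addBond(iT, i2)
      }
    }
  }
  if (nitro) {
    base <- .ringCoords[5, ]
    dir <- radial(5)
    iNn <- addAtom("N", base + 1.40 * dir, +1L)
    iO1 <- addAtom("O", base + 1.40 * dir + c(1.14, -0.33, 0))
    iO2 <- addAtom("O", base + 1.40 * dir + c(-0.67, -0.93, 0), -1L)
    addBond(ringIdx[5], iNn); addBond(iNn, iO1, 2L); addBond(iNn, iO2, 1L)
  }
  list(atoms = atoms, bonds = bonds, coords = coords,
       head = c(Oh = if (chemotype == "benzohydroxamate") iOh else NA,
                N = iN, C = iC, Oc = iOc),
       ring = ringIdx)
}

.scaffoldMolecule <- function(id, ..., stateTag = "other", labels = list()) {
  sc <- .buildScaffold(...)
  mb <- writeMolBlock(sc$atoms, sc$bonds, sc$coords, title = id)
  mol <- moleculeFromMolBlock(mb, id = id, stateTag = stateTag,
                              labels = labels)
  attr(mol, "scaffold") <- sc
  mol
}

# --- pocket ---------------------------------------------------------------

# Zinc position in the scaffold frame: the in-plane point at the printed
# hit-pose chelation distances (2.41 A to the carbonyl O, 2.17 A to the
# hydroxyl O), on the solvent side away from the ring.
.solveZinc <- function(oc, oh, r1 = 2.41, r2 = 2.17) {
  v <- oh[1:2] - oc[1:2]
  d <- sqrt(sum(v^2))
  a <- (r1^2 - r2^2 + d^2) / (2 * d)
  h <- sqrt(r1^2 - a^2)
  base <- oc[1:2] + a * v / d
  perp <- c(v[2], -v[1]) / d
  cand1 <- c(base + h * perp, 0)
  cand2 <- c(base - h * perp, 0)
  if (cand1[1] < cand2[1]) cand1 else cand2   # the -x (solvent) solution
}

#' Generate a synthetic zinc pocket with its pharmacophore hypothesis
#'
#' Builds a template anionic benzohydroxamate pose in a canonical frame,
#' places the catalytic zinc at the classic bidentate geometry (2.41 /
#' 2.17 Angstrom to the carbonyl and hydroxyl oxygens), surrounds the
#' ligand head with pseudo-protein shell atoms (which become the excluded
#' volumes) plus two histidine-like interaction partners, and derives the
#' four-feature hypothesis (acceptor, donor, negative, aromatic) from the
#' template pose with [buildHypothesis()].
#'
#' @param seed integer seed (reserved; the pocket itself is deterministic).
#' @param isoform receptor label.
#' @param shellDistance,tolerance,volumeRadius hypothesis construction
#'   parameters (see [buildHypothesis()]).
#' @return list with `receptor` ([ReceptorContext-class]), `hypothesis`
#'   ([PharmacophoreHypothesis-class]), `template` ([Molecule-class] whose
#'   conformer 1 is the pose), and `zinc` (the planted coordinate).
#' @export
genPocket <- function(seed = 1L, isoform = "HDAC11", shellDistance = 5.0,
                      tolerance = 1.5, volumeRadius = 1.2) {
  template <- .scaffoldMolecule("template", anionic = TRUE, ortho = "OMe",
                                tailLen = 1L,
                                stateTag = "hydroxamate_anion")
  sc <- attr(template, "scaffold")
  zinc <- .solveZinc(sc$coords[sc$head[["Oc"]], ],
                     sc$coords[sc$head[["Oh"]], ])
  shellXY <- rbind(c(0, 0), c(2, 1), c(-1, 1), c(3, -1), c(1, -2),
                   c(4, 1.5))
  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(shellXY))) for (zs in c(3.5, -3.5)) {
    k <- k + 1L
    rows[[k]] <- data.frame(elety = "CA", resid = "GLY", chain = "A",
                            resno = k, elem = "C",
                            x = shellXY[i, 1], y = shellXY[i, 2], z = zs,
                            stringsAsFactors = FALSE)
  }
  oh <- sc$coords[sc$head[["Oh"]], ]
  oc <- sc$coords[sc$head[["Oc"]], ]
  his <- rbind(
    data.frame(elety = "NE2", resid = "HIS", chain = "A", resno = 142,
               elem = "N", x = oh[1], y = oh[2], z = oh[3] - 3.3),
    data.frame(elety = "NE2", resid = "HIS", chain = "A", resno = 143,
               elem = "N", x = oc[1], y = oc[2], z = oc[3] + 3.0),
    data.frame(elety = "HE2", resid = "HIS", chain = "A", resno = 143,
               elem = "H", x = oc[1], y = oc[2], z = oc[3] + 1.9))
  atoms <- rbind(do.call(rbind, rows), his)
  receptor <- new("ReceptorContext", isoform = isoform, atoms = atoms,
                  zinc = zinc)
  hypothesis <- buildHypothesis(template, receptor,
                                picks = c("acceptor", "donor", "negative",
                                          "aromatic"),
                                shellDistance = shellDistance,
                                tolerance = tolerance,
                                volumeRadius = volumeRadius)
  # construction self-checks: the planted pose must be bidentate and must
  # match its own hypothesis
  pose <- new("DockedPose", ligandId = "template", molecule = template,
              coords = template@conformers[[1]],
              chelatorPair = unname(sc$head[c("Oc", "Oh")]),
              receptor = isoform)
  stopifnot(chelationClass(assessChelation(pose, receptor)) == "bidentate",
            nrow(hypothesis@features) == 4L,
            !is.null(matchPharmacophore(template, hypothesis)))
  list(receptor = receptor, hypothesis = hypothesis, template = template,
       zinc = zinc)
}

#' Write a receptor (with its zinc) as a PDB file
#' @param receptor a [ReceptorContext-class].
#' @param path output PDB.
#' @return `path`, invisibly.
#' @export
writeReceptorPDB <- function(receptor, path) {
  at <- receptor@atoms
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(at)),
    ifelse(nchar(at$elety) < 4, paste0(" ", at$elety), at$elety),
    at$resid, ifelse(is.na(at$chain), "A", at$chain), at$resno,
    at$x, at$y, at$z, at$elem)
  zn <- sprintf(
    "HETATM%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    nrow(at) + 1L, " ZN", "ZN", "A", 999L,
    receptor@zinc[1], receptor@zinc[2], receptor@zinc[3], "ZN")
  writeLines(c(lines, zn, "END"), path)
  invisible(path)
}

# --- library --------------------------------------------------------------

#' Specification for a synthetic ligand library
#'
#' Planted subset sizes are `roundHalfUp(n * fraction)`, so tests can
#' assert exact counts.  The subsets nest the way the funnel consumes
#' them: anionic ligands are benzohydroxamates; rule-of-five violators are
#' anionic (so they reach, and fail, the property filter); pharmacophore
#' matchers are anionic non-violators; alert bearers are comparative
#' survivors.
#'
#' @param n library size.
#' @param fractions named numeric vector with entries `benzohydroxamate`,
#'   `anionic`, `ro5_violator`, `pharmacophore_matcher`, `alert_bearer`
#'   (all relative to `n`).
#' @param targetChelation chelation-class distribution of the matchers in
#'   the target pocket (`bidentate`, `monodentate`, `none`).
#' @param antitargetChelation named list (one entry per anti-target) of
#'   distributions over `bidentate`, `monodentate`, `none`, `absent`
#'   (fractions of the target-bidentate set; `absent` = docking fails
#'   there).
#' @param seed integer seed.
#' @return a `librarySpec` list.
#' @export
librarySpec <- function(n = 200L,
                        fractions = c(benzohydroxamate = 0.70,
                                      anionic = 0.50,
                                      ro5_violator = 0.10,
                                      pharmacophore_matcher = 0.25,
                                      alert_bearer = 0.02),
                        targetChelation = c(bidentate = 0.70,
                                            monodentate = 0.10,
                                            none = 0.20),
                        antitargetChelation = list(
                          HDAC1 = c(bidentate = 0.10, monodentate = 0.10,
                                    none = 0.60, absent = 0.20),
                          HDAC6 = c(bidentate = 0.05, monodentate = 0.15,
                                    none = 0.70, absent = 0.10),
                          HDAC8 = c(bidentate = 0.10, monodentate = 0.10,
                                    none = 0.75, absent = 0.05)),
                        seed = 1L) {
  if (any(fractions < 0 | fractions > 1))
    stop("fractions must lie in [0, 1]")
  need <- c("benzohydroxamate", "anionic", "ro5_violator",
            "pharmacophore_matcher", "alert_bearer")
  if (!all(need %in% names(fractions)))
    stop("fractions must name: ", paste(need, collapse = ", "))
  if (abs(sum(targetChelation) - 1) > 1e-9)
    stop("targetChelation must sum to 1")
  for (nm in names(antitargetChelation)) {
    if (abs(sum(antitargetChelation[[nm]]) - 1) > 1e-9)
      stop("antitargetChelation[['", nm, "']] must sum to 1")
  }
  structure(list(n = as.integer(n), fractions = fractions,
                 targetChelation = targetChelation,
                 antitargetChelation = antitargetChelation,
                 seed = as.integer(seed)),
            class = "librarySpec")
}

# distribute n items over classes by round-half-up, remainder to the
# largest class
.allocCounts <- function(n, fracs) {
  k <- roundHalfUp(n * fracs)
  diff <- n - sum(k)
  k[which.max(k)] <- k[which.max(k)] + diff
  if (any(k < 0)) stop("infeasible class distribution")
  k
}

#' Generate a labelled synthetic ligand library
#'
#' Molecules are ortho-substituted benzohydroxamate scaffolds (methoxy /
#' ethoxy / chloro, mirroring selective-hit chemotypes) with varying
#' aliphatic capping tails; planted negatives are benzamides (no
#' hydroxamate), neutral-state hydroxamic acids, perchlorinated-tail
#' rule-of-five violators and nitro-bearing alert compounds.  Matcher
#' conformers are constructed in the pocket frame of `pocket`; eligible
#' non-matchers have their ring block displaced out of the pharmacophore
#' geometry.  Every planted label is verified against the corresponding
#' filter at generation time.
#'
#' @param spec a [librarySpec()].
#' @param pocket a [genPocket()] result (supplies the frame, hypothesis
#'   and template geometry).
#' @return list with `library` ([MoleculeLibrary-class]), `truth`
#'   (data.frame of per-ligand ground-truth labels, per-receptor chelation
#'   classes, synthetic binding scores and expected per-stage survival),
#'   and `scores` (named vector for [rankHits()]).
#' @export
genLibrary <- function(spec = librarySpec(), pocket = genPocket()) {
  stopifnot(inherits(spec, "librarySpec"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(spec$seed)
  n <- spec$n
  fr <- spec$fractions
  nB <- roundHalfUp(n * fr[["benzohydroxamate"]])
  nA <- roundHalfUp(n * fr[["anionic"]])
  nV <- roundHalfUp(n * fr[["ro5_violator"]])
  nM <- roundHalfUp(n * fr[["pharmacophore_matcher"]])
  nAl <- roundHalfUp(n * fr[["alert_bearer"]])
  if (nA > nB) stop("anionic fraction cannot exceed benzohydroxamate fraction")
  if (nV > nA) stop("violator fraction cannot exceed anionic fraction")
  if (nM > nA - nV)
    stop("matcher fraction cannot exceed eligible (anionic non-violator) fraction")

  ids <- sprintf("L%03d", seq_len(n))
  truth <- data.frame(id = ids,
                      benzohydroxamate = seq_len(n) <= nB,
                      anionic = seq_len(n) <= nA,
                      ro5_violator = FALSE,
                      pharmacophore_matcher = FALSE,
                      stringsAsFactors = FALSE)
  # violators occupy the tail of the anionic block; matchers the head
  if (nV > 0) truth$ro5_violator[(nA - nV + 1L):nA] <- TRUE
  truth$pharmacophore_matcher[seq_len(n) <= nM] <- TRUE

  # chelation classes of the matchers in the target pocket
  truth$cls_target <- NA_character_
  mIdx <- which(truth$pharmacophore_matcher)
  kT <- .allocCounts(nM, spec$targetChelation)
  truth$cls_target[mIdx] <- rep(names(kT), kT)
  tbIdx <- which(!is.na(truth$cls_target) & truth$cls_target == "bidentate")
  nTB <- length(tbIdx)

  removed <- rep(FALSE, n)
  for (ri in seq_along(spec$antitargetChelation)) {
    rec <- names(spec$antitargetChelation)[ri]
    col <- paste0("cls_", rec)
    truth[[col]] <- NA_character_
    kA <- .allocCounts(nTB, spec$antitargetChelation[[rec]])
    # rotate the assignment per receptor so removal sets overlap partially
    ord <- tbIdx[(seq_len(nTB) + 7L * ri - 1L) %% nTB + 1L]
    cls <- rep(names(kA), kA)
    truth[[col]][ord] <- cls
    rule <- if (rec == "HDAC6") c("bidentate", "monodentate") else "bidentate"
    removed[ord[cls %in% rule]] <- TRUE
    truth[[col]][truth[[col]] == "absent"] <- NA_character_
  }
  compSurv <- intersect(tbIdx, which(!removed))
  if (nAl > length(compSurv))
    stop("alert_bearer fraction infeasible: only ", length(compSurv),
         " comparative survivors for ", nAl, " planted alert bearers")
  truth$alert_bearer <- FALSE
  truth$alert_bearer[compSurv[seq_len(nAl)]] <- TRUE

  truth$score <- round(-stats::runif(n, 5, 9), 3)

  # --- build the molecules -------------------------------------------------
  orthoPool <- c("OMe", "OEt", "Cl")
  hyp <- pocket$hypothesis
  templateSc <- attr(pocket$template, "scaffold")
  mols <- vector("list", n)
  for (i in seq_len(n)) {
    ortho <- orthoPool[(i - 1L) %% 3L + 1L]
    tail <- (i - 1L) %% 4L
    if (!truth$benzohydroxamate[i]) {
      mol <- .scaffoldMolecule(ids[i], chemotype = "benzamide",
                               ortho = ortho, tailLen = tail)
    } else if (truth$ro5_violator[i]) {
      mol <- .scaffoldMolecule(ids[i], anionic = TRUE, ortho = ortho,
                               tailLen = 6L, chloroTail = TRUE,
                               stateTag = "hydroxamate_anion")
    } else {
      mol <- .scaffoldMolecule(ids[i], anionic = truth$anionic[i],
                               ortho = ortho, tailLen = tail,
                               nitro = truth$alert_bearer[i],
                               stateTag = if (truth$anionic[i])
                                 "hydroxamate_anion" else "neutral")
    }
    if (truth$anionic[i] && !truth$ro5_violator[i] &&
        !truth$pharmacophore_matcher[i]) {
      # eligible non-matcher: displace the ring block (everything beyond
      # the hydroxamate head) out of the pharmacophore geometry
      sc <- attr(mol, "scaffold")
      conf <- mol@conformers[[1]]
      conf[-seq_len(4L), 3] <- conf[-seq_len(4L), 3] + 8.0
      mol@conformers <- list(conf)
    }
    mol@labels <- as.list(truth[i, -1])
    mols[[i]] <- mol
  }
  lib <- moleculeLibrary(mols)

  # --- generation-time self-checks ----------------------------------------
  smi <- smilesOf(lib)
  stopifnot(identical(obCountSmarts(smi, benzohydroxamateSmarts()) > 0,
                      truth$benzohydroxamate))
  stopifnot(identical(obCountSmarts(smi, hydroxamateAnionSmarts()) > 0,
                      truth$anionic))
  props <- computeProperties(lib)
  stopifnot(identical(truth$anionic & props$violations == 0L,
                      truth$anionic & !truth$ro5_violator))
  eligible <- which(truth$anionic & !truth$ro5_violator)
  matched <- vapply(eligible, function(i) {
    !is.null(matchPharmacophore(lib[[i]], hyp))
  }, logical(1))
  stopifnot(identical(matched, truth$pharmacophore_matcher[eligible]))
  nitroHits <- obCountSmarts(smi, "[N+](=O)[O-]") > 0
  stopifnot(identical(nitroHits, truth$alert_bearer))

  # expected stage-by-stage survival
  truth$surv_substructure <- truth$benzohydroxamate
  truth$surv_state <- truth$anionic
  truth$surv_ro5 <- truth$anionic & !truth$ro5_violator
  truth$surv_pharmacophore <- truth$pharmacophore_matcher
  truth$surv_docking <- truth$surv_pharmacophore & !is.na(truth$cls_target)
  truth$surv_pose <- truth$surv_docking &
    !is.na(truth$cls_target) & truth$cls_target == "bidentate"
  truth$surv_comparative <- seq_len(n) %in% compSurv
  truth$surv_alerts <- truth$surv_comparative & !truth$alert_bearer

  list(library = lib, truth = truth,
       scores = stats::setNames(truth$score, truth$id))
}

#' Docking backend driven by planted chelation classes
#'
#' Returns a backend function for [runFunnel()] that looks up the
#' ground-truth chelation class of (ligand, receptor) in the truth table
#' and realizes it geometrically with [mockDock()]; an `NA` class means
#' docking fails there (`NULL`).  Deterministic: the per-pose seed is
#' derived from `seed`, the ligand id and the receptor label.
#'
#' @param truth truth table from [genLibrary()].
#' @param target the target receptor label (its classes are stored in
#'   column `cls_target`).
#' @param seed integer base seed.
#' @return `function(molecule, receptor) -> DockedPose or NULL`.
#' @export
syntheticBackend <- function(truth, target = "HDAC11", seed = 1L) {
  force(truth); force(target); force(seed)
  function(mol, receptor) {
    col <- if (receptor@isoform == target) "cls_target" else
      paste0("cls_", receptor@isoform)
    if (!col %in% names(truth))
      stop("no planted chelation classes for receptor ", receptor@isoform)
    cls <- truth[[col]][truth$id == mol@id]
    if (!length(cls) || is.na(cls)) return(NULL)
    mode <- c(bidentate = "chelating", monodentate = "monodentate",
              none = "nonbinding")[[cls]]
    poseSeed <- (seed * 1000L +
                   sum(utf8ToInt(paste0(mol@id, receptor@isoform)))) %%
      .Machine$integer.max
    mockDock(mol, receptor, mode = mode, seed = poseSeed)
  }
}

# --- trajectories ---------------------------------------------------------

#' Specification for a synthetic trajectory
#'
#' @param nFrames number of frames.
#' @param sigma per-axis Gaussian positional jitter (Angstrom) applied to
#'   every atom except interaction participants (whose geometry realizes
#'   the planted masks exactly).
#' @param persistences named numeric vector of planted persistence
#'   fractions; supported interactions: `salt_bridge_His142` (ligand
#'   hydroxyl O to His142 NE2) and `hbond_His143` (His143 NE2-HE2 donor to
#'   the ligand carbonyl O).  `NULL` plants no interactions.
#' @param drift per-frame rigid +x displacement of the ligand (scalar or
#'   vector of length `nFrames`).
#' @param terminiSigma extra jitter applied to residues in `jitterResno`
#'   (models flexible termini).
#' @param jitterResno residue numbers receiving `terminiSigma`.
#' @param dt frame spacing in ns.
#' @param seed integer seed.
#' @return a `trajectorySpec` list.
#' @export
trajectorySpec <- function(nFrames = 1000L, sigma = 0.1,
                           persistences = c(salt_bridge_His142 = 1.0,
                                            hbond_His143 = 0.68),
                           drift = 0, terminiSigma = 0,
                           jitterResno = NULL, dt = 0.1, seed = 1L) {
  if (!is.null(persistences)) {
    bad <- setdiff(names(persistences),
                   c("salt_bridge_His142", "hbond_His143"))
    if (length(bad))
      stop("unsupported planted interaction(s): ",
           paste(bad, collapse = ", "))
    if (any(persistences < 0 | persistences > 1))
      stop("persistences must lie in [0, 1]")
  }
  structure(list(nFrames = as.integer(nFrames), sigma = sigma,
                 persistences = persistences, drift = drift,
                 terminiSigma = terminiSigma, jitterResno = jitterResno,
                 dt = dt, seed = as.integer(seed)),
            class = "trajectorySpec")
}

#' Generate a synthetic trajectory with planted ground truth
#'
#' The topology combines a 347-residue pseudo-protein backbone (C-alpha
#' trace on a helix, away from the pocket), the pocket's His142/His143
#' interaction partners, the catalytic zinc and the template ligand pose.
#' Planted interaction persistences are realized exactly as frame masks
#' by geometric construction (participant atoms are placed inside the
#' criteria in masked frames and well outside otherwise, and are exempt
#' from jitter); positional noise and ligand drift are applied on top.
#' Bit-identical for identical seeds.
#'
#' @param pocket a [genPocket()] result.
#' @param spec a [trajectorySpec()].
#' @return list with `trajectory` ([Trajectory-class]), `truth` (planted
#'   masks and realized fractions) and `specs` (named list of
#'   [interactionSpec()] objects resolving to the planted atoms).
#' @export
genTrajectory <- function(pocket = genPocket(), spec = trajectorySpec()) {
  stopifnot(inherits(spec, "trajectorySpec"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(spec$seed)
  template <- pocket$template
  sc <- attr(template, "scaffold")
  ligCoords <- template@conformers[[1]]
  nLig <- nrow(ligCoords)

  # pseudo-protein C-alpha helix, residues 1..347, displaced from the pocket
  resno <- seq_len(347L)
  helix <- cbind(30 + 2.3 * cos(resno * 100 * pi / 180),
                 2.3 * sin(resno * 100 * pi / 180),
                 1.5 * resno * 0.5)
  topProt <- data.frame(name = "CA", resid = "ALA", resno = resno,
                        elem = "C", role = "protein_backbone",
                        stringsAsFactors = FALSE)
  his <- pocket$receptor@atoms
  his <- his[his$resid == "HIS", ]
  topHis <- data.frame(name = his$elety, resid = "HIS", resno = his$resno,
                       elem = his$elem, role = "protein",
                       stringsAsFactors = FALSE)
  hisCoords <- as.matrix(his[, c("x", "y", "z")])
  topZn <- data.frame(name = "ZN", resid = "ZN", resno = 400L,
                      elem = "ZN", role = "zinc", stringsAsFactors = FALSE)
  topLig <- data.frame(name = paste0(template@atoms$elem, seq_len(nLig)),
                       resid = "LIG", resno = 401L,
                       elem = template@atoms$elem, role = "ligand",
                       stringsAsFactors = FALSE)
  topology <- rbind(topProt, topHis, topZn, topLig)
  base <- rbind(helix, hisCoords, matrix(pocket$zinc, 1), ligCoords)
  nAtoms <- nrow(base)
  ligIdx <- nrow(helix) + nrow(hisCoords) + 1L + seq_len(nLig)

  idxOf <- function(name, resno) {
    which(topology$name == name & topology$resno == resno)
  }
  iOh <- ligIdx[sc$head[["Oh"]]]
  iOc <- ligIdx[sc$head[["Oc"]]]
  iNe142 <- idxOf("NE2", 142L)
  iNe143 <- idxOf("NE2", 143L)
  iHe143 <- idxOf("HE2", 143L)

  interDefs <- list(
    salt_bridge_His142 = list(
      participants = c(iOh, iNe142),
      spec = interactionSpec("salt_bridge", a = iOh, b = iNe142),
      violate = function(X) {
        dir <- X[iNe142, ] - X[iOh, ]
        dir <- dir / sqrt(sum(dir^2))
        X[iNe142, ] <- X[iOh, ] + 5.5 * dir
        X
      }),
    hbond_His143 = list(
      participants = c(iOc, iNe143, iHe143),
      spec = interactionSpec("hbond", donor = iNe143, hydrogen = iHe143,
                             acceptor = iOc),
      violate = function(X) {
        dir <- X[iNe143, ] - X[iOc, ]
        dir <- dir / sqrt(sum(dir^2))
        X[iHe143, ] <- X[iOc, ] + 4.2 * dir
        X[iNe143, ] <- X[iOc, ] + 5.3 * dir
        X
      })
  )
  active <- interDefs[names(spec$persistences)]
  participants <- unique(unlist(lapply(active, `[[`, "participants")))
  masks <- lapply(names(active), function(nm) {
    k <- roundHalfUp(spec$persistences[[nm]] * spec$nFrames)
    m <- rep(FALSE, spec$nFrames)
    m[sample(spec$nFrames, k)] <- TRUE
    m
  })
  names(masks) <- names(active)

  drift <- rep_len(spec$drift, spec$nFrames)
  ligDriftIdx <- setdiff(ligIdx, participants)

  frames <- vector("list", spec$nFrames)
  for (f in seq_len(spec$nFrames)) {
    X <- base
    if (spec$sigma > 0) {
      noise <- matrix(stats::rnorm(nAtoms * 3, sd = spec$sigma), nAtoms, 3)
      noise[participants, ] <- 0
      X <- X + noise
    }
    if (spec$terminiSigma > 0 && length(spec$jitterResno)) {
      hit <- which(topology$resno %in% spec$jitterResno &
                     topology$role %in% c("protein", "protein_backbone"))
      hit <- setdiff(hit, participants)
      X[hit, ] <- X[hit, ] +
        matrix(stats::rnorm(length(hit) * 3, sd = spec$terminiSigma),
               length(hit), 3)
    }
    if (drift[f] != 0)
      X[ligDriftIdx, 1] <- X[ligDriftIdx, 1] + drift[f]
    for (nm in names(active)) {
      if (!masks[[nm]][f]) X <- active[[nm]]$violate(X)
    }
    frames[[f]] <- X
  }
  traj <- newTrajectory(topology, frames, dt = spec$dt)
  truth <- list(masks = masks,
                fractions = vapply(masks, mean, numeric(1)),
                sigma = spec$sigma, drift = drift,
                participants = participants,
                ligandIndices = ligIdx,
                chelatorIndices = c(carbonyl = iOc, hydroxyl = iOh))
  list(trajectory = traj, truth = truth,
       specs = lapply(active, `[[`, "spec"))
}
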