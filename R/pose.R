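# Receptor loading, hydroxamate chelator identification, zinc-chelation
# classification, and the docking-backend contract with a mock backend.

#' Load a receptor PDB and resolve its catalytic zinc
#'
#' @param path PDB file.
#' @param isoform receptor label (e.g. `"HDAC11"`).
#' @param zincSelector optional list narrowing the zinc choice by `chain`
#'   and/or `resno`; by default every atom with element ZN is a candidate.
#' @return a [ReceptorContext-class].  Zero or multiple matching zincs is
#'   an error listing the candidates.
#' @export
loadReceptor <- function(path, isoform = "receptor", zincSelector = list()) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  atoms <- data.frame(elety = at$elety, resid = at$resid, chain = at$chain,
                      resno = at$resno, elem = at$elesy,
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  zn <- atoms$elem == "ZN" | atoms$resid == "ZN"
  if (!is.null(zincSelector$chain))
    zn <- zn & atoms$chain %in% zincSelector$chain
  if (!is.null(zincSelector$resno))
    zn <- zn & atoms$resno %in% zincSelector$resno
  hits <- which(zn)
  if (length(hits) != 1L) {
    desc <- if (length(hits)) {
      paste(sprintf("chain %s resno %d", atoms$chain[hits],
                    atoms$resno[hits]), collapse = "; ")
    } else "none"
    stop("expected exactly one catalytic zinc, found ", length(hits),
         " (candidates: ", desc, ")")
  }
  zinc <- c(atoms$x[hits], atoms$y[hits], atoms$z[hits])
  new("ReceptorContext", isoform = isoform, atoms = atoms[-hits, ],
      zinc = zinc)
}

#' Identify the hydroxamate chelator oxygen pair
#'
#' Locates the `O=C-N(H)-O(-)` motif on the molecular graph and returns
#' the (carbonyl O, hydroxyl/anionic O) atom indices.  With several
#' hydroxamate embeddings and a receptor supplied, the embedding whose
#' oxygen midpoint (conformer coordinates) lies nearest the zinc is
#' chosen; without a receptor the first embedding wins.
#'
#' @param mol a [Molecule-class] matching the hydroxamate pattern.
#' @param receptor optional [ReceptorContext-class] used to disambiguate.
#' @param conformer conformer index used for the distance tie-break.
#' @return integer length-2: (carbonyl O index, hydroxyl O index).
#' @export
identifyChelators <- function(mol, receptor = NULL, conformer = 1L) {
  atoms <- mol@atoms
  bonds <- mol@bonds
  nb <- bondNeighbors(bonds, nrow(atoms))
  embeddings <- list()
  for (i in seq_len(nrow(atoms))) {
    if (atoms$elem[i] != "N") next
    nbi <- nb[[i]]
    if (is.null(nbi)) next
    hasH <- vapply(nbi[, 1], function(j) {
      js <- if (is.null(nb[[j]])) integer() else nb[[j]][, 1]
      atoms$nH[j] >= 1 || any(atoms$elem[js] == "H")
    }, logical(1))
    oh <- nbi[atoms$elem[nbi[, 1]] == "O" & nbi[, 2] == 1 &
              (atoms$charge[nbi[, 1]] < 0 | hasH), 1]
    cs <- nbi[atoms$elem[nbi[, 1]] == "C", 1]
    for (cc in cs) {
      nbc <- nb[[cc]]
      oc <- nbc[atoms$elem[nbc[, 1]] == "O" & nbc[, 2] == 2, 1]
      for (o1 in oc) for (o2 in oh) {
        embeddings[[length(embeddings) + 1L]] <- c(o1, o2)
      }
    }
  }
  if (!length(embeddings))
    stop("molecule '", mol@id, "' contains no hydroxamate moiety")
  if (length(embeddings) > 1L && !is.null(receptor) &&
      length(mol@conformers) >= conformer) {
    coords <- mol@conformers[[conformer]]
    dmid <- vapply(embeddings, function(p) {
      mid <- colMeans(coords[p, , drop = FALSE])
      sqrt(sum((mid - receptor@zinc)^2))
    }, numeric(1))
    embeddings <- embeddings[order(dmid)]
  }
  as.integer(embeddings[[1]])
}

#' Classify chelation geometry from the two chelator-zinc distances
#'
#' `bidentate` iff both distances are within the cutoff, `monodentate`
#' iff exactly one, `none` otherwise.  The boundary is inclusive: a
#' distance exactly equal to the cutoff passes (poses are removed only
#' when a distance exceeds the cutoff).
#'
#' @param dCarbonyl carbonyl-oxygen to zinc distance (Angstrom).
#' @param dHydroxyl hydroxyl-oxygen to zinc distance (Angstrom).
#' @param cutoff contact cutoff (Angstrom, default 2.6).
#' @return a [ChelationAssessment-class].
#' @examples
#' chelationClass(classifyChelation(2.41, 2.17))  # "bidentate"
#' @export
classifyChelation <- function(dCarbonyl, dHydroxyl, cutoff = 2.6) {
  stopifnot(dCarbonyl >= 0, dHydroxyl >= 0, cutoff > 0)
  nIn <- sum(c(dCarbonyl, dHydroxyl) <= cutoff)
  cls <- c("none", "monodentate", "bidentate")[nIn + 1L]
  new("ChelationAssessment", dCarbonyl = dCarbonyl, dHydroxyl = dHydroxyl,
      cls = cls, cutoff = cutoff)
}

#' Assess the zinc chelation geometry of a docked pose
#'
#' Euclidean distances from the pose's chelator oxygens to the receptor's
#' catalytic zinc, classified with [classifyChelation()].
#'
#' @param pose a [DockedPose-class].
#' @param receptor a [ReceptorContext-class] in the same frame.
#' @param cutoff contact cutoff (Angstrom, default 2.6).
#' @return a [ChelationAssessment-class].
#' @export
assessChelation <- function(pose, receptor, cutoff = 2.6) {
  p <- pose@chelatorPair
  d1 <- sqrt(sum((pose@coords[p[1], ] - receptor@zinc)^2))
  d2 <- sqrt(sum((pose@coords[p[2], ] - receptor@zinc)^2))
  classifyChelation(d1, d2, cutoff)
}

#' @describeIn chelationClass chelation class string of an assessment.
#' @export
setMethod("chelationClass", "ChelationAssessment", function(x) x@cls)

setMethod("show", "ChelationAssessment", function(object) {
  cat(sprintf(
    "ChelationAssessment: %s (d_carbonyl = %.2f A, d_hydroxyl = %.2f A, cutoff %.2f A)\n",
    object@cls, object@dCarbonyl, object@dHydroxyl, object@cutoff))
})

#' Deterministic mock docking backend
#'
#' Stands in for a real docking engine behind the backend contract
#' (`function(molecule, receptor) -> DockedPose`).  The requested
#' chelation mode is realized geometrically: `chelating` places both
#' hydroxamate oxygens 2.0-2.3 Angstrom from the zinc, `monodentate`
#' exactly one, `nonbinding` both beyond 4 Angstrom.  The remaining atoms
#' follow rigidly, with the spin about the oxygen-oxygen axis chosen from
#' a seeded candidate set to maximize clearance from protein atoms; a
#' small seeded jitter (0.05 Angstrom) is applied to non-chelator atoms.
#' Identical seeds give bit-identical coordinates.
#'
#' @param mol a [Molecule-class] with a hydroxamate and at least one
#'   conformer.
#' @param receptor a [ReceptorContext-class].
#' @param mode `"chelating"`, `"monodentate"` or `"nonbinding"`.
#' @param seed integer seed.
#' @return a [DockedPose-class] with a synthetic backend score.
#' @export
mockDock <- function(mol, receptor,
                     mode = c("chelating", "monodentate", "nonbinding"),
                     seed = 1L) {
  mode <- match.arg(mode)
  if (!length(mol@conformers))
    stop("molecule '", mol@id, "' has no conformer to dock")
  pair <- identifyChelators(mol, receptor)
  coords <- mol@conformers[[1]]
  d12 <- sqrt(sum((coords[pair[2], ] - coords[pair[1], ])^2))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  radii <- switch(mode,
    chelating = {
      r1 <- stats::runif(1, 2.0, 2.3)
      lo <- max(2.0, abs(r1 - d12) + 0.05)
      c(r1, stats::runif(1, lo, max(lo + 1e-6, 2.3)))
    },
    monodentate = {
      r1 <- stats::runif(1, 2.0, 2.3)
      hi <- r1 + d12 - 0.05
      c(r1, stats::runif(1, min(3.0, hi - 1e-6), hi))
    },
    nonbinding = {
      r1 <- stats::runif(1, 4.5, 6.0)
      lo <- max(4.05, abs(r1 - d12) + 0.05)
      hi <- r1 + d12 - 0.05
      c(r1, stats::runif(1, lo, hi))
    })
  if (mode == "monodentate" && radii[2] <= 2.6)
    stop("monodentate placement infeasible for this chelator geometry")
  phi <- stats::runif(1, 0, 2 * pi)
  spins <- stats::runif(12, 0, 2 * pi)
  prot <- as.matrix(receptor@atoms[, c("x", "y", "z")])
  # pocket frame: oxygens toward the zinc at the origin of receptor@zinc
  best <- NULL
  for (s in spins) {
    cand <- placeTwoAtoms(coords, pair[1], pair[2], radii[1], radii[2],
                          u = c(1, 0, 0), phi = phi, spin = s)
    cand <- sweep(cand, 2, receptor@zinc, "+")
    clearance <- if (nrow(prot)) {
      min(vapply(seq_len(nrow(prot)), function(i) {
        min(rowDistances(cand, prot[i, ]))
      }, numeric(1)))
    } else Inf
    if (is.null(best) || clearance > best$clearance)
      best <- list(coords = cand, clearance = clearance)
  }
  placed <- best$coords
  jitter <- matrix(stats::rnorm(length(placed), sd = 0.05),
                   nrow(placed), 3)
  jitter[pair, ] <- 0
  placed <- placed + jitter
  score <- -stats::runif(1, 5, 9)
  new("DockedPose", ligandId = mol@id, molecule = mol, coords = placed,
      chelatorPair = pair, score = score, receptor = receptor@isoform)
}

# save/restore .Random.seed so seeded helpers do not disturb the caller's
# RNG stream
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}

#' Write chelation assessments to CSV
#'
#' @param assessments named list (ids) of [ChelationAssessment-class], or
#'   a data.frame already holding the columns.
#' @param receptor receptor label for the `receptor` column.
#' @param path output CSV (`id,receptor,d_carbonyl,d_hydroxyl,class`).
#' @return `path`, invisibly.
#' @export
writeAssessments <- function(assessments, receptor, path) {
  df <- data.frame(
    id = names(assessments),
    receptor = receptor,
    d_carbonyl = vapply(assessments, function(a) a@dCarbonyl, numeric(1)),
    d_hydroxyl = vapply(assessments, function(a) a@dHydroxyl, numeric(1)),
    class = vapply(assessments, function(a) a@cls, character(1)),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write docked poses to an SDF file
#'
#' One V2000 record per pose with `score` and `receptor` data fields.
#'
#' @param poses list of [DockedPose-class].
#' @param path output SDF.
#' @return `path`, invisibly.
#' @export
writePoses <- function(poses, path) {
  blocks <- vapply(poses, function(p) {
    mb <- writeMolBlock(p@molecule@atoms, p@molecule@bonds, p@coords,
                        title = p@ligandId)
    sub("\\$\\$\\$\\$\n$",
        sprintf(">  <score>\n%.4f\n\n>  <receptor>\n%s\n\n$$$$\n",
                p@score, p@receptor),
        mb)
  }, character(1))
  writeLines(paste0(blocks, collapse = ""), sep = "", con = path)
  invisible(path)
}

#' Read docked poses from an SDF file
#'
#' Inverse of [writePoses()]: chelators are re-identified from the graph.
#'
#' @param path SDF file with optional `score` / `receptor` data fields.
#' @param receptor optional [ReceptorContext-class] used to disambiguate
#'   multiple hydroxamates.
#' @return list of [DockedPose-class].
#' @export
readPoses <- function(path, receptor = NULL) {
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  sdfset <- sdfset[ChemmineR::validSDF(sdfset)]
  lapply(seq_along(ChemmineR::cid(sdfset)), function(i) {
    sdf <- sdfset[[i]]
    mb <- paste(as(sdf, "character"), collapse = "\n")
    mol <- moleculeFromMolBlock(mb)
    db <- ChemmineR::datablock(sdf)
    score <- suppressWarnings(as.numeric(db["score"]))
    rec <- if ("receptor" %in% names(db)) unname(db["receptor"]) else
      NA_character_
    pair <- identifyChelators(mol, receptor)
    new("DockedPose", ligandId = mol@id, molecule = mol,
        coords = mol@conformers[[1]], chelatorPair = pair,
        score = if (length(score)) score else NA_real_, receptor = rec)
  })
}
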