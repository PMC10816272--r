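# Pharmacophore feature perception, hypothesis construction from a
# receptor-ligand pose, and multi-conformer matching with excluded volumes.

#' Perceive pharmacophore features of a 3D conformer
#'
#' Deterministic rule-based perception on the molecular graph:
#' \describe{
#'   \item{negative / positive}{formally charged atoms, anchored at the atom.}
#'   \item{donor}{N or O bearing at least one hydrogen, anchored at the
#'     heavy atom.}
#'   \item{acceptor}{neutral O; or neutral N without hydrogens and with at
#'     most two heavy-atom neighbours (pyridine-like).}
#'   \item{aromatic}{six-membered C/N rings with aromatic or alternating
#'     bond orders, anchored at the ring centroid.}
#'   \item{hydrophobic}{halogens and terminal carbons bonded only to
#'     carbon.}
#' }
#'
#' @param mol a [Molecule-class] with at least one conformer.
#' @param conformer conformer index (default 1).
#' @return data.frame with columns `kind`, `x`, `y`, `z`, `atoms`
#'   (comma-separated 1-based atom indices).
#' @export
perceiveFeatures <- function(mol, conformer = 1L) {
  if (length(mol@conformers) < conformer)
    stop("molecule '", mol@id, "' has no 3D coordinates for conformer ",
         conformer)
  coords <- mol@conformers[[conformer]]
  atoms <- mol@atoms
  bonds <- mol@bonds
  n <- nrow(atoms)
  deg <- integer(n)
  for (k in seq_len(nrow(bonds))) {
    deg[bonds$a1[k]] <- deg[bonds$a1[k]] + 1L
    deg[bonds$a2[k]] <- deg[bonds$a2[k]] + 1L
  }
  nbrElem <- function(i) {
    js <- c(bonds$a2[bonds$a1 == i], bonds$a1[bonds$a2 == i])
    atoms$elem[js]
  }
  # hydrogens may be implicit (nH) or explicit atoms in the graph
  hCount <- function(i) atoms$nH[i] + sum(nbrElem(i) == "H")
  feats <- list()
  add <- function(kind, idx) {
    anchor <- if (length(idx) == 1L) coords[idx, ] else colMeans(coords[idx, ])
    feats[[length(feats) + 1L]] <<- data.frame(
      kind = kind, x = anchor[1], y = anchor[2], z = anchor[3],
      atoms = paste(idx, collapse = ","), stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    el <- atoms$elem[i]; ch <- atoms$charge[i]; nh <- hCount(i)
    if (el == "H") next
    if (ch < 0) add("negative", i)
    if (ch > 0) add("positive", i)
    if (el %in% c("N", "O") && ch >= 0 && nh >= 1) add("donor", i)
    if (ch == 0 &&
        (el == "O" || (el == "N" && nh == 0 && deg[i] <= 2)))
      add("acceptor", i)
    if (el %in% c("F", "Cl", "Br", "I") ||
        (el == "C" && deg[i] == 1L && all(nbrElem(i) == "C")))
      add("hydrophobic", i)
  }
  for (ring in aromaticSixRings(atoms, bonds)) add("aromatic", ring)
  if (!length(feats))
    return(data.frame(kind = character(), x = numeric(), y = numeric(),
                      z = numeric(), atoms = character()))
  do.call(rbind, feats)
}

#' Construct a pharmacophore hypothesis
#'
#' @param features data.frame with columns `kind`, `x`, `y`, `z` and
#'   optionally `tolerance`.
#' @param volumes data.frame with columns `x`, `y`, `z` and optionally
#'   `radius`; may be empty.
#' @param requiredCount number of features a match must satisfy
#'   (default: all).
#' @param tolerance default feature tolerance in Angstrom.
#' @param volumeRadius default excluded-volume radius in Angstrom.
#' @return a [PharmacophoreHypothesis-class].
#' @export
newHypothesis <- function(features, volumes = NULL, requiredCount = NULL,
                          tolerance = 1.5, volumeRadius = 1.2) {
  features <- as.data.frame(features)
  if (is.null(features$tolerance)) features$tolerance <- tolerance
  if (is.null(volumes))
    volumes <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                          radius = numeric())
  volumes <- as.data.frame(volumes)
  if (nrow(volumes) && is.null(volumes$radius))
    volumes$radius <- volumeRadius
  if (is.null(requiredCount)) requiredCount <- nrow(features)
  new("PharmacophoreHypothesis",
      features = features[, c("kind", "x", "y", "z", "tolerance")],
      volumes = volumes, requiredCount = as.integer(requiredCount))
}

#' Build a structure-based hypothesis from a ligand pose in its receptor
#'
#' Features are placed at the picked perceived-feature anchors of the
#' ligand pose; one excluded volume is added per protein heavy atom within
#' `shellDistance` of any ligand heavy atom.  Volumes whose sphere would
#' contain a feature center are dropped.
#'
#' @param pose a [Molecule-class] whose conformer 1 is the pose, or a
#'   [DockedPose-class].
#' @param receptor a [ReceptorContext-class] sharing the pose frame.
#' @param picks character vector of feature kinds to implement (the first
#'   perceived feature of each kind is used); an unperceivable pick is an
#'   error naming it.
#' @param shellDistance excluded-volume shell radius (Angstrom).
#' @param tolerance feature tolerance (Angstrom).
#' @param volumeRadius excluded-volume radius (Angstrom).
#' @return a [PharmacophoreHypothesis-class].
#' @export
buildHypothesis <- function(pose, receptor,
                            picks = c("acceptor", "donor", "negative",
                                      "aromatic"),
                            shellDistance = 5.0, tolerance = 1.5,
                            volumeRadius = 1.2) {
  mol <- if (is(pose, "DockedPose")) pose@molecule else pose
  coords <- if (is(pose, "DockedPose")) pose@coords else mol@conformers[[1]]
  molCopy <- mol
  molCopy@conformers <- list(coords)
  perceived <- perceiveFeatures(molCopy)
  rows <- lapply(picks, function(kind) {
    hit <- which(perceived$kind == kind)
    if (!length(hit))
      stop("picked feature '", kind, "' is not present in the ligand pose")
    perceived[hit[1], c("kind", "x", "y", "z")]
  })
  features <- do.call(rbind, rows)
  prot <- receptor@atoms
  prot <- prot[prot$elem != "H", , drop = FALSE]
  ligHeavy <- coords[molCopy@atoms$elem != "H", , drop = FALSE]
  inShell <- vapply(seq_len(nrow(prot)), function(i) {
    p <- c(prot$x[i], prot$y[i], prot$z[i])
    min(rowDistances(ligHeavy, p)) <= shellDistance
  }, logical(1))
  vols <- data.frame(x = prot$x[inShell], y = prot$y[inShell],
                     z = prot$z[inShell],
                     radius = rep(volumeRadius, sum(inShell)))
  if (nrow(vols)) {
    fcent <- as.matrix(features[, c("x", "y", "z")])
    containsFeature <- vapply(seq_len(nrow(vols)), function(i) {
      v <- c(vols$x[i], vols$y[i], vols$z[i])
      any(rowDistances(fcent, v) < vols$radius[i])
    }, logical(1))
    vols <- vols[!containsFeature, , drop = FALSE]
  }
  newHypothesis(features, vols, tolerance = tolerance,
                volumeRadius = volumeRadius)
}

# Enumerate kind-compatible injective assignments of hypothesis features
# (rows of featKinds) to ligand features; returns a matrix with one
# assignment per row (ligand feature index per hypothesis feature).
.enumerateAssignments <- function(hypKinds, ligKinds) {
  candidates <- lapply(hypKinds, function(k) which(ligKinds == k))
  if (any(!lengths(candidates))) return(matrix(integer(), 0, length(hypKinds)))
  out <- list()
  walk <- function(i, chosen) {
    if (i > length(candidates)) {
      out[[length(out) + 1L]] <<- chosen
      return(invisible())
    }
    for (c in setdiff(candidates[[i]], chosen)) walk(i + 1L, c(chosen, c))
  }
  walk(1L, integer())
  if (!length(out)) return(matrix(integer(), 0, length(hypKinds)))
  do.call(rbind, out)
}

#' Match one ligand against a pharmacophore hypothesis
#'
#' For each conformer (up to `maxConformers`), every kind-compatible
#' injective assignment of hypothesis features to perceived ligand
#' features is evaluated: the ligand feature anchors are rigid-body
#' least-squares aligned onto the feature centers, and the assignment is
#' accepted iff every aligned anchor lies within its feature's tolerance
#' and no ligand heavy atom falls inside an excluded volume.  The accepted
#' assignment with the lowest anchor RMSD across all conformers is
#' returned; ties go to the lower conformer index.  At most one result per
#' ligand.
#'
#' When `requiredCount` is smaller than the number of features, all
#' feature subsets of that size are tried.
#'
#' @param mol a [Molecule-class] with conformers attached.
#' @param hypothesis a [PharmacophoreHypothesis-class].
#' @param maxConformers cap on the number of conformers examined
#'   (default 50).
#' @return `NULL` when no conformer matches, otherwise a list with
#'   `id`, `conformer`, `assignment` (named integer vector: hypothesis
#'   feature -> ligand feature anchor atoms), `fitRmsd` (Angstrom).
#' @export
matchPharmacophore <- function(mol, hypothesis, maxConformers = 50L) {
  if (nrow(hypothesis@features) == 0L)
    stop("hypothesis has no features")
  if (!length(mol@conformers))
    stop("molecule '", mol@id, "' has no conformers to match")
  nConf <- min(length(mol@conformers), maxConformers)
  feats <- hypothesis@features
  req <- hypothesis@requiredCount
  subsets <- if (req >= nrow(feats)) list(seq_len(nrow(feats))) else
    utils::combn(nrow(feats), req, simplify = FALSE)
  best <- NULL
  for (ci in seq_len(nConf)) {
    coords <- mol@conformers[[ci]]
    lig <- perceiveFeatures(mol, ci)
    if (!nrow(lig)) next
    ligAnchors <- as.matrix(lig[, c("x", "y", "z")])
    heavy <- coords[mol@atoms$elem != "H", , drop = FALSE]
    for (sub in subsets) {
      centers <- as.matrix(feats[sub, c("x", "y", "z")])
      tol <- feats$tolerance[sub]
      assignments <- .enumerateAssignments(feats$kind[sub], lig$kind)
      for (r in seq_len(nrow(assignments))) {
        sel <- assignments[r, ]
        if (length(sel) < 3L) next
        anchors <- ligAnchors[sel, , drop = FALSE]
        fit <- kabsch(centers, anchors)
        aligned <- applyTransform(anchors, fit)
        dev <- sqrt(rowSums((aligned - centers)^2))
        if (any(dev > tol)) next
        heavyAligned <- applyTransform(heavy, fit)
        if (nrow(hypothesis@volumes)) {
          clash <- FALSE
          for (v in seq_len(nrow(hypothesis@volumes))) {
            vc <- c(hypothesis@volumes$x[v], hypothesis@volumes$y[v],
                    hypothesis@volumes$z[v])
            if (any(rowDistances(heavyAligned, vc) <
                    hypothesis@volumes$radius[v])) {
              clash <- TRUE
              break
            }
          }
          if (clash) next
        }
        if (is.null(best) || fit$rmsd < best$fitRmsd - 1e-12) {
          assignment <- stats::setNames(sel, paste0(feats$kind[sub], sub))
          best <- list(id = mol@id, conformer = ci,
                       assignment = assignment, fitRmsd = fit$rmsd,
                       transform = fit)
        }
      }
    }
  }
  best
}

#' Screen a library against a pharmacophore hypothesis
#'
#' Survivors are exactly the molecules with a match result.
#'
#' @param lib a [MoleculeLibrary-class] (conformers attached).
#' @param hypothesis a [PharmacophoreHypothesis-class].
#' @param maxConformers per-ligand conformer cap.
#' @return a [FilterResult-class]; attribute `matches` holds the match
#'   table (`id`, `conformer`, `fitRmsd`).
#' @export
screenPharmacophore <- function(lib, hypothesis, maxConformers = 50L) {
  stage <- "pharmacophore"
  rows <- list()
  keep <- logical(length(lib))
  for (i in seq_len(length(lib))) {
    res <- tryCatch(
      matchPharmacophore(lib[[i]], hypothesis, maxConformers),
      error = function(e) NULL)
    if (!is.null(res)) {
      keep[i] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        id = res$id, conformer = res$conformer, fitRmsd = res$fitRmsd,
        stringsAsFactors = FALSE)
    }
  }
  out <- .filterResult(lib, keep, stage, "no pharmacophore match")
  attr(out, "matches") <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), conformer = integer(),
               fitRmsd = numeric())
  out
}

#' Write a hypothesis to YAML
#'
#' Coordinates are serialized with 12 significant digits, so a round trip
#' is lossless well below 1e-6 Angstrom.
#'
#' @param hypothesis a [PharmacophoreHypothesis-class].
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
writeHypothesis <- function(hypothesis, path) {
  f <- hypothesis@features
  v <- hypothesis@volumes
  obj <- list(
    required_count = hypothesis@requiredCount,
    features = lapply(seq_len(nrow(f)), function(i) list(
      kind = f$kind[i], center = c(f$x[i], f$y[i], f$z[i]),
      tolerance = f$tolerance[i])),
    volumes = lapply(seq_len(nrow(v)), function(i) list(
      center = c(v$x[i], v$y[i], v$z[i]), radius = v$radius[i]))
  )
  writeLines(yaml::as.yaml(obj, precision = 12L), path)
  invisible(path)
}

#' Read a hypothesis from YAML
#' @param path YAML file written by [writeHypothesis()] (or hand-edited in
#'   the same layout).
#' @return a [PharmacophoreHypothesis-class].
#' @export
readHypothesis <- function(path) {
  obj <- yaml::read_yaml(path)
  feats <- do.call(rbind, lapply(obj$features, function(f) data.frame(
    kind = f$kind, x = f$center[1], y = f$center[2], z = f$center[3],
    tolerance = f$tolerance, stringsAsFactors = FALSE)))
  vols <- if (length(obj$volumes)) {
    do.call(rbind, lapply(obj$volumes, function(v) data.frame(
      x = v$center[1], y = v$center[2], z = v$center[3],
      radius = v$radius)))
  } else NULL
  newHypothesis(feats, vols, requiredCount = obj$required_count)
}
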