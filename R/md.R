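# Trajectory analysis following the conventions of the simulation suites
# this funnel mirrors: backbone-fit superposition, RMSD series, per-atom
# RMSF, distance traces and interaction-persistence fractions.

#' Construct a Trajectory
#'
#' @param topology data.frame with at least columns `name`, `resid`,
#'   `resno`, `elem`, `role`.
#' @param frames list of n_atoms x 3 coordinate matrices (Angstrom).
#' @param dt frame spacing in ns (metadata).
#' @return a [Trajectory-class].
#' @export
newTrajectory <- function(topology, frames, dt = NA_real_) {
  new("Trajectory", topology = topology, frames = frames, dt = dt)
}

# Role classification used when reading PDB topologies.
.backboneNames <- c("N", "CA", "C", "O")
.aminoAcids <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "HIP", "HID", "HIE", "ILE", "LEU", "LYS", "MET",
                 "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

#' Read a trajectory from a multi-model PDB
#'
#' Multi-model PDB is the portable text baseline: every MODEL block
#' becomes one frame.  Roles are derived from residue names: standard
#' amino acids are `protein` (`protein_backbone` for N/CA/C/O), element
#' ZN is `zinc`, residues named in `ligandResid` are `ligand`, everything
#' else `other`.
#'
#' @param path multi-model PDB file.
#' @param ligandResid residue names treated as the ligand.
#' @param dt frame spacing in ns (metadata).
#' @return a [Trajectory-class].
#' @export
readTrajectory <- function(path, ligandResid = c("LIG", "UNL", "UNK"),
                           dt = NA_real_) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  at <- pdb$atom
  role <- rep("other", nrow(at))
  role[at$resid %in% .aminoAcids] <- "protein"
  role[at$resid %in% .aminoAcids & at$elety %in% .backboneNames] <-
    "protein_backbone"
  role[at$elesy == "ZN" | at$resid == "ZN"] <- "zinc"
  role[at$resid %in% ligandResid] <- "ligand"
  topology <- data.frame(name = at$elety, resid = at$resid,
                         resno = at$resno, elem = at$elesy, role = role,
                         stringsAsFactors = FALSE)
  nFrames <- nrow(pdb$xyz)
  frames <- lapply(seq_len(nFrames), function(i) {
    matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)
  })
  newTrajectory(topology, frames, dt)
}

#' Write a trajectory as multi-model PDB
#'
#' @param traj a [Trajectory-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTrajectoryPDB <- function(traj, path) {
  top <- traj@topology
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(traj@frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj@frames[[f]]
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(top)),
      ifelse(nchar(top$name) < 4, paste0(" ", top$name), top$name),
      top$resid, top$resno, xyz[, 1], xyz[, 2], xyz[, 3], top$elem), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Select atoms of a trajectory
#'
#' @param traj a [Trajectory-class].
#' @param role one of `"protein_backbone"`, `"protein"`, `"ligand"`,
#'   `"zinc"`, `"custom"`.
#' @param excludeResno residue numbers to drop (e.g. flexible termini
#'   excluded from a backbone fit).
#' @param custom integer atom indices, used when `role = "custom"`.
#' @return integer vector of atom indices (error when empty).
#' @export
selectAtoms <- function(traj, role = c("protein_backbone", "protein",
                                       "ligand", "zinc", "custom"),
                        excludeResno = NULL, custom = NULL) {
  role <- match.arg(role)
  idx <- if (role == "custom") {
    as.integer(custom)
  } else if (role == "protein") {
    which(traj@topology$role %in% c("protein", "protein_backbone"))
  } else {
    which(traj@topology$role == role)
  }
  if (!is.null(excludeResno))
    idx <- idx[!traj@topology$resno[idx] %in% excludeResno]
  if (!length(idx)) stop("selection resolves to zero atoms")
  idx
}

#' Rigid superposition of one frame onto a reference
#'
#' Kabsch least-squares fit on the selected atoms; requires at least three
#' non-collinear fit atoms.
#'
#' @param reference n x 3 reference coordinates.
#' @param mobile n x 3 mobile coordinates.
#' @param sel integer indices of the atoms to fit on (default: all).
#' @return list with `R`, `t` and `rmsd` (over the fit atoms), as in
#'   [kabsch()].
#' @export
superpose <- function(reference, mobile, sel = seq_len(nrow(reference))) {
  if (length(sel) < 3L)
    stop("fit selection must contain at least 3 atoms")
  refSel <- reference[sel, , drop = FALSE]
  if (isCollinear(refSel))
    stop("fit selection is collinear; rotation is undetermined")
  kabsch(refSel, mobile[sel, , drop = FALSE])
}

#' RMSD time series
#'
#' Per frame, the frame is fitted to the reference frame on
#' `fitSel` (backbone, typically) and the RMSD is then measured over
#' `measureSel` (e.g. the ligand, or the zinc ion fitted to the protein
#' backbone).  Element 1 is 0 when the reference is frame 1.
#'
#' @param traj a [Trajectory-class].
#' @param fitSel integer indices used for the superposition.
#' @param measureSel integer indices the RMSD is computed over (defaults
#'   to `fitSel`).
#' @param reference reference frame index (default 1) or an n x 3 matrix.
#' @return numeric vector, one value per frame (Angstrom).
#' @export
rmsdSeries <- function(traj, fitSel, measureSel = fitSel, reference = 1L) {
  if (!length(fitSel) || !length(measureSel))
    stop("selections must be non-empty")
  ref <- if (is.matrix(reference)) reference else
    traj@frames[[reference]]
  vapply(traj@frames, function(fr) {
    fit <- superpose(ref, fr, fitSel)
    moved <- applyTransform(fr, fit)
    sqrt(mean(rowSums(
      (moved[measureSel, , drop = FALSE] -
         ref[measureSel, , drop = FALSE])^2)))
  }, numeric(1))
}

#' Per-atom root-mean-square fluctuation
#'
#' Each frame is fitted to the reference frame on `fitSel`; the RMSF of
#' each selected atom is its root-mean-square deviation from its
#' time-average position.
#'
#' @param traj a [Trajectory-class] with at least two frames.
#' @param sel atoms to report RMSF for.
#' @param fitSel atoms to superpose on (defaults to `sel`).
#' @return numeric vector of per-atom RMSF values (Angstrom).
#' @export
rmsf <- function(traj, sel, fitSel = sel) {
  if (length(traj@frames) < 2L)
    stop("RMSF requires at least two frames")
  ref <- traj@frames[[1L]]
  fitted <- lapply(traj@frames, function(fr) {
    fit <- superpose(ref, fr, fitSel)
    applyTransform(fr, fit)[sel, , drop = FALSE]
  })
  arr <- simplify2array(fitted)          # atoms x 3 x frames
  meanPos <- apply(arr, c(1, 2), mean)
  dev2 <- sweep(arr, c(1, 2), meanPos)^2
  sqrt(apply(dev2, 1, mean) * 3)         # mean over (3, frames) times 3
}

#' Define an interaction to monitor
#'
#' Geometric criteria follow common simulation-suite conventions:
#' hydrogen bond = donor-H...acceptor distance <= 2.5 Angstrom and
#' donor-H-acceptor angle >= 120 degrees; salt bridge = charged-group
#' heavy-atom distance <= 4.0 Angstrom; plain distance = user cutoff
#' (chelation traces use the 2.6 Angstrom contact cutoff).
#'
#' Atom selectors are either integer indices or lists matched against the
#' topology columns (`name`, `resid`, `resno`); a selector that resolves
#' to anything but exactly one atom is an error.
#'
#' @param kind `"hbond"`, `"salt_bridge"` or `"distance"`.
#' @param donor,hydrogen,acceptor selectors for hbond participants.
#' @param a,b selectors for salt-bridge / distance participants.
#' @param distanceCutoff Angstrom; defaults: hbond 2.5 (H...acceptor),
#'   salt bridge 4.0, distance 2.6.
#' @param angleCutoff degrees (hbond only, default 120).
#' @return an interaction specification list.
#' @export
interactionSpec <- function(kind = c("hbond", "salt_bridge", "distance"),
                            donor = NULL, hydrogen = NULL, acceptor = NULL,
                            a = NULL, b = NULL,
                            distanceCutoff = NULL, angleCutoff = 120) {
  kind <- match.arg(kind)
  if (is.null(distanceCutoff))
    distanceCutoff <- switch(kind, hbond = 2.5, salt_bridge = 4.0,
                             distance = 2.6)
  stopifnot(distanceCutoff > 0, angleCutoff > 0)
  spec <- list(kind = kind, donor = donor, hydrogen = hydrogen,
               acceptor = acceptor, a = a, b = b,
               distanceCutoff = distanceCutoff, angleCutoff = angleCutoff)
  class(spec) <- "interactionSpec"
  spec
}

.resolveSelector <- function(traj, sel, what) {
  if (is.null(sel)) stop("missing selector for ", what)
  if (is.numeric(sel)) {
    idx <- as.integer(sel)
  } else {
    keep <- rep(TRUE, nrow(traj@topology))
    for (col in names(sel)) {
      if (!col %in% names(traj@topology))
        stop("unknown topology column '", col, "' in selector for ", what)
      keep <- keep & traj@topology[[col]] %in% sel[[col]]
    }
    idx <- which(keep)
  }
  if (length(idx) != 1L)
    stop("selector for ", what, " resolves to ", length(idx),
         " atoms (need exactly 1)")
  idx
}

.angleDeg <- function(p1, p2, p3) {
  v1 <- p1 - p2; v2 <- p3 - p2
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Interaction persistence over a trajectory
#'
#' Fraction of frames in which all geometric criteria of the
#' specification hold.  Exact on constructed frame masks: no smoothing or
#' sampling is involved.
#'
#' @param traj a [Trajectory-class].
#' @param spec an [interactionSpec()].
#' @return fraction in \[0, 1\].
#' @export
persistence <- function(traj, spec) {
  stopifnot(inherits(spec, "interactionSpec"))
  ok <- if (spec$kind == "hbond") {
    d <- .resolveSelector(traj, spec$donor, "donor")
    h <- .resolveSelector(traj, spec$hydrogen, "hydrogen")
    a <- .resolveSelector(traj, spec$acceptor, "acceptor")
    vapply(traj@frames, function(fr) {
      dist <- sqrt(sum((fr[h, ] - fr[a, ])^2))
      dist <= spec$distanceCutoff &&
        .angleDeg(fr[d, ], fr[h, ], fr[a, ]) >= spec$angleCutoff
    }, logical(1))
  } else {
    a <- .resolveSelector(traj, spec$a, "a")
    b <- .resolveSelector(traj, spec$b, "b")
    vapply(traj@frames, function(fr) {
      sqrt(sum((fr[a, ] - fr[b, ])^2)) <= spec$distanceCutoff
    }, logical(1))
  }
  mean(ok)
}

#' Distance time series between two atoms
#'
#' @param traj a [Trajectory-class].
#' @param a,b atom selectors (see [interactionSpec()]).
#' @return numeric vector of per-frame distances (Angstrom).
#' @export
distanceSeries <- function(traj, a, b) {
  ia <- .resolveSelector(traj, a, "a")
  ib <- .resolveSelector(traj, b, "b")
  vapply(traj@frames, function(fr) sqrt(sum((fr[ia, ] - fr[ib, ])^2)),
         numeric(1))
}

#' Write a per-frame series to CSV (`frame,value`)
#' @param series numeric vector.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
writeSeries <- function(series, path) {
  utils::write.csv(data.frame(frame = seq_along(series), value = series),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a persistence table to CSV (`interaction,fraction,percent`)
#' @param fractions named numeric vector of persistence fractions.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
writePersistence <- function(fractions, path) {
  utils::write.csv(data.frame(interaction = names(fractions),
                              fraction = unname(fractions),
                              percent = 100 * unname(fractions)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
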