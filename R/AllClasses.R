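#' @import methods
NULL

#' A single small molecule with optional 3D conformers
#'
#' `Molecule` stores the molecular graph (atoms with formal charges and
#' implicit-hydrogen counts, bonds with orders), the canonical SMILES as
#' perceived by Open Babel, an optional protonation-state tag, zero or more
#' 3D conformers (one coordinate triple per atom of the graph, in Angstrom)
#' and an optional list of ground-truth labels (used only by the synthetic
#' data generators).
#'
#' @slot id single character identifier, unique within a library.
#' @slot smiles canonical SMILES string.
#' @slot atoms data.frame with columns `elem`, `charge`, `nH` (implicit
#'   hydrogen count).
#' @slot bonds data.frame with columns `a1`, `a2`, `order` (1-based atom
#'   indices into `atoms`).
#' @slot conformers list of numeric matrices (n_atoms x 3), coordinates in
#'   Angstrom.
#' @slot stateTag one of `"neutral"`, `"hydroxamate_anion"`, `"other"`.
#' @slot labels named list of ground-truth flags (synthetic data only).
#' @exportClass Molecule
setClass("Molecule",
  representation(
    id         = "character",
    smiles     = "character",
    atoms      = "data.frame",
    bonds      = "data.frame",
    conformers = "list",
    stateTag   = "character",
    labels     = "list"
  ),
  prototype(
    conformers = list(),
    stateTag   = "other",
    labels     = list()
  )
)

setValidity("Molecule", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (!all(c("elem", "charge", "nH") %in% names(object@atoms)))
    msg <- c(msg, "'atoms' must have columns elem, charge, nH")
  if (nrow(object@bonds) > 0 &&
      !all(c("a1", "a2", "order") %in% names(object@bonds)))
    msg <- c(msg, "'bonds' must have columns a1, a2, order")
  if (!object@stateTag %in% c("neutral", "hydroxamate_anion", "other"))
    msg <- c(msg, "invalid stateTag")
  for (conf in object@conformers) {
    if (!is.matrix(conf) || ncol(conf) != 3 ||
        nrow(conf) != nrow(object@atoms)) {
      msg <- c(msg, "each conformer must be an n_atoms x 3 matrix")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' An ordered collection of molecules
#'
#' Thin container over a list of [Molecule-class] objects.  Identifiers must
#' be unique; input order is preserved by all filters.
#'
#' @slot molecules list of `Molecule` objects.
#' @exportClass MoleculeLibrary
setClass("MoleculeLibrary",
  representation(molecules = "list"),
  prototype(molecules = list())
)

setValidity("MoleculeLibrary", function(object) {
  ok <- vapply(object@molecules, is, logical(1), class2 = "Molecule")
  if (!all(ok)) return("all elements must be Molecule objects")
  ids <- vapply(object@molecules, function(m) m@id, character(1))
  if (anyDuplicated(ids)) {
    return(paste0("duplicate molecule ids: ",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  TRUE
})

#' Result of applying one funnel filter
#'
#' @slot kept surviving [MoleculeLibrary-class] (input order preserved).
#' @slot log data.frame with columns `id`, `stage`, `reason`, one row per
#'   removed molecule.
#' @slot stage character scalar naming the filter stage.
#' @exportClass FilterResult
setClass("FilterResult",
  representation(kept = "MoleculeLibrary", log = "data.frame",
                 stage = "character"))

#' A structure-based pharmacophore hypothesis
#'
#' Typed feature points with spherical tolerances plus excluded-volume
#' spheres marking space occupied by protein atoms.  A ligand conformer
#' matches when an assignment of its perceived features to the hypothesis
#' features exists such that, after rigid-body least-squares alignment,
#' every required feature anchor lies within its tolerance sphere and no
#' ligand heavy atom lies inside an excluded volume.
#'
#' @slot features data.frame with columns `kind`, `x`, `y`, `z`,
#'   `tolerance` (Angstrom).
#' @slot volumes data.frame with columns `x`, `y`, `z`, `radius` (Angstrom).
#' @slot requiredCount integer, number of features that must be matched
#'   (defaults to all).
#' @exportClass PharmacophoreHypothesis
setClass("PharmacophoreHypothesis",
  representation(features = "data.frame", volumes = "data.frame",
                 requiredCount = "integer"))

.featureKinds <- c("acceptor", "donor", "negative", "positive",
                   "aromatic", "hydrophobic")

setValidity("PharmacophoreHypothesis", function(object) {
  msg <- character()
  f <- object@features
  if (!all(c("kind", "x", "y", "z", "tolerance") %in% names(f)))
    msg <- c(msg, "features must have columns kind, x, y, z, tolerance")
  else {
    if (!all(f$kind %in% .featureKinds))
      msg <- c(msg, paste0("unknown feature kind(s): ",
                           paste(setdiff(f$kind, .featureKinds), collapse = ", ")))
    if (nrow(f) > 0 && any(f$tolerance <= 0))
      msg <- c(msg, "feature tolerances must be > 0")
  }
  v <- object@volumes
  if (nrow(v) > 0) {
    if (!all(c("x", "y", "z", "radius") %in% names(v)))
      msg <- c(msg, "volumes must have columns x, y, z, radius")
    else if (any(v$radius <= 0))
      msg <- c(msg, "excluded-volume radii must be > 0")
  }
  if (length(object@requiredCount) != 1L || is.na(object@requiredCount) ||
      object@requiredCount < 1L || object@requiredCount > nrow(f))
    msg <- c(msg, "requiredCount must be in 1..number of features")
  if (length(msg)) msg else TRUE
})

#' A receptor structure with a designated catalytic zinc
#'
#' @slot isoform receptor label, e.g. `"HDAC11"`, `"HDAC1"`.
#' @slot atoms data.frame of protein atoms (PDB semantics: `elety`, `resid`,
#'   `chain`, `resno`, `elem`, `x`, `y`, `z`; 1-based residue numbering
#'   kept as-is).
#' @slot zinc numeric length-3 coordinate of the catalytic zinc (Angstrom).
#' @exportClass ReceptorContext
setClass("ReceptorContext",
  representation(isoform = "character", atoms = "data.frame",
                 zinc = "numeric"))

setValidity("ReceptorContext", function(object) {
  if (length(object@zinc) != 3L || any(!is.finite(object@zinc)))
    return("zinc must be a finite length-3 coordinate")
  TRUE
})

#' A docked ligand pose in a receptor frame
#'
#' @slot ligandId ligand identifier.
#' @slot molecule the docked [Molecule-class].
#' @slot coords n_atoms x 3 coordinate matrix in the receptor frame.
#' @slot chelatorPair integer length-2: indices of the hydroxamate carbonyl
#'   oxygen and the (deprotonated) hydroxyl oxygen.
#' @slot score docking backend score (lower is better), `NA` when absent.
#' @slot receptor receptor label the pose belongs to.
#' @exportClass DockedPose
setClass("DockedPose",
  representation(ligandId = "character", molecule = "Molecule",
                 coords = "matrix", chelatorPair = "integer",
                 score = "numeric", receptor = "character"),
  prototype(score = NA_real_, receptor = NA_character_))

setValidity("DockedPose", function(object) {
  p <- object@chelatorPair
  if (length(p) != 2L || anyNA(p) || p[1] == p[2] ||
      any(p < 1L) || any(p > nrow(object@coords)))
    return("chelatorPair must be two distinct valid atom indices")
  if (ncol(object@coords) != 3L)
    return("coords must be an n x 3 matrix")
  TRUE
})

#' Zinc chelation geometry verdict for one pose
#'
#' Distances from the two hydroxamate chelator oxygens to the catalytic
#' zinc, and the resulting class: `bidentate` (both within the cutoff,
#' boundary inclusive), `monodentate` (exactly one), or `none`.
#'
#' @slot dCarbonyl carbonyl-oxygen to zinc distance (Angstrom).
#' @slot dHydroxyl hydroxyl-oxygen to zinc distance (Angstrom).
#' @slot cls one of `"bidentate"`, `"monodentate"`, `"none"`.
#' @slot cutoff contact cutoff used (Angstrom).
#' @exportClass ChelationAssessment
setClass("ChelationAssessment",
  representation(dCarbonyl = "numeric", dHydroxyl = "numeric",
                 cls = "character", cutoff = "numeric"))

setValidity("ChelationAssessment", function(object) {
  msg <- character()
  if (object@dCarbonyl < 0 || object@dHydroxyl < 0)
    msg <- c(msg, "distances must be >= 0")
  if (!object@cls %in% c("bidentate", "monodentate", "none"))
    msg <- c(msg, "invalid chelation class")
  nIn <- sum(c(object@dCarbonyl, object@dHydroxyl) <= object@cutoff)
  want <- c("none", "monodentate", "bidentate")[nIn + 1L]
  if (object@cls != want)
    msg <- c(msg, "class inconsistent with distances under the cutoff")
  if (length(msg)) msg else TRUE
})

#' An MD trajectory (topology plus frames)
#'
#' @slot topology data.frame of atom records with at least columns `name`,
#'   `resid`, `resno`, `elem`, `role` (one of `protein`, `protein_backbone`,
#'   `ligand`, `zinc`, `other`).
#' @slot frames list of n_atoms x 3 coordinate matrices (Angstrom).
#' @slot dt frame spacing in ns (metadata; `NA` when unknown).
#' @exportClass Trajectory
setClass("Trajectory",
  representation(topology = "data.frame", frames = "list", dt = "numeric"),
  prototype(dt = NA_real_))

setValidity("Trajectory", function(object) {
  if (length(object@frames) < 1L) return("at least one frame required")
  n <- nrow(object@topology)
  ok <- vapply(object@frames,
               function(f) is.matrix(f) && nrow(f) == n && ncol(f) == 3L,
               logical(1))
  if (!all(ok)) return("all frames must be n_atoms x 3 matrices")
  TRUE
})

#' Audit trail of a full funnel run
#'
#' @slot stages data.frame with columns `stage`, `nIn`, `nOut` in execution
#'   order; counts telescope (each stage's `nIn` equals the previous
#'   stage's `nOut`).
#' @slot survivors named list: stage -> character vector of surviving ids.
#' @slot removals data.frame with columns `id`, `stage`, `reason`.
#' @slot ranking data.frame with columns `id`, `score`, `rank` (final
#'   prioritization of the survivors).
#' @exportClass FunnelReport
setClass("FunnelReport",
  representation(stages = "data.frame", survivors = "list",
                 removals = "data.frame", ranking = "data.frame"))

setValidity("FunnelReport", function(object) {
  s <- object@stages
  if (nrow(s) > 1 && any(s$nIn[-1] != s$nOut[-nrow(s)]))
    return("stage counts must telescope")
  if (any(s$nOut > s$nIn))
    return("a stage cannot gain molecules")
  TRUE
})

#' Aggregated binding-pose-metadynamics result
#'
#' PoseScore is the mean over trials of each trial's time-averaged ligand
#' RMSD from the starting pose; PersScore is the mean over trials of the
#' mean per-interaction persistence; CompScore combines them as
#' `poseScore - weight * persScore` (weight defaults to 5), with more
#' negative values indicating a more stable pose.
#'
#' @slot poseScore Angstrom.
#' @slot persScore fraction in \[0, 1\].
#' @slot compScore composite score.
#' @slot poseStable logical, `poseScore <= 2` by default.
#' @slot contactsMaintained logical, `persScore >= 0.6` by default.
#' @slot weight the PersScore weight used in the composite.
#' @exportClass BPMDResult
setClass("BPMDResult",
  representation(poseScore = "numeric", persScore = "numeric",
                 compScore = "numeric", poseStable = "logical",
                 contactsMaintained = "logical", weight = "numeric"))
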