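#' Molecule identifiers
#' @param x a [Molecule-class] or [MoleculeLibrary-class].
#' @return character vector of ids.
#' @export
setGeneric("molIds", function(x) standardGeneric("molIds"))

#' Canonical SMILES
#' @param x a [Molecule-class] or [MoleculeLibrary-class].
#' @return character vector of canonical SMILES.
#' @export
setGeneric("smilesOf", function(x) standardGeneric("smilesOf"))

#' 3D conformers of a molecule
#' @param x a [Molecule-class].
#' @return list of n_atoms x 3 coordinate matrices.
#' @export
setGeneric("conformers", function(x) standardGeneric("conformers"))

#' Replace the conformers of a molecule
#' @param x a [Molecule-class].
#' @param value list of n_atoms x 3 coordinate matrices (Angstrom).
#' @export
setGeneric("conformers<-", function(x, value) standardGeneric("conformers<-"))

#' Ground-truth labels attached to a molecule (synthetic data only)
#' @param x a [Molecule-class].
#' @export
setGeneric("labelsOf", function(x) standardGeneric("labelsOf"))

#' Surviving molecules of a filter stage
#' @param x a [FilterResult-class].
#' @export
setGeneric("kept", function(x) standardGeneric("kept"))

#' Removal log of a filter stage or funnel run
#' @param x a [FilterResult-class] or [FunnelReport-class].
#' @export
setGeneric("removalLog", function(x) standardGeneric("removalLog"))

#' Chelation class of an assessment
#' @param x a [ChelationAssessment-class].
#' @export
setGeneric("chelationClass", function(x) standardGeneric("chelationClass"))

#' Per-stage counts of a funnel run
#' @param x a [FunnelReport-class].
#' @export
setGeneric("stageCounts", function(x) standardGeneric("stageCounts"))

#' Survivor id sets of a funnel run
#' @param x a [FunnelReport-class].
#' @export
setGeneric("stageSurvivors", function(x) standardGeneric("stageSurvivors"))

#' Final ranking table of a funnel run
#' @param x a [FunnelReport-class].
#' @export
setGeneric("rankingOf", function(x) standardGeneric("rankingOf"))
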