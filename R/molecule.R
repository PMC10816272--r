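# Constructors and accessors for Molecule / MoleculeLibrary.

#' Build a Molecule from a SMILES string
#'
#' The SMILES is parsed and canonicalized by Open Babel; the molecular
#' graph (atoms, bonds, formal charges, implicit-hydrogen counts) is
#' recovered from the kekulized connection table.  Conformers can be
#' attached afterwards with [conformers<-()]; their rows must follow this
#' graph's atom order.
#'
#' @param smiles SMILES string.
#' @param id identifier (defaults to the SMILES itself).
#' @param stateTag protonation-state tag; `"neutral"`,
#'   `"hydroxamate_anion"` or `"other"`.
#' @param labels optional named list of ground-truth flags.
#' @return a [Molecule-class].
#' @examples
#' m <- moleculeFromSmiles("ONC(=O)c1ccccc1", id = "bha")
#' @export
moleculeFromSmiles <- function(smiles, id = smiles, stateTag = "other",
                               labels = list()) {
  mols <- tryCatch(obParse(smiles, ids = id),
                   error = function(e)
                     stop("unparseable SMILES for '", id, "': ",
                          conditionMessage(e), call. = FALSE))
  props <- ChemmineOB::prop_OB(mols[[1]])
  mb <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "SDF", paste(smiles, id)))
  graph <- parseMolBlock(mb)
  atoms <- graph$atoms[, c("elem", "charge")]
  atoms$nH <- implicitHCounts(graph$atoms, graph$bonds)
  new("Molecule", id = as.character(id),
      smiles = props$cansmiNS[1], atoms = atoms, bonds = graph$bonds,
      stateTag = stateTag, labels = labels)
}

#' Build a Molecule from a V2000 molblock
#'
#' Used for molecules constructed with explicit coordinates (synthetic
#' scaffolds, SDF entries).  Non-zero coordinates become conformer 1.
#'
#' @param molblock molblock text (terminated by `M  END`; a trailing
#'   `$$$$` is tolerated).
#' @param id identifier; defaults to the molblock title line.
#' @inheritParams moleculeFromSmiles
#' @return a [Molecule-class].
#' @export
moleculeFromMolBlock <- function(molblock, id = NULL, stateTag = "other",
                                 labels = list()) {
  if (!grepl("\\$\\$\\$\\$", molblock))
    molblock <- paste0(molblock, "\n$$$$\n")
  if (!grepl("\n$", molblock)) molblock <- paste0(molblock, "\n")
  graph <- parseMolBlock(molblock)
  if (is.null(id)) {
    id <- trimws(strsplit(molblock, "\n", fixed = TRUE)[[1]][1])
    if (!nzchar(id)) id <- "mol"
  }
  smi <- tryCatch(
    sub("[[:space:]].*$", "",
        suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", molblock))),
    error = function(e) "")
  if (!nzchar(smi))
    stop("molblock for '", id, "' is not a valid molecule")
  atoms <- graph$atoms[, c("elem", "charge")]
  atoms$nH <- implicitHCounts(graph$atoms, graph$bonds)
  coords <- as.matrix(graph$atoms[, c("x", "y", "z")])
  dimnames(coords) <- NULL
  confs <- if (any(coords != 0)) list(coords) else list()
  new("Molecule", id = as.character(id), smiles = smi, atoms = atoms,
      bonds = graph$bonds, conformers = confs, stateTag = stateTag,
      labels = labels)
}

#' Assemble a MoleculeLibrary
#' @param molecules list of [Molecule-class] objects.
#' @return a [MoleculeLibrary-class].
#' @export
moleculeLibrary <- function(molecules = list()) {
  new("MoleculeLibrary", molecules = molecules)
}

#' @describeIn molIds identifier of a single molecule.
#' @export
setMethod("molIds", "Molecule", function(x) x@id)

#' @describeIn molIds identifiers of all molecules, in library order.
#' @export
setMethod("molIds", "MoleculeLibrary", function(x) {
  vapply(x@molecules, function(m) m@id, character(1))
})

#' @describeIn smilesOf canonical SMILES of one molecule.
#' @export
setMethod("smilesOf", "Molecule", function(x) x@smiles)

#' @describeIn smilesOf canonical SMILES of every molecule.
#' @export
setMethod("smilesOf", "MoleculeLibrary", function(x) {
  vapply(x@molecules, function(m) m@smiles, character(1))
})

#' @describeIn conformers conformer list of a molecule.
#' @export
setMethod("conformers", "Molecule", function(x) x@conformers)

#' @rdname conformers-set
#' @aliases conformers<-,Molecule-method
#' @export
setReplaceMethod("conformers", "Molecule", function(x, value) {
  x@conformers <- value
  validObject(x)
  x
})

#' @describeIn labelsOf labels of a molecule.
#' @export
setMethod("labelsOf", "Molecule", function(x) x@labels)

#' @export
setMethod("length", "MoleculeLibrary", function(x) length(x@molecules))

#' @export
setMethod("[", "MoleculeLibrary", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, molIds(x))
  new("MoleculeLibrary", molecules = x@molecules[i])
})

#' @export
setMethod("[[", "MoleculeLibrary", function(x, i) {
  if (is.character(i)) i <- match(i, molIds(x))
  x@molecules[[i]]
})

setMethod("show", "Molecule", function(object) {
  cat("Molecule", object@id, "\n")
  cat("  SMILES:", object@smiles, "\n")
  cat(sprintf("  %d heavy/explicit atoms, %d bonds, %d conformer(s), state %s\n",
              nrow(object@atoms), nrow(object@bonds),
              length(object@conformers), object@stateTag))
})

setMethod("show", "MoleculeLibrary", function(object) {
  n <- length(object)
  cat("MoleculeLibrary with", n, "molecule(s)\n")
  if (n) {
    shown <- utils::head(molIds(object), 5)
    cat("  ids:", paste(shown, collapse = ", "),
        if (n > 5) "..." else "", "\n")
  }
})

setMethod("show", "FilterResult", function(object) {
  cat(sprintf("FilterResult [%s]: %d kept, %d removed\n", object@stage,
              length(object@kept), nrow(object@log)))
})

#' @describeIn kept survivors of a filter stage.
#' @export
setMethod("kept", "FilterResult", function(x) x@kept)

#' @describeIn removalLog removal log of one filter stage.
#' @export
setMethod("removalLog", "FilterResult", function(x) x@log)
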