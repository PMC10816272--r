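# Library I/O, substructure/state filters, physicochemical properties,
# rule-of-five and structural-alert (REOS-style) filtering.

#' SMARTS pattern for the benzohydroxamate chemotype
#'
#' Aromatic-form equivalent of the classical kekulized benzohydroxamic
#' acid query; matches both the neutral acid and the deprotonated
#' (anionic) hydroxamate.
#' @return SMARTS string.
#' @export
benzohydroxamateSmarts <- function() "ONC(=O)c1ccccc1"

#' SMARTS pattern selecting the anionic (deprotonated) hydroxamate state
#' @return SMARTS string.
#' @export
hydroxamateAnionSmarts <- function() "[O-]N([H])C(=O)c1ccccc1"

.filterResult <- function(lib, keep, stage, reason) {
  reasons <- if (length(reason) == 1L) rep(reason, sum(!keep)) else
    reason[!keep]
  log <- data.frame(id = molIds(lib)[!keep],
                    stage = rep(stage, sum(!keep)),
                    reason = reasons, stringsAsFactors = FALSE)
  new("FilterResult", kept = lib[which(keep)], log = log, stage = stage)
}

#' Read a ligand library from a SMILES or SDF file
#'
#' SMILES files hold one whitespace-separated `SMILES id` record per line
#' (a missing id defaults to `M<line>`); blank lines and `#` comments are
#' skipped.  SDF files are read as V2000.  Malformed entries are skipped
#' with a warning and recorded in the `skipped` attribute of the result --
#' they are never fatal, so funnel audit counts still reconcile.
#'
#' @param path file path.
#' @param format `"smiles"` or `"sdf"`.
#' @return a [MoleculeLibrary-class]; attribute `skipped` is a data.frame
#'   with columns `entry`, `reason` for the rejected records.
#' @export
readLibrary <- function(path, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read library file: ", path)
  skipped <- data.frame(entry = character(), reason = character(),
                        stringsAsFactors = FALSE)
  mols <- list()
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    for (i in seq_along(lines)) {
      parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
      smi <- parts[1]
      id <- if (length(parts) >= 2) parts[2] else paste0("M", i)
      m <- tryCatch(moleculeFromSmiles(smi, id = id),
                    error = function(e) conditionMessage(e))
      if (is.character(m)) {
        skipped <- rbind(skipped, data.frame(entry = lines[i], reason = m))
      } else {
        mols[[length(mols) + 1L]] <- m
      }
    }
  } else {
    sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
    valid <- ChemmineR::validSDF(sdfset)
    for (i in which(!valid)) {
      skipped <- rbind(skipped, data.frame(
        entry = ChemmineR::sdfid(sdfset[i]),
        reason = "invalid SDF record"))
    }
    sdfset <- sdfset[valid]
    for (i in seq_along(ChemmineR::cid(sdfset))) {
      sdf <- sdfset[[i]]
      mb <- paste(as(sdf, "character"), collapse = "\n")
      id <- ChemmineR::sdfid(sdfset[i])
      m <- tryCatch(moleculeFromMolBlock(mb, id = id),
                    error = function(e) conditionMessage(e))
      if (is.character(m)) {
        skipped <- rbind(skipped, data.frame(entry = id, reason = m))
      } else {
        mols[[length(mols) + 1L]] <- m
      }
    }
  }
  if (nrow(skipped))
    warning(nrow(skipped), " malformed librar", "y entr",
            if (nrow(skipped) == 1) "y" else "ies", " skipped",
            call. = FALSE)
  if (!length(mols) && nrow(skipped) > 0)
    warning("no parseable records in ", path, call. = FALSE)
  lib <- moleculeLibrary(mols)
  attr(lib, "skipped") <- skipped
  lib
}

#' Write a library to a SMILES or SDF file
#'
#' @param lib a [MoleculeLibrary-class].
#' @param path output file.
#' @param format `"smiles"` or `"sdf"`.  SDF output uses conformer 1 as
#'   coordinates when present.
#' @return `path`, invisibly.
#' @export
writeLibrary <- function(lib, path, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  if (format == "smiles") {
    writeLines(paste(smilesOf(lib), molIds(lib)), path)
  } else {
    blocks <- vapply(lib@molecules, function(m) {
      coords <- if (length(m@conformers)) m@conformers[[1]] else NULL
      writeMolBlock(m@atoms, m@bonds, coords, title = m@id)
    }, character(1))
    writeLines(paste0(blocks, collapse = ""), sep = "", con = path)
  }
  invisible(path)
}

#' Keep molecules containing a substructure
#'
#' A molecule survives iff it contains at least one embedding of the
#' pattern; order is preserved.  Patterns written as kekulized SMILES are
#' normalized to their aromatic form first (see [canonicalizePattern()]),
#' matching the behaviour of the screening platforms such queries are
#' written for.
#'
#' @param lib a [MoleculeLibrary-class].
#' @param pattern SMARTS (or SMILES-style) pattern; defaults to the
#'   benzohydroxamate query.
#' @param normalize normalize SMILES-style patterns to aromatic form.
#' @param stage stage name used in the removal log.
#' @return a [FilterResult-class].
#' @export
substructureFilter <- function(lib, pattern = benzohydroxamateSmarts(),
                               normalize = TRUE,
                               stage = "substructure") {
  if (normalize) pattern <- canonicalizePattern(pattern)
  if (length(lib) == 0L)
    return(.filterResult(lib, logical(0), stage,
                         paste0("no match: ", pattern)))
  counts <- obCountSmarts(smilesOf(lib), pattern)
  .filterResult(lib, counts > 0, stage, paste0("no match: ", pattern))
}

#' Select the anionic-hydroxamate protonation state
#'
#' A molecule survives iff it matches the deprotonated-hydroxamate
#' pattern; survivors are tagged `stateTag = "hydroxamate_anion"`.
#' State enumeration itself is not performed -- the library must already
#' contain the states to choose among.
#'
#' @param lib a [MoleculeLibrary-class].
#' @param pattern anionic-hydroxamate SMARTS.
#' @return a [FilterResult-class].
#' @export
selectHydroxamateState <- function(lib, pattern = hydroxamateAnionSmarts()) {
  stage <- "state"
  if (length(lib) == 0L)
    return(.filterResult(lib, logical(0), stage, "not anionic hydroxamate"))
  counts <- obCountSmarts(smilesOf(lib), pattern)
  res <- .filterResult(lib, counts > 0, stage, "not anionic hydroxamate")
  res@kept@molecules <- lapply(res@kept@molecules, function(m) {
    m@stateTag <- "hydroxamate_anion"
    m
  })
  res
}

#' Hydrogen-bond donor/acceptor perception patterns
#'
#' The SMARTS definitions used for rule-of-five donor/acceptor counting.
#' They ship as editable YAML (`perception_smarts.yaml` under the package
#' `extdata`), not as code constants: `hbd` counts N/O atoms bearing at
#' least one hydrogen, `hba` counts all N and O atoms (the classical
#' rule-of-five convention).
#'
#' @param path YAML file; defaults to the packaged definitions.
#' @return named list with elements `hbd` and `hba`.
#' @export
perceptionPatterns <- function(path = system.file("extdata",
                                                  "perception_smarts.yaml",
                                                  package = "hdacfunnel")) {
  pats <- yaml::read_yaml(path)
  stopifnot(all(c("hbd", "hba") %in% names(pats)))
  pats
}

#' Physicochemical property profile
#'
#' Molecular weight from standard (average) atomic weights, logP from
#' Open Babel's published fragment-additive contribution model, donor and
#' acceptor counts from the perception SMARTS, and the number of violated
#' rule-of-five conditions.  Deterministic.
#'
#' @param lib a [MoleculeLibrary-class] or single [Molecule-class].
#' @param thresholds named list of rule-of-five limits.
#' @param strict use strict inequalities (`<`), the form in which the rule
#'   is usually printed; `FALSE` uses `<=`.
#' @param patterns perception SMARTS (see [perceptionPatterns()]).
#' @return data.frame with columns `id`, `formula`, `mw`, `logp`, `hbd`,
#'   `hba`, `violations`.
#' @export
computeProperties <- function(lib,
                              thresholds = list(mw = 500, logp = 5,
                                                hbd = 5, hba = 10),
                              strict = TRUE,
                              patterns = perceptionPatterns()) {
  if (is(lib, "Molecule")) lib <- moleculeLibrary(list(lib))
  if (length(lib) == 0L)
    return(data.frame(id = character(), formula = character(),
                      mw = numeric(), logp = numeric(), hbd = integer(),
                      hba = integer(), violations = integer()))
  smi <- smilesOf(lib)
  props <- obProps(smi)
  hbd <- as.integer(obCountSmarts(smi, patterns$hbd))
  hba <- as.integer(obCountSmarts(smi, patterns$hba))
  cmp <- if (strict) `<` else `<=`
  violations <- as.integer(!cmp(props$MW, thresholds$mw)) +
    as.integer(!cmp(props$logP, thresholds$logp)) +
    as.integer(!cmp(hbd, thresholds$hbd)) +
    as.integer(!cmp(hba, thresholds$hba))
  data.frame(id = molIds(lib), formula = props$formula, mw = props$MW,
             logp = props$logP, hbd = hbd, hba = hba,
             violations = violations, stringsAsFactors = FALSE)
}

#' Rule-of-five filter
#'
#' Discards every molecule with one or more violations of: molecular
#' weight < 500 Da, logP < 5, H-bond donors < 5, H-bond acceptors < 10
#' (strict inequalities by default).
#'
#' @inheritParams computeProperties
#' @return a [FilterResult-class]; the per-molecule property table is
#'   attached as attribute `properties`.
#' @export
lipinskiFilter <- function(lib,
                           thresholds = list(mw = 500, logp = 5,
                                             hbd = 5, hba = 10),
                           strict = TRUE,
                           patterns = perceptionPatterns()) {
  props <- computeProperties(lib, thresholds, strict, patterns)
  keep <- props$violations == 0L
  res <- .filterResult(lib, keep, "rule_of_five",
                       sprintf("%d rule-of-five violation(s)",
                               props$violations)[!keep])
  attr(res, "properties") <- props
  res
}

#' Default structural-alert set
#'
#' A compact REOS-style collection of reactive/assay-interfering
#' substructures (nitro, acyl halide, aldehyde, epoxide/aziridine,
#' isocyanate, thiol, peroxide, alkyl iodide/bromide), shipped as YAML
#' under the package `extdata` so it can be extended without code changes.
#'
#' @param path YAML file of `name: SMARTS` pairs.
#' @return named character vector of SMARTS patterns.
#' @export
defaultAlerts <- function(path = system.file("extdata", "reos_alerts.yaml",
                                             package = "hdacfunnel")) {
  al <- unlist(yaml::read_yaml(path))
  if (anyDuplicated(names(al))) stop("alert names must be unique")
  al
}

#' Structural-alert (REOS-style) filter
#'
#' A molecule is removed iff any alert pattern matches; the removal log
#' names the triggering alert (the first matching one, in alert order).
#'
#' @param lib a [MoleculeLibrary-class].
#' @param alerts named character vector of SMARTS patterns; the default
#'   set includes a nitro pattern.
#' @return a [FilterResult-class].
#' @export
reosFilter <- function(lib, alerts = defaultAlerts()) {
  stage <- "alerts"
  if (length(lib) == 0L || length(alerts) == 0L) {
    return(.filterResult(lib, rep(TRUE, length(lib)), stage, character(0)))
  }
  smi <- smilesOf(lib)
  hitAlert <- rep(NA_character_, length(lib))
  for (nm in names(alerts)) {
    counts <- obCountSmarts(smi, alerts[[nm]])
    hitAlert[is.na(hitAlert) & counts > 0] <- nm
  }
  keep <- is.na(hitAlert)
  .filterResult(lib, keep, stage, paste0("alert: ", hitAlert[!keep]))
}
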