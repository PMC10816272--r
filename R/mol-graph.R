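# Molecular-graph plumbing: Open Babel round trips, a V2000 reader for the
# degenerate cases the SDF container class rejects (zero-bond molecules),
# implicit-hydrogen perception and aromatic-ring detection.

# --- Open Babel helpers ----------------------------------------------------

# Parse a vector of SMILES into OBMol references; stops on the first
# unreadable entry, so callers that must tolerate bad input parse line by
# line (see readLibrary).
obParse <- function(smiles, ids = names(smiles)) {
  if (is.null(ids)) ids <- paste0("M", seq_along(smiles))
  txt <- paste(paste(smiles, ids), collapse = "\n")
  ChemmineOB::forEachMol("SMILES", txt, identity)
}

# Count SMARTS embeddings per molecule.  uniqueMatches = TRUE collapses
# symmetry-equivalent embeddings (so single-atom patterns count atoms).
obCountSmarts <- function(smiles, pattern, uniqueMatches = TRUE) {
  mols <- obParse(smiles)
  ok <- tryCatch(
    ChemmineOB::smartsSearch_OB(mols, pattern,
                                uniqueMatches = uniqueMatches),
    error = function(e)
      stop("invalid SMARTS pattern '", pattern, "': ",
           conditionMessage(e), call. = FALSE))
  as.numeric(ok)
}

# Open Babel descriptor block (canonical SMILES, formula, MW from average
# atomic weights, fragment-additive logP, ...).
obProps <- function(smiles) {
  mols <- obParse(smiles)
  do.call(rbind, lapply(mols, ChemmineOB::prop_OB))
}

#' Canonicalize a SMILES-like substructure pattern
#'
#' Rewrites a pattern written as plain (possibly kekulized) SMILES into
#' Open Babel's canonical aromatic form, so that queries drawn with
#' alternating single/double ring bonds -- the way benzohydroxamate queries
#' are usually printed -- match aromatic molecules under strict Daylight
#' SMARTS semantics.  Patterns that are not valid SMILES (e.g. ones using
#' SMARTS-only primitives) are returned unchanged.
#'
#' @param pattern SMILES or SMARTS string.
#' @return canonical aromatic SMILES when the input parses as SMILES,
#'   otherwise the input unchanged.
#' @examples
#' canonicalizePattern("C1=CC=C(C(=O)NO)C=C1")  # "ONC(=O)c1ccccc1"
#' @export
canonicalizePattern <- function(pattern) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", pattern)),
    error = function(e) "")
  out <- sub("[[:space:]].*$", "", out)
  if (nzchar(out)) out else pattern
}

# --- V2000 molblock reader / writer ---------------------------------------

# Minimal counts/atom/bond/charge reader.  Kept in-package because the
# usual SDF container class cannot represent zero-bond molecules (e.g.
# methane), which the property and feature-perception code must accept.
parseMolBlock <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) stop("truncated molblock")
  counts <- lines[4]
  nAtoms <- as.integer(substr(counts, 1, 3))
  nBonds <- as.integer(substr(counts, 4, 6))
  if (is.na(nAtoms) || is.na(nBonds)) stop("bad molblock counts line")
  atomLines <- lines[4 + seq_len(nAtoms)]
  atoms <- data.frame(
    elem = trimws(substr(atomLines, 32, 34)),
    charge = 0L,
    x = as.numeric(substr(atomLines, 1, 10)),
    y = as.numeric(substr(atomLines, 11, 20)),
    z = as.numeric(substr(atomLines, 21, 30)),
    stringsAsFactors = FALSE
  )
  if (nBonds > 0) {
    bondLines <- lines[4 + nAtoms + seq_len(nBonds)]
    bonds <- data.frame(
      a1 = as.integer(substr(bondLines, 1, 3)),
      a2 = as.integer(substr(bondLines, 4, 6)),
      order = as.integer(substr(bondLines, 7, 9))
    )
  } else {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  }
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    fields <- as.integer(strsplit(trimws(sub("^M  CHG[ ]*[0-9]+", "", ln)),
                                  "[[:space:]]+")[[1]])
    if (length(fields) >= 2) {
      idx <- fields[seq(1, length(fields), by = 2)]
      chg <- fields[seq(2, length(fields), by = 2)]
      atoms$charge[idx] <- chg
    }
  }
  list(atoms = atoms, bonds = bonds)
}

# Format an atom table + bond table (+ optional coordinates) as a V2000
# molblock terminated by "$$$$".
writeMolBlock <- function(atoms, bonds, coords = NULL, title = "mol") {
  n <- nrow(atoms)
  if (is.null(coords)) coords <- matrix(0, n, 3)
  hdr <- c(title, " hdacfunnel", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                   n, nrow(bonds)))
  atomLines <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    coords[, 1], coords[, 2], coords[, 3], atoms$elem)
  bondLines <- if (nrow(bonds)) {
    sprintf("%3d%3d%3d  0  0  0  0", bonds$a1, bonds$a2, bonds$order)
  } else character()
  chgIdx <- which(atoms$charge != 0)
  chgLines <- if (length(chgIdx)) {
    sprintf("M  CHG%3d%s", length(chgIdx),
            paste0(sprintf("%4d%4d", chgIdx, atoms$charge[chgIdx]),
                   collapse = ""))
  } else character()
  paste(c(hdr, atomLines, bondLines, chgLines, "M  END", "$$$$", ""),
        collapse = "\n")
}

# --- chemical perception ---------------------------------------------------

.standardValence <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, P = 3,
                      S = 2, Cl = 1, Br = 1, I = 1)

# Implicit hydrogen counts from standard valences.  Charge shifts the
# valence of N/P/O/S (O- has valence 1, N+ has 4); other charged atoms
# lose capacity.  Aromatic (order 4) bonds count 1.5.
implicitHCounts <- function(atoms, bonds) {
  n <- nrow(atoms)
  deg <- numeric(n)
  if (nrow(bonds)) {
    ord <- ifelse(bonds$order == 4L, 1.5, bonds$order)
    for (k in seq_len(nrow(bonds))) {
      deg[bonds$a1[k]] <- deg[bonds$a1[k]] + ord[k]
      deg[bonds$a2[k]] <- deg[bonds$a2[k]] + ord[k]
    }
  }
  val <- .standardValence[atoms$elem]
  val[is.na(val)] <- 0
  adj <- ifelse(atoms$elem %in% c("N", "P", "O", "S"),
                atoms$charge, -abs(atoms$charge))
  pmax(0L, as.integer(round(val + adj - deg)))
}

# Neighbor list: for atom i, data.frame of (atom index, bond order).
bondNeighbors <- function(bonds, n) {
  nb <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$a1[k]; b <- bonds$a2[k]; o <- bonds$order[k]
    nb[[a]] <- rbind(nb[[a]], c(b, o))
    nb[[b]] <- rbind(nb[[b]], c(a, o))
  }
  nb
}

# Enumerate unique 6-membered rings by DFS over the bond graph.
findSixRings <- function(bonds, n) {
  if (nrow(bonds) < 6L) return(list())
  adj <- lapply(seq_len(n), function(i) integer())
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$a1[k]]] <- c(adj[[bonds$a1[k]]], bonds$a2[k])
    adj[[bonds$a2[k]]] <- c(adj[[bonds$a2[k]]], bonds$a1[k])
  }
  rings <- list()
  seen <- character()
  walk <- function(path) {
    last <- path[length(path)]
    for (nxt in adj[[last]]) {
      if (length(path) == 6L && nxt == path[1]) {
        key <- paste(sort(path), collapse = "-")
        if (!key %in% seen) {
          seen <<- c(seen, key)
          rings[[length(rings) + 1L]] <<- path
        }
      } else if (length(path) < 6L && !(nxt %in% path) && nxt > path[1]) {
        walk(c(path, nxt))
      }
    }
  }
  for (start in seq_len(n)) walk(start)
  rings
}

# A six-ring counts as aromatic when every member is C or N and the ring
# bonds are either flagged aromatic (order 4) or alternate single/double
# around the cycle (kekulized form).
aromaticSixRings <- function(atoms, bonds) {
  rings <- findSixRings(bonds, nrow(atoms))
  ordOf <- function(a, b) {
    hit <- which((bonds$a1 == a & bonds$a2 == b) |
                 (bonds$a1 == b & bonds$a2 == a))
    bonds$order[hit[1]]
  }
  Filter(function(ring) {
    if (!all(atoms$elem[ring] %in% c("C", "N"))) return(FALSE)
    ords <- vapply(seq_along(ring), function(i) {
      ordOf(ring[i], ring[i %% 6L + 1L])
    }, numeric(1))
    all(ords == 4L) ||
      (sum(ords == 1L) == 3L && sum(ords == 2L) == 3L &&
         all(abs(diff(c(ords, ords[1]))) == 1L))
  }, rings)
}
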