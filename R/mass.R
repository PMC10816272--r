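# Elemental mass tables and the [M+H]+ calculator used to check synthetic
# intermediates and the final hit against printed MS values.

# monoisotopic: mass of the most abundant isotope (unified atomic mass
# units); nominal: its integer mass number; average: standard atomic
# weight.  Restricted to elements that occur in the screened chemotypes.
.massTable <- data.frame(
  elem = c("H", "B", "C", "N", "O", "F", "Na", "P", "S",
           "Cl", "K", "Zn", "Br", "I"),
  monoisotopic = c(1.00782503207, 11.0093054, 12.0, 14.0030740048,
                   15.9949146196, 18.99840322, 22.9897692809,
                   30.97376163, 31.97207100, 34.96885268,
                   38.96370668, 63.9291422, 78.9183371, 126.904473),
  nominal = c(1, 11, 12, 14, 16, 19, 23, 31, 32, 35, 39, 64, 79, 127),
  average = c(1.008, 10.81, 12.011, 14.007, 15.999, 18.998, 22.990,
              30.974, 32.06, 35.45, 39.098, 65.38, 79.904, 126.904),
  stringsAsFactors = FALSE
)

#' Parse a molecular formula into element counts
#'
#' @param formula Hill-style formula string such as `"C21H19N3O5"`.
#'   Element order is free; counts default to 1.
#' @return named integer vector of element counts.
#' @examples
#' parseFormula("C9H11NO3")
#' @export
parseFormula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  s <- gsub("[[:space:]]", "", formula)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks) || sum(nchar(toks)) != nchar(s))
    stop("cannot parse formula: ", formula)
  elems <- sub("[0-9]+$", "", toks)
  counts <- as.integer(ifelse(grepl("[0-9]+$", toks),
                              sub("^[A-Za-z]+", "", toks), "1"))
  agg <- tapply(counts, elems, sum)
  out <- stats::setNames(as.integer(agg), dimnames(agg)[[1]])
  out[order(names(out))]
}

.elementMasses <- function(elems, mode) {
  idx <- match(elems, .massTable$elem)
  if (anyNA(idx))
    stop("element(s) outside the supported mass table: ",
         paste(elems[is.na(idx)], collapse = ", "))
  .massTable[[mode]][idx]
}

#' Mass of a molecular formula
#'
#' @param formula formula string or named count vector (see
#'   [parseFormula()]).
#' @param mode `"monoisotopic"` (most-abundant-isotope masses),
#'   `"nominal"` (integer mass numbers) or `"average"` (standard atomic
#'   weights).
#' @return mass in Da (unrounded).
#' @examples
#' formulaMass("C", "monoisotopic")  # 12 exactly
#' @export
formulaMass <- function(formula, mode = c("monoisotopic", "nominal",
                                          "average")) {
  mode <- match.arg(mode)
  counts <- if (is.character(formula)) parseFormula(formula) else formula
  sum(.elementMasses(names(counts), mode) * as.numeric(counts))
}

#' m/z of the protonated molecular ion \[M+H\]+
#'
#' The electron mass is ignored, i.e. the ion mass is the plain sum of
#' atomic masses of the protonated formula -- the convention under which
#' published "calculated" HRMS values for these compounds are quoted.
#' Monoisotopic values are reported to 4 decimals; nominal values are
#' integers.
#'
#' @param formula formula string or named count vector.  By default the
#'   formula is that of the neutral molecule M and one hydrogen is added;
#'   set `assume = "protonated"` when the formula already describes the
#'   \[M+H\]+ ion (as printed in HRMS "calculated for ..." statements).
#' @param mode `"monoisotopic"` or `"nominal"`.
#' @param assume `"neutral"` (default) or `"protonated"`.
#' @return numeric m/z.
#' @examples
#' protonatedMass("C21H20O5N3", assume = "protonated")  # 394.1403
#' protonatedMass("C9H11NO3", mode = "nominal")         # 182
#' @export
protonatedMass <- function(formula, mode = c("monoisotopic", "nominal"),
                           assume = c("neutral", "protonated")) {
  mode <- match.arg(mode)
  assume <- match.arg(assume)
  counts <- if (is.character(formula)) parseFormula(formula) else formula
  counts <- counts[order(names(counts))]
  if (assume == "neutral") {
    if ("H" %in% names(counts)) {
      counts[["H"]] <- counts[["H"]] + 1L
    } else {
      counts <- c(counts, H = 1L)
    }
  }
  m <- formulaMass(counts, mode)
  if (mode == "monoisotopic") round(m, 4) else m
}
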