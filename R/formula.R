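# Molecular formula parsing and ion composition arithmetic.

#' Parse a molecular formula into element counts
#'
#' Accepts Hill-style condensed formulas such as `"C6H12O6"` or `"H2O"`.
#' Multi-letter element symbols are recognized greedily (`"Na"` is sodium,
#' not nitrogen + a stray letter).
#'
#' @param formula character scalar, e.g. `"C6H12O6"`.
#' @return Named integer vector of positive element counts.
#' @export
#' @examples
#' parse_formula("C6H12O6")
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  if (is.na(formula) || !nzchar(formula)) {
    stop("empty molecular formula")
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop("unparseable molecular formula: ", formula)
  }
  elements <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  if (any(counts <= 0L)) stop("non-positive element count in ", formula)
  sums <- tapply(counts, elements, sum)
  out <- setNames(as.integer(sums), names(sums))
  out <- out[order(names(out))]
  unknown <- setdiff(names(out), isotope_elements())
  if (length(unknown)) {
    stop("unknown element(s) in ", formula, ": ",
         paste(unknown, collapse = ", "))
  }
  out
}

# Render element counts back to a condensed formula string (alphabetical).
format_composition <- function(counts) {
  counts <- counts[counts > 0L]
  paste0(names(counts), ifelse(counts > 1L, counts, ""), collapse = "")
}

#' Apply an adduct to a molecular formula
#'
#' An adduct is written `"+X"` (attach one atom of X) or `"-X"` (remove one),
#' optionally chained (`"+Na-H2"` style is not needed here; single terms with
#' an optional count such as `"-H"`, `"+K"` are supported, plus the composite
#' `"+X-2H"` family used for some negative-mode adducts).
#'
#' @param formula neutral molecular formula string.
#' @param adduct adduct specification, e.g. `"+H"`, `"+Na"`, `"-H"`, `"+Cl"`.
#' @param polarity `"positive"` or `"negative"`; sets the charge sign.
#' @return A list with `composition` (named integer vector), `charge`
#'   (+1 or -1) and `mz` (monoisotopic m/z of the ion including the electron
#'   mass correction).
#' @export
#' @examples
#' ion_formula("H2O", "+H", "positive")
ion_formula <- function(formula, adduct, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  comp <- parse_formula(formula)
  terms <- parse_adduct(adduct)
  for (i in seq_len(nrow(terms))) {
    el <- terms$element[i]
    delta <- terms$n[i]
    cur <- if (el %in% names(comp)) comp[[el]] else 0L
    new <- cur + delta
    if (new < 0L) {
      stop("invalid ion: adduct ", adduct, " removes ", -delta, " ", el,
           " from ", formula, " which has only ", cur)
    }
    comp[el] <- new
  }
  comp <- comp[comp > 0L]
  comp <- comp[order(names(comp))]
  if (!length(comp)) stop("invalid ion: empty composition")
  charge <- if (polarity == "positive") 1L else -1L
  mass <- monoisotopic_mass(comp)
  mz <- (mass - charge * ELECTRON_MASS) / abs(charge)
  list(composition = comp, charge = charge, mz = mz)
}

# Parse an adduct string into a data.frame of (element, signed count).
parse_adduct <- function(adduct) {
  stopifnot(is.character(adduct), length(adduct) == 1L, nzchar(adduct))
  m <- gregexpr("([+-])([0-9]*)([A-Z][a-z]?)", adduct)[[1]]
  tokens <- regmatches(adduct, list(m))[[1]]
  if (!length(tokens) || sum(attr(m, "match.length")) != nchar(adduct)) {
    stop("unparseable adduct: ", adduct)
  }
  sign <- ifelse(substr(tokens, 1, 1) == "+", 1L, -1L)
  body <- substring(tokens, 2)
  n <- as.integer(ifelse(grepl("^[0-9]", body), sub("[A-Za-z]+$", "", body), "1"))
  element <- sub("^[0-9]*", "", body)
  data.frame(element = element, n = sign * n, stringsAsFactors = FALSE)
}

# Monoisotopic (principal-isotope) mass of a composition.
monoisotopic_mass <- function(composition) {
  tab <- isotope_table()
  total <- 0
  for (el in names(composition)) {
    iso <- tab[[el]]
    total <- total + composition[[el]] * iso$mass[which.max(iso$abundance)]
  }
  total
}
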