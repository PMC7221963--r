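# Exact-mass and formula arithmetic: every calculated m/z, ppm error and
# ring-double-bond (RDB) value in the package derives from these functions.

# Atomic-mass constants are pinned to 7 decimals in a versioned plain-text
# file so downstream values are bit-stable.
.atomic_masses <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "atomic_masses.tsv",
                          package = "teaphenolics", mustWork = TRUE)
      tab <- utils::read.delim(path, stringsAsFactors = FALSE)
      cache <<- stats::setNames(tab$monoisotopic_mass, tab$element)
    }
    cache
  }
})

#' Mass of a proton in Da
#'
#' The `[M - H]-` convention used throughout subtracts the proton mass
#' (1.007276 Da) from the neutral monoisotopic mass; the electron mass is
#' neglected, which reproduces printed 4-decimal calc values on QqTOF data.
#' @export
PROTON_MASS <- 1.007276

#' Round half away from zero
#'
#' Decimal rounding with ties going up in magnitude (the convention of the
#' printed tables), unlike [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Parse a Hill-notation elemental formula
#'
#' Accepts concatenated `Element[count]` tokens (`"C15H14O6"`); an omitted
#' count means 1. Returns an `elemental_formula`: a named integer vector of
#' element counts.
#'
#' @param text formula string, e.g. `"C7H14N2O3"`.
#' @return named integer vector of class `elemental_formula`.
#' @examples
#' parse_formula("C15H14O6")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  masses <- .atomic_masses()
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (paste(tokens, collapse = "") != text) {
    stop("cannot parse formula string: ", sQuote(text))
  }
  elems <- sub("[0-9]*$", "", tokens)
  counts <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", tokens)))
  counts[is.na(counts)] <- 1L
  unknown <- setdiff(elems, names(masses))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  if (any(counts <= 0L)) stop("zero counts are not allowed in a formula")
  out <- tapply(counts, factor(elems, levels = unique(elems)), sum)
  structure(stats::setNames(as.integer(out), names(out)),
            class = "elemental_formula")
}

.as_formula <- function(f) {
  if (inherits(f, "elemental_formula")) return(f)
  if (is.character(f)) return(parse_formula(f))
  stopifnot(is.numeric(f), !is.null(names(f)), all(f >= 0))
  structure(stats::setNames(as.integer(f), names(f)),
            class = "elemental_formula")
}

#' Format a formula in canonical Hill order
#'
#' Carbon first, hydrogen second, remaining elements alphabetical; counts of
#' one are omitted. `format_formula(parse_formula(x))` round-trips any
#' canonical input.
#'
#' @param f `elemental_formula` or formula string.
#' @return single string.
#' @export
format_formula <- function(f) {
  f <- .as_formula(f)
  f <- f[f > 0]
  elems <- names(f)
  rest <- sort(setdiff(elems, c("C", "H")))
  ord <- c(intersect(c("C", "H"), elems), rest)
  paste0(vapply(ord, function(e) {
    if (f[[e]] == 1L) e else paste0(e, f[[e]])
  }, character(1)), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula>", format_formula(x), "\n")
  invisible(x)
}

#' Element-wise sum of two formulas
#'
#' @param f,g formulas (objects or strings).
#' @return `elemental_formula` with summed counts.
#' @export
formula_add <- function(f, g) {
  f <- .as_formula(f); g <- .as_formula(g)
  elems <- union(names(f), names(g))
  out <- stats::setNames(integer(length(elems)), elems)
  out[names(f)] <- out[names(f)] + f
  out[names(g)] <- out[names(g)] + g
  structure(out, class = "elemental_formula")
}

#' Monoisotopic mass of a neutral formula
#'
#' Sum of count times the standard monoisotopic atomic mass (C 12 exactly,
#' H 1.0078250, N 14.0030740, O 15.9949146, ...).
#'
#' @param f formula object or string.
#' @return mass in Da.
#' @examples
#' monoisotopic_mass("C6H10O5")  # hexose residue, 162.0528
#' @export
monoisotopic_mass <- function(f) {
  f <- .as_formula(f)
  f <- f[f > 0]
  if (!length(f)) stop("empty formula has no mass")
  masses <- .atomic_masses()
  sum(masses[names(f)] * as.numeric(f))
}

#' m/z of the deprotonated molecular ion [M - H]-
#'
#' Neutral monoisotopic mass minus [PROTON_MASS]. Use `digits = NA` for the
#' unrounded value; the default rounds half-up to 4 decimals as in printed
#' tables.
#'
#' @param f formula object or string (must contain hydrogen).
#' @param digits decimals for reporting, or `NA` for no rounding.
#' @return m/z in Da.
#' @examples
#' deprotonated_mz("C15H14O6")  # catechin, 289.0718
#' @export
deprotonated_mz <- function(f, digits = 4) {
  f <- .as_formula(f)
  if (is.na(match("H", names(f))) || f[["H"]] < 1L) {
    stop("formula has no hydrogen to lose")
  }
  mz <- monoisotopic_mass(f) - PROTON_MASS
  if (is.na(digits)) mz else round_half_up(mz, digits)
}

#' m/z of the radical anion [M - 2H].-
#'
#' One hydrogen atom (1.0078250 Da) below the even-electron `[M - H]-` ion;
#' the channel behind radical aglycones of 3-O-glycosylated flavonols.
#'
#' @inheritParams deprotonated_mz
#' @return m/z in Da.
#' @export
radical_anion_mz <- function(f, digits = 4) {
  f <- .as_formula(f)
  if (is.na(match("H", names(f))) || f[["H"]] < 2L) {
    stop("formula needs at least two hydrogens")
  }
  mz <- monoisotopic_mass(f) - PROTON_MASS - .atomic_masses()[["H"]]
  if (is.na(digits)) mz else round_half_up(mz, digits)
}

#' Signed mass error in parts per million
#'
#' `(found - calc) / calc * 1e6`, rounded half-up to 1 decimal by default.
#'
#' @param found_mz observed m/z.
#' @param calc_mz calculated m/z (> 0).
#' @param digits decimals for reporting, or `NA`.
#' @return signed ppm error.
#' @export
ppm_error <- function(found_mz, calc_mz, digits = 1) {
  if (any(calc_mz <= 0)) stop("calc_mz must be positive")
  ppm <- (found_mz - calc_mz) / calc_mz * 1e6
  if (is.na(digits)) ppm else round_half_up(ppm, digits)
}

#' Ring double bond equivalents
#'
#' Degrees of unsaturation of the neutral formula: C - H/2 + N/2 + 1.
#' Monovalent halogens count against like hydrogen.
#'
#' @param f formula object or string over C/H/N/O (halogens allowed).
#' @return half-integer RDB value.
#' @examples
#' rdb("C15H14O6")  # catechin, 9
#' @export
rdb <- function(f) {
  f <- .as_formula(f)
  cnt <- function(e) if (e %in% names(f)) f[[e]] else 0L
  halides <- cnt("Cl")
  cnt("C") - (cnt("H") + halides) / 2 + cnt("N") / 2 + 1
}
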