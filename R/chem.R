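# Elemental-formula arithmetic and derivatization mass chemistry.
#
# Formulas are named numeric vectors of non-negative element counts, in
# Hill-like string notation with bracketed isotope labels, e.g. "C2H5NO2"
# or "[13C]2[2H]2[15N]C2HO2" (the doubly-labeled glycine internal standard
# written as labeled atoms plus the remaining natural atoms).

# IUPAC/CODATA monoisotopic atomic masses (Da). Bracketed symbols denote
# atoms fixed at the named heavy isotope, as in isotope-labeled internal
# standards.
.element_masses <- c(
  C      = 12.0,
  H      = 1.00782503207,
  N      = 14.0030740048,
  O      = 15.9949146196,
  S      = 31.97207100,
  P      = 30.97376163,
  Cl     = 34.96885268,
  Na     = 22.9897692809,
  K      = 38.96370668,
  "[13C]" = 13.0033548378,
  "[2H]"  = 2.01410177785,
  "[15N]" = 15.0001088989
)

#' Monoisotopic mass of a proton (Da)
#'
#' Mass of H minus the electron mass; added per charge for positive-mode
#' (M+H)+ ions.
#' @export
proton_mass <- 1.00727646688

#' Parse an elemental formula string
#'
#' Accepts Hill-like notation with optional bracketed isotope labels:
#' `"C3H7NO3"`, `"[13C]4C6H11NO4"`. A count of 1 may be omitted. The empty
#' string is the empty formula (mass 0).
#'
#' @param x A single formula string, or an already-parsed named numeric
#'   vector (returned unchanged after validation).
#' @return Named numeric vector of element counts.
#' @examples
#' parse_formula("C2H5NO2")
#' parse_formula("[13C]2[2H]2[15N]H3O2")
#' @export
parse_formula <- function(x) {
  if (is.numeric(x)) {
    .validate_formula(x)
    return(x)
  }
  stopifnot(is.character(x), length(x) == 1L)
  x <- trimws(x)
  if (x == "" || x == "{}") {
    out <- numeric(0)
    names(out) <- character(0)
    return(out)
  }
  pat <- "(\\[[0-9]+[A-Z][a-z]?\\]|[A-Z][a-z]?)([0-9]*)"
  m <- gregexpr(pat, x, perl = TRUE)[[1]]
  tokens <- regmatches(x, gregexpr(pat, x, perl = TRUE))[[1]]
  if (sum(attr(m, "match.length")) != nchar(x)) {
    stop("malformed formula string: '", x, "'", call. = FALSE)
  }
  sym <- sub("^(\\[[0-9]+[A-Z][a-z]?\\]|[A-Z][a-z]?)[0-9]*$", "\\1", tokens)
  cnt <- sub("^(\\[[0-9]+[A-Z][a-z]?\\]|[A-Z][a-z]?)([0-9]*)$", "\\2", tokens)
  cnt <- ifelse(cnt == "", 1L, as.integer(cnt))
  counts <- tapply(cnt, sym, sum)
  out <- as.numeric(counts)
  names(out) <- names(counts)
  .validate_formula(out)
  out
}

.validate_formula <- function(counts) {
  if (length(counts) == 0L) return(invisible(counts))
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stop("formula counts must be a named vector", call. = FALSE)
  }
  unknown <- setdiff(names(counts), names(.element_masses))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts < 0)) stop("negative element counts", call. = FALSE)
  invisible(counts)
}

#' Add or subtract elemental formulas
#'
#' @param a,b Formulas (strings or named count vectors).
#' @return Named count vector. Subtraction errors if any count would go
#'   negative.
#' @export
formula_add <- function(a, b) {
  a <- parse_formula(a); b <- parse_formula(b)
  sym <- union(names(a), names(b))
  out <- vapply(sym, function(s) {
    sum(a[names(a) == s], b[names(b) == s])
  }, numeric(1))
  out[out != 0]
}

#' @rdname formula_add
#' @export
formula_subtract <- function(a, b) {
  a <- parse_formula(a); b <- parse_formula(b)
  sym <- union(names(a), names(b))
  out <- vapply(sym, function(s) {
    sum(a[names(a) == s]) - sum(b[names(b) == s])
  }, numeric(1))
  if (any(out < 0)) {
    stop("formula subtraction yields negative count for: ",
         paste(sym[out < 0], collapse = ", "), call. = FALSE)
  }
  out[out != 0]
}

#' Monoisotopic mass of an elemental formula
#'
#' Sums element counts times monoisotopic atomic masses. Bracketed
#' isotope-labeled atoms (`[13C]`, `[2H]`, `[15N]`) use the labeled
#' isotope's mass, so isotope-labeled internal standards get their true
#' (heavy) mass.
#'
#' @param formula Formula string or named count vector.
#' @return Mass in Da (0 for the empty formula).
#' @examples
#' monoisotopic_mass("H2O")     # 18.010565
#' monoisotopic_mass("C2H5NO2") # glycine, 75.032028
#' @export
monoisotopic_mass <- function(formula) {
  f <- parse_formula(formula)
  if (length(f) == 0L) return(0)
  sum(f * .element_masses[names(f)])
}

#' Derivatization schemes
#'
#' Net per-site neutral mass shifts for the two derivatization chemistries:
#' dansylation of primary amines (dansyl chloride C12H12ClNO2S minus HCl)
#' and O-benzylhydroxylamine (O-BHA, C7H9NO minus H2O) condensation with
#' carboxyls (amide) or ketones/aldehydes (oxime) — both O-BHA products
#' share one net shift. Shifts are additive across sites.
#'
#' @param scheme One of `"dansyl"`, `"obha"`, `"none"`.
#' @return Neutral mass delta per derivatized site, in Da.
#' @examples
#' derivatization_shift("dansyl") # +233.051049 (C12H11NO2S)
#' derivatization_shift("obha")   # +105.057849 (C7H7N)
#' @export
derivatization_shift <- function(scheme = c("dansyl", "obha", "none")) {
  scheme <- match.arg(scheme)
  switch(scheme,
    dansyl = monoisotopic_mass(formula_subtract("C12H12ClNO2S", "HCl")),
    obha   = monoisotopic_mass(formula_subtract("C7H9NO", "H2O")),
    none   = {
      warning("derivatization scheme 'none': zero mass shift", call. = FALSE)
      0
    }
  )
}

#' Theoretical m/z of a derivatized, protonated compound
#'
#' @param formula Neutral compound formula (string or named vector).
#' @param n_sites Number of derivatized sites (>= 0).
#' @param scheme Derivatization scheme (see [derivatization_shift()]).
#' @param charge Positive charge state; `charge` protons are added
#'   (positive mode, MH+ and multiply protonated ions).
#' @return Theoretical m/z.
#' @examples
#' derivatized_mz("C3H7NO3", 1, "dansyl") # dansyl-serine MH+, 339.100919
#' @export
derivatized_mz <- function(formula, n_sites, scheme = "dansyl", charge = 1L) {
  stopifnot(length(n_sites) == 1L, n_sites >= 0, n_sites == round(n_sites))
  stopifnot(length(charge) == 1L, charge >= 1, charge == round(charge))
  shift <- if (n_sites > 0) derivatization_shift(scheme) else 0
  (monoisotopic_mass(formula) + n_sites * shift + charge * proton_mass) /
    charge
}

#' Signed mass accuracy in parts per million
#'
#' @param observed_mz,theoretical_mz m/z values; `theoretical_mz` must be
#'   positive.
#' @return `(observed - theoretical) / theoretical * 1e6` (vectorized).
#' @export
ppm_error <- function(observed_mz, theoretical_mz) {
  if (any(theoretical_mz <= 0)) {
    stop("theoretical m/z must be positive", call. = FALSE)
  }
  (observed_mz - theoretical_mz) / theoretical_mz * 1e6
}
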