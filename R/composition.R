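# Elemental compositions: the substrate of all mass and pattern arithmetic.

.SUPPORTED_ELEMENTS <- c("C", "H", "N", "O", "S")

new_composition <- function(counts) {
  full <- stats::setNames(integer(length(.SUPPORTED_ELEMENTS)), .SUPPORTED_ELEMENTS)
  full[names(counts)] <- as.integer(round(counts))
  structure(full, class = "elemental_composition")
}

#' Construct or parse an elemental composition
#'
#' Accepts a molecular formula string such as `"C63H104N18O20"`, a named
#' numeric vector of element counts, or an existing composition. Supported
#' elements are C, H, N, O and S; counts must be non-negative integers with
#' at least one atom overall.
#'
#' @param x formula string, named count vector, or `elemental_composition`.
#' @return An `elemental_composition` (named integer vector over C,H,N,O,S).
#' @examples
#' as_composition("C6H10NO4")
#' as_composition(c(C = 2, H = 5, N = 1, O = 2))
#' @export
as_composition <- function(x) {
  if (inherits(x, "elemental_composition")) {
    return(x)
  }
  if (is.character(x) && length(x) == 1L) {
    counts <- parse_formula(x)
  } else if (is.numeric(x) && !is.null(names(x))) {
    counts <- x
  } else {
    stop("cannot interpret input as an elemental composition")
  }
  bad <- setdiff(names(counts), .SUPPORTED_ELEMENTS)
  if (length(bad)) {
    stop("unsupported element(s): ", paste(bad, collapse = ", "))
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("element counts must be non-negative integers")
  }
  comp <- new_composition(counts)
  if (sum(comp) < 1L) stop("composition must contain at least one atom")
  comp
}

parse_formula <- function(formula) {
  formula <- gsub("[[:space:]_]", "", formula)
  tokens <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!length(tokens) || paste(tokens, collapse = "") != formula) {
    stop("cannot parse formula: ", formula)
  }
  counts <- integer(0)
  for (tok in tokens) {
    el <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  counts
}

#' @export
format.elemental_composition <- function(x, ...) {
  nz <- x[x > 0]
  paste0(names(nz), ifelse(nz > 1, nz, ""), collapse = "")
}

#' @export
print.elemental_composition <- function(x, ...) {
  cat("<elemental composition> ", format(x), "\n", sep = "")
  invisible(x)
}

comp_add <- function(a, b) new_composition(unclass(a) + unclass(b))

comp_subtract <- function(a, b) {
  d <- unclass(a) - unclass(b)
  if (any(d < 0)) stop("composition subtraction would go negative")
  new_composition(d)
}

#' Elemental composition of a peptide from its sequence
#'
#' Sums the residue compositions of the 20 standard amino acids (one-letter
#' codes) and adds one water for the termini, giving the neutral peptide
#' composition.
#'
#' @param sequence peptide string in one-letter amino-acid codes.
#' @param const constants from [isotope_constants()].
#' @return An `elemental_composition`.
#' @examples
#' composition_from_sequence("FVQAGSEVSALLGR")  # C63 H104 N18 O20
#' @export
composition_from_sequence <- function(sequence, const = isotope_constants()) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("sequence must be a single non-empty string")
  }
  aa <- strsplit(toupper(sequence), "")[[1]]
  unknown <- which(!aa %in% names(const$residues))
  if (length(unknown)) {
    stop(
      "unknown residue '", aa[unknown[1]], "' at position ", unknown[1],
      " in sequence ", sequence
    )
  }
  total <- const$water
  for (r in aa) total <- total + const$residues[[r]]
  new_composition(total)
}

#' Monoisotopic mass of a composition
#'
#' Sum of element counts times the lightest-isotope atomic masses.
#'
#' @param comp anything accepted by [as_composition()].
#' @inheritParams composition_from_sequence
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O")  # 18.0106
#' @export
monoisotopic_mass <- function(comp, const = isotope_constants()) {
  comp <- as_composition(comp)
  sum(unclass(comp) * const$masses[names(comp)])
}

#' m/z of a protonated ion
#'
#' `(M + z * proton) / z` for charge `z >= 1`; the electron mass is ignored
#' (protonation model), which stays within 0.001 Da of reference values at
#' peptide masses.
#'
#' @inheritParams monoisotopic_mass
#' @param z positive integer charge.
#' @return m/z in Th.
#' @examples
#' mz_for_charge("C63H104N18O20", 2)  # 717.391
#' @export
mz_for_charge <- function(comp, z, const = isotope_constants()) {
  if (length(z) != 1L || is.na(z) || z < 1 || z != round(z)) {
    stop("charge z must be a positive integer")
  }
  (monoisotopic_mass(comp, const) + z * const$proton) / z
}

#' Number of carbon atoms in a peptide
#'
#' Convenience wrapper: the C count of [composition_from_sequence()]. This
#' sets the number of 13C isotope channels used in protein-turnover
#' modeling.
#'
#' @inheritParams composition_from_sequence
#' @return Integer carbon count.
#' @examples
#' carbon_count("FVQAGSEVSALLGR")  # 63
#' @export
carbon_count <- function(sequence, const = isotope_constants()) {
  unname(composition_from_sequence(sequence, const)["C"])
}
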