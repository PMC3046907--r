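# Theoretical isotope patterns.
#
# A pattern is a normalized vector of relative abundances over integer
# nucleon-shift channels j = 0, 1, 2, ... above a monoisotopic baseline
# mass. Channels aggregate all isotopologues with the same total nucleon
# count (no fine structure), which is the channel model the downstream
# enrichment and turnover methods assume. Multi-element patterns are built
# by polynomial expansion: each element's per-atom isotope distribution is
# raised to its atom count by repeated discrete convolution, and elements
# are then convolved together.

new_pattern <- function(abundance, baseline_mass) {
  abundance <- abundance / sum(abundance)
  structure(
    list(abundance = abundance, baseline_mass = baseline_mass),
    class = "isotope_pattern"
  )
}

#' @export
print.isotope_pattern <- function(x, ...) {
  cat(
    "<isotope pattern> baseline ", sprintf("%.4f", x$baseline_mass),
    " Da, ", length(x$abundance), " channels\n", sep = ""
  )
  ab <- x$abundance
  names(ab) <- paste0("j=", seq_along(ab) - 1L)
  print(round(ab, 6))
  invisible(x)
}

# Plain discrete convolution of two abundance vectors.
conv_vec <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# Drop a negligible trailing tail (guards vector growth during repeated
# convolution without visibly perturbing the final pattern).
drop_tail <- function(x, tol = 1e-18) {
  keep <- which(rev(cumsum(rev(x))) > tol)
  if (!length(keep)) {
    return(x[1L])
  }
  x[seq_len(max(keep))]
}

# Final truncation rule: keep channels until the cumulative abundance
# reaches 1 - tol, then renormalize.
truncate_abundance <- function(x, tol = 1e-10) {
  k <- which(cumsum(x) >= 1 - tol)
  k <- if (length(k)) k[1L] else length(x)
  x <- x[seq_len(k)]
  x / sum(x)
}

# n-fold convolution power of a per-atom isotope distribution.
atom_power <- function(dist, n) {
  out <- 1
  for (i in seq_len(n)) out <- drop_tail(conv_vec(out, dist))
  out
}

# Abundance vector (unnormalized truncation tolerance only) for a whole
# composition at natural abundance; `empty composition` gives the delta.
composition_abundance <- function(comp, const) {
  out <- 1
  for (el in names(comp)) {
    n <- comp[[el]]
    if (n > 0L) {
      out <- drop_tail(conv_vec(out, atom_power(const$abundances[[el]], n)))
    }
  }
  out
}

#' Natural-abundance isotope pattern
#'
#' Theoretical isotope distribution of a composition with every element at
#' its natural isotope abundance, over nucleon-shift channels above the
#' monoisotopic mass.
#'
#' @param comp anything accepted by [as_composition()].
#' @param const constants from [isotope_constants()].
#' @return An `isotope_pattern`: normalized channel abundances plus the
#'   monoisotopic baseline mass.
#' @examples
#' natural_pattern("C6H10NO4")
#' @export
natural_pattern <- function(comp, const = isotope_constants()) {
  comp <- as_composition(comp)
  ab <- composition_abundance(comp, const)
  new_pattern(truncate_abundance(ab), monoisotopic_mass(comp, const))
}

#' Isotope pattern with enriched carbons
#'
#' Assigns `n_enriched` of the composition's carbon atoms a 13C abundance
#' of `p` (binomial labeling model) and leaves every remaining atom at
#' natural abundance; the two parts are combined by convolution. With
#' `p` equal to the natural 13C abundance this reproduces
#' [natural_pattern()]; with `p` near 1 the envelope concentrates at shift
#' `n_enriched`.
#'
#' @inheritParams natural_pattern
#' @param n_enriched number of carbons carrying enrichment `p`
#'   (`0 <= n_enriched <=` carbon count).
#' @param p 13C isotope abundance of the enriched carbons, in `[0, 1]`.
#' @return An `isotope_pattern`.
#' @examples
#' # Asp MCF fragment: 3 analyte carbons at 99 atom% shift the top peak to j=3
#' enriched_pattern("C6H10NO4", 3, 0.99)
#' @export
enriched_pattern <- function(comp, n_enriched, p, const = isotope_constants()) {
  comp <- as_composition(comp)
  if (length(n_enriched) != 1L || n_enriched < 0 || n_enriched != round(n_enriched)) {
    stop("n_enriched must be a single non-negative integer")
  }
  if (n_enriched > comp[["C"]]) {
    stop(
      "n_enriched (", n_enriched, ") exceeds the carbon count (",
      comp[["C"]], ")"
    )
  }
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("enrichment p must be a single value in [0, 1]")
  }
  residual <- unclass(comp)
  residual["C"] <- residual["C"] - as.integer(n_enriched)
  lab <- stats::dbinom(0:n_enriched, n_enriched, p)
  nat <- composition_abundance(residual, const)
  ab <- drop_tail(conv_vec(lab, nat))
  new_pattern(truncate_abundance(ab), monoisotopic_mass(comp, const))
}

#' Convolve two isotope patterns
#'
#' Discrete convolution of the channel abundances; baseline masses add.
#' This is the composition rule for patterns of disjoint atom sets.
#'
#' @param a,b `isotope_pattern` objects.
#' @return An `isotope_pattern`.
#' @export
pattern_convolve <- function(a, b) {
  stopifnot(inherits(a, "isotope_pattern"), inherits(b, "isotope_pattern"))
  ab <- drop_tail(conv_vec(a$abundance, b$abundance))
  new_pattern(truncate_abundance(ab), a$baseline_mass + b$baseline_mass)
}

#' Beta-binomial probability mass function
#'
#' Parameterized by the mean success probability `p` and the intra-class
#' correlation `rho` (`rho = 0` reduces exactly to the binomial;
#' `rho -> 1` concentrates mass on 0 and `n`). Used as the per-carbon
#' labeling model of peptide populations, where `rho` absorbs
#' overdispersion from precursor-pool heterogeneity.
#'
#' @param k quantile vector (number of 13C atoms).
#' @param n number of trials (carbon count).
#' @param p mean 13C probability in `[0, 1]`.
#' @param rho intra-class correlation in `[0, 1)`.
#' @return Probabilities `P(K = k)`.
#' @examples
#' dbetabinom(0:2, 2, 0.5, 0)  # 0.25 0.50 0.25
#' @export
dbetabinom <- function(k, n, p, rho) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (p <= 0) {
    return(as.numeric(k == 0L))
  }
  if (p >= 1) {
    return(as.numeric(k == n))
  }
  if (rho < 1e-12) {
    return(stats::dbinom(k, n, p))
  }
  a <- p * (1 - rho) / rho
  b <- (1 - p) * (1 - rho) / rho
  exp(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
}

#' Beta-binomial isotope envelope of a peptide population
#'
#' Channel distribution of a peptide population whose `nC` carbons are
#' labeled under a beta-binomial model with mean enrichment `p` and
#' overdispersion `rho`, convolved with the natural-abundance pattern of
#' the peptide's non-carbon atoms (`residual_comp`), which is what places
#' signal in the channels beyond `nC` (15N, 2H, 18O, ...).
#'
#' @param nC number of carbon atoms.
#' @inheritParams dbetabinom
#' @param residual_comp composition of the non-carbon atoms (or a
#'   composition whose pattern should be convolved in); `NULL` for none.
#' @param const constants from [isotope_constants()].
#' @return An `isotope_pattern` over shifts `0..nC + tail`.
#' @export
beta_binomial_envelope <- function(nC, p, rho, residual_comp = NULL,
                                   const = isotope_constants()) {
  if (length(nC) != 1L || nC < 1 || nC != round(nC)) {
    stop("nC must be a single positive integer")
  }
  lab <- dbetabinom(0:nC, nC, p, rho)
  base <- const$masses[["C"]] * nC
  if (!is.null(residual_comp)) {
    residual_comp <- as_composition(residual_comp)
    nat <- composition_abundance(unclass(residual_comp), const)
    lab <- drop_tail(conv_vec(lab, nat))
    base <- base + monoisotopic_mass(residual_comp, const)
  }
  new_pattern(truncate_abundance(lab), base)
}
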