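# Brute-force isotope-pattern oracle: enumerate every isotope assignment
# of every atom and bin the joint probabilities by total nucleon shift.
# Exponential in atom count; intended for compositions of <= ~6 atoms.
brute_force_pattern <- function(comp, const = isotope_constants()) {
  comp <- as_composition(comp)
  atoms <- rep(names(comp), unclass(comp))
  dists <- lapply(atoms, function(el) const$abundances[[el]])
  grid <- expand.grid(lapply(dists, function(d) seq_along(d) - 1L))
  prob <- apply(grid, 1L, function(row) {
    prod(mapply(function(d, j) d[j + 1L], dists, row))
  })
  shifts <- rowSums(grid)
  ab <- numeric(max(shifts) + 1L)
  for (i in seq_along(prob)) {
    ab[shifts[i] + 1L] <- ab[shifts[i] + 1L] + prob[i]
  }
  ab
}

# The engine's published truncation rule, applied to oracle output so both
# sides are compared on the same support.
truncate_like_engine <- function(ab, tol = 1e-10) {
  k <- which(cumsum(ab) >= 1 - tol)
  k <- if (length(k)) k[1L] else length(ab)
  ab <- ab[seq_len(k)]
  ab / sum(ab)
}

# All CHNO compositions with at most `max_atoms` atoms (at least one).
chno_compositions <- function(max_atoms = 5L) {
  grid <- expand.grid(C = 0:max_atoms, H = 0:max_atoms, N = 0:max_atoms, O = 0:max_atoms)
  grid <- grid[rowSums(grid) >= 1L & rowSums(grid) <= max_atoms, ]
  lapply(seq_len(nrow(grid)), function(i) {
    as_composition(c(
      C = grid$C[i], H = grid$H[i], N = grid$N[i], O = grid$O[i]
    ))
  })
}
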