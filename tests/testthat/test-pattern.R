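test_that("natural pattern of a two-carbon species matches the binomial expansion", {
  const <- isotope_constants()
  p13 <- const$abundances$C[2]
  pat <- natural_pattern("C2")
  expect_equal(pat$abundance, dbinom(0:2, 2, p13), tolerance = 1e-12)
  expect_equal(sum(pat$abundance), 1, tolerance = 1e-9)
})

test_that("zeroing the heavy-carbon abundance collapses the carbon pattern", {
  cfg <- tempfile()
  writeLines("abundance.C.1=0", cfg)
  pat <- natural_pattern("C", const = isotope_constants(cfg))
  expect_equal(pat$abundance, 1)
})

test_that("the Asp MCF fragment peaks at the monoisotopic channel naturally", {
  pat <- natural_pattern("C6H10NO4")
  expect_equal(which.max(pat$abundance) - 1L, 0L)
})

test_that("patterns are normalized and non-negative for assorted compositions", {
  for (f in c("C6H10NO4", "C63H104N18O20", "S2", "C10H20N5O5S")) {
    pat <- natural_pattern(f)
    expect_gte(min(pat$abundance), 0)
    expect_equal(sum(pat$abundance), 1, tolerance = 1e-9)
  }
})

test_that("enriching 3 of 6 fragment carbons to 99 atom% moves the top peak to shift 3", {
  pat <- enriched_pattern("C6H10NO4", 3, 0.99)
  expect_equal(which.max(pat$abundance) - 1L, 3L)
})

test_that("enrichment edge cases: none enriched, certainty, natural abundance", {
  # n = 0 leaves the natural pattern untouched
  a <- enriched_pattern("C6H10NO4", 0, 0.42)$abundance
  b <- natural_pattern("C6H10NO4")$abundance
  expect_equal(a, b, tolerance = 1e-12)

  # all-carbon species at p = 1 is a delta at shift n
  pat <- enriched_pattern("C3", 3, 1.0)
  expect_equal(pat$abundance, c(0, 0, 0, 1))

  # p equal to natural 13C abundance reproduces the natural pattern
  const <- isotope_constants()
  e <- enriched_pattern("C6H10NO4", 6, const$abundances$C[2])$abundance
  n <- natural_pattern("C6H10NO4")$abundance
  len <- min(length(e), length(n))
  expect_lt(max(abs(e[1:len] - n[1:len])), 1e-12)

  expect_error(enriched_pattern("C2H4", 3, 0.5), "exceeds the carbon count")
  expect_error(enriched_pattern("C2H4", 1, 1.5), "in \\[0, 1\\]")
})

test_that("pattern convolution has a delta identity and is commutative", {
  x <- natural_pattern("C4H7NO2")
  delta <- isochase:::new_pattern(1, 0)
  expect_equal(pattern_convolve(x, delta)$abundance, x$abundance, tolerance = 1e-12)
  expect_equal(pattern_convolve(x, delta)$baseline_mass, x$baseline_mass)

  a <- natural_pattern("C3H5S")
  b <- natural_pattern("N2O3")
  ab <- pattern_convolve(a, b)
  ba <- pattern_convolve(b, a)
  expect_equal(ab$abundance, ba$abundance, tolerance = 1e-14)
  expect_equal(ab$baseline_mass, ba$baseline_mass)
})

test_that("convolving two one-carbon patterns reproduces C2 and the brute-force oracle", {
  c1 <- natural_pattern("C")
  c2 <- pattern_convolve(c1, c1)
  expect_equal(c2$abundance, natural_pattern("C2")$abundance, tolerance = 1e-12)
  oracle <- truncate_like_engine(brute_force_pattern("C2"))
  expect_equal(c2$abundance, oracle, tolerance = 1e-12)
})

test_that("pattern engine matches brute-force enumeration on small mixed compositions", {
  for (f in c("CHNO", "C2O2", "H3NS", "C2H2O")) {
    engine <- natural_pattern(f)$abundance
    oracle <- truncate_like_engine(brute_force_pattern(f))
    len <- max(length(engine), length(oracle))
    pad <- function(x) c(x, numeric(len - length(x)))
    expect_lt(max(abs(pad(engine) - pad(oracle))), 1e-12)
  }
})

test_that("beta-binomial pmf has binomial and polarized limits", {
  expect_equal(dbetabinom(0:2, 2, 0.5, 0), c(0.25, 0.5, 0.25))
  expect_equal(sum(dbetabinom(0:10, 10, 0.3, 0.2)), 1, tolerance = 1e-12)
  # rho -> 1 concentrates mass on the extremes
  polar <- dbetabinom(0:2, 2, 0.5, 0.999)
  expect_gt(polar[1] + polar[3], 0.999)
  expect_error(dbetabinom(0, 2, 0.5, 1), "rho")
  expect_error(dbetabinom(0, 2, 2, 0.1), "p must")
})

test_that("beta-binomial envelope at natural abundance equals the natural pattern", {
  comp <- as_composition("C6H10NO4")
  const <- isotope_constants()
  env <- beta_binomial_envelope(6, const$abundances$C[2], 0,
    residual_comp = c(H = 10, N = 1, O = 4)
  )
  nat <- natural_pattern(comp)
  len <- min(length(env$abundance), length(nat$abundance))
  expect_lt(max(abs(env$abundance[1:len] - nat$abundance[1:len])), 1e-9)
})
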