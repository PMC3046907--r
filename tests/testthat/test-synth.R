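test_that("a pure-spike envelope without noise is exactly the natural pattern", {
  x <- simulate_envelope("IGLFGGAGVGK", w_nat = 1, w_new = 0, w_old = 0)
  comp <- composition_from_sequence("IGLFGGAGVGK")
  nat <- natural_pattern(comp)$abundance
  J <- length(x)
  expected <- numeric(J)
  expected[seq_len(min(J, length(nat)))] <- nat[seq_len(min(J, length(nat)))]
  expect_equal(x, expected / sum(expected), tolerance = 1e-12)
})

test_that("the t=0 spike envelope is bimodal: natural plus fully labeled", {
  x <- simulate_envelope("FVQAGSEVSALLGR",
    w_nat = 0.2, w_new = 0, w_old = 0.8,
    p_old = 0.93, rho = 0.001
  )
  # global maximum inside the labeled cluster near j = 63 * 0.93
  expect_lt(abs(which.max(x) - 1L - 63 * 0.93), 3)
  # a second local maximum at the monoisotopic channel
  expect_gt(x[1], x[2])
  expect_gt(x[1], 0.5 * max(x))
})

test_that("envelope simulation is reproducible under a fixed seed", {
  a <- simulate_envelope("IGLFGGAGVGK",
    w_nat = 0.2, w_new = 0.3, w_old = 0.5,
    noise_cv = 0.1, noise_floor = 0.01, seed = 42
  )
  b <- simulate_envelope("IGLFGGAGVGK",
    w_nat = 0.2, w_new = 0.3, w_old = 0.5,
    noise_cv = 0.1, noise_floor = 0.01, seed = 42
  )
  expect_identical(a, b)
  expect_error(simulate_envelope("G", w_nat = 0.5, w_new = 0.2, w_old = 0.2), "sum to 1")
})

test_that("noise-free GC-MS series reproduce the decay curve through Rt exactly", {
  s <- simulate_gcms_series("C6H10NO4", 3,
    k = 0.08, plateau = 0.15,
    timepoints_h = c(0, 5, 10, 30, 60)
  )
  refs <- reference_distributions("C6H10NO4", 3)
  rt <- apply(as.matrix(s[, c("m1", "m2", "m3")]), 1, function(em) {
    relative_isotope_abundance(em, refs$SM, refs$TM)
  })
  expect_equal(unname(rt), s$r_true, tolerance = 1e-9)
  expect_equal(s$r_true, (1 - 0.15) * exp(-0.08 * s$time_h) + 0.15)
})

test_that("a fully labeled fragment peaks at shift 3 like the Asp m/z 163 ion", {
  s <- simulate_gcms_series("C6H10NO4", 3, k = 0.1, timepoints_h = 0)
  em <- as.numeric(s[1, paste0("m", 0:3)])
  expect_equal(which.max(em) - 1L, 3L)
})

test_that("chase simulation writes reproducible fixtures with a truth sidecar", {
  sc <- chase_scenario(
    sequences = "IGLFGGAGVGK", charges = 2L,
    timepoints_h = c(0, 24), seed = 99
  )
  d1 <- tempfile()
  d2 <- tempfile()
  p1 <- simulate_chase(sc, d1)
  p2 <- simulate_chase(sc, d2)
  expect_identical(readLines(p1$spectra[1]), readLines(p2$spectra[1]))
  expect_identical(readLines(p1$ids), readLines(p2$ids))

  truth <- read.delim(p1$truth)
  expect_equal(truth$time_point_h, c(0, 24))
  expect_equal(truth$half_life_h, rep(log(2) / sc$k, 2))
  expect_equal(truth$dar, sc$dar0 * exp(-sc$k * c(0, 24)))
  # DAR identity holds in the generated weights
  expect_equal(truth$w_old / truth$w_new, truth$dar, tolerance = 1e-12)
})

test_that("without turnover the generated old:new ratio is constant", {
  sc <- chase_scenario(
    sequences = "IGLFGGAGVGK", charges = 2L,
    k = 0, timepoints_h = c(0, 24, 48), seed = 5
  )
  d <- tempfile()
  paths <- simulate_chase(sc, d)
  truth <- read.delim(paths$truth)
  expect_equal(diff(range(truth$w_old / truth$w_new)), 0, tolerance = 1e-12)
})

test_that("doubling the scan interval halves the scan count", {
  sc1 <- chase_scenario(
    sequences = "IGLFGGAGVGK", charges = 2L,
    timepoints_h = 0, scan_interval_s = 1, seed = 3
  )
  sc2 <- chase_scenario(
    sequences = "IGLFGGAGVGK", charges = 2L,
    timepoints_h = 0, scan_interval_s = 2, seed = 3
  )
  n1 <- length(read_peaklist(simulate_chase(sc1, tempfile())$spectra[1])$scans)
  n2 <- length(read_peaklist(simulate_chase(sc2, tempfile())$spectra[1])$scans)
  expect_lte(abs(n1 - 2 * n2), 2)
})

test_that("scenario validation catches bad spike fractions and time grids", {
  expect_error(chase_scenario(spike_fraction = 1.5), "spike_fraction")
  expect_error(chase_scenario(timepoints_h = c(24, 48)), "include 0")
  expect_error(chase_scenario(sequences = c("GG", "AA"), charges = 2L), "match")
})
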