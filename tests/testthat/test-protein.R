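# Helper: an xic_matrix built directly from a common elution profile.
make_xic <- function(coefs, profile = NULL, nscans = 301) {
  if (is.null(profile)) {
    t <- seq_len(nscans)
    profile <- exp(-(t - nscans / 2)^2 / (2 * (nscans / 10)^2))
  }
  mat <- outer(profile, coefs)
  structure(
    list(
      intensity = mat,
      scan_rt = seq_along(profile),
      channels = build_channels(700, 2, length(coefs) - 7L),
      window = c(1, length(profile))
    ),
    class = "xic_matrix"
  )
}

test_that("channel sets have nC+7 channels spaced by the 13C defect over z", {
  ch <- build_channels(717.391, 2, 63)
  expect_length(ch$mz, 70)
  expect_equal(ch$mz[1], 717.391)
  expect_equal(ch$mz[2], 717.8927, tolerance = 1e-4 / 718)
  expect_equal(unique(round(diff(ch$mz), 12)), 1.003355 / 2, tolerance = 1e-9)

  ch1 <- build_channels(100, 1, 3)
  expect_equal(ch1$mz, 100 + (0:9) * 1.003355)
  expect_equal(ch1$mz[10], 109.030195)
  expect_error(build_channels(100, 0, 3), "positive integer")
})

test_that("XIC extraction sums peaks within tolerance inside the window", {
  # one Gaussian elution peak per channel; apex at rt 100
  ch <- build_channels(500, 1, 2)
  scans <- lapply(seq(40, 160), function(rt) {
    g <- exp(-(rt - 100)^2 / (2 * 15^2))
    list(rt_s = rt, mz = ch$mz, intensity = g * c(100, 50, 25, 10, 5, 2, 1, 1, 1))
  })
  sp <- ms1_spectra(scans)
  xic <- extract_xics(sp, ch, rt_center_s = 100, window_s = 120, mz_tol = 0.01)
  expect_equal(nrow(xic$intensity), 121)
  apex <- apply(xic$intensity, 2, which.max)
  expect_true(all(xic$scan_rt[apex] == 100))

  # scans every 1 s with a 300 s window give 301 slots
  sp2 <- ms1_spectra(lapply(0:400, function(rt) {
    list(rt_s = rt, mz = 500, intensity = 1)
  }))
  xic2 <- extract_xics(sp2, ch, rt_center_s = 200, window_s = 300)
  expect_equal(nrow(xic2$intensity), 301)

  # channels entirely outside the scan m/z range give an all-zero matrix
  far <- build_channels(3000, 1, 2)
  xic3 <- extract_xics(sp, far, rt_center_s = 100, window_s = 120)
  expect_true(all(xic3$intensity == 0))
  expect_error(channel_abundances(xic3), "unquantifiable")

  expect_error(
    extract_xics(sp, ch, rt_center_s = 10000, window_s = 300),
    "no MS1 scans"
  )
})

test_that("channel regression recovers exact proportionality", {
  coefs <- c(1, 0.8, 0.5, 0.2, 0.05, 0, 0.01, 0, 0, 0)
  ab <- channel_abundances(make_xic(coefs))
  expect_equal(ab$abundance, coefs / sum(coefs), tolerance = 1e-12)
  expect_equal(ab$slopes[1], 1)
  expect_equal(ab$r2[6], 0) # all-zero channel
})

test_that("slope estimation resists an uncorrelated spike better than summing", {
  coefs <- c(1, 0.6, 0.3, 0.1, 0.05, 0.01, 0, 0, 0, 0)
  xic <- make_xic(coefs)
  # contaminant at the window edge in channel 3 (true coef 0.3)
  spike <- numeric(301)
  spike[290:301] <- 2
  xic$intensity[, 3] <- xic$intensity[, 3] + spike
  x <- xic$intensity[, 1]
  slope_est <- channel_abundances(xic)$slopes[3]
  sum_est <- sum(xic$intensity[, 3]) / sum(x)
  expect_lt(abs(slope_est - 0.3), abs(sum_est - 0.3))
})

test_that("mixture MLE decomposes the t=0 spike scenario", {
  # 1:4 unlabeled:labeled spike, fully labeled old population, no noise
  x <- simulate_envelope("FVQAGSEVSALLGR",
    w_nat = 0.2, w_new = 0, w_old = 0.8,
    p_old = 0.93, rho = 0.001
  )
  fit <- fit_mixture(x, sequence = "FVQAGSEVSALLGR")
  expect_equal(unname(fit$weights["nat"]), 0.2, tolerance = 0.01)
  expect_equal(unname(fit$weights["old"]), 0.8, tolerance = 0.01)
  expect_lt(unname(fit$weights["new"]), 0.01)
  expect_equal(fit$p_old, 0.93, tolerance = 0.005)
  expect_gt(fit$dar, 50)
})

test_that("pure natural abundance input collapses onto the spike component", {
  x <- natural_pattern("C63H104N18O20")$abundance
  fit <- fit_mixture(x, comp = "C63H104N18O20")
  expect_gte(unname(fit$weights["nat"]), 0.99)
})

test_that("mixture MLE is scale invariant", {
  x <- simulate_envelope("IGLFGGAGVGK",
    w_nat = 0.2, w_new = 0.3, w_old = 0.5,
    p_new = 0.3, p_old = 0.93, rho = 0.01
  )
  a <- fit_mixture(x, sequence = "IGLFGGAGVGK")
  b <- fit_mixture(1e4 * x, sequence = "IGLFGGAGVGK")
  expect_equal(a$weights, b$weights, tolerance = 1e-6)
  expect_equal(a$p_new, b$p_new, tolerance = 1e-6)
  expect_equal(a$p_old, b$p_old, tolerance = 1e-6)
})

test_that("three-component recovery from a single multinomial draw", {
  set.seed(11)
  truth <- simulate_envelope("FVQAGSEVSALLGR",
    w_nat = 0.2, w_new = 0.3, w_old = 0.5,
    p_new = 0.3, p_old = 0.93, rho = 0.01
  )
  obs <- as.vector(rmultinom(1, 1e5, truth / sum(truth)))
  fit <- fit_mixture(obs, sequence = "FVQAGSEVSALLGR", n_eff = 1e5)
  expect_equal(unname(fit$weights), c(0.2, 0.3, 0.5), tolerance = 0.05)
  expect_equal(fit$p_new, 0.3, tolerance = 0.02)
  expect_equal(fit$p_old, 0.93, tolerance = 0.02)
})

test_that("peptide half-life is recovered from noise-free DAR kinetics", {
  t <- c(0, 24, 48, 96)
  dar <- 5 * exp(-log(2) / 57 * t)
  fit <- fit_peptide_halflife(t, dar)
  expect_equal(fit$half_life_h, 57, tolerance = 0.01 / 57)
})

test_that("undefined DARs are dropped and flat DAR yields no half-life", {
  t <- c(0, 24, 48, 96)
  dar <- c(Inf, 4, 3, 2)
  expect_warning(fit <- fit_peptide_halflife(t, dar), "dropped")
  expect_equal(fit$n_points, 3)
  expect_error(
    suppressWarnings(fit_peptide_halflife(c(0, 24, 48), c(Inf, Inf, 2))),
    "3 distinct times"
  )
  flat <- suppressWarnings(fit_peptide_halflife(c(0, 24, 48, 96), rep(3, 4)))
  expect_true(is.na(flat$half_life_h) || flat$half_life_h > 1e4)
})

test_that("pooled protein half-life agrees with a shared peptide rate", {
  t <- c(0, 24, 48, 96)
  k <- log(2) / 57
  fits <- lapply(1:5, function(i) fit_peptide_halflife(t, (2 + i) * exp(-k * t)))
  ph <- protein_halflife(fits, "ATPB")
  expect_equal(ph$pooled_half_life_h, 57, tolerance = 0.01)
  expect_equal(ph$n_peptides, 5)
  expect_lt(ph$mad_h, 1e-3)

  single <- protein_halflife(fits[1], "ATPB")
  expect_equal(single$pooled_half_life_h, fits[[1]]$half_life_h, tolerance = 1e-6)
})

test_that("pooled half-life of mixed rates lies between the component half-lives", {
  t <- c(0, 12, 24, 48, 96)
  k <- 0.02
  fits <- c(
    lapply(1:2, function(i) fit_peptide_halflife(t, 4 * exp(-k * t))),
    lapply(1:2, function(i) fit_peptide_halflife(t, 4 * exp(-2 * k * t)))
  )
  ph <- protein_halflife(fits, "MIX")
  expect_gt(ph$pooled_half_life_h, log(2) / (2 * k))
  expect_lt(ph$pooled_half_life_h, log(2) / k)
})
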