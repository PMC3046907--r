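test_that("Rt endpoints: unlabeled gives 0, fully labeled gives 1", {
  refs <- reference_distributions("C6H10NO4", 3)
  expect_equal(relative_isotope_abundance(refs$SM, refs$SM, refs$TM), 0)
  expect_equal(relative_isotope_abundance(refs$TM, refs$SM, refs$TM), 1)
})

test_that("Rt matches the hand-computed two-channel case", {
  # (0*1 + 0.5*2) / (0*1 + 1*2) = 0.5
  expect_equal(
    relative_isotope_abundance(c(0, 0.5), c(0, 0), c(0, 1)),
    0.5
  )
})

test_that("Rt rejects a degenerate reference and mismatched supports", {
  expect_error(
    relative_isotope_abundance(c(0, 1), c(0, 1), c(0, 1)),
    "degenerate"
  )
  expect_error(
    relative_isotope_abundance(c(0, 1), c(0, 0), c(0, 1, 0)),
    "support"
  )
})

test_that("Rt is a net-difference ratio: common offsets cancel", {
  refs <- reference_distributions("C6H10NO4", 3)
  em <- refs$SM + 0.4 * (refs$TM - refs$SM)
  v <- c(0.01, 0.02, 0.03)
  expect_equal(
    relative_isotope_abundance(em + v, refs$SM + v, refs$TM + v),
    relative_isotope_abundance(em, refs$SM, refs$TM),
    tolerance = 1e-12
  )
})

test_that("fully labeled references put their mass at the top shift", {
  refs <- reference_distributions("C6H10NO4", 3)
  expect_equal(which.max(refs$TM), 3L)
  refs_c3 <- reference_distributions("C3", 3)
  expect_equal(refs_c3$TM, c(0, 0, 1))
})

test_that("a measured unlabeled standard can replace the generated SM", {
  own_sm <- c(0.02, 0.005, 0.001)
  refs <- reference_distributions("C6H10NO4", 3, SM = own_sm)
  expect_equal(refs$SM, own_sm)
  expect_error(reference_distributions("C6H10NO4", 3, SM = c(1, 2)), "shifts 1..n")
})

test_that("noise-free exponential decay is recovered to machine-level accuracy", {
  t <- c(0, 5, 10, 20, 40)
  k_true <- log(2) / 10
  fit <- fit_decay(t, exp(-k_true * t))
  expect_true(fit$converged)
  expect_equal(fit$half_life_h, 10, tolerance = 1e-7)
  expect_equal(fit$R0, 1, tolerance = 1e-6)
  expect_equal(fit$k, k_true, tolerance = 1e-6)
})

test_that("the plateau model recovers its generating plateau exactly", {
  t <- c(0, 5, 10, 20, 40, 80)
  rt <- (1 - 0.2) * exp(-0.1 * t) + 0.2
  fit <- fit_decay(t, rt, with_plateau = TRUE)
  expect_equal(fit$plateau, 0.2, tolerance = 1e-6)
  expect_equal(fit$half_life_h, log(2) / 0.1, tolerance = 1e-5)
})

test_that("insufficient or growing series are handled explicitly", {
  expect_error(fit_decay(c(0, 5), c(1, 0.5)), "at least 3")
  expect_error(fit_decay(c(0, 1, 2), c(1, 0.9, 0.8), with_plateau = TRUE), "at least 4")
  expect_error(fit_decay(c(1, 1, 1), c(1, 0.9, 0.8)), "span")
  # label gain instead of dilution: k <= 0, half-life undefined
  fit <- fit_decay(c(0, 10, 20, 40), c(0.1, 0.3, 0.6, 1.2))
  expect_true(is.na(fit$half_life_h))
})

test_that("Monte-Carlo decay fits recover the half-life within 5% median error", {
  k_true <- 0.05
  t <- c(0, 8, 16, 24, 48, 96)
  half <- vapply(1:100, function(s) {
    set.seed(s)
    rt <- exp(-k_true * t) + rnorm(length(t), 0, 0.02)
    fit_decay(t, rt)$half_life_h
  }, numeric(1))
  expect_lt(abs(median(half, na.rm = TRUE) - log(2) / k_true), 0.05 * log(2) / k_true)
})

test_that("aa_turnover runs the full MIDA workflow per analyte", {
  tab <- rbind(
    simulate_gcms_series("C6H10NO4", 3,
      k = 0.1, timepoints_h = c(0, 4, 8, 16, 32, 64),
      analyte = "Asp_160"
    ),
    simulate_gcms_series("C7H13NO2", 3,
      k = 0.35, timepoints_h = c(0, 4, 8, 16, 32, 64),
      analyte = "Ala_frag"
    )
  )
  res <- aa_turnover(tab)
  expect_equal(nrow(res), 2)
  expect_equal(
    res$half_life_h[res$analyte == "Asp_160"], log(2) / 0.1,
    tolerance = 1e-6
  )
  expect_equal(
    res$half_life_h[res$analyte == "Ala_frag"], log(2) / 0.35,
    tolerance = 1e-6
  )
  expect_error(aa_turnover(tab[, -4]), "lacks column")
})
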