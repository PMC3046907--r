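# Synthetic-data generators.
#
# Forward models with the statistical structure the estimators assume, so
# every stage of the package is testable by parameter recovery without
# instrument data. All generators are deterministic under a fixed seed and
# write a ground-truth sidecar next to their outputs.

#' Simulate one peptide isotope envelope
#'
#' Mixture of the peptide's fixed natural-abundance pattern and two
#' beta-binomial envelopes (newly synthesized and old populations),
#' optionally perturbed by per-channel multiplicative lognormal noise and
#' an additive floor.
#'
#' @param sequence peptide sequence.
#' @param z charge (affects channel m/z only, not the envelope shape).
#' @param w_nat,w_new,w_old mixture weights (must sum to 1).
#' @param p_new,p_old mean enrichments of the two labeled populations.
#' @param rho beta-binomial overdispersion shared by both populations.
#' @param noise_cv coefficient of variation of the multiplicative
#'   lognormal channel noise (0 = noise-free).
#' @param noise_floor additive noise scale as a fraction of the maximum
#'   channel intensity.
#' @param scale overall intensity scale.
#' @param seed optional RNG seed (restored afterwards).
#' @param const constants from [isotope_constants()].
#' @return Numeric intensity vector over channels j = 0 .. nC + 6.
#' @export
simulate_envelope <- function(sequence, z = 2, w_nat = 0.2, w_new = 0,
                              w_old = 0.8, p_new = 0.35, p_old = 0.93,
                              rho = 0.01, noise_cv = 0, noise_floor = 0,
                              scale = 1, seed = NULL,
                              const = isotope_constants()) {
  if (abs(w_nat + w_new + w_old - 1) > 1e-6) {
    stop("mixture weights must sum to 1")
  }
  comp <- composition_from_sequence(sequence, const)
  nC <- unname(comp[["C"]])
  J <- nC + 7L
  residual <- unclass(comp)
  residual["C"] <- 0L
  resid_ab <- composition_abundance(residual, const)
  env_of <- function(p, rho) {
    restrict_channels(drop_tail(conv_vec(dbetabinom(0:nC, nC, p, rho), resid_ab)), J)
  }
  nat <- restrict_channels(natural_pattern(comp, const)$abundance, J)
  mix <- w_nat * nat
  if (w_new > 0) mix <- mix + w_new * env_of(p_new, rho)
  if (w_old > 0) mix <- mix + w_old * env_of(p_old, rho)
  x <- scale * mix
  if (noise_cv > 0 || noise_floor > 0) {
    if (!is.null(seed)) {
      old_seed <- if (exists(".Random.seed", envir = globalenv())) {
        get(".Random.seed", envir = globalenv())
      } else {
        NULL
      }
      on.exit(
        if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
      )
      set.seed(seed)
    }
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      x <- x * stats::rlnorm(J, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    if (noise_floor > 0) {
      x <- pmax(x + stats::rnorm(J, 0, noise_floor * max(x)), 0)
    }
  }
  x
}

#' Chase-experiment scenario
#'
#' Bundles every knob of the simulated labeling/chase experiment. The
#' defaults emulate the study conditions the analyses were designed for:
#' plants fully labeled at ~93 atom% 13C, an unlabeled spike mixed in at a
#' 1:4 unlabeled:labeled ratio (spike weight 0.2), chase time points 0,
#' 24, 48 and 96 h, and a protein turnover rate k = ln(2)/57 per hour.
#' The old:new distribution abundance ratio follows
#' `DAR(t) = dar0 * exp(-k t)` by construction (first-order turnover).
#'
#' @param sequences tryptic peptide sequences to simulate.
#' @param charges charge state per peptide.
#' @param protein_id protein identifier shared by the peptides.
#' @param k true turnover rate constant (1/h).
#' @param dar0 old:new distribution abundance ratio at t = 0.
#' @param p_label enrichment of the old (pre-chase) population.
#' @param p_new enrichment of the newly synthesized population.
#' @param rho beta-binomial overdispersion of both labeled populations.
#' @param spike_fraction weight of the unlabeled natural-abundance spike.
#' @param timepoints_h chase sampling times (must include 0).
#' @param noise_cv multiplicative lognormal noise CV per peak.
#' @param noise_floor additive noise floor as a fraction of the apex peak.
#' @param elution_width_s Gaussian elution peak sigma in seconds.
#' @param scan_interval_s MS1 scan spacing in seconds.
#' @param rt_start_s retention time of the first peptide apex.
#' @param rt_spacing_s spacing between consecutive peptide apexes.
#' @param amplitude apex intensity of each peptide envelope.
#' @param mz_jitter_sd centroid m/z jitter (Th, 1 sd).
#' @param contaminant add one uncorrelated contaminant trace overlapping
#'   the first peptide's window edge (for channel-regression stress
#'   tests).
#' @param seed RNG seed; fixed seed implies byte-identical output.
#' @return A `chase_scenario` list.
#' @export
chase_scenario <- function(sequences = c(
                             "FVQAGSEVSALLGR", "IGLFGGAGVGK",
                             "AHGGYSVFAGVGER", "TVLIMELINNIAK",
                             "VALVYGQMNEPPGAR"
                           ),
                           charges = rep(2L, length(sequences)),
                           protein_id = "ATPB",
                           k = log(2) / 57,
                           dar0 = 10,
                           p_label = 0.93,
                           p_new = 0.35,
                           rho = 0.01,
                           spike_fraction = 0.2,
                           timepoints_h = c(0, 24, 48, 96),
                           noise_cv = 0.05,
                           noise_floor = 0.001,
                           elution_width_s = 15,
                           scan_interval_s = 1,
                           rt_start_s = 600,
                           rt_spacing_s = 150,
                           amplitude = 1e6,
                           mz_jitter_sd = 0.002,
                           contaminant = FALSE,
                           seed = 1) {
  if (spike_fraction < 0 || spike_fraction > 1) {
    stop("spike_fraction must be in [0, 1]")
  }
  if (!0 %in% timepoints_h) stop("timepoints_h must include 0")
  if (length(charges) != length(sequences)) {
    stop("charges must match sequences in length")
  }
  structure(
    list(
      sequences = sequences, charges = as.integer(charges),
      protein_id = protein_id, k = k, dar0 = dar0,
      p_label = p_label, p_new = p_new, rho = rho,
      spike_fraction = spike_fraction, timepoints_h = timepoints_h,
      noise_cv = noise_cv, noise_floor = noise_floor,
      elution_width_s = elution_width_s,
      scan_interval_s = scan_interval_s,
      rt_start_s = rt_start_s, rt_spacing_s = rt_spacing_s,
      amplitude = amplitude, mz_jitter_sd = mz_jitter_sd,
      contaminant = contaminant, seed = seed
    ),
    class = "chase_scenario"
  )
}

#' Simulate a full chase experiment
#'
#' Writes, per chase time point, an MS1 spectra file (peak-list TSV by
#' default, or mzXML) with Gaussian elution of every peptide's mixture
#' envelope, plus the matching peptide ID table and a ground-truth sidecar
#' (`truth.tsv`) holding the generating parameters and the per-time-point
#' mixture weights.
#'
#' Population weights at time t: the spike contributes `spike_fraction`;
#' the remainder is split between old and new populations so that
#' `w_old / w_new = dar0 * exp(-k t)`.
#'
#' @param scenario a [chase_scenario()].
#' @param out_dir output directory (created if missing).
#' @param format `"tsv"` (peak-list fixtures) or `"mzxml"`.
#' @return Invisibly, a list with `ids` (path), `spectra` (named paths per
#'   time point), `truth` (path).
#' @export
simulate_chase <- function(scenario, out_dir,
                           format = c("tsv", "mzxml")) {
  stopifnot(inherits(scenario, "chase_scenario"))
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- scenario

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit(
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  )
  set.seed(sc$seed)

  const <- isotope_constants()
  np <- length(sc$sequences)
  comps <- lapply(sc$sequences, composition_from_sequence, const = const)
  nCs <- vapply(comps, function(cmp) unname(cmp[["C"]]), numeric(1))
  mono_mzs <- mapply(function(cmp, z) mz_for_charge(cmp, z, const), comps, sc$charges)
  rt_centers <- sc$rt_start_s + (seq_len(np) - 1L) * sc$rt_spacing_s

  # Clean envelopes per peptide per time point (noise is per scan/peak).
  env_list <- vector("list", length(sc$timepoints_h))
  truth_rows <- list()
  for (ti in seq_along(sc$timepoints_h)) {
    t <- sc$timepoints_h[ti]
    dar_t <- sc$dar0 * exp(-sc$k * t)
    w_old <- (1 - sc$spike_fraction) * dar_t / (1 + dar_t)
    w_new <- (1 - sc$spike_fraction) - w_old
    env_list[[ti]] <- lapply(seq_len(np), function(pi) {
      simulate_envelope(
        sc$sequences[pi],
        z = sc$charges[pi],
        w_nat = sc$spike_fraction, w_new = w_new, w_old = w_old,
        p_new = sc$p_new, p_old = sc$p_label, rho = sc$rho,
        noise_cv = 0, noise_floor = 0, scale = 1, const = const
      )
    })
    truth_rows[[ti]] <- data.frame(
      time_point_h = t, dar = dar_t,
      w_nat = sc$spike_fraction, w_new = w_new, w_old = w_old,
      p_new = sc$p_new, p_old = sc$p_label, rho = sc$rho,
      k = sc$k, half_life_h = log(2) / sc$k, seed = sc$seed
    )
  }

  rt_grid <- seq(
    min(rt_centers) - 5 * sc$elution_width_s - 160,
    max(rt_centers) + 5 * sc$elution_width_s + 160,
    by = sc$scan_interval_s
  )

  spectra_paths <- character(length(sc$timepoints_h))
  names(spectra_paths) <- as.character(sc$timepoints_h)
  for (ti in seq_along(sc$timepoints_h)) {
    t <- sc$timepoints_h[ti]
    scans <- vector("list", length(rt_grid))
    for (si in seq_along(rt_grid)) {
      rt <- rt_grid[si]
      mz_all <- numeric(0)
      int_all <- numeric(0)
      for (pi in seq_len(np)) {
        g <- exp(-(rt - rt_centers[pi])^2 / (2 * sc$elution_width_s^2))
        if (g < 1e-4) next
        env <- env_list[[ti]][[pi]]
        J <- length(env)
        base <- sc$amplitude * g * env
        if (sc$noise_cv > 0) {
          sdlog <- sqrt(log(1 + sc$noise_cv^2))
          base <- base * stats::rlnorm(J, -sdlog^2 / 2, sdlog)
        }
        if (sc$noise_floor > 0) {
          base <- pmax(base + stats::rnorm(J, 0, sc$noise_floor * max(base)), 0)
        }
        ch_mz <- mono_mzs[pi] + (0:(J - 1L)) * const$c13_defect / sc$charges[pi]
        if (sc$mz_jitter_sd > 0) {
          ch_mz <- ch_mz + stats::rnorm(J, 0, sc$mz_jitter_sd)
        }
        keep <- base > 0
        mz_all <- c(mz_all, ch_mz[keep])
        int_all <- c(int_all, base[keep])
      }
      if (sc$contaminant) {
        # Uncorrelated species at the first peptide's channel 3, eluting
        # near the window edge.
        g_c <- exp(-(rt - (rt_centers[1L] + 140))^2 / (2 * sc$elution_width_s^2))
        if (g_c >= 1e-4) {
          mz_all <- c(mz_all, mono_mzs[1L] + 3 * const$c13_defect / sc$charges[1L])
          int_all <- c(int_all, 0.5 * sc$amplitude * g_c)
        }
      }
      o <- order(mz_all)
      scans[[si]] <- list(rt_s = rt, mz = mz_all[o], intensity = int_all[o])
    }
    spectra <- ms1_spectra(scans)
    fname <- if (format == "tsv") {
      sprintf("spectra_t%03d.tsv", as.integer(t))
    } else {
      sprintf("spectra_t%03d.mzXML", as.integer(t))
    }
    path <- file.path(out_dir, fname)
    if (format == "tsv") write_peaklist(spectra, path) else write_mzxml(spectra, path)
    spectra_paths[ti] <- path
  }

  ids <- do.call(rbind, lapply(seq_along(sc$timepoints_h), function(ti) {
    data.frame(
      protein_id = sc$protein_id,
      sequence = sc$sequences,
      charge = sc$charges,
      mono_mz = round(mono_mzs, 4),
      rt_s = rt_centers,
      time_point_h = sc$timepoints_h[ti],
      stringsAsFactors = FALSE
    )
  }))
  ids_path <- file.path(out_dir, "ids.tsv")
  utils::write.table(ids, ids_path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )

  truth <- do.call(rbind, truth_rows)
  truth_path <- file.path(out_dir, "truth.tsv")
  utils::write.table(truth, truth_path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )

  invisible(list(ids = ids_path, spectra = spectra_paths, truth = truth_path))
}

#' Simulate a GC-MS mass-isotopomer time series
#'
#' Generates per-time fractional abundances of a derivatized amino-acid
#' fragment whose relative isotope abundance follows
#' `R(t) = (R0 - plateau) * exp(-k t) + plateau` exactly before noise:
#' each channel is the convex combination `SM + R(t) * (TM - SM)` of the
#' natural and fully labeled references, so the Rt statistic recovers the
#' decay curve by construction.
#'
#' @param fragment_comp fragment-ion composition.
#' @param n_labeled number of analyte-derived carbons.
#' @param k decay rate (1/h, >= 0).
#' @param plateau residual relative abundance at infinite time.
#' @param R0 relative abundance at t = 0 (1 = fully labeled).
#' @param timepoints_h sampling times in hours.
#' @param noise_cv per-channel multiplicative lognormal noise CV.
#' @param seed optional RNG seed (restored afterwards).
#' @param analyte,replicate metadata columns for the output table.
#' @param const constants from [isotope_constants()].
#' @return data.frame in the [aa_turnover()] input layout (`m0..mn`
#'   fractional abundance columns), with the true `R(t)` in column
#'   `r_true` as ground truth.
#' @export
simulate_gcms_series <- function(fragment_comp, n_labeled, k, plateau = 0,
                                 R0 = 1, timepoints_h = c(0, 4, 8, 24, 48, 96),
                                 noise_cv = 0, seed = NULL,
                                 analyte = "analyte", replicate = 1L,
                                 const = isotope_constants()) {
  if (k < 0) stop("k must be >= 0")
  comp <- as_composition(fragment_comp)
  n <- as.integer(n_labeled)
  take_full <- function(pattern) {
    ab <- pattern$abundance
    out <- numeric(n + 1L)
    avail <- seq_len(min(n + 1L, length(ab)))
    out[avail] <- ab[avail]
    out
  }
  SM_full <- take_full(natural_pattern(comp, const))
  TM_full <- take_full(enriched_pattern(comp, n, 1.0, const))

  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit(
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    )
    set.seed(seed)
  }

  rows <- lapply(timepoints_h, function(t) {
    r_t <- (R0 - plateau) * exp(-k * t) + plateau
    em <- SM_full + r_t * (TM_full - SM_full)
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      em <- em * stats::rlnorm(length(em), -sdlog^2 / 2, sdlog)
    }
    row <- data.frame(
      analyte = analyte,
      fragment_formula = format(comp),
      n_labeled = n,
      time_h = t,
      replicate = replicate,
      r_true = r_t,
      stringsAsFactors = FALSE
    )
    for (j in 0:n) row[[paste0("m", j)]] <- em[j + 1L]
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
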