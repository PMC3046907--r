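# Peptide and protein turnover from LC-MS isotope envelopes.
#
# Workflow per identified peptide and chase time point:
#   1. isotope channels: monoisotopic m/z plus j * 1.003355 / z for
#      j = 0 .. nC + 6 (six channels beyond the carbon count cover the
#      natural abundance of 15N, 2H, 18O, ...);
#   2. extracted ion chromatograms per channel in a retention window
#      centered on the triggering MS/MS retention time;
#   3. zero-intercept regression of each channel trace on the monoisotope
#      trace, suppressing chemical noise that does not co-elute;
#   4. maximum-likelihood fit of a three-component mixture — fixed natural
#      abundance (the unlabeled spike), newly synthesized, and old
#      (pre-chase) peptide populations, the latter two beta-binomial;
#   5. distribution abundance ratio DAR = w_old / w_new per time point,
#      first-order decay fit across time points, half-life = ln(2)/k,
#      pooled across a protein's peptides.

#' Isotope channel m/z values for a peptide
#'
#' Channel j sits at `mono_mz + j * 1.003355 / z` for `j = 0 .. nC + 6`:
#' one channel per possible 13C substitution plus six more for heavy
#' isotopes of the non-carbon elements.
#'
#' @param mono_mz observed monoisotopic m/z.
#' @param z charge state (>= 1).
#' @param nC carbon count of the peptide (see [carbon_count()]).
#' @param const constants from [isotope_constants()].
#' @return A `channel_set`: list with `mz` (length `nC + 7`), `z`, `nC`,
#'   `spacing`.
#' @examples
#' ch <- build_channels(717.391, 2, 63)
#' length(ch$mz)  # 70
#' @export
build_channels <- function(mono_mz, z, nC, const = isotope_constants()) {
  if (mono_mz <= 0) stop("mono_mz must be positive")
  if (z < 1 || z != round(z)) stop("charge z must be a positive integer")
  if (nC < 1 || nC != round(nC)) stop("nC must be a positive integer")
  spacing <- const$c13_defect / z
  structure(
    list(
      mz = mono_mz + (0:(nC + 6L)) * spacing,
      z = as.integer(z),
      nC = as.integer(nC),
      spacing = spacing
    ),
    class = "channel_set"
  )
}

#' Extract per-channel ion chromatograms
#'
#' For every MS1 scan inside the retention window, sums the centroid peak
#' intensity within `mz_tol` of each channel m/z. Scans with no matching
#' peak contribute zero.
#'
#' @param spectra an `ms1_spectra` object ([read_mzxml()],
#'   [read_peaklist()], or [simulate_chase()] output).
#' @param channels a `channel_set` from [build_channels()].
#' @param rt_center_s window center in seconds (MS/MS trigger time).
#' @param window_s window width in seconds (default 300, i.e. 5 min).
#' @param mz_tol half-width of the channel m/z match window (default 0.01).
#' @return An `xic_matrix`: intensity matrix (scans x channels), scan
#'   retention times, window bounds.
#' @export
extract_xics <- function(spectra, channels, rt_center_s, window_s = 300,
                         mz_tol = 0.01) {
  stopifnot(inherits(channels, "channel_set"))
  if (mz_tol <= 0) stop("mz_tol must be positive")
  scans <- spectra$scans
  rts <- vapply(scans, function(s) s$rt_s, numeric(1))
  lo <- rt_center_s - window_s / 2
  hi <- rt_center_s + window_s / 2
  sel <- which(rts >= lo & rts <= hi)
  if (!length(sel)) {
    stop(
      "no MS1 scans in retention window [", lo, ", ", hi, "] s",
      " (run spans ", min(rts), "-", max(rts), " s)"
    )
  }
  ch <- channels$mz
  mat <- matrix(0, nrow = length(sel), ncol = length(ch))
  for (i in seq_along(sel)) {
    s <- scans[[sel[i]]]
    if (!length(s$mz)) next
    o <- order(s$mz)
    mz <- s$mz[o]
    cs <- c(0, cumsum(s$intensity[o]))
    a <- findInterval(ch - mz_tol, mz, left.open = TRUE)
    b <- findInterval(ch + mz_tol, mz)
    mat[i, ] <- cs[b + 1L] - cs[a + 1L]
  }
  structure(
    list(
      intensity = mat,
      scan_rt = rts[sel],
      channels = channels,
      window = c(lo, hi)
    ),
    class = "xic_matrix"
  )
}

#' Channel abundances by regression on the monoisotope trace
#'
#' The abundance of channel j is the zero-intercept ordinary-least-squares
#' slope of its trace regressed on the monoisotope (j = 0) trace. Signal
#' that does not co-elute with the monoisotope peak (chemical noise,
#' overlapping uncorrelated peptides) pulls the slope far less than it
#' would a plain summed intensity, which is the point of this step.
#' Negative slopes are clipped to zero and the vector renormalized to
#' sum 1; a per-channel r-squared is kept as a QC field.
#'
#' @param xics an `xic_matrix` from [extract_xics()].
#' @return A `channel_abundances`: `abundance` (normalized, length =
#'   number of channels), `r2`, and the raw slopes.
#' @export
channel_abundances <- function(xics) {
  stopifnot(inherits(xics, "xic_matrix"))
  x <- xics$intensity[, 1L]
  if (!any(x > 0) || stats::var(x) == 0) {
    stop("monoisotope channel trace is flat; peptide unquantifiable")
  }
  sxx <- sum(x^2)
  slopes <- as.vector(crossprod(xics$intensity, x)) / sxx
  r2 <- vapply(seq_len(ncol(xics$intensity)), function(j) {
    y <- xics$intensity[, j]
    syy <- sum(y^2)
    if (syy == 0) {
      return(0)
    }
    1 - sum((y - slopes[j] * x)^2) / syy
  }, numeric(1))
  ab <- pmax(slopes, 0)
  structure(
    list(abundance = ab / sum(ab), r2 = r2, slopes = slopes),
    class = "channel_abundances"
  )
}

# Mixture model internals ----------------------------------------------

# Component envelopes restricted to the observed channel range and
# renormalized there, so the mixture is a proper multinomial over channels.
restrict_channels <- function(ab, J) {
  out <- numeric(J)
  avail <- seq_len(min(J, length(ab)))
  out[avail] <- ab[avail]
  out / sum(out)
}

mixture_theta_to_par <- function(theta) {
  w <- exp(c(0, theta[1L], theta[2L]))
  w <- w / sum(w)
  p_old <- stats::plogis(theta[3L])
  p_new <- p_old * stats::plogis(theta[4L])
  rho_new <- 0.999 * stats::plogis(theta[5L])
  rho_old <- 0.999 * stats::plogis(theta[6L])
  list(
    w_nat = w[1L], w_new = w[2L], w_old = w[3L],
    p_new = p_new, p_old = p_old, rho_new = rho_new, rho_old = rho_old
  )
}

#' Fit the three-component isotope envelope mixture
#'
#' Maximum-likelihood decomposition of an observed channel abundance
#' vector into (1) the fixed theoretical natural-abundance pattern of the
#' peptide (the unlabeled spike; only its weight is fitted), (2) a newly
#' synthesized population and (3) an old (pre-chase) population, the
#' latter two modeled as beta-binomial envelopes over the peptide's
#' carbons convolved with the natural pattern of its non-carbon atoms.
#' Identifiability is enforced by the constraint `p_new <= p_old`
#' (new peptide is made from a more diluted precursor pool than peptide
#' synthesized during labeling).
#'
#' The likelihood is multinomial with an effective count `n_eff`
#' (channel abundances are intensities, not counts; `n_eff` sets the
#' assumed information content). Optimization is bounded quasi-Newton
#' (L-BFGS-B) from `n_restarts` seeded starting points; ties are broken
#' by log-likelihood, then by lower `p_new`. When one labeled component
#' carries essentially no weight the new/old labels are not identifiable
#' from the envelope alone; the surviving component is reported as "old"
#' if its mean enrichment is at least 0.5 and as "new" otherwise.
#'
#' @param abundances a `channel_abundances` object or a plain non-negative
#'   numeric vector over channels j = 0, 1, ...
#' @param sequence peptide sequence (used to derive the composition);
#'   alternatively pass `comp`.
#' @param comp optional explicit composition (overrides `sequence`).
#' @param n_eff effective multinomial count (default 1e4).
#' @param n_restarts number of optimizer restarts (default 5).
#' @param seed RNG seed for the restart draws (default 1).
#' @param const constants from [isotope_constants()].
#' @return A `mixture_fit`: `weights` (nat/new/old), `p_new`, `p_old`,
#'   `rho_new`, `rho_old`, `loglik`, `fia` (fractional isotopic abundance
#'   of the new component: mean nucleon shift / nC), `dar`
#'   (`w_old / w_new`, `Inf` when `w_new` is 0), `converged`.
#' @export
fit_mixture <- function(abundances, sequence = NULL, comp = NULL,
                        n_eff = 1e4, n_restarts = 5, seed = 1,
                        const = isotope_constants()) {
  if (inherits(abundances, "channel_abundances")) {
    obs <- abundances$abundance
  } else {
    obs <- as.numeric(abundances)
  }
  if (any(obs < 0) || !any(obs > 0)) {
    stop("abundances must be non-negative with positive total")
  }
  obs <- obs / sum(obs)
  if (is.null(comp)) {
    if (is.null(sequence)) stop("provide sequence or comp")
    comp <- composition_from_sequence(sequence, const)
  } else {
    comp <- as_composition(comp)
  }
  nC <- unname(comp[["C"]])
  if (nC < 1) stop("peptide must contain carbon")
  J <- length(obs)

  nat <- restrict_channels(natural_pattern(comp, const)$abundance, J)
  residual <- unclass(comp)
  residual["C"] <- 0L
  resid_ab <- composition_abundance(residual, const)

  bb_env <- function(p, rho) {
    restrict_channels(drop_tail(conv_vec(dbetabinom(0:nC, nC, p, rho), resid_ab)), J)
  }

  nll <- function(theta) {
    par <- mixture_theta_to_par(theta)
    model <- par$w_nat * nat +
      par$w_new * bb_env(par$p_new, par$rho_new) +
      par$w_old * bb_env(par$p_old, par$rho_old)
    -n_eff * sum(obs * log(pmax(model, 1e-300)))
  }

  # Heuristic start plus seeded random restarts.
  starts <- list(c(0, 0, stats::qlogis(0.9), stats::qlogis(0.35), -4.5, -4.5))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  for (i in seq_len(max(0L, n_restarts - 1L))) {
    starts[[i + 1L]] <- c(
      stats::rnorm(2, 0, 1.5),
      stats::qlogis(stats::runif(1, 0.55, 0.99)),
      stats::qlogis(stats::runif(1, 0.1, 0.9)),
      stats::rnorm(2, -4.5, 1)
    )
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      stats::optim(
        st, nll,
        method = "L-BFGS-B",
        lower = rep(-15, 6), upper = rep(15, 6),
        control = list(maxit = 500)
      ),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    if (is.null(best) ||
      opt$value < best$value - 1e-9 ||
      (abs(opt$value - best$value) <= 1e-9 &&
        mixture_theta_to_par(opt$par)$p_new <
          mixture_theta_to_par(best$par)$p_new)) {
      best <- opt
    }
  }
  if (is.null(best)) stop("mixture optimization failed from every start")

  par <- mixture_theta_to_par(best$par)

  # Degenerate relabeling: a single surviving labeled component is "old"
  # when highly enriched (the t=0 spike scenario), "new" otherwise.
  tol_w <- 1e-3
  if (par$w_old < tol_w && par$w_new > tol_w && par$p_new >= 0.5) {
    par <- list(
      w_nat = par$w_nat, w_new = par$w_old, w_old = par$w_new,
      p_new = par$p_new, p_old = par$p_new,
      rho_new = par$rho_new, rho_old = par$rho_new
    )
  } else if (par$w_new < tol_w && par$w_old > tol_w && par$p_old < 0.5) {
    par <- list(
      w_nat = par$w_nat, w_new = par$w_old, w_old = par$w_new,
      p_new = par$p_old, p_old = par$p_old,
      rho_new = par$rho_old, rho_old = par$rho_old
    )
  }

  new_env <- bb_env(par$p_new, par$rho_new)
  fia <- sum((seq_len(J) - 1L) * new_env) / nC
  dar <- if (par$w_new < 1e-6) Inf else par$w_old / par$w_new

  structure(
    list(
      weights = c(nat = par$w_nat, new = par$w_new, old = par$w_old),
      p_new = par$p_new, p_old = par$p_old,
      rho_new = par$rho_new, rho_old = par$rho_old,
      loglik = -best$value,
      fia = fia,
      dar = dar,
      converged = best$convergence == 0,
      n_eff = n_eff,
      nC = nC
    ),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<beta-binomial mixture fit> (", x$nC, " carbons)\n", sep = "")
  cat(sprintf(
    "  weights: nat %.3f / new %.3f / old %.3f\n",
    x$weights["nat"], x$weights["new"], x$weights["old"]
  ))
  cat(sprintf(
    "  p_new %.4f (rho %.4f), p_old %.4f (rho %.4f)\n",
    x$p_new, x$rho_new, x$p_old, x$rho_old
  ))
  cat(sprintf(
    "  FIA %.4f, DAR %s, loglik %.2f%s\n",
    x$fia, format(x$dar, digits = 4), x$loglik,
    if (!x$converged) " [not converged]" else ""
  ))
  invisible(x)
}

#' Peptide half-life from distribution abundance ratios
#'
#' Fits `DAR(t) = DAR0 * exp(-k t)` by nonlinear least squares over the
#' chase time points and reports `half-life = ln(2) / k`. Undefined
#' (non-finite) DAR values (e.g. `w_new = 0` before any new synthesis)
#' are dropped with a warning.
#'
#' @param time_h chase times in hours.
#' @param dar distribution abundance ratios (old / new weight).
#' @return A `decay_fit` (see [fit_decay()]).
#' @export
fit_peptide_halflife <- function(time_h, dar) {
  keep <- is.finite(dar) & is.finite(time_h)
  if (any(!keep)) {
    warning(sum(!keep), " undefined DAR value(s) dropped")
  }
  time_h <- time_h[keep]
  dar <- dar[keep]
  if (length(unique(time_h)) < 3L) {
    stop("need DAR at >= 3 distinct times after dropping undefined values")
  }
  fit_decay(time_h, dar, with_plateau = FALSE)
}

#' Protein half-life pooled over peptides
#'
#' Per-peptide half-lives plus a pooled estimate: each peptide's DAR
#' series is normalized by its fitted DAR0 and a single one-parameter
#' exponential `exp(-k t)` is fitted over all points jointly. The spread
#' across peptides is summarized by the median absolute deviation of the
#' per-peptide half-lives.
#'
#' @param peptide_fits list of converged `decay_fit` objects from
#'   [fit_peptide_halflife()].
#' @param protein_id optional identifier carried into the result.
#' @return A `protein_halflife`: `pooled_half_life_h`, `k`,
#'   `per_peptide` (data.frame), `mad_h`, `n_peptides`.
#' @export
protein_halflife <- function(peptide_fits, protein_id = NA_character_) {
  ok <- vapply(
    peptide_fits,
    function(f) isTRUE(f$converged) && is.finite(f$half_life_h),
    logical(1)
  )
  if (!any(ok)) stop("no converged peptide fits for protein ", protein_id)
  fits <- peptide_fits[ok]

  per <- data.frame(
    peptide = seq_along(fits),
    k = vapply(fits, function(f) f$k, numeric(1)),
    half_life_h = vapply(fits, function(f) f$half_life_h, numeric(1)),
    n_points = vapply(fits, function(f) f$n_points, numeric(1))
  )
  if (!is.null(names(fits))) per$peptide <- names(fits)

  pooled_dat <- do.call(rbind, lapply(fits, function(f) {
    data.frame(t = f$data$t, y = f$data$y / f$R0)
  }))
  pooled <- tryCatch(
    minpack.lm::nlsLM(
      y ~ exp(-k * t),
      data = pooled_dat,
      start = list(k = stats::median(per$k)),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  k_pool <- if (is.null(pooled)) stats::median(per$k) else unname(stats::coef(pooled)[["k"]])

  structure(
    list(
      protein_id = protein_id,
      pooled_half_life_h = if (k_pool > 0) log(2) / k_pool else NA_real_,
      k = k_pool,
      per_peptide = per,
      mad_h = stats::mad(per$half_life_h),
      n_peptides = nrow(per)
    ),
    class = "protein_halflife"
  )
}

#' @export
print.protein_halflife <- function(x, ...) {
  cat(
    "<protein half-life> ", x$protein_id, ": ",
    signif(x$pooled_half_life_h, 4), " h pooled over ",
    x$n_peptides, " peptide(s), MAD ", signif(x$mad_h, 3), " h\n",
    sep = ""
  )
  invisible(x)
}

#' Run the full protein-turnover pipeline
#'
#' Spectra + peptide identifications in, per-peptide mixture fits and
#' per-protein half-lives out. Each ID row is quantified in the spectra
#' file of its chase time point (channels, XIC window, channel regression,
#' mixture MLE); the per-time DAR series of each peptide is then fitted
#' for a half-life and pooled per protein.
#'
#' @param ids data.frame of peptide identifications (columns `protein_id`,
#'   `sequence`, `charge`, `mono_mz`, `rt_s`, `time_point_h`), e.g. from
#'   [read_peptide_ids()].
#' @param spectra_by_time named list mapping time point (hours, as
#'   character) to an `ms1_spectra` object or a spectra file path
#'   (`.mzXML` or peak-list `.tsv`).
#' @param window_s,mz_tol XIC extraction parameters (see
#'   [extract_xics()]).
#' @param n_eff,n_restarts,seed mixture MLE parameters (see
#'   [fit_mixture()]).
#' @param const constants from [isotope_constants()].
#' @return List with `peptides` (one row per ID: weights, enrichments,
#'   FIA, DAR, status), `peptide_fits` (per peptide `decay_fit`),
#'   `proteins` (pooled half-lives).
#' @export
run_protein_turnover <- function(ids, spectra_by_time, window_s = 300,
                                 mz_tol = 0.01, n_eff = 1e4,
                                 n_restarts = 5, seed = 1,
                                 const = isotope_constants()) {
  required <- c("protein_id", "sequence", "charge", "mono_mz", "rt_s", "time_point_h")
  missing_cols <- setdiff(required, names(ids))
  if (length(missing_cols)) {
    stop("ids table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  spectra_cache <- lapply(spectra_by_time, function(s) {
    if (is.character(s)) {
      if (grepl("\\.mzxml$", s, ignore.case = TRUE)) read_mzxml(s) else read_peaklist(s)
    } else {
      s
    }
  })

  rows <- vector("list", nrow(ids))
  for (i in seq_len(nrow(ids))) {
    row <- ids[i, ]
    key <- as.character(row$time_point_h)
    status <- "ok"
    fit <- NULL
    if (!key %in% names(spectra_cache)) {
      status <- "no_spectra_for_time_point"
    } else {
      fit <- tryCatch(
        {
          nC <- carbon_count(row$sequence, const)
          ch <- build_channels(row$mono_mz, row$charge, nC, const)
          xic <- extract_xics(
            spectra_cache[[key]], ch, row$rt_s,
            window_s = window_s, mz_tol = mz_tol
          )
          ab <- channel_abundances(xic)
          fit_mixture(
            ab,
            sequence = row$sequence, n_eff = n_eff,
            n_restarts = n_restarts, seed = seed, const = const
          )
        },
        error = function(e) {
          status <<- conditionMessage(e)
          NULL
        }
      )
    }
    rows[[i]] <- if (is.null(fit)) {
      data.frame(
        protein_id = row$protein_id, sequence = row$sequence,
        charge = row$charge, time_point_h = row$time_point_h,
        w_nat = NA_real_, w_new = NA_real_, w_old = NA_real_,
        p_new = NA_real_, p_old = NA_real_,
        rho_new = NA_real_, rho_old = NA_real_,
        fia = NA_real_, dar = NA_real_, loglik = NA_real_,
        status = status, stringsAsFactors = FALSE
      )
    } else {
      data.frame(
        protein_id = row$protein_id, sequence = row$sequence,
        charge = row$charge, time_point_h = row$time_point_h,
        w_nat = fit$weights[["nat"]], w_new = fit$weights[["new"]],
        w_old = fit$weights[["old"]],
        p_new = fit$p_new, p_old = fit$p_old,
        rho_new = fit$rho_new, rho_old = fit$rho_old,
        fia = fit$fia, dar = fit$dar, loglik = fit$loglik,
        status = if (fit$converged) "ok" else "not_converged",
        stringsAsFactors = FALSE
      )
    }
  }
  peptides <- do.call(rbind, rows)

  peptide_fits <- list()
  quant <- peptides[peptides$status %in% c("ok", "not_converged"), ]
  for (key in unique(paste(quant$protein_id, quant$sequence, quant$charge, sep = "|"))) {
    d <- quant[paste(quant$protein_id, quant$sequence, quant$charge, sep = "|") == key, ]
    fit <- tryCatch(
      suppressWarnings(fit_peptide_halflife(d$time_point_h, d$dar)),
      error = function(e) NULL
    )
    if (!is.null(fit)) peptide_fits[[key]] <- fit
  }

  proteins <- list()
  prot_of <- sub("\\|.*$", "", names(peptide_fits))
  for (pid in unique(prot_of)) {
    ph <- tryCatch(
      protein_halflife(peptide_fits[prot_of == pid], protein_id = pid),
      error = function(e) NULL
    )
    if (!is.null(ph)) {
      proteins[[pid]] <- data.frame(
        protein_id = pid,
        pooled_half_life_h = ph$pooled_half_life_h,
        n_peptides = ph$n_peptides,
        mad_h = ph$mad_h,
        stringsAsFactors = FALSE
      )
    }
  }
  proteins <- if (length(proteins)) do.call(rbind, proteins) else NULL
  if (!is.null(proteins)) rownames(proteins) <- NULL

  list(peptides = peptides, peptide_fits = peptide_fits, proteins = proteins)
}
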