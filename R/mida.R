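# Amino-acid turnover by mass isotopomer distribution analysis (MIDA).
#
# The relative isotope abundance at chase time t is
#
#   Rt = sum_{i=1..n} (EMi - SMi) * i / sum_{i=1..n} (TMi - SMi) * i
#
# where EM is the measured fractional abundance of isotopic peak i of the
# analyte fragment, SM the unlabeled (natural-abundance) reference, TM the
# theoretical 100% labeled reference, and n the number of analyte-derived
# carbons. Rt runs from 1 (fully labeled) to 0 (unlabeled) and its decay
# over the chase gives the turnover rate: Rt = R0 * exp(-k t), optionally
# with a plateau term for label recycling, and half-life = ln(2) / k.

#' Reference mass-isotopomer distributions (SM and TM)
#'
#' Builds the unlabeled (natural abundance, SM) and theoretical fully
#' labeled (TM) fractional abundances of a derivatized amino-acid fragment
#' over shifts 1..n_labeled. Values are fractional abundances of the whole
#' envelope (the full pattern is normalized before restriction to shifts
#' >= 1). SM may instead be supplied from a measured unlabeled standard.
#'
#' @param fragment_comp fragment-ion composition (see [as_composition()]).
#' @param n_labeled number of analyte-derived carbons (the label-bearing
#'   subset of the fragment's carbons).
#' @param SM optional measured unlabeled fractional abundances over shifts
#'   1..n_labeled; default generates them from the natural pattern.
#' @param const constants from [isotope_constants()].
#' @return List with numeric vectors `SM` and `TM` (shifts 1..n_labeled).
#' @examples
#' refs <- reference_distributions("C6H10NO4", 3)
#' which.max(refs$TM)  # 3: fully labeled fragment peaks at m/z 160 + 3
#' @export
reference_distributions <- function(fragment_comp, n_labeled, SM = NULL,
                                    const = isotope_constants()) {
  fragment_comp <- as_composition(fragment_comp)
  n <- as.integer(n_labeled)
  take_shifts <- function(pattern) {
    ab <- pattern$abundance
    out <- numeric(n)
    avail <- seq_len(min(n, length(ab) - 1L))
    out[avail] <- ab[avail + 1L]
    out
  }
  TM <- take_shifts(enriched_pattern(fragment_comp, n, 1.0, const))
  if (is.null(SM)) {
    SM <- take_shifts(natural_pattern(fragment_comp, const))
  } else {
    if (length(SM) != n) stop("supplied SM must cover shifts 1..n_labeled")
    SM <- as.numeric(SM)
  }
  list(SM = SM, TM = TM)
}

#' Relative isotope abundance (Rt)
#'
#' Net labeled fraction of an analyte: the carbon-weighted net experimental
#' abundance over the carbon-weighted net abundance of the fully labeled
#' reference. 1 for a fully labeled sample, 0 for an unlabeled one; small
#' negatives from measurement noise are retained, not clipped.
#'
#' @param EM measured fractional abundances over shifts 1..n.
#' @param SM unlabeled reference abundances over shifts 1..n.
#' @param TM theoretical 100% labeled abundances over shifts 1..n.
#' @return Rt, a dimensionless signed scalar.
#' @examples
#' relative_isotope_abundance(c(0, 0.5), c(0, 0), c(0, 1))  # 0.5
#' @export
relative_isotope_abundance <- function(EM, SM, TM) {
  n <- length(TM)
  if (length(EM) != n || length(SM) != n) {
    stop("EM, SM and TM must share the shift support 1..n")
  }
  i <- seq_len(n)
  denom <- sum((TM - SM) * i)
  if (abs(denom) < 1e-12) {
    stop("degenerate reference: TM equals SM, Rt undefined")
  }
  sum((EM - SM) * i) / denom
}

#' Fit first-order label dilution
#'
#' Nonlinear least squares of `Rt = R0 * exp(-k t)` or, with a plateau
#' term for label recycling, `Rt = (R0 - plateau) * exp(-k t) + plateau`.
#' The half-life is `ln(2) / k`. The default (no plateau) is the model
#' used for the amino-acid half-lives; a plateau is appropriate when label
#' recycling leaves a persistent residual enrichment.
#'
#' Initialization: R0 from the earliest observation, k from the time at
#' which Rt is nearest R0/2, plateau from the smallest Rt.
#'
#' @param time_h observation times in hours.
#' @param Rt relative isotope abundances (from
#'   [relative_isotope_abundance()] or any first-order tracer statistic).
#' @param with_plateau fit the plateau model (needs >= 4 points; default
#'   `FALSE`, needs >= 3).
#' @return A `decay_fit`: `R0`, `k` (1/h), `plateau` (or `NA`),
#'   `half_life_h` (`NA` when `k <= 0` or the fit failed), `rss`,
#'   `n_points`, `converged`, and the fitted data.
#' @examples
#' t <- c(0, 5, 10, 20, 40)
#' fit_decay(t, exp(-log(2) / 10 * t))$half_life_h  # 10
#' @export
fit_decay <- function(time_h, Rt, with_plateau = FALSE) {
  time_h <- unname(as.numeric(time_h))
  Rt <- unname(as.numeric(Rt))
  ok <- is.finite(time_h) & is.finite(Rt)
  time_h <- time_h[ok]
  Rt <- Rt[ok]
  n_min <- if (with_plateau) 4L else 3L
  if (length(time_h) < n_min) {
    stop("need at least ", n_min, " finite points for this model")
  }
  if (diff(range(time_h)) <= 0) stop("observation times must span > 0 time")

  o <- order(time_h)
  time_h <- time_h[o]
  Rt <- Rt[o]

  R0_0 <- Rt[1L]
  target <- R0_0 / 2
  t_half_guess <- time_h[which.min(abs(Rt - target))]
  if (t_half_guess <= 0) t_half_guess <- max(time_h) / 2
  k_0 <- log(2) / t_half_guess
  dat <- data.frame(t = time_h, y = Rt)

  fit <- NULL
  if (with_plateau) {
    start <- list(R0 = R0_0, k = k_0, plateau = min(Rt))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ (R0 - plateau) * exp(-k * t) + plateau,
        data = dat, start = start,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  } else {
    start <- list(R0 = R0_0, k = k_0)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ R0 * exp(-k * t),
        data = dat, start = start,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }

  if (is.null(fit)) {
    return(structure(
      list(
        R0 = NA_real_, k = NA_real_, plateau = NA_real_,
        half_life_h = NA_real_, rss = NA_real_,
        n_points = length(time_h), converged = FALSE,
        with_plateau = with_plateau, data = dat
      ),
      class = "decay_fit"
    ))
  }

  cf <- stats::coef(fit)
  k <- unname(cf[["k"]])
  structure(
    list(
      R0 = unname(cf[["R0"]]),
      k = k,
      plateau = if (with_plateau) unname(cf[["plateau"]]) else NA_real_,
      half_life_h = if (k > 0) log(2) / k else NA_real_,
      rss = sum(stats::resid(fit)^2),
      n_points = length(time_h),
      converged = TRUE,
      with_plateau = with_plateau,
      data = dat
    ),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<first-order decay fit>\n")
  cat(
    "  R0 = ", signif(x$R0, 6), ", k = ", signif(x$k, 6), " 1/h",
    if (x$with_plateau) paste0(", plateau = ", signif(x$plateau, 6)) else "",
    "\n  half-life = ",
    if (is.na(x$half_life_h)) "undefined" else paste0(signif(x$half_life_h, 6), " h"),
    " (", x$n_points, " points, rss = ", signif(x$rss, 4),
    if (!x$converged) ", NOT CONVERGED" else "", ")\n",
    sep = ""
  )
  invisible(x)
}

#' Amino-acid turnover from a GC-MS isotopomer table
#'
#' Runs the full MIDA workflow per analyte: build SM/TM references from the
#' fragment composition, compute Rt per observation, and fit the decay
#' model across time points.
#'
#' @param gcms data.frame with columns `analyte`, `fragment_formula`,
#'   `n_labeled`, `time_h`, `replicate`, and fractional abundance columns
#'   `m0`, `m1`, ... (shift 0 upward), as read by [read_gcms_table()].
#' @param model `"decay"` (no plateau, the default) or `"plateau"`.
#' @param const constants from [isotope_constants()].
#' @return data.frame with one row per analyte: `R0`, `k`, `plateau`,
#'   `half_life_h`, `rss`, `n_points`, `converged`.
#' @export
aa_turnover <- function(gcms, model = c("decay", "plateau"),
                        const = isotope_constants()) {
  model <- match.arg(model)
  required <- c("analyte", "fragment_formula", "n_labeled", "time_h")
  missing_cols <- setdiff(required, names(gcms))
  if (length(missing_cols)) {
    stop("gcms table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  res <- lapply(split(gcms, gcms$analyte), function(d) {
    n <- d$n_labeled[1L]
    refs <- reference_distributions(d$fragment_formula[1L], n, const = const)
    mcols <- paste0("m", 1:n)
    if (!all(mcols %in% names(d))) {
      stop("analyte ", d$analyte[1L], ": missing abundance column(s)")
    }
    rt <- apply(as.matrix(d[, mcols, drop = FALSE]), 1L, function(em) {
      relative_isotope_abundance(em, refs$SM, refs$TM)
    })
    fit <- fit_decay(d$time_h, rt, with_plateau = model == "plateau")
    data.frame(
      analyte = d$analyte[1L],
      R0 = fit$R0, k = fit$k, plateau = fit$plateau,
      half_life_h = fit$half_life_h, rss = fit$rss,
      n_points = fit$n_points, converged = fit$converged,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
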