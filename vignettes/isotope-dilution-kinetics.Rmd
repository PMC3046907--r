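---
title: "Isotope dilution kinetics: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope dilution kinetics: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

isochase implements the data-analysis side of whole-plant ¹³CO₂
pulse-chase experiments: plants are grown under ¹³CO₂ until their carbon
pools are highly enriched, then transferred to ambient (¹²CO₂) air, and
the dilution of the label is followed by GC-MS (free amino acids) and
LC-MS/MS (tryptic peptides). This vignette describes the models behind
each stage, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the
design was genuinely open.

## Isotope patterns

All pattern math works on *nucleon-shift channels*: channel $j$ collects
every isotopologue whose nucleon count is $j$ above the monoisotopic
species. Fine structure within a channel (the small m/z splits between,
say, ¹³C and ¹⁵N substitutions) is deliberately not modeled — the
channel model downstream aggregates by nominal shift, and instrument
channels are wide relative to those splits.

A composition's natural pattern is the product of per-element isotope
polynomials, computed by repeated discrete convolution. The *enriched*
pattern assigns a chosen subset of $n$ carbons a ¹³C abundance $p$
(binomial model, $\mathrm{Bin}(n, p)$ over carbon shifts) and convolves
with the natural pattern of the remaining atoms. Enrichment is defined
as the absolute ¹³C abundance of those carbons, so an unlabeled sample
reads ≈ 0.011 (natural abundance), not 0.

Numerical conventions:

* Atomic monoisotopic masses are hard-coded to ≥ 6 decimals
  (¹²C = 12 exactly, ¹H = 1.0078250319, ¹⁴N = 14.0030740052,
  ¹⁶O = 15.9949146221, ³²S = 31.97207069; proton = 1.00727646) for
  bit-reproducibility. Ion m/z uses the protonation model and ignores
  the electron mass, which stays within 0.001 Da at peptide masses.
* Natural abundances default to IUPAC representative values
  (¹³C 0.0107, ²H 0.000115, ¹⁵N 0.00364, ¹⁷O 0.00038, ¹⁸O 0.00205,
  ³³S 0.0075, ³⁴S 0.0425) and are overridable through a plain-text
  config (`isotope_constants(config = ...)`), so results under an
  alternative abundance table are exactly reproducible.
* Truncation: channels are kept until the cumulative abundance reaches
  $1 - 10^{-10}$, then the vector is renormalized. This bounds pattern
  length while preserving the sum-to-one invariant to $10^{-9}$.
* Shift indexing is 0-based everywhere ($j = 0$ is monoisotopic).

The test suite checks the convolution engine against a brute-force
oracle that enumerates every isotope assignment for all CHNO
compositions with ≤ 5 atoms and bins by nucleon count; agreement is
required to $10^{-12}$ per channel.

## Atom% enrichment by correlation scan

`estimate_enrichment()` varies the ¹³C abundance $p$ of the enriched
carbons over a uniform grid on $[0, 1]$, predicts the pattern at each
$p$, and correlates it (Pearson $r$) against the measured channel
intensities. Predicted and measured vectors are aligned on the
monoisotopic channel and the prediction is truncated or zero-padded to
the measured range. Because $r$ is scale-invariant, raw and normalized
intensities give identical scans, so no normalization choice needs to
be made.

The default grid step is 0.001 (0.1 atom%), refined by a single
parabolic interpolation of $r$ through the best grid point and its
neighbors; the refinement is kept only if it does not decrease $r$.
Noise-free self-consistency is then exact to well under half a grid
step. One caution: the scan is only locally unimodal. Near the optimum
$r$ rises and falls monotonically, but far away it can have secondary
local structure, so the estimator takes the *global* argmax over the
full grid rather than hill-climbing.

## Amino-acid turnover (MIDA)

For a derivatized amino-acid fragment with $n$ analyte-derived carbons,
the relative isotope abundance at chase time $t$ is

$$R_t = \frac{\sum_{i=1}^{n} (EM_i - SM_i)\, i}{\sum_{i=1}^{n} (TM_i - SM_i)\, i}$$

with $EM$ the measured fractional abundances, $SM$ the unlabeled
(natural-abundance) reference and $TM$ the theoretical 100%-labeled
reference. $R_t$ is 1 for a fully labeled pool, 0 for an unlabeled one.
Small negative values arising from noise are retained, not clipped, to
avoid biasing the subsequent fit. Note the statistic is *not* invariant
to adding a common offset to $EM$ and $SM$ alone — $SM$ also enters the
denominator — but it is invariant when the same offset is applied to
all three vectors.

$SM$ can be generated from the fragment's natural pattern (the default)
or supplied from measured unlabeled standards; both paths are exposed
because derivatization artifacts sometimes make the measured standard
the better reference.

Turnover is estimated by nonlinear least squares of
$R_t = R_0 e^{-kt}$ (default) or
$R_t = (R_0 - \mathrm{plateau})e^{-kt} + \mathrm{plateau}$,
with half-life $t_{1/2} = \ln 2 / k$. The plateau variant absorbs label
recycling, which in practice leaves a persistent residual enrichment;
the no-plateau form is the convention for the amino-acid half-life
summaries. Biphasic dilution (a fast initial phase followed by a slow
one) is a real phenomenon in these experiments but no biphasic model is
fitted; when present it inflates the single-exponential RSS, which is
reported. Initialization: $R_0$ from the earliest observation, $k$ from
the time at which $R_t$ is nearest $R_0/2$, plateau from the smallest
$R_t$. Fits use Levenberg–Marquardt (minpack.lm); non-convergence is
flagged, never silently replaced, and $k \le 0$ yields an undefined
half-life rather than a negative one.

## Peptide and protein turnover

Each identified peptide (sequence, charge $z$, observed monoisotopic
m/z, retention time, chase time point) is quantified as follows.

**Channels.** The carbon count $n_C$ comes from the amino-acid
composition. Channel $j$ sits at the observed monoisotopic m/z plus
$j \cdot 1.003355 / z$ (the ¹³C mass defect over charge) for
$j = 0..n_C + 6$; the six extra channels accommodate heavy isotopes of
the non-carbon elements (¹⁵N, ²H, ¹⁸O, ...).

**XICs.** Extracted ion chromatograms are built per channel over a 5-min
(300 s) window centered on the MS/MS trigger time, summing centroid
intensity within ± 0.01 m/z of each channel (both defaults
configurable; ± 0.01 suits QSTAR-era TOF accuracy).

**Channel regression.** The abundance of channel $j$ is the
zero-intercept OLS slope of its trace on the monoisotope trace. A
channel with no real signal must regress to zero, which is why the
intercept is suppressed; signal that does not co-elute with the
monoisotope peak (chemical noise, overlapping peptides) moves the slope
far less than it would a plain intensity sum. Negative slopes are
clipped to zero, the vector is renormalized, and a per-channel $r^2$ is
kept for QC.

**Mixture MLE.** The channel abundance vector is modeled as
$w_{nat}\,\mathrm{NAT} + w_{new}\,\mathrm{BB}(p_{new}, \rho_{new}) +
w_{old}\,\mathrm{BB}(p_{old}, \rho_{old})$: a *fixed* theoretical
natural-abundance pattern for the unlabeled spike (only its weight is
fitted — the spike is unlabeled by construction, and fixing its shape
removes parameters), plus two beta-binomial envelopes over the
peptide's carbons convolved with the natural pattern of its non-carbon
atoms. The beta-binomial is parameterized by mean $p$ and intra-class
correlation $\rho$ ($\rho = 0$ reduces to the binomial); $\rho$ absorbs
overdispersion from precursor-pool heterogeneity. $\rho$ is fitted per
component rather than shared — the new population, fed by a changing
precursor pool, has no reason to share the old population's dispersion.

Channel abundances are intensities, not counts, so the likelihood is
multinomial with an effective count $N_{\mathrm{eff}}$ (default $10^4$,
configurable): $N_{\mathrm{eff}}$ sets how much information the fit
assumes the envelope carries, and only rescales the log-likelihood
surface without moving its optimum. Optimization is bounded
quasi-Newton (L-BFGS-B) on an unconstrained reparameterization (softmax
weights; $p_{new} = p_{old}\cdot\sigma(v)$ enforces the identifiability
constraint $p_{new} \le p_{old}$) from one heuristic plus four seeded
random starts; ties are broken by log-likelihood, then lower $p_{new}$.
When one labeled component carries essentially no weight the new/old
labels are unidentifiable from the envelope alone (the likelihood is
unchanged under a swap); the convention is that a single surviving
labeled component is reported as *old* if its mean enrichment is ≥ 0.5
and as *new* otherwise, which matches the $t = 0$ situation where only
the spike and the fully labeled population exist.

From the fit: the *fractional isotopic abundance* (FIA) of the new
population is its envelope's mean nucleon shift divided by $n_C$
(reported descriptively; its kinetics mix amino-acid turnover, protein
turnover and recycling, and are often biphasic, so no model is fitted
to it), and the *distribution abundance ratio*
$\mathrm{DAR} = w_{old}/w_{new}$, which decays with first-order protein
turnover. `fit_peptide_halflife()` fits
$\mathrm{DAR}(t) = \mathrm{DAR}_0 e^{-kt}$; `protein_halflife()` pools
peptides by normalizing each series to its fitted $\mathrm{DAR}_0$ and
fitting a single one-parameter exponential across all points, reporting
per-peptide half-lives and their median absolute deviation alongside
(so both a pooled fit and the per-peptide spread are available).

## The synthetic-data generator

`chase_scenario()` fixes the simulated study conditions; its defaults
are the conditions the estimators were designed for:

* five doubly charged tryptic peptides of one protein, with
  FVQAGSEVSALLGR (C₆₃H₁₀₄N₁₈O₂₀, monoisotopic m/z 717.391 at 2+) the
  reference case;
* old-population enrichment 0.93, spike weight 0.2 (1:4
  unlabeled:labeled), chase time points 0/24/48/96 h;
* protein turnover k = ln 2 / 57 h⁻¹;
* per-peak multiplicative lognormal noise (CV 0.05) plus a mean-zero
  additive floor at 0.1% of the local maximum channel, clipped at zero;
  Gaussian elution (σ = 15 s), 1 s MS1 scans, ± 0.002 m/z centroid
  jitter.

The new-population enrichment is held at 0.35 across time points. In
real data it drifts downward as the precursor pool dilutes; holding it
fixed keeps the generator's truth table unambiguous and does not affect
DAR kinetics, which is what the pipeline estimates.

Population dynamics are parameterized directly as
$\mathrm{DAR}(t) = \mathrm{DAR}_0 e^{-kt}$ (default
$\mathrm{DAR}_0 = 10$), the first-order form the estimator assumes. A
closed steady-state pool model would instead give
$e^{-kt}/(1 - e^{-kt})$, which is not a single exponential and diverges
at $t = 0$; parameterizing the ratio directly keeps the generator's
truth well-defined at every time point. The generator therefore tests
estimator correctness under the model's own kinetics, not the adequacy
of first-order kinetics for real chase data.

What the generator does *not* emulate: peptide co-elution and shared
channels (beyond one optional uncorrelated contaminant trace used by
the regression tests), retention-time drift between time points,
detector saturation, isotope fine structure, and precursor-pool
dilution of $p_{new}$. Passing recovery tests therefore demonstrates
that the estimators invert their own forward model at realistic noise —
not that the model captures every feature of real spectra.

GC-MS series are generated channel-wise as
$EM(t) = SM + R(t)(TM - SM)$ with $R(t)$ following the plateau decay
model, so the Rt statistic reproduces the generating curve exactly
before noise. All generators are bit-reproducible under a fixed seed
and write a ground-truth sidecar; recovery tests read truth only from
that sidecar.

## Problem sizes in the test suite

Simulation sizes were chosen so the full suite exercises every
estimator at meaningful scale while staying quick on a laptop: 125
compositions for the brute-force pattern oracle; 50 noise replicates
per enrichment level for the correlation scan; 500 replicates for the
Monte-Carlo decay recovery; 20 multinomial draws at
$N_{\mathrm{eff}} = 10^5$ for mixture recovery; and one full 4-point,
5-peptide chase for the end-to-end pipeline (about 1200 scans × 70
channels per time point).

## Known limitations

* One envelope in, one estimate out: no deconvolution of co-eluting
  species sharing channels.
* Only mzXML and the peak-list TSV dialect are read (no mzML or vendor
  formats); peptide identification, protein inference and FDR control
  are upstream of this package — the ID list is an input.
* No biphasic dilution model; plateau decay is the closest fitted form.
* The beta-binomial treats carbons as exchangeable; site-specific
  labeling patterns (e.g. from compartmented precursor pools) are
  outside the model family.
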