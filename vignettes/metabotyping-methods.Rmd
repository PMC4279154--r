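---
title: "Methods: simulation-backed 1H-NMR metabotyping of willow extracts"
author: "willowNMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation-backed 1H-NMR metabotyping of willow extracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(willowNMR)
```

## The problem

High-throughput metabotyping of biomass willow (*Salix*) screens leaf and
stem polar extracts by 600-MHz 1D ^1^H-NMR: spectra are referenced to an
internal standard (d~4~-TSP), reduced to fixed-width chemical-shift buckets,
scaled to the TSP region, and mined with PCA and OPLS; in parallel, a
library of metabolite signatures is fitted to each spectrum to report
absolute concentrations. Willow extracts are chemically hostile to this
workflow: high calcium (much of it as oxalate) interacts with abundant
citrate and malate, broadening their signals and moving their chemical
shifts from sample to sample, and the flavan-3-ol catechin slowly loses its
aromatic H-6 and H-8 protons to H/D exchange in buffered deuterated
solvent, which can masquerade as a biological difference between freshly
prepared and rested samples. The buffered-pH 7.4 + EDTA protocol
implemented in the prep calculator suppresses these artifacts; the rest of
the package quantifies how the pipeline behaves when they are present.

Because no real spectra ship with the package, a simulator is a
first-class component: it renders cohorts with known ground truth,
including the matrix artifacts above, and every downstream claim made by
the test suite is a statement about recovery of that ground truth.

## The spectrum model

Spectra are synthesised directly in the frequency domain as sums of
Lorentzian lines. A multiplet with centre $\delta_0$ (ppm), couplings
$J_1..J_k$ (Hz), $n_H$ protons and width $w$ (FWHM, Hz) expands into
first-order lines at $\delta_0 \pm J_i/(2\nu)$ combinations ($\nu$ the
spectrometer frequency in MHz) with binomial weights (d 1:1, t 1:2:1,
q 1:3:3:1, dd 1:1:1:1). Each line is a unit-area Lorentzian scaled so that

$$\text{area} = K \cdot c \,[\text{mM}] \cdot n_H,$$

with $K$ a library-wide constant. This is the same lineshape model that
the fitting engine assumes, which is deliberate: targeted profiling by
lineshape fitting is exact when the model matches, and the simulator's
job is to provide a controlled world in which the *processing* choices
(binning, scaling, exclusion, deconvolution) can be validated. Free
induction decays are never synthesised; the 0.5-Hz exponential
apodisation of the acquisition protocol is folded into the rendered
linewidths. Lorentzian tails are truncated at 100 FWHM (99.7 % of the
analytic area); simulation and fitting truncate identically, so the
constant cancels in calibrated concentrations.

Acquisition defaults follow the protocol: 65,536 points across a 12-ppm
sweep at 600 MHz (axis stored ascending from -1 ppm), TSP at the
concentration implied by 0.01 % w/v in the extraction solvent after
additive dilution (0.1 mg/mL / 172.26 g/mol x 700/730 = 0.557 mM in the
tube), Gaussian baseline noise, and residual-solvent humps at 4.82 ppm
(HDO) and 3.31 ppm (CHD~2~OD). Unresolved multiplets (pattern "m") are
rendered as a single Lorentzian at three times the natural width, since
only shift *ranges* are documented for those signals.

## Matrix-state chemistry

A `MatrixState` carries the tube chemistry and drives three artifacts:

* **pH.** Multiplets with a titration model move to the
  Henderson--Hasselbalch weighted mean of their protonated and
  deprotonated state shifts at the sample pH. Citrate and malate carry
  such models; their state shifts are simulator conventions chosen to
  bracket the documented pH-7.4 centres, not measured titration curves.
* **Calcium broadening.** Free calcium (total Ca minus EDTA-complexed,
  floored at zero) multiplies the linewidth of Ca-sensitive metabolites
  (citrate, malate) by $1 + \beta \cdot [\mathrm{Ca}^{2+}]_{free}$ with
  $\beta = 2\ \mathrm{mM}^{-1}$ by default. No quantitative
  calcium-broadening relationship is documented for this system; the
  linear model is an explicit stand-in, configurable and recorded in the
  spectrum metadata.
* **H/D exchange.** Exchangeable multiplet areas decay as
  $e^{-kt}$ with $k = \ln(100)/12 \approx 0.384\ \mathrm{h^{-1}}$, chosen
  so exchange is 99 % complete at 12 h, matching the observed completion
  of catechin H-6/H-8 exchange at pH 7.4. After 6 h, 10 % of the signal
  remains.

When EDTA is present the complexed fraction appears as the Ca-EDTA
quartet (3.10 ppm) and singlet (2.55 ppm) and any excess as free-EDTA
peaks. These species are also *fit targets*, so chelator intensity is
never misattributed to nearby metabolites (the 2.55-ppm singlet sits in
the middle of the citrate AB system).

## The signature library

The built-in library holds 49 signatures: the abundant primary
metabolites of willow leaf and stem (sugars, organic acids, amino acids),
the documented secondary metabolites (catechin, gallocatechin,
dihydromyricetin, chlorogenic acid, salicin, triandrin,
2-phenylethylamine), TSP and the chelator species. Chemical shifts that
are printed for this exact solvent system carry provenance `"paper"`;
everything else is a standard reference value for D~2~O-based solvents and
is tagged `"reference"`. Signatures record the *diagnostic* multiplets
used for fitting rather than every resonance, which keeps the fitted
design matrix well conditioned in the crowded 3.2-4.0 ppm sugar region.
Two simplifications are worth knowing about: glucose is stored as one
signature whose alpha- and beta-anomeric doublets each count one proton
(an equilibrium convention rather than the true ~36:64 ratio), and AB
systems (citrate) are rendered as two independent doublets with the roof
effect ignored, which is negligible at 600 MHz where the shift difference
far exceeds J. The JSON serialisation is canonical (fixed key order,
signatures sorted by name), making the write-read-write round trip
byte-identical.

## Processing

* **Referencing** shifts the axis so the tallest peak within 0.3 ppm of
  zero sits at exactly 0.00 ppm (ties break towards zero). The apex is
  located on the digital grid, so a residual sub-gridpoint offset of at
  most half the axis step (9 x 10^-5^ ppm at acquisition size) remains.
* **Scaling** divides by the integral over -0.05..0.05 ppm; the area is
  accumulated in the metadata so absolute quantitation remains possible,
  and the operation is idempotent.
* **Binning** integrates half-open 0.015-ppm buckets on a grid anchored
  at -0.05 ppm. The grid origin is not documented in the source
  protocol; -0.05 was chosen so the TSP scaling region sits flush against
  the grid. Bucket values are trapezoidal integrals computed from a
  shared cumulative integral, so the sum of all buckets telescopes to the
  total integral exactly. Buckets intersecting an exclusion region
  (water 4.775-4.865, methanol 3.285-3.335, TSP -0.05-0.05 ppm) are
  dropped whole rather than truncated, matching spreadsheet-style bucket
  bookkeeping. An optional guard drops the buckets containing 6.09 and
  6.00 ppm - the exchangeable catechin resonances - so that variable
  sample resting time cannot create false fingerprint differences; the
  non-exchangeable catechin signals at 6.93/6.85/2.86 ppm remain as
  honest markers of catechin abundance.

The bucket table is a `SummarizedExperiment` subclass (buckets as rows
with their geometry in `rowData`, samples as columns with cohort metadata
in `colData`), so standard Bioconductor tooling applies.

## Quantitation

Fitting solves a constrained least-squares problem on the union of
per-multiplet windows (each multiplet's line span padded by 0.02 ppm plus
the shift tolerance): the model is a non-negative combination of
unit-concentration metabolite templates plus a per-window linear
baseline, with per-multiplet shift offsets bounded by 0.01 ppm and
linewidths bounded to 0.5-6 Hz. The solver alternates (i) a non-negative
least-squares solve for all concentrations (`pracma::lsqnonneg`) with
(ii) a deterministic per-multiplet refinement: a grid search over the
shift offset (0.001-ppm grid, then a continuous 1-D minimisation inside
the winning grid cell) followed by bounded width optimisation. The
refinement objective profiles out the local amplitude, so a metabolite
zeroed by an earlier solve can still relocate and re-enter the fit - this
is what lets a citrate mis-calibrated by +0.008 ppm be found at its true
position. Lines within a multiplet share one offset because pH moves
whole spin systems together. Three sweeps are the default; the problem
is smooth enough that more buys nothing measurable.

Concentrations are calibrated against the internal standard:
$c_m = (\text{area per proton of } m)/(\text{area per proton of TSP})
\times c_{TSP}$, which cancels the area constant and any global intensity
scale. Exchangeable multiplets are excluded from templates by default
(`dropExchangeable`), because in the rested protocol those protons are
gone; fitting their full-intensity template would bias catechin downward.
Metabolites whose every multiplet stays below three times the noise floor
(estimated from the signature-free 9.4-9.9 ppm region) report zero with a
`below_noise` flag, fits at a box bound are flagged `boundary_hit`, and a
residual spectrum is returned for every fit so that manual inspection
remains possible.

Tube concentrations convert to tissue units through the volume chain:
undilute by the additive volumes (x 730/700), refer to the extracted
tissue (x 1.0 mL / 15 mg), giving 1 mM in the tube = 69.52 umol/g dry
weight; mg/g multiplies by MW/1000.

## Statistics and normalisation

Technical RSDs are computed as sd/mean within each biological sample and
averaged across the samples of a tissue. The genotype screen averages
technical replicates first, then runs a classical one-way ANOVA
(`stats::aov`) per tissue x position x metabolite and sorts by p-value;
raw p-values are reported by default because that is how such screens are
conventionally tabulated, with a Benjamini--Hochberg option off by
default. Trajectories order positions bottom/middle/top and, with only
two biological replicates, show the replicate *range* rather than a
standard deviation, which would be misleading at n = 2.

Pool normalisation rescales per-sample responses to a constant 3 mg of
extractable material (values x 3/extract mass). Because stem extract
yields fall roughly 2.7-fold from the top of the plant to the base, any
raw stem decline smaller than about three-fold reverses direction under
normalisation while larger declines keep it - a property the tests verify
on constructed inputs. Compound-class totals divide by the pool mass
(percent extractable x 10 mg/g) and report the unquantified +
NMR-invisible remainder without attempting to decompose it, floored at
zero with a flag if the quantified mass oversubscribes the pool.

## Multivariate models

PCA operates on unit-variance-scaled matrices via the singular value
decomposition, with a deterministic sign convention (the
largest-magnitude loading of each component is positive) so repeated fits
are bit-identical. Zero-variance variables are flagged and left centred
instead of producing NaN. OPLS follows the orthogonal-signal-correction
scheme: each orthogonal component's weight vector is the part of the X
loading orthogonal to the predictive weight, making its scores exactly
uncorrelated with the +/-1 dummy response by construction; a single
predictive PLS component is then fitted on the filtered matrix. One
orthogonal component is the default, since no component count is
documented for the original models. The S-line reports per-variable
covariance and correlation with the predictive score; with the dummy
coding used, positive values mark variables elevated in the
alphabetically later class. R^2^Y of a pure-noise response scales like
p/n for this class of model, so the null check in the tests uses few
variables at the full 72-sample size rather than asserting a universal
near-zero value.

## The simulated cohort

The default design reproduces the study layout - 2 genotypes x 2 tissues
x 3 positions x 2 biological x 3 technical replicates, 72 spectra - with
three nested sources of variation: biological (lognormal, CV 15 %),
technical (lognormal, CV 4.5 %, since each technical replicate is a
separate 15-mg extraction) and spectral noise (sd 0.5 intensity units).
The technical CV was set once so that replicate RSDs land inside the
observed 2-8 % band. Extract masses are drawn per sample from
genotype/tissue/position-specific normal models whose means and sds are
the published extractable-pool percentages (leaf ~26-32 % at every
position; stem falling from ~32 % at the top to 12-14 % at the base).
The composition model plants the documented qualitative structure - the
leaf/stem contrast dominant (so the first principal component separates
tissues), sucrose the only metabolite rising towards the stem base,
organic acids rising in older leaves, Resolution richer in amide amino
acids and 2-phenylethylamine, Tora in the major sugars - with absolute
levels calibrated so quantified leaf totals land near 100 mg/g d.w.,
about a third of the extractable pool. Preparation variant "b" (direct
deuterated extraction, no dry-down) differs from "a" only by ascorbate
and acetate increments, which is the documented difference between the
two protocols.

What the simulator does **not** emulate: real baseline roll and phasing
errors, peak-shape deviations from Lorentzian (field inhomogeneity,
unresolved long-range couplings), the full metabolite complement of a
real extract (19 cohort metabolites out of 49 library signatures), ionic
strength effects beyond the linear Ca model, and between-batch drift.
Green tests therefore certify the processing and inference machinery
under a faithful lineshape model with known truth - not instrument
performance on real willow extracts.

## Numerical choices and problem sizes

Unit tests run on a 16,384-point axis (same sweep, coarser grid) and
cohorts of 12-24 spectra; the acceptance script
(`scripts/acceptance.R`) re-runs the headline numbers at the full
65,536-point acquisition size with the complete 72-spectrum cohort.
These sizes were chosen so the whole suite stays desk-fast while the
script still exercises the full-resolution pipeline. Shift grids
(0.001 ppm default, 0.0025 ppm for the batch cohort where shifts are
known to be sub-grid), optimizer tolerances (1e-6 ppm for shifts, 1e-3 Hz
for widths) and the NNLS solver are all deterministic, and every
stochastic step flows from a single seed, so cohorts, fits and models are
bit-reproducible.
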