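#' Simulation configuration
#'
#' Acquisition-matched defaults: 65,536 points across a 12 ppm sweep at
#' 600 MHz, axis ascending from -1 ppm (so the window comfortably covers
#' -0.5..10 ppm), 0.5 Hz exponential line broadening folded into the
#' linewidths, and TSP at the concentration given by 0.01 % w/v in the
#' extraction solvent diluted by the additive volumes
#' (0.1 mg/mL / 172.26 g/mol * 700/730).
#'
#' @param nPoints number of axis points
#' @param sweepPpm sweep width (ppm)
#' @param axisMinPpm left edge of the axis (ppm)
#' @param fieldMHz spectrometer frequency (MHz)
#' @param lbHz line broadening added to every natural linewidth (Hz)
#' @param noiseSd standard deviation of additive Gaussian baseline noise
#' @param tspConcMM TSP concentration in the tube (mM)
#' @param areaConstant library-wide area constant K: rendered area =
#'   K * concentration (mM) * proton count
#' @param waterArea,meohArea areas of the residual-solvent humps at
#'   4.82 ppm (HDO) and 3.31 ppm (CHD2OD)
#' @param baselineCoefs polynomial baseline coefficients (intercept first);
#'   default none
#' @param mBroadenFactor width inflation applied to unresolved "m"
#'   multiplets
#' @param truncFwhm Lorentzian tails are rendered out to this many FWHM
#'   either side of each line
#' @return a list of class \code{simConfig}
#' @export
simConfig <- function(nPoints = 65536L, sweepPpm = 12, axisMinPpm = -1.0,
                      fieldMHz = 600, lbHz = 0.5, noiseSd = 0.5,
                      tspConcMM = 0.1 / 172.26 * 1000 * 700 / 730,
                      areaConstant = 1.0, waterArea = 40, meohArea = 15,
                      baselineCoefs = numeric(0), mBroadenFactor = 3,
                      truncFwhm = 100) {
  structure(list(nPoints = as.integer(nPoints), sweepPpm = sweepPpm,
                 axisMinPpm = axisMinPpm, fieldMHz = fieldMHz, lbHz = lbHz,
                 noiseSd = noiseSd, tspConcMM = tspConcMM,
                 areaConstant = areaConstant, waterArea = waterArea,
                 meohArea = meohArea, baselineCoefs = baselineCoefs,
                 mBroadenFactor = mBroadenFactor, truncFwhm = truncFwhm),
            class = "simConfig")
}

#' The default ppm axis of a configuration
#' @param config a \code{\link{simConfig}}
#' @export
configAxis <- function(config = simConfig()) {
  step <- config$sweepPpm / config$nPoints
  config$axisMinPpm + step * (seq_len(config$nPoints) - 1L)
}

#' Construct a MatrixState
#'
#' @param ph sample pH (default 7.4, the buffered protocol)
#' @param totalCaMM total calcium in the tube (mM)
#' @param edtaMM EDTA in the tube (mM); default 10 uL of 32 mM stock into
#'   730 uL
#' @param standingTimeH hours between buffering and acquisition
#' @param broadeningBeta linear Ca-broadening slope (per mM free Ca)
#' @param caSensitive metabolites whose widths respond to free calcium
#' @return a \linkS4class{MatrixState}
#' @export
MatrixState <- function(ph = 7.4, totalCaMM = 0.4, edtaMM = 10 * 32 / 730,
                        standingTimeH = 12, broadeningBeta = 2.0,
                        caSensitive = c("citrate", "malate")) {
  new("MatrixState", ph = ph, totalCaMM = totalCaMM, edtaMM = edtaMM,
      standingTimeH = standingTimeH, broadeningBeta = broadeningBeta,
      caSensitive = caSensitive)
}

.DEFAULT_EXCHANGE_RATE <- log(100) / 12  # per hour; >= 99% exchanged at 12 h

## O(1) uniformity check: endpoints fix the step; one interior point is
## verified against it. Full validation happens where spectra enter the
## package (class validity, readSpectrum); this guard is for raw vectors.
.check_uniform_axis <- function(axis) {
  n <- length(axis)
  if (n < 2L) stop("axis too short")
  step <- (axis[n] - axis[1]) / (n - 1)
  if (step <= 0 || abs(axis[2] - axis[1] - step) > 1e-8 * step ||
      abs(axis[n %/% 2L + 1L] - (axis[1] + step * (n %/% 2L))) > 1e-6 * step)
    stop("axis must be uniform and ascending")
  step
}

#' Render one multiplet onto an axis
#'
#' The multiplet is expanded into first-order lines and each line rendered
#' as a Lorentzian whose area is \code{concentration * nProtons * K *
#' weight}. Line positions sit at centre +/- combinations of J/(2 field).
#' Tails are truncated at \code{truncFwhm} half-widths to keep rendering
#' fast; at the default (100 FWHM) 99.7 % of the analytic area is captured.
#'
#' @param multiplet a \linkS4class{Multiplet}
#' @param concentrationMM concentration (mM)
#' @param axis uniform ascending ppm axis
#' @param fieldMHz spectrometer frequency (MHz)
#' @param fwhmHz rendered linewidth (Hz); defaults to the multiplet's
#'   natural width (no extra broadening)
#' @param areaConstant area constant K
#' @param centerPpm override of the multiplet centre (used for shift
#'   offsets during fitting and matrix effects)
#' @param areaScale extra multiplicative area factor (e.g. H/D exchange)
#' @param truncFwhm tail truncation in units of FWHM
#' @return intensity vector of \code{length(axis)}
#' @export
renderMultiplet <- function(multiplet, concentrationMM, axis, fieldMHz,
                            fwhmHz = multiplet@fwhmHz, areaConstant = 1.0,
                            centerPpm = multiplet@centerPpm, areaScale = 1.0,
                            truncFwhm = 100) {
  .check_uniform_axis(axis)
  if (fwhmHz <= 0) stop("fwhmHz must be positive")
  out <- numeric(length(axis))
  totalArea <- concentrationMM * multiplet@nProtons * areaConstant * areaScale
  if (totalArea == 0) return(out)
  lines <- expandPattern(multiplet@pattern, multiplet@jHz, fieldMHz)
  fw <- fwhmHz / fieldMHz          # FWHM in ppm
  hw <- fw / 2                     # half width at half maximum
  step <- axis[2] - axis[1]
  span <- truncFwhm * fw
  for (i in seq_len(nrow(lines))) {
    x0 <- centerPpm + lines$offsetPpm[i]
    lo <- max(1L, ceiling((x0 - span - axis[1]) / step) + 1L)
    hi <- min(length(axis), floor((x0 + span - axis[1]) / step) + 1L)
    if (lo > hi) next
    idx <- lo:hi
    dx <- axis[idx] - x0
    out[idx] <- out[idx] +
      totalArea * lines$weight[i] * (hw / pi) / (dx * dx + hw * hw)
  }
  out
}

#' Build the render plan for a composition
#'
#' A render plan is a data.frame with one row per (metabolite, multiplet):
#' the centre, width and area scale that \code{\link{simulateSpectrum}}
#' will hand to \code{\link{renderMultiplet}}. Matrix effects operate on
#' this plan before rendering.
#'
#' @param composition named numeric vector of tube concentrations (mM)
#' @param library a \linkS4class{SignatureLibrary}
#' @param config a \code{\link{simConfig}}
#' @return data.frame (metabolite, multipletIndex, centerPpm, fwhmHz,
#'   areaScale, concentrationMM)
#' @export
buildRenderPlan <- function(composition, library, config = simConfig()) {
  unknown <- setdiff(names(composition), signatureNames(library))
  if (length(unknown))
    stop("unknown metabolite(s): ", paste(unknown, collapse = ", "))
  rows <- list()
  for (nm in names(composition)) {
    sig <- getSignature(library, nm)
    for (k in seq_along(sig@multiplets)) {
      m <- sig@multiplets[[k]]
      w <- m@fwhmHz * (if (m@pattern == "m") config$mBroadenFactor else 1)
      rows[[length(rows) + 1L]] <- data.frame(
        metabolite = nm, multipletIndex = k, centerPpm = m@centerPpm,
        fwhmHz = w + config$lbHz, areaScale = 1.0,
        concentrationMM = unname(composition[[nm]]))
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(metabolite = character(0), multipletIndex = integer(0),
               centerPpm = numeric(0), fwhmHz = numeric(0),
               areaScale = numeric(0), concentrationMM = numeric(0))
}

#' Apply matrix effects to a render plan
#'
#' Three chemistry-driven modifications plus the chelator peaks:
#' \enumerate{
#'   \item pH: multiplets carrying a pH model move to the
#'     Henderson--Hasselbalch-weighted mean of their protonated and
#'     deprotonated state shifts at the sample pH.
#'   \item Calcium broadening: Ca-sensitive metabolites (default citrate
#'     and malate) have widths multiplied by \code{1 + beta * freeCa};
#'     when EDTA is at or above total calcium the multiplier is exactly 1.
#'   \item H/D exchange: exchangeable multiplet areas decay as
#'     \code{exp(-k * standingTime)}; the default rate log(100)/12 per hour
#'     makes exchange >= 99\% complete at 12 h.
#' }
#' If EDTA is present, Ca-EDTA peaks (complexed fraction) and free-EDTA
#' peaks (excess) are appended to the plan, provided the library carries
#' the "Ca-EDTA"/"EDTA" entries.
#'
#' @param plan a render plan from \code{\link{buildRenderPlan}}
#' @param state a \linkS4class{MatrixState}
#' @param library the \linkS4class{SignatureLibrary} behind the plan
#' @param config a \code{\link{simConfig}}
#' @return the modified plan
#' @export
applyMatrixEffects <- function(plan, state, library, config = simConfig()) {
  bf <- broadeningFactor(state)
  for (i in seq_len(nrow(plan))) {
    sig <- getSignature(library, plan$metabolite[i])
    m <- sig@multiplets[[plan$multipletIndex[i]]]
    if (length(m@phModel)) {
      fDeprot <- 1 / (1 + 10^(m@phModel$pka[1] - state@ph))
      plan$centerPpm[i] <- fDeprot * m@phModel$deltaDeprotonated +
        (1 - fDeprot) * m@phModel$deltaProtonated
    }
    if (plan$metabolite[i] %in% state@caSensitive)
      plan$fwhmHz[i] <- plan$fwhmHz[i] * bf
    if (isTRUE(m@exchangeable)) {
      k <- if (is.na(m@exchangeRate)) .DEFAULT_EXCHANGE_RATE else m@exchangeRate
      plan$areaScale[i] <- plan$areaScale[i] * exp(-k * state@standingTimeH)
    }
  }
  if (state@edtaMM > 0) {
    complexed <- min(state@edtaMM, state@totalCaMM)
    free <- state@edtaMM - complexed
    extras <- c("Ca-EDTA" = complexed, "EDTA" = free)
    extras <- extras[extras > 0 & names(extras) %in% signatureNames(library)]
    if (length(extras))
      plan <- rbind(plan, buildRenderPlan(extras, library, config))
  }
  plan
}

.render_plan <- function(plan, axis, fieldMHz, library, config) {
  out <- numeric(length(axis))
  for (i in seq_len(nrow(plan))) {
    sig <- getSignature(library, plan$metabolite[i])
    m <- sig@multiplets[[plan$multipletIndex[i]]]
    out <- out + renderMultiplet(m, plan$concentrationMM[i], axis, fieldMHz,
                                 fwhmHz = plan$fwhmHz[i],
                                 areaConstant = config$areaConstant,
                                 centerPpm = plan$centerPpm[i],
                                 areaScale = plan$areaScale[i],
                                 truncFwhm = config$truncFwhm)
  }
  out
}

.solvent_residuals <- function(axis, config) {
  out <- numeric(length(axis))
  if (config$waterArea > 0)   # broad HDO hump, Gaussian-ish
    out <- out + config$waterArea *
      exp(-0.5 * ((axis - 4.82) / 0.018)^2) / (0.018 * sqrt(2 * pi))
  if (config$meohArea > 0)
    out <- out + config$meohArea *
      exp(-0.5 * ((axis - 3.31) / 0.004)^2) / (0.004 * sqrt(2 * pi))
  out
}

#' Simulate one 1D 1H-NMR spectrum
#'
#' Frequency-domain synthesis: the signature library is rendered as a sum
#' of Lorentzians for the given composition (widths are natural widths
#' plus the configured exponential line broadening, modified by matrix
#' effects), TSP is added at its configured concentration, residual-water
#' and residual-methanol humps and optional polynomial baseline are
#' superimposed, and Gaussian noise of the configured standard deviation
#' is added. The ground-truth composition, matrix state and configuration
#' are stored in the spectrum metadata.
#'
#' @param composition named numeric vector of tube concentrations (mM);
#'   TSP need not be listed, it is always added
#' @param library a \linkS4class{SignatureLibrary}
#' @param config a \code{\link{simConfig}}
#' @param matrixState a \linkS4class{MatrixState}
#' @param globalShiftPpm global chemical-shift offset applied to every
#'   centre (mis-referencing artifact; removed later by TSP referencing)
#' @param meta extra metadata fields to store
#' @return an \linkS4class{NMRSpectrum}
#' @export
simulateSpectrum <- function(composition = numeric(0),
                             library = builtinWillowLibrary(),
                             config = simConfig(),
                             matrixState = MatrixState(),
                             globalShiftPpm = 0, meta = list()) {
  axis <- configAxis(config)
  composition <- composition[setdiff(names(composition), "TSP")]
  plan <- buildRenderPlan(composition, library, config)
  plan <- applyMatrixEffects(plan, matrixState, library, config)
  tsp <- buildRenderPlan(c(TSP = config$tspConcMM), library, config)
  plan <- rbind(plan, tsp)
  plan$centerPpm <- plan$centerPpm + globalShiftPpm
  y <- .render_plan(plan, axis, config$fieldMHz, library, config)
  y <- y + .solvent_residuals(axis, config)
  if (length(config$baselineCoefs))
    y <- y + drop(outer(axis, seq_along(config$baselineCoefs) - 1, `^`) %*%
                    config$baselineCoefs)
  if (config$noiseSd > 0)
    y <- y + rnorm(length(axis), sd = config$noiseSd)
  meta$truth_composition <- composition
  meta$tsp_conc_mM <- config$tspConcMM
  meta$matrix_state <- list(ph = matrixState@ph,
                            total_ca_mM = matrixState@totalCaMM,
                            edta_mM = matrixState@edtaMM,
                            standing_time_h = matrixState@standingTimeH,
                            broadening_factor = broadeningFactor(matrixState))
  meta$global_shift_ppm <- globalShiftPpm
  meta$noise_sd <- config$noiseSd
  new("NMRSpectrum", ppm = axis, intensity = y, fieldMHz = config$fieldMHz,
      meta = meta)
}
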