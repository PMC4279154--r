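#' Construct a PrepRecipe
#'
#' @param tissueMassMg dry tissue mass (mg), default 15.0
#' @param extractionVolumeML extraction solvent (mL), default 1.0
#' @param supernatantUL supernatant taken (uL), default 850
#' @param aliquotUL aliquot carried to the NMR sample (uL), default 700
#' @param additiveVolumesUL named additive volumes (uL), default 20 uL
#'   buffer + 10 uL EDTA
#' @param tspConcMM TSP tube concentration (mM)
#' @param prepMethod "a" or "b"
#' @return a \linkS4class{PrepRecipe}
#' @export
PrepRecipe <- function(tissueMassMg = 15.0, extractionVolumeML = 1.0,
                       supernatantUL = 850, aliquotUL = 700,
                       additiveVolumesUL = c(buffer = 20, edta = 10),
                       tspConcMM = 0.1 / 172.26 * 1000 * 700 / 730,
                       prepMethod = "a") {
  new("PrepRecipe", tissueMassMg = tissueMassMg,
      extractionVolumeML = extractionVolumeML,
      supernatantUL = supernatantUL, aliquotUL = aliquotUL,
      additiveVolumesUL = additiveVolumesUL, tspConcMM = tspConcMM,
      prepMethod = prepMethod)
}

#' Options of the signature-fitting engine
#'
#' @param shiftTolPpm maximum per-multiplet shift offset (ppm)
#' @param gridStepPpm step of the shift grid search (ppm)
#' @param widthBoundsHz allowed fitted linewidth range (Hz)
#' @param lbHz line broadening assumed on top of natural widths (should
#'   match the processing of the spectra being fitted)
#' @param nIter number of coordinate-refinement sweeps
#' @param refineWidths also refine linewidths (1-D bounded optimisation)
#' @param windowPadPpm padding added to each multiplet span when building
#'   fit windows
#' @param noiseK multiplier of the noise floor below which a metabolite is
#'   reported as 0 with a flag
#' @param baseline include a per-window linear baseline in the fit
#' @param mBroadenFactor width inflation of unresolved "m" multiplets
#' @param truncFwhm Lorentzian tail truncation (FWHM units)
#' @export
quantOptions <- function(shiftTolPpm = 0.01, gridStepPpm = 0.001,
                         widthBoundsHz = c(0.5, 6), lbHz = 0.5,
                         nIter = 3L, refineWidths = TRUE,
                         windowPadPpm = 0.02, noiseK = 3,
                         baseline = TRUE, mBroadenFactor = 3,
                         truncFwhm = 100, dropExchangeable = TRUE,
                         excludeRegions = list(c(4.775, 4.865),
                                               c(3.285, 3.335))) {
  list(shiftTolPpm = shiftTolPpm, gridStepPpm = gridStepPpm,
       widthBoundsHz = widthBoundsHz, lbHz = lbHz, nIter = as.integer(nIter),
       refineWidths = refineWidths, windowPadPpm = windowPadPpm,
       noiseK = noiseK, baseline = baseline,
       mBroadenFactor = mBroadenFactor, truncFwhm = truncFwhm,
       dropExchangeable = dropExchangeable, excludeRegions = excludeRegions)
}

## Remove exchangeable multiplets from every signature: in the rested
## protocol those protons have been lost to H/D exchange, so fitting their
## full-intensity template would bias the concentration down. Signatures
## consisting only of exchangeable multiplets are dropped entirely.
.strip_exchangeable <- function(library) {
  sigs <- list()
  for (nm in signatureNames(library)) {
    sig <- getSignature(library, nm)
    keep <- Filter(function(m) !isTRUE(m@exchangeable), sig@multiplets)
    if (!length(keep)) next
    sigs[[length(sigs) + 1L]] <-
      MetaboliteSignature(sig@name, sig@compoundClass, sig@molecularWeight,
                          keep)
  }
  SignatureLibrary(sigs, fieldMHz = library@fieldMHz,
                   solventTag = library@solventTag)
}

## Per-multiplet fitting state: centre offset and width, shared by all
## lines of the multiplet (whole spin systems move together under pH).
.init_fit_state <- function(library, opts) {
  st <- list()
  for (nm in signatureNames(library)) {
    sig <- getSignature(library, nm)
    st[[nm]] <- lapply(sig@multiplets, function(m) {
      w0 <- m@fwhmHz * (if (m@pattern == "m") opts$mBroadenFactor else 1) +
        opts$lbHz
      list(delta = 0,
           fwhm = min(max(w0, opts$widthBoundsHz[1]), opts$widthBoundsHz[2]))
    })
  }
  st
}

.mult_window <- function(m, fieldMHz, pad, tol) {
  lines <- expandMultiplet(m, fieldMHz)
  span <- max(lines$ppm) - min(lines$ppm)
  c(min(lines$ppm) - pad - span - tol, max(lines$ppm) + pad + span + tol)
}

.render_template <- function(sig, state, axis, fieldMHz, truncFwhm) {
  out <- numeric(length(axis))
  for (k in seq_along(sig@multiplets))
    out <- out + renderMultiplet(sig@multiplets[[k]], 1, axis, fieldMHz,
                                 fwhmHz = state[[k]]$fwhm,
                                 centerPpm = sig@multiplets[[k]]@centerPpm +
                                   state[[k]]$delta,
                                 truncFwhm = truncFwhm)
  out
}

## Signed linear baseline columns per contiguous masked segment, expressed
## as +/- pairs so a non-negative solver can realise signed coefficients.
.baseline_columns <- function(axis, mask) {
  segs <- split(mask, cumsum(c(1, diff(mask) != 1)))
  cols <- list()
  for (s in segs) {
    x <- axis[s]; xc <- x - mean(x)
    b1 <- numeric(length(axis)); b1[s] <- 1
    b2 <- numeric(length(axis)); b2[s] <- xc / max(abs(xc), 1e-12)
    cols <- c(cols, list(b1, -b1, b2, -b2))
  }
  if (length(cols)) do.call(cbind, cols) else NULL
}

#' Fit a signature library to a spectrum
#'
#' Targeted profiling by constrained least squares: the model is a
#' non-negative combination of per-metabolite templates (each the sum of
#' its multiplets rendered as Lorentzians) plus a per-window linear
#' baseline. Per-multiplet shift offsets up to \code{shiftTolPpm} and
#' linewidths within \code{widthBoundsHz} are refined by a deterministic
#' two-stage scheme: a grid search over the shift offset followed by
#' bounded 1-D width optimisation, each inside an outer loop that
#' re-solves the non-negative least-squares problem. TSP is fitted jointly
#' and anchors the concentration scale:
#' \code{c_m = (area per proton of m) / (area per proton of TSP) * c_TSP}.
#'
#' Metabolites whose every multiplet stays below \code{noiseK} times the
#' noise floor are reported as 0 with a \code{below_noise} flag. A
#' residual spectrum is returned for manual inspection of every fit.
#'
#' @param spectrum a referenced \linkS4class{NMRSpectrum}
#' @param library a \linkS4class{SignatureLibrary} containing "TSP"
#' @param options a \code{\link{quantOptions}} list
#' @param tspConcMM TSP tube concentration; defaults to the value recorded
#'   in the spectrum metadata
#' @return list with \code{results} (data.frame: metabolite,
#'   conc_tube_mM, shift_offsets_ppm, fitted_fwhm_hz, residual_norm,
#'   flags), \code{residual} (an \linkS4class{NMRSpectrum}) and
#'   \code{noiseSd}
#' @export
fitSignatures <- function(spectrum, library, options = quantOptions(),
                          tspConcMM = NULL) {
  opts <- options
  if (!("TSP" %in% signatureNames(library)))
    stop("calibration error: library has no TSP signature")
  ## protocol constant: 0.01 % w/v TSP diluted by the additive volumes
  tspConcMM <- tspConcMM %||% spectrum@meta$tsp_conc_mM %||%
    (0.1 / 172.26 * 1000 * 700 / 730)
  if (isTRUE(opts$dropExchangeable)) library <- .strip_exchangeable(library)
  axis <- ppm(spectrum); y <- intensity(spectrum)
  field <- fieldMHz(spectrum)
  nms <- signatureNames(library)
  state <- .init_fit_state(library, opts)

  ## fit windows (indices) per multiplet and per metabolite
  excluded <- rep(FALSE, length(axis))
  for (ex in opts$excludeRegions)
    excluded <- excluded | (axis >= min(ex) & axis <= max(ex))
  winIdx <- list(); metIdx <- list()
  for (nm in nms) {
    sig <- getSignature(library, nm)
    winIdx[[nm]] <- lapply(sig@multiplets, function(m) {
      w <- .mult_window(m, field, opts$windowPadPpm, opts$shiftTolPpm)
      which(axis >= w[1] & axis <= w[2] & !excluded)
    })
    metIdx[[nm]] <- sort(unique(unlist(winIdx[[nm]])))
  }
  mask <- sort(unique(unlist(metIdx)))

  templates <- vapply(nms, function(nm)
    .render_template(getSignature(library, nm), state[[nm]], axis, field,
                     opts$truncFwhm), numeric(length(axis)))
  bl <- if (opts$baseline) .baseline_columns(axis, mask) else NULL
  nMet <- length(nms)

  solve_nnls <- function() {
    C <- cbind(templates[mask, , drop = FALSE],
               if (!is.null(bl)) bl[mask, , drop = FALSE])
    fit <- pracma::lsqnonneg(C, y[mask])
    fit$x
  }
  coef <- solve_nnls()

  ## noise floor from a signature-free downfield region
  quiet <- which(axis >= 9.4 & axis <= 9.9)
  noiseSd <- if (length(quiet) > 10) mad(y[quiet]) else
    mad(y[mask] - drop(templates[mask, , drop = FALSE] %*% coef[seq_len(nMet)]))

  grid <- seq(-opts$shiftTolPpm, opts$shiftTolPpm, by = opts$gridStepPpm)
  for (iter in seq_len(opts$nIter)) {
    model <- drop(cbind(templates, bl) %*% coef)
    for (j in seq_len(nMet)) {
      cj <- coef[j]   # may be 0: the projection objective still lets a
                      # mis-shifted metabolite relocate and re-enter the fit
      nm <- nms[j]; sig <- getSignature(library, nm)
      for (k in seq_along(sig@multiplets)) {
        m <- sig@multiplets[[k]]
        idx <- winIdx[[nm]][[k]]
        if (!length(idx)) next
        ## render on the contiguous sub-axis spanning the window only
        sub <- idx[1]:idx[length(idx)]
        pos <- idx - idx[1] + 1L
        subAxis <- axis[sub]
        old <- renderMultiplet(m, 1, subAxis, field,
                               fwhmHz = state[[nm]][[k]]$fwhm,
                               centerPpm = m@centerPpm + state[[nm]][[k]]$delta,
                               truncFwhm = opts$truncFwhm)[pos]
        base <- y[idx] - (model[idx] - cj * old)
        ## projection objective: the local amplitude is profiled out, so
        ## shift/width refinement does not depend on a stale coefficient
        obj <- function(delta, fw) {
          tmp <- renderMultiplet(m, 1, subAxis, field, fwhmHz = fw,
                                 centerPpm = m@centerPpm + delta,
                                 truncFwhm = opts$truncFwhm)[pos]
          ss <- sum(tmp^2)
          if (ss <= 0) return(sum(base^2))
          sum(base^2) - max(0, sum(base * tmp))^2 / ss
        }
        vals <- vapply(grid, obj, numeric(1), fw = state[[nm]][[k]]$fwhm)
        dBest <- grid[which.min(vals)]
        ## continuous refinement inside the winning grid cell: shifts are
        ## not quantised to the grid (nor to the axis step)
        oD <- optimize(obj, fw = state[[nm]][[k]]$fwhm,
                       interval = c(max(dBest - opts$gridStepPpm,
                                        -opts$shiftTolPpm),
                                    min(dBest + opts$gridStepPpm,
                                        opts$shiftTolPpm)),
                       tol = 1e-6)
        if (oD$objective < min(vals)) dBest <- oD$minimum
        fwBest <- state[[nm]][[k]]$fwhm
        if (opts$refineWidths && cj > 0) {
          o <- optimize(function(w) obj(dBest, w),
                        interval = opts$widthBoundsHz, tol = 1e-3)
          if (o$objective < min(vals) + 1e-12) fwBest <- o$minimum
        }
        if (abs(dBest - state[[nm]][[k]]$delta) > 1e-12 ||
            abs(fwBest - state[[nm]][[k]]$fwhm) > 1e-12) {
          state[[nm]][[k]]$delta <- dBest
          state[[nm]][[k]]$fwhm <- fwBest
        }
      }
      newcol <- .render_template(sig, state[[nm]], axis, field, opts$truncFwhm)
      model <- model + cj * (newcol - templates[, j])
      templates[, j] <- newcol
    }
    coef <- solve_nnls()
  }

  model <- drop(cbind(templates, bl) %*% coef)
  tspJ <- match("TSP", nms)
  tspCoef <- coef[tspJ]
  if (!is.finite(tspCoef) || tspCoef <= 0)
    stop("calibration error: TSP could not be fitted")
  ## templates are unit-concentration renders, so coefficients are already
  ## areas per unit (concentration x K); the TSP ratio removes K
  conc <- coef[seq_len(nMet)] / tspCoef * tspConcMM

  res <- lapply(seq_len(nMet), function(j) {
    nm <- nms[j]
    flags <- character(0)
    peakH <- vapply(seq_along(state[[nm]]), function(k) {
      idx <- winIdx[[nm]][[k]]
      max(templates[idx, j]) * coef[j]
    }, numeric(1))
    below <- all(peakH < opts$noiseK * max(noiseSd, 0))
    cj <- conc[j]
    if (below && noiseSd > 0) { cj <- 0; flags <- c(flags, "below_noise") }
    deltas <- vapply(state[[nm]], `[[`, numeric(1), "delta")
    fws <- vapply(state[[nm]], `[[`, numeric(1), "fwhm")
    if (any(abs(deltas) >= opts$shiftTolPpm - 1e-9) ||
        any(fws <= opts$widthBoundsHz[1] + 1e-6) ||
        any(fws >= opts$widthBoundsHz[2] - 1e-6))
      flags <- c(flags, "boundary_hit")
    others <- unlist(metIdx[setdiff(nms, nm)])
    if (length(intersect(metIdx[[nm]], others)))
      flags <- c(flags, "overlapped")
    data.frame(metabolite = nm, conc_tube_mM = cj,
               shift_offsets_ppm = paste(sprintf("%.4f", deltas),
                                         collapse = ";"),
               fitted_fwhm_hz = paste(sprintf("%.3f", fws), collapse = ";"),
               residual_norm = sqrt(sum((y[mask] - model[mask])^2)),
               flags = paste(flags, collapse = ","),
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, res)
  residual <- new("NMRSpectrum", ppm = axis, intensity = y - model,
                  fieldMHz = field,
                  meta = list(sample_id = spectrum@meta$sample_id))
  list(results = results, residual = residual, noiseSd = noiseSd,
       tspCoef = tspCoef)
}

#' Convert a tube concentration to tissue units
#'
#' The tube concentration is first undiluted back to the extract
#' (\code{x (aliquot + additives)/aliquot}), then referred to the
#' extracted tissue: umol/g = C_extract (mM) x extraction volume (mL) /
#' tissue mass (g); mg/g = umol/g x MW / 1000.
#'
#' @param concTubeMM tube concentration (mM), vectorised
#' @param prep a \linkS4class{PrepRecipe}
#' @param mw molecular weight (g/mol); NA allowed when only umol/g is used
#' @return data.frame (conc_umol_per_g, conc_mg_per_g)
#' @export
tubeToTissueUnits <- function(concTubeMM, prep = PrepRecipe(), mw = NA_real_) {
  validObject(prep)
  dil <- (prep@aliquotUL + sum(prep@additiveVolumesUL)) / prep@aliquotUL
  cExtract <- concTubeMM * dil
  umol <- cExtract * prep@extractionVolumeML / (prep@tissueMassMg / 1000)
  data.frame(conc_umol_per_g = umol, conc_mg_per_g = umol * mw / 1000)
}

#' Profile a batch of spectra
#'
#' References each spectrum, fits the signature library, converts tube
#' concentrations to tissue units and returns one long table with one row
#' per sample x metabolite. Technical replicates are preserved; averaging
#' happens in the downstream statistics.
#'
#' @param spectra list of \linkS4class{NMRSpectrum}
#' @param library a \linkS4class{SignatureLibrary}
#' @param prep a single \linkS4class{PrepRecipe} applied to every sample,
#'   or a named list of recipes keyed by sample id (a missing sample is an
#'   error naming it)
#' @param options \code{\link{quantOptions}}
#' @param reference run TSP referencing before fitting
#' @return long data.frame with sample metadata, metabolite,
#'   conc_tube_mM, conc_umol_per_g, conc_mg_per_g and fit flags
#' @export
batchProfile <- function(spectra, library, prep = PrepRecipe(),
                         options = quantOptions(), reference = TRUE) {
  mws <- vapply(signatures(library), molecularWeight, numeric(1))
  out <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    id <- s@meta$sample_id %||% sprintf("sample_%03d", i)
    pr <- if (is(prep, "PrepRecipe")) prep else {
      p <- prep[[id]]
      if (is.null(p)) stop("missing prep row for sample ", id)
      p
    }
    if (reference) s <- referenceToTsp(s)
    fit <- fitSignatures(s, library, options)
    tab <- fit$results
    units <- tubeToTissueUnits(tab$conc_tube_mM, pr,
                               mws[tab$metabolite])
    m <- s@meta
    out[[i]] <- data.frame(
      sample_id = id, genotype = m$genotype %||% NA_character_,
      tissue = m$tissue %||% NA_character_,
      position = m$position %||% NA_character_,
      biological_rep = m$biological_rep %||% NA_integer_,
      technical_rep = m$technical_rep %||% NA_integer_,
      extract_mass_mg = m$extract_mass_mg %||% NA_real_,
      metabolite = tab$metabolite, conc_tube_mM = tab$conc_tube_mM,
      conc_umol_per_g = units$conc_umol_per_g,
      conc_mg_per_g = units$conc_mg_per_g, flags = tab$flags,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
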