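## Exact integral of the piecewise-linear interpolant of a spectrum.
## Returns a function F(x) = integral from axis[1] to x; bucket integrals
## F(r) - F(l) then telescope exactly, which is what makes the
## integral-conservation property hold to rounding error.
.cum_integral <- function(axis, y) {
  n <- length(axis)
  step <- axis[2] - axis[1]
  cum <- c(0, cumsum((y[-1] + y[-n]) / 2 * step))
  function(x) {
    x <- pmin(pmax(x, axis[1]), axis[n])
    i <- pmin(pmax(floor((x - axis[1]) / step) + 1, 1), n - 1)
    t <- (x - axis[i]) / step
    yx <- y[i] + (y[i + 1] - y[i]) * t
    cum[i] + (y[i] + yx) / 2 * (x - axis[i])
  }
}

#' Integrate a spectrum over a ppm interval
#'
#' Trapezoidal integration of the spectrum between two chemical shifts.
#' @param spectrum an \linkS4class{NMRSpectrum}
#' @param from,to interval bounds (ppm)
#' @export
integrateRegion <- function(spectrum, from, to) {
  F <- .cum_integral(ppm(spectrum), intensity(spectrum))
  F(max(from, to)) - F(min(from, to))
}

#' Reference a spectrum to TSP at 0.00 ppm
#'
#' Shifts the axis so that the apex of the tallest peak within
#' \code{+/- searchHalfwidth} ppm of zero lands exactly at 0.00 ppm.
#' When several points tie for the apex the one nearest 0 wins. The
#' applied shift is recorded in the metadata as \code{reference_shift_ppm}.
#'
#' @param spectrum an \linkS4class{NMRSpectrum}
#' @param searchHalfwidth half-width of the search window (ppm)
#' @return the referenced spectrum
#' @export
referenceToTsp <- function(spectrum, searchHalfwidth = 0.3) {
  x <- ppm(spectrum); y <- intensity(spectrum)
  win <- which(x >= -searchHalfwidth & x <= searchHalfwidth)
  if (!length(win)) stop("referencing error: no axis points near 0 ppm")
  noiseFloor <- mad(y, center = stats::median(y))
  apexH <- max(y[win])
  if (apexH <= 5 * noiseFloor)
    stop("referencing error: no peak above the noise floor in the TSP window")
  cand <- win[y[win] == apexH]
  apex <- cand[which.min(abs(x[cand]))]
  shift <- -x[apex]
  meta <- spectrum@meta
  meta$reference_shift_ppm <- shift
  new("NMRSpectrum", ppm = x + shift, intensity = y,
      fieldMHz = spectrum@fieldMHz, meta = meta)
}

#' Default excluded regions
#'
#' Residual unsuppressed water (4.775-4.865 ppm), residual methanol
#' (3.285-3.335 ppm) and the TSP region (-0.05-0.05 ppm). The TSP region
#' is used for scaling before it is excluded from the bucket table.
#' @export
defaultExclusions <- function()
  list(water = c(4.775, 4.865), meoh = c(3.285, 3.335), tsp = c(-0.05, 0.05))

#' Scale a spectrum to the TSP region
#'
#' Divides every intensity by the integral over -0.05..0.05 ppm, so that
#' the recomputed TSP-region integral is exactly 1. The area used is
#' accumulated in the metadata (\code{tsp_area}) for later absolute
#' quantitation; scaling an already-scaled spectrum is the identity.
#'
#' @param spectrum an \linkS4class{NMRSpectrum}
#' @return the scaled spectrum
#' @export
scaleToTsp <- function(spectrum) {
  area <- integrateRegion(spectrum, -0.05, 0.05)
  if (!is.finite(area) || area <= 0)
    stop("TSP area is not positive; cannot scale")
  meta <- spectrum@meta
  meta$tsp_area <- (meta$tsp_area %||% 1) * area
  new("NMRSpectrum", ppm = ppm(spectrum),
      intensity = intensity(spectrum) / area,
      fieldMHz = spectrum@fieldMHz, meta = meta)
}

.bucket_edges <- function(width, range) {
  if (width <= 0) stop("bucket width must be positive")
  if (range[2] <= range[1]) stop("inverted bucket range")
  nb <- floor((range[2] - range[1]) / width + 1e-9)
  left <- range[1] + width * (seq_len(nb) - 1)
  data.frame(left = left, right = left + width, center = left + width / 2)
}

#' Bin a spectrum into fixed-width buckets
#'
#' Buckets are half-open intervals of equal width (default 0.015 ppm) on a
#' grid anchored at the left end of the range (default -0.05 ppm, chosen so
#' the TSP scaling region sits flush against the grid). Each bucket value
#' is the trapezoidal integral of the spectrum over the bucket. Buckets
#' whose interval intersects any exclusion region are dropped whole.
#'
#' @param spectrum a referenced \linkS4class{NMRSpectrum}
#' @param width bucket width (ppm)
#' @param range two-element ppm range to bucket
#' @param exclusions list of 2-element ppm intervals to remove
#' @return named numeric vector of retained bucket integrals (names are
#'   bucket centres); attributes \code{edges} (retained bucket geometry)
#'   and \code{droppedEdges}
#' @export
binSpectrum <- function(spectrum, width = 0.015, range = c(-0.05, 10.0),
                        exclusions = defaultExclusions()) {
  ed <- .bucket_edges(width, range)
  F <- .cum_integral(ppm(spectrum), intensity(spectrum))
  vals <- F(ed$right) - F(ed$left)
  drop <- rep(FALSE, nrow(ed))
  for (ex in exclusions)
    drop <- drop | (ed$left < max(ex) & ed$right > min(ex))
  out <- setNames(vals[!drop], format(ed$center[!drop], trim = TRUE))
  attr(out, "edges") <- ed[!drop, , drop = FALSE]
  attr(out, "droppedEdges") <- ed[drop, , drop = FALSE]
  out
}

#' Assemble a bucket table from a set of spectra
#'
#' Runs the standard reduction on every spectrum - TSP referencing, TSP
#' scaling, binning with exclusions - and collects the result into a
#' \linkS4class{BucketTable} (buckets x samples), rows ordered by sample
#' id. Optionally removes the buckets covering the exchangeable catechin
#' resonances at 6.09 and 6.00 ppm, the guard against H/D-exchange false
#' positives in fingerprint mining.
#'
#' @param spectra list of \linkS4class{NMRSpectrum}
#' @param width,range,exclusions as in \code{\link{binSpectrum}}
#' @param reference,scale run TSP referencing / scaling first
#' @param dropCatechinBins drop buckets containing 6.09 or 6.00 ppm
#' @return a \linkS4class{BucketTable}
#' @export
assembleBucketTable <- function(spectra, width = 0.015,
                                range = c(-0.05, 10.0),
                                exclusions = defaultExclusions(),
                                reference = TRUE, scale = TRUE,
                                dropCatechinBins = FALSE) {
  if (!length(spectra)) stop("no spectra")
  ax1 <- ppm(spectra[[1]])
  for (s in spectra) {
    ax <- ppm(s)
    if (length(ax) != length(ax1) ||
        abs(ax[1] - ax1[1]) > 0.5 ||
        abs(diff(range(ax)) - diff(range(ax1))) > 1e-6)
      stop("mixed bucket grids: spectra do not share one axis geometry")
  }
  ids <- vapply(seq_along(spectra), function(i)
    spectra[[i]]@meta$sample_id %||% sprintf("sample_%03d", i), character(1))
  ord <- order(ids)
  spectra <- spectra[ord]; ids <- ids[ord]
  rows <- lapply(spectra, function(s) {
    if (reference) s <- referenceToTsp(s)
    if (scale) s <- scaleToTsp(s)
    binSpectrum(s, width, range, exclusions)
  })
  ed <- attr(rows[[1]], "edges")
  mat <- do.call(cbind, lapply(rows, as.numeric))
  colnames(mat) <- ids
  if (dropCatechinBins) {
    hit <- (ed$left <= 6.09 & ed$right > 6.09) |
           (ed$left <= 6.00 & ed$right > 6.00)
    mat <- mat[!hit, , drop = FALSE]
    ed <- ed[!hit, , drop = FALSE]
  }
  cd <- do.call(rbind, lapply(spectra, function(s) {
    m <- s@meta
    data.frame(sample_id = m$sample_id %||% NA_character_,
               genotype = m$genotype %||% NA_character_,
               tissue = m$tissue %||% NA_character_,
               position = m$position %||% NA_character_,
               biological_rep = m$biological_rep %||% NA_integer_,
               technical_rep = m$technical_rep %||% NA_integer_,
               extract_mass_mg = m$extract_mass_mg %||% NA_real_,
               prep_method = m$prep_method %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
  rownames(cd) <- ids
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(buckets = mat),
    rowData = S4Vectors::DataFrame(ed),
    colData = S4Vectors::DataFrame(cd))
  new("BucketTable", se, excludedRegions = unname(exclusions),
      scaled = isTRUE(scale), catechinBinsDropped = isTRUE(dropCatechinBins))
}

#' Export a bucket table as the classic ASCII/CSV layout
#'
#' First row holds the bucket centres, then one row per sample.
#' @param bt a \linkS4class{BucketTable}
#' @param path output CSV path
#' @export
writeBucketTable <- function(bt, path) {
  m <- bucketValues(bt)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  colnames(df) <- c("sample_id", format(bucketCenters(bt), trim = TRUE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
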