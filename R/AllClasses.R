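#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats approx cor mad optimize pf rnorm runif sd setNames var
#'   aov anova lm aggregate median p.adjust
#' @importFrom utils read.csv write.csv read.table write.table packageVersion
NULL

## Recognised splitting patterns and the number of coupling constants each
## pattern consumes. "m" is an unresolved multiplet rendered as a single
## broadened line; "ab" is one half of an AB system rendered as a doublet
## with its own centre (roof effect ignored at 600 MHz).
.PATTERNS <- c(s = 0L, d = 1L, dd = 2L, t = 1L, q = 1L, m = 0L, ab = 1L)

.COMPOUND_CLASSES <- c("carbohydrate", "amino acid", "organic acid",
                       "aromatic", "other")

#' Multiplet: one NMR multiplet of a metabolite signature
#'
#' A multiplet is defined by its chemical-shift centre (ppm), splitting
#' pattern, scalar coupling constants (Hz, field-independent), proton count
#' and natural linewidth. Optional components describe pH-dependent centre
#' movement (Henderson--Hasselbalch interpolation between protonated and
#' deprotonated state shifts) and slow hydrogen--deuterium exchange of the
#' proton(s) in buffered deuterated solvent.
#'
#' @slot centerPpm chemical shift of the multiplet centre (ppm)
#' @slot pattern one of s, d, dd, t, q, m, ab
#' @slot jHz coupling constants in Hz (length must match the pattern arity)
#' @slot nProtons number of protons giving rise to the multiplet
#' @slot fwhmHz natural full width at half maximum (Hz)
#' @slot phModel empty list, or \code{list(pka, deltaProtonated,
#'   deltaDeprotonated)} describing the titration of the centre
#' @slot exchangeable logical; TRUE for protons lost by H/D exchange on
#'   standing (e.g. catechin H-6/H-8)
#' @slot exchangeRate first-order exchange rate (per hour); NA means use
#'   the package default when matrix effects are applied
#' @slot provenance "paper" for centres printed in the source study,
#'   "reference" for standard literature shifts
#' @export
setClass("Multiplet",
  representation(centerPpm = "numeric", pattern = "character",
                 jHz = "numeric", nProtons = "numeric", fwhmHz = "numeric",
                 phModel = "list", exchangeable = "logical",
                 exchangeRate = "numeric", provenance = "character"),
  prototype(jHz = numeric(0), phModel = list(), exchangeable = FALSE,
            exchangeRate = NA_real_, provenance = "reference"))

setValidity("Multiplet", function(object) {
  msg <- character(0)
  if (length(object@centerPpm) != 1L || !is.finite(object@centerPpm))
    msg <- c(msg, "centerPpm must be a single finite number")
  if (length(object@pattern) != 1L || !(object@pattern %in% names(.PATTERNS)))
    msg <- c(msg, sprintf("pattern must be one of %s",
                          paste(names(.PATTERNS), collapse = ", ")))
  if (length(msg) == 0L) msg else msg
})

#' MetaboliteSignature: all multiplets of one metabolite
#'
#' @slot name metabolite name, unique within a library
#' @slot compoundClass one of carbohydrate, amino acid, organic acid,
#'   aromatic, other
#' @slot molecularWeight g/mol
#' @slot multiplets list of \linkS4class{Multiplet}
#' @export
setClass("MetaboliteSignature",
  representation(name = "character", compoundClass = "character",
                 molecularWeight = "numeric", multiplets = "list"))

#' SignatureLibrary: the metabolite signature database
#'
#' Collection of metabolite signatures recorded at a given spectrometer
#' frequency in a given solvent system, used both to synthesise spectra and
#' as the template set for targeted quantification.
#'
#' @slot fieldMHz spectrometer proton frequency (MHz)
#' @slot solventTag free-text solvent description
#' @slot signatures named list of \linkS4class{MetaboliteSignature},
#'   ordered by name
#' @export
setClass("SignatureLibrary",
  representation(fieldMHz = "numeric", solventTag = "character",
                 signatures = "list"))

setValidity("SignatureLibrary", function(object) {
  msg <- character(0)
  if (length(object@fieldMHz) != 1L || object@fieldMHz <= 0)
    msg <- c(msg, "fieldMHz must be a single positive number")
  nm <- names(object@signatures)
  if (length(object@signatures) &&
      (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm))))
    msg <- c(msg, "signature names must be present and unique")
  if (length(msg) == 0L) TRUE else msg
})

#' NMRSpectrum: a frequency-domain 1D 1H-NMR spectrum
#'
#' @slot ppm strictly ascending uniform chemical-shift axis (ppm)
#' @slot intensity intensity vector of the same length
#' @slot fieldMHz spectrometer frequency (MHz)
#' @slot meta list of sample/acquisition metadata (sample id, genotype,
#'   tissue, position, replicate indices, extract mass, prep method,
#'   simulation ground truth where applicable)
#' @export
setClass("NMRSpectrum",
  representation(ppm = "numeric", intensity = "numeric",
                 fieldMHz = "numeric", meta = "list"),
  prototype(fieldMHz = 600, meta = list()))

setValidity("NMRSpectrum", function(object) {
  msg <- character(0)
  if (length(object@ppm) != length(object@intensity))
    msg <- c(msg, "ppm and intensity must have equal length")
  if (length(object@ppm) >= 2L) {
    d <- diff(object@ppm)
    if (any(d <= 0)) msg <- c(msg, "ppm axis must be strictly ascending")
    else if (max(d) - min(d) > 1e-8 * mean(d))
      msg <- c(msg, "ppm axis must be uniform")
  }
  if (any(!is.finite(object@intensity)))
    msg <- c(msg, "intensity must be finite")
  if (length(msg) == 0L) TRUE else msg
})

#' MatrixState: sample-matrix condition of an NMR tube
#'
#' Captures the chemistry that perturbs willow extract spectra: sample pH
#' (moves titratable centres), free calcium (broadens citrate/malate),
#' EDTA (complexes calcium, adds Ca-EDTA peaks) and standing time
#' (drives catechin H/D exchange).
#'
#' @slot ph sample pH
#' @slot totalCaMM total calcium (mM)
#' @slot edtaMM total EDTA (mM)
#' @slot standingTimeH hours between buffering and acquisition
#' @slot broadeningBeta slope of the linear Ca broadening model (per mM)
#' @slot caSensitive metabolite names whose linewidths respond to free Ca
#' @export
setClass("MatrixState",
  representation(ph = "numeric", totalCaMM = "numeric", edtaMM = "numeric",
                 standingTimeH = "numeric", broadeningBeta = "numeric",
                 caSensitive = "character"),
  prototype(ph = 7.4, totalCaMM = 0, edtaMM = 0, standingTimeH = 0,
            broadeningBeta = 2.0, caSensitive = c("citrate", "malate")))

#' CohortDesign: the sampling design of a simulated willow cohort
#'
#' @slot genotypes,tissues,positions factor levels of the design
#' @slot nBio number of biological replicates per cell
#' @slot nTech number of technical replicates (separate extractions) per
#'   biological sample
#' @slot composition data.frame of per-metabolite mean tube concentrations
#'   and design effects (see \code{\link{defaultCompositionModel}})
#' @slot extractable data.frame of percent-extractable means and sds per
#'   genotype x tissue x position
#' @slot biologicalCV,technicalCV lognormal coefficients of variation
#' @slot noiseSd baseline spectral noise standard deviation
#' @slot prepMethod "a" (dry-down) or "b" (direct deuterated extraction)
#' @slot standingTimeH resting time before acquisition (hours)
#' @slot seed RNG seed
#' @export
setClass("CohortDesign",
  representation(genotypes = "character", tissues = "character",
                 positions = "character", nBio = "integer", nTech = "integer",
                 composition = "data.frame", extractable = "data.frame",
                 biologicalCV = "numeric", technicalCV = "numeric",
                 noiseSd = "numeric", prepMethod = "character",
                 standingTimeH = "numeric", seed = "integer"))

#' PrepRecipe: volumes and masses of the extraction protocol
#'
#' Defaults follow the dry-down protocol: 15.0 mg freeze-dried tissue,
#' 1.0 mL extraction solvent, 850 uL supernatant taken, 700 uL to the NMR
#' sample, plus 20 uL buffer and 10 uL EDTA additives.
#'
#' @slot tissueMassMg dry tissue mass extracted (mg)
#' @slot extractionVolumeML extraction solvent volume (mL)
#' @slot supernatantUL supernatant removed after centrifugation (uL)
#' @slot aliquotUL aliquot carried to the NMR sample (uL)
#' @slot additiveVolumesUL named vector of additive volumes (uL)
#' @slot tspConcMM TSP concentration in the final tube (mM)
#' @slot prepMethod "a" or "b"
#' @export
setClass("PrepRecipe",
  representation(tissueMassMg = "numeric", extractionVolumeML = "numeric",
                 supernatantUL = "numeric", aliquotUL = "numeric",
                 additiveVolumesUL = "numeric", tspConcMM = "numeric",
                 prepMethod = "character"))

setValidity("PrepRecipe", function(object) {
  msg <- character(0)
  vols <- c(object@tissueMassMg, object@extractionVolumeML,
            object@supernatantUL, object@aliquotUL)
  if (any(vols <= 0)) msg <- c(msg, "masses and volumes must be positive")
  if (object@aliquotUL > object@supernatantUL)
    msg <- c(msg, "aliquot cannot exceed supernatant volume")
  if (object@supernatantUL > 1000 * object@extractionVolumeML)
    msg <- c(msg, "supernatant cannot exceed extraction volume")
  if (length(msg) == 0L) TRUE else msg
})

#' BucketTable: binned spectra as a SummarizedExperiment
#'
#' Rows are fixed-width chemical-shift buckets (rowData: left, right,
#' center in ppm), columns are samples (colData: the cohort metadata).
#' The single assay \code{"buckets"} holds the integrated intensities.
#'
#' @slot excludedRegions list of 2-vectors (ppm intervals removed before
#'   analysis: residual water, methanol, TSP)
#' @slot scaled TRUE if spectra were scaled to the TSP region before binning
#' @slot catechinBinsDropped TRUE if buckets covering the exchangeable
#'   catechin resonances (6.09 and 6.00 ppm) were removed
#' @export
setClass("BucketTable", contains = "SummarizedExperiment",
  representation(excludedRegions = "list", scaled = "logical",
                 catechinBinsDropped = "logical"),
  prototype(excludedRegions = list(), scaled = FALSE,
            catechinBinsDropped = FALSE))

setValidity("BucketTable", function(object) {
  msg <- character(0)
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("left", "right", "center") %in% colnames(rd)))
    return("rowData must contain left, right, center")
  w <- rd$right - rd$left
  if (length(w) > 1L && (max(w) - min(w)) > 1e-9)
    msg <- c(msg, "all buckets must share one width")
  for (ex in object@excludedRegions) {
    if (any(rd$center >= min(ex) & rd$center <= max(ex)))
      msg <- c(msg, "no bucket centre may lie inside an excluded region")
  }
  if (any(!is.finite(SummarizedExperiment::assay(object))))
    msg <- c(msg, "bucket values must be finite")
  if (length(msg) == 0L) TRUE else msg
})

#' PCAModel: principal component analysis of a scaled feature matrix
#'
#' @slot center,scaleSd per-variable centring and scaling applied upstream
#' @slot loadings orthonormal loading matrix (variables x components)
#' @slot scores score matrix (samples x components)
#' @slot explainedVariance fraction of total variance per component
#' @slot constantFlagged names of zero-variance variables
#' @export
setClass("PCAModel",
  representation(center = "numeric", scaleSd = "numeric",
                 loadings = "matrix", scores = "matrix",
                 explainedVariance = "numeric", constantFlagged = "character"))

setValidity("PCAModel", function(object) {
  g <- crossprod(object@loadings)
  if (max(abs(g - diag(ncol(g)))) > 1e-10)
    return("loadings must be orthonormal")
  ev <- object@explainedVariance
  if (any(diff(ev) > 1e-12)) return("explained variance must be non-increasing")
  if (sum(ev) > 1 + 1e-8) return("explained variance fractions must sum to <= 1")
  TRUE
})

#' OPLSModel: orthogonal projections to latent structures (two-class)
#'
#' Trygg--Wold orthogonal signal correction followed by a single predictive
#' PLS component against a +/-1 dummy response.
#'
#' @slot predictiveScores t_p, the predictive score vector
#' @slot predictiveWeights,predictiveLoadings w and p of the predictive
#'   component (on the orthogonal-filtered matrix)
#' @slot orthScores,orthLoadings,orthWeights the removed y-orthogonal
#'   components (matrices with one column per component)
#' @slot r2x fraction of X variance captured per component
#'   (orthogonal components then predictive)
#' @slot r2y fraction of y variance explained by t_p
#' @slot y the centred dummy response used in fitting
#' @export
setClass("OPLSModel",
  representation(predictiveScores = "numeric", predictiveWeights = "numeric",
                 predictiveLoadings = "numeric", orthScores = "matrix",
                 orthLoadings = "matrix", orthWeights = "matrix",
                 r2x = "numeric", r2y = "numeric", y = "numeric"))

setValidity("OPLSModel", function(object) {
  if (ncol(object@orthScores) > 0) {
    ct <- abs(crossprod(object@orthScores, object@y))
    yn <- sqrt(sum(object@y^2))
    tn <- sqrt(colSums(object@orthScores^2))
    ok <- ct / pmax(yn * tn, .Machine$double.eps)
    if (any(ok > 1e-8))
      return("orthogonal scores must be uncorrelated with y")
  }
  TRUE
})
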