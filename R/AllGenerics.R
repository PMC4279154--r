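#' @export
setGeneric("ppm", function(object) standardGeneric("ppm"))
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))
#' @export
setGeneric("fieldMHz", function(object) standardGeneric("fieldMHz"))
#' @export
setGeneric("spectrumMeta", function(object) standardGeneric("spectrumMeta"))
#' @export
setGeneric("signatures", function(object) standardGeneric("signatures"))
#' @export
setGeneric("signatureNames", function(object) standardGeneric("signatureNames"))
#' @export
setGeneric("multiplets", function(object) standardGeneric("multiplets"))
#' @export
setGeneric("compoundClass", function(object) standardGeneric("compoundClass"))
#' @export
setGeneric("molecularWeight", function(object) standardGeneric("molecularWeight"))
#' @export
setGeneric("bucketCenters", function(object) standardGeneric("bucketCenters"))
#' @export
setGeneric("bucketValues", function(object) standardGeneric("bucketValues"))
#' @export
setGeneric("isScaled", function(object) standardGeneric("isScaled"))
#' @export
setGeneric("scores", function(object, ...) standardGeneric("scores"))
#' @export
setGeneric("modelLoadings", function(object) standardGeneric("modelLoadings"))
#' @export
setGeneric("explainedVariance", function(object) standardGeneric("explainedVariance"))
#' @export
setGeneric("freeCaMM", function(object) standardGeneric("freeCaMM"))
#' @export
setGeneric("broadeningFactor", function(object) standardGeneric("broadeningFactor"))

#' Accessors for spectra, libraries, bucket tables and models
#'
#' @param object an object of the corresponding class
#' @param ... unused
#' @name accessors
#' @aliases ppm intensity fieldMHz spectrumMeta signatures signatureNames
#'   multiplets compoundClass molecularWeight bucketCenters bucketValues
#'   isScaled scores explainedVariance freeCaMM broadeningFactor
NULL

setMethod("ppm", "NMRSpectrum", function(object) object@ppm)
setMethod("intensity", "NMRSpectrum", function(object) object@intensity)
setMethod("fieldMHz", "NMRSpectrum", function(object) object@fieldMHz)
setMethod("fieldMHz", "SignatureLibrary", function(object) object@fieldMHz)
setMethod("spectrumMeta", "NMRSpectrum", function(object) object@meta)
setMethod("signatures", "SignatureLibrary", function(object) object@signatures)
setMethod("signatureNames", "SignatureLibrary",
          function(object) names(object@signatures))
setMethod("multiplets", "MetaboliteSignature", function(object) object@multiplets)
setMethod("compoundClass", "MetaboliteSignature",
          function(object) object@compoundClass)
setMethod("molecularWeight", "MetaboliteSignature",
          function(object) object@molecularWeight)

setMethod("bucketCenters", "BucketTable",
          function(object) SummarizedExperiment::rowData(object)$center)
setMethod("bucketValues", "BucketTable",
          function(object) t(SummarizedExperiment::assay(object, "buckets")))
setMethod("isScaled", "BucketTable", function(object) object@scaled)

setMethod("scores", "PCAModel", function(object, ...) object@scores)
setMethod("modelLoadings", "PCAModel", function(object) object@loadings)
setMethod("explainedVariance", "PCAModel",
          function(object) object@explainedVariance)
setMethod("scores", "OPLSModel", function(object, ...)
  cbind(predictive = object@predictiveScores, object@orthScores))

#' Free calcium of a matrix state
#'
#' Free Ca2+ is total calcium minus EDTA-complexed calcium, floored at zero;
#' the linewidth multiplier for Ca-sensitive resonances is
#' \code{1 + beta * freeCa} and equals 1 when all calcium is complexed.
#' @param object a \linkS4class{MatrixState}
#' @export
setMethod("freeCaMM", "MatrixState",
          function(object) max(0, object@totalCaMM - object@edtaMM))
setMethod("broadeningFactor", "MatrixState",
          function(object) 1 + object@broadeningBeta * freeCaMM(object))

setMethod("show", "NMRSpectrum", function(object) {
  cat(sprintf("NMRSpectrum: %d points, %.3f..%.3f ppm, %.0f MHz\n",
              length(object@ppm), min(object@ppm), max(object@ppm),
              object@fieldMHz))
  if (!is.null(object@meta$sample_id))
    cat("  sample:", object@meta$sample_id, "\n")
})

setMethod("show", "SignatureLibrary", function(object) {
  cat(sprintf("SignatureLibrary: %d signatures at %.0f MHz\n  solvent: %s\n",
              length(object@signatures), object@fieldMHz, object@solventTag))
})

setMethod("show", "MetaboliteSignature", function(object) {
  cat(sprintf("MetaboliteSignature '%s' (%s, MW %.2f): %d multiplet(s)\n",
              object@name, object@compoundClass, object@molecularWeight,
              length(object@multiplets)))
  for (m in object@multiplets)
    cat(sprintf("  %7.3f ppm %-2s nH=%d J=[%s] fwhm=%.2f Hz%s\n",
                m@centerPpm, m@pattern, as.integer(m@nProtons),
                paste(format(m@jHz), collapse = ","), m@fwhmHz,
                if (isTRUE(m@exchangeable)) " (exchangeable)" else ""))
})

setMethod("show", "BucketTable", function(object) {
  callNextMethod()
  cat(sprintf("  scaled to TSP: %s; catechin bins dropped: %s; %d excluded region(s)\n",
              object@scaled, object@catechinBinsDropped,
              length(object@excludedRegions)))
})

setMethod("show", "PCAModel", function(object) {
  cat(sprintf("PCAModel: %d component(s), explained variance %s\n",
              ncol(object@loadings),
              paste(sprintf("%.1f%%", 100 * object@explainedVariance),
                    collapse = " ")))
})

setMethod("show", "OPLSModel", function(object) {
  cat(sprintf("OPLSModel: 1 predictive + %d orthogonal component(s), R2Y = %.3f\n",
              ncol(object@orthScores), object@r2y))
})
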