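#' Construct a Multiplet
#'
#' @param centerPpm chemical shift of the multiplet centre (ppm)
#' @param pattern splitting pattern: s, d, dd, t, q, m or ab
#' @param jHz coupling constants (Hz); length must equal the pattern arity
#'   (s and m take none; d, t, q and ab take one; dd takes two)
#' @param nProtons proton count (positive integer)
#' @param fwhmHz natural linewidth, full width at half maximum (Hz)
#' @param phModel optional \code{list(pka, deltaProtonated,
#'   deltaDeprotonated)} for titratable centres
#' @param exchangeable TRUE for slowly H/D-exchanging protons
#' @param exchangeRate first-order exchange rate (per hour); NA uses the
#'   package default \code{log(100)/12} when matrix effects are applied
#' @param provenance "paper" or "reference"
#' @return a \linkS4class{Multiplet}
#' @export
Multiplet <- function(centerPpm, pattern, jHz = numeric(0), nProtons,
                      fwhmHz = 1.2, phModel = list(), exchangeable = FALSE,
                      exchangeRate = NA_real_, provenance = "reference") {
  obj <- new("Multiplet", centerPpm = as.numeric(centerPpm),
             pattern = pattern, jHz = as.numeric(jHz),
             nProtons = as.numeric(nProtons), fwhmHz = as.numeric(fwhmHz),
             phModel = phModel, exchangeable = isTRUE(exchangeable),
             exchangeRate = as.numeric(exchangeRate), provenance = provenance)
  diag <- validateMultiplet(obj)
  if (length(diag))
    stop("invalid Multiplet: ", paste(diag, collapse = "; "))
  obj
}

#' Construct a MetaboliteSignature
#'
#' @param name metabolite name
#' @param compoundClass carbohydrate, amino acid, organic acid, aromatic
#'   or other
#' @param molecularWeight g/mol
#' @param multiplets list of \linkS4class{Multiplet}
#' @return a \linkS4class{MetaboliteSignature}
#' @export
MetaboliteSignature <- function(name, compoundClass, molecularWeight,
                                multiplets) {
  obj <- new("MetaboliteSignature", name = name,
             compoundClass = compoundClass,
             molecularWeight = as.numeric(molecularWeight),
             multiplets = multiplets)
  diag <- validateSignature(obj)
  if (length(diag))
    stop("invalid signature '", name, "': ", paste(diag, collapse = "; "))
  obj
}

#' Construct a SignatureLibrary
#'
#' Signatures are stored sorted by name; names must be unique.
#'
#' @param signatures list of \linkS4class{MetaboliteSignature}
#' @param fieldMHz spectrometer frequency (default 600)
#' @param solventTag free-text solvent description
#' @return a \linkS4class{SignatureLibrary}
#' @export
SignatureLibrary <- function(signatures = list(), fieldMHz = 600,
                             solventTag = "D2O:CD3OD 4:1, pH 7.4 phosphate + EDTA") {
  nms <- vapply(signatures, function(s) s@name, character(1))
  if (anyDuplicated(nms))
    stop("duplicate signature names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  signatures <- setNames(signatures, nms)[order(nms)]
  new("SignatureLibrary", fieldMHz = as.numeric(fieldMHz),
      solventTag = solventTag, signatures = as.list(signatures))
}

#' Look up one signature by name
#' @param library a \linkS4class{SignatureLibrary}
#' @param name metabolite name
#' @export
getSignature <- function(library, name) {
  sig <- signatures(library)[[name]]
  if (is.null(sig)) stop("unknown metabolite: ", name)
  sig
}

## ---- validation (diagnostics, not exceptions) -------------------------

#' Validate a multiplet, returning diagnostics
#'
#' Accepts either a \linkS4class{Multiplet} or a plain list with the same
#' field names, so that candidate definitions (e.g. parsed from JSON) can be
#' checked before construction. Each diagnostic names the offending field
#' and rule; an empty character vector means all invariants hold.
#'
#' @param m multiplet or list
#' @param fieldMHz spectrometer frequency used for resolution warnings
#' @param axisStepPpm digital resolution of the target axis (default
#'   12 ppm / 65536 points); expanded lines closer than this produce a
#'   warning diagnostic
#' @return character vector of diagnostics
#' @export
validateMultiplet <- function(m, fieldMHz = 600, axisStepPpm = 12 / 65536) {
  if (is(m, "Multiplet"))
    m <- list(centerPpm = m@centerPpm, pattern = m@pattern, jHz = m@jHz,
              nProtons = m@nProtons, fwhmHz = m@fwhmHz, phModel = m@phModel,
              exchangeable = m@exchangeable)
  out <- character(0)
  pat <- m$pattern
  if (is.null(pat) || length(pat) != 1L || !(pat %in% names(.PATTERNS))) {
    out <- c(out, sprintf("pattern: unknown pattern '%s'",
                          paste(pat, collapse = ",")))
    return(out)
  }
  arity <- .PATTERNS[[pat]]
  if (length(m$jHz %||% numeric(0)) != arity)
    out <- c(out, sprintf("j_hz: pattern '%s' takes %d coupling constant(s), got %d",
                          pat, arity, length(m$jHz)))
  if (is.null(m$nProtons) || m$nProtons < 1 ||
      abs(m$nProtons - round(m$nProtons)) > 1e-9)
    out <- c(out, "n_protons: must be a positive integer")
  if (is.null(m$fwhmHz) || m$fwhmHz <= 0)
    out <- c(out, "fwhm_hz: must be positive")
  if (length(m$phModel %||% list())) {
    pm <- m$phModel
    need <- c("pka", "deltaProtonated", "deltaDeprotonated")
    if (!all(need %in% names(pm))) {
      out <- c(out, "ph_model: requires pka, deltaProtonated, deltaDeprotonated")
    } else {
      lo <- min(pm$deltaProtonated, pm$deltaDeprotonated)
      hi <- max(pm$deltaProtonated, pm$deltaDeprotonated)
      if (!(m$centerPpm >= lo - 1e-9 && m$centerPpm <= hi + 1e-9))
        out <- c(out, "ph_model: state shifts must bracket center_ppm")
    }
  }
  if (length(out) == 0L && length(m$jHz %||% numeric(0)) == arity &&
      m$fwhmHz > 0) {
    lines <- expandPattern(pat, m$jHz, fieldMHz)
    if (nrow(lines) > 1L) {
      gaps <- diff(sort(lines$offsetPpm))
      if (any(gaps > 0 & gaps < axisStepPpm))
        out <- c(out, sprintf(
          "j_hz: warning: line spacing %.5f ppm below axis step %.5f ppm at %g MHz",
          min(gaps[gaps > 0]), axisStepPpm, fieldMHz))
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a metabolite signature, returning diagnostics
#'
#' @param sig a \linkS4class{MetaboliteSignature} or a plain list with
#'   fields name, compoundClass, molecularWeight, multiplets
#' @param fieldMHz spectrometer frequency for resolution warnings
#' @return character vector of diagnostics, empty when valid
#' @export
validateSignature <- function(sig, fieldMHz = 600) {
  if (is(sig, "MetaboliteSignature"))
    sig <- list(name = sig@name, compoundClass = sig@compoundClass,
                molecularWeight = sig@molecularWeight,
                multiplets = sig@multiplets)
  out <- character(0)
  if (is.null(sig$compoundClass) || !(sig$compoundClass %in% .COMPOUND_CLASSES))
    out <- c(out, sprintf("class: must be one of %s",
                          paste(.COMPOUND_CLASSES, collapse = ", ")))
  if (is.null(sig$molecularWeight) || sig$molecularWeight <= 0)
    out <- c(out, "mw: must be positive")
  if (length(sig$multiplets %||% list()) < 1L)
    out <- c(out, "multiplets: at least one multiplet required")
  for (i in seq_along(sig$multiplets)) {
    d <- validateMultiplet(sig$multiplets[[i]], fieldMHz = fieldMHz)
    if (length(d))
      out <- c(out, sprintf("multiplet %d: %s", i, d))
  }
  out
}

## ---- multiplet expansion ----------------------------------------------

#' Expand a splitting pattern into line positions and weights
#'
#' First-order expansion: a doublet gives two lines at +/- J/2 with equal
#' weight, dd the four combinations, triplet 1:2:1, quartet 1:3:3:1.
#' Offsets are returned in ppm relative to the multiplet centre
#' (J in Hz divided by the field in MHz); weights sum to one. "m" and "s"
#' give a single line; "ab" is rendered as a doublet on its own centre.
#'
#' @param pattern pattern code
#' @param jHz coupling constants (Hz)
#' @param fieldMHz spectrometer frequency (MHz)
#' @return data.frame with columns offsetPpm, weight
#' @export
expandPattern <- function(pattern, jHz, fieldMHz) {
  jppm <- jHz / fieldMHz
  switch(pattern,
    s = ,
    m = data.frame(offsetPpm = 0, weight = 1),
    d = ,
    ab = data.frame(offsetPpm = c(-jppm / 2, jppm / 2), weight = c(.5, .5)),
    dd = {
      o <- c(-jppm[1] / 2 - jppm[2] / 2, -jppm[1] / 2 + jppm[2] / 2,
             jppm[1] / 2 - jppm[2] / 2,  jppm[1] / 2 + jppm[2] / 2)
      data.frame(offsetPpm = o, weight = rep(.25, 4))
    },
    t = data.frame(offsetPpm = c(-jppm, 0, jppm), weight = c(1, 2, 1) / 4),
    q = data.frame(offsetPpm = jppm * c(-1.5, -.5, .5, 1.5),
                   weight = c(1, 3, 3, 1) / 8),
    stop("unknown pattern: ", pattern))
}

#' Expand a multiplet into absolute line positions
#'
#' @param multiplet a \linkS4class{Multiplet}
#' @param fieldMHz spectrometer frequency (MHz)
#' @return data.frame with columns ppm, weight (weights sum to 1)
#' @export
expandMultiplet <- function(multiplet, fieldMHz) {
  lines <- expandPattern(multiplet@pattern, multiplet@jHz, fieldMHz)
  data.frame(ppm = multiplet@centerPpm + lines$offsetPpm,
             weight = lines$weight)
}

## ---- JSON serialisation -----------------------------------------------

.multiplet_to_list <- function(m) {
  out <- list(center_ppm = m@centerPpm, pattern = m@pattern,
              j_hz = as.numeric(m@jHz), n_protons = as.integer(m@nProtons),
              fwhm_hz = m@fwhmHz)
  if (length(m@phModel))
    out$ph_model <- list(pka = as.numeric(m@phModel$pka),
                         delta_protonated = m@phModel$deltaProtonated,
                         delta_deprotonated = m@phModel$deltaDeprotonated)
  if (isTRUE(m@exchangeable)) out$exchangeable <- TRUE
  if (!is.na(m@exchangeRate)) out$exchange_rate_per_h <- m@exchangeRate
  out$provenance <- m@provenance
  out
}

.multiplet_from_list <- function(x, sigName, idx) {
  cand <- list(centerPpm = x$center_ppm, pattern = x$pattern,
               jHz = as.numeric(x$j_hz %||% numeric(0)),
               nProtons = x$n_protons, fwhmHz = x$fwhm_hz,
               phModel = if (!is.null(x$ph_model))
                 list(pka = as.numeric(x$ph_model$pka),
                      deltaProtonated = x$ph_model$delta_protonated,
                      deltaDeprotonated = x$ph_model$delta_deprotonated)
                 else list(),
               exchangeable = isTRUE(x$exchangeable))
  d <- validateMultiplet(cand)
  d <- d[!grepl("warning", d)]
  if (length(d))
    stop("validation error in signature '", sigName, "', multiplet ", idx,
         ": ", paste(d, collapse = "; "))
  Multiplet(cand$centerPpm, cand$pattern, cand$jHz, cand$nProtons,
            cand$fwhmHz, phModel = cand$phModel,
            exchangeable = cand$exchangeable,
            exchangeRate = x$exchange_rate_per_h %||% NA_real_,
            provenance = x$provenance %||% "reference")
}

#' Read a signature library from JSON
#'
#' The format is a JSON object \code{\{field_mhz, solvent_tag,
#' signatures: [\{name, class, mw, multiplets: [...]\}]\}}. All invariants
#' are validated on load; violations raise errors naming the signature and
#' field. Signatures are returned ordered by name.
#'
#' @param path path to a JSON library file
#' @return a \linkS4class{SignatureLibrary}
#' @export
readSignatureLibrary <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(x$field_mhz) || x$field_mhz <= 0)
    stop("validation error: field_mhz must be positive")
  sigs <- lapply(x$signatures %||% list(), function(s) {
    if (is.null(s$name) || !nzchar(s$name))
      stop("validation error: signature without a name")
    mults <- lapply(seq_along(s$multiplets),
                    function(i) .multiplet_from_list(s$multiplets[[i]],
                                                     s$name, i))
    cand <- list(name = s$name, compoundClass = s$class,
                 molecularWeight = s$mw, multiplets = mults)
    d <- validateSignature(cand, fieldMHz = x$field_mhz)
    d <- d[!grepl("warning", d)]
    if (length(d))
      stop("validation error in signature '", s$name, "': ",
           paste(d, collapse = "; "))
    MetaboliteSignature(s$name, s$class, s$mw, mults)
  })
  SignatureLibrary(sigs, fieldMHz = x$field_mhz,
                   solventTag = x$solvent_tag %||% "")
}

#' Write a signature library to JSON
#'
#' Writing is canonical (fixed key order, signatures sorted by name), so
#' that \code{writeSignatureLibrary(readSignatureLibrary(p), p2)} is a
#' byte-identical round trip for files produced by this writer.
#'
#' @param library a \linkS4class{SignatureLibrary}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeSignatureLibrary <- function(library, path) {
  x <- list(field_mhz = library@fieldMHz, solvent_tag = library@solventTag,
            signatures = unname(lapply(signatures(library), function(s)
              list(name = s@name, class = s@compoundClass,
                   mw = s@molecularWeight,
                   multiplets = lapply(s@multiplets, .multiplet_to_list)))))
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}
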