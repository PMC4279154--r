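#' Final concentrations after additive dilution
#'
#' Additives (each a volume of a stock) are mixed into the base NMR
#' aliquot; for every species the final concentration is
#' sum(stock x volume) / (base volume + all additive volumes). Volume
#' addition is order-independent. Removing an aliquot to the NMR tube
#' afterwards does not change concentrations and is ignored.
#'
#' @param additives data.frame with columns species, volume_uL, stock_mM
#'   (one row per addition; repeat a species to pool contributions)
#' @param baseVolumeUL base aliquot volume (uL), default 700
#' @return named numeric vector of final concentrations (mM) per species
#' @export
finalConcentration <- function(additives, baseVolumeUL = 700) {
  if (!nrow(additives)) return(setNames(numeric(0), character(0)))
  if (any(additives$volume_uL <= 0)) stop("additive volumes must be positive")
  if (any(additives$stock_mM < 0)) stop("stock concentrations must be >= 0")
  total <- baseVolumeUL + sum(additives$volume_uL)
  amounts <- tapply(additives$stock_mM * additives$volume_uL,
                    additives$species, sum)
  out <- as.numeric(amounts) / total
  setNames(out, names(amounts))
}

#' Molarity of a stock solution
#'
#' @param massMg solute mass (mg)
#' @param mwGPerMol molecular weight (g/mol)
#' @param volumeML solution volume (mL)
#' @return concentration in mM
#' @export
stockMolarity <- function(massMg, mwGPerMol, volumeML) {
  if (mwGPerMol <= 0) stop("molecular weight must be positive")
  if (volumeML <= 0) stop("volume must be positive")
  massMg / mwGPerMol / volumeML * 1000
}

#' Phosphate buffer recipe from first principles
#'
#' @param massesG named vector of salt masses (g)
#' @param mws named vector of molecular weights (g/mol); defaults cover
#'   anhydrous K2HPO4 and KH2PO4
#' @param volumeML final volume (mL)
#' @return list with \code{totalMolarity} (mol/L) and \code{baseAcidRatio}
#'   (K2HPO4 : KH2PO4 mole ratio; NA with a single salt)
#' @export
bufferRecipe <- function(massesG, mws = c(K2HPO4 = 174.18, KH2PO4 = 136.09),
                         volumeML = 10) {
  if (!length(massesG)) stop("at least one salt required")
  unknown <- setdiff(names(massesG), names(mws))
  if (length(unknown))
    stop("unknown salt without molecular weight: ",
         paste(unknown, collapse = ", "))
  moles <- massesG / mws[names(massesG)]
  total <- sum(moles) / (volumeML / 1000)
  ratio <- if (all(c("K2HPO4", "KH2PO4") %in% names(massesG)))
    unname(moles[["K2HPO4"]] / moles[["KH2PO4"]]) else NA_real_
  list(totalMolarity = total, baseAcidRatio = ratio)
}

#' Print a prep sheet for the two protocol variants
#'
#' Method "a": extraction in H2O:CH3OH (4:1), dry-down of a 700-uL aliquot
#' for extract-mass recording, reconstitution in deuterated solvent with
#' TSP, then buffer and EDTA additions. Method "b": direct extraction into
#' the deuterated TSP solvent, no dry-down, same additions.
#'
#' @param method "a" or "b"
#' @param file connection passed to \code{cat}
#' @return the final-concentration vector, invisibly
#' @export
prepSheet <- function(method = c("a", "b"), file = "") {
  method <- match.arg(method)
  edtaStock <- stockMolarity(12, 372.24, 1)       # disodium EDTA dihydrate
  buf <- bufferRecipe(c(K2HPO4 = 4.19, KH2PO4 = 0.808))
  ## final concentrations use the nominal stock labels (32 mM, 2.6 M);
  ## the computed stock molarities are printed alongside
  adds <- data.frame(species = c("phosphate", "EDTA"),
                     volume_uL = c(20, 10),
                     stock_mM = c(2600, 32))
  fin <- finalConcentration(adds)
  cat(sprintf("Prep sheet - method '%s'\n", method), file = file)
  if (method == "a") {
    cat("  15.0 mg dry tissue + 1.0 mL H2O:CH3OH (4:1); 850 uL supernatant;\n",
        "  700 uL dried down (record mass), reconstituted in 700 uL\n",
        "  D2O:CD3OD (4:1) + 0.01% w/v d4-TSP\n", sep = "", file = file,
        append = TRUE)
  } else {
    cat("  15.0 mg dry tissue + 1.0 mL D2O:CD3OD (4:1) + 0.01% w/v d4-TSP;\n",
        "  850 uL supernatant; 700 uL to NMR sample (no dry-down)\n",
        sep = "", file = file, append = TRUE)
  }
  cat(sprintf("  + 20 uL 2.6 M potassium phosphate pH 7.4 (computed %.2f M, ratio %.2f)\n",
              buf$totalMolarity, buf$baseAcidRatio), file = file, append = TRUE)
  cat(sprintf("  + 10 uL %.0f mM EDTA (12 mg Na2EDTA.2H2O / 1 mL D2O)\n",
              edtaStock), file = file, append = TRUE)
  cat(sprintf("  final: %.0f mM phosphate, %.0f uM EDTA in 730 uL; 650 uL to tube\n",
              fin[["phosphate"]], fin[["EDTA"]] * 1000),
      file = file, append = TRUE)
  invisible(fin)
}
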