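## Shorthand used only while assembling the builtin library.
.mp <- function(center, pattern, j = numeric(0), nH, fwhm = 1.2,
                ph = list(), exch = FALSE, prov = "reference")
  Multiplet(center, pattern, j, nH, fwhm, phModel = ph,
            exchangeable = exch, provenance = prov)

.sig <- function(name, cls, mw, ...) MetaboliteSignature(name, cls, mw, list(...))

#' Built-in willow metabolite signature library
#'
#' Signature database for 600-MHz 1D 1H-NMR spectra of willow leaf and stem
#' polar extracts in D2O:CD3OD (4:1) buffered to pH 7.4 with EDTA added.
#' Centres of the diagnostic resonances that are documented for this
#' system (sucrose and alpha-glucose anomeric doublets, the citrate AB
#' doublets between 2.50 and 2.75 ppm, the Ca-EDTA complex peaks at 3.10
#' and 2.55 ppm, catechin aromatic signals including the exchangeable
#' H-6/H-8 pair at 6.09/6.00 ppm, the quinate envelope at 1.845-2.073 ppm
#' and TSP at exactly 0.00 ppm) carry provenance "paper"; all remaining
#' shifts are standard reference values for this solvent system and carry
#' provenance "reference". Signatures record the diagnostic multiplets used
#' for fitting, not every resonance of the molecule; crowded mid-field
#' sugar resonances are deliberately under-represented to keep templates
#' well conditioned. Glucose is stored as a single signature whose
#' alpha/beta anomeric doublets each count one proton (an equilibrium
#' convention, see the package vignette).
#'
#' Citrate and malate carry Henderson--Hasselbalch pH models (their centres
#' titrate) and are the default calcium-broadening-sensitive species.
#' Catechin H-6 and H-8 are flagged exchangeable. The "Ca-EDTA" and "EDTA"
#' entries describe the chelator, not metabolites; they are fit targets so
#' that chelator peaks never contaminate neighbouring metabolite estimates.
#'
#' @return a \linkS4class{SignatureLibrary} with 49 signatures
#' @export
builtinWillowLibrary <- function() {
  ph_cit <- function(center)
    list(pka = 5.6, deltaProtonated = center + 0.12,
         deltaDeprotonated = center - 0.002)
  ph_mal <- function(center)
    list(pka = 4.7, deltaProtonated = center + 0.10,
         deltaDeprotonated = center - 0.001)
  sigs <- list(
    ## --- carbohydrates ---
    .sig("sucrose", "carbohydrate", 342.30,
         .mp(5.41, "d", 3.9, 1, prov = "paper"),
         .mp(4.21, "d", 8.8, 1)),
    .sig("glucose", "carbohydrate", 180.16,
         .mp(5.22, "d", 3.8, 1, prov = "paper"),
         .mp(4.64, "d", 8.0, 1),
         .mp(3.24, "dd", c(9.3, 8.0), 1)),
    .sig("fructose", "carbohydrate", 180.16,
         .mp(4.11, "m", nH = 2, fwhm = 1.6)),
    .sig("myo-inositol", "carbohydrate", 180.16,
         .mp(4.06, "t", 2.8, 1),
         .mp(3.27, "t", 9.2, 1)),
    .sig("maltose", "carbohydrate", 342.30,
         .mp(5.40, "d", 3.9, 1),
         .mp(4.66, "d", 7.9, 1)),
    .sig("raffinose", "carbohydrate", 504.42,
         .mp(4.99, "d", 3.7, 1)),
    .sig("stachyose", "carbohydrate", 666.58,
         .mp(5.04, "d", 3.6, 1)),
    .sig("galactose", "carbohydrate", 180.16,
         .mp(5.27, "d", 3.8, 1)),
    ## --- organic acids ---
    .sig("citrate", "organic acid", 192.12,
         .mp(2.67, "ab", 15.8, 2, ph = ph_cit(2.67), prov = "paper"),
         .mp(2.55, "ab", 15.8, 2, ph = ph_cit(2.55), prov = "paper")),
    .sig("malate", "organic acid", 134.09,
         .mp(4.30, "dd", c(10.2, 3.0), 1, ph = ph_mal(4.30)),
         .mp(2.68, "dd", c(15.4, 3.0), 1, ph = ph_mal(2.68)),
         .mp(2.37, "dd", c(15.4, 10.2), 1, ph = ph_mal(2.37))),
    .sig("succinate", "organic acid", 118.09,
         .mp(2.41, "s", nH = 4)),
    .sig("lactate", "organic acid", 90.08,
         .mp(1.33, "d", 6.9, 3),
         .mp(4.12, "q", 6.9, 1)),
    .sig("quinate", "organic acid", 192.17,
         .mp(1.96, "m", nH = 4, fwhm = 1.8, prov = "paper"),
         .mp(4.14, "m", nH = 1, fwhm = 1.6)),
    .sig("ascorbate", "organic acid", 176.12,
         .mp(4.52, "d", 2.0, 1),
         .mp(4.00, "m", nH = 1)),
    .sig("fumarate", "organic acid", 116.07,
         .mp(6.52, "s", nH = 2)),
    .sig("acetate", "organic acid", 60.05,
         .mp(1.92, "s", nH = 3)),
    .sig("formate", "organic acid", 46.03,
         .mp(8.46, "s", nH = 1)),
    .sig("2-oxoglutarate", "organic acid", 146.10,
         .mp(3.01, "t", 6.8, 2),
         .mp(2.45, "t", 6.8, 2)),
    ## --- amino acids ---
    .sig("alanine", "amino acid", 89.09,
         .mp(1.48, "d", 7.2, 3),
         .mp(3.78, "q", 7.2, 1)),
    .sig("threonine", "amino acid", 119.12,
         .mp(1.33, "d", 6.6, 3),
         .mp(4.25, "m", nH = 1)),
    .sig("valine", "amino acid", 117.15,
         .mp(0.99, "d", 7.0, 3),
         .mp(1.04, "d", 7.0, 3)),
    .sig("leucine", "amino acid", 131.17,
         .mp(0.96, "d", 6.2, 6),
         .mp(1.71, "m", nH = 3, fwhm = 1.6)),
    .sig("isoleucine", "amino acid", 131.17,
         .mp(0.94, "t", 7.4, 3),
         .mp(1.01, "d", 7.0, 3)),
    .sig("glutamine", "amino acid", 146.15,
         .mp(2.14, "m", nH = 2, fwhm = 1.6),
         .mp(2.46, "m", nH = 2, fwhm = 1.6)),
    .sig("glutamate", "amino acid", 147.13,
         .mp(2.06, "m", nH = 2, fwhm = 1.6),
         .mp(2.35, "m", nH = 2, fwhm = 1.6)),
    .sig("asparagine", "amino acid", 132.12,
         .mp(2.86, "dd", c(16.9, 7.6), 1),
         .mp(2.95, "dd", c(16.9, 4.3), 1)),
    .sig("aspartate", "amino acid", 133.10,
         .mp(2.69, "dd", c(17.4, 8.2), 1),
         .mp(2.80, "dd", c(17.4, 3.8), 1)),
    .sig("GABA", "amino acid", 103.12,
         .mp(2.30, "t", 7.3, 2),
         .mp(3.01, "t", 7.5, 2),
         .mp(1.90, "m", nH = 2, fwhm = 1.6)),
    .sig("glycine", "amino acid", 75.07,
         .mp(3.56, "s", nH = 2)),
    .sig("lysine", "amino acid", 146.19,
         .mp(3.02, "t", 7.5, 2),
         .mp(1.72, "m", nH = 2, fwhm = 1.6)),
    .sig("arginine", "amino acid", 174.20,
         .mp(3.24, "t", 6.8, 2),
         .mp(1.68, "m", nH = 2, fwhm = 1.6)),
    .sig("tyrosine", "amino acid", 181.19,
         .mp(7.19, "d", 8.5, 2),
         .mp(6.90, "d", 8.5, 2)),
    .sig("methionine", "amino acid", 149.21,
         .mp(2.13, "s", nH = 3),
         .mp(2.64, "t", 7.6, 2)),
    .sig("tryptophan", "amino acid", 204.23,
         .mp(7.73, "d", 8.0, 1),
         .mp(7.54, "d", 8.1, 1)),
    .sig("phenylalanine", "amino acid", 165.19,
         .mp(7.42, "m", nH = 3, fwhm = 1.6),
         .mp(7.33, "m", nH = 2, fwhm = 1.6)),
    ## --- aromatics / secondary metabolites ---
    .sig("catechin", "aromatic", 290.27,
         .mp(6.93, "d", 8.1, 1, prov = "paper"),
         .mp(6.85, "dd", c(8.2, 1.9), 1, prov = "paper"),
         .mp(2.86, "dd", c(16.1, 5.4), 1, prov = "paper"),
         .mp(6.09, "d", 2.2, 1, exch = TRUE, prov = "paper"),
         .mp(6.00, "d", 2.2, 1, exch = TRUE, prov = "paper")),
    .sig("gallocatechin", "aromatic", 306.27,
         .mp(6.42, "s", nH = 2),
         .mp(2.84, "dd", c(16.2, 5.5), 1)),
    .sig("dihydromyricetin", "aromatic", 320.25,
         .mp(6.56, "s", nH = 2),
         .mp(4.95, "d", 11.4, 1)),
    .sig("chlorogenic acid", "aromatic", 354.31,
         .mp(7.62, "d", 15.9, 1),
         .mp(6.38, "d", 15.9, 1),
         .mp(7.15, "s", nH = 1)),
    .sig("salicin", "aromatic", 286.28,
         .mp(7.35, "m", nH = 2, fwhm = 1.6),
         .mp(7.10, "m", nH = 2, fwhm = 1.6)),
    .sig("triandrin", "aromatic", 316.30,
         .mp(7.38, "d", 8.6, 2),
         .mp(6.99, "d", 8.6, 2)),
    .sig("2-phenylethylamine", "aromatic", 121.18,
         .mp(7.36, "m", nH = 5, fwhm = 1.8),
         .mp(3.22, "t", 7.2, 2),
         .mp(2.94, "t", 7.2, 2)),
    .sig("uridine", "aromatic", 244.20,
         .mp(7.87, "d", 8.1, 1),
         .mp(5.91, "d", 8.1, 1)),
    .sig("trigonelline", "other", 137.14,
         .mp(9.12, "s", nH = 1),
         .mp(8.83, "m", nH = 2, fwhm = 1.6)),
    .sig("betaine", "other", 117.15,
         .mp(3.26, "s", nH = 9),
         .mp(3.90, "s", nH = 2)),
    .sig("choline", "other", 104.17,
         .mp(3.19, "s", nH = 9)),
    ## --- standards and chelator species ---
    .sig("TSP", "other", 172.26,
         .mp(0.00, "s", nH = 9, prov = "paper")),
    .sig("Ca-EDTA", "other", 330.36,
         .mp(3.10, "q", 8.0, 8, prov = "paper"),
         .mp(2.55, "s", nH = 4, prov = "paper")),
    .sig("EDTA", "other", 292.24,
         .mp(3.61, "s", nH = 8),
         .mp(3.22, "s", nH = 4))
  )
  SignatureLibrary(sigs, fieldMHz = 600)
}
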