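#' Default composition model of the simulated willow cohort
#'
#' Mean tube concentrations (mM, at the mid-stem/mid-leaf reference) and
#' multiplicative design effects for 19 abundant metabolites. The effect
#' structure encodes the qualitative biology of field-grown biomass
#' willow: sucrose, malate and the flavanols (catechin, gallocatechin,
#' dihydromyricetin) higher in leaf; glucose, glutamine, asparagine and
#' 2-phenylethylamine higher in stem; sucrose the only metabolite rising
#' towards the stem base while most others fall; organic acids rising in
#' older (lower) leaves; and Resolution carrying more glutamine,
#' asparagine, 2-phenylethylamine and quinate while Tora is richer in the
#' major sugars. The leaf/stem contrast is the dominant effect axis, and
#' the absolute levels are calibrated so the quantified leaf total lands
#' near 100 mg/g dry weight - roughly a third of a ~30\% extractable
#' pool - matching field observations for this crop.
#'
#' Columns: \code{leaf}/\code{stem} give the middle-position mean (mM);
#' \code{leaf_top}, \code{leaf_bottom}, \code{stem_top}, \code{stem_bottom}
#' multiply them at the other positions; \code{resolution} multiplies the
#' cell mean for the Resolution genotype (Tora = 1).
#'
#' @return data.frame, one row per metabolite
#' @export
defaultCompositionModel <- function() {
  cm <- read.csv(text = "metabolite,leaf,stem,leaf_top,leaf_bottom,stem_top,stem_bottom,resolution
sucrose,1.00,0.50,1.25,0.80,0.80,1.30,0.87
glucose,0.90,1.30,1.20,0.80,1.25,0.65,0.88
fructose,0.70,0.80,1.15,0.85,1.20,0.70,1.00
malate,1.20,0.50,0.80,1.30,1.25,0.70,1.00
citrate,0.50,0.35,0.80,1.30,1.30,0.75,1.00
succinate,0.20,0.25,1.00,1.00,1.10,0.85,1.00
quinate,0.40,0.50,0.95,1.05,1.15,0.80,1.12
glutamine,0.25,0.50,1.10,0.90,1.30,0.70,1.30
asparagine,0.15,0.40,1.00,1.00,1.20,0.80,1.50
alanine,0.25,0.30,1.20,0.90,1.15,0.80,1.00
threonine,0.15,0.18,1.20,0.90,1.15,0.85,1.10
valine,0.10,0.12,0.90,1.20,1.10,0.85,1.00
GABA,0.18,0.20,0.85,1.30,1.15,0.80,1.00
2-phenylethylamine,0.08,0.35,1.00,1.00,1.20,0.80,1.25
catechin,0.30,0.12,1.10,0.90,1.15,1.30,1.00
gallocatechin,0.25,0.08,1.10,0.90,1.10,1.25,1.00
dihydromyricetin,0.20,0.06,1.20,0.85,1.15,1.00,1.10
ascorbate,0.30,0.35,1.05,0.95,1.10,0.90,1.00
acetate,0.10,0.10,1.00,1.00,1.00,1.00,1.00
", stringsAsFactors = FALSE)
  cm
}

#' Default extractable-pool model
#'
#' Percent of dry biomass recovered as polar extract, by genotype, tissue
#' and position, with the spread treated as a standard deviation across
#' replicate extractions. Leaf yields sit near 30 % at every position;
#' stem yields fall from ~32 % at the top to ~12-14 % at the base.
#'
#' @return data.frame (genotype, tissue, position, meanPct, sdPct)
#' @export
defaultExtractableModel <- function() {
  read.csv(text = "genotype,tissue,position,meanPct,sdPct
Tora,leaf,top,26.9,1.7
Tora,leaf,middle,28.2,1.7
Tora,leaf,bottom,31.1,1.2
Tora,stem,top,32.0,2.9
Tora,stem,middle,18.3,1.8
Tora,stem,bottom,11.9,1.7
Resolution,leaf,top,26.4,2.6
Resolution,leaf,middle,31.6,3.4
Resolution,leaf,bottom,30.0,3.7
Resolution,stem,top,32.4,2.3
Resolution,stem,middle,18.1,1.8
Resolution,stem,bottom,13.8,1.9
", stringsAsFactors = FALSE)
}

#' Construct a cohort design
#'
#' Defaults reproduce the study layout: 2 genotypes x 2 tissues x
#' 3 stem/leaf positions x 2 biological x 3 technical replicates
#' (72 spectra).
#'
#' @param genotypes,tissues,positions design levels
#' @param nBio biological replicates per cell
#' @param nTech technical replicates (separate 15-mg extractions) per
#'   biological sample
#' @param composition composition model data.frame
#'   (\code{\link{defaultCompositionModel}})
#' @param extractable extractable-pool model
#'   (\code{\link{defaultExtractableModel}})
#' @param biologicalCV lognormal CV of biological variation
#' @param technicalCV lognormal CV of technical (extraction) variation,
#'   calibrated so replicate RSDs land in the observed 2-8 % band
#' @param noiseSd spectral baseline noise sd
#' @param prepMethod "a" (dry-down) or "b" (direct deuterated extraction;
#'   adds ascorbate and acetate increments)
#' @param standingTimeH resting time before acquisition; the default 12 h
#'   is the rested protocol under which catechin H/D exchange is complete
#' @param seed RNG seed
#' @return a \linkS4class{CohortDesign}
#' @export
cohortDesign <- function(genotypes = c("Tora", "Resolution"),
                         tissues = c("leaf", "stem"),
                         positions = c("bottom", "middle", "top"),
                         nBio = 2L, nTech = 3L,
                         composition = defaultCompositionModel(),
                         extractable = defaultExtractableModel(),
                         biologicalCV = 0.15, technicalCV = 0.045,
                         noiseSd = 0.5, prepMethod = "a",
                         standingTimeH = 12, seed = 20260101L) {
  if (nTech < 1L || nBio < 1L) stop("replicate counts must be >= 1")
  if (any(composition$leaf < 0) || any(composition$stem < 0))
    stop("concentrations must be non-negative")
  if (!prepMethod %in% c("a", "b")) stop("prepMethod must be 'a' or 'b'")
  new("CohortDesign", genotypes = genotypes, tissues = tissues,
      positions = positions, nBio = as.integer(nBio),
      nTech = as.integer(nTech), composition = composition,
      extractable = extractable, biologicalCV = biologicalCV,
      technicalCV = technicalCV, noiseSd = noiseSd,
      prepMethod = prepMethod, standingTimeH = standingTimeH,
      seed = as.integer(seed))
}

.lognorm_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

.cell_means <- function(cm, genotype, tissue, position) {
  base <- cm[[tissue]]
  poscol <- paste(tissue, position, sep = "_")
  mult <- if (position == "middle") rep(1, nrow(cm)) else cm[[poscol]]
  gmult <- if (genotype == "Resolution") cm$resolution else rep(1, nrow(cm))
  setNames(base * mult * gmult, cm$metabolite)
}

#' Simulate a willow cohort
#'
#' Draws biological compositions per design cell, technical replicates
#' around each biological composition, per-sample extract masses from the
#' extractable-pool model, and (optionally) renders the full spectrum of
#' every sample. Deterministic for a fixed design seed.
#'
#' @param design a \linkS4class{CohortDesign}
#' @param library signature library used for rendering
#' @param config a \code{\link{simConfig}}; its noise sd is overridden by
#'   the design's
#' @param renderSpectra if FALSE, only the metadata and ground-truth
#'   concentration tables are produced (fast path for statistical
#'   simulations)
#' @return list with elements \code{spectra} (list of
#'   \linkS4class{NMRSpectrum}, or NULL), \code{metadata} (data.frame, one
#'   row per sample) and \code{truth} (long data.frame: sample_id,
#'   metabolite, conc_tube_mM)
#' @export
simulateCohort <- function(design = cohortDesign(),
                           library = builtinWillowLibrary(),
                           config = simConfig(), renderSpectra = TRUE) {
  set.seed(design@seed)
  config$noiseSd <- design@noiseSd
  cm <- design@composition
  state <- MatrixState(standingTimeH = design@standingTimeH)
  meta <- list(); truth <- list(); spectra <- list()
  prepAdd <- c(ascorbate = 0.4, acetate = 0.3)  # method "b" increments
  for (g in design@genotypes) for (ti in design@tissues)
    for (po in design@positions) {
      ex <- design@extractable
      exRow <- ex[ex$genotype == g & ex$tissue == ti & ex$position == po, ]
      if (nrow(exRow) != 1L)
        stop("extractable model lacks cell ", paste(g, ti, po))
      mu <- .cell_means(cm, g, ti, po)
      for (b in seq_len(design@nBio)) {
        bioConc <- mu * .lognorm_mult(length(mu), design@biologicalCV)
        for (te in seq_len(design@nTech)) {
          conc <- bioConc * .lognorm_mult(length(mu), design@technicalCV)
          if (design@prepMethod == "b")
            for (nm in names(prepAdd))
              conc[nm] <- (if (nm %in% names(conc)) conc[[nm]] else 0) +
                prepAdd[[nm]]
          frac <- max(1, rnorm(1, exRow$meanPct, exRow$sdPct)) / 100
          extractMass <- frac * 15.0 * 700 / 1000
          id <- sprintf("%s_%s_%s_b%d_t%d", g, ti, po, b, te)
          meta[[id]] <- data.frame(
            sample_id = id, genotype = g, tissue = ti, position = po,
            biological_rep = b, technical_rep = te,
            extract_mass_mg = extractMass, percent_extractable = frac * 100,
            prep_method = design@prepMethod, stringsAsFactors = FALSE)
          truth[[id]] <- data.frame(
            sample_id = id, metabolite = names(conc),
            conc_tube_mM = unname(conc), stringsAsFactors = FALSE)
          if (renderSpectra)
            spectra[[id]] <- simulateSpectrum(
              conc, library, config, state,
              meta = list(sample_id = id, genotype = g, tissue = ti,
                          position = po, biological_rep = b,
                          technical_rep = te,
                          extract_mass_mg = extractMass,
                          prep_method = design@prepMethod))
        }
      }
    }
  list(spectra = if (renderSpectra) spectra else NULL,
       metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}
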