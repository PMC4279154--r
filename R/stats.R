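#' Percent extractable metabolite pool
#'
#' The dried mass of the NMR aliquot is scaled back to the whole extract
#' (extraction volume over aliquot volume) and expressed as a percentage
#' of the dry tissue mass:
#' \code{\%} = mass_mg * (extractionVolume_mL * 1000 / aliquot_uL) /
#' tissueMass_mg * 100.
#'
#' @param extractMassMg dried mass of the aliquot (mg), vectorised
#' @param prep a \linkS4class{PrepRecipe}
#' @return percent of dry biomass that is extractable
#' @export
percentExtractable <- function(extractMassMg, prep = PrepRecipe()) {
  if (prep@tissueMassMg <= 0) stop("zero tissue mass")
  if (any(extractMassMg < 0)) stop("extract mass must be >= 0")
  extractMassMg * (prep@extractionVolumeML * 1000 / prep@aliquotUL) /
    prep@tissueMassMg * 100
}

#' Normalise values to a constant extractable-pool mass
#'
#' Rescales per-sample responses to what they would be had every sample
#' yielded \code{targetMg} of extract: values * target / extract mass.
#' Within-sample metabolite ratios are untouched.
#'
#' @param values numeric vector or matrix (rows = one sample)
#' @param extractMassMg extract mass of the sample(s) (mg)
#' @param targetMg normalisation target (mg), default 3.0
#' @export
normalizeToPool <- function(values, extractMassMg, targetMg = 3.0) {
  if (any(!is.finite(extractMassMg)) || any(extractMassMg <= 0))
    stop("extract mass must be positive; flag the sample instead of dropping it")
  factor <- targetMg / extractMassMg
  if (is.matrix(values)) values * factor else values * factor
}

#' Technical relative standard deviations
#'
#' RSD = 100 * sd / mean of the technical replicates within each
#' biological sample, then averaged across all samples of a tissue.
#' Cells with zero mean are reported missing.
#'
#' @param conc long concentration table with columns metabolite, tissue,
#'   genotype, position, biological_rep, technical_rep and a value column
#' @param value name of the value column (default "conc_tube_mM")
#' @return data.frame (metabolite, tissue, rsd_pct, n_samples)
#' @export
technicalRSD <- function(conc, value = "conc_tube_mM") {
  need <- c("metabolite", "tissue", "genotype", "position", "biological_rep")
  if (!all(need %in% names(conc))) stop("missing grouping columns")
  key <- interaction(conc$metabolite, conc$tissue, conc$genotype,
                     conc$position, conc$biological_rep, drop = TRUE)
  per <- do.call(rbind, lapply(split(conc, key), function(d) {
    m <- mean(d[[value]])
    data.frame(metabolite = d$metabolite[1], tissue = d$tissue[1],
               rsd = if (m == 0) NA_real_ else 100 * sd(d[[value]]) / m)
  }))
  out <- do.call(rbind, lapply(
    split(per, list(per$metabolite, per$tissue), drop = TRUE),
    function(d) data.frame(metabolite = d$metabolite[1], tissue = d$tissue[1],
                           rsd_pct = mean(d$rsd, na.rm = TRUE),
                           n_samples = sum(is.finite(d$rsd)))))
  rownames(out) <- NULL
  out
}

#' Classical one-way ANOVA
#'
#' Thin wrapper around \code{stats::aov} returning the F statistic and its
#' p-value from the F distribution. Two identical groups give F = 0,
#' p = 1.
#'
#' @param values numeric response
#' @param groups group labels (>= 2 groups, every group non-empty)
#' @return named list with \code{F} and \code{p}
#' @export
onewayAnova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 1)) stop("every group needs an observation")
  if (length(values) - nlevels(groups) < 1) stop("no residual degrees of freedom")
  tab <- anova(aov(values ~ groups))
  f <- tab[["F value"]][1]; p <- tab[["Pr(>F)"]][1]
  if (!is.finite(f)) { f <- 0; p <- 1 }   # zero within- and between-group SS
  list(F = f, p = p)
}

.avg_technical <- function(conc, value) {
  key <- list(conc$metabolite, conc$genotype, conc$tissue, conc$position,
              conc$biological_rep)
  agg <- aggregate(conc[[value]], by = setNames(key, c(
    "metabolite", "genotype", "tissue", "position", "biological_rep")), mean)
  names(agg)[ncol(agg)] <- value
  agg
}

#' Screen metabolites for genotype differences
#'
#' Technical replicates are averaged within each biological sample, then a
#' one-way ANOVA on genotype is run separately for every tissue x position
#' x metabolite cell. Rows are sorted by ascending p; those with p below
#' \code{alpha} carry \code{significant = TRUE}. Raw p-values are reported
#' by default; set \code{adjust = "BH"} for a Benjamini-Hochberg column.
#'
#' @param conc long concentration table (see \code{\link{batchProfile}})
#' @param alpha significance threshold (default 0.05)
#' @param value value column name
#' @param adjust "none" (default) or "BH"
#' @return data.frame (tissue, position, metabolite, p, significant
#'   [, p_adj])
#' @export
genotypeScreen <- function(conc, alpha = 0.05, value = "conc_tube_mM",
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (length(unique(conc$genotype)) < 2)
    return(data.frame(tissue = character(0), position = character(0),
                      metabolite = character(0), p = numeric(0),
                      significant = logical(0)))
  avg <- .avg_technical(conc, value)
  out <- list()
  for (ti in unique(avg$tissue)) for (po in unique(avg$position))
    for (met in unique(avg$metabolite)) {
      d <- avg[avg$tissue == ti & avg$position == po &
               avg$metabolite == met, ]
      if (length(unique(d$genotype)) < 2 || nrow(d) < 3) {
        message("genotypeScreen: skipping incomplete cell ",
                paste(ti, po, met))
        next
      }
      a <- onewayAnova(d[[value]], d$genotype)
      out[[length(out) + 1L]] <- data.frame(
        tissue = ti, position = po, metabolite = met, p = a$p,
        stringsAsFactors = FALSE)
    }
  res <- do.call(rbind, out)
  res <- res[order(res$p), , drop = FALSE]
  res$significant <- res$p < alpha
  if (adjust == "BH") res$p_adj <- stats::p.adjust(res$p, "BH")
  rownames(res) <- NULL
  res
}

#' Positional trajectory of a metabolite
#'
#' Technical replicates are averaged per biological sample, then the mean
#' and range over the biological replicates is reported for each position
#' (ordered bottom, middle, top) per genotype x tissue. With only two
#' biological replicates the range is the honest error measure, so lo/hi
#' are the replicate extremes. The normalised variant rescales each
#' sample to the 3-mg extractable pool first.
#'
#' @param conc long concentration table with extract_mass_mg
#' @param metabolite metabolite name
#' @param normalised apply \code{\link{normalizeToPool}} per sample
#' @param value value column
#' @param targetMg pool target (mg)
#' @return data.frame (genotype, tissue, position, mean, lo, hi)
#' @export
trajectory <- function(conc, metabolite, normalised = FALSE,
                       value = "conc_tube_mM", targetMg = 3.0) {
  d <- conc[conc$metabolite == metabolite, ]
  if (!nrow(d)) stop("unknown metabolite: ", metabolite)
  if (normalised)
    d[[value]] <- normalizeToPool(d[[value]], d$extract_mass_mg, targetMg)
  avg <- .avg_technical(d, value)
  posLevels <- intersect(c("bottom", "middle", "top"), unique(avg$position))
  out <- list()
  for (g in unique(avg$genotype)) for (ti in unique(avg$tissue))
    for (po in posLevels) {
      v <- avg[[value]][avg$genotype == g & avg$tissue == ti &
                        avg$position == po]
      if (!length(v)) next
      out[[length(out) + 1L]] <- data.frame(
        genotype = g, tissue = ti, position = po, mean = mean(v),
        lo = min(v), hi = max(v), stringsAsFactors = FALSE)
    }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Compound-class totals and pool proportions
#'
#' Sums quantified concentrations (mg/g dry weight) per compound class for
#' every sample and expresses each class as a proportion of the
#' extractable metabolite pool (percent extractable / 100 * 1000 mg/g).
#' The remainder of the pool - unquantified plus NMR-invisible mass - is
#' floored at zero and flagged when negative.
#'
#' @param conc long table with sample_id, metabolite, conc_mg_per_g
#' @param library \linkS4class{SignatureLibrary} supplying the classes
#' @param percentExtract named vector of percent-extractable per sample id
#' @return data.frame (sample_id, class, mg_per_g, proportion_of_pool,
#'   flag); the classes of each sample plus a "remainder" row
#' @export
classTotals <- function(conc, library, percentExtract) {
  unclassed <- setdiff(unique(conc$metabolite), signatureNames(library))
  if (length(unclassed))
    stop("unclassified metabolite(s): ", paste(unclassed, collapse = ", "))
  cls <- vapply(signatures(library), compoundClass, character(1))
  conc$class <- cls[conc$metabolite]
  out <- list()
  for (id in unique(conc$sample_id)) {
    d <- conc[conc$sample_id == id, ]
    poolMg <- percentExtract[[id]] / 100 * 1000  # mg of pool per g d.w.
    sums <- tapply(d$conc_mg_per_g, d$class, sum)
    rem <- poolMg - sum(sums)
    flag <- if (rem < 0) "pool_exceeded" else ""
    out[[length(out) + 1L]] <- data.frame(
      sample_id = id, class = c(names(sums), "remainder"),
      mg_per_g = c(as.numeric(sums), max(rem, 0)),
      proportion_of_pool = c(as.numeric(sums), max(rem, 0)) / poolMg,
      flag = flag, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
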