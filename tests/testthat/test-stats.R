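test_that("extractable-pool arithmetic follows the volume chain", {
  expect_equal(percentExtractable(0), 0)
  ## 3.15 mg from the 700-uL aliquot of a 1-mL extract of 15 mg tissue
  expect_equal(percentExtractable(3.15), 30.0, tolerance = 1e-12)
  expect_error(percentExtractable(1, PrepRecipe(tissueMassMg = 1e-9)),
               NA)  # tiny but positive mass is fine
  expect_error(percentExtractable(-1), ">= 0")
})

test_that("pool normalisation rescales to 3 mg and preserves ratios", {
  expect_equal(normalizeToPool(c(1, 2), 3.0), c(1, 2))
  expect_equal(normalizeToPool(c(1, 2), 6.0), c(0.5, 1))
  ## stem-bottom sample at 11.9% extractable: factor 3 / (0.119*15*0.7)
  mass <- 0.119 * 15 * 0.7
  expect_equal(normalizeToPool(1, mass), 3 / 1.2495, tolerance = 1e-9)
  expect_equal(round(normalizeToPool(1, mass), 2), 2.40)
  ## within-sample ratios unchanged
  v <- c(a = 2, b = 5)
  n <- normalizeToPool(v, 1.7)
  expect_equal(n[["a"]] / n[["b"]], 2 / 5)
  expect_error(normalizeToPool(1, 0), "positive")
})

test_that("technical RSD is sd/mean within biological samples, averaged per tissue", {
  mk <- function(vals, met = "x", tis = "leaf")
    data.frame(metabolite = met, tissue = tis, genotype = "g",
               position = "top", biological_rep = 1,
               technical_rep = seq_along(vals), conc_tube_mM = vals)
  expect_equal(technicalRSD(mk(c(5, 5, 5)))$rsd_pct, 0)
  expect_equal(technicalRSD(mk(c(9, 10, 11)))$rsd_pct, 10.0)
  ## averaged across two biological samples of one tissue
  d <- rbind(mk(c(9, 10, 11)), transform(mk(c(18, 20, 22)),
                                         biological_rep = 2))
  expect_equal(technicalRSD(d)$rsd_pct, 10.0)

  ## the default simulated cohort lands in the observed 2-8% band
  truthCohort <- simulateCohort(renderSpectra = FALSE)
  conc <- merge(truthCohort$truth, truthCohort$metadata, by = "sample_id")
  rsd <- technicalRSD(conc)
  expect_true(all(rsd$rsd_pct > 2 & rsd$rsd_pct < 8))
})

test_that("one-way ANOVA matches the sum-of-squares oracle", {
  ## two identical groups carry no between-group variance
  a0 <- onewayAnova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(a0$F, 0)
  expect_equal(a0$p, 1)

  ## two-group F equals the squared pooled t statistic
  set.seed(9)
  x <- rnorm(10); g <- rep(c("a", "b"), each = 5)
  tt <- t.test(x ~ g, var.equal = TRUE)
  expect_equal(onewayAnova(x, g)$F, unname(tt$statistic)^2, tolerance = 1e-12)

  ## worked example: SSB = 1.5, SSW = 4 on (1, 4) df
  vals <- c(1, 2, 3, 2, 3, 4); grp <- rep(c("g1", "g2"), each = 3)
  means <- tapply(vals, grp, mean); grand <- mean(vals)
  ssb <- sum(3 * (means - grand)^2)
  ssw <- sum((vals - means[grp])^2)
  fOracle <- (ssb / 1) / (ssw / 4)
  a <- onewayAnova(vals, grp)
  expect_equal(a$F, fOracle)
  expect_equal(a$F, 1.5)
  expect_equal(a$p, 1 - pf(1.5, 1, 4))
  expect_equal(a$p, 0.288, tolerance = 1e-3)

  expect_error(onewayAnova(1:3, rep("a", 3)), "two groups")
})

test_that("genotype screen flags planted effects and controls false positives", {
  ## planted effect: only asparagine differs between genotypes
  cm <- defaultCompositionModel()
  cm$resolution <- ifelse(cm$metabolite == "asparagine", 1.8, 1)
  dsgn <- cohortDesign(composition = cm, biologicalCV = 0.08, seed = 301L)
  ch <- simulateCohort(dsgn, renderSpectra = FALSE)
  conc <- merge(ch$truth, ch$metadata, by = "sample_id")
  scr <- genotypeScreen(conc)
  expect_true(all(c("tissue", "position", "metabolite", "p") %in%
                  colnames(scr)))
  expect_false(is.unsorted(scr$p))
  asn <- scr[scr$metabolite == "asparagine", ]
  expect_gt(sum(asn$significant), nrow(asn) / 2)
  nullRows <- scr[scr$metabolite != "asparagine", ]
  expect_lt(mean(nullRows$significant), 0.15)

  ## under the null the false-positive rate sits near alpha and p is uniform
  cmNull <- defaultCompositionModel(); cmNull$resolution <- 1
  ps <- unlist(lapply(1:9, function(sd) {
    d <- cohortDesign(composition = cmNull, seed = 1000L + sd)
    chN <- simulateCohort(d, renderSpectra = FALSE)
    cN <- merge(chN$truth, chN$metadata, by = "sample_id")
    genotypeScreen(cN)$p
  }))
  expect_gte(length(ps), 900)
  fpr <- mean(ps < 0.05)
  expect_gt(fpr, 0.02); expect_lt(fpr, 0.09)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)

  ## one genotype only: nothing to screen
  one <- conc[conc$genotype == "Tora", ]
  expect_equal(nrow(genotypeScreen(one)), 0)
})

test_that("trajectories order positions and report biological ranges", {
  base <- expand.grid(genotype = "Tora", tissue = "stem",
                      position = c("bottom", "middle", "top"),
                      biological_rep = 1:2, technical_rep = 1:2,
                      stringsAsFactors = FALSE)
  base$sample_id <- with(base, paste(position, biological_rep,
                                     technical_rep, sep = "_"))
  base$metabolite <- "sucrose"
  lev <- c(bottom = 3, middle = 2, top = 1)
  base$conc_tube_mM <- lev[base$position] + 0.1 * (base$biological_rep - 1)
  base$extract_mass_mg <- 2
  tr <- trajectory(base, "sucrose")
  expect_equal(tr$position, c("bottom", "middle", "top"))
  expect_equal(tr$mean, c(3.05, 2.05, 1.05))
  expect_equal(tr$hi - tr$lo, rep(0.1, 3))
  ## constant metabolite gives a flat trajectory
  flat <- base; flat$conc_tube_mM <- 1
  expect_equal(unique(trajectory(flat, "sucrose")$mean), 1)
  expect_error(trajectory(base, "nosuch"), "unknown")

  ## normalised and raw trajectories differ by the per-sample pool factor
  base$extract_mass_mg <- ifelse(base$position == "bottom", 1.5, 3.0)
  trRaw <- trajectory(base, "sucrose")
  trN <- trajectory(base, "sucrose", normalised = TRUE)
  expect_equal(trN$mean[trN$position == "bottom"],
               trRaw$mean[trRaw$position == "bottom"] * 2)
  expect_equal(trN$mean[trN$position == "top"],
               trRaw$mean[trRaw$position == "top"])
})

test_that("sub-three-fold stem declines reverse under pool normalisation", {
  ## extract masses follow the observed stem gradient: ~32% at the top,
  ## ~12% at the bottom of the plant (a 2.69-fold pool difference)
  massTop <- 0.32 * 15 * 0.7; massBottom <- 0.119 * 15 * 0.7
  mk <- function(ratioTopOverBottom) {
    d <- expand.grid(genotype = "g", tissue = "stem",
                     position = c("bottom", "top"), biological_rep = 1:2,
                     technical_rep = 1, stringsAsFactors = FALSE)
    d$sample_id <- with(d, paste(position, biological_rep))
    d$metabolite <- "m"
    d$conc_tube_mM <- ifelse(d$position == "top", ratioTopOverBottom, 1)
    d$extract_mass_mg <- ifelse(d$position == "top", massTop, massBottom)
    d
  }
  dir <- function(tr) sign(tr$mean[tr$position == "top"] -
                           tr$mean[tr$position == "bottom"])
  ## a 2-fold decline (within three-fold) flips direction when normalised
  d2 <- mk(2)
  expect_equal(dir(trajectory(d2, "m")), 1)
  expect_equal(dir(trajectory(d2, "m", normalised = TRUE)), -1)
  ## a 4-fold decline (beyond three-fold) keeps its direction
  d4 <- mk(4)
  expect_equal(dir(trajectory(d4, "m")), 1)
  expect_equal(dir(trajectory(d4, "m", normalised = TRUE)), 1)
})

test_that("class totals account for the extractable pool", {
  lib <- builtinWillowLibrary()
  conc <- data.frame(sample_id = "s1",
                     metabolite = c("sucrose", "glucose", "citrate",
                                    "catechin"),
                     conc_mg_per_g = c(40, 30, 15, 5))
  ct <- classTotals(conc, lib, c(s1 = 30))
  expect_equal(ct$mg_per_g[ct$class == "carbohydrate"], 70)
  expect_equal(ct$mg_per_g[ct$class == "organic acid"], 15)
  expect_equal(sum(ct$proportion_of_pool), 1, tolerance = 1e-9)
  ## 90 mg/g quantified out of a 30% extractable pool is a 30% share
  conc90 <- data.frame(sample_id = "s1", metabolite = "sucrose",
                       conc_mg_per_g = 90)
  ct90 <- classTotals(conc90, lib, c(s1 = 30))
  expect_equal(ct90$proportion_of_pool[ct90$class == "carbohydrate"], 0.30)
  ## a single metabolite is its own class total
  ct1 <- classTotals(data.frame(sample_id = "s", metabolite = "alanine",
                                conc_mg_per_g = 7), lib, c(s = 30))
  expect_equal(ct1$mg_per_g[ct1$class == "amino acid"], 7)
  expect_error(classTotals(data.frame(sample_id = "s", metabolite = "unobt",
                                      conc_mg_per_g = 1), lib, c(s = 30)),
               "unclassified.*unobt")
  ## oversubscribed pool is floored and flagged
  over <- classTotals(data.frame(sample_id = "s", metabolite = "sucrose",
                                 conc_mg_per_g = 400), lib, c(s = 30))
  expect_true(all(over$flag == "pool_exceeded"))
  expect_equal(over$mg_per_g[over$class == "remainder"], 0)
})
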