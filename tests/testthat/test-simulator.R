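test_that("rendered multiplets have the analytic area and line geometry", {
  lib <- builtinWillowLibrary()
  cfg <- smallConfig()
  axis <- configAxis(cfg)
  d <- Multiplet(5.0, "d", 3.8, nProtons = 1, fwhmHz = 1.2)

  ## zero concentration renders nothing
  expect_equal(renderMultiplet(d, 0, axis, 600), numeric(length(axis)))

  ## doublet splitting: J = 3.8 Hz at 600 MHz is 0.00633 ppm
  y <- renderMultiplet(d, 1, axis, 600, fwhmHz = 0.6)
  pk <- which(diff(sign(diff(y))) == -2) + 1
  expect_length(pk, 2)
  expect_lt(abs(diff(axis[pk]) - 3.8 / 600), 2 * 12 / 16384)
  hts <- y[pk]   # sampled apices; grid offset allows a small height skew
  expect_equal(hts[1], hts[2], tolerance = 0.05)

  ## trapezoid oracle: integral over >= 50 FWHM is c * nH * K within 1%
  t3 <- Multiplet(3.0, "t", 7.3, nProtons = 2, fwhmHz = 1.2)
  yy <- renderMultiplet(t3, 1.7, axis, 600, fwhmHz = 1.2, areaConstant = 1,
                        truncFwhm = 200)
  area <- trapzOracle(axis, yy, 3.0 - 0.3, 3.0 + 0.3)
  expect_equal(area, 1.7 * 2, tolerance = 0.01)

  ## non-uniform axis rejected
  expect_error(renderMultiplet(d, 1, c(axis[1:10], 5), 600), "uniform")
})

test_that("simulated spectra are linear in concentration and conserve total area", {
  lib <- builtinWillowLibrary()
  cfg <- smallConfig(waterArea = 0, meohArea = 0)
  comp <- c(sucrose = 1.2, alanine = 0.7)
  base <- simulateSpectrum(numeric(0), lib, cfg, cleanMatrix())
  s1 <- simulateSpectrum(comp, lib, cfg, cleanMatrix())
  s2 <- simulateSpectrum(2 * comp, lib, cfg, cleanMatrix())
  expect_equal(intensity(s2) - intensity(base),
               2 * (intensity(s1) - intensity(base)), tolerance = 1e-10)

  ## total integral = K * sum(c * nH) within 1% (TSP included)
  nh <- function(nm) sum(vapply(multiplets(getSignature(lib, nm)),
                                function(m) m@nProtons, numeric(1)))
  want <- sum(vapply(names(comp), function(nm) comp[[nm]] * nh(nm),
                     numeric(1))) + cfg$tspConcMM * 9
  got <- trapzOracle(ppm(s1), intensity(s1), -1, 11)
  expect_equal(got, want, tolerance = 0.01)

  ## diagnostic windows: sucrose anomeric doublet rises far above noise
  cfgN <- smallConfig(noiseSd = 0.5)
  set.seed(11)
  sN <- simulateSpectrum(c(sucrose = 1.8), lib, cfgN, cleanMatrix())
  win <- ppm(sN) >= 5.40 & ppm(sN) <= 5.425
  expect_gt(max(intensity(sN)[win]), 5 * 0.5)

  expect_error(simulateSpectrum(c(nosuch = 1), lib, cfg), "unknown")
})

test_that("matrix effects: pH shifts, Ca broadening, H/D exchange, chelator peaks", {
  lib <- builtinWillowLibrary()
  cfg <- smallConfig()
  plan <- buildRenderPlan(c(citrate = 1, catechin = 1, sucrose = 1), lib, cfg)

  ## standing time zero leaves exchangeable areas untouched
  p0 <- applyMatrixEffects(plan, MatrixState(standingTimeH = 0, edtaMM = 0,
                                             totalCaMM = 0), lib, cfg)
  expect_equal(p0$areaScale, rep(1, nrow(p0)))

  ## 6 h at the default rate leaves 10% of the exchangeable area
  p6 <- applyMatrixEffects(plan, MatrixState(standingTimeH = 6, edtaMM = 0,
                                             totalCaMM = 0), lib, cfg)
  exchRows <- p6$metabolite == "catechin" & p6$areaScale < 1
  expect_equal(sum(exchRows), 2)
  expect_equal(unique(round(p6$areaScale[exchRows], 6)), 0.1)
  ## non-exchangeable rows invariant
  expect_equal(p6$areaScale[!exchRows], rep(1, sum(!exchRows)))

  ## monotone non-increasing decay in standing time
  times <- c(0, 1, 3, 6, 12, 24)
  areas <- vapply(times, function(h) {
    p <- applyMatrixEffects(plan, MatrixState(standingTimeH = h, edtaMM = 0,
                                              totalCaMM = 0), lib, cfg)
    sum(p$areaScale[p$metabolite == "catechin"])
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))

  ## EDTA at or above total Ca removes all broadening
  pEq <- applyMatrixEffects(plan, MatrixState(totalCaMM = 0.4, edtaMM = 0.45,
                                              standingTimeH = 0), lib, cfg)
  cit0 <- plan$fwhmHz[plan$metabolite == "citrate"]
  expect_equal(pEq$fwhmHz[pEq$metabolite == "citrate"], cit0)
  ## free calcium broadens citrate by 1 + beta * freeCa
  pCa <- applyMatrixEffects(plan, MatrixState(totalCaMM = 1.0, edtaMM = 0.2,
                                              standingTimeH = 0), lib, cfg)
  expect_equal(pCa$fwhmHz[pCa$metabolite == "citrate"], cit0 * (1 + 2 * 0.8))
  ## sucrose untouched by calcium
  expect_equal(pCa$fwhmHz[pCa$metabolite == "sucrose"],
               plan$fwhmHz[plan$metabolite == "sucrose"])

  ## chelator peaks appear split into complexed and free pools
  expect_true(any(pCa$metabolite == "Ca-EDTA"))
  expect_equal(unique(pCa$concentrationMM[pCa$metabolite == "Ca-EDTA"]), 0.2)
  expect_false(any(pCa$metabolite == "EDTA"))  # no excess EDTA left
  pXs <- applyMatrixEffects(plan, MatrixState(totalCaMM = 0.1, edtaMM = 0.45,
                                              standingTimeH = 0), lib, cfg)
  expect_equal(unique(pXs$concentrationMM[pXs$metabolite == "EDTA"]), 0.35)

  ## pH model: centre is the Henderson-Hasselbalch mix of the state shifts
  m <- multiplets(getSignature(lib, "citrate"))[[1]]
  pAcid <- applyMatrixEffects(plan, MatrixState(ph = 5.6, totalCaMM = 0,
                                                edtaMM = 0, standingTimeH = 0),
                              lib, cfg)
  want <- 0.5 * m@phModel$deltaProtonated + 0.5 * m@phModel$deltaDeprotonated
  expect_equal(pAcid$centerPpm[pAcid$metabolite == "citrate"][1], want,
               tolerance = 1e-9)
})

test_that("cohort simulation is seeded, deterministic and reproduces the design", {
  dsgn <- cohortDesign(nBio = 1L, nTech = 2L, noiseSd = 0.2, seed = 42L)
  a <- simulateCohort(dsgn, config = smallConfig(), renderSpectra = TRUE)
  b <- simulateCohort(dsgn, config = smallConfig(), renderSpectra = TRUE)
  expect_identical(lapply(a$spectra, intensity), lapply(b$spectra, intensity))
  expect_identical(a$truth, b$truth)
  expect_equal(nrow(a$metadata), 2 * 2 * 3 * 1 * 2)

  ## default design dimensions: 2 x 2 x 3 x 2 x 3 = 72 samples
  full <- simulateCohort(renderSpectra = FALSE)
  expect_equal(nrow(full$metadata), 72)
  expect_equal(nrow(full$truth), 72 * nrow(defaultCompositionModel()))

  ## zero noise and zero variability collapse each cell to identical spectra
  flat <- cohortDesign(nBio = 1L, nTech = 2L, biologicalCV = 0,
                       technicalCV = 0, noiseSd = 0, seed = 5L)
  fc <- simulateCohort(flat, config = smallConfig())
  ids <- fc$metadata$sample_id[fc$metadata$tissue == "leaf" &
                               fc$metadata$position == "top" &
                               fc$metadata$genotype == "Tora"]
  expect_identical(intensity(fc$spectra[[ids[1]]]),
                   intensity(fc$spectra[[ids[2]]]))

  ## extractable pool: stem top yields roughly three-fold more than bottom
  md <- full$metadata
  ratio <- mean(md$percent_extractable[md$tissue == "stem" &
                                       md$position == "top"]) /
           mean(md$percent_extractable[md$tissue == "stem" &
                                       md$position == "bottom"])
  expect_gt(ratio, 2.2)
  expect_lt(ratio, 3.2)
  ## and leaf sits near 30% of dry mass
  leafPct <- mean(md$percent_extractable[md$tissue == "leaf"])
  expect_gt(leafPct, 26); expect_lt(leafPct, 32)

  ## prep method "b" adds the ascorbate/acetate increments
  pb <- cohortDesign(nBio = 1L, nTech = 1L, biologicalCV = 0,
                     technicalCV = 0, noiseSd = 0, prepMethod = "b", seed = 5L)
  pa <- cohortDesign(nBio = 1L, nTech = 1L, biologicalCV = 0,
                     technicalCV = 0, noiseSd = 0, prepMethod = "a", seed = 5L)
  ta <- simulateCohort(pa, renderSpectra = FALSE)$truth
  tb <- simulateCohort(pb, renderSpectra = FALSE)$truth
  id <- ta$sample_id[1]; idb <- tb$sample_id[1]
  da <- ta[ta$sample_id == id, ]; db <- tb[tb$sample_id == idb, ]
  expect_equal(db$conc_tube_mM[db$metabolite == "ascorbate"] -
               da$conc_tube_mM[da$metabolite == "ascorbate"], 0.4)
  expect_equal(db$conc_tube_mM[db$metabolite == "acetate"] -
               da$conc_tube_mM[da$metabolite == "acetate"], 0.3)
})
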