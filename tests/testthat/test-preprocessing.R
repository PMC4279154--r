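lib <- builtinWillowLibrary()

test_that("TSP referencing finds the apex, ties break towards zero", {
  cfg <- smallConfig()
  s <- simulateSpectrum(c(sucrose = 1), lib, cfg, cleanMatrix())
  r <- referenceToTsp(s)
  ## TSP already on 0.00: shift is at most the digital resolution
  expect_lt(abs(spectrumMeta(r)$reference_shift_ppm), 12 / 16384)

  ## constructed +0.02 ppm mis-reference comes back as a -0.02 shift
  s2 <- simulateSpectrum(c(sucrose = 1), lib, cfg, cleanMatrix(),
                         globalShiftPpm = 0.02)
  r2 <- referenceToTsp(s2)
  expect_lt(abs(spectrumMeta(r2)$reference_shift_ppm + 0.02),
            1.5 * 12 / 16384)

  ## two exactly equal apices: the one nearer 0 ppm wins
  ax <- configAxis(cfg)
  y <- numeric(length(ax))
  i1 <- which.min(abs(ax + 0.2)); i2 <- which.min(abs(ax - 0.1))
  y[i1] <- 10; y[i2] <- 10
  tie <- new("NMRSpectrum", ppm = ax, intensity = y, fieldMHz = 600,
             meta = list())
  rt <- referenceToTsp(tie)
  expect_equal(spectrumMeta(rt)$reference_shift_ppm, -ax[i2])

  ## featureless spectrum cannot be referenced
  set.seed(3)
  flat <- new("NMRSpectrum", ppm = ax, intensity = rnorm(length(ax)),
              fieldMHz = 600, meta = list())
  expect_error(referenceToTsp(flat), "noise floor")
})

test_that("binning integrates exactly and drops excluded buckets whole", {
  cfg <- smallConfig()
  ax <- configAxis(cfg)
  zero <- new("NMRSpectrum", ppm = ax, intensity = numeric(length(ax)),
              fieldMHz = 600, meta = list())
  expect_true(all(binSpectrum(zero) == 0))

  ## a narrow unit-area line inside one bucket lands there almost entirely
  ## (fine local axis: the line must be well-sampled and FWHM << width)
  fine <- seq(2.9, 3.1, by = 1e-5)
  m <- Multiplet(3.0025, "s", nProtons = 1, fwhmHz = 0.1)
  y <- renderMultiplet(m, 1, fine, 600, fwhmHz = 0.1, truncFwhm = 600)
  s <- new("NMRSpectrum", ppm = fine, intensity = y, fieldMHz = 600,
           meta = list())
  b <- binSpectrum(s, exclusions = list())
  ed <- attr(b, "edges")
  hit <- which(ed$left <= 3.0025 & ed$right > 3.0025)
  expect_equal(unname(b[hit]), 1, tolerance = 0.01)
  expect_lt(max(b[c(hit - 1, hit + 1)]), 0.01)

  ## conservation: retained + dropped = integral over the binned range
  s2 <- simulateSpectrum(c(sucrose = 1, citrate = 0.5), lib, cfg)
  bAll <- binSpectrum(s2, exclusions = list())
  total <- integrateRegion(s2, -0.05, 10)
  expect_equal(sum(bAll), total, tolerance = 1e-9)
  bEx <- binSpectrum(s2)
  dropped <- attr(bEx, "droppedEdges")
  droppedInt <- sum(integrateRegion(s2, dropped$left[1], dropped$right[1]))
  droppedAll <- sum(vapply(seq_len(nrow(dropped)), function(i)
    integrateRegion(s2, dropped$left[i], dropped$right[i]), numeric(1)))
  expect_equal(sum(bEx), total - droppedAll, tolerance = 1e-6)

  ## bad arguments
  expect_error(binSpectrum(s2, width = -0.1), "positive")
  expect_error(binSpectrum(s2, range = c(10, -0.05)), "inverted")
})

test_that("TSP scaling normalises the reference region and is idempotent", {
  cfg <- smallConfig()
  s <- simulateSpectrum(c(sucrose = 1), lib, cfg, cleanMatrix())
  sc <- scaleToTsp(s)
  expect_equal(integrateRegion(sc, -0.05, 0.05), 1, tolerance = 1e-12)
  sc2 <- scaleToTsp(sc)
  expect_equal(intensity(sc2), intensity(sc), tolerance = 1e-12)
  expect_equal(spectrumMeta(sc2)$tsp_area, spectrumMeta(sc)$tsp_area,
               tolerance = 1e-9)

  ## doubling the TSP level halves every scaled bucket
  cfg2 <- cfg; cfg2$tspConcMM <- 2 * cfg$tspConcMM
  sBig <- simulateSpectrum(c(sucrose = 1), lib, cfg2, cleanMatrix())
  b1 <- binSpectrum(scaleToTsp(s))
  b2 <- binSpectrum(scaleToTsp(sBig))
  sucBins <- which(attr(b1, "edges")$center > 5.39 &
                   attr(b1, "edges")$center < 5.43)
  expect_equal(unname(b2[sucBins]), unname(b1[sucBins]) / 2,
               tolerance = 1e-6)

  zero <- new("NMRSpectrum", ppm = ppm(s),
              intensity = numeric(length(ppm(s))), fieldMHz = 600,
              meta = list())
  expect_error(scaleToTsp(zero), "not positive")
})

test_that("residual shifts below 0.004 ppm keep every marker peak in its bucket", {
  cfg <- smallConfig()
  comp <- c(glycine = 1.5, acetate = 1.2, formate = 0.8, betaine = 0.5)
  shifts <- c(-0.002, 0, 0.002)   # residual mis-referencing artifacts
  markers <- c(3.56, 1.92, 8.46, 3.26)
  assigned <- sapply(shifts, function(sh) {
    s <- simulateSpectrum(comp, lib, cfg, globalShiftPpm = sh)
    s <- referenceToTsp(s)
    b <- binSpectrum(s, exclusions = list())
    ed <- attr(b, "edges")
    ax <- ppm(s); y <- intensity(s)
    vapply(markers, function(mk) {
      win <- which(abs(ax - mk) < 0.05)
      apex <- ax[win[which.max(y[win])]]
      which(ed$left <= apex & ed$right > apex)
    }, numeric(1))
  })
  expect_true(all(assigned[, 1] == assigned[, 2]))
  expect_true(all(assigned[, 2] == assigned[, 3]))
})

test_that("bucket table assembly orders samples and can drop the catechin bins", {
  cfg <- smallConfig()
  mkspec <- function(id, catechin, aged) {
    st <- MatrixState(standingTimeH = if (aged) 12 else 0)
    simulateSpectrum(c(catechin = catechin, sucrose = 1), lib, cfg, st,
                     meta = list(sample_id = id, tissue = "leaf",
                                 genotype = if (aged) "aged" else "fresh"))
  }
  specs <- c(lapply(1:3, function(i) mkspec(sprintf("f%d", i), 0.6, FALSE)),
             lapply(1:3, function(i) mkspec(sprintf("a%d", i), 0.6, TRUE)))
  bt <- assembleBucketTable(specs)
  expect_s4_class(bt, "BucketTable")
  expect_equal(colnames(SummarizedExperiment::assay(bt)),
               sort(c(sprintf("f%d", 1:3), sprintf("a%d", 1:3))))
  expect_true(isScaled(bt))
  ## no bucket centre may sit inside an excluded region
  expect_true(all(abs(bucketCenters(bt) - 4.82) > 0.045))

  btDrop <- assembleBucketTable(specs, dropCatechinBins = TRUE)
  ed <- SummarizedExperiment::rowData(bt)
  nHit <- sum((ed$left <= 6.09 & ed$right > 6.09) |
              (ed$left <= 6.00 & ed$right > 6.00))
  expect_equal(nrow(bt) - nrow(btDrop), nHit)
  expect_gt(nHit, 0)
  expect_false(any(bucketCenters(btDrop) > 5.995 &
                   bucketCenters(btDrop) < 6.10 &
                   vapply(bucketCenters(btDrop), function(ctr)
                     (ctr - 0.0075 <= 6.09 & ctr + 0.0075 > 6.09) ||
                     (ctr - 0.0075 <= 6.00 & ctr + 0.0075 > 6.00),
                     logical(1))))

  ## with the exchangeable bins present, ageing is detectable there;
  ## after dropping them the remaining catechin bins carry no age signal
  v <- bucketValues(bt)
  fresh <- grepl("^f", rownames(v)); aged <- grepl("^a", rownames(v))
  ctr <- bucketCenters(bt)
  exchBin <- which(ctr > 6.085 & ctr < 6.10)[1]
  stableBin <- which(ctr > 6.925 & ctr < 6.94)[1]
  expect_gt(mean(v[fresh, exchBin]), 10 * mean(v[aged, exchBin]))
  expect_equal(mean(v[fresh, stableBin]), mean(v[aged, stableBin]),
               tolerance = 0.02)

  ## incompatible axes are refused
  other <- simulateSpectrum(c(sucrose = 1), lib,
                            simConfig(nPoints = 8192L, sweepPpm = 6,
                                      noiseSd = 0),
                            meta = list(sample_id = "odd"))
  expect_error(assembleBucketTable(c(specs, list(other))), "mixed")
})
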