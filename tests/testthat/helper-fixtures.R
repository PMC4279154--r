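## Shared fixtures: a reduced-resolution acquisition configuration for fast
## tests (same sweep and field, fewer points) and small oracle utilities.

smallConfig <- function(noiseSd = 0, ...)
  simConfig(nPoints = 16384L, noiseSd = noiseSd, ...)

## Library restricted to a set of signatures (plus whatever extra names).
subLibrary <- function(names, lib = builtinWillowLibrary())
  SignatureLibrary(unname(signatures(lib)[unique(names)]),
                   fieldMHz = fieldMHz(lib))

## Matrix state with no chelator chemistry and no exchange: clean spectra.
cleanMatrix <- function()
  MatrixState(totalCaMM = 0, edtaMM = 0, standingTimeH = 0)

## Brute-force multiplet expansion oracle: every first-order pattern is a
## convolution of doublets (t = d*d with equal J, q = d*d*d, dd = d(J1)*d(J2)).
## Independent of expandPattern's closed forms.
convolveDoublets <- function(jHzList, fieldMHz) {
  pos <- 0; w <- 1
  for (j in jHzList) {
    half <- j / fieldMHz / 2
    pos <- c(outer(pos, c(-half, half), `+`))
    w <- c(outer(w, c(0.5, 0.5), `*`))
  }
  agg <- tapply(w, round(pos, 12), sum)
  data.frame(offsetPpm = as.numeric(names(agg)), weight = as.numeric(agg))
}

## Sorted-and-aggregated view of expandPattern for comparison.
normalizeLines <- function(df) {
  agg <- tapply(df$weight, round(df$offsetPpm, 12), sum)
  data.frame(offsetPpm = as.numeric(names(agg)), weight = as.numeric(agg))
}

## Every printed final concentration of the published additive-optimisation
## matrix, as (volumes/stocks in, printed concentration out). `unit` maps
## the mM result onto the printed unit (1000 = uM).
table1Rows <- function() {
  edta32 <- function(vol) data.frame(species = "EDTA", volume_uL = vol,
                                     stock_mM = 32)
  edta3p2 <- function(vol) data.frame(species = "EDTA", volume_uL = vol,
                                      stock_mM = 3.2)
  buffer <- function(vol) data.frame(species = "phosphate", volume_uL = vol,
                                     stock_mM = 2600)
  list(
    list(adds = edta3p2(10),  want = c(EDTA = 45),  unit = 1000),
    list(adds = edta3p2(30),  want = c(EDTA = 131), unit = 1000),
    list(adds = edta3p2(50),  want = c(EDTA = 213), unit = 1000),
    list(adds = edta3p2(100), want = c(EDTA = 400), unit = 1000),
    list(adds = edta32(10),   want = c(EDTA = 450), unit = 1000),
    list(adds = data.frame(species = "KF", volume_uL = 10, stock_mM = 2000),
         want = c(KF = 28), unit = 1),
    list(adds = buffer(10),   want = c(phosphate = 37), unit = 1),
    list(adds = rbind(buffer(10), edta32(10)),
         want = c(EDTA = 444, phosphate = 36), unit = c(1000, 1)),
    list(adds = rbind(buffer(20), edta32(10)),
         want = c(EDTA = 438, phosphate = 71), unit = c(1000, 1)),
    list(adds = rbind(buffer(20), edta32(20)),
         want = c(EDTA = 865, phosphate = 70), unit = c(1000, 1)))
}

## Direct trapezoid on a vector (oracle independent of .cum_integral).
trapzOracle <- function(x, y, a, b) {
  keep <- x >= a & x <= b
  pracma::trapz(x[keep], y[keep])
}
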