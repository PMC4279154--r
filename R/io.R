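#' Write a spectrum to disk
#'
#' Two-column ASCII (ppm, intensity; tab separated) or JCAMP-DX with an
#' \code{XYDATA=(X++(Y..Y))} block in AFFN form. Both are plain text and
#' round-trip through \code{\link{readSpectrum}}.
#'
#' @param spectrum an \linkS4class{NMRSpectrum}
#' @param path output path
#' @param format "tsv" or "jcamp"
#' @export
writeSpectrum <- function(spectrum, path, format = c("tsv", "jcamp")) {
  format <- match.arg(format)
  x <- ppm(spectrum); y <- intensity(spectrum)
  if (format == "tsv") {
    write.table(data.frame(ppm = x, intensity = y), path, sep = "\t",
                row.names = FALSE, col.names = TRUE, quote = FALSE)
  } else {
    n <- length(x)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      sprintf("##TITLE=%s", spectrum@meta$sample_id %||% "spectrum"),
      "##JCAMP-DX=5.00",
      "##DATA TYPE=NMR SPECTRUM",
      "##XUNITS=PPM", "##YUNITS=ARBITRARY",
      sprintf("##.OBSERVE FREQUENCY=%.6g", fieldMHz(spectrum)),
      sprintf("##FIRSTX=%.10g", x[1]), sprintf("##LASTX=%.10g", x[n]),
      sprintf("##NPOINTS=%d", n), "##XFACTOR=1", "##YFACTOR=1",
      "##XYDATA=(X++(Y..Y))"), con)
    step <- (x[n] - x[1]) / (n - 1)
    per <- 6L
    for (i in seq(1L, n, by = per)) {
      j <- min(i + per - 1L, n)
      writeLines(paste(c(sprintf("%.10g", x[i]),
                         sprintf("%.8g", y[i:j])), collapse = " "), con)
    }
    writeLines("##END=", con)
  }
  invisible(path)
}

.read_jcamp <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^##", lines)
  getval <- function(key) {
    i <- grep(paste0("^##", key, "="), lines)
    if (!length(i)) return(NULL)
    sub(paste0("^##", key, "="), "", lines[i[1]])
  }
  freq <- as.numeric(getval("\\.OBSERVE FREQUENCY") %||% "600")
  xf <- as.numeric(getval("XFACTOR") %||% "1")
  yf <- as.numeric(getval("YFACTOR") %||% "1")
  start <- grep("^##XYDATA=", lines)
  if (!length(start)) stop("unreadable JCAMP file: no XYDATA block")
  end <- grep("^##END", lines)
  end <- min(end[end > start[1]])
  xs <- list(); ys <- list()
  for (ln in lines[(start[1] + 1L):(end - 1L)]) {
    tok <- as.numeric(strsplit(trimws(ln), "[ \t]+")[[1]])
    xs[[length(xs) + 1L]] <- tok[1]
    ys[[length(ys) + 1L]] <- tok[-1]
  }
  firstx <- unlist(xs) * xf
  yv <- unlist(ys) * yf
  counts <- lengths(ys)
  n <- as.integer(getval("NPOINTS") %||% length(yv))
  lastx <- as.numeric(getval("LASTX") %||% NA)
  firstx0 <- as.numeric(getval("FIRSTX") %||% firstx[1])
  step <- if (is.finite(lastx)) (lastx - firstx0) / (n - 1) else
    (firstx[2] - firstx[1]) / counts[1]
  x <- firstx0 + step * (seq_len(n) - 1L)
  list(ppm = x, intensity = yv[seq_len(n)], fieldMHz = freq)
}

#' Read a spectrum from disk
#'
#' Accepts two-column text (ppm, intensity; header optional) or JCAMP-DX
#' XYDATA. A descending axis is reversed so spectra are always returned
#' with ascending ppm; a non-uniform axis is resampled onto a uniform
#' grid with a warning.
#'
#' @param path input path
#' @param format "tsv" or "jcamp"; default guesses from the extension
#' @param fieldMHz spectrometer frequency when the file does not carry one
#' @param meta metadata list to attach
#' @return an \linkS4class{NMRSpectrum}
#' @export
readSpectrum <- function(path, format = NULL, fieldMHz = 600, meta = list()) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  format <- format %||%
    (if (grepl("\\.(jdx|dx|jcamp)$", path, ignore.case = TRUE)) "jcamp"
     else "tsv")
  if (format == "jcamp") {
    d <- .read_jcamp(path)
    x <- d$ppm; y <- d$intensity; fieldMHz <- d$fieldMHz
  } else {
    first <- readLines(path, n = 1L)
    skip <- if (suppressWarnings(
      any(is.na(as.numeric(strsplit(first, "[\t, ]+")[[1]]))))) 1L else 0L
    tab <- read.table(path, skip = skip)
    x <- tab[[1]]; y <- tab[[2]]
  }
  if (length(x) >= 2 && x[1] > x[length(x)]) { x <- rev(x); y <- rev(y) }
  d <- diff(x)
  if (length(d) && (max(d) - min(d)) > 1e-8 * mean(d)) {
    warning("non-uniform axis; resampling to a uniform grid")
    grid <- seq(min(x), max(x), length.out = length(x))
    y <- approx(x, y, xout = grid)$y
    x <- grid
  }
  new("NMRSpectrum", ppm = x, intensity = y, fieldMHz = fieldMHz,
      meta = meta)
}

#' Write cohort outputs as plain text
#'
#' Spectra as two-column TSV plus a sidecar metadata CSV and the
#' ground-truth concentration CSV.
#'
#' @param cohort list from \code{\link{simulateCohort}}
#' @param dir output directory (created if needed)
#' @param format spectrum format, "tsv" or "jcamp"
#' @export
writeCohort <- function(cohort, dir, format = "tsv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "jcamp") ".jdx" else ".tsv"
  for (id in names(cohort$spectra))
    writeSpectrum(cohort$spectra[[id]], file.path(dir, paste0(id, ext)),
                  format)
  write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
            row.names = FALSE)
  write.csv(cohort$truth, file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a directory of spectra with its sidecar metadata
#'
#' @param dir directory holding spectra (.tsv or .jdx) and metadata.csv
#' @return list of \linkS4class{NMRSpectrum}, metadata attached per sample
#' @export
readCohort <- function(dir) {
  metaPath <- file.path(dir, "metadata.csv")
  md <- if (file.exists(metaPath)) read.csv(metaPath) else NULL
  files <- list.files(dir, pattern = "\\.(tsv|jdx)$", full.names = TRUE)
  files <- files[order(basename(files))]
  spectra <- list()
  for (f in files) {
    id <- sub("\\.(tsv|jdx)$", "", basename(f))
    meta <- list(sample_id = id)
    if (!is.null(md) && id %in% md$sample_id)
      meta <- c(meta, as.list(md[md$sample_id == id, ,
                                 drop = FALSE])[-1])
    spectra[[id]] <- readSpectrum(f, meta = meta)
  }
  spectra
}
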