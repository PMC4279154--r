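#' Unit-variance scaling
#'
#' Centres each column and divides by its standard deviation. Columns
#' with zero variance are left centred, given scale 1 and flagged rather
#' than producing NaN.
#'
#' @param x numeric matrix (samples x variables)
#' @return list with \code{x} (scaled matrix), \code{center},
#'   \code{scale}, \code{flagged} (names/indices of constant columns)
#' @export
uvScale <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least two rows")
  ctr <- colMeans(x)
  sds <- apply(x, 2, sd)
  flagged <- which(sds == 0 | !is.finite(sds))
  sds[flagged] <- 1
  list(x = sweep(sweep(x, 2, ctr), 2, sds, "/"), center = ctr, scale = sds,
       flagged = if (length(flagged))
         (colnames(x) %||% as.character(seq_len(ncol(x))))[flagged]
       else character(0))
}

#' Invert unit-variance scaling
#' @param scaled the list returned by \code{\link{uvScale}}
#' @export
uvUnscale <- function(scaled)
  sweep(sweep(scaled$x, 2, scaled$scale, "*"), 2, scaled$center, "+")

## Deterministic sign convention: the largest-|loading| element of each
## component is made positive (first such element on ties).
.fix_signs <- function(loadings, scores) {
  for (j in seq_len(ncol(loadings))) {
    k <- which.max(abs(loadings[, j]))
    if (loadings[k, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(loadings = loadings, scores = scores)
}

#' Principal component analysis via singular value decomposition
#'
#' Operates on an already unit-variance-scaled (or otherwise centred)
#' matrix; no further centring is applied. Components come from the SVD
#' of the matrix, with a deterministic sign convention (largest-magnitude
#' loading positive).
#'
#' @param x scaled matrix (samples x variables)
#' @param nComp number of components to keep
#' @return a \linkS4class{PCAModel}
#' @export
pcaFit <- function(x, nComp = min(dim(x) - c(1L, 0L))) {
  x <- as.matrix(x)
  sv <- svd(x)
  rank <- sum(sv$d > max(dim(x)) * .Machine$double.eps * sv$d[1])
  if (nComp > rank) {
    warning("nComp exceeds rank; truncated to ", rank)
    nComp <- rank
  }
  ev <- sv$d^2 / sum(sv$d^2)
  loadings <- sv$v[, seq_len(nComp), drop = FALSE]
  scoresM <- sv$u[, seq_len(nComp), drop = FALSE] %*%
    diag(sv$d[seq_len(nComp)], nComp)
  fx <- .fix_signs(loadings, scoresM)
  dimnames(fx$loadings) <- list(colnames(x),
                                paste0("PC", seq_len(nComp)))
  dimnames(fx$scores) <- list(rownames(x), paste0("PC", seq_len(nComp)))
  new("PCAModel", center = numeric(ncol(x)), scaleSd = rep(1, ncol(x)),
      loadings = fx$loadings, scores = fx$scores,
      explainedVariance = ev[seq_len(nComp)],
      constantFlagged = character(0))
}

## One-component NIPALS-equivalent PLS on (X, y): w ~ X'y normalised.
.pls1 <- function(x, y) {
  w <- drop(crossprod(x, y))
  w <- w / sqrt(sum(w^2))
  t <- drop(x %*% w)
  p <- drop(crossprod(x, t)) / sum(t^2)
  q <- sum(y * t) / sum(t^2)
  list(w = w, t = t, p = p, q = q)
}

#' Two-class OPLS
#'
#' Orthogonal projections to latent structures with a binary dummy
#' response encoded +/-1. Y-orthogonal variation is removed iteratively
#' (Trygg--Wold orthogonal signal correction): each orthogonal component
#' has weights proportional to the part of the X loading that is
#' orthogonal to the predictive weight vector, so its scores are exactly
#' uncorrelated with y. A single predictive PLS component is then fitted
#' on the filtered matrix.
#'
#' @param x scaled matrix (samples x variables)
#' @param y two-level response (any two values; internally +/-1, centred)
#' @param nOrth number of orthogonal components (default 1)
#' @return an \linkS4class{OPLSModel}
#' @export
oplsFit <- function(x, y, nOrth = 1L) {
  x <- as.matrix(x)
  lev <- sort(unique(y))
  if (length(lev) != 2) stop("y must have exactly two classes")
  yy <- ifelse(y == lev[2], 1, -1)
  yy <- yy - mean(yy)
  E <- x
  tos <- pos <- wos <- list()
  ssxTot <- sum(x^2)
  r2x <- numeric(0)
  for (k in seq_len(nOrth)) {
    f <- .pls1(E, yy)
    wo <- f$p - sum(f$w * f$p) * f$w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) break       # nothing orthogonal left to remove
    wo <- wo / nwo
    to <- drop(E %*% wo)
    po <- drop(crossprod(E, to)) / sum(to^2)
    E <- E - tcrossprod(to, po)
    tos <- c(tos, list(to)); pos <- c(pos, list(po)); wos <- c(wos, list(wo))
    r2x <- c(r2x, sum(to^2) * sum(po^2) / ssxTot)
  }
  f <- .pls1(E, yy)
  r2y <- 1 - sum((yy - f$q * f$t)^2) / sum(yy^2)
  orthScores <- if (length(tos)) do.call(cbind, tos) else
    matrix(numeric(0), nrow(x), 0)
  new("OPLSModel", predictiveScores = f$t, predictiveWeights = f$w,
      predictiveLoadings = f$p,
      orthScores = orthScores,
      orthLoadings = if (length(pos)) do.call(cbind, pos) else
        matrix(numeric(0), ncol(x), 0),
      orthWeights = if (length(wos)) do.call(cbind, wos) else
        matrix(numeric(0), ncol(x), 0),
      r2x = c(r2x, sum(f$t^2) * sum(f$p^2) / ssxTot), r2y = r2y, y = yy)
}

#' S-line covariance/correlation profile of an OPLS model
#'
#' For every variable: p_cov = cov(x_j, t_p) and p_corr = corr(x_j, t_p)
#' with the predictive score vector. With the +/-1 dummy coding, positive
#' values mark variables elevated in the second (alphabetically later)
#' class. Constant variables get p_corr 0 and a flag.
#'
#' @param model an \linkS4class{OPLSModel}
#' @param x the matrix the model was fitted on
#' @return data.frame (variable, p_cov, p_corr, flag)
#' @export
sLine <- function(model, x) {
  x <- as.matrix(x)
  tp <- model@predictiveScores
  n <- nrow(x)
  xc <- sweep(x, 2, colMeans(x))
  tc <- tp - mean(tp)
  pcov <- drop(crossprod(xc, tc)) / (n - 1)
  sx <- apply(x, 2, sd)
  flag <- ifelse(sx == 0, "constant", "")
  pcorr <- ifelse(sx == 0, 0, pcov / (sx * sd(tp)))
  data.frame(variable = colnames(x) %||% as.character(seq_len(ncol(x))),
             p_cov = pcov, p_corr = pcorr, flag = flag,
             stringsAsFactors = FALSE)
}

#' Reconstruct the scaled matrix from a PCA model
#' @param model a \linkS4class{PCAModel}
#' @export
pcaReconstruct <- function(model)
  tcrossprod(model@scores, model@loadings)
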