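## Morphological allometry: multivariate least-squares regression of all
## shape coordinates on centroid size, overall fit summarized by the
## percentage of shape variance explained and by Wilks' lambda with a
## permutation test.

## Resolve various inputs to a (shapes, sizes) pair. Shape rows are
## tangent-projected vectorized configurations; the full (unprojected)
## row means are kept for reconstructing predicted outlines.
resolveShapes <- function(x, sizes = NULL) {
  if (is(x, "SymmetryDecomposition")) x <- x@alignment
  if (is(x, "AlignedOutlines")) {
    V <- shapeMatrix(x, tangent = TRUE)
    Vfull <- shapeMatrix(x, tangent = FALSE)
    if (is.null(sizes)) sizes <- x@centroidSizes
  } else if (is.matrix(x)) {
    V <- x
    Vfull <- x
    if (is.null(sizes)) stop("sizes must be supplied with matrix input")
  } else stop("unsupported input of class ", class(x)[1L])
  if (length(sizes) != nrow(V))
    stop("need one size per configuration")
  list(V = V, Vfull = Vfull, sizes = as.numeric(sizes))
}

#' Multivariate regression of shape on centroid size
#'
#' Fits all shape coordinates jointly on centroid size by least squares.
#' The overall fit is reported as the percentage of total shape variance
#' explained and as Wilks' lambda, computed on the principal-component
#' basis of the shape data (raw Procrustes coordinates are rank-deficient,
#' so the determinant is only defined on axes with nonzero variance);
#' with a single centered predictor this reduces to
#' \eqn{\lambda = 1 - \sum_j q_j^2 / t_j} with \eqn{q_j} the
#' size-score covariances and \eqn{t_j} the total scores sums of squares.
#' Significance is assessed by permuting the size labels; the p-value
#' uses the \eqn{(b + 1)/(n + 1)} convention.
#'
#' @param x an \code{\linkS4class{AlignedOutlines}}, a
#'   \code{\linkS4class{SymmetryDecomposition}} (its joint alignment is
#'   used), or an \code{n x 2k} shape matrix.
#' @param sizes centroid sizes (defaults to the alignment's raw sizes).
#' @param nPerm number of size-label permutations.
#' @param seed RNG seed for the permutations.
#' @param logSize regress on log centroid size instead of raw size.
#' @return An \code{\linkS4class{AllometryFit}}.
#' @export
fitAllometry <- function(x, sizes = NULL, nPerm = 999L, seed = 1L,
                         logSize = FALSE) {
  rs <- resolveShapes(x, sizes)
  s <- if (logSize) log(rs$sizes) else rs$sizes
  n <- nrow(rs$V)
  if (n < 3L) stop("need at least 3 configurations")
  if (sd(s) == 0) stop("degenerate predictor: sizes are constant")
  sc <- s - mean(s)
  Yc <- sweep(rs$V, 2L, colMeans(rs$V))
  beta <- as.vector(crossprod(Yc, sc)) / sum(sc^2)
  fitted <- outer(sc, beta)
  ssTot <- sum(Yc^2)
  ssRes <- sum((Yc - fitted)^2)
  pct <- 100 * (1 - ssRes / ssTot)
  ## Wilks' lambda on the PC basis, permutation via the rank-one identity
  pc <- prcomp(Yc, center = FALSE)
  keep <- which(pc$sdev > pc$sdev[1L] * 1e-10)
  S <- pc$x[, keep, drop = FALSE]
  tj <- colSums(S^2)
  lambdaOf <- function(scPerm) {
    qj <- as.vector(crossprod(S, scPerm)) / sqrt(sum(scPerm^2))
    1 - sum(qj^2 / tj)
  }
  lambda <- lambdaOf(sc)
  pval <- NA_real_
  if (nPerm > 0L) {
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(nPerm)) {
      sp <- sample(sc)
      if (lambdaOf(sp) <= lambda) hits <- hits + 1L
    }
    pval <- (hits + 1L) / (nPerm + 1L)
  }
  k <- ncol(rs$V) %/% 2L
  meanFull <- colMeans(rs$Vfull)
  intercept <- meanFull - beta * mean(s)
  extremes <- lapply(range(s), function(sz)
    unvecShape(intercept + beta * sz, k))
  names(extremes) <- c("smallest", "largest")
  new("AllometryFit", slope = beta, intercept = intercept,
      sizes = rs$sizes, pctExplained = pct, wilksLambda = lambda,
      pValue = pval, nPerm = as.integer(nPerm), seed = as.integer(seed),
      sizeRange = range(s), predictedExtremes = extremes)
}

#' Model shape at a given centroid size
#'
#' Evaluates the allometric regression at a size: intercept + slope x
#' size. Sizes outside the observed range are allowed but produce a
#' warning (extrapolation).
#'
#' @param fit an \code{\linkS4class{AllometryFit}}.
#' @param size centroid size at which to predict.
#' @return A \code{k x 2} coordinate matrix.
#' @export
predictShapeAtSize <- function(fit, size) {
  if (size < fit@sizeRange[1L] || size > fit@sizeRange[2L])
    warning("size ", size, " lies outside the observed range [",
            paste(format(fit@sizeRange, digits = 4), collapse = ", "),
            "]: extrapolating")
  unvecShape(fit@intercept + fit@slope * size,
             length(fit@slope) %/% 2L)
}

#' Remove the allometric subspace from shape data
#'
#' Regresses shape on centroid size and returns the residual shapes (mean
#' shape plus residuals), suitable as input for a nested ANOVA on the
#' non-allometric variation. The sequential sums of squares add exactly:
#' total SS = size SS + residual SS.
#'
#' @param x an \code{\linkS4class{AlignedOutlines}},
#'   \code{\linkS4class{SymmetryDecomposition}} or \code{n x 2k} matrix.
#' @param sizes centroid sizes (defaults as in
#'   \code{\link{fitAllometry}}).
#' @param logSize regress on log size.
#' @return A list: \code{shapes} (\code{n x 2k} residual shape matrix),
#'   \code{ssSize}, \code{ssResid}, \code{ssTotal}, \code{fit} (the
#'   underlying \code{\linkS4class{AllometryFit}}, no permutations).
#' @export
sizeAdjust <- function(x, sizes = NULL, logSize = FALSE) {
  rs <- resolveShapes(x, sizes)
  fit <- fitAllometry(rs$V, rs$sizes, nPerm = 0L, logSize = logSize)
  s <- if (logSize) log(rs$sizes) else rs$sizes
  sc <- s - mean(s)
  fitted <- outer(sc, fit@slope)
  Yc <- sweep(rs$V, 2L, colMeans(rs$V))
  resid <- Yc - fitted
  list(shapes = sweep(resid, 2L, colMeans(rs$V), "+"),
       ssSize = sum(fitted^2), ssResid = sum(resid^2),
       ssTotal = sum(Yc^2), fit = fit)
}
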