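## Geometric foundation: centroid size, ordinary (pairwise) and
## generalized Procrustes superimposition, tangent-space distances.
## Conventions (partial Procrustes): aligned configurations are centered
## at the origin and scaled to unit centroid size; only proper rotations
## (det +1) are used inside alignment -- reflections enter the analysis
## explicitly through reflectRelabel().

centerConfig <- function(xy) sweep(xy, 2L, colMeans(xy))

vecShape <- function(xy) c(xy)          # k x 2 -> (x1..xk, y1..yk)

unvecShape <- function(v, k) matrix(v, nrow = k, ncol = 2L)

rot2 <- function(a) {
  ca <- cos(a); sa <- sin(a)
  rbind(c(ca, sa), c(-sa, ca))          # xy %*% rot2(a): ccw rotation
}

#' Centroid size of a configuration
#'
#' The square root of the summed squared distances of all points from
#' their centroid -- the standard geometric-morphometric size measure. It
#' scales linearly under isotropic scaling and is invariant to rotation
#' and translation.
#'
#' @param points a \code{k x 2} coordinate matrix, \code{k >= 2}.
#' @return A positive number.
#' @examples
#' centroidSize(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # sqrt(2)
#' @export
centroidSize <- function(points) {
  if (!is.matrix(points) || nrow(points) < 2L)
    stop("centroidSize needs a k x 2 matrix with k >= 2")
  cs <- sqrt(sum(centerConfig(points)^2))
  if (cs == 0)
    stop("degenerate configuration: all points identical")
  cs
}

## Optimal proper rotation R (2x2) minimizing ||X %*% R - Y||_F.
optimalRotation <- function(X, Y) {
  M <- crossprod(X, Y)
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, d)) %*% t(sv$v)
}

#' Ordinary Procrustes alignment of one configuration onto a reference
#'
#' Translates the configuration to the origin, scales it to unit centroid
#' size and rotates it (proper rotation only) to minimize the summed
#' squared distance to the centered reference. The reference is not
#' modified; a mirror image of the reference therefore keeps a nonzero
#' residual.
#'
#' @param config,reference \code{k x 2} coordinate matrices with equal
#'   point counts.
#' @return The aligned \code{k x 2} matrix, with attributes
#'   \code{"rotation"} (the 2x2 matrix applied) and \code{"residual"}
#'   (summed squared distance to the centered, unit-size reference).
#' @export
alignPair <- function(config, reference) {
  if (!identical(dim(config), dim(reference)))
    stop("dimension mismatch between config and reference")
  X <- centerConfig(config)
  X <- X / sqrt(sum(X^2))
  Y <- centerConfig(reference)
  Y <- Y / sqrt(sum(Y^2))
  R <- optimalRotation(X, Y)
  out <- X %*% R
  attr(out, "rotation") <- R
  attr(out, "residual") <- sum((out - Y)^2)
  out
}

## One full set of align-to-consensus iterations on an array of centered,
## unit-size configurations. Returns the rotated array and consensus.
gpaIterate <- function(arr, tol = 1e-7, maxIter = 100L) {
  n <- dim(arr)[3]
  cons <- arr[, , 1L]
  cons <- cons / sqrt(sum(cons^2))
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      R <- optimalRotation(arr[, , i], cons)
      arr[, , i] <- arr[, , i] %*% R
    }
    newCons <- apply(arr, c(1L, 2L), mean)
    newCons <- centerConfig(newCons)
    newCons <- newCons / sqrt(sum(newCons^2))
    shift <- sqrt(sum((newCons - cons)^2))
    cons <- newCons
    if (shift < tol) { converged <- TRUE; break }
    if (iter >= maxIter) break
  }
  list(arr = arr, consensus = cons, iterations = iter,
       converged = converged)
}

## Rotate a whole alignment so the consensus symmetry axis (fixed point ->
## axis partner) points along +y. Makes signs of PCs and DA reproducible.
orientByAxis <- function(arr, cons, scheme) {
  v <- cons[scheme@axisIndices[2L], ] - cons[scheme@axisIndices[1L], ]
  a <- pi / 2 - atan2(v[2L], v[1L])
  R <- rot2(a)
  cons <- cons %*% R
  for (i in seq_len(dim(arr)[3])) arr[, , i] <- arr[, , i] %*% R
  list(arr = arr, consensus = cons)
}

#' Generalized Procrustes analysis with optional semilandmark sliding
#'
#' Iteratively superimposes all configurations on their consensus until
#' the consensus moves less than \code{tol} between iterations. Under the
#' sliding treatments, sliding cycles (against the current consensus, by
#' minimum bending energy or minimum Procrustes distance) are interleaved
#' with full re-superimposition; the consensus and, for \code{"min_be"},
#' the bending-energy kernel are refreshed each cycle. The output
#' alignment is oriented so the consensus symmetry axis is vertical with
#' the fixed landmark at the bottom.
#'
#' @param outlines an \code{\linkS4class{OutlineSet}} (or bare
#'   \code{k x 2 x n} array).
#' @param treatment \code{"unslid"}, \code{"min_be"} or \code{"min_pd"}.
#' @param slideIters number of slide/re-superimpose cycles for the sliding
#'   treatments.
#' @param tol convergence tolerance on consensus displacement.
#' @param maxIter maximum superimposition iterations per cycle; on
#'   non-convergence the best iterate is returned with a warning and a
#'   diagnostics flag.
#' @return An \code{\linkS4class{AlignedOutlines}}.
#' @seealso \code{\link{slideMinBE}}, \code{\link{slideMinPD}},
#'   \code{\link{procrustesDistances}}
#' @export
gpa <- function(outlines, treatment = c("unslid", "min_be", "min_pd"),
                slideIters = 3L, tol = 1e-7, maxIter = 100L) {
  treatment <- match.arg(treatment)
  if (is.array(outlines) && length(dim(outlines)) == 3L)
    outlines <- OutlineSet(outlines, checkCurve = FALSE)
  arr <- outlines@coords
  n <- dim(arr)[3]
  if (n < 2L) stop("gpa needs at least 2 configurations")
  sizes <- numeric(n)
  for (i in seq_len(n)) {
    xy <- centerConfig(arr[, , i])
    sizes[i] <- sqrt(sum(xy^2))
    if (sizes[i] == 0) stop("configuration ", i, " is degenerate")
    arr[, , i] <- xy / sizes[i]
  }
  if (treatment == "unslid") {
    fit <- gpaIterate(arr, tol, maxIter)
    out <- list(arr = fit$arr, consensus = fit$consensus,
                diagnostics = list(iterations = fit$iterations,
                                   converged = fit$converged,
                                   treatment = treatment))
  } else {
    out <- slideRealignLoop(arr, outlines@scheme, treatment, slideIters,
                            tol, maxIter)
  }
  if (!out$diagnostics$converged)
    warning("GPA did not reach tolerance ", tol, " within ", maxIter,
            " iterations; returning best iterate")
  orn <- orientByAxis(out$arr, out$consensus, outlines@scheme)
  new("AlignedOutlines", coords = orn$arr, info = outlines@info,
      scheme = outlines@scheme, consensus = orn$consensus,
      centroidSizes = sizes, treatment = treatment,
      diagnostics = out$diagnostics)
}

## Orthogonal projection of vectorized shapes to the tangent space at the
## consensus pole c (unit vector): v - (v . c) c.
tangentProject <- function(V, cons) {
  cv <- c(cons) / sqrt(sum(cons^2))
  V - outer(as.vector(V %*% cv), cv)
}

#' Shape coordinates of an alignment as an n x 2k matrix
#'
#' Rows are vectorized aligned configurations (all x then all y),
#' optionally projected orthogonally to the tangent space at the
#' consensus.
#'
#' @param aligned an \code{\linkS4class{AlignedOutlines}}.
#' @param tangent project to the tangent space at the consensus.
#' @return An \code{n x 2k} numeric matrix.
#' @export
shapeMatrix <- function(aligned, tangent = FALSE) {
  arr <- aligned@coords
  d <- dim(arr)
  V <- t(matrix(arr, nrow = d[1] * 2L, ncol = d[3]))
  colnames(V) <- c(paste0("x", seq_len(d[1])), paste0("y", seq_len(d[1])))
  if (tangent) V <- tangentProject(V, aligned@consensus)
  V
}

#' Tangent-space Procrustes distances within one alignment
#'
#' Euclidean distances between vectorized configurations after orthogonal
#' projection to the tangent space at the consensus. \code{"consensus"}
#' returns each configuration's distance to the consensus;
#' \code{"pairwise"} the full distance matrix.
#'
#' @param aligned an \code{\linkS4class{AlignedOutlines}}.
#' @param what \code{"consensus"} or \code{"pairwise"}.
#' @return A numeric vector (length n) or a \code{dist} object.
#' @export
procrustesDistances <- function(aligned,
                                what = c("consensus", "pairwise")) {
  what <- match.arg(what)
  V <- shapeMatrix(aligned, tangent = TRUE)
  ## the unit-size consensus projects to the origin of the tangent space
  if (what == "consensus")
    sqrt(rowSums(V^2))
  else
    stats::dist(V)
}

#' Tangent-space distance between two configurations of one alignment
#'
#' @param a,b \code{k x 2} aligned coordinate matrices (from the same
#'   alignment).
#' @param consensus the \code{k x 2} consensus of that alignment.
#' @return A nonnegative number; zero iff the aligned shapes coincide.
#' @export
procrustesDistance <- function(a, b, consensus) {
  if (!identical(dim(a), dim(b)))
    stop("configurations must have equal dimensions")
  V <- rbind(vecShape(a), vecShape(b))
  V <- tangentProject(V, consensus)
  sqrt(sum((V[1L, ] - V[2L, ])^2))
}
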