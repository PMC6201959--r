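## Object-symmetry machinery. Each configuration is analyzed jointly with
## its reflected, relabeled copy; principal components of the combined
## data split into symmetric axes (original and copy score equally) and
## asymmetric axes (scores mirror with opposite sign).

#' Reflect a configuration across the symmetry axis and relabel
#'
#' Negates the x coordinates and swaps every left/right point pair of the
#' scheme, so that the reflected copy has the same point-ordering
#' convention as the original. The on-axis points keep their labels.
#' Applying the operation twice returns the original configuration.
#'
#' @param x a \code{k x 2} coordinate matrix or an
#'   \code{\linkS4class{OutlineSet}} (every configuration is reflected
#'   and the \code{reflected} flag toggled).
#' @param scheme a \code{\linkS4class{LandmarkScheme}} (taken from the
#'   object for \code{OutlineSet} input).
#' @return Same type as \code{x}.
#' @export
setGeneric("reflectRelabel",
           function(x, scheme) standardGeneric("reflectRelabel"))

#' @rdname reflectRelabel
#' @export
setMethod("reflectRelabel", "matrix", function(x, scheme) {
  if (nrow(x) != scheme@nPoints)
    stop("configuration does not match the scheme point count")
  out <- x
  out[, 1L] <- -out[, 1L]
  pr <- scheme@pairing
  tmp <- out[pr[, 1L], , drop = FALSE]
  out[pr[, 1L], ] <- out[pr[, 2L], , drop = FALSE]
  out[pr[, 2L], ] <- tmp
  out
})

#' @rdname reflectRelabel
#' @export
setMethod("reflectRelabel", "OutlineSet", function(x, scheme) {
  if (missing(scheme)) scheme <- x@scheme
  arr <- x@coords
  for (i in seq_len(dim(arr)[3]))
    arr[, , i] <- reflectRelabel(arr[, , i], scheme)
  info <- x@info
  info$reflected <- !info$reflected
  initialize(x, coords = arr, info = info)
})

#' Joint superimposition and PCA of originals with reflected copies
#'
#' Builds the combined dataset of all original configurations and their
#' reflected/relabeled copies, superimposes it in a single generalized
#' Procrustes analysis under the requested semilandmark treatment, and
#' performs a covariance PCA of the tangent-projected coordinates. Each
#' axis is classified as symmetric (original and reflected copies score
#' equally) or asymmetric (scores of the copies mirror with opposite
#' sign) by the correlation of the two score vectors; correlations
#' strictly between \code{-classifyTol} and \code{classifyTol} trigger a
#' diagnostics warning (possible only under numerically tied
#' eigenvalues). The per-object total-asymmetry statistic is computed
#' under both candidate definitions.
#'
#' @param outlines an \code{\linkS4class{OutlineSet}} of original
#'   (unreflected) configurations.
#' @param treatment semilandmark treatment for the joint superimposition.
#' @param slideIters sliding cycles for the sliding treatments.
#' @param classifyTol score-mirroring correlation threshold for axis
#'   classification.
#' @return A \code{\linkS4class{SymmetryDecomposition}}.
#' @export
buildSymmetryDecomposition <- function(outlines,
                                       treatment = c("min_be", "unslid",
                                                     "min_pd"),
                                       slideIters = 3L,
                                       classifyTol = 0.99) {
  treatment <- match.arg(treatment)
  if (nConfigs(outlines) < 2L)
    stop("need at least 2 original configurations")
  if (any(outlines@info$reflected))
    stop("input must contain only original (unreflected) configurations")
  refl <- reflectRelabel(outlines)
  n <- nConfigs(outlines)
  k <- outlines@scheme@nPoints
  arr <- array(c(outlines@coords, refl@coords), dim = c(k, 2L, 2L * n))
  info <- rbind(outlines@info, refl@info)
  info$side <- rep(c("original", "reflected"), each = n)
  combined <- new("OutlineSet", coords = arr, info = info,
                  scheme = outlines@scheme)
  aligned <- gpa(combined, treatment = treatment,
                 slideIters = slideIters)
  V <- shapeMatrix(aligned, tangent = TRUE)
  pc <- prcomp(V, center = TRUE, scale. = FALSE)
  keep <- which(pc$sdev > pc$sdev[1L] * 1e-8)
  ev <- pc$sdev[keep]^2
  scores <- pc$x[, keep, drop = FALSE]
  rot <- pc$rotation[, keep, drop = FALSE]
  oIdx <- seq_len(n)
  rIdx <- n + seq_len(n)
  cls <- character(length(keep))
  for (j in seq_along(keep)) {
    r <- suppressWarnings(cor(scores[oIdx, j], scores[rIdx, j]))
    if (is.na(r)) r <- 1        # zero-variance split: call it symmetric
    if (r >= classifyTol) cls[j] <- "symmetric"
    else if (r <= -classifyTol) cls[j] <- "asymmetric"
    else {
      warning(sprintf(
        "PC%d score-mirroring correlation %.3f is inconclusive (tied eigenvalues?); classified by sign",
        j, r))
      cls[j] <- if (r >= 0) "symmetric" else "asymmetric"
    }
  }
  asymAxes <- which(cls == "asymmetric")
  aScores <- scores[oIdx, asymAxes, drop = FALSE]
  new("SymmetryDecomposition",
      alignment = aligned, originalIdx = oIdx, reflectedIdx = rIdx,
      center = pc$center, rotation = rot, eigenvalues = ev,
      varFraction = ev / sum(ev), axisClass = cls, scores = scores,
      totalAsymmetry = sqrt(rowSums(aScores^2)),
      totalAsymmetryAbs = rowSums(abs(aScores)))
}

#' Symmetric and asymmetric shape components per object
#'
#' For each original object, the symmetric component is the mean of its
#' aligned original and reflected/relabeled coordinates and the
#' asymmetric component is half their difference, so symmetric +
#' asymmetric reconstructs the aligned original exactly.
#'
#' @param decomp a \code{\linkS4class{SymmetryDecomposition}}.
#' @return A list with \code{n x 2k} matrices \code{symmetric} and
#'   \code{asymmetric}.
#' @export
symmetryComponents <- function(decomp) {
  V <- shapeMatrix(decomp@alignment, tangent = FALSE)
  orig <- V[decomp@originalIdx, , drop = FALSE]
  refl <- V[decomp@reflectedIdx, , drop = FALSE]
  list(symmetric = (orig + refl) / 2, asymmetric = (orig - refl) / 2)
}

#' Total shape asymmetry per object
#'
#' The default statistic is the Euclidean norm of an object's PC scores
#' restricted to the asymmetric axes; the alternative sums the absolute
#' per-axis scores. Both are invariant to whether the original or the
#' reflected copy is used.
#'
#' @param decomp a \code{\linkS4class{SymmetryDecomposition}}.
#' @param statistic \code{"euclidean"} (default) or \code{"abssum"}.
#' @return Numeric vector, one nonnegative value per original object.
#' @export
totalAsymmetry <- function(decomp,
                           statistic = c("euclidean", "abssum")) {
  statistic <- match.arg(statistic)
  if (statistic == "euclidean") decomp@totalAsymmetry
  else decomp@totalAsymmetryAbs
}
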