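#' @import methods
#' @importFrom stats cor median prcomp quantile rnorm runif sd var
NULL

## Central S4 containers. Coordinates are stored as a k x 2 x n array
## (points x dimensions x configurations); user-facing indices are 1-based
## throughout, matching the usual landmark-numbering convention.

#' Landmark scheme: the symmetry and topology contract of an outline
#'
#' A \code{LandmarkScheme} declares, for a closed outline of \code{nPoints}
#' points, which point is the fixed (anatomical) landmark, which points lie
#' on the axis of bilateral symmetry, and how off-axis points pair up
#' left/right. Sliding and reflection operations take their topology from
#' this object.
#'
#' @slot nPoints integer, number of points per configuration.
#' @slot fixedIndex integer, 1-based index of the fixed landmark (never
#'   slides).
#' @slot axisIndices integer(2), 1-based indices of the two on-axis points;
#'   these keep their labels under reflection.
#' @slot pairing integer matrix with columns \code{left} and \code{right};
#'   every off-axis point appears in exactly one pair.
#' @slot closed logical, whether the outline wraps around.
#'
#' @export
setClass("LandmarkScheme",
  representation(
    nPoints = "integer",
    fixedIndex = "integer",
    axisIndices = "integer",
    pairing = "matrix",
    closed = "logical"
  )
)

setValidity("LandmarkScheme", function(object) {
  k <- object@nPoints
  msg <- character()
  if (length(k) != 1L || k < 3L)
    msg <- c(msg, "nPoints must be a single integer >= 3")
  if (length(object@fixedIndex) != 1L ||
      object@fixedIndex < 1L || object@fixedIndex > k)
    msg <- c(msg, "fixedIndex out of range")
  if (length(object@axisIndices) != 2L ||
      any(object@axisIndices < 1L | object@axisIndices > k))
    msg <- c(msg, "axisIndices must be two in-range indices")
  pr <- object@pairing
  if (!is.matrix(pr) || ncol(pr) != 2L || !is.numeric(pr))
    msg <- c(msg, "pairing must be a 2-column integer matrix")
  else {
    paired <- sort(as.integer(pr))
    offAxis <- sort(setdiff(seq_len(k), object@axisIndices))
    if (any(object@axisIndices %in% pr))
      msg <- c(msg, "axis indices must be unpaired")
    if (!identical(paired, offAxis))
      msg <- c(msg, "every off-axis point must appear in exactly one pair")
  }
  if (length(msg)) msg else TRUE
})

#' A set of digitized outline configurations with hierarchical metadata
#'
#' Coordinates of \code{n} outlines, each with \code{k} ordered 2D points,
#' together with identity metadata: locality, plant, segment, digitization
#' replicate and a reflection flag. The point ordering convention (after
#' the replicate-2 reversal correction) is identical for all
#' configurations.
#'
#' @slot coords numeric array, \code{k x 2 x n}.
#' @slot info data.frame with one row per configuration and columns
#'   \code{locality}, \code{plant}, \code{segment}, \code{replicate},
#'   \code{reflected}.
#' @slot scheme a \code{\linkS4class{LandmarkScheme}}.
#'
#' @export
setClass("OutlineSet",
  representation(
    coords = "array",
    info = "data.frame",
    scheme = "LandmarkScheme"
  )
)

setValidity("OutlineSet", function(object) {
  d <- dim(object@coords)
  msg <- character()
  if (length(d) != 3L || d[2] != 2L)
    msg <- c(msg, "coords must be a k x 2 x n array")
  else {
    if (d[1] != object@scheme@nPoints)
      msg <- c(msg, sprintf("coords have %d points but scheme expects %d",
                            d[1], object@scheme@nPoints))
    if (nrow(object@info) != d[3])
      msg <- c(msg, "info must have one row per configuration")
  }
  need <- c("locality", "plant", "segment", "replicate", "reflected")
  miss <- setdiff(need, names(object@info))
  if (length(miss))
    msg <- c(msg, paste("info lacks columns:", paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Superimposed configurations, their consensus and centroid sizes
#'
#' Result of a generalized Procrustes analysis under one of the three
#' semilandmark treatments. Aligned configurations are centered at the
#' origin with unit centroid size (partial Procrustes convention); the
#' consensus is the mean shape rescaled to unit centroid size.
#' \code{centroidSizes} are the sizes of the raw inputs, never of the
#' scaled copies.
#'
#' @slot consensus numeric \code{k x 2} matrix, unit centroid size.
#' @slot centroidSizes numeric, raw centroid size per input configuration.
#' @slot treatment one of \code{"unslid"}, \code{"min_be"},
#'   \code{"min_pd"}.
#' @slot diagnostics list: iteration counts, convergence, slide-behind
#'   counts for min-PD sliding, bending-energy totals per sliding cycle.
#'
#' @export
setClass("AlignedOutlines",
  contains = "OutlineSet",
  representation(
    consensus = "matrix",
    centroidSizes = "numeric",
    treatment = "character",
    diagnostics = "list"
  )
)

setValidity("AlignedOutlines", function(object) {
  msg <- character()
  n <- dim(object@coords)[3]
  if (length(object@centroidSizes) != n)
    msg <- c(msg, "one centroid size per configuration required")
  if (any(object@centroidSizes <= 0))
    msg <- c(msg, "centroid sizes must be positive")
  if (!object@treatment %in% c("unslid", "min_be", "min_pd"))
    msg <- c(msg, "treatment must be unslid, min_be or min_pd")
  if (!identical(dim(object@consensus),
                 c(object@scheme@nPoints, 2L)) &&
      !identical(dim(object@consensus),
                 as.integer(c(object@scheme@nPoints, 2))))
    msg <- c(msg, "consensus must be a k x 2 matrix")
  if (length(msg)) msg else TRUE
})

#' Decomposition of shape variation into symmetric and asymmetric parts
#'
#' Joint superimposition of original configurations with their
#' reflected/relabeled copies, the principal components of the combined
#' data classified as symmetric or asymmetric, per-object scores, and the
#' total shape-asymmetry statistic per original object.
#'
#' @slot alignment \code{\linkS4class{AlignedOutlines}} over originals and
#'   reflected copies (2n configurations).
#' @slot originalIdx,reflectedIdx integer indices into the alignment:
#'   configuration \code{originalIdx[i]} and \code{reflectedIdx[i]} are
#'   the two copies of object \code{i}.
#' @slot center numeric(2k), mean of the combined aligned coordinates.
#' @slot rotation \code{2k x m} matrix of eigenvectors (PC loadings).
#' @slot eigenvalues numeric(m), covariance eigenvalues.
#' @slot varFraction numeric(m), fractions of total variance (sum to 1).
#' @slot axisClass character(m), \code{"symmetric"} or
#'   \code{"asymmetric"} per axis.
#' @slot scores \code{2n x m} score matrix.
#' @slot totalAsymmetry numeric(n), Euclidean norm of each original
#'   object's scores on the asymmetric axes.
#' @slot totalAsymmetryAbs numeric(n), the alternative statistic: sum of
#'   absolute per-axis scores on the asymmetric axes.
#'
#' @export
setClass("SymmetryDecomposition",
  representation(
    alignment = "AlignedOutlines",
    originalIdx = "integer",
    reflectedIdx = "integer",
    center = "numeric",
    rotation = "matrix",
    eigenvalues = "numeric",
    varFraction = "numeric",
    axisClass = "character",
    scores = "matrix",
    totalAsymmetry = "numeric",
    totalAsymmetryAbs = "numeric"
  )
)

#' Multivariate regression of shape on centroid size
#'
#' @slot slope numeric(2k), shape change per unit of centroid size.
#' @slot intercept numeric(2k).
#' @slot sizes numeric, the size predictor used.
#' @slot pctExplained percentage of total shape variance captured by the
#'   regression, \code{100 * (1 - SS_resid / SS_total)}.
#' @slot wilksLambda Wilks' lambda of the multivariate fit, computed on a
#'   reduced-rank principal-component basis.
#' @slot pValue permutation p-value for lambda.
#' @slot nPerm,seed permutation bookkeeping.
#' @slot sizeRange numeric(2), observed size range.
#' @slot predictedExtremes list of two \code{k x 2} matrices: model shapes
#'   at the smallest and largest observed size.
#'
#' @export
setClass("AllometryFit",
  representation(
    slope = "numeric",
    intercept = "numeric",
    sizes = "numeric",
    pctExplained = "numeric",
    wilksLambda = "numeric",
    pValue = "numeric",
    nPerm = "integer",
    seed = "integer",
    sizeRange = "numeric",
    predictedExtremes = "list"
  )
)

#' An ordered ANOVA table with type I (sequential) sums of squares
#'
#' @slot table data.frame with columns \code{effect}, \code{df},
#'   \code{SS}, \code{MS}, \code{F}, \code{p}, \code{R2}; the residual row
#'   has \code{NA} for F and p, and degenerate F (zero denominator MS) is
#'   reported as \code{NA} with a note.
#' @slot response short description of the response.
#' @slot nPerm,seed permutation bookkeeping (\code{nPerm = 0} means no
#'   permutation p-values were computed).
#' @slot notes list of diagnostics (degenerate effects, permutation
#'   scheme).
#'
#' @export
setClass("AnovaTable",
  representation(
    table = "data.frame",
    response = "character",
    nPerm = "integer",
    seed = "integer",
    notes = "list"
  )
)

setValidity("AnovaTable", function(object) {
  need <- c("effect", "df", "SS", "MS", "F", "p", "R2")
  if (!all(need %in% names(object@table)))
    return(paste("table must have columns", paste(need, collapse = ", ")))
  TRUE
})

#' Bootstrap comparison of two group medians
#'
#' @slot medianA,medianB observed group medians.
#' @slot estimates bootstrap replicates of \code{medianA - medianB}.
#' @slot ci numeric(2), 2.5 and 97.5 percentiles of the replicates.
#' @slot pValue two-sided bootstrap p, floored at \code{1/nBoot}.
#' @slot nBoot,seed resampling bookkeeping.
#'
#' @export
setClass("BootstrapResult",
  representation(
    medianA = "numeric",
    medianB = "numeric",
    estimates = "numeric",
    ci = "numeric",
    pValue = "numeric",
    nBoot = "integer",
    seed = "integer"
  )
)

#' Parameters of the hierarchical synthetic outline generator
#'
#' All magnitudes are in shape units (coordinates of a configuration
#' scaled to unit centroid size); see the methods vignette for how the
#' defaults were chosen.
#'
#' @slot nLocalities,plantsPerLocality design counts.
#' @slot segmentCounts list (one integer vector per locality) of segments
#'   per plant.
#' @slot nPoints points per outline (fixed landmark at index 1, axis
#'   partner at index nPoints/2 + 1).
#' @slot medianSizes numeric, per-locality median centroid size.
#' @slot sizeLogSd total lognormal spread of segment sizes within a
#'   locality.
#' @slot plantSizeShare fraction of the size log-variance attributed to
#'   the plant level (the rest varies among segments within plants).
#' @slot allometrySlope magnitude of the symmetric allometric deformation
#'   per unit centroid size.
#' @slot plantSd per-plant symmetric shape variation.
#' @slot symmetricSd per-segment symmetric shape variation.
#' @slot daMagnitude per-plant directional-asymmetry field scale.
#' @slot faSd per-segment fluctuating-asymmetry field scale.
#' @slot meSd per-replicate digitization noise (per coordinate).
#' @slot seed integer master seed; all sub-streams derive from it.
#'
#' @export
setClass("SyntheticSpec",
  representation(
    nLocalities = "integer",
    plantsPerLocality = "integer",
    segmentCounts = "list",
    nPoints = "integer",
    medianSizes = "numeric",
    sizeLogSd = "numeric",
    plantSizeShare = "numeric",
    allometrySlope = "numeric",
    plantSd = "numeric",
    symmetricSd = "numeric",
    daMagnitude = "numeric",
    faSd = "numeric",
    meSd = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (length(object@segmentCounts) != object@nLocalities)
    msg <- c(msg, "segmentCounts must have one vector per locality")
  if (any(vapply(object@segmentCounts, length, 1L) !=
          object@plantsPerLocality))
    msg <- c(msg, "each locality needs plantsPerLocality segment counts")
  if (object@nPoints %% 2L != 0L)
    msg <- c(msg, "nPoints must be even (two on-axis points)")
  sds <- c(object@allometrySlope, object@plantSd, object@symmetricSd,
           object@daMagnitude, object@faSd, object@meSd,
           object@sizeLogSd)
  if (any(sds < 0))
    msg <- c(msg, "all magnitude parameters must be >= 0")
  if (length(object@medianSizes) != object@nLocalities)
    msg <- c(msg, "one median size per locality required")
  if (object@plantSizeShare < 0 || object@plantSizeShare > 1)
    msg <- c(msg, "plantSizeShare must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
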