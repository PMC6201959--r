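#' Construct a landmark scheme
#'
#' Declares the topology and symmetry contract of an outline: the fixed
#' landmark, the two on-axis points, and the left/right pairing of the
#' remaining points. All indices are 1-based.
#'
#' @param nPoints number of points per configuration.
#' @param fixedIndex index of the fixed landmark.
#' @param axisIndices indices of the two points on the symmetry axis
#'   (unpaired; they keep their labels under reflection).
#' @param pairing 2-column matrix (\code{left}, \code{right}) pairing all
#'   off-axis points.
#' @param closed whether the outline is a closed curve.
#' @return A \code{\linkS4class{LandmarkScheme}}.
#' @examples
#' LandmarkScheme(6L, 1L, c(1L, 4L), cbind(left = c(2L, 3L), right = c(6L, 5L)))
#' @export
LandmarkScheme <- function(nPoints, fixedIndex = 1L, axisIndices, pairing,
                           closed = TRUE) {
  pr <- matrix(as.integer(pairing), ncol = 2L,
               dimnames = list(NULL, c("left", "right")))
  new("LandmarkScheme", nPoints = as.integer(nPoints),
      fixedIndex = as.integer(fixedIndex),
      axisIndices = as.integer(axisIndices), pairing = pr,
      closed = isTRUE(closed))
}

#' The 90-point segment-outline scheme
#'
#' The scheme used for alga segment outlines: 90 points, point 1 the fixed
#' basal landmark, points 1 and 46 on the axis of bilateral symmetry, and
#' point \eqn{i} paired with point \eqn{92 - i} for \eqn{i = 2, \dots,
#' 45}. \code{pairedScheme} builds the analogous scheme for any even
#' number of points: fixed point 1, axis partner at \code{n/2 + 1}, and
#' \eqn{i \leftrightarrow n + 2 - i} pairing.
#'
#' @param nPoints even number of outline points.
#' @return A \code{\linkS4class{LandmarkScheme}}.
#' @examples
#' studyScheme()
#' pairedScheme(10L)
#' @export
studyScheme <- function() pairedScheme(90L)

#' @rdname studyScheme
#' @export
pairedScheme <- function(nPoints) {
  n <- as.integer(nPoints)
  if (n %% 2L != 0L || n < 4L)
    stop("pairedScheme needs an even number of points >= 4")
  half <- n %/% 2L
  left <- 2:half
  LandmarkScheme(n, 1L, c(1L, half + 1L),
                 cbind(left = left, right = n + 2L - left))
}

#' Bundle outline coordinates with hierarchical metadata
#'
#' @param coords a \code{k x 2 x n} array, or a list of \code{k x 2}
#'   matrices (one per configuration).
#' @param info data.frame with columns \code{locality}, \code{plant},
#'   \code{segment}, \code{replicate}; a logical \code{reflected} column
#'   is added (all \code{FALSE}) when absent. Defaults label each
#'   configuration as its own segment of a single plant.
#' @param scheme a \code{\linkS4class{LandmarkScheme}}; defaults to the
#'   paired scheme for the observed point count.
#' @param checkCurve check that no two consecutive points coincide (the
#'   outline must be a simple ordered curve).
#' @return An \code{\linkS4class{OutlineSet}}.
#' @export
OutlineSet <- function(coords, info = NULL, scheme = NULL,
                       checkCurve = TRUE) {
  if (is.list(coords) && !is.array(coords))
    coords <- array(unlist(coords),
                    dim = c(nrow(coords[[1L]]), 2L, length(coords)))
  if (length(dim(coords)) != 3L)
    stop("coords must be a k x 2 x n array or a list of k x 2 matrices")
  n <- dim(coords)[3]
  k <- dim(coords)[1]
  if (is.null(scheme)) scheme <- pairedScheme(k)
  if (is.null(info))
    info <- data.frame(locality = "L1", plant = "P1",
                       segment = sprintf("S%03d", seq_len(n)),
                       replicate = 1L, reflected = FALSE,
                       stringsAsFactors = FALSE)
  if (is.null(info$reflected)) info$reflected <- FALSE
  if (checkCurve) {
    for (i in seq_len(n)) {
      xy <- coords[, , i]
      nxt <- rbind(xy[-1L, , drop = FALSE], xy[1L, , drop = FALSE])
      if (any(rowSums((xy - nxt)^2) == 0))
        stop("configuration ", i,
             " has two consecutive coincident points")
    }
  }
  rownames(info) <- NULL
  new("OutlineSet", coords = coords, info = info, scheme = scheme)
}
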