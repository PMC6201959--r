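#' Accessors for morphosym containers
#'
#' \code{landmarkCoords} returns the \code{k x 2 x n} coordinate array,
#' \code{outlineInfo} the metadata data.frame, \code{outlineScheme} the
#' \code{\linkS4class{LandmarkScheme}}, \code{nConfigs} the number of
#' configurations, \code{consensusShape} the consensus of an alignment,
#' \code{centroidSizes} the raw centroid sizes, and \code{anovaTable} the
#' plain data.frame of an \code{\linkS4class{AnovaTable}}.
#'
#' @param x a morphosym object.
#' @return See description; accessors never expose slots for writing.
#' @name accessors
#' @aliases landmarkCoords outlineInfo outlineScheme nConfigs
#'   consensusShape centroidSizes anovaTable
NULL

#' @rdname accessors
#' @export
setGeneric("landmarkCoords", function(x) standardGeneric("landmarkCoords"))

#' @rdname accessors
#' @export
setGeneric("outlineInfo", function(x) standardGeneric("outlineInfo"))

#' @rdname accessors
#' @export
setGeneric("outlineScheme", function(x) standardGeneric("outlineScheme"))

#' @rdname accessors
#' @export
setGeneric("nConfigs", function(x) standardGeneric("nConfigs"))

#' @rdname accessors
#' @export
setGeneric("consensusShape", function(x) standardGeneric("consensusShape"))

#' @rdname accessors
#' @export
setGeneric("centroidSizes", function(x) standardGeneric("centroidSizes"))

#' @rdname accessors
#' @export
setGeneric("anovaTable", function(x) standardGeneric("anovaTable"))

#' @rdname accessors
#' @export
setMethod("landmarkCoords", "OutlineSet", function(x) x@coords)

#' @rdname accessors
#' @export
setMethod("outlineInfo", "OutlineSet", function(x) x@info)

#' @rdname accessors
#' @export
setMethod("outlineScheme", "OutlineSet", function(x) x@scheme)

#' @rdname accessors
#' @export
setMethod("nConfigs", "OutlineSet", function(x) dim(x@coords)[3])

#' @rdname accessors
#' @export
setMethod("consensusShape", "AlignedOutlines", function(x) x@consensus)

#' @rdname accessors
#' @export
setMethod("centroidSizes", "AlignedOutlines", function(x) x@centroidSizes)

#' @rdname accessors
#' @export
setMethod("anovaTable", "AnovaTable", function(x) x@table)

setMethod("show", "LandmarkScheme", function(object) {
  cat("LandmarkScheme:", object@nPoints, "points,",
      if (object@closed) "closed outline\n" else "open curve\n")
  cat("  fixed landmark:", object@fixedIndex,
      " axis:", paste(object@axisIndices, collapse = ", "), "\n")
  cat("  ", nrow(object@pairing), "left/right pairs\n")
})

setMethod("show", "OutlineSet", function(object) {
  d <- dim(object@coords)
  cat(class(object), "with", d[3], "configurations of", d[1], "points\n")
  inf <- object@info
  cat("  localities:", length(unique(inf$locality)),
      " plants:", length(unique(paste(inf$locality, inf$plant))),
      " segments:",
      length(unique(paste(inf$locality, inf$plant, inf$segment))), "\n")
})

setMethod("show", "AlignedOutlines", function(object) {
  callNextMethod()
  cat("  treatment:", object@treatment,
      " consensus centroid size:",
      format(centroidSize(object@consensus), digits = 6), "\n")
  if (!is.null(object@diagnostics$iterations))
    cat("  GPA iterations:", object@diagnostics$iterations,
        if (isTRUE(object@diagnostics$converged)) "(converged)\n"
        else "(NOT converged)\n")
})

setMethod("show", "SymmetryDecomposition", function(object) {
  nAxes <- length(object@eigenvalues)
  nSym <- sum(object@axisClass == "symmetric")
  cat("SymmetryDecomposition:", length(object@originalIdx),
      "objects,", nAxes, "PC axes (", nSym, "symmetric,",
      nAxes - nSym, "asymmetric )\n")
  top <- head(order(-object@varFraction), 4L)
  for (j in top)
    cat(sprintf("  PC%d: %5.1f%% (%s)\n", j, 100 * object@varFraction[j],
                object@axisClass[j]))
})

setMethod("show", "AllometryFit", function(object) {
  cat("AllometryFit: shape ~ centroid size\n")
  cat(sprintf("  %% variance explained: %.2f\n", object@pctExplained))
  cat(sprintf("  Wilks' lambda: %.4f  (p = %.4g, %d permutations)\n",
              object@wilksLambda, object@pValue, object@nPerm))
})

setMethod("show", "AnovaTable", function(object) {
  cat("AnovaTable (type I):", object@response, "\n")
  tab <- object@table
  tab$SS <- signif(tab$SS, 5)
  tab$MS <- signif(tab$MS, 5)
  tab$F <- signif(tab$F, 5)
  tab$R2 <- signif(tab$R2, 4)
  print(tab, row.names = FALSE)
  if (object@nPerm > 0L)
    cat("  p-values from", object@nPerm, "restricted permutations\n")
})

setMethod("show", "BootstrapResult", function(object) {
  cat("BootstrapResult: difference of medians\n")
  cat(sprintf("  median A = %.5g, median B = %.5g, diff = %.5g\n",
              object@medianA, object@medianB,
              object@medianA - object@medianB))
  cat(sprintf("  95%% CI [%.5g, %.5g], p = %.4g (%d resamples)\n",
              object@ci[1], object@ci[2], object@pValue, object@nBoot))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", object@nLocalities, "localities x",
      object@plantsPerLocality, "plants,",
      sum(unlist(object@segmentCounts)), "segments,",
      object@nPoints, "points per outline\n")
  cat(sprintf("  allometry %.3g | plant %.3g | segment %.3g | DA %.3g | FA %.3g | ME %.3g\n",
              object@allometrySlope, object@plantSd, object@symmetricSd,
              object@daMagnitude, object@faSd, object@meSd))
})

#' @importFrom utils head
NULL
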