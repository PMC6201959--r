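## Semilandmark machinery: equidistant resampling, tangent estimation,
## thin-plate-spline bending energy, and the two sliding criteria.

#' Thin-plate-spline bending-energy kernel
#'
#' Holds the TPS system matrix built from a reference configuration and
#' the k x k bending matrix (the upper-left block of its inverse). The
#' bending matrix annihilates affine fields: \code{B 1 = B x = B y = 0},
#' so the bending energy of any affine transform of the reference is
#' zero. Kernel function \code{U(r) = r^2 log r}.
#'
#' @slot reference the \code{k x 2} reference configuration.
#' @slot Lmatrix the \code{(k+3) x (k+3)} TPS system matrix.
#' @slot bending the \code{k x k} positive semidefinite bending matrix.
#'
#' @export
setClass("BendingEnergyKernel",
  representation(reference = "matrix", Lmatrix = "matrix",
                 bending = "matrix"))

#' Build the bending-energy kernel for a reference configuration
#'
#' @param reference \code{k x 2} coordinate matrix (typically the
#'   consensus of an alignment).
#' @return A \code{\linkS4class{BendingEnergyKernel}}.
#' @export
bendingEnergyKernel <- function(reference) {
  k <- nrow(reference)
  D <- as.matrix(stats::dist(reference))
  if (any(D[upper.tri(D)] == 0))
    stop("duplicate points in reference: TPS system is singular")
  K <- D^2 * log(D)
  diag(K) <- 0
  Q <- cbind(1, reference)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3L, 3L)))
  Linv <- tryCatch(solve(L), error = function(e)
    stop("singular TPS system matrix: ", conditionMessage(e)))
  B <- Linv[seq_len(k), seq_len(k), drop = FALSE]
  B <- (B + t(B)) / 2
  new("BendingEnergyKernel", reference = reference, Lmatrix = L,
      bending = B)
}

#' Bending energy of a target configuration relative to a reference
#'
#' The TPS quadratic form \eqn{x^T B x + y^T B y} evaluated on the
#' target's coordinates, with \eqn{B} the bending matrix of the kernel.
#' Zero iff the target is an affine transform of the reference.
#'
#' @param kernel a \code{\linkS4class{BendingEnergyKernel}}.
#' @param target \code{k x 2} matrix with the kernel's point count.
#' @return A nonnegative number (tiny negative round-off is clipped).
#' @export
bendingEnergy <- function(kernel, target) {
  B <- kernel@bending
  if (!is.matrix(target) || nrow(target) != nrow(B) || ncol(target) != 2L)
    stop("target must be a ", nrow(B), " x 2 matrix")
  e <- sum(target[, 1L] * (B %*% target[, 1L])) +
       sum(target[, 2L] * (B %*% target[, 2L]))
  max(e, 0)
}

#' Resample a closed outline to equidistant points
#'
#' Places \code{nPoints} points at equal arc-length spacing along the
#' piecewise-linear input curve (spacing = perimeter / nPoints), starting
#' exactly at the fixed basal landmark, which is retained as point 1.
#'
#' @param outline \code{k x 2} matrix of ordered points on a closed
#'   curve.
#' @param nPoints number of output points.
#' @param fixedStart index of the point to keep as the fixed landmark.
#' @return A \code{nPoints x 2} coordinate matrix.
#' @export
resampleEquidistant <- function(outline, nPoints, fixedStart = 1L) {
  k <- nrow(outline)
  if (k < 3L) stop("outline needs at least 3 points")
  if (nPoints > 10L * k)
    warning("resampling ", k, " input points to ", nPoints,
            " outputs exceeds a sensible resolution bound")
  ord <- c(fixedStart:k, seq_len(fixedStart - 1L))
  pts <- outline[ord, , drop = FALSE]
  pts <- rbind(pts, pts[1L, , drop = FALSE])       # close the curve
  seg <- sqrt(rowSums(diff(pts)^2))
  if (any(seg == 0)) {
    keep <- c(TRUE, seg > 0)
    pts <- pts[keep, , drop = FALSE]
    seg <- sqrt(rowSums(diff(pts)^2))
  }
  cum <- c(0, cumsum(seg))
  per <- cum[length(cum)]
  target <- per * (seq_len(nPoints) - 1L) / nPoints
  idx <- findInterval(target, cum, rightmost.closed = TRUE)
  idx[idx >= length(cum)] <- length(cum) - 1L
  frac <- (target - cum[idx]) / seg[idx]
  out <- pts[idx, , drop = FALSE] +
    frac * (pts[idx + 1L, , drop = FALSE] - pts[idx, , drop = FALSE])
  dimnames(out) <- NULL
  out
}

#' Tangent directions at the semilandmarks of a configuration
#'
#' For each sliding point \eqn{i}, the unit vector along the neighbor
#' chord \eqn{p_{i+1} - p_{i-1}}, with wraparound through the fixed
#' landmark on a closed outline. The fixed landmark never slides; its row
#' is zero.
#'
#' @param config \code{k x 2} coordinate matrix.
#' @param scheme a \code{\linkS4class{LandmarkScheme}}.
#' @return A \code{k x 2} matrix of unit tangents (zero row at the fixed
#'   landmark).
#' @export
tangentDirections <- function(config, scheme) {
  k <- nrow(config)
  if (k != scheme@nPoints)
    stop("configuration does not match the scheme point count")
  nxt <- c(2:k, 1L)
  prv <- c(k, seq_len(k - 1L))
  tg <- config[nxt, , drop = FALSE] - config[prv, , drop = FALSE]
  len <- sqrt(rowSums(tg^2))
  bad <- which(len == 0 & seq_len(k) != scheme@fixedIndex)
  if (length(bad))
    stop("zero-length tangent at point(s) ",
         paste(bad, collapse = ", "), ": coincident neighbors")
  len[len == 0] <- 1
  tg <- tg / len
  tg[scheme@fixedIndex, ] <- 0
  tg
}

## Jointly slide all semilandmarks of each configuration along their
## tangents to minimize the TPS bending energy relative to the consensus.
## Because B annihilates the reference's own coordinates, minimizing the
## quadratic form of the slid configuration equals minimizing it for the
## deviation from the consensus.
slideConfigsMinBE <- function(arr, cons, kern, scheme) {
  B <- kern@bending
  k <- nrow(B)
  n <- dim(arr)[3]
  slid <- seq_len(k)[-scheme@fixedIndex]
  totalBE <- 0
  for (i in seq_len(n)) {
    xy <- arr[, , i]
    tg <- tangentDirections(xy, scheme)
    ux <- tg[, 1L]; uy <- tg[, 2L]
    Bx <- B %*% xy[, 1L]
    By <- B %*% xy[, 2L]
    M <- B * outer(ux, ux) + B * outer(uy, uy)
    r <- ux * Bx + uy * By
    t_s <- tryCatch(solve(M[slid, slid], -r[slid]),
                    error = function(e)
                      qr.solve(M[slid, slid] +
                               diag(1e-12, length(slid)), -r[slid]))
    tt <- numeric(k)
    tt[slid] <- t_s
    xy[, 1L] <- xy[, 1L] + ux * tt
    xy[, 2L] <- xy[, 2L] + uy * tt
    arr[, , i] <- xy
    totalBE <- totalBE + bendingEnergy(kern, xy)
  }
  list(arr = arr, totalBE = totalBE)
}

## Slide each semilandmark independently to the point of its tangent line
## closest to the corresponding consensus point (minimum Procrustes
## distance criterion). Points sliding past a neighbor are counted, not
## corrected: this pathology is a documented property of the criterion on
## variable data.
slideConfigsMinPD <- function(arr, cons, scheme) {
  k <- dim(arr)[1]
  n <- dim(arr)[3]
  behind <- 0L
  nxt <- c(2:k, 1L)
  for (i in seq_len(n)) {
    xy <- arr[, , i]
    tg <- tangentDirections(xy, scheme)
    dv <- cons - xy
    tt <- rowSums(dv * tg)               # projection length per point
    newXY <- xy + tg * tt
    chord <- xy[nxt, , drop = FALSE] - xy
    newChord <- newXY[nxt, , drop = FALSE] - newXY
    behind <- behind + sum(rowSums(chord * newChord) < 0)
    arr[, , i] <- newXY
  }
  list(arr = arr, behindCount = behind)
}

## Shared slide/re-superimpose loop on an already aligned array.
slideRealignLoop <- function(arr, scheme, treatment, cycles, tol,
                             maxIter) {
  fit <- gpaIterate(arr, tol, maxIter)
  diag <- list(iterations = fit$iterations, converged = fit$converged,
               treatment = treatment, slideCycles = cycles)
  slideBehind <- integer(0)
  beTotals <- numeric(0)
  n <- dim(arr)[3]
  for (cycle in seq_len(cycles)) {
    if (treatment == "min_be") {
      kern <- bendingEnergyKernel(fit$consensus)
      slid <- slideConfigsMinBE(fit$arr, fit$consensus, kern, scheme)
      beTotals <- c(beTotals, slid$totalBE)
    } else {
      slid <- slideConfigsMinPD(fit$arr, fit$consensus, scheme)
      slideBehind <- c(slideBehind, slid$behindCount)
    }
    arr2 <- slid$arr
    for (i in seq_len(n)) {
      xy <- centerConfig(arr2[, , i])
      arr2[, , i] <- xy / sqrt(sum(xy^2))
    }
    fit <- gpaIterate(arr2, tol, maxIter)
    diag$iterations <- diag$iterations + fit$iterations
    diag$converged <- diag$converged && fit$converged
  }
  if (treatment == "min_pd") diag$slideBehindPerCycle <- slideBehind
  if (treatment == "min_be") diag$bendingEnergyPerCycle <- beTotals
  list(arr = fit$arr, consensus = fit$consensus, diagnostics = diag)
}

#' Slide semilandmarks of an existing alignment
#'
#' \code{slideMinBE} slides all semilandmarks of each configuration
#' jointly along their tangents to minimize the thin-plate-spline bending
#' energy relative to the current consensus; \code{slideMinPD} slides
#' each semilandmark independently to minimize its distance to the
#' corresponding consensus point. Both re-superimpose and refresh the
#' consensus between cycles and return a new alignment (the input is not
#' modified). Min-PD sliding counts points that slid past a neighbor in
#' \code{diagnostics$slideBehindPerCycle}.
#'
#' @param aligned an \code{\linkS4class{AlignedOutlines}}.
#' @param nIter number of slide/re-superimpose cycles.
#' @param tol,maxIter superimposition control, as in \code{\link{gpa}}.
#' @return An \code{\linkS4class{AlignedOutlines}} with treatment
#'   \code{"min_be"} or \code{"min_pd"}.
#' @export
slideMinBE <- function(aligned, nIter = 3L, tol = 1e-7, maxIter = 100L) {
  out <- slideRealignLoop(aligned@coords, aligned@scheme, "min_be",
                          nIter, tol, maxIter)
  orn <- orientByAxis(out$arr, out$consensus, aligned@scheme)
  initialize(aligned, coords = orn$arr, consensus = orn$consensus,
             treatment = "min_be", diagnostics = out$diagnostics)
}

#' @rdname slideMinBE
#' @export
slideMinPD <- function(aligned, nIter = 3L, tol = 1e-7, maxIter = 100L) {
  out <- slideRealignLoop(aligned@coords, aligned@scheme, "min_pd",
                          nIter, tol, maxIter)
  orn <- orientByAxis(out$arr, out$consensus, aligned@scheme)
  initialize(aligned, coords = orn$arr, consensus = orn$consensus,
             treatment = "min_pd", diagnostics = out$diagnostics)
}

#' Compare two semilandmark treatments against digitization error
#'
#' Joins the same digitized segments superimposed under two treatments
#' into one dataset (re-superimposed jointly, without sliding) and fits a
#' sequential (type I) decomposition: segment identity, then
#' treatment-within-segment, with the residual being the digitization
#' error between replicate digitizations. The headline diagnostic is the
#' mean-square ratio treatment / error: a ratio near 1 means the sliding
#' step moved points about as much as redigitizing the outline did.
#'
#' @param datasetA,datasetB \code{\linkS4class{AlignedOutlines}} over the
#'   same segments and replicates.
#' @param nPerm permutations for the treatment F (swapping treatment
#'   labels within segments); 0 skips p-values.
#' @param seed RNG seed used when \code{nPerm > 0}.
#' @return An \code{\linkS4class{AnovaTable}} with rows \code{segment},
#'   \code{treatment (segment)} and \code{digitization error}; the
#'   MS ratio is stored in \code{notes$msRatio}.
#' @export
treatmentEffectAnova <- function(datasetA, datasetB, nPerm = 0L,
                                 seed = 1L) {
  ia <- datasetA@info; ib <- datasetB@info
  segA <- paste(ia$locality, ia$plant, ia$segment, ia$replicate)
  segB <- paste(ib$locality, ib$plant, ib$segment, ib$replicate)
  if (!identical(sort(segA), sort(segB)))
    stop("the two datasets do not cover the same digitized segments")
  arr <- array(c(datasetA@coords, datasetB@coords),
               dim = c(dim(datasetA@coords)[1:2],
                       nConfigs(datasetA) + nConfigs(datasetB)))
  fit <- gpaIterate(arr)
  V <- t(matrix(fit$arr, nrow = prod(dim(arr)[1:2])))
  V <- tangentProject(V, fit$consensus)
  segment <- c(paste(ia$locality, ia$plant, ia$segment),
               paste(ib$locality, ib$plant, ib$segment))
  treatment <- rep(c(datasetA@treatment, datasetB@treatment),
                   c(nConfigs(datasetA), nConfigs(datasetB)))
  cell <- paste(segment, treatment)
  decomp <- function(V, segment, cell) {
    grand <- colMeans(V)
    Vc <- sweep(V, 2L, grand)
    ssTot <- sum(Vc^2)
    mSeg <- rowsum(V, segment) / as.vector(table(segment))
    nSeg <- as.vector(table(segment)[rownames(mSeg)])
    ssSeg <- sum(nSeg * rowSums(sweep(mSeg, 2L, grand)^2))
    mCell <- rowsum(V, cell) / as.vector(table(cell))
    segOfCell <- sub(" [^ ]+$", "", rownames(mCell))
    dev <- mCell - mSeg[segOfCell, , drop = FALSE]
    nCell <- as.vector(table(cell)[rownames(mCell)])
    ssTrt <- sum(nCell * rowSums(dev^2))
    ssErr <- ssTot - ssSeg - ssTrt
    c(ssTot, ssSeg, ssTrt, ssErr)
  }
  ss <- decomp(V, segment, cell)
  S <- length(unique(segment))
  df <- c(S - 1L, S, 2L * S)
  SS <- ss[2:4]
  MS <- SS / df
  Fval <- c(NA, MS[2L] / MS[3L], NA)
  pval <- rep(NA_real_, 3L)
  if (nPerm > 0L) {
    set.seed(seed)
    segIdx <- split(seq_len(nrow(V)), segment)
    count <- 0L
    for (b in seq_len(nPerm)) {
      permTrt <- treatment
      for (ii in segIdx)               # reshuffle records across the two
        permTrt[ii] <- sample(permTrt[ii])  # treatment cells per segment
      permCell <- paste(segment, permTrt)
      ssP <- decomp(V, segment, permCell)
      fP <- (ssP[3L] / df[2L]) / (ssP[4L] / df[3L])
      if (fP >= Fval[2L]) count <- count + 1L
    }
    pval[2L] <- (count + 1L) / (nPerm + 1L)
  }
  tab <- data.frame(
    effect = c("segment", "treatment (segment)", "digitization error"),
    df = df, SS = SS, MS = MS, F = Fval, p = pval, R2 = SS / ss[1L],
    stringsAsFactors = FALSE)
  new("AnovaTable", table = tab,
      response = paste("shape:", datasetA@treatment, "vs",
                       datasetB@treatment),
      nPerm = as.integer(nPerm), seed = as.integer(seed),
      notes = list(msRatio = MS[2L] / MS[3L]))
}
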