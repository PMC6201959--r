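## Nested ANOVA machinery. Multivariate sums of squares are traces of
## effect cross-product matrices, identical to summing univariate SS
## over coordinates and to the squared-tangent-distance formulation.
## Sequential (type I) decomposition is computed exactly through the
## nesting structure: the model space of [size covariate, nested factor]
## splits orthogonally into the factor's group-indicator space plus the
## component of size orthogonal to the group means, so every sequential
## increment is a closed-form projection. With a size covariate the side
## and segment-x-side rows are untouched by construction: centroid size
## is identical for the original and the reflected copy of a
## digitization, so size carries no signal in the asymmetric subspaces.

## Between-group SS (about the grand mean), plus the projection onto the
## within-group component of the size covariate when `u` is present.
## `sums`: per-group column sums (G x p); `N`: group counts; `sS`:
## per-group sums of the centered covariate; `u = V' sTilde`.
modelSS <- function(sums, N, grandTerm, u = NULL, sS = NULL,
                    s2tot = NULL) {
  between <- sum(rowSums(sums^2) / N) - grandTerm
  if (is.null(u)) return(between)
  d <- u - colSums(sums * (sS / N))
  wss <- s2tot - sum(sS^2 / N)
  projW <- if (wss > 1e-10 * s2tot) sum(d^2) / wss else 0
  between + projW
}

resolveAnovaInput <- function(x, design, sizes) {
  if (is(x, "SymmetryDecomposition")) {
    V <- shapeMatrix(x@alignment, tangent = TRUE)
    if (is.null(design)) design <- x@alignment@info
    if (is.null(sizes)) sizes <- x@alignment@centroidSizes
  } else if (is(x, "AlignedOutlines")) {
    V <- shapeMatrix(x, tangent = TRUE)
    if (is.null(design)) design <- x@info
    if (is.null(sizes)) sizes <- x@centroidSizes
  } else {
    V <- as.matrix(x)
    if (is.null(design)) stop("design must be supplied with matrix input")
  }
  if (nrow(design) != nrow(V))
    stop("design must have one row per observation")
  list(V = V, design = design, sizes = sizes)
}

degenerateF <- function(num, den) {
  if (!is.finite(den) || den <= 0) NA_real_ else num / den
}

## Group bookkeeping: factor, per-group sums/counts/covariate sums.
groupStat <- function(V, g, sTilde = NULL) {
  f <- factor(g)
  list(f = f, idx = as.integer(f), levels = levels(f),
       sums = rowsum(V, f), N = as.vector(table(f)),
       sS = if (!is.null(sTilde)) as.vector(rowsum(sTilde, f)) else NULL)
}

#' Multivariate nested Procrustes ANOVA of object-symmetry shape data
#'
#' Sequential (type I) decomposition of superimposed shape coordinates in
#' the fixed order: optional centroid size, locality, plant within
#' locality, segment within plant (symmetric variation), side within
#' plant (directional asymmetry), segment x side within plant
#' (fluctuating asymmetry), and measurement error (between replicate
#' digitizations). Each segment must enter in four instances: the
#' original and the reflected/relabeled copy of each of two
#' digitizations. F ratios follow the nesting: locality over plant,
#' plant over segment, segment and side over their interaction (FA), and
#' FA over measurement error.
#'
#' P-values come from restricted permutations that shuffle labels only
#' at the design level appropriate to each effect: whole plants across
#' localities (locality), whole segments across plants within locality
#' (plant), symmetry copies across segment-side cells within plants
#' (segment and side), and individual digitization records across the
#' four cells of their segment (FA against error). The p-value
#' convention is \eqn{(b + 1)/(n_{perm} + 1)}.
#'
#' @param x a \code{\linkS4class{SymmetryDecomposition}} (recommended),
#'   an \code{\linkS4class{AlignedOutlines}} over originals plus
#'   reflected copies, or an \code{n x p} shape matrix.
#' @param design data.frame with columns \code{locality}, \code{plant},
#'   \code{segment}, \code{side}, \code{replicate}; taken from the
#'   object when possible.
#' @param sizes centroid sizes, required when \code{adjustSize = TRUE}.
#' @param nPerm number of restricted permutations (0 skips p-values;
#'   positive values below 99 warn).
#' @param seed RNG seed for the permutations.
#' @param adjustSize fit centroid size before the nested factors.
#' @return An \code{\linkS4class{AnovaTable}}.
#' @export
nestedProcrustesAnova <- function(x, design = NULL, sizes = NULL,
                                  nPerm = 999L, seed = 1L,
                                  adjustSize = FALSE) {
  ri <- resolveAnovaInput(x, design, sizes)
  V <- ri$V; design <- ri$design
  if (nPerm > 0L && nPerm < 99L)
    warning("fewer than 99 permutations gives a very coarse p-value")
  if (is.null(design$side))
    stop("design needs a 'side' column (original/reflected)")
  loc <- as.character(design$locality)
  plant <- paste(loc, design$plant, sep = "\r")
  seg <- paste(plant, design$segment, sep = "\r")
  side <- as.character(design$side)
  cell <- paste(seg, side, sep = "\r")
  tab <- table(seg, paste(side, design$replicate))
  if (ncol(tab) != 4L || any(tab != 1L))
    stop("unbalanced design: every segment needs 2 sides x 2 replicates")
  n <- nrow(V)
  sTilde <- NULL; u <- NULL; s2tot <- NULL
  if (adjustSize) {
    if (is.null(ri$sizes)) stop("sizes required when adjustSize = TRUE")
    sTilde <- as.numeric(ri$sizes) - mean(as.numeric(ri$sizes))
    if (sum(sTilde^2) == 0) stop("degenerate covariate: constant sizes")
    u <- as.vector(crossprod(V, sTilde))
    s2tot <- sum(sTilde^2)
  }
  totalSum <- colSums(V)
  grandTerm <- sum(totalSum^2) / n
  ssTot <- sum(V^2) - grandTerm
  gLoc <- groupStat(V, loc, sTilde)
  gPlant <- groupStat(V, plant, sTilde)
  gSeg <- groupStat(V, seg, sTilde)
  gCell <- groupStat(V, cell, sTilde)
  ## index maps between grouping levels (no string parsing)
  plantOfSegIdx <- gPlant$idx[match(gSeg$levels, as.character(gSeg$f))]
  locOfPlantIdx <- gLoc$idx[match(gPlant$levels,
                                  as.character(gPlant$f))]
  cellFirst <- match(gCell$levels, as.character(gCell$f))
  segOfCellIdx <- gSeg$idx[cellFirst]
  plantOfCellIdx <- gPlant$idx[cellFirst]
  sideOfCell <- as.integer(factor(side))[cellFirst]
  psideOfCellKey <- paste(plantOfCellIdx, sideOfCell)
  mLoc <- modelSS(gLoc$sums, gLoc$N, grandTerm, u, gLoc$sS, s2tot)
  mPlant <- modelSS(gPlant$sums, gPlant$N, grandTerm, u, gPlant$sS,
                    s2tot)
  mSeg <- modelSS(gSeg$sums, gSeg$N, grandTerm, u, gSeg$sS, s2tot)
  betweenLocRaw <- modelSS(gLoc$sums, gLoc$N, grandTerm)
  betweenPlantRaw <- modelSS(gPlant$sums, gPlant$N, grandTerm)
  betweenSegRaw <- modelSS(gSeg$sums, gSeg$N, grandTerm)
  betweenCellRaw <- modelSS(gCell$sums, gCell$N, grandTerm)
  ssSize <- if (adjustSize) sum(u^2) / s2tot else 0
  ssLoc <- mLoc - ssSize
  ssPlant <- mPlant - mLoc
  ssSeg <- mSeg - mPlant
  plantMeans <- gPlant$sums / gPlant$N
  sideSSfromCells <- function(cellSums, cellN, psideKey) {
    ds <- rowsum(cellSums, psideKey)
    dN <- as.vector(rowsum(cellN, psideKey))
    pIdx <- as.integer(sub(" .*$", "", rownames(ds)))
    sum(dN * rowSums((ds / dN -
                      plantMeans[pIdx, , drop = FALSE])^2))
  }
  ssSide <- sideSSfromCells(gCell$sums, gCell$N, psideOfCellKey)
  ssFA <- betweenCellRaw - betweenSegRaw - ssSide
  ssErr <- ssTot - ssSize - ssLoc - ssPlant - ssSeg - ssSide - ssFA
  stopifnot(abs((ssSize + ssLoc + ssPlant + ssSeg + ssSide + ssFA +
                 ssErr) - ssTot) <= 1e-6 * max(ssTot, 1))
  L <- length(gLoc$levels); P <- length(gPlant$levels)
  S <- length(gSeg$levels)
  dfSize <- if (adjustSize) 1L else 0L
  dfLoc <- L - 1L; dfPlant <- P - L; dfSeg <- S - P
  dfSide <- P; dfFA <- S - P
  dfErr <- n - 1L - dfSize - dfLoc - dfPlant - dfSeg - dfSide - dfFA
  eff <- c(if (adjustSize) "centroid size", "locality",
           "plant (locality)", "segment (plant)", "side (plant)",
           "segment x side (plant)", "measurement error")
  SS <- c(if (adjustSize) ssSize, ssLoc, ssPlant, ssSeg, ssSide, ssFA,
          ssErr)
  df <- c(if (adjustSize) dfSize, dfLoc, dfPlant, dfSeg, dfSide, dfFA,
          dfErr)
  MS <- ifelse(df > 0, SS / df, NA_real_)
  ms <- function(e) { i <- match(e, eff); if (is.na(i)) NA_real_ else MS[i] }
  put <- function(v, e, val) { i <- match(e, eff); v[i] <- val; v }
  Fv <- rep(NA_real_, length(eff))
  Fv <- put(Fv, "locality",
            degenerateF(ms("locality"), ms("plant (locality)")))
  Fv <- put(Fv, "plant (locality)",
            degenerateF(ms("plant (locality)"), ms("segment (plant)")))
  Fv <- put(Fv, "segment (plant)",
            degenerateF(ms("segment (plant)"),
                        ms("segment x side (plant)")))
  Fv <- put(Fv, "side (plant)",
            degenerateF(ms("side (plant)"),
                        ms("segment x side (plant)")))
  Fv <- put(Fv, "segment x side (plant)",
            degenerateF(ms("segment x side (plant)"),
                        ms("measurement error")))
  if (adjustSize)
    Fv <- put(Fv, "centroid size",
              degenerateF(ms("centroid size"), ms("measurement error")))
  pv <- rep(NA_real_, length(eff))
  if (nPerm > 0L) {
    set.seed(seed)
    FlObs <- Fv[match("locality", eff)]
    FpObs <- Fv[match("plant (locality)", eff)]
    FsObs <- Fv[match("segment (plant)", eff)]
    FdObs <- Fv[match("side (plant)", eff)]
    FfObs <- Fv[match("segment x side (plant)", eff)]
    hitL <- hitP <- hitS <- hitD <- hitF <- 0L
    segIdxByLoc <- split(seq_along(plantOfSegIdx),
                         locOfPlantIdx[plantOfSegIdx])
    cellIdxByPlant <- split(seq_along(plantOfCellIdx), plantOfCellIdx)
    recOfSeg <- split(seq_len(n), gSeg$idx)
    cellOfRec <- gCell$idx
    for (b in seq_len(nPerm)) {
      if (is.finite(FlObs)) {
        permLoc <- sample(locOfPlantIdx)
        ls <- rowsum(gPlant$sums, permLoc)
        lN <- as.vector(rowsum(gPlant$N, permLoc))
        lsS <- if (adjustSize) as.vector(rowsum(gPlant$sS, permLoc))
               else NULL
        mL <- modelSS(ls, lN, grandTerm, u, lsS, s2tot)
        f <- ((mL - ssSize) / dfLoc) / ((mPlant - mL) / dfPlant)
        if (is.finite(f) && f >= FlObs) hitL <- hitL + 1L
      }
      if (is.finite(FpObs)) {
        permPlant <- plantOfSegIdx
        for (ii in segIdxByLoc) permPlant[ii] <- sample(permPlant[ii])
        ps <- rowsum(gSeg$sums, permPlant)
        pN <- as.vector(rowsum(gSeg$N, permPlant))
        psS <- if (adjustSize) as.vector(rowsum(gSeg$sS, permPlant))
               else NULL
        mP <- modelSS(ps, pN, grandTerm, u, psS, s2tot)
        f <- ((mP - mLoc) / dfPlant) / ((mSeg - mP) / dfSeg)
        if (is.finite(f) && f >= FpObs) hitP <- hitP + 1L
      }
      if (is.finite(FsObs) || is.finite(FdObs)) {
        permSegIdx <- segOfCellIdx
        permSide <- sideOfCell
        for (ii in cellIdxByPlant) {
          sh <- sample(ii)
          permSegIdx[ii] <- segOfCellIdx[sh]
          permSide[ii] <- sideOfCell[sh]
        }
        ss2 <- rowsum(gCell$sums, permSegIdx)
        sN2 <- as.vector(rowsum(gCell$N, permSegIdx))
        ssS2 <- if (adjustSize) as.vector(rowsum(gCell$sS, permSegIdx))
                else NULL
        mS2 <- modelSS(ss2, sN2, grandTerm, u, ssS2, s2tot)
        betweenSegPerm <- modelSS(ss2, sN2, grandTerm)
        sidePerm <- sideSSfromCells(gCell$sums, gCell$N,
                                    paste(plantOfCellIdx, permSide))
        faPerm <- betweenCellRaw - betweenSegPerm - sidePerm
        fS <- ((mS2 - mPlant) / dfSeg) / (faPerm / dfFA)
        fD <- (sidePerm / dfSide) / (faPerm / dfFA)
        if (is.finite(FsObs) && is.finite(fS) && fS >= FsObs)
          hitS <- hitS + 1L
        if (is.finite(FdObs) && is.finite(fD) && fD >= FdObs)
          hitD <- hitD + 1L
      }
      if (is.finite(FfObs)) {
        permCell <- cellOfRec
        for (ii in recOfSeg) permCell[ii] <- sample(permCell[ii])
        cs <- rowsum(V, permCell)            # cell labels keep identity
        bcPerm <- modelSS(cs, gCell$N, grandTerm)
        sideP <- sideSSfromCells(cs, gCell$N, psideOfCellKey)
        faP <- (bcPerm - betweenSegRaw) - sideP
        errP <- ssTot - bcPerm
        f <- (faP / dfFA) / (errP / dfErr)
        if (is.finite(f) && f >= FfObs) hitF <- hitF + 1L
      }
    }
    setp <- function(v, e, hits, obs) {
      if (is.finite(obs)) v[match(e, eff)] <- (hits + 1) / (nPerm + 1)
      v
    }
    pv <- setp(pv, "locality", hitL, FlObs)
    pv <- setp(pv, "plant (locality)", hitP, FpObs)
    pv <- setp(pv, "segment (plant)", hitS, FsObs)
    pv <- setp(pv, "side (plant)", hitD, FdObs)
    pv <- setp(pv, "segment x side (plant)", hitF, FfObs)
  }
  notes <- list(permutationScheme = paste(
    "locality: plants across localities;",
    "plant: segments across plants within locality;",
    "segment & side: symmetry copies across cells within plant;",
    "FA: records across the cells of their segment"))
  degen <- eff[df > 0 & !is.finite(Fv) &
               !(eff %in% c("measurement error", "centroid size"))]
  if (length(degen)) notes$degenerate <- degen
  tab <- data.frame(effect = eff, df = df, SS = SS, MS = MS, F = Fv,
                    p = pv, R2 = SS / ssTot, stringsAsFactors = FALSE)
  new("AnovaTable", table = tab,
      response = if (adjustSize) "shape (size-adjusted)" else "shape",
      nPerm = as.integer(nPerm), seed = as.integer(seed), notes = notes)
}

#' Univariate nested ANOVA of total shape asymmetry
#'
#' Decomposes one asymmetry value per digitized outline (two replicates
#' per segment) into optional centroid size, locality, plant within
#' locality, segment within plant, and measurement error, with F ratios
#' locality/plant, plant/segment, segment/error. Restricted permutation
#' p-values shuffle plants across localities, segments across plants
#' within locality, and records across segments within plant.
#'
#' @param values numeric vector, one value per digitization record.
#' @param design data.frame with columns \code{locality}, \code{plant},
#'   \code{segment}, \code{replicate} (one row per record).
#' @param sizes centroid sizes per record (needed for
#'   \code{adjustSize}).
#' @param nPerm,seed,adjustSize as in
#'   \code{\link{nestedProcrustesAnova}}.
#' @return An \code{\linkS4class{AnovaTable}}.
#' @export
totalAsymmetryAnova <- function(values, design, sizes = NULL,
                                nPerm = 999L, seed = 1L,
                                adjustSize = FALSE) {
  V <- matrix(as.numeric(values), ncol = 1L)
  if (nrow(design) != nrow(V))
    stop("design must have one row per value")
  if (nPerm > 0L && nPerm < 99L)
    warning("fewer than 99 permutations gives a very coarse p-value")
  loc <- as.character(design$locality)
  plant <- paste(loc, design$plant, sep = "\r")
  seg <- paste(plant, design$segment, sep = "\r")
  if (any(table(seg) != 2L))
    stop("every segment needs exactly 2 replicate records")
  n <- nrow(V)
  sTilde <- NULL; u <- NULL; s2tot <- NULL
  if (adjustSize) {
    if (is.null(sizes)) stop("sizes required when adjustSize = TRUE")
    sTilde <- as.numeric(sizes) - mean(as.numeric(sizes))
    if (sum(sTilde^2) == 0) stop("degenerate covariate: constant sizes")
    u <- as.vector(crossprod(V, sTilde))
    s2tot <- sum(sTilde^2)
  }
  grandTerm <- sum(colSums(V)^2) / n
  ssTot <- sum(V^2) - grandTerm
  gLoc <- groupStat(V, loc, sTilde)
  gPlant <- groupStat(V, plant, sTilde)
  gSeg <- groupStat(V, seg, sTilde)
  plantOfSegIdx <- gPlant$idx[match(gSeg$levels, as.character(gSeg$f))]
  locOfPlantIdx <- gLoc$idx[match(gPlant$levels,
                                  as.character(gPlant$f))]
  mLoc <- modelSS(gLoc$sums, gLoc$N, grandTerm, u, gLoc$sS, s2tot)
  mPlant <- modelSS(gPlant$sums, gPlant$N, grandTerm, u, gPlant$sS,
                    s2tot)
  mSeg <- modelSS(gSeg$sums, gSeg$N, grandTerm, u, gSeg$sS, s2tot)
  betweenSegRaw <- modelSS(gSeg$sums, gSeg$N, grandTerm)
  ssSize <- if (adjustSize) sum(u^2) / s2tot else 0
  ssLoc <- mLoc - ssSize
  ssPlant <- mPlant - mLoc
  ssSeg <- mSeg - mPlant
  ssErr <- ssTot - ssSize - ssLoc - ssPlant - ssSeg
  L <- length(gLoc$levels); P <- length(gPlant$levels)
  S <- length(gSeg$levels)
  dfSize <- if (adjustSize) 1L else 0L
  dfLoc <- L - 1L; dfPlant <- P - L; dfSeg <- S - P
  dfErr <- n - 1L - dfSize - dfLoc - dfPlant - dfSeg
  eff <- c(if (adjustSize) "centroid size", "locality",
           "plant (locality)", "segment (plant)", "measurement error")
  SS <- c(if (adjustSize) ssSize, ssLoc, ssPlant, ssSeg, ssErr)
  df <- c(if (adjustSize) dfSize, dfLoc, dfPlant, dfSeg, dfErr)
  MS <- ifelse(df > 0, SS / df, NA_real_)
  ms <- function(e) { i <- match(e, eff); if (is.na(i)) NA_real_ else MS[i] }
  Fv <- rep(NA_real_, length(eff))
  Fv[match("locality", eff)] <-
    degenerateF(ms("locality"), ms("plant (locality)"))
  Fv[match("plant (locality)", eff)] <-
    degenerateF(ms("plant (locality)"), ms("segment (plant)"))
  Fv[match("segment (plant)", eff)] <-
    degenerateF(ms("segment (plant)"), ms("measurement error"))
  if (adjustSize)
    Fv[match("centroid size", eff)] <-
      degenerateF(ms("centroid size"), ms("measurement error"))
  pv <- rep(NA_real_, length(eff))
  if (nPerm > 0L && ssTot > 0) {
    set.seed(seed)
    FlObs <- Fv[match("locality", eff)]
    FpObs <- Fv[match("plant (locality)", eff)]
    FsObs <- Fv[match("segment (plant)", eff)]
    hitL <- hitP <- hitS <- 0L
    segIdxByLoc <- split(seq_along(plantOfSegIdx),
                         locOfPlantIdx[plantOfSegIdx])
    recByPlant <- split(seq_len(n), gPlant$idx)
    segOfRec <- gSeg$idx
    for (b in seq_len(nPerm)) {
      if (is.finite(FlObs)) {
        permLoc <- sample(locOfPlantIdx)
        ls <- rowsum(gPlant$sums, permLoc)
        lN <- as.vector(rowsum(gPlant$N, permLoc))
        lsS <- if (adjustSize) as.vector(rowsum(gPlant$sS, permLoc))
               else NULL
        mL <- modelSS(ls, lN, grandTerm, u, lsS, s2tot)
        f <- ((mL - ssSize) / dfLoc) / ((mPlant - mL) / dfPlant)
        if (is.finite(f) && f >= FlObs) hitL <- hitL + 1L
      }
      if (is.finite(FpObs)) {
        permPlant <- plantOfSegIdx
        for (ii in segIdxByLoc) permPlant[ii] <- sample(permPlant[ii])
        ps <- rowsum(gSeg$sums, permPlant)
        pN <- as.vector(rowsum(gSeg$N, permPlant))
        psS <- if (adjustSize) as.vector(rowsum(gSeg$sS, permPlant))
               else NULL
        mP <- modelSS(ps, pN, grandTerm, u, psS, s2tot)
        f <- ((mP - mLoc) / dfPlant) / ((mSeg - mP) / dfSeg)
        if (is.finite(f) && f >= FpObs) hitP <- hitP + 1L
      }
      if (is.finite(FsObs)) {
        permSeg <- segOfRec
        for (ii in recByPlant) permSeg[ii] <- sample(permSeg[ii])
        ss2 <- rowsum(V, permSeg)
        sN2 <- as.vector(table(permSeg))
        ssS2 <- if (adjustSize) as.vector(rowsum(sTilde, permSeg))
                else NULL
        mS2 <- modelSS(ss2, sN2, grandTerm, u, ssS2, s2tot)
        ssSegP <- mS2 - mPlant
        ssErrP <- ssTot - ssSize - (mLoc - ssSize) - (mPlant - mLoc) -
          ssSegP
        f <- (ssSegP / dfSeg) / (ssErrP / dfErr)
        if (is.finite(f) && f >= FsObs) hitS <- hitS + 1L
      }
    }
    if (is.finite(FlObs))
      pv[match("locality", eff)] <- (hitL + 1) / (nPerm + 1)
    if (is.finite(FpObs))
      pv[match("plant (locality)", eff)] <- (hitP + 1) / (nPerm + 1)
    if (is.finite(FsObs))
      pv[match("segment (plant)", eff)] <- (hitS + 1) / (nPerm + 1)
  }
  tab <- data.frame(effect = eff, df = df, SS = SS, MS = MS, F = Fv,
                    p = pv, R2 = if (ssTot > 0) SS / ssTot else 0,
                    stringsAsFactors = FALSE)
  notes <- list()
  if (ssTot == 0) notes$degenerate <- "constant response"
  new("AnovaTable", table = tab,
      response = if (adjustSize)
        "total asymmetry (size-adjusted)" else "total asymmetry",
      nPerm = as.integer(nPerm), seed = as.integer(seed), notes = notes)
}

#' Per-plant decomposition into symmetric variation, DA and FA
#'
#' Runs, for each plant separately, the type I decomposition of its
#' segments' four-instance records into segment (symmetric variation),
#' side (directional asymmetry), segment x side (fluctuating asymmetry)
#' and measurement error, reporting MS and R-squared per component.
#' These per-plant tables are meant for comparing populations, not for
#' significance testing, so no p-values are attached. Plants with fewer
#' than \code{minSegments} segments are skipped with a warning.
#'
#' @param x as in \code{\link{nestedProcrustesAnova}}.
#' @param design optional design data.frame.
#' @param minSegments minimum number of segments for a plant to be
#'   decomposed.
#' @return A data.frame with one row per plant: \code{locality},
#'   \code{plant}, \code{nSegments}, MS and R2 columns for
#'   \code{symmetric}, \code{da}, \code{fa}, plus \code{errorMS}.
#' @export
perPlantDecomposition <- function(x, design = NULL, minSegments = 3L) {
  ri <- resolveAnovaInput(x, design, NULL)
  V <- ri$V; design <- ri$design
  loc <- as.character(design$locality)
  plant <- paste(loc, design$plant, sep = "\r")
  out <- list()
  skipped <- character()
  for (p in unique(plant)) {
    rows <- which(plant == p)
    d <- design[rows, , drop = FALSE]
    nSeg <- length(unique(d$segment))
    if (nSeg < minSegments) {
      skipped <- c(skipped, p)
      next
    }
    Vp <- V[rows, , drop = FALSE]
    seg <- as.character(d$segment)
    side <- as.character(d$side)
    cellp <- paste(seg, side, sep = "\r")
    np <- nrow(Vp)
    grandTerm <- sum(colSums(Vp)^2) / np
    ssTot <- sum(Vp^2) - grandTerm
    gS <- groupStat(Vp, seg); gC <- groupStat(Vp, cellp)
    gD <- groupStat(Vp, side)
    ssSeg <- modelSS(gS$sums, gS$N, grandTerm)
    ssSide <- modelSS(gD$sums, gD$N, grandTerm)
    betweenCell <- modelSS(gC$sums, gC$N, grandTerm)
    ssFA <- betweenCell - ssSeg - ssSide
    ssErr <- ssTot - betweenCell
    dfSeg <- nSeg - 1L; dfSide <- 1L; dfFA <- nSeg - 1L
    dfErr <- np - 2L * nSeg
    out[[p]] <- data.frame(
      locality = d$locality[1L], plant = d$plant[1L], nSegments = nSeg,
      symmetricMS = ssSeg / dfSeg, daMS = ssSide / dfSide,
      faMS = ssFA / dfFA, errorMS = ssErr / dfErr,
      symmetricR2 = ssSeg / ssTot, daR2 = ssSide / ssTot,
      faR2 = ssFA / ssTot, stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning(length(skipped), " plant(s) with fewer than ", minSegments,
            " segments skipped")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bootstrap confidence interval for a difference of group medians
#'
#' Resamples each group independently with replacement and reports the
#' percentile 95\% interval of \code{median(A) - median(B)}. The
#' two-sided p-value is twice the smaller tail fraction of the bootstrap
#' distribution around zero, floored at \code{1/nBoot}; the difference
#' is called significant when the interval excludes zero.
#'
#' @param valuesA,valuesB numeric vectors (at least 5 values each).
#' @param nBoot number of bootstrap resamples.
#' @param seed RNG seed.
#' @return A \code{\linkS4class{BootstrapResult}}.
#' @export
bootstrapMedianDifference <- function(valuesA, valuesB, nBoot = 999L,
                                      seed = 1L) {
  if (length(valuesA) < 5L || length(valuesB) < 5L)
    stop("need at least 5 values per group")
  set.seed(seed)
  est <- numeric(nBoot)
  nA <- length(valuesA); nB <- length(valuesB)
  for (b in seq_len(nBoot))
    est[b] <- median(valuesA[sample.int(nA, nA, replace = TRUE)]) -
      median(valuesB[sample.int(nB, nB, replace = TRUE)])
  ci <- unname(quantile(est, c(0.025, 0.975), type = 7))
  pl <- mean(est <= 0); pg <- mean(est >= 0)
  p <- max(min(2 * min(pl, pg), 1), 1 / nBoot)
  new("BootstrapResult", medianA = median(valuesA),
      medianB = median(valuesB), estimates = est, ci = ci,
      pValue = p, nBoot = as.integer(nBoot), seed = as.integer(seed))
}

#' Correlations among per-plant variance components
#'
#' Pearson correlations between the per-plant mean squares of symmetric
#' variation, directional asymmetry and fluctuating asymmetry, telling
#' whether plants with variable segments also tend to have asymmetric
#' segments.
#'
#' @param perPlant a data.frame from
#'   \code{\link{perPlantDecomposition}} (needs at least 3 plants).
#' @return A 3 x 3 correlation matrix over \code{symmetricMS},
#'   \code{daMS}, \code{faMS}; constant columns give \code{NA} with a
#'   warning.
#' @export
msCorrelations <- function(perPlant) {
  need <- c("symmetricMS", "daMS", "faMS")
  if (!all(need %in% names(perPlant)))
    stop("perPlant must contain columns ", paste(need, collapse = ", "))
  if (nrow(perPlant) < 3L) stop("need at least 3 plants")
  M <- as.matrix(perPlant[, need])
  if (any(apply(M, 2L, sd) == 0))
    warning("constant MS column: correlation undefined")
  suppressWarnings(cor(M))
}

#' Correlation between centroid size and total shape asymmetry
#'
#' @param sizes,asymmetry paired numeric vectors.
#' @return A list with Pearson \code{r} and \code{pctVariance}
#'   (\code{100 r^2}).
#' @export
sizeAsymmetryCorrelation <- function(sizes, asymmetry) {
  if (length(sizes) != length(asymmetry))
    stop("sizes and asymmetry must be paired")
  if (sd(sizes) == 0 || sd(asymmetry) == 0)
    stop("constant input: correlation undefined")
  r <- cor(sizes, asymmetry)
  list(r = r, pctVariance = 100 * r^2)
}
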