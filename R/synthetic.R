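## Hierarchical synthetic outline generator. Emulates the statistical
## structure the nested models assume: localities differing in median
## segment size, plants with their own symmetric shape and directional
## asymmetry, segments with symmetric variation, size-coupled allometric
## shape change and fluctuating asymmetry, and two digitization
## replicates with independent coordinate noise. Symmetric perturbations
## are built in an exactly mirror-symmetric basis and asymmetric ones in
## an exactly antisymmetric basis, so injected variance lands in the
## intended subspace and bookkeeping is exact.

## Index parameter t_i = 2*pi*(i-1)/n. Under the paired scheme the
## mirror maps i -> n + 2 - i, i.e. t -> -t, so fields with
## x ~ sin, y ~ cos are exactly symmetric and x ~ cos, y ~ sin exactly
## antisymmetric.
fieldBasis <- function(n, modes, type = c("symmetric", "asymmetric")) {
  type <- match.arg(type)
  t <- 2 * pi * (seq_len(n) - 1L) / n
  out <- list()
  for (m in modes) {
    if (type == "symmetric") {
      bx <- sin(m * t); by <- cos(m * t)
    } else {
      bx <- cos(m * t); by <- sin(m * t)
    }
    out[[length(out) + 1L]] <- cbind(bx / sqrt(sum(bx^2)), 0)
    out[[length(out) + 1L]] <- cbind(0, by / sqrt(sum(by^2)))
  }
  out
}

## Random smooth field of total expected squared norm `mag^2`. Field
## variance is spread anisotropically over the basis elements with
## geometrically decaying weights (ratio `decay`), emulating the
## low-dimensional dominant shape trends of real outline data; an
## optional leading direction (e.g. the allometric deformation) takes
## the fraction `leadWeight` of the variance.
randomField <- function(basis, mag, decay = 0.55, lead = NULL,
                        leadWeight = 0.7) {
  w <- decay^(seq_along(basis) - 1L)
  w <- w / sum(w)
  if (!is.null(lead)) w <- c(leadWeight, (1 - leadWeight) * w)
  co <- rnorm(length(w), 0, mag * sqrt(w))
  basis <- c(if (!is.null(lead)) list(lead), basis)
  Reduce(`+`, Map(function(B, a) a * B, basis, co))
}

## Orthonormal basis of the similarity directions at a centered base
## shape: x/y translation, scaling (the shape itself) and infinitesimal
## rotation. Generator fields are projected out of this subspace so the
## injected variance survives superimposition instead of being absorbed
## by it; because the base is mirror-symmetric the projection preserves
## the exact symmetry class of each field.
similarityBasis <- function(base) {
  k <- nrow(base)
  t1 <- cbind(rep(1 / sqrt(k), k), 0)
  t2 <- cbind(0, rep(1 / sqrt(k), k))
  s <- base / sqrt(sum(base^2))
  r <- cbind(-base[, 2L], base[, 1L])
  r <- r / sqrt(sum(r^2))
  list(t1, t2, s, r)
}

orthogonalizeField <- function(F, simBasis) {
  for (U in simBasis) F <- F - sum(F * U) * U
  nrm <- sqrt(sum(F^2))
  if (nrm < 1e-10) stop("field collapses onto the similarity subspace")
  F / nrm
}

## Deterministic unit-norm symmetric deformation used as the allometric
## direction: elongation plus widening of the apical half, orthogonal to
## the similarity directions.
allometryDirection <- function(n, simBasis) {
  t <- 2 * pi * (seq_len(n) - 1L) / n
  D <- cbind(0.6 * sin(2 * t), cos(t) + 0.5 * cos(2 * t))
  orthogonalizeField(D / sqrt(sum(D^2)), simBasis)
}

#' Mirror-symmetric bean-shaped reference outline
#'
#' Samples the closed curve \eqn{r(\phi) = r_0 (1 + \sum_m a_m \cos
#' m\phi)} at arc-length-equidistant positions, with point 1 at the
#' basal pole (\eqn{\phi = 0}, pointing down) and counterclockwise
#' ordering, then centers it and scales it to unit centroid size. The
#' cosine-only radial series makes the curve exactly mirror-symmetric
#' under the paired scheme; symmetry is additionally enforced to
#' floating-point exactness on the sampled points.
#'
#' @param nPoints number of sampled points (even).
#' @param harmonics named or plain numeric vector of radial coefficients
#'   \eqn{a_m} for \eqn{m = 1, 2, \dots}.
#' @param r0 base radius.
#' @return A \code{nPoints x 2} coordinate matrix (unit centroid size).
#' @export
baseOutline <- function(nPoints = 90L,
                        harmonics = c(0.12, -0.15, 0, 0.03),
                        r0 = 1) {
  dense <- 20000L
  phi <- 2 * pi * (seq_len(dense) - 1L) / dense
  r <- rep(r0, dense)
  for (m in seq_along(harmonics))
    r <- r + r0 * harmonics[m] * cos(m * phi)
  if (any(r <= 0)) stop("harmonics drive the radius non-positive")
  psi <- phi - pi / 2
  curve <- cbind(r * cos(psi), r * sin(psi))
  pts <- resampleEquidistant(curve, nPoints, fixedStart = 1L)
  ## enforce exact mirror symmetry: i <-> nPoints + 2 - i
  half <- nPoints %/% 2L
  for (i in 2:half) {
    j <- nPoints + 2L - i
    x <- (pts[i, 1L] - pts[j, 1L]) / 2
    y <- (pts[i, 2L] + pts[j, 2L]) / 2
    pts[i, ] <- c(x, y)
    pts[j, ] <- c(-x, y)
  }
  pts[1L, 1L] <- 0
  pts[half + 1L, 1L] <- 0
  pts <- centerConfig(pts)
  pts[, 1L] <- pts[, 1L] - mean(pts[, 1L])   # keep x exactly centered
  pts / sqrt(sum(centerConfig(pts)^2))
}

#' Construct a synthetic-data specification
#'
#' Default magnitudes are calibrated so that a study-like design
#' reproduces the variance decomposition typical of field data of this
#' kind (see the methods vignette): per-record shape variance of about
#' 0.006 from allometry, 0.002 between plants, 0.009 between segments,
#' 0.0004 directional asymmetry, 0.003 fluctuating asymmetry and 0.0006
#' digitization error. Asymmetric and digitization effects are applied
#' on an absolute (image-unit) scale, so relative asymmetry grows as
#' segments get smaller, reproducing the negative size-asymmetry
#' coupling of real segment data.
#'
#' @param nLocalities,plantsPerLocality design counts.
#' @param segmentCounts list with one integer vector (segments per
#'   plant) per locality; default 8 segments everywhere.
#' @param nPoints points per outline (even; scheme =
#'   \code{pairedScheme(nPoints)}).
#' @param medianSizes per-locality median centroid size (recycled).
#' @param sizeLogSd total lognormal sd of sizes within a locality.
#' @param plantSizeShare fraction of the size log-variance at the plant
#'   level; the rest varies among segments within plants (in field data
#'   of this kind most size variation is among segments).
#' @param allometrySlope shape displacement (unit-field norm) per unit
#'   centroid size.
#' @param plantSd,symmetricSd symmetric field magnitudes (plant and
#'   segment level).
#' @param daMagnitude,faSd antisymmetric field magnitudes (plant-level
#'   DA and segment-level FA), in shape units at the mean size.
#' @param meSd per-coordinate digitization noise sd, in shape units at
#'   the mean size.
#' @param seed master seed; all level-specific random streams derive
#'   from it.
#' @return A \code{\linkS4class{SyntheticSpec}}.
#' @export
SyntheticSpec <- function(nLocalities = 2L, plantsPerLocality = 6L,
                          segmentCounts = NULL, nPoints = 90L,
                          medianSizes = c(0.82, 1),
                          sizeLogSd = 0.3, plantSizeShare = 0.1,
                          allometrySlope = 0.25,
                          plantSd = 0.042, symmetricSd = 0.093,
                          daMagnitude = 0.015, faSd = 0.053,
                          meSd = 0.002, seed = 1L) {
  nLocalities <- as.integer(nLocalities)
  plantsPerLocality <- as.integer(plantsPerLocality)
  if (is.null(segmentCounts))
    segmentCounts <- rep(list(rep(8L, plantsPerLocality)), nLocalities)
  new("SyntheticSpec", nLocalities = nLocalities,
      plantsPerLocality = plantsPerLocality,
      segmentCounts = lapply(segmentCounts, as.integer),
      nPoints = as.integer(nPoints),
      medianSizes = rep_len(medianSizes, nLocalities),
      sizeLogSd = sizeLogSd, plantSizeShare = plantSizeShare,
      allometrySlope = allometrySlope,
      plantSd = plantSd, symmetricSd = symmetricSd,
      daMagnitude = daMagnitude, faSd = faSd, meSd = meSd,
      seed = as.integer(seed))
}

#' The study-like synthetic preset
#'
#' Two localities of 48 plants each, a fixed deterministic vector of
#' segments per plant with median 9.5 and 491 segments per locality (982
#' in total, so the nested shape model has the df column 1, 94, 886, 96,
#' 886, 1964), and locality A's median centroid size 18\% below locality
#' B's. Magnitude defaults are the calibrated values of
#' \code{\link{SyntheticSpec}}.
#'
#' @param seed master seed.
#' @return A \code{\linkS4class{SyntheticSpec}}.
#' @export
studyLikeSpec <- function(seed = 1L) {
  counts <- c(rep(6:9, each = 6L), 10L, rep(13L, 21L), rep(14L, 2L))
  SyntheticSpec(nLocalities = 2L, plantsPerLocality = 48L,
                segmentCounts = list(counts, counts), nPoints = 90L,
                medianSizes = c(0.82, 1), seed = seed)
}

## Bounded deterministic sub-seed per (level, index) so that, e.g.,
## changing segment counts does not shift plant-level draws.
subSeed <- function(seed, level, index) {
  (as.numeric(seed) * 48271 + level * 7919 + index * 104729) %%
    2147483562
}

#' Generate a hierarchical synthetic outline dataset
#'
#' Draws, for every segment, a centroid size from the plant/locality
#' size model and a shape equal to the symmetric base outline plus the
#' allometric deformation, plant- and segment-level symmetric fields,
#' the plant's directional-asymmetry field and the segment's fluctuating
#' asymmetry, then digitizes it twice: each replicate gets a random
#' rotation and independent coordinate noise. The same seed reproduces
#' the output bit for bit.
#'
#' @param spec a \code{\linkS4class{SyntheticSpec}}.
#' @return A list: \code{outlines} (an
#'   \code{\linkS4class{OutlineSet}} with 2 replicates per segment),
#'   \code{truth} (every drawn effect: per-segment sizes, per-plant DA
#'   fields, per-segment FA fields, the allometric direction and base
#'   shape), for parameter-recovery tests.
#' @export
generateOutlines <- function(spec) {
  validObject(spec)
  k <- spec@nPoints
  scheme <- pairedScheme(k)
  base <- baseOutline(k)
  sim <- similarityBasis(base)
  D <- allometryDirection(k, sim)
  symBasis <- lapply(fieldBasis(k, 1:4, "symmetric"),
                     orthogonalizeField, simBasis = sim)
  asymBasis <- lapply(fieldBasis(k, 1:4, "asymmetric"),
                      orthogonalizeField, simBasis = sim)
  sBar <- mean(spec@medianSizes)
  nSegTot <- sum(unlist(spec@segmentCounts))
  coords <- array(0, dim = c(k, 2L, 2L * nSegTot))
  info <- data.frame(locality = character(2L * nSegTot),
                     plant = "", segment = "", replicate = 1L,
                     reflected = FALSE, stringsAsFactors = FALSE)
  truth <- list(base = base, allometryDirection = D,
                sizes = numeric(nSegTot),
                daFields = array(0, dim = c(k, 2L,
                                            spec@nLocalities *
                                            spec@plantsPerLocality)),
                faFields = array(0, dim = c(k, 2L, nSegTot)),
                segLocality = character(nSegTot),
                segPlant = character(nSegTot),
                segId = character(nSegTot))
  rec <- 0L
  segGlobal <- 0L
  plantGlobal <- 0L
  locNames <- LETTERS[seq_len(spec@nLocalities)]
  for (l in seq_len(spec@nLocalities)) {
    for (p in seq_len(spec@plantsPerLocality)) {
      plantGlobal <- plantGlobal + 1L
      set.seed(subSeed(spec@seed, 1L, plantGlobal))
      daField <- randomField(asymBasis, spec@daMagnitude)
      plantField <- randomField(symBasis, spec@plantSd, lead = D)
      plantSizeFactor <- exp(rnorm(1L, 0, spec@sizeLogSd *
                                          sqrt(spec@plantSizeShare)))
      truth$daFields[, , plantGlobal] <- daField
      plantName <- sprintf("P%02d", p)
      for (s in seq_len(spec@segmentCounts[[l]][p])) {
        segGlobal <- segGlobal + 1L
        set.seed(subSeed(spec@seed, 2L, segGlobal))
        size <- spec@medianSizes[l] * plantSizeFactor *
          exp(rnorm(1L, 0, spec@sizeLogSd *
                          sqrt(1 - spec@plantSizeShare)))
        segField <- randomField(symBasis, spec@symmetricSd, lead = D)
        faField <- randomField(asymBasis, spec@faSd)
        symShape <- base + spec@allometrySlope * (size - sBar) * D +
          plantField + segField
        imageBase <- size * symShape + sBar * (daField + faField)
        truth$sizes[segGlobal] <- size
        truth$faFields[, , segGlobal] <- faField
        truth$segLocality[segGlobal] <- locNames[l]
        truth$segPlant[segGlobal] <- plantName
        segName <- sprintf("S%03d", s)
        truth$segId[segGlobal] <- segName
        for (r in 1:2) {
          rec <- rec + 1L
          ang <- runif(1L, 0, 2 * pi)
          noise <- matrix(rnorm(2L * k, 0, sBar * spec@meSd), k, 2L)
          coords[, , rec] <- imageBase %*% rot2(ang) + noise
          info$locality[rec] <- locNames[l]
          info$plant[rec] <- plantName
          info$segment[rec] <- segName
          info$replicate[rec] <- r
        }
      }
    }
  }
  list(outlines = new("OutlineSet", coords = coords, info = info,
                      scheme = scheme),
       truth = truth)
}
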