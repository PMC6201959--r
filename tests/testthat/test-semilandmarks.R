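test_that("equidistant resampling hits arc-length positions exactly", {
  ## square from a corner: 8 points = 4 corners + 4 edge midpoints
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  out <- resampleEquidistant(sq, 8L)
  expect_equal(out, rbind(c(0, 0), c(0.5, 0), c(1, 0), c(1, 0.5),
                          c(1, 1), c(0.5, 1), c(0, 1), c(0, 0.5)),
               tolerance = 1e-12)
  ## resampling an already-equidistant closed curve is the identity
  circ16 <- resampleEquidistant(denseCurve(2000L, seed = 2L, mag = 0),
                                16L)
  expect_equal(resampleEquidistant(circ16, 16L), circ16,
               tolerance = 1e-12)
  ## spacing on a random smooth curve, re-measured along the input
  dense <- denseCurve()
  out90 <- resampleEquidistant(dense, 90L)
  pos <- arcPositions(out90, dense)
  per <- sum(sqrt(rowSums((rbind(dense[-1L, ], dense[1L, ]) -
                           dense)^2)))
  spacing <- diff(c(pos, pos[1L] + per))
  expect_lt(max(abs(spacing - per / 90)), 1e-9)
  expect_equal(out90[1L, ], dense[1L, ])  # fixed start retained
  expect_warning(resampleEquidistant(sq, 140L), "resolution")
})

test_that("tangent directions follow the neighbor chords", {
  sc <- pairedScheme(24L)
  ## circle: tangents perpendicular to radii
  phi <- 2 * pi * (0:23) / 24
  circ <- cbind(cos(phi), sin(phi))
  tg <- tangentDirections(circ, sc)
  dots <- abs(rowSums(tg * circ))[-sc@fixedIndex]
  expect_lt(max(dots), 1e-9)
  expect_equal(tg[sc@fixedIndex, ], c(0, 0))
  ## collinear triple: middle tangent along the line
  cfg <- circ
  cfg[5L, ] <- (cfg[4L, ] + cfg[6L, ]) / 2
  tg2 <- tangentDirections(cfg, sc)
  lineDir <- cfg[6L, ] - cfg[4L, ]
  lineDir <- lineDir / sqrt(sum(lineDir^2))
  expect_equal(abs(sum(tg2[5L, ] * lineDir)), 1, tolerance = 1e-12)
  ## coincident neighbors are an error
  bad <- circ
  bad[4L, ] <- bad[6L, ]
  expect_error(tangentDirections(bad, sc), "zero-length tangent")
  ## bean outline: tangents within 2 degrees of the analytic tangent
  ## of the radial curve r(phi) = 1 + sum a cos + b sin
  set.seed(13)
  a <- rnorm(4L, 0, 0.1); b <- rnorm(4L, 0, 0.1)
  dense <- denseCurve(20000L, seed = 13L, mag = 0.1)
  out <- resampleEquidistant(dense, 90L)
  tg3 <- tangentDirections(out, pairedScheme(90L))
  phi <- atan2(out[, 2L], out[, 1L])
  r <- rep(1, 90L); rp <- rep(0, 90L)
  for (m in 1:4) {
    r <- r + a[m] * cos(m * phi) + b[m] * sin(m * phi)
    rp <- rp - a[m] * m * sin(m * phi) + b[m] * m * cos(m * phi)
  }
  ref <- cbind(rp * cos(phi) - r * sin(phi),
               rp * sin(phi) + r * cos(phi))
  ref <- ref / sqrt(rowSums(ref^2))
  ang <- acos(pmin(abs(rowSums(tg3 * ref))[-1L], 1)) * 180 / pi
  expect_lt(max(ang), 2)
})

test_that("min-PD sliding projects each point onto its tangent line", {
  k <- 24L
  sc <- pairedScheme(k)
  cons <- baseOutline(k)
  ## configuration equal to the consensus: nothing moves
  arr <- array(cons, dim = c(k, 2L, 1L))
  slid <- morphosym:::slideConfigsMinPD(arr, cons, sc)
  expect_equal(slid$arr[, , 1L], cons, tolerance = 1e-15)
  ## a deviation perpendicular to the tangent does not move the point
  tg <- tangentDirections(cons, sc)
  perp <- cbind(-tg[7L, 2L], tg[7L, 1L])
  cfg <- cons
  cfg[7L, ] <- cfg[7L, ] + 0.05 * as.vector(perp)
  tgc <- tangentDirections(cfg, sc)
  slid2 <- morphosym:::slideConfigsMinPD(array(cfg, dim = c(k, 2L, 1L)),
                                         cons, sc)
  moved <- slid2$arr[7L, , 1L] - cfg[7L, ]
  ## movement happens only along the (slightly rotated) tangent at the
  ## perturbed configuration, never along the perpendicular offset
  expect_lt(abs(sum(moved * perp)) / sqrt(sum(perp^2)),
            abs(sum((cons[7L, ] - cfg[7L, ]) * perp)) * 0.1 + 1e-6)
  ## grid-search oracle, point by point
  set.seed(9)
  cfg2 <- cons + 0.03 * matrix(rnorm(2 * k), k, 2L)
  tg2 <- tangentDirections(cfg2, sc)
  slid3 <- morphosym:::slideConfigsMinPD(array(cfg2, dim = c(k, 2L, 1L)),
                                         cons, sc)
  grid <- seq(-0.2, 0.2, by = 1e-4)
  for (i in c(3L, 12L, 20L)) {
    dists <- vapply(grid, function(t)
      sum((cfg2[i, ] + t * tg2[i, ] - cons[i, ])^2), numeric(1))
    best <- cfg2[i, ] + grid[which.min(dists)] * tg2[i, ]
    expect_lt(sqrt(sum((slid3$arr[i, , 1L] - best)^2)), 1e-4)
  }
})

test_that("bending energy vanishes exactly on affine deformations", {
  ref <- baseOutline(16L)
  kern <- bendingEnergyKernel(ref)
  expect_lt(max(abs(kern@bending %*% cbind(1, ref))), 1e-10)
  expect_equal(bendingEnergy(kern, ref), 0, tolerance = 1e-12)
  A <- matrix(c(1.3, 0.4, -0.2, 0.7), 2L, 2L)
  expect_equal(bendingEnergy(kern, ref %*% A + 2), 0,
               tolerance = 1e-10)
  set.seed(10)
  expect_gt(bendingEnergy(kern, ref + 0.02 * matrix(rnorm(32), 16L, 2L)),
            0)
  expect_error(bendingEnergyKernel(ref[c(1L, 1L, 2:15), ]),
               "singular|duplicate")
})

test_that("bending energy matches an independently assembled TPS form", {
  ## second code path: explicit double-loop assembly and inversion
  set.seed(12)
  ref <- matrix(runif(8), 4L, 2L)
  tgt <- ref + 0.1 * matrix(rnorm(8), 4L, 2L)
  k <- nrow(ref)
  K <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    r <- sqrt(sum((ref[i, ] - ref[j, ])^2))
    K[i, j] <- if (r > 0) r^2 * log(r) else 0
  }
  L <- rbind(cbind(K, 1, ref), cbind(t(cbind(1, ref)),
                                     matrix(0, 3L, 3L)))
  B <- solve(L)[1:k, 1:k]
  oracle <- drop(t(tgt[, 1L]) %*% B %*% tgt[, 1L] +
                 t(tgt[, 2L]) %*% B %*% tgt[, 2L])
  expect_equal(bendingEnergy(bendingEnergyKernel(ref), tgt), oracle,
               tolerance = 1e-10)
})

test_that("min-BE sliding minimizes the bending quadratic along tangents", {
  k <- 24L
  sc <- pairedScheme(k)
  cons <- baseOutline(k)
  kern <- bendingEnergyKernel(cons)
  ## affine relative to the consensus: BE already 0, no displacement
  aff <- cons %*% matrix(c(1.1, 0.15, -0.1, 0.9), 2L, 2L)
  slid <- morphosym:::slideConfigsMinBE(array(aff, dim = c(k, 2L, 1L)),
                                        cons, kern, sc)
  expect_equal(slid$arr[, , 1L], aff, tolerance = 1e-8)
  ## a slide step never increases the total bending energy
  set.seed(14)
  arr <- array(0, dim = c(k, 2L, 3L))
  for (i in 1:3) arr[, , i] <- cons + 0.04 * matrix(rnorm(2 * k), k, 2L)
  before <- sum(apply(arr, 3L, function(m) bendingEnergy(kern, m)))
  slid2 <- morphosym:::slideConfigsMinBE(arr, cons, kern, sc)
  expect_lte(slid2$totalBE, before + 1e-12)
  ## the fixed landmark is bit-identical
  expect_identical(slid2$arr[sc@fixedIndex, , ], arr[sc@fixedIndex, , ])
  ## single free point against a fine grid search: pin all others by
  ## comparing the joint solution on a configuration deviating at one
  ## point only
  cfg <- cons
  cfg[9L, ] <- cfg[9L, ] + c(0.03, -0.02)
  tg <- tangentDirections(cfg, sc)
  slid3 <- morphosym:::slideConfigsMinBE(array(cfg, dim = c(k, 2L, 1L)),
                                         cons, kern, sc)
  ## grid oracle over the displacement of point 9 with the others at
  ## their jointly-slid optimum
  opt <- slid3$arr[, , 1L]
  grid <- seq(-0.05, 0.05, by = 1e-4)
  be <- vapply(grid, function(t) {
    m <- opt
    m[9L, ] <- cfg[9L, ] + t * tg[9L, ]
    bendingEnergy(kern, m)
  }, numeric(1))
  tstar <- sum((opt[9L, ] - cfg[9L, ]) * tg[9L, ])
  expect_lt(abs(grid[which.min(be)] - tstar), 1.5e-4)
})

test_that("sliding a dataset of exactly symmetric shapes preserves symmetry", {
  spec <- smallSpec(seed = 21L, daMagnitude = 0, faSd = 0, meSd = 0)
  gen <- generateOutlines(spec)
  al <- gpa(gen$outlines, "unslid")
  albe <- slideMinBE(al, nIter = 2L)
  sc <- outlineScheme(gen$outlines)
  for (i in c(1L, 10L, 25L)) {
    cfg <- landmarkCoords(albe)[, , i]
    expect_lt(attr(alignPair(reflectRelabel(cfg, sc), cfg),
                   "residual"), 1e-10)
  }
})

test_that("treatment comparison ANOVA isolates the sliding effect", {
  al <- fixAligned
  ## dataset against itself: treatment MS ~ 0
  self <- treatmentEffectAnova(al, al)
  expect_lt(anovaTable(self)$MS[2L], 1e-20)
  expect_equal(sum(anovaTable(self)$R2), 1, tolerance = 1e-9)
  ## known injected offset: SS matches the closed-form prediction and
  ## grows with the square of the offset
  k <- 24L
  cons <- consensusShape(al)
  sc <- outlineScheme(fixGen$outlines)
  set.seed(15)
  n <- nConfigs(al)
  noise <- 2e-4
  mkAligned <- function(delta) {
    arr <- array(0, dim = c(k, 2L, n))
    for (i in seq_len(n))
      arr[, , i] <- cons + delta + noise * matrix(rnorm(2 * k), k, 2L)
    gpa(OutlineSet(arr, outlineInfo(fixGen$outlines), sc,
                   checkCurve = FALSE), "unslid")
  }
  delta <- morphosym:::orthogonalizeField(
    morphosym:::fieldBasis(k, 2L, "symmetric")[[2L]],
    morphosym:::similarityBasis(cons)) * 0.01
  set.seed(16); dsA <- mkAligned(delta * 0)
  set.seed(16); dsB <- mkAligned(delta)
  set.seed(16); dsC <- mkAligned(delta * 2)
  ## label the offset datasets as a different treatment
  dsB <- initialize(dsB, treatment = "min_be")
  dsC <- initialize(dsC, treatment = "min_be")
  S <- n / 2                       # segments (2 replicates each)
  anB <- treatmentEffectAnova(dsA, dsB)
  anC <- treatmentEffectAnova(dsA, dsC)
  predB <- S * sum(delta^2)        # cells deviate by +/- delta/2
  expect_equal(anovaTable(anB)$SS[2L], predB, tolerance = 0.05)
  expect_equal(anovaTable(anC)$SS[2L] / anovaTable(anB)$SS[2L], 4,
               tolerance = 0.05)
  expect_gt(anC@notes$msRatio, anB@notes$msRatio)
  ## mismatched segment sets are rejected
  half <- fixGen$outlines
  halfSet <- OutlineSet(landmarkCoords(half)[, , 1:10],
                        outlineInfo(half)[1:10, ], sc,
                        checkCurve = FALSE)
  expect_error(treatmentEffectAnova(al, gpa(halfSet, "unslid")),
               "same digitized segments")
})
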