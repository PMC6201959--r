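test_that("reflection/relabeling mirrors coordinates and bookkeeping", {
  sc <- pairedScheme(24L)
  base <- baseOutline(24L)
  ## an exactly symmetric shape maps to itself
  expect_equal(reflectRelabel(base, sc), base, tolerance = 1e-14)
  ## involution on an arbitrary configuration
  set.seed(17)
  cfg <- base + 0.05 * matrix(rnorm(48), 24L, 2L)
  expect_equal(reflectRelabel(reflectRelabel(cfg, sc), sc), cfg,
               tolerance = 1e-14)
  ## a bump on one side lands on the paired index, mirrored in x
  bump <- base
  iRight <- sc@pairing[5L, "right"]
  iLeft <- sc@pairing[5L, "left"]
  bump[iRight, ] <- bump[iRight, ] + c(0.2, 0.1)
  refl <- reflectRelabel(bump, sc)
  expect_equal(refl[iLeft, ],
               c(-bump[iRight, 1L], bump[iRight, 2L]))
  ## on-axis points keep their labels (x negated only)
  expect_equal(refl[sc@axisIndices, 2L], bump[sc@axisIndices, 2L])
  ## OutlineSet method toggles the reflected flag
  os <- reflectRelabel(fixGen$outlines)
  expect_true(all(outlineInfo(os)$reflected))
})

test_that("an exactly symmetric dataset has no asymmetric variation", {
  spec <- smallSpec(seed = 23L, daMagnitude = 0, faSd = 0, meSd = 0)
  gen <- generateOutlines(spec)
  dec <- buildSymmetryDecomposition(gen$outlines, treatment = "unslid")
  nz <- dec@varFraction > 1e-12
  expect_true(all(dec@axisClass[nz] == "symmetric"))
  expect_lt(max(totalAsymmetry(dec)), 1e-8)
  expect_lt(max(totalAsymmetry(dec, "abssum")), 1e-7)
})

test_that("PC axes classify by score mirroring and partition the variance", {
  dec <- fixDecomp
  expect_equal(sum(dec@varFraction), 1, tolerance = 1e-12)
  o <- dec@originalIdx; r <- dec@reflectedIdx
  for (j in seq_along(dec@eigenvalues)[1:10]) {
    cc <- cor(dec@scores[o, j], dec@scores[r, j])
    if (dec@axisClass[j] == "symmetric") expect_gt(cc, 0.99)
    else expect_lt(cc, -0.99)
  }
  ## symmetric + asymmetric axis variance = total variance (exact)
  V <- shapeMatrix(dec@alignment, tangent = TRUE)
  totVar <- sum(scale(V, scale = FALSE)^2)
  expect_equal(sum(dec@eigenvalues) * (nrow(V) - 1), totVar,
               tolerance = 1e-8)
})

test_that("asymmetric axes capture exactly the injected asymmetric share", {
  ## without digitization noise the symmetric/asymmetric split is
  ## exact, so axis classes must recover the generator's bookkeeping
  spec <- smallSpec(seed = 29L, meSd = 0)
  gen <- generateOutlines(spec)
  dec <- buildSymmetryDecomposition(gen$outlines, treatment = "unslid")
  V <- shapeMatrix(dec@alignment, tangent = TRUE)
  A <- (V[dec@originalIdx, ] - V[dec@reflectedIdx, ]) / 2
  asymShare <- 2 * sum(A^2) / sum(scale(V, scale = FALSE)^2)
  pcaShare <- sum(dec@varFraction[dec@axisClass == "asymmetric"])
  expect_equal(pcaShare, asymShare, tolerance = 1e-6)
  expect_gt(pcaShare, 0.01)
})

test_that("symmetric and asymmetric components reconstruct each object", {
  comp <- symmetryComponents(fixDecomp)
  V <- shapeMatrix(fixDecomp@alignment)
  expect_equal(comp$symmetric + comp$asymmetric,
               V[fixDecomp@originalIdx, ], tolerance = 1e-12)
  ## squared asymmetric norm = squared original-reflected distance / 4
  d2 <- rowSums((V[fixDecomp@originalIdx, ] -
                 V[fixDecomp@reflectedIdx, ])^2)
  expect_equal(rowSums(comp$asymmetric^2), d2 / 4, tolerance = 1e-12)
})

test_that("total asymmetry matches an independent PCA code path", {
  dec <- fixDecomp
  ## independent path: eigen() of the covariance of the tangent
  ## coordinates, classification by score sign-flip, Euclidean norm
  V <- shapeMatrix(dec@alignment, tangent = TRUE)
  Vc <- scale(V, scale = FALSE)
  ee <- eigen(crossprod(Vc) / (nrow(Vc) - 1), symmetric = TRUE)
  keep <- which(ee$values > ee$values[1L] * 1e-12)
  sc2 <- Vc %*% ee$vectors[, keep, drop = FALSE]
  o <- dec@originalIdx; r <- dec@reflectedIdx
  isAsym <- vapply(seq_along(keep), function(j)
    cor(sc2[o, j], sc2[r, j]) < 0, logical(1))
  oracle <- sqrt(rowSums(sc2[o, isAsym, drop = FALSE]^2))
  expect_equal(totalAsymmetry(dec), oracle, tolerance = 1e-8)
  ## invariant under the original/reflected choice
  oracleRefl <- sqrt(rowSums(sc2[r, isAsym, drop = FALSE]^2))
  expect_equal(totalAsymmetry(dec), oracleRefl, tolerance = 1e-6)
  ## both statistics, and their equivalence rank-wise
  expect_equal(length(totalAsymmetry(dec, "abssum")), length(o))
  expect_gte(min(totalAsymmetry(dec, "abssum") - totalAsymmetry(dec)),
             -1e-12)
})

test_that("mean total asymmetry grows with injected DA and FA", {
  daLv <- c(0, 0.1, 0.3)
  faLv <- c(0.01, 0.05, 0.15)
  cellMean <- function(da, fa) {
    mean(vapply(61:63, function(s) {
      spec <- SyntheticSpec(nLocalities = 1L, plantsPerLocality = 8L,
                            segmentCounts = list(rep(8L, 8L)),
                            nPoints = 20L, medianSizes = 1,
                            daMagnitude = da, faSd = fa, meSd = 5e-4,
                            seed = s)
      dec <- buildSymmetryDecomposition(
        generateOutlines(spec)$outlines, treatment = "unslid")
      mean(totalAsymmetry(dec))
    }, numeric(1)))
  }
  means <- sapply(faLv, function(fa)
    vapply(daLv, cellMean, numeric(1), fa = fa))
  ## monotone in DA down each column and in FA along each row
  for (j in 1:3) expect_true(all(diff(means[, j]) > 0))
  for (i in 1:3) expect_true(all(diff(means[i, ]) > 0))
})
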