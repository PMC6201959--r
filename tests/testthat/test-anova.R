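test_that("the nested shape model matches a sequential lm oracle", {
  set.seed(40)
  design <- fourInstanceDesign(2L, 2L, 3L)
  n <- nrow(design)
  V <- matrix(rnorm(n * 5L), n, 5L)
  key <- paste(design$locality, design$plant, design$segment,
               design$replicate)
  usz <- runif(length(unique(key)), 1, 2)
  names(usz) <- unique(key)
  sz <- unname(usz[key])
  ## raw model
  an <- nestedProcrustesAnova(V, design, nPerm = 0L)
  expect_equal(anovaTable(an)$SS, unname(lmTypeIOracle(V, design)),
               tolerance = 1e-10)
  ## size-adjusted model (covariate varies between replicates)
  anA <- nestedProcrustesAnova(V, design, sizes = sz, nPerm = 0L,
                               adjustSize = TRUE)
  expect_equal(anovaTable(anA)$SS,
               unname(lmTypeIOracle(V, design, sz)),
               tolerance = 1e-10)
  ## df bookkeeping and exact additivity
  expect_equal(sum(anovaTable(an)$df), n - 1L)
  expect_equal(sum(anovaTable(anA)$df), n - 1L)
  expect_equal(sum(anovaTable(an)$R2), 1, tolerance = 1e-10)
  expect_equal(anovaTable(an)$MS,
               anovaTable(an)$SS / anovaTable(an)$df,
               tolerance = 1e-12)
})

test_that("asymmetric rows are invariant under size adjustment", {
  an <- suppressWarnings(nestedProcrustesAnova(fixDecomp, nPerm = 0L))
  anA <- suppressWarnings(nestedProcrustesAnova(fixDecomp, nPerm = 0L,
                                                adjustSize = TRUE))
  raw <- anovaTable(an); adj <- anovaTable(anA)
  for (e in c("side (plant)", "segment x side (plant)")) {
    i <- match(e, raw$effect); j <- match(e, adj$effect)
    expect_equal(adj$SS[j], raw$SS[i],
                 tolerance = 1e-8 * max(raw$SS[i], 1e-12))
  }
})

test_that("hand-computed sums of squares agree on a 12-observation design", {
  ## one plant, three segments, four instances each: small enough to
  ## verify every row from group means written out by hand
  set.seed(41)
  design <- fourInstanceDesign(1L, 1L, 3L)
  y <- rnorm(12L)
  an <- nestedProcrustesAnova(matrix(y, ncol = 1L), design, nPerm = 0L)
  tab <- anovaTable(an)
  g <- mean(y)
  segs <- split(seq_len(12L), design$segment)
  mSeg <- vapply(segs, function(i) mean(y[i]), numeric(1))
  ssSeg <- sum(4 * (mSeg - g)^2)
  mSide <- vapply(split(seq_len(12L), design$side),
                  function(i) mean(y[i]), numeric(1))
  ssSide <- sum(6 * (mSide - g)^2)
  cells <- split(seq_len(12L), paste(design$segment, design$side))
  mCell <- vapply(cells, function(i) mean(y[i]), numeric(1))
  segOfCell <- vapply(strsplit(names(cells), " "), `[`, "", 1L)
  sideOfCell <- vapply(strsplit(names(cells), " "), `[`, "", 2L)
  ssFA <- sum(2 * (mCell - mSeg[segOfCell] - mSide[sideOfCell] + g)^2)
  ssErr <- sum((y - mCell[paste(design$segment, design$side)])^2)
  expect_equal(tab$SS[match("segment (plant)", tab$effect)], ssSeg,
               tolerance = 1e-12)
  expect_equal(tab$SS[match("side (plant)", tab$effect)], ssSide,
               tolerance = 1e-12)
  expect_equal(tab$SS[match("segment x side (plant)", tab$effect)],
               ssFA, tolerance = 1e-12)
  expect_equal(tab$SS[match("measurement error", tab$effect)], ssErr,
               tolerance = 1e-12)
  ## single locality and plant: those rows carry no df
  expect_equal(tab$df[match("locality", tab$effect)], 0L)
  expect_equal(tab$df[match("plant (locality)", tab$effect)], 0L)
})

test_that("the univariate model reduces to a textbook one-way ANOVA", {
  set.seed(42)
  G <- 5L
  design <- expand.grid(replicate = 1:2,
                        segment = paste0("s", seq_len(G)),
                        plant = "p1", locality = "L1",
                        stringsAsFactors = FALSE)
  y <- rnorm(nrow(design), rep(seq_len(G), each = 2L))
  ta <- totalAsymmetryAnova(y, design, nPerm = 0L)
  a <- anova(lm(y ~ factor(design$segment)))
  tab <- anovaTable(ta)
  i <- match("segment (plant)", tab$effect)
  expect_equal(tab$SS[i], a[["Sum Sq"]][1L], tolerance = 1e-12)
  expect_equal(tab$F[i], a$F[1L], tolerance = 1e-12)
  expect_equal(tab$SS[match("measurement error", tab$effect)],
               a[["Sum Sq"]][2L], tolerance = 1e-12)
})

test_that("degenerate designs are flagged instead of failing silently", {
  design <- fourInstanceDesign(2L, 2L, 2L)
  ## constant response: all SS zero, F undefined and flagged
  ta <- totalAsymmetryAnova(rep(1, 16L),
                            design[design$side == "original", ],
                            nPerm = 0L)
  expect_true(all(anovaTable(ta)$SS == 0))
  expect_true(all(is.na(anovaTable(ta)$F)))
  expect_identical(ta@notes$degenerate, "constant response")
  ## unbalanced side structure is a design error
  V <- matrix(rnorm(31 * 2), 31L, 2L)
  expect_error(nestedProcrustesAnova(V, design[-1L, ], nPerm = 0L),
               "unbalanced")
  expect_warning(nestedProcrustesAnova(matrix(rnorm(64), 32L, 2L),
                                       design, nPerm = 9L, seed = 1L),
                 "coarse")
})

test_that("per-plant decompositions agree with the whole-model restriction", {
  pp <- perPlantDecomposition(fixDecomp)
  expect_equal(nrow(pp), 6L)
  ## restriction consistency: rerun the nested model on one plant only
  info <- fixDecomp@alignment@info
  target <- pp[3L, ]
  rows <- which(info$locality == target$locality &
                info$plant == target$plant)
  V <- shapeMatrix(fixDecomp@alignment, tangent = TRUE)
  an1 <- nestedProcrustesAnova(V[rows, ], info[rows, ], nPerm = 0L)
  tab <- anovaTable(an1)
  expect_equal(target$symmetricMS,
               tab$MS[match("segment (plant)", tab$effect)],
               tolerance = 1e-10)
  expect_equal(target$daMS, tab$MS[match("side (plant)", tab$effect)],
               tolerance = 1e-10)
  expect_equal(target$faMS,
               tab$MS[match("segment x side (plant)", tab$effect)],
               tolerance = 1e-10)
  ## a plant of identical, exactly symmetric segments has zero MS
  base <- baseOutline(16L)
  n <- 12L
  arr <- array(rep(base, n), dim = c(16L, 2L, n))
  design <- fourInstanceDesign(1L, 1L, 3L)
  Vs <- t(apply(arr, 3L, as.vector))
  pp0 <- perPlantDecomposition(Vs, design)
  expect_lt(max(pp0$symmetricMS, pp0$daMS, pp0$faMS), 1e-20)
  ## too few segments: skipped with a warning
  expect_warning(perPlantDecomposition(Vs, design, minSegments = 4L),
                 "skipped")
})

test_that("bootstrap median differences match exhaustive enumeration", {
  a <- c(1.0, 1.5, 2.0, 4.0, 6.0)
  b <- c(0.2, 0.4, 0.5, 0.8, 1.1)
  bs <- bootstrapMedianDifference(a, b, nBoot = 20000L, seed = 5L)
  ## exhaustive oracle: all 5^5 ordered resamples per group
  tuples <- as.matrix(expand.grid(rep(list(1:5), 5L)))
  medA <- apply(matrix(a[tuples], nrow(tuples)), 1L, median)
  medB <- apply(matrix(b[tuples], nrow(tuples)), 1L, median)
  allDiff <- as.vector(outer(medA, medB, `-`))
  ciEx <- quantile(allDiff, c(0.025, 0.975), type = 7)
  expect_lt(max(abs(bs@ci - ciEx)), 0.02 * diff(range(allDiff)))
  expect_equal(bs@medianA - bs@medianB, median(a) - median(b))
  ## identical groups: interval straddles zero, p large
  set.seed(6)
  x <- rnorm(20)
  bs2 <- bootstrapMedianDifference(x, x, nBoot = 999L, seed = 7L)
  expect_lte(bs2@ci[1L], 0)
  expect_gte(bs2@ci[2L], 0)
  expect_gt(bs2@pValue, 0.2)
  ## pure shift with zero within-group variance
  bs3 <- bootstrapMedianDifference(rep(3, 6), rep(1, 6),
                                   nBoot = 499L, seed = 8L)
  expect_equal(unname(bs3@ci), c(2, 2))
  expect_equal(bs3@pValue, 1 / 499)
  expect_error(bootstrapMedianDifference(1:3, 1:6), "at least 5")
})

test_that("MS correlations follow the Pearson definition", {
  set.seed(43)
  pp <- data.frame(symmetricMS = runif(5), daMS = runif(5),
                   faMS = runif(5))
  M <- msCorrelations(pp)
  ## hand-computed Pearson formula
  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(M["symmetricMS", "daMS"],
               pearson(pp$symmetricMS, pp$daMS), tolerance = 1e-12)
  ## duplicated column correlates perfectly
  pp2 <- pp; pp2$faMS <- pp2$daMS
  expect_equal(msCorrelations(pp2)["daMS", "faMS"], 1)
  ## independent columns at n = 96 stay near zero
  pp3 <- data.frame(symmetricMS = rnorm(96), daMS = rnorm(96),
                    faMS = rnorm(96))
  M3 <- msCorrelations(pp3)
  expect_lt(max(abs(M3[upper.tri(M3)])), 0.3)
  pp4 <- pp; pp4$daMS <- 1
  expect_warning(msCorrelations(pp4), "constant")
})

test_that("size-asymmetry correlation reports r and variance share", {
  x <- seq_len(20)
  y <- 5 - 2 * x
  cc <- sizeAsymmetryCorrelation(x, y)
  expect_equal(cc$r, -1)
  expect_equal(cc$pctVariance, 100)
  set.seed(44)
  a <- rnorm(30); b <- rnorm(30)
  cc2 <- sizeAsymmetryCorrelation(a, b)
  expect_equal(cc2$pctVariance, 100 * cc2$r^2, tolerance = 1e-12)
  expect_error(sizeAsymmetryCorrelation(rep(1, 10), rnorm(10)),
               "constant")
})
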