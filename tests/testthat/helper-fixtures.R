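## Shared small fixtures, built once per test run. All data are
## generated in code; nothing is read from disk.

rotMat <- function(a) rbind(c(cos(a), sin(a)), c(-sin(a), cos(a)))

## Small hierarchical dataset: 2 localities x 3 plants, 24-point
## outlines, ~26 segments, 52 digitized records.
smallSpec <- function(seed = 3L, ...) {
  SyntheticSpec(nLocalities = 2L, plantsPerLocality = 3L,
                segmentCounts = list(c(4L, 5L, 4L), c(5L, 4L, 4L)),
                nPoints = 24L, seed = seed, ...)
}

fixGen <- generateOutlines(smallSpec())
fixAligned <- gpa(fixGen$outlines, "unslid")
fixDecomp <- buildSymmetryDecomposition(fixGen$outlines,
                                        treatment = "unslid")

## A smooth random closed curve (radial Fourier) sampled densely;
## deterministic given the seed.
denseCurve <- function(nDense = 5000L, seed = 11L, nHarm = 4L,
                       mag = 0.08) {
  set.seed(seed)
  a <- rnorm(nHarm, 0, mag)
  b <- rnorm(nHarm, 0, mag)
  phi <- 2 * pi * (seq_len(nDense) - 1L) / nDense
  r <- rep(1, nDense)
  for (m in seq_len(nHarm))
    r <- r + a[m] * cos(m * phi) + b[m] * sin(m * phi)
  cbind(r * cos(phi), r * sin(phi))
}

## Arc-length position of each query point along a dense closed
## polyline (projection onto the nearest segment).
arcPositions <- function(query, dense) {
  seg <- rbind(dense[-1L, ] , dense[1L, ]) - dense
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  apply(query, 1L, function(q) {
    dx <- q[1L] - dense[, 1L]; dy <- q[2L] - dense[, 2L]
    t <- pmin(pmax((dx * seg[, 1L] + dy * seg[, 2L]) / len^2, 0), 1)
    px <- dense[, 1L] + t * seg[, 1L]
    py <- dense[, 2L] + t * seg[, 2L]
    i <- which.min((q[1L] - px)^2 + (q[2L] - py)^2)
    cum[i] + t[i] * len[i]
  })
}

## Balanced four-instance design data.frame for direct engine tests.
fourInstanceDesign <- function(nLoc, nPlant, nSeg) {
  expand.grid(replicate = 1:2, side = c("original", "reflected"),
              segment = paste0("s", seq_len(nSeg)),
              plant = paste0("p", seq_len(nPlant)),
              locality = LETTERS[seq_len(nLoc)],
              stringsAsFactors = FALSE)
}

## Independent sequential-SS oracle: per-coordinate stats::anova over
## the nested factor chain, summed across coordinates. Single-level
## factors (absent design levels) are dropped; the result is named.
lmTypeIOracle <- function(V, design, sizes = NULL) {
  fl <- list(
    locality = factor(design$locality),
    plant = factor(paste(design$locality, design$plant)),
    segment = factor(paste(design$locality, design$plant,
                           design$segment)),
    side = factor(paste(design$locality, design$plant, design$side)),
    fa = factor(paste(design$locality, design$plant, design$segment,
                      design$side)))
  fl <- fl[vapply(fl, nlevels, 1L) > 1L]
  df <- as.data.frame(fl)
  if (!is.null(sizes)) df <- cbind(size = sizes, df)
  ss <- numeric(ncol(df) + 1L)
  for (j in seq_len(ncol(V))) {
    dat <- cbind(data.frame(y = V[, j]), df)
    ss <- ss + anova(lm(y ~ ., data = dat))[["Sum Sq"]]
  }
  names(ss) <- c(colnames(df), "error")
  ss
}
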