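## File formats. Two plain-text interchange formats are supported: the
## TPS landmark format (LM=, coordinate rows, ID=, optional SCALE=) and
## a bare x/y coordinate table with one point per row, records separated
## either by blank lines or implicitly by a fixed point count (both
## dialects auto-detected). Coordinates are treated as dimensionless.

parseNumericPair <- function(line, lineNo) {
  toks <- strsplit(trimws(line), "[ \t,]+")[[1L]]
  vals <- suppressWarnings(as.numeric(toks))
  if (length(vals) < 2L || any(is.na(vals[1:2])))
    stop("parse error at line ", lineNo, ": expected two numbers, got '",
         line, "'")
  vals[1:2]
}

#' Read a plain-text coordinate table with sidecar metadata
#'
#' Accepts both common dialects of the one-point-per-row x/y table:
#' records separated by blank lines, or a continuous block of rows cut
#' into records of the scheme's point count. Metadata comes from a
#' sidecar table (a data.frame or CSV path) with columns
#' \code{config_index}, \code{locality}, \code{plant}, \code{segment},
#' \code{replicate}, because the coordinate file itself stores no
#' identities.
#'
#' @param path coordinate file.
#' @param metadata sidecar data.frame or CSV path; \code{NULL} gives
#'   default metadata.
#' @param scheme a \code{\linkS4class{LandmarkScheme}}; defaults to the
#'   90-point study scheme when the data fit it, otherwise to the paired
#'   scheme of the detected point count.
#' @return An \code{\linkS4class{OutlineSet}}, configurations in file
#'   order.
#' @export
readCoordinateTable <- function(path, metadata = NULL, scheme = NULL) {
  lines <- readLines(path)
  blank <- grepl("^[ \t]*$", lines)
  nonBlank <- which(!blank)
  if (length(nonBlank) == 0L) stop("empty coordinate file")
  pts <- t(vapply(nonBlank, function(i) parseNumericPair(lines[i], i),
                  numeric(2L)))
  if (any(blank[seq(min(nonBlank), max(nonBlank))])) {
    ## blank-line dialect: group consecutive non-blank runs
    runId <- cumsum(c(1L, diff(nonBlank) > 1L))
    ks <- table(runId)
    if (length(unique(ks)) != 1L)
      stop("records differ in point count: ",
           paste(unique(ks), collapse = ", "))
    k <- as.integer(ks[1L])
  } else {
    k <- if (!is.null(scheme)) scheme@nPoints
         else if (nrow(pts) %% 90L == 0L) 90L
         else stop("cannot infer the point count: supply a scheme or ",
                   "use blank-line separated records")
    if (nrow(pts) %% k != 0L)
      stop("total of ", nrow(pts), " rows is not a multiple of the ",
           k, "-point scheme")
  }
  n <- nrow(pts) %/% k
  if (is.null(scheme)) scheme <- pairedScheme(k)
  if (k != scheme@nPoints)
    stop("file has ", k, "-point records but the scheme expects ",
         scheme@nPoints)
  coords <- array(0, dim = c(k, 2L, n))
  for (i in seq_len(n))
    coords[, , i] <- pts[((i - 1L) * k + 1L):(i * k), , drop = FALSE]
  if (is.character(metadata))
    metadata <- utils::read.csv(metadata, stringsAsFactors = FALSE)
  info <- NULL
  if (!is.null(metadata)) {
    need <- c("config_index", "locality", "plant", "segment",
              "replicate")
    if (!all(need %in% names(metadata)))
      stop("metadata needs columns ", paste(need, collapse = ", "))
    if (!setequal(metadata$config_index, seq_len(n)))
      stop("metadata must cover configuration indices 1..", n)
    metadata <- metadata[order(metadata$config_index), , drop = FALSE]
    info <- data.frame(locality = as.character(metadata$locality),
                       plant = as.character(metadata$plant),
                       segment = as.character(metadata$segment),
                       replicate = as.integer(metadata$replicate),
                       reflected = FALSE, stringsAsFactors = FALSE)
  }
  OutlineSet(coords, info = info, scheme = scheme, checkCurve = FALSE)
}

#' @rdname readCoordinateTable
#' @param x an \code{\linkS4class{OutlineSet}} or \code{k x 2 x n}
#'   array.
#' @param blankSeparated write blank lines between records (the
#'   alternative is the count-based dialect).
#' @param digits significant digits written.
#' @export
writeCoordinateTable <- function(x, path, blankSeparated = TRUE,
                                 digits = 8L) {
  arr <- if (is(x, "OutlineSet")) x@coords else x
  con <- file(path, "w")
  on.exit(close(con))
  n <- dim(arr)[3]
  for (i in seq_len(n)) {
    xy <- format(arr[, , i], digits = digits, trim = TRUE,
                 scientific = FALSE)
    writeLines(paste(xy[, 1L], xy[, 2L]), con)
    if (blankSeparated && i < n) writeLines("", con)
  }
  invisible(path)
}

#' Read and write TPS landmark files
#'
#' Standard TPS records: an \code{LM=} line with the point count,
#' coordinate rows, and an optional \code{ID=} line. \code{SCALE=} lines
#' are ignored with a warning (coordinates are treated as
#' dimensionless); records without an \code{ID=} get a synthesized
#' sequential identifier \code{config_<i>} in file order.
#'
#' @param path TPS file.
#' @return \code{readTps}: a list with \code{coords} (a
#'   \code{k x 2 x n} array) and \code{ids} (character). Wrap with
#'   \code{\link{OutlineSet}} to attach a scheme and metadata.
#' @export
readTps <- function(path) {
  lines <- readLines(path)
  recs <- list()
  ids <- character()
  i <- 1L
  nLines <- length(lines)
  scaleWarned <- FALSE
  while (i <= nLines) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    if (!grepl("^LM\\s*=", ln, ignore.case = TRUE))
      stop("parse error at line ", i, ": expected 'LM=' record header")
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", ln,
                                         ignore.case = TRUE)))
    if (is.na(k) || k < 1L)
      stop("parse error at line ", i, ": bad LM= count")
    if (i + k > nLines)
      stop("record at line ", i, " declares LM=", k,
           " but the file ends early")
    xy <- matrix(0, k, 2L)
    for (j in seq_len(k))
      xy[j, ] <- parseNumericPair(lines[i + j], i + j)
    i <- i + k + 1L
    id <- NA_character_
    while (i <= nLines) {
      ln <- trimws(lines[i])
      if (grepl("^ID\\s*=", ln, ignore.case = TRUE)) {
        id <- sub("^ID\\s*=\\s*", "", ln, ignore.case = TRUE)
      } else if (grepl("^SCALE\\s*=", ln, ignore.case = TRUE)) {
        if (!scaleWarned) {
          warning("SCALE= lines ignored: coordinates are dimensionless")
          scaleWarned <- TRUE
        }
      } else if (grepl("^IMAGE\\s*=", ln, ignore.case = TRUE) ||
                 ln == "") {
        ## tolerated, carries no information used here
      } else break
      i <- i + 1L
    }
    recs[[length(recs) + 1L]] <- xy
    ids <- c(ids, id)
  }
  ks <- vapply(recs, nrow, 1L)
  if (length(unique(ks)) != 1L)
    stop("TPS records differ in point count: ",
         paste(unique(ks), collapse = ", "))
  ids[is.na(ids)] <- sprintf("config_%d", which(is.na(ids)))
  list(coords = array(unlist(recs), dim = c(ks[1L], 2L, length(recs))),
       ids = ids)
}

#' @rdname readTps
#' @param x an \code{\linkS4class{OutlineSet}} or \code{k x 2 x n}
#'   array.
#' @param ids record identifiers; defaults to the segment metadata or
#'   sequential ids.
#' @param digits significant digits written.
#' @export
writeTps <- function(x, path, ids = NULL, digits = 8L) {
  arr <- if (is(x, "OutlineSet")) x@coords else x
  n <- dim(arr)[3]
  if (is.null(ids)) {
    ids <- if (is(x, "OutlineSet"))
      paste(x@info$segment, x@info$replicate, sep = "_")
    else sprintf("config_%d", seq_len(n))
  }
  con <- file(path, "w")
  on.exit(close(con))
  k <- dim(arr)[1]
  for (i in seq_len(n)) {
    writeLines(paste0("LM=", k), con)
    xy <- format(arr[, , i], digits = digits, trim = TRUE,
                 scientific = FALSE)
    writeLines(paste(xy[, 1L], xy[, 2L]), con)
    writeLines(paste0("ID=", ids[i]), con)
  }
  invisible(path)
}

#' Reverse a configuration's traversal direction about the fixed
#' landmark
#'
#' A second digitization registered in the opposite direction (clockwise
#' instead of counterclockwise) is relabeled so the fixed landmark keeps
#' its index and the remaining indices advance in the convention
#' direction: index \eqn{j} maps to the reflection of \eqn{j} about the
#' fixed index around the closed outline. Applying the operation twice
#' restores the original ordering.
#'
#' @param config \code{k x 2} coordinate matrix.
#' @param scheme a \code{\linkS4class{LandmarkScheme}}.
#' @return The relabeled \code{k x 2} matrix.
#' @export
reverseRelabelReplicate <- function(config, scheme) {
  k <- nrow(config)
  if (k != scheme@nPoints)
    stop("configuration does not match the scheme point count")
  f <- scheme@fixedIndex
  ord <- ((2L * (f - 1L) - (seq_len(k) - 1L)) %% k) + 1L
  config[ord, , drop = FALSE]
}

#' Write an ANOVA table as CSV
#'
#' Columns \code{effect}, \code{df}, \code{SS}, \code{MS}, \code{F},
#' \code{p}, \code{R2}, one row per effect.
#'
#' @param x an \code{\linkS4class{AnovaTable}} (or compatible
#'   data.frame).
#' @param path output file.
#' @export
writeAnovaTable <- function(x, path) {
  tab <- if (is(x, "AnovaTable")) x@table else x
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
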