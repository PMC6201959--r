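## One-command analysis driver: read (or generate) outlines, superimpose
## under the requested semilandmark treatments, decompose symmetry, fit
## allometry, run the nested models and the population comparisons, and
## write every table plus a manifest. The pipeline is a pure function of
## (inputs, config): rerunning with the same config reproduces every
## stochastic output.

#' Read and validate a pipeline configuration
#'
#' The YAML file (or an equivalent list) understands:
#' \describe{
#'   \item{coordinates, metadata}{input coordinate table/TPS file and
#'     sidecar metadata CSV; alternatively \code{synthetic: study_like}
#'     or \code{synthetic: small} generates data instead.}
#'   \item{treatments}{subset of \code{unslid}, \code{min_be},
#'     \code{min_pd}; min-PD runs superimposition diagnostics only
#'     unless \code{include_min_pd: true} (its distortions make it
#'     unsuitable for subtle asymmetry signal).}
#'   \item{n_perm, n_boot}{permutation/bootstrap counts (>= 99).}
#'   \item{seed}{master seed, mandatory.}
#'   \item{output_dir}{where tables and the manifest are written.}
#' }
#'
#' @param path YAML file path, or a list with the same fields.
#' @return A validated config list with defaults filled in.
#' @export
readPipelineConfig <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set a seed")
  cfg$treatments <- if (is.null(cfg$treatments))
    c("unslid", "min_be") else unlist(cfg$treatments)
  bad <- setdiff(cfg$treatments, c("unslid", "min_be", "min_pd"))
  if (length(bad)) stop("unknown treatment(s): ",
                        paste(bad, collapse = ", "))
  if (is.null(cfg$n_perm)) cfg$n_perm <- 999L
  if (is.null(cfg$n_boot)) cfg$n_boot <- 999L
  if (cfg$n_perm < 99L || cfg$n_boot < 99L)
    stop("n_perm and n_boot must be at least 99")
  if (is.null(cfg$include_min_pd)) cfg$include_min_pd <- FALSE
  if (is.null(cfg$output_dir)) cfg$output_dir <- "morphosym_out"
  if (is.null(cfg$synthetic) && is.null(cfg$coordinates))
    stop("config needs either 'coordinates' (+ 'metadata') or ",
         "'synthetic'")
  if (!is.null(cfg$coordinates) && !file.exists(cfg$coordinates))
    stop("coordinate file not found: ", cfg$coordinates)
  if (!is.null(cfg$metadata) && is.character(cfg$metadata) &&
      !file.exists(cfg$metadata))
    stop("metadata file not found: ", cfg$metadata)
  cfg
}

stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full symmetry/asymmetry analysis pipeline
#'
#' Chains every stage for each configured treatment: generalized
#' Procrustes superimposition with diagnostics, joint symmetry
#' decomposition, allometric regression, the multivariate nested
#' Procrustes ANOVA (raw and size-adjusted), the univariate
#' total-asymmetry ANOVA (raw and size-adjusted), per-plant
#' decompositions with bootstrap locality comparisons, and MS
#' correlations. All tables are written as CSV under the configured
#' output directory together with a JSON manifest of seeds, counts and
#' input hashes.
#'
#' @param config a config list or YAML path (see
#'   \code{\link{readPipelineConfig}}).
#' @return Invisibly, a nested list with every result object, keyed by
#'   treatment.
#' @export
runPipeline <- function(config) {
  cfg <- readPipelineConfig(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  inputHash <- NULL
  if (!is.null(cfg$synthetic)) {
    message("stage input: generating synthetic data (", cfg$synthetic,
            ")")
    spec <- stageTry("input", switch(as.character(cfg$synthetic),
      study_like = , "study-like" = studyLikeSpec(seed = seed),
      small = SyntheticSpec(seed = seed),
      stop("unknown synthetic preset '", cfg$synthetic, "'")))
    gen <- stageTry("input", generateOutlines(spec))
    outlines <- gen$outlines
  } else {
    message("stage input: reading ", cfg$coordinates)
    outlines <- stageTry("input",
      readCoordinateTable(cfg$coordinates, metadata = cfg$metadata))
    inputHash <- unname(tools::md5sum(cfg$coordinates))
  }
  results <- list()
  downstream <- setdiff(cfg$treatments,
                        if (cfg$include_min_pd) character() else
                          "min_pd")
  for (tr in cfg$treatments) {
    message("stage superimpose [", tr, "]")
    aligned <- stageTry("superimpose", gpa(outlines, treatment = tr))
    pd <- procrustesDistances(aligned)
    diag <- c(aligned@diagnostics,
              list(meanPD = mean(pd), maxPD = max(pd)))
    jsonlite::write_json(diag,
      file.path(cfg$output_dir, paste0("superimpose_", tr, ".json")),
      auto_unbox = TRUE, digits = NA)
    res <- list(aligned = aligned, diagnostics = diag)
    if (tr %in% downstream) {
      message("stage symmetry [", tr, "]")
      decomp <- stageTry("symmetry",
        buildSymmetryDecomposition(outlines, treatment = tr))
      axisTab <- data.frame(pc = seq_along(decomp@eigenvalues),
                            class = decomp@axisClass,
                            varFraction = decomp@varFraction)
      utils::write.csv(axisTab,
        file.path(cfg$output_dir, paste0("pc_axes_", tr, ".csv")),
        row.names = FALSE)
      message("stage allometry [", tr, "]")
      allo <- stageTry("allometry",
        fitAllometry(decomp, nPerm = cfg$n_perm, seed = seed + 1L))
      message("stage nested ANOVA [", tr, "]")
      anovaRaw <- stageTry("nested ANOVA",
        nestedProcrustesAnova(decomp, nPerm = cfg$n_perm,
                              seed = seed + 2L))
      anovaAdj <- stageTry("nested ANOVA",
        nestedProcrustesAnova(decomp, nPerm = cfg$n_perm,
                              seed = seed + 3L, adjustSize = TRUE))
      writeAnovaTable(anovaRaw,
        file.path(cfg$output_dir, paste0("anova_shape_", tr, ".csv")))
      writeAnovaTable(anovaAdj,
        file.path(cfg$output_dir,
                  paste0("anova_shape_sizeadj_", tr, ".csv")))
      message("stage total asymmetry [", tr, "]")
      asym <- totalAsymmetry(decomp)
      oInfo <- outlines@info
      oSizes <- decomp@alignment@centroidSizes[decomp@originalIdx]
      taRaw <- stageTry("total asymmetry",
        totalAsymmetryAnova(asym, oInfo, sizes = oSizes,
                            nPerm = cfg$n_perm, seed = seed + 4L))
      taAdj <- stageTry("total asymmetry",
        totalAsymmetryAnova(asym, oInfo, sizes = oSizes,
                            nPerm = cfg$n_perm, seed = seed + 5L,
                            adjustSize = TRUE))
      writeAnovaTable(taRaw,
        file.path(cfg$output_dir, paste0("anova_asym_", tr, ".csv")))
      writeAnovaTable(taAdj,
        file.path(cfg$output_dir,
                  paste0("anova_asym_sizeadj_", tr, ".csv")))
      message("stage per-plant comparison [", tr, "]")
      pp <- stageTry("per-plant", perPlantDecomposition(decomp))
      utils::write.csv(pp,
        file.path(cfg$output_dir, paste0("per_plant_", tr, ".csv")),
        row.names = FALSE)
      locs <- sort(unique(pp$locality))
      boots <- NULL
      if (length(locs) == 2L) {
        comp <- list()
        for (colName in c("symmetricMS", "daMS", "faMS",
                          "symmetricR2", "daR2", "faR2")) {
          bs <- bootstrapMedianDifference(
            pp[[colName]][pp$locality == locs[1L]],
            pp[[colName]][pp$locality == locs[2L]],
            nBoot = cfg$n_boot, seed = seed + 6L)
          comp[[colName]] <- data.frame(
            factor = colName, medianA = bs@medianA,
            medianB = bs@medianB, ciLow = bs@ci[1L],
            ciHigh = bs@ci[2L], p = bs@pValue)
        }
        boots <- do.call(rbind, comp)
        utils::write.csv(boots,
          file.path(cfg$output_dir,
                    paste0("bootstrap_comparison_", tr, ".csv")),
          row.names = FALSE)
      }
      msCor <- stageTry("per-plant", msCorrelations(pp))
      utils::write.csv(as.data.frame(msCor),
        file.path(cfg$output_dir, paste0("ms_correlations_", tr,
                                         ".csv")))
      segSizes <- tapply(oSizes, paste(oInfo$locality, oInfo$plant,
                                       oInfo$segment), mean)
      segAsym <- tapply(asym, paste(oInfo$locality, oInfo$plant,
                                    oInfo$segment), mean)
      sizeCor <- sizeAsymmetryCorrelation(as.vector(segSizes),
                                          as.vector(segAsym))
      res <- c(res, list(decomposition = decomp, allometry = allo,
                         anovaShape = anovaRaw,
                         anovaShapeSizeAdj = anovaAdj,
                         anovaAsym = taRaw, anovaAsymSizeAdj = taAdj,
                         perPlant = pp, bootstrap = boots,
                         msCorrelations = msCor,
                         sizeAsymmetry = sizeCor))
    }
    results[[tr]] <- res
  }
  manifest <- list(
    package = "morphosym",
    version = as.character(utils::packageVersion("morphosym")),
    seed = seed, n_perm = cfg$n_perm, n_boot = cfg$n_boot,
    treatments = cfg$treatments,
    synthetic = if (is.null(cfg$synthetic)) NULL else
      as.character(cfg$synthetic),
    input_md5 = inputHash,
    n_configurations = nConfigs(outlines))
  jsonlite::write_json(manifest,
                       file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeSummary(results, cfg)
  invisible(results)
}

writeSummary <- function(results, cfg) {
  path <- file.path(cfg$output_dir, "summary.txt")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("morphosym pipeline summary",
               paste("seed:", cfg$seed, " permutations:", cfg$n_perm,
                     " bootstrap:", cfg$n_boot), ""), con)
  for (tr in names(results)) {
    r <- results[[tr]]
    writeLines(paste0("== treatment: ", tr), con)
    writeLines(sprintf("  mean PD to consensus: %.4f  (max %.4f)",
                       r$diagnostics$meanPD, r$diagnostics$maxPD), con)
    if (!is.null(r$allometry))
      writeLines(sprintf(
        "  allometry: %.1f%% of shape variance (Wilks lambda %.3f, p %.4g)",
        r$allometry@pctExplained, r$allometry@wilksLambda,
        r$allometry@pValue), con)
    if (!is.null(r$anovaShape)) {
      tab <- r$anovaShape@table
      for (i in seq_len(nrow(tab)))
        writeLines(sprintf("  %-24s df %4d  SS %9.4f  F %8.3f  p %s",
                           tab$effect[i], tab$df[i], tab$SS[i],
                           ifelse(is.na(tab$F[i]), NA, tab$F[i]),
                           format(tab$p[i])), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
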