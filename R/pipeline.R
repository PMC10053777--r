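# End-to-end orchestration: synthetic generation (or TSV inputs) ->
# outlier screen -> common-dispersion NB contrasts -> cross-mixture
# comparison -> three-way gene-set overrepresentation -> enrichment map +
# term reduction -> developmental-screen and chemistry summaries. Every
# threshold is a named, defaulted config entry; a manifest pins the run.

#' Default run configuration
#'
#' All tunable constants of the pipeline as a named list: DEG thresholds
#' (\code{lfcHeatmap} = 1 for heatmaps/PCA, \code{lfcGo} = 0.5 for
#' overrepresentation, \code{padjMax} = 0.05), term-size window (15--400),
#' enrichment-map edge threshold (0.4), Jaccard merge threshold (0.45),
#' per-treatment top-term cutoff (60), heatmap k-means settings (k = 8,
#' 500 starts), and the synthetic-mode generator parameters.
#'
#' @param ... overrides as name = value pairs.
#' @return named list.
#' @export
defaultConfig <- function(...) {
  cfg <- list(
    mode = "synthetic", seed = 1L, outDir = "mixturetox_run",
    control = "control",
    # thresholds
    lfcHeatmap = 1.0, lfcGo = 0.5, padjMax = 0.05,
    termMin = 15, termMax = 400, edgeThreshold = 0.4,
    mergeAt = 0.45, topN = 60, k = 8, starts = 500,
    # synthetic-mode generator parameters
    nGenes = 4000, samplesPerGroup = 3, deFraction = 0.1,
    beta = 0.59, epsSd = 0.3, alpha = 0.05,
    nTerms = 90, nActive = 12, extraGroups = TRUE,
    # real-mode input paths (counts/meta/gmt mandatory; tox/chem optional)
    counts = NULL, meta = NULL, gmt = NULL, tox = NULL, chem = NULL)
  over <- list(...)
  cfg[names(over)] <- over
  .validateConfig(cfg)
  cfg
}

.validateConfig <- function(cfg) {
  stopifnot(cfg$padjMax > 0, cfg$padjMax <= 1,
            cfg$lfcHeatmap >= 0, cfg$lfcGo >= 0,
            cfg$termMin <= cfg$termMax,
            cfg$edgeThreshold >= 0, cfg$edgeThreshold <= 1,
            cfg$mergeAt >= 0, cfg$mergeAt <= 1,
            cfg$topN >= 1, cfg$k >= 1, cfg$starts >= 1)
  if (cfg$mode == "real" &&
      (is.null(cfg$counts) || is.null(cfg$meta) || is.null(cfg$gmt)))
    stop("real mode needs 'counts', 'meta' and 'gmt' paths")
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(defaultConfig())
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(defaultConfig, y)
}

.log <- function(stage, ...) {
  message(sprintf("[mixturetox %s] %s", format(Sys.time(), "%H:%M:%S"),
                  paste0(stage, ": ", ...)))
}

# Evaluate a stage body (lazily, in the caller's frame, so `<-` inside the
# braces lands in runPipeline's locals) with stage-named error reporting.
.stage <- function(name, expr, outDir) {
  .log(name, "start")
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         " (partial outputs kept in ", outDir, ")", call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full comparative mixture-toxicogenomics pipeline
#'
#' Executes, in order: synthetic generation (or TSV input loading), the
#' MDS outlier screen, common-dispersion estimation and one NB Wald
#' contrast per treatment against the control, cross-mixture comparison
#' (concordance, origin regression, heatmap structure, treatment PCA when
#' at least three treatments are present), the three-way DEG partition and
#' hypergeometric overrepresentation, enrichment-map construction and
#' Jaccard term reduction, and -- when screen/chemistry tables are present
#' -- the developmental-screen and PAH summaries. All module outputs are
#' written as TSV under \code{config$outDir} along with a YAML manifest
#' (package version, seed, parameter echo, per-stage row counts) that
#' fully pins the run: re-running with the same config is byte-identical.
#' A stage failure aborts with the stage name; earlier outputs are kept.
#'
#' @param config a config list from [defaultConfig()] or a YAML path.
#' @return invisibly, the manifest list (also written to
#'   \code{manifest.yaml}).
#' @export
runPipeline <- function(config = defaultConfig()) {
  if (is.character(config)) config <- readRunConfig(config)
  .validateConfig(config)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  truth <- NULL; screen <- NULL; plates <- NULL; chem <- NULL
  se <- NULL; gsc <- NULL

  if (config$mode == "synthetic") {
    .stage("synthdata", {
      truth <- synthTruth(config$nGenes, deFraction = config$deFraction,
                          beta = config$beta, epsSd = config$epsSd,
                          alpha = config$alpha, seed = config$seed)
      extra <- NULL
      groups <- c("control", "mixtureA", "mixtureB")
      if (isTRUE(config$extraGroups)) {
        # two single-chemical-style groups sharing part of the mixtures'
        # program, so treatment-level PCA has >= 3 informative points
        set.seed(deriveSeed(config$seed, 9L))
        nG <- length(truth@theta)
        mask <- rbinom(nG, 1, 0.6)
        extra <- list(
          chemPAH = 0.8 * truth@theta * mask,
          chemOPAH = 0.45 * truth@theta +
            rnorm(nG, 0, 0.2) * (truth@theta != 0))
        groups <- c(groups, names(extra))
      }
      sim <- simulateCounts(truth, samplesPerGroup = config$samplesPerGroup,
                            groups = groups, extraLfc = extra)
      truth <- sim$truth
      gs <- simulateGeneSets(truth, nTerms = config$nTerms,
                             sizeRange = c(config$termMin,
                                           min(config$termMax,
                                               config$nGenes %/% 3)),
                             nActive = config$nActive)
      truth <- gs$truth
      tox <- simulateToxScreen(seed = config$seed)
      screen <- tox$screen; plates <- tox$plates
      chem <- simulateChemTable(seed = config$seed)
      se <- sim$counts
      gsc <- gs$geneSets
      writeCountsTsv(se, file.path(config$outDir, "counts.tsv"),
                     file.path(config$outDir, "metadata.tsv"))
      writeGmt(gsc, file.path(config$outDir, "genesets.gmt"))
      .writeTsv(screen, file.path(config$outDir, "tox_screen.tsv"))
      .writeTsv(plates, file.path(config$outDir, "tox_plates.tsv"))
      .writeTsv(chem, file.path(config$outDir, "chemistry.tsv"))
      .writeTsv(data.frame(gene_id = names(truth@theta),
                           theta = truth@theta, lfc_b = truth@lfcB),
                file.path(config$outDir, "truth_genes.tsv"))
      stages$synthdata <- list(genes = nrow(se), samples = ncol(se),
                               terms = length(gsc))
    }, config$outDir)
  } else {
    .stage("load", {
      se <- readCountsTsv(config$counts, config$meta)
      gsc <- readGmt(config$gmt)
      if (!is.null(config$tox)) screen <- read.delim(config$tox)
      if (!is.null(config$chem)) chem <- read.delim(config$chem)
      stages$load <- list(genes = nrow(se), samples = ncol(se),
                          terms = length(gsc))
    }, config$outDir)
  }

  contrasts <- NULL
  .stage("diffexpr", {
    mds <- mdsScreen(se)
    .writeTsv(mds, file.path(config$outDir, "mds_screen.tsv"))
    sf <- estimateSizeFactors(se)
    alphaHat <- estimateCommonDispersion(se, sizeFactors = sf)
    treatments <- setdiff(unique(as.character(sampleGroups(se))),
                          config$control)
    contrasts <- lapply(treatments, function(tr) {
      cc <- nbWaldContrast(se, tr, config$control, alphaHat,
                           sizeFactors = sf)
      writeContrastTsv(cc, file.path(config$outDir,
                                     paste0("contrast_", tr, ".tsv")))
      cc
    })
    names(contrasts) <- treatments
    stages$diffexpr <- list(
      alpha_hat = alphaHat, outliers_flagged = sum(mds$outlier_flag),
      degs_lfc1 = lapply(contrasts, function(cc)
        length(classifyDegs(cc, config$lfcHeatmap, config$padjMax))),
      degs_lfc05 = lapply(contrasts, function(cc)
        length(classifyDegs(cc, config$lfcGo, config$padjMax))))
  }, config$outDir)

  lfcAll <- NULL
  .stage("mixture_compare", {
    cA <- contrasts[["mixtureA"]] %||% contrasts[[1]]
    cB <- contrasts[["mixtureB"]] %||% contrasts[[2]]
    conc <- directionConcordance(cA, cB, config$lfcHeatmap, config$padjMax)
    lfcAB <- buildLfcMatrix(list(A = cA, B = cB),
                            config$lfcHeatmap, config$padjMax)
    reg <- if (nrow(lfcAB) >= 3)
      originRegression(lfcAB[, 1], lfcAB[, 2]) else NULL
    .writeTsv(data.frame(metric = names(conc), value = unlist(conc)),
              file.path(config$outDir, "concordance.tsv"))
    if (!is.null(reg))
      .writeTsv(data.frame(slope = reg$slope, se = reg$se,
                           ci_lo = reg$ci[1], ci_hi = reg$ci[2],
                           r2 = reg$r2, n = reg$n),
                file.path(config$outDir, "origin_regression.tsv"))
    lfcAll <- buildLfcMatrix(contrasts, config$lfcHeatmap, config$padjMax)
    stages$mixture_compare <- list(concordance = conc)
    if (!is.null(reg)) {
      stages$mixture_compare$slope <- reg$slope
      stages$mixture_compare$r2 <- reg$r2
    }
    if (nrow(lfcAll) > config$k) {
      hs <- heatmapStructure(lfcAll, k = config$k, starts = config$starts,
                             seed = config$seed)
      .writeTsv(data.frame(gene_id = names(hs$cluster),
                           cluster = hs$cluster),
                file.path(config$outDir, "heatmap_clusters.tsv"))
      .writeTsv(hs$cluster_summary,
                file.path(config$outDir, "heatmap_cluster_summary.tsv"))
    }
    if (ncol(lfcAll) >= 3 && nrow(lfcAll) >= 2) {
      pca <- pcaTreatments(lfcAll)
      .writeTsv(data.frame(treatment = rownames(pca$coordinates),
                           pca$coordinates),
                file.path(config$outDir, "pca_coordinates.tsv"))
      .writeTsv(data.frame(component = seq_along(pca$variance_fractions),
                           fraction = pca$variance_fractions),
                file.path(config$outDir, "pca_variance.tsv"))
      stages$mixture_compare$pc1_fraction <- pca$variance_fractions[1]
    }
  }, config$outDir)

  enrichment <- NULL
  .stage("enrichment", {
    cA <- contrasts[["mixtureA"]] %||% contrasts[[1]]
    cB <- contrasts[["mixtureB"]] %||% contrasts[[2]]
    # universe: genes with a defined test result in both contrasts
    defined <- function(cc) cc@results$gene_id[!is.na(cc@results$p)]
    universe <- intersect(defined(cA), defined(cB))
    filtered <- filterTerms(gsc, config$termMin, config$termMax, universe)
    part <- partitionDegs(classifyDegs(cA, config$lfcGo, config$padjMax),
                          classifyDegs(cB, config$lfcGo, config$padjMax))
    rows3 <- enrichQueries(part, filtered, padjMax = config$padjMax)
    perTrt <- lapply(contrasts, function(cc)
      degGenes(classifyDegs(cc, config$lfcGo, config$padjMax)))
    rowsT <- enrichQueries(perTrt, filtered, padjMax = config$padjMax)
    .writeTsv(rows3, file.path(config$outDir, "enrichment_partition.tsv"))
    .writeTsv(rowsT, file.path(config$outDir, "enrichment_treatments.tsv"))
    stages$enrichment <- list(
      universe = length(universe), terms_tested = length(filtered),
      significant_partition = sum(rows3$significant),
      significant_treatments = sum(rowsT$significant))
    enrichment <- list(rows3 = rows3, rowsT = rowsT, filtered = filtered)
  }, config$outDir)

  .stage("termtopology", {
    if (is.null(enrichment) || !nrow(enrichment$rows3) ||
        !sum(enrichment$rows3$significant)) {
      .log("termtopology", "no significant terms; skipped gracefully")
      stages$termtopology <- list(skipped = TRUE)
    } else {
      tg <- buildEnrichmentMap(enrichment$rows3, enrichment$filtered,
                               threshold = config$edgeThreshold)
      writeTermGraph(tg, file.path(config$outDir, "enrichment_map"))
      red <- reduceTerms(enrichment$rowsT, enrichment$filtered,
                         topN = config$topN, mergeAt = config$mergeAt)
      .writeTsv(red@summary, file.path(config$outDir, "reduced_terms.tsv"))
      .writeTsv(red@manifest,
                file.path(config$outDir, "reduced_terms_manifest.tsv"))
      stages$termtopology <- list(
        nodes = nrow(tg@nodes), edges = nrow(tg@edges),
        clusters = length(unique(tg@nodes$cluster)),
        merged_terms = length(unique(red@summary$merged_term)))
    }
  }, config$outDir)

  if (!is.null(screen)) .stage("toxscreen", {
    if (!is.null(plates))
      .writeTsv(plateQc(plates), file.path(config$outDir, "plate_qc.tsv"))
    dil <- sort(unique(screen$dilution[screen$dilution > 0]))
    # second-highest dilution: the discriminating mid dose in a series
    # whose top dose saturates
    mid <- dil[max(1, length(dil) - 1)]
    prof <- endpointProfile(screen, mid, control = config$control)
    .writeTsv(prof$profile,
              file.path(config$outDir, "endpoint_profile.tsv"))
    if (!is.null(prof$between))
      .writeTsv(prof$between,
                file.path(config$outDir, "endpoint_between.tsv"))
    stages$toxscreen <- list(profiled_dilution = mid,
                             endpoints = nrow(prof$profile))
  }, config$outDir)

  if (!is.null(chem)) .stage("chemistry", {
    smps <- unique(chem$sample)
    totals <- lapply(smps, function(s) sumPah(chem, s))
    names(totals) <- smps
    .writeTsv(data.frame(sample = smps,
                         total = vapply(totals, `[[`, 0, "total"),
                         ci_lo = vapply(totals, function(t) t$ci[1], 0),
                         ci_hi = vapply(totals, function(t) t$ci[2], 0)),
              file.path(config$outDir, "chem_totals.tsv"))
    if (length(smps) >= 2)
      .writeTsv(diagnosticRatios(chem, smps[1:2]),
                file.path(config$outDir, "chem_ratios.tsv"))
    .writeTsv(do.call(rbind, lapply(smps, function(s)
      cbind(sample = s, compositionProfile(chem, s)))),
      file.path(config$outDir, "chem_composition.tsv"))
    stages$chemistry <- list(totals = lapply(totals, `[[`, "total"))
  }, config$outDir)

  manifest <- list(package = as.character(packageVersion("mixturetox")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = config$seed,
                   parameters = config[setdiff(names(config), "outDir")],
                   stages = stages)
  yaml::write_yaml(manifest, file.path(config$outDir, "manifest.yaml"))
  .log("done", "outputs in ", config$outDir)
  invisible(manifest)
}

#' One-command synthetic demonstration run
#'
#' Generates a synthetic experiment and runs the full pipeline at reduced
#' problem sizes (a few thousand genes, three replicates per group).
#'
#' @param outDir output directory.
#' @param seed master seed.
#' @param ... further [defaultConfig()] overrides.
#' @return invisibly, the run manifest.
#' @export
runDemo <- function(outDir = tempfile("mixturetox_demo_"), seed = 1L, ...) {
  runPipeline(defaultConfig(outDir = outDir, seed = seed,
                            nGenes = 3000, starts = 50, ...))
}
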