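## End-to-end orchestration: normalize -> (modules | BGC) -> network ->
## stats, with a single validated configuration, deterministic seeding and
## a provenance record alongside every run.

.configDefaults <- list(
  countsPath = NULL, taxonPath = NULL, sampleDataPath = NULL,
  koTablePath = NULL, moduleDbPath = NULL, gffPath = NULL,
  regionsPath = NULL, outDir = NULL,
  minCount = 10, minSampleFrac = 0.5, minSpeciesReads = 1000,
  minCoverage = 0.5, estimator = "median",
  maxGap = 300, rMin = 0.5, majorityFrac = 0.7, rCore = 0.5,
  discrepancy = 0.3, beta = 6, minWeight = 0.2, minShared = 5,
  iterations = 50000, seed = 1,
  stages = c("normalize", "gmm", "bgc", "network", "stats"))

#' Build a validated pipeline configuration
#'
#' All thresholds default to the analysis defaults: low-expression filter
#' of 10 reads in half of the samples, module coverage 0.5 with the median
#' estimator, BGC refinement at 300 bp / r > 0.5 with the 70% majority and
#' core-co-expression filters, discrepancy threshold 0.3, signed power 6
#' with display cut-off 0.2, and 50000 bootstrap iterations. Unknown keys
#' and out-of-range thresholds are rejected.
#'
#' @param ... named configuration entries overriding the defaults (see
#'   `xcoex:::.configDefaults` for the full key list).
#' @return a validated named list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(.configDefaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(.configDefaults, over, keep.null = TRUE)
  .validateConfig(cfg)
  structure(cfg, class = "PipelineConfig")
}

.validateConfig <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid configuration: ", msg)
  chk(cfg$minCount >= 0, "minCount must be >= 0")
  chk(cfg$minSampleFrac >= 0 && cfg$minSampleFrac <= 1,
      "minSampleFrac must lie in [0, 1]")
  chk(cfg$minCoverage >= 0 && cfg$minCoverage <= 1,
      "minCoverage must lie in [0, 1]")
  chk(cfg$maxGap >= 0, "maxGap must be >= 0")
  chk(cfg$rMin >= -1 && cfg$rMin <= 1, "rMin must lie in [-1, 1]")
  chk(cfg$majorityFrac >= 0 && cfg$majorityFrac <= 1,
      "majorityFrac must lie in [0, 1]")
  chk(cfg$rCore >= -1 && cfg$rCore <= 1, "rCore must lie in [-1, 1]")
  chk(cfg$discrepancy >= 0, "discrepancy must be >= 0")
  chk(cfg$beta >= 1, "beta must be >= 1")
  chk(cfg$minWeight >= 0 && cfg$minWeight <= 1,
      "minWeight must lie in [0, 1]")
  chk(cfg$iterations >= 1, "iterations must be >= 1")
  chk(all(cfg$stages %in% .configDefaults$stages), "unknown stage name")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' YAML keys mirror the arguments of [pipelineConfig()]; unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @return a validated `"PipelineConfig"`.
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

#' Run the co-expression pipeline end to end
#'
#' Stages run in order: `normalize` (low-expression filter, per-taxon TMM
#' CPM), `gmm` (KO aggregation and module scoring), `bgc` (region
#' refinement and retention filters), `network` (correlation, discrepancy
#' filter, signed power scaling, thresholding) and `stats` (matched-module
#' bootstrap tests for every module carried by >= 2 taxa). Missing inputs
#' fail before any stage runs; on a stage failure, outputs written so far
#' are retained next to a `status.json` naming the failed stage. A rerun
#' with identical config and inputs is bit-identical.
#'
#' @param config a `"PipelineConfig"` from [pipelineConfig()] /
#'   [readPipelineConfig()].
#' @return invisibly, a list with the produced objects and file paths.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  out <- config$outDir
  if (is.null(out)) stop("configuration must set outDir")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  needed <- c(countsPath = TRUE, taxonPath = TRUE,
              koTablePath = "gmm" %in% config$stages,
              moduleDbPath = "gmm" %in% config$stages,
              gffPath = "bgc" %in% config$stages,
              regionsPath = "bgc" %in% config$stages)
  for (key in names(needed)[unlist(needed)]) {
    p <- config[[key]]
    if (is.null(p) || !file.exists(p))
      stop("missing input before any stage ran: ", key,
           if (!is.null(p)) paste0(" (", p, ")"))
  }
  res <- list(paths = character(0))
  status <- list(stages = list())
  writeStatus <- function() jsonlite::write_json(
    status, file.path(out, "status.json"), auto_unbox = TRUE)
  runStage <- function(name, fun) {
    t0 <- Sys.time()
    r <- tryCatch(fun(), error = function(e) {
      status$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(e))
      writeStatus()
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    status$stages[[name]] <<- list(
      status = "ok",
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3))
    r
  }

  cc <- readCounts(config$countsPath, config$taxonPath, config$sampleDataPath)

  norm <- runStage("normalize", function() {
    filt <- filterLowExpression(cc, config$minCount, config$minSampleFrac)
    n <- normalizePerTaxon(filt, config$minSpeciesReads)
    v <- data.frame(gene_id = rownames(n), normValues(n, transformed = FALSE),
                    check.names = FALSE)
    utils::write.table(v, file.path(out, "normalized.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    n
  })
  res$normalized <- norm
  status$stages$normalize$genes <- nrow(norm)

  features <- NULL; featureTaxa <- NULL; featureKinds <- NULL; db <- NULL
  if ("gmm" %in% config$stages) {
    mods <- runStage("gmm", function() {
      db <<- readGmmDatabase(config$moduleDbPath)
      kt <- readKoTable(config$koTablePath)
      koSE <- aggregateKO(norm, kt)
      scoreModules(koSE, db, config$minCoverage, config$estimator)
    })
    res$modules <- mods
    status$stages$gmm$modules <- nrow(mods)
    m <- SummarizedExperiment::assay(mods, "score")
    utils::write.table(
      data.frame(feature = rownames(m),
                 coverage = SummarizedExperiment::rowData(mods)$coverage, m,
                 check.names = FALSE),
      file.path(out, "modules.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    features <- m
    featureTaxa <- SummarizedExperiment::rowData(mods)$taxon
    featureKinds <- rep("module", nrow(m))
  }
  if ("bgc" %in% config$stages) {
    sub <- runStage("bgc", function() {
      genes <- readGff3(config$gffPath)
      regions <- readBgcRegions(config$regionsPath, genes)
      expr <- normValues(norm, transformed = TRUE)
      cl <- do.call(rbind, lapply(split(regions, regions$region_id),
        function(r) refineRegion(r, expr, config$maxGap, config$rMin)))
      fl <- filterSubClusters(cl, rownames(norm), expr,
                              config$majorityFrac, config$rCore)
      flat <- function(d) data.frame(
        region_id = d$region_id, suffix = d$suffix,
        members = vapply(d$members, paste, character(1), collapse = ","),
        cores = vapply(d$cores, paste, character(1), collapse = ","),
        status = d$status, stringsAsFactors = FALSE)
      utils::write.table(flat(cl), file.path(out, "subclusters.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(fl$audit, file.path(out, "bgc_audit.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      fl
    })
    res$subclusters <- sub
    status$stages$bgc$retained <- nrow(sub$retained)
  }

  if ("network" %in% config$stages && !is.null(features)) {
    net <- runStage("network", function() {
      edges <- correlateFeatures(features, featureTaxa,
                                 presence = presenceMatrix(norm),
                                 kinds = featureKinds,
                                 minShared = config$minShared)
      edges <- discrepancyFilter(edges, config$discrepancy)
      n <- buildNetwork(edges, beta = config$beta,
                        minWeight = config$minWeight, db = db)
      allEdges <- edges
      allEdges$weight <- signedPower(allEdges$r, config$beta)
      writeEdgeTable(allEdges, file.path(out, "edges.tsv"))
      writeGraphML(n, file.path(out, "network.graphml"))
      n
    })
    res$network <- net
    res$edges <- readEdgeTable(file.path(out, "edges.tsv"))
    status$stages$network$edges <- nrow(networkEdges(net))
  }

  if ("stats" %in% config$stages && !is.null(res$edges) && !is.null(db)) {
    stats <- runStage("stats", function() {
      pool <- res$edges$r[res$edges$cross_species &
                            res$edges$removed_by == "none"]
      rows <- list()
      rd <- SummarizedExperiment::rowData(res$modules)
      for (mid in unique(rd$module)) {
        mm <- matchedModuleCorrelations(res$modules, mid,
                                        presence = presenceMatrix(norm),
                                        minShared = config$minShared,
                                        maxDiscrepancy = config$discrepancy)
        if (!length(mm$values) || length(pool) < length(mm$values)) next
        bs <- bootstrapMeanShift(mm$values, pool, config$iterations,
                                 seed = config$seed)
        rows[[mid]] <- data.frame(
          module = mid, n_taxa = mm$nTaxa, n_values = length(mm$values),
          observed_mean = bs@observedMean, null_mean = bs@nullMean,
          p_high = bs@pHigh, p_low = bs@pLow, stringsAsFactors = FALSE)
      }
      df <- if (length(rows)) do.call(rbind, rows) else
        data.frame(module = character(0))
      utils::write.table(df, file.path(out, "stats.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      df
    })
    res$stats <- stats
  }

  prov <- list(
    package = "xcoex",
    version = as.character(utils::packageVersion("xcoex")),
    seed = config$seed,
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
    inputs = lapply(
      config[c("countsPath", "taxonPath", "koTablePath", "moduleDbPath",
               "gffPath", "regionsPath")],
      function(p) if (!is.null(p) && file.exists(p))
        unname(tools::md5sum(p)) else NULL),
    outputs = local({
      fs <- setdiff(list.files(out, full.names = TRUE),
                    file.path(out, c("provenance.json", "status.json")))
      stats::setNames(lapply(fs, function(f) unname(tools::md5sum(f))),
                      basename(fs))
    }))
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  writeStatus()
  res$paths <- list.files(out, full.names = TRUE)
  invisible(res)
}
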