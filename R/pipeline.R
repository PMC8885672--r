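.pkgVersion <- function() {
  as.character(utils::packageVersion("svcycles"))
}

.provHeader <- function(seed, params = character()) {
  paste0("# svcycles ", .pkgVersion(), " | seed=", seed,
         if (length(params)) paste0(" | ", paste(params, collapse = " ")))
}

.writeTsv <- function(df, path, seed, params = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provHeader(seed, params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export clusters as BED
#'
#' Cluster spans as 0-based half-open BED intervals, name = cluster id,
#' score = member count.
#'
#' @param cl cluster data.frame (see [clusters()]).
#' @param path output path.
#' @export
writeClusterBed <- function(cl, path) {
  df <- data.frame(chrom = cl$chrom,
                   start = format(cl$span_lo - 1, scientific = FALSE),
                   end = format(cl$span_hi, scientific = FALSE),
                   name = cl$cluster_id, score = cl$n_members,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML with optional blocks \code{simulate} (arguments of
#' [simulationConfig()]), \code{inputs} (\code{format}, \code{files} as a
#' sample-to-path map, \code{genome} as a chrom-to-length map,
#' \code{cn_segments}, \code{cancer_map}), \code{clustering}
#' ([clusteringConfig()] arguments), \code{permtest} (\code{n_datasets}),
#' \code{switching} ([switchingConfig()] arguments), \code{classification}
#' (\code{window}, \code{gain_threshold}, \code{loss_threshold}),
#' \code{output_dir} and \code{seed}.
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

.pipelineDataset <- function(config) {
  if (!is.null(config$simulate)) {
    sim <- do.call(simulationConfig, utils::modifyList(
      config$simulate,
      list(seed = config$simulate$seed %||% config$seed %||% 1L)))
    gen <- generateDataset(sim)
    return(gen$dataset)
  }
  inp <- config$inputs
  if (is.null(inp)) stop("config needs either 'simulate' or 'inputs'")
  paths <- c(unlist(inp$files), inp$cn_segments, inp$cancer_map)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input path(s) not found: ", paste(missing, collapse = ", "))
  reader <- if (identical(inp$format, "vcf")) readVcfBreakends else readBedpe
  adj <- do.call(rbind, lapply(names(inp$files), function(s)
    reader(inp$files[[s]], s)))
  SVDataset(
    adj, genome = unlist(inp$genome),
    cnSegments = if (!is.null(inp$cn_segments))
      readCnSegments(inp$cn_segments) else .emptyCnSegments(),
    cancerType = if (!is.null(inp$cancer_map))
      readCancerTypeMap(inp$cancer_map) else character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full SV pattern pipeline
#'
#' Stages, in order: \code{cluster} (two-step KDE clustering),
#' \code{permtest} (pooled-breakpoint permutation validation), \code{mine}
#' (graph construction and cycle enumeration), \code{abundance}
#' (edge-switching null and Abundance per cycle size), \code{classify}
#' (triangle subtyping, overlap matrix, per-cancer summary). Every output
#' table carries a provenance header with the package version, seed and
#' stage parameters. A failing stage renames its partial outputs with a
#' \code{.partial} suffix and raises an error.
#'
#' @param config a configuration list or the path to a YAML file (see
#'   [readPipelineConfig()]).
#' @param stages subset of stages to run (prerequisites are computed in
#'   memory regardless).
#' @return invisible list of in-memory stage results.
#' @export
runPipeline <- function(config,
                        stages = c("cluster", "permtest", "mine",
                                   "abundance", "classify")) {
  if (is.character(config)) config <- readPipelineConfig(config)
  seed <- config$seed %||% 1L
  outDir <- config$output_dir %||% "."
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stageFiles <- character()
  runStage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      for (f in stageFiles[file.exists(stageFiles)])
        file.rename(f, paste0(f, ".partial"))
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out <- file.path
  res <- list()

  dataset <- runStage("input", .pipelineDataset(config))
  clCfg <- do.call(clusteringConfig, config$clustering %||% list())

  svc <- runStage("cluster", twoStepClustering(dataset, clCfg))
  res$clusters <- svc
  if ("cluster" %in% stages) {
    stageFiles <- c(out(outDir, "clusters.tsv"), out(outDir, "clusters.bed"))
    .writeTsv(clusters(svc), stageFiles[1], seed,
              paste0("h1=", clCfg$h1, " h2=", clCfg$h2))
    writeClusterBed(clusters(svc), stageFiles[2])
  }

  if ("permtest" %in% stages) {
    nPerm <- config$permtest$n_datasets %||% 100
    pt <- runStage("permtest",
                   clusterPermutationTest(dataset, clCfg, nPerm,
                                          seed = seed + 1L))
    res$permtest <- pt
    stageFiles <- out(outDir, "permtest.tsv")
    .writeTsv(pt, stageFiles, seed, paste0("n_datasets=", nPerm))
  }

  graphs <- runStage("mine", buildSampleGraphs(svc))
  cycleSet <- runStage("mine", enumerateCycles(graphs))
  res$graphs <- graphs
  res$cycles <- cycleSet
  if ("mine" %in% stages) {
    stageFiles <- c(out(outDir, "cycles.jsonl"),
                    out(outDir, "pattern_stats.tsv"))
    occ <- cycles(cycleSet)
    writeLines(vapply(seq_len(nrow(occ)), function(i)
      jsonlite::toJSON(as.list(occ[i, ]), auto_unbox = TRUE),
      character(1)), stageFiles[1])
    .writeTsv(patternStatistics(cycleSet), stageFiles[2], seed)
  }

  if (any(c("abundance", "classify") %in% stages)) {
    swCfg <- do.call(switchingConfig, utils::modifyList(
      config$switching %||% list(), list(seed = seed + 2L)))
    if ("abundance" %in% stages) {
      ens <- runStage("abundance", randomizedEnsemble(graphs, swCfg))
      abRep <- runStage("abundance",
                        motifAbundanceReport(cycleSet, graphs, ens,
                                             epsilon = swCfg$epsilon))
      res$abundance <- abRep
      stageFiles <- out(outDir, "abundance.tsv")
      .writeTsv(abRep, stageFiles, seed,
                paste0("n_datasets=", swCfg$n_datasets, " multiplier=",
                       swCfg$multiplier, " epsilon=", swCfg$epsilon))
    }
  }

  if ("classify" %in% stages) {
    cls <- config$classification %||% list()
    calls <- runStage("classify",
      classifyTriangles(cycleSet, graphs, adjacencies(svc),
                        seg = if (nrow(cnSegments(dataset)))
                          cnSegments(dataset) else NULL,
                        window = cls$window %||% 1e6,
                        gain_threshold = cls$gain_threshold %||% 1,
                        loss_threshold = cls$loss_threshold %||% 1))
    res$triangles <- calls
    stageFiles <- out(outDir, "triangles.tsv")
    .writeTsv(calls, stageFiles, seed)
    ov <- triangleOverlapMatrix(calls)
    stageFiles <- out(outDir, "triangle_overlap.tsv")
    .writeTsv(data.frame(type = rownames(ov), ov, check.names = FALSE),
              stageFiles, seed)
    if (length(cancerTypes(dataset)) && nrow(calls)) {
      summ <- runStage("classify",
        triangleTypeCancerSummary(calls, cancerTypes(dataset)))
      res$cancer_summary <- summ
      stageFiles <- out(outDir, "triangle_cancer_summary.tsv")
      .writeTsv(summ, stageFiles, seed)
    }
  }
  invisible(res)
}
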