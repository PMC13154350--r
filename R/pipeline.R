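.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full correlation-network pipeline
#'
#' Executes read -> minimum-area filter -> ion grouping -> pseudomolecular
#' ion identification -> Pearson correlation -> weight rescaling -> edge
#' thinning -> layout -> quality metrics -> export as one step. Defaults
#' follow the reference parameter block: positive mode, minimum area 9000,
#' alpha 0.01 unadjusted, normal clustering, grouping on with RT shift 0.02
#' min and m/z error 0.016 Da. Any stage failure aborts with the stage name
#' and its diagnostic.
#'
#' @param input path of a feature-table file (CSV/TSV/XLSX), or \code{NULL}
#'   when \code{table} is given directly.
#' @param table a [FeatureTable-class] (alternative to \code{input}).
#' @param mode ionization polarity (used when reading \code{input}; a
#'   \code{table} keeps its own).
#' @param minArea minimum maximum-area to consider a feature.
#' @param alpha,bonferroni correlation significance policy.
#' @param clustering clustering preset name (\code{weak/normal/strong}).
#' @param ionGrouping group ions into cliques (\code{FALSE}: every feature
#'   is its own node candidate).
#' @param rtShift,mzError grouping RT window (min) and m/z measurement
#'   error (Da).
#' @param sampleType sample type selecting the characteristic neutral
#'   losses.
#' @param weightAccept,isoWindow,areaFrac identification-cascade parameters
#'   (see [identifyPseudomolecular()]).
#' @param iterations,seed layout sweeps and seed (see [layoutNetwork()]).
#' @param outDir output directory; \code{NULL} skips all file output.
#' @param outFormats export formats for [exportNetwork()].
#' @param verbose print the run log to the console.
#' @return (invisibly) list with \code{table}, \code{filtered},
#'   \code{cliqueSet}, \code{correlation}, \code{network} and the run
#'   \code{log} (character vector). The network carries layout coordinates
#'   and quality metrics.
#' @examples
#' ds <- makeSyntheticDataset(syntheticSpec(nMetabolites = 8, seed = 7,
#'                                          blocks = rep(1:2, each = 4),
#'                                          withinR = 0.9, betweenR = -0.6))
#' run <- runPipeline(table = ds$table, minArea = 0, alpha = 0.05)
#' run$network
#' @export
runPipeline <- function(input = NULL, table = NULL,
                        mode = c("positive", "negative"),
                        minArea = 9000, alpha = 0.01, bonferroni = FALSE,
                        clustering = "normal", ionGrouping = TRUE,
                        rtShift = 0.02, mzError = 0.016,
                        sampleType = "plant", weightAccept = 4,
                        isoWindow = 1.008, areaFrac = 0.5,
                        iterations = NULL, seed = 0, outDir = NULL,
                        outFormats = c("graphml", "edge_tsv", "png"),
                        verbose = TRUE) {
  mode <- match.arg(mode)
  log <- character()
  say <- function(...) {
    line <- sprintf(...)
    log <<- c(log, line)
    if (verbose) message(line)
  }
  if (is.null(table)) {
    if (is.null(input)) stop("stage 'read': provide input or table")
    table <- .stage("read", readFeatureTable(input, mode = mode))
  }
  stopifnot(is(table, "FeatureTable"))
  mode <- ionMode(table)
  say("correnet pipeline")
  say("  ion mode: %s | min area: %g | alpha: %g (%s) | clustering: %s",
      mode, minArea, alpha, if (bonferroni) "Bonferroni" else "unadjusted",
      clustering)
  say("  ion grouping: %s | max RT shift: %g min | max m/z error: %g Da | seed: %d",
      if (ionGrouping) "on" else "off", rtShift, mzError, seed)
  say("read: %d features x %d samples", nrow(table), ncol(table))

  filtered <- .stage("filter", filterMinArea(table, minArea))
  say("filter: %d features with max area >= %g", nrow(filtered), minArea)

  cs <- .stage("group", groupIons(filtered, rtShift = rtShift,
                                  rsdMax = 0.25, enabled = ionGrouping))
  say("group: %d cliques (sizes %d-%d)", length(cs),
      min(lengths(cliques(cs))), max(lengths(cliques(cs))))

  cs <- .stage("identify",
               identifyCliques(cs, filtered, sampleType = sampleType,
                               er = mzError, weightAccept = weightAccept,
                               isoWindow = isoWindow, areaFrac = areaFrac))
  say("identify: %d pseudomolecular ions (%d virtual)",
      nrow(pseudoIons(cs)), sum(pseudoIons(cs)$virtual))

  profiles <- cliqueProfiles(filtered, cs)
  corr <- .stage("correlate",
                 pearsonMatrix(profiles, alpha = alpha,
                               bonferroni = bonferroni))
  say("correlate: %d profiles over %d samples", nrow(profiles),
      ncol(profiles))

  preset <- clusteringPreset(clustering)
  ps <- pseudoIons(cs)
  labels <- stats::setNames(sprintf("%.4f", ps$pseudoMz), ps$clique)
  sizes <- stats::setNames(unname(maxAreas(filtered)[basePeaks(cs)]),
                           names(cliques(cs)))
  annot <- stats::setNames(ps$annotation, ps$clique)
  mzv <- stats::setNames(ps$pseudoMz, ps$clique)
  net <- .stage("network",
                buildNetwork(corr, labels = labels, sizes = sizes,
                             mzValues = mzv, annotation = annot,
                             preset = preset))
  say("network: %d displayed nodes, %d displayed edges (of %d significant)",
      nrow(nodes(net)), sum(edges(net)$displayed), nrow(edges(net)))

  net <- .stage("layout", layoutNetwork(net, iterations = iterations,
                                        seed = seed))
  net <- .stage("metrics", qualityMetrics(net))
  say("metrics: mean silhouette %s, %d DBSCAN clusters",
      format(networkMetrics(net)$meanSilhouette, digits = 3),
      networkMetrics(net)$nClusters)

  if (!is.null(outDir)) {
    .stage("export", {
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      for (fmt in outFormats) {
        ext <- if (fmt == "edge_tsv") "tsv" else fmt
        exportNetwork(net, file.path(outDir, paste0("network.", ext)), fmt)
      }
      writeCliqueReport(cs, file.path(outDir, "cliques.tsv"))
      writeFeatureTable(filtered, file.path(outDir, "features-filtered.csv"))
      writeLines(log, file.path(outDir, "run-log.txt"))
    })
    say("export: written to %s", outDir)
  }
  invisible(list(table = table, filtered = filtered, cliqueSet = cs,
                 correlation = corr, network = net, log = log))
}
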