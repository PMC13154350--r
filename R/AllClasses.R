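#' FeatureTable: an LC-MS feature table
#'
#' A \linkS4class{SummarizedExperiment} holding one detected LC-MS feature per
#' row (characterised by its mass-to-charge ratio, retention time and optional
#' text annotation in \code{rowData}) and one sample per column, with a single
#' \code{"area"} assay of peak areas. The ionization polarity of the
#' acquisition is stored in the object metadata.
#'
#' Validity requires unique feature identifiers (rownames), \code{mz > 0},
#' \code{rt >= 0}, non-negative areas and at least one positive area per
#' feature.
#'
#' @slot .  inherits all slots from \code{SummarizedExperiment}
#' @seealso [FeatureTable()], [readFeatureTable()], [filterMinArea()]
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata SimpleList
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  msg <- character()
  if (!"area" %in% assayNames(object))
    msg <- c(msg, "assay 'area' is required")
  rd <- rowData(object)
  if (!all(c("mz", "rt") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'mz' and 'rt'")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "feature identifiers (rownames) must be present and unique")
  if (length(msg))
    return(msg)
  a <- assay(object, "area")
  if (nrow(object)) {
    if (any(!is.finite(rd$mz)) || any(rd$mz <= 0))
      msg <- c(msg, "all m/z values must be finite and > 0")
    if (any(!is.finite(rd$rt)) || any(rd$rt < 0))
      msg <- c(msg, "all retention times must be finite and >= 0")
    if (any(!is.finite(a)) || any(a < 0))
      msg <- c(msg, "areas must be finite and non-negative")
    else if (any(rowSums(a > 0) == 0))
      msg <- c(msg, "every feature needs at least one positive area")
  }
  mode <- metadata(object)$ionMode
  if (is.null(mode) || !mode %in% c("positive", "negative"))
    msg <- c(msg, "metadata 'ionMode' must be 'positive' or 'negative'")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureTable
#'
#' @param mz numeric vector of mass-to-charge ratios (Da), one per feature.
#' @param rt numeric vector of retention times (min).
#' @param areas numeric matrix of peak areas, features in rows and samples in
#'   columns; column names are the sample identifiers.
#' @param mode ionization polarity, \code{"positive"} or \code{"negative"}.
#' @param ids feature identifiers; generated (\code{F0001}, ...) when missing.
#' @param annotation optional character vector of text annotations.
#' @return a validated [FeatureTable-class] object.
#' @examples
#' ft <- FeatureTable(mz = c(339.07, 679.15), rt = c(5.1, 5.1),
#'                    areas = matrix(1:8, 2, 4), mode = "negative")
#' mz(ft)
#' @export
FeatureTable <- function(mz, rt, areas, mode = c("positive", "negative"),
                         ids = NULL, annotation = NULL) {
  mode <- match.arg(mode)
  areas <- as.matrix(areas)
  storage.mode(areas) <- "double"
  n <- length(mz)
  if (is.null(ids))
    ids <- sprintf("F%04d", seq_len(n))
  if (is.null(annotation))
    annotation <- rep(NA_character_, n)
  if (is.null(colnames(areas)))
    colnames(areas) <- sprintf("S%02d", seq_len(ncol(areas)))
  rownames(areas) <- ids
  se <- SummarizedExperiment(
    assays = SimpleList(area = areas),
    rowData = DataFrame(mz = as.numeric(mz), rt = as.numeric(rt),
                        annotation = as.character(annotation),
                        row.names = ids))
  metadata(se)$ionMode <- mode
  new("FeatureTable", se)
}

#' @describeIn FeatureTable m/z values, named by feature id
#' @param x a \code{FeatureTable}
#' @export
setMethod("mz", "FeatureTable", function(x, ...)
  stats::setNames(rowData(x)$mz, rownames(x)))

#' @describeIn FeatureTable retention times, named by feature id
#' @export
setMethod("rt", "FeatureTable", function(x, ...)
  stats::setNames(rowData(x)$rt, rownames(x)))

#' @describeIn FeatureTable the peak-area matrix (features x samples)
#' @export
setMethod("areas", "FeatureTable", function(x, ...) assay(x, "area"))

#' @describeIn FeatureTable ionization polarity of the acquisition
#' @export
setMethod("ionMode", "FeatureTable", function(x, ...) metadata(x)$ionMode)

#' @describeIn FeatureTable optional text annotations
#' @export
setMethod("annotations", "FeatureTable", function(x, ...)
  stats::setNames(rowData(x)$annotation, rownames(x)))

#' @describeIn FeatureTable feature identifiers
#' @export
setMethod("featureIds", "FeatureTable", function(x, ...) rownames(x))

#' @describeIn FeatureTable per-feature maximum area across samples; this is
#'   the "area" used for base-peak selection, minimum-area filtering and the
#'   area weights of the identification cascade
#' @export
setMethod("maxAreas", "FeatureTable", function(x, ...) {
  a <- assay(x, "area")
  stats::setNames(apply(a, 1L, max), rownames(x))
})

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d features x %d samples (%s mode)\n",
              nrow(object), ncol(object), ionMode(object)))
  if (nrow(object)) {
    cat(sprintf("  m/z %.4f-%.4f, RT %.3f-%.3f min\n",
                min(rowData(object)$mz), max(rowData(object)$mz),
                min(rowData(object)$rt), max(rowData(object)$rt)))
  }
})

#' CliqueSet: features partitioned into per-metabolite cliques
#'
#' The result of [groupIons()]: a partition of the features of a
#' [FeatureTable-class] into cliques, each clique holding the ions (adducts,
#' fragments, isotopologues, dimers) attributed to one metabolite. Each clique
#' records its base peak (the member with the largest maximum area) and its
#' representative retention time. After [identifyCliques()] the
#' \code{pseudo} slot carries one row per clique with the identified
#' pseudomolecular ion.
#'
#' @slot cliques named list of character vectors of member feature ids.
#' @slot basePeak character vector, base-peak feature id per clique.
#' @slot rt numeric vector, representative retention time per clique.
#' @slot pseudo data.frame of identification results (possibly 0-row).
#' @slot params list of the grouping parameters used.
#' @export
setClass("CliqueSet",
         representation(cliques = "list", basePeak = "character",
                        rt = "numeric", pseudo = "data.frame",
                        params = "list"))

setValidity("CliqueSet", function(object) {
  msg <- character()
  k <- length(object@cliques)
  if (length(object@basePeak) != k || length(object@rt) != k)
    msg <- c(msg, "basePeak and rt must have one entry per clique")
  else if (k) {
    members <- unlist(object@cliques, use.names = FALSE)
    if (anyDuplicated(members))
      msg <- c(msg, "cliques must be disjoint")
    inClique <- mapply(function(m, b) b %in% m, object@cliques, object@basePeak)
    if (!all(inClique))
      msg <- c(msg, "every base peak must belong to its clique")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn CliqueSet the list of member-id vectors
#' @param x a \code{CliqueSet}
#' @export
setMethod("cliques", "CliqueSet", function(x, ...) x@cliques)

#' @describeIn CliqueSet base-peak feature id per clique
#' @export
setMethod("basePeaks", "CliqueSet", function(x, ...)
  stats::setNames(x@basePeak, names(x@cliques)))

#' @describeIn CliqueSet identification results (empty before
#'   [identifyCliques()])
#' @export
setMethod("pseudoIons", "CliqueSet", function(x, ...) x@pseudo)

#' @describeIn CliqueSet number of cliques
#' @export
setMethod("length", "CliqueSet", function(x) length(x@cliques))

setMethod("show", "CliqueSet", function(object) {
  sizes <- lengths(object@cliques)
  cat(sprintf("CliqueSet: %d cliques over %d features\n",
              length(sizes), sum(sizes)))
  if (length(sizes))
    cat(sprintf("  clique sizes: %d-%d (median %g)\n",
                min(sizes), max(sizes), stats::median(sizes)))
  if (nrow(object@pseudo))
    cat(sprintf("  pseudomolecular ions identified for %d cliques\n",
                nrow(object@pseudo)))
})

#' CorrelationResult: pairwise Pearson correlations with significance mask
#'
#' Symmetric matrices of Pearson coefficients and two-sided p-values over
#' metabolite concentration profiles, together with the significance policy
#' (level \code{alpha}, optionally Bonferroni-corrected over the
#' \eqn{k(k-1)/2} tested pairs) and the resulting boolean mask.
#'
#' @slot r symmetric correlation matrix, unit diagonal.
#' @slot p symmetric p-value matrix (diagonal not tested, stored as 0).
#' @slot nSamples number of samples the correlations were computed over.
#' @slot alpha nominal significance level.
#' @slot bonferroni whether alpha is divided by the number of tested pairs.
#' @slot significant symmetric logical mask, FALSE on the diagonal.
#' @export
setClass("CorrelationResult",
         representation(r = "matrix", p = "matrix", nSamples = "integer",
                        alpha = "numeric", bonferroni = "logical",
                        significant = "matrix"))

setValidity("CorrelationResult", function(object) {
  msg <- character()
  r <- object@r; p <- object@p
  if (!isTRUE(all.equal(r, t(r))) || !isTRUE(all.equal(p, t(p))))
    msg <- c(msg, "r and p must be symmetric")
  if (any(abs(r) > 1 + 1e-12))
    msg <- c(msg, "correlations must lie in [-1, 1]")
  if (max(abs(diag(r) - 1)) > 1e-12)
    msg <- c(msg, "diagonal of r must be 1")
  if (any(p < 0 | p > 1))
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (!identical(dim(r), dim(p)) || !identical(dim(r), dim(object@significant)))
    msg <- c(msg, "r, p and significant must share dimensions")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must lie in (0, 1)")
  if (any(diag(object@significant)))
    msg <- c(msg, "the diagonal is never significant")
  if (length(msg)) msg else TRUE
})

#' @describeIn CorrelationResult the Pearson coefficient matrix
#' @param x a \code{CorrelationResult}
#' @export
setMethod("corCoef", "CorrelationResult", function(x, ...) x@r)

#' @describeIn CorrelationResult the two-sided p-value matrix
#' @export
setMethod("corPValues", "CorrelationResult", function(x, ...) x@p)

#' @describeIn CorrelationResult the significance mask
#' @export
setMethod("isSignificant", "CorrelationResult", function(x, ...) x@significant)

setMethod("show", "CorrelationResult", function(object) {
  k <- nrow(object@r)
  nsig <- sum(object@significant[upper.tri(object@significant)])
  cat(sprintf(
    "CorrelationResult: %d profiles, n = %d samples\n  alpha = %g (%s), %d of %d pairs significant\n",
    k, object@nSamples, object@alpha,
    if (object@bonferroni) "Bonferroni" else "unadjusted",
    nsig, k * (k - 1) / 2))
})

#' NetworkModel: a weighted metabolite correlation network
#'
#' Nodes are metabolites (cliques) with at least one significant correlation;
#' node size is proportional to the base-peak area. Edges are significant
#' correlations carrying the Pearson r, its sign and the rescaled layout
#' weight in [0, 1]; the \code{displayed} flag marks the thinned edge set that
#' is drawn, while the layout always uses the full significant edge set.
#'
#' @slot nodes data.frame: id, label, mz, annotation, size.
#' @slot edges data.frame: from, to, r, p, sign, weight, displayed.
#' @slot coords numeric matrix of 2-D positions (empty until
#'   [layoutNetwork()]).
#' @slot metrics list of spatialization quality metrics (empty until
#'   [qualityMetrics()]).
#' @slot preset the clustering preset used for weight rescaling.
#' @export
setClass("NetworkModel",
         representation(nodes = "data.frame", edges = "data.frame",
                        coords = "matrix", metrics = "list", preset = "list"))

setValidity("NetworkModel", function(object) {
  msg <- character()
  e <- object@edges
  need <- c("from", "to", "r", "sign", "weight", "displayed")
  if (!all(need %in% colnames(e)))
    msg <- c(msg, paste("edges must contain columns:",
                        paste(need, collapse = ", ")))
  else if (nrow(e)) {
    if (any(e$weight < -1e-12 | e$weight > 1 + 1e-12))
      msg <- c(msg, "rescaled weights must lie in [0, 1]")
    if (!all(c(e$from, e$to) %in% object@nodes$id))
      msg <- c(msg, "edge endpoints must be nodes")
  }
  if (nrow(object@coords) && nrow(object@coords) != nrow(object@nodes))
    msg <- c(msg, "coords must have one row per node")
  if (length(msg)) msg else TRUE
})

#' @describeIn NetworkModel the node table
#' @param x a \code{NetworkModel}
#' @export
setMethod("nodes", "NetworkModel", function(x, ...) x@nodes)

#' @describeIn NetworkModel the edge table (full significant set;
#'   \code{displayed} marks drawn edges)
#' @export
setMethod("edges", "NetworkModel", function(x, ...) x@edges)

#' @describeIn NetworkModel 2-D node coordinates
#' @export
setMethod("layoutCoords", "NetworkModel", function(x, ...) x@coords)

#' @describeIn NetworkModel spatialization quality metrics
#' @export
setMethod("networkMetrics", "NetworkModel", function(x, ...) x@metrics)

setMethod("show", "NetworkModel", function(object) {
  cat(sprintf("NetworkModel: %d nodes, %d significant edges (%d displayed)\n",
              nrow(object@nodes), nrow(object@edges),
              sum(object@edges$displayed)))
  if (length(object@preset))
    cat(sprintf("  clustering preset: %s (s = %g, x = %g)\n",
                object@preset$name, object@preset$s, object@preset$x))
  if (nrow(object@coords)) cat("  layout: computed\n")
  if (length(object@metrics))
    cat(sprintf("  quality: mean silhouette %s, %d DBSCAN clusters\n",
                format(object@metrics$meanSilhouette, digits = 3),
                object@metrics$nClusters))
})
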