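#' Clustering presets for correlation rescaling
#'
#' A preset bundles the central scaling value \code{s} in (0, 1) that
#' separates positive from negative correlations in the rescaled weight
#' space, and the even exponent \code{x} that spreads correlations close to
#' \eqn{\pm 1}. The three presets trade cluster tightness:
#' \code{weak} (s = 0.5, x = 16), \code{normal} (s = 0.3, x = 8) and
#' \code{strong} (s = 0.1, x = 2).
#'
#' @param name preset name, or \code{"custom"} together with \code{s} and
#'   \code{x}.
#' @param s,x override values for a custom preset.
#' @return list with \code{name}, \code{s}, \code{x}.
#' @examples
#' clusteringPreset("strong")
#' @export
clusteringPreset <- function(name = c("normal", "weak", "strong", "custom"),
                             s = NULL, x = NULL) {
  name <- match.arg(name)
  preset <- switch(name,
    weak = list(name = "weak", s = 0.5, x = 16),
    normal = list(name = "normal", s = 0.3, x = 8),
    strong = list(name = "strong", s = 0.1, x = 2),
    custom = {
      stopifnot(!is.null(s), !is.null(x))
      list(name = "custom", s = s, x = x)
    })
  stopifnot(preset$s > 0, preset$s < 1, preset$x > 0)
  preset
}

#' Rescale a Pearson correlation into a layout weight
#'
#' The raw coefficient r is a poor force-directed edge weight: almost all
#' informative values crowd near \eqn{\pm 1}. The rescaling maps positive
#' correlations into \eqn{[0, s)} via \eqn{s (1 - |r|^x)} and non-positive
#' ones into \eqn{[s, 1]} via \eqn{s + |r|^x (1 - s)}, so that r = 1 gives
#' 0, r = 0 gives s and r = -1 gives 1. Used as the desired edge length,
#' small weights pull strongly correlated nodes together while
#' anti-correlated nodes are pushed apart. The map is continuous at 0 and
#' monotone non-increasing in r.
#'
#' @param r numeric vector of correlations in [-1, 1].
#' @param preset a [clusteringPreset()].
#' @return weights in [0, 1], same length as \code{r}.
#' @examples
#' rescaleWeight(c(1, 0, -1), clusteringPreset("normal"))
#' @export
rescaleWeight <- function(r, preset = clusteringPreset("normal")) {
  if (any(abs(r) > 1 + 1e-12))
    stop("correlations must lie in [-1, 1]")
  r <- pmin(pmax(r, -1), 1)
  s <- preset$s
  x <- preset$x
  ifelse(r > 0, s * (1 - abs(r)^x), s + abs(r)^x * (1 - s))
}

#' Thin the significant edge set for display
#'
#' Network clarity comes from drawing few edges: (1) every displayed node
#' shows its single strongest significant correlation (maximum |r|); (2) to
#' balance the signs, each node's strongest significant correlation of the
#' sign opposite to its primary edge is collected, these candidates are
#' ranked globally by |r|, and the top \eqn{\lceil N/3 \rceil} (N displayed
#' nodes) are also shown when they pass the significance level. Hidden edges
#' remain in the returned table with \code{displayed = FALSE}; the layout
#' always uses the full set, so thinning never moves nodes.
#'
#' @param x a [CorrelationResult-class] with the significance mask filled.
#' @return data.frame of all significant edges: \code{from, to, r, p, sign,
#'   displayed}.
#' @export
selectEdges <- function(x) {
  stopifnot(is(x, "CorrelationResult"))
  sig <- isSignificant(x)
  r <- corCoef(x)
  p <- corPValues(x)
  ids <- rownames(r)
  disp <- which(rowSums(sig) > 0)
  ut <- which(sig & upper.tri(sig), arr.ind = TRUE)
  edges <- data.frame(
    from = ids[ut[, 1L]], to = ids[ut[, 2L]],
    r = r[ut], p = p[ut],
    sign = ifelse(r[ut] > 0, "positive", "negative"),
    displayed = FALSE, stringsAsFactors = FALSE)
  if (!nrow(edges))
    return(edges)
  key <- paste(pmin(ut[, 1L], ut[, 2L]), pmax(ut[, 1L], ut[, 2L]))

  primarySign <- stats::setNames(numeric(length(disp)), disp)
  shown <- character()
  for (n in disp) {
    partners <- which(sig[n, ])
    j <- partners[which.max(abs(r[n, partners]))]
    shown <- c(shown, paste(min(n, j), max(n, j)))
    primarySign[as.character(n)] <- sign(r[n, j])
  }
  oppKey <- character(); oppAbs <- numeric()
  for (n in disp) {
    partners <- which(sig[n, ])
    opp <- partners[sign(r[n, partners]) != primarySign[as.character(n)]]
    if (!length(opp)) next
    j <- opp[which.max(abs(r[n, opp]))]
    oppKey <- c(oppKey, paste(min(n, j), max(n, j)))
    oppAbs <- c(oppAbs, abs(r[n, j]))
  }
  if (length(oppKey)) {
    # several nodes may nominate the same pair; a pair counts once
    keep <- !duplicated(oppKey)
    oppKey <- oppKey[keep]; oppAbs <- oppAbs[keep]
    quota <- ceiling(length(disp) / 3)
    take <- order(-oppAbs)[seq_len(min(quota, length(oppKey)))]
    shown <- c(shown, oppKey[take])
  }
  edges$displayed <- key %in% shown
  edges
}

#' Build a network model from a correlation result
#'
#' Nodes are the profiles with at least one significant correlation; edges
#' are all significant pairs, carrying the rescaled layout weight and the
#' display flag from [selectEdges()].
#'
#' @param x a [CorrelationResult-class].
#' @param labels node labels (named by profile id, or in profile order);
#'   defaults to the profile ids.
#' @param sizes node sizes, proportional to the base-peak area in the
#'   pipeline; defaults to 1.
#' @param mzValues optional numeric m/z per node (for export).
#' @param annotation optional text annotation per node.
#' @param preset a [clusteringPreset()] for weight rescaling.
#' @return a [NetworkModel-class] (no layout yet).
#' @export
buildNetwork <- function(x, labels = NULL, sizes = NULL, mzValues = NULL,
                         annotation = NULL,
                         preset = clusteringPreset("normal")) {
  stopifnot(is(x, "CorrelationResult"))
  ids <- rownames(corCoef(x))
  pick <- function(v, default) {
    if (is.null(v)) return(rep(default, length(ids)))
    if (!is.null(names(v))) v <- v[ids]
    unname(v)
  }
  labv <- pick(labels, NA); labv[is.na(labv)] <- ids[is.na(labv)]
  nodesAll <- data.frame(
    id = ids, label = as.character(labv),
    mz = as.numeric(pick(mzValues, NA_real_)),
    annotation = as.character(pick(annotation, NA_character_)),
    size = as.numeric(pick(sizes, 1)),
    stringsAsFactors = FALSE)
  keep <- rowSums(isSignificant(x)) > 0
  edges <- selectEdges(x)
  edges$weight <- rescaleWeight(edges$r, preset)
  new("NetworkModel", nodes = nodesAll[keep, , drop = FALSE], edges = edges,
      coords = matrix(numeric(0), 0, 2), metrics = list(), preset = preset)
}

#' Force-directed spatialization of the network
#'
#' Positions nodes so that the inter-node distances approximate the rescaled
#' edge weights used as desired edge lengths (small weight = strongly
#' correlated = close). Target distances between all node pairs are taken as
#' shortest weighted paths over the \emph{full} significant edge set —
#' hiding edges therefore never changes coordinates — and the configuration
#' is obtained by stress majorization from a classical-scaling start with a
#' small seeded jitter, which makes the layout fully reproducible for a
#' given seed while allowing organic run-to-run variability with
#' \code{seed = NULL}-style random seeds chosen by the caller.
#'
#' @param model a [NetworkModel-class].
#' @param iterations number of majorization sweeps; the default scales with
#'   the number of displayed nodes N as \code{10 * ceiling(N / 83)}.
#' @param seed integer seed for the jittered start.
#' @return the model with 2-D coordinates filled in.
#' @export
layoutNetwork <- function(model, iterations = NULL, seed = 0) {
  stopifnot(is(model, "NetworkModel"))
  n <- nrow(model@nodes)
  if (n == 0L)
    stop("empty graph: no nodes to lay out")
  if (is.null(iterations))
    iterations <- 10L * as.integer(ceiling(n / 83))
  ids <- model@nodes$id
  if (n == 1L) {
    model@coords <- matrix(0, 1, 2, dimnames = list(ids, c("x", "y")))
    return(model)
  }
  e <- model@edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$from, to = e$to,
               weight = pmax(e$weight, 1e-3)),
    directed = FALSE, vertices = data.frame(name = ids))
  D <- igraph::distances(g)
  D <- D[ids, ids, drop = FALSE]
  finite <- D[is.finite(D) & D > 0]
  gap <- if (length(finite)) 1.5 * max(finite) else 1
  D[!is.finite(D)] <- gap

  X <- tryCatch(cmdscale(D, k = 2), error = function(e) NULL)
  if (is.null(X) || ncol(X) < 2L) {
    X0 <- matrix(0, n, 2)
    if (!is.null(X) && ncol(X) >= 1L) X0[, 1L] <- X[, 1L]
    X <- X0
  }
  set.seed(seed)
  X <- X + matrix(rnorm(n * 2, sd = 0.01 * (max(D) + 1e-9)), n, 2)
  for (it in seq_len(iterations)) {
    dd <- as.matrix(dist(X))
    ratio <- ifelse(dd > 0, D / dd, 0)
    diag(ratio) <- 0
    B <- -ratio
    diag(B) <- rowSums(ratio)
    X <- B %*% X / n
  }
  dimnames(X) <- list(ids, c("x", "y"))
  model@coords <- X
  model
}

#' DBSCAN cluster labels on 2-D coordinates
#'
#' Plain density-based clustering: points with at least \code{minPts}
#' neighbours within \code{eps} (the point itself counts) are core points;
#' clusters grow by density-reachability from cores; remaining points are
#' noise (label 0).
#'
#' @param coords numeric matrix of 2-D positions.
#' @param eps neighbourhood radius.
#' @param minPts minimum neighbourhood size of a core point.
#' @return integer labels, 0 for noise.
#' @export
dbscanLabels <- function(coords, eps, minPts = 3) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- lengths(nb) >= minPts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    while (length(queue)) {
      p <- queue[1L]
      queue <- queue[-1L]
      for (q in nb[[p]]) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

#' Spatialization quality metrics
#'
#' Scores a 2-D layout by clustering it with DBSCAN and averaging the
#' silhouette width over the non-noise points (Euclidean distance). The
#' cluster count excludes noise; with fewer than 2 clusters the silhouette
#' is undefined and reported as \code{NA}.
#'
#' @param x a [NetworkModel-class] with coordinates, or a coordinate matrix
#'   (at least 3 points).
#' @param eps DBSCAN radius; default 0.08 times the bounding-box diagonal of
#'   the layout.
#' @param minPts DBSCAN core-point threshold.
#' @return for a matrix: list with \code{meanSilhouette}, \code{nClusters},
#'   \code{labels}, \code{eps}, \code{minPts}. For a \code{NetworkModel}:
#'   the model with its \code{metrics} slot filled.
#' @export
qualityMetrics <- function(x, eps = NULL, minPts = 3) {
  if (is(x, "NetworkModel")) {
    stopifnot(nrow(x@coords) > 0L)
    x@metrics <- qualityMetrics(x@coords, eps = eps, minPts = minPts)
    return(x)
  }
  coords <- as.matrix(x)
  if (nrow(coords) < 3L)
    stop("at least 3 nodes are required")
  if (is.null(eps)) {
    diag_ <- sqrt(diff(range(coords[, 1L]))^2 + diff(range(coords[, 2L]))^2)
    eps <- 0.08 * diag_
  }
  labels <- dbscanLabels(coords, eps = eps, minPts = minPts)
  nClusters <- length(setdiff(unique(labels), 0L))
  meanSil <- NA_real_
  inCl <- labels > 0L
  if (nClusters >= 2L && sum(inCl) >= 3L) {
    sil <- cluster::silhouette(labels[inCl], dist(coords[inCl, , drop = FALSE]))
    meanSil <- mean(sil[, "sil_width"])
  }
  list(meanSilhouette = meanSil, nClusters = nClusters, labels = labels,
       eps = eps, minPts = minPts)
}

#' Export the network
#'
#' Writes the model as machine-readable GraphML (canonical), node/edge TSVs,
#' or an image (\code{png}, \code{pdf}, \code{tif}, \code{svg}) drawing the
#' displayed edges coloured by correlation sign and nodes sized by
#' base-peak area.
#'
#' @param model a [NetworkModel-class] (laid out, for image formats).
#' @param path output file path.
#' @param format one of \code{"graphml"}, \code{"edge_tsv"}, \code{"png"},
#'   \code{"pdf"}, \code{"tif"}, \code{"svg"}.
#' @param palette length-2 named colour vector for positive/negative edges.
#' @return the path, invisibly.
#' @export
exportNetwork <- function(model, path,
                          format = c("graphml", "edge_tsv", "png", "pdf",
                                     "tif", "svg"),
                          palette = c(positive = "forestgreen",
                                      negative = "firebrick")) {
  stopifnot(is(model, "NetworkModel"))
  supported <- c("graphml", "edge_tsv", "png", "pdf", "tif", "svg")
  if (!is.character(format) || !format[1L] %in% supported)
    stop("unknown format '", format[1L], "'; supported: ",
         paste(supported, collapse = ", "))
  format <- format[1L]
  if (format == "graphml") {
    nd <- model@nodes
    nd$annotation[is.na(nd$annotation)] <- ""
    nd$mz[is.na(nd$mz)] <- 0
    g <- igraph::graph_from_data_frame(model@edges, directed = FALSE,
                                       vertices = nd)
    if (nrow(model@coords)) {
      igraph::V(g)$x <- model@coords[nd$id, 1L]
      igraph::V(g)$y <- model@coords[nd$id, 2L]
    }
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "edge_tsv") {
    write.table(model@edges, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    nodePath <- paste0(tools::file_path_sans_ext(path), "-nodes.tsv")
    nd <- model@nodes
    if (nrow(model@coords)) {
      nd$x <- model@coords[nd$id, 1L]
      nd$y <- model@coords[nd$id, 2L]
    }
    write.table(nd, nodePath, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "")
  } else {
    if (!nrow(model@coords))
      stop("image export requires a layout; run layoutNetwork() first")
    opener <- switch(format,
      png = function(p) grDevices::png(p, width = 1600, height = 1600,
                                       res = 200),
      pdf = function(p) grDevices::pdf(p, width = 8, height = 8),
      svg = function(p) grDevices::svg(p, width = 8, height = 8),
      tif = function(p) grDevices::tiff(p, width = 1600, height = 1600,
                                        res = 200))
    opener(path)
    on.exit(grDevices::dev.off(), add = TRUE)
    .plotNetwork(model, palette)
  }
  invisible(path)
}

.plotNetwork <- function(model, palette = c(positive = "forestgreen",
                                            negative = "firebrick")) {
  co <- model@coords
  nd <- model@nodes
  e <- model@edges[model@edges$displayed, , drop = FALSE]
  graphics::par(mar = c(1, 1, 2, 1))
  graphics::plot(co, type = "n", axes = FALSE, xlab = "", ylab = "",
                 asp = 1, main = sprintf("%d nodes / %d displayed edges",
                                         nrow(nd), nrow(e)))
  if (nrow(e))
    graphics::segments(co[e$from, 1L], co[e$from, 2L],
                       co[e$to, 1L], co[e$to, 2L],
                       col = palette[e$sign], lwd = 1.2)
  cexs <- 0.6 + 1.8 * sqrt(nd$size / max(nd$size))
  graphics::points(co[nd$id, , drop = FALSE], pch = 21, bg = "grey85",
                   cex = cexs)
  graphics::text(co[nd$id, , drop = FALSE], labels = nd$label, cex = 0.45,
                 pos = 3, offset = 0.25)
  invisible(NULL)
}
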