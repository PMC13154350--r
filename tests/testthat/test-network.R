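test_that("weight rescaling pins its endpoints and centre for all presets", {
  for (name in c("weak", "normal", "strong")) {
    pr <- clusteringPreset(name)
    expect_equal(rescaleWeight(1, pr), 0)
    expect_equal(rescaleWeight(-1, pr), 1)
    expect_equal(rescaleWeight(0, pr), pr$s)
  }
  expect_equal(clusteringPreset("weak")[c("s", "x")], list(s = 0.5, x = 16))
  expect_equal(clusteringPreset("normal")[c("s", "x")], list(s = 0.3, x = 8))
  expect_equal(clusteringPreset("strong")[c("s", "x")], list(s = 0.1, x = 2))
  expect_error(rescaleWeight(1.2), "\\[-1, 1\\]")
})

test_that("rescaling is monotone non-increasing and continuous at zero", {
  grid <- seq(-1, 1, length.out = 2001)
  for (name in c("weak", "normal", "strong")) {
    pr <- clusteringPreset(name)
    w <- rescaleWeight(grid, pr)
    expect_true(all(diff(w) <= 1e-12))
    expect_true(all(w >= 0 & w <= 1))
    expect_equal(rescaleWeight(1e-12, pr), pr$s, tolerance = 1e-6)
    expect_equal(rescaleWeight(-1e-12, pr), pr$s, tolerance = 1e-6)
  }
})


test_that("every node shows its strongest correlation, plus a one-third quota
           of opposite-sign edges", {
  # two nodes, one significant pair -> exactly one displayed edge
  r2 <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  s2 <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2)
  e2 <- selectEdges(directCorrelation(r2, s2))
  expect_equal(sum(e2$displayed), 1L)

  res <- bothSignsFixture()
  e <- selectEdges(res)
  shown <- e[e$displayed, ]
  # 15 disjoint positive primaries + ceil(30/3) = 10 opposite-sign edges
  expect_equal(sum(shown$sign == "positive"), 15L)
  expect_equal(sum(shown$sign == "negative"), 10L)
  # the strongest negatives win the quota
  expect_equal(sort(-shown$r[shown$sign == "negative"]),
               0.5 + 0.01 * (6:15), tolerance = 1e-12)
})

test_that("primary edges equal the per-node argmax-|r| oracle", {
  set.seed(12)
  pr <- matrix(rnorm(12 * 10), 12, 10,
               dimnames = list(paste0("m", 1:12), NULL))
  res <- pearsonMatrix(pr, alpha = 0.3)      # permissive: dense mask
  e <- selectEdges(res)
  r <- corCoef(res); sig <- isSignificant(res)
  ids <- rownames(r)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  shownKeys <- key(e$from[e$displayed], e$to[e$displayed])
  for (n in which(rowSums(sig) > 0)) {
    partners <- which(sig[n, ])
    best <- partners[which.max(abs(r[n, partners]))]
    expect_true(key(ids[n], ids[best]) %in% shownKeys)
  }
  # displayed degree >= 1 for every displayed node; count within bounds
  dispNodes <- ids[rowSums(sig) > 0]
  N <- length(dispNodes)
  deg <- table(c(e$from[e$displayed], e$to[e$displayed]))
  expect_true(all(dispNodes %in% names(deg)))
  expect_gte(sum(e$displayed), ceiling(N / 2))
  expect_lte(sum(e$displayed), N + ceiling(N / 3))
})

test_that("the layout is seeded, deterministic, and ignores edge hiding", {
  set.seed(21)
  spec <- syntheticSpec(nMetabolites = 12, blocks = rep(1:2, each = 6),
                        withinR = 0.9, betweenR = -0.7, seed = 77)
  ds <- makeSyntheticDataset(spec)
  run <- runPipeline(table = ds$table, minArea = 0, alpha = 0.05,
                     verbose = FALSE)
  net <- run$network
  again <- layoutNetwork(net, seed = 0)
  expect_identical(layoutCoords(again), layoutCoords(net))
  expect_false(identical(layoutCoords(layoutNetwork(net, seed = 1)),
                         layoutCoords(net)))
  # hiding edges never moves nodes
  hidden <- net
  hidden@edges$displayed <- FALSE
  expect_identical(layoutCoords(layoutNetwork(hidden, seed = 0)),
                   layoutCoords(net))
})

test_that("a positive edge pulls harder than an equal-magnitude negative one", {
  mk <- function(rv) {
    r <- matrix(c(1, rv, rv, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
    s <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2)
    m <- buildNetwork(directCorrelation(r, s), preset = clusteringPreset("normal"))
    co <- layoutCoords(layoutNetwork(m, seed = 0))
    sqrt(sum((co[1, ] - co[2, ])^2))
  }
  expect_lt(mk(0.9), mk(-0.9))
})

test_that("DBSCAN labels match a density-reachability oracle and score blobs", {
  set.seed(30)
  for (i in 1:5) {
    pts <- rbind(matrix(rnorm(16, 0, 0.3), ncol = 2),
                 matrix(rnorm(14, 5, 0.3), ncol = 2),
                 matrix(runif(10, -3, 8), ncol = 2))
    eps <- 1.0
    got <- dbscanLabels(pts, eps = eps, minPts = 3)
    want <- oracleDbscan(pts, eps = eps, minPts = 3)
    # same partition up to label names, same noise set
    expect_equal(got == 0, want == 0)
    expect_equal(outer(got, got, "=="), outer(want, want, "=="))
  }

  blobs <- rbind(matrix(rnorm(20, 0, 0.05), ncol = 2),
                 matrix(rnorm(20, 3, 0.05), ncol = 2))
  qm <- qualityMetrics(blobs, minPts = 3)
  expect_equal(qm$nClusters, 2L)
  expect_gt(qm$meanSilhouette, 0.9)

  one <- matrix(runif(30), ncol = 2)
  qm1 <- qualityMetrics(one, eps = 2, minPts = 3)
  expect_equal(qm1$nClusters, 1L)
  expect_true(is.na(qm1$meanSilhouette))
})

test_that("GraphML export round-trips and formats are validated", {
  spec <- syntheticSpec(nMetabolites = 8, blocks = rep(1:2, each = 4),
                        withinR = 0.9, betweenR = -0.7, seed = 5)
  run <- runPipeline(table = makeSyntheticDataset(spec)$table, minArea = 0,
                     alpha = 0.05, verbose = FALSE)
  dir <- withr::local_tempdir()
  gp <- file.path(dir, "net.graphml")
  exportNetwork(run$network, gp, "graphml")
  g <- igraph::read_graph(gp, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(nodes(run$network)))
  expect_equal(igraph::ecount(g), nrow(edges(run$network)))
  expect_true(all(c("r", "weight", "sign", "displayed") %in%
                    igraph::edge_attr_names(g)))

  ep <- file.path(dir, "net.tsv")
  exportNetwork(run$network, ep, "edge_tsv")
  expect_true(file.exists(ep) && file.exists(file.path(dir, "net-nodes.tsv")))
  pp <- file.path(dir, "net.png")
  exportNetwork(run$network, pp, "png")
  expect_gt(file.size(pp), 0)
  expect_error(exportNetwork(run$network, "x.foo", "foo"), "supported")
})
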