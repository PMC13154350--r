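# Independent oracles and small fixture builders. These deliberately
# re-derive results from first principles (plain loops, textbook formulas)
# and never call the code paths they check.

PROTON <- 1.00727646688
C13 <- 1.0033548378

# a feature table with arbitrary areas and retention times
simpleTable <- function(mz, rt, areas, mode = "negative", ids = NULL) {
  FeatureTable(mz = mz, rt = rt, areas = areas, mode = mode, ids = ids)
}

# area vectors with an analytically fixed ratio RSD against a unit base:
# ratios 1 + rsd * z with z standardized, so sd/mean is exactly rsd
areasWithRSD <- function(rsd, n = 12) {
  z <- as.numeric(scale(seq_len(n)))
  1 + rsd * z
}

# brute-force greedy grouping, re-derived step by step
oracleGrouping <- function(mzv, rtv, areaMat, rtShift, rsdMax) {
  n <- length(mzv)
  amax <- apply(areaMat, 1, max)
  left <- seq_len(n)
  out <- list()
  while (length(left)) {
    ord <- left[order(-amax[left], mzv[left], left)]
    b <- ord[1]
    members <- c()
    for (i in left) {
      if (abs(rtv[i] - rtv[b]) > rtShift) next
      if (i == b) { members <- c(members, i); next }
      use <- areaMat[b, ] > 0
      if (sum(use) < 3) next
      ratios <- areaMat[i, use] / areaMat[b, use]
      if (mean(ratios) == 0) next
      if (sd(ratios) / mean(ratios) <= rsdMax) members <- c(members, i)
    }
    out[[length(out) + 1]] <- list(base = b, members = sort(members))
    left <- setdiff(left, members)
  }
  out
}

# exhaustive pair x rule accumulation of identification weights
oracleWeightMap <- function(feat, rules, er) {
  baseArea <- max(feat$area)
  implied <- c(); total <- c()
  n <- nrow(feat)
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    L <- min(feat$mz[i], feat$mz[j]); H <- max(feat$mz[i], feat$mz[j])
    for (k in seq_len(nrow(rules))) {
      ok <- if (rules$kind[k] == "dimer") {
        expH <- if (rules$mode[k] == "negative") 2 * L + PROTON else 2 * L - PROTON
        abs(H - expH) <= er
      } else abs((H - L) - rules$deltaMz[k]) <= er
      if (!ok) next
      implied <- c(implied, L + rules$impliedOffset[k])
      total <- c(total, rules$wr[k] + (feat$area[i] + feat$area[j]) / baseArea)
    }
  }
  if (!length(implied))
    return(data.frame(impliedMz = numeric(), totalWeight = numeric()))
  ord <- order(implied)
  grp <- cumsum(c(0, diff(implied[ord]) > er))
  agg <- tapply(total[ord], grp, sum)
  data.frame(impliedMz = as.numeric(tapply(implied[ord], grp, mean)),
             totalWeight = as.numeric(agg))
}

# textbook Pearson r and two-sided p from explicit sums
oraclePearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  r <- num / den
  t <- abs(r) * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * (1 - pt(t, n - 2)))
}

# naive DBSCAN by repeated density-reachability closure
oracleDbscan <- function(coords, eps, minPts) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  core <- sapply(seq_len(n), function(i) sum(d[i, ] <= eps) >= minPts)
  labels <- integer(n)
  cl <- 0
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0) next
    cl <- cl + 1
    members <- i
    repeat {
      reach <- unique(unlist(lapply(members[core[members]],
                                    function(p) which(d[p, ] <= eps))))
      reach <- setdiff(reach, members)
      reach <- reach[labels[reach] == 0]
      if (!length(reach)) break
      members <- c(members, reach)
    }
    labels[members] <- cl
  }
  labels
}

# hand-built correlation result with a fully controlled r matrix
directCorrelation <- function(r, sigMask, n = 12, alpha = 0.01) {
  k <- nrow(r)
  p <- matrix(1, k, k, dimnames = dimnames(r))
  p[sigMask] <- alpha / 10
  p <- pmin(p, t(p)); diag(p) <- 0
  sig <- p <= alpha; diag(sig) <- FALSE
  new("CorrelationResult", r = r, p = p, nSamples = as.integer(n),
      alpha = alpha, bonferroni = FALSE, significant = sig)
}

# 30 nodes: positive primary pairs within halves, one graded negative edge
# per node across halves, primary and opposite pairs disjoint
bothSignsFixture <- function() {
  k <- 30
  r <- matrix(0, k, k, dimnames = list(paste0("n", 1:k), paste0("n", 1:k)))
  sig <- matrix(FALSE, k, k)
  for (i in seq(1, k, by = 2)) {          # positive pairs (1,2), (3,4), ...
    r[i, i + 1] <- r[i + 1, i] <- 0.95
    sig[i, i + 1] <- sig[i + 1, i] <- TRUE
  }
  for (i in 1:15) {                       # negative pairs (i, i+15)
    r[i, i + 15] <- r[i + 15, i] <- -(0.5 + 0.01 * i)
    sig[i, i + 15] <- sig[i + 15, i] <- TRUE
  }
  diag(r) <- 1
  directCorrelation(r, sig)
}
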