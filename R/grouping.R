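#' Relative standard deviation of the member-to-base area ratio
#'
#' For two features sharing the sample index, computes the per-sample ratios
#' \eqn{r_k = a_{cand,k} / a_{base,k}} over the samples where the base area
#' is positive and returns their relative standard deviation
#' \eqn{sd(r_k)/mean(r_k)}. Ions of one metabolite keep a constant intensity
#' ratio across samples, so a small RSD is the grouping evidence. The RSD is
#' undefined (\code{NA}) when fewer than 3 samples are usable or the mean
#' ratio is 0; an undefined RSD never groups.
#'
#' @param candidate,base numeric vectors of per-sample peak areas.
#' @return the RSD as a fraction, or \code{NA_real_} when undefined.
#' @examples
#' ratioRSD(c(5, 10, 20), c(10, 20, 40))   # constant ratio -> 0
#' @export
ratioRSD <- function(candidate, base) {
  if (length(candidate) != length(base))
    stop("candidate and base must share the sample index")
  use <- base > 0
  if (sum(use) < 3L)
    return(NA_real_)
  ratios <- candidate[use] / base[use]
  m <- mean(ratios)
  if (m == 0)
    return(NA_real_)
  sd(ratios) / m
}

#' Group co-eluting ions into per-metabolite cliques
#'
#' Greedy clique extraction: the remaining feature with the largest maximum
#' area becomes the base peak and is grouped with every remaining feature
#' that (i) elutes at the same retention time within \code{rtShift} and (ii)
#' keeps a stable area ratio to the base peak across samples
#' ([ratioRSD()] at most \code{rsdMax}). The clique is removed and the
#' procedure repeats until no feature is left, so the result is always a
#' partition of the feature set. Ties for the largest area break towards the
#' lower m/z, then input order, making the partition deterministic.
#'
#' @param x a [FeatureTable-class].
#' @param rtShift maximum retention-time difference to the base peak (min),
#'   two-sided and inclusive.
#' @param rsdMax maximum ratio RSD (fraction in (0, 1)).
#' @param enabled with \code{FALSE}, every feature becomes a singleton clique
#'   (grouping off).
#' @return a [CliqueSet-class]; cliques are named \code{Q0001}, ... in
#'   extraction order (base-peak areas non-increasing).
#' @examples
#' ft <- FeatureTable(mz = c(339.07, 679.15, 120.0), rt = c(5.1, 5.1, 2.0),
#'                    areas = rbind(c(10, 20, 40), c(3, 6, 12), c(5, 5, 5)),
#'                    mode = "negative")
#' groupIons(ft, rtShift = 0.02, rsdMax = 0.25)
#' @export
groupIons <- function(x, rtShift = 0.02, rsdMax = 0.25, enabled = TRUE) {
  stopifnot(is(x, "FeatureTable"), nrow(x) > 0L,
            rtShift >= 0, rsdMax > 0, rsdMax < 1)
  ids <- featureIds(x)
  a <- areas(x)
  mzv <- unname(mz(x))
  rtv <- unname(rt(x))
  amax <- apply(a, 1L, max)

  if (!enabled) {
    cl <- as.list(ids)
    names(cl) <- sprintf("Q%04d", seq_along(cl))
    return(new("CliqueSet", cliques = cl, basePeak = ids, rt = rtv,
               pseudo = data.frame(),
               params = list(rtShift = rtShift, rsdMax = rsdMax,
                             enabled = FALSE)))
  }

  remaining <- order(-amax, mzv, seq_along(ids))
  cliquesL <- list()
  bases <- character()
  rts <- numeric()
  while (length(remaining)) {
    b <- remaining[1L]
    inRt <- abs(rtv[remaining] - rtv[b]) <= rtShift
    cand <- remaining[inRt]
    rsd <- vapply(cand, function(i) {
      if (i == b) 0 else ratioRSD(a[i, ], a[b, ])
    }, numeric(1))
    memberIdx <- cand[!is.na(rsd) & rsd <= rsdMax]
    cliquesL[[length(cliquesL) + 1L]] <- ids[sort(memberIdx)]
    bases <- c(bases, ids[b])
    rts <- c(rts, rtv[b])
    remaining <- setdiff(remaining, memberIdx)
  }
  names(cliquesL) <- sprintf("Q%04d", seq_along(cliquesL))
  new("CliqueSet", cliques = cliquesL, basePeak = bases, rt = rts,
      pseudo = data.frame(),
      params = list(rtShift = rtShift, rsdMax = rsdMax, enabled = TRUE))
}

# Per-clique representation used by the identification cascade: one row per
# member with its m/z and maximum area across samples.
.cliqueFrame <- function(x, memberIds) {
  data.frame(id = memberIds,
             mz = unname(mz(x)[memberIds]),
             area = unname(maxAreas(x)[memberIds]),
             stringsAsFactors = FALSE)
}

#' Per-clique concentration profiles
#'
#' Returns the matrix (cliques x samples) of the base-peak area vectors: the
#' base peak carries the strongest signal of its clique and therefore the
#' most precise concentration profile, so it represents the metabolite in
#' the correlation stage.
#'
#' @param x a [FeatureTable-class].
#' @param cs a [CliqueSet-class] over the same table.
#' @return numeric matrix with one row per clique.
#' @export
cliqueProfiles <- function(x, cs) {
  stopifnot(is(x, "FeatureTable"), is(cs, "CliqueSet"))
  p <- areas(x)[cs@basePeak, , drop = FALSE]
  rownames(p) <- names(cliques(cs))
  p
}
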