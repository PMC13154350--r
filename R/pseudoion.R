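#' Collapse isotopologue envelopes within a clique
#'
#' Features are sorted by m/z in descending order and chained into
#' subclusters while every consecutive gap is at most \code{isoWindow + er}
#' Da; each subcluster is then represented by its most abundant member. This
#' removes isotopic peaks and closely co-eluting ions (gaps around 1 Da)
#' before the mass-difference arithmetic. The most abundant feature of the
#' clique always survives.
#'
#' @param features data.frame with columns \code{id}, \code{mz},
#'   \code{area} (maximum area across samples), as built per clique by the
#'   identification driver.
#' @param er m/z measurement error (Da).
#' @param isoWindow isotope-collapse gap (Da); the default 1.008 covers the
#'   13C and 2H mass shifts.
#' @return the surviving features, sorted by decreasing m/z.
#' @examples
#' fx <- data.frame(id = c("a", "b", "c"),
#'                  mz = c(341.09, 340.083, 339.077),
#'                  area = c(1, 10, 100))
#' collapseIsotopes(fx, er = 0)
#' @export
collapseIsotopes <- function(features, er = 0.016, isoWindow = 1.008) {
  stopifnot(is.data.frame(features), nrow(features) > 0L, er >= 0,
            isoWindow > 0)
  f <- features[order(-features$mz), , drop = FALSE]
  if (nrow(f) == 1L)
    return(f)
  gaps <- -diff(f$mz)
  sub <- cumsum(c(0, gaps > isoWindow + er))
  keep <- vapply(split(seq_len(nrow(f)), sub), function(ix) {
    ix[which.max(f$area[ix])]
  }, integer(1))
  f[sort(keep), , drop = FALSE]
}

.basePeakRow <- function(features) {
  # largest area, ties towards lower m/z
  ord <- order(-features$area, features$mz)
  features[ord[1L], , drop = FALSE]
}

# Signed proton offset of the dimer relation: in negative mode
# [2M-H]- = 2 [M-H]- + H+, in positive mode [2M+H]+ = 2 [M+H]+ - H+.
.dimerExpectedH <- function(L, mode) {
  if (mode == "negative") 2 * L + PROTON_MASS else 2 * L - PROTON_MASS
}

#' Match pairwise mass differences against the rule system
#'
#' Every unordered pair of (isotope-collapsed) clique members is compared to
#' every rule; a rule matching within \code{er} contributes the total weight
#' \eqn{w_r + w_a} to the pseudomolecular m/z it implies, where \eqn{w_r} is
#' the predefined rule weight and \eqn{w_a = (A_i + A_j) / A_{base}} is the
#' sum of the two feature areas normalized to the base-peak area (areas are
#' maxima across samples). Weights of all matched pairs supporting the same
#' implied m/z (within \code{er}) accumulate, so multiply supported ions win.
#'
#' @inheritParams collapseIsotopes
#' @param rules adduct rule table ([adductRules()] or a user-edited one).
#' @param er m/z tolerance (Da) for both the rule match and the grouping of
#'   implied m/z values.
#' @return list with \code{matches} (one row per pair x rule match:
#'   \code{idLow, idHigh, label, wr, wa, total, impliedMz}) and \code{map}
#'   (accumulated weight per implied ion, sorted by decreasing
#'   \code{totalWeight}).
#' @export
matchMassDifferences <- function(features, rules, er = 0.016) {
  stopifnot(is.data.frame(features), er >= 0)
  .checkAdductRules(rules)
  empty <- list(
    matches = data.frame(idLow = character(), idHigh = character(),
                         label = character(), wr = numeric(),
                         wa = numeric(), total = numeric(),
                         impliedMz = numeric(), stringsAsFactors = FALSE),
    map = data.frame(impliedMz = numeric(), totalWeight = numeric(),
                     nMatches = integer()))
  n <- nrow(features)
  if (n < 2L || !nrow(rules))
    return(empty)
  baseArea <- max(features$area)
  rows <- vector("list", 0L)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    lo <- if (features$mz[i] < features$mz[j]) i else j
    hi <- if (lo == i) j else i
    L <- features$mz[lo]; H <- features$mz[hi]
    for (k in seq_len(nrow(rules))) {
      hit <- if (rules$kind[k] == "dimer") {
        abs(H - .dimerExpectedH(L, rules$mode[k])) <= er
      } else {
        abs((H - L) - rules$deltaMz[k]) <= er
      }
      if (!hit) next
      wa <- (features$area[lo] + features$area[hi]) / baseArea
      rows[[length(rows) + 1L]] <- data.frame(
        idLow = features$id[lo], idHigh = features$id[hi],
        label = rules$label[k], wr = rules$wr[k], wa = wa,
        total = rules$wr[k] + wa,
        impliedMz = L + rules$impliedOffset[k],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(empty)
  matches <- do.call(rbind, rows)
  ord <- order(matches$impliedMz)
  grp <- cumsum(c(0, diff(matches$impliedMz[ord]) > er))
  map <- do.call(rbind, lapply(split(ord, grp), function(ix) {
    data.frame(impliedMz = mean(matches$impliedMz[ix]),
               totalWeight = sum(matches$total[ix]),
               nMatches = length(ix))
  }))
  map <- map[order(-map$totalWeight, map$impliedMz), , drop = FALSE]
  rownames(map) <- NULL
  list(matches = matches, map = map)
}

#' Candidate #1: best rule-supported ion detected in the clique
#'
#' Considers the implied pseudomolecular ions of the weight map in order of
#' decreasing total weight and returns the first one that (a) lies at or
#' above the base-peak m/z, (b) is supported by at least one rule match and
#' (c) was actually detected, i.e. a clique member lies within \code{er} of
#' the implied m/z. Invoked only when the best total weight falls short of
#' the direct-acceptance threshold; with no qualifying ion there is no
#' candidate #1.
#'
#' @param map the \code{map} element of [matchMassDifferences()].
#' @inheritParams collapseIsotopes
#' @return a one-row data.frame (the detected feature), or \code{NULL}.
#' @export
candidate1 <- function(map, features, er = 0.016) {
  if (!nrow(map))
    return(NULL)
  baseMz <- .basePeakRow(features)$mz
  for (k in seq_len(nrow(map))) {
    implied <- map$impliedMz[k]
    if (implied < baseMz - er) next
    d <- abs(features$mz - implied)
    if (min(d) <= er)
      return(features[which.min(d), , drop = FALSE])
  }
  NULL
}

#' Candidate #2: neutral-loss parent of the base peak
#'
#' Assumes the base peak is a stable fragment: the m/z differences between
#' the base peak and every clique member of higher m/z are compared against
#' the characteristic neutral losses of the sample type. The highest-m/z
#' matching member becomes candidate #2; if no member exceeds the base
#' peak's m/z, the base peak itself is candidate #2; otherwise there is
#' none.
#'
#' @inheritParams collapseIsotopes
#' @param losses neutral-loss table ([neutralLossRules()]).
#' @return a one-row data.frame, or \code{NULL}.
#' @export
candidate2 <- function(features, losses, er = 0.016) {
  base <- .basePeakRow(features)
  higher <- features[features$mz > base$mz, , drop = FALSE]
  if (nrow(higher) && nrow(losses)) {
    delta <- higher$mz - base$mz
    hit <- vapply(delta, function(d) any(abs(d - losses$deltaMz) <= er),
                  logical(1))
    if (any(hit)) {
      hits <- higher[hit, , drop = FALSE]
      return(hits[which.max(hits$mz), , drop = FALSE])
    }
  }
  if (!nrow(higher))
    return(base)
  NULL
}

#' Candidate #3: abundant high-m/z member
#'
#' Members with m/z above the base peak and area larger than
#' \code{areaFrac} (default 50\%) of the base-peak area are considered; the
#' highest-m/z one is candidate #3, falling back to the base peak when no
#' member qualifies. Candidate #3 always exists.
#'
#' @inheritParams collapseIsotopes
#' @param areaFrac relative-area cutoff as a fraction of the base-peak area
#'   (strictly larger-than).
#' @return a one-row data.frame.
#' @export
candidate3 <- function(features, areaFrac = 0.5) {
  stopifnot(areaFrac > 0, areaFrac < 1)
  base <- .basePeakRow(features)
  elig <- features[features$mz > base$mz &
                     features$area > areaFrac * base$area, , drop = FALSE]
  if (nrow(elig))
    elig[which.max(elig$mz), , drop = FALSE]
  else
    base
}

#' Identify the pseudomolecular ion of one clique
#'
#' Runs the full decision cascade on the members of one clique:
#' \enumerate{
#'   \item a single-feature clique is its own pseudomolecular ion;
#'   \item isotopologue envelopes are collapsed ([collapseIsotopes()]);
#'   \item pairwise mass differences are matched against the rule system
#'     ([matchMassDifferences()]); the best implied ion is accepted
#'     immediately when its accumulated total weight reaches
#'     \code{weightAccept} — possibly naming a \emph{virtual} ion that was
#'     never detected;
#'   \item otherwise candidates #1 (rule-supported, detected), #2
#'     (neutral-loss parent) and #3 (abundant high-m/z member) are proposed;
#'     agreement of #1 and #2 decides early, any two identical candidates
#'     (within \code{er}) decide by vote, and failing that the highest-m/z
#'     candidate is taken.
#' }
#'
#' @inheritParams matchMassDifferences
#' @param losses neutral-loss table for candidate #2.
#' @param weightAccept total-weight threshold for direct acceptance.
#' @param isoWindow isotope-collapse gap (Da).
#' @param areaFrac candidate-#3 relative-area cutoff.
#' @return an \code{IdResult}: list with \code{pseudoMz}, \code{pseudoId}
#'   (\code{NA} for a virtual ion), \code{source} (one of
#'   \code{"single_feature"}, \code{"weight_accept"},
#'   \code{"candidate_vote"}, \code{"highest_mz_fallback"}),
#'   \code{virtual}, \code{candidates} and the match tables.
#' @export
identifyPseudomolecular <- function(features, rules, losses, er = 0.016,
                                    weightAccept = 4, isoWindow = 1.008,
                                    areaFrac = 0.5) {
  stopifnot(is.data.frame(features), weightAccept > 0)
  if (!nrow(features))
    stop("empty clique")
  if (nrow(features) == 1L) {
    return(.idResult(features$mz[1L], features$id[1L], "single_feature",
                     virtual = FALSE))
  }
  collapsed <- collapseIsotopes(features, er = er, isoWindow = isoWindow)
  mm <- matchMassDifferences(collapsed, rules, er = er)
  if (nrow(mm$map) && mm$map$totalWeight[1L] >= weightAccept) {
    implied <- mm$map$impliedMz[1L]
    d <- abs(collapsed$mz - implied)
    if (min(d) <= er) {
      hit <- collapsed[which.min(d), , drop = FALSE]
      return(.idResult(hit$mz, hit$id, "weight_accept", virtual = FALSE,
                       mm = mm))
    }
    return(.idResult(implied, NA_character_, "weight_accept", virtual = TRUE,
                     mm = mm))
  }
  c1 <- candidate1(mm$map, collapsed, er = er)
  c2 <- candidate2(collapsed, losses, er = er)
  cand <- list(c1 = c1, c2 = c2)
  if (!is.null(c1) && !is.null(c2) && abs(c1$mz - c2$mz) <= er) {
    return(.idResult(c1$mz, c1$id, "candidate_vote", virtual = FALSE,
                     mm = mm, candidates = cand))
  }
  c3 <- candidate3(collapsed, areaFrac = areaFrac)
  cand$c3 <- c3
  present <- Filter(Negate(is.null), cand)
  mzs <- vapply(present, function(f) f$mz, numeric(1))
  # majority vote: any two identical candidates (within er) decide
  if (length(mzs) >= 2L) {
    pairs <- utils::combn(length(mzs), 2L)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1L, k]; j <- pairs[2L, k]
      if (abs(mzs[i] - mzs[j]) <= er) {
        win <- present[[i]]
        return(.idResult(win$mz, win$id, "candidate_vote", virtual = FALSE,
                         mm = mm, candidates = cand))
      }
    }
  }
  win <- present[[which.max(mzs)]]
  .idResult(win$mz, win$id, "highest_mz_fallback", virtual = FALSE,
            mm = mm, candidates = cand)
}

.idResult <- function(pseudoMz, pseudoId, source, virtual, mm = NULL,
                      candidates = list()) {
  structure(list(pseudoMz = pseudoMz, pseudoId = pseudoId, source = source,
                 virtual = virtual, candidates = candidates,
                 map = if (is.null(mm)) NULL else mm$map,
                 matches = if (is.null(mm)) NULL else mm$matches),
            class = "IdResult")
}

#' @export
print.IdResult <- function(x, ...) {
  cat(sprintf("IdResult: pseudomolecular m/z %.4f (%s%s)\n", x$pseudoMz,
              x$source, if (x$virtual) ", virtual" else ""))
  invisible(x)
}

#' Identify pseudomolecular ions for every clique
#'
#' Applies [identifyPseudomolecular()] to each clique of a
#' [CliqueSet-class] and fills its \code{pseudo} slot.
#'
#' @param cs a [CliqueSet-class] from [groupIons()].
#' @param x the [FeatureTable-class] the cliques were built from.
#' @param rules adduct rules; defaults to [adductRules()] for the table's
#'   ionization mode.
#' @param losses neutral losses; defaults to [neutralLossRules()] for
#'   \code{sampleType}.
#' @param sampleType sample type selecting the characteristic neutral
#'   losses.
#' @inheritParams identifyPseudomolecular
#' @return the \code{CliqueSet} with one identification row per clique.
#' @export
identifyCliques <- function(cs, x, rules = NULL, losses = NULL,
                            sampleType = "plant", er = 0.016,
                            weightAccept = 4, isoWindow = 1.008,
                            areaFrac = 0.5) {
  stopifnot(is(cs, "CliqueSet"), is(x, "FeatureTable"))
  if (is.null(rules))
    rules <- adductRules(ionMode(x))
  if (is.null(losses))
    losses <- neutralLossRules(sampleType)
  res <- lapply(cliques(cs), function(members) {
    identifyPseudomolecular(.cliqueFrame(x, members), rules, losses,
                            er = er, weightAccept = weightAccept,
                            isoWindow = isoWindow, areaFrac = areaFrac)
  })
  ann <- annotations(x)
  cs@pseudo <- data.frame(
    clique = names(cliques(cs)),
    pseudoMz = vapply(res, function(r) r$pseudoMz, numeric(1)),
    pseudoId = vapply(res, function(r) r$pseudoId, character(1)),
    source = vapply(res, function(r) r$source, character(1)),
    virtual = vapply(res, function(r) r$virtual, logical(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  cs@pseudo$annotation <- ifelse(is.na(cs@pseudo$pseudoId), NA_character_,
                                 unname(ann[cs@pseudo$pseudoId]))
  validObject(cs)
  cs
}
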