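# Exact m/z offsets (relative to the pseudomolecular ion) of the species the
# generator can emit, per polarity.
.synthOffsets <- function(mode) {
  if (mode == "negative")
    c("dimer" = NA, "formate adduct" = .MASS[["formic"]],
      "chloride adduct" = .MASS[["hcl"]], "water loss" = -.MASS[["water"]],
      "CO2 loss" = -.MASS[["co2"]], "hexose parent" = .MASS[["hexose"]])
  else
    c("dimer" = NA, "sodium adduct" = .MASS[["na_h"]],
      "potassium adduct" = .MASS[["k_h"]],
      "ammonium adduct" = .MASS[["nh3"]], "water loss" = -.MASS[["water"]],
      "hexose parent" = .MASS[["hexose"]])
}

.synthFractions <- c("dimer" = 0.3, "formate adduct" = 0.4,
                     "chloride adduct" = 0.35, "water loss" = 0.25,
                     "CO2 loss" = 0.2, "sodium adduct" = 0.4,
                     "potassium adduct" = 0.3, "ammonium adduct" = 0.35,
                     "hexose parent" = 0.2)

#' Specification for a synthetic LC-MS dataset
#'
#' Bundles the parameters of the fixture generator. The generator emulates
#' the two structures the analysis relies on: (a) cliques of co-eluting ions
#' with fixed cross-sample area ratios derived from a known neutral mass
#' (adducts, dimer, isotopologues, neutral-loss parents, optional noise
#' features), and (b) sample-wise concentration profiles with block
#' correlation structure (co-varying metabolite groups plus noise).
#'
#' @param nMetabolites number of metabolites (cliques).
#' @param nSamples number of samples.
#' @param mode ionization polarity.
#' @param adductMenu list (one character vector of species per metabolite,
#'   from the names of the default rule chemistry), or \code{NULL} to sample
#'   menus randomly.
#' @param isotopeFraction 13C isotopologue abundance relative to its parent
#'   (added for the monomer and the dimer); 0 disables isotopes.
#' @param blocks integer block assignment per metabolite (\code{NULL}: one
#'   block).
#' @param withinR,betweenR target Pearson correlation within / between
#'   blocks.
#' @param areaNoiseCv coefficient of variation of the multiplicative
#'   (log-normal) area noise.
#' @param rtJitter standard deviation of the RT scatter within a clique
#'   (min).
#' @param baseLevel median base-peak area (arbitrary units).
#' @param lognormalSigma log-scale sd of the concentration profiles.
#' @param nNoise number of uncorrelated singleton noise features.
#' @param seed integer seed; every draw of the generator flows from it.
#' @return a list of class \code{SyntheticSpec}.
#' @export
syntheticSpec <- function(nMetabolites = 20, nSamples = 12,
                          mode = c("negative", "positive"),
                          adductMenu = NULL, isotopeFraction = 0.1,
                          blocks = NULL, withinR = 0.9, betweenR = 0,
                          areaNoiseCv = 0.05, rtJitter = 0.002,
                          baseLevel = 1e5, lognormalSigma = 0.3,
                          nNoise = 0, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(areaNoiseCv >= 0, rtJitter >= 0, nSamples >= 3)
  if (is.null(blocks))
    blocks <- rep(1L, nMetabolites)
  stopifnot(length(blocks) == nMetabolites)
  structure(list(nMetabolites = nMetabolites, nSamples = nSamples,
                 mode = mode, adductMenu = adductMenu,
                 isotopeFraction = isotopeFraction, blocks = as.integer(blocks),
                 withinR = withinR, betweenR = betweenR,
                 areaNoiseCv = areaNoiseCv, rtJitter = rtJitter,
                 baseLevel = baseLevel, lognormalSigma = lognormalSigma,
                 nNoise = nNoise, seed = seed),
            class = "SyntheticSpec")
}

# multiplicative log-normal noise with a given CV (unit mean on the log
# scale; RSD of a ratio of two such terms ~ sqrt(2) * cv for small cv)
.areaNoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, mean = 0, sd = sdlog))
}

#' Generate one synthetic clique
#'
#' Emits the features of a single metabolite of known neutral mass M: the
#' pseudomolecular ion (the base peak, relative area 1), the species in
#' \code{menu} at rule-exact m/z offsets and fixed area fractions, and 13C
#' isotopologues of the monomer and dimer. Per-sample areas are
#' \code{fraction * profile * noise}; retention times share \code{rt} up to
#' \code{rtJitter}. Uses the current RNG state (seed upstream).
#'
#' @param M neutral monoisotopic mass (Da), > 50.
#' @param mode ionization polarity.
#' @param menu character vector of species to emit (see
#'   \code{names(adductRules(mode)$label)} plus \code{"hexose parent"});
#'   may be empty.
#' @param profile numeric vector of per-sample concentrations.
#' @param noiseCv CV of the multiplicative area noise.
#' @param rt,rtJitter clique retention time and within-clique scatter (min).
#' @param isotopeFraction relative isotopologue abundance (0 disables).
#' @param fractions named overrides of the default relative areas.
#' @param idPrefix feature-id prefix.
#' @return list with \code{features} (id, mz, rt, annotation),
#'   \code{areas} (features x samples) and \code{truth} (the true
#'   pseudomolecular m/z and the member ids).
#' @examples
#' cl <- makeClique(340.079, "negative", menu = "dimer",
#'                  profile = rep(1000, 6))
#' cl$truth$pseudoMz
#' @export
makeClique <- function(M, mode = c("negative", "positive"), menu = "dimer",
                       profile, noiseCv = 0, rt = 5, rtJitter = 0,
                       isotopeFraction = 0.1, fractions = NULL,
                       idPrefix = "C1") {
  mode <- match.arg(mode)
  stopifnot(M > 50, all(profile > 0))
  offsets <- .synthOffsets(mode)
  bad <- setdiff(menu, names(offsets))
  if (length(bad))
    stop("unknown species: ", paste(bad, collapse = ", "))
  # A "hexose parent" clique models a glycoside whose molecular ion lost a
  # hexose: the base peak is the aglycone fragment and the parent itself is
  # the true pseudomolecular ion. Monomer-anchored species (dimer, adducts)
  # would contradict that ground truth, so the parent stands alone.
  glycoside <- "hexose parent" %in% menu
  if (glycoside && length(unique(menu)) > 1L)
    stop("'hexose parent' cannot be combined with other species")
  fr <- .synthFractions
  if (!is.null(fractions))
    fr[names(fractions)] <- fractions
  mono <- if (mode == "negative") M - PROTON_MASS else M + PROTON_MASS

  mzs <- mono
  fracs <- 1
  labels <- "monomer"
  for (sp in unique(menu)) {
    mzSp <- if (sp == "dimer") {
      if (mode == "negative") 2 * M - PROTON_MASS else 2 * M + PROTON_MASS
    } else mono + offsets[[sp]]
    mzs <- c(mzs, mzSp)
    fracs <- c(fracs, fr[[sp]])
    labels <- c(labels, sp)
  }
  if (isotopeFraction > 0) {
    for (sp in intersect(c("monomer", "dimer"), labels)) {
      i <- match(sp, labels)
      mzs <- c(mzs, mzs[i] + C13_SHIFT)
      fracs <- c(fracs, fracs[i] * isotopeFraction)
      labels <- c(labels, paste(sp, "13C"))
    }
  }
  n <- length(mzs)
  nS <- length(profile)
  ids <- sprintf("%s_%02d", idPrefix, seq_len(n))
  areas <- matrix(0, n, nS)
  for (i in seq_len(n))
    areas[i, ] <- fracs[i] * profile * .areaNoise(nS, noiseCv)
  rownames(areas) <- ids
  list(features = data.frame(id = ids, mz = mzs,
                             rt = rt + rnorm(n, 0, rtJitter),
                             annotation = labels, stringsAsFactors = FALSE),
       areas = areas,
       truth = list(M = M,
                    pseudoMz = if (glycoside) mono + offsets[["hexose parent"]]
                               else mono,
                    members = ids, basePeak = ids[1L]))
}

#' Generate block-correlated concentration profiles
#'
#' Draws log-normal per-sample concentration profiles with a block
#' correlation structure: metabolites of one block share a latent factor
#' (within-block correlation \code{withinR}), and factors of different
#' blocks are correlated so that between-block profile correlations target
#' \code{betweenR}. Strongly negative equicorrelation between more than two
#' blocks is not realisable (the factor correlation matrix must stay
#' positive definite); infeasible targets are clamped with a warning.
#' Seeded by \code{spec$seed}, hence reproducible.
#'
#' @param spec a [syntheticSpec()].
#' @return matrix (metabolites x samples) of positive concentrations.
#' @export
makeProfiles <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  n <- spec$nMetabolites
  nS <- spec$nSamples
  blocks <- spec$blocks
  nB <- max(blocks)
  w <- spec$withinR
  stopifnot(w > 0, w <= 1)
  rhoB <- if (w > 0) spec$betweenR / w else 0
  lo <- if (nB > 1) -1 / (nB - 1) + 0.01 else -1
  if (rhoB < lo) {
    warning(sprintf(
      "between-block target %.2f infeasible for %d blocks; clamped",
      spec$betweenR, nB))
    rhoB <- lo
  }
  Cb <- matrix(rhoB, nB, nB)
  diag(Cb) <- 1
  Fb <- matrix(rnorm(nS * nB), nS, nB) %*% chol(Cb)
  z <- matrix(0, n, nS)
  for (i in seq_len(n))
    z[i, ] <- sqrt(w) * Fb[, blocks[i]] + sqrt(1 - w) * rnorm(nS)
  conc <- spec$baseLevel * exp(spec$lognormalSigma * z)
  rownames(conc) <- sprintf("M%04d", seq_len(n))
  conc
}

#' Generate a complete synthetic feature table with ground truth
#'
#' Draws neutral masses, adduct menus, block-correlated concentration
#' profiles and per-clique features, and assembles them (plus optional
#' uncorrelated noise singletons) into a [FeatureTable-class]. Clique
#' retention times sit on a 0.1-min grid, so distinct metabolites never
#' co-elute within the default grouping window and the partition ground
#' truth is unambiguous.
#'
#' @param spec a [syntheticSpec()].
#' @return list with \code{table} (the [FeatureTable-class]), \code{truth}
#'   (one row per metabolite: neutral mass, true pseudomolecular m/z,
#'   member ids, block, whether the menu contains the dimer), and
#'   \code{profiles}.
#' @export
makeSyntheticDataset <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  profiles <- makeProfiles(spec)   # seeds the stream with spec$seed
  n <- spec$nMetabolites
  M <- runif(n, 150, 600)
  menuPool <- setdiff(names(.synthOffsets(spec$mode)), "dimer")
  menus <- spec$adductMenu
  if (is.null(menus)) {
    menus <- lapply(seq_len(n), function(i) {
      m <- menuPool[runif(length(menuPool)) < 0.3]
      if ("hexose parent" %in% m) return("hexose parent")
      if (runif(1) < 0.7) m <- c("dimer", m)
      m
    })
  }
  stopifnot(length(menus) == n)
  rtGrid <- sample(seq(1, by = 0.1, length.out = n + spec$nNoise))

  feats <- list(); areaRows <- list(); truthRows <- list()
  for (i in seq_len(n)) {
    cl <- makeClique(M[i], spec$mode, menu = menus[[i]],
                     profile = profiles[i, ], noiseCv = spec$areaNoiseCv,
                     rt = rtGrid[i], rtJitter = spec$rtJitter,
                     isotopeFraction = spec$isotopeFraction,
                     idPrefix = sprintf("M%04d", i))
    feats[[i]] <- cl$features
    areaRows[[i]] <- cl$areas
    truthRows[[i]] <- data.frame(
      metabolite = sprintf("M%04d", i), M = M[i],
      pseudoMz = cl$truth$pseudoMz, basePeak = cl$truth$basePeak,
      members = paste(cl$truth$members, collapse = ";"),
      block = spec$blocks[i], hasDimer = "dimer" %in% menus[[i]],
      noise = FALSE, stringsAsFactors = FALSE)
  }
  if (spec$nNoise > 0) {
    for (j in seq_len(spec$nNoise)) {
      id <- sprintf("N%04d", j)
      prof <- spec$baseLevel * 0.2 *
        exp(spec$lognormalSigma * rnorm(spec$nSamples))
      feats[[n + j]] <- data.frame(id = id, mz = runif(1, 100, 900),
                                   rt = rtGrid[n + j], annotation = "noise",
                                   stringsAsFactors = FALSE)
      areaRows[[n + j]] <- matrix(prof, 1, dimnames = list(id, NULL))
      truthRows[[n + j]] <- data.frame(
        metabolite = id, M = NA_real_, pseudoMz = NA_real_, basePeak = id,
        members = id, block = NA_integer_, hasDimer = FALSE, noise = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  feats <- do.call(rbind, feats)
  areas <- do.call(rbind, areaRows)
  colnames(areas) <- sprintf("S%02d", seq_len(spec$nSamples))
  table <- FeatureTable(mz = feats$mz, rt = feats$rt, areas = areas,
                        mode = spec$mode, ids = feats$id,
                        annotation = feats$annotation)
  list(table = table, truth = do.call(rbind, truthRows), profiles = profiles,
       spec = spec)
}

#' Write a synthetic dataset to disk
#'
#' Serializes the feature table in the same CSV schema [readFeatureTable()]
#' accepts, with the ground truth as a sidecar TSV.
#'
#' @param ds result of [makeSyntheticDataset()].
#' @param dir output directory (created if needed).
#' @return named character vector of the two paths, invisibly.
#' @export
writeSyntheticDataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- file.path(dir, "features.csv")
  tp <- file.path(dir, "truth.tsv")
  writeFeatureTable(ds$table, fp)
  write.table(ds$truth, tp, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(c(features = fp, truth = tp))
}
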