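# Monoisotopic constants (Da)
PROTON_MASS <- 1.00727646688
C13_SHIFT <- 1.0033548378   # 13C - 12C

# Neutral monoisotopic masses of the species behind the default rules
.MASS <- c(
  water    = 18.0105646,    # H2O
  formic   = 46.0054793,    # CH2O2
  hcl      = 35.9766777,    # HCl
  co2      = 43.9898292,    # CO2
  na_h     = 21.9819425,    # Na - H
  k_h      = 37.9558815,    # K - H
  nh3      = 17.0265491,    # NH3
  hexose   = 162.0528234,   # C6H10O5
  dhexose  = 146.0579088,   # C6H10O4
  pentose  = 132.0422587,   # C5H8O4
  malonyl  = 86.0003939,    # C3H2O3
  glucuron = 176.0320880,   # C6H8O6
  sulfate  = 79.9568150     # SO3
)

#' Default adduct / fragment mass-difference rules
#'
#' The rule system that drives pseudomolecular ion identification. Each rule
#' describes an expected m/z difference between two co-eluting ions of the
#' same metabolite, carries a predefined weight \code{wr} (0-10) expressing
#' its diagnostic value, and maps a matched pair (lower m/z \code{L}, higher
#' m/z \code{H}) to the implied pseudomolecular m/z as
#' \code{L + impliedOffset}.
#'
#' Two rule kinds exist. \code{"fixed"} rules match a constant difference
#' \code{|H - L - deltaMz| <= er}. The \code{"dimer"} rule relates the
#' pseudomolecular ion to its proton-bound dimer; its difference equals the
#' neutral mass and therefore depends on the pair, so it matches
#' \code{H = 2L + 1.007276} (negative mode) or \code{H = 2L - 1.007276}
#' (positive mode) and stores \code{NA} as \code{deltaMz}. The monomer/dimer
#' pair is the single most diagnostic pattern and carries the maximal weight
#' 10; the weights of the remaining rules grade their reliability and are
#' fully user-editable via [writeAdductRules()] / [readAdductRules()].
#'
#' @param mode ionization polarity, \code{"positive"} or \code{"negative"}.
#' @return data.frame with columns \code{label}, \code{mode}, \code{kind},
#'   \code{deltaMz}, \code{wr}, \code{impliedOffset}.
#' @seealso [matchMassDifferences()], [identifyPseudomolecular()]
#' @examples
#' adductRules("negative")
#' @export
adductRules <- function(mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  neg <- data.frame(
    label = c("monomer/dimer", "formate adduct", "chloride adduct",
              "water loss", "CO2 loss"),
    mode = "negative",
    kind = c("dimer", "fixed", "fixed", "fixed", "fixed"),
    deltaMz = c(NA, .MASS[["formic"]], .MASS[["hcl"]], .MASS[["water"]],
                .MASS[["co2"]]),
    wr = c(10, 6, 5, 4, 3),
    impliedOffset = c(0, 0, 0, .MASS[["water"]], .MASS[["co2"]]),
    stringsAsFactors = FALSE)
  pos <- data.frame(
    label = c("monomer/dimer", "sodium adduct", "potassium adduct",
              "ammonium adduct", "water loss"),
    mode = "positive",
    kind = c("dimer", "fixed", "fixed", "fixed", "fixed"),
    deltaMz = c(NA, .MASS[["na_h"]], .MASS[["k_h"]], .MASS[["nh3"]],
                .MASS[["water"]]),
    wr = c(10, 6, 5, 5, 4),
    impliedOffset = c(0, 0, 0, 0, .MASS[["water"]]),
    stringsAsFactors = FALSE)
  if (mode == "negative") neg else pos
}

#' Default characteristic neutral losses
#'
#' Neutral-loss masses searched between the base peak and higher-m/z clique
#' members when proposing candidate #2 of the identification cascade. Losses
#' are tagged by the sample type they are characteristic for; selecting a
#' type returns its losses plus the generic ones.
#'
#' @param sampleType one of \code{"plant"}, \code{"fungi"}, \code{"animal"},
#'   \code{"generic"}.
#' @return data.frame with columns \code{label}, \code{deltaMz},
#'   \code{sampleType}.
#' @examples
#' neutralLossRules("plant")
#' @export
neutralLossRules <- function(sampleType = c("plant", "fungi", "animal",
                                            "generic")) {
  sampleType <- match.arg(sampleType)
  tab <- data.frame(
    label = c("water", "hexose", "deoxyhexose", "pentose", "malonyl",
              "hexose", "glucuronide", "sulfate"),
    deltaMz = c(.MASS[["water"]], .MASS[["hexose"]], .MASS[["dhexose"]],
                .MASS[["pentose"]], .MASS[["malonyl"]], .MASS[["hexose"]],
                .MASS[["glucuron"]], .MASS[["sulfate"]]),
    sampleType = c("generic", "plant", "plant", "plant", "plant",
                   "fungi", "animal", "animal"),
    stringsAsFactors = FALSE)
  tab[tab$sampleType %in% c(sampleType, "generic"), , drop = FALSE]
}

.checkAdductRules <- function(rules) {
  need <- c("label", "mode", "kind", "deltaMz", "wr", "impliedOffset")
  if (!all(need %in% colnames(rules)))
    stop("adduct rule table needs columns: ", paste(need, collapse = ", "))
  fixed <- rules$kind == "fixed"
  if (any(fixed & (!is.finite(rules$deltaMz) | rules$deltaMz <= 0)))
    stop("fixed rules require deltaMz > 0")
  if (any(rules$wr < 0 | rules$wr > 10))
    stop("rule weights must lie in [0, 10]")
  if (!all(rules$kind %in% c("fixed", "dimer")))
    stop("rule kind must be 'fixed' or 'dimer'")
  invisible(rules)
}

#' Read / write editable rule tables
#'
#' Rule tables are plain TSV so that the adduct chemistry and its weights can
#' be adapted to the instrument and sample at hand.
#'
#' @param path file path of a tab-separated rule table.
#' @param rules,losses tables as returned by [adductRules()] /
#'   [neutralLossRules()].
#' @return the rule table (readers), or the path invisibly (writers).
#' @export
readAdductRules <- function(path) {
  rules <- read.delim(path, stringsAsFactors = FALSE)
  .checkAdductRules(rules)
}

#' @rdname readAdductRules
#' @export
writeAdductRules <- function(rules, path) {
  .checkAdductRules(rules)
  write.table(rules, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname readAdductRules
#' @export
readNeutralLosses <- function(path) {
  losses <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "deltaMz", "sampleType")
  if (!all(need %in% colnames(losses)))
    stop("neutral-loss table needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(losses$deltaMz) | losses$deltaMz <= 0))
    stop("neutral losses require deltaMz > 0")
  losses
}

#' @rdname readAdductRules
#' @export
writeNeutralLosses <- function(losses, path) {
  write.table(losses, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
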