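#' Read an LC-MS feature table
#'
#' Reads a feature list (one row per detected feature: m/z, retention time,
#' optional annotation, then one peak-area column per sample) from CSV, TSV
#' or XLSX into a validated [FeatureTable-class]. Rows violating the data
#' model (non-numeric or non-positive m/z, negative RT, negative area, all
#' areas zero) are rejected with row-indexed diagnostics; blank or missing
#' area cells are read as 0; duplicated features (same m/z and RT to within
#' machine precision) are kept with a warning. The table is not transformed
#' on read: log-transformation and outlier removal are left to the user.
#'
#' @param path path of the input file.
#' @param mode ionization polarity of the acquisition.
#' @param format \code{"auto"} (by extension), \code{"csv"}, \code{"tsv"} or
#'   \code{"xlsx"} (requires the readxl package).
#' @param mzCol,rtCol,annotationCol,idCol column names (matched
#'   case-insensitively); the id and annotation columns are optional.
#' @param sampleCols sample column names; by default every remaining column.
#' @return a [FeatureTable-class].
#' @seealso [writeFeatureTable()], [filterMinArea()]
#' @export
readFeatureTable <- function(path, mode = c("positive", "negative"),
                             format = c("auto", "csv", "tsv", "xlsx"),
                             mzCol = "mz", rtCol = "rt",
                             annotationCol = "annotation", idCol = "id",
                             sampleCols = NULL) {
  mode <- match.arg(mode)
  format <- match.arg(format)
  if (!file.exists(path))
    stop("input file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                     xlsx = "xlsx", xls = "xlsx",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format="))
  }
  raw <- switch(format,
    csv = read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    tsv = read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading xlsx requires the readxl package")
      as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE)
    })
  .featureTableFromFrame(raw, mode, mzCol, rtCol, annotationCol, idCol,
                         sampleCols)
}

.matchCol <- function(raw, name) {
  hit <- which(tolower(colnames(raw)) == tolower(name))
  if (length(hit)) hit[1L] else NA_integer_
}

.featureTableFromFrame <- function(raw, mode, mzCol, rtCol, annotationCol,
                                   idCol, sampleCols) {
  iMz <- .matchCol(raw, mzCol)
  iRt <- .matchCol(raw, rtCol)
  if (is.na(iMz)) stop("mandatory column '", mzCol, "' not found")
  if (is.na(iRt)) stop("mandatory column '", rtCol, "' not found")
  iAnn <- .matchCol(raw, annotationCol)
  iId <- .matchCol(raw, idCol)
  if (is.null(sampleCols)) {
    iSamp <- setdiff(seq_along(raw), c(iMz, iRt, iAnn, iId))
  } else {
    iSamp <- vapply(sampleCols, function(s) .matchCol(raw, s), integer(1))
    if (anyNA(iSamp))
      stop("sample column(s) not found: ",
           paste(sampleCols[is.na(iSamp)], collapse = ", "))
  }
  if (!length(iSamp)) stop("no sample (area) columns found")

  n <- nrow(raw)
  mzv <- suppressWarnings(as.numeric(raw[[iMz]]))
  rtv <- suppressWarnings(as.numeric(raw[[iRt]]))
  areas <- suppressWarnings(
    vapply(iSamp, function(j) as.numeric(raw[[j]]), numeric(n)))
  areas <- matrix(areas, nrow = n,
                  dimnames = list(NULL, colnames(raw)[iSamp]))
  hadValue <- vapply(iSamp, function(j) {
    v <- raw[[j]]
    !(is.na(v) | (is.character(v) & trimws(as.character(v)) == ""))
  }, logical(n))
  hadValue <- matrix(hadValue, nrow = n)
  # blank / missing cells are 0-area; a value that fails numeric conversion
  # is a row defect
  badArea <- rowSums(is.na(areas) & hadValue) > 0
  areas[is.na(areas)] <- 0

  bad <- character(n)
  bad[is.na(mzv)] <- "non-numeric m/z"
  bad[!is.na(mzv) & mzv <= 0] <- "m/z must be > 0"
  bad[bad == "" & is.na(rtv)] <- "non-numeric RT"
  bad[bad == "" & !is.na(rtv) & rtv < 0] <- "negative RT"
  bad[bad == "" & badArea] <- "non-numeric area"
  bad[bad == "" & rowSums(areas < 0) > 0] <- "negative area"
  bad[bad == "" & rowSums(areas > 0) == 0] <- "no positive area"
  if (any(bad != "")) {
    idx <- which(bad != "")
    warning(sprintf("rejected %d row(s): %s", length(idx),
                    paste(sprintf("row %d (%s)", idx, bad[idx]),
                          collapse = "; ")))
  }
  keep <- bad == ""
  ids <- if (!is.na(iId)) as.character(raw[[iId]])[keep] else NULL
  ann <- if (!is.na(iAnn)) as.character(raw[[iAnn]])[keep] else NULL
  mzv <- mzv[keep]; rtv <- rtv[keep]
  areas <- areas[keep, , drop = FALSE]
  dup <- duplicated(cbind(mzv, rtv))
  if (any(dup))
    warning(sprintf("%d duplicated feature row(s) (identical m/z and RT) kept",
                    sum(dup)))
  FeatureTable(mz = mzv, rt = rtv, areas = areas, mode = mode, ids = ids,
               annotation = ann)
}

#' Write a feature table
#'
#' Serializes a [FeatureTable-class] to CSV or TSV in the same column layout
#' [readFeatureTable()] accepts (id, mz, rt, annotation, one column per
#' sample), so that read -> write -> read is the identity.
#'
#' @param x a [FeatureTable-class].
#' @param path output path; extension picks the delimiter unless
#'   \code{format} is given.
#' @param format \code{"auto"}, \code{"csv"} or \code{"tsv"}.
#' @return the path, invisibly.
#' @export
writeFeatureTable <- function(x, path, format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "tsv") "tsv" else "csv"
  out <- data.frame(id = featureIds(x), mz = unname(mz(x)), rt = unname(rt(x)),
                    annotation = unname(annotations(x)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(areas(x), check.names = FALSE))
  write.table(out, path, sep = if (format == "csv") "," else "\t",
              quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Filter features by minimum area
#'
#' Keeps exactly the features whose maximum peak area across samples reaches
#' \code{minArea} (inclusive), preserving order. Using the maximum rather
#' than the mean keeps metabolites that are abundant in only a subset of
#' conditions, which are often the biologically interesting ones.
#'
#' @param x a [FeatureTable-class].
#' @param minArea non-negative area threshold (same arbitrary units as the
#'   table); 0 keeps everything.
#' @return the filtered [FeatureTable-class].
#' @examples
#' ft <- FeatureTable(mz = c(100, 200), rt = c(1, 2),
#'                    areas = rbind(c(8000, 500), c(10000, 2)),
#'                    mode = "positive")
#' nrow(filterMinArea(ft, 9000))
#' @export
setMethod("filterMinArea", "FeatureTable", function(x, minArea, ...) {
  stopifnot(is.numeric(minArea), length(minArea) == 1L, minArea >= 0)
  x[maxAreas(x) >= minArea, ]
})

#' Write the clique report
#'
#' One row per clique: id, representative RT, member count and ids, base
#' peak, and (when identification has been run) the pseudomolecular m/z, the
#' cascade path that decided it, and whether the ion is virtual (implied by
#' the rule system but not detected).
#'
#' @param x a [CliqueSet-class].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeCliqueReport <- function(x, path) {
  stopifnot(is(x, "CliqueSet"))
  out <- data.frame(
    clique = names(cliques(x)),
    rt = x@rt,
    nMembers = lengths(cliques(x)),
    members = vapply(cliques(x), paste, "", collapse = ";"),
    basePeak = x@basePeak,
    stringsAsFactors = FALSE)
  if (nrow(x@pseudo)) {
    ps <- x@pseudo[match(out$clique, x@pseudo$clique), ]
    out$pseudoMz <- ps$pseudoMz
    out$pseudoId <- ps$pseudoId
    out$source <- ps$source
    out$virtual <- ps$virtual
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
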