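#' Pairwise Pearson correlation of concentration profiles
#'
#' Computes the symmetric Pearson coefficient matrix over metabolite
#' concentration profiles and the two-sided p-value of each pair from the t
#' transform \eqn{t = r \sqrt{n-2} / \sqrt{1-r^2}} with \eqn{n-2} degrees of
#' freedom. Zero-variance profiles have no defined correlation; such pairs
#' are recorded as \eqn{r = 0}, \eqn{p = 1} with a warning. The significance
#' mask is filled immediately via [applySignificance()].
#'
#' @param profiles numeric matrix, metabolites in rows and samples in
#'   columns (at least 2 rows and 3 columns).
#' @param alpha significance level in (0, 1).
#' @param bonferroni divide alpha by the number of tested pairs
#'   \eqn{k(k-1)/2}?
#' @return a [CorrelationResult-class].
#' @examples
#' set.seed(1)
#' pr <- matrix(rnorm(40), 4, 10, dimnames = list(paste0("m", 1:4), NULL))
#' pearsonMatrix(pr, alpha = 0.05)
#' @export
pearsonMatrix <- function(profiles, alpha = 0.01, bonferroni = FALSE) {
  profiles <- as.matrix(profiles)
  k <- nrow(profiles)
  n <- ncol(profiles)
  if (n < 3L)
    stop("at least 3 samples are required")
  if (k < 2L)
    stop("at least 2 profiles are required")
  if (is.null(rownames(profiles)))
    rownames(profiles) <- sprintf("P%04d", seq_len(k))
  noVar <- apply(profiles, 1L, sd) == 0
  if (any(noVar))
    warning(sum(noVar), " zero-variance profile(s): correlations undefined,",
            " recorded as r = 0, p = 1")
  r <- suppressWarnings(cor(t(profiles)))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  rc <- pmin(pmax(r, -1), 1)
  tstat <- abs(rc) * sqrt(n - 2) / sqrt(pmax(1 - rc^2, 0))
  p <- 2 * pt(tstat, df = n - 2, lower.tail = FALSE)
  p[abs(rc) >= 1] <- 0
  if (any(noVar)) {
    p[noVar, ] <- 1
    p[, noVar] <- 1
  }
  diag(p) <- 0            # the diagonal is not tested
  res <- new("CorrelationResult", r = r, p = p, nSamples = as.integer(n),
             alpha = alpha, bonferroni = bonferroni,
             significant = matrix(FALSE, k, k, dimnames = dimnames(r)))
  applySignificance(res, alpha = alpha, bonferroni = bonferroni)
}

#' @describeIn pearsonMatrix Recompute the significance mask of an existing
#'   result under a (possibly different) significance policy. The effective
#'   level is \code{alpha} itself, or \code{alpha / m} with
#'   \eqn{m = k(k-1)/2} tested pairs under Bonferroni correction; a pair is
#'   significant when \eqn{p \le \alpha_{eff}} (the diagonal never is).
#' @param x a [CorrelationResult-class].
#' @export
setMethod("applySignificance", "CorrelationResult",
  function(x, alpha = 0.01, bonferroni = FALSE) {
    stopifnot(alpha > 0, alpha < 1)
    k <- nrow(x@r)
    m <- k * (k - 1) / 2
    alphaEff <- if (bonferroni) alpha / m else alpha
    sig <- x@p <= alphaEff
    diag(sig) <- FALSE
    x@alpha <- alpha
    x@bonferroni <- bonferroni
    x@significant <- sig
    validObject(x)
    x
  })
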