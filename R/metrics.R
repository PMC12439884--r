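# Model-selection and concordance statistics for externally supplied
# clusterings: BIC with a pluggable degrees-of-freedom accounting, the
# plain Rand index, and concordance of cluster assignments across
# overlapping (technically replicated) spots.

#' Degrees of freedom of a latent-factor spatial clustering model
#'
#' Default accounting: \code{p * q} loading parameters, \code{k * q}
#' cluster means in the latent space, plus per-cluster covariance
#' parameters (\code{q} for diagonal, \code{q (q + 1) / 2} for full,
#' counted once for shared), plus an optional embedding-rank term
#' \code{q * rMax}. The exact accounting of any particular model is not
#' recoverable in general, which is why \code{\link{bic}} accepts a
#' custom df.
#'
#' @param k clusters; \code{q} latent dimensions; \code{p} genes;
#'   \code{rMax} embedding rank (0 to disable the term).
#' @param q,p,rMax see above.
#' @param covStructure \code{"diagonal"}, \code{"shared"} or
#'   \code{"full"}.
#' @return Degrees of freedom (numeric).
#' @export
modelDf <- function(k, q, p, rMax = 0,
                    covStructure = c("diagonal", "shared", "full")) {
    covStructure <- match.arg(covStructure)
    covTerms <- switch(covStructure,
                       diagonal = k * q,
                       shared = q * (q + 1) / 2,
                       full = k * q * (q + 1) / 2)
    p * q + k * q + covTerms + q * rMax
}

#' Bayesian information criterion
#'
#' \code{BIC = -2 * logLik + df * ln(n)} (natural log).
#'
#' @param logLik model log-likelihood.
#' @param df degrees of freedom (e.g. from \code{\link{modelDf}}).
#' @param n number of observations (spots); must exceed 1.
#' @return The BIC value.
#' @examples
#' bic(-1000, 10, 100) # 2000 + 10 * log(100)
#' @export
bic <- function(logLik, df, n) {
    if (n <= 1) stop("n must be > 1")
    -2 * logLik + df * log(n)
}

#' Plain (unadjusted) Rand index
#'
#' Fraction of observation pairs on which two partitions agree (both
#' together or both apart).
#'
#' @param a,b label vectors of equal length.
#' @return Rand index in [0, 1].
#' @export
randIndex <- function(a, b) {
    if (length(a) != length(b)) stop("label vectors differ in length")
    n <- length(a)
    if (n < 2) stop("at least 2 observations are required")
    tab <- table(a, b)
    sumSq <- sum(tab^2)
    sumA <- sum(rowSums(tab)^2)
    sumB <- sum(colSums(tab)^2)
    # agreements = pairs together in both + pairs apart in both
    (choose(n, 2) + sumSq - (sumA + sumB) / 2) / choose(n, 2)
}

#' Concordance of cluster assignments across overlapping spots
#'
#' Overlapping spots from different capture areas are technical
#' replicates; this returns the fraction of overlap pairs whose two spots
#' received the same cluster label.
#'
#' @param labels named cluster label per spot (names are barcodes).
#' @param pairs data.frame with columns spot_a, spot_b (e.g. the
#'   \code{pairs} element of \code{\link{detectOverlaps}}).
#' @return Fraction in [0, 1]; no pairs is an error.
#' @export
overlapConcordance <- function(labels, pairs) {
    if (nrow(pairs) == 0)
        stop("concordance is undefined without overlap pairs")
    mean(labels[pairs$spot_a] == labels[pairs$spot_b])
}
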