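# Per-donor detection of spatially autocorrelated expression patterns:
# binary neighbor graph, global and local Moran statistics with
# permutation inference, spatial cross-correlation between genes,
# hierarchical pattern grouping and per-spot pattern scores.

#' Build a binary spatial neighbor graph
#'
#' Two spots are neighbors (W_ij = 1) iff their Euclidean distance is
#' positive and at most \code{threshold}. On a hexagonal lattice a
#' threshold of 1.5 x pitch connects exactly the six first-ring neighbors.
#'
#' @param coords n x 2 matrix of spot coordinates.
#' @param threshold neighbor distance cutoff (> 0).
#' @return A \linkS4class{SpatialGraph}.
#' @export
buildSpatialGraph <- function(coords, threshold) {
    if (threshold <= 0) stop("threshold must be > 0")
    coords <- rbind2cols(coords)
    d <- as.matrix(stats::dist(coords))
    A <- Matrix::Matrix((d > 0 & d <= threshold) * 1, sparse = TRUE)
    dimnames(A) <- NULL
    new("SpatialGraph", adjacency = methods::as(A, "generalMatrix"),
        coords = coords, threshold = threshold)
}

centeredLag <- function(x, graph) {
    xc <- x - mean(x)
    list(xc = xc, lag = as.numeric(graph@adjacency %*% xc),
         ss = sum(xc^2))
}

#' Global Moran's I
#'
#' \code{I = (n / S0) * sum_ij W_ij (x_i - xbar)(x_j - xbar) /
#' sum_i (x_i - xbar)^2} with binary, non-row-standardized weights.
#'
#' @param x per-spot values with nonzero variance.
#' @param graph a \linkS4class{SpatialGraph}.
#' @return The Moran's I statistic.
#' @seealso \code{\link{moransIPermutation}} for permutation inference.
#' @export
moransI <- function(x, graph) {
    if (stats::var(x) == 0)
        stop("Moran's I is undefined for zero-variance input")
    cl <- centeredLag(x, graph)
    (length(x) / graphS0(graph)) * sum(cl$xc * cl$lag) / cl$ss
}

#' Permutation test for global Moran's I
#'
#' Recomputes the statistic under \code{nPerm} random permutations of the
#' values over the spots. The permutation expectation of I is
#' \code{-1 / (n - 1)}.
#'
#' @param x per-spot values.
#' @param graph a \linkS4class{SpatialGraph}.
#' @param nPerm number of permutations (default 999).
#' @param alternative \code{"greater"} (positive autocorrelation, the
#'   default), \code{"less"} or \code{"two.sided"}.
#' @param seed integer seed.
#' @return List with \code{statistic}, \code{p.value}, and the
#'   permutation draws \code{perm}.
#' @export
moransIPermutation <- function(x, graph, nPerm = 999,
                               alternative = c("greater", "two.sided",
                                               "less"),
                               seed = 1L) {
    alternative <- match.arg(alternative)
    obs <- moransI(x, graph)
    perm <- withSeed(seed, vapply(seq_len(nPerm), function(b)
        moransI(sample(x), graph), numeric(1)))
    p <- switch(alternative,
        greater = (1 + sum(perm >= obs)) / (nPerm + 1),
        less = (1 + sum(perm <= obs)) / (nPerm + 1),
        two.sided = min(1, 2 * min(
            (1 + sum(perm >= obs)) / (nPerm + 1),
            (1 + sum(perm <= obs)) / (nPerm + 1))))
    list(statistic = obs, p.value = p, perm = perm)
}

#' Fraction of spots with significant local spatial association
#'
#' Computes the local Moran (LISA) statistic per spot, p-values under the
#' conditional randomization null (the spot's own value held fixed,
#' neighbor values drawn from the remaining spots), Benjamini-Hochberg
#' FDR across spots, and the fraction of spots with FDR below
#' \code{alpha}. A gene is considered spatially patterned when this
#' fraction is at least \code{minFraction}. The default inference uses
#' the analytic moments of the conditional null with a normal
#' approximation; \code{method = "permutation"} uses Monte-Carlo
#' conditional permutations instead (coarser p-value resolution:
#' \code{1 / (nPerm + 1)}).
#'
#' @param x per-spot values.
#' @param graph a \linkS4class{SpatialGraph}.
#' @param method \code{"normal"} (analytic, default) or
#'   \code{"permutation"}.
#' @param alternative \code{"greater"} (positive local association, the
#'   default: both high-high and low-low cluster spots score positive) or
#'   \code{"two.sided"}.
#' @param nPerm permutations for \code{method = "permutation"}.
#' @param alpha FDR threshold (default 0.05).
#' @param minFraction pass threshold on the significant fraction
#'   (default 0.05).
#' @param seed integer seed (permutation method only).
#' @return List with \code{fraction}, \code{pass}, per-spot \code{local}
#'   statistics and \code{fdr}.
#' @export
lisaSignificantFraction <- function(x, graph,
                                    method = c("normal", "permutation"),
                                    alternative = c("greater",
                                                    "two.sided"),
                                    nPerm = 999, alpha = 0.05,
                                    minFraction = 0.05, seed = 1L) {
    method <- match.arg(method)
    alternative <- match.arg(alternative)
    n <- length(x)
    if (stats::var(x) == 0) {
        warning("zero-variance input: significant fraction is 0")
        return(list(fraction = 0, pass = FALSE,
                    local = rep(0, n), fdr = rep(1, n)))
    }
    xc <- x - mean(x)
    m2 <- sum(xc^2) / n
    lag <- as.numeric(graph@adjacency %*% xc)
    local <- xc / m2 * lag
    if (method == "normal") {
        # conditional randomization moments: neighbor values are k_i draws
        # without replacement from the n - 1 remaining centered values
        k <- as.numeric(Matrix::rowSums(graph@adjacency))
        meanRest <- -xc / (n - 1)
        ssRest <- sum(xc^2) - xc^2
        varRest <- ssRest / (n - 1) - meanRest^2
        eLag <- k * meanRest
        vLag <- k * varRest * (n - 1 - k) / (n - 2)
        coef <- xc / m2
        eLocal <- coef * eLag
        sdLocal <- abs(coef) * sqrt(pmax(vLag, 0))
        z <- ifelse(sdLocal == 0, 0, (local - eLocal) / sdLocal)
        p <- if (alternative == "greater") stats::pnorm(z,
                                                        lower.tail = FALSE)
             else 2 * stats::pnorm(-abs(z))
    } else {
        permLocal <- withSeed(seed, {
            Xp <- vapply(seq_len(nPerm), function(b) sample(xc),
                         numeric(n))
            (xc / m2) * as.matrix(graph@adjacency %*% Xp)
        })
        pg <- (1 + rowSums(permLocal >= local)) / (nPerm + 1)
        pl <- (1 + rowSums(permLocal <= local)) / (nPerm + 1)
        p <- if (alternative == "greater") pg
             else pmin(1, 2 * pmin(pg, pl))
    }
    fdr <- stats::p.adjust(p, method = "BH")
    fraction <- mean(fdr < alpha)
    list(fraction = fraction, pass = fraction >= minFraction,
         local = local, fdr = fdr)
}

#' Spatial cross-correlation matrix between genes
#'
#' \code{SCC(a, b) = (n / S0) * sum_ij W_ij (a_i - abar)(b_j - bbar) /
#' sqrt(sum (a - abar)^2 * sum (b - bbar)^2)}, symmetrized as
#' \code{(M + t(M)) / 2}. The diagonal equals each gene's Moran's I.
#' Zero-variance genes have their row and column set to 0 with a warning.
#'
#' @param expr genes x spots expression matrix (log-normalized).
#' @param graph a \linkS4class{SpatialGraph}.
#' @return Symmetric genes x genes SCC matrix.
#' @export
spatialCrossCorrelation <- function(expr, graph) {
    expr <- as.matrix(expr)
    n <- ncol(expr)
    Xc <- expr - rowMeans(expr)
    ss <- rowSums(Xc^2)
    zeroVar <- ss == 0
    if (any(zeroVar)) {
        warning(sprintf("%d zero-variance gene(s): SCC set to 0",
                        sum(zeroVar)))
        ss[zeroVar] <- 1
    }
    num <- (n / graphS0(graph)) *
        (Xc %*% as.matrix(graph@adjacency) %*% t(Xc))
    scc <- num / sqrt(outer(ss, ss))
    scc <- (scc + t(scc)) / 2
    scc[zeroVar, ] <- 0
    scc[, zeroVar] <- 0
    dimnames(scc) <- list(rownames(expr), rownames(expr))
    scc
}

#' Group genes into spatial patterns
#'
#' Hierarchically clusters genes on the dissimilarity 1 - SCC and cuts the
#' tree into \code{k} groups (or at height \code{h}).
#'
#' @param scc symmetric SCC matrix from
#'   \code{\link{spatialCrossCorrelation}}.
#' @param method linkage: \code{"complete"} or \code{"ward"} (ward.D2).
#' @param k number of patterns; must not exceed the number of genes.
#' @param h alternatively, a cut height.
#' @return Named integer vector assigning each gene to a pattern.
#' @export
groupPatterns <- function(scc, method = c("complete", "ward"), k = NULL,
                          h = NULL) {
    method <- match.arg(method)
    if (!is.null(k) && k > nrow(scc))
        stop("k exceeds the number of genes")
    hc <- stats::hclust(stats::as.dist(1 - scc),
                        method = if (method == "ward") "ward.D2" else
                            "complete")
    stats::cutree(hc, k = k, h = h)
}

#' Per-pattern per-spot scores
#'
#' Z-scores each gene's expression across spots and averages the
#' standardized values of all genes within a pattern.
#'
#' @param expr genes x spots expression matrix.
#' @param partition named integer pattern assignment (from
#'   \code{\link{groupPatterns}}).
#' @return patterns x spots matrix of scores (mean 0 across spots per
#'   pattern).
#' @export
patternScores <- function(expr, partition) {
    expr <- as.matrix(expr)[names(partition), , drop = FALSE]
    z <- (expr - rowMeans(expr)) / apply(expr, 1, stats::sd)
    z[!is.finite(z)] <- 0
    out <- t(vapply(sort(unique(partition)), function(p)
        colMeans(z[partition == p, , drop = FALSE]),
        numeric(ncol(expr))))
    rownames(out) <- sprintf("pattern%d", sort(unique(partition)))
    colnames(out) <- colnames(expr)
    out
}

#' Run the per-donor spatial pattern workflow
#'
#' Convenience wrapper: Moran's I screen, LISA significant-fraction
#' filter, SCC, hierarchical grouping and pattern scores for one donor.
#'
#' @param expr genes x spots log-normalized expression.
#' @param coords n x 2 spot coordinates.
#' @param threshold neighbor distance cutoff.
#' @param k number of patterns to cut.
#' @param nPerm LISA permutations.
#' @param minFraction LISA pass threshold.
#' @param seed integer seed.
#' @return List with the graph, per-gene Moran's I and LISA fractions,
#'   the retained gene set, SCC, \code{partition} (gene sets per pattern)
#'   and \code{scores}.
#' @export
donorSpatialPatterns <- function(expr, coords, threshold, k = 2L,
                                 nPerm = 199, minFraction = 0.05,
                                 seed = 1L) {
    graph <- buildSpatialGraph(coords, threshold)
    expr <- as.matrix(expr)
    varOk <- apply(expr, 1, stats::var) > 0
    moran <- rep(NA_real_, nrow(expr))
    moran[varOk] <- apply(expr[varOk, , drop = FALSE], 1, moransI, graph)
    lisa <- vapply(seq_len(nrow(expr)), function(g) {
        if (!varOk[g]) return(0)
        lisaSignificantFraction(expr[g, ], graph, nPerm = nPerm,
                                seed = seed + g)$fraction
    }, numeric(1))
    keep <- varOk & lisa >= minFraction
    if (sum(keep) < 2)
        stop("fewer than 2 spatially patterned genes retained")
    scc <- spatialCrossCorrelation(expr[keep, , drop = FALSE], graph)
    partition <- groupPatterns(scc, method = "ward", k = k)
    scores <- patternScores(expr[keep, , drop = FALSE], partition)
    list(graph = graph, moran = stats::setNames(moran, rownames(expr)),
         lisaFraction = stats::setNames(lisa, rownames(expr)),
         genes = rownames(expr)[keep], scc = scc,
         partition = split(names(partition), partition),
         scores = scores)
}
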