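# Non-negative matrix factorization on nuclei expression, held-out
# cross-validation for rank selection, literal projection of loadings onto
# spatial data, factor QC/exclusion, domain summaries, gene correlation
# and drug-association testing.

nmfObjective <- function(A, W, H, l1w, mask = NULL) {
    R <- A - W %*% H
    if (!is.null(mask)) R <- R * mask
    0.5 * sum(R^2) + l1w * sum(W)
}

#' Fit a non-negative matrix factorization
#'
#' Minimizes \code{0.5 ||A - W H||_F^2 + l1w ||W||_1} by alternating
#' exact coordinate-descent non-negative least squares on W and H (the
#' masked variant used in cross-validation falls back to multiplicative
#' updates), from a seeded uniform initialization. After convergence the
#' factors are rescaled by a diagonal so each column of W sums to 1,
#' with the scale absorbed into H. The objective trace is
#' non-increasing.
#'
#' @param A non-negative genes x observations matrix (dense or sparse).
#' @param k factorization rank, below \code{min(dim(A))}.
#' @param l1w L1 penalty on W (default 0.1).
#' @param tol relative objective-change convergence tolerance (default
#'   1e-6).
#' @param maxit maximum iterations (default 1000).
#' @param seed integer seed for initialization.
#' @param mask optional 0/1 matrix; entries with 0 are excluded from the
#'   fit (used by \code{\link{crossValidateRank}}).
#' @return A \linkS4class{FactorModel}.
#' @export
fitNMF <- function(A, k, l1w = 0.1, tol = 1e-6, maxit = 1000, seed = 1L,
                   mask = NULL) {
    A <- as.matrix(A)
    if (any(!is.finite(A))) stop("A must be finite")
    if (any(A < 0)) stop("A must be non-negative")
    if (k >= min(dim(A))) stop("k must be below min(dim(A))")
    eps <- 1e-10
    withSeed(seed, {
        W <- matrix(stats::runif(nrow(A) * k), nrow(A), k)
        H <- matrix(stats::runif(k * ncol(A)), k, ncol(A))
        obj <- nmfObjective(A, W, H, l1w, mask)
        trace <- obj
        for (it in seq_len(maxit)) {
            if (is.null(mask)) {
                # exact coordinate descent, one factor at a time,
                # vectorized over observations / genes
                HHt <- H %*% t(H)
                AHt <- A %*% t(H)
                for (f in seq_len(k)) {
                    if (HHt[f, f] <= eps) next
                    W[, f] <- pmax(0, W[, f] +
                        (AHt[, f] - W %*% HHt[, f] - l1w) / HHt[f, f])
                }
                WtW <- t(W) %*% W
                WtA <- t(W) %*% A
                for (f in seq_len(k)) {
                    if (WtW[f, f] <= eps) next
                    H[f, ] <- pmax(0, H[f, ] +
                        (WtA[f, ] - WtW[f, ] %*% H) / WtW[f, f])
                }
            } else {
                WH <- (W %*% H) * mask
                W <- W * ((A * mask) %*% t(H)) / (WH %*% t(H) + l1w + eps)
                WH <- (W %*% H) * mask
                H <- H * (t(W) %*% (A * mask)) / (t(W) %*% WH + eps)
            }
            newObj <- nmfObjective(A, W, H, l1w, mask)
            trace <- c(trace, newObj)
            if (abs(obj - newObj) <= tol * max(obj, eps)) {
                obj <- newObj
                break
            }
            obj <- newObj
        }
        scale <- colSums(W)
        scale[scale == 0] <- 1
        W <- sweep(W, 2, scale, "/")
        H <- sweep(H, 1, scale, "*")
        dimnames(W) <- list(rownames(A), sprintf("factor%d", seq_len(k)))
        dimnames(H) <- list(sprintf("factor%d", seq_len(k)), colnames(A))
        new("FactorModel", w = W, h = H, k = as.integer(k),
            objective = trace, l1w = l1w, seed = as.integer(seed))
    })
}

#' Cross-validate the factorization rank on held-out entries
#'
#' For each candidate rank and replicate, a random 20% of matrix entries
#' is withheld (masked out of the objective, not zero-filled), the model
#' is fit on the rest, and the root-mean-square reconstruction error on
#' the held-out entries is recorded. The recommended rank is the smallest
#' whose mean error is within one standard error of the minimum.
#'
#' @param A non-negative genes x observations matrix.
#' @param ranks integer vector of candidate ranks (all >= 1).
#' @param nRep replicates per rank (default 3).
#' @param holdout fraction of entries withheld, in (0, 1) (default 0.2).
#' @param l1w,tol,maxit passed to \code{\link{fitNMF}} (looser defaults
#'   for speed).
#' @param seed integer seed; masks and initializations derive from it.
#' @return List with \code{errors} (rank x replicate matrix),
#'   \code{mean}, \code{se} and \code{recommended} rank.
#' @export
crossValidateRank <- function(A, ranks, nRep = 3, holdout = 0.2,
                              l1w = 0.1, tol = 1e-5, maxit = 200,
                              seed = 1L) {
    if (holdout <= 0 || holdout >= 1) stop("holdout must be in (0, 1)")
    if (any(ranks < 1)) stop("ranks must be >= 1")
    A <- as.matrix(A)
    errors <- matrix(NA_real_, length(ranks), nRep,
                     dimnames = list(as.character(ranks), NULL))
    for (r in seq_len(nRep)) {
        maskVec <- withSeed(seed + 1000L * r,
            stats::runif(length(A)) >= holdout)
        mask <- matrix(as.numeric(maskVec), nrow(A))
        for (i in seq_along(ranks)) {
            fit <- fitNMF(A, ranks[i], l1w = l1w, tol = tol,
                          maxit = maxit, seed = seed + r, mask = mask)
            recon <- basisMatrix(fit) %*% scoreMatrix(fit)
            held <- mask == 0
            errors[i, r] <- sqrt(mean((A[held] - recon[held])^2))
        }
    }
    m <- rowMeans(errors)
    se <- apply(errors, 1, stats::sd) / sqrt(nRep)
    best <- which.min(m)
    recommended <- ranks[min(which(m <= m[best] + se[best]))]
    list(errors = errors, mean = m, se = se, recommended = recommended)
}

#' Project factor loadings onto a new expression matrix
#'
#' Primary mode computes the literal matrix product \code{H' = t(W) A'}
#' over the genes shared between the loadings and the target matrix.
#' \code{method = "lstsq"} instead solves the non-negative least-squares
#' problem \code{min ||A' - W H'||} per observation. Projections are then
#' normalized so each observation's factor vector sums to 1; all-zero
#' observations are exempt and flagged.
#'
#' @param W genes x k loadings (or a \linkS4class{FactorModel}).
#' @param target genes x observations log-normalized expression.
#' @param method \code{"product"} (literal transpose-product) or
#'   \code{"lstsq"} (non-negative least squares).
#' @param normalize apply the per-observation sum-to-1 normalization.
#' @return A \linkS4class{ProjectionResult}.
#' @export
projectFactors <- function(W, target, method = c("product", "lstsq"),
                           normalize = TRUE) {
    method <- match.arg(method)
    if (is(W, "FactorModel")) W <- basisMatrix(W)
    target <- as.matrix(target)
    shared <- intersect(rownames(W), rownames(target))
    if (length(shared) == 0) stop("no genes shared with the target matrix")
    coverage <- length(shared) / nrow(W)
    Ws <- W[shared, , drop = FALSE]
    As <- target[shared, , drop = FALSE]
    H <- if (method == "product") t(Ws) %*% As
         else nnlsSolve(Ws, As)
    zero <- which(colSums(abs(H)) == 0)
    if (normalize) {
        s <- colSums(H)
        s[s == 0] <- 1
        H <- sweep(H, 2, s, "/")
    }
    rownames(H) <- colnames(W)
    new("ProjectionResult", h = H, normalized = normalize,
        zeroObservations = as.integer(zero), geneCoverage = coverage)
}

# non-negative least squares by cyclic coordinate descent, one column of
# B at a time; adequate for the small k used here
nnlsSolve <- function(W, B, iters = 200, tol = 1e-10) {
    WtW <- crossprod(W)
    WtB <- crossprod(W, B)
    k <- ncol(W)
    H <- matrix(0, k, ncol(B))
    for (j in seq_len(ncol(B))) {
        h <- rep(0, k)
        for (it in seq_len(iters)) {
            maxDelta <- 0
            for (f in seq_len(k)) {
                grad <- WtB[f, j] - sum(WtW[f, ] * h)
                newVal <- max(0, h[f] + grad / WtW[f, f])
                maxDelta <- max(maxDelta, abs(newVal - h[f]))
                h[f] <- newVal
            }
            if (maxDelta < tol) break
        }
        H[, j] <- h
    }
    H
}

#' Exclude factors correlated with sex or with sparse spatial support
#'
#' Drops factors whose scores correlate with a binary sex indicator at
#' \code{|r| > rMax}, and factors with nonzero projection in fewer than
#' \code{minSpots} spots.
#'
#' @param scores k x observations matrix (H, for the sex filter).
#' @param sex sex label per observation (two levels).
#' @param projections k x spots matrix (H', for the support filter); may
#'   equal \code{scores}.
#' @param rMax absolute correlation threshold (default 0.3, strict).
#' @param minSpots minimum spots with nonzero projection (default 200).
#' @return List with \code{keep} (logical per factor), \code{sexR} and
#'   \code{nNonzero}.
#' @export
excludeFactors <- function(scores, sex, projections = scores, rMax = 0.3,
                           minSpots = 200) {
    indicator <- as.numeric(factor(sex)) - 1
    sexR <- apply(scores, 1, function(h)
        if (stats::sd(h) == 0) 0 else stats::cor(h, indicator))
    nNonzero <- rowSums(projections > 0)
    keep <- abs(sexR) <= rMax & nNonzero >= minSpots
    list(keep = keep, sexR = sexR, nNonzero = nNonzero)
}

#' Summarize factor projections by spatial domain
#'
#' Per (factor, domain): prevalence (fraction of the domain's spots with
#' nonzero projection) and mean projection; the means are z-scaled across
#' domains within each factor. A factor is domain-associated when both
#' prevalence and scaled mean exceed their thresholds in at least one
#' domain.
#'
#' @param projections k x spots matrix.
#' @param domains domain label per spot.
#' @param prevalenceMin,scaledMeanMin association thresholds (defaults
#'   0.2 and 0.2, strict).
#' @return List with matrices \code{prevalence}, \code{mean},
#'   \code{scaledMean} (factors x domains) and logical
#'   \code{associated} per factor.
#' @export
summarizeByDomain <- function(projections, domains, prevalenceMin = 0.2,
                              scaledMeanMin = 0.2) {
    dl <- sort(unique(domains))
    prev <- vapply(dl, function(d)
        rowMeans(projections[, domains == d, drop = FALSE] > 0),
        numeric(nrow(projections)))
    mn <- vapply(dl, function(d)
        rowMeans(projections[, domains == d, drop = FALSE]),
        numeric(nrow(projections)))
    colnames(prev) <- colnames(mn) <- as.character(dl)
    sds <- apply(mn, 1, stats::sd)
    sds[!is.finite(sds) | sds == 0] <- 1   # single-domain or flat factor
    scaled <- (mn - rowMeans(mn)) / sds
    associated <- apply(prev > prevalenceMin & scaled > scaledMeanMin, 1,
                        any)
    list(prevalence = prev, mean = mn, scaledMean = scaled,
         associated = associated)
}

#' Correlate gene expression with factor activity
#'
#' Pearson correlation of each gene's expression with each factor's
#' scores (or spatial projections), returning the top genes per factor.
#' Constant genes get r = 0 with a warning.
#'
#' @param scores k x observations factor activity matrix.
#' @param expr genes x observations expression matrix.
#' @param topN genes returned per factor (default 20).
#' @return List with the full \code{correlation} (genes x factors) and
#'   \code{top} (list of named vectors, descending r).
#' @export
factorGeneCorrelation <- function(scores, expr, topN = 20) {
    expr <- as.matrix(expr)
    constant <- apply(expr, 1, stats::sd) == 0
    if (any(constant))
        warning(sprintf("%d constant gene(s): correlation set to 0",
                        sum(constant)))
    r <- suppressWarnings(stats::cor(t(expr), t(scores)))
    r[constant, ] <- 0
    top <- lapply(stats::setNames(seq_len(ncol(r)), colnames(r)),
                  function(f) {
        ord <- order(r[, f], decreasing = TRUE)[seq_len(min(topN,
                                                            nrow(r)))]
        stats::setNames(r[ord, f], rownames(r)[ord])
    })
    list(correlation = r, top = top)
}

#' Test factors for drug association within cell types
#'
#' Within each cell type, compares factor scores between drug-exposed and
#' control observations with a two-sided Wilcoxon rank-sum test. The
#' effect size is the rank-biserial correlation \code{2 W / (n1 n2) - 1}
#' (equivalently \code{1 - 2 U / (n1 n2)}), +1 when every drug score
#' exceeds every control score. FDR is BH-adjusted across all (factor,
#' cell type) tests; a factor is drug-responsive when \code{|effect| >
#' effectMin} and \code{fdr < fdrMax} in at least one cell type.
#'
#' @param scores k x observations factor score matrix.
#' @param condition \code{"drug"} / \code{"control"} label per
#'   observation.
#' @param cellTypes cell-type label per observation.
#' @param effectMin,fdrMax response thresholds (defaults 0.3, 0.05).
#' @return List with \code{table} (factor, cell_type, effect, p, fdr)
#'   and logical \code{responsive} per factor.
#' @export
drugFactorAssociation <- function(scores, condition, cellTypes,
                                  effectMin = 0.3, fdrMax = 0.05) {
    rows <- list()
    for (ct in sort(unique(cellTypes))) {
        inCt <- cellTypes == ct
        drug <- inCt & condition == "drug"
        ctrl <- inCt & condition == "control"
        if (!any(drug) || !any(ctrl)) next
        for (f in seq_len(nrow(scores))) {
            wt <- suppressWarnings(
                stats::wilcox.test(scores[f, drug], scores[f, ctrl],
                                   exact = FALSE))
            n1 <- sum(drug); n2 <- sum(ctrl)
            effect <- 2 * unname(wt$statistic) / (n1 * n2) - 1
            rows[[length(rows) + 1L]] <- data.frame(
                factor = rownames(scores)[f] %||% sprintf("factor%d", f),
                cell_type = ct, effect = effect, p = wt$p.value)
        }
    }
    if (!length(rows)) {
        warning("no (cell type, condition) stratum had both conditions")
        return(list(table = NULL, responsive = logical(0)))
    }
    tab <- do.call(rbind, rows)
    tab$fdr <- stats::p.adjust(tab$p, method = "BH")
    hit <- abs(tab$effect) > effectMin & tab$fdr < fdrMax
    responsive <- vapply(unique(tab$factor),
                         function(f) any(hit[tab$factor == f]),
                         logical(1))
    list(table = tab, responsive = responsive)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Match estimated factors to reference factors by cosine similarity
#'
#' Finds the factor permutation maximizing the total cosine similarity
#' between matched columns (exhaustive over permutations; intended for
#' the small ranks used in validation).
#'
#' @param W estimated genes x k loadings.
#' @param Wref reference genes x k loadings.
#' @return List with \code{permutation} (reference column for each
#'   estimated column) and \code{cosines} of the matched pairs.
#' @export
matchFactors <- function(W, Wref) {
    k <- ncol(W)
    if (k > 8) stop("exhaustive matching supports k <= 8")
    normalize <- function(M) sweep(M, 2, sqrt(colSums(M^2)), "/")
    S <- t(normalize(W)) %*% normalize(Wref)
    perms <- permutations(k)
    scores <- apply(perms, 1, function(p) sum(S[cbind(seq_len(k), p)]))
    best <- as.integer(perms[which.max(scores), ])
    list(permutation = best, cosines = S[cbind(seq_len(k), best)])
}

permutations <- function(k) {
    if (k == 1) return(matrix(1))
    sub <- permutations(k - 1)
    do.call(rbind, lapply(seq_len(k), function(i)
        cbind(i, sub + (sub >= i))))
}
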