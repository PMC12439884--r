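# Cross-donor integration of spatial patterns into consensus groups:
# gene-set Jaccard similarity, domain-profile correlation, their average
# as a consensus similarity, Ward clustering with a k-cut, and selection
# of one representative pattern per donor per group.

#' Jaccard similarity of two gene sets
#'
#' @param a,b character vectors (sets).
#' @return |intersection| / |union|; two empty sets give 0 with a warning.
#' @export
jaccardSimilarity <- function(a, b) {
    a <- unique(a); b <- unique(b)
    u <- length(union(a, b))
    if (u == 0) {
        warning("both sets empty; Jaccard defined as 0")
        return(0)
    }
    length(intersect(a, b)) / u
}

#' Pairwise Jaccard matrix over a list of gene sets
#' @param geneSets named list of character vectors.
#' @return Symmetric matrix of Jaccard indices, unit diagonal.
#' @export
jaccardMatrix <- function(geneSets) {
    n <- length(geneSets)
    J <- matrix(1, n, n, dimnames = list(names(geneSets),
                                         names(geneSets)))
    if (n > 1)
        for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
            J[i, j] <- J[j, i] <- jaccardSimilarity(geneSets[[i]],
                                                    geneSets[[j]])
        }
    J
}

#' Correlation of domain-averaged pattern profiles
#'
#' Pearson correlation between the per-domain mean score vectors of all
#' pattern pairs. Zero-variance profiles yield 0 correlations with a
#' warning.
#'
#' @param profiles patterns x domains matrix of domain-mean scores
#'   (at least 3 shared domains for a meaningful correlation).
#' @return Symmetric correlation matrix, unit diagonal.
#' @export
domainProfileCorrelation <- function(profiles) {
    profiles <- as.matrix(profiles)
    if (ncol(profiles) < 3)
        warning("fewer than 3 shared domains; correlations are weakly determined")
    sds <- apply(profiles, 1, stats::sd)
    r <- suppressWarnings(stats::cor(t(profiles)))
    if (any(sds == 0)) {
        warning(sprintf("%d zero-variance profile(s): correlations set to 0",
                        sum(sds == 0)))
        r[sds == 0, ] <- 0
        r[, sds == 0] <- 0
    }
    diag(r) <- 1
    r
}

#' Consensus similarity matrix
#'
#' Element-wise mean of the gene-set Jaccard matrix and the domain-profile
#' correlation matrix; the diagonal is forced to 1. Negative entries are
#' permitted (a [0,1] and a [-1,1] similarity are averaged as printed);
#' \code{rescale = TRUE} maps the correlation to [0,1] first.
#'
#' @param jaccard,correlation same-shape symmetric matrices.
#' @param rescale rescale the correlation to (r + 1) / 2 before averaging.
#' @return Symmetric consensus similarity matrix with unit diagonal.
#' @export
consensusMatrix <- function(jaccard, correlation, rescale = FALSE) {
    if (!all(dim(jaccard) == dim(correlation)))
        stop("similarity matrices have mismatched shapes")
    if (rescale) correlation <- (correlation + 1) / 2
    s <- (jaccard + correlation) / 2
    s <- (s + t(s)) / 2
    diag(s) <- 1
    s
}

#' Cluster patterns on the consensus similarity
#'
#' Converts similarity to the dissimilarity 1 - s (floored at 0, so
#' negative similarities cap the distance at 1), runs agglomerative
#' Ward clustering (ward.D2) and cuts the tree into \code{k} groups.
#'
#' @param consensus consensus similarity matrix.
#' @param k number of groups (default 6).
#' @param linkage hclust linkage method.
#' @return List with \code{labels} (named integer group per pattern) and
#'   the \code{hclust} tree.
#' @export
clusterPatterns <- function(consensus, k = 6, linkage = "ward.D2") {
    if (k < 1) stop("k must be >= 1")
    if (k > nrow(consensus)) stop("k exceeds the number of patterns")
    d <- 1 - pmax(consensus, 0)
    diag(d) <- 0
    hc <- stats::hclust(stats::as.dist(d), method = linkage)
    list(labels = stats::cutree(hc, k = k), tree = hc)
}

#' Select one representative pattern per donor per consensus group
#'
#' Within each group, donors contributing exactly one pattern have that
#' pattern as their representative; donors contributing more than one get
#' none by default. With \code{keepBest = TRUE} the multi-pattern case
#' keeps the pattern with the highest mean domain score instead.
#'
#' @param labels named integer group label per pattern.
#' @param donors named character donor per pattern.
#' @param meanScores named numeric mean domain score per pattern (used by
#'   the \code{keepBest} override).
#' @param keepBest resolve multi-pattern donors by score.
#' @return Logical vector (same names as \code{labels}), TRUE for
#'   representatives.
#' @export
selectRepresentatives <- function(labels, donors, meanScores = NULL,
                                  keepBest = FALSE) {
    rep <- stats::setNames(logical(length(labels)), names(labels))
    for (g in unique(labels)) {
        inG <- names(labels)[labels == g]
        for (d in unique(donors[inG])) {
            mine <- inG[donors[inG] == d]
            if (length(mine) == 1) {
                rep[mine] <- TRUE
            } else if (keepBest) {
                if (is.null(meanScores))
                    stop("meanScores required for keepBest")
                rep[mine[which.max(meanScores[mine])]] <- TRUE
            }
        }
    }
    rep
}

#' Build consensus patterns across donors
#'
#' End-to-end consensus step: Jaccard over pattern gene sets, correlation
#' of domain-mean score profiles, their average, Ward clustering with a
#' k-cut, and representative selection.
#'
#' @param geneSets named list (one per donor-pattern) of gene sets; names
#'   like \code{"donor1.pattern2"}.
#' @param domainProfiles patterns x domains matrix of domain-mean scores,
#'   rows matching \code{names(geneSets)}.
#' @param donors named character donor of each pattern.
#' @param k tree-cut groups (default 6).
#' @param keepBest see \code{\link{selectRepresentatives}}.
#' @param rescale see \code{\link{consensusMatrix}}.
#' @return A \linkS4class{ConsensusPatterns}.
#' @export
consensusPatterns <- function(geneSets, domainProfiles, donors, k = 6,
                              keepBest = FALSE, rescale = FALSE) {
    stopifnot(identical(names(geneSets), rownames(domainProfiles)),
              identical(names(geneSets), names(donors)))
    J <- jaccardMatrix(geneSets)
    r <- domainProfileCorrelation(domainProfiles)
    s <- consensusMatrix(J, r, rescale = rescale)
    cl <- clusterPatterns(s, k = k)
    meanScores <- rowMeans(domainProfiles)
    rep <- selectRepresentatives(cl$labels, donors, meanScores,
                                 keepBest = keepBest)
    membership <- data.frame(donor = donors, pattern = names(geneSets),
                             mcp = cl$labels, representative = rep,
                             row.names = NULL, stringsAsFactors = FALSE)
    new("ConsensusPatterns", membership = membership, similarity = s,
        k = as.integer(k))
}
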