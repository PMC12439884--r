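# Spot- and nucleus-level quality control filters, count normalization
# variants, gene filters, and cross-donor aggregation of ranked gene lists.

#' Combined low-depth / edge-proximity spot filter
#'
#' A spot is excluded iff its UMI total is below \code{umiMin} AND its
#' distance to the capture-area edge is below \code{edgeMax} (conjunction:
#' low depth far from the edge, or high depth near the edge, are kept).
#'
#' @param sumUmi per-spot UMI totals.
#' @param edgeDist per-spot edge distances (array units, see
#'   \code{\link{edgeDistance}}).
#' @param umiMin,edgeMax thresholds (defaults 250 and 6).
#' @return Logical vector, TRUE for kept spots.
#' @export
spotQCFilter <- function(sumUmi, edgeDist, umiMin = 250, edgeMax = 6) {
    stopifnot(length(sumUmi) == length(edgeDist))
    !(sumUmi < umiMin & edgeDist < edgeMax)
}

#' Batch-wise MAD outlier filter
#'
#' Flags values beyond \code{n} median absolute deviations from the batch
#' median (MAD with the 1.4826 consistency constant), optionally on the
#' log1p scale, lower-tail only or two-sided. The number of MADs may
#' differ per batch (e.g. different nucleus sorting strategies). Batches
#' with MAD 0 flag nothing; batches with fewer than 3 observations warn
#' and flag nothing.
#'
#' @param values numeric vector.
#' @param batch batch label per value.
#' @param nMads named vector/list of per-batch MAD multipliers, or a
#'   single number applied to all batches.
#' @param logScale apply log1p before computing median/MAD.
#' @param direction \code{"lower"} flags the low tail only; \code{"both"}
#'   flags both tails.
#' @return Logical vector, TRUE for flagged (outlier) values.
#' @export
madOutlierFilter <- function(values, batch = rep("all", length(values)),
                             nMads = 3, logScale = FALSE,
                             direction = c("lower", "both")) {
    direction <- match.arg(direction)
    v <- if (logScale) log1p(values) else values
    flag <- logical(length(v))
    for (b in unique(batch)) {
        sel <- batch == b
        n <- if (length(nMads) == 1 && is.null(names(nMads))) nMads
             else {
                 if (is.null(names(nMads)) || !b %in% names(nMads))
                     stop(sprintf("no MAD multiplier for batch '%s'", b))
                 nMads[[b]]
             }
        if (sum(sel) < 3) {
            warning(sprintf("batch '%s' has < 3 observations; not filtered",
                            b))
            next
        }
        med <- stats::median(v[sel])
        madv <- stats::mad(v[sel])
        if (madv == 0) next
        low <- v[sel] < med - n * madv
        high <- v[sel] > med + n * madv
        flag[sel] <- if (direction == "lower") low else low | high
    }
    flag
}

#' Fixed-threshold nucleus filters
#'
#' Flags nuclei with mitochondrial expression ratio strictly above
#' \code{mitoMax} or doublet score at or above \code{doubletMax}.
#'
#' @param mitoRatio per-nucleus mitochondrial read fraction.
#' @param doubletScore per-nucleus doublet score (externally supplied).
#' @param mitoMax strict upper bound on mitoRatio (default 0.05).
#' @param doubletMax inclusive upper bound on doubletScore (default 5).
#' @return Logical vector, TRUE for flagged nuclei.
#' @export
fixedThresholdFilters <- function(mitoRatio, doubletScore,
                                  mitoMax = 0.05, doubletMax = 5) {
    mitoRatio > mitoMax | doubletScore >= doubletMax
}

#' Log-normalize a count matrix
#'
#' \code{scale_factor}: natural-log normalization
#' \code{ln(count / libsize * scale + 1)}. \code{size_factor}: library-size
#' factors relative to the mean library size,
#' \code{log2(count / sizeFactor + 1)}. Observations with zero library
#' size are dropped with a warning.
#'
#' @param counts genes x observations matrix (sparse or dense).
#' @param method \code{"scale_factor"} or \code{"size_factor"}.
#' @param scale scaling factor for the scale_factor method (default
#'   10000).
#' @return Normalized matrix of the same class family as the input.
#' @export
logNormalizeCounts <- function(counts,
                               method = c("scale_factor", "size_factor"),
                               scale = 10000) {
    method <- match.arg(method)
    lib <- Matrix::colSums(counts)
    if (any(lib == 0)) {
        warning(sprintf("dropping %d observation(s) with zero library size",
                        sum(lib == 0)))
        counts <- counts[, lib > 0, drop = FALSE]
        lib <- lib[lib > 0]
    }
    if (method == "scale_factor") {
        out <- counts %*% Matrix::Diagonal(x = scale / lib)
        out@x <- log1p(out@x)
    } else {
        sf <- lib / mean(lib)
        out <- counts %*% Matrix::Diagonal(x = 1 / sf)
        out@x <- log2(out@x + 1)
    }
    dimnames(out) <- dimnames(counts)
    methods::as(out, "CsparseMatrix")
}

#' Gene filters
#'
#' \code{all_donors_nonzero} keeps genes with a nonzero count total in
#' every donor. \code{min_count_prop} keeps genes with at least
#' \code{minCount} counts in at least \code{minProp} of observations
#' (both bounds inclusive).
#'
#' @param counts genes x observations count matrix.
#' @param mode filter rule.
#' @param donors donor label per observation (required for
#'   all_donors_nonzero).
#' @param minCount,minProp parameters of the min_count_prop rule.
#' @return Logical gene mask, TRUE for kept genes.
#' @export
geneFilters <- function(counts,
                        mode = c("all_donors_nonzero", "min_count_prop"),
                        donors = NULL, minCount = 3, minProp = 0.005) {
    mode <- match.arg(mode)
    if (mode == "all_donors_nonzero") {
        if (is.null(donors)) stop("donor labels are required")
        keep <- rep(TRUE, nrow(counts))
        for (d in unique(donors))
            keep <- keep &
                Matrix::rowSums(counts[, donors == d, drop = FALSE]) > 0
        keep
    } else {
        Matrix::rowSums(counts >= minCount) / ncol(counts) >= minProp
    }
}

#' Aggregate per-donor ranked gene tables into one consensus ranking
#'
#' Genes are first restricted to those significant (\code{padj <
#' padjMax}) in every donor; the per-donor rank metric is then averaged
#' and genes re-ranked ascending by mean rank (alphabetical tie-break).
#'
#' @param tables list of data.frames with columns gene, rank, padj (one
#'   per donor).
#' @param topN number of genes to return (default 2000).
#' @param padjMax significance threshold applied in every donor.
#' @return data.frame with gene and mean_rank, best first, at most
#'   \code{topN} rows.
#' @export
aggregateGeneRanks <- function(tables, topN = 2000, padjMax = 0.05) {
    sig <- lapply(tables, function(t) t$gene[t$padj < padjMax])
    shared <- Reduce(intersect, sig)
    universes <- lapply(tables, `[[`, "gene")
    if (length(unique(vapply(universes, function(u)
        paste(sort(u), collapse = ";"), character(1)))) > 1)
        warning("gene universes differ across donors; intersecting")
    ranks <- vapply(tables, function(t)
        t$rank[match(shared, t$gene)], numeric(length(shared)))
    if (length(shared) == 1) ranks <- matrix(ranks, nrow = 1)
    meanRank <- rowMeans(ranks)
    ord <- order(meanRank, shared)
    out <- data.frame(gene = shared[ord], mean_rank = meanRank[ord],
                      stringsAsFactors = FALSE)
    utils::head(out, topN)
}
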