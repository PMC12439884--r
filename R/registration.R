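# Pseudobulk one-vs-all differential statistics, marker selection,
# ortholog mapping, cross-dataset correlation registration, Fisher
# over-representation, and heritability gene-set/BED construction.

#' Pseudobulk aggregation of counts
#'
#' Sums counts over all observations sharing a (group, unit) label, drops
#' pseudobulk samples aggregating fewer than \code{minObs} observations,
#' and optionally applies the downstream sample filters (minimum detected
#' genes per sample, minimum samples per group).
#'
#' @param counts genes x observations count matrix.
#' @param groups group label per observation (e.g. cluster).
#' @param units unit label per observation (e.g. capture area).
#' @param minObs minimum observations per pseudobulk sample (default 50).
#' @param minGenes minimum detected genes per retained sample (default
#'   2000; set 0 to disable).
#' @param minSamples minimum samples per retained group (default 10; set
#'   0 to disable).
#' @return List with \code{counts} (genes x samples), \code{group} and
#'   \code{unit} per sample, and \code{nObs} contributing observations.
#' @export
pseudobulkAggregate <- function(counts, groups, units, minObs = 50,
                                minGenes = 0, minSamples = 0) {
    key <- paste(groups, units, sep = "\r")
    keys <- unique(key)
    agg <- vapply(keys, function(k)
        Matrix::rowSums(counts[, key == k, drop = FALSE]),
        numeric(nrow(counts)))
    nObs <- vapply(keys, function(k) sum(key == k), integer(1))
    parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    keep <- nObs >= minObs
    if (minGenes > 0)
        keep <- keep & (colSums(agg > 0) >= minGenes)
    agg <- agg[, keep, drop = FALSE]
    grp <- parts[keep, 1]; unit <- parts[keep, 2]; nObs <- nObs[keep]
    if (minSamples > 0) {
        ok <- grp %in% names(which(table(grp) >= minSamples))
        agg <- agg[, ok, drop = FALSE]
        unit <- unit[ok]; nObs <- nObs[ok]; grp <- grp[ok]
    }
    rownames(agg) <- rownames(counts)
    colnames(agg) <- paste(grp, unit, sep = "_")
    list(counts = agg, group = grp, unit = unit, nObs = nObs)
}

#' One-vs-all t-statistics per gene and group
#'
#' For each gene g and group c, computes
#' \code{t = (mean_c - mean_notc) / sqrt((var_c + var_notc) / (2 n_c))},
#' where means and variances are taken over the log-normalized expression
#' inside and outside the group and \code{n_c} is the group size. The
#' denominator pools the two variances over \code{2 n_c} regardless of the
#' complement's size (this is not the Welch statistic; set
#' \code{welch = TRUE} for the Welch form). p-values use a t reference
#' with \code{2 n_c - 2} degrees of freedom and are BH-adjusted per group
#' across genes; logFC is the log-scale mean difference.
#'
#' @param expr genes x observations log-normalized expression matrix.
#' @param groups group label per observation (each group needs >= 2
#'   members).
#' @param welch use the Welch denominator
#'   \code{sqrt(var_c / n_c + var_notc / n_notc)} instead.
#' @return List of genes x groups matrices: \code{t}, \code{logFC},
#'   \code{p}, \code{fdr}.
#' @export
oneVsAllT <- function(expr, groups, welch = FALSE) {
    expr <- as.matrix(expr)
    gl <- sort(unique(groups))
    t_ <- logFC <- p <- matrix(NA_real_, nrow(expr), length(gl),
                               dimnames = list(rownames(expr), gl))
    for (c in gl) {
        inC <- groups == c
        nc <- sum(inC); nnot <- sum(!inC)
        if (nc < 2 || nnot < 2)
            stop(sprintf("group '%s' or its complement has < 2 members", c))
        m1 <- rowMeans(expr[, inC, drop = FALSE])
        m2 <- rowMeans(expr[, !inC, drop = FALSE])
        v1 <- apply(expr[, inC, drop = FALSE], 1, stats::var)
        v2 <- apply(expr[, !inC, drop = FALSE], 1, stats::var)
        denom <- if (welch) sqrt(v1 / nc + v2 / nnot)
                 else sqrt((v1 + v2) / (2 * nc))
        diff <- m1 - m2
        tt <- diff / denom
        degenerate <- denom == 0
        if (any(degenerate)) {
            tt[degenerate & diff == 0] <- 0
            if (any(degenerate & diff != 0))
                warning(sprintf(
                    "%d gene(s) in group '%s' have zero pooled variance with nonzero difference",
                    sum(degenerate & diff != 0), c))
            tt[degenerate & diff != 0] <- sign(diff[degenerate & diff != 0]) *
                Inf
        }
        t_[, c] <- tt
        logFC[, c] <- diff
        p[, c] <- 2 * stats::pt(-abs(tt), df = 2 * nc - 2)
    }
    fdr <- apply(p, 2, stats::p.adjust, method = "BH")
    list(t = t_, logFC = logFC, p = p, fdr = fdr)
}

#' Select per-group marker genes from one-vs-all results
#'
#' Per group: genes passing \code{fdr < fdrMax} and \code{logFC > 0},
#' ranked by logFC descending, top \code{topN} kept.
#'
#' @param de result of \code{\link{oneVsAllT}}.
#' @param topN markers per group (default 250).
#' @param fdrMax FDR threshold (default 0.05).
#' @return List with \code{perGroup} (named list of marker vectors, in
#'   rank order) and \code{union}.
#' @export
selectMarkers <- function(de, topN = 250, fdrMax = 0.05) {
    perGroup <- lapply(stats::setNames(colnames(de$t), colnames(de$t)),
                       function(c) {
        pass <- which(de$fdr[, c] < fdrMax & de$logFC[, c] > 0)
        if (!length(pass)) {
            warning(sprintf("no marker genes pass filters for group '%s'",
                            c))
            return(character())
        }
        sel <- pass[order(de$logFC[pass, c], decreasing = TRUE)]
        utils::head(rownames(de$t)[sel], topN)
    })
    list(perGroup = perGroup, union = unique(unlist(perGroup)))
}

#' Translate gene lists through one-to-one ortholog pairs
#'
#' @param genes character vector of source-species symbols.
#' @param homologs data.frame from \code{\link{readHomologTable}} (already
#'   one-to-one filtered).
#' @return List with \code{mapped} (target symbols, source order
#'   preserved), \code{nMapped}, \code{nDropped}.
#' @export
mapOrthologs <- function(genes, homologs) {
    idx <- match(genes, homologs$source_symbol)
    mapped <- homologs$target_symbol[idx[!is.na(idx)]]
    list(mapped = mapped, nMapped = length(mapped),
         nDropped = sum(is.na(idx)))
}

#' Correlate one-vs-all t-statistic profiles between two datasets
#'
#' Pearson correlation between query-group and reference-group t-vectors
#' over a shared gene universe: either the union of per-group top markers
#' of the reference or the intersection of the supplied matrices' genes.
#'
#' @param queryT genes x query-groups t matrix.
#' @param referenceT genes x reference-groups t matrix (gene names
#'   comparable to the query's, i.e. already ortholog-mapped).
#' @param universe optional character vector restricting the genes used.
#' @return query-groups x reference-groups correlation matrix.
#' @export
registrationCorrelation <- function(queryT, referenceT, universe = NULL) {
    shared <- intersect(rownames(queryT), rownames(referenceT))
    if (!is.null(universe)) shared <- intersect(shared, universe)
    if (length(shared) < 3)
        stop("fewer than 3 shared genes in the registration universe")
    stats::cor(queryT[shared, , drop = FALSE],
               referenceT[shared, , drop = FALSE])
}

#' Union of top reference markers by |t|
#'
#' Helper producing the registration universe: the union over reference
#' groups of the \code{topN} genes by t-statistic.
#'
#' @param referenceT genes x groups t matrix.
#' @param topN markers per group (default 100).
#' @return Character vector of genes.
#' @export
topMarkerUniverse <- function(referenceT, topN = 100) {
    unique(unlist(lapply(seq_len(ncol(referenceT)), function(j)
        rownames(referenceT)[order(referenceT[, j],
                                   decreasing = TRUE)[seq_len(min(topN,
                                       nrow(referenceT)))]])))
}

#' One-sided Fisher over-representation of a gene list in group DEG sets
#'
#' For each group, builds the 2 x 2 contingency table of membership in
#' the input list versus the group's DEG set over the stated universe and
#' reports the sample odds ratio (ad / bc) and the one-sided
#' (enrichment) Fisher exact p-value. Lists shorter than \code{minList}
#' after intersection with the universe are skipped with a warning.
#'
#' @param geneList character vector of genes of interest.
#' @param degSets named list of per-group DEG vectors.
#' @param universe character vector of all testable genes.
#' @param minList minimum list size (default 25).
#' @return data.frame with group, overlap, odds_ratio, p.
#' @export
overRepresentation <- function(geneList, degSets, universe, minList = 25) {
    geneList <- intersect(unique(geneList), universe)
    if (length(geneList) < minList) {
        warning(sprintf("gene list has %d genes after intersection (< %d); skipped",
                        length(geneList), minList))
        return(data.frame(group = character(), overlap = integer(),
                          odds_ratio = numeric(), p = numeric()))
    }
    out <- lapply(names(degSets), function(g) {
        deg <- intersect(unique(degSets[[g]]), universe)
        a <- length(intersect(geneList, deg))
        b <- length(setdiff(deg, geneList))
        c <- length(setdiff(geneList, deg))
        d <- length(universe) - a - b - c
        tab <- matrix(c(a, c, b, d), 2, 2)
        p <- stats::fisher.test(tab, alternative = "greater")$p.value
        or <- if (b * c == 0) Inf else (a * d) / (b * c)
        data.frame(group = g, overlap = a, odds_ratio = or, p = p)
    })
    do.call(rbind, out)
}

#' Heritability gene sets and flanked intervals per group
#'
#' From pseudobulk counts: CPM per group, relative expression = CPM
#' divided by the group's total CPM, selection of the top
#' \code{topFraction} of genes per group (ceiling rule), and construction
#' of flanked intervals \code{[start - flank, end + flank]} clipped at 0,
#' with sex and mitochondrial chromosomes excluded. Gene coordinates are
#' 0-based half-open on input (see \code{\link{writeBed}}).
#'
#' @param pseudobulk genes x groups summed count matrix.
#' @param topFraction fraction of genes to keep per group (e.g. 0.10 for
#'   cell types, 0.15 for spatial domains).
#' @param geneCoords data.frame with gene, chrom, start, end (0-based
#'   half-open).
#' @param flank bp added on both sides (default 1e5).
#' @param excludeChroms chromosomes dropped (default chrX, chrY, chrMT).
#' @return Named list (per group) of BED-ready data.frames
#'   (chrom/start/end/name); genes lacking coordinates are dropped and
#'   counted in the \code{dropped} attribute.
#' @export
heritabilityGenesets <- function(pseudobulk, topFraction, geneCoords,
                                 flank = 100000,
                                 excludeChroms = c("chrX", "chrY",
                                                   "chrMT")) {
    pseudobulk <- as.matrix(pseudobulk)
    cpm <- sweep(pseudobulk, 2, colSums(pseudobulk), "/") * 1e6
    rel <- sweep(cpm, 2, colSums(cpm), "/")
    lapply(stats::setNames(colnames(pseudobulk), colnames(pseudobulk)),
           function(g) {
        nTop <- ceiling(nrow(rel) * topFraction)
        top <- rownames(rel)[order(rel[, g],
                                   decreasing = TRUE)[seq_len(nTop)]]
        coords <- geneCoords[match(top, geneCoords$gene), ]
        dropped <- sum(is.na(coords$chrom))
        coords <- coords[!is.na(coords$chrom), ]
        coords <- coords[!coords$chrom %in% excludeChroms, ]
        out <- data.frame(chrom = coords$chrom,
                          start = pmax(0L, coords$start - flank),
                          end = coords$end + flank, name = coords$gene,
                          stringsAsFactors = FALSE)
        attr(out, "dropped") <- dropped
        out
    })
}
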