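# Trait-informed ligand-receptor prioritization and spatial co-occurrence
# enrichment from spot classifications and deconvolution weights.

#' Prioritize ligand-receptor candidates by trait evidence
#'
#' Evidence entries of "no data" (NA) are treated as 0 and a per-gene
#' maximum over the evidence columns is computed; genes above
#' \code{evidenceMin} are trait risk genes. Candidates are kept when the
#' ligand or the receptor is a risk gene, neither symbol starts with
#' "HLA" (MHC artifacts), and the aggregate rank is at most
#' \code{rankMax}.
#'
#' @param candidates data.frame with columns ligand, receptor,
#'   aggregate_rank (plus any scores carried along).
#' @param evidence data.frame: first column gene, remaining columns
#'   numeric evidence scores (NA = no data).
#' @param evidenceMin risk-gene threshold on the per-gene max evidence
#'   (strict >, default 0.1).
#' @param rankMax inclusive aggregate-rank cutoff (default 0.01).
#' @return The filtered candidate data.frame.
#' @export
prioritizeTraitLR <- function(candidates, evidence, evidenceMin = 0.1,
                              rankMax = 0.01) {
    scores <- as.matrix(evidence[, -1, drop = FALSE])
    scores[is.na(scores)] <- 0
    maxEvidence <- stats::setNames(apply(scores, 1, max),
                                   evidence[[1]])
    riskGenes <- names(maxEvidence)[maxEvidence > evidenceMin]
    keep <- (candidates$ligand %in% riskGenes |
             candidates$receptor %in% riskGenes) &
            !startsWith(candidates$ligand, "HLA") &
            !startsWith(candidates$receptor, "HLA") &
            candidates$aggregate_rank <= rankMax
    candidates[keep, , drop = FALSE]
}

#' Classify spots by ligand/receptor expression
#'
#' A spot "expresses" a gene when its log-normalized value is strictly
#' positive. Each spot is assigned exactly one of four classes.
#'
#' @param expr genes x spots log-normalized expression.
#' @param ligand,receptor gene names present in \code{expr}.
#' @return Factor per spot with levels coexpressing, ligand_only,
#'   receptor_only, neither.
#' @export
classifySpots <- function(expr, ligand, receptor) {
    if (!ligand %in% rownames(expr) || !receptor %in% rownames(expr))
        stop("ligand or receptor not found in the expression matrix")
    l <- as.numeric(expr[ligand, ]) > 0
    r <- as.numeric(expr[receptor, ]) > 0
    cls <- ifelse(l & r, "coexpressing",
                  ifelse(l, "ligand_only",
                         ifelse(r, "receptor_only", "neither")))
    factor(cls, levels = c("coexpressing", "ligand_only",
                           "receptor_only", "neither"))
}

#' Per-domain class proportions
#'
#' @param classification factor from \code{\link{classifySpots}}.
#' @param domains domain label per spot.
#' @return domains x classes matrix of fractions; rows sum to 1.
#' @export
domainClassProportions <- function(classification, domains) {
    tab <- table(domains, classification)
    prop <- tab / rowSums(tab)
    as.matrix(prop)
}

processCooccurrence <- function(C) {
    C[upper.tri(C, diag = TRUE)] <- 0
    s <- sum(C)
    if (s > 0) C <- C / s
    C
}

#' Cell-type co-occurrence enrichment in co-expressing spots
#'
#' With W the spots x cell-types deconvolution weight matrix, computes
#' \code{C = t(W_S) W_S} over the co-expressing spot set and its
#' complement, zeroes the diagonal and upper triangle of each, normalizes
#' the lower-triangle entries to sum to 1, and forms the element-wise
#' enrichment ratio \code{R = C_LR / (C_ctrl + epsilon)} on the lower
#' triangle. Entries of R above 1 mark cell-type pairs that co-occur
#' preferentially in co-expressing spots.
#'
#' @param weights spots x cell-types weight matrix; rows are renormalized
#'   to sum to 1 unless \code{renormalize = FALSE}.
#' @param classification factor from \code{\link{classifySpots}} (or a
#'   logical vector marking co-expressing spots).
#' @param epsilon stabilizer added to the control co-occurrence (default
#'   1e-6).
#' @param renormalize renormalize weight rows to sum 1 first.
#' @return A \linkS4class{CooccurrenceResult}; an empty co-expressing set
#'   flags the result undefined.
#' @export
cooccurrenceEnrichment <- function(weights, classification,
                                   epsilon = 1e-6, renormalize = TRUE) {
    weights <- as.matrix(weights)
    coex <- if (is.logical(classification)) classification
            else classification == "coexpressing"
    if (length(coex) != nrow(weights))
        stop("classification length must match the number of spots")
    if (renormalize) {
        rs <- rowSums(weights)
        rs[rs == 0] <- 1
        weights <- weights / rs
    }
    nct <- ncol(weights)
    ctNames <- colnames(weights) %||% sprintf("ct%d", seq_len(nct))
    emptyM <- matrix(0, nct, nct, dimnames = list(ctNames, ctNames))
    if (!any(coex)) {
        warning("no co-expressing spots; result undefined")
        return(new("CooccurrenceResult", cLR = emptyM, cCtrl = emptyM,
                   ratio = emptyM, epsilon = epsilon, nCoexpress = 0L,
                   nControl = as.integer(sum(!coex)), undefined = TRUE))
    }
    cLR <- processCooccurrence(crossprod(weights[coex, , drop = FALSE]))
    cCtrl <- processCooccurrence(crossprod(weights[!coex, , drop = FALSE]))
    ratio <- matrix(0, nct, nct)
    lower <- lower.tri(ratio)
    ratio[lower] <- cLR[lower] / (cCtrl[lower] + epsilon)
    dimnames(cLR) <- dimnames(cCtrl) <- dimnames(ratio) <-
        list(ctNames, ctNames)
    new("CooccurrenceResult", cLR = cLR, cCtrl = cCtrl, ratio = ratio,
        epsilon = epsilon, nCoexpress = as.integer(sum(coex)),
        nControl = as.integer(sum(!coex)), undefined = FALSE)
}
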