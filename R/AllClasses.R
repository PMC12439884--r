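#' @import methods
#' @importFrom Matrix Matrix t colSums rowSums readMM writeMM sparseMatrix
NULL

#' Rigid transform in the plane
#'
#' A rotation by \code{theta} radians about \code{center}, followed by a
#' translation. Applied to points as
#' \code{p' = R(theta) (p - center) + center + translation}, with points in
#' (x, y) pixel coordinates.
#'
#' @slot theta rotation angle in radians (counter-clockwise).
#' @slot translation numeric length-2 translation in pixels.
#' @slot center numeric length-2 rotation pivot in pixels.
#'
#' @exportClass RigidTransform2D
setClass("RigidTransform2D",
    representation(theta = "numeric", translation = "numeric",
                   center = "numeric"),
    prototype(theta = 0, translation = c(0, 0), center = c(0, 0)))

setValidity("RigidTransform2D", function(object) {
    if (length(object@theta) != 1L || !is.finite(object@theta))
        return("'theta' must be a single finite number")
    if (length(object@translation) != 2L || any(!is.finite(object@translation)))
        return("'translation' must be a finite length-2 vector")
    if (length(object@center) != 2L || any(!is.finite(object@center)))
        return("'center' must be a finite length-2 vector")
    TRUE
})

#' Construct a rigid transform
#'
#' @param theta rotation in radians.
#' @param translation length-2 numeric translation (px).
#' @param center length-2 numeric rotation pivot (px).
#' @return A \linkS4class{RigidTransform2D}.
#' @examples
#' tr <- RigidTransform2D(theta = pi / 6, translation = c(5, -2))
#' applyTransform(tr, cbind(1, 0))
#' @export
RigidTransform2D <- function(theta = 0, translation = c(0, 0),
                             center = c(0, 0)) {
    new("RigidTransform2D", theta = as.numeric(theta),
        translation = as.numeric(translation), center = as.numeric(center))
}

setMethod("show", "RigidTransform2D", function(object) {
    cat(sprintf("RigidTransform2D: theta = %.6g rad (%.4g deg), ",
                object@theta, object@theta * 180 / pi))
    cat(sprintf("translation = (%.6g, %.6g), center = (%.6g, %.6g)\n",
                object@translation[1], object@translation[2],
                object@center[1], object@center[2]))
})

#' Binary spatial neighbor graph over spots
#'
#' Symmetric 0/1 adjacency with zero diagonal, built by thresholding
#' pairwise Euclidean distances between spot coordinates. \code{S0} is the
#' sum of all adjacency entries, the normalizing constant of Moran-type
#' statistics.
#'
#' @slot adjacency sparse symmetric 0/1 matrix, zero diagonal.
#' @slot coords n x 2 matrix of spot coordinates.
#' @slot threshold distance threshold used to define neighbors.
#'
#' @exportClass SpatialGraph
setClass("SpatialGraph",
    representation(adjacency = "Matrix", coords = "matrix",
                   threshold = "numeric"))

setValidity("SpatialGraph", function(object) {
    A <- object@adjacency
    if (nrow(A) != ncol(A)) return("adjacency must be square")
    if (nrow(A) != nrow(object@coords))
        return("adjacency and coords disagree on the number of spots")
    if (any(Matrix::diag(A) != 0)) return("adjacency diagonal must be zero")
    if (!Matrix::isSymmetric(A)) return("adjacency must be symmetric")
    TRUE
})

#' @describeIn SpatialGraph-class number of spots.
#' @param x,object a \code{SpatialGraph}.
#' @export
setMethod("dim", "SpatialGraph", function(x) dim(x@adjacency))

setMethod("show", "SpatialGraph", function(object) {
    deg <- Matrix::rowSums(object@adjacency)
    cat(sprintf(
        "SpatialGraph: %d spots, %d edges, threshold %.6g, median degree %g\n",
        nrow(object@adjacency), sum(deg) / 2, object@threshold,
        stats::median(deg)))
})

#' Adjacency matrix of a spatial graph
#' @param graph a \linkS4class{SpatialGraph}.
#' @return Sparse symmetric adjacency matrix.
#' @export
adjacencyMatrix <- function(graph) {
    stopifnot(is(graph, "SpatialGraph"))
    graph@adjacency
}

#' Sum of adjacency weights (S0)
#' @param graph a \linkS4class{SpatialGraph}.
#' @return The scalar normalizing constant S0.
#' @export
graphS0 <- function(graph) {
    stopifnot(is(graph, "SpatialGraph"))
    sum(graph@adjacency)
}

#' Non-negative matrix factorization model
#'
#' Fitted factorization \code{A ~ W H} with non-negative gene loadings
#' \code{W} (genes x k) and observation scores \code{H} (k x observations).
#' After diagonal rescaling every column of \code{W} sums to 1 with the
#' scale absorbed into \code{H}.
#'
#' @slot w genes x k loadings matrix, non-negative.
#' @slot h k x observations scores matrix, non-negative.
#' @slot k factorization rank.
#' @slot objective numeric trace of the penalized objective per iteration.
#' @slot l1w L1 penalty applied to W during fitting.
#' @slot seed integer seed used for initialization.
#'
#' @exportClass FactorModel
setClass("FactorModel",
    representation(w = "matrix", h = "matrix", k = "integer",
                   objective = "numeric", l1w = "numeric", seed = "integer"))

setValidity("FactorModel", function(object) {
    if (ncol(object@w) != object@k || nrow(object@h) != object@k)
        return("rank k inconsistent with W/H dimensions")
    if (any(object@w < 0) || any(object@h < 0))
        return("W and H must be non-negative")
    TRUE
})

setMethod("show", "FactorModel", function(object) {
    cat(sprintf("FactorModel: %d genes x %d factors x %d observations\n",
                nrow(object@w), object@k, ncol(object@h)))
    cat(sprintf("  final objective %.6g after %d iterations (l1_w = %g)\n",
                utils::tail(object@objective, 1), length(object@objective),
                object@l1w))
})

#' Accessors for FactorModel
#'
#' \code{basisMatrix} returns the gene loadings W; \code{scoreMatrix} the
#' observation scores H; \code{objectiveTrace} the per-iteration objective.
#'
#' @param model a \linkS4class{FactorModel}.
#' @return The requested component.
#' @export
basisMatrix <- function(model) {
    stopifnot(is(model, "FactorModel"))
    model@w
}

#' @rdname basisMatrix
#' @export
scoreMatrix <- function(model) {
    stopifnot(is(model, "FactorModel"))
    model@h
}

#' @rdname basisMatrix
#' @export
objectiveTrace <- function(model) {
    stopifnot(is(model, "FactorModel"))
    model@objective
}

#' Projection of factor loadings onto a new dataset
#'
#' @slot h k x observations projected scores.
#' @slot normalized whether per-observation sum-to-1 normalization was
#'   applied.
#' @slot zeroObservations indices of all-zero observations, exempt from
#'   normalization.
#' @slot geneCoverage fraction of loading genes found in the target data.
#'
#' @exportClass ProjectionResult
setClass("ProjectionResult",
    representation(h = "matrix", normalized = "logical",
                   zeroObservations = "integer", geneCoverage = "numeric"))

setMethod("show", "ProjectionResult", function(object) {
    cat(sprintf(
        "ProjectionResult: %d factors x %d observations (%s, %.1f%% gene coverage)\n",
        nrow(object@h), ncol(object@h),
        if (object@normalized) "normalized" else "unnormalized",
        100 * object@geneCoverage))
})

#' Projected score matrix
#' @param projection a \linkS4class{ProjectionResult}.
#' @return k x observations matrix of projected factor scores.
#' @export
projectedScores <- function(projection) {
    stopifnot(is(projection, "ProjectionResult"))
    projection@h
}

#' Cell-type co-occurrence enrichment result
#'
#' Lower-triangular co-occurrence matrices over co-expressing and control
#' spot sets, and their enrichment ratio. After processing, the strictly
#' lower-triangular entries of each co-occurrence matrix sum to 1 and the
#' diagonal and upper triangle are 0.
#'
#' @slot cLR co-occurrence over co-expressing spots (processed).
#' @slot cCtrl co-occurrence over the complement spot set (processed).
#' @slot ratio element-wise enrichment on the lower triangle.
#' @slot epsilon stabilizer added to \code{cCtrl} in the ratio.
#' @slot nCoexpress,nControl sizes of the two spot sets.
#' @slot undefined TRUE when the co-expressing set was empty.
#'
#' @exportClass CooccurrenceResult
setClass("CooccurrenceResult",
    representation(cLR = "matrix", cCtrl = "matrix", ratio = "matrix",
                   epsilon = "numeric", nCoexpress = "integer",
                   nControl = "integer", undefined = "logical"))

setMethod("show", "CooccurrenceResult", function(object) {
    cat(sprintf(
        "CooccurrenceResult: %d cell types, %d co-expressing / %d control spots%s\n",
        nrow(object@cLR), object@nCoexpress, object@nControl,
        if (object@undefined) " [undefined: empty co-expressing set]" else ""))
    if (!object@undefined) {
        lower <- lower.tri(object@ratio)
        cat(sprintf("  enrichment ratio range on lower triangle: [%.3g, %.3g]\n",
                    min(object@ratio[lower]), max(object@ratio[lower])))
    }
})

#' Enrichment ratio matrix
#' @param result a \linkS4class{CooccurrenceResult}.
#' @return Cell-type x cell-type matrix with the enrichment ratio on the
#'   strict lower triangle and zeros elsewhere.
#' @export
enrichmentRatio <- function(result) {
    stopifnot(is(result, "CooccurrenceResult"))
    result@ratio
}

#' Cross-donor consensus grouping of spatial patterns
#'
#' @slot membership data.frame with one row per (donor, pattern):
#'   \code{donor}, \code{pattern}, \code{mcp} consensus group label,
#'   \code{representative} logical flag.
#' @slot similarity consensus similarity matrix used for clustering.
#' @slot k number of groups in the tree cut.
#'
#' @exportClass ConsensusPatterns
setClass("ConsensusPatterns",
    representation(membership = "data.frame", similarity = "matrix",
                   k = "integer"))

setMethod("show", "ConsensusPatterns", function(object) {
    cat(sprintf("ConsensusPatterns: %d patterns in %d consensus groups, %d representatives\n",
                nrow(object@membership), object@k,
                sum(object@membership$representative)))
})

#' Consensus membership table
#' @param x a \linkS4class{ConsensusPatterns}.
#' @return data.frame of donor/pattern/group/representative assignments.
#' @export
consensusMembership <- function(x) {
    stopifnot(is(x, "ConsensusPatterns"))
    x@membership
}
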