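# Reconstruction of a whole tissue section from several capture areas:
# rigid-transform algebra, landmark-based rotation/translation estimation,
# propagation of pairwise refinements along a spanning tree of the overlap
# graph, construction of a donor-level artificial hexagonal grid, nearest-
# lattice-point respotting, and detection/resolution of overlapping spots.

#' Apply a rigid transform to points
#'
#' @param transform a \linkS4class{RigidTransform2D}.
#' @param points n x 2 matrix of (x, y) coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
applyTransform <- function(transform, points) {
    points <- rbind2cols(points)
    R <- rotationMatrix(transform@theta)
    sweep(t(R %*% t(sweep(points, 2, transform@center))), 2,
          transform@center + transform@translation, "+")
}

rotationMatrix <- function(theta) {
    matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Invert a rigid transform
#'
#' @param transform a \linkS4class{RigidTransform2D}.
#' @return The inverse transform; composing the two is the identity to
#'   within numerical precision on any point.
#' @export
invertTransform <- function(transform) {
    Rinv <- rotationMatrix(-transform@theta)
    RigidTransform2D(theta = -transform@theta,
                     translation = as.numeric(-Rinv %*%
                                              transform@translation),
                     center = transform@center)
}

#' Convert a rigid transform to a 2x3 affine matrix
#' @param transform a \linkS4class{RigidTransform2D}.
#' @return 2x3 matrix acting on column points as \code{A[,1:2] p + A[,3]}.
#' @export
asAffine <- function(transform) {
    R <- rotationMatrix(transform@theta)
    offset <- transform@center + transform@translation -
        R %*% transform@center
    cbind(R, offset)
}

#' Compose two affine transforms
#' @param outer,inner 2x3 affine matrices; the result applies \code{inner}
#'   first.
#' @return 2x3 affine matrix of the composition.
#' @export
composeAffine <- function(outer, inner) {
    cbind(outer[, 1:2] %*% inner[, 1:2],
          outer[, 1:2] %*% inner[, 3] + outer[, 3])
}

#' Estimate the rotation aligning one landmark set to another
#'
#' For every unordered pair of landmarks, the segment joining them is
#' formed in each capture area and the signed angle between the two
#' segments is computed via atan2 of their cross and dot products. The
#' returned angle is the weighted circular mean of these pairwise angles,
#' with weights equal to the geometric mean of the two segment lengths.
#' Rotating the B-side landmarks by the returned angle aligns their
#' orientation with the A side.
#'
#' @param landmarks data.frame with columns xA, yA, xB, yB (>= 2 rows).
#' @return Rotation angle in radians.
#' @export
estimateRotation <- function(landmarks) {
    n <- nrow(landmarks)
    if (n < 2) stop("at least 2 landmark pairs are required")
    idx <- utils::combn(n, 2)
    vax <- landmarks$xA[idx[2, ]] - landmarks$xA[idx[1, ]]
    vay <- landmarks$yA[idx[2, ]] - landmarks$yA[idx[1, ]]
    vbx <- landmarks$xB[idx[2, ]] - landmarks$xB[idx[1, ]]
    vby <- landmarks$yB[idx[2, ]] - landmarks$yB[idx[1, ]]
    lenA <- sqrt(vax^2 + vay^2)
    lenB <- sqrt(vbx^2 + vby^2)
    ok <- lenA > 0 & lenB > 0
    if (!all(ok))
        warning(sprintf("%d zero-length segment pair(s) skipped",
                        sum(!ok)))
    if (!any(ok)) stop("degenerate input: all segment pairs have zero length")
    angle <- atan2(vbx * vay - vby * vax, vbx * vax + vby * vay)[ok]
    w <- sqrt(lenA * lenB)[ok]
    atan2(sum(w * sin(angle)), sum(w * cos(angle)))
}

#' Estimate the translation after de-rotation
#'
#' Rotates the B-side landmarks by \code{theta} about their centroid, then
#' returns the mean of the per-landmark displacement vectors from the
#' rotated B points to the A points.
#'
#' @param landmarks data.frame with columns xA, yA, xB, yB.
#' @param theta rotation (radians) from \code{\link{estimateRotation}}.
#' @return Length-2 translation vector (px).
#' @export
estimateTranslation <- function(landmarks, theta = 0) {
    if (nrow(landmarks) == 0) stop("no landmark pairs")
    pb <- cbind(landmarks$xB, landmarks$yB)
    centroid <- colMeans(pb)
    rotated <- applyTransform(RigidTransform2D(theta, c(0, 0), centroid),
                              pb)
    colMeans(cbind(landmarks$xA, landmarks$yA) - rotated)
}

#' Estimate a full rigid transform from landmark pairs
#'
#' Convenience wrapper combining \code{\link{estimateRotation}} and
#' \code{\link{estimateTranslation}}; the rotation pivot is the B-side
#' landmark centroid.
#'
#' @param landmarks data.frame with columns xA, yA, xB, yB.
#' @return A \linkS4class{RigidTransform2D} mapping B coordinates onto A.
#' @export
estimateRigidTransform <- function(landmarks) {
    theta <- estimateRotation(landmarks)
    shift <- estimateTranslation(landmarks, theta)
    RigidTransform2D(theta = theta, translation = shift,
                     center = colMeans(cbind(landmarks$xB, landmarks$yB)))
}

#' Refine coarse alignment of capture areas from landmark pairs
#'
#' Fixes the first area as reference and propagates pairwise rigid
#' refinements along a spanning tree of the overlap graph (areas as nodes,
#' landmark-sharing pairs as edges), composing the refinements on top of
#' the supplied coarse transforms.
#'
#' @param areaIds character vector of capture-area ids, in order; the
#'   first is the reference.
#' @param landmarks named list of landmark data.frames; names are
#'   \code{"idA|idB"}, coordinates in each area's own (native) frame.
#' @param coarse named list of 2x3 coarse affine matrices per area;
#'   identity assumed for areas absent from the list.
#' @return List with \code{transforms} (named list of final 2x3 affines,
#'   native frame to stitched frame), \code{residuals} (named numeric,
#'   mean landmark distance per pair after refinement) and
#'   \code{coarseResiduals} (same, before refinement).
#' @export
refineAlignment <- function(areaIds, landmarks, coarse = list()) {
    identity23 <- cbind(diag(2), c(0, 0))
    coarseOf <- function(a) if (!is.null(coarse[[a]])) coarse[[a]] else
        identity23
    edges <- strsplit(names(landmarks), "|", fixed = TRUE)
    adj <- lapply(stats::setNames(areaIds, areaIds),
                  function(a) character())
    for (e in seq_along(edges)) {
        a <- edges[[e]][1]; b <- edges[[e]][2]
        adj[[a]] <- c(adj[[a]], b)
        adj[[b]] <- c(adj[[b]], a)
    }
    # connectivity check over the overlap graph
    seen <- areaIds[1]
    frontier <- areaIds[1]
    while (length(frontier)) {
        nxt <- setdiff(unlist(adj[frontier]), seen)
        seen <- c(seen, nxt)
        frontier <- nxt
    }
    if (length(setdiff(areaIds, seen)))
        stop(sprintf("overlap graph is disconnected; unreachable area(s): %s",
                     paste(setdiff(areaIds, seen), collapse = ", ")))
    # landmarks mapped through the coarse transforms
    coarseLm <- lapply(seq_along(landmarks), function(e) {
        a <- edges[[e]][1]; b <- edges[[e]][2]
        pa <- applyAffine(coarseOf(a), cbind(landmarks[[e]]$xA,
                                             landmarks[[e]]$yA))
        pb <- applyAffine(coarseOf(b), cbind(landmarks[[e]]$xB,
                                             landmarks[[e]]$yB))
        data.frame(xA = pa[, 1], yA = pa[, 2], xB = pb[, 1], yB = pb[, 2])
    })
    names(coarseLm) <- names(landmarks)
    # BFS spanning tree from the reference, composing corrections
    correction <- stats::setNames(vector("list", length(areaIds)), areaIds)
    correction[[areaIds[1]]] <- identity23
    queue <- areaIds[1]
    while (length(queue)) {
        p <- queue[1]; queue <- queue[-1]
        for (b in adj[[p]]) {
            if (!is.null(correction[[b]])) next
            key <- if (!is.null(coarseLm[[paste(p, b, sep = "|")]]))
                paste(p, b, sep = "|") else paste(b, p, sep = "|")
            lm <- coarseLm[[key]]
            if (!startsWith(key, paste0(p, "|"))) # swap so A side is parent
                lm <- data.frame(xA = lm$xB, yA = lm$yB, xB = lm$xA,
                                 yB = lm$yA)
            pairwise <- asAffine(estimateRigidTransform(lm))
            correction[[b]] <- composeAffine(correction[[p]], pairwise)
            queue <- c(queue, b)
        }
    }
    transforms <- lapply(stats::setNames(areaIds, areaIds), function(a)
        composeAffine(correction[[a]], coarseOf(a)))
    residualOf <- function(trA, trB, lm) {
        pa <- applyAffine(trA, cbind(lm$xA, lm$yA))
        pb <- applyAffine(trB, cbind(lm$xB, lm$yB))
        mean(sqrt(rowSums((pa - pb)^2)))
    }
    residuals <- vapply(seq_along(landmarks), function(e) {
        a <- edges[[e]][1]; b <- edges[[e]][2]
        residualOf(correction[[a]], correction[[b]], coarseLm[[e]])
    }, numeric(1))
    coarseResiduals <- vapply(coarseLm, function(lm)
        mean(sqrt((lm$xA - lm$xB)^2 + (lm$yA - lm$yB)^2)), numeric(1))
    names(residuals) <- names(landmarks)
    list(transforms = transforms, residuals = residuals,
         coarseResiduals = coarseResiduals)
}

#' Apply per-area transforms to spot positions
#'
#' @param spots data.frame with capture_area and native pixel x, y.
#' @param transforms named list of 2x3 affines per capture area.
#' @return The data.frame with stitched coordinates \code{gx}, \code{gy}.
#' @export
stitchSpots <- function(spots, transforms) {
    out <- spots
    out$gx <- NA_real_; out$gy <- NA_real_
    for (a in unique(spots$capture_area)) {
        sel <- spots$capture_area == a
        tr <- transforms[[a]]
        if (is.null(tr)) stop(sprintf("no transform for area '%s'", a))
        g <- applyAffine(tr, cbind(spots$x[sel], spots$y[sel]))
        out$gx[sel] <- g[, 1]; out$gy[sel] <- g[, 2]
    }
    out
}

#' Donor-level artificial hexagonal grid
#'
#' @slot pitch lattice spacing in pixels.
#' @slot origin (x, y) of the array (0, 0) lattice point, anchored at the
#'   minimum pixel coordinates of the stitched spots.
#' @slot rows,cols number of lattice rows and columns generated.
#' @exportClass ArtificialGrid
setClass("ArtificialGrid",
    representation(pitch = "numeric", origin = "numeric", rows = "integer",
                   cols = "integer"))

setMethod("show", "ArtificialGrid", function(object) {
    cat(sprintf(
        "ArtificialGrid: %d rows x %d cols at pitch %.6g px, origin (%.6g, %.6g)\n",
        object@rows, object@cols, object@pitch, object@origin[1],
        object@origin[2]))
})

#' Build the donor-level artificial grid covering all stitched spots
#'
#' Lays a hexagonal lattice with spacing \code{pitchPx} over the bounding
#' box of the stitched coordinates. The origin is anchored so the minimum
#' pixel coordinates map to array index 0; rows and columns are added as
#' necessary (typically far beyond the native 77 x 127) so every spot is
#' covered.
#'
#' @param coords n x 2 matrix (or data.frame with gx, gy) of stitched
#'   spot coordinates.
#' @param pitchPx lattice spacing in pixels (e.g. the pixel realization of
#'   the 100 um spot pitch).
#' @return An \linkS4class{ArtificialGrid}.
#' @export
buildArtificialGrid <- function(coords, pitchPx) {
    if (pitchPx <= 0) stop("pitch must be > 0")
    if (is.data.frame(coords)) coords <- cbind(coords$gx, coords$gy)
    coords <- rbind2cols(coords)
    dy <- pitchPx * sqrt(3) / 2
    rows <- as.integer(ceiling((max(coords[, 2]) - min(coords[, 2])) / dy)
                       + 1L)
    cols <- as.integer(ceiling((max(coords[, 1]) - min(coords[, 1])) /
                               (pitchPx / 2)) + 2L)
    new("ArtificialGrid", pitch = pitchPx,
        origin = c(min(coords[, 1]), min(coords[, 2])), rows = rows,
        cols = cols)
}

#' Lattice point centers of an artificial grid
#' @param grid an \linkS4class{ArtificialGrid}.
#' @return data.frame with array_row, array_col, x, y for every lattice
#'   point (array_col parity equals array_row parity).
#' @export
gridCenters <- function(grid) {
    dy <- grid@pitch * sqrt(3) / 2
    rows <- seq_len(grid@rows) - 1L
    out <- do.call(rbind, lapply(rows, function(r) {
        cc <- seq(r %% 2L, grid@cols, by = 2L)
        data.frame(array_row = r, array_col = cc)
    }))
    out$x <- grid@origin[1] + out$array_col * grid@pitch / 2
    out$y <- grid@origin[2] + out$array_row * dy
    out
}

#' Assign stitched spots to their nearest artificial lattice point
#'
#' Each spot receives the (array_row, array_col) of the nearest lattice
#' point by Euclidean distance; exact ties go to the lexicographically
#' smallest (array_row, array_col). Multiple spots may share coordinates in
#' regions of capture-area overlap. The native coordinates are preserved as
#' \code{array_row_original} / \code{array_col_original}.
#'
#' @param spots data.frame with stitched gx, gy (and optionally native
#'   array coordinates).
#' @param grid an \linkS4class{ArtificialGrid}.
#' @return The data.frame with redefined array_row/array_col, the original
#'   values in *_original columns, and the assignment distance in
#'   \code{grid_distance}.
#' @export
assignToGrid <- function(spots, grid) {
    dy <- grid@pitch * sqrt(3) / 2
    halfp <- grid@pitch / 2
    n <- nrow(spots)
    newRow <- integer(n); newCol <- integer(n); dist <- numeric(n)
    for (i in seq_len(n)) {
        px <- spots$gx[i] - grid@origin[1]
        py <- spots$gy[i] - grid@origin[2]
        r0 <- py / dy
        rCand <- unique(pmin(pmax(c(floor(r0) - 1, floor(r0), ceiling(r0),
                                    ceiling(r0) + 1), 0), grid@rows - 1L))
        best <- NULL
        for (r in rCand) {
            par <- r %% 2
            c0 <- round((px / halfp - par) / 2) * 2 + par
            for (cc in c(c0 - 2, c0, c0 + 2)) {
                if (cc < 0 || cc > grid@cols) next
                d <- sqrt((px - cc * halfp)^2 + (py - r * dy)^2)
                cand <- c(d, r, cc)
                if (is.null(best) || d < best[1] - 1e-9 ||
                    (abs(d - best[1]) <= 1e-9 &&
                     (r < best[2] || (r == best[2] && cc < best[3]))))
                    best <- cand
            }
        }
        dist[i] <- best[1]; newRow[i] <- best[2]; newCol[i] <- best[3]
    }
    out <- spots
    if ("array_row" %in% names(spots) &&
        !"array_row_original" %in% names(spots)) {
        out$array_row_original <- spots$array_row
        out$array_col_original <- spots$array_col
    }
    out$array_row <- newRow
    out$array_col <- newCol
    out$grid_distance <- dist
    out
}

#' Detect overlapping spots across capture areas
#'
#' The overlap threshold is 1.5 times the median nearest-neighbor distance
#' of the first listed capture area's spots (its native spacing realized in
#' stitched pixels). Cross-area spot pairs within the threshold are
#' overlap pairs.
#'
#' @param spots data.frame with capture_area and stitched gx, gy; area
#'   order follows the order of first appearance.
#' @param thresholdFactor multiplier of the median nearest-neighbor
#'   distance.
#' @return List with \code{pairs} (spot_a, spot_b, area_a, area_b,
#'   distance), \code{threshold}, and \code{areas} in listed order. A
#'   single area yields an empty assignment.
#' @export
detectOverlaps <- function(spots, thresholdFactor = 1.5) {
    areas <- unique(spots$capture_area)
    empty <- data.frame(spot_a = character(), spot_b = character(),
                        area_a = character(), area_b = character(),
                        distance = numeric())
    if (length(areas) < 2)
        return(list(pairs = empty, threshold = NA_real_, areas = areas))
    first <- spots[spots$capture_area == areas[1], ]
    d <- as.matrix(stats::dist(cbind(first$gx, first$gy)))
    diag(d) <- Inf
    threshold <- thresholdFactor * stats::median(apply(d, 1, min))
    pairs <- list()
    for (i in seq_along(areas)) for (j in seq_along(areas)) {
        if (j <= i) next
        A <- spots[spots$capture_area == areas[i], ]
        B <- spots[spots$capture_area == areas[j], ]
        d2 <- outer(A$gx, B$gx, "-")^2 + outer(A$gy, B$gy, "-")^2
        # a spot is overlapping when its nearest cross-area spot is within
        # the threshold; each such spot pairs with that nearest spot
        nearB <- max.col(-d2, ties.method = "first")       # per A spot
        nearA <- max.col(-t(d2), ties.method = "first")    # per B spot
        hits <- rbind(
            cbind(which(d2[cbind(seq_len(nrow(A)), nearB)] <= threshold^2),
                  nearB[d2[cbind(seq_len(nrow(A)), nearB)] <= threshold^2]),
            cbind(nearA[d2[cbind(nearA, seq_len(nrow(B)))] <= threshold^2],
                  which(d2[cbind(nearA, seq_len(nrow(B)))] <= threshold^2)))
        hits <- unique(hits)
        if (nrow(hits))
            pairs[[length(pairs) + 1L]] <- data.frame(
                spot_a = A$barcode[hits[, 1]], spot_b = B$barcode[hits[, 2]],
                area_a = areas[i], area_b = areas[j],
                distance = sqrt(d2[hits]))
    }
    pairs <- if (length(pairs)) do.call(rbind, pairs) else empty
    list(pairs = pairs, threshold = threshold, areas = areas)
}

#' Resolve overlapping spots by sequencing depth
#'
#' For each pair of overlapping capture areas, the side whose overlapping
#' spots have the lower minimum UMI count is marked for exclusion
#' (\code{exclude_overlapping}); ties flag the later-listed area. Spots of
#' the prioritized (kept) side are never flagged.
#'
#' @param assignment result of \code{\link{detectOverlaps}}.
#' @param umiPerSpot named numeric vector of per-spot UMI totals.
#' @return data.frame with barcode and logical exclude_overlapping for
#'   every spot involved in an overlap.
#' @export
resolveOverlaps <- function(assignment, umiPerSpot) {
    pairs <- assignment$pairs
    if (!nrow(pairs))
        return(data.frame(barcode = character(),
                          exclude_overlapping = logical()))
    excluded <- character()
    for (key in unique(paste(pairs$area_a, pairs$area_b, sep = "|"))) {
        sub <- pairs[paste(pairs$area_a, pairs$area_b, sep = "|") == key, ]
        minA <- min(umiPerSpot[unique(sub$spot_a)])
        minB <- min(umiPerSpot[unique(sub$spot_b)])
        # ties flag the later-listed area (the B side)
        excluded <- c(excluded,
                      if (minA < minB) unique(sub$spot_a)
                      else unique(sub$spot_b))
    }
    involved <- unique(c(pairs$spot_a, pairs$spot_b))
    data.frame(barcode = involved,
               exclude_overlapping = involved %in% excluded)
}

#' Distance of a native spot to the capture-area boundary
#'
#' Computed per capture area from the untransformed array_row / array_col
#' values as the Euclidean distance (in array units) to the boundary of the
#' native array rectangle. For spots inside the rectangle this is the
#' minimum of the four edge distances.
#'
#' @param positions data.frame with array_row and array_col (native).
#' @param rowMax,colMax native array bounds (defaults 77 and 127).
#' @return Numeric vector of per-spot edge distances.
#' @export
edgeDistance <- function(positions, rowMax = 77, colMax = 127) {
    if (is.null(positions$array_row) || is.null(positions$array_col) ||
        any(is.na(positions$array_row)) || any(is.na(positions$array_col)))
        stop("native array coordinates are missing")
    pmin(positions$array_row, rowMax - positions$array_row,
         positions$array_col, colMax - positions$array_col)
}
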