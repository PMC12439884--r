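# Synthetic Visium-like data with planted ground truth: multi-capture-area
# hexagonal layouts with known rigid offsets and overlaps, domain-structured
# negative-binomial counts (lateral gradients or island domains), cell-type
# labelled nuclei, and Dirichlet deconvolution weights. Every generator is a
# pure function of (config, seed).

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, runs the expression, and restores the caller's RNG state,
#' so generators are pure functions of their seed.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic data generators. The defaults are the
#' study conditions used throughout the test-suite simulations: two capture
#' areas of 20 x 20 hexagonal spots at 100 um pitch with 20% overlap, 200
#' genes across 3 domains, negative-binomial counts (mean 2, dispersion 5)
#' and domain markers at 8-fold enrichment.
#'
#' @param seed integer seed driving every random draw.
#' @param nCaptureAreas number of capture areas per section.
#' @param gridRows,gridCols hexagonal lattice dimensions per area.
#' @param pitch center-to-center spot distance (um; realized 1:1 in px).
#' @param overlapFraction fraction of each area's width shared with the
#'   next area, in [0, 1).
#' @param trueTransforms optional list of per-area
#'   \linkS4class{RigidTransform2D}; by default areas are chained left to
#'   right with the configured overlap and a small alternating rotation.
#' @param nGenes,nDomains counts of genes and spatial domains.
#' @param domainLayout \code{"lateral_gradient"}, \code{"island"} or
#'   \code{"uniform"}.
#' @param nbMean,nbDispersion negative binomial baseline mean and
#'   dispersion theta (variance mu + mu^2 / theta).
#' @param markerFoldChange fold enrichment of domain markers (> 1).
#' @param markersPerDomain genes reserved as markers per domain.
#' @param landmarkNoiseSd Gaussian jitter of landmark coordinates (px).
#' @param nLandmarks landmark pairs per overlapping area pair (>= 4).
#' @return A list of class \code{"simConfig"}.
#' @export
simConfig <- function(seed = 1L, nCaptureAreas = 2L, gridRows = 20L,
                      gridCols = 20L, pitch = 100, overlapFraction = 0.2,
                      trueTransforms = NULL, nGenes = 200L, nDomains = 3L,
                      domainLayout = c("lateral_gradient", "island",
                                       "uniform"),
                      nbMean = 2, nbDispersion = 5, markerFoldChange = 8,
                      markersPerDomain = 10L, landmarkNoiseSd = 0,
                      nLandmarks = 8L) {
    domainLayout <- match.arg(domainLayout)
    if (pitch <= 0) stop("pitch must be > 0")
    if (nbDispersion <= 0) stop("nb_dispersion must be > 0")
    if (markerFoldChange <= 1) stop("marker_fold_change must be > 1")
    if (overlapFraction < 0 || overlapFraction >= 1)
        stop("overlap_fraction must be in [0, 1)")
    if (nGenes < nDomains * markersPerDomain)
        stop("n_genes must be at least n_domains * markers_per_domain")
    structure(list(seed = as.integer(seed),
                   nCaptureAreas = as.integer(nCaptureAreas),
                   gridRows = as.integer(gridRows),
                   gridCols = as.integer(gridCols), pitch = pitch,
                   overlapFraction = overlapFraction,
                   trueTransforms = trueTransforms,
                   nGenes = as.integer(nGenes),
                   nDomains = as.integer(nDomains),
                   domainLayout = domainLayout, nbMean = nbMean,
                   nbDispersion = nbDispersion,
                   markerFoldChange = markerFoldChange,
                   markersPerDomain = as.integer(markersPerDomain),
                   landmarkNoiseSd = landmarkNoiseSd,
                   nLandmarks = as.integer(nLandmarks)),
              class = "simConfig")
}

#' Hexagonal spot lattice in native array coordinates
#'
#' Builds a Visium-parity hexagonal lattice: array_col parity equals
#' array_row parity, the same-row neighbor sits at +/- 2 columns, and each
#' interior spot has six equidistant neighbors at \code{pitch}. Pixel
#' coordinates use x = array_col * pitch / 2, y = array_row * pitch *
#' sqrt(3) / 2.
#'
#' @param rows,cols number of lattice rows and spots per row.
#' @param pitch neighbor distance.
#' @param barcodePrefix prefix for generated barcodes.
#' @return data.frame with barcode, array_row, array_col, x, y.
#' @export
hexLattice <- function(rows, cols, pitch = 100, barcodePrefix = "SPOT") {
    r <- rep(seq_len(rows) - 1L, each = cols)
    j <- rep(seq_len(cols) - 1L, times = rows)
    cc <- 2L * j + r %% 2L
    data.frame(barcode = sprintf("%s-%05d", barcodePrefix, seq_along(r)),
               array_row = r, array_col = cc,
               x = cc * pitch / 2, y = r * pitch * sqrt(3) / 2,
               stringsAsFactors = FALSE)
}

defaultTransforms <- function(config) {
    width <- (2 * (config$gridCols - 1)) * config$pitch / 2
    step <- (1 - config$overlapFraction) * width
    lapply(seq_len(config$nCaptureAreas), function(a) {
        theta <- if (a == 1) 0 else ((-1)^a) * 0.05 * (a - 1)
        RigidTransform2D(theta = theta,
                         translation = c((a - 1) * step, 0))
    })
}

#' Simulate stitched capture areas with landmarks and ground truth
#'
#' Generates \code{nCaptureAreas} hexagonal capture areas, places them in a
#' common pixel frame by the (possibly planted) true rigid transforms, and
#' derives matched landmark pairs across each overlapping pair of areas
#' with Gaussian jitter. Cross-area spots closer than half a pitch in the
#' common frame are recorded as true overlap pairs.
#'
#' @param config a \code{\link{simConfig}}.
#' @return List with elements \code{spots} (data.frame over all areas with
#'   capture_area, native array coordinates, native pixel x/y and true
#'   stitched pixel coordinates \code{gx}/\code{gy}), \code{landmarks}
#'   (named list per adjacent pair, data.frames with xA, yA, xB, yB in the
#'   two areas' own frames), and \code{groundTruth} (true transforms and
#'   overlap pairs).
#' @export
simulateCaptureAreas <- function(config) {
    stopifnot(inherits(config, "simConfig"))
    if (config$nLandmarks < 4)
        stop("configuration error: at least 4 landmark pairs per overlap are required")
    transforms <- config$trueTransforms
    if (is.null(transforms)) transforms <- defaultTransforms(config)
    if (length(transforms) != config$nCaptureAreas)
        stop("one true transform per capture area is required")
    withSeed(config$seed, {
        areas <- lapply(seq_len(config$nCaptureAreas), function(a) {
            lat <- hexLattice(config$gridRows, config$gridCols, config$pitch,
                              barcodePrefix = sprintf("A%d", a))
            g <- applyTransform(transforms[[a]], cbind(lat$x, lat$y))
            lat$capture_area <- sprintf("area%d", a)
            lat$gx <- g[, 1]
            lat$gy <- g[, 2]
            lat
        })
        spots <- do.call(rbind, areas)
        landmarks <- list()
        if (config$nCaptureAreas > 1) {
            for (a in seq_len(config$nCaptureAreas - 1L)) {
                A <- areas[[a]]; B <- areas[[a + 1L]]
                xr <- c(max(min(A$gx), min(B$gx)), min(max(A$gx), max(B$gx)))
                yr <- c(max(min(A$gy), min(B$gy)), min(max(A$gy), max(B$gy)))
                if (xr[1] >= xr[2] || yr[1] >= yr[2])
                    stop(sprintf(
                        "configuration error: areas %d and %d do not overlap",
                        a, a + 1L))
                gpts <- cbind(stats::runif(config$nLandmarks, xr[1], xr[2]),
                              stats::runif(config$nLandmarks, yr[1], yr[2]))
                pa <- applyTransform(invertTransform(transforms[[a]]), gpts)
                pb <- applyTransform(invertTransform(transforms[[a + 1L]]),
                                     gpts)
                jitter <- function(p) p + matrix(
                    stats::rnorm(length(p), sd = config$landmarkNoiseSd),
                    ncol = 2)
                pa <- jitter(pa); pb <- jitter(pb)
                landmarks[[sprintf("area%d|area%d", a, a + 1L)]] <-
                    data.frame(xA = pa[, 1], yA = pa[, 2],
                               xB = pb[, 1], yB = pb[, 2])
            }
        }
        overlapPairs <- trueOverlapPairs(spots, config$pitch / 2)
        list(spots = spots, landmarks = landmarks,
             groundTruth = list(trueTransforms = transforms,
                                trueOverlapPairs = overlapPairs))
    })
}

trueOverlapPairs <- function(spots, maxDist) {
    out <- list()
    areas <- unique(spots$capture_area)
    for (i in seq_along(areas)) for (j in seq_along(areas)) {
        if (j <= i) next
        A <- spots[spots$capture_area == areas[i], ]
        B <- spots[spots$capture_area == areas[j], ]
        d2 <- outer(A$gx, B$gx, "-")^2 + outer(A$gy, B$gy, "-")^2
        hit <- which(d2 <= maxDist^2, arr.ind = TRUE)
        if (nrow(hit))
            out[[length(out) + 1L]] <- data.frame(
                spot_a = A$barcode[hit[, 1]], spot_b = B$barcode[hit[, 2]],
                area_a = areas[i], area_b = areas[j],
                distance = sqrt(d2[hit]))
    }
    if (length(out)) do.call(rbind, out)
    else data.frame(spot_a = character(), spot_b = character(),
                    area_a = character(), area_b = character(),
                    distance = numeric())
}

#' Assign spatial domain labels to spots
#'
#' \code{lateral_gradient} lays \code{nDomains} bands along the lateral
#' (x) axis with linear hat-function marker weights so domain transitions
#' are gradual; \code{island} plants circular domains 2..nDomains on a
#' background domain 1; \code{uniform} assigns labels at random.
#'
#' @param spots data.frame with \code{gx}, \code{gy} (or \code{x},
#'   \code{y}) coordinates.
#' @param config a \code{\link{simConfig}}.
#' @return List with integer \code{labels} (one per spot) and the spot x
#'   weight matrix \code{weights} (n x nDomains marker intensity weights
#'   in [0, 1]).
#' @export
assignDomains <- function(spots, config) {
    x <- if ("gx" %in% names(spots)) spots$gx else spots$x
    y <- if ("gy" %in% names(spots)) spots$gy else spots$y
    n <- length(x)
    k <- config$nDomains
    W <- matrix(0, n, k)
    if (config$domainLayout == "lateral_gradient") {
        centers <- seq(min(x), max(x), length.out = k)
        halfwidth <- if (k > 1) diff(centers[1:2]) else diff(range(x)) + 1
        for (d in seq_len(k))
            W[, d] <- pmax(0, 1 - abs(x - centers[d]) / halfwidth)
        labels <- max.col(W, ties.method = "first")
    } else if (config$domainLayout == "island") {
        labels <- rep(1L, n)
        W[, 1] <- 1
        nIsl <- k - 1L
        if (nIsl > 0) {
            radius <- config$pitch * max(2, min(config$gridRows,
                                                config$gridCols) / 6)
            cx <- stats::quantile(x, probs = seq(0.2, 0.8,
                                                 length.out = nIsl))
            cy <- stats::quantile(y, probs = rep(0.5, nIsl))
            for (d in seq_len(nIsl)) {
                inside <- (x - cx[d])^2 + (y - cy[d])^2 <= radius^2
                labels[inside] <- d + 1L
                W[inside, d + 1L] <- 1
                W[inside, 1] <- 0
            }
        }
    } else {
        labels <- sample.int(k, n, replace = TRUE)
        W[cbind(seq_len(n), labels)] <- 1
    }
    list(labels = labels, weights = W)
}

#' Simulate domain-structured negative-binomial spot counts
#'
#' Each domain owns a disjoint marker set whose negative-binomial mean is
#' multiplied by \code{markerFoldChange} according to the spot's domain
#' weight (so gradient layouts interpolate marker means linearly along the
#' lateral axis); all other genes share the baseline mean.
#'
#' @param spots data.frame of spots (see \code{\link{simulateCaptureAreas}}).
#' @param config a \code{\link{simConfig}}.
#' @param seed seed; defaults to \code{config$seed + 1}.
#' @return List with \code{counts} (sparse genes x spots matrix),
#'   \code{domains} (integer labels) and \code{markers} (list of marker
#'   gene names per domain).
#' @export
simulateDomainCounts <- function(spots, config, seed = config$seed + 1L) {
    stopifnot(inherits(config, "simConfig"))
    dom <- assignDomains(spots, config)
    n <- nrow(spots)
    g <- config$nGenes
    genes <- sprintf("gene%04d", seq_len(g))
    markers <- split(genes[seq_len(config$nDomains *
                                   config$markersPerDomain)],
                     rep(seq_len(config$nDomains),
                         each = config$markersPerDomain))
    names(markers) <- sprintf("domain%d", seq_len(config$nDomains))
    withSeed(seed, {
        mu <- matrix(config$nbMean, nrow = g, ncol = n,
                     dimnames = list(genes, spots$barcode))
        for (d in seq_len(config$nDomains)) {
            fold <- 1 + (config$markerFoldChange - 1) * dom$weights[, d]
            mu[markers[[d]], ] <- config$nbMean *
                matrix(fold, nrow = config$markersPerDomain, ncol = n,
                       byrow = TRUE)
        }
        counts <- matrix(stats::rnbinom(g * n, mu = mu,
                                        size = config$nbDispersion),
                         nrow = g, dimnames = dimnames(mu))
        list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                  "CsparseMatrix"),
             domains = dom$labels, markers = markers)
    })
}

#' Simulate cell-type-labelled nuclei counts
#'
#' Cell types carry disjoint marker programs. Optionally a binary drug
#' condition shifts a planted gene program in selected cell types, and a
#' sex covariate drives a small planted program, for downstream factor
#' association and exclusion tests.
#'
#' @param nNuclei number of nuclei.
#' @param nCellTypes number of cell types.
#' @param nGenes number of genes.
#' @param markersPerType marker genes per cell type.
#' @param foldChange marker fold enrichment.
#' @param nbMean,nbDispersion negative binomial parameters.
#' @param drugEffect multiplicative shift applied to the drug program in
#'   \code{drugCellTypes} for condition \code{"drug"}; 1 disables it.
#' @param drugCellTypes integer cell types receiving the drug program.
#' @param sexEffect multiplicative shift of the sex program in male
#'   nuclei; 1 disables it.
#' @param programSize genes per planted drug/sex program.
#' @param seed integer seed.
#' @return List with \code{counts}, \code{cellType}, \code{sex},
#'   \code{condition} and \code{groundTruth} (marker and program genes).
#' @export
simulateNuclei <- function(nNuclei = 500L, nCellTypes = 4L, nGenes = 200L,
                           markersPerType = 10L, foldChange = 8,
                           nbMean = 2, nbDispersion = 5, drugEffect = 1,
                           drugCellTypes = 1L, sexEffect = 1,
                           programSize = 10L, seed = 1L) {
    genes <- sprintf("gene%04d", seq_len(nGenes))
    nMarker <- nCellTypes * markersPerType
    if (nGenes < nMarker + 2 * programSize)
        stop("nGenes too small for the requested marker and program sets")
    markers <- split(genes[seq_len(nMarker)],
                     rep(seq_len(nCellTypes), each = markersPerType))
    drugProgram <- genes[nMarker + seq_len(programSize)]
    sexProgram <- genes[nMarker + programSize + seq_len(programSize)]
    withSeed(seed, {
        cellType <- sample.int(nCellTypes, nNuclei, replace = TRUE)
        sex <- sample(c("F", "M"), nNuclei, replace = TRUE)
        condition <- sample(c("control", "drug"), nNuclei, replace = TRUE)
        mu <- matrix(nbMean, nrow = nGenes, ncol = nNuclei,
                     dimnames = list(genes,
                                     sprintf("nucleus%05d",
                                             seq_len(nNuclei))))
        for (ct in seq_len(nCellTypes))
            mu[markers[[ct]], cellType == ct] <- nbMean * foldChange
        hit <- condition == "drug" & cellType %in% drugCellTypes
        mu[drugProgram, hit] <- mu[drugProgram, hit] * drugEffect
        mu[sexProgram, sex == "M"] <- mu[sexProgram, sex == "M"] * sexEffect
        counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                        size = nbDispersion),
                         nrow = nGenes, dimnames = dimnames(mu))
        list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                  "CsparseMatrix"),
             cellType = sprintf("type%d", cellType), sex = sex,
             condition = condition,
             groundTruth = list(markers = markers,
                                drugProgram = drugProgram,
                                sexProgram = sexProgram))
    })
}

#' Simulate per-spot deconvolution weights
#'
#' Draws each spot's cell-type weight vector from a Dirichlet distribution
#' centered on its domain's configured mixture; rows sum to 1.
#'
#' @param domainLabels integer domain label per spot.
#' @param mixtures nDomains x nCellTypes matrix of mixture proportions
#'   (rows sum to 1); by default each domain is dominated by one cell type.
#' @param concentration Dirichlet concentration (larger = less noisy).
#' @param cellTypes character names for the weight columns.
#' @param seed integer seed.
#' @return spots x cell-types weight matrix with rows summing to 1.
#' @export
simulateDeconvWeights <- function(domainLabels, mixtures = NULL,
                                  concentration = 50,
                                  cellTypes = NULL, seed = 1L) {
    k <- max(domainLabels)
    if (is.null(mixtures)) {
        nct <- k
        mixtures <- matrix(0.5 / max(1, nct - 1), k, nct)
        diag(mixtures) <- ifelse(nct == 1, 1, 0.5)
        mixtures <- mixtures / rowSums(mixtures)
    }
    nct <- ncol(mixtures)
    if (is.null(cellTypes)) cellTypes <- sprintf("ct%d", seq_len(nct))
    withSeed(seed, {
        alpha <- mixtures[domainLabels, , drop = FALSE] * concentration
        draws <- matrix(stats::rgamma(length(alpha),
                                      shape = pmax(alpha, 1e-8)),
                        nrow = nrow(alpha))
        w <- draws / rowSums(draws)
        dimnames(w) <- list(NULL, cellTypes)
        w
    })
}
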