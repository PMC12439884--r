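test_that("spatial graph degrees follow the lattice geometry", {
    lat <- hexLattice(50, 50, 100)
    g <- buildSpatialGraph(cbind(lat$x, lat$y), 150)
    deg <- Matrix::rowSums(adjacencyMatrix(g))
    expect_equal(median(deg), 6)
    # below the pitch no edges form
    g0 <- buildSpatialGraph(cbind(lat$x[1:50], lat$y[1:50]), 50)
    expect_equal(graphS0(g0), 0)
    # three collinear points at unit spacing, unit threshold
    g3 <- buildSpatialGraph(cbind(0:2, 0), 1)
    expect_equal(Matrix::rowSums(adjacencyMatrix(g3)), c(1, 2, 1))
    expect_error(buildSpatialGraph(cbind(0:2, 0), 0), "threshold")
})

test_that("Moran's I matches closed forms and the double-sum oracle", {
    rook <- rookGrid(6, 6)
    g <- buildSpatialGraph(rook$coords, 1)
    # balanced checkerboard: every neighbor product is -1, so I = -1
    x <- (-1)^(rook$coords[, 1] + rook$coords[, 2])
    expect_equal(moransI(x, g), -1)
    # smooth gradient is positively autocorrelated
    expect_gt(moransI(rook$coords[, 1], g), 0)
    # brute-force equivalence on random 20-spot instances
    set.seed(5)
    for (rep in 1:5) {
        coords <- matrix(runif(40, 0, 10), ncol = 2)
        gg <- buildSpatialGraph(coords, 3)
        if (graphS0(gg) == 0) next
        xx <- rnorm(20)
        expect_equal(moransI(xx, gg),
                     oracleMoran(xx, as.matrix(adjacencyMatrix(gg))),
                     tolerance = 1e-12)
    }
    expect_error(moransI(rep(1, 36), g), "zero-variance")
})

test_that("permutation null of Moran's I is centered at -1/(n-1)", {
    rook <- rookGrid(6, 6)
    g <- buildSpatialGraph(rook$coords, 1)
    set.seed(9)
    x <- rnorm(36)
    res <- moransIPermutation(x, g, nPerm = 2000, seed = 3)
    mcse <- sd(res$perm) / sqrt(length(res$perm))
    expect_lt(abs(mean(res$perm) - (-1 / 35)), 3 * mcse)
    # a planted gradient is detected
    grad <- moransIPermutation(rook$coords[, 1] + rnorm(36, sd = 0.3),
                               g, nPerm = 199, seed = 2)
    expect_lt(grad$p.value, 0.05)
})

test_that("LISA significant fraction separates noise from islands", {
    lat <- hexLattice(12, 12, 100)
    g <- buildSpatialGraph(cbind(lat$x, lat$y), 150)
    set.seed(21)
    # 50 pure-noise genes: the overwhelming majority fail the 5% rule
    fails <- vapply(1:50, function(i)
        !lisaSignificantFraction(rnorm(144), g)$pass, logical(1))
    expect_gte(mean(fails), 0.9)
    # a strong island pattern passes, under both inference methods
    centre <- c(mean(lat$x), mean(lat$y))
    island <- as.numeric((lat$x - centre[1])^2 +
                         (lat$y - centre[2])^2 < 300^2)
    expr <- island * 3 + rnorm(144, sd = 0.3)
    res <- lisaSignificantFraction(expr, g)
    expect_true(res$pass)
    expect_gte(res$fraction, 0.05)
    resPerm <- lisaSignificantFraction(expr, g, method = "permutation",
                                       nPerm = 499, seed = 1)
    expect_true(resPerm$pass)
    # the analytic and permutation local statistics agree (same LISA)
    expect_equal(res$local, resPerm$local)
    # constant input: fraction 0 with warning
    expect_warning(z <- lisaSignificantFraction(rep(2, 144), g),
                   "zero-variance")
    expect_equal(z$fraction, 0)
})

test_that("spatial cross-correlation collapses to Moran's I and matches the oracle", {
    set.seed(3)
    coords <- matrix(runif(30, 0, 10), ncol = 2)
    g <- buildSpatialGraph(coords, 3.5)
    expr <- matrix(rnorm(5 * 15), 5, 15,
                   dimnames = list(paste0("g", 1:5), NULL))
    scc <- spatialCrossCorrelation(expr, g)
    # diagonal equals per-gene Moran's I
    for (i in 1:5)
        expect_equal(scc[i, i], moransI(expr[i, ], g), tolerance = 1e-12)
    # identical genes: off-diagonal equals the shared Moran's I
    expr2 <- rbind(a = expr[1, ], b = expr[1, ])
    scc2 <- spatialCrossCorrelation(expr2, g)
    expect_equal(scc2["a", "b"], moransI(expr[1, ], g), tolerance = 1e-12)
    # full matrix against the brute-force double sum
    expect_equal(unname(scc),
                 oracleSCC(expr, as.matrix(adjacencyMatrix(g))),
                 tolerance = 1e-12)
    expect_true(isSymmetric(scc))
    # zero-variance gene zeroes its row and column
    expr3 <- rbind(expr, flat = rep(1, 15))
    expect_warning(scc3 <- spatialCrossCorrelation(expr3, g),
                   "zero-variance")
    expect_equal(unname(scc3["flat", ]), rep(0, 6))
})

test_that("pattern grouping separates planted programs", {
    lat <- hexLattice(15, 15, 100)
    g <- buildSpatialGraph(cbind(lat$x, lat$y), 150)
    set.seed(12)
    left <- as.numeric(lat$x < median(lat$x))
    progA <- t(replicate(5, left * 2 + rnorm(225, sd = 0.3)))
    progB <- t(replicate(5, (1 - left) * 2 + rnorm(225, sd = 0.3)))
    expr <- rbind(progA, progB)
    rownames(expr) <- c(paste0("a", 1:5), paste0("b", 1:5))
    scc <- spatialCrossCorrelation(expr, g)
    part <- groupPatterns(scc, method = "ward", k = 2)
    expect_equal(length(unique(part[1:5])), 1)
    expect_equal(length(unique(part[6:10])), 1)
    expect_true(part[1] != part[10])
    # k = n gives singletons; permuting genes permutes labels only
    expect_equal(length(unique(groupPatterns(scc, k = 10))), 10)
    perm <- sample(10)
    partP <- groupPatterns(scc[perm, perm], method = "ward", k = 2)
    expect_equal(randIndex(part[rownames(scc)[perm]], partP), 1)
    expect_error(groupPatterns(scc, k = 11), "exceeds")
})

test_that("pattern scores average z-scored member genes", {
    expr <- rbind(g1 = c(1, 2, 3, 4), g2 = c(4, 3, 2, 1),
                  g3 = c(0, 0, 1, 3))
    part <- c(g1 = 1L, g2 = 1L, g3 = 2L)
    sc <- patternScores(expr, part)
    # anti-correlated pair cancels exactly
    expect_equal(unname(sc["pattern1", ]), rep(0, 4))
    # single-gene cluster is that gene's z-score
    expect_equal(unname(sc["pattern2", ]),
                 as.numeric(scale(expr["g3", ])))
    # per-pattern scores have mean 0 across spots
    expect_equal(rowMeans(sc), c(pattern1 = 0, pattern2 = 0))
})

test_that("donor-level run recovers planted island programs", {
    # generator defaults: two island programs plus background at 8-fold
    cfg <- simConfig(seed = 17, nCaptureAreas = 1L, gridRows = 30L,
                     gridCols = 30L, domainLayout = "island",
                     nDomains = 3L, nGenes = 40L, markersPerDomain = 8L,
                     markerFoldChange = 8)
    sim <- simulateCaptureAreas(cfg)
    dc <- simulateDomainCounts(sim$spots, cfg)
    norm <- logNormalizeCounts(dc$counts)
    res <- donorSpatialPatterns(as.matrix(norm),
                                cbind(sim$spots$gx, sim$spots$gy),
                                threshold = 150, k = 3, seed = 3)
    # no noise gene is retained as spatially patterned
    planted <- unlist(dc$markers)
    expect_length(setdiff(res$genes, planted), 0)
    # zero misassignments: each pattern's retained genes come from one
    # planted program, and the two island programs land in distinct
    # patterns at near-complete marker recovery
    assignmentOf <- function(genes)
        unique(vapply(dc$markers, function(m)
            any(genes %in% m), logical(1)))
    for (p in res$partition)
        expect_equal(sum(vapply(dc$markers, function(m)
            any(p %in% m), logical(1))), 1)
    for (m in dc$markers) {
        best <- which.max(vapply(res$partition, function(p)
            length(intersect(p, m)), integer(1)))
        expect_gte(length(intersect(res$partition[[best]], m)) /
                   length(m), 7 / 8)
    }
})
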