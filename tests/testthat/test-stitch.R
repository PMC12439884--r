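test_that("rotation estimation is exact on noiseless constructions", {
    set.seed(1)
    pa <- matrix(runif(16, 0, 500), ncol = 2)
    th <- 30 * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    pb <- t(t(R) %*% t(pa))  # B = A rotated by -30, so B -> A needs +30
    lm <- data.frame(xA = pa[, 1], yA = pa[, 2], xB = pb[, 1],
                     yB = pb[, 2])
    expect_equal(estimateRotation(lm), th, tolerance = 1e-12)
    lmId <- data.frame(xA = pa[, 1], yA = pa[, 2], xB = pa[, 1],
                       yB = pa[, 2])
    expect_equal(estimateRotation(lmId), 0)

    # degenerate segments are skipped; all-degenerate errors
    lmDup <- lm[c(1, 1, 2), ]
    expect_warning(th2 <- estimateRotation(lmDup), "zero-length")
    expect_equal(th2, th, tolerance = 1e-12)
    expect_error(suppressWarnings(estimateRotation(lm[c(1, 1), ])),
                 "degenerate")
})

test_that("translation estimation recovers planted offsets", {
    pa <- matrix(runif(12, 0, 100), ncol = 2)
    lm <- data.frame(xA = pa[, 1] + 5, yA = pa[, 2] - 2, xB = pa[, 1],
                     yB = pa[, 2])
    expect_equal(estimateTranslation(lm, 0), c(5, -2))
    lm0 <- data.frame(xA = pa[, 1], yA = pa[, 2], xB = pa[, 1],
                      yB = pa[, 2])
    expect_equal(estimateTranslation(lm0, 0), c(0, 0))
    expect_error(estimateTranslation(lm0[0, ], 0), "no landmark")

    # rotate-then-translate construction recovered to 1e-9
    tr <- RigidTransform2D(theta = 0.3, translation = c(12, -7),
                           center = colMeans(pa))
    pA <- applyTransform(tr, pa)
    lm2 <- data.frame(xA = pA[, 1], yA = pA[, 2], xB = pa[, 1],
                      yB = pa[, 2])
    est <- estimateRigidTransform(lm2)
    expect_equal(applyTransform(est, pa), pA, tolerance = 1e-9)
})

test_that("noisy estimates agree with the least-squares rigid oracle", {
    set.seed(42)
    worstTheta <- 0; worstShift <- 0
    for (rep in 1:25) {
        pa <- matrix(runif(16, 0, 800), ncol = 2)
        th <- runif(1, -0.5, 0.5)
        tr <- RigidTransform2D(th, runif(2, -50, 50), colMeans(pa))
        pA <- applyTransform(tr, pa) + matrix(rnorm(16, sd = 2), ncol = 2)
        lm <- data.frame(xA = pA[, 1], yA = pA[, 2], xB = pa[, 1],
                         yB = pa[, 2])
        est <- estimateRigidTransform(lm)
        orc <- oracleRigidFit(pA, pa)
        worstTheta <- max(worstTheta, abs(est@theta - orc$theta))
        # compare the full maps on the landmark cloud
        mapped <- applyTransform(est, pa)
        oracleMapped <- t(orc$R %*% t(pa) + orc$translation)
        worstShift <- max(worstShift,
                          max(abs(colMeans(mapped - oracleMapped))))
    }
    expect_lt(worstTheta, 1 * pi / 180)
    expect_lt(worstShift, 3)
})

test_that("transform algebra inverts and composes to identity", {
    tr <- RigidTransform2D(0.7, c(30, -12), c(100, 50))
    pts <- matrix(runif(20, -200, 200), ncol = 2)
    expect_equal(applyTransform(invertTransform(tr),
                                applyTransform(tr, pts)), pts,
                 tolerance = 1e-9)
    aff <- composeAffine(asAffine(invertTransform(tr)), asAffine(tr))
    expect_equal(aff, cbind(diag(2), c(0, 0)), tolerance = 1e-9)
})

test_that("alignment refinement recovers chained transforms", {
    # three areas in a chain; noiseless
    cfg <- simConfig(seed = 4, nCaptureAreas = 3L, gridRows = 10L,
                     gridCols = 12L, overlapFraction = 0.35)
    sim <- simulateCaptureAreas(cfg)
    ref <- refineAlignment(unique(sim$spots$capture_area), sim$landmarks)
    expect_true(all(ref$residuals < 1e-6))
    st <- stitchSpots(sim$spots, ref$transforms)
    # area1's truth is identity, so the reference frame is the global one
    expect_equal(st$gx, sim$spots$gx, tolerance = 1e-6)
    expect_equal(st$gy, sim$spots$gy, tolerance = 1e-6)
    # composed transform for area 3 equals the product of pairwise truths
    tt <- sim$groundTruth$trueTransforms
    expect_equal(ref$transforms$area3, asAffine(tt[[3]]),
                 tolerance = 1e-6)

    # noisy landmarks: refinement never degrades the coarse alignment
    cfgN <- simConfig(seed = 8, nCaptureAreas = 2L, gridRows = 10L,
                      gridCols = 12L, overlapFraction = 0.35,
                      landmarkNoiseSd = 2)
    simN <- simulateCaptureAreas(cfgN)
    refN <- refineAlignment(unique(simN$spots$capture_area),
                            simN$landmarks)
    expect_true(all(refN$residuals <= refN$coarseResiduals))

    # disconnected overlap graph is reported
    expect_error(refineAlignment(c("area1", "area2", "area9"),
                                 sim$landmarks["area1|area2"]), "area9")
})

test_that("artificial grid covers spots at exactly the requested pitch", {
    set.seed(2)
    spots <- data.frame(gx = runif(40, 0, 1000), gy = runif(40, 0, 400))
    grid <- buildArtificialGrid(spots, 100)
    centers <- gridCenters(grid)
    expect_gte(length(unique(centers$array_col)), 11)
    d <- as.matrix(dist(cbind(centers$x, centers$y)))
    diag(d) <- Inf
    expect_equal(min(d), 100, tolerance = 1e-6)
    # origin anchored at the minimum pixel coordinates
    expect_equal(min(centers$x), min(spots$gx))
    expect_equal(min(centers$y), min(spots$gy))
    # degenerate single spot still yields a covering lattice point
    g1 <- buildArtificialGrid(cbind(5, 5), 100)
    expect_gte(nrow(gridCenters(g1)), 1)
    expect_error(buildArtificialGrid(spots, 0), "pitch")
})

test_that("grid assignment picks nearest with deterministic ties", {
    grid <- buildArtificialGrid(cbind(c(0, 1000), c(0, 500)), 100)
    near <- assignToGrid(data.frame(gx = 60, gy = 0), grid)
    expect_equal(near$array_col, 2)  # x = 100 beats x = 0
    tie <- assignToGrid(data.frame(gx = 50, gy = 0), grid)
    expect_equal(tie$array_col, 0)   # exact midpoint: smaller (row, col)
    # lattice-centered spots are fixed points with distance 0
    centers <- gridCenters(grid)[1:10, ]
    assigned <- assignToGrid(data.frame(gx = centers$x, gy = centers$y),
                             grid)
    expect_equal(assigned$array_row, centers$array_row)
    expect_equal(assigned$array_col, centers$array_col)
    expect_equal(assigned$grid_distance, rep(0, 10))
    again <- assignToGrid(assigned, grid)
    expect_equal(again$array_row, assigned$array_row)
    expect_equal(again$array_col, assigned$array_col)
})

test_that("overlap detection thresholds at 1.5x native spacing", {
    lat <- hexLattice(8, 8, 100)
    # pair at 120 px is overlapping, 160 px is not
    two <- rbind(
        data.frame(barcode = lat$barcode, capture_area = "area1",
                   gx = lat$x, gy = lat$y),
        data.frame(barcode = "far-1", capture_area = "area2",
                   gx = min(lat$x) - 120, gy = lat$y[1]),
        data.frame(barcode = "far-2", capture_area = "area2",
                   gx = max(lat$x) + 160, gy = lat$y[1]))
    ov <- detectOverlaps(two)
    expect_equal(ov$threshold, 150)
    expect_true("far-1" %in% ov$pairs$spot_b)
    expect_false("far-2" %in% ov$pairs$spot_b)

    # identical grids offset by 10 px: a clean bijection of overlap pairs
    dup <- rbind(
        data.frame(barcode = lat$barcode, capture_area = "area1",
                   gx = lat$x, gy = lat$y),
        data.frame(barcode = paste0("B", lat$barcode),
                   capture_area = "area2", gx = lat$x + 10, gy = lat$y))
    ovd <- detectOverlaps(dup)
    expect_equal(nrow(ovd$pairs), nrow(lat))
    expect_equal(sort(ovd$pairs$spot_a), sort(lat$barcode))
    expect_equal(anyDuplicated(ovd$pairs$spot_b), 0)
    # oracle: each spot's nearest cross-grid spot is its own copy
    expect_equal(ovd$pairs$spot_b[match(lat$barcode, ovd$pairs$spot_a)],
                 paste0("B", lat$barcode))

    # invariant to global rigid motion
    rot <- RigidTransform2D(0.4, c(500, -200))
    moved <- dup
    g <- applyTransform(rot, cbind(dup$gx, dup$gy))
    moved$gx <- g[, 1]; moved$gy <- g[, 2]
    ovm <- detectOverlaps(moved)
    expect_equal(nrow(ovm$pairs), nrow(ovd$pairs))
    expect_equal(sort(paste(ovm$pairs$spot_a, ovm$pairs$spot_b)),
                 sort(paste(ovd$pairs$spot_a, ovd$pairs$spot_b)))

    # single area: empty assignment, not an error
    single <- detectOverlaps(two[two$capture_area == "area1", ])
    expect_equal(nrow(single$pairs), 0)
})

test_that("overlap resolution flags the lower-depth side", {
    pairs <- data.frame(spot_a = c("x1", "x2"), spot_b = c("y1", "y2"),
                        area_a = "area1", area_b = "area2",
                        distance = c(10, 12))
    assignment <- list(pairs = pairs, areas = c("area1", "area2"))
    umi <- c(x1 = 500, x2 = 800, y1 = 600, y2 = 700)
    flags <- resolveOverlaps(assignment, umi)
    expect_true(all(flags$exclude_overlapping[flags$barcode %in%
                                              c("x1", "x2")]))
    expect_false(any(flags$exclude_overlapping[flags$barcode %in%
                                               c("y1", "y2")]))
    # equal minima flag the later-listed area
    umiTie <- c(x1 = 500, x2 = 800, y1 = 500, y2 = 700)
    flagsTie <- resolveOverlaps(assignment, umiTie)
    expect_true(all(flagsTie$exclude_overlapping[flagsTie$barcode %in%
                                                 c("y1", "y2")]))
    # no overlaps, no flags
    none <- resolveOverlaps(list(pairs = pairs[0, ]), umi)
    expect_equal(nrow(none), 0)
})

test_that("edge distance is the gap to the native array rectangle", {
    pos <- data.frame(array_row = c(0, 5, 39), array_col = c(5, 64, 64))
    expect_equal(edgeDistance(pos), c(0, 5, 38))
    expect_error(edgeDistance(data.frame(array_row = NA,
                                         array_col = 1)), "missing")
})
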