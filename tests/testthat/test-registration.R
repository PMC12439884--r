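test_that("pseudobulk aggregation sums by (group, unit) with filters", {
    counts <- Matrix::Matrix(matrix(1:24, nrow = 3,
                                    dimnames = list(paste0("g", 1:3),
                                                    NULL)),
                             sparse = TRUE)
    groups <- rep(c("c1", "c2"), each = 4)
    units <- rep(c("u1", "u2"), times = 4)
    pb <- pseudobulkAggregate(counts, groups, units, minObs = 1)
    expect_equal(ncol(pb$counts), 4)
    # hand-checked sums for (c1, u1): observations 1 and 3
    expect_equal(unname(pb$counts[, pb$group == "c1" & pb$unit == "u1"]),
                 unname(Matrix::rowSums(counts[, c(1, 3)])))
    expect_equal(unname(pb$counts[, pb$group == "c2" & pb$unit == "u2"]),
                 unname(Matrix::rowSums(counts[, c(6, 8)])))
    # samples under the minimum observation count are dropped
    pb2 <- pseudobulkAggregate(counts, groups, units, minObs = 3)
    expect_equal(ncol(pb2$counts), 0)
    # all observations in one cell: a single column of row sums
    pb3 <- pseudobulkAggregate(counts, rep("c", 8), rep("u", 8),
                               minObs = 1)
    expect_equal(unname(pb3$counts[, 1]),
                 unname(Matrix::rowSums(counts)))
})

test_that("one-vs-all t matches the printed formula exactly", {
    # closed form: means 2 vs 0, variances 1, n_c = 4 gives t = 4
    grpA <- c(0.775, 1.925, 2.075, 3.225)   # mean 2
    grpB <- grpA - 2                        # mean 0, same variance
    scale <- sqrt(1 / var(grpA))
    grpA <- (grpA - 2) * scale + 2          # variance exactly 1
    grpB <- grpB * scale
    expr <- rbind(g = c(grpA, grpB))
    de <- oneVsAllT(expr, rep(c("a", "b"), each = 4))
    expect_equal(unname(de$t["g", "a"]), 2 / sqrt(2 / 8))
    expect_equal(unname(de$t["g", "b"]), -4)
    expect_equal(unname(de$logFC["g", "a"]), 2)

    # equal means (with spread) give t = 0
    expr0 <- rbind(g = c(1, 2, 1, 2, 2, 1, 2, 1))
    de0 <- oneVsAllT(expr0, rep(c("a", "b"), each = 4))
    expect_equal(unname(de0$t["g", "a"]), 0)

    # random instance against a direct formula oracle, both variants
    set.seed(6)
    exprR <- matrix(rnorm(20 * 12), 20, 12,
                    dimnames = list(paste0("g", 1:20), NULL))
    grp <- rep(c("a", "b", "c"), each = 4)
    deR <- oneVsAllT(exprR, grp)
    deW <- oneVsAllT(exprR, grp, welch = TRUE)
    for (g in 1:20) for (cc in c("a", "b", "c")) {
        x1 <- exprR[g, grp == cc]; x2 <- exprR[g, grp != cc]
        want <- (mean(x1) - mean(x2)) /
            sqrt((var(x1) + var(x2)) / (2 * length(x1)))
        expect_equal(unname(deR$t[g, cc]), want, tolerance = 1e-12)
        wantW <- (mean(x1) - mean(x2)) /
            sqrt(var(x1) / length(x1) + var(x2) / length(x2))
        expect_equal(unname(deW$t[g, cc]), wantW, tolerance = 1e-12)
    }
    # sign always matches the mean difference
    expect_true(all(sign(deR$t) == sign(deR$logFC)))
    # BH keeps FDR >= p elementwise
    expect_true(all(deR$fdr >= deR$p - 1e-15))
})

test_that("marker selection filters, ranks and truncates as stated", {
    de <- list(
        t = matrix(1, 5, 1, dimnames = list(paste0("g", 1:5), "c1")),
        logFC = matrix(c(2, 3, -1, 1, 0.5), 5, 1,
                       dimnames = list(paste0("g", 1:5), "c1")),
        p = matrix(0.01, 5, 1),
        fdr = matrix(c(0.01, 0.2, 0.01, 0.04, 0.01), 5, 1,
                     dimnames = list(paste0("g", 1:5), "c1")))
    sel <- selectMarkers(de, topN = 250)
    expect_equal(sel$perGroup$c1, c("g1", "g4", "g5"))
    expect_equal(selectMarkers(de, topN = 1)$perGroup$c1, "g1")
    deNone <- de
    deNone$fdr[] <- 0.9
    expect_warning(selNone <- selectMarkers(deNone), "no marker")
    expect_length(selNone$perGroup$c1, 0)
})

test_that("ortholog mapping drops unmatched genes and reports counts", {
    hom <- data.frame(source_symbol = c("A", "C", "D"),
                      target_symbol = c("a", "c", "d"))
    res <- mapOrthologs(c("A", "B", "C", "E", "D"), hom)
    expect_equal(res$mapped, c("a", "c", "d"))
    expect_equal(res$nMapped, 3)
    expect_equal(res$nDropped, 2)
})

test_that("registration correlation puts matched groups on the diagonal", {
    set.seed(9)
    tref <- matrix(rnorm(200 * 4), 200, 4,
                   dimnames = list(paste0("g", 1:200),
                                   paste0("c", 1:4)))
    expect_equal(unname(diag(registrationCorrelation(tref, tref))),
                 rep(1, 4))
    expect_equal(unname(diag(registrationCorrelation(-tref, tref))),
                 rep(-1, 4))
    expect_error(registrationCorrelation(tref[1:2, ], tref[1:2, ]),
                 "fewer than 3")

    # split-half synthetic registration: simulate nuclei, split, compute
    # one-vs-all t on each half; row-wise arg-max recovers the identity
    nuc <- simulateNuclei(nNuclei = 800, nCellTypes = 4, foldChange = 4,
                          seed = 12)
    norm <- as.matrix(logNormalizeCounts(nuc$counts))
    half <- seq_len(ncol(norm)) %% 2 == 0
    tA <- oneVsAllT(norm[, half], nuc$cellType[half])$t
    tB <- oneVsAllT(norm[, !half], nuc$cellType[!half])$t
    cors <- registrationCorrelation(tA, tB,
                                    universe = topMarkerUniverse(tB, 100))
    expect_equal(colnames(cors)[apply(cors, 1, which.max)],
                 rownames(cors))
})

test_that("Fisher over-representation equals hypergeometric enumeration", {
    # worked table [[3,1],[1,3]]: one-sided p = 17/70
    universe <- paste0("g", 1:8)
    degs <- list(grp = paste0("g", 1:4))
    lst <- paste0("g", c(1, 2, 3, 5))
    res <- overRepresentation(lst, degs, universe, minList = 1)
    expect_equal(res$p, 17 / 70)
    expect_equal(res$odds_ratio, 9)

    # universe 100, DEG 20, list 30, overlap 10: OR = ad/bc = 3
    uni <- paste0("g", 1:100)
    deg <- paste0("g", 1:20)
    lst2 <- paste0("g", c(1:10, 21:40))
    res2 <- overRepresentation(lst2, list(grp = deg), uni, minList = 25)
    expect_equal(res2$odds_ratio, (10 * 60) / (20 * 10))
    expect_equal(res2$p, oracleFisherP(10, 10, 20, 60), tolerance = 1e-12)

    # random small tables (N <= 30) against exhaustive enumeration
    set.seed(11)
    for (rep in 1:20) {
        N <- sample(8:30, 1)
        uniR <- paste0("g", seq_len(N))
        degR <- sample(uniR, sample(2:(N - 2), 1))
        lstR <- sample(uniR, sample(2:(N - 2), 1))
        resR <- overRepresentation(lstR, list(x = degR), uniR,
                                   minList = 1)
        a <- length(intersect(lstR, degR))
        b <- length(setdiff(degR, lstR))
        c <- length(setdiff(lstR, degR))
        d <- N - a - b - c
        expect_equal(resR$p, oracleFisherP(a, b, c, d),
                     tolerance = 1e-12)
    }

    # disjoint list is depleted, not enriched
    res3 <- overRepresentation(paste0("g", 90:99),
                               list(grp = paste0("g", 1:20)),
                               uni, minList = 1)
    expect_lte(res3$odds_ratio, 1)
    expect_gte(res3$p, 0.5)
    # short lists are skipped with a warning
    expect_warning(
        short <- overRepresentation(paste0("g", 1:3),
                                    list(grp = deg), uni),
        "skipped")
    expect_equal(nrow(short), 0)
})

test_that("BH adjustment is the step-up transform", {
    expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
                 rep(0.04, 4))
    set.seed(2)
    p <- runif(25)
    expect_equal(p.adjust(p, "BH"), oracleBH(p), tolerance = 1e-12)
})

test_that("heritability gene sets select top relative expression with flanks", {
    pb <- matrix(c(10, 1, 1, 1, 1, 1, 1, 1, 1, 1,
                   1, 1, 1, 1, 1, 1, 1, 1, 1, 20), ncol = 2,
                 dimnames = list(paste0("g", 1:10), c("c1", "c2")))
    coords <- data.frame(gene = paste0("g", 1:10),
                         chrom = c(rep("chr1", 8), "chrX", "chr2"),
                         start = c(1000000L, 50000L, seq(2e6, 8e6, 1e6),
                                   100000L),
                         end = c(1005000L, 60000L, seq(2e6, 8e6, 1e6) +
                                 10000L, 200000L))
    # 10 genes at top 10%: exactly the single highest gene per group
    sets <- heritabilityGenesets(pb, 0.10, coords)
    expect_equal(sets$c1$name, "g1")
    expect_equal(sets$c1$start, 900000)
    expect_equal(sets$c1$end, 1105000)
    expect_equal(sets$c2$name, "g10")
    # start clipped at zero
    pb2 <- pb; pb2["g2", "c1"] <- 100
    sets2 <- heritabilityGenesets(pb2, 0.10, coords)
    expect_equal(sets2$c1$start, 0)
    # excluded chromosome drops the gene
    pb3 <- pb; pb3["g9", "c1"] <- 100
    sets3 <- heritabilityGenesets(pb3, 0.10, coords)
    expect_equal(nrow(sets3$c1), 0)
    # ceiling rule: 15% of 10 genes keeps 2
    expect_equal(nrow(heritabilityGenesets(pb, 0.15, coords)$c2), 2)
    # output is BED-writable
    path <- withr::local_tempfile()
    writeBed(sets$c1, path)
    expect_equal(readBed(path)$name, "g1")
})
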