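# Shared synthetic fixtures, built in code at test time.

# two-area section with a planted relative transform
twoAreaSection <- function(seed = 2, theta = 10 * pi / 180,
                           translation = c(400, 30), noise = 0,
                           nLandmarks = 8L, gridRows = 10L,
                           gridCols = 10L) {
    simulateCaptureAreas(simConfig(
        seed = seed, nCaptureAreas = 2L, gridRows = gridRows,
        gridCols = gridCols, landmarkNoiseSd = noise,
        nLandmarks = nLandmarks,
        trueTransforms = list(RigidTransform2D(0, c(0, 0)),
                              RigidTransform2D(theta, translation))))
}

# multi-donor study with planted shared spatial programs: each donor gets
# an island-structured section where program p's genes (a 70%-shared core
# plus donor-specific extras) are enriched in island p
consensusStudy <- function(nDonors = 5L, nPrograms = 4L, coreFrac = 0.7,
                           genesPerProgram = 10L, nNoise = 15L,
                           gridSize = 26L, fold = 8, seed = 11L) {
    lat <- hexLattice(gridSize, gridSize, 100)
    coords <- cbind(lat$x, lat$y)
    # island centers staggered so ~4-pitch islands stay disjoint
    cx <- quantile(lat$x, probs = seq(0.15, 0.85,
                                      length.out = nPrograms))
    cy <- quantile(lat$y, probs = rep(c(0.3, 0.7),
                                      length.out = nPrograms))
    radius <- 420
    domains <- rep(1L, nrow(lat))
    for (p in seq_len(nPrograms)) {
        inside <- (lat$x - cx[p])^2 + (lat$y - cy[p])^2 <= radius^2
        domains[inside] <- p + 1L
    }
    nCore <- round(coreFrac * genesPerProgram)
    nOwn <- genesPerProgram - nCore
    donors <- vector("list", nDonors)
    for (d in seq_len(nDonors)) {
        geneSets <- lapply(seq_len(nPrograms), function(p)
            c(sprintf("core_p%d_g%02d", p, seq_len(nCore)),
              sprintf("own_d%d_p%d_g%02d", d, p, seq_len(nOwn))))
        # a flat housekeeping block keeps library sizes comparable
        # between island and background spots, as in real tissue where
        # spatial programs are a small share of each library
        genes <- c(unlist(geneSets),
                   sprintf("noise_d%d_g%02d", d, seq_len(nNoise)),
                   sprintf("hk_g%02d", seq_len(30)))
        mu <- matrix(2, length(genes), nrow(lat),
                     dimnames = list(genes, lat$barcode))
        mu[startsWith(genes, "hk_"), ] <- 10
        for (p in seq_len(nPrograms))
            mu[geneSets[[p]], domains == p + 1L] <- 2 * fold
        set.seed(seed + d)
        counts <- matrix(rnbinom(length(mu), mu = mu, size = 5),
                         nrow = nrow(mu), dimnames = dimnames(mu))
        donors[[d]] <- list(counts = counts, geneSets = geneSets,
                            genes = genes)
    }
    list(donors = donors, coords = coords, domains = domains,
         nPrograms = nPrograms)
}

# run patterns -> consensus over a consensusStudy and compare the k-cut
# against the planted program grouping
runConsensusRecovery <- function(study, nPerm = 49L, seed = 5L) {
    geneSets <- list(); donorsOf <- character(); profiles <- list()
    truth <- integer()
    for (d in seq_along(study$donors)) {
        don <- study$donors[[d]]
        norm <- logNormalizeCounts(Matrix::Matrix(don$counts,
                                                  sparse = TRUE))
        pat <- donorSpatialPatterns(as.matrix(norm), study$coords,
                                    threshold = 150,
                                    k = study$nPrograms, nPerm = nPerm,
                                    seed = seed + d)
        for (p in seq_along(pat$partition)) {
            id <- sprintf("donor%d.p%d", d, p)
            genes <- pat$partition[[p]]
            geneSets[[id]] <- genes
            donorsOf[id] <- sprintf("donor%d", d)
            sc <- pat$scores[p, ]
            profiles[[id]] <- vapply(sort(unique(study$domains)),
                function(dm) mean(sc[study$domains == dm]), numeric(1))
            # planted program = the one contributing most genes
            hits <- vapply(don$geneSets, function(gs)
                length(intersect(gs, genes)), integer(1))
            truth[id] <- which.max(hits)
        }
    }
    cp <- consensusPatterns(geneSets, do.call(rbind, profiles), donorsOf,
                            k = study$nPrograms)
    labels <- consensusMembership(cp)$mcp
    list(consensus = cp, rand = randIndex(labels, truth), truth = truth)
}
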