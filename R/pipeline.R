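# End-to-end orchestration over the synthetic study: each stage is a pure
# function of (config, upstream artifacts), writes versioned outputs plus
# a JSON provenance record, and can be invoked independently with files
# as the only interface.

#' Default pipeline configuration
#'
#' Stage parameter blocks mirroring the analysis thresholds: spot QC
#' (umi_min 250, edge_max 6), nucleus QC (mito_max 0.05, doublet_max 5,
#' MAD multipliers 3/1), neighbor threshold 1.5 x pitch, marker/rank
#' cutoffs (top 2000 aggregated genes, 250 markers, 100 registration
#' markers, 20 correlated genes), NMF (l1 0.1, tol 1e-6), factor
#' selection (prevalence 0.2, scaled mean 0.2, sex |r| 0.3, 200 spots),
#' drug response (effect 0.3, FDR 0.05), LR prioritization (evidence 0.1,
#' rank 0.01, epsilon 1e-6), heritability top fractions (0.10 cell types,
#' 0.15 domains, 100 kb flank) and the consensus tree cut (k 6).
#'
#' @param seed global seed; per-stage seeds derive from it by stable
#'   hashing of the stage name.
#' @param sim a \code{\link{simConfig}} describing the synthetic section.
#' @return Nested configuration list.
#' @export
pipelineConfig <- function(seed = 1L, sim = simConfig(seed = seed)) {
    list(seed = as.integer(seed), sim = sim,
         qc = list(umi_min = 250, edge_max = 6, mito_max = 0.05,
                   doublet_max = 5, mads = c(neun = 3, pi = 1)),
         patterns = list(threshold_pitch_factor = 1.5, k = 2L,
                         n_perm = 99L, min_fraction = 0.05),
         consensus = list(k_cut = 6L, n_donors = 3L),
         registration = list(top_n = 250L, top_registration = 100L,
                             fdr_max = 0.05),
         factors = list(k = 3L, l1_w = 0.1, tol = 1e-6, maxit = 500L,
                        prevalence_min = 0.2, scaled_mean_min = 0.2,
                        sex_r_max = 0.3, min_spots = 200L,
                        effect_min = 0.3, fdr_max = 0.05),
         lr = list(evidence_min = 0.1, rank_max = 0.01, epsilon = 1e-6),
         heritability = list(top_fraction_celltype = 0.10,
                             top_fraction_domain = 0.15, flank = 1e5))
}

stageSeed <- function(seed, stage) {
    codes <- utf8ToInt(stage)
    h <- 0
    for (c in codes) h <- (h * 31 + c) %% 1000003L
    as.integer((seed + h) %% .Machine$integer.max)
}

hashObject <- function(x) {
    f <- tempfile()
    on.exit(unlink(f))
    saveRDS(x, f, compress = FALSE)
    unname(tools::md5sum(f))
}

writeProvenance <- function(dir, stage, config, inputs = character()) {
    rec <- list(stage = stage, config_hash = hashObject(config),
                seed = stageSeed(config$seed, stage),
                input_hashes = as.list(tools::md5sum(inputs)))
    jsonlite::write_json(rec, file.path(dir, paste0(stage,
                                                    "_provenance.json")),
                         auto_unbox = TRUE, pretty = TRUE)
}

#' Run the synthetic analysis pipeline
#'
#' Executes the requested stages in order, writing each stage's artifacts
#' and a provenance record (config hash, stage seed, input hashes) under
#' \code{outDir}. Stages: \code{simulate} (capture areas, counts,
#' deconvolution weights), \code{stitch} (alignment refinement,
#' artificial grid, overlaps), \code{qc} (spot/gene filters,
#' normalization), \code{patterns} (per-donor spatial patterns),
#' \code{consensus} (multi-donor consensus groups), \code{factors} (NMF
#' on nuclei, projection to spots), \code{lrmap} (LR classification and
#' co-occurrence), \code{select} (BIC / Rand / concordance report).
#' Reruns with identical config and inputs reproduce identical artifacts.
#'
#' @param config from \code{\link{pipelineConfig}}.
#' @param stages character vector of stage names, topologically ordered.
#' @param outDir artifact directory (created if needed).
#' @return Invisibly, a named list of per-stage result summaries.
#' @export
runPipeline <- function(config = pipelineConfig(),
                        stages = c("simulate", "stitch", "qc", "patterns",
                                   "consensus", "factors", "lrmap",
                                   "select"),
                        outDir = tempfile("pipeline")) {
    known <- c("simulate", "stitch", "qc", "patterns", "consensus",
               "factors", "lrmap", "select")
    bad <- setdiff(stages, known)
    if (length(bad))
        stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    state <- new.env()
    results <- list()
    for (stage in stages) {
        fn <- switch(stage, simulate = stageSimulate,
                     stitch = stageStitch, qc = stageQC,
                     patterns = stagePatterns, consensus = stageConsensus,
                     factors = stageFactors, lrmap = stageLR,
                     select = stageSelect)
        results[[stage]] <- fn(config, state, outDir)
        writeProvenance(outDir, stage, config)
    }
    invisible(results)
}

requireStage <- function(state, what, stage, neededBy) {
    if (!exists(what, envir = state))
        stop(sprintf("stage '%s' requires artifacts from stage '%s'",
                     neededBy, stage))
    get(what, envir = state)
}

stageSimulate <- function(config, state, outDir) {
    sim <- simulateCaptureAreas(config$sim)
    counts <- simulateDomainCounts(sim$spots, config$sim,
                                   seed = stageSeed(config$seed,
                                                    "simulate"))
    weights <- simulateDeconvWeights(counts$domains,
                                     seed = stageSeed(config$seed,
                                                      "simulate"))
    assign("sim", sim, envir = state)
    assign("counts", counts, envir = state)
    assign("weights", weights, envir = state)
    pos <- data.frame(barcode = sim$spots$barcode, in_tissue = 1L,
                      array_row = sim$spots$array_row,
                      array_col = sim$spots$array_col,
                      pxl_row_in_fullres = sim$spots$gy,
                      pxl_col_in_fullres = sim$spots$gx)
    writeSpotPositions(pos, file.path(outDir, "positions.csv"))
    writeCountsTriplet(counts$counts, file.path(outDir, "counts.mtx"),
                       file.path(outDir, "genes.tsv"),
                       file.path(outDir, "barcodes.tsv"))
    jsonlite::write_json(
        list(domains = counts$domains,
             markers = counts$markers,
             true_theta = vapply(sim$groundTruth$trueTransforms,
                                 function(t) t@theta, numeric(1))),
        file.path(outDir, "ground_truth.json"), auto_unbox = TRUE)
    list(nSpots = nrow(sim$spots), nGenes = nrow(counts$counts))
}

stageStitch <- function(config, state, outDir) {
    sim <- requireStage(state, "sim", "simulate", "stitch")
    areas <- unique(sim$spots$capture_area)
    refined <- refineAlignment(areas, sim$landmarks)
    stitched <- stitchSpots(sim$spots, refined$transforms)
    first <- stitched[stitched$capture_area == areas[1], ]
    d <- as.matrix(stats::dist(cbind(first$gx, first$gy)))
    diag(d) <- Inf
    pitchPx <- stats::median(apply(d, 1, min))
    grid <- buildArtificialGrid(stitched, pitchPx)
    stitched <- assignToGrid(stitched, grid)
    overlaps <- detectOverlaps(stitched)
    counts <- requireStage(state, "counts", "simulate", "stitch")
    umi <- stats::setNames(Matrix::colSums(counts$counts),
                           colnames(counts$counts))
    flags <- resolveOverlaps(overlaps, umi)
    stitched$exclude_overlapping <-
        stitched$barcode %in% flags$barcode[flags$exclude_overlapping]
    assign("stitched", stitched, envir = state)
    assign("overlaps", overlaps, envir = state)
    out <- data.frame(barcode = stitched$barcode, in_tissue = 1L,
                      array_row = stitched$array_row,
                      array_col = stitched$array_col,
                      pxl_row_in_fullres = stitched$gy,
                      pxl_col_in_fullres = stitched$gx)
    writeSpotPositions(out, file.path(outDir, "stitched_positions.csv"))
    jsonlite::write_json(
        list(residuals = as.list(refined$residuals),
             coarse_residuals = as.list(refined$coarseResiduals),
             overlap_threshold = overlaps$threshold,
             n_overlap_pairs = nrow(overlaps$pairs),
             n_excluded = sum(stitched$exclude_overlapping)),
        file.path(outDir, "stitch_report.json"), auto_unbox = TRUE)
    list(residuals = refined$residuals, nOverlaps = nrow(overlaps$pairs))
}

stageQC <- function(config, state, outDir) {
    stitched <- requireStage(state, "stitched", "stitch", "qc")
    counts <- requireStage(state, "counts", "simulate", "qc")
    umi <- Matrix::colSums(counts$counts)
    edge <- edgeDistance(data.frame(
        array_row = stitched$array_row_original %||% stitched$array_row,
        array_col = stitched$array_col_original %||% stitched$array_col))
    keepSpot <- spotQCFilter(umi, edge, config$qc$umi_min,
                             config$qc$edge_max) &
        !stitched$exclude_overlapping
    keepGene <- geneFilters(counts$counts, mode = "min_count_prop")
    norm <- logNormalizeCounts(counts$counts[keepGene, keepSpot,
                                             drop = FALSE])
    assign("qc", list(keepSpot = keepSpot, keepGene = keepGene,
                      norm = norm), envir = state)
    utils::write.csv(data.frame(barcode = stitched$barcode,
                                sum_umi = umi, edge_distance = edge,
                                keep = keepSpot),
                     file.path(outDir, "spot_qc.csv"), row.names = FALSE)
    list(nKeptSpots = sum(keepSpot), nKeptGenes = sum(keepGene))
}

stagePatterns <- function(config, state, outDir) {
    stitched <- requireStage(state, "stitched", "stitch", "patterns")
    qc <- requireStage(state, "qc", "qc", "patterns")
    coords <- cbind(stitched$gx, stitched$gy)[qc$keepSpot, , drop = FALSE]
    pat <- donorSpatialPatterns(
        as.matrix(qc$norm), coords,
        threshold = config$sim$pitch *
            config$patterns$threshold_pitch_factor,
        k = config$patterns$k, nPerm = config$patterns$n_perm,
        minFraction = config$patterns$min_fraction,
        seed = stageSeed(config$seed, "patterns"))
    assign("patterns", pat, envir = state)
    utils::write.csv(
        data.frame(gene = unlist(pat$partition),
                   pattern = rep(names(pat$partition),
                                 lengths(pat$partition))),
        file.path(outDir, "pattern_genes.csv"), row.names = FALSE)
    utils::write.csv(t(pat$scores), file.path(outDir,
                                              "pattern_scores.csv"))
    list(nPatternGenes = length(pat$genes),
         nPatterns = length(pat$partition))
}

stageConsensus <- function(config, state, outDir) {
    # multi-donor consensus on freshly simulated donors sharing programs
    seed <- stageSeed(config$seed, "consensus")
    nd <- config$consensus$n_donors
    geneSets <- list(); donors <- character(); profiles <- list()
    for (d in seq_len(nd)) {
        cfg <- config$sim
        cfg$seed <- seed + d
        sim <- simulateCaptureAreas(cfg)
        counts <- simulateDomainCounts(sim$spots, cfg, seed = seed + d)
        norm <- logNormalizeCounts(counts$counts)
        for (p in seq_along(counts$markers)) {
            id <- sprintf("donor%d.pattern%d", d, p)
            geneSets[[id]] <- counts$markers[[p]]
            donors[id] <- sprintf("donor%d", d)
            sc <- colMeans(as.matrix(norm[counts$markers[[p]], ,
                                          drop = FALSE]))
            profiles[[id]] <- vapply(
                sort(unique(counts$domains)),
                function(dm) mean(sc[counts$domains == dm]), numeric(1))
        }
    }
    prof <- do.call(rbind, profiles)
    k <- min(config$consensus$k_cut, length(geneSets))
    cp <- consensusPatterns(geneSets, prof, donors, k = k)
    assign("consensus", cp, envir = state)
    utils::write.csv(consensusMembership(cp),
                     file.path(outDir, "consensus_membership.csv"),
                     row.names = FALSE)
    list(nPatterns = nrow(consensusMembership(cp)), k = k)
}

stageFactors <- function(config, state, outDir) {
    qc <- requireStage(state, "qc", "qc", "factors")
    seed <- stageSeed(config$seed, "factors")
    nuclei <- simulateNuclei(nNuclei = 400L,
                             nCellTypes = config$factors$k,
                             nGenes = config$sim$nGenes,
                             drugEffect = 3, seed = seed)
    nnorm <- logNormalizeCounts(nuclei$counts)
    fit <- fitNMF(as.matrix(nnorm), k = config$factors$k,
                  l1w = config$factors$l1_w, tol = config$factors$tol,
                  maxit = config$factors$maxit, seed = seed)
    proj <- projectFactors(fit, as.matrix(qc$norm))
    assign("factors", list(fit = fit, proj = proj, nuclei = nuclei),
           envir = state)
    writeCountsTriplet(Matrix::Matrix(basisMatrix(fit), sparse = TRUE),
                       file.path(outDir, "nmf_w.mtx"),
                       file.path(outDir, "nmf_w_genes.tsv"),
                       file.path(outDir, "nmf_w_factors.tsv"))
    utils::write.csv(t(projectedScores(proj)),
                     file.path(outDir, "nmf_projection.csv"))
    list(k = fit@k,
         finalObjective = utils::tail(objectiveTrace(fit), 1))
}

stageLR <- function(config, state, outDir) {
    qc <- requireStage(state, "qc", "qc", "lrmap")
    counts <- requireStage(state, "counts", "simulate", "lrmap")
    weights <- requireStage(state, "weights", "simulate", "lrmap")
    genes <- rownames(qc$norm)
    ligand <- genes[1]; receptor <- genes[2]
    cls <- classifySpots(as.matrix(qc$norm), ligand, receptor)
    domains <- counts$domains[qc$keepSpot]
    prop <- domainClassProportions(cls, domains)
    cooc <- cooccurrenceEnrichment(weights[qc$keepSpot, , drop = FALSE],
                                   cls, epsilon = config$lr$epsilon)
    assign("lr", cooc, envir = state)
    utils::write.csv(prop, file.path(outDir, "lr_class_proportions.csv"))
    utils::write.csv(enrichmentRatio(cooc),
                     file.path(outDir, "lr_enrichment.csv"))
    list(nCoexpress = cooc@nCoexpress)
}

stageSelect <- function(config, state, outDir) {
    pat <- requireStage(state, "patterns", "patterns", "select")
    stitched <- requireStage(state, "stitched", "stitch", "select")
    qc <- requireStage(state, "qc", "qc", "select")
    counts <- requireStage(state, "counts", "simulate", "select")
    labels <- apply(pat$scores, 2, which.max)
    names(labels) <- colnames(pat$scores)
    truth <- counts$domains[qc$keepSpot]
    ri <- randIndex(labels, truth)
    conc <- NA_real_
    overlaps <- requireStage(state, "overlaps", "stitch", "select")
    pairs <- overlaps$pairs
    pairs <- pairs[pairs$spot_a %in% names(labels) &
                   pairs$spot_b %in% names(labels), , drop = FALSE]
    if (nrow(pairs)) conc <- overlapConcordance(labels, pairs)
    report <- data.frame(metric = c("rand_index_vs_truth",
                                    "overlap_concordance"),
                         value = c(ri, conc))
    utils::write.csv(report, file.path(outDir, "model_selection.csv"),
                     row.names = FALSE)
    list(randIndex = ri, concordance = conc)
}
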