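plantedFactorData <- function(genes = 60, obs = 80, k = 3, seed = 42) {
    set.seed(seed)
    W <- matrix(0, genes, k)
    W[cbind(seq_len(genes), rep(seq_len(k), each = genes / k))] <-
        runif(genes, 0.5, 1.5)
    H <- matrix(rexp(k * obs), k, obs)
    A <- W %*% H
    rownames(A) <- paste0("g", seq_len(genes))
    list(A = A, W = W, H = H)
}

test_that("NMF recovers planted factors and keeps its invariants", {
    pd <- plantedFactorData()
    fit <- fitNMF(pd$A, 3, l1w = 0.01, tol = 1e-9, maxit = 2000,
                  seed = 7)
    # objective trace is non-increasing
    expect_true(all(diff(objectiveTrace(fit)) <= 1e-8))
    # planted-factor cosine recovery after optimal matching
    m <- matchFactors(basisMatrix(fit), pd$W)
    expect_true(all(m$cosines >= 0.95))
    expect_equal(sort(m$permutation), 1:3)
    # small relative reconstruction error on noiseless data (unpenalized
    # fit: the L1 term leaves a deliberate shrinkage floor)
    fit0 <- fitNMF(pd$A, 3, l1w = 0, tol = 1e-10, maxit = 3000, seed = 7)
    recon <- basisMatrix(fit0) %*% scoreMatrix(fit0)
    expect_lt(norm(pd$A - recon, "F") / norm(pd$A, "F"), 1e-3)
    # diagonal rescaling: W columns sum to 1
    expect_equal(unname(colSums(basisMatrix(fit))), rep(1, 3))
    # same seed reproduces identically; non-negativity enforced
    fit2 <- fitNMF(pd$A, 3, l1w = 0.01, tol = 1e-9, maxit = 2000,
                   seed = 7)
    expect_identical(basisMatrix(fit), basisMatrix(fit2))
    expect_true(all(basisMatrix(fit) >= 0) && all(scoreMatrix(fit) >= 0))

    # rank-1 matrix is reconstructed essentially exactly at k = 1
    r1 <- outer(runif(20, 0.1, 1), runif(15, 0.1, 1))
    f1 <- fitNMF(r1, 1, l1w = 0, tol = 1e-12, maxit = 2000, seed = 1)
    expect_lt(norm(r1 - basisMatrix(f1) %*% scoreMatrix(f1), "F") /
              norm(r1, "F"), 1e-6)

    expect_error(fitNMF(-pd$A, 3), "non-negative")
    expect_error(fitNMF(pd$A, 80), "k must be")
    expect_error(fitNMF(pd$A * NA, 3), "finite")
})

test_that("held-out cross-validation finds the planted rank", {
    pd <- plantedFactorData(seed = 3)
    noisy <- pd$A + matrix(rexp(length(pd$A), rate = 20), nrow(pd$A))
    cv <- crossValidateRank(noisy, 1:6, nRep = 3, seed = 5)
    # error drops sharply up to the planted rank, then flattens
    expect_equal(cv$recommended, 3)
    expect_equal(unname(which.min(cv$mean[1:3])), 3)
    # reproducible with the same seed
    cv2 <- crossValidateRank(noisy, 1:6, nRep = 3, seed = 5)
    expect_identical(cv$mean, cv2$mean)
    expect_error(crossValidateRank(noisy, 0:2), "ranks")
    expect_error(crossValidateRank(noisy, 1:3, holdout = 1.2),
                 "holdout")
})

test_that("projection is the literal transpose product, with nnls option", {
    set.seed(4)
    # orthonormal W: the product mode inverts A' = W H exactly (t(Q)Q = I)
    qr <- qr.Q(qr(matrix(rnorm(20 * 5), 20, 5)))
    H <- matrix(rexp(5 * 7), 5, 7)
    A <- qr %*% H
    rownames(qr) <- rownames(A) <- paste0("g", 1:20)
    pr <- projectFactors(qr, A, normalize = FALSE)
    expect_equal(unname(projectedScores(pr)), H, tolerance = 1e-10)

    # random instance equals the direct matrix product oracle
    Wr <- matrix(runif(20 * 5), 20, 5,
                 dimnames = list(paste0("g", 1:20), NULL))
    Ar <- matrix(runif(20 * 6), 20, 6,
                 dimnames = list(paste0("g", 1:20), NULL))
    pr2 <- projectFactors(Wr, Ar, normalize = FALSE)
    expect_equal(unname(projectedScores(pr2)), t(Wr) %*% Ar,
                 tolerance = 1e-12)

    # per-spot normalization sums to 1; all-zero spots exempt + flagged
    Az <- Ar; Az[, 3] <- 0
    pr3 <- projectFactors(Wr, Az)
    sums <- colSums(projectedScores(pr3))
    expect_equal(unname(sums[-3]), rep(1, 5))
    expect_equal(unname(sums[3]), 0)
    expect_equal(pr3@zeroObservations, 3L)

    # nnls mode reproduces H exactly when A' = W H with full column rank
    Hn <- matrix(rexp(5 * 6), 5, 6)
    An <- Wr %*% Hn
    prn <- projectFactors(Wr, An, method = "lstsq", normalize = FALSE)
    expect_equal(unname(projectedScores(prn)), Hn, tolerance = 1e-6)

    expect_error(projectFactors(Wr, matrix(1, 2, 2,
        dimnames = list(c("zz1", "zz2"), NULL))), "no genes shared")
})

test_that("factor exclusion applies sex and support rules", {
    set.seed(5)
    sex <- rep(c("F", "M"), each = 100)
    scores <- rbind(
        sexLike = as.numeric(sex == "M"),
        dense = runif(200, 0.1, 1),
        sparse = c(runif(150), rep(0, 50)))
    res <- excludeFactors(scores, sex, minSpots = 160)
    expect_false(res$keep["sexLike"])   # |r| = 1 with sex
    expect_true(res$keep["dense"])      # orthogonal to sex, dense
    expect_false(res$keep["sparse"])    # nonzero support below minimum
    expect_equal(unname(abs(res$sexR["sexLike"])), 1)
})

test_that("domain summaries flag domain-restricted factors only", {
    proj <- rbind(f1 = c(0, 0, 0.3, 0.5), f2 = rep(0.25, 4))
    domains <- c("a", "a", "a", "a")
    s <- summarizeByDomain(proj, domains)
    expect_equal(unname(s$prevalence["f1", "a"]), 0.5)
    expect_equal(unname(s$mean["f1", "a"]), 0.2)

    # a factor uniform across domains has all scaled means 0
    proj2 <- rbind(flat = rep(0.5, 6), spec = c(1, 1, 0, 0, 0, 0))
    dom2 <- rep(c("a", "b", "c"), each = 2)
    s2 <- summarizeByDomain(proj2, dom2)
    expect_equal(unname(s2$scaledMean["flat", ]), rep(0, 3))
    expect_false(s2$associated["flat"])
    expect_true(s2$associated["spec"])
    expect_equal(unname(apply(s2$scaledMean["spec", , drop = FALSE], 1,
                              which.max)), 1)

    # planted domain-specific factor from the generators
    nuc <- simulateNuclei(nNuclei = 300, nCellTypes = 3, seed = 9)
    norm <- as.matrix(logNormalizeCounts(nuc$counts))
    fit <- fitNMF(norm, 3, seed = 2, maxit = 300, tol = 1e-7)
    s3 <- summarizeByDomain(scoreMatrix(fit), nuc$cellType)
    expect_true(any(s3$associated))
})

test_that("factor-gene correlation ranks planted markers first", {
    set.seed(8)
    h <- matrix(runif(2 * 150), 2, 150,
                dimnames = list(c("f1", "f2"), NULL))
    expr <- rbind(marker = h[1, ] * 3 + rnorm(150, sd = 0.1),
                  noise1 = rnorm(150), noise2 = rnorm(150),
                  flat = rep(1, 150))
    expect_warning(fc <- factorGeneCorrelation(h, expr, topN = 2),
                   "constant")
    expect_equal(names(fc$top$f1)[1], "marker")
    expect_equal(unname(fc$correlation["flat", ]), c(0, 0))
    # correlation values match the direct formula
    expect_equal(unname(fc$correlation["noise1", "f2"]),
                 cor(expr["noise1", ], h["f2", ]), tolerance = 1e-12)
})

test_that("drug association flags planted shifts and controls the null", {
    set.seed(13)
    n <- 200
    condition <- rep(c("drug", "control"), each = n / 2)
    ct <- rep("mA", n)
    # complete separation gives rank-biserial effect exactly 1
    sep <- rbind(f = c(rep(1, 100) + seq_len(100) / 1000, rep(0, 100)))
    resSep <- drugFactorAssociation(sep, condition, ct)
    expect_equal(resSep$table$effect, 1)
    # identical distributions are not flagged
    same <- rbind(f = rep(c(1, 2), 100))
    resSame <- drugFactorAssociation(same, condition, ct)
    expect_lt(abs(resSame$table$effect), 0.2)
    expect_false(any(resSame$responsive))
    # planted 1-SD shift at n = 100/arm is flagged; 50 null factors stay
    # below the nominal false-flag budget
    scores <- rbind(matrix(rnorm(50 * n), 50, n,
                           dimnames = list(paste0("null", 1:50), NULL)),
                    shifted = rnorm(n) + (condition == "drug"))
    res <- drugFactorAssociation(scores, condition, ct)
    expect_true(res$responsive["shifted"])
    falseRate <- mean(res$responsive[paste0("null", 1:50)])
    expect_lte(falseRate, 0.05 + 3 * sqrt(0.05 * 0.95 / 50))
    # strata lacking a condition are skipped
    expect_warning(
        res2 <- drugFactorAssociation(scores[1:2, , drop = FALSE],
                                      rep("drug", n), ct),
        "stratum")
    expect_null(res2$table)
})
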