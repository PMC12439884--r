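# Independent oracles used across the suite. These deliberately use naive
# formulations (double sums, exhaustive enumeration, SVD fits) so they do
# not share code paths with the implementation they check.

# Moran's I by literal double sum over all (i, j)
oracleMoran <- function(x, W) {
    n <- length(x)
    xc <- x - mean(x)
    num <- 0
    for (i in seq_len(n)) for (j in seq_len(n))
        num <- num + W[i, j] * xc[i] * xc[j]
    (n / sum(W)) * num / sum(xc^2)
}

# spatial cross-correlation by literal double sum, then symmetrized
oracleSCC <- function(expr, W) {
    g <- nrow(expr)
    n <- ncol(expr)
    out <- matrix(0, g, g)
    cm <- rowMeans(expr)
    for (a in seq_len(g)) for (b in seq_len(g)) {
        num <- 0
        for (i in seq_len(n)) for (j in seq_len(n))
            num <- num + W[i, j] * (expr[a, i] - cm[a]) *
                (expr[b, j] - cm[b])
        out[a, b] <- (n / sum(W)) * num /
            sqrt(sum((expr[a, ] - cm[a])^2) * sum((expr[b, ] - cm[b])^2))
    }
    (out + t(out)) / 2
}

# least-squares rigid fit (Kabsch/Procrustes via SVD): rotation + shift
# minimizing ||A - (R B + t)||
oracleRigidFit <- function(pa, pb) {
    ca <- colMeans(pa); cb <- colMeans(pb)
    H <- t(sweep(pb, 2, cb)) %*% sweep(pa, 2, ca)
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
    list(theta = atan2(R[2, 1], R[1, 1]),
         translation = ca - as.numeric(R %*% cb), R = R)
}

# one-sided Fisher p by exhaustive hypergeometric enumeration over the
# enrichment tail (all tables with overlap >= observed)
oracleFisherP <- function(a, b, c, d) {
    K <- a + b   # DEG set size
    n <- a + c   # list size
    N <- a + b + c + d
    tail <- 0
    for (x in a:min(K, n))
        tail <- tail + choose(K, x) * choose(N - K, n - x)
    tail / choose(N, n)
}

# Rand index by brute force over all observation pairs
oracleRand <- function(a, b) {
    n <- length(a)
    agree <- 0; total <- 0
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
        total <- total + 1
        agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
    }
    agree / total
}

# BH step-up adjustment by direct enumeration
oracleBH <- function(p) {
    n <- length(p)
    ord <- order(p)
    adj <- p[ord] * n / seq_len(n)
    for (i in seq(n - 1, 1)) adj[i] <- min(adj[i], adj[i + 1])
    out <- numeric(n)
    out[ord] <- pmin(adj, 1)
    out
}

# naive agglomerative clustering with the Lance-Williams ward.D2 update
oracleWardD2 <- function(d, k) {
    d <- as.matrix(d)
    n <- nrow(d)
    active <- seq_len(n)
    sizes <- rep(1, n)
    members <- as.list(seq_len(n))
    while (length(active) > k) {
        best <- c(Inf, NA, NA)
        for (ii in seq_along(active)) for (jj in seq_along(active)) {
            if (jj <= ii) next
            i <- active[ii]; j <- active[jj]
            if (d[i, j] < best[1]) best <- c(d[i, j], i, j)
        }
        i <- best[2]; j <- best[3]
        for (h in setdiff(active, c(i, j))) {
            ni <- sizes[i]; nj <- sizes[j]; nh <- sizes[h]
            d[i, h] <- d[h, i] <- sqrt(
                ((ni + nh) * d[i, h]^2 + (nj + nh) * d[j, h]^2 -
                 nh * d[i, j]^2) / (ni + nj + nh))
        }
        sizes[i] <- sizes[i] + sizes[j]
        members[[i]] <- c(members[[i]], members[[j]])
        active <- setdiff(active, j)
    }
    labels <- integer(n)
    for (g in seq_along(active)) labels[members[[active[g]]]] <- g
    labels
}

# rook-adjacency binary weight matrix over a rows x cols grid
rookGrid <- function(rows, cols) {
    coords <- expand.grid(r = seq_len(rows), c = seq_len(cols))
    n <- nrow(coords)
    W <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        if (abs(coords$r[i] - coords$r[j]) +
            abs(coords$c[i] - coords$c[j]) == 1) W[i, j] <- 1
    }
    list(W = W, coords = as.matrix(coords))
}
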