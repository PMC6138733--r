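# Independent brute-force oracles and small data helpers shared by the
# suite. Each oracle is a direct transcription of the defining formula,
# kept free of any code path it is used to check.

AA <- aminoAcidAlphabet()

randSeq <- function(L) paste(sample(AA, L, replace = TRUE), collapse = "")

# --- CTD: naive enumeration of group counts, adjacent pairs and
#     occurrence-quantile positions.
ctdOracle <- function(seq) {
    g <- unname(ctdGroupScheme()[strsplit(seq, "")[[1]]])
    L <- length(g)
    comp <- vapply(1:4, function(i) sum(g == i), numeric(1)) / L
    pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
    trans <- apply(pairs, 1, function(p) {
        cnt <- 0
        for (t in seq_len(L - 1)) {
            if ((g[t] == p[1] && g[t + 1] == p[2]) ||
                (g[t] == p[2] && g[t + 1] == p[1])) cnt <- cnt + 1
        }
        cnt / (L - 1)
    })
    distr <- numeric(20)
    for (i in 1:4) {
        occ <- which(g == i)
        n <- length(occ)
        if (n > 0) {
            idx <- c(1, ceiling(0.25 * n), ceiling(0.5 * n),
                     ceiling(0.75 * n), n)
            distr[(i - 1) * 5 + 1:5] <- occ[idx] / L
        }
    }
    c(comp, trans, distr)
}

# --- DFT: direct O(L^2) evaluation with the n = 1..L convention.
dftOracle <- function(profile) {
    L <- length(profile)
    vapply(0:(L - 1), function(k) {
        Mod(sum(profile * exp(-2i * pi * (1:L) * k / L)))^2
    }, numeric(1))
}

# --- Relief: literal per-instance weight updates on min-max scaled
#     features with naive distance scans.
reliefOracle <- function(X, y) {
    X <- as.matrix(X)
    lo <- apply(X, 2, min); hi <- apply(X, 2, max)
    span <- ifelse(hi - lo == 0, 1, hi - lo)
    Xs <- sweep(sweep(X, 2, lo, "-"), 2, span, "/")
    n <- nrow(X)
    W <- numeric(ncol(X))
    for (i in seq_len(n)) {
        dists <- vapply(seq_len(n), function(j)
            sqrt(sum((Xs[i, ] - Xs[j, ])^2)), numeric(1))
        same <- setdiff(which(y == y[i]), i)
        other <- which(y != y[i])
        nh <- same[which.min(dists[same])]
        nm <- other[which.min(dists[other])]
        W <- W - abs(Xs[i, ] - Xs[nh, ]) / n + abs(Xs[i, ] - Xs[nm, ]) / n
    }
    unname(W)
}

# --- AUC: Mann-Whitney pair counting with half credit for ties.
aucOracle <- function(scores, labels) {
    sp <- scores[labels == 1]
    sn <- scores[labels == 0]
    tot <- 0
    for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
    tot / (length(sp) * length(sn))
}

# --- Gaussian NB posterior: direct density product (ML variances, no
#     floor relevant when variances are healthy).
nbOracle <- function(X, y, x) {
    post <- vapply(c(0, 1), function(cls) {
        M <- X[y == cls, , drop = FALSE]
        mu <- colMeans(M)
        v <- colMeans(sweep(M, 2, mu, "-")^2)
        prod(dnorm(x, mu, sqrt(v))) * mean(y == cls)
    }, numeric(1))
    post[2] / sum(post)
}

# --- Penalised logistic log-likelihood, maximised numerically.
lrOracle <- function(X, y, ridge) {
    Xd <- cbind(1, as.matrix(X))
    negLogLik <- function(w) {
        eta <- drop(Xd %*% w)
        -sum(y * eta - log1p(exp(eta))) + ridge / 2 * sum(w[-1]^2)
    }
    fit <- optim(numeric(ncol(Xd)), negLogLik, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14))
    fit$par
}

.withSeedForTest <- function(seed, expr) {
    set.seed(seed)
    expr
}

writeTempFasta <- function(lines) {
    path <- tempfile(fileext = ".fasta")
    writeLines(lines, path)
    path
}
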