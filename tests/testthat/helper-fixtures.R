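# Fixtures built in code: tiny labeled references and model-generated bulk.

# A small reference with hand-controllable expression: focal cells carry
# pseudotime 1..kFocal (shuffled column order to exercise ordering
# invariance), other types get their own columns.
makeTinyRef <- function(nGenes = 30, kFocal = 10, others = c(4, 4),
                        seed = 1, shuffle = TRUE) {
    set.seed(seed)
    nCells <- kFocal + sum(others)
    expr <- matrix(stats::rexp(nGenes * nCells, rate = 0.5), nGenes, nCells)
    rownames(expr) <- sprintf("g%03d", seq_len(nGenes))
    ct <- c(rep("epi", kFocal),
            rep(paste0("type", seq_along(others)), times = others))
    pt <- c(seq_len(kFocal), rep(NA_real_, sum(others)))
    ord <- if (shuffle) sample(nCells) else seq_len(nCells)
    StateReference(expr[, ord], cellType = ct[ord], pseudotime = pt[ord],
                   focalType = "epi",
                   cellIds = sprintf("c%03d", seq_len(nCells))[ord])
}

# A raw StateDesign with random Z/C (no reference semantics), for the LMM
# core: m equal bins of the k cells, X = per-bin means of Z.
makeRawDesign <- function(n, k, p = 2, m = 4, seed = 1) {
    set.seed(seed)
    pt <- sort(stats::runif(k))
    Z <- matrix(stats::rnorm(n * k), n, k,
                dimnames = list(sprintf("g%03d", seq_len(n)), NULL))
    C <- matrix(stats::rexp(n * p), n, p)
    sizes <- diff(round(seq(0, k, length.out = m + 1)))
    members <- split(seq_len(k), rep(seq_len(m), sizes))
    X <- vapply(members, function(ix) rowMeans(Z[, ix, drop = FALSE]),
                numeric(n))
    dim(X) <- c(n, m)
    new(Class = "StateDesign", mStates = as.integer(m),
        stateMembers = unname(members),
        statePseudotime = vapply(members, function(ix) median(pt[ix]),
                                 numeric(1)),
        X = X, C = C, Z = Z,
        signatureGenes = rownames(Z), cellPseudotime = pt,
        cellIds = paste0("c", seq_len(k)))
}

# Draw y from the CAR mixed model at given variance parameters.
simulateCarY <- function(design, weights, theta, lambda2, sigmaE2,
                         gamma = NULL) {
    k <- ncol(design@Z)
    M <- diag(weights@D) - theta * weights@W
    Sig <- solve(M) * lambda2
    alpha <- drop(crossprod(chol(Sig), stats::rnorm(k)))
    p <- ncol(design@C)
    if (is.null(gamma)) gamma <- rep(1, p)
    fixed <- if (p > 0) drop(design@C %*% gamma) else 0
    fixed + drop(design@Z %*% alpha) +
        stats::rnorm(nrow(design@Z), sd = sqrt(sigmaE2))
}

# Dense-grid REML oracle: maximize remlLogLikDense over a parameter grid.
denseGridREML <- function(y, design, weights,
                          thetas = seq(0, 0.9, by = 0.1),
                          lambda2s, sigmaE2s) {
    best <- -Inf
    for (th in thetas) for (l2 in lambda2s) for (s2 in sigmaE2s) {
        ll <- remlLogLikDense(y, design, weights, th, l2, s2)
        if (ll > best) best <- ll
    }
    best
}
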