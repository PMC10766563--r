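test_that("polynomial profile fits match an independent least-squares oracle", {
    m <- 20
    t <- seq(0.1, 0.9, length.out = m)
    cst <- rep(0.4, m)
    b <- fitPolynomialProfile(cst, t, degree = 2)$coefficients
    expect_equal(b, c(0.4, 0, 0), tolerance = 1e-10)
    # exactly linear profile: quadratic coefficient vanishes
    lin <- 2 - 3 * t
    bl <- fitPolynomialProfile(lin, t, degree = 2)$coefficients
    expect_lt(abs(bl[3]), 1e-10)
    # random profile, degree 3, against lm on the same rescaled basis
    set.seed(5)
    y <- rnorm(m)
    t01 <- (t - min(t)) / (max(t) - min(t))
    ora <- unname(coef(lm(y ~ t01 + I(t01^2) + I(t01^3))))
    b3 <- fitPolynomialProfile(y, t, degree = 3)$coefficients
    expect_equal(unname(b3), ora, tolerance = 1e-10)
    expect_error(fitPolynomialProfile(y[1:3], t[1:3], degree = 3), "states")
})

test_that("MANOVA-Pro reproduces the Pillai-trace F approximation and its degrees of freedom", {
    set.seed(9)
    B <- matrix(rnorm(3 * 40), 3, 40)
    groups <- rep(c("case", "control"), each = 20)
    res <- manovaPro(B, groups)
    expect_equal(res@s, 1)
    expect_equal(res@m, 0.5)
    expect_equal(res@u, 17)
    expect_equal(res@df1, 3)
    expect_equal(res@df2, 36)
    # established-implementation oracle
    fit <- summary(stats::manova(t(B) ~ groups), test = "Pillai")
    st <- fit$stats
    expect_lt(abs(res@pillai - st[1, "Pillai"]), 1e-8)
    expect_lt(abs(res@Fstat - st[1, "approx F"]), 1e-8)
    expect_equal(res@df1, unname(st[1, "num Df"]))
    expect_equal(res@df2, unname(st[1, "den Df"]))
    expect_lt(abs(res@pParametric - st[1, "Pr(>F)"]), 1e-8)
    # three groups, 4 coefficients
    B2 <- matrix(rnorm(4 * 45), 4, 45)
    g3 <- rep(letters[1:3], each = 15)
    r2 <- manovaPro(B2, g3)
    f2 <- summary(stats::manova(t(B2) ~ g3), test = "Pillai")$stats
    expect_lt(abs(r2@pillai - f2[1, "Pillai"]), 1e-8)
    expect_lt(abs(r2@Fstat - f2[1, "approx F"]), 1e-8)
})

test_that("MANOVA-Pro degenerates gracefully and reduces to one-way ANOVA for scalar profiles", {
    B <- matrix(rep(c(1, 2, 3), 10), 3, 10)
    g <- rep(c("a", "b"), each = 5)
    res <- manovaPro(B, g)
    expect_equal(res@pillai, 0)
    expect_equal(res@Fstat, 0)
    expect_equal(res@pParametric, 1)
    # scalar coefficient: equals the two-sample ANOVA F
    set.seed(31)
    b1 <- matrix(rnorm(30), 1, 30)
    g2 <- rep(c("x", "y"), each = 15)
    r <- manovaPro(b1, g2)
    aF <- anova(lm(drop(b1) ~ g2))$`F value`[1]
    expect_lt(abs(r@Fstat - aF), 1e-8)
    expect_error(manovaPro(matrix(rnorm(6), 3, 2), c("a", "b")),
                 "at least 2 samples")
    expect_error(manovaPro(matrix(rnorm(9), 3, 3), c("a", "a", "a")),
                 "2 groups")
})

test_that("parametric MANOVA-Pro holds its size on independent Gaussian profiles", {
    set.seed(77)
    reps <- 600
    g <- rep(c("a", "b"), each = 12)
    p <- replicate(reps, {
        B <- matrix(rnorm(3 * 24), 3, 24)
        manovaPro(B, g)@pParametric
    })
    rate <- mean(p < 0.05)
    tol <- 2.5 * sqrt(0.05 * 0.95 / reps)
    expect_gte(rate, 0.05 - tol)
    expect_lte(rate, 0.05 + tol)
})

test_that("signature-gene shuffling permutation test is deterministic and uses the add-one convention", {
    ref <- generateSyntheticReference(nGenes = 150, nCells = 120, nTypes = 2,
                                      nSignature = 60, focalFrac = 0.7,
                                      seed = 3)
    # two groups with strongly different planted shapes
    yA <- sapply(1:5, function(r)
        synthesizeBulk(ref, "increasing", k = 2, L = 8, noiseSd = 0.1,
                       seed = r)@y)
    yB <- sapply(1:5, function(r)
        synthesizeBulk(ref, "decreasing", k = 2, L = 8, noiseSd = 0.1,
                       seed = 100 + r)@y)
    bulk <- cbind(yA, yB)
    rownames(bulk) <- rownames(ref)
    colnames(bulk) <- paste0("s", 1:10)
    groups <- rep(c("inc", "dec"), each = 5)
    res <- permutationGroupTest(bulk, ref, groups, nPerm = 9, seed = 42,
                                mStates = 8, nSignature = 60,
                                thetaGrid = c(0, 0.5),
                                smoothMethod = "none")
    # a real group difference should beat every gene-shuffled permutation
    expect_equal(res@pEmpirical, 1 / 10)
    expect_lt(res@pParametric, 0.05)
    res2 <- permutationGroupTest(bulk, ref, groups, nPerm = 9, seed = 42,
                                 mStates = 8, nSignature = 60,
                                 thetaGrid = c(0, 0.5),
                                 smoothMethod = "none")
    expect_identical(res2@pEmpirical, res@pEmpirical)
    # label permutation route works too
    res3 <- permutationGroupTest(bulk, ref, groups, nPerm = 9, seed = 1,
                                 shuffle = "labels", mStates = 8,
                                 nSignature = 60, thetaGrid = c(0, 0.5),
                                 smoothMethod = "none")
    expect_true(res3@pEmpirical >= 0 && res3@pEmpirical <= 1)
    expect_error(permutationGroupTest(bulk, ref, groups, nPerm = 0), "nPerm")
})
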