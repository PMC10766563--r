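test_that("fast-path restricted likelihood matches dense evaluation and the dense-grid optimum", {
    des <- makeRawDesign(n = 50, k = 30, m = 3, seed = 5)
    w <- buildTrajectoryWeights(des@cellPseudotime)
    set.seed(5)
    y <- simulateCarY(des, w, theta = 0.5, lambda2 = 1.5, sigmaE2 = 1)
    vc <- fitNullREML(y, des, w)
    # the reported optimum re-evaluates identically through the dense path
    dense <- remlLogLikDense(y, des, w, vc@theta, vc@lambda2, vc@sigmaE2)
    expect_lt(abs(dense - vc@loglik), 1e-4)
    # and is at least as good as an independent dense-grid maximizer
    gridBest <- denseGridREML(y, des, w,
                              lambda2s = seq(0, 4, by = 0.2),
                              sigmaE2s = seq(0.3, 3, by = 0.15))
    expect_gte(vc@loglik, gridBest - 1e-4)
    # lambda2 = 0 reference likelihood matches its dense evaluation at the
    # closed-form REML residual variance
    ols <- lm(y ~ 0 + des@C)
    s2hat <- sum(resid(ols)^2) / (length(y) - 2)
    expect_lt(abs(remlLogLikDense(y, des, w, 0, 0, s2hat) - vc@loglik0), 1e-6)
})

test_that("GLS plug-in equals the naive matrix-inverse formula and reduces to OLS when V is diagonal", {
    des <- makeRawDesign(n = 50, k = 30, m = 5, seed = 8)
    w <- buildTrajectoryWeights(des@cellPseudotime)
    set.seed(8)
    y <- simulateCarY(des, w, theta = 0.4, lambda2 = 2, sigmaE2 = 0.8)
    vc <- fitNullREML(y, des, w)
    est <- estimateStateAbundances(y, des, vc)
    Vi <- solve(vc@V)
    for (i in seq_len(des@mStates)) {
        Xi <- cbind(des@X[, i], des@C)
        A <- solve(t(Xi) %*% Vi %*% Xi)
        b <- drop(A %*% t(Xi) %*% Vi %*% y)
        expect_lt(abs(est$raw[i] - b[1]), 1e-8)
        expect_lt(abs(est$se[i] - sqrt(A[1, 1])), 1e-8)
        expect_lt(max(abs(est$gammaHat[, i] - b[-1])), 1e-8)
    }
    # V = I sigma2: GLS estimate equals OLS
    vcI <- new("VarianceComponents", theta = 0, lambda2 = 0, sigmaE2 = 2,
               loglik = 0, loglik0 = 0, V = diag(2, nrow(des@Z)))
    estI <- estimateStateAbundances(y, des, vcI)
    ols <- coef(lm(y ~ 0 + des@X[, 2] + des@C))
    expect_equal(estI$raw[2], unname(ols[1]), tolerance = 1e-10)
    # y built exactly as x_i, no covariates: beta = 1, zero residual
    desX <- des
    desX@C <- matrix(0, nrow(des@Z), 0)
    yx <- des@X[, 3]
    estX <- estimateStateAbundances(yx, desX, vcI)
    expect_equal(estX$raw[3], 1, tolerance = 1e-10)
})

test_that("REML finds the zero boundary when no random effects were simulated", {
    des <- makeRawDesign(n = 80, k = 20, m = 4, seed = 13)
    w <- buildTrajectoryWeights(des@cellPseudotime)
    set.seed(13)
    ratio <- olsGap <- numeric(20)
    for (r in 1:20) {
        y <- drop(des@C %*% c(1, 1)) + rnorm(80)
        vc <- fitNullREML(y, des, w)
        kbar <- mean(diag(des@Z %*% solve(diag(w@D) - vc@theta * w@W,
                                          t(des@Z))))
        ratio[r] <- vc@lambda2 * kbar / vc@sigmaE2
        est <- estimateStateAbundances(y, des, vc)
        ols <- coef(lm(y ~ 0 + des@X[, 1] + des@C))
        olsGap[r] <- abs(est$raw[1] - unname(ols[1]))
    }
    # the random-effect share of variance typically collapses to zero
    expect_lt(median(ratio), 0.01)
    # and whenever it does, the GLS estimate is exactly the OLS estimate
    atZero <- ratio < 1e-10
    expect_gt(sum(atZero), 5)
    expect_lt(max(olsGap[atZero]), 1e-6)
})

test_that("boundary LRT for the random effect is calibrated under the null and powered under signal", {
    # LRT = 0 gives p = 0.5 under the 50:50 mixture
    vc0 <- new("VarianceComponents", theta = 0, lambda2 = 0, sigmaE2 = 1,
               loglik = -10, loglik0 = -10, V = diag(1, 2))
    expect_equal(testRandomEffect(vc0), 0.5)

    des <- makeRawDesign(n = 60, k = 15, m = 3, seed = 21)
    w <- buildTrajectoryWeights(des@cellPseudotime)
    grid <- c(0, 0.3, 0.6, 0.9)
    set.seed(21)
    pNull <- replicate(300, {
        y <- drop(des@C %*% c(1, 1)) + rnorm(60)
        testRandomEffect(fitNullREML(y, des, w, thetaGrid = grid))
    })
    # stochastically no smaller than uniform: P(p <= a) <= a at several a
    for (a in c(0.01, 0.05, 0.2))
        expect_lte(mean(pNull < a), a + 2.5 * sqrt(a * (1 - a) / 300))

    pAlt <- replicate(40, {
        y <- simulateCarY(des, w, theta = 0.5, lambda2 = 5, sigmaE2 = 1)
        testRandomEffect(fitNullREML(y, des, w, thetaGrid = grid))
    })
    expect_gte(mean(pAlt < 0.05), 0.95)
})

test_that("the one-shot null covariance approximates per-state REML refits", {
    des <- makeRawDesign(n = 150, k = 60, m = 30, seed = 34)
    w <- buildTrajectoryWeights(des@cellPseudotime)
    set.seed(34)
    a <- shapeAbundance("unimodal", t = des@statePseudotime)
    y <- drop(des@X %*% (a * 30)) + drop(des@C %*% c(1, 1)) + rnorm(150, sd = 0.5)
    vc <- fitNullREML(y, des, w)
    fast <- estimateStateAbundances(y, des, vc)$raw
    slow <- vapply(seq_len(30), function(i) {
        desi <- des
        desi@C <- cbind(des@X[, i], des@C)      # full per-state REML refit
        vci <- fitNullREML(y, desi, w)
        desOne <- des
        vv <- new("VarianceComponents", theta = vci@theta,
                  lambda2 = vci@lambda2, sigmaE2 = vci@sigmaE2,
                  loglik = vci@loglik, loglik0 = vci@loglik0, V = vci@V)
        estimateStateAbundances(y, desOne, vv)$raw[i]
    }, numeric(1))
    expect_gt(cor(fast, slow), 0.99)
})

test_that("CAR covariance is positive definite across the theta domain", {
    for (seed in 1:5) {
        set.seed(seed)
        w <- buildTrajectoryWeights(runif(12))
        for (theta in c(0, 0.25, 0.5, 0.75, 0.95, 0.999)) {
            Sig <- solve(diag(w@D) - theta * w@W)
            ev <- eigen((Sig + t(Sig)) / 2, only.values = TRUE)$values
            expect_gt(min(ev), 0)
        }
    }
})

test_that("smoothing preserves constants, respects method none, and reduces noise", {
    t <- seq(0, 1, length.out = 50)
    cst <- rep(0.3, 50)
    expect_equal(smoothAbundances(cst, t, "loess"), cst, tolerance = 1e-8)
    expect_equal(smoothAbundances(cst, t, "knn"), cst, tolerance = 1e-12)
    x <- rnorm(50)
    expect_identical(smoothAbundances(x, t, "none"), x)
    set.seed(40)
    truth <- sin(2 * pi * t)
    noisy <- truth + rnorm(50, sd = 0.3)
    for (m in c("loess", "knn")) {
        sm <- smoothAbundances(noisy, t, m)
        expect_lt(sqrt(mean((sm - truth)^2)), sqrt(mean((noisy - truth)^2)))
    }
    expect_error(smoothAbundances(x, t, "loess", span = 0), "span")
    expect_error(smoothAbundances(x, t, "knn", q = 0), "q must")
})

test_that("unit-sum rescaling obeys both the truncation and min-max conventions", {
    expect_equal(normalizeAbundances(c(-1, 1, 3), method = "truncate"),
                 c(0, 0.25, 0.75))
    x <- c(0.2, 0.3, 0.5)
    expect_equal(normalizeAbundances(x, method = "truncate"), x)
    expect_equal(normalizeAbundances(rep(2, 5), method = "truncate"),
                 rep(0.2, 5))
    expect_equal(normalizeAbundances(rep(2, 5), method = "minmax"),
                 rep(0.2, 5))
    mm <- normalizeAbundances(c(-1, 1, 3), method = "minmax")
    expect_equal(mm, c(0, 0.5, 1) / 1.5)     # shift min to 0, then unit sum
    expect_true(all(mm >= 0 & mm <= 1))
    expect_equal(sum(mm), 1)
    expect_error(normalizeAbundances(c(-2, -1), method = "truncate"),
                 "degenerate")
    expect_error(normalizeAbundances(c(-2, -2), method = "minmax"),
                 "degenerate")
})
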