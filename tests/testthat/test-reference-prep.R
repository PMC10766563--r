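test_that("state binning gives contiguous equal-count states whose profiles are member means", {
    ref <- makeTinyRef(nGenes = 24, kFocal = 10, others = c(4, 4), seed = 3)
    sig <- rownames(ref)
    des <- buildStates(ref, mStates = 5, signatureGenes = sig)

    expect_identical(lengths(des@stateMembers), rep(2L, 5))
    # members are contiguous in pseudotime order
    expect_identical(unlist(des@stateMembers), 1:10)
    expect_true(all(diff(des@cellPseudotime) >= 0))
    # X column i is the mean of the member Z columns, to machine precision
    for (i in seq_len(5)) {
        ix <- des@stateMembers[[i]]
        expect_equal(des@X[, i], rowMeans(des@Z[, ix, drop = FALSE]),
                     tolerance = 1e-14)
    }
    # one cell per state: X equals Z
    des1 <- buildStates(ref, mStates = 10, signatureGenes = sig)
    expect_equal(unname(des1@X), unname(des1@Z), tolerance = 1e-14)
    # C columns are brute-force per-type means
    E <- SummarizedExperiment::assay(ref, 1)
    for (ty in c("type1", "type2")) {
        expect_equal(unname(des@C[, ty]),
                     unname(rowMeans(E[, cellType(ref) == ty])),
                     tolerance = 1e-14)
    }
    expect_error(buildStates(ref, 1, sig), "at least 2")
    expect_error(buildStates(ref, 11, sig), "exceeds")
    expect_error(buildStates(ref, 5, c(sig, "nope")), "absent")
})

test_that("rare-gene filter uses an inclusive focal-fraction boundary and is idempotent", {
    set.seed(7)
    kFocal <- 100
    expr <- matrix(1, 4, kFocal)
    rownames(expr) <- paste0("g", 1:4)
    expr[1, ] <- 0                                  # never expressed
    expr[2, ] <- c(rep(1, 9), rep(0, 91))           # 9%
    expr[3, ] <- c(rep(1, 10), rep(0, 90))          # exactly 10%
    ref <- StateReference(expr, cellType = rep("epi", kFocal),
                          pseudotime = seq_len(kFocal), focalType = "epi")
    flt <- filterGenes(ref, minFrac = 0.10)
    expect_identical(rownames(flt), c("g3", "g4"))
    expect_identical(rownames(filterGenes(flt, 0.10)), rownames(flt))
    expect_error(filterGenes(ref, minFrac = 1), "minFrac")
    ref0 <- ref[1, ]
    expect_error(filterGenes(ref0, 0.10), "empty")
})

test_that("signature selection ranks trajectory genes first, skips constants, recovers planted genes", {
    kFocal <- 40
    t <- seq(0, 1, length.out = kFocal)
    set.seed(11)
    expr <- rbind(mono = 5 * t,
                  flat = rep(2, kFocal),
                  matrix(runif(20 * kFocal), 20, kFocal))
    rownames(expr) <- c("mono", "flat", paste0("noise", 1:20))
    ref <- StateReference(expr, cellType = rep("epi", kFocal),
                          pseudotime = t, focalType = "epi")
    sel <- selectSignatureGenes(ref, nGenes = 5)
    expect_identical(sel[1], "mono")     # noiseless monotone gene outranks noise
    expect_false("flat" %in% selectSignatureGenes(ref, nGenes = 21))
    expect_error(selectSignatureGenes(ref, nGenes = 23), "exceeds")

    # planted-signal recovery: 50 trajectory genes among 450 noise genes
    big <- generateSyntheticReference(nGenes = 500, nCells = 400,
                                      nSignature = 50, focalFrac = 0.5,
                                      seed = 42)
    big <- filterGenes(big)
    planted <- S4Vectors::metadata(big)$plantedSignature
    got <- selectSignatureGenes(big, nGenes = 50)
    expect_gte(mean(planted %in% got), 0.9)

    # invariant to cell ordering
    set.seed(99)
    perm <- sample(ncol(big))
    expect_setequal(selectSignatureGenes(big[, perm], nGenes = 50), got)
})

test_that("trajectory weights follow the Gaussian kernel of rescaled distances", {
    w <- buildTrajectoryWeights(c(0, 0.5, 1), bandwidth = 1)
    expect_equal(w@W[1, 2], exp(-0.25))
    expect_equal(w@W[2, 3], exp(-0.25))
    expect_equal(w@W[1, 3], exp(-1))
    expect_equal(w@D[1], exp(-0.25) + exp(-1))
    expect_identical(diag(w@W), rep(0, 3))
    expect_true(isSymmetric(w@W))

    # zero distance gives weight one
    w2 <- buildTrajectoryWeights(c(0.3, 0.3, 0.9))
    expect_equal(w2@W[1, 2], 1)
    expect_warning(buildTrajectoryWeights(c(1, 1, 1)), "identical")

    # automatic bandwidth calibrates the median weight to one half
    set.seed(2)
    wa <- buildTrajectoryWeights(runif(40))
    expect_equal(median(wa@W[upper.tri(wa@W)]), 0.5, tolerance = 1e-5)

    # permuting coordinates permutes W consistently
    pt <- runif(12)
    perm <- sample(12)
    wp <- buildTrajectoryWeights(pt[perm], bandwidth = 2)
    wo <- buildTrajectoryWeights(pt, bandwidth = 2)
    expect_equal(wp@W, wo@W[perm, perm], tolerance = 1e-12)
    expect_error(buildTrajectoryWeights(0.5), "at least 2")
})

test_that("library-size normalization equalizes column totals without logs", {
    m <- matrix(rpois(60, 10) + 1, 10, 6)
    rownames(m) <- paste0("g", 1:10)
    nm <- libSizeNormalize(m)
    expect_equal(unname(colSums(nm)), rep(1e4, 6))
    expect_true(all(nm >= 0))
})
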