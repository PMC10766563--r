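#' @include AllClasses.R deconvolve.R
NULL

#' Fit a polynomial profile to a per-state abundance vector
#'
#' Ordinary least squares of the abundance profile on the polynomial basis
#' \code{T = [t^0, t^1, ..., t^degree]}, with the state pseudotime rescaled
#' to [0, 1] for conditioning. The coefficients summarize the whole profile
#' in \code{degree + 1} numbers, one vector per sample, for the group test.
#'
#' @param abundance per-state abundance vector, or a states-by-samples
#'   matrix (one fit per column).
#' @param statePseudotime coordinate per state.
#' @param degree polynomial degree (>= 1).
#' @return A list with \code{coefficients} (a \code{degree + 1} vector, or
#'   matrix with one column per sample), \code{design} (the T matrix) and
#'   \code{degree}.
#' @export
fitPolynomialProfile <- function(abundance, statePseudotime, degree = 2) {
    if (degree < 1) stop("degree must be at least 1")
    B <- if (is.null(dim(abundance))) matrix(abundance, ncol = 1)
         else as.matrix(abundance)
    m <- nrow(B)
    if (m <= degree + 1)
        stop("need more states than polynomial coefficients")
    t <- as.numeric(statePseudotime)
    if (length(t) != m) stop("statePseudotime must match the number of states")
    rng <- range(t)
    t01 <- if (rng[2] > rng[1]) (t - rng[1]) / (rng[2] - rng[1]) else t
    T <- outer(t01, 0:degree, "^")
    TtT <- crossprod(T)
    b <- tryCatch(solve(TtT, crossprod(T, B)),
                  error = function(e)
                      stop("singular polynomial design; try a lower degree"))
    coef <- if (ncol(B) == 1L) drop(b) else b
    list(coefficients = coef, design = T, degree = degree)
}

#' Pillai-trace MANOVA on polynomial profile coefficients
#'
#' Tests whether any polynomial coefficient of the abundance profile differs
#' among groups. With per-sample coefficient vectors \code{b} (dimension k),
#' the hypothesis SSCP \code{H} sums \code{n_j} times the outer products of
#' group-mean deviations from the grand mean, the error SSCP \code{E} sums
#' within-group deviations, and the Pillai trace is
#' \code{tr(H (H + E)^-1)}. The F approximation uses
#' \code{s = min(g - 1, k)}, \code{m = (|k - (g - 1)| - 1)/2},
#' \code{u = (N - k - g - 1)/2}, with
#' \code{F = Pillai (2u + s + 1) / ((s - Pillai)(2m + s + 1))} on
#' \code{s(2m + s + 1)} and \code{s(2u + s + 1)} degrees of freedom.
#'
#' @param profiles coefficients matrix, one column per sample (k-by-N).
#' @param groups group labels, length N, at least 2 groups of size >= 2.
#' @return A \linkS4class{ManovaProResult}.
#' @export
manovaPro <- function(profiles, groups) {
    B <- as.matrix(profiles)
    k <- nrow(B); N <- ncol(B)
    groups <- as.factor(groups)
    if (length(groups) != N) stop("groups must label every sample")
    nj <- table(groups)
    g <- length(nj)
    if (g < 2) stop("at least 2 groups are required")
    if (any(nj < 2)) stop("every group needs at least 2 samples")
    if (N <= k + g + 1)
        stop("too few samples for the F approximation (need N > k + g + 1)")
    grand <- rowMeans(B)
    H <- matrix(0, k, k); E <- matrix(0, k, k)
    for (lv in levels(groups)) {
        Bj <- B[, groups == lv, drop = FALSE]
        mj <- rowMeans(Bj)
        H <- H + ncol(Bj) * tcrossprod(mj - grand)
        E <- E + tcrossprod(sweep(Bj, 1L, mj))
    }
    if (sum(abs(H)) == 0) {
        pillai <- 0
    } else {
        HE <- H + E
        inv <- tryCatch(solve(HE), error = function(e)
            stop("singular H + E matrix; profiles are degenerate"))
        pillai <- sum(diag(H %*% inv))
    }
    s <- min(g - 1, k)
    mM <- (abs(k - (g - 1)) - 1) / 2
    u <- (N - k - g - 1) / 2
    Fstat <- pillai * (2 * u + s + 1) / ((s - pillai) * (2 * mM + s + 1))
    df1 <- s * (2 * mM + s + 1)
    df2 <- s * (2 * u + s + 1)
    p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
    new("ManovaProResult", H = H, E = E, pillai = pillai,
        s = s, m = mM, u = u, Fstat = Fstat, df1 = df1, df2 = df2,
        pParametric = p, pEmpirical = NA_real_, nPerm = NA_real_)
}

#' Parametric group test on an AbundanceSet
#'
#' Fits a polynomial profile to each sample's normalized abundance and runs
#' \code{\link{manovaPro}} on the coefficients. Note that the parametric
#' p-value can be inflated when abundance estimates are correlated across
#' samples; use \code{\link{permutationGroupTest}} for a calibrated test.
#'
#' @param abund an \linkS4class{AbundanceSet}.
#' @param groups group labels per sample.
#' @param degree polynomial degree.
#' @param type which abundance estimates to profile. The unconstrained
#'   estimates (\code{"smoothed"} or \code{"raw"}) are the intended input:
#'   unit-sum normalized profiles satisfy an exact affine constraint on the
#'   polynomial coefficients (the intercept makes residuals sum to zero),
#'   which degenerates the SSCP matrices.
#' @return A \linkS4class{ManovaProResult}.
#' @export
groupTest <- function(abund, groups, degree = 2,
                      type = c("smoothed", "raw", "normalized")) {
    stopifnot(is(abund, "AbundanceSet"))
    type <- match.arg(type)
    prof <- fitPolynomialProfile(abundances(abund, type),
                                 statePseudotime(abund), degree = degree)
    manovaPro(prof$coefficients, groups)
}

#' Permutation group test with signature-gene shuffling
#'
#' Runs the full deconvolution pipeline, computes the MANOVA-Pro F across
#' groups, and calibrates it by permutation: each permutation shuffles the
#' signature-gene labels of the reference (a joint row permutation of the
#' fixed and random designs, breaking gene-to-gene correspondence with the
#' bulk while preserving the correlation structure that inflates the
#' parametric test), re-runs the deconvolution for every sample, and
#' recomputes F. The empirical p-value uses the add-one convention
#' \code{(1 + #(F_perm >= F_obs)) / (1 + nPerm)}. Setting
#' \code{shuffle = "labels"} permutes group labels instead.
#'
#' @inheritParams deconvolve
#' @param groups group labels per bulk sample.
#' @param nPerm number of permutations (paper default 1000).
#' @param seed RNG seed; the test is deterministic given it.
#' @param degree polynomial degree for the profile fit.
#' @param shuffle \code{"genes"} (signature-gene shuffling) or
#'   \code{"labels"} (group-label permutation).
#' @return A \linkS4class{ManovaProResult} carrying both the parametric and
#'   the empirical p-value.
#' @export
permutationGroupTest <- function(bulk, ref, groups, nPerm = 1000, seed = 1,
                                 degree = 2, shuffle = c("genes", "labels"),
                                 mStates = 50, nSignature = 500,
                                 minGeneFrac = 0.10,
                                 thetaGrid = seq(0, 0.95, by = 0.05),
                                 bandwidth = "auto",
                                 smoothMethod = c("loess", "knn", "none"),
                                 span = 0.5, knnQ = NULL,
                                 normalizeUnits = TRUE) {
    shuffle <- match.arg(shuffle)
    smoothMethod <- match.arg(smoothMethod)
    if (nPerm < 1) stop("nPerm must be at least 1")
    bulk <- as.matrix(bulk)
    common <- intersect(rownames(ref), rownames(bulk))
    if (length(common) < 50)
        stop("only ", length(common),
             " genes shared between reference and bulk (>= 50 required)")
    ref <- ref[common, ]
    bulk <- bulk[common, , drop = FALSE]
    if (normalizeUnits) {
        ref <- libSizeNormalize(ref)
        bulk <- libSizeNormalize(bulk)
    }
    ref <- filterGenes(ref, minFrac = minGeneFrac)
    nSig <- min(nSignature, nrow(ref))
    sig <- selectSignatureGenes(ref, nGenes = nSig)
    design <- buildStates(ref, mStates = mStates, signatureGenes = sig)
    weights <- buildTrajectoryWeights(design@cellPseudotime,
                                      bandwidth = bandwidth)
    Y <- bulk[sig, , drop = FALSE]
    stateT <- design@statePseudotime

    runF <- function(X, C, Z, grp) {
        core <- .deconvolveCore(Y, X, C, Z, weights, stateT, thetaGrid,
                                smoothMethod, span, knnQ)
        prof <- fitPolynomialProfile(core$smoothed, stateT, degree = degree)
        manovaPro(prof$coefficients, grp)
    }
    obs <- runF(design@X, design@C, design@Z, groups)
    set.seed(seed)
    n <- length(sig)
    exceed <- 0L
    for (b in seq_len(nPerm)) {
        if (shuffle == "genes") {
            perm <- sample.int(n)
            resB <- runF(design@X[perm, , drop = FALSE],
                         design@C[perm, , drop = FALSE],
                         design@Z[perm, , drop = FALSE], groups)
        } else {
            resB <- tryCatch(
                runF(design@X, design@C, design@Z, sample(groups)),
                error = function(e) NULL)
            if (is.null(resB)) next
        }
        if (resB@Fstat >= obs@Fstat) exceed <- exceed + 1L
    }
    obs@pEmpirical <- (1 + exceed) / (1 + nPerm)
    obs@nPerm <- nPerm
    obs
}
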