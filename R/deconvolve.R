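#' @include AllClasses.R reml.R lmm-core.R reference-prep.R
NULL

# Shared per-sample engine: null REML fit, GLS per state, boundary LRT,
# smoothing and unit-sum rescaling, for an arbitrary (X, C, Z) design.
.deconvolveCore <- function(Y, X, C, Z, weights, stateT, thetaGrid,
                            smoothMethod, span, knnQ) {
    design <- new(Class = "StateDesign",
                  mStates = ncol(X),
                  stateMembers = as.list(seq_len(ncol(Z))),
                  statePseudotime = stateT,
                  X = X, C = C, Z = Z,
                  signatureGenes = rownames(Z) %||% paste0("g", seq_len(nrow(Z))),
                  cellPseudotime = rep(NA_real_, ncol(Z)),
                  cellIds = colnames(Z) %||% paste0("c", seq_len(ncol(Z))))
    m <- ncol(X); ns <- ncol(Y)
    raw <- se <- sm <- nm <- matrix(NA_real_, m, ns,
                                    dimnames = list(NULL, colnames(Y)))
    theta <- lambda2 <- sigmaE2 <- pRe <- rep(NA_real_, ns)
    gammaHat <- matrix(NA_real_, ncol(C), ns)
    for (j in seq_len(ns)) {
        y <- Y[, j]
        vc <- fitNullREML(y, design, weights, thetaGrid = thetaGrid)
        est <- estimateStateAbundances(y, design, vc)
        raw[, j] <- est$raw
        se[, j] <- est$se
        sm[, j] <- smoothAbundances(est$raw, stateT, method = smoothMethod,
                                    span = span, q = knnQ)
        nm[, j] <- tryCatch(normalizeAbundances(sm[, j]), error = function(e) {
            warning("sample ", j, ": ", conditionMessage(e))
            rep(NA_real_, m)
        })
        theta[j] <- vc@theta; lambda2[j] <- vc@lambda2
        sigmaE2[j] <- vc@sigmaE2; pRe[j] <- testRandomEffect(vc)
        if (ncol(C) > 0L) gammaHat[, j] <- rowMeans(est$gammaHat, na.rm = TRUE)
    }
    list(raw = raw, se = se, smoothed = sm, normalized = nm,
         theta = theta, lambda2 = lambda2, sigmaE2 = sigmaE2,
         pRandomEffect = pRe, gammaHat = gammaHat)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assembleAbundanceSet <- function(core, stateT, params) {
    se <- SummarizedExperiment(
        assays = list(raw = core$raw, se = core$se,
                      smoothed = core$smoothed, normalized = core$normalized),
        rowData = DataFrame(state = seq_along(stateT),
                            statePseudotime = stateT),
        colData = DataFrame(theta = core$theta, lambda2 = core$lambda2,
                            sigmaE2 = core$sigmaE2,
                            pRandomEffect = core$pRandomEffect,
                            row.names = colnames(core$raw)))
    metadata(se)$gammaHat <- core$gammaHat
    metadata(se)$params <- params
    new("AbundanceSet", se)
}

#' Deconvolute cell-state abundances in bulk RNA-seq samples
#'
#' The main entry point. Matches genes between the bulk matrix and the
#' single-cell reference, library-size normalizes both to a common scale,
#' filters rarely expressed genes, selects trajectory-associated signature
#' genes, partitions the focal-type cells into \code{mStates} consecutive
#' states, and, for every bulk sample, fits the null linear mixed model by
#' REML (CAR random-effect covariance over trajectory distance) and plugs
#' the fitted covariance into GLS to estimate each state's abundance. Raw
#' estimates are smoothed over the trajectory and rescaled to a unit-sum
#' profile.
#'
#' @param bulk genes-by-samples matrix (or a single named vector).
#' @param ref a \linkS4class{StateReference}.
#' @param mStates number of consecutive cell states.
#' @param nSignature number of signature genes to select.
#' @param minGeneFrac focal expressed-fraction threshold for
#'   \code{\link{filterGenes}}.
#' @param signatureGenes optional explicit signature gene set (skips
#'   selection).
#' @param thetaGrid grid for the CAR dependence parameter.
#' @param bandwidth trajectory kernel bandwidth (\code{"auto"} or numeric).
#' @param smoothMethod,span,knnQ see \code{\link{smoothAbundances}}.
#' @param normalizeUnits library-size normalize reference and bulk to
#'   counts-per-10k before modeling.
#' @return An \linkS4class{AbundanceSet}.
#' @examples
#' ref <- generateSyntheticReference(nGenes = 300, nCells = 250,
#'                                   nSignature = 60, seed = 1)
#' pb <- synthesizeBulk(ref, shape = "increasing", L = 10, seed = 2)
#' ab <- deconvolve(as.matrix(pb@y), ref, mStates = 10, nSignature = 60,
#'                  smoothMethod = "knn")
#' colSums(abundances(ab))
#' @export
deconvolve <- function(bulk, ref, mStates = 50, nSignature = 500,
                       minGeneFrac = 0.10, signatureGenes = NULL,
                       thetaGrid = seq(0, 0.95, by = 0.05),
                       bandwidth = "auto",
                       smoothMethod = c("loess", "knn", "none"),
                       span = 0.5, knnQ = NULL, normalizeUnits = TRUE) {
    smoothMethod <- match.arg(smoothMethod)
    if (is.null(dim(bulk))) bulk <- matrix(bulk, ncol = 1,
                                           dimnames = list(names(bulk), "bulk"))
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
    if (is.null(signatureGenes)) {
        nSig <- min(nSignature, nrow(ref))
        signatureGenes <- selectSignatureGenes(ref, nGenes = nSig)
    } else {
        signatureGenes <- intersect(signatureGenes, rownames(ref))
        if (length(signatureGenes) < 2L)
            stop("fewer than 2 of the supplied signature genes survive filtering")
    }
    design <- buildStates(ref, mStates = mStates,
                          signatureGenes = signatureGenes)
    weights <- buildTrajectoryWeights(design@cellPseudotime,
                                      bandwidth = bandwidth)
    Y <- bulk[signatureGenes, , drop = FALSE]
    core <- .deconvolveCore(Y, design@X, design@C, design@Z, weights,
                            design@statePseudotime, thetaGrid,
                            smoothMethod, span, knnQ)
    .assembleAbundanceSet(core, design@statePseudotime,
                          params = list(mStates = mStates,
                                        nSignature = length(signatureGenes),
                                        signatureGenes = signatureGenes,
                                        minGeneFrac = minGeneFrac,
                                        thetaGrid = thetaGrid,
                                        bandwidth = weights@bandwidth,
                                        smoothMethod = smoothMethod,
                                        span = span, knnQ = knnQ))
}

#' Binned-ablation deconvolution baselines
#'
#' Reference baselines for the full per-cell mixed model: the trajectory is
#' binned into the same \code{mStates} states, but the non-focal states
#' enter either as fixed effects (all state means fitted jointly by OLS) or
#' as random effects at the bin level (state means as the random-effect
#' design, CAR weights over state pseudotime). Used to quantify what fitting
#' every focal cell individually adds.
#'
#' @inheritParams deconvolve
#' @param effect \code{"fixed"} or \code{"random"} bin ablation.
#' @return An \linkS4class{AbundanceSet}.
#' @export
deconvolveBinned <- function(bulk, ref, mStates = 50, nSignature = 500,
                             minGeneFrac = 0.10, signatureGenes = NULL,
                             effect = c("fixed", "random"),
                             thetaGrid = seq(0, 0.95, by = 0.05),
                             bandwidth = "auto",
                             smoothMethod = c("loess", "knn", "none"),
                             span = 0.5, knnQ = NULL, normalizeUnits = TRUE) {
    effect <- match.arg(effect)
    smoothMethod <- match.arg(smoothMethod)
    if (is.null(dim(bulk))) bulk <- matrix(bulk, ncol = 1,
                                           dimnames = list(names(bulk), "bulk"))
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
    if (is.null(signatureGenes)) {
        nSig <- min(nSignature, nrow(ref))
        signatureGenes <- selectSignatureGenes(ref, nGenes = nSig)
    }
    design <- buildStates(ref, mStates = mStates,
                          signatureGenes = signatureGenes)
    Y <- bulk[signatureGenes, , drop = FALSE]
    m <- design@mStates; ns <- ncol(Y)
    stateT <- design@statePseudotime
    if (effect == "fixed") {
        XC <- cbind(design@X, design@C)
        q <- qr(XC)
        raw <- qr.coef(q, Y)[seq_len(m), , drop = FALSE]
        covd <- chol2inv(qr.R(q))
        sm <- nm <- se <- matrix(NA_real_, m, ns,
                                 dimnames = list(NULL, colnames(Y)))
        res <- Y - XC %*% qr.coef(q, Y)
        s2 <- colSums(res^2) / (nrow(Y) - q$rank)
        for (j in seq_len(ns)) {
            se[, j] <- sqrt(diag(covd)[seq_len(m)] * s2[j])
            sm[, j] <- smoothAbundances(raw[, j], stateT,
                                        method = smoothMethod,
                                        span = span, q = knnQ)
            nm[, j] <- tryCatch(normalizeAbundances(sm[, j]),
                                error = function(e) rep(NA_real_, m))
        }
        core <- list(raw = raw, se = se, smoothed = sm, normalized = nm,
                     theta = rep(NA_real_, ns), lambda2 = rep(NA_real_, ns),
                     sigmaE2 = s2, pRandomEffect = rep(NA_real_, ns),
                     gammaHat = matrix(NA_real_, ncol(design@C), ns))
    } else {
        weights <- buildTrajectoryWeights(stateT, bandwidth = bandwidth)
        core <- .deconvolveCore(Y, design@X, design@C, design@X, weights,
                                stateT, thetaGrid, smoothMethod, span, knnQ)
    }
    .assembleAbundanceSet(core, stateT,
                          params = list(mStates = mStates, effect = effect,
                                        ablation = "binned"))
}
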