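#' @include AllClasses.R
NULL

#' Library-size normalization to a common scale
#'
#' Rescales every column (cell or sample) to a constant total of
#' \code{scale} (counts-per-10k by default), so that reference designs and
#' bulk expression enter the model in commensurate units. No log transform.
#'
#' @param x a genes-by-columns matrix or a \linkS4class{StateReference}.
#' @param scale target column total.
#' @return Object of the same class with rescaled expression.
#' @export
libSizeNormalize <- function(x, scale = 1e4) {
    if (is(x, "StateReference")) {
        a <- assay(x, 1L)
        assay(x, 1L) <- libSizeNormalize(a, scale)
        return(x)
    }
    x <- as.matrix(x)
    cs <- colSums(x)
    if (any(cs <= 0)) stop("columns with zero total expression cannot be normalized")
    sweep(x, 2L, cs / scale, "/")
}

# focal-cell column indices, ordered by (pseudotime, cell id) with stable
# tie-break on cell id
.focalOrder <- function(ref) {
    idx <- which(cellType(ref) == focalType(ref))
    pt <- pseudotime(ref)[idx]
    idx[order(pt, colnames(ref)[idx], method = "radix")]
}

#' Remove genes rarely expressed in the focal cell type
#'
#' Drops genes expressed (value > 0) in fewer than \code{minFrac} of the
#' focal-type cells; such genes carry little trajectory information and
#' destabilize the signature selection. The boundary is inclusive: a gene
#' expressed in exactly \code{minFrac} of cells is retained. Idempotent.
#'
#' @param ref a \linkS4class{StateReference}.
#' @param minFrac minimum expressed fraction in [0, 1).
#' @return The filtered \linkS4class{StateReference}.
#' @export
filterGenes <- function(ref, minFrac = 0.10) {
    stopifnot(is(ref, "StateReference"))
    if (minFrac < 0 || minFrac >= 1)
        stop("minFrac must lie in [0, 1)")
    focal <- cellType(ref) == focalType(ref)
    frac <- rowMeans(assay(ref, 1L)[, focal, drop = FALSE] > 0)
    keep <- frac >= minFrac
    if (!any(keep))
        stop("all genes removed by the expression filter; reference is empty")
    ref[keep, ]
}

#' Select trajectory-associated signature genes
#'
#' Ranks genes by the strength of association between focal-type expression
#' and pseudotime, measured by the F statistic of a natural-cubic-spline
#' regression, and balances the selection along the trajectory: genes passing
#' a BH q < 0.05 association filter are binned by the location of their
#' fitted expression peak into \code{nBins} trajectory segments and picked
#' round-robin across bins in descending F order. If fewer than
#' \code{nGenes} genes pass the filter, the remainder is filled by global F
#' rank. Constant genes are never selected. Deterministic, and invariant to
#' the ordering of cells in the reference.
#'
#' @param ref a \linkS4class{StateReference}, typically after
#'   \code{\link{filterGenes}}.
#' @param nGenes number of signature genes to return.
#' @param nBins number of trajectory segments used for balancing.
#' @param splineDf degrees of freedom of the spline basis.
#' @return Character vector of \code{nGenes} gene identifiers, in descending
#'   order of association F.
#' @export
selectSignatureGenes <- function(ref, nGenes = 500, nBins = 10, splineDf = 4) {
    stopifnot(is(ref, "StateReference"))
    ord <- .focalOrder(ref)
    E <- assay(ref, 1L)[, ord, drop = FALSE]
    t <- pseudotime(ref)[ord]
    k <- length(t)
    if (nGenes > nrow(E))
        stop("nGenes exceeds the number of available genes")
    H <- cbind(1, splines::ns(t, df = splineDf))
    q <- qr(H)
    Yt <- t(E)                                   # cells x genes
    fitted <- qr.fitted(q, Yt)
    rss <- colSums((Yt - fitted)^2)
    tss <- colSums(sweep(Yt, 2L, colMeans(Yt))^2)
    df1 <- splineDf
    df2 <- k - splineDf - 1
    Fstat <- ((tss - rss) / df1) / (rss / df2)
    constant <- tss < .Machine$double.eps * k
    Fstat[constant | !is.finite(Fstat)] <- 0
    pval <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
    pval[constant] <- 1
    if (sum(!constant) < nGenes)
        stop("nGenes exceeds the number of non-constant genes")
    qval <- stats::p.adjust(pval, method = "BH")
    # rescaled peak location of the fitted curve along the trajectory
    t01 <- if (max(t) > min(t)) (t - min(t)) / (max(t) - min(t)) else rep(0.5, k)
    peak <- t01[apply(fitted, 2L, which.max)]
    genes <- rownames(E)
    cand <- which(qval < 0.05 & !constant)
    if (length(cand) <= nGenes) {
        sel <- cand
        pool <- setdiff(which(!constant), cand)
        fill <- pool[order(-Fstat[pool], genes[pool], method = "radix")]
        sel <- c(sel, fill[seq_len(nGenes - length(sel))])
    } else {
        bins <- findInterval(peak[cand], seq(0, 1, length.out = nBins + 1),
                             rightmost.closed = TRUE, all.inside = TRUE)
        byBin <- split(cand[order(-Fstat[cand], genes[cand], method = "radix")],
                       factor(bins, levels = seq_len(nBins)))
        sel <- integer(0)
        while (length(sel) < nGenes) {
            for (b in seq_len(nBins)) {
                if (length(sel) >= nGenes) break
                if (length(byBin[[b]]) == 0L) next
                sel <- c(sel, byBin[[b]][1L])
                byBin[[b]] <- byBin[[b]][-1L]
            }
            if (all(lengths(byBin) == 0L)) break
        }
    }
    sel <- sel[order(-Fstat[sel], genes[sel], method = "radix")]
    genes[sel]
}

#' Partition the trajectory into consecutive cell states
#'
#' Ranks the focal-type cells by pseudotime (ties broken by cell id) and
#' splits them into \code{mStates} contiguous, equal-count bins. Builds the
#' LMM design: \code{X} holds the per-state mean signature profile, \code{Z}
#' the individual focal cells, and \code{C} the per-type mean profile of each
#' other cell type.
#'
#' @param ref a \linkS4class{StateReference}.
#' @param mStates number of consecutive states (>= 2).
#' @param signatureGenes gene identifiers to restrict the designs to.
#' @return A \linkS4class{StateDesign}.
#' @export
buildStates <- function(ref, mStates = 50, signatureGenes) {
    stopifnot(is(ref, "StateReference"))
    mStates <- as.integer(mStates)
    if (mStates < 2L) stop("mStates must be at least 2")
    if (!all(signatureGenes %in% rownames(ref)))
        stop("signature genes absent from the reference")
    ct <- cellType(ref)
    focal <- ct == focalType(ref)
    if (!any(focal)) stop("reference contains no focal-type cells")
    ord <- .focalOrder(ref)
    k <- length(ord)
    if (mStates > k) stop("mStates exceeds the number of focal cells")
    E <- assay(ref, 1L)[signatureGenes, , drop = FALSE]
    Z <- E[, ord, drop = FALSE]
    pt <- pseudotime(ref)[ord]
    sizes <- diff(round(seq(0, k, length.out = mStates + 1)))
    members <- split(seq_len(k), rep(seq_len(mStates), times = sizes))
    X <- vapply(members, function(ix) rowMeans(Z[, ix, drop = FALSE]),
                numeric(nrow(Z)))
    stateT <- vapply(members, function(ix) stats::median(pt[ix]), numeric(1))
    otherTypes <- sort(setdiff(unique(ct), focalType(ref)))
    C <- vapply(otherTypes,
                function(ty) rowMeans(E[, ct == ty, drop = FALSE]),
                numeric(nrow(E)))
    if (length(otherTypes) == 0L)
        C <- matrix(0, nrow(E), 0)
    dim(X) <- c(nrow(Z), mStates)
    dimnames(X) <- list(signatureGenes, paste0("state", seq_len(mStates)))
    new(Class = "StateDesign",
        mStates = mStates,
        stateMembers = unname(members),
        statePseudotime = unname(stateT),
        X = X, C = as.matrix(C), Z = Z,
        signatureGenes = signatureGenes,
        cellPseudotime = pt,
        cellIds = colnames(Z))
}

#' Build CAR trajectory-distance weights
#'
#' Rescales the trajectory coordinates to [0, 1], forms pairwise Euclidean
#' distances, and sets \code{W[i,j] = exp(-(h d_ij)^2)} with zero diagonal.
#' The bandwidth \code{h} calibrates the scale-sensitive Gaussian kernel:
#' with \code{bandwidth = "auto"} it is chosen as
#' \code{sqrt(log 2) / median(d_ij)} so that the median off-diagonal weight
#' is exactly 0.5. \code{D} holds the row sums of \code{W}.
#'
#' @param pt numeric trajectory coordinates (>= 2 values).
#' @param bandwidth \code{"auto"} or a positive number.
#' @return A \linkS4class{TrajectoryWeights}.
#' @export
buildTrajectoryWeights <- function(pt, bandwidth = "auto") {
    pt <- as.numeric(pt)
    k <- length(pt)
    if (k < 2L) stop("at least 2 trajectory coordinates are required")
    rng <- range(pt)
    if (rng[2] > rng[1]) {
        t01 <- (pt - rng[1]) / (rng[2] - rng[1])
    } else {
        warning("all trajectory coordinates identical; weights are all one")
        t01 <- rep(0, k)
    }
    d <- abs(outer(t01, t01, "-"))
    if (identical(bandwidth, "auto")) {
        med <- stats::median(d[upper.tri(d)])
        h <- if (med > 0) sqrt(log(2)) / med else 1
    } else {
        h <- as.numeric(bandwidth)
        if (!is.finite(h) || h <= 0) stop("bandwidth must be positive")
    }
    W <- exp(-(h * d)^2)
    diag(W) <- 0
    new("TrajectoryWeights", W = W, D = rowSums(W), dist = d, bandwidth = h)
}
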