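#' @include AllClasses.R
NULL

#' Cell-state abundance shape functions
#'
#' Maps state coordinates \code{t} in [0, 1] to abundances under one of four
#' pre-designed distributions: monotonically increasing \code{t^k},
#' monotonically decreasing \code{(1 - t)^k}, unimodal
#' \code{[-(t - 0.5)^2 + max((t - 0.5)^2)]^k} (the max over [0, 1] is 0.25),
#' and bimodal \code{sin(3 pi t) - min(sin(3 pi t))} (the min over [0, 1] is
#' -1). The result is normalized to sum to one.
#'
#' @param shape one of \code{"increasing"}, \code{"decreasing"},
#'   \code{"unimodal"}, \code{"bimodal"}.
#' @param L number of uniformly distributed states (used when \code{t} is
#'   not supplied; then \code{t = (l - 0.5)/L}).
#' @param k curvature exponent (> 0).
#' @param t optional explicit state coordinates in [0, 1].
#' @return Numeric abundance vector summing to one, with the coordinates as
#'   the \code{"t"} attribute.
#' @examples
#' a <- shapeAbundance("bimodal", L = 12)
#' sum(a)
#' @export
shapeAbundance <- function(shape = c("increasing", "decreasing",
                                     "unimodal", "bimodal"),
                           L = 50, k = 1, t = NULL) {
    shape <- match.arg(shape)
    if (k <= 0) stop("curvature k must be positive")
    if (is.null(t)) {
        if (L < 2) stop("L must be at least 2")
        t <- (seq_len(L) - 0.5) / L
    }
    f <- shapeFunction(shape, k)(t)
    a <- f / sum(f)
    attr(a, "t") <- t
    a
}

#' Raw (pre-normalization) shape mapping function
#'
#' Returns \code{f(t)} for a shape as a function, without the unit-sum
#' normalization; useful for checking the shape formulas pointwise.
#'
#' @inheritParams shapeAbundance
#' @return A function of \code{t}.
#' @export
shapeFunction <- function(shape = c("increasing", "decreasing",
                                    "unimodal", "bimodal"), k = 1) {
    shape <- match.arg(shape)
    switch(shape,
        increasing = function(t) t^k,
        decreasing = function(t) (1 - t)^k,
        unimodal   = function(t) (-(t - 0.5)^2 + 0.25)^k,
        bimodal    = function(t) sin(3 * pi * t) + 1)
}

# half-up rounding; base round() is banker's
.roundHalfUp <- function(x) floor(x + 0.5)

#' Number of cells implied by the mixture rule
#'
#' The smallest integer n with \code{n * a_l >= 1} for every non-zero state
#' abundance, guaranteeing at least one sampled cell per non-empty state.
#'
#' @param a state abundance vector (sums to one).
#' @return Integer n.
#' @export
mixtureSize <- function(a) {
    a <- a[a > 0]
    if (length(a) == 0L) stop("all abundances are zero")
    as.integer(ceiling(1 / min(a)))
}

#' Synthesize a pseudo-bulk mixture with known state abundances
#'
#' Bins the focal-type source cells into \code{L} uniform (equal-count)
#' states by pseudotime, assigns each state an abundance from the shape
#' function evaluated at the median trajectory rank of its members, sets
#' \code{n} to the smallest integer with \code{n * a_l >= 1} for every
#' non-zero abundance, draws \code{round(n * a_l)} cells (half-up, with
#' replacement) from each state, averages their expression profiles, and
#' applies multiplicative log-normal noise \code{exp(N(0, noiseSd^2))} per
#' gene to mimic batch differences between single-cell and bulk data.
#'
#' @param ref source \linkS4class{StateReference}.
#' @param shape,k shape of the planted abundance distribution.
#' @param L number of states.
#' @param noiseSd standard deviation of the log-normal noise on the natural
#'   log scale (0 disables noise).
#' @param seed optional RNG seed.
#' @param nInflate multiplier on the mixture-rule n (1 for the rule itself;
#'   larger values shrink the sampling variance, e.g. for convergence
#'   checks).
#' @return A \linkS4class{PseudoBulk}.
#' @export
synthesizeBulk <- function(ref, shape = "increasing", k = 1, L = 50,
                           noiseSd = 0.2, seed = NULL, nInflate = 1) {
    stopifnot(is(ref, "StateReference"))
    if (!is.null(seed)) set.seed(seed)
    ord <- .focalOrder(ref)
    kc <- length(ord)
    if (L > kc)
        stop("L exceeds the number of focal source cells; state ",
             kc + 1, " would be empty")
    sizes <- diff(round(seq(0, kc, length.out = L + 1)))
    members <- split(seq_len(kc), rep(seq_len(L), times = sizes))
    empty <- which(lengths(members) == 0L)
    ranks <- seq_len(kc)
    tl <- vapply(members, function(ix)
        (stats::median(ranks[ix]) - 0.5) / kc, numeric(1))
    a <- shapeAbundance(shape, k = k, t = tl)
    if (any(a[empty] > 0))
        stop("state(s) ", paste(empty, collapse = ", "),
             " required by the abundance distribution but empty in source")
    n <- as.integer(mixtureSize(a) * nInflate)
    counts <- .roundHalfUp(n * a)
    counts[a == 0] <- 0L
    E <- assay(ref, 1L)[, ord, drop = FALSE]
    draws <- vector("list", L)
    for (l in seq_len(L)) {
        if (counts[l] == 0L) { draws[[l]] <- integer(0); next }
        draws[[l]] <- sample(members[[l]], counts[l], replace = TRUE)
    }
    drawn <- unlist(draws)
    y <- rowSums(E[, drawn, drop = FALSE]) / length(drawn)
    if (noiseSd > 0)
        y <- y * exp(stats::rnorm(length(y), 0, noiseSd))
    new("PseudoBulk",
        y = y, truth = as.numeric(a), statePseudotime = unname(tl),
        nCellsSampled = n, draws = draws,
        seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

#' Generate a trajectory-structured synthetic single-cell reference
#'
#' Builds a counts matrix with a focal cell type whose cells carry a latent
#' pseudotime ~ U(0, 1) and planted signature genes whose mean expression
#' follows smooth curves over pseudotime (an even mixture of increasing,
#' decreasing and peaked profiles, with peak centers spread along the
#' trajectory), plus other cell types with distinct mean profiles.
#' Counts are negative-binomial (moderate overdispersion, \code{size = 2}
#' by default, typical of UMI data). Fully deterministic given the seed.
#'
#' @param nGenes,nCells total dimensions.
#' @param nTypes number of cell types (1 focal + nTypes - 1 others).
#' @param nSignature number of planted trajectory-associated genes.
#' @param focalFrac fraction of cells in the focal type.
#' @param nbSize negative-binomial size (dispersion) parameter.
#' @param seed RNG seed.
#' @return A \linkS4class{StateReference} of counts; the planted gene ids
#'   are in \code{metadata()$plantedSignature}.
#' @export
generateSyntheticReference <- function(nGenes = 1000, nCells = 1200,
                                       nTypes = 3, nSignature = 300,
                                       focalFrac = 0.6, nbSize = 2,
                                       seed = 1) {
    if (nSignature > nGenes) stop("nSignature exceeds nGenes")
    if (nTypes < 1) stop("nTypes must be at least 1")
    kFocal <- round(nCells * focalFrac)
    if (kFocal < 2 || (nTypes > 1 && nCells - kFocal < nTypes - 1))
        stop("impossible cell-type dimensions")
    set.seed(seed)
    geneIds <- sprintf("gene%04d", seq_len(nGenes))
    baseMean <- exp(stats::rnorm(nGenes, mean = 1, sd = 1))
    sig <- sort(sample.int(nGenes, nSignature))
    profType <- rep_len(c("inc", "dec", "peak"), nSignature)
    centers <- seq(0.05, 0.95, length.out = nSignature)  # spread peaks
    # log-fold trajectory profile per planted gene
    lfc <- function(g, t) {
        i <- match(g, sig)
        switch(profType[i],
               inc  = 3 * (t - 0.5),
               dec  = -3 * (t - 0.5),
               peak = 2.5 * exp(-(t - centers[i])^2 / (2 * 0.1^2)) - 1)
    }
    nOther <- if (nTypes > 1) nCells - kFocal else 0
    typeOf <- c(rep("Focal", kFocal),
                if (nTypes > 1)
                    paste0("Other", rep_len(seq_len(nTypes - 1), nOther)))
    pt <- c(stats::runif(kFocal), rep(NA_real_, nOther))
    counts <- matrix(0L, nGenes, nCells)
    mu <- matrix(rep(baseMean, nCells), nGenes, nCells)
    for (g in seq_along(sig))
        mu[sig[g], seq_len(kFocal)] <-
            baseMean[sig[g]] * exp(lfc(sig[g], pt[seq_len(kFocal)]))
    if (nTypes > 1) {
        for (ty in seq_len(nTypes - 1)) {
            cols <- which(typeOf == paste0("Other", ty))
            de <- sample.int(nGenes, round(0.2 * nGenes))
            shift <- exp(stats::rnorm(length(de), 0, 1.5))
            mu[de, cols] <- mu[de, cols] * shift
        }
    }
    counts[] <- stats::rnbinom(length(mu), mu = mu, size = nbSize)
    rownames(counts) <- geneIds
    ref <- StateReference(counts, cellType = typeOf, pseudotime = pt,
                          focalType = "Focal",
                          cellIds = sprintf("cell%04d", seq_len(nCells)))
    metadata(ref)$plantedSignature <- geneIds[sig]
    ref
}

#' Deconvolution accuracy metrics
#'
#' Concordance correlation coefficient (population moments:
#' \code{2 cov / (var_x + var_y + (mean_x - mean_y)^2)}), Pearson's
#' correlation, and root mean square deviation between an estimated and a
#' true abundance profile. When both inputs have zero variance the
#' correlation-based metrics are undefined and returned as \code{NA}.
#'
#' @param estimate,truth numeric vectors of equal length (>= 2).
#' @return List with elements \code{ccc}, \code{r}, \code{rmsd}.
#' @examples
#' evaluateAccuracy(c(2, 3, 4), c(1, 2, 3))  # ccc 4/7, r 1, rmsd 1
#' @export
evaluateAccuracy <- function(estimate, truth) {
    estimate <- as.numeric(estimate); truth <- as.numeric(truth)
    if (length(estimate) != length(truth) || length(truth) < 2)
        stop("estimate and truth must have equal length >= 2")
    ok <- !is.na(estimate) & !is.na(truth)
    x <- estimate[ok]; y <- truth[ok]
    n <- length(x)
    rmsd <- sqrt(mean((x - y)^2))
    vx <- mean((x - mean(x))^2); vy <- mean((y - mean(y))^2)
    if (vx == 0 && vy == 0)
        return(list(ccc = NA_real_, r = NA_real_, rmsd = rmsd))
    cxy <- mean((x - mean(x)) * (y - mean(y)))
    ccc <- 2 * cxy / (vx + vy + (mean(x) - mean(y))^2)
    r <- if (vx == 0 || vy == 0) NA_real_ else cxy / sqrt(vx * vy)
    list(ccc = ccc, r = r, rmsd = rmsd)
}
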