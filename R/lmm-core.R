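#' @include AllClasses.R
NULL

#' Estimate per-state abundances by GLS with the null covariance
#'
#' For each focal state i the fixed design is \code{[x_i, C]} and the
#' estimate is the generalized least squares solution
#' \code{([x_i C]' V^-1 [x_i C])^-1 [x_i C]' V^-1 y} with \code{V} held at
#' its null REML estimate. \code{V} is Cholesky-factorized once and the
#' factorization reused across all states; the explicit inverse is never
#' formed. Standard errors come from the GLS covariance. A state whose
#' normal matrix is singular (e.g. \code{x_i} collinear with \code{C})
#' yields \code{NA} with a warning rather than a global failure.
#'
#' @param y bulk expression vector over the signature genes.
#' @param design a \linkS4class{StateDesign}.
#' @param vc a \linkS4class{VarianceComponents} fitted on the same genes.
#' @return A list with \code{raw} (per-state estimates), \code{se},
#'   and \code{gammaHat} (covariate effects, one column per state).
#' @export
estimateStateAbundances <- function(y, design, vc) {
    stopifnot(is(vc, "VarianceComponents"))
    y <- as.numeric(y)
    X <- design@X; C <- design@C
    m <- design@mStates; p <- ncol(C)
    R <- chol(vc@V)
    ty <- backsolve(R, y, transpose = TRUE)
    tX <- backsolve(R, X, transpose = TRUE)
    tC <- if (p > 0L) backsolve(R, C, transpose = TRUE)
          else matrix(0, length(y), 0)
    raw <- se <- rep(NA_real_, m)
    gammaHat <- matrix(NA_real_, p, m)
    bad <- 0L
    for (i in seq_len(m)) {
        Xi <- cbind(tX[, i], tC)
        q <- qr(Xi)
        if (q$rank < ncol(Xi)) { bad <- bad + 1L; next }
        coef <- qr.coef(q, ty)
        covb <- chol2inv(qr.R(q))
        raw[i] <- coef[1L]
        se[i] <- sqrt(covb[1L, 1L])
        if (p > 0L) gammaHat[, i] <- coef[-1L]
    }
    if (bad > 0L)
        warning(bad, " state(s) had a singular GLS design; estimates set to NA")
    list(raw = raw, se = se, gammaHat = gammaHat)
}

#' Smooth a per-state abundance profile
#'
#' Reduces the sampling variance of the raw per-state estimates using the
#' neighboring states: \code{"loess"} fits a local quadratic over the state
#' pseudotime with the given span, \code{"knn"} replaces each state by the
#' symmetric average of its \code{q} nearest states (including itself),
#' \code{"none"} is the identity.
#'
#' @param raw per-state values.
#' @param statePseudotime coordinate per state.
#' @param method one of \code{"loess"}, \code{"knn"}, \code{"none"}.
#' @param span loess span in (0, 1].
#' @param q neighborhood size for knn; default \code{max(3, m/10)}.
#' @return Smoothed vector of the same length.
#' @export
smoothAbundances <- function(raw, statePseudotime,
                             method = c("loess", "knn", "none"),
                             span = 0.5, q = NULL) {
    method <- match.arg(method)
    m <- length(raw)
    if (method == "none") return(raw)
    if (length(statePseudotime) != m)
        stop("statePseudotime must match the number of states")
    ok <- !is.na(raw)
    if (method == "loess") {
        if (!is.numeric(span) || span <= 0 || span > 1)
            stop("span must lie in (0, 1]")
        t <- statePseudotime
        fit <- stats::loess(raw[ok] ~ t[ok], span = span, degree = 2,
                            surface = "direct",
                            control = stats::loess.control(statistics = "none"))
        out <- rep(NA_real_, m)
        out[ok] <- stats::predict(fit, newdata = t[ok])
        return(out)
    }
    if (is.null(q)) q <- max(3L, round(m / 10))
    q <- as.integer(q)
    if (q < 1L || q > m) stop("q must lie in [1, number of states]")
    out <- rep(NA_real_, m)
    for (i in which(ok)) {
        d <- abs(statePseudotime - statePseudotime[i])
        d[!ok] <- Inf
        nb <- order(d, seq_len(m))[seq_len(min(q, sum(ok)))]
        out[i] <- mean(raw[nb])
    }
    out
}

#' Rescale raw abundances to a unit-sum profile
#'
#' The unconstrained GLS estimates are made interpretable by rescaling to
#' [0, 1] and a unit sum. Because the per-state estimates measure each
#' state's contribution against the CAR-smooth background, a profile can
#' carry a common negative offset; the default \code{"minmax"} mode removes
#' it by shifting the minimum to zero ((x - min)/(max - min)) before
#' dividing by the total, preserving the relative shape. The
#' \code{"truncate"} mode instead clips negatives at zero and divides by the
#' sum, discarding sub-background structure. Both return values in [0, 1]
#' summing to one.
#'
#' @param raw per-state values.
#' @param method \code{"minmax"} or \code{"truncate"}.
#' @return Normalized vector.
#' @examples
#' normalizeAbundances(c(-1, 1, 3), method = "truncate")  # 0, 0.25, 0.75
#' @export
normalizeAbundances <- function(raw, method = c("minmax", "truncate")) {
    method <- match.arg(method)
    if (all(is.na(raw))) stop("degenerate profile: all values missing")
    if (method == "truncate") {
        x <- pmax(raw, 0)
    } else {
        rng <- range(raw, na.rm = TRUE)
        if (rng[2] > rng[1]) {
            x <- (raw - rng[1]) / (rng[2] - rng[1])
        } else if (rng[1] > 0) {
            x <- rep(1, length(raw))            # constant positive profile
        } else {
            stop("degenerate profile: constant non-positive values")
        }
    }
    s <- sum(x, na.rm = TRUE)
    if (!is.finite(s) || s <= 0)
        stop("degenerate profile: no positive abundance after truncation")
    x / s
}
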