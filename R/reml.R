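#' @include AllClasses.R
NULL

# Rank-k representation of K = Z (D - theta W)^-1 Z' for one theta:
# chol(D - theta W) = R (upper), B = Z R^-1, svd(B) -> K = U diag(s2) U'.
# Returns NULL when (D - theta W) is not positive definite.
.carPieces <- function(theta, weights, Z) {
    M <- diag(weights@D) - theta * weights@W
    R <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    B <- t(backsolve(R, t(Z), transpose = TRUE))
    sv <- svd(B, nu = min(dim(B)), nv = 0)
    list(U = sv$u, s2 = sv$d^2)
}

# Profiled restricted log-likelihood at variance ratio phi = lambda2/sigmaE2,
# with sigmaE2 concentrated out analytically. Returns the attained restricted
# log-likelihood and the implied sigmaE2. All quantities live in the rank-r
# eigenbasis of K, so each evaluation is O(r p + p^3).
.remlProfile <- function(phi, pre) {
    d <- 1 + phi * pre$s2                       # eigenvalues of Vr on range(U)
    n <- pre$n; p <- pre$p
    ldVr <- sum(log(d))
    yVy <- sum(pre$uy^2 / d) + pre$yres         # y' Vr^-1 y
    if (p > 0L) {
        CVC <- crossprod(pre$uc / d, pre$uc) + pre$Cres
        CVy <- crossprod(pre$uc, pre$uy / d) + pre$cyres
        cA <- tryCatch(chol(CVC), error = function(e) NULL)
        if (is.null(cA)) return(list(ll = -Inf, sigmaE2 = NA_real_))
        ldA <- 2 * sum(log(diag(cA)))
        quad <- yVy - sum(backsolve(cA, CVy, transpose = TRUE)^2)
    } else {
        ldA <- 0
        quad <- yVy
    }
    if (quad <= 0) return(list(ll = -Inf, sigmaE2 = NA_real_))
    sigmaE2 <- quad / (n - p)
    ll <- -0.5 * ((n - p) * (log(2 * pi) + 1 + log(sigmaE2)) + ldVr + ldA)
    list(ll = ll, sigmaE2 = sigmaE2)
}

# Precompute the data projections used by .remlProfile for one theta.
.remlPre <- function(pieces, y, C) {
    U <- pieces$U
    n <- length(y); p <- ncol(C)
    uy <- drop(crossprod(U, y))
    yres <- max(sum(y^2) - sum(uy^2), 0)        # complement of range(U)
    if (p > 0L) {
        uc <- crossprod(U, C)
        Cres <- crossprod(C) - crossprod(uc)
        cyres <- crossprod(C, y) - crossprod(uc, uy)
    } else {
        uc <- matrix(0, length(uy), 0); Cres <- matrix(0, 0, 0)
        cyres <- matrix(0, 0, 1)
    }
    list(U = U, s2 = pieces$s2, uy = uy, uc = uc, yres = yres,
         Cres = Cres, cyres = cyres, n = n, p = p)
}

#' Fit the null linear mixed model by REML
#'
#' Fits the null model (all focal-state fixed effects dropped)
#' \code{y ~ N(C gamma, Z (D - theta W)^-1 lambda2 Z' + I sigmaE2)} by
#' restricted maximum likelihood. The CAR dependence parameter \code{theta}
#' is profiled over a grid on [0, 1) (where \code{D - theta W} is guaranteed
#' positive definite); at each grid point the variance ratio
#' \code{lambda2/sigmaE2} is optimized on the restricted likelihood with
#' \code{sigmaE2} concentrated out analytically, including the
#' \code{lambda2 = 0} boundary. The fitted covariance \code{V} is the one
#' plugged into GLS for every focal state, so the expensive variance
#' estimation happens once per sample.
#'
#' @param y bulk expression vector over the signature genes.
#' @param design a \linkS4class{StateDesign}.
#' @param weights a \linkS4class{TrajectoryWeights} over \code{design}'s
#'   random-effect cells.
#' @param thetaGrid grid of CAR dependence values in [0, 1).
#' @return A \linkS4class{VarianceComponents}.
#' @export
fitNullREML <- function(y, design, weights,
                        thetaGrid = seq(0, 0.95, by = 0.05)) {
    y <- as.numeric(y)
    Z <- design@Z
    C <- design@C
    n <- length(y)
    if (n != nrow(Z)) stop("y must have one value per signature gene")
    if (any(thetaGrid < 0 | thetaGrid >= 1))
        stop("thetaGrid must lie in [0, 1)")
    p <- ncol(C)

    best <- list(ll = -Inf)
    failures <- character()
    for (theta in thetaGrid) {
        pieces <- .carPieces(theta, weights, Z)
        if (is.null(pieces)) {
            failures <- c(failures, sprintf("theta=%.3g not PD", theta))
            next
        }
        pre <- .remlPre(pieces, y, C)
        kbar <- mean(pre$s2[pre$s2 > 0])
        if (!is.finite(kbar) || kbar <= 0) kbar <- 1
        f <- function(logphi) -.remlProfile(exp(logphi), pre)$ll
        opt <- tryCatch(
            stats::optimize(f, interval = log(1 / kbar) + c(-14, 14)),
            error = function(e) NULL)
        cand <- list()
        if (!is.null(opt))
            cand <- c(cand, list(c(phi = exp(opt$minimum), ll = -opt$objective)))
        at0 <- .remlProfile(0, pre)
        cand <- c(cand, list(c(phi = 0, ll = at0$ll)))
        for (cc in cand) {
            if (is.finite(cc["ll"]) && cc["ll"] > best$ll) {
                prof <- .remlProfile(cc["phi"], pre)
                best <- list(ll = prof$ll, theta = theta, phi = cc[["phi"]],
                             sigmaE2 = prof$sigmaE2, pre = pre)
            }
        }
    }
    if (!is.finite(best$ll))
        stop("REML failed at every theta grid point: ",
             paste(failures, collapse = "; "))
    lambda2 <- best$phi * best$sigmaE2
    ll0 <- .remlProfile(0, best$pre)$ll
    U <- best$pre$U
    V <- U %*% (lambda2 * best$pre$s2 * t(U))
    diag(V) <- diag(V) + best$sigmaE2
    new("VarianceComponents",
        theta = best$theta, lambda2 = lambda2, sigmaE2 = best$sigmaE2,
        loglik = best$ll, loglik0 = ll0, V = V)
}

#' Restricted log-likelihood by direct dense computation
#'
#' Evaluates the same restricted likelihood as \code{\link{fitNullREML}} at a
#' given parameter triple via explicit formation of \code{V}, dense solves
#' and determinants. Slow and independent of the fast path; used for
#' verification.
#'
#' @param y,design,weights as in \code{\link{fitNullREML}}.
#' @param theta,lambda2,sigmaE2 the variance parameters.
#' @return The restricted log-likelihood (scalar).
#' @export
remlLogLikDense <- function(y, design, weights, theta, lambda2, sigmaE2) {
    Z <- design@Z; C <- design@C
    n <- length(y); p <- ncol(C)
    M <- diag(weights@D) - theta * weights@W
    V <- Z %*% solve(M, t(Z)) * lambda2
    diag(V) <- diag(V) + sigmaE2
    Vi <- solve(V)
    ldV <- determinant(V, logarithm = TRUE)$modulus
    if (p > 0L) {
        A <- t(C) %*% Vi %*% C
        b <- t(C) %*% Vi %*% y
        ldA <- determinant(A, logarithm = TRUE)$modulus
        quad <- drop(t(y) %*% Vi %*% y - t(b) %*% solve(A, b))
    } else {
        ldA <- 0
        quad <- drop(t(y) %*% Vi %*% y)
    }
    as.numeric(-0.5 * ((n - p) * log(2 * pi) + ldV + ldA + quad))
}

#' Test the CAR random-effect component
#'
#' Likelihood-ratio test of \code{lambda2 = 0} against \code{lambda2 > 0}
#' from the null REML fit. Because the null value lies on the boundary of
#' the parameter space, the statistic is referred to a 50:50 mixture of a
#' point mass at zero and a chi-squared with one degree of freedom:
#' \code{p = 0.5 P(chi2_1 >= LRT)}, which equals 0.5 for LRT = 0.
#'
#' @param vc a \linkS4class{VarianceComponents} from \code{\link{fitNullREML}}.
#' @return The mixture p-value.
#' @export
testRandomEffect <- function(vc) {
    stopifnot(is(vc, "VarianceComponents"))
    lrt <- max(2 * (vc@loglik - vc@loglik0), 0)
    0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
}
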