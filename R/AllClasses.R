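#' @import methods
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   rowData colData assayNames
#' @importFrom S4Vectors metadata metadata<- DataFrame
NULL

#' Single-cell reference with a cell-state trajectory
#'
#' A \linkS4class{SingleCellExperiment} whose \code{colData} carries a
#' \code{cellType} label for every cell and a \code{pseudotime} coordinate for
#' every cell of the focal type (the type being deconvoluted, recorded in
#' \code{metadata(x)$focalType}). Expression values must be non-negative;
#' gene identifiers (rownames) must be unique.
#'
#' @export
setClass("StateReference", contains = "SingleCellExperiment")

setValidity("StateReference", function(object) {
    msg <- character()
    cd <- colData(object)
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "rownames (gene ids) must be present and unique")
    if (!all(c("cellType", "pseudotime") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'cellType' and 'pseudotime'")
    ft <- metadata(object)$focalType
    if (is.null(ft) || length(ft) != 1L)
        msg <- c(msg, "metadata(object)$focalType must be a single type name")
    if (length(msg) == 0L) {
        ct <- as.character(cd$cellType)
        if (!any(ct == ft))
            msg <- c(msg, sprintf("no cells of focal type '%s'", ft))
        if (anyNA(cd$pseudotime[ct == ft]))
            msg <- c(msg, "pseudotime must be defined for every focal cell")
        a <- assay(object, 1L)
        if (min(a) < 0)
            msg <- c(msg, "expression values must be non-negative")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a StateReference
#'
#' @param expr genes-by-cells matrix of non-negative expression values
#'   (counts or library-size-normalized values).
#' @param cellType character/factor of per-cell type labels.
#' @param pseudotime numeric trajectory coordinate per cell; may be \code{NA}
#'   for cells outside the focal type.
#' @param focalType name of the cell type to deconvolute.
#' @param cellIds optional cell identifiers (default: colnames of expr).
#'
#' @return A \linkS4class{StateReference}.
#' @examples
#' ref <- generateSyntheticReference(nGenes = 50, nCells = 60, seed = 1)
#' focalType(ref)
#' @export
StateReference <- function(expr, cellType, pseudotime, focalType,
                           cellIds = colnames(expr)) {
    expr <- as.matrix(expr)
    if (is.null(cellIds)) cellIds <- paste0("cell", seq_len(ncol(expr)))
    colnames(expr) <- cellIds
    sce <- SingleCellExperiment(
        assays = list(expr = expr),
        colData = DataFrame(cellType = as.character(cellType),
                            pseudotime = as.numeric(pseudotime),
                            row.names = cellIds))
    metadata(sce)$focalType <- focalType
    new("StateReference", sce)
}

#' Fixed/random design objects for the state LMM
#'
#' Holds the focal-state signature profiles \code{X} (one column per state,
#' each the mean over the state's member cells), the other-cell-type covariate
#' matrix \code{C}, the random-effect design \code{Z} (one column per
#' individual focal cell, ordered by pseudotime), state membership, and the
#' representative pseudotime per state.
#'
#' @slot mStates number of consecutive states.
#' @slot stateMembers list of member column indices (into \code{Z}) per state.
#' @slot statePseudotime median member pseudotime per state.
#' @slot X signature-genes-by-states profile matrix.
#' @slot C signature-genes-by-other-types covariate matrix (0 columns if the
#'   reference has a single cell type).
#' @slot Z signature-genes-by-cells random-effect design.
#' @slot signatureGenes the gene identifiers indexing the rows.
#' @slot cellPseudotime pseudotime of each \code{Z} column.
#' @slot cellIds identifiers of each \code{Z} column.
#' @export
setClass("StateDesign", slots = c(
    mStates = "integer",
    stateMembers = "list",
    statePseudotime = "numeric",
    X = "matrix",
    C = "matrix",
    Z = "matrix",
    signatureGenes = "character",
    cellPseudotime = "numeric",
    cellIds = "character"))

setValidity("StateDesign", function(object) {
    msg <- character()
    n <- length(object@signatureGenes)
    if (nrow(object@X) != n || nrow(object@Z) != n || nrow(object@C) != n)
        msg <- c(msg, "X, C, Z must all have one row per signature gene")
    if (ncol(object@X) != object@mStates)
        msg <- c(msg, "X must have one column per state")
    memb <- unlist(object@stateMembers)
    if (length(memb) != ncol(object@Z) ||
        !setequal(memb, seq_len(ncol(object@Z))))
        msg <- c(msg, "every focal cell must belong to exactly one state")
    if (length(msg)) msg else TRUE
})

#' Trajectory-distance weight matrices
#'
#' CAR weight structure over the trajectory: \code{W[i,j] = exp(-(h d_ij)^2)}
#' with \code{d_ij} the Euclidean distance between (rescaled) trajectory
#' coordinates and \code{h} the bandwidth; \code{W} is symmetric with zero
#' diagonal and \code{D} holds its row sums.
#'
#' @slot W symmetric zero-diagonal weight matrix.
#' @slot D numeric vector of row sums of \code{W} (the diagonal of the
#'   degree matrix).
#' @slot dist pairwise trajectory distances (after rescaling, before the
#'   bandwidth is applied).
#' @slot bandwidth the bandwidth actually used.
#' @export
setClass("TrajectoryWeights", slots = c(
    W = "matrix", D = "numeric", dist = "matrix", bandwidth = "numeric"))

setValidity("TrajectoryWeights", function(object) {
    msg <- character()
    W <- object@W
    if (!isSymmetric(unname(W), tol = 1e-10)) msg <- c(msg, "W must be symmetric")
    if (any(abs(diag(W)) > 0)) msg <- c(msg, "W must have a zero diagonal")
    if (any(W < 0) || any(W > 1)) msg <- c(msg, "weights must lie in [0, 1]")
    if (any(object@D <= 0)) msg <- c(msg, "row sums D must be positive")
    if (length(msg)) msg else TRUE
})

#' REML variance-component estimates
#'
#' Output of \code{\link{fitNullREML}}: the CAR dependence parameter
#' \code{theta}, random-effect scale \code{lambda2}, residual variance
#' \code{sigmaE2}, the restricted log-likelihood at the optimum, the
#' restricted log-likelihood of the no-random-effect fit (\code{lambda2 = 0},
#' used by the boundary LRT), and the implied covariance
#' \code{V = Z (D - theta W)^-1 lambda2 Z' + I sigmaE2}.
#'
#' @slot theta CAR dependence scalar in [0, 1).
#' @slot lambda2 random-effect scale (>= 0).
#' @slot sigmaE2 residual variance (> 0).
#' @slot loglik restricted log-likelihood at the optimum.
#' @slot loglik0 restricted log-likelihood with lambda2 fixed at 0.
#' @slot V implied n-by-n covariance of the bulk signature vector.
#' @export
setClass("VarianceComponents", slots = c(
    theta = "numeric", lambda2 = "numeric", sigmaE2 = "numeric",
    loglik = "numeric", loglik0 = "numeric", V = "matrix"))

setValidity("VarianceComponents", function(object) {
    msg <- character()
    if (object@lambda2 < 0) msg <- c(msg, "lambda2 must be >= 0")
    if (object@sigmaE2 <= 0) msg <- c(msg, "sigmaE2 must be > 0")
    if (length(msg)) msg else TRUE
})

#' Per-sample, per-state abundance estimates
#'
#' A \linkS4class{SummarizedExperiment} with states as rows and bulk samples
#' as columns, carrying assays \code{raw} (unconstrained GLS estimates),
#' \code{se}, \code{smoothed} and \code{normalized} (truncated at zero and
#' rescaled to sum to one per sample). \code{rowData} records the state index
#' and representative pseudotime; \code{colData} records the per-sample
#' variance components and the random-effect test p-value.
#'
#' @export
setClass("AbundanceSet", contains = "SummarizedExperiment")

setValidity("AbundanceSet", function(object) {
    msg <- character()
    need <- c("raw", "se", "smoothed", "normalized")
    if (!all(need %in% assayNames(object)))
        msg <- c(msg, paste("assays must include", paste(need, collapse = ", ")))
    if (!"statePseudotime" %in% colnames(rowData(object)))
        msg <- c(msg, "rowData must contain 'statePseudotime'")
    if (length(msg) == 0L) {
        nm <- assay(object, "normalized")
        sums <- colSums(nm)
        ok <- is.na(sums) | abs(sums - 1) < 1e-6
        if (!all(ok)) msg <- c(msg, "normalized columns must sum to 1")
        if (min(nm, na.rm = TRUE) < -1e-12)
            msg <- c(msg, "normalized values must be non-negative")
    }
    if (length(msg)) msg else TRUE
})

#' Pseudo-bulk mixture with known state abundances
#'
#' @slot y named gene expression vector (mean over the sampled cells, with
#'   optional multiplicative log-normal noise).
#' @slot truth normalized state abundance vector (sums to one).
#' @slot statePseudotime representative coordinate per state.
#' @slot nCellsSampled the n of the mixture rule: the smallest integer with
#'   \code{n * a_l >= 1} for every non-zero state abundance.
#' @slot draws list of sampled source-cell column indices per state.
#' @slot seed the RNG seed used (NA if none supplied).
#' @export
setClass("PseudoBulk", slots = c(
    y = "numeric", truth = "numeric", statePseudotime = "numeric",
    nCellsSampled = "integer", draws = "list", seed = "numeric"))

#' Pillai-trace MANOVA on polynomial abundance profiles
#'
#' @slot H hypothesis sums-of-squares-and-cross-products matrix.
#' @slot E error SSCP matrix.
#' @slot pillai the Pillai trace.
#' @slot s,m,u auxiliary scalars of the F approximation.
#' @slot Fstat the F statistic.
#' @slot df1,df2 degrees of freedom.
#' @slot pParametric analytic upper-tail F p-value.
#' @slot pEmpirical permutation p-value (NA unless a permutation test ran).
#' @slot nPerm number of permutations behind \code{pEmpirical}.
#' @export
setClass("ManovaProResult", slots = c(
    H = "matrix", E = "matrix", pillai = "numeric",
    s = "numeric", m = "numeric", u = "numeric",
    Fstat = "numeric", df1 = "numeric", df2 = "numeric",
    pParametric = "numeric", pEmpirical = "numeric", nPerm = "numeric"))

#' Fold enrichment against matched control sets
#'
#' @slot fold mean query score divided by the mean of control-set means.
#' @slot variance delta-method sampling variance of the fold.
#' @slot ci95 95\% confidence interval.
#' @slot nControlSets number of control sets drawn.
#' @slot controlMeans the per-set control means.
#' @slot matchedOn record of the matching criteria.
#' @export
setClass("EnrichmentResult", slots = c(
    fold = "numeric", variance = "numeric", ci95 = "numeric",
    nControlSets = "integer", controlMeans = "numeric", matchedOn = "list"))
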