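#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname cellType
#' @export
setMethod("cellType", "StateReference", function(x)
    as.character(colData(x)$cellType))

#' @rdname pseudotime
#' @export
setMethod("pseudotime", "StateReference", function(x)
    colData(x)$pseudotime)

#' @rdname focalType
#' @export
setMethod("focalType", "StateReference", function(x)
    metadata(x)$focalType)

#' @rdname signatureGenes
#' @export
setMethod("signatureGenes", "StateDesign", function(x) x@signatureGenes)

#' @rdname statePseudotime
#' @export
setMethod("statePseudotime", "StateDesign", function(x) x@statePseudotime)

#' @rdname statePseudotime
#' @export
setMethod("statePseudotime", "AbundanceSet", function(x)
    rowData(x)$statePseudotime)

#' @rdname abundances
#' @export
setMethod("abundances", "AbundanceSet", function(x, type = "normalized") {
    type <- match.arg(type, c("normalized", "raw", "se", "smoothed"))
    assay(x, type)
})

setMethod("show", "StateReference", function(object) {
    ct <- cellType(object)
    cat("StateReference:", nrow(object), "genes x", ncol(object), "cells\n")
    cat("  focal type:", focalType(object),
        sprintf("(%d cells on trajectory)\n", sum(ct == focalType(object))))
    cat("  cell types:", paste(unique(ct), collapse = ", "), "\n")
})

setMethod("show", "StateDesign", function(object) {
    cat("StateDesign:", object@mStates, "states,",
        length(object@signatureGenes), "signature genes,",
        ncol(object@Z), "focal cells,",
        ncol(object@C), "covariate cell types\n")
})

setMethod("show", "VarianceComponents", function(object) {
    cat("VarianceComponents (REML):\n")
    cat(sprintf("  theta = %.3f, lambda2 = %.4g, sigmaE2 = %.4g\n",
                object@theta, object@lambda2, object@sigmaE2))
    cat(sprintf("  restricted logLik = %.4f (lambda2=0 fit: %.4f)\n",
                object@loglik, object@loglik0))
})

setMethod("show", "ManovaProResult", function(object) {
    cat("MANOVA-Pro (Pillai trace on polynomial profiles)\n")
    cat(sprintf("  Pillai = %.4f, F(%g, %g) = %.4f, parametric p = %.3g\n",
                object@pillai, object@df1, object@df2, object@Fstat,
                object@pParametric))
    if (!is.na(object@pEmpirical))
        cat(sprintf("  empirical p = %.3g (%d permutations)\n",
                    object@pEmpirical, object@nPerm))
})

setMethod("show", "EnrichmentResult", function(object) {
    cat(sprintf("Fold enrichment = %.3f (95%% CI %.3f-%.3f), %d control sets\n",
                object@fold, object@ci95[1], object@ci95[2],
                object@nControlSets))
})

setMethod("show", "PseudoBulk", function(object) {
    cat("PseudoBulk:", length(object@y), "genes,",
        length(object@truth), "states, n =", object@nCellsSampled,
        "cells sampled\n")
})
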