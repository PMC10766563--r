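#' @include AllClasses.R
NULL

#' Cell-type labels of a reference
#'
#' @param x a \linkS4class{StateReference}.
#' @return A character vector of per-cell type labels.
#' @export
setGeneric("cellType", function(x) standardGeneric("cellType"))

#' Pseudotime coordinates of a reference
#'
#' @param x a \linkS4class{StateReference}.
#' @return Numeric pseudotime per cell; \code{NA} outside the focal type.
#' @export
setGeneric("pseudotime", function(x) standardGeneric("pseudotime"))

#' Focal cell type of a reference
#'
#' @param x a \linkS4class{StateReference}.
#' @return The name of the cell type being deconvoluted.
#' @export
setGeneric("focalType", function(x) standardGeneric("focalType"))

#' Signature genes used by a design
#'
#' @param x a \linkS4class{StateDesign}.
#' @return Character vector of gene identifiers.
#' @export
setGeneric("signatureGenes", function(x) standardGeneric("signatureGenes"))

#' Representative pseudotime per cell state
#'
#' @param x a \linkS4class{StateDesign} or \linkS4class{AbundanceSet}.
#' @return Numeric vector, one coordinate per state.
#' @export
setGeneric("statePseudotime", function(x) standardGeneric("statePseudotime"))

#' Extract abundance estimates
#'
#' @param x an \linkS4class{AbundanceSet}.
#' @param type one of \code{"raw"}, \code{"se"}, \code{"smoothed"},
#'   \code{"normalized"}.
#' @return A states-by-samples numeric matrix.
#' @export
setGeneric("abundances", function(x, type = "normalized")
    standardGeneric("abundances"))
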