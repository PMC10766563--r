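#' @include AllClasses.R
NULL

.readTsvMatrix <- function(path) {
    d <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- as.character(d[[1]])
    storage.mode(m) <- "double"
    if (anyDuplicated(rownames(m))) stop("duplicated ids in ", path)
    m
}

#' Read a single-cell reference with cell metadata
#'
#' The expression input is either a dense tab-separated file (genes in the
#' first column, one column per cell, header row) or a directory holding an
#' MTX triplet (\code{matrix.mtx}, \code{features.tsv}, \code{barcodes.tsv}).
#' The metadata file is tab-separated with required columns \code{cell_id},
#' \code{cell_type} and \code{pseudotime}.
#'
#' @param expr path to the expression TSV or MTX directory.
#' @param metadata path to the cell metadata TSV.
#' @param focalType name of the cell type to deconvolute.
#' @return A \linkS4class{StateReference}.
#' @export
readReference <- function(expr, metadata, focalType) {
    if (dir.exists(expr)) {
        m <- as.matrix(Matrix::readMM(file.path(expr, "matrix.mtx")))
        feats <- utils::read.delim(file.path(expr, "features.tsv"),
                                   header = FALSE)[[1]]
        bars <- utils::read.delim(file.path(expr, "barcodes.tsv"),
                                  header = FALSE)[[1]]
        rownames(m) <- as.character(feats)
        colnames(m) <- as.character(bars)
    } else {
        m <- .readTsvMatrix(expr)
    }
    md <- utils::read.delim(metadata, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("cell_id", "cell_type", "pseudotime")
    miss <- setdiff(need, colnames(md))
    if (length(miss))
        stop("metadata is missing required column(s): ",
             paste(miss, collapse = ", "))
    md <- md[match(colnames(m), md$cell_id), ]
    if (anyNA(md$cell_id))
        stop("metadata does not cover every cell in the expression matrix")
    StateReference(m, cellType = md$cell_type, pseudotime = md$pseudotime,
                   focalType = focalType, cellIds = colnames(m))
}

#' Read a bulk expression matrix
#'
#' Tab-separated, genes in the first column, one column per sample.
#'
#' @param path file path.
#' @return genes-by-samples numeric matrix.
#' @export
readBulk <- function(path) .readTsvMatrix(path)

#' Read sample group labels
#'
#' Tab-separated with columns \code{sample_id} and \code{group}.
#'
#' @param path file path.
#' @return Named character vector of group labels.
#' @export
readGroups <- function(path) {
    d <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    miss <- setdiff(c("sample_id", "group"), colnames(d))
    if (length(miss))
        stop("group file is missing required column(s): ",
             paste(miss, collapse = ", "))
    stats::setNames(as.character(d$group), d$sample_id)
}

#' Read a genotype dosage matrix
#'
#' Either a tab-separated dosage table (variants in the first column, one
#' column per sample, values 0..2) or a VCF (GT or DS fields; requires the
#' vcfR package).
#'
#' @param path file path.
#' @return variants-by-samples dosage matrix.
#' @export
readGenotypes <- function(path) {
    if (grepl("\\.vcf(\\.gz)?$", path)) {
        if (!requireNamespace("vcfR", quietly = TRUE))
            stop("reading VCF requires the vcfR package")
        v <- vcfR::read.vcfR(path, verbose = FALSE)
        ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                       error = function(e) NULL)
        if (is.null(ds) || all(is.na(ds))) {
            gt <- vcfR::extract.gt(v, element = "GT")
            ds <- apply(gt, c(1, 2), function(g) {
                if (is.na(g)) return(NA_real_)
                sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
            })
        }
        ids <- vcfR::getID(v)
        rownames(ds) <- ifelse(is.na(ids) | ids == ".",
                               paste0(vcfR::getCHROM(v), ":", vcfR::getPOS(v)),
                               ids)
        return(ds)
    }
    .readTsvMatrix(path)
}

#' Write an AbundanceSet to tab-separated files
#'
#' Writes one TSV per assay (\code{abundance_raw.tsv},
#' \code{abundance_smoothed.tsv}, \code{abundance_normalized.tsv},
#' \code{abundance_se.tsv}; rows = states with index and pseudotime,
#' columns = samples) and a run log recording the parameters and the
#' per-sample variance components and random-effect p-values.
#'
#' @param abund an \linkS4class{AbundanceSet}.
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
writeAbundanceSet <- function(abund, dir) {
    stopifnot(is(abund, "AbundanceSet"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(0)
    for (a in c("raw", "smoothed", "normalized", "se")) {
        d <- data.frame(state = rowData(abund)$state,
                        state_pseudotime = statePseudotime(abund),
                        assay(abund, a), check.names = FALSE)
        p <- file.path(dir, paste0("abundance_", a, ".tsv"))
        utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
        paths <- c(paths, p)
    }
    log <- file.path(dir, "run_log.txt")
    cd <- colData(abund)
    prm <- metadata(abund)$params
    prm$signatureGenes <- NULL
    lines <- c(
        paste0("package_version\t", as.character(utils::packageVersion("CARDecon"))),
        vapply(names(prm), function(k)
            paste0(k, "\t", paste(format(prm[[k]]), collapse = ",")),
            character(1)),
        "",
        paste(c("sample", "theta", "lambda2", "sigmaE2", "p_random_effect"),
              collapse = "\t"),
        vapply(seq_len(nrow(cd)), function(j)
            paste(c(rownames(cd)[j], format(cd$theta[j]),
                    format(cd$lambda2[j]), format(cd$sigmaE2[j]),
                    format(cd$pRandomEffect[j])), collapse = "\t"),
            character(1)))
    writeLines(lines, log)
    invisible(c(paths, log))
}
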