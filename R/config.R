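#' @include AllClasses.R
NULL

#' Default run configuration
#'
#' Flat key-value configuration for the run wrappers. Every default equals
#' the package default of the corresponding function. Paths are empty until
#' set by the user.
#'
#' @return A named list of class \code{RunConfig}.
#' @export
defaultRunConfig <- function() {
    cfg <- list(
        ref_expr = "",
        ref_metadata = "",
        bulk_expr = "",
        groups = "",
        focal_type = "",
        out_dir = ".",
        m_states = 50,
        n_signature = 500,
        min_gene_fraction = 0.10,
        theta_grid = seq(0, 0.95, by = 0.05),
        bandwidth = "auto",
        smooth_method = "loess",
        smooth_span = 0.5,
        knn_q = NA_real_,
        normalize_units = TRUE,
        degree = 2,
        n_perm = 1000,
        shuffle = "genes",
        maf_min = 0.05,
        cis_window = 1e6,
        fdr_threshold = 0.05,
        n_pcs = 15,
        n_control_sets = 1000,
        noise_sd = 0.2,
        seed = 1)
    class(cfg) <- "RunConfig"
    cfg
}

#' Write a run configuration to a flat key-value file
#'
#' One \code{key = value} pair per line; numeric vectors are
#' comma-separated. Round-trips losslessly through
#' \code{\link{readRunConfig}}.
#'
#' @param config a \code{RunConfig} list.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeRunConfig <- function(config, path) {
    lines <- vapply(names(config), function(k) {
        v <- config[[k]]
        paste0(k, " = ", paste(vapply(v, function(x) {
            if (is.character(x)) x
            else if (is.logical(x)) as.character(x)
            else format(x, digits = 17)
        }, character(1)), collapse = ","))
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read and validate a run configuration
#'
#' Parses a flat key-value file, coercing every value to the type of the
#' corresponding default. Unknown keys are errors (protecting against
#' silent typos).
#'
#' @param path configuration file.
#' @return A validated \code{RunConfig} list.
#' @export
readRunConfig <- function(path) {
    cfg <- defaultRunConfig()
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    for (ln in lines) {
        kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
        if (length(kv) < 2)
            stop("malformed configuration line: ", ln)
        key <- trimws(kv[1])
        val <- trimws(paste(kv[-1], collapse = "="))
        if (!key %in% names(cfg))
            stop("unknown configuration key: ", key)
        proto <- cfg[[key]]
        parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
        cfg[[key]] <- if (is.character(proto)) {
            paste(parts, collapse = ",")
        } else if (is.logical(proto)) {
            as.logical(parts)
        } else {
            num <- suppressWarnings(as.numeric(parts))
            if (any(is.na(num) & parts != "NA"))
                stop("non-numeric value for key ", key, ": ", val)
            num
        }
    }
    cfg
}

#' Run the deconvolution pipeline from a configuration
#'
#' Reads the reference and bulk inputs named in the configuration, runs
#' \code{\link{deconvolve}}, and writes the abundance tables and run log to
#' \code{out_dir}. Deterministic given the configuration.
#'
#' @param config a \code{RunConfig} list or a path to a configuration file.
#' @return The \linkS4class{AbundanceSet}, invisibly; files are written to
#'   \code{config$out_dir}.
#' @export
runDeconvolve <- function(config) {
    if (is.character(config)) config <- readRunConfig(config)
    ref <- readReference(config$ref_expr, config$ref_metadata,
                         config$focal_type)
    bulk <- readBulk(config$bulk_expr)
    set.seed(config$seed)
    ab <- deconvolve(bulk, ref,
                     mStates = config$m_states,
                     nSignature = config$n_signature,
                     minGeneFrac = config$min_gene_fraction,
                     thetaGrid = config$theta_grid,
                     bandwidth = if (config$bandwidth == "auto") "auto"
                                 else as.numeric(config$bandwidth),
                     smoothMethod = config$smooth_method,
                     span = config$smooth_span,
                     knnQ = if (is.na(config$knn_q)) NULL else config$knn_q,
                     normalizeUnits = config$normalize_units)
    writeAbundanceSet(ab, config$out_dir)
    invisible(ab)
}

#' Write a complete synthetic fixture bundle
#'
#' Generates a synthetic reference and pseudo-bulk mixtures under the four
#' abundance shapes, writing an MTX reference (\code{matrix.mtx},
#' \code{features.tsv}, \code{barcodes.tsv}), cell metadata, the bulk
#' matrix, the per-state truth, and the configuration used, to a directory.
#'
#' @param outDir output directory.
#' @param nGenes,nCells,nTypes,nSignature passed to
#'   \code{\link{generateSyntheticReference}}.
#' @param L states for the pseudo-bulk truth.
#' @param nReps pseudo-bulk samples per shape.
#' @param noiseSd log-normal noise level.
#' @param seed RNG seed.
#' @return Invisibly, the output directory.
#' @export
runSimulate <- function(outDir, nGenes = 1000, nCells = 1200, nTypes = 3,
                        nSignature = 300, L = 50, nReps = 5, noiseSd = 0.2,
                        seed = 1) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    ref <- generateSyntheticReference(nGenes = nGenes, nCells = nCells,
                                      nTypes = nTypes,
                                      nSignature = nSignature, seed = seed)
    Matrix::writeMM(Matrix::Matrix(assay(ref, 1L), sparse = TRUE),
                    file.path(outDir, "matrix.mtx"))
    writeLines(rownames(ref), file.path(outDir, "features.tsv"))
    writeLines(colnames(ref), file.path(outDir, "barcodes.tsv"))
    md <- data.frame(cell_id = colnames(ref), cell_type = cellType(ref),
                     pseudotime = pseudotime(ref))
    utils::write.table(md, file.path(outDir, "metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    shapes <- c("increasing", "decreasing", "unimodal", "bimodal")
    bulks <- list(); truths <- list()
    for (si in seq_along(shapes)) for (r in seq_len(nReps)) {
        pb <- synthesizeBulk(ref, shape = shapes[si], L = L,
                             noiseSd = noiseSd,
                             seed = seed + 1000 * si + r)
        nm <- paste0(shapes[si], "_rep", r)
        bulks[[nm]] <- pb@y
        truths[[nm]] <- pb@truth
    }
    bulk <- do.call(cbind, bulks)
    utils::write.table(data.frame(gene_id = rownames(ref), bulk,
                                  check.names = FALSE),
                       file.path(outDir, "bulk.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    truth <- do.call(cbind, truths)
    utils::write.table(data.frame(state = seq_len(L), truth,
                                  check.names = FALSE),
                       file.path(outDir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cfg <- defaultRunConfig()
    cfg$ref_expr <- outDir
    cfg$ref_metadata <- file.path(outDir, "metadata.tsv")
    cfg$bulk_expr <- file.path(outDir, "bulk.tsv")
    cfg$focal_type <- "Focal"
    cfg$noise_sd <- noiseSd
    cfg$seed <- seed
    writeRunConfig(cfg, file.path(outDir, "config.txt"))
    invisible(outDir)
}

#' Run the permutation group test from a configuration
#'
#' Deconvolutes the configured bulk data, tests for group differences in
#' the cell-state abundance profile with MANOVA-Pro, calibrates the p-value
#' by signature-gene-shuffling permutations, and writes a one-row result
#' table (\code{grouptest.tsv}).
#'
#' @param config a \code{RunConfig} list or configuration file path.
#' @return The \linkS4class{ManovaProResult}, invisibly.
#' @export
runGroupTest <- function(config) {
    if (is.character(config)) config <- readRunConfig(config)
    ref <- readReference(config$ref_expr, config$ref_metadata,
                         config$focal_type)
    bulk <- readBulk(config$bulk_expr)
    groups <- readGroups(config$groups)
    groups <- groups[colnames(bulk)]
    res <- permutationGroupTest(bulk, ref, groups,
                                nPerm = config$n_perm, seed = config$seed,
                                degree = config$degree,
                                shuffle = config$shuffle,
                                mStates = config$m_states,
                                nSignature = config$n_signature,
                                minGeneFrac = config$min_gene_fraction,
                                thetaGrid = config$theta_grid,
                                smoothMethod = config$smooth_method,
                                span = config$smooth_span,
                                knnQ = if (is.na(config$knn_q)) NULL
                                       else config$knn_q)
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    d <- data.frame(pillai = res@pillai, F = res@Fstat, df1 = res@df1,
                    df2 = res@df2, p_parametric = res@pParametric,
                    p_empirical = res@pEmpirical, n_perm = res@nPerm)
    utils::write.table(d, file.path(config$out_dir, "grouptest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(res)
}

#' Run csd-eQTL mapping from files
#'
#' Reads expression, genotype dosages, quartile abundances and the
#' coordinate tables, maps cell-state-dependent eQTLs, applies the
#' gene-level correction, and writes \code{csd_eqtl_records.tsv} and
#' \code{csd_egenes.tsv}.
#'
#' @param config a \code{RunConfig} list or configuration file path.
#' @param expression,genotypes,abundance,geneInfo,variantInfo file paths
#'   (expression/genotypes/abundance as TSV matrices; info tables as TSV).
#' @return List with \code{records} and \code{genes}, invisibly.
#' @export
runEqtl <- function(config, expression, genotypes, abundance,
                    geneInfo, variantInfo) {
    if (is.character(config)) config <- readRunConfig(config)
    expr <- .readTsvMatrix(expression)
    geno <- readGenotypes(genotypes)
    ab <- .readTsvMatrix(abundance)
    gi <- utils::read.delim(geneInfo, stringsAsFactors = FALSE)
    vi <- utils::read.delim(variantInfo, stringsAsFactors = FALSE)
    rec <- mapCsdEqtl(expr, geno, ab, gi, vi,
                      nPCs = config$n_pcs, mafMin = config$maf_min,
                      cisWindow = config$cis_window)
    genes <- multipleTesting(rec, fdrThreshold = config$fdr_threshold)
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(rec, file.path(config$out_dir, "csd_eqtl_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(genes, file.path(config$out_dir, "csd_egenes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(list(records = rec, genes = genes))
}

#' Run fold enrichment from score tables
#'
#' Reads query and pool tables (TSV with columns \code{score} and
#' optionally \code{maf}), computes the MAF-matched fold enrichment, and
#' writes \code{enrichment.tsv}.
#'
#' @param config a \code{RunConfig} list or configuration file path.
#' @param query,pool file paths.
#' @return The \linkS4class{EnrichmentResult}, invisibly.
#' @export
runEnrich <- function(config, query, pool) {
    if (is.character(config)) config <- readRunConfig(config)
    q <- utils::read.delim(query, stringsAsFactors = FALSE)
    p <- utils::read.delim(pool, stringsAsFactors = FALSE)
    hasMaf <- all(c("maf") %in% colnames(q)) && "maf" %in% colnames(p)
    res <- foldEnrichment(q$score, p$score,
                          queryMaf = if (hasMaf) q$maf else NULL,
                          poolMaf = if (hasMaf) p$maf else NULL,
                          nSets = config$n_control_sets, seed = config$seed)
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    d <- data.frame(fold = res@fold, variance = res@variance,
                    ci_low = res@ci95[1], ci_high = res@ci95[2],
                    n_control_sets = res@nControlSets)
    utils::write.table(d, file.path(config$out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(res)
}
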