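#' @include AllClasses.R
NULL

#' Rank-based inverse normal transformation
#'
#' Maps values to normal quantiles of their ranks,
#' \code{qnorm((rank - 3/8) / (n + 1/4))} (Blom offset), with average ranks
#' for ties. Used on expression values and state abundances before eQTL
#' mapping to suppress outlier effects.
#'
#' @param values numeric vector (length >= 2, not all identical).
#' @return The transformed vector.
#' @export
inverseNormalTransform <- function(values) {
    x <- as.numeric(values)
    n <- length(x)
    if (n < 2) stop("need at least 2 values")
    if (length(unique(x)) == 1L)
        stop("all values identical; ranks are undefined")
    r <- rank(x, ties.method = "average")
    stats::qnorm((r - 3 / 8) / (n + 1 / 4))
}

#' Per-quartile cell-state abundance
#'
#' Splits the trajectory into four quartiles by state pseudotime and sums
#' the normalized abundance within each, giving the per-sample overall
#' abundance of cells in each trajectory quartile (Q1-Q4).
#'
#' @param abund an \linkS4class{AbundanceSet}.
#' @return A 4-by-samples matrix with rows Q1..Q4.
#' @export
quartileAbundance <- function(abund) {
    stopifnot(is(abund, "AbundanceSet"))
    t <- statePseudotime(abund)
    t01 <- (t - min(t)) / (max(t) - min(t))
    q <- cut(t01, breaks = c(-Inf, 0.25, 0.5, 0.75, Inf),
             labels = paste0("Q", 1:4))
    nm <- abundances(abund, "normalized")
    out <- rowsum(nm, q)
    out[match(paste0("Q", 1:4), rownames(out)), , drop = FALSE]
}

#' Map cell-state-dependent eQTLs
#'
#' For every gene, tests cis variants (within \code{cisWindow} of the TSS,
#' closed interval, same chromosome) with minor allele frequency >=
#' \code{mafMin} under the interaction model
#' \code{y = x a + s b + x s g + covariates + e}, one model per trajectory
#' quartile, where \code{x} is the 0/1/2 minor-allele dosage and \code{s}
#' the quartile abundance. Expression and abundances are rank-based
#' inverse-normal transformed; hidden expression factors are captured by the
#' top principal components of the transformed expression, added to the
#' user covariates. The reported p-value is the two-sided t test on the
#' interaction coefficient.
#'
#' @param expression genes-by-samples matrix.
#' @param genotypes variants-by-samples dosage matrix (0..2).
#' @param stateAbundance quartiles-by-samples abundance matrix (e.g. from
#'   \code{\link{quartileAbundance}}).
#' @param geneInfo data.frame with columns gene_id, chrom, tss.
#' @param variantInfo data.frame with columns variant_id, chrom, pos.
#' @param covariates optional samples-by-covariates matrix.
#' @param nPCs number of expression principal components to add as hidden-
#'   factor covariates (capped by sample count).
#' @param mafMin minor allele frequency threshold.
#' @param cisWindow half-width of the cis window around the TSS (bp).
#' @param applyINT apply the inverse normal transformation (disable only if
#'   inputs are already transformed).
#' @return data.frame with one row per (gene, variant, quartile) test:
#'   effect estimates \code{alpha} (genotype), \code{beta} (state),
#'   \code{gamma} (interaction), \code{se_gamma} and \code{p_interaction}.
#'   The number of monomorphic variants skipped is in
#'   \code{attr(, "nSkipped")}.
#' @export
mapCsdEqtl <- function(expression, genotypes, stateAbundance,
                       geneInfo, variantInfo, covariates = NULL,
                       nPCs = 15, mafMin = 0.05, cisWindow = 1e6,
                       applyINT = TRUE) {
    expression <- as.matrix(expression)
    genotypes <- as.matrix(genotypes)
    S <- as.matrix(stateAbundance)
    N <- ncol(expression)
    if (ncol(genotypes) != N || ncol(S) != N)
        stop("expression, genotypes and stateAbundance must share samples")
    constS <- apply(S, 1L, function(s) stats::var(s) == 0)
    if (any(constS))
        stop("state abundance constant across samples for quartile(s) ",
             paste(rownames(S)[constS], collapse = ", "),
             "; the interaction model is unidentifiable")
    if (applyINT) {
        expression <- t(apply(expression, 1L, inverseNormalTransform))
        S <- t(apply(S, 1L, inverseNormalTransform))
    }
    covar <- if (is.null(covariates)) matrix(0, N, 0) else as.matrix(covariates)
    nPCs <- min(nPCs, N - 1L, nrow(expression))
    if (nPCs > 0) {
        pcs <- stats::prcomp(t(expression), center = TRUE)$x[, seq_len(nPCs),
                                                             drop = FALSE]
        colnames(pcs) <- paste0("exprPC", seq_len(nPCs))
        covar <- cbind(covar, pcs)
    }
    if (qr(cbind(1, covar))$rank < ncol(covar) + 1L)
        stop("rank-deficient covariate matrix")
    maf <- pmin(rowMeans(genotypes) / 2, 1 - rowMeans(genotypes) / 2)
    mono <- apply(genotypes, 1L, function(g) stats::var(g) == 0)
    nSkipped <- sum(mono)
    rows <- list()
    quartiles <- rownames(S) %||% paste0("Q", seq_len(nrow(S)))
    for (gi in seq_len(nrow(geneInfo))) {
        gene <- geneInfo$gene_id[gi]
        if (!gene %in% rownames(expression)) next
        y <- expression[gene, ]
        cis <- which(variantInfo$chrom == geneInfo$chrom[gi] &
                     abs(variantInfo$pos - geneInfo$tss[gi]) <= cisWindow)
        cis <- cis[!mono[cis] & maf[cis] >= mafMin]
        for (vi in cis) {
            x <- genotypes[vi, ]
            for (qi in seq_len(nrow(S))) {
                s <- S[qi, ]
                Xd <- cbind(1, x, s, x * s, covar)
                fit <- stats::lm.fit(Xd, y)
                if (fit$rank < ncol(Xd)) next
                rss <- sum(fit$residuals^2)
                dfres <- N - fit$rank
                XtXinv <- chol2inv(qr.R(fit$qr))
                XtXinv <- XtXinv[order(fit$qr$pivot), order(fit$qr$pivot)]
                seg <- sqrt(XtXinv[4L, 4L] * rss / dfres)
                gam <- fit$coefficients[4L]
                p <- 2 * stats::pt(abs(gam / seg), dfres, lower.tail = FALSE)
                rows[[length(rows) + 1L]] <- data.frame(
                    gene_id = gene,
                    variant_id = variantInfo$variant_id[vi],
                    position = variantInfo$pos[vi],
                    quartile = quartiles[qi],
                    maf = maf[vi],
                    alpha = fit$coefficients[2L],
                    beta = fit$coefficients[3L],
                    gamma = gam, se_gamma = seg, p_interaction = p,
                    stringsAsFactors = FALSE)
            }
        }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(gene_id = character(), variant_id = character(),
                   position = numeric(), quartile = character(),
                   maf = numeric(), alpha = numeric(), beta = numeric(),
                   gamma = numeric(), se_gamma = numeric(),
                   p_interaction = numeric())
    rownames(out) <- NULL
    attr(out, "nSkipped") <- nSkipped
    out
}

#' Gene-level multiple-testing correction for csd-eQTLs
#'
#' Within each gene, the minimum interaction p-value is Bonferroni-adjusted
#' by the number of tested variants (a conservative, dependency-free
#' stand-in for effective-test estimation); Benjamini-Hochberg FDR is then
#' computed across genes on the adjusted values. A csd-eGene is a gene with
#' FDR below \code{fdrThreshold}.
#'
#' @param records output of \code{\link{mapCsdEqtl}}.
#' @param fdrThreshold eGene FDR cutoff.
#' @return data.frame with one row per gene: \code{min_p},
#'   \code{n_variants}, \code{p_adjusted}, \code{fdr}, \code{is_eGene}.
#' @export
multipleTesting <- function(records, fdrThreshold = 0.05) {
    if (nrow(records) == 0L) stop("no association records supplied")
    sp <- split(records, records$gene_id)
    gl <- do.call(rbind, lapply(sp, function(d) {
        data.frame(gene_id = d$gene_id[1L],
                   min_p = min(d$p_interaction),
                   n_variants = length(unique(d$variant_id)),
                   stringsAsFactors = FALSE)
    }))
    gl$p_adjusted <- pmin(1, gl$min_p * gl$n_variants)
    gl$fdr <- stats::p.adjust(gl$p_adjusted, method = "BH")
    gl$is_eGene <- gl$fdr < fdrThreshold
    rownames(gl) <- NULL
    gl
}

#' Fold enrichment of a query set against MAF-matched controls
#'
#' Compares the mean score (e.g. trajectory-association chi-squared) of a
#' query variant or gene set against control sets drawn from a null pool,
#' matched on count and on the query's minor-allele-frequency distribution
#' over \code{nBins} equal-width bins on [0.05, 0.5]. The fold is the query
#' mean divided by the mean of the control-set means; its sampling variance
#' is the delta-method approximation
#' \code{fold^2 [var(y)/x^2 + var(y)/(m ybar^2)]} under cov(x, ybar) ~ 0 and
#' var(x) ~ var(y), giving the 95\% CI \code{fold +/- 1.96 sqrt(var)}.
#'
#' @param queryScores scores of the query set.
#' @param poolScores scores of the null pool.
#' @param queryMaf,poolMaf minor allele frequencies for matching; omit both
#'   to match on count only.
#' @param nSets number of control sets (paper default 1000).
#' @param nBins number of MAF bins.
#' @param seed optional RNG seed.
#' @return An \linkS4class{EnrichmentResult}.
#' @export
foldEnrichment <- function(queryScores, poolScores, queryMaf = NULL,
                           poolMaf = NULL, nSets = 1000, nBins = 10,
                           seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    nq <- length(queryScores)
    if (nq < 1 || length(poolScores) < nq)
        stop("pool must be at least as large as the query set")
    matched <- list(count = nq)
    if (!is.null(queryMaf) && !is.null(poolMaf)) {
        br <- seq(0.05, 0.5, length.out = nBins + 1)
        qb <- findInterval(queryMaf, br, rightmost.closed = TRUE,
                           all.inside = TRUE)
        pb <- findInterval(poolMaf, br, rightmost.closed = TRUE,
                           all.inside = TRUE)
        need <- table(factor(qb, levels = seq_len(nBins)))
        have <- table(factor(pb, levels = seq_len(nBins)))
        short <- which(as.integer(have) < as.integer(need))
        if (length(short))
            stop("MAF matching infeasible in bin(s) ",
                 paste(short, collapse = ", "),
                 " (pool too small)")
        poolByBin <- split(seq_along(poolScores), factor(pb, seq_len(nBins)))
        drawSet <- function() {
            idx <- unlist(lapply(seq_len(nBins), function(b) {
                nb <- need[[b]]
                if (nb == 0L) return(integer(0))
                poolByBin[[b]][sample.int(length(poolByBin[[b]]), nb)]
            }))
            mean(poolScores[idx])
        }
        matched$mafBins <- as.integer(need)
    } else {
        drawSet <- function()
            mean(poolScores[sample.int(length(poolScores), nq)])
    }
    setMeans <- vapply(seq_len(nSets), function(i) drawSet(), numeric(1))
    x <- mean(queryScores)
    ybar <- mean(setMeans)
    vy <- stats::var(setMeans)
    fold <- x / ybar
    variance <- fold^2 * (vy / x^2 + vy / (nSets * ybar^2))
    ci <- fold + c(-1.96, 1.96) * sqrt(variance)
    new("EnrichmentResult", fold = fold, variance = variance, ci95 = ci,
        nControlSets = as.integer(nSets), controlMeans = setMeans,
        matchedOn = matched)
}

#' Simulate an eQTL dataset with planted state-by-genotype interactions
#'
#' Generates per-sample genotypes (binomial with given MAFs), quartile
#' state abundances, covariates, and gene expression under the interaction
#' model \code{y = x a + s b + x s g + e} with standardized effect sizes;
#' \code{gamma} is non-zero for the planted genes only. Variants are placed
#' in the cis window of their gene; one extra far variant per gene is placed
#' outside the window to exercise the window filter.
#'
#' @param nSamples number of samples.
#' @param nGenes number of genes.
#' @param nVariants cis variants per gene.
#' @param plantedGenes indices of genes receiving a true interaction.
#' @param gamma standardized interaction effect for planted genes.
#' @param alpha,beta standardized genotype and state main effects.
#' @param mafRange range minor allele frequencies are drawn from.
#' @param seed RNG seed.
#' @return A list with \code{expression}, \code{genotypes},
#'   \code{stateAbundance}, \code{geneInfo}, \code{variantInfo}, and
#'   \code{planted} (gene ids with a true interaction).
#' @export
simulateEqtlData <- function(nSamples = 500, nGenes = 20, nVariants = 5,
                             plantedGenes = integer(0), gamma = 0.5,
                             alpha = 0.3, beta = 0.3,
                             mafRange = c(0.1, 0.5), seed = 1) {
    set.seed(seed)
    geneIds <- sprintf("gene%03d", seq_len(nGenes))
    S <- matrix(stats::runif(4 * nSamples), 4, nSamples,
                dimnames = list(paste0("Q", 1:4), NULL))
    S <- sweep(S, 2L, colSums(S), "/")
    expr <- matrix(0, nGenes, nSamples, dimnames = list(geneIds, NULL))
    vinfo <- list(); gidx <- 0L
    genos <- list()
    planted <- geneIds[plantedGenes]
    for (g in seq_len(nGenes)) {
        tss <- 1e6 + g * 5e6
        mafs <- stats::runif(nVariants, mafRange[1], mafRange[2])
        pos <- tss + sort(round(stats::runif(nVariants, -9e5, 9e5)))
        X <- vapply(mafs, function(f)
            stats::rbinom(nSamples, 2L, f), numeric(nSamples))
        causal <- 1L
        s <- scale(S[1L, ])[, 1L]
        x <- scale(X[, causal])[, 1L]
        mu <- alpha * x + beta * s
        if (g %in% plantedGenes) mu <- mu + gamma * x * s
        expr[g, ] <- mu + stats::rnorm(nSamples)
        ids <- sprintf("var_%s_%d", geneIds[g], seq_len(nVariants))
        vinfo[[g]] <- data.frame(
            variant_id = c(ids, sprintf("far_%s", geneIds[g])),
            chrom = "chr1",
            pos = c(pos, tss + 1.5e6),
            stringsAsFactors = FALSE)
        far <- stats::rbinom(nSamples, 2L, 0.3)
        genos[[g]] <- rbind(t(X), far)
        rownames(genos[[g]]) <- vinfo[[g]]$variant_id
        gidx <- gidx + 1L
    }
    list(expression = expr,
         genotypes = do.call(rbind, genos),
         stateAbundance = S,
         geneInfo = data.frame(gene_id = geneIds, chrom = "chr1",
                               tss = 1e6 + seq_len(nGenes) * 5e6,
                               stringsAsFactors = FALSE),
         variantInfo = do.call(rbind, vinfo),
         planted = planted)
}
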