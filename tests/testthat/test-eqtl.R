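test_that("inverse normal transformation matches the Blom formula and preserves symmetry", {
    x <- c(10, 3, 7, 1, 5)
    r <- rank(x)
    expect_equal(inverseNormalTransform(x), qnorm((r - 3 / 8) / 5.25))
    # symmetric ranks give antisymmetric output
    y <- inverseNormalTransform(1:9)
    expect_equal(y, -rev(y))
    expect_lt(abs(mean(y)), 1e-12)
    # monotone in the input ranks
    set.seed(4)
    z <- rnorm(30)
    expect_identical(order(inverseNormalTransform(z)), order(z))
    expect_error(inverseNormalTransform(rep(1, 5)), "identical")
    expect_error(inverseNormalTransform(1), "at least 2")
})

test_that("csd-eQTL mapping enforces the cis window, MAF filter and identifiability", {
    sim <- simulateEqtlData(nSamples = 150, nGenes = 3, nVariants = 3,
                            plantedGenes = 1, gamma = 1, seed = 2)
    rec <- mapCsdEqtl(sim$expression, sim$genotypes, sim$stateAbundance,
                      sim$geneInfo, sim$variantInfo, nPCs = 2)
    # variants 1.5 Mb beyond the TSS are never tested
    expect_false(any(grepl("^far_", rec$variant_id)))
    expect_true(all(rec$p_interaction >= 0 & rec$p_interaction <= 1))
    expect_true(all(rec$maf >= 0.05))
    expect_identical(sort(unique(rec$quartile)), paste0("Q", 1:4))

    # a rare variant is filtered by MAF, a monomorphic one is skipped
    geno2 <- sim$genotypes
    geno2["var_gene001_2", ] <- c(rep(0, 148), 1, 1)     # MAF < 0.05
    geno2["var_gene001_3", ] <- 0                        # monomorphic
    rec2 <- mapCsdEqtl(sim$expression, geno2, sim$stateAbundance,
                       sim$geneInfo, sim$variantInfo, nPCs = 2)
    expect_false("var_gene001_2" %in% rec2$variant_id)
    expect_false("var_gene001_3" %in% rec2$variant_id)
    expect_gte(attr(rec2, "nSkipped"), 1)

    # constant state abundance makes the interaction unidentifiable
    sConst <- sim$stateAbundance
    sConst[2, ] <- 0.25
    expect_error(mapCsdEqtl(sim$expression, sim$genotypes, sConst,
                            sim$geneInfo, sim$variantInfo, nPCs = 2),
                 "unidentifiable")
})

test_that("gene-level correction is Bonferroni-then-BH with eGene calls", {
    rec <- data.frame(
        gene_id = c("g1", rep("g2", 100)),
        variant_id = c("v0", paste0("v", 1:100)),
        p_interaction = c(0.03, 1e-4, runif(99, 0.5, 1)))
    out <- multipleTesting(rec)
    expect_equal(out$p_adjusted[out$gene_id == "g1"], 0.03)     # single variant
    expect_equal(out$p_adjusted[out$gene_id == "g2"], 1e-2)     # 1e-4 x 100
    expect_equal(out$fdr, p.adjust(out$p_adjusted, "BH"))
    expect_error(multipleTesting(rec[0, ]), "no association")
})

test_that("planted genotype-by-state interactions are found and nulls are not", {
    sim <- simulateEqtlData(nSamples = 300, nGenes = 10, nVariants = 4,
                            plantedGenes = 1:4, gamma = 0.8, seed = 8)
    rec <- mapCsdEqtl(sim$expression, sim$genotypes, sim$stateAbundance,
                      sim$geneInfo, sim$variantInfo, nPCs = 3)
    out <- multipleTesting(rec)
    expect_true(all(out$is_eGene[out$gene_id %in% sim$planted]))
    # enrichment of planted genes among eGene calls
    tab <- table(planted = out$gene_id %in% sim$planted, egene = out$is_eGene)
    if (all(dim(tab) == c(2, 2)))
        expect_lt(fisher.test(tab)$p.value, 0.05)
})

test_that("fold enrichment is scale-invariant, tracks planted signal, and covers the null", {
    set.seed(3)
    pool <- rchisq(4000, df = 1)
    maf <- runif(4000, 0.05, 0.5)
    qIdx <- sample(4000, 80)
    r1 <- foldEnrichment(pool[qIdx], pool, maf[qIdx], maf, nSets = 300,
                         seed = 11)
    r2 <- foldEnrichment(10 * pool[qIdx], 10 * pool, maf[qIdx], maf,
                         nSets = 300, seed = 11)
    expect_equal(r1@fold, r2@fold, tolerance = 1e-12)
    expect_true(r1@ci95[1] <= r1@fold && r1@fold <= r1@ci95[2])
    # doubled scores give a fold near two
    r3 <- foldEnrichment(2 * pool[qIdx], pool, maf[qIdx], maf, nSets = 300,
                         seed = 12)
    expect_lt(abs(r3@fold - 2 * r1@fold), 0.2)
    # null queries: the CI covers 1 in at least 90% of repetitions
    cover <- replicate(40, {
        qi <- sample(4000, 80)
        r <- foldEnrichment(pool[qi], pool, maf[qi], maf, nSets = 150)
        r@ci95[1] <= 1 && 1 <= r@ci95[2]
    })
    expect_gte(mean(cover), 0.9)
    expect_error(foldEnrichment(pool[1:5], pool[1:3]), "pool")
    # infeasible MAF bin is reported: the pool covers only one bin
    expect_error(foldEnrichment(pool[qIdx], pool[1:200], maf[qIdx],
                                rep(0.06, 200), nSets = 10),
                 "bin")
})

test_that("quartile abundances sum the normalized profile within trajectory quarters", {
    nm <- matrix(c(0.1, 0.2, 0.3, 0.4,
                   0.25, 0.25, 0.25, 0.25), 4, 2)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(raw = nm, se = nm, smoothed = nm, normalized = nm),
        rowData = S4Vectors::DataFrame(state = 1:4,
                                       statePseudotime = c(0.1, 0.35, 0.6,
                                                           0.9)))
    ab <- new("AbundanceSet", se)
    q <- quartileAbundance(ab)
    expect_equal(unname(q[, 1]), c(0.1, 0.2, 0.3, 0.4))
    expect_equal(unname(colSums(q)), c(1, 1))
})
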