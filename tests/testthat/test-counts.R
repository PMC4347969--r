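toyCounts <- function(mat, heat = NULL, genotype = NULL) {
    if (is.null(colnames(mat)))
        colnames(mat) <- paste0("s", seq_len(ncol(mat)))
    if (is.null(rownames(mat)))
        rownames(mat) <- paste0("g", seq_len(nrow(mat)))
    if (is.null(heat)) heat <- rep(c(25, 38), length.out = ncol(mat))
    if (is.null(genotype)) genotype <- rep("A", ncol(mat))
    HeatCounts(mat, genotype = genotype, heat_c = heat,
               rep = seq_len(ncol(mat)))
}

test_that("counts per million follow their definition", {
    m <- matrix(c(2, 0, 10, 4, 0, 20), nrow = 3)
    hc <- toyCounts(m)
    colData(hc)$lib_size <- c(1e6, 2e6)
    cpm <- countsPerMillion(hc)
    expect_equal(cpm[1, 1], 2)
    expect_equal(cpm[2, 1], 0)
    expect_equal(cpm[1, 2], 2)          # 4 / 2e6 * 1e6
    # doubling counts and library leaves CPM unchanged
    hc2 <- toyCounts(cbind(m[, 1] * 2, m[, 2]))
    colData(hc2)$lib_size <- c(2e6, 2e6)
    expect_equal(countsPerMillion(hc2)[, 1], cpm[, 1])
    colData(hc)$lib_size <- c(0, 1)
    expect_error(countsPerMillion(hc), "library")
})

test_that("CPM filter applies inclusive thresholds and is monotone", {
    m <- rbind(boundary = c(2, 2, 0, 0),
               zero     = c(0, 0, 0, 0),
               single   = c(5, 0, 0, 0),
               strong   = c(50, 60, 70, 80))
    hc <- toyCounts(m)
    colData(hc)$lib_size <- rep(1e6, 4)
    f <- cpmFilter(hc)
    expect_setequal(rownames(f), c("boundary", "strong"))
    expect_setequal(metadata(f)$dropped_genes, c("zero", "single"))
    # monotone: raising either threshold never adds genes
    f2 <- cpmFilter(hc, min_cpm = 3)
    f3 <- cpmFilter(hc, min_samples = 3)
    expect_true(all(rownames(f2) %in% rownames(f)))
    expect_true(all(rownames(f3) %in% rownames(f)))
})

test_that("TMM factors satisfy their contract and match a brute force", {
    set.seed(10)
    base <- rpois(200, 200)
    m <- cbind(s1 = base, s2 = base, s3 = base)
    hc <- toyCounts(m, heat = c(25, 32, 38))
    f <- normFactors(tmmFactors(hc))
    expect_equal(unname(f), rep(1, 3), tolerance = 1e-10)

    # one sample scaled x2 on shared composition: factors from an
    # independently coded trimmed weighted mean of M values
    m2 <- cbind(s1 = base, s2 = base * 2L, s3 = base)
    hc2 <- toyCounts(m2, heat = c(25, 32, 38))
    hc2 <- tmmFactors(hc2)
    f2 <- normFactors(hc2)
    expect_equal(prod(f2)^(1 / 3), 1, tolerance = 1e-12)
    # oracle: factor of s2 against reference s1, de-scaled by geomean
    raw <- c(tmmOracle(m2[, 1], m2[, 1]), tmmOracle(m2[, 2], m2[, 1]),
             tmmOracle(m2[, 3], m2[, 1]))
    expect_equal(unname(f2), raw / prod(raw)^(1 / 3), tolerance = 1e-6)
    # invariant to gene and sample order
    perm <- sample(nrow(m2)); sperm <- c(2, 3, 1)
    hc3 <- tmmFactors(toyCounts(m2[perm, sperm],
                                heat = c(32, 38, 25)))
    expect_equal(unname(normFactors(hc3)), unname(f2[sperm]),
                 tolerance = 1e-12)
})

test_that("common dispersion recovers the truth and reports bcv", {
    # Poisson data: phi estimate collapses to (near) zero
    hcp <- simulateCounts(countsSimConfig(n_genes = 500, bcv = 0,
                                          frac_responsive = 0,
                                          frac_tolerance = 0,
                                          drop_one_sample = FALSE,
                                          seed = 8))
    dp <- commonDispersion(hcp)
    expect_lte(dp$phi, 0.005)
    expect_equal(dp$bcv, sqrt(dp$phi))
    # monotone in the simulated overdispersion
    phis <- vapply(c(0.13, 0.26, 0.52), function(b) {
        hc <- simulateCounts(countsSimConfig(n_genes = 600, bcv = b,
                                             frac_responsive = 0,
                                             frac_tolerance = 0,
                                             drop_one_sample = FALSE,
                                             seed = 77))
        commonDispersion(hc)$phi
    }, numeric(1))
    expect_true(all(diff(c(dp$phi, phis)) > 0))
    # agreement with the established Cox-Reid common dispersion
    hc <- simulateCounts(countsSimConfig(n_genes = 800, bcv = 0.26,
                                         frac_responsive = 0,
                                         frac_tolerance = 0,
                                         drop_one_sample = FALSE,
                                         seed = 15))
    ours <- commonDispersion(hc)
    cd <- colData(hc)
    design <- model.matrix(~ interaction(cd$genotype, cd$heat_c))
    ref <- edgeR::estimateGLMCommonDisp(assay(hc, "counts"),
                                        design = design,
                                        offset = log(libSizes(hc)))
    expect_equal(ours$phi, ref, tolerance = 0.1)
})

test_that("expression PCA scores samples and finds planted structure", {
    m <- matrix(rpois(400, 100), 100, 4)
    m[, 2] <- m[, 1]
    hc <- toyCounts(m, heat = c(25, 25, 38, 38))
    ep <- expressionPCA(hc)
    expect_equal(sum(ep$explained), 1)
    expect_equal(unname(as.numeric(ep$scores[1, -(1:2)])),
                 unname(as.numeric(ep$scores[2, -(1:2)])),
                 tolerance = 1e-8)
    # heat level as dominant planted effect separates on PC1
    hc2 <- simulateCounts(countsSimConfig(n_genes = 500,
                                          frac_responsive = 0.3,
                                          frac_tolerance = 0,
                                          slope_magnitude = 3,
                                          seed = 23))
    hc2 <- tmmFactors(cpmFilter(hc2))
    ep2 <- expressionPCA(hc2)
    sil <- cluster::silhouette(as.integer(factor(ep2$scores$heat_c)),
                               dist(ep2$scores$PC1))
    expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("count matrix TSV round-trips through HeatCounts", {
    hc <- simulateCounts(countsSimConfig(n_genes = 30, seed = 2))
    normFactors(hc) <- seq(0.9, by = 0.005, length.out = ncol(hc))
    cp <- tempfile(fileext = ".tsv"); mp <- tempfile(fileext = ".tsv")
    writeCountMatrix(hc, cp, mp)
    back <- readCountMatrix(cp, mp)
    expect_equal(assay(back, "counts"), assay(hc, "counts"))
    expect_equal(normFactors(back), normFactors(hc))
    expect_equal(colData(back)$heat_c, colData(hc)$heat_c)
})
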