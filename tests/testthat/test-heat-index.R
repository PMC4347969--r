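test_that("metric coding maps the gradient affinely onto [0, 1]", {
    expect_equal(unname(metricHeatCoding(c(25, 32, 38))),
                 c(0, 7 / 13, 1))
    expect_equal(unname(metricHeatCoding(c(25, 38))), c(0, 1))
    expect_equal(unname(metricHeatCoding(c(20, 30, 40))), c(0, 0.5, 1))
    expect_error(metricHeatCoding(c(25, 25)), "distinct")
})

toyMeans <- function(mat, levels = c(25, 38)) {
    # mat: genotypes x traits per level stacked; build long means table
    do.call(rbind, lapply(seq_along(levels), function(j) {
        m <- mat[[j]]
        data.frame(genotype = rep(rownames(m), ncol(m)),
                   heat_c = levels[j],
                   trait = rep(colnames(m), each = nrow(m)),
                   mean = as.vector(m), stringsAsFactors = FALSE)
    }))
}

test_that("PCA of means handles rank-1 data and conserves variance", {
    m1 <- matrix(c(1, 2, 3, 2, 4, 6), 3,
                 dimnames = list(c("A", "B", "C"), c("t1", "t2")))
    m2 <- m1 + matrix(c(1, 1, 1, 2, 2, 2), 3)  # keeps t2 = 2 * t1
    means <- toyMeans(list(m1, m2))
    pca <- pcaMeans(means, standardize = FALSE)
    expect_equal(pca$explained[["PC1"]], 1)
    pca2 <- pcaMeans(means, standardize = TRUE)
    expect_equal(sum(pca2$explained), 1)
    # missing cell errors with the offender named
    expect_error(pcaMeans(means[-1, ]), "missing")
})

test_that("PCA matches a hand eigen-decomposition of the covariance", {
    m1 <- matrix(c(2, 1, 0, 1, 3, 1), 3,
                 dimnames = list(c("A", "B", "C"), c("t1", "t2")))
    m2 <- matrix(c(4, 2, 1, 2, 5, 3), 3,
                 dimnames = list(c("A", "B", "C"), c("t1", "t2")))
    means <- toyMeans(list(m1, m2))
    X <- rbind(m1, m2)
    Xc <- scale(X, center = TRUE, scale = FALSE)
    ev <- eigen(cov(Xc))
    pca <- pcaMeans(means, standardize = FALSE)
    expect_equal(sort(pca$explained, decreasing = TRUE),
                 sort(ev$values / sum(ev$values), decreasing = TRUE),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(abs(pca$loadings[, 1]), abs(ev$vectors[, 1]),
                 tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("trait-PC1 correlations follow the Pearson formula", {
    cfg <- phenoSimConfig(n_genotypes = 5, n_reps = 3, seed = 17)
    means <- adjustedMeansTable(simulatePhenotypes(cfg))
    pca <- pcaMeans(means)
    cors <- correlateTraitsPC1(means, pca)
    # oracle: direct Pearson formula on one trait
    tr <- cors$trait[1]
    v <- means[means$trait == tr, ]
    key <- paste(pca$scores$genotype, pca$scores$heat_c)
    y <- v$mean[match(key, paste(v$genotype, v$heat_c))]
    x <- pca$scores$PC1
    r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(cors$r[1], r, tolerance = 1e-10)
    # a trait equal to +/- PC1 correlates exactly +/-1
    fake <- data.frame(genotype = pca$scores$genotype,
                       heat_c = pca$scores$heat_c, trait = "pc1",
                       mean = pca$scores$PC1)
    fake2 <- transform(fake, trait = "negpc1", mean = -mean)
    cc <- correlateTraitsPC1(rbind(fake, fake2),
                             structure(list(scores = pca$scores,
                                            loadings = matrix(0, 2, 1,
                                                              dimnames = list(c("pc1", "negpc1"), "PC1"))),
                                       class = "heatPCA"))
    expect_equal(cc$r, c(1, -1), tolerance = 1e-12)
})

test_that("HSI is the per-genotype OLS slope of PC1 on the coding", {
    codes <- c(0, 7 / 13, 1)
    sc <- data.frame(genotype = rep(c("A", "B", "C"), each = 3),
                     heat_c = rep(c(25, 32, 38), 3),
                     PC1 = c(1, 1, 1,                 # constant -> 0
                             0, 7 / 13, 1,            # identity -> 1
                             0.2, 1.1, 1.9))
    pca <- structure(list(scores = sc), class = "heatPCA")
    h <- computeHSI(pca, metricHeatCoding(c(25, 32, 38)))
    expect_equal(h$hsi[h$genotype == "A"], 0)
    expect_equal(h$hsi[h$genotype == "B"], 1)
    o <- olsOracle(codes, c(0.2, 1.1, 1.9))
    expect_equal(h$hsi[h$genotype == "C"], o$slope)
    expect_equal(h$genotype[1], "C")          # ranked descending
    # invariance to adding a constant per genotype
    sc2 <- sc; sc2$PC1 <- sc2$PC1 + rep(c(5, -3, 100), each = 3)
    h2 <- computeHSI(structure(list(scores = sc2), class = "heatPCA"),
                     metricHeatCoding(c(25, 32, 38)))
    expect_equal(h2$hsi[match(h$genotype, h2$genotype)], h$hsi)
    # genotype at a single level is excluded with a warning
    sc3 <- rbind(sc, data.frame(genotype = "D", heat_c = 25, PC1 = 0))
    expect_warning(h3 <- computeHSI(structure(list(scores = sc3),
                                              class = "heatPCA"),
                                    metricHeatCoding(c(25, 32, 38))),
                   "single level")
    expect_false("D" %in% h3$genotype)
})

test_that("PC1 orientation makes high HSI mean heat susceptible", {
    cfg <- phenoSimConfig(seed = 5, interaction_strength = 0.5)
    ph <- simulatePhenotypes(cfg)
    pca <- pcaMeans(adjustedMeansTable(ph))
    sc <- pca$scores
    expect_gt(mean(sc$PC1[sc$heat_c == 38]),
              mean(sc$PC1[sc$heat_c == 25]))
    h <- computeHSI(pca)
    s <- attr(ph, "susceptibility")
    expect_gt(cor(h$hsi[match(names(s), h$genotype)], s,
                  method = "spearman"), 0.7)
})

test_that("HSI ranking recovers planted susceptibility across seeds", {
    rho <- vapply(1:30, function(i) {
        cfg <- phenoSimConfig(seed = 2000 + i,
                              interaction_strength = 0.5)
        ph <- simulatePhenotypes(cfg)
        h <- computeHSI(pcaMeans(adjustedMeansTable(ph)))
        s <- attr(ph, "susceptibility")
        cor(h$hsi[match(names(s), h$genotype)], s, method = "spearman")
    }, numeric(1))
    expect_gte(mean(rho), 0.9)
})
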