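test_that("NB fit at phi = 0 equals a Poisson GLM gene by gene", {
    hc <- simulateCounts(countsSimConfig(n_genes = 50, bcv = 0.2,
                                         frac_responsive = 0.2,
                                         frac_tolerance = 0,
                                         drop_one_sample = FALSE,
                                         seed = 31))
    x <- metricHeatCoding(heatLevels(hc))[
        as.character(colData(hc)$heat_c)]
    o <- log(libSizes(hc))
    fits <- fitDoseResponse(hc, phi = 0)
    y <- assay(hc, "counts")
    for (g in seq_len(nrow(y))) {
        ref <- glm(y[g, ] ~ x, family = poisson(), offset = o)
        expect_equal(fits$beta_log2[g], unname(coef(ref)[2]) / log(2),
                     tolerance = 1e-6)
    }
})

test_that("two-level Poisson slope equals the closed-form log ratio", {
    set.seed(3)
    y <- matrix(rpois(20 * 8, 500), 20, 8,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:8)))
    hc <- HeatCounts(y, genotype = "A", heat_c = rep(c(25, 38), 4),
                     rep = 1:8, lib_size = rep(1e6, 8))
    fits <- fitDoseResponse(hc, phi = 0)
    hot <- rep(c(FALSE, TRUE), 4)
    closed <- log2(rowMeans(y[, hot]) / rowMeans(y[, !hot]))
    expect_equal(fits$beta_log2, unname(closed), tolerance = 1e-6)
    # identical counts at all levels, equal libraries: slope exactly 0
    y0 <- matrix(7, 3, 8, dimnames = list(paste0("g", 1:3),
                                          paste0("s", 1:8)))
    hc0 <- HeatCounts(y0, genotype = "A", heat_c = rep(c(25, 38), 4),
                      rep = 1:8, lib_size = rep(1e6, 8))
    f0 <- fitDoseResponse(hc0, phi = 0.05)
    expect_equal(f0$beta_log2, rep(0, 3), tolerance = 1e-8)
    # all-zero gene: beta 0, p 1
    y0[2, ] <- 0
    hcz <- HeatCounts(y0, genotype = "A", heat_c = rep(c(25, 38), 4),
                      rep = 1:8, lib_size = rep(1e6, 8))
    fz <- fitDoseResponse(hcz, phi = 0.05)
    expect_equal(fz$beta_log2[2], 0)
    expect_equal(fz$p[2], 1)
})

test_that("LRT p-values are uniform under the null", {
    hc <- simulateCounts(countsSimConfig(n_genes = 1000, bcv = 0.26,
                                         frac_responsive = 0,
                                         frac_tolerance = 0, seed = 41))
    hc <- tmmFactors(cpmFilter(hc))
    d <- commonDispersion(hc)
    fits <- fitDoseResponse(hc, d)
    ks <- suppressWarnings(ks.test(fits$p, "punif"))
    expect_gt(ks$p.value, 0.01)
    calls <- callSignificant(fits)
    expect_lte(length(calls$up) + length(calls$down),
               0.01 * nrow(fits))
})

test_that("significance calling is strict on both thresholds", {
    fits <- data.frame(gene_id = c("a", "b", "c", "d"),
                       beta_log2 = c(2.0, 2.1, -2.1, -5),
                       p = c(0.001, 0.001, 0.001, 0.5),
                       fdr = c(0.01, 0.01, 0.01, 0.6))
    calls <- callSignificant(fits)
    expect_equal(calls$up, "b")        # beta exactly 2 is not called
    expect_equal(calls$down, "c")      # fdr 0.6 is not called
    empty <- callSignificant(fits[0, ])
    expect_length(empty$up, 0)
    # BH adjustment matches the brute-force step-up enumeration
    set.seed(12)
    p <- runif(10)^2
    expect_equal(p.adjust(p, "BH"), bhOracle(p))
    hc <- simulateCounts(countsSimConfig(n_genes = 10, seed = 1))
    f <- fitDoseResponse(hc, 0.07)
    expect_equal(f$fdr, bhOracle(f$p))
})

test_that("per-genotype slopes recover planted genotype structure", {
    # planted: responsive genes slope +3 everywhere; for genotype-level
    # checking simulate two genotypes and overwrite gamma truth by class
    cfg <- countsSimConfig(n_genes = 200, genotypes = c("A", "B"),
                           hsi = c(A = 1, B = 1),
                           heat_levels = c(25, 32, 38), n_reps = 4,
                           lib_sizes = 2e6, bcv = 0.05,
                           frac_responsive = 0.3, frac_tolerance = 0,
                           slope_magnitude = 3,
                           drop_one_sample = FALSE, seed = 19)
    hc <- simulateCounts(cfg)
    truth <- simTruth(hc)
    # build a two-class gene set: slope +3 in A, 0 in B, by stitching
    # samples of genotype B from a null simulation
    cfg0 <- countsSimConfig(n_genes = 200, genotypes = c("A", "B"),
                            hsi = c(A = 1, B = 1),
                            heat_levels = c(25, 32, 38), n_reps = 4,
                            lib_sizes = 2e6, bcv = 0.05,
                            frac_responsive = 0, frac_tolerance = 0,
                            drop_one_sample = FALSE, seed = 19)
    hc0 <- simulateCounts(cfg0)
    selB <- colData(hc0)$genotype == "B"
    y <- cbind(assay(hc, "counts")[, !selB], assay(hc0, "counts")[, selB])
    meta <- rbind(as.data.frame(colData(hc))[!selB, ],
                  as.data.frame(colData(hc0))[selB, ])
    mix <- HeatCounts(y, genotype = meta$genotype, heat_c = meta$heat_c,
                      rep = meta$rep)
    mix <- tmmFactors(mix)    # corrects the composition shift at 38 C
    s <- fitDoseResponseByGenotype(mix, phi = 0.0025)
    resp <- truth$status == "responsive" & truth$beta > 0 &
        truth$baseline_q * 2e6 >= 50
    expect_true(all(abs(s$gamma[resp, "A"] - 3) < 0.3))
    expect_true(all(abs(s$gamma[resp, "B"]) < 0.3))
    # reduction: a single genotype reproduces the overall fit
    sub <- mix[, colData(mix)$genotype == "A"]
    s1 <- fitDoseResponseByGenotype(sub, phi = 0.01)
    f1 <- fitDoseResponse(sub, phi = 0.01)
    expect_equal(unname(s1$gamma[, "A"]), f1$beta_log2,
                 tolerance = 1e-10)
    expect_equal(unname(s1$p[, "A"]), f1$p, tolerance = 1e-10)
})

test_that("shared-intercept mode fits the literal joint model", {
    hc <- simulateCounts(countsSimConfig(n_genes = 60,
                                         genotypes = c("A", "B", "C"),
                                         n_reps = 3, bcv = 0.15,
                                         frac_responsive = 0.2,
                                         frac_tolerance = 0,
                                         drop_one_sample = FALSE,
                                         seed = 53))
    s <- fitDoseResponseByGenotype(hc, phi = 0.0225,
                                   mode = "shared-intercept")
    sp <- fitDoseResponseByGenotype(hc, phi = 0.0225)
    # strongly responsive genes agree between modes (baselines are equal
    # in the simulation, so the shared intercept is correctly specified)
    resp <- simTruth(hc)$status == "responsive"
    expect_equal(unname(s$gamma[resp, ]), unname(sp$gamma[resp, ]),
                 tolerance = 0.3)
})

test_that("overlap sets follow set algebra", {
    calls <- list(A = list(up = c("g1", "g2", "g3"), down = c("g9")),
                  B = list(up = c("g2", "g3", "g4"), down = c("g9")),
                  C = list(up = c("g3", "g2"), down = character()))
    ov <- overlapSets(calls)
    expect_equal(ov$n[ov$direction == "up"], 2)    # g2, g3
    expect_equal(ov$n[ov$direction == "down"], 0)
    ov2 <- overlapSets(calls, list(AB = c("A", "B")))
    sets <- attr(ov2, "sets")
    expect_setequal(sets$AB$up, c("g2", "g3"))
    expect_setequal(sets$AB$down, "g9")
    # identical sets intersect to themselves; disjoint sets to nothing
    same <- list(A = list(up = c("x", "y"), down = character()),
                 B = list(up = c("y", "x"), down = character()))
    expect_setequal(attr(overlapSets(same), "sets")$all$up, c("x", "y"))
    disj <- list(A = list(up = "x", down = character()),
                 B = list(up = "y", down = character()))
    expect_equal(overlapSets(disj)$n, c(0, 0))
    expect_error(overlapSets(calls, list(bad = "Z")), "unknown")
})

test_that("tolerance regression matches the closed-form OLS oracle", {
    # collinear boundary case: delta exactly 2 is not called
    g <- matrix(c(1, 3, 5, 7), 1,
                dimnames = list("g1", paste0("G", 1:4)))
    tf <- toleranceRegression(g, setNames(1:4, paste0("G", 1:4)))
    expect_equal(tf$delta, 2)
    expect_false(tf$called)
    # constant gamma: delta 0, not called
    gc <- matrix(5, 1, 4, dimnames = list("g1", paste0("G", 1:4)))
    tfc <- toleranceRegression(gc, setNames(c(1, 2, 3, 5),
                                            paste0("G", 1:4)))
    expect_equal(tfc$delta, 0)
    expect_false(tfc$called)
    # random 8-genotype input against the textbook formulas
    set.seed(6)
    h <- setNames(runif(8, 0.9, 1.9), paste0("G", 1:8))
    gm <- matrix(rnorm(8 * 5), 5, 8,
                 dimnames = list(paste0("g", 1:5), names(h)))
    tf2 <- toleranceRegression(gm, h)
    for (i in 1:5) {
        o <- olsOracle(h, gm[i, ])
        expect_equal(tf2$delta[i], o$slope, tolerance = 1e-12)
        expect_equal(tf2$t[i], o$t, tolerance = 1e-10)
        expect_equal(tf2$p[i], o$p, tolerance = 1e-12)
    }
    expect_error(toleranceRegression(gm, setNames(rep(1, 8), names(h))),
                 "variance")
})

test_that("tolerance test holds its type-I error on null genes", {
    hc <- simulateCounts(countsSimConfig(n_genes = 1500, bcv = 0.26,
                                         frac_responsive = 0,
                                         frac_tolerance = 0, seed = 61))
    hc <- tmmFactors(cpmFilter(hc))
    d <- commonDispersion(hc)
    s <- fitDoseResponseByGenotype(hc, d)
    tf <- toleranceRegression(s, metadata(hc)$hsi)
    rate <- mean(tf$p < 0.05)
    expect_gt(rate, 0.03)
    expect_lt(rate, 0.07)
})

test_that("tolerance-gene clustering recovers planted patterns", {
    set.seed(44)
    up_sus <- matrix(rnorm(10 * 8, mean = rep(c(0, 4), each = 4)),
                     10, 8, byrow = TRUE)
    up_tol <- matrix(rnorm(6 * 8, mean = rep(c(4, 0), each = 4)),
                     6, 8, byrow = TRUE)
    gm <- rbind(up_sus, up_tol)
    rownames(gm) <- paste0("g", 1:16)
    cl <- clusterToleranceGenes(gm, k = 2)
    expect_equal(length(unique(cl$cluster[1:10])), 1)
    expect_equal(length(unique(cl$cluster[11:16])), 1)
    expect_true(cl$cluster[1] != cl$cluster[16])
    # duplicated rows land together; k = 1 puts everything together
    dup <- gm[c(1, 1, 12), ]
    rownames(dup) <- c("a", "b", "c")
    cld <- clusterToleranceGenes(dup, k = 2)
    expect_equal(cld$cluster[1], cld$cluster[2])
    expect_equal(length(unique(clusterToleranceGenes(gm, k = 1)$cluster)),
                 1)
    one <- clusterToleranceGenes(gm[1, , drop = FALSE])
    expect_equal(one$cluster, 1L)
})
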