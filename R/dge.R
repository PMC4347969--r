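#' Overall dose-response differential expression
#'
#' Per gene, negative-binomial log-linear regression of counts on the
#' metric-coded heat level, pooling all genotypes as replications of one
#' average genotype: `log mu = intercept + x * beta_ln + log(effective
#' library size)`, with the dispersion fixed at the common estimate.  The
#' fit is iteratively reweighted least squares (tolerance 1e-8, at most 50
#' iterations); the slope p-value is a likelihood-ratio test of `beta = 0`
#' against chi-square with 1 df, and FDR is Benjamini-Hochberg across
#' genes.  Reported `beta_log2` is the slope in log2 units per unit of
#' `x`, i.e. the log2 fold change across the full heat gradient.
#'
#' @param x a filtered, normalized [HeatCounts-class] object.
#' @param phi common dispersion; a [commonDispersion()] result or number.
#' @param coding optional [metricHeatCoding()] vector.
#' @return data frame with columns `gene_id`, `beta_log2`, `intercept`,
#'   `p`, `fdr`, `converged`.  All-zero genes get `beta_log2 = 0, p = 1`;
#'   non-converged genes are flagged and excluded from calling by
#'   [callSignificant()].
#' @export
fitDoseResponse <- function(x, phi, coding = NULL) {
    stopifnot(methods::is(x, "HeatCounts"))
    if (inherits(phi, "dispersionEstimate")) phi <- phi$phi
    if (is.null(coding)) coding <- metricHeatCoding(heatLevels(x))
    xj <- coding[as.character(colData(x)$heat_c)]
    stopIf(anyNA(xj), "coding does not cover all heat levels")
    y <- assay(x, "counts")
    o <- log(libSizes(x) * normFactors(x))
    allzero <- rowSums(y) == 0
    out <- data.frame(gene_id = rownames(y), beta_log2 = 0,
                      intercept = NA_real_, p = 1, fdr = NA_real_,
                      converged = TRUE, stringsAsFactors = FALSE)
    if (any(!allzero)) {
        X <- cbind(1, as.numeric(xj))
        fit <- nbLrtSlope(y[!allzero, , drop = FALSE], X, o, phi)
        out$beta_log2[!allzero] <- fit$full$coef[, 2] / log(2)
        out$intercept[!allzero] <- fit$full$coef[, 1]
        out$p[!allzero] <- fit$p
        out$converged[!allzero] <- fit$full$converged
    }
    out$fdr <- stats::p.adjust(out$p, method = "BH")
    out
}

#' Call significantly heat-responsive genes
#'
#' Strict thresholds on both criteria: called iff `fdr < fdr_max` and
#' `|beta_log2| > lfc_min`.  A slope of exactly `lfc_min` is not called.
#' Non-converged fits are never called.
#'
#' @param fits a [fitDoseResponse()] data frame (or per-genotype subset
#'   with columns `gene_id`, `beta_log2` or `gamma_log2`, `fdr`).
#' @param fdr_max FDR threshold (default 0.05).
#' @param lfc_min absolute log2 fold-change threshold (default 2).
#' @return list with character vectors `up` and `down` of gene IDs.
#' @export
callSignificant <- function(fits, fdr_max = 0.05, lfc_min = 2) {
    if (nrow(fits) == 0) return(list(up = character(), down = character()))
    b <- if ("beta_log2" %in% names(fits)) fits$beta_log2
         else fits$gamma_log2
    ok <- if ("converged" %in% names(fits)) fits$converged else TRUE
    sig <- ok & !is.na(fits$fdr) & fits$fdr < fdr_max & abs(b) > lfc_min
    list(up = fits$gene_id[sig & b > 0], down = fits$gene_id[sig & b < 0])
}

#' Per-genotype dose-response slopes
#'
#' Fits the genotype-specific dose-response model: each genotype gets its
#' own slope `gamma_i` over the metric heat coding.  In the default
#' `"per-genotype"` mode each inbred line additionally keeps its own
#' intercept (baseline expression differs between lines), which makes the
#' joint model separable: each genotype is fitted on its own samples,
#' exactly as [fitDoseResponse()] on that subset.  The `"shared-intercept"`
#' mode fits the literal joint model with one common intercept and
#' genotype-specific slopes.  Slope p-values are likelihood-ratio tests;
#' FDR is Benjamini-Hochberg within genotype.
#'
#' @inheritParams fitDoseResponse
#' @param mode `"per-genotype"` (default) or `"shared-intercept"`.
#' @return list of class `genotypeSlopes` with elements `gamma` (genes x
#'   genotypes matrix of log2 slopes), `p` and `fdr` (same shape),
#'   `converged`, `mode`.
#' @export
fitDoseResponseByGenotype <- function(x, phi, coding = NULL,
                                      mode = c("per-genotype",
                                               "shared-intercept")) {
    stopifnot(methods::is(x, "HeatCounts"))
    mode <- match.arg(mode)
    if (inherits(phi, "dispersionEstimate")) phi <- phi$phi
    if (is.null(coding)) coding <- metricHeatCoding(heatLevels(x))
    gn <- genotypes(x)
    y <- assay(x, "counts")
    G <- nrow(y)
    gamma <- p <- matrix(NA_real_, G, length(gn),
                         dimnames = list(rownames(y), gn))
    conv <- matrix(TRUE, G, length(gn), dimnames = dimnames(gamma))
    if (mode == "per-genotype") {
        for (g in gn) {
            sel <- colData(x)$genotype == g
            if (length(unique(colData(x)$heat_c[sel])) < 2) {
                warning("genotype ", g,
                        " observed at a single level; gamma undefined")
                next
            }
            fit <- fitDoseResponse(x[, sel], phi, coding)
            gamma[, g] <- fit$beta_log2
            p[, g] <- fit$p
            conv[, g] <- fit$converged
        }
    } else {
        xj <- as.numeric(coding[as.character(colData(x)$heat_c)])
        gf <- factor(colData(x)$genotype, levels = gn)
        X <- cbind(1, sapply(gn, function(g) xj * (gf == g)))
        o <- log(libSizes(x) * normFactors(x))
        full <- nbGlmFit(y, X, o, phi)
        null <- nbGlmFit(y, X[, 1, drop = FALSE], o, phi)
        for (j in seq_along(gn)) {
            red <- nbGlmFit(y, X[, -(j + 1), drop = FALSE], o, phi)
            lrt <- pmax(2 * (full$loglik - red$loglik), 0)
            p[, j] <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
            gamma[, j] <- full$coef[, j + 1] / log(2)
            conv[, j] <- full$converged & red$converged
        }
    }
    fdr <- apply(p, 2L, stats::p.adjust, method = "BH")
    structure(list(gamma = gamma, p = p, fdr = fdr, converged = conv,
                   mode = mode),
              class = "genotypeSlopes")
}

#' @export
print.genotypeSlopes <- function(x, ...) {
    cat(sprintf("per-genotype dose-response slopes: %d genes x %d genotypes (%s mode)\n",
                nrow(x$gamma), ncol(x$gamma), x$mode))
    invisible(x)
}

#' Per-genotype significance calls
#'
#' Applies [callSignificant()] within each genotype of a
#' [fitDoseResponseByGenotype()] result.
#'
#' @param slopes a `genotypeSlopes` object.
#' @inheritParams callSignificant
#' @return named list per genotype, each with `up` and `down` gene IDs.
#' @export
callSignificantByGenotype <- function(slopes, fdr_max = 0.05,
                                      lfc_min = 2) {
    stopifnot(inherits(slopes, "genotypeSlopes"))
    gn <- colnames(slopes$gamma)
    stats::setNames(lapply(gn, function(g) {
        callSignificant(data.frame(gene_id = rownames(slopes$gamma),
                                   beta_log2 = slopes$gamma[, g],
                                   fdr = slopes$fdr[, g],
                                   converged = slopes$converged[, g],
                                   stringsAsFactors = FALSE),
                        fdr_max, lfc_min)
    }), gn)
}

#' Intersections of per-genotype responsive gene sets
#'
#' For each named group of genotypes, intersects the per-genotype up-sets
#' and down-sets, giving e.g. the common heat-responsive genes (group of
#' all genotypes) or pool- and tolerance-class overlaps.
#'
#' @param calls a [callSignificantByGenotype()] list.
#' @param groups named list of genotype vectors; default one group `all`
#'   containing every genotype.
#' @return data frame with columns `group`, `direction`, `n`, and a
#'   comma-separated `genes` column; the gene sets are also attached as
#'   attribute `sets` (list of lists).
#' @export
overlapSets <- function(calls, groups = NULL) {
    gn <- names(calls)
    if (is.null(groups)) groups <- list(all = gn)
    bad <- setdiff(unlist(groups), gn)
    stopIf(length(bad) > 0, "unknown genotype(s) in groups: ",
           paste(bad, collapse = ", "))
    sets <- list()
    rows <- list()
    for (nm in names(groups)) {
        for (dir in c("up", "down")) {
            gs <- lapply(calls[groups[[nm]]], `[[`, dir)
            inter <- Reduce(intersect, gs)
            sets[[nm]][[dir]] <- inter
            rows[[length(rows) + 1L]] <-
                data.frame(group = nm, direction = dir,
                           n = length(inter),
                           genes = paste(inter, collapse = ","),
                           stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    attr(out, "sets") <- sets
    out
}

#' Heat-tolerance regression of expression slopes on the HSI
#'
#' Second-stage test: per gene, ordinary least squares of the per-genotype
#' expression slopes `gamma_i` on the genotypes' heat susceptibility index
#' `h_i`.  The slope `delta` measures how much a genotype's expression
#' response to heat depends on its phenotypic susceptibility.  The
#' two-sided p-value uses the t distribution with `n_genotypes - 2` df and
#' is deliberately NOT adjusted for multiple testing (the test is
#' low-powered with few genotypes, analogous to an association scan).  A
#' gene is called a heat-tolerance gene iff `p < p_max` and
#' `|delta| > delta_min` (both strict).
#'
#' @param slopes a [fitDoseResponseByGenotype()] result, or a genes x
#'   genotypes matrix of log2 slopes.
#' @param hsi named numeric vector of HSI values (or a [computeHSI()]
#'   data frame).
#' @param p_max p-value threshold (default 0.05).
#' @param delta_min absolute slope threshold (default 2).
#' @return data frame with columns `gene_id`, `delta`, `intercept`, `t`,
#'   `p`, `called`.
#' @export
toleranceRegression <- function(slopes, hsi, p_max = 0.05,
                                delta_min = 2) {
    gamma <- if (inherits(slopes, "genotypeSlopes")) slopes$gamma
             else as.matrix(slopes)
    if (is.data.frame(hsi)) hsi <- stats::setNames(hsi$hsi, hsi$genotype)
    common <- intersect(colnames(gamma), names(hsi))
    stopIf(length(common) < 3,
           "need >= 3 genotypes with both slopes and HSI")
    g <- gamma[, common, drop = FALSE]
    h <- hsi[common]
    stopIf(stats::var(h) == 0, "HSI has zero variance across genotypes")
    n <- length(h)
    hc <- h - mean(h)
    sxx <- sum(hc^2)
    gbar <- rowMeans(g)
    delta <- as.numeric(g %*% hc) / sxx
    mu <- gbar - delta * mean(h)
    fitted <- matrix(mu, nrow(g), n) + outer(delta, h)
    resid <- g - fitted
    s2 <- rowSums(resid^2) / (n - 2)
    se <- sqrt(s2 / sxx)
    tval <- delta / se
    pval <- 2 * stats::pt(-abs(tval), df = n - 2)
    pval[se == 0] <- ifelse(abs(delta[se == 0]) > 0, 0, 1)
    data.frame(gene_id = rownames(g), delta = delta, intercept = mu,
               t = tval, p = pval,
               called = pval < p_max & abs(delta) > delta_min,
               stringsAsFactors = FALSE)
}

#' Cluster heat-tolerance genes by their genotype reaction pattern
#'
#' Hierarchical clustering (Euclidean distance, complete linkage) of the
#' per-genotype slope vectors of the called tolerance genes, cut at `k`
#' clusters; typically separates genes upregulated in susceptible lines
#' from genes upregulated in tolerant lines.
#'
#' @param gamma genes x genotypes matrix of log2 slopes (called genes).
#' @param k number of clusters (default 2).
#' @return data frame with columns `gene_id`, `cluster`, `order` (leaf
#'   order of the dendrogram, for heatmap export); the `hclust` tree is
#'   attached as attribute `tree`.
#' @export
clusterToleranceGenes <- function(gamma, k = 2) {
    gamma <- as.matrix(gamma)
    stopIf(nrow(gamma) == 0, "no genes to cluster")
    if (nrow(gamma) == 1) {
        return(data.frame(gene_id = rownames(gamma), cluster = 1L,
                          order = 1L, stringsAsFactors = FALSE))
    }
    tree <- stats::hclust(stats::dist(gamma), method = "complete")
    cl <- stats::cutree(tree, k = min(k, nrow(gamma)))
    out <- data.frame(gene_id = rownames(gamma),
                      cluster = as.integer(cl),
                      order = match(seq_len(nrow(gamma)), tree$order),
                      stringsAsFactors = FALSE)
    attr(out, "tree") <- tree
    out
}
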