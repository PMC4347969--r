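#' Metric coding of heat levels
#'
#' Maps temperatures affinely onto \[0, 1\]: the lowest level becomes 0,
#' the highest 1, intermediate levels `(T - Tmin) / (Tmax - Tmin)`.  For
#' the gradient 25/32/38 C this yields 0, 7/13, 1, so one unit of the
#' regressor spans the full temperature range and dose-response slopes are
#' expressed per full gradient.
#'
#' @param levels numeric vector of at least two distinct heat levels
#'   (degrees C).
#' @return named numeric vector of codes, names are the input levels.
#' @examples
#' metricHeatCoding(c(25, 32, 38))   # 0, 7/13, 1
#' @export
metricHeatCoding <- function(levels) {
    stopIf(length(unique(levels)) < 2, "need >= 2 distinct heat levels")
    x <- (levels - min(levels)) / (max(levels) - min(levels))
    stats::setNames(x, levels)
}

#' PCA of genotype-by-level adjusted means
#'
#' Principal component analysis of the (genotype x heat level) x trait
#' matrix of adjusted entry means, after centering each trait and, by
#' default, scaling to unit variance (traits carry incommensurable
#' units).  The sign of PC1 is oriented so that the mean PC1 score
#' increases from the lowest to the highest heat level, making
#' "susceptible = steep positive PC1 trend" deterministic.
#'
#' @param means long data frame from [adjustedMeansTable()] with columns
#'   `genotype`, `heat_c`, `trait`, `mean`; must be complete.
#' @param standardize scale traits to unit variance (default TRUE).
#' @return list of class `heatPCA`: `scores` (rows = genotype-level
#'   combinations with columns `genotype`, `heat_c`, `PC1`, ...),
#'   `loadings` (trait x PC matrix), `explained` (fraction of variance
#'   per PC, summing to 1).
#' @export
pcaMeans <- function(means, standardize = TRUE) {
    w <- stats::reshape(means[, c("genotype", "heat_c", "trait", "mean")],
                        idvar = c("genotype", "heat_c"),
                        timevar = "trait", direction = "wide")
    traits <- sub("^mean\\.", "", colnames(w)[-(1:2)])
    m <- as.matrix(w[, -(1:2), drop = FALSE])
    colnames(m) <- traits
    if (anyNA(m)) {
        bad <- which(is.na(m), arr.ind = TRUE)
        stop("missing adjusted means for: ",
             paste(sprintf("(%s, %g, %s)", w$genotype[bad[, 1]],
                           w$heat_c[bad[, 1]], traits[bad[, 2]]),
                   collapse = "; "), call. = FALSE)
    }
    stopIf(nrow(m) < 2 || ncol(m) < 2,
           "need >= 2 genotype-level rows and >= 2 traits")
    if (standardize) {
        sds <- apply(m, 2L, stats::sd)
        stopIf(any(sds == 0), "zero-variance trait(s): ",
               paste(traits[sds == 0], collapse = ", "))
    }
    pc <- stats::prcomp(m, center = TRUE, scale. = standardize)
    scores <- pc$x
    loadings <- pc$rotation
    expl <- pc$sdev^2 / sum(pc$sdev^2)
    # orient PC1: mean score must increase from lowest to highest level
    hi <- w$heat_c == max(w$heat_c); lo <- w$heat_c == min(w$heat_c)
    if (mean(scores[hi, 1]) < mean(scores[lo, 1])) {
        scores[, 1] <- -scores[, 1]
        loadings[, 1] <- -loadings[, 1]
    }
    structure(list(scores = data.frame(genotype = w$genotype,
                                       heat_c = w$heat_c, scores,
                                       stringsAsFactors = FALSE),
                   loadings = loadings,
                   explained = stats::setNames(expl, colnames(scores))),
              class = "heatPCA")
}

#' @export
print.heatPCA <- function(x, ...) {
    cat("PCA of adjusted means:", nrow(x$scores), "rows x",
        nrow(x$loadings), "traits\n")
    cat("explained:", paste0(sprintf("%.1f%%",
                                     100 * utils::head(x$explained, 4)),
                             collapse = " "), "\n")
    invisible(x)
}

#' Pearson correlation of traits with PC1
#'
#' @param means adjusted means table (as for [pcaMeans()]).
#' @param pca the [pcaMeans()] result computed on the same table.
#' @return data frame with columns `trait`, `r`, `p` (two-sided, from the
#'   t transform).  Constant traits get `NA` correlations.
#' @export
correlateTraitsPC1 <- function(means, pca) {
    stopifnot(inherits(pca, "heatPCA"))
    key <- paste(pca$scores$genotype, pca$scores$heat_c)
    traits <- rownames(pca$loadings)
    out <- lapply(traits, function(tr) {
        v <- means[means$trait == tr, ]
        v <- v$mean[match(key, paste(v$genotype, v$heat_c))]
        if (stats::sd(v) == 0)
            return(data.frame(trait = tr, r = NA_real_, p = NA_real_))
        ct <- stats::cor.test(v, pca$scores$PC1)
        data.frame(trait = tr, r = unname(ct$estimate), p = ct$p.value,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Heat susceptibility index
#'
#' Per genotype, the OLS slope of its PC1 scores over the metric-coded
#' heat levels.  With PC1 oriented to increase with heat, a steep slope
#' (high HSI) marks a heat-susceptible genotype.  Genotypes present at a
#' single level only are excluded with a warning.
#'
#' @param pca a [pcaMeans()] result.
#' @param coding a [metricHeatCoding()] vector for the levels present, or
#'   `NULL` to compute it from the score table.
#' @return data frame sorted by decreasing HSI (most susceptible first)
#'   with columns `genotype`, `hsi`, `intercept`, `rank`.
#' @export
computeHSI <- function(pca, coding = NULL) {
    stopifnot(inherits(pca, "heatPCA"))
    sc <- pca$scores
    if (is.null(coding)) coding <- metricHeatCoding(sort(unique(sc$heat_c)))
    x_all <- coding[as.character(sc$heat_c)]
    stopIf(anyNA(x_all), "coding does not cover all heat levels")
    out <- lapply(split(seq_len(nrow(sc)), sc$genotype), function(i) {
        if (length(unique(sc$heat_c[i])) < 2) return(NULL)
        x <- x_all[i]; y <- sc$PC1[i]
        b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
        data.frame(genotype = sc$genotype[i][1], hsi = b,
                   intercept = mean(y) - b * mean(x),
                   stringsAsFactors = FALSE)
    })
    dropped <- names(out)[vapply(out, is.null, logical(1))]
    if (length(dropped))
        warning("excluded genotype(s) observed at a single level: ",
                paste(dropped, collapse = ", "))
    res <- do.call(rbind, out)
    res <- res[order(-res$hsi), , drop = FALSE]
    res$rank <- seq_len(nrow(res))
    rownames(res) <- NULL
    res
}
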