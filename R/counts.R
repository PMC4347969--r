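#' Counts per million
#'
#' `cpm[g, s] = counts[g, s] / (lib_size_s * norm_factor_s) * 1e6`, using
#' the effective (normalized) library size.
#'
#' @param x a [HeatCounts-class] object.
#' @return numeric matrix of CPM values, same dimensions as the counts.
#' @export
countsPerMillion <- function(x) {
    stopifnot(methods::is(x, "HeatCounts"))
    eff <- libSizes(x) * normFactors(x)
    stopIf(any(eff <= 0), "zero or negative effective library size")
    sweep(assay(x, "counts"), 2L, eff, "/") * 1e6
}

#' Expression filter on counts per million
#'
#' Keeps a gene iff it reaches at least `min_cpm` counts per million in at
#' least `min_samples` samples (both bounds inclusive), removing genes not
#' expressed at a reasonable level in any genotype-level combination.
#'
#' @param x a [HeatCounts-class] object.
#' @param min_cpm CPM threshold (default 2).
#' @param min_samples minimum number of qualifying samples (default 2).
#' @return the filtered `HeatCounts`; the dropped gene IDs are available
#'   as `metadata(result)$dropped_genes`.
#' @export
cpmFilter <- function(x, min_cpm = 2, min_samples = 2) {
    stopIf(min_cpm <= 0 || min_samples <= 0, "thresholds must be > 0")
    cpm <- countsPerMillion(x)
    keep <- rowSums(cpm >= min_cpm) >= min_samples
    out <- x[keep, ]
    metadata(out)$dropped_genes <- rownames(x)[!keep]
    out
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values factors for library-composition normalization:
#' the reference sample is the one whose upper quartile is closest to the
#' mean upper quartile; each sample's factor is the weighted mean of gene
#' log-ratios against the reference after trimming the most extreme 30
#' percent of M values and 5 percent of A values, and the factors are
#' rescaled to geometric mean 1.  Computation is delegated to edgeR's TMM
#' implementation.
#'
#' @param x a [HeatCounts-class] object (ideally CPM-filtered).
#' @param trim_m,trim_a trim fractions for log-ratios and abundances
#'   (defaults 0.30, 0.05).
#' @return the `HeatCounts` with `norm_factor` filled in `colData`.
#' @export
tmmFactors <- function(x, trim_m = 0.30, trim_a = 0.05) {
    stopifnot(methods::is(x, "HeatCounts"))
    stopIf(ncol(x) < 2, "need >= 2 samples")
    f <- edgeR::calcNormFactors(assay(x, "counts"),
                                lib.size = libSizes(x), method = "TMM",
                                logratioTrim = trim_m, sumTrim = trim_a)
    normFactors(x) <- as.numeric(f)
    x
}

#' Common negative-binomial dispersion and BCV
#'
#' Estimates a single dispersion `phi` shared by all genes by maximizing
#' the Cox-Reid adjusted profile log-likelihood, summed over genes, of the
#' NB model whose mean structure is a one-way layout on the
#' genotype-by-level cells (biological replicates within a cell are the
#' replication unit).  For each candidate `phi` the per-cell gene means
#' are profiled out by Fisher scoring with log effective library size
#' offsets; the adjustment subtracts half the log-determinant of the
#' per-gene weighted information, which removes the downward bias that
#' plain maximum likelihood has with few replicates per cell.  The search
#' maximizes over log `phi` in `interval`.  The biological coefficient of
#' variation is `sqrt(phi)`.
#'
#' @param x a [HeatCounts-class] object, filtered and normalized.
#' @param groups factor defining the replicate groups; default the
#'   genotype-by-level interaction.
#' @param interval search interval for `phi` (default `c(1e-6, 10)`).
#' @return list of class `dispersionEstimate` with `phi` and `bcv`.
#' @export
commonDispersion <- function(x, groups = NULL, interval = c(1e-6, 10)) {
    stopifnot(methods::is(x, "HeatCounts"))
    cd <- colData(x)
    if (is.null(groups))
        groups <- interaction(cd$genotype, cd$heat_c, drop = TRUE)
    groups <- as.factor(groups)
    stopIf(ncol(x) - nlevels(groups) <= 0,
           "no residual degrees of freedom for dispersion estimation")
    y <- assay(x, "counts")
    o <- log(libSizes(x) * normFactors(x))
    gidx <- as.integer(groups)
    ncell <- nlevels(groups)
    G <- nrow(y)
    # profile the per-(gene, cell) means at a given phi by Fisher scoring
    apl <- function(logphi) {
        phi <- exp(logphi)
        beta <- log((t(rowsum(t(y), gidx)) /
                     matrix(tabulate(gidx, ncell), G, ncell,
                            byrow = TRUE)) + 0.5) - mean(o)
        for (it in 1:30) {
            eta <- beta[, gidx, drop = FALSE] +
                matrix(o, G, length(o), byrow = TRUE)
            eta <- pmin(pmax(eta, -30), 30)
            mu <- exp(eta)
            w <- mu / (1 + phi * mu)
            num <- t(rowsum(t(w * (y - mu) / mu), gidx))
            den <- t(rowsum(t(w), gidx))
            step <- num / den
            beta <- beta + step
            if (max(abs(step)) < 1e-8) break
        }
        eta <- pmin(pmax(beta[, gidx, drop = FALSE] +
                         matrix(o, G, length(o), byrow = TRUE), -30), 30)
        mu <- exp(eta)
        w <- mu / (1 + phi * mu)
        ll <- sum(nbLogLik(y, mu, phi))
        cr <- 0.5 * sum(log(t(rowsum(t(w), gidx))))
        ll - cr
    }
    opt <- stats::optimize(apl, interval = log(interval), maximum = TRUE,
                           tol = 1e-6)
    phi <- exp(opt$maximum)
    structure(list(phi = phi, bcv = sqrt(phi)),
              class = "dispersionEstimate")
}

#' @export
print.dispersionEstimate <- function(x, ...) {
    cat(sprintf("common dispersion phi = %.4f (BCV = %.3f)\n",
                x$phi, x$bcv))
    invisible(x)
}

#' Sample-level expression PCA
#'
#' PCA of `log2(CPM + pseudo)` with genes centered, scoring the samples;
#' used to check that heat levels (and pools) separate in expression
#' space.
#'
#' @param x a filtered, normalized [HeatCounts-class] object.
#' @param pseudo pseudo-count added before the log (default 1).
#' @param n_top optionally restrict to the `n_top` most variable genes.
#' @return list of class `heatPCA` with sample `scores` (including
#'   `genotype` and `heat_c` columns), gene `loadings` and `explained`
#'   variance fractions.
#' @export
expressionPCA <- function(x, pseudo = 1, n_top = NULL) {
    stopifnot(methods::is(x, "HeatCounts"))
    stopIf(ncol(x) < 2, "need >= 2 samples")
    l <- log2(countsPerMillion(x) + pseudo)
    if (!is.null(n_top) && n_top < nrow(l)) {
        v <- apply(l, 1L, stats::var)
        l <- l[order(-v)[seq_len(n_top)], , drop = FALSE]
    }
    pc <- stats::prcomp(t(l), center = TRUE, scale. = FALSE)
    expl <- pc$sdev^2 / sum(pc$sdev^2)
    structure(list(scores = data.frame(genotype = colData(x)$genotype,
                                       heat_c = colData(x)$heat_c,
                                       pc$x, stringsAsFactors = FALSE),
                   loadings = pc$rotation,
                   explained = stats::setNames(expl, colnames(pc$x))),
              class = "heatPCA")
}

#' Read a count matrix and sample metadata from TSV
#'
#' The count matrix has gene IDs in the first column and one column per
#' sample; the metadata has columns `sample`, `genotype`, `heat_c`, `rep`
#' and optionally `lib_size` (defaults to column sums) and `norm_factor`.
#'
#' @param counts_path count matrix TSV.
#' @param meta_path sample metadata TSV.
#' @return a [HeatCounts-class] object.
#' @export
readCountMatrix <- function(counts_path, meta_path) {
    cnt <- utils::read.table(counts_path, sep = "\t", header = TRUE,
                             row.names = 1, check.names = FALSE)
    cnt <- as.matrix(cnt)
    meta <- readTSV(meta_path)
    stopIf(!all(colnames(cnt) %in% meta$sample),
           "samples missing from metadata: ",
           paste(setdiff(colnames(cnt), meta$sample), collapse = ", "))
    meta <- meta[match(colnames(cnt), meta$sample), ]
    HeatCounts(cnt, genotype = meta$genotype, heat_c = meta$heat_c,
               rep = meta$rep,
               lib_size = if ("lib_size" %in% names(meta)) meta$lib_size
                          else colSums(cnt),
               norm_factor = if ("norm_factor" %in% names(meta))
                                 meta$norm_factor else 1)
}

#' Write a HeatCounts object as count matrix + metadata TSVs
#' @param x a [HeatCounts-class] object.
#' @param counts_path,meta_path output paths.
#' @return invisibly, the two paths.
#' @export
writeCountMatrix <- function(x, counts_path, meta_path) {
    cnt <- data.frame(gene_id = rownames(x), assay(x, "counts"),
                      check.names = FALSE)
    writeTSV(cnt, counts_path)
    cd <- colData(x)
    writeTSV(data.frame(sample = colnames(x), genotype = cd$genotype,
                        heat_c = cd$heat_c, rep = cd$rep,
                        lib_size = cd$lib_size,
                        norm_factor = normFactors(x)),
             meta_path)
    invisible(c(counts_path, meta_path))
}
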