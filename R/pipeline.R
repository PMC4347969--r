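#' Configuration for the end-to-end gradient pipeline
#'
#' Collects every threshold and simulator setting in one object.  When no
#' input paths are given the pipeline simulates both the phenotype table
#' and the count matrix with a shared planted susceptibility per genotype,
#' so the phenotype-derived HSI and the planted expression-slope structure
#' refer to the same ground truth.  All randomness flows from the single
#' `seed`, fanned out deterministically to the stages.  Can also be read
#' from a YAML file with [readPipelineConfig()].
#'
#' @param phenotype_tsv,counts_tsv,samples_tsv optional input paths; when
#'   `NULL` the corresponding data are simulated.
#' @param annotation_tsv optional gene-to-term annotation path; when
#'   `NULL` a synthetic annotation is generated.
#' @param n_genes,n_genotypes,heat_levels,n_pheno_reps,n_count_reps
#'   simulator dimensions (defaults 2000 genes, 8 genotypes, 25/32/38 C,
#'   10 phenotype replications, 2 sequencing replicates).
#' @param bcv,frac_responsive,frac_tolerance,slope_magnitude,delta_magnitude
#'   count-simulator settings, see [countsSimConfig()].
#' @param drop_one_sample emulate the missing pooled replicate (default
#'   TRUE).
#' @param fdr_max,lfc_min FDR and absolute log2 fold-change thresholds for
#'   responsive-gene calling (defaults 0.05, 2).
#' @param p_max,delta_min thresholds for tolerance-gene calling (defaults
#'   0.05, 2).
#' @param min_cpm,min_samples CPM filter thresholds (defaults 2, 2).
#' @param q_threshold,max_lowq_frac FASTQ filter thresholds (defaults
#'   20, 0.30).
#' @param simulate_fastq run the small FASTQ simulate-and-filter stage
#'   (default TRUE).
#' @param pca_standardize standardize traits before the phenotype PCA.
#' @param genotype_mode intercept mode for the per-genotype fits, see
#'   [fitDoseResponseByGenotype()].
#' @param seed master seed.
#' @return list of class `HeatPipelineConfig`.
#' @export
heatPipelineConfig <- function(phenotype_tsv = NULL, counts_tsv = NULL,
                               samples_tsv = NULL, annotation_tsv = NULL,
                               n_genes = 2000, n_genotypes = 8,
                               heat_levels = c(25, 32, 38),
                               n_pheno_reps = 10, n_count_reps = 2,
                               bcv = 0.26, frac_responsive = 0.1,
                               frac_tolerance = 0.02,
                               slope_magnitude = 4, delta_magnitude = 4,
                               drop_one_sample = TRUE,
                               fdr_max = 0.05, lfc_min = 2,
                               p_max = 0.05, delta_min = 2,
                               min_cpm = 2, min_samples = 2,
                               q_threshold = 20, max_lowq_frac = 0.30,
                               simulate_fastq = TRUE,
                               pca_standardize = TRUE,
                               genotype_mode = "per-genotype",
                               seed = 1L) {
    cfg <- as.list(environment())
    stopIf(any(c(fdr_max, lfc_min, p_max, delta_min, min_cpm,
                 min_samples, q_threshold, max_lowq_frac) <= 0),
           "all thresholds must be positive")
    structure(cfg, class = "HeatPipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys are [heatPipelineConfig()] arguments.
#' @return list of class `HeatPipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
    stopIf(!requireNamespace("yaml", quietly = TRUE),
           "the 'yaml' package is required to read config files")
    vals <- yaml::read_yaml(path)
    do.call(heatPipelineConfig, vals)
}

#' Run the full gradient heat-stress pipeline
#'
#' Executes, in order: (optional FASTQ simulate + quality filter) ->
#' phenotype simulation or import -> adjusted entry means ->
#' repeatability -> combined-model tests -> phenotype PCA, trait-PC1
#' correlations and HSI -> count simulation or import -> CPM filter ->
#' TMM normalization -> common dispersion (BCV) -> expression PCA ->
#' overall dose-response fits and calls -> per-genotype fits and calls ->
#' overlap sets -> tolerance regression on the HSI -> tolerance-gene
#' clustering -> hypergeometric enrichment of the up- and downregulated
#' responsive sets.  Every stage writes a TSV into `out_dir`, plus a run
#' manifest and a plain-text summary.  Any stage failure aborts with a
#' stage-named message; artifacts of completed stages are retained.
#'
#' @param config a [heatPipelineConfig()] object.
#' @param out_dir artifact directory (created if needed).
#' @return invisibly, a list with the main in-memory results
#'   (`means`, `hsi`, `counts`, `dispersion`, `overall`, `slopes`,
#'   `tolerance`, `summary`).
#' @export
runHeatPipeline <- function(config, out_dir) {
    stopifnot(inherits(config, "HeatPipelineConfig"))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    seeds <- spawnSeeds(config$seed, 8L)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    p <- function(f) file.path(out_dir, f)
    summary_lines <- character()
    note <- function(...) summary_lines <<- c(summary_lines,
                                              sprintf(...))

    ## read QC stage (optional, synthetic exercise of the filter)
    if (isTRUE(config$simulate_fastq)) {
        stage("fastq", {
            fq <- p("reads.fastq")
            simulateFastq(fq, n_reads = 1000, read_len = 100,
                          frac_lowq = 0.1,
                          adapters = "AGATCGGAAGAGC",
                          frac_adapter = 0.05, seed = seeds[1])
            rep <- filterReads(fq, p("reads.filtered.fastq"),
                               q_threshold = config$q_threshold,
                               max_lowq_frac = config$max_lowq_frac,
                               adapters = "AGATCGGAAGAGC")
            writeFilterReport(rep, p("read_filter.tsv"))
            note("reads kept after QC filter: %d of %d", rep$n_kept,
                 rep$n_input)
        })
    }

    ## phenotype stage
    pheno <- stage("phenotype-input", {
        if (!is.null(config$phenotype_tsv)) {
            ph <- readTSV(config$phenotype_tsv)
            susceptibility <- NULL
            ph
        } else {
            pcfg <- phenoSimConfig(n_genotypes = config$n_genotypes,
                                   heat_levels = config$heat_levels,
                                   n_reps = config$n_pheno_reps,
                                   seed = seeds[2])
            ph <- simulatePhenotypes(pcfg)
            writeTSV(ph, p("phenotypes.tsv"))
            ph
        }
    })
    susceptibility <- attr(pheno, "susceptibility")

    means <- stage("adjusted-means", {
        m <- adjustedMeansTable(pheno)
        writeTSV(m, p("adjusted_means.tsv"))
        m
    })
    stage("repeatability", {
        vc <- do.call(rbind, lapply(unique(pheno$trait), function(tr)
            do.call(rbind, lapply(sort(unique(pheno$heat_c)), function(lv)
                varianceComponents(pheno, lv, tr)))))
        writeTSV(vc, p("repeatability.tsv"))
        note("repeatability H2 range: %.2f - %.2f", min(vc$H2),
             max(vc$H2))
    })
    stage("combined-model", {
        tst <- do.call(rbind, lapply(unique(pheno$trait), function(tr) {
            f <- combinedModelTests(pheno, tr)
            cbind(trait = tr, f$tests)
        }))
        writeTSV(tst, p("pheno_tests.tsv"))
    })

    hsi <- stage("hsi", {
        pca <- pcaMeans(means, standardize = config$pca_standardize)
        writeTSV(pca$scores, p("pheno_pca_scores.tsv"))
        writeTSV(data.frame(trait = rownames(pca$loadings),
                            pca$loadings), p("pheno_pca_loadings.tsv"))
        writeTSV(data.frame(pc = names(pca$explained),
                            explained = pca$explained),
                 p("pheno_pca_explained.tsv"))
        writeTSV(correlateTraitsPC1(means, pca), p("trait_pc1_cor.tsv"))
        h <- computeHSI(pca)
        writeTSV(h, p("hsi.tsv"))
        note("phenotype PCA: PC1 %.0f%%, PC2 %.0f%% of variance",
             100 * pca$explained[1], 100 * pca$explained[2])
        note("HSI ranking (susceptible first): %s",
             paste(h$genotype, collapse = " "))
        h
    })

    ## counts stage
    hc <- stage("counts-input", {
        if (!is.null(config$counts_tsv)) {
            readCountMatrix(config$counts_tsv, config$samples_tsv)
        } else {
            gn <- paste0("G", seq_len(config$n_genotypes))
            planted <- if (!is.null(susceptibility))
                stats::setNames(as.numeric(susceptibility), gn)
            else NULL
            ccfg <- countsSimConfig(n_genes = config$n_genes,
                                    genotypes = gn, hsi = planted,
                                    heat_levels = config$heat_levels,
                                    n_reps = config$n_count_reps,
                                    bcv = config$bcv,
                                    frac_responsive = config$frac_responsive,
                                    frac_tolerance = config$frac_tolerance,
                                    slope_magnitude = config$slope_magnitude,
                                    delta_magnitude = config$delta_magnitude,
                                    drop_one_sample = config$drop_one_sample,
                                    seed = seeds[3])
            sim <- simulateCounts(ccfg)
            writeCountMatrix(sim, p("counts.tsv"), p("samples.tsv"))
            writeTSV(data.frame(gene_id = rownames(sim),
                                as.data.frame(simTruth(sim))),
                     p("truth.tsv"))
            sim
        }
    })

    hc <- stage("cpm-filter", {
        f <- cpmFilter(hc, config$min_cpm, config$min_samples)
        note("genes passing CPM filter: %d of %d", nrow(f), nrow(hc))
        f
    })
    hc <- stage("normalize", {
        n <- tmmFactors(hc)
        writeTSV(data.frame(sample = colnames(n),
                            norm_factor = normFactors(n)),
                 p("norm_factors.tsv"))
        n
    })
    disp <- stage("dispersion", {
        d <- commonDispersion(hc)
        writeTSV(data.frame(phi = d$phi, bcv = d$bcv),
                 p("dispersion.tsv"))
        note("common dispersion: phi = %.4f, BCV = %.3f", d$phi, d$bcv)
        d
    })
    stage("expression-pca", {
        ep <- expressionPCA(hc)
        writeTSV(data.frame(sample = colnames(hc),
                            ep$scores[, c("genotype", "heat_c", "PC1",
                                          "PC2")]),
                 p("expr_pca_scores.tsv"))
        note("expression PCA: PC1 %.0f%%, PC2 %.0f%% of variance",
             100 * ep$explained[1], 100 * ep$explained[2])
    })

    overall <- stage("dge-overall", {
        f <- fitDoseResponse(hc, disp)
        calls <- callSignificant(f, config$fdr_max, config$lfc_min)
        f$call <- "none"
        f$call[f$gene_id %in% calls$up] <- "up"
        f$call[f$gene_id %in% calls$down] <- "down"
        writeTSV(f, p("dge_overall.tsv"))
        note("overall heat responsive genes: %d (%d up, %d down)",
             length(calls$up) + length(calls$down), length(calls$up),
             length(calls$down))
        list(fits = f, calls = calls)
    })

    slopes <- stage("dge-per-genotype", {
        s <- fitDoseResponseByGenotype(hc, disp,
                                       mode = config$genotype_mode)
        writeTSV(data.frame(gene_id = rownames(s$gamma), s$gamma),
                 p("gamma_matrix.tsv"))
        s
    })
    gcalls <- callSignificantByGenotype(slopes, config$fdr_max,
                                        config$lfc_min)
    stage("overlaps", {
        gn <- names(gcalls)
        rk <- hsi$genotype[hsi$genotype %in% gn]
        half <- floor(length(rk) / 2)
        groups <- list(all = gn,
                       susceptible = utils::head(rk, half),
                       tolerant = utils::tail(rk, length(rk) - half))
        ov <- overlapSets(gcalls, groups)
        percall <- data.frame(genotype = gn,
                              up = vapply(gcalls, function(z)
                                  length(z$up), integer(1)),
                              down = vapply(gcalls, function(z)
                                  length(z$down), integer(1)))
        writeTSV(percall, p("per_genotype_calls.tsv"))
        writeTSV(ov, p("overlaps.tsv"))
        common <- ov$n[ov$group == "all"]
        note("common heat responsive genes: %d up, %d down", common[1],
             common[2])
    })

    tol <- stage("tolerance", {
        tfit <- toleranceRegression(slopes, hsi, config$p_max,
                                    config$delta_min)
        writeTSV(tfit, p("tolerance.tsv"))
        note("heat tolerance genes called: %d", sum(tfit$called))
        tfit
    })
    stage("tolerance-clustering", {
        called <- tol$gene_id[tol$called]
        if (length(called) >= 2) {
            cl <- clusterToleranceGenes(slopes$gamma[called, ,
                                                     drop = FALSE])
            writeTSV(cl, p("tolerance_clusters.tsv"))
            hm <- slopes$gamma[called[order(cl$order)], , drop = FALSE]
            writeTSV(data.frame(gene_id = rownames(hm), hm),
                     p("heatmap_matrix.tsv"))
            note("tolerance gene clusters: %s",
                 paste(table(cl$cluster), collapse = " / "))
        } else note("tolerance gene clusters: too few genes to cluster")
    })

    stage("enrichment", {
        universe <- rownames(hc)
        ann <- if (!is.null(config$annotation_tsv))
            readTSV(config$annotation_tsv)
        else simulateAnnotation(universe,
                                target_set = overall$calls$up,
                                seed = seeds[4])
        for (dir in c("up", "down")) {
            gs <- intersect(overall$calls[[dir]], universe)
            res <- hypergeomEnrich(gs, ann, universe, config$fdr_max)
            writeTSV(res, p(sprintf("enrichment_%s.tsv", dir)))
            note("enriched terms (%s): %d", dir, sum(res$enriched))
        }
    })

    ## manifest + summary
    stage("manifest", {
        cfgdump <- p("config.txt")
        writeLines(paste(names(config),
                         vapply(config, function(v)
                             paste(format(v), collapse = ","),
                             character(1)),
                         sep = " = "), cfgdump)
        manifest <- data.frame(
            key = c("package", "version", "seed", "config_md5"),
            value = c("heatgrad",
                      as.character(utils::packageVersion("heatgrad")),
                      config$seed,
                      unname(tools::md5sum(cfgdump))))
        writeTSV(manifest, p("manifest.tsv"))
        writeLines(summary_lines, p("summary.txt"))
    })

    invisible(list(means = means, hsi = hsi, counts = hc,
                   dispersion = disp, overall = overall,
                   slopes = slopes, tolerance = tol,
                   summary = summary_lines))
}

#' Assemble a plain-text report from a pipeline artifact directory
#'
#' Mirrors the standard reporting surfaces of a gradient heat-stress
#' study: repeatability per trait and level, the HSI ranking,
#' per-genotype up/down counts with the overlap sets, the tolerance gene
#' table and the top enriched terms.  Missing stage outputs are listed as
#' absent, not fatal.
#'
#' @param out_dir a directory written by [runHeatPipeline()].
#' @param report_file output path (default `report.txt` inside
#'   `out_dir`).
#' @return the report path, invisibly.
#' @export
writeRunReport <- function(out_dir,
                           report_file = file.path(out_dir,
                                                   "report.txt")) {
    lines <- c("Gradient heat-stress pipeline report", "")
    grab <- function(f) {
        path <- file.path(out_dir, f)
        if (file.exists(path)) readTSV(path) else NULL
    }
    fmt <- function(df) c(utils::capture.output(print(df,
                                                      row.names = FALSE)),
                          "")
    sec <- function(title, df, absent = "  (absent)") {
        lines <<- c(lines, title)
        if (is.null(df)) lines <<- c(lines, absent, "")
        else lines <<- c(lines, fmt(df))
    }
    vc <- grab("repeatability.tsv")
    if (!is.null(vc)) {
        wide <- stats::reshape(vc[, c("trait", "heat_c", "H2")],
                               idvar = "trait", timevar = "heat_c",
                               direction = "wide")
        names(wide) <- sub("^H2\\.", "H2_", names(wide))
        sec("Repeatability per trait and heat level", wide)
    } else sec("Repeatability per trait and heat level", NULL)
    sec("HSI ranking (most susceptible first)", grab("hsi.tsv"))
    sec("Per-genotype responsive gene counts",
        grab("per_genotype_calls.tsv"))
    sec("Overlap sets", grab("overlaps.tsv"))
    tol <- grab("tolerance.tsv")
    if (!is.null(tol)) {
        called <- tol[tol$called, c("gene_id", "delta", "p")]
        if (nrow(called) == 0)
            sec("Heat tolerance genes", NULL,
                "  zero tolerance genes called")
        else sec("Heat tolerance genes", called)
    } else sec("Heat tolerance genes", NULL)
    for (dir in c("up", "down")) {
        en <- grab(sprintf("enrichment_%s.tsv", dir))
        if (!is.null(en)) en <- utils::head(en[en$enriched, ], 10)
        sec(sprintf("Enriched terms (%sregulated set)", dir), en)
    }
    writeLines(lines, report_file)
    invisible(report_file)
}
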