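#' Configuration for the phenotype simulator
#'
#' Builds the effect tables for a randomized complete block heat-gradient
#' phenotyping experiment: `n_genotypes` inbred lines grown at each heat
#' level in `heat_levels` with `n_reps` replications (blocks) per level,
#' scored for the six seedling traits of a typical gradient screen (leaf
#' growth rate, shoot dry weight, plant height, number of leaves, leaf
#' temperature, leaf greenness).
#'
#' The trait-by-level population means default to values realistic for
#' temperate maize seedlings under 25/32/38 C regimes.  Each genotype gets
#' a planted susceptibility `s_i`; its trait response to heat is amplified
#' by `1 + interaction_strength * (s_i - mean(s))`, so genotype-by-heat
#' interaction is proportional to susceptibility and a downstream
#' multi-trait index should rank genotypes by `s_i`.  The default
#' `interaction_strength` is calibrated so that the heat susceptibility
#' index recovered from the simulated phenotypes has roughly the same
#' spread as the planted susceptibility values (about one unit across a
#' diverse panel).
#'
#' @param n_genotypes number of genotypes (default 8).
#' @param genotypes genotype labels (default `G1..Gn`).
#' @param heat_levels strictly increasing heat levels in degrees C.
#' @param n_reps replications (blocks) per heat level (default 10).
#' @param traits trait names; defaults to the six standard traits.
#' @param trait_level_means matrix traits x levels of population means;
#'   default emulates a maize seedling heat screen.
#' @param susceptibility planted susceptibility per genotype; default
#'   drawn uniform on \[0.9, 1.9\] from `seed`.
#' @param interaction_strength scaling of the susceptibility-dependent
#'   genotype-by-heat interaction (default 0.25).
#' @param sigma_genotype,sigma_rep,sigma_resid standard deviations of the
#'   genotype main effect, the replication (block) effect and the residual,
#'   per trait, expressed as fractions of each trait's heat-response range
#'   (defaults 0.08, 0.05, 0.12).
#' @param seed integer seed.
#'
#' @return A list of class `PhenoSimConfig`.
#' @seealso [simulatePhenotypes()]
#' @export
phenoSimConfig <- function(n_genotypes = 8,
                           genotypes = paste0("G", seq_len(n_genotypes)),
                           heat_levels = c(25, 32, 38),
                           n_reps = 10,
                           traits = c("growth_rate", "dry_weight",
                                      "plant_height", "n_leaves",
                                      "leaf_temp", "leaf_greenness"),
                           trait_level_means = NULL,
                           susceptibility = NULL,
                           interaction_strength = 0.25,
                           sigma_genotype = 0.08,
                           sigma_rep = 0.05,
                           sigma_resid = 0.12,
                           seed = 1L) {
    stopIf(n_reps < 1, "n_reps must be >= 1")
    stopIf(is.unsorted(heat_levels, strictly = TRUE),
           "heat_levels must be strictly increasing")
    stopIf(any(c(sigma_genotype, sigma_rep, sigma_resid) < 0),
           "all sigmas must be >= 0")
    n_genotypes <- length(genotypes)
    if (is.null(trait_level_means)) {
        ref <- rbind(growth_rate   = c(0.24, 0.29, 0.19),
                     dry_weight    = c(2.02, 1.55, 0.62),
                     plant_height  = c(21.9, 20.6, 12.5),
                     n_leaves      = c(3.5, 4.4, 4.6),
                     leaf_temp     = c(24.7, 31.8, 36.4),
                     leaf_greenness = c(47.1, 34.2, 29.4))
        x <- (heat_levels - min(heat_levels)) /
            (max(heat_levels) - min(heat_levels))
        trait_level_means <- matrix(NA_real_, length(traits),
                                    length(heat_levels),
                                    dimnames = list(traits, heat_levels))
        for (i in seq_along(traits)) {
            r <- ref[((i - 1) %% nrow(ref)) + 1, ]
            # interpolate the reference three-point profile onto the grid
            trait_level_means[i, ] <- stats::approx(c(0, 7 / 13, 1), r,
                                                    xout = x, rule = 2)$y
        }
    }
    if (is.null(susceptibility))
        susceptibility <- withSeed(seed,
            stats::runif(n_genotypes, 0.9, 1.9))
    names(susceptibility) <- genotypes
    # per-trait scale of noise terms: fraction of the heat-response range
    rng <- apply(trait_level_means, 1L, function(v) max(abs(diff(range(v))),
                                                        1e-8))
    structure(list(genotypes = genotypes, heat_levels = heat_levels,
                   n_reps = as.integer(n_reps), traits = traits,
                   trait_level_means = trait_level_means,
                   susceptibility = susceptibility,
                   interaction_strength = interaction_strength,
                   sigma_genotype = sigma_genotype * rng,
                   sigma_rep = sigma_rep * rng,
                   sigma_resid = sigma_resid * rng,
                   seed = as.integer(seed)),
              class = "PhenoSimConfig")
}

#' Simulate a long-format phenotype table
#'
#' Draws one observation per genotype x heat level x replication x trait
#' following the combined gradient model: trait value = trait-by-level
#' mean + genotype main effect + susceptibility-scaled genotype-by-heat
#' interaction + replication (block within level) effect + residual, with
#' block and residual effects drawn from zero-mean normal distributions.
#' Reproducible given `cfg$seed`.
#'
#' @param cfg a [phenoSimConfig()] object.
#' @return data frame with columns `genotype`, `heat_c`, `rep`, `trait`,
#'   `value`, plus attribute `susceptibility` (the planted ranking truth).
#' @examples
#' ph <- simulatePhenotypes(phenoSimConfig(n_reps = 2, seed = 7))
#' head(ph)
#' @export
simulatePhenotypes <- function(cfg) {
    stopifnot(inherits(cfg, "PhenoSimConfig"))
    gn <- cfg$genotypes; lv <- cfg$heat_levels; tr <- cfg$traits
    x <- (lv - min(lv)) / (max(lv) - min(lv))
    s <- cfg$susceptibility
    withSeed(cfg$seed, {
        # genotype main effects per trait
        Imat <- matrix(stats::rnorm(length(tr) * length(gn)),
                       length(tr), length(gn),
                       dimnames = list(tr, gn)) * cfg$sigma_genotype
        out <- vector("list", length(tr))
        for (ti in seq_along(tr)) {
            mu_j <- cfg$trait_level_means[ti, ]
            delta_t <- mu_j[length(lv)] - mu_j[1]   # heat-response range
            # block effects: one per (level, rep)
            Rjk <- matrix(stats::rnorm(length(lv) * cfg$n_reps,
                                       sd = cfg$sigma_rep[ti]),
                          length(lv), cfg$n_reps)
            cell <- expand.grid(genotype = gn, heat_c = lv,
                                rep = seq_len(cfg$n_reps),
                                KEEP.OUT.ATTRS = FALSE,
                                stringsAsFactors = FALSE)
            gi <- match(cell$genotype, gn)
            ji <- match(cell$heat_c, lv)
            inter <- cfg$interaction_strength * (s[gi] - mean(s)) *
                x[ji] * delta_t
            val <- mu_j[ji] + Imat[ti, gi] + inter +
                Rjk[cbind(ji, cell$rep)] +
                stats::rnorm(nrow(cell), sd = cfg$sigma_resid[ti])
            out[[ti]] <- data.frame(cell, trait = tr[ti], value = val,
                                    stringsAsFactors = FALSE)
        }
        res <- do.call(rbind, out)
        res <- res[, c("genotype", "heat_c", "rep", "trait", "value")]
        rownames(res) <- NULL
        attr(res, "susceptibility") <- s
        res
    })
}

#' Configuration for the count-matrix simulator
#'
#' Defines a negative-binomial RNA-seq simulation over a heat gradient:
#' each sample's counts are NB with mean
#' `lib_size * q_g * 2^(gamma_ig * x_j)` and dispersion `phi = bcv^2`,
#' where `q_g` are log-normal relative abundances, `x_j` the metric heat
#' coding and `gamma_ig` the planted per-genotype log2 slope.  Three gene
#' classes are planted: null (`gamma = 0`), responsive (common slope
#' `+/- slope_magnitude` in every genotype) and tolerance genes, whose
#' genotype slopes are `h_i * delta_g` with `delta_g = +/- delta_magnitude`
#' and `h_i` the planted susceptibility index.
#'
#' @param n_genes number of genes (default 2000).
#' @param genotypes genotype labels (default 8 lines `G1..G8`).
#' @param hsi planted susceptibility per genotype; default uniform on
#'   \[0.9, 1.9\] from `seed`.
#' @param heat_levels heat levels in degrees C (default 25, 32, 38).
#' @param n_reps sequencing replicates per genotype-level cell (default 2).
#' @param lib_sizes nominal library size per sample; default uniform on
#'   0.5e6 to 2e6 (a desk-scale stand-in for deep libraries).
#' @param bcv biological coefficient of variation (default 0.26);
#'   dispersion is `bcv^2`.
#' @param frac_responsive fraction of genes with a common nonzero slope.
#' @param frac_tolerance fraction of genes with HSI-dependent slopes.
#' @param slope_magnitude absolute common slope, log2 units over the full
#'   gradient (default 4).
#' @param delta_magnitude absolute tolerance slope `delta` (default 4).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   unnormalized baseline abundances.
#' @param drop_one_sample drop one randomly chosen sample, emulating a
#'   design with one missing pooled replicate (default TRUE).
#' @param seed integer seed.
#' @return A list of class `CountsSimConfig`.
#' @seealso [simulateCounts()]
#' @export
countsSimConfig <- function(n_genes = 2000,
                            genotypes = paste0("G", 1:8),
                            hsi = NULL,
                            heat_levels = c(25, 32, 38),
                            n_reps = 2,
                            lib_sizes = NULL,
                            bcv = 0.26,
                            frac_responsive = 0.1,
                            frac_tolerance = 0.02,
                            slope_magnitude = 4,
                            delta_magnitude = 4,
                            baseline_meanlog = log(100),
                            baseline_sdlog = 1,
                            drop_one_sample = TRUE,
                            seed = 1L) {
    stopIf(length(genotypes) == 0, "at least one genotype is required")
    stopIf(bcv < 0, "bcv must be >= 0")
    stopIf(frac_responsive < 0 || frac_responsive > 1 ||
           frac_tolerance < 0 || frac_tolerance > 1,
           "fractions must be in [0, 1]")
    stopIf(frac_responsive + frac_tolerance > 1,
           "frac_responsive + frac_tolerance must be <= 1")
    stopIf(is.unsorted(heat_levels, strictly = TRUE),
           "heat_levels must be strictly increasing")
    if (is.null(hsi))
        hsi <- withSeed(seed + 1L, stats::runif(length(genotypes), 0.9, 1.9))
    names(hsi) <- genotypes
    structure(list(n_genes = as.integer(n_genes), genotypes = genotypes,
                   hsi = hsi, heat_levels = heat_levels,
                   n_reps = as.integer(n_reps), lib_sizes = lib_sizes,
                   bcv = bcv, frac_responsive = frac_responsive,
                   frac_tolerance = frac_tolerance,
                   slope_magnitude = slope_magnitude,
                   delta_magnitude = delta_magnitude,
                   baseline_meanlog = baseline_meanlog,
                   baseline_sdlog = baseline_sdlog,
                   drop_one_sample = isTRUE(drop_one_sample),
                   seed = as.integer(seed)),
              class = "CountsSimConfig")
}

#' Simulate a heat-gradient count matrix with planted truth
#'
#' @param cfg a [countsSimConfig()] object.
#' @return A [HeatCounts-class] object.  `rowData` holds the planted truth
#'   (`status`, `beta`, `delta` and the per-genotype slopes
#'   `gamma_<genotype>`); `metadata(x)$hsi` holds the planted
#'   susceptibility values.
#' @examples
#' hc <- simulateCounts(countsSimConfig(n_genes = 50, seed = 3))
#' table(simTruth(hc)$status)
#' @export
simulateCounts <- function(cfg) {
    stopifnot(inherits(cfg, "CountsSimConfig"))
    gn <- cfg$genotypes; lv <- cfg$heat_levels
    x <- (lv - min(lv)) / (max(lv) - min(lv))
    samp <- expand.grid(rep = seq_len(cfg$n_reps), heat_c = lv,
                        genotype = gn, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    samp <- samp[, c("genotype", "heat_c", "rep")]
    samp$sample <- sprintf("%s_T%g_R%d", samp$genotype, samp$heat_c,
                           samp$rep)
    S <- nrow(samp)
    G <- cfg$n_genes
    withSeed(cfg$seed, {
        if (is.null(cfg$lib_sizes))
            lib <- round(stats::runif(S, 0.5e6, 2e6))
        else lib <- rep_len(cfg$lib_sizes, S)
        q <- stats::rlnorm(G, cfg$baseline_meanlog, cfg$baseline_sdlog)
        q <- q / sum(q)
        nR <- round(cfg$frac_responsive * G)
        nT <- round(cfg$frac_tolerance * G)
        status <- rep("null", G)
        idx <- sample.int(G, nR + nT)
        status[idx[seq_len(nR)]] <- "responsive"
        if (nT > 0) status[idx[nR + seq_len(nT)]] <- "tolerance"
        beta <- numeric(G)
        delta <- numeric(G)
        sgn <- function(n) sample(c(-1, 1), n, replace = TRUE)
        beta[status == "responsive"] <- sgn(nR) * cfg$slope_magnitude
        delta[status == "tolerance"] <- sgn(nT) * cfg$delta_magnitude
        # per-genotype log2 slopes
        gamma <- matrix(0, G, length(gn), dimnames = list(NULL, gn))
        gamma[status == "responsive", ] <- beta[status == "responsive"]
        for (j in seq_along(gn))
            gamma[status == "tolerance", j] <-
                cfg$hsi[j] * delta[status == "tolerance"]
        gi <- match(samp$genotype, gn)
        ji <- match(samp$heat_c, lv)
        mu <- outer(q, lib) * 2^(gamma[, gi] * rep(x[ji], each = G))
        phi <- cfg$bcv^2
        counts <- if (phi > 0) {
            matrix(stats::rnbinom(G * S, size = 1 / phi, mu = mu), G, S)
        } else {
            matrix(stats::rpois(G * S, lambda = mu), G, S)
        }
        if (cfg$drop_one_sample && S > 1) {
            drop <- sample.int(S, 1)
            counts <- counts[, -drop, drop = FALSE]
            samp <- samp[-drop, , drop = FALSE]
            gi <- gi[-drop]
        }
        gene_ids <- sprintf("gene%05d", seq_len(G))
        dimnames(counts) <- list(gene_ids, samp$sample)
        hc <- HeatCounts(counts, genotype = samp$genotype,
                         heat_c = samp$heat_c, rep = samp$rep)
        truth <- DataFrame(status = status, beta = beta, delta = delta,
                           baseline_q = q, row.names = gene_ids)
        gcols <- DataFrame(gamma)
        colnames(gcols) <- paste0("gamma_", gn)
        rowData(hc) <- cbind(truth, gcols)
        metadata(hc)$hsi <- cfg$hsi
        metadata(hc)$bcv <- cfg$bcv
        hc
    })
}

#' Simulate a FASTQ file with planted low-quality and adapter reads
#'
#' Writes Phred+33 single-end reads of length `read_len`.  A planted
#' fraction `frac_lowq` of reads has more than 30 percent of bases at
#' quality <= 20 (they should be removed by [filterReads()] at default
#' settings); a disjoint fraction `frac_adapter` carries `adapters[1]` as
#' an exact substring; the remainder are clean (all bases above Q20, no
#' adapter).
#'
#' @param path output FASTQ path.
#' @param n_reads number of reads.
#' @param read_len read length in bases (default 100).
#' @param frac_lowq fraction of planted low-quality reads.
#' @param adapters character vector of adapter sequences (first is planted).
#' @param frac_adapter fraction of planted adapter-containing reads.
#' @param seed integer seed.
#' @return Invisibly, a list with `path` and the planted read IDs
#'   (`lowq_ids`, `adapter_ids`).
#' @export
simulateFastq <- function(path, n_reads, read_len = 100,
                          frac_lowq = 0, adapters = character(),
                          frac_adapter = 0, seed = 1L) {
    stopIf(frac_lowq < 0 || frac_lowq > 1 ||
           frac_adapter < 0 || frac_adapter > 1,
           "fractions must be in [0, 1]")
    stopIf(frac_adapter > 0 && length(adapters) == 0,
           "frac_adapter > 0 requires an adapter sequence")
    stopIf(frac_adapter > 0 && nchar(adapters[1]) > read_len,
           "read_len must be >= adapter length")
    withSeed(seed, {
        n_low <- round(frac_lowq * n_reads)
        n_ad <- round(frac_adapter * n_reads)
        stopIf(n_low + n_ad > n_reads,
               "planted fractions exceed the number of reads")
        ids <- sprintf("read%06d", seq_len(n_reads))
        randseq <- function(n, len)
            vapply(seq_len(n), function(i)
                paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                      collapse = ""), character(1))
        seqs <- randseq(n_reads, read_len)
        # plant the adapter into the middle of the chosen reads
        kind <- rep("clean", n_reads)
        if (n_low > 0) kind[seq_len(n_low)] <- "lowq"
        if (n_ad > 0) kind[n_low + seq_len(n_ad)] <- "adapter"
        kind <- sample(kind)                  # shuffle positions
        ad_idx <- which(kind == "adapter")
        low_idx <- which(kind == "lowq")
        if (length(ad_idx)) {
            ad <- adapters[1]
            pos <- sample.int(read_len - nchar(ad) + 1, length(ad_idx),
                              replace = TRUE)
            for (k in seq_along(ad_idx)) {
                s <- seqs[ad_idx[k]]
                substr(s, pos[k], pos[k] + nchar(ad) - 1) <- ad
                seqs[ad_idx[k]] <- s
            }
        }
        # make sure no unplanted read contains an adapter by chance
        if (length(adapters)) {
            dna <- Biostrings::DNAStringSet(seqs)
            hit <- rep(FALSE, n_reads)
            for (ad in adapters)
                hit <- hit | Biostrings::vcountPattern(ad, dna) > 0
            redo <- setdiff(which(hit), ad_idx)
            while (length(redo)) {
                seqs[redo] <- randseq(length(redo), read_len)
                dna <- Biostrings::DNAStringSet(seqs[redo])
                still <- rep(FALSE, length(redo))
                for (ad in adapters)
                    still <- still | Biostrings::vcountPattern(ad, dna) > 0
                redo <- redo[still]
            }
        }
        # qualities: clean reads all > Q20; low-quality reads get 40% of
        # bases at Q <= 20 (strictly above the 30% exclusion bound)
        quals <- matrix(sample(28:40, n_reads * read_len, replace = TRUE),
                        n_reads, read_len)
        if (length(low_idx)) {
            n_bad <- ceiling(0.4 * read_len)
            for (i in low_idx) {
                bad <- sample.int(read_len, n_bad)
                quals[i, bad] <- sample(2:20, n_bad, replace = TRUE)
            }
        }
        qstr <- apply(quals, 1L, function(q)
            rawToChar(as.raw(q + 33L)))
        reads <- Biostrings::QualityScaledDNAStringSet(
            Biostrings::DNAStringSet(stats::setNames(seqs, ids)),
            Biostrings::PhredQuality(qstr))
        Biostrings::writeQualityScaledXStringSet(reads, path)
        invisible(list(path = path, lowq_ids = ids[low_idx],
                       adapter_ids = ids[ad_idx]))
    })
}

#' Simulate a gene-to-category annotation map
#'
#' Random two-column annotation (gene, term) over a gene universe, with
#' optional planted enriched terms: each planted term draws a share
#' `enrich_frac` of its genes from `target_set` instead of the whole
#' universe, producing real enrichment signal for [hypergeomEnrich()].
#'
#' @param gene_ids universe of gene identifiers.
#' @param n_terms number of annotation terms (default 30).
#' @param term_size_range range of genes per term (default 10 to 100).
#' @param target_set genes from which planted terms preferentially draw.
#' @param n_enriched number of planted enriched terms (default 3).
#' @param enrich_frac fraction of a planted term's genes taken from
#'   `target_set` (default 0.5).
#' @param seed integer seed.
#' @return data frame with columns `gene_id`, `term_id`.
#' @export
simulateAnnotation <- function(gene_ids, n_terms = 30,
                               term_size_range = c(10, 100),
                               target_set = character(),
                               n_enriched = 3, enrich_frac = 0.5,
                               seed = 1L) {
    withSeed(seed, {
        out <- vector("list", n_terms)
        n_enriched <- min(n_enriched, n_terms)
        for (t in seq_len(n_terms)) {
            sz <- sample(term_size_range[1]:term_size_range[2], 1)
            sz <- min(sz, length(gene_ids))
            if (t <= n_enriched && length(target_set)) {
                k <- min(round(enrich_frac * sz), length(target_set))
                genes <- c(sample(target_set, k),
                           sample(setdiff(gene_ids, target_set), sz - k))
            } else genes <- sample(gene_ids, sz)
            out[[t]] <- data.frame(gene_id = unique(genes),
                                   term_id = sprintf("TERM%03d", t),
                                   stringsAsFactors = FALSE)
        }
        do.call(rbind, out)
    })
}
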