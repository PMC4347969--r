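#' Adjusted entry means (BLUEs) at one heat level
#'
#' Best linear unbiased estimates of the genotype means for one trait at
#' one heat level from the randomized-complete-block model
#' `value = mu + genotype(fixed) + replication(random) + error`, fitted by
#' REML.  For balanced complete data the BLUEs equal the arithmetic
#' per-genotype means for any replication variance, so a balanced input
#' takes the exact arithmetic path ("mean"); unbalanced data are fitted
#' with `lme4`.  With a single replication the means equal the raw
#' observations.
#'
#' @param records long-format phenotype data frame with columns
#'   `genotype`, `heat_c`, `rep`, `trait`, `value`.
#' @param heat_c the heat level to analyse.
#' @param trait the trait to analyse.
#' @param method `"auto"` (arithmetic path when balanced, REML otherwise),
#'   `"reml"` (always mixed model) or `"mean"` (always arithmetic).
#' @param genotypes optional genotype set to report; genotypes without
#'   observations are reported as `NA`, never imputed.
#' @return data frame with columns `genotype`, `mean`, `n_obs`.
#' @examples
#' ph <- data.frame(genotype = rep(c("A", "B"), each = 2), heat_c = 25,
#'                  rep = c(1, 2, 1, 2), trait = "t",
#'                  value = c(2, 4, 6, 8))
#' adjustedEntryMeans(ph, 25, "t")   # A: 3, B: 7
#' @export
adjustedEntryMeans <- function(records, heat_c, trait,
                               method = c("auto", "reml", "mean"),
                               genotypes = NULL) {
    method <- match.arg(method)
    d <- records[records$heat_c == heat_c & records$trait == trait, ,
                 drop = FALSE]
    stopIf(nrow(d) == 0, "no observations at heat level ", heat_c,
           " for trait '", trait, "'")
    stopIf(anyDuplicated(d[, c("genotype", "rep")]) > 0,
           "duplicate (genotype, rep) observations")
    if (is.null(genotypes)) genotypes <- unique(d$genotype)
    tab <- table(factor(d$genotype, levels = genotypes), d$rep)
    balanced <- all(tab == 1)
    single_rep <- length(unique(d$rep)) < 2
    est <- if (method == "mean" || single_rep ||
               (method == "auto" && balanced)) {
        tapply(d$value, factor(d$genotype, levels = genotypes), mean)
    } else {
        fit <- lme4::lmer(value ~ 0 + genotype + (1 | repf),
                          data = transform(d,
                                           genotype = factor(genotype,
                                                             levels = genotypes),
                                           repf = factor(rep)),
                          REML = TRUE,
                          control = lme4::lmerControl(
                              check.conv.singular = "ignore"))
        fe <- lme4::fixef(fit)
        stats::setNames(fe[paste0("genotype", genotypes)], genotypes)
    }
    data.frame(genotype = genotypes, mean = as.numeric(est),
               n_obs = as.integer(rowSums(tab)),
               stringsAsFactors = FALSE)
}

#' Table of adjusted entry means over all levels and traits
#'
#' Applies [adjustedEntryMeans()] to every heat level x trait combination.
#'
#' @inheritParams adjustedEntryMeans
#' @return long data frame with columns `genotype`, `heat_c`, `trait`,
#'   `mean`.
#' @export
adjustedMeansTable <- function(records, method = c("auto", "reml", "mean")) {
    method <- match.arg(method)
    gn <- unique(records$genotype)
    out <- list()
    for (lv in sort(unique(records$heat_c)))
        for (tr in unique(records$trait)) {
            m <- adjustedEntryMeans(records, lv, tr, method = method,
                                    genotypes = gn)
            out[[length(out) + 1L]] <- data.frame(genotype = m$genotype,
                                                  heat_c = lv, trait = tr,
                                                  mean = m$mean,
                                                  stringsAsFactors = FALSE)
        }
    do.call(rbind, out)
}

#' Variance components and inputs to repeatability at one heat level
#'
#' Estimates the genotypic variance and residual variance for one trait at
#' one heat level from the block model with genotype and replication both
#' random.  Balanced complete data use the exact ANOVA expected-mean-square
#' solution (identical to REML away from the boundary, with negative
#' estimates truncated at zero); unbalanced data are fitted by REML via
#' `lme4`.
#'
#' @inheritParams adjustedEntryMeans
#' @param method `"auto"`, `"reml"` or `"anova"` (balanced only).
#' @return data frame with one row: `trait`, `heat_c`, `sigma2_genotype`,
#'   `sigma2_resid`, `n_reps`, `H2` (see [repeatability()]).
#' @export
varianceComponents <- function(records, heat_c, trait,
                               method = c("auto", "reml", "anova")) {
    method <- match.arg(method)
    d <- records[records$heat_c == heat_c & records$trait == trait, ,
                 drop = FALSE]
    gf <- factor(d$genotype); rf <- factor(d$rep)
    stopIf(nlevels(gf) < 2, "need >= 2 genotypes")
    stopIf(nlevels(rf) < 2, "need >= 2 replications")
    n_reps <- nlevels(rf)
    balanced <- all(table(gf, rf) == 1)
    if (stats::var(d$value) == 0) {
        warning("all values identical; variances set to 0")
        s2g <- s2e <- 0
    } else if (method == "anova" || (method == "auto" && balanced)) {
        stopIf(!balanced, "method 'anova' needs balanced complete data")
        a <- nlevels(gf); r <- nlevels(rf)
        gm <- mean(d$value)
        ssg <- r * sum((tapply(d$value, gf, mean) - gm)^2)
        ssr <- a * sum((tapply(d$value, rf, mean) - gm)^2)
        sst <- sum((d$value - gm)^2)
        mse <- (sst - ssg - ssr) / ((a - 1) * (r - 1))
        msg <- ssg / (a - 1)
        s2g <- max((msg - mse) / r, 0)
        s2e <- mse
    } else {
        fit <- lme4::lmer(value ~ 1 + (1 | gf) + (1 | rf),
                          data = data.frame(value = d$value, gf = gf,
                                            rf = rf),
                          REML = TRUE,
                          control = lme4::lmerControl(
                              check.conv.singular = "ignore"))
        vc <- as.data.frame(lme4::VarCorr(fit))
        s2g <- vc$vcov[vc$grp == "gf"]
        s2e <- vc$vcov[vc$grp == "Residual"]
    }
    data.frame(trait = trait, heat_c = heat_c, sigma2_genotype = s2g,
               sigma2_resid = s2e, n_reps = n_reps,
               H2 = repeatability(s2g, s2e, n_reps),
               stringsAsFactors = FALSE)
}

#' Repeatability of entry means
#'
#' `H2 = sigma2_genotype / (sigma2_genotype + sigma2_resid / n)`: the
#' fraction of the variance of a genotype's entry mean (over `n`
#' replications) that is genotypic.  Both variances zero is degenerate and
#' returns 0 with a warning.
#'
#' @param sigma2_genotype genotypic variance (>= 0).
#' @param sigma2_resid residual variance (>= 0).
#' @param n number of replications (>= 1).
#' @return repeatability in \[0, 1\].
#' @examples
#' repeatability(1, 1, 10)   # 10/11
#' @export
repeatability <- function(sigma2_genotype, sigma2_resid, n) {
    stopIf(n < 1, "n must be >= 1")
    stopIf(sigma2_genotype < 0 || sigma2_resid < 0,
           "variances must be >= 0")
    if (sigma2_genotype == 0 && sigma2_resid == 0) {
        warning("both variance components are 0; H2 set to 0")
        return(0)
    }
    sigma2_genotype / (sigma2_genotype + sigma2_resid / n)
}

#' Combined-model fixed-effect tests across heat levels
#'
#' Fits the combined gradient model
#' `value = mu + genotype + heat + genotype:heat + block(random) + error`,
#' where the block is the replication nested within heat level, and tests
#' the fixed genotype, heat-level and interaction effects by Wald F.
#' Effects use sum-to-zero contrasts, so the reported coefficients are
#' deviations from the general mean.  For balanced complete data the mixed
#' model F statistics coincide with the classical ANOVA F values with
#' replication-within-level as block stratum, which is the fast `"anova"`
#' path; `"reml"` fits the mixed model via `lmerTest` with Satterthwaite
#' denominator degrees of freedom.
#'
#' @inheritParams adjustedEntryMeans
#' @param method `"auto"`, `"reml"` or `"anova"`.
#' @return object of class `phenoFit`: a list with `tests` (data frame
#'   with `term`, `df1`, `df2`, `F`, `p`), `effects` (sum-to-zero fixed
#'   effect estimates), `degenerate` flag and `method`.
#' @export
combinedModelTests <- function(records, trait,
                               method = c("auto", "reml", "anova")) {
    method <- match.arg(method)
    d <- records[records$trait == trait, , drop = FALSE]
    gf <- factor(d$genotype); hf <- factor(d$heat_c); rf <- factor(d$rep)
    stopIf(nlevels(gf) < 2 || nlevels(hf) < 2,
           "need >= 2 genotypes and >= 2 heat levels")
    balanced <- all(table(gf, hf, rf) == 1)
    if (stats::var(d$value) == 0) {
        warning("all responses identical; F tests undefined")
        return(structure(list(tests = data.frame(term = c("genotype",
                                                          "heat", "genotype:heat"),
                                                 df1 = NA, df2 = NA,
                                                 F = NA, p = NA),
                              effects = NULL, degenerate = TRUE,
                              method = method),
                         class = "phenoFit"))
    }
    dd <- data.frame(value = d$value, genotype = gf, heat = hf,
                     block = interaction(hf, rf, drop = TRUE))
    if (method == "anova" || (method == "auto" && balanced)) {
        stopIf(!balanced, "method 'anova' needs balanced complete data")
        fit <- stats::aov(value ~ genotype * heat + Error(block),
                          data = dd)
        sm <- summary(fit)
        blk <- as.data.frame(sm[["Error: block"]][[1]])
        wth <- as.data.frame(sm[["Error: Within"]][[1]])
        rn <- function(x) trimws(rownames(x))
        pick <- function(tab, term) {
            i <- match(term, rn(tab))
            c(df1 = tab$Df[i], F = tab$`F value`[i], p = tab$`Pr(>F)`[i],
              df2 = tab$Df[match("Residuals", rn(tab))])
        }
        g <- pick(wth, "genotype"); i2 <- pick(wth, "genotype:heat")
        h <- pick(blk, "heat")
        tests <- data.frame(term = c("genotype", "heat", "genotype:heat"),
                            df1 = c(g["df1"], h["df1"], i2["df1"]),
                            df2 = c(g["df2"], h["df2"], i2["df2"]),
                            F = c(g["F"], h["F"], i2["F"]),
                            p = c(g["p"], h["p"], i2["p"]))
        eff <- stats::aov(value ~ genotype * heat, data = dd,
                          contrasts = list(genotype = "contr.sum",
                                           heat = "contr.sum"))
        coefs <- stats::coef(eff)
        used <- "anova"
    } else {
        fit <- lmerTest::lmer(value ~ genotype * heat + (1 | block),
                              data = dd, REML = TRUE,
                              contrasts = list(genotype = "contr.sum",
                                               heat = "contr.sum"),
                              control = lme4::lmerControl(
                                  check.conv.singular = "ignore"))
        an <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
        idx <- match(c("genotype", "heat", "genotype:heat"), rownames(an))
        tests <- data.frame(term = c("genotype", "heat", "genotype:heat"),
                            df1 = an$NumDF[idx], df2 = an$DenDF[idx],
                            F = an$`F value`[idx], p = an$`Pr(>F)`[idx])
        coefs <- lme4::fixef(fit)
        used <- "reml"
    }
    rownames(tests) <- NULL
    structure(list(tests = tests, effects = coefs, degenerate = FALSE,
                   method = used),
              class = "phenoFit")
}

#' @export
print.phenoFit <- function(x, ...) {
    cat("Combined-model fixed-effect tests (", x$method, ")\n", sep = "")
    if (x$degenerate) cat("  degenerate fit: all responses identical\n")
    print(x$tests, row.names = FALSE)
    invisible(x)
}
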