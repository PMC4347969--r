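# Independent oracles used across tests.  Each is a brute-force or
# closed-form computation kept deliberately separate from the package's
# own code paths.

# simple-regression closed form: slope, intercept, t and two-sided p
olsOracle <- function(x, y) {
    n <- length(x)
    b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    a <- mean(y) - b * mean(x)
    res <- y - a - b * x
    s2 <- sum(res^2) / (n - 2)
    se <- sqrt(s2 / sum((x - mean(x))^2))
    tval <- b / se
    list(slope = b, intercept = a, t = tval,
         p = 2 * pt(-abs(tval), df = n - 2))
}

# Benjamini-Hochberg step-up by direct enumeration
bhOracle <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- rep(NA_real_, n)
    running <- 1
    for (i in n:1) {
        running <- min(running, p[o[i]] * n / i)
        adj[o[i]] <- running
    }
    adj
}

# hypergeometric upper tail P(X >= k) by exhaustive enumeration over all
# C(N, K) draws; feasible for N <= 12
hyperOracle <- function(N, n, K, k) {
    draws <- combn(N, K)
    annotated <- seq_len(n)     # first n universe elements carry the term
    hits <- apply(draws, 2L, function(d) sum(d %in% annotated))
    mean(hits >= k)
}

# REML for y = X b + Z u + e with one random factor, by brute-force grid
# search over the variance ratio lambda = sigma2_u / sigma2_e; returns the
# GLS fixed effects at the optimum
gridRemlOracle <- function(y, X, Z, lambdas = exp(seq(-12, 12, by = 0.01))) {
    n <- length(y); p <- qr(X)$rank
    best <- NULL; best_ll <- -Inf
    for (lam in lambdas) {
        V <- diag(n) + lam * tcrossprod(Z)
        Vi <- solve(V)
        XtViX <- t(X) %*% Vi %*% X
        b <- solve(XtViX, t(X) %*% Vi %*% y)
        r <- y - X %*% b
        quad <- as.numeric(t(r) %*% Vi %*% r)
        ll <- -0.5 * (determinant(V)$modulus +
                      determinant(XtViX)$modulus +
                      (n - p) * log(quad))
        if (ll > best_ll) {
            best_ll <- ll
            best <- list(lambda = lam, beta = as.numeric(b))
        }
    }
    best
}

# TMM factor for one sample against a reference, coded directly from the
# trimmed weighted-mean-of-M-values definition
tmmOracle <- function(obs, ref, lib_obs = sum(obs), lib_ref = sum(ref),
                      trim_m = 0.30, trim_a = 0.05) {
    keep <- obs > 0 & ref > 0
    obs <- obs[keep]; ref <- ref[keep]
    M <- log2((obs / lib_obs) / (ref / lib_ref))
    A <- 0.5 * log2((obs / lib_obs) * (ref / lib_ref))
    w <- (lib_obs - obs) / (lib_obs * obs) +
        (lib_ref - ref) / (lib_ref * ref)
    fin <- is.finite(M) & is.finite(A) & A > -1e10
    M <- M[fin]; A <- A[fin]; w <- w[fin]
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
        rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
}

# small balanced phenotype table builder
phenoToy <- function(genotype_means, n_reps, sd = 0, seed = 1,
                     heat_c = 25, trait = "t") {
    set.seed(seed)
    g <- names(genotype_means)
    d <- expand.grid(genotype = g, rep = seq_len(n_reps),
                     stringsAsFactors = FALSE)
    d$heat_c <- heat_c
    d$trait <- trait
    d$value <- genotype_means[d$genotype] + rnorm(nrow(d), sd = sd)
    d
}
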