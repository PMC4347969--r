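# Vectorized negative-binomial GLM fitting (log link) for many genes
# sharing one design matrix.
#
# Model per gene g: y_gs ~ NB(mu_gs, phi), log mu_gs = X[s,] beta_g + o_s,
# variance mu + phi mu^2.  phi = 0 gives the Poisson limit.  Fisher
# scoring / IRLS with working weights w = mu / (1 + phi mu); the update is
# solved per gene from the p x p weighted normal equations, assembled for
# all genes at once via matrix products.

nbLogLik <- function(y, mu, phi) {
    mu <- pmax(mu, 1e-12)
    if (phi > 0) {
        rowSums(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
    } else {
        rowSums(stats::dpois(y, lambda = mu, log = TRUE))
    }
}

# y: G x S count matrix; X: S x p design; offset: length-S vector (or G x S
# matrix) of log effective library sizes; phi: common dispersion (scalar).
# Returns list(coef = G x p, loglik = G, converged = logical G, iter).
nbGlmFit <- function(y, X, offset, phi, tol = 1e-8, maxit = 50L) {
    y <- as.matrix(y)
    X <- as.matrix(X)
    G <- nrow(y); S <- ncol(y); p <- ncol(X)
    stopifnot(nrow(X) == S, phi >= 0)
    if (is.matrix(offset)) O <- offset else
        O <- matrix(offset, nrow = G, ncol = S, byrow = TRUE)

    # pairwise column products of X, for assembling X' W X per gene
    ij <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
    Xcross <- X[, ij[, 1], drop = FALSE] * X[, ij[, 2], drop = FALSE]

    # start from weighted least squares on log(y + 0.5) - offset
    Z0 <- log(y + 0.5) - O
    XtX <- crossprod(X)
    beta <- t(solve(XtX, t(Z0 %*% X)))

    converged <- rep(FALSE, G)
    iter <- 0L
    repeat {
        iter <- iter + 1L
        eta <- tcrossprod(beta, X) + O
        eta <- pmin(pmax(eta, -30), 30)       # guard against overflow
        mu <- exp(eta)
        w <- mu / (1 + phi * mu)
        z <- (eta - O) + (y - mu) / mu
        A <- w %*% Xcross                      # G x npair, entries of X'WX
        B <- (w * z) %*% X                     # G x p, entries of X'Wz
        newbeta <- beta
        if (p == 1L) {
            newbeta[, 1] <- B[, 1] / A[, 1]
        } else if (p == 2L) {
            # A columns follow upper.tri order: (1,1), (1,2), (2,2)
            det <- A[, 1] * A[, 3] - A[, 2]^2
            newbeta[, 1] <- (A[, 3] * B[, 1] - A[, 2] * B[, 2]) / det
            newbeta[, 2] <- (A[, 1] * B[, 2] - A[, 2] * B[, 1]) / det
        } else {
            M <- matrix(0, p, p)
            lo <- which(upper.tri(M, diag = TRUE))
            for (g in seq_len(G)) {
                M[lo] <- A[g, ]
                M[lower.tri(M)] <- t(M)[lower.tri(M)]
                bg <- try(solve(M, B[g, ]), silent = TRUE)
                if (!inherits(bg, "try-error")) newbeta[g, ] <- bg
            }
        }
        bad <- !is.finite(newbeta)
        if (any(bad)) newbeta[bad] <- beta[bad]
        delta <- apply(abs(newbeta - beta), 1L, max)
        beta <- newbeta
        converged <- converged | delta < tol
        if (all(converged) || iter >= maxit) break
    }
    eta <- pmin(pmax(tcrossprod(beta, X) + O, -30), 30)
    mu <- exp(eta)
    list(coef = beta, loglik = nbLogLik(y, mu, phi),
         converged = converged, iter = iter, mu = mu)
}

# Likelihood-ratio test of the last column of X being zero.
# Returns data.frame(slope, intercept-ish coefs dropped), p from chisq(1).
nbLrtSlope <- function(y, Xfull, offset, phi, tol = 1e-8, maxit = 50L) {
    p <- ncol(Xfull)
    full <- nbGlmFit(y, Xfull, offset, phi, tol, maxit)
    null <- nbGlmFit(y, Xfull[, -p, drop = FALSE], offset, phi, tol, maxit)
    lrt <- pmax(2 * (full$loglik - null$loglik), 0)
    pval <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
    list(full = full, null = null, lrt = lrt, p = pval)
}
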