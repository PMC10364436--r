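# Independent oracle implementations used to cross-check the package's
# numerics. Deliberately written as plain loops / direct formulas.

# topological overlap by explicit O(n^3) triple loop
tomOracle <- function(a) {
    n <- nrow(a)
    k <- rowSums(a)
    tom <- diag(n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        l <- 0
        for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
        tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
    tom
}

# TMM factors traced step by step from the recipe
tmmTraceOracle <- function(m, logratio_trim = 0.3, sum_trim = 0.05) {
    lib <- colSums(m)
    uq <- vapply(seq_len(ncol(m)),
                 function(j) unname(quantile(m[, j], 0.75)) / lib[j], numeric(1))
    ref <- which.min(abs(uq - mean(uq)))
    fac <- numeric(ncol(m))
    for (j in seq_len(ncol(m))) {
        if (j == ref) { fac[j] <- 1; next }
        o <- m[, j]; r <- m[, ref]
        use <- o > 0 & r > 0
        o <- o[use]; r <- r[use]
        M <- log2(o / lib[j]) - log2(r / lib[ref])
        A <- (log2(o / lib[j]) + log2(r / lib[ref])) / 2
        if (max(abs(M)) < 1e-6) { fac[j] <- 1; next }
        n <- length(M)
        loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
        loS <- floor(n * sum_trim) + 1; hiS <- n + 1 - loS
        keep <- rank(M) >= loL & rank(M) <= hiL &
            rank(A) >= loS & rank(A) <= hiS
        w <- 1 / ((lib[j] - o[keep]) / (lib[j] * o[keep]) +
                  (lib[ref] - r[keep]) / (lib[ref] * r[keep]))
        fac[j] <- 2^(sum(w * M[keep]) / sum(w))
    }
    fac / exp(mean(log(fac)))
}

# conditional NB exact test by full enumeration with hand-written log-pmfs
nbEnumOracle <- function(a, b, phi) {
    na <- length(a); nb <- length(b)
    sa <- round(sum(a)); tot <- sa + round(sum(b))
    if (tot == 0) return(1)
    mu <- tot / (na + nb)
    logpmf <- function(y, n) {
        if (phi == 0) return(y * log(n * mu) - n * mu - lgamma(y + 1))
        r <- n / phi; m <- n * mu
        lgamma(y + r) - lgamma(r) - lgamma(y + 1) +
            r * log(r / (r + m)) + y * log(m / (r + m))
    }
    lp <- vapply(0:tot, function(s) logpmf(s, na) + logpmf(tot - s, nb),
                 numeric(1))
    pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
    sum(pr[pr <= pr[sa + 1] * (1 + 1e-12)])
}

# hypergeometric upper tail by direct summation of binomial coefficients
hgSumOracle <- function(k, K, n, N) {
    xs <- k:min(K, n)
    sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# exhaustive-permutation Spearman p (recursive permutation generation)
permsOf <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
        for (p in permsOf(v[-i])) out <- c(out, list(c(v[i], p)))
    out
}
spearmanPermOracle <- function(x, y) {
    rho <- cor(rank(x), rank(y))
    all_rho <- vapply(permsOf(seq_along(y)),
                      function(ix) cor(rank(x), rank(y)[ix]), numeric(1))
    list(rho = rho, p = mean(abs(all_rho) >= abs(rho) - 1e-12))
}

# scale-free fit index by direct slope/R^2 formulas
scaleFreeFitOracle <- function(k, nbins = 10) {
    cuts <- cut(k, nbins)
    xs <- log10(tapply(k, cuts, mean))
    ys <- log10(tapply(k, cuts, length) / length(k))
    ok <- is.finite(xs) & is.finite(ys)
    xs <- xs[ok]; ys <- ys[ok]
    slope <- sum((xs - mean(xs)) * (ys - mean(ys))) / sum((xs - mean(xs))^2)
    -sign(slope) * cor(xs, ys)^2
}
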