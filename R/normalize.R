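#' @importFrom stats quantile
NULL

.countsAndLengths <- function(x) {
    if (is(x, "RnaExperiment"))
        list(m = counts(x), len = as.numeric(featureLength(x)))
    else stop("expected an RnaExperiment")
}

#' Transcripts per million
#'
#' `tpm_gj = (count_gj / length_g) / sum_h(count_hj / length_h) * 1e6`;
#' every column sums to 1e6.
#'
#' @param x an [RnaExperiment-class].
#' @return numeric matrix of TPM values.
#' @export
tpm <- function(x) {
    cl <- .countsAndLengths(x)
    rate <- cl$m / cl$len
    cs <- colSums(rate)
    if (any(cs == 0))
        stop("zero column sum in sample(s): ",
             paste(colnames(cl$m)[cs == 0], collapse = ", "))
    sweep(rate, 2, cs, `/`) * 1e6
}

#' Fragments per kilobase per million
#'
#' `fpkm_gj = count_gj * 1e9 / (length_g * library_size_j)` with the library
#' size the column sum of counts.
#'
#' @param x an [RnaExperiment-class].
#' @return numeric matrix of FPKM values.
#' @export
fpkm <- function(x) {
    cl <- .countsAndLengths(x)
    lib <- colSums(cl$m)
    if (any(lib == 0))
        stop("zero library size in sample(s): ",
             paste(colnames(cl$m)[lib == 0], collapse = ", "))
    sweep(cl$m / cl$len, 2, lib, `/`) * 1e9
}

# Trimmed-mean-of-M-values factor of one sample against the reference.
# obs/ref are count vectors, nO/nR their library sizes.
.tmmPair <- function(obs, ref, nO, nR,
                     logratio_trim = 0.3, sum_trim = 0.05) {
    keep <- obs > 0 & ref > 0
    obs <- obs[keep]; ref <- ref[keep]
    if (length(obs) < 2) {
        warning("fewer than 2 usable genes for TMM; factor set to 1")
        return(1)
    }
    M <- log2((obs / nO) / (ref / nR))
    A <- 0.5 * log2((obs / nO) * (ref / nR))
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loL <- floor(n * logratio_trim) + 1
    hiL <- n + 1 - loL
    loS <- floor(n * sum_trim) + 1
    hiS <- n + 1 - loS
    rM <- rank(M); rA <- rank(A)
    keep2 <- rM >= loL & rM <= hiL & rA >= loS & rA <= hiS
    if (sum(keep2) < 2) {
        warning("fewer than 2 genes left after TMM trimming; factor set to 1")
        return(1)
    }
    o <- obs[fin][keep2]; r <- ref[fin][keep2]
    w <- (nO - o) / (nO * o) + (nR - r) / (nR * r)  # asymptotic var of M
    f <- sum(M[keep2] / w) / sum(1 / w)
    if (!is.finite(f)) f <- 0
    2^f
}

#' Trimmed mean of M-values normalization factors
#'
#' The reference sample is the one whose upper-quartile count/library-size
#' ratio is closest to the mean upper quartile. Per sample, genes with a
#' zero in either sample are excluded, 30% of genes are trimmed on the
#' log-ratio M and 5% on the abundance A (both tails), and the factor is
#' 2^(inverse-asymptotic-variance weighted mean of the trimmed M). Factors
#' are rescaled so their geometric mean is 1.
#'
#' @param x an [RnaExperiment-class] (or count matrix).
#' @return data.frame with `sample_id`, `library_size`, `tmm_factor`,
#'   `effective_size` (= library_size * tmm_factor).
#' @export
tmmFactors <- function(x) {
    m <- if (is(x, "RnaExperiment")) counts(x) else as.matrix(x)
    if (ncol(m) < 2) stop("TMM needs at least 2 samples")
    lib <- colSums(m)
    f75 <- vapply(seq_len(ncol(m)),
                  function(j) quantile(m[, j], 0.75) / lib[j], numeric(1))
    ref <- which.min(abs(f75 - mean(f75)))
    f <- vapply(seq_len(ncol(m)), function(j)
        if (j == ref) 1 else .tmmPair(m[, j], m[, ref], lib[j], lib[ref]),
        numeric(1))
    f <- f / exp(mean(log(f)))
    data.frame(sample_id = colnames(m), library_size = unname(lib),
               tmm_factor = unname(f),
               effective_size = unname(lib * f),
               stringsAsFactors = FALSE)
}

#' TMM-normalized counts per million
#'
#' @param x an [RnaExperiment-class].
#' @param norm optional precomputed [tmmFactors()] table.
#' @return numeric matrix of CPM on TMM effective library sizes.
#' @export
tmmCpm <- function(x, norm = tmmFactors(x)) {
    m <- counts(x)
    sweep(m, 2, norm$effective_size[match(colnames(m), norm$sample_id)],
          `/`) * 1e6
}
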