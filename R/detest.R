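#' @importFrom stats dnbinom dpois var median
NULL

#' Conditional negative-binomial exact test
#'
#' Two-sided exact test for a difference in mean between two groups of
#' counts already scaled to a common effective library size. Group sums are
#' modelled as NB with mean `n_k * mu` and dispersion `phi / n_k` (the sum
#' of `n_k` iid NB(mu, phi) variables); conditioning on the total, the
#' p-value is the sum of the probabilities of all splits of the total at
#' most as probable as the observed one. `phi = 0` reduces to the
#' conditional binomial (Poisson) test.
#'
#' @param groupA,groupB numeric count vectors (scaled to a common effective
#'   size; sums are rounded for the enumeration).
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2), >= 0.
#' @return two-sided p-value in (0, 1\].
#' @export
nbExactTest <- function(groupA, groupB, dispersion) {
    if (dispersion < 0) stop("dispersion must be >= 0")
    nA <- length(groupA); nB <- length(groupB)
    sA <- round(sum(groupA)); sB <- round(sum(groupB))
    total <- sA + sB
    if (total == 0) return(1)
    mu <- total / (nA + nB)
    s <- 0:total
    if (dispersion == 0) {
        lpA <- dpois(s, nA * mu, log = TRUE)
        lpB <- dpois(s, nB * mu, log = TRUE)
    } else {
        lpA <- dnbinom(s, size = nA / dispersion, mu = nA * mu, log = TRUE)
        lpB <- dnbinom(s, size = nB / dispersion, mu = nB * mu, log = TRUE)
    }
    lp <- lpA + rev(lpB)                 # log P(sA = s, sB = total - s)
    lmax <- max(lp)
    pr <- exp(lp - lmax)
    obs <- pr[sA + 1]
    min(1, sum(pr[pr <= obs * (1 + 1e-12)]) / sum(pr))
}

#' Method-of-moments common dispersion
#'
#' Per gene, a method-of-moments estimate
#' `phi_g = max(0, (s^2_g - mu_g) / mu_g^2)` is computed from
#' within-group means/variances of effective-size-scaled counts (groups
#' pooled by replicate-weighted averaging), then pooled across genes by the
#' median. Deterministic.
#'
#' @param x an [RnaExperiment-class].
#' @param groups factor of group membership per sample (defaults to time
#'   point).
#' @param norm optional precomputed [tmmFactors()] table.
#' @return the pooled dispersion estimate (a single number >= 0).
#' @export
estimateCommonDispersion <- function(x, groups = factor(timePoints(x)),
                                     norm = tmmFactors(x)) {
    m <- counts(x)
    eff <- norm$effective_size[match(colnames(m), norm$sample_id)]
    scaled <- sweep(m, 2, exp(mean(log(eff))) / eff, `*`)
    groups <- as.factor(groups)
    use <- names(table(groups))[table(groups) >= 2]
    if (length(use) < 2)
        stop("need >= 2 groups with >= 2 replicates; supply dispersion manually")
    num <- 0; den <- 0
    phi_g <- rep(0, nrow(m))
    num <- matrix(0, nrow(m), length(use))
    wts <- numeric(length(use))
    for (k in seq_along(use)) {
        j <- which(groups == use[k])
        mu <- rowMeans(scaled[, j, drop = FALSE])
        s2 <- apply(scaled[, j, drop = FALSE], 1, var)
        num[, k] <- ifelse(mu > 0, (s2 - mu) / mu^2, 0)
        wts[k] <- length(j) - 1
    }
    phi_g <- pmax(0, as.vector(num %*% wts) / sum(wts))
    median(phi_g)
}

.classFcThreshold <- function(rna_class, config) {
    ifelse(rna_class == "circRNA", log2(config$fc_circ),
           log2(config$fc_lnc_mi_mrna))
}

#' Per-time-point differential expression calls
#'
#' Each proliferative time point (12/24/48/72 h) is contrasted against the
#' 0 h group with the conditional NB exact test on TMM-scaled counts.
#' Fold changes are computed from group-mean TMM-CPM (or TPM, per config)
#' with a pseudo-count of 0.5 per group mean. A feature is called up at a
#' contrast iff `log2fc > ` its class threshold (log2(1.5) for
#' lncRNA/miRNA/mRNA, 0 for circRNA) and `p < p_de`; down symmetrically;
#' `union_de` flags features DE at one or more contrasts.
#'
#' @param x an [RnaExperiment-class] (after [filterLowExpression()]).
#' @param dispersion NB dispersion; `NULL` estimates it with
#'   [estimateCommonDispersion()].
#' @param config a [cernaConfig()].
#' @return data.frame (`DETable`): `feature_id`, `rna_class`, `contrast`,
#'   `log2fc`, `p_value`, `direction` (up/down/ns), `union_de`.
#' @export
callDE <- function(x, dispersion = NULL, config = cernaConfig()) {
    tps <- timePoints(x)
    if (!any(tps == 0)) stop("missing 0 h reference group")
    norm <- tmmFactors(x)
    if (is.null(dispersion))
        dispersion <- estimateCommonDispersion(x, norm = norm)
    m <- counts(x)
    eff <- norm$effective_size[match(colnames(m), norm$sample_id)]
    scaled <- sweep(m, 2, exp(mean(log(eff))) / eff, `*`)
    expr_fc <- switch(config$fc_on, tmm_cpm = tmmCpm(x, norm), tpm = tpm(x))
    cls <- rnaClass(x)
    thr <- .classFcThreshold(cls, config)
    ref <- which(tps == 0)
    out <- list()
    for (t in setdiff(sort(unique(tps)), 0)) {
        j <- which(tps == t)
        meanA <- rowMeans(expr_fc[, j, drop = FALSE])
        meanR <- rowMeans(expr_fc[, ref, drop = FALSE])
        lfc <- log2((meanA + 0.5) / (meanR + 0.5))
        p <- vapply(seq_len(nrow(m)), function(g)
            nbExactTest(scaled[g, j], scaled[g, ref], dispersion), numeric(1))
        dir <- ifelse(p < config$p_de & lfc > thr, "up",
                      ifelse(p < config$p_de & lfc < -thr, "down", "ns"))
        out[[paste0(t)]] <- data.frame(
            feature_id = rownames(m), rna_class = unname(cls),
            contrast = sprintf("%d_vs_0", t), log2fc = unname(lfc),
            p_value = unname(p), direction = unname(dir),
            stringsAsFactors = FALSE)
    }
    de <- do.call(rbind, out)
    rownames(de) <- NULL
    de_ids <- unique(de$feature_id[de$direction != "ns"])
    de$union_de <- de$feature_id %in% de_ids
    de
}

#' Union-DE feature ids of a DETable
#'
#' @param de a [callDE()] table.
#' @param rna_class optional class filter.
#' @return character vector of feature ids DE at >= 1 contrast.
#' @export
unionDE <- function(de, rna_class = NULL) {
    keep <- de$direction != "ns"
    if (!is.null(rna_class)) keep <- keep & de$rna_class %in% rna_class
    unique(de$feature_id[keep])
}
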