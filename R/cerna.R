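#' @importFrom stats cor pt complete.cases
NULL

# all permutations of 1..n (n <= 8), as an n! x n matrix
.allPerms <- function(n) {
    if (n == 1) return(matrix(1L, 1, 1))
    sub <- .allPerms(n - 1L)
    out <- matrix(0L, n * nrow(sub), n)
    r <- 0L
    for (pos in seq_len(n)) {
        blk <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                             drop = FALSE]
        out[r + seq_len(nrow(sub)), ] <- blk
        r <- r + nrow(sub)
    }
    out
}

#' Spearman rank correlation with exact small-sample p
#'
#' Average ranks for ties; the two-sided p-value comes from exhaustive
#' permutation of one variable for n <= 8 observations and from the
#' t-approximation `t = rho sqrt((n-2)/(1-rho^2))` otherwise.
#'
#' @param x,y paired numeric vectors (n >= 5).
#' @return list with `rho` and `p`.
#' @export
spearmanCor <- function(x, y) {
    ok <- complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 5) stop("need >= 5 paired observations")
    if (sd(x) == 0 || sd(y) == 0) {
        warning("constant vector; rho = 0, p = 1")
        return(list(rho = 0, p = 1))
    }
    rx <- rank(x); ry <- rank(y)
    rho <- cor(rx, ry)
    if (n <= 8) {
        perms <- .allPerms(n)
        zx <- (rx - mean(rx)) / sd(rx)
        zy <- (ry - mean(ry)) / sd(ry)
        rho_perm <- as.vector((matrix(zy[perms], nrow(perms)) %*% zx) / (n - 1))
        p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    } else {
        tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-300))
        p <- 2 * pt(-abs(tt), n - 2)
        if (abs(rho) >= 1) p <- 0
    }
    list(rho = rho, p = p)
}

#' Candidate ceRNA triads from shared miRNA targets
#'
#' All (ceRNA, miRNA, mRNA) triples such that the miRNA is DE, the ceRNA is
#' a DE lncRNA or circRNA, the mRNA is a hub gene, and the target table
#' contains both (miRNA, ceRNA) and (miRNA, mRNA) rows. With
#' `config$target_combine = "intersection"` a row must be supported by both
#' evidence sources; the default `"union"` accepts any source.
#'
#' @param targets target table (see [readTargets()]).
#' @param de a [callDE()] table.
#' @param hubs character vector of hub mRNA ids.
#' @param config a [cernaConfig()].
#' @return data.frame `cerna_id`, `mirna_id`, `mrna_id`, `cerna_class`.
#' @export
candidateTriads <- function(targets, de, hubs, config = cernaConfig()) {
    de_mir <- unionDE(de, "miRNA")
    de_cer <- unionDE(de, c("lncRNA", "circRNA"))
    cls <- de$rna_class[match(de_cer, de$feature_id)]
    names(cls) <- de_cer
    if (config$target_combine == "intersection") {
        key <- paste(targets$mirna_id, targets$target_id, sep = "\r")
        nsrc <- tapply(targets$source, key, function(s) length(unique(s)))
        ok <- nsrc[paste(targets$mirna_id, targets$target_id, sep = "\r")] >= 2
        targets <- targets[ok, , drop = FALSE]
    }
    targets <- unique(targets[, c("mirna_id", "target_id")])
    targets <- targets[targets$mirna_id %in% de_mir, , drop = FALSE]
    out <- lapply(split(targets$target_id, targets$mirna_id), function(tg) {
        cerna <- intersect(tg, de_cer)
        mrna <- intersect(tg, hubs)
        if (!length(cerna) || !length(mrna)) return(NULL)
        expand.grid(cerna_id = cerna, mrna_id = mrna, stringsAsFactors = FALSE)
    })
    keep <- !vapply(out, is.null, logical(1))
    if (!any(keep))
        return(data.frame(cerna_id = character(), mirna_id = character(),
                          mrna_id = character(), cerna_class = character(),
                          stringsAsFactors = FALSE))
    res <- do.call(rbind, Map(function(df, m) {
        df$mirna_id <- m; df
    }, out[keep], names(out)[keep]))
    res <- res[, c("cerna_id", "mirna_id", "mrna_id")]
    res$cerna_class <- unname(cls[res$cerna_id])
    res <- res[order(res$cerna_id, res$mirna_id, res$mrna_id), ]
    rownames(res) <- NULL
    res
}

# Spearman rho/p for many (a, b) index pairs at once on a rank-standardized
# matrix Z (features x samples).
.spearmanPairs <- function(Z, ia, ib, n) {
    rho <- rowSums(Z[ia, , drop = FALSE] * Z[ib, , drop = FALSE]) / (n - 1)
    rho <- pmin(1, pmax(-1, rho))
    tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-300))
    p <- 2 * pt(-abs(tt), n - 2)
    list(rho = rho, p = p)
}

#' Filter candidate triads by the ceRNA sign and significance rules
#'
#' A candidate (c, m, g) is kept iff Spearman rho(c, g) > 0,
#' rho(m, c) < 0, rho(m, g) < 0 and all three correlation-test p-values are
#' below `config$spearman_p` (with `config$spearman_rule = "coefficient"`,
#' the literal |rho| < threshold reading replaces the p-value rule).
#'
#' @param candidates from [candidateTriads()].
#' @param expr expression matrix (features x samples) covering all members.
#' @param config a [cernaConfig()].
#' @return `TriadTable` data.frame with rho/p evidence columns.
#' @export
filterTriads <- function(candidates, expr, config = cernaConfig()) {
    empty <- data.frame(cerna_id = character(), mirna_id = character(),
                        mrna_id = character(), cerna_class = character(),
                        rho_cm = numeric(), rho_mic = numeric(),
                        rho_mim = numeric(), p_cm = numeric(),
                        p_mic = numeric(), p_mim = numeric(),
                        stringsAsFactors = FALSE)
    if (!nrow(candidates)) return(empty)
    feats <- unique(c(candidates$cerna_id, candidates$mirna_id,
                      candidates$mrna_id))
    miss <- setdiff(feats, rownames(expr))
    if (length(miss)) stop("expression missing for: ",
                           paste(utils::head(miss, 5), collapse = ", "))
    n <- ncol(expr)
    R <- t(apply(expr[feats, , drop = FALSE], 1, rank))
    Z <- t(scale(t(R)))
    Z[!is.finite(Z)] <- 0
    idx <- setNames(seq_along(feats), feats)
    cm <- .spearmanPairs(Z, idx[candidates$cerna_id], idx[candidates$mrna_id], n)
    mic <- .spearmanPairs(Z, idx[candidates$mirna_id], idx[candidates$cerna_id], n)
    mim <- .spearmanPairs(Z, idx[candidates$mirna_id], idx[candidates$mrna_id], n)
    sig <- if (config$spearman_rule == "pvalue")
        cm$p < config$spearman_p & mic$p < config$spearman_p &
            mim$p < config$spearman_p
    else
        abs(cm$rho) < config$spearman_p & abs(mic$rho) < config$spearman_p &
            abs(mim$rho) < config$spearman_p
    keep <- cm$rho > 0 & mic$rho < 0 & mim$rho < 0 & sig
    out <- cbind(candidates,
                 data.frame(rho_cm = cm$rho, rho_mic = mic$rho,
                            rho_mim = mim$rho, p_cm = cm$p, p_mic = mic$p,
                            p_mim = mim$p))[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' ceRNA core networks split by ceRNA class
#'
#' Each triad contributes the edges (miRNA, ceRNA) and (miRNA, mRNA); one
#' network is built per ceRNA class.
#'
#' @param triads a [filterTriads()] table.
#' @param moduleLabels optional named module labels for mRNA node colours.
#' @return named list (`lncRNA`, `circRNA`) of `nodes`/`edges` table pairs
#'   ready for [exportNetwork()], plus unique-member `summary` counts.
#' @export
buildCoreNetworks <- function(triads, moduleLabels = NULL) {
    build <- function(sub, cer_class) {
        ids <- sort(unique(c(sub$cerna_id, sub$mirna_id, sub$mrna_id)))
        cls <- ifelse(ids %in% sub$mirna_id, "miRNA",
                      ifelse(ids %in% sub$mrna_id, "mRNA", cer_class))
        mod <- if (!is.null(moduleLabels))
            ifelse(ids %in% names(moduleLabels),
                   moduleColorName(moduleLabels[ids]), "none")
        else rep("none", length(ids))
        nodes <- data.frame(id = ids, rna_class = cls, module = mod,
                            stringsAsFactors = FALSE)
        edges <- unique(rbind(
            data.frame(from = sub$mirna_id, to = sub$cerna_id,
                       interaction = rep("mirna_cerna", nrow(sub)),
                       stringsAsFactors = FALSE),
            data.frame(from = sub$mirna_id, to = sub$mrna_id,
                       interaction = rep("mirna_mrna", nrow(sub)),
                       stringsAsFactors = FALSE)))
        summary <- c(n_cerna = length(unique(sub$cerna_id)),
                     n_mirna = length(unique(sub$mirna_id)),
                     n_mrna = length(unique(sub$mrna_id)),
                     n_triads = nrow(sub))
        list(nodes = nodes, edges = edges, summary = summary)
    }
    list(lncRNA = build(triads[triads$cerna_class == "lncRNA", , drop = FALSE],
                        "lncRNA"),
         circRNA = build(triads[triads$cerna_class == "circRNA", , drop = FALSE],
                         "circRNA"))
}
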