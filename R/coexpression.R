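#' @importFrom stats cor hclust cutree dist as.dist lm pt sd prcomp coef
NULL

#' Remove outlier samples by hierarchical clustering
#'
#' Samples are clustered by average linkage on the Euclidean distance of
#' per-gene standardized expression; samples that only join the tree above
#' `cutHeight` (default: mean + 2.5 sd of the merge heights), i.e. that are
#' still singletons when the tree is cut there, are removed.
#'
#' @param expr numeric matrix, genes x samples.
#' @param cutHeight numeric height, or `"auto"`.
#' @return list with `expr` (columns kept) and `removed` (sample ids).
#' @export
removeOutlierSamples <- function(expr, cutHeight = "auto") {
    if (ncol(expr) < 4) stop("need >= 4 samples")
    z <- t(scale(t(expr)))
    z <- z[apply(expr, 1, sd) > 0, , drop = FALSE]
    h <- hclust(dist(t(z)), method = "average")
    if (identical(cutHeight, "auto"))
        cutHeight <- mean(h$height) + 2.5 * sd(h$height)
    cl <- cutree(h, h = cutHeight)
    sizes <- table(cl)
    detached <- cl %in% as.integer(names(sizes)[sizes == 1])
    removed <- colnames(expr)[detached]
    if (length(removed) > 0.2 * ncol(expr))
        stop("more than 20% of samples flagged as outliers; review manually")
    list(expr = expr[, !detached, drop = FALSE], removed = removed)
}

# scale-free topology fit index of a connectivity vector: the connectivity
# range is split into 10 equal-width bins and the bin occupancy p(k) is
# regressed on the bin mean connectivity on the log-log scale; returns
# -sign(slope) * R^2.
.scaleFreeFit <- function(k, nbins = 10) {
    bin <- cut(k, nbins)
    dk <- tapply(k, bin, mean)
    pk <- tapply(k, bin, length) / length(k)
    ok <- !is.na(dk) & dk > 0 & !is.na(pk) & pk > 0
    if (sum(ok) < 3) return(NA_real_)
    fit <- lm(log10(pk[ok]) ~ log10(dk[ok]))
    r2 <- summary(fit)$r.squared
    unname(-sign(coef(fit)[2]) * r2)
}

#' Pick the soft-threshold power
#'
#' For each candidate power, the unsigned adjacency `|cor|^beta` is formed
#' and the scale-free topology fit index (signed R^2 of the log-log
#' connectivity distribution over 10 equal-occupancy bins) computed. The
#' selected power is the smallest one reaching `target` (default 0.85), or
#' the argmax of the fit index if none does.
#'
#' @param expr numeric matrix, genes x samples.
#' @param powers candidate powers (default 1:20).
#' @param target scale-free fit target.
#' @return list with `power` and `fit` (data.frame power, fit_index,
#'   mean_k).
#' @export
pickSoftThreshold <- function(expr, powers = 1:20, target = 0.85) {
    keep <- apply(expr, 1, sd) > 0
    if (any(!keep)) {
        warning(sum(!keep), " constant gene(s) excluded")
        expr <- expr[keep, , drop = FALSE]
    }
    r <- abs(cor(t(expr)))
    diag(r) <- 0
    tab <- data.frame(power = powers, fit_index = NA_real_, mean_k = NA_real_)
    for (i in seq_along(powers)) {
        a <- r^powers[i]
        k <- rowSums(a)
        tab$fit_index[i] <- .scaleFreeFit(k)
        tab$mean_k[i] <- mean(k)
    }
    hit <- which(!is.na(tab$fit_index) & tab$fit_index >= target)
    power <- if (length(hit)) powers[hit[1]] else powers[which.max(tab$fit_index)]
    list(power = power, fit = tab)
}

#' Unsigned weighted adjacency
#'
#' @param expr numeric matrix, genes x samples.
#' @param power soft-threshold power beta.
#' @return symmetric adjacency `|cor|^beta` with zero diagonal.
#' @export
adjacencyMatrix <- function(expr, power) {
    a <- abs(cor(t(expr)))^power
    diag(a) <- 0
    a
}

#' Topological overlap similarity
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` (u != i, j) and unit diagonal.
#'
#' @param adjacency symmetric matrix, zero diagonal, entries in \[0, 1\].
#' @return TOM similarity matrix, entries in \[0, 1\], unit diagonal.
#' @export
tomSimilarity <- function(adjacency) {
    a <- as.matrix(adjacency)
    if (!isSymmetric(unname(a), tol = 1e-10)) stop("adjacency must be symmetric")
    if (any(diag(a) != 0)) stop("adjacency must have a zero diagonal")
    if (any(a < 0) || any(a > 1)) stop("adjacency entries must be in [0, 1]")
    l <- a %*% a                     # diagonal of a is 0, so u != i, j terms only
    k <- rowSums(a)
    kmin <- outer(k, k, pmin)
    tom <- (l + a) / (kmin + 1 - a)
    diag(tom) <- 1
    dimnames(tom) <- dimnames(a)
    tom
}

#' Module eigengene
#'
#' First principal component of the per-gene standardized module submatrix,
#' scaled to unit variance and sign-oriented so the mean correlation with
#' member genes is positive.
#'
#' @param expr numeric matrix, genes x samples (module members only).
#' @return numeric vector over samples (unit variance).
#' @export
moduleEigengene <- function(expr) {
    if (nrow(expr) == 1) {
        warning("module of a single gene; eigengene is the standardized gene")
        e <- as.numeric(scale(as.numeric(expr)))
        names(e) <- colnames(expr)
        return(e)
    }
    z <- t(scale(t(expr)))
    ok <- rowSums(!is.finite(z)) == 0
    z <- z[ok, , drop = FALSE]
    sv <- svd(z, nu = 0, nv = 1)
    e <- sv$v[, 1]
    e <- e / sd(e)
    cors <- suppressWarnings(cor(t(expr), e))
    if (mean(cors, na.rm = TRUE) < 0) e <- -e
    names(e) <- colnames(expr)
    e
}

.eigengeneMatrix <- function(expr, labels) {
    mods <- sort(unique(labels[labels > 0]))
    me <- t(vapply(mods, function(m)
        moduleEigengene(expr[names(labels)[labels == m], , drop = FALSE]),
        numeric(ncol(expr))))
    rownames(me) <- paste0("ME", mods)
    colnames(me) <- colnames(expr)
    me
}

#' Cut the gene tree into modules
#'
#' Average-linkage dendrogram on the TOM dissimilarity, constant-height cut
#' at `cut_height`, clusters below `min_size` unassigned (label 0), then
#' iterative merging of modules whose eigengenes correlate above
#' `1 - merge_height`. Labels are renumbered by decreasing module size.
#'
#' @param dissTOM symmetric dissimilarity matrix (1 - TOM).
#' @param expr genes x samples expression (for eigengene merging), rows
#'   matching `dissTOM`.
#' @param min_size smallest retained module (default 30).
#' @param merge_height eigengene dissimilarity below which modules are
#'   merged (default 0.25).
#' @param cut_height static tree-cut height (default 0.99).
#' @return named integer label vector (0 = unassigned).
#' @export
cutModules <- function(dissTOM, expr, min_size = 30, merge_height = 0.25,
                       cut_height = 0.99) {
    stopifnot(isSymmetric(unname(as.matrix(dissTOM)), tol = 1e-8))
    genes <- rownames(dissTOM)
    if (is.null(genes)) genes <- rownames(expr)
    h <- hclust(as.dist(dissTOM), method = "average")
    cl <- cutree(h, h = min(cut_height, max(h$height) - 1e-12))
    names(cl) <- genes
    sizes <- table(cl)
    small <- as.integer(names(sizes)[sizes < min_size])
    labels <- ifelse(cl %in% small, 0L, cl)
    names(labels) <- genes
    if (all(labels == 0)) {
        warning("all genes unassigned at min_size = ", min_size)
        return(labels)
    }
    # iterative eigengene merging
    repeat {
        mods <- sort(unique(labels[labels > 0]))
        if (length(mods) < 2) break
        me <- .eigengeneMatrix(expr, labels)
        cc <- cor(t(me))
        diag(cc) <- -Inf
        best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
        if (max(cc) <= 1 - merge_height) break
        from <- mods[best[2]]; to <- mods[best[1]]
        labels[labels == from] <- to
    }
    # renumber by decreasing size (ties by old label for determinism)
    mods <- sort(unique(labels[labels > 0]))
    sz <- vapply(mods, function(m) sum(labels == m), integer(1))
    ord <- mods[order(-sz, mods)]
    new <- labels
    for (i in seq_along(ord)) new[labels == ord[i]] <- i
    names(new) <- genes
    new
}

#' Module-trait correlations and key modules
#'
#' Pearson correlation (with two-sided t-test p) between each module
#' eigengene and the binary indicator of each time point; for each time
#' point the module with the highest |r| is the key module (ties broken by
#' smaller p, then larger module size).
#'
#' @param eigengenes modules x samples matrix (rownames `ME<label>`).
#' @param time named vector of time points per sample (matching columns).
#' @param sizes named module sizes (names = labels) for tie-breaking.
#' @return list with `r`, `p` (modules x time points) and `key` (named
#'   integer vector time point -> module label).
#' @export
moduleTraitCor <- function(eigengenes, time, sizes = NULL) {
    time <- time[colnames(eigengenes)]
    tps <- sort(unique(time))
    if (any(table(time) < 2)) stop("every time point needs >= 2 samples")
    ind <- sapply(tps, function(t) as.numeric(time == t))
    colnames(ind) <- paste0(tps)
    n <- ncol(eigengenes)
    r <- cor(t(eigengenes), ind)
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
    p <- 2 * pt(-abs(tt), n - 2)
    labels <- as.integer(sub("^ME", "", rownames(eigengenes)))
    key <- vapply(seq_along(tps), function(j) {
        o <- order(-abs(r[, j]), p[, j],
                   if (!is.null(sizes)) -sizes[paste0(labels)] else labels)
        labels[o[1]]
    }, integer(1))
    names(key) <- paste0(tps)
    list(r = r, p = p, key = key)
}

#' Gene significance and module membership
#'
#' GS is the Pearson correlation of each gene with each time-point
#' indicator; MM is its correlation with each module eigengene. Constant
#' genes get 0 with a warning.
#'
#' @param expr genes x samples matrix.
#' @param eigengenes modules x samples matrix.
#' @param time named time point vector per sample.
#' @return list with matrices `GS` (genes x time points) and `MM`
#'   (genes x modules).
#' @export
geneSignificanceMembership <- function(expr, eigengenes, time) {
    time <- time[colnames(expr)]
    tps <- sort(unique(time))
    ind <- sapply(tps, function(t) as.numeric(time == t))
    colnames(ind) <- paste0(tps)
    const <- apply(expr, 1, sd) == 0
    if (any(const)) warning(sum(const), " constant gene(s); GS/MM set to 0")
    ze <- expr
    ze[const, ] <- 0
    GS <- suppressWarnings(cor(t(ze), ind))
    MM <- suppressWarnings(cor(t(ze), t(eigengenes)))
    GS[const, ] <- 0
    MM[const, ] <- 0
    GS[is.na(GS)] <- 0
    MM[is.na(MM)] <- 0
    list(GS = GS, MM = MM)
}

#' Select hub genes
#'
#' A gene is a hub iff it belongs to a key module and, strictly,
#' `|MM| > mm_hub` to its own module and `|GS| > gs_hub` to that module's
#' associated time point.
#'
#' @param labels named module labels.
#' @param GS,MM matrices from [geneSignificanceMembership()].
#' @param key named key-module map (time point -> label).
#' @param config a [cernaConfig()] (uses `mm_hub`, `gs_hub`, `key_traits`).
#' @return list with `hubs` (character) and `hubModule` (named integer).
#' @export
selectHubGenes <- function(labels, GS, MM, key, config = cernaConfig()) {
    traits <- names(key)
    if (!is.null(config$key_traits))
        traits <- intersect(traits, paste0(config$key_traits))
    hubs <- character(); hubmod <- integer()
    for (tr in traits) {
        m <- key[[tr]]
        mem <- names(labels)[labels == m]
        mmcol <- paste0("ME", m)
        ok <- abs(MM[mem, mmcol]) > config$mm_hub &
            abs(GS[mem, tr]) > config$gs_hub
        newhubs <- setdiff(mem[ok], hubs)
        hubs <- c(hubs, newhubs)
        hubmod <- c(hubmod, setNames(rep(as.integer(m), length(newhubs)), newhubs))
    }
    list(hubs = hubs, hubModule = hubmod)
}

#' Run the full weighted co-expression stage
#'
#' Outlier removal, soft-threshold selection, adjacency, TOM, tree cutting,
#' eigengenes, module-trait correlation, GS/MM and hub selection, on
#' log2(FPKM + 1) of the supplied features (typically union-DE mRNAs).
#'
#' @param x an [RnaExperiment-class] restricted to the genes to cluster.
#' @param config a [cernaConfig()].
#' @return a [ModuleResult-class].
#' @export
runCoexpression <- function(x, config = cernaConfig()) {
    expr <- log2(fpkm(x) + 1)
    out <- removeOutlierSamples(expr, config$outlier_cut)
    expr <- out$expr
    keep <- apply(expr, 1, sd) > 0
    expr <- expr[keep, , drop = FALSE]
    power <- if (identical(config$soft_power, "auto"))
        pickSoftThreshold(expr, target = config$sft_target)$power
    else as.integer(config$soft_power)
    a <- adjacencyMatrix(expr, power)
    tom <- tomSimilarity(a)
    labels <- cutModules(1 - tom, expr, min_size = config$min_module_size,
                         merge_height = config$merge_height)
    time <- timePoints(x)[colnames(expr)]
    if (!any(labels > 0)) {
        return(new("ModuleResult", labels = labels,
                   colors = setNames(moduleColorName(labels), names(labels)),
                   eigengenes = matrix(0, 0, ncol(expr)),
                   moduleTraitR = matrix(0, 0, 0), moduleTraitP = matrix(0, 0, 0),
                   keyModules = integer(), GS = matrix(0, 0, 0),
                   MM = matrix(0, 0, 0), hubGenes = character(),
                   hubModule = integer(), softPower = as.integer(power),
                   removedSamples = out$removed))
    }
    me <- .eigengeneMatrix(expr, labels)
    sizes <- table(labels[labels > 0])
    mt <- moduleTraitCor(me, time, sizes = sizes)
    gm <- geneSignificanceMembership(expr, me, time)
    hb <- selectHubGenes(labels, gm$GS, gm$MM, mt$key, config)
    new("ModuleResult", labels = labels,
        colors = setNames(moduleColorName(labels), names(labels)),
        eigengenes = me, moduleTraitR = mt$r, moduleTraitP = mt$p,
        keyModules = mt$key, GS = gm$GS, MM = gm$MM,
        hubGenes = hb$hubs, hubModule = hb$hubModule,
        softPower = as.integer(power), removedSamples = out$removed)
}
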