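#' @importFrom GenomicRanges distance
NULL

#' Pairwise Pearson correlation with p-values
#'
#' @param exprA,exprB numeric matrices (features x samples, matched columns).
#' @return list of matrices `r` and `p` (two-sided t-distribution p-values),
#'   rows = features of A, columns = features of B.
#' @export
pearsonMatrix <- function(exprA, exprB) {
    if (!identical(colnames(exprA), colnames(exprB)))
        stop("sample columns must match")
    n <- ncol(exprA)
    if (n < 3) stop("need >= 3 samples")
    r <- cor(t(exprA), t(exprB))
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
    p <- 2 * pt(-abs(tt), n - 2)
    p[abs(r) >= 1] <- 0
    list(r = r, p = p)
}

# gap (positions strictly between) of two feature sets from the annotation;
# NA for different chromosomes, 0 for overlap/adjacency.
.pairGap <- function(annotation, ids_a, ids_b) {
    ia <- match(ids_a, mcols(annotation)$feature_id)
    ib <- match(ids_b, mcols(annotation)$feature_id)
    suppressWarnings(distance(annotation[ia], annotation[ib],
                              ignore.strand = TRUE))
}

.emptyPairTable <- function() {
    data.frame(regulator_id = character(), regulator_class = character(),
               target_id = character(), pair_type = character(),
               distance_bp = integer(), r = numeric(), p = numeric(),
               is_core = logical(), stringsAsFactors = FALSE)
}

#' Cis regulatory pairs
#'
#' Candidate pairs are DE lncRNA/circRNA regulators and DE mRNA targets on
#' the same chromosome with an inter-feature gap of at most `cis_window_bp`
#' (overlap counts as 0; the boundary is inclusive, so a gap of exactly
#' 100,000 bp qualifies); a candidate is kept iff `|r| > r_cis`.
#'
#' @param annotation GRanges annotation covering all features.
#' @param de_regulators character vector of DE lncRNA/circRNA ids.
#' @param de_mrna character vector of DE mRNA ids.
#' @param expr numeric expression matrix (features x samples) covering both.
#' @param config a [cernaConfig()].
#' @return a `PairTable` data.frame (`pair_type = "cis"`).
#' @export
cisPairs <- function(annotation, de_regulators, de_mrna, expr,
                     config = cernaConfig()) {
    ann_ids <- mcols(annotation)$feature_id
    noCoord <- setdiff(c(de_regulators, de_mrna), ann_ids)
    if (length(noCoord)) {
        warning(length(noCoord), " feature(s) without coordinates excluded")
        de_regulators <- setdiff(de_regulators, noCoord)
        de_mrna <- setdiff(de_mrna, noCoord)
    }
    if (!length(de_regulators) || !length(de_mrna)) return(.emptyPairTable())
    grid <- expand.grid(regulator_id = de_regulators, target_id = de_mrna,
                        stringsAsFactors = FALSE)
    gap <- .pairGap(annotation, grid$regulator_id, grid$target_id)
    inwin <- !is.na(gap) & gap <= config$cis_window_bp
    grid <- grid[inwin, , drop = FALSE]
    gap <- gap[inwin]
    if (!nrow(grid)) return(.emptyPairTable())
    r <- vapply(seq_len(nrow(grid)), function(i)
        cor(expr[grid$regulator_id[i], ], expr[grid$target_id[i], ]),
        numeric(1))
    n <- ncol(expr)
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
    p <- 2 * pt(-abs(tt), n - 2)
    keep <- abs(r) > config$r_cis
    cls <- mcols(annotation)$rna_class[match(grid$regulator_id, ann_ids)]
    out <- data.frame(regulator_id = grid$regulator_id,
                      regulator_class = cls,
                      target_id = grid$target_id, pair_type = "cis",
                      distance_bp = as.integer(gap), r = r, p = p,
                      is_core = FALSE, stringsAsFactors = FALSE)[keep, ]
    rownames(out) <- NULL
    out
}

#' Trans regulatory pairs
#'
#' All DE lncRNA x DE mRNA pairs with `|r| > r_trans`; pairs that are
#' window-eligible (same chromosome, gap <= `cis_window_bp`) are excluded
#' when `config$trans_exclude_cis` is TRUE so the cis and trans networks
#' stay disjoint.
#'
#' @param annotation GRanges annotation (for the window exclusion).
#' @param de_lnc,de_mrna DE lncRNA / mRNA ids.
#' @param expr expression matrix covering both.
#' @param config a [cernaConfig()].
#' @return a `PairTable` data.frame (`pair_type = "trans"`).
#' @export
transPairs <- function(annotation, de_lnc, de_mrna, expr,
                       config = cernaConfig()) {
    if (!length(de_lnc) || !length(de_mrna)) return(.emptyPairTable())
    pm <- pearsonMatrix(expr[de_lnc, , drop = FALSE],
                        expr[de_mrna, , drop = FALSE])
    hit <- which(abs(pm$r) > config$r_trans, arr.ind = TRUE)
    if (!nrow(hit)) return(.emptyPairTable())
    grid <- data.frame(regulator_id = de_lnc[hit[, 1]],
                       target_id = de_mrna[hit[, 2]],
                       stringsAsFactors = FALSE)
    gap <- .pairGap(annotation, grid$regulator_id, grid$target_id)
    keep <- if (config$trans_exclude_cis)
        is.na(gap) | gap > config$cis_window_bp else rep(TRUE, nrow(grid))
    out <- data.frame(regulator_id = grid$regulator_id,
                      regulator_class = "lncRNA",
                      target_id = grid$target_id, pair_type = "trans",
                      distance_bp = NA_integer_,
                      r = pm$r[hit], p = pm$p[hit],
                      is_core = FALSE, stringsAsFactors = FALSE)[keep, ]
    out <- out[order(out$regulator_id, out$target_id), ]
    rownames(out) <- NULL
    out
}

#' circRNA-parent gene pairs
#'
#' One pair per DE circRNA with an annotated host mRNA; the Pearson r with
#' the host is attached for reporting but no threshold is applied.
#'
#' @param annotation GRanges annotation with `host_gene_id`.
#' @param de_circ DE circRNA ids.
#' @param expr expression matrix (may omit features; r becomes NA).
#' @return a `PairTable` data.frame (`pair_type = "parent"`).
#' @export
parentPairs <- function(annotation, de_circ, expr = NULL) {
    ann_ids <- mcols(annotation)$feature_id
    host <- mcols(annotation)$host_gene_id[match(de_circ, ann_ids)]
    miss <- is.na(host)
    if (any(miss))
        warning(sum(miss), " circRNA(s) without host annotation skipped")
    circ <- de_circ[!miss]; host <- host[!miss]
    if (!length(circ)) return(.emptyPairTable())
    r <- rep(NA_real_, length(circ)); p <- rep(NA_real_, length(circ))
    if (!is.null(expr)) {
        ok <- circ %in% rownames(expr) & host %in% rownames(expr)
        if (any(ok)) {
            n <- ncol(expr)
            r[ok] <- vapply(which(ok), function(i)
                cor(expr[circ[i], ], expr[host[i], ]), numeric(1))
            tt <- r[ok] * sqrt((n - 2) / pmax(1 - r[ok]^2, 1e-300))
            p[ok] <- 2 * pt(-abs(tt), n - 2)
        }
    }
    data.frame(regulator_id = circ, regulator_class = "circRNA",
               target_id = host, pair_type = "parent",
               distance_bp = 0L, r = r, p = p, is_core = FALSE,
               stringsAsFactors = FALSE)
}

#' Restrict pairs to hub-gene targets
#'
#' Marks `is_core = target_id %in% hubs`; the core network is the marked
#' subset.
#'
#' @param pairs a `PairTable`.
#' @param hubs character vector of hub gene ids.
#' @param keep_all return all pairs with the flag set (default) or only the
#'   core subset.
#' @return the `PairTable` with `is_core` set (optionally filtered).
#' @export
coreFilter <- function(pairs, hubs, keep_all = TRUE) {
    pairs$is_core <- pairs$target_id %in% hubs
    if (keep_all) pairs else pairs[pairs$is_core, , drop = FALSE]
}

#' Node/edge tables of a pair network
#'
#' @param pairs a `PairTable`.
#' @param annotation GRanges annotation (for node classes).
#' @param moduleLabels optional named module labels for mRNA nodes.
#' @return list with `nodes` and `edges` for [exportNetwork()].
#' @export
pairNetworkTables <- function(pairs, annotation, moduleLabels = NULL) {
    ids <- sort(unique(c(pairs$regulator_id, pairs$target_id)))
    cls <- mcols(annotation)$rna_class[match(ids, mcols(annotation)$feature_id)]
    mod <- if (!is.null(moduleLabels))
        ifelse(ids %in% names(moduleLabels),
               moduleColorName(moduleLabels[ids]), "none")
    else rep("none", length(ids))
    nodes <- data.frame(id = ids, rna_class = cls, module = mod,
                        stringsAsFactors = FALSE)
    edges <- data.frame(from = pairs$regulator_id, to = pairs$target_id,
                        interaction = pairs$pair_type,
                        stringsAsFactors = FALSE)
    list(nodes = nodes, edges = edges)
}
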