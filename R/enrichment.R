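#' @importFrom stats phyper p.adjust
NULL

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`: drawing `n` query genes from a universe
#' of `N` genes of which `K` carry the term.
#'
#' @param k query genes carrying the term.
#' @param K universe genes carrying the term.
#' @param n query size.
#' @param N universe size.
#' @return p-value in (0, 1\].
#' @export
hypergeomTest <- function(k, K, n, N) {
    if (any(k < 0 | k > pmin(K, n) | K > N | n > N))
        stop("hypergeometric bounds violated")
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values `p_(i) * m / i` with cumulative-minimum
#' enforcement, capped at 1, returned in the input order (delegates to
#' [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values.
#' @export
fdrAdjust <- function(p) p.adjust(p, method = "BH")

#' Hypergeometric gene-set enrichment
#'
#' One row per term with at least one query gene; p-values from
#' [hypergeomTest()] against the supplied universe, FDR-adjusted across the
#' tested terms, ordered by p (top-10 first).
#'
#' @param query character vector of query gene ids (must be in `universe`).
#' @param termMap data.frame with `term_id`, `gene_id` and optionally
#'   `term_name`; genes outside the universe are dropped with a warning.
#' @param universe character vector of background gene ids.
#' @param config a [cernaConfig()] (uses `fdr_enrich`).
#' @return `EnrichResult` data.frame: `term_id`, `term_name`, `k`, `K`,
#'   `n`, `N`, `p`, `fdr`, `significant`, `rank`.
#' @export
enrich <- function(query, termMap, universe, config = cernaConfig()) {
    empty <- data.frame(term_id = character(), term_name = character(),
                        k = integer(), K = integer(), n = integer(),
                        N = integer(), p = numeric(), fdr = numeric(),
                        significant = logical(), rank = integer(),
                        stringsAsFactors = FALSE)
    if (!length(query)) return(empty)
    bad <- setdiff(query, universe)
    if (length(bad)) stop("query gene(s) outside the universe: ",
                          paste(utils::head(bad, 5), collapse = ", "))
    out_univ <- !(termMap$gene_id %in% universe)
    if (any(out_univ)) {
        warning(sum(out_univ), " term-map gene(s) outside the universe dropped")
        termMap <- termMap[!out_univ, , drop = FALSE]
    }
    if (is.null(termMap$term_name)) termMap$term_name <- termMap$term_id
    termMap <- unique(termMap[, c("term_id", "gene_id", "term_name")])
    N <- length(unique(universe))
    n <- length(unique(query))
    byterm <- split(termMap$gene_id, termMap$term_id)
    k <- vapply(byterm, function(g) length(intersect(g, query)), integer(1))
    K <- lengths(byterm)
    keep <- k >= 1
    if (!any(keep)) return(empty)
    k <- k[keep]; K <- K[keep]
    terms <- names(byterm)[keep]
    p <- hypergeomTest(k, K, n, N)
    fdr <- fdrAdjust(p)
    nm <- termMap$term_name[match(terms, termMap$term_id)]
    out <- data.frame(term_id = terms, term_name = nm,
                      k = as.integer(k), K = as.integer(K),
                      n = n, N = N, p = unname(p), fdr = unname(fdr),
                      significant = unname(fdr < config$fdr_enrich),
                      stringsAsFactors = FALSE)
    out <- out[order(out$p, out$term_id), ]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
}

#' Read / write a two-column term-gene map TSV
#'
#' @param path TSV with columns `term_id`, `gene_id` and optional
#'   `term_name`.
#' @return `readTermMap`: data.frame.
#' @export
readTermMap <- function(path) {
    tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    if (!all(c("term_id", "gene_id") %in% colnames(tab)))
        stop("term map must have columns term_id, gene_id")
    tab
}

#' @rdname readTermMap
#' @param termMap term map data.frame.
#' @export
writeTermMap <- function(termMap, path) {
    write.table(termMap, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
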