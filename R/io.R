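#' @importFrom utils read.delim write.table
#' @importFrom GenomicRanges GRanges mcols `mcols<-` seqnames start end strand
#' @importFrom IRanges IRanges
NULL

#' Read a count matrix from TSV
#'
#' The file must have a header row of sample ids and the feature ids in the
#' first column. RNA classes and feature lengths are joined from the
#' annotation; feature and sample order are preserved.
#'
#' @param path counts TSV path.
#' @param annotation a [GenomicRanges::GRanges] annotation as returned by
#'   [readAnnotation()] or [simulateAnnotation()] (metadata columns
#'   `feature_id`, `rna_class`, `feature_length`).
#' @param sampleTable data.frame with `sample_id`, `time_point_hours`,
#'   `replicate` covering all count columns.
#' @return An [RnaExperiment-class].
#' @export
readCounts <- function(path, annotation, sampleTable) {
    header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
    samples <- header[-1]
    if (anyDuplicated(samples))
        stop("duplicate sample column(s): ",
             paste(unique(samples[duplicated(samples)]), collapse = ", "))
    tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      colClasses = c("character", rep("numeric", length(samples))))
    ids <- tab[[1]]
    if (anyDuplicated(ids))
        stop("duplicate feature id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- ids
    if (anyNA(m) || any(m < 0) || any(m != round(m)))
        stop("counts must be non-negative integers")
    storage.mode(m) <- "integer"
    ann_ids <- mcols(annotation)$feature_id
    missing <- setdiff(ids, ann_ids)
    if (length(missing))
        stop("feature(s) missing from annotation: ",
             paste(utils::head(missing, 10), collapse = ", "),
             if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10) else "")
    idx <- match(ids, ann_ids)
    RnaExperiment(m, mcols(annotation)$rna_class[idx],
                  mcols(annotation)$feature_length[idx], sampleTable)
}

#' @rdname readCounts
#' @param x an [RnaExperiment-class] (or integer matrix).
#' @export
writeCounts <- function(x, path) {
    m <- if (is(x, "RnaExperiment")) counts(x) else x
    df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read / write a feature annotation table
#'
#' A simplified 7-column TSV (`feature_id`, `chromosome`, `start`, `end`,
#' `strand`, `rna_class`, `host_gene_id`) with 1-based inclusive coordinates,
#' plus a `feature_length` column. Returned as a
#' [GenomicRanges::GRanges] whose metadata carry `feature_id`, `rna_class`,
#' `feature_length` and (for circRNAs) `host_gene_id`.
#'
#' @param path TSV path.
#' @return `readAnnotation`: a `GRanges`.
#' @export
readAnnotation <- function(path) {
    tab <- read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, na.strings = c("NA", ""))
    req <- c("feature_id", "chromosome", "start", "end", "strand", "rna_class",
             "feature_length")
    if (!all(req %in% colnames(tab)))
        stop("annotation must have columns: ", paste(req, collapse = ", "))
    if (anyDuplicated(tab$feature_id))
        stop("duplicate feature id(s) in annotation")
    if (any(tab$start > tab$end)) stop("annotation has start > end")
    if (is.null(tab$host_gene_id)) tab$host_gene_id <- NA_character_
    has_host <- !is.na(tab$host_gene_id)
    if (any(has_host & tab$rna_class != "circRNA"))
        stop("host_gene_id is only valid for circRNAs")
    hosts <- tab$host_gene_id[has_host]
    host_cls <- tab$rna_class[match(hosts, tab$feature_id)]
    if (any(is.na(host_cls) | host_cls != "mRNA"))
        stop("host_gene_id must name an mRNA feature")
    gr <- GRanges(tab$chromosome, IRanges(tab$start, tab$end),
                  strand = ifelse(tab$strand %in% c("+", "-"), tab$strand, "*"))
    mcols(gr) <- S4Vectors::DataFrame(
        feature_id = tab$feature_id, rna_class = tab$rna_class,
        feature_length = as.integer(tab$feature_length),
        host_gene_id = tab$host_gene_id)
    names(gr) <- tab$feature_id
    gr
}

#' @rdname readAnnotation
#' @param annotation a `GRanges` as produced by [readAnnotation()].
#' @export
writeAnnotation <- function(annotation, path) {
    std <- as.character(strand(annotation))
    df <- data.frame(feature_id = mcols(annotation)$feature_id,
                     chromosome = as.character(seqnames(annotation)),
                     start = start(annotation), end = end(annotation),
                     strand = ifelse(std == "*", ".", std),
                     rna_class = mcols(annotation)$rna_class,
                     feature_length = mcols(annotation)$feature_length,
                     host_gene_id = mcols(annotation)$host_gene_id,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read / write a miRNA-target interaction table
#'
#' Four columns: `mirna_id`, `target_id`, `source`
#' (`starbase_like`/`miranda_like`) and optional `score`.
#' (mirna_id, target_id, source) triples must be unique.
#'
#' @param path TSV path.
#' @return `readTargets`: a data.frame.
#' @export
readTargets <- function(path) {
    tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    req <- c("mirna_id", "target_id", "source")
    if (!all(req %in% colnames(tab)))
        stop("target table must have columns: ", paste(req, collapse = ", "))
    if (is.null(tab$score)) tab$score <- NA_real_
    key <- paste(tab$mirna_id, tab$target_id, tab$source, sep = "\r")
    if (anyDuplicated(key))
        stop("duplicate (mirna_id, target_id, source) row(s)")
    tab
}

#' @rdname readTargets
#' @param targets a target data.frame.
#' @export
writeTargets <- function(targets, path) {
    write.table(targets, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Drop features with too many zero-count samples
#'
#' A feature is retained iff the fraction of its samples with a zero count is
#' strictly below `max_zero_fraction`; a feature with exactly 25% zeros is
#' dropped under the default. The rule depends only on each feature's own
#' zero fraction, so it is applied identically whether classes are filtered
#' separately or together, and it is idempotent.
#'
#' @param x an [RnaExperiment-class].
#' @param max_zero_fraction fraction of zero samples at/above which a feature
#'   is excluded (default 0.25).
#' @return The filtered [RnaExperiment-class].
#' @export
filterLowExpression <- function(x, max_zero_fraction = 0.25) {
    zf <- rowMeans(counts(x) == 0)
    keep <- zf < max_zero_fraction
    if (!any(keep)) warning("no features retained after low-expression filtering")
    x[keep, ]
}

#' Export a network as GraphML and SIF
#'
#' Nodes and edges are written in sorted order so that re-exporting the same
#' network is byte-identical. Node attributes (e.g. `rna_class`, `module`)
#' are carried into the GraphML.
#'
#' @param nodes data.frame with first column `id` plus attribute columns.
#' @param edges data.frame with columns `from`, `to` and optionally
#'   `interaction` (defaults to `"pp"`) plus attribute columns.
#' @param basePath output path without extension; writes `<basePath>.graphml`
#'   and `<basePath>.sif`.
#' @return invisibly, the two file paths.
#' @export
exportNetwork <- function(nodes, edges, basePath) {
    stopifnot(is.data.frame(nodes), "id" %in% colnames(nodes))
    if (anyDuplicated(nodes$id)) stop("duplicate node ids")
    if (nrow(edges)) {
        stopifnot(all(c("from", "to") %in% colnames(edges)))
        dangling <- setdiff(c(edges$from, edges$to), nodes$id)
        if (length(dangling))
            stop("edge endpoint(s) not in node table: ",
                 paste(utils::head(dangling, 10), collapse = ", "))
    }
    if (is.null(edges$interaction)) edges$interaction <- rep("pp", nrow(edges))
    nodes <- nodes[order(nodes$id), , drop = FALSE]
    if (nrow(edges))
        edges <- edges[order(edges$from, edges$to, edges$interaction), , drop = FALSE]
    g <- igraph::graph_from_data_frame(
        edges[, c("from", "to",
                  setdiff(colnames(edges), c("from", "to"))), drop = FALSE],
        directed = FALSE, vertices = nodes)
    graphml <- paste0(basePath, ".graphml")
    igraph::write_graph(g, graphml, format = "graphml")
    sif <- paste0(basePath, ".sif")
    lines <- if (nrow(edges))
        paste(edges$from, edges$interaction, edges$to, sep = "\t")
    else character()
    isolated <- setdiff(nodes$id, c(edges$from, edges$to))
    writeLines(c(lines, isolated), sif)
    invisible(c(graphml = graphml, sif = sif))
}
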