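#' @import methods
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom BiocGenerics counts
NULL

RNA_CLASSES <- c("lncRNA", "circRNA", "miRNA", "mRNA")
TIME_POINTS <- c(0L, 12L, 24L, 48L, 72L)

#' Multi-class RNA-seq count container
#'
#' `RnaExperiment` extends [SummarizedExperiment::SummarizedExperiment] with a
#' `"counts"` assay of non-negative integers, per-feature RNA class
#' (`lncRNA`, `circRNA`, `miRNA` or `mRNA`) and feature length in `rowData`,
#' and the time-course design (`time_point_hours`, `replicate`) in `colData`.
#' It is the input type of every analysis stage of the pipeline.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("RnaExperiment", contains = "SummarizedExperiment")

.validRnaExperiment <- function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (anyNA(cnt) || any(cnt < 0))
        msg <- c(msg, "counts must be non-negative and non-missing")
    if (any(cnt != round(cnt)))
        msg <- c(msg, "counts must be integers")
    rd <- rowData(object)
    if (!all(c("rna_class", "feature_length") %in% colnames(rd)))
        msg <- c(msg, "rowData must contain 'rna_class' and 'feature_length'")
    else {
        if (!all(rd$rna_class %in% RNA_CLASSES))
            msg <- c(msg, sprintf("rna_class must be one of %s",
                                  paste(RNA_CLASSES, collapse = ", ")))
        if (any(rd$feature_length <= 0))
            msg <- c(msg, "feature_length must be positive")
    }
    cd <- colData(object)
    if (!all(c("time_point_hours", "replicate") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'time_point_hours' and 'replicate'")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate feature ids")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample ids")
    if (length(msg)) msg else TRUE
}
setValidity("RnaExperiment", .validRnaExperiment)

#' Construct an RnaExperiment
#'
#' @param counts integer matrix, features x samples, with row and column names.
#' @param rnaClass character vector (one of `lncRNA`, `circRNA`, `miRNA`,
#'   `mRNA`) per feature.
#' @param featureLength positive integer vector of feature lengths (nt),
#'   used by [tpm()] and [fpkm()].
#' @param sampleTable data.frame with columns `sample_id`,
#'   `time_point_hours`, `replicate`; rows matched to `colnames(counts)`.
#' @return An [RnaExperiment-class] object.
#' @examples
#' cnt <- matrix(rpois(12, 20), 3, 4,
#'               dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' st <- data.frame(sample_id = colnames(cnt),
#'                  time_point_hours = c(0, 0, 12, 12), replicate = c(1, 2, 1, 2))
#' re <- RnaExperiment(cnt, rep("mRNA", 3), c(500L, 1000L, 1500L), st)
#' @export
RnaExperiment <- function(counts, rnaClass, featureLength, sampleTable) {
    counts <- as.matrix(counts)
    stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
    if (!all(colnames(counts) %in% sampleTable$sample_id))
        stop("sampleTable does not cover all count columns")
    sampleTable <- sampleTable[match(colnames(counts), sampleTable$sample_id), ,
                               drop = FALSE]
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowData = DataFrame(rna_class = as.character(rnaClass),
                            feature_length = as.integer(featureLength),
                            row.names = rownames(counts)),
        colData = DataFrame(time_point_hours = as.integer(sampleTable$time_point_hours),
                            replicate = as.integer(sampleTable$replicate),
                            row.names = colnames(counts)))
    new("RnaExperiment", se)
}

#' @describeIn RnaExperiment counts assay accessor.
#' @param object,x an `RnaExperiment`.
#' @export
setMethod("counts", "RnaExperiment", function(object)
    SummarizedExperiment::assay(object, "counts"))

#' RNA class of each feature
#' @param x an [RnaExperiment-class].
#' @return named character vector.
#' @export
rnaClass <- function(x) setNames(rowData(x)$rna_class, rownames(x))

#' Feature length (nt) of each feature
#' @param x an [RnaExperiment-class].
#' @return named integer vector.
#' @export
featureLength <- function(x) setNames(rowData(x)$feature_length, rownames(x))

#' Time point (hours post-surgery) of each sample
#' @param x an [RnaExperiment-class].
#' @return named integer vector.
#' @export
timePoints <- function(x) setNames(colData(x)$time_point_hours, colnames(x))

#' Sample table of an RnaExperiment
#' @param x an [RnaExperiment-class].
#' @return data.frame with `sample_id`, `time_point_hours`, `replicate`.
#' @export
sampleTable <- function(x)
    data.frame(sample_id = colnames(x),
               time_point_hours = colData(x)$time_point_hours,
               replicate = colData(x)$replicate,
               stringsAsFactors = FALSE)

setMethod("show", "RnaExperiment", function(object) {
    cls <- table(factor(rowData(object)$rna_class, RNA_CLASSES))
    cat("RnaExperiment:", nrow(object), "features x", ncol(object), "samples\n")
    cat("  classes:",
        paste(sprintf("%s=%d", names(cls), as.integer(cls)), collapse = ", "), "\n")
    tp <- table(colData(object)$time_point_hours)
    cat("  time points (h):",
        paste(sprintf("%s(n=%d)", names(tp), as.integer(tp)), collapse = ", "), "\n")
})

#' Co-expression analysis result
#'
#' Holds everything the weighted co-expression stage computes: module labels
#' (0 = unassigned/grey) with colour-style names, module eigengenes,
#' module-trait correlations, per-trait key modules, gene significance (GS),
#' module membership (MM), and the hub-gene set.
#'
#' @slot labels named integer vector, gene -> module label (0 = unassigned).
#' @slot colors named character vector of colour-style module names per gene.
#' @slot eigengenes numeric matrix, modules x samples, unit-variance rows.
#' @slot moduleTraitR,moduleTraitP numeric matrices, modules x time points.
#' @slot keyModules named integer vector: time point (hours, as name) -> label.
#' @slot GS numeric matrix genes x time points (gene significance).
#' @slot MM numeric matrix genes x modules (module membership).
#' @slot hubGenes character vector of hub gene ids.
#' @slot hubModule named integer vector: hub gene -> module of provenance.
#' @slot softPower integer, selected soft-threshold power.
#' @slot removedSamples character vector of outlier samples dropped.
#' @export
setClass("ModuleResult", representation(
    labels = "integer",
    colors = "character",
    eigengenes = "matrix",
    moduleTraitR = "matrix",
    moduleTraitP = "matrix",
    keyModules = "integer",
    GS = "matrix",
    MM = "matrix",
    hubGenes = "character",
    hubModule = "integer",
    softPower = "integer",
    removedSamples = "character"))

setValidity("ModuleResult", function(object) {
    msg <- character()
    if (length(object@labels) && is.null(names(object@labels)))
        msg <- c(msg, "labels must be named by gene")
    if (any(abs(object@moduleTraitR) > 1 + 1e-8, na.rm = TRUE))
        msg <- c(msg, "|module-trait r| must be <= 1")
    if (any(abs(object@GS) > 1 + 1e-8, na.rm = TRUE))
        msg <- c(msg, "|GS| must be <= 1")
    if (any(abs(object@MM) > 1 + 1e-8, na.rm = TRUE))
        msg <- c(msg, "|MM| must be <= 1")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ModuleResult", function(object) {
    sz <- table(object@labels[object@labels > 0])
    cat("ModuleResult:", length(object@labels), "genes,",
        length(sz), "modules (+", sum(object@labels == 0), "unassigned)\n")
    if (length(sz))
        cat("  sizes:", paste(sprintf("%s=%d", moduleColorName(as.integer(names(sz))),
                                      as.integer(sz)), collapse = ", "), "\n")
    cat("  soft power:", object@softPower, "\n")
    cat("  key modules:",
        paste(sprintf("%sh->%s", names(object@keyModules),
                      moduleColorName(object@keyModules)), collapse = ", "), "\n")
    cat("  hub genes:", length(object@hubGenes), "\n")
})

#' @describeIn ModuleResult module labels accessor.
#' @param x a `ModuleResult`.
#' @export
moduleLabels <- function(x) x@labels

#' @describeIn ModuleResult eigengene matrix accessor (modules x samples).
#' @export
moduleEigengenes <- function(x) x@eigengenes

#' @describeIn ModuleResult hub gene accessor.
#' @export
hubGenes <- function(x) x@hubGenes

#' @describeIn ModuleResult key module accessor (time point -> module label).
#' @export
keyModules <- function(x) x@keyModules

# WGCNA-style colour vocabulary, cosmetic only; label 0 is grey.
.MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                    "black", "pink", "magenta", "purple", "greenyellow", "tan",
                    "salmon", "cyan", "midnightblue", "lightcyan", "grey60",
                    "lightgreen", "lightyellow", "royalblue")

#' Colour-style name of a module label
#' @param label integer module label(s); 0 is "grey" (unassigned).
#' @return character vector of colour names.
#' @export
moduleColorName <- function(label) {
    ifelse(label == 0, "grey",
           ifelse(label <= length(.MODULE_COLORS), .MODULE_COLORS[pmax(label, 1)],
                  paste0("module", label)))
}
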