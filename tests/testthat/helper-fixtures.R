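# Small fixtures built in code at test time.

tinyParams <- function(seed = 3L, ...) {
    args <- utils::modifyList(
        list(n_lnc = 60L, n_circ = 20L, n_mirna = 40L, n_mrna = 300L,
             n_modules = 3L, module_size = 60L, n_cis = 10L,
             n_triads_lnc = 6L, n_triads_circ = 4L, seed = seed),
        list(...))
    do.call(simParams, args)
}

tinyRex <- function(seed = 3L, n_genes = 8L, n_per_group = 3L, mu = 50) {
    set.seed(seed)
    cnt <- matrix(rpois(n_genes * 2 * n_per_group, mu), n_genes,
                  dimnames = list(paste0("g", seq_len(n_genes)),
                                  paste0("s", seq_len(2 * n_per_group))))
    st <- data.frame(sample_id = colnames(cnt),
                     time_point_hours = rep(c(0L, 12L), each = n_per_group),
                     replicate = rep(seq_len(n_per_group), 2))
    RnaExperiment(cnt, rep("mRNA", n_genes),
                  sample(500:2000, n_genes, replace = TRUE), st)
}

# a minimal valid annotation GRanges built directly
tinyAnnotation <- function(df) {
    gr <- GenomicRanges::GRanges(df$chromosome,
                                 IRanges::IRanges(df$start, df$end))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        feature_id = df$feature_id, rna_class = df$rna_class,
        feature_length = df$feature_length,
        host_gene_id = if (!is.null(df$host_gene_id)) df$host_gene_id
        else rep(NA_character_, nrow(df)))
    names(gr) <- df$feature_id
    gr
}
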