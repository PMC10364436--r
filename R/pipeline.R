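#' @importFrom jsonlite write_json read_json
NULL

.stageSeed <- function(seed, stage)
    as.integer((as.numeric(seed) * 1009 + stage) %% 2147483629)

.log <- function(logfile, ...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    message(msg)
    if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
}

#' Run the full pipeline on a synthetic benchmark
#'
#' Executes simulate -> low-expression filter -> differential expression ->
#' weighted co-expression -> cis/trans/parent regulatory pairing -> ceRNA
#' triads -> enrichment, writing every intermediate table plus GraphML/SIF
#' networks and a machine-readable run summary to `outdir`. Identical
#' `params`/`config`/`seed` produce byte-identical outputs (wall times go
#' to the log only).
#'
#' @param params a [simParams()]; its `seed` is overridden by `seed`.
#' @param config a [cernaConfig()].
#' @param outdir output directory (created).
#' @param seed integer seed fanned out to per-stage child seeds.
#' @param logfile optional log file path.
#' @return the run summary (a nested list), invisibly also written to
#'   `run_summary.json`.
#' @export
runAll <- function(params = simParams(), config = cernaConfig(),
                   outdir = "cerna_run", seed = params$seed,
                   logfile = NULL) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    t0 <- Sys.time()
    params$seed <- .stageSeed(seed, 1L)
    # --- simulate ---
    .log(logfile, "stage simulate: seed ", params$seed)
    sim <- simulateAll(params)
    rex <- sim$rex
    writeCounts(rex, file.path(outdir, "counts.tsv"))
    write.table(sampleTable(rex), file.path(outdir, "samples.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeAnnotation(sim$annotation, file.path(outdir, "annotation.tsv"))
    writeTargets(sim$targets, file.path(outdir, "targets.tsv"))
    writeTermMap(sim$termMap, file.path(outdir, "term_map.tsv"))
    write_json(list(cis = sim$truth$cis, triads = sim$truth$triads,
                    module = as.list(sim$truth$module),
                    de = sim$truth$de),
               file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
    # --- filter ---
    filt <- filterLowExpression(rex)
    writeCounts(filt, file.path(outdir, "counts_filtered.tsv"))
    .log(logfile, "stage filter: ", nrow(filt), "/", nrow(rex),
         " features retained")
    # --- differential expression ---
    de <- callDE(filt, config = config)
    write.table(de, file.path(outdir, "de_table.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    de_counts <- table(de$rna_class[de$direction != "ns"],
                       de$contrast[de$direction != "ns"])
    .log(logfile, "stage de: ", length(unionDE(de)), " union-DE features")
    # --- co-expression on union-DE mRNAs ---
    de_mrna <- unionDE(de, "mRNA")
    if (length(de_mrna) < 2 * config$min_module_size)
        stop("stage coexpression: too few union-DE mRNAs (",
             length(de_mrna), ")")
    mres <- runCoexpression(filt[de_mrna, ], config)
    write.table(data.frame(gene_id = names(moduleLabels(mres)),
                           module = unname(moduleLabels(mres)),
                           color = unname(mres@colors),
                           stringsAsFactors = FALSE),
                file.path(outdir, "modules.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(module = rownames(moduleEigengenes(mres)),
                           moduleEigengenes(mres), check.names = FALSE),
                file.path(outdir, "eigengenes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(gene_id = rownames(mres@GS), mres@GS,
                           check.names = FALSE),
                file.path(outdir, "gene_significance.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(gene_id = rownames(mres@MM), mres@MM,
                           check.names = FALSE),
                file.path(outdir, "module_membership.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(gene_id = hubGenes(mres),
                           module = unname(mres@hubModule[hubGenes(mres)]),
                           stringsAsFactors = FALSE),
                file.path(outdir, "hub_genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    .log(logfile, "stage coexpression: ",
         length(unique(moduleLabels(mres)[moduleLabels(mres) > 0])),
         " modules, ", length(hubGenes(mres)), " hubs, power ",
         mres@softPower)
    # --- regulatory pairs ---
    expr <- log2(tpm(filt) + 1)
    de_lnc <- unionDE(de, "lncRNA")
    de_circ <- unionDE(de, "circRNA")
    cis <- cisPairs(sim$annotation, c(de_lnc, de_circ), de_mrna, expr, config)
    trans <- transPairs(sim$annotation, de_lnc, de_mrna, expr, config)
    parent <- parentPairs(sim$annotation, de_circ, expr)
    hubs <- hubGenes(mres)
    cis <- coreFilter(cis, hubs); trans <- coreFilter(trans, hubs)
    parent <- coreFilter(parent, hubs)
    pairs <- rbind(cis, trans, parent)
    write.table(pairs, file.path(outdir, "pair_table.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (pt in c("cis", "trans")) {
        core <- pairs[pairs$pair_type == pt & pairs$is_core, , drop = FALSE]
        nt <- pairNetworkTables(core, sim$annotation, moduleLabels(mres))
        exportNetwork(nt$nodes, nt$edges,
                      file.path(outdir, paste0("core_", pt)))
    }
    .log(logfile, "stage regnet: ", sum(pairs$pair_type == "cis"), " cis / ",
         sum(pairs$pair_type == "trans"), " trans / ",
         sum(pairs$pair_type == "parent"), " parent pairs (",
         sum(pairs$is_core), " core)")
    # --- ceRNA triads ---
    cand <- candidateTriads(sim$targets, de, hubs, config)
    triads <- filterTriads(cand, expr, config)
    write.table(triads, file.path(outdir, "triad_table.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    nets <- buildCoreNetworks(triads, moduleLabels(mres))
    for (cl in names(nets))
        exportNetwork(nets[[cl]]$nodes, nets[[cl]]$edges,
                      file.path(outdir, paste0("cerna_", cl)))
    .log(logfile, "stage cerna: ", nrow(cand), " candidates -> ",
         nrow(triads), " triads")
    # --- enrichment of hub genes ---
    universe <- rownames(filt)[rnaClass(filt) == "mRNA"]
    er <- enrich(intersect(hubs, universe), sim$termMap, universe, config)
    write.table(er, file.path(outdir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    .log(logfile, "stage enrich: ", sum(er$significant), " significant terms")
    # --- summary ---
    msize <- table(moduleLabels(mres)[moduleLabels(mres) > 0])
    summary <- list(
        seed = seed,
        config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
        n_features = nrow(rex), n_samples = ncol(rex),
        n_retained = nrow(filt),
        de_per_class_contrast = as.list(as.data.frame.matrix(de_counts)),
        n_union_de = list(lncRNA = length(de_lnc), circRNA = length(de_circ),
                          miRNA = length(unionDE(de, "miRNA")),
                          mRNA = length(de_mrna)),
        soft_power = mres@softPower,
        removed_samples = mres@removedSamples,
        n_modules = length(msize),
        module_sizes = as.list(setNames(as.integer(msize), names(msize))),
        key_modules = as.list(keyModules(mres)),
        n_hub_genes = length(hubs),
        n_pairs = list(cis = sum(pairs$pair_type == "cis"),
                       trans = sum(pairs$pair_type == "trans"),
                       parent = sum(pairs$pair_type == "parent"),
                       core = sum(pairs$is_core)),
        n_triads = list(lncRNA = sum(triads$cerna_class == "lncRNA"),
                        circRNA = sum(triads$cerna_class == "circRNA")),
        cerna_members = lapply(nets, function(n) as.list(n$summary)),
        n_enriched_terms = sum(er$significant))
    write_json(summary, file.path(outdir, "run_summary.json"),
               auto_unbox = TRUE, digits = NA, pretty = TRUE)
    .log(logfile, "done in ",
         round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1), " s")
    invisible(summary)
}
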