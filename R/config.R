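#' Pipeline configuration
#'
#' All tunable thresholds of the pipeline, with the study defaults:
#' fold-change cutoff 1.5 for lncRNA/miRNA/mRNA and 1.0 for circRNA
#' (so the p-value alone decides for circRNAs), raw p < 0.05 for DE calls,
#' a 100-kb cis window, |r| > 0.6 for cis and |r| > 0.9 for trans pairs,
#' |MM| > 0.8 and |GS| > 0.5 for hub genes, Spearman p < 0.05 for ceRNA
#' triads, and FDR < 0.05 for enrichment.
#'
#' @param fc_lnc_mi_mrna linear fold-change threshold for lncRNA/miRNA/mRNA.
#' @param fc_circ linear fold-change threshold for circRNA (1.0 = none).
#' @param p_de raw p-value threshold for DE calls.
#' @param cis_window_bp genomic window (bp) for cis pairing.
#' @param r_cis,r_trans Pearson |r| thresholds for cis/trans pairs.
#' @param mm_hub,gs_hub module-membership / gene-significance hub thresholds
#'   (strict inequalities).
#' @param spearman_p Spearman correlation p threshold for ceRNA triads.
#' @param fdr_enrich FDR significance threshold for enrichment.
#' @param soft_power integer soft-threshold power (default 10, a robust
#'   choice for unsigned networks at ~30 samples) or `"auto"` to select the
#'   smallest power reaching the scale-free fit target.
#' @param sft_target scale-free fit index target for automatic power choice.
#' @param min_module_size smallest module retained by tree cutting.
#' @param merge_height eigengene dissimilarity below which modules merge.
#' @param outlier_cut `"auto"` or numeric dendrogram height for outlier
#'   sample removal.
#' @param fc_on expression unit for fold changes: `"tmm_cpm"` or `"tpm"`.
#' @param trans_exclude_cis drop window-eligible pairs from the trans set
#'   so cis and trans networks are disjoint.
#' @param target_combine combine miRNA-target evidence sources by
#'   `"union"` or `"intersection"`.
#' @param spearman_rule `"pvalue"` (correlation-test p < `spearman_p`) or
#'   `"coefficient"` (|rho| < `spearman_p`, the literal reading).
#' @param key_traits time points (hours) for which key modules are used in
#'   hub selection; `NULL` = all time points.
#' @param seed integer RNG seed recorded in the config.
#' @return A list of class `cerna_config`.
#' @export
cernaConfig <- function(fc_lnc_mi_mrna = 1.5, fc_circ = 1.0, p_de = 0.05,
                        cis_window_bp = 100000L, r_cis = 0.6, r_trans = 0.9,
                        mm_hub = 0.8, gs_hub = 0.5, spearman_p = 0.05,
                        fdr_enrich = 0.05, soft_power = 10L,
                        sft_target = 0.85, min_module_size = 30L,
                        merge_height = 0.25, outlier_cut = "auto",
                        fc_on = c("tmm_cpm", "tpm"),
                        trans_exclude_cis = TRUE,
                        target_combine = c("union", "intersection"),
                        spearman_rule = c("pvalue", "coefficient"),
                        key_traits = NULL, seed = 1L) {
    fc_on <- match.arg(fc_on)
    target_combine <- match.arg(target_combine)
    spearman_rule <- match.arg(spearman_rule)
    cfg <- list(fc_lnc_mi_mrna = fc_lnc_mi_mrna, fc_circ = fc_circ, p_de = p_de,
                cis_window_bp = as.integer(cis_window_bp), r_cis = r_cis,
                r_trans = r_trans, mm_hub = mm_hub, gs_hub = gs_hub,
                spearman_p = spearman_p, fdr_enrich = fdr_enrich,
                soft_power = soft_power, sft_target = sft_target,
                min_module_size = as.integer(min_module_size),
                merge_height = merge_height, outlier_cut = outlier_cut,
                fc_on = fc_on, trans_exclude_cis = trans_exclude_cis,
                target_combine = target_combine, spearman_rule = spearman_rule,
                key_traits = key_traits, seed = as.integer(seed))
    stopifnot(all(vapply(cfg[c("fc_lnc_mi_mrna", "fc_circ", "p_de",
                               "cis_window_bp", "r_cis", "r_trans", "mm_hub",
                               "gs_hub", "spearman_p", "fdr_enrich")],
                         function(v) is.numeric(v) && v > 0, logical(1))))
    class(cfg) <- "cerna_config"
    cfg
}

#' Read / write a pipeline configuration file (YAML key/value)
#'
#' @param path file path.
#' @return `readCernaConfig` returns a `cerna_config`; unknown keys error.
#' @export
readCernaConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    known <- names(formals(cernaConfig))
    bad <- setdiff(names(vals), known)
    if (length(bad))
        stop("unknown config keys: ", paste(bad, collapse = ", "))
    do.call(cernaConfig, vals)
}

#' @rdname readCernaConfig
#' @param config a `cerna_config` list.
#' @export
writeCernaConfig <- function(config, path) {
    stopifnot(inherits(config, "cerna_config"))
    vals <- unclass(config)
    vals <- vals[!vapply(vals, is.null, logical(1))]
    yaml::write_yaml(vals, path)
    invisible(path)
}
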