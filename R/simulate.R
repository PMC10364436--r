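#' @importFrom stats rnbinom rpois rnorm runif setNames
NULL

#' Simulation parameters
#'
#' Defines the synthetic study: a 5-time-point (0/12/24/48/72 h) x
#' `n_replicates` design over four RNA classes with negative-binomial counts
#' (variance mu + phi mu^2), planted co-expression modules tied to time
#' points, planted differential expression, planted cis lncRNA-mRNA
#' neighbours and planted ceRNA triads with the sign structure the ceRNA
#' hypothesis predicts (ceRNA-mRNA +, miRNA-ceRNA -, miRNA-mRNA -).
#'
#' Module archetypes cycle over "high at 0 h", "peak at 12 h", "peak at
#' 48 h" and "peak at 72 h", i.e. each module's latent driver is (up to
#' sign) the indicator of one time point, so key-module selection has a
#' planted answer.
#'
#' @param n_lnc,n_circ,n_mirna,n_mrna features per RNA class.
#' @param n_replicates replicates per time point (default 6, the study design).
#' @param nb_dispersion NB dispersion phi (variance = mu + phi mu^2).
#' @param de_log2fc planted log2 fold change (default 1.5).
#' @param n_modules planted co-expression modules among mRNAs.
#' @param module_size genes per planted module.
#' @param module_sample_sd sd (log2) of the shared per-sample module factor.
#' @param gene_noise_sd sd (log2) of extra independent per-gene-sample
#'   noise beyond the NB sampling noise (default 0: the count model is
#'   exactly NB with dispersion `nb_dispersion`).
#' @param loading_range range of per-gene loadings on the module driver.
#' @param n_cis planted cis (lncRNA, mRNA) pairs within the 100-kb window.
#' @param n_triads_lnc,n_triads_circ planted lncRNA- and circRNA-anchored
#'   ceRNA triads.
#' @param frac_extra_de fraction of unstructured non-mRNA features per class planted
#'   DE at one random time point.
#' @param library_size_range range of per-sample library-size factors
#'   (log-uniform; default \[0.5, 2\] to exercise TMM).
#' @param cis_window_bp genomic window used to place cis neighbours.
#' @param target_bg_density background density of decoy miRNA-target rows.
#' @param triad_strength loading of triad ceRNAs (positive) and miRNAs
#'   (negative) on the triad mRNA's module driver: the sponge strength.
#' @param outlier_sample index of a sample to distort (per-gene log-normal
#'   distortion of sd `outlier_sd`), or `FALSE` for none.
#' @param outlier_sd sd (log2) of the outlier distortion.
#' @param seed integer RNG seed.
#' @return list of class `sim_params`.
#' @export
simParams <- function(n_lnc = 300L, n_circ = 60L, n_mirna = 150L,
                      n_mrna = 1000L, n_replicates = 6L, nb_dispersion = 0.1,
                      de_log2fc = 1.5, n_modules = 4L, module_size = 100L,
                      module_sample_sd = 0.6, gene_noise_sd = 0,
                      loading_range = c(0.8, 1.2), n_cis = 40L,
                      n_triads_lnc = 30L, n_triads_circ = 20L,
                      frac_extra_de = 0.2, library_size_range = c(0.5, 2),
                      cis_window_bp = 100000L, target_bg_density = 0.002,
                      triad_strength = 1.1, outlier_sample = FALSE,
                      outlier_sd = 2, seed = 1L) {
    p <- list(n_lnc = as.integer(n_lnc), n_circ = as.integer(n_circ),
              n_mirna = as.integer(n_mirna), n_mrna = as.integer(n_mrna),
              n_timepoints = 5L, n_replicates = as.integer(n_replicates),
              nb_dispersion = nb_dispersion, de_log2fc = de_log2fc,
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              module_sample_sd = module_sample_sd,
              gene_noise_sd = gene_noise_sd, loading_range = loading_range,
              n_cis = as.integer(n_cis),
              n_triads_lnc = as.integer(n_triads_lnc),
              n_triads_circ = as.integer(n_triads_circ),
              frac_extra_de = frac_extra_de,
              library_size_range = library_size_range,
              cis_window_bp = as.integer(cis_window_bp),
              target_bg_density = target_bg_density,
              triad_strength = triad_strength,
              outlier_sample = outlier_sample, outlier_sd = outlier_sd,
              seed = as.integer(seed))
    stopifnot(p$nb_dispersion >= 0, p$de_log2fc > 0, p$n_replicates >= 2,
              p$n_modules * p$module_size <= p$n_mrna,
              p$n_triads_lnc + p$n_triads_circ + p$n_cis <=
                  p$n_modules * p$module_size,
              p$n_triads_circ <= p$n_circ)
    n_triads <- p$n_triads_lnc + p$n_triads_circ
    if (p$n_cis + p$n_triads_lnc > p$n_lnc)
        stop("requested cis pairs + lncRNA triads exceed available lncRNAs")
    if (n_triads > p$n_mirna)
        stop("requested triads exceed available miRNAs")
    class(p) <- "sim_params"
    p
}

.featureIds <- function(p) {
    list(lnc = sprintf("LNC%04d", seq_len(p$n_lnc)),
         circ = sprintf("CIRC%03d", seq_len(p$n_circ)),
         mir = sprintf("MIR%04d", seq_len(p$n_mirna)),
         mrna = sprintf("MRNA%05d", seq_len(p$n_mrna)))
}

# Deterministic planted design shared by annotation and count simulation:
# which features belong to which module, which are cis partners, which form
# triads, and which get extra planted DE. Index-based, no RNG.
.plantDesign <- function(p) {
    ids <- .featureIds(p)
    mod_times <- rep(c(0L, 12L, 48L, 72L), length.out = p$n_modules)
    module <- setNames(integer(p$n_mrna), ids$mrna)
    for (m in seq_len(p$n_modules))
        module[(m - 1L) * p$module_size + seq_len(p$module_size)] <- m
    # distinct module-member picks: triads first, then cis partners
    n_triads <- p$n_triads_lnc + p$n_triads_circ
    member_pool <- which(module > 0)
    pick <- function(k, offset) {
        # spread picks over modules round-robin
        m <- ((seq_len(k) - 1L) %% p$n_modules) + 1L
        j <- ((seq_len(k) - 1L) %/% p$n_modules) + 1L + offset
        if (any(j > p$module_size))
            stop("not enough module members for planted triads/cis pairs")
        (m - 1L) * p$module_size + j
    }
    triad_mrna_idx <- pick(n_triads, 0L)
    cis_mrna_idx <- pick(p$n_cis, ceiling(n_triads / p$n_modules))
    cerna <- c(ids$lnc[p$n_cis + seq_len(p$n_triads_lnc)],
               ids$circ[seq_len(p$n_triads_circ)])
    triads <- data.frame(
        cerna_id = cerna,
        mirna_id = ids$mir[seq_len(n_triads)],
        mrna_id = ids$mrna[triad_mrna_idx],
        cerna_class = c(rep("lncRNA", p$n_triads_lnc),
                        rep("circRNA", p$n_triads_circ)),
        stringsAsFactors = FALSE)
    cis <- data.frame(lncrna_id = ids$lnc[seq_len(p$n_cis)],
                      mrna_id = ids$mrna[cis_mrna_idx],
                      stringsAsFactors = FALSE)
    # driver module of every structured non-mRNA feature
    driver <- c(setNames(module[cis$mrna_id], cis$lncrna_id),
                setNames(module[triads$mrna_id], triads$cerna_id),
                setNames(module[triads$mrna_id], triads$mirna_id))
    driver_sign <- c(rep(1, nrow(cis)), rep(1, nrow(triads)),
                     rep(-1, nrow(triads)))
    names(driver_sign) <- names(driver)
    # extra planted DE among unstructured non-mRNA features; mRNA DE truth
    # comes from module members so that non-member mRNAs are pure noise for
    # the co-expression benchmark
    structured <- c(names(driver), ids$mrna[module > 0])
    extra <- unlist(lapply(ids[c("lnc", "circ", "mir")], function(v) {
        free <- setdiff(v, structured)
        utils::head(free, round(p$frac_extra_de * length(free)))
    }), use.names = FALSE)
    list(ids = ids, module = module, mod_times = mod_times, triads = triads,
         cis = cis, driver = driver, driver_sign = driver_sign, extra = extra)
}

#' Simulate a feature annotation
#'
#' Places all features on two synthetic chromosomes in slots spaced far
#' enough apart (300 kb) that no unplanted cross-class pair falls within the
#' cis window. The planted cis lncRNAs are placed on the same chromosome as
#' their partner mRNA with an inter-feature gap drawn uniformly in
#' \[0, `cis_window_bp`\]; every circRNA is placed inside its host mRNA.
#'
#' @param params a [simParams()] object.
#' @return A [GenomicRanges::GRanges] annotation (see [readAnnotation()]).
#' @export
simulateAnnotation <- function(params) {
    p <- params
    set.seed(p$seed + 1L)
    d <- .plantDesign(p)
    ids <- d$ids
    n_all <- length(unlist(ids))
    lens <- c(pmax(200L, as.integer(runif(p$n_lnc, 400, 2000))),
              pmax(100L, as.integer(runif(p$n_circ, 200, 1500))),
              rep(22L, p$n_mirna),
              pmax(300L, as.integer(runif(p$n_mrna, 500, 3000))))
    feat <- data.frame(feature_id = unlist(ids),
                       rna_class = rep(c("lncRNA", "circRNA", "miRNA", "mRNA"),
                                       c(p$n_lnc, p$n_circ, p$n_mirna, p$n_mrna)),
                       feature_length = lens, stringsAsFactors = FALSE)
    rownames(feat) <- feat$feature_id
    # slot layout: mRNAs, miRNAs and non-cis lncRNAs each get their own slot
    slot_gap <- 300000L + p$cis_window_bp
    own_slot <- c(ids$mrna, ids$mir, setdiff(ids$lnc, d$cis$lncrna_id))
    n_slots <- length(own_slot)
    chrom <- ifelse(seq_len(n_slots) %% 2L == 0L, "chr2", "chr1")
    slot_start <- 1L + (seq_len(n_slots) %/% 2L) * slot_gap
    start <- setNames(integer(n_all), feat$feature_id)
    end <- start
    chr <- setNames(character(n_all), feat$feature_id)
    start[own_slot] <- slot_start
    end[own_slot] <- slot_start + lens[match(own_slot, feat$feature_id)] - 1L
    chr[own_slot] <- chrom
    # cis lncRNAs downstream of their partner mRNA, gap uniform in the window
    if (nrow(d$cis)) {
        gap <- as.integer(floor(runif(nrow(d$cis), 0, p$cis_window_bp + 1)))
        gap <- pmin(gap, p$cis_window_bp)
        s <- end[d$cis$mrna_id] + gap + 1L
        start[d$cis$lncrna_id] <- s
        end[d$cis$lncrna_id] <- s + lens[match(d$cis$lncrna_id, feat$feature_id)] - 1L
        chr[d$cis$lncrna_id] <- chr[d$cis$mrna_id]
    }
    # circRNAs sit inside a host mRNA
    host <- setNames(rep(NA_character_, n_all), feat$feature_id)
    host_pick <- ids$mrna[(seq_len(p$n_circ) * 7L) %% p$n_mrna + 1L]
    host[ids$circ] <- host_pick
    start[ids$circ] <- start[host_pick]
    end[ids$circ] <- pmin(end[host_pick],
                          start[host_pick] + lens[match(ids$circ, feat$feature_id)] - 1L)
    chr[ids$circ] <- chr[host_pick]
    gr <- GRanges(chr[feat$feature_id],
                  IRanges(start[feat$feature_id], end[feat$feature_id]),
                  strand = sample(c("+", "-"), n_all, replace = TRUE))
    mcols(gr) <- S4Vectors::DataFrame(feature_id = feat$feature_id,
                                      rna_class = feat$rna_class,
                                      feature_length = feat$feature_length,
                                      host_gene_id = unname(host[feat$feature_id]))
    names(gr) <- feat$feature_id
    gr
}

#' Simulate counts, sample table and ground truth
#'
#' Counts are drawn as NB(mean = s_j * mu_gj, variance mu + phi mu^2) with
#' per-sample library factors s_j log-uniform in `library_size_range`.
#' Planted module members share a latent per-module driver (a time-point
#' archetype plus per-sample jitter); planted cis lncRNAs follow their
#' partner's module driver; planted triad ceRNAs load positively and triad
#' miRNAs negatively on the triad mRNA's module driver; extra planted DE
#' features shift by `de_log2fc` at one random time point.
#'
#' @param params a [simParams()] object.
#' @param annotation output of [simulateAnnotation()] on the same params.
#' @return list with elements `rex` ([RnaExperiment-class]), `truth`
#'   (a `TruthBundle`-style list: `de` data.frame with feature/time/direction,
#'   `module` named vector, `module_time` archetype map, `cis`, `triads`,
#'   `library_factors`, `params`).
#' @export
simulateCounts <- function(params, annotation) {
    p <- params
    set.seed(p$seed + 2L)
    d <- .plantDesign(p)
    times <- TIME_POINTS
    n_s <- p$n_timepoints * p$n_replicates
    tp <- rep(times, each = p$n_replicates)
    repl <- rep(seq_len(p$n_replicates), times = p$n_timepoints)
    sample_ids <- sprintf("T%02d_R%d", tp, repl)
    feat <- mcols(annotation)$feature_id
    n_g <- length(feat)
    cls <- setNames(mcols(annotation)$rna_class, feat)
    a <- p$de_log2fc
    # per-module driver: delta profile over time points + shared sample jitter
    delta_prof <- sapply(seq_len(p$n_modules), function(m) {
        t_m <- d$mod_times[m]
        if (t_m == 0L) ifelse(times == 0L, 0, -a) else a * (times == t_m)
    })                                          # 5 x n_modules
    z <- matrix(rnorm(n_s * p$n_modules, 0, p$module_sample_sd),
                n_s, p$n_modules)
    driver_mat <- delta_prof[match(tp, times), , drop = FALSE] + z  # samples x modules
    # per-gene structure
    planted <- setNames(logical(n_g), feat)
    offset <- matrix(0, n_g, n_s, dimnames = list(feat, sample_ids))
    lam <- setNames(runif(n_g, p$loading_range[1], p$loading_range[2]), feat)
    # cis pairs are planted as strongly co-expressed neighbours, so both
    # members take the full driver loading; triad ceRNA/miRNA loadings are
    # the configured sponge strength
    lam[d$cis$lncrna_id] <- p$loading_range[2]
    lam[d$cis$mrna_id] <- p$loading_range[2]
    lam[d$triads$cerna_id] <- p$triad_strength
    lam[d$triads$mirna_id] <- p$triad_strength
    de_dir <- matrix("null", n_g, length(times),
                     dimnames = list(feat, paste0(times)))
    # mRNA module members
    mem <- names(d$module)[d$module > 0]
    planted[mem] <- TRUE
    for (m in seq_len(p$n_modules)) {
        g <- names(d$module)[d$module == m]
        offset[g, ] <- outer(lam[g], driver_mat[, m])
        dd <- delta_prof[, m]
        de_dir[g, dd > 0] <- "up"
        de_dir[g, dd < 0] <- "down"
    }
    # structured non-mRNA features (cis lncRNAs, triad ceRNAs, triad miRNAs)
    for (gname in names(d$driver)) {
        m <- d$driver[gname]
        s <- d$driver_sign[gname]
        planted[gname] <- TRUE
        offset[gname, ] <- s * lam[gname] * driver_mat[, m]
        dd <- s * delta_prof[, m]
        de_dir[gname, dd > 0] <- "up"
        de_dir[gname, dd < 0] <- "down"
    }
    # extra planted DE at one random non-zero time point
    if (length(d$extra)) {
        t_pick <- sample(times[-1], length(d$extra), replace = TRUE)
        s_pick <- sample(c(1, -1), length(d$extra), replace = TRUE)
        for (i in seq_along(d$extra)) {
            g <- d$extra[i]
            planted[g] <- TRUE
            offset[g, tp == t_pick[i]] <- s_pick[i] * a
            de_dir[g, paste0(t_pick[i])] <- if (s_pick[i] > 0) "up" else "down"
        }
    }
    base <- setNames(2^runif(n_g, 3, 8), feat)
    base[planted] <- 2^runif(sum(planted), 4, 8)
    # planted cis/triad members sit above the counting-noise floor so the
    # planted correlation structure is expressed in the counts
    cis_members <- unique(c(d$cis$lncrna_id, d$cis$mrna_id))
    base[cis_members] <- 2^runif(length(cis_members), 6, 9)
    tri_members <- unique(c(d$triads$cerna_id, d$triads$mirna_id,
                            d$triads$mrna_id))
    base[tri_members] <- 2^runif(length(tri_members), 5, 8)
    lib <- exp(runif(n_s, log(p$library_size_range[1]),
                     log(p$library_size_range[2])))
    noise <- matrix(rnorm(n_g * n_s, 0, p$gene_noise_sd), n_g, n_s)
    if (!identical(p$outlier_sample, FALSE)) {
        j <- as.integer(p$outlier_sample)
        stopifnot(j >= 1, j <= n_s)
        noise[, j] <- noise[, j] + rnorm(n_g, 0, p$outlier_sd)
    }
    mu <- base * 2^(offset + noise)
    mu <- sweep(mu, 2, lib, `*`)
    cnt <- matrix(0L, n_g, n_s, dimnames = list(feat, sample_ids))
    if (p$nb_dispersion == 0) {
        cnt[] <- as.integer(rpois(n_g * n_s, as.vector(mu)))
    } else {
        cnt[] <- as.integer(rnbinom(n_g * n_s, size = 1 / p$nb_dispersion,
                                    mu = as.vector(mu)))
    }
    st <- data.frame(sample_id = sample_ids, time_point_hours = tp,
                     replicate = repl, stringsAsFactors = FALSE)
    rex <- RnaExperiment(cnt, cls[feat],
                         mcols(annotation)$feature_length, st)
    de_long <- data.frame(
        feature_id = rep(feat, length(times)),
        rna_class = rep(unname(cls[feat]), length(times)),
        time_point_hours = rep(times, each = n_g),
        direction = as.vector(de_dir), stringsAsFactors = FALSE)
    de_long <- de_long[de_long$direction != "null", ]
    rownames(de_long) <- NULL
    truth <- list(de = de_long, module = d$module, module_time = d$mod_times,
                  cis = d$cis, triads = d$triads,
                  library_factors = setNames(lib, sample_ids),
                  params = p)
    list(rex = rex, truth = truth)
}

#' Simulate a miRNA-target interaction table
#'
#' Every planted triad (c, m, g) contributes the rows (m, c) and (m, g);
#' decoy rows are added independently with probability `target_bg_density`
#' over all remaining (miRNA, non-miRNA feature) combinations.
#'
#' @param truth truth list from [simulateCounts()].
#' @param params the same [simParams()] object.
#' @param annotation annotation GRanges (defines the background universe).
#' @return target table data.frame (see [readTargets()]).
#' @export
simulateTargets <- function(truth, params, annotation) {
    p <- params
    set.seed(p$seed + 3L)
    tr <- truth$triads
    planted <- data.frame(
        mirna_id = rep(tr$mirna_id, 2),
        target_id = c(tr$cerna_id, tr$mrna_id),
        source = "miranda_like", score = NA_real_, stringsAsFactors = FALSE)
    mirs <- mcols(annotation)$feature_id[mcols(annotation)$rna_class == "miRNA"]
    tgts <- mcols(annotation)$feature_id[mcols(annotation)$rna_class != "miRNA"]
    bg <- NULL
    if (p$target_bg_density > 0 && length(mirs) && length(tgts)) {
        hit <- which(runif(length(mirs) * length(tgts)) < p$target_bg_density)
        if (length(hit)) {
            mi <- mirs[((hit - 1L) %% length(mirs)) + 1L]
            tg <- tgts[((hit - 1L) %/% length(mirs)) + 1L]
            src <- sample(c("starbase_like", "miranda_like"), length(hit),
                          replace = TRUE)
            bg <- data.frame(mirna_id = mi, target_id = tg, source = src,
                             score = NA_real_, stringsAsFactors = FALSE)
        }
    }
    out <- rbind(planted, bg)
    key <- paste(out$mirna_id, out$target_id, out$source, sep = "\r")
    out <- out[!duplicated(key), ]
    rownames(out) <- NULL
    out
}

#' Simulate a term-gene annotation map
#'
#' Random gene-set terms over the mRNA universe plus one term per planted
#' module (a subset of its members), so enrichment of module-derived gene
#' sets has a planted positive.
#'
#' @param truth truth list from [simulateCounts()].
#' @param params the same [simParams()] object.
#' @param n_terms number of random background terms.
#' @return data.frame with `term_id`, `gene_id`, `term_name`.
#' @export
simulateTermMap <- function(truth, params, n_terms = 40L) {
    p <- params
    set.seed(p$seed + 4L)
    genes <- names(truth$module)
    rows <- lapply(seq_len(n_terms), function(i) {
        sz <- sample(10:50, 1)
        data.frame(term_id = sprintf("TERM%03d", i),
                   gene_id = sample(genes, sz),
                   term_name = sprintf("random process %03d", i),
                   stringsAsFactors = FALSE)
    })
    mod_rows <- lapply(seq_len(p$n_modules), function(m) {
        mem <- names(truth$module)[truth$module == m]
        data.frame(term_id = sprintf("TERM_MOD%d", m),
                   gene_id = sample(mem, max(2L, round(0.6 * length(mem)))),
                   term_name = sprintf("planted module %d program", m),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(rows, mod_rows))
    rownames(out) <- NULL
    out
}

#' Run the whole generator
#'
#' Convenience wrapper producing annotation, counts, truth, targets and a
#' term map from one parameter set.
#'
#' @param params a [simParams()] object.
#' @return list with `rex`, `annotation`, `targets`, `termMap`, `truth`.
#' @export
simulateAll <- function(params) {
    ann <- simulateAnnotation(params)
    sim <- simulateCounts(params, ann)
    targets <- simulateTargets(sim$truth, params, ann)
    tm <- simulateTermMap(sim$truth, params)
    list(rex = sim$rex, annotation = ann, targets = targets,
         termMap = tm, truth = sim$truth)
}
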