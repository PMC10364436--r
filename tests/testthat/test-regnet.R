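test_that("pearsonMatrix matches direct formulas", {
    set.seed(14)
    x <- rnorm(20)
    a <- rbind(x = x, w = rnorm(20))
    b <- rbind(y = 2 * x + 1, z = rnorm(20))
    colnames(a) <- colnames(b) <- paste0("s", 1:20)
    pm <- pearsonMatrix(a, b)
    expect_equal(pm$r["x", "y"], 1)
    expect_lt(pm$p["x", "y"], 1e-12)
    # orthogonal by construction
    y0 <- rnorm(20); y0 <- residuals(lm(y0 ~ x))
    b2 <- rbind(y = y0); colnames(b2) <- colnames(a)
    expect_lt(abs(pearsonMatrix(a["x", , drop = FALSE], b2)$r[1, 1]), 1e-12)
    # random block against cor() + t-test oracle
    A <- matrix(rnorm(5 * 20), 5, 20, dimnames = list(paste0("a", 1:5), colnames(a)))
    B <- matrix(rnorm(4 * 20), 4, 20, dimnames = list(paste0("b", 1:4), colnames(a)))
    pm2 <- pearsonMatrix(A, B)
    expect_equal(unname(pm2$r), unname(cor(t(A), t(B))), tolerance = 1e-12)
    p_or <- outer(1:5, 1:4, Vectorize(function(i, j)
        cor.test(A[i, ], B[j, ])$p.value))
    expect_equal(unname(pm2$p), p_or, tolerance = 1e-10)
    expect_error(pearsonMatrix(A[, 1:2], B[, 1:2]), "3 samples")
})

.regnetFixture <- function(seed = 15) {
    set.seed(seed)
    ann <- tinyAnnotation(data.frame(
        feature_id = c("L1", "L2", "L3", "C1", "M1", "M2", "M3"),
        chromosome = c("chr1", "chr1", "chr2", "chr1",
                       "chr1", "chr1", "chr2"),
        # L1 ends at 10,000; M1 starts at 110,001: gap exactly 100,000
        # L2 ends at 500,000; M2 starts at 600,002: gap 100,001
        start = c(9001, 499001, 100, 110001, 110001, 600002, 5000),
        end = c(10000, 500000, 1200, 112000, 115000, 602000, 7000),
        rna_class = c("lncRNA", "lncRNA", "lncRNA", "circRNA",
                      "mRNA", "mRNA", "mRNA"),
        feature_length = 1000L,
        host_gene_id = c(NA, NA, NA, "M1", NA, NA, NA)))
    base <- rnorm(20)
    expr <- rbind(L1 = base + rnorm(20, 0, 0.2),
                  L2 = base + rnorm(20, 0, 0.2),
                  L3 = base + rnorm(20, 0, 0.05),
                  C1 = base + rnorm(20, 0, 0.2),
                  M1 = base + rnorm(20, 0, 0.2),
                  M2 = base + rnorm(20, 0, 0.2),
                  M3 = base + rnorm(20, 0, 0.05))
    colnames(expr) <- paste0("s", 1:20)
    list(ann = ann, expr = expr)
}

test_that("cis pairing applies the inclusive 100-kb window and the |r| rule", {
    fx <- .regnetFixture()
    cis <- cisPairs(fx$ann, c("L1", "L2", "L3", "C1"), c("M1", "M2", "M3"),
                    fx$expr)
    key <- paste(cis$regulator_id, cis$target_id)
    expect_true("L1 M1" %in% key)          # gap exactly 100,000 -> kept
    expect_false("L2 M2" %in% key)         # gap 100,001 -> excluded
    expect_false("L3 M1" %in% key)         # different chromosome
    expect_true("C1 M1" %in% key)          # circRNA inside host: distance 0
    expect_equal(cis$distance_bp[cis$regulator_id == "L1" &
                                 cis$target_id == "M1"], 100000L)
    # brute-force double loop over all candidate pairs with both rules
    brute <- list()
    sets <- expand.grid(reg = c("L1", "L2", "L3", "C1"),
                        tgt = c("M1", "M2", "M3"), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(sets))) {
        ra <- fx$ann[sets$reg[i]]; ta <- fx$ann[sets$tgt[i]]
        if (as.character(GenomicRanges::seqnames(ra)) !=
            as.character(GenomicRanges::seqnames(ta))) next
        gap <- max(0, GenomicRanges::start(ta) - GenomicRanges::end(ra) - 1,
                   GenomicRanges::start(ra) - GenomicRanges::end(ta) - 1)
        if (gap > 100000) next
        if (abs(cor(fx$expr[sets$reg[i], ], fx$expr[sets$tgt[i], ])) <= 0.6) next
        brute[[length(brute) + 1]] <- paste(sets$reg[i], sets$tgt[i])
    }
    expect_setequal(key, unlist(brute))
})

test_that("trans pairs require |r| > 0.9 and exclude window-eligible pairs", {
    fx <- .regnetFixture()
    trans <- transPairs(fx$ann, c("L1", "L2", "L3"), c("M1", "M2", "M3"),
                        fx$expr)
    key <- paste(trans$regulator_id, trans$target_id)
    # L3-M3 correlate ~0.99 on different loci of the same chr2... same chr but
    # far apart? they sit 100 bp..7000 region: window-eligible -> excluded
    expect_false("L3 M3" %in% key)
    # L3-M1: different chromosome, r ~ 0.97 -> trans
    expect_true("L3 M1" %in% key)
    # L1-M1: r ~ 0.95 but window-eligible -> cis only
    expect_false("L1 M1" %in% key)
    # with the exclusion off, window-eligible high-r pairs reappear
    cfg <- cernaConfig(trans_exclude_cis = FALSE)
    trans2 <- transPairs(fx$ann, c("L1", "L2", "L3"), c("M1", "M2", "M3"),
                         fx$expr, cfg)
    expect_true("L3 M3" %in% paste(trans2$regulator_id, trans2$target_id))
    # cis and trans outputs are disjoint under the default config
    cis <- cisPairs(fx$ann, c("L1", "L2", "L3"), c("M1", "M2", "M3"), fx$expr)
    expect_length(intersect(paste(cis$regulator_id, cis$target_id), key), 0)
})

test_that("parent pairs link every DE circRNA to its host and core filtering intersects hubs", {
    fx <- .regnetFixture()
    pp <- parentPairs(fx$ann, "C1", fx$expr)
    expect_equal(nrow(pp), 1)
    expect_equal(pp$target_id, "M1")
    expect_equal(pp$pair_type, "parent")
    expect_false(is.na(pp$r))
    # circRNA without host annotation is skipped with a warning
    ann2 <- fx$ann
    S4Vectors::mcols(ann2)$host_gene_id[4] <- NA
    expect_warning(pp2 <- parentPairs(ann2, "C1", fx$expr), "host")
    expect_equal(nrow(pp2), 0)

    cis <- cisPairs(fx$ann, c("L1", "C1"), c("M1", "M2", "M3"), fx$expr)
    expect_equal(sum(coreFilter(cis, character(0))$is_core), 0)
    expect_equal(sum(coreFilter(cis, c("M1", "M2", "M3"))$is_core), nrow(cis))
    mixed <- coreFilter(cis, "M1")
    expect_equal(sum(mixed$is_core), sum(cis$target_id == "M1"))
    expect_equal(nrow(coreFilter(cis, "M1", keep_all = FALSE)),
                 sum(cis$target_id == "M1"))
})

test_that("planted cis pairs are recovered and no out-of-window pair is emitted", {
    p <- tinyParams(seed = 16L)
    sim <- simulateAll(p)
    filt <- filterLowExpression(sim$rex)
    de <- callDE(filt)
    expr <- log2(tpm(filt) + 1)
    cis <- cisPairs(sim$annotation, c(unionDE(de, "lncRNA"), unionDE(de, "circRNA")),
                    unionDE(de, "mRNA"), expr)
    lnc_cis <- cis[cis$regulator_class == "lncRNA", ]
    key <- paste(lnc_cis$regulator_id, lnc_cis$target_id)
    truth <- paste(sim$truth$cis$lncrna_id, sim$truth$cis$mrna_id)
    expect_gte(mean(truth %in% key), 0.9)
    # the window rule is exact: every emitted cis pair is within 100 kb
    gaps <- GenomicRanges::distance(sim$annotation[cis$regulator_id],
                                    sim$annotation[cis$target_id],
                                    ignore.strand = TRUE)
    expect_true(all(!is.na(gaps) & gaps <= 100000))
    # correlations equal pearsonMatrix output (cross-check)
    pm <- pearsonMatrix(expr[unique(cis$regulator_id), , drop = FALSE],
                        expr[unique(cis$target_id), , drop = FALSE])
    expect_equal(cis$r, pm$r[cbind(cis$regulator_id, cis$target_id)],
                 tolerance = 1e-12)
})
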