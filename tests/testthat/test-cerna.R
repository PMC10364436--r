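test_that("spearmanCor handles monotone, tied and small-sample cases exactly", {
    x <- c(3, 9, 1, 6, 5, 7)
    expect_equal(spearmanCor(x, sort(x)[rank(x)])$rho, 1)
    expect_equal(spearmanCor(x, x^3)$rho, 1)          # monotone transform
    expect_equal(spearmanCor(x, -x)$rho, -1)
    expect_warning(out <- spearmanCor(x, rep(2, 6)), "constant")
    expect_equal(out, list(rho = 0, p = 1))
    expect_error(spearmanCor(1:3, 1:3), ">= 5")

    # n = 6: p equals exhaustive permutation over all 720 orders
    set.seed(17)
    for (i in 1:5) {
        a <- rnorm(6); b <- rnorm(6)
        got <- spearmanCor(a, b)
        want <- spearmanPermOracle(a, b)
        expect_equal(got$rho, want$rho, tolerance = 1e-12)
        expect_equal(got$p, want$p, tolerance = 1e-12)
    }
    # ties handled through average ranks in the permutation null too
    a <- c(1, 1, 2, 3, 4, 5); b <- c(2, 1, 1, 3, 3, 4)
    expect_equal(spearmanCor(a, b)$p, spearmanPermOracle(a, b)$p,
                 tolerance = 1e-12)
    # large-sample t-approximation agrees with cor.test
    set.seed(18)
    a <- rnorm(30); b <- a + rnorm(30)
    ct <- cor.test(a, b, method = "spearman", exact = FALSE)
    got <- spearmanCor(a, b)
    expect_equal(got$rho, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(got$p, ct$p.value, tolerance = 1e-9)
})

test_that("candidate triads require shared targets, DE status and hub membership", {
    de <- data.frame(
        feature_id = c("m1", "c1", "g1", "g2", "c2"),
        rna_class = c("miRNA", "lncRNA", "mRNA", "mRNA", "circRNA"),
        contrast = "12_vs_0", log2fc = 1, p_value = 0.01,
        direction = "up", union_de = TRUE)
    targets <- data.frame(
        mirna_id = c("m1", "m1", "m1", "m2"),
        target_id = c("c1", "g1", "c2", "g2"),
        source = "miranda_like", score = NA)
    cand <- candidateTriads(targets, de, hubs = c("g1", "g2"))
    # m1 shares c1/c2 with g1; m2 is not DE; g2 has no DE ceRNA partner
    expect_equal(nrow(cand), 2)
    expect_setequal(cand$cerna_id, c("c1", "c2"))
    expect_equal(unique(cand$mrna_id), "g1")
    expect_setequal(cand$cerna_class[cand$cerna_id == "c2"], "circRNA")
    # no shared target -> no candidate
    expect_equal(nrow(candidateTriads(targets[2, ], de, "g1")), 0)
    # brute-force triple loop oracle on a random fixture
    set.seed(19)
    mir <- paste0("m", 1:5); cer <- paste0("c", 1:6); g <- paste0("g", 1:6)
    tg <- expand.grid(mirna_id = mir, target_id = c(cer, g),
                      stringsAsFactors = FALSE)
    tg <- tg[runif(nrow(tg)) < 0.3, ]
    tg$source <- "starbase_like"
    de2 <- data.frame(feature_id = c(mir, cer, g),
                      rna_class = rep(c("miRNA", "lncRNA", "mRNA"), c(5, 6, 6)),
                      contrast = "12_vs_0", log2fc = 1, p_value = 0.01,
                      direction = "up", union_de = TRUE)
    hubs <- c("g2", "g4")
    cand2 <- candidateTriads(tg, de2, hubs)
    brute <- character()
    for (m in mir) for (cc in cer) for (gg in hubs)
        if (any(tg$mirna_id == m & tg$target_id == cc) &&
            any(tg$mirna_id == m & tg$target_id == gg))
            brute <- c(brute, paste(cc, m, gg))
    expect_setequal(paste(cand2$cerna_id, cand2$mirna_id, cand2$mrna_id), brute)
    # row order of the target table does not matter
    cand3 <- candidateTriads(tg[sample(nrow(tg)), ], de2, hubs)
    expect_identical(cand2, cand3)
})

test_that("triad filtering enforces the sign pattern and significance rules row-wise", {
    set.seed(20)
    n <- 30
    drv <- rnorm(n)
    expr <- rbind(c1 = drv + rnorm(n, 0, 0.4),
                  m1 = -drv + rnorm(n, 0, 0.4),
                  g1 = drv + rnorm(n, 0, 0.4),
                  c2 = -drv + rnorm(n, 0, 0.4),  # wrong sign vs g1
                  m2 = rnorm(n),                 # uncorrelated miRNA
                  g2 = rnorm(n))
    colnames(expr) <- paste0("s", 1:n)
    cand <- data.frame(
        cerna_id = c("c1", "c2", "c1"), mirna_id = c("m1", "m1", "m2"),
        mrna_id = c("g1", "g1", "g2"),
        cerna_class = c("lncRNA", "lncRNA", "lncRNA"))
    tri <- filterTriads(cand, expr)
    expect_equal(nrow(tri), 1)
    expect_equal(tri$cerna_id, "c1")
    expect_true(tri$rho_cm > 0 && tri$rho_mic < 0 && tri$rho_mim < 0)
    expect_true(all(c(tri$p_cm, tri$p_mic, tri$p_mim) < 0.05))
    # rho/p agree with the scalar spearman on each pair
    sc <- spearmanCor(expr["c1", ], expr["g1", ])
    expect_equal(tri$rho_cm, sc$rho, tolerance = 1e-12)
    expect_equal(tri$p_cm, sc$p, tolerance = 1e-9)
    # literal coefficient reading (|rho| < 0.05) rejects the strong triad
    cfg <- cernaConfig(spearman_rule = "coefficient")
    expect_equal(nrow(filterTriads(cand, expr, cfg)), 0)
    # invariant to sample column order
    perm <- sample(n)
    tri2 <- filterTriads(cand, expr[, perm])
    expect_equal(tri2$rho_cm, tri$rho_cm, tolerance = 1e-12)
})

test_that("planted triads are recovered and random-expression decoys rejected", {
    p <- tinyParams(seed = 22L)
    sim <- simulateAll(p)
    filt <- filterLowExpression(sim$rex)
    expr <- log2(tpm(filt) + 1)
    tt <- sim$truth$triads
    structured <- unique(c(unique(sim$truth$de$feature_id),
                           names(sim$truth$module)[sim$truth$module > 0]))
    cls <- rnaClass(filt)
    null_cer <- setdiff(names(cls)[cls %in% c("lncRNA", "circRNA")], structured)
    null_mir <- setdiff(names(cls)[cls == "miRNA"], structured)
    null_g <- setdiff(names(cls)[cls == "mRNA"], structured)
    set.seed(23)
    dec <- unique(data.frame(cerna_id = sample(null_cer, 800, TRUE),
                             mirna_id = sample(null_mir, 800, TRUE),
                             mrna_id = sample(null_g, 800, TRUE)))
    dec$cerna_class <- ifelse(grepl("^LNC", dec$cerna_id), "lncRNA", "circRNA")
    cand <- rbind(tt[, c("cerna_id", "mirna_id", "mrna_id", "cerna_class")], dec)
    tri <- filterTriads(cand, expr)
    key <- paste(tri$cerna_id, tri$mirna_id, tri$mrna_id)
    tk <- paste(tt$cerna_id, tt$mirna_id, tt$mrna_id)
    expect_gte(mean(tk %in% key), 0.9)
    # decoys pass all three sign+significance gates at well under 5% each
    expect_lte(sum(!(key %in% tk)), 0.05 * nrow(dec))
    # every emitted row satisfies the invariants
    expect_true(all(tri$rho_cm > 0 & tri$rho_mic < 0 & tri$rho_mim < 0))
    expect_true(all(tri$p_cm < 0.05 & tri$p_mic < 0.05 & tri$p_mim < 0.05))
})

test_that("core networks split by ceRNA class with two edges per triad", {
    tri <- data.frame(
        cerna_id = c("L1", "L1", "C1"), mirna_id = c("m1", "m1", "m2"),
        mrna_id = c("g1", "g2", "g1"),
        cerna_class = c("lncRNA", "lncRNA", "circRNA"),
        rho_cm = 0.8, rho_mic = -0.8, rho_mim = -0.8,
        p_cm = 0.001, p_mic = 0.001, p_mim = 0.001)
    nets <- buildCoreNetworks(tri)
    expect_equal(unname(nets$lncRNA$summary),
                 c(1, 1, 2, 2))  # ceRNAs, miRNAs, mRNAs, triads
    # m1 appears in 2 lncRNA triads sharing the ceRNA: 3 unique edges
    expect_equal(nrow(nets$lncRNA$edges), 3)
    expect_equal(sum(nets$lncRNA$edges$from == "m1"), 3)
    expect_equal(nrow(nets$circRNA$nodes), 3)
    expect_equal(nrow(nets$circRNA$edges), 2)
    # empty table -> two empty networks
    nets0 <- buildCoreNetworks(tri[0, ])
    expect_equal(nrow(nets0$lncRNA$nodes), 0)
    expect_equal(nrow(nets0$circRNA$edges), 0)
})
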