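# Gaussian block generator used for clustering-level tests
blockExpr <- function(n_blocks = 2, block_size = 50, n_noise = 0,
                      n_samples = 40, r = 0.9, seed = 1) {
    set.seed(seed)
    drivers <- matrix(rnorm(n_blocks * n_samples), n_blocks)
    load <- sqrt(r)
    rows <- if (block_size > 0)
        lapply(seq_len(n_blocks), function(b)
            t(sapply(seq_len(block_size), function(i)
                load * drivers[b, ] + sqrt(1 - r) * rnorm(n_samples))))
    else list()
    x <- do.call(rbind, c(rows, list(matrix(0, 0, n_samples))))
    if (n_noise) x <- rbind(x, matrix(rnorm(n_noise * n_samples), n_noise))
    rownames(x) <- paste0("g", seq_len(nrow(x)))
    colnames(x) <- paste0("s", seq_len(n_samples))
    list(expr = x,
         truth = rep(c(if (block_size > 0) seq_len(n_blocks) else integer(), 0),
                     c(rep(block_size, if (block_size > 0) n_blocks else 0),
                       n_noise)),
         drivers = drivers)
}

test_that("outlier sample detection removes a distorted sample and nothing else", {
    set.seed(2)
    x <- matrix(rnorm(200 * 12, 8, 1), 200, 12,
                dimnames = list(paste0("g", 1:200), paste0("s", 1:12)))
    expect_length(removeOutlierSamples(x)$removed, 0)
    x[, 5] <- x[, 5] * 10
    out <- removeOutlierSamples(x)
    expect_equal(out$removed, "s5")
    expect_length(removeOutlierSamples(out$expr)$removed, 0)
    # refuse to silently drop too many samples (tiny cut -> all singletons)
    expect_error(removeOutlierSamples(x, cutHeight = 1e-6), "20%")
})

test_that("soft-threshold fit index matches an independent oracle; beta = 1 is |r|", {
    b <- blockExpr(n_blocks = 3, block_size = 40, n_noise = 80, seed = 4)
    expect_equal(adjacencyMatrix(b$expr[1:2, ], 1)[1, 2],
                 abs(cor(b$expr[1, ], b$expr[2, ])))
    r <- abs(cor(t(b$expr))); diag(r) <- 0
    for (beta in c(1, 4, 9)) {
        k <- rowSums(r^beta)
        expect_equal(ceRNAflow:::.scaleFreeFit(k), scaleFreeFitOracle(k),
                     tolerance = 1e-8)
    }
    # selected power is reported, deterministic for the same input, and the
    # fit table covers the candidate grid
    p1 <- pickSoftThreshold(b$expr)
    expect_true(is.numeric(p1$power) && p1$power %in% 1:20)
    expect_identical(p1, pickSoftThreshold(b$expr))
    expect_equal(dim(p1$fit), c(20L, 3L))
    # a power meeting the fit target is never skipped in favour of a later one
    hit <- which(p1$fit$fit_index >= 0.85)
    if (length(hit)) expect_equal(p1$power, p1$fit$power[hit[1]])
})

test_that("TOM similarity matches hand values and the triple-loop oracle", {
    # complete triangle: all off-diagonal TOM = (1 + 1) / (2 + 1 - 1) = 1
    tri <- matrix(1, 3, 3) - diag(3)
    expect_equal(tomSimilarity(tri), diag(3) * 0 + 1)
    # zero adjacency -> zero off-diagonal
    z <- matrix(0, 4, 4)
    expect_equal(tomSimilarity(z), diag(4))
    set.seed(6)
    r <- abs(cor(matrix(rnorm(20 * 30), 30)))^3
    diag(r) <- 0
    expect_equal(unname(tomSimilarity(r)), tomOracle(r), tolerance = 1e-12)
    tom <- tomSimilarity(r)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_true(isSymmetric(unname(tom), tol = 1e-12))
    expect_error(tomSimilarity(matrix(c(0, 1, 0.5, 0), 2, 2)), "symmetric")
})

test_that("tree cutting recovers planted blocks and respects the size floor", {
    b <- blockExpr(n_blocks = 2, block_size = 50, seed = 7)
    tom <- tomSimilarity(adjacencyMatrix(b$expr, 6))
    lab <- cutModules(1 - tom, b$expr)
    expect_equal(length(unique(lab)), 2)
    expect_equal(mclust::adjustedRandIndex(lab, b$truth), 1)
    # labels renumbered by decreasing size
    sz <- table(lab); expect_true(all(diff(as.integer(sz)) <= 0))

    # 20 independent noise genes under min_size 30 -> all unassigned
    nz <- blockExpr(n_blocks = 1, block_size = 0, n_noise = 20, seed = 8)
    tomz <- tomSimilarity(adjacencyMatrix(nz$expr, 6))
    expect_warning(labz <- cutModules(1 - tomz, nz$expr, min_size = 30),
                   "unassigned")
    expect_true(all(labz == 0))

    # duplicated genes always co-cluster (zero-distance pairs merge first)
    dup <- rbind(b$expr, b$expr)
    rownames(dup) <- paste0("g", seq_len(nrow(dup)))
    tomd <- tomSimilarity(adjacencyMatrix(dup, 6))
    labd <- cutModules(1 - tomd, dup)
    expect_equal(unname(labd[1:100]), unname(labd[101:200]))
})

test_that("module eigengene is the oriented unit-variance first PC", {
    set.seed(9)
    g <- rnorm(20)
    same <- matrix(rep(g, 5), 5, byrow = TRUE,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:20)))
    e <- moduleEigengene(same)
    expect_equal(abs(cor(e, g)), 1)
    expect_equal(sd(e), 1)
    expect_gte(mean(cor(t(same), e)), 1 - 1e-12)

    # antagonistic members: orientation keeps mean correlation >= 0
    anti <- rbind(x = g, y = -g, z = g + rnorm(20, 0, 0.01))
    colnames(anti) <- paste0("s", 1:20)
    expect_gte(mean(cor(t(anti), moduleEigengene(anti))), 0)

    # first PC of the standardized submatrix (eigendecomposition check)
    b <- blockExpr(n_blocks = 1, block_size = 12, n_samples = 25, seed = 10)
    e2 <- moduleEigengene(b$expr)
    pc <- prcomp(t(scale(t(b$expr))) |> t(), center = FALSE, scale. = FALSE)
    expect_equal(abs(cor(e2, pc$x[, 1])), 1, tolerance = 1e-8)
    # tracks the latent driver closely
    expect_gte(abs(cor(e2, b$drivers[1, ])), 0.9)
})

test_that("module-trait correlation, key selection, GS/MM match direct computation", {
    time <- setNames(rep(c(0L, 12L, 24L, 48L, 72L), each = 4),
                     paste0("s", 1:20))
    ind12 <- as.numeric(time == 12)
    me <- rbind(ME1 = (ind12 - mean(ind12)) / sd(ind12),
                ME2 = rnorm(20))
    colnames(me) <- names(time)
    mt <- moduleTraitCor(me, time, sizes = c(`1` = 30, `2` = 40))
    expect_equal(mt$r["ME1", "12"], 1)
    expect_equal(unname(mt$key["12"]), 1L)
    expect_true(all(abs(mt$r) <= 1 + 1e-12))

    set.seed(11)
    expr <- matrix(rnorm(8 * 20), 8, 20,
                   dimnames = list(paste0("g", 1:8), names(time)))
    expr[1, ] <- me["ME1", ] + rnorm(20, 0, 1e-8)   # equals eigengene -> MM 1
    expr[2, ] <- ind12                               # equals indicator -> GS 1
    gm <- geneSignificanceMembership(expr, me, time)
    expect_equal(gm$MM["g1", "ME1"], 1, tolerance = 1e-6)
    expect_equal(gm$GS["g2", "12"], 1, tolerance = 1e-12)
    # direct correlation oracle over the random block
    ind <- sapply(sort(unique(time)), function(t) as.numeric(time == t))
    expect_equal(unname(gm$GS), unname(cor(t(expr), ind)), tolerance = 1e-12)
    expect_equal(unname(gm$MM), unname(cor(t(expr), t(me))), tolerance = 1e-12)
})

test_that("hub selection is strict and confined to key modules", {
    labels <- setNames(c(1L, 1L, 1L, 2L), paste0("g", 1:4))
    GS <- matrix(c(0.9, 0.9, 0.4, 0.95), 4, 1,
                 dimnames = list(names(labels), "0"))
    MM <- matrix(c(0.85, 0.8, 0.9, 0.99), 4, 2,
                 dimnames = list(names(labels), c("ME1", "ME2")))
    MM[4, "ME2"] <- 0.99
    key <- c(`0` = 1L)
    hb <- selectHubGenes(labels, GS, MM, key)
    # g1 passes; g2 sits exactly at MM = 0.8 (strict, excluded); g3 fails GS;
    # g4 has perfect scores but is outside the key module
    expect_equal(hb$hubs, "g1")
    expect_equal(unname(hb$hubModule["g1"]), 1L)
})

test_that("the co-expression stage is deterministic end to end", {
    p <- tinyParams(seed = 13L)
    sim <- simulateCounts(p, simulateAnnotation(p))
    x <- sim$rex[rnaClass(sim$rex) == "mRNA", ]
    m1 <- runCoexpression(x)
    m2 <- runCoexpression(x)
    expect_identical(moduleLabels(m1), moduleLabels(m2))
    expect_identical(moduleEigengenes(m1), moduleEigengenes(m2))
    expect_identical(hubGenes(m1), hubGenes(m2))
    expect_true(all(abs(m1@GS) <= 1 + 1e-8))
    expect_true(all(abs(m1@MM) <= 1 + 1e-8))
    # eigengene rows have unit variance
    expect_equal(apply(moduleEigengenes(m1), 1, sd),
                 setNames(rep(1, nrow(moduleEigengenes(m1))),
                          rownames(moduleEigengenes(m1))))
})
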