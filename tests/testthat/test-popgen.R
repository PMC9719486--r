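test_that("allele frequencies match a brute-force recount", {
    sim <- simulatePanel(nSnps = 200, nPops = 3, samplesPerPop = 4, seed = 71)
    af <- alleleFreqs(sim$panel)
    g <- genoMatrix(sim$panel)
    pops <- indInfo(sim$panel)$population
    for (p in c("Pop1", "Pop2", "Outgroup")) {
        sub <- g[, pops == p, drop = FALSE]
        manual <- vapply(seq_len(nrow(sub)), function(j) {
            v <- sub[j, ]
            if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE) /
                (2 * sum(!is.na(v)))
        }, 0)
        expect_equal(unname(af$freq[, p]), manual)
    }
    # single individual with genotype 2 -> frequency 1; {0,1,2} -> 0.5
    snp <- data.frame(id = c("x1", "x2"), chrom = 1L, pos = c(1L, 2L),
                      ref = "A", alt = "G")
    geno <- matrix(c(2L, 2L, NA, 0L, 1L, 2L), nrow = 2, byrow = TRUE,
                   dimnames = list(snp$id, NULL))
    pan <- new("GenotypePanel", snp = snp, geno = geno,
               ind = data.frame(id = c("a", "b", "c"),
                                population = c("P", "Q", "Q")))
    af2 <- alleleFreqs(pan)
    expect_equal(unname(af2$freq["x1", "P"]), 1)
    expect_equal(unname(af2$freq["x2", "Q"]), 0.75)
    expect_error(alleleFreqs(pan, "Nope"), "empty population")
})

test_that("outgroup f3 reproduces identities and hand arithmetic", {
    set.seed(72)
    o <- runif(50)
    a <- runif(50)
    blocks <- rep(1:5, each = 10)
    # A identical to the outgroup: zero shared drift, exactly
    z <- f3Outgroup(o, a, o, blocks, minSnps = 1L)
    expect_equal(z@value, 0)
    # A = B: f3 becomes a mean square, non-negative
    s <- f3Outgroup(a, a, o, blocks, minSnps = 1L)
    expect_gte(s@value, 0)
    # 3-SNP hand table
    h <- f3Outgroup(c(1, 0, 0.5), c(1, 0.5, 0), c(0, 0, 0), c(1, 1, 2),
                    minSnps = 1L)
    expect_equal(h@value, 1 / 3)
    expect_equal(h@nSnps, 3L)
    # the reporting floor refuses thin overlaps
    expect_error(f3Outgroup(a, a, o, blocks), "usable SNPs")
})

test_that("f4 symmetry identities hold exactly", {
    for (seed in 73:77) {
        set.seed(seed)
        a <- runif(60); b <- runif(60); c <- runif(60); d <- runif(60)
        a[sample(60, 5)] <- NA
        blocks <- rep(1:6, each = 10)
        f <- f4Stat(a, b, c, d, blocks)
        expect_equal(f4Stat(b, a, c, d, blocks)@value, -f@value)
        expect_equal(f4Stat(a, b, d, c, blocks)@value, -f@value)
        expect_equal(f4Stat(c, d, a, b, blocks)@value, f@value)
        expect_equal(f4Stat(a, a, c, d, blocks)@value, 0)
        expect_equal(f4Stat(b, a, c, d, blocks)@se, f@se)
    }
})

test_that("weighted block jackknife reduces to delete-one for equal blocks", {
    set.seed(78)
    x <- rnorm(200)
    blocks <- rep(1:4, each = 50)
    jk <- blockJackknife(x, blocks)
    loo <- vapply(1:4, function(k) mean(x[blocks != k]), 0)
    g <- 4
    seClassic <- sqrt((g - 1) / g * sum((loo - mean(loo))^2))
    expect_equal(jk$se, seClassic, tolerance = 1e-12)
    expect_equal(unname(jk$loo), loo)
    # constant contributions: zero variance
    expect_equal(blockJackknife(rep(0.3, 100), rep(1:4, 25))$se, 0)
    expect_error(blockJackknife(x, rep(1, 200)), "2 blocks")
})

test_that("jackknife SE of a mean tracks the classic s/sqrt(n)", {
    ratios <- vapply(1:50, function(seed) {
        set.seed(seed)
        x <- rnorm(2200)
        jk <- blockJackknife(x, rep(1:22, each = 100))
        jk$se / (sd(x) / sqrt(2200))
    }, 0)
    expect_lt(abs(median(ratios) - 1), 0.15)
})

test_that("unequal block sizes follow the weighted formula", {
    set.seed(79)
    x <- rnorm(130)
    blocks <- rep(c("a", "b", "c"), c(100, 20, 10))
    jk <- blockJackknife(x, blocks)
    n <- 130; m <- c(100, 20, 10); h <- n / m
    theta <- mean(x)
    loo <- vapply(c("a", "b", "c"), function(b) mean(x[blocks != b]), 0)
    tau <- h * theta - (h - 1) * loo
    thetaJ <- 3 * theta - sum((1 - m / n) * loo)
    expect_equal(jk$thetaJack, thetaJ)
    expect_equal(jk$se, sqrt(sum((tau - thetaJ)^2 / (h - 1)) / 3))
})

test_that("PCA separates two homogeneous groups on PC1", {
    snp <- data.frame(id = paste0("s", 1:20), chrom = rep(1:2, 10),
                      pos = 1:20, ref = "A", alt = "G")
    geno <- cbind(matrix(0L, 20, 3), matrix(2L, 20, 3))
    rownames(geno) <- snp$id
    pan <- new("GenotypePanel", snp = snp, geno = geno,
               ind = data.frame(id = paste0("i", 1:6),
                                population = rep(c("P", "Q"), each = 3)))
    fit <- pcaFit(pan, k = 2)
    expect_true(all(sign(fit@scores[1:3, 1]) != sign(fit@scores[4:6, 1])))
    expect_lt(fit@eigenvalues[2] / fit@eigenvalues[1], 1e-10)
})

test_that("SVD scores match a dense eigendecomposition oracle", {
    set.seed(80)
    snp <- data.frame(id = paste0("s", 1:8), chrom = 1L, pos = 1:8,
                      ref = "A", alt = "G")
    geno <- matrix(sample(0:2, 48, TRUE), 8, 6, dimnames = list(snp$id, NULL))
    geno[1, ] <- 1L   # constant but not monomorphic-scale: kept
    geno[2, ] <- 0L   # monomorphic: dropped
    pan <- new("GenotypePanel", snp = snp, geno = geno,
               ind = data.frame(id = paste0("i", 1:6),
                                population = "P"))
    fit <- pcaFit(pan, k = 3)
    expect_equal(fit@dropped, 2L)  # the monomorphic SNP and the constant one
    # oracle: standardise identically, eigendecompose the Gram matrix
    keep <- fit@snpIds
    X <- t(geno[keep, ])
    mu <- colMeans(X); p <- mu / 2; s <- sqrt(p * (1 - p))
    Z <- sweep(sweep(X, 2, mu, "-"), 2, s, "/")
    ev <- eigen(Z %*% t(Z), symmetric = TRUE)
    oracleScores <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)))
    for (j in 1:3) {
        diffs <- c(max(abs(fit@scores[, j] - oracleScores[, j])),
                   max(abs(fit@scores[, j] + oracleScores[, j])))
        expect_lt(min(diffs), 1e-8)
    }
    expect_error(pcaFit(pan, k = 7), "fewer individuals")
})

test_that("projection is self-consistent and centred", {
    sim <- simulatePanel(nSnps = 800, nPops = 3, samplesPerPop = 6, seed = 81)
    moderns <- paste0("Pop", 1:3)
    fit <- pcaFit(sim$panel, moderns, k = 2)
    g <- genoMatrix(sim$panel)
    ind1 <- which(indInfo(sim$panel)$population == "Pop1")[1]
    codes <- setNames(g[, ind1], snpInfo(sim$panel)$id)
    pr <- pcaProject(codes, fit)
    expect_equal(unname(pr@coordinates), unname(fit@scores[ind1, ]),
                 tolerance = 1e-8)
    # the exact per-SNP mean genotype projects to the origin
    mcodes <- setNames(rep(NA_real_, nrow(g)), snpInfo(sim$panel)$id)
    mcodes[fit@snpIds] <- fit@center
    pr0 <- pcaProject(mcodes, fit)
    expect_lt(max(abs(pr0@coordinates)), 1e-10)
    expect_error(pcaProject(codes[1:1], fit), "shares only")
})

test_that("a sparse ancient sample projects near its source population", {
    sim <- simulatePanel(nSnps = 4000, nPops = 3, samplesPerPop = 8,
                         ancientMissingness = 0.5, seed = 82)
    moderns <- paste0("Pop", 1:3)
    fit <- pcaFit(sim$panel, moderns, k = 2)
    g <- genoMatrix(sim$panel)
    codes <- setNames(g[, indInfo(sim$panel)$id == "Ancient1"],
                      snpInfo(sim$panel)$id)
    chrom <- setNames(snpInfo(sim$panel)$chrom, snpInfo(sim$panel)$id)
    pj <- pcaJackknife(codes, fit, chrom, k = 2)
    # target: the projection of the source population's expected genotype
    # (2 x its true allele frequency). Fitted individuals' own scores are
    # inflated by overfitting relative to out-of-sample projections, so
    # they are not the right yardstick for a projected sample.
    expCodes <- setNames(2 * sim$truth$freq[, 1], snpInfo(sim$panel)$id)
    target <- pcaProject(expCodes, fit, k = 2)@coordinates
    for (j in 1:2)
        expect_lt(abs(pj@coordinates[j] - target[j]), 4 * pj@se[j])
    # and it is closer to its source than to the other populations
    d <- vapply(1:3, function(k) {
        t2 <- pcaProject(setNames(2 * sim$truth$freq[, k],
                                  snpInfo(sim$panel)$id), fit, k = 2)
        sqrt(sum((pj@coordinates - t2@coordinates)^2))
    }, 0)
    expect_equal(which.min(d), 1L)
})

test_that("chromosome-drop jackknife equals from-scratch reprojection", {
    sim <- simulatePanel(nSnps = 1200, nPops = 2, samplesPerPop = 6,
                         nChrom = 6, seed = 83)
    fit <- pcaFit(sim$panel, c("Pop1", "Pop2"), k = 2)
    g <- genoMatrix(sim$panel)
    codes <- setNames(g[, indInfo(sim$panel)$id == "Ancient1"],
                      snpInfo(sim$panel)$id)
    chrom <- setNames(snpInfo(sim$panel)$chrom, snpInfo(sim$panel)$id)
    pj <- pcaJackknife(codes, fit, chrom, k = 2)
    for (c in rownames(pj@loo)) {
        sub <- codes
        sub[names(chrom)[chrom == as.integer(c)]] <- NA
        oracle <- pcaProject(sub, fit, k = 2)@coordinates
        expect_lt(max(abs(unlist(pj@loo[c, ]) - oracle)), 1e-10)
    }
    # SE present and non-negative
    expect_true(all(pj@se >= 0))
    # a sample confined to one chromosome cannot be jackknifed
    one <- codes
    one[chrom != 1] <- NA
    expect_error(pcaJackknife(one, fit, chrom, k = 2), "single chromosome")
})

test_that("jackknife SEs shrink like one over root n", {
    ratios <- vapply(1:20, function(seed) {
        sim <- simulatePanel(nSnps = 2000, nPops = 2, samplesPerPop = 6,
                             ancientMissingness = 0.5, seed = 900 + seed)
        fit <- pcaFit(sim$panel, c("Pop1", "Pop2"), k = 2)
        g <- genoMatrix(sim$panel)
        ids <- snpInfo(sim$panel)$id
        chrom <- setNames(snpInfo(sim$panel)$chrom, ids)
        codes <- setNames(g[, indInfo(sim$panel)$id == "Ancient1"], ids)
        half <- codes
        drop <- !is.na(codes)
        drop[drop] <- seq_len(sum(drop)) %% 2 == 0
        half[drop] <- NA       # half the informative SNPs
        seFull <- median(pcaJackknife(codes, fit, chrom, k = 2)@se)
        seHalf <- median(pcaJackknife(half, fit, chrom, k = 2)@se)
        seFull / seHalf
    }, 0)
    expect_lt(abs(median(ratios) - 1 / sqrt(2)), 0.25 / sqrt(2))
})

test_that("non-cladal population pairs are detected by f4", {
    # power: A and B from populations at drift distance 0.05, tested
    # against X = A's source population. Under the star phylogeny any
    # third population is cladal with the pair by construction, so the
    # source is the informative X; splitting its samples between A and X
    # keeps their sampling noise independent. A single pseudo-haploid
    # sample carries too little per-SNP information for this design at
    # 5000 SNPs (the attainable |Z| tops out near 2), so power is
    # checked on sample allele frequencies.
    hits <- vapply(1:20, function(seed) {
        sim <- simulatePanel(nSnps = 5000, nPops = 3, samplesPerPop = 10,
                             Fst = 0.05, seed = 200 + seed)
        pan <- sim$panel
        g <- genoMatrix(pan)
        ind <- indInfo(pan)
        p1a <- rowMeans(g[, which(ind$population == "Pop1")[1:5]]) / 2
        p1b <- rowMeans(g[, which(ind$population == "Pop1")[6:10]]) / 2
        p2 <- rowMeans(g[, ind$population == "Pop2"]) / 2
        og <- g[, ind$population == "Outgroup"] / 2
        f <- f4Stat(p1a, p2, p1b, og, snpInfo(pan)$chrom)
        abs(f@z) > 3
    }, TRUE)
    expect_gte(mean(hits), 0.8)
})
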