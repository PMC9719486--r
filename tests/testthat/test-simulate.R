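test_that("makeReference respects lengths, compartments and determinism", {
    spec <- data.frame(name = c("a", "b"), length = c(1000, 1000),
                       compartment = "nuclear", gc = 0.41)
    ref <- makeReference(spec, seed = 1)
    expect_equal(unname(chromLengths(ref)), c(1000L, 1000L))
    expect_equal(compartmentLength(ref, "nuclear"), 2000)
    ref2 <- makeReference(spec, seed = 1)
    expect_identical(as.character(ref@sequences), as.character(ref2@sequences))
    ref3 <- makeReference(spec, seed = 2)
    expect_false(identical(as.character(ref@sequences),
                           as.character(ref3@sequences)))
    expect_error(makeReference(spec[0, ]), "empty")
    expect_error(makeReference(rbind(spec, spec)), "duplicate")
})

test_that("makeReference hits the configured GC fraction", {
    ref <- makeReference(data.frame(name = "c", length = 1e6,
                                    compartment = "nuclear", gc = 0.41),
                         seed = 3)
    f <- Biostrings::alphabetFrequency(ref@sequences, baseOnly = TRUE)
    gc <- sum(f[, c("C", "G")]) / 1e6
    # binomial tolerance 4 * sqrt(p (1 - p) / n)
    expect_lt(abs(gc - 0.41), 4 * sqrt(0.41 * 0.59 / 1e6))
})

test_that("fragment length sampling matches its components", {
    pm <- fragmentLengthModel(1, list(list(family = "pointMass", value = 30)))
    expect_identical(sampleFragmentLengths(pm, 5, seed = 1), rep(30L, 5))
    se <- fragmentLengthModel(1, list(list(family = "shiftedExponential",
                                           shift = 15, scale = 12)))
    x <- sampleFragmentLengths(se, 1e5, seed = 2)
    # closed-form mean 15 + 12 vs Monte Carlo, 4 SE tolerance
    expect_lt(abs(mean(x) - 27), 4 * 12 / sqrt(1e5))
    expect_error(fragmentLengthModel(c(0.5, 0.4),
        list(list(family = "pointMass", value = 20),
             list(family = "pointMass", value = 30))), "sum to 1")
    expect_error(sampleFragmentLengths(pm, 0), "n must be")
})

test_that("default hair lengths give the calibrated post-filter median", {
    x <- sampleFragmentLengths(hairFragmentModel(), 2e5, seed = 4)
    expect_true(all(x >= 10))
    kept <- x[x >= 25]
    med <- sort(kept)[floor((length(kept) + 1) / 2)]
    expect_true(abs(med - 25) <= 1)
})

test_that("lengthTailProbability matches Monte Carlo tails", {
    m <- hairFragmentModel()
    x <- sampleFragmentLengths(m, 2e5, seed = 5)
    for (cut in c(25L, 30L)) {
        p <- lengthTailProbability(m, cut)
        expect_lt(abs(mean(x >= cut) - p), 4 * sqrt(p * (1 - p) / 2e5))
    }
})

test_that("degradation is identity under zero parameters", {
    mols <- c("ACGTACGT", "CCCCCCCC")
    out <- applyDegradation(mols, degradationParams(), seed = 1)
    expect_identical(out$reads, mols)
    expect_identical(out$events, c(0L, 0L))
    # no cytosines: nothing can deaminate
    noErr <- degradationParams(a5 = 0.05, lambda5 = 0.5, plateau = 0.10,
                               b3 = 0.9, mu3 = 1, epsilon = 0)
    outA <- applyDegradation("AAAAAAAA", noErr, seed = 1)
    expect_identical(outA$reads, "AAAAAAAA")
    expect_error(applyDegradation("ACGN", hairDegradationParams()),
                 "non-ACGT")
})

test_that("per-position C->T rates match d(i, L) directly", {
    mol <- paste(rep("CA", 20), collapse = "") # C at odd positions, L = 40
    params <- hairDegradationParams()
    n <- 6e4
    out <- applyDegradation(rep(mol, n), params, seed = 6)
    reads <- out$reads
    cpos <- seq(1, 39, by = 2)
    eps <- params@epsilon
    for (i in cpos[c(1, 2, 5, 10, 20)]) {
        obs <- mean(substr(reads, i, i) == "T")
        d <- damageRate(params, i, 40)
        pT <- d * (1 - eps) + (1 - d) * eps / 3
        expect_lt(abs(obs - pT), 4 * sqrt(pT * (1 - pT) / n))
    }
    # a position deep in the 3' suppression zone
    d40 <- damageRate(params, 39, 40)
    expect_lt(d40, 0.07)
})

test_that("hairDegradationParams reproduce the hair endpoint damage rates", {
    p <- hairDegradationParams()
    expect_lt(abs(damageRate(p, 1, 30) - 0.15), 0.005)
    expect_lt(abs(damageRate(p, 10, 30) - 0.10), 0.005)
    expect_lt(damageRate(p, 30, 30), 0.015)
})

test_that("simulateLibrary respects source fractions and conservation", {
    ref <- tinyReference()
    cfg <- librarySimConfig(2000, endogenousFraction = 0,
                            contaminantFraction = 1, seed = 7)
    lib <- simulateLibrary(ref, cfg)
    expect_true(all(lib@truth$source == "contaminant"))
    expect_equal(length(lib@sequences), nrow(lib@truth))
    expect_identical(names(lib@sequences), lib@truth$id)
    # intervals within chromosome bounds
    expect_true(all(lib@truth$start >= 0))
    expect_true(all(lib@truth$end <= chromLengths(ref)[lib@truth$chrom]))
    # determinism
    lib2 <- simulateLibrary(ref, cfg)
    expect_identical(lib@sequences, lib2@sequences)
    expect_identical(lib@truth, lib2@truth)
})

test_that("endogenous share follows the configured binomial", {
    ref <- tinyReference()
    n <- 2e5
    cfg <- librarySimConfig(n, endogenousFraction = 0.00231, seed = 8)
    lib <- simulateLibrary(ref, cfg)
    cnt <- sum(lib@truth$source == "endogenous")
    expect_lt(abs(cnt - n * 0.00231),
              4 * sqrt(n * 0.00231 * (1 - 0.00231)))
})

test_that("deamination is exclusively C->T in read orientation", {
    ref <- tinyReference()
    cfg <- librarySimConfig(5000, endogenousFraction = 1, mitoShare = 0.3,
                            seed = 9)
    lib <- simulateLibrary(ref, cfg)
    aln <- truthAlignments(lib)
    refTxt <- setNames(as.character(ref@sequences), chromNames(ref))
    slice <- substring(refTxt[aln$chrom], aln$start + 1, aln$end)
    minus <- aln$strand == "-"
    slice[minus] <- revcompStr(slice[minus])
    rb <- strsplit(slice, "")
    ob <- strsplit(aln$seq, "")
    ct <- ga <- other <- 0
    for (i in seq_along(rb)) {
        mm <- which(rb[[i]] != ob[[i]])
        for (j in mm) {
            if (rb[[i]][j] == "C" && ob[[i]][j] == "T") ct <- ct + 1
            else if (rb[[i]][j] == "G" && ob[[i]][j] == "A") ga <- ga + 1
            else other <- other + 1
        }
    }
    ev <- sum(lib@truth$events)
    # C->T mismatches track deamination events (flat errors are the
    # only other channel); no G->A channel exists in an ssDNA library
    expect_gt(ct / ev, 0.97)
    expect_lt(ct / ev, 1.03)
    expect_gt(ct / (ct + ga + other), 0.95)
})

test_that("capture bias follows its retention formula", {
    truth <- data.frame(id = paste0("r", 1:6),
                        length = c(20, 25, 30, 35, 60, 30),
                        events = c(0, 1, 2, 0, 5, 3))
    bias <- c(L0 = 30, slope = 0.2, penalty = 0.5)
    p <- captureRetentionProb(truth, bias)
    expected <- pmin(1, pmax(0, plogis(0.2 * (truth$length - 30)) *
                                    exp(-0.5 * truth$events)))
    expect_equal(unname(p), expected, tolerance = 1e-12)
    expect_error(simulateCapture(truth, bias, ids = c("r1", "nope")),
                 "truth row missing")
})

test_that("neutral capture retains about half, positive slope favours long", {
    ref <- tinyReference()
    lib <- simulateLibrary(ref, librarySimConfig(2e4, seed = 10))
    keep <- simulateCapture(lib, c(L0 = 0, slope = 0, penalty = 0), seed = 1)
    expect_lt(abs(length(keep) / 2e4 - 0.5), 4 * sqrt(0.25 / 2e4))
    keepLong <- simulateCapture(lib, c(L0 = 25, slope = 0.4, penalty = 0),
                                seed = 2)
    tr <- lib@truth
    expect_gt(mean(tr$length[tr$id %in% keepLong]), mean(tr$length))
})

test_that("panel simulation has no spread without drift", {
    sim <- simulatePanel(nSnps = 500, nPops = 3, Fst = 1e-6,
                         samplesPerPop = 5, seed = 11)
    rng <- apply(sim$truth$freq, 1, function(v) diff(range(v)))
    expect_lt(max(rng), 0.05)
})

test_that("Balding-Nichols drift yields the requested Fst", {
    sim <- simulatePanel(nSnps = 5000, nPops = 2, Fst = 0.05,
                         samplesPerPop = 10, seed = 12)
    p1 <- sim$truth$freq[, 1]
    p2 <- sim$truth$freq[, 2]
    # Hudson-type ratio-of-averages on the true population frequencies
    fst <- mean((p1 - p2)^2 - 0) / mean(p1 * (1 - p2) + p2 * (1 - p1))
    expect_lt(abs(fst - 0.05), 0.01)
})

test_that("sample allele frequencies converge to simulated truth", {
    corFor <- function(nSamp) {
        sim <- simulatePanel(nSnps = 1500, nPops = 2, Fst = 0.05,
                             samplesPerPop = nSamp, seed = 13)
        af <- alleleFreqs(sim$panel, "Pop1")
        cor(af$freq[, 1], sim$truth$freq[, 1])
    }
    c5 <- corFor(5)
    c50 <- corFor(50)
    expect_gt(c50, c5)
    expect_gt(c50, 0.98)
})

test_that("ancient pair is pseudo-haploid with configured missingness", {
    sim <- simulatePanel(nSnps = 2000, seed = 14, ancientMissingness = 0.5)
    g <- genoMatrix(sim$panel)
    anc <- g[, indInfo(sim$panel)$population %in% c("Ancient1", "Ancient2")]
    expect_true(all(anc[!is.na(anc)] %in% c(0L, 2L)))
    miss <- colMeans(is.na(anc))
    expect_true(all(abs(miss - 0.5) < 4 * sqrt(0.25 / 2000)))
})
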