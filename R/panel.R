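#' Simulate a multi-population genotype panel with a cladal ancient pair
#'
#' Allele frequencies follow the Balding-Nichols model: the ancestral
#' frequency of each SNP's first (ref) allele is Uniform(0.05, 0.95) and
#' population k drifts with parameter `F_k`, i.e. its frequency is
#' Beta(p (1 - F) / F, (1 - p)(1 - F) / F). Diploid genotypes are
#' Binomial(2, freq) counts of the ref allele. The outgroup is a single
#' pseudo-diploid individual fixed for an allele drawn at the ancestral
#' frequency, flipped with probability `outgroupDivergence`. Two ancient
#' samples are independent pseudo-haploid draws (one allele,
#' Binomial(1, freq)) from the *same* designated source population -- a
#' cladal pair by construction -- stored as homozygous diploid codes with
#' i.i.d. missingness. SNPs are assigned chromosome labels 1..`nChrom`
#' in contiguous blocks.
#'
#' @param nSnps Number of SNPs (>= nChrom).
#' @param nPops Number of drifted modern populations.
#' @param Fst Per-population drift parameter(s) in (0, 1), recycled.
#' @param samplesPerPop Diploid individuals per modern population.
#' @param outgroupDivergence Probability the outgroup allele flips away
#'   from the ancestral draw.
#' @param ancientMissingness Per-SNP missingness of each ancient sample.
#' @param ancientSource Index of the ancients' source population.
#' @param nChrom Number of chromosome labels (default 22).
#' @param seed Integer seed.
#' @return List with `panel` (a [GenotypePanel-class] holding moderns,
#'   outgroup and the two ancient individuals), `truth` (list with
#'   `ancestral`, `freq` matrix SNPs x populations, `sourcePop`).
#' @export
simulatePanel <- function(nSnps = 5000L, nPops = 4L, Fst = 0.05,
                          samplesPerPop = 10L, outgroupDivergence = 0.1,
                          ancientMissingness = 0.5, ancientSource = 1L,
                          nChrom = 22L, seed = NULL) {
    nSnps <- as.integer(nSnps)
    if (nSnps < nChrom) stop("need nSnps >= nChrom so every block is non-empty")
    Fst <- rep_len(Fst, nPops)
    if (any(Fst <= 0 | Fst >= 1)) stop("F must lie in (0, 1)")
    withSeed(seed, {
        pa <- runif(nSnps, 0.05, 0.95)
        freq <- vapply(seq_len(nPops), function(k) {
            F <- Fst[k]
            rbeta(nSnps, pa * (1 - F) / F, (1 - pa) * (1 - F) / F)
        }, numeric(nSnps))
        geno <- matrix(NA_integer_, nSnps, nPops * samplesPerPop +
                                           1L + 2L)
        pops <- character(ncol(geno))
        ids <- character(ncol(geno))
        col <- 0L
        for (k in seq_len(nPops)) {
            for (s in seq_len(samplesPerPop)) {
                col <- col + 1L
                geno[, col] <- rbinom(nSnps, 2L, freq[, k])
                pops[col] <- paste0("Pop", k)
                ids[col] <- paste0("Pop", k, "_ind", s)
            }
        }
        og <- rbinom(nSnps, 1L, pa)
        flip <- runif(nSnps) < outgroupDivergence
        og[flip] <- 1L - og[flip]
        col <- col + 1L
        geno[, col] <- 2L * og
        pops[col] <- "Outgroup"; ids[col] <- "Outgroup1"
        for (a in 1:2) {
            col <- col + 1L
            hap <- rbinom(nSnps, 1L, freq[, ancientSource])
            g <- 2L * hap
            g[runif(nSnps) < ancientMissingness] <- NA_integer_
            geno[, col] <- g
            pops[col] <- paste0("Ancient", a)
            ids[col] <- paste0("Ancient", a)
        }
        chrom <- rep(seq_len(nChrom), length.out = nSnps)
        chrom <- sort(chrom)
        alleles <- cbind(sample(c("A", "C", "G", "T"), nSnps, replace = TRUE),
                         NA)
        alleles[, 2] <- vapply(alleles[, 1], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
        snp <- data.frame(id = sprintf("snp%06d", seq_len(nSnps)),
                          chrom = chrom,
                          pos = unlist(lapply(split(seq_len(nSnps), chrom),
                                              function(i) seq_along(i) * 1000L),
                                       use.names = FALSE),
                          ref = alleles[, 1], alt = alleles[, 2],
                          stringsAsFactors = FALSE)
        rownames(geno) <- snp$id
        panel <- new("GenotypePanel", snp = snp, geno = geno,
                     ind = data.frame(id = ids, population = pops,
                                      stringsAsFactors = FALSE))
        list(panel = panel,
             truth = list(ancestral = pa, freq = freq,
                          sourcePop = ancientSource))
    })
}

#' @describeIn simulatePanel SNP table accessor.
#' @param x A `GenotypePanel`.
#' @export
snpInfo <- function(x) x@snp

#' @describeIn simulatePanel Genotype matrix accessor (SNPs x individuals).
#' @export
genoMatrix <- function(x) x@geno

#' @describeIn simulatePanel Individual table accessor.
#' @export
indInfo <- function(x) x@ind

setMethod("show", "GenotypePanel", function(object) {
    cat("GenotypePanel:", nrow(object@snp), "SNPs x", nrow(object@ind),
        "individuals,", length(unique(object@ind$population)),
        "population(s)\n")
    miss <- mean(is.na(object@geno))
    cat(sprintf("  chromosomes %s..%s, missingness %.1f%%\n",
                min(object@snp$chrom), max(object@snp$chrom), 100 * miss))
})
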