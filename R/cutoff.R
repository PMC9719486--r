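#' Spurious alignment rate at a given read length
#'
#' Draws `nSims` reads of exactly `length` bp from a non-target source --
#' either random sequence with the target's GC content, or real decoy
#' chromosomes -- maps them against the target and returns the fraction
#' passing the MQ filter, with its binomial standard error. Ultra-short
#' reads align to the target by chance far more often than longer ones,
#' which is the hazard the read-length cutoff guards against.
#'
#' @param ref A [ReferenceSet-class].
#' @param length Read length in bp (>= the mapper seed `k`).
#' @param nSims Number of simulated reads (>= 1000 for a stable rate;
#'   smaller values are allowed for exploration).
#' @param source `"random-gc"` or `"decoy"`.
#' @param maxMismatch,k Mapper parameters (see [mapReads()]).
#' @param minMQ MQ threshold defining a spurious "hit" (default 30).
#' @param seed Integer seed.
#' @return List with `fraction`, `se`, `n`.
#' @export
spuriousRate <- function(ref, length, nSims = 1000L,
                         source = c("random-gc", "decoy"),
                         maxMismatch = 0.06, k = 13L, minMQ = 30L,
                         seed = NULL) {
    source <- match.arg(source)
    if (length < k) stop("length must be >= mapper seed k")
    reads <- withSeed(seed, {
        if (source == "random-gc") {
            gc <- targetGC(ref)
            bases <- sample(c("A", "C", "G", "T"), nSims * length,
                            replace = TRUE,
                            prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
            vapply(seq_len(nSims), function(i)
                paste(bases[((i - 1) * length + 1):(i * length)], collapse = ""),
                "")
        } else {
            comp <- compartments(ref)
            dec <- names(comp)[comp == "decoy"]
            if (!length(dec)) stop("decoy source requested but reference has no decoy")
            clen <- chromLengths(ref)[dec]
            if (any(clen < length)) stop("decoy chromosome shorter than read length")
            chrom <- if (base::length(dec) == 1L) rep(dec, nSims)
                     else sample(dec, nSims, replace = TRUE, prob = clen)
            start <- as.integer(floor(runif(nSims) * (clen[chrom] - length + 1)))
            sl <- substring(refChars(ref)[chrom], start + 1L, start + length)
            minus <- runif(nSims) < 0.5
            sl[minus] <- cpp_revcomp(sl[minus])
            sl
        }
    })
    aln <- mapReads(setNames(reads, sprintf("sim%06d", seq_len(nSims))), ref,
                    maxMismatch = maxMismatch, k = k)
    frac <- mean(aln$mapped & aln$mapq >= minMQ)
    list(fraction = frac, se = sqrt(frac * (1 - frac) / nSims), n = nSims)
}

#' Per-cutoff mapping, damage, contamination and spurious-rate report
#'
#' For each candidate cutoff: applies the length filter (with MQ 30),
#' removes duplicates, and reports read count, median length, 5'
#' position-1 C->T rate, estimated contamination and the simulated
#' spurious alignment fraction at that read length. A failing stage
#' annotates its row; other rows are still produced.
#'
#' @param aln Alignment data frame (mapped library, unfiltered).
#' @param ref A [ReferenceSet-class].
#' @param cutoffs Integer vector of candidate length cutoffs (sorted
#'   internally).
#' @param model Optional [ContaminationModel-class]; default profiles the
#'   filtered reads themselves.
#' @param nSpurious Simulated reads per spurious-rate estimate.
#' @param spuriousSource `"random-gc"` or `"decoy"`.
#' @param minMQ MQ threshold (default 30).
#' @param seed Integer seed (spurious simulations use `seed + cutoff`).
#' @return Data frame with one row per cutoff: `cutoff`, `n`,
#'   `medianLength`, `damagePos1`, `rho`, `rhoSE`, `spurious`,
#'   `spuriousSE`, `note`.
#' @export
cutoffReport <- function(aln, ref, cutoffs, model = NULL, nSpurious = 1000L,
                         spuriousSource = "random-gc", minMQ = 30L,
                         seed = NULL) {
    if (!length(cutoffs)) stop("no cutoffs supplied")
    cutoffs <- sort(as.integer(cutoffs))
    rows <- lapply(cutoffs, function(cut) {
        row <- data.frame(cutoff = cut, n = NA_integer_,
                          medianLength = NA_real_, damagePos1 = NA_real_,
                          rho = NA_real_, rhoSE = NA_real_,
                          spurious = NA_real_, spuriousSE = NA_real_,
                          note = "", stringsAsFactors = FALSE)
        err <- function(e) conditionMessage(e)
        res <- tryCatch({
            fl <- dedupReads(filterReads(aln, minLength = cut, minMQ = minMQ))
            row$n <- nrow(fl)
            if (nrow(fl)) {
                row$medianLength <- lowerMedian(fl$length)
                row$damagePos1 <- substitutionProfile(fl, ref)@fivePrime$ctRate[1]
            }
            ""
        }, error = err)
        if (nzchar(res)) row$note <- paste0("filter/damage: ", res)
        res <- tryCatch({
            fl <- dedupReads(filterReads(aln, minLength = cut, minMQ = minMQ))
            est <- estimateContamination(fl, ref, model)
            row$rho <- est@rho
            row$rhoSE <- est@se
            ""
        }, error = err)
        if (nzchar(res))
            row$note <- paste0(row$note, if (nzchar(row$note)) "; ",
                               "contamination: ", res)
        res <- tryCatch({
            sp <- spuriousRate(ref, cut, nSims = nSpurious,
                               source = spuriousSource, minMQ = minMQ,
                               seed = if (is.null(seed)) NULL else seed + cut)
            row$spurious <- sp$fraction
            row$spuriousSE <- sp$se
            ""
        }, error = err)
        if (nzchar(res))
            row$note <- paste0(row$note, if (nzchar(row$note)) "; ",
                               "spurious: ", res)
        row
    })
    do.call(rbind, rows)
}

#' Choose the safe read-length cutoff
#'
#' Returns the smallest cutoff whose contamination estimate satisfies
#' `rho + 2 * SE <= maxContamination` and whose spurious alignment
#' fraction is `<= maxSpurious`. Rows with missing values for a criterion
#' do not qualify. Returns `NA` when no row qualifies.
#'
#' @param report Data frame from [cutoffReport()] (any row order).
#' @param maxContamination Contamination ceiling (default 0.05).
#' @param maxSpurious Spurious-fraction ceiling (default 0.10).
#' @return The chosen cutoff (integer), or `NA_integer_`.
#' @export
chooseCutoff <- function(report, maxContamination = 0.05, maxSpurious = 0.10) {
    if (!nrow(report)) stop("empty report")
    report <- report[order(report$cutoff), , drop = FALSE]
    ok <- !is.na(report$rho) & !is.na(report$rhoSE) & !is.na(report$spurious) &
        report$rho + 2 * report$rhoSE <= maxContamination &
        report$spurious <= maxSpurious
    if (!any(ok)) return(NA_integer_)
    as.integer(report$cutoff[which(ok)[1]])
}
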