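#' Construct a library simulation configuration
#'
#' @param nReads Number of molecules to emit.
#' @param endogenousFraction Fraction of raw molecules that are endogenous.
#' @param contaminantFraction Fraction of human-mapping molecules
#'   (endogenous + contaminant) that are modern contaminants. The remainder
#'   of the library, `1 - endogenousFraction / (1 - contaminantFraction)`,
#'   is environmental (decoy-derived).
#' @param mitoShare Share of human-mapping molecules drawn from the
#'   mitochondrial compartment.
#' @param endoLengths,contLengths,envLengths Fragment length models.
#' @param mitoLengths Length model for endogenous molecules in the
#'   mitochondrial compartment (default: same as `endoLengths`).
#' @param degradation [DegradationParams-class] for endogenous molecules.
#' @param contErrorProb,envErrorProb Flat per-base error probabilities for
#'   contaminant and environmental reads (no deamination).
#' @param seed Default seed used by [simulateLibrary()].
#' @return A [LibrarySimConfig-class].
#' @export
librarySimConfig <- function(nReads, endogenousFraction = 1,
                             contaminantFraction = 0, mitoShare = 0,
                             endoLengths = hairFragmentModel(),
                             contLengths = contaminantFragmentModel(),
                             envLengths = hairFragmentModel(),
                             mitoLengths = endoLengths,
                             degradation = hairDegradationParams(),
                             contErrorProb = 0.001, envErrorProb = 0.001,
                             seed = NA_integer_) {
    new("LibrarySimConfig", nReads = as.integer(nReads),
        endogenousFraction = endogenousFraction,
        contaminantFraction = contaminantFraction, mitoShare = mitoShare,
        endoLengths = endoLengths, contLengths = contLengths,
        envLengths = envLengths, mitoLengths = mitoLengths,
        degradation = degradation,
        contErrorProb = contErrorProb, envErrorProb = envErrorProb,
        seed = as.integer(seed))
}

#' Mitochondrial share needed for a target coverage-normalised mt/nuc ratio
#'
#' The coverage-normalised ratio is `(nMito / mitoLength) / (nNuclear /
#' nuclearLength)`; this inverts it for the share of molecules that must be
#' mitochondrial.
#'
#' @param ratio Target mt/nuc ratio (e.g. 200).
#' @param mitoLength,nuclearLength Compartment lengths in bp.
#' @return Share in `(0, 1)`.
#' @export
mitoShareForRatio <- function(ratio, mitoLength = 16569, nuclearLength = 2e6) {
    r <- ratio * mitoLength / nuclearLength
    r / (1 + r)
}

#' Named simulation scenarios for the hair library
#'
#' The two cutoff regimes mirror the published per-cutoff contamination
#' estimates, and the shotgun regime mirrors the published endogenous rate:
#'
#' * `hair_25bp`: contaminant share 0.001 *among reads passing a 25 bp
#'   length filter* (the scale on which per-cutoff contamination is
#'   reported); no environmental reads.
#' * `hair_30bp`: contaminant share 0.473 among reads passing a 30 bp
#'   filter; no environmental reads.
#' * `hair_shotgun`: endogenous pipeline rate 0.00231 -- the probability
#'   that a raw read ends up as a length(>= 25)- and MQ-filtered mapped
#'   read; everything else is environmental.
#'
#' The contamination targets are shares among *mapped, MQ-passing* reads
#' above the cutoff (the scale on which per-cutoff contamination is
#' estimated in practice); they are converted to raw-library fractions
#' analytically from the two length-model tails at the scenario cutoff
#' (see [lengthTailProbability()]) times fixed endogenous alignability
#' constants (0.95 at 25 bp, 0.965 at 30 bp; contaminants ~1.0) derived
#' once from the default damage model under the default mapper, because
#' the mismatch gate preferentially discards damaged reads. The shotgun
#' conversion divides by the length tail and the same 0.95 factor. All
#' scenarios use the mitochondrial share giving a coverage-normalised
#' mt/nuc ratio of 200 on the default toy genome.
#'
#' @param name One of `"hair_25bp"`, `"hair_30bp"`, `"hair_shotgun"`.
#' @param nReads Number of molecules.
#' @param seed Default seed for [simulateLibrary()].
#' @return A [LibrarySimConfig-class].
#' @export
hairScenario <- function(name = c("hair_25bp", "hair_30bp", "hair_shotgun"),
                         nReads = 2e5, seed = NA_integer_) {
    name <- match.arg(name)
    endo <- hairFragmentModel()
    cont <- contaminantFragmentModel()
    share <- mitoShareForRatio(200)
    postToRawContaminant <- function(target, cutoff, alignEndo) {
        pe <- lengthTailProbability(endo, cutoff) * alignEndo
        pc <- lengthTailProbability(cont, cutoff)
        odds <- target / (1 - target) * pe / pc
        odds / (1 + odds)
    }
    switch(name,
        hair_25bp = {
            f0 <- postToRawContaminant(0.001, 25L, 0.95)
            librarySimConfig(nReads, endogenousFraction = 1 - f0,
                             contaminantFraction = f0, mitoShare = share,
                             seed = seed)
        },
        hair_30bp = {
            f0 <- postToRawContaminant(0.473, 30L, 0.965)
            librarySimConfig(nReads, endogenousFraction = 1 - f0,
                             contaminantFraction = f0, mitoShare = share,
                             seed = seed)
        },
        hair_shotgun = {
            alignability <- 0.95
            e <- 0.00231 / (lengthTailProbability(endo, 25L) * alignability)
            librarySimConfig(nReads, endogenousFraction = e,
                             contaminantFraction = 0, mitoShare = share,
                             seed = seed)
        })
}

#' Simulate a single-stranded sequencing library
#'
#' Each molecule is assigned a source (endogenous, contaminant or
#' environmental) by the configured fractions, a compartment (mito vs
#' nuclear for human-mapping molecules, decoy for environmental), a
#' chromosome (probability proportional to length within the compartment),
#' a uniform start, and a uniform strand. The molecule is the reference
#' slice for plus-strand reads and its reverse complement for minus-strand
#' reads; degradation is applied in molecule orientation (so all
#' deamination is C->T as sequenced), endogenous molecules under the
#' configured damage model, contaminant and environmental molecules under
#' flat error only.
#'
#' @param ref A [ReferenceSet-class].
#' @param config A [LibrarySimConfig-class].
#' @param seed Integer seed (defaults to the config's seed slot).
#' @return A [HairLibrary-class] with per-read truth.
#' @export
simulateLibrary <- function(ref, config, seed = config@seed) {
    validObject(ref)
    validObject(config)
    n <- config@nReads
    humanFraction <- if (config@contaminantFraction < 1)
        config@endogenousFraction / (1 - config@contaminantFraction)
    else 1
    pEnv <- max(0, 1 - humanFraction)
    pCont <- humanFraction * config@contaminantFraction
    pEndo <- 1 - pEnv - pCont
    comp <- compartments(ref)
    clen <- chromLengths(ref)
    if (pEnv > 0 && !any(comp == "decoy"))
        stop("environmental reads requested but reference has no decoy chromosomes")
    if (config@mitoShare > 0 && !any(comp == "mito"))
        stop("mito share requested but reference has no mito chromosome")
    refTxt <- refChars(ref)

    withSeed(seed, {
        src <- sample(c("endogenous", "contaminant", "environmental"), n,
                      replace = TRUE, prob = c(pEndo, pCont, pEnv))
        human <- src != "environmental"
        compartment <- character(n)
        compartment[!human] <- "decoy"
        compartment[human] <- ifelse(runif(sum(human)) < config@mitoShare,
                                     "mito", "nuclear")
        mitoEndo <- compartment == "mito" & src == "endogenous"
        len <- integer(n)
        for (s in c("endogenous", "contaminant", "environmental")) {
            idx <- which(src == s & !mitoEndo)
            if (length(idx)) {
                model <- switch(s, endogenous = config@endoLengths,
                                contaminant = config@contLengths,
                                environmental = config@envLengths)
                len[idx] <- sampleFragmentLengths(model, length(idx))
            }
        }
        if (any(mitoEndo))
            len[mitoEndo] <- sampleFragmentLengths(config@mitoLengths,
                                                   sum(mitoEndo))
        chrom <- character(n)
        for (cp in unique(compartment)) {
            idx <- which(compartment == cp)
            cands <- names(comp)[comp == cp]
            if (!length(cands))
                stop("reference lacks requested compartment: ", cp)
            chrom[idx] <- if (length(cands) == 1L) cands
                else sample(cands, length(idx), replace = TRUE,
                            prob = clen[cands])
        }
        maxlen <- clen[chrom]
        if (any(len > maxlen))
            stop("requested fragment longer than chromosome")
        start <- as.integer(floor(runif(n) * (maxlen - len + 1)))
        strand <- sample(c("+", "-"), n, replace = TRUE)
        slice <- substring(refTxt[chrom], start + 1L, start + len)
        mol <- slice
        minus <- strand == "-"
        if (any(minus)) mol[minus] <- cpp_revcomp(slice[minus])
        reads <- character(n)
        events <- integer(n)
        for (s in c("endogenous", "contaminant", "environmental")) {
            idx <- which(src == s)
            if (!length(idx)) next
            dp <- switch(s,
                endogenous = config@degradation,
                contaminant = degradationParams(epsilon = config@contErrorProb),
                environmental = degradationParams(epsilon = config@envErrorProb))
            dg <- cpp_degrade(mol[idx], dp@a5, dp@lambda5, dp@plateau,
                              dp@b3, dp@mu3, dp@epsilon)
            reads[idx] <- dg$reads
            events[idx] <- dg$events
        }
        ids <- sprintf("read%07d", seq_len(n))
        truth <- data.frame(id = ids, source = src, compartment = compartment,
                            chrom = chrom, start = start,
                            end = start + len, strand = strand,
                            length = len, events = events,
                            stringsAsFactors = FALSE)
        new("HairLibrary", sequences = setNames(reads, ids), truth = truth,
            config = config,
            seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
    })
}

#' Simulate capture (hybridisation enrichment) bias
#'
#' Retention probability `plogis(slope * (L - L0)) * exp(-penalty *
#' events)`, clamped to `[0, 1]`: capture preferentially retains longer
#' molecules and molecules without deamination damage.
#'
#' @param lib A [HairLibrary-class], or a truth data frame with `id`,
#'   `length` and `events` columns.
#' @param bias Named numeric vector or list with `L0` (length midpoint,
#'   bp), `slope` (per bp) and `penalty` (per deamination event).
#' @param seed Integer seed.
#' @param ids Optional subset of read ids to consider; every id must have a
#'   truth row.
#' @return Character vector of retained read ids.
#' @export
simulateCapture <- function(lib, bias = c(L0 = 30, slope = 0.1, penalty = 0.5),
                            seed = NULL, ids = NULL) {
    truth <- if (is(lib, "HairLibrary")) lib@truth else lib
    if (!is.null(ids)) {
        miss <- setdiff(ids, truth$id)
        if (length(miss))
            stop("truth row missing for read(s): ", paste(head(miss, 3), collapse = ", "))
        truth <- truth[match(ids, truth$id), ]
    }
    bias <- as.list(bias)
    if (!all(vapply(bias, is.finite, TRUE)))
        stop("bias parameters must be finite")
    p <- pmin(1, pmax(0, plogis(bias$slope * (truth$length - bias$L0)) *
                             exp(-bias$penalty * truth$events)))
    withSeed(seed, truth$id[runif(nrow(truth)) < p])
}

#' Capture retention probabilities without sampling
#'
#' @inheritParams simulateCapture
#' @return Named numeric vector of retention probabilities.
#' @export
captureRetentionProb <- function(lib, bias = c(L0 = 30, slope = 0.1, penalty = 0.5)) {
    truth <- if (is(lib, "HairLibrary")) lib@truth else lib
    bias <- as.list(bias)
    setNames(pmin(1, pmax(0, plogis(bias$slope * (truth$length - bias$L0)) *
                                 exp(-bias$penalty * truth$events))), truth$id)
}

#' Subset a simulated library by read ids
#'
#' @param lib A [HairLibrary-class].
#' @param ids Read ids to keep (order preserved).
#' @export
subsetLibrary <- function(lib, ids) {
    keep <- match(ids, lib@truth$id)
    if (anyNA(keep)) stop("unknown read id(s)")
    new("HairLibrary", sequences = lib@sequences[keep],
        truth = lib@truth[keep, , drop = FALSE], config = lib@config,
        seed = lib@seed)
}

#' Alignments at the simulator's true placements
#'
#' Bypasses mapping by aligning every read at its truth interval with
#' MQ 37. Environmental (decoy-derived) reads are excluded: they have no
#' placement on the mapping target.
#'
#' @param lib A [HairLibrary-class].
#' @return An alignment data frame (see [mapReads()] for columns).
#' @export
truthAlignments <- function(lib) {
    keep <- lib@truth$source != "environmental"
    tr <- lib@truth[keep, , drop = FALSE]
    aln <- data.frame(id = tr$id, chrom = tr$chrom, start = tr$start,
                      end = tr$end, strand = tr$strand, mapq = 37L,
                      length = tr$length,
                      seq = unname(lib@sequences[keep]), nm = NA_integer_,
                      mapped = TRUE, stringsAsFactors = FALSE)
    attr(aln, "nRaw") <- nrow(lib@truth)
    aln
}

#' Write library reads as FASTQ (Phred+33)
#'
#' All base qualities are written as Q37 ('F'); the simulator's flat error
#' model does not modulate qualities.
#'
#' @param lib A [HairLibrary-class].
#' @param path Output file.
#' @export
writeLibraryFastq <- function(lib, path) {
    qual <- strrep("F", nchar(lib@sequences))
    out <- paste0("@", names(lib@sequences), "\n", lib@sequences, "\n+\n", qual)
    writeLines(out, path)
    invisible(path)
}

#' Write the truth table as TSV
#'
#' @param lib A [HairLibrary-class].
#' @param path Output file.
#' @export
writeTruthTable <- function(lib, path) {
    utils::write.table(lib@truth, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a FASTQ file into a named character vector of sequences
#'
#' @param path FASTQ file (plain text).
#' @return Named character vector.
#' @export
readFastqSequences <- function(path) {
    x <- readLines(path)
    if (length(x) %% 4L != 0L) stop("truncated FASTQ: ", path)
    ids <- sub("\\s.*$", "", sub("^@", "", x[seq(1, length(x), by = 4)]))
    setNames(x[seq(2, length(x), by = 4)], ids)
}

setMethod("show", "HairLibrary", function(object) {
    tab <- table(object@truth$source)
    cat("HairLibrary with", length(object@sequences), "reads\n")
    for (s in names(tab)) cat(sprintf("  %-13s %d\n", s, tab[[s]]))
    cat("  median length", lowerMedian(object@truth$length), "bp\n")
})
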