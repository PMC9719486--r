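# Reference slices oriented to read direction: reverse-complemented for
# minus-strand alignments so position 1 is the read's 5' base.
orientedRefSlices <- function(aln, ref) {
    refTxt <- refChars(ref)
    slice <- substring(refTxt[aln$chrom], aln$start + 1L, aln$end)
    minus <- aln$strand == "-"
    if (any(minus)) slice[minus] <- cpp_revcomp(slice[minus])
    slice
}

#' Position-specific substitution profile
#'
#' Tallies reference-C opportunities and C->T observations (and the
#' reference-G / G->A channel) at each of the first `P` positions from the
#' 5' and 3' read ends, with the reference slice oriented to read
#' direction. Reads shorter than `P` contribute only their positions;
#' reads shorter than `2 * P` contribute the same bases to both end
#' tallies (their number is recorded, not silently hidden).
#'
#' @param aln Alignment data frame (mapped, ungapped or gap-collapsed).
#' @param ref A [ReferenceSet-class].
#' @param P Positions profiled per end (default 25).
#' @return A [DamageProfile-class].
#' @export
substitutionProfile <- function(aln, ref, P = 25L) {
    if (P < 1L) stop("P must be >= 1")
    aln <- aln[aln$mapped, , drop = FALSE]
    if (!nrow(aln)) stop("no mapped reads to profile")
    if (any(aln$length != aln$end - aln$start))
        stop("read/reference length mismatch (gapped input?)")
    slices <- orientedRefSlices(aln, ref)
    tl <- cpp_substitution_profile(aln$seq, slices, as.integer(P))
    mk <- function(opp, ct, gopp, ga) {
        data.frame(position = seq_len(P), cOpportunities = opp, ctCount = ct,
                   ctRate = ifelse(opp > 0, ct / opp, 0),
                   gOpportunities = gopp, gaCount = ga,
                   gaRate = ifelse(gopp > 0, ga / gopp, 0))
    }
    new("DamageProfile", positions = as.integer(P),
        fivePrime = mk(tl$c5opp, tl$c5ct, tl$g5opp, tl$g5ga),
        threePrime = mk(tl$c3opp, tl$c3ct, tl$g3opp, tl$g3ga),
        nReads = tl$nReads, mismatches = tl$mismatches,
        shortReadOverlap = sum(aln$length < 2L * P))
}

#' @describeIn substitutionProfile C->T rate at a given 5' position.
#' @param profile A [DamageProfile-class].
#' @param position 1-based position from the 5' end.
#' @export
damageRateAt <- function(profile, position) {
    profile@fivePrime$ctRate[position]
}

#' Read length statistics
#'
#' @param x Alignment data frame or numeric vector of lengths.
#' @return List with `histogram` (integer table), `median` (lower-middle
#'   order statistic for even n), `mean` and `n`.
#' @export
lengthStats <- function(x) {
    len <- if (is.data.frame(x)) x$length else x
    if (!length(len)) stop("empty input")
    list(histogram = table(len), median = lowerMedian(len),
         mean = mean(len), n = length(len))
}

#' Compare damage and length between nuclear and mitochondrial reads
#'
#' Computes per-compartment substitution profiles under identical settings
#' plus a per-position rate-difference table and per-compartment median
#' lengths. A compartment with no reads yields an explicit empty flag
#' rather than a silent zero profile.
#'
#' @param aln Alignment data frame.
#' @param ref A [ReferenceSet-class].
#' @param P Positions per end.
#' @return List with `nuclear`, `mito` ([DamageProfile-class] or NULL),
#'   `empty` (character vector of missing compartments), `differences`
#'   (5' position, nuclear rate, mito rate, difference) and
#'   `medianLength` (named vector).
#' @export
compareCompartments <- function(aln, ref, P = 25L) {
    comp <- compartments(ref)
    aln <- aln[aln$mapped, , drop = FALSE]
    readComp <- comp[aln$chrom]
    out <- list(nuclear = NULL, mito = NULL, empty = character(),
                differences = NULL, medianLength = c(nuclear = NA_real_,
                                                     mito = NA_real_))
    for (cp in c("nuclear", "mito")) {
        sub <- aln[readComp == cp, , drop = FALSE]
        if (!nrow(sub)) {
            out$empty <- c(out$empty, cp)
        } else {
            out[[cp]] <- substitutionProfile(sub, ref, P)
            out$medianLength[cp] <- lowerMedian(sub$length)
        }
    }
    if (is.null(out$nuclear) || is.null(out$mito)) return(out)
    out$differences <- data.frame(
        position = seq_len(P),
        nuclearRate = out$nuclear@fivePrime$ctRate,
        mitoRate = out$mito@fivePrime$ctRate,
        difference = out$mito@fivePrime$ctRate - out$nuclear@fivePrime$ctRate)
    out
}

#' Write damage profile tables as TSV
#'
#' Emits `damage_5p.tsv` and `damage_3p.tsv` under `dir`.
#'
#' @param profile A [DamageProfile-class].
#' @param dir Output directory.
#' @export
writeDamageProfile <- function(profile, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.table(profile@fivePrime, file.path(dir, "damage_5p.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(profile@threePrime, file.path(dir, "damage_3p.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}

setMethod("show", "DamageProfile", function(object) {
    cat("DamageProfile over", object@positions, "positions per end,",
        format(object@nReads, big.mark = ","), "reads\n")
    f <- object@fivePrime
    cat(sprintf("  5' C->T: pos1 %.3f  pos2 %.3f  pos10 %.3f\n",
                f$ctRate[1], f$ctRate[2],
                if (object@positions >= 10) f$ctRate[10] else NA))
    cat(sprintf("  3' C->T: last %.3f\n", object@threePrime$ctRate[1]))
})
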