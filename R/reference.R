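#' Build a synthetic reference with compartment labels
#'
#' Generates i.i.d. bases at a configured GC fraction for each requested
#' chromosome. Decoy chromosomes represent environmental (non-target) DNA
#' sources: reads are simulated from them but they are excluded from the
#' mapping target.
#'
#' @param spec Data frame with columns `name`, `length` (bp, >= 200),
#'   `compartment` (`nuclear`/`mito`/`decoy`) and `gc` (in (0, 1)).
#' @param seed Integer seed.
#' @return A [ReferenceSet-class].
#' @examples
#' ref <- makeReference(data.frame(
#'     name = c("chr1", "MT"), length = c(1000, 500),
#'     compartment = c("nuclear", "mito"), gc = 0.41), seed = 1)
#' ref
#' @export
makeReference <- function(spec, seed = NULL) {
    if (!is.data.frame(spec) || nrow(spec) == 0L) stop("empty reference spec")
    need <- c("name", "length", "compartment", "gc")
    if (!all(need %in% names(spec))) stop("spec needs columns ", paste(need, collapse = ", "))
    if (anyDuplicated(spec$name)) stop("duplicate chromosome names")
    if (any(spec$length < 200)) stop("chromosome lengths must be >= 200 bp")
    if (any(spec$gc <= 0 | spec$gc >= 1)) stop("gc must lie in (0, 1)")
    seqs <- withSeed(seed, {
        vapply(seq_len(nrow(spec)), function(i) {
            gc <- spec$gc[i]
            paste(sample(c("A", "C", "G", "T"), spec$length[i], replace = TRUE,
                         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
                  collapse = "")
        }, "")
    })
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- as.character(spec$name)
    new("ReferenceSet", sequences = x, compartment = as.character(spec$compartment))
}

#' Default toy genome for the hair-library scenarios
#'
#' Two 1 Mb nuclear chromosomes, one 16,569 bp mitochondrial chromosome and
#' one 1 Mb decoy chromosome standing for environmental DNA, all at GC 0.41.
#'
#' @param seed Integer seed.
#' @param nuclearLength,decoyLength Lengths in bp.
#' @return A [ReferenceSet-class].
#' @export
makeHairReference <- function(seed = 1L, nuclearLength = 1e6, decoyLength = 1e6) {
    makeReference(data.frame(
        name = c("chr1", "chr2", "MT", "decoy1"),
        length = c(nuclearLength, nuclearLength, 16569, decoyLength),
        compartment = c("nuclear", "nuclear", "mito", "decoy"),
        gc = 0.41), seed = seed)
}

#' @describeIn makeReference Chromosome names.
#' @param x A `ReferenceSet`.
#' @export
chromNames <- function(x) names(x@sequences)

#' @describeIn makeReference Compartment label per chromosome.
#' @export
compartments <- function(x) setNames(x@compartment, names(x@sequences))

#' @describeIn makeReference Chromosome widths in bp.
#' @export
chromLengths <- function(x) setNames(Biostrings::width(x@sequences), names(x@sequences))

#' @describeIn makeReference Total length (bp) of one compartment.
#' @param compartment Compartment name.
#' @export
compartmentLength <- function(x, compartment) {
    sum(chromLengths(x)[x@compartment == compartment])
}

#' @describeIn makeReference The mapping target: all non-decoy chromosomes.
#' @export
targetReference <- function(x) {
    keep <- x@compartment != "decoy"
    if (!any(keep)) stop("reference has no target (non-decoy) chromosomes")
    new("ReferenceSet", sequences = x@sequences[keep],
        compartment = x@compartment[keep])
}

#' Write a ReferenceSet to FASTA
#'
#' @param x A [ReferenceSet-class].
#' @param path Output file.
#' @export
writeReferenceFasta <- function(x, path) {
    Biostrings::writeXStringSet(x@sequences, filepath = path)
    invisible(path)
}

#' Read a FASTA file into a ReferenceSet
#'
#' @param path FASTA file.
#' @param compartment Compartment label per sequence (recycled if length 1).
#' @export
readReferenceFasta <- function(path, compartment = "nuclear") {
    seqs <- Biostrings::readDNAStringSet(path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    new("ReferenceSet", sequences = seqs,
        compartment = rep_len(compartment, length(seqs)))
}

# Plain character access used by the simulation / profiling hot paths.
refChars <- function(x) {
    setNames(as.character(x@sequences), names(x@sequences))
}

# GC fraction of the target compartments (used for GC-matched decoys and
# spurious-alignment read generation).
targetGC <- function(x) {
    tgt <- targetReference(x)
    f <- Biostrings::alphabetFrequency(tgt@sequences, baseOnly = TRUE)
    sum(f[, c("C", "G")]) / sum(f[, c("A", "C", "G", "T")])
}

setMethod("show", "ReferenceSet", function(object) {
    w <- chromLengths(object)
    cat("ReferenceSet with", length(w), "chromosomes\n")
    for (comp in unique(object@compartment)) {
        idx <- object@compartment == comp
        cat(sprintf("  %-8s %d chromosome(s), %s bp\n", comp, sum(idx),
                    format(sum(w[idx]), big.mark = ",")))
    }
})
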