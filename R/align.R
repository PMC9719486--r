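#' Map reads with the compact seed-and-extend mapper
#'
#' All exact k-mer seeds of each read (both strands, default k = 13) are
#' looked up in a hash index of the mapping target (all non-decoy
#' chromosomes); every implied ungapped placement is scored by full
#' mismatch count and accepted when mismatches <= `ceil(maxMismatch * L)`.
#' A unique best-scoring placement receives MQ 37, tied best placements
#' MQ 0; reads with no accepted placement stay unmapped. This is a
#' deliberately small, deterministic stand-in for a production aligner: it
#' is ungapped, two-valued in mapping quality, and requires at least one
#' exact seed.
#'
#' @param reads A [HairLibrary-class], a named character vector of read
#'   sequences, or a path to a FASTQ file.
#' @param ref A [ReferenceSet-class] (decoy chromosomes are excluded from
#'   the target).
#' @param maxMismatch Maximum mismatch fraction (default 0.06).
#' @param k Seed length (default 13; must not exceed the shortest read you
#'   expect to map -- shorter reads stay unmapped).
#' @return Data frame with one row per input read: `id`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, `mapq`, `length`, `seq`, `nm`
#'   (mismatches of the reported placement), `mapped`. The attribute
#'   `nRaw` records the number of input reads.
#' @export
mapReads <- function(reads, ref, maxMismatch = 0.06, k = 13L) {
    if (is(reads, "HairLibrary")) reads <- reads@sequences
    if (is.character(reads) && length(reads) == 1L && file.exists(reads) &&
        grepl("\\.(fastq|fq)$", reads))
        reads <- readFastqSequences(reads)
    if (!length(reads)) stop("no reads supplied")
    if (is.null(names(reads)))
        names(reads) <- sprintf("read%07d", seq_along(reads))
    tgt <- targetReference(ref)
    res <- cpp_map_reads(unname(reads), unname(as.character(tgt@sequences)),
                         as.integer(k), maxMismatch)
    chromName <- chromNames(tgt)[res$chrom]
    len <- nchar(reads)
    aln <- data.frame(id = names(reads), chrom = chromName,
                      start = res$start,
                      end = res$start + ifelse(res$mapped, len, NA_integer_),
                      strand = ifelse(res$minus, "-", "+"),
                      mapq = res$mapq, length = as.integer(len),
                      seq = unname(reads), nm = res$nm, mapped = res$mapped,
                      stringsAsFactors = FALSE)
    attr(aln, "nRaw") <- length(reads)
    aln
}

restoreAlnAttrs <- function(aln, from) {
    attr(aln, "nRaw") <- attr(from, "nRaw")
    aln
}

#' Apply length and mapping-quality filters
#'
#' Keeps mapped reads with `length >= minLength` and `mapq >= minMQ`,
#' preserving order. Idempotent.
#'
#' @param aln Alignment data frame from [mapReads()] or
#'   [truthAlignments()].
#' @param minLength Minimum read length in bp (default 25).
#' @param minMQ Minimum mapping quality (default 30).
#' @export
filterReads <- function(aln, minLength = 25L, minMQ = 30L) {
    keep <- aln$mapped & aln$length >= minLength & aln$mapq >= minMQ
    restoreAlnAttrs(aln[which(keep), , drop = FALSE], aln)
}

#' Remove duplicate alignments
#'
#' Among reads sharing (chromosome, start, end, strand) exactly one -- the
#' first encountered -- is retained. Idempotent.
#'
#' @param aln Alignment data frame.
#' @export
dedupReads <- function(aln) {
    key <- paste(aln$chrom, aln$start, aln$end, aln$strand, sep = "\r")
    restoreAlnAttrs(aln[!duplicated(key), , drop = FALSE], aln)
}

#' Mitochondrial vs nuclear read counts and coverage-normalised ratio
#'
#' The mt/nuc ratio is `(nMito / mitoLength) / (nNuclear / nuclearLength)`;
#' it is 0 when no mitochondrial reads are present and flagged undefined
#' when no nuclear reads are present.
#'
#' @param aln Alignment data frame (mapped reads are counted).
#' @param ref A [ReferenceSet-class] with compartment labels.
#' @return List with `nMito`, `nNuclear`, `ratio`, `undefined`.
#' @export
compartmentStats <- function(aln, ref) {
    comp <- compartments(ref)
    readComp <- comp[aln$chrom]
    nMito <- sum(readComp == "mito", na.rm = TRUE)
    nNuclear <- sum(readComp == "nuclear", na.rm = TRUE)
    mlen <- compartmentLength(ref, "mito")
    nlen <- compartmentLength(ref, "nuclear")
    if (nNuclear == 0L)
        return(list(nMito = nMito, nNuclear = 0L, ratio = NA_real_,
                    undefined = TRUE))
    ratio <- if (nMito == 0L) 0 else (nMito / mlen) / (nNuclear / nlen)
    list(nMito = nMito, nNuclear = nNuclear, ratio = ratio, undefined = FALSE)
}

#' Write alignments as minimal SAM
#'
#' Emits @HD/@SQ headers, FLAG bits 4 (unmapped) and 16 (reverse strand),
#' 1-based POS, two-valued MAPQ, ungapped `<L>M` CIGAR, the read as
#' sequenced, flat Q37 qualities and an `NM:i:` tag where known.
#'
#' @param aln Alignment data frame.
#' @param ref A [ReferenceSet-class] (for @SQ lines; target chromosomes
#'   only).
#' @param path Output file.
#' @export
writeSam <- function(aln, ref, path) {
    tgt <- targetReference(ref)
    hdr <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", chromNames(tgt), chromLengths(tgt)))
    flag <- ifelse(!aln$mapped, 4L, ifelse(aln$strand == "-", 16L, 0L))
    rec <- paste(aln$id, flag,
                 ifelse(aln$mapped, aln$chrom, "*"),
                 ifelse(aln$mapped, aln$start + 1L, 0L),
                 ifelse(aln$mapped, aln$mapq, 0L),
                 ifelse(aln$mapped, paste0(aln$length, "M"), "*"),
                 "*", 0L, 0L, aln$seq, strrep("F", aln$length),
                 sep = "\t")
    hasNM <- aln$mapped & !is.na(aln$nm)
    rec[hasNM] <- paste0(rec[hasNM], "\tNM:i:", aln$nm[hasNM])
    writeLines(c(hdr, rec), path)
    invisible(path)
}

# Collapse a gapped CIGAR alignment onto reference columns: M/=/X emit the
# read base, D/N emit an N placeholder, I/S consume read bases silently.
# Keeps read length equal to the reference interval length.
collapseCigar <- function(seq, cigar) {
    ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^\\d+", "", ops)
    out <- character(0)
    rp <- 1L
    for (i in seq_along(op)) {
        if (op[i] %in% c("M", "=", "X")) {
            out <- c(out, substr(seq, rp, rp + n[i] - 1L))
            rp <- rp + n[i]
        } else if (op[i] %in% c("I", "S")) {
            rp <- rp + n[i]
        } else if (op[i] %in% c("D", "N")) {
            out <- c(out, strrep("N", n[i]))
        }
    }
    paste(out, collapse = "")
}

#' Read a SAM file into an alignment data frame
#'
#' Accepts externally produced SAM: FLAG bits 4/16 are honoured and gapped
#' CIGARs are collapsed onto reference columns (insertions and soft clips
#' dropped, deletions padded with N so that the stored read length always
#' equals the reference interval length; N never counts as a substitution
#' opportunity downstream).
#'
#' @param path SAM file.
#' @return Alignment data frame (see [mapReads()]).
#' @export
readSam <- function(path) {
    x <- readLines(path)
    x <- x[!startsWith(x, "@")]
    if (!length(x))
        return(data.frame(id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character(), mapq = integer(),
                          length = integer(), seq = character(),
                          nm = integer(), mapped = logical()))
    f <- strsplit(x, "\t", fixed = TRUE)
    nf <- lengths(f)
    if (any(nf < 11L))
        stop("malformed SAM record at line ", which(nf < 11L)[1])
    flag <- as.integer(vapply(f, `[[`, "", 2L))
    mapped <- bitwAnd(flag, 4L) == 0L
    seqs <- vapply(f, `[[`, "", 10L)
    cig <- vapply(f, `[[`, "", 6L)
    gapped <- mapped & grepl("[IDNS]", cig)
    if (any(gapped))
        seqs[gapped] <- vapply(which(gapped), function(i)
            collapseCigar(seqs[i], cig[i]), "")
    nm <- vapply(f, function(v) {
        tag <- grep("^NM:i:", v[-(1:11)], value = TRUE)
        if (length(tag)) as.integer(sub("^NM:i:", "", tag[1])) else NA_integer_
    }, 1L)
    start <- as.integer(vapply(f, `[[`, "", 4L)) - 1L
    len <- nchar(seqs)
    aln <- data.frame(id = vapply(f, `[[`, "", 1L),
                      chrom = ifelse(mapped, vapply(f, `[[`, "", 3L), NA),
                      start = ifelse(mapped, start, NA),
                      end = ifelse(mapped, start + len, NA),
                      strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
                      mapq = as.integer(vapply(f, `[[`, "", 5L)),
                      length = as.integer(len), seq = seqs, nm = nm,
                      mapped = mapped, stringsAsFactors = FALSE)
    attr(aln, "nRaw") <- nrow(aln)
    aln
}
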