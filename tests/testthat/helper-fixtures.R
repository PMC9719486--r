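# Small references shared across test files. Built in code; sizes chosen
# so that a 20+ bp read is almost surely unique.

tinyReference <- function(seed = 42L, nuclear = 2e4, mito = 1600,
                          decoy = 2e4) {
    makeReference(data.frame(
        name = c("chr1", "MT", "decoy1"),
        length = c(nuclear, mito, decoy),
        compartment = c("nuclear", "mito", "decoy"),
        gc = 0.41), seed = seed)
}

# A ReferenceSet wrapping explicit sequences (for hand-tally fixtures).
literalReference <- function(seqs, compartment = rep("nuclear", length(seqs))) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- names(seqs)
    new("ReferenceSet", sequences = x, compartment = compartment)
}

# Minimal alignment data frame for hand-built fixtures.
makeAln <- function(chrom, start, seq, strand = "+", mapq = 37L,
                    id = sprintf("r%03d", seq_along(start))) {
    len <- nchar(seq)
    data.frame(id = id, chrom = chrom, start = as.integer(start),
               end = as.integer(start + len), strand = strand,
               mapq = as.integer(mapq), length = as.integer(len), seq = seq,
               nm = NA_integer_, mapped = TRUE, stringsAsFactors = FALSE)
}

revcompStr <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
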