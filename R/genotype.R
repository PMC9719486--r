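complementBase <- function(b) c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]

#' Pileup of base counts at panel SNP positions
#'
#' Counts reference-oriented bases from reads passing the mapping-quality
#' gate, at bases passing the base-quality gate. SNP positions are 1-based
#' physical positions on the named chromosome; a SNP outside the reference
#' bounds (or on an absent chromosome) is flagged and skipped. Alignments
#' may carry a `qual` column (Phred+33 string); without one, all bases are
#' treated as Q37.
#'
#' @param aln Alignment data frame.
#' @param ref A [ReferenceSet-class].
#' @param panel A [GenotypePanel-class] (its `snp` table is used; `chrom`
#'   labels must match reference chromosome names).
#' @param minBQ Minimum base quality (default 30).
#' @param minMQ Minimum mapping quality (default 30).
#' @return Data frame: `snpId`, `A`, `C`, `G`, `T`, `depth`, `skipped`.
#' @export
pileupAtSnps <- function(aln, ref, panel, minBQ = 30L, minMQ = 30L) {
    snp <- panel@snp
    clen <- chromLengths(ref)
    aln <- aln[aln$mapped & aln$mapq >= minMQ, , drop = FALSE]
    hasQual <- "qual" %in% names(aln)
    out <- data.frame(snpId = snp$id, A = 0L, C = 0L, G = 0L, T = 0L,
                      depth = 0L, skipped = FALSE, stringsAsFactors = FALSE)
    byChrom <- split(seq_len(nrow(aln)), aln$chrom)
    for (j in seq_len(nrow(snp))) {
        chr <- as.character(snp$chrom[j])
        p <- snp$pos[j]
        if (!chr %in% names(clen) || p < 1L || p > clen[[chr]]) {
            out$skipped[j] <- TRUE
            next
        }
        rows <- byChrom[[chr]]
        if (is.null(rows)) next
        cover <- rows[aln$start[rows] < p & aln$end[rows] >= p]
        if (!length(cover)) next
        for (r in cover) {
            offRef <- p - aln$start[r]              # 1-based in ref slice
            L <- aln$length[r]
            readPos <- if (aln$strand[r] == "-") L - offRef + 1L else offRef
            b <- substr(aln$seq[r], readPos, readPos)
            if (aln$strand[r] == "-") b <- complementBase(b)
            if (!b %in% c("A", "C", "G", "T")) next
            if (hasQual) {
                q <- utf8ToInt(substr(aln$qual[r], readPos, readPos)) - 33L
                if (q < minBQ) next
            } else if (37L < minBQ) next
            out[[b]][j] <- out[[b]][j] + 1L
        }
    }
    out$depth <- out$A + out$C + out$G + out$T
    out
}

#' Pseudo-haploid genotype calls
#'
#' Per SNP, bases matching neither panel allele are discarded; if no
#' allelic base remains the call is missing, otherwise one base is drawn
#' uniformly at random among the passing allelic bases and its allele is
#' called. Haploid calls are represented as homozygous diploid codes
#' (2 = ref/ref, 0 = alt/alt) for panel compatibility.
#'
#' @param pileup Data frame from [pileupAtSnps()].
#' @param panel A [GenotypePanel-class].
#' @param seed Integer seed.
#' @return Data frame: `snpId`, `call` (`"ref"`/`"alt"`/NA), `allele`,
#'   `support` (count of the called allele), `code` (2/0/NA).
#' @export
pseudoHaploidCall <- function(pileup, panel, seed = NULL) {
    snp <- panel@snp
    stopifnot(identical(pileup$snpId, snp$id))
    nref <- mapply(function(j, a) pileup[[a]][j], seq_len(nrow(snp)), snp$ref)
    nalt <- mapply(function(j, a) pileup[[a]][j], seq_len(nrow(snp)), snp$alt)
    tot <- nref + nalt
    withSeed(seed, {
        u <- runif(nrow(snp))
        isRef <- ifelse(tot > 0L, u < nref / tot, NA)
        data.frame(snpId = snp$id,
                   call = ifelse(is.na(isRef), NA_character_,
                                 ifelse(isRef, "ref", "alt")),
                   allele = ifelse(is.na(isRef), NA_character_,
                                   ifelse(isRef, snp$ref, snp$alt)),
                   support = ifelse(is.na(isRef), 0L,
                                    ifelse(isRef, nref, nalt)),
                   code = ifelse(is.na(isRef), NA_integer_,
                                 ifelse(isRef, 2L, 0L)),
                   stringsAsFactors = FALSE)
    })
}

#' Write a genotype panel in EIGENSTRAT format
#'
#' Writes `prefix.geno` (one line per SNP, one digit per individual:
#' count of the ref allele, 9 for missing), `prefix.snp` (id, chromosome,
#' genetic position 0.0, physical position, ref, alt) and `prefix.ind`
#' (id, U, population).
#'
#' @param panel A [GenotypePanel-class].
#' @param prefix Output path prefix.
#' @export
writeEigenstrat <- function(panel, prefix) {
    g <- panel@geno
    g[is.na(g)] <- 9L
    writeLines(apply(g, 1L, paste, collapse = ""), paste0(prefix, ".geno"))
    snp <- panel@snp
    writeLines(sprintf("%s\t%s\t0.0\t%d\t%s\t%s", snp$id, snp$chrom, snp$pos,
                       snp$ref, snp$alt), paste0(prefix, ".snp"))
    ind <- panel@ind
    writeLines(sprintf("%s\tU\t%s", ind$id, ind$population),
               paste0(prefix, ".ind"))
    invisible(prefix)
}

#' Read an EIGENSTRAT panel
#'
#' @param prefix Path prefix of `.geno`, `.snp`, `.ind` files.
#' @return A [GenotypePanel-class].
#' @export
readEigenstrat <- function(prefix) {
    snpLines <- readLines(paste0(prefix, ".snp"))
    indLines <- readLines(paste0(prefix, ".ind"))
    genoLines <- readLines(paste0(prefix, ".geno"))
    if (length(genoLines) != length(snpLines))
        stop("geno has ", length(genoLines), " lines but snp has ",
             length(snpLines))
    snpF <- strsplit(trimws(snpLines), "\\s+")
    if (any(lengths(snpF) < 6L))
        stop("malformed snp line ", which(lengths(snpF) < 6L)[1])
    indF <- strsplit(trimws(indLines), "\\s+")
    if (any(lengths(indF) < 3L))
        stop("malformed ind line ", which(lengths(indF) < 3L)[1])
    nInd <- length(indF)
    bad <- which(nchar(genoLines) != nInd)
    if (length(bad))
        stop("geno line ", bad[1], " has width ", nchar(genoLines)[bad[1]],
             ", expected ", nInd)
    codes <- matrix(as.integer(unlist(strsplit(genoLines, ""),
                                      use.names = FALSE)),
                    nrow = length(genoLines), byrow = TRUE)
    if (anyNA(codes) || !all(codes %in% c(0L, 1L, 2L, 9L)))
        stop("unknown genotype code in geno file (allowed: 0, 1, 2, 9)")
    codes[codes == 9L] <- NA_integer_
    snp <- data.frame(id = vapply(snpF, `[[`, "", 1L),
                      chrom = suppressWarnings(
                          as.integer(vapply(snpF, `[[`, "", 2L))),
                      pos = as.integer(vapply(snpF, `[[`, "", 4L)),
                      ref = vapply(snpF, `[[`, "", 5L),
                      alt = vapply(snpF, `[[`, "", 6L),
                      stringsAsFactors = FALSE)
    rownames(codes) <- snp$id
    new("GenotypePanel", snp = snp, geno = codes,
        ind = data.frame(id = vapply(indF, `[[`, "", 1L),
                         population = vapply(indF, `[[`, "", 3L),
                         stringsAsFactors = FALSE))
}

#' Insert sample calls into a panel as a new individual
#'
#' @param panel A [GenotypePanel-class].
#' @param codes Named (by SNP id) or panel-ordered vector of genotype
#'   codes (0/1/2/NA).
#' @param id,population Labels for the new individual.
#' @return A [GenotypePanel-class] with one more column.
#' @export
addIndividual <- function(panel, codes, id, population = id) {
    if (!is.null(names(codes))) codes <- codes[panel@snp$id]
    stopifnot(length(codes) == nrow(panel@snp))
    geno <- cbind(panel@geno, as.integer(codes))
    new("GenotypePanel", snp = panel@snp, geno = geno,
        ind = rbind(panel@ind, data.frame(id = id, population = population,
                                          stringsAsFactors = FALSE)))
}
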