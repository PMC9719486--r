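#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
NULL

setClassUnion("dataframeOrNULL", c("data.frame", "NULL"))

#' ReferenceSet: a small genome with compartment labels
#'
#' Holds an ordered set of chromosome sequences together with a compartment
#' label per chromosome. Compartments are `"nuclear"`, `"mito"` (at most one
#' chromosome) and `"decoy"`; decoy chromosomes stand for environmental,
#' non-target DNA sources and are excluded from the mapping target.
#'
#' @slot sequences A [Biostrings::DNAStringSet] with unique names, A/C/G/T
#'   alphabet only.
#' @slot compartment Character vector parallel to `sequences`, values in
#'   `nuclear`, `mito`, `decoy`.
#' @export
setClass("ReferenceSet",
    representation(sequences = "DNAStringSet", compartment = "character"))

setValidity("ReferenceSet", function(object) {
    n <- length(object@sequences)
    nm <- names(object@sequences)
    if (n == 0L) return("reference has no chromosomes")
    if (is.null(nm) || anyDuplicated(nm)) return("chromosome names must be unique")
    if (length(object@compartment) != n)
        return("one compartment label per chromosome required")
    if (!all(object@compartment %in% c("nuclear", "mito", "decoy")))
        return("compartment must be nuclear, mito or decoy")
    if (sum(object@compartment == "mito") > 1L)
        return("at most one mito chromosome allowed")
    w <- Biostrings::width(object@sequences)
    if (any(w == 0L)) return("empty chromosome sequence")
    bad <- Biostrings::alphabetFrequency(object@sequences, baseOnly = TRUE)[, "other"]
    if (any(bad > 0)) return("sequences must contain only A, C, G, T")
    TRUE
})

#' FragmentLengthModel: mixture model for molecule lengths
#'
#' A finite mixture over length-distribution families. Supported families:
#' `pointMass` (`value`), `shiftedExponential` (`shift`, `scale`, both bp)
#' and `lognormal` (`meanlog`, `sdlog`). Sampled lengths are rounded to
#' integers and clamped to `hardMin`.
#'
#' @slot weights Non-negative mixture weights summing to 1.
#' @slot components List of component descriptions (`family` plus parameters).
#' @slot hardMin Hard minimum length in bp (>= 10).
#' @export
setClass("FragmentLengthModel",
    representation(weights = "numeric", components = "list", hardMin = "integer"))

setValidity("FragmentLengthModel", function(object) {
    if (length(object@weights) != length(object@components))
        return("one weight per component required")
    if (any(object@weights < 0)) return("weights must be non-negative")
    if (abs(sum(object@weights) - 1) > 1e-9) return("weights must sum to 1")
    if (object@hardMin < 10L) return("hard minimum length must be >= 10")
    fams <- vapply(object@components, function(x) x$family, "")
    if (!all(fams %in% c("pointMass", "shiftedExponential", "lognormal")))
        return("unknown component family")
    TRUE
})

#' DegradationParams: parametric single-stranded damage model
#'
#' Position-dependent C->T deamination probability for a molecule of length
#' L at 1-based position i (from the 5' end):
#' \deqn{d(i, L) = (a_5 e^{-\lambda_5 (i-1)} + c)(1 - b_3 e^{-\mu_3 (L-i)})}
#' i.e. a 5'-terminal excess decaying into an interior plateau, suppressed
#' towards the 3' terminus. A flat per-base sequencing error `epsilon` flips
#' any base to a uniformly chosen other base after deamination. No G->A
#' channel exists: a single-stranded protocol reads all deamination as C->T
#' in read orientation.
#'
#' @slot a5 5' terminal excess deamination probability.
#' @slot lambda5 5' decay rate per bp.
#' @slot plateau Interior plateau deamination probability.
#' @slot b3 3' suppression depth in `[0, 1]`.
#' @slot mu3 3' suppression decay rate per bp.
#' @slot epsilon Per-base sequencing error probability.
#' @export
setClass("DegradationParams",
    representation(a5 = "numeric", lambda5 = "numeric", plateau = "numeric",
                   b3 = "numeric", mu3 = "numeric", epsilon = "numeric"))

setValidity("DegradationParams", function(object) {
    p <- c(object@a5, object@plateau, object@b3, object@epsilon)
    if (any(p < 0 | p > 1)) return("probabilities must lie in [0, 1]")
    if (object@lambda5 < 0 || object@mu3 < 0) return("decay rates must be >= 0")
    if (object@a5 + object@plateau > 1)
        return("a5 + plateau must be <= 1 so that d(i, L) <= 1")
    TRUE
})

#' LibrarySimConfig: scenario container for library simulation
#'
#' @slot nReads Number of molecules to emit.
#' @slot endogenousFraction Fraction of raw molecules that are endogenous.
#' @slot contaminantFraction Fraction of human-mapping molecules (endogenous
#'   plus contaminant) that are modern contaminants.
#' @slot mitoShare Share of human-mapping molecules drawn from the
#'   mitochondrial compartment.
#' @slot endoLengths,contLengths,envLengths Fragment length models per source.
#' @slot mitoLengths Fragment length model for human-mapping molecules in
#'   the mitochondrial compartment (defaults to `endoLengths`; mitochondrial
#'   molecules are often somewhat longer than nuclear ones).
#' @slot degradation [DegradationParams-class] for endogenous molecules.
#' @slot contErrorProb Per-base error probability for contaminant reads.
#' @slot envErrorProb Per-base error probability for environmental reads.
#' @slot seed Default seed for [simulateLibrary()] (NA for none).
#' @export
setClass("LibrarySimConfig",
    representation(nReads = "integer", endogenousFraction = "numeric",
                   contaminantFraction = "numeric", mitoShare = "numeric",
                   endoLengths = "FragmentLengthModel",
                   contLengths = "FragmentLengthModel",
                   envLengths = "FragmentLengthModel",
                   mitoLengths = "FragmentLengthModel",
                   degradation = "DegradationParams",
                   contErrorProb = "numeric", envErrorProb = "numeric",
                   seed = "integer"))

setValidity("LibrarySimConfig", function(object) {
    if (object@nReads <= 0L) return("nReads must be > 0")
    fr <- c(object@endogenousFraction, object@contaminantFraction,
            object@mitoShare)
    if (any(fr < 0 | fr > 1)) return("fractions must lie in [0, 1]")
    if (object@contaminantFraction < 1) {
        hf <- object@endogenousFraction / (1 - object@contaminantFraction)
        if (hf > 1 + 1e-9)
            return("endogenousFraction / (1 - contaminantFraction) exceeds 1")
    } else if (object@endogenousFraction > 0) {
        return("endogenousFraction must be 0 when contaminantFraction is 1")
    }
    TRUE
})

#' HairLibrary: a simulated sequencing library with per-read truth
#'
#' @slot sequences Named character vector of read sequences (5'->3' as
#'   sequenced).
#' @slot truth Truth table: one row per read with source, compartment, true
#'   placement, strand, molecule length and deamination event count.
#' @slot config The [LibrarySimConfig-class] used.
#' @slot seed Seed used for generation.
#' @export
setClass("HairLibrary",
    representation(sequences = "character", truth = "data.frame",
                   config = "LibrarySimConfig", seed = "integer"))

setValidity("HairLibrary", function(object) {
    if (length(object@sequences) != nrow(object@truth))
        return("every emitted read needs exactly one truth row")
    if (!identical(names(object@sequences), object@truth$id))
        return("sequence names must match truth ids in order")
    TRUE
})

#' DamageProfile: observed position-specific substitution rates
#'
#' Per-position counts and rates of C->T (on reference-C opportunities) and
#' G->A (reference-G) substitutions, tallied from both the 5' and the 3'
#' read ends. Reads shorter than `2 * positions` contribute the same base
#' to both tallies; their count is recorded in `shortReadOverlap`.
#'
#' @slot positions Number of positions profiled per end.
#' @slot fivePrime,threePrime Data frames with columns `position`,
#'   `cOpportunities`, `ctCount`, `ctRate`, `gOpportunities`, `gaCount`,
#'   `gaRate`.
#' @slot nReads Reads used.
#' @slot mismatches Total mismatch count over all profiled reads.
#' @slot shortReadOverlap Number of reads shorter than `2 * positions`.
#' @export
setClass("DamageProfile",
    representation(positions = "integer", fivePrime = "data.frame",
                   threePrime = "data.frame", nReads = "numeric",
                   mismatches = "numeric", shortReadOverlap = "numeric"))

setValidity("DamageProfile", function(object) {
    for (df in list(object@fivePrime, object@threePrime)) {
        if (any(df$ctCount > df$cOpportunities) ||
            any(df$gaCount > df$gOpportunities))
            return("substitution count exceeds opportunities")
    }
    TRUE
})

#' ContaminationModel: damage curve and error model for the mixture
#'
#' The endogenous component evaluates the C->T probability at each
#' reference-C position from either a parametric [DegradationParams-class]
#' curve or an empirical 5' damage profile (smoothed, interior rate used
#' beyond the profiled positions). The contaminant component has no
#' deamination; both share the flat error probability `epsilon`.
#'
#' @slot type `"parametric"` or `"empirical"`.
#' @slot params [DegradationParams-class] (parametric type).
#' @slot d5 Smoothed empirical per-position 5' damage rates (empirical type).
#' @slot epsilon Per-base error probability.
#' @slot gate Mapper acceptance gate for conditioning: `c(maxMismatch, k)`
#'   when the alignments came from the package's mismatch-gated mapper
#'   (likelihoods are then conditioned on mapping success, removing the
#'   damage-depletion selection bias), or `numeric(0)` for unconditioned
#'   likelihoods (e.g. truth-placed reads).
#' @export
setClass("ContaminationModel",
    representation(type = "character", params = "DegradationParams",
                   d5 = "numeric", epsilon = "numeric", gate = "numeric"))

#' ContaminationEstimate: contaminant-fraction point estimate
#'
#' @slot rho Estimated contaminant fraction in `[0, 1]`.
#' @slot se Standard error (observed Fisher information; one-sided profile
#'   likelihood when the estimate sits on a boundary).
#' @slot loglik Log-likelihood at the optimum.
#' @slot nReads Informative reads used.
#' @slot boundary TRUE when the estimate lies within 1e-4 of 0 or 1.
#' @export
setClass("ContaminationEstimate",
    representation(rho = "numeric", se = "numeric", loglik = "numeric",
                   nReads = "integer", boundary = "logical"))

setValidity("ContaminationEstimate", function(object) {
    if (object@rho < 0 || object@rho > 1) return("rho must lie in [0, 1]")
    if (!is.na(object@se) && object@se < 0) return("se must be >= 0")
    TRUE
})

#' GenotypePanel: biallelic SNP panel with per-individual genotypes
#'
#' Genotype codes count copies of the first (`ref`) allele of each SNP,
#' matching the EIGENSTRAT convention; `NA` encodes missing (EIGENSTRAT 9).
#'
#' @slot snp Data frame: `id`, `chrom` (1..22 convention), `pos`, `ref`,
#'   `alt` (distinct single bases).
#' @slot geno Integer matrix, SNPs x individuals, values 0/1/2/NA.
#' @slot ind Data frame: `id`, `population`.
#' @export
setClass("GenotypePanel",
    representation(snp = "data.frame", geno = "matrix", ind = "data.frame"))

setValidity("GenotypePanel", function(object) {
    if (nrow(object@geno) != nrow(object@snp))
        return("geno rows must match SNP table")
    if (ncol(object@geno) != nrow(object@ind))
        return("geno columns must match individual table")
    v <- object@geno[!is.na(object@geno)]
    if (length(v) && !all(v %in% 0:2)) return("genotype codes must be 0/1/2/NA")
    al <- c(object@snp$ref, object@snp$alt)
    if (!all(al %in% c("A", "C", "G", "T")))
        return("alleles must be single bases")
    if (any(object@snp$ref == object@snp$alt))
        return("ref and alt alleles must differ")
    TRUE
})

#' FStatResult: f-statistic with weighted block-jackknife uncertainty
#'
#' @slot value Full-data estimate.
#' @slot se Weighted block-jackknife standard error.
#' @slot z `value / se`.
#' @slot nSnps SNPs used.
#' @slot nBlocks Jackknife blocks.
#' @slot loo Leave-one-block-out estimates (named by block).
#' @export
setClass("FStatResult",
    representation(value = "numeric", se = "numeric", z = "numeric",
                   nSnps = "integer", nBlocks = "integer", loo = "numeric"))

setValidity("FStatResult", function(object) {
    if (!is.na(object@se) && object@se < 0) return("se must be >= 0")
    if (object@nSnps < 1L) return("nSnps must be >= 1")
    if (any(!is.finite(object@loo))) return("leave-out estimates must be finite")
    TRUE
})

#' PCABasis: principal-component basis fit on a modern panel
#'
#' @slot loadings SNP x PC loading matrix (rownames are SNP ids); each
#'   column's largest-magnitude entry is made positive to fix signs.
#' @slot eigenvalues Variance explained per PC.
#' @slot center Per-SNP genotype means over non-missing individuals.
#' @slot scale Per-SNP scale `sqrt(p (1 - p))` with `p = mean / 2`.
#' @slot scores Individual scores (individuals x PCs) of the fitting panel.
#' @slot snpIds SNP ids retained in the basis (zero-variance SNPs dropped).
#' @slot dropped Number of SNPs dropped at fit time.
#' @export
setClass("PCABasis",
    representation(loadings = "matrix", eigenvalues = "numeric",
                   center = "numeric", scale = "numeric", scores = "matrix",
                   snpIds = "character", dropped = "integer"))

#' PCAProjection: least-squares projection of a sparse sample
#'
#' @slot coordinates Per-PC coordinates of the projected sample.
#' @slot se Per-PC block-jackknife standard error (NA before
#'   [pcaJackknife()]).
#' @slot nSnps Non-missing SNPs used.
#' @slot loo Leave-one-chromosome-out coordinates (chromosomes x PCs), or
#'   NULL before jackknifing.
#' @export
setClass("PCAProjection",
    representation(coordinates = "numeric", se = "numeric", nSnps = "integer",
                   loo = "dataframeOrNULL"))

setValidity("PCAProjection", function(object) {
    if (any(!is.na(object@se) & object@se < 0)) return("SEs must be >= 0")
    TRUE
})
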