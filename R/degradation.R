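#' Construct degradation parameters
#'
#' @param a5 5' terminal excess deamination probability.
#' @param lambda5 5' decay rate per bp.
#' @param plateau Interior plateau deamination probability.
#' @param b3 3' suppression depth in `[0, 1]`.
#' @param mu3 3' suppression decay rate per bp.
#' @param epsilon Per-base sequencing error probability.
#' @return A [DegradationParams-class].
#' @seealso [hairDegradationParams()] for the hair defaults.
#' @export
degradationParams <- function(a5 = 0, lambda5 = 0, plateau = 0, b3 = 0,
                              mu3 = 0, epsilon = 0) {
    new("DegradationParams", a5 = a5, lambda5 = lambda5, plateau = plateau,
        b3 = b3, mu3 = mu3, epsilon = epsilon)
}

#' Default hair degradation parameters
#'
#' `a5 = 0.05`, `lambda5 = 0.5`, `plateau = 0.10`, `b3 = 0.90`,
#' `mu3 = 1.0`, `epsilon = 0.001`. These place the C->T rate at about 15%
#' at the first 5' base, about 10% across the interior plateau, and about
#' 1% at the final 3' base -- the pattern characteristic of sun-exposed,
#' largely single-stranded hair DNA, whose interior damage far exceeds
#' that of typical bone-derived material while its 5' terminal damage is
#' comparatively mild.
#'
#' @return A [DegradationParams-class].
#' @export
hairDegradationParams <- function() {
    degradationParams(a5 = 0.05, lambda5 = 0.5, plateau = 0.10, b3 = 0.90,
                      mu3 = 1.0, epsilon = 0.001)
}

#' Position-dependent deamination probability d(i, L)
#'
#' Vectorised over `position` and `length`.
#'
#' @param params A [DegradationParams-class].
#' @param position 1-based position from the molecule's 5' end.
#' @param length Molecule length L.
#' @return Deamination probability, clamped to `[0, 1]`.
#' @export
damageRate <- function(params, position, length) {
    d <- (params@a5 * exp(-params@lambda5 * (position - 1)) + params@plateau) *
        (1 - params@b3 * exp(-params@mu3 * (length - position)))
    pmin(1, pmax(0, d))
}

#' Apply single-stranded degradation to molecules
#'
#' Each C at molecule position i (1-based from the 5' end) deaminates to T
#' independently with probability `d(i, L)`; afterwards every base flips to
#' a uniformly chosen different base with probability `epsilon`. No G->A
#' channel is applied: in a single-stranded library every strand is read in
#' its own orientation, so all deamination appears as C->T. Length is
#' unchanged.
#'
#' @param molecules Character vector of A/C/G/T molecule sequences.
#' @param params A [DegradationParams-class].
#' @param seed Integer seed.
#' @return List with `reads` (character) and `events` (integer deamination
#'   counts per molecule).
#' @examples
#' applyDegradation("CCCC", hairDegradationParams(), seed = 1)
#' @export
applyDegradation <- function(molecules, params, seed = NULL) {
    validObject(params)
    if (!length(molecules)) return(list(reads = character(), events = integer()))
    withSeed(seed, cpp_degrade(molecules, params@a5, params@lambda5,
                               params@plateau, params@b3, params@mu3,
                               params@epsilon))
}

setMethod("show", "DegradationParams", function(object) {
    cat(sprintf(paste0("DegradationParams: a5=%.3g lambda5=%.3g plateau=%.3g ",
                       "b3=%.3g mu3=%.3g epsilon=%.3g\n"),
                object@a5, object@lambda5, object@plateau, object@b3,
                object@mu3, object@epsilon))
    cat(sprintf("  d(1, 40)=%.3f d(10, 40)=%.3f d(40, 40)=%.3f\n",
                damageRate(object, 1, 40), damageRate(object, 10, 40),
                damageRate(object, 40, 40)))
})
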