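#' Construct a contamination model
#'
#' The endogenous component's C->T probability comes either from a
#' parametric [DegradationParams-class] curve (evaluated at the read's
#' position and length) or from an empirical 5' [DamageProfile-class]
#' (rates smoothed with a 3-position moving average; the last profiled
#' rate extends beyond `P`). The contaminant component is the same model
#' with zero deamination. This is an independent-sites mixture: the
#' hidden-state structure of full single-stranded damage estimators
#' (overhang lengths, contiguous single/double-stranded tracts) is
#' deliberately not modelled.
#'
#' @param damage A [DegradationParams-class] or a [DamageProfile-class].
#' @param epsilon Per-base error probability; defaults to the parametric
#'   model's epsilon, or 0.001 for empirical profiles.
#' @param gate Either `NULL` (no conditioning) or `c(maxMismatch, k)`
#'   describing the mapper whose acceptance rule selected the reads. With
#'   a gate, each component likelihood is divided by the component's
#'   probability of passing the mapper (at most `ceil(maxMismatch * L)`
#'   mismatches and at least one exact k-mer seed), computed exactly per
#'   read by dynamic programming. Without this correction, mapping
#'   preferentially discards damaged endogenous reads and the contaminant
#'   fraction is overestimated.
#' @return A [ContaminationModel-class].
#' @export
contaminationModel <- function(damage, epsilon = NULL, gate = NULL) {
    gate <- if (is.null(gate)) numeric() else as.numeric(gate)
    if (is(damage, "DegradationParams")) {
        new("ContaminationModel", type = "parametric", params = damage,
            d5 = numeric(),
            epsilon = if (is.null(epsilon)) damage@epsilon else epsilon,
            gate = gate)
    } else if (is(damage, "DamageProfile")) {
        r <- damage@fivePrime$ctRate
        sm <- as.numeric(stats::filter(r, rep(1 / 3, 3), sides = 2))
        sm[1] <- mean(r[1:2])
        sm[length(r)] <- mean(r[(length(r) - 1):length(r)])
        new("ContaminationModel", type = "empirical",
            params = degradationParams(), d5 = pmin(1, pmax(0, sm)),
            epsilon = if (is.null(epsilon)) 0.001 else epsilon, gate = gate)
    } else stop("damage must be DegradationParams or DamageProfile")
}

# Endogenous deamination probability at read position i for a read of
# length L, under either model type.
modelDamage <- function(model, position, length) {
    if (model@type == "parametric")
        damageRate(model@params, position, length)
    else
        model@d5[pmin(position, length(model@d5))]
}

#' Per-read component log-likelihoods
#'
#' For each read, the log-likelihood of its bases at reference-C positions
#' (reference oriented to read direction) under the endogenous component
#' (deamination rate `d(i, L)` then error `epsilon`) and the contaminant
#' component (`d = 0`). Exact generative probabilities are used: observed
#' T has probability `d (1 - eps) + (1 - d) eps / 3`, observed C
#' `(1 - d)(1 - eps) + d eps / 3`, any other base `eps / 3`. Non-C
#' reference positions contribute identically to both components and are
#' skipped. Reads without any reference-C position are uninformative
#' (both log-likelihoods 0).
#'
#' @param aln Alignment data frame (mapped reads).
#' @param ref A [ReferenceSet-class].
#' @param model A [ContaminationModel-class].
#' @return Data frame with `id`, `llEndo`, `llCont`, `informative`.
#' @export
readLogLik <- function(aln, ref, model) {
    aln <- aln[aln$mapped, , drop = FALSE]
    if (!nrow(aln)) stop("no mapped reads")
    if (any(aln$length != aln$end - aln$start)) stop("length mismatch")
    slices <- orientedRefSlices(aln, ref)
    rl <- aln$length
    idx <- rep.int(seq_len(nrow(aln)), rl)
    pos <- sequence(rl)
    refb <- unlist(strsplit(slices, "", fixed = TRUE), use.names = FALSE)
    obs <- unlist(strsplit(aln$seq, "", fixed = TRUE), use.names = FALSE)
    isC <- refb == "C"
    eps <- model@epsilon
    d <- modelDamage(model, pos[isC], rl[idx[isC]])
    o <- obs[isC]
    pEndo <- ifelse(o == "T", d * (1 - eps) + (1 - d) * eps / 3,
             ifelse(o == "C", (1 - d) * (1 - eps) + d * eps / 3, eps / 3))
    pCont <- ifelse(o == "T", eps / 3,
             ifelse(o == "C", 1 - eps, eps / 3))
    ridx <- idx[isC]
    lle <- llc <- numeric(nrow(aln))
    if (any(isC)) {
        se <- rowsum(log(pEndo), ridx)
        sc <- rowsum(log(pCont), ridx)
        rows <- as.integer(rownames(se))
        lle[rows] <- se[, 1]
        llc[rows] <- sc[, 1]
    }
    if (length(model@gate) == 2L) {
        # condition each component on the read's probability of passing
        # the mapper's acceptance rule (mismatch ceiling + exact seed)
        allowed <- as.integer(ceiling(model@gate[1] * rl))
        k <- as.integer(model@gate[2])
        qE <- rep(eps, length(refb))
        dAll <- modelDamage(model, pos[isC], rl[idx[isC]])
        qE[isC] <- 1 - ((1 - dAll) * (1 - eps) + dAll * eps / 3)
        qC <- rep(eps, length(refb))
        off <- c(0L, cumsum(rl))
        pE <- cpp_pass_prob(qE, off, allowed, k)
        pC2 <- cpp_pass_prob(qC, off, allowed, k)
        lle <- lle - log(pE)
        llc <- llc - log(pC2)
    }
    data.frame(id = aln$id, llEndo = lle, llCont = llc,
               informative = tabulate(ridx, nbins = nrow(aln)) > 0L,
               stringsAsFactors = FALSE)
}

# Maximise the mixture log-likelihood over rho with golden-section search
# plus a Newton polish; aE/aC are per-read component likelihoods rescaled
# by a common per-read factor (which cancels in the mixture weight).
# `range` may extend beyond [0, 1] (up to where every read's mixture
# density stays positive): per-stratum estimates fitted on an extended
# domain are unbiased around a boundary and cancel when aggregated.
mixtureMLE <- function(aE, aC, tol = 1e-6, range = c(0, 1)) {
    lo <- range[1]
    hi <- range[2]
    up <- aC > aE
    if (lo < 0 && any(up))
        lo <- max(lo, max(-aE[up] / (aC[up] - aE[up])) + 1e-9)
    if (hi > 1 && any(!up & aC < aE))
        hi <- min(hi, min(aE[!up & aC < aE] / (aE - aC)[!up & aC < aE]) - 1e-9)
    lo <- min(lo, 1)
    hi <- max(hi, 0)
    f <- function(rho) sum(log(rho * aC + (1 - rho) * aE))
    opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = tol / 10)
    rho <- opt$maximum
    dd <- aC - aE
    for (i in 1:25) {
        den <- rho * aC + (1 - rho) * aE
        g <- sum(dd / den)
        h <- -sum((dd / den)^2)
        if (h == 0) break
        step <- g / h
        rhoNew <- min(hi, max(lo, rho - step))
        if (abs(rhoNew - rho) < tol / 10) { rho <- rhoNew; break }
        rho <- rhoNew
    }
    # Newton can walk off the optimum at a boundary; keep the better point
    cand <- c(rho, opt$maximum, lo, hi)
    rho <- cand[which.max(vapply(cand, f, 0))]
    list(rho = rho, loglik = f(rho), f = f, lo = lo, hi = hi)
}

# Fit the two-component mixture on one set of reads; SE from observed
# Fisher information, or a one-sided profile-likelihood SE (1/2 unit
# log-likelihood drop towards the interior) at a boundary.
fitMixture <- function(llEndo, llCont, range = c(0, 1)) {
    m <- pmax(llEndo, llCont)
    aE <- exp(llEndo - m)
    aC <- exp(llCont - m)
    fit <- mixtureMLE(aE, aC, range = range)
    rho <- fit$rho
    boundary <- rho < fit$lo + 1e-4 || rho > fit$hi - 1e-4
    if (boundary) {
        target <- fit$loglik - 0.5
        mid <- (fit$lo + fit$hi) / 2
        lo <- if (rho < mid) rho else fit$lo
        hi <- if (rho < mid) fit$hi else rho
        se <- tryCatch({
            r <- uniroot(function(x) fit$f(x) - target,
                         c(lo + 1e-12, hi - 1e-12), tol = 1e-9)$root
            abs(r - rho)
        }, error = function(e) NA_real_)
    } else {
        den <- rho * aC + (1 - rho) * aE
        info <- sum(((aC - aE) / den)^2)
        se <- if (info > 0) 1 / sqrt(info) else NA_real_
    }
    list(rho = rho, se = se, loglik = fit$loglik + sum(m),
         boundary = boundary, lo = fit$lo, hi = fit$hi)
}

#' Estimate the contaminant fraction by likelihood mixture
#'
#' Fits `sum_r log(rho * L_cont,r + (1 - rho) * L_endo,r)` over `rho` in
#' `[0, 1]`.
#'
#' With `method = "stratified"` (the default) the mixture is fitted
#' separately within read-length strata and the per-stratum estimates are
#' combined weighted by read counts. This matters because contaminant
#' molecules are systematically longer than endogenous ones: after any
#' length filter the true contaminant share varies strongly with read
#' length, and a single pooled mixture weight converges to an
#' information-weighted average dominated by long reads rather than to
#' the read fraction. Within a stratum the share is constant, so the
#' per-stratum MLE is consistent and the count-weighted combination
#' estimates the contaminant read fraction. `method = "pooled"` fits the
#' single global weight.
#'
#' The standard error comes from the observed Fisher information (summed
#' in quadrature over strata); when an estimate lies within 1e-4 of a
#' boundary the boundary flag is set and a one-sided profile-likelihood
#' standard error (1/2 log-likelihood unit drop towards the interior) is
#' used instead.
#'
#' @param aln Alignment data frame.
#' @param ref A [ReferenceSet-class].
#' @param model A [ContaminationModel-class]. Defaults to an empirical
#'   model profiled from the same alignments (self-calibration).
#' @param method `"stratified"` or `"pooled"`.
#' @param minReads Minimum number of informative reads (default 100).
#' @param minStratum Lengths with fewer reads than this are pooled into a
#'   single remainder stratum (default 500; large strata keep the
#'   per-stratum finite-sample MLE bias negligible).
#' @return A [ContaminationEstimate-class].
#' @export
estimateContamination <- function(aln, ref, model = NULL,
                                  method = c("stratified", "pooled"),
                                  minReads = 100L, minStratum = 500L) {
    method <- match.arg(method)
    if (is.null(model))
        model <- contaminationModel(substitutionProfile(aln, ref))
    aln <- aln[aln$mapped, , drop = FALSE]
    ll <- readLogLik(aln, ref, model)
    inf <- ll$informative
    if (!any(inf)) stop("all reads uninformative (no reference-C positions)")
    if (sum(inf) < minReads)
        stop("only ", sum(inf), " informative reads; need >= ", minReads)
    if (method == "pooled") {
        fit <- fitMixture(ll$llEndo[inf], ll$llCont[inf])
        return(new("ContaminationEstimate", rho = fit$rho, se = fit$se,
                   loglik = fit$loglik, nReads = as.integer(sum(inf)),
                   boundary = fit$boundary))
    }
    len <- aln$length
    tab <- table(len)
    big <- as.integer(names(tab)[tab >= minStratum])
    stratum <- ifelse(len %in% big, len, -1L)
    n <- length(len)
    rho <- 0
    var <- 0
    loglik <- 0
    # Per-stratum fits use a moderately extended domain: around a true
    # share of 0 (or 1) the [0,1]-clipped per-stratum estimates would all
    # be pushed inward and summing many positive parts biases the
    # aggregate, whereas extended-domain errors are symmetric and cancel;
    # only the final aggregate is clipped. An optimum pinned at an
    # extension cap signals a monotone likelihood (a stratum that is
    # purely one component, where the mixture density is not normalised
    # beyond [0, 1]) and is snapped back to the true boundary.
    for (s in unique(stratum)) {
        rows <- which(stratum == s)
        w <- length(rows) / n
        rowsInf <- rows[inf[rows]]
        if (!length(rowsInf)) next  # no C positions: share unidentifiable,
                                    # contributes the prior weight of 0
        fit <- fitMixture(ll$llEndo[rowsInf], ll$llCont[rowsInf],
                          range = c(-0.5, 1.5))
        rhoS <- fit$rho
        if (fit$hi > 1 && rhoS >= fit$hi - 1e-8) rhoS <- 1
        if (fit$lo < 0 && rhoS <= fit$lo + 1e-8) rhoS <- 0
        rho <- rho + w * rhoS
        var <- var + (w * fit$se)^2
        loglik <- loglik + fit$loglik
    }
    clipped <- rho < 0 || rho > 1
    rho <- min(1, max(0, rho))
    new("ContaminationEstimate", rho = rho, se = sqrt(var), loglik = loglik,
        nReads = as.integer(sum(inf)),
        boundary = clipped || rho < 1e-4 || rho > 1 - 1e-4)
}

setMethod("show", "ContaminationEstimate", function(object) {
    cat(sprintf("Contamination estimate: %.2f%% +/- %.2f%% (n=%d%s)\n",
                100 * object@rho, 100 * object@se, object@nReads,
                if (object@boundary) ", at boundary" else ""))
})
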