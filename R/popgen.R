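#' Per-population allele frequencies
#'
#' Frequency of each SNP's first (ref) allele per population:
#' `sum(codes) / (2 * non-missing individuals)`. Populations with no data
#' at a SNP are NA in the frequency matrix and marked in the mask.
#'
#' @param panel A [GenotypePanel-class].
#' @param populations Populations to include (default: all).
#' @return List with `freq` (SNPs x populations), `n` (non-missing
#'   individual counts) and `mask` (TRUE where a population has no data).
#' @export
alleleFreqs <- function(panel, populations = NULL) {
    pops <- if (is.null(populations)) unique(panel@ind$population)
            else populations
    freq <- matrix(NA_real_, nrow(panel@snp), length(pops),
                   dimnames = list(panel@snp$id, pops))
    nmat <- matrix(0L, nrow(panel@snp), length(pops),
                   dimnames = list(panel@snp$id, pops))
    for (j in seq_along(pops)) {
        cols <- which(panel@ind$population == pops[j])
        if (!length(cols)) stop("empty population: ", pops[j])
        g <- panel@geno[, cols, drop = FALSE]
        nonmiss <- rowSums(!is.na(g))
        freq[, j] <- ifelse(nonmiss > 0, rowSums(g, na.rm = TRUE) / (2 * nonmiss),
                            NA_real_)
        nmat[, j] <- nonmiss
    }
    list(freq = freq, n = nmat, mask = is.na(freq))
}

#' Weighted block jackknife from per-SNP contributions
#'
#' For an estimator that is the mean of per-SNP contributions, computes
#' the full-data estimate, the leave-one-block-out estimates, and the
#' weighted jackknife standard error for unequal block sizes: with
#' `h_k = n / m_k`, pseudo-values `tau_k = h_k theta - (h_k - 1)
#' theta_(-k)` and jackknife mean `theta_J = g theta - sum_k (1 - m_k / n)
#' theta_(-k)`, the variance is `(1 / g) sum_k (tau_k - theta_J)^2 /
#' (h_k - 1)`. With equal block sizes this reduces to the classic
#' delete-one jackknife.
#'
#' @param contrib Numeric vector of per-SNP contributions.
#' @param blocks Block label per contribution (e.g. chromosome).
#' @return List with `theta` (full-data mean), `thetaJack`, `se`, `loo`
#'   (named leave-out estimates), `m` (block sizes).
#' @export
blockJackknife <- function(contrib, blocks) {
    keep <- !is.na(contrib)
    contrib <- contrib[keep]
    blocks <- as.character(blocks[keep])
    n <- length(contrib)
    ub <- unique(blocks)
    g <- length(ub)
    if (g < 2L) stop("need at least 2 blocks")
    m <- vapply(ub, function(b) sum(blocks == b), 0L)
    S <- sum(contrib)
    Sk <- vapply(ub, function(b) sum(contrib[blocks == b]), 0)
    theta <- S / n
    loo <- (S - Sk) / (n - m)
    jk <- jackknifeFromLoo(theta, loo, m)
    list(theta = theta, thetaJack = jk$thetaJack, se = jk$se,
         loo = setNames(loo, ub), m = setNames(m, ub))
}

#' @describeIn blockJackknife Weighted jackknife from a full-data estimate
#'   and leave-one-block-out estimates with block sizes `m`.
#' @param theta Full-data estimate.
#' @param loo Leave-one-block-out estimates.
#' @param m Block sizes (same order as `loo`).
#' @export
jackknifeFromLoo <- function(theta, loo, m) {
    g <- length(loo)
    if (g < 2L) stop("need at least 2 blocks")
    n <- sum(m)
    h <- n / m
    tau <- h * theta - (h - 1) * loo
    thetaJack <- g * theta - sum((1 - m / n) * loo)
    se2 <- sum((tau - thetaJack)^2 / (h - 1)) / g
    list(thetaJack = thetaJack, se = sqrt(se2))
}

fstatFromContrib <- function(contrib, blocks, minSnps, label) {
    usable <- !is.na(contrib)
    nUse <- sum(usable)
    if (nUse < minSnps)
        stop(label, ": only ", nUse, " usable SNPs; need >= ", minSnps)
    jk <- blockJackknife(contrib[usable], blocks[usable])
    z <- if (jk$se > 0) jk$theta / jk$se else
        (if (jk$theta == 0) 0 else Inf * sign(jk$theta))
    new("FStatResult", value = jk$theta, se = jk$se, z = z,
        nSnps = as.integer(nUse), nBlocks = length(jk$loo), loo = jk$loo)
}

#' Outgroup f3 statistic
#'
#' `f3(A, B; O) = mean over usable SNPs of (a - o)(b - o)`, the shared
#' drift of A and B relative to outgroup O -- outgroup mode: no
#' heterozygosity normalisation and no finite-sample bias correction.
#' Standard error by weighted block jackknife over `blocks`.
#'
#' @param a,b,o Per-SNP allele frequencies (same SNP order).
#' @param blocks Block label per SNP (e.g. chromosome).
#' @param minSnps Minimum usable SNPs (default 1000, the conventional
#'   reporting floor; relax for unit-scale inputs).
#' @return An [FStatResult-class].
#' @export
f3Outgroup <- function(a, b, o, blocks, minSnps = 1000L) {
    contrib <- (a - o) * (b - o)
    fstatFromContrib(contrib, blocks, minSnps, "f3")
}

#' f4 statistic
#'
#' `f4(A, B; C, D) = mean over usable SNPs of (a - b)(c - d)`; zero in
#' expectation when (A, B) form a clade relative to (C, D). Jackknife Z
#' with the conventional |Z| > 3 significance rule.
#'
#' @param a,b,c,d Per-SNP allele frequencies.
#' @param blocks Block label per SNP.
#' @param minSnps Minimum usable SNPs (default 1).
#' @return An [FStatResult-class].
#' @export
f4Stat <- function(a, b, c, d, blocks, minSnps = 1L) {
    contrib <- (a - b) * (c - d)
    fstatFromContrib(contrib, blocks, minSnps, "f4")
}

#' Fit a PCA basis on a modern panel
#'
#' Genotypes are standardised per SNP: mean `mu_j` over non-missing
#' individuals, `p_j = mu_j / 2`, scale `s_j = sqrt(p_j (1 - p_j))`;
#' missing entries become 0 after centering (mean imputation). SNPs with
#' zero variance (monomorphic or all-missing) are dropped and counted.
#' The singular value decomposition of the standardised matrix gives SNP
#' loadings, individual scores and eigenvalues; each loading vector's
#' sign is fixed by making its largest-magnitude entry positive.
#'
#' @param panel A [GenotypePanel-class].
#' @param populations Populations used to fit the basis (default: all).
#' @param k Number of PCs to retain.
#' @return A [PCABasis-class].
#' @export
pcaFit <- function(panel, populations = NULL, k = 2L) {
    cols <- if (is.null(populations)) seq_len(nrow(panel@ind))
            else which(panel@ind$population %in% populations)
    if (length(cols) < 2L) stop("need at least 2 individuals")
    if (k > length(cols)) stop("fewer individuals than requested PCs")
    X <- t(panel@geno[, cols, drop = FALSE]) # individuals x SNPs
    mu <- colMeans(X, na.rm = TRUE)
    p <- mu / 2
    s <- sqrt(p * (1 - p))
    obsVar <- apply(X, 2L, function(v) {
        v <- v[!is.na(v)]
        if (length(v) < 2L) 0 else stats::var(v)
    })
    keep <- which(!is.na(s) & s > 0 & obsVar > 0)
    if (!length(keep)) stop("no polymorphic SNPs")
    Z <- sweep(X[, keep, drop = FALSE], 2L, mu[keep], "-")
    Z <- sweep(Z, 2L, s[keep], "/")
    Z[is.na(Z)] <- 0
    sv <- svd(Z, nu = k, nv = k)
    flip <- vapply(seq_len(k), function(j) {
        v <- sv$v[, j]
        sign(v[which.max(abs(v))])
    }, 0)
    V <- sweep(sv$v[, seq_len(k), drop = FALSE], 2L, flip, "*")
    scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                        diag(sv$d[seq_len(k)], k, k), 2L, flip, "*")
    rownames(V) <- panel@snp$id[keep]
    rownames(scores) <- panel@ind$id[cols]
    colnames(V) <- colnames(scores) <- paste0("PC", seq_len(k))
    new("PCABasis", loadings = V,
        eigenvalues = sv$d[seq_len(k)]^2 / (length(cols) - 1),
        center = setNames(mu[keep], panel@snp$id[keep]),
        scale = setNames(s[keep], panel@snp$id[keep]), scores = scores,
        snpIds = panel@snp$id[keep],
        dropped = as.integer(nrow(panel@snp) - length(keep)))
}

#' Least-squares projection onto a PCA basis
#'
#' Restricts the loadings to the sample's non-missing SNPs, standardises
#' the sample's genotype codes with the basis's center and scale (haploid
#' calls as 0/2 diploid codes), and solves the least-squares problem
#' `min_c || x_obs - V_obs c ||^2`.
#'
#' @param codes Genotype codes named by SNP id (0/1/2/NA), e.g. the
#'   `code` column of [pseudoHaploidCall()] named by SNP.
#' @param basis A [PCABasis-class].
#' @param k PCs to project onto (default: all in the basis).
#' @return A [PCAProjection-class] (no SEs; see [pcaJackknife()]).
#' @export
pcaProject <- function(codes, basis, k = ncol(basis@loadings)) {
    if (is.null(names(codes))) stop("codes must be named by SNP id")
    shared <- intersect(basis@snpIds, names(codes)[!is.na(codes)])
    if (length(shared) < k)
        stop("sample shares only ", length(shared),
             " non-missing SNPs with the basis; need >= ", k)
    x <- (as.numeric(codes[shared]) - basis@center[shared]) /
        basis@scale[shared]
    V <- basis@loadings[shared, seq_len(k), drop = FALSE]
    qr. <- qr(V)
    if (qr.$rank < k) stop("rank-deficient restricted loadings")
    coef <- qr.coef(qr., x)
    new("PCAProjection", coordinates = setNames(coef, colnames(V)),
        se = rep(NA_real_, k), nSnps = length(shared), loo = NULL)
}

#' Chromosome-drop jackknife for projected PCA coordinates
#'
#' Leave-one-chromosome-out: the sample is re-projected onto the *fixed*
#' modern basis with each chromosome's SNPs removed in turn; the
#' leave-out coordinates enter the weighted block jackknife with block
#' sizes equal to the sample's non-missing SNP count per chromosome.
#'
#' @param codes Genotype codes named by SNP id.
#' @param basis A [PCABasis-class].
#' @param chrom Chromosome label per basis SNP (named by SNP id, or in
#'   basis SNP order).
#' @param k PCs.
#' @return A [PCAProjection-class] with per-PC standard errors and the
#'   leave-out coordinate table.
#' @export
pcaJackknife <- function(codes, basis, chrom, k = ncol(basis@loadings)) {
    if (is.null(names(chrom))) {
        stopifnot(length(chrom) == length(basis@snpIds))
        names(chrom) <- basis@snpIds
    }
    full <- pcaProject(codes, basis, k)
    shared <- intersect(basis@snpIds, names(codes)[!is.na(codes)])
    ch <- chrom[shared]
    ub <- unique(ch)
    if (length(ub) < 2L)
        stop("sample's informative SNPs span a single chromosome")
    loo <- matrix(NA_real_, length(ub), k,
                  dimnames = list(as.character(ub), paste0("PC", seq_len(k))))
    m <- integer(length(ub))
    for (i in seq_along(ub)) {
        drop <- shared[ch == ub[i]]
        m[i] <- length(drop)
        sub <- codes
        sub[drop] <- NA
        loo[i, ] <- pcaProject(sub, basis, k)@coordinates
    }
    se <- vapply(seq_len(k), function(j)
        jackknifeFromLoo(full@coordinates[j], loo[, j], m)$se, 0)
    new("PCAProjection", coordinates = full@coordinates,
        se = setNames(se, paste0("PC", seq_len(k))), nSnps = full@nSnps,
        loo = as.data.frame(loo))
}

setMethod("show", "FStatResult", function(object) {
    cat(sprintf("f-statistic: %.6g +/- %.3g (Z = %.2f, %d SNPs, %d blocks)\n",
                object@value, object@se, object@z, object@nSnps,
                object@nBlocks))
})

setMethod("show", "PCAProjection", function(object) {
    cat("PCAProjection over", object@nSnps, "SNPs\n")
    for (j in seq_along(object@coordinates))
        cat(sprintf("  %s: %.4f%s\n", names(object@coordinates)[j],
                    object@coordinates[j],
                    if (!is.na(object@se[j]))
                        sprintf(" +/- %.4f", object@se[j]) else ""))
})
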