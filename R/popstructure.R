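## Posterior expected minor-allele dosage given GLs and a per-entry (or
## per-site) Hardy-Weinberg prior frequency.
.posteriorDosage <- function(L0, L1, L2, prior) {
    if (is.matrix(prior)) {
        w0 <- L0 * (1 - prior)^2
        w1 <- L1 * 2 * prior * (1 - prior)
        w2 <- L2 * prior^2
    } else {
        w0 <- L0 * (1 - prior)^2
        w1 <- L1 * (2 * prior * (1 - prior))
        w2 <- L2 * prior^2
    }
    (w1 + 2 * w2) / (w0 + w1 + w2)
}

## Rank choice for the individual-allele-frequency reconstruction: largest
## gap among the leading eigenvalues (an elbow heuristic).
.elbowRank <- function(ev, maxRank = 10L) {
    k <- min(maxRank, length(ev) - 1L)
    if (k < 1L) return(1L)
    gaps <- ev[seq_len(k)] - ev[seq_len(k) + 1L]
    which.max(gaps)
}

#' Iterative individual-allele-frequency PCA from genotype likelihoods
#'
#' Low-coverage PCA in the PCAngsd style. Iteration 0 uses the pooled
#' minor-allele frequency of every site as each individual's prior; each
#' subsequent iteration (i) computes posterior expected dosages under the
#' current per-individual priors, (ii) standardizes them by
#' `sqrt(2 f (1 - f))` around `2 f`, (iii) forms the individual x individual
#' covariance `C = t(X) X / M`, and (iv) rebuilds per-individual site
#' frequencies from the top-`rank` eigenvector reconstruction, clamped to
#' `[1e-4, 1 - 1e-4]`. Iteration stops when `C` changes by less than `tol`
#' in max norm. Sites whose pooled frequency estimate is 0 or 1 are
#' excluded (with a message).
#'
#' @param gl a [GLExperiment-class].
#' @param sites site subset (typically the MAF >= 0.10 pass set).
#' @param individuals individual subset (e.g. outgroup removed).
#' @param nIter maximum iterations.
#' @param tol convergence tolerance on the covariance (max norm).
#' @param rank reconstruction rank; `NULL` picks the largest eigenvalue gap
#'   among the leading 10.
#' @param f optional precomputed pooled minor-allele frequencies aligned
#'   with `sites` (skips the internal EM pass).
#' @return a [PCAResult-class]. Scores are eigenvectors scaled by
#'   `sqrt(eigenvalue)`; loadings are the projections `X' v_k` of the
#'   standardized site vectors on each component.
#' @export
pcaFromGLs <- function(gl, sites = NULL, individuals = NULL,
                       nIter = 100L, tol = 1e-7, rank = NULL, f = NULL) {
    stopifnot(is(gl, "GLExperiment"))
    if (is.null(sites)) sites <- seq_len(nrow(gl))
    sites <- seq_len(nrow(gl))[sites]
    if (is.null(individuals)) individuals <- seq_len(ncol(gl))
    individuals <- seq_len(ncol(gl))[individuals]
    if (length(individuals) < 2 || length(sites) < 2)
        stop("need at least 2 individuals and 2 sites")
    if (is.null(f))
        f <- estimateMAF(gl, sites = sites, individuals = individuals)$altFreq
    stopifnot(length(f) == length(sites))
    bad <- is.na(f) | f <= 0 | f >= 1
    if (any(bad)) {
        message(sum(bad), " site(s) with pooled frequency 0 or 1 excluded")
        sites <- sites[!bad]
        f <- f[!bad]
    }
    lin <- .glLinear(gl, sites, individuals)
    M <- length(sites); N <- length(individuals)
    sd <- sqrt(2 * f * (1 - f))
    eg <- .posteriorDosage(lin$L0, lin$L1, lin$L2, f)
    X <- (eg - 2 * f) / sd
    C <- crossprod(X) / M
    it <- 0L
    e <- if (is.null(rank)) NULL else as.integer(rank)
    repeat {
        it <- it + 1L
        eig <- eigen(C, symmetric = TRUE)
        eUse <- if (is.null(e)) .elbowRank(eig$values) else e
        V <- eig$vectors[, seq_len(eUse), drop = FALSE]
        R <- X %*% V %*% t(V)
        prior <- clamp(f + R * sd / 2, 1e-4, 1 - 1e-4)
        eg <- .posteriorDosage(lin$L0, lin$L1, lin$L2, prior)
        X <- (eg - 2 * f) / sd
        Cnew <- crossprod(X) / M
        delta <- max(abs(Cnew - C))
        C <- Cnew
        if (delta < tol || it >= nIter) break
    }
    eig <- eigen(C, symmetric = TRUE)
    k <- min(N, 10L)
    ev <- eig$values
    pos <- pmax(ev, 0)
    scores <- sweep(eig$vectors[, seq_len(k), drop = FALSE], 2,
                    sqrt(pos[seq_len(k)]), `*`)
    rownames(scores) <- colnames(gl)[individuals]
    loadings <- X %*% eig$vectors[, seq_len(k), drop = FALSE]
    dimnames(C) <- list(colnames(gl)[individuals], colnames(gl)[individuals])
    new("PCAResult", cov = C, eigenvalues = ev, scores = scores,
        vectors = eig$vectors[, seq_len(k), drop = FALSE],
        loadings = loadings, varExplained = pos / sum(pos),
        siteIndex = as.integer(sites), f = as.numeric(f),
        rank = as.integer(if (is.null(e)) .elbowRank(ev) else e),
        nIter = it)
}

## One EM pass for admixture; returns updated Q, F and the log-likelihood of
## the *input* parameters (computed from the same responsibilities).
.admixStep <- function(L0, L1, L2, Q, F) {
    M <- ncol(F); N <- nrow(Q); K <- ncol(Q)
    H <- Q %*% F                      # N x M individual allele frequencies
    Ht <- t(H)                        # M x N, matching the GL layout
    w0 <- L0 * (1 - Ht)^2
    w1 <- L1 * 2 * Ht * (1 - Ht)
    w2 <- L2 * Ht^2
    tot <- w0 + w1 + w2
    ll <- sum(log(tot))
    eg <- (w1 + 2 * w2) / tot         # expected minor dosage, M x N
    Fnew <- matrix(0, K, M)
    Qnew <- matrix(0, N, K)
    for (k in seq_len(K)) {
        ## per-copy attribution of minor/major alleles to ancestry k
        aMin <- t(eg) * (Q[, k] %o% F[k, ]) / H          # N x M
        aMaj <- t(2 - eg) * (Q[, k] %o% (1 - F[k, ])) / (1 - H)
        Fnew[k, ] <- colSums(aMin) / colSums(aMin + aMaj)
        Qnew[, k] <- rowSums(aMin + aMaj) / (2 * M)
    }
    Fnew <- clamp(Fnew, 1e-6, 1 - 1e-6)
    Qnew <- Qnew / rowSums(Qnew)
    list(Q = Qnew, F = Fnew, logLik = ll)
}

#' Admixture proportions from genotype likelihoods by EM
#'
#' Maximizes `sum_ij log sum_g GL_ijg Binom(g; 2, h_ij)` with
#' `h_ij = sum_k Q_ik F_kj` over ancestry proportions `Q` (rows on the
#' simplex) and ancestral allele frequencies `F` (clamped to
#' `[1e-6, 1 - 1e-6]`), using multiple random starts and keeping the best
#' final likelihood. `K = 1` reduces to pooled frequency estimation.
#'
#' @param gl a [GLExperiment-class].
#' @param sites site subset (typically MAF >= 0.10 passes); randomly
#'   downsampled to at most `maxSites` sites using `seed`.
#' @param K number of ancestral components (`K <=` individuals).
#' @param seed integer seed for starts and downsampling.
#' @param individuals individual subset.
#' @param nStarts random restarts.
#' @param maxIter EM iteration cap per start.
#' @param tol convergence: change in log-likelihood below `tol`.
#' @param maxSites site cap (the analysis design downsamples dense SNP
#'   lists; default 2e6).
#' @return an [AdmixtureResult-class].
#' @export
admixtureEM <- function(gl, sites = NULL, K = 2L, seed = 1L,
                        individuals = NULL, nStarts = 5L, maxIter = 200L,
                        tol = 1e-4, maxSites = 2e6) {
    stopifnot(is(gl, "GLExperiment"))
    K <- as.integer(K)
    if (is.null(sites)) sites <- seq_len(nrow(gl))
    sites <- seq_len(nrow(gl))[sites]
    if (is.null(individuals)) individuals <- seq_len(ncol(gl))
    individuals <- seq_len(ncol(gl))[individuals]
    N <- length(individuals)
    if (K < 1L) stop("K must be >= 1")
    if (K > N) stop("K exceeds the number of individuals")
    set.seed(seed)
    if (length(sites) > maxSites) sites <- sort(sample(sites, maxSites))
    lin <- .glLinear(gl, sites, individuals)
    M <- length(sites)
    if (K == 1L) {
        est <- estimateMAF(gl, sites = sites, individuals = individuals)
        F <- matrix(clamp(ifelse(is.na(est$altFreq), 0.5, est$altFreq),
                          1e-6, 1 - 1e-6), 1, M)
        Q <- matrix(1, N, 1)
        ll <- sum(mafLogLik(gl, F[1, ], sites = sites,
                            individuals = individuals))
        return(new("AdmixtureResult", K = 1L, Q = Q, F = F, logLik = ll,
                   nIter = 0L))
    }
    best <- NULL
    for (s in seq_len(nStarts)) {
        Q <- matrix(rgamma(N * K, 1), N, K)
        Q <- Q / rowSums(Q)
        F <- matrix(runif(K * M, 0.05, 0.95), K, M)
        llPrev <- -Inf
        it <- 0L
        repeat {
            it <- it + 1L
            stp <- .admixStep(lin$L0, lin$L1, lin$L2, Q, F)
            Q <- stp$Q; F <- stp$F
            if (is.finite(llPrev) && stp$logLik - llPrev < tol) break
            llPrev <- stp$logLik
            if (it >= maxIter) break
        }
        llFinal <- sum(log(.admixLik(lin, Q, F)))
        if (is.null(best) || llFinal > best$ll)
            best <- list(Q = Q, F = F, ll = llFinal, it = it)
    }
    rownames(best$Q) <- colnames(gl)[individuals]
    new("AdmixtureResult", K = K, Q = best$Q, F = best$F,
        logLik = best$ll, nIter = best$it)
}

.admixLik <- function(lin, Q, F) {
    Ht <- t(Q %*% F)
    lin$L0 * (1 - Ht)^2 + lin$L1 * 2 * Ht * (1 - Ht) + lin$L2 * Ht^2
}

#' Observed-data log-likelihood of an admixture solution
#' @param gl a [GLExperiment-class].
#' @param fit an [AdmixtureResult-class].
#' @param sites,individuals the subsets the fit was computed on.
#' @return the log-likelihood.
#' @export
admixtureLogLik <- function(gl, fit, sites = NULL, individuals = NULL) {
    lin <- .glLinear(gl, sites, individuals)
    sum(log(.admixLik(lin, fit@Q, fit@F)))
}

#' Kinship matrix from genotype likelihoods
#'
#' Average product of standardized centered posterior dosages
#' (`(E[g] - 2 f) / sqrt(2 f (1 - f))`) over a SNP subset — the realized
#' genomic-relationship form of kinship — with sites missing by depth
#' dropped pairwise. Unlike a per-pair correlation, this form retains each
#' individual's dosage magnitude, which is what lets the leading
#' eigenvector resolve the three genotype classes of a haplotype block
#' (heterozygotes and derived homozygotes deviate in the same direction but
#' by different amounts; a correlation would collapse them). Individuals
#' with no covered site in the subset get `NA` rows (reported in the
#' `missing` attribute).
#'
#' @param gl a [GLExperiment-class].
#' @param snpSubset site indices (non-empty).
#' @param individuals individual subset.
#' @return individuals x individuals matrix with attribute `missing`.
#' @export
kinshipFromGLs <- function(gl, snpSubset, individuals = NULL) {
    stopifnot(length(snpSubset) > 0)
    if (is.null(individuals)) individuals <- seq_len(ncol(gl))
    individuals <- seq_len(ncol(gl))[individuals]
    est <- estimateMAF(gl, sites = snpSubset, individuals = individuals)
    f <- ifelse(is.na(est$altFreq) | est$altFreq <= 0 | est$altFreq >= 1,
                0.5, est$altFreq)
    lin <- .glLinear(gl, snpSubset, individuals)
    eg <- .posteriorDosage(lin$L0, lin$L1, lin$L2, f)
    X <- (eg - 2 * f) / sqrt(2 * f * (1 - f))
    Z <- (lin$depth > 0) * 1
    Xm <- X * Z
    S1 <- crossprod(Xm)                 # sum of products over shared sites
    m <- crossprod(Z)                   # shared covered sites per pair
    kin <- S1 / m
    kin[m == 0] <- NA_real_
    noInfo <- colSums(Z) == 0
    kin[noInfo, ] <- NA_real_
    kin[, noInfo] <- NA_real_
    dimnames(kin) <- list(colnames(gl)[individuals],
                          colnames(gl)[individuals])
    attr(kin, "missing") <- colnames(gl)[individuals][noInfo]
    kin
}

#' Callable-site fraction per individual
#'
#' Fraction of sites with depth at least 1, the yardstick used to exclude
#' excessively low-coverage individuals from structure analyses.
#'
#' @param pileup a [PileupExperiment-class] (or [GLExperiment-class] with a
#'   `depth` assay).
#' @return named numeric vector.
#' @export
callableFraction <- function(pileup) {
    d <- if (is(pileup, "PileupExperiment")) pileupDepth(pileup)
         else assay(pileup, "depth")
    colMeans(d > 0)
}

#' Individuals passing the callable-fraction threshold
#' @param pileup see [callableFraction()].
#' @param minFraction minimum callable-site fraction (default 0.10).
#' @return integer indices of retained individuals.
#' @export
filterIndividuals <- function(pileup, minFraction = 0.10) {
    which(callableFraction(pileup) >= minFraction)
}
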