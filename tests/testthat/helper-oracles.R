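suppressMessages({
    library(SummarizedExperiment)
    library(S4Vectors)
})

## ---- independent oracles (kept free of the package's own code paths) ----

## Direct product-form genotype likelihood for one individual's read counts.
oracleGL <- function(nMaj, nMin, nOth, eps) {
    vapply(0:2, function(g) {
        pM <- (1 - g / 2) * (1 - eps) + (g / 2) * (eps / 3)
        pm <- (g / 2) * (1 - eps) + (1 - g / 2) * (eps / 3)
        pM^nMaj * pm^nMin * (eps / 3)^nOth
    }, 0)
}

## Grid-search maximizer of the HWE allele-frequency likelihood.
oracleGridMAF <- function(L0, L1, L2, grid = seq(0, 1, by = 0.001)) {
    ll <- vapply(grid, function(f)
        sum(log(L0 * (1 - f)^2 + L1 * 2 * f * (1 - f) + L2 * f^2)), 0)
    grid[which.max(ll)]
}

## Brute-force sample-allele-frequency likelihood over all 3^n genotype
## vectors, with per-individual binomial weights and hypergeometric
## normalization.
oracleSAF <- function(Lmat) {       # Lmat: n x 3 linear likelihoods
    n <- nrow(Lmat)
    combos <- as.matrix(expand.grid(rep(list(0:2), n)))
    out <- numeric(2 * n + 1)
    for (r in seq_len(nrow(combos))) {
        g <- combos[r, ]
        d <- sum(g)
        w <- prod(choose(2, g)) * prod(Lmat[cbind(seq_len(n), g + 1)])
        out[d + 1] <- out[d + 1] + w
    }
    out / choose(2 * n, 0:(2 * n))
}

## Textbook Tajima's D from sample size, segregating sites and mean pairwise
## difference totals.
oracleTajimaD <- function(n, S, piTotal) {
    a1 <- sum(1 / (1:(n - 1)))
    a2 <- sum(1 / (1:(n - 1))^2)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1
    e2 <- c2 / (a1^2 + a2)
    (piTotal - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

## ---- fixture builders ----

## GLExperiment with exact (deep-coverage) genotypes: dosage matrix is
## sites x individuals.
glFromGenotypes <- function(geno, chrom = "chr1",
                            pos0 = seq_len(nrow(geno)) * 10) {
    M <- nrow(geno); N <- ncol(geno)
    big <- -1000
    ll <- lapply(0:2, function(g) {
        m <- matrix(big, M, N)
        m[geno == g] <- 0
        m
    })
    if (is.null(colnames(geno)))
        colnames(geno) <- sprintf("ind%03d", seq_len(N))
    for (i in 1:3) colnames(ll[[i]]) <- colnames(geno)
    se <- SummarizedExperiment(
        assays = list(ll0 = ll[[1]], ll1 = ll[[2]], ll2 = ll[[3]],
                      depth = matrix(30L, M, N,
                                     dimnames = list(NULL, colnames(geno)))),
        rowData = DataFrame(chrom = rep_len(chrom, M), pos0 = pos0,
                            refBase = rep("A", M), altBase = rep("C", M)),
        colData = DataFrame(individual = colnames(geno),
                            locality = rep("loc01", N),
                            species = rep("ingroup", N),
                            row.names = colnames(geno)))
    new("GLExperiment", se)
}

## Small pileup built directly from count matrices.
pileupFromCounts <- function(nMajor, nMinor, nOther, eps = 0.01) {
    M <- nrow(nMajor); N <- ncol(nMajor)
    ids <- sprintf("ind%03d", seq_len(N))
    se <- SummarizedExperiment(
        assays = list(nMajor = `colnames<-`(nMajor, ids),
                      nMinor = `colnames<-`(nMinor, ids),
                      nOther = `colnames<-`(nOther, ids)),
        rowData = DataFrame(chrom = rep("chr1", M),
                            pos0 = seq_len(M) * 10,
                            refBase = rep("A", M), altBase = rep("C", M),
                            siteClass = rep("private", M)),
        colData = DataFrame(individual = ids,
                            locality = rep("loc01", N),
                            species = rep("ingroup", N),
                            row.names = ids))
    S4Vectors::metadata(se) <- list(baseError = eps)
    new("PileupExperiment", se)
}

## Tiny standard configs used across test files.
tinyConfig <- function(seed = 1, ...) {
    args <- list(nSites = 400, chromLength = 2e5, nLocalities = 3,
                 nPerLocality = 12, nOutgroup = 8, seed = seed)
    args[names(list(...))] <- list(...)
    do.call(SimConfig, args)
}
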