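test_that("PCA on certain GLs equals PCA on the true dosage matrix", {
    set.seed(3)
    M <- 300; N <- 30
    f <- runif(M, 0.1, 0.9)
    g <- matrix(rbinom(M * N, 2, f), M, N)
    poly <- rowMeans(g) / 2 > 0 & rowMeans(g) / 2 < 1
    gl <- glFromGenotypes(g)
    fit <- pcaFromGLs(gl, nIter = 30)
    ## oracle: standardized dosage covariance using the same pooled
    ## frequencies
    fHat <- rowMeans(g[poly, ]) / 2
    X <- (g[poly, ] - 2 * fHat) / sqrt(2 * fHat * (1 - fHat))
    C <- crossprod(X) / nrow(X)
    expect_lt(max(abs(fit@cov - C)), 1e-6)
    ## eigen reconstruction of the covariance
    eig <- eigen(fit@cov, symmetric = TRUE)
    rec <- eig$vectors %*% diag(eig$values) %*% t(eig$vectors)
    expect_lt(max(abs(rec - fit@cov)), 1e-8)
})

test_that("deep species divergence separates on PC1 with zero overlap", {
    cfg <- tinyConfig(seed = 31, nSites = 800, nOutgroup = 12)
    sim <- simulateStudy(cfg)
    gl <- computeGLs(sim$pileup)
    st <- callSnps(gl)
    fit <- pcaFromGLs(gl, sites = which(st$passMaf05 & st$passSnp))
    sp <- colData(sim$pileup)$species
    a <- fit@scores[sp == "ingroup", 1]
    b <- fit@scores[sp == "outgroup", 1]
    expect_true(max(a) < min(b) || max(b) < min(a))
})

test_that("panmictic localities do not separate on leading PCs", {
    cfg <- tinyConfig(seed = 55, nSites = 1500, nLocalities = 5,
                      nPerLocality = 16, nOutgroup = 0, fstTarget = 0)
    sim <- simulateStudy(cfg)
    gl <- computeGLs(sim$pileup)
    st <- callSnps(gl)
    fit <- pcaFromGLs(gl, sites = which(st$passMaf10 & st$passSnp))
    loc <- colData(sim$pileup)$locality
    p <- vapply(1:4, function(k)
        anova(lm(fit@scores[, k] ~ loc))$`Pr(>F)`[1], 0)
    expect_true(all(p > 0.001))
})

test_that("a duplicated individual attains the maximal off-diagonal covariance", {
    set.seed(8)
    g <- matrix(rbinom(4000, 2, runif(200, 0.2, 0.8)), 200, 20)
    g <- cbind(g, g[, 7])  # duplicate
    fit <- pcaFromGLs(glFromGenotypes(g), nIter = 5)
    od <- fit@cov
    diag(od) <- -Inf
    expect_equal(sort(arrayInd(which.max(od), dim(od))), sort(c(7, 21)))
})

test_that("permuting individuals permutes scores and covariance identically", {
    cfg <- tinyConfig(seed = 61, nSites = 500, nOutgroup = 0)
    sim <- simulateStudy(cfg)
    gl <- computeGLs(sim$pileup)
    st <- callSnps(gl)
    sites <- which(st$passMaf10 & st$passSnp)
    fit <- pcaFromGLs(gl, sites = sites, nIter = 10, rank = 1)
    set.seed(1); perm <- sample(ncol(gl))
    fitP <- pcaFromGLs(gl, sites = sites, individuals = perm, nIter = 10,
                       rank = 1)
    expect_equal(fitP@cov, fit@cov[perm, perm], tolerance = 1e-8)
    expect_equal(abs(fitP@scores[, 1]), abs(fit@scores[perm, 1]),
                 tolerance = 1e-6)
})

test_that("admixture EM recovers species split and stays monotone", {
    cfg <- tinyConfig(seed = 41, nSites = 600, nOutgroup = 10)
    sim <- simulateStudy(cfg)
    gl <- computeGLs(sim$pileup)
    st <- callSnps(gl)
    sites <- which(st$passMaf05 & st$passSnp)
    fit <- admixtureEM(gl, sites = sites, K = 2, seed = 5, nStarts = 2,
                       maxIter = 80)
    sp <- colData(sim$pileup)$species
    ## each species is nearly pure in its own cluster
    qOut <- fit@Q[sp == "outgroup", ]
    col <- which.max(colMeans(qOut))
    expect_gt(mean(qOut[, col]), 0.95)
    expect_lt(mean(fit@Q[sp == "ingroup", col]), 0.05)
    expect_true(all(abs(rowSums(fit@Q) - 1) < 1e-9))

    ## log-likelihood non-decreasing along EM iterations
    lls <- vapply(c(1, 2, 4, 8, 16, 32), function(it)
        admixtureEM(gl, sites = sites[1:200], K = 2, seed = 7,
                    nStarts = 1, maxIter = it, tol = 0)@logLik, 0)
    expect_true(all(diff(lls) > -1e-6))
})

test_that("K = 1 admixture equals pooled frequency estimation", {
    cfg <- tinyConfig(seed = 47, nSites = 300, nOutgroup = 0)
    sim <- simulateStudy(cfg)
    gl <- computeGLs(sim$pileup)
    fit <- admixtureEM(gl, K = 1)
    expect_true(all(fit@Q == 1))
    est <- estimateMAF(gl)
    ok <- !est$missing
    expect_equal(as.numeric(fit@F[1, ok]),
                 clamp(est$altFreq[ok], 1e-6, 1 - 1e-6), tolerance = 1e-4)
    expect_equal(fit@logLik, sum(panmixGL:::mafLogLik(gl, fit@F[1, ])),
                 tolerance = 1e-6)
})

test_that("admixture errors when K exceeds the number of individuals", {
    gl <- glFromGenotypes(matrix(rbinom(40, 2, 0.5), 10, 4))
    expect_error(admixtureEM(gl, K = 5), "exceeds")
})

test_that("panmictic data show no locality-aligned admixture clusters", {
    cfg <- tinyConfig(seed = 71, nSites = 800, nLocalities = 5,
                      nPerLocality = 14, nOutgroup = 0, fstTarget = 0)
    sim <- simulateStudy(cfg)
    gl <- computeGLs(sim$pileup)
    st <- callSnps(gl)
    for (K in 2:3) {
        fit <- admixtureEM(gl, sites = which(st$passMaf10 & st$passSnp),
                           K = K, seed = 3, nStarts = 2, maxIter = 60)
        loc <- colData(sim$pileup)$locality
        q <- fit@Q[, 1]
        within <- mean(tapply(q, loc, var))
        between <- var(tapply(q, loc, mean))
        expect_lt(between / within, 2)
    }
})

test_that("kinship is maximal for identical genotype vectors and near zero for independents", {
    set.seed(17)
    ## 60 individuals: the -1/(N-1) sample-centering bias stays small
    g <- matrix(rbinom(60000, 2, runif(1000, 0.2, 0.8)), 1000, 60)
    g[, 2] <- g[, 1]
    kin <- kinshipFromGLs(glFromGenotypes(g), snpSubset = 1:1000)
    ## identical vectors: the pair term equals both self terms exactly and
    ## sits near 1 (the standardized-dosage variance), the row maximum
    expect_equal(kin[1, 2], kin[1, 1], tolerance = 1e-9)
    expect_equal(kin[1, 2], kin[2, 2], tolerance = 1e-9)
    expect_lt(abs(kin[1, 2] - 1), 0.15)
    offRow <- kin[1, -c(1, 2)]
    expect_true(all(kin[1, 2] > offRow))
    off <- kin[upper.tri(kin)]
    off <- off[off < 0.5]    # drop the engineered duplicate pair
    expect_lt(mean(abs(off)), 0.05)
})

test_that("kinship recovers inversion genotype classes", {
    cfg <- SimConfig(nSites = 1500, chromLength = 1e6, nLocalities = 5,
                     nPerLocality = 30, nOutgroup = 0,
                     inversionSpan = c(2e5, 8e5), inversionFreq = 0.35,
                     meanDepth = 1.4, seed = 29)
    sim <- simulateStudy(cfg)
    gl <- computeGLs(sim$pileup)
    rd <- rowData(sim$pileup)
    inv <- which(rd$siteClass == "inversion" & sim$truth@invDiffSite)
    kin <- kinshipFromGLs(gl, snpSubset = inv)
    cls <- sim$truth@inversionGenotype
    within <- function(a) {
        ia <- which(cls == a)
        mean(kin[ia, ia][upper.tri(kin[ia, ia])])
    }
    between <- function(a, b)
        mean(kin[which(cls == a), which(cls == b)])
    ## the two homozygote classes are each more self-similar than they are
    ## to any other class
    for (a in c("hap1/hap1", "hap2/hap2"))
        for (b in setdiff(unique(cls), a))
            expect_gt(within(a), between(a, b))
    ## heterozygotes sit between the extremes: more self-similar than the
    ## two homozygote classes are to each other
    expect_gt(within("hap1/hap2"), between("hap1/hap1", "hap2/hap2"))
})

test_that("individuals with no informative sites get flagged missing kinship", {
    g <- matrix(rbinom(200, 2, 0.5), 20, 10)
    gl <- glFromGenotypes(g)
    d <- assay(gl, "depth")
    d[, 3] <- 0L
    ll0 <- assay(gl, "ll0"); ll0[, 3] <- 0
    ll1 <- assay(gl, "ll1"); ll1[, 3] <- 0
    ll2 <- assay(gl, "ll2"); ll2[, 3] <- 0
    se <- SummarizedExperiment(
        assays = list(ll0 = ll0, ll1 = ll1, ll2 = ll2, depth = d),
        rowData = rowData(gl), colData = colData(gl))
    kin <- kinshipFromGLs(new("GLExperiment", se), snpSubset = 1:20)
    expect_true(all(is.na(kin[3, ])))
    expect_equal(attr(kin, "missing"), colnames(gl)[3])
})

test_that("low-coverage individuals are excluded by callable fraction", {
    cfg <- tinyConfig(seed = 9, nSites = 300, meanDepth = 1.4)
    sim <- simulateStudy(cfg)
    pe <- sim$pileup
    ## zero out most sites of individual 5
    nM <- assay(pe, "nMajor"); nm <- assay(pe, "nMinor")
    no <- assay(pe, "nOther")
    kill <- seq_len(floor(0.95 * nrow(pe)))
    nM[kill, 5] <- 0L; nm[kill, 5] <- 0L; no[kill, 5] <- 0L
    se <- SummarizedExperiment(
        assays = list(nMajor = nM, nMinor = nm, nOther = no),
        rowData = rowData(pe), colData = colData(pe))
    pe2 <- new("PileupExperiment", se)
    keep <- filterIndividuals(pe2, minFraction = 0.10)
    expect_false(5 %in% keep)
    expect_true(all(setdiff(1:ncol(pe2), 5) %in% keep))
})
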