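test_that("outgroup consensus takes the majority allele, N on ties", {
    nM <- rbind(c(5L, 3L), c(0L, 0L), c(2L, 2L), c(0L, 4L))
    nm <- rbind(c(0L, 0L), c(3L, 1L), c(2L, 2L), c(5L, 4L))
    pe <- pileupFromCounts(nM, nm, matrix(0L, 4, 2))
    cons <- outgroupConsensus(pe, 1:2)
    expect_equal(cons, c("ref", "alt", "N", "alt"))
    ## zero coverage -> N
    pe0 <- pileupFromCounts(matrix(0L), matrix(0L), matrix(0L))
    expect_equal(outgroupConsensus(pe0, 1), "N")
})

test_that("consensus recovers the true ancestral allele without divergence", {
    cfg <- SimConfig(nSites = 2000, chromLength = 1e6, nLocalities = 2,
                     nPerLocality = 5, nOutgroup = 30,
                     divergenceMafShift = 0, outgroupFixedFraction = 0,
                     outgroupSharedFraction = 0, outgroupPrivateFraction = 0,
                     meanDepth = 1.4, seed = 3)
    sim <- simulateStudy(cfg)
    og <- which(colData(sim$pileup)$species == "outgroup")
    cons <- outgroupConsensus(sim$pileup, og)
    depth <- rowSums(pileupDepth(sim$pileup)[, og])
    deep <- depth >= 5
    ## the outgroup is fixed ancestral here, so the consensus should be the
    ## reference at essentially every well-covered site
    expect_gt(mean(cons[deep] == "ref"), 0.99)
})

test_that("consensus FASTA places bases at the simulated coordinates", {
    nM <- matrix(c(5L, 0L), 2, 1); nm <- matrix(c(0L, 5L), 2, 1)
    pe <- pileupFromCounts(nM, nm, matrix(0L, 2, 1))
    cons <- outgroupConsensus(pe, 1)
    path <- tempfile(fileext = ".fa")
    writeConsensusFasta(cons, pe, chromLength = 50, path = path)
    seq <- Biostrings::readDNAStringSet(path)
    s <- as.character(seq[[1]])
    rd <- rowData(pe)
    expect_equal(substr(s, rd$pos0[1] + 1, rd$pos0[1] + 1), "A")
    expect_equal(substr(s, rd$pos0[2] + 1, rd$pos0[2] + 1), "C")
    expect_equal(nchar(gsub("N", "", s)), 2L)
})

test_that("depth filters keep sites inside inclusive bounds", {
    d <- c(14L, 15L, 500L, 1000L, 1001L)
    nM <- matrix(d, 5, 1)
    pe <- pileupFromCounts(nM, matrix(0L, 5, 1), matrix(0L, 5, 1))
    expect_equal(siteFilters(pe), c(2L, 3L, 4L))
    ## all within bounds -> identity
    pe2 <- pileupFromCounts(matrix(20L, 3, 1), matrix(0L, 3, 1),
                            matrix(0L, 3, 1))
    expect_equal(siteFilters(pe2), 1:3)
})

test_that("sample-allele-frequency likelihoods match brute-force enumeration", {
    ## certain small cases
    gl <- glFromGenotypes(matrix(1, 1, 1))      # n = 1, certain het
    saf <- safPerSite(gl, ancestral = "ref")
    expect_equal(which.max(saf$logSaf[1, ]), 2L)  # d = 1
    expect_lt(max(saf$logSaf[1, -2]), -100)

    gl2 <- glFromGenotypes(matrix(c(1, 2), 1, 2))  # het + hom-derived
    saf2 <- safPerSite(gl2, ancestral = "ref")
    expect_equal(which.max(saf2$logSaf[1, ]), 4L)  # d = 3

    ## random small instances vs the 3^n enumeration oracle
    set.seed(11)
    for (rep in 1:25) {
        n <- sample(1:3, 1)
        depth <- rpois(n, 2)
        g <- rbinom(n, 2, 0.5)
        eps <- 0.05
        nM <- rbinom(n, depth, (1 - g / 2) * (1 - eps) + (g / 2) * eps / 3)
        pe <- pileupFromCounts(matrix(nM, 1), matrix(depth - nM, 1),
                               matrix(0L, 1, n), eps = eps)
        gl <- computeGLs(pe)
        saf <- safPerSite(gl, ancestral = "ref")
        Lmat <- cbind(exp(assay(gl, "ll0")[1, ]),
                      exp(assay(gl, "ll1")[1, ]),
                      exp(assay(gl, "ll2")[1, ]))
        want <- oracleSAF(Lmat)
        want <- log(want) - max(log(want))
        expect_equal(saf$logSaf[1, ], want, tolerance = 1e-9)
    }
})

test_that("flipped ancestral orientation counts derived alleles", {
    ## hom-reference individual at a site whose ancestral allele is the
    ## alternative base: derived count must be 2
    gl <- glFromGenotypes(matrix(0, 1, 1))
    saf <- safPerSite(gl, ancestral = "alt")
    expect_equal(which.max(saf$logSaf[1, ]), 3L)
    ## ancestral N skips the site
    saf2 <- safPerSite(glFromGenotypes(matrix(0, 2, 1)),
                       ancestral = c("N", "ref"))
    expect_equal(length(saf2$siteIndex), 1L)
})

test_that("SFS EM equals direct counting on certain genotypes", {
    set.seed(19)
    n <- 5
    g <- matrix(rbinom(n * 400, 2, runif(400, 0.1, 0.9)), 400, n)
    gl <- glFromGenotypes(g)
    saf <- safPerSite(gl, ancestral = rep("ref", 400))
    sfs <- sfsEM(saf)
    want <- tabulate(rowSums(g) + 1, nbins = 2 * n + 1) / 400
    expect_equal(sfs$probs, want, tolerance = 1e-3)
    expect_equal(sum(sfs$counts), 400, tolerance = 1e-6)
    expect_true(all(sfs$probs >= 0))
})

test_that("SFS EM recovers a neutral 1/d spectrum from deep data", {
    set.seed(29)
    n <- 20
    M <- 50000
    w <- 1 / (1:(2 * n - 1))
    d <- sample(1:(2 * n - 1), M, replace = TRUE, prob = w / sum(w))
    ## draw genotype configurations consistent with each d by sampling
    ## alleles without replacement across individuals
    g <- matrix(0L, M, n)
    for (i in seq_len(M)) {
        alleles <- sample(c(rep(1L, d[i]), rep(0L, 2 * n - d[i])))
        g[i, ] <- alleles[seq_len(n)] + alleles[n + seq_len(n)]
    }
    gl <- glFromGenotypes(g)
    saf <- safPerSite(gl, ancestral = rep("ref", M))
    sfs <- sfsEM(saf)
    target <- (w / sum(w))
    got <- sfs$probs[2:(2 * n)]
    rel <- abs(got[1:10] - target[1:10]) / target[1:10]
    expect_true(all(rel < 0.1))
})

test_that("Tajima's D agrees with the textbook constants to 1e-9", {
    ## classic worked example: 10 sequences, 16 segregating sites, mean
    ## pairwise difference 3.888889
    expect_equal(tajimasD(10, 16, 3.888889),
                 oracleTajimaD(10, 16, 3.888889), tolerance = 1e-9)
    set.seed(5)
    for (i in 1:20) {
        n <- sample(4:60, 1)
        S <- sample(5:200, 1)
        piT <- runif(1, 0.2, 1.5) * S / sum(1 / (1:(n - 1)))
        expect_equal(tajimasD(n, S, piT), oracleTajimaD(n, S, piT),
                     tolerance = 1e-9)
    }
    expect_true(is.na(tajimasD(10, 0, 0)))
})

test_that("windowed theta_pi equals direct pairwise difference on certain data", {
    set.seed(23)
    n <- 6
    M <- 200
    g <- matrix(rbinom(n * M, 2, runif(M, 0.1, 0.9)), M, n)
    gl <- glFromGenotypes(g, pos0 = seq_len(M) * 20)
    saf <- safPerSite(gl, ancestral = rep("ref", M))
    sfs <- sfsEM(saf)
    wd <- windowThetas(saf, sfs, windowBp = 1e6)  # one window
    ## direct average pairwise difference per site
    d <- rowSums(g)
    piDirect <- mean(d * (2 * n - d) / choose(2 * n, 2))
    expect_equal(wd$thetaPi[1], piDirect, tolerance = 1e-6)
    ## monomorphic window: both thetas 0, D missing
    gMono <- matrix(0, 50, n)
    glM <- glFromGenotypes(gMono, pos0 = seq_len(50) * 10)
    safM <- safPerSite(glM, ancestral = rep("ref", 50))
    wdM <- windowThetas(safM, sfsEM(safM), windowBp = 1e6)
    expect_lt(wdM$thetaPi[1], 1e-6)
    expect_true(is.na(wdM$tajimaD[1]) || abs(wdM$tajimaD[1]) < 0.1)
})

test_that("folding the unfolded spectrum is consistent", {
    p <- c(0.1, 0.2, 0.3, 0.25, 0.15)     # 2n = 4
    f <- foldSFS(p)
    expect_equal(sum(f), 1)
    expect_equal(f, c(0.1 + 0.15, 0.2 + 0.25, 0.3))
})

test_that("the outgroup sweep region loses diversity, the ingroup does not", {
    cfg <- SimConfig(nSites = 3000, chromLength = 1e6, nLocalities = 3,
                     nPerLocality = 12, nOutgroup = 20,
                     inversionSpan = c(4e5, 6e5), inversionFreq = 0.29,
                     outgroupInversionFreq = 0.98, meanDepth = 4, seed = 59)
    sim <- simulateStudy(cfg)
    gl <- computeGLs(sim$pileup)
    sp <- colData(sim$pileup)$species
    anc <- rep("ref", nrow(gl))
    for (who in c("outgroup", "ingroup")) {
        ids <- which(sp == who)
        saf <- safPerSite(gl, anc, individuals = ids)
        sfs <- sfsEM(saf)
        wd <- windowThetas(saf, sfs, windowBp = 5000)
        inReg <- wd$winStart0 >= 4e5 & wd$winEnd0 <= 6e5
        ratio <- median(wd$thetaPi[inReg], na.rm = TRUE) /
            median(wd$thetaPi[!inReg], na.rm = TRUE)
        ## the residual 2% non-swept haplotypes set the floor of regional
        ## diversity in the outgroup (~2*0.02*0.98 times the ~0.95
        ## hap1-hap2 divergence, plus sparse young mutations, against a
        ## genome median of ~0.15); the ingroup block (two diverged
        ## haplotypes at intermediate frequency) is not depressed at all
        if (who == "outgroup") expect_lt(ratio, 0.35)
        else expect_gt(ratio, 0.5)
    }
})
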