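test_that("region SNP selection keeps the top fraction with positional ties", {
    m <- 300
    tr <- DataFrame(chrom = rep("chr1", m), pos0 = seq_len(m) * 100,
                    site = seq_len(m), stat = rep(1, m),
                    pvalue = rep(0.5, m))
    idx <- selectRegionSNPs(tr, "chr1", 0, 100 * m + 1, topFraction = 0.10)
    expect_equal(length(idx), 30L)
    expect_equal(idx, 1:30)  # uniform stats: earliest positions win
    ## topFraction = 1 is the identity
    expect_equal(selectRegionSNPs(tr, "chr1", 0, 100 * m + 1, 1),
                 seq_len(m))
    ## minimum 20 enforced
    expect_equal(length(selectRegionSNPs(tr, "chr1", 0, 100 * m + 1,
                                         0.01)), 20L)
    expect_error(selectRegionSNPs(tr, "chr1", 0, 500), "overlaps only")
})

test_that("selected SNPs concentrate on inversion-differentiating sites", {
    cfg <- SimConfig(nSites = 2500, chromLength = 1e6, nLocalities = 5,
                     nPerLocality = 30, nOutgroup = 0,
                     inversionSpan = c(4e5, 6e5), inversionFreq = 0.29,
                     seed = 73)
    sim <- simulateStudy(cfg)
    gl <- computeGLs(sim$pileup)
    st <- callSnps(gl)
    sc <- pcSelectionScan(gl, sites = which(st$passMaf10 & st$passSnp))
    idx <- selectRegionSNPs(sc, "chr1", 4e5, 6e5)
    sel <- sc$site[idx]
    expect_gte(mean(sim$truth@invDiffSite[sel]), 0.9)
})

test_that("kinship clustering genotypes the inversion accurately", {
    cfg <- SimConfig(nSites = 4000, chromLength = 2e6, nLocalities = 10,
                     nPerLocality = 40, nOutgroup = 0,
                     inversionSpan = c(0.9e6, 1.1e6), inversionFreq = 0.29,
                     meanDepth = 1.4, seed = 79)
    sim <- simulateStudy(cfg)
    gl <- computeGLs(sim$pileup)
    st <- callSnps(gl)
    sc <- pcSelectionScan(gl, sites = which(st$passMaf10 & st$passSnp))
    idx <- selectRegionSNPs(sc, "chr1", 0.9e6, 1.1e6, topFraction = 0.5)
    region <- sc$site[idx]
    kin <- kinshipFromGLs(gl, region)
    cs <- clusterThreeGroups(kin, gl, region, chrom = "chr1",
                             start0 = 0.9e6, end0 = 1.1e6)
    truthMap <- c(`hap1/hap1` = "hom1", `hap1/hap2` = "het",
                  `hap2/hap2` = "hom2")
    want <- truthMap[sim$truth@inversionGenotype]
    assigned <- cs@group != "unassigned"
    expect_gt(mean(assigned), 0.95)
    acc <- mean(cs@group[assigned] == want[assigned])
    expect_gte(acc, 0.99)
    ## het frequency consistent with HWE at the recovered frequency
    fHat <- cs@hap2FreqOverall
    expect_lt(abs(fHat - 0.29), 0.06)
    nHet <- sum(cs@group == "het")
    nAss <- sum(assigned)
    expect_gte(nHet, qbinom(0.005, nAss, 2 * 0.29 * 0.71))
    expect_lte(nHet, qbinom(0.995, nAss, 2 * 0.29 * 0.71))
    ## plugging truth genotypes in place of GLs reproduces the simulated
    ## frequency within binomial error
    hap2 <- c(`hap1/hap1` = 0, `hap1/hap2` = 1, `hap2/hap2` = 2)
    fTruth <- sum(hap2[sim$truth@inversionGenotype]) /
        (2 * length(sim$truth@inversionGenotype))
    expect_lt(abs(fHat - fTruth), 0.03)
})

test_that("cluster labels are invariant to individual order", {
    cfg <- SimConfig(nSites = 1500, chromLength = 1e6, nLocalities = 3,
                     nPerLocality = 30, nOutgroup = 0,
                     inversionSpan = c(3e5, 7e5), inversionFreq = 0.35,
                     seed = 83)
    sim <- simulateStudy(cfg)
    gl <- computeGLs(sim$pileup)
    rd <- rowData(sim$pileup)
    region <- which(rd$siteClass == "inversion" & sim$truth@invDiffSite)
    kin <- kinshipFromGLs(gl, region)
    cs <- clusterThreeGroups(kin, gl, region)
    set.seed(2); perm <- sample(ncol(gl))
    kinP <- kinshipFromGLs(gl, region, individuals = perm)
    csP <- clusterThreeGroups(kinP, gl, region, individuals = perm)
    expect_equal(csP@group, cs@group[perm])
})

test_that("indistinguishable clusters leave everyone unassigned with a warning", {
    g <- matrix(rbinom(600, 2, 0.5), 30, 20)
    g[, ] <- 0  # everyone an identical homozygote
    gl <- glFromGenotypes(g)
    kin <- suppressWarnings(kinshipFromGLs(gl, 1:30))
    expect_warning(cs <- clusterThreeGroups(kin, gl, 1:30),
                   "unassigned")
    expect_true(all(cs@group == "unassigned"))
})

test_that("windowed dosage profiles band inside the region and collapse outside", {
    cfg <- SimConfig(nSites = 3000, chromLength = 1e6, nLocalities = 3,
                     nPerLocality = 40, nOutgroup = 0,
                     inversionSpan = c(4e5, 6e5), inversionFreq = 0.35,
                     meanDepth = 4, seed = 89)
    sim <- simulateStudy(cfg)
    gl <- computeGLs(sim$pileup)
    prof <- windowedDosageProfiles(gl, chrom = "chr1", window = 100,
                                   step = 10)
    mid <- prof$windows$startPos0 >= 4.2e5 & prof$windows$endPos0 <= 5.8e5
    out <- prof$windows$endPos0 < 3e5 | prof$windows$startPos0 > 7e5
    cls <- sim$truth@inversionGenotype
    sep <- function(w) {
        m <- colMeans(prof$profile[w, , drop = FALSE])
        gm <- tapply(m, cls, mean)
        gv <- mean(tapply(m, cls, var))
        var(gm) / gv
    }
    expect_gt(sep(mid), 10 * sep(out))
    ## identical individuals give all-zero profiles
    g0 <- matrix(1, 300, 10)
    p0 <- windowedDosageProfiles(glFromGenotypes(g0), window = 100,
                                 step = 10)
    expect_lt(max(abs(p0$profile)), 1e-9)
})

test_that("window mean of a constant dosage equals that dosage", {
    ## one hom-alt individual among hom-ref: its centered track is
    ## 2 - cohort mean within every window
    g <- cbind(matrix(0, 200, 9), 2)
    prof <- windowedDosageProfiles(glFromGenotypes(g), window = 50,
                                   step = 25)
    expect_equal(unname(prof$profile[, 10]), rep(2 - 0.2, nrow(prof$profile)),
                 tolerance = 1e-9)
})

test_that("hap2 homozygotes show more negative regional Tajima's D", {
    cfg <- SimConfig(nSites = 2500, chromLength = 1e6, nLocalities = 5,
                     nPerLocality = 30, nOutgroup = 0,
                     inversionSpan = c(3e5, 7e5), inversionFreq = 0.35,
                     meanDepth = 2, seed = 97)
    sim <- simulateStudy(cfg)
    gl <- computeGLs(sim$pileup)
    rd <- rowData(sim$pileup)
    region <- which(rd$siteClass == "inversion" & sim$truth@invDiffSite)
    kin <- kinshipFromGLs(gl, region)
    cs <- clusterThreeGroups(kin, gl, region, chrom = "chr1",
                             start0 = 3e5, end0 = 7e5)
    anc <- rep("ref", nrow(gl))
    d1 <- groupTajimasD(gl, cs, "hom1", anc)
    d2 <- groupTajimasD(gl, cs, "hom2", anc)
    expect_lt(mean(d2$tajimaD, na.rm = TRUE), mean(d1$tajimaD, na.rm = TRUE))
    ## identical haplotype sets give equal D
    gEq <- matrix(rbinom(3000, 2, runif(150, 0.2, 0.8)), 150, 20)
    glEq <- glFromGenotypes(gEq, pos0 = seq_len(150) * 10)
    csEq <- new("HaplotypeCallSet", chrom = "chr1", start0 = 0,
                end0 = 2000, snpIndex = 1:150,
                group = rep(c("hom1", "hom2"), each = 10),
                meanDosage = numeric(20), locality = rep("loc01", 20),
                hap2Freq = c(loc01 = 0.5), hap2FreqOverall = 0.5)
    csEq@group <- rep(c("hom1", "hom2"), each = 10)
    e1 <- groupTajimasD(glEq, csEq, "hom1", rep("ref", 150))
    gl2 <- glFromGenotypes(gEq[, c(11:20, 1:10)], pos0 = seq_len(150) * 10)
    e2 <- groupTajimasD(gl2, csEq, "hom2", rep("ref", 150))
    expect_equal(e1$tajimaD, e2$tajimaD, tolerance = 1e-9)
    expect_error(groupTajimasD(glEq, csEq, "het", rep("ref", 150)),
                 "fewer than 4")
})

test_that("the homogeneity test matches the standard Pearson statistic", {
    ## hand-checkable two-locality table
    cs <- new("HaplotypeCallSet", chrom = "chr1", start0 = 0, end0 = 1,
              snpIndex = 1L,
              group = c(rep("hom2", 15), rep("hom1", 35),
                        rep("hom2", 30), rep("hom1", 20)),
              meanDosage = numeric(100),
              locality = rep(c("locA", "locB"), each = 50),
              hap2Freq = c(locA = 0.3, locB = 0.6),
              hap2FreqOverall = 0.45)
    res <- frequencyHomogeneityTest(cs)
    expect_equal(unname(res$table[, "hap2"]), c(30, 60))
    expect_equal(res$statistic,
                 unname(chisq.test(res$table, correct = FALSE)$statistic),
                 tolerance = 1e-9)
    expect_equal(res$statistic, 18.18182, tolerance = 1e-4)
    expect_equal(res$pvalue, 2.007866e-05, tolerance = 1e-4)
    expect_equal(res$df, 1L)

    ## identical counts across 10 localities: statistic 0, df 9, p 1
    grp <- rep(c(rep("hom2", 10), rep("het", 20), rep("hom1", 10)), 10)
    loc <- rep(sprintf("loc%02d", 1:10), each = 40)
    cs2 <- new("HaplotypeCallSet", chrom = "chr1", start0 = 0, end0 = 1,
               snpIndex = 1L, group = grp, meanDosage = numeric(400),
               locality = loc, hap2Freq = setNames(rep(0.5, 10),
                                                   unique(loc)),
               hap2FreqOverall = 0.5)
    res2 <- frequencyHomogeneityTest(cs2)
    expect_equal(res2$statistic, 0)
    expect_equal(res2$df, 9L)
    expect_equal(res2$pvalue, 1)
})

test_that("panmictic inversion frequencies give null-uniform homogeneity p", {
    ## small replicate sweep: p should span the unit interval, median near
    ## 0.5 rather than piling near 0
    ps <- vapply(c(3, 17, 23), function(sd) {
        cfg <- SimConfig(nSites = 1200, chromLength = 1e6, nLocalities = 10,
                         nPerLocality = 20, nOutgroup = 0,
                         inversionSpan = c(3e5, 7e5), inversionFreq = 0.29,
                         meanDepth = 2, seed = sd)
        sim <- simulateStudy(cfg)
        gl <- computeGLs(sim$pileup)
        rd <- rowData(sim$pileup)
        region <- which(rd$siteClass == "inversion" &
                        sim$truth@invDiffSite)
        kin <- kinshipFromGLs(gl, region)
        cs <- clusterThreeGroups(kin, gl, region)
        frequencyHomogeneityTest(cs)$pvalue
    }, 0)
    expect_gt(max(ps), 0.05)   # not systematically significant
    expect_gt(mean(ps > 0.001), 0.6)
})
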