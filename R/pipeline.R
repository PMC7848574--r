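#' Preset study configurations
#'
#' `panmicticPreset()` is the null design: 10 localities x 40 diploids plus
#' the outgroup, no differentiation. `structuredPreset()` raises the
#' Balding-Nichols differentiation to 0.05 as a positive control.
#' `inversionDemoPreset()` adds the 200-kb inversion-like block at ingroup
#' haplotype frequency 0.29 (near-fixed in the outgroup) plus 3%
#' introgression into the mid-Atlantic localities.
#'
#' @param nSites number of sites (kept moderate so a full run stays
#'   desk-scale).
#' @param seed integer seed.
#' @return a [SimConfig-class].
#' @export
panmicticPreset <- function(nSites = 5000, seed = 1L) {
    SimConfig(nSites = nSites, chromLength = 5e6, fstTarget = 0,
              introgressionFraction = 0, seed = seed)
}

#' @rdname panmicticPreset
#' @export
structuredPreset <- function(nSites = 5000, seed = 1L) {
    SimConfig(nSites = nSites, chromLength = 5e6, fstTarget = 0.05,
              introgressionFraction = 0, seed = seed)
}

#' @rdname panmicticPreset
#' @export
inversionDemoPreset <- function(nSites = 5000, seed = 1L) {
    SimConfig(nSites = nSites, chromLength = 5e6, fstTarget = 0,
              inversionSpan = c(2.4e6, 2.6e6), inversionFreq = 0.29,
              outgroupInversionFreq = 0.98, introgressionFraction = 0.03,
              seed = seed)
}

.stage <- function(name, hash, expr) {
    tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed (config ", hash, "): ",
             conditionMessage(e), call. = FALSE))
}

#' Run the full panmixia study pipeline on simulated data
#'
#' Sequences the analysis end to end: simulation, genotype likelihoods and
#' SNP calling, admixture and PCA, delta-allele-frequency contrasts, the
#' PC selection scan, inversion-region haplotype genotyping with the
#' locality homogeneity test and group-wise Tajima's D (when an inversion
#' block is configured), per-population windowed diversity, and the
#' selection-load table. Returns a machine-readable report; all
#' randomness derives deterministically from the configuration seed, so the
#' same configuration yields a byte-identical report.
#'
#' @param cfg a [SimConfig-class] (e.g. a preset).
#' @param contrastLocalities localities forming group A of the
#'   within-species contrast (indices; the remainder is group B).
#' @param outDir optional directory; when given, the report is written to
#'   `report.json` and the main tables as TSV.
#' @param admixStarts,admixMaxSites admixture EM settings.
#' @return a nested list report (invisibly also written as JSON when
#'   `outDir` is given).
#' @export
runPanmixiaStudy <- function(cfg, contrastLocalities = 1:3, outDir = NULL,
                             admixStarts = 2L, admixMaxSites = 4000L) {
    validObject(cfg)
    hash <- configHash(cfg)
    sim <- .stage("simdata", hash, simulateStudy(cfg))
    pe <- sim$pileup
    gl <- .stage("genolik", hash, computeGLs(pe))
    keep <- filterIndividuals(pe)
    cd <- colData(pe)
    ingroup <- intersect(keep, which(cd$species == "ingroup"))
    outgroup <- intersect(keep, which(cd$species == "outgroup"))
    st <- .stage("genolik", hash, callSnps(gl, individuals = keep))
    stIn <- .stage("genolik", hash, callSnps(gl, individuals = ingroup))
    snpAll <- which(st$passSnp & st$passMaf05)
    snp10In <- which(stIn$passSnp & stIn$passMaf10)

    admix <- .stage("popstructure", hash,
        admixtureEM(gl, sites = which(st$passSnp & st$passMaf10), K = 2L,
                    seed = childSeed(cfg@seed, "admix"),
                    individuals = keep, nStarts = admixStarts,
                    maxSites = admixMaxSites))
    Qin <- admix@Q[match(ingroup, keep), , drop = FALSE]
    minorCol <- which.min(colSums(Qin))
    locIn <- cd$locality[ingroup]
    qv <- Qin[, minorCol]
    withinVar <- mean(tapply(qv, locIn, var))
    betweenVar <- var(tapply(qv, locIn, mean))
    admixRatio <- if (withinVar > 0) betweenVar / withinVar else Inf

    pca <- .stage("popstructure", hash,
                  pcaFromGLs(gl, sites = snp10In, individuals = ingroup,
                             f = stIn$altFreq[snp10In]))
    anovaP <- vapply(1:4, function(k)
        anova(lm(pca@scores[, k] ~ locIn))$`Pr(>F)`[1], 0)

    groupA <- intersect(ingroup,
                        which(cd$locality %in%
                              sprintf("loc%02d", contrastLocalities)))
    groupB <- setdiff(ingroup, groupA)
    snp05In <- which(stIn$passSnp & stIn$passMaf05)
    contrast <- .stage("scans", hash,
        deltaAFContrast(gl, groupA, groupB, sites = snp05In))
    noise <- contrastNoiseScale(stIn$altFreq[snp05In],
                                length(groupA), length(groupB))
    scan <- .stage("scans", hash,
        pcSelectionScan(gl, sites = snp10In, individuals = ingroup,
                        f = stIn$altFreq[snp10In]))

    hap <- NULL
    if (length(cfg@inversionSpan)) {
        hap <- .stage("hapregion", hash, {
            snpIdx <- selectRegionSNPs(scan, "chr1", cfg@inversionSpan[1],
                                       cfg@inversionSpan[2],
                                       topFraction = 1)
            regionSites <- scan$site[snpIdx]
            ## genotype the block within the focal species: the outgroup is
            ## near-fixed for haplotype 2 and would inflate its frequency
            kin <- kinshipFromGLs(gl, regionSites, individuals = ingroup)
            cs <- clusterThreeGroups(kin, gl, regionSites,
                                     individuals = ingroup,
                                     chrom = "chr1",
                                     start0 = cfg@inversionSpan[1],
                                     end0 = cfg@inversionSpan[2])
            hom <- frequencyHomogeneityTest(cs)
            list(callset = cs, homogeneity = hom[c("statistic", "df",
                                                   "pvalue")],
                 groupCounts = as.list(table(cs@group)),
                 hap2FreqOverall = cs@hap2FreqOverall,
                 hap2FreqPerLocality = as.list(cs@hap2Freq))
        })
    }

    anc <- .stage("diversity", hash, outgroupConsensus(pe, outgroup))
    divSites <- .stage("diversity", hash,
                       siteFilters(pe, individuals = ingroup))
    loc1 <- intersect(ingroup, which(cd$locality == "loc01"))
    saf <- .stage("diversity", hash,
                  safPerSite(gl, anc, sites = divSites,
                             individuals = loc1))
    sfs <- .stage("diversity", hash, sfsEM(saf))
    wd <- .stage("diversity", hash, windowThetas(saf, sfs))

    loadTab <- .stage("loadmodel", hash, selectionLoadTable())

    report <- list(
        config = list(hash = hash, seed = cfg@seed, nSites = cfg@nSites,
                      fstTarget = cfg@fstTarget,
                      inversion = length(cfg@inversionSpan) > 0),
        counts = list(individualsKept = length(keep),
                      snpsMaf05 = length(snpAll),
                      snpsMaf10Ingroup = length(snp10In)),
        admixture = list(K = admix@K, logLik = admix@logLik,
                         withinLocalityVar = withinVar,
                         betweenLocalityVar = betweenVar,
                         betweenWithinRatio = admixRatio,
                         structured = is.finite(admixRatio) &&
                             admixRatio >= 2),
        pca = list(varExplained = pca@varExplained[1:4],
                   anovaP = anovaP,
                   structured = any(anovaP < 1e-3)),
        deltaAF = list(noiseScale = noise,
                       maxRolling = max(contrast$rollAbsDelta, na.rm = TRUE),
                       meanRolling = mean(contrast$rollAbsDelta,
                                          na.rm = TRUE),
                       ## the mean rolling |dAF| sits near 1.15x the
                       ## binomial noise scale under panmixia (EM noise at
                       ## 1.4x depth); sustained excess beyond 1.5x marks
                       ## genuine differentiation, and any single window
                       ## beyond 3x does too
                       structured = mean(contrast$rollAbsDelta,
                                         na.rm = TRUE) > 1.5 * noise ||
                           max(contrast$rollAbsDelta,
                               na.rm = TRUE) > 3 * noise),
        selectionScan = list(meanStat = mean(scan$stat),
                             nOutliers = sum(scan$pvalue <
                                             0.05 / nrow(scan))),
        haplotypeRegion = if (is.null(hap)) NULL else hap[-1],
        diversity = list(population = "loc01",
                         nWindows = nrow(wd),
                         meanThetaPi = mean(wd$thetaPi, na.rm = TRUE),
                         meanTajimaD = mean(wd$tajimaD, na.rm = TRUE)),
        loadModel = loadTab,
        panmicticOnAllSurfaces = !(is.finite(admixRatio) &&
                                   admixRatio >= 2) &&
            !any(anovaP < 1e-3) &&
            !(mean(contrast$rollAbsDelta, na.rm = TRUE) > 1.5 * noise ||
              max(contrast$rollAbsDelta, na.rm = TRUE) > 3 * noise)
    )
    if (!is.null(hap)) report$haplotypeRegion$callset <- NULL
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        jsonlite::write_json(report,
                             file.path(outDir, "report.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        writeSiteTable(st, file.path(outDir, "sites.tsv.gz"))
        writeScanTrack(contrast, file.path(outDir, "contrast.tsv"))
        writeScanTrack(scan, file.path(outDir, "pc_selection.tsv"))
        writeWindowDiversity(wd, file.path(outDir, "diversity.tsv"))
        write.table(loadTab, file.path(outDir, "load_model.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    report
}
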