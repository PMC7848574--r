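#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

#' Simulation configuration for a low-coverage panmixia study design
#'
#' `SimConfig` bundles the parameters of the synthetic study: a set of
#' conspecific sampling localities with zero-to-low differentiation, a
#' diverged outgroup species, an inversion-like non-recombining haplotype
#' block segregating in all localities, low-rate introgression from the
#' outgroup into designated "mid-Atlantic" localities, and shallow
#' (Poisson-depth) sequencing with a fixed per-base error rate.
#'
#' @slot nLocalities number of conspecific (ingroup) sampling localities.
#' @slot nPerLocality diploid individuals sampled per locality.
#' @slot nOutgroup diploid individuals in the outgroup sample.
#' @slot nSites number of segregating sites to simulate.
#' @slot chromLength chromosome length in bp; site positions are uniform on it.
#' @slot fstTarget Balding-Nichols differentiation parameter among ingroup
#'   localities; 0 is the panmixia null.
#' @slot divergenceMafShift Balding-Nichols parameter for outgroup allele
#'   frequencies at sites polymorphic in both species.
#' @slot outgroupFixedFraction fraction of sites fixed for opposite alleles
#'   between ingroup and outgroup.
#' @slot outgroupSharedFraction fraction of sites polymorphic in both species.
#' @slot outgroupPrivateFraction fraction of sites polymorphic only in the
#'   outgroup (the outgroup is as diverse as the ingroup); the remainder of
#'   sites is private to the ingroup.
#' @slot inversionSpan length-2 numeric, 0-based half-open bp interval of the
#'   non-recombining block; length-0 disables the block.
#' @slot inversionFreq ingroup frequency of the derived (younger) haplotype 2.
#' @slot outgroupInversionFreq haplotype 2 frequency in the outgroup
#'   (near-fixed under the introgression-after-sweep scenario).
#' @slot introgressionFraction per-individual outgroup ancestry fraction in
#'   the mid-Atlantic localities.
#' @slot midAtlanticLocalities integer indices of localities receiving
#'   introgression.
#' @slot meanDepth mean per-site per-individual sequencing depth (reads).
#' @slot baseError per-read base error rate (errors uniform over the three
#'   non-true bases).
#' @slot seed integer seed; identical seed + config gives identical output.
#' @export
setClass("SimConfig", representation(
    nLocalities = "integer",
    nPerLocality = "integer",
    nOutgroup = "integer",
    nSites = "integer",
    chromLength = "numeric",
    fstTarget = "numeric",
    divergenceMafShift = "numeric",
    outgroupFixedFraction = "numeric",
    outgroupSharedFraction = "numeric",
    outgroupPrivateFraction = "numeric",
    inversionSpan = "numeric",
    inversionFreq = "numeric",
    outgroupInversionFreq = "numeric",
    introgressionFraction = "numeric",
    midAtlanticLocalities = "integer",
    meanDepth = "numeric",
    baseError = "numeric",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    chk01 <- function(x, nm) {
        if (length(x) != 1 || is.na(x) || x < 0 || x > 1)
            msg <<- c(msg, sprintf("%s must be a single value in [0, 1]", nm))
    }
    if (object@nLocalities < 1L) msg <- c(msg, "nLocalities must be >= 1")
    if (object@nPerLocality < 1L) msg <- c(msg, "nPerLocality must be >= 1")
    if (object@nOutgroup < 0L) msg <- c(msg, "nOutgroup must be >= 0")
    if (object@nSites < 1L) msg <- c(msg, "nSites must be >= 1")
    if (object@chromLength < object@nSites)
        msg <- c(msg, "chromLength must be >= nSites")
    if (object@fstTarget < 0 || object@fstTarget >= 1)
        msg <- c(msg, "fstTarget must lie in [0, 1)")
    chk01(object@divergenceMafShift, "divergenceMafShift")
    chk01(object@outgroupFixedFraction, "outgroupFixedFraction")
    chk01(object@outgroupSharedFraction, "outgroupSharedFraction")
    chk01(object@outgroupPrivateFraction, "outgroupPrivateFraction")
    if (object@outgroupFixedFraction + object@outgroupSharedFraction +
        object@outgroupPrivateFraction > 1)
        msg <- c(msg, "outgroup site-class fractions must sum to <= 1")
    chk01(object@inversionFreq, "inversionFreq")
    chk01(object@outgroupInversionFreq, "outgroupInversionFreq")
    chk01(object@introgressionFraction, "introgressionFraction")
    if (length(object@inversionSpan) %in% c(0L, 2L)) {
        if (length(object@inversionSpan) == 2L) {
            sp <- object@inversionSpan
            if (sp[1] < 0 || sp[2] > object@chromLength || sp[1] >= sp[2])
                msg <- c(msg, "inversionSpan must be a non-empty interval within [0, chromLength)")
        }
    } else msg <- c(msg, "inversionSpan must have length 0 or 2")
    if (object@meanDepth < 0) msg <- c(msg, "meanDepth must be >= 0")
    if (object@baseError < 0 || object@baseError >= 0.75)
        msg <- c(msg, "baseError must lie in [0, 0.75)")
    if (any(object@midAtlanticLocalities < 1L) ||
        any(object@midAtlanticLocalities > object@nLocalities))
        msg <- c(msg, "midAtlanticLocalities out of range")
    if (length(msg)) msg else TRUE
})

#' Construct a [SimConfig-class]
#'
#' Defaults follow the study design the package emulates: 10 localities of 40
#' diploids plus a 49-individual outgroup, median sequencing depth 1.4x, a
#' 200-kb inversion-like block at derived-haplotype frequency 0.29 in the
#' ingroup and 0.98 in the outgroup.
#'
#' @param nSites number of segregating sites.
#' @param chromLength chromosome length in bp.
#' @param nLocalities,nPerLocality,nOutgroup sample design.
#' @param fstTarget Balding-Nichols ingroup differentiation (0 = panmixia).
#' @param divergenceMafShift,outgroupFixedFraction,outgroupSharedFraction,outgroupPrivateFraction
#'   outgroup divergence model; see [SimConfig-class].
#' @param inversionSpan 0-based half-open bp interval or `numeric(0)`.
#' @param inversionFreq,outgroupInversionFreq haplotype 2 frequencies.
#' @param introgressionFraction,midAtlanticLocalities introgression model.
#' @param meanDepth,baseError sequencing model.
#' @param seed integer seed.
#' @return a validated `SimConfig` object.
#' @examples
#' cfg <- SimConfig(nSites = 1000, chromLength = 1e6, seed = 1)
#' @export
SimConfig <- function(nSites, chromLength,
                      nLocalities = 10, nPerLocality = 40, nOutgroup = 49,
                      fstTarget = 0, divergenceMafShift = 0.3,
                      outgroupFixedFraction = 0.15,
                      outgroupSharedFraction = 0.25,
                      outgroupPrivateFraction = 0.30,
                      inversionSpan = numeric(0),
                      inversionFreq = 0.29, outgroupInversionFreq = 0.98,
                      introgressionFraction = 0,
                      midAtlanticLocalities = seq_len(min(3, nLocalities)),
                      meanDepth = 1.4, baseError = 0.01, seed = 1L) {
    new("SimConfig",
        nLocalities = as.integer(nLocalities),
        nPerLocality = as.integer(nPerLocality),
        nOutgroup = as.integer(nOutgroup),
        nSites = as.integer(nSites),
        chromLength = as.numeric(chromLength),
        fstTarget = fstTarget,
        divergenceMafShift = divergenceMafShift,
        outgroupFixedFraction = outgroupFixedFraction,
        outgroupSharedFraction = outgroupSharedFraction,
        outgroupPrivateFraction = outgroupPrivateFraction,
        inversionSpan = as.numeric(inversionSpan),
        inversionFreq = inversionFreq,
        outgroupInversionFreq = outgroupInversionFreq,
        introgressionFraction = introgressionFraction,
        midAtlanticLocalities = as.integer(midAtlanticLocalities),
        meanDepth = meanDepth,
        baseError = baseError,
        seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nLocalities, "localities x", object@nPerLocality,
        "diploids +", object@nOutgroup, "outgroup;",
        object@nSites, "sites on", format(object@chromLength, big.mark = ","),
        "bp\n")
    cat("  fstTarget", object@fstTarget,
        "| meanDepth", object@meanDepth, "| baseError", object@baseError,
        "| seed", object@seed, "\n")
    if (length(object@inversionSpan))
        cat("  inversion block [", object@inversionSpan[1], ",",
            object@inversionSpan[2], ") at freq", object@inversionFreq,
            "(ingroup) /", object@outgroupInversionFreq, "(outgroup)\n")
    if (object@introgressionFraction > 0)
        cat("  introgression", object@introgressionFraction,
            "into localities", paste(object@midAtlanticLocalities,
                                     collapse = ","), "\n")
})

#' Simulated ground truth
#'
#' True genotypes (sites x individuals), population labels, inversion
#' haplotype carriage, per-locality true allele frequencies and the ancestral
#' allele per site. Genotypes are dosages of the derived (`alt`) allele;
#' the ancestral allele equals the reference base, matching the convention
#' that the major allele is taken from the reference.
#'
#' @slot genotypes integer matrix, sites x individuals, entries in {0,1,2}.
#' @slot localityLabels character per individual (`locXX` or `outgroup`).
#' @slot speciesLabels character per individual (`ingroup`/`outgroup`).
#' @slot inversionGenotype character per individual, one of
#'   `hap1/hap1`, `hap1/hap2`, `hap2/hap2` (or `NA` when no block simulated).
#' @slot trueFreqs derived-allele frequency matrix, sites x populations.
#' @slot chrom,pos0 site keys (0-based positions, sorted).
#' @slot refBase,altBase per-site alleles; `refBase` is ancestral.
#' @slot siteClass per-site class: `private`, `shared`, `fixedDiff`,
#'   or `inversion`.
#' @slot invDiffSite logical; inside the block, sites whose two founder
#'   haplotypes carry strongly different alleles.
#' @slot introgressedMask logical sites x individuals matrix flag of segments
#'   copied from the outgroup (empty matrix when introgression is off).
#' @slot config the generating [SimConfig-class].
#' @export
setClass("SimTruth", representation(
    genotypes = "matrix",
    localityLabels = "character",
    speciesLabels = "character",
    inversionGenotype = "character",
    trueFreqs = "matrix",
    chrom = "character",
    pos0 = "numeric",
    refBase = "character",
    altBase = "character",
    siteClass = "character",
    invDiffSite = "logical",
    introgressedMask = "matrix",
    config = "SimConfig"
))

setValidity("SimTruth", function(object) {
    g <- object@genotypes
    if (!all(g %in% 0:2)) return("genotype dosages must be in {0,1,2}")
    if (ncol(g) != length(object@localityLabels))
        return("localityLabels length must match individuals")
    if (nrow(g) != length(object@pos0))
        return("pos0 length must match sites")
    TRUE
})

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth:", nrow(object@genotypes), "sites x",
        ncol(object@genotypes), "individuals (",
        sum(object@speciesLabels == "ingroup"), "ingroup /",
        sum(object@speciesLabels == "outgroup"), "outgroup )\n")
    if (length(object@config@inversionSpan))
        cat("  inversion genotypes:",
            paste(names(table(object@inversionGenotype)),
                  table(object@inversionGenotype), collapse = ", "), "\n")
})

#' Per-site read-count pileup container
#'
#' A [SummarizedExperiment-class] with assays `nMajor`, `nMinor` and `nOther`
#' (sites x individuals): counts of reads supporting the major (reference)
#' allele, the minor (alternative) allele, and any other base. `rowData`
#' holds `chrom`, `pos0`, `refBase`, `altBase`; `metadata` records the base
#' error rate and mean depth used in simulation.
#' @export
setClass("PileupExperiment", contains = "SummarizedExperiment")

setValidity("PileupExperiment", function(object) {
    need <- c("nMajor", "nMinor", "nOther")
    if (!all(need %in% names(assays(object))))
        return("assays nMajor, nMinor, nOther are required")
    for (a in need) if (any(assay(object, a) < 0))
        return("read counts must be non-negative")
    TRUE
})

#' Genotype-likelihood container
#'
#' A [SummarizedExperiment-class] with assays `ll0`, `ll1`, `ll2`
#' (sites x individuals): normalized log-likelihoods of the data given minor
#' (alternative) allele dosage 0, 1, 2. Per site and individual the maximum
#' of the three is 0; individuals with no reads have all three equal to 0.
#' `rowData` carries the site keys and allele identities; assay `depth`
#' records the read depth used.
#' @export
setClass("GLExperiment", contains = "SummarizedExperiment")

setValidity("GLExperiment", function(object) {
    need <- c("ll0", "ll1", "ll2")
    if (!all(need %in% names(assays(object))))
        return("assays ll0, ll1, ll2 are required")
    m <- pmax(assay(object, "ll0"), assay(object, "ll1"), assay(object, "ll2"))
    if (any(abs(m) > 1e-8))
        return("log-likelihoods must be normalized (per-entry max 0)")
    TRUE
})

#' Result of iterative individual-allele-frequency PCA
#'
#' @slot cov individuals x individuals covariance matrix.
#' @slot eigenvalues eigenvalues in descending order.
#' @slot scores individuals x k matrix, eigenvectors scaled by sqrt(eigenvalue).
#' @slot vectors individuals x k orthonormal eigenvectors.
#' @slot loadings sites x k per-SNP projections of standardized dosages.
#' @slot varExplained fraction of (positive) variance per component.
#' @slot siteIndex indices (into the supplied site set) actually used.
#' @slot f pooled minor-allele frequency per used site.
#' @slot rank rank used for the individual-allele-frequency reconstruction.
#' @slot nIter iterations run.
#' @export
setClass("PCAResult", representation(
    cov = "matrix", eigenvalues = "numeric", scores = "matrix",
    vectors = "matrix", loadings = "matrix", varExplained = "numeric",
    siteIndex = "integer", f = "numeric", rank = "integer", nIter = "integer"))

setMethod("show", "PCAResult", function(object) {
    cat("PCAResult:", nrow(object@cov), "individuals,",
        length(object@siteIndex), "sites,", object@nIter, "iterations, rank",
        object@rank, "\n  varExplained:",
        paste(sprintf("%.1f%%", 100 * utils::head(object@varExplained, 4)),
              collapse = " "), "\n")
})

#' Result of genotype-likelihood admixture EM
#'
#' @slot K number of ancestral components.
#' @slot Q individuals x K ancestry proportions (rows sum to 1).
#' @slot F K x sites ancestral minor-allele frequencies, clamped away from
#'   0 and 1.
#' @slot logLik final observed-data log-likelihood.
#' @slot nIter iterations of the best start.
#' @export
setClass("AdmixtureResult", representation(
    K = "integer", Q = "matrix", F = "matrix", logLik = "numeric",
    nIter = "integer"))

setValidity("AdmixtureResult", function(object) {
    if (any(abs(rowSums(object@Q) - 1) > 1e-9))
        return("Q rows must sum to 1")
    if (any(object@F < 1e-6 - 1e-12) || any(object@F > 1 - 1e-6 + 1e-12))
        return("F must be clamped to [1e-6, 1-1e-6]")
    if (!is.finite(object@logLik)) return("logLik must be finite")
    TRUE
})

setMethod("show", "AdmixtureResult", function(object) {
    cat("AdmixtureResult: K =", object@K, ",", nrow(object@Q),
        "individuals,", ncol(object@F), "sites; logLik =",
        format(object@logLik), "\n")
})

#' Haplotype genotype calls for a candidate inversion region
#'
#' @slot chrom,start0,end0 region (0-based half-open).
#' @slot snpIndex indices of the region SNPs used for kinship clustering.
#' @slot group per-individual call: `hom1`, `het`, `hom2` or `unassigned`.
#' @slot meanDosage per-individual mean posterior minor dosage over the
#'   region SNPs.
#' @slot locality per-individual locality labels.
#' @slot hap2Freq named vector of haplotype 2 frequency per locality.
#' @slot hap2FreqOverall overall haplotype 2 frequency among assigned calls.
#' @export
setClass("HaplotypeCallSet", representation(
    chrom = "character", start0 = "numeric", end0 = "numeric",
    snpIndex = "integer", group = "character", meanDosage = "numeric",
    locality = "character", hap2Freq = "numeric",
    hap2FreqOverall = "numeric"))

setMethod("show", "HaplotypeCallSet", function(object) {
    tab <- table(factor(object@group,
                        levels = c("hom1", "het", "hom2", "unassigned")))
    cat("HaplotypeCallSet:", object@chrom, sprintf("[%d, %d)",
        as.integer(object@start0), as.integer(object@end0)), "-",
        length(object@snpIndex), "SNPs\n  groups:",
        paste(names(tab), tab, sep = "=", collapse = " "),
        sprintf("| hap2 freq %.3f\n", object@hap2FreqOverall))
})
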