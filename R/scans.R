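#' Delta-allele-frequency contrast between two sample groups
#'
#' Estimates each group's allele frequency at a shared, pre-oriented site
#' list (the study-wide MAF >= 5% set) by EM on the group's genotype
#' likelihoods, forms the signed per-SNP difference, and adds the rolling
#' mean of `|dAF|` over windows of `window` consecutive SNPs (step 1) within
#' each chromosome. Because both groups are estimated from one
#' [GLExperiment-class], allele orientation is harmonized by construction;
#' supplying sites whose orientation differs between groups is an error at
#' the lower-level track builder.
#'
#' @param gl a [GLExperiment-class].
#' @param groupA,groupB individual indices for the two groups.
#' @param sites site subset (typically `passMaf05` from [callSnps()]).
#' @param window rolling window in SNPs.
#' @return a [DataFrame][S4Vectors::DataFrame-class] with `chrom`, `pos0`,
#'   `fA`, `fB`, `deltaAF` and `rollAbsDelta` (NA where a full window does
#'   not fit).
#' @export
deltaAFContrast <- function(gl, groupA, groupB, sites = NULL,
                            window = 100L) {
    if (is.null(sites)) sites <- seq_len(nrow(gl))
    sites <- seq_len(nrow(gl))[sites]
    estA <- estimateMAF(gl, sites = sites, individuals = groupA)
    estB <- estimateMAF(gl, sites = sites, individuals = groupB)
    rd <- rowData(gl)[sites, ]
    deltaAFTrack(chrom = rd$chrom, pos0 = rd$pos0,
                 fA = estA$altFreq, fB = estB$altFreq,
                 allelesA = paste(rd$refBase, rd$altBase),
                 allelesB = paste(rd$refBase, rd$altBase),
                 window = window)
}

#' @rdname deltaAFContrast
#' @param fA,fB per-site frequency estimates for the two groups.
#' @param chrom,pos0 site keys.
#' @param allelesA,allelesB per-site allele orientation strings for each
#'   group; any mismatch is an error (alleles must be harmonized first).
#' @export
deltaAFTrack <- function(chrom, pos0, fA, fB, allelesA = NULL,
                         allelesB = NULL, window = 100L) {
    if (!is.null(allelesA) && !is.null(allelesB) &&
        any(allelesA != allelesB))
        stop("allele orientation differs between groups; harmonize first")
    delta <- fA - fB
    DataFrame(chrom = chrom, pos0 = pos0, fA = fA, fB = fB,
              deltaAF = delta,
              rollAbsDelta = rollingMean(abs(delta), chrom, window))
}

#' PC-based selection scan
#'
#' For each SNP, the squared projection of its standardized dosage vector on
#' a leading principal component, scaled by that component's eigenvalue:
#' `D_j = (x_j' v)^2 / lambda`. Under neutrality (no SNP-specific
#' association with the component) `D_j` follows chi-square with 1 degree of
#' freedom; p-values are upper-tail. The scan is computed for each
#' chromosome individually: a separate PCA is fitted per chromosome, so
#' concatenating chromosomes never changes a per-chromosome statistic.
#'
#' @param gl a [GLExperiment-class].
#' @param sites site subset (typically `passMaf10`).
#' @param individuals individual subset (the outgroup is removed for the
#'   within-species scan).
#' @param pc which principal component to test (default 1).
#' @param pca optionally, a precomputed [PCAResult-class] for a
#'   single-chromosome site set; when supplied its loadings are reused.
#' @param f optional precomputed pooled frequencies aligned with `sites`.
#' @param ... passed to [pcaFromGLs()].
#' @return a [DataFrame][S4Vectors::DataFrame-class] with `chrom`, `pos0`,
#'   `site` (row index into `gl`), `stat` and `pvalue` for every scanned
#'   site.
#' @export
pcSelectionScan <- function(gl, sites = NULL, individuals = NULL, pc = 1L,
                            pca = NULL, f = NULL, ...) {
    if (is.null(sites)) sites <- seq_len(nrow(gl))
    sites <- seq_len(nrow(gl))[sites]
    rd <- rowData(gl)
    out <- NULL
    for (ch in unique(rd$chrom[sites])) {
        onCh <- rd$chrom[sites] == ch
        chSites <- sites[onCh]
        fit <- if (!is.null(pca)) pca else
            pcaFromGLs(gl, sites = chSites, individuals = individuals,
                       f = if (is.null(f)) NULL else f[onCh], ...)
        lam <- fit@eigenvalues[pc]
        if (!is.finite(lam) || lam <= 0)
            stop("principal component ", pc, " is degenerate on ", ch)
        D <- fit@loadings[, pc]^2 / lam
        p <- pchisq(D, df = 1, lower.tail = FALSE)
        block <- DataFrame(chrom = rep(ch, length(D)),
                           pos0 = rd$pos0[fit@siteIndex],
                           site = fit@siteIndex, stat = D, pvalue = p)
        out <- if (is.null(out)) block else rbind(out, block)
    }
    out
}

#' Binomial sampling-noise scale for a two-group frequency contrast
#'
#' The per-site standard deviation of `fA - fB` expected from binomial
#' sampling alone, `sqrt(f (1 - f) (1 / (2 nA) + 1 / (2 nB)))`, averaged
#' over sites; the reference scale against which rolling |dAF| means are
#' judged.
#'
#' @param f per-site pooled allele frequencies.
#' @param nA,nB diploid sample sizes of the two groups.
#' @return a single numeric noise scale.
#' @export
contrastNoiseScale <- function(f, nA, nB) {
    mean(sqrt(f * (1 - f) * (1 / (2 * nA) + 1 / (2 * nB))), na.rm = TRUE)
}

#' Write per-SNP scan tracks and windowed rolling means
#'
#' The per-SNP track is TSV with 1-based positions; the windowed track is
#' BED (0-based half-open) over each rolling window's span.
#'
#' @param track output of [deltaAFContrast()] or [pcSelectionScan()].
#' @param path TSV path.
#' @param bedPath optional BED path for `rollAbsDelta` windows.
#' @param window window size used (for BED spans).
#' @return `path`, invisibly.
#' @export
writeScanTrack <- function(track, path, bedPath = NULL, window = 100L) {
    df <- as.data.frame(track)
    df$pos <- df$pos0 + 1
    df$pos0 <- NULL
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(bedPath) && "rollAbsDelta" %in% names(df)) {
        i <- which(!is.na(track$rollAbsDelta))
        bed <- data.frame(chrom = track$chrom[i],
                          start = track$pos0[i],
                          end = track$pos0[pmin(i + window - 1L,
                                                nrow(track))] + 1,
                          value = track$rollAbsDelta[i])
        write.table(bed, bedPath, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
    }
    invisible(path)
}
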