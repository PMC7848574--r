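#' Outgroup consensus (ancestral) allele per site
#'
#' The allele with the larger pooled outgroup read count, reference versus
#' alternative; ties and uncovered sites give `"N"`. Used to polarize
#' ingroup alleles for the unfolded site frequency spectrum.
#'
#' @param pileup a [PileupExperiment-class].
#' @param outgroup indices of the outgroup individuals.
#' @return character vector per site: `"ref"`, `"alt"` or `"N"`.
#' @export
outgroupConsensus <- function(pileup, outgroup) {
    nR <- rowSums(assay(pileup, "nMajor")[, outgroup, drop = FALSE])
    nA <- rowSums(assay(pileup, "nMinor")[, outgroup, drop = FALSE])
    out <- rep("N", nrow(pileup))
    out[nR > nA] <- "ref"
    out[nA > nR] <- "alt"
    out
}

#' Write a consensus FASTA over the simulated coordinates
#'
#' Builds a single-sequence FASTA of length `chromLength`, `N` everywhere
#' except the simulated sites, which carry the consensus base.
#'
#' @param consensus per-site states from [outgroupConsensus()].
#' @param pileup the [PileupExperiment-class] providing site keys and
#'   allele letters.
#' @param chromLength sequence length in bp.
#' @param path FASTA output path.
#' @return `path`, invisibly.
#' @export
writeConsensusFasta <- function(consensus, pileup, chromLength, path) {
    rd <- rowData(pileup)
    base <- rep("N", chromLength)
    keep <- consensus != "N"
    base[rd$pos0[keep] + 1] <-
        ifelse(consensus[keep] == "ref", rd$refBase[keep], rd$altBase[keep])
    seq <- Biostrings::DNAStringSet(paste(base, collapse = ""))
    names(seq) <- rd$chrom[1]
    Biostrings::writeXStringSet(seq, path)
    invisible(path)
}

#' Depth-based site filters for diversity estimation
#'
#' Retains sites whose total read depth over the chosen individuals lies in
#' `[minDepth, maxDepth]` (bounds inclusive). No MAF filter is applied:
#' frequency cutoffs bias spectrum-based diversity estimates. The
#' per-individual minimum-depth flag of the original pipeline has no
#' fractional-depth analogue at this abstraction; an individual simply
#' contributes to a site when it has at least one read.
#'
#' @param pileup a [PileupExperiment-class].
#' @param individuals individual subset defining the population.
#' @param minDepth,maxDepth inclusive total-depth bounds.
#' @return integer indices of retained sites.
#' @export
siteFilters <- function(pileup, individuals = NULL, minDepth = 15,
                        maxDepth = 1000) {
    if (is.null(individuals)) individuals <- seq_len(ncol(pileup))
    tot <- rowSums(pileupDepth(pileup)[, individuals, drop = FALSE])
    which(tot >= minDepth & tot <= maxDepth)
}

#' Per-site sample-allele-frequency likelihoods
#'
#' Dynamic-programming convolution of per-individual genotype likelihoods
#' into the likelihood of each derived-allele count `d = 0..2n` for the
#' sample of `n` diploids:
#' `L(d) proportional to (1 / C(2n, d)) * sum over genotype vectors with
#' sum g_i = d of prod_i C(2, g_i) L_i(g_i)`. Sites whose ancestral state
#' is `"N"` are skipped; sites whose ancestral allele is the alternative
#' base have their genotype-likelihood order flipped so `d` always counts
#' derived alleles.
#'
#' @param gl a [GLExperiment-class].
#' @param ancestral per-site states (`"ref"`, `"alt"`, `"N"`), full-length
#'   for the `gl` object.
#' @param sites site subset to process.
#' @param individuals individuals forming the sample.
#' @return list of class `SAFMatrix`: `logSaf` (sites x (2n+1), per-row max
#'   0), `n` diploids, `siteIndex`, `chrom`, `pos0`.
#' @export
safPerSite <- function(gl, ancestral, sites = NULL, individuals = NULL) {
    if (is.null(sites)) sites <- seq_len(nrow(gl))
    sites <- seq_len(nrow(gl))[sites]
    if (is.null(individuals)) individuals <- seq_len(ncol(gl))
    individuals <- seq_len(ncol(gl))[individuals]
    anc <- ancestral[sites]
    keep <- anc != "N"
    sites <- sites[keep]
    anc <- anc[keep]
    lin <- .glLinear(gl, sites, individuals)
    ## orient to derived dosage: where the ancestral is the alternative
    ## allele, dosage of the derived (reference) allele is 2 - g
    flip <- anc == "alt"
    L0 <- lin$L0; L1 <- lin$L1; L2 <- lin$L2
    if (any(flip)) {
        tmp <- L0[flip, , drop = FALSE]
        L0[flip, ] <- L2[flip, , drop = FALSE]
        L2[flip, ] <- tmp
    }
    M <- length(sites); n <- length(individuals)
    z <- matrix(0, M, 2 * n + 1)
    z[, 1] <- 1
    for (i in seq_len(n)) {
        w0 <- L0[, i]; w1 <- 2 * L1[, i]; w2 <- L2[, i]
        upTo <- 2 * i + 1
        prev <- z[, seq_len(upTo), drop = FALSE]
        znew <- prev * w0
        znew[, 2:upTo] <- znew[, 2:upTo] +
            prev[, 1:(upTo - 1), drop = FALSE] * w1
        znew[, 3:upTo] <- znew[, 3:upTo] +
            prev[, 1:(upTo - 2), drop = FALSE] * w2
        mx <- znew[cbind(seq_len(M),               # rescale against underflow
                         max.col(znew, ties.method = "first"))]
        z[, seq_len(upTo)] <- znew / mx
    }
    z <- sweep(z, 2, choose(2 * n, 0:(2 * n)), `/`)
    logSaf <- log(z) - log(apply(z, 1, max))
    rd <- rowData(gl)
    structure(list(logSaf = logSaf, n = n, siteIndex = sites,
                   chrom = rd$chrom[sites], pos0 = rd$pos0[sites]),
              class = "SAFMatrix")
}

#' Site frequency spectrum by EM over sample-allele-frequency likelihoods
#'
#' Maximizes `sum_sites log sum_d SFS_d SAF(site, d)` over the probability
#' simplex by EM (each iteration: per-site posterior over `d` under the
#' current spectrum, then the spectrum is the mean posterior). Converges on
#' relative log-likelihood change below `tol`.
#'
#' @param saf a `SAFMatrix` from [safPerSite()].
#' @param tol relative log-likelihood tolerance.
#' @param maxIter iteration cap.
#' @return list of class `SFS`: `probs` (length 2n+1), `counts` (expected
#'   sites per bin, summing to the number of sites), `logLik`, `nIter`.
#' @export
sfsEM <- function(saf, tol = 1e-6, maxIter = 500L) {
    A <- exp(saf$logSaf)
    M <- nrow(A); B <- ncol(A)
    if (M < 1) stop("no sites with known ancestral state")
    sfs <- rep(1 / B, B)
    llPrev <- -Inf
    it <- 0L
    repeat {
        it <- it + 1L
        w <- sweep(A, 2, sfs, `*`)
        rs <- rowSums(w)
        ll <- sum(log(rs))
        post <- w / rs
        sfs <- colMeans(post)
        if (is.finite(llPrev) &&
            abs(ll - llPrev) < tol * abs(llPrev)) break
        llPrev <- ll
        if (it >= maxIter) break
    }
    structure(list(probs = sfs, counts = sfs * M, logLik = ll, nIter = it),
              class = "SFS")
}

#' Tajima's D from segregating sites and total pairwise diversity
#'
#' The 1989 normalization: `D = (pi - S / a1) / sqrt(e1 S + e2 S (S - 1))`
#' with the standard constants computed from the number of sequences.
#' `S` may be an expected (fractional) count.
#'
#' @param nChrom number of sequences (chromosomes) in the sample.
#' @param S number of segregating sites.
#' @param piTotal sum over sites of pairwise diversity.
#' @return Tajima's D, or `NA` when undefined (S = 0 or non-positive
#'   variance).
#' @export
tajimasD <- function(nChrom, S, piTotal) {
    n <- nChrom
    if (n < 2 || !is.finite(S) || S <= 0) return(NA_real_)
    a1 <- sum(1 / seq_len(n - 1))
    a2 <- sum(1 / seq_len(n - 1)^2)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1
    e2 <- c2 / (a1^2 + a2)
    v <- e1 * S + e2 * S * (S - 1)
    if (v <= 0) return(NA_real_)
    (piTotal - S / a1) / sqrt(v)
}

#' Windowed diversity statistics with a spectrum prior
#'
#' Empirical-Bayes per-site posteriors over the derived count `d` under the
#' estimated spectrum give each site's expected pairwise diversity
#' (`d (2n - d) / C(2n, 2)`) and expected segregating-site indicator; these
#' are summed in non-overlapping windows (default 5 kb), divided by the
#' number of contributing sites to give per-site averages, and combined into
#' Tajima's D via [tajimasD()] (using the window sums and `2n` sequences).
#'
#' @param saf a `SAFMatrix`.
#' @param sfs an `SFS` prior from [sfsEM()].
#' @param windowBp window size in bp (0-based half-open bins).
#' @return a [DataFrame][S4Vectors::DataFrame-class]: `chrom`, `winStart0`,
#'   `winEnd0`, `nSites`, `thetaPi`, `thetaW` (per-site averages), `segS`
#'   (expected segregating sites) and `tajimaD` (`NA` where undefined).
#' @export
windowThetas <- function(saf, sfs, windowBp = 5000L) {
    A <- exp(saf$logSaf)
    w <- sweep(A, 2, sfs$probs, `*`)
    post <- w / rowSums(w)
    n2 <- 2 * saf$n
    d <- 0:n2
    piW <- d * (n2 - d) / choose(n2, 2)
    segW <- as.numeric(d > 0 & d < n2)
    a1 <- sum(1 / seq_len(n2 - 1))
    piSite <- as.vector(post %*% piW)
    segSite <- as.vector(post %*% segW)
    bin <- floor(saf$pos0 / windowBp)
    key <- paste(saf$chrom, bin)
    uk <- unique(key)
    idx <- match(key, uk)
    agg <- function(x) as.vector(tapply(x, idx, sum))
    nSites <- as.vector(table(factor(idx, levels = seq_along(uk))))
    piSum <- agg(piSite)
    segSum <- agg(segSite)
    first <- !duplicated(key)
    D <- vapply(seq_along(uk), function(i)
        tajimasD(n2, segSum[i], piSum[i]), 0)
    DataFrame(chrom = saf$chrom[first],
              winStart0 = bin[first] * windowBp,
              winEnd0 = (bin[first] + 1) * windowBp,
              nSites = nSites,
              thetaPi = piSum / nSites,
              thetaW = segSum / a1 / nSites,
              segS = segSum,
              tajimaD = D)
}

#' Fold an unfolded site frequency spectrum
#' @param probs unfolded spectrum of length 2n+1.
#' @return folded spectrum of length n+1.
#' @export
foldSFS <- function(probs) {
    B <- length(probs)
    n2 <- B - 1
    half <- floor(n2 / 2)
    out <- numeric(half + 1)
    for (d in 0:half) {
        dd <- n2 - d
        out[d + 1] <- if (dd == d) probs[d + 1] else
            probs[d + 1] + probs[dd + 1]
    }
    out
}

#' Write windowed diversity as TSV (+ optional BED)
#' @param wd output of [windowThetas()].
#' @param path TSV path.
#' @param bedPath optional BED path (0-based half-open windows).
#' @return `path`, invisibly.
#' @export
writeWindowDiversity <- function(wd, path, bedPath = NULL) {
    write.table(as.data.frame(wd), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (!is.null(bedPath))
        write.table(as.data.frame(wd)[, c("chrom", "winStart0", "winEnd0",
                                          "thetaPi")],
                    bedPath, sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
    invisible(path)
}
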