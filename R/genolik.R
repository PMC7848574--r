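#' Genotype likelihoods from read-count pileups
#'
#' GATK-style model with a single per-run error rate: given minor-allele
#' dosage `g`, a read reports the major allele with probability
#' `(1 - g/2)(1 - e) + (g/2) e/3` and the minor allele with
#' `(g/2)(1 - e) + (1 - g/2) e/3`; any other base has probability `e/3`
#' under either allele, so "other" reads cancel on normalization. The
#' per-genotype likelihood is the product over reads; results are returned
#' in normalized log space (per site and individual the maximum is 0, and
#' zero-depth entries are identically 0 for all three genotypes).
#'
#' @param pileup a [PileupExperiment-class].
#' @param eps per-base error rate in (0, 0.75); defaults to the rate stored
#'   in the pileup metadata.
#' @return a [GLExperiment-class] with assays `ll0`, `ll1`, `ll2`, `depth`.
#' @examples
#' ## two major reads, no minor, e = 0.01:
#' ## L(0):L(1):L(2) = 0.98010 : 0.24668 : 1.111e-5
#' @export
computeGLs <- function(pileup, eps = metadata(pileup)$baseError) {
    stopifnot(is(pileup, "PileupExperiment"))
    if (is.null(eps) || !is.finite(eps) || eps <= 0 || eps >= 0.75)
        stop("eps must lie in (0, 0.75)")
    nMaj <- assay(pileup, "nMajor")
    nMin <- assay(pileup, "nMinor")
    nOth <- assay(pileup, "nOther")
    if (any(nMaj < 0) || any(nMin < 0) || any(nOth < 0))
        stop("negative read counts")
    ll <- vector("list", 3)
    for (g in 0:2) {
        pM <- (1 - g / 2) * (1 - eps) + (g / 2) * (eps / 3)
        pm <- (g / 2) * (1 - eps) + (1 - g / 2) * (eps / 3)
        ll[[g + 1]] <- nMaj * log(pM) + nMin * log(pm) + nOth * log(eps / 3)
    }
    mx <- pmax(ll[[1]], ll[[2]], ll[[3]])
    ## "other" reads cancel on normalization, so the GL triple depends only
    ## on the (major, minor) count pair; the distinct pairs form a small
    ## class table that lets frequency estimation run on per-site class
    ## counts instead of the full individual matrix
    key <- nMaj * (max(nMin) + 1L) + nMin
    uk <- sort(unique(as.vector(key)))
    classId <- matrix(match(key, uk), nrow(key), ncol(key),
                      dimnames = dimnames(nMaj))
    a <- uk %/% (max(nMin) + 1L)
    b <- uk %% (max(nMin) + 1L)
    cgl <- matrix(vapply(0:2, function(g) {
        pM <- (1 - g / 2) * (1 - eps) + (g / 2) * (eps / 3)
        pm <- (g / 2) * (1 - eps) + (1 - g / 2) * (eps / 3)
        a * log(pM) + b * log(pm)
    }, numeric(length(uk))), ncol = 3)
    cgl <- exp(cgl - pmax(cgl[, 1], cgl[, 2], cgl[, 3]))
    se <- SummarizedExperiment(
        assays = list(ll0 = ll[[1]] - mx, ll1 = ll[[2]] - mx,
                      ll2 = ll[[3]] - mx, depth = nMaj + nMin + nOth,
                      classId = classId),
        rowData = rowData(pileup), colData = colData(pileup))
    metadata(se) <- c(metadata(pileup),
                      list(eps = eps,
                           classGL = cgl, classReads = a + b))
    new("GLExperiment", se)
}

## Linear-scale likelihood matrices for a site/individual subset.
.glLinear <- function(gl, sites = NULL, individuals = NULL) {
    if (is.null(sites)) sites <- seq_len(nrow(gl))
    if (is.null(individuals)) individuals <- seq_len(ncol(gl))
    list(L0 = exp(assay(gl, "ll0")[sites, individuals, drop = FALSE]),
         L1 = exp(assay(gl, "ll1")[sites, individuals, drop = FALSE]),
         L2 = exp(assay(gl, "ll2")[sites, individuals, drop = FALSE]),
         depth = assay(gl, "depth")[sites, individuals, drop = FALSE])
}

#' EM estimate of the minor-allele frequency from genotype likelihoods
#'
#' Maximizes the likelihood of the minor-allele frequency `f` under
#' Hardy-Weinberg genotype priors by EM: each individual's expected dosage
#' is computed under the current `f`, and `f` is updated as half the mean
#' expected dosage. Individuals without reads have flat likelihoods and do
#' not move the estimate. Runs on all sites simultaneously; sites converge
#' independently (|change in f| < `tol`).
#'
#' @param gl a [GLExperiment-class].
#' @param sites integer/logical site subset (default all).
#' @param individuals integer/logical individual subset (default all).
#' @param f0 EM start frequency.
#' @param tol convergence tolerance on f.
#' @param maxIter iteration cap.
#' @param newtonAfter iteration at which safeguarded Newton steps replace
#'   plain EM for still-unconverged sites (EM converges only linearly at
#'   low depth); a Newton step is accepted only if it stays inside (0, 1)
#'   and does not decrease the observed-data log-likelihood, otherwise the
#'   EM update is used, so the log-likelihood trace remains non-decreasing.
#' @return a [DataFrame][S4Vectors::DataFrame-class] with per-site `altFreq`
#'   (frequency of the designated minor/alternative allele), `logLik` at the
#'   optimum, `logLik0` at the nearest monomorphic boundary, `nIter`, and
#'   `missing` (no individual had reads; the frequency is `NA`, not zero).
#' @export
estimateMAF <- function(gl, sites = NULL, individuals = NULL,
                        f0 = 0.1, tol = 1e-8, maxIter = 200L,
                        newtonAfter = 25L) {
    stopifnot(is(gl, "GLExperiment"))
    if ("classId" %in% names(assays(gl)) &&
        !is.null(metadata(gl)$classGL))
        return(.estimateMAFClasses(gl, sites, individuals, f0, tol,
                                   maxIter, newtonAfter))
    lin <- .glLinear(gl, sites, individuals)
    M <- nrow(lin$L0); N <- ncol(lin$L0)
    if (N < 1) stop("no individuals selected")
    f <- rep(f0, M)
    nIter <- rep(0L, M)
    ## active-set bookkeeping: matrices shrink as sites converge
    act <- seq_len(M)
    A0 <- lin$L0; A1 <- lin$L1; A2 <- lin$L2
    ## individuals without reads are uninformative and are excluded from the
    ## dosage mean, so adding them never perturbs the estimate
    Z <- (lin$depth > 0) * 1
    AZ <- Z
    nCov <- pmax(rowSums(Z), 1)
    aCov <- nCov
    for (it in seq_len(maxIter)) {
        if (!length(act)) break
        fa <- f[act]
        w0 <- A0 * (1 - fa)^2
        w1 <- A1 * (2 * fa * (1 - fa))
        w2 <- A2 * fa^2
        tot <- w0 + w1 + w2
        fEM <- rowSums(((w1 + 2 * w2) / tot) * AZ) / (2 * aCov)
        if (it > newtonAfter) {
            ## safeguarded Newton on the profile log-likelihood
            dw <- -2 * A0 * (1 - fa) + 2 * A1 * (1 - 2 * fa) + 2 * A2 * fa
            d2w <- 2 * (A0 - 2 * A1 + A2)
            r <- dw / tot
            sc <- rowSums(r)
            hess <- rowSums(d2w / tot - r * r)
            fN <- fa - sc / hess
            ok <- is.finite(fN) & fN > 0 & fN < 1
            if (any(ok)) {
                llRows <- function(fv, rows) {
                    B0 <- A0[rows, , drop = FALSE]
                    B1 <- A1[rows, , drop = FALSE]
                    B2 <- A2[rows, , drop = FALSE]
                    rowSums(log(B0 * (1 - fv)^2 +
                                B1 * (2 * fv * (1 - fv)) + B2 * fv^2))
                }
                ok[ok] <- llRows(fN[ok], ok) >= llRows(fEM[ok], ok) - 1e-12
            }
            fnew <- ifelse(ok, fN, fEM)
        } else fnew <- fEM
        nIter[act] <- it
        done <- abs(fnew - fa) < tol
        f[act] <- fnew
        if (any(done)) {
            keep <- !done
            act <- act[keep]
            A0 <- A0[keep, , drop = FALSE]
            A1 <- A1[keep, , drop = FALSE]
            A2 <- A2[keep, , drop = FALSE]
            AZ <- AZ[keep, , drop = FALSE]
            aCov <- aCov[keep]
        }
    }
    covered <- rowSums(lin$depth > 0) > 0
    loglikAt <- function(fv) {
        w <- lin$L0 * (1 - fv)^2 + lin$L1 * (2 * fv * (1 - fv)) +
            lin$L2 * fv^2
        rowSums(log(w))
    }
    ll <- loglikAt(f)
    llMono <- pmax(rowSums(log(lin$L0)), rowSums(log(lin$L2)))
    f[!covered] <- NA_real_
    DataFrame(altFreq = f, logLik = ll, logLik0 = llMono, nIter = nIter,
              missing = !covered)
}

## Class-compressed frequency estimation: identical model and updates to
## the matrix path, but run on per-site counts of the distinct read-pair
## classes, which is ~2 orders of magnitude smaller at study scale.
.estimateMAFClasses <- function(gl, sites, individuals, f0, tol, maxIter,
                                newtonAfter) {
    if (is.null(sites)) sites <- seq_len(nrow(gl))
    sites <- seq_len(nrow(gl))[sites]
    if (is.null(individuals)) individuals <- seq_len(ncol(gl))
    individuals <- seq_len(ncol(gl))[individuals]
    N <- length(individuals)
    if (N < 1) stop("no individuals selected")
    cid <- assay(gl, "classId")[sites, individuals, drop = FALSE]
    Lc <- metadata(gl)$classGL              # K x 3, linear, max 1
    reads <- metadata(gl)$classReads
    M <- length(sites); K <- nrow(Lc)
    C <- matrix(tabulate(rep.int(seq_len(M), N) +
                         M * (as.vector(cid) - 1L), nbins = M * K), M, K)
    inf <- reads > 0                        # classes carrying reads
    Ci <- C
    Ci[, !inf] <- 0
    nCov <- rowSums(Ci)
    covered <- nCov > 0
    nCov <- pmax(nCov, 1)
    L0 <- Lc[, 1]; L1 <- Lc[, 2]; L2 <- Lc[, 3]
    f <- rep(f0, M)
    nIter <- rep(0L, M)
    act <- seq_len(M)
    aC <- C; aCi <- Ci; aCov <- nCov
    for (it in seq_len(maxIter)) {
        if (!length(act)) break
        fa <- f[act]
        W0 <- (1 - fa)^2 %o% L0
        W1 <- (2 * fa * (1 - fa)) %o% L1
        W2 <- fa^2 %o% L2
        tot <- W0 + W1 + W2
        fEM <- rowSums(aCi * ((W1 + 2 * W2) / tot)) / (2 * aCov)
        if (it > newtonAfter) {
            dw <- (-2 * (1 - fa)) %o% L0 + (2 * (1 - 2 * fa)) %o% L1 +
                (2 * fa) %o% L2
            r <- dw / tot
            sc <- rowSums(aC * r)
            hess <- rowSums(aC * (rep(2, length(fa)) %o%
                                  (L0 - 2 * L1 + L2) / tot - r * r))
            fN <- fa - sc / hess
            ok <- is.finite(fN) & fN > 0 & fN < 1
            if (any(ok)) {
                llRows <- function(fv, rows) {
                    w <- (1 - fv)^2 %o% L0 +
                        (2 * fv * (1 - fv)) %o% L1 + fv^2 %o% L2
                    rowSums(aC[rows, , drop = FALSE] * log(w))
                }
                ok[ok] <- llRows(fN[ok], ok) >= llRows(fEM[ok], ok) - 1e-12
            }
            fnew <- ifelse(ok, fN, fEM)
        } else fnew <- fEM
        nIter[act] <- it
        done <- abs(fnew - fa) < tol
        f[act] <- fnew
        if (any(done)) {
            keep <- !done
            act <- act[keep]
            aC <- aC[keep, , drop = FALSE]
            aCi <- aCi[keep, , drop = FALSE]
            aCov <- aCov[keep]
        }
    }
    wAt <- function(fv) (1 - fv)^2 %o% L0 + (2 * fv * (1 - fv)) %o% L1 +
        fv^2 %o% L2
    ll <- rowSums(C * log(wAt(f)))
    llMono <- pmax(as.vector(C %*% log(L0)), as.vector(C %*% log(L2)))
    f[!covered] <- NA_real_
    DataFrame(altFreq = f, logLik = ll, logLik0 = llMono, nIter = nIter,
              missing = !covered)
}

## Observed-data log-likelihood of a frequency vector; used by the EM
## monotonicity checks and the admixture K = 1 reduction.
mafLogLik <- function(gl, f, sites = NULL, individuals = NULL) {
    lin <- .glLinear(gl, sites, individuals)
    w <- lin$L0 * (1 - f)^2 + lin$L1 * (2 * f * (1 - f)) + lin$L2 * f^2
    rowSums(log(w))
}

#' Call SNPs and apply minor-allele-frequency filters
#'
#' Builds the per-site table used by every downstream stage: the EM
#' frequency estimate, a likelihood-ratio SNP test against the nearest
#' monomorphic boundary (`LRT = 2 (logL(f-hat) - logL(boundary))`, p-value
#' from the upper tail of chi-square with 1 df), and inclusive MAF filters
#' at 5% and 10% after folding to the minor-allele orientation.
#'
#' @param gl a [GLExperiment-class].
#' @param individuals individual subset used for the study-wide estimates.
#' @param snpPval SNP-calling p-value threshold.
#' @param ... passed to [estimateMAF()].
#' @return a [DataFrame][S4Vectors::DataFrame-class] (one row per site):
#'   `chrom`, `pos0`, `major`, `minor`, `altFreq`, `maf` (folded),
#'   `snpLrt`, `snpPvalue`, `passSnp`, `passMaf05`, `passMaf10`, `missing`.
#' @export
callSnps <- function(gl, individuals = NULL, snpPval = 1e-6, ...) {
    est <- estimateMAF(gl, individuals = individuals, ...)
    rd <- rowData(gl)
    f <- est$altFreq
    maf <- pmin(f, 1 - f)
    lrt <- pmax(0, 2 * (est$logLik - est$logLik0))
    p <- pchisq(lrt, df = 1, lower.tail = FALSE)
    DataFrame(chrom = rd$chrom, pos0 = rd$pos0,
              major = rd$refBase, minor = rd$altBase,
              altFreq = f, maf = maf, snpLrt = lrt, snpPvalue = p,
              passSnp = !is.na(p) & p < snpPval,
              passMaf05 = !is.na(maf) & maf >= 0.05,
              passMaf10 = !is.na(maf) & maf >= 0.10,
              missing = est$missing)
}

#' Orient major/minor alleles from a reference
#'
#' The major allele is fixed to the reference base; the minor allele is the
#' most frequent alternative by pooled counts, with ties broken
#' lexicographically (A < C < G < T). Sites where the reference allele is
#' absent from the observed alleles are flagged rather than re-oriented.
#' The operation is idempotent.
#'
#' @param baseCounts sites x 4 matrix of pooled per-base counts, columns
#'   `A`, `C`, `G`, `T`.
#' @param refAllele character vector of reference bases.
#' @return a [DataFrame][S4Vectors::DataFrame-class] with `major`, `minor`
#'   and `refAbsent`.
#' @export
majorMinorFromReference <- function(baseCounts, refAllele) {
    bases <- c("A", "C", "G", "T")
    stopifnot(ncol(baseCounts) == 4, all(refAllele %in% bases))
    colnames(baseCounts) <- bases
    M <- nrow(baseCounts)
    refIdx <- match(refAllele, bases)
    alt <- character(M)
    refAbsent <- logical(M)
    for (i in seq_len(M)) {
        cnt <- baseCounts[i, ]
        refAbsent[i] <- cnt[refIdx[i]] == 0 && sum(cnt) > 0
        cnt[refIdx[i]] <- -Inf
        alt[i] <- bases[which.max(cnt)]  # which.max takes the first maximum:
    }                                    # lexicographic tie-break
    DataFrame(major = refAllele, minor = alt, refAbsent = refAbsent)
}

#' Pooled per-base expected read counts
#'
#' Attributes each pileup's major/minor counts to the site's reference and
#' alternative bases and sums over individuals, producing the sites x 4
#' count table consumed by [majorMinorFromReference()].
#'
#' @param pileup a [PileupExperiment-class].
#' @return sites x 4 numeric matrix with columns A, C, G, T.
#' @export
pooledBaseCounts <- function(pileup) {
    bases <- c("A", "C", "G", "T")
    rd <- rowData(pileup)
    M <- nrow(pileup)
    out <- matrix(0, M, 4, dimnames = list(NULL, bases))
    maj <- rowSums(assay(pileup, "nMajor"))
    mnr <- rowSums(assay(pileup, "nMinor"))
    out[cbind(seq_len(M), match(rd$refBase, bases))] <- maj
    out[cbind(seq_len(M), match(rd$altBase, bases))] <-
        out[cbind(seq_len(M), match(rd$altBase, bases))] + mnr
    out
}

#' Write/read genotype likelihoods in Beagle text format
#'
#' Columns `marker` (`chrom_pos`, 1-based), `allele1`, `allele2` (0-3 coding
#' A, C, G, T) and three linear-scale likelihood columns per individual,
#' normalized to sum to 1 per site and individual. Reading restores the
#' normalized log-space representation (maximum 0).
#'
#' @param gl a [GLExperiment-class].
#' @param path output path; `.gz` gives a compressed file.
#' @return `path` invisibly; `readBeagle()` returns a
#'   [GLExperiment-class].
#' @export
writeBeagle <- function(gl, path) {
    bases <- c("A", "C", "G", "T")
    rd <- rowData(gl)
    L0 <- exp(assay(gl, "ll0")); L1 <- exp(assay(gl, "ll1"))
    L2 <- exp(assay(gl, "ll2"))
    tot <- L0 + L1 + L2
    L0 <- L0 / tot; L1 <- L1 / tot; L2 <- L2 / tot
    N <- ncol(gl)
    inds <- colnames(gl)
    cols <- vector("list", 3 * N)
    for (i in seq_len(N)) {
        cols[[3 * i - 2]] <- L0[, i]
        cols[[3 * i - 1]] <- L1[, i]
        cols[[3 * i]] <- L2[, i]
    }
    df <- data.frame(marker = paste0(rd$chrom, "_", rd$pos0 + 1),
                     allele1 = match(rd$refBase, bases) - 1L,
                     allele2 = match(rd$altBase, bases) - 1L,
                     cols, check.names = FALSE)
    names(df)[-(1:3)] <- rep(inds, each = 3)
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    write.table(format(df, digits = 6, scientific = FALSE, trim = TRUE),
                con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeBeagle
#' @export
readBeagle <- function(path) {
    bases <- c("A", "C", "G", "T")
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE)
    mk <- df$marker
    us <- regexpr("_[0-9]+$", mk)
    chrom <- substr(mk, 1, us - 1)
    pos1 <- as.numeric(substring(mk, us + 1))
    gcols <- as.matrix(df[, -(1:3), drop = FALSE])
    N <- ncol(gcols) / 3
    inds <- colnames(gcols)[3 * seq_len(N) - 2]
    L0 <- gcols[, 3 * seq_len(N) - 2, drop = FALSE]
    L1 <- gcols[, 3 * seq_len(N) - 1, drop = FALSE]
    L2 <- gcols[, 3 * seq_len(N), drop = FALSE]
    mx <- pmax(L0, L1, L2)
    colnames(L0) <- colnames(L1) <- colnames(L2) <- inds
    flat <- abs(L0 - L1) < 1e-12 & abs(L1 - L2) < 1e-12
    se <- SummarizedExperiment(
        assays = list(ll0 = log(L0 / mx), ll1 = log(L1 / mx),
                      ll2 = log(L2 / mx),
                      depth = matrix(as.integer(!flat), nrow(L0), N,
                                     dimnames = list(NULL, inds))),
        rowData = DataFrame(chrom = chrom, pos0 = pos1 - 1,
                            refBase = bases[df$allele1 + 1L],
                            altBase = bases[df$allele2 + 1L]),
        colData = DataFrame(individual = inds, row.names = inds))
    new("GLExperiment", se)
}

#' Write a per-site table as TSV (1-based positions, 0/1 flags)
#'
#' @param siteTable output of [callSnps()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSiteTable <- function(siteTable, path) {
    df <- as.data.frame(siteTable)
    df$pos <- df$pos0 + 1
    df$pos0 <- NULL
    for (fl in c("passSnp", "passMaf05", "passMaf10", "missing"))
        df[[fl]] <- as.integer(df[[fl]])
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
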