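clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Rolling mean over consecutive SNPs within a chromosome
#'
#' Mean of `x` over windows of `window` consecutive entries, step 1, computed
#' independently per chromosome. Entry `i` of the result is the mean of
#' `x[i:(i + window - 1)]` when that window lies fully inside chromosome
#' `chrom[i]`, and `NA` otherwise.
#'
#' @param x numeric vector (one value per SNP, position-sorted).
#' @param chrom chromosome label per SNP; `NULL` treats all as one.
#' @param window window size in SNPs.
#' @return numeric vector of the same length as `x`.
#' @export
rollingMean <- function(x, chrom = NULL, window = 100L) {
    window <- as.integer(window)
    stopifnot(window >= 1L)
    if (is.null(chrom)) chrom <- rep("chr", length(x))
    out <- rep(NA_real_, length(x))
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        n <- length(idx)
        if (n < window) next
        cs <- c(0, cumsum(x[idx]))
        m <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
        out[idx[seq_len(n - window + 1)]] <- m
    }
    out
}

## Deterministic fan-out of a run seed into per-stage child seeds, so that a
## stage can be re-run in isolation with the same stream it saw in a full run.
childSeed <- function(seed, stage) {
    offsets <- c(simfreq = 1L, simgeno = 2L, simpile = 3L, maf = 4L,
                 pca = 5L, admix = 6L, kinship = 7L, scan = 8L,
                 hapregion = 9L, diversity = 10L, load = 11L, report = 12L)
    k <- if (is.character(stage)) offsets[[stage]] else as.integer(stage)
    as.integer((as.numeric(seed) * 1009 + 7919 * k) %% 2147483647)
}

## FNV-1a over the deparsed object; used only to stamp reports.
configHash <- function(object) {
    bytes <- utf8ToInt(paste(deparse(object), collapse = "\n"))
    h <- 2166136261 %% 2147483648      # 31-bit state keeps bitwXor exact
    for (b in bytes) {
        h <- bitwXor(h, b)
        h <- (h * 16777619) %% 2147483648
    }
    sprintf("%08x", h)
}

#' Hudson-style FST from a table of population allele frequencies
#'
#' Ratio-of-averages estimator over all population pairs and sites:
#' numerator `(p1 - p2)^2`, denominator `p1 (1 - p2) + p2 (1 - p1)`, summed
#' over sites and pairs. Frequencies are treated as population parameters
#' (no sample-size correction), which is the relevant form for checking a
#' frequency-level simulator against its differentiation target. Sites
#' monomorphic across all populations contribute nothing.
#'
#' @param freqs numeric matrix, sites x populations, of allele frequencies.
#' @return a single FST value.
#' @export
hudsonFst <- function(freqs) {
    stopifnot(is.matrix(freqs), ncol(freqs) >= 2)
    num <- 0
    den <- 0
    L <- ncol(freqs)
    for (a in seq_len(L - 1)) for (b in (a + 1):L) {
        p1 <- freqs[, a]; p2 <- freqs[, b]
        num <- num + sum((p1 - p2)^2)
        den <- den + sum(p1 * (1 - p2) + p2 * (1 - p1))
    }
    if (den == 0) return(0)
    num / den
}
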