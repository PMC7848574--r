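#' Simulate per-locality true allele frequencies
#'
#' Draws, for every site, an ancestral-pool derived-allele frequency uniform
#' on [0.05, 0.95], then locality frequencies from a Balding-Nichols
#' distribution with parameter `fstTarget` around it
#' (`Beta(p (1 - F) / F, (1 - p)(1 - F) / F)`); `fstTarget = 0` makes every
#' locality carry the ancestral frequency exactly (the panmixia null).
#' Sites fall into four divergence classes for the outgroup:
#' `fixedDiff` (ingroup fixed ancestral, outgroup fixed derived),
#' `shared` (outgroup Balding-Nichols around the same ancestral frequency
#' with parameter `divergenceMafShift`), `outgroupPrivate` (polymorphic
#' only in the outgroup, at its own uniform ancestral frequency, so both
#' species carry comparable genome-wide diversity) and `private`
#' (polymorphic only in the ingroup).
#'
#' @param cfg a [SimConfig-class].
#' @return a list with per-site fields `chrom`, `pos0` (0-based, sorted),
#'   `refBase`, `altBase`, `ancestralFreq`, `siteClass`, and `freq`, a
#'   sites x (localities + outgroup) matrix of derived-allele frequencies.
#' @examples
#' fr <- simulateFrequencies(SimConfig(nSites = 200, chromLength = 1e5,
#'                                     fstTarget = 0, seed = 7))
#' stopifnot(all(apply(fr$freq[, 1:10], 1, var) == 0))
#' @export
simulateFrequencies <- function(cfg) {
    validObject(cfg)
    set.seed(childSeed(cfg@seed, "simfreq"))
    M <- cfg@nSites
    L <- cfg@nLocalities
    pos0 <- sort(sample.int(cfg@chromLength, M)) - 1
    bases <- c("A", "C", "G", "T")
    refBase <- sample(bases, M, replace = TRUE)
    altBase <- bases[(match(refBase, bases) - 1L +
                      sample.int(3L, M, replace = TRUE)) %% 4L + 1L]
    p <- runif(M, 0.05, 0.95)
    cls <- sample(c("fixedDiff", "shared", "outgroupPrivate", "private"),
                  M, replace = TRUE,
                  prob = c(cfg@outgroupFixedFraction,
                           cfg@outgroupSharedFraction,
                           cfg@outgroupPrivateFraction,
                           1 - cfg@outgroupFixedFraction -
                               cfg@outgroupSharedFraction -
                               cfg@outgroupPrivateFraction))
    bn <- function(p, F, m) {
        if (F == 0) return(p)
        rbeta(m, p * (1 - F) / F, (1 - p) * (1 - F) / F)
    }
    freq <- matrix(0, M, L + 1,
                   dimnames = list(NULL, c(sprintf("loc%02d", seq_len(L)),
                                           "outgroup")))
    for (l in seq_len(L)) freq[, l] <- bn(p, cfg@fstTarget, M)
    og <- numeric(M)
    og[cls == "fixedDiff"] <- 1
    sh <- cls == "shared"
    og[sh] <- bn(p[sh], cfg@divergenceMafShift, sum(sh))
    op <- cls == "outgroupPrivate"
    og[op] <- runif(sum(op), 0.05, 0.95)
    freq[cls %in% c("fixedDiff", "outgroupPrivate"), seq_len(L)] <- 0
    freq[, L + 1] <- og
    list(chrom = rep("chr1", M), pos0 = pos0, refBase = refBase,
         altBase = altBase, ancestralFreq = p, siteClass = cls, freq = freq)
}

## Allele counts carried by c copies of the founder haplotype 2 at the span
## sites: the founder allele a2, flipped per copy with the sparse new-mutation
## rate; haplotype 1 copies are independent draws from the diverse f1 pool.
.invHap2Dosage <- function(a2, copies, mutRate) {
    flips <- rbinom(length(a2), copies, mutRate)
    ifelse(a2 == 1, copies - flips, flips)
}

#' Simulate true genotypes (and the inversion block) from a frequency table
#'
#' Outside the inversion span, genotypes are Hardy-Weinberg binomial draws
#' from each locality's true frequency. Inside the span there is no
#' recombination: each individual carries 0-2 copies of haplotype 2, drawn
#' binomially at `inversionFreq` (ingroup) or `outgroupInversionFreq`
#' (outgroup). At a fraction `invDivergence` of span sites the two
#' haplotype classes are diverged: haplotype 1 copies are near-fixed for one
#' allele (residual within-class frequency uniform on [0.01, 0.10]) and the
#' haplotype 2 founder carries the opposite allele; the remaining span sites
#' are shared polymorphisms of the haplotype 1 pool. Haplotype 2 descends
#' from a single founder with sparse new mutations, so its homozygotes have
#' depressed diversity. When `introgressionFraction` is positive, that
#' fraction of each mid-Atlantic individual's sites is replaced, in
#' contiguous segments, by genotypes drawn from the outgroup frequencies.
#'
#' @param freqs output of [simulateFrequencies()].
#' @param cfg the same [SimConfig-class].
#' @param invMutationRate per-site new-mutation rate on haplotype 2 copies.
#' @param invDivergence fraction of span sites diverged between the two
#'   haplotype classes (the accumulated divergence of a non-recombining
#'   haplotype); the remainder are shared polymorphisms.
#' @return a [SimTruth-class].
#' @export
simulateGenotypes <- function(freqs, cfg, invMutationRate = 0.005,
                              invDivergence = 0.9) {
    validObject(cfg)
    set.seed(childSeed(cfg@seed, "simgeno"))
    M <- cfg@nSites
    L <- cfg@nLocalities
    nIn <- L * cfg@nPerLocality
    N <- nIn + cfg@nOutgroup
    locality <- c(rep(sprintf("loc%02d", seq_len(L)), each = cfg@nPerLocality),
                  rep("outgroup", cfg@nOutgroup))
    species <- c(rep("ingroup", nIn), rep("outgroup", cfg@nOutgroup))
    popcol <- ifelse(species == "outgroup", L + 1,
                     match(locality, colnames(freqs$freq)))
    geno <- matrix(0L, M, N)
    for (i in seq_len(N))
        geno[, i] <- rbinom(M, 2L, freqs$freq[, popcol[i]])

    siteClass <- freqs$siteClass
    trueFreqs <- freqs$freq
    invGeno <- rep(NA_character_, N)
    invDiff <- rep(FALSE, M)
    if (length(cfg@inversionSpan)) {
        span <- which(freqs$pos0 >= cfg@inversionSpan[1] &
                      freqs$pos0 < cfg@inversionSpan[2])
        if (!length(span))
            stop("inversion span [", cfg@inversionSpan[1], ", ",
                 cfg@inversionSpan[2], ") contains no simulated sites")
        nSpan <- length(span)
        diverged <- runif(nSpan) < invDivergence
        edge <- runif(nSpan, 0.01, 0.10)   # residual hap1-pool variation
        side <- rbinom(nSpan, 1L, 0.5)     # allele hap1 is near-fixed for
        f1 <- ifelse(diverged, ifelse(side == 1L, 1 - edge, edge),
                     freqs$ancestralFreq[span])
        a2 <- ifelse(diverged, 1L - side, rbinom(nSpan, 1L, f1))
        invDiff[span] <- diverged
        qInv <- ifelse(species == "outgroup", cfg@outgroupInversionFreq,
                       cfg@inversionFreq)
        nHap2 <- rbinom(N, 2L, qInv)
        for (i in seq_len(N)) {
            c2 <- nHap2[i]
            geno[span, i] <- rbinom(length(span), 2L - c2, f1) +
                .invHap2Dosage(a2, c2, invMutationRate)
        }
        invGeno <- c("hap1/hap1", "hap1/hap2", "hap2/hap2")[nHap2 + 1L]
        a2term <- a2 * (1 - invMutationRate) + (1 - a2) * invMutationRate
        for (pop in seq_len(L + 1)) {
            q <- if (pop == L + 1) cfg@outgroupInversionFreq else
                cfg@inversionFreq
            trueFreqs[span, pop] <- (1 - q) * f1 + q * a2term
        }
        siteClass[span] <- "inversion"
    }

    introMask <- matrix(FALSE, 0, 0)
    if (cfg@introgressionFraction > 0) {
        introMask <- matrix(FALSE, M, N)
        target <- which(species == "ingroup" &
                        locality %in% sprintf("loc%02d",
                                              cfg@midAtlanticLocalities))
        mSites <- round(cfg@introgressionFraction * M)
        nSeg <- max(1L, min(3L, mSites))
        per <- mSites %/% nSeg + (seq_len(nSeg) <= mSites %% nSeg)
        blockEnd <- round(seq_len(nSeg) * M / nSeg)
        blockStart <- c(1L, blockEnd[-nSeg] + 1L)
        for (i in target) {
            ## one segment per genome block keeps segments disjoint so each
            ## individual carries exactly the configured ancestry fraction
            idx <- unlist(lapply(seq_len(nSeg), function(s) {
                room <- blockEnd[s] - blockStart[s] + 1L - per[s]
                st <- blockStart[s] + sample.int(max(1L, room + 1L), 1L) - 1L
                seq(st, min(blockEnd[s], st + per[s] - 1L))
            }))
            geno[idx, i] <- rbinom(length(idx), 2L, freqs$freq[idx, L + 1])
            introMask[idx, i] <- TRUE
        }
    }

    ids <- c(sprintf("%s_i%02d", locality[seq_len(nIn)],
                     rep(seq_len(cfg@nPerLocality), L)),
             sprintf("outgroup_i%02d", seq_len(cfg@nOutgroup)))
    colnames(geno) <- ids
    new("SimTruth", genotypes = geno, localityLabels = locality,
        speciesLabels = species, inversionGenotype = invGeno,
        trueFreqs = trueFreqs, chrom = freqs$chrom, pos0 = freqs$pos0,
        refBase = freqs$refBase, altBase = freqs$altBase,
        siteClass = siteClass, invDiffSite = invDiff,
        introgressedMask = introMask, config = cfg)
}

#' Simulate low-coverage read pileups from true genotypes
#'
#' Per individual and site, depth is Poisson(`meanDepth`); each read reports
#' the reference allele with probability
#' `(1 - g/2)(1 - e) + (g/2) e/3`, the alternative allele with
#' `(g/2)(1 - e) + (1 - g/2) e/3`, and one of the two remaining bases
#' otherwise (errors uniform over the three non-true bases).
#'
#' @param truth a [SimTruth-class].
#' @param cfg the generating [SimConfig-class].
#' @return a [PileupExperiment-class] with the truth's site keys and
#'   individual annotations.
#' @export
simulatePileups <- function(truth, cfg) {
    validObject(cfg)
    set.seed(childSeed(cfg@seed, "simpile"))
    g <- truth@genotypes
    M <- nrow(g); N <- ncol(g)
    eps <- cfg@baseError
    depth <- matrix(rpois(M * N, cfg@meanDepth), M, N)
    pRef <- (1 - g / 2) * (1 - eps) + (g / 2) * (eps / 3)
    pAlt <- (g / 2) * (1 - eps) + (1 - g / 2) * (eps / 3)
    pOther <- 2 * eps / 3
    nRef <- matrix(rbinom(M * N, depth, pRef), M, N)
    rest <- depth - nRef
    pa <- pAlt / (pAlt + pOther)
    pa[pAlt + pOther == 0] <- 0
    nAlt <- matrix(rbinom(M * N, rest, pa), M, N)
    nOther <- rest - nAlt
    dimnames(nRef) <- dimnames(nAlt) <- dimnames(nOther) <- dimnames(g)
    rd <- DataFrame(chrom = truth@chrom, pos0 = truth@pos0,
                    refBase = truth@refBase, altBase = truth@altBase,
                    siteClass = truth@siteClass)
    cd <- DataFrame(individual = colnames(g),
                    locality = truth@localityLabels,
                    species = truth@speciesLabels,
                    inversionGenotype = truth@inversionGenotype,
                    row.names = colnames(g))
    se <- SummarizedExperiment(
        assays = list(nMajor = nRef, nMinor = nAlt, nOther = nOther),
        rowData = rd, colData = cd)
    metadata(se) <- list(baseError = eps, meanDepth = cfg@meanDepth,
                         seed = cfg@seed)
    new("PileupExperiment", se)
}

#' One-call simulation of a full study dataset
#'
#' Convenience wrapper running [simulateFrequencies()],
#' [simulateGenotypes()] and [simulatePileups()] with one configuration.
#'
#' @param cfg a [SimConfig-class].
#' @return list with elements `freqs`, `truth` and `pileup`.
#' @export
simulateStudy <- function(cfg) {
    freqs <- simulateFrequencies(cfg)
    truth <- simulateGenotypes(freqs, cfg)
    list(freqs = freqs, truth = truth, pileup = simulatePileups(truth, cfg))
}

#' Read depth per site and individual
#' @param pileup a [PileupExperiment-class].
#' @return integer matrix, sites x individuals.
#' @export
pileupDepth <- function(pileup) {
    assay(pileup, "nMajor") + assay(pileup, "nMinor") +
        assay(pileup, "nOther")
}

#' Write/read pileups as long-format TSV
#'
#' Columns `chrom`, `pos` (1-based), `individual_id`, `n_major`, `n_minor`,
#' `n_other`; use a `.gz` path for compression. Individual annotations and
#' the error rate travel in `# key=value` header lines.
#'
#' @param pileup a [PileupExperiment-class].
#' @param path output path.
#' @return `path`, invisibly; `readPileups()` returns the reconstructed
#'   [PileupExperiment-class].
#' @export
writePileups <- function(pileup, path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    rd <- rowData(pileup)
    cd <- colData(pileup)
    writeLines(c(
        paste0("# baseError=", metadata(pileup)$baseError),
        paste0("# individuals=", paste(cd$individual, collapse = ",")),
        paste0("# locality=", paste(cd$locality, collapse = ",")),
        paste0("# species=", paste(cd$species, collapse = ",")),
        paste0("# refBase=", paste(rd$refBase, collapse = "")),
        paste0("# altBase=", paste(rd$altBase, collapse = ""))), con)
    M <- nrow(pileup); N <- ncol(pileup)
    df <- data.frame(
        chrom = rep(rd$chrom, N), pos = rep(rd$pos0 + 1, N),
        individual_id = rep(cd$individual, each = M),
        n_major = as.vector(assay(pileup, "nMajor")),
        n_minor = as.vector(assay(pileup, "nMinor")),
        n_other = as.vector(assay(pileup, "nOther")))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writePileups
#' @export
readPileups <- function(path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
    hdr <- character()
    repeat {
        ln <- readLines(con, 1)
        if (!startsWith(ln, "#")) break
        hdr <- c(hdr, sub("^# ", "", ln))
    }
    close(con)
    kv <- strsplit(hdr, "=", fixed = TRUE)
    meta <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "#",
                            colClasses = c("character", "numeric",
                                           "character", "integer",
                                           "integer", "integer"))
    inds <- strsplit(meta[["individuals"]], ",")[[1]]
    key <- paste(df$chrom, df$pos)
    ukey <- unique(key)
    M <- length(ukey); N <- length(inds)
    row <- match(key, ukey)
    col <- match(df$individual_id, inds)
    shape <- function(v) {
        m <- matrix(0L, M, N)
        m[cbind(row, col)] <- v
        colnames(m) <- inds
        m
    }
    first <- !duplicated(key)
    rd <- DataFrame(chrom = df$chrom[first], pos0 = df$pos[first] - 1,
                    refBase = strsplit(meta[["refBase"]], "")[[1]],
                    altBase = strsplit(meta[["altBase"]], "")[[1]],
                    siteClass = NA_character_)
    cd <- DataFrame(individual = inds,
                    locality = strsplit(meta[["locality"]], ",")[[1]],
                    species = strsplit(meta[["species"]], ",")[[1]],
                    row.names = inds)
    se <- SummarizedExperiment(
        assays = list(nMajor = shape(df$n_major), nMinor = shape(df$n_minor),
                      nOther = shape(df$n_other)),
        rowData = rd, colData = cd)
    metadata(se) <- list(baseError = as.numeric(meta[["baseError"]]))
    new("PileupExperiment", se)
}

#' Write simulation truth tables as TSV
#'
#' Emits `genotypes.tsv.gz` (site keys + one dosage column per individual),
#' `labels.tsv.gz` (individual, locality, species, inversion genotype) and
#' `freqs.tsv.gz` (per-population true derived-allele frequencies), with
#' 1-based positions in the files.
#'
#' @param truth a [SimTruth-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeTruth <- function(truth, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    gz <- function(name) gzfile(file.path(dir, name), "w")
    key <- data.frame(chrom = truth@chrom, pos = truth@pos0 + 1,
                      ref = truth@refBase, alt = truth@altBase,
                      class = truth@siteClass)
    con <- gz("genotypes.tsv.gz")
    write.table(cbind(key, truth@genotypes), con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    close(con)
    con <- gz("labels.tsv.gz")
    write.table(data.frame(individual = colnames(truth@genotypes),
                           locality = truth@localityLabels,
                           species = truth@speciesLabels,
                           inversion_genotype = truth@inversionGenotype),
                con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    con <- gz("freqs.tsv.gz")
    write.table(cbind(key, truth@trueFreqs), con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    close(con)
    invisible(dir)
}
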