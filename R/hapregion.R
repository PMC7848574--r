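#' Select the SNPs driving a selection signal in a region
#'
#' Ranks the scanned SNPs inside a candidate region by their selection
#' statistic and keeps the top fraction (at least 20 SNPs, the minimum for a
#' usable kinship signal), with ties broken by position.
#'
#' @param selTrack output of [pcSelectionScan()].
#' @param chrom,start0,end0 region, 0-based half-open.
#' @param topFraction fraction of region SNPs kept (default 0.10).
#' @return integer indices into `selTrack` rows, position-sorted.
#' @export
selectRegionSNPs <- function(selTrack, chrom, start0, end0,
                             topFraction = 0.10) {
    inReg <- which(selTrack$chrom == chrom & selTrack$pos0 >= start0 &
                   selTrack$pos0 < end0)
    m <- length(inReg)
    if (m < 20)
        stop(sprintf("region %s:[%d, %d) overlaps only %d scanned SNPs",
                     chrom, as.integer(start0), as.integer(end0), m))
    nKeep <- max(20L, as.integer(ceiling(topFraction * m)))
    nKeep <- min(nKeep, m)
    ord <- inReg[order(-selTrack$stat[inReg], selTrack$pos0[inReg])]
    sort(ord[seq_len(nKeep)])
}

## Exact 1-D k-means by dynamic programming over the sorted values:
## globally optimal within-cluster sum of squares, deterministic and
## invariant to input order. Returns cluster ids (1..k, in increasing order
## of center) and the centers.
.kmeans1dExact <- function(x, k) {
    n <- length(x)
    ord <- order(x)
    xs <- x[ord]
    cs <- c(0, cumsum(xs))
    cs2 <- c(0, cumsum(xs^2))
    cost <- function(i, j)   # SSQ of xs[i..j]
        (cs2[j + 1] - cs2[i]) - (cs[j + 1] - cs[i])^2 / (j - i + 1)
    D <- matrix(Inf, k, n)
    B <- matrix(0L, k, n)
    for (j in 1:n) D[1, j] <- cost(1, j)
    if (k > 1) for (m in 2:k) for (j in m:n) {
        for (t in m:j) {
            v <- D[m - 1, t - 1] + cost(t, j)
            if (v < D[m, j]) { D[m, j] <- v; B[m, j] <- t }
        }
    }
    bounds <- integer(k + 1)
    bounds[k + 1] <- n
    j <- n
    for (m in k:2) {
        bounds[m] <- B[m, j] - 1L
        j <- B[m, j] - 1L
    }
    cl <- integer(n)
    centers <- numeric(k)
    for (m in 1:k) {
        rng <- (bounds[m] + 1):bounds[m + 1]
        cl[ord[rng]] <- m
        centers[m] <- mean(xs[rng])
    }
    list(cluster = cl, centers = centers)
}

## Mean silhouette for a 1-D 3-cluster assignment.
.silhouette1d <- function(x, cl) {
    s <- numeric(length(x))
    for (i in seq_along(x)) {
        own <- mean(abs(x[i] - x[cl == cl[i]][-match(i, which(cl == cl[i]))]))
        if (!is.finite(own)) own <- 0
        oth <- min(vapply(setdiff(unique(cl), cl[i]),
                          function(k) mean(abs(x[i] - x[cl == k])), 0))
        s[i] <- if (max(own, oth) > 0) (oth - own) / max(own, oth) else 0
    }
    mean(s)
}

#' Genotype individuals for a candidate inversion via kinship clustering
#'
#' Projects individuals on the leading eigenvector of the region kinship
#' matrix, clusters the projection with exact 1-D k-means (k = 3, solved by
#' dynamic programming, so the optimum is deterministic and independent of
#' input order), orders clusters by their mean regional minor dosage and
#' labels them `hom1 < het < hom2`. Individuals farther than 3
#' within-cluster standard deviations from their center, or with missing
#' kinship, are left `unassigned`. If the three clusters are not
#' distinguishable (mean silhouette < 0.2) everything is unassigned with a
#' warning.
#'
#' @param kin kinship matrix from [kinshipFromGLs()] on the region SNPs.
#' @param gl the [GLExperiment-class] the kinship was computed from.
#' @param snpSubset region SNP indices (as used for `kin`).
#' @param individuals individual subset matching `kin`'s rows.
#' @param locality per-individual locality labels (defaults to the `locality`
#'   column of `colData(gl)`).
#' @param chrom,start0,end0 region annotation for the result.
#' @return a [HaplotypeCallSet-class].
#' @export
clusterThreeGroups <- function(kin, gl, snpSubset, individuals = NULL,
                               locality = NULL, chrom = NA_character_,
                               start0 = NA_real_, end0 = NA_real_) {
    if (is.null(individuals)) individuals <- seq_len(ncol(gl))
    individuals <- seq_len(ncol(gl))[individuals]
    N <- length(individuals)
    stopifnot(nrow(kin) == N)
    if (is.null(locality)) locality <- colData(gl)$locality[individuals]
    est <- estimateMAF(gl, sites = snpSubset, individuals = individuals)
    f <- ifelse(is.na(est$altFreq), 0.5, est$altFreq)
    lin <- .glLinear(gl, snpSubset, individuals)
    eg <- .posteriorDosage(lin$L0, lin$L1, lin$L2, f)
    ## fold to minor-allele orientation: haplotype 2 is the minor regional
    ## haplotype, so its carriers have the higher mean minor dosage
    flip <- f > 0.5
    eg[flip, ] <- 2 - eg[flip, , drop = FALSE]
    meanDos <- colMeans(eg)
    ids <- colnames(gl)[individuals]

    ok <- rowSums(is.na(kin)) < N
    group <- rep("unassigned", N)
    kin0 <- kin
    kin0[is.na(kin0)] <- 0
    ev <- eigen(kin0, symmetric = TRUE)$vectors[, 1]
    x <- ev[ok]
    degenerate <- FALSE
    if (length(unique(round(x, 12))) < 3) {
        degenerate <- TRUE
    } else {
        km <- .kmeans1dExact(x, 3L)
        cl <- km$cluster
        if (length(unique(cl)) < 3 || .silhouette1d(x, cl) < 0.2) {
            degenerate <- TRUE
        } else {
            ## order clusters by mean regional minor dosage
            dosByCl <- vapply(1:3, function(k)
                mean(meanDos[ok][cl == k]), 0)
            lab <- c("hom1", "het", "hom2")[rank(dosByCl)]
            assigned <- lab[cl]
            ## 3-SD outlier rule within clusters
            for (kk in 1:3) {
                mk <- cl == kk
                sdk <- sd(x[mk])
                if (!is.finite(sdk) || sdk == 0) next
                far <- abs(x[mk] - km$centers[kk]) > 3 * sdk
                assigned[mk][far] <- "unassigned"
            }
            group[ok] <- assigned
        }
    }
    if (degenerate)
        warning("fewer than 3 distinguishable clusters; ",
                "all individuals unassigned")
    isA <- group != "unassigned"
    dos2 <- c(hom1 = 0, het = 1, hom2 = 2)
    hapCount <- function(sel) {
        g <- group[sel & isA]
        c(hap2 = sum(dos2[g]), hap1 = sum(2 - dos2[g]))
    }
    locs <- sort(unique(locality))
    perLoc <- vapply(locs, function(l) {
        hc <- hapCount(locality == l)
        hc["hap2"] / max(1, sum(hc))
    }, 0)
    names(perLoc) <- locs
    overall <- {
        hc <- hapCount(rep(TRUE, N))
        if (sum(hc) > 0) unname(hc["hap2"] / sum(hc)) else NA_real_
    }
    names(group) <- ids
    names(meanDos) <- ids
    new("HaplotypeCallSet", chrom = chrom, start0 = start0, end0 = end0,
        snpIndex = as.integer(snpSubset), group = group,
        meanDosage = meanDos, locality = as.character(locality),
        hap2Freq = perLoc, hap2FreqOverall = overall)
}

#' Per-individual windowed dosage profiles along a chromosome
#'
#' Sliding windows of `window` consecutive SNPs (step `step`): per
#' individual, the mean posterior expected minor-allele dosage in the window
#' (dosages folded per site so the counted allele is the less frequent one),
#' centered by the cohort mean of that window. Inside a non-recombining
#' block the minor alleles of the differentiating sites are the
#' haplotype 2 alleles, so the three haplotype genotypes separate into three
#' bands; the bands collapse toward zero outside the block.
#'
#' @param gl a [GLExperiment-class].
#' @param individuals individual subset.
#' @param chrom chromosome to profile.
#' @param window,step window size and step, in SNPs.
#' @return list with `windows` (a [DataFrame][S4Vectors::DataFrame-class] of
#'   window start/end positions and SNP index ranges) and `profile`
#'   (windows x individuals centered dosage matrix).
#' @export
windowedDosageProfiles <- function(gl, individuals = NULL, chrom = NULL,
                                   window = 100L, step = 10L) {
    rd <- rowData(gl)
    if (is.null(chrom)) chrom <- rd$chrom[1]
    sites <- which(rd$chrom == chrom)
    if (is.null(individuals)) individuals <- seq_len(ncol(gl))
    individuals <- seq_len(ncol(gl))[individuals]
    est <- estimateMAF(gl, sites = sites, individuals = individuals)
    f <- ifelse(is.na(est$altFreq), 0.5, est$altFreq)
    lin <- .glLinear(gl, sites, individuals)
    eg <- .posteriorDosage(lin$L0, lin$L1, lin$L2, f)
    flip <- f > 0.5                    # fold to minor-allele orientation
    eg[flip, ] <- 2 - eg[flip, , drop = FALSE]
    M <- length(sites)
    if (M < window) stop("fewer than ", window, " SNPs on ", chrom)
    starts <- seq(1L, M - window + 1L, by = step)
    cs <- rbind(0, apply(eg, 2, cumsum))
    prof <- (cs[starts + window, , drop = FALSE] -
             cs[starts, , drop = FALSE]) / window
    prof <- prof - rowMeans(prof)
    rownames(prof) <- NULL
    colnames(prof) <- colnames(gl)[individuals]
    win <- DataFrame(chrom = chrom,
                     startPos0 = rd$pos0[sites[starts]],
                     endPos0 = rd$pos0[sites[starts + window - 1L]] + 1,
                     firstSnp = starts, lastSnp = starts + window - 1L)
    list(windows = win, profile = prof)
}

#' Tajima's D for one haplotype group across a region
#'
#' Restricts the genotype likelihoods to one cluster of individuals (at
#' least 4), runs the site-allele-frequency / site-frequency-spectrum
#' machinery on the region, and returns per-window diversity statistics.
#'
#' @param gl a [GLExperiment-class].
#' @param callset a [HaplotypeCallSet-class].
#' @param group `"hom1"` or `"hom2"`.
#' @param ancestral per-site ancestral states (`"ref"`, `"alt"` or `"N"`),
#'   as from [outgroupConsensus()] or the simulation truth.
#' @param chrom,start0,end0 region to window (defaults to the callset's).
#' @param windowBp window size in bp.
#' @param individuals the individual subset the callset was computed on.
#' @return a [DataFrame][S4Vectors::DataFrame-class] as from
#'   [windowThetas()].
#' @export
groupTajimasD <- function(gl, callset, group, ancestral,
                          chrom = callset@chrom, start0 = callset@start0,
                          end0 = callset@end0, windowBp = 5000L,
                          individuals = NULL) {
    stopifnot(group %in% c("hom1", "het", "hom2"))
    if (is.null(individuals)) individuals <- seq_len(ncol(gl))
    individuals <- seq_len(ncol(gl))[individuals]
    members <- individuals[callset@group == group]
    if (length(members) < 4)
        stop("group ", group, " has fewer than 4 individuals")
    rd <- rowData(gl)
    sites <- which(rd$chrom == chrom & rd$pos0 >= start0 & rd$pos0 < end0)
    saf <- safPerSite(gl, ancestral = ancestral, sites = sites,
                      individuals = members)
    sfs <- sfsEM(saf)
    windowThetas(saf, sfs, windowBp = windowBp)
}

#' Chi-square homogeneity test of haplotype frequency across localities
#'
#' Tests whether the haplotype 2 frequency differs among localities using
#' the standard Pearson chi-square statistic on the 2 x L table of hap2/hap1
#' allele counts (two alleles per assigned individual); df = L - 1.
#' Localities with no assigned individuals are dropped with a warning.
#'
#' @param callset a [HaplotypeCallSet-class].
#' @return list with `statistic`, `df`, `pvalue` and the counts `table`.
#' @export
frequencyHomogeneityTest <- function(callset) {
    ok <- callset@group != "unassigned" & callset@locality != "outgroup"
    dos2 <- c(hom1 = 0, het = 1, hom2 = 2)
    locs <- sort(unique(callset@locality[callset@locality != "outgroup"]))
    tab <- t(vapply(locs, function(l) {
        g <- callset@group[ok & callset@locality == l]
        c(hap2 = sum(dos2[g]), hap1 = sum(2 - dos2[g]))
    }, c(hap2 = 0, hap1 = 0)))
    empty <- rowSums(tab) == 0
    if (any(empty)) {
        warning("dropping localities with no assigned individuals: ",
                paste(locs[empty], collapse = ", "))
        tab <- tab[!empty, , drop = FALSE]
    }
    if (nrow(tab) < 2) stop("need at least 2 localities with assignments")
    identical_rows <- all(abs(tab[, 1] / rowSums(tab) -
                              sum(tab[, 1]) / sum(tab)) < 1e-12)
    if (identical_rows) {
        res <- list(statistic = 0, df = nrow(tab) - 1L, pvalue = 1)
    } else {
        ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
        res <- list(statistic = unname(ct$statistic),
                    df = unname(ct$parameter), pvalue = ct$p.value)
    }
    c(res, list(table = tab))
}

#' Write haplotype calls as TSV
#' @param callset a [HaplotypeCallSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHaplotypeCalls <- function(callset, path) {
    df <- data.frame(individual = names(callset@group),
                     locality = callset@locality,
                     group = callset@group,
                     mean_dosage = callset@meanDosage)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
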