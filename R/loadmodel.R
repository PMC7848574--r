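#' One generation of codominant viability selection
#'
#' Deterministic recursion under genotype fitnesses
#' `1 : 1 - s/2 : 1 - s` for the favored-allele frequency `p`:
#' `p' = (p^2 + p q (1 - s/2)) / wbar`,
#' `wbar = p^2 + 2 p q (1 - s/2) + q^2 (1 - s)`.
#'
#' @param p current favored-allele frequency.
#' @param s selection coefficient in [0, 1].
#' @return the frequency after one generation.
#' @export
nextFrequency <- function(p, s) {
    q <- 1 - p
    (p^2 + p * q * (1 - s / 2)) / (1 - s * q)
}

#' Selection coefficient required for a one-generation frequency shift
#'
#' Closed-form inversion of the codominant recursion: with `q = 1 - p0` and
#' target `p' = p0 + deltaP`, `s = deltaP / (q (p' - p0 / 2))`. The result
#' is verified by forward-iterating the recursion (round-trip agreement to
#' 1e-12).
#'
#' @param p0 starting allele frequency in (0, 1).
#' @param deltaP required per-generation shift (0 < deltaP < 1 - p0).
#' @return the selection coefficient `s`.
#' @examples
#' solveSelectionCoefficient(0.5, 0.05)  # 1/3
#' @export
solveSelectionCoefficient <- function(p0, deltaP) {
    stopifnot(p0 > 0, p0 < 1)
    if (deltaP < 0 || p0 + deltaP >= 1)
        stop("infeasible shift: p0 + deltaP must stay below 1")
    if (deltaP == 0) return(0)
    q <- 1 - p0
    pT <- p0 + deltaP
    s <- deltaP / (q * (pT - p0 / 2))
    if (s > 1)
        stop("infeasible shift: requires selection coefficient > 1")
    if (abs(nextFrequency(p0, s) - pT) > 1e-12)
        stop("internal error: recursion round-trip failed")
    s
}

#' Per-locus survival under codominant selection
#'
#' Mean fitness at frequency `p0` relative to the fittest genotype
#' (fitness 1): the fraction of a cohort surviving viability selection at
#' one locus.
#'
#' @param s selection coefficient.
#' @param p0 allele frequency at selection.
#' @return survival fraction in (0, 1].
#' @export
survivalFraction <- function(s, p0) {
    q <- 1 - p0
    p0^2 + 2 * p0 * q * (1 - s / 2) + q^2 * (1 - s)
}

#' Joint survival and mortality across independent loci
#'
#' Per-locus survival (for the `s` solving the requested shift) raised to
#' the number of loci, assuming independent loci with multiplicative
#' survival; mortality is its complement. The reciprocal survival is also
#' reported rounded to the nearest power of ten.
#'
#' @param p0 starting allele frequency.
#' @param deltaP per-locus frequency shift per generation.
#' @param nLoci number of loci (0 gives survival 1).
#' @return list with `s`, `perLocusSurvival`, `jointSurvival`, `mortality`,
#'   `mortalityPercent` (nearest integer percent) and
#'   `reciprocalSurvivalPow10` (power of ten nearest to 1/survival).
#' @examples
#' jointSurvival(0.5, 0.05, 10)$mortalityPercent   # 84
#' jointSurvival(0.5, 0.05, 100)$reciprocalSurvivalPow10  # 1e8
#' @export
jointSurvival <- function(p0, deltaP, nLoci) {
    stopifnot(nLoci >= 0)
    s <- solveSelectionCoefficient(p0, deltaP)
    surv1 <- survivalFraction(s, p0)
    joint <- surv1^nLoci
    list(s = s,
         perLocusSurvival = surv1,
         jointSurvival = joint,
         mortality = 1 - joint,
         mortalityPercent = round(100 * (1 - joint)),
         reciprocalSurvivalPow10 = 10^round(log10(1 / joint)))
}

#' Selection-load table over locus counts
#'
#' @param p0 starting allele frequency (default 0.5).
#' @param deltaP per-locus shift per generation.
#' @param nLoci vector of locus counts.
#' @return data.frame with one row per locus count.
#' @export
selectionLoadTable <- function(p0 = 0.5, deltaP = 0.05,
                               nLoci = c(1, 10, 100)) {
    rows <- lapply(nLoci, function(L) {
        js <- jointSurvival(p0, deltaP, L)
        data.frame(nLoci = L, s = js$s,
                   perLocusSurvival = js$perLocusSurvival,
                   jointSurvival = js$jointSurvival,
                   mortality = js$mortality,
                   mortalityPercent = js$mortalityPercent,
                   reciprocalSurvivalPow10 = js$reciprocalSurvivalPow10)
    })
    do.call(rbind, rows)
}

#' Wright-Fisher cohort check of the deterministic load model
#'
#' Simulates a finite cohort at `nLoci` independent loci in Hardy-Weinberg
#' proportions at frequency `p0`, applies multiplicative viability selection
#' with the fitnesses `1 : 1 - s/2 : 1 - s`, and reports the realized
#' survivor fraction and per-locus allele-frequency shift.
#'
#' @param p0,deltaP,nLoci scenario; `s` is solved from `deltaP`.
#' @param n cohort size.
#' @param seed integer seed.
#' @return list with `survival` and `meanShift` (mean realized shift over
#'   loci).
#' @export
simulateSelectionCohort <- function(p0, deltaP, nLoci, n = 1e6, seed = 1L) {
    set.seed(seed)
    s <- solveSelectionCoefficient(p0, deltaP)
    g <- matrix(rbinom(n * nLoci, 2L, p0), n, nLoci)
    w <- c(1 - s, 1 - s / 2, 1)[g + 1L]  # fitness by favored-allele dosage
    dim(w) <- dim(g)
    fit <- exp(rowSums(log(w)))
    alive <- runif(n) < fit
    list(survival = mean(alive),
         meanShift = mean(colMeans(g[alive, , drop = FALSE]) / 2) - p0)
}
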