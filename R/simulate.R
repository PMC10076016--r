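# Deterministic synthetic-data generators. Each is a pure function of its
# arguments including the mandatory seed (withr::with_seed, so the caller's
# RNG state is untouched): codon pairs diverging at a controlled dN/dS,
# population samples with planted polymorphism/divergence events, and
# allele-frequency matrices whose logit depends linearly on an ecological
# covariate for planted signal genes.

.senseCodons <- function() {
    tab <- .codonTables()
    setdiff(tab$codons, tab$stops)
}

#' Simulate a pair of coding sequences diverging at a target dN/dS
#'
#' Starts from a random stop-free coding sequence and evolves a copy by
#' proposing uniform single-nucleotide changes (proposals creating stop
#' codons are rejected), accepting synonymous proposals with probability
#' `min(1, 1/omegaTarget)` and nonsynonymous ones with probability
#' `min(1, omegaTarget)`, until the target proportion of sites differs from
#' the ancestor. For long sequences the counting estimator recovers
#' `omegaTarget` in expectation.
#'
#' @param nCodons Number of codons (>= 10).
#' @param omegaTarget Target dN/dS (>= 0; `0` permits only synonymous change).
#' @param divergence Target proportion of differing nucleotide sites
#'   (default 0.05).
#' @param seed Integer seed (required).
#' @return A list with `alignment` (a 2-row [CodonAlignment-class]:
#'   `ancestor`, `derived`) and `truth`
#'   (`omega_target`, `n_diff_sites`, `n_syn_accepted`, `n_nonsyn_accepted`).
#' @export
simulateCodingPair <- function(nCodons, omegaTarget, divergence = 0.05, seed) {
    if (missing(seed)) stop("an explicit integer 'seed' is required")
    stopifnot(nCodons >= 10L, divergence > 0, divergence < 0.5)
    if (omegaTarget < 0)
        stop("'omegaTarget' must be >= 0")
    tab <- .codonTables()
    pSyn <- if (omegaTarget > 1) 1 / omegaTarget else 1
    pNon <- min(1, omegaTarget)
    withr::with_seed(as.integer(seed), {
        anc <- unlist(strsplit(sample(.senseCodons(), nCodons, replace = TRUE),
                               ""))
        der <- anc
        nSites <- 3L * nCodons
        target <- max(1L, round(divergence * nSites))
        nDiff <- 0L
        nSynAcc <- 0L; nNonAcc <- 0L
        maxIter <- 5000L * target
        iter <- 0L
        while (nDiff < target && iter < maxIter) {
            iter <- iter + 1L
            pos <- sample.int(nSites, 1L)
            newBase <- sample(setdiff(.bases, der[pos]), 1L)
            cd <- (pos - 1L) %/% 3L
            idx <- (3L * cd + 1L):(3L * cd + 3L)
            oldCodon <- paste(der[idx], collapse = "")
            cand <- der[idx]
            cand[pos - 3L * cd] <- newBase
            newCodon <- paste(cand, collapse = "")
            if (newCodon %in% tab$stops)
                next
            syn <- tab$aa[newCodon] == tab$aa[oldCodon]
            pAcc <- if (syn) pSyn else pNon
            if (pAcc < 1 && stats::runif(1L) > pAcc)
                next
            wasDiff <- der[pos] != anc[pos]
            der[pos] <- newBase
            isDiff <- der[pos] != anc[pos]
            nDiff <- nDiff + (isDiff - wasDiff)
            if (syn) nSynAcc <- nSynAcc + 1L else nNonAcc <- nNonAcc + 1L
        }
        if (nDiff < target)
            stop("could not reach the target divergence (too constrained)")
        aln <- CodonAlignment(c(ancestor = paste(anc, collapse = ""),
                                derived = paste(der, collapse = "")))
        list(alignment = aln,
             truth = list(omega_target = omegaTarget, n_diff_sites = nDiff,
                          n_syn_accepted = nSynAcc,
                          n_nonsyn_accepted = nNonAcc))
    })
}

# pick a single-nucleotide substitution of the requested class for a codon;
# returns list(pos 1..3, base, syn) or NULL if the class is unavailable
.pickSubstitution <- function(codon, wantSyn, tab) {
    chars <- strsplit(codon, "")[[1L]]
    opts <- list()
    for (p in 1:3) for (b in setdiff(.bases, chars[p])) {
        cand <- chars; cand[p] <- b
        cc <- paste(cand, collapse = "")
        if (cc %in% tab$stops) next
        syn <- tab$aa[cc] == tab$aa[codon]
        if (syn == wantSyn)
            opts[[length(opts) + 1L]] <- list(pos = p, base = b, syn = syn)
    }
    if (length(opts) == 0L)
        return(NULL)
    opts[[sample.int(length(opts), 1L)]]
}

#' Simulate a population sample with planted polymorphism and divergence
#'
#' Builds a random stop-free coding sequence, then plants `nDivergences`
#' fixed differences on the outgroup branch and `nPolymorphisms` segregating
#' sites within the ingroup (derived-allele counts uniform on
#' `1..nSamples-1`), each event at a distinct codon and independently
#' nonsynonymous with the configured proportion. Because events never share a
#' codon, [classifySites()] recovers the planted table exactly.
#'
#' @param nCodons Codons in the gene (must exceed
#'   `nPolymorphisms + nDivergences`).
#' @param nSamples Ingroup haplotypes (>= 2).
#' @param nPolymorphisms,nDivergences Numbers of planted events.
#' @param propNonsynPoly,propNonsynDiv Probability that an event is
#'   nonsynonymous (a codon lacking the requested class, e.g. ATG for a
#'   synonymous event, falls back to the other class; the truth table
#'   records realised classes).
#' @param seed Integer seed (required).
#' @return A list with `popaln` (a [PopulationAlignment-class]) and `truth`
#'   (the realised [MKTable-class] and the per-event records).
#' @export
simulatePopulationCds <- function(nCodons = 600L, nSamples = 20L,
                                  nPolymorphisms = 160L, nDivergences = 160L,
                                  propNonsynPoly = 0.5, propNonsynDiv = 0.5,
                                  seed) {
    if (missing(seed)) stop("an explicit integer 'seed' is required")
    stopifnot(nSamples >= 2L, nPolymorphisms >= 0L, nDivergences >= 0L,
              propNonsynPoly >= 0, propNonsynPoly <= 1,
              propNonsynDiv >= 0, propNonsynDiv <= 1)
    nEvents <- nPolymorphisms + nDivergences
    if (nEvents > nCodons)
        stop(sprintf("requested %d events exceed the %d available codons",
                     nEvents, nCodons))
    tab <- .codonTables()
    withr::with_seed(as.integer(seed), {
        codons <- sample(.senseCodons(), nCodons, replace = TRUE)
        base <- unlist(strsplit(codons, ""))
        ing <- matrix(rep(base, nSamples), nrow = nSamples, byrow = TRUE)
        outg <- base
        eventCodons <- sample.int(nCodons, nEvents)
        events <- data.frame(codon = eventCodons,
                             type = rep(c("poly", "div"),
                                        c(nPolymorphisms, nDivergences)),
                             syn = NA, derived_count = NA_integer_)
        Dn <- Ds <- Pn <- Ps <- 0L
        for (e in seq_len(nEvents)) {
            cd <- events$codon[e]
            wantSyn <- stats::runif(1L) >=
                if (events$type[e] == "poly") propNonsynPoly else propNonsynDiv
            sub <- .pickSubstitution(codons[cd], wantSyn, tab)
            if (is.null(sub))   # codon lacks that class; take the other
                sub <- .pickSubstitution(codons[cd], !wantSyn, tab)
            ntPos <- 3L * (cd - 1L) + sub$pos
            events$syn[e] <- sub$syn
            if (events$type[e] == "poly") {
                d <- sample.int(nSamples - 1L, 1L)
                carriers <- sample.int(nSamples, d)
                ing[carriers, ntPos] <- sub$base
                events$derived_count[e] <- d
                if (sub$syn) Ps <- Ps + 1L else Pn <- Pn + 1L
            } else {
                outg[ntPos] <- sub$base
                if (sub$syn) Ds <- Ds + 1L else Dn <- Dn + 1L
            }
        }
        haps <- apply(ing, 1L, paste, collapse = "")
        names(haps) <- sprintf("hap%d", seq_len(nSamples))
        popaln <- PopulationAlignment(CodonAlignment(haps),
                                      paste(outg, collapse = ""))
        list(popaln = popaln,
             truth = list(table = MKTable(Dn, Ds, Pn, Ps), events = events))
    })
}

#' Simulate an allele-frequency / environment dataset
#'
#' Generates `nPops` populations with `nVars` standard-normal ecological
#' variables (optionally sharing a latent factor, mimicking correlated
#' bioclimatic summaries) and `nGenes` genes of `variantsPerGene` biallelic
#' variants each. For a planted signal gene, every variant's true
#' alternate-allele frequency follows
#' `logit(AF_p) = a + betaEffect * z_p` with intercept `a ~ Normal(-1, 0.5)`
#' and `z` the first ecological variable; null genes have slope 0. Observed
#' counts are `AC ~ Binomial(AN, AF_p)` with `AN` fixed at `meanAN` called
#' alleles per population. Per-gene random substreams keep earlier genes
#' byte-identical when genes are added.
#'
#' @param nGenes,variantsPerGene,nPops,nVars Dataset dimensions
#'   (`nPops >= 5`).
#' @param fracSignal Fraction of genes planted with an environmental effect.
#' @param betaEffect Logit-scale slope for signal genes.
#' @param meanAN Called alleles per population (>= 2).
#' @param latentRho Correlation of each variable with a shared latent factor
#'   (0 = independent variables).
#' @param seed Integer seed (required).
#' @return A list with `fm` (a [FrequencyMatrix-class]; `rowData` carries
#'   `gene`), `eco` (populations x variables `data.frame`), and `truth`
#'   (per gene: `gene`, `is_signal`, `beta`).
#' @export
simulateEnvDataset <- function(nGenes = 200L, variantsPerGene = 20L,
                               nPops = 25L, nVars = 3L, fracSignal = 0.005,
                               betaEffect = 1.5, meanAN = 40L,
                               latentRho = 0, seed) {
    if (missing(seed)) stop("an explicit integer 'seed' is required")
    stopifnot(nPops >= 5L, nGenes >= 1L, variantsPerGene >= 1L,
              fracSignal >= 0, fracSignal <= 1, latentRho >= 0, latentRho < 1)
    if (meanAN < 2L)
        stop("'meanAN' must be >= 2")
    seed <- as.integer(seed)
    setup <- withr::with_seed(seed, {
        latent <- stats::rnorm(nPops)
        eco <- vapply(seq_len(nVars), function(v)
            sqrt(latentRho) * latent + sqrt(1 - latentRho) * stats::rnorm(nPops),
            numeric(nPops))
        nSignal <- round(fracSignal * nGenes)
        signal <- sort(sample.int(nGenes, nSignal))
        list(eco = eco, signal = signal)
    })
    eco <- as.data.frame(setup$eco)
    names(eco) <- sprintf("env%d", seq_len(nVars))
    rownames(eco) <- sprintf("pop%d", seq_len(nPops))
    z <- setup$eco[, 1L]

    AC <- matrix(0L, nGenes * variantsPerGene, nPops)
    for (g in seq_len(nGenes)) {
        beta <- if (g %in% setup$signal) betaEffect else 0
        block <- withr::with_seed((seed + 7919L * g) %% .Machine$integer.max, {
            t(vapply(seq_len(variantsPerGene), function(v) {
                a <- stats::rnorm(1L, -1, 0.5)
                af <- stats::plogis(a + beta * z)
                stats::rbinom(nPops, meanAN, af)
            }, integer(nPops)))
        })
        AC[(g - 1L) * variantsPerGene + seq_len(variantsPerGene), ] <- block
    }
    AN <- matrix(as.integer(meanAN), nrow(AC), nPops)
    rownames(AC) <- rownames(AN) <-
        sprintf("gene%d_v%d", rep(seq_len(nGenes), each = variantsPerGene),
                rep(seq_len(variantsPerGene), nGenes))
    colnames(AC) <- colnames(AN) <- rownames(eco)
    fm <- FrequencyMatrix(AC, AN, rowData = S4Vectors::DataFrame(
        gene = sprintf("gene%d", rep(seq_len(nGenes), each = variantsPerGene)),
        row.names = rownames(AC)))
    truth <- data.frame(gene = sprintf("gene%d", seq_len(nGenes)),
                        is_signal = seq_len(nGenes) %in% setup$signal,
                        beta = ifelse(seq_len(nGenes) %in% setup$signal,
                                      betaEffect, 0))
    list(fm = fm, eco = eco, truth = truth)
}
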