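# Codon-counting dN/dS: Nei-Gojobori style expected-site and pathway-averaged
# difference counting under the standard genetic code (translation table 1),
# with Jukes-Cantor multiple-hit correction.

.codonCache <- new.env(parent = emptyenv())

.bases <- c("A", "C", "G", "T")

# permutations of 1..k for k in 1..3; codon pathways never need more
.permutations <- list(
    matrix(1L, 1L, 1L),
    rbind(c(1L, 2L), c(2L, 1L)),
    rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
          c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

# Lazily built lookup tables keyed by codon string: amino acid, per-codon
# expected site counts, and the 64x64 pathway-averaged difference counts.
.codonTables <- function() {
    if (!is.null(.codonCache$tables))
        return(.codonCache$tables)
    aa <- Biostrings::GENETIC_CODE
    codons <- names(aa)
    stops <- codons[aa == "*"]

    siteS <- rep(NA_real_, 64L)
    names(siteS) <- codons
    for (cd in setdiff(codons, stops)) {
        chars <- strsplit(cd, "")[[1L]]
        s <- 0
        for (p in 1:3) {
            nb <- vapply(setdiff(.bases, chars[p]), function(b) {
                x <- chars; x[p] <- b; paste(x, collapse = "")
            }, character(1L))
            nb <- nb[!nb %in% stops]          # stop-creating neighbours excluded
            if (length(nb))
                s <- s + sum(aa[nb] == aa[cd]) / length(nb)
        }
        siteS[cd] <- s
    }

    diffS <- matrix(NA_real_, 64L, 64L, dimnames = list(codons, codons))
    diffN <- diffS
    sense <- setdiff(codons, stops)
    for (a in sense) for (b in sense) {
        d <- .pathwayAverage(a, b, aa, stops)
        diffS[a, b] <- d[1L]
        diffN[a, b] <- d[2L]
    }

    .codonCache$tables <- list(aa = aa, codons = codons, stops = stops,
                               siteS = siteS, diffS = diffS, diffN = diffN)
    .codonCache$tables
}

# Average (sd, nd) over all minimal single-step pathways between two codons.
# Pathways visiting a stop codon at an intermediate step are excluded; if every
# pathway does, all are retained (steps to/from the stop count as
# nonsynonymous since the translated product changes).
.pathwayAverage <- function(a, b, aa, stops) {
    ca <- strsplit(a, "")[[1L]]
    cb <- strsplit(b, "")[[1L]]
    pos <- which(ca != cb)
    k <- length(pos)
    if (k == 0L)
        return(c(0, 0))
    perms <- .permutations[[k]]
    res <- matrix(NA_real_, nrow(perms), 2L)
    clean <- logical(nrow(perms))
    for (i in seq_len(nrow(perms))) {
        cur <- ca
        s <- 0; n <- 0; hitStop <- FALSE
        for (p in pos[perms[i, ]]) {
            nxt <- cur
            nxt[p] <- cb[p]
            aaCur <- aa[paste(cur, collapse = "")]
            aaNxt <- aa[paste(nxt, collapse = "")]
            if (aaNxt == "*")
                hitStop <- TRUE
            if (aaCur == aaNxt) s <- s + 1 else n <- n + 1
            cur <- nxt
        }
        res[i, ] <- c(s, n)
        clean[i] <- !hitStop
    }
    if (any(clean))
        res <- res[clean, , drop = FALSE]
    colMeans(res)
}

#' Expected synonymous and nonsynonymous sites of one codon
#'
#' For each codon position, the synonymous site fraction is the proportion of
#' the single-nucleotide neighbours that encode the same amino acid;
#' neighbours that create stop codons are excluded from both numerator and
#' denominator at that position. The three fractions sum to `s_sites`, and
#' `n_sites = 3 - s_sites`.
#'
#' @param codon A single 3-letter codon over `A,C,G,T`, not a stop codon.
#' @return Named numeric vector `c(s_sites =, n_sites =)`, summing to 3.
#' @examples
#' codonSiteCounts("TTT")  # s_sites = 1/3
#' codonSiteCounts("ATG")  # s_sites = 0 (Met is a single codon)
#' @export
codonSiteCounts <- function(codon) {
    tab <- .codonTables()
    codon <- toupper(codon)
    if (!is.character(codon) || length(codon) != 1L || !codon %in% tab$codons)
        stop("'codon' must be a single 3-mer over {A,C,G,T}")
    if (codon %in% tab$stops)
        stop(sprintf("'%s' is a stop codon; excluded from site counting", codon))
    s <- tab$siteS[[codon]]
    c(s_sites = s, n_sites = 3 - s)
}

#' Pathway-averaged synonymous/nonsynonymous differences between two codons
#'
#' Counts the synonymous and nonsynonymous steps between two codons, averaged
#' over all minimal single-nucleotide-step pathways. Pathways passing through
#' a stop codon are excluded from the average; if all pathways do, they are
#' all retained. `sd + nd` always equals the Hamming distance of the codons.
#'
#' @param codonA,codonB 3-letter codons over `A,C,G,T`, neither a stop codon.
#' @return Named numeric vector `c(sd =, nd =)`.
#' @examples
#' countCodonDifferences("GGG", "GGA")  # (1, 0): Gly -> Gly
#' countCodonDifferences("TTT", "GTA")  # (0.5, 1.5): average of two pathways
#' @export
countCodonDifferences <- function(codonA, codonB) {
    tab <- .codonTables()
    codonA <- toupper(codonA); codonB <- toupper(codonB)
    for (cd in c(codonA, codonB)) {
        if (!cd %in% tab$codons)
            stop("codons must be 3-mers over {A,C,G,T}")
        if (cd %in% tab$stops)
            stop(sprintf("'%s' is a stop codon", cd))
    }
    c(sd = tab$diffS[codonA, codonB], nd = tab$diffN[codonA, codonB])
}

#' Jukes-Cantor distance correction
#'
#' Corrects an observed proportion of differing sites for multiple hits:
#' `d = -(3/4) * log(1 - (4/3) p)`.
#'
#' @param p Proportion(s) of observed differences, `0 <= p < 3/4`.
#' @return Corrected distance(s).
#' @examples
#' jukesCantor(0.3)   # 0.38311...
#' @export
jukesCantor <- function(p) {
    if (any(!is.finite(p)) || any(p < 0))
        stop("'p' must be a finite proportion in [0, 0.75)")
    if (any(p >= 0.75))
        stop("saturation: Jukes-Cantor distance undefined for p >= 3/4",
             call. = FALSE)
    -0.75 * log(1 - 4 * p / 3)
}

# split one aligned row into codon strings
.rowCodons <- function(chars) {
    L <- length(chars) %/% 3L
    vapply(seq_len(L),
           function(i) paste(chars[(3L * i - 2L):(3L * i)], collapse = ""),
           character(1L))
}

# indices (into the 64-codon table) of codons comparable between two rows:
# plain ACGT codons, not stops, in both rows
.comparableCodons <- function(aln, i, j) {
    tab <- .codonTables()
    s <- as.character(aln@seqs)
    ca <- .rowCodons(strsplit(s[[i]], "")[[1L]])
    cb <- .rowCodons(strsplit(s[[j]], "")[[1L]])
    ok <- ca %in% setdiff(tab$codons, tab$stops) &
          cb %in% setdiff(tab$codons, tab$stops)
    list(a = ca, b = cb, ok = ok)
}

#' Pairwise dN/dS between two rows of a codon alignment
#'
#' Nei-Gojobori style counting: expected synonymous/nonsynonymous sites are
#' averaged between the two sequences, observed differences are summed with
#' equal-weight pathway averaging, proportions are Jukes-Cantor corrected,
#' and `omega = dN/dS`. Codons containing a gap, `N`, or a stop in either row
#' are excluded pairwise.
#'
#' @param aln A [CodonAlignment-class].
#' @param i,j Row indices or sequence ids of the two sequences to compare.
#' @return A [PairwiseRates-class]. `omega` is `NA` with status `"dS_zero"`
#'   when no synonymous divergence is observed, and `NA` with a saturation
#'   status when a corrected distance is undefined.
#' @examples
#' aln <- CodonAlignment(c(a = "ATGAAAGGG", b = "ATGAAAGGA"))
#' pairwiseDnDs(aln, "a", "b")
#' @export
pairwiseDnDs <- function(aln, i = 1L, j = 2L) {
    stopifnot(is(aln, "CodonAlignment"))
    tab <- .codonTables()
    if (is.character(i)) i <- match(i, names(aln@seqs))
    if (is.character(j)) j <- match(j, names(aln@seqs))
    if (anyNA(c(i, j)))
        stop("sequence id not found in alignment")
    cc <- .comparableCodons(aln, i, j)
    a <- cc$a[cc$ok]; b <- cc$b[cc$ok]
    n <- length(a)
    if (n == 0L)
        stop("no comparable codons (all contain gaps, N, or stops)")
    sA <- sum(tab$siteS[a]); sB <- sum(tab$siteS[b])
    S <- (sA + sB) / 2
    N <- 3 * n - S
    Sd <- sum(tab$diffS[cbind(a, b)])
    Nd <- sum(tab$diffN[cbind(a, b)])
    pS <- Sd / S
    pN <- Nd / N
    dS <- dN <- NA_real_
    status <- "ok"
    if (pS < 0.75) dS <- jukesCantor(pS) else status <- "saturated_dS"
    if (pN < 0.75) dN <- jukesCantor(pN)
    else if (status == "ok") status <- "saturated_dN"
    om <- NA_real_
    if (!is.na(dS) && !is.na(dN)) {
        if (dS > 0) om <- dN / dS else status <- "dS_zero"
    }
    new("PairwiseRates", S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
        dS = dS, dN = dN, omega = om, nCodons = as.integer(n), status = status)
}

#' Sliding-window dN/dS scan along a codon alignment
#'
#' Scans a pair of aligned sequences in windows of `windowCodons` codons
#' (default 34 codons = 102 nt) advanced by `stepCodons` (default 31, i.e.
#' consecutive windows overlap by 3 codons). If the last regular window does
#' not reach the end of the alignment, an additional window anchored at the
#' end is appended, so the windows always tile the whole alignment. Windows
#' where `omega` is undefined are reported with `NA`, not dropped.
#'
#' @inheritParams pairwiseDnDs
#' @param windowCodons,stepCodons Window length and step, in codons.
#' @return A `data.frame` with one row per window: `start_codon` (0-based),
#'   `end_codon` (exclusive), `S, N, Sd, Nd, dS, dN, omega, status`.
#' @export
slidingWindowDnDs <- function(aln, i = 1L, j = 2L,
                              windowCodons = 34L, stepCodons = 31L) {
    stopifnot(is(aln, "CodonAlignment"),
              windowCodons >= 1L, stepCodons >= 1L)
    L <- codonLength(aln)
    if (L < windowCodons) {
        warning(sprintf(
            "alignment (%d codons) shorter than one window (%d codons); %s",
            L, windowCodons, "returning a single whole-alignment window"))
        starts <- 0L
        windowCodons <- L
    } else {
        starts <- seq.int(0L, L - windowCodons, by = stepCodons)
        if (max(starts) + windowCodons < L)
            starts <- c(starts, L - windowCodons)
    }
    s <- as.character(aln@seqs)
    rows <- do.call(rbind, lapply(starts, function(st) {
        nt <- (3L * st + 1L):(3L * (st + windowCodons))
        sub <- CodonAlignment(stats::setNames(
            c(substr(s[[i]], min(nt), max(nt)), substr(s[[j]], min(nt), max(nt))),
            c("a", "b")))
        pr <- tryCatch(pairwiseDnDs(sub, 1L, 2L), error = function(e) NULL)
        if (is.null(pr))
            data.frame(start_codon = st, end_codon = st + windowCodons,
                       S = NA_real_, N = NA_real_, Sd = NA_real_, Nd = NA_real_,
                       dS = NA_real_, dN = NA_real_, omega = NA_real_,
                       status = "no_comparable_codons")
        else
            cbind(data.frame(start_codon = st, end_codon = st + windowCodons),
                  ratesAsDataFrame(pr)[c("S", "N", "Sd", "Nd", "dS", "dN",
                                         "omega", "status")])
    }))
    rownames(rows) <- NULL
    rows
}

#' Percentile-rank genes by their dN/dS
#'
#' Ranks each gene's omega among all genes with a defined omega using the
#' midpoint-tie percentile rule (see [percentileRank()]); genes with
#' undefined omega are excluded from the ranking and reported separately.
#'
#' @param perGeneOmega Named numeric vector, gene -> omega (`NA` = undefined).
#' @return A list with `percentiles` (named vector over defined genes) and
#'   `undefined` (character vector of excluded gene ids).
#' @export
rankDnDs <- function(perGeneOmega) {
    if (is.null(names(perGeneOmega)))
        stop("'perGeneOmega' must be a named vector")
    def <- perGeneOmega[!is.na(perGeneOmega)]
    if (length(def) < 2L)
        stop("need at least 2 genes with defined omega to rank")
    pct <- vapply(def, percentileRank, numeric(1L), population = def)
    list(percentiles = pct,
         undefined = names(perGeneOmega)[is.na(perGeneOmega)])
}
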