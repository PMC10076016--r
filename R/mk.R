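# McDonald-Kreitman test: per-site classification of polymorphism and fixed
# divergence into synonymous/nonsynonymous classes, alpha, and an exact
# two-sided Fisher test computed by full hypergeometric enumeration.

#' Build a McDonald-Kreitman table from an ingroup sample plus outgroup
#'
#' Walks the alignment codon by codon. A codon column is analyzable when no
#' ingroup haplotype or the outgroup carries a gap, `N`, or a stop codon
#' there. Within an analyzable codon, each nucleotide position is classified
#' independently against the ingroup major-allele codon context:
#' \itemize{
#'   \item a position segregating within the ingroup contributes one
#'     polymorphism per non-major allele, classified by substituting that
#'     allele into the major-allele codon;
#'   \item a position monomorphic in the ingroup but differing from the
#'     outgroup contributes one fixed difference, classified by substituting
#'     the outgroup base into the ingroup codon;
#'   \item a position that is both polymorphic and divergent counts as
#'     polymorphism only (the ingroup major allele defines the lineage state).
#' }
#' Majority ties are broken toward the outgroup allele when it is among the
#' tied alleles, otherwise alphabetically. A substitution that would create a
#' stop codon is counted as nonsynonymous (it alters the protein).
#'
#' @param popaln A [PopulationAlignment-class].
#' @return An [MKTable-class] of integer counts `(Dn, Ds, Pn, Ps)`.
#' @examples
#' ing <- c(h1 = "ATGGGG", h2 = "ATGGGG", h3 = "ATGGGA", h4 = "ATGGGA")
#' classifySites(PopulationAlignment(ing, "ATGGGG"))  # Ps = 1
#' @export
classifySites <- function(popaln) {
    stopifnot(is(popaln, "PopulationAlignment"))
    tab <- .codonTables()
    ing <- as.character(popaln@ingroup@seqs)
    out <- as.character(popaln@outgroup)
    mat <- do.call(rbind, strsplit(ing, ""))       # haplotypes x positions
    outc <- strsplit(out, "")[[1L]]
    L <- ncol(mat) %/% 3L
    Dn <- Ds <- Pn <- Ps <- 0L
    analyzable <- 0L
    for (cd in seq_len(L)) {
        cols <- (3L * cd - 2L):(3L * cd)
        block <- mat[, cols, drop = FALSE]
        ocd <- paste(outc[cols], collapse = "")
        if (any(!block %in% .bases) || any(!outc[cols] %in% .bases))
            next
        rowCodons <- apply(block, 1L, paste, collapse = "")
        if (any(rowCodons %in% tab$stops) || ocd %in% tab$stops)
            next
        # ingroup major-allele codon; ties toward the outgroup base
        major <- vapply(seq_len(3L), function(k) {
            cnt <- table(block[, k])
            top <- names(cnt)[cnt == max(cnt)]
            if (outc[cols[k]] %in% top) outc[cols[k]] else sort(top)[1L]
        }, character(1L))
        majorCodon <- paste(major, collapse = "")
        if (majorCodon %in% tab$stops)
            next
        analyzable <- analyzable + 1L
        for (k in seq_len(3L)) {
            alleles <- unique(block[, k])
            if (length(alleles) > 1L) {
                for (al in setdiff(alleles, major[k])) {
                    alt <- major
                    alt[k] <- al
                    syn <- tab$aa[paste(alt, collapse = "")] == tab$aa[majorCodon]
                    if (isTRUE(syn)) Ps <- Ps + 1L else Pn <- Pn + 1L
                }
            } else if (alleles != outc[cols[k]]) {
                alt <- major
                alt[k] <- outc[cols[k]]
                syn <- tab$aa[paste(alt, collapse = "")] == tab$aa[majorCodon]
                if (isTRUE(syn)) Ds <- Ds + 1L else Dn <- Dn + 1L
            }
        }
    }
    if (analyzable == 0L)
        stop("no analyzable codons (every codon has a gap, N, or stop)")
    MKTable(Dn = Dn, Ds = Ds, Pn = Pn, Ps = Ps)
}

#' Proportion of substitutions driven by positive selection (alpha)
#'
#' `alpha = 1 - (Ds * Pn) / (Dn * Ps)`. Undefined (error) when `Dn = 0` or
#' `Ps = 0`; use [mkTest()] for an NA-returning wrapper.
#'
#' @param table An [MKTable-class].
#' @return A single numeric alpha (<= 1).
#' @examples
#' mkAlpha(MKTable(20, 10, 5, 10))  # 0.75
#' @export
mkAlpha <- function(table) {
    stopifnot(is(table, "MKTable"))
    if (table@Dn == 0L || table@Ps == 0L) {
        e <- simpleError(sprintf(
            "alpha undefined for table (Dn=%d, Ds=%d, Pn=%d, Ps=%d): needs Dn > 0 and Ps > 0",
            table@Dn, table@Ds, table@Pn, table@Ps))
        e$mkTable <- table
        class(e) <- c("mkAlphaUndefined", class(e))
        stop(e)
    }
    1 - (table@Ds * table@Pn) / (table@Dn * table@Ps)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Full hypergeometric enumeration with the probability-mass two-sided rule:
#' the p-value sums the probabilities of every table with the same margins
#' whose probability does not exceed that of the observed table (with a
#' relative tolerance of `1e-7` on the comparison). A table with any zero
#' row or column margin gets `p = 1` by convention, with a warning.
#'
#' @param table An [MKTable-class] or a 2x2 numeric matrix
#'   `[[Dn, Ds], [Pn, Ps]]`.
#' @return The two-sided p-value in `[0, 1]`.
#' @examples
#' fisherExact2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))  # 34/70
#' @export
fisherExact2x2 <- function(table) {
    m <- if (is(table, "MKTable")) as.matrix(table) else as.matrix(table)
    stopifnot(all(dim(m) == c(2L, 2L)), all(is.finite(m)), all(m >= 0))
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
        warning("degenerate 2x2 table (zero margin); p = 1 by convention")
        return(1)
    }
    r1 <- sum(m[1L, ]); c1 <- sum(m[, 1L]); n <- sum(m)
    lo <- max(0, c1 - (n - r1))
    hi <- min(r1, c1)
    ks <- lo:hi
    probs <- stats::dhyper(ks, c1, n - c1, r1)
    pObs <- probs[ks == m[1L, 1L]]
    min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

#' McDonald-Kreitman test
#'
#' Convenience wrapper: classifies sites (or takes a ready [MKTable-class]),
#' then computes alpha and the two-sided Fisher's exact p-value.
#'
#' @param x A [PopulationAlignment-class] or an [MKTable-class].
#' @return An [MKResult-class]; `alpha` is `NA` when undefined
#'   (`Dn = 0` or `Ps = 0`).
#' @export
mkTest <- function(x) {
    tab <- if (is(x, "PopulationAlignment")) classifySites(x) else x
    stopifnot(is(tab, "MKTable"))
    alpha <- tryCatch(mkAlpha(tab),
                      mkAlphaUndefined = function(e) NA_real_)
    p <- withCallingHandlers(
        fisherExact2x2(tab),
        warning = function(w) invokeRestart("muffleWarning"))
    new("MKResult", alpha = alpha, pValue = p, table = tab)
}
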