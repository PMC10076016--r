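#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importClassesFrom Biostrings DNAStringSet DNAString AAStringSet
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importMethodsFrom SummarizedExperiment assay assayNames rowData "rowData<-"
NULL

#' In-frame codon alignment
#'
#' A set of aligned, in-frame coding sequences (the alignment is assumed to
#' start on codon position 1). Rows may contain `-` (alignment gap) and `N`
#' (ambiguous base); such codons are excluded pairwise by downstream
#' estimators.
#'
#' @slot seqs A [Biostrings::DNAStringSet] of equal-width aligned sequences,
#'   width divisible by 3, at least two sequences, unique names.
#'
#' @seealso [CodonAlignment()], [pairwiseDnDs()], [slidingWindowDnDs()]
#' @exportClass CodonAlignment
setClass("CodonAlignment", slots = c(seqs = "DNAStringSet"))

setValidity("CodonAlignment", function(object) {
    s <- object@seqs
    if (length(s) < 2L)
        return("a codon alignment needs at least 2 sequences")
    w <- Biostrings::width(s)
    if (length(unique(w)) != 1L)
        return("aligned sequences must all have equal length")
    if (w[1L] == 0L)
        return("aligned sequences must be non-empty")
    if (w[1L] %% 3L != 0L)
        return("alignment length must be divisible by 3 (in-frame)")
    if (is.null(names(s)) || anyNA(names(s)) || any(names(s) == ""))
        return("all sequences must be named")
    if (anyDuplicated(names(s)))
        return(sprintf("duplicate sequence ids: %s",
                       paste(unique(names(s)[duplicated(names(s))]),
                             collapse = ", ")))
    bad <- grepl("[^ACGTN-]", as.character(s))
    if (any(bad))
        return(sprintf("sequence '%s' contains characters outside {A,C,G,T,N,-}",
                       names(s)[which(bad)[1L]]))
    TRUE
})

#' Construct a CodonAlignment
#'
#' @param seqs A named [Biostrings::DNAStringSet] or named character vector of
#'   equal-length, in-frame aligned sequences (alphabet `A,C,G,T,N,-`;
#'   lower case is accepted and normalised).
#' @return A [CodonAlignment-class] object.
#' @examples
#' aln <- CodonAlignment(c(a = "ATGAAAGGG", b = "ATGAAAGGA"))
#' codonLength(aln)
#' @export
CodonAlignment <- function(seqs) {
    if (is.character(seqs))
        seqs <- Biostrings::DNAStringSet(toupper(seqs))
    new("CodonAlignment", seqs = seqs)
}

#' @describeIn CodonAlignment-class the aligned sequences as a `DNAStringSet`.
#' @param x,object A `CodonAlignment`.
#' @export
alignedSequences <- function(x) x@seqs

#' @describeIn CodonAlignment-class alignment length in codons.
#' @export
codonLength <- function(x) Biostrings::width(x@seqs)[1L] %/% 3L

#' @exportMethod show
setMethod("show", "CodonAlignment", function(object) {
    cat(sprintf("CodonAlignment: %d sequences x %d codons (%d nt)\n",
                length(object@seqs), codonLength(object),
                Biostrings::width(object@seqs)[1L]))
    cat("  ids:", paste(utils::head(names(object@seqs), 6L), collapse = ", "),
        if (length(object@seqs) > 6L) "..." else "", "\n")
})

#' Ingroup population sample plus one outgroup sequence
#'
#' Holds an ingroup [CodonAlignment-class] of sampled haplotypes together with
#' a single aligned outgroup sequence of the same length, the input of
#' [classifySites()] / [mkTest()].
#'
#' @slot ingroup A [CodonAlignment-class] of n >= 2 ingroup haplotypes.
#' @slot outgroup A [Biostrings::DNAString] of the same aligned length.
#'
#' @exportClass PopulationAlignment
setClass("PopulationAlignment",
         slots = c(ingroup = "CodonAlignment", outgroup = "DNAString"))

setValidity("PopulationAlignment", function(object) {
    win <- Biostrings::width(object@ingroup@seqs)[1L]
    if (length(object@outgroup) != win)
        return("outgroup length must match the ingroup alignment length")
    if (grepl("[^ACGTN-]", as.character(object@outgroup)))
        return("outgroup contains characters outside {A,C,G,T,N,-}")
    TRUE
})

#' Construct a PopulationAlignment
#'
#' @param ingroup A [CodonAlignment-class] (or its constructor input) of
#'   ingroup haplotypes.
#' @param outgroup A single aligned outgroup sequence (character or
#'   `DNAString`) of equal length.
#' @return A [PopulationAlignment-class].
#' @export
PopulationAlignment <- function(ingroup, outgroup) {
    if (!is(ingroup, "CodonAlignment"))
        ingroup <- CodonAlignment(ingroup)
    if (is.character(outgroup))
        outgroup <- Biostrings::DNAString(toupper(outgroup))
    new("PopulationAlignment", ingroup = ingroup, outgroup = outgroup)
}

#' @describeIn PopulationAlignment-class the ingroup alignment.
#' @param x,object A `PopulationAlignment`.
#' @export
ingroup <- function(x) x@ingroup

#' @describeIn PopulationAlignment-class the outgroup sequence.
#' @export
outgroup <- function(x) x@outgroup

#' @exportMethod show
setMethod("show", "PopulationAlignment", function(object) {
    cat(sprintf("PopulationAlignment: %d ingroup haplotypes + outgroup, %d codons\n",
                length(object@ingroup@seqs), codonLength(object@ingroup)))
})

#' Pairwise dN/dS estimate
#'
#' Result container of [pairwiseDnDs()]: expected site counts, observed
#' pathway-averaged difference counts, Jukes-Cantor corrected distances and
#' their ratio.
#'
#' @slot S,N expected synonymous / nonsynonymous sites (averaged over the two
#'   sequences; `S + N` equals 3 x the number of compared codons).
#' @slot Sd,Nd synonymous / nonsynonymous differences (pathway-averaged, so
#'   possibly fractional; `Sd + Nd` equals the summed codon Hamming distances).
#' @slot pS,pN proportions `Sd/S`, `Nd/N`.
#' @slot dS,dN Jukes-Cantor corrected distances (`NA` when saturated).
#' @slot omega `dN/dS`; `NA` when `dS` is 0 or undefined.
#' @slot nCodons number of comparable codons used.
#' @slot status `"ok"`, `"dS_zero"`, `"saturated_dS"` or `"saturated_dN"`.
#'
#' @exportClass PairwiseRates
setClass("PairwiseRates",
         slots = c(S = "numeric", N = "numeric", Sd = "numeric", Nd = "numeric",
                   pS = "numeric", pN = "numeric", dS = "numeric", dN = "numeric",
                   omega = "numeric", nCodons = "integer", status = "character"))

setValidity("PairwiseRates", function(object) {
    if (any(c(object@S, object@N, object@Sd, object@Nd) < 0))
        return("site and difference counts must be non-negative")
    if (abs(object@S + object@N - 3 * object@nCodons) > 1e-6)
        return("S + N must equal 3 x number of compared codons")
    if (!object@status %in% c("ok", "dS_zero", "saturated_dS", "saturated_dN"))
        return("unknown status")
    TRUE
})

#' @exportMethod show
setMethod("show", "PairwiseRates", function(object) {
    cat(sprintf("PairwiseRates (%d codons): S=%.2f N=%.2f Sd=%.2f Nd=%.2f\n",
                object@nCodons, object@S, object@N, object@Sd, object@Nd))
    cat(sprintf("  dS=%s dN=%s omega=%s [%s]\n",
                format(object@dS, digits = 4), format(object@dN, digits = 4),
                format(object@omega, digits = 4), object@status))
})

#' @describeIn PairwiseRates-class `dN/dS` (`NA` when undefined).
#' @param x,object A `PairwiseRates`.
#' @export
omega <- function(x) x@omega

#' @describeIn PairwiseRates-class the estimate as a one-row `data.frame`
#'   with columns `S, N, Sd, Nd, pS, pN, dS, dN, omega, n_codons, status`.
#' @export
ratesAsDataFrame <- function(x) {
    data.frame(S = x@S, N = x@N, Sd = x@Sd, Nd = x@Nd, pS = x@pS, pN = x@pN,
               dS = x@dS, dN = x@dN, omega = x@omega, n_codons = x@nCodons,
               status = x@status)
}

#' McDonald-Kreitman contingency table
#'
#' The 2x2 table contrasting fixed divergence with polymorphism, split by
#' functional class: `[[Dn, Ds], [Pn, Ps]]`.
#'
#' @slot Dn,Ds nonsynonymous / synonymous fixed differences to the outgroup.
#' @slot Pn,Ps nonsynonymous / synonymous polymorphisms within the ingroup.
#'
#' @exportClass MKTable
setClass("MKTable",
         slots = c(Dn = "integer", Ds = "integer", Pn = "integer", Ps = "integer"))

setValidity("MKTable", function(object) {
    v <- c(object@Dn, object@Ds, object@Pn, object@Ps)
    if (length(v) != 4L || anyNA(v) || any(v < 0L))
        return("Dn, Ds, Pn, Ps must be single non-negative integers")
    TRUE
})

#' Construct an MKTable
#'
#' @param Dn,Ds,Pn,Ps non-negative integer counts.
#' @return An [MKTable-class].
#' @examples
#' mkAlpha(MKTable(Dn = 20, Ds = 10, Pn = 5, Ps = 10))  # 0.75
#' @export
MKTable <- function(Dn, Ds, Pn, Ps)
    new("MKTable", Dn = as.integer(Dn), Ds = as.integer(Ds),
        Pn = as.integer(Pn), Ps = as.integer(Ps))

#' @exportMethod show
setMethod("show", "MKTable", function(object) {
    cat("MKTable (divergence | polymorphism x nonsyn | syn):\n")
    m <- as.matrix(object)
    print(m)
})

#' @describeIn MKTable-class the table as a 2x2 matrix
#'   (rows divergence/polymorphism, columns nonsynonymous/synonymous).
#' @param x An `MKTable`.
#' @param ... unused.
#' @export
setMethod("as.matrix", "MKTable", function(x, ...) {
    matrix(c(x@Dn, x@Ds, x@Pn, x@Ps), nrow = 2L, byrow = TRUE,
           dimnames = list(c("divergence", "polymorphism"),
                           c("nonsynonymous", "synonymous")))
})

#' McDonald-Kreitman test result
#'
#' @slot alpha estimated proportion of adaptive substitutions,
#'   `1 - (Ds*Pn)/(Dn*Ps)`; `NA` when `Dn = 0` or `Ps = 0`.
#' @slot pValue two-sided Fisher's exact p-value for the table.
#' @slot table the underlying [MKTable-class].
#'
#' @exportClass MKResult
setClass("MKResult",
         slots = c(alpha = "numeric", pValue = "numeric", table = "MKTable"))

#' @exportMethod show
setMethod("show", "MKResult", function(object) {
    cat(sprintf("MKResult: alpha=%s, Fisher p=%.4g\n",
                format(object@alpha, digits = 3), object@pValue))
    print(as.matrix(object@table))
})

#' @describeIn MKResult-class the alpha estimate (`NA` if undefined).
#' @param x,object An `MKResult`.
#' @export
mkResultAlpha <- function(x) x@alpha

#' @describeIn MKResult-class the Fisher p-value.
#' @export
mkResultP <- function(x) x@pValue

#' @describeIn MKResult-class the underlying `MKTable`.
#' @export
mkResultTable <- function(x) x@table

#' Variants-by-populations allele frequency matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one row per biallelic
#' variant and one column per population, carrying three assays:
#' `AC` (alternate allele count among called alleles), `AN` (called allele
#' count) and `AF = AC/AN` (`NA` where `AN = 0`).
#'
#' @seealso [FrequencyMatrix()], [populationAlleleFrequency()]
#' @exportClass FrequencyMatrix
setClass("FrequencyMatrix", contains = "SummarizedExperiment")

setValidity("FrequencyMatrix", function(object) {
    a <- SummarizedExperiment::assayNames(object)
    if (!all(c("AC", "AN", "AF") %in% a))
        return("FrequencyMatrix needs assays 'AC', 'AN' and 'AF'")
    ac <- SummarizedExperiment::assay(object, "AC")
    an <- SummarizedExperiment::assay(object, "AN")
    af <- SummarizedExperiment::assay(object, "AF")
    if (any(an < 0, na.rm = TRUE) || any(ac < 0, na.rm = TRUE))
        return("AC and AN must be non-negative")
    if (any(ac > an, na.rm = TRUE))
        return("AC cannot exceed AN")
    pos <- !is.na(an) & an > 0
    if (any(abs(af[pos] - ac[pos] / an[pos]) > 1e-12, na.rm = TRUE))
        return("AF must equal AC/AN where AN > 0")
    if (any(!is.na(af[!is.na(an) & an == 0])))
        return("AF must be missing where AN = 0")
    TRUE
})

#' Construct a FrequencyMatrix
#'
#' @param AC,AN integer matrices (variants x populations) of alternate allele
#'   counts and called allele counts; equal dimensions.
#' @param rowData optional `DataFrame`/`data.frame` of per-variant annotation
#'   (e.g. a `gene` column used by the association stage).
#' @return A [FrequencyMatrix-class]; `AF` is derived as `AC/AN` with `NA`
#'   where `AN = 0`.
#' @export
FrequencyMatrix <- function(AC, AN, rowData = NULL) {
    stopifnot(all(dim(AC) == dim(AN)))
    AF <- ifelse(AN > 0, AC / AN, NA_real_)
    dimnames(AF) <- dimnames(AC)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(AC = AC, AN = AN, AF = AF),
        rowData = if (is.null(rowData)) S4Vectors::DataFrame(row.names = rownames(AC))
                  else S4Vectors::DataFrame(rowData))
    new("FrequencyMatrix", se)
}

#' @describeIn FrequencyMatrix-class the AF assay (variants x populations).
#' @param x A `FrequencyMatrix`.
#' @export
alleleFrequencies <- function(x) SummarizedExperiment::assay(x, "AF")

#' @exportMethod show
setMethod("show", "FrequencyMatrix", function(object) {
    cat(sprintf("FrequencyMatrix: %d variants x %d populations\n",
                nrow(object), ncol(object)))
    callNextMethod()
})
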