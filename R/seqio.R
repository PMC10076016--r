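# FASTA input with strict validation, GC content, percentile ranks, signal
# peptide cleavage and amino-acid composition of mature (cleaved) proteins.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# shared FASTA sanity check: non-empty, starts with '>', no sequence lines
# before the first header; reports the offending 1-based line
.checkFasta <- function(path) {
    if (!file.exists(path))
        stop(sprintf("file not found: %s", path))
    lines <- readLines(path, warn = FALSE)
    nonblank <- which(nzchar(trimws(lines)))
    if (length(nonblank) == 0L)
        stop(sprintf("empty FASTA file: %s", path))
    first <- nonblank[1L]
    if (!startsWith(trimws(lines[first]), ">"))
        stop(sprintf("malformed FASTA %s: line %d ('%s') precedes any '>' header",
                     path, first, substr(trimws(lines[first]), 1L, 40L)))
    invisible(TRUE)
}

.checkDuplicateIds <- function(x, path) {
    ids <- sub("\\s.*$", "", names(x))
    if (anyDuplicated(ids))
        stop(sprintf("duplicate sequence id(s) in %s: %s", path,
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    names(x) <- ids
    x
}

#' Read a nucleotide FASTA file
#'
#' Thin, strict wrapper around [Biostrings::readDNAStringSet()]: entries keep
#' file order, sequences are upper-cased, ids are the first whitespace-
#' delimited token of each header, and duplicate ids, empty files and
#' sequence text before the first header are rejected with informative
#' errors.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
readFastaDNA <- function(path) {
    .checkFasta(path)
    x <- Biostrings::readDNAStringSet(path)
    x <- .checkDuplicateIds(x, path)
    bad <- grepl("[^ACGTN-]", as.character(x))
    if (any(bad))
        stop(sprintf("sequence '%s' in %s contains characters outside {A,C,G,T,N,-}",
                     names(x)[which(bad)[1L]], path))
    x
}

#' Read a protein FASTA file, optionally attaching signal-peptide cleavage sites
#'
#' @param path Path to a protein FASTA file.
#' @param cleavage Optional `data.frame` as returned by [readCleavageTable()]
#'   (columns `protein_id`, `cleavage_index`); matched by id, proteins without
#'   an entry get `NA`.
#' @return A named [Biostrings::AAStringSet]; `mcols(x)$cleavage_index` holds
#'   the number of N-terminal signal-peptide residues (`NA` if unknown).
#' @export
readFastaProtein <- function(path, cleavage = NULL) {
    .checkFasta(path)
    x <- Biostrings::readAAStringSet(path)
    x <- .checkDuplicateIds(x, path)
    idx <- rep(NA_integer_, length(x))
    if (!is.null(cleavage)) {
        m <- match(names(x), cleavage$protein_id)
        idx <- as.integer(cleavage$cleavage_index[m])
    }
    S4Vectors::mcols(x) <- S4Vectors::DataFrame(cleavage_index = idx)
    x
}

#' Read a signal-peptide cleavage table
#'
#' @param path TSV with columns `protein_id` and `cleavage_index` (number of
#'   N-terminal residues forming the predicted signal peptide).
#' @return A `data.frame` with those two columns.
#' @export
readCleavageTable <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("protein_id", "cleavage_index")
    if (!all(need %in% names(tab)))
        stop(sprintf("%s must have columns %s", path,
                     paste(need, collapse = ", ")))
    tab[need]
}

#' GC content of nucleotide sequences, in percent
#'
#' `100 * (G + C) / (A + C + G + T)`; `N` residues are excluded from both
#' numerator and denominator, alignment gaps likewise.
#'
#' @param seqs A [Biostrings::DNAStringSet], `DNAString`, or character vector.
#' @return Numeric vector of GC percentages in `[0, 100]`.
#' @examples
#' gcContent(c(x = "ATGC", y = "GGCC"))  # 50, 100
#' @export
gcContent <- function(seqs) {
    if (is(seqs, "DNAString"))
        seqs <- Biostrings::DNAStringSet(seqs)
    if (is.character(seqs))
        seqs <- Biostrings::DNAStringSet(toupper(seqs))
    freq <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
    acgt <- freq[, c("A", "C", "G", "T"), drop = FALSE]
    denom <- rowSums(acgt)
    if (any(denom == 0))
        stop("GC content undefined: sequence contains no unambiguous A/C/G/T")
    stats::setNames(100 * rowSums(acgt[, c("G", "C"), drop = FALSE]) / denom,
                    names(seqs))
}

#' Midpoint-tie percentile rank
#'
#' The percentile of `value` within `population`:
#' `100 * (#below + 0.5 * #equal) / N`. Stable under duplicated values; a
#' value tied only with itself in a population of N that contains it ranks at
#' `100 * (N - 0.5) / N`.
#'
#' @param value A single number.
#' @param population Non-empty numeric vector to rank against.
#' @return Percentile in `[0, 100]`.
#' @examples
#' percentileRank(3, c(1, 2, 3, 4, 5))  # 50
#' @export
percentileRank <- function(value, population) {
    stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
    population <- population[!is.na(population)]
    if (length(population) == 0L)
        stop("'population' must be non-empty")
    100 * (sum(population < value) + 0.5 * sum(population == value)) /
        length(population)
}

#' Remove predicted signal peptides
#'
#' Drops the first `cleavage_index` residues of each protein, yielding the
#' mature (secreted) form. Ids are preserved; a missing cleavage index or a
#' cleavage that would empty the sequence is an error.
#'
#' @param proteins A named [Biostrings::AAStringSet] whose
#'   `mcols(proteins)$cleavage_index` is set (see [readFastaProtein()]), or a
#'   named character vector together with `cleavageIndex`.
#' @param cleavageIndex Optional integer vector overriding the metadata
#'   column; recycled checkwise, `0` leaves a sequence unchanged.
#' @return An [Biostrings::AAStringSet] of mature proteins.
#' @examples
#' p <- Biostrings::AAStringSet(c(p1 = "MKWLAAA"))
#' cleaveSignal(p, cleavageIndex = 4L)  # "AAA"
#' @export
cleaveSignal <- function(proteins, cleavageIndex = NULL) {
    if (is.character(proteins))
        proteins <- Biostrings::AAStringSet(proteins)
    if (is.null(cleavageIndex))
        cleavageIndex <- S4Vectors::mcols(proteins)$cleavage_index
    if (is.null(cleavageIndex) || anyNA(cleavageIndex))
        stop("cleavage_index missing for at least one protein")
    cleavageIndex <- as.integer(cleavageIndex)
    if (length(cleavageIndex) == 1L)
        cleavageIndex <- rep(cleavageIndex, length(proteins))
    w <- Biostrings::width(proteins)
    if (any(cleavageIndex < 0L))
        stop("cleavage_index must be >= 0")
    if (any(cleavageIndex >= w))
        stop(sprintf("cleaving %s would leave an empty mature protein",
                     paste(names(proteins)[cleavageIndex >= w], collapse = ", ")))
    out <- Biostrings::subseq(proteins, start = cleavageIndex + 1L)
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
        cleavage_index = rep(0L, length(out)))
    out
}

#' Mean amino-acid composition of a protein set
#'
#' Computes, per protein, the percentage of each residue (over the 20
#' standard amino acids plus `X`; per-protein percentages sum to 100), then
#' averages the percentages over proteins with equal weight — a mean of
#' per-protein percents, not a pooled residue count. Intended to be run on
#' mature proteins (after [cleaveSignal()]).
#'
#' @param proteins An [Biostrings::AAStringSet] or character vector of
#'   non-empty sequences over the 20 amino-acid letters (plus `X`).
#' @param minLength Minimum (mature) protein length; shorter proteins are
#'   dropped before averaging (`0` keeps everything).
#' @return Named numeric vector of mean percentages for the 20 standard
#'   residues (zeros included) plus `X`, in alphabetical order.
#' @examples
#' aaComposition(c("AA", "CC"))  # A: 50, C: 50
#' @export
aaComposition <- function(proteins, minLength = 0L) {
    if (is.character(proteins))
        proteins <- Biostrings::AAStringSet(proteins)
    if (length(proteins) == 0L)
        stop("'proteins' must be non-empty")
    w <- Biostrings::width(proteins)
    if (any(w == 0L))
        stop("empty protein sequence in input")
    bad <- grepl(sprintf("[^%sX]", paste(.AA20, collapse = "")),
                 as.character(proteins))
    if (any(bad))
        stop("protein sequences may only contain the 20 amino-acid letters and X")
    proteins <- proteins[w >= minLength]
    if (length(proteins) == 0L)
        stop(sprintf("no protein of length >= %d left to average", minLength))
    letters <- c(.AA20, "X")
    counts <- vapply(letters, function(a)
        vapply(as.character(proteins),
               function(s) lengths(regmatches(s, gregexpr(a, s, fixed = TRUE))),
               numeric(1L)), numeric(length(proteins)))
    counts <- matrix(counts, nrow = length(proteins),
                     dimnames = list(names(proteins), letters))
    pct <- 100 * counts / rowSums(counts)
    colMeans(pct)
}
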