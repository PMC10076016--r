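# Variant handling: VCF genotype import (via VariantAnnotation), multiallelic
# splitting, per-population alternate-allele frequencies, and the
# missingness / quality / frequency filters.

#' Diploid genotype calls for a set of variants
#'
#' A lightweight container for per-individual diploid genotypes: a table of
#' variant fields plus two integer allele matrices (`NA` = missing allele;
#' half-calls keep the called allele). Allele codes are VCF-style: `0` = ref,
#' `j` = j-th alternate allele. After [splitMultiallelic()] every record is
#' biallelic and the codes are `0`/`1`.
#'
#' @slot info `data.frame` with columns `chrom`, `pos` (1-based), `id`,
#'   `ref`, `alt` (comma-joined when multiallelic), `qual`.
#' @slot a1,a2 integer matrices, variants x individuals (named columns).
#'
#' @exportClass VariantSet
setClass("VariantSet",
         slots = c(info = "data.frame", a1 = "matrix", a2 = "matrix"))

setValidity("VariantSet", function(object) {
    n <- nrow(object@info)
    if (nrow(object@a1) != n || nrow(object@a2) != n)
        return("allele matrices must have one row per variant")
    if (!identical(dim(object@a1), dim(object@a2)) ||
        !identical(colnames(object@a1), colnames(object@a2)))
        return("a1 and a2 must have identical dimensions and column names")
    if (n > 0L && is.null(colnames(object@a1)))
        return("allele matrices must have individual ids as column names")
    need <- c("chrom", "pos", "id", "ref", "alt", "qual")
    if (!all(need %in% names(object@info)))
        return(sprintf("info must have columns %s", paste(need, collapse = ", ")))
    TRUE
})

#' @exportMethod show
setMethod("show", "VariantSet", function(object) {
    cat(sprintf("VariantSet: %d variants x %d individuals\n",
                nrow(object@info), ncol(object@a1)))
})

#' @describeIn VariantSet-class number of variant records.
#' @param x A `VariantSet`.
#' @export
setMethod("length", "VariantSet", function(x) nrow(x@info))

#' @describeIn VariantSet-class subset records.
#' @param i Row index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "VariantSet", function(x, i, j, ..., drop = FALSE) {
    new("VariantSet", info = x@info[i, , drop = FALSE],
        a1 = x@a1[i, , drop = FALSE], a2 = x@a2[i, , drop = FALSE])
})

#' @describeIn VariantSet-class the variant table.
#' @export
variantInfo <- function(x) x@info

#' Construct a VariantSet
#'
#' @param info `data.frame` with columns `chrom, pos, id, ref, alt, qual`.
#' @param a1,a2 integer allele matrices (variants x individuals), `NA` for a
#'   missing allele.
#' @return A [VariantSet-class].
#' @export
VariantSet <- function(info, a1, a2) {
    info$pos <- as.integer(info$pos)
    new("VariantSet", info = info,
        a1 = matrix(as.integer(a1), nrow(info), dimnames = dimnames(a1)),
        a2 = matrix(as.integer(a2), nrow(info), dimnames = dimnames(a2)))
}

#' Read a population panel file
#'
#' @param path TSV with header columns `individual_id` and `population_id`;
#'   every individual must appear exactly once.
#' @return A `data.frame` with those two columns.
#' @export
readPanel <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("individual_id", "population_id")
    if (!all(need %in% names(tab)))
        stop(sprintf("%s must have columns %s", path, paste(need, collapse = ", ")))
    if (anyDuplicated(tab$individual_id))
        stop(sprintf("individual(s) listed more than once in panel: %s",
                     paste(unique(tab$individual_id[duplicated(tab$individual_id)]),
                           collapse = ", ")))
    tab[need]
}

# parse a GT character matrix (variants x individuals) into allele matrices
.parseGT <- function(gt) {
    parse1 <- function(g) {
        if (is.na(g) || g == "." || g == "./." || g == ".|.")
            return(c(NA_integer_, NA_integer_))
        parts <- strsplit(g, "[/|]")[[1L]]
        if (length(parts) == 1L)
            stop(sprintf("haploid genotype '%s' not supported (diploid calls required)", g))
        if (length(parts) != 2L)
            stop(sprintf("cannot parse genotype '%s'", g))
        ifelse(parts == ".", NA_integer_, suppressWarnings(as.integer(parts)))
    }
    al <- vapply(as.vector(gt), parse1, integer(2L))
    list(a1 = matrix(al[1L, ], nrow(gt), dimnames = dimnames(gt)),
         a2 = matrix(al[2L, ], nrow(gt), dimnames = dimnames(gt)))
}

#' Read per-individual genotypes from a VCF file
#'
#' Parses a VCF 4.x file (plain or bgzipped) with
#' [VariantAnnotation::readVcf()] and extracts the `GT` field into a
#' [VariantSet-class]. Records keep file order; multiallelic records are kept
#' as-is (split them with [splitMultiallelic()]). Only diploid calls are
#' supported; half-calls retain the called allele.
#'
#' @param path Path to a VCF file.
#' @return A [VariantSet-class].
#' @export
readVcfGenotypes <- function(path) {
    if (!file.exists(path))
        stop(sprintf("VCF not found: %s", path))
    vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
    rr <- SummarizedExperiment::rowRanges(vcf)
    alt <- VariantAnnotation::alt(vcf)
    altStr <- vapply(as.list(alt), function(a)
        paste(as.character(a), collapse = ","), character(1L))
    info <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(rr)),
        pos = GenomicRanges::start(rr),
        id = names(rr),
        ref = as.character(VariantAnnotation::ref(vcf)),
        alt = altStr,
        qual = as.numeric(VariantAnnotation::qual(vcf)),
        stringsAsFactors = FALSE)
    rownames(info) <- NULL
    gt <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gt))
        stop(sprintf("VCF %s has no GT genotype field", path))
    al <- .parseGT(gt)
    VariantSet(info, al$a1, al$a2)
}

#' Split multiallelic records into biallelic ones
#'
#' One output record per alternate allele (as `bcftools norm -m -` does for
#' genotypes): in the record for alternate allele `j`, allele codes equal to
#' `j` become `1`, reference stays `0`, and alleles belonging to *other*
#' alternates become missing. Records without any alternate allele are
#' dropped. QUAL is copied. Biallelic input passes through unchanged.
#'
#' @param vs A [VariantSet-class].
#' @return A [VariantSet-class] of biallelic records, input order preserved
#'   (alternates of one record stay adjacent, in allele order).
#' @export
splitMultiallelic <- function(vs) {
    stopifnot(is(vs, "VariantSet"))
    pieces <- lapply(seq_len(length(vs)), function(r) {
        alts <- strsplit(vs@info$alt[r], ",", fixed = TRUE)[[1L]]
        alts <- alts[nzchar(alts) & alts != "."]
        if (length(alts) == 0L)
            return(NULL)
        lapply(seq_along(alts), function(j) {
            recode <- function(a) ifelse(is.na(a), NA_integer_,
                                  ifelse(a == 0L, 0L,
                                  ifelse(a == j, 1L, NA_integer_)))
            info <- vs@info[r, , drop = FALSE]
            info$alt <- alts[j]
            if (length(alts) > 1L)
                info$id <- sprintf("%s_alt%d", info$id, j)
            list(info = info,
                 a1 = recode(vs@a1[r, ]), a2 = recode(vs@a2[r, ]))
        })
    })
    pieces <- unlist(pieces, recursive = FALSE)
    if (length(pieces) == 0L)
        return(vs[integer(0L)])
    info <- do.call(rbind, lapply(pieces, `[[`, "info"))
    rownames(info) <- NULL
    a1 <- do.call(rbind, lapply(pieces, `[[`, "a1"))
    a2 <- do.call(rbind, lapply(pieces, `[[`, "a2"))
    colnames(a1) <- colnames(a2) <- colnames(vs@a1)
    VariantSet(info, a1, a2)
}

# population -> ordered individual columns, with coverage check
.panelColumns <- function(vs, panel) {
    inds <- colnames(vs@a1)
    missing <- setdiff(inds, panel$individual_id)
    if (length(missing))
        stop(sprintf("individual(s) absent from panel: %s",
                     paste(missing, collapse = ", ")))
    split(inds, factor(panel$population_id[match(inds, panel$individual_id)],
                       levels = unique(panel$population_id)))
}

#' Per-population alternate-allele frequencies
#'
#' For every (biallelic) variant and population: `AC` = number of alternate
#' alleles among the called alleles of that population's individuals, `AN` =
#' number of called alleles, `AF = AC/AN` (missing where `AN = 0`).
#'
#' @param vs A biallelic [VariantSet-class] (run [splitMultiallelic()] first).
#' @param panel Panel `data.frame` from [readPanel()], covering every
#'   genotyped individual.
#' @return A [FrequencyMatrix-class] (variants x populations).
#' @export
populationAlleleFrequency <- function(vs, panel) {
    stopifnot(is(vs, "VariantSet"))
    if (any(grepl(",", vs@info$alt, fixed = TRUE)))
        stop("multiallelic records present; run splitMultiallelic() first")
    byPop <- .panelColumns(vs, panel)
    nv <- length(vs)
    AC <- AN <- matrix(0L, nv, length(byPop),
                       dimnames = list(vs@info$id, names(byPop)))
    for (p in names(byPop)) {
        cols <- byPop[[p]]
        a1 <- vs@a1[, cols, drop = FALSE]
        a2 <- vs@a2[, cols, drop = FALSE]
        AC[, p] <- rowSums(a1 == 1L, na.rm = TRUE) + rowSums(a2 == 1L, na.rm = TRUE)
        AN[, p] <- rowSums(!is.na(a1)) + rowSums(!is.na(a2))
    }
    FrequencyMatrix(AC, AN, rowData = vs@info)
}

#' Filter variants on missingness, quality, and population frequency
#'
#' Drops a record when
#' (a) in any single population the fraction of individuals with a fully
#' missing genotype (both alleles uncalled) exceeds `missingFrac`, or
#' (b) `QUAL < qualMin` (records with missing QUAL also fail), or
#' (c) its alternate-allele frequency is below `afMin` in every population
#' with a non-missing frequency.
#' Boundaries follow the strict wording: `AF` exactly equal to `afMin`
#' retains, `QUAL` exactly equal to `qualMin` retains. Survivors keep input
#' order; each dropped record is tallied under the first rule (in the order
#' above) that removes it. The filter is idempotent.
#'
#' @param vs A biallelic [VariantSet-class].
#' @param panel Panel `data.frame` from [readPanel()].
#' @param missingFrac,qualMin,afMin Thresholds (defaults 0.9, 30, 0.05).
#' @return A list with `variants` (the surviving [VariantSet-class]),
#'   `tally` (named integer vector `missing`, `qual`, `af`), and
#'   `keptIds`.
#' @export
filterVariants <- function(vs, panel, missingFrac = 0.9, qualMin = 30,
                           afMin = 0.05) {
    stopifnot(is(vs, "VariantSet"))
    if (length(vs) == 0L)
        return(list(variants = vs,
                    tally = c(missing = 0L, qual = 0L, af = 0L),
                    keptIds = character(0L)))
    byPop <- .panelColumns(vs, panel)
    missGeno <- is.na(vs@a1) & is.na(vs@a2)
    overMissing <- Reduce(`|`, lapply(byPop, function(cols)
        rowMeans(missGeno[, cols, drop = FALSE]) > missingFrac))
    lowQual <- is.na(vs@info$qual) | vs@info$qual < qualMin
    af <- alleleFrequencies(populationAlleleFrequency(vs, panel))
    rareEverywhere <- apply(af, 1L, function(x) all(x < afMin, na.rm = TRUE))
    reason <- rep(NA_character_, length(vs))
    reason[overMissing] <- "missing"
    reason[is.na(reason) & lowQual] <- "qual"
    reason[is.na(reason) & rareEverywhere] <- "af"
    keep <- is.na(reason)
    tally <- c(missing = sum(reason == "missing", na.rm = TRUE),
               qual = sum(reason == "qual", na.rm = TRUE),
               af = sum(reason == "af", na.rm = TRUE))
    list(variants = vs[keep], tally = tally,
         keptIds = vs@info$id[keep])
}

#' Read a gene-interval table
#'
#' @param path TSV with columns `gene_id`, `chrom`, `start_1based`,
#'   `end_1based` (1-based, inclusive).
#' @return A `data.frame` with those columns.
#' @export
readGeneIntervals <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start_1based", "end_1based")
    if (!all(need %in% names(tab)))
        stop(sprintf("%s must have columns %s", path, paste(need, collapse = ", ")))
    tab[need]
}

#' Assign variants to genes by interval overlap
#'
#' Maps each variant position to the gene interval containing it (1-based,
#' inclusive coordinates). A variant inside several overlapping genes is
#' assigned to the first interval in table order; variants outside every
#' interval get `NA`.
#'
#' @param vs A [VariantSet-class].
#' @param intervals Gene intervals from [readGeneIntervals()].
#' @return Character vector of gene ids, one per variant.
#' @export
assignVariantsToGenes <- function(vs, intervals) {
    stopifnot(is(vs, "VariantSet"))
    vgr <- GenomicRanges::GRanges(vs@info$chrom,
                                  IRanges::IRanges(vs@info$pos, width = 1L))
    ggr <- GenomicRanges::GRanges(intervals$chrom,
                                  IRanges::IRanges(intervals$start_1based,
                                                   intervals$end_1based))
    hit <- GenomicRanges::findOverlaps(vgr, ggr, select = "first")
    intervals$gene_id[hit]
}

#' Write a small plain-text VCF
#'
#' Emits a minimal VCF 4.2 file (FORMAT `GT` only) from a
#' [VariantSet-class], suitable as a fixture and round-trippable through
#' [readVcfGenotypes()]. Column order follows the allele matrices.
#'
#' @param vs A [VariantSet-class] (an empty one yields a header-only file).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeToyVcf <- function(vs, path) {
    stopifnot(is(vs, "VariantSet"))
    inds <- colnames(vs@a1)
    hdr <- c("##fileformat=VCFv4.2",
             "##source=adaptscan",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             vapply(unique(vs@info$chrom), function(ch)
                 sprintf("##contig=<ID=%s>", ch), character(1L)),
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", inds), collapse = "\t"))
    fmt1 <- function(a) ifelse(is.na(a), ".", as.character(a))
    body <- vapply(seq_len(length(vs)), function(r) {
        gts <- paste(fmt1(vs@a1[r, ]), fmt1(vs@a2[r, ]), sep = "/")
        paste(c(vs@info$chrom[r], vs@info$pos[r], vs@info$id[r],
                vs@info$ref[r], vs@info$alt[r],
                ifelse(is.na(vs@info$qual[r]), ".",
                       format(vs@info$qual[r], trim = TRUE)),
                "PASS", ".", "GT", gts), collapse = "\t")
    }, character(1L))
    con <- file(path, "w")
    on.exit(close(con))
    tryCatch(writeLines(c(hdr, body), con),
             error = function(e)
                 stop(sprintf("failed writing VCF to %s: %s", path,
                              conditionMessage(e))))
    invisible(path)
}
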