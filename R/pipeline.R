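# Orchestration: expression-based gene subsetting, TSV emission with echoed
# thresholds, and a reproducible multi-stage driver.

#' Read a per-gene TPM table
#'
#' @param path TSV whose first column is `gene_id`, remaining columns one TPM
#'   value per condition / time point.
#' @return A `data.frame`.
#' @export
readTpmTable <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (names(tab)[1L] != "gene_id" || ncol(tab) < 2L)
        stop(sprintf("%s must have 'gene_id' first and >= 1 condition column",
                     path))
    tab
}

#' Subset genes by expression
#'
#' Keeps the genes whose maximum TPM across conditions is strictly greater
#' than `tpmMin` (default 2). Genes absent from the table are excluded and
#' counted, not an error.
#'
#' @param genes Character vector of gene ids.
#' @param tpmTable `data.frame` from [readTpmTable()].
#' @param tpmMin Strict lower TPM bound (default 2).
#' @return Character vector of surviving genes;
#'   `attr(, "n_absent")` counts genes missing from the table.
#' @export
subsetByExpression <- function(genes, tpmTable, tpmMin = 2) {
    m <- match(genes, tpmTable$gene_id)
    absent <- is.na(m)
    maxTpm <- apply(tpmTable[m[!absent], -1L, drop = FALSE], 1L, max,
                    na.rm = TRUE)
    out <- genes[!absent][maxTpm > tpmMin]
    attr(out, "n_absent") <- sum(absent)
    out
}

#' Write a TSV with echoed parameters
#'
#' Tab-separated, UTF-8, `NA` for missing values; any supplied parameters are
#' echoed as leading `#key=value` comment lines so every output records the
#' thresholds that produced it.
#'
#' @param df A `data.frame`.
#' @param path Output path.
#' @param params Optional named list echoed into the header.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(df, path, params = list()) {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    if (length(params))
        writeLines(sprintf("#%s=%s", names(params),
                           vapply(params, format, character(1L))), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    invisible(path)
}

#' Read a TSV written by [writeTsv()]
#'
#' @param path Input path.
#' @return A `data.frame` (comment lines skipped).
#' @export
readTsv <- function(path)
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)


#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order and writes one TSV per
#' output under `config$out_dir`:
#' \describe{
#'   \item{composition}{`config$protein_fasta` (+ optional
#'     `config$cleavage_tsv`): GC content per nucleotide sequence of
#'     `config$gene_fasta` (if given) and mean amino-acid composition of the
#'     mature proteome (`min_protein_length`, default 60).}
#'   \item{dnds / mk}{`config$cds_fasta` (aligned, in frame) with
#'     `config$outgroup_id`: gene-wide rates for every non-outgroup sequence
#'     against the outgroup, the sliding-window track
#'     (`window_codons`/`step_codons`, defaults 34/31) for the first pair,
#'     and the McDonald-Kreitman test of all ingroup haplotypes against the
#'     outgroup.}
#'   \item{variants / association}{`config$vcf` + `config$panel_tsv`
#'     (+ `config$gene_intervals_tsv`, `config$eco_tsv`): multiallelic
#'     splitting, filtering (`missing_frac`/`qual_min`/`af_min`, defaults
#'     0.9/30/0.05), per-population frequencies, and the gene-level
#'     association table (permutation test for `config$perm_genes` with
#'     `config$permutations` replicates and `config$seed`).}
#' }
#' Rerunning with an identical config reproduces identical outputs
#' (stochastic stages are controlled by `config$seed`). A stage failure
#' aborts with the stage name; outputs written so far are retained and the
#' report carries a `failed` marker.
#'
#' @param config A named list; unknown entries are ignored, referenced files
#'   must exist.
#' @return The run report: per-stage record counts, filter tallies, output
#'   paths, package version and the echoed config.
#' @export
runPipeline <- function(config) {
    stopifnot(is.list(config), !is.null(config$out_dir))
    for (f in intersect(names(config),
                        c("protein_fasta", "cleavage_tsv", "gene_fasta",
                          "cds_fasta", "vcf", "panel_tsv",
                          "gene_intervals_tsv", "eco_tsv", "tpm_tsv"))) {
        if (!file.exists(config[[f]]))
            stop(sprintf("config$%s: file not found: %s", f, config[[f]]))
    }
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    report <- list(version = as.character(utils::packageVersion("adaptscan")),
                   config = config, counts = list(), files = character(0L),
                   failed = NULL)
    emit <- function(df, name, params = list()) {
        p <- file.path(config$out_dir, name)
        writeTsv(df, p, params)
        report$files <<- c(report$files, p)
        report$counts[[sub("\\.tsv$", "", name)]] <<- nrow(df)
        p
    }
    writeReport <- function() {
        tab <- data.frame(
            key = c("version",
                    if (!is.null(report$failed)) "FAILED",
                    if (length(report$counts))
                        paste0("n_", names(report$counts)),
                    if (!is.null(report$filter_tally))
                        paste0("filtered_", names(report$filter_tally))),
            value = c(report$version,
                      if (!is.null(report$failed)) report$failed,
                      unlist(report$counts, use.names = FALSE),
                      if (!is.null(report$filter_tally))
                          unname(report$filter_tally)))
        p <- file.path(config$out_dir, "run_report.tsv")
        writeTsv(tab, p)
        report$files <<- c(report$files, p)
    }
    .stage <- function(name, expr) {
        res <- tryCatch(force(expr), error = function(e) e)
        if (inherits(res, "error")) {
            report$failed <<- name
            report$error <<- conditionMessage(res)
            writeReport()   # partial outputs retained, marked FAILED
            stop(sprintf("stage '%s' failed: %s", name,
                         conditionMessage(res)), call. = FALSE)
        }
        res
    }

    if (!is.null(config$gene_fasta)) {
        gcTab <- .stage("gc_content", {
            seqs <- readFastaDNA(config$gene_fasta)
            data.frame(gene = names(seqs), gc_percent = gcContent(seqs))
        })
        emit(gcTab, "gc_content.tsv")
    }

    if (!is.null(config$protein_fasta)) {
        minLen <- config$min_protein_length %||% 60L
        compTab <- .stage("aa_composition", {
            cl <- if (!is.null(config$cleavage_tsv))
                readCleavageTable(config$cleavage_tsv) else NULL
            prot <- readFastaProtein(config$protein_fasta, cleavage = cl)
            mature <- if (is.null(cl)) prot else cleaveSignal(prot)
            comp <- aaComposition(mature, minLength = minLen)
            data.frame(residue = names(comp), mean_percent = unname(comp))
        })
        emit(compTab, "aa_composition.tsv",
             list(min_protein_length = minLen))
    }

    if (!is.null(config$cds_fasta)) {
        win <- config$window_codons %||% 34L
        stp <- config$step_codons %||% 31L
        res <- .stage("dnds_mk", {
            aln <- CodonAlignment(readFastaDNA(config$cds_fasta))
            og <- config$outgroup_id %||% names(alignedSequences(aln))[
                length(alignedSequences(aln))]
            ids <- names(alignedSequences(aln))
            if (!og %in% ids)
                stop(sprintf("outgroup id '%s' not in alignment", og))
            ingIds <- setdiff(ids, og)
            rates <- do.call(rbind, lapply(ingIds, function(id)
                cbind(data.frame(sequence = id),
                      ratesAsDataFrame(pairwiseDnDs(aln, id, og)))))
            wins <- cbind(data.frame(sequence = ingIds[1L]),
                          slidingWindowDnDs(aln, ingIds[1L], og,
                                            windowCodons = win,
                                            stepCodons = stp))
            mk <- if (length(ingIds) >= 2L) {
                pa <- PopulationAlignment(
                    CodonAlignment(alignedSequences(aln)[ingIds]),
                    alignedSequences(aln)[[og]])
                r <- mkTest(pa)
                t <- mkResultTable(r)
                data.frame(Dn = t@Dn, Ds = t@Ds, Pn = t@Pn, Ps = t@Ps,
                           alpha = mkResultAlpha(r), p_value = mkResultP(r))
            } else NULL
            list(rates = rates, wins = wins, mk = mk)
        })
        emit(res$rates, "dnds.tsv", list(outgroup = config$outgroup_id))
        emit(res$wins, "dnds_windows.tsv",
             list(window_codons = win, step_codons = stp))
        if (!is.null(res$mk))
            emit(res$mk, "mk_test.tsv")
    }

    if (!is.null(config$vcf)) {
        mf <- config$missing_frac %||% 0.9
        qm <- config$qual_min %||% 30
        am <- config$af_min %||% 0.05
        res <- .stage("variants", {
            panel <- readPanel(config$panel_tsv)
            vs <- splitMultiallelic(readVcfGenotypes(config$vcf))
            flt <- filterVariants(vs, panel, missingFrac = mf,
                                  qualMin = qm, afMin = am)
            fm <- populationAlleleFrequency(flt$variants, panel)
            list(flt = flt, fm = fm, panel = panel)
        })
        report$counts$variants_in <- sum(res$flt$tally) +
            length(res$flt$variants)
        report$filter_tally <- res$flt$tally
        afTab <- data.frame(variant_id = rownames(res$fm),
                            as.data.frame(alleleFrequencies(res$fm)),
                            check.names = FALSE)
        emit(afTab, "allele_frequencies.tsv",
             list(missing_frac = mf, qual_min = qm, af_min = am))

        if (!is.null(config$eco_tsv)) {
            assoc <- .stage("association", {
                fm <- res$fm
                if (!is.null(config$gene_intervals_tsv)) {
                    iv <- readGeneIntervals(config$gene_intervals_tsv)
                    SummarizedExperiment::rowData(fm)$gene <-
                        assignVariantsToGenes(res$flt$variants, iv)
                }
                if (!is.null(config$tpm_tsv)) {
                    # rank only genes expressed above the TPM floor
                    keep <- subsetByExpression(
                        unique(SummarizedExperiment::rowData(fm)$gene),
                        readTpmTable(config$tpm_tsv),
                        tpmMin = config$tpm_min %||% 2)
                    fm <- fm[SummarizedExperiment::rowData(fm)$gene %in% keep, ]
                }
                associateGenes(fm, readEcoTable(config$eco_tsv),
                               permGenes = config$perm_genes %||% character(0L),
                               B = config$permutations %||% 1000L,
                               seed = config$seed)
            })
            emit(attr(assoc, "correlations"), "variant_correlations.tsv")
            emit(assoc, "gene_association.tsv",
                 list(permutations = config$permutations %||% 1000L,
                      seed = config$seed %||% "NA"))
        }
    }

    writeReport()
    report$files <- unname(report$files)
    report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
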