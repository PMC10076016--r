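# Gene-level genotype-environment association: per-variant Pearson
# correlation of population allele frequencies with ecological variables,
# harmonic-mean-p combination per gene, percentile ranking, and a
# variant-count-matched permutation null.

#' Read a population-by-ecological-variable table
#'
#' @param path TSV whose first column is `population_id`, remaining columns
#'   one ecological variable each (numeric; empty/NA cells allowed).
#' @return A `data.frame` with populations as row names.
#' @export
readEcoTable <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (names(tab)[1L] != "population_id")
        stop(sprintf("%s must have 'population_id' as its first column", path))
    if (ncol(tab) < 2L)
        stop("ecological table needs at least one variable column")
    if (anyDuplicated(names(tab)))
        stop("ecological variable names must be unique")
    rownames(tab) <- tab$population_id
    tab$population_id <- NULL
    if (nrow(tab) < 3L)
        stop("ecological table needs at least 3 populations")
    tab
}

#' Pearson correlation with two-tailed p-value
#'
#' Pairwise-deletes missing entries, then computes the sample correlation and
#' its two-tailed p-value from `t = r * sqrt((n-2)/(1-r^2))` on `n - 2`
#' degrees of freedom (via [stats::cor.test()]). Inputs that leave fewer than
#' 3 complete pairs, or a constant vector, yield an undefined-correlation
#' result (`ok = FALSE`) rather than an error, so callers can skip and count.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A list with `r`, `p`, `n_used`, and `ok`.
#' @export
pearsonWithP <- function(x, y) {
    stopifnot(length(x) == length(y))
    use <- !is.na(x) & !is.na(y)
    n <- sum(use)
    if (n < 3L || stats::sd(x[use]) == 0 || stats::sd(y[use]) == 0)
        return(list(r = NA_real_, p = NA_real_, n_used = n, ok = FALSE))
    ct <- stats::cor.test(x[use], y[use], method = "pearson",
                          alternative = "two.sided")
    list(r = unname(ct$estimate), p = ct$p.value, n_used = n, ok = TRUE)
}

#' Per-variant correlations of allele frequency with ecological variables
#'
#' Correlates each variant's per-population alternate-allele frequency with
#' each ecological variable (populations matched by name). Variants failing
#' the correlation preconditions for a variable (fewer than 3 complete
#' populations, or a constant vector) are excluded and counted.
#'
#' @param fm A [FrequencyMatrix-class].
#' @param eco Ecological table from [readEcoTable()] (or any data.frame with
#'   population row names matching `colnames(fm)`).
#' @return A `data.frame` with columns `variant`, `variable`, `r`, `p`,
#'   `n_used`; the number of skipped (variant, variable) pairs is in
#'   `attr(, "n_skipped")`.
#' @export
variantCorrelations <- function(fm, eco) {
    stopifnot(is(fm, "FrequencyMatrix"))
    pops <- intersect(colnames(fm), rownames(eco))
    if (length(pops) < 3L)
        stop("fewer than 3 populations shared between frequencies and ecological table")
    af <- alleleFrequencies(fm)[, pops, drop = FALSE]
    res <- vector("list", ncol(eco))
    skipped <- 0L
    for (v in seq_along(eco)) {
        z <- eco[pops, v]
        rows <- lapply(seq_len(nrow(af)), function(i) {
            pw <- pearsonWithP(af[i, ], z)
            if (!pw$ok)
                return(NULL)
            data.frame(variant = rownames(af)[i], variable = names(eco)[v],
                       r = pw$r, p = pw$p, n_used = pw$n_used)
        })
        skipped <- skipped + sum(vapply(rows, is.null, logical(1L)))
        res[[v]] <- do.call(rbind, rows)
    }
    out <- do.call(rbind, res)
    if (is.null(out))
        out <- data.frame(variant = character(), variable = character(),
                          r = numeric(), p = numeric(), n_used = integer())
    rownames(out) <- NULL
    attr(out, "n_skipped") <- skipped
    out
}

#' Gene-level correlation-test metric
#'
#' Combines the p-values of one gene's variants for one ecological variable
#' with the harmonic mean p-value and reports `metric = -log10(HMP)` — the
#' correlation-test score a gene is ranked by. The asymptotically exact
#' adjusted combined p is carried alongside.
#'
#' @param ps Numeric vector of the gene's per-variant correlation p-values
#'   (one variable).
#' @return A list with `L`, `combined_p` (raw HMP), `combined_p_adjusted`,
#'   and `metric`.
#' @examples
#' geneMetric(0.01)$metric  # 2
#' @export
geneMetric <- function(ps) {
    if (length(ps) == 0L)
        stop("gene has no usable variant correlations")
    h <- harmonicMeanP(ps)
    list(L = h$L, combined_p = h$raw, combined_p_adjusted = h$adjusted,
         metric = -log10(h$raw))
}

#' Percentile-rank genes by their correlation metric
#'
#' Ranks each gene's metric among all genes, per variable, with the
#' midpoint-tie rule of [percentileRank()], and flags genes at or above the
#' 90th percentile.
#'
#' @param metrics A `data.frame` with columns `gene`, `variable`, `metric`
#'   (as assembled by [associateGenes()]).
#' @return The input with `percentile` and `top_decile` columns added.
#' @export
rankGenes <- function(metrics) {
    stopifnot(all(c("gene", "variable", "metric") %in% names(metrics)))
    out <- lapply(split(metrics, metrics$variable), function(d) {
        if (nrow(d) < 2L)
            stop("need at least 2 usable genes per variable to rank")
        d$percentile <- vapply(d$metric, percentileRank, numeric(1L),
                               population = d$metric)
        d$top_decile <- d$percentile >= 90
        d
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Variant-count-matched permutation test for one gene
#'
#' Builds an empirical null for the gene-wide correlation statistic
#' `T = mean(|r|)` by repeatedly drawing, without replacement within each of
#' the `B` replicates, as many variants as the gene has from the genome-wide
#' pool of variant correlations, and recomputing `T`. The permutation
#' p-value uses the add-one rule `(1 + #(T_null >= T_obs)) / (1 + B)`;
#' significance is `perm_p < 0.05`.
#'
#' @param geneR Numeric vector: the gene's variant correlation coefficients
#'   for one variable (length `k >= 1`).
#' @param poolR Numeric vector: all variants' correlation coefficients for
#'   the same variable (`length(poolR) >= k`).
#' @param B Number of permutation replicates (`>= 1`).
#' @param seed Integer seed; required, no default.
#' @return A list with `perm_p`, `T_obs`, `significant`, `B`, and `k`.
#' @export
permutationTest <- function(geneR, poolR, B = 1000L, seed) {
    if (missing(seed))
        stop("an explicit integer 'seed' is required")
    k <- length(geneR)
    if (k < 1L)
        stop("gene has no variants")
    if (length(poolR) < k)
        stop(sprintf("pool (%d) smaller than gene variant count (%d)",
                     length(poolR), k))
    if (B < 1L)
        stop("'B' must be >= 1")
    tObs <- mean(abs(geneR))
    absPool <- abs(poolR)
    tNull <- withr::with_seed(as.integer(seed),
        vapply(seq_len(B), function(b)
            mean(absPool[sample.int(length(absPool), k)]), numeric(1L)))
    p <- (1 + sum(tNull >= tObs)) / (1 + B)
    list(perm_p = p, T_obs = tObs, significant = p < 0.05,
         B = as.integer(B), k = k)
}

#' Gene-level environment association for every gene and variable
#'
#' End-to-end association stage: per-variant Pearson correlations
#' ([variantCorrelations()]), harmonic-mean-p combination and
#' `-log10` metric per gene ([geneMetric()]), percentile ranking with
#' top-decile flags ([rankGenes()]), and optionally the variant-count-matched
#' permutation test for selected genes.
#'
#' @param fm A [FrequencyMatrix-class] whose `rowData(fm)$gene` assigns each
#'   variant to a gene (variants with `NA` gene are ignored).
#' @param eco Ecological table from [readEcoTable()].
#' @param permGenes Character vector of genes to permutation-test
#'   (default none, since the test is the expensive step).
#' @param B,seed Permutation replicates and seed (seed required if
#'   `permGenes` is non-empty).
#' @param adjust Also compute the asymptotically exact adjusted combined p
#'   per gene (default `TRUE`; the ranking metric always uses the raw HMP).
#' @return A `data.frame` with one row per (gene, variable): `gene`,
#'   `variable`, `L`, `combined_p`, `combined_p_adjusted`, `metric`,
#'   `percentile`, `top_decile`, `perm_p`, `significant`. The per-variant
#'   correlation table is attached as `attr(, "correlations")`.
#' @export
associateGenes <- function(fm, eco, permGenes = character(0L), B = 1000L,
                           seed = NULL, adjust = TRUE) {
    genes <- SummarizedExperiment::rowData(fm)$gene
    if (is.null(genes))
        stop("rowData(fm)$gene must assign each variant to a gene")
    if (length(permGenes) && is.null(seed))
        stop("an explicit integer 'seed' is required for permutation tests")
    corrs <- variantCorrelations(fm, eco)
    corrs$gene <- genes[match(corrs$variant, rownames(fm))]
    corrs <- corrs[!is.na(corrs$gene), , drop = FALSE]
    if (nrow(corrs) == 0L)
        stop("no usable variant correlations")
    metrics <- do.call(rbind, lapply(
        split(corrs, list(corrs$gene, corrs$variable), drop = TRUE),
        function(d) {
            h <- harmonicMeanP(d$p, adjust = adjust)
            data.frame(gene = d$gene[1L], variable = d$variable[1L],
                       L = h$L, combined_p = h$raw,
                       combined_p_adjusted = h$adjusted,
                       metric = -log10(h$raw))
        }))
    metrics <- rankGenes(metrics)
    metrics$perm_p <- NA_real_
    metrics$significant <- NA
    run <- 0L
    for (g in intersect(permGenes, metrics$gene)) {
        for (v in unique(metrics$variable)) {
            sel <- corrs$variable == v
            gr <- corrs$r[sel & corrs$gene == g]
            if (length(gr) == 0L)
                next
            run <- run + 1L   # distinct substream per (gene, variable)
            pt <- permutationTest(gr, corrs$r[sel], B = B,
                                  seed = (as.integer(seed) + 131L * run) %%
                                      .Machine$integer.max)
            row <- metrics$gene == g & metrics$variable == v
            metrics$perm_p[row] <- pt$perm_p
            metrics$significant[row] <- pt$significant
        }
    }
    rownames(metrics) <- NULL
    attr(metrics, "correlations") <- corrs
    metrics
}
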