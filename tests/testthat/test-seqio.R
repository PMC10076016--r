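test_that("FASTA reading preserves order, upper-cases, and rejects bad input", {
    f <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">a", "acgt"), f)
    x <- readFastaDNA(f)
    expect_identical(as.character(x), c(a = "ACGT"))

    writeLines(c(">a", "ACGT", ">b desc text", "GGCC"), f)
    x <- readFastaDNA(f)
    expect_identical(names(x), c("a", "b"))
    expect_identical(as.character(x[["b"]]), "GGCC")

    writeLines(c(">a", "ACGT", ">a", "GGCC"), f)
    expect_error(readFastaDNA(f), "duplicate.*a")

    writeLines(c("ACGT", ">a", "ACGT"), f)
    expect_error(readFastaDNA(f), "line 1")

    writeLines(character(0L), f)
    expect_error(readFastaDNA(f), "empty")
})

test_that("GC content matches hand counts and excludes N", {
    expect_equal(unname(gcContent("ATGC")), 50)
    expect_equal(unname(gcContent("GGCC")), 100)
    expect_equal(unname(gcContent("ANGC")), 100 * 2 / 3)  # N dropped both sides
    expect_error(gcContent("NNNN"), "undefined")
})

test_that("GC and AT content are complementary on N-free sequences", {
    atContent <- function(s) {   # defined analogously, test-side
        ch <- strsplit(s, "")[[1L]]
        100 * sum(ch %in% c("A", "T")) / sum(ch %in% c("A", "C", "G", "T"))
    }
    seqs <- withr::with_seed(7L, vapply(1:25, function(i)
        paste(sample(c("A", "C", "G", "T"), 30L, replace = TRUE),
              collapse = ""), character(1L)))
    expect_equal(unname(gcContent(seqs)) + vapply(seqs, atContent, numeric(1L)),
                 rep(100, 25L), ignore_attr = TRUE)
})

test_that("percentile rank follows the midpoint tie rule", {
    expect_equal(percentileRank(3, c(1, 2, 3, 4, 5)), 50)        # hand count
    expect_equal(percentileRank(4, c(1, 2, 3, 4, 5, 6, 7)), 50)  # odd-N median
    pop <- c(1:99, 100)
    expect_equal(percentileRank(100, pop), 99.5)                 # strict max
    expect_error(percentileRank(1, numeric(0L)), "non-empty")
})

test_that("percentile rank is monotone non-decreasing in the value", {
    pop <- withr::with_seed(3L, sample(rep(1:20, 3L)))
    vals <- seq(0, 21, by = 0.5)
    pct <- vapply(vals, percentileRank, numeric(1L), population = pop)
    expect_true(all(diff(pct) >= 0))
})

test_that("signal peptide cleavage slices and validates", {
    p <- Biostrings::AAStringSet(c(p1 = "MKWLAAA"))
    expect_identical(as.character(cleaveSignal(p, cleavageIndex = 4L)),
                     c(p1 = "AAA"))
    expect_identical(as.character(cleaveSignal(p, cleavageIndex = 0L)),
                     c(p1 = "MKWLAAA"))
    expect_error(cleaveSignal(p, cleavageIndex = 7L), "empty mature")
    expect_error(cleaveSignal(p), "missing")

    cl <- data.frame(protein_id = "p1", cleavage_index = 4L)
    f <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">p1", "MKWLAAA"), f)
    prot <- readFastaProtein(f, cleavage = cl)
    expect_identical(as.character(cleaveSignal(prot)), c(p1 = "AAA"))
})

test_that("amino-acid composition is a mean of per-protein percents", {
    comp <- aaComposition("AAAA")
    expect_equal(unname(comp["A"]), 100)
    expect_equal(unname(comp["W"]), 0)
    expect_length(comp, 21L)  # 20 residues + X, zeros included

    comp <- aaComposition("ACDE")
    expect_equal(unname(comp[c("A", "C", "D", "E")]), rep(25, 4L))

    # mean of percents, not pooled counts: pooled would give A 50 only if
    # lengths were equal; make them unequal to discriminate
    comp <- aaComposition(c("AA", "CCCCCC"))
    expect_equal(unname(comp["A"]), 50)
    expect_equal(unname(comp["C"]), 50)

    expect_error(aaComposition(character(0L)), "non-empty")
    expect_error(aaComposition(c("AA", "")), "empty")
})

test_that("composition sums to 100 for any input set and respects minLength", {
    seqs <- withr::with_seed(11L, vapply(1:10, function(i)
        paste(sample(c(adaptscan:::.AA20, "X"), sample(60:120, 1L),
                     replace = TRUE), collapse = ""), character(1L)))
    expect_equal(sum(aaComposition(seqs)), 100, tolerance = 1e-9)

    # X is its own category; the 20 standard letters alone need not sum to 100
    withX <- aaComposition("AXXX")
    expect_equal(unname(withX["X"]), 75)

    expect_equal(unname(aaComposition(c("AA", "CCC"), minLength = 3L)["C"]),
                 100)
    expect_error(aaComposition("AA", minLength = 60L), "no protein")
})

test_that("cleaved composition matches hand counts end to end", {
    p <- Biostrings::AAStringSet(c(x = "MKWDDEE"))  # signal MKW, mature DDEE
    comp <- aaComposition(cleaveSignal(p, cleavageIndex = 3L))
    expect_equal(unname(comp["D"]), 50)
    expect_equal(unname(comp["E"]), 50)
    expect_equal(unname(comp["M"]), 0)
})
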