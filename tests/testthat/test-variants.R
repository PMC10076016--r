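test_that("multiallelic splitting recodes genotypes per alternate allele", {
    info <- data.frame(chrom = "chr1", pos = 100L, id = "m1", ref = "A",
                       alt = "T,G", qual = 40)
    a1 <- matrix(c(0L, 0L), 1L, dimnames = list(NULL, c("i1", "i2")))
    a2 <- matrix(c(1L, 2L), 1L, dimnames = list(NULL, c("i1", "i2")))
    vs <- VariantSet(info, a1, a2)   # genotypes 0/1 and 0/2
    sp <- splitMultiallelic(vs)
    expect_equal(length(sp), 2L)
    expect_equal(variantInfo(sp)$alt, c("T", "G"))
    # first split record: the 0/2 individual's alt-2 allele becomes missing
    expect_equal(unname(sp@a2[1L, ]), c(1L, NA_integer_))
    expect_equal(unname(sp@a1[1L, ]), c(0L, 0L))
    # second split record: the 0/1 individual's alt-1 allele becomes missing
    expect_equal(unname(sp@a2[2L, ]), c(NA_integer_, 1L))
    expect_equal(variantInfo(sp)$qual, c(40, 40))

    # biallelic input passes through unchanged
    vs2 <- toyFilterFixture()
    expect_equal(splitMultiallelic(vs2)@a1, vs2@a1)

    # record with no alternate allele disappears
    info$alt <- "."
    vs3 <- VariantSet(info, a1, a2)
    expect_equal(length(splitMultiallelic(vs3)), 0L)
})

test_that("population allele frequencies match hand counts", {
    info <- data.frame(chrom = "c", pos = 1L, id = "v", ref = "A", alt = "T",
                       qual = 50)
    panel <- data.frame(individual_id = paste0("i", 1:5),
                        population_id = "pop")
    # genotypes 0/1, 0/0, 1/1, 0/0, ./.
    a1 <- matrix(c(0L, 0L, 1L, 0L, NA), 1L,
                 dimnames = list(NULL, panel$individual_id))
    a2 <- matrix(c(1L, 0L, 1L, 0L, NA), 1L,
                 dimnames = list(NULL, panel$individual_id))
    fm <- populationAlleleFrequency(VariantSet(info, a1, a2), panel)
    expect_equal(unname(SummarizedExperiment::assay(fm, "AN")[1L, 1L]), 8L)
    expect_equal(unname(SummarizedExperiment::assay(fm, "AC")[1L, 1L]), 3L)
    expect_equal(unname(alleleFrequencies(fm)[1L, 1L]), 0.375)

    # all missing -> NA; all hom alt -> 1
    a1[] <- NA_integer_; a2[] <- NA_integer_
    expect_true(is.na(alleleFrequencies(
        populationAlleleFrequency(VariantSet(info, a1, a2), panel))[1L, 1L]))
    a1[] <- 1L; a2[] <- 1L
    expect_equal(unname(alleleFrequencies(
        populationAlleleFrequency(VariantSet(info, a1, a2), panel))[1L, 1L]), 1)

    # unknown individual is reported by name
    expect_error(populationAlleleFrequency(VariantSet(info, a1, a2),
                                           panel[1:3, ]),
                 "absent from panel.*i4")
})

test_that("allele counts are conserved under the population partition", {
    vs <- toyFilterFixture()
    panel <- toyPanel()
    fm <- populationAlleleFrequency(vs, panel)
    AN <- SummarizedExperiment::assay(fm, "AN")
    AC <- SummarizedExperiment::assay(fm, "AC")
    totalCalled <- rowSums(!is.na(vs@a1)) + rowSums(!is.na(vs@a2))
    totalAlt <- rowSums(vs@a1 == 1L, na.rm = TRUE) +
        rowSums(vs@a2 == 1L, na.rm = TRUE)
    expect_equal(unname(rowSums(AN)), unname(totalCalled))
    expect_equal(unname(rowSums(AC)), unname(totalAlt))
})

test_that("the six-record fixture filters to two survivors with the right tally", {
    flt <- filterVariants(toyFilterFixture(), toyPanel())
    expect_identical(flt$keptIds, c("v1", "v6"))
    expect_equal(flt$tally, c(missing = 1L, qual = 2L, af = 1L))
})

test_that("filter boundaries are strict as worded", {
    panel <- data.frame(individual_id = paste0("i", 1:10),
                        population_id = "pop")
    mkVs <- function(qual, nMissing, nHet) {
        g <- rep(0L, 10L)
        a1 <- a2 <- matrix(g, 1L, dimnames = list(NULL, panel$individual_id))
        if (nHet > 0L) a2[1L, seq_len(nHet)] <- 1L
        if (nMissing > 0L) {
            idx <- 10L - seq_len(nMissing) + 1L
            a1[1L, idx] <- NA_integer_; a2[1L, idx] <- NA_integer_
        }
        VariantSet(data.frame(chrom = "c", pos = 1L, id = "v", ref = "A",
                              alt = "T", qual = qual), a1, a2)
    }
    # AF exactly 0.05 (1/20) is retained: "less than 5%" excluded
    expect_equal(length(filterVariants(mkVs(50, 0L, 1L), panel)$variants), 1L)
    # QUAL exactly 30 is retained: "quality below 30" excluded
    expect_equal(length(filterVariants(mkVs(30, 0L, 2L), panel)$variants), 1L)
    expect_equal(length(filterVariants(mkVs(29.9, 0L, 2L), panel)$variants), 0L)
    # missing fraction exactly 0.9 is retained: "over 90%" excluded
    expect_equal(length(filterVariants(mkVs(50, 9L, 1L), panel)$variants), 1L)
    expect_equal(length(filterVariants(mkVs(50, 10L, 0L), panel)$variants), 0L)
})

test_that("filtering is idempotent and tolerates empty input", {
    vs <- toyFilterFixture()
    panel <- toyPanel()
    once <- filterVariants(vs, panel)
    twice <- filterVariants(once$variants, panel)
    expect_identical(twice$keptIds, once$keptIds)
    expect_equal(sum(twice$tally), 0L)

    empty <- filterVariants(vs[integer(0L)], panel)
    expect_equal(length(empty$variants), 0L)
    expect_equal(sum(empty$tally), 0L)
})

test_that("toy VCF round-trips through VariantAnnotation to the same frequencies", {
    vs <- toyFilterFixture()
    panel <- toyPanel()
    f <- withr::local_tempfile(fileext = ".vcf")
    writeToyVcf(vs, f)
    back <- readVcfGenotypes(f)
    expect_equal(variantInfo(back)$pos, variantInfo(vs)$pos)
    expect_equal(variantInfo(back)$qual, variantInfo(vs)$qual)
    expect_equal(unname(back@a1), unname(vs@a1))
    expect_equal(unname(back@a2), unname(vs@a2))
    fmA <- populationAlleleFrequency(vs, panel)
    fmB <- populationAlleleFrequency(back, panel)
    expect_equal(alleleFrequencies(fmA), alleleFrequencies(fmB),
                 ignore_attr = TRUE)

    # empty set -> header-only file
    f2 <- withr::local_tempfile(fileext = ".vcf")
    writeToyVcf(vs[integer(0L)], f2)
    expect_true(all(startsWith(readLines(f2), "#")))
})

test_that("haploid genotype calls are rejected", {
    f <- withr::local_tempfile(fileext = ".vcf")
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"G\">",
                 "##contig=<ID=chr1>",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ti1",
                 "chr1\t5\tv1\tA\tT\t40\tPASS\t.\tGT\t1"), f)
    expect_error(readVcfGenotypes(f), "haploid")
})

test_that("variants map to genes through 1-based inclusive intervals", {
    vs <- toyFilterFixture()   # positions 100..600
    iv <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                     start_1based = c(100L, 400L), end_1based = c(300L, 450L))
    g <- assignVariantsToGenes(vs, iv)
    expect_equal(g, c("gA", "gA", "gA", "gB", NA, NA))
})
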