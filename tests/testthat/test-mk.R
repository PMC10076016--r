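test_that("site classification matches hand-worked cases", {
    # identity: nothing to count
    ing <- c(h1 = "ATGGGG", h2 = "ATGGGG")
    tab <- classifySites(PopulationAlignment(ing, "ATGGGG"))
    expect_identical(as.vector(as.matrix(tab)), rep(0L, 4L))

    # one synonymous segregating site (Gly GGG/GGA), outgroup GGG
    ing <- c(h1 = "ATGGGG", h2 = "ATGGGG", h3 = "ATGGGA", h4 = "ATGGGA")
    tab <- classifySites(PopulationAlignment(ing, "ATGGGG"))
    expect_equal(tab@Ps, 1L)
    expect_equal(tab@Pn + tab@Dn + tab@Ds, 0L)

    # monomorphic ingroup AAA (Lys), outgroup CAA (Gln): one Dn
    ing <- c(h1 = "ATGAAA", h2 = "ATGAAA")
    tab <- classifySites(PopulationAlignment(ing, "ATGCAA"))
    expect_equal(tab@Dn, 1L)
    expect_equal(tab@Ds + tab@Pn + tab@Ps, 0L)

    # synonymous divergence: GGG vs GGA, ingroup monomorphic
    ing <- c(h1 = "ATGGGG", h2 = "ATGGGG")
    tab <- classifySites(PopulationAlignment(ing, "ATGGGA"))
    expect_equal(tab@Ds, 1L)
})

test_that("a site both polymorphic and divergent counts as polymorphism only", {
    # position segregates G/A in the ingroup AND the outgroup carries A
    ing <- c(h1 = "ATGGGG", h2 = "ATGGGG", h3 = "ATGGGA")
    tab <- classifySites(PopulationAlignment(ing, "ATGGGA"))
    expect_equal(tab@Ps, 1L)
    expect_equal(tab@Ds, 0L)
})

test_that("multiple segregating positions in one codon classify independently", {
    # codon GGG; position 2 segregates G/A (Gly->Glu, nonsyn),
    # position 3 segregates G/A (Gly->Gly, syn); major codon stays GGG
    ing <- c(h1 = "GGGATG", h2 = "GGGATG", h3 = "GAGATG", h4 = "GGAATG")
    tab <- classifySites(PopulationAlignment(ing, "GGGATG"))
    expect_equal(tab@Pn, 1L)
    expect_equal(tab@Ps, 1L)
})

test_that("codons with gaps, N, or stops are excluded; none left is an error", {
    ing <- c(h1 = "ATG---GGG", h2 = "ATGAAAGGG")
    tab <- classifySites(PopulationAlignment(ing, "ATGAANGGA"))
    # codons 2 (gap, N) dropped; codon 3 contributes Ds
    expect_equal(tab@Ds, 1L)

    ing <- c(h1 = "---", h2 = "---")
    expect_error(classifySites(PopulationAlignment(ing, "ATG")),
                 "no analyzable")
})

test_that("using an ingroup haplotype as outgroup yields zero divergence", {
    sim <- simulatePopulationCds(nCodons = 200L, nPolymorphisms = 30L,
                                 nDivergences = 0L, seed = 77L)
    haps <- alignedSequences(ingroup(sim$popaln))
    pa <- PopulationAlignment(CodonAlignment(haps), as.character(haps[[1L]]))
    tab <- classifySites(pa)
    expect_equal(tab@Dn + tab@Ds, 0L)
})

test_that("alpha follows its closed form and its domain", {
    expect_equal(mkAlpha(MKTable(20, 10, 5, 10)), 0.75)
    expect_equal(mkAlpha(MKTable(10, 10, 10, 10)), 0)   # neutral
    expect_error(mkAlpha(MKTable(0, 10, 10, 10)), "undefined")
    expect_error(mkAlpha(MKTable(10, 10, 10, 0)), "undefined")
})

test_that("adding a nonsynonymous divergence weakly increases alpha", {
    tab <- MKTable(5, 10, 10, 10)
    for (dn in 6:30) {
        nxt <- MKTable(dn, 10, 10, 10)
        expect_gte(mkAlpha(nxt), mkAlpha(tab))
        tab <- nxt
    }
})

test_that("Fisher's exact test matches enumeration and conventions", {
    # full enumeration over k = 0..4 gives 34/70
    expect_equal(fisherExact2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)),
                 34 / 70)
    expect_equal(fisherExact2x2(matrix(c(5, 5, 5, 5), 2, byrow = TRUE)), 1)
    expect_warning(p <- fisherExact2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
                   "zero margin")
    expect_equal(p, 1)
})

test_that("Fisher p agrees with stats::fisher.test on random tables", {
    tabs <- withr::with_seed(13L,
        matrix(rpois(4L * 100L, 6) + 1L, ncol = 4L))
    for (i in seq_len(nrow(tabs))) {
        m <- matrix(tabs[i, ], 2L)
        expect_equal(fisherExact2x2(m), stats::fisher.test(m)$p.value,
                     tolerance = 1e-12)
    }
})

test_that("mkTest returns NA alpha on undefined tables instead of failing", {
    r <- mkTest(MKTable(0, 5, 3, 4))
    expect_true(is.na(mkResultAlpha(r)))
    expect_true(mkResultP(r) >= 0 && mkResultP(r) <= 1)
    r <- mkTest(MKTable(20, 10, 5, 10))
    expect_equal(mkResultAlpha(r), 0.75)
})

test_that("alpha is recovered from tables with large expected counts", {
    # expected cells: Dn = Ds = Ps = 300, Pn = 300 * (1 - alpha)
    for (target in c(0.25, 0.5, 0.8)) {
        alphas <- withr::with_seed(round(1000 * target), vapply(1:200, function(i) {
            tab <- MKTable(rpois(1L, 300), rpois(1L, 300),
                           rpois(1L, 300 * (1 - target)), rpois(1L, 300))
            mkAlpha(tab)
        }, numeric(1L)))
        expect_lt(abs(mean(alphas) - target), 0.05)
    }
})
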