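test_that("codon site counts match neighbour enumeration on worked examples", {
    expect_equal(codonSiteCounts("TTT"),
                 c(s_sites = 1 / 3, n_sites = 8 / 3))   # only TTT->TTC is syn
    expect_equal(codonSiteCounts("ATG"), c(s_sites = 0, n_sites = 3))
    expect_error(codonSiteCounts("TAA"), "stop")
    expect_error(codonSiteCounts("AC"), "3-mer")
})

test_that("site counts always sum to 3 across the sense codons", {
    for (cd in allSenseCodons())
        expect_equal(sum(codonSiteCounts(cd)), 3)
})

test_that("codon differences average over minimal pathways", {
    expect_equal(countCodonDifferences("GGG", "GGA"), c(sd = 1, nd = 0))
    expect_equal(countCodonDifferences("AAA", "CAA"), c(sd = 0, nd = 1))
    # two pathways: TTT->GTT->GTA = (1,1); TTT->TTA->GTA = (0,2)
    expect_equal(countCodonDifferences("TTT", "GTA"), c(sd = 0.5, nd = 1.5))
    expect_error(countCodonDifferences("TTT", "TGA"), "stop")
})

test_that("codon differences are symmetric and sum to the Hamming distance", {
    sense <- allSenseCodons()
    pairs <- withr::with_seed(5L, cbind(sample(sense, 80L, replace = TRUE),
                                        sample(sense, 80L, replace = TRUE)))
    for (i in seq_len(nrow(pairs))) {
        a <- pairs[i, 1L]; b <- pairs[i, 2L]
        d <- countCodonDifferences(a, b)
        expect_equal(d, countCodonDifferences(b, a)[c("sd", "nd")])
        ham <- sum(seqinr::s2c(a) != seqinr::s2c(b))
        expect_equal(unname(sum(d)), ham)
    }
})

test_that("Jukes-Cantor correction matches the closed form and its domain", {
    expect_equal(jukesCantor(0), 0)
    expect_equal(jukesCantor(0.3), -0.75 * log(1 - 0.4))  # 0.3831192...
    expect_error(jukesCantor(0.75), "saturation")
    expect_error(jukesCantor(-0.1), "proportion")
})

test_that("pairwise dN/dS handles identity, synonymous-only, and dS = 0", {
    aln <- CodonAlignment(c(a = "ATGAAAGGG", b = "ATGAAAGGG"))
    pr <- pairwiseDnDs(aln)
    expect_equal(pr@Sd, 0); expect_equal(pr@Nd, 0)
    expect_equal(pr@dS, 0); expect_equal(pr@dN, 0)
    expect_true(is.na(omega(pr)))
    expect_identical(pr@status, "dS_zero")

    # one synonymous difference in a context with enough synonymous sites
    aln <- CodonAlignment(c(a = "ATGAAAGGGCCC", b = "ATGAAAGGACCC"))
    pr <- pairwiseDnDs(aln)
    expect_equal(pr@Nd, 0); expect_equal(pr@Sd, 1)
    expect_gt(pr@dS, 0); expect_equal(pr@dN, 0)
    expect_equal(omega(pr), 0)

    aln <- CodonAlignment(c(a = "ATGAAA", b = "ATGCAA"))
    pr <- pairwiseDnDs(aln)
    expect_equal(pr@Sd, 0); expect_equal(pr@dS, 0)
    expect_true(is.na(omega(pr)))
    expect_identical(pr@status, "dS_zero")
})

test_that("pairwise dN/dS excludes gap/N/stop codons pairwise", {
    aln <- CodonAlignment(c(a = "ATGAAAGGGCCC", b = "ATG---GGANCC"))
    pr <- pairwiseDnDs(aln)
    expect_equal(pr@nCodons, 2L)        # codons 2 and 4 dropped
    expect_equal(pr@Sd, 1)
    expect_equal(pr@S + pr@N, 6)

    aln <- CodonAlignment(c(a = "ATGAAA", b = "------"))
    expect_error(pairwiseDnDs(aln), "no comparable codons")
})

test_that("sites and differences in pairwiseDnDs equal the per-codon sums", {
    sim <- simulateCodingPair(120L, 1, seed = 21L)
    s <- as.character(alignedSequences(sim$alignment))
    codA <- substring(s[[1L]], seq(1L, nchar(s[[1L]]), 3L),
                      seq(3L, nchar(s[[1L]]), 3L))
    codB <- substring(s[[2L]], seq(1L, nchar(s[[2L]]), 3L),
                      seq(3L, nchar(s[[2L]]), 3L))
    pr <- pairwiseDnDs(sim$alignment)
    sumS <- (sum(vapply(codA, function(x) codonSiteCounts(x)[1L], numeric(1L))) +
             sum(vapply(codB, function(x) codonSiteCounts(x)[1L], numeric(1L)))) / 2
    diffs <- mapply(function(a, b) countCodonDifferences(a, b), codA, codB)
    expect_equal(pr@S, sumS)
    expect_equal(pr@Sd, sum(diffs["sd", ]))
    expect_equal(pr@Nd, sum(diffs["nd", ]))
})

test_that("sliding windows step, end-anchor, and tile the alignment", {
    mkAln <- function(nCodons)
        simulateCodingPair(nCodons, 1, seed = 9L)$alignment

    win <- slidingWindowDnDs(mkAln(34L))
    expect_equal(nrow(win), 1L)
    expect_equal(win$start_codon, 0L)
    expect_equal(win$end_codon, 34L)

    win <- slidingWindowDnDs(mkAln(100L))
    expect_equal(win$start_codon, c(0L, 31L, 62L, 66L))  # end-anchored last
    expect_equal(win$end_codon, win$start_codon + 34L)
    covered <- sort(unique(unlist(Map(seq, win$start_codon,
                                      win$end_codon - 1L))))
    expect_equal(covered, 0:99)                          # tiling invariant

    expect_warning(win <- slidingWindowDnDs(mkAln(20L)), "shorter")
    expect_equal(nrow(win), 1L)
    expect_equal(win$end_codon, 20L)

    # identical window -> omega reported missing, not dropped
    aln <- CodonAlignment(c(a = strrep("ATG", 40L), b = strrep("ATG", 40L)))
    win <- slidingWindowDnDs(aln)
    expect_true(all(is.na(win$omega)))
    expect_true(nrow(win) >= 1L)
})

test_that("dN/dS percentile ranking excludes undefined omegas", {
    r <- rankDnDs(c(g1 = 0.1, g2 = 2.0))
    expect_equal(unname(r$percentiles), c(25, 75))

    r <- rankDnDs(c(a = 0.5, b = 0.5, c = 0.5))
    expect_equal(unname(r$percentiles), rep(50, 3L))

    r <- rankDnDs(c(a = 0.1, b = NA, c = 0.3))
    expect_identical(r$undefined, "b")
    expect_length(r$percentiles, 2L)

    expect_error(rankDnDs(c(a = NA_real_, b = NA_real_)), "at least 2")
    expect_error(rankDnDs(c(0.1, 0.2)), "named")
})

test_that("a planted fast gene ranks above the 95th percentile", {
    omegas <- vapply(1:200, function(g) {
        target <- if (g == 1L) 5 else 0.2
        sim <- simulateCodingPair(300L, target, seed = 300L + g)
        omega(pairwiseDnDs(sim$alignment))
    }, numeric(1L))
    names(omegas) <- paste0("g", 1:200)
    r <- rankDnDs(omegas)
    expect_gte(r$percentiles[["g1"]], 95)
})
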