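# Independent oracles, written against seqinr's translation (not the
# package's lookup tables), plus reusable toy fixtures built in code.

oracleTranslate <- function(codon) seqinr::translate(seqinr::s2c(codon))

oracleIsStop <- function(codon) oracleTranslate(codon) == "*"

# expected site counts by naive neighbour enumeration
oracleSiteCounts <- function(codon) {
    chars <- seqinr::s2c(codon)
    s <- 0
    for (p in 1:3) {
        syn <- 0; tot <- 0
        for (b in setdiff(c("A", "C", "G", "T"), chars[p])) {
            x <- chars; x[p] <- b
            nb <- paste(x, collapse = "")
            if (oracleIsStop(nb)) next
            tot <- tot + 1
            if (oracleTranslate(nb) == oracleTranslate(codon)) syn <- syn + 1
        }
        if (tot > 0) s <- s + syn / tot
    }
    c(s_sites = s, n_sites = 3 - s)
}

# brute-force pathway enumeration: list every ordering of the differing
# positions explicitly, walk the codon, classify each step by translation
oraclePathwayDiffs <- function(a, b) {
    ca <- seqinr::s2c(a); cb <- seqinr::s2c(b)
    pos <- which(ca != cb)
    if (length(pos) == 0L) return(c(sd = 0, nd = 0))
    orderings <- if (length(pos) == 1L) list(pos) else {
        perms <- list()
        permute <- function(prefix, rest) {
            if (length(rest) == 0L) perms[[length(perms) + 1L]] <<- prefix
            else for (r in rest) permute(c(prefix, r), setdiff(rest, r))
        }
        permute(integer(0L), pos)
        perms
    }
    paths <- lapply(orderings, function(ord) {
        cur <- ca; s <- 0; n <- 0; stopped <- FALSE
        for (p in ord) {
            nxt <- cur; nxt[p] <- cb[p]
            aa1 <- seqinr::translate(cur); aa2 <- seqinr::translate(nxt)
            if (aa2 == "*") stopped <- TRUE
            if (aa1 == aa2) s <- s + 1 else n <- n + 1
            cur <- nxt
        }
        list(s = s, n = n, stopped = stopped)
    })
    clean <- Filter(function(p) !p$stopped, paths)
    if (length(clean) == 0L) clean <- paths
    c(sd = mean(vapply(clean, `[[`, numeric(1L), "s")),
      nd = mean(vapply(clean, `[[`, numeric(1L), "n")))
}

allSenseCodons <- function() {
    all <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                             c("A", "C", "G", "T")), 1L, paste, collapse = "")
    all[!vapply(all, oracleIsStop, logical(1L))]
}

# --- toy variant fixtures -------------------------------------------------

toyPanel <- function() {
    data.frame(individual_id = c(paste0("A", 1:4), paste0("B", 1:4)),
               population_id = rep(c("P1", "P2"), each = 4L))
}

# six records engineered so that the default filters keep exactly v1 and v6:
# v2, v3 fail quality; v4 is fully missing in population P1; v5 is below 5%
# frequency in every population
toyFilterFixture <- function() {
    inds <- toyPanel()$individual_id
    gEmpty <- rep(NA_integer_, 8L)
    gClean1 <- c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L)
    mk <- function(...) matrix(c(...), nrow = 6L, byrow = TRUE,
                               dimnames = list(NULL, inds))
    #        A1 A2 A3 A4 B1 B2 B3 B4
    a1 <- mk(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L,   # v1: hets in P1
             0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L,   # v2: like v1, low qual
             0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L,   # v3: like v1, low qual
             gEmpty[1:4], 0L, 0L, 0L, 0L,      # v4: P1 fully missing
             gClean1,                          # v5: no alt anywhere
             0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L)   # v6: alt in P2
    a2 <- mk(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L,
             1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L,
             1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L,
             gEmpty[1:4], 1L, 0L, 0L, 0L,
             gClean1,
             0L, 0L, 0L, 0L, 1L, 1L, 0L, 0L)
    info <- data.frame(chrom = "chr1", pos = seq(100L, 600L, by = 100L),
                       id = paste0("v", 1:6), ref = "A", alt = "T",
                       qual = c(50, 10, 20, 50, 50, 60))
    VariantSet(info, a1, a2)
}
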