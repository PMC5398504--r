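test_that("alignment identity follows the published convention", {
    ea <- identityFromAlignment("ACGTACGT", "ACGTACGT")
    expect_identical(identityPct(ea), 100)
    # 19/20 truncates to 95.0
    a <- "ACGTACGTACGTACGTACGT"
    expect_identical(identityPct(identityFromAlignment(a, substituteAt(a, 3, seed = 1))),
                     95.0)
    # gap-vs-base counts as mismatch; both-gap columns are excluded
    ea2 <- identityFromAlignment("AC-TA-", "ACG-A-")
    expect_identical(ea2@scoredColumns, 5L)
    expect_identical(ea2@matches, 3L)
    expect_identical(identityPct(ea2), 60.0)
    # truncation, not rounding: 43/45 = 95.55... -> 95.5
    ref <- paste(rep("A", 45), collapse = "")
    row <- substituteAt(ref, c(1, 2), seed = 2)
    expect_identical(identityPct(identityFromAlignment(ref, row)), 95.5)
    expect_error(identityFromAlignment("ACGT", "ACG"), "length")
})

test_that("every verified printed identity in the end-table fixtures reproduces", {
    ver <- identityVerification()
    files <- c(is605I_left = "is605I_left_end.tsv",
               is605I_right = "is605I_right_end.tsv",
               isl3_left = "isl3_left_end.tsv",
               isl3_right = "isl3_right_end.tsv",
               typeC_left = "typeC_left_end.tsv",
               typeC_right = "typeC_right_end.tsv",
               typeD_left = "typeD_left_end.tsv",
               typeD_right = "typeD_right_end.tsv")
    nChecked <- 0
    for (key in names(files)) {
        suppressWarnings(
            da <- parseDottedAlignment(fixturePath(files[[key]]),
                                       dropBadRows = TRUE))
        tab <- endIdentityTable(da)
        verified <- names(ver[[key]])[unlist(ver[[key]])]
        tab <- tab[tab$rowId %in% verified & !is.na(tab$printedIdentity), ]
        expect_true(all(abs(tab$identityPct - tab$printedIdentity) <= 0.1),
                    info = key)
        # truncation makes the verified rows exact
        expect_identical(tab$identityPct, tab$printedIdentity)
        nChecked <- nChecked + nrow(tab)
    }
    expect_gte(nChecked, 130)
})

test_that("end alignment is symmetric and monotone under substitutions", {
    set.seed(111)
    for (i in 1:10) {
        a <- randomDna(40)
        b <- substituteAt(a, sample(40, 5))
        # indel
        b <- paste0(substr(b, 1, 17), substr(b, 20, 40))
        expect_identical(identityPct(alignEnds(a, b)),
                         identityPct(alignEnds(b, a)))
    }
    # adding a substitution never increases identity
    ref <- randomDna(50, seed = 112)
    row <- ref
    last <- 100
    for (pos in c(5, 12, 23, 34, 45)) {
        row <- substituteAt(row, pos)
        cur <- identityPct(identityFromAlignment(ref, row))
        expect_lte(cur, last)
        last <- cur
    }
})

test_that("planted inverted repeats are recovered exactly", {
    set.seed(121)
    ir <- randomDna(25)
    up <- paste0(randomDna(475), ir)          # repeat abuts the start codon
    gene <- randomDna(600)
    down <- paste0(reverseComplementSeq(ir), randomDna(475))
    fg <- new("FlankedGene", geneId = "g", contigId = "c", start = 476L,
              end = 1075L, strand = "+", geneSeq = gene, upstream = up,
              downstream = down, window = 500L)
    re <- findInvertedRepeats(fg, minLen = 20)
    expect_false(is.null(re))
    expect_identical(re@leftSeq, ir)
    expect_identical(re@rightSeq, reverseComplementSeq(ir))
    expect_identical(re@mismatches, 0L)
    expect_identical(re@leftDistance, 0L)
    expect_identical(re@rightDistance, 0L)
})

test_that("a repeat with 3 substitutions in 30 bp is found with 3 mismatches", {
    set.seed(131)
    ir <- randomDna(30)
    irMut <- substituteAt(ir, c(5, 15, 25))
    up <- paste0(randomDna(300), ir, randomDna(10))
    gene <- randomDna(400)
    down <- paste0(randomDna(10), reverseComplementSeq(irMut), randomDna(300))
    fg <- new("FlankedGene", geneId = "g", contigId = "c", start = 321L,
              end = 720L, strand = "+", geneSeq = gene, upstream = up,
              downstream = down, window = 400L)
    re <- findInvertedRepeats(fg, minLen = 20, maxMismatchFrac = 0.25)
    expect_false(is.null(re))
    expect_identical(re@mismatches, 3L)
    # the reported left end covers the planted repeat (chance matches may
    # extend it by a base or two on either side)
    expect_true(grepl(ir, re@leftSeq, fixed = TRUE))
    expect_lte(re@alignedLength, 36L)
})

test_that("the scan scoring agrees with an exhaustive local-alignment oracle", {
    set.seed(141)
    sub <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                    baseOnly = FALSE)
    for (i in 1:8) {
        a <- randomDna(sample(60:200, 1))
        b <- randomDna(sample(60:200, 1))
        aln <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                             substitutionMatrix = sub,
                                             gapOpening = 0, gapExtension = 2)
        expect_equal(aln@score, swOracleScore(a, b))
    }
})

test_that("random flanks rarely produce a spurious repeat call", {
    set.seed(151)
    hits <- 0
    for (i in 1:25) {
        fg <- new("FlankedGene", geneId = "g", contigId = "c", start = 1001L,
                  end = 1300L, strand = "+", geneSeq = randomDna(300),
                  upstream = randomDna(1000), downstream = randomDna(1000),
                  window = 1000L)
        re <- suppressMessages(findInvertedRepeats(fg, minLen = 20,
                                                   maxMismatchFrac = 0.1))
        if (!is.null(re)) hits <- hits + 1
    }
    expect_lte(hits, 1)
})

test_that("end distances carry the published sign convention", {
    mkFeat <- function(s, e, strand = "+") {
        gr <- GenomicRanges::GRanges("c", IRanges::IRanges(s, e),
                                     strand = strand)
        S4Vectors::mcols(gr)$gene_id <- "g"
        gr
    }
    ft <- mkFeat(1042, 2041)
    # repeat ending 41 bp before the start codon
    expect_identical(endDistance(950, 1000, ft, "left"), 41L)
    # repeat beginning 33 bp inside the gene (right end)
    expect_identical(endDistance(2009, 2060, ft, "right"), -33L)
    # repeat abutting the start codon
    expect_identical(endDistance(991, 1041, ft, "left"), 0L)
    # minus strand mirrors the convention
    ftm <- mkFeat(1042, 2041, "-")
    expect_identical(endDistance(2083, 2120, ftm, "left"), 41L)
    expect_identical(endDistance(991, 1041, ftm, "right"), 0L)
})
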