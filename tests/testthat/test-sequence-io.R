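test_that("FASTA reading normalizes case, maps U to T, and validates", {
    tf <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">x some description", "acgu", ">y", "GGNNCC"), tf)
    g <- readGenomes(tf)
    expect_identical(names(g), c("x", "y"))
    expect_identical(as.character(g[[1]]), "ACGT")
    expect_identical(as.character(g[[2]]), "GGNNCC")

    bad <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">x", "ACJT"), bad)
    expect_error(readGenomes(bad), "illegal character 'J'")

    dup <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">x", "ACGT", ">x", "ACGT"), dup)
    expect_error(readGenomes(dup), "duplicate")

    empty <- withr::local_tempfile(fileext = ".fa")
    writeLines(character(0), empty)
    expect_error(readGenomes(empty), "no FASTA records")
})

test_that("FASTA round trip preserves ids and sequences exactly", {
    tf <- withr::local_tempfile(fileext = ".fa")
    set.seed(11)
    seqs <- vapply(1:5, function(i) randomDna(50 + i), "")
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- paste0("contig", 1:5)
    writeGenomes(x, tf)
    y <- readGenomes(tf)
    expect_identical(names(y), names(x))
    expect_identical(as.character(y), as.character(x))
})

test_that("feature tables parse, validate and cross-check against the genome", {
    tf <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("contig\tstart\tend\tstrand\tgene_id",
                 "c1\t100\t400\t+\tg1",
                 "c1\t500\t520\t-\tg2"), tf)
    ft <- readFeatures(tf, "tsv")
    expect_s4_class(ft, "GRanges")
    expect_identical(GenomicRanges::start(ft), c(100L, 500L))
    expect_identical(GenomicRanges::end(ft)[1], 400L)
    expect_identical(S4Vectors::mcols(ft)$gene_id, c("g1", "g2"))

    bad <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("contig\tstart\tend\tstrand\tgene_id",
                 "c1\t400\t100\t+\tg1"), bad)
    expect_error(readFeatures(bad, "tsv"), "start > end")

    genome <- Biostrings::DNAStringSet(c(c1 = randomDna(450, seed = 1)))
    expect_error(readFeatures(tf, "tsv", genome = genome),
                 "beyond contig end")
    other <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("contig\tstart\tend\tstrand\tgene_id",
                 "nope\t1\t10\t+\tg1"), other)
    expect_error(readFeatures(other, "tsv", genome = genome),
                 "not in genome")
})

test_that("GFF3 features are read 1-based inclusive and '.' strand is rejected", {
    gff <- withr::local_tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3",
                 "c1\tsrc\tgene\t100\t400\t.\t+\t.\tID=g1;product=transposase"),
               gff)
    ft <- readFeatures(gff, "gff3")
    expect_identical(GenomicRanges::start(ft), 100L)
    expect_identical(GenomicRanges::end(ft), 400L)
    expect_identical(S4Vectors::mcols(ft)$gene_id, "g1")

    gff2 <- withr::local_tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3",
                 "c1\tsrc\tgene\t100\t400\t.\t.\t.\tID=g1"), gff2)
    expect_error(readFeatures(gff2, "gff3"), "strand")
})

test_that("flank extraction matches direct slicing on both strands", {
    set.seed(21)
    gseq <- randomDna(5000)
    genome <- Biostrings::DNAStringSet(c(c1 = gseq))
    mkFeat <- function(s, e, strand) {
        gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(s, e),
                                     strand = strand)
        S4Vectors::mcols(gr)$gene_id <- "g"
        gr
    }
    fg <- extractFlankedGene(genome, mkFeat(1001, 2000, "+"), window = 1000)
    expect_identical(fg@upstream, substr(gseq, 1, 1000))
    expect_identical(fg@geneSeq, substr(gseq, 1001, 2000))
    expect_identical(fg@downstream, substr(gseq, 2001, 3000))

    # edge truncation
    fg2 <- extractFlankedGene(genome, mkFeat(1, 300, "+"), window = 1000)
    expect_identical(nchar(fg2@upstream), 0L)
    expect_identical(nchar(fg2@downstream), 1000L)

    # minus strand: upstream is 5' of the coding strand
    fg3 <- extractFlankedGene(genome, mkFeat(1001, 2000, "-"), window = 1000)
    expect_identical(fg3@upstream,
                     reverseComplementSeq(substr(gseq, 2001, 3000)))
    expect_identical(fg3@geneSeq,
                     reverseComplementSeq(substr(gseq, 1001, 2000)))

    # concatenation equals the strand-adjusted contiguous slice (oracle)
    for (strand in c("+", "-")) {
        fg4 <- extractFlankedGene(genome, mkFeat(1500, 1700, strand),
                                  window = 200)
        slice <- substr(gseq, 1300, 1900)
        if (strand == "-") slice <- reverseComplementSeq(slice)
        expect_identical(paste0(fg4@upstream, fg4@geneSeq, fg4@downstream),
                         slice)
    }
})

test_that("dot-notation rows expand by the published conventions", {
    da <- parseDottedAlignment(c("ref TTACG", "r1 ..G.-", "r2 ....."))
    expect_identical(da@expandedRows, c("TTGC-", "TTACG"))

    # en-dash gaps are accepted and normalized
    da2 <- parseDottedAlignment(c("ref TTACG", "r1 ..–.."))
    expect_identical(da2@expandedRows, "TT-CG")

    expect_error(parseDottedAlignment(c("ref TTACG", "r1 ...")),
                 "r1")
    expect_error(parseDottedAlignment(c("ref TT-CG", "r1 ....G")),
                 "under a reference gap")
    expect_warning(
        da3 <- parseDottedAlignment(data.frame(id = c("ref", "r1", "r2"),
                                               row = c("TTACG", "...", ".....")),
                                    dropBadRows = TRUE), "r1")
    expect_identical(da3@ids, "r2")
})

test_that("a fixture row with two substitutions expands onto the reference", {
    da <- parseDottedAlignment(fixturePath("typeC_left_end.tsv"))
    ref <- strsplit(da@referenceRow, "")[[1]]
    t2 <- strsplit(da@expandedRows[da@ids == "T2"], "")[[1]]
    expect_identical(sum(ref != t2), 2L)              # exactly 2 substitutions
    expect_identical(which(t2 == "-"), which(ref == "-"))  # gaps only at ref gaps
})

test_that("dotted serialization round-trips up to gap-glyph normalization", {
    for (f in c("is605I_left_end.tsv", "typeD_right_end.tsv")) {
        suppressWarnings(da <- parseDottedAlignment(fixturePath(f),
                                                    dropBadRows = TRUE))
        lines <- writeDottedAlignment(da)
        da2 <- parseDottedAlignment(lines)
        expect_identical(da2@referenceRow, da@referenceRow)
        expect_identical(da2@expandedRows, da@expandedRows)
        expect_identical(da2@dottedRows, da@dottedRows)
    }
})

test_that("reverse complement is correct and involutive", {
    expect_identical(reverseComplementSeq("ACGT"), "ACGT")
    expect_identical(reverseComplementSeq("AAAC"), "GTTT")
    expect_identical(reverseComplementSeq("AN"), "NT")
    expect_error(reverseComplementSeq("AXGT"), "illegal")
    set.seed(31)
    for (i in 1:20) {
        s <- randomDna(sample(1:80, 1))
        expect_identical(reverseComplementSeq(reverseComplementSeq(s)), s)
    }
})
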