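test_that("composition models are seeded, stochastic and well formed", {
    m1 <- sampleComposition(1)
    m1b <- sampleComposition(1)
    expect_identical(m1@transition, m1b@transition)
    expect_true(all(abs(rowSums(m1@transition) - 1) < 1e-12))
    expect_true(all(m1@transition > 0))
    expect_equal(sum(m1@initial), 1, tolerance = 1e-9)
    expect_error(sampleComposition(1, concentration = 0), "> 0")
    # distinct seeds give distinct stationary compositions
    divs <- vapply(1:10, function(i)
        modelDivergence(sampleComposition(2 * i),
                        sampleComposition(2 * i + 1)), 0)
    expect_true(all(divs >= 0.02))
})

test_that("generated genomes converge to the stationary tetramer distribution", {
    m <- sampleComposition(5)
    g <- generateGenome(m, 1e5, seed = 9)
    expect_identical(Biostrings::width(g), 100000L)
    g2 <- generateGenome(m, 1e5, seed = 9)
    expect_identical(as.character(g[[1]]), as.character(g2[[1]]))
    # eigen-analysis oracle: stationary tetramer distribution of the chain
    p <- tetraFrequencies(tetraProfile(as.character(g[[1]]), alpha = 0))
    tv <- 0.5 * sum(abs(p - stationaryTetra(m)))
    expect_lte(tv, 0.05)
    expect_error(generateGenome(m, 5000, seed = 1), "10 kb")
})

test_that("synthetic IS elements have the canonical structure", {
    m <- sampleComposition(7)
    el <- buildIsElement(m, orfLen = 300, irLen = 30, seed = 3)
    expect_identical(nchar(el$sequence), 2L * 30L + 300L)
    orf <- substr(el$sequence, el$geneStart, el$geneEnd)
    expect_identical(substr(orf, 1, 3), "ATG")
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(orf)))
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
    # ends are a perfect inverted-repeat pair
    expect_identical(substr(el$sequence, 331, 360),
                     reverseComplementSeq(substr(el$sequence, 1, 30)))
    # palindromic mode: the end is its own reverse complement
    ep <- buildIsElement(m, orfLen = 300, irLen = 30, palindromic = TRUE,
                         seed = 3)
    left <- substr(ep$sequence, 1, 30)
    expect_identical(left, reverseComplementSeq(left))
    expect_error(buildIsElement(m, orfLen = 301), "multiple of 3")
})

test_that("the IR scanner recovers a planted element end to end", {
    m <- sampleComposition(11)
    el <- buildIsElement(m, orfLen = 600, irLen = 30, seed = 4)
    genome <- generateGenome(sampleComposition(12), 2e4, seed = 5,
                             id = "host")
    imp <- implantElements(genome, list(el), mu = 0, seed = 6)
    fg <- extractFlankedGene(imp$genome, imp$features[1], window = 500)
    re <- findInvertedRepeats(fg)
    expect_false(is.null(re))
    # the reported ends cover the planted repeats; chance matches in the
    # surrounding genome may extend the best-scoring alignment a little
    expect_true(grepl(substr(el$sequence, 1, 30), re@leftSeq, fixed = TRUE))
    expect_true(grepl(substr(el$sequence, 631, 660), re@rightSeq,
                      fixed = TRUE))
    expect_lte(abs(re@leftDistance), 6L)
    expect_lte(abs(re@rightDistance), 6L)
})

test_that("implantation keeps coordinates and truth labels consistent", {
    m <- sampleComposition(13)
    els <- lapply(1:3, function(i)
        buildIsElement(m, orfLen = 300, irLen = 20, seed = 20 + i,
                       id = paste0("e", i)))
    genome <- generateGenome(m, 2e4, seed = 14, id = "host")
    imp <- implantElements(genome, els, copies = c(2L, 1L, 1L), mu = 0.02,
                           seed = 15, origin = c("native", "transferred",
                                                 "native"),
                           donorId = c("host", "donor", "host"))
    expect_identical(nrow(imp$truth), 4L)
    gseq <- as.character(imp$genome[[1]])
    for (k in seq_len(nrow(imp$truth))) {
        tr <- imp$truth[k, ]
        expect_identical(substr(gseq, tr$elementStart, tr$elementEnd),
                         unname(imp$elementSeqs[tr$elementId]))
    }
    # mu = 0 copies are identical to the template
    imp0 <- implantElements(genome, els[1], copies = 2L, mu = 0, seed = 16)
    expect_identical(unname(imp0$elementSeqs[1]), els[[1]]$sequence)
    expect_identical(unname(imp0$elementSeqs[2]), els[[1]]$sequence)
    expect_identical(imp0$truth$substitutions, c(0L, 0L))
})

test_that("substitution counts behave binomially", {
    m <- sampleComposition(17)
    el <- buildIsElement(m, orfLen = 960, irLen = 20, seed = 18)  # 1000 bp
    genome <- generateGenome(m, 7e4, seed = 19, id = "host")
    imp <- implantElements(genome, list(el), copies = 50L, mu = 0.01,
                           seed = 20)
    subs <- imp$truth$substitutions
    # mean of 50 Binomial(1000, 0.01) draws: 10 +/- 3 * sd/sqrt(50)
    expect_lt(abs(mean(subs) - 10), 3 * sqrt(1000 * 0.01 * 0.99 / 50))
})

test_that("one master seed fixes the whole simulated study", {
    s1 <- simulateHgtStudy(3, genomeLength = 1e4, nTransferred = 2,
                           nNative = 2, orfLen = 300)
    s2 <- simulateHgtStudy(3, genomeLength = 1e4, nTransferred = 2,
                           nNative = 2, orfLen = 300)
    expect_identical(as.character(s1$recipientGenome[[1]]),
                     as.character(s2$recipientGenome[[1]]))
    expect_identical(s1$truth, s2$truth)
    expect_identical(s1$comparators$seq, s2$comparators$seq)
    # study conditions: donor and recipient compositions diverge
    expect_gte(modelDivergence(s1$models$donor, s1$models$recipient), 0.05)
    expect_identical(sort(unique(s1$truth$origin)),
                     c("native", "transferred"))
})

test_that("transferred elements sit closer to the donor genome signature", {
    sim <- simulateHgtStudy(21)
    donorProf <- tetraProfile(as.character(sim$donorGenome[[1]]),
                              ownerId = "donor", bothStrands = TRUE)
    kl <- vapply(seq_along(sim$features), function(i)
        klDivergence(tetraProfile(
            extractFlankedGene(sim$recipientGenome, sim$features[i],
                               window = 0)@geneSeq,
            ownerId = "g"), donorProf), 0)
    tr <- sim$truth$origin == "transferred"
    # pairwise: a transferred element diverges less than a native one
    expect_gte(mean(outer(kl[tr], kl[!tr], "<")), 0.9)
})
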