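.simFrom <- function(m, ids) {
    dimnames(m) <- NULL
    new("SimilarityMatrix", ids = ids, s = m, definition = "identity")
}

test_that("single-linkage grouping follows the threshold semantics", {
    ids <- c("a", "b", "c")
    all100 <- .simFrom(matrix(100, 3, 3), ids)
    g <- clusterBySimilarity(all100, threshold = 70)
    expect_length(g, 1)
    expect_identical(groupMembers(g[[1]]), ids)

    # two blocks: 95 within, 30 between
    m <- matrix(30, 4, 4); m[1:2, 1:2] <- 95; m[3:4, 3:4] <- 95; diag(m) <- 100
    g2 <- clusterBySimilarity(.simFrom(m, c("a", "b", "c", "d")), 70)
    expect_length(g2, 2)
    expect_identical(lapply(g2, groupMembers), list(c("a", "b"), c("c", "d")))

    # chain a-b 75, b-c 75, a-c 40 -> one group under single linkage
    m3 <- matrix(c(100, 75, 40, 75, 100, 75, 40, 75, 100), 3)
    g3 <- clusterBySimilarity(.simFrom(m3, ids), 70)
    expect_length(g3, 1)
})

.toyCall <- function(sOutVal, sInVal, margin = 10, kl = NULL, ir = NULL) {
    ids <- c("rep", "out1", "in1")
    m <- matrix(0, 3, 3); diag(m) <- 100
    m[1, 2] <- m[2, 1] <- sOutVal
    m[1, 3] <- m[3, 1] <- sInVal
    m[2, 3] <- m[3, 2] <- 20
    sim <- .simFrom(m, ids)
    taxa <- data.frame(id = ids,
                       genus = c("Fervidobacterium", "Caldicellulosiruptor",
                                 "Petrotoga"),
                       phylum = c("Thermotogae", "Firmicutes", "Thermotogae"))
    gp <- new("TransposaseGroup", groupId = "G1", members = "rep",
              representative = "rep", family = "")
    callHgt(gp, sim, taxa, kl = kl, ir = ir, margin = margin)
}

test_that("the verdict integrates the three evidence lines", {
    kl <- data.frame(queryId = "rep", referenceId = c("out1", "in1"),
                     dKl = c(0.02, 0.30))
    ir <- data.frame(geneId = "rep", partnerId = c("out1", "in1"),
                     leftIdentity = c(95, 45), rightIdentity = c(92, 50))
    # donor-implanted signature: high out similarity, concordant kl and ir
    expect_identical(hgtVerdict(.toyCall(98, 40, kl = kl, ir = ir)), "y")
    # native element: in-phylum similarity dominates
    expect_identical(hgtVerdict(.toyCall(40, 95, kl = kl, ir = ir)), "n")
    # E1 boundary is inclusive
    cl <- .toyCall(60, 50, margin = 10, kl = kl)
    expect_true(cl@e1)
    expect_identical(hgtVerdict(cl), "y")
    # an undetermined E3 does not veto when E2 holds
    expect_identical(hgtVerdict(.toyCall(98, 40, kl = kl, ir = NULL)), "y")
    # E1 alone is not enough when both E2 and E3 are undetermined
    expect_identical(hgtVerdict(.toyCall(98, 40)), "n")
})

test_that("no interphylum context yields 'n' with a reason", {
    ids <- c("rep", "in1")
    m <- matrix(c(100, 80, 80, 100), 2)
    sim <- .simFrom(m, ids)
    taxa <- data.frame(id = ids, genus = c("Fervidobacterium", "Petrotoga"),
                       phylum = c("Thermotogae", "Thermotogae"))
    gp <- new("TransposaseGroup", groupId = "G1", members = "rep",
              representative = "rep", family = "")
    cl <- callHgt(gp, sim, taxa)
    expect_identical(hgtVerdict(cl), "n")
    expect_match(cl@reason, "no interphylum context")
})

test_that("raising the margin never flips n to y", {
    kl <- data.frame(queryId = "rep", referenceId = c("out1", "in1"),
                     dKl = c(0.02, 0.30))
    verdicts <- vapply(seq(0, 60, by = 5), function(mg)
        hgtVerdict(.toyCall(80, 45, margin = mg, kl = kl)), "")
    flips <- paste(verdicts, collapse = "")
    expect_false(grepl("ny", flips))   # monotone: once n, stays n
})

test_that("verdicts are invariant to id relabeling and comparator order", {
    mkArgs <- function(ids) {
        m <- matrix(20, 4, 4); diag(m) <- 100
        m[1, 2] <- m[2, 1] <- 95
        m[1, 3] <- m[3, 1] <- 40
        m[1, 4] <- m[4, 1] <- 35
        taxa <- data.frame(id = ids,
                           genus = c("Fervidobacterium", "Caldicellulosiruptor",
                                     "Petrotoga", "Kosmotoga"),
                           phylum = c("Thermotogae", "Firmicutes",
                                      "Thermotogae", "Thermotogae"))
        kl <- data.frame(queryId = ids[1], referenceId = ids[2:4],
                         dKl = c(0.02, 0.3, 0.4))
        list(sim = .simFrom(m, ids), taxa = taxa, kl = kl,
             gp = new("TransposaseGroup", groupId = "G1", members = ids[1],
                      representative = ids[1], family = ""))
    }
    a <- mkArgs(c("rep", "x", "y", "z"))
    b <- mkArgs(c("r2", "q1", "q2", "q3"))
    ca <- callHgt(a$gp, a$sim, a$taxa, kl = a$kl)
    cb <- callHgt(b$gp, b$sim, b$taxa, kl = b$kl)
    expect_identical(hgtVerdict(ca), hgtVerdict(cb))
    # comparator order permutation
    cc <- callHgt(a$gp, a$sim, a$taxa[c(1, 4, 2, 3), ],
                  kl = a$kl[c(3, 1, 2), ])
    expect_identical(hgtVerdict(cc), hgtVerdict(ca))
    expect_identical(cc@sOut, ca@sOut)
    expect_identical(cc@klOut, ca@klOut)
})

test_that("the family report has one row per group and supports empty input", {
    kl <- data.frame(queryId = "rep", referenceId = c("out1", "in1"),
                     dKl = c(0.02, 0.30))
    c1 <- .toyCall(98, 40, kl = kl)
    c2 <- .toyCall(40, 95, kl = kl)
    gp <- new("TransposaseGroup", groupId = "G1", members = "rep",
              representative = "rep", family = "IS605_I")
    tab <- familyReport(list(c1, c2), list(gp, gp))
    expect_identical(nrow(tab), 2L)
    expect_identical(tab$verdict, c("y", "n"))
    expect_identical(tab$family[1], "IS605_I")
    empty <- familyReport(list(), list())
    expect_identical(nrow(empty), 0L)
    expect_true(all(c("groupId", "verdict") %in% names(empty)))
    # per-genome member counts
    tab2 <- familyReport(list(c1), list(gp), genomeOf = c(rep = "recipient"))
    expect_identical(tab2$n_recipient, 1L)
})
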