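# Order-3 Markov generators: 64 trimer contexts x 4 next bases. Trimer and
# tetramer indices are alphabetical (A,C,G,T), matching the k-mer order of
# Biostrings::oligonucleotideFrequency.

.allKmers <- function(k) {
    b <- .DNA_BASES
    out <- b
    for (i in seq_len(k - 1L)) out <- as.vector(t(outer(out, b, paste0)))
    out
}

# derive a child seed from a master seed; keeps results < 2^31
.deriveSeed <- function(seed, offset) {
    as.integer((as.numeric(seed) * 1103L + offset * 12289) %% 2147483647)
}

#' Draw a random genome composition model
#'
#' Each of the 64 trimer-context transition rows is drawn from a symmetric
#' Dirichlet with the given concentration (smaller concentration = more
#' skewed compositions, hence larger between-model divergences). The initial
#' trimer distribution is the stationary distribution of the induced trimer
#' chain, computed by eigen-decomposition.
#'
#' @param seed integer seed; the same seed always returns the same model.
#' @param concentration Dirichlet concentration, default 5 (genome-like
#'   moderate compositional bias).
#' @return a \code{\linkS4class{CompositionModel}}.
#' @export
#' @importFrom stats rgamma
sampleComposition <- function(seed, concentration = 5) {
    if (concentration <= 0)
        stop("concentration must be > 0")
    set.seed(as.integer(seed))
    g <- matrix(stats::rgamma(64L * 4L, shape = concentration), 64L, 4L)
    tr <- g / rowSums(g)
    rownames(tr) <- .allKmers(3L)
    colnames(tr) <- .DNA_BASES
    new("CompositionModel", transition = tr,
        initial = .trimerStationary(tr),
        concentration = concentration, seed = as.integer(seed))
}

# stationary distribution of the 64-state trimer chain induced by the
# transition matrix: trimer xyz -> yzb with probability T[xyz, b]
.trimerStationary <- function(tr) {
    M <- matrix(0, 64L, 64L)
    for (s in seq_len(64L)) {
        nxt <- ((s - 1L) %% 16L) * 4L + seq_len(4L)
        M[s, nxt] <- tr[s, ]
    }
    e <- eigen(t(M))
    i <- which.min(abs(e$values - 1))
    v <- Re(e$vectors[, i])
    v <- v / sum(v)
    if (any(v < -1e-9)) stop("stationary distribution has negative mass")
    v[v < 0] <- 0
    stats::setNames(v / sum(v), rownames(tr))
}

#' Stationary tetranucleotide distribution of a composition model
#'
#' \eqn{P(xyzw) = \pi(xyz) T(xyz, w)} with \eqn{\pi} the stationary trimer
#' distribution; this is the infinite-length limit of the model's genome
#' tetranucleotide profile and the natural reference for model-vs-model
#' divergence.
#'
#' @param model a \code{CompositionModel}.
#' @return named numeric vector of length 256 summing to 1.
#' @export
stationaryTetra <- function(model) {
    p <- as.vector(model@initial * model@transition)  # column-major: base w varies slowest
    # reorder: element (s, w) should be named trimer_s + base_w
    names(p) <- as.vector(outer(rownames(model@transition), .DNA_BASES, paste0))
    p[.allKmers(4L)]
}

#' K-L divergence between the stationary compositions of two models
#'
#' @param model,refModel \code{CompositionModel}s.
#' @return divergence in nats.
#' @export
modelDivergence <- function(model, refModel) {
    p <- stationaryTetra(model)
    q <- stationaryTetra(refModel)
    sum(p * log(p / q))
}

# sample n bases from the chain; returns a character scalar of length
# max(n, 3) starting with a stationary trimer
.sampleChain <- function(model, n, cum = NULL) {
    if (is.null(cum)) cum <- t(apply(model@transition, 1L, cumsum))
    s <- sample.int(64L, 1L, prob = model@initial)
    out <- integer(n)
    tri <- rownames(model@transition)[s]
    if (n <= 3L) return(substr(tri, 1L, n))
    u <- stats::runif(n - 3L)
    for (i in seq_len(n - 3L)) {
        p <- cum[s, ]
        b <- 1L + (u[i] > p[1L]) + (u[i] > p[2L]) + (u[i] > p[3L])
        out[i] <- b
        s <- ((s - 1L) %% 16L) * 4L + b
    }
    paste0(tri, paste(.DNA_BASES[out[seq_len(n - 3L)]], collapse = ""))
}

#' Generate a synthetic genome from a composition model
#'
#' Samples a sequence from the order-3 Markov chain. At realistic lengths the
#' genome's tetranucleotide profile converges to the model's stationary
#' tetramer distribution (total-variation distance of roughly a few percent
#' at 100 kb), which is what gives donor and recipient genomes their distinct
#' signatures.
#'
#' @param model a \code{CompositionModel}.
#' @param length genome length in bp (at least 10 kb).
#' @param seed integer seed.
#' @param id sequence name.
#' @return a single-sequence \code{DNAStringSet}.
#' @export
generateGenome <- function(model, length, seed, id = "genome") {
    if (length < 10000L)
        stop("genome length must be at least 10 kb")
    set.seed(as.integer(seed))
    seq <- .sampleChain(model, as.integer(length))
    x <- Biostrings::DNAStringSet(seq)
    names(x) <- id
    x
}

#' Build a synthetic IS element
#'
#' Structure: left inverted repeat + ATG-initiated, internal-stop-free ORF
#' (ending in a stop codon) sampled under the model + right repeat, where the
#' right repeat is the reverse complement of the left. With
#' \code{palindromic = TRUE} the left repeat is built as a perfect palindrome
#' (so both ends are identical and self-reverse-complementary), mimicking the
#' palindromic ends of some IS families; this requires an even repeat
#' length.
#'
#' @param model a \code{CompositionModel}.
#' @param orfLen ORF length in bp including start and stop codons; must be a
#'   multiple of 3 (default 1002, a typical transposase).
#' @param irLen repeat length, default 30.
#' @param palindromic build palindromic ends.
#' @param seed integer seed.
#' @param id element id.
#' @return list with sequence, geneStart, geneEnd (element-relative, 1-based
#'   inclusive ORF coordinates), irLen, orfLen, id.
#' @export
buildIsElement <- function(model, orfLen = 1002L, irLen = 30L,
                           palindromic = FALSE, seed = 1L, id = "element") {
    orfLen <- as.integer(orfLen); irLen <- as.integer(irLen)
    if (orfLen %% 3L != 0L || orfLen < 9L)
        stop("orfLen must be a multiple of 3 and at least 9")
    if (irLen < 4L)
        stop("irLen must be at least 4")
    if (palindromic && irLen %% 2L != 0L)
        stop("palindromic ends need an even irLen")
    set.seed(as.integer(seed))
    cum <- t(apply(model@transition, 1L, cumsum))
    left <- if (palindromic) {
        h <- .sampleChain(model, irLen %/% 2L, cum)
        paste0(h, reverseComplementSeq(h))
    } else .sampleChain(model, irLen, cum)
    stops <- c("TAA", "TAG", "TGA")
    interior <- .sampleChain(model, orfLen - 6L, cum)
    codons <- substring(interior, seq(1L, orfLen - 6L, 3L),
                        seq(3L, orfLen - 6L, 3L))
    tetra <- model@initial   # trimer distribution doubles as a codon sampler
    ok <- !names(tetra) %in% stops
    for (pass in seq_len(100L)) {
        bad <- codons %in% stops
        if (!any(bad)) break
        codons[bad] <- sample(names(tetra)[ok], sum(bad), replace = TRUE,
                              prob = tetra[ok])
    }
    if (any(codons %in% stops))
        stop("could not build a stop-free ORF after bounded resampling")
    orf <- paste0("ATG", paste(codons, collapse = ""),
                  sample(stops, 1L, prob = c(.5, .25, .25)))
    right <- reverseComplementSeq(left)
    list(id = id, sequence = paste0(left, orf, right),
         geneStart = irLen + 1L, geneEnd = irLen + orfLen,
         irLen = irLen, orfLen = orfLen, palindromic = palindromic)
}

# i.i.d. substitutions at per-base rate mu; N is left untouched
.mutateSeq <- function(seq, mu) {
    if (mu == 0) return(list(seq = seq, substitutions = 0L))
    chars <- strsplit(seq, "")[[1L]]
    hit <- stats::runif(length(chars)) < mu & chars %in% .DNA_BASES
    for (i in which(hit))
        chars[i] <- sample(setdiff(.DNA_BASES, chars[i]), 1L)
    list(seq = paste(chars, collapse = ""), substitutions = sum(hit))
}

#' Implant IS elements into a genome
#'
#' Inserts \code{copies[i]} independently mutated copies of each element at
#' uniform, non-overlapping positions (no target-site duplication; insertions
#' only grow the genome, so prior copies are never disrupted). Each copy is
#' mutated by i.i.d. substitutions at rate \code{mu}; indels are deliberately
#' not modelled so that truth alignments stay trivial. The returned truth
#' table and feature set use final (post-insertion) 1-based coordinates, and
#' the mutated copy sequences are returned so coordinate consistency can be
#' asserted exactly.
#'
#' @param recipient single-sequence \code{DNAStringSet}.
#' @param elements list of elements from \code{\link{buildIsElement}}.
#' @param copies integer vector of copy counts per element (default 1 each).
#' @param mu per-base substitution rate per copy, default 0.01.
#' @param seed integer seed.
#' @param origin character vector per element: "native" or "transferred".
#' @param donorId character vector per element: id of the genome whose
#'   composition the element was built from.
#' @return list(genome, features, truth, elementSeqs).
#' @export
implantElements <- function(recipient, elements, copies = NULL, mu = 0.01,
                            seed = 1L, origin = NULL, donorId = NULL) {
    stopifnot(length(recipient) == 1L)
    nel <- length(elements)
    if (is.null(copies)) copies <- rep(1L, nel)
    if (is.null(origin)) origin <- rep("native", nel)
    if (is.null(donorId)) donorId <- rep(names(recipient), nel)
    stopifnot(length(copies) == nel, length(origin) == nel,
              length(donorId) == nel)
    host <- names(recipient)
    gseq <- as.character(recipient[[1L]])
    L <- nchar(gseq)
    total <- sum(copies)
    if (L + 1L < total)
        stop("genome too short to host all copies")
    set.seed(as.integer(seed))
    pos <- sort(sample.int(L + 1L, total))   # insertion before original base pos
    rec <- list(); k <- 0L
    for (i in seq_len(nel)) for (cp in seq_len(copies[i])) {
        k <- k + 1L
        mut <- .mutateSeq(elements[[i]]$sequence, mu)
        rec[[k]] <- list(elementId = sprintf("%s_c%d", elements[[i]]$id, cp),
                         template = i, pos = pos[k], seq = mut$seq,
                         substitutions = mut$substitutions)
    }
    pieces <- character(0); cursor <- 1L; offset <- 0L
    starts <- integer(total)
    for (k in seq_len(total)) {
        p <- rec[[k]]$pos
        pieces <- c(pieces, substr(gseq, cursor, p - 1L))
        starts[k] <- p + offset
        pieces <- c(pieces, rec[[k]]$seq)
        offset <- offset + nchar(rec[[k]]$seq)
        cursor <- p
    }
    pieces <- c(pieces, substr(gseq, cursor, L))
    out <- Biostrings::DNAStringSet(paste(pieces, collapse = ""))
    names(out) <- host
    truth <- do.call(rbind, lapply(seq_len(total), function(k) {
        i <- rec[[k]]$template
        el <- elements[[i]]
        data.frame(elementId = rec[[k]]$elementId, host = host,
                   origin = origin[i], donorId = donorId[i],
                   templateId = el$id,
                   elementStart = starts[k],
                   elementEnd = starts[k] + nchar(rec[[k]]$seq) - 1L,
                   geneStart = starts[k] + el$geneStart - 1L,
                   geneEnd = starts[k] + el$geneEnd - 1L,
                   irLen = el$irLen,
                   substitutions = rec[[k]]$substitutions,
                   stringsAsFactors = FALSE)
    }))
    features <- GenomicRanges::GRanges(
        host, IRanges::IRanges(truth$geneStart, truth$geneEnd), strand = "+")
    S4Vectors::mcols(features)$gene_id <- truth$elementId
    S4Vectors::mcols(features)$product <- "transposase"
    S4Vectors::mcols(features)$taxon <- ""
    names(features) <- truth$elementId
    elementSeqs <- stats::setNames(
        vapply(rec, function(r) r$seq, ""),
        vapply(rec, function(r) r$elementId, ""))
    list(genome = out, features = features, truth = truth,
         elementSeqs = elementSeqs)
}

#' Simulate a two-genome interphylum HGT study
#'
#' Builds the complete study design the HGT caller assumes: a recipient
#' genome (query genus \emph{Fervidobacterium}, phylum Thermotogae) carrying
#' both native IS elements (recipient composition) and horizontally
#' transferred elements (donor composition, phylum Firmicutes), a donor
#' genome, and for every element family one close and one distant comparator
#' sequence with taxon labels:
#' \itemize{
#'   \item transferred family: the out-phylum comparator (genus
#'     \emph{Caldicellulosiruptor}, Firmicutes) diverges from the template at
#'     rate \code{muCompClose}, the in-phylum comparator (genus
#'     \emph{Petrotoga}, Thermotogae) at \code{muCompFar} — recent interphylum
#'     transfer leaves the donor lineage as the closest relative;
#'   \item native family: the labels are the same but the rates are swapped —
#'     a vertically inherited element's closest relatives are in-phylum.
#' }
#' The donor model is redrawn (deterministically, by seed increments) until
#' its stationary tetranucleotide composition diverges from the recipient's
#' by at least \code{minModelDivergence} nats, the regime where
#' composition-based evidence is informative.
#'
#' @param seed master seed; every other seed is derived from it.
#' @param genomeLength recipient/donor genome length, default 1e5.
#' @param nTransferred,nNative number of element families of each origin,
#'   default 6 each.
#' @param mu per-copy substitution rate for implanted copies, default 0.01.
#' @param muCompClose,muCompFar comparator divergence rates, defaults 0.05
#'   and 0.30.
#' @param orfLen,irLen element geometry, defaults 900 and 30.
#' @param minModelDivergence minimum donor-vs-recipient stationary
#'   divergence, default 0.05 nats.
#' @return list with recipientGenome, donorGenome, features, truth,
#'   elementSeqs, comparators (data.frame id, seq, geneStart, geneEnd,
#'   genus, phylum, family), taxa, models, params.
#' @export
simulateHgtStudy <- function(seed, genomeLength = 1e5, nTransferred = 6L,
                             nNative = 6L, mu = 0.01, muCompClose = 0.05,
                             muCompFar = 0.30, orfLen = 900L, irLen = 30L,
                             minModelDivergence = 0.05) {
    seed <- as.integer(seed)
    recipModel <- sampleComposition(.deriveSeed(seed, 1L))
    donorModel <- NULL
    for (k in 0:99) {
        cand <- sampleComposition(.deriveSeed(seed, 2L + k))
        if (modelDivergence(cand, recipModel) >= minModelDivergence) {
            donorModel <- cand; break
        }
    }
    if (is.null(donorModel))
        stop("could not draw a donor model at the requested divergence")
    nT <- as.integer(nTransferred); nN <- as.integer(nNative)
    mkElements <- function(model, n, prefix, offs)
        lapply(seq_len(n), function(i)
            buildIsElement(model, orfLen = orfLen, irLen = irLen,
                           seed = .deriveSeed(seed, offs + i),
                           id = sprintf("%s%d", prefix, i)))
    natives <- mkElements(recipModel, nN, "nat", 100L)
    transferred <- mkElements(donorModel, nT, "hgt", 200L)
    elements <- c(natives, transferred)
    origin <- c(rep("native", nN), rep("transferred", nT))
    donorId <- c(rep("recipient", nN), rep("donor", nT))
    recip <- generateGenome(recipModel, genomeLength,
                            .deriveSeed(seed, 3L), id = "recipient")
    donor <- generateGenome(donorModel, genomeLength,
                            .deriveSeed(seed, 4L), id = "donor")
    imp <- implantElements(recip, elements, mu = mu,
                           seed = .deriveSeed(seed, 5L),
                           origin = origin, donorId = donorId)
    comp <- list(); k <- 0L
    for (i in seq_along(elements)) {
        el <- elements[[i]]
        rates <- if (origin[i] == "transferred")
            c(out = muCompClose, inn = muCompFar)
        else c(out = muCompFar, inn = muCompClose)
        set.seed(.deriveSeed(seed, 300L + i))
        mOut <- .mutateSeq(el$sequence, rates[["out"]])
        set.seed(.deriveSeed(seed, 400L + i))
        mIn <- .mutateSeq(el$sequence, rates[["inn"]])
        comp[[k <- k + 1L]] <- data.frame(
            id = paste0(el$id, "_out"), seq = mOut$seq,
            geneStart = el$geneStart, geneEnd = el$geneEnd,
            genus = "Caldicellulosiruptor", phylum = "Firmicutes",
            family = el$id, stringsAsFactors = FALSE)
        comp[[k <- k + 1L]] <- data.frame(
            id = paste0(el$id, "_in"), seq = mIn$seq,
            geneStart = el$geneStart, geneEnd = el$geneEnd,
            genus = "Petrotoga", phylum = "Thermotogae",
            family = el$id, stringsAsFactors = FALSE)
    }
    comparators <- do.call(rbind, comp)
    taxa <- rbind(
        data.frame(id = imp$truth$elementId, genus = "Fervidobacterium",
                   phylum = "Thermotogae", stringsAsFactors = FALSE),
        comparators[, c("id", "genus", "phylum")])
    list(seed = seed, recipientGenome = imp$genome, donorGenome = donor,
         features = imp$features, truth = imp$truth,
         elementSeqs = imp$elementSeqs, comparators = comparators,
         taxa = taxa, models = list(recipient = recipModel, donor = donorModel),
         params = list(genomeLength = genomeLength, nTransferred = nT,
                       nNative = nN, mu = mu, muCompClose = muCompClose,
                       muCompFar = muCompFar, orfLen = orfLen, irLen = irLen,
                       minModelDivergence = minModelDivergence))
}
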