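#' Count overlapping tetranucleotides
#'
#' Counts all overlapping windows of width \code{k} (step 1) on the given
#' strand, i.e. \code{nchar(seq) - k + 1} windows; windows containing N are
#' skipped. With \code{bothStrands = TRUE} the counts of the reverse
#' complement are added, which makes the profile strand-symmetric (useful for
#' whole-genome references; oriented gene sequences are counted single-strand
#' by default).
#'
#' @param seq nucleotide string (character or \code{DNAString}) over
#'   A,C,G,T,N.
#' @param bothStrands add reverse-complement counts.
#' @param k word size, default 4.
#' @return named integer vector of length \code{4^k}.
#' @export
#' @importFrom Biostrings DNAString oligonucleotideFrequency
countTetranucleotides <- function(seq, bothStrands = FALSE, k = 4L) {
    if (is(seq, "DNAString")) seq <- as.character(seq)
    seq <- toupper(seq)
    if (grepl("[^ACGTN]", seq))
        stop("illegal character in sequence (alphabet is A,C,G,T,N)")
    if (nchar(seq) < k)
        stop("sequence shorter than k = ", k)
    counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                                   width = k, step = 1L)
    if (bothStrands) {
        rc <- reverseComplementSeq(seq)
        counts <- counts + Biostrings::oligonucleotideFrequency(
            Biostrings::DNAString(rc), width = k, step = 1L)
    }
    counts
}

#' Build a composition profile from k-mer counts
#'
#' Frequencies are Laplace-smoothed: \code{(counts + alpha) / (sum(counts) +
#' 4^k * alpha)}. The default \code{alpha = 1} guarantees strictly positive
#' frequencies so that Kullback-Leibler divergence is always finite; with
#' \code{alpha = 0} the raw relative frequencies are returned.
#'
#' @param counts named integer vector from \code{countTetranucleotides}.
#' @param alpha pseudocount, default 1.
#' @param ownerId id recorded in the profile.
#' @return a \code{\linkS4class{TetraProfile}}.
#' @export
makeProfile <- function(counts, alpha = 1, ownerId = "profile") {
    nm <- names(counts)
    counts <- stats::setNames(as.integer(round(counts)), nm)
    nk <- length(counts)
    k <- as.integer(round(log(nk, 4)))
    if (4L^k != nk)
        stop("counts length must be a power of 4")
    if (sum(counts) == 0L)
        stop("all-zero counts: cannot normalize")
    if (alpha < 0)
        stop("alpha must be >= 0")
    if (is.null(nm))
        stop("counts must be named by k-mer")
    freq <- (counts + alpha) / (sum(counts) + nk * alpha)
    new("TetraProfile", ownerId = ownerId, k = k, counts = counts,
        frequencies = freq, alpha = as.numeric(alpha),
        nWindows = sum(counts))
}

#' One-call tetranucleotide profile of a sequence
#'
#' @inheritParams countTetranucleotides
#' @inheritParams makeProfile
#' @return a \code{\linkS4class{TetraProfile}}.
#' @export
tetraProfile <- function(seq, ownerId = "profile", alpha = 1,
                         bothStrands = FALSE, k = 4L) {
    makeProfile(countTetranucleotides(seq, bothStrands = bothStrands, k = k),
                alpha = alpha, ownerId = ownerId)
}

#' Kullback-Leibler divergence between two composition profiles
#'
#' Computes \eqn{D_{KL}(g \| G) = \sum_i g(i) \, \ln(g(i)/G(i))} in natural
#' log units (nats) over the k-mer frequency vectors, with the convention
#' \eqn{0 \ln 0 = 0}. The divergence is asymmetric: \code{g} is the query
#' (e.g. a transposase gene) and \code{G} the reference (another gene or a
#' whole genome).
#'
#' @param g query \code{TetraProfile}.
#' @param G reference \code{TetraProfile}.
#' @return divergence in nats (non-negative; 0 iff the frequency vectors are
#'   identical).
#' @export
klDivergence <- function(g, G) {
    stopifnot(is(g, "TetraProfile"), is(G, "TetraProfile"))
    if (g@k != G@k)
        stop("profiles use different word sizes")
    p <- g@frequencies
    q <- G@frequencies[names(p)]
    if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
        stop("profiles must be normalized")
    pos <- p > 0
    if (any(pos & q == 0))
        stop("infinite divergence: reference has zero frequency where the ",
             "query does not; rebuild the profiles with a pseudocount ",
             "(alpha > 0)")
    sum(p[pos] * log(p[pos] / q[pos]))
}

#' Rank queries by divergence from a reference
#'
#' Computes gene-vs-gene divergences of every query against \code{reference}
#' and, when whole-genome profiles are supplied, gene-vs-genome divergences of
#' every query against each of them (the horizontal "line" of a ranking
#' plot). Results are sorted ascending by divergence with a stable id
#' tiebreak, ready for a rank-vs-divergence plot.
#'
#' @param queries list of \code{TetraProfile}.
#' @param reference reference \code{TetraProfile} (typically one of the
#'   queries).
#' @param genomeRefs optional list of whole-genome \code{TetraProfile}s.
#' @return data.frame with columns rank, queryId, referenceId, kind, dKl.
#' @export
divergenceRanking <- function(queries, reference, genomeRefs = list()) {
    if (length(queries) == 0L)
        stop("empty query list")
    res <- data.frame(
        queryId = vapply(queries, ownerId, ""),
        referenceId = ownerId(reference),
        kind = "gene_vs_gene",
        dKl = vapply(queries, klDivergence, 0, G = reference),
        stringsAsFactors = FALSE)
    for (gref in genomeRefs) {
        res <- rbind(res, data.frame(
            queryId = vapply(queries, ownerId, ""),
            referenceId = ownerId(gref),
            kind = "gene_vs_genome",
            dKl = vapply(queries, klDivergence, 0, G = gref),
            stringsAsFactors = FALSE))
    }
    res <- res[order(res$dKl, res$queryId, res$referenceId), , drop = FALSE]
    res$rank <- seq_len(nrow(res))
    rownames(res) <- NULL
    res[, c("rank", "queryId", "referenceId", "kind", "dKl")]
}

#' Write a profile to TSV (256 rows: kmer, count, frequency)
#'
#' @param profile a \code{TetraProfile}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTetraProfile <- function(profile, path) {
    tab <- data.frame(kmer = names(profile@counts),
                      count = profile@counts,
                      frequency = profile@frequencies)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a profile TSV written by \code{writeTetraProfile}
#'
#' @param path profile TSV.
#' @param ownerId id for the rebuilt profile.
#' @param alpha pseudocount to re-apply (frequencies are recomputed from the
#'   stored counts so the alpha convention stays explicit).
#' @return a \code{TetraProfile}.
#' @export
readTetraProfile <- function(path, ownerId = basename(path), alpha = 1) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    counts <- stats::setNames(as.integer(tab$count), tab$kmer)
    makeProfile(counts, alpha = alpha, ownerId = ownerId)
}
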