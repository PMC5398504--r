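#' Pairwise percent similarity between protein sequences
#'
#' Global alignment of every pair (BLOSUM62, gap open -10, gap extend -1);
#' similarity is 100 * identical columns / scored columns, truncated to one
#' decimal. "Similarity" is implemented as percent identity: alignment tools
#' differ on whether conservative substitutions count, so the definition is
#' recorded in the result and figure-style similarity columns should only be
#' compared qualitatively.
#'
#' @param seqs named character vector of amino-acid sequences (standard
#'   20-letter alphabet plus X and *).
#' @return a \code{\linkS4class{SimilarityMatrix}}.
#' @export
#' @importFrom Biostrings AAString AAStringSet nmatch
pairwiseProteinSimilarity <- function(seqs) {
    if (length(seqs) < 2L)
        stop("need at least 2 sequences")
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
        stop("sequences must carry unique names")
    seqs <- toupper(seqs)
    if (any(!nzchar(seqs)))
        stop("empty sequence: ", paste(names(seqs)[!nzchar(seqs)], collapse = ", "))
    if (any(grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", seqs)))
        stop("illegal amino-acid character (20-letter alphabet plus X and *)")
    data("BLOSUM62", package = "Biostrings", envir = environment())
    sub <- get("BLOSUM62", envir = environment())
    n <- length(seqs)
    s <- matrix(100, n, n)
    # one vectorised alignment call per subject; a global alignment has no
    # both-gap columns, so scored columns = alignment width
    for (j in 2:n) {
        aln <- Biostrings::pairwiseAlignment(
            Biostrings::AAStringSet(seqs[seq_len(j - 1L)]),
            Biostrings::AAString(seqs[j]), type = "global",
            substitutionMatrix = sub, gapOpening = 10, gapExtension = 1)
        ident <- 100 * Biostrings::nmatch(aln) / nchar(aln)
        s[seq_len(j - 1L), j] <- s[j, seq_len(j - 1L)] <- .trunc1(ident)
    }
    new("SimilarityMatrix", ids = names(seqs), s = s, definition = "identity")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining via \code{\link[ape]{nj}}; the tree is
#' unrooted and exact on additive distances. Negative branch lengths (an NJ
#' artifact on noisy distances) are clamped to zero and flagged in the
#' \code{"clamped"} attribute.
#'
#' @param dm a \code{dist} or symmetric numeric matrix with at least 3 taxa.
#' @return an \code{\link[ape]{ape}} \code{phylo} tree.
#' @export
#' @importFrom ape nj
#' @importFrom stats as.dist
njTree <- function(dm) {
    m <- as.matrix(dm)
    if (nrow(m) < 3L)
        stop("need at least 3 taxa")
    if (any(!is.finite(m)))
        stop("non-finite distances")
    tree <- ape::nj(stats::as.dist(m))
    clamped <- any(tree$edge.length < 0)
    tree$edge.length[tree$edge.length < 0] <- 0
    attr(tree, "clamped") <- clamped
    tree
}

#' p-distance matrix from an alignment
#'
#' For each pair, the fraction of mismatching columns among columns where
#' both rows are ungapped (pairwise deletion). This is the default distance
#' fed to neighbor joining; substitution-model distances are deliberately not
#' layered on top so the tree input stays transparent.
#'
#' @param alignment named character vector of equal-length aligned rows.
#' @return a \code{dist}.
#' @export
pDistanceMatrix <- function(alignment) {
    if (length(alignment) < 2L)
        stop("need at least 2 rows")
    if (length(unique(nchar(alignment))) != 1L)
        stop("rows must have equal length")
    chars <- do.call(rbind, strsplit(toupper(alignment), ""))
    n <- nrow(chars)
    d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        ok <- chars[i, ] != "-" & chars[j, ] != "-"
        if (!any(ok))
            stop("rows ", names(alignment)[i], " and ", names(alignment)[j],
                 " share no ungapped columns")
        d[i, j] <- d[j, i] <- mean(chars[i, ok] != chars[j, ok])
    }
    stats::as.dist(d)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement \code{nReps} times, rebuilds
#' the p-distance NJ tree per replicate, and reports for every internal edge
#' of the full-data tree the fraction of replicate trees containing its
#' bipartition. Deterministic given \code{seed}. Columns gapped in every row
#' are dropped with a warning; an alignment of identical rows has no
#' phylogenetic signal and is flagged degenerate (supports NA).
#'
#' @param alignment named character vector of equal-length amino-acid rows
#'   (at least 4).
#' @param nReps bootstrap replicates, default 1000.
#' @param seed integer seed.
#' @return the full-data NJ \code{phylo} with supports in \code{node.label}
#'   (root NA) and attributes \code{"nReps"} and \code{"degenerate"}.
#' @export
#' @importFrom ape prop.clades
bootstrapSupport <- function(alignment, nReps = 1000L, seed = 1L) {
    if (length(alignment) < 4L)
        stop("need at least 4 rows for bootstrap supports")
    if (length(unique(nchar(alignment))) != 1L)
        stop("rows must have equal length")
    chars <- do.call(rbind, strsplit(toupper(alignment), ""))
    rownames(chars) <- names(alignment)
    allGap <- colSums(chars != "-") == 0L
    if (any(allGap)) {
        warning(sum(allGap), " all-gap column(s) dropped")
        chars <- chars[, !allGap, drop = FALSE]
    }
    rows <- apply(chars, 1L, paste, collapse = "")
    dm <- pDistanceMatrix(rows)
    degenerate <- all(as.vector(dm) == 0)
    tree <- njTree(dm)
    if (degenerate) {
        warning("identical rows: distances are all zero, supports undefined")
        tree$node.label <- rep(NA_real_, tree$Nnode)
        attr(tree, "degenerate") <- TRUE
        attr(tree, "nReps") <- as.integer(nReps)
        return(tree)
    }
    set.seed(as.integer(seed))
    reps <- vector("list", nReps)
    for (r in seq_len(nReps)) {
        cols <- sample.int(ncol(chars), replace = TRUE)
        rrows <- apply(chars[, cols, drop = FALSE], 1L, paste, collapse = "")
        reps[[r]] <- njTree(pDistanceMatrix(rrows))
    }
    counts <- ape::prop.clades(tree, reps, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    supports <- counts / nReps
    supports[1L] <- NA_real_   # root of an unrooted tree carries no support
    tree$node.label <- supports
    attr(tree, "degenerate") <- FALSE
    attr(tree, "nReps") <- as.integer(nReps)
    tree
}

#' Support of the bipartition separating a given taxon set
#'
#' Convenience accessor: the bootstrap support of the internal edge whose
#' bipartition splits \code{taxa} from the rest, or NA when the full-data
#' tree does not contain that bipartition.
#'
#' @param tree a \code{phylo} from \code{bootstrapSupport}.
#' @param taxa character vector of tip labels on one side of the split.
#' @return support fraction in [0, 1], or NA.
#' @export
#' @importFrom ape prop.part
bipartitionSupport <- function(tree, taxa) {
    parts <- ape::prop.part(tree)
    labs <- attr(parts, "labels")
    want <- sort(match(taxa, labs))
    if (any(is.na(want)))
        stop("unknown tip label(s)")
    all <- seq_along(labs)
    for (i in seq_along(parts)) {
        p <- sort(parts[[i]])
        if (identical(p, want) || identical(p, sort(setdiff(all, want))))
            return(tree$node.label[i])
    }
    NA_real_
}
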