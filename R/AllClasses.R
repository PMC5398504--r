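#' @import methods
#' @importFrom S4Vectors isSingleString isSingleNumber
#' @importMethodsFrom Biostrings nchar
NULL

.DNA_BASES <- c("A", "C", "G", "T")

#' TetraProfile: a k-mer composition profile
#'
#' Holds overlapping k-mer (default tetranucleotide) counts for one sequence
#' together with pseudocounted frequencies. The 256-dimensional tetranucleotide
#' frequency vector is the genomic signature on which divergence estimation and
#' ordination operate.
#'
#' @slot ownerId id of the sequence the profile was computed from.
#' @slot k word size (4 for tetranucleotides; only k = 4 is validated against
#'   published identities, other k are supported for exploration).
#' @slot counts named integer vector of length 4^k, raw window counts.
#' @slot frequencies named numeric vector, \code{(counts + alpha) /
#'   (sum(counts) + 4^k * alpha)}; sums to 1.
#' @slot alpha pseudocount used for the frequencies.
#' @slot nWindows total number of counted windows (windows containing N are
#'   skipped and do not contribute).
#' @export
setClass("TetraProfile",
    representation(ownerId = "character", k = "integer",
                   counts = "integer", frequencies = "numeric",
                   alpha = "numeric", nWindows = "integer"))

setValidity("TetraProfile", function(object) {
    nk <- 4L^object@k
    msg <- character()
    if (length(object@counts) != nk || length(object@frequencies) != nk)
        msg <- c(msg, sprintf("counts and frequencies must have length 4^k = %d", nk))
    if (!identical(names(object@counts), names(object@frequencies)))
        msg <- c(msg, "counts and frequencies must share k-mer names")
    if (any(object@counts < 0L))
        msg <- c(msg, "counts must be non-negative")
    if (abs(sum(object@frequencies) - 1) > 1e-12)
        msg <- c(msg, "frequencies must sum to 1 (tolerance 1e-12)")
    if (object@alpha > 0 && any(object@frequencies <= 0))
        msg <- c(msg, "all frequencies must be positive when alpha > 0")
    if (object@nWindows != sum(object@counts))
        msg <- c(msg, "nWindows must equal sum(counts)")
    if (length(msg)) msg else TRUE
})

setMethod("show", "TetraProfile", function(object) {
    cat(sprintf("TetraProfile '%s': k=%d, %d windows, alpha=%g\n",
                object@ownerId, object@k, object@nWindows, object@alpha))
    nz <- sum(object@counts > 0L)
    cat(sprintf("  %d/%d k-mers observed\n", nz, length(object@counts)))
})

#' @export
setGeneric("ownerId", function(x) standardGeneric("ownerId"))
#' @export
setGeneric("tetraCounts", function(x) standardGeneric("tetraCounts"))
#' @export
setGeneric("tetraFrequencies", function(x) standardGeneric("tetraFrequencies"))

#' @describeIn TetraProfile id of the profiled sequence
#' @param x a \code{TetraProfile}
#' @export
setMethod("ownerId", "TetraProfile", function(x) x@ownerId)
#' @describeIn TetraProfile raw window counts
#' @export
setMethod("tetraCounts", "TetraProfile", function(x) x@counts)
#' @describeIn TetraProfile pseudocounted frequency vector
#' @export
setMethod("tetraFrequencies", "TetraProfile", function(x) x@frequencies)

#' FlankedGene: a gene with its flanking windows
#'
#' A gene sequence in gene orientation together with its 5' (upstream) and 3'
#' (downstream) flanks, each at most \code{window} bases and truncated at
#' contig edges. For minus-strand genes all three pieces are
#' reverse-complemented so that "upstream" is always 5' of the coding strand,
#' matching the gene-anchored layout of published IS end tables.
#'
#' @slot geneId gene identifier.
#' @slot contigId contig the gene lies on.
#' @slot start,end 1-based inclusive genomic coordinates.
#' @slot strand "+" or "-".
#' @slot geneSeq,upstream,downstream nucleotide strings in gene orientation.
#' @slot window requested flank window (bp).
#' @export
setClass("FlankedGene",
    representation(geneId = "character", contigId = "character",
                   start = "integer", end = "integer", strand = "character",
                   geneSeq = "character", upstream = "character",
                   downstream = "character", window = "integer"))

setValidity("FlankedGene", function(object) {
    msg <- character()
    if (nchar(object@geneSeq) != object@end - object@start + 1L)
        msg <- c(msg, "geneSeq length must equal end - start + 1")
    if (nchar(object@upstream) > object@window ||
        nchar(object@downstream) > object@window)
        msg <- c(msg, "flank lengths must not exceed the window")
    if (!object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    if (length(msg)) msg else TRUE
})

setMethod("show", "FlankedGene", function(object) {
    cat(sprintf("FlankedGene '%s' (%s:%d-%d%s): gene %d bp, flanks %d/%d bp\n",
                object@geneId, object@contigId, object@start, object@end,
                object@strand, nchar(object@geneSeq),
                nchar(object@upstream), nchar(object@downstream)))
})

#' DottedAlignment: dot-notation end alignment
#'
#' Parsed representation of the dot-notation alignment blocks used to publish
#' IS end (inverted repeat) alignments: the reference row is explicit, and in
#' every other row '.' means "same base as the reference at this column", a
#' letter is a substitution, and '-' (or the typographic en-dash) a gap.
#'
#' @slot referenceId id of the reference row.
#' @slot referenceRow explicit reference row over A,C,G,T,-.
#' @slot ids row ids (excluding the reference).
#' @slot dottedRows rows as given, gap glyphs normalized to '-'.
#' @slot expandedRows rows with dots expanded to explicit bases.
#' @slot distance printed distance (bp) from the repeat to the gene start/stop
#'   codon, NA when not determined.
#' @slot printedIdentity printed identity percentage, NA when absent.
#' @slot organism source organism per row (may be empty).
#' @export
setClass("DottedAlignment",
    representation(referenceId = "character", referenceRow = "character",
                   ids = "character", dottedRows = "character",
                   expandedRows = "character", distance = "numeric",
                   printedIdentity = "numeric", organism = "character"))

setValidity("DottedAlignment", function(object) {
    n <- length(object@ids)
    msg <- character()
    if (length(object@dottedRows) != n || length(object@expandedRows) != n ||
        length(object@distance) != n + 1L || length(object@printedIdentity) != n)
        msg <- c(msg, "row annotation lengths inconsistent (distance includes the reference)")
    if (n && any(nchar(object@expandedRows) != nchar(object@referenceRow)))
        msg <- c(msg, "all rows must have the reference row length")
    if (length(msg)) msg else TRUE
})

setMethod("show", "DottedAlignment", function(object) {
    cat(sprintf("DottedAlignment: reference '%s' (%d columns), %d rows\n",
                object@referenceId, nchar(object@referenceRow),
                length(object@ids)))
})

#' EndAlignment: aligned IS ends with identity
#'
#' Two equal-length aligned rows over A,C,G,T,- and the identity computed as
#' 100 * matches / scored columns, where scored columns exclude columns gapped
#' in both rows and gap-vs-base columns count as mismatches. The displayed
#' percentage is truncated (not rounded) to one decimal, the convention the
#' published identity columns follow; the full-precision value is kept too.
#'
#' @slot referenceId,rowId row identifiers.
#' @slot alignedRef,alignedRow aligned sequences.
#' @slot matches columns with identical non-gap symbols.
#' @slot scoredColumns columns minus both-gap columns.
#' @slot identityPct identity truncated to one decimal.
#' @slot identityRaw identity at full precision.
#' @export
setClass("EndAlignment",
    representation(referenceId = "character", rowId = "character",
                   alignedRef = "character", alignedRow = "character",
                   matches = "integer", scoredColumns = "integer",
                   identityPct = "numeric", identityRaw = "numeric"))

setValidity("EndAlignment", function(object) {
    msg <- character()
    if (nchar(object@alignedRef) != nchar(object@alignedRow))
        msg <- c(msg, "aligned rows must have equal length")
    if (object@identityPct < 0 || object@identityPct > 100)
        msg <- c(msg, "identityPct must lie in [0, 100]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "EndAlignment", function(object) {
    cat(sprintf("EndAlignment %s vs %s: %d/%d matches, identity %.1f%%\n",
                object@referenceId, object@rowId, object@matches,
                object@scoredColumns, object@identityPct))
})

#' @export
setGeneric("identityPct", function(x) standardGeneric("identityPct"))
#' @describeIn EndAlignment identity truncated to one decimal
#' @param x an \code{EndAlignment}
#' @export
setMethod("identityPct", "EndAlignment", function(x) x@identityPct)

#' RepeatEnds: an inverted-repeat pair flanking a transposase gene
#'
#' Result of the automated IR scan: the best local alignment between the
#' upstream search span and the reverse complement of the downstream span.
#' Distances follow the published sign convention: bp from the repeat to the
#' gene start (left) or stop (right) codon, negative when the repeat extends
#' into the coding region.
#'
#' @slot geneId gene the ends flank.
#' @slot leftSeq,rightSeq repeat sequences in gene orientation.
#' @slot leftDistance,rightDistance signed bp to the start/stop codon.
#' @slot score local alignment score (match +1, mismatch -1, gap -2).
#' @slot mismatches mismatching columns (including gap columns).
#' @slot alignedLength columns in the local alignment.
#' @slot palindromic TRUE when the left repeat is its own reverse complement.
#' @export
setClass("RepeatEnds",
    representation(geneId = "character", leftSeq = "character",
                   rightSeq = "character", leftDistance = "integer",
                   rightDistance = "integer", score = "numeric",
                   mismatches = "integer", alignedLength = "integer",
                   palindromic = "logical"))

setMethod("show", "RepeatEnds", function(object) {
    cat(sprintf(
        "RepeatEnds '%s': %d bp aligned, %d mismatches, score %g%s\n",
        object@geneId, object@alignedLength, object@mismatches, object@score,
        if (object@palindromic) " (palindromic)" else ""))
    cat(sprintf("  left  %s (distance %d)\n", object@leftSeq, object@leftDistance))
    cat(sprintf("  right %s (distance %d)\n", object@rightSeq, object@rightDistance))
})

#' NmdsEmbedding: a two-dimensional NMDS configuration
#'
#' @slot ids item ids, in input order.
#' @slot coordinates n x dims matrix, column means zero.
#' @slot stress Kruskal stress-1 of the best restart.
#' @slot nRestarts number of restarts run (restart 0 is the metric-MDS start).
#' @slot seed seed controlling the random restarts.
#' @slot converged whether the best restart converged before maxIter.
#' @export
setClass("NmdsEmbedding",
    representation(ids = "character", coordinates = "matrix",
                   stress = "numeric", nRestarts = "integer",
                   seed = "integer", converged = "logical"))

setValidity("NmdsEmbedding", function(object) {
    msg <- character()
    if (nrow(object@coordinates) != length(object@ids))
        msg <- c(msg, "one coordinate row per id required")
    if (object@stress < 0) msg <- c(msg, "stress must be non-negative")
    if (any(abs(colMeans(object@coordinates)) > 1e-8))
        msg <- c(msg, "coordinates must be centred")
    if (length(msg)) msg else TRUE
})

setMethod("show", "NmdsEmbedding", function(object) {
    cat(sprintf("NmdsEmbedding: %d items in %d dims, stress %.3g (%d restarts, seed %d)\n",
                length(object@ids), ncol(object@coordinates), object@stress,
                object@nRestarts, object@seed))
})

#' @export
setGeneric("nmdsStress", function(x) standardGeneric("nmdsStress"))
#' @describeIn NmdsEmbedding Kruskal stress-1 of the returned configuration
#' @param x an \code{NmdsEmbedding}
#' @export
setMethod("nmdsStress", "NmdsEmbedding", function(x) x@stress)
#' @export
setGeneric("nmdsCoordinates", function(x) standardGeneric("nmdsCoordinates"))
#' @describeIn NmdsEmbedding the centred configuration matrix
#' @export
setMethod("nmdsCoordinates", "NmdsEmbedding", function(x) {
    m <- x@coordinates
    rownames(m) <- x@ids
    m
})

#' SimilarityMatrix: pairwise percent identity between protein sequences
#'
#' @slot ids sequence ids.
#' @slot s symmetric percent matrix, diagonal 100.
#' @slot definition how "similarity" is computed; this package uses percent
#'   identity over scored columns of a global alignment.
#' @export
setClass("SimilarityMatrix",
    representation(ids = "character", s = "matrix", definition = "character"))

setValidity("SimilarityMatrix", function(object) {
    msg <- character()
    if (!identical(dim(object@s), c(length(object@ids), length(object@ids))))
        msg <- c(msg, "s must be square with one row per id")
    else {
        if (any(abs(diag(object@s) - 100) > 1e-9))
            msg <- c(msg, "diagonal must be 100")
        if (any(abs(object@s - t(object@s)) > 1e-9))
            msg <- c(msg, "s must be symmetric")
        if (any(object@s < 0 | object@s > 100))
            msg <- c(msg, "entries must lie in [0, 100]")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "SimilarityMatrix", function(object) {
    cat(sprintf("SimilarityMatrix (%s): %d sequences\n",
                object@definition, length(object@ids)))
})

#' @export
setGeneric("simValues", function(x) standardGeneric("simValues"))
#' @describeIn SimilarityMatrix the percent matrix with ids as dimnames
#' @param x a \code{SimilarityMatrix}
#' @export
setMethod("simValues", "SimilarityMatrix", function(x) {
    m <- x@s
    dimnames(m) <- list(x@ids, x@ids)
    m
})

#' TransposaseGroup: a similarity cluster of transposase genes
#'
#' @slot groupId group identifier ("G1", "G2", ... ordered by size then by
#'   representative).
#' @slot members member gene ids.
#' @slot representative the member with the highest mean within-group
#'   similarity (ties broken lexicographically).
#' @slot family free-text family label (e.g. "IS605_I"), may be empty.
#' @export
setClass("TransposaseGroup",
    representation(groupId = "character", members = "character",
                   representative = "character", family = "character"))

setValidity("TransposaseGroup", function(object) {
    if (!object@representative %in% object@members)
        "representative must be a member" else TRUE
})

setMethod("show", "TransposaseGroup", function(object) {
    cat(sprintf("TransposaseGroup %s%s: %d members, representative %s\n",
                object@groupId,
                if (nzchar(object@family)) paste0(" [", object@family, "]") else "",
                length(object@members), object@representative))
})

#' @export
setGeneric("groupMembers", function(x) standardGeneric("groupMembers"))
#' @describeIn TransposaseGroup member gene ids
#' @param x a \code{TransposaseGroup}
#' @export
setMethod("groupMembers", "TransposaseGroup", function(x) x@members)

#' HgtCall: per-group interphylum HGT verdict
#'
#' The verdict integrates three evidence lines against the best interphylum
#' (out) and best intraphylum-but-other-genus (in) comparators of the group
#' representative: E1 a protein-similarity margin, E2 lower tetranucleotide
#' K-L divergence to the out-phylum partner, E3 at least as high inverted
#' repeat identity to the out-phylum partner on both ends. verdict == "y" iff
#' E1 and (E2 or E3); an undetermined E3 (no repeats) does not veto.
#'
#' @slot groupId group the call is for.
#' @slot verdict "y" or "n".
#' @slot sOut,sIn best out-/in-phylum percent similarity of the representative.
#' @slot klOut,klIn minimum divergence (nats) to out-/in-phylum genes.
#' @slot irOutLeft,irOutRight,irInLeft,irInRight repeat identities (percent,
#'   NA when repeats are missing).
#' @slot e1,e2,e3 the evidence flags (e2/e3 may be NA).
#' @slot margin similarity margin (percentage points) used for E1.
#' @slot reason diagnostic note (e.g. "no interphylum context").
#' @export
setClass("HgtCall",
    representation(groupId = "character", verdict = "character",
                   sOut = "numeric", sIn = "numeric",
                   klOut = "numeric", klIn = "numeric",
                   irOutLeft = "numeric", irOutRight = "numeric",
                   irInLeft = "numeric", irInRight = "numeric",
                   e1 = "logical", e2 = "logical", e3 = "logical",
                   margin = "numeric", reason = "character"))

setValidity("HgtCall", function(object) {
    msg <- character()
    if (!object@verdict %in% c("y", "n"))
        msg <- c(msg, "verdict must be 'y' or 'n'")
    want <- isTRUE(object@e1) && (isTRUE(object@e2) || isTRUE(object@e3))
    if ((object@verdict == "y") != want)
        msg <- c(msg, "verdict must equal E1 AND (E2 OR E3)")
    if (length(msg)) msg else TRUE
})

setMethod("show", "HgtCall", function(object) {
    cat(sprintf("HgtCall %s: %s (E1=%s E2=%s E3=%s; S_out=%.1f S_in=%.1f, margin %g)\n",
                object@groupId, object@verdict, object@e1, object@e2, object@e3,
                object@sOut, object@sIn, object@margin))
    if (nzchar(object@reason)) cat("  ", object@reason, "\n", sep = "")
})

#' @export
setGeneric("hgtVerdict", function(x) standardGeneric("hgtVerdict"))
#' @describeIn HgtCall the "y"/"n" verdict
#' @param x an \code{HgtCall}
#' @export
setMethod("hgtVerdict", "HgtCall", function(x) x@verdict)

#' CompositionModel: order-3 Markov model of genome composition
#'
#' An order-3 Markov chain over A,C,G,T: 64 trimer contexts, each with a
#' next-base distribution. Order 3 is the natural generator here because it
#' controls tetranucleotide statistics directly, i.e. the feature space of the
#' composition analysis. The initial trimer distribution is the stationary
#' distribution of the induced trimer chain.
#'
#' @slot transition 64 x 4 matrix, rows sum to 1, all entries positive.
#' @slot initial stationary trimer distribution (length 64).
#' @slot concentration Dirichlet concentration the rows were drawn with.
#' @slot seed seed the model was drawn with.
#' @export
setClass("CompositionModel",
    representation(transition = "matrix", initial = "numeric",
                   concentration = "numeric", seed = "integer"))

setValidity("CompositionModel", function(object) {
    msg <- character()
    if (!identical(dim(object@transition), c(64L, 4L)))
        msg <- c(msg, "transition must be 64 x 4")
    else {
        if (any(abs(rowSums(object@transition) - 1) > 1e-12))
            msg <- c(msg, "transition rows must sum to 1 (tolerance 1e-12)")
        if (any(object@transition <= 0))
            msg <- c(msg, "all transition entries must be positive")
    }
    if (length(object@initial) != 64L || abs(sum(object@initial) - 1) > 1e-9)
        msg <- c(msg, "initial must be a length-64 distribution")
    if (length(msg)) msg else TRUE
})

setMethod("show", "CompositionModel", function(object) {
    cat(sprintf("CompositionModel: order-3 Markov chain (seed %d, concentration %g)\n",
                object@seed, object@concentration))
})

#' RunConfig: parameters of a pipeline run
#'
#' @slot genome,features,taxa input file paths ("" when the stage does not
#'   need them, e.g. after \code{simulate}).
#' @slot window flank window (bp) for gene extraction and the IR scan.
#' @slot alpha pseudocount for composition profiles.
#' @slot nmdsMetric "euclidean" or "bray-curtis".
#' @slot nmdsRestarts NMDS random restarts.
#' @slot irMinLen,irMaxMismatchFrac IR scan acceptance parameters.
#' @slot clusterThreshold percent similarity for single-linkage grouping.
#' @slot hgtMargin E1 similarity margin (percentage points).
#' @slot queryGenus,queryPhylum the taxon whose elements are grouped and
#'   called.
#' @slot outDir artifact directory.
#' @slot seed master seed; per-stage seeds are derived by fixed offsets.
#' @export
setClass("RunConfig",
    representation(genome = "character", features = "character",
                   taxa = "character", window = "integer", alpha = "numeric",
                   nmdsMetric = "character", nmdsRestarts = "integer",
                   irMinLen = "integer", irMaxMismatchFrac = "numeric",
                   clusterThreshold = "numeric", hgtMargin = "numeric",
                   queryGenus = "character", queryPhylum = "character",
                   outDir = "character", seed = "integer"))

setValidity("RunConfig", function(object) {
    msg <- character()
    if (object@window < 1L) msg <- c(msg, "window must be >= 1")
    if (object@alpha < 0) msg <- c(msg, "alpha must be >= 0")
    if (!object@nmdsMetric %in% c("euclidean", "bray-curtis"))
        msg <- c(msg, "nmdsMetric must be 'euclidean' or 'bray-curtis'")
    if (object@nmdsRestarts < 1L) msg <- c(msg, "nmdsRestarts must be >= 1")
    if (object@irMinLen < 4L) msg <- c(msg, "irMinLen must be >= 4")
    if (object@irMaxMismatchFrac < 0 || object@irMaxMismatchFrac > 1)
        msg <- c(msg, "irMaxMismatchFrac must lie in [0, 1]")
    if (object@clusterThreshold < 0 || object@clusterThreshold > 100)
        msg <- c(msg, "clusterThreshold must lie in [0, 100]")
    if (object@hgtMargin < 0) msg <- c(msg, "hgtMargin must be >= 0")
    if (!nzchar(object@queryGenus) || !nzchar(object@queryPhylum))
        msg <- c(msg, "queryGenus and queryPhylum must be non-empty")
    if (length(msg)) msg else TRUE
})

setMethod("show", "RunConfig", function(object) {
    cat("RunConfig:\n")
    cat(sprintf("  inputs: genome='%s' features='%s' taxa='%s'\n",
                object@genome, object@features, object@taxa))
    cat(sprintf("  window=%d alpha=%g nmds=%s/%d ir=%d/%.2f cluster=%g margin=%g\n",
                object@window, object@alpha, object@nmdsMetric,
                object@nmdsRestarts, object@irMinLen, object@irMaxMismatchFrac,
                object@clusterThreshold, object@hgtMargin))
    cat(sprintf("  query: %s (%s)\n", object@queryGenus, object@queryPhylum))
    cat(sprintf("  outDir='%s' seed=%d\n", object@outDir, object@seed))
})
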