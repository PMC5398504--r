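# Identity convention (validated against the published end tables): the
# denominator excludes columns gapped in BOTH rows, gap-vs-base columns count
# as mismatches, and the printed value truncates (never rounds) to 1 decimal:
# 43/45 = 95.55... prints as 95.5.
.trunc1 <- function(x) floor(round(x * 10, 6)) / 10

#' Identity between two aligned IS ends
#'
#' Matches are columns where both rows carry the same non-gap symbol; scored
#' columns are all columns except those gapped in both rows; identity is
#' 100 * matches / scored, truncated to one decimal for display (the
#' full-precision value is kept in the result).
#'
#' @param alignedRef,alignedRow equal-length strings over A,C,G,T,N,-.
#' @param referenceId,rowId ids recorded in the result.
#' @return an \code{\linkS4class{EndAlignment}}.
#' @export
identityFromAlignment <- function(alignedRef, alignedRow,
                                  referenceId = "ref", rowId = "row") {
    alignedRef <- .normGaps(alignedRef)
    alignedRow <- .normGaps(alignedRow)
    if (nchar(alignedRef) != nchar(alignedRow))
        stop("aligned rows differ in length (", nchar(alignedRef), " vs ",
             nchar(alignedRow), ")")
    if (nchar(alignedRef) == 0L)
        stop("empty alignment")
    a <- strsplit(alignedRef, "")[[1L]]
    b <- strsplit(alignedRow, "")[[1L]]
    if (any(!c(a, b) %in% c("A", "C", "G", "T", "N", "-")))
        stop("illegal symbol in aligned rows")
    bothGap <- a == "-" & b == "-"
    scored <- sum(!bothGap)
    if (scored == 0L)
        stop("no scored columns (all columns gapped in both rows)")
    matches <- sum(a == b & a != "-" & !bothGap)
    raw <- 100 * matches / scored
    new("EndAlignment", referenceId = referenceId, rowId = rowId,
        alignedRef = alignedRef, alignedRow = alignedRow,
        matches = as.integer(matches), scoredColumns = as.integer(scored),
        identityPct = .trunc1(raw), identityRaw = raw)
}

#' Globally align two IS ends and compute identity
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap open -2, gap
#' extend -1), then identity via \code{identityFromAlignment}. To make the
#' result invariant under argument order in the presence of score ties, the
#' pair is aligned in canonical (lexicographic) order and swapped back.
#'
#' @param refEnd,otherEnd nucleotide strings.
#' @param referenceId,rowId ids recorded in the result.
#' @return an \code{\linkS4class{EndAlignment}} (reference row first).
#' @export
#' @importFrom Biostrings pairwiseAlignment nucleotideSubstitutionMatrix
#'   alignedPattern alignedSubject
alignEnds <- function(refEnd, otherEnd, referenceId = "ref", rowId = "row") {
    refEnd <- toupper(refEnd); otherEnd <- toupper(otherEnd)
    if (!nzchar(refEnd) || !nzchar(otherEnd))
        stop("empty input sequence")
    swap <- otherEnd < refEnd
    p <- if (swap) otherEnd else refEnd
    s <- if (swap) refEnd else otherEnd
    sub <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                    baseOnly = FALSE)
    aln <- Biostrings::pairwiseAlignment(p, s, type = "global",
                                         substitutionMatrix = sub,
                                         gapOpening = 2, gapExtension = 1)
    ap <- as.character(Biostrings::alignedPattern(aln))
    as_ <- as.character(Biostrings::alignedSubject(aln))
    if (swap) { tmp <- ap; ap <- as_; as_ <- tmp }
    identityFromAlignment(ap, as_, referenceId = referenceId, rowId = rowId)
}

# vectorised end identity: one global DNA alignment call for many partners,
# same scoring as alignEnds; used on the hot path of the HGT caller where the
# per-call canonicalization of alignEnds is unnecessary
.batchEndIdentity <- function(refEnd, otherEnds) {
    if (!length(otherEnds)) return(numeric(0))
    sub <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                    baseOnly = FALSE)
    aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(otherEnds), Biostrings::DNAString(refEnd),
        type = "global", substitutionMatrix = sub,
        gapOpening = 2, gapExtension = 1)
    .trunc1(100 * Biostrings::nmatch(aln) / nchar(aln))
}

#' Scan the flanks of a transposase gene for inverted-repeat ends
#'
#' Finds the best local alignment (match +1, mismatch -1, gap -2) between the
#' upstream search span and the reverse complement of the downstream search
#' span, where each span is the full flank plus \code{searchIn} bases into
#' the gene (repeats often overlap the coding region, giving the negative
#' distances seen in published tables). A hit is reported when the aligned
#' length reaches \code{minLen} and the mismatch fraction (mismatching plus
#' gapped columns over aligned columns) stays at or below
#' \code{maxMismatchFrac}. The published analyses located these ends by eye;
#' this scan is the reproducible, parameterised replacement.
#'
#' @param flanked a \code{\linkS4class{FlankedGene}}.
#' @param minLen minimum aligned length, default 20.
#' @param maxMismatchFrac maximum mismatch fraction, default 0.25.
#' @param searchIn bases of the gene included in each search span, default
#'   100.
#' @return a \code{\linkS4class{RepeatEnds}}, or NULL (with a message) when
#'   no acceptable repeat pair exists.
#' @export
findInvertedRepeats <- function(flanked, minLen = 20L, maxMismatchFrac = 0.25,
                                searchIn = 100L) {
    stopifnot(is(flanked, "FlankedGene"))
    gene <- flanked@geneSeq
    intoGene <- min(as.integer(searchIn), nchar(gene))
    upSpan <- paste0(flanked@upstream, substr(gene, 1L, intoGene))
    dnSpan <- paste0(substr(gene, nchar(gene) - intoGene + 1L, nchar(gene)),
                     flanked@downstream)
    if (!nzchar(flanked@upstream) && !nzchar(flanked@downstream)) {
        message("gene '", flanked@geneId, "': no flanking sequence, skipping")
        return(NULL)
    }
    if (nchar(upSpan) < minLen || nchar(dnSpan) < minLen) {
        message("gene '", flanked@geneId, "': flanks shorter than minLen")
        return(NULL)
    }
    target <- reverseComplementSeq(dnSpan)
    sub <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                    baseOnly = FALSE)
    aln <- Biostrings::pairwiseAlignment(upSpan, target, type = "local",
                                         substitutionMatrix = sub,
                                         gapOpening = 0, gapExtension = 2)
    ap <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
    as_ <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
    # trim to the shortest segment attaining the maximal score: the optimal
    # local alignment may carry zero-net-score extensions (chance matches
    # balancing mismatches) that would blur the repeat boundaries
    colScore <- ifelse(ap == "-" | as_ == "-", -2, ifelse(ap == as_, 1, -1))
    cur <- 0; st <- 1L
    bestSum <- -Inf; bestI <- 1L; bestJ <- length(colScore)
    for (i in seq_along(colScore)) {
        if (cur <= 0) { cur <- colScore[i]; st <- i } else
            cur <- cur + colScore[i]
        if (cur > bestSum ||
            (cur == bestSum && (i - st) < (bestJ - bestI))) {
            bestSum <- cur; bestI <- st; bestJ <- i
        }
    }
    keep <- bestI:bestJ
    pOff0 <- sum(ap[seq_len(bestI - 1L)] != "-")
    tOff0 <- sum(as_[seq_len(bestI - 1L)] != "-")
    pLen <- sum(ap[keep] != "-")
    tLen <- sum(as_[keep] != "-")
    ap <- ap[keep]; as_ <- as_[keep]
    alnLen <- length(ap)
    mism <- sum(ap != as_ | ap == "-" | as_ == "-")
    if (alnLen < minLen || mism / alnLen > maxMismatchFrac) {
        message("gene '", flanked@geneId, "': no repeat pair at minLen=",
                minLen, ", maxMismatchFrac=", maxMismatchFrac)
        return(NULL)
    }
    pStart <- aln@pattern@range@start + pOff0
    pEnd <- pStart + pLen - 1L
    tStart <- aln@subject@range@start + tOff0
    tEnd <- tStart + tLen - 1L
    # map subject hit back from revcomp(dnSpan) to dnSpan coordinates
    dStart <- nchar(dnSpan) - tEnd + 1L
    dEnd <- nchar(dnSpan) - tStart + 1L
    U <- nchar(flanked@upstream)
    leftDistance <- U - pEnd                    # 0 when abutting the start codon
    rightDistance <- dStart - intoGene - 1L     # negative when inside the gene
    leftSeq <- substr(upSpan, pStart, pEnd)
    rightSeq <- substr(dnSpan, dStart, dEnd)
    new("RepeatEnds", geneId = flanked@geneId,
        leftSeq = leftSeq, rightSeq = rightSeq,
        leftDistance = as.integer(leftDistance),
        rightDistance = as.integer(rightDistance),
        score = aln@score, mismatches = as.integer(mism),
        alignedLength = as.integer(alnLen),
        palindromic = identical(leftSeq, reverseComplementSeq(leftSeq)))
}

#' Signed distance from a repeat to the gene start/stop codon
#'
#' Left end: bp between the last repeat base and the first base of the start
#' codon; right end: bp between the last base of the stop codon and the first
#' repeat base. Negative values mean the repeat overlaps the coding region.
#' Coordinates are genomic, 1-based inclusive; minus-strand genes are handled
#' by mirroring.
#'
#' @param irStart,irEnd genomic coordinates of the repeat.
#' @param feature a length-1 \code{GRanges} for the gene.
#' @param end "left" (upstream of the start codon) or "right".
#' @return signed integer distance in bp.
#' @export
endDistance <- function(irStart, irEnd, feature, end = c("left", "right")) {
    end <- match.arg(end)
    s <- GenomicRanges::start(feature)
    e <- GenomicRanges::end(feature)
    minus <- as.character(GenomicRanges::strand(feature)) == "-"
    if (end == "left") {
        if (!minus) as.integer(s - irEnd - 1L)
        else        as.integer(irStart - e - 1L)
    } else {
        if (!minus) as.integer(irStart - e - 1L)
        else        as.integer(s - irEnd - 1L)
    }
}

#' Identity table for a dot-notation alignment
#'
#' Computes the end identity of every row of a \code{DottedAlignment} against
#' its reference, mirroring the layout of the published end tables.
#'
#' @param da a \code{\linkS4class{DottedAlignment}}.
#' @param end label recorded in the output ("left" or "right").
#' @return data.frame with columns referenceId, rowId, end, distance,
#'   matches, scoredColumns, identityPct, printedIdentity.
#' @export
endIdentityTable <- function(da, end = "left") {
    rows <- lapply(seq_along(da@ids), function(i)
        identityFromAlignment(da@referenceRow, da@expandedRows[i],
                              referenceId = da@referenceId,
                              rowId = da@ids[i]))
    data.frame(
        referenceId = da@referenceId,
        rowId = da@ids,
        end = end,
        distance = da@distance[-1L],
        matches = vapply(rows, function(x) x@matches, 0L),
        scoredColumns = vapply(rows, function(x) x@scoredColumns, 0L),
        identityPct = vapply(rows, identityPct, 0),
        printedIdentity = da@printedIdentity,
        stringsAsFactors = FALSE)
}
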