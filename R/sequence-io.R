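#' Read genome sequences from a FASTA file
#'
#' Reads a multi-record FASTA file into a \code{DNAStringSet}. Sequences are
#' uppercased, U is mapped to T, and the alphabet is restricted to A, C, G, T
#' and N: ambiguity codes other than N are rejected so that downstream
#' tetranucleotide counting stays exact.
#'
#' @param path path to a FASTA file.
#' @return a \code{\link[Biostrings]{DNAStringSet}} named by the first token
#'   of each header; the full headers are kept in
#'   \code{metadata(x)$description}.
#' @export
#' @importFrom Biostrings readBStringSet DNAStringSet
#' @importFrom S4Vectors metadata metadata<-
readGenomes <- function(path) {
    if (!file.exists(path))
        stop("FASTA file not found: ", path)
    raw <- Biostrings::readBStringSet(path)
    if (length(raw) == 0L)
        stop("no FASTA records in ", path)
    headers <- names(raw)
    ids <- sub("\\s.*$", "", headers)
    if (anyDuplicated(ids))
        stop("duplicate FASTA ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    seqs <- chartr("u", "t", toupper(as.character(raw)))
    seqs <- chartr("U", "T", seqs)
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad)) {
        culprit <- regmatches(seqs[bad][1L],
                              regexpr("[^ACGTN]", seqs[bad][1L]))
        stop(sprintf("record '%s' contains illegal character '%s' (alphabet is A,C,G,T,N)",
                     ids[bad][1L], culprit))
    }
    if (any(!nzchar(seqs)))
        stop("empty sequence for record ", ids[!nzchar(seqs)][1L])
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    S4Vectors::metadata(x)$description <- headers
    x
}

#' Write genome sequences to FASTA
#'
#' @param x a \code{DNAStringSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
#' @importFrom Biostrings writeXStringSet
writeGenomes <- function(x, path) {
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

#' Read gene features from a TSV or GFF3 file
#'
#' The TSV dialect has columns \code{contig}, \code{start}, \code{end},
#' \code{strand}, \code{gene_id} and optionally \code{product} and
#' \code{taxon}. GFF3 is read through \pkg{rtracklayer}; the gene id is taken
#' from the \code{ID} (or \code{locus_tag}) attribute. Coordinates are 1-based
#' inclusive on every interface.
#'
#' @param path feature file.
#' @param dialect "tsv" or "gff3".
#' @param genome optional \code{DNAStringSet}; when given, features are
#'   cross-checked against contig names and lengths.
#' @return a \code{\link[GenomicRanges]{GRanges}} with metadata columns
#'   \code{gene_id}, \code{product}, \code{taxon}.
#' @export
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom utils read.delim
readFeatures <- function(path, dialect = c("tsv", "gff3"), genome = NULL) {
    dialect <- match.arg(dialect)
    if (!file.exists(path))
        stop("feature file not found: ", path)
    if (dialect == "tsv") {
        tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                                 comment.char = "#")
        need <- c("contig", "start", "end", "strand", "gene_id")
        miss <- setdiff(need, names(tab))
        if (length(miss))
            stop("feature TSV lacks columns: ", paste(miss, collapse = ", "))
        contig <- as.character(tab$contig)
        start <- as.integer(tab$start)
        end <- as.integer(tab$end)
        strand <- as.character(tab$strand)
        gene_id <- as.character(tab$gene_id)
        product <- if ("product" %in% names(tab)) as.character(tab$product) else rep("", nrow(tab))
        taxon <- if ("taxon" %in% names(tab)) as.character(tab$taxon) else rep("", nrow(tab))
    } else {
        g <- rtracklayer::import(path, format = "gff3")
        contig <- as.character(GenomicRanges::seqnames(g))
        start <- GenomicRanges::start(g)
        end <- GenomicRanges::end(g)
        strand <- as.character(GenomicRanges::strand(g))
        mc <- S4Vectors::mcols(g)
        gene_id <- if ("ID" %in% names(mc)) as.character(mc$ID)
                   else if ("locus_tag" %in% names(mc)) as.character(mc$locus_tag)
                   else stop("GFF3 features need an ID or locus_tag attribute")
        product <- if ("product" %in% names(mc)) as.character(mc$product) else rep("", length(g))
        taxon <- if ("taxon" %in% names(mc)) as.character(mc$taxon) else rep("", length(g))
    }
    if (any(is.na(start)) || any(is.na(end)))
        stop("non-numeric start/end in ", path)
    if (any(start < 1L))
        stop("start coordinates must be >= 1 (1-based inclusive)")
    if (any(start > end))
        stop("start > end for gene(s): ",
             paste(gene_id[start > end], collapse = ", "))
    if (any(!strand %in% c("+", "-")))
        stop("strand must be '+' or '-'; offending gene(s): ",
             paste(gene_id[!strand %in% c("+", "-")], collapse = ", "))
    if (!is.null(genome)) {
        unknown <- !contig %in% names(genome)
        if (any(unknown))
            stop("contig(s) not in genome: ",
                 paste(unique(contig[unknown]), collapse = ", "))
        lens <- IRanges::width(genome)[match(contig, names(genome))]
        over <- end > lens
        if (any(over))
            stop("feature(s) extend beyond contig end: ",
                 paste(gene_id[over], collapse = ", "))
    }
    gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(start, end),
                                 strand = strand)
    S4Vectors::mcols(gr)$gene_id <- gene_id
    S4Vectors::mcols(gr)$product <- product
    S4Vectors::mcols(gr)$taxon <- taxon
    names(gr) <- gene_id
    gr
}

#' Write gene features to the package TSV dialect
#'
#' @param features a \code{GRanges} as returned by \code{readFeatures}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
#' @importFrom utils write.table
writeFeatures <- function(features, path) {
    mc <- S4Vectors::mcols(features)
    tab <- data.frame(
        contig = as.character(GenomicRanges::seqnames(features)),
        start = GenomicRanges::start(features),
        end = GenomicRanges::end(features),
        strand = as.character(GenomicRanges::strand(features)),
        gene_id = mc$gene_id,
        product = if ("product" %in% names(mc)) mc$product else "",
        taxon = if ("taxon" %in% names(mc)) mc$taxon else "",
        stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Extract a gene with flanking windows
#'
#' Returns the gene sequence together with up to \code{window} bases of 5' and
#' 3' flank, truncated at contig edges (flanks are not clipped at neighbouring
#' genes). For minus-strand genes the gene and both flanks are
#' reverse-complemented so "upstream" is always 5' of the coding strand;
#' published IS end tables are gene-anchored in exactly this sense.
#'
#' @param genome a \code{DNAStringSet}.
#' @param feature a length-1 \code{GRanges} row from \code{readFeatures}.
#' @param window flank length in bp (default 1000, the window the IS end
#'   analysis uses).
#' @return a \code{\linkS4class{FlankedGene}}.
#' @export
extractFlankedGene <- function(genome, feature, window = 1000L) {
    stopifnot(length(feature) == 1L)
    window <- as.integer(window)
    contig <- as.character(GenomicRanges::seqnames(feature))
    if (!contig %in% names(genome))
        stop("feature contig '", contig, "' not found in genome")
    chrom <- genome[[contig]]
    clen <- length(chrom)
    s <- GenomicRanges::start(feature)
    e <- GenomicRanges::end(feature)
    if (e > clen)
        stop("feature extends beyond contig '", contig, "'")
    strand <- as.character(GenomicRanges::strand(feature))
    gene <- as.character(Biostrings::subseq(chrom, s, e))
    up <- as.character(Biostrings::subseq(chrom, max(1L, s - window),
                                          max(0L, s - 1L)))
    if (s == 1L) up <- ""
    dn <- if (e == clen) "" else
        as.character(Biostrings::subseq(chrom, e + 1L, min(clen, e + window)))
    if (strand == "-") {
        gene <- reverseComplementSeq(gene)
        tmp <- reverseComplementSeq(dn)   # genomic right side is the 5' flank
        dn <- reverseComplementSeq(up)
        up <- tmp
    }
    new("FlankedGene",
        geneId = as.character(S4Vectors::mcols(feature)$gene_id),
        contigId = contig, start = as.integer(s), end = as.integer(e),
        strand = strand, geneSeq = gene, upstream = up, downstream = dn,
        window = window)
}

#' Reverse complement of a nucleotide string
#'
#' Standard complement over A,C,G,T with N self-complementary, reversed.
#' Vectorised over its input.
#'
#' @param seq character vector over A,C,G,T,N (empty strings allowed).
#' @return character vector of reverse complements.
#' @export
reverseComplementSeq <- function(seq) {
    if (any(grepl("[^ACGTN]", seq)))
        stop("illegal character in sequence (alphabet is A,C,G,T,N)")
    comp <- chartr("ACGTN", "TGCAN", seq)
    vapply(strsplit(comp, ""), function(x) paste(rev(x), collapse = ""), "")
}

.normGaps <- function(x) gsub("[[:space:]]", "", chartr("–", "-", x))

#' Parse a dot-notation end alignment
#'
#' Accepts either a path to a TSV with columns \code{id}, \code{row} and
#' optionally \code{organism}, \code{distance}, \code{identity}, or a
#' character vector of whitespace-separated "id row" lines. The first row is
#' the reference, written explicitly over A,C,G,T and gaps; subsequent rows
#' use '.' for "same as reference", substitution letters, and gaps. Both '-'
#' and the typographic en-dash are accepted as gaps (tables are typeset with
#' en-dashes); output always uses '-'. Stray spaces inside rows are dropped.
#'
#' A row whose length differs from the reference, or that places '.' under a
#' reference gap, is a parse error naming the row; with
#' \code{dropBadRows = TRUE} such rows are skipped with a warning instead,
#' which is how the shipped fixtures (faithful transcriptions, typographic
#' artifacts included) are loaded.
#'
#' @param x path, character vector of lines, or data.frame.
#' @param dropBadRows skip malformed rows with a warning instead of erroring.
#' @return a \code{\linkS4class{DottedAlignment}}.
#' @export
parseDottedAlignment <- function(x, dropBadRows = FALSE) {
    if (is.character(x) && length(x) == 1L && file.exists(x))
        x <- utils::read.delim(x, stringsAsFactors = FALSE)
    if (is.character(x)) {
        parts <- strsplit(trimws(x[nzchar(trimws(x))]), "[[:space:]]+")
        if (any(lengths(parts) < 2L))
            stop("each alignment line needs an id and a row")
        x <- data.frame(id = vapply(parts, `[`, "", 1L),
                        row = vapply(parts, function(p)
                            paste(p[-1L], collapse = ""), ""),
                        stringsAsFactors = FALSE)
    }
    if (!all(c("id", "row") %in% names(x)))
        stop("dotted alignment table needs 'id' and 'row' columns")
    if (nrow(x) < 1L)
        stop("empty dotted alignment")
    rows <- .normGaps(as.character(x$row))
    ids <- as.character(x$id)
    refRow <- rows[1L]
    if (grepl("[^ACGTN-]", refRow))
        stop("reference row must be explicit bases and gaps")
    n <- length(ids)
    parseNum <- function(col) {
        if (!col %in% names(x)) return(rep(NA_real_, n))
        v <- as.character(x[[col]])
        v[v %in% c("", "nd", "NA")] <- NA
        suppressWarnings(as.numeric(chartr("−–", "--", v)))
    }
    distance <- parseNum("distance")
    printed <- parseNum("identity")
    organism <- if ("organism" %in% names(x)) as.character(x$organism) else rep("", n)

    refChars <- strsplit(refRow, "")[[1L]]
    keep <- logical(n); keep[1L] <- TRUE
    expanded <- character(n)
    for (i in seq_len(n)[-1L]) {
        row <- rows[i]
        if (nchar(row) != nchar(refRow)) {
            msg <- sprintf("row '%s' has %d columns, reference has %d",
                           ids[i], nchar(row), nchar(refRow))
            if (dropBadRows) { warning(msg); next }
            stop(msg)
        }
        rc <- strsplit(row, "")[[1L]]
        if (any(rc == "." & refChars == "-")) {
            msg <- sprintf("row '%s' places '.' under a reference gap", ids[i])
            if (dropBadRows) { warning(msg); next }
            stop(msg)
        }
        if (any(!rc %in% c(".", "-", "A", "C", "G", "T", "N"))) {
            msg <- sprintf("row '%s' contains illegal symbols", ids[i])
            if (dropBadRows) { warning(msg); next }
            stop(msg)
        }
        out <- ifelse(rc == ".", refChars, rc)
        expanded[i] <- paste(out, collapse = "")
        keep[i] <- TRUE
    }
    idx <- which(keep)[-1L]
    new("DottedAlignment",
        referenceId = ids[1L], referenceRow = refRow,
        ids = ids[idx], dottedRows = rows[idx], expandedRows = expanded[idx],
        distance = distance[keep], printedIdentity = printed[idx],
        organism = organism[idx])
}

#' Serialize a DottedAlignment back to dot notation
#'
#' Rebuilds each row from its expanded form: columns equal to the reference
#' (both non-gap) become '.', everything else is written explicitly. Gap
#' glyphs are emitted as '-', so a round trip through
#' \code{parseDottedAlignment} reproduces the input up to gap-glyph
#' normalization.
#'
#' @param da a \code{DottedAlignment}.
#' @param path optional output path; when NULL the lines are returned.
#' @return character vector of "id<TAB>row" lines (invisibly when written).
#' @export
writeDottedAlignment <- function(da, path = NULL) {
    refChars <- strsplit(da@referenceRow, "")[[1L]]
    dotted <- vapply(da@expandedRows, function(row) {
        rc <- strsplit(row, "")[[1L]]
        paste(ifelse(rc == refChars & rc != "-", ".", rc), collapse = "")
    }, "", USE.NAMES = FALSE)
    lines <- c(paste(da@referenceId, da@referenceRow, sep = "\t"),
               paste(da@ids, dotted, sep = "\t"))
    if (is.null(path)) return(lines)
    writeLines(lines, path)
    invisible(lines)
}
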