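# shared test utilities

fixturePath <- function(name) {
    p <- system.file("extdata", name, package = "istrace")
    if (!nzchar(p)) stop("fixture not found: ", name)
    p
}

# which printed identities in the shipped end-table fixtures were verified by
# an independent re-computation; unverified entries are typographic artifacts
# of the printed tables and are skipped by the reproduction tests
identityVerification <- function() {
    jsonlite::read_json(fixturePath("printed_identity_verification.json"),
                        simplifyVector = TRUE)
}

randomDna <- function(n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

randomAa <- function(n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], n,
                 replace = TRUE), collapse = "")
}

# substitute k positions of a sequence (never to the original base)
substituteAt <- function(seq, pos, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    chars <- strsplit(seq, "")[[1L]]
    for (i in pos)
        chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    paste(chars, collapse = "")
}

# independent Smith-Waterman oracle: best local alignment score with
# match +1, mismatch -1, linear gap -2 (the IR scan scoring)
swOracleScore <- function(a, b) {
    a <- strsplit(a, "")[[1L]]; b <- strsplit(b, "")[[1L]]
    n <- length(a); m <- length(b)
    H <- matrix(0, n + 1L, m + 1L)
    best <- 0
    for (i in seq_len(n)) for (j in seq_len(m)) {
        sc <- max(0,
                  H[i, j] + if (a[i] == b[j]) 1 else -1,
                  H[i, j + 1L] - 2,
                  H[i + 1L, j] - 2)
        H[i + 1L, j + 1L] <- sc
        if (sc > best) best <- sc
    }
    best
}

# naive overlapping-window k-mer counter (enumeration oracle)
naiveKmerCounts <- function(seq, k = 4L) {
    kmers <- character(0)
    for (i in seq_len(nchar(seq) - k + 1L))
        kmers <- c(kmers, substr(seq, i, i + k - 1L))
    kmers <- kmers[!grepl("N", kmers)]
    table(kmers)
}
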