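#' Pairwise distances between composition profiles
#'
#' Euclidean distance on the k-mer frequency vectors by default; Bray-Curtis
#' is offered as the dissimilarity commonly paired with NMDS in community
#' ecology workflows. The published figures never name the dissimilarity
#' actually used, so cluster membership rather than coordinates is the
#' comparable quantity.
#'
#' @param profiles list of \code{TetraProfile} (at least 3).
#' @param metric "euclidean" or "bray-curtis".
#' @return a \code{\link[stats]{dist}} with an attribute \code{metric}.
#' @export
#' @importFrom stats dist
#' @importFrom vegan vegdist
profileDistanceMatrix <- function(profiles,
                                  metric = c("euclidean", "bray-curtis")) {
    metric <- match.arg(metric)
    if (length(profiles) < 3L)
        stop("need at least 3 profiles for an ordination distance matrix")
    m <- do.call(rbind, lapply(profiles, tetraFrequencies))
    rownames(m) <- vapply(profiles, ownerId, "")
    d <- if (metric == "euclidean") stats::dist(m)
         else vegan::vegdist(m, method = "bray")
    attr(d, "metric") <- metric
    d
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Minimizes Kruskal stress-1 (monotone regression via
#' \code{\link[vegan]{monoMDS}}, the engine the original analyses used
#' through vegan) over \code{nRestarts + 1} starts: start 0 is the classical
#' metric MDS configuration, which makes the usual best solution
#' deterministic, and the remaining starts are seeded Gaussian
#' configurations. The whole procedure is reproducible bit-for-bit given
#' \code{(seed, nRestarts, maxIter, tol)}.
#'
#' @param dm a \code{dist} (or symmetric matrix) of dissimilarities.
#' @param dims embedding dimension, default 2.
#' @param nRestarts random restarts beyond the metric start, default 50.
#' @param seed integer seed for the random starts.
#' @param maxIter iteration cap per restart.
#' @param tol stress convergence tolerance.
#' @return an \code{\linkS4class{NmdsEmbedding}}.
#' @export
#' @importFrom stats cmdscale rnorm
#' @importFrom vegan monoMDS
nmdsEmbed <- function(dm, dims = 2L, nRestarts = 50L, seed = 42L,
                      maxIter = 500L, tol = 1e-9) {
    if (is.matrix(dm)) dm <- stats::as.dist(dm)
    n <- attr(dm, "Size")
    ids <- attr(dm, "Labels")
    if (is.null(ids)) ids <- as.character(seq_len(n))
    if (n < 3L)
        stop("need at least 3 items")
    dv <- as.vector(dm)
    if (any(dv < 0)) stop("negative dissimilarities")
    if (length(unique(round(dv, 12))) == 1L)
        warning("degenerate distance matrix: all dissimilarities equal; ",
                "the configuration is arbitrary")
    starts <- vector("list", nRestarts + 1L)
    cm <- stats::cmdscale(dm, k = dims)
    if (ncol(cm) < dims)   # cmdscale may drop null dimensions
        cm <- cbind(cm, matrix(0, n, dims - ncol(cm)))
    starts[[1L]] <- cm
    set.seed(as.integer(seed))
    for (i in seq_len(nRestarts))
        starts[[i + 1L]] <- matrix(stats::rnorm(n * dims), n, dims)
    best <- NULL
    for (st in starts) {
        fit <- vegan::monoMDS(dm, y = st, k = dims, model = "global",
                              maxit = maxIter, smin = tol, sfgrmin = tol,
                              sratmax = 1 - 1e-12)
        # a later restart replaces the incumbent only when it improves the
        # stress meaningfully: among effectively tied solutions this keeps
        # the deterministic metric start, which also avoids preferring a
        # collapsed (degenerate) zero-stress configuration over an equally
        # good structured one
        if (is.null(best) || fit$stress < best$stress - 1e-6) best <- fit
    }
    coords <- scale(best$points, center = TRUE, scale = FALSE)
    attr(coords, "scaled:center") <- NULL
    dimnames(coords) <- NULL
    new("NmdsEmbedding", ids = ids, coordinates = coords,
        stress = best$stress, nRestarts = as.integer(nRestarts),
        seed = as.integer(seed),
        converged = best$icause %in% c(1L, 2L))
}

#' Write an embedding to TSV (+ JSON stress sidecar)
#'
#' @param emb an \code{NmdsEmbedding}.
#' @param path coordinates TSV path; the sidecar is \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
writeEmbedding <- function(emb, path) {
    tab <- data.frame(id = emb@ids,
                      x = emb@coordinates[, 1L],
                      y = emb@coordinates[, 2L])
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
        list(stress = emb@stress, nRestarts = emb@nRestarts,
             seed = emb@seed, converged = emb@converged),
        paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
    invisible(path)
}
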