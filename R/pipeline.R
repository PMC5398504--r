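#' Build a pipeline run configuration
#'
#' @param genome,features,taxa input file paths (may stay "" when the run
#'   starts from \code{simulate}).
#' @param window flank window (bp), default 1000.
#' @param alpha profile pseudocount, default 1.
#' @param nmdsMetric,nmdsRestarts ordination settings.
#' @param irMinLen,irMaxMismatchFrac IR scan settings.
#' @param clusterThreshold,hgtMargin grouping and verdict settings.
#' @param queryGenus,queryPhylum the query taxon whose elements are called.
#' @param outDir artifact directory.
#' @param seed master seed; per-stage seeds are derived by fixed offsets so
#'   one knob reproduces a whole run.
#' @return a \code{\linkS4class{RunConfig}}.
#' @export
runConfig <- function(genome = "", features = "", taxa = "", window = 1000L,
                      alpha = 1, nmdsMetric = "euclidean",
                      nmdsRestarts = 20L, irMinLen = 20L,
                      irMaxMismatchFrac = 0.25, clusterThreshold = 70,
                      hgtMargin = 10, queryGenus = "Fervidobacterium",
                      queryPhylum = "Thermotogae", outDir = "istrace_out",
                      seed = 1L) {
    new("RunConfig", genome = genome, features = features, taxa = taxa,
        window = as.integer(window), alpha = alpha, nmdsMetric = nmdsMetric,
        nmdsRestarts = as.integer(nmdsRestarts),
        irMinLen = as.integer(irMinLen),
        irMaxMismatchFrac = irMaxMismatchFrac,
        clusterThreshold = clusterThreshold, hgtMargin = hgtMargin,
        queryGenus = queryGenus, queryPhylum = queryPhylum,
        outDir = outDir, seed = as.integer(seed))
}

# RunConfig carries queryGenus/queryPhylum through the stage functions; they
# are stored alongside the S4 slots in the serialized form.
.configList <- function(config) {
    slots <- slotNames("RunConfig")
    out <- lapply(slots, function(s) slot(config, s))
    names(out) <- slots
    out
}

#' Serialize / restore a run configuration (lossless JSON round trip)
#'
#' @param config a \code{RunConfig}.
#' @param path JSON file path.
#' @return \code{writeRunConfig}: the path, invisibly; \code{readRunConfig}:
#'   the restored \code{RunConfig}.
#' @export
writeRunConfig <- function(config, path) {
    jsonlite::write_json(.configList(config), path, auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (s in c("alpha", "irMaxMismatchFrac", "clusterThreshold",
                "hgtMargin"))
        x[[s]] <- as.numeric(x[[s]])
    do.call(runConfig, x)
}

#' Hash of a run configuration
#'
#' MD5 of the canonical JSON serialization of the analysis parameters and the
#' master seed; stamped into every artifact manifest so artifacts computed
#' under different parameters cannot be mixed. File locations (input paths,
#' outDir) are provenance, recorded in the manifest but not hashed — the
#' \code{simulate} stage legitimately rewrites the input paths mid-run.
#'
#' @param config a \code{RunConfig}.
#' @return character MD5 hash.
#' @export
configHash <- function(config) {
    config@outDir <- ""
    config@genome <- ""
    config@features <- ""
    config@taxa <- ""
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    writeRunConfig(config, tmp)
    unname(tools::md5sum(tmp))
}

.manifestPath <- function(outDir) file.path(outDir, "manifest.json")

.checkManifest <- function(outDir, hash) {
    mp <- .manifestPath(outDir)
    if (!file.exists(mp)) return(list(stages = list(), configHash = hash))
    man <- jsonlite::read_json(mp, simplifyVector = FALSE)
    if (!identical(man$configHash, hash))
        stop("output directory '", outDir, "' holds artifacts from a ",
             "different configuration (hash mismatch); refusing to mix")
    man
}

.recordStage <- function(outDir, man, stage, files, seed) {
    man$stages[[stage]] <- list(files = as.list(files), seed = seed,
                                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                package = as.character(utils::packageVersion("istrace")))
    jsonlite::write_json(man, .manifestPath(outDir), auto_unbox = TRUE,
                         digits = NA)
    man
}

# ---- shared analysis engine -------------------------------------------------

.translateOrf <- function(seq) {
    as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                       if.fuzzy.codon = "X"))
}

.subsetSimilarity <- function(sim, ids) {
    m <- simValues(sim)[ids, ids, drop = FALSE]
    new("SimilarityMatrix", ids = ids, s = unname(m),
        definition = sim@definition)
}

#' Full HGT analysis of a gene set
#'
#' The engine behind the \code{call} stage: extracts every gene with flanks,
#' computes pairwise protein similarity over all genes, groups the
#' query-taxon genes by single linkage, and calls interphylum HGT per group
#' using similarity (E1), tetranucleotide divergence to the comparator genes
#' (E2), and inverted-repeat identity from the automated end scan (E3).
#'
#' @param genome \code{DNAStringSet} with all contigs (query genome plus
#'   comparator sequences).
#' @param features \code{GRanges} of transposase genes on those contigs.
#' @param taxa data.frame (id, genus, phylum) covering all gene ids.
#' @param window,alpha,irMinLen,irMaxMismatchFrac,clusterThreshold,margin
#'   analysis parameters, see \code{\link{runConfig}}.
#' @param queryGenus,queryPhylum the taxon whose genes are grouped and
#'   called.
#' @return list(groups, calls, perGene, similarity, repeats).
#' @export
analyzeGenes <- function(genome, features, taxa, window = 1000L, alpha = 1,
                         irMinLen = 20L, irMaxMismatchFrac = 0.25,
                         clusterThreshold = 70, margin = 10,
                         queryGenus = "Fervidobacterium",
                         queryPhylum = "Thermotogae") {
    ids <- as.character(S4Vectors::mcols(features)$gene_id)
    flanked <- lapply(seq_along(features), function(i)
        extractFlankedGene(genome, features[i], window = window))
    names(flanked) <- ids
    prots <- vapply(flanked, function(f) .translateOrf(f@geneSeq), "")
    sim <- pairwiseProteinSimilarity(prots)
    tx <- taxa[match(ids, taxa$id), ]
    queryIds <- ids[tx$genus == queryGenus & tx$phylum == queryPhylum]
    if (!length(queryIds))
        stop("no genes labelled with the query taxon (", queryGenus, ", ",
             queryPhylum, ")")
    groups <- clusterBySimilarity(.subsetSimilarity(sim, queryIds),
                                  threshold = clusterThreshold)
    profiles <- lapply(ids, function(id)
        tetraProfile(flanked[[id]]@geneSeq, ownerId = id, alpha = alpha))
    names(profiles) <- ids
    reps <- suppressMessages(lapply(flanked, findInvertedRepeats,
                                    minLen = irMinLen,
                                    maxMismatchFrac = irMaxMismatchFrac))
    comparatorIds <- setdiff(ids, queryIds)
    calls <- lapply(groups, function(gp) {
        r <- gp@representative
        kl <- do.call(rbind, lapply(comparatorIds, function(cid)
            data.frame(queryId = r, referenceId = cid,
                       dKl = klDivergence(profiles[[r]], profiles[[cid]]),
                       stringsAsFactors = FALSE)))
        ir <- NULL
        if (!is.null(reps[[r]])) {
            withIr <- comparatorIds[!vapply(reps[comparatorIds], is.null,
                                            TRUE)]
            if (length(withIr)) {
                ir <- data.frame(
                    geneId = r, partnerId = unname(withIr),
                    leftIdentity = .batchEndIdentity(
                        reps[[r]]@leftSeq,
                        unname(vapply(reps[withIr], function(x) x@leftSeq, ""))),
                    rightIdentity = .batchEndIdentity(
                        reps[[r]]@rightSeq,
                        unname(vapply(reps[withIr], function(x) x@rightSeq, ""))),
                    stringsAsFactors = FALSE)
            }
        }
        callHgt(gp, sim, taxa, kl = kl, ir = ir, margin = margin,
                queryGenus = queryGenus, queryPhylum = queryPhylum)
    })
    verdictOf <- stats::setNames(
        rep(vapply(calls, hgtVerdict, ""), vapply(groups, function(g)
            length(g@members), 0L)),
        unlist(lapply(groups, groupMembers)))
    perGene <- data.frame(geneId = queryIds,
                          groupId = vapply(queryIds, function(id) {
                              for (g in groups)
                                  if (id %in% g@members) return(g@groupId)
                              NA_character_
                          }, ""),
                          verdict = unname(verdictOf[queryIds]),
                          stringsAsFactors = FALSE)
    list(groups = groups, calls = calls, perGene = perGene,
         similarity = sim, repeats = reps)
}

#' Analyze a simulated study end to end
#'
#' Assembles the simulated recipient genome, donor genome and comparator
#' sequences (each comparator as its own contig) into one gene set, runs
#' \code{\link{analyzeGenes}}, and joins the verdicts to the simulation
#' truth.
#'
#' @param sim result of \code{\link{simulateHgtStudy}}.
#' @param ... analysis parameters forwarded to \code{analyzeGenes}.
#' @return the \code{analyzeGenes} result plus \code{perElement} (elementId,
#'   origin, verdict).
#' @export
analyzeStudy <- function(sim, ...) {
    compSeqs <- Biostrings::DNAStringSet(sim$comparators$seq)
    names(compSeqs) <- paste0(sim$comparators$id, "_ctg")
    genome <- c(sim$recipientGenome, sim$donorGenome, compSeqs)
    compFeat <- GenomicRanges::GRanges(
        names(compSeqs),
        IRanges::IRanges(sim$comparators$geneStart, sim$comparators$geneEnd),
        strand = "+")
    S4Vectors::mcols(compFeat)$gene_id <- sim$comparators$id
    S4Vectors::mcols(compFeat)$product <- "transposase"
    S4Vectors::mcols(compFeat)$taxon <- sim$comparators$genus
    features <- suppressWarnings(c(sim$features, compFeat))
    res <- analyzeGenes(genome, features, sim$taxa, ...)
    perElement <- merge(sim$truth[, c("elementId", "origin")],
                        res$perGene, by.x = "elementId", by.y = "geneId")
    res$perElement <- perElement[order(perElement$elementId), ]
    res
}

#' Sensitivity and false-positive rate of the caller on synthetic truth
#'
#' Runs \code{\link{simulateHgtStudy}} + \code{\link{analyzeStudy}} for each
#' master seed and pools the per-element verdicts: sensitivity is the
#' fraction of transferred elements called "y", the false-positive rate the
#' fraction of native elements called "y".
#'
#' @param seeds integer vector of master seeds.
#' @param simArgs list of arguments for \code{simulateHgtStudy}.
#' @param ... analysis parameters forwarded to \code{analyzeStudy}.
#' @return list(perSeed, perElement, sensitivity, fpr).
#' @export
evaluateHgtRecovery <- function(seeds, simArgs = list(), ...) {
    all <- list()
    perSeed <- list()
    for (s in seeds) {
        sim <- do.call(simulateHgtStudy, c(list(seed = s), simArgs))
        res <- analyzeStudy(sim, ...)
        pe <- res$perElement
        pe$seed <- s
        all[[as.character(s)]] <- pe
        perSeed[[as.character(s)]] <- data.frame(
            seed = s,
            sensitivity = mean(pe$verdict[pe$origin == "transferred"] == "y"),
            fpr = mean(pe$verdict[pe$origin == "native"] == "y"))
    }
    pe <- do.call(rbind, all)
    list(perSeed = do.call(rbind, perSeed), perElement = pe,
         sensitivity = mean(pe$verdict[pe$origin == "transferred"] == "y"),
         fpr = mean(pe$verdict[pe$origin == "native"] == "y"))
}

# ---- file-based stages ------------------------------------------------------

.stageSeeds <- c(simulate = 11L, profile = 13L, kl = 17L, nmds = 19L,
                 ends = 23L, tree = 29L, call = 31L)

.readStageInputs <- function(config) {
    if (!nzchar(config@genome) || !file.exists(config@genome))
        stop("genome FASTA not found: '", config@genome, "'")
    if (!nzchar(config@features) || !file.exists(config@features))
        stop("feature table not found: '", config@features, "'")
    genome <- readGenomes(config@genome)
    features <- readFeatures(config@features, dialect = "tsv",
                             genome = genome)
    taxa <- NULL
    if (nzchar(config@taxa)) {
        if (!file.exists(config@taxa))
            stop("taxa table not found: '", config@taxa, "'")
        taxa <- utils::read.delim(config@taxa, stringsAsFactors = FALSE)
    }
    list(genome = genome, features = features, taxa = taxa)
}

.geneProfiles <- function(genome, features, alpha, window) {
    ids <- as.character(S4Vectors::mcols(features)$gene_id)
    profiles <- lapply(seq_along(features), function(i) {
        fg <- extractFlankedGene(genome, features[i], window = window)
        tetraProfile(fg@geneSeq, ownerId = ids[i], alpha = alpha)
    })
    names(profiles) <- ids
    profiles
}

#' Run one pipeline stage
#'
#' Stages: \code{simulate} (write a synthetic study into outDir and point the
#' config inputs at it), \code{profile} (per-gene and per-contig composition
#' profiles), \code{kl} (divergence ranking against the first gene and the
#' contig profiles), \code{nmds} (ordination coordinates + stress),
#' \code{ends} (IR scan per gene), \code{tree} (protein similarity matrix +
#' NJ newick), \code{call} (grouping + HGT verdicts), \code{all} (everything
#' in order). Artifacts are plain TSV/JSON, stamped with the configuration
#' hash; a stage refuses to write into a directory holding artifacts of a
#' different configuration. On stage failure, files created by that stage
#' are removed.
#'
#' @param name stage name.
#' @param config a \code{\linkS4class{RunConfig}}.
#' @param verbose log progress lines (logging only; results are unaffected).
#' @return the (possibly updated) \code{RunConfig}, invisibly; \code{simulate}
#'   updates the input paths to the generated files.
#' @export
runStage <- function(name = c("profile", "kl", "nmds", "ends", "tree",
                              "call", "simulate", "all"),
                     config, verbose = FALSE) {
    name <- match.arg(name)
    stopifnot(is(config, "RunConfig"))
    validObject(config)
    if (name == "all") {
        config <- runStage("simulate", config, verbose)
        for (st in c("profile", "kl", "nmds", "ends", "tree", "call"))
            config <- runStage(st, config, verbose)
        return(invisible(config))
    }
    dir.create(config@outDir, showWarnings = FALSE, recursive = TRUE)
    hash <- configHash(config)
    man <- .checkManifest(config@outDir, hash)
    man$configHash <- hash
    seed <- .deriveSeed(config@seed, .stageSeeds[[name]])
    log <- function(...) if (verbose)
        message(sprintf("[%s] seed=%d %s", name, seed, paste0(...)))
    out <- function(f) file.path(config@outDir, f)
    written <- character()
    result <- tryCatch({
        if (name == "simulate") {
            log("generating synthetic study")
            sim <- simulateHgtStudy(seed)
            compSeqs <- Biostrings::DNAStringSet(sim$comparators$seq)
            names(compSeqs) <- paste0(sim$comparators$id, "_ctg")
            genome <- c(sim$recipientGenome, sim$donorGenome, compSeqs)
            compFeat <- GenomicRanges::GRanges(
                names(compSeqs),
                IRanges::IRanges(sim$comparators$geneStart,
                                 sim$comparators$geneEnd), strand = "+")
            S4Vectors::mcols(compFeat)$gene_id <- sim$comparators$id
            S4Vectors::mcols(compFeat)$product <- "transposase"
            S4Vectors::mcols(compFeat)$taxon <- sim$comparators$genus
            written <- c(out("genomes.fasta"), out("features.tsv"),
                         out("taxa.tsv"), out("truth.tsv"),
                         out("sim_params.json"))
            writeGenomes(genome, out("genomes.fasta"))
            writeFeatures(suppressWarnings(c(sim$features, compFeat)),
                          out("features.tsv"))
            utils::write.table(sim$taxa, out("taxa.tsv"), sep = "\t",
                               quote = FALSE, row.names = FALSE)
            utils::write.table(sim$truth, out("truth.tsv"), sep = "\t",
                               quote = FALSE, row.names = FALSE)
            jsonlite::write_json(sim$params, out("sim_params.json"),
                                 auto_unbox = TRUE, digits = NA)
            config@genome <- out("genomes.fasta")
            config@features <- out("features.tsv")
            config@taxa <- out("taxa.tsv")
        } else if (name == "profile") {
            io <- .readStageInputs(config)
            log("profiling ", length(io$features), " genes")
            profiles <- .geneProfiles(io$genome, io$features, config@alpha,
                                      config@window)
            tab <- do.call(rbind, lapply(profiles, function(p)
                data.frame(id = ownerId(p), kmer = names(tetraCounts(p)),
                           count = tetraCounts(p),
                           frequency = tetraFrequencies(p))))
            written <- out("gene_profiles.tsv")
            utils::write.table(tab, written, sep = "\t", quote = FALSE,
                               row.names = FALSE)
        } else if (name == "kl") {
            io <- .readStageInputs(config)
            profiles <- .geneProfiles(io$genome, io$features, config@alpha,
                                      config@window)
            genomeProfiles <- lapply(names(io$genome), function(ct)
                tetraProfile(as.character(io$genome[[ct]]),
                             ownerId = ct, alpha = config@alpha,
                             bothStrands = TRUE))
            big <- genomeProfiles[vapply(genomeProfiles, function(p)
                p@nWindows, 0L) >= 10000L]
            log("ranking ", length(profiles), " genes")
            rk <- divergenceRanking(profiles, profiles[[1L]],
                                    genomeRefs = big)
            written <- out("kl_ranking.tsv")
            utils::write.table(rk, written, sep = "\t", quote = FALSE,
                               row.names = FALSE)
        } else if (name == "nmds") {
            io <- .readStageInputs(config)
            profiles <- .geneProfiles(io$genome, io$features, config@alpha,
                                      config@window)
            dm <- profileDistanceMatrix(profiles, metric = config@nmdsMetric)
            emb <- nmdsEmbed(dm, nRestarts = config@nmdsRestarts, seed = seed)
            log("stress ", format(nmdsStress(emb)))
            written <- c(out("nmds_coordinates.tsv"),
                         out("nmds_coordinates.tsv.json"))
            writeEmbedding(emb, out("nmds_coordinates.tsv"))
        } else if (name == "ends") {
            io <- .readStageInputs(config)
            rows <- lapply(seq_along(io$features), function(i) {
                fg <- extractFlankedGene(io$genome, io$features[i],
                                         window = config@window)
                re <- suppressMessages(findInvertedRepeats(
                    fg, minLen = config@irMinLen,
                    maxMismatchFrac = config@irMaxMismatchFrac))
                if (is.null(re)) return(NULL)
                data.frame(geneId = re@geneId, leftSeq = re@leftSeq,
                           rightSeq = re@rightSeq,
                           leftDistance = re@leftDistance,
                           rightDistance = re@rightDistance,
                           score = re@score, mismatches = re@mismatches,
                           alignedLength = re@alignedLength,
                           palindromic = re@palindromic)
            })
            tab <- do.call(rbind, rows)
            if (is.null(tab))
                tab <- data.frame(geneId = character(), leftSeq = character(),
                                  rightSeq = character(),
                                  leftDistance = integer(),
                                  rightDistance = integer(), score = numeric(),
                                  mismatches = integer(),
                                  alignedLength = integer(),
                                  palindromic = logical())
            log(nrow(tab), " repeat pairs")
            written <- out("repeat_ends.tsv")
            utils::write.table(tab, written, sep = "\t", quote = FALSE,
                               row.names = FALSE)
        } else if (name == "tree") {
            io <- .readStageInputs(config)
            ids <- as.character(S4Vectors::mcols(io$features)$gene_id)
            prots <- vapply(seq_along(io$features), function(i)
                .translateOrf(extractFlankedGene(io$genome, io$features[i],
                                                 window = 0L)@geneSeq), "")
            names(prots) <- ids
            sim <- pairwiseProteinSimilarity(prots)
            tree <- njTree(100 - simValues(sim))
            written <- c(out("similarity.tsv"), out("nj_tree.nwk"))
            utils::write.table(simValues(sim), out("similarity.tsv"),
                               sep = "\t", quote = FALSE)
            ape::write.tree(tree, out("nj_tree.nwk"))
        } else if (name == "call") {
            io <- .readStageInputs(config)
            if (is.null(io$taxa))
                stop("the call stage needs a taxa table (id, genus, phylum)")
            res <- analyzeGenes(io$genome, io$features, io$taxa,
                                window = config@window, alpha = config@alpha,
                                irMinLen = config@irMinLen,
                                irMaxMismatchFrac = config@irMaxMismatchFrac,
                                clusterThreshold = config@clusterThreshold,
                                margin = config@hgtMargin,
                                queryGenus = config@queryGenus,
                                queryPhylum = config@queryPhylum)
            rep_ <- familyReport(res$calls, res$groups)
            log(nrow(rep_), " groups called")
            written <- c(out("hgt_calls.tsv"), out("hgt_calls.json"),
                         out("per_gene_verdicts.tsv"))
            utils::write.table(rep_, out("hgt_calls.tsv"), sep = "\t",
                               quote = FALSE, row.names = FALSE)
            jsonlite::write_json(lapply(res$calls, function(cl) {
                sl <- slotNames("HgtCall")
                stats::setNames(lapply(sl, function(s) slot(cl, s)), sl)
            }), out("hgt_calls.json"), auto_unbox = TRUE, digits = NA,
                na = "null")
            utils::write.table(res$perGene, out("per_gene_verdicts.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        }
        TRUE
    }, error = function(e) {
        unlink(written)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
    })
    man <- .recordStage(config@outDir, man, name, written, seed)
    invisible(config)
}

#' Run the whole pipeline (simulate + all analysis stages)
#'
#' @param config a \code{RunConfig}.
#' @param verbose log progress.
#' @return the updated \code{RunConfig}, invisibly.
#' @export
runPipeline <- function(config, verbose = FALSE)
    runStage("all", config, verbose)
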