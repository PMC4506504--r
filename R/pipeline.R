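#' Read an expression matrix TSV
#'
#' Expects a tab-separated file with a `gene_id` column followed by one
#' column per (time, replicate) named `t<HH>_r<K>` (e.g. `t06_r1` ...
#' `t54_r4`), linear-scale intensities.
#'
#' @param path file path.
#' @return a [TimeCourseExperiment-class] with rows in file order.
#' @export
readMatrix <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (colnames(df)[1L] != "gene_id")
        stop("first column must be 'gene_id'")
    hdr <- colnames(df)[-1L]
    m <- regmatches(hdr, regexec("^t([0-9]+)_r([0-9]+)$", hdr))
    bad <- vapply(m, length, integer(1)) != 3L
    if (any(bad))
        stop(sprintf("unparseable column header(s): %s",
                     paste(hdr[bad], collapse = ", ")))
    tcol <- as.numeric(vapply(m, `[`, character(1), 2L))
    rcol <- as.integer(vapply(m, `[`, character(1), 3L))
    times <- sort(unique(tcol))
    nrep <- max(rcol)
    for (t0 in times) {
        have <- sort(rcol[tcol == t0])
        if (!identical(have, seq_len(nrep)))
            stop(sprintf("time point %g is missing replicate column(s): %s",
                         t0, paste(setdiff(seq_len(nrep), have),
                                   collapse = ", ")))
    }
    vals <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(vals))
        stop("non-numeric values in the expression matrix")
    if (any(vals < 0))
        stop(sprintf("negative intensity at row %d",
                     which(apply(vals < 0, 1L, any))[1L]))
    ord <- order(tcol, rcol)
    TimeCourseExperiment(vals[, ord, drop = FALSE], times = times,
                         nReplicates = nrep, geneIds = df$gene_id)
}

#' Write an expression matrix TSV
#'
#' Inverse of [readMatrix()]: tab-separated, UTF-8, `.` decimal, no
#' quoting; values round-trip at full double precision.
#'
#' @param x a [TimeCourseExperiment-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMatrix <- function(x, path) {
    stopifnot(is(x, "TimeCourseExperiment"))
    df <- data.frame(gene_id = rownames(x), format(intensities(x),
                     digits = 17, trim = TRUE, scientific = FALSE),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write the synthetic ground-truth table
#'
#' @param x a simulated [TimeCourseExperiment-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeTruth <- function(x, path) {
    tr <- syntheticTruth(x)
    df <- data.frame(gene_id = rownames(x), class_kind = tr$classKind,
                     period = tr$truePeriod, phase = tr$truePhase,
                     amplitude = tr$trueAmplitude, is_tf = tr$isTF)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a transcription-factor gene list
#'
#' One gene identifier per line; blank lines ignored.
#'
#' @param path file path.
#' @return character vector of identifiers.
#' @export
readTFList <- function(path) {
    ids <- readLines(path, warn = FALSE)
    ids[nzchar(trimws(ids))]
}

#' Pipeline configuration
#'
#' Collects and validates every stage parameter of [runPipeline()]. The
#' defaults are the analysis constants of the lateral-root study:
#' expression floor 100, FDR 0.05, twofold restriction, clustering spar
#' 0.4 on blocks of 1000 cut at `hMax = 2` with centre-merge distance 2,
#' period-estimation spar 0.1 on a 1000-point grid, and a 20-28 h rhythm
#' template grid.
#'
#' @param floor expressed-gene intensity floor.
#' @param alpha FDR level of the DE call.
#' @param foldChange restriction fold-change.
#' @param pairs,poolScope see [differentialExpression()].
#' @param universe `"restricted"` (default) or `"expressed"`: which gene
#'   set is clustered.
#' @param sparCluster spline smoothness for profile standardization.
#' @param sparPeriod spline smoothness for period estimation.
#' @param divisor variance divisor of the standardization.
#' @param blockSize,hMax,mergeDistance,linkage,consolidateSingleBlock,maxIter
#'   clustering parameters, see [blockCluster()] and [clusterTwoPass()].
#' @param gridSize period-estimation grid.
#' @param minTurningPoints,periodBand oscillatory-cluster rule, see
#'   [classifyOscillatory()].
#' @param periods rhythm-screen period grid (hours).
#' @param pMethod,nullSamples gene-level p-value method of [jtkScreen()].
#' @param qThreshold rhythmic-gene FDR level.
#' @param nComponents PCA QC components.
#' @param seed integer seed governing every stochastic step.
#' @return a validated `lrclockConfig` list.
#' @export
pipelineConfig <- function(floor = 100, alpha = 0.05, foldChange = 2,
                           pairs = "all", poolScope = "global",
                           universe = c("restricted", "expressed"),
                           sparCluster = 0.4, sparPeriod = 0.1,
                           divisor = "sample", blockSize = 1000, hMax = 2,
                           mergeDistance = 2, linkage = "ward.D2",
                           consolidateSingleBlock = TRUE, maxIter = 300L,
                           gridSize = 1000, minTurningPoints = 4,
                           periodBand = c(15, 40), periods = 20:28,
                           pMethod = "permutation", nullSamples = 20000,
                           qThreshold = 0.05, nComponents = 4, seed = 1) {
    universe <- match.arg(universe)
    stopifnot(floor > 0, alpha > 0, alpha < 1, foldChange >= 1,
              sparCluster > 0, sparCluster <= 1, sparPeriod > 0,
              sparPeriod <= 1, blockSize >= 2, hMax > 0,
              mergeDistance >= 0, gridSize >= 10,
              length(periodBand) == 2L, periodBand[1L] < periodBand[2L],
              qThreshold > 0, qThreshold < 1)
    cfg <- as.list(environment())
    structure(cfg[sort(names(cfg))], class = "lrclockConfig")
}

.writeTSV <- function(df, dir, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
}

#' Run the full circadian-structure pipeline
#'
#' Executes, in order: expressed-gene filtering, pairwise differential
#' expression with pooled BH correction, spline standardization of the
#' selected gene universe, two-pass TF/non-TF hybrid clustering,
#' per-cluster mean/s.d. summaries, turning-point period estimation and
#' oscillatory classification of the cluster means, the Kendall-tau
#' rhythm screen over expressed genes, and the PCA oscillation QC. All
#' stage tables are written as TSV into `outDir` together with the
#' resolved configuration and a run manifest; a rerun with the same
#' inputs, configuration and seed is byte-identical.
#'
#' @param x a [TimeCourseExperiment-class], or a path to a matrix TSV for
#'   [readMatrix()].
#' @param tfGenes character vector of TF gene ids, a path to a one-id-per-
#'   line file, or `NULL`/empty (single-pass clustering with a warning).
#'   Ids absent from the matrix are warned about and ignored.
#' @param outDir output directory (created if needed).
#' @param config a [pipelineConfig()].
#' @return the run manifest (named list), invisibly; also written as
#'   `manifest.json`.
#' @export
runPipeline <- function(x, tfGenes = NULL, outDir,
                        config = pipelineConfig()) {
    stopifnot(inherits(config, "lrclockConfig"))
    if (is.character(x) && length(x) == 1L)
        x <- readMatrix(x)
    stopifnot(is(x, "TimeCourseExperiment"))
    if (is.character(tfGenes) && length(tfGenes) == 1L &&
        file.exists(tfGenes))
        tfGenes <- readTFList(tfGenes)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(config), file.path(outDir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    times <- timePoints(x)
    tlab <- sprintf("t%s", .timeLabel(times))

    stage <- function(name, expr) {
        t0 <- proc.time()[["elapsed"]]
        out <- tryCatch(expr, error = function(e)
            stop(sprintf("stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE))
        message(sprintf("[%s] done in %.1f s", name,
                        proc.time()[["elapsed"]] - t0))
        out
    }

    de <- stage("differential-expression", {
        expressed <- filterExpressed(x, floor = config$floor)
        differentialExpression(x, expressed, alpha = config$alpha,
                               foldChange = config$foldChange,
                               pairs = config$pairs,
                               poolScope = config$poolScope)
    })
    .writeTSV(as.data.frame(de), outDir, "de_results.tsv")

    sel <- if (config$universe == "restricted") de$restricted else
        de$expressed
    selIds <- rownames(x)[sel]
    if (length(selIds) < 2L)
        stop("fewer than 2 genes survive the expression/DE filters")

    prof <- stage("spline-normalization", {
        normalizedSplineProfiles(x[selIds, ], spar = config$sparCluster,
                                 divisor = config$divisor)
    })

    tfGenes <- unique(tfGenes)
    unknown <- setdiff(tfGenes, rownames(x))
    if (length(unknown))
        warning(sprintf("%d TF id(s) not present in the matrix; ignored",
                        length(unknown)))
    tfSel <- intersect(tfGenes, rownames(prof$profiles))

    cl <- stage("clustering", {
        tfProf <- prof$profiles[rownames(prof$profiles) %in% tfSel, ,
                                drop = FALSE]
        otProf <- prof$profiles[!rownames(prof$profiles) %in% tfSel, ,
                                drop = FALSE]
        if (nrow(tfProf) == 0L)
            clusterTwoPass(NULL, otProf, blockSize = config$blockSize,
                           hMax = config$hMax,
                           mergeDistance = config$mergeDistance,
                           linkage = config$linkage,
                           consolidateSingleBlock =
                               config$consolidateSingleBlock,
                           maxIter = config$maxIter, times = times)
        else
            clusterTwoPass(tfProf, otProf, blockSize = config$blockSize,
                           hMax = config$hMax,
                           mergeDistance = config$mergeDistance,
                           linkage = config$linkage,
                           consolidateSingleBlock =
                               config$consolidateSingleBlock,
                           maxIter = config$maxIter, times = times)
    })
    asn <- clusterAssignments(cl)
    .writeTSV(data.frame(gene_id = names(asn), cluster_id = unname(asn)),
              outDir, "clusters.tsv")
    cent <- clusterCentres(cl)
    colnames(cent) <- tlab
    .writeTSV(data.frame(cluster_id = seq_len(nrow(cent)), cent,
                         check.names = FALSE), outDir, "centres.tsv")
    sm <- clusterSummary(cl)
    colnames(sm$means) <- paste0("mean_", tlab)
    colnames(sm$sds) <- paste0("sd_", tlab)
    .writeTSV(data.frame(cluster_id = seq_len(nrow(cent)),
                         size = clusterSizes(cl), sm$means, sm$sds,
                         check.names = FALSE), outDir,
              "cluster_summary.tsv")

    osc <- stage("period-estimation", {
        classifyOscillatory(clusterSummary(cl)$means, times,
                            spar = config$sparPeriod,
                            gridSize = config$gridSize,
                            minTurningPoints = config$minTurningPoints,
                            periodBand = config$periodBand)
    })
    .writeTSV(data.frame(cluster_id = osc$clusterId,
                         n_turning_points = osc$nTurningPoints,
                         turning_point_times = osc$turningPoints,
                         period = osc$period,
                         oscillatory_flag = osc$oscillatory),
              outDir, "periods.tsv")

    rhythm <- stage("rhythm-screen", {
        jtkScreen(x[de$expressed, ], periods = config$periods,
                  pMethod = config$pMethod,
                  nullSamples = config$nullSamples,
                  qThreshold = config$qThreshold, seed = config$seed)
    })
    .writeTSV(data.frame(gene_id = rhythm$geneId, tau = rhythm$tau,
                         p = rhythm$p, q = rhythm$q,
                         best_period = rhythm$bestPeriod,
                         best_phase = rhythm$bestPhase,
                         rhythmic_flag = rhythm$rhythmic),
              outDir, "rhythmicity.tsv")

    qc <- stage("pca-qc", pcaTimeScores(x, nComponents = config$nComponents,
                                        spar = config$sparPeriod,
                                        gridSize = config$gridSize))
    pcadf <- data.frame(time = times, qc$scores, check.names = FALSE)
    .writeTSV(pcadf, outDir, "pca_scores.tsv")

    manifest <- list(
        package = "lrclock",
        version = as.character(utils::packageVersion("lrclock")),
        seed = config$seed,
        nGenes = nrow(x),
        nTimePoints = length(times),
        nReplicates = nReplicates(x),
        nExpressed = sum(de$expressed),
        nDE = sum(de$de),
        nRestricted = sum(de$restricted),
        nClustered = length(asn),
        nDegenerate = length(prof$degenerate),
        nSeedCentres = nrow(cl@initialCentres),
        nClusters = nrow(cent),
        nOscillatoryClusters = sum(osc$oscillatory),
        nRhythmic = sum(rhythm$rhythmic),
        pcPeriods = vapply(qc$periods, function(e)
            if (is.null(e)) NA_real_ else periodHours(e), numeric(1))
    )
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}
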