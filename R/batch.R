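#' One-stop quantification of reads against a locus
#'
#' Aligns reads to the locus, builds the position profile and editing
#' statistics, classifies window alleles, and derives the quantification
#' table, editing metrics and triage call.
#'
#' @param reads a `QualityScaledDNAStringSet` (already quality-filtered and
#'   demultiplexed).
#' @param locus an [AmpliconLocus-class].
#' @param scoring see [alignmentScoring()].
#' @param thresholds see [triageThresholds()].
#' @return list with `aligned`, `profile`, `stats`, `classes`, `counts`,
#'   `quantTable`, `metrics`, `triage`.
#' @examples
#' loc <- exampleLocus()
#' fq <- simulateEditedReads(loc, makeEditorModel("abe9_like"), n = 200,
#'                           seed = 5)
#' res <- quantifyAmplicon(fq, loc)
#' res$metrics
#' @export
quantifyAmplicon <- function(reads, locus, scoring = alignmentScoring(),
                             thresholds = triageThresholds()) {
    aln <- alignReads(reads, locus, scoring)
    classes <- classifyReads(aln, locus)
    counts <- tallyAlleles(classes)
    qt <- toQuantTable(counts)
    metrics <- if (qt[["Reads_aligned_all_amplicons"]] > 0)
        computeMetrics(qt)
    else c(specified_incl_bystanders_pct = NA_real_,
           specified_without_bystanders_pct = NA_real_,
           purity_pct = NA_real_, indels_pct = NA_real_)
    list(aligned = aln, profile = buildProfile(aln, locus),
         stats = editingStats(aln, locus), classes = classes,
         counts = counts, quantTable = qt, metrics = metrics,
         triage = founderTriage(counts, thresholds))
}

.summaryRow <- function(sampleId, locId, nInput, nPass, nAssigned, res) {
    cc <- classCountsVector(res$counts)
    qt <- res$quantTable
    data.frame(sample_id = sampleId, locus_id = locId, status = "ok",
               message = "", n_reads_input = nInput, n_pass_filter = nPass,
               n_assigned = nAssigned,
               total_aligned = cc[["totalAligned"]], wt = cc[["wt"]],
               desired_only = cc[["desiredOnly"]],
               desired_bystander = cc[["desiredBystander"]],
               bystander_only = cc[["bystanderOnly"]],
               indel = cc[["indel"]], short_reads = cc[["shortReads"]],
               Reads_aligned_all_amplicons = qt[["Reads_aligned_all_amplicons"]],
               Reads_aligned = qt[["Reads_aligned"]],
               Unmodified = qt[["Unmodified"]], Modified = qt[["Modified"]],
               Discarded = qt[["Discarded"]],
               specified_incl_bystanders_pct =
                   round(res$metrics[["specified_incl_bystanders_pct"]], 4L),
               specified_without_bystanders_pct =
                   round(res$metrics[["specified_without_bystanders_pct"]], 4L),
               purity_pct = round(res$metrics[["purity_pct"]], 4L),
               indels_pct = round(res$metrics[["indels_pct"]], 4L),
               cumulative_editing_pct = round(res$stats$cumulative, 4L),
               precision_metric = round(res$stats$precision, 6L),
               triage = res$triage$call,
               stringsAsFactors = FALSE)
}

.errorRow <- function(sampleId, locId, msg) {
    row <- data.frame(sample_id = sampleId, locus_id = locId,
                      status = "error", message = as.character(msg),
                      stringsAsFactors = FALSE)
    row
}

#' Run the batch pipeline over a sample sheet
#'
#' For every sample: read the FASTQ, apply the mean-quality filter,
#' demultiplex to the sample's loci, then quantify each locus
#' ([quantifyAmplicon()]) and write per-sample-per-locus TSVs (nucleotide
#' percentage summary, editing statistics, quantification/classification)
#' plus one consolidated `summary.tsv` sorted by sample and locus. Failures
#' are isolated per sample: one bad FASTQ yields an error row without
#' aborting the batch. Reruns with identical inputs produce byte-identical
#' outputs.
#'
#' @param sampleSheet data.frame with columns `sample_id`, `fastq`, and
#'   optionally `locus_ids` (semicolon-separated; defaults to all loci).
#' @param loci named list of [AmpliconLocus-class] objects, or a path for
#'   [readLocusConfig()].
#' @param outDir output directory (created if needed).
#' @param minQuality mean-quality filter threshold.
#' @param scoring,thresholds,minScoreFrac,margin stage parameters.
#' @return invisibly, a list with `summary` (data.frame) and `nErrors`.
#' @examples
#' \donttest{
#' loci <- exampleLoci()
#' fq <- tempfile(fileext = ".fastq")
#' simulateEditedReads(loci$demoA, makeEditorModel("abe9_like"), n = 50,
#'                     seed = 1, path = fq)
#' sheet <- data.frame(sample_id = "s1", fastq = fq, locus_ids = "demoA")
#' res <- runBatch(sheet, loci, tempfile("batch"))
#' res$summary$triage
#' }
#' @export
runBatch <- function(sampleSheet, loci, outDir, minQuality = 30,
                     scoring = alignmentScoring(),
                     thresholds = triageThresholds(),
                     minScoreFrac = 0.6, margin = 1) {
    if (is.character(loci)) loci <- readLocusConfig(loci)
    if (!all(c("sample_id", "fastq") %in% names(sampleSheet)))
        stop("malformed config: sampleSheet needs columns sample_id, fastq")
    if (!"locus_ids" %in% names(sampleSheet))
        sampleSheet$locus_ids <- paste(names(loci), collapse = ";")
    wanted <- unique(unlist(strsplit(sampleSheet$locus_ids, ";", fixed = TRUE)))
    wanted <- trimws(wanted[nzchar(wanted)])
    unknown <- setdiff(wanted, names(loci))
    if (length(unknown))
        stop("malformed config: unknown locus_id(s): ",
             paste(unknown, collapse = ", "))
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)

    # provenance header: the stage parameters this run used
    params <- data.frame(
        parameter = c("min_average_read_quality", "window_upstream_nt",
                      "window_downstream_nt", "triage_min_desired_only_pct",
                      "triage_max_unwanted_pct", "demux_min_score_frac",
                      "demux_margin", "align_match", "align_mismatch",
                      "align_gap_open", "align_gap_extend"),
        value = c(minQuality, loci[[1L]]@window@upstream,
                  loci[[1L]]@window@downstream, thresholds$minDesiredOnly,
                  thresholds$maxUnwanted, minScoreFrac, margin,
                  scoring$match, scoring$mismatch, scoring$gapOpen,
                  scoring$gapExtend))
    write.table(params, file.path(outDir, "run_parameters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    rows <- list()
    errRows <- list()
    for (i in seq_len(nrow(sampleSheet))) {
        sid <- sampleSheet$sample_id[i]
        locIds <- trimws(strsplit(sampleSheet$locus_ids[i], ";",
                                  fixed = TRUE)[[1L]])
        locIds <- locIds[nzchar(locIds)]
        res <- tryCatch({
            reads <- readFastq(sampleSheet$fastq[i])
            nInput <- length(reads)
            reads <- meanQualityFilter(reads, minQuality)
            nPass <- length(reads)
            myLoci <- loci[locIds]
            bins <- if (length(myLoci) > 1L)
                demultiplexReads(reads, myLoci, minScoreFrac, margin, scoring)
            else setNames(list(reads), locIds)
            for (lid in locIds) {
                r <- quantifyAmplicon(bins[[lid]], myLoci[[lid]], scoring,
                                      thresholds)
                stem <- file.path(outDir, paste0(sid, ".", lid))
                writeProfileTSV(r$profile,
                                paste0(stem, ".nucleotide_percentage_summary.tsv"))
                statsDf <- data.frame(
                    position = names(r$stats$aToG),
                    a_to_g_pct = round(unname(r$stats$aToG), 4L))
                write.table(statsDf, paste0(stem, ".editing_stats.tsv"),
                            sep = "\t", quote = FALSE, row.names = FALSE)
                row <- .summaryRow(sid, lid, nInput, nPass,
                                   length(bins[[lid]]), r)
                write.table(row, paste0(stem, ".quantification.tsv"),
                            sep = "\t", quote = FALSE, row.names = FALSE)
                rows[[length(rows) + 1L]] <- row
            }
            NULL
        }, error = function(e) conditionMessage(e))
        if (!is.null(res))
            errRows[[length(errRows) + 1L]] <-
                .errorRow(sid, paste(locIds, collapse = ";"), res)
    }
    summary <- do.call(rbind, rows)
    if (!is.null(summary))
        summary <- summary[order(summary$sample_id, summary$locus_id), ,
                           drop = FALSE]
    if (length(errRows)) {
        err <- do.call(rbind, errRows)
        pad <- setdiff(names(summary), names(err))
        for (p in pad) err[[p]] <- NA
        summary <- if (is.null(summary)) err else rbind(summary, err)
    }
    write.table(summary, file.path(outDir, "summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(list(summary = summary, nErrors = length(errRows)))
}
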