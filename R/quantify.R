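.SYMBOLS <- c("A", "C", "G", "T", "N", "-")

#' Build a per-position nucleotide profile
#'
#' Tallies the observed base at every reference position of the profiled
#' interval (by default the quantification window, spacer - upstream to
#' PAM + downstream) across all aligned reads, on the protospacer strand.
#' Deletions are tallied as `-`; insertions do not shift the reference frame
#' and are not part of the per-position counts.
#'
#' @param aln an [AlignedReads-class] object.
#' @param locus the [AmpliconLocus-class] the reads were aligned to.
#' @param refRange optional integer `c(start, end)` of 1-based reference
#'   coordinates to profile instead of the quantification window.
#' @return a [PositionProfile-class].
#' @examples
#' loc <- exampleLocus()
#' fq <- simulateEditedReads(loc, makeEditorModel("abe9_like"), n = 50,
#'                           seed = 3)
#' prof <- buildProfile(alignReads(fq, loc), loc)
#' prof
#' @export
buildProfile <- function(aln, locus, refRange = quantWindowRange(locus)) {
    coords <- seq.int(refRange[[1L]], refRange[[2L]])
    refChr <- as.character(referenceSeq(locus))
    counts <- matrix(0L, nrow = 6L, ncol = length(coords),
                     dimnames = list(.SYMBOLS, NULL))
    if (length(aln) > 0L) {
        for (k in seq_along(coords)) {
            ci <- coords[k]
            covered <- aln@start <= ci & aln@end >= ci
            if (!any(covered)) next
            b <- substr(aln@refCalls[covered], ci - aln@start[covered] + 1L,
                        ci - aln@start[covered] + 1L)
            tab <- table(factor(b, levels = .SYMBOLS))
            counts[, k] <- as.integer(tab)
        }
    }
    new("PositionProfile", locusId = locusId(locus),
        positions = refToProto(locus, coords), counts = counts,
        refBases = substring(refChr, coords, coords))
}

.atogNames <- function(pos) paste0("A", pos)
.atogPos <- function(x) as.integer(sub("^A", "", names(x)))

#' Per-position A-to-G editing frequencies
#'
#' For every reference adenine in the profiled interval (always the
#' protospacer; flanking adenines such as position A-2 when
#' `includeFlanks = TRUE`), the percentage of covering reads carrying G.
#' Positions with zero depth are reported as `NA`, never 0, so absence of
#' coverage is not mistaken for absence of editing.
#'
#' @param profile a [PositionProfile-class].
#' @param includeFlanks include adenines outside protospacer positions 1..20.
#' @return named numeric vector of percentages; names are `"A<position>"`
#'   labels (e.g. `"A5"`, `"A-2"`).
#' @examples
#' loc <- exampleLocus()
#' fq <- simulateEditedReads(loc, makeEditorModel("abe9_like"), n = 200,
#'                           seed = 3)
#' aToGFrequencies(buildProfile(alignReads(fq, loc), loc))
#' @export
aToGFrequencies <- function(profile, includeFlanks = TRUE) {
    isA <- profile@refBases == "A"
    if (!includeFlanks)
        isA <- isA & profile@positions >= 1L & profile@positions <= 20L
    pos <- profile@positions[isA]
    depth <- colSums(profile@counts)[isA]
    g <- profile@counts["G", isA]
    pct <- ifelse(depth > 0L, 100 * g / depth, NA_real_)
    names(pct) <- .atogNames(pos)
    pct
}

# window-overlapping indel flag per read (closed-interval overlap;
# insertions at either window boundary count)
.windowIndelFlags <- function(aln, locus) {
    wr <- quantWindowRange(locus)
    ws <- wr[[1L]]; we <- wr[[2L]]
    n <- length(aln)
    flags <- logical(n)
    for (i in seq_len(n)) {
        lo <- max(ws, aln@start[i]); hi <- min(we, aln@end[i])
        if (lo <= hi &&
            grepl("-", substr(aln@refCalls[i], lo - aln@start[i] + 1L,
                              hi - aln@start[i] + 1L), fixed = TRUE)) {
            flags[i] <- TRUE
            next
        }
        ins <- aln@insertions[[i]]
        if (nrow(ins) && any(ins$pos >= ws - 1L & ins$pos <= we))
            flags[i] <- TRUE
    }
    flags
}

#' Indel frequency within the quantification window
#'
#' Percentage of aligned reads carrying at least one insertion or deletion
#' overlapping the quantification window (closed-interval overlap; an
#' insertion at either window boundary counts as overlapping). Indels
#' strictly outside the window are ignored.
#'
#' @inheritParams buildProfile
#' @return percentage in \[0, 100\] (`NA` for an empty read set).
#' @export
indelFrequency <- function(aln, locus) {
    if (length(aln) == 0L) return(NA_real_)
    100 * mean(.windowIndelFlags(aln, locus))
}

#' Cumulative editing across the spacer
#'
#' Arithmetic sum of per-adenine A-to-G percentages over protospacer
#' positions 1..20 only (flank positions are dropped). The sum may exceed
#' 100 when several adenines are edited.
#'
#' @param aToG named percentage vector from [aToGFrequencies()].
#' @return the cumulative percentage.
#' @examples
#' cumulativeEditing(c(A2 = 10, A5 = 50, A12 = 20))  # 80
#' @export
cumulativeEditing <- function(aToG) {
    pos <- .atogPos(aToG)
    sum(aToG[pos >= 1L & pos <= 20L], na.rm = TRUE)
}

#' Positional precision metric
#'
#' Second-highest adenine editing frequency divided by the highest; lower
#' values mean more positionally concentrated editing. Returns 0 when only
#' one adenine is present or the highest frequency is 0.
#'
#' @param aToG named percentage vector from [aToGFrequencies()].
#' @return a fraction in \[0, 1\].
#' @examples
#' precisionMetric(c(A5 = 40, A6 = 20, A2 = 5))  # 0.5
#' @export
precisionMetric <- function(aToG) {
    if (length(aToG) == 0L) stop("input error: empty frequency map")
    v <- sort(aToG[!is.na(aToG)], decreasing = TRUE)
    if (length(v) < 2L || v[1L] == 0) return(0)
    unname(v[2L] / v[1L])
}

#' Percent reduction between two activities
#'
#' `100 * (reference - value) / reference`: the relative drop of an editing
#' activity (e.g. a mean per-position frequency) against a reference
#' activity, in percent.
#'
#' @param reference the baseline activity.
#' @param value the compared activity.
#' @return the percent reduction (negative for an increase).
#' @examples
#' percentReduction(43.6, 34.5)  # ~20.9, i.e. 21% after rounding
#' @export
percentReduction <- function(reference, value) {
    stopifnot(reference != 0)
    100 * (reference - value) / reference
}

#' Position-level editing statistics for one locus
#'
#' Convenience wrapper computing the per-adenine A-to-G map, the
#' window-overlap indel percentage, cumulative spacer editing, and the
#' precision metric from one set of aligned reads.
#'
#' @inheritParams buildProfile
#' @param includeFlanks passed to [aToGFrequencies()].
#' @return list with elements `aToG`, `indelPct`, `cumulative`, `precision`.
#' @export
editingStats <- function(aln, locus, includeFlanks = TRUE) {
    prof <- buildProfile(aln, locus)
    atog <- aToGFrequencies(prof, includeFlanks = includeFlanks)
    list(aToG = atog,
         indelPct = indelFrequency(aln, locus),
         cumulative = cumulativeEditing(atog),
         precision = precisionMetric(atog))
}

#' Write a nucleotide percentage summary TSV
#'
#' Rows are base symbols (A, C, G, T, N, `-`) plus a depth row; columns are
#' protospacer-frame position labels. Values are percentages of depth.
#'
#' @param profile a [PositionProfile-class].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeProfileTSV <- function(profile, path) {
    depth <- colSums(profile@counts)
    pct <- sweep(profile@counts, 2L, pmax(depth, 1L), "/") * 100
    pct[, depth == 0L] <- NA_real_
    out <- rbind(as.data.frame(round(pct, 4L)),
                 depth = as.integer(depth))
    colnames(out) <- sprintf("%s%d", profile@refBases, profile@positions)
    write.table(cbind(symbol = rownames(out), out), path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(path)
}
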