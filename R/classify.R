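.ALLELE_CLASSES <- c("wt", "desired_only", "desired_bystander",
                     "bystander_only", "indel", "short_read")

#' Classify reads into five window allele classes
#'
#' Each read's allele within the quantification window is classified, in
#' order: reads whose aligned span does not cover the full window are
#' `short_read`; reads with an insertion or deletion overlapping the window
#' are `indel`; reads with no substitution inside the window are `wt`; reads
#' whose in-window substitution set equals the desired-edit set are
#' `desired_only`; reads whose substitution set strictly contains it are
#' `desired_bystander`; everything else (at least one substitution, desired
#' set incomplete — including a partial desired set) is `bystander_only`.
#' N calls never count as substitutions, and substitutions outside the
#' window are ignored: the window defines the allele.
#'
#' @param aln an [AlignedReads-class] aligned to `locus`.
#' @param locus the [AmpliconLocus-class].
#' @return factor of length `length(aln)` with levels `wt`, `desired_only`,
#'   `desired_bystander`, `bystander_only`, `indel`, `short_read`.
#' @examples
#' loc <- exampleLocus()
#' fq <- simulateEditedReads(loc, makeEditorModel("abe9_like"), n = 100,
#'                           seed = 11)
#' table(classifyReads(alignReads(fq, loc), loc))
#' @export
classifyReads <- function(aln, locus) {
    if (!is.na(aln@locusId) && aln@locusId != locusId(locus))
        stop("input error: reads were aligned to locus '", aln@locusId,
             "', not '", locusId(locus), "'")
    n <- length(aln)
    out <- factor(rep(NA_character_, n), levels = .ALLELE_CLASSES)
    if (n == 0L) return(out)
    wr <- quantWindowRange(locus)
    ws <- wr[[1L]]; we <- wr[[2L]]
    wlen <- we - ws + 1L
    covers <- aln@start <= ws & aln@end >= we
    out[!covers] <- "short_read"
    hasIndel <- .windowIndelFlags(aln, locus)
    out[covers & hasIndel] <- "indel"
    todo <- which(covers & !hasIndel)
    if (length(todo)) {
        win <- substr(aln@refCalls[todo], ws - aln@start[todo] + 1L,
                      we - aln@start[todo] + 1L)
        mat <- matrix(unlist(strsplit(win, "", fixed = TRUE), use.names = FALSE),
                      nrow = length(todo), byrow = TRUE)
        refWin <- strsplit(substr(as.character(referenceSeq(locus)), ws, we),
                           "", fixed = TRUE)[[1L]]
        isSub <- sweep(mat, 2L, refWin, "!=") & mat != "N"
        nSub <- rowSums(isSub)
        de <- desiredEdits(locus)
        k <- nrow(de)
        if (k > 0L) {
            di <- protoToRef(locus, de$pos) - ws + 1L
            stopifnot(all(di >= 1L & di <= wlen))
            hit <- vapply(seq_len(k), function(j) mat[, di[j]] == de$alt[j],
                          logical(length(todo)))
            desiredOK <- rowSums(matrix(hit, nrow = length(todo))) == k
        } else {
            desiredOK <- rep(FALSE, length(todo))   # empty desired set: no
        }                                           # read is "desired"
        cls <- rep("bystander_only", length(todo))
        cls[nSub == 0L] <- "wt"
        cls[desiredOK & nSub == k & k > 0L] <- "desired_only"
        cls[desiredOK & nSub > k & k > 0L] <- "desired_bystander"
        out[todo] <- cls
    }
    out
}

#' Tally allele classes
#'
#' Classifies (if needed) and counts reads per allele class; the six counts
#' always sum to the number of aligned reads.
#'
#' @param x an [AlignedReads-class] or a factor from [classifyReads()].
#' @param locus the [AmpliconLocus-class] (needed when `x` is `AlignedReads`).
#' @return an [AlleleClassCounts-class].
#' @export
tallyAlleles <- function(x, locus = NULL) {
    cls <- if (is.factor(x)) x else {
        if (is.null(locus)) stop("'locus' is required to classify reads")
        classifyReads(x, locus)
    }
    tab <- table(factor(cls, levels = .ALLELE_CLASSES))
    alleleClassCounts(wt = tab[["wt"]], desiredOnly = tab[["desired_only"]],
                      desiredBystander = tab[["desired_bystander"]],
                      bystanderOnly = tab[["bystander_only"]],
                      indel = tab[["indel"]], shortReads = tab[["short_read"]])
}

#' Map allele-class counts onto quantification-table columns
#'
#' Produces the read-count columns used by the editing-metric formulas:
#' `Reads_aligned_all_amplicons` (all window-covering aligned reads),
#' `Reads_aligned` (reads carrying the full desired-edit set, indel-free),
#' `Unmodified` (desired-only), `Modified` (desired + bystander) and
#' `Discarded` (window-overlapping indel reads).
#'
#' @param counts an [AlleleClassCounts-class].
#' @return named integer vector with the five columns above.
#' @examples
#' toQuantTable(alleleClassCounts(wt = 530, desiredOnly = 300,
#'                                desiredBystander = 100, bystanderOnly = 50,
#'                                indel = 20))
#' @export
toQuantTable <- function(counts) {
    stopifnot(is(counts, "AlleleClassCounts"))
    c(Reads_aligned_all_amplicons = counts@totalAligned - counts@shortReads,
      Reads_aligned = counts@desiredOnly + counts@desiredBystander,
      Unmodified = counts@desiredOnly,
      Modified = counts@desiredBystander,
      Discarded = counts@indel)
}

#' Editing metrics from a quantification table
#'
#' Computes, as percentages of `Reads_aligned_all_amplicons`: the specified
#' mutation including bystanders (`Reads_aligned / total x 100`), the
#' specified mutation without bystanders (`Unmodified / total x 100`), the
#' indel rate (`Discarded / total x 100`); and product purity
#' (`Unmodified / Reads_aligned x 100`), the fraction of desired-carrying
#' reads free of bystander edits. Purity is `NA` (never 0 or 100) when no
#' read carries the desired edit set.
#'
#' @param qt named vector from [toQuantTable()].
#' @return named numeric: `specified_incl_bystanders_pct`,
#'   `specified_without_bystanders_pct`, `purity_pct`, `indels_pct`.
#' @examples
#' qt <- c(Reads_aligned_all_amplicons = 1000, Reads_aligned = 400,
#'         Unmodified = 300, Modified = 100, Discarded = 20)
#' computeMetrics(qt)  # 40, 30, 75, 2
#' @export
computeMetrics <- function(qt) {
    need <- c("Reads_aligned_all_amplicons", "Reads_aligned", "Unmodified",
              "Modified", "Discarded")
    stopifnot(all(need %in% names(qt)))
    total <- qt[["Reads_aligned_all_amplicons"]]
    if (total <= 0) stop("input error: Reads_aligned_all_amplicons must be > 0")
    ra <- qt[["Reads_aligned"]]
    c(specified_incl_bystanders_pct = 100 * ra / total,
      specified_without_bystanders_pct = 100 * qt[["Unmodified"]] / total,
      purity_pct = if (ra > 0) 100 * qt[["Unmodified"]] / ra else NA_real_,
      indels_pct = 100 * qt[["Discarded"]] / total)
}

#' Founder triage thresholds
#'
#' Defaults call a founder high-confidence when desired-only reads are at
#' least 20% and unwanted outcomes (desired + bystander, bystander-only and
#' indel reads) are at most 2.5% of the window-covering aligned reads. The
#' unwanted comparator is inclusive (`<=`) by default; set
#' `strictUnwanted = TRUE` for a strict `<`.
#'
#' @param minDesiredOnly minimum desired-only percentage.
#' @param maxUnwanted maximum unwanted-outcome percentage.
#' @param strictUnwanted use strict `<` for the unwanted comparison.
#' @return a list of thresholds.
#' @export
triageThresholds <- function(minDesiredOnly = 20, maxUnwanted = 2.5,
                             strictUnwanted = FALSE) {
    stopifnot(minDesiredOnly >= 0, maxUnwanted >= 0)
    list(minDesiredOnly = minDesiredOnly, maxUnwanted = maxUnwanted,
         strictUnwanted = strictUnwanted)
}

#' Founder triage call
#'
#' Calls a founder `high_confidence` when the desired-only percentage
#' reaches `minDesiredOnly` and the unwanted percentage (desired+bystander +
#' bystander-only + indel reads, over window-covering aligned reads) does not
#' exceed `maxUnwanted`.
#'
#' @param counts an [AlleleClassCounts-class].
#' @param thresholds see [triageThresholds()].
#' @return list with `call` (`"high_confidence"` or `"not_high_confidence"`),
#'   `desiredOnlyPct` and `unwantedPct`.
#' @examples
#' founderTriage(alleleClassCounts(wt = 700, desiredOnly = 290, indel = 10))
#' @export
founderTriage <- function(counts, thresholds = triageThresholds()) {
    stopifnot(is(counts, "AlleleClassCounts"))
    total <- counts@totalAligned - counts@shortReads
    if (total <= 0)
        return(list(call = "not_high_confidence", desiredOnlyPct = NA_real_,
                    unwantedPct = NA_real_))
    dp <- 100 * counts@desiredOnly / total
    up <- 100 * (counts@desiredBystander + counts@bystanderOnly +
                 counts@indel) / total
    okUnwanted <- if (thresholds$strictUnwanted) up < thresholds$maxUnwanted
                  else up <= thresholds$maxUnwanted
    list(call = if (dp >= thresholds$minDesiredOnly && okUnwanted)
             "high_confidence" else "not_high_confidence",
         desiredOnlyPct = dp, unwantedPct = up)
}
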