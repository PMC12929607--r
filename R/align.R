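#' @importFrom Biostrings pairwiseAlignment pattern subject score
NULL

#' Alignment scoring parameters
#'
#' Affine-gap scoring for semi-global read-to-amplicon alignment. A gap of
#' length L scores `gapOpen + L * gapExtend`. The defaults (+2/-4/-10/-1)
#' make a single substitution preferable to two short gaps, the usual choice
#' for amplicon resequencing. N scores 0 against every base.
#'
#' @param match,mismatch,gapOpen,gapExtend numeric scores (penalties
#'   negative).
#' @return a list of scoring parameters with the substitution matrix attached.
#' @examples
#' alignmentScoring()$match
#' @export
alignmentScoring <- function(match = 2, mismatch = -4, gapOpen = -10,
                             gapExtend = -1) {
    stopifnot(match > 0, mismatch <= 0, gapOpen <= 0, gapExtend <= 0)
    bases <- c("A", "C", "G", "T", "N")
    mat <- matrix(mismatch, 5, 5, dimnames = list(bases, bases))
    diag(mat) <- match
    mat["N", ] <- 0
    mat[, "N"] <- 0
    list(match = match, mismatch = mismatch, gapOpen = gapOpen,
         gapExtend = gapExtend, matrix = mat)
}

.checkDNA <- function(x) {
    bad <- grepl("[^ACGTN]", x)
    if (any(bad))
        stop("input error: sequence contains non-DNA characters (other than N)")
    invisible(x)
}

# Core semi-global alignment of character sequences against one reference:
# global in the read, free end gaps in the reference. Returns per-read span,
# reference-frame calls and insertion records.
.alignBatch <- function(seqs, refChr, scoring) {
    pa <- pairwiseAlignment(DNAStringSet(seqs), DNAString(refChr),
                            type = "global-local",
                            substitutionMatrix = scoring$matrix,
                            gapOpening = -scoring$gapOpen,
                            gapExtension = -scoring$gapExtend)
    patStr <- as.character(pattern(pa))
    subStr <- as.character(subject(pa))
    starts <- Biostrings::start(subject(pa))
    n <- length(seqs)
    refCalls <- character(n)
    insertions <- vector("list", n)
    for (i in seq_len(n)) {
        p <- strsplit(patStr[i], "", fixed = TRUE)[[1L]]
        s <- strsplit(subStr[i], "", fixed = TRUE)[[1L]]
        insHere <- s == "-"
        if (any(insHere)) {
            # reference coordinate after which each insertion run occurs
            refIdx <- starts[i] - 1L + cumsum(!insHere)
            runs <- rle(insHere)
            endsAt <- cumsum(runs$lengths)
            insRuns <- which(runs$values)
            pos <- integer(0); insSeq <- character(0)
            for (r in insRuns) {
                lo <- endsAt[r] - runs$lengths[r] + 1L
                pos <- c(pos, if (lo == 1L) starts[i] - 1L else refIdx[lo - 1L])
                insSeq <- c(insSeq,
                            paste0(p[lo:endsAt[r]], collapse = ""))
            }
            insertions[[i]] <- data.frame(pos = pos, seq = insSeq,
                                          stringsAsFactors = FALSE)
            refCalls[i] <- paste0(p[!insHere], collapse = "")
        } else {
            insertions[[i]] <- data.frame(pos = integer(), seq = character(),
                                          stringsAsFactors = FALSE)
            refCalls[i] <- patStr[i]
        }
    }
    list(score = score(pa), start = starts,
         end = starts + nchar(refCalls) - 1L,
         refCalls = refCalls, insertions = insertions)
}

# Best score per sequence against a locus reference, both orientations.
bestAlignmentScores <- function(seqs, locus, scoring = alignmentScoring()) {
    refChr <- as.character(referenceSeq(locus))
    fwd <- pairwiseAlignment(DNAStringSet(seqs), DNAString(refChr),
                             type = "global-local",
                             substitutionMatrix = scoring$matrix,
                             gapOpening = -scoring$gapOpen,
                             gapExtension = -scoring$gapExtend,
                             scoreOnly = TRUE)
    rc <- as.character(reverseComplement(DNAStringSet(seqs)))
    rev <- pairwiseAlignment(DNAStringSet(rc), DNAString(refChr),
                             type = "global-local",
                             substitutionMatrix = scoring$matrix,
                             gapOpening = -scoring$gapOpen,
                             gapExtension = -scoring$gapExtend,
                             scoreOnly = TRUE)
    pmax(fwd, rev)
}

#' Semi-global alignment of a read to a reference
#'
#' Aligns the read globally against the reference with free end gaps in the
#' reference (the read maps to the best-scoring reference interval) under
#' affine gap penalties. The optimal alignment is deterministic; ties are
#' resolved by the aligner's fixed internal preference so outputs are
#' reproducible.
#'
#' @param read,reference character or `DNAString` sequences (A/C/G/T/N).
#' @param scoring see [alignmentScoring()].
#' @return an [AlignedReads-class] object of length 1 (orientation
#'   `"forward"`).
#' @examples
#' ref <- as.character(referenceSeq(exampleLocus()))
#' aln <- semiglobalAlign(substr(ref, 11, 60), ref)
#' alignmentScore(aln)
#' @export
semiglobalAlign <- function(read, reference, scoring = alignmentScoring()) {
    read <- toupper(as.character(read))
    reference <- toupper(as.character(reference))
    stopifnot(nzchar(read), nzchar(reference))
    .checkDNA(c(read, reference))
    b <- .alignBatch(read, reference, scoring)
    new("AlignedReads", locusId = NA_character_, readId = "read1",
        orientation = "forward", start = b$start, end = b$end,
        refCalls = b$refCalls, insertions = b$insertions, score = b$score)
}

#' Orient and align reads to an amplicon locus
#'
#' Every read and its reverse complement are aligned to the locus reference
#' (which is stored on the protospacer strand); the higher-scoring
#' orientation is kept, with ties going to forward. Identical read sequences
#' are aligned once and the result reused.
#'
#' @param reads a `QualityScaledDNAStringSet`, `DNAStringSet`, or character
#'   vector.
#' @param locus an [AmpliconLocus-class].
#' @param scoring see [alignmentScoring()].
#' @return an [AlignedReads-class] object, one entry per input read.
#' @examples
#' loc <- exampleLocus()
#' fq <- simulateEditedReads(loc, makeEditorModel("abe9_like"), n = 10,
#'                           seed = 7)
#' aln <- alignReads(fq, loc)
#' table(orientation(aln))
#' @export
alignReads <- function(reads, locus, scoring = alignmentScoring()) {
    seqs <- toupper(as.character(reads))
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("read%d", seq_along(seqs))
    .checkDNA(seqs)
    if (any(!nzchar(seqs))) stop("input error: empty read")
    refChr <- as.character(referenceSeq(locus))
    uniq <- unique(seqs)
    map <- match(seqs, uniq)
    fwd <- .alignBatch(uniq, refChr, scoring)
    rcu <- as.character(reverseComplement(DNAStringSet(uniq)))
    rev <- .alignBatch(rcu, refChr, scoring)
    useRev <- rev$score > fwd$score           # tie -> forward
    pick <- function(f, r) ifelse(useRev, r, f)
    uStart <- pick(fwd$start, rev$start)
    uEnd <- pick(fwd$end, rev$end)
    uCalls <- ifelse(useRev, rev$refCalls, fwd$refCalls)
    uScore <- pick(fwd$score, rev$score)
    uIns <- fwd$insertions
    uIns[useRev] <- rev$insertions[useRev]
    new("AlignedReads", locusId = locusId(locus), readId = ids,
        orientation = c("forward", "reverse")[1L + useRev[map]],
        start = as.integer(uStart[map]), end = as.integer(uEnd[map]),
        refCalls = uCalls[map], insertions = uIns[map],
        score = uScore[map])
}

#' @param read a single read (character or `DNAString`).
#' @rdname alignReads
#' @export
orientAndAlign <- function(read, locus, scoring = alignmentScoring()) {
    alignReads(as.character(read), locus, scoring)
}
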