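#' @importFrom Biostrings GENETIC_CODE
NULL

#' PAM class of a 3-nt protospacer-adjacent motif
#'
#' `NGG` when bases 2-3 are `GG` (canonical SpCas9); otherwise `NRN` when the
#' middle base is a purine (A/G) or `NYN` when it is a pyrimidine (C/T).
#' PAM-relaxed nickases target NRN sites efficiently and NYN sites to a
#' lesser degree.
#'
#' @param pam 3-nt character string, no N.
#' @return `"NGG"`, `"NRN"` or `"NYN"`.
#' @examples
#' classifyPam("AGG")  # NGG
#' classifyPam("TAT")  # NRN
#' classifyPam("GCA")  # NYN
#' @export
classifyPam <- function(pam) {
    pam <- toupper(as.character(pam))
    if (nchar(pam) != 3L || grepl("[^ACGT]", pam))
        stop("input error: PAM must be 3 bases of A/C/G/T")
    if (substr(pam, 2L, 3L) == "GG") return("NGG")
    if (substr(pam, 2L, 2L) %in% c("A", "G")) "NRN" else "NYN"
}

#' Candidate sgRNA spacer
#'
#' @slot spacer 20-nt spacer sequence (protospacer strand).
#' @slot strand `"sense"` or `"antisense"` relative to the coding sequence.
#' @slot pam PAM sequence 3' of the spacer.
#' @slot pamClass `"NGG"`, `"NRN"` or `"NYN"`.
#' @slot start0 0-based offset of the spacer on the protospacer-strand
#'   context.
#' @slot targetPositions protospacer positions of the required adenines.
#' @slot windowAdenines all adenine protospacer positions inside the design
#'   window.
#' @slot consequences data.frame of codon consequences for the target edits.
#' @export
setClass("SpacerCandidate",
    representation(spacer = "character", strand = "character",
                   pam = "character", pamClass = "character",
                   start0 = "integer", targetPositions = "integer",
                   windowAdenines = "integer", consequences = "data.frame"))

setMethod("show", "SpacerCandidate", function(object) {
    cat(sprintf("SpacerCandidate %s | PAM %s (%s) | %s strand | targets A%s | window adenines %s\n",
                object@spacer, object@pam, object@pamClass, object@strand,
                paste(object@targetPositions, collapse = ",A"),
                paste(object@windowAdenines, collapse = ",")))
})

.translateCodon <- function(codon) {
    unname(GENETIC_CODE[[toupper(codon)]])
}

.effect <- function(aaBefore, aaAfter) {
    if (aaBefore == aaAfter) "silent"
    else if (aaAfter == "*") "nonsense"
    else if (aaBefore == "*") "stop_lost"
    else "missense"
}

# revcomp for plain character (no Biostrings round trip for tiny strings)
.rc <- function(x) {
    chartr("ACGTN", "TGCAN",
           vapply(x, function(s) paste(rev(strsplit(s, "")[[1L]]),
                                       collapse = ""), ""))
}

#' Enumerate sgRNA spacers for a desired amino-acid change
#'
#' Searches both strands of a coding-sequence context for 20-nt spacer frames
#' that place every adenine required for the target amino-acid change within
#' the design window (protospacer positions `window[1]..window[2]`, default
#' 3..11). The change must be reachable by A-to-G edits on one strand (a
#' T-to-C change on the coding strand is an A-to-G edit on the antisense
#' protospacer); otherwise a design error is raised. Candidates are sorted by
#' proximity of the target adenines to the peak editing positions 5-6, then
#' by fewest window adenines (fewer bystander opportunities).
#'
#' @param context coding-strand DNA context containing the target codon.
#' @param targetCodon 1-based codon index within the reading frame.
#' @param aaTo single-letter target amino acid.
#' @param cdsFrame 1-based position in `context` where the reading frame
#'   starts.
#' @param window integer `c(start, end)` design window in protospacer
#'   positions.
#' @param pamLen PAM length.
#' @return list of [SpacerCandidate-class] objects (possibly empty when the
#'   change is reachable but no frame fits the context).
#' @examples
#' ctx <- paste0("GATTTCCAGGCTGCTCACCTGGAT", "AAG",
#'               "GTCATCGACTCTGCTGAGAAGCTG")
#' cands <- enumerateSpacers(ctx, targetCodon = 9, aaTo = "E", cdsFrame = 1)
#' cands[[1]]
#' @export
enumerateSpacers <- function(context, targetCodon, aaTo, cdsFrame = 1L,
                             window = c(3L, 11L), pamLen = 3L) {
    context <- toupper(as.character(context))
    .checkDNA(context)
    cdsFrame <- as.integer(cdsFrame)
    window <- as.integer(window)
    pamLen <- as.integer(pamLen)
    L <- nchar(context)
    cstart <- cdsFrame + 3L * (as.integer(targetCodon) - 1L)
    if (cstart < 1L || cstart + 2L > L)
        stop("input error: target codon outside the context")
    codon <- substr(context, cstart, cstart + 2L)
    aaFrom <- .translateCodon(codon)
    aaTo <- toupper(aaTo)
    codonChars <- strsplit(codon, "")[[1L]]

    # per strand: codon positions editable by A-to-G on that strand
    editable <- list(sense = which(codonChars == "A"),
                     antisense = which(codonChars == "T"))
    subsetsFor <- function(strand) {
        cand <- editable[[strand]]
        res <- list()
        if (length(cand) == 0L) return(res)
        for (msk in seq_len(2L^length(cand) - 1L)) {
            sel <- cand[bitwAnd(msk, 2L^(seq_along(cand) - 1L)) > 0L]
            edited <- codonChars
            edited[sel] <- if (strand == "sense") "G" else "C"
            if (.translateCodon(paste(edited, collapse = "")) == aaTo)
                res[[length(res) + 1L]] <- sel
        }
        # keep only minimal edit sets: never demand an extra edit whose
        # omission already yields the target amino acid
        if (length(res) > 1L) {
            minimal <- vapply(seq_along(res), function(i)
                !any(vapply(seq_along(res), function(j)
                    j != i && all(res[[j]] %in% res[[i]]) &&
                        length(res[[j]]) < length(res[[i]]), TRUE)), TRUE)
            res <- res[minimal]
        }
        res
    }
    subsets <- list(sense = subsetsFor("sense"),
                    antisense = subsetsFor("antisense"))
    if (length(subsets$sense) + length(subsets$antisense) == 0L)
        stop(sprintf(
            "design error: %s (%s) -> %s is not reachable by A-to-G (or T-to-C) editing",
            aaFrom, codon, aaTo))

    out <- list()
    for (strand in c("sense", "antisense")) {
        S <- if (strand == "sense") context else .rc(context)
        for (sel in subsets[[strand]]) {
            ctx0 <- cstart - 1L + (sel - 1L)          # 0-based, sense coords
            p0 <- if (strand == "sense") ctx0 else L - 1L - ctx0
            stLo <- max(0L, max(p0) - window[2L] + 1L)
            stHi <- min(L - 20L - pamLen, min(p0) - window[1L] + 1L)
            if (stLo > stHi) next
            for (st in stLo:stHi) {
                spacer <- substr(S, st + 1L, st + 20L)
                pam <- substr(S, st + 21L, st + 20L + pamLen)
                if (grepl("N", paste0(spacer, pam), fixed = TRUE)) next
                targetPos <- as.integer(sort(p0 - st + 1L))
                spacerChars <- strsplit(spacer, "")[[1L]]
                winPos <- window[1L]:window[2L]
                winA <- winPos[spacerChars[winPos] == "A"]
                cand <- new("SpacerCandidate", spacer = spacer,
                            strand = strand, pam = pam,
                            pamClass = classifyPam(pam),
                            start0 = st, targetPositions = targetPos,
                            windowAdenines = as.integer(winA),
                            consequences = data.frame())
                cand@consequences <- annotateConsequences(
                    cand, targetPos, context, cdsFrame)
                out[[length(out) + 1L]] <- cand
            }
        }
    }
    # dedupe identical placements arising from different subsets
    key <- vapply(out, function(x)
        paste(x@strand, x@start0,
              paste(x@targetPositions, collapse = ","), sep = "|"), "")
    out <- out[!duplicated(key)]
    dist56 <- vapply(out, function(x)
        min(pmin(abs(x@targetPositions - 5L), abs(x@targetPositions - 6L))), 0L)
    nWinA <- vapply(out, function(x) length(x@windowAdenines), 0L)
    strandOrd <- vapply(out, function(x) x@strand, "")
    st0 <- vapply(out, function(x) x@start0, 0L)
    out[order(dist56, nWinA, strandOrd, st0)]
}

#' Codon consequences of editing chosen adenines
#'
#' Applies A-to-G conversions at the given protospacer positions of a spacer
#' candidate (T-to-C on the coding strand for antisense candidates),
#' translates every affected codon before and after with the standard genetic
#' code, and reports the effect. Adenines edited in the same codon are
#' handled jointly. An empty `editedPositions` returns a zero-row frame.
#'
#' @param candidate a [SpacerCandidate-class].
#' @param editedPositions protospacer positions (must hold adenines on the
#'   protospacer strand).
#' @param context the coding-strand context the candidate was designed on.
#' @param cdsFrame 1-based start of the reading frame in `context`.
#' @return data.frame with columns `protoPositions`, `codonIndex`,
#'   `codonBefore`, `codonAfter`, `aaBefore`, `aaAfter`, `effect`.
#' @examples
#' ctx <- paste0("GATTTCCAGGCTGCTCACCTGGAT", "AAG",
#'               "GTCATCGACTCTGCTGAGAAGCTG")
#' cand <- enumerateSpacers(ctx, 9, "E")[[1]]
#' annotateConsequences(cand, cand@targetPositions, ctx, 1)
#' @export
annotateConsequences <- function(candidate, editedPositions, context,
                                 cdsFrame = 1L) {
    empty <- data.frame(protoPositions = character(), codonIndex = integer(),
                        codonBefore = character(), codonAfter = character(),
                        aaBefore = character(), aaAfter = character(),
                        effect = character(), stringsAsFactors = FALSE)
    if (length(editedPositions) == 0L) return(empty)
    context <- toupper(as.character(context))
    L <- nchar(context)
    editedPositions <- as.integer(editedPositions)
    S <- if (candidate@strand == "sense") context else .rc(context)
    s0 <- candidate@start0 + editedPositions - 1L     # on protospacer strand
    if (any(substring(S, s0 + 1L, s0 + 1L) != "A"))
        stop("input error: edited position is not an adenine on the protospacer strand")
    ctx0 <- if (candidate@strand == "sense") s0 else L - 1L - s0
    edited <- strsplit(context, "")[[1L]]
    edited[ctx0 + 1L] <- if (candidate@strand == "sense") "G" else "C"
    before <- strsplit(context, "")[[1L]]
    codonIdx <- (ctx0 + 1L - cdsFrame) %/% 3L
    inFrame <- ctx0 + 1L >= cdsFrame &
        (cdsFrame + 3L * codonIdx + 2L) <= L
    rows <- empty
    for (k in sort(unique(codonIdx[inFrame]))) {
        cs <- cdsFrame + 3L * k
        cb <- paste(before[cs:(cs + 2L)], collapse = "")
        ca <- paste(edited[cs:(cs + 2L)], collapse = "")
        if (cb == ca) next
        aaB <- .translateCodon(cb); aaA <- .translateCodon(ca)
        rows <- rbind(rows, data.frame(
            protoPositions = paste(editedPositions[codonIdx == k & inFrame],
                                   collapse = ","),
            codonIndex = k + 1L, codonBefore = cb, codonAfter = ca,
            aaBefore = aaB, aaAfter = aaA, effect = .effect(aaB, aaA),
            stringsAsFactors = FALSE))
    }
    rows
}

#' Annotate an off-target site against the on-target spacer
#'
#' Positional comparison of the 20-nt spacer with a candidate off-target
#' protospacer: mismatch count and positions, a display string with
#' mismatched site bases in lowercase, and the site's PAM class.
#'
#' @param spacer on-target 20-nt spacer.
#' @param site off-target protospacer of the same length.
#' @param sitePam optional 3-nt site PAM for classification.
#' @return list with `nMismatch`, `positions`, `display`, `pamClass`.
#' @examples
#' annotateOfftarget("GACAAACATACAATGCTGCT", "GTCAAACATTACATGCTGCT")
#' @export
annotateOfftarget <- function(spacer, site, sitePam = NULL) {
    spacer <- toupper(as.character(spacer))
    site <- toupper(as.character(site))
    if (nchar(spacer) != nchar(site))
        stop("input error: spacer and site lengths differ")
    a <- strsplit(spacer, "")[[1L]]
    b <- strsplit(site, "")[[1L]]
    mm <- which(a != b)
    disp <- b
    disp[mm] <- tolower(disp[mm])
    list(nMismatch = length(mm), positions = mm,
         display = paste(disp, collapse = ""),
         pamClass = if (is.null(sitePam)) NA_character_
                    else classifyPam(sitePam))
}
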