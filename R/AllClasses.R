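#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#' @importClassesFrom Biostrings DNAString DNAStringSet
#'   QualityScaledDNAStringSet
NULL

#' Quantification window specification
#'
#' Defines the interval, in protospacer coordinates, within which read alleles
#' are classified and indels counted: from `upstream` nt 5' of the spacer to
#' `downstream` nt past the PAM. With the defaults (7, 3, 3) and a 20-nt
#' spacer the window spans 33 nt.
#'
#' @slot upstream integer, nt upstream of protospacer position 1.
#' @slot downstream integer, nt downstream of the PAM.
#' @slot pamLen integer, PAM length.
#' @export
setClass("WindowSpec",
    representation(upstream = "integer", downstream = "integer",
                   pamLen = "integer"),
    prototype(upstream = 7L, downstream = 3L, pamLen = 3L))

setValidity("WindowSpec", function(object) {
    if (length(object@upstream) != 1L || is.na(object@upstream) ||
        object@upstream < 0L)
        return("'upstream' must be a single non-negative integer")
    if (length(object@downstream) != 1L || is.na(object@downstream) ||
        object@downstream < 0L)
        return("'downstream' must be a single non-negative integer")
    if (length(object@pamLen) != 1L || is.na(object@pamLen) ||
        object@pamLen < 1L)
        return("'pamLen' must be a single positive integer")
    TRUE
})

#' @param upstream,downstream,pamLen window geometry in nucleotides.
#' @rdname WindowSpec-class
#' @return `windowSpec()` returns a `WindowSpec` object.
#' @examples
#' windowSpec()             # the default -7 .. PAM+3 window
#' windowSpec(upstream = 5)
#' @export
windowSpec <- function(upstream = 7L, downstream = 3L, pamLen = 3L) {
    new("WindowSpec", upstream = as.integer(upstream),
        downstream = as.integer(downstream), pamLen = as.integer(pamLen))
}

setMethod("show", "WindowSpec", function(object) {
    cat(sprintf("WindowSpec: spacer -%d nt .. spacer + PAM(%d nt) + %d nt\n",
                object@upstream, object@pamLen, object@downstream))
})

#' Reference amplicon with spacer placement
#'
#' An `AmpliconLocus` couples a reference amplicon to the placement of a
#' 20-nt protospacer and PAM on it, the set of desired A-to-G edits
#' (protospacer coordinates, 1..20, position 20 PAM-proximal), and the
#' quantification window. The reference is always stored on the protospacer
#' strand: if the spacer was given as matching the antisense strand of the
#' input reference, the reference is reverse-complemented once at
#' construction so that all downstream accounting lives in a single
#' coordinate frame.
#'
#' @slot locusId character label.
#' @slot reference `DNAString`, amplicon on the protospacer strand.
#' @slot spacer `DNAString`, the 20-nt spacer.
#' @slot pam `DNAString`, PAM immediately 3' of the spacer.
#' @slot spacerStart integer, 0-based offset of the spacer on `reference`.
#' @slot spacerStrand `"sense"` or `"antisense"`: strand of the input
#'   reference the spacer matched (record only; `reference` is already
#'   protospacer-strand).
#' @slot desiredEdits data.frame with columns `pos` (protospacer position),
#'   `ref`, `alt`; may have zero rows.
#' @slot window a [WindowSpec-class] object.
#' @export
setClass("AmpliconLocus",
    representation(locusId = "character", reference = "DNAString",
                   spacer = "DNAString", pam = "DNAString",
                   spacerStart = "integer", spacerStrand = "character",
                   desiredEdits = "data.frame", window = "WindowSpec"))

setValidity("AmpliconLocus", function(object) {
    msg <- character()
    if (length(object@locusId) != 1L || !nzchar(object@locusId))
        msg <- c(msg, "'locusId' must be a non-empty string")
    if (length(object@spacer) != 20L)
        msg <- c(msg, "'spacer' must be 20 nt")
    if (length(object@pam) != object@window@pamLen)
        msg <- c(msg, sprintf("'pam' must be %d nt", object@window@pamLen))
    sp <- as.character(object@spacer); pm <- as.character(object@pam)
    if (grepl("N", paste0(sp, pm), fixed = TRUE))
        msg <- c(msg, "spacer/PAM must not contain N")
    if (!object@spacerStrand %in% c("sense", "antisense"))
        msg <- c(msg, "'spacerStrand' must be \"sense\" or \"antisense\"")
    st <- object@spacerStart
    lenNeeded <- st + 20L + object@window@pamLen
    ref <- as.character(object@reference)
    if (length(st) != 1L || is.na(st) || st < 0L || lenNeeded > nchar(ref)) {
        msg <- c(msg, "spacer+PAM do not fit the reference at 'spacerStart'")
    } else if (substr(ref, st + 1L, lenNeeded) != paste0(sp, pm)) {
        msg <- c(msg, sprintf(
            "placement error: spacer+PAM not found on the protospacer strand at offset %d", st))
    }
    de <- object@desiredEdits
    if (!all(c("pos", "ref", "alt") %in% names(de))) {
        msg <- c(msg, "'desiredEdits' needs columns pos, ref, alt")
    } else if (nrow(de) > 0L) {
        if (any(de$pos < 1L | de$pos > 20L))
            msg <- c(msg, "desired-edit positions must be in 1..20")
        else {
            refBase <- substring(sp, de$pos, de$pos)
            if (any(refBase != "A") || any(de$ref != "A") ||
                any(de$alt != "G"))
                msg <- c(msg,
                    "validation error: every desired edit must be A-to-G at an adenine of the protospacer")
        }
        if (anyDuplicated(de$pos))
            msg <- c(msg, "duplicated desired-edit positions")
    }
    if (length(msg)) msg else TRUE
})

#' @param locusId,reference,spacer,pam,spacerStart,desiredEdits,window see slots.
#'   `reference`/`spacer`/`pam` may be character or `DNAString`. `spacerStart`
#'   may be `NULL`, in which case the spacer+PAM is searched on both strands
#'   of `reference`. `desiredEdits` may also be given as a character vector of
#'   `"pos:ref>alt"` tokens (e.g. `"5:A>G"`).
#' @rdname AmpliconLocus-class
#' @return `ampliconLocus()` returns a validated `AmpliconLocus`.
#' @examples
#' loc <- exampleLocus()
#' spacerRange(loc)
#' quantWindowRange(loc)
#' @export
ampliconLocus <- function(locusId, reference, spacer, pam,
                          spacerStart = NULL, desiredEdits = NULL,
                          window = windowSpec()) {
    reference <- DNAString(toupper(as.character(reference)))
    spacer <- toupper(as.character(spacer))
    pam <- toupper(as.character(pam))
    de <- parseDesiredEdits(desiredEdits)
    target <- paste0(spacer, pam)
    refChr <- as.character(reference)
    rcChr <- as.character(reverseComplement(reference))
    if (is.null(spacerStart)) {
        hitF <- regexpr(target, refChr, fixed = TRUE)
        hitR <- regexpr(target, rcChr, fixed = TRUE)
        if (hitF > 0L) {
            spacerStart <- hitF - 1L
            strand <- "sense"
        } else if (hitR > 0L) {
            spacerStart <- hitR - 1L
            strand <- "antisense"
            reference <- reverseComplement(reference)
        } else {
            stop("placement error: spacer+PAM not found on either strand of the reference")
        }
    } else {
        spacerStart <- as.integer(spacerStart)
        # decide strand from the stated offset: sense first, else antisense
        at <- function(x) substr(x, spacerStart + 1L,
                                 spacerStart + nchar(target))
        if (identical(at(refChr), target)) {
            strand <- "sense"
        } else if (identical(at(rcChr), target)) {
            strand <- "antisense"
            reference <- reverseComplement(reference)
        } else {
            stop(sprintf(
                "placement error: spacer+PAM not found at offset %d on either strand",
                spacerStart))
        }
    }
    new("AmpliconLocus", locusId = as.character(locusId),
        reference = reference, spacer = DNAString(spacer),
        pam = DNAString(pam), spacerStart = as.integer(spacerStart),
        spacerStrand = strand, desiredEdits = de, window = window)
}

# "5:A>G;8:A>G" tokens or a data.frame -> canonical data.frame
parseDesiredEdits <- function(x) {
    if (is.null(x) || (is.character(x) && length(x) == 1L && !nzchar(x)))
        return(data.frame(pos = integer(), ref = character(),
                          alt = character(), stringsAsFactors = FALSE))
    if (is.data.frame(x)) {
        need <- c("pos", "ref", "alt")
        if (!all(need %in% names(x)))
            stop("configuration error: desiredEdits is missing field(s) ",
                 paste(setdiff(need, names(x)), collapse = ", "))
        out <- data.frame(pos = as.integer(x$pos),
                          ref = toupper(as.character(x$ref)),
                          alt = toupper(as.character(x$alt)),
                          stringsAsFactors = FALSE)
        return(out[order(out$pos), , drop = FALSE])
    }
    tokens <- unlist(strsplit(as.character(x), ";", fixed = TRUE))
    tokens <- trimws(tokens[nzchar(trimws(tokens))])
    m <- regmatches(tokens, regexec("^([0-9]+):([ACGT])>([ACGT])$",
                                    toupper(tokens)))
    bad <- lengths(m) != 4L
    if (any(bad))
        stop("configuration error: cannot parse desired-edit token(s): ",
             paste(tokens[bad], collapse = ", "))
    out <- data.frame(pos = as.integer(vapply(m, `[`, "", 2L)),
                      ref = vapply(m, `[`, "", 3L),
                      alt = vapply(m, `[`, "", 4L),
                      stringsAsFactors = FALSE)
    out[order(out$pos), , drop = FALSE]
}

setGeneric("locusId", function(x) standardGeneric("locusId"))
#' @rdname AmpliconLocus-class
#' @param x an object.
#' @export
setMethod("locusId", "AmpliconLocus", function(x) x@locusId)

setGeneric("referenceSeq", function(x) standardGeneric("referenceSeq"))
#' @rdname AmpliconLocus-class
#' @export
setMethod("referenceSeq", "AmpliconLocus", function(x) x@reference)

setGeneric("desiredEdits", function(x) standardGeneric("desiredEdits"))
#' @rdname AmpliconLocus-class
#' @export
setMethod("desiredEdits", "AmpliconLocus", function(x) x@desiredEdits)

#' @rdname AmpliconLocus-class
#' @export
spacerRange <- function(x) {
    stopifnot(is(x, "AmpliconLocus"))
    c(start = x@spacerStart + 1L, end = x@spacerStart + 20L)
}

#' Reference coordinates of the quantification window
#'
#' @param x an `AmpliconLocus`.
#' @return integer vector `c(start, end)` of 1-based reference coordinates of
#'   the allele-classification window (spacer - upstream .. PAM + downstream),
#'   clipped to the reference.
#' @rdname AmpliconLocus-class
#' @export
quantWindowRange <- function(x) {
    stopifnot(is(x, "AmpliconLocus"))
    w <- x@window
    s <- x@spacerStart + 1L - w@upstream
    e <- x@spacerStart + 20L + w@pamLen + w@downstream
    c(start = max(1L, s), end = min(length(x@reference), e))
}

#' Map reference coordinates to protospacer positions
#'
#' Protospacer positions are 1..20 (5' to 3', 20 adjacent to the PAM), PAM
#' and downstream bases continue 21, 22, ...; upstream flank positions are
#' -1, -2, ... immediately 5' of position 1 (there is no position 0).
#'
#' @param locus an `AmpliconLocus`.
#' @param refPos integer vector of 1-based reference coordinates.
#' @return integer vector of protospacer-frame position labels.
#' @examples
#' loc <- exampleLocus()
#' refToProto(loc, spacerRange(loc)["start"] + 0:2)  # 1 2 3
#' @export
refToProto <- function(locus, refPos) {
    off <- as.integer(refPos) - locus@spacerStart
    ifelse(off >= 1L, off, off - 1L)
}

#' @param protoPos integer vector of protospacer-frame labels (no 0).
#' @rdname refToProto
#' @export
protoToRef <- function(locus, protoPos) {
    protoPos <- as.integer(protoPos)
    if (any(protoPos == 0L)) stop("protospacer position 0 does not exist")
    locus@spacerStart + ifelse(protoPos >= 1L, protoPos, protoPos + 1L)
}

setMethod("show", "AmpliconLocus", function(object) {
    de <- object@desiredEdits
    cat(sprintf("AmpliconLocus '%s' (%d-nt reference, spacer at %d..%d [%s], PAM %s)\n",
                object@locusId, length(object@reference),
                object@spacerStart + 1L, object@spacerStart + 20L,
                object@spacerStrand, as.character(object@pam)))
    if (nrow(de))
        cat("  desired edits:",
            paste(sprintf("A%d>%s", de$pos, de$alt), collapse = ", "), "\n")
    else cat("  desired edits: none\n")
})

#' Aligned reads in reference coordinates
#'
#' Container for reads aligned semi-globally to one amplicon reference.
#' For read i, `refCalls[i]` is the read spelled in the reference frame over
#' `start[i]..end[i]` (deletions as `-`, insertions removed and recorded in
#' `insertions[[i]]` as 0-based reference gap positions).
#'
#' @slot locusId character scalar.
#' @slot readId character vector.
#' @slot orientation `"forward"` or `"reverse"` per read.
#' @slot start,end integer vectors, 1-based reference span per read.
#' @slot refCalls character vector of reference-frame call strings.
#' @slot insertions list of data.frames (`pos`, `seq`) per read; `pos` is the
#'   reference coordinate after which the insertion occurs (0 = before base 1).
#' @slot score numeric alignment scores.
#' @export
setClass("AlignedReads",
    representation(locusId = "character", readId = "character",
                   orientation = "character", start = "integer",
                   end = "integer", refCalls = "character",
                   insertions = "list", score = "numeric"))

setValidity("AlignedReads", function(object) {
    n <- length(object@readId)
    lens <- c(length(object@orientation), length(object@start),
              length(object@end), length(object@refCalls),
              length(object@insertions), length(object@score))
    if (any(lens != n))
        return("slot lengths disagree")
    if (n && any(nchar(object@refCalls) != object@end - object@start + 1L))
        return("refCalls must cover exactly start..end")
    TRUE
})

setMethod("show", "AlignedReads", function(object) {
    cat(sprintf("AlignedReads: %d read(s) aligned to locus '%s'\n",
                length(object@readId), object@locusId))
})

setMethod("length", "AlignedReads", function(x) length(x@readId))

setMethod("[", "AlignedReads", function(x, i, j, ..., drop = TRUE) {
    new("AlignedReads", locusId = x@locusId, readId = x@readId[i],
        orientation = x@orientation[i], start = x@start[i], end = x@end[i],
        refCalls = x@refCalls[i], insertions = x@insertions[i],
        score = x@score[i])
})

setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))
#' @rdname AlignedReads-class
#' @param x an `AlignedReads` object.
#' @export
setMethod("alignmentScore", "AlignedReads", function(x) x@score)

setGeneric("orientation", function(x) standardGeneric("orientation"))
#' @rdname AlignedReads-class
#' @export
setMethod("orientation", "AlignedReads", function(x) x@orientation)

#' Per-position nucleotide profile
#'
#' Counts of observed symbols (A, C, G, T, N, `-`) at each position of the
#' profiled interval, in protospacer-frame coordinates. At every position the
#' column sum equals the depth (reads covering the position).
#'
#' @slot locusId character scalar.
#' @slot positions integer protospacer-frame labels (negative = upstream
#'   flank, 1..20 = spacer, >20 = PAM/downstream).
#' @slot counts 6 x P integer matrix, rows A, C, G, T, N, `-`.
#' @slot refBases character vector of reference bases at `positions`.
#' @export
setClass("PositionProfile",
    representation(locusId = "character", positions = "integer",
                   counts = "matrix", refBases = "character"))

setValidity("PositionProfile", function(object) {
    if (!identical(rownames(object@counts), c("A", "C", "G", "T", "N", "-")))
        return("counts rows must be A, C, G, T, N, -")
    if (ncol(object@counts) != length(object@positions))
        return("counts columns must match positions")
    if (length(object@refBases) != length(object@positions))
        return("refBases must match positions")
    TRUE
})

setGeneric("profileDepth", function(x) standardGeneric("profileDepth"))
#' @rdname PositionProfile-class
#' @param x a `PositionProfile`.
#' @export
setMethod("profileDepth", "PositionProfile", function(x) {
    d <- colSums(x@counts)
    names(d) <- x@positions
    d
})

setGeneric("profileCounts", function(x) standardGeneric("profileCounts"))
#' @rdname PositionProfile-class
#' @export
setMethod("profileCounts", "PositionProfile", function(x) x@counts)

setGeneric("profilePositions", function(x) standardGeneric("profilePositions"))
#' @rdname PositionProfile-class
#' @export
setMethod("profilePositions", "PositionProfile", function(x) x@positions)

setMethod("show", "PositionProfile", function(object) {
    cat(sprintf("PositionProfile for locus '%s': %d positions (%s..%s), max depth %d\n",
                object@locusId, length(object@positions),
                min(object@positions), max(object@positions),
                if (length(object@positions)) max(colSums(object@counts)) else 0L))
})

#' Five-way allele class tallies
#'
#' Read counts per allele class within the quantification window. The six
#' classes partition all aligned reads:
#' `wt + desiredOnly + desiredBystander + bystanderOnly + indel + shortReads
#' == totalAligned`.
#'
#' @slot totalAligned,wt,desiredOnly,desiredBystander,bystanderOnly,indel,shortReads
#'   integer counts.
#' @export
setClass("AlleleClassCounts",
    representation(totalAligned = "integer", wt = "integer",
                   desiredOnly = "integer", desiredBystander = "integer",
                   bystanderOnly = "integer", indel = "integer",
                   shortReads = "integer"))

setValidity("AlleleClassCounts", function(object) {
    v <- c(object@wt, object@desiredOnly, object@desiredBystander,
           object@bystanderOnly, object@indel, object@shortReads)
    if (any(v < 0L)) return("counts must be non-negative")
    if (sum(v) != object@totalAligned)
        return("class counts must sum to totalAligned")
    TRUE
})

#' @param wt,desiredOnly,desiredBystander,bystanderOnly,indel,shortReads counts.
#' @rdname AlleleClassCounts-class
#' @return `alleleClassCounts()` returns a validated `AlleleClassCounts`.
#' @examples
#' alleleClassCounts(wt = 530, desiredOnly = 300, desiredBystander = 100,
#'                   bystanderOnly = 50, indel = 20)
#' @export
alleleClassCounts <- function(wt = 0L, desiredOnly = 0L,
                              desiredBystander = 0L, bystanderOnly = 0L,
                              indel = 0L, shortReads = 0L) {
    v <- as.integer(c(wt, desiredOnly, desiredBystander, bystanderOnly,
                      indel, shortReads))
    new("AlleleClassCounts", totalAligned = sum(v), wt = v[1L],
        desiredOnly = v[2L], desiredBystander = v[3L], bystanderOnly = v[4L],
        indel = v[5L], shortReads = v[6L])
}

setMethod("show", "AlleleClassCounts", function(object) {
    cat(sprintf(paste0("AlleleClassCounts (%d aligned): wt %d | desired-only %d | ",
                       "desired+bystander %d | bystander-only %d | indel %d | short %d\n"),
                object@totalAligned, object@wt, object@desiredOnly,
                object@desiredBystander, object@bystanderOnly, object@indel,
                object@shortReads))
})

#' @rdname AlleleClassCounts-class
#' @param x an `AlleleClassCounts`.
#' @export
classCountsVector <- function(x) {
    stopifnot(is(x, "AlleleClassCounts"))
    c(totalAligned = x@totalAligned, wt = x@wt, desiredOnly = x@desiredOnly,
      desiredBystander = x@desiredBystander, bystanderOnly = x@bystanderOnly,
      indel = x@indel, shortReads = x@shortReads)
}

#' Generative editor model for the read simulator
#'
#' @slot name character label.
#' @slot engageProb probability a molecule is edited at all.
#' @slot windowProfile named numeric: protospacer position -> A-to-G
#'   conversion probability given engagement.
#' @slot ctotProb per-active-position C-to-T probability.
#' @slot atocProb per-active-adenine A-to-C probability (applied when the
#'   adenine was not converted to G).
#' @slot indelProb per-molecule indel probability.
#' @slot indelLenDist named numeric distribution over indel lengths
#'   (-3..-1 deletions, 1..3 insertions); probabilities sum to 1.
#' @export
setClass("EditorModel",
    representation(name = "character", engageProb = "numeric",
                   windowProfile = "numeric", ctotProb = "numeric",
                   atocProb = "numeric", indelProb = "numeric",
                   indelLenDist = "numeric"))

setValidity("EditorModel", function(object) {
    p <- c(object@engageProb, object@windowProfile, object@ctotProb,
           object@atocProb, object@indelProb)
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        return("all probabilities must lie in [0, 1]")
    pos <- suppressWarnings(as.integer(names(object@windowProfile)))
    if (length(object@windowProfile) &&
        (any(is.na(pos)) || any(pos == 0L) || any(pos > 20L)))
        return("windowProfile names must be protospacer positions (<= 20, no 0)")
    d <- object@indelLenDist
    lens <- suppressWarnings(as.integer(names(d)))
    if (any(is.na(lens)) || any(!lens %in% c(-3:-1, 1:3)))
        return("indelLenDist names must be in -3..-1, 1..3")
    if (abs(sum(d) - 1) > 1e-8 || any(d < 0))
        return("indelLenDist must be a probability distribution")
    TRUE
})

setMethod("show", "EditorModel", function(object) {
    wp <- object@windowProfile
    cat(sprintf("EditorModel '%s': engage %.2f; active positions %s; C-to-T %.3g; A-to-C %.3g; indel %.3g\n",
                object@name, object@engageProb,
                if (length(wp)) paste0(names(wp), collapse = ",") else "none",
                object@ctotProb, object@atocProb, object@indelProb))
})

#' Mosaic founder: a mixture of cell-lineage alleles
#'
#' A founder animal is modelled as K cell lineages, each carrying one fixed
#' edited (or wild-type) allele of the amplicon; sequencing reads sample
#' lineages by weight.
#'
#' @slot locusId character scalar.
#' @slot alleles character vector of full amplicon sequences (one per lineage).
#' @slot weights numeric lineage weights, summing to 1.
#' @export
setClass("MosaicFounder",
    representation(locusId = "character", alleles = "character",
                   weights = "numeric"))

setValidity("MosaicFounder", function(object) {
    if (length(object@alleles) < 1L) return("need at least one lineage")
    if (length(object@weights) != length(object@alleles))
        return("weights must match alleles")
    if (any(object@weights < 0) || abs(sum(object@weights) - 1) > 1e-8)
        return("weights must be non-negative and sum to 1")
    TRUE
})

#' @param locusId,alleles,weights see slots.
#' @rdname MosaicFounder-class
#' @return `mosaicFounder()` returns a validated `MosaicFounder`.
#' @export
mosaicFounder <- function(locusId, alleles, weights) {
    new("MosaicFounder", locusId = as.character(locusId),
        alleles = toupper(as.character(alleles)),
        weights = as.numeric(weights) / sum(weights))
}

setMethod("show", "MosaicFounder", function(object) {
    cat(sprintf("MosaicFounder at locus '%s': %d lineage(s), weights %s\n",
                object@locusId, length(object@alleles),
                paste(sprintf("%.3f", object@weights), collapse = ", ")))
})

setGeneric("lineageWeights", function(x) standardGeneric("lineageWeights"))
#' @rdname MosaicFounder-class
#' @param x a `MosaicFounder`.
#' @export
setMethod("lineageWeights", "MosaicFounder", function(x) x@weights)

setGeneric("lineageAlleles", function(x) standardGeneric("lineageAlleles"))
#' @rdname MosaicFounder-class
#' @export
setMethod("lineageAlleles", "MosaicFounder", function(x) x@alleles)
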