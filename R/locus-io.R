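#' @importFrom Biostrings readDNAStringSet readQualityScaledDNAStringSet
#'   writeQualityScaledXStringSet QualityScaledDNAStringSet PhredQuality
#'   quality width
#' @importFrom jsonlite fromJSON
#' @importFrom utils read.delim write.table
#' @importFrom tools file_ext
NULL

.LOCUS_FIELDS <- c("locus_id", "reference", "spacer", "spacer_strand",
                   "spacer_start", "pam", "desired_edits")

#' Load a locus configuration (TSV or JSON)
#'
#' Reads a table of amplicon loci and returns validated
#' [AmpliconLocus-class] objects. Two dialects are accepted: a flat TSV with
#' one locus per row (`desired_edits` as semicolon-joined `pos:ref>alt`
#' tokens) or an equivalent JSON array of objects. Required fields:
#' `locus_id`, `reference`, `spacer`, `spacer_strand`, `spacer_start`
#' (0-based; empty/NA to search), `pam`, `desired_edits`. Optional:
#' `window_upstream`, `window_downstream` (defaults 7 and 3).
#'
#' References may alternatively be supplied in a separate FASTA via
#' `fasta`, in which case the `reference` column holds FASTA record names.
#'
#' @param path configuration file path.
#' @param fasta optional FASTA path with reference amplicons.
#' @return named list of `AmpliconLocus` objects.
#' @examples
#' cfg <- system.file("extdata", "example_loci.tsv", package = "abequant")
#' loci <- readLocusConfig(cfg)
#' names(loci)
#' @export
readLocusConfig <- function(path, fasta = NULL) {
    if (!file.exists(path)) stop("configuration error: file not found: ", path)
    ext <- tolower(file_ext(path))
    tab <- if (ext == "json") {
        as.data.frame(fromJSON(path), stringsAsFactors = FALSE)
    } else {
        read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
    }
    missing <- setdiff(.LOCUS_FIELDS, names(tab))
    if (length(missing))
        stop("configuration error: missing field(s): ",
             paste(missing, collapse = ", "))
    refs <- NULL
    if (!is.null(fasta)) refs <- readDNAStringSet(fasta)
    loci <- lapply(seq_len(nrow(tab)), function(i) {
        row <- tab[i, ]
        refSeq <- if (!is.null(refs)) {
            if (!row$reference %in% names(refs))
                stop("configuration error: reference '", row$reference,
                     "' not in FASTA")
            as.character(refs[[row$reference]])
        } else row$reference
        st <- row$spacer_start
        st <- if (is.na(st) || !nzchar(st)) NULL else as.integer(st)
        w <- windowSpec(
            upstream = if ("window_upstream" %in% names(row) &&
                           nzchar(row$window_upstream)) row$window_upstream else 7L,
            downstream = if ("window_downstream" %in% names(row) &&
                             nzchar(row$window_downstream)) row$window_downstream else 3L,
            pamLen = nchar(row$pam))
        loc <- ampliconLocus(locusId = row$locus_id, reference = refSeq,
                             spacer = row$spacer, pam = row$pam,
                             spacerStart = st,
                             desiredEdits = row$desired_edits, window = w)
        stated <- tolower(row$spacer_strand)
        if (nzchar(stated) && !identical(stated, loc@spacerStrand))
            stop("configuration error: locus '", row$locus_id,
                 "' states spacer_strand=", stated, " but spacer+PAM was found on the ",
                 loc@spacerStrand, " strand")
        loc
    })
    names(loci) <- vapply(loci, locusId, "")
    if (anyDuplicated(names(loci)))
        stop("configuration error: duplicated locus_id")
    loci
}

#' Read and write FASTQ
#'
#' Thin wrappers over Biostrings' quality-aware FASTQ IO (Sanger Phred+33).
#' Gzip-compressed input is handled transparently; `writeFastq()` compresses
#' when `path` ends in `.gz`.
#'
#' @param path FASTQ path (optionally `.gz`).
#' @return `readFastq()` returns a `QualityScaledDNAStringSet`.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' loc <- exampleLocus()
#' simulateEditedReads(loc, makeEditorModel("abe9_like"), n = 5, seed = 1,
#'                     path = fq)
#' length(readFastq(fq))
#' @export
readFastq <- function(path) {
    if (!file.exists(path)) stop("input error: FASTQ not found: ", path)
    withCallingHandlers(
        readQualityScaledDNAStringSet(path, quality.scoring = "phred"),
        warning = function(w) {
            if (grepl("metadata columns.*dropped", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
}

#' @param reads a `QualityScaledDNAStringSet`.
#' @rdname readFastq
#' @export
writeFastq <- function(reads, path) {
    writeQualityScaledXStringSet(reads, path,
                                 compress = grepl("\\.gz$", path))
    invisible(path)
}

#' Mean read quality and the mean-quality filter
#'
#' `meanQuality()` returns the arithmetic mean Phred score per read;
#' `meanQualityFilter()` keeps reads whose mean quality is at or above
#' `threshold` (default 30).
#'
#' @param reads a `QualityScaledDNAStringSet`.
#' @param threshold minimum mean Phred score.
#' @return `meanQuality()`: numeric vector; `meanQualityFilter()`: the
#'   filtered `QualityScaledDNAStringSet` with attribute `"nFiltered"`.
#' @examples
#' fq <- simulateEditedReads(exampleLocus(), makeEditorModel("abe9_like"),
#'                           n = 20, seed = 1)
#' summary(meanQuality(fq))
#' length(meanQualityFilter(fq, threshold = 30))
#' @export
meanQuality <- function(reads) {
    if (any(width(reads) == 0L)) stop("input error: empty read")
    q <- as(quality(reads), "IntegerList")
    vapply(q, function(x) mean(as.numeric(x)), 0)
}

#' @rdname meanQuality
#' @export
meanQualityFilter <- function(reads, threshold = 30) {
    keep <- meanQuality(reads) >= threshold
    out <- reads[keep]
    attr(out, "nFiltered") <- sum(!keep)
    out
}

#' Merge a read pair by overlap consensus
#'
#' The mate (`seq2`) is reverse-complemented, the unique best overlap of at
#' least `minOverlap` nt between the end of read 1 and the start of the
#' reverse-complemented mate is located (score = matches - mismatches,
#' requiring >= 90% identity and a strictly unique best), and a consensus is
#' emitted taking the higher-quality base at disagreements (read 1 wins
#' quality ties).
#'
#' @param seq1,seq2 character read sequences (read 2 in sequencing
#'   orientation).
#' @param qual1,qual2 integer Phred vectors matching the sequences.
#' @param minOverlap minimum overlap length in nt.
#' @param minIdentity minimum identity within the overlap.
#' @return a list with `seq` and `qual` of the merged read, or `NULL` when
#'   unmergeable.
#' @examples
#' left <- "ACGTACGTACGTACGTACGTGGGGCCCCAAAA"
#' right <- "ACGTGGGGCCCCAAAATTTTGGGGTTTTCCCC"
#' rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(right)))
#' m <- mergeReadPair(left, rc, rep(30L, nchar(left)), rep(30L, nchar(right)),
#'                    minOverlap = 10)
#' m$seq
#' @export
mergeReadPair <- function(seq1, seq2, qual1, qual2, minOverlap = 20L,
                          minIdentity = 0.9) {
    s1 <- strsplit(toupper(seq1), "")[[1L]]
    rc2 <- strsplit(as.character(
        reverseComplement(DNAString(toupper(seq2)))), "")[[1L]]
    q2 <- rev(as.integer(qual2))
    q1 <- as.integer(qual1)
    n1 <- length(s1); n2 <- length(rc2)
    maxO <- min(n1, n2)
    if (maxO < minOverlap) return(NULL)
    os <- minOverlap:maxO
    scores <- vapply(os, function(o) {
        a <- s1[(n1 - o + 1L):n1]; b <- rc2[1L:o]
        m <- sum(a == b)
        if (m / o < minIdentity) return(-Inf)
        2 * m - o
    }, 0)
    if (all(!is.finite(scores))) return(NULL)
    best <- which(scores == max(scores))
    if (length(best) != 1L) return(NULL)      # no unique best overlap
    o <- os[best]
    i1 <- (n1 - o + 1L):n1; i2 <- 1L:o
    a <- s1[i1]; b <- rc2[i2]; qa <- q1[i1]; qb <- q2[i2]
    agree <- a == b
    cons <- ifelse(agree | qa >= qb, a, b)    # higher quality wins, r1 on tie
    consQ <- ifelse(agree, pmax(qa, qb), pmax(qa, qb))
    list(seq = paste0(c(s1[seq_len(n1 - o)], cons,
                        rc2[(o + 1L):n2][seq_len(n2 - o)]), collapse = ""),
         qual = c(q1[seq_len(n1 - o)], consQ, q2[(o + 1L):n2][seq_len(n2 - o)]))
}

#' Merge paired FASTQ read sets
#'
#' Applies [mergeReadPair()] to each pair in two parallel
#' `QualityScaledDNAStringSet`s.
#'
#' @param fwd,rev paired `QualityScaledDNAStringSet`s of equal length.
#' @inheritParams mergeReadPair
#' @return a `QualityScaledDNAStringSet` of merged reads; unmergeable pairs
#'   are dropped and counted in attribute `"nUnmerged"`.
#' @export
mergeReadPairs <- function(fwd, rev, minOverlap = 20L, minIdentity = 0.9) {
    stopifnot(length(fwd) == length(rev))
    qf <- as(quality(fwd), "IntegerList")
    qr <- as(quality(rev), "IntegerList")
    sf <- as.character(fwd); sr <- as.character(rev)
    merged <- lapply(seq_along(fwd), function(i)
        mergeReadPair(sf[i], sr[i], as.integer(qf[[i]]), as.integer(qr[[i]]),
                      minOverlap = minOverlap, minIdentity = minIdentity))
    ok <- !vapply(merged, is.null, TRUE)
    seqs <- vapply(merged[ok], `[[`, "", "seq")
    quals <- vapply(merged[ok], function(m)
        rawToChar(as.raw(pmin(93L, m$qual) + 33L)), "")
    out <- QualityScaledDNAStringSet(DNAStringSet(seqs), PhredQuality(quals))
    names(out) <- names(fwd)[ok]
    attr(out, "nUnmerged") <- sum(!ok)
    out
}

#' Demultiplex pooled reads by best reference alignment
#'
#' Each read (both orientations) is aligned to every locus reference; it is
#' assigned to the best-scoring locus when that score reaches
#' `minScoreFrac` of the read's self-alignment maximum (match score x read
#' length) and exceeds the runner-up by at least `margin`; otherwise it falls
#' into the `unassigned` bin. Deterministic and invariant under read order.
#'
#' @param reads a `QualityScaledDNAStringSet`.
#' @param loci list of [AmpliconLocus-class] objects.
#' @param minScoreFrac fraction of the self-alignment score required.
#' @param margin minimum score separation from the runner-up locus.
#' @param scoring alignment scoring, see [alignmentScoring()].
#' @return list with one `QualityScaledDNAStringSet` per locus id plus
#'   `unassigned`.
#' @examples
#' loci <- exampleLoci()
#' fq <- simulateEditedReads(loci[[1]], makeEditorModel("abe9_like"),
#'                           n = 10, seed = 1)
#' dm <- demultiplexReads(fq, loci)
#' lengths(dm)
#' @export
demultiplexReads <- function(reads, loci, minScoreFrac = 0.6, margin = 1,
                             scoring = alignmentScoring()) {
    stopifnot(length(loci) >= 1L)
    ids <- vapply(loci, locusId, "")
    seqs <- as.character(reads)
    uniq <- unique(seqs)
    idx <- match(seqs, uniq)
    scoreMat <- vapply(loci, function(loc)
        bestAlignmentScores(uniq, loc, scoring), numeric(length(uniq)))
    scoreMat <- matrix(scoreMat, nrow = length(uniq),
                       dimnames = list(NULL, ids))
    selfMax <- scoring$match * nchar(uniq)
    assign <- rep(NA_character_, length(uniq))
    for (i in seq_along(uniq)) {
        s <- scoreMat[i, ]
        o <- order(s, decreasing = TRUE)
        best <- s[o[1L]]
        second <- if (length(s) > 1L) s[o[2L]] else -Inf
        if (best >= minScoreFrac * selfMax[i] && best - second >= margin)
            assign[i] <- ids[o[1L]]
    }
    perRead <- assign[idx]
    out <- lapply(ids, function(id) reads[!is.na(perRead) & perRead == id])
    names(out) <- ids
    out$unassigned <- reads[is.na(perRead)]
    out
}

#' Built-in synthetic demonstration loci
#'
#' `exampleLocus()` returns a fully synthetic amplicon locus (83-nt
#' reference, spacer with adenines at protospacer positions 2, 4, 5, 6, 8,
#' 10, 12 and 13, an upstream flank adenine at position -2, desired edit
#' A5>G) used throughout examples and tests. `exampleLoci()` returns it
#' together with a second, unrelated synthetic locus for demultiplexing and
#' batch examples.
#'
#' @param id which demonstration locus.
#' @return an `AmpliconLocus` (`exampleLocus`) or named list of two
#'   (`exampleLoci`).
#' @examples
#' exampleLocus()
#' @export
exampleLocus <- function(id = c("demoA", "demoB")) {
    id <- match.arg(id)
    if (id == "demoA") {
        # flank ends ...A C so that protospacer positions -2/-1 are A/C
        up <- "TGCTTGACCTGTAGGTCATTGCGACTGAAC"
        spacer <- "GACAAACATACAATGCTGCT"
        pam <- "TGG"
        down <- "GTCCTAGGTTACGGATCTTGAGCTTACGTC"
        ampliconLocus("demoA", paste0(up, spacer, pam, down), spacer, pam,
                      spacerStart = 30L, desiredEdits = "5:A>G")
    } else {
        up <- "GGATCCTTAGCAGTCGGTTCAGGCTTCAAG"
        spacer <- "CTAGACAATGCAGTACCATG"
        pam <- "AGG"
        down <- "TCGATTCAGGCATGCAAGGTTCCAGTTCGA"
        ampliconLocus("demoB", paste0(up, spacer, pam, down), spacer, pam,
                      spacerStart = 30L, desiredEdits = "7:A>G")
    }
}

#' @rdname exampleLocus
#' @export
exampleLoci <- function() {
    list(demoA = exampleLocus("demoA"), demoB = exampleLocus("demoB"))
}
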