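# Independent oracles and fixture builders used across the suite.

# Exhaustive Gotoh dynamic program for semi-global alignment scores:
# global in the read x, free end gaps in the reference y, affine gaps
# costing gapOpen + L * gapExtend. Written independently of the package's
# alignment backend.
gotohScore <- function(x, y, match = 2, mismatch = -4, gapOpen = -10,
                       gapExtend = -1) {
    xc <- strsplit(x, "")[[1L]]
    yc <- strsplit(y, "")[[1L]]
    m <- length(xc); n <- length(yc)
    NEG <- -1e9
    H <- matrix(NEG, m + 1L, n + 1L)
    E <- matrix(NEG, m + 1L, n + 1L)   # gap in reference (read insertion)
    F <- matrix(NEG, m + 1L, n + 1L)   # gap in read (deletion)
    H[1L, ] <- 0                       # leading reference bases are free
    for (i in seq_len(m) + 1L) {
        E[i, 1L] <- gapOpen + gapExtend * (i - 1L)
        H[i, 1L] <- E[i, 1L]
    }
    for (i in seq_len(m) + 1L) {
        for (j in seq_len(n) + 1L) {
            s <- if (xc[i - 1L] == yc[j - 1L]) match else mismatch
            E[i, j] <- max(H[i - 1L, j] + gapOpen + gapExtend,
                           E[i - 1L, j] + gapExtend)
            F[i, j] <- max(H[i, j - 1L] + gapOpen + gapExtend,
                           F[i, j - 1L] + gapExtend)
            H[i, j] <- max(H[i - 1L, j - 1L] + s, E[i, j], F[i, j])
        }
    }
    max(H[m + 1L, ])                   # trailing reference bases are free
}

# Literal rule-by-rule window allele classifier: obs/ref are character
# vectors over the window, desired is a data.frame(idx, alt) in window
# indices. Indel and coverage handling are upstream of these rules.
classifyOracle <- function(obs, ref, desired) {
    if (any(obs == "-")) return("indel")
    subs <- which(obs != ref & obs != "N")
    subSet <- paste0(subs, ":", obs[subs])
    desSet <- if (nrow(desired)) paste0(desired$idx, ":", desired$alt)
              else character(0)
    if (length(subs) == 0L) return("wt")
    if (length(desSet) && setequal(subSet, desSet)) return("desired_only")
    if (length(desSet) && all(desSet %in% subSet) &&
        length(subSet) > length(desSet)) return("desired_bystander")
    "bystander_only"
}

# Build a full-amplicon read from a locus reference with point edits
# (named: ref coordinate -> base), an optional deletion (refStart, len) and
# an optional insertion (after refPos, seq).
makeRead <- function(locus, subs = NULL, del = NULL, ins = NULL) {
    ch <- strsplit(as.character(referenceSeq(locus)), "")[[1L]]
    if (!is.null(subs))
        ch[as.integer(names(subs))] <- unname(subs)
    s <- paste(ch, collapse = "")
    if (!is.null(del))
        s <- paste0(substr(s, 1L, del[1L] - 1L),
                    substr(s, del[1L] + del[2L], nchar(s)))
    if (!is.null(ins))
        s <- paste0(substr(s, 1L, ins$after), ins$seq,
                    substr(s, ins$after + 1L, nchar(s)))
    s
}

# Wrap plain sequences as a QualityScaledDNAStringSet at constant quality.
asReads <- function(seqs, qual = 35L) {
    quals <- vapply(nchar(seqs), function(L)
        rawToChar(as.raw(rep(qual + 33L, L))), "")
    r <- Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
    names(r) <- sprintf("t%03d", seq_along(seqs))
    r
}

revcompChr <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

randomDNA <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# demoA locus with a chosen desired-edit set (protospacer A>G positions)
demoAWithDesired <- function(positions) {
    base <- exampleLocus()
    ampliconLocus("demoA", as.character(referenceSeq(base)),
                  as.character(base@spacer), as.character(base@pam),
                  spacerStart = 30L,
                  desiredEdits = if (length(positions))
                      paste(sprintf("%d:A>G", positions), collapse = ";")
                  else NULL)
}
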