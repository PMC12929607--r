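test_that("locus config round-trips through TSV and JSON", {
    cfg <- system.file("extdata", "example_loci.tsv", package = "abequant")
    loci <- readLocusConfig(cfg)
    expect_named(loci, c("demoA", "demoB"))
    expect_equal(loci$demoA@spacerStart, 30L)
    expect_equal(desiredEdits(loci$demoA)$pos, 5L)
    expect_equal(desiredEdits(loci$demoB)$pos, 7L)

    tab <- read.delim(cfg, colClasses = "character")
    js <- tempfile(fileext = ".json")
    jsonlite::write_json(tab, js, auto_unbox = TRUE)
    lociJson <- readLocusConfig(js)
    expect_equal(as.character(referenceSeq(lociJson$demoA)),
                 as.character(referenceSeq(loci$demoA)))
    expect_equal(desiredEdits(lociJson$demoB), desiredEdits(loci$demoB))
})

test_that("config errors name the problem", {
    cfg <- system.file("extdata", "example_loci.tsv", package = "abequant")
    tab <- read.delim(cfg, colClasses = "character")
    noField <- tempfile(fileext = ".tsv")
    write.table(tab[, setdiff(names(tab), "spacer")], noField, sep = "\t",
                quote = FALSE, row.names = FALSE)
    expect_error(readLocusConfig(noField), "missing field.*spacer")

    badPlace <- tab
    badPlace$spacer_start <- "10"
    f <- tempfile(fileext = ".tsv")
    write.table(badPlace, f, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readLocusConfig(f), "placement error")

    # desired edit at a non-adenine (position 3 of demoA's spacer is C)
    badEdit <- tab
    badEdit$desired_edits[1] <- "3:A>G"
    f2 <- tempfile(fileext = ".tsv")
    write.table(badEdit, f2, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readLocusConfig(f2), "adenine")
})

test_that("antisense spacers are mapped to the protospacer strand", {
    loc <- exampleLocus()
    rcRef <- revcompChr(as.character(referenceSeq(loc)))
    anti <- ampliconLocus("rc", rcRef, as.character(loc@spacer),
                          as.character(loc@pam), desiredEdits = "5:A>G")
    expect_equal(anti@spacerStrand, "antisense")
    # independent check: the stored reference equals the reverse complement
    # of the input, and re-running the sense-strand search on it succeeds
    expect_equal(as.character(referenceSeq(anti)),
                 as.character(referenceSeq(loc)))
    expect_equal(anti@spacerStart, loc@spacerStart)
})

test_that("mean quality filter uses the arithmetic mean", {
    allQ30 <- asReads("ACGTACGT", qual = 30L)
    expect_length(meanQualityFilter(allQ30, 30), 1L)

    # 50 bases Q29 + 50 bases Q30: mean 29.5 fails a Q30 threshold
    mixed <- Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(randomDNA(100)),
        Biostrings::PhredQuality(paste0(
            rawToChar(as.raw(rep(29L + 33L, 50))),
            rawToChar(as.raw(rep(30L + 33L, 50))))))
    expect_equal(meanQuality(mixed), 29.5)
    expect_length(meanQualityFilter(mixed, 30), 0L)
    expect_length(meanQualityFilter(mixed, 0), 1L)
})

test_that("read pairs merge by overlap consensus with quality arbitration", {
    set.seed(41)
    left <- randomDNA(50)
    core <- substr(left, 21, 50)                 # 30-nt overlap
    right <- paste0(core, randomDNA(20))
    r2 <- revcompChr(right)                      # mate in sequencing orientation
    m <- mergeReadPair(left, r2, rep(30L, 50), rep(30L, 50), minOverlap = 20)
    expect_equal(m$seq, paste0(substr(left, 1, 20), right))
    expect_length(m$qual, 70L)

    # one disagreement: Q40 base beats Q10 base
    leftMut <- left
    substr(leftMut, 25, 25) <- if (substr(left, 25, 25) == "A") "C" else "A"
    q1 <- rep(10L, 50); q2 <- rep(40L, 50)
    m2 <- mergeReadPair(leftMut, r2, q1, q2, minOverlap = 20)
    expect_equal(substr(m2$seq, 25, 25), substr(left, 25, 25))

    # no sufficient overlap is a return state, not an error
    expect_null(mergeReadPair(randomDNA(40), randomDNA(40),
                              rep(30L, 40), rep(30L, 40), minOverlap = 30))
})

test_that("demultiplexing assigns, ties out, and conserves reads", {
    loci <- exampleLoci()
    refA <- as.character(referenceSeq(loci$demoA))
    refB <- as.character(referenceSeq(loci$demoB))
    set.seed(7)
    reads <- asReads(c(substr(refA, 5, 70), substr(refB, 5, 70),
                       revcompChr(substr(refA, 10, 75)), randomDNA(66)))
    dm <- demultiplexReads(reads, loci)
    expect_equal(names(dm$demoA), c("t001", "t003"))
    expect_equal(names(dm$demoB), "t002")
    expect_equal(names(dm$unassigned), "t004")
    expect_equal(sum(lengths(dm)), length(reads))

    # order permutation leaves assignments unchanged
    perm <- c(4, 2, 1, 3)
    dm2 <- demultiplexReads(reads[perm], loci)
    expect_setequal(names(dm2$demoA), names(dm$demoA))
    expect_setequal(names(dm2$unassigned), names(dm$unassigned))

    # a read and its reverse complement land in the same bin
    rc <- asReads(revcompChr(as.character(reads)))
    dm3 <- demultiplexReads(rc, loci)
    expect_equal(lengths(dm3), lengths(dm))

    # a read equidistant from two identical references is unassigned
    twin <- list(a = loci$demoA,
                 b = ampliconLocus("b", refA, as.character(loci$demoA@spacer),
                                   as.character(loci$demoA@pam),
                                   spacerStart = 30L, desiredEdits = "5:A>G"))
    dmTie <- demultiplexReads(asReads(substr(refA, 5, 70)), twin)
    expect_length(dmTie$unassigned, 1L)
})
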