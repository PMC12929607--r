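test_that("window allele classes follow the five-way rules", {
    loc <- exampleLocus()                       # desired A5>G
    ref <- as.character(referenceSeq(loc))
    r <- function(...) makeRead(loc, ...)
    a <- function(p) protoToRef(loc, p)
    wr <- quantWindowRange(loc)

    reads <- c(wt = ref,
               desired = r(subs = setNames("G", a(5))),
               desiredByst = r(subs = setNames(c("G", "G"), c(a(5), a(4)))),
               bystOnly = r(subs = setNames("G", a(4))),
               wrongAlt = r(subs = setNames("C", a(5))),
               outside = r(subs = setNames("G", wr[["end"]] + 5L)),
               indel = r(subs = setNames("G", a(5)), del = c(a(8), 2L)),
               short = substr(ref, wr[["start"]] + 4L, nchar(ref)))
    cls <- classifyReads(alignReads(asReads(unname(reads)), loc), loc)
    expect_equal(as.character(cls),
                 c("wt", "desired_only", "desired_bystander",
                   "bystander_only", "bystander_only", "wt", "indel",
                   "short_read"))
})

test_that("a partial desired set is bystander-only, not desired", {
    # two targeted adenines (A5 and A6); editing only one of them gives a
    # different amino-acid substitution and must not count as desired
    loc <- demoAWithDesired(c(5L, 6L))
    oneOfTwo <- makeRead(loc, subs = setNames("G", protoToRef(loc, 5)))
    both <- makeRead(loc, subs = setNames(c("G", "G"),
                                          protoToRef(loc, c(5, 6))))
    cls <- classifyReads(alignReads(asReads(c(oneOfTwo, both)), loc), loc)
    expect_equal(as.character(cls), c("bystander_only", "desired_only"))
})

test_that("classifier matches the literal rule oracle over all patterns", {
    # k = 4 variable adenine positions, every substitution pattern and every
    # desired-set choice
    varPos <- c(2L, 4L, 5L, 6L)
    base <- exampleLocus()
    refCoord <- protoToRef(base, varPos)
    wr <- quantWindowRange(base)
    refWin <- strsplit(substr(as.character(referenceSeq(base)),
                              wr[["start"]], wr[["end"]]), "")[[1]]
    patterns <- expand.grid(rep(list(c(FALSE, TRUE)), length(varPos)))
    readSeqs <- apply(patterns, 1L, function(row) {
        subs <- setNames(rep("G", sum(row)), refCoord[as.logical(row)])
        if (length(subs)) makeRead(base, subs = subs)
        else as.character(referenceSeq(base))
    })
    aln <- alignReads(asReads(readSeqs), base)

    for (mask in 0:(2^length(varPos) - 1)) {
        desPos <- varPos[bitwAnd(mask, 2^(seq_along(varPos) - 1)) > 0]
        loc <- demoAWithDesired(desPos)
        got <- as.character(classifyReads(aln, loc))
        want <- apply(patterns, 1L, function(row) {
            obs <- refWin
            obs[refCoord[as.logical(row)] - wr[["start"]] + 1L] <- "G"
            classifyOracle(obs, refWin,
                           data.frame(idx = protoToRef(loc, desPos) -
                                          wr[["start"]] + 1L,
                                      alt = rep("G", length(desPos))))
        })
        expect_equal(got, unname(want), info = paste("desired:",
                                                     paste(desPos, collapse = ",")))
    }
})

test_that("N calls never count as substitutions", {
    loc <- exampleLocus()
    nAtDesired <- makeRead(loc, subs = setNames("N", protoToRef(loc, 5)))
    nPlusByst <- makeRead(loc, subs = setNames(c("N", "G"),
                                               protoToRef(loc, c(5, 4))))
    cls <- classifyReads(alignReads(asReads(c(nAtDesired, nPlusByst)), loc),
                         loc)
    expect_equal(as.character(cls), c("wt", "bystander_only"))
})

test_that("tallies conserve reads and map onto the quantification table", {
    cc <- alleleClassCounts(wt = 530, desiredOnly = 300,
                            desiredBystander = 100, bystanderOnly = 50,
                            indel = 20)
    expect_equal(cc@totalAligned, 1000L)
    qt <- toQuantTable(cc)
    expect_equal(qt, c(Reads_aligned_all_amplicons = 1000L,
                       Reads_aligned = 400L, Unmodified = 300L,
                       Modified = 100L, Discarded = 20L))
    expect_equal(unname(toQuantTable(alleleClassCounts())),
                 rep(0L, 5L))
    noByst <- toQuantTable(alleleClassCounts(wt = 5, desiredOnly = 10))
    expect_equal(noByst[["Modified"]], 0L)
    expect_equal(noByst[["Reads_aligned"]], noByst[["Unmodified"]])

    expect_error(alleleClassCounts(wt = -1), "non-negative")

    loc <- exampleLocus()
    fq <- simulateEditedReads(loc, makeEditorModel("abe8e_like"), n = 300,
                              seed = 9)
    aln <- alignReads(fq, loc)
    tal <- tallyAlleles(aln, loc)
    v <- classCountsVector(tal)
    expect_equal(sum(v[-1]), v[["totalAligned"]])
    expect_equal(v[["totalAligned"]], 300L)
})

test_that("editing metrics satisfy the formula identities", {
    qt <- c(Reads_aligned_all_amplicons = 1000, Reads_aligned = 400,
            Unmodified = 300, Modified = 100, Discarded = 20)
    m <- computeMetrics(qt)
    expect_equal(unname(m), c(40, 30, 75, 2))

    # purity is undefined (never 0 or 100) with no desired-carrying reads
    m0 <- computeMetrics(c(Reads_aligned_all_amplicons = 100,
                           Reads_aligned = 0, Unmodified = 0, Modified = 0,
                           Discarded = 0))
    expect_true(is.na(m0[["purity_pct"]]))
    expect_equal(m0[["specified_incl_bystanders_pct"]], 0)

    m100 <- computeMetrics(c(Reads_aligned_all_amplicons = 50,
                             Reads_aligned = 10, Unmodified = 10,
                             Modified = 0, Discarded = 0))
    expect_equal(m100[["purity_pct"]], 100)

    expect_error(computeMetrics(c(Reads_aligned_all_amplicons = 0,
                                  Reads_aligned = 0, Unmodified = 0,
                                  Modified = 0, Discarded = 0)),
                 "input error")

    # invariants over random tallies
    set.seed(33)
    for (i in 1:200) {
        v <- as.integer(rmultinom(1, 2000, prob = runif(5)))
        cc <- alleleClassCounts(wt = v[1], desiredOnly = v[2],
                                desiredBystander = v[3], bystanderOnly = v[4],
                                indel = v[5])
        qt <- toQuantTable(cc)
        m <- computeMetrics(qt)
        expect_gte(m[["specified_incl_bystanders_pct"]],
                   m[["specified_without_bystanders_pct"]])
        expect_equal(m[["specified_incl_bystanders_pct"]] -
                         m[["specified_without_bystanders_pct"]],
                     100 * qt[["Modified"]] /
                         qt[["Reads_aligned_all_amplicons"]])
        if (qt[["Reads_aligned"]] > 0)
            expect_equal(m[["purity_pct"]] * qt[["Reads_aligned"]],
                         100 * qt[["Unmodified"]])
    }
})

test_that("founder triage applies both thresholds and is monotone", {
    mk <- function(desired, unwanted, total = 1000L) {
        alleleClassCounts(wt = total - desired - unwanted,
                          desiredOnly = desired, bystanderOnly = unwanted)
    }
    expect_equal(founderTriage(mk(261, 10))$call, "high_confidence")
    expect_equal(founderTriage(mk(199, 0))$call, "not_high_confidence")
    expect_equal(founderTriage(mk(500, 26))$call, "not_high_confidence")
    # boundary: inclusive by default, strict on request
    expect_equal(founderTriage(mk(200, 25))$call, "high_confidence")
    expect_equal(founderTriage(mk(200, 25),
                               triageThresholds(strictUnwanted = TRUE))$call,
                 "not_high_confidence")
    # monotone in desired-only at fixed unwanted
    calls <- vapply(seq(0, 900, by = 50), function(d)
        founderTriage(mk(d, 20))$call, "")
    flips <- rle(calls)
    expect_lte(length(flips$values), 2L)
    expect_equal(unique(calls[calls != calls[1]]), "high_confidence")
})
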