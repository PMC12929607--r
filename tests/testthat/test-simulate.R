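test_that("editor presets have the documented window structure", {
    abe9 <- makeEditorModel("abe9_like")
    w9 <- abe9@windowProfile
    expect_setequal(names(w9), c("4", "5", "6"))            # zero elsewhere
    expect_true(all(w9[c("5", "6")] > w9["4"]))
    abe8e <- makeEditorModel("abe8e_like")
    w8 <- abe8e@windowProfile
    expect_true(all(as.integer(names(w8)) %in% 2:14))
    expect_equal(names(which.max(w8)), "5")
    expect_gt(w8[["13"]], 0)                                # extended shoulder
    # matched peak activity between presets
    expect_equal(max(w8), max(w9))

    expect_error(makeEditorModel(windowProfile = c(`5` = 1.2)), "\\[0, 1\\]")
    expect_error(seqNoise(subError = 0.2), "input error")
})

test_that("founder simulation is seeded and honours forced outcomes", {
    loc <- exampleLocus()
    wtOnly <- makeEditorModel(windowProfile = c(`5` = 1), engageProb = 0)
    f0 <- simulateFounder(loc, wtOnly, K = 1, seed = 1)
    expect_equal(lineageAlleles(f0), as.character(referenceSeq(loc)))

    forced <- makeEditorModel(windowProfile = c(`5` = 1), engageProb = 1,
                              indelProb = 0)
    f1 <- simulateFounder(loc, forced, K = 1, seed = 1)
    want <- makeRead(loc, subs = setNames("G", protoToRef(loc, 5)))
    expect_equal(lineageAlleles(f1), want)

    ed <- makeEditorModel("abe8e_like")
    fa <- simulateFounder(loc, ed, K = 4, seed = 99)
    fb <- simulateFounder(loc, ed, K = 4, seed = 99)
    expect_equal(lineageAlleles(fa), lineageAlleles(fb))
    expect_equal(lineageWeights(fa), lineageWeights(fb))
    expect_equal(sum(lineageWeights(fa)), 1)
})

test_that("noise-free single-lineage reads classify 100% to one class", {
    loc <- exampleLocus()
    forced <- makeEditorModel(windowProfile = c(`5` = 1), engageProb = 1,
                              indelProb = 0)
    f <- simulateFounder(loc, forced, K = 1, seed = 3)
    reads <- simulateReads(f, n = 50, noise = seqNoise(subError = 0), seed = 4)
    cls <- classifyReads(alignReads(reads, loc), loc)
    expect_true(all(cls == "desired_only"))
})

test_that("lineage weights are recovered within binomial bounds", {
    loc <- exampleLocus()
    wt <- as.character(referenceSeq(loc))
    edited <- makeRead(loc, subs = setNames("G", protoToRef(loc, 5)))
    f <- mosaicFounder("demoA", c(wt, edited), c(0.7, 0.3))
    n <- 4000L
    reads <- simulateReads(f, n = n, noise = seqNoise(subError = 0),
                           seed = 21)
    cls <- classifyReads(alignReads(reads, loc), loc)
    frac <- mean(cls == "desired_only")
    expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("expected purity follows the independence product", {
    loc <- exampleLocus()                       # desired A5; adenines 4,6 active
    ed <- makeEditorModel(windowProfile = c(`4` = 0.1, `5` = 1, `6` = 0.2),
                          engageProb = 1)
    expect_equal(expectedPurity(ed, loc), 100 * 0.9 * 0.8)
    expect_equal(expectedPurity(
        makeEditorModel(windowProfile = c(`5` = 0.8)), loc), 100)
    expect_equal(expectedPurity(
        makeEditorModel(windowProfile = c(`5` = 0.5, `6` = 1)), loc), 0)
})

test_that("Monte-Carlo purity converges to the closed form", {
    loc <- exampleLocus()
    ed <- makeEditorModel(windowProfile = c(`4` = 0.15, `5` = 1, `6` = 0.35),
                          engageProb = 1, indelProb = 0)
    n <- 4000L
    reads <- simulateEditedReads(loc, ed, n = n,
                                 noise = seqNoise(subError = 0), seed = 31)
    m <- computeMetrics(toQuantTable(tallyAlleles(alignReads(reads, loc),
                                                  loc)))
    pExp <- expectedPurity(ed, loc) / 100
    se <- sqrt(pExp * (1 - pExp) / n)       # every read carries the desired edit
    expect_lt(abs(m[["purity_pct"]] / 100 - pExp), 3 * se)
})

test_that("simulated FASTQ is byte-identical under a fixed seed", {
    loc <- exampleLocus()
    ed <- makeEditorModel("abe9_like")
    f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
    simulateEditedReads(loc, ed, n = 100, seed = 77, path = f1)
    simulateEditedReads(loc, ed, n = 100, seed = 77, path = f2)
    expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

    fndr <- simulateFounder(loc, ed, K = 3, seed = 5)
    g1 <- tempfile(fileext = ".fastq"); g2 <- tempfile(fileext = ".fastq")
    simulateReads(fndr, n = 50, seed = 6, path = g1)
    simulateReads(fndr, n = 50, seed = 6, path = g2)
    expect_equal(unname(tools::md5sum(g1)), unname(tools::md5sum(g2)))

    # round trip through FASTQ preserves reads
    back <- readFastq(g1)
    expect_length(back, 50L)
    expect_true(all(meanQuality(back) > 20))
})

test_that("off-target panels attenuate engagement by mismatch count", {
    loc <- exampleLocus()
    sp <- as.character(loc@spacer)
    site3 <- sp
    for (p in c(3L, 9L, 15L))
        substr(site3, p, p) <- setdiff(c("A", "C", "G", "T"),
                                       substr(sp, p, p))[1]
    sites <- data.frame(site_id = c("OT0", "OT3"),
                        protospacer = c(sp, site3),
                        pam = c("TGG", "TAC"))
    ed <- makeEditorModel("abe8e_like")
    panel <- simulateOfftargetPanel(sp, sites, ed, n = 400,
                                    noise = seqNoise(subError = 0), seed = 12)
    expect_equal(panel$OT0$attenuationFactor, 1)
    expect_equal(panel$OT3$nMismatch, 3L)
    expect_equal(panel$OT3$attenuationFactor, 4^-3)
    cum <- vapply(panel, function(s) {
        aln <- alignReads(s$reads, s$locus)
        cumulativeEditing(aToGFrequencies(buildProfile(aln, s$locus)))
    }, 0)
    expect_gt(cum[["OT0"]], 20 * cum[["OT3"]])   # 64-fold attenuation expected

    expect_error(simulateOfftargetPanel(sp, sites, ed,
                                        attenuation = function(m) 1 + m),
                 "input error")
})
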