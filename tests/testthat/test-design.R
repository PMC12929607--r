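test_that("PAM classification partitions all 48 N-free 3-mers", {
    bases <- c("A", "C", "G", "T")
    pams <- apply(expand.grid(bases, bases, bases), 1L, paste, collapse = "")
    cls <- vapply(pams, classifyPam, "")
    expect_equal(sum(cls == "NGG"), 4L)
    mids <- substr(pams, 2, 2)
    expect_true(all(cls[cls != "NGG"] ==
                        ifelse(mids[cls != "NGG"] %in% c("A", "G"),
                               "NRN", "NYN")))
    expect_equal(classifyPam("AGG"), "NGG")
    expect_equal(classifyPam("TAT"), "NRN")
    expect_equal(classifyPam("GCA"), "NYN")
    expect_error(classifyPam("AG"), "input error")
    expect_error(classifyPam("ANG"), "input error")
})

test_that("spacer enumeration matches brute-force frame search", {
    set.seed(5)
    ctx <- paste0(randomDNA(24), "AAG", randomDNA(24))  # codon 9 = Lys
    cands <- enumerateSpacers(ctx, targetCodon = 9, aaTo = "E", cdsFrame = 1)
    expect_gt(length(cands), 0L)
    # K(AAG) -> E(GAG) needs exactly codon position 1 (context position 25)
    # edited on the sense strand; brute force every 20-nt frame on both
    # strands and keep those placing context position 25 at protospacer 3..11
    # the change is only reachable on the sense strand (AAG has no T), so
    # the oracle enumerates sense frames placing context position 25 in-window
    L <- nchar(ctx)
    p0 <- 24L
    want <- list()
    for (st in 0:(L - 23L)) {
        p <- p0 - st + 1L
        if (p >= 3L && p <= 11L)
            want[[length(want) + 1L]] <- c("sense", st, p)
    }
    got <- lapply(cands, function(x)
        c(x@strand, x@start0, x@targetPositions))
    keyify <- function(l) sort(vapply(l, paste, "", collapse = "|"))
    expect_equal(keyify(got), keyify(want))
    # every candidate places the target adenine inside the window
    expect_true(all(vapply(cands, function(x)
        all(x@targetPositions >= 3 & x@targetPositions <= 11), TRUE)))
    # sorted by proximity to the peak positions 5-6
    d <- vapply(cands, function(x)
        min(pmin(abs(x@targetPositions - 5L), abs(x@targetPositions - 6L))), 0L)
    expect_true(!is.unsorted(d))
})

test_that("two-adenine substitutions require both adenines in-window", {
    set.seed(6)
    ctx <- paste0(randomDNA(24), "AAA", randomDNA(24))  # Lys (AAA), codon 9
    cands <- enumerateSpacers(ctx, targetCodon = 9, aaTo = "G", cdsFrame = 1)
    expect_gt(length(cands), 0L)
    expect_true(all(vapply(cands, function(x)
        length(x@targetPositions) == 2L, TRUE)))
    expect_true(all(vapply(cands, function(x)
        all(x@targetPositions >= 3 & x@targetPositions <= 11), TRUE)))
})

test_that("unreachable amino-acid changes raise a design error", {
    ctx <- paste0(strrep("GC", 12), "ATC", strrep("CT", 12))  # Ile (ATC)
    expect_error(enumerateSpacers(ctx, targetCodon = 9, aaTo = "M",
                                  cdsFrame = 1),
                 "design error")
})

test_that("codon consequences translate jointly and detect effect class", {
    set.seed(8)
    ctx <- paste0(randomDNA(24), "AAG", randomDNA(24))
    candE <- enumerateSpacers(ctx, 9, "E")[[1]]
    consE <- annotateConsequences(candE, candE@targetPositions, ctx, 1)
    expect_equal(consE$codonBefore, "AAG")
    expect_equal(consE$codonAfter, "GAG")
    expect_equal(consE$aaBefore, "K")
    expect_equal(consE$aaAfter, "E")
    expect_equal(consE$effect, "missense")

    # editing both adenines of the same codon is handled jointly: K -> G
    candG <- enumerateSpacers(ctx, 9, "G")[[1]]
    consG <- annotateConsequences(candG, candG@targetPositions, ctx, 1)
    expect_equal(consG$codonAfter, "GGG")
    expect_equal(consG$aaAfter, "G")

    # third-position degeneracy: GCA -> GCG is silent
    ctx2 <- paste0(strrep("CT", 12), "GCA", strrep("GA", 12))
    cand2 <- enumerateSpacers(ctx2, 9, "A", cdsFrame = 1)[[1]]
    cons2 <- annotateConsequences(cand2, cand2@targetPositions, ctx2, 1)
    expect_equal(cons2$effect, "silent")

    # no edits, no consequences
    expect_equal(nrow(annotateConsequences(candE, integer(0), ctx, 1)), 0L)
    expect_error(annotateConsequences(candE,
                                      setdiff(1:20, candE@windowAdenines)[1],
                                      ctx, 1),
                 "input error")
})

test_that("off-target annotation lowercases mismatches and checks lengths", {
    sp <- "GACAAACATACAATGCTGCT"
    same <- annotateOfftarget(sp, sp, sitePam = "AGG")
    expect_equal(same$nMismatch, 0L)
    expect_equal(same$display, sp)
    expect_equal(same$pamClass, "NGG")

    site <- sp
    for (p in c(2L, 9L, 17L))
        substr(site, p, p) <- setdiff(c("A", "C", "G", "T"),
                                      substr(sp, p, p))[1]
    ann <- annotateOfftarget(sp, site)
    expect_equal(ann$nMismatch, 3L)
    expect_equal(ann$positions, c(2L, 9L, 17L))
    mmChars <- strsplit(ann$display, "")[[1]][c(2, 9, 17)]
    expect_true(all(mmChars %in% letters))

    expect_error(annotateOfftarget(substr(sp, 1, 19), sp), "input error")
})
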