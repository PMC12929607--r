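#' @importFrom stats rgamma rnorm runif setNames
NULL

.PRESETS <- list(
    # narrow-window editor: activity confined to positions 4-6, peak at 5,
    # minimal shoulder at 4; low C-to-T / A-to-C / indel rates
    abe9_like = list(
        windowProfile = c(`4` = 0.10, `5` = 0.80, `6` = 0.42),
        engageProb = 0.5, ctotProb = 0.002, atocProb = 0.001,
        indelProb = 0.003),
    # broad-window editor: activity across 2-14 peaking at 5-6 with decaying
    # shoulders (non-zero out to 13-14); higher bystander and indel rates
    abe8e_like = list(
        windowProfile = c(`2` = 0.15, `3` = 0.45, `4` = 0.62, `5` = 0.80,
                          `6` = 0.70, `7` = 0.55, `8` = 0.45, `9` = 0.25,
                          `10` = 0.18, `11` = 0.10, `12` = 0.08, `13` = 0.05,
                          `14` = 0.02),
        engageProb = 0.5, ctotProb = 0.010, atocProb = 0.002,
        indelProb = 0.010))

.DEFAULT_INDEL_LEN <- setNames(rep(1 / 6, 6L), c(-3:-1, 1:3))

#' Construct a generative editor model
#'
#' Either one of the two built-in presets — `"abe9_like"`, a narrow-window
#' editor active only at protospacer positions 4-6 with positions 5-6
#' dominant, or `"abe8e_like"`, a broad-window editor active across positions
#' 2-14 peaking at 5-6 with decaying shoulders — or an explicit per-position
#' conversion profile. The two presets share the same engagement probability
#' and the same peak activity (0.80 at position 5) so that comparisons
#' between them reflect window shape, not bulk activity.
#'
#' @param preset `"abe9_like"` or `"abe8e_like"`; ignored when
#'   `windowProfile` is given.
#' @param windowProfile named numeric, protospacer position -> conversion
#'   probability given engagement.
#' @param engageProb probability a molecule is edited at all.
#' @param ctotProb C-to-T probability at active-window cytosines.
#' @param atocProb A-to-C probability at active-window adenines that were not
#'   converted to G.
#' @param indelProb per-engaged-molecule indel probability.
#' @param indelLenDist named probability vector over lengths -3..-1, 1..3.
#' @param name model label.
#' @return an [EditorModel-class].
#' @examples
#' makeEditorModel("abe9_like")
#' makeEditorModel(windowProfile = c(`5` = 1), engageProb = 1, indelProb = 0)
#' @export
makeEditorModel <- function(preset = c("abe9_like", "abe8e_like"),
                            windowProfile = NULL, engageProb = NULL,
                            ctotProb = NULL, atocProb = NULL,
                            indelProb = NULL,
                            indelLenDist = .DEFAULT_INDEL_LEN,
                            name = NULL) {
    if (is.null(windowProfile)) {
        preset <- match.arg(preset)
        p <- .PRESETS[[preset]]
        if (is.null(name)) name <- preset
    } else {
        p <- list(windowProfile = windowProfile, engageProb = 0.5,
                  ctotProb = 0, atocProb = 0, indelProb = 0)
        if (is.null(name)) name <- "custom"
    }
    pick <- function(x, d) if (is.null(x)) d else x
    new("EditorModel", name = name,
        engageProb = pick(engageProb, p$engageProb),
        windowProfile = p$windowProfile,
        ctotProb = pick(ctotProb, p$ctotProb),
        atocProb = pick(atocProb, p$atocProb),
        indelProb = pick(indelProb, p$indelProb),
        indelLenDist = indelLenDist)
}

#' Sequencing noise model
#'
#' Per-base substitution error probability and the distribution of emitted
#' Phred scores. Defaults (0.001 substitutions/base, Phred ~ N(33, 3)
#' clamped to 2..40) emulate typical well-behaved short-read data and keep a
#' Q30 mean-quality filter meaningful.
#'
#' @param subError per-base substitution error probability (at most 0.05).
#' @param qualMean,qualSd mean and spread of emitted Phred scores.
#' @return a list noise model.
#' @export
seqNoise <- function(subError = 0.001, qualMean = 33, qualSd = 3) {
    if (subError < 0 || subError > 0.05)
        stop("input error: subError must be in [0, 0.05]")
    list(subError = subError, qualMean = qualMean, qualSd = qualSd)
}

# active reference coordinates of an editor on a locus, split by base
.activeSites <- function(locus, editor) {
    wp <- editor@windowProfile
    pos <- as.integer(names(wp))
    refC <- protoToRef(locus, pos)
    base <- substring(as.character(referenceSeq(locus)), refC, refC)
    list(aRef = refC[base == "A"], aW = unname(wp[base == "A"]),
         aProto = pos[base == "A"],
         cRef = refC[base == "C"], cProto = pos[base == "C"])
}

# draw one indel-free edited amplicon per engaged molecule (vectorised),
# then apply per-molecule indels individually
.simulateAlleles <- function(locus, editor, n) {
    refChr <- as.character(referenceSeq(locus))
    alleles <- rep(refChr, n)
    engaged <- runif(n) < editor@engageProb
    ne <- sum(engaged)
    if (ne > 0L) {
        act <- .activeSites(locus, editor)
        chars <- matrix(rep(strsplit(refChr, "")[[1L]], each = ne), nrow = ne)
        for (j in seq_along(act$aRef)) {
            u <- runif(ne)
            toG <- u < act$aW[j]
            toC <- !toG & (runif(ne) < editor@atocProb)
            chars[toG, act$aRef[j]] <- "G"
            chars[toC, act$aRef[j]] <- "C"
        }
        for (j in seq_along(act$cRef)) {
            toT <- runif(ne) < editor@ctotProb
            chars[toT, act$cRef[j]] <- "T"
        }
        edited <- apply(chars, 1L, paste, collapse = "")
        hasIndel <- runif(ne) < editor@indelProb
        if (any(hasIndel)) {
            wr <- quantWindowRange(locus)
            lens <- as.integer(names(editor@indelLenDist))
            for (i in which(hasIndel)) {
                len <- sample(lens, 1L, prob = editor@indelLenDist)
                pos <- sample(wr[[1L]]:wr[[2L]], 1L)
                s <- edited[i]
                if (len < 0L) {          # deletion of |len| bases at pos
                    d <- min(-len, nchar(s) - pos + 1L)
                    edited[i] <- paste0(substr(s, 1L, pos - 1L),
                                        substr(s, pos + d, nchar(s)))
                } else {                 # insertion of len bases after pos
                    ins <- paste(sample(c("A", "C", "G", "T"), len,
                                        replace = TRUE), collapse = "")
                    edited[i] <- paste0(substr(s, 1L, pos), ins,
                                        substr(s, pos + 1L, nchar(s)))
                }
            }
        }
        alleles[engaged] <- edited
    }
    alleles
}

#' Simulate a mosaic founder
#'
#' A founder is modelled as `K` cell lineages with Dirichlet(`alpha`)
#' weights; each lineage's allele is drawn once from the editor model (with
#' probability `engageProb` the molecule is edited: each active-window
#' adenine converts independently with its profile probability, cytosines
#' with `ctotProb`, and an indel occurs with `indelProb`). Reproducible
#' under `seed`.
#'
#' @param locus an [AmpliconLocus-class].
#' @param editor an [EditorModel-class].
#' @param K number of lineages.
#' @param alpha Dirichlet concentration (1 = uniform over the simplex).
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return a [MosaicFounder-class].
#' @examples
#' simulateFounder(exampleLocus(), makeEditorModel("abe9_like"), K = 4,
#'                 seed = 1)
#' @export
simulateFounder <- function(locus, editor, K = 4L, alpha = 1, seed = NULL) {
    stopifnot(K >= 1L)
    if (!is.null(seed)) set.seed(seed)
    w <- rgamma(K, shape = alpha)
    if (sum(w) == 0) w <- rep(1, K)
    mosaicFounder(locusId(locus), .simulateAlleles(locus, editor, K),
                  w / sum(w))
}

# apply sequencing noise to a vector of molecule sequences and emit reads
.emitReads <- function(seqs, noise, idPrefix, labels = NULL) {
    n <- length(seqs)
    outSeq <- character(n)
    outQual <- character(n)
    bases <- c("A", "C", "G", "T")
    for (i in seq_len(n)) {
        ch <- strsplit(seqs[i], "")[[1L]]
        L <- length(ch)
        if (noise$subError > 0) {
            err <- which(runif(L) < noise$subError)
            if (length(err)) {
                orig <- match(ch[err], bases)
                shift <- sample.int(3L, length(err), replace = TRUE)
                ch[err] <- bases[((orig - 1L + shift) %% 4L) + 1L]
            }
        }
        q <- pmin(40L, pmax(2L, as.integer(round(
            rnorm(L, noise$qualMean, noise$qualSd)))))
        outSeq[i] <- paste(ch, collapse = "")
        outQual[i] <- rawToChar(as.raw(q + 33L))
    }
    reads <- QualityScaledDNAStringSet(DNAStringSet(outSeq),
                                       PhredQuality(outQual))
    names(reads) <- if (is.null(labels))
        sprintf("%s_%06d", idPrefix, seq_len(n))
    else sprintf("%s_%06d_%s", idPrefix, seq_len(n), labels)
    reads
}

#' Simulate reads from a mosaic founder
#'
#' Each read samples a lineage by weight and emits that lineage's allele over
#' the full amplicon, with independent per-base substitution errors and Phred
#' scores from the noise model. With a fixed seed the output (including a
#' written FASTQ file) is byte-identical across runs.
#'
#' @param founder a [MosaicFounder-class].
#' @param n number of reads.
#' @param noise a [seqNoise()] model.
#' @param seed integer seed.
#' @param path optional FASTQ output path (`.gz` to compress).
#' @return a `QualityScaledDNAStringSet`; read names carry the lineage index
#'   (`_L<k>` suffix). Written to `path` as FASTQ when given.
#' @examples
#' f <- simulateFounder(exampleLocus(), makeEditorModel("abe9_like"),
#'                      K = 2, seed = 1)
#' simulateReads(f, n = 5, seed = 2)
#' @export
simulateReads <- function(founder, n, noise = seqNoise(), seed = NULL,
                          path = NULL) {
    stopifnot(is(founder, "MosaicFounder"), n >= 1L)
    if (!is.null(seed)) set.seed(seed)
    lin <- sample.int(length(founder@weights), n, replace = TRUE,
                      prob = founder@weights)
    reads <- .emitReads(founder@alleles[lin], noise,
                        idPrefix = founder@locusId,
                        labels = sprintf("L%d", lin))
    if (!is.null(path)) writeFastq(reads, path)
    reads
}

#' Simulate independently edited molecules
#'
#' Unlike [simulateReads()], every read is its own molecule drawn from the
#' editor model, so per-position A-to-G read frequencies are binomial with
#' success probability `engageProb * w_i`. This is the generator used for
#' parameter-recovery checks and off-target panels.
#'
#' @inheritParams simulateFounder
#' @inheritParams simulateReads
#' @return a `QualityScaledDNAStringSet` of `n` reads.
#' @examples
#' simulateEditedReads(exampleLocus(), makeEditorModel("abe9_like"), n = 5,
#'                     seed = 1)
#' @export
simulateEditedReads <- function(locus, editor, n, noise = seqNoise(),
                                seed = NULL, path = NULL) {
    stopifnot(n >= 1L)
    if (!is.null(seed)) set.seed(seed)
    seqs <- .simulateAlleles(locus, editor, n)
    reads <- .emitReads(seqs, noise, idPrefix = locusId(locus))
    if (!is.null(path)) writeFastq(reads, path)
    reads
}

#' Closed-form expected product purity under the editor model
#'
#' Under per-position conditional independence given engagement, the
#' probability that a molecule carrying the full desired-edit set acquires no
#' bystander edit is the product over non-desired active adenines `b` of
#' `(1 - w_b) (1 - atocProb)` times the product over active cytosines of
#' `(1 - ctotProb)`, expressed as a percentage. This is the closed-form
#' companion of the read-level purity metric for indel-free molecules.
#'
#' @param editor an [EditorModel-class].
#' @param locus an [AmpliconLocus-class].
#' @return expected purity percentage.
#' @examples
#' ed <- makeEditorModel(windowProfile = c(`4` = 0.1, `5` = 1, `6` = 0.2),
#'                       engageProb = 1)
#' expectedPurity(ed, exampleLocus())  # 100 * 0.9 * 0.8 = 72
#' @export
expectedPurity <- function(editor, locus) {
    act <- .activeSites(locus, editor)
    desired <- desiredEdits(locus)$pos
    bys <- !(act$aProto %in% desired)
    100 * prod((1 - act$aW[bys]) * (1 - editor@atocProb)) *
        prod(rep(1 - editor@ctotProb, length(act$cRef)))
}

#' Simulate an off-target site panel
#'
#' Builds one synthetic amplicon per candidate off-target site (the site's
#' protospacer and PAM embedded in generated flanks), attenuates the editor's
#' engagement probability by `attenuation(m)` where `m` is the number of
#' spacer/site mismatches, and simulates independently edited reads per site.
#' The attenuation function must satisfy `attenuation(0) == 1` and be
#' non-increasing in `m`; the default is `4^-m`.
#'
#' @param spacer the on-target 20-nt spacer.
#' @param sites data.frame with columns `site_id`, `protospacer` (20 nt) and
#'   `pam`.
#' @param editor an [EditorModel-class].
#' @param attenuation function mapping mismatch count to a factor in \[0, 1\].
#' @param n reads per site.
#' @param noise a [seqNoise()] model.
#' @param seed integer seed.
#' @param dir optional directory to write one FASTQ per site.
#' @param flank flank length of the synthetic site amplicons.
#' @return named list per site with elements `locus`, `reads`, `nMismatch`,
#'   `attenuationFactor` and (when `dir` is given) `path`.
#' @export
simulateOfftargetPanel <- function(spacer, sites, editor,
                                   attenuation = function(m) 4^(-m),
                                   n = 1000L, noise = seqNoise(),
                                   seed = NULL, dir = NULL, flank = 30L) {
    stopifnot(all(c("site_id", "protospacer", "pam") %in% names(sites)))
    att <- vapply(0:10, attenuation, 0)
    if (abs(att[1L] - 1) > 1e-12 || any(diff(att) > 1e-12))
        stop("input error: attenuation must satisfy attenuation(0) = 1 and be non-increasing")
    if (!is.null(seed)) set.seed(seed)
    if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out <- vector("list", nrow(sites))
    for (i in seq_len(nrow(sites))) {
        mm <- annotateOfftarget(spacer, sites$protospacer[i])$nMismatch
        fac <- attenuation(mm)
        ed <- editor
        ed@engageProb <- editor@engageProb * fac
        up <- paste(sample(c("A", "C", "G", "T"), flank, TRUE), collapse = "")
        down <- paste(sample(c("A", "C", "G", "T"), flank, TRUE), collapse = "")
        loc <- ampliconLocus(sites$site_id[i],
                             paste0(up, toupper(sites$protospacer[i]),
                                    toupper(sites$pam[i]), down),
                             sites$protospacer[i], sites$pam[i],
                             spacerStart = flank)
        reads <- simulateEditedReads(loc, ed, n = n, noise = noise)
        res <- list(locus = loc, reads = reads, nMismatch = mm,
                    attenuationFactor = fac)
        if (!is.null(dir)) {
            res$path <- file.path(dir, paste0(sites$site_id[i], ".fastq"))
            writeFastq(reads, res$path)
        }
        out[[i]] <- res
    }
    names(out) <- sites$site_id
    out
}
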