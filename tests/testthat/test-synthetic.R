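test_that("generation is fully determined by the seed", {
    a <- simulatePeptides(nPos = 20, nNeg = 20, seed = 99)
    b <- simulatePeptides(nPos = 20, nNeg = 20, seed = 99)
    c <- simulatePeptides(nPos = 20, nNeg = 20, seed = 100)
    expect_identical(as.character(peptideSequences(a)),
                     as.character(peptideSequences(b)))
    expect_false(identical(as.character(peptideSequences(a)),
                           as.character(peptideSequences(c))))

    # byte-identical FASTA output
    fa <- tempfile(); fb <- tempfile()
    writePeptideFasta(a, fa)
    writePeptideFasta(b, fb)
    expect_identical(readLines(fa), readLines(fb))
})

test_that("invalid configurations are rejected", {
    expect_error(simulatePeptides(effect = 1.5), "effect")
    expect_error(simulatePeptides(lengthRange = c(5, 30)),
                 "terminalWindow")
    expect_error(simulatePeptides(nPos = 0), "nPos")
    expect_error(simulatePeptides(background = c(A = 1)), "missing")
})

test_that("null data (effect = 0) draws both classes from the background", {
    pep <- simulatePeptides(nPos = 100, nNeg = 100,
                            lengthRange = c(25, 25), effect = 0, seed = 7)
    # chi-square goodness of fit against the uniform background
    res <- strsplit(paste(as.character(peptideSequences(pep)),
                          collapse = ""), "")[[1]]
    counts <- table(factor(res, levels = AA))
    gof <- chisq.test(counts, p = rep(1 / 20, 20))
    expect_gt(gof$p.value, 0.01)

    # positives and negatives are exchangeable: residue frequencies agree
    isPos <- rep(c(TRUE, FALSE), each = 100)
    posRes <- table(factor(strsplit(paste(
        as.character(peptideSequences(pep))[isPos], collapse = ""),
        "")[[1]], levels = AA))
    negRes <- table(factor(strsplit(paste(
        as.character(peptideSequences(pep))[!isPos], collapse = ""),
        "")[[1]], levels = AA))
    expect_gt(suppressWarnings(
        chisq.test(rbind(posRes, negRes))$p.value), 0.01)
})

test_that("effect = 1 plants the documented residue enrichment with terminal boost", {
    pep <- simulatePeptides(nPos = 150, nNeg = 150,
                            lengthRange = c(30, 30), effect = 1,
                            seed = 8)
    seqs <- as.character(peptideSequences(pep))
    lab <- classLabels(pep)
    freqOf <- function(ss, set, positions) {
        res <- unlist(lapply(ss, function(s)
            strsplit(s, "")[[1]][positions]))
        mean(res %in% set)
    }
    enr <- enrichedResidues()
    # positives carry more of the positive-enriched set than negatives do
    expect_gt(freqOf(seqs[lab == 1], enr$positive, 1:30),
              freqOf(seqs[lab == 0], enr$positive, 1:30))
    expect_gt(freqOf(seqs[lab == 0], enr$negative, 1:30),
              freqOf(seqs[lab == 1], enr$negative, 1:30))
    # the terminal windows are hotter than the interior
    expect_gt(freqOf(seqs[lab == 1], enr$positive, c(1:10, 21:30)),
              freqOf(seqs[lab == 1], enr$positive, 11:20))
})

test_that("Relief ranks planted terminal BpB features above background on biased data", {
    # mix the 40 planted BpB features with 40 pure-noise columns; the
    # planted block should dominate the top of the ranking
    gap <- vapply(1:10, function(s) {
        pep <- simulatePeptides(nPos = 40, nNeg = 40, effect = 1,
                                seed = s)
        X <- encodeFeatures(pep, "bpb")
        set.seed(s)
        noise <- matrix(runif(nrow(X) * 40), ncol = 40,
                        dimnames = list(NULL, paste0("noise", 1:40)))
        rel <- reliefRank(cbind(X, noise), classLabels(pep))
        rankPos <- match(seq_len(80), featureRanking(rel))
        median(rankPos[1:40]) - median(rankPos[41:80])
    }, numeric(1))
    expect_lt(median(gap), 0)
})
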