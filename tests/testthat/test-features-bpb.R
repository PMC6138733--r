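test_that("posterior tables match hand counts with and without smoothing", {
    # degenerate single-class composition, no smoothing
    pep <- PeptideSet(c(p = "AAAAAAAAAA", n = "CCCCCCCCCC"),
                      labels = c(1L, 0L))
    mod <- fitBpB(pep, m = 10, pseudocount = 0)
    expect_equal(unname(bpbTables(mod)$Npos[, "A"]), rep(1, 10))
    expect_equal(sum(bpbTables(mod)$Npos[, setdiff(AA, "A")]), 0)

    # add-one smoothing: P(A at N-pos 1 | pos) = (1 + 1) / (2 + 20)
    pep2 <- PeptideSet(c(p1 = "ACACACACAC", p2 = "CCCCCCCCCC",
                         n1 = "DDDDDDDDDD", n2 = "EEEEEEEEEE"),
                       labels = c(1L, 1L, 0L, 0L))
    mod2 <- fitBpB(pep2, m = 2, pseudocount = 1)
    expect_equal(unname(bpbTables(mod2)$Npos[1, "A"]), 2 / 22)
    expect_equal(unname(bpbTables(mod2)$Npos[1, "C"]), 2 / 22)
    expect_equal(unname(bpbTables(mod2)$Npos[1, "D"]), 1 / 22)

    # every position row sums to 1; strict interior with smoothing
    for (tab in bpbTables(mod2)) {
        expect_equal(unname(rowSums(tab)), rep(1, 2), tolerance = 1e-12)
        expect_true(all(tab > 0 & tab < 1))
    }
})

test_that("identical positive and negative training sets give identical class tables", {
    set.seed(7)
    seqs <- replicate(6, randSeq(12))
    pep <- PeptideSet(c(seqs, seqs),
                      ids = paste0("r", 1:12),
                      labels = rep(c(1L, 0L), each = 6))
    mod <- fitBpB(pep)
    expect_identical(bpbTables(mod)$Npos, bpbTables(mod)$Nneg)
    expect_identical(bpbTables(mod)$Cpos, bpbTables(mod)$Cneg)
})

test_that("encoding emits 4m gathered features in the documented block order", {
    set.seed(42)
    pep <- simulatePeptides(nPos = 10, nNeg = 10, seed = 9)
    mod <- fitBpB(pep)
    X <- encodeBpB(mod, pep)
    expect_identical(dim(X), c(20L, 40L))
    expect_identical(colnames(X)[c(1, 11, 21, 31)],
                     c("BpB_N_pos_1", "BpB_C_pos_1", "BpB_N_neg_1",
                       "BpB_C_neg_1"))

    # every encoded value is a gather from a model table
    tabs <- bpbTables(mod)
    expect_true(all(X[, 1:10] %in% tabs$Npos))
    expect_true(all(X[, 11:20] %in% tabs$Cpos))
    expect_true(all(X[, 21:30] %in% tabs$Nneg))
    expect_true(all(X[, 31:40] %in% tabs$Cneg))

    # length exactly m on fixed-length training data: the N and C windows
    # coincide for query and training sequences, so the paired blocks match
    pep10 <- simulatePeptides(nPos = 10, nNeg = 10,
                              lengthRange = c(10, 10), seed = 9)
    mod10 <- fitBpB(pep10)
    v <- encodeBpB(mod10, "ACDEFGHIKL")
    expect_equal(v[1, 1:10], v[1, 11:20], ignore_attr = TRUE)
    expect_equal(v[1, 21:30], v[1, 31:40], ignore_attr = TRUE)

    # dimension is 4m regardless of sequence length
    expect_identical(ncol(encodeBpB(mod, randSeq(25))), 40L)
})

test_that("C-terminal window reads the last m residues left-to-right", {
    pep <- PeptideSet(c(p = "AAWWWWWWWWWWCC", n = "DDDDDDDDDDDDDD"),
                      labels = c(1L, 0L))
    mod <- fitBpB(pep, m = 2, pseudocount = 0)
    # C-window of the positive is "CC": position 1 = residue L-1, pos 2 = L
    expect_equal(unname(bpbTables(mod)$Cpos[, "C"]), c(1, 1))
    expect_equal(unname(bpbTables(mod)$Npos[, "A"]), c(1, 1))
})

test_that("fit and encode reject short sequences and missing classes by record", {
    pep <- PeptideSet(c(longpos = "ACDEFGHIKLMN", shorty = "ACDEF"),
                      labels = c(1L, 0L))
    expect_error(fitBpB(pep, m = 10), "shorty")
    onecls <- PeptideSet(c(a = "ACDEFGHIKL", b = "ACDEFGHIKL"),
                         labels = c(1L, 1L))
    expect_error(fitBpB(onecls), "both classes")
    ok <- simulatePeptides(nPos = 5, nNeg = 5, seed = 1)
    mod <- fitBpB(ok)
    expect_error(encodeBpB(mod, c(tiny = "ACDEF")), "tiny")
})

test_that("held-out encodings never read held-out labels", {
    pep <- simulatePeptides(nPos = 20, nNeg = 20, seed = 3)
    train <- pep[1:30]
    test <- pep[31:40]
    mod <- fitBpB(train)
    enc1 <- encodeBpB(mod, test)
    flipped <- PeptideSet(as.character(peptideSequences(test)),
                          ids = peptideIds(test),
                          labels = 1L - classLabels(test))
    expect_identical(encodeBpB(mod, flipped), enc1)
})

test_that("uniform tables encode every sequence as a constant 0.05 vector", {
    uni <- matrix(1 / 20, nrow = 10, ncol = 20,
                  dimnames = list(NULL, AA))
    mod <- new("BpBModel", m = 10L, pseudocount = 1,
               alphabet = AA,
               tables = list(Npos = uni, Cpos = uni, Nneg = uni,
                             Cneg = uni))
    expect_equal(unname(encodeBpB(mod, randSeq(15))[1, ]), rep(0.05, 40))
})

test_that("BpB model serialization reproduces encodings at full precision", {
    pep <- simulatePeptides(nPos = 15, nNeg = 15, seed = 8)
    mod <- fitBpB(pep)
    path <- tempfile(fileext = ".json")
    writeBpBModel(mod, path)
    back <- readBpBModel(path)
    expect_equal(encodeBpB(back, pep), encodeBpB(mod, pep),
                 tolerance = 1e-14)
    # the serialized file itself is deterministic
    path2 <- tempfile(fileext = ".json")
    writeBpBModel(mod, path2)
    expect_identical(readLines(path), readLines(path2))
})
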