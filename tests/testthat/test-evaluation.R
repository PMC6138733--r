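test_that("confusion metrics follow the defining formulas", {
    m <- confusionMetrics(TP = 10, FP = 0, TN = 10, FN = 0)
    expect_equal(unname(m), c(1, 1, 1, 1))

    m2 <- confusionMetrics(TP = 6, FP = 2, TN = 8, FN = 4)
    expect_equal(m2[["sn"]], 6 / 10)
    expect_equal(m2[["sp"]], 8 / 10)
    expect_equal(m2[["acc"]], 14 / 20)
    expect_equal(m2[["mcc"]],
                 (6 * 8 - 2 * 4) / sqrt(10 * 8 * 10 * 12))

    # named-vector calling convention
    expect_identical(confusionMetrics(c(TP = 6, FP = 2, TN = 8, FN = 4)),
                     m2)

    # zero denominator factor: MCC reported as 0 with a warning
    expect_warning(z <- confusionMetrics(TP = 0, FP = 0, TN = 5, FN = 5),
                   "MCC")
    expect_identical(z[["mcc"]], 0)
    expect_error(confusionMetrics(TP = 0, FP = 0, TN = 0, FN = 0), "zero")
    expect_error(confusionMetrics(TP = -1, FP = 1, TN = 1, FN = 1),
                 "non-negative")
})

test_that("stratified folds partition each class to within one sample", {
    y <- rep(c(0L, 1L), each = 107)
    folds <- stratifiedFolds(y, k = 10, seed = 1)
    expect_setequal(unique(folds), 1:10)
    perClass <- table(folds, y)
    expect_true(all(perClass %in% c(10, 11)))
    expect_true(all(table(folds) %in% c(21, 22)))
    expect_identical(folds, stratifiedFolds(y, k = 10, seed = 1))
    expect_false(identical(folds, stratifiedFolds(y, k = 10, seed = 2)))
    expect_error(stratifiedFolds(rep(c(0L, 1L), c(5, 20)), k = 10),
                 "at least k")
})

test_that("ROC sweep and trapezoidal AUC match hand values and handle ties", {
    r <- rocAuc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))
    expect_equal(r$auc, 0.75)
    expect_equal(r$roc[1, ], c(FPR = 0, TPR = 0))
    expect_equal(r$roc[nrow(r$roc), ], c(FPR = 1, TPR = 1))

    perfect <- rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
    expect_equal(perfect$auc, 1)
    allTied <- rocAuc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))
    expect_equal(allTied$auc, 0.5)
    expect_identical(nrow(allTied$roc), 2L)
    expect_error(rocAuc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("trapezoidal AUC equals Mann-Whitney pair counting on random score vectors", {
    set.seed(71)
    for (rep in 1:200) {
        n <- sample(4:30, 1)
        y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
        s <- round(runif(n), sample(1:3, 1))  # coarse rounding forces ties
        expect_equal(rocAuc(s, y)$auc, aucOracle(s, y), tolerance = 1e-12)
    }
})

test_that("cross-validation pools counts consistently and is seed-deterministic", {
    pep <- simulatePeptides(nPos = 25, nNeg = 25, seed = 12)
    rep1 <- crossValidate(pep, encoders = "bpb",
                          classifiers = c("nb", "lr"), k = 5, seed = 3)
    cnt <- confusionCounts(rep1)
    expect_identical(cnt[["TP"]] + cnt[["FN"]], 25L)
    expect_identical(cnt[["TN"]] + cnt[["FP"]], 25L)
    expect_identical(nrow(pooledScores(rep1)), 50L)
    expect_true(all(pooledScores(rep1)$score >= 0 &
                    pooledScores(rep1)$score <= 1))

    rep2 <- crossValidate(pep, encoders = "bpb",
                          classifiers = c("nb", "lr"), k = 5, seed = 3)
    expect_identical(pooledScores(rep1), pooledScores(rep2))
    expect_error(crossValidate(pep, encoders = "bogus"), "encoder")
    expect_error(crossValidate(pep, classifiers = "svm"), "unknown")
})

test_that("leave-one-out is a valid boundary case of the fold scheme", {
    pep <- simulatePeptides(nPos = 10, nNeg = 10, seed = 13)
    rep <- crossValidate(pep, encoders = "ctd", classifiers = "lr",
                         k = 10, seed = 1)
    expect_identical(sum(confusionCounts(rep)), 20L)
})

test_that("strongly separated synthetic data scores near-perfectly, permuted labels at chance", {
    pep <- simulatePeptides(nPos = 50, nNeg = 50, effect = 1, seed = 14)
    rep <- crossValidate(pep, encoders = "bpb",
                         classifiers = c("nb", "lr"), k = 5, seed = 1)
    expect_gt(performance(rep)[["acc"]], 0.9)
    expect_gt(performance(rep)[["auc"]], 0.95)

    # label permutation kills the signal
    aucs <- vapply(1:10, function(s) {
        y <- .withSeedForTest(s, sample(classLabels(pep)))
        perm <- PeptideSet(as.character(peptideSequences(pep)),
                           ids = peptideIds(pep), labels = y)
        crossValidate(perm, encoders = "bpb",
                      classifiers = c("nb", "lr"), k = 5, seed = 1)@auc
    }, numeric(1))
    se <- sd(aucs) / sqrt(length(aucs))
    expect_lt(abs(mean(aucs) - 0.5), 3 * se + 0.02)
})

test_that("per-fold metrics and report export round-trip", {
    pep <- simulatePeptides(nPos = 20, nNeg = 20, seed = 15)
    rep <- crossValidate(pep, encoders = "bpb", classifiers = "nb",
                         k = 4, seed = 2, perFold = TRUE)
    expect_length(rep@perFold, 4L)
    path <- tempfile(fileext = ".json")
    scoresPath <- tempfile(fileext = ".tsv")
    writeEvalReport(rep, path, scoresPath = scoresPath)
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    expect_equal(payload$auc, rep@auc)
    expect_equal(unlist(payload$counts),
                 structure(as.numeric(confusionCounts(rep)),
                           names = names(confusionCounts(rep))),
                 tolerance = 0)
    tab <- read.delim(scoresPath)
    expect_identical(nrow(tab), 40L)
})
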