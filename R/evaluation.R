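#' Confusion-matrix metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/(TP+TN+FP+FN)` and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN))`. When any
#' factor of the MCC denominator is zero the MCC is reported as 0 (with a
#' warning); an Sn or Sp whose class is absent is `NaN`.
#'
#' @param TP,FP,TN,FN Non-negative integer counts; alternatively pass a
#'   single named vector as `TP`.
#' @return Named numeric vector `sn`, `sp`, `acc`, `mcc`.
#' @examples
#' confusionMetrics(TP = 83, FP = 12, TN = 95, FN = 24)
#' @export
confusionMetrics <- function(TP, FP = NULL, TN = NULL, FN = NULL) {
    if (is.null(FP) && length(TP) == 4L && !is.null(names(TP))) {
        cnt <- TP
        TP <- cnt[["TP"]]; FP <- cnt[["FP"]]
        TN <- cnt[["TN"]]; FN <- cnt[["FN"]]
    }
    cnt <- c(TP = TP, FP = FP, TN = TN, FN = FN)
    if (any(cnt < 0) || any(cnt != round(cnt)))
        stopValidation("counts must be non-negative integers")
    if (sum(cnt) == 0)
        stopValidation("all confusion counts are zero")
    sn <- TP / (TP + FN)
    sp <- TN / (TN + FP)
    acc <- (TP + TN) / sum(cnt)
    denom <- (TP + FN) * (TP + FP) * (TN + FP) * (TN + FN)
    if (denom == 0) {
        warning("MCC denominator is zero; reporting MCC = 0")
        mcc <- 0
    } else {
        mcc <- (TP * TN - FP * FN) / sqrt(denom)
    }
    c(sn = sn, sp = sp, acc = acc, mcc = mcc)
}

#' Confusion counts implied by printed per-class rates
#'
#' Reconstructs integer confusion counts from a reported sensitivity and
#' specificity on a benchmark of known class sizes:
#' `TP = round(sn * nPos)`, `TN = round(sp * nNeg)`, with `FN` and `FP`
#' as the complements. Useful for internal-consistency checks of
#' published metric tables.
#'
#' @param sn,sp Reported sensitivity and specificity.
#' @param nPos,nNeg Class sizes.
#' @return Named integer vector `TP`, `FP`, `TN`, `FN`.
#' @examples
#' confusionMetrics(impliedCounts(0.776, 0.888, 107, 107))
#' @export
impliedCounts <- function(sn, sp, nPos, nNeg) {
    TP <- as.integer(round(sn * nPos))
    TN <- as.integer(round(sp * nNeg))
    c(TP = TP, FP = as.integer(nNeg) - TN, TN = TN,
      FN = as.integer(nPos) - TP)
}

#' Stratified fold assignment
#'
#' Partitions labelled samples into `k` folds so that per-class counts
#' across folds differ by at most one. Within each class the members are
#' shuffled under `seed`; the folds receiving the leftover samples rotate
#' from class to class so overall fold sizes also stay within one of each
#' other. The same `(y, k, seed)` always yields the same assignment.
#'
#' @param y Binary 0/1 label vector.
#' @param k Number of folds (default 10); no class may be smaller
#'   than `k`.
#' @param seed Integer shuffle seed.
#' @return Integer vector of fold ids in `1..k`, parallel to `y`.
#' @examples
#' table(stratifiedFolds(rep(c(0, 1), each = 107), k = 10, seed = 1))
#' @export
stratifiedFolds <- function(y, k = 10L, seed = 1L) {
    y <- as.integer(y)
    if (anyNA(y)) stopValidation("all samples must be labelled")
    k <- as.integer(k)
    if (k < 2L) stopValidation("k must be >= 2")
    counts <- table(factor(y, levels = c(0L, 1L)))
    if (any(counts < k))
        stopValidation("every class needs at least k = ", k, " samples")
    folds <- integer(length(y))
    offset <- 0L
    .withSeed(seed, {
        for (cls in c(0L, 1L)) {
            members <- sample(which(y == cls))
            ids <- ((seq_along(members) - 1L + offset) %% k) + 1L
            folds[members] <- ids
            offset <- (offset + length(members)) %% k
        }
    })
    folds
}

#' ROC curve and AUC
#'
#' Builds the ROC by sweeping the decision threshold over the distinct
#' score values from high to low (tied scores enter as one group) and
#' computes the AUC by the trapezoidal rule, which equals the normalised
#' Mann-Whitney statistic with half credit for cross-class score ties.
#'
#' @param scores Numeric positive-class scores.
#' @param labels Binary 0/1 truth labels; both classes must be present.
#' @return List with `roc` (two-column matrix of FPR, TPR points, starting
#'   at (0, 0) and ending at (1, 1)) and `auc`.
#' @examples
#' rocAuc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))$auc  # 0.75
#' @export
rocAuc <- function(scores, labels) {
    labels <- as.integer(labels)
    if (length(scores) != length(labels))
        stopValidation("scores and labels sizes differ")
    nPos <- sum(labels == 1L)
    nNeg <- sum(labels == 0L)
    if (nPos == 0L || nNeg == 0L)
        stopValidation("both classes must be present")
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]
    yPos <- labels[ord] == 1L
    isGroupEnd <- c(s[-1L] != s[-length(s)], TRUE)
    tpr <- c(0, cumsum(yPos)[isGroupEnd] / nPos)
    fpr <- c(0, cumsum(!yPos)[isGroupEnd] / nNeg)
    auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
    list(roc = cbind(FPR = fpr, TPR = tpr), auc = auc)
}

## Feature matrix for a PeptideSet. "bpb" needs a fitted BpBModel.
.buildFeatureMatrix <- function(pep, encoders, bpb = NULL, nFreq = 10L,
                                scales = NULL) {
    encoders <- match.arg(encoders, c("bpb", "ctd", "dft"),
                          several.ok = TRUE)
    encoders <- intersect(c("bpb", "ctd", "dft"), encoders)
    blocks <- list()
    if ("bpb" %in% encoders) {
        if (is.null(bpb))
            stop("internal: BpB encoder requested without a fitted model")
        blocks$bpb <- encodeBpB(bpb, pep)
    }
    if ("ctd" %in% encoders) blocks$ctd <- encodeCTD(pep)
    if ("dft" %in% encoders) {
        if (is.null(scales))
            scales <- list(hydrophobicity = kyteDoolittleScale(),
                           hydrophilicity = hoppWoodsScale())
        blocks$dft <- encodeDFT(pep, scales = scales, nFreq = nFreq)
    }
    do.call(cbind, unname(blocks))
}

#' Encode a peptide set into a named feature matrix
#'
#' Applies any combination of the three encoders in the canonical order
#' BpB, CTD, DFT and binds the blocks column-wise (40 + 30 + 20 = 90
#' features with all three at the defaults). The BpB block needs a
#' fitted [BpBModel-class]: pass one via `bpb`, or leave `bpb = NULL`
#' to fit it on `x` itself (requires labels; fine for exploratory
#' whole-dataset encoding, but inside cross-validation fit the model on
#' the training fold only).
#'
#' @param x A [PeptideSet-class].
#' @param encoders Subset of `c("bpb", "ctd", "dft")`.
#' @param bpb Optional fitted [BpBModel-class] for the BpB block.
#' @param m,pseudocount BpB window and smoothing, used only when `bpb`
#'   is fitted here.
#' @param nFreq,scales DFT parameters (see [encodeDFT()]).
#' @return Numeric matrix, rows named by record id.
#' @examples
#' pep <- simulatePeptides(nPos = 15, nNeg = 15, seed = 7)
#' dim(encodeFeatures(pep, c("bpb", "ctd", "dft")))  # 30 x 90
#' @export
encodeFeatures <- function(x, encoders = c("bpb", "ctd", "dft"),
                           bpb = NULL, m = 10L, pseudocount = 1,
                           nFreq = 10L, scales = NULL) {
    stopifnot(is(x, "PeptideSet"))
    if ("bpb" %in% encoders && is.null(bpb))
        bpb <- fitBpB(x, m = m, pseudocount = pseudocount)
    .buildFeatureMatrix(x, encoders, bpb = bpb, nFreq = nFreq,
                        scales = scales)
}

## Pooled out-of-fold fused scores on a fixed feature matrix.
.cvScoresMatrix <- function(X, y, classifiers, folds) {
    scores <- numeric(length(y))
    for (f in sort(unique(folds))) {
        test <- folds == f
        models <- lapply(classifiers, function(nm)
            .getTrainer(nm)(X[!test, , drop = FALSE], y[!test]))
        probs <- vapply(models, function(mdl)
            predictProba(mdl, X[test, , drop = FALSE]),
            numeric(sum(test)))
        if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
        scores[test] <- rowMeans(probs)
    }
    scores
}

#' Stratified cross-validation of the full pipeline
#'
#' Runs stratified k-fold cross-validation of the encode / (optional
#' subset) / train / score pipeline on a labelled peptide set. Per fold,
#' the Bi-profile Bayes tables are fitted on the training folds only
#' (the leakage-free default); `wholeDatasetBpB = TRUE` instead fits them
#' once on the complete dataset before splitting, the protocol commonly
#' used with this encoder. Base classifiers are trained per fold and the
#' held-out fused scores are pooled into a single confusion matrix
#' (micro-average), ROC curve and AUC.
#'
#' @param pep A fully labelled [PeptideSet-class].
#' @param encoders Subset of `c("bpb", "ctd", "dft")`.
#' @param classifiers One or two registered classifier names; two are
#'   fused by probability averaging.
#' @param k Number of folds (default 10).
#' @param seed Fold-assignment seed (recorded in the report).
#' @param m,pseudocount,nFreq,scales Encoder parameters.
#' @param featureIndices Optional integer columns of the combined
#'   feature matrix to restrict the classifiers to (e.g. an IFS
#'   selection).
#' @param wholeDatasetBpB Fit BpB tables once on the full dataset instead
#'   of per training fold.
#' @param threshold Decision cut-off on the fused probability
#'   (default 0.5).
#' @param perFold Also record per-fold metric vectors.
#' @return An [EvalReport-class].
#' @examples
#' pep <- simulatePeptides(nPos = 30, nNeg = 30, seed = 3)
#' crossValidate(pep, encoders = "bpb", classifiers = c("nb", "lr"),
#'               k = 5, seed = 1)
#' @export
crossValidate <- function(pep, encoders = "bpb",
                          classifiers = c("nb", "lr"), k = 10L,
                          seed = 1L, m = 10L, pseudocount = 1,
                          nFreq = 10L, scales = NULL,
                          featureIndices = NULL, wholeDatasetBpB = FALSE,
                          threshold = 0.5, perFold = FALSE) {
    stopifnot(is(pep, "PeptideSet"))
    y <- pep@labels
    if (anyNA(y)) stopValidation("all records must be labelled")
    if (!length(encoders) || !all(encoders %in% c("bpb", "ctd", "dft")))
        stopValidation("unknown encoder: ",
                       paste(setdiff(encoders, c("bpb", "ctd", "dft")),
                             collapse = ", "))
    for (nm in classifiers) .getTrainer(nm)  # fail fast on unknown names
    if (length(classifiers) < 1L || length(classifiers) > 2L)
        stopValidation("classifiers must name one or two base learners")
    folds <- stratifiedFolds(y, k = k, seed = seed)
    staticBlocks <- setdiff(encoders, "bpb")
    Xstatic <- if (length(staticBlocks))
        .buildFeatureMatrix(pep, staticBlocks, nFreq = nFreq,
                            scales = scales) else NULL
    bpbFull <- if ("bpb" %in% encoders && wholeDatasetBpB)
        fitBpB(pep, m = m, pseudocount = pseudocount) else NULL
    scores <- numeric(length(y))
    foldMetrics <- list()
    for (f in sort(unique(folds))) {
        test <- folds == f
        if ("bpb" %in% encoders) {
            bpbMod <- if (wholeDatasetBpB) bpbFull else
                fitBpB(pep[!test], m = m, pseudocount = pseudocount)
            Xbpb <- encodeBpB(bpbMod, pep)
            X <- if (is.null(Xstatic)) Xbpb else cbind(Xbpb, Xstatic)
        } else {
            X <- Xstatic
        }
        if (!is.null(featureIndices))
            X <- X[, featureIndices, drop = FALSE]
        models <- lapply(classifiers, function(nm)
            .getTrainer(nm)(X[!test, , drop = FALSE], y[!test]))
        probs <- vapply(models, function(mdl)
            predictProba(mdl, X[test, , drop = FALSE]),
            numeric(sum(test)))
        if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
        scores[test] <- rowMeans(probs)
        if (perFold) {
            cnt <- .countsAt(scores[test], y[test], threshold)
            foldMetrics[[as.character(f)]] <-
                suppressWarnings(confusionMetrics(cnt))
        }
    }
    cnt <- .countsAt(scores, y, threshold)
    roc <- rocAuc(scores, y)
    new("EvalReport", counts = cnt,
        metrics = suppressWarnings(confusionMetrics(cnt)),
        roc = roc$roc, auc = roc$auc,
        scores = data.frame(id = peptideIds(pep), label = y,
                            score = scores),
        foldSeed = as.integer(seed), perFold = foldMetrics)
}

.countsAt <- function(scores, y, threshold) {
    call <- as.integer(scores >= threshold)
    c(TP = sum(call == 1L & y == 1L), FP = sum(call == 1L & y == 0L),
      TN = sum(call == 0L & y == 0L), FN = sum(call == 0L & y == 1L))
}

#' Cross-validated performance of each candidate base classifier
#'
#' Evaluates every candidate classifier alone under the same
#' cross-validation setup and returns one row per candidate with its
#' pooled Sn, Sp, Acc, MCC and AUC -- the table that
#' [selectBasePair()] consumes to pick the best-sensitivity /
#' best-specificity ensemble.
#'
#' @inheritParams crossValidate
#' @param candidates Character vector of registered classifier names.
#' @return `data.frame` with columns `classifier`, `sn`, `sp`, `acc`,
#'   `mcc`, `auc`.
#' @export
evaluateCandidates <- function(pep, candidates = c("nb", "lr", "nna"),
                               encoders = "bpb", k = 10L, seed = 1L,
                               ...) {
    rows <- lapply(candidates, function(nm) {
        rep <- crossValidate(pep, encoders = encoders, classifiers = nm,
                             k = k, seed = seed, ...)
        data.frame(classifier = nm, sn = rep@metrics[["sn"]],
                   sp = rep@metrics[["sp"]], acc = rep@metrics[["acc"]],
                   mcc = rep@metrics[["mcc"]], auc = rep@auc)
    })
    do.call(rbind, rows)
}

#' Export an evaluation report
#'
#' Writes the report as structured JSON plus (optionally) a TSV of the
#' pooled per-sample scores (`id`, `label`, `score`) for external ROC
#' plotting.
#'
#' @param object An [EvalReport-class].
#' @param path Output JSON path.
#' @param scoresPath Optional TSV path for the pooled scores.
#' @return `path`, invisibly.
#' @export
writeEvalReport <- function(object, path, scoresPath = NULL) {
    stopifnot(is(object, "EvalReport"))
    payload <- list(format = "AntiAngioPep/EvalReport", version = 1L,
                    counts = as.list(object@counts),
                    metrics = as.list(object@metrics),
                    auc = object@auc, foldSeed = object@foldSeed,
                    roc = list(FPR = object@roc[, "FPR"],
                               TPR = object@roc[, "TPR"]),
                    perFold = lapply(object@perFold, as.list))
    jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
    if (!is.null(scoresPath))
        utils::write.table(object@scores, scoresPath, sep = "\t",
                           quote = FALSE, row.names = FALSE)
    invisible(path)
}
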