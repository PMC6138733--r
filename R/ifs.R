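#' Incremental feature selection over a ranking
#'
#' Scans prefixes of a feature ranking: for each `k = 1..d` the supplied
#' evaluator scores the subset made of the `k` top-ranked features, and
#' the smallest `k` attaining the maximum score is chosen. The evaluator
#' is typically a cross-validated accuracy (see [makeCVEvaluator()]) but
#' any procedure mapping a set of column indices to a value in `[0, 1]`
#' can drive the scan.
#'
#' @param ranking Integer vector of feature column indices, best first
#'   (usually `featureRanking(reliefRank(...))`).
#' @param evaluator Function taking an integer vector of column indices
#'   and returning an accuracy in `[0, 1]`.
#' @return An [IFSResult-class].
#' @examples
#' res <- ifsSelect(1:5, function(idx) 0.9)  # constant curve
#' res@chosenK  # 1: smallest k wins ties
#' @export
ifsSelect <- function(ranking, evaluator) {
    ranking <- as.integer(ranking)
    d <- length(ranking)
    if (d < 1L) stopValidation("ranking is empty")
    if (anyDuplicated(ranking))
        stopValidation("ranking must not repeat features")
    curve <- numeric(d)
    for (k in seq_len(d)) {
        acc <- evaluator(ranking[seq_len(k)])
        if (!is.numeric(acc) || length(acc) != 1L || !is.finite(acc) ||
            acc < 0 || acc > 1)
            stop("evaluator must return a single value in [0, 1]")
        curve[k] <- acc
    }
    chosenK <- which.max(curve)  # first maximum = smallest k
    new("IFSResult", curve = curve, chosenK = as.integer(chosenK),
        selected = ranking[seq_len(chosenK)], ranking = ranking)
}

#' Cross-validated accuracy evaluator for IFS
#'
#' Returns a closure suitable for [ifsSelect()]: given column indices it
#' trains the named classifier(s) on the corresponding columns of `X`
#' under stratified k-fold cross-validation (folds fixed once from
#' `seed`, so every prefix is scored on the same partition) and returns
#' the pooled accuracy of the (fused) predictions at threshold 0.5.
#'
#' @param X Numeric feature matrix.
#' @param y Binary 0/1 labels.
#' @param classifiers Character vector of one or two registered
#'   classifier names (`"nb"`, `"lr"`, `"nna"`); two are fused by
#'   probability averaging.
#' @param k Number of folds (default 10).
#' @param seed Fold seed (default 1).
#' @return Function mapping an integer index vector to an accuracy.
#' @export
makeCVEvaluator <- function(X, y, classifiers = c("nb", "lr"), k = 10L,
                            seed = 1L) {
    X <- as.matrix(X)
    y <- as.integer(y)
    folds <- stratifiedFolds(y, k = k, seed = seed)
    force(classifiers)
    function(featureIdx) {
        scores <- .cvScoresMatrix(X[, featureIdx, drop = FALSE], y,
                                  classifiers, folds)
        mean((scores >= 0.5) == (y == 1L))
    }
}

#' Write an IFS curve as TSV
#'
#' Two columns: prefix size k, accuracy.
#'
#' @param object An [IFSResult-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeIFSCurveTSV <- function(object, path) {
    stopifnot(is(object, "IFSResult"))
    tab <- data.frame(k = seq_along(object@curve),
                      accuracy = object@curve)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
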