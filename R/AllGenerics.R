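#' Positive-class probability of new samples
#'
#' Every trained classifier in the package (Gaussian naive Bayes,
#' ridge-stabilised logistic regression, nearest neighbour, and the fused
#' ensemble) answers `predictProba()` with the probability of the positive
#' (anti-angiogenic) class, always in `[0, 1]`.
#'
#' @param object A trained model.
#' @param X Numeric feature matrix (or single feature vector) whose columns
#'   match the model's training feature space. For [FusionModel-class] the
#'   matrix is the full encoder output; the model subsets its own selected
#'   columns.
#' @return Numeric vector of positive-class probabilities, one per row.
#' @export
setGeneric("predictProba", function(object, X) standardGeneric("predictProba"))

#' @rdname PeptideSet-class
#' @param object,x A `PeptideSet`.
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))

#' Accessors for PeptideSet
#'
#' `peptideSequences()` returns the underlying [Biostrings::AAStringSet];
#' `classLabels()` the integer 0/1/`NA` label vector (named by record id);
#' `peptideIds()` the record identifiers.
#'
#' @rdname PeptideSet-class
#' @export
setGeneric("peptideSequences",
           function(object) standardGeneric("peptideSequences"))

setMethod("peptideSequences", "PeptideSet", function(object) object@sequences)

setMethod("classLabels", "PeptideSet", function(object) {
    stats::setNames(object@labels, names(object@sequences))
})

#' @rdname PeptideSet-class
#' @export
peptideIds <- function(object) names(object@sequences)

#' @rdname PeptideSet-class
#' @export
setMethod("length", "PeptideSet", function(x) length(x@sequences))

#' @rdname PeptideSet-class
#' @param i Index vector (integer, logical or record ids).
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "PeptideSet", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i)) i <- match(i, names(x@sequences))
    new("PeptideSet", sequences = x@sequences[i], labels = x@labels[i])
})

setMethod("show", "PeptideSet", function(object) {
    lab <- object@labels
    cat("PeptideSet with", length(object), "records (",
        sum(lab == 1L, na.rm = TRUE), "positive,",
        sum(lab == 0L, na.rm = TRUE), "negative,",
        sum(is.na(lab)), "unlabelled )\n")
    rng <- range(Biostrings::width(object@sequences))
    cat("  lengths:", rng[1L], "-", rng[2L], "\n")
})

setMethod("show", "BpBModel", function(object) {
    cat("BpBModel: terminal window m =", object@m,
        "| pseudocount =", object@pseudocount, "\n")
    cat("  four", object@m, "x", length(object@alphabet),
        "posterior tables (Npos, Cpos, Nneg, Cneg)\n")
})

setMethod("show", "ReliefResult", function(object) {
    cat("ReliefResult over", length(object@weights), "features,",
        object@nIter, "iterations\n")
    top <- utils::head(object@ranking, 5L)
    cat("  top features:",
        paste(names(object@weights)[top], collapse = ", "), "\n")
})

setMethod("show", "IFSResult", function(object) {
    cat("IFSResult: chosen k =", object@chosenK, "of",
        length(object@curve), "features; accuracy at peak =",
        format(max(object@curve), digits = 4), "\n")
})

setMethod("show", "GaussNB", function(object) {
    cat("Gaussian naive Bayes:", ncol(object@means), "features; priors",
        paste(format(object@priors, digits = 3), collapse = "/"), "\n")
})

setMethod("show", "RidgeLR", function(object) {
    cat("Ridge logistic regression:", length(object@coef) - 1L,
        "features; ridge =", object@ridge, ";",
        if (object@converged) "converged" else "not converged",
        "in", object@nIter, "iterations\n")
})

setMethod("show", "FusionModel", function(object) {
    cat("FusionModel:", paste(object@baseNames, collapse = " + "),
        "average-probability ensemble\n")
    cat("  encoders:", paste(object@encoders, collapse = "+"),
        "|", length(object@featureIndices), "of",
        length(object@featureNames), "features | threshold",
        object@threshold, "\n")
})

setMethod("show", "EvalReport", function(object) {
    cat("EvalReport (pooled over folds, seed", object@foldSeed, ")\n")
    cat("  counts:", paste(names(object@counts), object@counts,
                           collapse = " "), "\n")
    m <- object@metrics
    cat(sprintf("  Sn %.3f  Sp %.3f  Acc %.3f  MCC %.3f  AUC %.3f\n",
                m["sn"], m["sp"], m["acc"], m["mcc"], object@auc))
})

#' @rdname EvalReport-class
#' @param object An `EvalReport`.
#' @export
setGeneric("performance", function(object) standardGeneric("performance"))

#' @rdname EvalReport-class
#' @export
setMethod("performance", "EvalReport", function(object) {
    c(object@metrics, auc = object@auc)
})

#' @rdname EvalReport-class
#' @export
confusionCounts <- function(object) {
    stopifnot(is(object, "EvalReport"))
    object@counts
}

#' @rdname EvalReport-class
#' @export
rocPoints <- function(object) {
    stopifnot(is(object, "EvalReport"))
    object@roc
}

#' @rdname EvalReport-class
#' @export
pooledScores <- function(object) {
    stopifnot(is(object, "EvalReport"))
    object@scores
}

#' @rdname ReliefResult-class
#' @param object A `ReliefResult` (or `IFSResult` for `featureRanking`).
#' @export
featureWeights <- function(object) {
    stopifnot(is(object, "ReliefResult"))
    object@weights
}

#' @rdname ReliefResult-class
#' @export
featureRanking <- function(object) {
    stopifnot(is(object, "ReliefResult") || is(object, "IFSResult"))
    object@ranking
}

#' @rdname IFSResult-class
#' @param object An `IFSResult`.
#' @export
ifsCurve <- function(object) {
    stopifnot(is(object, "IFSResult"))
    object@curve
}

#' @rdname IFSResult-class
#' @export
selectedFeatures <- function(object) {
    stopifnot(is(object, "IFSResult"))
    object@selected
}

#' @rdname BpBModel-class
#' @param object A `BpBModel`.
#' @export
bpbTables <- function(object) {
    stopifnot(is(object, "BpBModel"))
    object@tables
}
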