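#' @import methods
#' @importClassesFrom Biostrings AAStringSet
#' @importFrom stats dnorm fft plogis sd var
NULL

## Canonical residue ordering used by every encoder and model table.
.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' The 20-letter amino-acid alphabet
#'
#' Fixed alphabetical ordering of the 20 canonical residues used throughout
#' the package (encoder tables, feature names, serialized models).
#'
#' @return Character vector of length 20.
#' @examples
#' aminoAcidAlphabet()
#' @export
aminoAcidAlphabet <- function() .AA20

## Classed condition for user-input problems (CLI exit code 1).
stopValidation <- function(...) {
    stop(errorCondition(paste0(...), class = "aapValidationError"))
}

#' PeptideSet: labelled peptide sequences
#'
#' An ordered collection of identified, validated peptide sequences over the
#' 20-letter amino-acid alphabet, with an optional binary class label per
#' record (1 = anti-angiogenic / positive, 0 = negative, `NA` = unlabelled).
#'
#' @slot sequences An [Biostrings::AAStringSet] with unique names (record ids).
#' @slot labels Integer vector parallel to `sequences`; values 0, 1 or `NA`.
#'
#' @seealso [PeptideSet()], [readPeptideFasta()], [simulatePeptides()]
#' @export
setClass("PeptideSet",
    representation(sequences = "AAStringSet", labels = "integer"))

setValidity("PeptideSet", function(object) {
    msg <- character()
    ids <- names(object@sequences)
    if (is.null(ids) || anyNA(ids) || any(ids == ""))
        msg <- c(msg, "every record needs a non-empty id")
    else if (anyDuplicated(ids))
        msg <- c(msg, paste0("duplicate record id: ",
                             ids[duplicated(ids)][1L]))
    if (length(object@labels) != length(object@sequences))
        msg <- c(msg, "labels must be parallel to sequences")
    if (!all(object@labels %in% c(0L, 1L, NA_integer_)))
        msg <- c(msg, "labels must be 0, 1 or NA")
    chars <- unique(unlist(strsplit(as.character(object@sequences), "")))
    bad <- setdiff(chars, .AA20)
    if (length(bad))
        msg <- c(msg, paste0("non-canonical residue(s): ",
                             paste(bad, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' BpBModel: Bi-profile Bayes posterior tables
#'
#' Four position-by-residue tables of posterior probabilities
#' P(residue at position | class), estimated on a labelled training set:
#' one table each for the N-terminal and C-terminal window under the
#' positive and the negative class.
#'
#' @slot m Integer window length (positions per terminus).
#' @slot pseudocount Non-negative smoothing constant added per residue count.
#' @slot alphabet Character vector, the fixed residue ordering of the columns.
#' @slot tables Named list of four `m x 20` matrices:
#'   `Npos`, `Cpos`, `Nneg`, `Cneg`. Every row sums to 1.
#'
#' @seealso [fitBpB()], [encodeBpB()]
#' @export
setClass("BpBModel",
    representation(m = "integer", pseudocount = "numeric",
                   alphabet = "character", tables = "list"))

setValidity("BpBModel", function(object) {
    msg <- character()
    need <- c("Npos", "Cpos", "Nneg", "Cneg")
    if (!identical(names(object@tables), need))
        msg <- c(msg, "tables must be named Npos, Cpos, Nneg, Cneg")
    else {
        for (nm in need) {
            tab <- object@tables[[nm]]
            if (!is.matrix(tab) || nrow(tab) != object@m ||
                ncol(tab) != length(object@alphabet)) {
                msg <- c(msg, paste0(nm, " table has wrong shape"))
            } else if (any(abs(rowSums(tab) - 1) > 1e-9)) {
                msg <- c(msg, paste0(nm, " rows must sum to 1"))
            }
        }
    }
    if (length(msg)) msg else TRUE
})

#' ReliefResult: per-feature Relief weights and ranking
#'
#' @slot weights Named numeric vector, one Relief weight per feature.
#' @slot ranking Integer permutation of feature indices, highest weight
#'   first; ties broken by ascending original index.
#' @slot nIter Integer, number of instances iterated over.
#' @slot seed Integer seed used for random sampling (`NA` in the
#'   deterministic all-instances mode).
#'
#' @seealso [reliefRank()]
#' @export
setClass("ReliefResult",
    representation(weights = "numeric", ranking = "integer",
                   nIter = "integer", seed = "integer"))

setValidity("ReliefResult", function(object) {
    d <- length(object@weights)
    if (!identical(sort(object@ranking), seq_len(d)))
        return("ranking must be a permutation of the feature indices")
    TRUE
})

#' IFSResult: incremental feature selection curve and chosen prefix
#'
#' @slot curve Numeric vector; evaluator accuracy at each prefix size
#'   `k = 1..d` of the supplied ranking.
#' @slot chosenK Integer, the smallest prefix size attaining the curve
#'   maximum.
#' @slot selected Integer vector, the first `chosenK` features of the
#'   ranking (original column indices).
#' @slot ranking Integer, the feature ranking that was scanned.
#'
#' @seealso [ifsSelect()]
#' @export
setClass("IFSResult",
    representation(curve = "numeric", chosenK = "integer",
                   selected = "integer", ranking = "integer"))

setValidity("IFSResult", function(object) {
    if (any(object@curve < 0 | object@curve > 1))
        return("curve values must lie in [0, 1]")
    if (object@chosenK != which.max(object@curve))
        return("chosenK must be the smallest argmax of the curve")
    TRUE
})

#' GaussNB: Gaussian naive Bayes model
#'
#' Per-class, per-feature Gaussian densities with maximum-likelihood means
#' and variances (variances floored for numerical stability) and class
#' priors equal to the training class frequencies.
#'
#' @slot priors Numeric length-2 vector named `neg`, `pos`; sums to 1.
#' @slot means,vars 2 x d matrices (rows `neg`, `pos`).
#' @slot varFloor Positive variance floor applied to `vars`.
#' @slot features Character vector of training feature names.
#'
#' @seealso [trainGaussianNB()], [predictProba()]
#' @export
setClass("GaussNB",
    representation(priors = "numeric", means = "matrix", vars = "matrix",
                   varFloor = "numeric", features = "character"))

setValidity("GaussNB", function(object) {
    msg <- character()
    if (abs(sum(object@priors) - 1) > 1e-9)
        msg <- c(msg, "priors must sum to 1")
    if (any(object@vars < object@varFloor - 1e-15))
        msg <- c(msg, "all variances must be >= varFloor")
    if (length(msg)) msg else TRUE
})

#' RidgeLR: ridge-stabilised logistic regression model
#'
#' Binomial logistic regression fitted by iteratively reweighted least
#' squares, maximising the L2-penalised log-likelihood (the intercept is
#' not penalised).
#'
#' @slot coef Named numeric vector: intercept followed by one coefficient
#'   per feature; all finite.
#' @slot ridge Non-negative L2 penalty constant.
#' @slot converged Logical convergence flag.
#' @slot nIter Integer, IRLS iterations performed.
#'
#' @seealso [trainRidgeLogistic()], [predictProba()]
#' @export
setClass("RidgeLR",
    representation(coef = "numeric", ridge = "numeric",
                   converged = "logical", nIter = "integer"))

setValidity("RidgeLR", function(object) {
    if (!all(is.finite(object@coef))) return("coefficients must be finite")
    TRUE
})

#' NNAModel: nearest-neighbour classifier
#'
#' Stores the training matrix; a query is assigned the label of the
#' Euclidean-nearest training sample (distance ties broken by lowest
#' training index). The pseudo-probability of the positive class is a hard
#' 0/1, so the ROC of this classifier is a single point.
#'
#' @slot X Numeric training matrix.
#' @slot y Integer 0/1 training labels.
#'
#' @seealso [trainNearestNeighbor()]
#' @export
setClass("NNAModel", representation(X = "matrix", y = "integer"))

#' FusionModel: two-classifier average-probability ensemble
#'
#' The trained prediction pipeline: the fitted Bi-profile Bayes tables (if
#' the BpB encoder is used), the selected feature columns, and two trained
#' base classifiers -- one chosen for best sensitivity, one for best
#' specificity. The fused positive-class probability of a query is the
#' arithmetic mean of the two base probabilities; the label is positive
#' when the fused probability reaches the decision threshold.
#'
#' @slot baseA,baseB Trained base classifiers exposing [predictProba()]
#'   (`baseA` the max-sensitivity one, `baseB` the max-specificity one).
#' @slot baseNames Character length-2, registry names of the bases.
#' @slot threshold Decision cut-off on the fused probability (default 0.5;
#'   a fused probability `>= threshold` is called positive).
#' @slot featureIndices Integer columns of the full feature matrix used by
#'   the bases.
#' @slot featureNames Character names of the full feature space.
#' @slot bpb A fitted [BpBModel-class] or `NULL`.
#' @slot encoders Character subset of `c("bpb", "ctd", "dft")`, in the
#'   canonical order.
#' @slot params List of encoder parameters (`m`, `pseudocount`, `nFreq`).
#'
#' @seealso [trainFusionModel()], [predictPeptides()]
#' @export
setClass("FusionModel",
    representation(baseA = "ANY", baseB = "ANY", baseNames = "character",
                   threshold = "numeric", featureIndices = "integer",
                   featureNames = "character", bpb = "ANY",
                   encoders = "character", params = "list"))

#' EvalReport: pooled cross-validation evaluation report
#'
#' Confusion counts pooled over all folds (micro-average), threshold
#' metrics, the ROC curve of the pooled scores and its trapezoidal AUC.
#'
#' @slot counts Named integer vector `TP`, `FP`, `TN`, `FN`.
#' @slot metrics Named numeric vector `sn`, `sp`, `acc`, `mcc`.
#' @slot roc Two-column matrix of (FPR, TPR) points.
#' @slot auc Numeric in `[0, 1]`.
#' @slot scores `data.frame` with columns `id`, `label`, `score` (pooled
#'   per-sample fused probabilities).
#' @slot foldSeed Integer seed that generated the fold assignment.
#' @slot perFold List of per-fold metric vectors (empty unless requested).
#'
#' @seealso [crossValidate()], [confusionMetrics()]
#' @export
setClass("EvalReport",
    representation(counts = "integer", metrics = "numeric", roc = "matrix",
                   auc = "numeric", scores = "data.frame",
                   foldSeed = "integer", perFold = "list"))

setValidity("EvalReport", function(object) {
    msg <- character()
    if (!identical(names(object@counts), c("TP", "FP", "TN", "FN")))
        msg <- c(msg, "counts must be named TP, FP, TN, FN")
    if (object@auc < 0 || object@auc > 1)
        msg <- c(msg, "auc must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})
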