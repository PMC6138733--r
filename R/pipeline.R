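#' Train the full fusion prediction pipeline
#'
#' Fits the complete anti-angiogenic peptide predictor on a labelled
#' training set: encodes the peptides (BpB tables fitted on the whole
#' training set), optionally runs Relief + incremental feature selection
#' with a cross-validated NB+LR evaluator, resolves the base-classifier
#' pair (either the two names given, or `"auto"` to pick the
#' best-sensitivity and best-specificity candidates by cross-validation),
#' and trains both bases on the selected columns.
#'
#' @param pep A fully labelled [PeptideSet-class].
#' @param encoders Subset of `c("bpb", "ctd", "dft")` (default `"bpb"`,
#'   the best-performing space).
#' @param classifiers Two registered classifier names (sensitive base
#'   first), or `"auto"`.
#' @param select Run Relief + IFS feature selection (default `FALSE`,
#'   i.e. use all features unless `featureIndices` is given).
#' @param featureIndices Optional explicit feature columns (overrides
#'   `select`).
#' @param k,seed Cross-validation folds and seed used for candidate
#'   evaluation and the IFS evaluator.
#' @param m,pseudocount,nFreq,scales Encoder parameters.
#' @param reliefIter Relief iteration count (`"all"` or an integer; see
#'   [reliefRank()]).
#' @param threshold Decision cut-off on the fused probability.
#' @return A [FusionModel-class].
#' @examples
#' pep <- simulatePeptides(nPos = 30, nNeg = 30, seed = 11)
#' mod <- trainFusionModel(pep, classifiers = c("lr", "nb"))
#' head(predictPeptides(mod, pep), 3)
#' @export
trainFusionModel <- function(pep, encoders = "bpb",
                             classifiers = c("lr", "nb"),
                             select = FALSE, featureIndices = NULL,
                             k = 10L, seed = 1L, m = 10L,
                             pseudocount = 1, nFreq = 10L, scales = NULL,
                             reliefIter = "all", threshold = 0.5) {
    stopifnot(is(pep, "PeptideSet"))
    y <- pep@labels
    if (anyNA(y)) stopValidation("all training records must be labelled")
    if (identical(classifiers, "auto")) {
        cand <- evaluateCandidates(pep, candidates = c("nb", "lr", "nna"),
                                   encoders = encoders, k = k,
                                   seed = seed, m = m,
                                   pseudocount = pseudocount,
                                   nFreq = nFreq, scales = scales)
        classifiers <- unname(selectBasePair(cand))
    }
    if (length(classifiers) != 2L)
        stopValidation("classifiers must be two names or \"auto\"")
    bpb <- if ("bpb" %in% encoders)
        fitBpB(pep, m = m, pseudocount = pseudocount) else NULL
    X <- .buildFeatureMatrix(pep, encoders, bpb = bpb, nFreq = nFreq,
                             scales = scales)
    if (is.null(featureIndices) && select) {
        rel <- reliefRank(X, y, nIter = reliefIter, seed = seed)
        ev <- makeCVEvaluator(X, y, classifiers = classifiers, k = k,
                              seed = seed)
        featureIndices <- selectedFeatures(ifsSelect(featureRanking(rel),
                                                     ev))
    }
    if (is.null(featureIndices)) featureIndices <- seq_len(ncol(X))
    featureIndices <- as.integer(featureIndices)
    Xsel <- X[, featureIndices, drop = FALSE]
    baseA <- .getTrainer(classifiers[1L])(Xsel, y)
    baseB <- .getTrainer(classifiers[2L])(Xsel, y)
    new("FusionModel", baseA = baseA, baseB = baseB,
        baseNames = classifiers, threshold = threshold,
        featureIndices = featureIndices, featureNames = colnames(X),
        bpb = bpb, encoders = intersect(c("bpb", "ctd", "dft"), encoders),
        params = list(m = as.integer(m), pseudocount = pseudocount,
                      nFreq = as.integer(nFreq)))
}

#' Score new peptides with a trained fusion model
#'
#' Encodes the query peptides with the model's stored encoder
#' configuration (including its fitted BpB tables -- the queries' labels,
#' if any, are never read) and returns the fused positive-class
#' probability and the thresholded label per record.
#'
#' @param model A [FusionModel-class].
#' @param pep A [PeptideSet-class] (labels optional and ignored).
#' @return `data.frame` with columns `id`, `probability`, `label`.
#' @export
predictPeptides <- function(model, pep) {
    stopifnot(is(model, "FusionModel"), is(pep, "PeptideSet"))
    X <- .buildFeatureMatrix(pep, model@encoders, bpb = model@bpb,
                             nFreq = model@params$nFreq)
    if (!identical(colnames(X), model@featureNames))
        stopValidation("encoded feature space does not match the model")
    prob <- predictProba(model, X)
    data.frame(id = peptideIds(pep), probability = prob,
               label = as.integer(prob >= model@threshold))
}

## --- model serialization -------------------------------------------------

.serializeBase <- function(mdl) {
    if (is(mdl, "GaussNB")) {
        list(type = "nb", priors = as.list(mdl@priors),
             means = as.data.frame(mdl@means),
             vars = as.data.frame(mdl@vars), varFloor = mdl@varFloor,
             features = mdl@features)
    } else if (is(mdl, "RidgeLR")) {
        list(type = "lr", coef = as.list(mdl@coef), ridge = mdl@ridge,
             converged = mdl@converged, nIter = mdl@nIter)
    } else if (is(mdl, "NNAModel")) {
        list(type = "nna", X = as.data.frame(mdl@X), y = mdl@y)
    } else {
        stop("cannot serialize base classifier of class ", class(mdl))
    }
}

.deserializeBase <- function(obj) {
    switch(obj$type,
        nb = new("GaussNB",
                 priors = unlist(obj$priors)[c("neg", "pos")],
                 means = as.matrix(obj$means),
                 vars = as.matrix(obj$vars),
                 varFloor = obj$varFloor,
                 features = as.character(obj$features)),
        lr = new("RidgeLR", coef = unlist(obj$coef), ridge = obj$ridge,
                 converged = obj$converged,
                 nIter = as.integer(obj$nIter)),
        nna = new("NNAModel", X = as.matrix(obj$X),
                  y = as.integer(obj$y)),
        stop("unknown base classifier type: ", obj$type))
}

#' Serialize / restore a trained FusionModel
#'
#' Single versioned plain-text JSON file embedding the feature indices,
#' the fitted BpB tables (if any) and both base classifiers, so saved
#' models reproduce predictions exactly.
#'
#' @param model A [FusionModel-class].
#' @param path Output (input) file path.
#' @return `writeFusionModel()`: `path`, invisibly.
#'   `readFusionModel()`: the restored [FusionModel-class].
#' @export
writeFusionModel <- function(model, path) {
    stopifnot(is(model, "FusionModel"))
    bpb <- NULL
    if (!is.null(model@bpb))
        bpb <- list(m = model@bpb@m, pseudocount = model@bpb@pseudocount,
                    alphabet = model@bpb@alphabet,
                    tables = lapply(model@bpb@tables, as.data.frame))
    payload <- list(format = "AntiAngioPep/FusionModel", version = 1L,
                    baseNames = model@baseNames,
                    threshold = model@threshold,
                    featureIndices = model@featureIndices,
                    featureNames = model@featureNames,
                    encoders = model@encoders, params = model@params,
                    bpb = bpb,
                    baseA = .serializeBase(model@baseA),
                    baseB = .serializeBase(model@baseB))
    jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname writeFusionModel
#' @export
readFusionModel <- function(path) {
    if (!file.exists(path))
        stopValidation("model file not found: ", path)
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(payload$format, "AntiAngioPep/FusionModel"))
        stopValidation("not a FusionModel file: ", path)
    bpb <- NULL
    if (!is.null(payload$bpb)) {
        tables <- lapply(payload$bpb$tables, function(df) {
            tab <- as.matrix(df)
            dimnames(tab) <- list(NULL, payload$bpb$alphabet)
            tab
        })
        bpb <- new("BpBModel", m = as.integer(payload$bpb$m),
                   pseudocount = payload$bpb$pseudocount,
                   alphabet = payload$bpb$alphabet, tables = tables)
    }
    new("FusionModel",
        baseA = .deserializeBase(payload$baseA),
        baseB = .deserializeBase(payload$baseB),
        baseNames = payload$baseNames, threshold = payload$threshold,
        featureIndices = as.integer(payload$featureIndices),
        featureNames = payload$featureNames, bpb = bpb,
        encoders = payload$encoders,
        params = list(m = as.integer(payload$params$m),
                      pseudocount = payload$params$pseudocount,
                      nFreq = as.integer(payload$params$nFreq)))
}
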