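#' Train a Gaussian naive Bayes classifier
#'
#' Per-class, per-feature Gaussian densities with maximum-likelihood
#' estimates (variances divide by the class size, not `n - 1`) and class
#' priors equal to the training class frequencies. Every variance is
#' floored at `1e-9 * max(feature variance)` (absolute `1e-9` when all
#' variances are zero) so constant features contribute equally to both
#' classes instead of degenerating.
#'
#' @param X Numeric feature matrix (samples x features).
#' @param y Binary 0/1 labels; both classes must have at least two
#'   samples.
#' @return A [GaussNB-class].
#' @export
trainGaussianNB <- function(X, y) {
    X <- as.matrix(X)
    y <- as.integer(y)
    if (nrow(X) != length(y)) stopValidation("X and y sizes differ")
    if (sum(y == 1L) < 2L || sum(y == 0L) < 2L)
        stopValidation("each class needs >= 2 samples")
    if (!all(is.finite(X))) stopValidation("X must be finite")
    mlVar <- function(M) {
        mu <- colMeans(M)
        colMeans(sweep(M, 2L, mu, "-")^2)
    }
    means <- rbind(neg = colMeans(X[y == 0L, , drop = FALSE]),
                   pos = colMeans(X[y == 1L, , drop = FALSE]))
    vars <- rbind(neg = mlVar(X[y == 0L, , drop = FALSE]),
                  pos = mlVar(X[y == 1L, , drop = FALSE]))
    maxVar <- max(vars)
    floor <- if (maxVar > 0) 1e-9 * maxVar else 1e-9
    vars <- pmax(vars, floor)
    fn <- colnames(X)
    if (is.null(fn)) fn <- paste0("f", seq_len(ncol(X)))
    new("GaussNB",
        priors = c(neg = mean(y == 0L), pos = mean(y == 1L)),
        means = means, vars = vars, varFloor = floor, features = fn)
}

.asMatrixRows <- function(X, d) {
    if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
    X <- as.matrix(X)
    if (ncol(X) != d)
        stopValidation("feature dimension mismatch: got ", ncol(X),
                       ", model expects ", d)
    X
}

#' @rdname predictProba
#' @export
setMethod("predictProba", "GaussNB", function(object, X) {
    X <- .asMatrixRows(X, ncol(object@means))
    logLik <- function(cls) {
        mu <- object@means[cls, ]
        sdv <- sqrt(object@vars[cls, ])
        rowSums(dnorm(X, mean = matrix(mu, nrow(X), ncol(X), byrow = TRUE),
                      sd = matrix(sdv, nrow(X), ncol(X), byrow = TRUE),
                      log = TRUE)) + log(object@priors[cls])
    }
    lp <- logLik("pos")
    ln <- logLik("neg")
    m <- pmax(lp, ln)
    unname(exp(lp - m) / (exp(lp - m) + exp(ln - m)))
})

#' Train a ridge-stabilised logistic regression
#'
#' Maximises the L2-penalised binomial log-likelihood
#' `l(w) - (ridge / 2) * sum(w_j^2)` (intercept unpenalised) by
#' iteratively reweighted least squares. Convergence is declared when the
#' largest coefficient change drops below `tol`, with a hard cap of
#' `maxIter` iterations; the tiny default ridge keeps the solution finite
#' even on linearly separable data.
#'
#' @param X Numeric feature matrix.
#' @param y Binary 0/1 labels, at least one sample per class.
#' @param ridge Non-negative L2 penalty (default `1e-8`,
#'   near-unpenalised).
#' @param maxIter Iteration cap (default 100).
#' @param tol Convergence tolerance on the max coefficient change
#'   (default `1e-8`).
#' @return A [RidgeLR-class].
#' @export
trainRidgeLogistic <- function(X, y, ridge = 1e-8, maxIter = 100L,
                               tol = 1e-8) {
    X <- as.matrix(X)
    y <- as.integer(y)
    if (nrow(X) != length(y)) stopValidation("X and y sizes differ")
    if (!any(y == 1L) || !any(y == 0L))
        stopValidation("both classes must be present")
    if (!all(is.finite(X))) stopValidation("X must be finite")
    if (ridge < 0) stopValidation("ridge must be non-negative")
    fn <- colnames(X)
    if (is.null(fn)) fn <- paste0("f", seq_len(ncol(X)))
    Xd <- cbind(1, X)
    p <- ncol(Xd)
    pen <- c(0, rep(ridge, p - 1L))
    w <- numeric(p)
    converged <- FALSE
    it <- 0L
    while (it < maxIter) {
        it <- it + 1L
        eta <- drop(Xd %*% w)
        mu <- plogis(eta)
        wt <- pmax(mu * (1 - mu), 1e-10)
        z <- eta + (y - mu) / wt
        A <- crossprod(Xd, Xd * wt) + diag(pen, p)
        wNew <- tryCatch(drop(solve(A, crossprod(Xd, wt * z))),
                         error = function(e) stop(
                             "IRLS system is singular: ",
                             conditionMessage(e)))
        delta <- max(abs(wNew - w))
        w <- wNew
        if (delta < tol) {
            converged <- TRUE
            break
        }
    }
    new("RidgeLR", coef = stats::setNames(w, c("(Intercept)", fn)),
        ridge = ridge, converged = converged, nIter = it)
}

#' @rdname predictProba
#' @export
setMethod("predictProba", "RidgeLR", function(object, X) {
    X <- .asMatrixRows(X, length(object@coef) - 1L)
    unname(plogis(drop(cbind(1, X) %*% object@coef)))
})

#' Train a nearest-neighbour classifier
#'
#' Stores the training data; see [NNAModel-class] for the prediction
#' rule.
#'
#' @param X Numeric feature matrix.
#' @param y Binary 0/1 labels.
#' @return An [NNAModel-class].
#' @export
trainNearestNeighbor <- function(X, y) {
    X <- as.matrix(X)
    y <- as.integer(y)
    if (nrow(X) < 1L) stopValidation("training set is empty")
    if (nrow(X) != length(y)) stopValidation("X and y sizes differ")
    if (!all(is.finite(X))) stopValidation("X must be finite")
    new("NNAModel", X = X, y = y)
}

#' @rdname predictProba
#' @export
setMethod("predictProba", "NNAModel", function(object, X) {
    X <- .asMatrixRows(X, ncol(object@X))
    out <- numeric(nrow(X))
    for (q in seq_len(nrow(X))) {
        d2 <- colSums((t(object@X) - X[q, ])^2)
        out[q] <- as.numeric(object@y[which.min(d2)])  # tie: lowest index
    }
    out
})

## Classifier registry: name -> training function.
.CLASSIFIERS <- list(nb = trainGaussianNB, lr = trainRidgeLogistic,
                     nna = trainNearestNeighbor)

.getTrainer <- function(name) {
    fn <- .CLASSIFIERS[[name]]
    if (is.null(fn))
        stopValidation("unknown classifier '", name, "'; registered: ",
                       paste(names(.CLASSIFIERS), collapse = ", "))
    fn
}

#' Registered base classifiers
#'
#' @return Character vector of classifier names accepted wherever a
#'   classifier is referenced by name: `"nb"` (Gaussian naive Bayes),
#'   `"lr"` (ridge logistic regression), `"nna"` (nearest neighbour).
#' @export
registeredClassifiers <- function() names(.CLASSIFIERS)

#' Pick the best-sensitivity / best-specificity base pair
#'
#' Given per-classifier cross-validated sensitivity and specificity,
#' returns the classifier with the highest sensitivity and the one with
#' the highest specificity (ties towards the earlier row). When a single
#' classifier wins both criteria, the runner-up on the second criterion
#' (specificity) is taken so the pair is distinct.
#'
#' @param candidates `data.frame` with columns `classifier`, `sn`, `sp`
#'   (at least two rows).
#' @return Character length-2 vector: `c(sensitive = ..., specific = ...)`.
#' @examples
#' selectBasePair(data.frame(classifier = c("nb", "lr"),
#'                           sn = c(0.682, 0.785), sp = c(0.925, 0.748)))
#' @export
selectBasePair <- function(candidates) {
    need <- c("classifier", "sn", "sp")
    if (!is.data.frame(candidates) || !all(need %in% names(candidates)))
        stopValidation("candidates needs columns classifier, sn, sp")
    if (nrow(candidates) < 2L)
        stopValidation("need at least 2 candidate classifiers")
    iSn <- which.max(candidates$sn)
    iSp <- which.max(candidates$sp)
    if (iSn == iSp) {
        spOrder <- order(-candidates$sp, seq_len(nrow(candidates)))
        iSp <- spOrder[2L]
    }
    c(sensitive = as.character(candidates$classifier[iSn]),
      specific = as.character(candidates$classifier[iSp]))
}

#' @rdname predictProba
#' @export
setMethod("predictProba", "FusionModel", function(object, X) {
    if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
    X <- as.matrix(X)
    if (ncol(X) == length(object@featureNames))
        X <- X[, object@featureIndices, drop = FALSE]
    else if (ncol(X) != length(object@featureIndices))
        stopValidation("feature dimension mismatch: got ", ncol(X),
                       " columns, model expects ",
                       length(object@featureNames), " (full space) or ",
                       length(object@featureIndices), " (selected)")
    (predictProba(object@baseA, X) + predictProba(object@baseB, X)) / 2
})

#' Fused probability and label for one feature vector
#'
#' Convenience wrapper around [predictProba()] for a
#' [FusionModel-class]: the fused probability is the arithmetic mean of
#' the two base probabilities and the call is positive when it reaches
#' the model threshold (`>=`).
#'
#' @param model A [FusionModel-class].
#' @param x Feature vector or matrix (full or selected feature space).
#' @return `data.frame` with columns `probability` and `label`.
#' @export
fusePredict <- function(model, x) {
    stopifnot(is(model, "FusionModel"))
    prob <- predictProba(model, x)
    data.frame(probability = prob,
               label = as.integer(prob >= model@threshold))
}
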