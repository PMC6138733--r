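## Column-wise min-max scaling to [0, 1]; constant columns map to 0.
.minMaxScale <- function(X) {
    lo <- apply(X, 2L, min)
    hi <- apply(X, 2L, max)
    span <- hi - lo
    span[span == 0] <- 1
    sweep(sweep(X, 2L, lo, "-"), 2L, span, "/")
}

## Evaluate an expression under a temporary RNG state.
.withSeed <- function(seed, expr) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1L)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
}

#' Relief feature weighting
#'
#' Weights each feature by its ability to separate nearest neighbours of
#' opposite classes. Features are min-max scaled to `[0, 1]` internally;
#' for each visited instance `s_i`, the nearest same-class neighbour
#' (nearest hit, self excluded) and the nearest other-class neighbour
#' (nearest miss) under the Euclidean distance on the scaled features
#' update every feature weight `p` by
#' `W_p <- W_p - |x_p - NH_p| / n + |x_p - NM_p| / n`.
#' Distance ties are broken towards the lowest original sample index, and
#' ranking ties towards the lowest original feature index. Weights are
#' reported raw (they can be negative); ranking uses the raw weights.
#'
#' @param X Numeric feature matrix (samples x features).
#' @param y Binary 0/1 labels, one per row; each class needs at least two
#'   samples (otherwise the nearest hit is undefined).
#' @param nIter `"all"` (default) visits every instance once in index
#'   order, which is fully deterministic; an integer draws that many
#'   instances at random (with replacement) under `seed`.
#' @param seed Integer seed for the random-sampling mode; ignored when
#'   `nIter = "all"`.
#' @return A [ReliefResult-class].
#' @examples
#' X <- cbind(sep = c(0, 0, 1, 1), noise = c(0.1, 0.9, 0.2, 0.8))
#' y <- c(1, 1, 0, 0)
#' featureRanking(reliefRank(X, y))  # separator ranked first
#' @export
reliefRank <- function(X, y, nIter = "all", seed = 1L) {
    X <- as.matrix(X)
    y <- as.integer(y)
    if (nrow(X) != length(y))
        stopValidation("X and y sizes differ")
    if (sum(y == 1L) < 2L || sum(y == 0L) < 2L)
        stopValidation("each class needs >= 2 samples (nearest hit ",
                       "undefined otherwise)")
    if (!all(is.finite(X)))
        stopValidation("X must be finite")
    n <- nrow(X)
    d <- ncol(X)
    Xs <- .minMaxScale(X)
    D <- as.matrix(stats::dist(Xs))
    diag(D) <- Inf
    if (identical(nIter, "all")) {
        visit <- seq_len(n)
        seedUsed <- NA_integer_
    } else {
        nIter <- as.integer(nIter)
        if (nIter < 1L) stopValidation("nIter must be >= 1 or \"all\"")
        visit <- .withSeed(seed, sample.int(n, nIter, replace = TRUE))
        seedUsed <- as.integer(seed)
    }
    nVisit <- length(visit)
    W <- numeric(d)
    for (i in visit) {
        same <- which(y == y[i])
        same <- same[same != i]
        other <- which(y != y[i])
        nh <- same[which.min(D[i, same])]
        nm <- other[which.min(D[i, other])]
        W <- W - abs(Xs[i, ] - Xs[nh, ]) / nVisit +
                 abs(Xs[i, ] - Xs[nm, ]) / nVisit
    }
    W <- stats::setNames(as.numeric(W), colnames(X))
    ranking <- order(-W, seq_len(d))
    new("ReliefResult", weights = W, ranking = as.integer(ranking),
        nIter = as.integer(nVisit), seed = seedUsed)
}

#' Write a Relief ranking as TSV
#'
#' Three columns: rank, feature name, weight.
#'
#' @param object A [ReliefResult-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeReliefTSV <- function(object, path) {
    stopifnot(is(object, "ReliefResult"))
    nm <- names(object@weights)
    if (is.null(nm)) nm <- paste0("f", seq_along(object@weights))
    tab <- data.frame(rank = seq_along(object@ranking),
                      feature = nm[object@ranking],
                      weight = unname(object@weights[object@ranking]))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
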