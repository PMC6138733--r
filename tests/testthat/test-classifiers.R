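test_that("Gaussian NB posterior behaves on symmetric, separated and constant features", {
    # symmetric likelihoods: probability 0.5 everywhere
    X <- matrix(c(0, 1, 0, 1), ncol = 1)
    y <- c(0L, 0L, 1L, 1L)
    nb <- trainGaussianNB(X, y)
    expect_equal(predictProba(nb, matrix(c(-1, 0.5, 2), ncol = 1)),
                 rep(0.5, 3), tolerance = 1e-12)

    # well-separated 1-D classes
    nb2 <- trainGaussianNB(matrix(c(0, 0.2, 1, 1.2), ncol = 1),
                           c(1L, 1L, 0L, 0L))
    expect_gt(predictProba(nb2, matrix(0.1)), 0.99)

    # constant feature: floored variance, posterior driven by priors
    nb3 <- trainGaussianNB(matrix(rep(5, 6), ncol = 1),
                           c(0L, 0L, 0L, 0L, 1L, 1L))
    expect_equal(predictProba(nb3, matrix(5)), 2 / 6, tolerance = 1e-9)

    expect_error(trainGaussianNB(X, c(0L, 0L, 0L, 0L)), ">= 2")
    expect_error(predictProba(nb, matrix(1, 1, 3)), "dimension")
})

test_that("NB matches the closed-form Gaussian posterior oracle", {
    set.seed(61)
    for (rep in 1:10) {
        X <- matrix(rnorm(20 * 2, mean = rep(c(0, 1), each = 10)), 20, 2)
        y <- rep(c(0L, 1L), each = 10)
        nb <- trainGaussianNB(X, y)
        x <- rnorm(2)
        expect_equal(predictProba(nb, matrix(x, 1)), nbOracle(X, y, x),
                     tolerance = 1e-10)
    }
})

test_that("NB posterior is monotone towards the positive mean in 1-D", {
    nb <- trainGaussianNB(matrix(c(0, 0.4, 2, 2.4), ncol = 1),
                          c(1L, 1L, 0L, 0L))
    grid <- seq(2, 0, by = -0.1)
    p <- predictProba(nb, matrix(grid, ncol = 1))
    expect_false(is.unsorted(p))
})

test_that("ridge logistic regression maximises the penalised likelihood", {
    # mirror-symmetric classes: intercept converges to 0
    X <- matrix(c(-2, -1, 1, 2), ncol = 1)
    y <- c(0L, 0L, 1L, 1L)
    lr <- trainRidgeLogistic(X, y, ridge = 1)
    expect_lt(abs(lr@coef[["(Intercept)"]]), 1e-6)
    expect_true(lr@converged)

    # BFGS oracle on the same objective, moderate ridge
    set.seed(62)
    for (ridge in c(1, 0.1)) {
        X4 <- matrix(c(0.1, 0.9, 0.4, 0.8, 1.1, 0.2, 0.7, 0.3), 4, 2)
        y4 <- c(0L, 1L, 0L, 1L)
        fit <- trainRidgeLogistic(X4, y4, ridge = ridge)
        expect_equal(unname(fit@coef), lrOracle(X4, y4, ridge),
                     tolerance = 1e-6)
    }

    # near-unpenalised fit agrees with glm on non-separable data
    set.seed(63)
    Xg <- matrix(rnorm(40), 20, 2)
    yg <- rbinom(20, 1, plogis(Xg[, 1]))
    fit <- trainRidgeLogistic(Xg, yg, ridge = 0)
    ref <- glm.fit(cbind(1, Xg), yg, family = binomial())
    expect_equal(unname(fit@coef), unname(coef(ref)), tolerance = 1e-6)

    # separable toy: ridge keeps weights finite, training accuracy 1
    sep <- trainRidgeLogistic(matrix(c(0, 1, 10, 11), ncol = 1),
                              c(0L, 0L, 1L, 1L))
    expect_true(all(is.finite(sep@coef)))
    p <- predictProba(sep, matrix(c(0, 1, 10, 11), ncol = 1))
    expect_identical(as.integer(p >= 0.5), c(0L, 0L, 1L, 1L))

    expect_error(trainRidgeLogistic(matrix(c(1, Inf), 2, 1), c(0L, 1L)),
                 "finite")
})

test_that("NB and LR training is deterministic", {
    set.seed(64)
    X <- matrix(rnorm(60), 20, 3)
    y <- rep(c(0L, 1L), 10)
    expect_identical(trainGaussianNB(X, y), trainGaussianNB(X, y))
    expect_identical(trainRidgeLogistic(X, y), trainRidgeLogistic(X, y))
})

test_that("nearest neighbour follows the exhaustive-scan rule with low-index ties", {
    X <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
    y <- c(1L, 0L)
    nna <- trainNearestNeighbor(X, y)
    expect_identical(predictProba(nna, matrix(c(0, 0.1), 1)), 1)
    # exact midpoint: tie resolves to the lowest training index
    expect_identical(predictProba(nna, matrix(c(0.5, 0.5), 1)), 1)

    set.seed(65)
    Xt <- matrix(rnorm(40), 20, 2)
    yt <- rep(c(0L, 1L), 10)
    mod <- trainNearestNeighbor(Xt, yt)
    for (q in 1:10) {
        x <- rnorm(2)
        d <- apply(Xt, 1, function(r) sum((r - x)^2))
        expect_identical(predictProba(mod, matrix(x, 1)),
                         as.numeric(yt[which.min(d)]))
    }
})

test_that("fusion is the exact arithmetic mean with a >= threshold rule", {
    set.seed(66)
    X <- matrix(rnorm(40), 20, 2)
    y <- rep(c(0L, 1L), 10)
    mod <- new("FusionModel", baseA = trainRidgeLogistic(X, y),
               baseB = trainGaussianNB(X, y), baseNames = c("lr", "nb"),
               threshold = 0.5, featureIndices = 1:2,
               featureNames = c("f1", "f2"), bpb = NULL,
               encoders = character(), params = list())
    q <- matrix(rnorm(10), 5, 2)
    pa <- predictProba(mod@baseA, q)
    pb <- predictProba(mod@baseB, q)
    expect_equal(predictProba(mod, q), (pa + pb) / 2, tolerance = 1e-12)
    expect_true(all(predictProba(mod, q) >= 0 &
                    predictProba(mod, q) <= 1))

    # boundary convention: fused probability exactly at threshold is positive
    half <- fusePredict(mod, q)
    expect_identical(half$label,
                     as.integer(((pa + pb) / 2) >= 0.5))
})

test_that("base-pair selection takes argmax-Sn and argmax-Sp with a distinctness rule", {
    cand <- data.frame(classifier = c("nb", "lr"),
                       sn = c(0.682, 0.785), sp = c(0.925, 0.748))
    pair <- selectBasePair(cand)
    expect_identical(unname(pair), c("lr", "nb"))

    dominant <- data.frame(classifier = c("a", "b", "c"),
                           sn = c(0.9, 0.7, 0.6),
                           sp = c(0.9, 0.8, 0.85))
    expect_identical(unname(selectBasePair(dominant)), c("a", "c"))

    tied <- data.frame(classifier = c("a", "b"),
                       sn = c(0.8, 0.8), sp = c(0.6, 0.7))
    expect_identical(unname(selectBasePair(tied))[1], "a")
    expect_error(selectBasePair(dominant[1, ]), "at least 2")
})
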