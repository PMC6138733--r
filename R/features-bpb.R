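## Residue counts per window position: m x 20 matrix.
.positionCounts <- function(seqs, m, terminal = c("N", "C")) {
    terminal <- match.arg(terminal)
    L <- nchar(seqs)
    counts <- matrix(0L, nrow = m, ncol = length(.AA20),
                     dimnames = list(NULL, .AA20))
    for (i in seq_len(m)) {
        pos <- if (terminal == "N") rep(i, length(seqs)) else L - m + i
        res <- substring(seqs, pos, pos)
        counts[i, ] <- as.integer(table(factor(res, levels = .AA20)))
    }
    counts
}

#' Fit Bi-profile Bayes posterior tables
#'
#' Estimates, from a labelled training set, the posterior probability of
#' each residue at each of the first `m` (N-terminal) and last `m`
#' (C-terminal) positions, separately under the positive and the negative
#' class. Entry (i, a) of a class-c table is
#' `(count of residue a at position i among class-c sequences + pseudocount)
#'  / (n_c + 20 * pseudocount)`.
#' C-terminal position `i` refers to sequence position `L - m + i`
#' (left-to-right within the last-`m` window).
#'
#' @param train A labelled [PeptideSet-class]; both classes must be
#'   non-empty and every sequence at least `m` residues long.
#' @param m Terminal window length (default 10).
#' @param pseudocount Non-negative smoothing constant (default 1,
#'   add-one smoothing; 0 gives raw frequencies).
#' @return A [BpBModel-class].
#' @examples
#' pep <- simulatePeptides(nPos = 20, nNeg = 20, seed = 1)
#' fitBpB(pep)
#' @export
fitBpB <- function(train, m = 10L, pseudocount = 1) {
    stopifnot(is(train, "PeptideSet"))
    m <- as.integer(m)
    if (m < 1L) stopValidation("window length m must be >= 1")
    if (pseudocount < 0) stopValidation("pseudocount must be non-negative")
    y <- train@labels
    if (anyNA(y))
        stopValidation("all training records must be labelled")
    if (!any(y == 1L) || !any(y == 0L))
        stopValidation("both classes must be present in the training set")
    seqs <- as.character(train@sequences)
    tooShort <- nchar(seqs) < m
    if (any(tooShort))
        stopValidation("sequence shorter than window m = ", m, ": ",
                       peptideIds(train)[tooShort][1L])
    mkTable <- function(sub, terminal) {
        counts <- .positionCounts(sub, m, terminal)
        (counts + pseudocount) / (length(sub) + 20 * pseudocount)
    }
    tables <- list(Npos = mkTable(seqs[y == 1L], "N"),
                   Cpos = mkTable(seqs[y == 1L], "C"),
                   Nneg = mkTable(seqs[y == 0L], "N"),
                   Cneg = mkTable(seqs[y == 0L], "C"))
    new("BpBModel", m = m, pseudocount = pseudocount, alphabet = .AA20,
        tables = tables)
}

.bpbFeatureNames <- function(m) {
    paste0("BpB_", rep(c("N_pos", "C_pos", "N_neg", "C_neg"), each = m),
           "_", seq_len(m))
}

#' Encode peptides with fitted Bi-profile Bayes tables
#'
#' Each sequence becomes a vector of length `4m`: the posterior
#' probabilities of its N-terminal window residues under the positive
#' class, its C-terminal window residues under the positive class, then
#' the same two windows under the negative class. Encoding is a pure
#' table lookup: it reads the residues of the query and the tables of the
#' fitted model, never the query's label.
#'
#' @param model A fitted [BpBModel-class].
#' @param x A [PeptideSet-class] or character vector of validated
#'   sequences, each at least `m` residues long.
#' @return Numeric matrix, one row per sequence, `4m` named columns
#'   (`BpB_N_pos_1` ... `BpB_C_neg_m`).
#' @examples
#' pep <- simulatePeptides(nPos = 20, nNeg = 20, seed = 1)
#' mod <- fitBpB(pep)
#' dim(encodeBpB(mod, pep))  # 40 x 40
#' @export
encodeBpB <- function(model, x) {
    stopifnot(is(model, "BpBModel"))
    if (is(x, "PeptideSet")) {
        seqs <- as.character(x@sequences)
        ids <- peptideIds(x)
    } else {
        seqs <- canonicalizeSequence(as.character(x))
        ids <- names(x)
    }
    m <- model@m
    L <- nchar(seqs)
    if (any(L < m))
        stopValidation("sequence shorter than window m = ", m, ": ",
                       if (is.null(ids)) which(L < m)[1L]
                       else ids[L < m][1L])
    out <- matrix(NA_real_, nrow = length(seqs), ncol = 4L * m,
                  dimnames = list(ids, .bpbFeatureNames(m)))
    pos <- seq_len(m)
    for (s in seq_along(seqs)) {
        nRes <- substring(seqs[s], pos, pos)
        cRes <- substring(seqs[s], L[s] - m + pos, L[s] - m + pos)
        nIdx <- match(nRes, model@alphabet)
        cIdx <- match(cRes, model@alphabet)
        out[s, ] <- c(model@tables$Npos[cbind(pos, nIdx)],
                      model@tables$Cpos[cbind(pos, cIdx)],
                      model@tables$Nneg[cbind(pos, nIdx)],
                      model@tables$Cneg[cbind(pos, cIdx)])
    }
    out
}

#' Serialize / restore a BpBModel
#'
#' Plain-text JSON with the alphabet ordering recorded, so encodings are
#' reproducible bit-for-bit across runs and machines.
#'
#' @param model A [BpBModel-class].
#' @param path Output (input) file path.
#' @return `writeBpBModel()`: `path`, invisibly. `readBpBModel()`: the
#'   restored [BpBModel-class].
#' @export
writeBpBModel <- function(model, path) {
    stopifnot(is(model, "BpBModel"))
    payload <- list(format = "AntiAngioPep/BpBModel", version = 1L,
                    m = model@m, pseudocount = model@pseudocount,
                    alphabet = model@alphabet,
                    tables = lapply(model@tables, function(tab)
                        as.data.frame(tab)))
    jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname writeBpBModel
#' @export
readBpBModel <- function(path) {
    if (!file.exists(path))
        stopValidation("model file not found: ", path)
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(payload$format, "AntiAngioPep/BpBModel"))
        stopValidation("not a BpBModel file: ", path)
    tables <- lapply(payload$tables, function(df) {
        tab <- as.matrix(df)
        dimnames(tab) <- list(NULL, payload$alphabet)
        tab
    })
    new("BpBModel", m = as.integer(payload$m),
        pseudocount = payload$pseudocount,
        alphabet = payload$alphabet, tables = tables)
}
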