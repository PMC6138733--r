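## Four physicochemical residue groups: hydrophobic, polar, positively
## charged, negatively charged. They partition the 20-letter alphabet.
.CTD_GROUPS <- local({
    g <- integer(20)
    names(g) <- .AA20
    g[c("A", "F", "G", "I", "L", "M", "P", "V", "W")] <- 1L
    g[c("C", "N", "Q", "S", "T", "Y")] <- 2L
    g[c("H", "K", "R")] <- 3L
    g[c("D", "E")] <- 4L
    g
})

#' Physicochemical residue grouping used by the CTD encoder
#'
#' Residue -> group index map: group 1 hydrophobic (A, F, G, I, L, M, P, V,
#' W), group 2 polar (C, N, Q, S, T, Y), group 3 positively charged (H, K,
#' R), group 4 negatively charged (D, E).
#'
#' @return Named integer vector over the 20 canonical residues.
#' @examples
#' table(ctdGroupScheme())
#' @export
ctdGroupScheme <- function() .CTD_GROUPS

.TRANS_PAIRS <- cbind(i = c(1L, 1L, 1L, 2L, 2L, 3L),
                      j = c(2L, 3L, 4L, 3L, 4L, 4L))

.ctdFeatureNames <- function() {
    c(paste0("CTD_C_g", 1:4),
      paste0("CTD_T_g", .TRANS_PAIRS[, "i"], "g", .TRANS_PAIRS[, "j"]),
      paste0("CTD_D_g", rep(1:4, each = 5), "_q",
             rep(c(0, 25, 50, 75, 100), 4)))
}

.ctdOne <- function(groups) {
    L <- length(groups)
    comp <- tabulate(groups, nbins = 4L) / L
    trans <- numeric(6L)
    a <- groups[-L]
    b <- groups[-1L]
    for (t in seq_len(6L)) {
        i <- .TRANS_PAIRS[t, "i"]
        j <- .TRANS_PAIRS[t, "j"]
        trans[t] <- (sum(a == i & b == j) + sum(a == j & b == i)) / (L - 1)
    }
    distr <- numeric(20L)
    for (g in 1:4) {
        occ <- which(groups == g)
        n <- length(occ)
        if (n > 0L) {
            marks <- c(1L, ceiling(c(0.25, 0.5, 0.75) * n), n)
            distr[(g - 1L) * 5L + 1:5] <- occ[marks] / L
        }
    }
    c(comp, trans, distr)
}

#' Composition-Transition-Distribution descriptors
#'
#' Encodes each peptide as 30 features over the four physicochemical
#' groups of [ctdGroupScheme()]:
#' \describe{
#'   \item{Composition (4)}{frequency of each group, `N_i / L`.}
#'   \item{Transition (6)}{for each unordered group pair (i, j), the
#'     number of adjacent residue pairs going i->j or j->i divided by
#'     `L - 1`; pair order (1,2), (1,3), (1,4), (2,3), (2,4), (3,4).}
#'   \item{Distribution (20)}{for each group, the 1-based sequence
#'     positions of its first, 25\%, 50\%, 75\% and 100\% occurrences
#'     (occurrence index `ceiling(q * N_i)`, first mark fixed at
#'     occurrence 1), each divided by `L`; all five marks are 0 when the
#'     group is absent.}
#' }
#'
#' @param x A [PeptideSet-class] or character vector of validated
#'   sequences, each at least 2 residues long.
#' @return Numeric matrix, one row per sequence, 30 named columns; all
#'   values in `[0, 1]`.
#' @examples
#' encodeCTD("ACDH")[, 1:10]
#' @export
encodeCTD <- function(x) {
    if (is(x, "PeptideSet")) {
        seqs <- as.character(x@sequences)
        ids <- peptideIds(x)
    } else {
        seqs <- canonicalizeSequence(as.character(x))
        ids <- names(x)
    }
    short <- nchar(seqs) < 2L
    if (any(short))
        stopValidation("CTD needs length >= 2: ",
                       if (is.null(ids)) which(short)[1L]
                       else ids[short][1L])
    out <- matrix(NA_real_, nrow = length(seqs), ncol = 30L,
                  dimnames = list(ids, .ctdFeatureNames()))
    for (s in seq_along(seqs)) {
        groups <- unname(.CTD_GROUPS[strsplit(seqs[s], "")[[1]]])
        out[s, ] <- .ctdOne(groups)
    }
    out
}
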