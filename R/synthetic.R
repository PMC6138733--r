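## Residue sets reported as class-discriminating: enriched in
## anti-angiogenic peptides vs enriched in the negative class.
.POS_ENRICHED <- c("C", "P", "S", "R", "W", "T", "G")
.NEG_ENRICHED <- c("A", "D", "I", "L", "V", "F")

#' Enriched residue sets of the synthetic generator
#'
#' @return Named list with the residues whose probability mass is boosted
#'   in positive (`positive`) and negative (`negative`) synthetic
#'   peptides.
#' @export
enrichedResidues <- function() {
    list(positive = .POS_ENRICHED, negative = .NEG_ENRICHED)
}

.enrichedProbs <- function(background, enriched, factor) {
    p <- background
    p[enriched] <- p[enriched] * factor
    p / sum(p)
}

#' Simulate a labelled peptide dataset with terminal residue enrichment
#'
#' Draws peptides from a background residue distribution (uniform by
#' default) and plants the class signal this toolkit is built to detect:
#' in positive peptides the probability mass of Cys, Pro, Ser, Arg, Trp,
#' Thr and Gly is multiplied by `1 + 2 * effect` (renormalised), and by
#' `1 + 4 * effect` within the first and last `terminalWindow` positions,
#' mimicking the reported terminal-position residue preferences of
#' anti-angiogenic peptides; negative peptides are enriched symmetrically
#' in Ala, Asp, Ile, Leu, Val and Phe. `effect = 0` makes the two classes
#' exchangeable (a null dataset); `effect = 1` is the maximal planted
#' signal. Lengths are uniform on `lengthRange`. The output is fully
#' determined by `seed`.
#'
#' @param nPos,nNeg Numbers of positive and negative peptides
#'   (defaults 107 + 107, the size of the published benchmark).
#' @param lengthRange Integer min/max peptide length (default `c(10, 30)`;
#'   the minimum must be at least `terminalWindow`).
#' @param effect Bias strength in `[0, 1]` (default 1).
#' @param terminalWindow Positions at each end carrying the extra
#'   positional boost (default 10, matching the BpB window).
#' @param seed Integer seed.
#' @param background Optional named residue frequency vector (defaults
#'   to uniform 1/20).
#' @return A labelled [PeptideSet-class]: positives first
#'   (`pos_001`, ...), then negatives (`neg_001`, ...).
#' @examples
#' simulatePeptides(nPos = 5, nNeg = 5, seed = 42)
#' @export
simulatePeptides <- function(nPos = 107L, nNeg = 107L,
                             lengthRange = c(10L, 30L), effect = 1,
                             terminalWindow = 10L, seed = 1L,
                             background = NULL) {
    nPos <- as.integer(nPos)
    nNeg <- as.integer(nNeg)
    lengthRange <- as.integer(lengthRange)
    terminalWindow <- as.integer(terminalWindow)
    if (nPos < 1L || nNeg < 1L)
        stopValidation("nPos and nNeg must be >= 1")
    if (length(lengthRange) != 2L || lengthRange[1L] > lengthRange[2L])
        stopValidation("lengthRange must be c(min, max) with min <= max")
    if (lengthRange[1L] < terminalWindow)
        stopValidation("minimum length must be >= terminalWindow")
    if (effect < 0 || effect > 1)
        stopValidation("effect must lie in [0, 1]")
    if (is.null(background)) {
        background <- stats::setNames(rep(1 / 20, 20), .AA20)
    } else {
        missing <- setdiff(.AA20, names(background))
        if (length(missing))
            stopValidation("background is missing residue(s): ",
                           paste(missing, collapse = ", "))
        background <- background[.AA20] / sum(background[.AA20])
    }
    probs <- list(
        pos = list(core = .enrichedProbs(background, .POS_ENRICHED,
                                         1 + 2 * effect),
                   term = .enrichedProbs(background, .POS_ENRICHED,
                                         1 + 4 * effect)),
        neg = list(core = .enrichedProbs(background, .NEG_ENRICHED,
                                         1 + 2 * effect),
                   term = .enrichedProbs(background, .NEG_ENRICHED,
                                         1 + 4 * effect)))
    .withSeed(seed, {
        lenPool <- seq.int(lengthRange[1L], lengthRange[2L])
        draw <- function(n, cls) {
            lens <- lenPool[sample.int(length(lenPool), n,
                                       replace = TRUE)]
            vapply(lens, function(L) {
                inTerm <- seq_len(L) <= terminalWindow |
                          seq_len(L) > L - terminalWindow
                res <- character(L)
                res[inTerm] <- sample(.AA20, sum(inTerm), replace = TRUE,
                                      prob = probs[[cls]]$term)
                res[!inTerm] <- sample(.AA20, sum(!inTerm), replace = TRUE,
                                       prob = probs[[cls]]$core)
                paste(res, collapse = "")
            }, character(1L))
        }
        seqs <- c(draw(nPos, "pos"), draw(nNeg, "neg"))
        ids <- c(sprintf("pos_%03d", seq_len(nPos)),
                 sprintf("neg_%03d", seq_len(nNeg)))
        PeptideSet(seqs, ids = ids,
                   labels = rep(c(1L, 0L), c(nPos, nNeg)))
    })
}
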