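#' Built-in amino-acid property scales
#'
#' `kyteDoolittleScale()` is the Kyte-Doolittle hydropathy index;
#' `hoppWoodsScale()` the Hopp-Woods hydrophilicity index. These are the
#' default property profiles for the discrete-Fourier encoder; any other
#' scale can be supplied as a named numeric vector covering all 20
#' residues, or read from a two-column text table with
#' [readPropertyScale()].
#'
#' @return Named numeric vector over the 20 canonical residues.
#' @examples
#' kyteDoolittleScale()["W"]
#' @export
kyteDoolittleScale <- function() {
    c(A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
      G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
      M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
      S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3)
}

#' @rdname kyteDoolittleScale
#' @export
hoppWoodsScale <- function() {
    c(A = -0.5, C = -1.0, D =  3.0, E =  3.0, F = -2.5,
      G =  0.0, H = -0.5, I = -1.8, K =  3.0, L = -1.8,
      M = -1.3, N =  0.2, P =  0.0, Q =  0.2, R =  3.0,
      S =  0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3)
}

#' Read a property scale from a two-column text table
#'
#' @param path Path to a whitespace- or tab-separated file with two
#'   columns: residue letter, numeric value; no header. All 20 residues
#'   must be present.
#' @return Named numeric vector over the 20 canonical residues.
#' @export
readPropertyScale <- function(path) {
    if (!file.exists(path))
        stopValidation("scale file not found: ", path)
    tab <- utils::read.table(path, header = FALSE,
                             col.names = c("residue", "value"),
                             colClasses = c("character", "numeric"))
    vals <- stats::setNames(tab$value, toupper(tab$residue))
    missing <- setdiff(.AA20, names(vals))
    if (length(missing))
        stopValidation("scale is missing residue(s): ",
                       paste(missing, collapse = ", "))
    vals[.AA20]
}

#' Discrete Fourier power spectrum of a numeric profile
#'
#' Computes `F(k) = sum_{n=1..L} H(p_n) exp(-2*pi*i*n*k/L)` for
#' `k = 0..L-1` and the power spectrum `PS(k) = |F(k)|^2`. The returned
#' coefficients carry the `n = 1..L` phase convention; the power spectrum
#' is identical to that of the usual `n = 0..L-1` transform.
#'
#' @param profile Numeric vector of length `L >= 1` (per-residue property
#'   values).
#' @return List with elements `coefficients` (complex, length `L`) and
#'   `power` (numeric, length `L`, non-negative; conjugate-symmetric for
#'   real input: `PS(k) = PS(L - k)`).
#' @examples
#' dftPower(c(1, -1, 1, -1))$power  # 0 0 16 0
#' @export
dftPower <- function(profile) {
    if (length(profile) == 0L)
        stopValidation("empty profile")
    if (!all(is.finite(profile)))
        stopValidation("profile must be finite")
    L <- length(profile)
    k <- seq_len(L) - 1L
    coef <- fft(profile) * exp(-2i * pi * k / L)
    list(coefficients = coef, power = Mod(coef)^2)
}

#' Low-frequency DFT power-spectrum features
#'
#' Maps each peptide onto two numeric profiles -- hydrophobicity and
#' hydrophilicity by default -- and emits the DFT power spectrum at the
#' `nFreq` lowest frequencies `k = 0..nFreq-1` for each scale, in scale
#' order. With the defaults this is a 20-dimensional vector per peptide.
#'
#' @param x A [PeptideSet-class] or character vector of validated
#'   sequences, each at least `nFreq` residues long.
#' @param scales Named list of property scales (named numeric vectors
#'   over the 20 residues). Default: Kyte-Doolittle hydrophobicity and
#'   Hopp-Woods hydrophilicity.
#' @param nFreq Number of low-frequency components per scale (default 10,
#'   DC component `k = 0` included).
#' @param center If `TRUE`, each profile is mean-centred before the
#'   transform, which zeroes the `k = 0` component. Default `FALSE` (raw
#'   scale values).
#' @return Numeric matrix, one row per sequence, `length(scales) * nFreq`
#'   named columns (`DFT_<scale>_k<k>`).
#' @examples
#' encodeDFT("ACDEFGHIKL")[, 1:5]
#' @export
encodeDFT <- function(x,
                      scales = list(hydrophobicity = kyteDoolittleScale(),
                                    hydrophilicity = hoppWoodsScale()),
                      nFreq = 10L, center = FALSE) {
    if (is(x, "PeptideSet")) {
        seqs <- as.character(x@sequences)
        ids <- peptideIds(x)
    } else {
        seqs <- canonicalizeSequence(as.character(x))
        ids <- names(x)
    }
    nFreq <- as.integer(nFreq)
    if (nFreq < 1L) stopValidation("nFreq must be >= 1")
    if (is.null(names(scales)) || any(names(scales) == ""))
        stopValidation("scales must be a named list")
    for (nm in names(scales)) {
        missing <- setdiff(.AA20, names(scales[[nm]]))
        if (length(missing))
            stopValidation("scale '", nm, "' is missing residue(s): ",
                           paste(missing, collapse = ", "))
    }
    short <- nchar(seqs) < nFreq
    if (any(short))
        stopValidation("DFT needs length >= nFreq = ", nFreq, ": ",
                       if (is.null(ids)) which(short)[1L]
                       else ids[short][1L])
    cols <- paste0("DFT_", rep(names(scales), each = nFreq), "_k",
                   rep(seq_len(nFreq) - 1L, length(scales)))
    out <- matrix(NA_real_, nrow = length(seqs), ncol = length(cols),
                  dimnames = list(ids, cols))
    for (s in seq_along(seqs)) {
        res <- strsplit(seqs[s], "")[[1]]
        feats <- lapply(scales, function(sc) {
            prof <- unname(sc[res])
            if (center) prof <- prof - mean(prof)
            dftPower(prof)$power[seq_len(nFreq)]
        })
        out[s, ] <- unlist(feats, use.names = FALSE)
    }
    out
}
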