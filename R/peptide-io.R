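#' Canonicalize a raw peptide sequence
#'
#' Strips whitespace, uppercases, and validates that only the 20 canonical
#' amino-acid letters remain. Ambiguity codes and non-standard residues
#' (B, J, O, U, X, Z) are rejected, not remapped: every downstream encoder
#' assumes the 20-letter alphabet.
#'
#' @param x Character vector of raw sequences.
#' @param id Optional identifier(s) used in error messages.
#' @return Character vector of validated sequences.
#' @examples
#' canonicalizeSequence("acDE")   # "ACDE"
#' canonicalizeSequence("AC DE")  # "ACDE"
#' @export
canonicalizeSequence <- function(x, id = NULL) {
    out <- toupper(gsub("[[:space:]]+", "", x))
    for (k in seq_along(out)) {
        bad <- setdiff(strsplit(out[k], "")[[1]], .AA20)
        if (length(bad)) {
            who <- if (is.null(id)) paste0("sequence ", k) else id[k]
            stopValidation("record '", who, "' contains non-canonical ",
                           "residue(s): ", paste(bad, collapse = ", "))
        }
    }
    out
}

#' Construct a PeptideSet
#'
#' @param sequences Character vector or [Biostrings::AAStringSet]. Character
#'   input is canonicalized (whitespace stripped, uppercased, validated).
#' @param ids Record identifiers; defaults to the names of `sequences`.
#' @param labels Binary class labels (1 = positive/anti-angiogenic,
#'   0 = negative, `NA` = unlabelled); recycled if length 1.
#' @return A [PeptideSet-class].
#' @examples
#' PeptideSet(c(a = "ACDEFGHIKL", b = "WWWWWWWWWW"), labels = c(1, 0))
#' @export
PeptideSet <- function(sequences, ids = names(sequences),
                       labels = NA_integer_) {
    if (is(sequences, "AAStringSet")) {
        seqs <- as.character(sequences)
        if (is.null(ids)) ids <- names(sequences)
    } else {
        seqs <- as.character(sequences)
    }
    if (is.null(ids))
        ids <- paste0("pep", seq_along(seqs))
    seqs <- canonicalizeSequence(seqs, id = ids)
    if (anyDuplicated(ids))
        stopValidation("duplicate record id: ", ids[duplicated(ids)][1L])
    labels <- as.integer(rep_len(labels, length(seqs)))
    if (!all(labels %in% c(0L, 1L, NA_integer_)))
        stopValidation("labels must be 0, 1 or NA")
    aa <- Biostrings::AAStringSet(stats::setNames(seqs, ids))
    new("PeptideSet", sequences = aa, labels = labels)
}

## Pull a trailing "|1" / "|0" class tag off FASTA ids.
.splitHeaderTag <- function(ids) {
    tag <- rep(NA_integer_, length(ids))
    hit <- grepl("\\|[01]$", ids)
    tag[hit] <- as.integer(sub("^.*\\|([01])$", "\\1", ids[hit]))
    ids[hit] <- sub("\\|[01]$", "", ids[hit])
    list(ids = ids, labels = tag)
}

#' Read peptides from a FASTA file
#'
#' Reads one record per FASTA entry, in file order. Lowercase letters are
#' canonicalized to uppercase; whitespace inside sequences is dropped.
#' Labels come either from the `label` argument (applied to every record,
#' the two-files-one-per-class layout) or from a header id ending in
#' `|1` / `|0`.
#'
#' @param path FASTA file path.
#' @param label Optional class (0 or 1) assigned to all records; overrides
#'   header tags.
#' @param dropInvalid If `TRUE`, records containing non-canonical residues
#'   are discarded with a warning instead of raising an error.
#' @return A [PeptideSet-class].
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1|1", "ACDEFGHIKL", ">p2|0", "WWWWWWWWWW"), fa)
#' readPeptideFasta(fa)
#' @export
readPeptideFasta <- function(path, label = NULL, dropInvalid = FALSE) {
    if (!file.exists(path))
        stopValidation("file not found: ", path)
    aa <- tryCatch(Biostrings::readAAStringSet(path),
                   error = function(e) stopValidation(
                       "cannot parse FASTA '", path, "': ",
                       conditionMessage(e)))
    if (length(aa) == 0L)
        stopValidation("empty FASTA file: ", path)
    ids <- sub("\\s.*$", "", names(aa))
    parsed <- .splitHeaderTag(ids)
    seqs <- toupper(as.character(aa))
    labels <- parsed$labels
    if (!is.null(label))
        labels <- rep(as.integer(label), length(seqs))
    if (dropInvalid) {
        ok <- vapply(strsplit(seqs, ""), function(ch)
            all(ch %in% .AA20), logical(1))
        if (!all(ok)) {
            warning("dropping ", sum(!ok), " record(s) with non-canonical ",
                    "residues: ",
                    paste(parsed$ids[!ok], collapse = ", "))
            seqs <- seqs[ok]
            labels <- labels[ok]
            parsed$ids <- parsed$ids[ok]
            if (!length(seqs))
                stopValidation("no valid records left in ", path)
        }
    }
    PeptideSet(seqs, ids = parsed$ids, labels = labels)
}

#' Write peptides to a FASTA file
#'
#' Headers carry the record id, with a `|1` / `|0` class tag appended for
#' labelled records so that a write/read round trip reproduces ids,
#' sequences and labels exactly.
#'
#' @param object A [PeptideSet-class].
#' @param path Output file path.
#' @param tagLabels Append `|label` to the header of labelled records
#'   (default `TRUE`).
#' @return `path`, invisibly.
#' @export
writePeptideFasta <- function(object, path, tagLabels = TRUE) {
    stopifnot(is(object, "PeptideSet"))
    ids <- peptideIds(object)
    if (tagLabels) {
        lab <- object@labels
        ids <- ifelse(is.na(lab), ids, paste0(ids, "|", lab))
    }
    out <- object@sequences
    names(out) <- ids
    Biostrings::writeXStringSet(out, filepath = path)
    invisible(path)
}

#' Read a TSV label file
#'
#' Alternative label source: a two-column tab-separated file
#' `id<TAB>label` with labels 0/1 and no header.
#'
#' @param object A [PeptideSet-class].
#' @param path Path to the TSV file.
#' @return `object` with labels replaced for every id listed in the file.
#' @export
applyLabelTSV <- function(object, path) {
    stopifnot(is(object, "PeptideSet"))
    if (!file.exists(path))
        stopValidation("label file not found: ", path)
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("id", "label"),
                             colClasses = c("character", "integer"))
    if (!all(tab$label %in% c(0L, 1L)))
        stopValidation("labels in ", path, " must be 0 or 1")
    hit <- match(tab$id, peptideIds(object))
    if (anyNA(hit))
        stopValidation("label file lists unknown id: ",
                       tab$id[is.na(hit)][1L])
    labels <- object@labels
    labels[hit] <- tab$label
    new("PeptideSet", sequences = object@sequences, labels = labels)
}

#' Combine two PeptideSets
#'
#' @param x,y [PeptideSet-class] objects with disjoint ids.
#' @return The concatenated [PeptideSet-class].
#' @export
combinePeptideSets <- function(x, y) {
    stopifnot(is(x, "PeptideSet"), is(y, "PeptideSet"))
    PeptideSet(c(as.character(x@sequences), as.character(y@sequences)),
               ids = c(peptideIds(x), peptideIds(y)),
               labels = c(x@labels, y@labels))
}
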