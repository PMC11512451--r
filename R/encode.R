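## Alignments are AAStringSet objects of equal width (gap = '-').
## Column-dropping operations record the surviving original column indices
## in metadata(al)$columns so downstream feature labels and PositionMap
## joins stay in the original coordinate frame.

#' Read an aligned FASTA file
#'
#' @param path aligned FASTA; all rows must share one width.
#' @return \code{AAStringSet} with ids trimmed at the first whitespace.
#' @export
readAlignment <- function(path) {
    al <- Biostrings::readAAStringSet(path)
    names(al) <- sub("\\s.*$", "", names(al))
    if (length(unique(Biostrings::width(al))) > 1L)
        stop("alignment rows differ in length")
    al
}

#' @keywords internal
alignmentMatrix <- function(al) {
    if (is.matrix(al)) return(al)
    stopifnot(is(al, "AAStringSet"))
    if (length(unique(Biostrings::width(al))) > 1L)
        stop("alignment rows differ in length")
    mat <- do.call(rbind, strsplit(as.character(al), ""))
    rownames(mat) <- names(al)
    mat
}

#' @keywords internal
alignmentColumns <- function(al) {
    cols <- S4Vectors::metadata(al)$columns
    if (is.null(cols)) seq_len(Biostrings::width(al)[1L]) else cols
}

subsetColumns <- function(al, keep_idx) {
    mat <- alignmentMatrix(al)
    out <- Biostrings::AAStringSet(apply(
        mat[, keep_idx, drop = FALSE], 1L, paste, collapse = ""))
    names(out) <- rownames(mat)
    S4Vectors::metadata(out)$columns <- alignmentColumns(al)[keep_idx]
    out
}

#' Per-column composition, Shannon entropy and gap statistics
#'
#' For every alignment column: residue frequencies over non-gap cells, the
#' gap fraction, Shannon entropy \eqn{H = -\sum p \log_2 p} in bits, and
#' relative entropy \eqn{H / \max_c H} scaled so the most variable column
#' scores 1. All-gap columns have undefined entropy: they are flagged
#' (\code{all_gap}) and excluded from the relative scaling.
#'
#' @param al alignment (\code{AAStringSet} or character matrix).
#' @return data.frame with one row per column: \code{column} (original
#'   index), \code{gap_fraction}, \code{n_states} (distinct non-gap
#'   residues), \code{entropy} (bits, \code{NA} for all-gap columns),
#'   \code{rel_entropy}, \code{all_gap}, \code{residues}
#'   (comma-joined observed residues), \code{consensus}.
#' @examples
#' al <- Biostrings::AAStringSet(c(a = "AAC", b = "ACD", c = "ACE"))
#' columnProfiles(al)
#' @export
columnProfiles <- function(al) {
    mat <- alignmentMatrix(al)
    if (!nrow(mat)) stop("empty alignment")
    cols <- alignmentColumns(al)
    stats_one <- function(j) {
        v <- mat[, j]
        nongap <- v[v != "-"]
        gapf <- 1 - length(nongap) / length(v)
        if (!length(nongap))
            return(list(gapf = gapf, n = 0L, H = NA_real_,
                        res = "", cons = NA_character_))
        tab <- table(nongap)
        p <- as.numeric(tab) / sum(tab)
        H <- -sum(p * log2(p))
        list(gapf = gapf, n = length(tab), H = H,
             res = paste(names(tab), collapse = ","),
             cons = names(tab)[which.max(tab)])
    }
    st <- lapply(seq_len(ncol(mat)), stats_one)
    H <- vapply(st, `[[`, numeric(1), "H")
    maxH <- suppressWarnings(max(H, na.rm = TRUE))
    rel <- if (is.finite(maxH) && maxH > 0) H / maxH else
        ifelse(is.na(H), NA_real_, 0)
    data.frame(
        column = cols,
        gap_fraction = vapply(st, `[[`, numeric(1), "gapf"),
        n_states = vapply(st, `[[`, integer(1), "n"),
        entropy = H,
        rel_entropy = rel,
        all_gap = is.na(H),
        residues = vapply(st, `[[`, character(1), "res"),
        consensus = vapply(st, `[[`, character(1), "cons"),
        stringsAsFactors = FALSE)
}

#' Drop invariant (zero-entropy) alignment columns
#'
#' Columns with fewer than two distinct non-gap residues carry no signal
#' for a regressor and are removed before encoding. Invariance is judged on
#' non-gap residues, so a column of \{A, gap\} is invariant. The indices of
#' dropped columns (original frame) are stored in
#' \code{metadata(result)$dropped}.
#'
#' @param al alignment.
#' @return alignment restricted to variable columns; warns when nothing
#'   survives.
#' @export
dropInvariantColumns <- function(al) {
    prof <- columnProfiles(al)
    keep <- prof$n_states >= 2L
    if (!any(keep)) warning("all columns are invariant; empty alignment returned")
    out <- subsetColumns(al, which(keep))
    S4Vectors::metadata(out)$dropped <- prof$column[!keep]
    out
}

#' Remove heavily gapped columns
#'
#' A light-weight alignment cleanup in the spirit of gap-based block
#' filtering: columns whose gap fraction exceeds \code{max_gap_fraction}
#' are removed. This is a gap-fraction rule only, not a conservation-aware
#' block selector. \code{max_gap_fraction = 1} is the identity.
#'
#' @param al alignment.
#' @param max_gap_fraction keep columns with gap fraction \code{<=} this
#'   value, in [0, 1].
#' @return trimmed alignment; removed original column indices in
#'   \code{metadata(result)$removed}.
#' @export
trimColumns <- function(al, max_gap_fraction) {
    stopifnot(max_gap_fraction >= 0, max_gap_fraction <= 1)
    prof <- columnProfiles(al)
    keep <- prof$gap_fraction <= max_gap_fraction
    out <- subsetColumns(al, which(keep))
    S4Vectors::metadata(out)$removed <- prof$column[!keep]
    out
}

#' One-hot encode an alignment
#'
#' Training mode (\code{vocab = NULL}) builds the per-column residue
#' vocabulary from the alignment itself: one indicator feature per
#' (column, residue) pair observed, labelled \code{"p<column>:<residue>"}.
#' Prediction mode (\code{vocab} from a training \code{EncodedAlignment})
#' reuses the training features exactly; residues not in a column's
#' training vocabulary — and gaps — encode as all-zero across that column's
#' block, so any unseen residue is indistinguishable from any other.
#'
#' @param al alignment (rows to encode).
#' @param vocab \code{NULL} for training mode, or the named per-column
#'   residue list from \code{\link{vocabulary}} of the training encoding.
#' @return an \code{\link{EncodedAlignment}}.
#' @export
oneHot <- function(al, vocab = NULL) {
    mat <- alignmentMatrix(al)
    cols <- alignmentColumns(al)
    if (is.null(vocab)) {
        vocab <- lapply(seq_along(cols), function(j) {
            v <- unique(mat[, j])
            sort(v[v != "-"])
        })
        names(vocab) <- as.character(cols)
    } else {
        if (length(vocab) != length(cols) ||
            !identical(names(vocab), as.character(cols)))
            stop("vocabulary columns do not match the alignment columns")
    }
    feat <- do.call(rbind, lapply(seq_along(vocab), function(j) {
        if (!length(vocab[[j]])) return(NULL)
        data.frame(label = paste0("p", names(vocab)[j], ":", vocab[[j]]),
                   column = as.integer(names(vocab)[j]),
                   residue = vocab[[j]], stringsAsFactors = FALSE)
    }))
    if (is.null(feat))
        feat <- data.frame(label = character(), column = integer(),
                           residue = character(), stringsAsFactors = FALSE)
    x <- matrix(0, nrow = nrow(mat), ncol = nrow(feat),
                dimnames = list(rownames(mat), feat$label))
    colpos <- match(as.character(feat$column), names(vocab))
    for (f in seq_len(nrow(feat)))
        x[, f] <- as.numeric(mat[, colpos[f]] == feat$residue[f])
    new("EncodedAlignment", x = x, features = feat, vocabulary = vocab)
}

#' Map alignment columns to reference (bovine rhodopsin) coordinates
#'
#' Walks the reference row: its non-gap columns receive consecutive
#' reference positions \code{1..L}; columns where the reference is gapped
#' receive insertion codes \code{"<prevPos>+k"} (\code{"0+k"} before the
#' first reference residue). Each column is labelled with the
#' transmembrane domain whose reference interval contains it, or
#' \code{"loop"}.
#'
#' @param al alignment containing the reference row.
#' @param reference_row accession of the reference sequence in \code{al}.
#' @param tmd_table optional data.frame \code{tmd}, \code{start},
#'   \code{end} (closed intervals, reference coordinates); see
#'   \code{\link{readTmdTable}}.
#' @return a \code{\link{PositionMap}}.
#' @examples
#' al <- Biostrings::AAStringSet(c(ref = "M-A", x = "MCA"))
#' positionTable(mapToReference(al, "ref"))
#' @export
mapToReference <- function(al, reference_row, tmd_table = NULL) {
    mat <- alignmentMatrix(al)
    if (!reference_row %in% rownames(mat))
        stop("reference row '", reference_row, "' not found in alignment")
    cols <- alignmentColumns(al)
    refc <- mat[reference_row, ]
    ref_index <- cumsum(refc != "-")
    is_ins <- refc == "-"
    ins_k <- integer(length(refc))
    run <- 0L
    for (j in seq_along(refc)) {
        if (is_ins[j]) { run <- run + 1L; ins_k[j] <- run } else run <- 0L
    }
    ref_pos <- ifelse(is_ins, paste0(ref_index, "+", ins_k),
                      as.character(ref_index))
    tmd <- rep("loop", length(refc))
    if (!is.null(tmd_table)) {
        for (r in seq_len(nrow(tmd_table))) {
            hit <- !is_ins & ref_index >= tmd_table$start[r] &
                ref_index <= tmd_table$end[r]
            tmd[hit] <- paste0("TMD", tmd_table$tmd[r])
        }
    }
    new("PositionMap", reference = reference_row,
        map = data.frame(column = cols, ref_pos = ref_pos,
                         ref_index = as.integer(ref_index),
                         is_insertion = is_ins, tmd = tmd,
                         stringsAsFactors = FALSE))
}

#' Read a transmembrane-domain boundary table
#'
#' Key-value file with lines \code{TMD<k> = <start>-<end>} (reference
#' coordinates, closed intervals); '#' comments and blank lines ignored.
#'
#' @param path file path.
#' @return data.frame \code{tmd}, \code{start}, \code{end}, ordered and
#'   checked for overlap.
#' @export
readTmdTable <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    pat <- "^TMD([1-7])\\s*=\\s*([0-9]+)\\s*-\\s*([0-9]+)$"
    if (any(!grepl(pat, lines)))
        stop("malformed TMD line(s): ",
             paste(lines[!grepl(pat, lines)], collapse = "; "))
    tab <- data.frame(tmd = as.integer(sub(pat, "\\1", lines)),
                      start = as.integer(sub(pat, "\\2", lines)),
                      end = as.integer(sub(pat, "\\3", lines)))
    tab <- tab[order(tab$start), ]
    if (any(tab$end < tab$start)) stop("TMD interval end before start")
    if (nrow(tab) > 1L && any(tab$start[-1L] <= tab$end[-nrow(tab)]))
        stop("TMD intervals overlap")
    tab
}
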