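#' Parse compact mutation notation
#'
#' Tokens of the form \code{<wt><position><new>} (e.g. \code{"D83N"}) joined
#' by underscores describe point mutations relative to a parent sequence:
#' \code{"D83N_A292S"} replaces D at position 83 with N and A at 292 with S.
#' Positions are 1-based indices into the ungapped parent by default
#' (\code{frame = "native"}); \code{frame = "reference"} marks positions as
#' bovine-rhodopsin numbering to be resolved through a \code{PositionMap}.
#'
#' @param s non-empty notation string.
#' @param frame \code{"native"} (default) or \code{"reference"}.
#' @return a \code{\link{MutationSpec}} with edits sorted by position.
#' @examples
#' parseMutations("D83N_A292S")
#' @export
parseMutations <- function(s, frame = c("native", "reference")) {
    frame <- match.arg(frame)
    if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s))
        stop("notation must be a non-empty string")
    tokens <- strsplit(s, "_", fixed = TRUE)[[1]]
    pat <- "^([A-Z])([0-9]+)([A-Z])$"
    for (tok in tokens) {
        if (!grepl(pat, tok))
            stop("malformed mutation token: '", tok, "'")
        aa <- c(sub(pat, "\\1", tok), sub(pat, "\\3", tok))
        if (any(!aa %in% AA_ALPHABET20))
            stop("unknown amino-acid letter in token: '", tok, "'")
        if (as.integer(sub(pat, "\\2", tok)) < 1L)
            stop("position must be >= 1 in token: '", tok, "'")
    }
    pos <- as.integer(sub(pat, "\\2", tokens))
    o <- order(pos)
    new("MutationSpec",
        wt = sub(pat, "\\1", tokens)[o], pos = pos[o],
        new = sub(pat, "\\3", tokens)[o], frame = frame)
}

#' Render a MutationSpec back to notation
#'
#' @param spec a \code{MutationSpec}.
#' @return underscore-joined tokens in ascending position order; \code{""}
#'   for an empty spec.
#' @export
notation <- function(spec) {
    stopifnot(is(spec, "MutationSpec"))
    if (length(spec@pos) == 0L) return("")
    paste0(spec@wt, spec@pos, spec@new, collapse = "_")
}

#' Apply point mutations to a sequence
#'
#' Every edit is checked against the sequence before application: the
#' residue at each edit position must equal the spec's wild-type residue
#' (guarding against coordinate-frame mistakes), and positions must lie
#' within the sequence. Reference-frame specs must first be translated with
#' \code{\link{translateSpec}}.
#'
#' @param seq ungapped amino-acid string.
#' @param spec a \code{MutationSpec} in the native frame.
#' @return mutated sequence, same length, differing from \code{seq} exactly
#'   at the edit positions.
#' @examples
#' applyMutations("MDA", parseMutations("A3V"))
#' @export
applyMutations <- function(seq, spec) {
    stopifnot(is(spec, "MutationSpec"))
    if (spec@frame != "native")
        stop("spec is in the reference frame; translate it with translateSpec() first")
    chars <- strsplit(seq, "")[[1]]
    if (length(spec@pos) && max(spec@pos) > length(chars))
        stop("edit position ", max(spec@pos), " beyond sequence length ",
             length(chars))
    have <- chars[spec@pos]
    bad <- which(have != spec@wt)
    if (length(bad))
        stop("wild-type residue mismatch at position ",
             paste(spec@pos[bad], collapse = ", "), ": sequence has ",
             paste(have[bad], collapse = ", "), ", notation expects ",
             paste(spec@wt[bad], collapse = ", "))
    chars[spec@pos] <- spec@new
    paste(chars, collapse = "")
}

#' Translate a reference-frame MutationSpec into native coordinates
#'
#' Maps bovine-rhodopsin-numbered positions onto the ungapped coordinates of
#' a target row of the alignment underlying \code{pmap}.
#'
#' @param spec \code{MutationSpec} with \code{frame == "reference"}.
#' @param pmap \code{PositionMap} for the alignment.
#' @param target_row aligned sequence (string with gaps) of the target
#'   record in that alignment.
#' @return native-frame \code{MutationSpec} for the ungapped target.
#' @export
translateSpec <- function(spec, pmap, target_row) {
    stopifnot(is(spec, "MutationSpec"), is(pmap, "PositionMap"))
    if (spec@frame != "reference") return(spec)
    m <- pmap@map
    tchars <- strsplit(target_row, "")[[1]]
    if (length(tchars) != nrow(m))
        stop("target row length does not match the PositionMap alignment")
    native_of_col <- cumsum(tchars != "-")
    cols <- m$column[match(as.character(spec@pos), m$ref_pos)]
    if (anyNA(cols))
        stop("reference position(s) not present in PositionMap: ",
             paste(spec@pos[is.na(cols)], collapse = ", "))
    if (any(tchars[cols] == "-"))
        stop("target is gapped at reference position(s): ",
             paste(spec@pos[tchars[cols] == "-"], collapse = ", "))
    o <- order(native_of_col[cols])
    new("MutationSpec", wt = spec@wt[o],
        pos = as.integer(native_of_col[cols][o]),
        new = spec@new[o], frame = "native")
}

#' Derive mutation notation from a wild-type / mutant pair
#'
#' The inverse of \code{\link{applyMutations}}: positions where the two
#' equal-length ungapped sequences differ become tokens, joined by
#' underscores in ascending position order.
#'
#' @param wt,mut equal-length amino-acid strings.
#' @return notation string; \code{""} when the sequences are identical.
#' @examples
#' diffToNotation("MDA", "MDV")
#' @export
diffToNotation <- function(wt, mut) {
    a <- strsplit(wt, "")[[1]]
    b <- strsplit(mut, "")[[1]]
    if (length(a) != length(b))
        stop("sequences differ in length (", length(a), " vs ", length(b), ")")
    d <- which(a != b)
    if (!length(d)) return("")
    paste0(a[d], d, b[d], collapse = "_")
}

#' Build a chimeric sequence by transmembrane-domain swap
#'
#' Within the alignment columns covered by the selected transmembrane
#' domains (resolved from reference coordinates through \code{pmap}) the
#' donor row's residues replace the parent's; all other columns keep the
#' parent. Gaps are removed from the result, yielding the ungapped chimera.
#'
#' @param parent_row,donor_row aligned rows (strings with gaps) from the
#'   same alignment.
#' @param spec a \code{\link{ChimeraSpec}}.
#' @param pmap \code{PositionMap} of that alignment.
#' @return ungapped chimeric amino-acid string.
#' @export
buildChimera <- function(parent_row, donor_row, spec, pmap) {
    stopifnot(is(spec, "ChimeraSpec"), is(pmap, "PositionMap"))
    p <- strsplit(parent_row, "")[[1]]
    d <- strsplit(donor_row, "")[[1]]
    m <- pmap@map
    if (length(p) != nrow(m) || length(d) != length(p))
        stop("rows must match the PositionMap alignment width")
    sel <- rep(FALSE, length(p))
    for (k in spec@domains) {
        b <- spec@boundaries[spec@boundaries$tmd == k, ]
        cols <- m$column[!m$is_insertion &
                         m$ref_index >= b$start & m$ref_index <= b$end]
        if (!length(cols) || all(d[cols] == "-"))
            stop("donor is entirely gapped over TMD", k)
        sel[cols] <- TRUE
    }
    out <- ifelse(sel, d, p)
    paste(out[out != "-"], collapse = "")
}
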