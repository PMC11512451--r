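#' Construct an OpsinSet from metadata and sequences
#'
#' @param meta data.frame (or DataFrame) with the standard metadata columns;
#'   missing optional columns (\code{dna_seq}, \code{mutation_notation},
#'   \code{parent_accession}) are filled with \code{NA}.
#' @param seqs named character vector or \code{AAStringSet}; names are
#'   accessions and must cover \code{meta$accession}.
#' @param name,version dataset name and version strings.
#' @return a validated \code{\link{OpsinSet}}.
#' @export
OpsinSet <- function(meta, seqs, name = "dataset", version = "1.0") {
    meta <- as.data.frame(meta)
    for (col in c("species", "phylum", "class_name", "gene_family",
                  "mutation_notation", "parent_accession", "source_ref"))
        if (!col %in% colnames(meta)) meta[[col]] <- NA_character_
    if (!"accession" %in% colnames(meta)) stop("meta needs an accession column")
    if (!"lambda_max" %in% colnames(meta)) stop("meta needs a lambda_max column")
    if (!"record_type" %in% colnames(meta)) meta$record_type <- "wt"
    if (is.character(seqs)) seqs <- Biostrings::AAStringSet(seqs)
    idx <- match(meta$accession, names(seqs))
    if (anyNA(idx))
        stop("missing sequence for accession(s): ",
             paste(meta$accession[is.na(idx)], collapse = ", "))
    new("OpsinSet", name = name, version = version,
        meta = S4Vectors::DataFrame(meta[, OPSIN_META_COLS]),
        seqs = seqs[idx])
}

#' Load a genotype-phenotype dataset from FASTA + TSV
#'
#' Joins a FASTA file of ungapped amino-acid sequences (ids = accessions;
#' descriptions ignored) with a tab-separated metadata table by accession.
#' The FASTA ids must form a superset of the metadata accessions; a metadata
#' row without a sequence is a hard error naming the accession.
#'
#' @param seq_path path to FASTA file.
#' @param meta_path path to TSV with header; required columns
#'   \code{accession} and \code{lambda_max}; '.' decimal, UTF-8.
#' @param name,version dataset name/version recorded on the object.
#' @return an \code{OpsinSet}.
#' @examples
#' study <- generateStudy(n_tips = 6, n_mutants = 2, seed = 1)
#' d <- tempfile(); dir.create(d)
#' paths <- writeOpsinSet(study$dataset, d)
#' ds <- loadOpsinSet(paths["fasta"], paths["meta"])
#' length(ds)
#' @export
loadOpsinSet <- function(seq_path, meta_path, name = "dataset",
                         version = "1.0") {
    seqs <- Biostrings::readAAStringSet(seq_path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    meta <- utils::read.delim(meta_path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE, quote = "",
                              na.strings = c("NA", ""),
                              fileEncoding = "UTF-8")
    lam <- suppressWarnings(as.numeric(meta$lambda_max))
    bad <- which(is.na(lam))
    if (length(bad))
        stop("malformed lambda_max in metadata row(s): ",
             paste(bad, collapse = ", "))
    meta$lambda_max <- lam
    OpsinSet(meta, seqs, name = name, version = version)
}

#' Write an OpsinSet as FASTA + TSV
#'
#' Writers are bit-stable: identical input yields identical files, and
#' \code{loadOpsinSet(writeOpsinSet(ds))} reproduces \code{ds} field by
#' field (record order preserved).
#'
#' @param ds an \code{OpsinSet}.
#' @param dir output directory (created if needed).
#' @param stem file stem; files are \code{<stem>.fasta}, \code{<stem>.tsv}.
#' @return named character vector with paths \code{fasta} and \code{meta}.
#' @export
writeOpsinSet <- function(ds, dir, stem = "dataset") {
    stopifnot(is(ds, "OpsinSet"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fa <- file.path(dir, paste0(stem, ".fasta"))
    tsv <- file.path(dir, paste0(stem, ".tsv"))
    Biostrings::writeXStringSet(ds@seqs, fa, width = 80L)
    df <- as.data.frame(ds@meta)
    utils::write.table(df, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
    c(fasta = fa, meta = tsv)
}

#' Collapse records with identical sequences
#'
#' Records sharing an identical amino-acid sequence are collapsed to a
#' single record. If their \eqn{\lambda_{max}} values span at most
#' \code{tol_nm}, the retained value is their mean; a wider spread is a
#' curation conflict and raises an error listing the accessions involved
#' rather than silently averaging. The first record (input order) lends its
#' metadata; collapsed accessions are recorded in the \code{dedup_report}
#' attribute (a data.frame \code{kept}, \code{collapsed}, \code{lambda_kept}).
#'
#' Deduplication is idempotent: applying it twice equals applying it once.
#'
#' @param ds an \code{OpsinSet}.
#' @param tol_nm maximum tolerated lambda_max spread (nm) among identical
#'   sequences; default 3.
#' @return deduplicated \code{OpsinSet} with a \code{dedup_report} attribute.
#' @export
deduplicate <- function(ds, tol_nm = 3) {
    stopifnot(is(ds, "OpsinSet"), tol_nm >= 0)
    seqc <- as.character(ds@seqs)
    grp <- match(seqc, unique(seqc))
    keep <- !duplicated(grp)
    lam <- as.numeric(ds@meta$lambda_max)
    rep_rows <- list()
    new_lam <- lam[keep]
    for (g in unique(grp[duplicated(grp)])) {
        members <- which(grp == g)
        span <- diff(range(lam[members]))
        accs <- as.character(ds@meta$accession[members])
        if (span > tol_nm)
            stop("lambda_max conflict (spread ", format(span),
                 " nm > ", tol_nm, " nm) among identical sequences: ",
                 paste(accs, collapse = ", "))
        mval <- mean(lam[members])
        new_lam[which(which(keep) == members[1L])] <- mval
        rep_rows[[length(rep_rows) + 1L]] <- data.frame(
            kept = accs[1L], collapsed = paste(accs[-1L], collapse = ","),
            lambda_kept = mval, stringsAsFactors = FALSE)
    }
    out <- ds[which(keep)]
    out@meta$lambda_max <- new_lam
    validObject(out)
    report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
        data.frame(kept = character(), collapsed = character(),
                   lambda_kept = numeric(), stringsAsFactors = FALSE)
    attr(out, "dedup_report") <- report
    out
}

#' Filter a dataset by standard subset rules
#'
#' Implements the study's named subsets: \code{"vertebrate"} keeps
#' phylum Chordata, \code{"invertebrate"} its complement,
#' \code{"wild_type_only"} keeps \code{record_type == "wt"},
#' \code{"mutants_only"} keeps mutants and chimeras. A \code{gene_family}
#' set and an arbitrary \code{predicate} (function of the metadata
#' data.frame returning a logical mask) can be combined with any named
#' rule; all supplied filters are intersected, so calls compose.
#'
#' @param ds an \code{OpsinSet}.
#' @param rule optional character vector of named rules (any of
#'   \code{"vertebrate"}, \code{"invertebrate"}, \code{"wild_type_only"},
#'   \code{"mutants_only"}).
#' @param gene_family optional character set of gene families to keep.
#' @param predicate optional \code{function(meta) -> logical}.
#' @return the filtered \code{OpsinSet}; an empty result warns, it does not
#'   error.
#' @export
opsinSubset <- function(ds, rule = NULL, gene_family = NULL,
                        predicate = NULL) {
    stopifnot(is(ds, "OpsinSet"))
    m <- as.data.frame(ds@meta)
    keep <- rep(TRUE, nrow(m))
    for (r in rule) {
        keep <- keep & switch(match.arg(r, c("vertebrate", "invertebrate",
                                             "wild_type_only", "mutants_only")),
            vertebrate    = m$phylum == "Chordata",
            invertebrate  = m$phylum != "Chordata",
            wild_type_only = m$record_type == "wt",
            mutants_only  = m$record_type %in% c("mutant", "chimera"))
    }
    if (!is.null(gene_family)) keep <- keep & m$gene_family %in% gene_family
    if (!is.null(predicate))   keep <- keep & predicate(m)
    keep[is.na(keep)] <- FALSE
    if (!any(keep)) warning("subset rule selected no records")
    ds[which(keep)]
}
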