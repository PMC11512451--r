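#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings AAStringSet
NULL

AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' OpsinSet: a genotype-phenotype dataset
#'
#' An \code{OpsinSet} holds one record per characterized opsin: an ungapped
#' amino-acid sequence, its measured wavelength of peak absorbance
#' (\eqn{\lambda_{max}}, nm), and curation metadata (taxonomy, gene family,
#' record type, mutation notation, parent accession, literature source).
#' Sequences live in a \code{\link[Biostrings]{AAStringSet}} keyed by
#' accession; tabular metadata in a \code{\link[S4Vectors]{DataFrame}} in the
#' same order.
#'
#' Validity requires: unique accessions; non-empty, gap-free sequences over
#' the 20-letter alphabet; \code{lambda_max > 0}; mutant records carry both a
#' mutation notation and a parent accession; chimera records carry a parent
#' accession.
#'
#' @slot name dataset name.
#' @slot version dataset version string.
#' @slot meta \code{DataFrame} with columns \code{accession}, \code{species},
#'   \code{phylum}, \code{class_name}, \code{gene_family}, \code{lambda_max},
#'   \code{record_type} (\code{wt}, \code{mutant} or \code{chimera}),
#'   \code{mutation_notation}, \code{parent_accession}, \code{source_ref}.
#' @slot seqs \code{AAStringSet}, names equal to \code{meta$accession}.
#' @exportClass OpsinSet
setClass("OpsinSet",
    representation(name = "character", version = "character",
                   meta = "DataFrame", seqs = "AAStringSet"))

OPSIN_META_COLS <- c("accession", "species", "phylum", "class_name",
                     "gene_family", "lambda_max", "record_type",
                     "mutation_notation", "parent_accession", "source_ref")

setValidity("OpsinSet", function(object) {
    m <- object@meta
    msgs <- character()
    missing_cols <- setdiff(OPSIN_META_COLS, colnames(m))
    if (length(missing_cols))
        return(paste("missing metadata columns:",
                     paste(missing_cols, collapse = ", ")))
    if (nrow(m) != length(object@seqs))
        return("metadata rows and sequences differ in number")
    if (nrow(m) == 0L) return(TRUE)
    if (anyDuplicated(m$accession))
        msgs <- c(msgs, paste("duplicated accessions:",
            paste(unique(m$accession[duplicated(m$accession)]), collapse = ", ")))
    if (!identical(names(object@seqs), as.character(m$accession)))
        msgs <- c(msgs, "sequence names do not match metadata accessions")
    chars <- unique(unlist(strsplit(as.character(object@seqs), "")))
    bad <- setdiff(chars, AA_ALPHABET20)
    if (length(bad))
        msgs <- c(msgs, paste("sequences contain non-standard characters:",
                              paste(bad, collapse = " ")))
    if (any(Biostrings::width(object@seqs) == 0L))
        msgs <- c(msgs, "empty sequences present")
    if (any(!is.finite(m$lambda_max)) || any(m$lambda_max <= 0))
        msgs <- c(msgs, "lambda_max must be finite and > 0")
    if (!all(m$record_type %in% c("wt", "mutant", "chimera")))
        msgs <- c(msgs, "record_type must be one of wt, mutant, chimera")
    is_mut <- m$record_type == "mutant"
    if (any(is_mut & (is.na(m$mutation_notation) | m$mutation_notation == "")))
        msgs <- c(msgs, "mutant records require mutation_notation")
    if (any(is_mut & (is.na(m$parent_accession) | m$parent_accession == "")))
        msgs <- c(msgs, "mutant records require parent_accession")
    is_chi <- m$record_type == "chimera"
    if (any(is_chi & (is.na(m$parent_accession) | m$parent_accession == "")))
        msgs <- c(msgs, "chimera records require parent_accession")
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' MutationSpec: parsed point-mutation edits
#'
#' An ordered set of single-residue edits, each a (wild-type residue,
#' 1-based position, replacement residue) triple, as written in compact
#' notation such as \code{"D83N_A292S"}. The \code{frame} flag records
#' whether positions index the ungapped native parent sequence
#' (\code{"native"}) or the bovine-rhodopsin reference frame
#' (\code{"reference"}, resolved through a \code{PositionMap} before
#' application).
#'
#' @slot wt character vector of wild-type residues.
#' @slot pos integer vector of 1-based positions, strictly increasing.
#' @slot new character vector of replacement residues.
#' @slot frame \code{"native"} or \code{"reference"}.
#' @exportClass MutationSpec
setClass("MutationSpec",
    representation(wt = "character", pos = "integer", new = "character",
                   frame = "character"),
    prototype(frame = "native"))

setValidity("MutationSpec", function(object) {
    n <- length(object@pos)
    if (length(object@wt) != n || length(object@new) != n)
        return("wt, pos and new must have equal length")
    if (!object@frame %in% c("native", "reference"))
        return("frame must be 'native' or 'reference'")
    if (n == 0L) return(TRUE)
    if (any(!object@wt %in% AA_ALPHABET20) || any(!object@new %in% AA_ALPHABET20))
        return("residues must be in the 20-letter amino-acid alphabet")
    if (any(object@pos < 1L)) return("positions must be >= 1")
    if (anyDuplicated(object@pos))
        return("multiple edits at the same position are ambiguous")
    if (is.unsorted(object@pos, strictly = TRUE))
        return("positions must be strictly increasing")
    if (any(object@wt == object@new))
        return("wild-type and replacement residue must differ")
    TRUE
})

#' ChimeraSpec: transmembrane-domain swap instructions
#'
#' Describes a chimeric opsin in which the listed transmembrane domains
#' (TMD1..TMD7) of a parent are replaced by the corresponding domains of a
#' donor. Domain boundaries are given as closed 1-based intervals in
#' reference (bovine rhodopsin) coordinates and are translated to alignment
#' columns through a \code{PositionMap}.
#'
#' @slot parent parent accession.
#' @slot donor donor accession.
#' @slot domains integer vector of TMD indices in 1..7, non-empty.
#' @slot boundaries data.frame with columns \code{tmd}, \code{start},
#'   \code{end} (reference coordinates, non-overlapping, ordered).
#' @exportClass ChimeraSpec
setClass("ChimeraSpec",
    representation(parent = "character", donor = "character",
                   domains = "integer", boundaries = "data.frame"))

setValidity("ChimeraSpec", function(object) {
    b <- object@boundaries
    if (!all(c("tmd", "start", "end") %in% colnames(b)))
        return("boundaries needs columns tmd, start, end")
    if (length(object@domains) == 0L) return("domains must be non-empty")
    if (any(!object@domains %in% seq_len(7L)))
        return("domains must be TMD indices in 1..7")
    if (any(!object@domains %in% b$tmd))
        return("every selected domain needs a boundary row")
    b <- b[order(b$start), ]
    if (any(b$end < b$start)) return("boundary end before start")
    if (nrow(b) > 1L && any(b$start[-1L] <= b$end[-nrow(b)]))
        return("boundaries overlap")
    TRUE
})

#' PositionMap: alignment column to reference coordinates
#'
#' Maps every column of an alignment to bovine-rhodopsin-style reference
#' coordinates: columns where the reference row is ungapped receive
#' consecutive reference positions \code{1..L}; columns where the reference
#' carries a gap receive insertion codes \code{"<prevPos>+k"}. Each column
#' also carries a transmembrane-domain label (\code{TMD1}..\code{TMD7}) or
#' \code{"loop"}.
#'
#' @slot reference accession of the reference row.
#' @slot map data.frame with columns \code{column} (alignment column),
#'   \code{ref_pos} (character position or insertion code), \code{ref_index}
#'   (integer position of the preceding ungapped reference residue, 0 before
#'   the first), \code{is_insertion}, \code{tmd}.
#' @exportClass PositionMap
setClass("PositionMap",
    representation(reference = "character", map = "data.frame"))

setValidity("PositionMap", function(object) {
    m <- object@map
    need <- c("column", "ref_pos", "ref_index", "is_insertion", "tmd")
    if (!all(need %in% colnames(m)))
        return(paste("map needs columns", paste(need, collapse = ", ")))
    ref <- m$ref_index[!m$is_insertion]
    if (length(ref) > 1L && is.unsorted(ref, strictly = TRUE))
        return("reference positions must be strictly increasing over non-gap columns")
    TRUE
})

#' EncodedAlignment: one-hot feature matrix with its vocabulary
#'
#' The numeric representation consumed by the regressors: one indicator
#' feature per (alignment column, residue) pair observed in training, labels
#' of the form \code{"p<column>:<residue>"}. Gaps and residues outside the
#' training vocabulary encode as all-zero within the column block (the
#' unseen-residue rule), so within one sample and one column at most one
#' indicator is 1.
#'
#' @slot x numeric 0/1 matrix, rows = samples, columns = features.
#' @slot features data.frame with columns \code{label}, \code{column}
#'   (original alignment column index), \code{residue}.
#' @slot vocabulary named list: per retained column (name =
#'   \code{as.character(column)}), the residue set seen in training.
#' @exportClass EncodedAlignment
setClass("EncodedAlignment",
    representation(x = "matrix", features = "data.frame",
                   vocabulary = "list"))

setValidity("EncodedAlignment", function(object) {
    if (ncol(object@x) != nrow(object@features))
        return("feature table and matrix disagree on feature count")
    if (nrow(object@features) &&
        !identical(colnames(object@x), object@features$label))
        return("matrix column names must equal feature labels")
    if (length(object@x) && !all(object@x %in% c(0, 1)))
        return("encoded matrix must be binary")
    TRUE
})

#' TruthModel: ground-truth phenotype function for synthetic studies
#'
#' Defines a deterministic-plus-stochastic map from genotype to
#' \eqn{\lambda_{max}}: a baseline, additive per-(site, residue) effects,
#' pairwise interaction terms that fire when both residues are present, a
#' Brownian-motion phylogenetic component, and Gaussian measurement noise.
#' Phenotypes are clamped to the empirical opsin range (350-611 nm by
#' default); default effect scales are chosen so the clamp never engages.
#'
#' @slot lambda0 baseline wavelength (nm), default 500.
#' @slot site_effects data.frame \code{site}, \code{residue}, \code{delta}
#'   (nm shift when \code{residue} occupies \code{site}).
#' @slot interactions data.frame \code{site1}, \code{res1}, \code{site2},
#'   \code{res2}, \code{gamma} (extra nm shift when both are present).
#' @slot sigma_phylo2 Brownian-motion rate (nm^2 per unit branch length).
#' @slot sigma_e residual measurement noise standard deviation (nm).
#' @slot lambda_range length-2 clamp interval (nm).
#' @exportClass TruthModel
setClass("TruthModel",
    representation(lambda0 = "numeric", site_effects = "data.frame",
                   interactions = "data.frame", sigma_phylo2 = "numeric",
                   sigma_e = "numeric", lambda_range = "numeric"))

setValidity("TruthModel", function(object) {
    if (!all(c("site", "residue", "delta") %in% colnames(object@site_effects)))
        return("site_effects needs columns site, residue, delta")
    if (!all(c("site1", "res1", "site2", "res2", "gamma") %in%
             colnames(object@interactions)))
        return("interactions needs columns site1, res1, site2, res2, gamma")
    if (object@sigma_phylo2 < 0 || object@sigma_e < 0)
        return("variance components must be >= 0")
    if (length(object@lambda_range) != 2L ||
        diff(object@lambda_range) <= 0)
        return("lambda_range must be an increasing length-2 interval")
    TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "OpsinSet", function(object) {
    m <- object@meta
    cat("OpsinSet '", object@name, "' (version ", object@version, ")\n",
        sep = "")
    cat("  ", nrow(m), " records: ",
        sum(m$record_type == "wt"), " wt, ",
        sum(m$record_type == "mutant"), " mutant, ",
        sum(m$record_type == "chimera"), " chimera\n", sep = "")
    if (nrow(m))
        cat("  lambda_max range: ", min(m$lambda_max), "-",
            max(m$lambda_max), " nm\n", sep = "")
})

setMethod("show", "MutationSpec", function(object) {
    cat("MutationSpec (", object@frame, " frame): ",
        notation(object), "\n", sep = "")
})

setMethod("show", "PositionMap", function(object) {
    cat("PositionMap vs reference '", object@reference, "': ",
        nrow(object@map), " columns (",
        sum(object@map$is_insertion), " insertions)\n", sep = "")
})

setMethod("show", "EncodedAlignment", function(object) {
    cat("EncodedAlignment: ", nrow(object@x), " samples x ",
        ncol(object@x), " features over ", length(object@vocabulary),
        " alignment columns\n", sep = "")
})

setMethod("show", "TruthModel", function(object) {
    cat("TruthModel: baseline ", object@lambda0, " nm, ",
        nrow(object@site_effects), " site effects, ",
        nrow(object@interactions), " interactions, sigma_phylo2 = ",
        object@sigma_phylo2, ", sigma_e = ", object@sigma_e, " nm\n",
        sep = "")
})

## ---- accessors ----------------------------------------------------------

#' Accessors for OpsinSet
#'
#' @param x an \code{OpsinSet}.
#' @return \code{accessions}: character vector of record ids;
#'   \code{lambdaMax}: named numeric vector of phenotypes (nm);
#'   \code{recordType}: named character vector; \code{aaSequences}: the
#'   \code{AAStringSet}; \code{opsinMeta}: the metadata \code{DataFrame};
#'   \code{datasetName}/\code{datasetVersion}: strings.
#' @name OpsinSet-accessors
#' @aliases accessions lambdaMax recordType aaSequences opsinMeta
#'   datasetName datasetVersion
NULL

#' @rdname OpsinSet-accessors
#' @export
setGeneric("accessions", function(x) standardGeneric("accessions"))
#' @rdname OpsinSet-accessors
#' @export
setMethod("accessions", "OpsinSet", function(x) as.character(x@meta$accession))

#' @rdname OpsinSet-accessors
#' @export
setGeneric("lambdaMax", function(x) standardGeneric("lambdaMax"))
#' @rdname OpsinSet-accessors
#' @export
setMethod("lambdaMax", "OpsinSet", function(x)
    stats::setNames(as.numeric(x@meta$lambda_max), x@meta$accession))

#' @rdname OpsinSet-accessors
#' @export
setGeneric("recordType", function(x) standardGeneric("recordType"))
#' @rdname OpsinSet-accessors
#' @export
setMethod("recordType", "OpsinSet", function(x)
    stats::setNames(as.character(x@meta$record_type), x@meta$accession))

#' @rdname OpsinSet-accessors
#' @export
setGeneric("aaSequences", function(x) standardGeneric("aaSequences"))
#' @rdname OpsinSet-accessors
#' @export
setMethod("aaSequences", "OpsinSet", function(x) x@seqs)

#' @rdname OpsinSet-accessors
#' @export
setGeneric("opsinMeta", function(x) standardGeneric("opsinMeta"))
#' @rdname OpsinSet-accessors
#' @export
setMethod("opsinMeta", "OpsinSet", function(x) x@meta)

#' @rdname OpsinSet-accessors
#' @export
setGeneric("datasetName", function(x) standardGeneric("datasetName"))
#' @rdname OpsinSet-accessors
#' @export
setMethod("datasetName", "OpsinSet", function(x) x@name)

#' @rdname OpsinSet-accessors
#' @export
setGeneric("datasetVersion", function(x) standardGeneric("datasetVersion"))
#' @rdname OpsinSet-accessors
#' @export
setMethod("datasetVersion", "OpsinSet", function(x) x@version)

#' Number of records in an OpsinSet
#' @param x an \code{OpsinSet}.
#' @export
setMethod("length", "OpsinSet", function(x) nrow(x@meta))

#' Subset an OpsinSet by index, accession or logical mask
#' @param x an \code{OpsinSet}.
#' @param i integer, character (accessions) or logical index.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "OpsinSet", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) {
        idx <- match(i, x@meta$accession)
        if (anyNA(idx))
            stop("unknown accessions: ", paste(i[is.na(idx)], collapse = ", "))
        i <- idx
    }
    initialize(x, meta = x@meta[i, , drop = FALSE], seqs = x@seqs[i])
})

#' Feature matrix and table of an EncodedAlignment
#'
#' @param x an \code{EncodedAlignment}.
#' @return \code{featureMatrix}: the numeric 0/1 matrix;
#'   \code{featureTable}: data.frame of feature label, alignment column and
#'   residue; \code{vocabulary}: per-column residue sets.
#' @name EncodedAlignment-accessors
#' @aliases featureMatrix featureTable vocabulary
NULL

#' @rdname EncodedAlignment-accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname EncodedAlignment-accessors
#' @export
setMethod("featureMatrix", "EncodedAlignment", function(x) x@x)

#' @rdname EncodedAlignment-accessors
#' @export
setGeneric("featureTable", function(x) standardGeneric("featureTable"))
#' @rdname EncodedAlignment-accessors
#' @export
setMethod("featureTable", "EncodedAlignment", function(x) x@features)

#' @rdname EncodedAlignment-accessors
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))
#' @rdname EncodedAlignment-accessors
#' @export
setMethod("vocabulary", "EncodedAlignment", function(x) x@vocabulary)

#' Position table of a PositionMap
#' @param x a \code{PositionMap}.
#' @return data.frame with one row per alignment column.
#' @export
setGeneric("positionTable", function(x) standardGeneric("positionTable"))
#' @rdname positionTable
#' @export
setMethod("positionTable", "PositionMap", function(x) x@map)
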