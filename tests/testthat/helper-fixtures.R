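# Fixture builders shared across tests. Everything is generated in code;
# no data files.

toy_meta <- function(n = 3, phylum = rep("Chordata", n),
                     type = rep("wt", n), lambda = seq(500, by = 10,
                                                       length.out = n)) {
    data.frame(accession = paste0("acc", seq_len(n)),
               species = paste0("sp", seq_len(n)),
               phylum = phylum, class_name = "X", gene_family = "Rh1",
               lambda_max = lambda, record_type = type,
               mutation_notation = NA_character_,
               parent_accession = NA_character_,
               source_ref = "doi:toy", stringsAsFactors = FALSE)
}

toy_seqs <- function(n = 3, L = 12, seed = 1) {
    set.seed(seed)
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    setNames(vapply(seq_len(n), function(i)
        paste(sample(aa, L, replace = TRUE), collapse = ""),
        character(1)), paste0("acc", seq_len(n)))
}

toy_opsinset <- function(n = 3, ...) {
    OpsinSet(toy_meta(n, ...), toy_seqs(n))
}

aln <- function(...) {
    rows <- c(...)
    if (is.null(names(rows))) names(rows) <- paste0("s", seq_along(rows))
    Biostrings::AAStringSet(rows)
}

# Independent brute-force Wilcoxon signed-rank oracle: enumerate every
# sign pattern of the observed |d| mid-ranks directly.
brute_wilcoxon_p <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Ws <- as.numeric(signs %*% r)
    mu <- sum(r) / 2
    mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
}

# An epistasis-ready dataset: wild type + singles + double, bovine-style.
epi_toy_dataset <- function(double_lambda = 514) {
    wt <- "MDAFGHKLAATV"
    s1 <- applyMutations(wt, parseMutations("D2N"))
    s2 <- applyMutations(wt, parseMutations("A9S"))
    dd <- applyMutations(wt, parseMutations("D2N_A9S"))
    meta <- data.frame(
        accession = c("WT", "M1", "M2", "M12"),
        species = "Bos", phylum = "Chordata", class_name = "Mammalia",
        gene_family = "Rh1",
        lambda_max = c(500, 514, 502, double_lambda),
        record_type = c("wt", "mutant", "mutant", "mutant"),
        mutation_notation = c(NA, "D2N", "A9S", "D2N_A9S"),
        parent_accession = c(NA, "WT", "WT", "WT"),
        source_ref = "toy", stringsAsFactors = FALSE)
    OpsinSet(meta, setNames(c(wt, s1, s2, dd), meta$accession))
}
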