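## Synthetic study generator: a Yule tree, sequences evolved along it,
## phenotypes from an explicit ground-truth model (additive tuning-site
## effects, pairwise interactions, Brownian background, measurement
## noise), and notation-labelled mutants spawned from the tips. Every
## stage is seeded and reproducible; the generator supplies ground truth
## for all downstream tests.

#' Construct a TruthModel
#'
#' @param lambda0 baseline wavelength (nm), default 500.
#' @param site_effects data.frame \code{site}, \code{residue},
#'   \code{delta} (nm); empty by default.
#' @param interactions data.frame \code{site1}, \code{res1}, \code{site2},
#'   \code{res2}, \code{gamma} (nm); empty by default.
#' @param sigma_phylo2 Brownian rate (nm^2/unit branch), default 0.
#' @param sigma_e residual noise SD (nm), default 0.
#' @param lambda_range clamp interval, default the empirical opsin range
#'   \code{c(350, 611)} nm.
#' @return a \code{\link{TruthModel}}.
#' @export
truthModel <- function(lambda0 = 500,
                       site_effects = data.frame(site = integer(),
                                                 residue = character(),
                                                 delta = numeric()),
                       interactions = data.frame(site1 = integer(),
                                                 res1 = character(),
                                                 site2 = integer(),
                                                 res2 = character(),
                                                 gamma = numeric()),
                       sigma_phylo2 = 0, sigma_e = 0,
                       lambda_range = c(350, 611)) {
    new("TruthModel", lambda0 = lambda0, site_effects = site_effects,
        interactions = interactions, sigma_phylo2 = sigma_phylo2,
        sigma_e = sigma_e, lambda_range = lambda_range)
}

#' Simulate a Yule tree
#'
#' Pure-birth tree with \code{n_tips} tips, rescaled to unit height, tip
#' labels \code{t1..tn}. Deterministic given the seed.
#'
#' @param n_tips number of tips, at least 2.
#' @param seed integer seed.
#' @return rooted \code{phylo} of height 1.
#' @export
simulateTree <- function(n_tips, seed = 1L) {
    if (n_tips < 2L) stop("n_tips must be >= 2")
    set.seed(seed)
    tree <- ape::rphylo(n_tips, birth = 1, death = 0)
    tree$tip.label <- paste0("t", seq_len(n_tips))
    depths <- ape::node.depth.edgelength(tree)
    tree$edge.length <- tree$edge.length / max(depths[seq_len(n_tips)])
    tree
}

#' Evolve amino-acid sequences along a tree
#'
#' A uniform (Jukes-Cantor-style) substitution process over the 20-letter
#' alphabet: the root sequence is uniform random; along each branch of
#' length \eqn{t}, each site substitutes with probability
#' \eqn{1 - e^{-rate \cdot t}}, drawing the new residue uniformly from the
#' other 19. No indels, so the rows form an exact alignment.
#'
#' @param tree \code{phylo}.
#' @param L sequence length (sites), at least 1.
#' @param rate substitutions per site per unit branch length.
#' @param seed integer seed.
#' @param site_rates optional length-\code{L} vector of per-site rate
#'   multipliers (default 1 everywhere); lets designated fast-evolving
#'   sites — like opsin spectral tuning sites, which substitute
#'   convergently across clades — accumulate more independent events.
#' @return \code{AAStringSet} of the tip sequences, names = tip labels.
#' @export
evolveSequences <- function(tree, L, rate, seed = 1L, site_rates = NULL) {
    stopifnot(L >= 1L, rate >= 0)
    if (is.null(site_rates)) site_rates <- rep(1, L)
    stopifnot(length(site_rates) == L, all(site_rates >= 0))
    set.seed(seed)
    n <- length(tree$tip.label)
    nnode <- n + tree$Nnode
    seqs <- vector("list", nnode)
    root <- n + 1L
    seqs[[root]] <- sample(AA_ALPHABET20, L, replace = TRUE)
    ## preorder: parent before child
    edges <- rev(ape::postorder(tree))
    for (e in edges) {
        par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
        s <- seqs[[par]]
        p_sub <- 1 - exp(-rate * site_rates * tree$edge.length[e])
        hit <- which(stats::runif(L) < p_sub)
        for (j in hit) {
            s[j] <- sample(setdiff(AA_ALPHABET20, s[j]), 1L)
        }
        seqs[[child]] <- s
    }
    out <- Biostrings::AAStringSet(vapply(seqs[seq_len(n)], paste,
                                          character(1), collapse = ""))
    names(out) <- tree$tip.label
    out
}

## deterministic part of the truth model for one ungapped sequence
truth_deterministic <- function(seq, truth) {
    chars <- strsplit(seq, "")[[1]]
    val <- truth@lambda0
    se <- truth@site_effects
    if (nrow(se)) {
        hit <- chars[se$site] == se$residue
        val <- val + sum(se$delta[hit])
    }
    ia <- truth@interactions
    if (nrow(ia)) {
        hit <- chars[ia$site1] == ia$res1 & chars[ia$site2] == ia$res2
        val <- val + sum(ia$gamma[hit])
    }
    val
}

#' Assign phenotypes to tips under a TruthModel
#'
#' \eqn{\lambda(tip) = clamp(\lambda_0 + \sum \delta + \sum \gamma +
#' BM(tree, \sigma^2_{phylo}) + N(0, \sigma_e^2))}: additive effects fire
#' when the tip carries the listed residue at the site, interactions when
#' both residues are present; the Brownian component is drawn jointly over
#' tips from the tree covariance; measurement noise is iid.
#'
#' @param al tip alignment (\code{AAStringSet}, ungapped rows).
#' @param tree \code{phylo} with the same tip labels.
#' @param truth a \code{TruthModel}.
#' @param seed integer seed.
#' @return named numeric vector of tip phenotypes (nm), plus attributes
#'   \code{bm} and \code{noise} holding the drawn components.
#' @export
assignPhenotypes <- function(al, tree, truth, seed = 1L) {
    stopifnot(is(truth, "TruthModel"))
    tips <- names(al)
    det <- vapply(as.character(al), truth_deterministic, numeric(1),
                  truth = truth)
    set.seed(seed)
    bm <- stats::setNames(rep(0, length(tips)), tips)
    if (truth@sigma_phylo2 > 0) {
        C <- bmVcv(tree)[tips, tips] * truth@sigma_phylo2
        z <- stats::rnorm(length(tips))
        ## chol of PSD matrix with tiny jitter for zero-length cherries
        U <- chol(C + diag(1e-10 * max(diag(C)), nrow(C)))
        bm <- stats::setNames(as.numeric(t(U) %*% z), tips)
    }
    noise <- stats::rnorm(length(tips), 0, truth@sigma_e)
    lam <- det + bm + noise
    clamped <- pmin(pmax(lam, truth@lambda_range[1L]), truth@lambda_range[2L])
    out <- stats::setNames(clamped, tips)
    attr(out, "bm") <- bm
    attr(out, "noise") <- stats::setNames(noise, tips)
    attr(out, "clamped") <- any(clamped != lam)
    out
}

#' Spawn notation-labelled mutants from a wild-type record
#'
#' Each mutant carries 1..\code{max_edits} random edits, biased toward the
#' truth model's tuning and interaction sites with probability
#' \code{site_bias} per edit. The mutant phenotype is computed noiselessly
#' from the truth model on the mutant sequence, keeping the parent's
#' phylogenetic and residual background (laboratory mutagenesis does not
#' re-draw evolutionary history): \eqn{\lambda_{mut} = \lambda_{parent} +
#' [f(seq_{mut}) - f(seq_{parent})]} with \eqn{f} the deterministic truth
#' part.
#'
#' @param wt_seq ungapped parent sequence.
#' @param wt_accession parent accession.
#' @param wt_lambda parent phenotype (nm).
#' @param truth \code{TruthModel}.
#' @param n number of mutants.
#' @param max_edits maximum edits per mutant (1..4).
#' @param seed integer seed.
#' @param site_bias probability that an edit targets a truth site
#'   (default 0.8).
#' @param pair_bias probability that a multi-edit mutant deliberately
#'   targets both sites of one interacting pair with the interacting
#'   residues (default 0.5) — mirroring how mutagenesis studies construct
#'   double mutants at suspected interacting tuning sites.
#' @param with_singles also emit the single-edit components of every
#'   multimutant (default TRUE), as mutagenesis studies characterize each
#'   single; makes multimutants decomposable for epistasis analysis.
#' @return data.frame \code{accession}, \code{aa_seq}, \code{lambda_max},
#'   \code{mutation_notation}, \code{parent_accession}.
#' @export
spawnMutants <- function(wt_seq, wt_accession, wt_lambda, truth, n,
                         max_edits = 2L, seed = 1L, site_bias = 0.8,
                         pair_bias = 0.5, with_singles = TRUE) {
    stopifnot(n >= 1L, max_edits >= 1L, max_edits <= 4L)
    set.seed(seed)
    L <- nchar(wt_seq)
    truth_sites <- unique(c(truth@site_effects$site,
                            truth@interactions$site1,
                            truth@interactions$site2))
    wt_det <- truth_deterministic(wt_seq, truth)
    background <- wt_lambda - wt_det
    rows <- list()
    for (i in seq_len(n)) {
        k <- sample.int(max_edits, 1L)
        chars <- strsplit(wt_seq, "")[[1]]
        sites <- integer(0)
        if (k >= 2L && nrow(truth@interactions) &&
            stats::runif(1) < pair_bias) {
            ## targeted double at one interacting pair
            ia <- truth@interactions[sample.int(nrow(truth@interactions), 1L), ]
            if (chars[ia$site1] != ia$res1 && chars[ia$site2] != ia$res2) {
                chars[ia$site1] <- ia$res1
                chars[ia$site2] <- ia$res2
                sites <- c(ia$site1, ia$site2)
            }
        }
        while (length(sites) < k) {
            s <- if (length(truth_sites) && stats::runif(1) < site_bias)
                sample(truth_sites, 1L) else sample.int(L, 1L)
            if (!s %in% sites) sites <- c(sites, s)
        }
        wt_chars <- strsplit(wt_seq, "")[[1]]
        for (s in sites) {
            if (chars[s] != wt_chars[s]) next  # already set by pair targeting
            eff_res <- unique(c(
                truth@site_effects$residue[truth@site_effects$site == s],
                truth@interactions$res1[truth@interactions$site1 == s],
                truth@interactions$res2[truth@interactions$site2 == s]))
            eff_res <- setdiff(eff_res, chars[s])
            chars[s] <- if (length(eff_res) && stats::runif(1) < site_bias)
                sample(eff_res, 1L)[[1]] else
                sample(setdiff(AA_ALPHABET20, chars[s]), 1L)
        }
        mut_seq <- paste(chars, collapse = "")
        if (mut_seq == wt_seq) next
        lam <- truth_deterministic(mut_seq, truth) + background
        notat <- diffToNotation(wt_seq, mut_seq)
        rows[[length(rows) + 1L]] <- data.frame(
            accession = paste0(wt_accession, "_m", i),
            aa_seq = mut_seq,
            lambda_max = lam,
            mutation_notation = notat,
            parent_accession = wt_accession, stringsAsFactors = FALSE)
        sp <- parseMutations(notat)
        if (with_singles && length(sp@pos) >= 2L) {
            for (e in seq_along(sp@pos)) {
                single <- new("MutationSpec", wt = sp@wt[e], pos = sp@pos[e],
                              new = sp@new[e], frame = "native")
                s_seq <- applyMutations(wt_seq, single)
                rows[[length(rows) + 1L]] <- data.frame(
                    accession = paste0(wt_accession, "_m", i, "s", e),
                    aa_seq = s_seq,
                    lambda_max = truth_deterministic(s_seq, truth) + background,
                    mutation_notation = notation(single),
                    parent_accession = wt_accession,
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(rows))
        return(data.frame(accession = character(), aa_seq = character(),
                          lambda_max = numeric(),
                          mutation_notation = character(),
                          parent_accession = character(),
                          stringsAsFactors = FALSE))
    do.call(rbind, rows)
}

#' Draw a random TruthModel matched to an alignment
#'
#' Tuning sites are chosen among columns whose minor-residue frequency is
#' at least \code{min_minor_freq} (so planted effects are identifiable);
#' at each chosen site every non-consensus residue carried by at least
#' \code{min_effect_freq} of the tips receives one shift drawn uniformly
#' from \code{delta_range} with random sign — residues too rare to learn
#' from carry no effect, like the consensus. Interactions pair
#' distinct tuning sites on residue combinations that co-occur in at least
#' \code{min_cooccur} tips, with magnitudes from \code{gamma_range}.
#'
#' @param al tip alignment.
#' @param n_sites number of tuning sites (default 5).
#' @param n_interactions number of interacting pairs (default 2).
#' @param delta_range absolute additive-effect range in nm (default
#'   \code{c(5, 25)}).
#' @param gamma_range absolute interaction range in nm (default
#'   \code{c(5, 20)}).
#' @param sigma_phylo2,sigma_e variance components (defaults 0 and 3 nm).
#' @param min_minor_freq minimum minor-residue frequency for a tuning site
#'   (default 0.2).
#' @param min_effect_freq minimum frequency for a residue to carry an
#'   effect (default 0.1).
#' @param min_cooccur minimum tips carrying both interacting residues
#'   (default 5).
#' @param sites optional fixed site indices to use as tuning sites
#'   (e.g. the fast-evolving sites designated at sequence evolution);
#'   default: sampled among eligible columns.
#' @param seed integer seed.
#' @return a \code{TruthModel}.
#' @export
randomTruthModel <- function(al, n_sites = 5L, n_interactions = 2L,
                             delta_range = c(5, 25), gamma_range = c(5, 20),
                             sigma_phylo2 = 0, sigma_e = 3,
                             min_minor_freq = 0.2, min_effect_freq = 0.1,
                             min_cooccur = 5L, sites = NULL, seed = 1L) {
    set.seed(seed)
    mat <- alignmentMatrix(al)
    n <- nrow(mat)
    minor_freq <- apply(mat, 2L, function(v) {
        tab <- table(v)
        if (length(tab) < 2L) 0 else 1 - max(tab) / length(v)
    })
    if (is.null(sites)) {
        eligible <- which(minor_freq >= min_minor_freq)
        if (length(eligible) < n_sites)
            stop("only ", length(eligible), " columns have minor-residue ",
                 "frequency >= ", min_minor_freq, "; need ", n_sites,
                 " (evolve with a higher rate or longer sequences)")
        sites <- sort(sample(eligible, n_sites))
    } else {
        ## candidate list may be larger than n_sites: keep the most
        ## variable eligible candidates
        cand <- sites[minor_freq[sites] >= min_minor_freq]
        if (length(cand) < n_sites)
            stop("only ", length(cand), " of the designated sites are ",
                 "variable enough (minor-residue frequency >= ",
                 min_minor_freq, ")")
        sites <- sort(cand[order(-minor_freq[cand])][seq_len(n_sites)])
    }
    se_rows <- list()
    for (s in sites) {
        tab <- table(mat[, s])
        consensus <- names(tab)[which.max(tab)]
        minor <- setdiff(names(tab), consensus)
        eff_res <- minor[tab[minor] / n >= min_effect_freq]
        if (!length(eff_res))
            eff_res <- minor[which.max(tab[minor])]
        for (res in eff_res) {
            delta <- sample(c(-1, 1), 1L) *
                stats::runif(1, delta_range[1L], delta_range[2L])
            se_rows[[length(se_rows) + 1L]] <- data.frame(
                site = s, residue = res, delta = delta,
                stringsAsFactors = FALSE)
        }
    }
    site_effects <- do.call(rbind, se_rows)
    ia_rows <- list()
    if (n_interactions > 0L && n_sites >= 2L) {
        ## enumerate minor-residue combos for every site pair with their
        ## co-occurrence support; prefer combos meeting min_cooccur, fall
        ## back to the best-supported remaining pairs
        combos <- list()
        pairs <- utils::combn(sites, 2L)
        for (pi in seq_len(ncol(pairs))) {
            s1 <- pairs[1L, pi]; s2 <- pairs[2L, pi]
            t1 <- table(mat[, s1]); t2 <- table(mat[, s2])
            for (r1 in setdiff(names(t1), names(t1)[which.max(t1)]))
                for (r2 in setdiff(names(t2), names(t2)[which.max(t2)])) {
                    cnt <- sum(mat[, s1] == r1 & mat[, s2] == r2)
                    if (cnt >= 2L)
                        combos[[length(combos) + 1L]] <- data.frame(
                            site1 = s1, res1 = r1, site2 = s2, res2 = r2,
                            support = cnt, stringsAsFactors = FALSE)
                }
        }
        if (length(combos)) {
            ct <- do.call(rbind, combos)
            good <- ct[ct$support >= min_cooccur, , drop = FALSE]
            good <- good[sample.int(nrow(good)), , drop = FALSE]
            rest <- ct[ct$support < min_cooccur, , drop = FALSE]
            rest <- rest[order(-rest$support), , drop = FALSE]
            ct <- rbind(good, rest)
            used <- character(0)
            for (ri in seq_len(nrow(ct))) {
                if (length(ia_rows) >= n_interactions) break
                key <- paste(ct$site1[ri], ct$site2[ri])
                if (key %in% used) next
                used <- c(used, key)
                gamma <- sample(c(-1, 1), 1L) *
                    stats::runif(1, gamma_range[1L], gamma_range[2L])
                ia_rows[[length(ia_rows) + 1L]] <- data.frame(
                    site1 = ct$site1[ri], res1 = ct$res1[ri],
                    site2 = ct$site2[ri], res2 = ct$res2[ri],
                    gamma = gamma, stringsAsFactors = FALSE)
            }
        }
    }
    interactions <- if (length(ia_rows)) do.call(rbind, ia_rows) else
        data.frame(site1 = integer(), res1 = character(),
                   site2 = integer(), res2 = character(),
                   gamma = numeric(), stringsAsFactors = FALSE)
    truthModel(site_effects = site_effects, interactions = interactions,
               sigma_phylo2 = sigma_phylo2, sigma_e = sigma_e)
}

#' Generate a complete synthetic study
#'
#' Orchestrates tree simulation, sequence evolution, truth-model draw,
#' phenotype assignment and mutant spawning into one reproducible bundle.
#' Defaults emulate the statistical structure of a curated opsin
#' genotype-phenotype set: 200 related wild types, 300-residue sequences,
#' 5 tuning sites with shifts of 5-25 nm, 2 interacting pairs of 5-20 nm,
#' and 3 nm measurement noise, with phenotypes clamped to 350-611 nm
#' (the clamp must not engage under these scales; the generator stops if
#' it does).
#'
#' @param n_tips wild-type tips (default 200).
#' @param L sequence length (default 300).
#' @param rate background substitution rate (default 0.1 per site per unit
#'   height, giving a handful of residue states per variable column as in
#'   curated opsin alignments).
#' @param tuning_rate_mult rate multiplier for the designated tuning sites
#'   (default 15): spectral tuning sites substitute convergently across
#'   clades, which also makes their effects statistically identifiable
#'   rather than confounded with clade-marker columns.
#' @param n_sites,n_interactions,delta_range,gamma_range,sigma_phylo2,sigma_e
#'   forwarded to \code{\link{randomTruthModel}}.
#' @param min_cooccur minimum number of wild-type tips carrying both
#'   residues of an interacting pair (default 15 of the 200 tips), so
#'   interactions remain visible in wild-type data after epistatic mutants
#'   are removed.
#' @param n_mutants total mutants spawned, spread over random wild-type
#'   parents (default 60).
#' @param max_edits maximum edits per mutant (default 2).
#' @param mutant_site_bias probability an edit targets a truth site
#'   (default 0.8).
#' @param seed integer master seed; every stage derives its own stream.
#' @param dir optional directory: writes \code{study.fasta} (ungapped
#'   sequences), \code{study_aln.fasta} (the exact alignment),
#'   \code{study.tsv}, \code{study.nwk} and \code{truth.json}.
#' @return list (class \code{SyntheticStudy}): \code{dataset}
#'   (\code{OpsinSet}), \code{alignment} (\code{AAStringSet} incl. mutant
#'   rows; indel-free so rows align trivially), \code{tree}, \code{truth},
#'   \code{phenotypes}, \code{seed}, and \code{paths} when \code{dir}
#'   is given.
#' @export
generateStudy <- function(n_tips = 200L, L = 300L, rate = 0.1,
                          tuning_rate_mult = 15,
                          n_sites = 5L, n_interactions = 2L,
                          delta_range = c(5, 25), gamma_range = c(5, 20),
                          sigma_phylo2 = 0, sigma_e = 3, min_cooccur = 15L,
                          n_mutants = 60L, max_edits = 2L,
                          mutant_site_bias = 0.8,
                          seed = 1L, dir = NULL) {
    tree <- simulateTree(n_tips, seed = seed)
    set.seed(seed + 10L)
    ## designate more fast-evolving candidates than needed; the truth
    ## model keeps the most variable n_sites of them
    tuning_sites <- sort(sample.int(L, min(L, 3L * n_sites)))
    site_rates <- rep(1, L)
    site_rates[tuning_sites] <- tuning_rate_mult
    al <- evolveSequences(tree, L, rate, seed = seed + 1L,
                          site_rates = site_rates)
    truth <- randomTruthModel(al, n_sites = n_sites,
                              n_interactions = n_interactions,
                              delta_range = delta_range,
                              gamma_range = gamma_range,
                              sigma_phylo2 = sigma_phylo2,
                              sigma_e = sigma_e, min_cooccur = min_cooccur,
                              sites = tuning_sites, seed = seed + 2L)
    lam <- assignPhenotypes(al, tree, truth, seed = seed + 3L)
    if (isTRUE(attr(lam, "clamped")))
        stop("phenotype clamp engaged; effect scales too large for the range")
    meta <- data.frame(accession = names(al),
                       species = paste0("sp_", names(al)),
                       phylum = rep(c("Chordata", "Mollusca"),
                                    length.out = length(al)),
                       class_name = "synthetic",
                       gene_family = "Rh1",
                       lambda_max = as.numeric(lam),
                       record_type = "wt",
                       mutation_notation = NA_character_,
                       parent_accession = NA_character_,
                       source_ref = "synthetic",
                       stringsAsFactors = FALSE)
    seq_tab <- data.frame(accession = names(al),
                          aa_seq = as.character(al),
                          stringsAsFactors = FALSE)
    if (n_mutants > 0L) {
        set.seed(seed + 4L)
        parents <- sample(names(al), n_mutants, replace = TRUE)
        per_parent <- table(parents)
        for (p in names(per_parent)) {
            mu <- spawnMutants(seq_tab$aa_seq[seq_tab$accession == p], p,
                               as.numeric(lam[p]), truth,
                               n = as.integer(per_parent[[p]]),
                               max_edits = max_edits,
                               seed = seed + 5L + match(p, names(al)),
                               site_bias = mutant_site_bias)
            if (!nrow(mu)) next
            meta <- rbind(meta, data.frame(
                accession = mu$accession, species = paste0("sp_", p),
                phylum = meta$phylum[meta$accession == p],
                class_name = "synthetic", gene_family = "Rh1",
                lambda_max = mu$lambda_max, record_type = "mutant",
                mutation_notation = mu$mutation_notation,
                parent_accession = p, source_ref = "synthetic",
                stringsAsFactors = FALSE))
            seq_tab <- rbind(seq_tab, mu[, c("accession", "aa_seq")])
        }
    }
    seqs <- Biostrings::AAStringSet(stats::setNames(seq_tab$aa_seq,
                                                    seq_tab$accession))
    ds <- OpsinSet(meta, seqs, name = "synthetic_study",
                   version = as.character(seed))
    alignment <- seqs  # indel-free evolution: ungapped rows are aligned
    out <- list(dataset = ds, alignment = alignment, tree = tree,
                truth = truth, phenotypes = lam, seed = seed)
    class(out) <- "SyntheticStudy"
    if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        paths <- writeOpsinSet(ds, dir, stem = "study")
        aln_path <- file.path(dir, "study_aln.fasta")
        Biostrings::writeXStringSet(alignment, aln_path, width = 80L)
        nwk <- file.path(dir, "study.nwk")
        ape::write.tree(tree, nwk)
        tj <- file.path(dir, "truth.json")
        writeTruthModel(truth, tj)
        out$paths <- c(paths, alignment = aln_path, tree = nwk, truth = tj)
    }
    out
}

#' @export
print.SyntheticStudy <- function(x, ...) {
    cat("SyntheticStudy (seed ", x$seed, "): ", length(x$dataset),
        " records on a ", length(x$tree$tip.label), "-tip tree\n", sep = "")
    print(x$truth)
    invisible(x)
}

#' Write / read a TruthModel as JSON
#'
#' @param truth a \code{TruthModel}.
#' @param path JSON file path.
#' @return \code{writeTruthModel}: the path, invisibly;
#'   \code{readTruthModel}: a \code{TruthModel} equal to the one written.
#' @export
writeTruthModel <- function(truth, path) {
    obj <- list(lambda0 = truth@lambda0,
                site_effects = truth@site_effects,
                interactions = truth@interactions,
                sigma_phylo2 = truth@sigma_phylo2,
                sigma_e = truth@sigma_e,
                lambda_range = truth@lambda_range)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeTruthModel
#' @export
readTruthModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    empty_se <- data.frame(site = integer(), residue = character(),
                           delta = numeric(), stringsAsFactors = FALSE)
    empty_ia <- data.frame(site1 = integer(), res1 = character(),
                           site2 = integer(), res2 = character(),
                           gamma = numeric(), stringsAsFactors = FALSE)
    se <- if (length(obj$site_effects)) as.data.frame(obj$site_effects)
          else empty_se
    ia <- if (length(obj$interactions)) as.data.frame(obj$interactions)
          else empty_ia
    truthModel(lambda0 = obj$lambda0, site_effects = se, interactions = ia,
               sigma_phylo2 = obj$sigma_phylo2, sigma_e = obj$sigma_e,
               lambda_range = obj$lambda_range)
}
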