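test_that("tree simulation is seeded, labeled and unit-height", {
    tr <- simulateTree(5, seed = 3)
    expect_equal(length(tr$tip.label), 5L)
    expect_true(all(tr$edge.length > 0))
    # unit height after scaling
    depths <- ape::node.depth.edgelength(tr)[1:5]
    expect_lte(abs(max(depths) - 1), 0.01)
    # determinism down to the Newick string
    expect_identical(ape::write.tree(simulateTree(8, seed = 12)),
                     ape::write.tree(simulateTree(8, seed = 12)))
    expect_error(simulateTree(1), "n_tips")
})

test_that("sequence evolution follows the substitution model", {
    tr <- simulateTree(6, seed = 5)
    # rate 0: all rows identical to the root
    al0 <- evolveSequences(tr, 40, rate = 0, seed = 7)
    expect_equal(length(unique(as.character(al0))), 1L)
    # determinism
    expect_identical(as.character(evolveSequences(tr, 30, 0.5, seed = 9)),
                     as.character(evolveSequences(tr, 30, 0.5, seed = 9)))
    # substitution probability over one branch matches 1 - exp(-rate*t)
    # within 3 standard errors (Bernoulli count over 1e4 sites)
    two <- ape::read.tree(text = "(A:0.5,B:0.00001);")
    al <- evolveSequences(two, 10000, rate = 0.4, seed = 11)
    diffs <- sum(strsplit(as.character(al[["A"]]), "")[[1]] !=
                 strsplit(as.character(al[["B"]]), "")[[1]])
    p <- 1 - exp(-0.4 * 0.5)
    se <- sqrt(p * (1 - p) * 10000)
    expect_lt(abs(diffs - p * 10000), 3 * se)
})

test_that("phenotypes decompose into baseline, site effects and interactions", {
    al <- aln(t1 = "AKCV", t2 = "VKCV", t3 = "AKSV", t4 = "VKST")
    tr <- ape::stree(4, "star"); tr$edge.length <- rep(1, 4)
    tr$tip.label <- names(al)

    # no effects, no noise: everything at the baseline
    lam0 <- assignPhenotypes(al, tr, truthModel(), seed = 1)
    expect_true(all(lam0 == 500))

    # single effect: +10 for V at site 1
    tm1 <- truthModel(site_effects = data.frame(site = 1L, residue = "V",
                                                delta = 10))
    lam1 <- assignPhenotypes(al, tr, tm1, seed = 1)
    expect_equal(unname(lam1[c("t1", "t2", "t3", "t4")]),
                 c(500, 510, 500, 510))

    # interaction fires only when both residues are present
    tm2 <- truthModel(
        site_effects = data.frame(site = c(1L, 3L), residue = c("V", "S"),
                                  delta = c(10, 4)),
        interactions = data.frame(site1 = 1L, res1 = "V", site2 = 3L,
                                  res2 = "S", gamma = -8))
    lam2 <- assignPhenotypes(al, tr, tm2, seed = 1)
    expect_equal(unname(lam2["t4"]), 500 + 10 + 4 - 8)
    expect_equal(unname(lam2["t2"]), 510)
    expect_equal(unname(lam2["t3"]), 504)
})

test_that("spawned mutants carry exact truth shifts and valid notation", {
    tm <- truthModel(site_effects = data.frame(site = c(3L, 7L),
                                               residue = c("S", "V"),
                                               delta = c(12, -6)),
        interactions = data.frame(site1 = 3L, res1 = "S", site2 = 7L,
                                  res2 = "V", gamma = 5))
    wt <- "MKADEFGHIL"
    muts <- spawnMutants(wt, "P1", 500, tm, n = 12, max_edits = 2,
                         seed = 13)
    expect_gt(nrow(muts), 0)
    for (i in seq_len(nrow(muts))) {
        # notation re-applies onto wt to reproduce the mutant sequence
        expect_identical(
            applyMutations(wt, parseMutations(muts$mutation_notation[i])),
            muts$aa_seq[i])
    }
    # single edit at a truth site shifts by exactly that site's delta
    single_at_3 <- muts[muts$mutation_notation == "A3S", ]
    if (nrow(single_at_3))
        expect_equal(single_at_3$lambda_max[1], 512)

    # a double at both interacting sites deviates from its additive
    # expectation by exactly the planted gamma
    dbl <- muts[muts$mutation_notation == "A3S_G7V", ]
    if (nrow(dbl)) {
        e <- eamv(500, c(512, 494))
        expect_equal(dbl$lambda_max[1] - e, 5)
    }
})

test_that("multimutants from the generator come with their component singles", {
    study <- generateStudy(n_tips = 20, L = 40, rate = 0.8, n_sites = 3,
                           n_interactions = 1, sigma_e = 1, n_mutants = 20,
                           max_edits = 2, seed = 17)
    m <- as.data.frame(opsinMeta(study$dataset))
    multis <- m[m$record_type == "mutant" &
                grepl("_", m$mutation_notation), ]
    expect_gt(nrow(multis), 0)
    cases <- findEpistasisCases(study$dataset)
    expect_equal(nrow(cases), nrow(multis))
})

test_that("generateStudy round-trips through files and is byte-reproducible", {
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    s1 <- generateStudy(n_tips = 12, L = 30, rate = 0.8, n_sites = 2,
                        n_interactions = 1, sigma_e = 1, n_mutants = 6,
                        seed = 19, dir = d1)
    s2 <- generateStudy(n_tips = 12, L = 30, rate = 0.8, n_sites = 2,
                        n_interactions = 1, sigma_e = 1, n_mutants = 6,
                        seed = 19, dir = d2)
    # byte-identical outputs for the same seed
    for (f in names(s1$paths))
        expect_identical(readLines(s1$paths[[f]]), readLines(s2$paths[[f]]),
                         info = f)
    # files parse back with the package's own readers
    ds <- loadOpsinSet(s1$paths["fasta"], s1$paths["meta"])
    expect_equal(length(ds), length(s1$dataset))
    tr <- ape::read.tree(s1$paths["tree"])
    expect_setequal(tr$tip.label, accessions(opsinSubset(ds, "wild_type_only")))
    al <- readAlignment(s1$paths["alignment"])
    expect_equal(length(al), length(ds))
    # truth JSON round-trips to an equal TruthModel
    tm <- readTruthModel(s1$paths["truth"])
    expect_equal(tm@site_effects, s1$truth@site_effects)
    expect_equal(tm@interactions, s1$truth@interactions)
    expect_equal(tm@lambda_range, s1$truth@lambda_range)
})

test_that("noiseless phenotypes are a deterministic function of sequences", {
    study <- generateStudy(n_tips = 25, L = 40, rate = 0.8, n_sites = 3,
                           n_interactions = 1, sigma_phylo2 = 0, sigma_e = 0,
                           n_mutants = 0, seed = 23)
    y <- lambdaMax(study$dataset)
    # an interpolating learner reaches (near) zero training error, so
    # in-sample r2 must be ~1 when the phenotype is noiseless
    model <- trainModel(study$alignment, y, estimator = "gbt", seed = 1)
    yhat <- predictNew(model, as.character(study$alignment),
                       mode = "prealigned")
    expect_gt(computeMetrics(as.numeric(y), yhat)$r2, 0.999)
    # clamp guard never triggers under default effect magnitudes
    expect_false(attr(study$phenotypes, "clamped"))
})
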