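test_that("BM covariance matches hand-traced path sharing", {
    # two tips from the root: no shared path
    t2 <- ape::read.tree(text = "(A:1.5,B:2);")
    C2 <- bmVcv(t2)
    expect_equal(C2, matrix(c(1.5, 0, 0, 2), 2, 2,
                            dimnames = list(c("A", "B"), c("A", "B"))))

    # ((A:1,B:1):1,C:2): shared path of A,B is 1
    t3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
    C3 <- bmVcv(t3)
    expect_equal(unname(diag(C3)), c(2, 2, 2))
    expect_equal(C3["A", "B"], 1)
    expect_equal(C3["A", "C"], 0)

    # star tree with equal branches: T * Identity
    ts <- ape::read.tree(text = "(A:0.7,B:0.7,C:0.7,D:0.7);")
    expect_equal(unname(bmVcv(ts)), 0.7 * diag(4))
})

test_that("bmVcv agrees with ape::vcv.phylo on random trees and is PSD", {
    set.seed(31)
    for (i in 1:20) {
        tree <- simulateTree(sample(3:10, 1), seed = i)
        C <- bmVcv(tree)
        expect_equal(C, ape::vcv.phylo(tree)[rownames(C), colnames(C)],
                     tolerance = 1e-12)
        expect_equal(C, t(C))
        expect_true(all(eigen(C, symmetric = TRUE,
                              only.values = TRUE)$values > -1e-10))
    }
    # lengthening every terminal branch by c adds c to the diagonal only
    tree <- simulateTree(6, seed = 99)
    C0 <- bmVcv(tree)
    tree2 <- tree
    term <- tree2$edge[, 2] <= length(tree2$tip.label)
    tree2$edge.length[term] <- tree2$edge.length[term] + 0.3
    expect_equal(bmVcv(tree2), C0 + 0.3 * diag(nrow(C0)), tolerance = 1e-12)
})

test_that("star-tree imputation reduces to the mean of observed values", {
    ts <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
    obs <- c(A = 480, B = 500, C = 520)
    r <- imputeBM(ts, obs)
    expect_equal(r$estimates$tip, "D")
    expect_equal(r$estimates$imputed, mean(obs))
    expect_equal(r$mu, mean(obs))
})

test_that("a zero-length cherry copies its observed sibling", {
    tc <- ape::read.tree(text = "((A:1e-9,B:1e-9):1,C:2);")
    r <- suppressWarnings(imputeBM(tc, c(A = 520, C = 470), missing = "B"))
    expect_equal(r$estimates$imputed, 520, tolerance = 1e-4)
})

test_that("imputed means match brute-force conditional-normal oracle", {
    set.seed(41)
    for (i in 1:40) {
        tree <- simulateTree(sample(4:8, 1), seed = 1000 + i)
        tips <- tree$tip.label
        n_missing <- sample(1:2, 1)
        missing <- sample(tips, n_missing)
        obs_tips <- setdiff(tips, missing)
        y <- setNames(runif(length(obs_tips), 450, 550), obs_tips)
        r <- imputeBM(tree, y, missing = missing)

        # oracle: assemble the full joint covariance with ape and condition
        Cfull <- ape::vcv.phylo(tree)
        Coo <- Cfull[obs_tips, obs_tips]
        ones <- rep(1, length(obs_tips))
        mu <- as.numeric(ones %*% solve(Coo, y)) /
              as.numeric(ones %*% solve(Coo, ones))
        cond <- mu + Cfull[missing, obs_tips, drop = FALSE] %*%
            solve(Coo, y - mu)
        expect_equal(r$estimates$imputed[match(missing, r$estimates$tip)],
                     as.numeric(cond), tolerance = 1e-8)
        expect_true(all(r$estimates$variance >= 0))
    }
})

test_that("imputation is tip-order invariant and translation-equivariant", {
    tree <- simulateTree(7, seed = 7)
    tips <- tree$tip.label
    y <- setNames(runif(5, 450, 550), tips[1:5])
    r1 <- imputeBM(tree, y, missing = tips[6:7])
    r2 <- imputeBM(tree, y[c(3, 1, 5, 2, 4)], missing = tips[7:6])
    expect_equal(r1$estimates$imputed[match(tips[6:7], r1$estimates$tip)],
                 r2$estimates$imputed[match(tips[6:7], r2$estimates$tip)])
    r3 <- imputeBM(tree, y + 25, missing = tips[6:7])
    expect_equal(r3$estimates$imputed, r1$estimates$imputed + 25,
                 tolerance = 1e-9)
    # no missing tips: empty result
    r4 <- imputeBM(tree, setNames(runif(7, 450, 550), tips))
    expect_equal(nrow(r4$estimates), 0L)
})

test_that("ML-vs-imputation harness pairs predictions on one hold-out", {
    study <- generateStudy(n_tips = 40, L = 80, rate = 0.8, n_sites = 3,
                           n_interactions = 0, sigma_e = 2, n_mutants = 0,
                           seed = 61)
    wt <- opsinSubset(study$dataset, "wild_type_only")
    cmp <- compareMLImputation(wt, study$alignment, study$tree,
                               holdout_n = 8, estimator = "ridge", seed = 5)
    expect_equal(nrow(cmp$holdout), 8L)
    expect_true(all(is.finite(cmp$holdout$pred_ml)))
    expect_true(all(is.finite(cmp$holdout$pred_imputation)))
    # holdout_n = 1: both methods emit exactly one prediction
    cmp1 <- compareMLImputation(wt, study$alignment, study$tree,
                                holdout_n = 1, estimator = "ridge", seed = 5)
    expect_equal(nrow(cmp1$holdout), 1L)
    # mismatched tips error
    tree_bad <- study$tree
    tree_bad$tip.label[1] <- "stranger"
    expect_error(compareMLImputation(wt, study$alignment, tree_bad, 5),
                 "stranger")
})

test_that("each method wins on the trait structure it models", {
    # pure Brownian trait, no sequence effects: imputation should win
    # majority of seeds; pure additive site trait: the regressor should win
    imp_wins <- 0L; ml_wins <- 0L
    n_seeds <- 10L
    for (s in seq_len(n_seeds)) {
        tree <- simulateTree(40, seed = 300 + s)
        # slowly-evolving sequences: little genotypic signal, so a pure
        # Brownian trait is the tree's to predict, not the regressor's
        al <- evolveSequences(tree, 60, rate = 0.05, seed = 400 + s)
        truth_bm <- truthModel(sigma_phylo2 = 400, sigma_e = 1)
        lam_bm <- assignPhenotypes(al, tree, truth_bm, seed = 500 + s)
        meta <- data.frame(accession = names(al), lambda_max = as.numeric(lam_bm),
                           record_type = "wt")
        ds_bm <- OpsinSet(meta, setNames(as.character(al), names(al)))
        cmp <- compareMLImputation(ds_bm, al, tree, holdout_n = 10,
                                   estimator = "ridge", seed = s)
        if (cmp$metrics$imputation$r2 >= cmp$metrics$ml$r2)
            imp_wins <- imp_wins + 1L
        # additive-site-only phenotype on a star tree: tips evolve
        # independently, so phylogeny carries no information about the
        # trait while the site effects remain learnable
        star <- ape::stree(40, "star")
        star$edge.length <- rep(1, nrow(star$edge))
        al_star <- evolveSequences(star, 60, rate = 0.8, seed = 400 + s)
        truth_add <- randomTruthModel(al_star, n_sites = 4,
                                      n_interactions = 0,
                                      delta_range = c(15, 25),
                                      sigma_phylo2 = 0, sigma_e = 1,
                                      seed = 600 + s)
        lam_add <- assignPhenotypes(al_star, star, truth_add, seed = 700 + s)
        meta_star <- data.frame(accession = names(al_star),
                                lambda_max = as.numeric(lam_add),
                                record_type = "wt")
        ds_add <- OpsinSet(meta_star,
                           setNames(as.character(al_star), names(al_star)))
        cmp2 <- compareMLImputation(ds_add, al_star, star, holdout_n = 10,
                                    estimator = "ridge", seed = s)
        if (cmp2$metrics$ml$r2 >= cmp2$metrics$imputation$r2)
            ml_wins <- ml_wins + 1L
    }
    expect_gt(imp_wins, n_seeds / 2)
    expect_gt(ml_wins, n_seeds / 2)
})
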