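test_that("iterative hold-out partitions targets and predicts each exactly once", {
    study <- generateStudy(n_tips = 30, L = 50, rate = 0.8, n_sites = 3,
                           n_interactions = 0, sigma_e = 1, n_mutants = 0,
                           seed = 71)
    ds <- study$dataset; al <- study$alignment
    # partition grid, including non-divisible group sizes
    for (gs in c(3L, 7L, 10L)) {
        hr <- iterativeHoldout(ds, al, group_size = gs, estimator = "ridge",
                               seed = 2)
        expect_equal(sort(hr$accession), sort(accessions(ds)))
        expect_equal(anyDuplicated(hr$accession), 0L)
        sizes <- as.numeric(table(hr$group))
        expect_true(all(sizes[-length(sizes)] == gs))
        expect_lte(sizes[length(sizes)], gs)
    }
    # determinism: same seed gives the same group assignment
    h1 <- iterativeHoldout(ds, al, group_size = 7, estimator = "ridge", seed = 9)
    h2 <- iterativeHoldout(ds, al, group_size = 7, estimator = "ridge", seed = 9)
    expect_identical(h1, h2)
    # with a target filter, group_size = |targets| degenerates to a single
    # train/test split (non-targets always remain in training)
    hr_t <- iterativeHoldout(ds, al, group_size = 10, estimator = "ridge",
                             seed = 2, targets = accessions(ds)[1:10])
    expect_equal(sort(hr_t$accession), sort(accessions(ds)[1:10]))
    expect_equal(unique(hr_t$group), 1L)
    # withholding every record leaves nothing to train on
    expect_error(iterativeHoldout(ds, al, group_size = 30,
                                  estimator = "ridge", seed = 2), "train")
    expect_error(iterativeHoldout(ds, al, group_size = 0), "group_size")
    expect_error(iterativeHoldout(ds, al, estimator = "nope", group_size = 5),
                 "unknown")
})

test_that("hold-out residuals and outlier rule feed the per-type breakdown", {
    hr <- data.frame(accession = paste0("a", 1:6),
                     known = rep(500, 6),
                     predicted = c(500, 512, 490, 508, 505, 512),
                     residual = c(0, 12, -10, 8, 5, 12),
                     type = c("wt", "wt", "single-mutant", "single-mutant",
                              "chimera", "multi-mutant"),
                     group = 1L)
    hr$outlier <- abs(hr$residual) > 10
    class(hr) <- c("HoldoutResult", "data.frame")
    bd <- residualBreakdown(hr)
    expect_equal(bd$outliers[bd$type == "wt"], 1L)          # 12 nm is out
    expect_equal(bd$outliers[bd$type == "single-mutant"], 0L) # -10 nm is not
    expect_equal(bd$n[bd$type == "all"], 6L)
    expect_equal(bd$median_residual[bd$type == "all"], median(hr$residual))
    # all-zero residuals: zero medians, zero outliers
    hr0 <- hr; hr0$residual <- 0
    bd0 <- residualBreakdown(hr0)
    expect_true(all(bd0$median_residual == 0))
    expect_true(all(bd0$outliers == 0L))
})

test_that("learning curve sizes grow by step with reps points per size", {
    study <- generateStudy(n_tips = 50, L = 40, rate = 0.8, n_sites = 3,
                           n_interactions = 0, sigma_e = 1, n_mutants = 0,
                           seed = 81)
    lc <- learningCurve(study$dataset, study$alignment, step = 15L,
                        reps = 2L, estimator = "ridge", seed = 4, k = 3L)
    expect_setequal(unique(lc$n_train), c(15, 30, 45, 50))
    expect_true(all(table(lc$n_train) == 2))
    # full-size performance should not trail the smallest size on a clean
    # additive signal
    agg <- tapply(lc$r2, lc$n_train, mean)
    expect_gte(agg[length(agg)], agg[1] - 0.05)
    expect_error(learningCurve(study$dataset, study$alignment, step = 60L),
                 "smaller")
})

test_that("AIC arithmetic and curve ranking recover a reciprocal law", {
    expect_equal(aicLeastSquares(10, 10, 2), 4)   # 10*ln(1) + 4

    # noiseless reciprocal data: y = 0.95 - 44/x
    x <- seq(25, 500, by = 25)
    y <- 0.95 - 44 / x
    fits <- fitCurves(data.frame(x = x, y = y))
    expect_equal(fits$model[1], "reciprocal")
    cf <- attr(fits, "coefficients")$reciprocal
    expect_equal(unname(cf["a"]), 0.95, tolerance = 1e-6)
    expect_equal(unname(cf["b"]), -44, tolerance = 1e-6)
    expect_true(all(c("reciprocal", "logarithmic", "power", "exp_rise",
                      "saturating", "quadratic") %in% fits$model))

    # constant y degenerates every candidate to its intercept behavior;
    # ties rank by parameter count
    fits0 <- fitCurves(data.frame(x = x, y = rep(0.8, length(x))))
    ok <- fits0[fits0$ok, ]
    expect_lte(ok$k[1], min(ok$k))
    expect_error(fitCurves(data.frame(x = 1, y = 1)), "fewer points")
})

test_that("AIC ranking is invariant to adding a constant to all y", {
    set.seed(51)
    x <- seq(20, 400, by = 20)
    y <- 0.9 - 30 / x + rnorm(length(x), 0, 0.01)
    f1 <- fitCurves(data.frame(x = x, y = y),
                    candidates = c("reciprocal", "logarithmic", "quadratic"))
    f2 <- fitCurves(data.frame(x = x, y = y + 5),
                    candidates = c("reciprocal", "logarithmic", "quadratic"))
    expect_equal(f1$model, f2$model)
    expect_equal(f1$aic, f2$aic, tolerance = 1e-6)
})

test_that("entropy-importance regression returns OLS r2 with guardrails", {
    prof <- data.frame(column = 1:20, rel_entropy = seq(0.05, 1, by = 0.05))
    imp <- data.frame(column = 1:20,
                      mean_rel_importance = seq(0.05, 1, by = 0.05))
    r2 <- suppressWarnings(entropyImportanceRegression(prof, imp))
    expect_equal(as.numeric(r2), 1)                  # identical -> r2 = 1
    expect_equal(attr(r2, "n"), 20L)

    # independence: seeded shuffle over many columns -> near-zero r2
    set.seed(61)
    prof_big <- data.frame(column = 1:1000, rel_entropy = runif(1000))
    imp_big <- data.frame(column = 1:1000,
                          mean_rel_importance = sample(runif(1000)))
    expect_lt(as.numeric(entropyImportanceRegression(prof_big, imp_big)), 0.05)

    expect_error(entropyImportanceRegression(prof[1:2, ], imp[1:2, ]),
                 "3 joined")
})

test_that("holdout error shrinks as planted noise shrinks", {
    mae_at <- function(sig) {
        study <- generateStudy(n_tips = 40, L = 50, rate = 0.8, n_sites = 3,
                               n_interactions = 0, sigma_e = sig,
                               n_mutants = 0, seed = 91)
        hr <- iterativeHoldout(study$dataset, study$alignment,
                               group_size = 10, estimator = "ridge", seed = 3)
        mean(abs(hr$residual))
    }
    expect_lt(mae_at(0.5), mae_at(8))
})
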