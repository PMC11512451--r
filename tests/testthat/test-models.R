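test_that("computeMetrics matches hand-derived values and definitions", {
    # identity predictions
    m0 <- computeMetrics(c(500, 510, 520), c(500, 510, 520))
    expect_equal(m0$r2, 1); expect_equal(m0$mae, 0); expect_equal(m0$rmse, 0)

    # derived fixture: direct evaluation of the definitions
    m <- computeMetrics(c(500, 510, 520), c(505, 510, 515))
    expect_equal(m$mae, 10 / 3, tolerance = 1e-12)
    expect_equal(m$mse, 50 / 3, tolerance = 1e-12)
    expect_equal(m$rmse, sqrt(50 / 3), tolerance = 1e-12)
    expect_equal(m$r2, 0.75, tolerance = 1e-12)
    expect_equal(m$mape, 100 * mean(c(5 / 500, 0, 5 / 520)), tolerance = 1e-12)

    # constant-mean prediction has r2 = 0
    y <- c(480, 500, 560)
    expect_equal(computeMetrics(y, rep(mean(y), 3))$r2, 0)

    # degenerate y: r2 NA with warning, other metrics intact
    expect_warning(mz <- computeMetrics(c(500, 500), c(499, 501)), "r2")
    expect_true(is.na(mz$r2)); expect_equal(mz$mae, 1)
})

test_that("metric identities hold on random vectors", {
    set.seed(7)
    for (i in 1:50) {
        n <- sample(3:30, 1)
        y <- runif(n, 350, 611); yhat <- y + rnorm(n, 0, 5)
        m <- computeMetrics(y, yhat)
        expect_equal(m$rmse^2, m$mse, tolerance = 1e-10)
        expect_lte(m$mae, m$rmse + 1e-12)
        expect_lte(m$r2, 1)
        # r2 invariant under common affine rescaling
        a <- runif(1, 0.5, 3); b <- runif(1, -50, 50)
        m2 <- computeMetrics(a * y + b, a * yhat + b)
        expect_equal(m2$r2, m$r2, tolerance = 1e-9)
    }
})

test_that("cross-validation is seeded, shares folds, and ranks by r2", {
    set.seed(11)
    n <- 60
    x <- matrix(rbinom(n * 6, 1, 0.5), n, 6,
                dimnames = list(NULL, paste0("p", 1:6, ":A")))
    y <- 500 + 20 * x[, 1]          # exactly linear in one indicator
    cv <- crossValidate(x, y, estimators = c("ridge", "rf"), k = 5, seed = 3)
    expect_gt(cv$table$r2[cv$table$estimator == "ridge"], 0.99)
    # determinism: identical report for the same seed
    cv2 <- crossValidate(x, y, estimators = c("ridge", "rf"), k = 5, seed = 3)
    expect_identical(cv$table, cv2$table)
    # fold partition is disjoint and exhaustive
    expect_equal(sort(unique(cv$folds)), 1:5)
    expect_length(cv$folds, n)
    # ranking is non-increasing in r2
    expect_true(all(diff(cv$table$r2) <= 1e-12))
    expect_error(crossValidate(x, y, k = n + 1, seed = 1), "exceeds")
    expect_error(crossValidate(x, y, estimators = "nope", seed = 1), "unknown")
})

test_that("every registry estimator fits, predicts and is deterministic", {
    set.seed(5)
    n <- 80
    x <- matrix(rbinom(n * 8, 1, 0.5), n, 8,
                dimnames = list(NULL, paste0("p", 1:8, ":A")))
    y <- 500 + 15 * x[, 2] - 8 * x[, 5] + rnorm(n, 0, 1)
    for (nm in names(defaultEstimators())) {
        est <- defaultEstimators()[[nm]]
        f1 <- est$fit(x, y, seed = 9)
        p1 <- est$predict(f1, x)
        f2 <- est$fit(x, y, seed = 9)
        expect_equal(est$predict(f2, x), p1, tolerance = 1e-12, info = nm)
        expect_lt(mean(abs(p1 - y)), 10)
        imp <- est$importance(f1, x)
        expect_named(imp, colnames(x), info = nm)
    }
})

test_that("prediction for new sequences honors the unseen-residue contract", {
    set.seed(21)
    study <- generateStudy(n_tips = 40, L = 60, rate = 0.8, n_sites = 3,
                           n_interactions = 0, sigma_e = 0, n_mutants = 0,
                           seed = 21)
    al <- study$alignment
    y <- lambdaMax(study$dataset)
    model <- trainModel(al, y, estimator = "ridge", seed = 1)

    # a training sequence re-submitted prealigned returns a finite prediction
    p <- predictNew(model, as.character(al[1]), mode = "prealigned")
    expect_true(is.finite(p))

    # sequence with unseen residues at every variable column: no error,
    # equals the model output on the all-zero encoding
    mat <- do.call(rbind, strsplit(as.character(al), ""))
    varcols <- model$columns
    q <- mat[1, ]
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (cc in varcols) {
        seen <- unique(mat[, cc])
        unseen <- setdiff(aa, seen)
        # a gap also encodes as all-zero when every residue was seen
        q[cc] <- if (length(unseen)) unseen[1] else "-"
    }
    p_unseen <- predictNew(model, paste(q, collapse = ""), mode = "prealigned")
    zero_x <- matrix(0, 1, ncol(model$train_x),
                     dimnames = list(NULL, colnames(model$train_x)))
    expect_equal(p_unseen, as.numeric(model$est$predict(model$fit, zero_x)),
                 tolerance = 1e-9)

    # pairwise mode: the reference sequence occupies its own columns,
    # prediction agrees with the prealigned route
    ref_acc <- model$reference_row
    p_pair <- predictNew(model, gsub("-", "", as.character(al[ref_acc])),
                         mode = "map_to_reference_pairwise")
    p_pre <- predictNew(model, as.character(al[ref_acc]), mode = "prealigned")
    expect_equal(p_pair, p_pre, tolerance = 1e-9)

    expect_error(predictNew(model, "MDA", mode = "prealigned"), "width")
})

test_that("tree-ensemble models recover training phenotypes within training MAE", {
    study <- generateStudy(n_tips = 60, L = 80, rate = 0.8, n_sites = 3,
                           n_interactions = 0, sigma_e = 1, n_mutants = 0,
                           seed = 31)
    al <- study$alignment
    y <- lambdaMax(study$dataset)
    model <- trainModel(al, y, estimator = "gbt", seed = 2)
    yhat <- predictNew(model, as.character(al), mode = "prealigned")
    train_mae <- mean(abs(yhat - as.numeric(y)))
    frac_ok <- mean(abs(yhat - as.numeric(y)) <= pmax(train_mae, 1e-6) + 1e-9)
    expect_gte(frac_ok, 0.5)  # at least half within the training MAE by definition
    expect_lt(train_mae, 5)
})

test_that("importance concentrates on the causal column and scales to max 1", {
    set.seed(13)
    n <- 100
    # an alignment whose column 2 carries the only signal
    mat <- matrix("K", n, 5)
    mat[, 2] <- sample(c("A", "V"), n, replace = TRUE)
    mat[, 4] <- sample(c("C", "D"), n, replace = TRUE)   # noise column
    rows <- apply(mat, 1, paste, collapse = "")
    al <- Biostrings::AAStringSet(setNames(rows, paste0("s", 1:n)))
    y <- 500 + 25 * (mat[, 2] == "V")
    m_lin <- trainModel(al, y, estimator = "ridge", seed = 1)
    rep1 <- importanceReport(list(m_lin))
    expect_equal(rep1$mean_rel_importance[rep1$column == 2], 1)
    expect_lt(rep1$mean_rel_importance[rep1$column == 4], 0.05)
    # invariant columns are absent from the report
    expect_setequal(rep1$column, c(2L, 4L))

    # all models agreeing on the top column keeps its mean at 1
    m_rf <- trainModel(al, y, estimator = "rf", seed = 1)
    m_gbt <- trainModel(al, y, estimator = "gbt", seed = 1)
    rep3 <- importanceReport(list(m_lin, m_rf, m_gbt))
    expect_equal(rep3$mean_rel_importance[rep3$column == 2], 1)

    # scaling invariance: positive rescaling of raw importances is a no-op
    est <- defaultEstimators()$ridge
    imp_raw <- est$importance(m_lin$fit, m_lin$train_x)
    v1 <- tapply(imp_raw, featureTable(m_lin$encoded)$column, sum)
    v2 <- tapply(imp_raw * 7.3, featureTable(m_lin$encoded)$column, sum)
    expect_equal(as.numeric(v1 / max(v1)), as.numeric(v2 / max(v2)))
})
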