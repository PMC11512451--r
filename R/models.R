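#' Regression evaluation metrics
#'
#' The five metrics used throughout: \eqn{R^2 = 1 - SS_{res}/SS_{tot}},
#' MAE (nm), MAPE (\%, true value in the denominator), MSE (nm^2) and
#' RMSE (nm). \code{rmse^2 == mse} and \code{mae <= rmse} by construction.
#'
#' @param y observed phenotypes (nm).
#' @param yhat predictions (nm).
#' @return named list \code{r2, mae, mape, mse, rmse}. With fewer than two
#'   observations or zero-variance \code{y}, \code{r2} is \code{NA} and a
#'   warning is raised (the other metrics are still returned).
#' @examples
#' computeMetrics(c(500, 510, 520), c(505, 510, 515))
#' @export
computeMetrics <- function(y, yhat) {
    if (length(y) != length(yhat)) stop("y and yhat differ in length")
    err <- y - yhat
    mse <- mean(err^2)
    sstot <- sum((y - mean(y))^2)
    if (length(y) < 2L || sstot == 0) {
        warning("r2 undefined: need >= 2 observations with variance in y")
        r2 <- NA_real_
    } else r2 <- 1 - sum(err^2) / sstot
    list(r2 = r2, mae = mean(abs(err)), mape = 100 * mean(abs(err) / y),
         mse = mse, rmse = sqrt(mse))
}

## ---- estimator registry -------------------------------------------------

## Each estimator is a list(fit(x, y, seed) -> model,
##                          predict(model, x) -> numeric,
##                          importance(model, x) -> named numeric,
##                          importance_metric = string).
## Linear families report absolute standardized coefficients; ranger reports
## impurity importance; xgboost families report total gain.

## Penalty strength is chosen by glmnet's internal cross-validation on the
## training fold (lambda.min), the standard usage; folds are seeded so a
## fit is reproducible.
glmnet_est <- function(alpha) {
    list(
        fit = function(x, y, seed = 1L) {
            set.seed(seed)
            ## grouped=FALSE below ~3 observations per fold, as cv.glmnet
            ## itself enforces
            glmnet::cv.glmnet(x, y, alpha = alpha, nfolds = 5L,
                              grouped = nrow(x) >= 15L, standardize = TRUE,
                              lambda.min.ratio = 1e-6, nlambda = 100L)
        },
        predict = function(model, x)
            as.numeric(stats::predict(model, x, s = "lambda.min")),
        importance = function(model, x) {
            b <- as.numeric(stats::coef(model, s = "lambda.min"))[-1L]
            sds <- apply(x, 2L, stats::sd)
            stats::setNames(abs(b) * sds, colnames(x))
        },
        importance_metric = "abs standardized coefficient")
}

## Bayesian ridge by evidence maximization (MacKay updates on the SVD of
## the centered design); hyperpriors are flat, stopping at 200 iterations
## or relative change < 1e-8 in (alpha, beta).
bayes_ridge_fit <- function(x, y) {
    xm <- colMeans(x); ym <- mean(y)
    xc <- sweep(x, 2L, xm); yc <- y - ym
    sv <- svd(xc)
    d2 <- sv$d^2
    uy <- crossprod(sv$u, yc)
    n <- nrow(x)
    alpha <- 1e-6; beta <- 1 / max(stats::var(yc), 1e-12)
    for (it in seq_len(200L)) {
        coef_svd <- (sv$d * as.numeric(uy)) * (beta / (alpha + beta * d2))
        w <- sv$v %*% coef_svd
        gamma <- sum(beta * d2 / (alpha + beta * d2))
        rss <- sum((yc - xc %*% w)^2)
        alpha_new <- gamma / max(sum(w^2), 1e-12)
        beta_new <- max(n - gamma, 1e-6) / max(rss, 1e-12)
        if (abs(alpha_new - alpha) < 1e-8 * alpha &&
            abs(beta_new - beta) < 1e-8 * beta) {
            alpha <- alpha_new; beta <- beta_new; break
        }
        alpha <- alpha_new; beta <- beta_new
    }
    coef_svd <- (sv$d * as.numeric(uy)) * (beta / (alpha + beta * d2))
    w <- as.numeric(sv$v %*% coef_svd)
    list(w = w, intercept = ym - sum(xm * w), alpha = alpha, beta = beta,
         features = colnames(x))
}

xgb_est <- function(max_depth, nrounds, eta) {
    list(
        fit = function(x, y, seed = 1L) {
            set.seed(seed)
            xgboost::xgb.train(
                params = list(max_depth = max_depth, eta = eta,
                              subsample = 1, nthread = 1L,
                              objective = "reg:squarederror"),
                data = xgboost::xgb.DMatrix(x, label = y, nthread = 1L),
                nrounds = nrounds, verbose = 0)
        },
        predict = function(model, x)
            as.numeric(stats::predict(model,
                xgboost::xgb.DMatrix(x, nthread = 1L))),
        importance = function(model, x) {
            imp <- stats::setNames(rep(0, ncol(x)), colnames(x))
            tab <- xgboost::xgb.importance(model = model)
            if (!is.null(tab) && nrow(tab))
                imp[tab$Feature] <- tab$Gain
            imp
        },
        importance_metric = "xgboost gain")
}

#' Default regressor registry
#'
#' A pluggable named list of estimator definitions with fixed defaults:
#' \describe{
#'   \item{ridge}{L2-penalized linear regression (glmnet; penalty chosen
#'     by seeded internal cross-validation, lambda.min).}
#'   \item{bayesRidge}{Bayesian ridge with evidence-maximized precision
#'     hyperparameters (implemented in-package).}
#'   \item{lasso}{L1-penalized linear regression (glmnet; penalty as for
#'     ridge).}
#'   \item{rf}{random forest (ranger, 300 trees, impurity importance).}
#'   \item{gbt}{gradient-boosted trees (xgboost, depth 6, eta 0.1,
#'     300 rounds).}
#'   \item{boostStump}{boosted depth-1 stumps (xgboost, depth 1, eta 0.3,
#'     400 rounds) — an AdaBoost-style additive-stump learner.}
#' }
#' Each entry is a list of \code{fit(x, y, seed)}, \code{predict(model, x)},
#' \code{importance(model, x)} and a human-readable
#' \code{importance_metric}; supply your own entries in the same shape to
#' extend the suite.
#'
#' @return named list of estimator definitions.
#' @export
defaultEstimators <- function() {
    list(
        ridge = glmnet_est(alpha = 0),
        bayesRidge = list(
            fit = function(x, y, seed = 1L) bayes_ridge_fit(x, y),
            predict = function(model, x)
                as.numeric(x %*% model$w + model$intercept),
            importance = function(model, x) {
                sds <- apply(x, 2L, stats::sd)
                stats::setNames(abs(model$w) * sds, colnames(x))
            },
            importance_metric = "abs standardized coefficient"),
        lasso = glmnet_est(alpha = 1),
        rf = list(
            fit = function(x, y, seed = 1L) {
                df <- data.frame(x, check.names = FALSE)
                ranger::ranger(y = y, x = df, num.trees = 300L,
                               importance = "impurity", seed = seed,
                               num.threads = 1L, respect.unordered.factors = TRUE)
            },
            predict = function(model, x)
                stats::predict(model, data.frame(x, check.names = FALSE),
                               num.threads = 1L)$predictions,
            importance = function(model, x) {
                imp <- model$variable.importance
                out <- stats::setNames(rep(0, ncol(x)), colnames(x))
                out[names(imp)] <- imp
                out
            },
            importance_metric = "impurity (Gini) importance"),
        gbt = xgb_est(max_depth = 6L, nrounds = 300L, eta = 0.1),
        boostStump = xgb_est(max_depth = 1L, nrounds = 400L, eta = 0.3))
}

resolveEstimators <- function(estimators) {
    reg <- defaultEstimators()
    if (is.character(estimators)) {
        unknown <- setdiff(estimators, names(reg))
        if (length(unknown))
            stop("unknown estimator(s): ", paste(unknown, collapse = ", "))
        reg[estimators]
    } else if (is.list(estimators)) estimators
    else stop("estimators must be names into the registry or a registry-shaped list")
}

as_feature_matrix <- function(X) {
    if (is(X, "EncodedAlignment")) featureMatrix(X) else as.matrix(X)
}

#' Seeded k-fold cross-validation over an estimator suite
#'
#' One seeded random partition into \code{k} folds is shared by every
#' estimator; the five metrics are computed per validation fold and
#' averaged; estimators are ranked by mean \eqn{R^2} (ties broken by lower
#' MAE, then name). The same call with the same seed returns an identical
#' report.
#'
#' @param X \code{EncodedAlignment} or numeric matrix.
#' @param y phenotype vector (nm), length \code{nrow(X)}.
#' @param estimators registry names (default: all of
#'   \code{\link{defaultEstimators}}) or a registry-shaped list.
#' @param k number of folds (default 10); must satisfy \code{2 <= k <= n}.
#' @param seed integer seed for the fold partition and estimator fits.
#' @return a \code{CVReport}: list with \code{table} (one row per
#'   estimator, mean metrics, rank), \code{ranking}, \code{k}, \code{seed},
#'   \code{folds}.
#' @export
crossValidate <- function(X, y, estimators = names(defaultEstimators()),
                          k = 10L, seed = 1L) {
    x <- as_feature_matrix(X)
    n <- nrow(x)
    if (length(y) != n) stop("y length does not match X rows")
    if (k < 2L) stop("k must be >= 2")
    if (k > n) stop("k = ", k, " exceeds the number of samples (", n, ")")
    ests <- resolveEstimators(estimators)
    set.seed(seed)
    folds <- sample(rep(seq_len(k), length.out = n))
    per_est <- lapply(names(ests), function(nm) {
        est <- ests[[nm]]
        fold_metrics <- lapply(seq_len(k), function(f) {
            tr <- folds != f
            fit <- est$fit(x[tr, , drop = FALSE], y[tr], seed = seed)
            yhat <- est$predict(fit, x[!tr, , drop = FALSE])
            suppressWarnings(computeMetrics(y[!tr], yhat))
        })
        ms <- vapply(c("r2", "mae", "mape", "mse", "rmse"), function(mname)
            mean(vapply(fold_metrics, function(m) m[[mname]], numeric(1))),
            numeric(1))
        c(as.list(ms))
    })
    tab <- data.frame(estimator = names(ests),
                      do.call(rbind, lapply(per_est, as.data.frame)),
                      stringsAsFactors = FALSE)
    o <- order(-tab$r2, tab$mae, tab$estimator)
    tab <- tab[o, ]
    tab$rank <- seq_len(nrow(tab))
    rownames(tab) <- NULL
    structure(list(table = tab, ranking = tab$estimator, k = k,
                   seed = seed, folds = folds),
              class = "CVReport")
}

#' @export
print.CVReport <- function(x, ...) {
    cat("Cross-validation report (k = ", x$k, ", seed = ", x$seed, ")\n",
        sep = "")
    print(x$table, digits = 4)
    invisible(x)
}

#' Train one regressor on an alignment with phenotypes
#'
#' The full training path: (optionally) drop invariant columns, one-hot
#' encode, fit the named estimator, and bundle everything needed to score
#' new sequences — the training vocabulary, retained columns, full
#' alignment width, and a \code{PositionMap} against the reference row (for
#' the pairwise projection mode and for importance reports).
#'
#' @param al training alignment (\code{AAStringSet}).
#' @param y phenotypes; either unnamed in row order or named by accession.
#' @param estimator registry name (see \code{\link{defaultEstimators}}).
#' @param seed integer seed forwarded to the fit.
#' @param reference_row accession used as coordinate reference; default the
#'   first row.
#' @param tmd_table optional TMD boundary data.frame for the position map.
#' @param drop_invariant drop zero-entropy columns first (default TRUE).
#' @return a \code{SpectralModel} (list) usable with
#'   \code{\link{predictNew}} and \code{\link{importanceReport}}.
#' @export
trainModel <- function(al, y, estimator = "gbt", seed = 1L,
                       reference_row = NULL, tmd_table = NULL,
                       drop_invariant = TRUE) {
    if (!is.null(names(y))) {
        idx <- match(names(al), names(y))
        if (anyNA(idx))
            stop("phenotypes missing for: ",
                 paste(names(al)[is.na(idx)], collapse = ", "))
        y <- as.numeric(y[idx])
    }
    if (is.null(reference_row)) reference_row <- names(al)[1L]
    full_width <- Biostrings::width(al)[1L]
    pmap <- mapToReference(al, reference_row, tmd_table)
    al_used <- if (drop_invariant) dropInvariantColumns(al) else al
    enc <- oneHot(al_used)
    est <- resolveEstimators(estimator)[[1L]]
    fit <- est$fit(featureMatrix(enc), y, seed = seed)
    ref_row_aligned <- as.character(al[[reference_row]])
    structure(list(estimator = if (is.character(estimator)) estimator else "custom",
                   est = est, fit = fit, encoded = enc,
                   columns = alignmentColumns(al_used),
                   full_width = full_width, pmap = pmap,
                   reference_row = reference_row,
                   ref_aligned = ref_row_aligned,
                   ref_ungapped = gsub("-", "", ref_row_aligned),
                   train_x = featureMatrix(enc), train_y = y,
                   seed = seed),
              class = "SpectralModel")
}

#' @export
print.SpectralModel <- function(x, ...) {
    cat("SpectralModel: estimator '", x$estimator, "', ",
        length(x$train_y), " training sequences, ",
        ncol(x$train_x), " features over ", length(x$columns),
        " variable columns (reference '", x$reference_row, "')\n", sep = "")
    invisible(x)
}

## Project an ungapped sequence onto the training alignment columns via
## global pairwise alignment to the ungapped reference row. Residues that
## align to a reference position land in that position's alignment column;
## insertions relative to the reference are dropped (the training alignment
## has no columns for them unless the reference itself was gapped there).
project_to_columns <- function(seq, model, gap_opening = 10,
                               gap_extension = 0.5) {
    pa <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::AAString(seq),
        subject = Biostrings::AAString(model$ref_ungapped),
        type = "global", substitutionMatrix = "BLOSUM62",
        gapOpening = gap_opening, gapExtension = gap_extension)
    qchars <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    schars <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    refpos <- cumsum(schars != "-")
    m <- model$pmap@map
    col_of_refpos <- m$column[match(as.character(seq_len(max(m$ref_index))),
                                    m$ref_pos)]
    row <- rep("-", model$full_width)
    hit <- schars != "-" & qchars != "-"
    row[col_of_refpos[refpos[hit]]] <- qchars[hit]
    paste(row, collapse = "")
}

#' Predict lambda-max for new sequences
#'
#' Prealigned mode expects sequences already in the training alignment's
#' column space (full width, gaps allowed). Pairwise mode takes ungapped
#' sequences and projects each onto the training columns by global pairwise
#' alignment (BLOSUM62, affine gaps) against the reference row. Either way
#' the sequences are then encoded with the training vocabulary — residues
#' never seen at a column in training (and gaps) encode as all-zero — and
#' scored; unseen residues never raise an error.
#'
#' @param model a \code{SpectralModel} from \code{\link{trainModel}}.
#' @param seqs character vector of sequences (named or not).
#' @param mode \code{"prealigned"} or \code{"map_to_reference_pairwise"}.
#' @param gap_opening,gap_extension affine gap penalties for pairwise mode.
#' @return numeric vector of predicted wavelengths (nm).
#' @export
predictNew <- function(model, seqs,
                       mode = c("prealigned", "map_to_reference_pairwise"),
                       gap_opening = 10, gap_extension = 0.5) {
    mode <- match.arg(mode)
    stopifnot(inherits(model, "SpectralModel"))
    seqs <- as.character(seqs)
    if (mode == "prealigned") {
        if (any(nchar(seqs) != model$full_width))
            stop("prealigned sequences must have the training alignment width (",
                 model$full_width, ")")
        rows <- seqs
    } else {
        if (any(grepl("-", seqs, fixed = TRUE)))
            stop("pairwise mode expects ungapped sequences")
        rows <- vapply(seqs, project_to_columns, character(1), model = model,
                       gap_opening = gap_opening,
                       gap_extension = gap_extension)
    }
    al <- Biostrings::AAStringSet(rows)
    names(al) <- if (!is.null(names(seqs))) names(seqs) else
        paste0("query", seq_along(seqs))
    keep <- match(model$columns, seq_len(model$full_width))
    al_sub <- subsetColumns(al, keep)
    enc <- oneHot(al_sub, vocab = vocabulary(model$encoded))
    as.numeric(model$est$predict(model$fit, featureMatrix(enc)))
}

#' Position-importance report across the top models
#'
#' For each fitted model, per-feature importances are summed within each
#' alignment-column block, scaled so the model's most important column
#' scores exactly 1 (all-zero vectors stay zero), then averaged across the
#' \code{n} models into a "mean relative importance" per position. The
#' report joins reference positions, observed residues and TMD labels from
#' the first model's position map.
#'
#' @param models list of \code{SpectralModel}s (typically the top 3 by CV
#'   rank), all trained on the same alignment; a single model is accepted.
#' @param n number of models to average (default \code{min(3, length)}).
#' @return data.frame, one row per retained column, sorted by decreasing
#'   mean relative importance: \code{column}, \code{ref_pos}, \code{tmd},
#'   \code{residues}, one \code{imp_<estimator>} column per model, and
#'   \code{mean_rel_importance}. The per-model importance metric names are
#'   kept in \code{attr(x, "importance_metrics")}.
#' @export
importanceReport <- function(models, n = NULL) {
    if (inherits(models, "SpectralModel")) models <- list(models)
    if (is.null(n)) n <- min(3L, length(models))
    models <- models[seq_len(min(n, length(models)))]
    ref <- models[[1L]]
    cols <- ref$columns
    per_model <- list(); metrics <- character()
    for (m in models) {
        if (!identical(m$columns, cols))
            stop("models were not trained on the same retained columns")
        imp_f <- tryCatch(m$est$importance(m$fit, m$train_x),
                          error = function(e) NULL)
        if (is.null(imp_f)) {
            warning("estimator '", m$estimator,
                    "' exposes no importances; skipped")
            next
        }
        by_col <- tapply(imp_f, featureTable(m$encoded)$column, sum)
        v <- as.numeric(by_col[as.character(cols)])
        v[is.na(v)] <- 0
        if (max(v) > 0) v <- v / max(v)
        per_model[[m$estimator]] <- v
        metrics[m$estimator] <- m$est$importance_metric
    }
    if (!length(per_model)) stop("no model provided usable importances")
    imp_mat <- do.call(cbind, per_model)
    pm <- ref$pmap@map
    idx <- match(cols, pm$column)
    residues <- vapply(as.character(cols), function(cc)
        paste(vocabulary(ref$encoded)[[cc]], collapse = ","), character(1))
    out <- data.frame(column = cols,
                      ref_pos = pm$ref_pos[idx],
                      tmd = pm$tmd[idx],
                      residues = residues,
                      stringsAsFactors = FALSE)
    colnames(imp_mat) <- paste0("imp_", colnames(imp_mat))
    out <- cbind(out, imp_mat)
    out$mean_rel_importance <- rowMeans(imp_mat)
    out <- out[order(-out$mean_rel_importance, out$column), ]
    rownames(out) <- NULL
    attr(out, "importance_metrics") <- metrics
    out
}
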