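## Dataset-level protocols: exhaustive iterative hold-out, learning curves,
## nonlinear curve selection by AIC, residual breakdowns, and the
## entropy-vs-importance regression.

record_type_tag <- function(meta) {
    tag <- as.character(meta$record_type)
    is_mut <- tag == "mutant"
    n_edits <- rep(NA_integer_, nrow(meta))
    n_edits[is_mut] <- vapply(meta$mutation_notation[is_mut], function(s)
        length(strsplit(s, "_", fixed = TRUE)[[1]]), integer(1))
    tag[is_mut & n_edits == 1L] <- "single-mutant"
    tag[is_mut & n_edits > 1L] <- "multi-mutant"
    tag
}

#' Exhaustive iterative hold-out prediction
#'
#' The target records are shuffled with \code{seed} and partitioned into
#' groups of \code{group_size} (the last group may be smaller). For each
#' group a fresh model is trained on every record \emph{not} in the group
#' — withheld records never appear in training — and the group's phenotypes
#' are predicted. The union of groups covers every target exactly once, so
#' each record receives exactly one out-of-training prediction.
#'
#' @param ds an \code{OpsinSet}.
#' @param al alignment whose rows cover \code{accessions(ds)}.
#' @param group_size records withheld per round (default 25).
#' @param estimator registry name (see \code{\link{defaultEstimators}}).
#' @param seed integer seed for the shuffle and the fits.
#' @param targets optional: character accessions, or a rule list
#'   (\code{list(rule=, gene_family=, predicate=)}) passed to
#'   \code{\link{opsinSubset}}) naming which records to predict; default
#'   all. Non-target records always stay in training.
#' @param outlier_nm residual magnitude beyond which a prediction is
#'   flagged as an outlier (strict \code{>}, default 10 nm).
#' @return a \code{HoldoutResult} data.frame: \code{accession},
#'   \code{known}, \code{predicted}, \code{residual}, \code{type}
#'   (\code{wt}, \code{single-mutant}, \code{multi-mutant},
#'   \code{chimera}), \code{outlier}, \code{group}.
#' @export
iterativeHoldout <- function(ds, al, group_size = 25L, estimator = "gbt",
                             seed = 1L, targets = NULL, outlier_nm = 10) {
    stopifnot(is(ds, "OpsinSet"))
    accs <- accessions(ds)
    if (!all(accs %in% names(al)))
        stop("alignment is missing rows for: ",
             paste(setdiff(accs, names(al)), collapse = ", "))
    target_accs <- if (is.null(targets)) accs
        else if (is.character(targets)) intersect(targets, accs)
        else accessions(do.call(opsinSubset, c(list(ds), targets)))
    if (!length(target_accs)) stop("no target records")
    if (group_size < 1L || group_size > length(target_accs))
        stop("group_size must be in 1..", length(target_accs))
    resolveEstimators(estimator)
    set.seed(seed)
    shuffled <- sample(target_accs)
    groups <- split(shuffled, ceiling(seq_along(shuffled) / group_size))
    lam <- lambdaMax(ds)
    preds <- numeric(0); pred_accs <- character(0); grp_id <- integer(0)
    for (g in seq_along(groups)) {
        held <- groups[[g]]
        train_accs <- setdiff(accs, held)
        if (!length(train_accs))
            stop("a hold-out group leaves no records to train on; ",
                 "reduce group_size or restrict targets")
        model <- trainModel(al[train_accs], lam[train_accs],
                            estimator = estimator, seed = seed)
        yhat <- predictNew(model, as.character(al[held]), mode = "prealigned")
        preds <- c(preds, yhat)
        pred_accs <- c(pred_accs, held)
        grp_id <- c(grp_id, rep(g, length(held)))
    }
    idx <- match(pred_accs, accs)
    res <- data.frame(accession = pred_accs,
                      known = as.numeric(lam[pred_accs]),
                      predicted = preds,
                      residual = preds - as.numeric(lam[pred_accs]),
                      type = record_type_tag(as.data.frame(ds@meta))[idx],
                      group = grp_id, stringsAsFactors = FALSE)
    res$outlier <- abs(res$residual) > outlier_nm
    class(res) <- c("HoldoutResult", "data.frame")
    attr(res, "outlier_nm") <- outlier_nm
    res
}

#' Per-record-type residual summary
#'
#' Summarizes a hold-out run by record type: count, median residual, MAE,
#' and the number of outliers (absolute residual strictly greater than the
#' threshold; a residual of exactly 10 nm is not an outlier).
#'
#' @param hr a \code{HoldoutResult}.
#' @param outlier_nm threshold (default: the one stored on \code{hr}).
#' @return data.frame with one row per record type plus an \code{all} row.
#' @export
residualBreakdown <- function(hr, outlier_nm = NULL) {
    if (is.null(outlier_nm))
        outlier_nm <- attr(hr, "outlier_nm") %||% 10
    one <- function(d, label) data.frame(
        type = label, n = nrow(d),
        median_residual = stats::median(d$residual),
        mae = mean(abs(d$residual)),
        outliers = sum(abs(d$residual) > outlier_nm),
        stringsAsFactors = FALSE)
    parts <- lapply(split(hr, hr$type), function(d) one(d, d$type[1L]))
    out <- rbind(do.call(rbind, parts), one(hr, "all"))
    rownames(out) <- NULL
    out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Learning curve: model performance versus training-set size
#'
#' For each repetition the records are permuted with a seed derived from
#' \code{seed}; nested training sets grow by \code{step} records at a time
#' (the full size is always included), and performance at each size is the
#' mean cross-validated \eqn{R^2} of the chosen estimator on that subset.
#'
#' @param ds an \code{OpsinSet}.
#' @param al alignment covering the dataset.
#' @param step records added per increment; the protocol uses values
#'   between 15 and 50.
#' @param reps number of repetitions (default 3).
#' @param estimator registry name.
#' @param seed integer base seed.
#' @param k CV folds at each size (capped at the subset size).
#' @return data.frame \code{n_train}, \code{r2}, \code{rep}.
#' @export
learningCurve <- function(ds, al, step, reps = 3L, estimator = "gbt",
                          seed = 1L, k = 5L) {
    stopifnot(is(ds, "OpsinSet"), step >= 2L)
    n <- length(ds)
    if (n < step) stop("dataset smaller than one step")
    sizes <- unique(c(seq(step, n, by = step), n))
    lam <- lambdaMax(ds)
    accs <- accessions(ds)
    out <- list()
    for (r in seq_len(reps)) {
        set.seed(seed + 1000L * r)
        perm <- sample(accs)
        for (s in sizes) {
            sub_accs <- perm[seq_len(s)]
            al_sub <- dropInvariantColumns(al[sub_accs])
            enc <- oneHot(al_sub)
            cv <- crossValidate(enc, as.numeric(lam[sub_accs]),
                                estimators = estimator,
                                k = min(k, s), seed = seed + r)
            out[[length(out) + 1L]] <- data.frame(
                n_train = s, r2 = cv$table$r2[1L], rep = r)
        }
    }
    do.call(rbind, out)
}

#' AIC for a least-squares fit
#'
#' \eqn{AIC = n \ln(RSS/n) + 2k} with \code{k} the number of fitted curve
#' parameters; additive constants common to all models are dropped, so
#' values are comparable only within one dataset.
#'
#' @param rss residual sum of squares.
#' @param n number of points.
#' @param k number of parameters.
#' @return numeric AIC.
#' @examples
#' aicLeastSquares(10, 10, 2)  # 10*log(1) + 4 = 4
#' @export
aicLeastSquares <- function(rss, n, k) n * log(rss / n) + 2 * k

curve_candidates <- function() {
    list(
        reciprocal = list(k = 2L, fit = function(x, y) {
            fit <- stats::lm(y ~ I(1 / x))
            list(coef = c(a = unname(stats::coef(fit)[1]),
                          b = unname(stats::coef(fit)[2])),
                 pred = function(x) stats::coef(fit)[1] + stats::coef(fit)[2] / x)
        }),
        logarithmic = list(k = 2L, fit = function(x, y) {
            fit <- stats::lm(y ~ log(x))
            list(coef = c(a = unname(stats::coef(fit)[1]),
                          b = unname(stats::coef(fit)[2])),
                 pred = function(x) stats::coef(fit)[1] + stats::coef(fit)[2] * log(x))
        }),
        quadratic = list(k = 3L, fit = function(x, y) {
            fit <- stats::lm(y ~ x + I(x^2))
            cf <- stats::coef(fit)
            list(coef = c(a = unname(cf[1]), b = unname(cf[2]), c = unname(cf[3])),
                 pred = function(x) cf[1] + cf[2] * x + cf[3] * x^2)
        }),
        power = list(k = 2L, fit = function(x, y) {
            starts <- list(c(a = max(abs(y)), b = 0.1),
                           c(a = stats::median(y), b = 0.5),
                           c(a = stats::median(y), b = -0.5))
            if (all(y > 0)) {
                lf <- stats::lm(log(y) ~ log(x))
                starts <- c(list(c(a = exp(unname(stats::coef(lf)[1])),
                                   b = unname(stats::coef(lf)[2]))), starts)
            }
            nls_multistart(y ~ a * x^b, data.frame(x = x, y = y), starts)
        }),
        exp_rise = list(k = 3L, fit = function(x, y) {
            rng <- max(y) - min(y)
            starts <- lapply(c(0.001, 0.01, 0.1, 1), function(cc)
                c(a = max(y), b = max(rng, 1e-3), c = cc))
            nls_multistart(y ~ a - b * exp(-c * x), data.frame(x = x, y = y),
                           starts, lower = c(-Inf, -Inf, 1e-9))
        }),
        saturating = list(k = 2L, fit = function(x, y) {
            starts <- lapply(stats::quantile(x, c(0.1, 0.5, 0.9)), function(b0)
                c(a = max(y), b = max(as.numeric(b0), 1e-6)))
            nls_multistart(y ~ a * x / (b + x), data.frame(x = x, y = y),
                           starts, lower = c(-Inf, 1e-9))
        }))
}

nls_multistart <- function(formula, data, starts, lower = NULL) {
    best <- NULL; best_rss <- Inf
    for (st in starts) {
        fit <- tryCatch(
            minpack.lm::nlsLM(formula, data = data, start = as.list(st),
                              lower = lower,
                              control = minpack.lm::nls.lm.control(maxiter = 200)),
            error = function(e) NULL)
        if (is.null(fit)) next
        rss <- sum(stats::residuals(fit)^2)
        if (rss < best_rss) { best <- fit; best_rss <- rss }
    }
    if (is.null(best)) stop("all starts failed")
    cf <- stats::coef(best)
    list(coef = cf, pred = function(x)
        stats::predict(best, newdata = data.frame(x = x)))
}

#' Fit and rank nonlinear performance curves by AIC
#'
#' Least-squares fits of six candidate forms to (size, performance) points
#' — reciprocal \eqn{y = a + b/x}, exponential rise \eqn{a - b e^{-cx}},
#' logarithmic \eqn{a + b\ln x}, power \eqn{a x^b}, saturating
#' \eqn{ax/(b+x)} and quadratic — ranked by
#' \code{\link{aicLeastSquares}} (ascending; ties broken by fewer
#' parameters). Nonlinear candidates use Levenberg-Marquardt with multiple
#' starts; a candidate whose fit fails is flagged and the rest returned.
#'
#' @param points data.frame with columns \code{x} and \code{y} (e.g.
#'   \code{n_train} and \code{r2} from \code{\link{learningCurve}}).
#' @param candidates names of candidates to fit (default all six).
#' @return data.frame \code{model}, \code{k}, \code{rss}, \code{aic},
#'   \code{ok}, \code{rank}, sorted by AIC; fitted coefficient vectors in
#'   \code{attr(x, "coefficients")}.
#' @export
fitCurves <- function(points, candidates = names(curve_candidates())) {
    x <- as.numeric(points$x); y <- as.numeric(points$y)
    cands <- curve_candidates()[candidates]
    n <- length(x)
    if (n < min(vapply(cands, `[[`, integer(1), "k")))
        stop("fewer points than parameters for every candidate")
    rows <- list(); coefs <- list()
    for (nm in names(cands)) {
        cand <- cands[[nm]]
        res <- tryCatch(cand$fit(x, y), error = function(e) NULL)
        if (is.null(res) || n < cand$k) {
            rows[[nm]] <- data.frame(model = nm, k = cand$k, rss = NA,
                                     aic = NA, ok = FALSE)
            next
        }
        rss <- sum((y - res$pred(x))^2)
        rows[[nm]] <- data.frame(model = nm, k = cand$k, rss = rss,
                                 aic = aicLeastSquares(rss, n, cand$k),
                                 ok = TRUE)
        coefs[[nm]] <- res$coef
    }
    out <- do.call(rbind, rows)
    out <- out[order(!out$ok, out$aic, out$k, out$model), ]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    attr(out, "coefficients") <- coefs
    out
}

#' Regression of position importance on column entropy
#'
#' Ordinary least squares of mean relative importance on relative Shannon
#' entropy across alignment columns (joined on the original column index).
#' A low \eqn{R^2} says the models are not simply ranking variable sites.
#'
#' @param profiles output of \code{\link{columnProfiles}} on the training
#'   alignment.
#' @param imp output of \code{\link{importanceReport}}.
#' @return the regression \eqn{R^2} (numeric scalar) with the number of
#'   joined columns in \code{attr(x, "n")}.
#' @export
entropyImportanceRegression <- function(profiles, imp) {
    j <- merge(profiles[, c("column", "rel_entropy")],
               imp[, c("column", "mean_rel_importance")], by = "column")
    j <- j[stats::complete.cases(j), ]
    if (nrow(j) < 3L) stop("need at least 3 joined columns")
    fit <- stats::lm(mean_rel_importance ~ rel_entropy, data = j)
    r2 <- summary(fit)$r.squared
    attr(r2, "n") <- nrow(j)
    r2
}
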