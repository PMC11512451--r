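## Intragenic epistasis: decomposable multimutants, additive expectations,
## the leave-epistatic-out protocol, and paired nonparametric testing.

#' Additive expectation for a multimutant phenotype
#'
#' The epistasis-free additive mutation value: the phenotype expected if
#' each component mutation contributed its single-mutant shift from wild
#' type independently, \eqn{\lambda_{wt} + \sum_i (\lambda_i -
#' \lambda_{wt})}. An empty component list returns the wild-type value.
#'
#' @param wt_lambda wild-type phenotype (nm).
#' @param single_lambdas numeric vector of single-mutant phenotypes (nm);
#'   may be empty.
#' @return expected multimutant phenotype (nm).
#' @examples
#' eamv(500, c(514, 502))  # 500 + 14 + 2 = 516
#' @export
eamv <- function(wt_lambda, single_lambdas = numeric()) {
    wt_lambda + sum(single_lambdas - wt_lambda)
}

#' Classify a multimutant as epistatic
#'
#' A multimutant is epistatic when its observed phenotype deviates from the
#' additive expectation by strictly more than \code{threshold} (default
#' 1 nm); a deviation of exactly the threshold is not epistatic. Symmetric
#' in the sign of the deviation.
#'
#' @param actual observed multimutant phenotype (nm).
#' @param expected additive expectation from \code{\link{eamv}} (nm).
#' @param threshold nm, strictly positive (default 1).
#' @return logical.
#' @export
classifyEpistatic <- function(actual, expected, threshold = 1) {
    stopifnot(threshold > 0)
    abs(actual - expected) > threshold
}

#' Find multimutants decomposable into measured single mutants
#'
#' Scans the mutant records for multimutants (two or more edits) whose
#' wild-type parent and \emph{every} single-component mutant are also in
#' the dataset, matched by identical parent accession and single-edit
#' notation — cross-background singles are not accepted. Each hit becomes a
#' case with its additive expectation, deviation, and epistasis flag.
#' Records with unparseable notation are skipped with a warning.
#'
#' @param ds an \code{OpsinSet}.
#' @param threshold epistasis threshold in nm (default 1, strict).
#' @return data.frame, one row per case: \code{multi_accession},
#'   \code{parent_accession}, \code{notation}, \code{n_edits},
#'   \code{single_accessions} (comma-joined), \code{wt_lambda},
#'   \code{multi_lambda}, \code{eamv}, \code{deviation},
#'   \code{is_epistatic}.
#' @export
findEpistasisCases <- function(ds, threshold = 1) {
    stopifnot(is(ds, "OpsinSet"))
    m <- as.data.frame(ds@meta)
    lam <- lambdaMax(ds)
    muts <- m[m$record_type == "mutant", , drop = FALSE]
    specs <- vector("list", nrow(muts))
    for (i in seq_len(nrow(muts))) {
        specs[[i]] <- tryCatch(parseMutations(muts$mutation_notation[i]),
                               error = function(e) {
            warning("skipping ", muts$accession[i],
                    ": unparseable notation (", conditionMessage(e), ")")
            NULL
        })
    }
    ok <- !vapply(specs, is.null, logical(1))
    muts <- muts[ok, , drop = FALSE]; specs <- specs[ok]
    n_edits <- vapply(specs, function(s) length(s@pos), integer(1))
    ## index single mutants by (parent, token)
    singles <- which(n_edits == 1L)
    single_key <- paste(muts$parent_accession[singles],
                        vapply(specs[singles], notation, character(1)))
    rows <- list()
    for (i in which(n_edits >= 2L)) {
        parent <- muts$parent_accession[i]
        if (!parent %in% m$accession) next
        tokens <- paste0(specs[[i]]@wt, specs[[i]]@pos, specs[[i]]@new)
        hit <- match(paste(parent, tokens), single_key)
        if (anyNA(hit)) next
        single_accs <- muts$accession[singles[hit]]
        wt_l <- as.numeric(lam[parent])
        e <- eamv(wt_l, as.numeric(lam[single_accs]))
        multi_l <- as.numeric(lam[muts$accession[i]])
        rows[[length(rows) + 1L]] <- data.frame(
            multi_accession = muts$accession[i],
            parent_accession = parent,
            notation = muts$mutation_notation[i],
            n_edits = length(tokens),
            single_accessions = paste(single_accs, collapse = ","),
            wt_lambda = wt_l, multi_lambda = multi_l, eamv = e,
            deviation = abs(multi_l - e),
            is_epistatic = classifyEpistatic(multi_l, e, threshold),
            stringsAsFactors = FALSE)
    }
    if (!length(rows))
        return(data.frame(multi_accession = character(),
                          parent_accession = character(),
                          notation = character(), n_edits = integer(),
                          single_accessions = character(),
                          wt_lambda = numeric(), multi_lambda = numeric(),
                          eamv = numeric(), deviation = numeric(),
                          is_epistatic = logical(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Leave-epistatic-out experiment
#'
#' Identifies the epistatic multimutants (deviation from additive
#' expectation strictly greater than \code{threshold}), removes \emph{all}
#' of them from training — single mutants stay — and predicts their
#' phenotypes three ways: (a) a model trained on the reduced dataset
#' ("minusepi"), (b) a model trained on wild types only, and (c) the
#' additive-expectation (EAMV) baseline computed from the measured
#' singles. Squared errors are paired by multimutant for downstream
#' \code{\link{wilcoxonSignedRank}} testing.
#'
#' @param ds an \code{OpsinSet} containing at least one epistatic case.
#' @param al alignment covering the dataset.
#' @param estimator registry name.
#' @param seed integer seed.
#' @param threshold epistasis threshold in nm (default 1).
#' @return list with \code{cases} (the epistatic case table),
#'   \code{predictions} (per multimutant: known, \code{pred_minusepi},
#'   \code{pred_wt_only}, \code{pred_eamv} and squared errors),
#'   \code{metrics} (per-method \code{computeMetrics}), and
#'   \code{training_accessions} for audit.
#' @export
leaveEpistaticOut <- function(ds, al, estimator = "gbt", seed = 1L,
                              threshold = 1) {
    cases <- findEpistasisCases(ds, threshold = threshold)
    epi <- cases[cases$is_epistatic, , drop = FALSE]
    if (!nrow(epi)) stop("no epistatic cases in the dataset")
    lam <- lambdaMax(ds)
    accs <- accessions(ds)
    train_a <- setdiff(accs, epi$multi_accession)
    wt_only <- accessions(opsinSubset(ds, rule = "wild_type_only"))
    model_a <- trainModel(al[train_a], lam[train_a], estimator = estimator,
                          seed = seed)
    model_b <- trainModel(al[wt_only], lam[wt_only], estimator = estimator,
                          seed = seed)
    rows_epi <- as.character(al[epi$multi_accession])
    known <- as.numeric(lam[epi$multi_accession])
    pred_a <- predictNew(model_a, rows_epi, mode = "prealigned")
    pred_b <- predictNew(model_b, rows_epi, mode = "prealigned")
    pred_c <- epi$eamv
    preds <- data.frame(multi_accession = epi$multi_accession,
                        known = known,
                        pred_minusepi = pred_a, pred_wt_only = pred_b,
                        pred_eamv = pred_c,
                        se_minusepi = (pred_a - known)^2,
                        se_wt_only = (pred_b - known)^2,
                        se_eamv = (pred_c - known)^2,
                        stringsAsFactors = FALSE)
    list(cases = epi,
         predictions = preds,
         metrics = list(
             minusepi = suppressWarnings(computeMetrics(known, pred_a)),
             wt_only = suppressWarnings(computeMetrics(known, pred_b)),
             eamv = suppressWarnings(computeMetrics(known, pred_c))),
         training_accessions = list(minusepi = train_a, wt_only = wt_only))
}

#' Wilcoxon signed-rank test for paired differences
#'
#' Zero differences are dropped; absolute differences are ranked with
#' midranks for ties and \eqn{W^+} is the sum of ranks of the positive
#' differences. For \code{n_effective <= exact_max} (default 25) the
#' two-sided p-value is exact, by enumeration of all \eqn{2^n} sign
#' assignments of the ranks (ties handled correctly because the observed
#' midranks are enumerated). Above the crossover a normal approximation
#' with tie-corrected variance and a 0.5 continuity correction is used.
#'
#' @param d numeric vector of paired differences.
#' @param exact_max largest \code{n_effective} for which enumeration is
#'   used (default 25).
#' @param m optional number of tests for a Bonferroni-adjusted p.
#' @return list \code{statistic} (\eqn{W^+}), \code{n_effective},
#'   \code{p_two_sided}, \code{method} (\code{"exact"} or
#'   \code{"normal-approx"}), and \code{p_adjusted} when \code{m} is given.
#' @examples
#' wilcoxonSignedRank(c(1, 2, 3))  # W+ = 6, exact p = 0.25
#' @export
wilcoxonSignedRank <- function(d, exact_max = 25L, m = NULL) {
    d <- d[d != 0]
    n <- length(d)
    if (n < 1L) stop("all differences are zero: test degenerate")
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    if (n <= exact_max) {
        method <- "exact"
        ## distribution of W+ over all 2^n equiprobable sign assignments
        ## of the observed (mid)ranks, via the generating polynomial
        ## convolution on a 0.5-grid (midranks are multiples of 0.5)
        grid <- round(r * 2)
        tot <- sum(grid)
        counts <- numeric(tot + 1L)  # counts[v+1] = #assignments with 2*W+ = v
        counts[1L] <- 1
        for (g in grid) {
            shifted <- c(rep(0, g), counts[seq_len(tot + 1L - g)])
            counts <- counts + shifted
        }
        probs <- counts / 2^n
        w2 <- round(2 * W)
        mu2 <- tot / 2
        dev <- abs(w2 - mu2)
        extreme <- abs(seq(0, tot) - mu2) >= dev - 1e-9
        p <- min(1, sum(probs[extreme]))
    } else {
        method <- "normal-approx"
        mu <- n * (n + 1) / 4
        ties <- table(r)
        sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
            sum(ties^3 - ties) / 48
        z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
        p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    out <- list(statistic = W, n_effective = n, p_two_sided = p,
                method = method)
    if (!is.null(m)) out$p_adjusted <- bonferroni(p, m)
    out
}

#' Bonferroni correction
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param m number of tests, at least \code{length(p)}.
#' @return adjusted p-values \code{pmin(1, m * p)}.
#' @export
bonferroni <- function(p, m = length(p)) {
    if (any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
    if (m < length(p)) stop("m must be >= length(p)")
    pmin(1, m * p)
}
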