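## Brownian-motion phylogenetic imputation of missing tip phenotypes and
## the machine-learning-versus-imputation comparison harness.

#' Brownian-motion covariance matrix of a rooted tree
#'
#' Under Brownian motion the covariance of two tips equals the branch
#' length shared by their root-to-tip paths; the diagonal holds each tip's
#' root-to-tip distance. Computed by an explicit edge traversal
#' accumulating each edge's length onto all tip pairs descending from it.
#'
#' @param tree rooted \code{\link[ape]{phylo}} with finite, non-negative
#'   branch lengths.
#' @return symmetric positive semidefinite matrix (tips x tips, tip-label
#'   dimnames), units of summed branch length.
#' @export
bmVcv <- function(tree) {
    stopifnot(inherits(tree, "phylo"))
    ## a single-internal-node (star) tree is rooted at its hub even though
    ## its basal node is a polytomy
    if (!ape::is.rooted(tree) && tree$Nnode > 1L)
        stop("tree must be rooted")
    if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length)) ||
        any(tree$edge.length < 0))
        stop("tree needs finite, non-negative branch lengths")
    n <- length(tree$tip.label)
    C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
    ## tips descending from each node
    desc <- vector("list", n + tree$Nnode)
    for (i in seq_len(n)) desc[[i]] <- i
    ## postorder guarantees children are resolved before parents
    for (e in ape::postorder(tree)) {
        par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
        desc[[par]] <- c(desc[[par]], desc[[child]])
        tips <- desc[[child]]
        C[tips, tips] <- C[tips, tips] + tree$edge.length[e]
    }
    C
}

#' Impute missing tip phenotypes under Brownian motion
#'
#' The standard conditional-normal tip imputation: with observed block
#' covariance \eqn{C_{oo}}, the ancestral (root) state is the GLS mean
#' \eqn{\hat\mu = (1' C_{oo}^{-1} y)/(1' C_{oo}^{-1} 1)}, the BM rate
#' \eqn{\hat\sigma^2} is its maximum-likelihood estimate on the observed
#' tips, each missing tip's imputed mean is
#' \eqn{\hat\mu + C_{mo} C_{oo}^{-1} (y - \hat\mu 1)}, and its conditional
#' variance is \eqn{\hat\sigma^2 (C_{mm} - C_{mo} C_{oo}^{-1}
#' C_{om})_{ii}}. Near-singular \eqn{C_{oo}} (e.g. duplicate zero-length
#' tips) is handled by adding a ridge of \code{ridge_eps} times the tree
#' height to the diagonal, with a warning.
#'
#' @param tree rooted \code{phylo}; tip labels must cover
#'   \code{names(observed)}.
#' @param observed named numeric vector of known tip phenotypes (nm).
#' @param missing tip labels to impute; default: all tips not in
#'   \code{observed}.
#' @param ridge_eps relative ridge for singular observed covariance
#'   (default 1e-8 of tree height).
#' @return list with \code{estimates} (data.frame \code{tip},
#'   \code{imputed}, \code{variance}), \code{mu} (GLS root estimate),
#'   \code{sigma2} (ML BM rate). Zero missing tips gives an empty
#'   \code{estimates} table.
#' @export
imputeBM <- function(tree, observed, missing = NULL, ridge_eps = 1e-8) {
    stopifnot(inherits(tree, "phylo"))
    tips <- tree$tip.label
    if (is.null(names(observed)) || !all(names(observed) %in% tips))
        stop("observed must be named by tip labels present in the tree")
    if (is.null(missing)) missing <- setdiff(tips, names(observed))
    if (!all(missing %in% tips))
        stop("unknown tips in 'missing': ",
             paste(setdiff(missing, tips), collapse = ", "))
    if (!length(observed)) stop("at least one observed tip is required")
    C <- bmVcv(tree)
    obs <- names(observed)
    Coo <- C[obs, obs, drop = FALSE]
    height <- max(diag(C))
    ko <- tryCatch(chol(Coo), error = function(e) NULL)
    if (is.null(ko) || kappa(Coo) > 1e12) {
        warning("observed covariance is near singular; adding ridge of ",
                format(ridge_eps * height))
        Coo <- Coo + diag(ridge_eps * height, nrow(Coo))
    }
    y <- as.numeric(observed)
    Cinv1 <- solve(Coo, rep(1, length(y)))
    Cinvy <- solve(Coo, y)
    mu <- sum(Cinvy) / sum(Cinv1)
    resid <- y - mu
    sigma2 <- as.numeric(crossprod(resid, solve(Coo, resid))) / length(y)
    if (length(missing)) {
        Cmo <- C[missing, obs, drop = FALSE]
        Cmm <- C[missing, missing, drop = FALSE]
        w <- t(solve(Coo, t(Cmo)))
        imputed <- as.numeric(mu + w %*% resid)
        cond_var <- sigma2 * pmax(diag(Cmm - w %*% t(Cmo)), 0)
        est <- data.frame(tip = missing, imputed = imputed,
                          variance = cond_var, stringsAsFactors = FALSE)
    } else {
        est <- data.frame(tip = character(), imputed = numeric(),
                          variance = numeric(), stringsAsFactors = FALSE)
    }
    list(estimates = est, mu = mu, sigma2 = sigma2)
}

#' Compare sequence-based prediction with phylogenetic imputation
#'
#' One seeded random hold-out: \code{holdout_n} records are withheld; both
#' methods then predict the same withheld phenotypes from the same
#' remaining data — the regressor from the retained sequences, Brownian
#' imputation from the retained tips on the tree. Metrics are paired per
#' withheld record.
#'
#' @param ds an \code{OpsinSet}.
#' @param al alignment covering the dataset.
#' @param tree rooted \code{phylo}; every tip must be a dataset accession.
#' @param holdout_n number withheld (the protocol's 50, or 15 for small
#'   subsets); must be smaller than the number of tips.
#' @param estimator registry name for the sequence model.
#' @param seed integer seed.
#' @return list with \code{holdout} (data.frame \code{accession},
#'   \code{known}, \code{pred_ml}, \code{pred_imputation}),
#'   \code{metrics} (per-method), and \code{seed}.
#' @export
compareMLImputation <- function(ds, al, tree, holdout_n, estimator = "gbt",
                                seed = 1L) {
    stopifnot(is(ds, "OpsinSet"), inherits(tree, "phylo"))
    accs <- accessions(ds)
    bad <- setdiff(tree$tip.label, accs)
    if (length(bad))
        stop("tree tips absent from the dataset: ",
             paste(bad, collapse = ", "))
    tips <- tree$tip.label
    if (holdout_n >= length(tips)) stop("holdout_n must be < number of tips")
    lam <- lambdaMax(ds)
    set.seed(seed)
    held <- sample(tips, holdout_n)
    train <- setdiff(accs, held)
    model <- trainModel(al[train], lam[train], estimator = estimator,
                        seed = seed)
    pred_ml <- predictNew(model, as.character(al[held]), mode = "prealigned")
    imp <- imputeBM(tree, lam[setdiff(tips, held)], missing = held)
    pred_imp <- imp$estimates$imputed[match(held, imp$estimates$tip)]
    known <- as.numeric(lam[held])
    list(holdout = data.frame(accession = held, known = known,
                              pred_ml = pred_ml,
                              pred_imputation = pred_imp,
                              stringsAsFactors = FALSE),
         metrics = list(
             ml = suppressWarnings(computeMetrics(known, pred_ml)),
             imputation = suppressWarnings(computeMetrics(known, pred_imp))),
         seed = seed)
}
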