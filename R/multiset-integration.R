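# Two-stage Elastic Net -> multi-set CCA pipeline linking connectome edges,
# behavioral outcomes and risk traits, with bootstrap/permutation inference
# and subnetwork back-projection.

#' Vectorize connectomes into an edge feature matrix
#'
#' Stacks the upper-triangle (i < j, row-major) edges of each subject's
#' symmetric adjacency matrix, applies `log(1 + count)` and z-scores each
#' edge column. Zero-variance columns are dropped and reported.
#'
#' @param connectomes named list of square labeled symmetric matrices
#'   sharing one region label set.
#' @return list with `X` (subjects x edges, standardized), `edge_index`
#'   (data frame `i`, `j`, `region_i`, `region_j` matching the columns of
#'   `X`), `transform_tag` and `dropped` (indices of constant edges).
#' @export
vectorize_connectomes <- function(connectomes) {
  labels <- rownames(connectomes[[1]])
  for (k in seq_along(connectomes)) {
    m <- connectomes[[k]]
    if (!identical(rownames(m), labels) || !identical(colnames(m), labels))
      stop_data("connectome ", k, " has mismatched region labels")
    if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE)))
      stop_data("connectome ", k, " is not symmetric")
    if (any(m < 0)) stop_data("connectome ", k, " has negative counts")
  }
  p <- length(labels)
  pairs <- upper_tri_pairs(p)
  X <- t(vapply(connectomes, function(m) m[pairs], numeric(nrow(pairs))))
  rownames(X) <- names(connectomes)
  X <- log1p(X)
  sds <- apply(X, 2, sd)
  dropped <- which(sds == 0)
  edge_index <- data.frame(i = pairs[, "i"], j = pairs[, "j"],
                           region_i = labels[pairs[, "i"]],
                           region_j = labels[pairs[, "j"]],
                           stringsAsFactors = FALSE)
  if (length(dropped)) {
    X <- X[, -dropped, drop = FALSE]
    edge_index <- edge_index[-dropped, , drop = FALSE]
    message(length(dropped), " zero-variance edge column(s) dropped")
  }
  X <- scale(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  list(X = X, edge_index = edge_index, transform_tag = "log1p_zscore",
       dropped = dropped)
}

#' Elastic Net loss
#'
#' `(1/2n) ||Y - X beta||^2 + lambda (alpha ||beta||_1 +
#' ((1 - alpha)/2) ||beta||^2)`, the objective minimized by the
#' coordinate-descent fit.
#'
#' @param beta coefficient vector.
#' @param X predictor matrix (subjects x features).
#' @param Y outcome vector.
#' @param lambda nonnegative penalty weight.
#' @param alpha L1/L2 mixing weight in \[0, 1\].
#' @return the loss value.
#' @export
elastic_net_loss <- function(beta, X, Y, lambda, alpha = 0.5) {
  if (lambda < 0) stop_data("lambda must be nonnegative")
  if (alpha < 0 || alpha > 1) stop_data("alpha must lie in [0, 1]")
  n <- nrow(X)
  r <- Y - X %*% beta
  sum(r^2) / (2 * n) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}

#' Elastic Net coefficients at a fixed penalty
#'
#' Cyclic coordinate descent on [elastic_net_loss()] exactly as stated (no
#' intercept, no internal response rescaling), with soft-threshold updates,
#' run to a tight convergence tolerance.
#'
#' @inheritParams elastic_net_loss
#' @param y outcome vector.
#' @param tol convergence tolerance on the coefficient change.
#' @param max_iter sweep cap.
#' @return coefficient vector.
#' @export
elastic_net_coef <- function(X, y, lambda, alpha = 0.5, tol = 1e-12,
                             max_iter = 1e5) {
  if (lambda < 0) stop_data("lambda must be nonnegative")
  n <- nrow(X)
  p <- ncol(X)
  b <- numeric(p)
  xs <- colSums(X^2) / n
  r <- as.numeric(y)
  soft <- function(z, g) sign(z) * max(abs(z) - g, 0)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      rho <- sum(X[, j] * r) / n + xs[j] * b[j]
      bj <- soft(rho, lambda * alpha) / (xs[j] + lambda * (1 - alpha))
      if (bj != b[j]) {
        r <- r - X[, j] * (bj - b[j])
        delta <- max(delta, abs(bj - b[j]))
        b[j] <- bj
      }
    }
    if (delta < tol) break
  }
  b
}

#' Cross-validated Elastic Net feature selection
#'
#' Per outcome column, fits the coordinate-descent Elastic Net path and
#' selects the penalty minimizing mean cross-validated MSE; the selected
#' feature set is the union over outcomes of edges with nonzero
#' coefficients at the optimum. Fold assignment is seeded and returned.
#'
#' @param X standardized feature matrix (subjects x features).
#' @param Y outcome matrix or vector (columns standardized internally).
#' @param alpha L1/L2 mixing weight (default 0.5).
#' @param n_folds number of CV folds (default 10).
#' @param lambda optional penalty grid (default glmnet's path).
#' @param seed seed for fold assignment.
#' @return list with `beta` (features x outcomes at the optimum),
#'   `selected` (sorted union of nonzero feature indices), `lambda_min`
#'   (per outcome), `foldid`.
#' @export
fit_elastic_net <- function(X, Y, alpha = 0.5, n_folds = 10, lambda = NULL,
                            seed = 1L) {
  Y <- as.matrix(Y)
  if (nrow(X) < 2 * n_folds)
    stop_data("need at least 2 subjects per fold")
  if (any(apply(Y, 2, sd) == 0))
    stop_data("degenerate (constant) outcome column")
  foldid <- withr::with_seed(seed,
    sample(rep(seq_len(n_folds), length.out = nrow(X))))
  beta <- matrix(0, ncol(X), ncol(Y),
                 dimnames = list(colnames(X), colnames(Y)))
  lambda_min <- numeric(ncol(Y))
  for (j in seq_len(ncol(Y))) {
    y <- as.numeric(scale(Y[, j]))
    cv <- glmnet::cv.glmnet(X, y, alpha = alpha, foldid = foldid,
                            lambda = lambda, intercept = FALSE,
                            standardize = FALSE)
    lambda_min[j] <- cv$lambda.min
    beta[, j] <- as.numeric(coef(cv, s = "lambda.min"))[-1]
  }
  selected <- sort(unique(which(rowSums(abs(beta)) > 0)))
  list(beta = beta, selected = selected, lambda_min = lambda_min,
       foldid = foldid)
}

#' Encode categorical risk traits for multivariate modeling
#'
#' One-hot encoding with sum-to-zero contrasts, then column
#' standardization.
#'
#' @param traits trait table (factor columns used as-is).
#' @param columns trait columns to encode.
#' @return numeric subjects x contrasts matrix.
#' @export
encode_traits <- function(traits,
                          columns = c("apoe", "diet", "sex", "age_group",
                                      "nos2")) {
  df <- traits[, columns, drop = FALSE]
  for (nm in columns) if (!is.numeric(df[[nm]])) df[[nm]] <- factor(df[[nm]])
  contr <- lapply(df, function(x) if (is.factor(x)) "contr.sum" else NULL)
  contr <- contr[!vapply(contr, is.null, logical(1))]
  mm <- model.matrix(~ ., data = df, contrasts.arg = contr)[, -1, drop = FALSE]
  out <- scale(mm)
  rownames(out) <- traits$subject_id
  out
}

#' Multi-set canonical correlation analysis (SUMCOR, Horst updates)
#'
#' Maximizes the summed pairwise correlation
#' `sum_{i<j} cor(X_i w_i, X_j w_j)` under unit-sample-variance constraints
#' on each canonical variate, by alternating Horst updates. Columns of each
#' domain are z-scored on entry. Initialization is deterministic (leading
#' right singular vector per domain) and the global sign is fixed so the
#' largest-magnitude weight of the first domain is positive. The summed
#' correlation is non-decreasing across iterations; non-convergence is
#' flagged, not raised.
#'
#' @param domains list of >= 2 numeric matrices with equal row counts.
#' @param tol convergence tolerance on the sumcor change (default 1e-8).
#' @param max_iter iteration cap (default 500).
#' @param ridge relative ridge added to each within-domain covariance for
#'   numerical invertibility (scaled by the mean covariance diagonal).
#' @return object of class `olfnet_mcca`: `weights` (per-domain vectors),
#'   `variates` (subjects x domains), `pairwise_corr`, `sumcor`,
#'   `converged`, `n_iter`, `trace` (sumcor per iteration).
#' @export
fit_mcca <- function(domains, tol = 1e-8, max_iter = 500, ridge = 1e-8) {
  m <- length(domains)
  if (m < 2) stop_data("need at least 2 domains")
  n <- nrow(domains[[1]])
  if (any(vapply(domains, nrow, 0L) != n))
    stop_data("domains have unequal subject counts")
  Xs <- lapply(domains, function(X) {
    X <- as.matrix(X)
    s <- apply(X, 2, sd)
    if (any(s == 0)) stop_data("zero-variance column in a domain")
    scale(X)
  })
  covs <- lapply(Xs, function(X) {
    S <- crossprod(X) / (n - 1)
    S + diag(ridge * mean(diag(S)), ncol(S))
  })
  # Deterministic init: leading right singular vector per domain.
  W <- lapply(Xs, function(X) svd(X, nu = 0, nv = 1)$v[, 1])
  normalize <- function(w, S) {
    v <- sqrt(drop(crossprod(w, S %*% w)))
    if (v == 0) stop_data("degenerate canonical weight")
    w / v
  }
  W <- Map(normalize, W, covs)
  Z <- mapply(function(X, w) drop(X %*% w), Xs, W)
  sumcor_of <- function(Z) {
    C <- cor(Z)
    sum(C[upper.tri(C)])
  }
  sc <- sumcor_of(Z)
  trace <- sc
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    for (k in seq_len(m)) {
      s <- rowSums(Z[, -k, drop = FALSE])
      w <- solve(covs[[k]], crossprod(Xs[[k]], s) / (n - 1))
      W[[k]] <- normalize(drop(w), covs[[k]])
      Z[, k] <- Xs[[k]] %*% W[[k]]
    }
    sc_new <- sumcor_of(Z)
    if (sc_new < sc - 1e-10)
      warning("sumcor decreased by ", format(sc - sc_new), " at iteration ",
              iter)
    trace <- c(trace, sc_new)
    if (abs(sc_new - sc) < tol) {
      sc <- sc_new
      converged <- TRUE
      break
    }
    sc <- sc_new
  }
  # Global sign convention: flipping every domain together leaves all
  # pairwise correlations unchanged.
  if (W[[1]][which.max(abs(W[[1]]))] < 0) {
    W <- lapply(W, `-`)
    Z <- -Z
  }
  C <- cor(Z)
  structure(list(weights = W, variates = Z, pairwise_corr = C,
                 sumcor = sum(C[upper.tri(C)]), converged = converged,
                 n_iter = iter, trace = trace),
            class = "olfnet_mcca")
}

#' @export
print.olfnet_mcca <- function(x, ...) {
  cat("SUMCOR MCCA:", length(x$weights), "domains, sumcor =",
      format(x$sumcor, digits = 6),
      if (x$converged) sprintf("(converged in %d iterations)", x$n_iter)
      else sprintf("(NOT converged after %d iterations)", x$n_iter), "\n")
  invisible(x)
}

#' Bootstrap and permutation inference for the summed canonical correlation
#'
#' Bootstrap: subjects resampled with replacement jointly across domains,
#' MCCA refit on the fixed feature set, sumcor collected; the 95% CI is the
#' percentile interval. Permutation: the designated domain's rows are
#' shuffled, breaking all its pairwise couplings;
#' `p = (1 + #\{perm >= observed\}) / (P + 1)`.
#'
#' @param domains list of domain matrices (post feature selection).
#' @param B bootstrap draws (default 1000).
#' @param P permutations (default 10000).
#' @param seed RNG seed.
#' @param permute_domain index of the domain whose rows are shuffled
#'   (default 2, the behavior domain in the standard ordering).
#' @param conf confidence level.
#' @param ... passed to [fit_mcca()].
#' @return list: `sumcor_observed`, `bootstrap_draws`, `ci95`,
#'   `permutation_draws`, `permutation_p`.
#' @export
resample_sumcor <- function(domains, B = 1000, P = 10000, seed = 1L,
                            permute_domain = 2L, conf = 0.95, ...) {
  if (B < 100) warning("fewer than 100 bootstrap draws; CI will be crude")
  obs <- fit_mcca(domains, ...)$sumcor
  n <- nrow(domains[[1]])
  safe_sumcor <- function(ds) {
    out <- try(suppressWarnings(fit_mcca(ds, ...)$sumcor), silent = TRUE)
    if (inherits(out, "try-error")) NA_real_ else out
  }
  boot <- withr::with_seed(child_seed(seed, 1L), vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    safe_sumcor(lapply(domains, function(X) X[idx, , drop = FALSE]))
  }, numeric(1)))
  a <- (1 - conf) / 2
  ci <- quantile(boot, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  perm <- withr::with_seed(child_seed(seed, 2L), vapply(seq_len(P), function(p) {
    ds <- domains
    ds[[permute_domain]] <-
      ds[[permute_domain]][sample.int(n), , drop = FALSE]
    safe_sumcor(ds)
  }, numeric(1)))
  p_val <- (1 + sum(perm >= obs, na.rm = TRUE)) / (P + 1)
  list(sumcor_observed = obs, bootstrap_draws = boot, ci95 = ci,
       permutation_draws = perm, permutation_p = p_val)
}

#' Back-project connectome-domain weights and threshold the subnetwork
#'
#' Maps the connectome-domain canonical weights back to region pairs,
#' zeroes entries below the MCCA sparsity tolerance, and retains edges with
#' `|weight| >= threshold`. Weights are used on the canonical-constraint
#' scale by default (`normalize = "none"`); unit-L2 or max-|w| rescaling is
#' available. Records the three stage counts: Elastic-Net-selected,
#' MCCA-nonzero, post-threshold.
#'
#' @param model an [fit_mcca()] result.
#' @param edge_index edge index data frame restricted to the selected
#'   features (rows match the connectome-domain columns).
#' @param threshold final weight cutoff (default 0.05).
#' @param domain index of the connectome domain in the model (default 1).
#' @param zero_tol weight magnitude below which an edge counts as zeroed by
#'   MCCA (default 1e-3).
#' @param normalize optional rescaling of the weight vector before
#'   thresholding: `"none"` (default), `"l2"` or `"max"`.
#' @return list: `retained_edges` (data frame `region_a`, `region_b`,
#'   `weight`, sorted by |weight| descending), `stage_counts`
#'   (`n_after_en`, `n_after_mcca`, `n_after_threshold`),
#'   `weight_threshold`.
#' @export
backproject_and_threshold <- function(model, edge_index, threshold = 0.05,
                                      domain = 1L, zero_tol = 1e-3,
                                      normalize = c("none", "l2", "max")) {
  normalize <- match.arg(normalize)
  w <- model$weights[[domain]]
  if (length(w) != nrow(edge_index))
    stop_data("edge_index rows (", nrow(edge_index),
              ") do not match connectome-domain weights (", length(w), ")")
  w <- switch(normalize, none = w, l2 = w / sqrt(sum(w^2)),
              max = w / max(abs(w)))
  nonzero <- abs(w) > zero_tol
  keep <- abs(w) >= threshold & nonzero
  retained <- data.frame(region_a = edge_index$region_i[keep],
                         region_b = edge_index$region_j[keep],
                         weight = w[keep], stringsAsFactors = FALSE)
  retained <- retained[order(-abs(retained$weight), retained$region_a,
                             retained$region_b), , drop = FALSE]
  rownames(retained) <- NULL
  list(retained_edges = retained,
       stage_counts = c(n_after_en = length(w),
                        n_after_mcca = sum(nonzero),
                        n_after_threshold = sum(keep)),
       weight_threshold = threshold)
}

#' Run the full Elastic Net + MCCA integration
#'
#' Vectorizes connectomes, selects edges by cross-validated Elastic Net
#' regression of the edge matrix on the behavioral outcomes, fits SUMCOR
#' MCCA over (selected edges, behavior, encoded traits), and back-projects
#' the thresholded subnetwork.
#'
#' @param connectomes named list of adjacency matrices.
#' @param behavior per-subject behavioral summary (data frame; non-numeric
#'   columns and `subject` are dropped).
#' @param traits trait table aligned with the connectome subjects.
#' @param alpha,n_folds Elastic Net parameters.
#' @param threshold subnetwork weight cutoff.
#' @param seed RNG seed for fold assignment.
#' @param ... passed to [fit_mcca()].
#' @return list: `en` (selection), `mcca`, `subnetwork`, `domains`,
#'   `edge_index` (selected edges).
#' @export
integrate_domains <- function(connectomes, behavior, traits, alpha = 0.5,
                              n_folds = 10, threshold = 0.05, seed = 1L,
                              ...) {
  ids <- names(connectomes)
  behavior <- behavior[match(ids, behavior$subject), , drop = FALSE]
  traits <- traits[match(ids, traits$subject_id), , drop = FALSE]
  if (any(is.na(behavior$subject)) || any(is.na(traits$subject_id)))
    stop_data("behavior/traits do not cover all connectome subjects")
  vec <- vectorize_connectomes(connectomes)
  Yb <- as.matrix(behavior[, vapply(behavior, is.numeric, TRUE),
                           drop = FALSE])
  en <- fit_elastic_net(vec$X, Yb, alpha = alpha, n_folds = n_folds,
                        seed = seed)
  if (length(en$selected) == 0)
    stop_data("Elastic Net selected no edges")
  Xsel <- vec$X[, en$selected, drop = FALSE]
  domains <- list(connectome = Xsel, behavior = scale(Yb),
                  traits = encode_traits(traits))
  mcca <- fit_mcca(domains, ...)
  sub <- backproject_and_threshold(
    mcca, vec$edge_index[en$selected, , drop = FALSE],
    threshold = threshold)
  list(en = en, mcca = mcca, subnetwork = sub, domains = domains,
       edge_index = vec$edge_index[en$selected, , drop = FALSE])
}
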