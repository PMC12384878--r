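make_connectomes <- function(n_subj, n_reg, seed = 1) {
  withr::with_seed(seed, lapply(setNames(nm = sprintf("s%02d", seq_len(n_subj))),
    function(id) {
      m <- matrix(rpois(n_reg^2, 20), n_reg,
                  dimnames = list(sprintf("R%02d", 1:n_reg),
                                  sprintf("R%02d", 1:n_reg)))
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      diag(m) <- 0
      m
    }))
}

test_that("vectorization produces the expected edge layout", {
  cc <- make_connectomes(10, 4)
  v <- vectorize_connectomes(cc)
  expect_equal(ncol(v$X), 6)                       # 4*3/2
  expect_equal(v$edge_index$i, c(1, 1, 1, 2, 2, 3))
  expect_equal(v$edge_index$j, c(2, 3, 4, 3, 4, 4))
  expect_equal(unname(colMeans(v$X)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(v$X, 2, sd)), rep(1, 6))
  # round trip through the index restores edge positions
  for (k in c(1, 5)) {
    raw <- log1p(vapply(cc, function(m)
      m[v$edge_index$i[k], v$edge_index$j[k]], 0))
    expect_equal(unname(v$X[, k]), as.numeric(scale(raw)))
  }
})

test_that("vectorization rejects malformed connectomes", {
  cc <- make_connectomes(5, 4)
  cc[[2]][1, 2] <- cc[[2]][1, 2] + 1   # asymmetric perturbation
  expect_error(vectorize_connectomes(cc), "not symmetric")
  cc2 <- make_connectomes(5, 4)
  rownames(cc2[[3]]) <- letters[1:4]
  expect_error(vectorize_connectomes(cc2), "mismatched")
})

test_that("elastic net loss matches its closed-form pieces", {
  withr::with_seed(8, {
    X <- matrix(rnorm(40), 20, 2)
    y <- rnorm(20)
  })
  expect_equal(elastic_net_loss(c(0, 0), X, y, 1), sum(y^2) / 40)
  b <- c(0.3, -0.2)
  expect_equal(elastic_net_loss(b, X, y, 2, alpha = 1) -
                 elastic_net_loss(b, X, y, 0, alpha = 1),
               2 * sum(abs(b)))
  expect_equal(elastic_net_loss(b, X, y, 2, alpha = 0) -
                 elastic_net_loss(b, X, y, 0, alpha = 0),
               2 * sum(b^2) / 2)
  # lambda = 0: OLS minimizes; any perturbation increases the loss
  bls <- qr.coef(qr(X), y)
  l0 <- elastic_net_loss(bls, X, y, 0)
  for (d in list(c(0.01, 0), c(0, -0.01), c(0.05, 0.05)))
    expect_gt(elastic_net_loss(bls + d, X, y, 0), l0)
  expect_error(elastic_net_loss(b, X, y, -1), "nonnegative")
})

test_that("coordinate descent matches dense grid search of the loss", {
  withr::with_seed(13, {
    X <- scale(matrix(rnorm(120), 60, 2))
    y <- as.numeric(scale(X %*% c(1, -0.5) + rnorm(60)))
  })
  for (lam in c(0.05, 0.2, 0.6)) {
    b_cd <- elastic_net_coef(X, y, lam, 0.5)
    b_gs <- en_grid_search(X, y, lam, 0.5)
    expect_equal(b_cd, b_gs, tolerance = 1e-4)
  }
})

test_that("large penalties give the empty selection", {
  withr::with_seed(14, {
    X <- scale(matrix(rnorm(400), 40, 10))
    y <- rnorm(40)
  })
  expect_equal(elastic_net_coef(X, y, lambda = 100, alpha = 0.5),
               rep(0, 10))
  en <- fit_elastic_net(X, cbind(y), lambda = c(100, 50), n_folds = 5)
  expect_length(en$selected, 0)
  expect_error(fit_elastic_net(X, rep(1, 40), n_folds = 5), "degenerate")
})

test_that("planted informative edges are recovered by CV selection", {
  hits <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      X <- matrix(rnorm(300 * 200), 300)
      beta <- c(rep(0.5, 5), rep(0, 195))
      y <- X %*% beta + rnorm(300)
    })
    en <- fit_elastic_net(X, y, seed = s)
    sum(1:5 %in% en$selected)
  }, numeric(1))
  expect_gte(mean(hits >= 4), 0.9)
})

test_that("three identical domains attain the sumcor bound", {
  withr::with_seed(20, X <- matrix(rnorm(60), 20, 3))
  m <- fit_mcca(list(X, X, X))
  expect_equal(m$sumcor, 3, tolerance = 1e-9)
  expect_true(all(abs(m$pairwise_corr) <= 1 + 1e-12))
})

test_that("two-domain solution matches classical CCA", {
  for (s in 1:20) {
    withr::with_seed(s, {
      X1 <- matrix(rnorm(40 * 3), 40)
      X2 <- matrix(rnorm(40 * 4), 40)
    })
    m <- fit_mcca(list(X1, X2), ridge = 0)
    cc <- cancor(scale(X1), scale(X2))
    expect_equal(m$pairwise_corr[1, 2], cc$cor[1], tolerance = 1e-6)
  }
})

test_that("Horst solution matches exhaustive grid search on 2-D toys", {
  withr::with_seed(30, Xs2 <- lapply(1:2, function(i) matrix(rnorm(60), 30)))
  m2 <- fit_mcca(Xs2)
  expect_equal(m2$sumcor, mcca_grid_search(Xs2), tolerance = 1e-3)
  withr::with_seed(31, Xs3 <- lapply(1:3, function(i) matrix(rnorm(60), 30)))
  m3 <- fit_mcca(Xs3)
  expect_equal(m3$sumcor, mcca_grid_search(Xs3), tolerance = 1e-3)
})

test_that("sumcor trace is monotone and the fit is deterministic", {
  withr::with_seed(33, Xs <- lapply(1:3, function(i) matrix(rnorm(200), 40)))
  m <- fit_mcca(Xs)
  expect_true(all(diff(m$trace) >= -1e-10))
  m2 <- fit_mcca(Xs)
  expect_identical(m$weights, m2$weights)
  expect_true(m$converged)
  # sign convention: dominant weight of domain 1 is positive
  expect_gt(m$weights[[1]][which.max(abs(m$weights[[1]]))], 0)
  # variates have unit sample variance
  expect_equal(unname(apply(m$variates, 2, var)), rep(1, 3))
})

test_that("planted latent factor weights are recovered across seeds", {
  cosim <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      z <- rnorm(500)
      mk <- function(p, k) matrix(rnorm(500 * p), 500) +
        outer(z, c(rep(0.6, k), rep(0, p - k)))
      Xs <- list(mk(10, 4), mk(6, 3), mk(6, 3))
    })
    m <- fit_mcca(Xs)
    planted <- c(rep(1, 4), rep(0, 6)) / 2
    w <- m$weights[[1]] / sqrt(sum(m$weights[[1]]^2))
    abs(sum(w * planted))
  }, numeric(1))
  expect_gte(mean(cosim >= 0.9), 0.9)
})

test_that("bootstrap and permutation inference behave at the extremes", {
  withr::with_seed(40, X <- matrix(rnorm(80), 20, 4))
  r <- resample_sumcor(list(X, X, X), B = 100, P = 49, seed = 1)
  expect_warning(resample_sumcor(list(X, X), B = 50, P = 9, seed = 1),
                 "fewer than 100")
  expect_equal(r$sumcor_observed, 3, tolerance = 1e-9)
  expect_true(all(abs(r$bootstrap_draws - 3) < 1e-6, na.rm = TRUE))
  expect_equal(unname(diff(r$ci95)), 0, tolerance = 1e-6)
  expect_gte(r$permutation_p, 1 / 50)
  # independent domains: observed sumcor sits inside the null bulk
  withr::with_seed(41, Xs <- lapply(1:3, function(i) matrix(rnorm(300), 100)))
  r0 <- resample_sumcor(Xs, B = 100, P = 99, seed = 2)
  expect_gt(r0$permutation_p, 0.01)
})

test_that("a planted factor drives the permutation p to its floor", {
  withr::with_seed(50, {
    z <- rnorm(150)
    Xs <- lapply(1:3, function(i)
      matrix(rnorm(150 * 3), 150) + outer(z, rep(0.6, 3)))
  })
  r <- resample_sumcor(Xs, B = 100, P = 199, seed = 3)
  expect_equal(r$permutation_p, 1 / 200)
})

test_that("back-projection thresholds and stage counts are exact", {
  w <- c(0.452, -0.158, 0.03)
  fake <- structure(list(weights = list(w)), class = "olfnet_mcca")
  ei <- data.frame(i = c(1, 1, 2), j = c(2, 3, 3),
                   region_i = c("A", "A", "B"), region_j = c("B", "C", "C"))
  res <- backproject_and_threshold(fake, ei, threshold = 0.05)
  expect_equal(res$stage_counts[["n_after_en"]], 3)
  expect_equal(res$stage_counts[["n_after_threshold"]], 2)
  expect_equal(nrow(res$retained_edges), 2)
  expect_equal(res$retained_edges$weight, c(0.452, -0.158))
  expect_equal(res$retained_edges$region_a, c("A", "A"))
  expect_equal(res$retained_edges$region_b, c("B", "C"))
  # threshold 0 retains every MCCA-nonzero edge
  res0 <- backproject_and_threshold(fake, ei, threshold = 0)
  expect_equal(nrow(res0$retained_edges),
               res0$stage_counts[["n_after_mcca"]])
  expect_error(backproject_and_threshold(fake, ei[1:2, ]), "do not match")
})

test_that("retained subnetwork is invariant to edge-column permutation", {
  withr::with_seed(60, {
    z <- rnorm(80)
    X1 <- matrix(rnorm(80 * 6), 80) + outer(z, c(1, 1, 0, 0, 0, 0))
    X2 <- cbind(z + rnorm(80, 0, 0.5), rnorm(80))
  })
  ei <- data.frame(i = 1:6, j = 7:12,
                   region_i = paste0("A", 1:6), region_j = paste0("B", 1:6))
  m <- fit_mcca(list(X1, X2))
  r <- backproject_and_threshold(m, ei, threshold = 0.1)
  perm <- c(4, 2, 6, 1, 3, 5)
  m2 <- fit_mcca(list(X1[, perm], X2))
  r2 <- backproject_and_threshold(m2, ei[perm, ], threshold = 0.1)
  o1 <- r$retained_edges[order(r$retained_edges$region_a), ]
  o2 <- r2$retained_edges[order(r2$retained_edges$region_a), ]
  expect_equal(o1$region_a, o2$region_a)
  expect_equal(o1$weight, o2$weight, tolerance = 1e-8)
})

test_that("end-to-end integration returns consistent bookkeeping", {
  spec <- tiny_spec(40, seed = 2)
  tr <- generate_traits(spec)
  cc <- generate_connectomes(tr, spec)
  bs <- summarize_behavior(generate_behavior(tr, spec))
  res <- integrate_domains(cc, bs, tr, n_folds = 5, seed = 1)
  sc <- res$subnetwork$stage_counts
  expect_true(sc[["n_after_en"]] >= sc[["n_after_mcca"]])
  expect_true(sc[["n_after_mcca"]] >= sc[["n_after_threshold"]])
  expect_equal(sc[["n_after_en"]], length(res$en$selected))
  expect_true(all(abs(res$subnetwork$retained_edges$weight) >= 0.05))
  # determinism
  res2 <- integrate_domains(cc, bs, tr, n_folds = 5, seed = 1)
  expect_equal(res$mcca$sumcor, res2$mcca$sumcor, tolerance = 1e-12)
})
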