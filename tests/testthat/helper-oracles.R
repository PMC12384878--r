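# Independent reference implementations used as oracles. These stay separate
# from the package code paths they check.

# Step-up BH reference, written directly from the definition.
bh_reference <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Exhaustive upper-tail hypergeometric probability by enumeration over all
# draws of size nq from a universe of size N containing K marked elements.
hyper_tail_enum <- function(k, K, N, nq) {
  ks <- max(0, nq - (N - K)):min(K, nq)
  probs <- choose(K, ks) * choose(N - K, nq - ks) / choose(N, nq)
  sum(probs[ks >= k])
}

# Dense 0.5-degree grid search of the SUMCOR objective for 2-feature
# domains, maximizing over directions and per-domain sign flips.
mcca_grid_search <- function(Xs, step_deg = 0.5) {
  th <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  n <- nrow(Xs[[1]])
  U <- lapply(Xs, function(X) {
    X <- scale(X)
    Z <- X %*% rbind(cos(th), sin(th))
    scale(Z) / sqrt(n - 1)          # columns: unit-norm variates
  })
  if (length(Xs) == 2) {
    return(max(abs(crossprod(U[[1]], U[[2]]))))
  }
  stopifnot(length(Xs) == 3)
  C12 <- crossprod(U[[1]], U[[2]])
  C13 <- crossprod(U[[1]], U[[3]])
  C23 <- crossprod(U[[2]], U[[3]])
  best <- -Inf
  for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
    base <- (s2 * s3) * C23
    for (a in seq_along(th)) {
      v <- outer(s2 * C12[a, ], s3 * C13[a, ], `+`) + base
      best <- max(best, max(v))
    }
  }
  best
}

# Zooming dense grid search of the elastic net loss on 2 features; final
# resolution ~1e-5 per coordinate.
en_grid_search <- function(X, y, lambda, alpha, lim = 2, levels = 6) {
  ctr <- c(0, 0)
  half <- lim
  for (l in seq_len(levels)) {
    b1 <- seq(ctr[1] - half, ctr[1] + half, length.out = 41)
    b2 <- seq(ctr[2] - half, ctr[2] + half, length.out = 41)
    losses <- outer(b1, b2, Vectorize(function(a, b)
      elastic_net_loss(c(a, b), X, y, lambda, alpha)))
    ix <- which(losses == min(losses), arr.ind = TRUE)[1, ]
    ctr <- c(b1[ix[1]], b2[ix[2]])
    half <- half / 10
  }
  ctr
}

# Small default spec for fast tests.
tiny_spec <- function(n = 40, seed = 1, ...) {
  simulation_spec(n_subjects = n, n_regions = 8, n_genes = 200,
                  n_modules = 4, module_size = 20, seed = seed, ...)
}
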