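toy_counts <- function(genes = 6, subjects = 5, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rpois(genes * subjects, 100), genes,
                dimnames = list(sprintf("G%02d", seq_len(genes)),
                                sprintf("s%02d", seq_len(subjects))))
    m
  })
}

test_that("normalization is CPM plus log2 plus gene centering", {
  m <- matrix(c(10, 20, 30, 20, 40, 60, 5, 10, 15), 3,
              dimnames = list(c("g1", "g2", "g3"), c("a", "b", "c")))
  norm <- normalize_expression(m)
  # hand computation: CPM then log2(+1) then row centering
  cpm_hand <- sweep(m, 2, colSums(m), `/`) * 1e6
  lg <- log2(cpm_hand + 1)
  expect_equal(norm, lg - rowMeans(lg), tolerance = 1e-9)
  # identical columns center to zero
  mm <- matrix(rep(c(5, 10, 15), 3), 3,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  expect_true(all(abs(normalize_expression(mm)) < 1e-12))
  # CPM invariance: doubling a library leaves its profile unchanged
  m2 <- m
  m2[, "b"] <- m2[, "b"] * 2
  expect_equal(normalize_expression(m2)[, "b"], norm[, "b"],
               tolerance = 1e-9)
  m3 <- m
  m3[, 2] <- 0
  expect_error(normalize_expression(m3), "zero library")
})

test_that("eigengene PCA recovers rank and reconstructs the input", {
  # rank-1 matrix: PC1 explains essentially all variance
  withr::with_seed(2, {
    u <- rnorm(30)
    v <- rnorm(50)
  })
  X <- outer(v, u)              # genes x subjects
  rownames(X) <- sprintf("G%02d", 1:50)
  colnames(X) <- sprintf("s%02d", 1:30)
  es <- compute_eigengenes(X, K = 3)
  expect_gt(es$variance_explained[1], 0.999)
  expect_equal(unname(apply(es$scores, 2, var)), rep(1, 3))
  # SVD identity: full reconstruction
  withr::with_seed(3, Y <- matrix(rnorm(20 * 8), 20,
                                  dimnames = list(sprintf("G%02d", 1:20),
                                                  sprintf("s%02d", 1:8))))
  esf <- compute_eigengenes(Y, K = 7)
  Xc <- scale(t(Y), center = TRUE, scale = FALSE)
  # reconstruction from all components: scores/sqrt(n-1) * d * loadings'
  recon <- (esf$scores / sqrt(nrow(Xc) - 1)) %*%
    (diag(esf$d) %*% t(esf$loadings))
  expect_equal(recon, Xc, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(compute_eigengenes(Y, K = 10), "exceeds")
})

test_that("orthogonal planted modules land on distinct components", {
  spec <- simulation_spec(n_subjects = 500, n_genes = 1000, n_modules = 4,
                          module_size = 50, seed = 12)
  tr <- generate_traits(spec)
  ex <- generate_expression(tr, spec, tissues = "blood")$blood
  es <- compute_eigengenes(normalize_expression(ex), K = 4)
  ms <- olfnet:::module_scores(tr, spec)
  best <- apply(abs(cor(es$scores, ms[, 1:4])), 2, max)
  expect_true(all(best > 0.95))
  # score columns are orthogonal
  cr <- cor(es$scores)
  expect_true(all(abs(cr[upper.tri(cr)]) < 1e-8))
})

test_that("top-loading gene ranking is deterministic and complete", {
  withr::with_seed(4, Y <- matrix(rnorm(200), 20,
                                  dimnames = list(sprintf("G%02d", 1:20),
                                                  sprintf("s%02d", 1:10))))
  es <- compute_eigengenes(Y, K = 3)
  top <- top_loading_genes(es, 1, n = 5)
  ord <- order(-abs(es$loadings[, 1]), rownames(es$loadings))
  expect_equal(top, rownames(es$loadings)[ord][1:5])
  expect_length(top_loading_genes(es, 1, n = 100), 20)
  # stable under row permutation of the input
  perm <- withr::with_seed(5, sample(20))
  es2 <- compute_eigengenes(Y[perm, ], K = 3)
  expect_setequal(top_loading_genes(es2, 1, n = 5), top)
  # a strongly planted module dominates the ranking
  spec <- tiny_spec(100, seed = 13)
  ex <- generate_expression(generate_traits(spec), spec,
                            tissues = "blood")$blood
  esb <- compute_eigengenes(normalize_expression(ex), K = 4)
  module1 <- rownames(ex)[1:20]
  ms <- olfnet:::module_scores(generate_traits(spec), spec)
  pc <- which.max(abs(cor(esb$scores, ms[, 1])))
  expect_gte(sum(module1 %in% top_loading_genes(esb, pc, n = 40)), 19)
})

test_that("BH adjustment matches the independent step-up reference", {
  expect_equal(bh_fdr(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  for (s in 1:20) {
    p <- withr::with_seed(s, runif(50))
    expect_equal(bh_fdr(p), bh_reference(p))
    expect_true(all(bh_fdr(p) >= p))
  }
  # bulk oracle comparison
  withr::with_seed(77, {
    for (i in 1:1000) {
      p <- runif(sample(3:40, 1))
      if (!isTRUE(all.equal(bh_fdr(p), bh_reference(p))))
        fail("BH mismatch")
    }
  })
  succeed()
  expect_error(bh_fdr(c(0.1, NA)), "non-finite")
  expect_error(bh_fdr(c(0.1, 1.2)), "outside")
})

test_that("coupling grid has exact cardinality and the slope equals r", {
  spec <- tiny_spec(50, seed = 14)
  tr <- generate_traits(spec)
  im <- generate_imaging_metrics(tr, spec)
  scores <- olfnet:::module_scores(tr, spec)
  g <- coupling_grid(im, scores, regions = olf_regions,
                     metrics = coupling_metrics)
  expect_equal(nrow(g), 8 * ncol(scores) * 7)
  expect_equal(g$r_squared, g$r^2)
  expect_true(all(abs(g$r) <= 1, na.rm = TRUE))
  expect_true(all(g$fdr >= g$p, na.rm = TRUE))
  # z-scored slope equals the Pearson correlation computed independently
  row <- g[g$region == "Hippocampus" & g$metric == "FA" &
             g$eigengene == 3, ]
  cell <- im[im$region == "Hippocampus" & im$metric == "FA", ]
  expect_equal(row$beta, cor(cell$value, scores[cell$subject, 3]),
               tolerance = 1e-12)
})

test_that("planted eigengene-metric coupling is recovered through PCA", {
  spec <- simulation_spec(n_subjects = 500, seed = 5)
  tr <- generate_traits(spec)
  im <- generate_imaging_metrics(tr, spec)
  ex <- generate_expression(tr, spec, tissues = "blood")$blood
  es <- compute_eigengenes(normalize_expression(ex), K = 10)
  ms <- olfnet:::module_scores(tr, spec)[, spec$coupling_module]
  pc <- which.max(abs(cor(es$scores, ms)))
  align <- sign(cor(es$scores[, pc], ms))
  g <- coupling_grid(im, es$scores, regions = olf_regions,
                     metrics = coupling_metrics)
  row <- g[g$region == "Parasubiculum" & g$metric == "AD" &
             g$eigengene == pc, ]
  expect_lt(abs(align * row$r - (-0.5)), 0.08)
  expect_equal(row$r_squared, row$r^2)
  expect_true(row$significant)
})

test_that("cells with too few subjects are flagged, not dropped", {
  spec <- tiny_spec(30, seed = 15)
  tr <- generate_traits(spec)
  im <- generate_imaging_metrics(tr, spec)
  scores <- olfnet:::module_scores(tr, spec)[1:3, , drop = FALSE]
  expect_message(g <- coupling_grid(im, scores, regions = olf_regions,
                                    metrics = coupling_metrics),
                 "dropped")
  expect_equal(nrow(g), 8 * ncol(scores) * 7)
  expect_true(all(g$incomplete))
  expect_true(all(is.na(g$r)))
})

test_that("top-region selection matches a brute-force sort", {
  spec <- tiny_spec(40, seed = 16)
  tr <- generate_traits(spec)
  im <- generate_imaging_metrics(tr, spec)
  scores <- olfnet:::module_scores(tr, spec)[, 1:3]
  g <- coupling_grid(im, scores, regions = olf_regions,
                     metrics = coupling_metrics)
  top <- top_regions_per_pair(g, k = 5)
  expect_equal(nrow(top), 7 * 3 * 5)
  pair <- g[g$metric == "FA" & g$eigengene == 2, ]
  brute <- pair[order(-abs(pair$r), pair$region), ][1:5, c("region", "r")]
  got <- top[top$metric == "FA" & top$eigengene == 2, c("region", "r")]
  expect_equal(got$region, brute$region)
  expect_equal(got$r, brute$r)
  expect_equal(nrow(top_regions_per_pair(g, k = 99)), nrow(g))
})
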