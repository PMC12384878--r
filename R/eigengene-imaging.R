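# Transcriptomic eigengenes and the z-scored eigengene x imaging-metric x
# region coupling grid with Benjamini-Hochberg FDR.

#' Normalize an expression count matrix
#'
#' Counts-per-million scaling, `log2(x + 1)`, then gene-wise centering:
#' the default normalization dialect feeding the eigengene PCA.
#'
#' @param expr genes x subjects nonnegative count matrix with gene rownames.
#' @return normalized matrix of the same shape.
#' @export
normalize_expression <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2) stop_data("need at least 2 subjects")
  if (any(expr < 0)) stop_data("negative entries in count matrix")
  lib <- colSums(expr)
  if (any(lib == 0))
    stop_data("zero library size for subject(s): ",
              paste(colnames(expr)[lib == 0], collapse = ", "))
  cpm <- edgeR::cpm(expr)
  lg <- log2(cpm + 1)
  sweep(lg, 1, rowMeans(lg))
}

#' Compute transcriptomic eigengenes (SVD-based PCA)
#'
#' Eigengene `k` is the k-th principal component of the normalized,
#' gene-centered matrix: per-subject scores standardized to unit sample
#' variance, per-gene loadings (unit norm) ranked for top-loading-gene
#' extraction. The sign of each component is fixed so its
#' largest-magnitude gene loading is positive.
#'
#' @param normalized output of [normalize_expression()].
#' @param K number of components (blood default 10, brain regions 4).
#' @param tissue optional tissue tag carried in the result.
#' @return object of class `olfnet_eigengenes`: `loadings` (genes x K),
#'   `scores` (subjects x K, unit variance), `variance_explained`, `K`,
#'   `d` (singular values), `tissue`.
#' @export
compute_eigengenes <- function(normalized, K = 10, tissue = NULL) {
  X <- t(as.matrix(normalized))          # subjects x genes
  n <- nrow(X)
  if (K > min(ncol(X), n - 1))
    stop_data("K = ", K, " exceeds min(genes, subjects - 1) = ",
              min(ncol(X), n - 1))
  X <- scale(X, center = TRUE, scale = FALSE)  # center over subjects
  sv <- svd(X, nu = K, nv = K)
  scores <- sv$u * sqrt(n - 1)           # unit sample variance when d > 0
  # Degenerate trailing components (d ~ 0) get an arbitrary basis; rescale
  # every column so all score variances are exactly 1.
  sds <- apply(scores, 2, sd)
  scores <- sweep(scores, 2, ifelse(sds > 0, sds, 1), `/`)
  loadings <- sv$v
  for (k in seq_len(K)) {
    g <- which.max(abs(loadings[, k]))
    if (loadings[g, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(K)))
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_len(K)))
  structure(list(loadings = loadings, scores = scores,
                 variance_explained = sv$d[seq_len(K)]^2 / sum(sv$d^2),
                 K = K, d = sv$d[seq_len(K)], tissue = tissue),
            class = "olfnet_eigengenes")
}

#' Top-loading genes of one eigengene
#'
#' Genes ranked by absolute loading, descending; ties broken
#' alphabetically by gene symbol.
#'
#' @param eigengenes an [compute_eigengenes()] result.
#' @param component component index.
#' @param n number of genes to return (default 200; capped at the gene
#'   count).
#' @return character vector of gene symbols.
#' @export
top_loading_genes <- function(eigengenes, component, n = 200) {
  if (component > eigengenes$K)
    stop_data("component exceeds K = ", eigengenes$K)
  l <- eigengenes$loadings[, component]
  ord <- order(-abs(l), names(l))
  names(l)[ord][seq_len(min(n, length(l)))]
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone-enforced and capped at 1.
#'
#' @param pvalues vector of p-values in \[0, 1\] (no missing values).
#' @return adjusted vector of the same length.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)))
    stop_data("missing or non-finite p-values")
  if (any(pvalues < 0 | pvalues > 1))
    stop_data("p-values outside [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Eigengene x imaging-metric x region coupling grid
#'
#' One record per (region, metric, eigengene) combination. Within each
#' region both the metric and the eigengene scores are z-scored over the
#' overlapping subjects, so the regression slope of the eigengene on the
#' metric equals the Pearson correlation. Two-sided t-test p-values are
#' BH-adjusted jointly across the whole grid. Combinations with fewer than
#' `min_n` overlapping subjects are emitted with missing statistics and
#' flagged.
#'
#' @param imaging_table long imaging table (`subject`, `region`, `metric`,
#'   `value`).
#' @param eigengene_scores subjects x K score matrix with subject rownames
#'   (e.g. `compute_eigengenes(...)$scores`).
#' @param regions,metrics grid axes (defaults: all regions in the table;
#'   [coupling_metrics]).
#' @param min_n minimum overlapping subjects per cell (default 4).
#' @param fdr_level significance level on the adjusted p (default 0.05).
#' @return data frame of records: `region`, `metric`, `eigengene`, `n`,
#'   `beta`, `r`, `p`, `fdr`, `r_squared`, `significant`, `incomplete`.
#' @export
coupling_grid <- function(imaging_table, eigengene_scores, regions = NULL,
                          metrics = coupling_metrics, min_n = 4,
                          fdr_level = 0.05) {
  regions <- regions %||% sort(unique(imaging_table$region))
  K <- ncol(eigengene_scores)
  subj_expr <- rownames(eigengene_scores)
  overlap <- intersect(unique(imaging_table$subject), subj_expr)
  dropped <- length(unique(imaging_table$subject)) - length(overlap)
  if (dropped > 0)
    message(dropped, " imaging subject(s) without eigengene scores dropped")
  it <- imaging_table[imaging_table$subject %in% overlap, ]
  grid <- expand.grid(eigengene = seq_len(K), metric = metrics,
                      region = regions, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)[, c("region", "metric",
                                                  "eigengene")]
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    cell <- it[it$region == grid$region[g] & it$metric == grid$metric[g], ]
    subj <- cell$subject
    n <- length(subj)
    rec <- data.frame(region = grid$region[g], metric = grid$metric[g],
                      eigengene = grid$eigengene[g], n = n,
                      beta = NA_real_, r = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE)
    if (n < min_n || sd(cell$value) == 0) {
      rec$incomplete <- TRUE
      return(rec)
    }
    x <- as.numeric(scale(cell$value))
    y <- as.numeric(scale(eigengene_scores[subj, grid$eigengene[g]]))
    r <- sum(x * y) / (n - 1)
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    rec$beta <- r                        # slope of z-scored regression
    rec$r <- r
    rec$p <- 2 * pt(-abs(tstat), n - 2)
    rec$incomplete <- FALSE
    rec
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  ok <- !out$incomplete
  out$fdr[ok] <- bh_fdr(out$p[ok])
  out$r_squared <- out$r^2
  out$significant <- !is.na(out$fdr) & out$fdr < fdr_level
  out
}

#' Top regions per metric-eigengene pair
#'
#' Keeps, within each (metric, eigengene) pair, the `k` records with the
#' largest absolute correlations; ties broken by region name.
#'
#' @param records a [coupling_grid()] result.
#' @param k regions to keep per pair (default 5).
#' @return filtered records, ordered by pair then |r| descending.
#' @export
top_regions_per_pair <- function(records, k = 5) {
  keyed <- split(records, list(records$metric, records$eigengene),
                 drop = TRUE)
  out <- lapply(keyed, function(df) {
    df <- df[order(-abs(df$r), df$region), , drop = FALSE]
    head(df, k)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
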