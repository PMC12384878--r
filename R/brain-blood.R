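# Brain-blood transcriptomic coupling: top-PC pair correlations across
# tissues, top-loading gene intersections for significant pairs, and
# hypergeometric gene-set over-representation.

#' Pairwise PC correlations across tissues
#'
#' For every unordered tissue pair and every PC pair (1..`top_k` each),
#' computes Pearson and Spearman correlations over the overlapping
#' subjects, with BH adjustment across all tests (one family per test type
#' by default, or pooled). A pair is significant when its smaller adjusted
#' p falls below `fdr_level`.
#'
#' @param eigengene_sets named list, tissue -> [compute_eigengenes()]
#'   result (subject rownames on scores are used for the overlap).
#' @param top_k PCs per tissue entering the comparison (default 4).
#' @param min_n minimum overlapping subjects; pairs below it are skipped
#'   with a message.
#' @param fdr_level significance level (default 0.05).
#' @param pool_fdr adjust Pearson and Spearman p-values in a single BH
#'   family (default FALSE: one family per test type).
#' @return data frame of records: `tissue_a`, `tissue_b`, `pc_a`, `pc_b`,
#'   `n`, `pearson_r`, `spearman_rho`, `p_pearson`, `p_spearman`,
#'   `fdr_pearson`, `fdr_spearman`, `significant`.
#' @export
pc_pair_correlations <- function(eigengene_sets, top_k = 4, min_n = 4,
                                 fdr_level = 0.05, pool_fdr = FALSE) {
  tissues <- names(eigengene_sets)
  if (length(tissues) < 2) stop_data("need at least 2 tissues")
  pairs <- upper_tri_pairs(length(tissues))
  rows <- list()
  for (pr in seq_len(nrow(pairs))) {
    ta <- tissues[pairs[pr, 1]]
    tb <- tissues[pairs[pr, 2]]
    sa <- eigengene_sets[[ta]]$scores
    sb <- eigengene_sets[[tb]]$scores
    common <- intersect(rownames(sa), rownames(sb))
    if (length(common) < min_n) {
      message("skipping ", ta, " vs ", tb, ": only ", length(common),
              " overlapping subjects")
      next
    }
    ka <- min(top_k, ncol(sa))
    kb <- min(top_k, ncol(sb))
    for (a in seq_len(ka)) for (b in seq_len(kb)) {
      x <- sa[common, a]
      y <- sb[common, b]
      pe <- cor.test(x, y, method = "pearson")
      sp <- suppressWarnings(cor.test(x, y, method = "spearman",
                                      exact = FALSE))
      rows[[length(rows) + 1]] <- data.frame(
        tissue_a = ta, tissue_b = tb, pc_a = a, pc_b = b,
        n = length(common),
        pearson_r = unname(pe$estimate),
        spearman_rho = unname(sp$estimate),
        p_pearson = pe$p.value, p_spearman = sp$p.value,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop_data("no tissue pair had enough subjects")
  out <- do.call(rbind, rows)
  if (pool_fdr) {
    adj <- bh_fdr(c(out$p_pearson, out$p_spearman))
    out$fdr_pearson <- adj[seq_len(nrow(out))]
    out$fdr_spearman <- adj[nrow(out) + seq_len(nrow(out))]
  } else {
    out$fdr_pearson <- bh_fdr(out$p_pearson)
    out$fdr_spearman <- bh_fdr(out$p_spearman)
  }
  out$significant <- pmin(out$fdr_pearson, out$fdr_spearman) < fdr_level
  out
}

#' Intersect the top-loading gene lists of a significant PC pair
#'
#' Intersection of the two top-`n` absolute-loading gene lists; returns an
#' empty vector (skip marker) when the overlap is below `min_overlap`.
#' Symmetric in its arguments.
#'
#' @param set_a,set_b [compute_eigengenes()] results for the two tissues.
#' @param pc_a,pc_b component indices.
#' @param n list length per side (default 200).
#' @param min_overlap minimum intersection size to report (default 5).
#' @return sorted character vector of shared gene symbols (possibly empty).
#' @export
intersect_top_loadings <- function(set_a, set_b, pc_a, pc_b, n = 200,
                                   min_overlap = 5) {
  shared <- sort(intersect(top_loading_genes(set_a, pc_a, n),
                           top_loading_genes(set_b, pc_b, n)))
  if (length(shared) < min_overlap) character(0) else shared
}

#' Build a gene-set collection
#'
#' @param sets named list of gene-symbol vectors.
#' @param descriptions optional named descriptions (defaults to the ids).
#' @param universe gene universe; set genes outside it are dropped, and
#'   sets emptied by the filter are removed.
#' @return object of class `olfnet_genesets`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe) {
  if (is.null(descriptions)) descriptions <- setNames(names(sets), names(sets))
  sets <- lapply(sets, function(g) sort(intersect(unique(g), universe)))
  keep <- lengths(sets) > 0
  structure(list(sets = sets[keep],
                 descriptions = descriptions[names(sets)[keep]],
                 universe = sort(unique(universe))),
            class = "olfnet_genesets")
}

#' Read a GMT gene-set file
#'
#' Tab-separated lines: set id, description, then member genes.
#'
#' @param path GMT file path.
#' @param universe gene universe; defaults to the union of all set genes.
#' @return an `olfnet_genesets` collection.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1)
  desc <- vapply(parts, `[`, "", 2)
  sets <- setNames(lapply(parts, function(x) unique(x[-(1:2)])), ids)
  gene_set_collection(sets, setNames(desc, ids),
                      universe %||% sort(unique(unlist(sets))))
}

#' Write a gene-set collection as GMT
#' @param collection an `olfnet_genesets` object.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
}

#' Hypergeometric gene-set over-representation
#'
#' Upper-tail hypergeometric test of the query list against each set in the
#' collection, BH-adjusted across sets; records sorted by adjusted p.
#' Query genes outside the universe are dropped with a message.
#'
#' @param query_genes character vector of query gene symbols.
#' @param collection an `olfnet_genesets` object.
#' @return data frame: `set_id`, `description`, `overlap_k`, `set_size`,
#'   `query_size`, `universe_size`, `p`, `fdr`, ordered by `fdr` then `p`.
#' @export
hypergeometric_enrichment <- function(query_genes, collection) {
  query <- unique(query_genes)
  outside <- setdiff(query, collection$universe)
  if (length(outside)) {
    message(length(outside), " query gene(s) outside the universe dropped")
    query <- setdiff(query, outside)
  }
  if (length(query) == 0) stop_data("empty query after universe filtering")
  N <- length(collection$universe)
  nq <- length(query)
  rows <- lapply(names(collection$sets), function(id) {
    set <- collection$sets[[id]]
    k <- length(intersect(query, set))
    K <- length(set)
    data.frame(set_id = id,
               description = unname(collection$descriptions[[id]] %||% id),
               overlap_k = k, set_size = K, query_size = nq,
               universe_size = N,
               p = phyper(k - 1, K, N - K, nq, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out <- out[order(out$fdr, out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the brain-blood coupling report
#'
#' Writes the PC-pair correlation table, one gene list per significant pair
#' intersection, and per-pair enrichment tables, with deterministic
#' ordering.
#'
#' @param records [pc_pair_correlations()] output.
#' @param eigengene_sets the tissue eigengene sets the records came from.
#' @param collection optional `olfnet_genesets` for enrichment (skipped
#'   when NULL).
#' @param out_dir output directory.
#' @param n,min_overlap passed to [intersect_top_loadings()].
#' @return character vector of written file paths, invisibly.
#' @export
coupling_report <- function(records, eigengene_sets, collection = NULL,
                            out_dir, n = 200, min_overlap = 5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  ord <- order(records$tissue_a, records$tissue_b, records$pc_a,
               records$pc_b)
  records <- records[ord, , drop = FALSE]
  f <- file.path(out_dir, "pc_pair_correlations.csv")
  write.csv(records, f, row.names = FALSE)
  files <- c(files, f)
  sig <- records[records$significant, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    tag <- sprintf("%s_PC%d__%s_PC%d", sig$tissue_a[i], sig$pc_a[i],
                   sig$tissue_b[i], sig$pc_b[i])
    shared <- intersect_top_loadings(eigengene_sets[[sig$tissue_a[i]]],
                                     eigengene_sets[[sig$tissue_b[i]]],
                                     sig$pc_a[i], sig$pc_b[i],
                                     n = n, min_overlap = min_overlap)
    if (length(shared) == 0) next
    f <- file.path(out_dir, paste0("intersection_", tag, ".txt"))
    writeLines(shared, f)
    files <- c(files, f)
    if (!is.null(collection)) {
      enr <- hypergeometric_enrichment(shared, collection)
      f <- file.path(out_dir, paste0("enrichment_", tag, ".csv"))
      write.csv(enr, f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  invisible(files)
}
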