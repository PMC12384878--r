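`%||%` <- function(x, y) if (is.null(x)) y else x

# Child seeds keep every table's RNG stream independent of the others while
# remaining a pure function of the master seed. Kept below 2^31.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + 1009 * offset) %% 2147483647)
}

with_child_seed <- function(seed, offset, code) {
  withr::with_seed(child_seed(seed, offset), code)
}

stop_config <- function(...) {
  stop(structure(class = c("olfnet_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("olfnet_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Truncated-at-zero normal draws for investigation times and metrics.
rnorm_pos <- function(n, mean, sd) pmax(rnorm(n, mean, sd), 0)

upper_tri_pairs <- function(n) {
  # (i, j) with i < j in row-major order: (1,2), (1,3), ..., (2,3), ...
  idx <- t(combn(seq_len(n), 2L))
  colnames(idx) <- c("i", "j")
  idx
}
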