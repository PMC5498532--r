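# Small builders used across test files.

toy_matrix <- function(values, genes, samples, scale = "linear", entity = "COAD") {
  m <- matrix(values, length(genes), length(samples), byrow = TRUE,
              dimnames = list(genes, samples))
  expression_matrix(m, scale = scale, entity = entity)
}

# a fast, small simulation for property tests (full defaults are exercised
# in the acceptance suite)
small_params <- function(seed = 1, ...) {
  sim_params(n_entities = 3, lines_per_state_per_entity = 8,
             n_tumor_entities = 2, n_tumors_per_entity = 120,
             n_epi_markers = 15, n_mes_markers = 15, n_entity_specific = 6,
             n_null = 80, seed = seed, ...)
}

quiet <- function(expr) {
  withr::with_options(list(emtscreen.verbose = FALSE), expr)
}

# two well-separated blobs of signature-gene profiles (for clustering tests)
two_blob_matrix <- function(n_per = 20, n_genes = 10, sep = 6, sd = 0.5, seed = 7) {
  set.seed(seed)
  centers <- matrix(rnorm(n_genes * 2, sd = 1), n_genes, 2)
  centers[, 2] <- centers[, 2] + sep * rep(c(1, -1), length.out = n_genes)
  m <- cbind(centers[, 1] + matrix(rnorm(n_genes * n_per, 0, sd), n_genes),
             centers[, 2] + matrix(rnorm(n_genes * n_per, 0, sd), n_genes))
  dimnames(m) <- list(paste0("G", seq_len(n_genes)),
                      paste0("s", seq_len(2 * n_per)))
  list(expr = expression_matrix(m, "log2", "X"),
       truth = rep(c(1, 2), each = n_per))
}
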