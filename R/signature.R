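#' Intersect the cell-line and tumor screens into the shared signature
#'
#' Class-wise set intersection; a gene survives only if both screens place it
#' in the same class. Provenance entries from both screens are merged.
#'
#' @param cell_line_sig,tumor_sig [gene_signature()] objects.
#' @return A [gene_signature()]; an empty result is allowed but warned about.
#' @export
intersect_screens <- function(cell_line_sig, tumor_sig) {
  stopifnot(inherits(cell_line_sig, "gene_signature"),
            inherits(tumor_sig, "gene_signature"))
  epi <- intersect(cell_line_sig$epithelial, tumor_sig$epithelial)
  mes <- intersect(cell_line_sig$mesenchymal, tumor_sig$mesenchymal)
  if (!length(epi) && !length(mes)) {
    warning("screens share no genes: shared signature is empty")
  }
  prov <- list()
  for (g in c(epi, mes)) {
    prov[[g]] <- list(cell_line = cell_line_sig$provenance[[g]],
                      tumor = tumor_sig$provenance[[g]])
  }
  gene_signature(epithelial = epi, mesenchymal = mes, provenance = prov)
}

#' Score samples by average z-scored expression of a gene list
#'
#' Each gene's log2 expression is z-scored across the cohort; a sample's
#' score is the mean z over the signature genes. Genes absent from the matrix
#' or constant across the cohort (sd = 0) are dropped with a warning. When no
#' gene is dropped, scores average to 0 over the cohort by construction.
#'
#' @param expr An [expression_matrix()]; linear input is converted with
#'   `log2(x + 1)` first.
#' @param genes Character vector of gene ids (e.g. one class of a
#'   [gene_signature()]).
#' @return A data.frame (`sample_id`, `score`) with attribute `n_genes_used`.
#' @export
score_signature <- function(expr, genes) {
  stopifnot(inherits(expr, "expression_matrix"), length(genes) >= 1)
  lg <- to_log2(expr)
  present <- intersect(genes, rownames(lg$values))
  if (!length(present)) stop("no signature gene present in the matrix")
  if (length(present) < length(genes)) {
    warning(sprintf("%d signature gene(s) absent from the matrix",
                    length(genes) - length(present)))
  }
  m <- lg$values[present, , drop = FALSE]
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d constant signature gene(s)", sum(sds == 0)))
    m <- m[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
    if (!nrow(m)) stop("all signature genes are constant")
  }
  z <- (m - rowMeans(m)) / sds
  out <- data.frame(sample_id = colnames(m), score = unname(colMeans(z)),
                    stringsAsFactors = FALSE)
  attr(out, "n_genes_used") <- nrow(m)
  out
}

# Correlation-distance k-means core. X: genes x samples, each column already
# standardized (mean 0, sd 1), so 1 - cor(x, c) is the distance and the plain
# mean of member columns is the within-cluster distance-minimizing centroid
# direction (all columns share the same norm). Lloyd iterations, stopping at
# an assignment fixpoint or max_iter.
kmeans_correlation <- function(X, k, max_iter, init_idx) {
  n <- ncol(X)
  centroids <- X[, init_idx, drop = FALSE]
  assign_old <- rep(0L, n)
  objective <- numeric()
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    d <- 1 - suppressWarnings(stats::cor(X, centroids)) # n x k
    assign_new <- max.col(-d, ties.method = "first")    # tie -> lower index
    for (j in seq_len(k)) {
      if (!any(assign_new == j)) {
        # re-seed an emptied centroid at the sample farthest from its centroid
        far <- which.max(d[cbind(seq_len(n), assign_new)])
        assign_new[far] <- j
      }
    }
    objective <- c(objective, sum(d[cbind(seq_len(n), assign_new)]))
    if (all(assign_new == assign_old)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    assign_old <- assign_new
    for (j in seq_len(k)) {
      centroids[, j] <- rowMeans(X[, assign_new == j, drop = FALSE])
    }
  }
  list(assignment = assign_new, objective = objective, iterations = iter,
       converged = converged)
}

#' Stratify samples by k-means with Pearson-correlation distance
#'
#' Samples are represented by their z-scored signature-gene profiles and
#' partitioned into `k = 2` groups by Lloyd's algorithm under the distance
#' `1 - Pearson(x, centroid)`, at most `max_iter` iterations, best of
#' `n_restarts` seeded restarts by total within-cluster distance. The cluster
#' with the higher mean epithelial-signature score (equivalently lower
#' mesenchymal score) is labeled `epi_group`, the other `mes_group`.
#'
#' @param expr An [expression_matrix()].
#' @param signature A [gene_signature()].
#' @param config A [screen_config()]; uses `k`, `max_iter`, `n_restarts`,
#'   `seed`.
#' @param genes Which signature class defines the clustering profiles:
#'   `"both"` (default), `"epithelial"` or `"mesenchymal"`.
#' @return A data.frame (`sample_id`, `cluster`, `score_epi`, `score_mes`)
#'   with attributes `iterations_run`, `converged`, `objective`
#'   (per-iteration totals of the winning restart).
#' @export
kmeans_stratify <- function(expr, signature, config = screen_config(),
                            genes = c("both", "epithelial", "mesenchymal")) {
  genes <- match.arg(genes)
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(signature, "gene_signature"))
  glist <- switch(genes,
                  both = c(signature$epithelial, signature$mesenchymal),
                  epithelial = signature$epithelial,
                  mesenchymal = signature$mesenchymal)
  glist <- intersect(glist, rownames(expr$values))
  if (length(glist) < 2) stop("need >= 2 signature genes present for correlation distance")
  if (ncol(expr$values) < 2 * config$k) stop("need at least 2k samples")
  lg <- to_log2(expr)
  m <- lg$values[glist, , drop = FALSE]
  sds <- apply(m, 1, stats::sd)
  m <- m[sds > 0, , drop = FALSE]
  if (nrow(m) < 2) stop("fewer than 2 non-constant signature genes")
  z <- (m - rowMeans(m)) / apply(m, 1, stats::sd)
  prof_sd <- apply(z, 2, stats::sd)
  if (any(prof_sd == 0)) stop("constant sample profile: correlation distance undefined")
  X <- scale(z) # standardize each sample profile over genes
  if (all(abs(stats::cor(X) - 1) < 1e-12)) stop("all profiles identical: distance degenerate")
  best <- NULL
  with_seed(derive_seed(config$seed, 3L), {
    for (r in seq_len(config$n_restarts)) {
      init <- sample(ncol(X), config$k)
      fit <- kmeans_correlation(X, config$k, config$max_iter, init)
      if (is.null(best) || utils::tail(fit$objective, 1) < utils::tail(best$objective, 1)) {
        best <- fit
      }
    }
  })
  score_for <- function(side) {
    if (!length(intersect(signature[[side]], rownames(expr$values)))) return(NULL)
    score_signature(expr, signature[[side]])$score
  }
  s_epi <- score_for("epithelial")
  s_mes <- score_for("mesenchymal")
  if (is.null(s_epi) && is.null(s_mes)) stop("signature has no scorable genes")
  polarity <- (if (is.null(s_epi)) 0 else s_epi) - (if (is.null(s_mes)) 0 else s_mes)
  mean_by_cluster <- tapply(polarity, best$assignment, mean)
  epi_cluster <- as.integer(names(which.max(mean_by_cluster)))
  cluster <- ifelse(best$assignment == epi_cluster, "epi_group", "mes_group")
  out <- data.frame(sample_id = colnames(expr$values), cluster = cluster,
                    score_epi = if (is.null(s_epi)) NA_real_ else s_epi,
                    score_mes = if (is.null(s_mes)) NA_real_ else s_mes,
                    stringsAsFactors = FALSE)
  attr(out, "iterations_run") <- best$iterations
  attr(out, "converged") <- best$converged
  attr(out, "objective") <- best$objective
  out
}
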