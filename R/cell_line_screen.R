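#' Classify cell lines by the anchor-ratio rule
#'
#' A line is epithelial-like when its linear-scale CDH1/VIM ratio exceeds
#' `ratio_threshold` (default 10), mesenchymal-like when the VIM/CDH1 ratio
#' does, and ambiguous otherwise (both inequalities strict; ambiguous lines
#' are excluded from downstream testing). log2 input is exponentiated first.
#'
#' @param expr An [expression_matrix()] containing both anchor genes.
#' @param config A [screen_config()].
#' @return A data.frame (`sample_id`, `entity`, `ratio`, `state`) with state
#'   in `epithelial_like` / `mesenchymal_like` / `ambiguous`.
#' @examples
#' m <- matrix(c(2000, 50, 100, 10), 2, 2,
#'             dimnames = list(c("CDH1", "VIM"), c("a", "b")))
#' classify_cell_lines(expression_matrix(m, "linear", "COAD"))
#' @export
classify_cell_lines <- function(expr, config = screen_config()) {
  stopifnot(inherits(expr, "expression_matrix"))
  lin <- to_linear(expr)
  anchors <- c(config$anchor_epithelial, config$anchor_mesenchymal)
  missing <- setdiff(anchors, rownames(lin$values))
  if (length(missing)) stop("anchor gene(s) absent: ", paste(missing, collapse = ", "))
  cdh1 <- lin$values[config$anchor_epithelial, ]
  vim <- lin$values[config$anchor_mesenchymal, ]
  ratio <- cdh1 / vim # 0/x -> 0, x/0 -> Inf, 0/0 -> NaN (ambiguous)
  state <- rep("ambiguous", length(ratio))
  state[!is.nan(ratio) & ratio > config$ratio_threshold] <- "epithelial_like"
  state[!is.nan(ratio) & ratio < 1 / config$ratio_threshold] <- "mesenchymal_like"
  out <- data.frame(sample_id = colnames(lin$values), entity = unname(lin$entity),
                    ratio = unname(ratio), state = state,
                    stringsAsFactors = FALSE)
  tab <- table(out$entity, out$state)
  for (ent in rownames(tab)) {
    log_info(sprintf("entity %s: %s", ent,
                     paste(sprintf("%s=%d", colnames(tab), tab[ent, ]), collapse = ", ")))
  }
  out
}

# Vectorized two-sample t over matrix rows; pooled-variance Student's t by
# default, Welch optional. Degenerate rows: both groups constant and equal
# -> t = 0, p = 1; constant but unequal -> t = +/-Inf, p = 0.
row_t_test <- function(x_a, x_b, welch = FALSE) {
  n_a <- ncol(x_a); n_b <- ncol(x_b)
  m_a <- rowMeans(x_a); m_b <- rowMeans(x_b)
  v_a <- apply(x_a, 1, stats::var); v_b <- apply(x_b, 1, stats::var)
  if (welch) {
    se2 <- v_a / n_a + v_b / n_b
    df <- se2^2 / ((v_a / n_a)^2 / (n_a - 1) + (v_b / n_b)^2 / (n_b - 1))
  } else {
    sp2 <- ((n_a - 1) * v_a + (n_b - 1) * v_b) / (n_a + n_b - 2)
    se2 <- sp2 * (1 / n_a + 1 / n_b)
    df <- rep(n_a + n_b - 2, length(m_a))
  }
  t_stat <- (m_a - m_b) / sqrt(se2)
  zero_se <- se2 == 0
  t_stat[zero_se & m_a == m_b] <- 0
  t_stat[zero_se & m_a != m_b] <- sign(m_a - m_b)[zero_se & m_a != m_b] * Inf
  p <- 2 * stats::pt(-abs(t_stat), df)
  p[zero_se & m_a == m_b] <- 1
  p[zero_se & m_a != m_b] <- 0
  list(mean_a = m_a, mean_b = m_b, t = t_stat, df = df, p = p)
}

#' Per-entity differential screen between anchor-defined states
#'
#' For one entity, compares every gene between epithelial-like and
#' mesenchymal-like lines with a two-sided Student's t-test (pooled variance;
#' Welch behind `config$welch`) on log2-scale values. Genes with `p < alpha`
#' are flagged `epithelial` when the log2 fold change (epithelial minus
#' mesenchymal mean) is positive, `mesenchymal` when negative.
#'
#' @param expr An [expression_matrix()] (converted to log2 internally).
#' @param calls Output of [classify_cell_lines()].
#' @param entity Entity label to screen.
#' @param config A [screen_config()].
#' @return A data.frame (`gene`, `mean_epi`, `mean_mes`, `log2_fc`, `t_stat`,
#'   `p_value`, `flag`), or `NULL` with a warning when a state has fewer than
#'   two lines in this entity.
#' @export
differential_screen <- function(expr, calls, entity, config = screen_config()) {
  stopifnot(inherits(expr, "expression_matrix"))
  lg <- to_log2(expr)
  sel <- calls$entity == entity
  epi_ids <- calls$sample_id[sel & calls$state == "epithelial_like"]
  mes_ids <- calls$sample_id[sel & calls$state == "mesenchymal_like"]
  if (length(epi_ids) < 2 || length(mes_ids) < 2) {
    warning(sprintf("entity %s skipped: %d epithelial-like, %d mesenchymal-like line(s)",
                    entity, length(epi_ids), length(mes_ids)))
    return(NULL)
  }
  tt <- row_t_test(lg$values[, epi_ids, drop = FALSE],
                   lg$values[, mes_ids, drop = FALSE], welch = config$welch)
  p_flag <- if (config$p_adjust == "none") tt$p else stats::p.adjust(tt$p, config$p_adjust)
  flag <- rep("none", nrow(lg$values))
  flag[p_flag < config$alpha & tt$t > 0] <- "epithelial"
  flag[p_flag < config$alpha & tt$t < 0] <- "mesenchymal"
  data.frame(gene = rownames(lg$values),
             mean_epi = unname(tt$mean_a), mean_mes = unname(tt$mean_b),
             log2_fc = unname(tt$mean_a - tt$mean_b),
             t_stat = unname(tt$t), p_value = unname(tt$p), flag = flag,
             stringsAsFactors = FALSE)
}

#' Intersect per-entity differential results into a signature
#'
#' A gene enters the epithelial (mesenchymal) list only when it is flagged
#' epithelial (mesenchymal) in every entity supplied. Provenance records the
#' per-entity p-value and log2 fold change of each kept gene.
#'
#' @param results Named list of [differential_screen()] data.frames.
#' @param config A [screen_config()].
#' @return A [gene_signature()].
#' @export
intersect_cell_line_screen <- function(results, config = screen_config()) {
  results <- Filter(Negate(is.null), results)
  if (!length(results)) stop("no per-entity results to intersect")
  flagged <- function(cls) {
    Reduce(intersect, lapply(results, function(r) r$gene[r$flag == cls]))
  }
  epi <- flagged("epithelial")
  mes <- flagged("mesenchymal")
  prov <- list()
  for (g in c(epi, mes)) {
    prov[[g]] <- list(screen = "cell_line", entities = lapply(results, function(r) {
      i <- match(g, r$gene)
      list(p_value = r$p_value[i], log2_fc = r$log2_fc[i])
    }))
  }
  log_info(sprintf("cell-line screen intersection over %d entities: %d epithelial, %d mesenchymal",
                   length(results), length(epi), length(mes)))
  gene_signature(epithelial = epi, mesenchymal = mes, provenance = prov)
}

#' Run the full cell-line screen
#'
#' Classifies lines by the anchor-ratio rule, runs the per-entity
#' differential screen, and intersects the flags across all entities.
#'
#' @param expr An [expression_matrix()] of a cell-line compendium.
#' @param config A [screen_config()].
#' @return A list with `calls`, `results` (per-entity data.frames) and
#'   `signature` (a [gene_signature()]).
#' @export
cell_line_screen <- function(expr, config = screen_config()) {
  calls <- classify_cell_lines(expr, config)
  ents <- unique(unname(expr$entity))
  results <- stats::setNames(
    lapply(ents, function(ent) differential_screen(expr, calls, ent, config)),
    ents)
  skipped <- names(results)[vapply(results, is.null, logical(1))]
  if (length(skipped) && config$require_all_entities) {
    stop("entity(ies) could not be screened: ", paste(skipped, collapse = ", "),
         " (set require_all_entities = FALSE to drop them)")
  }
  sig <- intersect_cell_line_screen(results, config)
  list(calls = calls, results = results, signature = sig)
}
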