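#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks). Returns
#' `NA` when either vector is constant, in which case the gene is excluded
#' from threshold classification downstream.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return A correlation in `[-1, 1]`, or `NA_real_`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Per-entity anchor-correlation screen over bulk tumors
#'
#' Correlates every gene with the epithelial anchor (CDH1) and the
#' mesenchymal anchor (VIM) by Spearman rank correlation within one entity.
#' A gene is classified epithelial-state when `r_cdh1 > r_pos` and
#' `r_vim < r_neg`, mesenchymal-state when `r_cdh1 < r_neg` and
#' `r_vim > r_pos` (strict inequalities), otherwise unclassified. Rank
#' correlations are unaffected by the linear/log2 distinction, so the matrix
#' is used on its native scale. Anchors are not excluded from their own
#' screen: the self-correlation of 1 simply classifies each anchor into its
#' own class whenever the anchors are themselves anti-correlated.
#'
#' @param expr An [expression_matrix()] of bulk tumors.
#' @param entity Entity label to screen.
#' @param config A [screen_config()]; `min_samples` is the per-entity floor.
#' @return A data.frame (`gene`, `r_cdh1`, `r_vim`, `n_samples`, `class`).
#' @export
correlation_screen <- function(expr, entity, config = screen_config()) {
  stopifnot(inherits(expr, "expression_matrix"))
  anchors <- c(config$anchor_epithelial, config$anchor_mesenchymal)
  missing <- setdiff(anchors, rownames(expr$values))
  if (length(missing)) stop("anchor gene(s) absent: ", paste(missing, collapse = ", "))
  ids <- names(expr$entity)[expr$entity == entity]
  if (length(ids) < config$min_samples) {
    stop(sprintf("entity %s has %d samples, below the floor of %d",
                 entity, length(ids), config$min_samples))
  }
  m <- expr$values[, ids, drop = FALSE]
  anchor_mat <- cbind(m[config$anchor_epithelial, ], m[config$anchor_mesenchymal, ])
  r <- suppressWarnings(stats::cor(t(m), anchor_mat, method = "spearman"))
  const <- apply(m, 1, function(v) stats::sd(v) == 0)
  r[const, ] <- NA_real_
  const_anchor <- stats::sd(anchor_mat[, 1]) == 0 || stats::sd(anchor_mat[, 2]) == 0
  if (const_anchor) r[] <- NA_real_
  r_cdh1 <- r[, 1]; r_vim <- r[, 2]
  cls <- rep("unclassified", nrow(m))
  ok <- !is.na(r_cdh1) & !is.na(r_vim)
  cls[ok & r_cdh1 > config$r_pos & r_vim < config$r_neg] <- "epithelial"
  cls[ok & r_cdh1 < config$r_neg & r_vim > config$r_pos] <- "mesenchymal"
  log_info(sprintf("entity %s (n=%d): %d epithelial-state, %d mesenchymal-state genes",
                   entity, length(ids), sum(cls == "epithelial"),
                   sum(cls == "mesenchymal")))
  data.frame(gene = rownames(m), r_cdh1 = unname(r_cdh1), r_vim = unname(r_vim),
             n_samples = length(ids), class = cls, stringsAsFactors = FALSE)
}

#' Intersect per-entity correlation profiles into a signature
#'
#' A gene enters the epithelial (mesenchymal) list only when it is classified
#' epithelial-state (mesenchymal-state) in every entity supplied. Provenance
#' stores each kept gene's per-entity anchor correlations.
#'
#' @param profiles Named list of [correlation_screen()] data.frames.
#' @param config A [screen_config()].
#' @return A [gene_signature()].
#' @export
intersect_tumor_screen <- function(profiles, config = screen_config()) {
  profiles <- Filter(Negate(is.null), profiles)
  if (!length(profiles)) stop("no per-entity profiles to intersect")
  classified <- function(cls) {
    Reduce(intersect, lapply(profiles, function(p) p$gene[p$class == cls]))
  }
  epi <- classified("epithelial")
  mes <- classified("mesenchymal")
  prov <- list()
  for (g in c(epi, mes)) {
    prov[[g]] <- list(screen = "tumor", entities = lapply(profiles, function(p) {
      i <- match(g, p$gene)
      list(r_cdh1 = p$r_cdh1[i], r_vim = p$r_vim[i])
    }))
  }
  log_info(sprintf("tumor screen intersection over %d entities: %d epithelial, %d mesenchymal",
                   length(profiles), length(epi), length(mes)))
  gene_signature(epithelial = epi, mesenchymal = mes, provenance = prov)
}

#' Run the full tumor screen
#'
#' Per-entity anchor correlations followed by the all-entity intersection.
#'
#' @param expr An [expression_matrix()] of bulk tumors.
#' @param config A [screen_config()].
#' @return A list with `profiles` (per-entity data.frames) and `signature`.
#' @export
tumor_screen <- function(expr, config = screen_config()) {
  ents <- unique(unname(expr$entity))
  profiles <- stats::setNames(
    lapply(ents, function(ent) correlation_screen(expr, ent, config)), ents)
  sig <- intersect_tumor_screen(profiles, config)
  list(profiles = profiles, signature = sig)
}
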