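#' Simulation parameters
#'
#' Free parameters of the synthetic compendium generator. Defaults define the
#' package's reference study conditions: 5 cell-line entities with 20
#' epithelial-state plus 20 mesenchymal-state lines each, 3 bulk-tumor
#' entities with 300 tumors each, 50 planted epithelial and 50 planted
#' mesenchymal markers, 20 entity-specific genes, 900 null genes, a 2.0 log2
#' between-state effect and 0.5 log2 noise.
#'
#' Bulk tumors are purity-weighted cancer/stroma mixtures. Stromal cells
#' express the canonical mesenchymal anchor (VIM) at `stroma_factor_range`
#' fold above cancer-cell baseline (one to two orders of magnitude); planted
#' mesenchymal markers are cancer-cell-intrinsic (stromal expression at
#' baseline), epithelial-class genes are nearly silent in stroma. This is the
#' asymmetry that makes bulk anchor correlations treacherous for mesenchymal
#' genes while leaving epithelial genes screenable.
#'
#' @param n_entities Number of cell-line cancer entities.
#' @param lines_per_state_per_entity Cell lines per state per entity.
#' @param n_tumor_entities Number of bulk-tumor entities (first entities of
#'   the same pool, so gene roles line up across the two compendia).
#' @param n_tumors_per_entity Tumors per entity.
#' @param n_epi_markers,n_mes_markers,n_entity_specific,n_null Planted gene
#'   counts by role.
#' @param effect_size Between-state shift in log2 units (default 2).
#' @param noise_sd Per-cell Gaussian noise, log2 units (default 0.5).
#' @param stroma_factor_range Fold range of stromal over cancer-cell
#'   expression for the mesenchymal anchor (default `c(10, 100)`).
#' @param purity_range Tumor purity range, a sub-interval of (0, 1]
#'   (default `c(0.5, 0.95)`).
#' @param response_weight_range Range of per-gene responsiveness weights in
#'   tumors (default `c(0.3, 1.5)`): a marker's fold response to the latent
#'   EMT score is `2^(effect_size * w * e)` (or `1 - e`) with `w` drawn once
#'   per gene. Real markers differ widely in dynamic range, and this
#'   heterogeneity is what gives signature-gene profiles a shape that
#'   correlation-distance clustering can use. Anchors keep `w = 1`.
#' @param stroma_epi_range Range of stromal expression of epithelial-class
#'   genes relative to cancer-cell baseline (default `c(0.02, 0.3)`; stromal
#'   cells are nearly silent for epithelial genes).
#' @param hazard_ratio_mes Hazard multiplier per unit latent EMT score
#'   (default 2).
#' @param censor_rate Target fraction of censored outcomes (default 0.2).
#' @param baseline_hazard Exponential baseline hazard (default 0.1 per time
#'   unit).
#' @param p_M1_base,p_M1_slope Logistic link of M1 (and N+) status to the
#'   latent EMT score: `P = plogis(p_M1_base + p_M1_slope * e)`.
#' @param seed Integer master seed; cell-line and tumor stages draw from
#'   deterministic sub-streams so either can be regenerated alone.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_entities = 5, lines_per_state_per_entity = 20,
                       n_tumor_entities = 3, n_tumors_per_entity = 300,
                       n_epi_markers = 50, n_mes_markers = 50,
                       n_entity_specific = 20, n_null = 900,
                       effect_size = 2.0, noise_sd = 0.5,
                       stroma_factor_range = c(10, 100),
                       purity_range = c(0.5, 0.95),
                       response_weight_range = c(0.3, 1.5),
                       stroma_epi_range = c(0.02, 0.3),
                       hazard_ratio_mes = 2.0, censor_rate = 0.2,
                       baseline_hazard = 0.1,
                       p_M1_base = -2.0, p_M1_slope = 3.0,
                       seed = 1) {
  stopifnot(n_entities >= 1, lines_per_state_per_entity >= 0,
            n_tumor_entities >= 1, n_tumors_per_entity >= 0,
            n_epi_markers >= 0, n_mes_markers >= 0,
            n_entity_specific >= 0, n_null >= 0,
            noise_sd > 0, length(stroma_factor_range) == 2,
            stroma_factor_range[1] >= 1,
            stroma_factor_range[1] <= stroma_factor_range[2],
            length(purity_range) == 2, purity_range[1] > 0,
            purity_range[1] <= purity_range[2], purity_range[2] <= 1,
            length(response_weight_range) == 2, response_weight_range[1] > 0,
            response_weight_range[1] <= response_weight_range[2],
            length(stroma_epi_range) == 2, stroma_epi_range[1] >= 0,
            stroma_epi_range[1] <= stroma_epi_range[2],
            hazard_ratio_mes > 0, censor_rate >= 0, censor_rate < 1,
            baseline_hazard > 0)
  structure(as.list(environment()), class = "sim_params")
}

entity_pool <- function(n) {
  pool <- c("COAD", "BRCA", "LUAD", "BLCA", "PAAD", "HNSC", "PRAD")
  if (n <= length(pool)) pool[seq_len(n)] else c(pool, paste0("ENT", seq_len(n - length(pool))))
}

# Gene universe shared by both compendia: anchors, planted markers,
# entity-specific genes (assigned round-robin over the cell-line entities),
# and nulls. Deterministic in the parameters, independent of the seed.
gene_universe <- function(params) {
  pad <- function(prefix, n) if (n > 0) sprintf("%s%03d", prefix, seq_len(n)) else character()
  ids <- c("CDH1", "VIM", pad("EPI", params$n_epi_markers),
           pad("MES", params$n_mes_markers),
           pad("ENT", params$n_entity_specific), pad("NUL", params$n_null))
  role <- c("anchor_epi", "anchor_mes",
            rep("epi_marker", params$n_epi_markers),
            rep("mes_marker", params$n_mes_markers),
            rep("entity_specific", params$n_entity_specific),
            rep("null", params$n_null))
  ents <- entity_pool(params$n_entities)
  target <- rep(NA_character_, length(ids))
  target[role == "entity_specific"] <-
    ents[(seq_len(params$n_entity_specific) - 1L) %% length(ents) + 1L]
  data.frame(gene_id = ids, role = role, target_entity = target,
             stringsAsFactors = FALSE)
}

new_truth_set <- function(gene_role, sample_state = NULL, emt_score = NULL,
                          purity = NULL) {
  structure(list(gene_role = gene_role, sample_state = sample_state,
                 emt_score = emt_score, purity = purity),
            class = "truth_set")
}

#' Simulate a cell-line compendium with planted EMT states
#'
#' Per entity, equal numbers of epithelial-state and mesenchymal-state lines.
#' Each gene gets a baseline log2 expression drawn once (uniform on [4, 10]);
#' planted epithelial markers (and the CDH1 anchor) are shifted up by
#' `effect_size` in epithelial-state lines, mesenchymal markers (and VIM) in
#' mesenchymal-state lines, entity-specific genes only in their designated
#' entity, nulls never. The two anchors share a common baseline and receive a
#' larger shift (`log2(10) + 8 * noise_sd`) so the 10-fold anchor-ratio rule
#' classifies every line correctly at the default noise level. Gaussian noise
#' of sd `noise_sd` is added per cell. Fully deterministic given the seed.
#'
#' @param params A [sim_params()] object.
#' @return A list with elements `expr` (a log2-scale [expression_matrix()])
#'   and `truth` (a `truth_set` with `gene_role` and `sample_state`).
#' @export
simulate_cell_lines <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  genes <- gene_universe(params)
  ents <- entity_pool(params$n_entities)
  n_per <- params$lines_per_state_per_entity
  with_seed(derive_seed(params$seed, 1L), {
    base <- stats::runif(nrow(genes), 4, 10)
    base[genes$role %in% c("anchor_epi", "anchor_mes")] <- 7
    anchor_shift <- log2(10) + 8 * params$noise_sd
    sample_id <- character(); entity <- character(); state <- character()
    for (ent in ents) {
      ids <- sprintf("CL_%s_%02d", ent, seq_len(2 * n_per))
      sample_id <- c(sample_id, ids)
      entity <- c(entity, rep(ent, 2 * n_per))
      state <- c(state, rep(c("epithelial", "mesenchymal"), each = n_per))
    }
    n <- length(sample_id)
    m <- matrix(base, nrow(genes), n)
    is_epi_state <- state == "epithelial"
    for (g in seq_len(nrow(genes))) {
      role <- genes$role[g]
      if (role == "epi_marker") {
        m[g, is_epi_state] <- m[g, is_epi_state] + params$effect_size
      } else if (role == "mes_marker") {
        m[g, !is_epi_state] <- m[g, !is_epi_state] + params$effect_size
      } else if (role == "anchor_epi") {
        m[g, is_epi_state] <- m[g, is_epi_state] + anchor_shift
      } else if (role == "anchor_mes") {
        m[g, !is_epi_state] <- m[g, !is_epi_state] + anchor_shift
      } else if (role == "entity_specific") {
        sel <- is_epi_state & entity == genes$target_entity[g]
        m[g, sel] <- m[g, sel] + params$effect_size
      }
    }
    m <- m + matrix(stats::rnorm(length(m), 0, params$noise_sd), nrow(m), ncol(m))
    dimnames(m) <- list(genes$gene_id, sample_id)
    expr <- expression_matrix(m, scale = "log2",
                              entity = stats::setNames(entity, sample_id))
    truth <- new_truth_set(
      gene_role = stats::setNames(genes$role, genes$gene_id),
      sample_state = stats::setNames(state, sample_id))
    attr(truth, "target_entity") <-
      stats::setNames(genes$target_entity, genes$gene_id)
    list(expr = expr, truth = truth)
  })
}

#' Simulate bulk-tumor cohorts with stromal contamination and outcomes
#'
#' Each tumor draws a latent EMT score `e ~ U(0, 1)` and a purity `rho` from
#' `purity_range`. Cancer-cell linear expression is baseline times a fold
#' response: epithelial markers and CDH1 respond by
#' `2^(effect_size * w * (1 - e))`, mesenchymal markers and VIM by
#' `2^(effect_size * w * e)` (per-gene responsiveness `w` from
#' `response_weight_range`, anchors at `w = 1`), entity-specific genes
#' respond like epithelial markers in their designated entity only, nulls are
#' flat. The stromal profile expresses VIM at baseline times the geometric
#' mean of `stroma_factor_range` (stromal cells carry the canonical
#' mesenchymal program at one to two orders of magnitude above cancer
#' cells), null and planted mesenchymal-marker genes at baseline (the
#' planted markers are cancer-cell-intrinsic), and epithelial-class genes at
#' a small per-gene fraction of baseline (`stroma_epi_range`; CDH1 at 0.1).
#' Bulk = `rho * cancer + (1 - rho) * stroma`, then multiplicative
#' log-normal noise (`noise_sd` in log2 space).
#'
#' Outcomes: overall and relapse-free survival are independent exponentials
#' with hazard `baseline_hazard * hazard_ratio_mes^e` and censoring tuned to
#' `censor_rate`; M and N status follow independent logistic links in `e`;
#' pseudo-subtypes CMS1-CMS4 are EMT-score quartiles (CMS4 = most
#' mesenchymal); the IHC score is a noisy 0-3 discretization of `1 - e`.
#'
#' @param params A [sim_params()] object.
#' @return A list with `expr` (linear-scale [expression_matrix()]),
#'   `clinical` (a [clinical_table()]) and `truth` (a `truth_set` with
#'   `gene_role`, `emt_score`, `purity`).
#' @export
simulate_bulk_tumors <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  genes <- gene_universe(params)
  ents <- entity_pool(params$n_tumor_entities)
  n_per <- params$n_tumors_per_entity
  with_seed(derive_seed(params$seed, 2L), {
    base_log2 <- stats::runif(nrow(genes), 4, 10)
    base_log2[genes$role %in% c("anchor_epi", "anchor_mes")] <- 7
    base <- 2^base_log2
    sample_id <- unlist(lapply(ents, function(ent) sprintf("TU_%s_%03d", ent, seq_len(n_per))))
    entity <- rep(ents, each = n_per)
    n <- length(sample_id)
    e <- stats::runif(n)
    rho <- stats::runif(n, params$purity_range[1], params$purity_range[2])
    s_vim <- sqrt(prod(params$stroma_factor_range))
    # per-gene responsiveness: markers differ in dynamic range; anchors keep w = 1
    w <- stats::runif(nrow(genes), params$response_weight_range[1],
                      params$response_weight_range[2])
    w[genes$role %in% c("anchor_epi", "anchor_mes")] <- 1
    stroma_floor <- stats::runif(nrow(genes), params$stroma_epi_range[1],
                                 params$stroma_epi_range[2])

    fold <- matrix(1, nrow(genes), n)
    for (g in seq_len(nrow(genes))) {
      role <- genes$role[g]
      if (role %in% c("epi_marker", "anchor_epi")) {
        fold[g, ] <- 2^(params$effect_size * w[g] * (1 - e))
      } else if (role %in% c("mes_marker", "anchor_mes")) {
        fold[g, ] <- 2^(params$effect_size * w[g] * e)
      } else if (role == "entity_specific") {
        sel <- entity == genes$target_entity[g]
        fold[g, sel] <- 2^(params$effect_size * w[g] * (1 - e[sel]))
      }
    }
    stroma_factor <- rep(1, nrow(genes))
    is_epi_class <- genes$role %in% c("epi_marker", "anchor_epi")
    stroma_factor[is_epi_class] <- stroma_floor[is_epi_class]
    stroma_factor[genes$role == "anchor_epi"] <- 0.1
    stroma_factor[genes$role == "anchor_mes"] <- s_vim
    cancer <- base * fold
    stroma <- base * stroma_factor
    bulk <- sweep(cancer, 2, rho, `*`) +
      outer(stroma, 1 - rho)
    bulk <- bulk * 2^matrix(stats::rnorm(length(bulk), 0, params$noise_sd),
                            nrow(bulk), ncol(bulk))
    dimnames(bulk) <- list(genes$gene_id, sample_id)
    expr <- expression_matrix(bulk, scale = "linear",
                              entity = stats::setNames(entity, sample_id))

    draw_surv <- function() {
      h <- params$baseline_hazard * params$hazard_ratio_mes^e
      t_event <- stats::rexp(n, rate = h)
      if (params$censor_rate > 0) {
        c_rate <- h * params$censor_rate / (1 - params$censor_rate)
        t_cens <- stats::rexp(n, rate = c_rate)
      } else {
        t_cens <- rep(Inf, n)
      }
      list(time = pmin(t_event, t_cens),
           event = as.integer(t_event <= t_cens))
    }
    os <- draw_surv()
    rfs <- draw_surv()
    p_m1 <- stats::plogis(params$p_M1_base + params$p_M1_slope * e)
    m_status <- ifelse(stats::runif(n) < p_m1, "M1", "M0")
    p_np <- stats::plogis(params$p_M1_base + params$p_M1_slope * e)
    n_status <- ifelse(stats::runif(n) < p_np, "Nplus", "N0")
    subtype <- paste0("CMS", findInterval(e, stats::quantile(e, c(0.25, 0.5, 0.75))) + 1L)
    ihc <- pmin(3L, pmax(0L, as.integer(round(3 * (1 - e) + stats::rnorm(n, 0, 0.5)))))
    clinical <- clinical_table(data.frame(
      sample_id = sample_id, entity = entity,
      m_status = m_status, n_status = n_status, subtype = subtype,
      os_time = os$time, os_event = os$event,
      rfs_time = rfs$time, rfs_event = rfs$event,
      ihc_score = ihc, stringsAsFactors = FALSE))
    truth <- new_truth_set(
      gene_role = stats::setNames(genes$role, genes$gene_id),
      emt_score = stats::setNames(e, sample_id),
      purity = stats::setNames(rho, sample_id))
    attr(truth, "target_entity") <-
      stats::setNames(genes$target_entity, genes$gene_id)
    list(expr = expr, clinical = clinical, truth = truth)
  })
}
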