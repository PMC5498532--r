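#' Run the full discovery pipeline on synthetic data
#'
#' Orchestrates the complete flow: simulate a cell-line compendium and bulk
#' tumor cohorts, run the anchor-ratio differential screen and the
#' anchor-correlation screen, intersect them into the shared signature, score
#' all tumors on each signature class, stratify tumors into epithelial-like
#' and mesenchymal-like groups by correlation-distance k-means, and test the
#' group difference in overall and relapse-free survival by the log-rank
#' test. Recovery of the planted gene roles is measured against the
#' generator's truth set. Fully deterministic given config and parameters.
#'
#' @param config A [screen_config()].
#' @param params A [sim_params()].
#' @param out_dir Optional output directory; when given, every stage's table
#'   is written as TSV (plus signature files and a JSON report) before the
#'   next stage begins.
#' @param genes_for_clustering Signature class used for stratification
#'   (`"both"`, `"epithelial"` or `"mesenchymal"`).
#' @return A list of class `emt_run_report`; see Details. Key elements:
#'   `signature` (shared [gene_signature()]), `counts` (per-stage ledger),
#'   `recovery` (per-role sensitivity/specificity), `survival` (log-rank
#'   results), `stratification`, `manifest` (written files with MD5 sums).
#' @export
run_pipeline <- function(config = screen_config(), params = sim_params(),
                         out_dir = NULL, genes_for_clustering = "both") {
  write_out <- !is.null(out_dir)
  if (write_out && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- character()
  emit <- function(obj, name, writer) {
    if (!write_out) return(invisible(NULL))
    path <- file.path(out_dir, name)
    writer(obj, path)
    manifest <<- c(manifest, path)
    invisible(path)
  }
  write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }

  log_info("stage 1/6: simulating cell-line compendium")
  cl <- simulate_cell_lines(params)
  emit(cl$expr, "cell_lines_expr.tsv", function(o, p) {
    write_expression(o, p, entity_path = file.path(out_dir, "cell_lines_entities.tsv"))
    manifest <<- c(manifest, file.path(out_dir, "cell_lines_entities.tsv"))
  })

  log_info("stage 2/6: simulating bulk-tumor cohorts")
  tu <- simulate_bulk_tumors(params)
  emit(tu$expr, "tumors_expr.tsv", function(o, p) {
    write_expression(o, p, entity_path = file.path(out_dir, "tumors_entities.tsv"))
    manifest <<- c(manifest, file.path(out_dir, "tumors_entities.tsv"))
  })
  emit(tu$clinical, "tumors_clinical.tsv", function(o, p) write_clinical(o, p))

  log_info("stage 3/6: cell-line screen (ratio > ", config$ratio_threshold,
           ", alpha = ", config$alpha, ")")
  cls <- cell_line_screen(cl$expr, config)
  for (ent in names(cls$results)) {
    if (!is.null(cls$results[[ent]])) {
      emit(cls$results[[ent]], sprintf("cell_line_screen_%s.tsv", ent), write_tsv)
    }
  }
  emit(cls$signature, "signature_cell_line.tsv", function(o, p) write_signature(o, p))

  log_info("stage 4/6: tumor screen (r > ", config$r_pos, " / r < ", config$r_neg, ")")
  tus <- tumor_screen(tu$expr, config)
  for (ent in names(tus$profiles)) {
    emit(tus$profiles[[ent]], sprintf("tumor_screen_%s.tsv", ent), write_tsv)
  }
  emit(tus$signature, "signature_tumor.tsv", function(o, p) write_signature(o, p))

  log_info("stage 5/6: intersecting screens")
  shared <- intersect_screens(cls$signature, tus$signature)
  emit(shared, "signature_shared.tsv", function(o, p) write_signature(o, p))

  log_info("stage 6/6: scoring, stratification, survival")
  strat <- NULL
  surv <- NULL
  scores <- NULL
  if (length(shared$epithelial) + length(shared$mesenchymal) >= 2) {
    strat <- kmeans_stratify(tu$expr, shared, config, genes = genes_for_clustering)
    scores <- strat[, c("sample_id", "score_epi", "score_mes")]
    emit(strat, "stratification.tsv", write_tsv)
    cli <- as.data.frame(tu$clinical)
    idx <- match(strat$sample_id, cli$sample_id)
    surv <- list()
    for (ep in c("os", "rfs")) {
      tm <- cli[[paste0(ep, "_time")]][idx]
      ev <- cli[[paste0(ep, "_event")]][idx]
      grp <- strat$cluster
      lr <- logrank_test(tm[grp == "epi_group"], ev[grp == "epi_group"],
                         tm[grp == "mes_group"], ev[grp == "mes_group"])
      surv[[ep]] <- list(
        logrank = lr,
        km = list(epi_group = km_estimate(tm[grp == "epi_group"], ev[grp == "epi_group"]),
                  mes_group = km_estimate(tm[grp == "mes_group"], ev[grp == "mes_group"])))
    }
    emit(data.frame(endpoint = c("os", "rfs"),
                    chisq = c(surv$os$logrank$statistic, surv$rfs$logrank$statistic),
                    p_value = c(surv$os$logrank$p_value, surv$rfs$logrank$p_value)),
         "survival_logrank.tsv", write_tsv)
  } else {
    warning("shared signature too small to stratify; survival stage skipped")
  }

  roles <- tu$truth$gene_role
  recovery <- signature_recovery(shared, roles)
  counts <- list(
    cell_lines = list(
      n_lines = ncol(cl$expr$values),
      states = as.list(table(cls$calls$state)),
      flagged_per_entity = lapply(cls$results, function(r) {
        if (is.null(r)) NULL else as.list(table(r$flag))
      }),
      signature = list(epithelial = length(cls$signature$epithelial),
                       mesenchymal = length(cls$signature$mesenchymal))),
    tumors = list(
      n_tumors = ncol(tu$expr$values),
      classified_per_entity = lapply(tus$profiles, function(p) as.list(table(p$class))),
      signature = list(epithelial = length(tus$signature$epithelial),
                       mesenchymal = length(tus$signature$mesenchymal))),
    shared = list(epithelial = length(shared$epithelial),
                  mesenchymal = length(shared$mesenchymal)))

  report <- structure(list(
    config = unclass(config), params = unclass(params),
    counts = counts, recovery = recovery,
    signature = shared,
    stratification = strat, scores = scores, survival = surv,
    truth = list(cell_lines = cl$truth, tumors = tu$truth),
    manifest = NULL), class = "emt_run_report")

  if (write_out) {
    json <- report
    json$signature <- list(epithelial = shared$epithelial,
                           mesenchymal = shared$mesenchymal)
    json$stratification <- NULL; json$truth <- NULL; json$scores <- NULL
    json$survival <- if (is.null(surv)) NULL else lapply(surv, function(s) {
      list(logrank_chisq = s$logrank$statistic, logrank_p = s$logrank$p_value)
    })
    report_path <- file.path(out_dir, "report.json")
    jsonlite::write_json(json, report_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    manifest <- c(manifest, report_path)
    report$manifest <- data.frame(
      path = basename(manifest),
      md5 = unname(tools::md5sum(manifest)), stringsAsFactors = FALSE)
    jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Recovery of planted gene roles by a signature
#'
#' Sensitivity and false-call counts of a signature measured against the
#' generator's truth roles: the fraction of planted epithelial (mesenchymal)
#' markers present in the epithelial (mesenchymal) list, and how many
#' entity-specific or null genes slipped in.
#'
#' @param signature A [gene_signature()].
#' @param gene_role Named character vector of true roles (from a truth set).
#' @return A list with `epi_sensitivity`, `mes_sensitivity`,
#'   `entity_specific_in_signature`, `null_in_signature`.
#' @export
signature_recovery <- function(signature, gene_role) {
  in_sig <- c(signature$epithelial, signature$mesenchymal)
  epi_planted <- names(gene_role)[gene_role == "epi_marker"]
  mes_planted <- names(gene_role)[gene_role == "mes_marker"]
  list(
    epi_sensitivity = if (length(epi_planted)) {
      mean(epi_planted %in% signature$epithelial)
    } else NA_real_,
    mes_sensitivity = if (length(mes_planted)) {
      mean(mes_planted %in% signature$mesenchymal)
    } else NA_real_,
    entity_specific_in_signature =
      sum(gene_role[in_sig] == "entity_specific", na.rm = TRUE),
    null_in_signature = sum(gene_role[in_sig] == "null", na.rm = TRUE))
}
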