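#' Construct an expression matrix
#'
#' The central container of the package: a genes-by-samples numeric matrix
#' with a declared scale (`"linear"` or `"log2"`) and a cancer-entity label
#' per sample. RNA-seq abundance estimates (e.g. RSEM) are typically on the
#' linear scale; microarray summaries (e.g. RMA) on the log2 scale. The scale
#' flag lets downstream screens convert explicitly instead of guessing.
#'
#' @param values Numeric matrix, genes as rows (rownames = gene ids), samples
#'   as columns (colnames = sample ids). No missing values.
#' @param scale `"linear"` or `"log2"`. Linear values must be non-negative.
#' @param entity Character vector of cancer-entity labels: either one label
#'   per sample (optionally named by sample id) or a single label recycled.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `scale`, `entity` (named character vector).
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' em <- expression_matrix(m, scale = "linear", entity = "COAD")
#' dim(em$values)
#' @export
expression_matrix <- function(values, scale = c("linear", "log2"), entity) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicated gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicated sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  }
  if (anyNA(values)) stop("`values` contains missing entries")
  if (scale == "linear" && any(values < 0)) {
    stop("linear-scale values must be >= 0")
  }
  if (length(entity) == 1) entity <- rep(entity, ncol(values))
  if (length(entity) != ncol(values)) {
    stop("`entity` must have one label per sample")
  }
  entity <- as.character(entity)
  if (!is.null(names(entity))) {
    if (!setequal(names(entity), colnames(values))) {
      stop("names of `entity` do not match sample ids")
    }
    entity <- entity[colnames(values)]
  } else {
    names(entity) <- colnames(values)
  }
  structure(list(values = values, scale = scale, entity = entity),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  tab <- table(x$entity)
  cat("entities:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read a genes-by-samples expression table
#'
#' Reads a delimited table (first column gene ids, header sample ids).
#' Duplicate gene rows are collapsed by their mean (multi-probe arrays);
#' genes with any missing value are dropped with a warning. Duplicated
#' sample ids or non-numeric cells are fatal.
#'
#' @param path Path to a TSV/CSV file.
#' @param scale Declared scale of the stored values (`"linear"` or `"log2"`).
#' @param entity Entity labels: a single label, a named character vector, or
#'   the path of a two-column TSV (`sample_id`, `entity`).
#' @param sep Field separator (default tab).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, scale = c("linear", "log2"), entity = "unspecified",
                            sep = "\t") {
  scale <- match.arg(scale)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          quote = "", comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression table needs a gene-id column plus >=1 sample")
  gene_ids <- as.character(df[[1]])
  samp_ids <- colnames(df)[-1]
  if (anyDuplicated(samp_ids)) {
    stop("duplicated sample ids in header: ",
         paste(unique(samp_ids[duplicated(samp_ids)]), collapse = ", "))
  }
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & v != "NA")
      if (length(bad)) {
        stop(sprintf("non-numeric cell at row %d (gene '%s'), column '%s'",
                     bad[1], gene_ids[bad[1]], samp_ids[j]))
      }
      vals[[j]] <- vn
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- gene_ids
  # complete-case genes: the screens are per-gene, imputation would inject structure
  has_na <- rowSums(is.na(m)) > 0
  if (any(has_na)) {
    warning(sprintf("dropping %d gene(s) with missing values: %s",
                    sum(has_na), paste(utils::head(gene_ids[has_na], 5), collapse = ", ")))
    m <- m[!has_na, , drop = FALSE]
  }
  if (anyDuplicated(rownames(m))) {
    dup <- unique(rownames(m)[duplicated(rownames(m))])
    log_info("collapsing ", length(dup), " duplicated gene id(s) by mean")
    counts <- table(rownames(m))
    m <- rowsum(m, group = rownames(m))
    m <- m / as.vector(counts[rownames(m)])
  }
  if (is.character(entity) && length(entity) == 1 && file.exists(entity)) {
    ann <- utils::read.table(entity, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
    entity <- stats::setNames(as.character(ann$entity), ann$sample_id)
  }
  expression_matrix(m, scale = scale, entity = entity)
}

#' Write an expression matrix to a TSV file
#'
#' @param x An [expression_matrix()].
#' @param path Output path; genes as rows, first column `gene_id`.
#' @param entity_path Optional path for a `sample_id`/`entity` annotation TSV.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, entity_path = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(entity_path)) {
    utils::write.table(
      data.frame(sample_id = names(x$entity), entity = unname(x$entity)),
      entity_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Convert an expression matrix to the linear scale
#'
#' log2 values are mapped through `2^x`; linear input is returned unchanged.
#' The anchor-ratio rule of the cell-line screen is stated in fold units, so
#' log2 compendia must pass through this before ratios are formed.
#'
#' @param x An [expression_matrix()].
#' @return An [expression_matrix()] with `scale = "linear"`.
#' @examples
#' m <- matrix(c(0, 3), 1, 2, dimnames = list("g", c("a", "b")))
#' to_linear(expression_matrix(m, "log2", "X"))$values  # 1, 8
#' @export
to_linear <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$scale == "linear") return(x)
  expression_matrix(2^x$values, scale = "linear", entity = x$entity)
}

#' Convert an expression matrix to the log2 scale
#'
#' Linear values are mapped through `log2(x + pseudocount)`. Differential
#' testing and signature scoring operate on the log2 scale; the pseudocount
#' (default 1) keeps zero counts finite.
#'
#' @param x An [expression_matrix()].
#' @param pseudocount Added to linear values before the log (default 1).
#' @return An [expression_matrix()] with `scale = "log2"`.
#' @export
to_log2 <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$scale == "log2") return(x)
  expression_matrix(log2(x$values + pseudocount), scale = "log2", entity = x$entity)
}

#' Construct a gene signature
#'
#' Disjoint epithelial and mesenchymal gene lists with optional per-gene
#' provenance (which screens/entities support each gene, with their
#' statistics).
#'
#' @param epithelial,mesenchymal Character vectors of gene ids.
#' @param provenance Named list, one entry per gene id.
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(epithelial = character(), mesenchymal = character(),
                           provenance = list()) {
  epithelial <- unique(as.character(epithelial))
  mesenchymal <- unique(as.character(mesenchymal))
  overlap <- intersect(epithelial, mesenchymal)
  if (length(overlap)) {
    stop("genes in both epithelial and mesenchymal lists: ",
         paste(overlap, collapse = ", "))
  }
  structure(list(epithelial = epithelial, mesenchymal = mesenchymal,
                 provenance = provenance),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature: %d epithelial, %d mesenchymal gene(s)\n",
              length(x$epithelial), length(x$mesenchymal)))
  invisible(x)
}

#' Write / read a gene signature
#'
#' The signature is stored as a two-column TSV (`gene_id`, `class`) with an
#' optional JSON provenance sidecar (`<path>.provenance.json`). Reading back
#' reproduces the signature exactly, provenance included.
#'
#' @param sig A [gene_signature()].
#' @param path Path of the signature TSV.
#' @return `write_signature()` returns `path` invisibly; `read_signature()`
#'   returns a [gene_signature()].
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "gene_signature"))
  df <- data.frame(
    gene_id = c(sig$epithelial, sig$mesenchymal),
    class = c(rep("epithelial", length(sig$epithelial)),
              rep("mesenchymal", length(sig$mesenchymal))),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(sig$provenance)) {
    jsonlite::write_json(sig$provenance, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("gene_id", "class") %in% colnames(df))) {
    stop("signature file must have columns gene_id, class: ", path)
  }
  bad <- which(!df$class %in% c("epithelial", "mesenchymal"))
  if (length(bad)) {
    stop(sprintf("malformed signature file %s at line %d: class '%s'",
                 path, bad[1] + 1L, df$class[bad[1]]))
  }
  prov_path <- paste0(path, ".provenance.json")
  prov <- if (file.exists(prov_path)) {
    jsonlite::read_json(prov_path, simplifyVector = TRUE)
  } else {
    list()
  }
  gene_signature(epithelial = df$gene_id[df$class == "epithelial"],
                 mesenchymal = df$gene_id[df$class == "mesenchymal"],
                 provenance = prov)
}

#' Validate and construct a clinical annotation table
#'
#' Per-sample outcome annotations: entity, distant-metastasis status (M0/M1),
#' nodal status (N0/Nplus), optional molecular subtype label, overall and
#' relapse-free survival time/event pairs, optional ordinal IHC score (0-3).
#'
#' @param df A data.frame with at least a `sample_id` column; missing optional
#'   columns are filled with `NA`/`"unknown"`.
#' @return A validated data.frame of class `clinical_table`.
#' @export
clinical_table <- function(df) {
  stopifnot(is.data.frame(df), "sample_id" %in% colnames(df))
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in clinical table")
  defaults <- list(entity = NA_character_, m_status = "unknown",
                   n_status = "unknown", subtype = NA_character_,
                   os_time = NA_real_, os_event = NA_integer_,
                   rfs_time = NA_real_, rfs_event = NA_integer_,
                   ihc_score = NA_integer_)
  for (col in names(defaults)) {
    if (!col %in% colnames(df)) df[[col]] <- defaults[[col]]
  }
  if (!all(df$m_status %in% c("M0", "M1", "unknown"))) {
    stop("m_status must be M0, M1 or unknown")
  }
  if (!all(df$n_status %in% c("N0", "Nplus", "unknown"))) {
    stop("n_status must be N0, Nplus or unknown")
  }
  for (ep in c("os", "rfs")) {
    tm <- df[[paste0(ep, "_time")]]
    ev <- df[[paste0(ep, "_event")]]
    if (any(!is.na(ev) & !ev %in% c(0, 1))) stop(ep, "_event must be 0/1")
    if (any(!is.na(tm) & tm < 0)) stop(ep, "_time must be >= 0")
    if (any(!is.na(ev) & is.na(tm))) {
      stop("recorded ", ep, "_event requires a recorded ", ep, "_time")
    }
  }
  if (any(!is.na(df$ihc_score) & !df$ihc_score %in% 0:3)) {
    stop("ihc_score must be in 0..3")
  }
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read / write a clinical annotation table
#'
#' @param path Path of a TSV keyed by `sample_id`.
#' @return `read_clinical()` returns a [clinical_table()];
#'   `write_clinical()` returns `path` invisibly.
#' @export
read_clinical <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  clinical_table(df)
}

#' @rdname read_clinical
#' @param x A [clinical_table()].
#' @export
write_clinical <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Screen configuration
#'
#' All thresholds of the discovery procedure in one place: the 10-fold
#' anchor-ratio rule and t-test alpha of the cell-line screen, the Spearman
#' thresholds (r > 0.1 vs the epithelial anchor, r < -0.1 vs the mesenchymal
#' anchor) of the tumor screen, and the k-means settings (k = 2, at most 50
#' iterations, Pearson-correlation distance) for patient stratification.
#'
#' @param ratio_threshold Anchor fold-ratio defining epithelial-like /
#'   mesenchymal-like cell lines (default 10; strict inequality).
#' @param alpha Two-sided significance level of the per-entity t-test
#'   (default 0.05, uncorrected; the all-entity intersection is the de facto
#'   multiplicity control).
#' @param r_pos,r_neg Spearman thresholds of the tumor screen (defaults
#'   0.1 and -0.1; strict inequalities).
#' @param anchor_epithelial,anchor_mesenchymal Anchor gene ids (defaults
#'   `"CDH1"`, `"VIM"`).
#' @param k,max_iter,n_restarts k-means settings (defaults 2, 50, 10).
#' @param welch Use Welch's t instead of the pooled-variance Student's t
#'   (default `FALSE`).
#' @param p_adjust Multiple-testing adjustment applied per entity before
#'   flagging (`"none"` default, or any [stats::p.adjust()] method).
#' @param require_all_entities If `TRUE` (default), an entity that cannot be
#'   screened (e.g. too few classified lines) is fatal rather than dropped.
#' @param min_samples Per-entity sample floor for the tumor correlation
#'   screen (default 10).
#' @param seed Integer seed controlling all randomized steps.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(ratio_threshold = 10, alpha = 0.05,
                          r_pos = 0.1, r_neg = -0.1,
                          anchor_epithelial = "CDH1", anchor_mesenchymal = "VIM",
                          k = 2, max_iter = 50, n_restarts = 10,
                          welch = FALSE, p_adjust = "none",
                          require_all_entities = TRUE, min_samples = 10,
                          seed = 1) {
  stopifnot(ratio_threshold > 1, alpha > 0, alpha < 1,
            r_neg < 0, r_pos > 0, k >= 2, max_iter >= 1, n_restarts >= 1,
            min_samples >= 3)
  structure(list(ratio_threshold = ratio_threshold, alpha = alpha,
                 r_pos = r_pos, r_neg = r_neg,
                 anchor_epithelial = anchor_epithelial,
                 anchor_mesenchymal = anchor_mesenchymal,
                 k = as.integer(k), max_iter = as.integer(max_iter),
                 n_restarts = as.integer(n_restarts), welch = welch,
                 p_adjust = p_adjust,
                 require_all_entities = require_all_entities,
                 min_samples = as.integer(min_samples),
                 seed = as.integer(seed)),
            class = "screen_config")
}

#' Read a screen configuration from a YAML file
#'
#' Keys mirror the arguments of [screen_config()]; absent keys keep their
#' defaults.
#'
#' @param path Path of a YAML file.
#' @return A [screen_config()].
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(screen_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(screen_config, vals)
}
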