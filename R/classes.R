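#' Construct an expression matrix
#'
#' The basic expression container of the package: a dense numeric gene-by-sample
#' matrix (genes as rows, samples as columns) tagged with the scale its values
#' live on. All downstream stages check the `scale` attribute rather than
#' guessing from the values.
#'
#' @param values numeric matrix with unique rownames (gene ids) and unique
#'   colnames (sample/AOI/patient ids).
#' @param scale one of `"counts"`, `"q3_normalized"`, `"log2"`.
#' @return the matrix with class `expr_matrix` and attribute `scale`.
#' @export
expr_matrix <- function(values, scale = c("counts", "q3_normalized", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    dsp_stop("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    dsp_stop("values must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) dsp_stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(values))) dsp_stop("duplicate sample identifiers")
  if (anyNA(values)) dsp_stop("missing expression values are not allowed")
  if (scale == "counts" && any(values < 0)) {
    dsp_stop("negative values are not allowed on the counts scale")
  }
  structure(values, scale = scale, class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [scale: %s]\n",
              nrow(x), ncol(x), attr(x, "scale")))
  invisible(x)
}

expr_scale <- function(m) attr(m, "scale")

# Rebuild an expr_matrix after subsetting (subsetting drops attributes).
as_expr_matrix <- function(values, scale) expr_matrix(as.matrix(values), scale)

#' Validate a table of AOI annotations
#'
#' Checks the mandatory DSP annotation columns and their enumerated values:
#' `mask` in CD68/CD3/CD20, `tissue` in RLT/DLBCL, `region` in
#' GC/IF/LZ/DZ/NONE (NONE only for DLBCL tissue), `saturation` in \[0, 1\].
#'
#' @param df data.frame of per-AOI annotations.
#' @return the validated data.frame with class `aoi_annotations`.
#' @export
aoi_annotations <- function(df) {
  required <- c("aoi_id", "roi_id", "patient_id", "tissue", "mask", "region",
                "batch", "raw_reads", "saturation")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    dsp_stop("annotation table lacks columns: %s", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$aoi_id)) dsp_stop("duplicate aoi_id in annotations")
  check_enum <- function(col, allowed) {
    bad <- which(!df[[col]] %in% allowed)
    if (length(bad)) {
      dsp_stop("invalid %s value '%s' in annotation row %d (allowed: %s)",
               col, df[[col]][bad[1]], bad[1], paste(allowed, collapse = ", "))
    }
  }
  check_enum("tissue", c("RLT", "DLBCL"))
  check_enum("mask", c("CD68", "CD3", "CD20"))
  check_enum("region", c("GC", "IF", "LZ", "DZ", "NONE"))
  bad <- which(df$region == "NONE" & df$tissue != "DLBCL")
  if (length(bad)) {
    dsp_stop("region NONE is only allowed for DLBCL tissue (row %d)", bad[1])
  }
  if (!is.numeric(df$raw_reads) || any(df$raw_reads < 0)) {
    dsp_stop("raw_reads must be non-negative numbers")
  }
  if (!is.numeric(df$saturation) || anyNA(df$saturation) ||
      any(df$saturation < 0 | df$saturation > 1)) {
    bad <- which(!is.finite(df$saturation) | df$saturation < 0 | df$saturation > 1)[1]
    dsp_stop("saturation out of [0, 1] in annotation row %s", bad)
  }
  class(df) <- unique(c("aoi_annotations", class(df)))
  df
}

#' Construct a DSP experiment
#'
#' Bundle of an AOI count matrix, AOI annotations, a negative-probe count grid
#' and (for synthetic data) the planted ground truth. Columns of `counts` and
#' `neg_probes` must align with `annotations$aoi_id`.
#'
#' @param counts [expr_matrix] on the counts scale.
#' @param annotations an [aoi_annotations] table.
#' @param neg_probes numeric probe-by-AOI matrix aligned with `counts` columns.
#' @param truth optional list of planted ground truth (see
#'   [simulate_dsp_experiment()]).
#' @return a `dsp_experiment` object.
#' @export
dsp_experiment <- function(counts, annotations, neg_probes, truth = NULL) {
  annotations <- aoi_annotations(as.data.frame(annotations))
  if (expr_scale(counts) != "counts") dsp_stop("counts must be on the counts scale")
  if (!setequal(colnames(counts), annotations$aoi_id) ||
      anyDuplicated(annotations$aoi_id)) {
    dsp_stop("every counts sample must have exactly one annotation row")
  }
  annotations <- annotations[match(colnames(counts), annotations$aoi_id), , drop = FALSE]
  rownames(annotations) <- NULL
  if (!identical(colnames(neg_probes), colnames(counts))) {
    dsp_stop("neg_probes columns must align with counts columns")
  }
  structure(list(counts = counts, annotations = annotations,
                 neg_probes = neg_probes, truth = truth),
            class = "dsp_experiment")
}

#' @export
print.dsp_experiment <- function(x, ...) {
  ann <- x$annotations
  cat(sprintf("dsp_experiment: %d genes x %d AOIs (%d negative probes)\n",
              nrow(x$counts), ncol(x$counts), nrow(x$neg_probes)))
  cat(sprintf("  tissues: %s\n",
              paste(sprintf("%s=%d", names(table(ann$tissue)), table(ann$tissue)),
                    collapse = ", ")))
  cat(sprintf("  masks:   %s\n",
              paste(sprintf("%s=%d", names(table(ann$mask)), table(ann$mask)),
                    collapse = ", ")))
  if (!is.null(x$truth)) cat("  planted truth recorded\n")
  invisible(x)
}

# Subset a dsp_experiment to a set of AOI ids (keeps alignment invariants).
subset_aois <- function(exp, aoi_ids) {
  keep <- colnames(exp$counts) %in% aoi_ids
  dsp_experiment(
    as_expr_matrix(exp$counts[, keep, drop = FALSE], "counts"),
    exp$annotations[exp$annotations$aoi_id %in% aoi_ids, , drop = FALSE],
    exp$neg_probes[, keep, drop = FALSE],
    truth = exp$truth
  )
}

#' Construct a gene signature
#'
#' @param name signature name.
#' @param genes non-empty character vector of unique gene ids.
#' @param description free-text description (the GMT second field).
#' @return a `gene_signature` object.
#' @export
gene_signature <- function(name, genes, description = "") {
  if (!is.character(genes) || length(genes) == 0) dsp_stop("genes must be non-empty")
  if (anyDuplicated(genes)) dsp_stop("duplicate genes in signature '%s'", name)
  structure(list(name = name, genes = genes, description = description),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Construct a bulk cohort dataset
#'
#' Gene-by-patient log2 expression plus survival (overall-survival time in
#' months and event indicator) and optional per-patient category labels
#' (e.g. cell-of-origin GCB/ABC/UNC).
#'
#' @param expression [expr_matrix] on the log2 scale, columns are patients.
#' @param survival data.frame with columns patient_id, time (> 0), event (0/1).
#' @param labels optional data.frame with columns patient_id, category.
#' @return a `cohort_dataset` object.
#' @export
cohort_dataset <- function(expression, survival, labels = NULL) {
  if (expr_scale(expression) != "log2") dsp_stop("cohort expression must be log2 scale")
  need <- c("patient_id", "time", "event")
  if (!all(need %in% names(survival))) {
    dsp_stop("survival table needs columns: %s", paste(need, collapse = ", "))
  }
  if (any(survival$time <= 0)) dsp_stop("survival times must be positive")
  if (!all(survival$event %in% c(0, 1))) dsp_stop("event must be 0 or 1")
  if (!setequal(colnames(expression), survival$patient_id)) {
    dsp_stop("expression columns and survival patients must match")
  }
  survival <- survival[match(colnames(expression), survival$patient_id), , drop = FALSE]
  rownames(survival) <- NULL
  if (!is.null(labels)) {
    if (!all(c("patient_id", "category") %in% names(labels))) {
      dsp_stop("labels table needs columns patient_id, category")
    }
    labels <- labels[match(colnames(expression), labels$patient_id), , drop = FALSE]
    rownames(labels) <- NULL
  }
  structure(list(expression = expression, survival = survival, labels = labels),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("cohort_dataset: %d genes x %d patients, %d events (%.0f%% censored)\n",
              nrow(x$expression), ncol(x$expression), sum(x$survival$event),
              100 * mean(x$survival$event == 0)))
  invisible(x)
}
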