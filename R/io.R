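#' Read a gene-by-sample expression table
#'
#' Two on-disk formats are supported: a TSV with a header row of sample ids and
#' a first column of gene ids, or a MatrixMarket coordinate file accompanied by
#' `<path>.genes.txt` and `<path>.samples.txt` index files (one id per line).
#'
#' @param path file path.
#' @param format `"tsv"` or `"mtx"`.
#' @param scale scale tag for the returned matrix (default `"counts"`).
#' @return an [expr_matrix].
#' @export
read_expression_table <- function(path, format = c("tsv", "mtx"),
                                  scale = "counts") {
  format <- match.arg(format)
  if (!file.exists(path)) dsp_stop("file not found: %s", path)
  if (format == "tsv") {
    first <- readLines(path, n = 1L)
    if (length(first) == 0L || !nzchar(first)) dsp_stop("parse error: empty file %s", path)
    df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                            colClasses = "character")
    if (ncol(df) < 2L) dsp_stop("parse error: %s has no sample columns", path)
    genes <- df[[1L]]
    samples <- colnames(df)[-1L]
    if (anyDuplicated(genes)) dsp_stop("format error: duplicate gene ids in %s", path)
    if (anyDuplicated(samples)) dsp_stop("format error: duplicate sample ids in %s", path)
    vals <- matrix(NA_real_, nrow(df), length(samples),
                   dimnames = list(genes, samples))
    for (j in seq_along(samples)) {
      v <- suppressWarnings(as.numeric(df[[j + 1L]]))
      bad <- which(is.na(v) & !is.na(df[[j + 1L]]))
      if (length(bad) || anyNA(df[[j + 1L]])) {
        bad <- c(bad, which(is.na(df[[j + 1L]])))[1L]
        dsp_stop("parse error: non-numeric cell at row %d, column '%s' in %s",
                 bad, samples[j], path)
      }
      vals[, j] <- v
    }
    expr_matrix(vals, scale)
  } else {
    gene_file <- paste0(path, ".genes.txt")
    sample_file <- paste0(path, ".samples.txt")
    if (!file.exists(gene_file) || !file.exists(sample_file)) {
      dsp_stop("mtx index files missing: %s / %s", gene_file, sample_file)
    }
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(gene_file)
    samples <- readLines(sample_file)
    if (anyDuplicated(genes)) dsp_stop("format error: duplicate gene ids for %s", path)
    if (anyDuplicated(samples)) dsp_stop("format error: duplicate sample ids for %s", path)
    if (nrow(m) != length(genes) || ncol(m) != length(samples)) {
      dsp_stop("mtx dimensions do not match index files for %s", path)
    }
    dimnames(m) <- list(genes, samples)
    expr_matrix(m, scale)
  }
}

#' Write an expression table
#'
#' TSV writing uses 15 significant digits so that write/read round trips are
#' exact for counts and bit-stable for doubles.
#'
#' @param m an [expr_matrix].
#' @param path output path.
#' @param format `"tsv"` or `"mtx"`.
#' @export
write_expression_table <- function(m, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(m),
                     format(unclass(m), digits = 15, trim = TRUE,
                            scientific = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("gene_id", colnames(m))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(unclass(m), sparse = TRUE), path)
    writeLines(rownames(m), paste0(path, ".genes.txt"))
    writeLines(colnames(m), paste0(path, ".samples.txt"))
  }
  invisible(path)
}

#' Read AOI annotations from TSV
#'
#' @param path TSV with the mandatory columns aoi_id, roi_id, patient_id,
#'   tissue, mask, region, batch, raw_reads, saturation (area and nuclei
#'   optional).
#' @return validated [aoi_annotations] data.frame.
#' @export
read_aoi_annotations <- function(path) {
  if (!file.exists(path)) dsp_stop("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  aoi_annotations(df)
}

#' Write AOI annotations to TSV
#' @param ann an [aoi_annotations] table.
#' @param path output path.
#' @export
write_aoi_annotations <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene signatures from a GMT file
#'
#' GMT dialect: one signature per line, tab-separated fields
#' `name, description, gene1, gene2, ...` with at least one gene.
#'
#' @param path GMT file path.
#' @return named list of [gene_signature] objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) dsp_stop("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sigs <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      dsp_stop("parse error: GMT line %d has fewer than 3 fields", i)
    }
    gene_signature(fields[1L], fields[-(1:2)], fields[2L])
  })
  names(sigs) <- vapply(sigs, `[[`, "", "name")
  sigs
}

#' Write gene signatures to a GMT file
#' @param signatures list of [gene_signature] objects.
#' @param path output path.
#' @export
write_gmt <- function(signatures, path) {
  lines <- vapply(signatures, function(s) {
    paste(c(s$name, if (nzchar(s$description)) s$description else "na", s$genes),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a bulk cohort from expression, survival and label tables
#'
#' Patients are aligned across the three tables; patients present in the
#' expression table but missing survival are dropped with a logged warning.
#' Zero overlapping patients is an error.
#'
#' @param expr_path TSV of gene-by-patient log2 expression.
#' @param survival_path TSV with columns patient_id, time, event.
#' @param labels_path optional TSV with columns patient_id, category.
#' @return a [cohort_dataset].
#' @export
read_cohort <- function(expr_path, survival_path, labels_path = NULL) {
  expr <- read_expression_table(expr_path, "tsv", scale = "log2")
  surv <- utils::read.delim(survival_path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("patient_id", "time", "event") %in% names(surv))) {
    dsp_stop("survival table needs columns patient_id, time, event")
  }
  if (!all(surv$event %in% c(0, 1))) {
    dsp_stop("validation error: event values must be 0 or 1")
  }
  if (any(surv$time <= 0)) dsp_stop("validation error: times must be positive")
  common <- intersect(colnames(expr), surv$patient_id)
  if (length(common) == 0L) dsp_stop("zero overlapping patients between tables")
  dropped <- setdiff(colnames(expr), common)
  if (length(dropped)) {
    dsp_log("read_cohort: dropped %d of %d patients lacking survival data",
            length(dropped), ncol(expr))
  }
  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- utils::read.delim(labels_path, sep = "\t", stringsAsFactors = FALSE)
    if (!all(c("patient_id", "category") %in% names(labels))) {
      dsp_stop("labels table needs columns patient_id, category")
    }
    common <- intersect(common, labels$patient_id)
    if (length(common) == 0L) dsp_stop("zero overlapping patients between tables")
    labels <- labels[labels$patient_id %in% common, , drop = FALSE]
  }
  cohort_dataset(
    as_expr_matrix(expr[, common, drop = FALSE], "log2"),
    surv[surv$patient_id %in% common, , drop = FALSE],
    labels
  )
}
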