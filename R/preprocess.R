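#' Quality-control thresholds
#'
#' Defaults follow standard DSP practice: AOIs need at least 10,000 raw reads
#' and 50% sequencing saturation, at least 5% of target genes detected; genes
#' must exceed the negative-probe limit of quantitation in at least 5% of AOIs.
#'
#' @param min_raw_reads minimum raw reads per AOI (strict: `< min` removed).
#' @param min_saturation minimum sequencing saturation (strict: `< min` removed).
#' @param min_gene_frac minimum fraction of target genes detected per AOI.
#' @param loq_detect_frac minimum fraction of AOIs in which a gene must exceed
#'   its AOI's LOQ to be retained.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_raw_reads = 10000, min_saturation = 0.5,
                          min_gene_frac = 0.05, loq_detect_frac = 0.05) {
  vals <- c(min_raw_reads, min_saturation, min_gene_frac, loq_detect_frac)
  if (any(vals <= 0)) dsp_stop("all QC thresholds must be positive")
  if (min_saturation > 1 || min_gene_frac > 1 || loq_detect_frac > 1) {
    dsp_stop("fractional thresholds must be <= 1")
  }
  structure(list(min_raw_reads = min_raw_reads, min_saturation = min_saturation,
                 min_gene_frac = min_gene_frac, loq_detect_frac = loq_detect_frac),
            class = "qc_thresholds")
}

#' Filter AOIs on sequencing quality
#'
#' Removes AOIs with fewer than `min_raw_reads` raw reads, saturation below
#' `min_saturation`, or a detected-gene fraction (nonzero counts) below
#' `min_gene_frac`. All comparisons are strict (`<`), so an AOI exactly at a
#' threshold is retained.
#'
#' @param exp a [dsp_experiment].
#' @param thr a [qc_thresholds] object.
#' @return the filtered [dsp_experiment].
#' @export
filter_aois <- function(exp, thr = qc_thresholds()) {
  ann <- exp$annotations
  detected <- colMeans(exp$counts > 0)
  fail_reads <- ann$raw_reads < thr$min_raw_reads
  fail_sat <- ann$saturation < thr$min_saturation
  fail_genes <- detected[ann$aoi_id] < thr$min_gene_frac
  keep <- !(fail_reads | fail_sat | fail_genes)
  dsp_log("filter_aois: %d/%d AOIs pass (removed: %d low reads, %d low saturation, %d low gene fraction)",
          sum(keep), nrow(ann), sum(fail_reads), sum(fail_sat), sum(fail_genes))
  if (!any(keep)) dsp_stop("empty experiment after QC")
  if (all(keep)) return(exp)
  subset_aois(exp, ann$aoi_id[keep])
}

#' Per-AOI limit of quantitation from negative probes
#'
#' `LOQ(aoi) = geomean(neg + eps) * geoSD(neg + eps)^2`, the platform
#' convention of a geometric mean plus two geometric standard deviations of
#' the negative-probe counts. geoSD uses the n-1 denominator on the log scale.
#'
#' @param neg_probes probe-by-AOI count matrix (>= 2 probes per AOI).
#' @param eps pseudo-count guarding zero probes (default 0.5).
#' @return named numeric vector of per-AOI LOQs (class `loq_table`).
#' @export
compute_loq <- function(neg_probes, eps = 0.5) {
  if (is.null(dim(neg_probes)) || nrow(neg_probes) < 2) {
    dsp_stop("at least 2 negative probes per AOI are required")
  }
  lg <- log(neg_probes + eps)
  loq <- exp(colMeans(lg)) * exp(apply(lg, 2, stats::sd))^2
  if (any(loq <= 0)) dsp_stop("non-positive LOQ computed")
  structure(loq, class = "loq_table")
}

#' Filter genes by the limit of quantitation
#'
#' A gene is retained iff its count exceeds the AOI's LOQ in at least
#' `loq_detect_frac` of AOIs (`>=` comparison on the fraction).
#'
#' @param exp a [dsp_experiment].
#' @param loq a [compute_loq()] table aligned to the experiment's AOIs.
#' @param thr a [qc_thresholds] object.
#' @return the gene-filtered [dsp_experiment].
#' @export
filter_genes_by_loq <- function(exp, loq = NULL, thr = qc_thresholds()) {
  if (is.null(loq)) loq <- compute_loq(exp$neg_probes)
  aois <- colnames(exp$counts)
  if (!all(aois %in% names(loq))) dsp_stop("LOQ table does not cover all AOIs")
  above <- sweep(unclass(exp$counts), 2, unclass(loq)[aois], `>`)
  frac <- rowMeans(above)
  keep <- frac >= thr$loq_detect_frac
  dsp_log("filter_genes_by_loq: %d/%d genes pass the LOQ filter",
          sum(keep), length(keep))
  if (!any(keep)) dsp_stop("zero genes retained after LOQ filtering")
  exp$counts <- as_expr_matrix(exp$counts[keep, , drop = FALSE], "counts")
  exp
}

#' Third-quartile (Q3) normalization
#'
#' Divides the counts in each AOI by that AOI's third quartile (type-7 linear
#' interpolation over the retained genes), then multiplies by the geometric
#' mean of the third quartiles of all AOIs. After normalization every AOI's Q3
#' equals that geometric mean, so the operation is idempotent.
#'
#' @param m an [expr_matrix] on the counts scale.
#' @return an [expr_matrix] with scale `q3_normalized`.
#' @export
q3_normalize <- function(m) {
  if (expr_scale(m) != "counts") dsp_stop("q3_normalize expects counts")
  q3 <- apply(unclass(m), 2, stats::quantile, probs = 0.75, type = 7, names = FALSE)
  zero <- which(q3 <= 0)
  if (length(zero)) {
    dsp_stop("Q3 is zero for AOI '%s'", colnames(m)[zero[1]])
  }
  out <- sweep(unclass(m), 2, q3, `/`) * geomean(q3)
  expr_matrix(out, "q3_normalized")
}

#' Log2 transform with pseudo-count
#'
#' @param m an [expr_matrix] with scale `q3_normalized`.
#' @param pseudo pseudo-count added before taking log2 (default 1).
#' @return an [expr_matrix] with scale `log2`.
#' @export
log_transform <- function(m, pseudo = 1) {
  if (expr_scale(m) != "q3_normalized") {
    dsp_stop("log_transform expects a q3_normalized matrix")
  }
  if (any(m < 0)) dsp_stop("negative input to log_transform")
  expr_matrix(log2(unclass(m) + pseudo), "log2")
}

#' Remove batch effects from a log2 matrix
#'
#' Per gene, a linear model with batch indicators plus preserved biological
#' design indicators is fitted and only the fitted batch terms are subtracted,
#' using the first batch as the reference level. With a single batch the input
#' is returned unchanged. A batch perfectly confounded with a preserved label
#' is an error.
#'
#' @param m an [expr_matrix] on the log2 scale.
#' @param batch per-sample batch labels.
#' @param preserve data.frame (or vector) of biological design labels to
#'   protect, typically the mask (plus region/tissue where applicable).
#' @return the batch-corrected [expr_matrix] (log2 scale).
#' @export
remove_batch_effect <- function(m, batch, preserve) {
  if (expr_scale(m) != "log2") dsp_stop("remove_batch_effect expects log2 data")
  batch <- as.factor(batch)
  if (length(batch) != ncol(m)) dsp_stop("batch labels must match sample count")
  if (nlevels(batch) < 2) return(m)
  if (is.null(dim(preserve))) preserve <- data.frame(g1 = preserve)
  preserve <- as.data.frame(lapply(preserve, as.factor))
  preserve <- preserve[, vapply(preserve, nlevels, 1L) > 1, drop = FALSE]
  design <- if (ncol(preserve)) stats::model.matrix(~., data = preserve) else
    matrix(1, ncol(m), 1)
  # reduce preserve-internal collinearity (e.g. tissue implied by region)
  dqr <- qr(design)
  design <- design[, dqr$pivot[seq_len(dqr$rank)], drop = FALSE]
  bmat <- stats::model.matrix(~batch)[, -1, drop = FALSE]
  if (qr(cbind(design, bmat))$rank < ncol(design) + ncol(bmat)) {
    dsp_stop("confounded design: batch is not separable from preserved labels")
  }
  # per-gene least squares on [preserved design | batch indicators]; only the
  # fitted batch terms (relative to the first batch) are subtracted
  fit <- stats::lm.fit(cbind(design, bmat), t(unclass(m)))
  bcoef <- fit$coefficients[ncol(design) + seq_len(ncol(bmat)), , drop = FALSE]
  out <- unclass(m) - t(bmat %*% bcoef)
  expr_matrix(out, "log2")
}

#' Flag outlier AOIs in PCA space
#'
#' Advisory flags for AOIs whose PC1 or PC2 coordinate lies more than `k_mads`
#' median-absolute-deviations from the median; the caller decides removal.
#'
#' @param m an [expr_matrix] on the log2 scale (>= 3 AOIs).
#' @param k_mads MAD multiplier (default 4; `Inf` flags nothing).
#' @return named logical vector of per-AOI flags.
#' @export
pca_outlier_flags <- function(m, k_mads = 4) {
  if (ncol(m) < 3) dsp_stop("at least 3 AOIs required for PCA outlier flagging")
  x <- t(unclass(m))
  keep <- apply(x, 2, stats::var) > 0
  if (!any(keep)) {
    return(stats::setNames(rep(FALSE, ncol(m)), colnames(m)))
  }
  pc <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  flags <- rep(FALSE, ncol(m))
  for (j in seq_len(min(2L, ncol(pc$x)))) {
    v <- pc$x[, j]
    md <- stats::mad(v)
    if (md > 0 && is.finite(k_mads)) {
      flags <- flags | (abs(v - stats::median(v)) > k_mads * md)
    }
  }
  dsp_log("pca_outlier_flags: %d/%d AOIs flagged", sum(flags), length(flags))
  stats::setNames(flags, colnames(m))
}

#' Run the full DSP preprocessing chain
#'
#' Fixed order: AOI QC, LOQ gene filter, Q3 normalization, log2 transform,
#' batch harmonization (preserving mask, tissue and region), PCA outlier
#' flagging (advisory, applied when `drop_outliers = TRUE`).
#'
#' @param exp a [dsp_experiment].
#' @param thr a [qc_thresholds] object.
#' @param pseudo log2 pseudo-count.
#' @param k_mads PCA outlier MAD multiplier.
#' @param drop_outliers whether flagged AOIs are removed (default FALSE:
#'   flags are advisory and never applied silently).
#' @return list with `log2` (harmonized [expr_matrix]), `q3` (normalized
#'   matrix before logging), `annotations`, `flags` and the filtered
#'   experiment `exp`.
#' @export
preprocess_dsp <- function(exp, thr = qc_thresholds(), pseudo = 1, k_mads = 4,
                           drop_outliers = FALSE) {
  exp <- filter_aois(exp, thr)
  loq <- compute_loq(exp$neg_probes)
  exp <- filter_genes_by_loq(exp, loq, thr)
  q3 <- q3_normalize(exp$counts)
  lg <- log_transform(q3, pseudo)
  ann <- exp$annotations
  lg <- remove_batch_effect(lg, ann$batch,
                            preserve = ann[, c("mask", "tissue", "region")])
  flags <- pca_outlier_flags(lg, k_mads)
  if (drop_outliers && any(flags)) {
    keep <- names(flags)[!flags]
    exp <- subset_aois(exp, keep)
    q3 <- as_expr_matrix(q3[, keep, drop = FALSE], "q3_normalized")
    lg <- as_expr_matrix(lg[, keep, drop = FALSE], "log2")
    ann <- exp$annotations
  }
  list(log2 = lg, q3 = q3, annotations = ann, flags = flags, exp = exp)
}
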