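#' Weighted signature score per patient
#'
#' For a paired signature (up-direction and down-direction of one contrast),
#' the per-patient score is
#' `score = sum_i -log10(p_i) * x_i * I_i`
#' over the union of the pair's genes, where `p_i` is the moderated-t p-value,
#' `I_i = +1/-1` the sign of the gene's log2 fold change in the originating
#' contrast and `x_i` the patient's expression of gene i. By default `x_i` is
#' the gene-wise z-score of log2 expression across the cohort
#' (`standardize = FALSE` uses the raw log2 values). Genes absent from the
#' cohort are dropped with a warning; less than 50% overlap is an error.
#'
#' @param cohort a [cohort_dataset].
#' @param pair a single `macrosig` or a list of two (up/down pair with
#'   disjoint genes).
#' @param standardize z-score expression per gene (default TRUE).
#' @return named numeric vector of per-patient scores; attributes `n_genes`
#'   and `dropped` record gene usage.
#' @export
signature_score <- function(cohort, pair, standardize = TRUE) {
  if (inherits(pair, "macrosig")) pair <- list(pair)
  entries <- do.call(rbind, lapply(pair, function(s) s$entries))
  if (anyDuplicated(entries$gene)) {
    dsp_stop("signature pair genes must be disjoint")
  }
  x <- unclass(cohort$expression)
  present <- entries$gene %in% rownames(x)
  if (mean(present) < 0.5) {
    dsp_stop("only %d/%d signature genes present in cohort (need >= 50%%); missing: %s",
             sum(present), nrow(entries),
             paste(utils::head(entries$gene[!present], 5), collapse = ", "))
  }
  dropped <- entries$gene[!present]
  if (length(dropped)) {
    dsp_warn("signature_score: %d signature genes absent from cohort, dropped",
             length(dropped))
  }
  entries <- entries[present, , drop = FALSE]
  xs <- x[entries$gene, , drop = FALSE]
  if (standardize) {
    mu <- rowMeans(xs)
    sdv <- apply(xs, 1, stats::sd)
    flat <- sdv == 0
    if (any(flat)) {
      dsp_warn("signature_score: %d zero-variance genes dropped", sum(flat))
      entries <- entries[!flat, , drop = FALSE]
      xs <- xs[!flat, , drop = FALSE]
      mu <- mu[!flat]; sdv <- sdv[!flat]
      if (nrow(entries) == 0) dsp_stop("no usable signature genes after dropping")
    }
    xs <- (xs - mu) / sdv
  }
  scores <- colSums(xs * (entries$weight * entries$sign))
  if (any(!is.finite(scores))) dsp_stop("non-finite scores computed")
  attr(scores, "n_genes") <- nrow(entries)
  attr(scores, "dropped") <- dropped
  scores
}

#' Tertile stratification of signature scores
#'
#' Cut points at the 1/3 and 2/3 type-7 quantiles; `score <= q1` is `low`,
#' `score > q2` is `high`, otherwise `mid` (boundary ties fall to the lower
#' group).
#'
#' @param scores named numeric scores (>= 6 patients, not all identical).
#' @return a `stratification` data.frame: patient_id, score, group.
#' @export
tertile_stratify <- function(scores) {
  if (length(scores) < 6) dsp_stop("need at least 6 patients to stratify")
  if (length(unique(scores)) == 1) dsp_stop("degenerate score distribution")
  q <- stats::quantile(scores, probs = c(1, 2) / 3, type = 7, names = FALSE)
  group <- ifelse(scores <= q[1], "low", ifelse(scores > q[2], "high", "mid"))
  out <- data.frame(patient_id = names(scores), score = as.numeric(scores),
                    group = factor(group, levels = c("low", "mid", "high")),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "cutpoints") <- q
  class(out) <- c("stratification", "data.frame")
  out
}

#' @export
print.stratification <- function(x, ...) {
  tab <- table(x$group)
  cat(sprintf("stratification: n = %d (low %d / mid %d / high %d), cutpoints %.3g, %.3g\n",
              nrow(x), tab["low"], tab["mid"], tab["high"],
              attr(x, "cutpoints")[1], attr(x, "cutpoints")[2]))
  invisible(x)
}

#' Single-cell quality-control filter
#'
#' Removes cells with fewer than `min_genes` detected genes or more than
#' `max_mito_frac` mitochondrial counts; then removes genes detected in fewer
#' than `min_cells` of the remaining cells.
#'
#' @param cells counts [expr_matrix], genes by cells.
#' @param mito_gene_ids mitochondrial gene ids.
#' @param min_genes detected-genes threshold (strict `<` removal; default 200).
#' @param max_mito_frac mitochondrial-fraction threshold (strict `>` removal;
#'   default 0.10).
#' @param min_cells detection threshold for genes (strict `<` removal;
#'   default 3).
#' @return the filtered counts [expr_matrix].
#' @export
sc_qc_filter <- function(cells, mito_gene_ids, min_genes = 200,
                         max_mito_frac = 0.10, min_cells = 3) {
  x <- unclass(cells)
  mito <- intersect(mito_gene_ids, rownames(x))
  n_detected <- colSums(x > 0)
  mito_frac <- if (length(mito)) colSums(x[mito, , drop = FALSE]) / pmax(colSums(x), 1)
               else rep(0, ncol(x))
  keep_cells <- n_detected >= min_genes & mito_frac <= max_mito_frac
  dsp_log("sc_qc_filter: %d/%d cells pass QC", sum(keep_cells), ncol(x))
  if (!any(keep_cells)) dsp_stop("all cells removed by QC")
  x <- x[, keep_cells, drop = FALSE]
  keep_genes <- rowSums(x > 0) >= min_cells
  dsp_log("sc_qc_filter: %d/%d genes detected in >= %d cells",
          sum(keep_genes), nrow(x), min_cells)
  as_expr_matrix(x[keep_genes, , drop = FALSE], "counts")
}

#' Library-size log-normalization for single cells
#'
#' `log1p(count / cell_total * scale_factor)`, the conventional single-cell
#' normalization feeding [module_score()].
#'
#' @param cells counts [expr_matrix].
#' @param scale_factor target library size (default 1e4).
#' @return normalized matrix tagged as `log2` scale for downstream use.
#' @export
sc_lognormalize <- function(cells, scale_factor = 1e4) {
  x <- unclass(cells)
  tot <- colSums(x)
  if (any(tot == 0)) dsp_stop("cells with zero total counts; run sc_qc_filter first")
  expr_matrix(log1p(sweep(x, 2, tot, `/`) * scale_factor), "log2")
}

#' Per-cell module score with expression-matched controls
#'
#' Genes are binned into `n_bins` equal-frequency bins of mean expression;
#' for every signature gene, `n_ctrl` control genes are sampled (seeded) from
#' its bin. The score is the per-cell mean of signature-gene expression minus
#' the mean over all sampled control genes. Cells with score above
#' `call_threshold` are called "expressing".
#'
#' @param cells log-normalized [expr_matrix] (e.g. [sc_lognormalize()]).
#' @param sig a `macrosig` or [gene_signature] (typically the [top_k()] set).
#' @param n_bins number of expression bins (default 25).
#' @param n_ctrl controls sampled per signature gene (default 100).
#' @param call_threshold expressing-call threshold on the score (default 0.1).
#' @param seed RNG seed for control sampling.
#' @return data.frame: cell, score, expressing.
#' @export
module_score <- function(cells, sig, n_bins = 25, n_ctrl = 100,
                         call_threshold = 0.1, seed = 1L) {
  genes <- if (inherits(sig, "macrosig")) sig$entries$gene else sig$genes
  x <- unclass(cells)
  present <- intersect(genes, rownames(x))
  if (length(present) == 0) dsp_stop("no signature gene present in the matrix")
  if (length(present) < length(genes)) {
    dsp_warn("module_score: %d signature genes absent, dropped",
             length(genes) - length(present))
  }
  mu <- rowMeans(x)
  n_bins <- min(n_bins, length(mu))
  bin <- ceiling(rank(mu, ties.method = "first") / (length(mu) / n_bins))
  set.seed(seed)
  ctrl <- unlist(lapply(present, function(g) {
    pool <- rownames(x)[bin == bin[g]]
    pool <- setdiff(pool, g)
    if (length(pool) == 0) pool <- rownames(x)[rownames(x) != g]
    sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
  }))
  score <- colMeans(x[present, , drop = FALSE]) - colMeans(x[ctrl, , drop = FALSE])
  data.frame(cell = colnames(x), score = as.numeric(score),
             expressing = score > call_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}
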