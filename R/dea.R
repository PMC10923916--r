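#' Collapse duplicate AOIs by averaging
#'
#' AOIs sharing (patient_id, mask, region, tissue) are technical duplicates
#' (duplicate cores); they are replaced by their per-gene arithmetic mean on
#' the log2 scale. The merged AOI keeps the shared annotation keys.
#'
#' @param m an [expr_matrix] on the log2 scale.
#' @param annotations [aoi_annotations] covering the matrix columns.
#' @return list with `m` (collapsed matrix) and `annotations` (one row per
#'   merged AOI).
#' @export
collapse_duplicates <- function(m, annotations) {
  ann <- annotations[match(colnames(m), annotations$aoi_id), , drop = FALSE]
  key <- paste(ann$patient_id, ann$mask, ann$region, ann$tissue, sep = "|")
  if (!anyDuplicated(key)) {
    return(list(m = m, annotations = ann))
  }
  groups <- split(seq_along(key), key)
  groups <- groups[order(vapply(groups, min, 1L))]  # preserve input order
  vals <- vapply(groups, function(ix) rowMeans(unclass(m)[, ix, drop = FALSE]),
                 numeric(nrow(m)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(m))
  rownames(vals) <- rownames(m)
  new_ann <- ann[vapply(groups, min, 1L), , drop = FALSE]
  colnames(vals) <- new_ann$aoi_id
  rownames(new_ann) <- NULL
  dsp_log("collapse_duplicates: %d AOIs collapsed into %d",
          ncol(m), length(groups))
  list(m = expr_matrix(vals, "log2"), annotations = new_ann)
}

#' Two-group per-gene contrast fit
#'
#' Per gene: `log2FC = mean_A - mean_B`, pooled residual variance `s2` and
#' residual degrees of freedom `df = n_A + n_B - 2`.
#'
#' @param m an [expr_matrix] on the log2 scale.
#' @param groups two-level factor/character labels aligned to columns; the
#'   first level (or `level_a`) is group A.
#' @param level_a optional name of group A (contrast direction A minus B).
#' @return data.frame (gene, mean_A, mean_B, log2FC, s2, df) plus attributes
#'   `n_A`, `n_B`.
#' @export
fit_group_contrast <- function(m, groups, level_a = NULL) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) dsp_stop("groups must have exactly two levels")
  if (is.null(level_a)) level_a <- lev[1]
  if (!level_a %in% lev) dsp_stop("level_a not found in groups")
  a <- groups == level_a
  n_a <- sum(a); n_b <- sum(!a)
  if (n_a < 2 || n_b < 2) dsp_stop("each group needs at least 2 samples")
  x <- unclass(m)
  mean_a <- rowMeans(x[, a, drop = FALSE])
  mean_b <- rowMeans(x[, !a, drop = FALSE])
  ss_a <- rowSums((x[, a, drop = FALSE] - mean_a)^2)
  ss_b <- rowSums((x[, !a, drop = FALSE] - mean_b)^2)
  df <- n_a + n_b - 2
  out <- data.frame(gene = rownames(m), mean_A = mean_a, mean_B = mean_b,
                    log2FC = mean_a - mean_b, s2 = (ss_a + ss_b) / df,
                    df = df, row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_A") <- n_a
  attr(out, "n_B") <- n_b
  out
}

# Newton inversion of the trigamma function (solves trigamma(y) = x).
trigamma_inverse <- function(x) {
  stopifnot(all(x > 0))
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Empirical-Bayes shrinkage of per-gene variances
#'
#' Estimates the prior (d0, s0^2) of a scaled inverse-chi-square variance
#' prior by matching the first two moments of log(s^2) to the theoretical
#' log-F moments (digamma/trigamma based), then returns posterior variances
#' `(d0 s0^2 + df s^2) / (d0 + df)`. If the trigamma inversion has no positive
#' solution (observed spread at or below the sampling spread), d0 is infinite
#' and all posterior variances equal s0^2.
#'
#' @param s2 per-gene residual variances (>= 10 genes with df >= 1).
#' @param df residual degrees of freedom (scalar or per-gene).
#' @return list with `d0`, `s0_sq`, `post_var` (per-gene posterior variances).
#' @export
eb_shrink_variances <- function(s2, df) {
  df <- rep_len(df, length(s2))
  usable <- which(df >= 1 & s2 > 0)
  if (all(s2 == 0)) dsp_stop("degenerate variances: all s2 are zero")
  if (length(usable) < 10) dsp_stop("need at least 10 genes with df >= 1 and s2 > 0")
  if (length(usable) < length(s2)) {
    dsp_warn("eb_shrink_variances: %d genes with zero variance or df < 1 excluded from prior estimation",
             length(s2) - length(usable))
  }
  z <- log(s2[usable])
  e <- z - digamma(df[usable] / 2) + log(df[usable] / 2)
  ebar <- mean(e)
  v <- stats::var(e) * (length(e) - 1) / length(e) - mean(trigamma(df[usable] / 2))
  if (is.finite(v) && v > 0) {
    d0 <- 2 * trigamma_inverse(v)
    s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
    post <- (d0 * s0_sq + df * s2) / (d0 + df)
  } else {
    # observed spread no larger than the sampling spread: infinite prior df,
    # prior variance = pooled mean variance (equals the common value when all
    # s2 coincide)
    d0 <- Inf
    s0_sq <- mean(s2[usable])
    post <- rep(s0_sq, length(s2))
  }
  list(d0 = d0, s0_sq = s0_sq, post_var = post)
}

#' Moderated t-test
#'
#' `t_mod = log2FC / sqrt(post_var * (1/n_A + 1/n_B))` with a two-sided
#' p-value from a t distribution on `d0 + df` degrees of freedom (standard
#' normal when d0 is infinite). A zero posterior variance yields p = 0 when
#' log2FC differs from zero and p = 1 otherwise, with a warning.
#'
#' @param contrast output of [fit_group_contrast()].
#' @param prior list with `d0` and `post_var` (from [eb_shrink_variances()];
#'   `d0 = 0` reproduces the ordinary pooled two-sample t-test when
#'   `post_var = s2`).
#' @return a `dea_result` data.frame: gene, log2FC, mean_A, mean_B, t_mod, p,
#'   adj_p, df_total.
#' @export
moderated_t_test <- function(contrast, prior) {
  n_a <- attr(contrast, "n_A"); n_b <- attr(contrast, "n_B")
  post <- prior$post_var
  if (length(post) != nrow(contrast)) dsp_stop("posterior variances misaligned")
  se <- sqrt(post * (1 / n_a + 1 / n_b))
  df_total <- prior$d0 + contrast$df
  t_mod <- ifelse(se > 0, contrast$log2FC / se, 0)
  zero <- which(se == 0)
  if (length(zero)) {
    dsp_warn("moderated_t_test: %d genes with zero posterior variance", length(zero))
  }
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  if (length(zero)) {
    p[zero] <- ifelse(contrast$log2FC[zero] != 0, 0, 1)
    t_mod[zero] <- ifelse(contrast$log2FC[zero] != 0,
                          sign(contrast$log2FC[zero]) * Inf, 0)
  }
  out <- data.frame(gene = contrast$gene, log2FC = contrast$log2FC,
                    mean_A = contrast$mean_A, mean_B = contrast$mean_B,
                    t_mod = t_mod, p = p, adj_p = bh_adjust(p),
                    df_total = if (length(df_total) == 1)
                      rep(df_total, nrow(contrast)) else df_total,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "prior") <- prior[c("d0", "s0_sq")]
  attr(out, "n_A") <- n_a
  attr(out, "n_B") <- n_b
  class(out) <- c("dea_result", "data.frame")
  out
}

#' @export
print.dea_result <- function(x, alpha = 0.05, lfc_min = 0.58, ...) {
  pr <- attr(x, "prior")
  cat(sprintf("dea_result: %d genes (prior d0 = %.3g, s0^2 = %.3g)\n",
              nrow(x), pr$d0, pr$s0_sq))
  cat(sprintf("  %d up / %d down at adj_p < %g, |log2FC| > %g\n",
              sum(x$adj_p < alpha & x$log2FC > lfc_min),
              sum(x$adj_p < alpha & x$log2FC < -lfc_min), alpha, lfc_min))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (sorted `p * m / rank`, cumulative
#' minimum from the largest p, capped at 1, returned in input order).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  check_probs(p, "p-values")
  stats::p.adjust(p, method = "BH")
}

#' Run a two-group moderated-t differential expression analysis
#'
#' Subsets the preprocessed DSP data to one mask and one two-group spatial
#' contrast, collapses duplicate cores by averaging, fits the per-gene
#' two-group contrast, shrinks variances empirically and returns moderated-t
#' results with BH adjustment.
#'
#' @param m an [expr_matrix] on the log2 scale (typically
#'   `preprocess_dsp(...)$log2`).
#' @param annotations matching [aoi_annotations].
#' @param contrast name in `GC_vs_IF`, `LZ_vs_DZ`, `RLT_vs_DLBCL`, or a list
#'   like those from `dsp_contrasts()`.
#' @param mask mask to restrict to (default the contrast's own mask).
#' @return a `dea_result`.
#' @export
run_dea <- function(m, annotations, contrast = "GC_vs_IF", mask = NULL) {
  if (is.character(contrast)) {
    all_ct <- dsp_contrasts()
    if (!contrast %in% names(all_ct)) {
      dsp_stop("unknown contrast '%s' (available: %s)", contrast,
               paste(names(all_ct), collapse = ", "))
    }
    ct <- all_ct[[contrast]]
  } else ct <- contrast
  if (is.null(mask)) mask <- ct$mask
  ann <- annotations[match(colnames(m), annotations$aoi_id), , drop = FALSE]
  side <- function(s) ann$mask == mask & ann$tissue == s$tissue & ann$region == s$region
  in_a <- side(ct$A); in_b <- side(ct$B)
  keep <- in_a | in_b
  if (sum(in_a) < 2 || sum(in_b) < 2) dsp_stop("each contrast group needs >= 2 AOIs")
  sub <- as_expr_matrix(m[, keep, drop = FALSE], "log2")
  coll <- collapse_duplicates(sub, ann[keep, , drop = FALSE])
  ann2 <- coll$annotations
  grp <- ifelse(ann2$tissue == ct$A$tissue & ann2$region == ct$A$region, "A", "B")
  fit <- fit_group_contrast(coll$m, grp, level_a = "A")
  prior <- eb_shrink_variances(fit$s2, fit$df)
  moderated_t_test(fit, prior)
}
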