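#' Aggregate signature expression per AOI
#'
#' Per-AOI mean of the signature genes' log2 expression; signature genes
#' absent from the matrix are dropped with a warning.
#'
#' @param m an [expr_matrix] on the log2 scale.
#' @param sig a [gene_signature].
#' @return named numeric vector, one value per AOI.
#' @export
aggregate_signature_expression <- function(m, sig) {
  present <- intersect(sig$genes, rownames(m))
  if (length(present) == 0) {
    dsp_stop("no gene of signature '%s' present in the matrix", sig$name)
  }
  missing <- setdiff(sig$genes, present)
  if (length(missing)) {
    dsp_warn("signature '%s': %d genes absent from matrix and dropped",
             sig$name, length(missing))
  }
  colMeans(unclass(m)[present, , drop = FALSE])
}

#' One-sided Kolmogorov-Smirnov mask enrichment
#'
#' Two-sample KS test comparing the per-AOI signature values of the target
#' mask against all other masks, alternative "target stochastically greater"
#' (the target CDF lies below). The statistic D is the one-sided supremum of
#' the ECDF difference.
#'
#' @param values per-AOI numeric values (e.g. from
#'   [aggregate_signature_expression()]).
#' @param masks per-AOI mask labels.
#' @param target_mask the mask claimed to be enriched.
#' @param alternative `"greater"` (default, one-sided enrichment) or
#'   `"two.sided"`.
#' @return list with `statistic` (D), `p`, group sizes.
#' @export
ks_mask_enrichment <- function(values, masks, target_mask,
                               alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  x <- values[masks == target_mask]
  y <- values[masks != target_mask]
  if (length(x) < 3 || length(y) < 3) {
    dsp_stop("need at least 3 AOIs in target and non-target groups")
  }
  # stats::ks.test 'less' tests that the CDF of x lies below y's,
  # i.e. target stochastically greater.
  alt <- if (alternative == "greater") "less" else "two.sided"
  kt <- suppressWarnings(stats::ks.test(x, y, alternative = alt))
  list(statistic = unname(kt$statistic), p = kt$p.value,
       n_target = length(x), n_other = length(y))
}

#' Validate masks via KS enrichment of hallmark signatures
#'
#' For each (signature, mask) pair in `mask_map`, tests whether the
#' signature's aggregate expression is stochastically greater in the matching
#' mask's AOIs than elsewhere; p-values are BH-adjusted across the whole
#' family.
#'
#' @param m an [expr_matrix] on the log2 scale.
#' @param masks per-AOI mask labels aligned to `colnames(m)`.
#' @param signatures named list of [gene_signature] objects.
#' @param mask_map named character vector mapping signature name to its
#'   expected mask; defaults to the packaged hallmark map (macrophage ->
#'   CD68, T cell -> CD3, B cell -> CD20).
#' @return data.frame with one row per (signature, mask) comparison:
#'   signature, mask, D, p, adj_p.
#' @export
validate_masks <- function(m, masks, signatures,
                           mask_map = c(macrophage = "CD68", t_cell = "CD3",
                                        b_cell = "CD20")) {
  rows <- lapply(names(mask_map), function(sn) {
    if (!sn %in% names(signatures)) dsp_stop("signature '%s' not supplied", sn)
    vals <- aggregate_signature_expression(m, signatures[[sn]])
    r <- ks_mask_enrichment(vals, masks, mask_map[[sn]])
    data.frame(signature = sn, mask = mask_map[[sn]], D = r$statistic,
               p = r$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out
}

#' Packaged hallmark mask-marker signatures
#'
#' Reads the GMT of macrophage (CD68, CD163, FCGR1A, CSF1R), T-cell (CD3D,
#' CD3E, UBASH3A, CD2, TRBC2) and B-cell (MS4A1, CD79A, CD79B, CD19, PAX5)
#' marker sets shipped with the package.
#'
#' @return named list of [gene_signature] objects.
#' @export
hallmark_mask_signatures <- function() {
  read_gmt(system.file("extdata", "hallmark_masks.gmt", package = "dspmacro",
                       mustWork = TRUE))
}
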