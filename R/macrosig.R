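#' Select differentially expressed genes
#'
#' Up set: `adj_p < alpha` and `log2FC > lfc_min`; down set: `adj_p < alpha`
#' and `log2FC < -lfc_min`. Both inequalities are strict, so a gene exactly at
#' a threshold is excluded.
#'
#' @param dea a `dea_result`.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param lfc_min absolute log2 fold-change threshold (default 0.58).
#' @return list with character vectors `up` and `down`.
#' @export
select_degs <- function(dea, alpha = 0.05, lfc_min = 0.58) {
  list(up = dea$gene[dea$adj_p < alpha & dea$log2FC > lfc_min],
       down = dea$gene[dea$adj_p < alpha & dea$log2FC < -lfc_min])
}

#' Per-mask percentile ranks of mean Q3-normalized expression
#'
#' For each mask, per-gene mean expression across that mask's AOIs is ranked
#' (ties averaged) and converted to a percentile `rank / n_genes`.
#'
#' @param m an [expr_matrix] with scale `q3_normalized`.
#' @param masks per-AOI mask labels aligned to columns.
#' @return gene-by-mask matrix of percentiles in (0, 1\].
#' @export
percentile_ranks <- function(m, masks) {
  if (nrow(m) < 2) dsp_stop("need at least 2 genes to rank")
  masks <- as.character(masks)
  levs <- unique(masks)
  out <- sapply(levs, function(mk) {
    cols <- masks == mk
    if (!any(cols)) dsp_stop("mask '%s' has zero AOIs", mk)
    mu <- rowMeans(unclass(m)[, cols, drop = FALSE])
    rank(mu, ties.method = "average") / nrow(m)
  })
  rownames(out) <- rownames(m)
  out
}

#' B-cell contamination filter
#'
#' Removes genes whose percentile rank of mean expression is strictly greater
#' in the contaminant mask (CD20, B cells) than in the source mask (CD68,
#' macrophages). Equal percentiles are retained.
#'
#' @param genes candidate gene set.
#' @param ranks matrix from [percentile_ranks()].
#' @param source_mask source mask column (default `"CD68"`).
#' @param contaminant_mask contaminant mask column (default `"CD20"`).
#' @return the filtered gene set; removed genes are logged.
#' @export
contamination_filter <- function(genes, ranks, source_mask = "CD68",
                                 contaminant_mask = "CD20") {
  if (!all(c(source_mask, contaminant_mask) %in% colnames(ranks))) {
    dsp_stop("ranks must contain columns '%s' and '%s'", source_mask, contaminant_mask)
  }
  missing <- setdiff(genes, rownames(ranks))
  if (length(missing)) {
    dsp_stop("genes absent from the rank table: %s",
             paste(utils::head(missing, 5), collapse = ", "))
  }
  removed <- genes[ranks[genes, contaminant_mask] > ranks[genes, source_mask]]
  if (length(removed)) {
    dsp_log("contamination_filter: removed %d/%d genes (%s%s)",
            length(removed), length(genes),
            paste(utils::head(removed, 8), collapse = ", "),
            if (length(removed) > 8) ", ..." else "")
  }
  setdiff(genes, removed)
}

#' Derive a signed, weighted macrophage signature from a DEA
#'
#' One signature per direction of a contrast: the `up` direction keeps genes
#' with `log2FC > lfc_min`, the `down` direction genes with
#' `log2FC < -lfc_min` (both at `adj_p < alpha`). Each entry carries the
#' weight `w = -log10(p)` (moderated-t p-value), the sign
#' `I = sign(log2FC)` from the originating contrast, log2FC and adj_p.
#' When `apply_filter` is TRUE the B-cell contamination filter is applied
#' (it is exempted for the RLT signature, whose germinal-center ROIs have no
#' matching CD20 mask).
#'
#' @param name signature name (e.g. `"MacroSig4_DZ"`).
#' @param dea a `dea_result`.
#' @param direction `"up"` or `"down"`.
#' @param ranks [percentile_ranks()] matrix (required if `apply_filter`).
#' @param apply_filter whether to apply [contamination_filter()].
#' @param alpha,lfc_min DEG thresholds (see [select_degs()]).
#' @return a `macrosig` object with `$entries` (gene, weight, sign, log2FC,
#'   adj_p), `$name`, `$contrast`, `$direction`.
#' @export
derive_macrosig <- function(name, dea, direction = c("up", "down"),
                            ranks = NULL, apply_filter = TRUE,
                            alpha = 0.05, lfc_min = 0.58) {
  direction <- match.arg(direction)
  degs <- select_degs(dea, alpha, lfc_min)
  genes <- degs[[direction]]
  n_before <- length(genes)
  if (apply_filter) {
    if (is.null(ranks)) dsp_stop("ranks required when apply_filter = TRUE")
    genes <- contamination_filter(genes, ranks)
  }
  if (length(genes) == 0) {
    dsp_stop("empty signature '%s': %d DEGs before filtering, %d after",
             name, n_before, length(genes))
  }
  ix <- match(genes, dea$gene)
  entries <- data.frame(gene = genes,
                        weight = -log10(dea$p[ix]),
                        sign = ifelse(dea$log2FC[ix] > 0, 1, -1),
                        log2FC = dea$log2FC[ix],
                        adj_p = dea$adj_p[ix],
                        row.names = NULL, stringsAsFactors = FALSE)
  entries <- entries[order(entries$gene), , drop = FALSE]  # order-invariant
  rownames(entries) <- NULL
  structure(list(name = name, contrast = attr(dea, "contrast"),
                 direction = direction, entries = entries,
                 alpha = alpha, lfc_min = lfc_min,
                 filtered = apply_filter, n_before_filter = n_before),
            class = "macrosig")
}

#' @export
print.macrosig <- function(x, ...) {
  cat(sprintf("macrosig '%s' (%s direction): %d genes%s\n",
              x$name, x$direction, nrow(x$entries),
              if (isTRUE(x$filtered))
                sprintf(" (%d before contamination filter)", x$n_before_filter)
              else ""))
  cat(sprintf("  weight range -log10(p): [%.2f, %.2f]\n",
              min(x$entries$weight), max(x$entries$weight)))
  invisible(x)
}

#' Construct a macrosig directly from entries
#'
#' Convenience constructor for tests and for signatures read back from disk.
#'
#' @param name signature name.
#' @param entries data.frame with columns gene, weight, sign, log2FC, adj_p.
#' @param direction `"up"` or `"down"`.
#' @return a `macrosig`.
#' @export
macrosig <- function(name, entries, direction = "up") {
  need <- c("gene", "weight", "sign", "log2FC", "adj_p")
  if (!all(need %in% names(entries))) {
    dsp_stop("entries need columns: %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(entries$gene)) dsp_stop("duplicate genes in signature")
  if (any(entries$weight <= 0)) dsp_stop("weights must be positive")
  if (!all(entries$sign %in% c(-1, 1))) dsp_stop("sign must be -1 or +1")
  structure(list(name = name, contrast = NULL, direction = direction,
                 entries = as.data.frame(entries), filtered = FALSE,
                 n_before_filter = nrow(entries)),
            class = "macrosig")
}

#' Keep the top-k signature genes by fold change
#'
#' Entries are ranked by absolute log2 fold change, descending (for an
#' up-signature this equals descending signed log2FC); ties go to the smaller
#' p-value, then lexicographic gene id. The first `min(k, size)` entries are
#' kept.
#'
#' @param sig a `macrosig`.
#' @param k number of genes to keep (default 50).
#' @return the truncated `macrosig`.
#' @export
top_k <- function(sig, k = 50) {
  if (nrow(sig$entries) == 0) dsp_stop("signature is empty")
  e <- sig$entries
  p <- 10^(-e$weight)
  ord <- order(-abs(e$log2FC), p, e$gene)
  sig$entries <- e[ord[seq_len(min(k, nrow(e)))], , drop = FALSE]
  rownames(sig$entries) <- NULL
  sig
}

#' Write a macrosig as GMT plus a weights sidecar TSV
#'
#' GMT cannot carry weights, so `<path>.gmt` holds the gene list and
#' `<path>.weights.tsv` the (gene, weight, sign, log2FC, adj_p) table.
#'
#' @param sig a `macrosig`.
#' @param path output path stem.
#' @return the path stem, invisibly.
#' @export
write_macrosig <- function(sig, path) {
  write_gmt(list(gene_signature(sig$name, sig$entries$gene,
                                paste0(sig$direction, " signature"))),
            paste0(path, ".gmt"))
  utils::write.table(sig$entries, paste0(path, ".weights.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a macrosig written by [write_macrosig()]
#' @param path path stem used at write time.
#' @param name optional name override.
#' @return a `macrosig`.
#' @export
read_macrosig <- function(path, name = NULL) {
  sigs <- read_gmt(paste0(path, ".gmt"))
  entries <- utils::read.delim(paste0(path, ".weights.tsv"),
                               stringsAsFactors = FALSE)
  if (is.null(name)) name <- sigs[[1]]$name
  macrosig(name, entries)
}
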