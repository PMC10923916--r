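#' Fisher exact association between a patient group and a category
#'
#' Builds the 2x2 table from set overlaps within `universe` and reports the
#' exact p-value: two-sided by the probability-mass rule (default), or the
#' one-tailed hypergeometric upper tail. The overlap ratio is
#' `|group intersect category| / |category|`.
#'
#' @param group_members patients in the signature group.
#' @param category_members patients in the category.
#' @param universe all patients (a superset of both).
#' @param alternative `"two.sided"` (default) or `"greater"` (hypergeometric
#'   upper tail).
#' @return one-row data.frame: overlap, overlap_ratio, odds_ratio, p.
#' @export
fisher_association <- function(group_members, category_members, universe,
                               alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (length(universe) == 0) dsp_stop("empty universe")
  if (!all(group_members %in% universe) || !all(category_members %in% universe)) {
    dsp_stop("group and category must be subsets of the universe")
  }
  a <- length(intersect(group_members, category_members))
  b <- length(setdiff(group_members, category_members))
  cc <- length(setdiff(category_members, group_members))
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, cc, b, d), 2, 2)
  p <- if (alternative == "two.sided") {
    stats::fisher.test(tab)$p.value
  } else {
    stats::phyper(a - 1, length(category_members),
                  length(universe) - length(category_members),
                  length(group_members), lower.tail = FALSE)
  }
  odds <- (a * d) / (b * cc)
  data.frame(overlap = a,
             overlap_ratio = if (length(category_members)) a / length(category_members) else NA_real_,
             odds_ratio = odds, p = min(p, 1), stringsAsFactors = FALSE)
}

#' Associate stratification groups with category labels
#'
#' Fisher exact tests for every (extreme tertile group x category) pair, with
#' BH adjustment across the whole family and the enrichment score
#' `-log10(adjusted p)`.
#'
#' @param strat a `stratification`.
#' @param labels data.frame with patient_id, category.
#' @param groups which stratification groups to test (default the extreme
#'   tertiles `c("low", "high")`).
#' @param alternative passed to [fisher_association()].
#' @return data.frame: group, category, overlap, overlap_ratio, odds_ratio,
#'   p, adj_p, enrichment_score.
#' @export
association_analysis <- function(strat, labels, groups = c("low", "high"),
                                 alternative = "two.sided") {
  merged <- merge(strat, labels, by = "patient_id")
  universe <- merged$patient_id
  cats <- sort(unique(merged$category))
  rows <- list()
  for (g in groups) {
    gm <- merged$patient_id[merged$group == g]
    for (ct in cats) {
      cm <- merged$patient_id[merged$category == ct]
      r <- fisher_association(gm, cm, universe, alternative)
      rows[[length(rows) + 1L]] <- cbind(data.frame(group = g, category = ct,
                                                    stringsAsFactors = FALSE), r)
    }
  }
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out$enrichment_score <- -log10(out$adj_p)
  out
}

#' Hypergeometric gene-set enrichment
#'
#' For each gene set: `count` = overlap with the query genes, `gene_ratio` =
#' count divided by the gene-set size (within the universe), upper-tail
#' hypergeometric p-value, BH adjustment across sets. Sets disjoint from the
#' universe are skipped with a warning.
#'
#' @param sig_genes query gene set (subset of `universe`).
#' @param genesets named list of [gene_signature] objects (e.g. from
#'   [read_gmt()]).
#' @param universe background gene universe.
#' @return data.frame: set, set_size, count, gene_ratio, p, adj_p.
#' @export
geneset_enrichment <- function(sig_genes, genesets, universe) {
  if (!all(sig_genes %in% universe)) {
    dsp_stop("sig_genes must be contained in the universe")
  }
  rows <- lapply(genesets, function(gs) {
    set <- intersect(gs$genes, universe)
    if (length(set) == 0) {
      dsp_warn("gene set '%s' disjoint from universe; skipped", gs$name)
      return(NULL)
    }
    count <- length(intersect(sig_genes, set))
    p <- stats::phyper(count - 1, length(set), length(universe) - length(set),
                       length(sig_genes), lower.tail = FALSE)
    data.frame(set = gs$name, set_size = length(set), count = count,
               gene_ratio = count / length(set), p = p,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) dsp_stop("no gene set overlaps the universe")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$adj_p <- bh_adjust(out$p)
  out
}
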