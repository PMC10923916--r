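#' Simulation parameters
#'
#' One declarative parameter set shared by the three generators
#' ([simulate_dsp_experiment()], [simulate_cohort()], [simulate_single_cell()]).
#' Defaults emulate a desk-scale version of a two-batch GeoMx DSP study of
#' reactive lymphoid tissue (RLT; regions GC/IF/LZ/DZ) and DLBCL tumors, with
#' three immunofluorescence masks (CD68 macrophage, CD3 T cell, CD20 B cell)
#' per ROI and a fraction of DLBCL patients contributing duplicate cores.
#'
#' @param n_genes number of target genes (hallmark mask markers and
#'   mitochondrial ids are included in this total).
#' @param n_neg_probes number of negative control probes.
#' @param n_rlt_patients RLT patients; each contributes one ROI per region,
#'   segmented into all three masks.
#' @param n_dlbcl_patients DLBCL patients; each contributes one ROI with all
#'   three masks; `dup_frac` of them contribute a duplicate core.
#' @param dup_frac fraction of DLBCL patients with duplicate cores.
#' @param aoi_design optional data.frame(tissue, mask, region, n_aois)
#'   overriding the derived design; region must be NONE for DLBCL rows.
#' @param frac_planted fraction of genes planted as differentially expressed
#'   per spatial contrast (half up, half down).
#' @param frac_contaminant fraction of the GC-upregulated planted genes that
#'   are additionally B-cell dominant (elevated in CD20 AOIs), exercising the
#'   contamination filter.
#' @param lfc_magnitude planted log2 fold-change magnitude.
#' @param nb_dispersion negative-binomial dispersion alpha in
#'   `var = mu + alpha * mu^2`.
#' @param size_factor_sd log-scale sd of per-AOI (or per-cell) size factors.
#' @param batch_sd log2-scale sd of per-gene per-batch effects.
#' @param patient_sd log2-scale sd of per-gene per-patient effects (shared by
#'   duplicate cores).
#' @param mask_marker_lfc log2 boost of hallmark marker genes in their mask.
#' @param neg_probe_mean mean count of negative probes at size factor 1.
#' @param sat_phi library-size scale of the synthetic saturation curve
#'   `1 - exp(-library_size / sat_phi)`.
#' @param reads_per_count raw sequencing reads emitted per deduplicated count.
#' @param n_patients bulk-cohort size for [simulate_cohort()].
#' @param hazard_coef log-hazard per unit of latent signature activity; the
#'   default 0.42 gives a true top-vs-bottom latent-tertile hazard ratio of
#'   about 2.5.
#' @param censor_frac target censoring fraction of the cohort.
#' @param label_coef strength of the dependence of category labels on latent
#'   activity (0 = independent labels).
#' @param weibull_shape,weibull_median shape and baseline median (months) of
#'   the Weibull event-time distribution.
#' @param n_cells_per_cluster cells per cluster for [simulate_single_cell()].
#' @param sc_dispersion NB dispersion of single-cell counts.
#' @param seed integer RNG seed; generators are pure functions of
#'   (params, seed).
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_genes = 2000, n_neg_probes = 100,
                       n_rlt_patients = 12, n_dlbcl_patients = 20,
                       dup_frac = 0.35, aoi_design = NULL,
                       frac_planted = 0.05, frac_contaminant = 0.25,
                       lfc_magnitude = 1.5, nb_dispersion = 0.1,
                       size_factor_sd = 0.3, batch_sd = 0.1,
                       patient_sd = 0.2, mask_marker_lfc = 2.5,
                       neg_probe_mean = 3, sat_phi = 6e4,
                       reads_per_count = 2,
                       n_patients = 600, hazard_coef = 0.42,
                       censor_frac = 0.3, label_coef = 1,
                       weibull_shape = 1.2, weibull_median = 36,
                       n_cells_per_cluster = 300, sc_dispersion = 0.5,
                       seed = 1L) {
  p <- as.list(environment())
  fracs <- c(dup_frac = dup_frac, frac_planted = frac_planted,
             frac_contaminant = frac_contaminant, censor_frac = censor_frac)
  if (any(fracs < 0 | fracs > 1)) dsp_stop("fractions must lie in [0, 1]")
  if (nb_dispersion <= 0) dsp_stop("nb_dispersion must be positive")
  if (!is.finite(hazard_coef)) dsp_stop("hazard_coef must be finite")
  structure(p, class = "sim_params")
}

# Hallmark immunofluorescence-mask marker genes (macrophage / T cell / B cell).
mask_marker_sets <- function() {
  list(CD68 = c("CD68", "CD163", "FCGR1A", "CSF1R"),
       CD3  = c("CD3D", "CD3E", "UBASH3A", "CD2", "TRBC2"),
       CD20 = c("MS4A1", "CD79A", "CD79B", "CD19", "PAX5"))
}

mito_gene_ids <- function() sprintf("MT-%d", 1:13)

sim_gene_ids <- function(n_genes) {
  fixed <- c(unlist(mask_marker_sets(), use.names = FALSE), mito_gene_ids())
  if (n_genes <= length(fixed)) dsp_stop("n_genes too small (< %d)", length(fixed) + 1)
  c(fixed, sprintf("G%04d", seq_len(n_genes - length(fixed))))
}

default_aoi_design <- function(params) {
  rlt <- expand.grid(tissue = "RLT", mask = c("CD68", "CD3", "CD20"),
                     region = c("GC", "IF", "LZ", "DZ"),
                     stringsAsFactors = FALSE)
  rlt$n_aois <- params$n_rlt_patients
  dlbcl <- expand.grid(tissue = "DLBCL", mask = c("CD68", "CD3", "CD20"),
                       region = "NONE", stringsAsFactors = FALSE)
  dlbcl$n_aois <- params$n_dlbcl_patients
  rbind(rlt, dlbcl)
}

# The three spatial contrasts of the study, each restricted to one mask.
dsp_contrasts <- function() {
  list(
    GC_vs_IF = list(mask = "CD68",
                    A = list(tissue = "RLT", region = "GC"),
                    B = list(tissue = "RLT", region = "IF")),
    LZ_vs_DZ = list(mask = "CD68",
                    A = list(tissue = "RLT", region = "LZ"),
                    B = list(tissue = "RLT", region = "DZ")),
    RLT_vs_DLBCL = list(mask = "CD68",
                        A = list(tissue = "RLT", region = "GC"),
                        B = list(tissue = "DLBCL", region = "NONE"))
  )
}

#' Simulate a DSP experiment with planted structure
#'
#' Negative-binomial AOI counts with per-AOI lognormal size factors, per-batch
#' lognormal gene effects, per-patient biology shared across duplicate cores,
#' hallmark marker genes boosted in their matching mask, and planted
#' differentially expressed genes shifted by `+/- lfc_magnitude` within the
#' designated mask-by-region stratum of each spatial contrast. A subset of the
#' GC-upregulated planted genes is additionally elevated in CD20 AOIs
#' (B-cell-dominant contaminants). Negative probes are drawn from the baseline
#' noise distribution; raw reads and sequencing saturation are emitted as
#' deterministic functions of library size. The full planted truth is recorded
#' in `$truth`.
#'
#' @param params a [sim_params] object.
#' @return a [dsp_experiment] with a `truth` list: `planted_up`,
#'   `planted_down` (per contrast), `planted_lfc`, `contaminants`,
#'   `batch_factors`, `seeds`.
#' @export
simulate_dsp_experiment <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  design <- if (is.null(params$aoi_design)) default_aoi_design(params) else params$aoi_design
  bad <- which(design$tissue == "DLBCL" & design$region != "NONE")
  if (length(bad)) {
    dsp_stop("aoi_design requests region '%s' for DLBCL tissue (regions apply to RLT only)",
             design$region[bad[1]])
  }
  bad <- which(design$tissue == "RLT" & design$region == "NONE")
  if (length(bad)) dsp_stop("RLT AOIs must carry a region label")

  genes <- sim_gene_ids(params$n_genes)
  n_genes <- length(genes)
  base_mean <- stats::rlnorm(n_genes, meanlog = log(50), sdlog = 1)
  names(base_mean) <- genes

  ## annotation rows -------------------------------------------------------
  ann <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    d <- design[i, ]
    pat <- if (d$tissue == "RLT") sprintf("R%02d", seq_len(d$n_aois)) else
      sprintf("D%02d", seq_len(d$n_aois))
    data.frame(tissue = d$tissue, mask = d$mask, region = d$region,
               patient_id = pat, dup = FALSE, stringsAsFactors = FALSE)
  }))
  # duplicate cores: a fraction of DLBCL patients contribute a second AOI per mask
  dl_pat <- sprintf("D%02d", seq_len(params$n_dlbcl_patients))
  n_dup <- round(params$dup_frac * length(dl_pat))
  if (n_dup > 0 && any(design$tissue == "DLBCL")) {
    dup_pat <- dl_pat[seq_len(n_dup)]
    extra <- ann[ann$tissue == "DLBCL" & ann$patient_id %in% dup_pat, , drop = FALSE]
    extra$dup <- TRUE
    ann <- rbind(ann, extra)
  }
  ann$roi_id <- ifelse(ann$tissue == "RLT",
                       paste0(ann$patient_id, "_", ann$region),
                       paste0(ann$patient_id, ifelse(ann$dup, "b", "a")))
  ann$batch <- ifelse(as.integer(sub("^[RD]", "", ann$patient_id)) %% 2 == 0,
                      "B2", "B1")
  ann$aoi_id <- paste(ann$tissue, ann$mask, ann$region, ann$roi_id, sep = "|")
  if (anyDuplicated(ann$aoi_id)) dsp_stop("internal: duplicate AOI ids in design")
  n_aoi <- nrow(ann)

  ## planted effects -------------------------------------------------------
  eligible <- setdiff(genes[base_mean >= 20],
                      c(unlist(mask_marker_sets()), mito_gene_ids()))
  n_per_contrast <- round(params$frac_planted * n_genes)
  contrasts <- dsp_contrasts()
  need <- n_per_contrast * length(contrasts)
  if (need > length(eligible)) dsp_stop("frac_planted too large for n_genes")
  chosen <- sample(eligible, need)
  truth <- list(planted_up = list(), planted_down = list(),
                planted_lfc = numeric(0), contaminants = character(0),
                seeds = params$seed)
  effect <- matrix(0, n_genes, n_aoi, dimnames = list(genes, ann$aoi_id))
  idx <- 0
  in_stratum <- function(side, mask) {
    ann$mask == mask & ann$tissue == side$tissue & ann$region == side$region
  }
  for (cn in names(contrasts)) {
    ct <- contrasts[[cn]]
    if (n_per_contrast == 0) {
      truth$planted_up[[cn]] <- character(0)
      truth$planted_down[[cn]] <- character(0)
      next
    }
    g <- chosen[(idx + 1):(idx + n_per_contrast)]; idx <- idx + n_per_contrast
    up <- g[seq_len(floor(length(g) / 2))]
    down <- setdiff(g, up)
    # Effects are applied in the B stratum (IF / DZ / DLBCL), which is unique
    # to its contrast, so the three contrasts stay orthogonal: an up gene of
    # A_vs_B is lowered in B, a down gene raised in B.
    colB <- in_stratum(ct$B, ct$mask)
    effect[up, colB] <- effect[up, colB] - params$lfc_magnitude
    effect[down, colB] <- effect[down, colB] + params$lfc_magnitude
    # planted genes are macrophage genes: elevated across the whole CD68 mask
    effect[g, ann$mask == "CD68"] <- effect[g, ann$mask == "CD68"] + 1
    truth$planted_up[[cn]] <- up
    truth$planted_down[[cn]] <- down
    truth$planted_lfc[g] <- params$lfc_magnitude
  }
  # B-cell-dominant contaminants among the GC-upregulated genes
  gc_up <- truth$planted_up$GC_vs_IF
  n_cont <- round(params$frac_contaminant * length(gc_up))
  if (n_cont > 0) {
    cont <- gc_up[seq_len(n_cont)]
    effect[cont, ann$mask == "CD20"] <- effect[cont, ann$mask == "CD20"] + 3
    truth$contaminants <- cont
  }
  # hallmark marker genes elevated in their own mask
  for (mk in names(mask_marker_sets())) {
    mg <- mask_marker_sets()[[mk]]
    effect[mg, ann$mask == mk] <- effect[mg, ann$mask == mk] + params$mask_marker_lfc
  }

  ## nuisance structure ----------------------------------------------------
  batches <- sort(unique(ann$batch))
  batch_fac <- matrix(stats::rnorm(n_genes * length(batches), 0, params$batch_sd),
                      n_genes, length(batches), dimnames = list(genes, batches))
  patients <- unique(ann$patient_id)
  pat_fac <- matrix(stats::rnorm(n_genes * length(patients), 0, params$patient_sd),
                    n_genes, length(patients), dimnames = list(genes, patients))
  size_fac <- exp(stats::rnorm(n_aoi, 0, params$size_factor_sd))
  truth$batch_factors <- batch_fac
  truth$size_factors <- stats::setNames(size_fac, ann$aoi_id)

  log2mu <- log2(base_mean) + effect +
    batch_fac[, ann$batch, drop = FALSE] +
    pat_fac[, ann$patient_id, drop = FALSE] +
    rep(log2(size_fac), each = n_genes)
  mu <- 2^log2mu
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / params$nb_dispersion),
                   n_genes, n_aoi, dimnames = dimnames(mu))

  probe_base <- stats::rlnorm(params$n_neg_probes, log(params$neg_probe_mean), 0.25)
  neg_mu <- outer(probe_base, size_fac)
  neg <- matrix(stats::rnbinom(length(neg_mu), mu = neg_mu, size = 1 / 0.5),
                params$n_neg_probes, n_aoi,
                dimnames = list(sprintf("NegProbe%03d", seq_len(params$n_neg_probes)),
                                ann$aoi_id))

  lib <- colSums(counts)
  ann$raw_reads <- round(lib * params$reads_per_count)
  ann$saturation <- 1 - exp(-lib / params$sat_phi)
  ann <- ann[, c("aoi_id", "roi_id", "patient_id", "tissue", "mask", "region",
                 "batch", "raw_reads", "saturation")]
  dsp_experiment(expr_matrix(counts, "counts"), ann, neg, truth = truth)
}

#' Simulate a bulk survival cohort driven by latent signature activity
#'
#' Each patient carries a latent activity `a ~ N(0, 1)`. Log2 expression of the
#' signature genes is shifted by `a * sign * lfc_magnitude`; event times are
#' Weibull with log-hazard `hazard_coef * a`; censoring is independent uniform
#' with its upper bound solved numerically so the realized censoring fraction
#' targets `censor_frac`; category labels (GCB/ABC/UNC) follow a softmax whose
#' ABC-vs-GCB contrast moves with `label_coef * a`.
#'
#' @param params a [sim_params] object.
#' @param signature a [macrosig], or a list of two macrosigs (an up/down pair)
#'   whose union drives the latent activity.
#' @return a [cohort_dataset]; `attr(, "truth")` records the latent activity,
#'   hazard coefficient and seed.
#' @export
simulate_cohort <- function(params = sim_params(), signature) {
  stopifnot(inherits(params, "sim_params"))
  if (inherits(signature, "macrosig")) signature <- list(signature)
  entries <- do.call(rbind, lapply(signature, function(s) s$entries))
  if (is.null(entries) || nrow(entries) == 0) dsp_stop("signature must be non-empty")
  if (anyDuplicated(entries$gene)) dsp_stop("signature pair genes must be disjoint")
  set.seed(params$seed + 1L)
  n <- params$n_patients
  sig_genes <- entries$gene
  filler <- setdiff(sim_gene_ids(params$n_genes), sig_genes)
  genes <- c(sig_genes, filler)
  pat <- sprintf("P%04d", seq_len(n))
  a <- stats::rnorm(n)
  base <- stats::rnorm(length(genes), 7, 1.5)
  x <- matrix(stats::rnorm(length(genes) * n, 0, 1), length(genes), n,
              dimnames = list(genes, pat)) + base
  shift <- outer(entries$sign * params$lfc_magnitude, a)
  x[sig_genes, ] <- x[sig_genes, ] + shift

  k <- params$weibull_shape
  lambda <- params$weibull_median / log(2)^(1 / k)
  ev <- stats::rexp(n)
  t_event <- lambda * (ev / exp(params$hazard_coef * a))^(1 / k)
  if (params$censor_frac > 0) {
    # P(C < T | C ~ U(0, cmax)) = min(T / cmax, 1); solve for the target fraction
    f <- function(cmax) mean(pmin(t_event / cmax, 1)) - params$censor_frac
    cmax <- stats::uniroot(f, c(1e-6, 1e9))$root
    cens <- stats::runif(n, 0, cmax)
    event <- as.integer(t_event <= cens)
    time <- pmin(t_event, cens)
  } else {
    event <- rep(1L, n)
    time <- t_event
  }
  eta <- cbind(GCB = -params$label_coef * a, ABC = params$label_coef * a, UNC = 0)
  prob <- exp(eta) / rowSums(exp(eta))
  category <- vapply(seq_len(n), function(i) {
    sample(colnames(prob), 1, prob = prob[i, ])
  }, "")
  cohort <- cohort_dataset(
    expr_matrix(x, "log2"),
    data.frame(patient_id = pat, time = time, event = event,
               stringsAsFactors = FALSE),
    data.frame(patient_id = pat, category = category, stringsAsFactors = FALSE)
  )
  attr(cohort, "truth") <- list(activity = stats::setNames(a, pat),
                                hazard_coef = params$hazard_coef,
                                seed = params$seed)
  cohort
}

#' Simulate a single-cell count matrix with signature-defined clusters
#'
#' Sparse negative-binomial counts; one cluster per supplied signature
#' overexpresses that signature's genes by `lfc_magnitude` (log2), plus one
#' background cluster. A designated set of mitochondrial gene ids (`MT-1` ...
#' `MT-13`) is included for QC exercises.
#'
#' @param params a [sim_params] object.
#' @param signatures list of [macrosig] or [gene_signature] objects (>= 1; with
#'   the background cluster this yields >= 2 clusters).
#' @return list with `counts` (an [expr_matrix]), `clusters` (per-cell labels)
#'   and `mito_genes`.
#' @export
simulate_single_cell <- function(params = sim_params(), signatures) {
  stopifnot(inherits(params, "sim_params"))
  if (length(signatures) < 1) dsp_stop("at least one signature required")
  set.seed(params$seed + 2L)
  sig_genes <- lapply(signatures, function(s) {
    if (inherits(s, "macrosig")) s$entries$gene else s$genes
  })
  sig_names <- vapply(seq_along(signatures), function(i) {
    nm <- if (inherits(signatures[[i]], "macrosig")) signatures[[i]]$name
          else signatures[[i]]$name
    if (is.null(nm) || !nzchar(nm)) sprintf("sig%d", i) else nm
  }, "")
  for (i in seq_along(sig_genes)) {
    for (j in seq_along(sig_genes)) {
      if (i < j && length(intersect(sig_genes[[i]], sig_genes[[j]]))) {
        dsp_warn("signatures '%s' and '%s' share genes; cluster separation may blur",
                 sig_names[i], sig_names[j])
      }
    }
  }
  genes <- unique(c(unlist(sig_genes), mito_gene_ids(), sim_gene_ids(params$n_genes)))
  clusters <- c(sig_names, "background")
  n_cells <- params$n_cells_per_cluster
  cell_cluster <- rep(clusters, each = n_cells)
  cells <- sprintf("C%05d", seq_along(cell_cluster))
  base <- stats::rlnorm(length(genes), log(0.5), 1)
  names(base) <- genes
  base[mito_gene_ids()] <- sum(base) * 0.05 / length(mito_gene_ids())
  log2mu <- matrix(log2(base), length(genes), length(cells),
                   dimnames = list(genes, cells))
  for (i in seq_along(sig_names)) {
    cols <- cell_cluster == sig_names[i]
    log2mu[sig_genes[[i]], cols] <- log2mu[sig_genes[[i]], cols] + params$lfc_magnitude
  }
  sf <- exp(stats::rnorm(length(cells), 0, params$size_factor_sd))
  mu <- 2^log2mu * rep(sf, each = length(genes))
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / params$sc_dispersion),
                   length(genes), length(cells), dimnames = dimnames(mu))
  list(counts = expr_matrix(counts, "counts"),
       clusters = stats::setNames(cell_cluster, cells),
       mito_genes = mito_gene_ids())
}
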