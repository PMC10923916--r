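#' Default pipeline configuration
#'
#' A single declarative configuration holding every threshold of the pipeline
#' (all defaulting to the standard values used throughout the package), the
#' global seed and the stage toggles.
#'
#' @param out_dir output directory.
#' @param seed global integer seed.
#' @param stages stages to run, in fixed order.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(out_dir, seed = 1L,
                                    stages = c("simulate", "preprocess",
                                               "validate_masks", "dea",
                                               "derive_sig", "score",
                                               "survive", "associate",
                                               "enrich")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = stages,
    sim = list(),                       # overrides for sim_params()
    qc = list(min_raw_reads = 10000, min_saturation = 0.5,
              min_gene_frac = 0.05, loq_detect_frac = 0.05),
    pseudo = 1, k_mads = 4,
    alpha = 0.05, lfc_min = 0.58, top_k = 50,
    standardize = TRUE,
    score_pair = c("MacroSig3_LZ", "MacroSig4_DZ"),
    genesets_gmt = system.file("extdata", "hallmark_masks.gmt",
                               package = "dspmacro", mustWork = TRUE)
  )
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML config path; keys as in [default_pipeline_config()].
#' @return configuration list merged over the defaults.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) dsp_stop("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  for (key in c("out_dir", "seed")) {
    if (is.null(user[[key]])) dsp_stop("missing config key: %s", key)
  }
  cfg <- default_pipeline_config(user$out_dir, user$seed)
  utils::modifyList(cfg, user)
}

write_provenance <- function(out_dir, stage, params, inputs, outputs) {
  rec <- list(stage = stage, package_version = as.character(utils::packageVersion("dspmacro")),
              parameters = params,
              inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
              outputs = outputs)
  path <- file.path(out_dir, sprintf("provenance_%s.json", stage))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  path
}

need_input <- function(path, producer, stage) {
  if (!file.exists(path)) {
    dsp_stop("stage '%s': input %s missing; run stage '%s' first",
             stage, basename(path), producer)
  }
  path
}

#' Run the full synthetic DSP analysis pipeline
#'
#' Executes the enabled stages in fixed order (simulate, preprocess,
#' validate_masks, dea, derive_sig, score, survive, associate, enrich).
#' Stages communicate only via files under `config$out_dir`; each stage writes
#' its outputs plus a JSON provenance record (input hashes, parameters,
#' package version). A failure in any stage aborts with a stage-named error.
#'
#' @param config list from [default_pipeline_config()] /
#'   [read_pipeline_config()], or a YAML path.
#' @param dry_run validate the configuration and input schemas without
#'   computing.
#' @return invisibly, the manifest: a named list of output files per stage.
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  for (key in c("seed", "out_dir", "stages")) {
    if (is.null(config[[key]])) dsp_stop("missing config key: %s", key)
  }
  order_all <- c("simulate", "preprocess", "validate_masks", "dea",
                 "derive_sig", "score", "survive", "associate", "enrich")
  bad <- setdiff(config$stages, order_all)
  if (length(bad)) dsp_stop("unknown stage(s): %s", paste(bad, collapse = ", "))
  stages <- order_all[order_all %in% config$stages]
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  if (dry_run) {
    return(invisible(list(stages = stages, out_dir = out, seed = config$seed)))
  }
  p <- function(...) file.path(out, ...)
  manifest <- list()
  sim_cfg <- do.call(sim_params, c(config$sim, list(seed = config$seed)))
  thr <- do.call(qc_thresholds, config$qc)
  sig_names <- c(GC_vs_IF = "MacroSig1_GC", GC_vs_IF.down = "MacroSig2_IF",
                 LZ_vs_DZ = "MacroSig3_LZ", LZ_vs_DZ.down = "MacroSig4_DZ",
                 RLT_vs_DLBCL = "MacroSig5_RLT", RLT_vs_DLBCL.down = "MacroSig6_DLBCL")

  for (stage in stages) {
    res <- switch(stage,
      simulate = {
        exp <- simulate_dsp_experiment(sim_cfg)
        write_expression_table(exp$counts, p("counts.tsv"))
        write_aoi_annotations(exp$annotations, p("annotations.tsv"))
        utils::write.table(
          data.frame(probe_id = rownames(exp$neg_probes), exp$neg_probes,
                     check.names = FALSE),
          p("neg_probes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(exp$truth[c("planted_up", "planted_down",
                                         "contaminants", "seeds")],
                             p("truth.json"), auto_unbox = TRUE, digits = NA)
        c("counts.tsv", "annotations.tsv", "neg_probes.tsv", "truth.json")
      },
      preprocess = {
        counts <- read_expression_table(
          need_input(p("counts.tsv"), "simulate", stage))
        ann <- read_aoi_annotations(need_input(p("annotations.tsv"), "simulate", stage))
        neg <- utils::read.delim(need_input(p("neg_probes.tsv"), "simulate", stage),
                                 check.names = FALSE)
        negm <- as.matrix(neg[, -1, drop = FALSE])
        rownames(negm) <- neg[[1]]
        exp <- dsp_experiment(counts, ann, negm)
        pp <- preprocess_dsp(exp, thr, pseudo = config$pseudo,
                             k_mads = config$k_mads)
        write_expression_table(pp$log2, p("log2_normalized.tsv"))
        write_expression_table(pp$q3, p("q3_normalized.tsv"))
        write_aoi_annotations(pp$annotations, p("annotations_qc.tsv"))
        qc_report <- data.frame(aoi_id = names(pp$flags),
                                criterion = "pca_outlier",
                                pass = !pp$flags)
        utils::write.table(qc_report, p("qc_report.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        c("log2_normalized.tsv", "q3_normalized.tsv", "annotations_qc.tsv",
          "qc_report.tsv")
      },
      validate_masks = {
        lg <- read_expression_table(
          need_input(p("log2_normalized.tsv"), "preprocess", stage),
          scale = "log2")
        ann <- read_aoi_annotations(need_input(p("annotations_qc.tsv"),
                                               "preprocess", stage))
        vm <- validate_masks(lg, ann$mask[match(colnames(lg), ann$aoi_id)],
                             hallmark_mask_signatures())
        utils::write.table(vm, p("mask_validation.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        "mask_validation.tsv"
      },
      dea = {
        lg <- read_expression_table(
          need_input(p("log2_normalized.tsv"), "preprocess", stage),
          scale = "log2")
        ann <- read_aoi_annotations(need_input(p("annotations_qc.tsv"),
                                               "preprocess", stage))
        files <- character(0)
        for (ct in names(dsp_contrasts())) {
          dea <- run_dea(lg, ann, ct)
          f <- sprintf("dea_%s.tsv", ct)
          utils::write.table(dea, p(f), sep = "\t", quote = FALSE,
                             row.names = FALSE)
          files <- c(files, f)
        }
        files
      },
      derive_sig = {
        q3 <- as_expr_matrix(unclass(read_expression_table(
          need_input(p("q3_normalized.tsv"), "preprocess", stage))),
          "q3_normalized")
        ann <- read_aoi_annotations(need_input(p("annotations_qc.tsv"),
                                               "preprocess", stage))
        ranks <- percentile_ranks(q3, ann$mask[match(colnames(q3), ann$aoi_id)])
        files <- character(0)
        for (ct in names(dsp_contrasts())) {
          dea_df <- utils::read.delim(
            need_input(p(sprintf("dea_%s.tsv", ct)), "dea", stage),
            stringsAsFactors = FALSE)
          class(dea_df) <- c("dea_result", "data.frame")
          for (dir in c("up", "down")) {
            nm <- sig_names[[if (dir == "up") ct else paste0(ct, ".down")]]
            # the contamination filter is exempted for the RLT signature
            filt <- !(nm == "MacroSig5_RLT")
            sig <- derive_macrosig(nm, dea_df, dir, ranks = ranks,
                                   apply_filter = filt,
                                   alpha = config$alpha,
                                   lfc_min = config$lfc_min)
            write_macrosig(sig, p(nm))
            files <- c(files, paste0(nm, ".gmt"), paste0(nm, ".weights.tsv"))
          }
        }
        files
      },
      score = {
        pair <- lapply(config$score_pair, function(nm) {
          need_input(p(paste0(nm, ".weights.tsv")), "derive_sig", stage)
          read_macrosig(p(nm))
        })
        cohort <- simulate_cohort(sim_cfg, pair)
        scores <- signature_score(cohort, pair, standardize = config$standardize)
        strat <- tertile_stratify(scores)
        utils::write.table(strat, p("scores.tsv"), sep = "\t", quote = FALSE,
                           row.names = FALSE)
        utils::write.table(cohort$survival, p("cohort_survival.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(cohort$labels, p("cohort_labels.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        c("scores.tsv", "cohort_survival.tsv", "cohort_labels.tsv")
      },
      survive = {
        strat <- utils::read.delim(need_input(p("scores.tsv"), "score", stage),
                                   stringsAsFactors = FALSE)
        strat$group <- factor(strat$group, levels = c("low", "mid", "high"))
        class(strat) <- c("stratification", "data.frame")
        surv <- utils::read.delim(need_input(p("cohort_survival.tsv"), "score",
                                             stage), stringsAsFactors = FALSE)
        ts <- tertile_survival(strat, surv)
        res <- data.frame(term = names(ts$cox$coef), log_hr = ts$cox$coef,
                          hr = ts$cox$hr, ci_lower = ts$cox$ci_lower,
                          ci_upper = ts$cox$ci_upper, wald_p = ts$cox$wald_p,
                          logrank_p = ts$logrank$p, n = ts$n)
        utils::write.table(res, p("survival_results.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        km <- do.call(rbind, lapply(names(ts$km), function(g) {
          cbind(group = g, ts$km[[g]])
        }))
        utils::write.table(km, p("km_curves.tsv"), sep = "\t", quote = FALSE,
                           row.names = FALSE)
        c("survival_results.tsv", "km_curves.tsv")
      },
      associate = {
        strat <- utils::read.delim(need_input(p("scores.tsv"), "score", stage),
                                   stringsAsFactors = FALSE)
        labels <- utils::read.delim(need_input(p("cohort_labels.tsv"), "score",
                                               stage), stringsAsFactors = FALSE)
        assoc <- association_analysis(strat, labels)
        utils::write.table(assoc, p("associations.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        "associations.tsv"
      },
      enrich = {
        need_input(paste0(p(config$score_pair[2]), ".weights.tsv"),
                   "derive_sig", stage)
        sig <- read_macrosig(p(config$score_pair[2]))
        lg <- read_expression_table(need_input(p("log2_normalized.tsv"),
                                               "preprocess", stage),
                                    scale = "log2")
        universe <- union(rownames(lg), sig$entries$gene)
        enr <- geneset_enrichment(sig$entries$gene, read_gmt(config$genesets_gmt),
                                  universe)
        utils::write.table(enr, p("enrichment.tsv"), sep = "\t", quote = FALSE,
                           row.names = FALSE)
        "enrichment.tsv"
      })
    params <- config[c("seed", "alpha", "lfc_min", "top_k", "standardize")]
    prov <- write_provenance(out, stage, params,
                             inputs = file.path(out, unlist(manifest)),
                             outputs = res)
    manifest[[stage]] <- res
  }
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = FALSE)
  invisible(manifest)
}
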