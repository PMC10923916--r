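options(dspmacro.verbose = FALSE)

# shared fixture cache so the default synthetic experiment is simulated once
.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

default_experiment <- function() {
  cached("default_exp", simulate_dsp_experiment(sim_params(seed = 101L)))
}

default_preprocessed <- function() {
  cached("default_pp", preprocess_dsp(default_experiment()))
}

# small gene-by-sample log2 matrix with deterministic content
toy_log2 <- function(n_genes = 10, n_samples = 8, seed = 1) {
  set.seed(seed)
  expr_matrix(matrix(rnorm(n_genes * n_samples, 8, 1), n_genes, n_samples,
                     dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                     sprintf("s%02d", seq_len(n_samples)))),
              "log2")
}

# minimal hand-built DSP experiment with controllable QC annotation fields
toy_experiment <- function(raw_reads, saturation, n_genes = 10, seed = 1) {
  n <- length(raw_reads)
  set.seed(seed)
  counts <- matrix(rpois(n_genes * n, 50), n_genes, n,
                   dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                   sprintf("a%02d", seq_len(n))))
  ann <- data.frame(aoi_id = colnames(counts),
                    roi_id = paste0("roi", seq_len(n)),
                    patient_id = paste0("p", seq_len(n)),
                    tissue = "RLT", mask = "CD68", region = "GC",
                    batch = "B1", raw_reads = raw_reads,
                    saturation = saturation,
                    stringsAsFactors = FALSE)
  neg <- matrix(rpois(5 * n, 3), 5, n,
                dimnames = list(paste0("np", 1:5), colnames(counts)))
  dsp_experiment(expr_matrix(counts, "counts"), ann, neg)
}

# independent brute-force BH step-up oracle
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# Cox partial log-likelihood for a single covariate, no ties (independent oracle)
cox_pll <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      risk <- time >= time[i]
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
  }
  ll
}
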