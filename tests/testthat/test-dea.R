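make_ann <- function(patient, mask = "CD68", region = "GC", tissue = "RLT",
                     ids = NULL) {
  n <- length(patient)
  aoi_annotations(data.frame(
    aoi_id = if (is.null(ids)) sprintf("a%02d", seq_len(n)) else ids,
    roi_id = sprintf("r%02d", seq_len(n)), patient_id = patient,
    tissue = tissue, mask = mask, region = region, batch = "B1",
    raw_reads = 20000, saturation = 0.9, stringsAsFactors = FALSE))
}

test_that("duplicate AOIs collapse to their per-gene mean", {
  m <- toy_log2(5, 4, seed = 1)
  colnames(m) <- sprintf("a%02d", 1:4)
  ann <- make_ann(c("p1", "p2", "p3", "p4"))
  no_dup <- collapse_duplicates(m, ann)
  expect_identical(unclass(no_dup$m), unclass(m))

  pair <- expr_matrix(matrix(c(2, 4), 1, 2,
                             dimnames = list("g1", c("a01", "a02"))), "log2")
  cp <- collapse_duplicates(pair, make_ann(c("p1", "p1"), ids = c("a01", "a02")))
  expect_equal(as.numeric(cp$m), 3)
  expect_equal(cp$annotations$patient_id, "p1")

  trip <- toy_log2(6, 3, seed = 2)
  colnames(trip) <- c("a01", "a02", "a03")
  ct <- collapse_duplicates(trip, make_ann(rep("p1", 3),
                                           ids = c("a01", "a02", "a03")))
  expect_equal(as.numeric(ct$m), rowMeans(unclass(trip)), ignore_attr = TRUE)
})

test_that("the two-group contrast fit matches a least-squares oracle", {
  m0 <- expr_matrix(matrix(c(0, 0, 1, 1), 1, 4,
                           dimnames = list("g1", sprintf("s%d", 1:4))), "log2")
  fit <- fit_group_contrast(m0, c("A", "A", "B", "B"))
  expect_equal(fit$log2FC, -1)
  expect_equal(fit$s2, 0)
  expect_equal(fit$df, 2)

  m <- toy_log2(20, 11, seed = 7)
  grp <- rep(c("A", "B"), c(5, 6))
  fit <- fit_group_contrast(m, grp, level_a = "A")
  for (i in c(1, 8, 20)) {
    lmfit <- lm(unclass(m)[i, ] ~ factor(grp, levels = c("B", "A")))
    expect_equal(fit$log2FC[i], unname(coef(lmfit)[2]), tolerance = 1e-12)
    expect_equal(fit$s2[i], sum(residuals(lmfit)^2) / lmfit$df.residual,
                 tolerance = 1e-12)
  }
  expect_error(fit_group_contrast(m, rep(c("A", "B"), c(1, 10))),
               "at least 2 samples")
})

test_that("EB shrinkage recovers planted hyperparameters and matches limma", {
  set.seed(42)
  n <- 20000; d0 <- 4; s0 <- 0.25; df <- 38
  sigma2 <- d0 * s0 / rchisq(n, d0)
  s2 <- sigma2 * rchisq(n, df) / df
  eb <- eb_shrink_variances(s2, df)
  expect_lt(abs(eb$d0 - d0), 1)
  expect_lt(abs(eb$s0_sq - s0) / s0, 0.10)
  ff <- limma::fitFDist(s2, df1 = df)
  expect_equal(eb$d0, ff$df2, tolerance = 0.01)
  expect_equal(eb$s0_sq, ff$scale, tolerance = 0.01)
  sq <- limma::squeezeVar(s2, df = df)
  expect_equal(eb$post_var, sq$var.post, tolerance = 0.01)

  # degenerate inputs
  expect_equal(eb_shrink_variances(rep(0.5, 50), 10)$d0, Inf)
  expect_equal(eb_shrink_variances(rep(0.5, 50), 10)$post_var, rep(0.5, 50))
  expect_error(eb_shrink_variances(rep(0, 50), 10), "degenerate variances")
  expect_error(eb_shrink_variances(runif(5) + 0.1, 10), "at least 10 genes")
})

test_that("with d0 = 0 the moderated t equals the ordinary pooled t-test", {
  set.seed(8)
  for (rep in 1:20) {
    n_a <- sample(3:8, 1); n_b <- sample(3:8, 1)
    m <- expr_matrix(matrix(rnorm(10 * (n_a + n_b)), 10, n_a + n_b,
                            dimnames = list(sprintf("g%d", 1:10),
                                            sprintf("s%d", 1:(n_a + n_b)))),
                     "log2")
    grp <- rep(c("A", "B"), c(n_a, n_b))
    fit <- fit_group_contrast(m, grp, "A")
    res <- moderated_t_test(fit, list(d0 = 0, s0_sq = 1, post_var = fit$s2))
    for (i in 1:10) {
      tt <- t.test(unclass(m)[i, grp == "A"], unclass(m)[i, grp == "B"],
                   var.equal = TRUE)
      expect_equal(res$t_mod[i], unname(tt$statistic), tolerance = 1e-10)
      expect_equal(res$p[i], tt$p.value, tolerance = 1e-10)
    }
  }
})

test_that("moderated t matches an independent beta-CDF formula oracle", {
  set.seed(9)
  m <- toy_log2(50, 12, seed = 9)
  grp <- rep(c("A", "B"), each = 6)
  fit <- fit_group_contrast(m, grp, "A")
  eb <- eb_shrink_variances(fit$s2, fit$df)
  res <- moderated_t_test(fit, eb)
  t_oracle <- fit$log2FC / sqrt(eb$post_var * (1 / 6 + 1 / 6))
  df_tot <- eb$d0 + fit$df
  # two-sided p via the incomplete-beta representation of the t CDF
  p_oracle <- pbeta(df_tot / (df_tot + t_oracle^2), df_tot / 2, 0.5)
  expect_equal(res$t_mod, t_oracle, tolerance = 1e-12)
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  expect_true(all(res$adj_p >= res$p - 1e-15))
  expect_true(all(sign(res$t_mod) == sign(res$log2FC) | res$log2FC == 0))

  # zero fold change gives t = 0, p = 1
  set.seed(91)
  v <- rnorm(25); w <- rnorm(25)
  fm <- cbind(s1 = v, s2 = w, s3 = w, s4 = v)
  rownames(fm) <- sprintf("g%d", 1:25)
  flat <- expr_matrix(fm, "log2")
  ffit <- fit_group_contrast(flat, c("A", "A", "B", "B"), "A")
  expect_true(all(ffit$log2FC == 0))
  fres <- moderated_t_test(ffit, eb_shrink_variances(ffit$s2, ffit$df))
  expect_true(all(fres$t_mod == 0))
  expect_true(all(fres$p == 1))
})

test_that("our moderated pipeline agrees with limma lmFit + eBayes", {
  pp <- default_preprocessed()
  ann <- pp$annotations
  keep <- ann$mask == "CD68" & ann$region %in% c("LZ", "DZ")
  m <- unclass(pp$log2)[, ann$aoi_id[keep]]
  grp <- factor(ann$region[keep], levels = c("DZ", "LZ"))
  design <- model.matrix(~grp)
  lfit <- limma::eBayes(limma::lmFit(m, design))
  ours <- run_dea(pp$log2, ann, "LZ_vs_DZ")
  lp <- lfit$p.value[ours$gene, "grpLZ"]
  expect_equal(ours$log2FC, unname(lfit$coefficients[ours$gene, "grpLZ"]),
               tolerance = 1e-9)
  expect_equal(ours$p, unname(lp), tolerance = 0.02)
  expect_gt(cor(-log10(ours$p), -log10(lp)), 0.9999)
})

test_that("BH adjustment equals the brute-force step-up and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(10)
  for (i in 1:20) {
    p <- runif(sample(5:200, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})
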