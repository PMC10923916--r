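toy_cohort <- function(x, genes = NULL, time = NULL, event = NULL) {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(x)))
  dimnames(x) <- list(genes, sprintf("p%d", seq_len(ncol(x))))
  n <- ncol(x)
  cohort_dataset(expr_matrix(x, "log2"),
                 data.frame(patient_id = colnames(x),
                            time = if (is.null(time)) seq_len(n) else time,
                            event = if (is.null(event)) rep(1, n) else event))
}

test_that("the weighted score reproduces the hand-computed 3-gene example", {
  # (p, I, x) = (0.01,+1,2), (0.1,-1,3), (0.001,+1,-1) -> 2*2 + 1*(-3) + 3*(-1) = -2
  sig <- macrosig("s", data.frame(gene = c("g1", "g2", "g3"),
                                  weight = -log10(c(0.01, 0.1, 0.001)),
                                  sign = c(1, -1, 1),
                                  log2FC = c(1, -1, 1), adj_p = 0.01))
  co <- toy_cohort(matrix(c(2, 3, -1,  0, 0, 0), 3, 2))
  sc <- signature_score(co, sig, standardize = FALSE)
  expect_equal(unname(sc["p1"]), -2)
  expect_equal(unname(sc["p2"]), 0)

  one <- macrosig("one", data.frame(gene = "g1", weight = -log10(0.1),
                                    sign = 1, log2FC = 1, adj_p = 0.01))
  co1 <- toy_cohort(matrix(c(1, 0), 1, 2))
  expect_equal(unname(signature_score(co1, one, standardize = FALSE)["p1"]), 1)
  flip <- one; flip$entries$sign <- -1
  expect_equal(unname(signature_score(co1, flip, standardize = FALSE)["p1"]), -1)
})

test_that("scores are linear in weights and invariant to orderings and shifts", {
  set.seed(30)
  x <- matrix(rnorm(200, 8), 10, 20)
  co <- toy_cohort(x)
  sig <- macrosig("s", data.frame(gene = sprintf("g%d", 1:10),
                                  weight = runif(10, 0.5, 3),
                                  sign = sample(c(-1, 1), 10, TRUE),
                                  log2FC = rnorm(10), adj_p = 0.01))
  base <- signature_score(co, sig, standardize = FALSE)
  dbl <- sig; dbl$entries$weight <- 2 * dbl$entries$weight
  expect_identical(signature_score(co, dbl, standardize = FALSE), 2 * base)

  perm <- sig; perm$entries <- perm$entries[sample(10), ]
  expect_equal(signature_score(co, perm, standardize = FALSE), base)
  co_perm <- toy_cohort(x[, 20:1])
  colnames(co_perm$expression) <- sprintf("p%d", 20:1)
  expect_equal(sort(signature_score(co_perm, sig, standardize = FALSE)),
               sort(base))

  # standardize: adding a constant to one gene's row changes nothing
  shifted <- x; shifted[4, ] <- shifted[4, ] + 100
  s1 <- signature_score(co, sig, standardize = TRUE)
  s2 <- signature_score(toy_cohort(shifted), sig, standardize = TRUE)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("scoring errors on poor overlap and drops flat genes", {
  set.seed(31)
  co <- toy_cohort(matrix(rnorm(40, 8), 2, 20), genes = c("g1", "g2"))
  sig <- macrosig("s", data.frame(gene = sprintf("g%d", 1:5), weight = 1,
                                  sign = 1, log2FC = 1, adj_p = 0.01))
  expect_error(signature_score(co, sig), ">= 50%")

  x <- matrix(rnorm(60, 8), 3, 20)
  x[2, ] <- 5  # zero variance
  co2 <- toy_cohort(x)
  sig3 <- macrosig("s", data.frame(gene = c("g1", "g2", "g3"), weight = 1,
                                   sign = 1, log2FC = 1, adj_p = 0.01))
  expect_warning(sc <- signature_score(co2, sig3, standardize = TRUE),
                 "zero-variance")
  expect_equal(attr(sc, "n_genes"), 2)
})

test_that("tertile stratification uses type-7 cuts with lower-group ties", {
  sc <- setNames(as.numeric(1:9), sprintf("p%d", 1:9))
  st <- tertile_stratify(sc)
  expect_identical(st$patient_id[st$group == "low"], sprintf("p%d", 1:3))
  expect_identical(st$patient_id[st$group == "mid"], sprintf("p%d", 4:6))
  expect_identical(st$patient_id[st$group == "high"], sprintf("p%d", 7:9))

  expect_error(tertile_stratify(setNames(rep(1, 9), sprintf("p%d", 1:9))),
               "degenerate")
  expect_error(tertile_stratify(setNames(1:5, sprintf("p%d", 1:5))),
               "at least 6")

  set.seed(33)
  r <- setNames(rnorm(10), sprintf("p%d", 1:10))
  st2 <- tertile_stratify(r)
  q <- quantile(r, c(1, 2) / 3, type = 7)
  oracle <- ifelse(r <= q[1], "low", ifelse(r > q[2], "high", "mid"))
  expect_identical(as.character(st2$group), unname(oracle))

  # negating scores swaps low and high exactly (cutpoints interpolate when
  # n mod 3 != 1, so no score sits on a boundary)
  r <- setNames(rnorm(11), sprintf("p%d", 1:11))
  st2 <- tertile_stratify(r)
  st3 <- tertile_stratify(-r)
  expect_identical(st2$patient_id[st2$group == "low"],
                   st3$patient_id[st3$group == "high"])
  expect_identical(st2$patient_id[st2$group == "high"],
                   st3$patient_id[st3$group == "low"])
})

test_that("single-cell QC removes low-quality cells and rare genes", {
  set.seed(34)
  n_genes <- 300
  counts <- matrix(rpois(n_genes * 5, 2), n_genes, 5,
                   dimnames = list(c(sprintf("G%03d", 1:(n_genes - 1)), "MT-1"),
                                   sprintf("c%d", 1:5)))
  counts[, 1][counts[, 1] > 0][-(1:100)] <- 0   # keep detections low
  counts[, 1] <- 0; counts[1:150, 1] <- 1       # 150 detected genes -> removed
  counts[, 2] <- 0; counts[1:200, 2] <- 1       # exactly 200 -> kept
  counts["MT-1", 3] <- ceiling(0.13 / 0.87 * sum(counts[-n_genes, 3]))  # >10%
  counts["MT-1", 4] <- 0
  counts["MT-1", 5] <- 0
  out <- sc_qc_filter(expr_matrix(counts, "counts"), "MT-1")
  expect_false("c1" %in% colnames(out))
  expect_true("c2" %in% colnames(out))
  expect_false("c3" %in% colnames(out))

  # gene present in 2 cells is removed, in 3 retained
  m2 <- matrix(1, 4, 4, dimnames = list(sprintf("G%d", 1:4), sprintf("c%d", 1:4)))
  m2[1, 1:2] <- 0   # detected in 2 cells
  m2[2, 1] <- 0     # detected in 3 cells
  out2 <- sc_qc_filter(expr_matrix(m2, "counts"), character(0), min_genes = 1)
  expect_false("G1" %in% rownames(out2))
  expect_true("G2" %in% rownames(out2))
})

test_that("module scores separate planted clusters at the 0.1 call threshold", {
  sig <- gene_signature("mac", sprintf("G%04d", 1:30))
  sc <- simulate_single_cell(sim_params(n_genes = 600, seed = 12,
                                        n_cells_per_cluster = 200), list(sig))
  norm <- sc_lognormalize(sc_qc_filter(sc$counts, sc$mito_genes, min_genes = 20))
  ms <- module_score(norm, sig, seed = 99)
  expect_identical(ms$expressing, ms$score > 0.1)
  cl <- sc$clusters[ms$cell]
  expect_gte(mean(ms$expressing[cl == "mac"]), 0.9)
  expect_lte(mean(ms$expressing[cl == "background"]), 0.1)
  # reproducible given the seed
  ms2 <- module_score(norm, sig, seed = 99)
  expect_identical(ms, ms2)
  expect_error(module_score(norm, gene_signature("x", "NOPE")), "no signature gene")
})
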