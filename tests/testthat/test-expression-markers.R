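test_that("median-of-ratios factors recover scale differences", {
  m <- matrix(rpois(200, 50) + 1, nrow = 100,
              dimnames = list(paste0("G", 1:100), c("a", "b")))
  m[, "b"] <- m[, "a"]
  nf <- normalize_counts(m)
  expect_equal(unname(nf$size_factors), c(1, 1))
  # sample b = 2x sample a countwise -> factors proportional to {1, 2}
  m2 <- m
  m2[, "b"] <- 2 * m2[, "a"]
  nf2 <- normalize_counts(m2)
  expect_equal(unname(nf2$size_factors[2] / nf2$size_factors[1]), 2)
  expect_equal(nf2$normalized[, "a"], nf2$normalized[, "b"])
  # an all-zero gene is excluded from estimation but kept in the matrix
  m3 <- rbind(m2, ZZ = c(0, 0))
  nf3 <- normalize_counts(m3)
  expect_true("ZZ" %in% rownames(nf3$normalized))
  expect_equal(nf3$size_factors, nf2$size_factors)
})

test_that("normalization preserves within-sample gene rank order", {
  set.seed(5)
  m <- matrix(rnbinom(500, mu = 60, size = 3) + 1, nrow = 100)
  rownames(m) <- paste0("G", 1:100)
  colnames(m) <- paste0("s", 1:5)
  nf <- normalize_counts(m)
  for (j in 1:5) expect_equal(rank(nf$normalized[, j]), rank(m[, j]))
})

test_that("purity scores are rank-invariant and enforce the exclusion cut", {
  set.seed(8)
  m <- matrix(rnorm(100 * 6, 5, 1), nrow = 100,
              dimnames = list(paste0("G", 1:100), paste0("s", 1:6)))
  imm <- paste0("G", 1:10); str_ <- paste0("G", 11:20)
  # push immune genes to the top in sample s1
  m[imm, "s1"] <- m[imm, "s1"] + 10
  ps <- suppressWarnings(purity_scores(m, imm, str_))
  expect_equal(ps$sample_id[which.max(ps$immune)], "s1")
  ps2 <- suppressWarnings(purity_scores(m[sample(rownames(m)), ], imm, str_))
  expect_equal(ps$immune, ps2$immune)
  # combined score above the threshold is flagged excluded
  ps3 <- suppressWarnings(purity_scores(m, imm, str_,
                                        exclude_above = min(ps$combined) - 1))
  expect_true(all(ps3$excluded))
  expect_error(purity_scores(m, "G1", str_), "fewer than 2")
})

test_that("differential stats recover planted fold changes and match lm", {
  set.seed(21)
  n <- 30
  labels <- rep(c("non", "met"), each = n / 2)
  m <- matrix(rnorm(50 * n, 8, 0.5), nrow = 50,
              dimnames = list(paste0("G", 1:50), paste0("s", 1:n)))
  m["G1", labels == "met"] <- m["G1", labels == "met"] + 2   # planted 4-fold
  cov_ <- rnorm(n)
  st <- differential_stats(m, factor(labels, levels = c("non", "met")), cov_)
  expect_equal(st$log2fc[st$gene == "G1"], 2, tolerance = 0.25)
  expect_lt(st$fdr[st$gene == "G1"], 0.01)
  # identical groups -> log2fc 0
  m["G2", ] <- 5
  st2 <- differential_stats(m, factor(labels, levels = c("non", "met")), cov_)
  expect_equal(st2$log2fc[st2$gene == "G2"], 0)
  expect_equal(st2$p[st2$gene == "G2"], 1)
  # per-gene p matches stats::lm on a handful of genes
  for (g in c("G1", "G5", "G9")) {
    fit <- summary(lm(m[g, ] ~ I(labels == "met") + cov_))
    expect_equal(st2$p[st2$gene == g], fit$coefficients[2, 4], tolerance = 1e-8)
  }
})

test_that("null differential expression is calibrated", {
  set.seed(77)
  n <- 40
  m <- matrix(rnorm(400 * n, 8, 1), nrow = 400,
              dimnames = list(paste0("G", 1:400), paste0("s", 1:n)))
  labels <- sample(rep(c("a", "b"), each = n / 2))
  st <- differential_stats(m, labels)
  expect_lt(sum(st$fdr < 0.05), 8)   # FDR controls false calls on null data
  expect_gt(mean(st$p), 0.4)         # p roughly uniform
})

test_that("signature selection applies magnitude, consistency and FDR rules", {
  mk_stats <- function(lfc, fdr = 1e-4) {
    tibble::tibble(gene = paste0("G", seq_along(lfc)), log2fc = lfc,
                   p = fdr, fdr = fdr)
  }
  strata <- list(
    pseudohypoxic = mk_stats(c(1.2, 0.75, 1.0, -1.0, 2.0)),
    kinase = mk_stats(c(1.0, 0.9, -1.0, -1.2, 1.4)),
    wnt = mk_stats(c(0.9, 0.8, 1.1, -0.9, 1.1)))
  pooled <- mk_stats(c(1.0, 0.8, 1.0, -1.0, 1.5),
                     fdr = c(0.001, 0.001, 0.001, 0.001, 0.5))
  sel <- select_signature(strata, pooled)
  # G1: passes everywhere. G2: |lfc| = 0.75 exactly in one stratum -> out.
  # G3: sign-discordant -> out. G4: consistent down -> in. G5: pooled FDR
  # 0.5 -> out.
  expect_setequal(sel$gene, c("G1", "G4"))
  expect_equal(sel$direction[sel$gene == "G1"], "up_in_metastatic")
  expect_equal(sel$direction[sel$gene == "G4"], "down_in_metastatic")
  # NULL stratum skipped with warning
  strata_null <- c(strata, list(extra = NULL))
  expect_warning(sel2 <- select_signature(strata_null, pooled), "skipped")
  expect_setequal(sel2$gene, sel$gene)
})

test_that("signature-gene dichotomization uses Q3 for up and median for down", {
  x <- c(1:8)
  expect_equal(dichotomize_signature_gene(x, "up_in_metastatic"),
               c(rep(0L, 6), 1L, 1L))
  expect_equal(dichotomize_signature_gene(x, "down_in_metastatic"),
               c(rep(0L, 4), rep(1L, 4)))
  # exactly at Q3 -> 0 (strict)
  q3 <- quantile(x, 0.75)
  y <- c(x, q3)
  d <- dichotomize_signature_gene(y, "up_in_metastatic")
  expect_equal(d[length(y)], 0L)
})

test_that("batch adjustment aligns per-batch location and scale", {
  set.seed(9)
  m <- matrix(rnorm(50 * 20, 5, 1), nrow = 50)
  colnames(m) <- paste0("s", 1:20)
  batch <- rep(c("A", "B"), each = 10)
  m[, batch == "B"] <- m[, batch == "B"] + 3
  adj <- adjust_batch(m, batch)
  shifts <- rowMeans(adj[, batch == "B"]) - rowMeans(adj[, batch == "A"])
  expect_lt(max(abs(shifts)), 1e-8)
})
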