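test_that("subset enumeration is complete and deterministically ordered", {
  s9 <- enumerate_subsets(letters[1:9])
  expect_length(s9, 511)
  expect_length(enumerate_subsets("a"), 1)
  expect_length(enumerate_subsets(letters[1:4]), 15)
  sizes <- lengths(s9)
  expect_true(all(diff(sizes) >= 0))             # ordered by size
  expect_equal(anyDuplicated(vapply(s9, paste, "", collapse = "+")), 0)
  expect_error(enumerate_subsets(character()), "at least one")
})

test_that("OR combination is the any-event rule and monotone in the subset", {
  m <- tibble::tibble(A = c(1, 0, 0), B = c(0, 0, 1), C = c(0, 0, 0))
  expect_equal(or_combine(m, c("A", "B")), c(1L, 0L, 1L))
  expect_equal(or_combine(m, "C"), c(0L, 0L, 0L))
  expect_error(or_combine(m, character()), "empty")
  set.seed(6)
  big <- as.data.frame(matrix(rbinom(50 * 4, 1, 0.3), ncol = 4,
                              dimnames = list(NULL, c("A", "B", "C", "D"))))
  for (i in 1:10) {
    sub <- sample(c("A", "B", "C", "D"), 2)
    sup <- union(sub, sample(c("A", "B", "C", "D"), 1))
    expect_true(all(or_combine(big, sup) >= or_combine(big, sub)))
  }
})

test_that("binary evaluation returns the single-operating-point ROC summary", {
  truth <- c(1, 1, 1, 0, 0, 0)
  expect_equal(evaluate_binary(truth, truth)$auc, 1)
  all_pos <- evaluate_binary(rep(1, 6), truth)
  expect_equal(all_pos$sensitivity, 1)
  expect_equal(all_pos$specificity, 0)
  expect_equal(all_pos$auc, 0.5)
  # sens 1, spec 0.8 -> trapezoid AUC 0.9
  pred <- c(1, 1, 1, 1, 0, 0, 0, 0)
  tr <- c(1, 1, 1, 0, 0, 0, 0, 0)
  got <- evaluate_binary(pred, tr)
  expect_equal(got$sensitivity, 1)
  expect_equal(got$specificity, 0.8)
  expect_equal(got$auc, 0.9)
  expect_error(evaluate_binary(c(1, 0), c(1, 1)), "degenerate")
})

test_that("AUC equals the brute-force Mann-Whitney pair probability", {
  set.seed(14)
  for (i in 1:50) {
    n <- sample(6:50, 1)
    truth <- c(1, 0, rbinom(n - 2, 1, 0.4))
    pred <- rbinom(n, 1, 0.5)
    got <- evaluate_binary(pred, truth)$auc
    expect_equal(got, oracle_auc_mw(pred, truth), tolerance = 1e-12)
  }
})

test_that("DeLong interval brackets the AUC and matches pROC", {
  skip_if_not_installed("pROC")
  set.seed(15)
  truth <- rbinom(80, 1, 0.4)
  truth[1:2] <- c(0, 1)
  pred <- as.integer(truth == 1 & runif(80) < 0.8 | runif(80) < 0.15)
  got <- evaluate_binary(pred, truth)
  pr <- pROC::roc(truth, pred, quiet = TRUE, direction = "<")
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(got$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  expect_equal(got$auc_ci_low, max(0, ci[1]), tolerance = 1e-9)
  expect_equal(got$auc_ci_high, min(1, ci[3]), tolerance = 1e-9)
  expect_true(got$auc_ci_low <= got$auc && got$auc <= got$auc_ci_high)
})

test_that("search evaluates every subset and ranks a planted combination first", {
  sim <- simulate_marker_cohort(n = 200, seed = 19)
  res <- classifier_search(sim$markers, ci = "none")
  expect_equal(nrow(res$results), 511)
  best_events <- strsplit(res$best$subset, "+", fixed = TRUE)[[1]]
  expect_setequal(best_events, sim$truth$planted)
  # a planted pair beats its singletons
  m2 <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:20),
    label = rep(c(1L, 0L), each = 10),
    A = c(rep(1, 5), rep(0, 15)),
    B = c(rep(0, 5), rep(1, 5), rep(0, 10)))
  r2 <- classifier_search(m2, ci = "none")
  tab <- r2$results
  auc_of <- function(s) tab$auc[tab$subset == s]
  expect_gt(auc_of("A+B"), auc_of("A"))
  expect_gt(auc_of("A+B"), auc_of("B"))
  # a single perfectly predictive event is best with AUC 1
  m3 <- tibble::tibble(sample_id = sprintf("S%02d", 1:20),
                       label = rep(c(1L, 0L), each = 10),
                       P = rep(c(1L, 0L), each = 10),
                       Q = rbinom(20, 1, 0.5))
  r3 <- classifier_search(m3, ci = "none")
  expect_equal(r3$best$subset, "P")
  expect_equal(r3$best$auc, 1)
})

test_that("search is invariant to row order and reports the sens-1 winner", {
  sim <- simulate_marker_cohort(n = 120, seed = 23)
  res <- classifier_search(sim$markers, ci = "none")
  perm <- sim$markers[sample(nrow(sim$markers)), ]
  res_perm <- classifier_search(perm, ci = "none")
  expect_equal(res$results, res_perm$results)
  expect_equal(res$best_sens1$sensitivity, 1)
  expect_true(!is.na(res$best$auc_ci_low))  # headline CI always filled
})

test_that("OR monotonicity holds across subset pairs on random matrices", {
  set.seed(99)
  for (i in 1:20) {
    n <- 40
    m <- as.data.frame(matrix(rbinom(n * 5, 1, runif(1, 0.1, 0.5)), ncol = 5,
                              dimnames = list(NULL, c("A", "B", "C", "D", "E"))))
    m$label <- rbinom(n, 1, 0.4)
    if (length(unique(m$label)) < 2) next
    res <- classifier_search(m, ci = "none")$results
    res$events <- strsplit(res$subset, "+", fixed = TRUE)
    for (j in sample(nrow(res), 10)) {
      sub <- res$events[[j]]
      sups <- which(vapply(res$events, function(e)
        all(sub %in% e) && length(e) > length(sub), TRUE))
      expect_true(all(res$sensitivity[sups] >= res$sensitivity[j] - 1e-12))
      expect_true(all(res$specificity[sups] <= res$specificity[j] + 1e-12))
    }
  }
})

test_that("tidy and glance summarize a search", {
  sim <- simulate_marker_cohort(n = 80, seed = 3)
  res <- classifier_search(sim$markers, ci = "none")
  td <- tidy(res)
  expect_equal(nrow(td), 511)
  gl <- glance(res)
  expect_equal(gl$n_classifiers, 511)
  expect_equal(gl$best_auc, res$best$auc)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
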