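test_that("segment filter applies the CN cap and log-ratio deadband", {
  s <- tibble::tibble(
    sample_id = "S1", chrom = "1", start = c(1, 100, 200, 300, 400),
    end = c(50, 150, 250, 350, 450),
    total_cn = c(9L, 8L, 2L, 2L, 2L),
    minor_cn = c(4L, 4L, 1L, 0L, 1L),
    log_ratio = c(1.2, 0.4, 0.05, 0.05, -0.5),
    annotation = c("DUP", "DUP", "NEUTRAL", "LOH-NEUTRAL", "HEMYZIG"))
  kept <- filter_segments(s)
  expect_false(9L %in% kept$total_cn)          # > 8 dropped
  expect_true(8L %in% kept$total_cn)           # boundary kept (strict >)
  expect_false(any(kept$annotation == "NEUTRAL" & abs(kept$log_ratio) < 0.1))
  expect_true("LOH-NEUTRAL" %in% kept$annotation)  # deadband exemption
  expect_identical(filter_segments(kept), kept)    # idempotent
})

test_that("SCNA burden counts non-neutral kept segments, NA for absent samples", {
  s <- tibble::tibble(
    sample_id = rep("S1", 6), chrom = "1", start = 1:6 * 100,
    end = 1:6 * 100 + 50, total_cn = c(3L, 3L, 1L, 0L, 2L, 2L),
    minor_cn = 1L, log_ratio = c(0.4, 0.4, -0.6, -1.8, 0, 0),
    annotation = c("DUP", "DUP", "HEMYZIG", "DEL", "NEUTRAL", "NEUTRAL"))
  b <- scna_burden(s, samples = c("S1", "S2"))
  expect_equal(b$scna_burden[b$sample_id == "S1"], 4L)
  expect_true(is.na(b$scna_burden[b$sample_id == "S2"]))
  expect_equal(scna_burden(s[0, ], samples = "S1")$scna_burden, NA_integer_)
})

test_that("burden never increases when filters tighten", {
  set.seed(7)
  s <- tibble::tibble(
    sample_id = "S1", chrom = "1", start = 1:50 * 1000,
    end = 1:50 * 1000 + 500,
    total_cn = sample(0:10, 50, TRUE), minor_cn = 0L,
    log_ratio = runif(50, -1, 1),
    annotation = sample(c("DUP", "HEMYZIG", "NEUTRAL"), 50, TRUE))
  loose <- scna_burden(filter_segments(s, cn_cap = 8, lr_deadband = c(-0.1, 0.1)))
  tight <- scna_burden(filter_segments(s, cn_cap = 6, lr_deadband = c(-0.3, 0.3)))
  loose_n <- if (nrow(loose)) loose$scna_burden else 0L
  tight_n <- if (nrow(tight)) tight$scna_burden else 0L
  expect_lte(tight_n, loose_n)
})

test_that("arm-level calls follow coverage thresholds and tie rules", {
  arms <- tibble::tibble(chrom = c("1", "1"), arm = c("1p", "1q"),
                         start = c(1, 1001), end = c(1000, 2000))
  # DEL covering 90% of 1p
  s <- tibble::tibble(sample_id = "S1", chrom = "1", start = 1, end = 900,
                      total_cn = 0L, minor_cn = 0L, log_ratio = -1.8,
                      annotation = "DEL")
  calls <- call_arm_levels(s, arms, min_fraction = 0.5)
  p_call <- calls[calls$arm == "1p", ]
  expect_equal(p_call$status, "loss")
  expect_equal(p_call$covered_fraction, 0.9)
  expect_equal(calls$status[calls$arm == "1q"], "neutral")
  # 40% coverage below the 0.5 threshold
  s40 <- s; s40$end <- 400
  expect_equal(call_arm_levels(s40, arms)$status[1], "neutral")
  # equal gain and loss coverage -> neutral
  tie <- tibble::tibble(
    sample_id = "S1", chrom = "1", start = c(1, 501), end = c(500, 1000),
    total_cn = c(3L, 1L), minor_cn = c(1L, 0L), log_ratio = c(0.4, -0.6),
    annotation = c("DUP", "HEMYZIG"))
  tie_call <- call_arm_levels(tie, arms)
  expect_equal(tie_call$status[tie_call$arm == "1p"], "neutral")
  # out-of-bounds segments are clipped with a warning
  oob <- s; oob$end <- 1500
  expect_warning(clip <- call_arm_levels(oob, arms), "clipped")
  expect_lte(max(clip$gain_fraction, clip$loss_fraction), 1)
})

test_that("arm coverage fractions stay within [0, 1]", {
  set.seed(11)
  arms <- arm_table("GRCh37")
  s <- tibble::tibble(
    sample_id = rep(c("A", "B"), each = 30), chrom = as.character(sample(1:22, 60, TRUE)),
    start = sample.int(5e7, 60), total_cn = sample(0:4, 60, TRUE),
    minor_cn = 0L, log_ratio = runif(60, -1, 1),
    annotation = sample(c("DUP", "DUP-LOH", "HEMYZIG", "DEL"), 60, TRUE))
  s$end <- s$start + sample.int(8e7, 60)
  calls <- suppressWarnings(call_arm_levels(s, arms))
  expect_true(all(calls$gain_fraction >= 0 & calls$gain_fraction <= 1))
  expect_true(all(calls$loss_fraction >= 0 & calls$loss_fraction <= 1))
})

test_that("whole-chromosome gain needs every cataloged arm gained", {
  calls <- tibble::tibble(
    sample_id = c("S1", "S1", "S2", "S2", "S3"),
    arm = c("5p", "5q", "5p", "5q", "5p"),
    chrom = "5",
    status = c("gain", "gain", "gain", "neutral", "gain"),
    gain_fraction = 0.9, loss_fraction = 0, covered_fraction = 0.9)
  g <- whole_chromosome_gain(calls, "5")
  expect_true(g$whole_gain[g$sample_id == "S1"])
  expect_false(g$whole_gain[g$sample_id == "S2"])
  # single cataloged arm: call made on what exists, flagged
  expect_true(g$whole_gain[g$sample_id == "S3"])
  expect_true(g$flagged[g$sample_id == "S3"])
})

test_that("genome doubling uses length-weighted major copy number", {
  dbl <- tibble::tibble(sample_id = "S1", chrom = "1", start = 1, end = 1000,
                        total_cn = 4L, minor_cn = 2L, log_ratio = 0.9,
                        annotation = "DUP")
  expect_true(genome_doubled(dbl)$doubled)
  dip <- dbl; dip$total_cn <- 2L; dip$minor_cn <- 1L
  expect_false(genome_doubled(dip)$doubled)
  # 60% of covered genome at major cn 2 -> doubled
  mix <- tibble::tibble(
    sample_id = "S1", chrom = "1", start = c(1, 601), end = c(600, 1000),
    total_cn = c(3L, 2L), minor_cn = c(1L, 1L), log_ratio = c(0.4, 0),
    annotation = c("DUP", "NEUTRAL"))
  g <- genome_doubled(mix)
  expect_equal(g$doubled_fraction, 0.6)
  expect_true(g$doubled)
  # minor CN missing everywhere: total - 1 approximation, flagged
  na_minor <- mix; na_minor$minor_cn <- NA_integer_
  g2 <- genome_doubled(na_minor)
  expect_true(g2$approximated)
})

test_that("per-arm Fisher tests match enumeration and respect BH", {
  calls <- tidyr::crossing(sample_id = sprintf("S%02d", 1:8),
                           arm = c("1p", "1q")) |>
    dplyr::mutate(chrom = "1", status = "neutral", gain_fraction = 0,
                  loss_fraction = 0, covered_fraction = 0)
  # arm 1p: losses in 3/4 metastatic vs 1/4 non-metastatic
  calls$status[calls$arm == "1p" & calls$sample_id %in%
                 c("S01", "S02", "S03", "S05")] <- "loss"
  groups <- tibble::tibble(sample_id = sprintf("S%02d", 1:8),
                           group = rep(c("met", "non"), each = 4))
  res <- arm_group_tests(calls, groups)
  p_1p_loss <- res$p[res$arm == "1p" & res$direction == "loss"]
  expect_equal(p_1p_loss, oracle_fisher_2x2(matrix(c(3, 1, 1, 3), 2)),
               tolerance = 1e-10)
  # identical groups -> p = 1; degenerate arms flagged
  expect_equal(res$p[res$arm == "1q" & res$direction == "gain"], 1)
  expect_true(all(res$degenerate[res$arm == "1q"]))
  expect_true(all(res$q >= res$p - 1e-12))
})
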