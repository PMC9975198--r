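test_that("consequence exclusion list matches the curation vocabulary", {
  expect_true(consequence_excluded("intron_variant"))
  expect_true(consequence_excluded("mature_miRNA_variant"))
  expect_false(consequence_excluded("missense_variant"))
  expect_false(consequence_excluded("totally_novel_term"))
})

test_that("curation ladder removes in order and records first reason", {
  v <- tibble::tibble(
    sample_id = "S1", chrom = "1", pos = 1:5 * 10L, ref = "A", alt = "G",
    gene = paste0("G", 1:5),
    consequence = c("intron_variant", "missense_variant", "missense_variant",
                    "missense_variant", "missense_variant"),
    vaf = c(0.05, 0.3, 0.3, 0.10, 0.05),
    gnomad_af = c(0.5, 0.2, NA, NA, NA), kg_af = NA_real_,
    deleterious_votes = 0L, in_cosmic = FALSE,
    artifact_flag = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  cur <- curate_variants(v)
  # both consequence and low VAF apply to row 1: consequence wins (first rung)
  expect_equal(cur$removal_reason,
               c("consequence_excluded", "germline_like", "artifact", NA, "low_vaf"))
  # VAF exactly 0.1 is retained (strict < 0.1 removal)
  expect_equal(cur$status[4], "retained")
  # survivors match rules applied independently per record
  indep <- !(consequence_excluded(v$consequence) |
               (!is.na(v$gnomad_af) & v$gnomad_af > 0.1) |
               v$artifact_flag | v$vaf < 0.1)
  expect_equal(cur$status == "retained", indep)
})

test_that("missing population AF never triggers germline-like removal", {
  v <- make_variants()
  cur <- curate_variants(v)
  na_af <- is.na(v$gnomad_af) & is.na(v$kg_af)
  expect_false(any(cur$removal_reason[na_af] %in% "germline_like"))
  expect_equal(cur$removal_reason[v$gnomad_af %in% 0.2], "germline_like")
})

test_that("high-impact calls cover truncating, predictor-vote and COSMIC routes", {
  expect_true(is_high_impact("stop_gained"))
  expect_true(is_high_impact("splice_donor_variant"))
  expect_false(is_high_impact("missense_variant", deleterious_votes = 2))
  expect_true(is_high_impact("missense_variant", deleterious_votes = 3))
  expect_true(is_high_impact("missense_variant", in_cosmic = TRUE))
  expect_false(is_high_impact("synonymous_variant", deleterious_votes = 5))
})

test_that("TMB counts retained coding variants above the VAF cut", {
  v <- make_variants()
  cur <- curate_variants(v)
  tmb <- compute_tmb(cur, samples = c("S1", "S2", "S3"))
  # S1: missense(0.3) + stop_gained(0.4) count; intron removed; vaf 0.05
  # removed; synonymous retained but non-coding for TMB
  expect_equal(tmb$tmb[tmb$sample_id == "S1"], 2L)
  # S2: gnomad 0.2 removed; vaf 0.10 not > 0.1 -> only the 0.25 missense left
  expect_equal(tmb$tmb[tmb$sample_id == "S2"], 1L)
  # S3 has no variant data: NA, not zero
  expect_true(is.na(tmb$tmb[tmb$sample_id == "S3"]))
  # sample whose records are all removed -> 0
  all_rm <- curate_variants(tibble::tibble(
    sample_id = "S9", chrom = "1", pos = 10L, ref = "A", alt = "G",
    gene = "G1", consequence = "intron_variant", vaf = 0.4,
    gnomad_af = NA_real_, kg_af = NA_real_, deleterious_votes = 0L,
    in_cosmic = FALSE, artifact_flag = FALSE))
  expect_equal(compute_tmb(all_rm)$tmb, 0L)
})

test_that("ladder filters are monotone and order-independent on survivors", {
  set.seed(42)
  n <- 300
  v <- tibble::tibble(
    sample_id = sample(paste0("S", 1:5), n, TRUE), chrom = "1",
    pos = seq_len(n), ref = "A", alt = "G", gene = paste0("G", seq_len(n)),
    consequence = sample(c("intron_variant", "5_prime_UTR_variant",
                           "missense_variant", "stop_gained",
                           "synonymous_variant"), n, TRUE),
    vaf = runif(n), gnomad_af = ifelse(runif(n) < 0.3, runif(n, 0, 0.4), NA),
    kg_af = ifelse(runif(n) < 0.2, runif(n, 0, 0.4), NA),
    deleterious_votes = rbinom(n, 4, 0.3), in_cosmic = runif(n) < 0.1,
    artifact_flag = runif(n) < 0.1)
  cur <- curate_variants(v)
  # survivor set equals the jointly-applied predicate set (order irrelevant)
  joint <- !(consequence_excluded(v$consequence) |
               (ifelse(is.na(v$gnomad_af), 0, v$gnomad_af) > 0.1) |
               (ifelse(is.na(v$kg_af), 0, v$kg_af) > 0.1) |
               v$artifact_flag | v$vaf < 0.1)
  expect_equal(cur$status == "retained", joint)
  # successive filters only shrink the survivor set
  s0 <- !consequence_excluded(v$consequence)
  s1 <- s0 & !(ifelse(is.na(v$gnomad_af), 0, v$gnomad_af) > 0.1 |
                 ifelse(is.na(v$kg_af), 0, v$kg_af) > 0.1)
  s2 <- s1 & !v$artifact_flag
  s3 <- s2 & !(v$vaf < 0.1)
  expect_true(all(s1 <= s0) && all(s2 <= s1) && all(s3 <= s2))
  # TMB equals brute-force joint count per sample
  tmb <- compute_tmb(cur)
  brute <- tapply(joint & !(v$consequence %in% c("synonymous_variant")) &
                    !consequence_excluded(v$consequence) & v$vaf > 0.1,
                  v$sample_id, sum)
  expect_equal(tmb$tmb, as.integer(brute[tmb$sample_id]),
               ignore_attr = TRUE)
  expect_true(all(tmb$tmb >= 0))
})
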