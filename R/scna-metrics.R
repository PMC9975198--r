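GAIN_ANNOTATIONS <- c("DUP", "DUP-LOH")
LOSS_ANNOTATIONS <- c("HEMYZIG", "DEL")

#' Filter FACETS-style copy-number segments
#'
#' Drops segments with total copy number strictly above `cn_cap` and segments
#' whose log-ratio lies strictly inside the deadband, except those annotated
#' copy-neutral LOH (`LOH-NEUTRAL`), which are always kept. Idempotent.
#'
#' @param segments segment tibble ([read_segment_table()]).
#' @param cn_cap maximum believable total copy number (default 8; strict `>`
#'   removal).
#' @param lr_deadband length-2 numeric, open interval of log-ratios treated as
#'   noise (default `c(-0.1, 0.1)`).
#' @return filtered tibble.
#' @export
filter_segments <- function(segments, cn_cap = 8, lr_deadband = c(-0.1, 0.1)) {
  s <- as_tibble(segments)
  if (nrow(s) == 0) return(s)
  drop_cn <- s$total_cn > cn_cap
  in_deadband <- s$log_ratio > lr_deadband[1] & s$log_ratio < lr_deadband[2]
  drop_lr <- in_deadband & s$annotation != "LOH-NEUTRAL"
  s[!(drop_cn | drop_lr), , drop = FALSE]
}

#' Somatic copy-number alteration burden per sample
#'
#' SCNA burden is the count of filtered segments that are not annotated
#' `NEUTRAL`. Samples named in `samples` but absent from the segment table get
#' `NA`, never 0.
#'
#' @param segments filtered segments ([filter_segments()]).
#' @param samples optional sample-id universe.
#' @return tibble `sample_id`, `scna_burden`.
#' @export
scna_burden <- function(segments, samples = NULL) {
  counts <- segments |>
    group_by(.data$sample_id) |>
    summarise(scna_burden = sum(.data$annotation != "NEUTRAL"), .groups = "drop")
  if (is.null(samples)) return(counts)
  tibble(sample_id = samples) |> left_join(counts, by = "sample_id")
}

# Sum of arm-overlap lengths for one sample's segments on one arm (1-based
# closed coordinates). Segments beyond arm bounds are clipped.
overlap_length <- function(seg_start, seg_end, arm_start, arm_end) {
  s <- pmax(seg_start, arm_start)
  e <- pmin(seg_end, arm_end)
  sum(pmax(0, e - s + 1))
}

#' Arm-level gain/loss calls
#'
#' Per sample and chromosome arm, computes the fraction of the arm covered by
#' gain-annotated (`DUP`, `DUP-LOH`) and by loss-annotated (`HEMYZIG`, `DEL`)
#' segments. An arm is called `gain` (`loss`) when the corresponding coverage
#' reaches `min_fraction`; if both directions qualify the larger coverage
#' wins, exact ties are `neutral`. Segments extending beyond the arm bounds
#' are clipped with a warning.
#'
#' @param segments filtered segments.
#' @param arm_table arm coordinates ([arm_table()]).
#' @param min_fraction minimum covered fraction of the arm length for a call
#'   (default 0.5).
#' @return tibble `sample_id`, `arm`, `chrom`, `status`, `gain_fraction`,
#'   `loss_fraction`, `covered_fraction` (coverage supporting the call).
#' @export
call_arm_levels <- function(segments, arm_table, min_fraction = 0.5) {
  seg <- as_tibble(segments)
  arms <- as_tibble(arm_table)
  samples <- unique(seg$sample_id)
  clipped <- FALSE
  grid <- tidyr::crossing(sample_id = samples, arm = arms$arm)
  arm_idx <- match(grid$arm, arms$arm)
  res <- purrr::map2_dfr(grid$sample_id, arm_idx, function(sid, ai) {
    a <- arms[ai, ]
    s <- seg[seg$sample_id == sid & seg$chrom == a$chrom, , drop = FALSE]
    s <- s[s$end >= a$start & s$start <= a$end, , drop = FALSE]
    if (nrow(s) > 0 && any(s$start < a$start | s$end > a$end)) clipped <<- TRUE
    arm_len <- a$end - a$start + 1
    g <- s[s$annotation %in% GAIN_ANNOTATIONS, , drop = FALSE]
    l <- s[s$annotation %in% LOSS_ANNOTATIONS, , drop = FALSE]
    gf <- min(1, overlap_length(g$start, g$end, a$start, a$end) / arm_len)
    lf <- min(1, overlap_length(l$start, l$end, a$start, a$end) / arm_len)
    status <- "neutral"
    if (gf >= min_fraction && (gf > lf || lf < min_fraction)) status <- "gain"
    if (lf >= min_fraction && (lf > gf || gf < min_fraction)) status <- "loss"
    if (gf >= min_fraction && lf >= min_fraction && gf == lf) status <- "neutral"
    tibble(sample_id = sid, arm = a$arm, chrom = a$chrom, status = status,
           gain_fraction = gf, loss_fraction = lf,
           covered_fraction = if (status == "gain") gf else if (status == "loss") lf else max(gf, lf))
  })
  if (clipped) warning("segment(s) beyond arm bounds were clipped", call. = FALSE)
  res
}

#' Whole-chromosome gain call
#'
#' A chromosome is whole-gained when every cataloged arm of that chromosome is
#' called `gain`. If the arm table lists only one arm (acrocentric catalogs),
#' the call is made on the available arm and flagged.
#'
#' @param arm_calls output of [call_arm_levels()].
#' @param chrom chromosome label (e.g. `"5"`).
#' @return tibble `sample_id`, `whole_gain`, `n_arms`, `flagged` (TRUE when
#'   fewer than two arms were available).
#' @export
whole_chromosome_gain <- function(arm_calls, chrom) {
  ac <- arm_calls[arm_calls$chrom == chrom, , drop = FALSE]
  if (nrow(ac) == 0) stop("no arm calls for chromosome ", chrom, call. = FALSE)
  ac |>
    group_by(.data$sample_id) |>
    summarise(whole_gain = all(.data$status == "gain"),
              n_arms = dplyr::n(), .groups = "drop") |>
    mutate(flagged = .data$n_arms < 2)
}

#' Genome-doubling call
#'
#' A genome is called doubled when the length-weighted fraction of the genome
#' with major copy number at least 2 exceeds 0.5. When `minor_cn` is missing
#' everywhere the major copy number is approximated by `total_cn - 1` and the
#' result flagged.
#'
#' @param segments filtered segments for one or more samples.
#' @param genome_length denominator; defaults to the summed segment lengths
#'   per sample.
#' @return tibble `sample_id`, `doubled`, `doubled_fraction`, `approximated`.
#' @export
genome_doubled <- function(segments, genome_length = NULL) {
  seg <- as_tibble(segments)
  approx <- all(is.na(seg$minor_cn))
  major <- if (approx) pmax(seg$total_cn - 1, 0) else seg$total_cn - seg$minor_cn
  seg$len <- seg$end - seg$start + 1
  seg$major_ge2 <- major >= 2
  out <- seg |>
    group_by(.data$sample_id) |>
    summarise(covered = sum(.data$len),
              doubled_len = sum(.data$len[.data$major_ge2]), .groups = "drop")
  denom <- if (is.null(genome_length)) out$covered else genome_length
  out$doubled_fraction <- out$doubled_len / denom
  out$doubled <- out$doubled_fraction > 0.5
  out$approximated <- approx
  out[, c("sample_id", "doubled", "doubled_fraction", "approximated")]
}

#' Per-arm group tests of alteration frequency
#'
#' For each arm and direction (gain, loss) builds the 2x2 table of altered vs
#' not by clinical group and applies a two-sided Fisher exact test;
#' Benjamini-Hochberg correction is applied across all arm-direction tests.
#' Arms with zero calls in both groups are reported with p = 1 and flagged
#' degenerate.
#'
#' @param arm_calls output of [call_arm_levels()].
#' @param groups tibble `sample_id`, `group` with exactly two group levels
#'   (e.g. metastatic primary vs non-metastatic).
#' @param fdr_threshold significance threshold on q (default 0.1).
#' @return tibble `arm`, `direction`, `p`, `q`, `significant`, `degenerate`
#'   plus per-group altered counts.
#' @export
arm_group_tests <- function(arm_calls, groups, fdr_threshold = 0.1) {
  groups <- as_tibble(groups)
  lv <- sort(unique(groups$group))
  if (length(lv) != 2) stop("exactly two groups required", call. = FALSE)
  df <- arm_calls |> inner_join(groups, by = "sample_id")
  res <- df |>
    tidyr::crossing(direction = c("gain", "loss")) |>
    group_by(.data$arm, .data$direction) |>
    summarise(
      n1_alt = sum(.data$status == .data$direction[1] & .data$group == lv[1]),
      n1_tot = sum(.data$group == lv[1]),
      n2_alt = sum(.data$status == .data$direction[1] & .data$group == lv[2]),
      n2_tot = sum(.data$group == lv[2]),
      .groups = "drop")
  res$degenerate <- res$n1_alt + res$n2_alt == 0
  res$p <- purrr::pmap_dbl(res[, c("n1_alt", "n1_tot", "n2_alt", "n2_tot")],
    function(n1_alt, n1_tot, n2_alt, n2_tot) {
      if (n1_alt + n2_alt == 0) return(1)
      tab <- matrix(c(n1_alt, n1_tot - n1_alt, n2_alt, n2_tot - n2_alt), 2)
      stats::fisher.test(tab)$p.value
    })
  res$q <- p.adjust(res$p, method = "BH")
  res$significant <- res$q < fdr_threshold
  res
}
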