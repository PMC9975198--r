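# Consequence vocabularies. Downstream matching is exact-string against the
# annotator's sequence-ontology terms.
CONSEQUENCE_EXCLUDE <- c(
  "intron_variant", "downstream_gene_variant", "3_prime_UTR_variant",
  "upstream_gene_variant", "NMD_transcript_variant",
  "non_coding_transcript_variant", "5_prime_UTR_variant",
  "mature_miRNA_variant")

CONSEQUENCE_TRUNCATING <- c(
  "stop_gained", "stop_lost", "start_lost", "frameshift_variant",
  "splice_acceptor_variant", "splice_donor_variant")

CONSEQUENCE_SYNONYMOUS <- c("synonymous_variant", "stop_retained_variant")

known_consequences <- function() {
  c(CONSEQUENCE_EXCLUDE, CONSEQUENCE_TRUNCATING, CONSEQUENCE_SYNONYMOUS,
    "missense_variant", "inframe_insertion", "inframe_deletion",
    "protein_altering_variant", "splice_region_variant",
    "coding_sequence_variant")
}

#' Is a consequence term on the fixed exclusion list?
#'
#' The curation ladder removes variants annotated with any of eight
#' non-coding/regulatory consequence terms. Unknown terms return `FALSE`.
#'
#' @param consequence character vector of sequence-ontology terms.
#' @return logical vector.
#' @export
consequence_excluded <- function(consequence) {
  consequence %in% CONSEQUENCE_EXCLUDE
}

#' High-impact classification of a retained variant
#'
#' A variant is high impact if its consequence is truncating, splice-site or
#' start/stop-affecting, or if it is missense and either called deleterious by
#' at least three in-silico predictors or present in COSMIC.
#'
#' @param consequence,deleterious_votes,in_cosmic vectors (recycled).
#' @return logical vector.
#' @export
is_high_impact <- function(consequence, deleterious_votes = 0L, in_cosmic = FALSE) {
  votes <- ifelse(is.na(deleterious_votes), 0L, deleterious_votes)
  cosmic <- !is.na(in_cosmic) & in_cosmic
  consequence %in% CONSEQUENCE_TRUNCATING |
    (consequence == "missense_variant" & (votes >= 3L | cosmic))
}

#' Apply the somatic-variant curation ladder
#'
#' Removal filters are applied in a fixed order and each removed variant
#' records the first-triggering reason:
#' \enumerate{
#'   \item `consequence_excluded` — consequence on the fixed exclusion list;
#'   \item `germline_like` — gnomAD or 1000G population allele frequency
#'     above `maf_max` (missing AFs never trigger this filter);
#'   \item `artifact` — blacklist flag set upstream;
#'   \item `low_vaf` — variant allele fraction strictly below `vaf_min`.
#' }
#' Survivors are annotated with `coding` (not excluded, not synonymous),
#' `tmb_eligible` (coding with VAF strictly above `vaf_min`) and
#' `high_impact` ([is_high_impact()]).
#'
#' @param variants variant tibble (see [read_variant_table()]).
#' @param vaf_min VAF threshold (default 0.1; removal is strict `<`, the TMB
#'   set is strict `>`).
#' @param maf_max population-AF threshold for germline-like removal
#'   (default 0.1, strict `>`).
#' @return input tibble plus columns `status` (`"retained"`/`"removed"`),
#'   `removal_reason`, `coding`, `tmb_eligible`, `high_impact`.
#' @export
curate_variants <- function(variants, vaf_min = 0.1, maf_max = 0.1) {
  v <- as_tibble(variants)
  gaf <- ifelse(is.na(v$gnomad_af), 0, v$gnomad_af)
  kaf <- ifelse(is.na(v$kg_af), 0, v$kg_af)
  reason <- rep(NA_character_, nrow(v))
  reason[v$vaf < vaf_min] <- "low_vaf"
  reason[v$artifact_flag] <- "artifact"
  reason[gaf > maf_max | kaf > maf_max] <- "germline_like"
  reason[consequence_excluded(v$consequence)] <- "consequence_excluded"
  removed <- !is.na(reason)
  v$status <- ifelse(removed, "removed", "retained")
  v$removal_reason <- reason
  v$coding <- !removed & !consequence_excluded(v$consequence) &
    !(v$consequence %in% CONSEQUENCE_SYNONYMOUS)
  v$tmb_eligible <- v$coding & v$vaf > vaf_min
  v$high_impact <- !removed &
    is_high_impact(v$consequence, v$deleterious_votes, v$in_cosmic)
  v
}

#' Tumor mutational burden per sample
#'
#' TMB is the count of curated (retained) coding variants with VAF strictly
#' above the threshold. Samples present in `samples` but absent from the
#' variant table get `NA` ("no data"), distinct from a present sample with
#' zero qualifying variants.
#'
#' @param curated output of [curate_variants()].
#' @param samples optional character vector of sample ids defining the output
#'   universe (defaults to the samples present in `curated`).
#' @return tibble with columns `sample_id`, `tmb`.
#' @export
compute_tmb <- function(curated, samples = NULL) {
  counts <- curated |>
    group_by(.data$sample_id) |>
    summarise(tmb = sum(.data$tmb_eligible), .groups = "drop")
  if (is.null(samples)) return(counts)
  tibble(sample_id = samples) |>
    left_join(counts, by = "sample_id") |>
    mutate(tmb = ifelse(.data$sample_id %in% curated$sample_id &
                          is.na(.data$tmb), 0L, .data$tmb))
}
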