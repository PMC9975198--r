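#' Run the integrated metastasis-risk pipeline
#'
#' Orchestrates the stages end to end on a cohort bundle: variant curation and
#' TMB, segment filtering with SCNA burden and arm calls, marker
#' dichotomization and assembly, the exhaustive OR-classifier search,
#' copy-number/expression integration (when gene coordinates are supplied),
#' Fges scoring with TME subtyping (when gene sets are supplied), and the
#' survival/regression report. Stages whose inputs are absent are skipped and
#' recorded in the manifest. Deterministic for fixed inputs and seed.
#'
#' @param bundle `ppgl_cohort` from [assemble_bundle()] or
#'   [simulate_cohort()]`$bundle`.
#' @param out_dir optional directory; when supplied every stage writes its
#'   TSV outputs there together with a JSON run manifest.
#' @param gene_coords optional tibble for [project_gene_cn()].
#' @param fges_sets optional named list of gene sets for TME subtyping.
#' @param immune_sets,fibrotic_sets axis tags for [label_archetypes()].
#' @param seed seed forwarded to seeded stages.
#' @param msi_threshold fixed MSI dichotomization cut (default 0.15).
#' @return list of stage outputs: `curated`, `tmb`, `segments_kept`,
#'   `scna_burden`, `arm_calls`, `chr5`, `markers`, `search`, `integration`,
#'   `tme`, `models`, `manifest`.
#' @export
run_pipeline <- function(bundle, out_dir = NULL, gene_coords = NULL,
                         fges_sets = NULL, immune_sets = NULL,
                         fibrotic_sets = NULL, seed = 1,
                         msi_threshold = 0.15) {
  stopifnot(inherits(bundle, "ppgl_cohort"))
  clin <- bundle$clinical
  stages <- character()
  out <- list()

  if (!is.null(bundle$variants)) {
    out$curated <- curate_variants(bundle$variants)
    out$tmb <- compute_tmb(out$curated, samples = clin$sample_id)
    stages <- c(stages, "curate")
  }
  if (!is.null(bundle$segments)) {
    out$segments_kept <- filter_segments(bundle$segments)
    out$scna_burden <- scna_burden(out$segments_kept, samples = clin$sample_id)
    out$arm_calls <- call_arm_levels(out$segments_kept, bundle$arm_table)
    out$chr5 <- whole_chromosome_gain(out$arm_calls, "5")
    stages <- c(stages, "instability")
  }

  norm <- NULL
  if (!is.null(bundle$expression)) {
    norm <- normalize_counts(bundle$expression)
    stages <- c(stages, "normalize")
  }

  # marker assembly needs at least the clinical channel
  markers <- tibble(sample_id = clin$sample_id)
  if ("krebs_germline" %in% names(clin))
    markers$krebs_germline <- as.integer(clin$krebs_germline)
  if ("maml3_fusion" %in% names(clin))
    markers$maml3_fusion <- as.integer(clin$maml3_fusion)
  if ("msi_score" %in% names(clin))
    markers$msi_high <- dichotomize_marker(clin$msi_score, "gt_fixed",
                                           threshold = msi_threshold)
  tert_cols <- c("tert_panel_mean", "tert_promoter", "tert_utss_mean",
                 "tert_gistic")
  if (any(tert_cols %in% names(clin))) {
    ev <- tibble(sample_id = clin$sample_id,
                 panel_expr_mean = clin$tert_panel_mean %||% NA_real_,
                 promoter_mutation = clin$tert_promoter %||% NA_character_,
                 utss_mean = clin$tert_utss_mean %||% NA_real_,
                 gistic_score = clin$tert_gistic %||% NA_real_)
    markers$tert_alt <- as.integer(call_tert_alterations(ev)$tert_alt)
  }
  if (!is.null(out$tmb))
    markers$tmb_high <- dichotomize_marker(out$tmb$tmb, "gt_q3")
  if (!is.null(out$curated)) {
    atrx <- out$curated |>
      filter(.data$gene == "ATRX", .data$high_impact) |>
      distinct(.data$sample_id) |> mutate(atrx_mut = 1L)
    markers <- markers |> left_join(atrx, by = "sample_id") |>
      mutate(atrx_mut = ifelse(is.na(.data$atrx_mut) &
                                 .data$sample_id %in% out$curated$sample_id,
                               0L, .data$atrx_mut))
  }
  if (!is.null(out$chr5)) {
    markers <- markers |>
      left_join(out$chr5 |> transmute(.data$sample_id,
                                      chr5_gain = as.integer(.data$whole_gain)),
                by = "sample_id") |>
      mutate(chr5_gain = ifelse(is.na(.data$chr5_gain) &
                                  .data$sample_id %in% bundle$segments$sample_id,
                                0L, .data$chr5_gain))
  }
  if (!is.null(norm)) {
    for (g in c("CDK1", "MKI67")) {
      if (g %in% rownames(norm$log2)) {
        col <- paste0(tolower(g), "_high")
        vals <- norm$log2[g, ][match(clin$sample_id, colnames(norm$log2))]
        markers[[col]] <- dichotomize_marker(vals, "gt_q3")
      }
    }
  }
  out$markers <- tryCatch(build_marker_matrix(markers, clin),
                          error = function(e) NULL)
  if (!is.null(out$markers)) {
    out$search <- classifier_search(out$markers, ci = "none", seed = seed)
    stages <- c(stages, "classify-search")
  }

  if (!is.null(out$segments_kept) && !is.null(gene_coords) && !is.null(norm)) {
    grp <- clin |>
      filter(.data$tumor_type %in% c("non_metastatic", "metastatic_primary")) |>
      transmute(.data$sample_id, group = .data$tumor_type)
    out$integration <- integrate_scna_expression(
      out$segments_kept |> semi_join(grp, by = "sample_id"),
      gene_coords, norm$log2[, intersect(colnames(norm$log2), grp$sample_id),
                             drop = FALSE], grp)
    stages <- c(stages, "integrate")
  }

  if (!is.null(norm) && !is.null(fges_sets)) {
    scores <- ssgsea_scores(norm$log2, fges_sets)
    if (is.null(immune_sets)) immune_sets <- names(fges_sets)[
      seq_len(ceiling(length(fges_sets) / 2))]
    if (is.null(fibrotic_sets)) fibrotic_sets <- setdiff(names(fges_sets),
                                                         immune_sets)
    out$tme <- tme_assign(scores, immune_sets, fibrotic_sets, seed = seed)
    stages <- c(stages, "tme")
  }

  surv_cols <- c("ttp_days", "progression_event", "msi_score")
  if (all(surv_cols %in% names(clin)) && !is.null(out$tmb)) {
    prim <- clin |>
      filter(.data$tumor_type %in% c("non_metastatic", "metastatic_primary")) |>
      left_join(out$tmb, by = "sample_id") |>
      mutate(metastatic = as.integer(.data$tumor_type == "metastatic_primary"),
             female = as.integer(.data$sex == "F"),
             msi_high = as.integer(.data$msi_score > msi_threshold),
             krebs = as.integer(.data$krebs_germline))
    covs <- c("female", "krebs", "msi_high", "tmb")
    out$models <- tryCatch(
      fit_risk_models(prim, "metastatic", covs),
      error = function(e) NULL)
    if (!is.null(out$models)) stages <- c(stages, "survival")
  }

  out$manifest <- list(
    seed = seed,
    stages_run = stages,
    n_samples = nrow(clin),
    stage_rows = lapply(out[vapply(out, is.data.frame, TRUE)], nrow))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name, meta) {
      if (!is.null(df)) write_table_tsv(as.data.frame(df),
                                        file.path(out_dir, name), meta)
    }
    wr(out$curated, "curated_variants.tsv", "per-variant curation; coordinates 1-based closed")
    wr(out$tmb, "tmb.tsv", "per-sample tumor mutational burden")
    wr(out$scna_burden, "scna_burden.tsv", "per-sample SCNA burden")
    wr(out$arm_calls, "arm_calls.tsv", "arm-level calls")
    if (!is.null(out$search)) wr(out$search$results, "classifier_search.tsv",
                                 "OR-combination classifier search")
    if (!is.null(out$models)) wr(out$models$estimates, "risk_models.tsv",
                                 "logistic/Cox risk models")
    jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
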