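MARKER_EVENTS <- c("krebs_germline", "maml3_fusion", "tert_alt", "atrx_mut",
                   "mki67_high", "msi_high", "tmb_high", "chr5_gain",
                   "cdk1_high")

#' Composite TERT-alteration caller
#'
#' A sample is TERT-altered when any of the evidence channels is positive:
#' \itemize{
#'   \item expression: targeted-panel mean of at least `expr_min` counts
#'     (default 4), or an RNA-seq overexpression flag;
#'   \item promoter mutation: `C228T` or `C250T` (the assay targets both even
#'     though only C228T has been observed in PPGL series);
#'   \item promoter hypermethylation: mean UTSS methylation of at least
#'     `utss_min` (default 14.1, inclusive);
#'   \item amplification: GISTIC score equal to 2.
#' }
#' When every evidence field is missing the call itself is missing, never
#' negative. The call is monotone: adding positive evidence can only turn a
#' negative call positive.
#'
#' @param evidence tibble with columns `sample_id` and any of
#'   `panel_expr_mean`, `overexpressed_rnaseq`, `promoter_mutation`
#'   (`"C228T"`, `"C250T"`, `"none"` or NA), `utss_mean`, `gistic_score`.
#' @param expr_min,utss_min thresholds (both inclusive `>=`).
#' @return tibble `sample_id`, `tert_alt` (logical, NA when no evidence),
#'   `reasons` (comma-separated satisfied criteria, `""` if none).
#' @export
call_tert_alterations <- function(evidence, expr_min = 4, utss_min = 14.1) {
  ev <- as_tibble(evidence)
  for (nm in c("panel_expr_mean", "utss_mean", "gistic_score"))
    if (!nm %in% names(ev)) ev[[nm]] <- NA_real_
  if (!"overexpressed_rnaseq" %in% names(ev)) ev$overexpressed_rnaseq <- NA
  if (!"promoter_mutation" %in% names(ev)) ev$promoter_mutation <- NA_character_
  crit <- tibble(
    overexpression = (!is.na(ev$panel_expr_mean) & ev$panel_expr_mean >= expr_min) |
      (!is.na(ev$overexpressed_rnaseq) & ev$overexpressed_rnaseq),
    promoter_mutation = !is.na(ev$promoter_mutation) &
      ev$promoter_mutation %in% c("C228T", "C250T"),
    hypermethylation = !is.na(ev$utss_mean) & ev$utss_mean >= utss_min,
    amplification = !is.na(ev$gistic_score) & ev$gistic_score == 2
  )
  no_evidence <- is.na(ev$panel_expr_mean) & is.na(ev$overexpressed_rnaseq) &
    (is.na(ev$promoter_mutation) | ev$promoter_mutation == "missing") &
    is.na(ev$utss_mean) & is.na(ev$gistic_score)
  altered <- apply(as.matrix(crit), 1, any)
  altered[no_evidence] <- NA
  reasons <- apply(as.matrix(crit), 1, function(r) paste(names(crit)[r], collapse = ","))
  tibble(sample_id = ev$sample_id, tert_alt = altered, reasons = reasons)
}

#' Dichotomize a continuous marker
#'
#' Converts a continuous per-sample value to a 0/1 event with a strict `>`
#' comparison against a threshold computed over the full cohort's non-missing
#' values. Missing values stay missing.
#'
#' @param values numeric vector.
#' @param rule `"gt_median"`, `"gt_q3"` or `"gt_fixed"`.
#' @param threshold required when `rule = "gt_fixed"` (e.g. 0.15 for the MSI
#'   score).
#' @param quantile_type quantile algorithm for the empirical rules (default 7,
#'   linear interpolation).
#' @return integer vector of 0/1/NA.
#' @export
dichotomize_marker <- function(values, rule = c("gt_median", "gt_q3", "gt_fixed"),
                               threshold = NULL, quantile_type = 7) {
  rule <- match.arg(rule)
  obs <- values[!is.na(values)]
  if (rule != "gt_fixed" && length(obs) < 4)
    stop("quantile rules need at least 4 non-missing values", call. = FALSE)
  cut <- switch(rule,
    gt_median = median(obs),
    gt_q3 = quantile(obs, 0.75, type = quantile_type, names = FALSE),
    gt_fixed = {
      if (is.null(threshold)) stop("gt_fixed requires a threshold", call. = FALSE)
      threshold
    })
  if (rule != "gt_fixed" && length(unique(obs)) == 1)
    warning("all values identical; dichotomy is all 0", call. = FALSE)
  as.integer(values > cut)
}

#' Assemble the samples-by-events marker matrix
#'
#' Joins the nine binary metastasis-marker events on sample id, restricts to
#' primary tumors (tumor types `non_metastatic` and `metastatic_primary`;
#' relapses and metastases are excluded from classifier training), attaches
#' the truth label, and restricts the analysis matrix to complete cases. The
#' full availability mask is kept as attribute `availability`.
#'
#' @param markers tibble with `sample_id` and any subset of the nine event
#'   columns (`r paste(MARKER_EVENTS, collapse = ", ")`), coded 0/1/NA.
#' @param clinical clinical tibble with `sample_id`, `tumor_type`.
#' @return `ppgl_markers`: tibble of complete-case rows with `sample_id`,
#'   `label` (1 = metastatic primary), and the event columns; attributes
#'   `availability` (logical mask tibble) and `events`.
#' @export
build_marker_matrix <- function(markers, clinical) {
  events <- intersect(MARKER_EVENTS, names(markers))
  if (length(events) == 0) stop("no marker event columns found", call. = FALSE)
  primaries <- clinical |>
    filter(.data$tumor_type %in% c("non_metastatic", "metastatic_primary")) |>
    transmute(.data$sample_id,
              label = as.integer(.data$tumor_type == "metastatic_primary"))
  m <- primaries |> left_join(as_tibble(markers)[, c("sample_id", events)],
                              by = "sample_id")
  availability <- m |>
    mutate(across(all_of(events), ~ !is.na(.x))) |>
    select("sample_id", all_of(events))
  complete <- m[complete.cases(m[, events, drop = FALSE]), , drop = FALSE]
  if (nrow(complete) == 0) stop("zero complete-case samples", call. = FALSE)
  structure(complete, class = c("ppgl_markers", class(complete)),
            availability = availability, events = events)
}
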