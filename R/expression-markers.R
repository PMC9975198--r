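#' Median-of-ratios normalization of a count matrix
#'
#' Computes size factors by the median-of-ratios method: the reference profile
#' is the per-gene geometric mean over samples, factors are the per-sample
#' median of count/reference ratios across genes positive in every sample.
#' If no gene is positive in all samples, library-size factors (scaled to
#' geometric mean 1) are used with a warning.
#'
#' @param counts genes-by-samples matrix of raw counts.
#' @return list with `normalized` (counts / size factor), `log2` (log2 of
#'   normalized + 1), `size_factors` (named vector).
#' @export
normalize_counts <- function(counts) {
  if (ncol(counts) < 2) stop("need at least 2 samples", call. = FALSE)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no gene positive in all samples; using library-size factors",
            call. = FALSE)
    libs <- colSums(counts)
    sf <- libs / exp(mean(log(libs)))
  } else {
    logs <- log(counts[pos, , drop = FALSE])
    ref <- rowMeans(logs)
    sf <- apply(logs, 2, function(x) exp(median(x - ref)))
  }
  norm <- sweep(counts, 2, sf, "/")
  list(normalized = norm, log2 = log2(norm + 1), size_factors = sf)
}

#' Per-batch location-scale adjustment on log expression
#'
#' Standardizes each gene within each batch to the gene's overall mean and
#' pooled scale (a location-scale batch correction without empirical-Bayes
#' shrinkage). Applied on log-scale values.
#'
#' @param log_mat genes-by-samples matrix on the log scale.
#' @param batch character/factor of length `ncol(log_mat)`.
#' @return adjusted matrix.
#' @export
adjust_batch <- function(log_mat, batch) {
  batch <- as.factor(batch)
  if (nlevels(batch) < 2) return(log_mat)
  grand_mean <- rowMeans(log_mat)
  grand_sd <- apply(log_mat, 1, sd)
  out <- log_mat
  for (b in levels(batch)) {
    idx <- which(batch == b)
    if (length(idx) < 2) next
    bm <- rowMeans(log_mat[, idx, drop = FALSE])
    bs <- apply(log_mat[, idx, drop = FALSE], 1, sd)
    scale <- ifelse(bs > 0, grand_sd / bs, 1)
    out[, idx] <- (log_mat[, idx, drop = FALSE] - bm) * scale + grand_mean
  }
  out
}

#' Tumor-purity scores from immune and stromal gene sets
#'
#' Rank-based single-sample enrichment ([ssgsea_scores()]) of an immune and a
#' stromal gene set; the combined score is their sum. Samples whose combined
#' score exceeds `exclude_above` are flagged for exclusion (low purity). The
#' default threshold of 5900 is meaningful only on the original ESTIMATE score
#' scale; supply a threshold matched to the score scale in use, or `Inf` to
#' disable.
#'
#' @param norm normalized expression (list from [normalize_counts()] or a
#'   matrix on any monotone-equivalent scale; scores are rank-based).
#' @param immune_set,stromal_set character vectors of gene symbols.
#' @param exclude_above exclusion threshold on the combined score (strict `>`).
#' @return tibble `sample_id`, `immune`, `stromal`, `combined`, `excluded`.
#' @export
purity_scores <- function(norm, immune_set, stromal_set, exclude_above = 5900) {
  mat <- if (is.list(norm) && !is.null(norm$log2)) norm$log2 else norm
  for (s in list(immune_set, stromal_set)) {
    if (length(intersect(s, rownames(mat))) < 2)
      stop("gene set with fewer than 2 measured genes", call. = FALSE)
  }
  sc <- ssgsea_scores(mat, list(immune = immune_set, stromal = stromal_set))
  combined <- sc[, "immune"] + sc[, "stromal"]
  if (identical(exclude_above, 5900) && all(abs(combined) < 100)) {
    warning("combined scores are far below the ESTIMATE-scale threshold 5900; ",
            "no sample will be excluded — supply a threshold matched to this ",
            "score scale", call. = FALSE)
  }
  tibble(sample_id = colnames(mat),
         immune = sc[, "immune"], stromal = sc[, "stromal"]) |>
    mutate(combined = .data$immune + .data$stromal,
           excluded = .data$combined > exclude_above)
}

# Closed-form per-gene OLS: response matrix Y (genes x samples), design X.
# Returns the t-test on the column named `term`.
fit_gene_lm <- function(Y, X, term) {
  qr_x <- qr(X)
  coefs <- t(qr.coef(qr_x, t(Y)))            # genes x p
  fitted <- coefs %*% t(X)
  resid <- Y - fitted
  df_res <- ncol(Y) - ncol(X)
  sigma2 <- rowSums(resid^2) / df_res
  xtx_inv <- chol2inv(qr.R(qr_x))
  j <- match(term, colnames(X))
  se <- sqrt(sigma2 * xtx_inv[j, j])
  tval <- coefs[, j] / se
  p <- 2 * pt(abs(tval), df_res, lower.tail = FALSE)
  p[se == 0 | is.na(p)] <- 1
  list(estimate = coefs[, j], p = p)
}

#' Per-gene differential expression statistics
#'
#' For each gene reports the log2 fold change of group means (computed on the
#' log2-normalized scale, group2 minus group1 where group2 is the second
#' factor level, conventionally metastatic) and a two-sided test from an
#' ordinary linear model of log2 expression on the group indicator plus an
#' optional covariate (e.g. a tumor-purity score). Benjamini-Hochberg FDR is
#' computed across genes. Constant genes get p = 1.
#'
#' @param log_mat genes-by-samples matrix of log2-normalized values.
#' @param labels factor/character of length `ncol(log_mat)` with two levels.
#' @param covariate optional numeric covariate per sample.
#' @return tibble `gene`, `log2fc`, `p`, `fdr`.
#' @export
differential_stats <- function(log_mat, labels, covariate = NULL) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels", call. = FALSE)
  if (min(table(labels)) < 3) stop("need >= 3 samples per group", call. = FALSE)
  g2 <- labels == levels(labels)[2]
  lfc <- rowMeans(log_mat[, g2, drop = FALSE]) -
    rowMeans(log_mat[, !g2, drop = FALSE])
  X <- cbind(intercept = 1, group = as.numeric(g2))
  if (!is.null(covariate)) X <- cbind(X, covariate = as.numeric(covariate))
  fit <- fit_gene_lm(log_mat, X, "group")
  constant <- apply(log_mat, 1, function(x) length(unique(x)) == 1)
  p <- fit$p
  p[constant] <- 1
  tibble(gene = rownames(log_mat), log2fc = unname(lfc), p = unname(p),
         fdr = unname(p.adjust(p, method = "BH")))
}

#' Select the metastasis expression signature
#'
#' A gene enters the signature when its absolute log2 fold change is strictly
#' above `lfc_min` in every per-stratum analysis, the fold-change sign is
#' consistent across strata, and the pooled-analysis FDR is strictly below
#' `fdr_max`.
#'
#' @param stratum_stats named list of [differential_stats()] tibbles, one per
#'   genomic-subtype stratum (strata with no qualifying samples may simply be
#'   omitted; a `NULL` entry is skipped with a warning).
#' @param pooled_stats [differential_stats()] tibble for the pooled analysis.
#' @param lfc_min fold-change magnitude threshold (default 0.75, strict).
#' @param fdr_max pooled FDR threshold (default 0.01, strict).
#' @return tibble `gene`, `direction` (`"up_in_metastatic"` /
#'   `"down_in_metastatic"`), per-stratum and pooled fold changes.
#' @export
select_signature <- function(stratum_stats, pooled_stats, lfc_min = 0.75,
                             fdr_max = 0.01) {
  keep <- !vapply(stratum_stats, is.null, TRUE)
  if (!all(keep)) {
    warning("stratum(s) skipped (no qualifying samples): ",
            paste(names(stratum_stats)[!keep], collapse = ", "), call. = FALSE)
    stratum_stats <- stratum_stats[keep]
  }
  if (length(stratum_stats) == 0) stop("no strata available", call. = FALSE)
  wide <- purrr::imap(stratum_stats, function(st, nm) {
    setNames(st[, c("gene", "log2fc")], c("gene", paste0("lfc_", nm)))
  }) |> purrr::reduce(inner_join, by = "gene")
  lfc_cols <- grep("^lfc_", names(wide), value = TRUE)
  lfc_mat <- as.matrix(wide[, lfc_cols, drop = FALSE])
  pass_mag <- rowSums(abs(lfc_mat) > lfc_min) == length(lfc_cols)
  consistent <- apply(lfc_mat, 1, function(x) all(x > 0) || all(x < 0))
  pooled <- pooled_stats[, c("gene", "log2fc", "fdr")]
  names(pooled) <- c("gene", "lfc_pooled", "fdr_pooled")
  out <- wide[pass_mag & consistent, , drop = FALSE] |>
    inner_join(pooled, by = "gene") |>
    filter(.data$fdr_pooled < fdr_max) |>
    mutate(direction = ifelse(.data[[lfc_cols[1]]] > 0,
                              "up_in_metastatic", "down_in_metastatic")) |>
    arrange(.data$gene)
  out
}

#' Dichotomize a signature gene
#'
#' Genes upregulated in metastatic tumors are coded 1 above the cohort third
#' quartile (strict `>`); genes downregulated in metastatic tumors are coded 1
#' above the cohort median (strict `>`). Either way 1 marks the
#' metastasis-like expression state.
#'
#' @param values per-sample expression of one gene.
#' @param direction `"up_in_metastatic"` or `"down_in_metastatic"`.
#' @param quantile_type quantile algorithm (default 7).
#' @return integer 0/1/NA vector.
#' @export
dichotomize_signature_gene <- function(values,
                                       direction = c("up_in_metastatic",
                                                     "down_in_metastatic"),
                                       quantile_type = 7) {
  direction <- match.arg(direction)
  rule <- if (direction == "up_in_metastatic") "gt_q3" else "gt_median"
  dichotomize_marker(values, rule, quantile_type = quantile_type)
}
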