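#' Enumerate non-empty subsets of marker events
#'
#' Returns all `2^k - 1` non-empty subsets of the event names, ordered by
#' subset size then lexicographically within a size.
#'
#' @param events character vector of event names (k >= 1).
#' @return list of character vectors.
#' @export
enumerate_subsets <- function(events) {
  k <- length(events)
  if (k == 0) stop("need at least one event", call. = FALSE)
  events <- sort(events)
  out <- list()
  for (size in seq_len(k)) {
    cmb <- combn(events, size, simplify = FALSE)
    ord <- order(vapply(cmb, paste, "", collapse = "\r"))
    out <- c(out, cmb[ord])
  }
  out
}

#' OR-combination of marker events
#'
#' The combined predictor is 1 when any event in the subset is present, 0 when
#' none is.
#'
#' @param markers data frame or matrix of 0/1 events (complete cases).
#' @param subset non-empty character vector of event columns.
#' @return integer 0/1 vector, one per row.
#' @export
or_combine <- function(markers, subset) {
  if (length(subset) == 0) stop("empty event subset", call. = FALSE)
  missing <- setdiff(subset, colnames(markers))
  if (length(missing) > 0)
    stop("unknown event(s): ", paste(missing, collapse = ", "), call. = FALSE)
  m <- as.matrix(as.data.frame(markers)[, subset, drop = FALSE])
  as.integer(rowSums(m) > 0)
}

# DeLong variance of the AUC of a (possibly tied) score; closed form via
# placement values. For a binary score this reduces to simple proportions.
delong_ci <- function(score, truth, level = 0.95) {
  pos <- score[truth == 1]
  neg <- score[truth == 0]
  m <- length(pos); n <- length(neg)
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), 0)
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)), 0)
  auc <- mean(v10)
  s <- var(v10) / m + var(v01) / n
  z <- qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(s)
  c(low = max(0, auc - half), high = min(1, auc + half), auc = auc)
}

#' Evaluate a binary classifier against truth labels
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP); the AUC of the
#' single-operating-point ROC equals (sensitivity + specificity)/2, i.e. the
#' Mann-Whitney probability of the binary score. The 95% CI uses the DeLong
#' variance of the binary score by default, or a seeded stratified bootstrap.
#'
#' @param predictions integer 0/1 vector.
#' @param truth integer 0/1 vector (both classes must be present).
#' @param ci `"delong"` (default), `"bootstrap"` or `"none"`.
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed seed for the bootstrap.
#' @return one-row tibble `sensitivity`, `specificity`, `auc`, `auc_ci_low`,
#'   `auc_ci_high`, `n_used`.
#' @export
evaluate_binary <- function(predictions, truth, ci = c("delong", "bootstrap", "none"),
                            n_boot = 2000, seed = 1) {
  ci <- match.arg(ci)
  if (length(unique(truth)) < 2) stop("degenerate truth: one class absent", call. = FALSE)
  tp <- sum(predictions == 1 & truth == 1)
  fn <- sum(predictions == 0 & truth == 1)
  tn <- sum(predictions == 0 & truth == 0)
  fp <- sum(predictions == 1 & truth == 0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  auc <- (sens + spec) / 2
  lo <- hi <- NA_real_
  if (ci == "delong") {
    d <- delong_ci(predictions, truth)
    lo <- d[["low"]]; hi <- d[["high"]]
  } else if (ci == "bootstrap") {
    set.seed(seed)
    ip <- which(truth == 1); iq <- which(truth == 0)
    reps <- replicate(n_boot, {
      idx <- c(sample(ip, replace = TRUE), sample(iq, replace = TRUE))
      p <- predictions[idx]; t <- truth[idx]
      s1 <- sum(p == 1 & t == 1) / sum(t == 1)
      s0 <- sum(p == 0 & t == 0) / sum(t == 0)
      (s1 + s0) / 2
    })
    qs <- quantile(reps, c(0.025, 0.975), names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  tibble(sensitivity = sens, specificity = spec, auc = auc,
         auc_ci_low = lo, auc_ci_high = hi, n_used = length(truth))
}

#' Exhaustive OR-combination classifier search
#'
#' Evaluates every non-empty subset of the marker events as an OR-combination
#' classifier of the truth label on complete-case rows. The full result table
#' is returned ranked by AUC; the headline `best` is the maximum-AUC subset
#' (ties broken by smaller subset, then lexicographically) and
#' `best_sens1` is the maximum-AUC subset among classifiers with sensitivity
#' exactly 1, when any exists.
#'
#' @param markers `ppgl_markers` from [build_marker_matrix()], or any data
#'   frame of 0/1 event columns.
#' @param labels 0/1 truth vector; taken from the `label` column when absent.
#' @param events event columns to search (defaults to the marker matrix's
#'   events attribute, else all non-id/label columns).
#' @param ci CI method forwarded to [evaluate_binary()]; `"none"` skips CIs
#'   during the scan (they are always computed for the two headline subsets).
#' @param seed bootstrap seed.
#' @return `ppgl_search`: list with `results` (one row per subset, ranked),
#'   `best`, `best_sens1`, `n_used`, `events`.
#' @export
classifier_search <- function(markers, labels = NULL, events = NULL,
                              ci = c("delong", "bootstrap", "none"), seed = 1) {
  ci <- match.arg(ci)
  df <- as.data.frame(markers)
  if (is.null(labels)) {
    if (!"label" %in% names(df)) stop("labels missing", call. = FALSE)
    labels <- df$label
  }
  if (is.null(events)) {
    events <- attr(markers, "events") %||%
      setdiff(names(df), c("sample_id", "label"))
  }
  keep <- complete.cases(df[, events, drop = FALSE]) & !is.na(labels)
  df <- df[keep, , drop = FALSE]
  labels <- labels[keep]
  if (nrow(df) < 10)
    warning("fewer than 10 complete cases; results flagged unstable", call. = FALSE)
  m <- as.matrix(df[, sort(events), drop = FALSE])
  subsets <- enumerate_subsets(events)
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stop("degenerate truth: one class absent", call. = FALSE)
  # vectorized scan: events x subsets indicator, then one matrix product
  indicator <- vapply(subsets, function(s) as.numeric(colnames(m) %in% s),
                      numeric(ncol(m)))
  pred <- (m %*% indicator) > 0
  tp <- colSums(pred[labels == 1, , drop = FALSE])
  tn <- colSums(!pred[labels == 0, , drop = FALSE])
  sens <- tp / npos
  spec <- tn / nneg
  stats_tab <- tibble(
    subset = vapply(subsets, paste, "", collapse = "+"),
    size = lengths(subsets),
    sensitivity = sens, specificity = spec, auc = (sens + spec) / 2)
  if (ci != "none") {
    cis <- purrr::map2_dfr(strsplit(stats_tab$subset, "+", fixed = TRUE),
                           seq_len(nrow(stats_tab)), function(s, i) {
      pred <- as.integer(rowSums(m[, s, drop = FALSE]) > 0)
      ev <- evaluate_binary(pred, labels, ci = ci, seed = seed)
      ev[, c("auc_ci_low", "auc_ci_high")]
    })
    stats_tab <- bind_cols(stats_tab, cis)
  } else {
    stats_tab$auc_ci_low <- NA_real_
    stats_tab$auc_ci_high <- NA_real_
  }
  stats_tab$n_used <- nrow(df)
  ranked <- stats_tab |>
    arrange(desc(.data$auc), .data$size, .data$subset)
  best <- ranked[1, ]
  sens1 <- ranked |> filter(.data$sensitivity == 1)
  best_sens1 <- if (nrow(sens1) > 0) sens1[1, ] else NULL
  fill_ci <- function(row) {
    if (!is.null(row) && is.na(row$auc_ci_low)) {
      s <- strsplit(row$subset, "+", fixed = TRUE)[[1]]
      pred <- as.integer(rowSums(m[, s, drop = FALSE]) > 0)
      ev <- evaluate_binary(pred, labels, ci = "delong")
      row$auc_ci_low <- ev$auc_ci_low; row$auc_ci_high <- ev$auc_ci_high
    }
    row
  }
  structure(list(results = ranked, best = fill_ci(best),
                 best_sens1 = fill_ci(best_sens1),
                 n_used = nrow(df), events = sort(events)),
            class = "ppgl_search")
}

#' @export
print.ppgl_search <- function(x, ...) {
  cat("<ppgl_search> ", nrow(x$results), " OR-combination classifiers over ",
      length(x$events), " events, n = ", x$n_used, "\n", sep = "")
  cat("  best (max AUC): {", x$best$subset, "} AUC = ",
      sprintf("%.3f", x$best$auc), " (sens ", sprintf("%.2f", x$best$sensitivity),
      ", spec ", sprintf("%.2f", x$best$specificity), ")\n", sep = "")
  if (!is.null(x$best_sens1)) {
    cat("  best at sensitivity 1: {", x$best_sens1$subset, "} AUC = ",
        sprintf("%.3f", x$best_sens1$auc), "\n", sep = "")
  }
  invisible(x)
}
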