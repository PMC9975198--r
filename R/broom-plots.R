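#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_errorbar geom_step
#'   geom_tile labs theme_minimal scale_fill_gradient2 geom_col coord_flip
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy the classifier-search result table
#' @param x `ppgl_search` object.
#' @param ... unused.
#' @return tibble, one row per evaluated subset, ranked by AUC.
#' @method tidy ppgl_search
#' @export
tidy.ppgl_search <- function(x, ...) x$results

#' One-row summary of a classifier search
#' @param x `ppgl_search` object.
#' @param ... unused.
#' @method glance ppgl_search
#' @export
glance.ppgl_search <- function(x, ...) {
  tibble(n_classifiers = nrow(x$results), n_events = length(x$events),
         n_used = x$n_used, best_subset = x$best$subset,
         best_auc = x$best$auc, best_sensitivity = x$best$sensitivity,
         best_specificity = x$best$specificity,
         best_sens1_subset = if (is.null(x$best_sens1)) NA_character_ else
           x$best_sens1$subset)
}

#' Tidy risk-model estimates
#' @param x `ppgl_models` object.
#' @param ... unused.
#' @method tidy ppgl_models
#' @export
tidy.ppgl_models <- function(x, ...) x$estimates

#' One-row summary of fitted risk models
#' @param x `ppgl_models` object.
#' @param ... unused.
#' @method glance ppgl_models
#' @export
glance.ppgl_models <- function(x, ...) {
  tibble(n_terms = nrow(x$estimates), max_vif = max(x$vif$vif),
         collinearity_warning = length(x$warnings) > 0)
}

#' Tidy Kaplan-Meier group summaries
#' @param x `ppgl_km` object.
#' @param ... unused.
#' @method tidy ppgl_km
#' @export
tidy.ppgl_km <- function(x, ...) x$medians

#' One-row log-rank summary
#' @param x `ppgl_km` object.
#' @param ... unused.
#' @method glance ppgl_km
#' @export
glance.ppgl_km <- function(x, ...) {
  tibble(logrank_chisq = x$logrank_chisq, logrank_p = x$logrank_p,
         n_groups = nrow(x$medians))
}

#' Tidy TME assignments
#' @param x `ppgl_tme` object.
#' @param ... unused.
#' @method tidy ppgl_tme
#' @export
tidy.ppgl_tme <- function(x, ...) x$assignments

#' Plot the top classifiers of a search
#'
#' Dot-and-interval chart of AUC (with CI when available) for the top-ranked
#' OR-combination classifiers.
#'
#' @param object `ppgl_search`.
#' @param top number of classifiers shown (default 20).
#' @param ... unused.
#' @return ggplot object.
#' @method autoplot ppgl_search
#' @export
autoplot.ppgl_search <- function(object, top = 20, ...) {
  df <- head(object$results, top)
  df$subset <- factor(df$subset, levels = rev(df$subset))
  p <- ggplot(df, aes(x = .data$auc, y = .data$subset)) +
    geom_point() +
    labs(x = "AUC (single operating point)", y = NULL,
         title = "Top OR-combination classifiers") +
    theme_minimal()
  if (!all(is.na(df$auc_ci_low))) {
    p <- p + geom_errorbar(aes(xmin = .data$auc_ci_low,
                               xmax = .data$auc_ci_high), width = 0.2)
  }
  p
}

#' Plot Kaplan-Meier curves
#'
#' @param object `ppgl_km` from [km_logrank()].
#' @param ... unused.
#' @return ggplot object with one step curve per group.
#' @method autoplot ppgl_km
#' @export
autoplot.ppgl_km <- function(object, ...) {
  fit <- object$fit
  strata <- rep(names(fit$strata) %||% "all",
                fit$strata %||% length(fit$time))
  df <- tibble(time = fit$time, surv = fit$surv,
               group = sub("^grp=", "", strata))
  ggplot(df, aes(x = .data$time, y = .data$surv, colour = .data$group)) +
    geom_step() +
    labs(x = "Time (days)", y = "Progression-free fraction",
         subtitle = paste0("log-rank p = ", format.pval(object$logrank_p, digits = 3))) +
    theme_minimal()
}

#' Heatmap of TME cluster centroids
#'
#' @param object `ppgl_tme` from [tme_assign()].
#' @param ... unused.
#' @return ggplot tile chart of centroid signature profiles by archetype.
#' @method autoplot ppgl_tme
#' @export
autoplot.ppgl_tme <- function(object, ...) {
  cen <- object$centroids
  map <- object$archetype_map
  df <- as_tibble(cen) |>
    mutate(cluster = seq_len(nrow(cen))) |>
    tidyr::pivot_longer(-"cluster", names_to = "signature", values_to = "score") |>
    left_join(map[, c("cluster", "archetype")], by = "cluster")
  ggplot(df, aes(x = .data$signature, y = .data$archetype, fill = .data$score)) +
    geom_tile() +
    scale_fill_gradient2() +
    labs(x = NULL, y = NULL, title = "TME centroid signature profiles") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6))
}
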