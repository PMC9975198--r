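#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by summing hypergeometric probabilities no larger
#' than that of the observed table. The odds ratio is the sample OR with a
#' Haldane (+0.5) correction when any cell is zero, flagged in the output
#' (`fisher.test`'s conditional MLE is available from the attached fit).
#'
#' @param tab 2x2 matrix of non-negative integer counts, or a length-4 vector
#'   (column-major).
#' @return one-row tibble `p`, `odds_ratio`, `haldane_corrected`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- matrix(as.vector(tab), 2)
  if (any(tab < 0)) stop("negative cell count", call. = FALSE)
  ft <- stats::fisher.test(tab)
  zero <- any(tab == 0)
  t2 <- if (zero) tab + 0.5 else tab
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  tibble(p = ft$p.value, odds_ratio = or, haldane_corrected = zero)
}

#' Freeman-Halton exact test for an r x c table
#'
#' Exact conditional test on fixed margins: the network-algorithm enumeration
#' for total counts up to `exact_max`, otherwise a seeded Monte-Carlo test
#' with fixed-margin sampling, with the Monte-Carlo standard error reported.
#' Rows/columns with zero margin are dropped with a warning.
#'
#' @param tab r x c matrix of non-negative integers.
#' @param exact_max largest total count for exact enumeration (default 200).
#' @param n_mc Monte-Carlo draws (default 1e5).
#' @param seed Monte-Carlo seed.
#' @return one-row tibble `p`, `method`, `mc_se` (NA for exact).
#' @export
freeman_halton <- function(tab, exact_max = 200, n_mc = 1e5, seed = 1) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("negative cell count", call. = FALSE)
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping zero-margin row(s)/column(s)", call. = FALSE)
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    return(tibble(p = 1, method = "degenerate", mc_se = NA_real_))
  }
  if (sum(tab) <= exact_max) {
    p <- stats::fisher.test(tab, workspace = 2e7)$p.value
    return(tibble(p = p, method = "exact", mc_se = NA_real_))
  }
  set.seed(seed)
  p <- stats::fisher.test(tab, simulate.p.value = TRUE, B = n_mc)$p.value
  tibble(p = p, method = "monte_carlo", mc_se = sqrt(p * (1 - p) / n_mc))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values (same order as input).
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0,1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Mann-Whitney-Wilcoxon two-sample test
#'
#' Exact p for combined n up to 20 (no ties), normal approximation with
#' continuity correction otherwise.
#'
#' @param x,y numeric samples.
#' @return one-row tibble `p`, `statistic`.
#' @export
mww_test <- function(x, y) {
  exact <- (length(x) + length(y)) <= 20
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  tibble(p = wt$p.value, statistic = unname(wt$statistic))
}

#' Kaplan-Meier curves with a log-rank group comparison
#'
#' Product-limit survival estimates per group, group median time-to-event with
#' Greenwood-based standard errors, and the two-sided log-rank test. Time to
#' progression (TTP) is the interval from primary diagnosis to first
#' documented metastasis, censored at last follow-up. Groups with no event
#' report the median as not reached (`NA`).
#'
#' @param data data frame.
#' @param time,event,group column names (strings) for time (days), event
#'   indicator (0/1 or logical) and group.
#' @return `ppgl_km`: list with `fit` (a `survfit`), `medians` (tibble
#'   `group`, `n`, `events`, `median`, `se`), `logrank_p`, `logrank_chisq`.
#' @export
km_logrank <- function(data, time = "ttp_days", event = "progression_event",
                       group = "group") {
  df <- as.data.frame(data)
  su <- survival::Surv(df[[time]], as.integer(df[[event]]))
  grp <- as.factor(df[[group]])
  fit <- survival::survfit(su ~ grp)
  st <- summary(fit)$table
  if (is.null(dim(st))) st <- matrix(st, nrow = 1, dimnames = list(levels(grp)[1], names(st)))
  medians <- tibble(
    group = sub("^grp=", "", rownames(st)),
    n = st[, "records"], events = st[, "events"],
    median = st[, "median"],
    se = (st[, "0.95UCL"] - st[, "0.95LCL"]) / (2 * 1.959964))
  if (nlevels(grp) >= 2 && sum(df[[event]] > 0) > 0) {
    sd_ <- survival::survdiff(su ~ grp)
    p <- stats::pchisq(sd_$chisq, df = nlevels(grp) - 1, lower.tail = FALSE)
    chisq <- sd_$chisq
  } else {
    p <- NA_real_; chisq <- NA_real_
  }
  structure(list(fit = fit, medians = medians, logrank_p = p,
                 logrank_chisq = chisq), class = "ppgl_km")
}

#' @export
print.ppgl_km <- function(x, ...) {
  cat("<ppgl_km> log-rank chi-square = ",
      sprintf("%.3f", x$logrank_chisq), ", p = ",
      format.pval(x$logrank_p, digits = 3), "\n", sep = "")
  print(x$medians)
  invisible(x)
}

# Variance inflation factors from the covariate design matrix (1 / (1 - R^2)
# of each column regressed on the others).
design_vif <- function(X) {
  X <- as.matrix(X)
  keep <- apply(X, 2, function(x) sd(x) > 0)
  X <- X[, keep, drop = FALSE]
  if (ncol(X) < 2) return(setNames(rep(1, ncol(X)), colnames(X)))
  vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2)
  }, 0) |> setNames(colnames(X))
}

# Ridge-penalized logistic fallback for separated fits (small fixed lambda).
penalized_logistic <- function(X, y) {
  padded <- ncol(X) == 1
  if (padded) X <- cbind(X, `.pad` = 0)   # glmnet needs >= 2 columns
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0, lambda = 1e-3,
                        standardize = FALSE)
  b <- setNames(as.vector(coef(fit)), c("(Intercept)", colnames(X)))
  if (padded) b <- b[names(b) != ".pad"]
  b
}

fit_logistic_row <- function(formula, df, label) {
  fit <- suppressWarnings(glm(formula, data = df, family = binomial()))
  sep <- !fit$converged || any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  flagged <- FALSE
  if (sep) {
    flagged <- TRUE
    X <- model.matrix(formula, df)[, -1, drop = FALSE]
    y <- model.response(model.frame(formula, df))
    est <- penalized_logistic(X, y)[names(coef(fit))]
    # keep the (inflated) Wald SEs from the unpenalized fit, flagged
  }
  terms_ <- setdiff(names(est), "(Intercept)")
  tibble(model = "logistic", mode = label, term = terms_,
         estimate = exp(est[terms_]),
         ci_low = exp(est[terms_] - 1.959964 * se[terms_]),
         ci_high = exp(est[terms_] + 1.959964 * se[terms_]),
         p = 2 * pnorm(abs(est[terms_] / se[terms_]), lower.tail = FALSE),
         n = nrow(df), flagged = flagged)
}

fit_cox_row <- function(formula, df, label) {
  fit <- survival::coxph(formula, data = df, ties = "efron")
  s <- summary(fit)
  terms_ <- rownames(s$coefficients)
  tibble(model = "cox", mode = label, term = terms_,
         estimate = s$coefficients[, "exp(coef)"],
         ci_low = s$conf.int[, "lower .95"],
         ci_high = s$conf.int[, "upper .95"],
         p = s$coefficients[, "Pr(>|z|)"],
         n = s$n, flagged = FALSE)
}

#' Univariate and multivariate risk models
#'
#' Fits logistic regressions of the binary metastasis outcome (odds ratios)
#' and Cox proportional-hazards models of time to progression (hazard ratios,
#' Efron ties) for each covariate alone (univariate) and jointly
#' (multivariate), with Wald 95% confidence intervals. Variance inflation
#' factors are computed from the covariate design matrix and a
#' multicollinearity warning is attached at VIF >= 2. Logistic fits showing
#' separation fall back to a lightly ridge-penalized estimate and are flagged.
#'
#' @param data data frame with complete cases on the covariates.
#' @param outcome name of the binary outcome column (0/1).
#' @param covariates character vector of covariate column names (e.g. sex,
#'   Krebs-cycle germline mutation, ATRX/TERT alteration, dichotomized MSI,
#'   continuous TMB).
#' @param time,event column names for the Cox outcome (set `time = NULL` to
#'   skip Cox fits).
#' @return `ppgl_models`: list with `estimates` (tidy tibble: `model`,
#'   `mode`, `term`, `estimate` (OR/HR), `ci_low`, `ci_high`, `p`, `n`,
#'   `flagged`), `vif` (tibble `term`, `vif`), `warnings`.
#' @export
fit_risk_models <- function(data, outcome, covariates,
                            time = "ttp_days", event = "progression_event") {
  df <- as.data.frame(data)
  df <- df[complete.cases(df[, c(outcome, covariates)]), , drop = FALSE]
  rows <- list()
  for (cv in covariates) {
    f <- stats::as.formula(paste(outcome, "~", cv))
    rows[[length(rows) + 1]] <- fit_logistic_row(f, df, "univariate")
  }
  f_multi <- stats::as.formula(paste(outcome, "~", paste(covariates, collapse = "+")))
  rows[[length(rows) + 1]] <- fit_logistic_row(f_multi, df, "multivariate")
  if (!is.null(time)) {
    for (cv in covariates) {
      f <- stats::as.formula(paste0("survival::Surv(", time, ", ", event, ") ~ ", cv))
      rows[[length(rows) + 1]] <- fit_cox_row(f, df, "univariate")
    }
    f <- stats::as.formula(paste0("survival::Surv(", time, ", ", event, ") ~ ",
                                  paste(covariates, collapse = "+")))
    rows[[length(rows) + 1]] <- fit_cox_row(f, df, "multivariate")
  }
  X <- model.matrix(stats::as.formula(paste("~", paste(covariates, collapse = "+"))),
                    df)[, -1, drop = FALSE]
  vif <- design_vif(X)
  warn <- character()
  if (any(vif >= 2)) {
    warn <- paste0("multicollinearity: VIF >= 2 for ",
                   paste(names(vif)[vif >= 2], collapse = ", "))
  }
  structure(list(estimates = bind_rows(rows),
                 vif = tibble(term = names(vif), vif = unname(vif)),
                 warnings = warn),
            class = "ppgl_models")
}

#' @export
print.ppgl_models <- function(x, ...) {
  cat("<ppgl_models> ", nrow(x$estimates), " fitted terms\n", sep = "")
  print(x$estimates, n = 20)
  if (length(x$warnings) > 0) cat("warning:", x$warnings, "\n")
  invisible(x)
}
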