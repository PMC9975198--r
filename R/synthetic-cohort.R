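# Find the negative-binomial mean whose median best matches a target count.
nb_mu_for_median <- function(target, size) {
  mus <- seq(max(0.5, target * 0.5), target * 2, by = 0.05)
  meds <- qnbinom(0.5, size = size, mu = mus)
  mus[which.min(abs(meds - target) + 1e-9 * abs(mus - target))]
}

#' Default synthetic-cohort configuration
#'
#' The defaults emulate the study conditions of a PPGL cohort: group-specific
#' TMB (negative binomial, group medians anchored at 8 / 17.5 / 24 for
#' non-metastatic primaries, metastatic primaries and metastases), an MSI
#' score generated as a monotone function of TMB plus noise (group medians
#' near 0.13 / 0.16 / 0.18, configurable TMB-MSI correlation), ATRX/TERT
#' alterations enriched in metastatic samples and adding a TMB/SCNA shift,
#' arm-level copy-number events including chromosome 5 gains enriched in
#' metastatic primaries, a planted differentially expressed signature-gene
#' block (including CDK1 and MKI67 up in metastatic tumors), Fges-archetype
#' structure in the expression matrix, and marker-dependent
#' proportional-hazards progression times with administrative censoring.
#'
#' @param n_non_metastatic,n_metastatic_primary,n_metastasis group sizes.
#' @param tmb_medians target group TMB medians.
#' @param tmb_size negative-binomial size (inverse dispersion) for TMB.
#' @param msi_medians target group MSI medians.
#' @param tmb_msi_cor target Pearson correlation between TMB and MSI.
#' @param removal_fraction expected fraction of raw variant calls removed by
#'   the curation ladder.
#' @param p_atrx,p_tert,p_krebs,p_maml3 per-group event probabilities, named
#'   vectors with elements `non_metastatic` and `metastatic` (metastatic
#'   applies to metastatic primaries and metastases).
#' @param alteration_tmb_shift additive TMB shift for ATRX/TERT-altered
#'   samples.
#' @param p_chr5_gain per-group probability of a whole-chromosome-5 gain.
#' @param n_genes,n_signature,signature_lfc_range,dispersion expression block:
#'   number of genes, planted signature size, |log2 fold change| range and NB
#'   dispersion.
#' @param n_fges,fges_set_size number and size of synthetic Fges gene sets.
#' @param fges_delta log-scale shift applied to archetype-active Fges genes.
#' @param base_hazard,hr_altered,admin_days progression model: baseline daily
#'   hazard, hazard ratio for marker-positive (ATRX/TERT-altered or MSI-high)
#'   samples, administrative censoring horizon.
#' @return named list of parameters for [simulate_cohort()].
#' @export
cohort_config <- function(n_non_metastatic = 150, n_metastatic_primary = 100,
                          n_metastasis = 50,
                          tmb_medians = c(non_metastatic = 8,
                                          metastatic_primary = 17.5,
                                          metastasis = 24),
                          tmb_size = 4,
                          msi_medians = c(non_metastatic = 0.13,
                                          metastatic_primary = 0.16,
                                          metastasis = 0.18),
                          tmb_msi_cor = 0.6,
                          removal_fraction = 0.4,
                          p_atrx = c(non_metastatic = 0.03, metastatic = 0.25),
                          p_tert = c(non_metastatic = 0.03, metastatic = 0.20),
                          p_krebs = c(non_metastatic = 0.05, metastatic = 0.25),
                          p_maml3 = c(non_metastatic = 0.03, metastatic = 0.15),
                          alteration_tmb_shift = 3,
                          p_chr5_gain = c(non_metastatic = 0.05, metastatic = 0.35),
                          n_genes = 2000, n_signature = 26,
                          signature_lfc_range = c(1, 2), dispersion = 0.2,
                          n_fges = 29, fges_set_size = 30, fges_delta = 1,
                          base_hazard = 1 / 4000, hr_altered = 3,
                          admin_days = 4000) {
  cfg <- as.list(environment())
  if (abs(cfg$tmb_msi_cor) > 1) stop("tmb_msi_cor must be in [-1, 1]", call. = FALSE)
  if (any(unlist(cfg[c("p_atrx", "p_tert", "p_krebs", "p_maml3", "p_chr5_gain")]) > 1))
    stop("event probabilities must be <= 1", call. = FALSE)
  cfg
}

draw_group_prob <- function(p, groups) {
  ifelse(groups == "non_metastatic", p[["non_metastatic"]], p[["metastatic"]])
}

#' Simulate a full synthetic PPGL cohort
#'
#' Generates a [assemble_bundle()]-validated cohort (clinical, variants,
#' segments, expression) plus a truth ledger recording every planted
#' parameter, so each pipeline stage has a recoverable ground truth. All
#' randomness flows through the single seed; the same config and seed
#' reproduce the bundle exactly.
#'
#' @param config list from [cohort_config()].
#' @param seed integer RNG seed.
#' @return list with `bundle` (`ppgl_cohort`), `truth` (list: `samples`
#'   tibble, `signature` tibble, `fges_sets`, `fges_axes`, `archetypes`,
#'   `config`, `seed`).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  set.seed(seed)
  cfg <- config
  groups <- rep(c("non_metastatic", "metastatic_primary", "metastasis"),
                c(cfg$n_non_metastatic, cfg$n_metastatic_primary, cfg$n_metastasis))
  n <- length(groups)
  sid <- sprintf("S%03d", seq_len(n))
  subtype <- sample(c("pseudohypoxic", "kinase_signaling", "wnt_altered"),
                    n, replace = TRUE, prob = c(0.45, 0.45, 0.10))
  metastatic <- groups != "non_metastatic"

  # --- marker truth ------------------------------------------------------
  atrx <- rbinom(n, 1, draw_group_prob(cfg$p_atrx, groups)) == 1
  tert <- rbinom(n, 1, draw_group_prob(cfg$p_tert, groups)) == 1
  krebs <- rbinom(n, 1, draw_group_prob(cfg$p_krebs, groups)) == 1
  maml3 <- rbinom(n, 1, draw_group_prob(cfg$p_maml3, groups)) == 1
  chr5 <- rbinom(n, 1, draw_group_prob(cfg$p_chr5_gain, groups)) == 1

  # --- TMB and MSI -------------------------------------------------------
  # baseline NB mean calibrated so the marginal group median (including the
  # additive shift carried by ATRX/TERT-altered samples) lands on target
  p_alt_group <- function(g) {
    key <- if (g == "non_metastatic") "non_metastatic" else "metastatic"
    1 - (1 - cfg$p_atrx[[key]]) * (1 - cfg$p_tert[[key]])
  }
  mu <- vapply(groups, function(g) {
    key <- if (g %in% names(cfg$tmb_medians)) g else "metastasis"
    target <- cfg$tmb_medians[[key]] - cfg$alteration_tmb_shift * p_alt_group(g)
    nb_mu_for_median(max(1, target), cfg$tmb_size)
  }, 0)
  tmb_true <- rnbinom(n, size = cfg$tmb_size, mu = mu) +
    ifelse(atrx | tert, cfg$alteration_tmb_shift, 0L)
  # MSI: global monotone function of TMB plus noise calibrated to the target
  # correlation; intercept/slope interpolate the configured group medians
  med_lo <- cfg$tmb_medians[["non_metastatic"]]
  med_hi <- cfg$tmb_medians[["metastasis"]]
  msi_lo <- cfg$msi_medians[["non_metastatic"]]
  msi_hi <- cfg$msi_medians[["metastasis"]]
  slope <- (msi_hi - msi_lo) / (med_hi - med_lo)
  intercept <- msi_lo - slope * med_lo
  signal <- intercept + slope * tmb_true
  rho <- cfg$tmb_msi_cor
  noise_sd <- if (abs(rho) >= 1 || sd(signal) == 0) 0 else
    sd(signal) * sqrt(1 / rho^2 - 1)
  msi <- pmax(0.05, signal + rnorm(n, 0, noise_sd))

  # --- variants ----------------------------------------------------------
  gene_pool <- sprintf("G%04d", seq_len(cfg$n_genes))
  variants <- purrr::map_dfr(seq_len(n), function(i) {
    n_keep <- tmb_true[i]
    n_rm <- rpois(1, n_keep * cfg$removal_fraction / (1 - cfg$removal_fraction))
    make_row <- function(k, kind) {
      if (k == 0) return(NULL)
      cons <- switch(kind,
        keep = sample(c("missense_variant", "stop_gained", "frameshift_variant",
                        "inframe_deletion"), k, replace = TRUE,
                      prob = c(0.8, 0.08, 0.08, 0.04)),
        removed = sample(CONSEQUENCE_EXCLUDE, k, replace = TRUE))
      vaf <- switch(kind,
        keep = runif(k, 0.15, 0.6),
        removed = runif(k, 0.15, 0.6))
      tibble(sample_id = sid[i],
             chrom = as.character(sample(1:22, k, replace = TRUE)),
             pos = sample.int(5e7, k), ref = sample(c("A", "C", "G", "T"), k, TRUE),
             alt = "T", gene = sample(gene_pool, k, replace = TRUE),
             consequence = cons, vaf = vaf,
             gnomad_af = NA_real_, kg_af = NA_real_,
             deleterious_votes = rbinom(k, 4, ifelse(cons == "missense_variant", 0.3, 0.1)),
             in_cosmic = runif(k) < 0.1, artifact_flag = FALSE)
    }
    keep <- make_row(n_keep, "keep")
    rm_mode <- if (n_rm > 0) sample(c("consequence", "germline", "artifact", "low_vaf"),
                                    n_rm, replace = TRUE) else character()
    removed <- make_row(n_rm, "removed")
    if (!is.null(removed)) {
      # overwrite the removal trigger per drawn mode
      fix <- rm_mode != "consequence"
      removed$consequence[fix] <- "missense_variant"
      removed$gnomad_af[rm_mode == "germline"] <- runif(sum(rm_mode == "germline"), 0.15, 0.5)
      removed$artifact_flag[rm_mode == "artifact"] <- TRUE
      removed$vaf[rm_mode == "low_vaf"] <- runif(sum(rm_mode == "low_vaf"), 0.01, 0.09)
    }
    atrx_row <- if (atrx[i]) {
      tibble(sample_id = sid[i], chrom = "X", pos = 76760000L, ref = "C",
             alt = "T", gene = "ATRX", consequence = "stop_gained", vaf = 0.4,
             gnomad_af = NA_real_, kg_af = NA_real_, deleterious_votes = 4L,
             in_cosmic = TRUE, artifact_flag = FALSE)
    } else NULL
    bind_rows(keep, removed, atrx_row)
  })
  ref_alt_same <- variants$ref == variants$alt
  variants$alt[ref_alt_same] <- "G"

  # --- segments ----------------------------------------------------------
  arms <- arm_table("GRCh37")
  seg_for <- function(arm_label, annotation, frac = 0.92) {
    a <- arms[arms$arm == arm_label, ]
    len <- a$end - a$start + 1
    ann_par <- switch(annotation,
      "DUP" = list(cn = 3L, minor = 1L, lr = 0.4),
      "HEMYZIG" = list(cn = 1L, minor = 0L, lr = -0.6),
      "DEL" = list(cn = 0L, minor = 0L, lr = -1.8),
      "LOH-NEUTRAL" = list(cn = 2L, minor = 0L, lr = 0.02),
      list(cn = 2L, minor = 1L, lr = 0))
    tibble(chrom = a$chrom, start = a$start,
           end = a$start + floor(len * frac), total_cn = ann_par$cn,
           minor_cn = ann_par$minor, log_ratio = ann_par$lr,
           annotation = annotation)
  }
  segments <- purrr::map_dfr(seq_len(n), function(i) {
    segs <- list()
    if (chr5[i]) segs <- c(segs, list(seg_for("5p", "DUP"), seg_for("5q", "DUP")))
    if (runif(1) < 0.35) segs <- c(segs, list(seg_for("1p", "HEMYZIG")))
    if (runif(1) < ifelse(metastatic[i], 0.30, 0.10))
      segs <- c(segs, list(seg_for(sample(c("3q", "11p", "17p", "22q"), 1), "HEMYZIG")))
    n_focal <- rpois(1, ifelse(metastatic[i], 4, 1.5) + (atrx[i] | tert[i]) * 2)
    if (n_focal > 0) {
      focal <- purrr::map_dfr(seq_len(n_focal), function(j) {
        a <- arms[sample.int(nrow(arms), 1), ]
        st <- sample(seq(a$start, max(a$start, a$end - 2e6)), 1)
        ann <- sample(c("DUP", "HEMYZIG", "DEL", "LOH-NEUTRAL"), 1,
                      prob = c(0.4, 0.4, 0.1, 0.1))
        seg <- seg_for(a$arm, ann)
        seg$start <- st
        seg$end <- min(a$end, st + sample(2e5:2e6, 1))
        seg
      })
      segs <- c(segs, list(focal))
    }
    segs <- c(segs, list(seg_for("2p", "NEUTRAL", frac = 0.99)))
    out <- bind_rows(segs)
    out$sample_id <- sid[i]
    out[, c("sample_id", "chrom", "start", "end", "total_cn", "minor_cn",
            "log_ratio", "annotation")]
  })

  # --- expression --------------------------------------------------------
  n_sig <- cfg$n_signature
  sig_genes <- gene_pool[seq_len(n_sig)]
  sig_genes[1] <- "CDK1"; if (n_sig >= 2) sig_genes[2] <- "MKI67"
  all_genes <- c(sig_genes, gene_pool[seq(n_sig + 1, cfg$n_genes)])
  n_up <- ceiling(n_sig * 0.75)
  lfc <- runif(n_sig, cfg$signature_lfc_range[1], cfg$signature_lfc_range[2]) *
    rep(c(1, -1), c(n_up, n_sig - n_up))
  base_mean <- exp(rnorm(cfg$n_genes, log(100), 1))
  log2_mu <- matrix(log2(base_mean), nrow = cfg$n_genes, ncol = n,
                    dimnames = list(all_genes, sid))
  log2_mu[seq_len(n_sig), metastatic] <- log2_mu[seq_len(n_sig), metastatic] + lfc
  # Fges archetype structure on a disjoint block of genes
  archetype <- sample(TME_ARCHETYPES, n, replace = TRUE,
                      prob = c(0.1, 0.25, 0.3, 0.35))
  fges_start <- n_sig + 1
  fges_genes_needed <- cfg$n_fges * cfg$fges_set_size
  stopifnot(fges_start + fges_genes_needed - 1 <= cfg$n_genes)
  fges_sets <- lapply(seq_len(cfg$n_fges), function(j) {
    all_genes[seq(fges_start + (j - 1) * cfg$fges_set_size,
                  fges_start + j * cfg$fges_set_size - 1)]
  })
  names(fges_sets) <- sprintf("Fges_%02d", seq_len(cfg$n_fges))
  immune_axis <- names(fges_sets)[seq_len(ceiling(cfg$n_fges / 2))]
  fibrotic_axis <- setdiff(names(fges_sets), immune_axis)
  active <- list("IE" = immune_axis, "IE/F" = c(immune_axis, fibrotic_axis),
                 "F" = fibrotic_axis, "D" = character())
  for (i in seq_len(n)) {
    on <- unlist(fges_sets[active[[archetype[i]]]])
    log2_mu[on, i] <- log2_mu[on, i] + cfg$fges_delta
  }
  counts <- matrix(rnbinom(length(log2_mu), size = 1 / cfg$dispersion,
                           mu = 2^log2_mu),
                   nrow = cfg$n_genes, dimnames = dimnames(log2_mu))

  # --- progression -------------------------------------------------------
  msi_high <- msi > 0.15
  lp <- log(cfg$hr_altered) * as.numeric(atrx | tert) +
    log(cfg$hr_altered) * 0.5 * as.numeric(msi_high) +
    1.0 * as.numeric(metastatic)
  ttp <- rexp(n, rate = cfg$base_hazard * exp(lp))
  event <- ttp < cfg$admin_days
  ttp_obs <- pmin(ttp, cfg$admin_days)

  # TERT evidence: each altered sample draws one positive channel; all
  # samples carry a (negative) panel-expression measurement
  tert_channel <- sample(c("expr", "promoter", "utss", "gistic"), n, TRUE)
  tert_panel_mean <- round(runif(n, 0.2, 3.2), 2)
  tert_panel_mean[tert & tert_channel == "expr"] <-
    round(runif(sum(tert & tert_channel == "expr"), 4.5, 12), 2)
  tert_promoter <- ifelse(tert & tert_channel == "promoter", "C228T", "none")
  tert_utss_mean <- round(runif(n, 4, 12), 1)
  tert_utss_mean[tert & tert_channel == "utss"] <-
    round(runif(sum(tert & tert_channel == "utss"), 14.1, 25), 1)
  tert_gistic <- ifelse(tert & tert_channel == "gistic", 2L, 0L)

  clinical <- tibble(
    sample_id = sid, patient_id = sprintf("P%03d", seq_len(n)),
    tumor_type = groups, genomic_subtype = subtype,
    genotype = ifelse(krebs, "SDHB", ifelse(maml3, "MAML3", "WT")),
    sex = sample(c("F", "M"), n, replace = TRUE),
    age_at_surgery = round(runif(n, 18, 75)),
    ttp_days = as.integer(round(ttp_obs)), progression_event = event,
    msi_score = round(msi, 4), krebs_germline = krebs, maml3_fusion = maml3,
    tert_panel_mean = tert_panel_mean, tert_promoter = tert_promoter,
    tert_utss_mean = tert_utss_mean, tert_gistic = tert_gistic)

  bundle <- assemble_bundle(clinical, variants = variants, segments = segments,
                            expression = counts, build = "GRCh37")
  truth <- list(
    samples = tibble(sample_id = sid, group = groups, subtype = subtype,
                     atrx = atrx, tert = tert, krebs = krebs, maml3 = maml3,
                     chr5_gain = chr5, tmb_true = tmb_true, msi_true = msi,
                     archetype = archetype, hazard_lp = lp),
    signature = tibble(gene = sig_genes, log2fc = lfc,
                       direction = ifelse(lfc > 0, "up_in_metastatic",
                                          "down_in_metastatic")),
    fges_sets = fges_sets,
    fges_axes = list(immune = immune_axis, fibrotic = fibrotic_axis),
    config = cfg, seed = seed)
  list(bundle = bundle, truth = truth)
}

#' Simulate a marker matrix with a planted best classifier
#'
#' Positives are partitioned across the planted events so that their
#' OR-combination has sensitivity 1, while each planted event fires rarely in
#' negatives; the remaining decoy events are weakly informative but noisy, so
#' adding any of them costs more specificity than it gains sensitivity. The
#' planted subset therefore has the uniquely highest sensitivity +
#' specificity by construction (realized gap recorded in the truth).
#'
#' @param n cohort size.
#' @param planted character vector of planted event names.
#' @param decoys character vector of decoy event names.
#' @param prevalence fraction of positive (metastatic) samples.
#' @param p_false positive rate of each planted event among negatives.
#' @param decoy_pos,decoy_neg decoy event rates in positives/negatives.
#' @param seed RNG seed.
#' @return list with `markers` (tibble: `sample_id`, `label`, events) and
#'   `truth` (planted subset and realized sensitivity/specificity gap).
#' @export
simulate_marker_cohort <- function(n = 200,
                                   planted = c("atrx_mut", "msi_high",
                                               "cdk1_high", "maml3_fusion"),
                                   decoys = setdiff(MARKER_EVENTS, planted),
                                   prevalence = 0.3, p_false = 0.02,
                                   decoy_pos = 0.35, decoy_neg = 0.25,
                                   seed = 1) {
  set.seed(seed)
  n_pos <- round(n * prevalence)
  label <- rep(c(1L, 0L), c(n_pos, n - n_pos))
  m <- matrix(0L, nrow = n, ncol = length(planted) + length(decoys),
              dimnames = list(NULL, c(planted, decoys)))
  block <- sample(rep_len(seq_along(planted), n_pos))
  for (j in seq_along(planted)) {
    m[which(label == 1)[block == j], planted[j]] <- 1L
    neg_idx <- which(label == 0)
    m[neg_idx, planted[j]] <- rbinom(length(neg_idx), 1, p_false)
  }
  for (d in decoys) {
    m[label == 1, d] <- rbinom(n_pos, 1, decoy_pos)
    m[label == 0, d] <- rbinom(n - n_pos, 1, decoy_neg)
  }
  markers <- bind_cols(tibble(sample_id = sprintf("S%03d", seq_len(n)),
                              label = label), as_tibble(m))
  pred <- as.integer(rowSums(m[, planted, drop = FALSE]) > 0)
  sens <- mean(pred[label == 1])
  spec <- mean(1 - pred[label == 0])
  list(markers = markers,
       truth = list(planted = sort(planted), sens = sens, spec = spec))
}

#' Simulate a stratified expression cohort with a planted signature
#'
#' Negative-binomial counts for `n_genes` genes over three genomic-subtype
#' strata, each split between non-metastatic and metastatic samples, with
#' `n_signature` planted genes whose log2 fold change (consistent in sign and
#' magnitude across strata) is drawn from `lfc_range`.
#'
#' @param n_per_stratum samples per stratum (split evenly between groups).
#' @param n_genes,n_signature,dispersion,lfc_range generator parameters.
#' @param seed RNG seed.
#' @return list with `counts`, `labels` (tibble `sample_id`, `group`,
#'   `stratum`), `truth` (tibble `gene`, `log2fc`).
#' @export
simulate_signature_cohort <- function(n_per_stratum = 60, n_genes = 2000,
                                      n_signature = 26, dispersion = 0.2,
                                      lfc_range = c(1, 2), seed = 1) {
  set.seed(seed)
  strata <- c("pseudohypoxic", "kinase_signaling", "wnt_altered")
  n <- n_per_stratum * length(strata)
  stratum <- rep(strata, each = n_per_stratum)
  group <- rep(rep(c("non_metastatic", "metastatic_primary"),
                   each = n_per_stratum / 2), length(strata))
  sid <- sprintf("S%03d", seq_len(n))
  genes <- sprintf("G%04d", seq_len(n_genes))
  lfc <- runif(n_signature, lfc_range[1], lfc_range[2]) *
    sample(c(1, -1), n_signature, replace = TRUE)
  base_mean <- exp(rnorm(n_genes, log(100), 1))
  log2_mu <- matrix(log2(base_mean), nrow = n_genes, ncol = n,
                    dimnames = list(genes, sid))
  met <- group == "metastatic_primary"
  log2_mu[seq_len(n_signature), met] <- log2_mu[seq_len(n_signature), met] + lfc
  counts <- matrix(rnbinom(length(log2_mu), size = 1 / dispersion, mu = 2^log2_mu),
                   nrow = n_genes, dimnames = dimnames(log2_mu))
  list(counts = counts,
       labels = tibble(sample_id = sid, group = group, stratum = stratum),
       truth = tibble(gene = genes[seq_len(n_signature)], log2fc = lfc))
}

#' Simulate a copy-number / expression integration cohort
#'
#' Builds per-gene coordinates, per-sample segments and a log-scale expression
#' matrix in which `n_planted` genes are concordant: their copy-number gains
#' are enriched in the metastatic group and their expression follows gene
#' dosage. The remaining genes carry group-independent copy-number events and
#' dosage-independent expression.
#'
#' @param n_per_group samples per group.
#' @param n_genes,n_planted generator sizes.
#' @param gain_met,gain_non gain probability per planted gene in
#'   metastatic/non-metastatic samples.
#' @param dosage_slope expression shift per copy-number unit for planted
#'   genes (log2 scale).
#' @param seed RNG seed.
#' @return list with `segments`, `gene_coords`, `expr` (genes x samples,
#'   log2), `groups` (tibble), `truth` (planted gene names).
#' @export
simulate_integration_cohort <- function(n_per_group = 100, n_genes = 5000,
                                        n_planted = 50, gain_met = 0.45,
                                        gain_non = 0.05, dosage_slope = 1.5,
                                        seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  sid <- sprintf("S%03d", seq_len(n))
  group <- rep(c("metastatic_primary", "non_metastatic"), each = n_per_group)
  genes <- sprintf("G%04d", seq_len(n_genes))
  # genes laid out on one synthetic chromosome, 10 kb each, 5 kb apart
  starts <- seq(1, by = 15000, length.out = n_genes)
  gene_coords <- tibble(gene = genes, chrom = "1", start = starts,
                        end = starts + 9999)
  planted <- genes[seq_len(n_planted)]
  is_met <- group == "metastatic_primary"
  # per gene-sample copy state drawn directly, then expressed as segments
  cn_state <- matrix(0L, nrow = n_genes, ncol = n, dimnames = list(genes, sid))
  p_gain <- matrix(0.05, nrow = n_genes, ncol = n)
  p_gain[seq_len(n_planted), is_met] <- gain_met
  p_gain[seq_len(n_planted), !is_met] <- gain_non
  gains <- matrix(rbinom(length(p_gain), 1, p_gain), nrow = n_genes)
  losses <- matrix(rbinom(length(p_gain), 1, 0.05), nrow = n_genes) * (gains == 0)
  cn_state[gains == 1] <- 1L
  cn_state[losses == 1] <- -1L
  segments <- purrr::map_dfr(seq_len(n), function(i) {
    st <- cn_state[, i]
    idx <- which(st != 0)
    if (length(idx) == 0) return(NULL)
    ann <- ifelse(st[idx] == 1, "DUP", "HEMYZIG")
    tibble(sample_id = sid[i], chrom = "1",
           start = gene_coords$start[idx], end = gene_coords$end[idx],
           total_cn = ifelse(st[idx] == 1, 3L, 1L),
           minor_cn = ifelse(st[idx] == 1, 1L, 0L),
           log_ratio = ifelse(st[idx] == 1, 0.4, -0.6), annotation = ann)
  })
  base <- rnorm(n_genes, 7, 1)
  expr <- matrix(rep(base, n), nrow = n_genes, dimnames = list(genes, sid)) +
    matrix(rnorm(n_genes * n, 0, 0.8), nrow = n_genes)
  expr[seq_len(n_planted), ] <- expr[seq_len(n_planted), ] +
    dosage_slope * cn_state[seq_len(n_planted), ]
  list(segments = segments, gene_coords = gene_coords, expr = expr,
       groups = tibble(sample_id = sid, group = group), truth = planted)
}

#' Simulate Fges score profiles with planted TME archetypes
#'
#' Each sample draws an archetype; immune-axis signatures have mean
#' `+separation` (in SD units) in immune-enriched archetypes and fibrotic-axis
#' signatures mean `+separation` in fibrotic archetypes, with unit noise.
#'
#' @param n samples.
#' @param n_sets number of signatures (default 29).
#' @param separation archetype mean shift in SD units (default 1).
#' @param seed RNG seed.
#' @return list with `scores` (n x n_sets matrix), `truth` (archetype per
#'   sample), `immune_sets`, `fibrotic_sets`.
#' @export
simulate_fges_scores <- function(n = 200, n_sets = 29, separation = 1, seed = 1) {
  set.seed(seed)
  sets <- sprintf("Fges_%02d", seq_len(n_sets))
  immune <- sets[seq_len(ceiling(n_sets / 2))]
  fibrotic <- setdiff(sets, immune)
  archetype <- sample(TME_ARCHETYPES, n, replace = TRUE)
  mu <- matrix(0, nrow = n, ncol = n_sets, dimnames = list(NULL, sets))
  mu[, immune] <- separation * ifelse(archetype %in% c("IE", "IE/F"), 1, -1)
  mu[, fibrotic] <- separation * ifelse(archetype %in% c("F", "IE/F"), 1, -1)
  scores <- mu + matrix(rnorm(n * n_sets), nrow = n)
  rownames(scores) <- sprintf("S%03d", seq_len(n))
  list(scores = scores, truth = archetype, immune_sets = immune,
       fibrotic_sets = fibrotic)
}

#' Simulate a binary-outcome cohort with a planted odds ratio
#'
#' One standard-normal exposure; outcome drawn from a logistic model with the
#' requested odds ratio per exposure unit.
#'
#' @param n cohort size.
#' @param or planted odds ratio.
#' @param intercept logit intercept (controls outcome prevalence).
#' @param seed RNG seed.
#' @return tibble `x`, `y`.
#' @export
simulate_logistic_cohort <- function(n = 500, or = 4, intercept = -0.5, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  p <- plogis(intercept + log(or) * x)
  tibble(x = x, y = rbinom(n, 1, p))
}

#' Simulate a survival cohort with a planted hazard ratio
#'
#' Exponential event times under a proportional-hazards model with one
#' standard-normal covariate; censoring is administrative at the quantile
#' giving the requested event fraction.
#'
#' @param n cohort size.
#' @param log_hr planted log hazard ratio per covariate unit.
#' @param event_fraction target fraction of observed events.
#' @param seed RNG seed.
#' @return tibble `x`, `time`, `event`.
#' @export
simulate_cox_cohort <- function(n = 500, log_hr = 0.7, event_fraction = 0.3,
                                seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  t_true <- rexp(n, rate = 0.01 * exp(log_hr * x))
  admin <- quantile(t_true, event_fraction, names = FALSE)
  tibble(x = x, time = pmin(t_true, admin),
         event = as.integer(t_true <= admin))
}

#' Recovery metrics of pipeline outputs against the truth ledger
#'
#' Compares whatever stage outputs are supplied against the planted truth and
#' reports one metric per stage; stages without an output are reported as
#' not run (`NA`).
#'
#' @param truth truth ledger from [simulate_cohort()] (or any list with the
#'   matching elements).
#' @param tmb optional tibble `sample_id`, `tmb` from [compute_tmb()].
#' @param signature optional selected-signature tibble ([select_signature()]).
#' @param best_subset optional character vector (recovered best classifier).
#' @param tme_labels optional integer/character cluster labels, named by
#'   sample or aligned with `truth$samples`.
#' @param planted_subset planted classifier subset (defaults to the four-event
#'   marker combination).
#' @return tibble `metric`, `value`, `note`.
#' @export
truth_report <- function(truth, tmb = NULL, signature = NULL,
                         best_subset = NULL, tme_labels = NULL,
                         planted_subset = c("atrx_mut", "cdk1_high",
                                            "maml3_fusion", "msi_high")) {
  rows <- list()
  add <- function(metric, value, note = NA_character_) {
    rows[[length(rows) + 1]] <<- tibble(metric = metric, value = value, note = note)
  }
  if (!is.null(tmb) && !is.null(truth$samples)) {
    j <- inner_join(tmb, truth$samples[, c("sample_id", "tmb_true")], by = "sample_id")
    add("tmb_mean_abs_error", mean(abs(j$tmb - j$tmb_true), na.rm = TRUE))
  } else add("tmb_mean_abs_error", NA_real_, "not run")
  if (!is.null(signature) && !is.null(truth$signature)) {
    found <- signature$gene
    planted <- truth$signature$gene
    add("signature_recall", length(intersect(found, planted)) / length(planted))
    add("signature_false_positives", length(setdiff(found, planted)))
  } else {
    add("signature_recall", NA_real_, "not run")
    add("signature_false_positives", NA_real_, "not run")
  }
  if (!is.null(best_subset)) {
    add("best_subset_recovered",
        as.numeric(setequal(best_subset, planted_subset)))
  } else add("best_subset_recovered", NA_real_, "not run")
  if (!is.null(tme_labels) && !is.null(truth$samples$archetype %||% truth$archetype %||% NULL)) {
    planted <- truth$samples$archetype %||% truth$archetype
    add("tme_ari", adjusted_rand_index(tme_labels, planted))
  } else add("tme_ari", NA_real_, "not run")
  bind_rows(rows)
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b label vectors of equal length.
#' @return numeric ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
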