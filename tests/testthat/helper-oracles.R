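# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from first principles rather than calling the
# implementation under test.

# Two-sided Fisher p for a 2x2 table by explicit hypergeometric enumeration:
# sum the probabilities of all tables (with the observed margins) whose
# probability does not exceed the observed one.
oracle_fisher_2x2 <- function(tab) {
  tab <- matrix(as.vector(tab), 2)
  m <- sum(tab[1, ])        # row-1 margin
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])        # col-1 margin
  support <- max(0, k - n):min(k, m)
  probs <- vapply(support, function(a) {
    choose(m, a) * choose(n, k - a) / choose(m + n, k)
  }, 0)
  p_obs <- probs[support == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact Freeman-Halton p for an r x c table by full enumeration of all tables
# with the observed margins under the multivariate hypergeometric.
enum_margin_rows <- function(total, caps) {
  if (length(caps) == 1) {
    if (total <= caps[1]) return(list(total)) else return(list())
  }
  out <- list()
  for (v in 0:min(total, caps[1])) {
    for (rest in enum_margin_rows(total - v, caps[-1])) {
      out[[length(out) + 1]] <- c(v, rest)
    }
  }
  out
}

enum_margin_tables <- function(rs, cs) {
  if (length(rs) == 1) {
    if (all(cs >= 0)) return(list(matrix(cs, 1))) else return(list())
  }
  out <- list()
  for (v in enum_margin_rows(rs[1], cs)) {
    for (rest in enum_margin_tables(rs[-1], cs - v)) {
      out[[length(out) + 1]] <- rbind(v, rest, deparse.level = 0)
    }
  }
  out
}

oracle_freeman_halton <- function(tab) {
  tab <- as.matrix(tab)
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  log_prob <- function(m) {
    sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(n) -
      sum(lfactorial(m))
  }
  lp_obs <- log_prob(tab)
  probs <- vapply(enum_margin_tables(rs, cs), log_prob, 0)
  sum(exp(probs[probs <= lp_obs + 1e-7]))
}

# Mann-Whitney pair probability: P(score_pos > score_neg) + 0.5 P(tie).
oracle_auc_mw <- function(score, truth) {
  pos <- score[truth == 1]; neg <- score[truth == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Classic GSEA enrichment score by a literal position-by-position walk.
oracle_classic_es <- function(ranked_genes, gene_set) {
  nh <- sum(ranked_genes %in% gene_set)
  n <- length(ranked_genes)
  best <- 0; rs <- 0
  for (g in ranked_genes) {
    rs <- rs + if (g %in% gene_set) 1 / nh else -1 / (n - nh)
    if (abs(rs) > abs(best)) best <- rs
  }
  best
}

# Log-rank O-E statistic computed from the textbook definition.
oracle_logrank_chisq <- function(time, event, group) {
  g <- sort(unique(group))
  stopifnot(length(g) == 2)
  death_times <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in death_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g[1])
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}

# Small deterministic fixtures -------------------------------------------

make_variants <- function() {
  tibble::tibble(
    sample_id = c("S1", "S1", "S1", "S1", "S1", "S2", "S2"),
    chrom = "1", pos = 1:7 * 100L, ref = "A", alt = "T",
    gene = c("TP53", "ATRX", "G1", "G2", "G3", "G4", "G5"),
    consequence = c("missense_variant", "stop_gained", "intron_variant",
                    "missense_variant", "synonymous_variant",
                    "missense_variant", "missense_variant"),
    vaf = c(0.3, 0.4, 0.5, 0.05, 0.2, 0.10, 0.25),
    gnomad_af = c(NA, NA, NA, NA, NA, 0.2, NA),
    kg_af = NA_real_,
    deleterious_votes = c(3L, 0L, 0L, 2L, 0L, 0L, 1L),
    in_cosmic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    artifact_flag = FALSE)
}

make_segments <- function() {
  tibble::tibble(
    sample_id = c("S1", "S1", "S1", "S2", "S2"),
    chrom = c("1", "1", "5", "5", "5"),
    start = c(1, 2e7, 1, 1, 50e6),
    end = c(1e7, 3e7, 48e6, 48e6, 180e6),
    total_cn = c(1L, 9L, 3L, 3L, 3L),
    minor_cn = c(0L, 4L, 1L, 1L, 1L),
    log_ratio = c(-0.6, 1.2, 0.4, 0.4, 0.4),
    annotation = c("HEMYZIG", "DUP", "DUP", "DUP", "DUP"))
}

make_clinical <- function(ids = c("S1", "S2")) {
  tibble::tibble(
    sample_id = ids, patient_id = paste0("P", seq_along(ids)),
    tumor_type = rep(c("metastatic_primary", "non_metastatic"),
                     length.out = length(ids)),
    genomic_subtype = "pseudohypoxic", genotype = "WT", sex = "F",
    age_at_surgery = 50, ttp_days = 1000L, progression_event = FALSE,
    msi_score = 0.12, krebs_germline = FALSE, maml3_fusion = FALSE)
}
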