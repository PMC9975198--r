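CN_RECODE <- c("DUP" = 1, "DUP-LOH" = 1, "NEUTRAL" = 0, "LOH-NEUTRAL" = 0,
               "HEMYZIG" = -1, "DEL" = -2)

#' Project segment annotations onto genes
#'
#' Per gene and sample, assigns the annotation of the copy-number segment with
#' maximal overlap of the gene body and recodes it: gains (`DUP`, `DUP-LOH`)
#' as 1, no event as 0, hemizygous deletion as -1, homozygous deletion as -2.
#' A gene with no overlapping segment gets 0. Overlap ties go to the more
#' extreme recode value (largest absolute value, deletions over gains at equal
#' magnitude).
#'
#' @param segments filtered segments ([filter_segments()]).
#' @param gene_coords tibble `gene`, `chrom`, `start`, `end` (1-based closed,
#'   same build as the segments).
#' @return genes-by-samples integer matrix with values in \{1, 0, -1, -2\}.
#' @export
project_gene_cn <- function(segments, gene_coords) {
  seg <- as_tibble(segments)
  gc <- as_tibble(gene_coords)
  samples <- sort(unique(seg$sample_id))
  out <- matrix(0L, nrow = nrow(gc), ncol = length(samples),
                dimnames = list(gc$gene, samples))
  seg_by <- split(seg, seg$sample_id)
  for (sid in samples) {
    s <- seg_by[[sid]]
    for (ch in unique(gc$chrom)) {
      gi <- which(gc$chrom == ch)
      sc <- s[s$chrom == ch, , drop = FALSE]
      if (nrow(sc) == 0) next
      # genes x segments overlap lengths for this sample/chromosome block
      ov <- outer(gc$end[gi], sc$end, pmin) - outer(gc$start[gi], sc$start, pmax) + 1
      codes <- CN_RECODE[sc$annotation]
      # tie-break: larger overlap, then more extreme recode value, then
      # deletions over gains at equal magnitude
      priority <- abs(codes) * 2 + as.integer(codes < 0)
      score <- ov * 8 + rep(priority, each = length(gi))
      score[ov <= 0] <- -Inf
      pick <- max.col(score, ties.method = "first")
      any_hit <- is.finite(score[cbind(seq_along(gi), pick)])
      out[gi[any_hit], sid] <- as.integer(codes[pick[any_hit]])
    }
  }
  out
}

#' Per-gene Fisher tests of copy-number event frequency between groups
#'
#' For each gene, builds the 2x2 table of gain-present (recode 1) versus not
#' by group, and separately loss-present (recode < 0) versus not, and applies
#' a two-sided Fisher exact test. Genes invariant across the cohort in a
#' direction get p = 1 for that direction.
#'
#' @param gene_cn genes-by-samples matrix from [project_gene_cn()].
#' @param groups tibble `sample_id`, `group` (two levels).
#' @param p_threshold selection threshold on the minimum of the two p-values
#'   (default 0.05, strict).
#' @return list with `stats` (tibble `gene`, `p_gain`, `p_loss`) and
#'   `selected` (genes with min(p) below the threshold).
#' @export
gene_group_fisher <- function(gene_cn, groups, p_threshold = 0.05) {
  groups <- as_tibble(groups)
  lv <- sort(unique(groups$group))
  if (length(lv) != 2) stop("exactly two groups required", call. = FALSE)
  idx <- match(colnames(gene_cn), groups$sample_id)
  grp <- groups$group[idx]
  g1 <- grp == lv[1]
  fisher_p <- function(event_mat) {
    a <- rowSums(event_mat[, g1, drop = FALSE])
    b <- sum(g1) - a
    c_ <- rowSums(event_mat[, !g1, drop = FALSE])
    d <- sum(!g1) - c_
    vapply(seq_along(a), function(i) {
      if (a[i] + c_[i] == 0 || b[i] + d[i] == 0) return(1)
      stats::fisher.test(matrix(c(a[i], b[i], c_[i], d[i]), 2))$p.value
    }, 0)
  }
  p_gain <- fisher_p(gene_cn == 1)
  p_loss <- fisher_p(gene_cn < 0)
  stats <- tibble(gene = rownames(gene_cn), p_gain = p_gain, p_loss = p_loss)
  list(stats = stats,
       selected = stats$gene[pmin(stats$p_gain, stats$p_loss) < p_threshold])
}

# Vectorized one-way ANOVA of each matrix row across the levels of f.
row_oneway_f <- function(Y, f) {
  f <- as.factor(f)
  n <- ncol(Y)
  k <- nlevels(f)
  counts <- as.vector(table(f))
  group_sums <- t(rowsum(t(Y), f))          # genes x levels
  group_means <- sweep(group_sums, 2, counts, "/")
  grand_mean <- rowMeans(Y)
  ss_between <- rowSums(sweep((group_means - grand_mean)^2, 2, counts, "*"))
  ss_total <- rowSums((Y - grand_mean)^2)
  ss_within <- ss_total - ss_between
  df1 <- k - 1
  df2 <- n - k
  fstat <- (ss_between / df1) / (ss_within / df2)
  p <- pf(fstat, df1, df2, lower.tail = FALSE)
  p[!is.finite(fstat)] <- 1
  list(f = fstat, p = p, df1 = df1, df2 = df2)
}

#' Copy-number / expression association per gene
#'
#' For each gene with at least two observed copy-number levels, a one-way
#' ANOVA of expression across the recoded CN levels (treated as categorical
#' over the observed levels) with BH FDR over the tested genes, and the
#' Pearson correlation between the recoded CN value and expression. Genes
#' qualify when FDR is below `fdr_threshold` and the correlation is positive
#' (dosage-concordant).
#'
#' @param gene_cn genes-by-samples recode matrix.
#' @param expr genes-by-samples expression matrix (log scale recommended),
#'   sharing gene and sample names with `gene_cn`.
#' @param fdr_threshold default 0.05 (strict).
#' @return list with `stats` (tibble `gene`, `anova_p`, `anova_fdr`,
#'   `pearson_r`, `excluded_reason`) and `selected`.
#' @export
cn_expr_association <- function(gene_cn, expr, fdr_threshold = 0.05) {
  genes <- intersect(rownames(gene_cn), rownames(expr))
  samples <- intersect(colnames(gene_cn), colnames(expr))
  cn <- gene_cn[genes, samples, drop = FALSE]
  ex <- expr[genes, samples, drop = FALSE]
  n_levels <- apply(cn, 1, function(x) length(unique(x)))
  testable <- n_levels >= 2
  anova_p <- rep(NA_real_, length(genes))
  r <- rep(NA_real_, length(genes))
  if (any(testable)) {
    # group ANOVA must be run per gene because the level partition differs,
    # but the F statistic itself is closed-form
    idx <- which(testable)
    anova_p[idx] <- vapply(idx, function(i) {
      row_oneway_f(ex[i, , drop = FALSE], factor(cn[i, ]))$p
    }, 0)
    r[idx] <- vapply(idx, function(i) {
      suppressWarnings(cor(cn[i, ], ex[i, ]))
    }, 0)
  }
  fdr <- rep(NA_real_, length(genes))
  fdr[testable] <- p.adjust(anova_p[testable], method = "BH")
  stats <- tibble(gene = genes, anova_p = unname(anova_p),
                  anova_fdr = unname(fdr), pearson_r = unname(r),
                  excluded_reason = unname(ifelse(testable, NA_character_,
                                                  "single CN level")))
  sel <- stats$gene[!is.na(stats$anova_fdr) & stats$anova_fdr < fdr_threshold &
                      !is.na(stats$pearson_r) & stats$pearson_r > 0]
  list(stats = stats, selected = sel)
}

#' Intersect the Fisher and dosage-association gene lists
#'
#' @param fisher_genes,association_genes character vectors on the same
#'   universe.
#' @return sorted character vector (possibly empty).
#' @export
intersect_concordant <- function(fisher_genes, association_genes) {
  sort(intersect(fisher_genes, association_genes))
}

#' Integrated copy-number / expression concordance analysis
#'
#' Runs the full chain: gene-level CN projection, per-gene group Fisher tests,
#' CN-expression dosage association, and the final intersection list.
#'
#' @inheritParams project_gene_cn
#' @inheritParams gene_group_fisher
#' @param expr genes-by-samples expression matrix (log scale).
#' @param fdr_threshold ANOVA FDR threshold (default 0.05).
#' @return list with `gene_cn`, `fisher`, `association`, `concordant`.
#' @export
integrate_scna_expression <- function(segments, gene_coords, expr, groups,
                                      p_threshold = 0.05, fdr_threshold = 0.05) {
  gene_cn <- project_gene_cn(segments, gene_coords)
  fisher <- gene_group_fisher(gene_cn, groups, p_threshold)
  assoc <- cn_expr_association(gene_cn, expr, fdr_threshold)
  list(gene_cn = gene_cn, fisher = fisher, association = assoc,
       concordant = intersect_concordant(fisher$selected, assoc$selected))
}
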