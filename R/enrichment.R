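# Weighted KS running-sum score for one ranked sample.
# ranks: named vector, higher = more expressed. gene_set: symbols.
ssgsea_one <- function(ranks, gene_set, alpha = 0.25) {
  genes <- names(ranks)
  hit <- genes %in% gene_set
  if (!any(hit)) return(NA_real_)
  ord <- order(ranks, decreasing = TRUE)
  hit <- hit[ord]
  w <- ranks[ord]^alpha
  p_hit <- cumsum(ifelse(hit, w, 0)) / sum(w[hit])
  n_miss <- sum(!hit)
  p_miss <- cumsum(!hit) / n_miss
  sum(p_hit - p_miss)
}

#' Rank-based single-sample gene-set scores
#'
#' For each sample, genes are ranked within the sample (ties mid-ranked) and
#' each gene set scored by the weighted Kolmogorov-Smirnov running-sum
#' difference between the in-set and out-of-set cumulative distributions, with
#' weight `rank^alpha`. The score depends on expression only through ranks, so
#' it is invariant under any strictly monotone transform.
#'
#' @param mat genes-by-samples expression matrix (any monotone scale).
#' @param gene_sets named list of gene symbol vectors.
#' @param alpha rank-weight exponent (default 0.25).
#' @return samples-by-sets numeric matrix; sets with an empty intersection
#'   with the measured universe score `NA`.
#' @export
ssgsea_scores <- function(mat, gene_sets, alpha = 0.25) {
  rk <- apply(mat, 2, rank, ties.method = "average")
  rownames(rk) <- rownames(mat)
  out <- vapply(gene_sets, function(gs) {
    apply(rk, 2, ssgsea_one, gene_set = gs, alpha = alpha)
  }, numeric(ncol(mat)))
  out <- matrix(out, nrow = ncol(mat),
                dimnames = list(colnames(mat), names(gene_sets)))
  out
}

# Classic (unweighted) GSEA enrichment score: hits add 1/Nh, misses subtract
# 1/(N - Nh); ES is the maximum deviation from zero (signed).
classic_es <- function(ranked_genes, gene_set) {
  hit <- ranked_genes %in% gene_set
  nh <- sum(hit)
  n <- length(ranked_genes)
  if (nh == 0 || nh == n) return(NA_real_)
  steps <- ifelse(hit, 1 / nh, -1 / (n - nh))
  rs <- cumsum(steps)
  rs[which.max(abs(rs))]
}

#' Pre-ranked GSEA with classic scoring
#'
#' Genes are ordered by a ranking metric (decreasing); the classic
#' (unweighted) enrichment score is the signed maximum deviation of the
#' running sum in which set members add `1/Nh` and non-members subtract
#' `1/(N-Nh)`. Significance uses gene-label permutations: NES is the observed
#' ES over the mean absolute permuted ES of matching sign; the nominal p is
#' the fraction of same-signed permuted ES at least as extreme; BH FDR is
#' applied across the sets tested. Sets outside the size bounds, or covering
#' the entire universe, are skipped with a reason.
#'
#' @param metric named numeric vector (e.g. per-gene log2 fold change).
#' @param gene_sets named list of gene symbol vectors.
#' @param n_perm number of gene-label permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @param set_min,set_max bounds on set size after intersection with the
#'   universe (defaults 10 and 1000).
#' @return tibble `set`, `size`, `es`, `nes`, `p`, `q`, `skipped`, `reason`.
#' @export
preranked_gsea <- function(metric, gene_sets, n_perm = 1000, seed = 1,
                           set_min = 10, set_max = 1000) {
  ranked <- names(sort(metric, decreasing = TRUE))
  n <- length(ranked)
  sizes <- vapply(gene_sets, function(g) sum(ranked %in% g), 0L)
  skip <- sizes < set_min | sizes > set_max | sizes == n
  reason <- rep(NA_character_, length(gene_sets))
  reason[sizes < set_min] <- "below set_min"
  reason[sizes > set_max] <- "above set_max"
  reason[sizes == n] <- "set covers entire universe"
  es <- rep(NA_real_, length(gene_sets))
  nes <- p <- rep(NA_real_, length(gene_sets))
  eval_idx <- which(!skip)
  if (length(eval_idx) > 0) {
    withr_seed <- function(expr) { set.seed(seed); expr }
    perm_store <- new.env()
    withr_seed({
      for (i in eval_idx) {
        gs <- gene_sets[[i]]
        es[i] <- classic_es(ranked, gs)
        nh <- sizes[i]
        key <- as.character(nh)
        if (is.null(perm_store[[key]])) {
          perm_store[[key]] <- replicate(n_perm, {
            classic_es(ranked, sample(ranked, nh))
          })
        }
        null_es <- perm_store[[key]]
        same_sign <- null_es[sign(null_es) == sign(es[i])]
        denom <- mean(abs(same_sign))
        nes[i] <- if (is.finite(denom) && denom > 0) es[i] / denom else NA_real_
        p[i] <- if (length(same_sign) == 0) 1 / (n_perm + 1) else
          (sum(abs(same_sign) >= abs(es[i])) + 1) / (length(same_sign) + 1)
      }
    })
  }
  q <- rep(NA_real_, length(gene_sets))
  q[eval_idx] <- p.adjust(p[eval_idx], method = "BH")
  tibble(set = names(gene_sets), size = as.integer(sizes), es = es, nes = nes,
         p = p, q = q, skipped = skip, reason = reason)
}

#' Over-representation (fold-enrichment) test
#'
#' For each gene set, fold enrichment is the overlap fraction of the query
#' over the set's fraction of the universe; the p-value is a one-sided Fisher
#' exact test on the 2x2 overlap table and BH FDR is applied across sets. A
#' set is called significant when fold enrichment is strictly above
#' `fc_threshold` and q strictly below `fdr_threshold`.
#'
#' @param query character vector of genes (must be a subset of `universe`,
#'   non-empty).
#' @param universe character vector of all measured genes.
#' @param gene_sets named list of gene sets.
#' @param fc_threshold fold-enrichment threshold (default 1.8).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @return tibble `set`, `overlap`, `set_size`, `fold_enrichment`, `p`, `q`,
#'   `significant`.
#' @export
overrepresentation_test <- function(query, universe, gene_sets,
                                    fc_threshold = 1.8, fdr_threshold = 0.05) {
  if (length(query) == 0) stop("query gene list is empty", call. = FALSE)
  extra <- setdiff(query, universe)
  if (length(extra) > 0)
    stop("query genes absent from universe: ",
         paste(head(extra, 5), collapse = ", "), call. = FALSE)
  n_u <- length(universe)
  n_q <- length(query)
  rows <- purrr::imap_dfr(gene_sets, function(gs, nm) {
    set_in_u <- intersect(gs, universe)
    ov <- length(intersect(query, set_in_u))
    fce <- if (length(set_in_u) == 0) NA_real_ else
      (ov / n_q) / (length(set_in_u) / n_u)
    p <- if (length(set_in_u) == 0) NA_real_ else {
      tab <- matrix(c(ov, length(set_in_u) - ov,
                      n_q - ov, n_u - length(set_in_u) - (n_q - ov)), 2)
      stats::fisher.test(tab, alternative = "greater")$p.value
    }
    tibble(set = nm, overlap = ov, set_size = length(set_in_u),
           fold_enrichment = fce, p = p)
  })
  rows$q <- p.adjust(rows$p, method = "BH")
  rows$significant <- !is.na(rows$fold_enrichment) &
    rows$fold_enrichment > fc_threshold & rows$q < fdr_threshold
  rows
}
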