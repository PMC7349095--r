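# Rank normalization of expression matrices, two-group differential
# expression on rank-normalized values with Benjamini-Hochberg correction,
# and preranked gene-set enrichment with a gene-permutation null.

#' Rank-normalize an expression matrix
#'
#' Within each sample, values are replaced by fractional ranks (average for
#' ties) rescaled as `(rank - 1) / (N - 1)`, so the lowest gene maps to 0
#' and the highest to 1. The result is invariant under any strictly
#' monotone per-sample transform of the input, which is what makes it
#' robust to batch effects in cross-dataset comparisons.
#'
#' @param mat numeric matrix, genes in rows (>= 2), samples in columns.
#' @return matrix of the same shape with values in `[0, 1]`.
#' @export
rank_normalize <- function(mat) {
  if (nrow(mat) < 2) {
    stop("rank normalization needs at least 2 genes", call. = FALSE)
  }
  apply(mat, 2, function(x) (rank(x, ties.method = "average") - 1) /
          (length(x) - 1))
}

#' Two-group differential expression on rank-normalized values
#'
#' Per gene, the fold change is the log2 ratio of group means of the
#' rank-normalized values, `log2((mean_a + eps) / (mean_b + eps))` with
#' `eps = 0` unless one mean is 0, in which case `eps = 1 / (2 * N)` (half
#' the rank-normalization grid step) keeps the ratio finite. The per-gene
#' p-value comes from a two-sided pooled-variance t-test on the normalized
#' values by default: after rank normalization every sample shares the same
#' marginal distribution, so group variances are comparable and the pooled
#' estimator's larger degrees of freedom are better calibrated at the small
#' group sizes this package targets. `test = "welch"` gives the
#' unequal-variance test, and `test = "ranksum"` a two-sided rank-sum
#' (Wilcoxon) test; note that with very small groups the exact rank-sum
#' p has a combinatorial floor (`2 / choose(n_a + n_b, n_a)`) that no gene
#' can beat, which makes genome-wide BH-adjusted significance unattainable.
#' Adjusted p-values use Benjamini-Hochberg over all genes; the
#' `significant` flag applies `|log2_fc| > lfc_threshold` and
#' `padj < padj_threshold`.
#'
#' @param mat_norm rank-normalized matrix from [rank_normalize()].
#' @param groups group label per column (exactly two levels, n >= 2 each).
#' @param group_order optional length-2 character giving which level is the
#'   fold-change numerator (first element); defaults to sorted order.
#' @param test `"t"` (pooled variance, default), `"welch"` or `"ranksum"`.
#' @param lfc_threshold,padj_threshold thresholds for the `significant`
#'   flag (defaults 1 and 0.05).
#' @return data.frame `gene`, `mean_a`, `mean_b`, `log2_fc`, `p`, `padj`,
#'   `significant`, with `attr(,"groups")` naming the a/b levels.
#' @export
differential_expression <- function(mat_norm, groups, group_order = NULL,
                                    test = c("t", "welch", "ranksum"),
                                    lfc_threshold = 1,
                                    padj_threshold = 0.05) {
  test <- match.arg(test)
  groups <- as.character(groups)
  if (length(groups) != ncol(mat_norm)) {
    stop("one group label per sample column is required", call. = FALSE)
  }
  lv <- if (is.null(group_order)) sort(unique(groups)) else group_order
  if (length(unique(groups)) != 2 || !setequal(lv, unique(groups))) {
    stop("need exactly two groups", call. = FALSE)
  }
  ia <- which(groups == lv[1])
  ib <- which(groups == lv[2])
  if (length(ia) < 2 || length(ib) < 2) {
    stop("each group needs at least two samples", call. = FALSE)
  }
  n_genes <- nrow(mat_norm)
  mean_a <- rowMeans(mat_norm[, ia, drop = FALSE])
  mean_b <- rowMeans(mat_norm[, ib, drop = FALSE])
  eps <- ifelse(mean_a == 0 | mean_b == 0, 1 / (2 * n_genes), 0)
  log2_fc <- log2((mean_a + eps) / (mean_b + eps))
  p <- vapply(seq_len(n_genes), function(g) {
    a <- mat_norm[g, ia]
    b <- mat_norm[g, ib]
    if (test == "ranksum") {
      return(suppressWarnings(stats::wilcox.test(a, b)$p.value))
    }
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    }
    stats::t.test(a, b, var.equal = (test == "t"))$p.value
  }, 0)
  padj <- stats::p.adjust(p, method = "BH")
  res <- data.frame(
    gene = rownames(mat_norm), mean_a = mean_a, mean_b = mean_b,
    log2_fc = log2_fc, p = p, padj = padj,
    significant = abs(log2_fc) > lfc_threshold & padj < padj_threshold,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(res, "groups") <- stats::setNames(lv, c("a", "b"))
  res
}

# running-sum enrichment score from sorted hit positions;
# w are the hit weights (|score|^p at the hit positions, in ranking order)
es_running <- function(hit_pos, w, n_total) {
  k <- length(hit_pos)
  nr <- sum(w)
  if (nr == 0) { w <- rep(1, k); nr <- k }  # all-zero scores: unweighted
  up <- cumsum(w) / nr - (hit_pos - seq_len(k)) / (n_total - k)
  down <- up - w / nr
  hi <- max(up)
  lo <- min(c(down, 0))
  if (hi >= -lo) hi else lo
}

#' Preranked gene-set enrichment analysis
#'
#' Walks the ranking from top to bottom accumulating a running sum that
#' increases by `|score|^weight_p` (normalized over the set's hits) at set
#' members and decreases by `1/(N - k)` at non-members; the enrichment
#' score (ES) is the signed maximum deviation. The null distribution comes
#' from `n_perm` random gene-label permutations (random sets of the same
#' size), the normalized score (NES) divides ES by the mean absolute null
#' ES of matching sign, the permutation p is the same-signed null tail, and
#' FDR q follows the standard pooled positive/negative-null procedure.
#'
#' @param scores named numeric vector of per-gene ranking scores (e.g.
#'   signed -log10 p); sorted internally in decreasing order.
#' @param gene_sets named list of character vectors.
#' @param weight_p hit-weight exponent (default 1; 0 gives the unweighted
#'   Kolmogorov-Smirnov-like statistic).
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @param min_size sets with fewer mapped members are skipped with a
#'   warning (default 2).
#' @return data.frame `set`, `size`, `es`, `nes`, `perm_p`, `fdr_q`.
#' @export
gsea_preranked <- function(scores, gene_sets, weight_p = 1, n_perm = 1000,
                           seed = NULL, min_size = 2) {
  if (!is.null(seed)) set.seed(seed)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  ranked_genes <- names(scores)[ord]
  ranked_scores <- abs(scores[ord])^weight_p
  n <- length(scores)
  res <- list()
  null_nes <- numeric(0)
  obs_nes <- numeric(0)
  for (nm in names(gene_sets)) {
    hits <- sort(match(gene_sets[[nm]], ranked_genes))
    hits <- hits[!is.na(hits)]
    k <- length(hits)
    if (k < min_size) {
      warning(sprintf("gene set %s has fewer than %d mapped members; skipped",
                      nm, min_size))
      next
    }
    es <- es_running(hits, ranked_scores[hits], n)
    null_es <- vapply(seq_len(n_perm), function(i) {
      hp <- sort(sample.int(n, k))
      es_running(hp, ranked_scores[hp], n)
    }, 0)
    mean_pos <- mean(null_es[null_es >= 0])
    mean_neg <- mean(abs(null_es[null_es < 0]))
    nes <- if (es >= 0) es / mean_pos else -abs(es) / mean_neg
    same <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    perm_p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    nn <- ifelse(null_es >= 0, null_es / mean_pos, -abs(null_es) / mean_neg)
    null_nes <- c(null_nes, nn)
    obs_nes <- c(obs_nes, nes)
    res[[length(res) + 1L]] <- data.frame(
      set = nm, size = k, es = es, nes = nes, perm_p = perm_p,
      fdr_q = NA_real_, stringsAsFactors = FALSE)
  }
  if (!length(res)) {
    return(data.frame(set = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0),
                      perm_p = numeric(0), fdr_q = numeric(0)))
  }
  out <- do.call(rbind, res)
  null_nes <- null_nes[is.finite(null_nes)]
  for (i in seq_len(nrow(out))) {
    v <- out$nes[i]
    if (!is.finite(v)) next
    if (v >= 0) {
      num <- mean(null_nes[null_nes >= 0] >= v)
      den <- mean(obs_nes[obs_nes >= 0] >= v)
    } else {
      num <- mean(null_nes[null_nes < 0] <= v)
      den <- mean(obs_nes[obs_nes < 0] <= v)
    }
    out$fdr_q[i] <- if (is.finite(den) && den > 0) min(1, num / den) else NA_real_
  }
  rownames(out) <- NULL
  out
}
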