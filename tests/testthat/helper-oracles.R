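# Independent oracles used across the suite. Each one recomputes a
# quantity from first principles (enumeration, closed form, literal walk)
# without touching the code path it checks.

# One-sided Fisher p by explicit enumeration of all 2x2 tables with the
# observed margins, summing multivariate hypergeometric probabilities of
# tables at least as tumor-alt-enriched as observed.
oracle_fisher_p <- function(tumor_ref, tumor_alt, normal_ref, normal_alt) {
  n1 <- tumor_ref + tumor_alt   # tumor row margin
  n2 <- normal_ref + normal_alt # normal row margin
  K <- tumor_alt + normal_alt   # alt column margin
  j <- max(0, K - n2):min(K, n1)  # support of tumor_alt
  prob <- choose(n1, j) * choose(n2, K - j) / choose(n1 + n2, K)
  sum(prob[j >= tumor_alt])
}

# Exhaustive all-splits max-t search using the pooled-variance two-sample t
# computed directly from the definition (means and sums of squares), with
# leftmost tie-breaking. Returns list(i, j, t).
oracle_max_t <- function(x, min_probes = 3) {
  n <- length(x)
  best <- list(i = -1L, j = -1L, t = -1)
  if (n < 2 * min_probes || n <= 2) return(best)
  for (i in 0:(n - min_probes)) {
    for (j in (i + min_probes):min(n, i + n - min_probes)) {
      a <- x[(i + 1):j]
      c_ <- x[-((i + 1):j)]
      m <- length(a); mc <- length(c_)
      diff <- mean(a) - mean(c_)
      ss <- sum((a - mean(a))^2) + sum((c_ - mean(c_))^2)
      s2 <- ss / (n - 2)
      den <- s2 * (1 / m + 1 / mc)
      t <- if (den <= 1e-300) {
        if (abs(diff) > 1e-12 * (1 + abs(mean(a)) + abs(mean(c_)))) Inf else 0
      } else {
        abs(diff) / sqrt(den)
      }
      if (t > best$t) best <- list(i = i, j = j, t = t)
    }
  }
  best
}

# Textbook Benjamini-Hochberg step-up: adj p_(i) = min_{j >= i} p_(j)*m/j,
# mapped back to the input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- ps * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Literal walk of the GSEA running sum over every position in the ranking.
oracle_gsea_es <- function(ranked_genes, ranked_scores, set, weight_p = 1) {
  n <- length(ranked_genes)
  hit <- ranked_genes %in% set
  k <- sum(hit)
  w <- abs(ranked_scores)^weight_p
  nr <- sum(w[hit])
  rs <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    cur <- if (hit[i]) cur + w[i] / nr else cur - 1 / (n - k)
    rs[i] <- cur
  }
  if (max(rs) >= -min(c(rs, 0))) max(rs) else min(c(rs, 0))
}

# Welch t-test from the closed-form definition (Welch-Satterthwaite df and
# the t distribution CDF).
oracle_welch_p <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * stats::pt(-abs(t), df)
}

# small well-formed variant data.frame in the package's internal layout
make_variants <- function(n = 5, seed = 1) {
  set.seed(seed)
  data.frame(
    chrom = "19", pos = sort(sample.int(1e6, n)),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    tumor_ref = rpois(n, 40), tumor_alt = rpois(n, 40),
    normal_ref = rpois(n, 40), normal_alt = rpois(n, 40),
    gene = sprintf("G%d", seq_len(n)), effect = "missense",
    coding = TRUE, pop_af = NA_real_, prediction = "unknown",
    stringsAsFactors = FALSE
  )
}

# small cohort configuration used by pipeline-level tests (kept light so
# the default suite stays fast; the full study-scale conditions are
# exercised in the acceptance tests)
small_sim_config <- function(seed, ...) {
  args <- list(
    seed = seed, n_samples = 4,
    genome = data.frame(chrom = "19", length = 2e7,
                        stringsAsFactors = FALSE),
    cnloh_region = genomic_interval("19", 373916, 8e6),
    cnloh_fraction = 3 / 4,
    gains = data.frame(chrom = "19", start = 12e6 + 1, end = 13.5e6,
                       log2_level = 2.33, n_carriers = 3,
                       stringsAsFactors = FALSE),
    expr_n_genes = 300, expr_group_sizes = c(4, 4)
  )
  do.call(sim_config, utils::modifyList(args, list(...)))
}
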