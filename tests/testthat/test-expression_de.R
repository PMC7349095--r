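test_that("rank normalization maps to [0,1] with average ties", {
  m <- matrix(c(5, 1, 9), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(as.numeric(rank_normalize(m)), c(0.5, 0, 1))
  # all tied: all 0.5
  tied <- matrix(7, 4, 2, dimnames = list(letters[1:4], c("s1", "s2")))
  expect_true(all(rank_normalize(tied) == 0.5))
  # per-sample mean is 0.5 when there are no ties
  set.seed(2)
  r <- rank_normalize(matrix(rnorm(500), 100, 5,
                             dimnames = list(sprintf("g%d", 1:100), NULL)))
  expect_equal(unname(colMeans(r)), rep(0.5, 5))
  expect_error(rank_normalize(matrix(1, 1, 2)), "at least 2")
})

test_that("rank normalization is invariant to strictly monotone transforms", {
  set.seed(4)
  m <- matrix(rexp(300), 60, 5,
              dimnames = list(sprintf("g%d", 1:60), sprintf("s%d", 1:5)))
  r0 <- rank_normalize(m)
  transforms <- list(function(x) exp(x), function(x) x^3 + 2,
                     function(x) log1p(x), function(x) 1000 * x - 5)
  for (i in seq_len(ncol(m))) {
    m[, i] <- transforms[[(i %% 4) + 1]](m[, i])
  }
  expect_equal(rank_normalize(m), r0)
})

test_that("fold change reproduces the mean-ratio arithmetic of marker genes", {
  # gene fixed at normalized rank 0.50 in one group and 0.95 in the other
  n_genes <- 21
  mk <- function(target_rank) {
    col <- seq_len(n_genes)
    col[c(target_rank, 11)] <- col[c(11, target_rank)]
    col
  }
  a_cols <- replicate(3, mk(11))   # gene 11 at rank 11 -> 0.50
  b_cols <- replicate(3, mk(20))   # gene 11 at rank 20 -> 0.95
  m <- cbind(a_cols, b_cols)
  rownames(m) <- sprintf("g%02d", seq_len(n_genes))
  rn <- rank_normalize(m)
  de <- differential_expression(rn, rep(c("tumor", "benign"), each = 3),
                                group_order = c("tumor", "benign"))
  g11 <- de[de$gene == "g11", ]
  expect_equal(g11$mean_a, 0.50)
  expect_equal(g11$mean_b, 0.95)
  expect_equal(g11$log2_fc, log2(0.50 / 0.95))
  expect_equal(round(g11$log2_fc, 2), -0.93)
})

test_that("identical groups yield zero fold change and p of 1", {
  m <- matrix(rep(c(3, 1, 2, 5), 4), 4, 4,
              dimnames = list(letters[1:4], sprintf("s%d", 1:4)))
  de <- differential_expression(rank_normalize(m), c("a", "a", "b", "b"))
  expect_equal(de$log2_fc, rep(0, 4))
  expect_equal(de$p, rep(1, 4))
  expect_false(any(de$significant))
  expect_error(differential_expression(rank_normalize(m),
                                       c("a", "b", "b", "b")),
               "at least two")
})

test_that("padj is the BH step-up and respects its invariants", {
  # hand-computed: [0.01, 0.02, 0.03, 0.04] with m = 4 -> all 0.04
  expect_equal(oracle_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(6)
  m <- matrix(rlnorm(400), 50, 8,
              dimnames = list(sprintf("g%d", 1:50), sprintf("s%d", 1:8)))
  de <- differential_expression(rank_normalize(m), rep(c("a", "b"), each = 4))
  expect_equal(de$padj, oracle_bh(de$p))
  expect_true(all(de$padj >= de$p - 1e-12))
  o <- order(de$p)
  expect_true(all(diff(de$padj[o]) >= -1e-12))
})

test_that("GSEA scores perfect, null and small sets correctly", {
  set.seed(8)
  scores <- setNames(sort(rnorm(40), decreasing = TRUE),
                     sprintf("g%02d", 1:40))
  # set = exactly the top 5, unweighted: es = 1
  top <- gsea_preranked(scores, list(TOP = names(scores)[1:5]),
                        weight_p = 0, n_perm = 100, seed = 1)
  expect_equal(top$es, 1)
  # set spread uniformly: small |es|, non-significant permutation p
  unif <- gsea_preranked(scores, list(U = names(scores)[seq(2, 40, 4)]),
                         n_perm = 1000, seed = 1)
  expect_lt(abs(unif$es), 0.5)
  expect_gt(unif$perm_p, 0.5)
  # a 3-gene set in a 10-gene ranking equals the literal running-sum walk
  s10 <- setNames(c(5, 4, 3, 2.5, 2, 1.5, 1, 0.8, 0.5, 0.1),
                  sprintf("h%d", 1:10))
  set3 <- c("h2", "h5", "h9")
  r <- gsea_preranked(s10, list(S = set3), n_perm = 50, seed = 2)
  expect_equal(r$es, oracle_gsea_es(names(s10), s10, set3, 1),
               tolerance = 1e-12)
  # sets below the size floor are skipped with a warning
  expect_warning(
    none <- gsea_preranked(s10, list(TINY = "h1"), n_perm = 10, seed = 1),
    "skipped")
  expect_equal(nrow(none), 0)
  expect_error(gsea_preranked(c(a = 1, b = Inf), list(S = c("a", "b"))),
               "finite")
})

test_that("unweighted ES of a set and its complement oppose in sign", {
  set.seed(9)
  scores <- setNames(rnorm(30), sprintf("g%02d", 1:30))
  for (rep in 1:20) {
    set <- sample(names(scores), sample(3:15, 1))
    comp <- setdiff(names(scores), set)
    ord <- order(scores, decreasing = TRUE)
    es_set <- oracle_gsea_es(names(scores)[ord], scores[ord], set, 0)
    es_comp <- oracle_gsea_es(names(scores)[ord], scores[ord], comp, 0)
    expect_equal(es_set, -es_comp, tolerance = 1e-12)
    # the package ES agrees with the oracle on both
    r <- gsea_preranked(scores, list(A = set, B = comp), weight_p = 0,
                        n_perm = 10, seed = rep)
    expect_equal(r$es, c(es_set, es_comp), tolerance = 1e-12)
  }
})

test_that("ES agrees with the independent fgsea implementation", {
  skip_if_not_installed("fgsea")
  set.seed(10)
  scores <- setNames(rnorm(100), sprintf("g%03d", 1:100))
  sets <- list(S1 = sample(names(scores), 10),
               S2 = sample(names(scores), 25))
  r <- gsea_preranked(scores, sets, weight_p = 1, n_perm = 10, seed = 1)
  f <- suppressWarnings(fgsea::fgsea(sets, scores, nperm = 100))
  expect_equal(r$es, f$ES[match(r$set, f$pathway)], tolerance = 1e-9)
})

test_that("planted regulation is recovered on the synthetic matrix", {
  dir <- withr::local_tempdir()
  b <- simulate_cohort(sim_config(seed = 42), dir)
  expr <- read_expression(b$manifest$expression)
  grp <- read_groups(b$manifest$expr_groups)
  grp <- grp[match(colnames(expr), grp$sample_id), ]
  de <- differential_expression(rank_normalize(expr), grp$group,
                                group_order = c("tumor", "control"))
  planted <- b$truth$de$gene
  detected <- de$gene[de$padj < 0.05]
  expect_gte(mean(planted %in% detected), 0.9)
  null_genes <- setdiff(de$gene, planted)
  expect_lte(mean(null_genes %in% detected), 0.05)
  # planted directions match the sign of the fitted fold change
  sub <- de[match(planted, de$gene), ]
  hit <- planted %in% detected
  expect_true(all(sign(sub$log2_fc[hit]) ==
                    ifelse(b$truth$de$direction[hit] == "up", 1, -1)))
})
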