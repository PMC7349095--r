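test_that("somatic Fisher p matches identity, symmetry and oracle cases", {
  # no alt reads anywhere: only one table possible
  expect_equal(somatic_fisher_p(30, 0, 30, 0), 1.0)
  # symmetric table: one-sided p well above 0.5
  expect_gt(somatic_fisher_p(10, 10, 10, 10), 0.5)
  # enriched-tumor table against the exhaustive hypergeometric oracle
  expect_equal(somatic_fisher_p(15, 15, 30, 0),
               oracle_fisher_p(15, 15, 30, 0), tolerance = 1e-12)
  # spot-check random tables against the oracle and against fisher.test
  set.seed(7)
  for (rep in 1:50) {
    tr <- sample(0:25, 1); ta <- sample(0:25, 1)
    nr <- sample(0:25, 1); na_ <- sample(0:25, 1)
    if (tr + ta == 0 || nr + na_ == 0) next
    p <- somatic_fisher_p(tr, ta, nr, na_)
    expect_equal(p, oracle_fisher_p(tr, ta, nr, na_), tolerance = 1e-12)
    ft <- fisher.test(matrix(c(ta, tr, na_, nr), 2, byrow = TRUE),
                      alternative = "greater")
    expect_equal(p, ft$p.value, tolerance = 1e-9)
  }
  expect_error(somatic_fisher_p(0, 0, 10, 0), "at least one")
  expect_error(somatic_fisher_p(-1, 2, 3, 4), "non-negative")
})

test_that("increasing tumor alt reads never increases the somatic p", {
  set.seed(11)
  for (rep in 1:30) {
    tr <- sample(1:30, 1); nr <- sample(1:30, 1); na_ <- sample(0:5, 1)
    p <- somatic_fisher_p(tr, 0:20, nr, na_)
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("tier-1 somatic-only calls respect every threshold edge", {
  v <- make_variants(3)
  v$tumor_ref <- c(10, 20, 0); v$tumor_alt <- c(10, 1, 5)
  v$normal_ref <- c(30, 30, 30); v$normal_alt <- c(0, 0, 0)
  calls <- call_tier1_somatic(v)
  # clear somatic
  expect_equal(calls$tier[1], "somatic_only")
  # VAF 1/21 = 0.048 fails the 0.10 floor
  expect_equal(calls$tier[2], "none")
  # tumor depth 5 fails the 6x floor even at VAF 1
  expect_equal(calls$tier[3], "none")

  # normal germline evidence excludes somatic-only status
  g <- make_variants(1)
  g$tumor_ref <- 10; g$tumor_alt <- 40
  g$normal_ref <- 25; g$normal_alt <- 25
  expect_equal(call_tier1_somatic(g)$tier, "none")
  # thresholds are configurable
  expect_equal(call_tier1_somatic(g, max_normal_vaf = 0.6)$tier,
               "somatic_only")
})

test_that("tier-2 LOH-related calls need higher tumor VAF, small p and coding", {
  v <- make_variants(3)
  v$tumor_ref <- c(8, 48, 8); v$tumor_alt <- c(72, 32, 72)     # VAF .9, .4, .9
  v$normal_ref <- c(40, 40, 40); v$normal_alt <- c(40, 40, 40) # VAF .5
  v$coding <- c(TRUE, TRUE, FALSE)
  calls <- call_tier2_loh(v)
  expect_equal(calls$tier, c("loh_related", "none", "none"))
  expect_lt(calls$somatic_p[1], 0.001)

  # combined tiers: somatic-only takes precedence
  both <- make_variants(1)
  both$tumor_ref <- 5; both$tumor_alt <- 45
  both$normal_ref <- 50; both$normal_alt <- 0
  both$coding <- TRUE
  expect_equal(call_variant_tiers(both)$tier, "somatic_only")
})

test_that("polymorphism and damaging-or-unknown flags follow pop AF and prediction", {
  v <- make_variants(3)
  v$pop_af <- c(0.02, NA, 0.005)
  v$prediction <- c("benign", "unknown", "probably_damaging")
  f <- flag_variants(call_tier1_somatic(v))
  expect_equal(f$polymorphism_flag, c(TRUE, FALSE, FALSE))
  expect_equal(f$damaging_or_unknown_flag, c(FALSE, TRUE, TRUE))
})

test_that("recurrence respects the ceiling rule and is order/case invariant", {
  calls <- data.frame(
    sample = c("s1", "s2", "s3", "s4", "s5", "s6", "s1", "s2"),
    gene = c("g", "G", "g", "H", "h", "x", "X", "x"),
    tier = c(rep("somatic_only", 3), "loh_related", "loh_related",
             "somatic_only", "loh_related", "none"),
    stringsAsFactors = FALSE)
  r <- recurrence_matrix(calls, samples = paste0("s", 1:6))
  # G altered in 3/6 = boundary ceil(0.5*6)=3 -> recurrent
  expect_true("G" %in% r$recurrent$gene)
  # H altered in 2/6 -> not recurrent
  expect_false("H" %in% r$recurrent$gene)
  # X: tier none does not count; altered in 1 sample only
  expect_false("X" %in% r$recurrent$gene)
  # most severe tier recorded per cell
  expect_equal(unname(r$matrix["X", "s1"]), "loh_related")

  # sample order and gene case never change the recurrent list
  perm <- calls[sample(nrow(calls)), ]
  perm$gene <- tolower(perm$gene)
  r2 <- recurrence_matrix(perm, samples = paste0("s", 1:6))
  expect_equal(r2$recurrent, r$recurrent)

  # degenerate cohort: 1 sample, 1 altered gene is recurrent (1 >= 1)
  r3 <- recurrence_matrix(calls[1, ], samples = "s1")
  expect_equal(r3$recurrent$gene, "G")

  # no qualifying variants: empty matrix and list, not an error
  none <- calls[calls$tier == "none", , drop = FALSE]
  r4 <- recurrence_matrix(none, samples = paste0("s", 1:6))
  expect_equal(nrow(r4$recurrent), 0)
  expect_equal(nrow(r4$matrix), 0)
})

test_that("TMB counts non-synonymous somatic-only calls over callable Mb", {
  cov <- data.frame(chrom = "19", start = 1, end = 2e6,
                    tumor_depth = 50, normal_depth = 50)
  calls <- make_variants(10)
  calls$pos <- seq(1e5, 1e6, length.out = 10)
  calls$tier <- "somatic_only"
  calls$effect <- rep(c("missense", "frameshift"), 5)
  r <- compute_tmb(calls, cov)
  expect_equal(r$tmb, 10 / 2.0)
  expect_equal(r$n_mutations, 10L)

  # doubling callable Mb with the variant set fixed halves TMB
  cov2 <- rbind(cov, data.frame(chrom = "19", start = 2e6 + 1, end = 4e6,
                                tumor_depth = 50, normal_depth = 50))
  expect_equal(compute_tmb(calls, cov2)$tmb, r$tmb / 2)

  # synonymous and non-somatic calls never count
  calls$effect <- "synonymous"
  expect_equal(compute_tmb(calls, cov)$n_mutations, 0L)
  calls$effect <- "missense"; calls$tier <- "loh_related"
  expect_equal(compute_tmb(calls, cov)$n_mutations, 0L)

  # low-coverage intervals leave the denominator
  cov$tumor_depth <- 5
  expect_error(compute_tmb(calls, cov), "callable region too small")
})

test_that("pooling two group means reproduces the cohort mean", {
  tmb <- c(4.98, 4.98, 4.98, 5.87, 5.87, 5.87)
  groups <- rep(c("exposed", "naive"), each = 3)
  r <- suppressWarnings(compare_group_tmb(tmb, groups))
  expect_equal(unname(r$means), c(4.98, 5.87))
  expect_equal(round(mean(tmb), 2), 5.43)
})

test_that("group TMB comparison matches the closed-form Welch computation", {
  set.seed(21)
  for (rep in 1:20) {
    a <- rnorm(3, 5, 1); b <- rnorm(3, 5.5, 1)
    r <- compare_group_tmb(c(a, b), rep(c("g1", "g2"), each = 3))
    expect_equal(r$p, oracle_welch_p(a, b), tolerance = 1e-10)
  }
  # identical groups: p = 1
  expect_warning(r0 <- compare_group_tmb(rep(5, 6), rep(c("a", "b"), 3)),
                 "zero variance")
  expect_equal(r0$p, 1)
  # distinct zero-variance groups: p = 0 with a warning
  expect_warning(r1 <- compare_group_tmb(c(1, 1, 1, 9, 9, 9),
                                         rep(c("a", "b"), each = 3)),
                 "zero variance")
  expect_equal(r1$p, 0)
  expect_error(compare_group_tmb(c(1, 2, 3), c("a", "a", "b")),
               "at least two")
})
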