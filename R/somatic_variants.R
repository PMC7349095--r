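# Two-tier somatic/LOH variant classification, Fisher's exact somatic
# p-value, polymorphism and functional-prediction flagging, gene-level
# recurrence and tumor mutation burden.

#' One-sided Fisher exact somatic p-value
#'
#' Tests enrichment of alt-supporting reads in the tumor relative to the
#' matched normal on the 2x2 table `[[tumor_alt, tumor_ref], [normal_alt,
#' normal_ref]]`. The one-sided p is the hypergeometric upper tail of the
#' observed `tumor_alt` given the table margins (the convention used by
#' tumor-normal callers such as VarScan). Vectorized over all arguments.
#'
#' @param tumor_ref,tumor_alt,normal_ref,normal_alt non-negative read counts.
#' @return p-value(s) in `(0, 1]`.
#' @examples
#' somatic_fisher_p(30, 0, 30, 0)   # no alt reads anywhere -> 1
#' somatic_fisher_p(10, 30, 39, 1)  # strong tumor enrichment -> small p
#' @export
somatic_fisher_p <- function(tumor_ref, tumor_alt, normal_ref, normal_alt) {
  counts <- cbind(tumor_ref, tumor_alt, normal_ref, normal_alt)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  td <- tumor_ref + tumor_alt
  nd <- normal_ref + normal_alt
  if (any(td == 0 | nd == 0)) {
    stop("need at least one tumor read and one normal read", call. = FALSE)
  }
  m <- tumor_alt + normal_alt  # alt reads (white balls)
  n <- tumor_ref + normal_ref  # ref reads (black balls)
  stats::phyper(tumor_alt - 1, m, n, td, lower.tail = FALSE)
}

tier_frame <- function(variants) {
  td <- variants$tumor_ref + variants$tumor_alt
  nd <- variants$normal_ref + variants$normal_alt
  if (any(td == 0)) {
    stop("tier evaluation needs tumor_ref + tumor_alt > 0 for every variant",
         call. = FALSE)
  }
  out <- variants
  out$tumor_vaf <- variants$tumor_alt / td
  out$normal_vaf <- ifelse(nd > 0, variants$normal_alt / nd, NA_real_)
  out$somatic_p <- NA_real_
  ok <- nd > 0
  if (any(ok)) {
    out$somatic_p[ok] <- somatic_fisher_p(
      variants$tumor_ref[ok], variants$tumor_alt[ok],
      variants$normal_ref[ok], variants$normal_alt[ok])
  }
  out
}

#' Tier-1 ("somatic-only") variant calls
#'
#' A variant is somatic-only when the tumor depth, matched-normal depth and
#' tumor allele fraction clear their minima, the one-sided Fisher somatic p
#' is below `max_somatic_p`, and the normal allele fraction shows no
#' germline evidence (below `max_normal_vaf`).
#'
#' @param variants variant data.frame (see [read_variant_table()]).
#' @param min_tumor_depth minimum tumor read depth (default 6).
#' @param min_normal_depth minimum matched-normal read depth (default 8).
#' @param min_tumor_vaf minimum tumor allele fraction (default 0.10).
#' @param max_somatic_p somatic p-value cut-off (default 0.05).
#' @param max_normal_vaf normal allele fraction ceiling for "somatic-only"
#'   status (default 0.05).
#' @return the input with `tumor_vaf`, `normal_vaf`, `somatic_p` and a
#'   `tier` column (`"somatic_only"` or `"none"`).
#' @export
call_tier1_somatic <- function(variants, min_tumor_depth = 6,
                               min_normal_depth = 8, min_tumor_vaf = 0.10,
                               max_somatic_p = 0.05, max_normal_vaf = 0.05) {
  out <- tier_frame(variants)
  td <- variants$tumor_ref + variants$tumor_alt
  nd <- variants$normal_ref + variants$normal_alt
  pass <- td >= min_tumor_depth & nd >= min_normal_depth &
    out$tumor_vaf >= min_tumor_vaf &
    !is.na(out$somatic_p) & out$somatic_p < max_somatic_p &
    !is.na(out$normal_vaf) & out$normal_vaf < max_normal_vaf
  out$tier <- ifelse(pass, "somatic_only", "none")
  out
}

#' Tier-2 ("LOH-related") variant calls
#'
#' Recovers alterations attributable to loss of heterozygosity: tumor allele
#' fraction strictly higher than in the normal, somatic p-value below
#' `max_somatic_p` (default 0.001), and location in a coding region.
#'
#' @inheritParams call_tier1_somatic
#' @param max_somatic_p somatic p-value cut-off (default 0.001).
#' @return the input with `tumor_vaf`, `normal_vaf`, `somatic_p` and `tier`
#'   (`"loh_related"` or `"none"`).
#' @export
call_tier2_loh <- function(variants, max_somatic_p = 0.001) {
  out <- tier_frame(variants)
  pass <- !is.na(out$normal_vaf) & out$tumor_vaf > out$normal_vaf &
    !is.na(out$somatic_p) & out$somatic_p < max_somatic_p &
    !is.na(out$coding) & out$coding
  out$tier <- ifelse(pass, "loh_related", "none")
  out
}

#' Combined two-tier classification with flags
#'
#' Runs both tiers and resolves the final tier per variant (somatic-only
#' takes precedence over LOH-related), then adds the polymorphism and
#' damaging-or-unknown follow-up flags via [flag_variants()].
#'
#' @inheritParams call_tier1_somatic
#' @param tier1_max_p,tier2_max_p somatic p-value cut-offs for the two tiers.
#' @return tier-call data.frame with `tier` in
#'   `{"somatic_only","loh_related","none"}` and flag columns.
#' @export
call_variant_tiers <- function(variants, min_tumor_depth = 6,
                               min_normal_depth = 8, min_tumor_vaf = 0.10,
                               tier1_max_p = 0.05, tier2_max_p = 0.001,
                               max_normal_vaf = 0.05) {
  t1 <- call_tier1_somatic(variants, min_tumor_depth, min_normal_depth,
                           min_tumor_vaf, tier1_max_p, max_normal_vaf)
  t2 <- call_tier2_loh(variants, tier2_max_p)
  t1$tier <- ifelse(t1$tier == "somatic_only", "somatic_only",
                    ifelse(t2$tier == "loh_related", "loh_related", "none"))
  flag_variants(t1)
}

#' Polymorphism and functional-prediction flags
#'
#' `polymorphism_flag` marks known polymorphisms (population allele
#' frequency known and at least 1 percent). `damaging_or_unknown_flag`
#' marks variants worth follow-up: functional prediction possibly or
#' probably damaging, or no prediction available, and not a polymorphism.
#'
#' @param calls tier-call data.frame with `pop_af` and `prediction`.
#' @param polymorphism_af population allele frequency cut-off (default 0.01).
#' @return `calls` with the two logical flag columns added.
#' @export
flag_variants <- function(calls, polymorphism_af = 0.01) {
  calls$polymorphism_flag <- !is.na(calls$pop_af) &
    calls$pop_af >= polymorphism_af
  calls$damaging_or_unknown_flag <-
    calls$prediction %in% c("possibly_damaging", "probably_damaging",
                            "unknown") & !calls$polymorphism_flag
  calls
}

#' Gene-by-sample alteration matrix and recurrently altered genes
#'
#' A gene counts as altered in a sample when any of its variants carries a
#' qualifying tier; the matrix cell records the most severe tier
#' (somatic-only over LOH-related). A gene is recurrently altered when it is
#' altered in at least `ceiling(min_fraction * n_samples)` samples. Gene
#' symbols are case-normalized (upper case) for counting.
#'
#' @param calls tier-call data.frame with a `sample` column.
#' @param samples optional full cohort sample ids (defaults to those present
#'   in `calls`); samples with no qualifying variants still count in the
#'   denominator.
#' @param min_fraction recurrence fraction (default 0.5).
#' @return list with `matrix` (gene x sample character matrix, `""` for not
#'   altered) and `recurrent` (data.frame `gene`, `n_altered`, `frequency`,
#'   sorted by frequency then gene).
#' @export
recurrence_matrix <- function(calls, samples = NULL, min_fraction = 0.5) {
  if (is.null(samples)) samples <- unique(calls$sample)
  if (!length(samples)) stop("need at least one sample", call. = FALSE)
  samples <- as.character(sort(samples))
  keep <- calls$tier %in% c("somatic_only", "loh_related") &
    !is.na(calls$gene) & calls$gene != "unknown"
  calls <- calls[keep, , drop = FALSE]
  genes <- sort(unique(toupper(calls$gene)))
  mat <- matrix("", nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  if (nrow(calls)) {
    sev <- function(tiers) {
      if ("somatic_only" %in% tiers) "somatic_only" else "loh_related"
    }
    agg <- tapply(calls$tier,
                  list(toupper(calls$gene), as.character(calls$sample)), sev)
    agg_genes <- rownames(agg)
    for (s in intersect(colnames(agg), samples)) {
      vals <- agg[, s]
      hit <- !is.na(vals)
      mat[agg_genes[hit], s] <- vals[hit]
    }
  }
  n_alt <- rowSums(mat != "")
  need <- ceiling(min_fraction * length(samples))
  rec <- data.frame(gene = genes, n_altered = as.integer(n_alt),
                    frequency = n_alt / length(samples),
                    stringsAsFactors = FALSE, row.names = NULL)
  rec <- rec[rec$n_altered >= need, , drop = FALSE]
  rec <- rec[order(-rec$frequency, rec$gene), , drop = FALSE]
  rownames(rec) <- NULL
  list(matrix = mat, recurrent = rec)
}

#' Tumor mutation burden over the callable coding region
#'
#' Counts non-synonymous somatic-only variants (see
#' [nonsynonymous_effects()]) falling inside the callable region, divided by
#' the callable length in megabases. Callable means coding intervals with
#' tumor depth and matched-normal depth at or above their minima.
#'
#' @param calls tier-call data.frame for one sample.
#' @param coverage coverage data.frame with `chrom`, `start`, `end`,
#'   `tumor_depth`, `normal_depth` (coding regions, non-overlapping).
#' @param min_tumor_depth,min_normal_depth callable-region depth cut-offs
#'   (defaults 6 and 8).
#' @param min_callable_mb minimum callable size (default 0.1 Mb); below this
#'   the estimate is refused.
#' @return list with `tmb` (mutations per Mb), `n_mutations` and
#'   `callable_mb`.
#' @export
compute_tmb <- function(calls, coverage, min_tumor_depth = 6,
                        min_normal_depth = 8, min_callable_mb = 0.1) {
  validate_intervals(coverage, what = "coverage")
  callable <- coverage[coverage$tumor_depth >= min_tumor_depth &
                         coverage$normal_depth >= min_normal_depth, ,
                       drop = FALSE]
  callable_mb <- sum(interval_width(callable)) / 1e6
  if (callable_mb < min_callable_mb) {
    stop(sprintf("callable region too small for TMB: %.4f Mb (need >= %.1f)",
                 callable_mb, min_callable_mb), call. = FALSE)
  }
  qual <- calls$tier == "somatic_only" & calls$effect %in% .nonsyn_effects
  qual <- qual & points_in_intervals(calls$chrom, calls$pos, callable)
  n <- sum(qual)
  list(tmb = n / callable_mb, n_mutations = as.integer(n),
       callable_mb = callable_mb)
}

#' Compare mutation burden between two groups
#'
#' Unpaired t-test on per-sample TMB values (Welch by default; pooled
#' variance with `var_equal = TRUE`). When both groups have zero variance
#' the test degenerates: p = 1 if the means are equal, p = 0 otherwise,
#' with a warning.
#'
#' @param tmb numeric per-sample TMB values.
#' @param groups group label per sample (exactly two distinct labels, each
#'   with n >= 2).
#' @param var_equal use the pooled-variance t-test.
#' @return list with `means` (named per group), `t`, `df`, `p`.
#' @export
compare_group_tmb <- function(tmb, groups, var_equal = FALSE) {
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  if (length(lv) != 2) stop("need exactly two groups", call. = FALSE)
  a <- tmb[groups == lv[1]]
  b <- tmb[groups == lv[2]]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least two samples", call. = FALSE)
  }
  means <- stats::setNames(c(mean(a), mean(b)), lv)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    warning("zero variance in both groups; degenerate t-test")
    p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    return(list(means = means, t = if (p == 1) 0 else Inf, df = NA_real_,
                p = p))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(means = means, t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
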