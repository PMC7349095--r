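# End-to-end orchestration: variants -> TMB -> LOH -> aCGH -> CN-LOH ->
# recurrence -> differential expression, with a machine-readable filter
# funnel log and graceful degradation for partial cohorts.

stage_try <- function(stage, context, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed (%s): %s", stage, context,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full cohort analysis
#'
#' Executes all stages in dependency order on the inputs listed in a
#' manifest: per-sample two-tier variant classification and mutation
#' burden, group comparison of TMB, LOH segmentation with cohort
#' common-region intersection, CBS segmentation of aCGH profiles with
#' noise-adaptive status calling, copy-neutral LOH integration, recurrent
#' gain analysis, and rank-normalized differential expression with GSEA.
#' Samples with missing aCGH input are kept: their LOH segments are
#' reported with copy-number state unknown (with a warning). Output is
#' deterministic for a fixed seed.
#'
#' @param manifest a manifest list (see [read_manifest()]) or path to a
#'   manifest file.
#' @param out_dir optional directory for TSV/SEG/BED result files.
#' @param seed integer seed used for all stochastic stages.
#' @param min_tumor_depth,min_normal_depth,min_tumor_vaf,tier1_max_p,tier2_max_p,max_normal_vaf
#'   variant-tier thresholds (see [call_variant_tiers()]).
#' @param recurrence_fraction recurrently-altered-gene fraction
#'   (default 0.5).
#' @param min_samples_common samples required to share the common LOH
#'   region; default is one less than the number of samples with variant
#'   data (at least 2).
#' @param loh_min_sites,loh_min_fraction,loh_max_gap_bp LOH segmentation
#'   parameters (see [segment_loh()]).
#' @param neutral_band copy-neutral log2-ratio band (see
#'   [integrate_cnloh()]).
#' @param cbs_alpha,cbs_n_perm,cbs_min_probes CBS parameters (see
#'   [cbs_segment()]).
#' @param status_k,status_min_abs noise-adaptive status parameters (see
#'   [call_status()]).
#' @param min_share,aberrant_threshold recurrent-gain parameters (see
#'   [recurrent_gains()]).
#' @param de_test per-gene test for differential expression.
#' @param gsea_n_perm,gsea_weight_p GSEA parameters.
#' @return report list: `samples`, `calls`, `tmb`, `tmb_group_test`,
#'   `recurrence`, `loh_segments`, `common_loh_region`, `cn_segments`,
#'   `noise`, `cnloh_calls`, `recurrent_gains`, `de`, `gsea`, `log`.
#' @export
run_all <- function(manifest, out_dir = NULL, seed = 1,
                    min_tumor_depth = 6, min_normal_depth = 8,
                    min_tumor_vaf = 0.10, tier1_max_p = 0.05,
                    tier2_max_p = 0.001, max_normal_vaf = 0.05,
                    recurrence_fraction = 0.5, min_samples_common = NULL,
                    loh_min_sites = 10, loh_min_fraction = 0.8,
                    loh_max_gap_bp = 2e6, neutral_band = 0.3,
                    cbs_alpha = 0.01, cbs_n_perm = 1000, cbs_min_probes = 3,
                    status_k = 3, status_min_abs = 0.2, min_share = 3,
                    aberrant_threshold = 1.0, de_test = "t",
                    gsea_n_perm = 1000, gsea_weight_p = 1) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stage_try("validate", "manifest", validate_manifest(manifest))
  s <- manifest$samples
  n <- nrow(s)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  log <- list()
  note <- function(stage, sample, metric, count) {
    log[[length(log) + 1L]] <<- data.frame(
      stage = stage, sample = sample, metric = metric, count = count,
      stringsAsFactors = FALSE)
  }

  all_calls <- list(); all_loh <- list(); all_cn <- list()
  tmb_rows <- list(); noise_rows <- list()
  for (i in seq_len(n)) {
    sid <- s$sample_id[i]
    has_var <- !is.na(s$variants[i]) && s$variants[i] != "."
    if (has_var) {
      variants <- stage_try("variants", sid,
                            read_variant_table(s$variants[i]))
      note("variants", sid, "input", nrow(variants))
      calls <- stage_try("variants", sid, call_variant_tiers(
        variants, min_tumor_depth, min_normal_depth, min_tumor_vaf,
        tier1_max_p, tier2_max_p, max_normal_vaf))
      calls$sample <- sid
      note("variants", sid, "tier1_somatic_only",
           sum(calls$tier == "somatic_only"))
      note("variants", sid, "tier2_loh_related",
           sum(calls$tier == "loh_related"))
      all_calls[[sid]] <- calls

      if (!is.na(s$coverage[i]) && s$coverage[i] != ".") {
        coverage <- stage_try("tmb", sid, read_bed(
          s$coverage[i], col_names = c("tumor_depth", "normal_depth")))
        tmb <- stage_try("tmb", sid, compute_tmb(
          calls, coverage, min_tumor_depth, min_normal_depth))
        tmb_rows[[sid]] <- data.frame(
          sample = sid, group = s$group[i], tmb = tmb$tmb,
          n_mutations = tmb$n_mutations, callable_mb = tmb$callable_mb,
          stringsAsFactors = FALSE)
        note("tmb", sid, "nonsyn_somatic_in_callable", tmb$n_mutations)
      }

      het <- stage_try("loh", sid, extract_het_sites(
        variants, min_normal_depth))
      note("loh", sid, "informative_het_sites", nrow(het))
      loh <- stage_try("loh", sid, segment_loh(
        het, loh_min_sites, loh_min_fraction, loh_max_gap_bp,
        sample = sid))
      note("loh", sid, "loh_segments", nrow(loh))
      if (nrow(loh)) all_loh[[sid]] <- loh
    }

    if (!is.na(s$probes[i]) && s$probes[i] != ".") {
      probes <- stage_try("cgh", sid, read_probes(s$probes[i]))
      sigma <- stage_try("cgh", sid, estimate_noise(probes))
      segs <- stage_try("cgh", sid, cbs_segment(
        probes, cbs_alpha, cbs_n_perm, cbs_min_probes,
        seed = seed + i, sample = sid))
      segs <- call_status(segs, sigma, status_k, status_min_abs)
      all_cn[[sid]] <- segs
      noise_rows[[sid]] <- data.frame(sample = sid, sigma = sigma,
                                      stringsAsFactors = FALSE)
      note("cgh", sid, "probes", nrow(probes))
      note("cgh", sid, "segments", nrow(segs))
    } else {
      warning(sprintf("no aCGH input for sample %s; copy-number state will be unknown",
                      sid))
    }
  }

  calls <- if (length(all_calls)) do.call(rbind, c(all_calls, list(make.row.names = FALSE))) else NULL
  loh_segments <- if (length(all_loh)) do.call(rbind, c(all_loh, list(make.row.names = FALSE))) else NULL
  cn_segments <- if (length(all_cn)) do.call(rbind, c(all_cn, list(make.row.names = FALSE))) else NULL
  tmb <- if (length(tmb_rows)) do.call(rbind, c(tmb_rows, list(make.row.names = FALSE))) else NULL
  noise <- if (length(noise_rows)) do.call(rbind, c(noise_rows, list(make.row.names = FALSE))) else NULL

  recurrence <- if (!is.null(calls)) {
    stage_try("recurrence", "cohort", recurrence_matrix(
      calls, samples = s$sample_id[!is.na(s$variants) & s$variants != "."],
      min_fraction = recurrence_fraction))
  }

  tmb_group_test <- NULL
  if (!is.null(tmb) && length(unique(tmb$group)) == 2 &&
      all(table(tmb$group) >= 2)) {
    tmb_group_test <- stage_try("tmb", "cohort",
                                compare_group_tmb(tmb$tmb, tmb$group))
  }

  common <- NULL
  if (!is.null(loh_segments)) {
    n_wes <- sum(!is.na(s$variants) & s$variants != ".")
    k <- if (is.null(min_samples_common)) max(2, n_wes - 1) else
      min_samples_common
    common <- stage_try("loh", "cohort",
                        common_loh_region(loh_segments, k))
  }

  cnloh_calls <- NULL
  if (!is.null(loh_segments)) {
    cnloh_calls <- stage_try("cnloh", "cohort", integrate_cnloh(
      loh_segments,
      if (is.null(cn_segments)) cn_segments_empty() else cn_segments,
      neutral_band))
  }

  gains <- NULL
  if (!is.null(cn_segments) && !is.na(manifest$genes)) {
    genes <- stage_try("cgh", "cohort",
                       read_bed(manifest$genes, col_names = "gene"))
    gains <- stage_try("cgh", "cohort", recurrent_gains(
      cn_segments, genes, min_share, aberrant_threshold))
  }

  de <- NULL; gsea <- NULL
  if (!is.na(manifest$expression) && !is.na(manifest$expr_groups)) {
    expr <- stage_try("de", "cohort", read_expression(manifest$expression))
    grp <- stage_try("de", "cohort", read_groups(manifest$expr_groups))
    grp <- grp[match(colnames(expr), grp$sample_id), ]
    if (any(is.na(grp$group))) {
      stop("stage 'de' failed (cohort): expression samples missing from groups file",
           call. = FALSE)
    }
    rn <- stage_try("de", "cohort", rank_normalize(expr))
    de <- stage_try("de", "cohort", differential_expression(
      rn, grp$group, group_order = rev(sort(unique(grp$group))),
      test = de_test))
    note("de", "cohort", "genes_tested", nrow(de))
    note("de", "cohort", "significant", sum(de$significant))
    if (!is.na(manifest$gene_sets)) {
      sets <- stage_try("de", "cohort", read_gene_sets(manifest$gene_sets))
      scores <- stats::setNames(
        -log10(pmax(de$p, 1e-300)) * sign(de$log2_fc), de$gene)
      gsea <- stage_try("de", "cohort", gsea_preranked(
        scores, sets, weight_p = gsea_weight_p, n_perm = gsea_n_perm,
        seed = seed + 10000L))
    }
  }

  report <- list(
    samples = s$sample_id, calls = calls, tmb = tmb,
    tmb_group_test = tmb_group_test, recurrence = recurrence,
    loh_segments = loh_segments, common_loh_region = common,
    cn_segments = cn_segments, noise = noise, cnloh_calls = cnloh_calls,
    recurrent_gains = gains, de = de, gsea = gsea,
    log = do.call(rbind, c(log, list(make.row.names = FALSE)))
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

cn_segments_empty <- function() {
  data.frame(sample = character(0), chrom = character(0),
             start = numeric(0), end = numeric(0), n_probes = integer(0),
             mean_log2 = numeric(0), stringsAsFactors = FALSE)
}

write_report <- function(report, out_dir) {
  wt <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(report$calls, "tiered_variants.tsv")
  wt(report$tmb, "tmb.tsv")
  if (!is.null(report$recurrence)) {
    m <- report$recurrence$matrix
    wt(data.frame(gene = rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE), "recurrence_matrix.tsv")
    wt(report$recurrence$recurrent, "recurrent_genes.tsv")
  }
  if (!is.null(report$loh_segments)) {
    write_bed(report$loh_segments[, c("chrom", "start", "end", "sample")],
              file.path(out_dir, "loh_segments.bed"))
  }
  if (!is.null(report$common_loh_region)) {
    write_bed(report$common_loh_region[, c("chrom", "start", "end")],
              file.path(out_dir, "common_loh_region.bed"))
  }
  if (!is.null(report$cn_segments)) {
    write_seg(report$cn_segments, file.path(out_dir, "segments.seg"))
  }
  wt(report$cnloh_calls, "cnloh_calls.tsv")
  wt(report$recurrent_gains, "recurrent_gains.tsv")
  wt(report$de, "de_results.tsv")
  wt(report$gsea, "gsea_results.tsv")
  wt(report$log, "run_log.tsv")
  invisible(out_dir)
}
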