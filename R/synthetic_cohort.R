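# Synthetic paired tumor-normal cohort generator with planted truth:
# germline het-SNP panel with binomial read sampling, a telomeric
# copy-neutral LOH block carried by most samples, sparse high-VAF somatic
# mutations, focal gains on aCGH probe profiles, and an expression matrix
# with planted up/down-regulated genes. Every emitted file uses the formats
# the pipeline reads, and every planted event is recorded in the truth set.

#' Simulation configuration
#'
#' Defaults emulate a small, genomically stable tumor cohort: six samples
#' on a single 100-Mb chromosome at 80x tumor/normal depth, a near-diploid
#' profile with one telomeric ~11-Mb copy-neutral LOH block carried by 5/6
#' samples, sparse non-synonymous somatic mutations at 5.5/Mb of coding
#' sequence (high allele fraction inside the CN-LOH block), three focal
#' gains (one at amplification level, log2 2.33) carried by subsets of
#' samples, and a 2000-gene expression matrix with 20 strongly up/down
#' regulated genes between a 6-sample tumor group and a 5-sample control
#' group.
#'
#' @param n_samples cohort size.
#' @param genome data.frame `chrom`, `length` (bp).
#' @param somatic_rate_per_mb expected non-synonymous somatic mutations per
#'   coding megabase.
#' @param cnloh_region planted copy-neutral LOH interval.
#' @param cnloh_fraction fraction of samples carrying the CN-LOH block.
#' @param cnloh_tumor_vaf tumor allele fraction of the retained allele at
#'   het sites inside the block (0.95 models residual normal reads).
#' @param somatic_vaf_inside,somatic_vaf_outside tumor allele fraction of
#'   somatic mutations inside/outside the CN-LOH block.
#' @param normal_site_error per-read error rate at somatic sites in the
#'   normal.
#' @param gains data.frame `chrom`, `start`, `end`, `log2_level`,
#'   `n_carriers` of planted copy-number gains.
#' @param probe_spacing_bp aCGH probe spacing.
#' @param probe_noise_sd Gaussian probe-level log2-ratio noise.
#' @param read_depth_tumor,read_depth_normal mean sequencing depths
#'   (Poisson-distributed per site).
#' @param het_snp_density_per_mb density of the cohort-shared germline
#'   heterozygous SNP panel.
#' @param purity tumor purity; below 1 tumor allele fractions are
#'   attenuated toward the germline expectation.
#' @param exon_width,exon_spacing coding-region model: one `exon_width`-bp
#'   coding block (one gene) every `exon_spacing` bp.
#' @param expr_n_genes,expr_n_de,expr_effect_size_sd expression matrix
#'   size, number of planted differentially expressed genes, and their
#'   shift in units of the between-gene baseline SD.
#' @param expr_group_sizes tumor/control group sizes (tumor group reuses
#'   the cohort samples).
#' @param expr_baseline_sd,expr_noise_sd between-gene and within-gene SDs
#'   of log expression.
#' @param seed mandatory RNG seed; the whole bundle is deterministic given
#'   the seed.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_samples = 6,
                       genome = data.frame(chrom = "19", length = 1e8,
                                           stringsAsFactors = FALSE),
                       somatic_rate_per_mb = 5.5,
                       cnloh_region = genomic_interval("19", 373916, 11465316),
                       cnloh_fraction = 5 / 6,
                       cnloh_tumor_vaf = 0.95,
                       somatic_vaf_inside = 0.88,
                       somatic_vaf_outside = 0.45,
                       normal_site_error = 0.001,
                       gains = data.frame(
                         chrom = "19",
                         start = c(50e6 + 1, 70e6 + 1, 85e6 + 1),
                         end = c(52e6, 71.5e6, 86e6),
                         log2_level = c(2.33, 1.5, 1.5),
                         n_carriers = c(3, 3, 2),
                         stringsAsFactors = FALSE),
                       probe_spacing_bp = 1e5,
                       probe_noise_sd = 0.1,
                       read_depth_tumor = 80,
                       read_depth_normal = 80,
                       het_snp_density_per_mb = 20,
                       purity = 1.0,
                       exon_width = 2000,
                       exon_spacing = 20000,
                       expr_n_genes = 2000,
                       expr_n_de = 20,
                       expr_effect_size_sd = 3,
                       expr_group_sizes = c(6, 5),
                       expr_baseline_sd = 1,
                       expr_noise_sd = 0.25,
                       seed = NULL) {
  if (is.null(seed)) stop("sim_config requires a seed", call. = FALSE)
  cfg <- as.list(environment())
  if (n_samples < 1 || somatic_rate_per_mb < 0 || probe_spacing_bp <= 0 ||
      probe_noise_sd < 0 || het_snp_density_per_mb <= 0 ||
      read_depth_tumor <= 0 || read_depth_normal <= 0 ||
      purity < 0 || purity > 1) {
    stop("invalid simulation configuration: rates and sizes must be positive",
         call. = FALSE)
  }
  glen <- stats::setNames(genome$length, normalize_chrom(genome$chrom))
  reg <- cnloh_region
  if (!(reg$chrom %in% names(glen)) || reg$end > glen[[reg$chrom]]) {
    stop("CN-LOH region falls outside the configured genome", call. = FALSE)
  }
  if (nrow(gains)) {
    gains$chrom <- normalize_chrom(gains$chrom)
    if (any(!(gains$chrom %in% names(glen))) ||
        any(gains$end > glen[gains$chrom])) {
      stop("a planted gain falls outside the configured genome",
           call. = FALSE)
    }
    if (any(gains$n_carriers > n_samples)) {
      stop("gain carriers exceed cohort size", call. = FALSE)
    }
  }
  cfg$genome$chrom <- normalize_chrom(cfg$genome$chrom)
  cfg$gains <- gains
  class(cfg) <- "sim_config"
  cfg
}

coding_blocks <- function(cfg) {
  out <- list()
  for (i in seq_len(nrow(cfg$genome))) {
    ch <- cfg$genome$chrom[i]
    starts <- seq(1, cfg$genome$length[i] - cfg$exon_width + 1,
                  by = cfg$exon_spacing)
    out[[i]] <- data.frame(
      chrom = ch, start = starts, end = starts + cfg$exon_width - 1,
      stringsAsFactors = FALSE)
  }
  blocks <- do.call(rbind, out)
  blocks$gene <- sprintf("CG%05d", seq_len(nrow(blocks)))
  blocks
}

block_gene <- function(chrom, pos, blocks) {
  gene <- rep("unknown", length(pos))
  for (ch in unique(blocks$chrom)) {
    b <- blocks[blocks$chrom == ch, , drop = FALSE]
    idx <- which(chrom == ch)
    if (!length(idx)) next
    j <- findInterval(pos[idx], b$start)
    inside <- j >= 1 & pos[idx] <= b$end[pmax(j, 1)]
    gene[idx[inside]] <- b$gene[j[inside]]
  }
  gene
}

#' Simulate a complete cohort with planted truth
#'
#' Writes per-sample variant tables (germline het-SNP panel plus planted
#' somatic mutations, with binomially sampled read counts), coverage BEDs
#' over the coding blocks, aCGH probe tables, a cohort expression matrix
#' with group labels, gene sets, a gene-annotation BED and a manifest to
#' `out_dir`, and returns the machine-readable truth set. Deterministic
#' (byte-identical output) for a fixed seed.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return list with `manifest` (parsed manifest), `manifest_path`,
#'   `truth` (planted CN-LOH region and carriers, somatic variants, gain
#'   carriers and genes, DE genes with directions) and `out_dir`.
#' @export
simulate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  samples <- sprintf("S%02d", seq_len(cfg$n_samples))
  chemo <- rep("chemo_naive", cfg$n_samples)
  chemo[seq_len(cfg$n_samples) > ceiling(cfg$n_samples / 2)] <- "chemo_exposed"
  blocks <- coding_blocks(cfg)
  bases <- c("A", "C", "G", "T")

  n_carry <- round(cfg$cnloh_fraction * cfg$n_samples)
  carriers <- sort(sample(samples, n_carry))
  gain_carriers <- lapply(seq_len(nrow(cfg$gains)), function(g) {
    sort(sample(samples, cfg$gains$n_carriers[g]))
  })

  # gene annotation for the copy-number recurrence analysis: two genes per
  # planted gain locus plus null genes drawn from the coding blocks
  gain_genes <- do.call(rbind, lapply(seq_len(nrow(cfg$gains)), function(g) {
    w <- cfg$gains$end[g] - cfg$gains$start[g] + 1
    s <- cfg$gains$start[g] + round(c(0.2, 0.7) * w)
    data.frame(chrom = cfg$gains$chrom[g], start = s,
               end = pmin(s + 49999, cfg$gains$end[g]),
               gene = sprintf("GG%d%s", g, c("A", "B")),
               log2_level = cfg$gains$log2_level[g],
               n_carriers = cfg$gains$n_carriers[g],
               stringsAsFactors = FALSE)
  }))
  in_gain <- rep(FALSE, nrow(blocks))
  for (g in seq_len(nrow(cfg$gains))) {
    in_gain <- in_gain | (blocks$chrom == cfg$gains$chrom[g] &
                            blocks$start <= cfg$gains$end[g] &
                            blocks$end >= cfg$gains$start[g])
  }
  null_pool <- blocks[!in_gain, , drop = FALSE]
  null_genes <- null_pool[sort(sample.int(nrow(null_pool), 30)),
                          c("chrom", "start", "end", "gene")]
  genes_bed <- rbind(gain_genes[, c("chrom", "start", "end", "gene")],
                     null_genes)
  genes_bed <- genes_bed[order(genes_bed$chrom, genes_bed$start), ]
  genes_path <- file.path(out_dir, "genes.bed")
  write_bed(genes_bed, genes_path)

  # cohort-shared germline het SNP panel
  total_mb <- sum(cfg$genome$length) / 1e6
  panel <- do.call(rbind, lapply(seq_len(nrow(cfg$genome)), function(i) {
    n_het <- round(cfg$het_snp_density_per_mb * cfg$genome$length[i] / 1e6)
    pos <- sort(sample.int(cfg$genome$length[i], n_het))
    data.frame(chrom = cfg$genome$chrom[i], pos = pos,
               stringsAsFactors = FALSE)
  }))
  n_panel <- nrow(panel)
  panel$ref <- sample(bases, n_panel, replace = TRUE)
  panel$alt <- vapply(panel$ref, function(r) sample(setdiff(bases, r), 1), "")
  known <- stats::runif(n_panel) < 0.85
  panel$pop_af <- ifelse(known, round(stats::runif(n_panel, 0.01, 0.5), 4),
                         NA_real_)
  panel$prediction <- sample(c("benign", "unknown", "possibly_damaging"),
                             n_panel, replace = TRUE,
                             prob = c(0.8, 0.15, 0.05))
  panel$gene <- block_gene(panel$chrom, panel$pos, blocks)
  panel$coding <- panel$gene != "unknown"
  in_region <- panel$chrom == cfg$cnloh_region$chrom &
    panel$pos >= cfg$cnloh_region$start & panel$pos <= cfg$cnloh_region$end

  coding_mb <- sum(interval_width(blocks)) / 1e6
  effects <- c("missense", "stop_gain", "stop_loss", "frameshift",
               "inframe_indel", "splice")
  eff_prob <- c(0.62, 0.12, 0.02, 0.12, 0.04, 0.08)

  sample_files <- data.frame(sample_id = samples, variants = "",
                             coverage = "", probes = "", group = chemo,
                             stringsAsFactors = FALSE)
  truth_somatic <- list()

  for (si in seq_along(samples)) {
    sid <- samples[si]
    is_carrier <- sid %in% carriers

    # germline het panel read counts
    nd <- pmax(1L, stats::rpois(n_panel, cfg$read_depth_normal))
    td <- pmax(1L, stats::rpois(n_panel, cfg$read_depth_tumor))
    p_t <- rep(0.5, n_panel)
    if (is_carrier) {
      flip <- sample(c(TRUE, FALSE), n_panel, replace = TRUE)
      p_loh <- ifelse(flip, cfg$cnloh_tumor_vaf, 1 - cfg$cnloh_tumor_vaf)
      p_t[in_region] <- (cfg$purity * p_loh +
                           (1 - cfg$purity) * 0.5)[in_region]
    }
    het <- data.frame(
      chrom = panel$chrom, pos = panel$pos, ref = panel$ref,
      alt = panel$alt,
      tumor_ref = 0L, tumor_alt = stats::rbinom(n_panel, td, p_t),
      normal_ref = 0L, normal_alt = stats::rbinom(n_panel, nd, 0.5),
      gene = panel$gene, effect = "other", coding = panel$coding,
      pop_af = panel$pop_af, prediction = panel$prediction,
      stringsAsFactors = FALSE)
    het$tumor_ref <- td - het$tumor_alt
    het$normal_ref <- nd - het$normal_alt

    # planted somatic mutations in coding blocks
    n_som <- stats::rpois(1, cfg$somatic_rate_per_mb * coding_mb)
    som <- NULL
    if (n_som > 0) {
      bi <- sample.int(nrow(blocks), n_som, replace = TRUE)
      pos <- blocks$start[bi] +
        sample.int(cfg$exon_width, n_som, replace = TRUE) - 1
      chrom <- blocks$chrom[bi]
      inside <- is_carrier & chrom == cfg$cnloh_region$chrom &
        pos >= cfg$cnloh_region$start & pos <= cfg$cnloh_region$end
      vaf <- ifelse(inside, cfg$somatic_vaf_inside,
                    cfg$somatic_vaf_outside) * cfg$purity
      std <- pmax(1L, stats::rpois(n_som, cfg$read_depth_tumor))
      snd <- pmax(1L, stats::rpois(n_som, cfg$read_depth_normal))
      ta <- stats::rbinom(n_som, std, vaf)
      na <- stats::rbinom(n_som, snd, cfg$normal_site_error)
      ref <- sample(bases, n_som, replace = TRUE)
      som <- data.frame(
        chrom = chrom, pos = pos, ref = ref,
        alt = vapply(ref, function(r) sample(setdiff(bases, r), 1), ""),
        tumor_ref = std - ta, tumor_alt = ta,
        normal_ref = snd - na, normal_alt = na,
        gene = blocks$gene[bi],
        effect = sample(effects, n_som, replace = TRUE, prob = eff_prob),
        coding = TRUE, pop_af = NA_real_,
        prediction = sample(c("probably_damaging", "possibly_damaging",
                              "benign", "unknown"), n_som, replace = TRUE,
                            prob = c(0.3, 0.2, 0.3, 0.2)),
        stringsAsFactors = FALSE)
      truth_somatic[[sid]] <- data.frame(
        sample = sid, chrom = chrom, pos = pos, gene = blocks$gene[bi],
        effect = som$effect, vaf = vaf, stringsAsFactors = FALSE)
    }
    vt <- rbind(het, som)
    vt <- vt[order(vt$chrom, vt$pos), , drop = FALSE]
    vpath <- file.path(out_dir, sprintf("%s.variants.tsv", sid))
    write_variant_table(vt, vpath)

    # coverage over coding blocks
    cov <- blocks[, c("chrom", "start", "end")]
    cov$tumor_depth <- pmax(0, round(stats::rnorm(
      nrow(blocks), cfg$read_depth_tumor, cfg$read_depth_tumor / 10)))
    cov$normal_depth <- pmax(0, round(stats::rnorm(
      nrow(blocks), cfg$read_depth_normal, cfg$read_depth_normal / 10)))
    cpath <- file.path(out_dir, sprintf("%s.coverage.bed", sid))
    write_bed(cov, cpath)

    # aCGH probes
    probes <- do.call(rbind, lapply(seq_len(nrow(cfg$genome)), function(i) {
      p <- seq(cfg$probe_spacing_bp, cfg$genome$length[i],
               by = cfg$probe_spacing_bp)
      data.frame(chrom = cfg$genome$chrom[i], pos = p,
                 log2_ratio = 0, stringsAsFactors = FALSE)
    }))
    for (g in seq_len(nrow(cfg$gains))) {
      if (sid %in% gain_carriers[[g]]) {
        hit <- probes$chrom == cfg$gains$chrom[g] &
          probes$pos >= cfg$gains$start[g] & probes$pos <= cfg$gains$end[g]
        probes$log2_ratio[hit] <- probes$log2_ratio[hit] +
          cfg$gains$log2_level[g]
      }
    }
    probes$log2_ratio <- probes$log2_ratio +
      stats::rnorm(nrow(probes), 0, cfg$probe_noise_sd)
    ppath <- file.path(out_dir, sprintf("%s.probes.tsv", sid))
    write_probes(probes, ppath)

    sample_files$variants[si] <- vpath
    sample_files$coverage[si] <- cpath
    sample_files$probes[si] <- ppath
  }

  # expression matrix: tumor group reuses cohort samples, controls added
  n_tum <- cfg$expr_group_sizes[1]
  n_ctl <- cfg$expr_group_sizes[2]
  if (n_tum > cfg$n_samples) {
    stop("expression tumor group larger than the cohort", call. = FALSE)
  }
  expr_samples <- c(samples[seq_len(n_tum)],
                    sprintf("C%02d", seq_len(n_ctl)))
  expr_groups <- data.frame(
    sample_id = expr_samples,
    group = rep(c("tumor", "control"), c(n_tum, n_ctl)),
    stringsAsFactors = FALSE)
  gene_ids <- sprintf("EXP%04d", seq_len(cfg$expr_n_genes))
  de_idx <- sort(sample.int(cfg$expr_n_genes, cfg$expr_n_de))
  de_dir <- rep(c("up", "down"), length.out = cfg$expr_n_de)
  mu <- stats::rnorm(cfg$expr_n_genes, 5, cfg$expr_baseline_sd)
  # planted regulation must be representable on the rank scale: a gene that
  # already sits at the extreme of the baseline distribution cannot move
  # further up (or down) in rank, so DE genes are drawn from mid-expressed
  # baselines, as in real strongly regulated marker genes
  mu[de_idx] <- 5 + stats::runif(cfg$expr_n_de, -0.5, 0.5) *
    cfg$expr_baseline_sd
  shift <- numeric(cfg$expr_n_genes)
  shift[de_idx] <- ifelse(de_dir == "up", 1, -1) *
    cfg$expr_effect_size_sd * cfg$expr_baseline_sd
  n_expr <- length(expr_samples)
  is_tumor <- expr_groups$group == "tumor"
  logx <- matrix(mu, cfg$expr_n_genes, n_expr) +
    outer(shift, as.numeric(is_tumor)) +
    matrix(stats::rnorm(cfg$expr_n_genes * n_expr, 0, cfg$expr_noise_sd),
           cfg$expr_n_genes, n_expr)
  expr <- exp(logx)
  rownames(expr) <- gene_ids
  colnames(expr) <- expr_samples
  expr_path <- file.path(out_dir, "expression.tsv")
  write_expression(round(expr, 4), expr_path)
  groups_path <- file.path(out_dir, "expr_groups.tsv")
  write_groups(expr_groups, groups_path)

  # gene sets: the planted up and down sets plus random null sets
  sets <- list(PLANTED_UP = gene_ids[de_idx[de_dir == "up"]],
               PLANTED_DOWN = gene_ids[de_idx[de_dir == "down"]])
  null_gene_pool <- setdiff(gene_ids, gene_ids[de_idx])
  for (k in 1:5) {
    sets[[sprintf("NULL_SET%d", k)]] <- sample(null_gene_pool, 20)
  }
  gmt_path <- file.path(out_dir, "gene_sets.gmt")
  write_gene_sets(sets, gmt_path)

  manifest <- list(samples = sample_files, expression = expr_path,
                   expr_groups = groups_path, gene_sets = gmt_path,
                   genes = genes_path)
  manifest_path <- file.path(out_dir, "manifest.tsv")
  write_manifest(manifest, manifest_path)
  validate_manifest(manifest)

  truth <- list(
    cnloh = list(region = cfg$cnloh_region, carriers = carriers),
    somatic = if (length(truth_somatic)) {
      do.call(rbind, c(truth_somatic, list(make.row.names = FALSE)))
    } else {
      data.frame(sample = character(0), chrom = character(0),
                 pos = numeric(0), gene = character(0),
                 effect = character(0), vaf = numeric(0))
    },
    gains = cbind(cfg$gains,
                  carriers = vapply(gain_carriers, paste, "",
                                    collapse = ",")),
    gain_genes = gain_genes,
    de = data.frame(gene = gene_ids[de_idx], direction = de_dir,
                    stringsAsFactors = FALSE),
    samples = samples
  )
  # truth files, for inspection and external tooling
  utils::write.table(truth$somatic,
                     file.path(out_dir, "truth_somatic.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$gain_genes,
                     file.path(out_dir, "truth_gain_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$de, file.path(out_dir, "truth_de.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(sprintf("region\t%s", format_region(truth$cnloh$region)),
               sprintf("carriers\t%s", paste(carriers, collapse = ","))),
             file.path(out_dir, "truth_cnloh.tsv"))

  list(manifest = manifest, manifest_path = manifest_path, truth = truth,
       out_dir = out_dir)
}

#' Compare pipeline output against the planted truth
#'
#' @param report result of [run_all()] on a simulated cohort.
#' @param truth the `truth` element returned by [simulate_cohort()].
#' @param min_share carrier threshold defining which planted gains count as
#'   recurrent truth (default 3, matching [recurrent_gains()]).
#' @param padj_threshold detection rule for differential expression
#'   (default 0.05 on the BH-adjusted p).
#' @return list with `cnloh_jaccard`, `somatic` (precision/recall),
#'   `gains` (precision/recall over gene symbols) and `de`
#'   (precision/recall plus `null_flag_rate`).
#' @export
truth_compare <- function(report, truth, min_share = 3,
                          padj_threshold = 0.05) {
  rep_samples <- unique(report$tmb$sample)
  if (!all(rep_samples %in% truth$samples)) {
    stop("sample ids in report do not match the truth set", call. = FALSE)
  }

  region <- report$common_loh_region
  cnloh_jaccard <- if (is.null(region)) 0 else {
    jaccard_intervals(region[, c("chrom", "start", "end")],
                      truth$cnloh$region)
  }

  pr <- function(pred, true) {
    tp <- length(intersect(pred, true))
    list(precision = if (length(pred)) tp / length(pred) else NA_real_,
         recall = if (length(true)) tp / length(true) else NA_real_)
  }
  calls <- report$calls
  pred_som <- unique(paste(calls$sample[calls$tier == "somatic_only"],
                           calls$chrom[calls$tier == "somatic_only"],
                           calls$pos[calls$tier == "somatic_only"]))
  true_som <- unique(paste(truth$somatic$sample, truth$somatic$chrom,
                           truth$somatic$pos))
  somatic <- pr(pred_som, true_som)

  pred_gain <- if (is.null(report$recurrent_gains)) character(0) else
    report$recurrent_gains$gene
  true_gain <- truth$gain_genes$gene[truth$gain_genes$n_carriers >= min_share]
  gains <- pr(pred_gain, true_gain)

  de <- list(precision = NA_real_, recall = NA_real_,
             null_flag_rate = NA_real_)
  if (!is.null(report$de)) {
    pred_de <- report$de$gene[report$de$padj < padj_threshold]
    de <- pr(pred_de, truth$de$gene)
    null_genes <- setdiff(report$de$gene, truth$de$gene)
    de$null_flag_rate <- mean(null_genes %in% pred_de)
  }
  list(cnloh_jaccard = cnloh_jaccard, somatic = somatic, gains = gains,
       de = de)
}
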