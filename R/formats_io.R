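# File formats: VCF-like TSV (reference dialect for paired variant calls),
# VCF (read-only convenience), BED3+ (coverage, gene annotation), SEG
# (copy-number segments), GMT (gene sets), TSV (expression, manifests).

.effect_levels <- c("missense", "stop_gain", "stop_loss", "frameshift",
                    "inframe_indel", "splice", "synonymous", "intronic",
                    "other")
.nonsyn_effects <- c("missense", "stop_gain", "stop_loss", "frameshift",
                     "inframe_indel", "splice")
.prediction_levels <- c("benign", "possibly_damaging", "probably_damaging",
                        "unknown")

#' Effect classes counted as non-synonymous for mutation burden
#'
#' Single-nucleotide and small indel effect classes that change the protein:
#' missense, stop gain/loss, frameshift, in-frame indel and splice variants.
#'
#' @return character vector of effect labels.
#' @export
nonsynonymous_effects <- function() .nonsyn_effects

#' Read a paired tumor-normal variant table
#'
#' The reference dialect is a TSV with one row per variant and per-sample
#' ref/alt read counts. A VCF dialect is provided for convenience and takes
#' the counts from per-sample `AD` fields (requires the vcfR package).
#'
#' Required TSV columns: `chrom`, `pos`, `ref`, `alt`, `tumor_ref_count`,
#' `tumor_alt_count`, `normal_ref_count`, `normal_alt_count`. Optional
#' annotation columns: `gene`, `effect`, `coding_flag`, `pop_af`,
#' `prediction_class`. Missing annotation is set to an explicit unknown
#' marker: `"unknown"` for gene and prediction class, `"other"` for effect,
#' `NA` for population allele frequency and coding flag.
#'
#' @param path input file.
#' @param dialect `"tsv"` (reference) or `"vcf"`.
#' @param tumor_sample,normal_sample sample column names in the VCF genotype
#'   block (VCF dialect only).
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `tumor_ref`, `tumor_alt`, `normal_ref`, `normal_alt`, `gene`, `effect`,
#'   `coding`, `pop_af`, `prediction`.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf"),
                               tumor_sample = NULL, normal_sample = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "vcf") {
    return(read_variant_vcf(path, tumor_sample, normal_sample))
  }
  # read everything as character first: allele columns like "T" must never
  # be auto-converted to logicals
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  required <- c("chrom", "pos", "ref", "alt", "tumor_ref_count",
                "tumor_alt_count", "normal_ref_count", "normal_alt_count")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("variant table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  counts <- c("tumor_ref_count", "tumor_alt_count",
              "normal_ref_count", "normal_alt_count")
  for (cc in counts) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad)) {
      stop(sprintf("variant table %s: column %s invalid at row %d (counts must be non-negative integers)",
                   path, cc, bad[1]), call. = FALSE)
    }
    df[[cc]] <- as.integer(v)
  }
  out <- data.frame(
    chrom = normalize_chrom(df$chrom),
    pos = as.numeric(df$pos),
    ref = as.character(df$ref),
    alt = as.character(df$alt),
    tumor_ref = df$tumor_ref_count,
    tumor_alt = df$tumor_alt_count,
    normal_ref = df$normal_ref_count,
    normal_alt = df$normal_alt_count,
    stringsAsFactors = FALSE
  )
  out$gene <- if ("gene" %in% names(df)) as.character(df$gene) else "unknown"
  out$gene[is.na(out$gene) | !nzchar(out$gene)] <- "unknown"
  out$effect <- if ("effect" %in% names(df)) as.character(df$effect) else "other"
  out$effect[is.na(out$effect) | !(out$effect %in% .effect_levels)] <- "other"
  out$coding <- if ("coding_flag" %in% names(df)) {
    as.logical(df$coding_flag)
  } else NA
  out$pop_af <- if ("pop_af" %in% names(df)) {
    suppressWarnings(as.numeric(df$pop_af))
  } else NA_real_
  if (any(!is.na(out$pop_af) & (out$pop_af < 0 | out$pop_af > 1))) {
    bad <- which(!is.na(out$pop_af) & (out$pop_af < 0 | out$pop_af > 1))[1]
    stop(sprintf("variant table %s: pop_af outside [0,1] at row %d",
                 path, bad), call. = FALSE)
  }
  out$prediction <- if ("prediction_class" %in% names(df)) {
    as.character(df$prediction_class)
  } else "unknown"
  out$prediction[is.na(out$prediction) |
                   !(out$prediction %in% .prediction_levels)] <- "unknown"
  if (nrow(out)) validate_intervals(
    data.frame(chrom = out$chrom, start = out$pos, end = out$pos),
    what = "variant table")
  out
}

read_variant_vcf <- function(path, tumor_sample, normal_sample) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the VCF dialect requires the vcfR package", call. = FALSE)
  }
  if (is.null(tumor_sample) || is.null(normal_sample)) {
    stop("VCF dialect needs tumor_sample and normal_sample names",
         call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  for (s in c(tumor_sample, normal_sample)) {
    if (!s %in% colnames(ad)) {
      stop("sample not present in VCF: ", s, call. = FALSE)
    }
  }
  split_ad <- function(x) {
    parts <- strsplit(ifelse(is.na(x), "0,0", x), ",", fixed = TRUE)
    cbind(ref = as.integer(vapply(parts, `[`, "", 1L)),
          alt = as.integer(vapply(parts, function(p) {
            if (length(p) >= 2) p[2] else "0"
          }, "")))
  }
  tad <- split_ad(ad[, tumor_sample])
  nad <- split_ad(ad[, normal_sample])
  fix <- vcfR::getFIX(v)
  data.frame(
    chrom = normalize_chrom(fix[, "CHROM"]),
    pos = as.numeric(fix[, "POS"]),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    tumor_ref = tad[, "ref"], tumor_alt = tad[, "alt"],
    normal_ref = nad[, "ref"], normal_alt = nad[, "alt"],
    gene = "unknown", effect = "other", coding = NA,
    pop_af = NA_real_, prediction = "unknown",
    stringsAsFactors = FALSE
  )
}

#' Write a variant table in the reference TSV dialect
#'
#' @param variants data.frame as returned by [read_variant_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  out <- data.frame(
    chrom = variants$chrom, pos = as.integer(variants$pos),
    ref = variants$ref, alt = variants$alt,
    tumor_ref_count = variants$tumor_ref,
    tumor_alt_count = variants$tumor_alt,
    normal_ref_count = variants$normal_ref,
    normal_alt_count = variants$normal_alt,
    gene = variants$gene, effect = variants$effect,
    coding_flag = variants$coding, pop_af = variants$pop_af,
    prediction_class = variants$prediction,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write BED files (the single 0-based/1-based conversion layer)
#'
#' On disk BED is 0-based half-open; in memory all intervals are 1-based
#' inclusive. `read_bed` adds 1 to starts, `write_bed` subtracts 1.
#'
#' @param path BED file.
#' @param col_names names for columns beyond `chrom,start,end`, e.g.
#'   `c("tumor_depth","normal_depth")` for coverage or `"gene"` for
#'   annotation.
#' @return data.frame with 1-based inclusive `start`/`end` plus any extra
#'   columns.
#' @export
read_bed <- function(path, col_names = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 3) stop("BED file needs at least 3 columns: ", path,
                         call. = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  df$chrom <- normalize_chrom(df$chrom)
  df$start <- as.numeric(df$start) + 1   # BED start is 0-based
  df$end <- as.numeric(df$end)           # BED end is exclusive == 1-based inclusive
  if (!is.null(col_names)) {
    extra <- seq_len(min(length(col_names), ncol(df) - 3)) + 3L
    names(df)[extra] <- col_names[seq_along(extra)]
  }
  validate_intervals(df, what = basename(path))
  df
}

#' @rdname read_bed
#' @param df interval data.frame (1-based inclusive) with optional extra
#'   columns after `chrom,start,end`.
#' @param chr_prefix re-add a `"chr"` prefix on output.
#' @export
write_bed <- function(df, path, chr_prefix = FALSE) {
  validate_intervals(df)
  out <- df
  out$chrom <- if (chr_prefix) paste0("chr", df$chrom) else df$chrom
  out$start <- format(df$start - 1, scientific = FALSE, trim = TRUE)
  out$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write copy-number segments as a SEG file
#'
#' Standard 6-column SEG: `ID`, `chrom`, `loc.start`, `loc.end`, `num.mark`,
#' `seg.mean`. Coordinates are 1-based inclusive. Segment means are written
#' with 6 decimal places, so a read/write round trip preserves them to that
#' precision.
#'
#' @param segments data.frame with `sample`, `chrom`, `start`, `end`,
#'   `n_probes`, `mean_log2`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, path) {
  need <- c("sample", "chrom", "start", "end", "n_probes", "mean_log2")
  miss <- setdiff(need, names(segments))
  if (length(miss)) {
    stop("segments are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(segments)) {
    validate_intervals(segments, what = "segments")
    sp <- split(segments, list(segments$sample, segments$chrom), drop = TRUE)
    for (g in sp) {
      g <- g[order(g$start), , drop = FALSE]
      if (nrow(g) > 1 && any(g$start[-1] <= g$end[-nrow(g)])) {
        stop(sprintf("overlapping segments for sample %s on chromosome %s",
                     g$sample[1], g$chrom[1]), call. = FALSE)
      }
    }
  }
  lines <- c(
    paste(c("ID", "chrom", "loc.start", "loc.end", "num.mark", "seg.mean"),
          collapse = "\t"),
    if (nrow(segments)) {
      sprintf("%s\t%s\t%d\t%d\t%d\t%.6f",
              segments$sample, segments$chrom,
              as.integer(segments$start), as.integer(segments$end),
              as.integer(segments$n_probes), segments$mean_log2)
    }
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("ID", "chrom", "loc.start", "loc.end", "num.mark", "seg.mean")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("SEG file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    sample = as.character(df$ID),
    chrom = normalize_chrom(df$chrom),
    start = as.numeric(df$loc.start),
    end = as.numeric(df$loc.end),
    n_probes = as.integer(df$num.mark),
    mean_log2 = as.numeric(df$seg.mean),
    stringsAsFactors = FALSE
  )
}

#' Read gene sets from a GMT file
#'
#' Each line is `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate
#' members within a set are collapsed; duplicate set names are an error.
#'
#' @param path GMT file.
#' @return named list of character vectors of gene symbols.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d has fewer than 3 fields", i), call. = FALSE)
    }
    nm <- fields[1]
    if (nm %in% names(sets)) {
      stop(sprintf("duplicate gene-set name at GMT line %d: %s", i, nm),
           call. = FALSE)
    }
    sets[[nm]] <- unique(fields[-(1:2)])
  }
  sets
}

#' @rdname read_gene_sets
#' @param sets named list of character vectors.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", unique(sets[[nm]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read/write a gene expression matrix
#'
#' TSV with a `gene` column followed by one column per sample; values are
#' non-negative measurements (e.g. normalized counts).
#'
#' @param path TSV file.
#' @return numeric matrix, genes in rows (rownames), samples in columns.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene") {
    stop("expression table must start with a 'gene' column", call. = FALSE)
  }
  if (anyDuplicated(df$gene)) {
    stop("duplicate gene symbols in expression table", call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$gene
  m
}

#' @rdname read_expression
#' @param mat numeric matrix with gene rownames.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cohort manifest
#'
#' A manifest lists one row per sample with paths to that sample's variant
#' table, coverage BED and aCGH probe table, plus a group label; cohort-level
#' inputs (expression matrix, gene sets, gene annotation) are carried as
#' `#key=value` header lines. Absent inputs are marked `"."`.
#'
#' @param manifest list with elements `samples` (data.frame `sample_id`,
#'   `variants`, `coverage`, `probes`, `group`) and optional scalar paths
#'   `expression`, `expr_groups`, `gene_sets`, `genes`.
#' @param path manifest TSV file. Paths pointing into the manifest's own
#'   directory are written relative to it (and resolved back on read), so a
#'   simulated bundle is relocatable and byte-reproducible.
#' @return `read_manifest` returns the manifest list; `validate_manifest`
#'   returns it invisibly or stops with an informative error.
#' @export
write_manifest <- function(manifest, path) {
  base <- normalizePath(dirname(path), mustWork = FALSE)
  relativize <- function(p) {
    if (is.null(p) || is.na(p) || p == ".") return(".")
    ap <- normalizePath(p, mustWork = FALSE)
    prefix <- paste0(base, .Platform$file.sep)
    if (startsWith(ap, prefix)) substring(ap, nchar(prefix) + 1) else p
  }
  hdr <- character(0)
  for (k in c("expression", "expr_groups", "gene_sets", "genes")) {
    hdr <- c(hdr, sprintf("#%s=%s", k, relativize(manifest[[k]])))
  }
  s <- manifest$samples
  for (cc in c("variants", "coverage", "probes")) {
    s[[cc]] <- vapply(s[[cc]], relativize, "")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(s, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  kv <- list(expression = NA_character_, expr_groups = NA_character_,
             gene_sets = NA_character_, genes = NA_character_)
  for (h in hdr) {
    m <- regmatches(h, regexec("^#([^=]+)=(.*)$", h))[[1]]
    if (length(m) == 3 && m[2] %in% names(kv)) {
      kv[[m[2]]] <- if (m[3] == ".") NA_character_ else m[3]
    }
  }
  samples <- utils::read.delim(text = paste(body, collapse = "\n"),
                               stringsAsFactors = FALSE,
                               colClasses = "character")
  need <- c("sample_id", "variants", "coverage", "probes", "group")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stop("manifest missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(normalizePath(path, mustWork = FALSE))
  resolve <- function(p) {
    if (is.na(p) || p == "." || grepl("^(/|[A-Za-z]:)", p)) p
    else file.path(base, p)
  }
  for (cc in c("variants", "coverage", "probes")) {
    samples[[cc]] <- vapply(samples[[cc]], resolve, "", USE.NAMES = FALSE)
  }
  kv <- lapply(kv, function(p) if (is.na(p)) p else resolve(p))
  c(list(samples = samples), kv)
}

#' @rdname write_manifest
#' @export
validate_manifest <- function(manifest) {
  s <- manifest$samples
  if (anyDuplicated(s$sample_id)) {
    stop("duplicate sample_id in manifest: ",
         s$sample_id[duplicated(s$sample_id)][1], call. = FALSE)
  }
  paths <- c(s$variants, s$coverage, s$probes, manifest$expression,
             manifest$expr_groups, manifest$gene_sets, manifest$genes)
  paths <- paths[!is.na(paths) & paths != "."]
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("manifest references missing file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(manifest)
}

#' Read/write an aCGH probe table
#'
#' TSV with columns `chrom`, `pos`, `log2_ratio`, positions strictly
#' increasing within each chromosome.
#'
#' @param path TSV file.
#' @return data.frame `chrom`, `pos`, `log2_ratio`.
#' @export
read_probes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "log2_ratio")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("probe table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$chrom <- normalize_chrom(df$chrom)
  df$pos <- as.numeric(df$pos)
  df$log2_ratio <- as.numeric(df$log2_ratio)
  if (any(!is.finite(df$log2_ratio))) {
    stop("probe table contains non-finite log2 ratios", call. = FALSE)
  }
  for (ch in unique(df$chrom)) {
    p <- df$pos[df$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("probe positions not strictly increasing on chromosome ", ch,
           call. = FALSE)
    }
  }
  df
}

#' @rdname read_probes
#' @param probes data.frame `chrom`, `pos`, `log2_ratio`.
#' @export
write_probes <- function(probes, path) {
  out <- data.frame(chrom = probes$chrom,
                    pos = format(probes$pos, scientific = FALSE, trim = TRUE),
                    log2_ratio = sprintf("%.6f", probes$log2_ratio),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write sample group labels
#'
#' @param path TSV with columns `sample_id`, `group`.
#' @return data.frame `sample_id`, `group`.
#' @export
read_groups <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop("groups file needs columns sample_id and group", call. = FALSE)
  }
  df
}

#' @rdname read_groups
#' @param groups data.frame `sample_id`, `group`.
#' @export
write_groups <- function(groups, path) {
  utils::write.table(groups, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
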