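# Loss-of-heterozygosity detection from B-allele fractions at germline
# heterozygous sites, cohort common-region intersection, and integration
# with copy-number segments into copy-neutral LOH calls.

#' Extract informative germline heterozygous sites
#'
#' A site is informative when the matched normal shows a heterozygous
#' B-allele fraction (inside `het_band`) at adequate depth. Its tumor
#' allele fraction then carries LOH evidence when it deviates strongly
#' toward either homozygous state (`>= loh_vaf_threshold` or
#' `<= 1 - loh_vaf_threshold`).
#'
#' @param variants variant data.frame (see [read_variant_table()]).
#' @param min_normal_depth minimum normal depth for the het call (default 8).
#' @param het_band normal allele-fraction window defining heterozygosity
#'   (default `c(0.3, 0.7)`).
#' @param loh_vaf_threshold tumor allele-fraction deviation defining LOH
#'   evidence (default 0.75).
#' @return data.frame `chrom`, `pos`, `normal_vaf`, `tumor_vaf`,
#'   `normal_depth`, `tumor_depth`, `loh_evidence`.
#' @export
extract_het_sites <- function(variants, min_normal_depth = 8,
                              het_band = c(0.3, 0.7),
                              loh_vaf_threshold = 0.75) {
  nd <- variants$normal_ref + variants$normal_alt
  td <- variants$tumor_ref + variants$tumor_alt
  nvaf <- ifelse(nd > 0, variants$normal_alt / nd, NA_real_)
  tvaf <- ifelse(td > 0, variants$tumor_alt / td, NA_real_)
  keep <- !is.na(nvaf) & nd >= min_normal_depth &
    nvaf >= het_band[1] & nvaf <= het_band[2] & !is.na(tvaf)
  out <- data.frame(
    chrom = variants$chrom[keep], pos = variants$pos[keep],
    normal_vaf = nvaf[keep], tumor_vaf = tvaf[keep],
    normal_depth = nd[keep], tumor_depth = td[keep],
    stringsAsFactors = FALSE
  )
  out$loh_evidence <- out$tumor_vaf >= loh_vaf_threshold |
    out$tumor_vaf <= 1 - loh_vaf_threshold
  out
}

#' Segment LOH from informative het sites of one sample
#'
#' Scans sites in genomic order and reports maximal runs dominated by LOH
#' evidence: a run starts at an evidence site, tolerates at most
#' `max_miss_run` consecutive non-evidence sites, breaks at inter-site gaps
#' larger than `max_gap_bp`, and is reported when it contains at least
#' `min_sites` informative sites with an evidence fraction of at least
#' `min_loh_fraction`. Trailing non-evidence sites are trimmed, so reported
#' segments start and end at evidence sites.
#'
#' @param sites het-site data.frame from [extract_het_sites()], sorted by
#'   position within chromosome.
#' @param min_sites minimum informative sites per segment (default 10).
#' @param min_loh_fraction minimum fraction of sites with evidence
#'   (default 0.8).
#' @param max_gap_bp maximum allowed gap between consecutive sites
#'   (default 2e6).
#' @param max_miss_run consecutive non-evidence sites that end a run
#'   (default 2).
#' @param sample sample id recorded on the output (default `"sample"`).
#' @return data.frame `sample`, `chrom`, `start`, `end`, `n_informative`,
#'   `n_loh`, `mean_tumor_deviation`.
#' @export
segment_loh <- function(sites, min_sites = 10, min_loh_fraction = 0.8,
                        max_gap_bp = 2e6, max_miss_run = 2,
                        sample = "sample") {
  empty <- data.frame(sample = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      n_informative = integer(0), n_loh = integer(0),
                      mean_tumor_deviation = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(sites)) return(empty)
  segs <- list()
  for (ch in unique(sites$chrom)) {
    s <- sites[sites$chrom == ch, , drop = FALSE]
    if (is.unsorted(s$pos, strictly = FALSE)) {
      stop("het sites must be sorted by position within chromosome ", ch,
           call. = FALSE)
    }
    n <- nrow(s)
    i <- 1L
    while (i <= n) {
      if (!s$loh_evidence[i]) { i <- i + 1L; next }
      # grow a candidate run from this evidence site
      j <- i
      last_ev <- i
      miss <- 0L
      while (j < n) {
        nxt <- j + 1L
        if (s$pos[nxt] - s$pos[j] > max_gap_bp) break
        if (s$loh_evidence[nxt]) {
          miss <- 0L
          last_ev <- nxt
        } else {
          miss <- miss + 1L
          if (miss > max_miss_run) break
        }
        j <- nxt
      }
      idx <- i:last_ev  # trimmed at trailing non-evidence
      n_inf <- length(idx)
      n_loh <- sum(s$loh_evidence[idx])
      if (n_inf >= min_sites && n_loh / n_inf >= min_loh_fraction) {
        segs[[length(segs) + 1L]] <- data.frame(
          sample = sample, chrom = ch,
          start = s$pos[i], end = s$pos[last_ev],
          n_informative = n_inf, n_loh = as.integer(n_loh),
          mean_tumor_deviation = mean(abs(s$tumor_vaf[idx] - 0.5)),
          stringsAsFactors = FALSE)
      }
      i <- max(j, last_ev) + 1L
    }
  }
  if (!length(segs)) return(empty)
  do.call(rbind, segs)
}

#' Smallest common LOH region across the cohort
#'
#' By sweep over segment boundaries, finds the maximal interval covered by
#' LOH segments of at least `min_samples` distinct samples (the longest such
#' interval when several exist), then returns the intersection of the
#' contributing samples' LOH intervals that overlap it. The result is
#' contained in every contributing sample's LOH segment.
#'
#' @param segments LOH segment data.frame across samples (from
#'   [segment_loh()], row-bound).
#' @param min_samples minimum number of samples that must share the region
#'   (>= 2, <= cohort size).
#' @return one-row interval data.frame (`chrom`, `start`, `end`, plus
#'   `n_samples` sharing), or `NULL` when no interval reaches
#'   `min_samples` coverage.
#' @export
common_loh_region <- function(segments, min_samples) {
  if (min_samples < 2) stop("min_samples must be >= 2", call. = FALSE)
  n_cohort <- length(unique(segments$sample))
  if (min_samples > n_cohort) {
    stop(sprintf("min_samples (%d) exceeds cohort size (%d)",
                 min_samples, n_cohort), call. = FALSE)
  }
  best <- NULL
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    # sweep: +1 at starts, -1 just past ends, counting distinct samples
    # (a sample's overlapping segments are merged first)
    per <- lapply(split(s, s$sample), function(g) {
      g <- g[order(g$start), , drop = FALSE]
      merged <- list()
      cs <- g$start[1]; ce <- g$end[1]
      for (k in seq_len(nrow(g))[-1]) {
        if (g$start[k] <= ce + 1) ce <- max(ce, g$end[k])
        else { merged[[length(merged) + 1L]] <- c(cs, ce); cs <- g$start[k]; ce <- g$end[k] }
      }
      merged[[length(merged) + 1L]] <- c(cs, ce)
      do.call(rbind, merged)
    })
    iv <- do.call(rbind, per)
    ev <- data.frame(pos = c(iv[, 1], iv[, 2] + 1),
                     d = rep(c(1, -1), each = nrow(iv)))
    ev <- stats::aggregate(d ~ pos, data = ev, FUN = sum)
    ev <- ev[order(ev$pos), ]
    cov <- cumsum(ev$d)
    # stretches [pos_k, pos_{k+1}-1] have coverage cov[k]
    hit <- which(cov >= min_samples)
    if (!length(hit)) next
    starts <- ev$pos[hit]
    ends <- ev$pos[hit + 1] - 1
    # merge contiguous qualifying stretches
    runs <- split(seq_along(hit), cumsum(c(1, diff(hit) != 1)))
    for (r in runs) {
      w_start <- starts[r[1]]
      w_end <- ends[r[length(r)]]
      window <- data.frame(chrom = ch, start = w_start, end = w_end)
      # intersect the per-sample intervals that overlap the window
      touch <- s[s$start <= w_end & s$end >= w_start, , drop = FALSE]
      region <- data.frame(
        chrom = ch, start = max(touch$start), end = min(touch$end),
        n_samples = length(unique(touch$sample)),
        stringsAsFactors = FALSE)
      if (region$start > region$end) {
        # overlapping-but-staggered intervals: fall back to the covered window
        region$start <- w_start; region$end <- w_end
      }
      if (is.null(best) ||
          (region$end - region$start) > (best$end - best$start)) {
        best <- region
      }
    }
  }
  best
}

#' Integrate LOH segments with copy-number segments into CN-LOH calls
#'
#' Each LOH segment is intersected with the same sample's copy-number
#' segments. The copy-number state is neutral when every overlapping
#' segment's mean log2 ratio stays within `+/- neutral_band`; any mean below
#' `-neutral_band` labels the region a loss, any mean above a gain, with
#' loss taking precedence over gain on mixed overlaps (conservative against
#' false copy-neutral calls). Copy-neutral LOH is called only for neutral
#' state. LOH segments with no overlapping copy-number segment get state
#' `"unknown"` with a warning.
#'
#' @param loh_segments LOH segment data.frame (one or more samples).
#' @param cn_segments copy-number segment data.frame with `sample`, `chrom`,
#'   `start`, `end`, `mean_log2`.
#' @param neutral_band half-width of the copy-neutral log2-ratio band
#'   (default 0.3).
#' @return data.frame `sample`, `chrom`, `start`, `end`, `cn_state`,
#'   `cnloh`.
#' @export
integrate_cnloh <- function(loh_segments, cn_segments, neutral_band = 0.3) {
  n <- nrow(loh_segments)
  state <- character(n)
  for (i in seq_len(n)) {
    cs <- cn_segments[cn_segments$sample == loh_segments$sample[i] &
                        cn_segments$chrom == loh_segments$chrom[i] &
                        cn_segments$start <= loh_segments$end[i] &
                        cn_segments$end >= loh_segments$start[i], ,
                      drop = FALSE]
    if (!nrow(cs)) {
      warning(sprintf("no copy-number segment overlaps LOH segment %s:%s:%d-%d; state unknown",
                      loh_segments$sample[i], loh_segments$chrom[i],
                      as.integer(loh_segments$start[i]),
                      as.integer(loh_segments$end[i])))
      state[i] <- "unknown"
    } else if (any(cs$mean_log2 < -neutral_band)) {
      state[i] <- "loss"
    } else if (any(cs$mean_log2 > neutral_band)) {
      state[i] <- "gain"
    } else {
      state[i] <- "neutral"
    }
  }
  data.frame(
    sample = loh_segments$sample, chrom = loh_segments$chrom,
    start = loh_segments$start, end = loh_segments$end,
    cn_state = state, cnloh = state == "neutral",
    stringsAsFactors = FALSE
  )
}
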