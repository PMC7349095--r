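# aCGH copy-number analysis: robust internal-noise estimation, circular
# binary segmentation (CBS) with a permutation stopping rule, noise-adaptive
# aberration status calling, cohort recurrence and amplification analysis.

#' Robust internal noise of an aCGH profile
#'
#' A derivative-based spread estimator: the median absolute difference of
#' log2 ratios across consecutive probes, scaled by `sqrt(2) * 0.6745` so it
#' is consistent for the probe-level standard deviation under Gaussian
#' noise. Differences are taken within chromosomes only, so chromosome
#' boundaries and isolated copy-number steps barely affect it.
#'
#' @param probes data.frame `chrom`, `pos`, `log2_ratio` (see
#'   [read_probes()]), at least 10 probes.
#' @return estimated probe-level noise standard deviation.
#' @export
estimate_noise <- function(probes) {
  if (nrow(probes) < 10) {
    stop("need at least 10 probes to estimate noise", call. = FALSE)
  }
  d <- unlist(lapply(split(probes$log2_ratio, probes$chrom), diff),
              use.names = FALSE)
  if (!length(d)) return(0)
  stats::median(abs(d)) / (sqrt(2) * 0.6745)
}

#' Circular binary segmentation of an aCGH profile
#'
#' Recursively splits each chromosome's probe sequence at the circular arc
#' maximizing the two-sample t statistic between the arc and its
#' complement. A split is accepted when its permutation p-value (from
#' `n_perm` permutations of probe order within the segment) is below
#' `alpha` and both parts keep at least `min_probes` probes; ties in the
#' max-t search are broken by the leftmost arc. A final merge pass joins
#' adjacent segments whose means differ by less than
#' `2 * sigma / sqrt(harmonic mean probe count)`, with `sigma` the profile's
#' internal noise ([estimate_noise()]). Deterministic for a fixed seed.
#'
#' @param probes data.frame `chrom`, `pos`, `log2_ratio`, positions strictly
#'   increasing within chromosome.
#' @param alpha permutation significance level for accepting a split
#'   (default 0.01).
#' @param n_perm number of permutations (default 1000).
#' @param min_probes minimum probes per segment (default 3).
#' @param seed RNG seed; when `NULL` the current RNG state is used.
#' @param sample sample id recorded on the output.
#' @return segment data.frame `sample`, `chrom`, `start`, `end`,
#'   `n_probes`, `mean_log2` (status unset; see [call_status()]).
#' @export
cbs_segment <- function(probes, alpha = 0.01, n_perm = 1000, min_probes = 3,
                        seed = NULL, sample = "sample") {
  if (!is.null(seed)) set.seed(seed)
  for (ch in unique(probes$chrom)) {
    if (is.unsorted(probes$pos[probes$chrom == ch], strictly = TRUE)) {
      stop("probe positions must be strictly increasing within chromosome ",
           ch, call. = FALSE)
    }
  }
  sigma <- if (nrow(probes) >= 10) estimate_noise(probes) else 0
  max_exceed <- floor(alpha * n_perm)
  out <- list()
  for (ch in unique(probes$chrom)) {
    p <- probes[probes$chrom == ch, , drop = FALSE]
    x <- p$log2_ratio
    bounds <- cbs_recurse(x, alpha, n_perm, min_probes, max_exceed)
    segs <- data.frame(
      sample = sample, chrom = ch,
      first = c(1L, bounds[-length(bounds)] + 1L),
      last = bounds,
      stringsAsFactors = FALSE
    )
    segs <- merge_segments(segs, x, sigma)
    out[[ch]] <- data.frame(
      sample = sample, chrom = ch,
      start = p$pos[segs$first], end = p$pos[segs$last],
      n_probes = segs$last - segs$first + 1L,
      mean_log2 = vapply(seq_len(nrow(segs)), function(k) {
        mean(x[segs$first[k]:segs$last[k]])
      }, 0),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# returns sorted vector of segment end indices (the last one is length(x))
cbs_recurse <- function(x, alpha, n_perm, min_probes, max_exceed) {
  n <- length(x)
  best <- cbs_max_t(x, as.integer(min_probes))
  if (best$t < 0) return(n)
  exceed <- cbs_perm_exceed(x, best$t, as.integer(n_perm),
                            as.integer(min_probes), as.integer(max_exceed))
  if (exceed > max_exceed || exceed / n_perm >= alpha) return(n)
  i <- best$i; j <- best$j  # cut counts: parts are 1..i, i+1..j, j+1..n
  cuts <- c(if (i > 0) i, j, if (j < n) n)
  parts <- list()
  lo <- 1L
  ends <- integer(0)
  for (cut in unique(cuts)) {
    sub <- x[lo:cut]
    ends <- c(ends, lo - 1L + cbs_recurse(sub, alpha, n_perm, min_probes,
                                          max_exceed))
    lo <- cut + 1L
  }
  sort(unique(ends))
}

# iterative merge of adjacent segments with near-equal means; the closest
# pair is merged first, thresholds re-evaluated after each merge
merge_segments <- function(segs, x, sigma) {
  repeat {
    if (nrow(segs) < 2) return(segs)
    m <- vapply(seq_len(nrow(segs)), function(k) {
      mean(x[segs$first[k]:segs$last[k]])
    }, 0)
    np <- segs$last - segs$first + 1
    dm <- abs(diff(m))
    hmean <- 2 * np[-length(np)] * np[-1] / (np[-length(np)] + np[-1])
    thr <- 2 * sigma / sqrt(hmean)
    cand <- which(dm < thr)
    if (!length(cand)) return(segs)
    k <- cand[which.min(dm[cand])]
    segs$last[k] <- segs$last[k + 1]
    segs <- segs[-(k + 1), , drop = FALSE]
  }
}

#' Noise-adaptive aberration status calling
#'
#' The gain/loss threshold adapts to the profile's internal noise:
#' `t = max(min_abs, k * sigma)`. Segments with mean log2 ratio above `t`
#' are gains, below `-t` losses, otherwise neutral. Independently of the
#' adaptive status, two fixed flags are set: `aberrant_flag` for
#' `|mean| > aberrant_threshold` (default 1, i.e. clearly aberrant copy
#' number) and `amplified_flag` for `mean > amplified_threshold` (default
#' 2.3, about a five-fold increase, suggestive of amplification).
#'
#' @param segments segment data.frame from [cbs_segment()].
#' @param sigma internal noise from [estimate_noise()].
#' @param k noise multiplier (default 3).
#' @param min_abs floor on the adaptive threshold (default 0.2 log2 units).
#' @param aberrant_threshold,amplified_threshold fixed, non-adaptive flag
#'   thresholds.
#' @return `segments` with `status`, `aberrant_flag`, `amplified_flag`.
#' @export
call_status <- function(segments, sigma, k = 3, min_abs = 0.2,
                        aberrant_threshold = 1.0,
                        amplified_threshold = 2.3) {
  thr <- max(min_abs, k * sigma)
  segments$status <- ifelse(segments$mean_log2 > thr, "gain",
                            ifelse(segments$mean_log2 < -thr, "loss",
                                   "neutral"))
  segments$aberrant_flag <- abs(segments$mean_log2) > aberrant_threshold
  segments$amplified_flag <- segments$mean_log2 > amplified_threshold
  segments
}

#' Recurrent gains across a cohort
#'
#' A gene shares a gain in a sample when at least 1 bp of its interval
#' overlaps a segment with mean log2 ratio above `aberrant_threshold`.
#' Genes shared by at least `min_share` samples are reported with the mean
#' of the sharing samples' qualifying segment means, sorted by locus.
#'
#' @param segments cohort segment data.frame (all samples).
#' @param genes gene annotation data.frame `chrom`, `start`, `end`, `gene`.
#' @param min_share minimum number of sharing samples (default 3).
#' @param aberrant_threshold log2-ratio threshold defining an aberrant gain
#'   (default 1.0).
#' @return data.frame `chrom`, `start`, `end`, `gene`, `n_samples_shared`,
#'   `mean_log2`.
#' @export
recurrent_gains <- function(segments, genes, min_share = 3,
                            aberrant_threshold = 1.0) {
  if (is.null(genes) || !nrow(genes)) {
    stop("gene annotation is empty", call. = FALSE)
  }
  validate_intervals(genes, what = "gene annotation")
  out <- list()
  for (g in seq_len(nrow(genes))) {
    ov <- segments[segments$chrom == genes$chrom[g] &
                     segments$start <= genes$end[g] &
                     segments$end >= genes$start[g] &
                     segments$mean_log2 > aberrant_threshold, , drop = FALSE]
    if (!nrow(ov)) next
    per_sample <- tapply(ov$mean_log2, ov$sample, mean)
    if (length(per_sample) >= min_share) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = genes$chrom[g], start = genes$start[g], end = genes$end[g],
        gene = genes$gene[g],
        n_samples_shared = length(per_sample),
        mean_log2 = mean(per_sample),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), gene = character(0),
                      n_samples_shared = integer(0), mean_log2 = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Copy-number fold change from a mean log2 ratio
#'
#' @param mean_log2 finite log2 ratio(s) relative to the diploid reference.
#' @return `2 ^ mean_log2`; e.g. 0 -> 1-fold (diploid), 1 -> 2-fold,
#'   2.3 -> 4.9-fold (about five-fold).
#' @export
fold_change_from_log2 <- function(mean_log2) {
  if (any(!is.finite(mean_log2))) stop("mean_log2 must be finite",
                                       call. = FALSE)
  2^mean_log2
}
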