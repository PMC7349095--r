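#' Genomic intervals
#'
#' All user-facing coordinates in this package are 1-based and inclusive at
#' both ends, the convention in which regions such as `chr19:373916-11465316`
#' are written. BED files on disk use the BED standard (0-based half-open);
#' the conversion happens in exactly one place, [read_bed()]/[write_bed()].
#'
#' @param chrom chromosome name(s); any `"chr"` prefix is stripped so that
#'   `"chr19"` and `"19"` compare equal.
#' @param start,end 1-based inclusive positions, `end >= start >= 1`.
#' @return A data.frame with columns `chrom`, `start`, `end`.
#' @examples
#' genomic_interval("chr19", 373916, 11465316)
#' @export
genomic_interval <- function(chrom, start, end) {
  df <- data.frame(
    chrom = normalize_chrom(as.character(chrom)),
    start = as.numeric(start),
    end = as.numeric(end),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

#' Strip any "chr" prefix from chromosome names
#'
#' @param chrom character vector of chromosome names.
#' @return character vector without a `chr`/`Chr` prefix.
#' @export
normalize_chrom <- function(chrom) {
  sub("^[Cc][Hh][Rr]", "", as.character(chrom))
}

#' Validate an interval data.frame
#'
#' Checks `start >= 1`, `end >= start` and non-empty chromosome names.
#'
#' @param df data.frame with `chrom`, `start`, `end`.
#' @param what label used in error messages.
#' @return `df`, invisibly.
#' @export
validate_intervals <- function(df, what = "interval") {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s table is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$chrom) | !nzchar(df$chrom))) {
    stop(sprintf("%s: empty chromosome name", what), call. = FALSE)
  }
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 1 | df$end < df$start)
  if (length(bad)) {
    stop(sprintf("%s: invalid coordinates at row %d (need 1 <= start <= end)",
                 what, bad[1]), call. = FALSE)
  }
  invisible(df)
}

#' Parse a region string like "chr19:373916-11465316"
#'
#' @param x character vector of `chrom:start-end` strings; thousands
#'   separators (`.` or `,`) inside the numbers are tolerated.
#' @return interval data.frame (1-based inclusive).
#' @export
parse_region <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([0-9.,]+)-([0-9.,]+)$", x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("cannot parse region string: ", x[bad][1], call. = FALSE)
  }
  strip <- function(s) as.numeric(gsub("[.,]", "", s))
  genomic_interval(
    chrom = vapply(m, `[`, "", 2L),
    start = strip(vapply(m, `[`, "", 3L)),
    end = strip(vapply(m, `[`, "", 4L))
  )
}

#' Format intervals as region strings
#'
#' @param df interval data.frame.
#' @param chr_prefix prepend `"chr"` to chromosome names.
#' @return character vector of `chrom:start-end`.
#' @export
format_region <- function(df, chr_prefix = TRUE) {
  if (nrow(df) == 0) return(character(0))
  chrom <- if (chr_prefix) paste0("chr", df$chrom) else df$chrom
  sprintf("%s:%d-%d", chrom, as.integer(df$start), as.integer(df$end))
}

#' Interval length in base pairs (1-based inclusive)
#'
#' @param df interval data.frame.
#' @return numeric vector of widths, `end - start + 1`.
#' @export
interval_width <- function(df) {
  if (nrow(df) == 0) return(numeric(0))
  df$end - df$start + 1
}

#' Pairwise intersection of two interval sets
#'
#' Returns the overlapping pieces of `a` and `b` on matching chromosomes.
#'
#' @param a,b interval data.frames.
#' @return interval data.frame of intersections (possibly 0 rows).
#' @export
intersect_intervals <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  out <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    aa <- a[a$chrom == ch, , drop = FALSE]
    bb <- b[b$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(aa))) {
      s <- pmax(aa$start[i], bb$start)
      e <- pmin(aa$end[i], bb$end)
      keep <- s <= e
      if (any(keep)) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = s[keep], end = e[keep],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start, res$end), , drop = FALSE]
}

#' Which points fall inside an interval set
#'
#' @param chrom,pos point coordinates (1-based).
#' @param intervals interval data.frame.
#' @return logical vector, one element per point.
#' @export
points_in_intervals <- function(chrom, pos, intervals) {
  chrom <- normalize_chrom(chrom)
  hit <- logical(length(pos))
  for (ch in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    idx <- which(chrom == ch)
    if (!length(idx)) next
    # sorted sweep: for each point find whether some interval covers it
    o <- order(iv$start)
    starts <- iv$start[o]; ends <- iv$end[o]
    # findInterval gives the last start <= pos; intervals may overlap, so
    # compare against the cumulative max end up to that index
    j <- findInterval(pos[idx], starts)
    cmax <- cummax(ends)
    hit[idx] <- j >= 1L & pos[idx] <= cmax[pmax(j, 1L)]
  }
  hit
}

#' Jaccard overlap of two interval sets
#'
#' Intersection length over union length, both in base pairs.
#'
#' @param a,b interval data.frames.
#' @return numeric scalar in `[0, 1]` (0 when both are empty).
#' @export
jaccard_intervals <- function(a, b) {
  la <- sum(interval_width(a)); lb <- sum(interval_width(b))
  if (la + lb == 0) return(0)
  li <- sum(interval_width(intersect_intervals(a, b)))
  li / (la + lb - li)
}
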