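# Interval and coverage utilities.
#
# Intervals use BED semantics: 0-based half-open [start, end). Binned
# tracks are data.frames of explicit [start, end) bins with one value per
# bin, directly writable as bedGraph. Coverage arithmetic is delegated to
# IRanges run-length encodings.

#' Construct an interval set (BED semantics)
#'
#' @param chrom chromosome label (recycled).
#' @param start,end 0-based half-open coordinates; `0 <= start < end`.
#' @param label free-text set label.
#' @param chrom_length optional chromosome length for bounds checking.
#' @return an `interval_set` data.frame with columns `chrom`, `start`,
#'   `end`.
#' @export
interval_set <- function(chrom = character(), start = numeric(),
                         end = numeric(), label = "intervals",
                         chrom_length = NULL) {
  chrom <- as.character(chrom)
  if (length(chrom) == 1L && length(start) > 1L) {
    chrom <- rep(chrom, length(start))
  }
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (length(start) && (any(start < 0) || any(start >= end))) {
    stop("intervals must satisfy 0 <= start < end")
  }
  if (!is.null(chrom_length) && length(end) && any(end > chrom_length)) {
    stop("interval beyond chromosome end")
  }
  structure(data.frame(chrom = chrom, start = as.numeric(start),
                       end = as.numeric(end), stringsAsFactors = FALSE),
            class = c("interval_set", "data.frame"), label = label)
}

# IRanges representation of a single-chromosome interval set (1-based)
.as_iranges <- function(intervals) {
  IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
}

.bin_bounds <- function(chrom_length, bin_size) {
  starts <- seq(0, chrom_length - 1, by = bin_size)
  ends <- pmin(starts + bin_size, chrom_length)
  list(starts = starts, ends = ends)
}

.binned_track <- function(chrom, starts, ends, values, semantics, bin_size) {
  structure(data.frame(chrom = chrom, start = starts, end = ends,
                       value = values, stringsAsFactors = FALSE),
            class = c("binned_track", "data.frame"),
            semantics = semantics, bin_size = bin_size)
}

#' Summed alignment depth track
#'
#' For every genomic position, sums the full lengths (`end - start`) of all
#' alignments overlapping that position; the per-position values are then
#' averaged within bins. Long alignments therefore contribute their entire
#' length at every position they cover — a deliberately length-weighted
#' depth that makes positions under long, repeat-family-associated
#' alignments stand out, which is how centromeres are localized from
#' satellite-repeat alignments. Computed as a weighted interval sweep
#' (coverage weighted by interval width), never by per-position loops.
#'
#' @param intervals an [interval_set()] on a single chromosome.
#' @param chrom_length chromosome length in bp.
#' @param bin_size bin width in bp; the last partial bin is retained and
#'   averaged over its true width.
#' @return a `binned_track` data.frame (`semantics = "summed_length"`).
#' @export
summed_alignment_depth <- function(intervals, chrom_length, bin_size = 100000) {
  stopifnot(chrom_length >= 1, bin_size >= 1)
  chrom <- if (nrow(intervals)) intervals$chrom[1] else NA_character_
  if (nrow(intervals) && length(unique(intervals$chrom)) > 1L) {
    stop("intervals must be on a single chromosome")
  }
  if (nrow(intervals) && any(intervals$end > chrom_length)) {
    stop("interval beyond chromosome end")
  }
  bb <- .bin_bounds(chrom_length, bin_size)
  if (nrow(intervals) == 0L) {
    return(.binned_track(chrom, bb$starts, bb$ends, rep(0, length(bb$starts)),
                         "summed_length", bin_size))
  }
  ir <- .as_iranges(intervals)
  cov <- IRanges::coverage(ir, weight = IRanges::width(ir),
                           width = as.integer(chrom_length))
  v <- IRanges::Views(cov, start = bb$starts + 1L, end = bb$ends)
  .binned_track(chrom, bb$starts, bb$ends, IRanges::viewMeans(v),
                "summed_length", bin_size)
}

#' Fraction of bases covered per bin
#'
#' Per bin, the fraction of bases covered by the union of the intervals
#' clipped to the bin (union semantics: duplicated or overlapping
#' intervals do not inflate the fraction).
#'
#' @inheritParams summed_alignment_depth
#' @return a `binned_track` (`semantics = "fraction_covered"`, values in
#'   \[0, 1\]).
#' @export
binned_fraction_covered <- function(intervals, chrom_length, bin_size = 100000) {
  stopifnot(chrom_length >= 1, bin_size >= 1)
  chrom <- if (nrow(intervals)) intervals$chrom[1] else NA_character_
  if (nrow(intervals) && length(unique(intervals$chrom)) > 1L) {
    stop("intervals must be on a single chromosome")
  }
  if (nrow(intervals) && any(intervals$end > chrom_length)) {
    stop("interval beyond chromosome end")
  }
  bb <- .bin_bounds(chrom_length, bin_size)
  if (nrow(intervals) == 0L) {
    return(.binned_track(chrom, bb$starts, bb$ends, rep(0, length(bb$starts)),
                         "fraction_covered", bin_size))
  }
  ir <- IRanges::reduce(.as_iranges(intervals))
  cov <- IRanges::coverage(ir, width = as.integer(chrom_length))
  v <- IRanges::Views(cov, start = bb$starts + 1L, end = bb$ends)
  .binned_track(chrom, bb$starts, bb$ends, IRanges::viewMeans(v),
                "fraction_covered", bin_size)
}

#' Locate the most likely centromere position from a depth track
#'
#' Median-smooths the track over `smooth_bins` bins and returns the center
#' of the maximal bin. Ties are broken leftmost.
#'
#' @param track a `binned_track` (typically from
#'   [summed_alignment_depth()]).
#' @param smooth_bins odd window size for running-median smoothing
#'   (default 3; 1 disables smoothing).
#' @return list with `position` (bp, bin center) and `score` (smoothed
#'   value at the argmax).
#' @export
locate_centromere <- function(track, smooth_bins = 3) {
  stopifnot(inherits(track, "binned_track"), nrow(track) >= 1)
  v <- track$value
  if (all(v == 0)) stop("no signal: all-zero track")
  if (smooth_bins > 1 && length(v) > smooth_bins) {
    if (smooth_bins %% 2 == 0) smooth_bins <- smooth_bins + 1
    v <- stats::runmed(v, k = smooth_bins, endrule = "median")
  }
  i <- which.max(v) # which.max returns the first (leftmost) maximum
  list(position = (track$start[i] + track$end[i]) / 2, score = v[i])
}

#' Target-linked Hi-C mate profile
#'
#' Selects read pairs with at least one mate inside `target` and counts
#' the other mate in bins anchored at the target's boundaries: bins extend
#' left from `target$start` and right from `target$end`, with the target
#' itself forming its own (central) bin. Pairs with both mates in the
#' target are counted once, in the target's own bin. With
#' `log_scale = TRUE` values are `log10(count + 1)`, so a score of 0 means
#' 0 interactions.
#'
#' @param pairs a [pair_set()].
#' @param target a one-row [interval_set()] (0-based half-open) on a
#'   chromosome present in `pairs`' size map.
#' @param bin_size bin width in bp.
#' @param log_scale report `log10(count + 1)` (default) instead of raw
#'   counts.
#' @return a `binned_track` whose bins tile `[0, chrom_length)` anchored
#'   at the target boundaries; attribute `n_selected` records the number
#'   of selected pairs.
#' @export
target_linked_profile <- function(pairs, target, bin_size, log_scale = TRUE) {
  stopifnot(inherits(pairs, "pair_set"), nrow(target) == 1L, bin_size >= 1)
  chrom <- target$chrom[1]
  sizes <- attr(pairs, "chrom_sizes")
  if (!chrom %in% names(sizes)) stop("target chromosome not in pair set")
  L <- sizes[[chrom]]
  if (target$end[1] > L) stop("target outside chromosome")
  ts <- target$start[1]
  te <- target$end[1]

  # 1-based point positions; in-target means within (ts, te] 1-based,
  # i.e. the 0-based half-open interval [ts, te)
  p <- pairs[pairs$chrom_a == chrom & pairs$chrom_b == chrom, , drop = FALSE]
  in_t_a <- p$pos_a > ts & p$pos_a <= te
  in_t_b <- p$pos_b > ts & p$pos_b <= te
  sel <- in_t_a | in_t_b
  p <- p[sel, , drop = FALSE]
  in_t_a <- in_t_a[sel]
  in_t_b <- in_t_b[sel]

  # bins anchored at target boundaries
  if (ts > 0) {
    left_ends <- rev(seq(ts, 1e-9, by = -bin_size))
    left_starts <- pmax(left_ends - bin_size, 0)
  } else {
    left_ends <- left_starts <- numeric(0)
  }
  if (te < L) {
    right_starts <- seq(te, L - 1e-9, by = bin_size)
    right_ends <- pmin(right_starts + bin_size, L)
  } else {
    right_starts <- right_ends <- numeric(0)
  }
  starts <- c(left_starts, ts, right_starts)
  ends <- c(left_ends, te, right_ends)

  counts <- rep(0, length(starts))
  target_bin <- length(left_starts) + 1L
  locate_bin <- function(pos) { # pos is 1-based; bin of the 0-based point pos-1
    findInterval(pos - 1 + 0.5, starts)
  }
  both <- in_t_a & in_t_b
  counts[target_bin] <- sum(both)
  other <- ifelse(in_t_a, p$pos_b, p$pos_a)[!both]
  if (length(other)) {
    tab <- table(locate_bin(other))
    idx <- as.integer(names(tab))
    counts[idx] <- counts[idx] + as.numeric(tab)
  }
  vals <- if (log_scale) log10(counts + 1) else counts
  out <- .binned_track(chrom, starts, ends, vals,
                       if (log_scale) "log10_count" else "summed_length",
                       bin_size)
  attr(out, "counts") <- counts
  attr(out, "n_selected") <- nrow(p)
  out
}
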