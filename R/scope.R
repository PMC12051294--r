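# SCOPE — Scatter Clusters Of Paired Ends.
#
# Long-range intra-chromosomal Hi-C interaction loci (fold-back regions,
# inversion-breakpoint dots) appear as off-diagonal dots in the scatter of
# mate1 vs mate2 positions. SCOPE filters pairs by MAPQ and inter-mate
# distance, smooths the scatter with a 2D binned kernel density estimate,
# thresholds the grid at a high quantile, hierarchically clusters the peak
# bins, summarizes clusters, keeps those whose loci are separated by a
# minimum distance, and optionally subtracts calls explained by a gDNA
# control or known SV breakpoints.

#' SCOPE parameter set
#'
#' Defaults follow the wide-estimate fold-back-region run: MAPQ >= 10,
#' inter-mate distance >= 1 Mb, a 1024 x 1024 grid (~68.9 kb bins on a
#' 70.5 Mb chromosome) with 250 kb Gaussian bandwidths, the 99.8th grid
#' percentile as peak threshold, 12 peak clusters, and a 5 Mb
#' median-separation filter. A narrow-estimate parameterization uses
#' `min_intermate_distance = 5e6`, `grid_size = 2048`, 50 kb bandwidths,
#' `peak_quantile = 0.9999` and `k_clusters = 4`.
#'
#' @param min_mapq minimum pair MAPQ (min of mates).
#' @param min_intermate_distance minimum |pos_b - pos_a| in bp.
#' @param grid_size grid dimension m (m x m bins).
#' @param bandwidth_x,bandwidth_y Gaussian kernel SDs in bp.
#' @param peak_quantile grid quantile above which bins are peaks.
#' @param k_clusters number of peak clusters to cut the tree into.
#' @param min_separation minimum |median_y - median_x| to retain a
#'   cluster, in bp.
#' @param kernel_truncation kernel support half-width in SDs (default 4).
#' @param linkage hierarchical clustering linkage for peak bins.
#' @return a `scope_params` list.
#' @export
scope_params <- function(min_mapq = 10, min_intermate_distance = 1e6,
                         grid_size = 1024, bandwidth_x = 250000,
                         bandwidth_y = 250000, peak_quantile = 0.998,
                         k_clusters = 12, min_separation = 5e6,
                         kernel_truncation = 4, linkage = "complete") {
  stopifnot(grid_size >= 2, bandwidth_x > 0, bandwidth_y > 0,
            peak_quantile > 0, peak_quantile < 1, k_clusters >= 1,
            kernel_truncation > 0)
  structure(list(min_mapq = min_mapq,
                 min_intermate_distance = min_intermate_distance,
                 grid_size = grid_size, bandwidth_x = bandwidth_x,
                 bandwidth_y = bandwidth_y, peak_quantile = peak_quantile,
                 k_clusters = k_clusters, min_separation = min_separation,
                 kernel_truncation = kernel_truncation, linkage = linkage),
            class = "scope_params")
}

#' Filter Hi-C pairs by MAPQ and inter-mate distance
#'
#' Retains pairs with `mapq >= min_mapq` and, for intra-chromosomal pairs,
#' `|pos_b - pos_a| >= min_intermate_distance`. With `intra_only = TRUE`
#' (default) inter-chromosomal pairs are dropped. Output is canonicalized
#' (`pos_a <= pos_b`).
#'
#' @param pairs a [pair_set()].
#' @param params a [scope_params()].
#' @param intra_only drop inter-chromosomal pairs (default TRUE).
#' @return a filtered `pair_set` (possibly empty).
#' @export
filter_pairs <- function(pairs, params, intra_only = TRUE) {
  stopifnot(inherits(pairs, "pair_set"), inherits(params, "scope_params"))
  keep <- pairs$mapq >= params$min_mapq
  intra <- pairs$chrom_a == pairs$chrom_b
  if (intra_only) keep <- keep & intra
  d <- abs(pairs$pos_b - pairs$pos_a)
  keep <- keep & (!intra | d >= params$min_intermate_distance)
  out <- pairs[keep, , drop = FALSE]
  pair_set(out$chrom_a, out$pos_a, out$chrom_b, out$pos_b, out$mapq,
           chrom_sizes = attr(pairs, "chrom_sizes"),
           source = attr(pairs, "source"))
}

# discrete Gaussian kernel sampled at bin offsets; half-width `hw` bins
.gauss_taps <- function(bandwidth, bin_width, hw) {
  j <- seq(-hw, hw)
  exp(-0.5 * (j * bin_width / bandwidth)^2)
}

# separable convolution of matrix z with taps wx (rows / x axis) and wy
# (columns / y axis), zero-padded at the borders
.sep_convolve <- function(z, wx, wy) {
  m <- nrow(z)
  n <- ncol(z)
  hwx <- (length(wx) - 1L) / 2L
  out <- matrix(0, m, n)
  for (t in seq_along(wx)) {
    off <- t - 1L - hwx # source row = dest row - off
    src <- seq_len(m) - off
    ok <- src >= 1L & src <= m
    if (any(ok)) out[ok, ] <- out[ok, ] + wx[t] * z[src[ok], , drop = FALSE]
  }
  z2 <- out
  hwy <- (length(wy) - 1L) / 2L
  out <- matrix(0, m, n)
  for (t in seq_along(wy)) {
    off <- t - 1L - hwy
    src <- seq_len(n) - off
    ok <- src >= 1L & src <= n
    if (any(ok)) out[, ok] <- out[, ok] + wy[t] * z2[, src[ok], drop = FALSE]
  }
  out
}

#' 2D binned kernel density estimate
#'
#' Linear-bins points onto an `m x m` grid of bin centers over the square
#' extent `[start, end]^2`, convolves with a separable Gaussian kernel
#' (SDs `bandwidths`, truncated at `truncation` SDs, zero-padded at the
#' grid borders), and normalizes so that `sum(z) * bin_width^2 == 1`.
#'
#' Linear binning splits each point's unit mass between the two bracketing
#' bin centers on each axis in proportion to proximity; a point exactly on
#' a bin center is binned exactly, so for such points the binned estimate
#' equals the direct kernel sum ([naive_kde_2d()]) to floating-point
#' accuracy (with truncation disabled). Off-center points incur the usual
#' O((bin_width/bandwidth)^2) linear-binning approximation error.
#'
#' @param x,y point coordinates in bp (equal length, >= 1 point).
#' @param extent numeric length-2 `(start, end)` of the grid on both axes.
#' @param m grid size (>= 2).
#' @param bandwidths numeric length-2 Gaussian SDs `(bx, by)` in bp.
#' @param truncation kernel support half-width in SDs; `Inf` disables
#'   truncation (full-grid kernel).
#' @return a `kde_grid` list: `start`, `end`, `m`, `bin_width`, `x_centers`,
#'   `y_centers`, and the `m x m` density matrix `z` (rows: x bins).
#' @export
binned_kde_2d <- function(x, y, extent, m, bandwidths, truncation = 4) {
  stopifnot(length(x) == length(y), m >= 2, length(extent) == 2,
            extent[2] > extent[1])
  if (length(x) < 1) stop("at least one point required")
  if (any(bandwidths <= 0)) stop("bandwidths must be > 0")
  start <- extent[1]
  end <- extent[2]
  bw <- (end - start) / m
  centers <- start + (seq_len(m) - 0.5) * bw
  # fractional grid coordinate: 1 at first center, m at last
  gx <- (x - start) / bw + 0.5
  gy <- (y - start) / bw + 0.5
  gx <- pmin(pmax(gx, 1), m)
  gy <- pmin(pmax(gy, 1), m)
  ix <- pmin(floor(gx), m - 1)
  iy <- pmin(floor(gy), m - 1)
  fx <- gx - ix
  fy <- gy - iy
  z <- matrix(0, m, m)
  acc <- function(i, j, w) {
    idx <- (j - 1) * m + i
    tab <- rowsum(w, idx)
    z[as.integer(rownames(tab))] <<- z[as.integer(rownames(tab))] + tab[, 1]
  }
  acc(ix,     iy,     (1 - fx) * (1 - fy))
  acc(ix + 1, iy,     fx * (1 - fy))
  acc(ix,     iy + 1, (1 - fx) * fy)
  acc(ix + 1, iy + 1, fx * fy)
  hw <- if (is.finite(truncation)) {
    tx <- ceiling(truncation * bandwidths[1] / bw)
    ty <- ceiling(truncation * bandwidths[2] / bw)
    c(min(tx, m - 1L), min(ty, m - 1L))
  } else {
    c(m - 1L, m - 1L)
  }
  wx <- .gauss_taps(bandwidths[1], bw, hw[1])
  wy <- .gauss_taps(bandwidths[2], bw, hw[2])
  z <- .sep_convolve(z, wx, wy)
  z <- z / (sum(z) * bw * bw)
  structure(list(start = start, end = end, m = as.integer(m), bin_width = bw,
                 x_centers = centers, y_centers = centers, z = z),
            class = "kde_grid")
}

#' Direct (naive) 2D kernel density estimate
#'
#' Test oracle for [binned_kde_2d()]: evaluates the sum of bivariate
#' Gaussian kernels at every bin center directly (O(N m^2)), with the same
#' normalization convention (`sum(z) * bin_width^2 == 1`). Intended for
#' small inputs only.
#'
#' @inheritParams binned_kde_2d
#' @return a `kde_grid`.
#' @export
naive_kde_2d <- function(x, y, extent, m, bandwidths) {
  stopifnot(length(x) == length(y), m >= 2)
  if (length(x) < 1) stop("at least one point required")
  if (any(bandwidths <= 0)) stop("bandwidths must be > 0")
  start <- extent[1]
  end <- extent[2]
  bw <- (end - start) / m
  centers <- start + (seq_len(m) - 0.5) * bw
  kx <- outer(centers, x, function(c, p) exp(-0.5 * ((c - p) / bandwidths[1])^2))
  ky <- outer(centers, y, function(c, p) exp(-0.5 * ((c - p) / bandwidths[2])^2))
  z <- kx %*% t(ky) # z[i, j] = sum_p kx[i,p] * ky[j,p]
  z <- z / (sum(z) * bw * bw)
  structure(list(start = start, end = end, m = as.integer(m), bin_width = bw,
                 x_centers = centers, y_centers = centers, z = z),
            class = "kde_grid")
}

#' Call peak bins above a grid quantile
#'
#' The threshold is the linear-interpolation empirical quantile
#' ([stats::quantile()] type 7) of all `m^2` grid values, zeros included;
#' bins strictly greater than the threshold are peaks, returned in
#' row-major order (x index varying last).
#'
#' @param grid a `kde_grid`.
#' @param peak_quantile quantile in (0, 1).
#' @return data.frame with columns `i`, `j` (bin indices), `x`, `y`
#'   (bin-center coordinates) and `z`; zero rows when no bin exceeds the
#'   threshold (e.g. a constant grid).
#' @export
call_peak_bins <- function(grid, peak_quantile = 0.998) {
  stopifnot(inherits(grid, "kde_grid"), peak_quantile > 0, peak_quantile < 1)
  thr <- stats::quantile(grid$z, peak_quantile, names = FALSE, type = 7)
  hit <- which(grid$z > thr, arr.ind = TRUE)
  out <- data.frame(i = hit[, 1], j = hit[, 2],
                    x = grid$x_centers[hit[, 1]],
                    y = grid$y_centers[hit[, 2]],
                    z = grid$z[hit])
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Hierarchically cluster peak bins
#'
#' Agglomerative clustering of peak bins under Euclidean distance on their
#' genomic bin-center coordinates (so the x and y axes share a scale), cut
#' into exactly `k` clusters. Bins are processed in row-major order, which
#' fixes tie-breaking.
#'
#' @param peaks data.frame from [call_peak_bins()].
#' @param k number of clusters; must not exceed the number of peaks.
#' @param linkage linkage method for [stats::hclust()].
#' @return `peaks` with an added integer `cluster` column (1..k).
#' @export
cluster_peak_bins <- function(peaks, k, linkage = "complete") {
  if (nrow(peaks) < k) {
    stop("fewer peak bins (", nrow(peaks), ") than requested clusters (", k, ")")
  }
  if (k == 1L || nrow(peaks) == 1L) {
    peaks$cluster <- 1L
    return(peaks)
  }
  hc <- stats::hclust(stats::dist(peaks[, c("x", "y")]), method = linkage)
  peaks$cluster <- stats::cutree(hc, k = k)
  peaks
}

#' Summarize peak clusters
#'
#' Per cluster: median/min/max of member bin-center coordinates on each
#' axis (median of an even-sized set is the midpoint of the two central
#' values), the summit (member bin with maximal density; ties broken by
#' smaller row-major index), and the separation `|median_y - median_x|`.
#'
#' @param clustered data.frame from [cluster_peak_bins()].
#' @param grid the `kde_grid` the peaks came from (records `bin_width`).
#' @return a `peak_cluster` data.frame, one row per cluster, ordered by
#'   cluster id.
#' @export
summarize_clusters <- function(clustered, grid) {
  stopifnot(nrow(clustered) > 0, "cluster" %in% names(clustered))
  rows <- lapply(sort(unique(clustered$cluster)), function(cl) {
    b <- clustered[clustered$cluster == cl, , drop = FALSE]
    b <- b[order(b$i, b$j), , drop = FALSE]
    s <- which.max(b$z) # first max = smallest row-major index
    data.frame(cluster = cl, n_bins = nrow(b),
               median_x = stats::median(b$x), median_y = stats::median(b$y),
               min_x = min(b$x), max_x = max(b$x),
               min_y = min(b$y), max_y = max(b$y),
               summit_x = b$x[s], summit_y = b$y[s], summit_z = b$z[s],
               separation = abs(stats::median(b$y) - stats::median(b$x)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("peak_cluster", "data.frame"),
            bin_width = grid$bin_width)
}

#' Filter clusters by median separation
#'
#' Retains clusters whose `|median_y - median_x|` is at least
#' `min_separation`, i.e. pairs of loci separated by that distance.
#'
#' @param clusters a `peak_cluster` data.frame from
#'   [summarize_clusters()].
#' @param min_separation bp.
#' @return the retained rows.
#' @export
filter_by_separation <- function(clusters, min_separation = 5e6) {
  keep <- clusters$separation >= min_separation
  out <- clusters[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# convert summarized clusters to interaction calls with anchor intervals
# (bin-edge extents, 0-based half-open)
.clusters_to_calls <- function(clusters, chrom, bin_width, label = "") {
  if (nrow(clusters) == 0L) {
    out <- data.frame(chrom = character(), anchor1_start = numeric(),
                      anchor1_end = numeric(), anchor2_start = numeric(),
                      anchor2_end = numeric(), summit_x = numeric(),
                      summit_y = numeric(), summit_z = numeric(),
                      n_bins = integer(), separation = numeric(),
                      label = character(), stringsAsFactors = FALSE)
    return(structure(out, class = c("interaction_call", "data.frame")))
  }
  h <- bin_width / 2
  out <- data.frame(chrom = chrom,
                    anchor1_start = pmax(clusters$min_x - h, 0),
                    anchor1_end = clusters$max_x + h,
                    anchor2_start = pmax(clusters$min_y - h, 0),
                    anchor2_end = clusters$max_y + h,
                    summit_x = clusters$summit_x,
                    summit_y = clusters$summit_y,
                    summit_z = clusters$summit_z,
                    n_bins = clusters$n_bins,
                    separation = clusters$separation,
                    label = label, stringsAsFactors = FALSE)
  # anchor_1 must precede anchor_2 on the chromosome
  swap <- out$anchor1_start > out$anchor2_start
  if (any(swap)) {
    a <- out[swap, c("anchor1_start", "anchor1_end")]
    out[swap, c("anchor1_start", "anchor1_end")] <-
      out[swap, c("anchor2_start", "anchor2_end")]
    out[swap, c("anchor2_start", "anchor2_end")] <- a
  }
  structure(out, class = c("interaction_call", "data.frame"))
}

.overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

#' Subtract background calls and SV breakpoints
#'
#' Removes any call whose two anchors both overlap the (padded) anchors of
#' a control call — in either anchor order — or either of whose anchors
#' overlaps a (padded) SV breakpoint interval. All other calls are
#' retained unchanged. Used to discard apparent long-range interactions
#' explained by structural differences visible in a gDNA control.
#'
#' @param calls,control_calls `interaction_call` data.frames on the same
#'   chromosome/coordinate system (control may be empty or NULL).
#' @param sv_breakpoints optional [interval_set()] of SV breakpoints.
#' @param pad padding in bp applied to control anchors and SV intervals
#'   (default 0; one bin width is a sensible choice).
#' @return the retained calls.
#' @export
subtract_background <- function(calls, control_calls = NULL,
                                sv_breakpoints = NULL, pad = 0) {
  if (nrow(calls) == 0L) return(calls)
  drop <- rep(FALSE, nrow(calls))
  if (!is.null(control_calls) && nrow(control_calls)) {
    for (i in seq_len(nrow(calls))) {
      for (j in seq_len(nrow(control_calls))) {
        if (calls$chrom[i] != control_calls$chrom[j]) next
        c1s <- control_calls$anchor1_start[j] - pad
        c1e <- control_calls$anchor1_end[j] + pad
        c2s <- control_calls$anchor2_start[j] - pad
        c2e <- control_calls$anchor2_end[j] + pad
        direct <-
          .overlaps(calls$anchor1_start[i], calls$anchor1_end[i], c1s, c1e) &&
          .overlaps(calls$anchor2_start[i], calls$anchor2_end[i], c2s, c2e)
        swapped <-
          .overlaps(calls$anchor1_start[i], calls$anchor1_end[i], c2s, c2e) &&
          .overlaps(calls$anchor2_start[i], calls$anchor2_end[i], c1s, c1e)
        if (direct || swapped) {
          drop[i] <- TRUE
          break
        }
      }
    }
  }
  if (!is.null(sv_breakpoints) && nrow(sv_breakpoints)) {
    for (i in seq_len(nrow(calls))) {
      if (drop[i]) next
      same <- sv_breakpoints$chrom == calls$chrom[i]
      if (!any(same)) next
      ss <- sv_breakpoints$start[same] - pad
      se <- sv_breakpoints$end[same] + pad
      hit1 <- any(.overlaps(calls$anchor1_start[i], calls$anchor1_end[i], ss, se))
      hit2 <- any(.overlaps(calls$anchor2_start[i], calls$anchor2_end[i], ss, se))
      if (hit1 || hit2) drop[i] <- TRUE
    }
  }
  out <- calls[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the SCOPE pipeline end to end
#'
#' Composition: [filter_pairs()] -> [binned_kde_2d()] (per chromosome,
#' extent `[0, chrom_length]`) -> [call_peak_bins()] ->
#' [cluster_peak_bins()] -> [summarize_clusters()] ->
#' [filter_by_separation()] -> optional [subtract_background()].
#'
#' @param pairs a [pair_set()].
#' @param params a [scope_params()].
#' @param chrom chromosome(s) to analyze (default: all with filtered
#'   pairs).
#' @param control optional `pair_set` of gDNA control pairs, run through
#'   the same pipeline; its calls are subtracted.
#' @param svs optional [interval_set()] of SV breakpoints to subtract.
#' @param pad padding for background subtraction; default one bin width.
#' @param keep_grid keep the `kde_grid` objects in the result (large).
#' @return an `interaction_call` data.frame with attributes `params`
#'   (the full parameter list, a machine-readable run log), `n_input`,
#'   `n_filtered`, and optionally `grids`.
#' @export
run_scope <- function(pairs, params = scope_params(), chrom = NULL,
                      control = NULL, svs = NULL, pad = NULL,
                      keep_grid = FALSE) {
  stopifnot(inherits(pairs, "pair_set"), inherits(params, "scope_params"))
  sizes <- attr(pairs, "chrom_sizes")
  filtered <- filter_pairs(pairs, params, intra_only = TRUE)
  if (is.null(chrom)) chrom <- unique(filtered$chrom_a)
  grids <- list()
  calls_list <- list()
  for (ch in chrom) {
    p <- filtered[filtered$chrom_a == ch, , drop = FALSE]
    if (nrow(p) == 0L) next
    grid <- binned_kde_2d(p$pos_a, p$pos_b, extent = c(0, sizes[[ch]]),
                          m = params$grid_size,
                          bandwidths = c(params$bandwidth_x, params$bandwidth_y),
                          truncation = params$kernel_truncation)
    if (keep_grid) grids[[ch]] <- grid
    peaks <- call_peak_bins(grid, params$peak_quantile)
    if (nrow(peaks) == 0L) {
      warning("no peak bins on ", ch)
      next
    }
    if (nrow(peaks) < params$k_clusters) {
      stop("fewer peak bins (", nrow(peaks), ") than k_clusters (",
           params$k_clusters, ") on ", ch)
    }
    clustered <- cluster_peak_bins(peaks, params$k_clusters, params$linkage)
    clusters <- summarize_clusters(clustered, grid)
    clusters <- filter_by_separation(clusters, params$min_separation)
    calls_list[[ch]] <- .clusters_to_calls(clusters, ch, grid$bin_width)
  }
  calls <- if (length(calls_list)) {
    do.call(rbind, calls_list)
  } else {
    warning("no interaction calls")
    .clusters_to_calls(data.frame(), NA_character_, 0)
  }
  rownames(calls) <- NULL
  if (is.null(pad)) {
    pad <- (if (length(chrom)) sizes[[chrom[1]]] else 0) / params$grid_size
  }
  if (!is.null(control) || !is.null(svs)) {
    control_calls <- NULL
    if (!is.null(control)) {
      control_calls <- run_scope(control, params, chrom = chrom,
                                 keep_grid = FALSE)
    }
    calls <- subtract_background(calls, control_calls, svs, pad = pad)
  }
  attr(calls, "params") <- c(unclass(params),
                             list(chrom = chrom, pad = pad,
                                  subtracted = !is.null(control) || !is.null(svs)))
  attr(calls, "n_input") <- nrow(pairs)
  attr(calls, "n_filtered") <- nrow(filtered)
  if (keep_grid) attr(calls, "grids") <- grids
  class(calls) <- c("interaction_call", "data.frame")
  calls
}
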