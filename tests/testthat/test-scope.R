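# SCOPE: pair filtering, binned KDE vs the direct oracle, peak calling,
# clustering, summaries, separation filtering, background subtraction.

test_that("pair filter applies MAPQ and inter-mate distance thresholds", {
  p <- scope_params(min_mapq = 10, min_intermate_distance = 5e6)
  pairs <- pair_set(rep("chrX", 3), c(1e6, 1e6, 1e6),
                    rep("chrX", 3), c(7e6, 3e6, 7e6),
                    mapq = c(60, 60, 5),
                    chrom_sizes = c(chrX = 1e7))
  out <- filter_pairs(pairs, p)
  # 6 Mb apart at MAPQ 60 kept; 2 Mb dropped; pair MAPQ 5 (min of mates)
  # dropped
  expect_equal(nrow(out), 1L)
  expect_equal(out$pos_b, 7e6)

  # inter-chromosomal pairs drop under intra_only, survive otherwise
  mixed <- pair_set(c("chrX", "chrX"), c(1e6, 1e6), c("chr2", "chrX"),
                    c(2e6, 8e6), mapq = c(60, 60),
                    chrom_sizes = c(chrX = 1e7, chr2 = 1e7))
  expect_equal(nrow(filter_pairs(mixed, p)), 1L)
  expect_equal(nrow(filter_pairs(mixed, p, intra_only = FALSE)), 2L)
})

test_that("pair sets canonicalize intra-chromosomal mate order", {
  ps <- pair_set("chrX", 8e6, "chrX", 2e6, 60, chrom_sizes = c(chrX = 1e7))
  expect_equal(ps$pos_a, 2e6)
  expect_equal(ps$pos_b, 8e6)
  expect_error(pair_set("chrX", 1, "chrY", 1, 60,
                        chrom_sizes = c(chrX = 10)), "absent")
  expect_error(pair_set("chrX", 11, "chrX", 1, 60,
                        chrom_sizes = c(chrX = 10)), "beyond")
})

test_that("binned KDE equals the direct Gaussian-sum oracle at bin centers", {
  set.seed(42)
  m <- 64
  L <- 1e6
  centers <- (seq_len(m) - 0.5) * (L / m)
  for (rep in 1:3) {
    x <- sample(centers, 100, replace = TRUE)
    y <- sample(centers, 100, replace = TRUE)
    bw <- c(runif(1, 2e4, 6e4), runif(1, 2e4, 6e4))
    zb <- binned_kde_2d(x, y, c(0, L), m, bw, truncation = Inf)
    zn <- naive_kde_2d(x, y, c(0, L), m, bw)
    expect_lt(max(abs(zb$z - zn$z)), 1e-6 * max(zn$z))
  }
})

test_that("binned KDE approximates the oracle for off-center points", {
  # linear binning carries O((bin/bandwidth)^2) error for points off the
  # bin centers; with bandwidth ~5 bins this stays below 1% relative
  set.seed(43)
  m <- 64
  L <- 1e6
  x <- runif(200, 0, L)
  y <- runif(200, 0, L)
  zb <- binned_kde_2d(x, y, c(0, L), m, c(8e4, 8e4), truncation = Inf)
  zn <- naive_kde_2d(x, y, c(0, L), m, c(8e4, 8e4))
  expect_lt(max(abs(zb$z - zn$z)), 0.01 * max(zn$z))
})

test_that("KDE grids are normalized and localize a single point", {
  g <- binned_kde_2d(5e5, 5e5, c(0, 1e6), 64, c(1e3, 1e3))
  expect_equal(sum(g$z) * g$bin_width^2, 1, tolerance = 1e-6)
  idx <- which(g$z == max(g$z), arr.ind = TRUE)
  expect_equal(g$x_centers[idx[1]], 5e5, tolerance = g$bin_width)
  expect_equal(g$y_centers[idx[2]], 5e5, tolerance = g$bin_width)

  # naive peak height for an isolated centered point ~ 1/(2 pi bx by)
  gn <- naive_kde_2d(5e5 + g$bin_width / 2, 5e5 + g$bin_width / 2,
                     c(0, 1e6), 64, c(5e4, 5e4))
  expect_equal(max(gn$z), 1 / (2 * pi * 5e4 * 5e4), tolerance = 1e-3)

  # symmetric two-point input gives a symmetric grid
  gs <- naive_kde_2d(c(3e5, 7e5), c(3e5, 7e5), c(0, 1e6), 32, c(5e4, 5e4))
  expect_equal(gs$z, gs$z[rev(seq_len(32)), rev(seq_len(32))],
               tolerance = 1e-9)
  expect_error(binned_kde_2d(numeric(), numeric(), c(0, 1), 8, c(1, 1)),
               "at least one point")
  expect_error(binned_kde_2d(1, 1, c(0, 10), 8, c(0, 1)), "bandwidths")
})

test_that("binned KDE agrees with the reference bkde2D implementation", {
  # independent cross-check against KernSmooth's binned KDE; grids are
  # aligned by matching bin centers to its (m-1)-spaced grid points
  set.seed(5)
  n <- 400
  x <- runif(n, 2e5, 8e5)
  y <- runif(n, 2e5, 8e5)
  m <- 64
  delta <- 1e6 / (m - 1)
  g <- binned_kde_2d(x, y, c(-delta / 2, 1e6 + delta / 2), m, c(5e4, 5e4),
                     truncation = Inf)
  ref <- KernSmooth::bkde2D(cbind(x, y), bandwidth = c(5e4, 5e4),
                            gridsize = c(m, m),
                            range.x = list(c(0, 1e6), c(0, 1e6)))
  expect_lt(max(abs(g$x_centers - ref$x1)), 1e-6)
  expect_gt(stats::cor(as.vector(g$z), as.vector(ref$fhat)), 0.9999)
  expect_lt(max(abs(g$z - ref$fhat)), 0.01 * max(ref$fhat))
})

test_that("grid bin widths match the scaffold geometry", {
  L <- x_scaffold_length()
  g1 <- binned_kde_2d(1e6, 2e6, c(0, L), 1024, c(250000, 250000))
  expect_equal(g1$bin_width, 68855.33, tolerance = 1e-6)
  g2 <- binned_kde_2d(1e6, 2e6, c(0, L), 2048, c(50000, 50000))
  expect_equal(g2$bin_width, 34427.67, tolerance = 1e-6)
})

test_that("peak calling thresholds at the grid quantile, strictly", {
  g <- binned_kde_2d(5e5, 5e5, c(0, 1e6), 32, c(1e3, 1e3))
  g$z[] <- 0
  g$z[10, 20] <- 10
  peaks <- call_peak_bins(g, 0.998)
  expect_equal(nrow(peaks), 1L)
  expect_equal(peaks$i, 10)
  expect_equal(peaks$j, 20)

  # constant grid: no bin strictly exceeds the quantile
  g$z[] <- 1
  expect_equal(nrow(call_peak_bins(g, 0.998)), 0L)
})

test_that("raising the peak quantile never adds peak bins", {
  set.seed(3)
  x <- runif(500, 0, 1e6)
  y <- runif(500, 0, 1e6)
  g <- binned_kde_2d(x, y, c(0, 1e6), 64, c(5e4, 5e4))
  prev <- NULL
  for (q in c(0.9, 0.95, 0.99, 0.999)) {
    cur <- call_peak_bins(g, q)
    key <- paste(cur$i, cur$j)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- paste(cur$i, cur$j)
  }
})

test_that("peak-bin clustering separates well-spaced blobs", {
  # three blobs far apart: each must come back as one cluster
  blob <- function(cx, cy) {
    expand.grid(x = cx + c(-1e4, 0, 1e4), y = cy + c(-1e4, 0, 1e4))
  }
  b <- rbind(blob(1e6, 5e6), blob(8e6, 2e7), blob(3e7, 4e7))
  peaks <- data.frame(i = seq_len(nrow(b)), j = seq_len(nrow(b)),
                      x = b$x, y = b$y, z = 1)
  cl <- cluster_peak_bins(peaks, k = 3)
  grp <- split(seq_len(nrow(b)), cl$cluster)
  expect_equal(length(grp), 3L)
  expect_setequal(lapply(grp, range),
                  list(c(1, 9), c(10, 18), c(19, 27)))

  # k = 1 puts everything together; k > n errors
  expect_equal(unique(cluster_peak_bins(peaks, 1)$cluster), 1L)
  expect_error(cluster_peak_bins(peaks[1:2, ], 5), "fewer")
})

test_that("cluster summaries use midpoint medians and row-major summit ties", {
  g <- list(bin_width = 1e4)
  class(g) <- "kde_grid"
  peaks <- data.frame(i = c(1, 2, 3, 4), j = c(1, 2, 3, 4),
                      x = c(10e6, 20e6, 30e6, 40e6),
                      y = c(15e6, 25e6, 35e6, 45e6),
                      z = c(2, 5, 5, 1), cluster = 1L)
  s <- summarize_clusters(peaks, g)
  expect_equal(s$median_x, 25e6) # even count: midpoint of 20 and 30
  expect_equal(s$min_x, 10e6)
  expect_equal(s$max_x, 40e6)
  # summit tie between rows 2 and 3 resolved to the smaller row-major index
  expect_equal(s$summit_x, 20e6)
  expect_equal(s$separation, abs(s$median_y - s$median_x))

  single <- summarize_clusters(peaks[2, ], g)
  expect_equal(single$median_x, single$summit_x)
  expect_equal(single$min_y, single$max_y)
})

test_that("separation filter keeps only distant locus pairs", {
  g <- list(bin_width = 1e4)
  class(g) <- "kde_grid"
  peaks <- data.frame(i = 1:2, j = 1:2, x = c(10e6, 10e6),
                      y = c(40e6, 12e6), z = 1, cluster = c(1L, 2L))
  s <- summarize_clusters(peaks, g)
  kept <- filter_by_separation(s, 5e6)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$median_y, 40e6)
})

test_that("background subtraction removes matched and SV-overlapping calls", {
  call <- function(a1s, a1e, a2s, a2e) {
    data.frame(chrom = "chrX", anchor1_start = a1s, anchor1_end = a1e,
               anchor2_start = a2s, anchor2_end = a2e,
               summit_x = (a1s + a1e) / 2, summit_y = (a2s + a2e) / 2,
               summit_z = 1, n_bins = 1L,
               separation = (a2s + a2e) / 2 - (a1s + a1e) / 2,
               label = "", stringsAsFactors = FALSE)
  }
  calls <- rbind(call(1e6, 2e6, 3e7, 3.1e7), call(5e6, 6e6, 5e7, 5.1e7))
  # identical control call removes the first; the second has no match
  kept <- subtract_background(calls, control_calls = calls[1, ])
  expect_equal(kept$anchor1_start, 5e6)
  # swapped anchor order still matches
  swapped <- call(1e6, 2e6, 3e7, 3.1e7)
  tmp <- swapped[, c("anchor1_start", "anchor1_end")]
  swapped[, c("anchor1_start", "anchor1_end")] <-
    swapped[, c("anchor2_start", "anchor2_end")]
  swapped[, c("anchor2_start", "anchor2_end")] <- tmp
  kept2 <- subtract_background(calls, control_calls = swapped)
  expect_equal(kept2$anchor1_start, 5e6)
  # SV breakpoint overlapping either anchor removes a call
  svs <- interval_set("chrX", 5.05e6, 5.06e6)
  kept3 <- subtract_background(calls, sv_breakpoints = svs)
  expect_equal(kept3$anchor1_start, 1e6)
  # no-op when nothing overlaps
  expect_equal(nrow(subtract_background(calls)), 2L)
})

test_that("run_scope is invariant to input pair order", {
  cfg <- sim_hic_config("chrX", 2e7, 20000,
                        loops = list(loop_spec(3e6, 1.5e7, 0.1)),
                        seed = 17)
  ps <- simulate_hic_pairs(cfg)
  params <- scope_params(grid_size = 256, k_clusters = 4,
                         min_intermate_distance = 1e6)
  calls1 <- run_scope(ps, params)
  perm <- withr::with_seed(1, sample(nrow(ps)))
  ps2 <- pair_set(ps$chrom_a[perm], ps$pos_a[perm], ps$chrom_b[perm],
                  ps$pos_b[perm], ps$mapq[perm],
                  chrom_sizes = attr(ps, "chrom_sizes"))
  calls2 <- run_scope(ps2, params)
  expect_equal(as.data.frame(calls1), as.data.frame(calls2))
})

test_that("run_scope returns an empty call set when nothing passes filters", {
  ps <- pair_set("chrX", c(1e6, 2e6), "chrX", c(1.5e6, 2.5e6), c(60, 60),
                 chrom_sizes = c(chrX = 1e7))
  expect_warning(out <- run_scope(ps, scope_params(min_intermate_distance = 5e6)),
                 "no interaction calls")
  expect_equal(nrow(out), 0L)
})

test_that("run_scope records a machine-readable parameter log", {
  cfg <- sim_hic_config("chrX", 2e7, 5000,
                        loops = list(loop_spec(3e6, 1.5e7, 0.2)),
                        seed = 19)
  calls <- run_scope(simulate_hic_pairs(cfg),
                     scope_params(grid_size = 128, k_clusters = 2))
  p <- attr(calls, "params")
  expect_equal(p$grid_size, 128)
  expect_equal(p$k_clusters, 2)
  expect_false(p$subtracted)
  expect_equal(attr(calls, "n_input"), 5000L)
})
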