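# Synthetic-data generators.
#
# These emulate the statistical structure the downstream analyses assume:
# SCO tables under a tunable inter-chromosomal translocation rate,
# intra-chromosomal Hi-C pairs with a power-law distance decay plus
# planted multi-Mb loop anchors and tight SV-like dots (with a matched
# loop-free control), and repeat-alignment intervals concentrated around
# a planted centromere. All generators are deterministic under their
# config seed; multi-stream runs derive per-stream seeds from a root seed
# with derive_seed().

#' Configuration for the SCO-table simulator
#'
#' @param chrom_labels_a chromosome labels of species A (species B uses
#'   the same labels, so the counterpart of each chromosome is itself).
#' @param sco_counts per-chromosome SCO counts (recycled; sum must be
#'   > 0).
#' @param theta translocation probability in \[0, 1\]: each SCO keeps its
#'   counterpart chromosome with probability `1 - theta`, otherwise it is
#'   reassigned.
#' @param reassignment `"uniform_any"` (uniform over all species-B labels,
#'   counterpart included) or `"uniform_other"` (uniform over the other
#'   labels).
#' @param seed integer seed.
#' @return a `sim_sco_config` list.
#' @export
sim_sco_config <- function(chrom_labels_a, sco_counts, theta = 0,
                           reassignment = c("uniform_any", "uniform_other"),
                           seed = 1L) {
  reassignment <- match.arg(reassignment)
  if (length(chrom_labels_a) == 0L) stop("empty chromosome set")
  sco_counts <- rep_len(as.integer(sco_counts), length(chrom_labels_a))
  if (any(sco_counts < 0) || sum(sco_counts) <= 0) {
    stop("sco_counts must be non-negative with positive sum")
  }
  if (theta < 0 || theta > 1) stop("theta must be in [0, 1]")
  structure(list(chrom_labels_a = as.character(chrom_labels_a),
                 sco_counts = sco_counts, theta = theta,
                 reassignment = reassignment, seed = as.integer(seed)),
            class = "sim_sco_config")
}

#' Simulate an SCO chromosome-assignment table
#'
#' Each SCO is placed on a species-A chromosome per `sco_counts`; its
#' species-B assignment equals the counterpart label with probability
#' `1 - theta` and is otherwise reassigned per the config. Models the
#' accumulation of inter-chromosomal translocations with evolutionary
#' distance.
#'
#' @param config a [sim_sco_config()].
#' @param species_a,species_b species names recorded on the table.
#' @return a [sco_table()].
#' @export
simulate_sco_table <- function(config, species_a = "sim_A",
                               species_b = "sim_B") {
  stopifnot(inherits(config, "sim_sco_config"))
  labs <- config$chrom_labels_a
  chrom_a <- rep(labs, config$sco_counts)
  n <- length(chrom_a)
  with_seed(config$seed, {
    chrom_b <- chrom_a
    move <- stats::runif(n) < config$theta
    if (any(move)) {
      if (config$reassignment == "uniform_any") {
        chrom_b[move] <- sample(labs, sum(move), replace = TRUE)
      } else {
        for (i in which(move)) {
          others <- labs[labs != chrom_a[i]]
          if (length(others) == 0L) next # single-chromosome genome
          chrom_b[i] <- if (length(others) == 1L) others else sample(others, 1L)
        }
      }
    }
    sco_table(sprintf("og%06d", seq_len(n)), chrom_a, chrom_b,
              chrom_labels_a = labs, chrom_labels_b = labs,
              species_a = species_a, species_b = species_b)
  })
}

#' Loop specification for the Hi-C simulator
#'
#' A planted long-range interaction: pairs are drawn with mate 1 at
#' `anchor_x` and mate 2 at `anchor_y`, each plus independent Gaussian
#' jitter. The default 150 kb jitter gives fold-back-region-scale dots.
#'
#' @param anchor_x,anchor_y anchor positions in bp (`anchor_x <
#'   anchor_y`).
#' @param weight mixture weight (probability a pair comes from this
#'   loop).
#' @param jitter_sd Gaussian SD of pair positions around the anchors, bp.
#' @return a `loop_spec` list.
#' @export
loop_spec <- function(anchor_x, anchor_y, weight, jitter_sd = 150000) {
  if (!(anchor_x < anchor_y)) stop("anchor_x must be < anchor_y")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  structure(list(anchor_x = anchor_x, anchor_y = anchor_y, weight = weight,
                 jitter_sd = jitter_sd), class = "loop_spec")
}

#' SV-dot specification for the Hi-C simulator
#'
#' A tight structural-variant-like dot: same sampling scheme as
#' [loop_spec()] but with a small default jitter (10 kb), emulating the
#' contrast between tiny SV dots and large fold-back-region dots.
#'
#' @param pos_x,pos_y dot position in bp.
#' @param weight mixture weight.
#' @param jitter_sd Gaussian SD in bp.
#' @return an `sv_spec` list.
#' @export
sv_spec <- function(pos_x, pos_y, weight, jitter_sd = 10000) {
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  structure(list(pos_x = pos_x, pos_y = pos_y, weight = weight,
                 jitter_sd = jitter_sd), class = "sv_spec")
}

#' Configuration for the intra-chromosomal Hi-C pair simulator
#'
#' Pairs are a mixture of background contacts (mate 1 uniform, inter-mate
#' distance following a truncated shifted power law
#' `density ~ (d + d0)^(-alpha)`, emulating the distance decay of Hi-C
#' interaction frequencies), planted loops, and planted SV dots. Loop and
#' SV weights plus the implied background weight must sum to 1.
#'
#' @param chrom_label chromosome name.
#' @param chrom_length chromosome length, bp.
#' @param n_pairs number of pairs to draw.
#' @param alpha decay exponent (> 0), default 1.
#' @param d0 decay offset in bp, default 10 kb.
#' @param loops list of [loop_spec()].
#' @param svs list of [sv_spec()].
#' @param mapq_model list `(fraction_low, low_value, high_value)`: each
#'   pair's MAPQ is `low_value` with probability `fraction_low`, else
#'   `high_value`.
#' @param seed integer seed.
#' @return a `sim_hic_config` list.
#' @export
sim_hic_config <- function(chrom_label = "chrX", chrom_length,
                           n_pairs, alpha = 1, d0 = 10000,
                           loops = list(), svs = list(),
                           mapq_model = list(fraction_low = 0.1,
                                             low_value = 0,
                                             high_value = 60),
                           seed = 1L) {
  stopifnot(chrom_length > 0, n_pairs >= 0, alpha > 0, d0 >= 0)
  for (l in loops) {
    stopifnot(inherits(l, "loop_spec"))
    if (l$anchor_x < 0 || l$anchor_y >= chrom_length) {
      stop("loop anchor outside chromosome")
    }
  }
  for (s in svs) {
    stopifnot(inherits(s, "sv_spec"))
    if (min(s$pos_x, s$pos_y) < 0 || max(s$pos_x, s$pos_y) >= chrom_length) {
      stop("SV position outside chromosome")
    }
  }
  w <- sum(vapply(loops, `[[`, numeric(1), "weight"),
           vapply(svs, `[[`, numeric(1), "weight"))
  if (w > 1 + 1e-9) stop("loop + SV weights exceed 1")
  structure(list(chrom_label = chrom_label, chrom_length = chrom_length,
                 n_pairs = as.integer(n_pairs), alpha = alpha, d0 = d0,
                 loops = loops, svs = svs, mapq_model = mapq_model,
                 seed = as.integer(seed)),
            class = "sim_hic_config")
}

#' Inverse CDF of the truncated shifted power-law distance distribution
#'
#' Distances have density proportional to `(d + d0)^(-alpha)` on
#' `[0, d_max]`. Closed-form inverse CDF; the reference sampler used both
#' by the simulator and as an independent oracle in tests.
#'
#' @param u uniforms in \[0, 1\].
#' @param alpha decay exponent > 0.
#' @param d0 offset, bp (> 0 required when `alpha >= 1`).
#' @param d_max truncation point, bp (scalar or one per element of `u`).
#' @return distances in bp.
#' @export
powerlaw_distance_quantile <- function(u, alpha, d0, d_max) {
  stopifnot(alpha > 0, all(d_max >= 0), d0 >= 0)
  if (d0 <= 0 && alpha >= 1) stop("d0 must be > 0 when alpha >= 1")
  if (abs(alpha - 1) < 1e-12) {
    # F(d) = log((d + d0)/d0) / log((d_max + d0)/d0)
    d0 * ((d_max + d0) / d0)^u - d0
  } else {
    a1 <- 1 - alpha
    lo <- d0^a1
    hi <- (d_max + d0)^a1
    (lo + u * (hi - lo))^(1 / a1) - d0
  }
}

.sample_mapq <- function(n, model) {
  ifelse(stats::runif(n) < model$fraction_low, model$low_value,
         model$high_value)
}

.simulate_hic <- function(config, include_loops) {
  L <- config$chrom_length
  n <- config$n_pairs
  specs <- c(config$loops, config$svs)
  weights <- vapply(specs, `[[`, numeric(1), "weight")
  kinds <- rep(c("loop", "sv"),
               c(length(config$loops), length(config$svs)))
  if (!include_loops) weights[kinds == "loop"] <- 0
  bg_w <- 1 - sum(weights)
  with_seed(config$seed, {
    comp <- if (length(weights)) {
      sample.int(length(weights) + 1L, n, replace = TRUE,
                 prob = c(weights, bg_w))
    } else {
      rep.int(1L, n) # background only
    }
    pos_a <- numeric(n)
    pos_b <- numeric(n)
    bg <- if (length(weights)) comp == length(weights) + 1L else comp == 1L
    if (any(bg)) {
      # mate 1 uniform; inter-mate distance follows the power law truncated
      # to the chromosome remaining downstream of mate 1 (avoids piling
      # long-distance pairs into the far corner of the map)
      p1 <- stats::runif(sum(bg), 0, L)
      d <- powerlaw_distance_quantile(stats::runif(sum(bg)), config$alpha,
                                      config$d0, pmax(L - 1 - p1, 0))
      pos_a[bg] <- p1
      pos_b[bg] <- pmin(p1 + d, L - 1)
    }
    for (s in seq_along(specs)) {
      hit <- comp == s
      if (!any(hit)) next
      sp <- specs[[s]]
      ax <- if (kinds[s] == "loop") sp$anchor_x else sp$pos_x
      ay <- if (kinds[s] == "loop") sp$anchor_y else sp$pos_y
      m <- sum(hit)
      # jitter clipped (not resampled) at chromosome bounds; slightly
      # inflates edge density for anchors near the ends
      pos_a[hit] <- pmin(pmax(ax + stats::rnorm(m, 0, sp$jitter_sd), 0), L - 1)
      pos_b[hit] <- pmin(pmax(ay + stats::rnorm(m, 0, sp$jitter_sd), 0), L - 1)
    }
    mapq <- .sample_mapq(n, config$mapq_model)
    component <- c(kinds, "background")[comp]
    sizes <- stats::setNames(L, config$chrom_label)
    ps <- pair_set(config$chrom_label, floor(pos_a) + 1,
                   config$chrom_label, floor(pos_b) + 1, mapq,
                   chrom_sizes = sizes, source = "simulated")
    attr(ps, "component") <- component
    ps
  })
}

#' Simulate intra-chromosomal Hi-C contact pairs
#'
#' Draws exactly `n_pairs` pairs from the background/loop/SV mixture of
#' the config (see [sim_hic_config()]); positions are canonicalized so
#' `pos_a <= pos_b` and MAPQs follow the config's two-point model. The
#' mixture component of each pair is recorded in the `"component"`
#' attribute for diagnostics.
#'
#' @param config a [sim_hic_config()].
#' @return a [pair_set()].
#' @export
simulate_hic_pairs <- function(config) {
  stopifnot(inherits(config, "sim_hic_config"))
  .simulate_hic(config, include_loops = TRUE)
}

#' Simulate a matched gDNA-style control pair set
#'
#' Identical to [simulate_hic_pairs()] but with all loop weights forced
#' to 0: the control carries the background decay and the SV dots (which
#' reflect structural differences, not spatial interactions) but no
#' loops. Used to test background subtraction.
#'
#' @param config a [sim_hic_config()].
#' @return a [pair_set()].
#' @export
simulate_control_pairs <- function(config) {
  stopifnot(inherits(config, "sim_hic_config"))
  .simulate_hic(config, include_loops = FALSE)
}

#' Simulate repeat-alignment intervals around a planted centromere
#'
#' Interval midpoints are `centromere_pos` plus Laplace noise with scale
#' `decay_scale`, clipped to the chromosome; lengths are exponential with
#' the given mean. Emulates satellite-repeat-family alignments
#' concentrating near centromeres.
#'
#' @param chrom_length chromosome length, bp.
#' @param centromere_pos planted centromere position, bp (in
#'   `[0, chrom_length)`).
#' @param n_intervals number of intervals.
#' @param mean_len mean interval length, bp.
#' @param decay_scale Laplace scale of midpoint displacement, bp (0 puts
#'   every midpoint at the centromere).
#' @param seed integer seed.
#' @param chrom chromosome label.
#' @return an [interval_set()].
#' @export
simulate_repeat_alignments <- function(chrom_length, centromere_pos,
                                       n_intervals, mean_len = 500,
                                       decay_scale = 200000, seed = 1L,
                                       chrom = "chrX") {
  if (centromere_pos < 0 || centromere_pos >= chrom_length) {
    stop("centromere_pos must be in [0, chrom_length)")
  }
  stopifnot(n_intervals >= 0, mean_len > 0, decay_scale >= 0)
  if (n_intervals == 0L) {
    return(interval_set(character(), numeric(), numeric(),
                        label = "repeat_alignments"))
  }
  with_seed(seed, {
    u <- stats::runif(n_intervals) - 0.5
    lap <- if (decay_scale > 0) {
      -decay_scale * sign(u) * log(1 - 2 * abs(u))
    } else {
      rep(0, n_intervals)
    }
    mid <- pmin(pmax(centromere_pos + lap, 0), chrom_length - 1)
    len <- pmax(stats::rexp(n_intervals, rate = 1 / mean_len), 1)
    start <- pmax(floor(mid - len / 2), 0)
    end <- pmin(ceiling(mid + len / 2), chrom_length)
    end <- pmax(end, start + 1)
    interval_set(chrom, start, end, label = "repeat_alignments",
                 chrom_length = chrom_length)
  })
}
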