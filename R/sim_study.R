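# Canonical X-chromosome simulation layout.
#
# The default conditions for testing SCOPE mirror the structure of the
# fungus-gnat X contact map: a 70,507,862 bp chromosome carrying three
# fold-back regions whose pairwise interactions give three far
# off-diagonal dots, one breakpoint-pair dot from the X' paracentric
# inversion, a set of short-separation (< 5 Mb) dots standing in for the
# small structural variants and shorter-range interactions that populate
# the rest of the peak clusters, and optional tiny SV dots used to test
# gDNA-control subtraction.

#' Planted X-chromosome landmark positions
#'
#' Landmark coordinates (bp) on the 70,507,862 bp X scaffold,
#' back-computed from the observed landmark distances: FBR3 12.3 Mb from
#' the 3' end, FBR2 42.7 Mb before FBR3, FBR1 10.3 Mb before FBR2, the
#' centromere 3.49 Mb before FBR1, and the X' inversion breakpoints
#' 0.62 Mb before FBR1 and 4.65 Mb after FBR3.
#'
#' @return named list: `length`, `centromere`, `fbr1`, `fbr2`, `fbr3`,
#'   `bp5`, `bp3` (all bp).
#' @export
x_landmarks <- function() {
  L <- x_scaffold_length()
  fbr3 <- L - 12.3e6
  fbr2 <- fbr3 - 42.7e6
  fbr1 <- fbr2 - 10.3e6
  list(length = L, centromere = fbr1 - 3.49e6,
       fbr1 = fbr1, fbr2 = fbr2, fbr3 = fbr3,
       bp5 = fbr1 - 0.62e6, bp3 = fbr3 + 4.65e6)
}

#' Default Hi-C simulation config for the X chromosome
#'
#' Mixture, fixed once as the package's canonical test condition:
#'
#' * four far loops — the three FBR pairs plus the breakpoint pair —
#'   at weight 0.02 each with 150 kb jitter (FBR-scale dots);
#' * eight short-separation dots (1.5-3.5 Mb separations, 100 kb jitter,
#'   weight 0.005 each) emulating the sub-5 Mb features that fill the
#'   remaining peak clusters on the real map;
#' * optionally, `n_svs` tiny SV dots (10 kb jitter, weight 0.01 each) at
#'   far separations, which a matched gDNA control also carries;
#' * the remaining weight in power-law background (`alpha = 1`,
#'   `d0 = 10 kb`).
#'
#' @param n_pairs number of pairs (default 200,000).
#' @param seed integer seed.
#' @param n_svs number of planted tiny SV dots (0-2; default 0).
#' @return a [sim_hic_config()].
#' @export
sim_x_config <- function(n_pairs = 200000, seed = 1L, n_svs = 0) {
  lm <- x_landmarks()
  loops <- list(
    loop_spec(lm$fbr1, lm$fbr2, 0.02),
    loop_spec(lm$fbr1, lm$fbr3, 0.02),
    loop_spec(lm$fbr2, lm$fbr3, 0.02),
    loop_spec(lm$bp5, lm$bp3, 0.02)
  )
  near <- list( # (x Mb, y Mb): separations 1.5-3.5 Mb, spread along X
    c(10, 12.5), c(18, 20), c(25, 28), c(30, 33.5),
    c(38, 39.5), c(44, 47), c(52, 54), c(65, 67)
  )
  loops <- c(loops, lapply(near, function(p) {
    loop_spec(p[1] * 1e6, p[2] * 1e6, 0.005, jitter_sd = 100000)
  }))
  svs <- list()
  if (n_svs >= 1) svs <- c(svs, list(sv_spec(23e6, 48e6, 0.01)))
  if (n_svs >= 2) svs <- c(svs, list(sv_spec(35e6, 61e6, 0.01)))
  sim_hic_config(chrom_label = "chrX", chrom_length = lm$length,
                 n_pairs = n_pairs, alpha = 1, d0 = 10000,
                 loops = loops, svs = svs, seed = seed)
}

#' True far-interaction anchors of the default X simulation
#'
#' The four planted interactions with separation >= 5 Mb (three FBR pairs
#' and the breakpoint pair), as an (x, y) matrix in bp, ordered by x then
#' y.
#'
#' @param n_svs as passed to [sim_x_config()]; SV dot positions are
#'   appended when > 0 (they too are separated by >= 5 Mb).
#' @return numeric matrix with columns `x`, `y`.
#' @export
sim_x_truth <- function(n_svs = 0) {
  lm <- x_landmarks()
  m <- rbind(c(lm$bp5, lm$bp3), c(lm$fbr1, lm$fbr2), c(lm$fbr1, lm$fbr3),
             c(lm$fbr2, lm$fbr3))
  if (n_svs >= 1) m <- rbind(m, c(23e6, 48e6))
  if (n_svs >= 2) m <- rbind(m, c(35e6, 61e6))
  colnames(m) <- c("x", "y")
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}
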