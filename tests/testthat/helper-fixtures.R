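# Shared helpers: small constructors and independent oracles used across
# test files. Oracles here are written directly from first principles and
# never call the implementation path they check.

# printed joint-probability matrix for the B. coprophila / P. hygida
# comparison (rows: B. cop X, II, III, IV; columns: P. hyg X, C, B, A)
table_joint_bcop_phyg <- function() {
  matrix(c(0.253, 0.002, 0.002, 0.003,
           0.000, 0.166, 0.001, 0.003,
           0.002, 0.001, 0.241, 0.004,
           0.002, 0.002, 0.002, 0.315),
         nrow = 4, byrow = TRUE,
         dimnames = list(c("X", "II", "III", "IV"),
                         c("X", "C", "B", "A")))
}

# independent entropy oracle (plain formula, no package call)
oracle_entropy <- function(p) {
  p <- as.numeric(p)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# independent inverse CDF of the shifted truncated power law
oracle_powerlaw_q <- function(u, alpha, d0, d_max) {
  if (abs(alpha - 1) < 1e-12) {
    d0 * exp(u * log((d_max + d0) / d0)) - d0
  } else {
    a1 <- 1 - alpha
    (d0^a1 + u * ((d_max + d0)^a1 - d0^a1))^(1 / a1) - d0
  }
}

# tiny pair set on a 10 Mb chromosome
tiny_pairs <- function(pos_a, pos_b, mapq = 60, chrom = "chrX", L = 1e7) {
  pair_set(chrom, pos_a, chrom, pos_b, rep_len(mapq, length(pos_a)),
           chrom_sizes = stats::setNames(L, chrom))
}

extdata <- function(f) system.file("extdata", f, package = "chromoscope")
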