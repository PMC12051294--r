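# Polytene-map distance expectations.
#
# Historical polytene chromosome maps divide each chromosome into zones of
# visually similar length, each split into sub-zones (A, B, C). Assuming
# nucleotide lengths of zones are also similar, a chromosome-scale scaffold
# length converts map distances (counted in sub-zones) into expected
# nucleotide distances between landmarks, which can be compared to the
# observed scaffold distances.

#' Polytene chromosome model
#'
#' @param label chromosome name.
#' @param scaffold_length scaffold length in bp.
#' @param n_zones number of polytene map zones (14 for the fungus-gnat X).
#' @param subzones_per_zone sub-zones per zone (3: A, B, C).
#' @return a `polytene_chromosome` list.
#' @export
polytene_chromosome <- function(label, scaffold_length, n_zones = 14,
                                subzones_per_zone = 3) {
  stopifnot(n_zones >= 1, subzones_per_zone >= 1, scaffold_length > 0)
  structure(list(label = label, scaffold_length = scaffold_length,
                 n_zones = n_zones, subzones_per_zone = subzones_per_zone),
            class = "polytene_chromosome")
}

#' Average sub-zone length in Mb
#'
#' `scaffold_length / (n_zones * subzones_per_zone)`, in Mb. For the
#' 70,507,862 bp X scaffold with 14 zones of 3 sub-zones this is
#' 1.678759 Mb (zone length 5.036276 Mb).
#'
#' @param chrom a [polytene_chromosome()].
#' @return sub-zone length in Mb.
#' @export
subzone_length <- function(chrom) {
  stopifnot(inherits(chrom, "polytene_chromosome"))
  chrom$scaffold_length / (chrom$n_zones * chrom$subzones_per_zone) / 1e6
}

#' Average zone length in Mb
#'
#' @inheritParams subzone_length
#' @return zone length in Mb.
#' @export
zone_length <- function(chrom) {
  stopifnot(inherits(chrom, "polytene_chromosome"))
  chrom$scaffold_length / chrom$n_zones / 1e6
}

#' Expected nucleotide distance for a polytene map distance
#'
#' @param n_subzones map distance in sub-zones (fractional allowed).
#' @param subzone_len sub-zone length in Mb (see [subzone_length()]).
#' @return expected distance in Mb (unrounded; see [round_printed()] for
#'   the reporting convention).
#' @export
expected_distance <- function(n_subzones, subzone_len) {
  if (anyNA(n_subzones) || any(n_subzones < 0)) stop("n_subzones must be >= 0")
  n_subzones * subzone_len
}

#' Round half away from zero at a fixed number of decimals
#'
#' Reporting convention for expected distances: 1 decimal place, except 3
#' decimal places for sub-Mb values. Round-half-away-from-zero (unlike
#' [round()]'s round-half-even) matches how the distances are reported.
#'
#' @param x numeric.
#' @param digits decimal places; if `NULL`, uses 3 for `|x| < 1` and 1
#'   otherwise (per element).
#' @return rounded numeric.
#' @export
round_printed <- function(x, digits = NULL) {
  if (is.null(digits)) digits <- ifelse(abs(x) < 1, 3L, 1L)
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Expected vs observed landmark distance table
#'
#' Converts polytene map distances (sub-zone counts) between pairs of
#' landmarks into expected Mb distances on the scaffold and tabulates them
#' against observed scaffold distances.
#'
#' @param chrom a [polytene_chromosome()].
#' @param rows data.frame with columns `locus_1`, `locus_2`, `n_subzones`
#'   and optionally `observed_mb`.
#' @return data.frame with added columns `expected_mb` (unrounded),
#'   `expected_mb_printed` (reporting precision), and — when `observed_mb`
#'   is present — `deviation_mb` and `relative_deviation`.
#' @examples
#' x <- polytene_chromosome("X", 70507862)
#' build_expectation_table(x, data.frame(
#'   locus_1 = "Centromere", locus_2 = "FBR1",
#'   n_subzones = 2, observed_mb = 3.49))
#' @export
build_expectation_table <- function(chrom, rows) {
  stopifnot(inherits(chrom, "polytene_chromosome"))
  needed <- c("locus_1", "locus_2", "n_subzones")
  if (!all(needed %in% names(rows))) {
    stop("rows must have columns ", paste(needed, collapse = ", "))
  }
  out <- as.data.frame(rows)
  if (nrow(out) == 0L) {
    out$expected_mb <- numeric(0)
    out$expected_mb_printed <- numeric(0)
    return(out)
  }
  sl <- subzone_length(chrom)
  out$expected_mb <- expected_distance(out$n_subzones, sl)
  out$expected_mb_printed <- round_printed(out$expected_mb)
  if ("observed_mb" %in% names(out)) {
    out$deviation_mb <- out$observed_mb - out$expected_mb
    out$relative_deviation <- ifelse(out$expected_mb > 0,
                                     out$deviation_mb / out$expected_mb, NA_real_)
  }
  out
}

#' Recover a scaffold length from assembly summary statistics
#'
#' For an assembly of exactly four chromosome-scale scaffolds whose summary
#' table reports the total length, the maximum and minimum scaffold
#' lengths, and the N50, the remaining scaffold's length is
#' `total - max - min - n50`. With four sequences the N50 is the
#' second-longest scaffold and the median is the mean of the two middle
#' lengths, so `2 * median - n50` recovers the same value — used as a
#' cross-check when the median is supplied.
#'
#' @param total sum of scaffold lengths (bp).
#' @param max_len,min_len longest and shortest scaffold lengths (bp).
#' @param n50 assembly N50 (bp).
#' @param median_len optional median scaffold length (bp) for the
#'   cross-check; an error is raised if the two derivations disagree.
#' @return the remaining scaffold length in bp.
#' @export
scaffold_length_from_summary <- function(total, max_len, min_len, n50,
                                         median_len = NULL) {
  len <- total - max_len - min_len - n50
  if (len <= 0) stop("inconsistent summary statistics")
  if (!is.null(median_len)) {
    alt <- 2 * median_len - n50
    if (alt != len) {
      stop("derivations disagree: total-based ", len, " vs median-based ", alt)
    }
  }
  len
}

#' Assembly summary statistics for the Bcop_v2 primary scaffolds
#'
#' Published contiguity statistics of the four chromosome-scale scaffolds
#' (X, II, III, IV) of the Bradysia coprophila Bcop_v2 assembly (GenBank
#' GCA_014529535.2). The X scaffold length is not printed as a single
#' number; [scaffold_length_from_summary()] recovers it as
#' `total - max - min - n50 = 70,507,862 bp`.
#'
#' @return named list: `total`, `max_len`, `min_len`, `n50`, `median_len`
#'   (all bp).
#' @export
bcop_v2_primary_summary <- function() {
  list(total = 296980291, max_len = 97081274, min_len = 58343183,
       n50 = 71047972, median_len = 70777917)
}

#' X chromosome scaffold length (bp)
#'
#' Derived from [bcop_v2_primary_summary()] via
#' [scaffold_length_from_summary()] with the median cross-check.
#'
#' @return 70,507,862.
#' @export
x_scaffold_length <- function() {
  s <- bcop_v2_primary_summary()
  scaffold_length_from_summary(s$total, s$max_len, s$min_len, s$n50,
                               s$median_len)
}

#' Landmark distances on the fungus-gnat X chromosome
#'
#' The six landmark pairs on the X scaffold — centromere, fold-back regions
#' FBR1-3, the X' paracentric-inversion breakpoints, and the 3' scaffold
#' end — with their polytene map distances in sub-zones and the observed
#' scaffold distances in Mb.
#'
#' @return data.frame with columns `locus_1`, `locus_2`, `n_subzones`,
#'   `observed_mb`.
#' @export
fbr_distance_rows <- function() {
  data.frame(
    locus_1 = c("Centromere", "5' X' breakpoint", "FBR1", "FBR2", "FBR3",
                "FBR3"),
    locus_2 = c("FBR1", "FBR1", "FBR2", "FBR3", "3' X' breakpoint",
                "3' end of chromosome"),
    n_subzones = c(2, 0.5, 7, 26, 3, 6),
    observed_mb = c(3.49, 0.620, 10.3, 42.7, 4.65, 12.3),
    stringsAsFactors = FALSE
  )
}
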