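#' Construct a Hi-C pair set
#'
#' A `pair_set` is a data.frame of contact records with columns `chrom_a`,
#' `pos_a`, `chrom_b`, `pos_b` (1-based point positions of the two mates)
#' and `mapq` (the pair MAPQ, taken as the minimum of the two mates'
#' MAPQs), carrying the chromosome size map and a source label as
#' attributes. Intra-chromosomal pairs are canonicalized so that
#' `pos_a <= pos_b`.
#'
#' @param chrom_a,pos_a,chrom_b,pos_b mate chromosomes and 1-based
#'   positions.
#' @param mapq pair mapping quality (min of mates).
#' @param chrom_sizes named numeric vector or list mapping chromosome
#'   label to length in bp.
#' @param source free-text label recording provenance.
#' @param canonicalize swap mates of intra-chromosomal pairs so
#'   `pos_a <= pos_b` (default TRUE).
#' @return a `pair_set` data.frame.
#' @export
pair_set <- function(chrom_a = character(), pos_a = numeric(),
                     chrom_b = character(), pos_b = numeric(),
                     mapq = numeric(), chrom_sizes, source = "pairs",
                     canonicalize = TRUE) {
  chrom_sizes <- unlist(chrom_sizes)
  if (any(chrom_sizes <= 0)) stop("chromosome lengths must be > 0")
  n <- length(pos_a)
  stopifnot(length(pos_b) == n, length(mapq) == n)
  chrom_a <- rep_len(as.character(chrom_a), n)
  chrom_b <- rep_len(as.character(chrom_b), n)
  bad <- setdiff(unique(c(chrom_a, chrom_b)), names(chrom_sizes))
  if (length(bad)) stop("chromosomes absent from size map: ",
                        paste(bad, collapse = ", "))
  if (n) {
    if (any(pos_a < 1) || any(pos_b < 1)) stop("positions must be >= 1")
    if (any(pos_a > chrom_sizes[chrom_a]) || any(pos_b > chrom_sizes[chrom_b])) {
      stop("position beyond chromosome end")
    }
  }
  df <- data.frame(chrom_a = chrom_a, pos_a = as.numeric(pos_a),
                   chrom_b = chrom_b, pos_b = as.numeric(pos_b),
                   mapq = as.numeric(mapq), stringsAsFactors = FALSE)
  if (canonicalize && n) {
    swap <- df$chrom_a == df$chrom_b & df$pos_a > df$pos_b
    if (any(swap)) {
      tmp <- df$pos_a[swap]
      df$pos_a[swap] <- df$pos_b[swap]
      df$pos_b[swap] <- tmp
    }
  }
  structure(df, class = c("pair_set", "data.frame"),
            chrom_sizes = chrom_sizes, source = source)
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("pair_set '%s': %d pairs on %d chromosome(s)\n",
              attr(x, "source"), nrow(x), length(attr(x, "chrom_sizes"))))
  if (nrow(x)) print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}
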