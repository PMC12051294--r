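# Readers and writers for the standard formats the pipeline touches.
#
# Conventions: BED and BEDPE are 0-based half-open; the minimal 5-column
# pair text format ("pair5": chrom1 pos1 chrom2 pos2 mapq) is 1-based
# points. BEDPE mate positions are taken as interval midpoints on read.
# Output tables are TSV with a "#"-prefixed header line for genome-browser
# compatibility.

.read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readLines(path, warn = FALSE)
}

.split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

#' Read a chromosome-sizes TSV
#'
#' Two columns, `chrom` and `length`, no header (a `#`-prefixed header is
#' tolerated and skipped).
#'
#' @param path file path.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  lines <- .read_tsv_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- .split_fields(lines)
  for (i in seq_along(fields)) {
    if (length(fields[[i]]) < 2 || is.na(suppressWarnings(as.numeric(fields[[i]][2])))) {
      stop("malformed chrom-sizes record at line ", i)
    }
  }
  sizes <- vapply(fields, function(f) as.numeric(f[2]), numeric(1))
  names(sizes) <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names(sizes))) stop("duplicated chromosome labels")
  if (any(sizes <= 0)) stop("chromosome lengths must be > 0")
  sizes
}

#' Read Hi-C pairs from BEDPE or 5-column pair text
#'
#' `dialect = "bedpe"`: standard BEDPE (chrom1 start1 end1 chrom2 start2
#' end2 \[name score strand1 strand2\]); mate positions are the interval
#' midpoints (converted to 1-based points) and MAPQ is taken from the
#' score column when present, else treated as 0 (missing MAPQ fails the
#' default SCOPE filter rather than being guessed).
#' `dialect = "pair5"`: `chrom1 pos1 chrom2 pos2 mapq` with 1-based point
#' positions; the MAPQ column is required.
#'
#' Records on chromosomes absent from `chrom_sizes`, or with out-of-bounds
#' positions, are rejected with their line numbers.
#'
#' @param path file path.
#' @param dialect `"bedpe"` or `"pair5"`.
#' @param chrom_sizes named lengths (see [read_chrom_sizes()]).
#' @param source label recorded on the result.
#' @return a [pair_set()].
#' @export
read_pairs <- function(path, dialect = c("pair5", "bedpe"), chrom_sizes,
                       source = basename(path)) {
  dialect <- match.arg(dialect)
  lines <- .read_tsv_lines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  fields <- .split_fields(lines[keep])
  if (length(fields) == 0L) {
    return(pair_set(chrom_sizes = chrom_sizes, source = source))
  }
  nmin <- if (dialect == "pair5") 5L else 6L
  num <- function(f, k, i) {
    v <- suppressWarnings(as.numeric(f[k]))
    if (is.na(v)) stop("malformed record at line ", i)
    v
  }
  recs <- lapply(seq_along(fields), function(r) {
    f <- fields[[r]]
    i <- lineno[r]
    if (length(f) < nmin) stop("malformed record at line ", i,
                               ": expected >= ", nmin, " fields")
    if (dialect == "pair5") {
      c1 <- f[1]; p1 <- num(f, 2, i); c2 <- f[3]; p2 <- num(f, 4, i)
      mq <- num(f, 5, i)
    } else {
      c1 <- f[1]; s1 <- num(f, 2, i); e1 <- num(f, 3, i)
      c2 <- f[4]; s2 <- num(f, 5, i); e2 <- num(f, 6, i)
      if (s1 < 0 || s1 >= e1 || s2 < 0 || s2 >= e2) {
        stop("malformed BEDPE intervals at line ", i)
      }
      p1 <- floor((s1 + e1) / 2) + 1 # midpoint, converted to 1-based point
      p2 <- floor((s2 + e2) / 2) + 1
      mq <- if (length(f) >= 8) suppressWarnings(as.numeric(f[8])) else NA_real_
      if (is.na(mq)) mq <- 0
    }
    if (!c1 %in% names(chrom_sizes) || !c2 %in% names(chrom_sizes)) {
      stop("unknown chromosome at line ", i)
    }
    if (p1 < 1 || p1 > chrom_sizes[[c1]] || p2 < 1 || p2 > chrom_sizes[[c2]]) {
      stop("position out of bounds at line ", i)
    }
    list(c1, p1, c2, p2, mq)
  })
  pair_set(vapply(recs, `[[`, character(1), 1),
           vapply(recs, `[[`, numeric(1), 2),
           vapply(recs, `[[`, character(1), 3),
           vapply(recs, `[[`, numeric(1), 4),
           vapply(recs, `[[`, numeric(1), 5),
           chrom_sizes = chrom_sizes, source = source)
}

#' Write Hi-C pairs
#'
#' `pair5` writes the 1-based 5-column pair text directly. `bedpe` writes
#' each 1-based point position p as the 0-based interval `[p-1, p)`, so a
#' write/read round trip is lossless for canonical records.
#'
#' @param pairs a [pair_set()].
#' @param path output path.
#' @param dialect `"pair5"` or `"bedpe"`.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path, dialect = c("pair5", "bedpe")) {
  dialect <- match.arg(dialect)
  if (dialect == "pair5") {
    df <- data.frame(pairs$chrom_a, format(pairs$pos_a, scientific = FALSE, trim = TRUE),
                     pairs$chrom_b, format(pairs$pos_b, scientific = FALSE, trim = TRUE),
                     pairs$mapq)
  } else {
    df <- data.frame(pairs$chrom_a,
                     format(pairs$pos_a - 1, scientific = FALSE, trim = TRUE),
                     format(pairs$pos_a, scientific = FALSE, trim = TRUE),
                     pairs$chrom_b,
                     format(pairs$pos_b - 1, scientific = FALSE, trim = TRUE),
                     format(pairs$pos_b, scientific = FALSE, trim = TRUE),
                     ".", pairs$mapq, "+", "+")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into an interval set
#'
#' Standard BED, 0-based half-open; only the first three columns are
#' used. Records on undeclared chromosomes or beyond chromosome ends are
#' rejected with their line numbers.
#'
#' @param path file path.
#' @param chrom_sizes optional named lengths for bounds checking.
#' @return an [interval_set()].
#' @export
read_bed <- function(path, chrom_sizes = NULL) {
  lines <- .read_tsv_lines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  lineno <- which(keep)
  fields <- .split_fields(lines[keep])
  if (length(fields) == 0L) return(interval_set())
  chrom <- character(length(fields))
  start <- numeric(length(fields))
  end <- numeric(length(fields))
  for (r in seq_along(fields)) {
    f <- fields[[r]]
    i <- lineno[r]
    if (length(f) < 3) stop("malformed BED record at line ", i)
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e) || s < 0 || s >= e) {
      stop("malformed BED record at line ", i)
    }
    if (!is.null(chrom_sizes)) {
      if (!f[1] %in% names(chrom_sizes)) stop("unknown chromosome at line ", i)
      if (e > chrom_sizes[[f[1]]]) stop("interval out of bounds at line ", i)
    }
    chrom[r] <- f[1]; start[r] <- s; end[r] <- e
  }
  interval_set(chrom, start, end, label = basename(path))
}

#' Write an interval set as BED
#'
#' @param intervals an [interval_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  df <- data.frame(intervals$chrom,
                   format(intervals$start, scientific = FALSE, trim = TRUE),
                   format(intervals$end, scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an SCO table TSV
#'
#' Expects a header line `ortho_id  chrom_a  chrom_b` (optionally
#' `#`-prefixed). Duplicate ortho_ids are rejected.
#'
#' @param path file path.
#' @param species_a,species_b species names recorded on the table.
#' @return a [sco_table()].
#' @export
read_sco_tsv <- function(path, species_a = "species_A",
                         species_b = "species_B") {
  lines <- .read_tsv_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty SCO file")
  header <- sub("^#\\s*", "", lines[1])
  hf <- strsplit(header, "\t", fixed = TRUE)[[1]]
  if (!identical(hf[1:3], c("ortho_id", "chrom_a", "chrom_b"))) {
    stop("SCO TSV must have header: ortho_id, chrom_a, chrom_b")
  }
  fields <- .split_fields(lines[-1])
  for (i in seq_along(fields)) {
    if (length(fields[[i]]) < 3) stop("malformed SCO record at line ", i + 1)
  }
  sco_table(vapply(fields, `[[`, character(1), 1),
            vapply(fields, `[[`, character(1), 2),
            vapply(fields, `[[`, character(1), 3),
            species_a = species_a, species_b = species_b)
}

#' Write a binned track as bedGraph
#'
#' @param track a `binned_track`.
#' @param path output path.
#' @param name track name for the bedGraph header.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, name = attr(track, "semantics")) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  df <- data.frame(track$chrom,
                   format(track$start, scientific = FALSE, trim = TRUE),
                   format(track$end, scientific = FALSE, trim = TRUE),
                   track$value)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a data.frame as a `#`-headered TSV
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a `#`-headered TSV written by [write_tsv_table()]
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  lines <- .read_tsv_lines(path)
  header <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  if (length(lines) == 1L) {
    df <- as.data.frame(setNames(rep(list(character()), length(header)), header))
    return(df)
  }
  df <- utils::read.table(text = lines[-1], sep = "\t", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  names(df) <- header
  df
}

#' Write a JSON run manifest
#'
#' Records parameters, seeds, package version, and md5 checksums of input
#' files so that every published number is regenerable from a single
#' command.
#'
#' @param path output path.
#' @param params named list of parameters/seeds.
#' @param inputs character vector of input file paths to checksum.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, params = list(), inputs = character()) {
  manifest <- list(
    tool = "chromoscope",
    version = as.character(utils::packageVersion("chromoscope")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = params,
    inputs = lapply(setNames(inputs, basename(inputs)), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
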