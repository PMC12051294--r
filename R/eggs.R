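# EGGS — Entropy of Gene Group Shuffling.
#
# Single-copy orthologs (SCOs) are genes present exactly once in each of two
# species. Counting how SCOs distribute over pairs of chromosomes (one from
# each species) yields a joint probability table; its entropy, normalized
# between the analytic minimum (perfectly conserved chromosomal gene sets)
# and maximum (independent assortment), measures how much inter-chromosomal
# shuffling separates the two karyotypes.

#' Construct an SCO assignment table
#'
#' A `sco_table` is a data.frame with columns `ortho_id`, `chrom_a`,
#' `chrom_b` (one row per single-copy ortholog) carrying the declared
#' chromosome label sets and species names as attributes. Only SCOs placed
#' on chromosome-scale sequences should be included; rows on unplaced
#' contigs must be removed upstream.
#'
#' @param ortho_id unique ortholog identifiers.
#' @param chrom_a,chrom_b chromosome assignment in species A / species B.
#' @param chrom_labels_a,chrom_labels_b declared chromosome label sets
#'   (default: sorted unique observed labels).
#' @param species_a,species_b species display names.
#' @return a `sco_table` data.frame.
#' @export
sco_table <- function(ortho_id, chrom_a, chrom_b,
                      chrom_labels_a = sort(unique(as.character(chrom_a))),
                      chrom_labels_b = sort(unique(as.character(chrom_b))),
                      species_a = "species_A", species_b = "species_B") {
  ortho_id <- as.character(ortho_id)
  chrom_a <- as.character(chrom_a)
  chrom_b <- as.character(chrom_b)
  if (anyDuplicated(ortho_id)) {
    stop("duplicated ortho_id: ", paste(unique(ortho_id[duplicated(ortho_id)]),
                                        collapse = ", "))
  }
  bad_a <- setdiff(chrom_a, chrom_labels_a)
  bad_b <- setdiff(chrom_b, chrom_labels_b)
  if (length(bad_a) || length(bad_b)) {
    stop("chromosome labels outside the declared sets: ",
         paste(c(bad_a, bad_b), collapse = ", "))
  }
  out <- data.frame(ortho_id = ortho_id, chrom_a = chrom_a,
                    chrom_b = chrom_b, stringsAsFactors = FALSE)
  structure(out, class = c("sco_table", "data.frame"),
            chrom_labels_a = chrom_labels_a, chrom_labels_b = chrom_labels_b,
            species_a = species_a, species_b = species_b)
}

#' Build the pseudo-counted joint probability table of SCO assignments
#'
#' Counts SCOs on every pair of inter-species chromosomes, optionally merges
#' chromosome arms (e.g. 2L + 2R -> 2), adds a pseudo-count to every cell,
#' and normalizes to joint probabilities. Marginals are the row and column
#' sums of the joint probabilities.
#'
#' @param sco a [sco_table()].
#' @param pseudo_count non-negative real added to every cell count
#'   (default 0.1). The pseudo-count is applied uniformly, including in
#'   self-comparisons, so a self-comparison MMNE is slightly above 0.
#' @param arm_merge named character vector mapping arm labels to merged
#'   labels (applies to both species' label sets where present), e.g.
#'   `c("2L" = "2", "2R" = "2")`. Empty by default.
#' @return a `joint_table`: list with `counts` (pseudo-counted matrix),
#'   `raw_counts`, `joint_probs`, `marginal_a`, `marginal_b`,
#'   `pseudo_count`, label vectors, and species names.
#' @examples
#' tab <- sco_table(paste0("og", 1:4), c("X", "X", "2", "2"),
#'                  c("X", "X", "2", "2"))
#' jt <- build_joint_table(tab, pseudo_count = 0.1)
#' jt$joint_probs
#' @export
build_joint_table <- function(sco, pseudo_count = 0.1, arm_merge = NULL) {
  if (!inherits(sco, "sco_table")) stop("`sco` must be a sco_table")
  if (nrow(sco) == 0L) stop("empty SCO table")
  if (pseudo_count < 0) stop("pseudo_count must be >= 0")
  labs_a <- attr(sco, "chrom_labels_a")
  labs_b <- attr(sco, "chrom_labels_b")
  ca <- sco$chrom_a
  cb <- sco$chrom_b
  if (length(arm_merge)) {
    if (is.null(names(arm_merge))) stop("arm_merge must be a named vector")
    unknown <- setdiff(names(arm_merge), union(labs_a, labs_b))
    if (length(unknown)) {
      stop("arm_merge refers to undeclared labels: ",
           paste(unknown, collapse = ", "))
    }
    merge_lab <- function(x) {
      hit <- x %in% names(arm_merge)
      x[hit] <- unname(arm_merge[x[hit]])
      x
    }
    ca <- merge_lab(ca)
    cb <- merge_lab(cb)
    relabel <- function(labs) {
      out <- labs
      hit <- out %in% names(arm_merge)
      out[hit] <- unname(arm_merge[out[hit]])
      unique(out)
    }
    labs_a <- relabel(labs_a)
    labs_b <- relabel(labs_b)
  }
  raw <- table(factor(ca, levels = labs_a), factor(cb, levels = labs_b))
  raw <- matrix(as.numeric(raw), nrow = length(labs_a),
                dimnames = list(labs_a, labs_b))
  counts <- raw + pseudo_count
  jp <- counts / sum(counts)
  structure(list(
    chrom_labels_a = labs_a, chrom_labels_b = labs_b,
    counts = counts, raw_counts = raw, joint_probs = jp,
    marginal_a = rowSums(jp), marginal_b = colSums(jp),
    pseudo_count = pseudo_count,
    species_a = attr(sco, "species_a"), species_b = attr(sco, "species_b")
  ), class = "joint_table")
}

#' Build a joint table directly from a count (or probability) matrix
#'
#' Convenience constructor used when the SCO counts or published joint
#' probabilities are already tabulated. A probability matrix can be passed
#' as-is with `pseudo_count = 0`; it is renormalized to sum to 1.
#'
#' @param counts numeric matrix (rows: species-A chromosomes, columns:
#'   species-B chromosomes), non-negative.
#' @inheritParams build_joint_table
#' @param species_a,species_b species display names.
#' @return a `joint_table`.
#' @export
joint_table_from_counts <- function(counts, pseudo_count = 0,
                                    species_a = "species_A",
                                    species_b = "species_B") {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(rownames(counts))) rownames(counts) <- paste0("A", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("B", seq_len(ncol(counts)))
  pc <- counts + pseudo_count
  if (sum(pc) <= 0) stop("all-zero count matrix")
  jp <- pc / sum(pc)
  structure(list(
    chrom_labels_a = rownames(counts), chrom_labels_b = colnames(counts),
    counts = pc, raw_counts = counts, joint_probs = jp,
    marginal_a = rowSums(jp), marginal_b = colSums(jp),
    pseudo_count = pseudo_count,
    species_a = species_a, species_b = species_b
  ), class = "joint_table")
}

#' Shannon entropy in bits
#'
#' `-sum(p * log2(p))` with the convention `0 * log2(0) = 0`, so tables with
#' structural zeros (or rounded published tables containing 0.000 cells)
#' are handled without producing NaN.
#'
#' @param probs numeric vector or matrix of probabilities; entries must be
#'   non-negative and sum to 1 within `tol`.
#' @param tol tolerance on the sum (default 1e-6).
#' @return entropy in bits.
#' @examples
#' entropy(rep(0.25, 4)) # 2 bits
#' entropy(c(0.75, 0.25))
#' @export
entropy <- function(probs, tol = 1e-6) {
  p <- as.numeric(probs)
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > tol) {
    stop("probabilities sum to ", format(sum(p)), ", not 1 (tol ", tol, ")")
  }
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

#' Min-Max Normalized Entropy (MMNE) of a joint SCO table
#'
#' Decomposes the observed joint entropy relative to the minimum and
#' maximum entropy states attainable given each species' marginal SCO
#' distribution:
#'
#' * `h_obs`: entropy of the joint probabilities;
#' * `h_min`: mean of the two marginal entropies — the fully conserved
#'   state, where knowing the chromosome in one species determines it in
#'   the other;
#' * `h_max`: entropy of the independence table (outer product of
#'   marginals) — the fully shuffled state. Analytically
#'   `h_max = H(A) + H(B) = 2 * h_min`.
#'
#' `mmne = (h_obs - h_min) / (h_max - h_min)`, which equals
#' `1 - 2 * MI / (H(A) + H(B))` where MI is the mutual information; it is 0
#' for perfectly conserved chromosomal gene sets and 1 under independence.
#'
#' @param joint a `joint_table`.
#' @return an `entropy_decomposition` list with fields `h_obs`, `h_min`,
#'   `h_max`, `mmne` (all in bits except the dimensionless `mmne`).
#' @examples
#' jt <- joint_table_from_counts(diag(4) * 10)
#' mmne(jt)$mmne # 0: conserved
#' jt2 <- joint_table_from_counts(matrix(1, 4, 4))
#' mmne(jt2)$mmne # 1: independent
#' @export
mmne <- function(joint) {
  if (!inherits(joint, "joint_table")) stop("`joint` must be a joint_table")
  h_obs <- entropy(joint$joint_probs)
  h_a <- entropy(joint$marginal_a)
  h_b <- entropy(joint$marginal_b)
  h_min <- (h_a + h_b) / 2
  h_max <- entropy(outer(joint$marginal_a, joint$marginal_b))
  if (h_max - h_min < 1e-12) {
    stop("MMNE undefined: degenerate comparison (fewer than 2 effective ",
         "chromosomes in a species makes h_max == h_min)")
  }
  structure(list(h_obs = h_obs, h_min = h_min, h_max = h_max,
                 mmne = (h_obs - h_min) / (h_max - h_min)),
            class = "entropy_decomposition")
}

#' @export
print.entropy_decomposition <- function(x, ...) {
  cat(sprintf("Entropy decomposition: H_obs = %.6f bits, H_min = %.6f, H_max = %.6f, MMNE = %.6f\n",
              x$h_obs, x$h_min, x$h_max, x$mmne))
  invisible(x)
}

#' Pairwise MMNE matrix across several species
#'
#' @param tables named list of `joint_table` objects, one per unordered
#'   species pair, with names `"A|B"` (see [pair_key()]). Self-pairs
#'   (`"A|A"`) supply the diagonal; missing self-pairs default the diagonal
#'   to each species compared against itself only if provided.
#' @param species character vector giving the species order of the output
#'   matrix.
#' @return symmetric numeric matrix of MMNE scores with `species` as
#'   dimnames.
#' @export
pairwise_mmne_matrix <- function(tables, species) {
  n <- length(species)
  m <- matrix(NA_real_, n, n, dimnames = list(species, species))
  for (i in seq_len(n)) {
    for (j in i:n) {
      key <- pair_key(species[i], species[j])
      tab <- tables[[key]]
      if (is.null(tab)) stop("missing joint table for pair ", key)
      v <- mmne(tab)$mmne
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}

#' Canonical key for an unordered species pair
#'
#' @param a,b species names.
#' @return `"a|b"` with the two names in sorted order.
#' @export
pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

#' Hierarchically cluster an MMNE matrix
#'
#' Treats MMNE scores as pairwise distances between species and returns the
#' agglomerative merge tree. Average linkage (UPGMA) by default; the
#' linkage is a recorded parameter of any downstream figure.
#'
#' @param mat symmetric MMNE matrix (e.g. from [pairwise_mmne_matrix()]).
#' @param linkage linkage method passed to [stats::hclust()].
#' @return an `hclust` tree for >= 2 species; for a single species, a
#'   single-leaf `phylo` tree (degenerate case `hclust` cannot represent).
#' @export
cluster_mmne_matrix <- function(mat, linkage = "average") {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat) || !isTRUE(all.equal(mat, t(mat), tolerance = 1e-8))) {
    stop("MMNE matrix must be symmetric")
  }
  if (nrow(mat) == 1L) {
    return(ape::read.tree(text = paste0("(", rownames(mat), ");")))
  }
  stats::hclust(stats::as.dist(mat), method = linkage)
}

#' Write a clustering tree as Newick
#'
#' @param tree an `hclust` (as returned by [cluster_mmne_matrix()]) or
#'   `phylo` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(tree, path) {
  phy <- if (inherits(tree, "phylo")) tree else ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Counterpart chromosomes by SCO percentage
#'
#' For each source (species-A) chromosome, ranks target (species-B)
#' chromosomes by the percent of the source's SCOs they hold, using raw
#' (non-pseudo-counted) counts. Reports the top target plus any others at
#' or above `report_threshold` percent. Ties are broken by declared target
#' label order, deterministically.
#'
#' @param joint a `joint_table`.
#' @param report_threshold minimum percent for secondary counterparts
#'   (default 20).
#' @return data.frame with columns `source`, `target`, `percent`, `rank`.
#' @export
counterpart_map <- function(joint, report_threshold = 20) {
  if (!inherits(joint, "joint_table")) stop("`joint` must be a joint_table")
  raw <- joint$raw_counts
  rows <- lapply(seq_len(nrow(raw)), function(i) {
    tot <- sum(raw[i, ])
    if (tot == 0) {
      stop("source chromosome ", rownames(raw)[i], " has zero SCOs")
    }
    pct <- 100 * raw[i, ] / tot
    ord <- order(-pct, seq_along(pct)) # descending, ties by label order
    pct <- pct[ord]
    keep <- c(TRUE, pct[-1] >= report_threshold)
    data.frame(source = rownames(raw)[i],
               target = names(pct)[keep],
               percent = unname(pct[keep]),
               rank = seq_len(sum(keep)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
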