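# EGGS: joint tables, entropy, MMNE, counterpart mapping, clustering.

test_that("joint table arithmetic matches direct hand computation", {
  # uniform counts, no pseudo-count
  jt <- joint_table_from_counts(matrix(5, 2, 2), pseudo_count = 0)
  expect_equal(unname(jt$joint_probs), matrix(0.25, 2, 2))
  expect_equal(unname(jt$marginal_a), c(0.5, 0.5))

  # diagonal counts with pseudo-count 0.1: (10.1, 0.1) / 20.4
  jt2 <- joint_table_from_counts(diag(2) * 10, pseudo_count = 0.1)
  expect_equal(unname(jt2$joint_probs),
               matrix(c(10.1, 0.1, 0.1, 10.1), 2, 2) / 20.4,
               tolerance = 1e-12)
  expect_equal(round(jt2$joint_probs[1, 1], 6), 0.495098)
  expect_equal(round(jt2$joint_probs[1, 2], 6), 0.004902)
})

test_that("joint table counts SCOs, applies pseudo-counts and arm merging", {
  tab <- sco_table(paste0("og", 1:6),
                   c("2L", "2R", "2L", "3", "3", "X"),
                   c("2", "2", "3", "3", "3", "X"),
                   chrom_labels_a = c("2L", "2R", "3", "X"),
                   chrom_labels_b = c("2", "3", "X"))
  jt <- build_joint_table(tab, pseudo_count = 0,
                          arm_merge = c("2L" = "2", "2R" = "2"))
  expect_equal(rownames(jt$raw_counts), c("2", "3", "X"))
  expect_equal(jt$raw_counts["2", "2"], 2) # 2L->2 and 2R->2 summed
  expect_equal(jt$raw_counts["2", "3"], 1)
  expect_equal(sum(jt$joint_probs), 1)

  # marginals are exactly the row/column sums of the joint probabilities
  jt2 <- build_joint_table(tab, pseudo_count = 0.1)
  expect_identical(jt2$marginal_a, rowSums(jt2$joint_probs))
  expect_identical(jt2$marginal_b, colSums(jt2$joint_probs))
  expect_true(all(jt2$joint_probs > 0))
  expect_equal(sum(jt2$joint_probs), 1, tolerance = 1e-9)
})

test_that("joint table rejects bad input", {
  expect_error(sco_table(c("a", "a"), c("X", "X"), c("X", "X")),
               "duplicated")
  expect_error(sco_table("a", "X", "Y", chrom_labels_b = "X"), "label")
  tab <- sco_table("a", "X", "X")
  expect_error(build_joint_table(tab[0, ]), "empty")
  expect_error(build_joint_table(tab, arm_merge = c("ZZ" = "Q")),
               "undeclared")
})

test_that("entropy follows the Shannon formula with 0 log 0 = 0", {
  expect_equal(entropy(rep(0.25, 4)), 2.0)
  expect_equal(entropy(1.0), 0.0)
  expect_equal(entropy(c(0.75, 0.25)), 0.8112781, tolerance = 1e-7)
  expect_equal(entropy(c(0.5, 0.5, 0)), 1.0) # zero cell contributes nothing
  expect_error(entropy(c(0.5, 0.4)), "sum")
  expect_error(entropy(c(1.2, -0.2)), "non-negative")
})

test_that("MMNE decomposition matches hand-computed cases", {
  # perfectly conserved: mmne exactly 0
  d <- mmne(joint_table_from_counts(diag(2) * 10))
  expect_equal(d$h_obs, 1)
  expect_equal(d$h_min, 1)
  expect_equal(d$h_max, 2)
  expect_identical(d$mmne, 0)

  # full independence: mmne exactly 1
  d2 <- mmne(joint_table_from_counts(matrix(1, 2, 2)))
  expect_equal(d2$h_obs, 2)
  expect_identical(d2$mmne, 1)

  # intermediate case, cross-checked against 1 - 2*MI/(H_A + H_B)
  d3 <- mmne(joint_table_from_counts(matrix(c(0.5, 0, 0.25, 0.25), 2, 2)))
  expect_equal(d3$mmne, 0.65629, tolerance = 1e-4)
})

test_that("MMNE analytic identities hold on random tables", {
  set.seed(7)
  for (rep in 1:25) {
    k <- sample(2:6, 2, replace = TRUE)
    counts <- matrix(stats::rexp(prod(k)) * 50, k[1], k[2])
    jt <- joint_table_from_counts(counts, pseudo_count = 0.1)
    d <- mmne(jt)
    h_a <- oracle_entropy(jt$marginal_a)
    h_b <- oracle_entropy(jt$marginal_b)
    # h_max = H(A) + H(B) = 2 * h_min
    expect_equal(d$h_max, 2 * d$h_min, tolerance = 1e-9)
    expect_equal(d$h_max, h_a + h_b, tolerance = 1e-9)
    # mmne = 1 - 2 MI / (H_A + H_B), MI from an independent computation
    mi <- h_a + h_b - oracle_entropy(jt$joint_probs)
    expect_equal(d$mmne, 1 - 2 * mi / (h_a + h_b), tolerance = 1e-9)
    expect_gte(d$mmne, 0)
    expect_lte(d$mmne, 1 + 1e-12)
    expect_true(d$h_min <= d$h_obs + 1e-9 && d$h_obs <= d$h_max + 1e-9)
    # symmetry under transposition
    dt <- mmne(joint_table_from_counts(t(counts), pseudo_count = 0.1))
    expect_equal(dt$mmne, d$mmne, tolerance = 1e-12)
  }
})

test_that("MMNE errors on a degenerate single-chromosome comparison", {
  expect_error(mmne(joint_table_from_counts(matrix(10, 1, 1))), "degenerate")
})

test_that("published fungus-gnat joint table reproduces the frozen fixture", {
  # regression fixture computed with an independent (numpy) oracle on the
  # printed 4x4 matrix, renormalized to sum to 1
  jt <- joint_table_from_counts(table_joint_bcop_phyg(), pseudo_count = 0)
  d <- mmne(jt)
  expect_equal(d$h_obs, 2.1618177939, tolerance = 1e-9)
  expect_equal(d$h_min, 1.9650967895, tolerance = 1e-9)
  expect_equal(d$h_max, 3.9301935790, tolerance = 1e-9)
  expect_equal(d$mmne, 0.1001075395, tolerance = 1e-8)
})

test_that("counterpart map ranks targets by raw-count percentage", {
  jt <- joint_table_from_counts(rbind(c(97, 1, 1, 1), c(55, 35, 10, 0)),
                                pseudo_count = 0.1)
  cm <- counterpart_map(jt, report_threshold = 20)
  a1 <- cm[cm$source == "A1", ]
  expect_equal(nrow(a1), 1L)
  expect_equal(a1$percent, 97)
  a2 <- cm[cm$source == "A2", ]
  expect_equal(a2$percent, c(55, 35))
  expect_equal(a2$rank, c(1L, 2L))

  # tie broken by declared target-label order
  jt2 <- joint_table_from_counts(rbind(c(50, 50)), pseudo_count = 0)
  cm2 <- counterpart_map(jt2, report_threshold = 20)
  expect_equal(cm2$target, c("B1", "B2"))
  expect_equal(cm2$percent, c(50, 50))

  # percentages per source sum to 100
  expect_error(counterpart_map(joint_table_from_counts(rbind(c(0, 0), c(1, 1)))),
               "zero SCOs")
})

test_that("pairwise MMNE matrix is symmetric and clustering orders clades", {
  set.seed(11)
  species <- c("s1", "s2", "s3", "s4")
  theta_for <- function(a, b) {
    if (a == b) return(0)
    same_clade <- (a %in% c("s1", "s2")) == (b %in% c("s1", "s2"))
    if (same_clade) 0.05 else 0.5
  }
  tables <- list()
  for (i in 1:4) {
    for (j in i:4) {
      cfg <- sim_sco_config(c("c1", "c2", "c3", "c4"), 500,
                            theta = theta_for(species[i], species[j]),
                            seed = 100 + 10 * i + j)
      tables[[pair_key(species[i], species[j])]] <-
        build_joint_table(simulate_sco_table(cfg))
    }
  }
  m <- pairwise_mmne_matrix(tables, species)
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) < 0.01)) # self-comparison near 0
  expect_true(m["s1", "s2"] < m["s1", "s3"])
  expect_true(m["s3", "s4"] < m["s1", "s3"])

  hc <- cluster_mmne_matrix(m)
  # the first two merges join the within-clade pairs (leaves 1+2 and 3+4),
  # before any cross-clade merge
  first_two <- lapply(1:2, function(r) as.numeric(sort(-hc$merge[r, ])))
  expect_setequal(first_two, list(c(1, 2), c(3, 4)))
  expect_error(pairwise_mmne_matrix(tables["s1|s2"], c("s1", "s9")), "missing")
})

test_that("single-species clustering degenerates to a one-leaf tree", {
  tr <- cluster_mmne_matrix(matrix(0, 1, 1, dimnames = list("s1", "s1")))
  expect_s3_class(tr, "phylo")
  expect_equal(tr$tip.label, "s1")
  p <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(tr, p)
  expect_true(grepl("s1", readLines(p)))
  expect_error(cluster_mmne_matrix(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})
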