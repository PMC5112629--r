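test_that("ANI averages shared-gene identities, symmetric with 100 diagonal", {
  cl <- data.frame(cluster_id = c("c1", "c1", "c2", "c2"),
                   uid = c("A|x", "B|x", "A|y", "B|y"),
                   genome_id = c("A", "B", "A", "B"),
                   gene_id = c("x", "x", "y", "y"))
  e <- data.frame(uid_a = c("A|x", "A|y"), uid_b = c("B|x", "B|y"),
                  identity = c(98, 96), coverage_shorter = 1, score = 1)
  m <- ani_matrix(cl, e, c("A", "B"))
  expect_equal(m["A", "B"], 97)
  expect_equal(m["B", "A"], 97)
  expect_equal(diag(m), c(A = 100, B = 100))

  # a pair sharing no aligned genes is missing, with a warning
  expect_warning(m2 <- ani_matrix(cl[1:2, ], e[0, ], c("A", "B")),
                 "no aligned genes")
  expect_true(is.na(m2["A", "B"]))
})

test_that("simulated ANI tracks the Jukes-Cantor expected identity", {
  sim <- small_sim(8)
  cm <- sim$community
  e <- all_vs_all_similarity(cm)
  cl <- markov_cluster(filter_homologs(e), cm$annotations$uid)
  ani <- ani_matrix(cl, e, names(cm$genomes))
  cmp <- truth_compare(sim$truth, ani = ani)
  # genic ANI sits near the realized-core expectation (local alignment
  # trims divergent ends so a small upward bias is expected)
  expect_lt(abs(cmp$ani_bias), 0.03)
})

test_that("Jukes-Cantor distance follows the closed form on its domain", {
  expect_equal(jc_distance(0), 0)
  expect_equal(jc_distance(0.05), -0.75 * log(1 - 4 * 0.05 / 3))
  expect_equal(jc_distance(0.05), 0.0517447, tolerance = 1e-6)
  expect_error(jc_distance(0.75), "undefined")
  p <- seq(0, 0.7, by = 0.01)
  d <- jc_distance(p)
  expect_true(all(diff(d) > 0))          # strictly increasing
  expect_equal(jc_distance(1e-6), 1e-6, tolerance = 1e-3)
})

test_that("pairwise JC matrix excludes gapped/ambiguous columns pairwise", {
  seqs <- c(a = "AAAAAAAAAA", b = "AAAAA-AAAT", c = "NNAAAAAAAA")
  jm <- jc_matrix(seqs)
  expect_equal(jm$p["a", "b"], 1 / 9)
  expect_equal(jm$p["a", "c"], 0)
  expect_true(isSymmetric(jm$d))
})

test_that("barcode gap partitioning splits blocks and respects priors", {
  ids <- paste0("g", 1:6)
  d <- matrix(0.15, 6, 6, dimnames = list(ids, ids))
  within <- matrix(c(0.004, 0.005, 0.006, 0.0045, 0.0055, 0.005), 3)
  d[1:3, 1:3] <- 0.005 + outer(1:3, 1:3, function(i, j) abs(i - j)) * 1e-4
  d[4:6, 4:6] <- 0.005 + outer(1:3, 1:3, function(i, j) abs(i - j)) * 2e-4
  diag(d) <- 0
  bp <- barcode_gap_partition(d, prior_grid = c(0.01, 0.05), gap_factor = 1.5)
  expect_equal(bp$report$n_groups, c(2L, 2L))
  expect_same_partition(bp$partition, rep(c("x", "y"), each = 3)[match(ids, ids)])

  # no qualifying gap: one group
  d1 <- matrix(0.004, 6, 6, dimnames = list(ids, ids)); diag(d1) <- 0
  d1[upper.tri(d1)] <- d1[upper.tri(d1)] + seq(0, 1e-4, length.out = 15)
  d1[lower.tri(d1)] <- t(d1)[lower.tri(d1)]
  bp1 <- barcode_gap_partition(d1, prior_grid = c(0.01, 0.05))
  expect_equal(unique(bp1$report$n_groups), 1L)

  # relabeling invariance
  perm <- sample(ids)
  bp2 <- barcode_gap_partition(d[perm, perm], prior_grid = c(0.01, 0.05))
  expect_same_partition(bp2$partition[ids], bp$partition[ids])

  expect_warning(barcode_gap_partition(d[1:2, 1:2]), "fewer than 3")
})

test_that("delimitation recovers planted lineages on simulated data", {
  sim <- small_sim(2)
  bp <- barcode_gap_partition(jc_matrix(core_rows_of(sim))$d)
  expect_equal(bp$converged_n_groups, 3L)
  expect_same_partition(bp$partition, sim$truth$lineages[names(bp$partition)])
})

test_that("ordination matches an independent eigen-decomposition oracle", {
  set.seed(31)
  ani <- matrix(runif(36, 80, 100), 6, 6)
  ani[upper.tri(ani)] <- t(ani)[upper.tri(ani)]
  ani <- (ani + t(ani)) / 2; diag(ani) <- 100
  rownames(ani) <- colnames(ani) <- paste0("g", 1:6)
  o <- ordinate_ani(ani, n_components = 3)
  # oracle: eigen decomposition of the covariance of the transformed matrix
  tr <- asin(sqrt(ani / 100))
  xc <- scale(tr, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(xc))
  scores <- xc %*% ev$vectors
  for (k in 1:3)
    expect_equal(abs(unname(o$coordinates[, k])), abs(unname(scores[, k])),
                 tolerance = 1e-8)
  expect_equal(o$variance_explained,
               (ev$values / sum(ev$values))[1:3], tolerance = 1e-8)
  expect_true(all(diff(o$variance_explained) <= 1e-12))

  # degenerate matrix: zero variance everywhere
  flat <- matrix(100, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  of <- ordinate_ani(flat)
  expect_true(all(of$coordinates == 0))
  expect_true(all(of$variance_explained == 0))
})

test_that("two well-separated clusters load on the first component", {
  ids <- paste0("g", 1:8)
  ani <- matrix(82, 8, 8, dimnames = list(ids, ids))
  ani[1:4, 1:4] <- 99.2; ani[5:8, 5:8] <- 99.4; diag(ani) <- 100
  o <- ordinate_ani(ani)
  expect_gt(o$variance_explained[1], 0.9)
  pc1 <- o$coordinates[, 1]
  expect_true(max(pc1[1:4]) < min(pc1[5:8]) || min(pc1[1:4]) > max(pc1[5:8]))
})

test_that("Mann-Whitney U uses exact enumeration for small samples", {
  # fully separated 5 vs 5: U = 0, exact two-tailed p = 2/252
  r <- phagepop:::mann_whitney(c(1, 2, 3, 4, 5), c(10, 11, 12, 13, 14))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 2 / choose(10, 5))
  expect_equal(r$method, "exact")

  # identical distributions: U near n1*n2/2, p near 1
  set.seed(41)
  x <- rnorm(30); y <- rnorm(30)
  r2 <- phagepop:::mann_whitney(x, y)
  expect_equal(r2$method, "normal_approx")
  expect_gt(r2$p_value, 0.05)

  r3 <- phagepop:::mann_whitney(1, 2)
  expect_equal(r3$method, "exact")
})

test_that("lineage divergence test separates an outlier lineage", {
  ids <- paste0("g", 1:9)
  part <- setNames(rep(c("A", "B", "C"), each = 3), ids)
  d <- matrix(0.1, 9, 9, dimnames = list(ids, ids))
  d[part == "C", ] <- 0.4; d[, part == "C"] <- 0.4
  for (l in c("A", "B", "C")) d[part == l, part == l] <- 0.005
  diag(d) <- 0
  r <- lineage_divergence_test(d, part, "C")
  expect_lt(r$p_value, 0.01)
  expect_error(lineage_divergence_test(d, part, "Z"), "absent")
})
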