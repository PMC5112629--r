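make_gene_community <- function(genes) {
  # one gene per genome so uids are predictable: gN|g
  seqs <- setNames(genes, paste0("G", seq_along(genes)))
  ann <- data.frame(genome_id = names(seqs), gene_id = "g",
                    start = 0L, end = nchar(genes), strand = "+",
                    stringsAsFactors = FALSE)
  phage_community(seqs, ann)
}

test_that("similarity reports identity and coverage of the shorter gene", {
  set.seed(21)
  g <- rand_seq(120)
  half <- substr(g, 1, 60)
  cm <- make_gene_community(c(g, g, half))
  e <- all_vs_all_similarity(cm, prescreen = FALSE)
  id_pair <- e[e$uid_a == "G1|g" & e$uid_b == "G2|g", ]
  expect_equal(id_pair$identity, 100)
  expect_equal(id_pair$coverage_shorter, 1)
  half_pair <- e[e$uid_b == "G3|g" & e$uid_a == "G1|g", ]
  expect_equal(half_pair$identity, 100)
  expect_equal(half_pair$coverage_shorter, 1)
})

test_that("similarity matches an exhaustive ungapped local alignment oracle", {
  set.seed(22)
  for (rep in 1:6) {
    core <- rand_seq(50)
    x <- paste0(rand_seq(15), core, rand_seq(10))
    y <- paste0(rand_seq(8), mutate_seq(core, 0.08), rand_seq(20))
    cm <- make_gene_community(c(x, y))
    e <- all_vs_all_similarity(cm, prescreen = FALSE)
    o <- ungapped_local_oracle(x, y)
    expect_equal(e$score[1], o$score)
    expect_equal(e$identity[1], 100 * o$ident / o$len, tolerance = 1e-9)
  }
})

test_that("the 40/60 homology filter treats boundaries inclusively", {
  e <- data.frame(uid_a = c("a", "a", "a", "a", "a"),
                  uid_b = c("b", "c", "d", "e", "f"),
                  identity = c(45, 39, 80, 40, 100),
                  coverage_shorter = c(0.7, 0.9, 0.5, 0.6, 0.59),
                  score = 1)
  kept <- filter_homologs(e)
  expect_setequal(kept$uid_b, c("b", "e"))
})

test_that("Markov clustering resolves cliques, bridges and singletons", {
  cl3 <- function(ids) {
    p <- combn(ids, 2)
    data.frame(uid_a = pmin(p[1, ], p[2, ]), uid_b = pmax(p[1, ], p[2, ]),
               identity = 90, coverage_shorter = 1, score = 1,
               stringsAsFactors = FALSE)
  }
  e <- rbind(cl3(c("a1", "a2", "a3")), cl3(c("b1", "b2", "b3")))
  cl <- markov_cluster(e, c("a1", "a2", "a3", "b1", "b2", "b3", "lone"))
  grp <- split(cl$uid, cl$cluster_id)
  expect_length(grp, 3)
  expect_true(any(vapply(grp, setequal, TRUE, c("a1", "a2", "a3"))))
  expect_true(any(vapply(grp, setequal, TRUE, c("b1", "b2", "b3"))))
  expect_true(any(vapply(grp, identical, TRUE, "lone")))

  single <- markov_cluster(
    data.frame(uid_a = "x", uid_b = "y", identity = 80,
               coverage_shorter = 1, score = 1), c("x", "y"))
  expect_equal(length(unique(single$cluster_id)), 1L)

  # two 5-cliques joined by one weak bridge separate into 2 clusters,
  # agreeing with an independent dense reference implementation
  ids <- c(paste0("p", 1:5), paste0("q", 1:5))
  w <- matrix(0, 10, 10, dimnames = list(ids, ids))
  w[1:5, 1:5] <- 1; w[6:10, 6:10] <- 1; diag(w) <- 0
  w["p1", "q1"] <- w["q1", "p1"] <- 0.05
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  e2 <- data.frame(uid_a = pmin(ids[ut[, 1]], ids[ut[, 2]]),
                   uid_b = pmax(ids[ut[, 1]], ids[ut[, 2]]),
                   identity = w[ut], coverage_shorter = 1, score = 1)
  cl2 <- markov_cluster(e2, ids)
  expect_equal(length(unique(cl2$cluster_id)), 2L)
  ref <- mcl_oracle(w)
  expect_same_partition(cl2$cluster_id[match(ids, cl2$uid)], ref)
})

test_that("clustering is a partition and invariant to input order", {
  sim <- small_sim(3)
  cm <- sim$community
  e <- filter_homologs(all_vs_all_similarity(cm))
  cl <- markov_cluster(e, cm$annotations$uid)
  expect_setequal(cl$uid, cm$annotations$uid)
  expect_equal(anyDuplicated(cl$uid), 0L)

  perm <- sample(nrow(e))
  cl_perm <- markov_cluster(e[perm, ], sample(cm$annotations$uid))
  expect_same_partition(cl$cluster_id[order(cl$uid)],
                        cl_perm$cluster_id[order(cl_perm$uid)])

  # planted families recovered exactly
  truth_fam <- sim$truth$gene_families
  expect_same_partition(cl$cluster_id[match(truth_fam$uid, cl$uid)],
                        truth_fam$family)
})

test_that("core clusters require a member in every genome", {
  cl <- data.frame(cluster_id = c("X", "X", "X", "Y", "Y", "Z", "Z"),
                   uid = paste0("u", 1:7),
                   genome_id = c("g1", "g2", "g3", "g1", "g3", "g1", "g1"),
                   gene_id = paste0("n", 1:7))
  cc <- core_clusters(cl, c("g1", "g2", "g3"))
  expect_true(cc$is_core[cc$cluster_id == "X"])
  expect_false(cc$is_core[cc$cluster_id == "Y"])
  expect_false(cc$is_core[cc$cluster_id == "Z"])
  expect_true(cc$multi_copy[cc$cluster_id == "Z"])
})

test_that("shared-gene fractions use per-genome denominators", {
  # A in 10 clusters, B in 16, 8 shared
  rows <- rbind(
    data.frame(cluster_id = paste0("s", 1:8), genome_id = "A"),
    data.frame(cluster_id = paste0("s", 1:8), genome_id = "B"),
    data.frame(cluster_id = paste0("a", 1:2), genome_id = "A"),
    data.frame(cluster_id = paste0("b", 1:8), genome_id = "B"))
  rows$uid <- paste0(rows$genome_id, "|", rows$cluster_id)
  rows$gene_id <- rows$cluster_id
  s <- shared_gene_fraction(rows, "A", "B")
  expect_equal(s$fraction_a, 0.8)
  expect_equal(s$fraction_b, 0.5)
  expect_equal(s$mean_fraction, 0.65)
  r <- shared_gene_fraction(rows, "B", "A")
  expect_equal(r$mean_fraction, s$mean_fraction)
  m <- shared_gene_matrix(rows, c("A", "B"))
  expect_equal(m["A", "B"], 0.65)
  expect_true(isSymmetric(m))

  rows2 <- rows[rows$cluster_id %in% c("a1", "b1"), ]
  z <- shared_gene_fraction(rows2, "A", "B")
  expect_equal(z$mean_fraction, 0)
})
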