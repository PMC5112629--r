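test_that("core block filter is strict on length and completeness", {
  mk_block <- function(id, len, genomes) list(
    block_id = id,
    seqs = setNames(rep(strrep("A", len), length(genomes)), genomes))
  blocks <- list(mk_block("b1", 501, c("g1", "g2")),
                 mk_block("b2", 500, c("g1", "g2")),
                 mk_block("b3", 800, "g1"))
  kept <- filter_core_blocks(blocks, min_len = 500, genomes = c("g1", "g2"))
  expect_equal(vapply(kept, `[[`, "", "block_id"), "b1")
})

test_that("nucleotide diversity equals the brute-force pair enumeration", {
  expect_equal(nucleotide_diversity(c(a = "ACGT", b = "ACGT"))$pi, 0)
  s <- c(a = "AAAAAAAAAA", b = "AAAAAAAATT")
  expect_equal(nucleotide_diversity(s)$pi, 0.2)

  set.seed(51)
  r <- setNames(vapply(1:5, function(i) mutate_seq(strrep("ACGT", 25), 0.2),
                       ""), paste0("s", 1:5))
  expect_equal(nucleotide_diversity(r)$pi, pi_oracle(r))

  # gapped columns drop out pairwise
  g <- c(a = "AA-A", b = "AATA", c = "AAAA")
  expect_equal(nucleotide_diversity(g)$pi, mean(c(0, 0, 1 / 4)))
  expect_error(nucleotide_diversity(c(a = "----", b = "AAAA")),
               "no comparable sites")
})

test_that("F_ST follows the printed identity, hitting 0 and 1 exactly", {
  # equidistant sequences: pi_within = pi_between, F_ST = 0
  eq <- vapply(1:4, function(i) {
    v <- rep("A", 4); v[i] <- "T"; paste(v, collapse = "")
  }, "")
  f0 <- fst(c(S1a = eq[1], S1b = eq[2]), c(S2a = eq[3], S2b = eq[4]))
  expect_equal(f0$fst, 0)

  # internally monomorphic, mutually fixed: F_ST = 1
  f1 <- fst(c(a1 = "AAAA", a2 = "AAAA"), c(b1 = "TTTT", b2 = "TTTT"))
  expect_equal(f1$fst, 1)

  # 3 + 3 random sequences vs direct evaluation of the equation
  set.seed(52)
  base <- strrep("ACGTT", 40)
  s1 <- setNames(vapply(1:3, function(i) mutate_seq(base, 0.05), ""),
                 paste0("c", 1:3))
  s2 <- setNames(vapply(1:3, function(i) mutate_seq(base, 0.15), ""),
                 paste0("o", 1:3))
  f <- fst(s1, s2)
  pi_b <- mean(outer(1:3, 1:3, Vectorize(function(i, j)
    pi_oracle(c(s1[i], s2[j])))))
  expect_equal(f$pi_between, pi_b)
  expect_equal(f$fst, 1 - ((pi_oracle(s1) + pi_oracle(s2)) / 2) / pi_b)

  # monomorphic everything: undefined
  fna <- fst(c(a = "AAAA", b = "AAAA"), c(c = "AAAA", d = "AAAA"))
  expect_true(is.na(fna$fst))
  expect_warning(fst(c(a = "AAAA"), c(b = "AATA", c = "AATA")),
                 "single-member")
})

test_that("frequency filter removes alleles strictly below the threshold", {
  mkseqs <- function(col) setNames(paste0(col, "A"), paste0("s", seq_along(col)))
  # n = 10: 1 carrier (10%) removed, 2 carriers (20%) retained
  s10 <- mkseqs(c(rep("A", 9), "T"))
  expect_true(all(substr(polymorphism_frequency_filter(s10), 1, 1) == "A"))
  s20 <- mkseqs(c(rep("A", 8), "T", "T"))
  expect_equal(sum(substr(polymorphism_frequency_filter(s20), 1, 1) == "T"), 2)
  # n = 20 with 3 carriers (15% exactly) retained
  s15 <- mkseqs(c(rep("A", 17), rep("T", 3)))
  expect_equal(sum(substr(polymorphism_frequency_filter(s15), 1, 1) == "T"), 3)
})

test_that("filtering never increases polymorphism counts", {
  set.seed(53)
  for (rep in 1:10) {
    base <- rand_seq(90)
    a <- setNames(vapply(1:6, function(i) mutate_seq(base, 0.02), ""),
                  paste0("a", 1:6))
    b <- setNames(vapply(1:6, function(i) mutate_seq(base, 0.02), ""),
                  paste0("b", 1:6))
    raw <- suppressWarnings(count_mk(a, b))
    flt <- suppressWarnings(count_mk(polymorphism_frequency_filter(a),
                                     polymorphism_frequency_filter(b)))
    if (isTRUE(raw$skipped) || isTRUE(flt$skipped)) next
    expect_lte(flt$b, raw$b)
    expect_lte(flt$d, raw$d)
  }
})

test_that("MK counting classifies fixed and segregating codons", {
  # fixed synonymous difference (Lys/Lys)
  r <- count_mk(c(a1 = "AAA", a2 = "AAA"), c(b1 = "AAG", b2 = "AAG"))
  expect_equal(unlist(r[c("a", "b", "c", "d")]), c(a = 1, b = 0, c = 0, d = 0))

  # segregating nonsynonymous polymorphism in A (Lys/Asn)
  r2 <- count_mk(c(a1 = "AAA", a2 = "AAC"), c(b1 = "AAA", b2 = "AAA"))
  expect_equal(unlist(r2[c("a", "b", "c", "d")]),
               c(a = 0, b = 0, c = 0, d = 1))

  # two-position fixed difference: average over both mutational orderings
  # AAA (Lys) -> AGG: via AGA (Arg): nonsyn then syn; via AAG (Lys): syn
  # then nonsyn => expected a = 1, c = 1
  r3 <- count_mk(c(a1 = "AAA"), c(b1 = "AGG"))
  path1 <- c(syn = 0 + 1, nonsyn = 1 + 0)  # AAA->AGA->AGG
  path2 <- c(syn = 1 + 0, nonsyn = 0 + 1)  # AAA->AAG->AGG
  expected <- (path1 + path2) / 2
  expect_equal(r3$a, expected[["syn"]])
  expect_equal(r3$c, expected[["nonsyn"]])

  # internal stop in a major codon skips the gene
  expect_warning(rs <- count_mk(c(a1 = "TAAAAA"), c(b1 = "TAAAAA")),
                 "internal stop")
  expect_true(rs$skipped)

  # codons with gaps are excluded, not fatal
  r4 <- count_mk(c(a1 = "A-AAAA", a2 = "AAAAAA"), c(b1 = "AAAAAG"))
  expect_equal(r4$n_codons, 1L)
})

test_that("Fisher two-tailed p equals hypergeometric enumeration", {
  expect_equal(mk_fisher(5, 5, 5, 5)$p_value, 1)
  expect_equal(mk_fisher(10, 10, 10, 10)$p_value, 1)
  expect_equal(mk_fisher(0, 5, 5, 0)$p_value, 2 / 252, tolerance = 1e-12)
  z <- mk_fisher(0, 0, 0, 0)
  expect_equal(z$p_value, 1)
  expect_true(z$degenerate)

  set.seed(54)
  for (rep in 1:25) {
    tab <- as.numeric(sample(0:8, 4, TRUE))
    if (sum(tab) == 0 || sum(tab) > 30) next
    expect_equal(mk_fisher(tab[1], tab[2], tab[3], tab[4])$p_value,
                 fisher_oracle(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-9)
  }
})

test_that("phi effect size follows its closed form and sign rule", {
  expect_equal(phi_coefficient(10, 10, 10, 10), 0)
  expect_equal(phi_coefficient(10, 0, 0, 10), 1)
  expect_equal(phi_coefficient(12, 3, 2, 9),
               (12 * 9 - 3 * 2) / sqrt(15 * 11 * 14 * 12))
  expect_equal(phi_coefficient(12, 3, 2, 9), 0.61264, tolerance = 1e-4)
  expect_true(is.na(phi_coefficient(0, 0, 5, 5)))

  # sign(phi) = sign(ad - bc), exhaustively over small tables
  for (a in 0:5) for (b in 0:5) for (cc in 0:5) for (d in 0:5) {
    ph <- phi_coefficient(a, b, cc, d)
    if (is.na(ph)) next
    expect_equal(sign(ph), sign(a * d - b * cc))
  }
})

test_that("selection scan applies the p, phi and direction gates", {
  sim <- small_sim(6, n_selected_genes = 2L, genomes_per_lineage = 4L)
  cm <- sim$community
  fam <- sim$truth$gene_families
  clusters <- data.frame(cluster_id = fam$family, uid = fam$uid,
                         genome_id = sub("\\|.*", "", fam$uid),
                         gene_id = sub(".*\\|", "", fam$uid),
                         stringsAsFactors = FALSE)
  scan <- selection_scan(cm, clusters, sim$truth$lineages)
  expect_true(all(scan$p_value[scan$selected] < 0.05))
  expect_true(all(abs(scan$phi[scan$selected]) >= 0.1))
  expect_true(all((scan$a * scan$d < scan$b * scan$c)[scan$selected]))
  fpr <- attr(scan, "fpr")
  expect_equal(fpr$n_tests, nrow(scan))
  expect_equal(fpr$expected_false_positives, 0.05 * nrow(scan))
})
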