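test_that("simulator bookkeeping and reproducibility", {
  cfg <- sim_config(seed = 77, n_lineages = 6L, genomes_per_lineage = 5L,
                    n_core_genes = 5L, n_flexible_genes = 3L,
                    mean_gene_codons = 50L)
  sim <- simulate_community(cfg)
  expect_length(sim$community$genomes, 30L)
  expect_equal(length(unique(sim$truth$lineages)), 6L)
  expect_setequal(names(sim$truth$lineages), names(sim$community$genomes))

  sim2 <- simulate_community(cfg)
  expect_identical(sim$community$genomes, sim2$community$genomes)
  expect_identical(sim$community$annotations, sim2$community$annotations)
  expect_identical(sim$truth$events, sim2$truth$events)

  # byte-identical files for a fixed seed
  f1 <- tempfile(); g1 <- tempfile(); f2 <- tempfile(); g2 <- tempfile()
  write_community(sim$community, f1, g1)
  write_community(sim2$community, f2, g2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(g1), readLines(g2))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(within_divergence = 0.8), "0, 0.7")
  expect_error(sim_config(within_divergence = 0.3,
                          between_divergence = c(0.11, 0.2)), "below")
  expect_error(sim_config(n_selected_genes = 99L), "more genes than")
})

test_that("realized divergences match the Jukes-Cantor targets", {
  sim <- simulate_community(sim_config(
    seed = 13, n_lineages = 3L, genomes_per_lineage = 4L,
    between_divergence = c(0.15, 0.15), within_divergence = 0.005,
    n_selected_genes = 0L, recomb_within_per_lineage = 0L,
    recomb_between_events = 0L, gene_loss_per_lineage = 0L,
    gene_gain_per_lineage = 0L))
  d <- sim$truth$divergence
  lin <- sim$truth$lineages[rownames(d)]
  between <- d[outer(lin, lin, "!=") & upper.tri(d)]
  within <- d[outer(lin, lin, "==") & upper.tri(d)]
  # founders diverge d/2 each from the ancestor; genic constraints
  # (no stop creation) shave a little off the target
  expect_equal(mean(between), 0.15, tolerance = 0.12)
  expect_equal(mean(within), 0.005, tolerance = 0.3)
  expect_true(max(within) < min(between))

  # realized between-lineage identity sits near the closed-form JC
  # expectation for the planted distance 0.15
  pm <- jc_matrix(core_rows_of(sim))$p
  obs_identity <- mean(1 - pm[outer(lin, lin, "!=") & upper.tri(pm)])
  expected_identity <- 1 - 0.75 * (1 - exp(-4 * 0.15 / 3))
  expect_lt(abs(obs_identity - expected_identity), 0.03)
})

test_that("emitted annotations are consistent with the genomes", {
  sim <- small_sim(4, gene_gain_per_lineage = 1L, gene_loss_per_lineage = 1L)
  cm <- sim$community
  ann <- cm$annotations
  slice <- substring(cm$genomes[ann$genome_id], ann$start + 1L, ann$end)
  expect_identical(unname(slice), ann$cds)   # all plus-strand
  expect_true(all(nchar(ann$cds) %% 3L == 0L))
  # no internal stop codons in any emitted gene
  has_internal_stop <- vapply(ann$cds, function(s) {
    cods <- substring(s, seq(1, nchar(s) - 3, 3), seq(3, nchar(s) - 3, 3))
    any(cods %in% c("TAA", "TAG", "TGA"))
  }, TRUE)
  expect_false(any(has_internal_stop))
})

test_that("planted breakpoints live inside the emitted genomes", {
  sim <- small_sim(5, n_core_genes = 8L, recomb_within_per_lineage = 1L,
                   recomb_between_events = 1L, recomb_segment = 200L)
  ev <- sim$truth$events
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$start >= 0 & ev$end <= sim$truth$core_len))
  expect_true(all(ev$start < ev$end))
  # donor and recipient agree on the transferred segment
  for (i in seq_len(nrow(ev))) {
    don <- substring(sim$community$genomes[[ev$donor[i]]],
                     ev$start[i] + 1L, ev$end[i])
    rec <- substring(sim$community$genomes[[ev$recipient[i]]],
                     ev$start[i] + 1L, ev$end[i])
    # low-frequency polymorphism injection may touch a few sites
    expect_gt(mean(strsplit(don, "")[[1]] == strsplit(rec, "")[[1]]), 0.98)
  }
})

test_that("truth comparison scores partitions, selections and breakpoints", {
  sim <- small_sim(6)
  truth <- sim$truth
  perfect <- truth_compare(truth, partition = truth$lineages)
  expect_equal(perfect$partition_ari, 1)

  relabel <- setNames(paste0("X", truth$lineages), names(truth$lineages))
  expect_equal(truth_compare(truth, partition = relabel)$partition_ari, 1)

  set.seed(99)
  aris <- replicate(20, truth_compare(truth, partition = setNames(
    sample(truth$lineages), names(truth$lineages)))$partition_ari)
  expect_lt(abs(mean(aris)), 0.15)   # near the chance level of the index

  sel <- truth_compare(truth,
                       selected_families = c(truth$selected$family, "zzz"))
  if (nrow(truth$selected)) {
    expect_equal(sel$selected_recall, 1)
    expect_lt(sel$selected_precision, 1)
  }
})
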