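# shared fixtures and independent oracles, built in code

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

mutate_seq <- function(s, p) {
  v <- strsplit(s, "")[[1]]
  hit <- which(runif(length(v)) < p)
  for (k in hit) v[k] <- sample(setdiff(c("A", "C", "G", "T"), v[k]), 1)
  paste(v, collapse = "")
}

# a tiny hand-built two-genome community with known coordinates
toy_community <- function() {
  g1 <- paste0("AAAA", "ATGAAATTTTAG", "CCCC", "ATGGGGAAATAA", "TTTT")
  g2 <- paste0("GGGG", "ATGAAATTCTAG", "CCCC")
  ann <- data.frame(
    genome_id = c("g1", "g1", "g2"),
    gene_id = c("a", "b", "c"),
    start = c(4L, 20L, 4L), end = c(16L, 32L, 16L),
    strand = c("+", "+", "+"), stringsAsFactors = FALSE)
  phage_community(c(g1 = g1, g2 = g2), ann,
                  sites = c(g1 = "coastal", g2 = "offshore"))
}

# small simulated community used by mid-weight tests
small_sim <- function(seed = 1, ...) {
  defaults <- list(
    seed = seed, n_lineages = 3L, genomes_per_lineage = 3L,
    n_core_genes = 5L, n_flexible_genes = 3L, mean_gene_codons = 60L,
    recomb_within_per_lineage = 0L, recomb_between_events = 0L,
    n_selected_genes = 0L)
  simulate_community(do.call(sim_config, modifyList(defaults, list(...))))
}

core_rows_of <- function(sim) {
  setNames(substring(sim$community$genomes, 1L, sim$truth$core_len),
           names(sim$community$genomes))
}

# brute-force nucleotide diversity: explicit double loop over pairs/sites
pi_oracle <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  vals <- c()
  for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
    diff <- 0; comp <- 0
    for (s in seq_len(ncol(m))) {
      bi <- m[i, s]; bj <- m[j, s]
      if (bi %in% c("A", "C", "G", "T") && bj %in% c("A", "C", "G", "T")) {
        comp <- comp + 1
        if (bi != bj) diff <- diff + 1
      }
    }
    vals <- c(vals, diff / comp)
  }
  mean(vals)
}

# exact two-tailed Fisher p by hypergeometric enumeration over all tables
# with the observed margins
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  kk <- max(0, k - n):min(k, m)
  probs <- dhyper(kk, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# best ungapped local alignment by scanning every diagonal (oracle for
# alignment identity/coverage on indel-free homology)
ungapped_local_oracle <- function(x, y, match = 2, mismatch = -3) {
  vx <- strsplit(x, "")[[1]]; vy <- strsplit(y, "")[[1]]
  best <- list(score = 0, len = 0, ident = 0)
  for (off in -(length(vx) - 1):(length(vy) - 1)) {
    i <- max(1, 1 - off); j <- i + off
    score <- 0; ident <- 0; len <- 0
    while (i <= length(vx) && j <= length(vy)) {
      s <- if (vx[i] == vy[j]) match else mismatch
      if (score + s < 0) { score <- 0; ident <- 0; len <- 0 }
      else {
        score <- score + s
        len <- len + 1
        ident <- ident + (vx[i] == vy[j])
        if (score > best$score) best <- list(score = score, len = len,
                                             ident = ident)
      }
      i <- i + 1; j <- j + 1
    }
  }
  best
}

# independent minimal Markov clustering (dense, no pruning) used as a
# reference for cluster structure on small graphs
mcl_oracle <- function(w, inflation = 2, iters = 300) {
  diag(w) <- apply(w, 1, max)
  M <- sweep(w, 2, colSums(w), "/")
  for (i in seq_len(iters)) {
    M <- M %*% M
    M <- M^inflation
    M <- sweep(M, 2, colSums(M), "/")
  }
  supp <- (M > 1e-5) | t(M > 1e-5)
  n <- nrow(w); lab <- seq_len(n); repeat {
    new <- lab
    for (i in seq_len(n)) new[i] <- min(lab[supp[i, ]])
    if (all(new == lab)) break
    lab <- new
  }
  lab
}

expect_same_partition <- function(a, b) {
  expect_equal(mclust::adjustedRandIndex(a, b), 1)
}
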