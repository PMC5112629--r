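#' All-vs-all gene similarity
#'
#' Best local alignment for every gene pair, reporting percent identity
#' over the aligned region and the fraction of the shorter gene covered by
#' the alignment. A k-mer seed prescreen (default on) skips pairs that do
#' not share any exact seed match; any pair sharing an exact run of
#' `seed_k + seed_step - 1` bp is guaranteed to be examined, which at the
#' default settings retains homologs down to roughly 70% identity. Set
#' `prescreen = FALSE` for an exhaustive scan (quadratic, use for small
#' gene sets or when distant homologs near the 40% filter boundary
#' matter).
#'
#' @param community a [phage_community] (gene sequences taken from
#'   `annotations$cds`).
#' @param prescreen logical; use the k-mer seed prescreen.
#' @param seed_k,seed_step seed length and indexing step of the prescreen.
#' @param match,mismatch,gap_opening,gap_extension local alignment scoring.
#' @return data.frame of class `similarity_edges` with columns `uid_a`,
#'   `uid_b` (canonical order `uid_a < uid_b`), `identity` (percent),
#'   `coverage_shorter` (fraction in (0,1]) and `score`.
#' @export
all_vs_all_similarity <- function(community, prescreen = TRUE,
                                  seed_k = 12L, seed_step = 6L,
                                  match = 2, mismatch = -3,
                                  gap_opening = 5, gap_extension = 2) {
  ann <- community$annotations
  if (nrow(ann) < 2L) stop("need at least 2 genes")
  seqs <- setNames(ann$cds, ann$uid)
  if (any(nchar(seqs) == 0L)) stop("empty gene sequence")
  n <- length(seqs)
  if (prescreen) {
    pairs <- seed_candidate_pairs(seqs, seed_k, seed_step)
  } else {
    idx <- combn(n, 2L)
    pairs <- data.frame(i = idx[1, ], j = idx[2, ])
  }
  if (nrow(pairs) == 0L)
    return(empty_edges())
  sm <- Biostrings::nucleotideSubstitutionMatrix(match, mismatch)
  out <- vector("list", length(unique(pairs$j)))
  k <- 0L
  for (j in sort(unique(pairs$j))) {
    ii <- pairs$i[pairs$j == j]
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(seqs[ii]), Biostrings::DNAString(seqs[[j]]),
      type = "local", substitutionMatrix = sm,
      gapOpening = gap_opening, gapExtension = gap_extension)
    len_i <- nchar(seqs[ii]); len_j <- nchar(seqs[[j]])
    span_p <- IRanges::width(Biostrings::pattern(aln))
    span_s <- IRanges::width(Biostrings::subject(aln))
    cov <- ifelse(len_i <= len_j, span_p / len_i, span_s / len_j)
    k <- k + 1L
    out[[k]] <- data.frame(
      uid_a = pmin(names(seqs)[ii], names(seqs)[j]),
      uid_b = pmax(names(seqs)[ii], names(seqs)[j]),
      identity = Biostrings::pid(aln, type = "PID1"),
      coverage_shorter = cov,
      score = Biostrings::score(aln),
      stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, out[seq_len(k)])
  edges <- edges[edges$coverage_shorter > 0, , drop = FALSE]
  edges <- edges[order(edges$uid_a, edges$uid_b), , drop = FALSE]
  rownames(edges) <- NULL
  class(edges) <- c("similarity_edges", "data.frame")
  edges
}

empty_edges <- function() {
  e <- data.frame(uid_a = character(), uid_b = character(),
                  identity = numeric(), coverage_shorter = numeric(),
                  score = numeric(), stringsAsFactors = FALSE)
  class(e) <- c("similarity_edges", "data.frame")
  e
}

# candidate pairs sharing >=1 exact seed k-mer (index stepped, query full)
seed_candidate_pairs <- function(seqs, k, step) {
  n <- length(seqs)
  index <- new.env(hash = TRUE, parent = emptyenv())
  for (g in seq_len(n)) {
    L <- nchar(seqs[[g]])
    if (L < k) next
    starts <- unique(c(seq(1L, L - k + 1L, by = step), L - k + 1L))
    for (km in unique(substring(seqs[[g]], starts, starts + k - 1L))) {
      index[[km]] <- c(index[[km]], g)
    }
  }
  hits <- vector("list", n)
  for (g in seq_len(n)) {
    L <- nchar(seqs[[g]])
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    partners <- integer(0)
    for (km in unique(substring(seqs[[g]], starts, starts + k - 1L))) {
      v <- index[[km]]
      if (!is.null(v)) partners <- c(partners, v)
    }
    partners <- unique(partners)
    hits[[g]] <- partners[partners > g]
  }
  data.frame(i = rep(seq_len(n), lengths(hits)), j = unlist(hits))
}

#' Read precomputed pairwise alignments (BLAST tabular, outfmt 6)
#'
#' Ingests a 12-column tabular alignment file (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore). Gene ids in
#' the file must be the community's gene uids. The best hit (highest bit
#' score) per unordered pair is kept; self hits are dropped. Coverage of
#' the shorter gene is alignment length / length of the shorter gene.
#'
#' @param path tabular file.
#' @param gene_lengths named integer vector: gene uid -> length (bp).
#' @return `similarity_edges` data.frame as from [all_vs_all_similarity].
#' @export
read_blast_pairs <- function(path, gene_lengths) {
  tb <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tb) < 12L) stop("expected 12-column tabular alignment file")
  names(tb)[1:12] <- c("q", "s", "pident", "length", "mismatch", "gapopen",
                       "qstart", "qend", "sstart", "send", "evalue", "bits")
  tb <- tb[tb$q != tb$s, , drop = FALSE]
  unknown <- setdiff(unique(c(tb$q, tb$s)), names(gene_lengths))
  if (length(unknown))
    stop("gene ids without lengths: ", paste(unknown, collapse = ", "))
  a <- pmin(tb$q, tb$s); b <- pmax(tb$q, tb$s)
  key <- paste(a, b)
  best <- tapply(seq_len(nrow(tb)), key, function(ii) ii[which.max(tb$bits[ii])])
  tb <- tb[unlist(best), , drop = FALSE]
  shorter <- pmin(gene_lengths[tb$q], gene_lengths[tb$s])
  edges <- data.frame(uid_a = pmin(tb$q, tb$s), uid_b = pmax(tb$q, tb$s),
                      identity = tb$pident,
                      coverage_shorter = pmin(1, tb$length / shorter),
                      score = tb$bits, stringsAsFactors = FALSE)
  edges <- edges[order(edges$uid_a, edges$uid_b), , drop = FALSE]
  rownames(edges) <- NULL
  class(edges) <- c("similarity_edges", "data.frame")
  edges
}

#' Homology filter
#'
#' Retains gene pairs with identity >= `min_identity` percent and coverage
#' of the shorter gene >= `min_coverage` (both boundaries inclusive).
#'
#' @param edges `similarity_edges`.
#' @param min_identity percent identity threshold (default 40).
#' @param min_coverage coverage-of-shorter threshold (default 0.60).
#' @return filtered `similarity_edges`.
#' @export
filter_homologs <- function(edges, min_identity = 40, min_coverage = 0.60) {
  keep <- edges$identity >= min_identity & edges$coverage_shorter >= min_coverage
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Markov clustering of the homology graph
#'
#' Groups genes into protein clusters by Markov clustering (MCL) of the
#' filtered homology graph, with percent identity as edge weight. Nodes
#' are sorted lexicographically before matrix construction so the result
#' is invariant to input order; self-loops with the maximum incident
#' weight are added before normalization. Expansion (matrix square) and
#' inflation (elementwise power `inflation`, column renormalization)
#' alternate until the maximum entry change drops below `tol` (error at
#' `max_iter`). Clusters are the connected components of the converged
#' attractor support; genes without surviving edges become singletons.
#'
#' @param edges filtered `similarity_edges`.
#' @param gene_uids character vector of all gene uids in the community
#'   (so isolated genes appear as singleton clusters).
#' @param inflation inflation exponent (granularity), default 2.
#' @param max_iter,tol iteration cap and convergence tolerance.
#' @return data.frame of class `gene_clusters`: `cluster_id`, `uid`,
#'   `genome_id`, `gene_id`, ordered by decreasing cluster size.
#' @export
markov_cluster <- function(edges, gene_uids, inflation = 2,
                           max_iter = 200L, tol = 1e-6) {
  gene_uids <- sort(unique(gene_uids))
  unknown <- setdiff(unique(c(edges$uid_a, edges$uid_b)), gene_uids)
  if (length(unknown))
    stop("edges refer to genes not in gene_uids: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  adj <- split(c(edges$uid_b, edges$uid_a), c(edges$uid_a, edges$uid_b))
  comps <- graph_components(gene_uids, adj)
  ekey <- paste(edges$uid_a, edges$uid_b)
  clusters <- list()
  for (comp in comps) {
    if (length(comp) == 1L) { clusters <- c(clusters, list(comp)); next }
    comp <- sort(comp)
    m <- matrix(0, length(comp), length(comp), dimnames = list(comp, comp))
    sel <- edges$uid_a %in% comp
    e <- edges[sel, , drop = FALSE]
    m[cbind(e$uid_a, e$uid_b)] <- e$identity
    m[cbind(e$uid_b, e$uid_a)] <- e$identity
    diag(m) <- apply(m, 1L, max)
    clusters <- c(clusters, mcl_component(m, inflation, max_iter, tol))
  }
  sizes <- lengths(clusters)
  ord <- order(-sizes, vapply(clusters, function(x) sort(x)[1], ""))
  clusters <- clusters[ord]
  ids <- sprintf("PC%05d", seq_along(clusters))
  uid <- unlist(clusters, use.names = FALSE)
  parts <- strsplit(uid, "|", fixed = TRUE)
  out <- data.frame(cluster_id = rep(ids, lengths(clusters)), uid = uid,
                    genome_id = vapply(parts, `[`, "", 1L),
                    gene_id = vapply(parts, `[`, "", 2L),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_clusters", "data.frame")
  out
}

# connected components via iterative BFS over an adjacency list
graph_components <- function(nodes, adj) {
  seen <- new.env(hash = TRUE, parent = emptyenv())
  comps <- list()
  for (v in nodes) {
    if (!is.null(seen[[v]])) next
    queue <- v; seen[[v]] <- TRUE; comp <- character(0)
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, u)
      for (w in adj[[u]]) if (is.null(seen[[w]])) {
        seen[[w]] <- TRUE; queue <- c(queue, w)
      }
    }
    comps <- c(comps, list(comp))
  }
  comps
}

mcl_component <- function(m, inflation, max_iter, tol) {
  norm_cols <- function(x) sweep(x, 2L, colSums(x), "/")
  M <- norm_cols(m)
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < 1e-12] <- 0
    M2 <- norm_cols(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) {
      supp <- (M > 1e-5) | t(M > 1e-5)
      lab <- rownames(m)
      adj <- setNames(lapply(seq_along(lab), function(i) lab[supp[i, ]]), lab)
      return(graph_components(lab, adj))
    }
  }
  stop("Markov clustering did not converge in ", max_iter,
       " iterations (residual ", signif(delta, 3), ")")
}

#' Flag core clusters
#'
#' A cluster is core when every genome of the collection contributes at
#' least one member. Genomes contributing more than one member to a core
#' cluster (possible intron artifacts) are flagged via `multi_copy`.
#'
#' @param clusters `gene_clusters` from [markov_cluster].
#' @param genome_ids character vector of all genome ids.
#' @return data.frame: `cluster_id`, `n_genes`, `n_genomes`, `is_core`,
#'   `multi_copy`.
#' @export
core_clusters <- function(clusters, genome_ids) {
  sp <- split(clusters$genome_id, clusters$cluster_id)
  out <- data.frame(
    cluster_id = names(sp),
    n_genes = lengths(sp),
    n_genomes = vapply(sp, function(g) length(unique(g)), 0L),
    stringsAsFactors = FALSE)
  out$is_core <- vapply(sp, function(g) all(genome_ids %in% g), TRUE)
  out$multi_copy <- vapply(sp, anyDuplicated, 0L) > 0L
  rownames(out) <- NULL
  out[order(out$cluster_id), ]
}

#' Shared-gene fraction between two genomes
#'
#' Number of clusters shared (>=1 member from each genome) divided by each
#' genome's total cluster count (singletons are clusters of size one and
#' count toward the denominator). The mean of the two directed fractions
#' is what matrix figures use.
#'
#' @param clusters `gene_clusters`.
#' @param genome_a,genome_b genome ids.
#' @return list with `fraction_a`, `fraction_b`, `mean_fraction`, `shared`,
#'   `n_clusters_a`, `n_clusters_b`.
#' @export
shared_gene_fraction <- function(clusters, genome_a, genome_b) {
  ca <- unique(clusters$cluster_id[clusters$genome_id == genome_a])
  cb <- unique(clusters$cluster_id[clusters$genome_id == genome_b])
  if (!length(ca)) stop("genome with no genes: ", genome_a)
  if (!length(cb)) stop("genome with no genes: ", genome_b)
  shared <- length(intersect(ca, cb))
  fa <- shared / length(ca); fb <- shared / length(cb)
  list(fraction_a = fa, fraction_b = fb, mean_fraction = (fa + fb) / 2,
       shared = shared, n_clusters_a = length(ca), n_clusters_b = length(cb))
}

#' Pairwise shared-gene fraction matrix
#'
#' @param clusters `gene_clusters`.
#' @param genome_ids genome ids spanning the matrix.
#' @return symmetric matrix of mean shared fractions, diagonal 1.
#' @export
shared_gene_matrix <- function(clusters, genome_ids) {
  inc <- table(clusters$genome_id, clusters$cluster_id) > 0
  inc <- inc[genome_ids, , drop = FALSE]
  shared <- inc %*% t(inc)
  tot <- rowSums(inc)
  frac <- (shared / tot + t(shared / tot)) / 2
  diag(frac) <- 1
  frac
}
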