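#' Read an aligned FASTA file
#'
#' @param path aligned FASTA; all records must have equal length.
#' @return named character vector of aligned sequences (uppercase).
#' @export
read_alignment <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  s <- setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
  if (length(unique(nchar(s))) != 1L)
    stop("alignment rows differ in length")
  s
}

#' Filter core alignment blocks
#'
#' Keeps blocks strictly longer than `min_len` alignment columns; with
#' `require_all`, blocks missing any of the required genomes are dropped.
#'
#' @param blocks list of blocks, each a list with `block_id`, `seqs`
#'   (named character, aligned) and optionally `start` (named 0-based
#'   genomic start per member).
#' @param min_len minimum alignment length, exclusive (default 500).
#' @param genomes genome ids that must all be present (default: union over
#'   blocks).
#' @param require_all drop blocks missing a required genome.
#' @return filtered list of blocks.
#' @export
filter_core_blocks <- function(blocks, min_len = 500, genomes = NULL,
                               require_all = TRUE) {
  if (is.null(genomes))
    genomes <- unique(unlist(lapply(blocks, function(b) names(b$seqs))))
  keep <- vapply(blocks, function(b) {
    len_ok <- nchar(b$seqs[[1]]) > min_len
    all_ok <- !require_all || all(genomes %in% names(b$seqs))
    len_ok && all_ok
  }, TRUE)
  blocks[keep]
}

# integer-coded alignment matrix: 1..4 for A/C/G/T, NA for gap/ambiguous
code_matrix <- function(seqs) {
  m <- seq_matrix(seqs)
  matrix(match(m, BASES), nrow = nrow(m), dimnames = dimnames(m))
}

pair_diff_rate <- function(xi, xj, who = "") {
  ok <- !is.na(xi) & !is.na(xj)
  if (!any(ok)) stop("no comparable sites for a sequence pair ", who)
  mean(xi[ok] != xj[ok])
}

#' Nucleotide diversity
#'
#' pi is the mean over all unordered sequence pairs of the per-site
#' mismatch proportion; columns with a gap or ambiguous base in either
#' member of a pair are excluded from that pair's comparison.
#'
#' @param seqs named character vector of >= 2 equal-length aligned
#'   sequences.
#' @return list with `pi` and `n_seq`.
#' @export
nucleotide_diversity <- function(seqs) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  x <- code_matrix(seqs)
  cmb <- combn(nrow(x), 2L)
  pi <- mean(vapply(seq_len(ncol(cmb)), function(k)
    pair_diff_rate(x[cmb[1, k], ], x[cmb[2, k], ]), 0))
  list(pi = pi, n_seq = nrow(x))
}

#' Fixation index between two subpopulations
#'
#' F_ST = 1 - pi_within / pi_between with pi_within the mean of the two
#' within-subpopulation diversities and pi_between the mean mismatch rate
#' over pairs spanning the two subpopulations. A single-member
#' subpopulation has within-diversity 0 (with a warning); when pi_between
#' is 0 the index is undefined and reported as `NA`.
#'
#' @param s1,s2 named character vectors of aligned sequences (same
#'   alignment length).
#' @return list with `pi_s1`, `pi_s2`, `pi_between`, `fst`.
#' @export
fst <- function(s1, s2) {
  if (!length(s1) || !length(s2)) stop("empty subpopulation")
  pw <- function(s, tag) {
    if (length(s) == 1L) {
      warning("single-member subpopulation ", tag, ": pi set to 0")
      0
    } else nucleotide_diversity(s)$pi
  }
  pi1 <- pw(s1, "S1"); pi2 <- pw(s2, "S2")
  x <- code_matrix(c(s1, s2))
  n1 <- length(s1)
  cross <- expand.grid(i = seq_len(n1), j = n1 + seq_along(s2))
  pib <- mean(vapply(seq_len(nrow(cross)), function(k)
    pair_diff_rate(x[cross$i[k], ], x[cross$j[k], ]), 0))
  f <- if (pib > 0) 1 - ((pi1 + pi2) / 2) / pib else NA_real_
  list(pi_s1 = pi1, pi_s2 = pi2, pi_between = pib, fst = f)
}

#' Remove low-frequency polymorphisms within a lineage
#'
#' At every alignment column, alleles carried by strictly less than
#' `threshold` of the lineage's individuals are replaced by the lineage
#' major allele (alleles at exactly the threshold are retained). Gap and
#' ambiguous characters are left untouched and do not count as alleles.
#'
#' @param seqs named character vector of a lineage's aligned sequences
#'   (n >= 2).
#' @param threshold frequency threshold (default 0.15).
#' @return character vector of filtered sequences, same names/order.
#' @export
polymorphism_frequency_filter <- function(seqs, threshold = 0.15) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  m <- seq_matrix(seqs)
  n <- nrow(m)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    isb <- col %in% BASES
    if (!any(isb)) next
    tab <- table(col[isb])
    if (length(tab) < 2L) next
    major <- names(tab)[order(-tab, names(tab))][1]
    low <- names(tab)[tab / n < threshold]
    low <- setdiff(low, major)
    if (length(low)) m[col %in% low, j] <- major
  }
  matrix_to_seqs(m)
}

# all orderings of a small index vector (codons: at most 3 positions)
small_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in small_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  out
}

.path_cache <- new.env(hash = TRUE, parent = emptyenv())

# average syn/nonsyn step counts over minimal mutational pathways between
# two codons; pathways through intermediate stop codons are excluded
# unless all pass through one; memoized (4096 codon pairs at most)
classify_codon_path <- function(c1, c2) {
  key <- paste0(c1, c2)
  hit <- .path_cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- classify_codon_path_raw(c1, c2)
  .path_cache[[key]] <- res
  res
}

classify_codon_path_raw <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(syn = 0, nonsyn = 0))
  v1 <- strsplit(c1, "")[[1]]; v2 <- strsplit(c2, "")[[1]]
  paths <- small_perms(pos)
  res <- lapply(paths, function(ord) {
    cur <- v1; syn <- 0; nonsyn <- 0; stop_mid <- FALSE
    for (k in seq_along(ord)) {
      nxt <- cur; nxt[ord[k]] <- v2[ord[k]]
      aa1 <- GENETIC_CODE_TABLE[paste(cur, collapse = "")]
      aa2 <- GENETIC_CODE_TABLE[paste(nxt, collapse = "")]
      if (aa2 == "*" && k < length(ord)) stop_mid <- TRUE
      if (aa1 == aa2) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn, stop_mid = as.numeric(stop_mid))
  })
  res <- do.call(rbind, res)
  use <- res[, "stop_mid"] == 0
  if (!any(use)) use <- rep(TRUE, nrow(res))
  c(syn = mean(res[use, "syn"]), nonsyn = mean(res[use, "nonsyn"]))
}

#' McDonald-Kreitman substitution/polymorphism counts for one gene
#'
#' Counts, per codon column of a codon-aligned gene, synonymous and
#' nonsynonymous fixed differences between two lineages (`a`, `c`) and
#' synonymous and nonsynonymous polymorphisms within them (`b`, `d`). A
#' column monomorphic in both lineages but for different codons is a fixed
#' difference; a column segregating in either lineage contributes each
#' distinct segregating codon once, classified against that lineage's
#' major codon, and never also counts as fixed. Codons differing at more
#' than one position are resolved by averaging over minimal mutational
#' pathways (fractional counts). Codon columns containing gaps or
#' ambiguous bases are skipped; a gene whose major codon at an internal
#' position is a stop is skipped entirely (with a warning).
#'
#' @param a_seqs,b_seqs aligned coding sequences of the two lineages
#'   (equal length, divisible by 3), after any frequency filtering.
#' @return list with fractional counts `a`, `b`, `c`, `d`, the number of
#'   usable codon columns `n_codons`, and `skipped`.
#' @export
count_mk <- function(a_seqs, b_seqs) {
  L <- unique(nchar(c(a_seqs, b_seqs)))
  if (length(L) != 1L || L %% 3L != 0L)
    stop("sequences must share one length divisible by 3")
  codA <- vapply(a_seqs, codons_of, character(L / 3))
  codB <- vapply(b_seqs, codons_of, character(L / 3))
  codA <- matrix(codA, ncol = length(a_seqs))
  codB <- matrix(codB, ncol = length(b_seqs))
  okA <- matrix(codA %in% names(GENETIC_CODE_TABLE), nrow = nrow(codA))
  okB <- matrix(codB %in% names(GENETIC_CODE_TABLE), nrow = nrow(codB))
  a <- b <- cc <- d <- 0; used <- 0L
  nc <- L / 3L
  major_of <- function(cods) {
    tab <- table(cods)
    names(tab)[order(-tab, names(tab))][1]
  }
  for (k in seq_len(nc)) {
    ca <- codA[k, ]; cb <- codB[k, ]
    if (!all(okA[k, ]) || !all(okB[k, ])) next
    invariant <- all(ca == ca[1L]) && all(cb == ca[1L])
    if (invariant && !is_stop(ca[1L])) { used <- used + 1L; next }
    ua <- unique(ca); ub <- unique(cb)
    majA <- major_of(ca); majB <- major_of(cb)
    if (k < nc && (is_stop(majA) || is_stop(majB))) {
      warning("internal stop codon: gene skipped")
      return(list(a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
                  n_codons = NA_integer_, skipped = TRUE))
    }
    used <- used + 1L
    if (length(ua) == 1L && length(ub) == 1L) {
      if (ua != ub) {
        cl <- classify_codon_path(ua, ub)
        a <- a + cl["syn"]; cc <- cc + cl["nonsyn"]
      }
    } else {
      for (v in setdiff(ua, majA)) {
        cl <- classify_codon_path(majA, v)
        b <- b + cl["syn"]; d <- d + cl["nonsyn"]
      }
      for (v in setdiff(ub, majB)) {
        cl <- classify_codon_path(majB, v)
        b <- b + cl["syn"]; d <- d + cl["nonsyn"]
      }
    }
  }
  list(a = unname(a), b = unname(b), c = unname(cc), d = unname(d),
       n_codons = used, skipped = FALSE)
}

#' Two-tailed Fisher's exact test on MK counts
#'
#' Exact p by summing hypergeometric probabilities no larger than the
#' observed table's, on the 2x2 table of (fixed, polymorphic) x
#' (synonymous, nonsynonymous). Fractional counts are rounded to the
#' nearest integer for the exact test.
#'
#' @param a,b,c,d MK counts (see [count_mk]).
#' @return list with `p_value` and `degenerate` (TRUE for the all-zero
#'   table, where p = 1 by convention).
#' @export
mk_fisher <- function(a, b, c, d) {
  tab <- matrix(round(c(a, b, c, d)), nrow = 2, byrow = TRUE)
  if (any(tab < 0)) stop("negative counts")
  if (all(tab == 0)) return(list(p_value = 1, degenerate = TRUE))
  list(p_value = fisher.test(tab)$p.value, degenerate = FALSE)
}

#' Phi effect size of an MK table
#'
#' phi = (ad - bc) / sqrt(efgh) with e = a+b, f = c+d, g = a+c, h = b+d.
#' Undefined (NA) when any marginal is zero. With `a` = synonymous fixed
#' and `c` = nonsynonymous fixed, an excess of nonsynonymous fixation
#' (the positive-selection direction) gives ad < bc, i.e. negative phi.
#'
#' @param a,b,c,d MK counts (raw, possibly fractional).
#' @return phi in `[-1, 1]` or NA.
#' @export
phi_coefficient <- function(a, b, c, d) {
  e <- a + b; f <- c + d; g <- a + c; h <- b + d
  if (any(c(e, f, g, h) == 0)) return(NA_real_)
  (a * d - b * c) / sqrt(e * f * g * h)
}

#' Genome-wide McDonald-Kreitman selection scan
#'
#' Runs the non-polarized MK test on every (gene cluster, lineage pair)
#' combination: within-lineage low-frequency polymorphisms are removed,
#' substitutions and polymorphisms are counted with [count_mk], and a gene
#' is called selected when the two-tailed Fisher p-value is below `alpha`,
#' the phi effect size passes `phi_min` (by absolute value by default, or
#' signed toward nonsynonymous fixation with `phi_gate = "signed"`), and
#' the table is oriented toward nonsynonymous fixation excess (ad < bc).
#' An expected-false-positive summary (`alpha` times the number of tests)
#' is attached as attribute `fpr`.
#'
#' @param community a [phage_community].
#' @param clusters `gene_clusters`.
#' @param partition named character vector genome id -> lineage.
#' @param which_clusters cluster ids to test (default: every cluster, as
#'   the scan runs on all genes shared by a lineage pair; clusters with
#'   multiple copies in a genome or inconsistent lengths are skipped).
#' @param freq_threshold low-frequency polymorphism threshold (default
#'   0.15).
#' @param alpha significance level (default 0.05).
#' @param phi_min effect-size cutoff (default 0.1).
#' @param phi_gate `"abs"` (default) or `"signed"`.
#' @return data.frame: `cluster_id`, `lineage_a`, `lineage_b`, `a`, `b`,
#'   `c`, `d`, `p_value`, `phi`, `selected`; attribute `fpr` carries
#'   `n_tests`, `expected_false_positives`, `n_selected`.
#' @export
selection_scan <- function(community, clusters, partition,
                           which_clusters = NULL, freq_threshold = 0.15,
                           alpha = 0.05, phi_min = 0.1,
                           phi_gate = c("abs", "signed")) {
  phi_gate <- match.arg(phi_gate)
  ann <- community$annotations
  genomes <- names(partition)
  if (is.null(which_clusters))
    which_clusters <- sort(unique(clusters$cluster_id))
  lineages <- sort(unique(partition))
  pairs <- if (length(lineages) >= 2L) combn(lineages, 2L) else
    matrix(character(0), 2, 0)
  cds_of <- setNames(ann$cds, ann$uid)
  rows <- list()
  for (cl in which_clusters) {
    mem <- clusters[clusters$cluster_id == cl & clusters$genome_id %in% genomes, ]
    if (anyDuplicated(mem$genome_id)) next
    seqs <- setNames(cds_of[mem$uid], mem$genome_id)
    if (length(seqs) < 2L) next
    if (length(unique(nchar(seqs))) != 1L || nchar(seqs[1]) %% 3L != 0L) {
      warning("cluster ", cl, " not codon-alignable; skipped")
      next
    }
    for (p in seq_len(ncol(pairs))) {
      la <- pairs[1, p]; lb <- pairs[2, p]
      ga <- names(partition)[partition == la]
      gb <- names(partition)[partition == lb]
      sa <- seqs[intersect(ga, names(seqs))]
      sb <- seqs[intersect(gb, names(seqs))]
      if (!length(sa) || !length(sb)) next
      if (length(sa) >= 2L)
        sa <- polymorphism_frequency_filter(sa, freq_threshold)
      if (length(sb) >= 2L)
        sb <- polymorphism_frequency_filter(sb, freq_threshold)
      cnt <- suppressWarnings(count_mk(sa, sb))
      if (isTRUE(cnt$skipped)) next
      pv <- mk_fisher(cnt$a, cnt$b, cnt$c, cnt$d)$p_value
      phi <- phi_coefficient(cnt$a, cnt$b, cnt$c, cnt$d)
      dn_excess <- cnt$a * cnt$d < cnt$b * cnt$c
      gate <- if (is.na(phi)) FALSE else
        if (phi_gate == "abs") abs(phi) >= phi_min else -phi >= phi_min
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = cl, lineage_a = la, lineage_b = lb,
        a = cnt$a, b = cnt$b, c = cnt$c, d = cnt$d,
        p_value = pv, phi = phi,
        selected = pv < alpha && gate && dn_excess,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = character(), lineage_a = character(),
               lineage_b = character(), a = numeric(), b = numeric(),
               c = numeric(), d = numeric(), p_value = numeric(),
               phi = numeric(), selected = logical())
  rownames(out) <- NULL
  attr(out, "fpr") <- list(n_tests = nrow(out),
                           expected_false_positives = alpha * nrow(out),
                           n_selected = sum(out$selected))
  out
}
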