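#' Per-genome genometrics
#'
#' Genome length, GC fraction and gene count for every genome in a
#' community. Ambiguous bases (anything outside A/C/G/T) are excluded from
#' the GC denominator; a genome with no unambiguous base gets `NA`.
#'
#' @param community a [phage_community].
#' @return data.frame with columns `genome_id`, `length_bp`, `gc_fraction`,
#'   `gene_count`.
#' @export
compute_genometrics <- function(community) {
  seqs <- community$genomes
  counts <- t(vapply(seqs, function(s) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    c(sum(v %in% c("G", "C")), sum(v %in% BASES))
  }, numeric(2)))
  gc <- ifelse(counts[, 2] > 0, counts[, 1] / counts[, 2], NA_real_)
  gcount <- table(factor(community$annotations$genome_id,
                         levels = names(seqs)))
  data.frame(genome_id = names(seqs),
             length_bp = unname(nchar(seqs)),
             gc_fraction = unname(gc),
             gene_count = as.integer(gcount),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Grubbs' test for a single outlier
#'
#' Two-sided Grubbs' test: G = max |x_i - mean| / sd, compared with the
#' t-distribution based critical value. With zero spread the statistic is
#' defined as 0 and no outlier is reported.
#'
#' @param values numeric vector, length >= 3.
#' @param alpha significance level for the outlier call.
#' @return list with `index` (index of the flagged value or `NA`), `G`,
#'   `p_value` and `critical` (critical G at `alpha`).
#' @export
grubbs_outlier <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3L) stop("Grubbs' test requires at least 3 values")
  s <- sd(values)
  if (s == 0) return(list(index = NA_integer_, G = 0, p_value = 1,
                          critical = grubbs_critical(n, alpha)))
  dev <- abs(values - mean(values))
  i <- which.max(dev)
  G <- dev[i] / s
  # p-value by inverting G -> t; G at the theoretical max gives p = 0
  num <- n * (n - 2) * G^2
  den <- (n - 1)^2 - n * G^2
  p <- if (den <= 0) 0 else min(1, 2 * n * pt(sqrt(num / den), df = n - 2,
                                              lower.tail = FALSE))
  crit <- grubbs_critical(n, alpha)
  list(index = if (G > crit) i else NA_integer_, G = unname(G),
       p_value = p, critical = crit)
}

grubbs_critical <- function(n, alpha) {
  t2 <- qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)^2
  (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
}

#' Per-lineage summaries of genometrics
#'
#' Mean and sample (n-1) standard deviation of genome length, GC percent
#' and gene count per lineage, with explicit exclusions (e.g. statistical
#' outliers flagged by [grubbs_outlier]). A single-member lineage gets
#' sd = 0 with `sd_defined = FALSE`.
#'
#' @param genometrics output of [compute_genometrics].
#' @param lineages named character vector: genome id -> lineage id; every
#'   genome in `genometrics` must be assigned.
#' @param exclude genome ids to drop before summarizing.
#' @return data.frame, one row per lineage.
#' @export
lineage_summary <- function(genometrics, lineages, exclude = character()) {
  gm <- genometrics
  if (!all(gm$genome_id %in% names(lineages)))
    stop("every genome must be assigned to a lineage")
  gm$lineage <- lineages[gm$genome_id]
  keep <- !(gm$genome_id %in% exclude)
  empty <- setdiff(unique(gm$lineage), unique(gm$lineage[keep]))
  if (length(empty))
    stop("lineage(s) with no non-excluded members: ",
         paste(empty, collapse = ", "))
  gm <- gm[keep, ]
  one <- function(d) {
    sdv <- function(x) if (length(x) > 1L) sd(x) else 0
    data.frame(lineage_id = d$lineage[1], n = nrow(d),
               mean_length_bp = mean(d$length_bp),
               sd_length_bp = sdv(d$length_bp),
               mean_gc_percent = mean(100 * d$gc_fraction),
               sd_gc_percent = sdv(100 * d$gc_fraction),
               mean_gene_count = mean(d$gene_count),
               sd_gene_count = sdv(d$gene_count),
               sd_defined = nrow(d) > 1L,
               excluded = paste(intersect(exclude, genometrics$genome_id[
                 lineages[genometrics$genome_id] == d$lineage[1]]),
                 collapse = ","),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(split(gm, gm$lineage), one))
  rownames(out) <- NULL
  out[order(out$lineage_id), ]
}

#' Codon usage per lineage
#'
#' Codon counts pooled over all genes of all member genomes, with relative
#' frequencies within each amino acid under the standard genetic code.
#' Genes whose coding sequence length is not divisible by 3 are skipped
#' with a warning; stop codons are tabulated under amino acid `"*"`.
#'
#' @param community a [phage_community].
#' @param lineages named character vector genome id -> lineage id.
#' @return data.frame with `lineage_id`, `codon`, `amino_acid`, `count`,
#'   `rel_freq` (within-amino-acid relative frequency).
#' @export
codon_usage <- function(community, lineages) {
  ann <- community$annotations
  ann$lineage <- lineages[ann$genome_id]
  bad <- nchar(ann$cds) %% 3L != 0L
  if (any(bad))
    warning("skipping ", sum(bad), " gene(s) with length not divisible by 3")
  ann <- ann[!bad, ]
  all_codons <- names(GENETIC_CODE_TABLE)
  out <- lapply(split(ann, ann$lineage), function(d) {
    cod <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(d$cds), width = 3L, step = 3L)
    counts <- colSums(cod)[all_codons]
    aa <- unname(GENETIC_CODE_TABLE[all_codons])
    tot <- tapply(counts, aa, sum)[aa]
    data.frame(lineage_id = d$lineage[1], codon = all_codons,
               amino_acid = aa, count = as.numeric(counts),
               rel_freq = ifelse(tot > 0, counts / tot, NA_real_),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
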