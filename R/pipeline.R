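#' Pipeline parameter set
#'
#' Every stage constant is surfaced here with its conventional default:
#' 40% identity / 60% coverage homology filter, Markov clustering
#' inflation 2, prior divergence grid 0.001-0.1 with barcode gap factor
#' 1.5, 500 bp core-block minimum, 15% polymorphism frequency filter,
#' alpha 0.05 with phi cutoff 0.1 for selection calls, and 50 bp
#' breakpoint flanks.
#'
#' @param min_identity,min_coverage homology filter thresholds.
#' @param inflation Markov clustering granularity.
#' @param prior_grid barcode-gap prior divergences (substitutions/site).
#' @param gap_factor barcode gap width multiplier.
#' @param min_block_len minimum core block length (exclusive bound, bp).
#' @param freq_threshold within-lineage polymorphism frequency filter.
#' @param alpha significance level for MK selection calls.
#' @param phi_min phi effect-size cutoff.
#' @param phi_gate `"abs"` or `"signed"` phi gating.
#' @param flank breakpoint flank length (bp).
#' @param detect_window,detect_min_run,detect_permutations parameters of
#'   the internal stand-in recombination detector.
#' @param prescreen use the k-mer prescreen in all-vs-all similarity.
#' @param seed RNG seed for permutation-based steps.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_identity = 40, min_coverage = 0.60,
                            inflation = 2,
                            prior_grid = 10^seq(log10(0.001), log10(0.1),
                                                length.out = 10),
                            gap_factor = 1.5, min_block_len = 500,
                            freq_threshold = 0.15, alpha = 0.05,
                            phi_min = 0.1, phi_gate = "abs", flank = 50L,
                            detect_window = 200L, detect_min_run = 3L,
                            detect_permutations = 500L,
                            prescreen = TRUE, seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline or simulation configuration from YAML
#'
#' Unknown keys are rejected; listed keys override the defaults of
#' [pipeline_config] / [sim_config].
#'
#' @param path YAML file.
#' @param kind `"pipeline"` or `"sim"`.
#' @return a `pipeline_config` or `sim_config`.
#' @export
read_config_yaml <- function(path, kind = c("pipeline", "sim")) {
  kind <- match.arg(kind)
  vals <- yaml::read_yaml(path)
  maker <- if (kind == "pipeline") pipeline_config else sim_config
  allowed <- names(formals(maker))
  bad <- setdiff(names(vals), allowed)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(maker, vals)
}

#' Run the full population-genomics pipeline
#'
#' Executes the stages in dependency order: genometrics; gene families
#' (all-vs-all similarity, homology filter, Markov clustering, core
#' clusters, shared-gene fractions); population structure (ANI,
#' Jukes-Cantor distances on the concatenated core genes, barcode-gap
#' delimitation over the prior grid, ordination, per-lineage divergence
#' tests); population genetics (F_ST per lineage between source sites, MK
#' selection scan); recombination (external event table or the internal
#' stand-in detector, event-rate normalization, breakpoint localization
#' and genic/intergenic classification). Given identical inputs and
#' configuration the returned summary (and any files written) is
#' reproduced exactly.
#'
#' @param community a [phage_community].
#' @param config a [pipeline_config].
#' @param core_blocks optional externally produced core alignment blocks
#'   (list of blocks as in [filter_core_blocks]); after length/completeness
#'   filtering they are concatenated and used for F_ST and recombination,
#'   mirroring the use of whole-genome-aligner output. Without them those
#'   stages fall back to the concatenated core genes.
#' @param event_lineages optional named vector genome id -> lineage used
#'   to normalize external event counts (external tables carry their own
#'   lineage labels); defaults to the inferred partition.
#' @param external_events optional recombination event table (columns
#'   `event_id`, `scope`, `lineage_a`, `lineage_b`, `recipient`,
#'   `breakpoint`, the latter a 0-based column of the F_ST/recombination
#'   alignment) taking precedence over the internal detector.
#' @param output_dir optional directory for per-stage TSVs and
#'   `summary.json`.
#' @return list of class `phagepop_result` with elements `genometrics`,
#'   `edges`, `clusters`, `core`, `shared`, `ani`, `jc`, `delimitation`,
#'   `partition`, `ordination`, `divergence_tests`, `lineage_table`,
#'   `fst`, `mk`, `events`, `event_rates`, `breakpoints`,
#'   `intergenic`, `summary`.
#' @export
run_pipeline <- function(community, config = pipeline_config(),
                         core_blocks = NULL, external_events = NULL,
                         event_lineages = NULL, output_dir = NULL) {
  stopifnot(inherits(community, "phage_community"))
  if (length(community$genomes) == 0L) stop("empty community")
  set.seed(config$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  genome_ids <- names(community$genomes)
  res <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  res$genometrics <- stage("genometrics", compute_genometrics(community))

  res$edges <- stage("families", all_vs_all_similarity(
    community, prescreen = config$prescreen))
  hom <- filter_homologs(res$edges, config$min_identity, config$min_coverage)
  res$clusters <- stage("families", markov_cluster(
    hom, community$annotations$uid, inflation = config$inflation))
  res$core <- core_clusters(res$clusters, genome_ids)
  res$shared <- shared_gene_matrix(res$clusters, genome_ids)

  res$ani <- stage("structure", ani_matrix(res$clusters, res$edges,
                                           genome_ids))
  core_rows <- stage("structure",
                     concat_core_genes(community, res$clusters, res$core))
  popgen_rows <- if (!is.null(core_blocks)) {
    blocks <- stage("popgen", filter_core_blocks(
      core_blocks, min_len = config$min_block_len, genomes = genome_ids))
    if (!length(blocks)) stop("no core blocks survive the length filter")
    rows <- setNames(rep("", length(genome_ids)), genome_ids)
    for (b in blocks) rows <- paste0(rows, b$seqs[genome_ids])
    setNames(rows, genome_ids)
  } else core_rows
  res$core_alignment <- popgen_rows
  res$jc <- stage("structure", jc_matrix(core_rows))
  res$delimitation <- stage("structure", barcode_gap_partition(
    res$jc$d, prior_grid = config$prior_grid,
    gap_factor = config$gap_factor))
  res$partition <- res$delimitation$partition
  res$ordination <- stage("structure", ordinate_ani(res$ani))
  res$divergence_tests <- stage("structure", {
    lin <- sort(unique(res$partition))
    if (length(lin) >= 3L) {
      do.call(rbind, lapply(lin, function(l) {
        t <- lineage_divergence_test(res$jc$d, res$partition, l)
        data.frame(lineage = l, U = t$U, p_value = t$p_value,
                   method = t$method, stringsAsFactors = FALSE)
      }))
    } else NULL
  })

  res$lineage_table <- stage("genometrics", {
    excl <- character(0)
    for (l in unique(res$partition)) {
      mem <- names(res$partition)[res$partition == l]
      if (length(mem) >= 3L) {
        g <- grubbs_outlier(res$genometrics$length_bp[
          match(mem, res$genometrics$genome_id)])
        if (!is.na(g$index)) excl <- c(excl, mem[g$index])
      }
    }
    lineage_summary(res$genometrics, res$partition, exclude = excl)
  })

  res$fst <- stage("popgen", {
    rows <- list()
    for (l in sort(unique(res$partition))) {
      mem <- names(res$partition)[res$partition == l]
      s <- community$sites[mem]
      if (sum(s == "coastal") >= 2L && sum(s == "offshore") >= 2L) {
        f <- suppressWarnings(fst(popgen_rows[mem[s == "coastal"]],
                                  popgen_rows[mem[s == "offshore"]]))
        rows[[l]] <- data.frame(lineage = l, n_coastal = sum(s == "coastal"),
                                n_offshore = sum(s == "offshore"),
                                pi_coastal = f$pi_s1, pi_offshore = f$pi_s2,
                                pi_between = f$pi_between, fst = f$fst,
                                stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  })

  res$mk <- stage("popgen", selection_scan(
    community, res$clusters, res$partition,
    freq_threshold = config$freq_threshold, alpha = config$alpha,
    phi_min = config$phi_min, phi_gate = config$phi_gate))

  res$events <- stage("recombination", {
    if (!is.null(external_events)) external_events
    else detect_events_simple(popgen_rows, res$partition,
                              window = config$detect_window,
                              min_run = config$detect_min_run,
                              n_permutations = config$detect_permutations)
  })
  sizes <- table(if (!is.null(event_lineages)) event_lineages else
                   res$partition)
  res$event_rates <- stage("recombination", normalize_events(
    res$events, setNames(as.integer(sizes), names(sizes))))
  res$breakpoints <- stage("recombination", {
    if (!nrow(res$events)) NULL else {
      calls <- lapply(seq_len(nrow(res$events)), function(i) {
        ev <- res$events[i, ]
        g <- if (!is.null(ev$recipient)) ev$recipient else ev$target
        bp <- if (!is.null(ev$breakpoint)) ev$breakpoint else ev$start
        ann <- community$annotations[community$annotations$genome_id == g, ]
        loc <- tryCatch(
          locate_breakpoint(popgen_rows[[g]], bp, community$genomes[[g]],
                            ann, flank = config$flank),
          error = function(e) list(coordinate = NA_integer_,
                                   label = "ambiguous",
                                   flank_start = NA_integer_))
        data.frame(event_id = ev$event_id, genome_id = g, scope = ev$scope,
                   alignment_locus = bp, coordinate = loc$coordinate,
                   label = loc$label, stringsAsFactors = FALSE)
      })
      do.call(rbind, calls)
    }
  })
  res$intergenic <- if (!is.null(res$breakpoints) &&
                        any(res$breakpoints$label != "ambiguous"))
    intergenic_fraction(res$breakpoints) else NULL

  res$summary <- pipeline_summary(res, community, config)
  class(res) <- "phagepop_result"
  if (!is.null(output_dir)) write_pipeline_outputs(res, output_dir)
  res
}

# concatenated single-copy core genes, ordered by cluster id; clusters
# whose members differ in length (not codon-alignable as-is) are skipped
concat_core_genes <- function(community, clusters, core) {
  ids <- names(community$genomes)
  usable <- core$cluster_id[core$is_core & !core$multi_copy]
  cds_of <- setNames(community$annotations$cds, community$annotations$uid)
  rows <- setNames(rep("", length(ids)), ids)
  used <- 0L
  for (cl in sort(usable)) {
    mem <- clusters[clusters$cluster_id == cl, ]
    seqs <- setNames(cds_of[mem$uid], mem$genome_id)[ids]
    if (length(unique(nchar(seqs))) != 1L) next
    rows <- paste0(rows, seqs)
    used <- used + 1L
  }
  if (used == 0L) stop("no single-copy equal-length core clusters")
  names(rows) <- ids
  rows
}

pipeline_summary <- function(res, community, config) {
  part <- res$partition
  ids <- names(part)
  cmb <- combn(ids, 2L)
  within <- part[cmb[1, ]] == part[cmb[2, ]]
  pick <- function(m) m[cbind(cmb[1, ], cmb[2, ])]
  fpr <- attr(res$mk, "fpr")
  list(
    n_genomes = length(ids),
    n_gene_families = length(unique(res$clusters$cluster_id)),
    n_core_families = sum(res$core$is_core),
    populations_per_prior = res$delimitation$report$n_groups,
    n_populations = res$delimitation$converged_n_groups,
    ani_within_mean = mean(pick(res$ani)[within], na.rm = TRUE),
    ani_between_mean = mean(pick(res$ani)[!within], na.rm = TRUE),
    shared_within_mean = mean(pick(res$shared)[within]),
    shared_between_mean = mean(pick(res$shared)[!within]),
    fst_max = if (!is.null(res$fst)) max(res$fst$fst, na.rm = TRUE) else NA,
    mk_n_tests = fpr$n_tests,
    mk_n_selected = fpr$n_selected,
    mk_expected_false_positives = fpr$expected_false_positives,
    recomb_rate_within = sum(res$event_rates$raw_count[
      res$event_rates$scope == "within"]) /
      sum(res$event_rates$normalizer[res$event_rates$scope == "within"]),
    recomb_rate_between = if (any(res$event_rates$scope == "between"))
      sum(res$event_rates$raw_count[res$event_rates$scope == "between"]) /
      sum(res$event_rates$normalizer[res$event_rates$scope == "between"])
      else NA,
    intergenic_breakpoint_fraction = if (!is.null(res$intergenic))
      res$intergenic$fraction[res$intergenic$scope == "all"] else NA,
    ordination_variance_explained = res$ordination$variance_explained
  )
}

#' @export
print.phagepop_result <- function(x, ...) {
  s <- x$summary
  cat("phagepop pipeline result\n")
  cat("  genomes:", s$n_genomes, "| gene families:", s$n_gene_families,
      "(", s$n_core_families, "core )\n")
  cat("  populations (converged over prior grid):", s$n_populations, "\n")
  cat(sprintf("  ANI within %.2f%% / between %.2f%%; shared genes %.3f / %.3f\n",
              s$ani_within_mean, s$ani_between_mean,
              s$shared_within_mean, s$shared_between_mean))
  if (!is.na(s$fst_max)) cat(sprintf("  max F_ST across site splits: %.4f\n",
                                     s$fst_max))
  cat("  MK tests:", s$mk_n_tests, "| selected:", s$mk_n_selected,
      sprintf("(expected false positives %.1f)\n",
              s$mk_expected_false_positives))
  cat(sprintf("  recombination rates within %.3f / between %.3f\n",
              s$recomb_rate_within, s$recomb_rate_between))
  invisible(x)
}

write_pipeline_outputs <- function(res, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) if (!is.null(d))
    write.table(d, file.path(output_dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wm <- function(m, f) if (!is.null(m))
    write.table(data.frame(genome_id = rownames(m), m, check.names = FALSE),
                file.path(output_dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wt(res$genometrics, "genometrics.tsv")
  wt(res$clusters, "clusters.tsv")
  wt(res$core, "core_clusters.tsv")
  wm(res$ani, "ani.tsv")
  wm(res$shared, "shared_genes.tsv")
  wm(res$jc$d, "jc_distance.tsv")
  wt(data.frame(genome_id = names(res$partition), group = res$partition),
     "partition.tsv")
  wt(res$delimitation$report, "delimitation_report.tsv")
  wt(res$lineage_table, "lineage_genometrics.tsv")
  wt(res$fst, "fst.tsv")
  wt(res$mk, "mk_tests.tsv")
  wt(res$events, "recombination_events.tsv")
  wt(res$event_rates, "recombination_rates.tsv")
  wt(res$breakpoints, "breakpoints.tsv")
  wt(res$intergenic, "intergenic_fraction.tsv")
  jsonlite::write_json(res$summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(output_dir)
}
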