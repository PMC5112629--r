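#' Simulation configuration
#'
#' Defaults emulate the study regime of closely related T4-like phage
#' communities at desk scale: a handful of discrete lineages with
#' within-lineage pairwise divergence about 1% and between-lineage
#' pairwise divergence 11-20% (ANI roughly 99%+ within, 80-89% between),
#' high within-lineage shared-gene fractions perturbed by gene gain/loss,
#' a few genes under lineage-specific positive selection (excess
#' nonsynonymous fixed differences), planted recombination events with
#' mostly genic breakpoints, and rare low-frequency polymorphisms.
#'
#' @param seed integer RNG seed.
#' @param n_lineages,genomes_per_lineage community shape.
#' @param n_core_genes,n_flexible_genes genes in the ancestral genome; the
#'   core block comes first and is never gained/lost, so core coordinates
#'   are shared by all genomes.
#' @param mean_gene_codons mean gene length in codons (start and stop
#'   included).
#' @param spacer_range intergenic spacer length range (bp).
#' @param within_divergence expected pairwise substitutions/site within a
#'   lineage (default 0.01, i.e. within-lineage ANI about 99%).
#' @param between_divergence length-2 range of expected pairwise
#'   substitutions/site between lineages.
#' @param syn_bias probability that a genic mutation is redirected to a
#'   synonymous alternative when one exists at the hit position.
#' @param n_selected_genes core genes given lineage-specific excess
#'   nonsynonymous fixation.
#' @param selection_multiplier multiplier on nonsynonymous fixed
#'   differences in selected genes (on the selected lineage's branch).
#' @param gene_gain_per_lineage,gene_loss_per_lineage flexible-gene
#'   turnover per lineage founder.
#' @param genome_gain_prob probability that an individual genome carries
#'   one extra private novel gene.
#' @param recomb_within_per_lineage planted within-lineage recombination
#'   events per lineage.
#' @param recomb_between_events planted between-lineage events (total).
#' @param recomb_segment recombination tract length (bp).
#' @param intergenic_breakpoint_prob probability a planted donor-segment
#'   start breakpoint is placed in an intergenic spacer.
#' @param low_freq_carrier_frac fraction of a lineage's members carrying
#'   an injected low-frequency allele (carriers = floor(frac * n); 0
#'   disables injection).
#' @param n_low_freq_sites injected low-frequency polymorphic sites per
#'   lineage.
#' @param within_structure within-lineage genealogy: `"star"` (default; a
#'   single unstructured population, matching the near-zero between-site
#'   differentiation and the barcode-gap assumption of the emulated
#'   regime) or `"clades"` (two subclades per lineage, so polymorphisms
#'   segregate at shared intermediate frequencies and survive the
#'   low-frequency filter in larger samples).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_lineages = 6L, genomes_per_lineage = 5L,
                       n_core_genes = 12L, n_flexible_genes = 8L,
                       mean_gene_codons = 250L, spacer_range = c(40L, 80L),
                       within_divergence = 0.01,
                       between_divergence = c(0.11, 0.20),
                       syn_bias = 0.5,
                       n_selected_genes = 5L, selection_multiplier = 5,
                       gene_gain_per_lineage = 2L, gene_loss_per_lineage = 1L,
                       genome_gain_prob = 0.2,
                       recomb_within_per_lineage = 2L,
                       recomb_between_events = 3L,
                       recomb_segment = 800L,
                       intergenic_breakpoint_prob = 0.1,
                       low_freq_carrier_frac = 0.1,
                       n_low_freq_sites = 30L,
                       within_structure = c("star", "clades")) {
  within_structure <- match.arg(within_structure)
  cfg <- as.list(environment())
  cfg$within_structure <- within_structure
  if (any(c(within_divergence, between_divergence) <= 0) ||
      any(c(within_divergence, between_divergence) >= 0.7))
    stop("divergences must lie in (0, 0.7)")
  if (within_divergence >= min(between_divergence))
    stop("within-lineage divergence must be below between-lineage divergence")
  if (n_selected_genes > n_core_genes)
    stop("cannot select more genes than core genes")
  stopifnot(n_lineages >= 1, genomes_per_lineage >= 1,
            intergenic_breakpoint_prob >= 0, intergenic_breakpoint_prob <= 1,
            selection_multiplier >= 1, syn_bias >= 0, syn_bias <= 1)
  class(cfg) <- "sim_config"
  cfg
}

SENSE_CODONS <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]

random_gene <- function(n_codons) {
  body <- sample(SENSE_CODONS, n_codons - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), sample(STOP_CODONS, 1L))
}

random_spacer <- function(range) {
  paste(sample(BASES, sample(range[1]:range[2], 1L), replace = TRUE),
        collapse = "")
}

# ancestor genome: core genes first, then flexible genes, spacers between
build_ancestor <- function(cfg) {
  n <- cfg$n_core_genes + cfg$n_flexible_genes
  ncod <- pmax(10L, stats::rpois(n, cfg$mean_gene_codons))
  parts <- character(0); ann <- list(); pos <- 0L; core_len <- NA_integer_
  for (i in seq_len(n)) {
    sp <- random_spacer(cfg$spacer_range)
    gene <- random_gene(ncod[i])
    parts <- c(parts, sp, gene)
    start <- pos + nchar(sp)
    ann[[i]] <- data.frame(family = sprintf("F%03d", i), start = start,
                           end = start + nchar(gene),
                           core = i <= cfg$n_core_genes,
                           stringsAsFactors = FALSE)
    pos <- start + nchar(gene)
    if (i == cfg$n_core_genes) core_len <- pos
  }
  parts <- c(parts, random_spacer(cfg$spacer_range))
  list(chars = strsplit(paste(parts, collapse = ""), "")[[1]],
       ann = do.call(rbind, ann), core_len = core_len)
}

gene_at_vector <- function(ann, L) {
  g <- integer(L)
  for (i in seq_len(nrow(ann))) g[(ann$start[i] + 1L):ann$end[i]] <- i
  g
}

# JC per-site change probability for an expected distance d
jc_change_prob <- function(d) 0.75 * (1 - exp(-4 * d / 3))

# one branch of codon-aware mutation; returns chars and per-gene
# nonsynonymous counts
mutate_branch <- function(chars, ann, d, syn_bias) {
  L <- length(chars)
  geneat <- gene_at_vector(ann, L)
  sites <- which(runif(L) < jc_change_prob(d))
  nonsyn <- integer(nrow(ann))
  for (pos in sites) {
    g <- geneat[pos]
    if (g == 0L) {
      chars[pos] <- sample(setdiff(BASES, chars[pos]), 1L)
      next
    }
    gs <- ann$start[g] + 1L
    cp <- (pos - gs) %% 3L
    cs <- pos - cp
    codon <- paste0(chars[cs], chars[cs + 1L], chars[cs + 2L])
    if (cs + 2L == ann$end[g] && is_stop(codon)) next  # keep terminal stop
    alt <- setdiff(BASES, chars[pos])
    cand <- vapply(alt, function(bb) {
      v <- c(chars[cs], chars[cs + 1L], chars[cs + 2L]); v[cp + 1L] <- bb
      paste(v, collapse = "")
    }, "")
    ok <- !is_stop(cand)
    if (!any(ok)) next
    cand <- cand[ok]; alt <- alt[ok]
    syn <- GENETIC_CODE_TABLE[cand] == GENETIC_CODE_TABLE[codon]
    pick <- if (runif(1) < syn_bias && any(syn))
      which(syn)[sample.int(sum(syn), 1L)] else sample.int(length(cand), 1L)
    chars[pos] <- alt[pick]
    if (!syn[pick]) nonsyn[g] <- nonsyn[g] + 1L
  }
  list(chars = chars, nonsyn = nonsyn)
}

# force n extra nonsynonymous (non-stop) substitutions inside one gene
add_forced_nonsyn <- function(chars, gstart, gend, n) {
  done <- 0L; tries <- 0L
  while (done < n && tries < 100L * max(n, 1L)) {
    tries <- tries + 1L
    pos <- sample((gstart + 1L):(gend - 3L), 1L)
    cp <- (pos - gstart - 1L) %% 3L
    cs <- pos - cp
    codon <- paste0(chars[cs], chars[cs + 1L], chars[cs + 2L])
    if (is_stop(codon)) next
    alt <- setdiff(BASES, chars[pos])
    cand <- vapply(alt, function(bb) {
      v <- c(chars[cs], chars[cs + 1L], chars[cs + 2L]); v[cp + 1L] <- bb
      paste(v, collapse = "")
    }, "")
    good <- !is_stop(cand) &
      GENETIC_CODE_TABLE[cand] != GENETIC_CODE_TABLE[codon]
    if (!any(good)) next
    chars[pos] <- alt[which(good)[sample.int(sum(good), 1L)]]
    done <- done + 1L
  }
  chars
}

#' Simulate a lineage-structured phage community with truth tables
#'
#' Builds an ancestral codon-structured genome, diverges lineage founders
#' and within-lineage individuals by Jukes-Cantor-style substitution
#' (codon-aware inside genes, with a synonymous bias and no internal stop
#' creation), multiplies nonsynonymous fixed differences in selected genes
#' on their lineage's founder branch, applies flexible-gene gain/loss per
#' lineage (plus rare private gains), plants recombination events by
#' copying donor core segments into recipients with recorded breakpoints,
#' and injects low-frequency polymorphisms. Output is byte-reproducible
#' for a fixed seed.
#'
#' @param config a [sim_config].
#' @return list of class `phage_sim` with `community` (a
#'   [phage_community]), `truth` (lineage labels, gene families, selected
#'   genes, recombination events with genic/intergenic labels, realized
#'   core divergences, `core_len`) and `config`.
#' @export
simulate_community <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  anc <- build_ancestor(config)
  k <- config$n_lineages; m <- config$genomes_per_lineage
  lineage_ids <- paste0("L", seq_len(k))
  core_fams <- anc$ann$family[anc$ann$core]
  flex_fams <- anc$ann$family[!anc$ann$core]
  selected <- if (config$n_selected_genes > 0) {
    data.frame(family = sample(core_fams, config$n_selected_genes),
               lineage = lineage_ids[1 + (seq_len(config$n_selected_genes) - 1L)
                                     %% k],
               stringsAsFactors = FALSE)
  } else data.frame(family = character(), lineage = character())

  genomes <- list(); anns <- list(); lineage_of <- character(0)
  novel_counter <- 0L
  for (l in seq_len(k)) {
    lid <- lineage_ids[l]
    b <- runif(1, config$between_divergence[1] / 2,
               config$between_divergence[2] / 2)
    fb <- mutate_branch(anc$chars, anc$ann, b, config$syn_bias)
    fchars <- fb$chars
    sel_l <- selected$family[selected$lineage == lid]
    for (fam in sel_l) {
      i <- match(fam, anc$ann$family)
      # the multiplier acts on the pairwise nonsynonymous fixed-difference
      # count, to which both founder branches contribute roughly equally
      extra <- round((config$selection_multiplier - 1) *
                       max(2L * fb$nonsyn[i], 1L))
      fchars <- add_forced_nonsyn(fchars, anc$ann$start[i], anc$ann$end[i],
                                  extra)
    }
    fann <- anc$ann
    # flexible gene loss (deletion, spacers retained)
    loss <- if (config$gene_loss_per_lineage > 0 && length(flex_fams))
      sample(flex_fams, min(config$gene_loss_per_lineage,
                            length(flex_fams))) else character(0)
    for (fam in loss) {
      i <- match(fam, fann$family)
      w <- fann$end[i] - fann$start[i]
      fchars <- fchars[-((fann$start[i] + 1L):fann$end[i])]
      shift <- fann$start > fann$start[i]
      fann$start[shift] <- fann$start[shift] - w
      fann$end[shift] <- fann$end[shift] - w
      fann <- fann[-i, ]
    }
    # flexible gene gain (novel genes, appended)
    if (config$gene_gain_per_lineage > 0) {
      for (j in seq_len(config$gene_gain_per_lineage)) {
        novel_counter <- novel_counter + 1L
        sp <- random_spacer(config$spacer_range)
        gene <- random_gene(max(10L, stats::rpois(1, config$mean_gene_codons)))
        start <- length(fchars) + nchar(sp)
        fchars <- c(fchars, strsplit(paste0(sp, gene), "")[[1]])
        fann <- rbind(fann, data.frame(
          family = sprintf("novel%03d_%s", novel_counter, lid),
          start = start, end = start + nchar(gene), core = FALSE,
          stringsAsFactors = FALSE))
      }
    }
    # within-lineage genealogy: two clades per lineage (when n >= 4) so
    # that polymorphisms arise at shared, intermediate frequencies rather
    # than only as singletons (a pure star topology would leave nothing
    # for the low-frequency filter to distinguish)
    dw <- config$within_divergence
    if (m >= 4L && config$within_structure == "clades") {
      clade_of <- rep(1:2, length.out = m)
      clades <- list(
        mutate_branch(fchars, fann, dw / 4, config$syn_bias)$chars,
        mutate_branch(fchars, fann, dw / 4, config$syn_bias)$chars)
      tip_branch <- dw / 4
    } else {
      clade_of <- rep(1L, m)
      clades <- list(fchars)
      tip_branch <- dw / 2
    }
    for (i in seq_len(m)) {
      gid <- sprintf("%s_g%02d", lid, i)
      gb <- mutate_branch(clades[[clade_of[i]]], fann, tip_branch,
                          config$syn_bias)
      gchars <- gb$chars; gann <- fann
      if (runif(1) < config$genome_gain_prob) {
        novel_counter <- novel_counter + 1L
        sp <- random_spacer(config$spacer_range)
        gene <- random_gene(max(10L, stats::rpois(1, config$mean_gene_codons)))
        start <- length(gchars) + nchar(sp)
        gchars <- c(gchars, strsplit(paste0(sp, gene), "")[[1]])
        gann <- rbind(gann, data.frame(
          family = sprintf("novel%03d_%s", novel_counter, gid),
          start = start, end = start + nchar(gene), core = FALSE,
          stringsAsFactors = FALSE))
      }
      genomes[[gid]] <- gchars
      gann$genome_id <- gid
      anns[[gid]] <- gann
      lineage_of[gid] <- lid
    }
  }

  # planted recombination in the shared core region
  core_ann <- anc$ann[anc$ann$core, ]
  core_len <- anc$core_len
  geneat_core <- gene_at_vector(core_ann, core_len)
  pick_breakpoint <- function() {
    intergenic <- runif(1) < config$intergenic_breakpoint_prob
    cand <- which(if (intergenic) geneat_core == 0L else geneat_core != 0L)
    cand <- cand[cand > 60L & cand < core_len - 200L]
    s <- cand[sample.int(length(cand), 1L)] - 1L   # 0-based
    list(pos = s, label = if (intergenic) "intergenic" else "genic")
  }
  events <- list()
  used_iv <- list()   # per-genome intervals already involved in an event
  plant <- function(donor, recipient, scope, la, lb) {
    # avoid overlapping tracts on either participant so planted segments
    # stay verifiable in the emitted genomes
    for (try in 1:50) {
      bp <- pick_breakpoint()
      s <- bp$pos
      e <- min(s + config$recomb_segment, core_len - 1L)
      busy <- c(used_iv[[donor]], used_iv[[recipient]])
      clash <- FALSE
      if (length(busy)) for (iv in busy)
        if (s < iv[2] && iv[1] < e) { clash <- TRUE; break }
      if (!clash) break
    }
    used_iv[[donor]] <<- c(used_iv[[donor]], list(c(s, e)))
    used_iv[[recipient]] <<- c(used_iv[[recipient]], list(c(s, e)))
    genomes[[recipient]][(s + 1L):e] <<- genomes[[donor]][(s + 1L):e]
    lab_e <- if (geneat_core[e + 1L] == 0L) "intergenic" else "genic"
    events[[length(events) + 1L]] <<- data.frame(
      scope = scope, lineage_a = la, lineage_b = lb,
      donor = donor, recipient = recipient, start = s, end = e,
      label_start = bp$label, label_end = lab_e, stringsAsFactors = FALSE)
  }
  if (m >= 2 && config$recomb_within_per_lineage > 0) {
    for (lid in lineage_ids) for (j in seq_len(config$recomb_within_per_lineage)) {
      pr <- sample(names(lineage_of)[lineage_of == lid], 2L)
      plant(pr[1], pr[2], "within", lid, NA_character_)
    }
  }
  if (k >= 2 && config$recomb_between_events > 0) {
    for (j in seq_len(config$recomb_between_events)) {
      ll <- sample(lineage_ids, 2L)
      donor <- sample(names(lineage_of)[lineage_of == ll[1]], 1L)
      recipient <- sample(names(lineage_of)[lineage_of == ll[2]], 1L)
      plant(donor, recipient, "between", min(ll), max(ll))
    }
  }
  events <- if (length(events)) {
    ev <- do.call(rbind, events)
    cbind(event_id = sprintf("TRUE_EV%03d", seq_len(nrow(ev))), ev)
  } else data.frame(event_id = character(), scope = character(),
                    lineage_a = character(), lineage_b = character(),
                    donor = character(), recipient = character(),
                    start = integer(), end = integer(),
                    label_start = character(), label_end = character())

  # low-frequency polymorphisms within lineages (core region)
  carriers_n <- floor(config$low_freq_carrier_frac * m)
  if (carriers_n >= 1L && config$n_low_freq_sites > 0) {
    for (lid in lineage_ids) {
      members <- names(lineage_of)[lineage_of == lid]
      for (j in seq_len(config$n_low_freq_sites)) {
        pos <- sample.int(core_len, 1L)
        carriers <- sample(members, carriers_n)
        cur <- genomes[[members[1]]][pos]
        allele <- sample(setdiff(BASES, cur), 1L)
        for (g in carriers) genomes[[g]][pos] <- allele
      }
    }
  }

  seqs <- vapply(genomes, paste, "", collapse = "")
  ann_all <- do.call(rbind, anns)
  ann_df <- data.frame(genome_id = ann_all$genome_id,
                       gene_id = ann_all$family,
                       start = ann_all$start, end = ann_all$end,
                       strand = "+", stringsAsFactors = FALSE)
  sites <- setNames(ifelse(seq_along(seqs) %% 2L == 1L, "coastal",
                           "offshore"), names(seqs))
  community <- phage_community(seqs, ann_df, sites)

  fam_truth <- data.frame(uid = gene_uid(ann_df$genome_id, ann_df$gene_id),
                          family = ann_all$family, stringsAsFactors = FALSE)
  core_rows <- substring(seqs, 1L, core_len)
  names(core_rows) <- names(seqs)
  divergence <- jc_matrix(core_rows)$d
  structure(list(
    community = community,
    truth = list(lineages = lineage_of, gene_families = fam_truth,
                 selected = selected, events = events,
                 divergence = divergence, core_len = core_len,
                 core_families = core_fams,
                 core_annotation = core_ann),
    config = config), class = "phage_sim")
}

#' @export
print.phage_sim <- function(x, ...) {
  cat("simulated phage community (seed ", x$config$seed, "):\n", sep = "")
  print(x$community)
  cat("  lineages:", length(unique(x$truth$lineages)),
      "| selected genes:", nrow(x$truth$selected),
      "| planted events:", nrow(x$truth$events), "\n")
  invisible(x)
}

#' Compare pipeline outputs against simulator truth
#'
#' @param truth the `truth` element of a `phage_sim`.
#' @param partition named character vector genome id -> inferred group.
#' @param selected_families character vector of gene families called
#'   selected (the simulator uses family ids as gene ids, so recovered
#'   clusters map to families by their members' gene ids).
#' @param detected_breakpoints integer vector of detected breakpoint
#'   alignment coordinates (0-based core coordinates).
#' @param ani optional ANI percent matrix for bias assessment.
#' @return list with `partition_ari` (adjusted Rand index),
#'   `selected_precision`, `selected_recall`,
#'   `breakpoint_error_bp` (per planted breakpoint, nearest detected),
#'   `ani_bias` (mean ANI fraction minus Jukes-Cantor expected identity
#'   from realized divergence, over between-lineage pairs).
#' @export
truth_compare <- function(truth, partition = NULL, selected_families = NULL,
                          detected_breakpoints = NULL, ani = NULL) {
  out <- list()
  if (!is.null(partition)) {
    ids <- names(truth$lineages)
    if (!all(ids %in% names(partition)))
      stop("partition is missing genomes: ",
           paste(setdiff(ids, names(partition)), collapse = ", "))
    out$partition_ari <- mclust::adjustedRandIndex(partition[ids],
                                                   truth$lineages[ids])
  }
  if (!is.null(selected_families)) {
    truth_sel <- unique(truth$selected$family)
    tp <- length(intersect(selected_families, truth_sel))
    out$selected_precision <- if (length(selected_families))
      tp / length(selected_families) else NA_real_
    out$selected_recall <- if (length(truth_sel))
      tp / length(truth_sel) else NA_real_
  }
  if (!is.null(detected_breakpoints) && nrow(truth$events)) {
    planted <- c(truth$events$start, truth$events$end)
    out$breakpoint_error_bp <- vapply(planted, function(b)
      if (length(detected_breakpoints))
        min(abs(detected_breakpoints - b)) else NA_real_, 0)
  }
  if (!is.null(ani)) {
    ids <- names(truth$lineages)
    cmb <- combn(ids, 2L)
    between <- truth$lineages[cmb[1, ]] != truth$lineages[cmb[2, ]]
    obs <- ani[cbind(cmb[1, between], cmb[2, between])] / 100
    d <- truth$divergence[cbind(cmb[1, between], cmb[2, between])]
    expected <- 1 - jc_change_prob(d)
    out$ani_bias <- mean(obs - expected, na.rm = TRUE)
  }
  out
}
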