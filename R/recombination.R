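#' Normalize recombination event counts by lineage sizes
#'
#' Within-lineage counts are divided by the lineage size n_L; between-
#' lineage counts by the sum of the two lineage sizes.
#'
#' @param events data.frame with columns `event_id`, `scope` (`"within"`
#'   or `"between"`), `lineage_a`, `lineage_b` (`NA` for within-scope).
#' @param lineage_sizes named integer vector lineage id -> number of
#'   genomes.
#' @return data.frame: `scope`, `lineage_a`, `lineage_b`, `raw_count`,
#'   `normalizer`, `rate`. Scopes with zero events are included (rate 0)
#'   for every lineage and lineage pair in `lineage_sizes`.
#' @export
normalize_events <- function(events, lineage_sizes) {
  lin <- names(lineage_sizes)
  if (nrow(events)) {
    bad <- setdiff(stats::na.omit(c(events$lineage_a, events$lineage_b)), lin)
    if (length(bad))
      stop("event references unknown lineage(s): ", paste(bad, collapse = ", "))
  }
  within <- data.frame(scope = "within", lineage_a = lin,
                       lineage_b = NA_character_, stringsAsFactors = FALSE)
  between <- if (length(lin) >= 2L) {
    cmb <- combn(sort(lin), 2L)
    data.frame(scope = "between", lineage_a = cmb[1, ], lineage_b = cmb[2, ],
               stringsAsFactors = FALSE)
  } else NULL
  out <- rbind(within, between)
  key <- function(s, a, b)
    ifelse(s == "within", paste(s, a), paste(s, pmin(a, b), pmax(a, b)))
  out_key <- key(out$scope, out$lineage_a, out$lineage_b)
  cnt <- if (nrow(events))
    table(key(events$scope, events$lineage_a, events$lineage_b)) else table(character())
  out$raw_count <- as.integer(ifelse(out_key %in% names(cnt),
                                     cnt[out_key], 0L))
  out$normalizer <- ifelse(out$scope == "within",
                           lineage_sizes[out$lineage_a],
                           lineage_sizes[out$lineage_a] +
                             lineage_sizes[out$lineage_b])
  out$rate <- out$raw_count / out$normalizer
  rownames(out) <- NULL
  out
}

#' Map a recombination breakpoint to full-genome coordinates
#'
#' Takes the 50 bp (ungapped) of the participant's alignment row preceding
#' the breakpoint column, locates that flank in the participant's full
#' genome by exact search (best local alignment at >= 90% identity as a
#' fallback), sets the breakpoint coordinate to the position immediately
#' after the located flank (0-based), and labels it `genic` when it falls
#' inside an annotated gene interval of that genome, else `intergenic`.
#' Multiple equally good flank hits, or no hit at the identity floor,
#' yield `ambiguous`.
#'
#' @param aln_row the participant's aligned sequence (gaps as `-`).
#' @param breakpoint 0-based alignment column of the breakpoint (the flank
#'   is taken from columns strictly before it).
#' @param genome the participant's full genome sequence.
#' @param annotations the community annotation table restricted by
#'   `genome_id` (only `start`/`end` used; 0-based half-open).
#' @param flank flank length in bp (default 50).
#' @return list with `coordinate` (0-based, NA when ambiguous), `label`
#'   (`"genic"`, `"intergenic"` or `"ambiguous"`) and `flank_start`
#'   (0-based start of the located flank).
#' @export
locate_breakpoint <- function(aln_row, breakpoint, genome, annotations,
                              flank = 50L) {
  chars <- strsplit(aln_row, "", fixed = TRUE)[[1]]
  if (breakpoint < 0 || breakpoint > length(chars))
    stop("breakpoint outside alignment")
  before <- chars[seq_len(breakpoint)]
  before <- before[before != "-"]
  if (length(before) < flank)
    stop("fewer than ", flank, " ungapped bases precede the breakpoint")
  probe <- paste(utils::tail(before, flank), collapse = "")
  hits <- Biostrings::matchPattern(probe, Biostrings::DNAString(genome))
  if (length(hits) == 1L) {
    fstart <- BiocGenerics::start(hits)[1] - 1L   # to 0-based
  } else if (length(hits) > 1L) {
    return(list(coordinate = NA_integer_, label = "ambiguous",
                flank_start = NA_integer_))
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(probe), Biostrings::DNAString(genome),
      type = "local")
    ok <- Biostrings::pid(aln, type = "PID1") >= 90 &&
      IRanges::width(Biostrings::pattern(aln)) >= 0.9 * flank
    if (!ok)
      return(list(coordinate = NA_integer_, label = "ambiguous",
                  flank_start = NA_integer_))
    fstart <- BiocGenerics::start(Biostrings::subject(aln)) - 1L -
      (BiocGenerics::start(Biostrings::pattern(aln)) - 1L)
  }
  coord <- fstart + flank
  genic <- any(annotations$start <= coord & coord < annotations$end)
  list(coordinate = as.integer(coord),
       label = if (genic) "genic" else "intergenic",
       flank_start = as.integer(fstart))
}

#' Fraction of intergenic breakpoints
#'
#' @param calls data.frame of breakpoint calls with a `label` column
#'   (`genic` / `intergenic` / `ambiguous`) and optionally `scope`.
#' @param by_scope also report per-scope fractions when a `scope` column
#'   is present.
#' @return data.frame with `scope` (`"all"` plus per-scope rows),
#'   `n_intergenic`, `n_unambiguous`, `fraction`.
#' @export
intergenic_fraction <- function(calls, by_scope = TRUE) {
  u <- calls[calls$label != "ambiguous", , drop = FALSE]
  if (!nrow(u)) stop("no unambiguous breakpoint calls")
  one <- function(d, tag) data.frame(
    scope = tag, n_intergenic = sum(d$label == "intergenic"),
    n_unambiguous = nrow(d),
    fraction = sum(d$label == "intergenic") / nrow(d),
    stringsAsFactors = FALSE)
  out <- one(u, "all")
  if (by_scope && !is.null(u$scope)) {
    per <- lapply(split(u, u$scope), function(d) one(d, d$scope[1]))
    out <- rbind(out, do.call(rbind, per))
  }
  rownames(out) <- NULL
  out
}

#' Simple windowed recombination-event detector
#'
#' A deliberately simple mosaic scanner used as plumbing when no external
#' event table (from coalescent or substitution detectors) is available:
#' for each target sequence and each candidate parent pair, per-window
#' mismatch counts decide the closer parent; a sustained switch (at least
#' `min_run` consecutive informative windows on each side) proposes a
#' breakpoint at the switch boundary; significance is assessed by
#' permuting alignment column order and requiring the observed flanking
#' run length to exceed the 95th percentile of permuted maximal runs.
#'
#' @param seqs named character vector of aligned sequences (>= 3).
#' @param partition named character vector genome id -> lineage; parents
#'   are drawn from lineage representatives (between-lineage scan) and
#'   from same-lineage members (within-lineage scan).
#' @param window window size in alignment columns (default 200).
#' @param min_run minimum run of consecutive windows on each side of a
#'   switch (default 3).
#' @param n_permutations column-order permutations for the null run
#'   length (default 500).
#' @param max_within_pairs cap on same-lineage parent pairs per target.
#' @return data.frame of events: `event_id`, `scope`, `lineage_a`,
#'   `lineage_b`, `target`, `parent_1`, `parent_2`, `breakpoint`
#'   (0-based alignment column), `run_length`, `source = "internal"`.
#' @export
detect_events_simple <- function(seqs, partition, window = 200L,
                                 min_run = 3L, n_permutations = 500L,
                                 max_within_pairs = 6L) {
  if (length(seqs) < 3L) stop("need at least 3 sequences")
  L <- nchar(seqs[[1]])
  if (window > L) stop("window larger than alignment")
  x <- code_matrix(seqs)
  ids <- names(seqs)
  lin <- partition[ids]
  reps <- vapply(split(ids, lin), function(v) sort(v)[1], "")
  rows <- list()
  for (t in ids) {
    own <- setdiff(ids[lin == lin[t]], t)
    foreign <- reps[names(reps) != lin[t]]
    # between-lineage scan: own-lineage representative vs each foreign rep
    own_rep <- if (length(own)) sort(own)[1] else NA_character_
    cand <- list()
    if (!is.na(own_rep))
      for (fr in foreign) cand <- c(cand, list(c(own_rep, fr)))
    if (length(own) >= 2L) {
      cmb <- combn(sort(own), 2L)
      keep <- seq_len(min(ncol(cmb), max_within_pairs))
      for (k in keep) cand <- c(cand, list(cmb[, k]))
    }
    for (pp in cand) {
      ev <- scan_target(x, t, pp[1], pp[2], window, min_run, n_permutations)
      if (is.null(ev)) next
      p_lin <- sort(c(lin[pp[1]], lin[pp[2]]))
      scope <- if (p_lin[1] == p_lin[2] && p_lin[1] == lin[t])
        "within" else "between"
      other <- setdiff(unique(c(lin[pp[1]], lin[pp[2]])), lin[t])
      rows[[length(rows) + 1L]] <- data.frame(
        scope = scope, lineage_a = unname(lin[t]),
        lineage_b = if (scope == "within") NA_character_ else other[1],
        target = t, parent_1 = pp[1], parent_2 = pp[2],
        breakpoint = ev$breakpoint, run_length = ev$run,
        source = "internal", stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scope = character(), lineage_a = character(),
               lineage_b = character(), target = character(),
               parent_1 = character(), parent_2 = character(),
               breakpoint = integer(), run_length = integer(),
               source = character(), stringsAsFactors = FALSE)
  if (nrow(out)) out <- cbind(event_id = sprintf("EV%04d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

# core of the detector: windowed closer-parent signs for one target
scan_target <- function(x, t, p1, p2, window, min_run, n_perm) {
  d1 <- (x[t, ] != x[p1, ]) & !is.na(x[t, ]) & !is.na(x[p1, ])
  d2 <- (x[t, ] != x[p2, ]) & !is.na(x[t, ]) & !is.na(x[p2, ])
  delta <- as.integer(d2) - as.integer(d1)   # >0: closer to p1
  if (all(delta == 0)) return(NULL)
  nw <- floor(length(delta) / window)
  if (nw < 2 * min_run) return(NULL)
  win_sign <- function(v) {
    s <- colSums(matrix(v[seq_len(nw * window)], nrow = window))
    sign(s)
  }
  obs <- win_sign(delta)
  inf <- obs[obs != 0]
  if (length(inf) < 2 * min_run) return(NULL)
  r <- rle(inf)
  if (length(r$lengths) < 2L) return(NULL)
  # best sustained switch: adjacent runs both >= min_run
  best <- NULL
  for (k in seq_len(length(r$lengths) - 1L)) {
    run <- min(r$lengths[k], r$lengths[k + 1L])
    if (run >= min_run && (is.null(best) || run > best$run)) {
      n_before <- sum(r$lengths[seq_len(k)])
      # breakpoint: boundary after the n_before-th informative window
      widx <- which(obs != 0)[n_before]
      best <- list(run = run, breakpoint = widx * window)
    }
  }
  if (is.null(best)) return(NULL)
  null_runs <- vapply(seq_len(n_perm), function(i) {
    ws <- win_sign(sample(delta))
    ws <- ws[ws != 0]
    if (length(ws) < 2L) return(0)
    rr <- rle(ws)
    if (length(rr$lengths) < 2L) return(0)
    m <- 0
    for (k in seq_len(length(rr$lengths) - 1L))
      m <- max(m, min(rr$lengths[k], rr$lengths[k + 1L]))
    m
  }, 0)
  if (best$run > stats::quantile(null_runs, 0.95)) best else NULL
}
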