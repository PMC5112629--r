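#' Average nucleotide identity matrix
#'
#' ANI between two genomes is the unweighted arithmetic mean of the percent
#' identities of all shared homologous gene pairs, i.e. cross-genome gene
#' pairs that fall in the same protein cluster and have an alignment in
#' `edges`. Pairs of genomes without any shared gene get `NA` with a
#' warning. The diagonal is 100.
#'
#' @param clusters `gene_clusters` from [markov_cluster].
#' @param edges `similarity_edges` holding percent identities (typically
#'   the unfiltered output of [all_vs_all_similarity]).
#' @param genome_ids genome ids spanning the matrix.
#' @return symmetric numeric matrix (percent), class kept plain.
#' @export
ani_matrix <- function(clusters, edges, genome_ids) {
  ekey <- paste(edges$uid_a, edges$uid_b)
  sp <- split(seq_len(nrow(clusters)), clusters$cluster_id)
  pair_rows <- lapply(sp, function(ii) {
    if (length(ii) < 2L) return(NULL)
    g <- clusters$genome_id[ii]; u <- clusters$uid[ii]
    cmb <- combn(length(ii), 2L)
    keep <- g[cmb[1, ]] != g[cmb[2, ]]
    if (!any(keep)) return(NULL)
    data.frame(ga = g[cmb[1, keep]], gb = g[cmb[2, keep]],
               key = paste(pmin(u[cmb[1, keep]], u[cmb[2, keep]]),
                           pmax(u[cmb[1, keep]], u[cmb[2, keep]])),
               stringsAsFactors = FALSE)
  })
  pr <- do.call(rbind, pair_rows)
  ani <- matrix(NA_real_, length(genome_ids), length(genome_ids),
                dimnames = list(genome_ids, genome_ids))
  diag(ani) <- 100
  if (!is.null(pr)) {
    pr$identity <- edges$identity[match(pr$key, ekey)]
    pr <- pr[!is.na(pr$identity), , drop = FALSE]
    if (nrow(pr)) {
      gk <- paste(pmin(pr$ga, pr$gb), pmax(pr$ga, pr$gb), sep = "\r")
      mu <- tapply(pr$identity, gk, mean)
      ab <- do.call(rbind, strsplit(names(mu), "\r", fixed = TRUE))
      ani[cbind(ab[, 1], ab[, 2])] <- mu
      ani[cbind(ab[, 2], ab[, 1])] <- mu
    }
  }
  miss <- sum(is.na(ani[upper.tri(ani)]))
  if (miss > 0)
    warning(miss, " genome pair(s) share no aligned genes; ANI set to NA")
  ani
}

#' Jukes-Cantor distance
#'
#' d = -(3/4) log(1 - (4/3) p) substitutions per site, for an observed
#' proportion `p` of mismatching (ungapped, unambiguous) aligned sites.
#'
#' @param p proportion(s) of differing sites, each in `[0, 0.75)`.
#' @return distance(s) in substitutions/site.
#' @export
jc_distance <- function(p) {
  if (any(p < 0 | p >= 0.75))
    stop("Jukes-Cantor distance undefined for p outside [0, 0.75)")
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise Jukes-Cantor distance matrix from aligned sequences
#'
#' Mismatch proportions are computed per pair over columns where both
#' members carry an unambiguous base (A/C/G/T); gapped or ambiguous
#' columns are excluded pairwise.
#'
#' @param seqs named character vector of equal-length aligned sequences.
#' @return list with `p` (mismatch proportion matrix) and `d` (JC matrix).
#' @export
jc_matrix <- function(seqs) {
  m <- seq_matrix(seqs)
  code <- matrix(match(m, BASES), nrow = nrow(m))  # NA for gap/ambiguous
  n <- nrow(m)
  p <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(code[i, ]) & !is.na(code[j, ])
    if (!any(ok)) stop("no comparable sites between ", names(seqs)[i],
                       " and ", names(seqs)[j])
    p[i, j] <- p[j, i] <- mean(code[i, ok] != code[j, ok])
  }
  list(p = p, d = jc_distance(p))
}

#' Barcode-gap population delimitation over a grid of priors
#'
#' Recursive partitioning of genomes from their pairwise distance matrix.
#' For a prior maximum intraspecific divergence `P`, the candidate
#' intraspecific distances are those `<= P` (with zero, the self-distance,
#' always included as an anchor); the barcode gap is the first interval
#' between consecutive sorted distinct distances wider than `gap_factor`
#' times the largest spacing among the candidates (when no observed
#' distance falls below `P`, the smallest observed distance serves as the
#' reference spacing). The genomes are split by single linkage at the
#' gap's lower edge and the procedure recurses within each group until no
#' further gap is found. The convergence report gives the group count per
#' prior and the modal count across the grid.
#'
#' @param d symmetric distance matrix with genome ids as dimnames.
#' @param prior_grid priors in substitutions/site (ascending); default ten
#'   log-spaced values from 0.001 to 0.1.
#' @param gap_factor gap width multiplier X (default 1.5).
#' @return object of class `barcode_partition`: list with `per_prior`
#'   (named list of partitions, each a named vector genome id -> group),
#'   `report` (data.frame `prior`, `n_groups`), `modal_n_groups` (most
#'   frequent count over the grid), `converged_n_groups` (count at the
#'   terminal plateau of the curve; low priors canonically oversplit, so
#'   convergence is read from the large-prior end), `plateau_length`
#'   (number of trailing priors sharing the converged count) and
#'   `partition` (the partition at the largest prior).
#' @export
barcode_gap_partition <- function(d,
                                  prior_grid = 10^seq(log10(0.001),
                                                      log10(0.1),
                                                      length.out = 10),
                                  gap_factor = 1.5) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), !is.null(rownames(d)))
  if (gap_factor <= 1) stop("gap_factor must exceed 1")
  if (any(diff(prior_grid) <= 0)) stop("prior grid must be ascending")
  ids <- rownames(d)
  if (length(ids) < 3L) {
    warning("fewer than 3 genomes: single group")
    part <- setNames(rep("G1", length(ids)), ids)
    per <- setNames(lapply(prior_grid, function(p) part),
                    format(prior_grid, digits = 4))
    return(structure(list(per_prior = per,
                          report = data.frame(prior = prior_grid,
                                              n_groups = 1L),
                          modal_n_groups = 1L, converged_n_groups = 1L,
                          plateau_length = length(prior_grid),
                          partition = part),
                     class = "barcode_partition"))
  }
  per <- lapply(prior_grid, function(P) {
    groups <- bg_recurse(ids, d, P, gap_factor)
    grp <- setNames(rep(sprintf("G%d", seq_along(groups)), lengths(groups)),
                    unlist(groups))
    grp[ids]
  })
  names(per) <- format(prior_grid, digits = 4)
  ng <- vapply(per, function(g) length(unique(g)), 0L)
  modal <- as.integer(names(which.max(table(ng))))
  converged <- ng[length(ng)]
  plateau <- with(rle(rev(unname(ng))), lengths[1])
  if (plateau < 2L)
    warning("group count not stable at the top of the prior grid")
  structure(list(per_prior = per,
                 report = data.frame(prior = prior_grid,
                                     n_groups = unname(ng)),
                 modal_n_groups = modal,
                 converged_n_groups = unname(converged),
                 plateau_length = plateau,
                 partition = per[[length(per)]]),
            class = "barcode_partition")
}

#' @export
print.barcode_partition <- function(x, ...) {
  cat("barcode-gap delimitation over", nrow(x$report), "priors\n")
  cat("  groups per prior:", paste(x$report$n_groups, collapse = " "), "\n")
  cat("  converged group count:", x$converged_n_groups,
      "(terminal plateau of", x$plateau_length, "priors; modal",
      x$modal_n_groups, ")\n")
  invisible(x)
}

# recursive splitting; groups sorted by first member for determinism
bg_recurse <- function(ids, d, P, X) {
  ids <- sort(ids)
  if (length(ids) < 3L) return(list(ids))
  sub <- d[ids, ids]
  dv <- sub[upper.tri(sub)]
  th <- bg_find_gap(dv, P, X)
  if (is.na(th)) return(list(ids))
  pairs <- which(upper.tri(sub) & sub <= th, arr.ind = TRUE)
  adj <- split(c(ids[pairs[, 2]], ids[pairs[, 1]]),
               c(ids[pairs[, 1]], ids[pairs[, 2]]))
  groups <- graph_components(ids, adj)
  if (length(groups) == 1L) return(list(ids))
  out <- list()
  for (g in groups) out <- c(out, bg_recurse(g, d, P, X))
  out[order(vapply(out, `[`, "", 1L))]
}

# threshold at the lower edge of the first qualifying gap, or NA
bg_find_gap <- function(dvals, P, X) {
  ds <- sort(unique(dvals))
  cand <- ds[ds <= P]
  ref <- if (length(cand)) max(diff(c(0, cand))) else min(ds)
  if (ref == 0) ref <- min(ds[ds > 0], P)
  gaps <- diff(ds)
  hit <- which(gaps > X * ref)
  if (!length(hit)) return(NA_real_)
  ds[hit[1]]
}

#' Ordination of the ANI matrix
#'
#' ANI percentages are converted to fractions, arcsine-square-root
#' transformed, and the genome-by-genome transformed matrix is ordinated
#' by principal component analysis (rows as observations). Missing entries
#' are imputed with the mean of the available off-diagonal values of their
#' row/column pair, with a warning. `method = "cmdscale"` instead runs
#' classical multidimensional scaling on the transformed dissimilarity.
#'
#' @param ani ANI percent matrix.
#' @param n_components number of components to report.
#' @param method `"pca"` (default) or `"cmdscale"`.
#' @return list with `coordinates` (genomes x components) and
#'   `variance_explained` (fraction per component, non-increasing).
#' @export
ordinate_ani <- function(ani, n_components = 3L, method = c("pca", "cmdscale")) {
  method <- match.arg(method)
  f <- pmin(pmax(ani / 100, 0), 1)
  if (any(is.na(f))) {
    warning("imputing missing ANI entries with row/column means")
    fill <- (rowMeans(f, na.rm = TRUE)[row(f)] +
               colMeans(f, na.rm = TRUE)[col(f)]) / 2
    f[is.na(f)] <- fill[is.na(f)]
  }
  tr <- asin(sqrt(f))
  k <- min(n_components, nrow(tr))
  if (method == "pca") {
    totvar <- sum(apply(tr, 2L, var))
    if (totvar < 1e-12) {
      co <- matrix(0, nrow(tr), k,
                   dimnames = list(rownames(tr), paste0("PC", seq_len(k))))
      return(list(coordinates = co,
                  variance_explained = rep(0, k)))
    }
    pc <- prcomp(tr, center = TRUE, scale. = FALSE)
    ve <- pc$sdev^2 / sum(pc$sdev^2)
    k <- min(k, ncol(pc$x))
    list(coordinates = pc$x[, seq_len(k), drop = FALSE],
         variance_explained = ve[seq_len(k)])
  } else {
    diss <- asin(sqrt(pmin(pmax(1 - f, 0), 1)))
    mds <- stats::cmdscale(stats::as.dist(diss), k = k, eig = TRUE)
    ev <- pmax(mds$eig, 0)
    list(coordinates = mds$points,
         variance_explained = (ev / sum(ev))[seq_len(k)])
  }
}

#' Mann-Whitney U test for lineage divergence
#'
#' Compares the between-lineage distances involving a focal lineage
#' against all remaining between-lineage distances. The exact two-tailed
#' p-value is used when both samples have at most `exact_max` observations
#' and no ties; otherwise the normal approximation with tie correction.
#'
#' @param d distance matrix with genome ids as dimnames.
#' @param partition named character vector genome id -> lineage.
#' @param focal focal lineage id.
#' @param exact_max sample size bound for the exact path (default 8).
#' @return list with `U`, `p_value`, `method`, `n_focal`, `n_other`.
#' @export
lineage_divergence_test <- function(d, partition, focal, exact_max = 8L) {
  ids <- rownames(d)
  lin <- partition[ids]
  if (!focal %in% lin) stop("focal lineage absent from partition")
  if (length(unique(lin)) < 2L) stop("need at least two lineages")
  cmb <- combn(length(ids), 2L)
  li <- lin[cmb[1, ]]; lj <- lin[cmb[2, ]]
  between <- li != lj
  vals <- d[cbind(cmb[1, between], cmb[2, between])]
  inv_focal <- (li[between] == focal) | (lj[between] == focal)
  x <- vals[inv_focal]; y <- vals[!inv_focal]
  if (!length(x) || !length(y)) stop("empty comparison set")
  mann_whitney(x, y, exact_max)
}

mann_whitney <- function(x, y, exact_max = 8L) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (n1 <= exact_max && n2 <= exact_max && !ties) {
    p <- 2 * min(stats::pwilcox(U, n1, n2),
                 stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE))
    p <- min(1, p)
    method <- "exact"
  } else {
    N <- n1 + n2
    tt <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
    z <- (U - n1 * n2 / 2) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(U = unname(U), p_value = p, method = method, n_focal = n1, n_other = n2)
}
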