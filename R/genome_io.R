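#' Assemble a phage community object
#'
#' A community bundles the genome sequences of a set of phage isolates with
#' their gene annotations and source-site labels. Coordinates are stored
#' 0-based half-open internally; the GFF3 reader/writer converts at the
#' boundary.
#'
#' @param genomes named character vector of uppercase nucleotide sequences
#'   (names are genome ids, unique).
#' @param annotations data.frame with columns `genome_id`, `gene_id`,
#'   `start`, `end` (0-based half-open), `strand` (`"+"`/`"-"`) and
#'   optionally `cds`; the coding sequence is extracted (minus strand
#'   reverse-complemented) when absent.
#' @param sites named character vector mapping genome ids to source sites
#'   (`"coastal"`, `"offshore"` or `"unknown"`); missing genomes get
#'   `"unknown"`.
#' @return an object of class `phage_community` with elements `genomes`,
#'   `annotations` (with a `uid` column and extracted `cds`) and `sites`.
#' @export
phage_community <- function(genomes, annotations, sites = NULL) {
  genomes <- toupper(genomes)
  if (is.null(names(genomes)) || anyDuplicated(names(genomes)))
    stop("genomes must be a named vector with unique genome ids")
  if (any(nchar(genomes) == 0L)) stop("empty genome sequence")
  ann <- as.data.frame(annotations, stringsAsFactors = FALSE)
  req <- c("genome_id", "gene_id", "start", "end", "strand")
  if (!all(req %in% names(ann)))
    stop("annotations need columns: ", paste(req, collapse = ", "))
  missing_g <- setdiff(unique(ann$genome_id), names(genomes))
  if (length(missing_g))
    stop("annotation refers to unknown genome(s): ",
         paste(missing_g, collapse = ", "))
  glen <- nchar(genomes)[ann$genome_id]
  bad <- which(!(ann$start >= 0L & ann$start < ann$end & ann$end <= glen))
  if (length(bad))
    stop("out-of-bounds gene coordinates for: ",
         paste(ann$gene_id[bad], collapse = ", "))
  if (!all(ann$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (is.null(ann$cds) || all(is.na(ann$cds))) {
    cds <- substring(genomes[ann$genome_id], ann$start + 1L, ann$end)
    neg <- ann$strand == "-"
    if (any(neg)) cds[neg] <- revcomp(cds[neg])
    ann$cds <- unname(cds)
  }
  ann$uid <- gene_uid(ann$genome_id, ann$gene_id)
  if (anyDuplicated(ann$uid)) stop("duplicated gene ids within a genome")
  nc3 <- nchar(ann$cds) %% 3L != 0L
  if (any(nc3))
    warning(sum(nc3), " gene(s) with length not divisible by 3 (flagged)")
  ann$frame_ok <- !nc3
  st <- setNames(rep("unknown", length(genomes)), names(genomes))
  if (!is.null(sites)) {
    sites <- sites[intersect(names(sites), names(st))]
    st[names(sites)] <- sites
  }
  if (!all(st %in% c("coastal", "offshore", "unknown")))
    stop("sites must be coastal, offshore or unknown")
  structure(list(genomes = genomes, annotations = ann, sites = st),
            class = "phage_community")
}

#' @export
print.phage_community <- function(x, ...) {
  cat("phage_community:", length(x$genomes), "genomes,",
      nrow(x$annotations), "genes\n")
  cat("  sites:", paste(names(table(x$sites)), table(x$sites),
                        sep = "=", collapse = ", "), "\n")
  cat("  genome length range:", min(nchar(x$genomes)), "-",
      max(nchar(x$genomes)), "bp\n")
  invisible(x)
}

#' Read genomes and annotations from FASTA and GFF3
#'
#' @param fasta_paths character vector of FASTA files (multi-record allowed).
#' @param gff_paths character vector of GFF3 files with gene/CDS features;
#'   1-based closed coordinates are converted to the internal 0-based
#'   half-open convention.
#' @param site_map optional named character vector genome id -> site label.
#' @return a [phage_community].
#' @export
read_community <- function(fasta_paths, gff_paths, site_map = NULL) {
  stopifnot(all(file.exists(fasta_paths)), all(file.exists(gff_paths)))
  seqs <- do.call(c, lapply(fasta_paths, function(p) {
    x <- Biostrings::readDNAStringSet(p)
    setNames(as.character(x), sub("\\s.*$", "", names(x)))
  }))
  ann <- do.call(rbind, lapply(gff_paths, function(p) {
    gr <- rtracklayer::import(p, format = "gff3")
    df <- as.data.frame(gr)
    gid <- if (!is.null(df$ID)) as.character(df$ID) else
      paste0("gene", seq_len(nrow(df)))
    data.frame(genome_id = as.character(df$seqnames),
               gene_id = gid,
               start = df$start - 1L,       # to 0-based half-open
               end = df$end,
               strand = ifelse(as.character(df$strand) == "-", "-", "+"),
               stringsAsFactors = FALSE)
  }))
  phage_community(seqs, ann, sites = site_map)
}

#' Write a community back to FASTA and GFF3
#'
#' Round-trip safe: [read_community] on the written files reproduces the
#' same sequences, coordinates, strands and coding sequences.
#'
#' @param community a [phage_community].
#' @param fasta_path,gff_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_community <- function(community, fasta_path, gff_path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(community$genomes), fasta_path)
  ann <- community$annotations
  gr <- GenomicRanges::GRanges(
    seqnames = ann$genome_id,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand)
  S4Vectors::mcols(gr)$ID <- ann$gene_id
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$source <- "phagepop"
  rtracklayer::export(gr, gff_path, format = "gff3")
  invisible(c(fasta_path, gff_path))
}
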