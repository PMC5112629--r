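# Internal sequence helpers. Sequences are plain uppercase character
# strings internally; Biostrings is used at I/O and alignment boundaries.

BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# split equal-length sequences into a character matrix (rows = sequences)
seq_matrix <- function(seqs) {
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences must have equal length")
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), byrow = TRUE)
  rownames(m) <- names(seqs)
  m
}

matrix_to_seqs <- function(m) {
  s <- apply(m, 1L, paste, collapse = "")
  names(s) <- rownames(m)
  s
}

# codons of a sequence (length must be divisible by 3)
codons_of <- function(x) {
  n <- nchar(x)
  stopifnot(n %% 3L == 0L)
  substring(x, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE
STOP_CODONS <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE == "*"]

translate_codon <- function(codon) {
  aa <- GENETIC_CODE_TABLE[codon]
  ifelse(is.na(aa), NA_character_, aa)
}

is_stop <- function(codon) codon %in% STOP_CODONS

# unique gene key used across the package: genome_id and gene_id joined
gene_uid <- function(genome_id, gene_id) paste(genome_id, gene_id, sep = "|")

`%||%` <- function(a, b) if (is.null(a)) b else a
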