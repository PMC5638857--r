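#' Read sequences from a FASTA file
#'
#' Case (soft-masking) is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write sequences to a FASTA file, wrapped at 60 columns
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 60L)
  invisible(path)
}

#' Read an aligned FASTA file (equal-length records)
#'
#' @param path Path to an aligned FASTA file.
#' @return A named character vector; errors if record lengths differ.
#' @export
read_alignment_fasta <- function(path) {
  seqs <- read_fasta(path)
  if (length(unique(nchar(seqs))) > 1) {
    abort("aligned FASTA records have unequal lengths")
  }
  seqs
}

#' Read a genes-by-samples expression matrix from TSV
#'
#' The first column holds gene identifiers; remaining columns are samples.
#'
#' @param path Path to a TSV file with a header row.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a genes-by-samples expression matrix to TSV
#' @param mat Numeric matrix with rownames (genes) and colnames (samples).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- tibble::as_tibble(mat, rownames = "gene_id")
  readr::write_tsv(df, path)
  invisible(path)
}
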