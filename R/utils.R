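# IUPAC nucleotide degeneracy classes (15-letter alphabet).
IUPAC_CLASSES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Complement map covering the full IUPAC alphabet plus gap characters.
COMPLEMENT_FROM <- "-.ACGTRYSWKMBDHVNacgtryswkmbdhvn"
COMPLEMENT_TO   <- "-.TGCAYRSWMKVHDBNtgcayrswmkvhdbn"

#' Reverse complement of a nucleotide string
#'
#' Handles the full IUPAC alphabet and preserves case; gap characters
#' (`-`, `.`) are kept in place.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("GAAAAGTTT")
revcomp <- function(x) {
  comp <- chartr(COMPLEMENT_FROM, COMPLEMENT_TO, x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Deterministic sub-seed derivation so that adding one simulated fixture does
# not shift the random draws of another. Stays below 2^31 - 1.
substream_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483647
}

# Sample a random DNA sequence with a given GC content.
random_dna <- function(n, gc_content = 0.5) {
  p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
         G = gc_content / 2, T = (1 - gc_content) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

is_gap <- function(ch) ch == "-" | ch == "."
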