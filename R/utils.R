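#' Reverse complement of a nucleotide string
#'
#' N is preserved as N.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# Encode a nucleotide string as integers for vectorized mismatch counting.
# N in a reference encodes to 0 and N in a read to -1, so N never matches
# anything (assemblies contain gap-filling Ns that must not count as matches).
encode_ref <- function(s) {
  v <- utf8ToInt(s)
  v[v == utf8ToInt("N")] <- 0L
  v
}

encode_read <- function(s) {
  v <- utf8ToInt(s)
  v[v == utf8ToInt("N")] <- -1L
  v
}

# Split a string into its characters.
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

#' Random nucleotide string under a given base composition
#'
#' @param n length in bases.
#' @param freqs named base frequencies.
#' @return nucleotide string.
#' @export
random_dna <- function(n, freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}

# Shuffle the characters of a string (used for composition-matched decoys).
shuffle_seq <- function(s) paste(sample(chars(s)), collapse = "")

#' Translate a coding sequence
#'
#' @param cds nucleotide string whose length is a multiple of 3.
#' @param trim_stop drop a trailing stop codon if present.
#' @return protein string (stops rendered as `*`, codons containing N or
#'   gaps as `X`).
#' @export
translate_cds <- function(cds, trim_stop = TRUE) {
  if (nchar(cds) %% 3L != 0L) stop("CDS length is not a multiple of 3")
  gc <- genetic_code()
  starts <- 3L * seq_len(nchar(cds) %/% 3L) - 2L
  cods <- substring(cds, starts, starts + 2L)
  aa <- ifelse(cods %in% names(gc), gc[cods], "X")
  if (trim_stop && length(aa) && aa[length(aa)] == "*") aa <- head(aa, -1L)
  paste(aa, collapse = "")
}
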