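#' Global pairwise alignment
#'
#' Needleman-Wunsch global alignment with affine gaps, computed with
#' [Biostrings::pairwiseAlignment()]. Nucleotide scoring is match +1 /
#' mismatch -1 with a length-L gap costing 4 + (L - 1); protein scoring is
#' BLOSUM62 with a length-L gap costing 11 + (L - 1). N never scores as a
#' match, not even against another N.
#'
#' @param a,b sequences (length-1 character, optionally named).
#' @param moltype `"nucleotide"` or `"protein"`; both inputs must share it.
#' @param gap_open,gap_extend override the default gap penalties (positive
#'   costs; a length-L gap costs `gap_open + L * gap_extend`).
#' @return list with elements `a_gapped`, `b_gapped` (equal-length strings
#'   with `-` for gaps) and `score`.
#' @export
align_global <- function(a, b, moltype = c("nucleotide", "protein"),
                         gap_open = NULL, gap_extend = NULL) {
  moltype <- match.arg(moltype)
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  if (moltype == "nucleotide") {
    bad <- grepl("[^ACGTN]", c(a, b))
    if (any(bad)) stop("moltype mismatch: non-nucleotide characters in input")
    if (is.null(gap_open)) gap_open <- 3
    if (is.null(gap_extend)) gap_extend <- 1
    sm <- nt_score_matrix()
    p <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = sm,
                                       gapOpening = gap_open,
                                       gapExtension = gap_extend)
  } else {
    bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", c(a, b))
    if (any(bad)) stop("moltype mismatch: non-protein characters in input")
    if (is.null(gap_open)) gap_open <- 10
    if (is.null(gap_extend)) gap_extend <- 1
    sm <- blosum62_matrix()
    p <- Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                       Biostrings::AAString(b),
                                       type = "global",
                                       substitutionMatrix = sm,
                                       gapOpening = gap_open,
                                       gapExtension = gap_extend)
  }
  out <- list(a_gapped = as.character(Biostrings::alignedPattern(p)),
              b_gapped = as.character(Biostrings::alignedSubject(p)),
              score = Biostrings::score(p))
  stopifnot(nchar(out$a_gapped) == nchar(out$b_gapped))
  out
}

nt_score_matrix <- function() {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5L, 5L, dimnames = list(bases, bases))
  diag(m) <- 1
  m["N", "N"] <- -1   # assembly gap filler: never a match
  m
}

blosum62_matrix <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

#' Percent identity of a pairwise alignment
#'
#' Identity is the number of matching residues divided by the number of
#' alignment columns, excluding gap-containing columns from both the
#' numerator and the denominator. A column where either residue is N (or X)
#' never counts as a match.
#'
#' @param aln alignment list from [align_global()] (or any list with
#'   `a_gapped` and `b_gapped`).
#' @return percent identity in `[0, 100]`.
#' @export
percent_identity <- function(aln) {
  a <- chars(aln$a_gapped)
  b <- chars(aln$b_gapped)
  stopifnot(length(a) == length(b))
  if (any(a == "-" & b == "-")) stop("alignment has a column gapped in both rows")
  keep <- a != "-" & b != "-"
  if (!any(keep)) stop("undefined identity: all alignment columns are gapped")
  a <- a[keep]; b <- b[keep]
  match <- a == b & a != "N" & a != "X"
  100 * sum(match) / length(a)
}

#' Pairwise identity matrices for a gene family
#'
#' Aligns every pair of coding sequences and every pair of protein
#' sequences globally and collects percent identities in two symmetric
#' matrices (diagonal 100), the layout used for identity heatmaps with
#' nucleotide values above and amino-acid values below the diagonal.
#'
#' @param cds_set named character vector of coding sequences.
#' @param protein_set named character vector of protein sequences; must have
#'   the same names as `cds_set`.
#' @return list with `labels`, `nt_identity`, `aa_identity`.
#' @export
identity_matrix <- function(cds_set, protein_set) {
  validate_seqs(cds_set, "nucleotide")
  validate_seqs(protein_set, "protein")
  if (!identical(sort(names(cds_set)), sort(names(protein_set)))) {
    stop("label mismatch between CDS and protein sets")
  }
  labels <- names(cds_set)
  protein_set <- protein_set[labels]
  n <- length(labels)
  nt <- aa <- matrix(100, n, n, dimnames = list(labels, labels))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        nt[i, j] <- nt[j, i] <-
          percent_identity(align_global(cds_set[[i]], cds_set[[j]], "nucleotide"))
        aa[i, j] <- aa[j, i] <-
          percent_identity(align_global(protein_set[[i]], protein_set[[j]], "protein"))
      }
    }
  }
  list(labels = labels, nt_identity = nt, aa_identity = aa)
}

#' Write identity matrices as TSV
#'
#' Writes two TSV files (`<prefix>_nt.tsv`, `<prefix>_aa.tsv`) plus a
#' combined heatmap-style table (`<prefix>_combined.tsv`) with nucleotide
#' identities above the diagonal and amino-acid identities below it.
#'
#' @param im list from [identity_matrix()].
#' @param prefix output path prefix.
#' @export
write_identity_matrix <- function(im, prefix) {
  write.table(round(im$nt_identity, 1), paste0(prefix, "_nt.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  write.table(round(im$aa_identity, 1), paste0(prefix, "_aa.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  comb <- im$nt_identity
  comb[lower.tri(comb)] <- im$aa_identity[lower.tri(comb)]
  write.table(round(comb, 1), paste0(prefix, "_combined.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  invisible(prefix)
}
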