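#' Codon-aware conserved-block trimming of a multiple alignment
#'
#' A column is conserved iff strictly more than half of the rows agree on
#' its majority residue (gaps never count toward the majority). A column
#' containing gaps is retained only if at most `floor(rows / 2)` rows are
#' gapped ("with half"); columns violating the gap rule are removed
#' outright. Retained regions must not contain a run of more than
#' `max_noncons_run` contiguous non-conserved columns, and every retained
#' block must span at least `min_block` columns. Columns are removed in full
#' codons (triplets of the original frame), and the run/length rules are
#' re-checked on the trimmed output until stable, so the result provably
#' satisfies both rules.
#'
#' @param aln named character vector: equal-length gapped nucleotide rows.
#' @param max_noncons_run maximum allowed run of non-conserved columns.
#' @param min_block minimum block length in columns.
#' @param gap_policy only `"with half"` is supported.
#' @return named character vector of trimmed rows (equal lengths, a
#'   multiple of 3).
#' @export
gblocks_trim <- function(aln, max_noncons_run = 8L, min_block = 10L,
                         gap_policy = "with half") {
  stopifnot(length(aln) >= 2L, gap_policy == "with half")
  L <- unique(nchar(aln))
  if (length(L) != 1L) stop("alignment rows differ in length")
  if (L %% 3L != 0L) stop("aligned length is not a multiple of 3")
  m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  nr <- nrow(m)

  cons <- logical(L)
  gap_ok <- logical(L)
  for (j in seq_len(L)) {
    col <- m[, j]
    gaps <- sum(col == "-")
    gap_ok[j] <- gaps <= nr %/% 2L
    res <- col[col != "-"]
    if (length(res)) {
      tab <- table(res)
      cons[j] <- max(tab) > nr / 2
    }
  }
  removable <- !cons | !gap_ok   # candidates; gap violations always go

  keep <- rep(TRUE, L)
  keep[!gap_ok] <- FALSE
  keep <- drop_partial_codons(keep, L)
  repeat {
    idx <- which(keep)
    if (!length(idx)) stop("trimming removed the whole alignment")
    bad <- logical(length(idx))
    # rule 1: runs of non-conserved columns longer than max_noncons_run
    r <- rle(!cons[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in seq_along(r$lengths)) {
      if (r$values[i] && r$lengths[i] > max_noncons_run) {
        bad[starts[i]:ends[i]] <- TRUE
      }
    }
    if (!any(bad)) {
      # rule 2: retained blocks shorter than min_block (in original coords)
      blocks <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
      for (b in blocks) if (length(b) < min_block) bad[idx %in% b] <- TRUE
    }
    if (!any(bad)) break
    keep[idx[bad]] <- FALSE
    keep <- drop_partial_codons(keep, L)
  }
  trimmed <- vapply(seq_len(nr), function(i) {
    paste(m[i, keep], collapse = "")
  }, character(1L))
  out <- setNames(trimmed, names(aln))
  attr(out, "kept_columns") <- which(keep)
  attr(out, "conserved") <- cons
  out
}

# Expand removals to whole codons of the original reading frame.
drop_partial_codons <- function(keep, L) {
  cod <- matrix(keep, nrow = 3L)
  full <- apply(cod, 2L, all)
  rep(full, each = 3L)[seq_len(L)] & keep
}
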