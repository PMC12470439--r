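#' Filter small-RNA reads by length and quality
#'
#' Keeps reads whose length lies in `[min_len, max_len]` (inclusive) and
#' whose mean Phred quality strictly exceeds `min_mean_q` (a read with mean
#' quality exactly at the threshold is dropped).
#'
#' @param reads data.frame from [read_fastq()].
#' @param min_len,max_len inclusive length bounds.
#' @param min_mean_q mean-quality threshold (strict).
#' @return filtered data.frame; attributes `n_kept` and `n_dropped` carry
#'   the tallies.
#' @export
filter_reads <- function(reads, min_len = 23L, max_len = 30L,
                         min_mean_q = 30) {
  len <- nchar(reads$sequence)
  meanq <- vapply(reads$qualities, mean, numeric(1L))
  keep <- len >= min_len & len <= max_len & meanq > min_mean_q
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Remove reads matching structural RNA contaminants
#'
#' Drops every read that maps to any contaminant reference (rRNA, snRNA,
#' snoRNA, miRNA, tRNA, ...) on either strand with at most one mismatch.
#'
#' @param reads read data.frame.
#' @param contaminant_refs named character vector of contaminant sequences.
#' @return filtered data.frame (a warning and identity pass-through if the
#'   contaminant set is empty).
#' @export
remove_structural <- function(reads, contaminant_refs) {
  if (length(contaminant_refs) == 0L) {
    warning("empty contaminant set: reads passed through unchanged")
    return(reads)
  }
  hits <- map_reads(reads, contaminant_refs, max_mismatches = 1L)
  bad <- unique(hits$read_id)
  out <- reads[!reads$id %in% bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- length(bad)
  out
}

#' Map reads to references, ungapped, with bounded mismatches
#'
#' Exact-seed pigeonhole mapping: each read is anchored by
#' `max_mismatches + 1` non-overlapping exact seeds, so every ungapped
#' placement of the full read with at most `max_mismatches` mismatches is
#' guaranteed to be found. Both strands are searched; minus-strand hits are
#' recorded against plus-strand coordinates. N never matches anything.
#'
#' @param reads read data.frame (columns `id`, `sequence`) or a named
#'   character vector of read sequences.
#' @param reference named character vector of reference sequences (a single
#'   unnamed string is accepted and named `ref`).
#' @param max_mismatches maximum mismatch count (0-2 supported).
#' @param seed_k seed length cap.
#' @return data.frame with `read_id`, `ref`, `start` (0-based), `strand`,
#'   `mismatches`, `read_len`.
#' @export
map_reads <- function(reads, reference, max_mismatches = 1L, seed_k = 12L) {
  if (is.data.frame(reads)) {
    seqs <- setNames(reads$sequence, reads$id)
  } else {
    seqs <- reads
    if (is.null(names(seqs))) names(seqs) <- paste0("r", seq_along(seqs))
  }
  if (is.null(names(reference))) {
    names(reference) <- if (length(reference) == 1L) "ref" else
      paste0("ref", seq_along(reference))
  }
  stopifnot(max_mismatches >= 0L, max_mismatches <= 2L)
  npieces <- max_mismatches + 1L
  lens <- unname(nchar(seqs))
  usable <- lens %/% npieces >= 5L   # below this, seeding is hopeless
  if (any(!usable)) {
    warning(sum(!usable), " read(s) shorter than seedable length skipped")
    seqs <- seqs[usable]; lens <- lens[usable]
  }
  if (length(seqs) == 0L) return(empty_hits())
  k <- min(seed_k, min(lens) %/% npieces)

  out <- vector("list", length(reference))
  for (ri in seq_along(reference)) {
    refname <- names(reference)[ri]
    refseq <- reference[[ri]]
    rlen <- nchar(refseq)
    if (rlen < k) next
    idx <- kmer_index(refseq, k)
    rv <- encode_ref(refseq)
    hits <- vector("list", 2L * length(seqs))
    hi <- 0L
    for (si in seq_along(seqs)) {
      for (strand in c("+", "-")) {
        s <- if (strand == "+") seqs[[si]] else revcomp(seqs[[si]])
        L <- lens[si]
        pl <- L %/% npieces
        offs <- pl * (seq_len(npieces) - 1L) + 1L
        cand <- integer(0)
        for (o in offs) {
          pos <- idx[[substr(s, o, o + k - 1L)]]
          if (!is.null(pos)) cand <- c(cand, pos - o + 1L)
        }
        cand <- unique(cand)
        cand <- cand[cand >= 1L & cand + L - 1L <= rlen]
        if (!length(cand)) next
        sv <- encode_read(s)
        mm <- vapply(cand, function(p) sum(rv[p:(p + L - 1L)] != sv),
                     integer(1L))
        ok <- mm <= max_mismatches
        if (!any(ok)) next
        hi <- hi + 1L
        hits[[hi]] <- data.frame(
          read_id = names(seqs)[si], ref = refname,
          start = as.integer(cand[ok] - 1L),
          strand = strand, mismatches = mm[ok], read_len = L,
          stringsAsFactors = FALSE)
      }
    }
    if (hi > 0L) out[[ri]] <- do.call(rbind, hits[seq_len(hi)])
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (!length(out)) return(empty_hits())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_hits <- function() {
  data.frame(read_id = character(), ref = character(), start = integer(),
             strand = character(), mismatches = integer(),
             read_len = integer(), stringsAsFactors = FALSE)
}

#' Keep one deterministic placement per read
#'
#' Selects, per read, the hit with the fewest mismatches, breaking ties by
#' leftmost start and then by plus strand, mirroring a single-alignment
#' mapper's deterministic report.
#'
#' @param hits hit table from [map_reads()].
#' @return hit table with one row per read.
#' @export
best_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$read_id, hits$mismatches, hits$start,
               hits$strand != "+")
  h <- hits[ord, , drop = FALSE]
  h <- h[!duplicated(h$read_id), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Locally unique read attribution to a focal region
#'
#' Two-pass attribution: pass 1 maps reads against the genome with the
#' focal interval excised; any read with a pass-1 hit can arise elsewhere
#' and is discarded. Pass 2 maps the survivors to the focal sequence; the
#' returned hits are pass-2 hits only, in focal-relative coordinates. A
#' read kept here is mappable only within the focal region ("locally
#' unique").
#'
#' @param reads read data.frame.
#' @param genome named character vector of chromosome sequences.
#' @param focal single-row interval data.frame (0-based half-open) on a
#'   chromosome of `genome`.
#' @param max_mismatches mismatch bound used in both passes.
#' @return hit data.frame (`ref` is `"focal"`, `start` relative to the
#'   focal interval); attribute `focal` carries the interval.
#' @export
locally_unique <- function(reads, genome, focal, max_mismatches = 1L) {
  chrom <- focal$chrom[1L]
  if (!chrom %in% names(genome)) stop("focal chromosome not in genome")
  cl <- nchar(genome[[chrom]])
  if (focal$end[1L] > cl || focal$start[1L] < 0L) {
    stop("focal interval not contained in genome")
  }
  left <- substr(genome[[chrom]], 1L, focal$start[1L])
  right <- substr(genome[[chrom]], focal$end[1L] + 1L, cl)
  masked <- genome[names(genome) != chrom]
  if (nchar(left) > 0L) masked <- c(masked, setNames(left, paste0(chrom, "_5p")))
  if (nchar(right) > 0L) masked <- c(masked, setNames(right, paste0(chrom, "_3p")))
  focal_seq <- substr(genome[[chrom]], focal$start[1L] + 1L, focal$end[1L])

  pass1 <- if (length(masked)) {
    suppressWarnings(map_reads(reads, masked, max_mismatches = max_mismatches))
  } else empty_hits()
  survivors <- reads[!reads$id %in% unique(pass1$read_id), , drop = FALSE]
  hits <- suppressWarnings(
    map_reads(survivors, setNames(focal_seq, "focal"),
              max_mismatches = max_mismatches))
  attr(hits, "focal") <- focal
  hits
}

#' Mismatch-stratified sense/antisense read counts for a transcript
#'
#' Each read mapping to the transcript with at most 2 mismatches is counted
#' once, in its minimal-mismatch stratum (0, 1, or 2) and strand class
#' (sense = read strand matches transcript orientation). Counts are
#' normalized to reads per million of `library_denominator`; the `0-2`
#' row is the sum of the three strata.
#'
#' @param reads read data.frame.
#' @param transcript transcript sequence (length-1 character).
#' @param library_denominator library size for rpm normalization (> 0).
#' @return data.frame with one row per stratum (`"0"`, `"1"`, `"2"`,
#'   `"0-2"`) and columns `sense_count`, `antisense_count`, `sense_rpm`,
#'   `antisense_rpm`.
#' @export
stratified_counts <- function(reads, transcript, library_denominator) {
  stopifnot(library_denominator > 0)
  hits <- suppressWarnings(
    map_reads(reads, setNames(transcript, "tx"), max_mismatches = 2L))
  best <- best_hits(hits)
  cnt <- matrix(0L, nrow = 3L, ncol = 2L,
                dimnames = list(c("0", "1", "2"), c("+", "-")))
  if (nrow(best) > 0L) {
    tab <- table(factor(best$mismatches, levels = 0:2),
                 factor(best$strand, levels = c("+", "-")))
    cnt[] <- as.integer(tab)
  }
  out <- data.frame(
    stratum = c("0", "1", "2", "0-2"),
    sense_count = c(cnt[, "+"], sum(cnt[, "+"])),
    antisense_count = c(cnt[, "-"], sum(cnt[, "-"])),
    stringsAsFactors = FALSE)
  out$sense_rpm <- 1e6 * out$sense_count / library_denominator
  out$antisense_rpm <- 1e6 * out$antisense_count / library_denominator
  attr(out, "library_denominator") <- library_denominator
  out
}

#' Per-position strand-separated read coverage
#'
#' Every hit increments its strand's counter at every position it covers,
#' so total coverage equals the summed hit lengths.
#'
#' @param hits hit data.frame (typically [best_hits()] of a mapping).
#' @param reference_length length of the reference sequence.
#' @return list with integer vectors `sense` and `antisense` (length
#'   `reference_length`).
#' @export
coverage_profile <- function(hits, reference_length) {
  sense <- integer(reference_length)
  antisense <- integer(reference_length)
  if (nrow(hits) > 0L) {
    if (any(hits$start < 0L | hits$start + hits$read_len > reference_length)) {
      stop("hit outside reference")
    }
    for (i in seq_len(nrow(hits))) {
      span <- (hits$start[i] + 1L):(hits$start[i] + hits$read_len[i])
      if (hits$strand[i] == "+") sense[span] <- sense[span] + 1L
      else antisense[span] <- antisense[span] + 1L
    }
  }
  list(sense = sense, antisense = antisense)
}

#' Ping-pong 5'-overlap signature
#'
#' For each offset o in `1..max_offset`, counts (sense, antisense) read
#' pairs whose 5' ends overlap by exactly o nt: the antisense read's 5' end
#' (its rightmost base in plus-strand coordinates) lies opposite plus-strand
#' position `sense_start + o - 1`. The canonical ping-pong signal is offset
#' 10; its z-score is computed against the mean and standard deviation of
#' the counts at all other offsets.
#'
#' @param sense_hits,antisense_hits hit data.frames on a shared coordinate
#'   system (columns `start`, `read_len`).
#' @param max_offset largest 5'-5' offset tallied.
#' @return list with `overlap_counts` (named numeric, offsets 1..max),
#'   `z10`, `pairs_at_10`, and `defined` (FALSE when the background sd is
#'   zero, in which case `z10` is `NA`).
#' @export
pingpong <- function(sense_hits, antisense_hits, max_offset = 25L) {
  counts <- setNames(numeric(max_offset), seq_len(max_offset))
  if (nrow(sense_hits) > 0L && nrow(antisense_hits) > 0L) {
    s5 <- sense_hits$start
    a5 <- antisense_hits$start + antisense_hits$read_len - 1L
    st <- table(s5)
    at <- table(a5)
    sv <- as.integer(names(st))
    av <- as.integer(names(at))
    for (o in seq_len(max_offset)) {
      m <- match(sv + o - 1L, av)
      ok <- !is.na(m)
      if (any(ok)) {
        counts[o] <- sum(as.numeric(st[ok]) * as.numeric(at[m[ok]]))
      }
    }
  }
  bg <- counts[-10L]
  z10 <- NA_real_
  defined <- FALSE
  if (sd(bg) > 0) {
    z10 <- (counts[[10L]] - mean(bg)) / sd(bg)
    defined <- TRUE
  }
  list(overlap_counts = counts, z10 = z10, pairs_at_10 = counts[[10L]],
       defined = defined)
}
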