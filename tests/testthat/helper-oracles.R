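# Independent brute-force oracles used to validate the package's optimized
# implementations on small inputs.

# Exhaustive-search optimal global alignment score. Affine gaps: a gap run
# of length L costs gap_open + L * gap_extend. Recursion enumerates every
# alignment of a and b; feasible for sequences up to ~6 residues.
oracle_nw_score <- function(a, b, match = 1, mismatch = -1,
                            gap_open = 3, gap_extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j] && av[i] != "N") match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, "D"))
    }
    if (i <= length(av)) {   # gap in b
      cost <- gap_extend + if (prev == "U") 0 else gap_open
      best <- max(best, -cost + rec(i + 1L, j, "U"))
    }
    if (j <= length(bv)) {   # gap in a
      cost <- gap_extend + if (prev == "L") 0 else gap_open
      best <- max(best, -cost + rec(i, j + 1L, "L"))
    }
    best
  }
  rec(1L, 1L, "D")
}

# Brute-force ungapped mapping: mismatch counts of a read at every position
# of a reference, both strands. Returns a data.frame(start, strand, mm)
# of placements with mm <= max_mm.
oracle_map <- function(read, refseq, max_mm) {
  gi <- utf8ToInt(refseq)
  gi[gi == utf8ToInt("N")] <- 0L
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") read else dupscan::revcomp(read)
    rv <- utf8ToInt(s)
    rv[rv == utf8ToInt("N")] <- -1L
    L <- length(rv)
    P <- length(gi) - L + 1L
    if (P < 1L) next
    acc <- integer(P)
    for (j in seq_len(L)) {
      acc <- acc + (gi[j:(P + j - 1L)] != rv[j])
    }
    keep <- which(acc <= max_mm)
    if (length(keep)) {
      out[[strand]] <- data.frame(start = keep - 1L, strand = strand,
                                  mm = acc[keep])
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), strand = character(), mm = integer()))
  }
  do.call(rbind, out)
}

# O(n^2) all-pairs ping-pong overlap histogram.
oracle_pingpong_counts <- function(sense_hits, antisense_hits,
                                   max_offset = 25L) {
  counts <- setNames(numeric(max_offset), seq_len(max_offset))
  for (i in seq_len(nrow(sense_hits))) {
    for (j in seq_len(nrow(antisense_hits))) {
      a5 <- antisense_hits$start[j] + antisense_hits$read_len[j] - 1L
      o <- a5 - sense_hits$start[i] + 1L
      if (o >= 1L && o <= max_offset) counts[o] <- counts[o] + 1
    }
  }
  counts
}

# Brute-force dotplot: exact k-mer set intersection, both strands.
oracle_dotplot <- function(a, b, k) {
  na <- nchar(a) - k + 1L
  nb <- nchar(b) - k + 1L
  rcb <- dupscan::revcomp(b)
  out <- list()
  for (i in seq_len(na)) {
    ka <- substr(a, i, i + k - 1L)
    for (j in seq_len(nb)) {
      if (ka == substr(b, j, j + k - 1L)) {
        out[[length(out) + 1L]] <- data.frame(a_pos = i - 1L, b_pos = j - 1L,
                                              strand = "+")
      }
      if (ka == substr(rcb, nchar(b) - (j - 1L) - k + 1L,
                       nchar(b) - (j - 1L))) {
        out[[length(out) + 1L]] <- data.frame(a_pos = i - 1L, b_pos = j - 1L,
                                              strand = "-")
      }
    }
  }
  if (!length(out)) {
    return(data.frame(a_pos = integer(), b_pos = integer(),
                      strand = character()))
  }
  do.call(rbind, out)
}

# Hamming distance between equal-length strings.
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Small FASTQ data.frame builder.
make_reads <- function(seqs, q = 38L, ids = NULL) {
  if (is.null(ids)) ids <- paste0("r", seq_along(seqs))
  data.frame(id = ids, sequence = seqs,
             qualities = I(lapply(nchar(seqs), function(n) rep(q, n))),
             stringsAsFactors = FALSE)
}

# Sort a hit table into canonical order for set comparison.
canon_hits <- function(h) {
  h <- h[order(h$read_id, h$ref, h$start, h$strand),
         c("read_id", "ref", "start", "strand", "mismatches")]
  rownames(h) <- NULL
  h
}
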