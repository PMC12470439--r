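#' Scan a genomic sequence for homologous gene copies
#'
#' Seed-and-verify homolog search: exact k-mer seeds (both strands) anchor
#' candidate full-length ungapped placements of the query, each candidate is
#' verified by direct mismatch counting, and same-strand hits that overlap
#' or abut within `merge_gap` bp are merged so a tandem copy is never
#' counted twice. The number of returned hits is the in-silico copy-number
#' estimate for the query gene in the assembly.
#'
#' @param genome nucleotide string (the region or assembly to scan).
#' @param query_cds nucleotide string (the query gene).
#' @param min_identity_pct identity floor (percent) for a hit.
#' @param min_query_cov query-coverage floor (fraction) for a hit.
#' @param k seed length.
#' @param merge_gap same-strand hits closer than this many bp are merged.
#' @return data.frame with 0-based half-open `start`, `end`, `strand`,
#'   `identity_pct`, `query_coverage`, ordered by `start`.
#' @export
homolog_scan <- function(genome, query_cds, min_identity_pct = 80,
                         min_query_cov = 0.8, k = 11L, merge_gap = 50L) {
  stopifnot(is.character(genome), length(genome) == 1L,
            is.character(query_cds), length(query_cds) == 1L)
  qlen <- nchar(query_cds)
  glen <- nchar(genome)
  if (qlen < k) stop("query shorter than seed length k = ", k)
  gref <- encode_ref(genome)
  gidx <- kmer_index(genome, k)

  scan_strand <- function(q, strand) {
    qv <- encode_read(q)
    npos <- qlen - k + 1L
    # seed every ~k/2 bp plus the final k-mer: dense enough to anchor
    # diverged copies down to ~85% identity while keeping lookups cheap
    offs <- unique(c(seq.int(1L, npos, by = max(1L, k %/% 2L)), npos))
    cand <- integer(0)
    for (o in offs) {
      seed <- substr(q, o, o + k - 1L)
      hit <- gidx[[seed]]
      if (!is.null(hit)) cand <- c(cand, hit - o + 1L)
    }
    cand <- unique(cand)
    cand <- cand[cand >= 1L & cand + qlen - 1L <= glen]
    if (!length(cand)) return(NULL)
    mm <- vapply(cand, function(s) {
      sum(gref[s:(s + qlen - 1L)] != qv)
    }, integer(1L))
    idp <- 100 * (1 - mm / qlen)
    keep <- idp >= min_identity_pct
    if (!any(keep)) return(NULL)
    data.frame(start = as.integer(cand[keep] - 1L),
               end = as.integer(cand[keep] - 1L + qlen),
               strand = strand, identity_pct = idp[keep],
               query_coverage = 1.0, stringsAsFactors = FALSE)
  }

  hits <- rbind(scan_strand(query_cds, "+"), scan_strand(revcomp(query_cds), "-"))
  if (is.null(hits) || nrow(hits) == 0L) {
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      identity_pct = numeric(), query_coverage = numeric()))
  }
  out <- do.call(rbind, lapply(split(hits, hits$strand), function(h) {
    merge_hits(h[order(h$start), , drop = FALSE], merge_gap, qlen)
  }))
  out <- out[out$query_coverage >= min_query_cov, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Hash of exact k-mer -> 1-based start positions in s.
kmer_index <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(list())
  starts <- seq_len(n - k + 1L)
  kmers <- substring(s, starts, starts + k - 1L)
  keep <- !grepl("N", kmers, fixed = TRUE)
  split(starts[keep], kmers[keep])
}

# Merge overlapping/near-abutting same-strand hits (sorted by start).
merge_hits <- function(h, merge_gap, qlen) {
  if (nrow(h) <= 1L) return(h)
  grp <- cumsum(c(1L, as.integer(h$start[-1L] > cummax(h$end[-nrow(h)]) + merge_gap)))
  do.call(rbind, lapply(split(h, grp), function(g) {
    data.frame(start = min(g$start), end = max(g$end), strand = g$strand[1L],
               identity_pct = max(g$identity_pct),
               query_coverage = min(1, (max(g$end) - min(g$start)) / qlen),
               stringsAsFactors = FALSE)
  }))
}

#' Dot-matrix comparison of two nucleotide sequences
#'
#' Reports every exact shared k-mer on both strands. For minus-strand
#' points, `b_pos` is the 0-based plus-strand start in `b` of the k-mer
#' whose reverse complement matches the k-mer of `a` at `a_pos`.
#'
#' @param a,b nucleotide strings.
#' @param k word size (at least 8 for genome-scale plots; smaller values are
#'   accepted for small inputs).
#' @return data.frame with `a_pos`, `b_pos` (0-based) and `strand`.
#' @export
dotplot <- function(a, b, k = 12L) {
  stopifnot(nchar(a) >= k, nchar(b) >= k)
  na <- nchar(a) - k + 1L
  a_kmers <- substring(a, seq_len(na), seq_len(na) + k - 1L)
  bidx <- kmer_index(b, k)
  bidx_rc <- kmer_index(revcomp(b), k)
  nb <- nchar(b)
  rows <- vector("list", 2L * na)
  ri <- 0L
  for (i in seq_len(na)) {
    fw <- bidx[[a_kmers[i]]]
    if (!is.null(fw)) {
      ri <- ri + 1L
      rows[[ri]] <- data.frame(a_pos = i - 1L, b_pos = fw - 1L, strand = "+")
    }
    rc <- bidx_rc[[a_kmers[i]]]
    if (!is.null(rc)) {
      ri <- ri + 1L
      # position on rc(b) -> plus-strand start of the matching b k-mer
      rows[[ri]] <- data.frame(a_pos = i - 1L, b_pos = nb - (rc - 1L) - k,
                               strand = "-")
    }
  }
  if (ri == 0L) {
    return(data.frame(a_pos = integer(), b_pos = integer(), strand = character()))
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  rownames(out) <- NULL
  out
}

#' Construct a gene locus record
#'
#' A located gene copy with up to three upstream and three downstream
#' flanking gene ids, the unit of the microsynteny survey.
#'
#' @param gene_id gene identifier.
#' @param species species label.
#' @param chrom,start,end,strand location (0-based half-open).
#' @param cds coding sequence (optional).
#' @param flank_up,flank_down character vectors of at most 3 flanking gene
#'   ids each, ordered away from the locus.
#' @return list of class `gene_locus`.
#' @export
gene_locus <- function(gene_id, species, chrom, start, end, strand = "+",
                       cds = NULL, flank_up = character(),
                       flank_down = character()) {
  if (length(flank_up) > 3L || length(flank_down) > 3L) {
    stop("at most three upstream and three downstream flanking genes")
  }
  stopifnot(end > start)
  structure(list(gene_id = gene_id, species = species,
                 location = data.frame(chrom = chrom, start = start, end = end,
                                       strand = strand),
                 cds = cds, flank_up = flank_up, flank_down = flank_down),
            class = "gene_locus")
}

#' Flanking homology between two gene loci
#'
#' The fraction of flanking-gene slots (up to three upstream plus three
#' downstream, order-insensitive) whose gene has an ortholog among the other
#' locus's flanking genes. The denominator is the larger of the two flank
#' counts, capped at six.
#'
#' @param a,b `gene_locus` objects.
#' @param ortholog_map named character vector mapping gene ids of `a`'s
#'   species to orthologous gene ids of `b`'s species (e.g. from
#'   [ortholog_map()]).
#' @return fraction in `[0, 1]`.
#' @export
flanking_homology <- function(a, b, ortholog_map) {
  fa <- c(a$flank_up, a$flank_down)
  fb <- c(b$flank_up, b$flank_down)
  if (length(fa) == 0L && length(fb) == 0L) {
    stop("undefined synteny: both flank lists are empty")
  }
  denom <- min(6L, max(length(fa), length(fb)))
  mapped <- unname(ortholog_map[fa])
  shared <- sum(!is.na(mapped) & mapped %in% fb)
  shared / denom
}

#' Classify a locus pair as syntenic
#'
#' Syntenic iff the flanking-homology fraction strictly exceeds 15%.
#'
#' @param fraction flanking-homology fraction from [flanking_homology()].
#' @param threshold synteny threshold (default 0.15).
#' @return logical.
#' @export
classify_syntenic <- function(fraction, threshold = 0.15) {
  fraction > threshold
}

#' Reciprocal-best ortholog map between two protein sets
#'
#' Pairs each protein in `set_a` with its highest-identity partner in
#' `set_b` when the choice is reciprocal and the global protein identity is
#' at least `min_identity` percent.
#'
#' @param set_a,set_b named character vectors of protein sequences.
#' @param min_identity identity floor (percent).
#' @return named character vector: names are ids in `set_a`, values ids in
#'   `set_b`.
#' @export
ortholog_map <- function(set_a, set_b, min_identity = 40) {
  idm <- matrix(0, length(set_a), length(set_b),
                dimnames = list(names(set_a), names(set_b)))
  for (i in seq_along(set_a)) {
    for (j in seq_along(set_b)) {
      idm[i, j] <- percent_identity(
        align_global(set_a[[i]], set_b[[j]], "protein"))
    }
  }
  best_ab <- apply(idm, 1L, which.max)
  best_ba <- apply(idm, 2L, which.max)
  keep <- vapply(seq_along(set_a), function(i) {
    j <- best_ab[i]
    best_ba[j] == i && idm[i, j] >= min_identity
  }, logical(1L))
  setNames(names(set_b)[best_ab], names(set_a))[keep]
}
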