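#' Disorder fraction and intrinsically disordered regions
#'
#' A residue is disordered iff its per-residue score is at least
#' `threshold`. The disorder fraction is the percent of disordered
#' residues; a protein is called highly disordered when the fraction
#' reaches 50%. Maximal disordered runs are reported as IDR intervals only
#' when they span at least `min_idr_len` residues.
#'
#' @param scores numeric vector of per-residue disorder scores in `[0, 1]`
#'   (one per residue).
#' @param threshold disorder call threshold (default 0.5, inclusive).
#' @param min_idr_len minimum reported IDR length (default 50 residues).
#' @return list with `fraction_pct`, `idr_intervals` (data.frame, 0-based
#'   half-open `start`/`end`), and `is_highly_disordered`.
#' @export
disorder_fraction <- function(scores, threshold = 0.5, min_idr_len = 50L) {
  if (length(scores) == 0L) stop("empty score vector")
  if (any(scores < 0 | scores > 1)) stop("disorder scores outside [0, 1]")
  dis <- scores >= threshold
  frac <- 100 * sum(dis) / length(dis)
  r <- rle(dis)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_idr_len
  iv <- data.frame(start = starts[keep] - 1L, end = ends[keep],
                   length = r$lengths[keep])
  list(fraction_pct = frac, idr_intervals = iv,
       is_highly_disordered = frac >= 50)
}

#' Read a per-residue disorder score table
#'
#' Two-column TSV: residue index (1-based) and score in `[0, 1]`.
#'
#' @param path TSV file.
#' @return numeric score vector ordered by residue index.
#' @export
read_disorder_scores <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("residue", "score"))
  tab <- tab[order(tab$residue), ]
  if (!identical(tab$residue, seq_len(nrow(tab)))) {
    stop("disorder table must cover residues 1..n without gaps")
  }
  tab$score
}

#' Detect intragenic tandem repeats by self-alignment periodicity
#'
#' For each candidate period u, the sequence is compared with itself
#' shifted by u residues; contiguous stretches of high shifted identity
#' define a repeat array of unit length u spanning the matched stretch plus
#' one trailing unit, so copy numbers can be fractional. Overlapping calls
#' are resolved in favour of the smallest period (multiples of a detected
#' period are suppressed), and within a period the maximal-scoring array is
#' kept.
#'
#' @param protein protein sequence (length-1 character).
#' @param min_unit,max_unit candidate unit lengths (residues).
#' @param min_copies minimum copy number for a call.
#' @param min_identity minimum mean unit identity (percent).
#' @return data.frame of calls: `unit_length`, `copies` (1 decimal),
#'   `start`, `end` (0-based half-open), `mean_unit_identity`.
#' @export
find_tandem_repeats <- function(protein, min_unit = 20L, max_unit = 120L,
                                min_copies = 2.0, min_identity = 60) {
  L <- nchar(protein)
  if (L < 2L * min_unit) {
    return(empty_repeat_calls())
  }
  s <- chars(protein)
  calls <- list()
  for (u in min_unit:min(max_unit, L %/% 2L)) {
    m <- s[seq_len(L - u)] == s[(u + 1L):L]   # match under shift u
    # pick the best run of shifted matches allowing isolated mismatches:
    # score +1 match, -1 mismatch, maximal-sum substring (Kadane)
    best <- max_scoring_run(ifelse(m, 1L, -1L))
    if (is.null(best)) next
    run <- m[best$start:best$end]
    ident <- 100 * sum(run) / length(run)
    span_len <- (best$end - best$start + 1L) + u
    copies <- span_len / u
    if (ident >= min_identity && copies >= min_copies) {
      calls[[length(calls) + 1L]] <- data.frame(
        unit_length = u, copies = round(copies, 1),
        start = best$start - 1L, end = best$start - 1L + span_len,
        mean_unit_identity = ident, score = best$score)
    }
  }
  if (!length(calls)) return(empty_repeat_calls())
  calls <- do.call(rbind, calls)
  # suppress exact multiples of a smaller detected period over the same span
  drop <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    for (j in seq_len(nrow(calls))) {
      if (i == j || drop[j]) next
      ov <- min(calls$end[i], calls$end[j]) - max(calls$start[i], calls$start[j])
      if (calls$unit_length[i] %% calls$unit_length[j] == 0L &&
          calls$unit_length[i] > calls$unit_length[j] &&
          ov >= 0.5 * (calls$end[i] - calls$start[i])) {
        drop[i] <- TRUE
        break
      }
    }
  }
  calls <- calls[!drop, , drop = FALSE]
  # then greedily keep maximal-scoring non-overlapping arrays
  calls <- calls[order(-calls$score, calls$unit_length), , drop = FALSE]
  kept <- calls[0L, ]
  for (i in seq_len(nrow(calls))) {
    ci <- calls[i, ]
    overlaps <- nrow(kept) > 0L &&
      any(ci$start < kept$end & kept$start < ci$end)
    if (!overlaps) kept <- rbind(kept, ci)
  }
  kept$score <- NULL
  kept <- kept[order(kept$start), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

empty_repeat_calls <- function() {
  data.frame(unit_length = integer(), copies = numeric(), start = integer(),
             end = integer(), mean_unit_identity = numeric())
}

# Maximal-sum contiguous run (Kadane); NULL when all entries negative.
max_scoring_run <- function(w) {
  best_sum <- 0L; best_start <- NA_integer_; best_end <- NA_integer_
  cur <- 0L; cur_start <- 1L
  for (i in seq_along(w)) {
    if (cur <= 0L) { cur <- 0L; cur_start <- i }
    cur <- cur + w[i]
    if (cur > best_sum) {
      best_sum <- cur; best_start <- cur_start; best_end <- i
    }
  }
  if (is.na(best_start)) return(NULL)
  # trim flanking mismatches inside the chosen window
  while (w[best_start] < 0L) best_start <- best_start + 1L
  while (w[best_end] < 0L) best_end <- best_end - 1L
  list(start = best_start, end = best_end, score = best_sum)
}

#' Residue-set composition of a protein or span
#'
#' Percent of residues belonging to `residue_set` (default: acidic residues
#' D and E plus serine), flagged when strictly above `flag_threshold`.
#'
#' @param protein protein sequence.
#' @param residue_set character vector of single-letter residues.
#' @param span optional `c(start, end)` 0-based half-open span to restrict
#'   the computation to (e.g. a repeat array).
#' @param flag_threshold percent threshold for flagging (strict).
#' @return list with `fraction_pct` and `flagged`.
#' @export
residue_composition <- function(protein, residue_set = c("D", "E", "S"),
                                span = NULL, flag_threshold = 40) {
  s <- chars(protein)
  if (!is.null(span)) {
    if (span[2L] <= span[1L]) stop("empty span")
    s <- s[(span[1L] + 1L):span[2L]]
  }
  if (length(s) == 0L) stop("empty span")
  frac <- 100 * sum(s %in% residue_set) / length(s)
  list(fraction_pct = frac, flagged = frac > flag_threshold)
}
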