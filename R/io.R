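#' @importFrom stats pnorm rexp runif rbinom sd setNames quantile as.dist
#' @importFrom utils head tail write.table read.table
NULL

NT_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X", "*")

#' Validate a named set of sequences
#'
#' Checks the invariants shared by all sequence collections in the package:
#' non-empty sequences, unique ids, and an alphabet consistent with the
#' declared molecule type (A/C/G/T/N for nucleotide; the 20 amino acids plus
#' X and `*` for protein).
#'
#' @param x named character vector of sequences.
#' @param moltype `"nucleotide"` or `"protein"`.
#' @return `x`, invisibly, after validation.
#' @keywords internal
validate_seqs <- function(x, moltype = c("nucleotide", "protein")) {
  moltype <- match.arg(moltype)
  if (length(x) == 0L) stop("empty sequence set")
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("all sequences must be named")
  }
  dup <- names(x)[duplicated(names(x))]
  if (length(dup)) stop("duplicate sequence id: ", dup[1L])
  if (any(!nzchar(x))) {
    stop("empty sequence for id: ", names(x)[!nzchar(x)][1L])
  }
  alpha <- if (moltype == "nucleotide") NT_ALPHABET else AA_ALPHABET
  bad <- vapply(x, function(s) {
    chars <- unique(strsplit(s, "", fixed = TRUE)[[1L]])
    any(!chars %in% alpha)
  }, logical(1L))
  if (any(bad)) {
    stop("sequence ", names(x)[bad][1L], " contains characters outside the ",
         moltype, " alphabet")
  }
  invisible(x)
}

#' Read a FASTA file
#'
#' Sequences are uppercased; in nucleotide mode U is converted to T.
#'
#' @param path FASTA file (plain or gzipped).
#' @param moltype `"nucleotide"` (default) or `"protein"`.
#' @return named character vector of sequences (one element per record).
#' @export
read_fasta <- function(path, moltype = c("nucleotide", "protein")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  x <- toupper(as.character(set))
  # headers: keep the first whitespace-delimited token as the id
  names(x) <- sub("\\s.*$", "", names(x))
  if (moltype == "nucleotide") x <- gsub("U", "T", x, fixed = TRUE)
  validate_seqs(x, moltype)
  x
}

#' Write sequences to FASTA
#'
#' @param x named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(length(x) > 0L, !is.null(names(x)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(paste0(">", names(x)[i]), con)
    s <- x[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' Reads plain or gzipped 4-line FASTQ. Qualities are decoded to integer
#' Phred scores. Phred+33 is the only supported encoding.
#'
#' @param path FASTQ file.
#' @return data.frame with columns `id`, `sequence`, and a list column
#'   `qualities` of integer vectors.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      qualities = I(list())))
  }
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: line count not a multiple of 4 in ", path)
  }
  ids <- lines[seq(1L, length(lines), by = 4L)]
  if (any(!startsWith(ids, "@"))) stop("malformed FASTQ header in ", path)
  ids <- sub("\\s.*$", "", sub("^@", "", ids))
  seqs <- toupper(lines[seq(2L, length(lines), by = 4L)])
  quals <- lines[seq(4L, length(lines), by = 4L)]
  bad <- nchar(seqs) != nchar(quals)
  if (any(bad)) {
    stop("malformed FASTQ record (sequence/quality length mismatch): ",
         ids[bad][1L])
  }
  qlist <- lapply(quals, function(q) utf8ToInt(q) - 33L)
  rng <- range(unlist(qlist, use.names = FALSE))
  if (rng[1L] < 0L || rng[2L] > 60L) {
    stop("Phred scores outside [0, 60]; only Phred+33 is supported")
  }
  data.frame(id = ids, sequence = seqs, qualities = I(qlist),
             stringsAsFactors = FALSE)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads data.frame as returned by [read_fastq()].
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  qstr <- vapply(reads$qualities, function(q) intToUtf8(q + 33L), character(1L))
  out <- rbind(paste0("@", reads$id), reads$sequence, "+", qstr)
  writeLines(as.vector(out), con)
  invisible(path)
}

#' Read genomic intervals from BED or GFF3
#'
#' Internal coordinates are 0-based half-open throughout the package; BED is
#' consumed as-is, GFF3 is converted from 1-based inclusive.
#'
#' @param path interval file.
#' @param dialect `"BED"` or `"GFF3"`.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand` (`+`, `-`, or `.`), and `name` where available.
#' @export
read_intervals <- function(path, dialect = c("BED", "GFF3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = if (dialect == "BED") "bed" else "gff3"),
    error = function(e) stop("coordinate error reading ", path, ": ",
                             conditionMessage(e))
  )
  iv <- data.frame(
    chrom  = as.character(GenomicRanges::seqnames(gr)),
    start  = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end    = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  iv$strand[iv$strand == "*"] <- "."
  nm <- if (!is.null(gr$name)) gr$name else if (!is.null(gr$ID)) gr$ID else NA_character_
  iv$name <- as.character(nm)
  if (any(iv$end <= iv$start)) {
    stop("coordinate error: end <= start after conversion in ", path)
  }
  iv
}

#' Write intervals as BED6
#'
#' @param iv interval data.frame (0-based half-open, as from
#'   [read_intervals()]).
#' @param path output path.
#' @export
write_bed <- function(iv, path) {
  stopifnot(all(iv$end > iv$start))
  bed <- data.frame(
    chrom = iv$chrom, start = iv$start, end = iv$end,
    name = if (!is.null(iv$name)) ifelse(is.na(iv$name), ".", iv$name) else ".",
    score = 0L,
    strand = ifelse(iv$strand %in% c("+", "-"), iv$strand, "."),
    stringsAsFactors = FALSE
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Render an interval 1-based inclusive for reports
#'
#' @param iv single-row interval data.frame.
#' @return character like `"chrX:21631001-22440000"`.
#' @export
format_interval <- function(iv) {
  sprintf("%s:%d-%d", iv$chrom, iv$start + 1L, iv$end)
}
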