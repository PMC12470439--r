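#' Tamura-Nei (TN93) distance between two aligned nucleotide sequences
#'
#' Closed-form TN93 distance separating the two transition classes (A<->G
#' and C<->T) from transversions, with base frequencies estimated as the
#' empirical means of the two sequences over gap-free paired columns.
#'
#' @param a,b aligned nucleotide strings of equal length (gaps `-` and N
#'   allowed; such columns are dropped pairwise).
#' @return non-negative distance (substitutions per site).
#' @export
tn93_distance <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  ca <- chars(a); cb <- chars(b)
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("no gap-free paired columns")
  ca <- ca[ok]; cb <- cb[ok]
  n <- length(ca)
  freq <- (table(factor(ca, levels = c("A", "C", "G", "T"))) +
           table(factor(cb, levels = c("A", "C", "G", "T")))) / (2 * n)
  pA <- freq[["A"]]; pC <- freq[["C"]]; pG <- freq[["G"]]; pT <- freq[["T"]]
  pR <- pA + pG; pY <- pC + pT

  diff <- ca != cb
  pair <- paste0(pmin(ca, cb), pmax(ca, cb))
  P1 <- sum(diff & pair == "AG") / n           # purine transitions
  P2 <- sum(diff & pair == "CT") / n           # pyrimidine transitions
  Q  <- sum(diff) / n - P1 - P2                # transversions

  k1 <- 2 * pA * pG / pR
  k2 <- 2 * pT * pC / pY
  k3 <- 2 * (pR * pY - pA * pG * pY / pR - pT * pC * pR / pY)
  w1 <- if (k1 > 0) 1 - P1 / k1 - Q / (2 * pR) else 1
  w2 <- if (k2 > 0) 1 - P2 / k2 - Q / (2 * pY) else 1
  w3 <- 1 - Q / (2 * pR * pY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) {
    stop("TN93 saturation: logarithm argument <= 0")
  }
  d <- -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
  max(d, 0)
}

#' TN93 distance matrix for a multiple alignment
#'
#' @param aln named character vector of equal-length gapped nucleotide rows.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
tn93_matrix <- function(aln) {
  n <- length(aln)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d[i, j] <- d[j, i] <- tn93_distance(aln[[i]], aln[[j]])
      }
    }
  }
  d
}
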