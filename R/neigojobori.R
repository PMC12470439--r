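# Codon-level machinery for the Nei-Gojobori estimator and the codon
# evolution simulator. All tables are built once per session and cached.

.codon_cache <- new.env(parent = emptyenv())

genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

translate_codon <- function(codon) {
  gc <- genetic_code()
  unname(gc[codon])
}

#' Per-codon synonymous site counts
#'
#' For each sense codon, the synonymous site count is the sum over the
#' three positions of the fraction of the three possible single-base
#' changes that are synonymous. Changes to stop codons count as
#' nonsynonymous, so synonymous + nonsynonymous sites = 3 for every codon.
#'
#' @return named numeric vector over the 61 sense codons.
#' @export
codon_syn_sites <- function() {
  if (!is.null(.codon_cache$syn_sites)) return(.codon_cache$syn_sites)
  gc <- genetic_code()
  bases <- c("A", "C", "G", "T")
  s <- setNames(numeric(length(sense_codons())), sense_codons())
  for (cd in sense_codons()) {
    aa <- gc[[cd]]
    cs <- chars(cd)
    syn <- 0
    for (p in 1:3) {
      for (b in setdiff(bases, cs[p])) {
        mut <- cs; mut[p] <- b
        mcd <- paste(mut, collapse = "")
        if (gc[[mcd]] == aa) syn <- syn + 1 / 3
      }
    }
    s[[cd]] <- syn
  }
  .codon_cache$syn_sites <- s
  s
}

#' Synonymous/nonsynonymous differences between two sense codons
#'
#' Averaged with equal weight over all shortest substitution pathways
#' between the codons. Pathways passing through a stop codon are excluded;
#' if every pathway does, all are used with stop-involving steps counted
#' as nonsynonymous. `sd + nd` always equals the codons' Hamming distance.
#'
#' @param c1,c2 sense codons (3-letter strings).
#' @return named numeric vector `c(sd, nd)`.
#' @export
codon_pair_diff <- function(c1, c2) {
  gc <- genetic_code()
  p <- which(chars(c1) != chars(c2))
  d <- length(p)
  if (d == 0L) return(c(sd = 0, nd = 0))
  perms <- permutations(p)
  paths <- lapply(perms, function(ord) {
    cur <- chars(c1)
    steps <- matrix(character(0), ncol = 2)
    codons <- character(0)
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- chars(c2)[pos]
      steps <- rbind(steps, c(paste(cur, collapse = ""), paste(nxt, collapse = "")))
      codons <- c(codons, paste(nxt, collapse = ""))
      cur <- nxt
    }
    list(steps = steps, intermediates = head(codons, -1L))
  })
  valid <- vapply(paths, function(pt) {
    !any(gc[pt$intermediates] == "*")
  }, logical(1L))
  if (any(valid)) paths <- paths[valid]
  counts <- vapply(paths, function(pt) {
    syn <- 0
    for (i in seq_len(nrow(pt$steps))) {
      a <- gc[[pt$steps[i, 1L]]]; b <- gc[[pt$steps[i, 2L]]]
      if (a != "*" && b != "*" && a == b) syn <- syn + 1
    }
    syn
  }, numeric(1L))
  sd <- mean(counts)
  c(sd = sd, nd = d - sd)
}

permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations(x[-i])) out <- c(out, list(c(x[i], rest)))
  }
  out
}

# 61 x 61 lookup tables of pathway-averaged synonymous (Sd) and
# nonsynonymous (Nd) differences.
codon_diff_tables <- function() {
  if (!is.null(.codon_cache$diff_sd)) {
    return(list(sd = .codon_cache$diff_sd, nd = .codon_cache$diff_nd))
  }
  sc <- sense_codons()
  n <- length(sc)
  sdm <- ndm <- matrix(0, n, n, dimnames = list(sc, sc))
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) next
      dd <- codon_pair_diff(sc[i], sc[j])
      sdm[i, j] <- sdm[j, i] <- dd[["sd"]]
      ndm[i, j] <- ndm[j, i] <- dd[["nd"]]
    }
  }
  .codon_cache$diff_sd <- sdm
  .codon_cache$diff_nd <- ndm
  list(sd = sdm, nd = ndm)
}

#' Nei-Gojobori estimate of synonymous and nonsynonymous divergence
#'
#' Computes per-site synonymous (dS) and nonsynonymous (dN) distances for a
#' codon-aligned sequence pair. Synonymous site counts enumerate all single
#' base changes per codon; multi-hit codons average differences with equal
#' weight over all shortest substitution pathways (pathways through stop
#' codons excluded). Proportions are Jukes-Cantor corrected,
#' \eqn{d = -3/4 \log(1 - 4p/3)}, with delta-method variances
#' \eqn{var = p(1-p) / (L (1 - 4p/3)^2)}. Codons containing a gap or N in
#' either row are removed pairwise (pairwise deletion), as are codons that
#' are stops in either row.
#'
#' @param a_cds,b_cds aligned coding sequences of equal length (gaps as
#'   `-`); length must be a multiple of 3.
#' @return list with `S_sites`, `N_sites`, `Sd`, `Nd`, `pS`, `pN`, `dS`,
#'   `dN`, `varS`, `varN`, and `codons_compared`.
#' @export
nei_gojobori <- function(a_cds, b_cds) {
  stopifnot(nchar(a_cds) == nchar(b_cds))
  if (nchar(a_cds) %% 3L != 0L) stop("aligned length is not a multiple of 3")
  n_cod <- nchar(a_cds) %/% 3L
  starts <- 3L * seq_len(n_cod) - 2L
  ca <- substring(a_cds, starts, starts + 2L)
  cb <- substring(b_cds, starts, starts + 2L)
  gc <- genetic_code()
  ok <- !grepl("[-N]", ca) & !grepl("[-N]", cb)
  ok[ok] <- gc[ca[ok]] != "*" & gc[cb[ok]] != "*"
  ca <- ca[ok]; cb <- cb[ok]
  if (length(ca) == 0L) stop("no comparable codons after pairwise deletion")

  ssites <- codon_syn_sites()
  S <- (sum(ssites[ca]) + sum(ssites[cb])) / 2
  N <- 3 * length(ca) - S
  tabs <- codon_diff_tables()
  idx <- cbind(match(ca, rownames(tabs$sd)), match(cb, colnames(tabs$sd)))
  Sd <- sum(tabs$sd[idx])
  Nd <- sum(tabs$nd[idx])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  if (pS >= 0.75 || pN >= 0.75) {
    stop("substitution proportion at or beyond saturation (p >= 0.75)")
  }
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  jc_var <- function(p, L) if (L > 0) p * (1 - p) / (L * (1 - 4 * p / 3)^2) else 0
  list(S_sites = S, N_sites = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       dS = jc(pS), dN = jc(pN), varS = jc_var(pS, S), varN = jc_var(pN, N),
       codons_compared = length(ca))
}

#' Codon-based Z-test of neutrality
#'
#' Tests dN - dS = 0 with \eqn{Z = (dN - dS) / \sqrt{var(dN) + var(dS)}}
#' against the standard normal. `neutral_two_sided` is the two-tailed test;
#' `purifying` is the lower tail (dN < dS); `positive` the upper tail.
#' Identical sequences have zero variance: the test is then undefined and
#' `Z`/`p` are returned as `NA` with `defined = FALSE` rather than an error.
#'
#' @param ng result of [nei_gojobori()].
#' @param alternative one of `"neutral_two_sided"`, `"purifying"`,
#'   `"positive"`.
#' @return list with `Z`, `p`, `alternative`, `defined`.
#' @export
z_test <- function(ng, alternative = c("neutral_two_sided", "purifying",
                                       "positive")) {
  alternative <- match.arg(alternative)
  v <- ng$varS + ng$varN
  if (!is.finite(v) || v <= 0) {
    return(list(Z = NA_real_, p = NA_real_, alternative = alternative,
                defined = FALSE))
  }
  Z <- (ng$dN - ng$dS) / sqrt(v)
  p <- switch(alternative,
              neutral_two_sided = 2 * pnorm(-abs(Z)),
              purifying = pnorm(Z),
              positive = pnorm(Z, lower.tail = FALSE))
  list(Z = Z, p = p, alternative = alternative, defined = TRUE)
}
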