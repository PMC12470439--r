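# Seeded generators emulating the study's data structures: codon evolution
# with duplication and gene conversion, genomes with repeat arrays embedded
# in transposon-like spacers, and small-RNA libraries with a tunable
# ping-pong (10-nt 5' overlap) bias. All randomness flows through R's RNG,
# so identical seeds give byte-identical outputs.

.evolver_cache <- new.env(parent = emptyenv())

# Neighbor/rate tables for the kappa/omega codon substitution process.
# Rates are normalized so that at omega = 1 each codon's total substitution
# rate is 3 (one per nucleotide site per unit branch length), with changes
# to stop codons rejected.
evolver_tables <- function(kappa, omega) {
  key <- paste(kappa, omega, sep = "_")
  if (!is.null(.evolver_cache[[key]])) return(.evolver_cache[[key]])
  gc <- genetic_code()
  sc <- sense_codons()
  bases <- c("A", "C", "G", "T")
  transitions <- c(AG = TRUE, GA = TRUE, CT = TRUE, TC = TRUE)
  n <- length(sc)
  NB <- matrix(NA_integer_, n, 9L)
  W <- W1 <- matrix(0, n, 9L)
  for (i in seq_len(n)) {
    cs <- chars(sc[i])
    col <- 0L
    for (p in 1:3) {
      for (b in setdiff(bases, cs[p])) {
        col <- col + 1L
        mut <- cs; mut[p] <- b
        mcd <- paste(mut, collapse = "")
        if (gc[[mcd]] == "*") next       # stop codons rejected
        ts <- isTRUE(transitions[paste0(cs[p], b)])
        syn <- gc[[mcd]] == gc[[sc[i]]]
        w1 <- if (ts) kappa else 1
        NB[i, col] <- match(mcd, sc)
        W1[i, col] <- w1
        W[i, col] <- w1 * if (syn) 1 else omega
      }
    }
  }
  Z <- rowSums(W1) / 3
  R <- rowSums(W) / Z
  P <- W / ifelse(rowSums(W) > 0, rowSums(W), 1)
  tab <- list(codons = sc, NB = NB, R = R, CUM = t(apply(P, 1L, cumsum)))
  .evolver_cache[[key]] <- tab
  tab
}

# Evolve a vector of codon indices for branch length t (expected
# substitutions per nucleotide site at neutrality). Returns the new state
# with the realized substitution count as attribute "n_subs".
evolve_codons <- function(state, t, kappa, omega) {
  tab <- evolver_tables(kappa, omega)
  n <- length(state)
  rem <- rep(t * 3, n)            # per-codon time budget against rate R
  active <- rep(TRUE, n)
  n_subs <- 0L
  while (any(active)) {
    i <- which(active)
    wait <- rexp(length(i), rate = tab$R[state[i]] / 3)
    # rate/3 against a 3t budget keeps unit branch length = 1 sub/nt site
    rem[i] <- rem[i] - wait
    done <- rem[i] <= 0
    active[i[done]] <- FALSE
    ev <- i[!done]
    if (length(ev)) {
      cp <- tab$CUM[state[ev], , drop = FALSE]
      r <- runif(length(ev))
      choice <- rowSums(cp < r) + 1L
      state[ev] <- tab$NB[cbind(state[ev], choice)]
      n_subs <- n_subs + length(ev)
    }
  }
  attr(state, "n_subs") <- n_subs
  state
}

#' Random coding sequence
#'
#' Uniformly random sense codons (no stops), optionally starting with ATG.
#'
#' @param n_codons number of codons.
#' @param start_atg begin with ATG?
#' @return nucleotide string of length `3 * n_codons`.
#' @export
random_cds <- function(n_codons, start_atg = TRUE) {
  sc <- sense_codons()
  cods <- sample(sc, n_codons, replace = TRUE)
  if (start_atg && n_codons >= 1L) cods[1L] <- "ATG"
  paste(cods, collapse = "")
}

#' Evolve a coding-sequence pair under a kappa/omega codon process
#'
#' A random ancestor is evolved independently down two lineages of length
#' `t_each` (expected neutral substitutions per nucleotide site), giving a
#' pair whose true dN/dS is `omega`. This is the calibration substrate for
#' the Z-test of neutrality.
#'
#' @param n_codons codons in the ancestor (default 300, a typical CDS).
#' @param t_each branch length per lineage; the default 0.05 gives a total
#'   pairwise divergence of ~0.1 substitutions/site, typical of sibling
#'   Drosophila species.
#' @param omega dN/dS of the process.
#' @param kappa transition/transversion rate ratio.
#' @param ancestor optional ancestral CDS (random if `NULL`).
#' @return list with `a`, `b` (nucleotide strings) and `ancestor`.
#' @export
evolve_pair <- function(n_codons = 300L, t_each = 0.05, omega = 1,
                        kappa = 2, ancestor = NULL) {
  tab <- evolver_tables(kappa, omega)
  if (is.null(ancestor)) ancestor <- random_cds(n_codons, start_atg = FALSE)
  starts <- 3L * seq_len(nchar(ancestor) %/% 3L) - 2L
  anc_idx <- match(substring(ancestor, starts, starts + 2L), tab$codons)
  if (anyNA(anc_idx)) stop("ancestor contains stop or invalid codons")
  a <- evolve_codons(anc_idx, t_each, kappa, omega)
  b <- evolve_codons(anc_idx, t_each, kappa, omega)
  list(a = paste(tab$codons[a], collapse = ""),
       b = paste(tab$codons[b], collapse = ""),
       ancestor = ancestor)
}

#' Simulate a gene family along a species tree
#'
#' Evolves an ancestral CDS along a (newick) species tree under the
#' kappa/omega codon process. Duplication events copy a gene at the top of
#' a stated branch; gene conversion homogenizes cluster members toward the
#' array consensus with a per-member per-branch probability, which at high
#' rates maintains the >99% intra-array identity characteristic of
#' recently amplified tandem copies.
#'
#' @param cfg list with elements: `tree` (newick string, branch lengths in
#'   substitutions/site), `n_codons`, `omega` (single value or named by
#'   child node/tip label), `kappa`, `duplications` (data.frame with
#'   columns `branch` (child node/tip label), `count`, `destination` in
#'   `adjacent|intron|cluster`), `conversion_rate`, `seed` (mandatory).
#' @return list with `sequences` (named character; ids `<tip>|<copy>`),
#'   `truth` (data.frame: tip, copy id, destination, cluster flag), and
#'   `tree` (the parsed [ape::phylo]).
#' @export
evolve_family <- function(cfg) {
  stopifnot(!is.null(cfg$seed))
  set.seed(cfg$seed)
  tr <- ape::read.tree(text = cfg$tree)
  if (is.null(tr$node.label)) {
    tr$node.label <- paste0("n", seq_len(tr$Nnode))
  }
  kappa <- if (is.null(cfg$kappa)) 2 else cfg$kappa
  omega_of <- function(label) {
    if (length(cfg$omega) > 1L && label %in% names(cfg$omega)) {
      cfg$omega[[label]]
    } else if (!is.null(cfg$omega)) cfg$omega[[1L]] else 1
  }
  dups <- cfg$duplications
  if (!is.null(dups)) {
    bad <- !dups$branch %in% c(tr$tip.label, tr$node.label)
    if (any(bad)) stop("duplication branch not in tree: ", dups$branch[bad][1L])
  }
  conv <- if (is.null(cfg$conversion_rate)) 0 else cfg$conversion_rate

  tab <- evolver_tables(kappa, 1)
  anc <- random_cds(cfg$n_codons)
  starts <- 3L * seq_len(cfg$n_codons) - 2L
  anc_idx <- match(substring(anc, starts, starts + 2L), tab$codons)

  ntip <- length(tr$tip.label)
  label_of <- function(node) {
    if (node <= ntip) tr$tip.label[node] else tr$node.label[node - ntip]
  }
  root <- ntip + 1L
  out_seqs <- character(0)
  truth <- list()

  recurse <- function(node, copies) {
    # copies: list of list(id, idx, destination, cluster)
    kids <- tr$edge[tr$edge[, 1L] == node, 2L]
    if (!length(kids)) {
      lab <- label_of(node)
      for (cp in copies) {
        out_seqs[[paste0(lab, "|", cp$id)]] <<-
          paste(tab$codons[cp$idx], collapse = "")
        truth[[length(truth) + 1L]] <<- data.frame(
          tip = lab, copy = cp$id, destination = cp$destination,
          cluster = cp$cluster, stringsAsFactors = FALSE)
      }
      return(invisible())
    }
    for (kid in kids) {
      lab <- label_of(kid)
      blen <- tr$edge.length[which(tr$edge[, 1L] == node & tr$edge[, 2L] == kid)]
      om <- omega_of(lab)
      cps <- copies
      if (!is.null(dups)) {
        for (d in which(dups$branch == lab)) {
          src <- cps[[length(cps)]]   # duplicate the newest copy
          for (ci in seq_len(dups$count[d])) {
            cps[[length(cps) + 1L]] <- list(
              id = paste0(src$id, ".", dups$destination[d], ci),
              idx = src$idx, destination = dups$destination[d],
              cluster = dups$destination[d] == "cluster")
          }
        }
      }
      cps <- lapply(cps, function(cp) {
        cp$idx <- as.integer(evolve_codons(cp$idx, blen, kappa, om))
        cp
      })
      in_cluster <- which(vapply(cps, function(cp) cp$cluster, logical(1L)))
      if (length(in_cluster) >= 2L && conv > 0) {
        mat <- do.call(rbind, lapply(cps[in_cluster], function(cp) cp$idx))
        consensus <- apply(mat, 2L, function(col) {
          tb <- table(col); as.integer(names(tb)[which.max(tb)])
        })
        for (ci in in_cluster) {
          if (runif(1L) < conv) cps[[ci]]$idx <- consensus
        }
      }
      recurse(kid, cps)
    }
  }
  recurse(root, list(list(id = "g1", idx = anc_idx, destination = "parental",
                          cluster = FALSE)))
  list(sequences = out_seqs, truth = do.call(rbind, truth), tree = tr,
       ancestor = anc)
}

#' Build a genome with an embedded tandem repeat array
#'
#' Lays out a single simulated chromosome: unique background sequence, a
#' focal region of `n_repeats` copies of the repeat CDS separated by
#' transposon-like spacers, and, outside the focal region, exact decoy
#' copies of every spacer. Reads drawn from a spacer therefore also map
#' outside the focal region, so only repeat-derived reads are locally
#' unique.
#'
#' @param cfg list with `n_repeats`, `repeat_cds` (nucleotide string),
#'   `spacer_len` (default 400), `background_len` (default 20000 per
#'   side), `mutation_rate` (per-base substitution probability applied
#'   independently to each repeat copy; the default 0.002 keeps pairwise
#'   intra-array identity above 99%, as in recently homogenized tandem
#'   arrays), and mandatory `seed`.
#' @return list with `genome` (named character, chromosome `chrSim`),
#'   `focal` (interval data.frame), and `truth` (list of interval
#'   data.frames: `repeats`, `spacers`, `decoys`).
#' @export
build_cluster_genome <- function(cfg) {
  stopifnot(!is.null(cfg$seed), cfg$n_repeats >= 1L)
  set.seed(cfg$seed)
  spacer_len <- if (is.null(cfg$spacer_len)) 400L else cfg$spacer_len
  bg_len <- if (is.null(cfg$background_len)) 20000L else cfg$background_len
  mu <- if (is.null(cfg$mutation_rate)) 0.002 else cfg$mutation_rate
  rep_seq <- cfg$repeat_cds
  rlen <- nchar(rep_seq)

  # transposon-like spacers: composition-matched shuffles of one AT-rich
  # base sequence; each spacer recurs verbatim as a decoy outside the focal
  base_tn <- random_dna(spacer_len, c(A = 0.35, C = 0.15, G = 0.15, T = 0.35))
  n_sp <- cfg$n_repeats + 1L
  spacers <- vapply(seq_len(n_sp), function(i) shuffle_seq(base_tn),
                    character(1L))

  mutate <- function(s) {
    if (mu <= 0) return(s)
    v <- chars(s)
    hit <- which(runif(length(v)) < mu)
    if (length(hit)) {
      v[hit] <- vapply(v[hit], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, character(1L))
    }
    paste(v, collapse = "")
  }
  copies <- vapply(seq_len(cfg$n_repeats), function(i) mutate(rep_seq),
                   character(1L))

  bg_left <- random_dna(bg_len)
  bg_right <- random_dna(bg_len)
  decoy_block <- paste(vapply(spacers, function(sp) {
    paste0(sp, random_dna(100L))
  }, character(1L)), collapse = "")

  focal_parts <- character(2L * cfg$n_repeats + 1L)
  focal_parts[1L] <- spacers[1L]
  for (i in seq_len(cfg$n_repeats)) {
    focal_parts[2L * i] <- copies[i]
    focal_parts[2L * i + 1L] <- spacers[i + 1L]
  }
  focal_seq <- paste(focal_parts, collapse = "")
  chrom <- paste0(bg_left, decoy_block, focal_seq, bg_right)
  focal_start <- nchar(bg_left) + nchar(decoy_block)
  focal <- data.frame(chrom = "chrSim", start = focal_start,
                      end = focal_start + nchar(focal_seq), strand = "+",
                      name = "focal")

  rep_starts <- focal_start + seq_len(cfg$n_repeats) * spacer_len +
    (seq_len(cfg$n_repeats) - 1L) * rlen
  truth <- list(
    repeats = data.frame(chrom = "chrSim", start = rep_starts,
                         end = rep_starts + rlen, strand = "+",
                         name = paste0("repeat", seq_len(cfg$n_repeats))),
    spacers = data.frame(chrom = "chrSim",
                         start = focal_start +
                           (seq_len(n_sp) - 1L) * (spacer_len + rlen),
                         end = focal_start +
                           (seq_len(n_sp) - 1L) * (spacer_len + rlen) +
                           spacer_len,
                         strand = "+", name = paste0("spacer", seq_len(n_sp))),
    decoys = data.frame(chrom = "chrSim",
                        start = nchar(bg_left) +
                          (seq_len(n_sp) - 1L) * (spacer_len + 100L),
                        end = nchar(bg_left) +
                          (seq_len(n_sp) - 1L) * (spacer_len + 100L) +
                          spacer_len,
                        strand = "+", name = paste0("decoy", seq_len(n_sp))))
  list(genome = setNames(chrom, "chrSim"), focal = focal, truth = truth)
}

#' Simulate a small-RNA library over a repeat cluster
#'
#' Sense reads are sampled uniformly over the focal repeats. In
#' `dual_strand` mode each sense read receives an antisense partner: with
#' probability `pingpong_bias` the partner's 5' end overlaps the sense 5'
#' end by exactly 10 nt (the ping-pong geometry), otherwise the partner is
#' placed uniformly. A `background_fraction` of reads is placed uniformly
#' outside the focal region. Read lengths are uniform on 23-30 nt and
#' per-base qualities are drawn high (Phred 33-40), so simulated reads
#' survive the standard length/quality filter.
#'
#' @param cfg list with `library_size` (total reads), `pingpong_bias` in
#'   `[0, 1]`, `strand_mode` (`"dual_strand"` or `"sense_only"`),
#'   `background_fraction`, and mandatory `seed`.
#' @param genome named character vector (from [build_cluster_genome()]).
#' @param focal focal interval data.frame.
#' @param repeats optional repeat interval data.frame (defaults to the
#'   whole focal region).
#' @return list with `reads` (FASTQ-style data.frame) and `truth`
#'   (data.frame: read id, origin start/end, strand, category).
#' @export
simulate_small_rna <- function(cfg, genome, focal, repeats = NULL) {
  stopifnot(!is.null(cfg$seed))
  p <- if (is.null(cfg$pingpong_bias)) 0 else cfg$pingpong_bias
  mode <- if (is.null(cfg$strand_mode)) "dual_strand" else cfg$strand_mode
  if (mode == "sense_only" && p > 0) {
    stop("pingpong_bias > 0 is inconsistent with sense_only mode")
  }
  bgf <- if (is.null(cfg$background_fraction)) 0 else cfg$background_fraction
  set.seed(cfg$seed)
  chrom <- genome[[focal$chrom[1L]]]
  clen <- nchar(chrom)
  if (is.null(repeats)) {
    repeats <- focal
  }
  n_total <- cfg$library_size
  n_bg <- round(bgf * n_total)
  n_f <- n_total - n_bg
  n_s <- if (mode == "sense_only") n_f else n_f %/% 2L

  draw_len <- function(n) sample(23:30, n, replace = TRUE)
  rand_in <- function(iv, len) {
    # uniform start such that the read fits inside one interval
    row <- iv[sample.int(nrow(iv), 1L), ]
    lo <- row$start
    hi <- row$end - len
    if (hi < lo) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
  }

  ids <- character(0); seqs <- character(0)
  truth <- list()
  emit <- function(start0, len, strand, category) {
    sq <- substr(chrom, start0 + 1L, start0 + len)
    if (strand == "-") sq <- revcomp(sq)
    i <- length(ids) + 1L
    ids[i] <<- sprintf("sim_r%05d", i)
    seqs[i] <<- sq
    truth[[i]] <<- data.frame(id = ids[i], start = start0,
                              end = start0 + len, strand = strand,
                              category = category, stringsAsFactors = FALSE)
  }

  for (i in seq_len(n_s)) {
    ls <- draw_len(1L)
    s0 <- rand_in(repeats, ls)
    emit(s0, ls, "+", "sense")
    if (mode == "dual_strand") {
      la <- draw_len(1L)
      if (runif(1L) < p) {
        a_end <- s0 + 9L              # antisense 5' end: 10-nt 5' overlap
        a0 <- a_end - la + 1L
        if (a0 >= 0L) emit(a0, la, "-", "antisense_pingpong")
      } else {
        a0 <- rand_in(repeats, la)
        emit(a0, la, "-", "antisense_uniform")
      }
    }
  }
  if (n_bg > 0L) {
    outside <- data.frame(start = c(0L, focal$end),
                          end = c(focal$start, clen))
    outside <- outside[outside$end - outside$start > 40L, , drop = FALSE]
    for (i in seq_len(n_bg)) {
      lb <- draw_len(1L)
      b0 <- rand_in(outside, lb)
      emit(b0, lb, sample(c("+", "-"), 1L), "background")
    }
  }
  quals <- lapply(nchar(seqs), function(n) sample(33:40, n, replace = TRUE))
  reads <- data.frame(id = ids, sequence = seqs, qualities = I(quals),
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = do.call(rbind, truth))
}
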