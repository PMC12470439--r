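test_that("codon-pair pathway counts match hand-worked cases", {
  # TTT|TTA: sites 0.5 synonymous of 3; the single difference is nonsynonymous
  ng <- nei_gojobori("TTT", "TTA")
  expect_equal(ng$S_sites, 0.5)
  expect_equal(ng$N_sites, 2.5)
  expect_equal(ng$Sd, 0)
  expect_equal(ng$Nd, 1)
  expect_equal(ng$pN, 0.4)

  expect_equal(unname(codon_pair_diff("GGA", "GGG")), c(1, 0))

  ident <- nei_gojobori("ATGAAA", "ATGAAA")
  expect_equal(ident$Sd, 0)
  expect_equal(ident$Nd, 0)
  expect_equal(ident$dS, 0)
  expect_equal(ident$dN, 0)
})

test_that("pathway-enumerated differences sum to the Hamming distance for all sense codon pairs", {
  sc <- dupscan:::sense_codons()
  ok <- TRUE
  worst <- NULL
  for (c1 in sc) {
    for (c2 in sc) {
      dd <- codon_pair_diff(c1, c2)
      if (abs(sum(dd) - hamming(c1, c2)) > 1e-9) {
        ok <- FALSE
        worst <- c(c1, c2)
      }
    }
  }
  expect_true(ok, label = paste("Sd+Nd == Hamming for", paste(worst, collapse = "|")))
})

test_that("site counts always sum to three per codon and the estimator is symmetric", {
  ss <- codon_syn_sites()
  expect_length(ss, 61L)
  expect_true(all(ss >= 0 & ss < 3))
  set.seed(21)
  for (rep in 1:5) {
    pr <- evolve_pair(n_codons = 100, t_each = 0.08)
    ab <- nei_gojobori(pr$a, pr$b)
    ba <- nei_gojobori(pr$b, pr$a)
    expect_equal(ab$dN, ba$dN)
    expect_equal(ab$dS, ba$dS)
    expect_equal(ab$S_sites + ab$N_sites, 3 * ab$codons_compared,
                 tolerance = 1e-9)
  }
})

test_that("pairwise deletion drops codons with gaps or N in either row", {
  a <- "ATG---AAATTT"
  b <- "ATGCCCAANTTT"
  ng <- nei_gojobori(a, b)
  expect_identical(ng$codons_compared, 2L)   # ATG and TTT only
})

test_that("the Z-test returns zero for equal rates and flags identical pairs", {
  ng <- list(dN = 0.1, dS = 0.1, varN = 2e-4, varS = 3e-4)
  zt <- z_test(ng)
  expect_equal(zt$Z, 0)
  expect_equal(zt$p, 1)

  same <- nei_gojobori("ATGGCA", "ATGGCA")
  und <- z_test(same)
  expect_false(und$defined)
  expect_true(is.na(und$Z))
})

test_that("codon-aware trimming removes long non-conserved stretches and short blocks", {
  cons_block <- function(n) strrep("ATGGCAGAT", ceiling(n / 9))
  mk_aln <- function(mid_rows) {
    left <- substr(cons_block(30), 1, 30)
    right <- substr(cons_block(30), 1, 30)
    vapply(mid_rows, function(m) paste0(left, m, right), character(1))
  }
  # a 9-codon stretch where the three rows disagree at every column
  mid <- c(strrep("A", 27), strrep("C", 27), strrep("G", 27))
  aln <- setNames(mk_aln(mid), c("r1", "r2", "r3"))
  tr <- gblocks_trim(aln)
  expect_identical(unname(nchar(tr)), rep(60L, 3))
  expect_identical(as.character(substr(tr, 1, 30)),
                   as.character(substr(aln, 1, 30)))

  # a fully conserved alignment is returned unchanged
  full <- setNames(rep(cons_block(27), 3), c("a", "b", "c"))
  expect_identical(as.character(gblocks_trim(full)), as.character(full))

  # a conserved island of 9 columns between removed regions is also removed
  island <- substr(cons_block(9), 1, 9)
  letters3 <- c("A", "C", "G")
  rows <- setNames(vapply(1:3, function(i) {
    paste0(substr(cons_block(12), 1, 12),
           strrep(letters3[i], 30), island, strrep(letters3[i], 30),
           substr(cons_block(12), 1, 12))
  }, character(1)), c("a", "b", "c"))
  # rows share the conserved flanks and the island; the 30-column stretches differ
  tr2 <- gblocks_trim(rows)
  expect_identical(unname(nchar(tr2)), rep(24L, 3))
})

test_that("trimmed alignments never violate the run-length or block-length rules", {
  set.seed(24)
  for (rep in 1:8) {
    n_rows <- sample(3:6, 1)
    n_cod <- 60
    base <- random_cds(n_cod, FALSE)
    rows <- vapply(seq_len(n_rows), function(i) {
      v <- dupscan:::chars(base)
      flip <- runif(length(v)) < 0.25
      v[flip] <- sample(c("A", "C", "G", "T"), sum(flip), replace = TRUE)
      paste(v, collapse = "")
    }, character(1))
    names(rows) <- paste0("t", seq_len(n_rows))
    tr <- try(gblocks_trim(rows), silent = TRUE)
    if (inherits(tr, "try-error")) next   # everything trimmed: acceptable
    kept <- attr(tr, "kept_columns")
    cons <- attr(tr, "conserved")[kept]
    r <- rle(!cons)
    expect_true(all(r$lengths[r$values] <= 8))
    block_lens <- table(cumsum(c(1, diff(kept) != 1)))
    expect_true(all(block_lens >= 10))
    expect_true(all(nchar(tr) %% 3 == 0))
  }
})

test_that("TN93 distance matches ape and dominates the p-distance", {
  expect_equal(tn93_distance("ACGTACGT", "ACGTACGT"), 0)
  set.seed(25)
  for (rep in 1:6) {
    pr <- evolve_pair(n_codons = 400, t_each = 0.05)
    mine <- tn93_distance(pr$a, pr$b)
    bin <- ape::as.DNAbin(matrix(c(strsplit(tolower(pr$a), "")[[1]],
                                   strsplit(tolower(pr$b), "")[[1]]),
                                 nrow = 2, byrow = TRUE,
                                 dimnames = list(c("a", "b"), NULL)))
    ref <- ape::dist.dna(bin, model = "TN93")[1]
    expect_equal(mine, ref, tolerance = 1e-9)
    pdist <- hamming(pr$a, pr$b) / nchar(pr$a)
    expect_gte(mine, pdist)
  }
})

test_that("transversion-only divergence at equal base frequencies reduces to the K2P transversion term", {
  # A<->C and G<->T swaps are transversions and preserve base frequencies
  set.seed(26)
  n <- 4000
  v <- sample(rep(c("A", "C", "G", "T"), n / 4))   # exactly equal counts
  a <- paste(v, collapse = "")
  m <- 120                                          # balanced swaps keep
  w <- v                                            # frequencies exact
  swap_pairs <- list(c("A", "C"), c("C", "A"), c("G", "T"), c("T", "G"))
  for (sp in swap_pairs) {
    at <- sample(which(v == sp[1]), m)
    w[at] <- sp[2]
  }
  d <- tn93_distance(a, paste(w, collapse = ""))
  q <- mean(v != w)
  k2p_tv <- -0.5 * log(1 - q) - 0.25 * log(1 - 2 * q)
  expect_equal(d, k2p_tv, tolerance = 1e-9)
})

test_that("neighbor joining recovers additive matrices exactly and stars give zero internal branches", {
  # additive 4-taxon matrix from a known tree ((A:1,B:2):1,(C:3,D:4):1);
  labs <- c("A", "B", "C", "D")
  D <- matrix(0, 4, 4, dimnames = list(labs, labs))
  D["A", "B"] <- D["B", "A"] <- 3
  D["A", "C"] <- D["C", "A"] <- 6
  D["A", "D"] <- D["D", "A"] <- 7
  D["B", "C"] <- D["C", "B"] <- 7
  D["B", "D"] <- D["D", "B"] <- 8
  D["C", "D"] <- D["D", "C"] <- 7
  tr <- nj_tree(D)
  ref <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(ref))), 0)
  pd <- ape::cophenetic.phylo(tr)[labs, labs]
  expect_equal(pd, D, tolerance = 1e-9)

  star <- matrix(2, 4, 4, dimnames = list(labs, labs))
  diag(star) <- 0
  st <- nj_tree(star)
  internal <- st$edge[, 2] > length(st$tip.label)
  expect_true(all(abs(st$edge.length[internal]) < 1e-12))

  expect_error(nj_tree(matrix(c(0, NA, NA, 0), 2, 2)), "finite|3")
})

test_that("bootstrap supports are reproducible, permutation-invariant, and flag degenerate input", {
  set.seed(27)
  fam <- evolve_family(list(
    tree = "((A:0.06,B:0.06):0.06,(C:0.06,D:0.06):0.06);",
    n_codons = 400, omega = 1, seed = 301))
  aln <- fam$sequences
  names(aln) <- sub("\\|g1$", "", names(aln))
  t1 <- bootstrap_support(aln, n_reps = 50, seed = 9)
  t2 <- bootstrap_support(aln, n_reps = 50, seed = 9)
  expect_identical(t1$node.label, t2$node.label)

  perm <- aln[c(3, 1, 4, 2)]
  t3 <- bootstrap_support(perm, n_reps = 50, seed = 9)
  b1 <- sort(unlist(lapply(ape::prop.part(t1), function(p) {
    paste(sort(t1$tip.label[p]), collapse = ",")
  })))
  b3 <- sort(unlist(lapply(ape::prop.part(t3), function(p) {
    paste(sort(t3$tip.label[p]), collapse = ",")
  })))
  expect_identical(b1, b3)

  same <- setNames(rep(strrep("ATGGCA", 20), 4), c("w", "x", "y", "z"))
  deg <- bootstrap_support(same, n_reps = 10, seed = 1)
  expect_true(attr(deg, "degenerate"))
  expect_true(all(is.na(deg$node.label)))

  expect_error(bootstrap_support(aln, n_reps = 0), "n_reps")
})
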