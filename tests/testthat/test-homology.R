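test_that("global alignment handles identity, single-gap, and disjoint pairs", {
  a1 <- align_global("ACGT", "ACGT")
  expect_identical(a1$a_gapped, "ACGT")
  expect_identical(a1$b_gapped, "ACGT")
  expect_equal(a1$score, 4)

  a2 <- align_global("ACGT", "AGT")
  expect_identical(nchar(a2$a_gapped), nchar(a2$b_gapped))
  expect_identical(sum(strsplit(a2$b_gapped, "")[[1]] == "-"), 1L)
  expect_false(grepl("-", a2$a_gapped, fixed = TRUE))

  a3 <- align_global("AAAA", "TTTT")
  cols <- cbind(strsplit(a3$a_gapped, "")[[1]], strsplit(a3$b_gapped, "")[[1]])
  gapless <- cols[, 1] != "-" & cols[, 2] != "-"
  expect_identical(sum(cols[gapless, 1] == cols[gapless, 2]), 0L)

  expect_error(align_global("ACGT", "MKV"), "moltype")
})

test_that("alignment score equals the exhaustive-search optimum on short pairs", {
  set.seed(11)
  for (rep in 1:25) {
    a <- random_dna(sample(2:6, 1))
    b <- random_dna(sample(2:6, 1))
    got <- align_global(a, b)$score
    expect_equal(got, oracle_nw_score(a, b), label = paste(a, b))
  }
})

test_that("percent identity follows the gap-excluded column formula", {
  self <- align_global("ACGTACGT", "ACGTACGT")
  expect_equal(percent_identity(self), 100)
  expect_equal(percent_identity(list(a_gapped = "AC-GT", b_gapped = "ACAGT")),
               100)
  expect_equal(percent_identity(list(a_gapped = "ACGT", b_gapped = "AGGT")),
               75)
  expect_error(percent_identity(list(a_gapped = "--", b_gapped = "AC")),
               "undefined")
})

test_that("percent identity is symmetric and invariant to a shared suffix", {
  set.seed(12)
  for (rep in 1:10) {
    a <- random_dna(40)
    b <- random_dna(40)
    ab <- align_global(a, b)
    ba <- align_global(b, a)
    expect_equal(percent_identity(ab), percent_identity(ba))
    sfx <- random_dna(20)
    ext <- list(a_gapped = paste0(ab$a_gapped, sfx),
                b_gapped = paste0(ab$b_gapped, sfx))
    base_cols <- sum(strsplit(ab$a_gapped, "")[[1]] != "-" &
                     strsplit(ab$b_gapped, "")[[1]] != "-")
    base_match <- percent_identity(ab) * base_cols / 100
    expect_equal(percent_identity(ext),
                 100 * (base_match + 20) / (base_cols + 20))
  }
})

test_that("identity matrices are symmetric with 100 on the diagonal and a minimal unrelated control", {
  set.seed(13)
  fam <- random_cds(60)
  cds <- c(g1 = fam, g2 = fam,
           g3 = paste0(substr(fam, 1, 150), random_cds(10, start_atg = FALSE)),
           ctrl = random_cds(60, start_atg = FALSE))
  prot <- vapply(cds, translate_cds, character(1))
  im <- identity_matrix(cds, prot)
  expect_true(isSymmetric(im$nt_identity))
  expect_true(all(diag(im$nt_identity) == 100))
  expect_equal(im$nt_identity["g1", "g2"], 100)
  # the unrelated control has the lowest mean off-diagonal identity
  offmean <- rowMeans(im$nt_identity) - 100 / nrow(im$nt_identity)
  expect_identical(names(which.min(offmean)), "ctrl")
  expect_error(identity_matrix(cds, prot[1:2]), "label")
})

test_that("homolog scan counts planted copies and respects the identity floor", {
  set.seed(14)
  q <- random_cds(150)
  g <- build_cluster_genome(list(n_repeats = 5, repeat_cds = q,
                                 mutation_rate = 0, seed = 99))
  h <- homolog_scan(g$genome[[1]], q, min_identity_pct = 95)
  expect_identical(nrow(h), 5L)
  expect_identical(sort(h$start), sort(g$truth$repeats$start))

  empty <- homolog_scan(random_dna(5000), q, min_identity_pct = 80)
  expect_identical(nrow(empty), 0L)

  # one copy mutated at a known 10% of sites
  qv <- strsplit(q, "")[[1]]
  idx <- sample(length(qv), round(0.1 * length(qv)))
  qv[idx] <- vapply(qv[idx], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                    character(1))
  mut <- paste(qv, collapse = "")
  genome2 <- paste0(random_dna(2000), mut, random_dna(2000))
  expect_identical(nrow(homolog_scan(genome2, q, min_identity_pct = 95)), 0L)
  expect_identical(nrow(homolog_scan(genome2, q, min_identity_pct = 85)), 1L)

  expect_error(homolog_scan(genome2, "ACGT", k = 11), "shorter")
})

test_that("homolog scan finds reverse-strand copies", {
  set.seed(15)
  q <- random_cds(120)
  genome <- paste0(random_dna(1500), revcomp(q), random_dna(1500))
  h <- homolog_scan(genome, q, min_identity_pct = 95)
  expect_identical(nrow(h), 1L)
  expect_identical(h$strand, "-")
  expect_identical(h$start, 1500L)
})

test_that("dotplot equals brute-force k-mer intersection and shows expected diagonals", {
  set.seed(16)
  a <- random_dna(80)
  d_self <- dotplot(a, a, k = 10)
  diag_pts <- d_self[d_self$strand == "+" & d_self$a_pos == d_self$b_pos, ]
  expect_identical(nrow(diag_pts), nchar(a) - 10L + 1L)

  d_rc <- dotplot(a, revcomp(a), k = 10)
  minus <- d_rc[d_rc$strand == "-", ]
  expect_true(all(minus$b_pos == nchar(a) - 10 - minus$a_pos))

  for (rep in 1:5) {
    x <- random_dna(60)
    y <- if (rep %% 2) paste0(substr(x, 11, 40), random_dna(30)) else random_dna(60)
    got <- dotplot(x, y, k = 8)
    want <- oracle_dotplot(x, y, 8)
    ord <- function(d) d[order(d$a_pos, d$b_pos, d$strand), ]
    expect_equal(unname(as.matrix(ord(got))), unname(as.matrix(ord(want))))
  }
})

test_that("flanking homology fraction and the >15% synteny rule behave as specified", {
  mk <- function(up, down, sp = "melA") {
    gene_locus("g", sp, "chrX", 100, 200, flank_up = up, flank_down = down)
  }
  a <- mk(c("a1", "a2", "a3"), c("a4", "a5", "a6"))
  b <- mk(c("b1", "b2", "b3"), c("b4", "b5", "b6"), "melB")
  full <- setNames(paste0("b", 1:6), paste0("a", 1:6))
  expect_equal(flanking_homology(a, b, full), 1)
  expect_true(classify_syntenic(flanking_homology(a, b, full)))

  none <- setNames(paste0("z", 1:6), paste0("a", 1:6))
  expect_equal(flanking_homology(a, b, none), 0)
  expect_false(classify_syntenic(0))

  one <- c(a1 = "b1")
  expect_equal(flanking_homology(a, b, one), 1 / 6, tolerance = 1e-12)
  expect_true(classify_syntenic(1 / 6))
  expect_false(classify_syntenic(0.15))   # strict inequality

  e1 <- mk(character(), character())
  e2 <- mk(character(), character(), "melB")
  expect_error(flanking_homology(e1, e2, full), "undefined")
})

test_that("reciprocal-best ortholog mapping pairs matching proteins only", {
  set.seed(17)
  pa <- c(x1 = "MKVLLEDAARNDWQS", x2 = "GGHHPPLLKKTTRRE")
  pb <- c(y1 = "MKVLLEDAARNDWQS", y2 = "WWYYFFCCMMIIVVA")
  om <- ortholog_map(pa, pb, min_identity = 40)
  expect_identical(om[["x1"]], "y1")
  expect_false("x2" %in% names(om))
})
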