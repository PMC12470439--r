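test_that("length/quality filtering applies inclusive length bounds and a strict mean-quality cutoff", {
  set.seed(31)
  reads <- rbind(
    make_reads(random_dna(22), q = 40, ids = "short"),
    make_reads(random_dna(26), q = 40, ids = "good"),
    make_reads(random_dna(30), q = 40, ids = "edge_len"),
    make_reads(random_dna(31), q = 40, ids = "long"),
    make_reads(random_dna(26), q = 30, ids = "edge_q"),
    make_reads(random_dna(26), q = 20, ids = "lowq"))
  kept <- filter_reads(reads)
  expect_identical(kept$id, c("good", "edge_len"))
  expect_identical(attr(kept, "n_dropped"), 4L)
})

test_that("contaminant removal drops reads within one mismatch of a structural RNA", {
  set.seed(32)
  trna <- random_dna(90)
  clean <- random_dna(26)
  sub <- substr(trna, 10, 35)
  v <- strsplit(sub, "")[[1]]
  v[13] <- setdiff(c("A", "C", "G", "T"), v[13])[1]
  one_mm <- paste(v, collapse = "")
  v[20] <- setdiff(c("A", "C", "G", "T"), v[20])[1]
  two_mm <- paste(v, collapse = "")
  reads <- make_reads(c(sub, one_mm, two_mm, clean, revcomp(sub)),
                      ids = c("exact", "mm1", "mm2", "clean", "rc"))
  out <- remove_structural(reads, c(tRNA1 = trna))
  expect_identical(sort(out$id), sort(c("mm2", "clean")))
  expect_warning(remove_structural(reads, character(0)), "empty")
})

test_that("read mapping finds planted hits on both strands under the mismatch bound", {
  set.seed(33)
  ref <- random_dna(4000)
  r0 <- substr(ref, 101, 126)
  h <- map_reads(setNames(r0, "fwd"), ref, max_mismatches = 0)
  expect_identical(h$start, 100L)
  expect_identical(h$strand, "+")
  expect_identical(h$mismatches, 0L)

  hrc <- map_reads(setNames(revcomp(r0), "rev"), ref, max_mismatches = 0)
  expect_identical(hrc$start, 100L)
  expect_identical(hrc$strand, "-")

  v <- strsplit(r0, "")[[1]]
  v[7] <- setdiff(c("A", "C", "G", "T"), v[7])[1]
  r1 <- paste(v, collapse = "")
  expect_identical(nrow(map_reads(setNames(r1, "x"), ref, max_mismatches = 0)), 0L)
  h1 <- map_reads(setNames(r1, "x"), ref, max_mismatches = 1)
  expect_identical(h1$start, 100L)
  expect_identical(h1$mismatches, 1L)
})

test_that("read mapping equals the brute-force sliding-window oracle", {
  set.seed(34)
  ref <- random_dna(6000)
  reads <- character(60)
  for (i in 1:60) {
    L <- sample(23:30, 1)
    if (i <= 40) {
      p <- sample(nchar(ref) - L, 1)
      s <- substr(ref, p, p + L - 1)
      v <- strsplit(s, "")[[1]]
      nmut <- sample(0:2, 1)
      if (nmut > 0) {
        at <- sample(L, nmut)
        v[at] <- vapply(v[at], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }, character(1))
      }
      s <- paste(v, collapse = "")
      if (i > 20) s <- revcomp(s)
      reads[i] <- s
    } else {
      reads[i] <- random_dna(L)
    }
  }
  names(reads) <- paste0("r", 1:60)
  for (mm in 0:2) {
    got <- map_reads(reads, setNames(ref, "ref"), max_mismatches = mm)
    for (id in names(reads)) {
      want <- oracle_map(reads[[id]], ref, mm)
      g <- got[got$read_id == id, c("start", "strand", "mismatches")]
      g <- g[order(g$start, g$strand), ]
      w <- want[order(want$start, want$strand), ]
      expect_equal(unname(as.matrix(g)),
                   unname(as.matrix(w[, c("start", "strand", "mm")])),
                   label = paste(id, "mm", mm))
    }
  }
})

test_that("locally unique attribution returns exactly the planted focal-only reads", {
  set.seed(35)
  q <- random_cds(200)
  cl <- build_cluster_genome(list(n_repeats = 6, repeat_cds = q,
                                  mutation_rate = 0.005, seed = 404))
  sim <- simulate_small_rna(list(library_size = 300, pingpong_bias = 0.5,
                                 background_fraction = 0.3, seed = 405),
                            cl$genome, cl$focal, cl$truth$repeats)
  lu <- locally_unique(sim$reads, cl$genome, cl$focal)
  focal_ids <- sim$truth$id[sim$truth$category != "background"]
  expect_setequal(unique(lu$read_id), focal_ids)

  # a read planted both inside and outside the focal region is excluded:
  # spacer-derived reads match their decoy copies
  sp <- cl$truth$spacers[1, ]
  sp_read <- substr(cl$genome[[1]], sp$start + 50 + 1, sp$start + 50 + 26)
  lu2 <- locally_unique(make_reads(sp_read, ids = "spacer_read"),
                        cl$genome, cl$focal)
  expect_identical(nrow(lu2), 0L)

  bad_focal <- data.frame(chrom = "chrMissing", start = 0L, end = 10L)
  expect_error(locally_unique(sim$reads, cl$genome, bad_focal), "chromosome")
})

test_that("stratified counts place planted reads in minimal-mismatch strata with rpm scaling", {
  set.seed(36)
  tx <- random_cds(300)
  plant <- function(n, nmut, rc = FALSE) {
    vapply(seq_len(n), function(i) {
      L <- sample(23:30, 1)
      p <- sample(nchar(tx) - L, 1)
      s <- substr(tx, p, p + L - 1)
      v <- strsplit(s, "")[[1]]
      if (nmut > 0) {
        at <- sample(L, nmut)
        v[at] <- vapply(v[at], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }, character(1))
      }
      s <- paste(v, collapse = "")
      if (rc) revcomp(s) else s
    }, character(1))
  }
  reads <- make_reads(c(plant(5, 0), plant(3, 1), plant(2, 2), plant(4, 0, rc = TRUE)))
  sc <- stratified_counts(reads, tx, library_denominator = 1e6)
  expect_identical(sc$sense_count[sc$stratum == "0"], 5L)
  expect_identical(sc$sense_count[sc$stratum == "1"], 3L)
  expect_identical(sc$sense_count[sc$stratum == "2"], 2L)
  expect_identical(sc$antisense_count[sc$stratum == "0"], 4L)
  expect_identical(sc$sense_count[sc$stratum == "0-2"], 10L)
  expect_equal(sc$sense_rpm, sc$sense_count * 1.0)

  sc2 <- stratified_counts(reads, tx, library_denominator = 5e5)
  expect_equal(sc2$sense_rpm, sc$sense_rpm * 2)
})

test_that("coverage accumulates per covered position and conserves total hit length", {
  hits <- data.frame(read_id = c("a", "b", "c"), ref = "r",
                     start = c(0L, 10L, 10L), strand = c("+", "-", "-"),
                     mismatches = 0L, read_len = c(25L, 24L, 24L))
  cov <- coverage_profile(hits, 100L)
  expect_identical(cov$sense[1:25], rep(1L, 25))
  expect_identical(sum(cov$sense), 25L)
  expect_identical(cov$antisense[11:34], rep(2L, 24))
  expect_identical(sum(cov$sense) + sum(cov$antisense), sum(hits$read_len))

  none <- coverage_profile(hits[0, ], 50L)
  expect_identical(sum(none$sense) + sum(none$antisense), 0L)

  bad <- hits
  bad$start[1] <- 90L
  expect_error(coverage_profile(bad, 100L), "outside")
})

test_that("ping-pong counting matches the all-pairs oracle and flags undefined backgrounds", {
  set.seed(37)
  sense <- data.frame(start = sample(0:500, 80, replace = TRUE),
                      read_len = sample(23:30, 80, replace = TRUE))
  anti <- data.frame(start = sample(0:500, 70, replace = TRUE),
                     read_len = sample(23:30, 70, replace = TRUE))
  pp <- pingpong(sense, anti)
  expect_equal(pp$overlap_counts, oracle_pingpong_counts(sense, anti))
  expect_equal(pp$pairs_at_10, unname(pp$overlap_counts[10]))

  # degenerate: every antisense 5' end exactly 10 nt into its sense partner
  s2 <- data.frame(start = seq(0, 900, by = 100), read_len = 26L)
  a2 <- data.frame(start = s2$start + 9 - 25, read_len = 26L)
  pp2 <- pingpong(s2, a2)
  expect_false(pp2$defined)
  expect_true(is.na(pp2$z10))
  expect_identical(unname(pp2$pairs_at_10), 10)
  expect_true(all(pp2$overlap_counts[-10] == 0))
})
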