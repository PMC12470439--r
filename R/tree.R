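#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor-joining via [ape::nj()], rooted on the stated
#' outgroup. NJ is consistent on additive matrices, so an additive input
#' recovers the generating topology and branch lengths exactly.
#'
#' @param D symmetric distance matrix with labelled rows/columns.
#' @param outgroup leaf label to root on (optional).
#' @return an [ape::phylo] tree.
#' @export
nj_tree <- function(D, outgroup = NULL) {
  stopifnot(is.matrix(D), nrow(D) >= 3L)
  if (any(!is.finite(D))) stop("non-finite distances")
  tr <- ape::nj(as.dist(D))
  if (!is.null(outgroup)) {
    if (!outgroup %in% tr$tip.label) stop("outgroup not among taxa: ", outgroup)
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
  tr
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Builds the NJ tree from TN93 distances on the full alignment, then
#' resamples alignment codons (triplets resampled as units) `n_reps` times,
#' rebuilds the NJ tree from each replicate, and reports for each internal
#' edge the percentage of replicates containing that bipartition. Supports
#' are stored in `$node.label`. An alignment of identical rows yields a
#' degenerate star-like tree: supports are then `NA` and the result carries
#' `degenerate = TRUE`.
#'
#' @param aln named character vector of equal-length gapped nucleotide rows
#'   (length a multiple of 3).
#' @param n_reps number of bootstrap replicates.
#' @param outgroup leaf label to root on (optional).
#' @param seed integer seed; replicates are reproducible for a given seed.
#' @return an [ape::phylo] tree with percent supports in `node.label` and
#'   attributes `n_reps` and `degenerate`.
#' @export
bootstrap_support <- function(aln, n_reps = 500L, outgroup = NULL,
                              seed = 1L) {
  if (n_reps < 1L) stop("n_reps must be at least 1")
  L <- unique(nchar(aln))
  stopifnot(length(L) == 1L)
  if (L %% 3L != 0L) stop("aligned length is not a multiple of 3")
  n_cod <- L %/% 3L
  D <- tn93_matrix(aln)
  if (all(D == 0)) {
    tr <- nj_tree(D + 1e-12, outgroup = NULL)  # shape only
    tr$edge.length[] <- 0
    tr$node.label <- rep(NA_real_, tr$Nnode)
    attr(tr, "degenerate") <- TRUE
    attr(tr, "n_reps") <- n_reps
    return(tr)
  }
  tr <- nj_tree(D)

  set.seed(seed)
  starts <- 3L * seq_len(n_cod) - 2L
  codons <- lapply(aln, function(s) substring(s, starts, starts + 2L))
  boots <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(n_cod, n_cod, replace = TRUE)
    rep_aln <- vapply(codons, function(cs) paste(cs[idx], collapse = ""),
                      character(1L))
    Dr <- tn93_matrix(rep_aln)
    boots[[r]] <- ape::nj(as.dist(Dr))
  }
  counts <- ape::prop.clades(tr, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  tr$node.label <- round(100 * counts / n_reps, 1)
  if (!is.null(outgroup)) {
    if (!outgroup %in% tr$tip.label) stop("outgroup not among taxa: ", outgroup)
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE,
                    edgelabel = TRUE)
  }
  attr(tr, "degenerate") <- FALSE
  attr(tr, "n_reps") <- n_reps
  tr
}

#' Write a tree to newick with supports as internal node labels
#'
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
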