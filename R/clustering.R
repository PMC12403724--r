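# Sister-stwintron clustering: pairwise identity, near-identical cluster
# calling (>97% identity, i.e. at most 5 SNPs on a 185-nt pair), and a
# neighbor-joining tree on 1 - identity exported as Newick.

#' Fraction identity of two sequences under global alignment
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap open 0,
#' gap extend -2 by default) followed by
#' identity = matched columns / alignment columns, gap columns included in
#' the denominator. On equal-length near-identical pairs this coincides with
#' 1 - SNPs/length, so 5 substitutions on 185 nt give 180/185 > 0.97 and 6
#' give < 0.97.
#'
#' @param a,b non-empty nucleotide strings.
#' @param match,mismatch,gap_extend alignment scores (gap opening is free).
#' @return identity fraction in [0, 1].
#' @export
pairwise_identity <- function(a, b, match = 1, mismatch = -1, gap_extend = -2) {
  a <- as_dna(a); b <- as_dna(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch)
  al <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = sm,
                                      gapOpening = 0,
                                      gapExtension = -gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  sum(pa == pb & pa != "-") / length(pa)
}

#' All-against-all identity matrix
#'
#' @param seqs named character vector (or DNAStringSet) of sequences; names
#'   become matrix dimnames.
#' @param ... passed to [pairwise_identity()].
#' @return symmetric numeric matrix with unit diagonal, of class
#'   `identity_matrix`.
#' @export
identity_matrix <- function(seqs, ...) {
  ids <- names(seqs)
  seqs <- as.character(seqs)
  n <- length(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  mat <- diag(1, n)
  dimnames(mat) <- list(ids, ids)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        mat[i, j] <- mat[j, i] <- pairwise_identity(seqs[i], seqs[j], ...)
      }
    }
  }
  class(mat) <- c("identity_matrix", class(mat))
  mat
}

#' Call clusters of near-identical sequences
#'
#' Single-linkage connected components over edges with identity strictly
#' greater than the threshold; only clusters of two or more members are
#' reported. The default threshold 0.97 encodes the near-identical
#' criterion: >97% identity, i.e. not more than five SNPs on a ~185-nt
#' stwintron.
#'
#' @param mat an [identity_matrix()] (or any symmetric identity matrix with
#'   dimnames).
#' @param threshold identity threshold; edges require identity > threshold
#'   (strict).
#' @return list of character vectors of member ids, largest first; ids
#'   sorted within each cluster. Empty list when no pair exceeds the
#'   threshold.
#' @export
near_identical_clusters <- function(mat, threshold = 0.97) {
  n <- nrow(mat)
  ids <- rownames(mat)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && mat[i, j] > threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  comps <- split(ids, roots)
  comps <- comps[vapply(comps, length, 0L) >= 2L]
  comps <- lapply(comps, sort)
  comps <- unname(comps[order(-vapply(comps, length, 0L),
                              vapply(comps, `[`, "", 1L))])
  comps
}

#' Neighbor-joining tree over an identity matrix, as Newick
#'
#' Distances are 1 - identity; the tree is inferred by neighbor joining and
#' serialised as a Newick string. Negative branch lengths, an artefact NJ
#' can produce, are clamped to zero and flagged via the
#' `clamped_negative_branches` attribute.
#'
#' @param mat an [identity_matrix()] over at least 3 sequences.
#' @return Newick string (with attribute `clamped_negative_branches`).
#' @export
nj_tree <- function(mat) {
  if (nrow(mat) < 3L) stop("at least 3 sequences are required")
  d <- stats::as.dist(1 - unclass(mat))
  tr <- ape::nj(d)
  clamped <- sum(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  nwk <- ape::write.tree(tr)
  attr(nwk, "clamped_negative_branches") <- clamped
  nwk
}

#' Drop sparsely occupied columns from a multiple sequence alignment
#'
#' Removes alignment columns occupied (non-gap) in fewer than
#' `min_occupancy` sequences, the usual trim of gappy regions before
#' multi-way identity computation.
#'
#' @param aln character vector of equal-length gapped sequences.
#' @param min_occupancy minimal number of non-gap characters for a column to
#'   be kept (default 3: columns occupied in only one or two sequences are
#'   removed).
#' @return character vector of trimmed gapped sequences.
#' @export
filter_msa_columns <- function(aln, min_occupancy = 3L) {
  aln <- toupper(aln)
  L <- unique(nchar(aln))
  if (length(L) != 1L) stop("aligned sequences have unequal lengths")
  m <- do.call(rbind, strsplit(aln, ""))
  occ <- colSums(m != "-")
  keep <- occ >= min_occupancy
  apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
}
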