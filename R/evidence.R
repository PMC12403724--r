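# Junction-read classification: the computational analog of verifying
# stwintron excision, the splinter intermediate, and missplicing with
# expression reads.

# Does `read` support `query` across its junction? Alignment-free sliding
# Hamming comparison: consider every ungapped offset of the read against the
# query; the overlap must cover the fusion point with >= min_overhang nt on
# both sides and contain at most max_mismatches mismatches.
.junction_support <- function(read, query, fusion_pos, max_mismatches,
                              min_overhang) {
  lr <- nchar(read); lq <- nchar(query)
  rc <- strsplit(read, "")[[1]]
  qc <- strsplit(query, "")[[1]]
  # offset o: read position 1 sits at query position o + 1
  for (o in seq(-(lr - 1L), lq - 1L)) {
    q_from <- max(1L, o + 1L)
    q_to <- min(lq, o + lr)
    if (q_to - q_from + 1L < 2L * min_overhang) next
    # junction lies between query positions fusion_pos and fusion_pos + 1
    if (q_from > fusion_pos - min_overhang + 1L) next
    if (q_to < fusion_pos + min_overhang) next
    r_from <- q_from - o
    mism <- sum(rc[seq(r_from, r_from + (q_to - q_from))] !=
                  qc[seq(q_from, q_to)])
    if (mism <= max_mismatches) return(TRUE)
  }
  FALSE
}

#' Classify junction-spanning reads against a query set
#'
#' A read supports product kind k when it matches a window of query k across
#' the fusion point, covering it with at least `min_overhang` nt on both
#' sides, within `max_mismatches` substitutions (ungapped comparison: reads
#' with indels simply fail, mirroring a perfect/near-perfect matching
#' criterion). Both read orientations are tried, so reverse-complemented
#' reads classify identically. Reads matching queries of more than one kind
#' are counted as `ambiguous`; reads matching none as `unassigned`.
#'
#' @param reads character vector or DNAStringSet of reads (>= 20 nt each).
#' @param queries a `junction_queries` data.frame from
#'   [make_junction_queries()] (columns `kind`, `query`, `fusion_pos`),
#'   all from one stwintron locus.
#' @param max_mismatches maximal substitutions within the matched window
#'   (default 1, "near-perfect").
#' @param min_overhang minimal read coverage of each side of the fusion
#'   point (default 8 nt).
#' @return list with `counts` (named integer vector over the query kinds
#'   plus `ambiguous` and `unassigned`) and `assignments` (data.frame:
#'   `read`, `kind`).
#' @export
classify_reads <- function(reads, queries, max_mismatches = 1L,
                           min_overhang = 8L) {
  reads <- as.character(reads)
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  reads_dna <- as_dna(reads)
  kinds <- queries$kind
  assigned <- character(length(reads))
  for (i in seq_along(reads_dna)) {
    r <- reads_dna[[i]]
    hits <- character(0)
    for (k in seq_along(kinds)) {
      q <- as_dna(queries$query[k])
      if (.junction_support(r, q, queries$fusion_pos[k], max_mismatches,
                            min_overhang) ||
          .junction_support(revcomp(r), q, queries$fusion_pos[k],
                            max_mismatches, min_overhang)) {
        hits <- c(hits, kinds[k])
      }
    }
    assigned[i] <- if (length(hits) == 0L) "unassigned"
                   else if (length(hits) > 1L) "ambiguous"
                   else hits
  }
  levels <- c(kinds, "ambiguous", "unassigned")
  counts <- table(factor(assigned, levels = levels))
  list(counts = stats::setNames(as.integer(counts), levels),
       assignments = data.frame(read = names(reads), kind = assigned,
                                stringsAsFactors = FALSE))
}

#' Summarise read support for one stwintron locus
#'
#' Presence/absence flags only: read counts are deliberately not compared
#' across loci or kinds (library depth makes such comparisons meaningless).
#'
#' @param counts named integer vector from [classify_reads()].
#' @return list of flags: `stwintron_confirmed` (>= 1 mature read),
#'   `splinter_confirmed`, `missplice_observed`, plus `pre_mrna_only`.
#' @export
locus_verdict <- function(counts) {
  g <- function(k) if (k %in% names(counts)) counts[[k]] else 0L
  list(stwintron_confirmed = g("mature") >= 1L,
       splinter_confirmed = g("splinter") >= 1L,
       missplice_observed = g("misspliced") >= 1L,
       pre_mrna_only = g("mature") == 0L && g("splinter") == 0L &&
         g("misspliced") == 0L && g("pre_mRNA") >= 1L)
}
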