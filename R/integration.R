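# Integration-site checks: target-site duplication and flanking-dinucleotide
# bias against the random-integration null.

#' Search for a target-site duplication at a stwintron insertion site
#'
#' A DNA-transposon-style insertion leaves a short direct repeat: one copy
#' ending at the 5' boundary, one beginning at the 3' boundary. This scans
#' for the longest exact such repeat between `min_len` and `max_len` nt.
#'
#' @param flank5 exonic sequence ending at the 5' boundary.
#' @param flank3 exonic sequence beginning at the 3' boundary. Both flanks
#'   must be at least `max_len` nt.
#' @param min_len,max_len repeat length window (defaults 3-10).
#' @return list with `length` and `seq` for the longest repeat found, or
#'   `NULL` when there is none of at least `min_len`.
#' @export
check_tsd <- function(flank5, flank3, min_len = 3L, max_len = 10L) {
  f5 <- as_dna(flank5); f3 <- as_dna(flank3)
  if (nchar(f5) < max_len || nchar(f3) < max_len) {
    stop("flanks must be at least max_len (", max_len, ") nt")
  }
  for (k in seq(as.integer(max_len), as.integer(min_len))) {
    tail5 <- substr(f5, nchar(f5) - k + 1L, nchar(f5))
    head3 <- substr(f3, 1L, k)
    if (tail5 == head3) return(list(length = k, seq = tail5))
  }
  NULL
}

#' Flanking-dinucleotide bias of stwintron insertion sites
#'
#' Tests whether 5' exons ending in AG, and 3' exons starting with GU, occur
#' more often than expected if integration sites were random. Under the
#' uniform null each specific dinucleotide occurs in one of every 16 cases;
#' a composition-adjusted null (product of observed mononucleotide
#' frequencies across the flank set) is available as an option. Two-sided
#' exact binomial p-values.
#'
#' @param records data.frame with columns `flank5` and `flank3` (one row per
#'   stwintron), or a list of length-2 character vectors.
#' @param null `"uniform"` (expected frequency exactly 1/16) or
#'   `"composition"`.
#' @return list: `n`, `ag_count`, `gt_count`, observed frequencies, expected
#'   frequency and count per dinucleotide, and p-values `p_ag`, `p_gt`.
#' @export
flank_dinucleotide_bias <- function(records, null = c("uniform", "composition")) {
  null <- match.arg(null)
  if (is.data.frame(records)) {
    f5 <- as_dna(records$flank5); f3 <- as_dna(records$flank3)
  } else {
    f5 <- as_dna(vapply(records, `[[`, "", 1L))
    f3 <- as_dna(vapply(records, `[[`, "", 2L))
  }
  n <- length(f5)
  if (n < 1L) stop("at least one record is required")
  ag <- sum(substr(f5, nchar(f5) - 1L, nchar(f5)) == "AG")
  gt <- sum(substr(f3, 1L, 2L) == "GT")
  if (null == "uniform") {
    exp_ag <- exp_gt <- 1 / 16
  } else {
    comp <- table(factor(strsplit(paste(c(f5, f3), collapse = ""), "")[[1]],
                         levels = c("A", "C", "G", "T")))
    p <- as.numeric(comp) / sum(comp)
    names(p) <- c("A", "C", "G", "T")
    exp_ag <- p[["A"]] * p[["G"]]
    exp_gt <- p[["G"]] * p[["T"]]
  }
  list(n = n,
       ag_count = ag, ag_freq = ag / n,
       gt_count = gt, gt_freq = gt / n,
       expected_freq_ag = exp_ag, expected_freq_gt = exp_gt,
       expected_count_ag = n * exp_ag, expected_count_gt = n * exp_gt,
       p_ag = stats::binom.test(ag, n, exp_ag)$p.value,
       p_gt = stats::binom.test(gt, n, exp_gt)$p.value)
}
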