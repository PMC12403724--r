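# IUPAC splice-site consensus motifs and matching primitives.
#
# Internal canonical alphabet is DNA: RNA input (U) is transliterated to T on
# read, and reports can render RNA on request via as_rna().

#' IUPAC nucleotide classes
#'
#' Named list mapping each IUPAC code to the set of concrete DNA bases it
#' covers. `N` in a *window* never matches any class (conservative handling of
#' assembly gaps); `N` as a *pattern* character covers A/C/G/T.
#' @keywords internal
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Canonicalise a nucleotide string to DNA
#'
#' Uppercases and transliterates U to T. U and T are interchangeable on input
#' throughout the package.
#'
#' @param x character vector of nucleotide strings (DNA or RNA).
#' @return character vector in DNA alphabet.
#' @export
as_dna <- function(x) {
  chartr("uU", "tT", toupper(x))
}

#' Render a nucleotide string as RNA
#'
#' @param x character vector of nucleotide strings.
#' @return character vector with T replaced by U.
#' @export
as_rna <- function(x) {
  chartr("tT", "uU", toupper(x))
}

.check_nt <- function(s, what = "sequence", allow_n = TRUE) {
  ok <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(ok, s)
  if (any(bad)) {
    stop(what, " contains invalid characters: ",
         paste(unique(strsplit(gsub("[ACGTN]", "", s[bad][1]), "")[[1]]),
               collapse = ", "))
  }
  invisible(s)
}

.check_iupac <- function(pattern) {
  p <- as_dna(pattern)
  chars <- strsplit(p, "")[[1]]
  bad <- setdiff(chars, names(.IUPAC))
  if (length(bad)) {
    stop("invalid IUPAC code(s) in pattern '", pattern, "': ",
         paste(bad, collapse = ", "))
  }
  p
}

#' Splice-site consensus motif set
#'
#' Bundles the degenerate splice-site consensus sequences used by the
#' nested-intron grammar: 5' donor hexamers, the branch element (containing
#' the branch-point adenosine) and the 3' acceptor triplet. Defaults are the
#' fungal U2 consensus GURWGY (plus the rare GC-initiated variant GCRWGY for
#' internal introns), RYURAY with the branch A at 0-based offset 4, and the
#' acceptor HAG (a superset of YAG; strict YAG can be requested).
#'
#' @param donor_patterns character vector of length-6 IUPAC donor patterns.
#'   All must start with G.
#' @param branch_pattern length-6 IUPAC branch-element pattern.
#' @param branch_a_offset 0-based offset of the branch adenosine within
#'   `branch_pattern`; the IUPAC class at that offset must include A.
#' @param acceptor_pattern length-3 IUPAC acceptor pattern.
#' @param internal_allow_gc should GC-initiated donors be allowed for
#'   internal introns? (The GC variant is restricted to internal introns by
#'   default; set `external_allow_gc` to widen.)
#' @param external_allow_gc allow GC-initiated donors for external introns.
#' @return an object of class `motif_set`.
#' @examples
#' m <- motif_set()
#' iupac_match(m$donor_patterns[1], "GTATGT")
#' @export
motif_set <- function(donor_patterns = c("GURWGY", "GCRWGY"),
                      branch_pattern = "RYURAY",
                      branch_a_offset = 4L,
                      acceptor_pattern = "HAG",
                      internal_allow_gc = TRUE,
                      external_allow_gc = FALSE) {
  donor_patterns <- vapply(donor_patterns, .check_iupac, "", USE.NAMES = FALSE)
  branch_pattern <- .check_iupac(branch_pattern)
  acceptor_pattern <- .check_iupac(acceptor_pattern)
  if (any(nchar(donor_patterns) != 6L)) stop("donor patterns must be 6 nt")
  if (nchar(branch_pattern) != 6L) stop("branch pattern must be 6 nt")
  if (nchar(acceptor_pattern) != 3L) stop("acceptor pattern must be 3 nt")
  if (any(substr(donor_patterns, 1L, 1L) != "G")) {
    stop("all donor patterns must start with G")
  }
  branch_a_offset <- as.integer(branch_a_offset)
  if (branch_a_offset < 0L || branch_a_offset > 5L) {
    stop("branch_a_offset must lie in 0..5")
  }
  a_class <- .IUPAC[[substr(branch_pattern, branch_a_offset + 1L,
                            branch_a_offset + 1L)]]
  if (!"A" %in% a_class) {
    stop("branch_a_offset must point at a position whose IUPAC class includes A")
  }
  structure(
    list(donor_patterns = donor_patterns,
         branch_pattern = branch_pattern,
         branch_a_offset = branch_a_offset,
         acceptor_pattern = acceptor_pattern,
         internal_allow_gc = internal_allow_gc,
         external_allow_gc = external_allow_gc),
    class = "motif_set"
  )
}

#' @export
print.motif_set <- function(x, ...) {
  cat("Splice consensus motif set\n")
  cat("  donors:  ", paste(as_rna(x$donor_patterns), collapse = ", "), "\n")
  cat("  branch:  ", as_rna(x$branch_pattern),
      " (branch A at 0-based offset ", x$branch_a_offset, ")\n", sep = "")
  cat("  acceptor:", as_rna(x$acceptor_pattern), "\n")
  invisible(x)
}

#' Donor patterns applicable to one intron level
#' @keywords internal
.donors_for <- function(motifs, level = c("internal", "external")) {
  level <- match.arg(level)
  allow_gc <- if (level == "internal") motifs$internal_allow_gc else motifs$external_allow_gc
  pats <- motifs$donor_patterns
  if (!allow_gc) pats <- pats[substr(pats, 2L, 2L) != "C"]
  pats
}

#' Match a window against a degenerate IUPAC pattern
#'
#' Strict per-position class membership: position i of `window` must be a
#' member of the IUPAC class at position i of `pattern`. `N` in the window
#' never matches (assembly gaps are treated as unknowable). U and T are
#' interchangeable in both arguments.
#'
#' @param pattern IUPAC string.
#' @param window concrete nucleotide string over A/C/G/T/U/N, same length as
#'   `pattern`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' iupac_match("GURWGY", "GTATGT")  # TRUE: the core internal donor
#' iupac_match("YAG", "CAG")        # TRUE
#' @export
iupac_match <- function(pattern, window) {
  p <- .check_iupac(pattern)
  w <- as_dna(window)
  .check_nt(w, "window")
  if (nchar(p) != nchar(w)) {
    stop("pattern and window lengths differ (", nchar(p), " vs ", nchar(w), ")")
  }
  pc <- strsplit(p, "")[[1]]
  wc <- strsplit(w, "")[[1]]
  all(mapply(function(cls, ch) ch %in% .IUPAC[[cls]], pc, wc))
}

#' Find all occurrences of an IUPAC motif in a sequence
#'
#' Exhaustive overlapping scan; returns all 1-based start positions in
#' ascending order. Implemented as a vectorised shift-and-AND over
#' per-position class membership, so genome-scale sequences are fine.
#'
#' @param seq nucleotide string (non-empty).
#' @param pattern IUPAC string.
#' @return integer vector of 1-based start positions (possibly empty).
#' @examples
#' find_motif_sites("CAGCAG", "YAG")  # 1, 4
#' @export
find_motif_sites <- function(seq, pattern) {
  if (!nzchar(seq)) stop("seq must be non-empty")
  p <- .check_iupac(pattern)
  s <- as_dna(seq)
  .check_nt(s, "seq")
  L <- nchar(s)
  k <- nchar(p)
  if (k > L) return(integer(0))
  chars <- strsplit(s, "")[[1]]
  pc <- strsplit(p, "")[[1]]
  n_starts <- L - k + 1L
  ok <- rep(TRUE, n_starts)
  for (j in seq_len(k)) {
    member <- chars[j:(j + n_starts - 1L)] %in% .IUPAC[[pc[j]]]
    ok <- ok & member
  }
  which(ok)
}
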