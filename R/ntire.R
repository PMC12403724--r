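# Near-terminal inverted repeat elements (NTIRE-9/10), branch-to-acceptor
# layout, and terminal-symmetry alignment of a sequence against its own
# reverse complement.

# Pair classification for two bases on antiparallel strands (DNA storage:
# the GU wobble classes are G.T and T.G).
.pair_class <- function(a, b) {
  key <- paste0(a, b)
  if (key %in% c("AT", "TA", "GC", "CG")) "WC"
  else if (key %in% c("GT", "TG")) "GU"
  else "mismatch"
}

#' Classify antiparallel pairing of two inverted-repeat elements
#'
#' Position i of the 5' element is paired with position L-i+1 of the 3'
#' element (antiparallel). Watson-Crick pairs are A:U and G:C; G:U wobble
#' pairs also count as paired. The complementarity fraction is
#' (WC + GU) / L.
#'
#' @param e5,e3 equal-length RNA or DNA strings, length 9 or 10 for the
#'   canonical NTIRE elements (other equal lengths are accepted for general
#'   use).
#' @param five_offset,three_gap_to_acceptor optional position annotations
#'   carried through to the record.
#' @return an object of class `ntire_pair` with fields `five_elem`,
#'   `three_elem`, `pair_classes` (per-position, in 5' element order),
#'   `complementarity_fraction`, `fully_complementary`.
#' @examples
#' pairing_classes("GUAUAAAAAC", "GUUUUUAUGU")$complementarity_fraction  # 1
#' @export
pairing_classes <- function(e5, e3, five_offset = NA_integer_,
                            three_gap_to_acceptor = NA_integer_) {
  a <- as_dna(e5); b <- as_dna(e3)
  .check_nt(a, "e5", allow_n = FALSE); .check_nt(b, "e3", allow_n = FALSE)
  L <- nchar(a)
  if (nchar(b) != L) {
    stop("element lengths differ (", L, " vs ", nchar(b), ")")
  }
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  cls <- vapply(seq_len(L), function(i) .pair_class(ac[i], bc[L - i + 1L]), "")
  frac <- mean(cls != "mismatch")
  structure(
    list(five_elem = as_rna(a), three_elem = as_rna(b),
         five_offset = as.integer(five_offset),
         three_gap_to_acceptor = as.integer(three_gap_to_acceptor),
         pair_classes = cls,
         complementarity_fraction = frac,
         fully_complementary = frac == 1),
    class = "ntire_pair"
  )
}

#' @export
print.ntire_pair <- function(x, ...) {
  cat(sprintf("NTIRE pair (%d nt): 5'-%s / 5'-%s\n",
              nchar(x$five_elem), x$five_elem, x$three_elem))
  cat(sprintf("  paired %.0f%% (%d WC, %d GU wobble, %d mismatch)\n",
              100 * x$complementarity_fraction,
              sum(x$pair_classes == "WC"), sum(x$pair_classes == "GU"),
              sum(x$pair_classes == "mismatch")))
  invisible(x)
}

#' Scan a stwintron for NTIRE-9/10 inverted-repeat pairs
#'
#' Searches for a 5' element starting within `near_terminal_limit` nt of the
#' stwintron's 5' terminal G and a 3' element lying strictly between the
#' external branch element and the acceptor, such that the two elements pair
#' antiparallel with complementarity (Watson-Crick + GU wobble) at or above
#' `threshold`. Pairs are ranked by complementarity fraction, then element
#' length (10 before 9), then 5' offset. The 3' region between branch
#' element and acceptor is often too short to contain a full element, in
#' which case the result is empty.
#'
#' @param stw a `stwintron_model`.
#' @param lengths element lengths to consider (default 10 then 9).
#' @param near_terminal_limit maximal offset (nt) of the 5' element start
#'   from the stwintron 5' end; default 5.
#' @param threshold minimal complementarity fraction to report; default 1
#'   (fully complementary), 0.8 is a reasonable partial-pair setting.
#' @return list of `ntire_pair` records (possibly empty).
#' @export
scan_ntire <- function(stw, lengths = c(10L, 9L), near_terminal_limit = 5L,
                       threshold = 1.0) {
  s <- as_dna(stw$seq)
  # 3' search region, stwintron-relative: strictly between the external
  # branch element and the acceptor
  br_end_rel <- stw$external$branch_start + 5L - stw$start + 1L
  acc_rel <- stw$external$acceptor_start - stw$start + 1L
  region_start <- br_end_rel + 1L
  region_end <- acc_rel - 1L
  out <- list()
  for (len in as.integer(lengths)) {
    if (region_end - region_start + 1L < len) next
    for (off in 0:as.integer(near_terminal_limit)) {
      if (off + len > nchar(s)) next
      e5 <- substr(s, off + 1L, off + len)
      for (ts in region_start:(region_end - len + 1L)) {
        e3 <- substr(s, ts, ts + len - 1L)
        pr <- pairing_classes(e5, e3, five_offset = off,
                              three_gap_to_acceptor = acc_rel - (ts + len - 1L) - 1L)
        if (pr$complementarity_fraction >= threshold) {
          out[[length(out) + 1L]] <- pr
        }
      }
    }
  }
  if (!length(out)) return(out)
  frac <- vapply(out, `[[`, 0, "complementarity_fraction")
  len <- vapply(out, function(p) nchar(p$five_elem), 0L)
  off <- vapply(out, `[[`, 0L, "five_offset")
  out[order(-frac, -len, off)]
}

#' Decompose the branch-to-acceptor distance into the NTIRE layout
#'
#' The distance between the external intron's branch element and its 3'
#' acceptor decomposes, when a 3' NTIRE is present, as
#' spacer5 + element + spacer3. The two recurring layouts are 2+10+2 = 14 nt
#' and 7+10+2 = 19 nt.
#'
#' @param ext an `intron_model` (external intron) with located branch
#'   element and acceptor, or a single integer giving the raw
#'   branch-to-acceptor distance.
#' @param ntire optionally an `ntire_pair` from [scan_ntire()]; its length
#'   and gap-to-acceptor annotation place the element. `NULL` (or element
#'   length 0) means no NTIRE: the total is the raw distance.
#' @return list with `spacer5`, `element_len`, `spacer3`, `total`; `total`
#'   always equals the branch-to-acceptor distance.
#' @export
bp_acceptor_layout <- function(ext, ntire = NULL) {
  dist <- if (is.numeric(ext)) as.integer(ext) else ext$bp_to_acceptor_distance
  if (is.null(ntire)) {
    return(list(spacer5 = 0L, element_len = 0L, spacer3 = dist, total = dist))
  }
  len <- nchar(ntire$three_elem)
  spacer3 <- ntire$three_gap_to_acceptor
  if (is.na(spacer3)) stop("ntire pair lacks a gap-to-acceptor annotation")
  spacer5 <- dist - len - spacer3
  if (spacer5 < 0L) {
    stop("NTIRE element does not fit the branch-to-acceptor distance")
  }
  list(spacer5 = as.integer(spacer5), element_len = as.integer(len),
       spacer3 = as.integer(spacer3), total = dist)
}

# Needleman-Wunsch over character vectors; returns the two gapped strings.
# Deterministic tie-break: diagonal, then up (gap in b), then left.
.nw_align <- function(a, b, match = 1, mismatch = 0, gap = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  sc <- matrix(0, n + 1L, m + 1L)
  sc[, 1] <- gap * (0:n)
  sc[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(bv == av[i], match, mismatch)
    for (j in seq_len(m)) {
      sc[i + 1L, j + 1L] <- max(sc[i, j] + sub[j],
                                sc[i, j + 1L] + gap,
                                sc[i + 1L, j] + gap)
    }
  }
  # traceback
  i <- n; j <- m; ra <- character(0); rb <- character(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        sc[i + 1L, j + 1L] == sc[i, j] + ifelse(av[i] == bv[j], match, mismatch)) {
      ra <- c(av[i], ra); rb <- c(bv[j], rb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && sc[i + 1L, j + 1L] == sc[i, j + 1L] + gap) {
      ra <- c(av[i], ra); rb <- c("-", rb); i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(bv[j], rb); j <- j - 1L
    }
  }
  list(a = paste(ra, collapse = ""), b = paste(rb, collapse = ""),
       score = sc[n + 1L, m + 1L])
}

# Consensus symbol for one alignment column of seq vs revcomp(seq):
# '*' identity (a Watson-Crick self-pair of the underlying positions),
# '#' GU equivalence (G aligned to A, or T aligned to C), ' ' otherwise.
.consensus_symbol <- function(a, b) {
  if (a == "-" || b == "-") return(" ")
  if (a == b) return("*")
  key <- paste0(a, b)
  if (key %in% c("GA", "AG", "TC", "CT")) "#" else " "
}

#' Align a sequence with its own reverse complement (terminal symmetry)
#'
#' Global alignment of S against revcomp(S), rendered with the diagnostic
#' consensus line: `*` marks nucleotide identity (the two underlying
#' positions could form a Watson-Crick pair), `#` marks GU interactions
#' (G aligned to A, or U aligned to C), and for odd-length sequences the
#' centre column (the G shared by the overlapping constituent introns of a
#' stwintron) is marked `|`.
#'
#' The alignment is palindromic by construction: the 5' half of S is aligned
#' against the reverse complement of the 3' half with Needleman-Wunsch, and
#' the full alignment is assembled as that half-alignment followed by its
#' own mirror image, so column i mirrors column L-i+1 in class.
#'
#' @param seq nucleotide string, length >= 2.
#' @param match,mismatch,gap alignment scores. Defaults: match +1,
#'   mismatch/GU-equivalence 0 (annotated separately), gap -2.
#' @param terminal_window number of columns at each end counted by
#'   `symmetry_score`.
#' @return object of class `symmetry_alignment`: `aligned_seq`,
#'   `aligned_revcomp`, `consensus_line`, `center_pos` (column index, `NA`
#'   for even lengths), `symmetry_score` (identity + wobble columns within
#'   the terminal windows), `score` (alignment score of the full
#'   alignment).
#' @export
self_revcomp_align <- function(seq, match = 1, mismatch = 0, gap = -2,
                               terminal_window = 15L) {
  s <- as_dna(seq)
  L <- nchar(s)
  if (L < 2L) stop("seq must be at least 2 nt")
  odd <- L %% 2L == 1L
  h <- L %/% 2L
  prefix <- substr(s, 1L, h)
  suffix <- substr(s, L - h + 1L, L)
  al <- .nw_align(prefix, revcomp(suffix), match, mismatch, gap)
  q1 <- al$a   # gapped prefix of S
  q2 <- al$b   # gapped revcomp(suffix)
  mirror <- function(g) {  # reverse-complement a gapped string, keeping gaps
    paste(rev(strsplit(chartr("ACGT", "TGCA", g), "")[[1]]), collapse = "")
  }
  center_a <- if (odd) substr(s, h + 1L, h + 1L) else ""
  center_b <- if (odd) chartr("ACGT", "TGCA", center_a) else ""
  aligned_seq <- paste0(q1, center_a, mirror(q2))
  aligned_rc <- paste0(q2, center_b, mirror(q1))
  ac <- strsplit(aligned_seq, "")[[1]]
  bc <- strsplit(aligned_rc, "")[[1]]
  cons <- vapply(seq_along(ac), function(i) .consensus_symbol(ac[i], bc[i]), "")
  center_pos <- if (odd) nchar(q1) + 1L else NA_integer_
  if (odd) cons[center_pos] <- "|"
  tw <- min(as.integer(terminal_window), length(cons))
  sym <- sum(cons[seq_len(tw)] %in% c("*", "#")) +
    sum(cons[seq(length(cons) - tw + 1L, length(cons))] %in% c("*", "#"))
  # score of the assembled full alignment (column-wise)
  colscore <- sum(vapply(seq_along(ac), function(i) {
    if (ac[i] == "-" || bc[i] == "-") gap
    else if (ac[i] == bc[i]) match else mismatch
  }, 0))
  structure(
    list(aligned_seq = paste(ac, collapse = ""),
         aligned_revcomp = paste(bc, collapse = ""),
         consensus_line = paste(cons, collapse = ""),
         center_pos = center_pos,
         symmetry_score = as.integer(sym),
         terminal_window = tw,
         score = colscore),
    class = "symmetry_alignment"
  )
}

#' Render a symmetry alignment as three plain-text lines
#'
#' Sequence / consensus / reverse complement, in RNA letters, matching the
#' diagnostic `*`/`#`/`|` notation.
#' @param x a `symmetry_alignment`.
#' @param ... ignored.
#' @export
format.symmetry_alignment <- function(x, ...) {
  paste(as_rna(x$aligned_seq), x$consensus_line, as_rna(x$aligned_revcomp),
        sep = "\n")
}

#' @export
print.symmetry_alignment <- function(x, ...) {
  cat(format(x), "\n")
  cat(sprintf("terminal symmetry score: %d (+/- %d-column windows)\n",
              x$symmetry_score, x$terminal_window))
  invisible(x)
}

#' Per-position nucleotide frequency table of NTIRE elements
#'
#' The tabular equivalent of a sequence logo: for a set of equal-length
#' elements, the frequency of each nucleotide at each position. Columns
#' (positions) each sum to 1.
#'
#' @param elements character vector (or list) of equal-length RNA/DNA
#'   strings; must be non-empty.
#' @return 4 x L numeric matrix, rows A/C/G/U, columns positions.
#' @export
ntire_frequency_table <- function(elements) {
  elements <- as.character(unlist(elements))
  if (!length(elements)) stop("no elements supplied")
  el <- as_dna(elements)
  L <- unique(nchar(el))
  if (length(L) != 1L) stop("elements have mixed lengths")
  mat <- matrix(0, nrow = 4L, ncol = L,
                dimnames = list(c("A", "C", "G", "U"), seq_len(L)))
  rows <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  for (e in el) {
    ch <- strsplit(e, "")[[1]]
    for (j in seq_len(L)) {
      mat[rows[[ch[j]]], j] <- mat[rows[[ch[j]]], j] + 1L
    }
  }
  mat / length(el)
}
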