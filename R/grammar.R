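# Nested-intron grammar: canonical intron enumeration and [D1,2] stwintron
# detection. All coordinates are 1-based inclusive on the scanned strand.

#' Reverse complement of a nucleotide string
#' @param x character vector of DNA/RNA strings.
#' @return character vector of reverse complements (DNA alphabet).
#' @export
revcomp <- function(x) {
  vapply(as_dna(x), function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Detection configuration for the stwintron grammar
#'
#' Length windows and branch-point geometry used when parsing candidate
#' introns and stwintrons. Defaults: constituent introns 40-200 nt
#' (the validated near-identical stwintrons total 184-185 nt), and a
#' branch-element-to-acceptor distance window of 2-25 nt (observed external
#' distances cluster at 14 and 19 nt; internal introns are shorter).
#'
#' @param internal_min,internal_max length window for internal introns (nt).
#' @param external_min,external_max length window for external introns (nt).
#' @param bp_min,bp_max admissible number of nucleotides strictly between the
#'   branch element and the acceptor.
#' @param both_strands scan the reverse strand as well?
#' @param preferred_bp_dist external branch-to-acceptor distances favoured
#'   when ranking overlapping candidates.
#' @return an object of class `detection_config`.
#' @export
detection_config <- function(internal_min = 40L, internal_max = 200L,
                             external_min = 40L, external_max = 200L,
                             bp_min = 2L, bp_max = 25L,
                             both_strands = TRUE,
                             preferred_bp_dist = c(14L, 19L)) {
  stopifnot(internal_min >= 20L, internal_max >= internal_min,
            external_min >= 20L, external_max >= external_min,
            bp_min >= 0L, bp_max >= bp_min)
  structure(
    list(internal_min = as.integer(internal_min),
         internal_max = as.integer(internal_max),
         external_min = as.integer(external_min),
         external_max = as.integer(external_max),
         bp_min = as.integer(bp_min), bp_max = as.integer(bp_max),
         both_strands = isTRUE(both_strands),
         preferred_bp_dist = as.integer(preferred_bp_dist)),
    class = "detection_config"
  )
}

#' Construct an intron model record
#' @keywords internal
.intron_model <- function(start, end, seq, donor_pattern_used,
                          branch_start, branch_a_pos, acceptor_start) {
  structure(
    list(start = as.integer(start), end = as.integer(end),
         len = as.integer(end - start + 1L),
         seq = seq,
         donor_pattern_used = donor_pattern_used,
         branch_start = as.integer(branch_start),
         branch_a_pos = as.integer(branch_a_pos),
         acceptor_start = as.integer(acceptor_start),
         bp_to_acceptor_distance = as.integer(acceptor_start - (branch_start + 5L) - 1L)),
    class = "intron_model"
  )
}

#' @export
print.intron_model <- function(x, ...) {
  cat(sprintf("Intron %d-%d (%d nt), donor %s, branch A at %d, bp-to-acceptor %d nt\n",
              x$start, x$end, x$len, x$donor_pattern_used,
              x$branch_a_pos, x$bp_to_acceptor_distance))
  invisible(x)
}

# All branch-element candidates in seq, as integer starts.
.branch_sites <- function(s, motifs) find_motif_sites(s, motifs$branch_pattern)

# Acceptor sites as the 1-based start of the 3-nt acceptor.
.acceptor_sites <- function(s, motifs) find_motif_sites(s, motifs$acceptor_pattern)

# For an acceptor starting at `acc`, pick the branch element nearest the
# acceptor whose bp-to-acceptor distance lies in [bp_min, bp_max] and whose
# start is >= min_start (inside the intron, after the donor). Returns the
# branch start or NA. Standard proximal branch-point convention.
.pick_branch <- function(branch_starts, acc, bp_min, bp_max, min_start) {
  # distance strictly between branch end (b+5) and acceptor start
  d <- acc - (branch_starts + 5L) - 1L
  ok <- d >= bp_min & d <= bp_max & branch_starts >= min_start
  if (!any(ok)) return(NA_integer_)
  max(branch_starts[ok])
}

#' Enumerate canonical U2 introns in a sequence
#'
#' Finds all substrings that parse as a canonical intron: a 6-nt donor match
#' at the 5' end, a 3-nt acceptor match at the 3' end, a length inside
#' `[min_len, max_len]`, and a branch element whose distance to the acceptor
#' lies in the configured window. When several branch elements qualify the
#' one nearest the acceptor is used. Only the forward strand of `seq` is
#' scanned.
#'
#' @param seq nucleotide string.
#' @param motifs a [motif_set()].
#' @param min_len,max_len intron length window (`max_len >= min_len >= 20`).
#' @param bp_window length-2 integer vector: admissible branch-to-acceptor
#'   distances.
#' @param level `"internal"` or `"external"`: which donor variants apply
#'   (the GC donor is restricted to internal introns by default).
#' @return list of `intron_model` records sorted by (start, end).
#' @export
enumerate_introns <- function(seq, motifs = motif_set(),
                              min_len = 40L, max_len = 200L,
                              bp_window = c(2L, 25L),
                              level = "internal") {
  if (!nzchar(seq)) stop("seq must be non-empty")
  stopifnot(max_len >= min_len, min_len >= 20L)
  s <- as_dna(seq)
  donors <- .donors_for(motifs, level)
  donor_hits <- lapply(donors, function(p) find_motif_sites(s, p))
  acc <- .acceptor_sites(s, motifs)
  br <- .branch_sites(s, motifs)
  out <- list()
  for (di in seq_along(donors)) {
    for (ds in donor_hits[[di]]) {
      # acceptor triplet ends the intron: end = acc + 2
      ends <- acc + 2L
      lens <- ends - ds + 1L
      keep <- which(lens >= min_len & lens <= max_len)
      for (k in keep) {
        a <- acc[k]
        b <- .pick_branch(br, a, bp_window[1], bp_window[2], ds + 6L)
        if (is.na(b)) next
        out[[length(out) + 1L]] <- .intron_model(
          ds, ends[k], substr(s, ds, ends[k]), donors[di],
          b, b + motifs$branch_a_offset, a)
      }
    }
  }
  if (!length(out)) return(list())
  ord <- order(vapply(out, `[[`, 0L, "start"), vapply(out, `[[`, 0L, "end"))
  out <- out[ord]
  # one model per (start, end): if both GT and GC donor variants matched,
  # keep the first (canonical pattern listed first)
  key <- vapply(out, function(m) paste(m$start, m$end), "")
  out[!duplicated(key)]
}

#' Construct a stwintron model record
#' @keywords internal
.stwintron_model <- function(s, internal, ext_end, motifs, cfg, strand = "+",
                             flank5 = "", flank3 = "") {
  start <- internal$start - 1L
  end <- ext_end
  stw_seq <- substr(s, start, end)
  # external intron on the post-internal-excision sequence:
  # G1 followed by the genomic segment internal$end+1 .. end
  ext_seq <- paste0(substr(s, start, start), substr(s, internal$end + 1L, end))
  br <- .branch_sites(s, motifs)
  acc_start <- end - 2L
  b <- .pick_branch(br, acc_start, cfg$bp_min, cfg$bp_max, internal$end + 6L)
  ext_donor <- paste0(substr(s, start, start),
                      substr(s, internal$end + 1L, internal$end + 5L))
  donors <- .donors_for(motifs, "external")
  used <- donors[vapply(donors, function(p) iupac_match(p, ext_donor), TRUE)][1]
  external <- structure(
    list(start = 1L, end = nchar(ext_seq), len = nchar(ext_seq),
         seq = ext_seq,
         donor_pattern_used = used,
         # genomic coordinates of the discontinuous external intron
         part1 = c(start, start),
         part2 = c(internal$end + 1L, end),
         branch_start = as.integer(b),
         branch_a_pos = as.integer(b + motifs$branch_a_offset),
         acceptor_start = as.integer(acc_start),
         bp_to_acceptor_distance = as.integer(acc_start - (b + 5L) - 1L)),
    class = "intron_model"
  )
  structure(
    list(start = as.integer(start), end = as.integer(end),
         len = as.integer(end - start + 1L),
         strand = strand,
         seq = stw_seq,
         internal = internal,
         external = external,
         phase = NA_integer_,
         flank5 = flank5, flank3 = flank3,
         rank = NA_integer_),
    class = "stwintron_model"
  )
}

#' @export
print.stwintron_model <- function(x, ...) {
  cat(sprintf("[D1,2] stwintron %d-%d (%s), %d nt = internal %d nt + external %d nt\n",
              x$start, x$end, x$strand, x$len, x$internal$len, x$external$len))
  cat(sprintf("  internal: %d-%d; external bp-to-acceptor distance: %d nt\n",
              x$internal$start, x$internal$end,
              x$external$bp_to_acceptor_distance))
  invisible(x)
}

# Rank candidates within groups of mutually overlapping intervals.
# Preference: (1) external bp-to-acceptor distance in cfg$preferred_bp_dist,
# (2) presence of a fully complementary NTIRE pair, (3) shorter total length,
# ties broken by leftmost start.
.rank_candidates <- function(models, cfg) {
  if (!length(models)) return(models)
  st <- vapply(models, `[[`, 0L, "start")
  en <- vapply(models, `[[`, 0L, "end")
  # overlap components by sweep
  ord <- order(st, en)
  grp <- integer(length(models))
  g <- 0L; right <- -Inf
  for (i in ord) {
    if (st[i] > right) g <- g + 1L
    grp[i] <- g
    right <- max(right, en[i])
  }
  pref <- !(vapply(models, function(m) m$external$bp_to_acceptor_distance, 0L)
            %in% cfg$preferred_bp_dist)
  full_ntire <- !vapply(models, function(m) {
    length(scan_ntire(m, threshold = 1)) > 0L
  }, TRUE)
  lens <- vapply(models, `[[`, 0L, "len")
  for (gi in unique(grp)) {
    idx <- which(grp == gi)
    o <- order(pref[idx], full_ntire[idx], lens[idx], st[idx])
    for (r in seq_along(o)) models[[idx[o[r]]]]$rank <- r
  }
  ord2 <- order(st, en)
  models[ord2]
}

.detect_one_strand <- function(s, motifs, cfg, strand) {
  internal <- enumerate_introns(s, motifs, cfg$internal_min, cfg$internal_max,
                                c(cfg$bp_min, cfg$bp_max), level = "internal")
  if (!length(internal)) return(list())
  acc <- .acceptor_sites(s, motifs)
  br <- .branch_sites(s, motifs)
  L <- nchar(s)
  donors <- .donors_for(motifs, "external")
  out <- list()
  for (im in internal) {
    if (im$start < 2L) next
    if (substr(s, im$start - 1L, im$start - 1L) != "G") next
    if (im$end + 5L > L) next
    ext_donor <- paste0("G", substr(s, im$end + 1L, im$end + 5L))
    if (!any(vapply(donors, function(p) iupac_match(p, ext_donor), TRUE))) next
    # walk 3' to find an external acceptor + branch in the length window
    ends <- acc + 2L
    ext_lens <- 1L + (ends - im$end)   # G1 plus the downstream segment
    keep <- which(ext_lens >= cfg$external_min & ext_lens <= cfg$external_max &
                    acc > im$end + 5L)
    for (k in keep) {
      b <- .pick_branch(br, acc[k], cfg$bp_min, cfg$bp_max, im$end + 6L)
      if (is.na(b)) next
      fl5 <- substr(s, max(1L, im$start - 21L), im$start - 2L)
      fl3 <- substr(s, ends[k] + 1L, min(L, ends[k] + 20L))
      out[[length(out) + 1L]] <-
        .stwintron_model(s, im, ends[k], motifs, cfg, strand, fl5, fl3)
    }
  }
  out
}

#' Detect [D1,2] stwintrons in genomic sequence
#'
#' Implements the nested-intron grammar: (i) enumerate internal-intron
#' candidates; (ii) require the nucleotide immediately preceding the internal
#' intron to be G and the 5 nt following the internal acceptor to complete an
#' external donor (the internal intron interrupts the external donor between
#' G1 and nt 2); (iii) walk 3' to find an external branch element and
#' acceptor within the external length window. All overlapping alternatives
#' are reported, ranked within overlap groups (see `rank` field): preferred
#' external branch-to-acceptor distances first, then presence of a fully
#' complementary NTIRE pair, then shorter total length, ties to the leftmost
#' start.
#'
#' Reverse-strand hits (when `cfg$both_strands`) are detected on the reverse
#' complement; their models carry coordinates in the scanned-strand frame
#' plus `plus_start`/`plus_end` fields giving the interval on the input
#' strand, and `strand == "-"`.
#'
#' @param seq nucleotide string (a genomic record).
#' @param motifs a [motif_set()].
#' @param cfg a [detection_config()].
#' @return list of `stwintron_model` records sorted by (start, end); empty
#'   list if no structure is found.
#' @export
detect_stwintrons <- function(seq, motifs = motif_set(),
                              cfg = detection_config()) {
  s <- as_dna(seq)
  .check_nt(s, "seq")
  out <- .detect_one_strand(s, motifs, cfg, "+")
  for (m in seq_along(out)) {
    out[[m]]$plus_start <- out[[m]]$start
    out[[m]]$plus_end <- out[[m]]$end
  }
  if (cfg$both_strands) {
    L <- nchar(s)
    rev_hits <- .detect_one_strand(revcomp(s), motifs, cfg, "-")
    for (m in seq_along(rev_hits)) {
      rev_hits[[m]]$plus_start <- L - rev_hits[[m]]$end + 1L
      rev_hits[[m]]$plus_end <- L - rev_hits[[m]]$start + 1L
    }
    out <- c(out, rev_hits)
  }
  .rank_candidates(out, cfg)
}

#' Detect stwintrons overlapping an anchor interval
#'
#' As [detect_stwintrons()], restricted to candidate structures that overlap
#' a given anchor interval (e.g. a similarity hit used as a seed, mirroring
#' an anchor-and-walk mining procedure). Models are ranked by the summed
#' distance of their boundaries to the anchor's.
#'
#' @param seq nucleotide string.
#' @param anchor length-2 integer vector, 1-based inclusive interval within
#'   `seq`.
#' @param motifs a [motif_set()].
#' @param cfg a [detection_config()].
#' @return list of `stwintron_model` records ranked by anchor proximity.
#' @export
anchored_detect <- function(seq, anchor, motifs = motif_set(),
                            cfg = detection_config()) {
  s <- as_dna(seq)
  anchor <- as.integer(anchor)
  if (length(anchor) != 2L || anchor[1] > anchor[2] ||
      anchor[1] < 1L || anchor[2] > nchar(s)) {
    stop("anchor interval lies outside seq")
  }
  hits <- detect_stwintrons(s, motifs, cfg)
  if (!length(hits)) return(hits)
  ps <- vapply(hits, function(m) m$plus_start, 0L)
  pe <- vapply(hits, function(m) m$plus_end, 0L)
  keep <- which(ps <= anchor[2] & pe >= anchor[1])
  hits <- hits[keep]
  if (!length(hits)) return(hits)
  d <- abs(vapply(hits, function(m) m$plus_start, 0L) - anchor[1]) +
       abs(vapply(hits, function(m) m$plus_end, 0L) - anchor[2])
  hits <- hits[order(d)]
  for (i in seq_along(hits)) hits[[i]]$rank <- i
  hits
}

#' Validate the structural invariants of a stwintron model
#'
#' Checks the [D1,2] grammar directly on the model: G at position 1, the
#' internal intron starting at position 2, donor/branch/acceptor matches for
#' both constituent introns, and the length identity
#' `len(stwintron) == len(internal) + len(external)`.
#'
#' @param stw a `stwintron_model`.
#' @param motifs a [motif_set()].
#' @return `TRUE` (invisibly) or an error describing the violated invariant.
#' @export
validate_stwintron <- function(stw, motifs = motif_set()) {
  s <- stw$seq
  if (substr(s, 1L, 1L) != "G") stop("stwintron must start with G (external G1)")
  if (stw$internal$start != stw$start + 1L) {
    stop("internal intron must start immediately after G1")
  }
  if (stw$len != stw$internal$len + stw$external$len) {
    stop("length identity violated: len(stw) != len(internal) + len(external)")
  }
  int_seq <- substr(s, 2L, 1L + stw$internal$len)
  donors_int <- .donors_for(motifs, "internal")
  if (!any(vapply(donors_int, function(p) iupac_match(p, substr(int_seq, 1, 6)), TRUE))) {
    stop("internal donor does not match any donor pattern")
  }
  if (!iupac_match(motifs$acceptor_pattern,
                   substr(int_seq, stw$internal$len - 2L, stw$internal$len))) {
    stop("internal acceptor does not match acceptor pattern")
  }
  ext_seq <- stw$external$seq
  donors_ext <- .donors_for(motifs, "external")
  if (!any(vapply(donors_ext, function(p) iupac_match(p, substr(ext_seq, 1, 6)), TRUE))) {
    stop("reconstituted external donor does not match any donor pattern")
  }
  if (!iupac_match(motifs$acceptor_pattern,
                   substr(ext_seq, nchar(ext_seq) - 2L, nchar(ext_seq)))) {
    stop("external acceptor does not match acceptor pattern")
  }
  if (stw$external$bp_to_acceptor_distance < 0L) {
    stop("external branch element must lie 5' of the acceptor")
  }
  invisible(TRUE)
}
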