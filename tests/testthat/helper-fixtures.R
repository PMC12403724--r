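# Shared fixtures and independent brute-force oracles.

# TOY1: minimal hand-checked [D1,2] stwintron (41 nt).
#   internal intron (20 nt): GTATGT AAA GCTAAC CT TAG
#   external intron (21 nt, discontinuous): G ... TATGT AA GCTAAC CTCT CAG
toy_internal <- function() "GTATGTAAAGCTAACCTTAG"
toy_stwintron <- function() {
  paste0("G", toy_internal(), "TATGTAAGCTAACCTCTCAG")
}
toy_gene <- function(e5 = strrep("A", 30), e3 = strrep("C", 30)) {
  paste0(e5, toy_stwintron(), e3)
}
toy_cfg <- function() {
  detection_config(internal_min = 20, internal_max = 60,
                   external_min = 20, external_max = 60)
}
toy_model <- function() {
  detect_stwintrons(toy_gene(), cfg = toy_cfg())[[1]]
}

# brute-force IUPAC membership, written independently of the package's
# matcher (simple per-character set lookup)
bf_classes <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
bf_match <- function(pattern, window) {
  p <- strsplit(chartr("U", "T", toupper(pattern)), "")[[1]]
  w <- strsplit(chartr("U", "T", toupper(window)), "")[[1]]
  length(p) == length(w) &&
    all(vapply(seq_along(p), function(i) w[i] %in% bf_classes[[p[i]]], TRUE))
}
bf_sites <- function(seq, pattern) {
  k <- nchar(pattern)
  L <- nchar(seq)
  if (k > L) return(integer(0))
  Filter(function(i) bf_match(pattern, substr(seq, i, i + k - 1L)),
         seq_len(L - k + 1L))
}

# brute-force intron enumeration over all (donor, branch, acceptor) triples
bf_enumerate <- function(seq, donors = c("GTRWGY", "GCRWGY"),
                         branch = "RYTRAY", acceptor = "HAG",
                         min_len = 40, max_len = 200, bp = c(2, 25)) {
  out <- list()
  L <- nchar(seq)
  for (ds in seq_len(L)) {
    if (ds + 5L > L) next
    if (!any(vapply(donors, function(p) bf_match(p, substr(seq, ds, ds + 5)), TRUE))) next
    for (as_ in seq_len(L)) {
      en <- as_ + 2L
      if (en > L) next
      len <- en - ds + 1L
      if (len < min_len || len > max_len) next
      if (!bf_match(acceptor, substr(seq, as_, en))) next
      best <- NA
      for (bs in seq(ds + 6L, as_ - 6L)) {
        if (bs + 5L >= as_) next
        d <- as_ - (bs + 5L) - 1L
        if (d < bp[1] || d > bp[2]) next
        if (bf_match(branch, substr(seq, bs, bs + 5L))) best <- bs
      }
      if (!is.na(best)) {
        out[[length(out) + 1L]] <- c(start = ds, end = en, branch = best)
      }
    }
  }
  out
}

# brute-force antiparallel pairing fraction
bf_pair_fraction <- function(e5, e3) {
  a <- strsplit(chartr("U", "T", toupper(e5)), "")[[1]]
  b <- strsplit(chartr("U", "T", toupper(e3)), "")[[1]]
  L <- length(a)
  paired <- vapply(seq_len(L), function(i) {
    pair <- paste0(a[i], b[L - i + 1L])
    pair %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }, TRUE)
  mean(paired)
}

# random DNA helper for property tests
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
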