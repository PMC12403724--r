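test_that("the canonical NTIRE-10 pairs are fully complementary", {
  # wobble-containing pair
  p <- pairing_classes("GUAUAAAAAC", "GUUUUUAUGU")
  expect_identical(p$complementarity_fraction, 1)
  expect_true(p$fully_complementary)
  expect_true(any(p$pair_classes == "GU"))
  # all-Watson-Crick pair (fully complementary as DNA)
  p2 <- pairing_classes("GUAUAAAAAC", "GUUUUUAUAC")
  expect_identical(p2$complementarity_fraction, 1)
  expect_true(all(p2$pair_classes == "WC"))
  # compensatory-mutation pairs
  expect_identical(pairing_classes("GUAUUAAAAU", "AUUUUGAUAU")$complementarity_fraction, 1)
  expect_identical(pairing_classes("GUAUAAAAGC", "GCUUUUAUGU")$complementarity_fraction, 1)
})

test_that("pairing agrees with a brute-force pairing table", {
  # a self-pair is not fully complementary
  p <- pairing_classes("GUAUAAAAAC", "GUAUAAAAAC")
  expect_identical(p$complementarity_fraction,
                   bf_pair_fraction("GUAUAAAAAC", "GUAUAAAAAC"))
  expect_lt(p$complementarity_fraction, 1)
  set.seed(3)
  for (i in 1:20) {
    a <- rand_dna(10); b <- rand_dna(10)
    expect_identical(pairing_classes(a, b)$complementarity_fraction,
                     bf_pair_fraction(a, b))
  }
})

test_that("pairing is symmetric and validates lengths", {
  set.seed(4)
  for (i in 1:10) {
    a <- rand_dna(9); b <- rand_dna(9)
    expect_identical(pairing_classes(a, b)$complementarity_fraction,
                     pairing_classes(b, a)$complementarity_fraction)
  }
  expect_error(pairing_classes("GUAUAAAAAC", "GUAUAAAAA"), "lengths differ")
})

test_that("scan_ntire finds the implanted pair in a preset template", {
  tpl <- do.call(build_stwintron, c(stw_preset("xylariaceae"), list(seed = 7)))
  g <- paste0(strrep("A", 40), tpl$seq, strrep("C", 40))
  hits <- detect_stwintrons(g)
  m <- Filter(function(h) h$rank == 1L, hits)[[1]]
  pairs <- scan_ntire(m, threshold = 1)
  expect_gte(length(pairs), 1)
  best <- pairs[[1]]
  expect_identical(best$five_elem, "GUAUAAAAAC")
  expect_identical(best$three_elem, "GUUUUUAUGU")
  expect_identical(best$complementarity_fraction, 1)
  expect_identical(best$five_offset, 5L)
  expect_identical(best$three_gap_to_acceptor, 2L)
})

test_that("scan_ntire is empty when the 3' region cannot hold the element", {
  tpl <- build_stwintron(ntire = NULL, external_bp_dist = 8, seed = 9)
  g <- paste0(strrep("A", 40), tpl$seq, strrep("C", 40))
  m <- Filter(function(h) h$plus_start == 41L &&
                h$plus_end == 40L + nchar(tpl$seq),
              detect_stwintrons(g))[[1]]
  expect_length(scan_ntire(m, lengths = 10, threshold = 0), 0)
})

test_that("scan_ntire equals brute-force enumeration of admissible pairs", {
  tpl <- do.call(build_stwintron, c(stw_preset("xylariaceae"), list(seed = 13)))
  g <- paste0(strrep("A", 40), tpl$seq, strrep("C", 40))
  m <- Filter(function(h) h$rank == 1L, detect_stwintrons(g))[[1]]
  got <- scan_ntire(m, threshold = 0.8)
  # independent brute force over all admissible substring pairs
  s <- m$seq
  br_end_rel <- m$external$branch_start + 5L - m$start + 1L
  acc_rel <- m$external$acceptor_start - m$start + 1L
  n_bf <- 0L
  for (len in c(10L, 9L)) {
    for (off in 0:5) {
      e5 <- substr(s, off + 1, off + len)
      ts_range <- seq(br_end_rel + 1L, acc_rel - 1L - len + 1L)
      for (ts in ts_range) {
        e3 <- substr(s, ts, ts + len - 1L)
        if (bf_pair_fraction(e5, e3) >= 0.8) n_bf <- n_bf + 1L
      }
    }
  }
  expect_identical(length(got), n_bf)
  # ranking: fractions non-increasing, 10-mers before 9-mers at equal fraction
  fr <- vapply(got, `[[`, 0, "complementarity_fraction")
  expect_true(all(diff(fr) <= 0))
})

test_that("bp_acceptor_layout reproduces the two canonical distances", {
  xyl <- do.call(build_stwintron, c(stw_preset("xylariaceae"), list(seed = 1)))
  hyp <- do.call(build_stwintron, c(stw_preset("hypoxylaceae"), list(seed = 1)))
  for (case in list(list(tpl = xyl, sp5 = 2L, total = 14L),
                    list(tpl = hyp, sp5 = 7L, total = 19L))) {
    g <- paste0(strrep("A", 40), case$tpl$seq, strrep("C", 40))
    m <- Filter(function(h) h$rank == 1L, detect_stwintrons(g))[[1]]
    lay <- bp_acceptor_layout(m$external, scan_ntire(m, threshold = 1)[[1]])
    expect_identical(lay$spacer5, case$sp5)
    expect_identical(lay$element_len, 10L)
    expect_identical(lay$spacer3, 2L)
    expect_identical(lay$total, case$total)
    expect_identical(lay$total, m$external$bp_to_acceptor_distance)
  }
  # no NTIRE: total is the raw distance
  lay0 <- bp_acceptor_layout(9L)
  expect_identical(lay0$element_len, 0L)
  expect_identical(lay0$total, 9L)
})

test_that("self_revcomp_align annotates palindromes and antipalindromes", {
  al <- self_revcomp_align("GAAUUC")
  expect_identical(al$consensus_line, "******")
  expect_identical(al$score, 6)
  al2 <- self_revcomp_align("AAAAAA")
  expect_false(grepl("\\*", al2$consensus_line))
})

test_that("self-revcomp alignment is mirror-symmetric about its centre", {
  set.seed(21)
  for (i in 1:10) {
    s <- rand_dna(sample(20:120, 1))
    al <- self_revcomp_align(s)
    cons <- strsplit(al$consensus_line, "")[[1]]
    expect_identical(cons, rev(cons))
    # gap-stripped rows recover S and revcomp(S)
    expect_identical(gsub("-", "", al$aligned_seq), as_dna(s))
    expect_identical(gsub("-", "", al$aligned_revcomp), revcomp(s))
    if (nchar(s) %% 2 == 1) {
      expect_identical(substr(al$consensus_line, al$center_pos, al$center_pos),
                       "|")
    }
  }
})

test_that("preset stwintrons show terminal symmetry windows", {
  tpl <- do.call(build_stwintron, c(stw_preset("xylariaceae"), list(seed = 7)))
  al <- self_revcomp_align(tpl$seq)
  cons <- strsplit(al$consensus_line, "")[[1]]
  # a contiguous run of >= 10 paired (identity or GU) columns within the
  # first 20 columns; mirror symmetry puts the same run at the other end
  runs <- rle(cons[1:20] %in% c("*", "#"))
  expect_gte(max(runs$lengths[runs$values]), 10)
  tail_runs <- rle(rev(cons)[1:20] %in% c("*", "#"))
  expect_gte(max(tail_runs$lengths[tail_runs$values]), 10)
})

test_that("alignment scores never beat the unrestricted optimum", {
  # Biostrings global alignment with the same scoring bounds the score of
  # the palindromic alignment from above; perfect reverse-complement
  # palindromes attain it exactly
  set.seed(8)
  for (i in 1:5) {
    s <- rand_dna(40)
    al <- self_revcomp_align(s)
    sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0)
    ref <- Biostrings::pairwiseAlignment(s, revcomp(s), type = "global",
                                         substitutionMatrix = sm,
                                         gapOpening = 0, gapExtension = 2,
                                         scoreOnly = TRUE)
    expect_lte(al$score, ref + 1e-9)
  }
  pal <- "GCATCGAATTCGATGC"  # self reverse complement
  expect_equal(self_revcomp_align(pal)$score, nchar(pal))
})

test_that("ntire_frequency_table is column-stochastic", {
  ft <- ntire_frequency_table(c("GUAUAAAAAC", "GUUUUUAUGU"))
  expect_identical(dim(ft), c(4L, 10L))
  expect_true(all(abs(colSums(ft) - 1) < 1e-12))
  expect_identical(ft["G", 1], 1)
  expect_identical(ft["U", 2], 1)
  ft1 <- ntire_frequency_table("GUAUAAAAAC")
  expect_identical(ft1["G", 1], 1)
  expect_error(ntire_frequency_table(character(0)), "no elements")
  expect_error(ntire_frequency_table(c("GUAU", "GUAUA")), "mixed")
})

test_that("a full NTIRE pair straddles the splice products as expected", {
  # both elements inside the misspliced intron; 5' element in the internal
  # intron, 3' element in the external intron after two-step splicing
  tpl <- do.call(build_stwintron, c(stw_preset("xylariaceae"), list(seed = 17)))
  g <- paste0(strrep("A", 40), tpl$seq, strrep("C", 40))
  m <- Filter(function(h) h$rank == 1L, detect_stwintrons(g))[[1]]
  p <- scan_ntire(m, threshold = 1)[[1]]
  e5_dna <- as_dna(p$five_elem); e3_dna <- as_dna(p$three_elem)
  misspliced_intron <- substr(m$seq, 2L, m$len)  # internal donor ... acceptor
  expect_true(grepl(e5_dna, misspliced_intron, fixed = TRUE))
  expect_true(grepl(e3_dna, misspliced_intron, fixed = TRUE))
  internal_seq <- substr(m$seq, 2L, 1L + m$internal$len)
  expect_true(grepl(e5_dna, internal_seq, fixed = TRUE))
  expect_true(grepl(e3_dna, m$external$seq, fixed = TRUE))
})
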