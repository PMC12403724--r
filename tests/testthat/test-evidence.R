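# random exon context: with homopolymer exons the mature and misspliced
# queries differ by a single substitution-equivalent, which is a degenerate
# corner, not the classification regime of interest
ev_exons <- function() {
  set.seed(202)
  list(e5 = rand_dna(60), e3 = rand_dna(60))
}
toy_queries <- function() {
  e <- ev_exons()
  make_junction_queries(toy_model(), e$e5, e$e3)
}

test_that("a verbatim query read is classified to its kind", {
  q <- toy_queries()
  for (k in q$kind) {
    cl <- classify_reads(q$query[q$kind == k], q)
    expect_identical(cl$counts[[k]], 1L, info = k)
  }
})

test_that("the synthetic closed loop recovers exact counts at 0 mismatches", {
  m <- toy_model()
  gen_counts <- c(mature = 10L, splinter = 4L, misspliced = 2L, pre_mRNA = 1L)
  e <- ev_exons(); e5 <- e$e5; e3 <- e$e3
  pr <- splice_products(m, e5, e3)
  q <- make_junction_queries(m, e5, e3)
  rr <- emit_reads(pr, gen_counts, read_len = 50, seed = 3)
  cl <- classify_reads(rr$reads, q, max_mismatches = 0)
  expect_identical(cl$counts[names(gen_counts)], gen_counts)
  expect_identical(cl$counts[["ambiguous"]], 0L)
  expect_identical(cl$counts[["unassigned"]], 0L)
})

test_that("reads with errors are tolerated within the mismatch budget", {
  m <- toy_model()
  counts <- c(mature = 30L, splinter = 10L, misspliced = 5L, pre_mRNA = 5L)
  e <- ev_exons()
  pr <- splice_products(m, e$e5, e$e3)
  q <- make_junction_queries(m, e$e5, e$e3)
  rr <- emit_reads(pr, counts, read_len = 40, error_rate = 0.02, seed = 101)
  cl <- classify_reads(rr$reads, q, max_mismatches = 2)
  # binomial tolerance: nearly all reads should still classify
  recovered <- sum(cl$counts[names(counts)])
  expect_gte(recovered, 0.9 * sum(counts))
})

test_that("junction overhang below the minimum leaves reads unassigned", {
  q <- toy_queries()
  mat <- q$query[q$kind == "mature"]
  # read overlapping the junction by only 3 nt on the right
  r <- substr(mat, 1, 33)
  cl <- classify_reads(r, q, max_mismatches = 0, min_overhang = 8)
  expect_identical(cl$counts[["unassigned"]], 1L)
  # widening the overlap past the overhang assigns it
  r2 <- substr(mat, 1, 38)
  cl2 <- classify_reads(r2, q, max_mismatches = 0, min_overhang = 8)
  expect_identical(cl2$counts[["mature"]], 1L)
})

test_that("classification is orientation-free", {
  m <- toy_model()
  counts <- c(mature = 5L, splinter = 3L, misspliced = 2L, pre_mRNA = 1L)
  e <- ev_exons()
  pr <- splice_products(m, e$e5, e$e3)
  q <- make_junction_queries(m, e$e5, e$e3)
  rr <- emit_reads(pr, counts, read_len = 44, seed = 9)
  fwd <- classify_reads(rr$reads, q, max_mismatches = 0)
  rev <- classify_reads(revcomp(rr$reads), q, max_mismatches = 0)
  expect_identical(fwd$counts, rev$counts)
})

test_that("zero-mismatch classification equals exact substring search", {
  m <- toy_model()
  counts <- c(mature = 8L, splinter = 4L, misspliced = 3L, pre_mRNA = 2L)
  e <- ev_exons()
  pr <- splice_products(m, e$e5, e$e3)
  q <- make_junction_queries(m, e$e5, e$e3)
  # read length 36 with overhang 8 keeps every read inside the 60-nt query
  # span, so exact substring search is a complete oracle at 0 mismatches
  rr <- emit_reads(pr, counts, read_len = 36, seed = 12)
  cl <- classify_reads(rr$reads, q, max_mismatches = 0, min_overhang = 8)
  supports <- function(r, i) {
    for (cand in c(r, revcomp(r))) {
      at <- regexpr(cand, q$query[i], fixed = TRUE)[1]
      if (at > 0) {
        covers <- at <= q$fusion_pos[i] - 8L + 1L &&
          at + nchar(cand) - 1L >= q$fusion_pos[i] + 8L
        if (covers) return(TRUE)
      }
    }
    FALSE
  }
  oracle <- vapply(rr$reads, function(r) {
    kinds <- q$kind[vapply(seq_len(nrow(q)), function(i) supports(r, i), TRUE)]
    if (length(kinds) == 1L) kinds
    else if (length(kinds) > 1L) "ambiguous" else "unassigned"
  }, "")
  for (k in c(names(counts), "ambiguous", "unassigned")) {
    expect_identical(cl$counts[[k]], sum(oracle == k), info = k)
  }
})

test_that("locus verdicts flag support without comparing counts", {
  v <- locus_verdict(c(mature = 1L, splinter = 1L, misspliced = 0L,
                       pre_mRNA = 0L))
  expect_true(v$stwintron_confirmed)
  expect_true(v$splinter_confirmed)
  expect_false(v$missplice_observed)
  v2 <- locus_verdict(c(mature = 0L, splinter = 0L, misspliced = 0L,
                        pre_mRNA = 5L))
  expect_false(v2$stwintron_confirmed)
  expect_true(v2$pre_mrna_only)
  v3 <- locus_verdict(c(mature = 3L, splinter = 1L, misspliced = 2L,
                        pre_mRNA = 0L))
  expect_true(v3$stwintron_confirmed && v3$splinter_confirmed &&
                v3$missplice_observed)
})
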