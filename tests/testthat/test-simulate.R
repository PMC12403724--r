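test_that("build_stwintron is deterministic and grammar-valid", {
  a <- do.call(build_stwintron, c(stw_preset("xylariaceae"), list(seed = 7)))
  b <- do.call(build_stwintron, c(stw_preset("xylariaceae"), list(seed = 7)))
  expect_identical(a$seq, b$seq)
  expect_identical(nchar(a$seq), 185L)
  t <- a$truth
  expect_identical(substr(a$seq, 1, 1), "G")
  expect_true(iupac_match("GURWGY", substr(a$seq, t$internal_donor[1],
                                           t$internal_donor[2])))
  expect_true(iupac_match("RYURAY", substr(a$seq, t$external_branch[1],
                                           t$external_branch[2])))
  expect_identical(substr(a$seq, t$ntire3[1], t$ntire3[2]),
                   as_dna("GUUUUUAUGU"))
  expect_identical(t$external_bp_dist, 14L)
  # different seed, different filler, same structure
  c2 <- do.call(build_stwintron, c(stw_preset("xylariaceae"), list(seed = 8)))
  expect_false(identical(a$seq, c2$seq))
  expect_identical(nchar(c2$seq), 185L)
})

test_that("infeasible layouts are rejected with a named constraint", {
  expect_error(build_stwintron(internal_len = 15),
               "internal_len")
  expect_error(build_stwintron(external_len = 28,
                               ntire = list(five = "GUAUAAAAAC",
                                            three = "GUUUUUAUGU",
                                            spacer5 = 2, spacer3 = 2)),
               "external_len")
  # a 10-nt element cannot fit an 8-nt distance: layout arithmetic
  expect_error(bp_acceptor_layout(8L, pairing_classes("GUAUAAAAAC",
                                                      "GUUUUUAUGU",
                                                      three_gap_to_acceptor = 2)),
               "does not fit")
  expect_error(build_stwintron(ntire = list(five = "AUAUAAAAAC",
                                            three = "GUUUUUAUGU",
                                            spacer5 = 2, spacer3 = 2)),
               "donor nt 5-6")
})

test_that("build_genome honours implant rate and emits valid truth", {
  gen0 <- build_genome(n_genes = 4, implant_rate = 0, seed = 3)
  expect_identical(nrow(gen0$truth), 0L)
  expect_length(unlist(lapply(gen0$genome, detect_stwintrons)), 0)
  gen <- build_genome(n_genes = 5, implant_rate = 1, seed = 3)
  expect_identical(nrow(gen$truth), 5L)
  for (i in seq_len(nrow(gen$truth))) {
    tr <- gen$truth[i, ]
    g <- gen$genome[[tr$gene]]
    expect_identical(substr(g, tr$start, tr$start), "G")
    expect_identical(tr$end - tr$start + 1L, tr$stw_len)
    expect_identical(tr$phase, (tr$start - 1L) %% 3L)
  }
  # determinism
  gen2 <- build_genome(n_genes = 5, implant_rate = 1, seed = 3)
  expect_identical(gen$genome, gen2$genome)
})

test_that("sister copies stay within the SNP budget and cluster together", {
  gen <- build_genome(n_genes = 6, sisters = list(copies = 4, snps = c(0, 2, 3, 5)),
                      template = "xylariaceae", seed = 11)
  tr <- gen$truth[gen$truth$sister, ]
  expect_identical(nrow(tr), 4L)
  expect_identical(sort(tr$n_snps), c(0L, 2L, 3L, 5L))
  seqs <- vapply(seq_len(nrow(tr)), function(i) {
    substr(gen$genome[[tr$gene[i]]], tr$start[i], tr$end[i])
  }, "")
  names(seqs) <- tr$gene
  cl <- near_identical_clusters(identity_matrix(seqs))
  expect_identical(cl, list(sort(tr$gene)))
  # SNPs never fall in consensus elements: every copy still detects and
  # still carries the full NTIRE pair
  for (i in seq_len(nrow(tr))) {
    hits <- detect_stwintrons(gen$genome[[tr$gene[i]]])
    hit <- Filter(function(m) m$plus_start == tr$start[i] &&
                    m$plus_end == tr$end[i], hits)
    expect_length(hit, 1)
    expect_gte(length(scan_ntire(hit[[1]], threshold = 1)), 1)
  }
})

test_that("emit_reads validates read length and counts match truth", {
  pr <- splice_products(toy_model(), strrep("A", 60), strrep("C", 60))
  expect_error(emit_reads(pr, c(mature = 1L), read_len = 10), "2 \\* min_overhang")
  rr <- emit_reads(pr, c(mature = 3L, splinter = 2L), read_len = 40, seed = 2)
  expect_length(rr$reads, 5)
  expect_identical(rr$truth$count, c(3L, 2L))
  rr2 <- emit_reads(pr, c(mature = 3L, splinter = 2L), read_len = 40, seed = 2)
  expect_identical(rr$reads, rr2$reads)
})

test_that("full pipeline closure reproduces the truth at zero noise", {
  gen <- build_genome(n_genes = 4, implant_rate = 1, seed = 29)
  for (i in seq_len(nrow(gen$truth))) {
    tr <- gen$truth[i, ]
    g <- gen$genome[[tr$gene]]
    hits <- detect_stwintrons(g)
    hit <- Filter(function(m) m$plus_start == tr$start &&
                    m$plus_end == tr$end, hits)[[1]]
    e5 <- substr(g, 1, hit$start - 1L)
    e3 <- substr(g, hit$end + 1L, nchar(g))
    pr <- splice_products(hit, e5, e3, phase = tr$phase)
    q <- make_junction_queries(hit, e5, e3)
    counts <- c(mature = 6L, splinter = 3L, misspliced = 2L, pre_mRNA = 1L)
    rr <- emit_reads(pr, counts, read_len = 50, error_rate = 0, seed = 500 + i)
    cl <- classify_reads(rr$reads, q, max_mismatches = 0)
    expect_identical(cl$counts[names(counts)], counts)
    v <- locus_verdict(cl$counts)
    expect_true(v$stwintron_confirmed && v$splinter_confirmed &&
                  v$missplice_observed)
  }
})
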