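test_that("splice products have the defining sequence arithmetic", {
  m <- toy_model()
  e5 <- strrep("A", 30); e3 <- strrep("C", 30)
  pr <- splice_products(m, e5, e3, phase = 0)
  expect_named(pr, c("pre_mRNA", "splinter", "mature", "misspliced"))
  # mature = ligated exons
  expect_identical(pr$mature$sequence, paste0(e5, e3))
  # misspliced retains exactly one G; removed segment = stwintron - 1
  expect_identical(pr$misspliced$sequence, paste0(e5, "G", e3))
  expect_identical(pr$misspliced$retained_intronic_nt, 1L)
  expect_identical(nchar(pr$pre_mRNA$sequence) - nchar(pr$misspliced$sequence),
                   m$len - 1L)
  # splinter lacks exactly the internal intron
  expect_identical(nchar(pr$pre_mRNA$sequence) - nchar(pr$splinter$sequence),
                   m$internal$len)
  # composition identity: excising the external intron from the splinter
  # yields the mature product
  ext <- m$external$seq
  expect_identical(sub(ext, "", pr$splinter$sequence, fixed = TRUE),
                   pr$mature$sequence)
})

test_that("splice order does not matter for the mature product", {
  m <- toy_model()
  pr <- splice_products(m, strrep("A", 30), strrep("C", 30))
  # direct removal of the whole stwintron
  direct <- sub(m$seq, "", pr$pre_mRNA$sequence, fixed = TRUE)
  expect_identical(direct, pr$mature$sequence)
})

test_that("splice validates its context and model", {
  m <- toy_model()
  expect_error(splice_products(m, "AAAA", strrep("C", 30)), "exon5")
  expect_error(splice_products(m, strrep("A", 30), "CC"), "exon3")
  bad <- m; bad$seq <- sub("^G", "T", bad$seq)
  expect_error(splice_products(bad, strrep("A", 30), strrep("C", 30)),
               "malformed")
})

test_that("junction queries are centred and of the requested length", {
  m <- toy_model()
  e5 <- strrep("A", 40); e3 <- strrep("C", 40)
  q <- make_junction_queries(m, e5, e3)
  expect_true(all(nchar(q$query) == 60L))
  expect_true(all(q$fusion_pos == 30L))
  expect_setequal(q$kind, c("mature", "splinter", "misspliced", "pre_mRNA"))
  # misspliced query carries the single retained G right of centre
  mq <- q$query[q$kind == "misspliced"]
  expect_identical(substr(mq, 31, 31), "G")
  expect_identical(substr(mq, 1, 30), strrep("A", 30))
  # short queries by construction
  q10 <- make_junction_queries(m, e5, e3, query_len = 20)
  mat <- q10$query[q10$kind == "mature"]
  expect_identical(mat, paste0(strrep("A", 10), strrep("C", 10)))
})

test_that("queries are substrings of their products", {
  m <- toy_model()
  e5 <- strrep("A", 40); e3 <- strrep("C", 40)
  pr <- splice_products(m, e5, e3)
  q <- make_junction_queries(m, e5, e3)
  for (k in q$kind) {
    expect_true(grepl(q$query[q$kind == k], pr[[k]]$sequence, fixed = TRUE),
                info = k)
  }
})

test_that("query construction rejects bad lengths and thin context", {
  m <- toy_model()
  expect_error(make_junction_queries(m, strrep("A", 40), strrep("C", 40),
                                     query_len = 59), "even")
  expect_error(make_junction_queries(m, strrep("A", 40), strrep("C", 40),
                                     query_len = 10), "at least 20")
  expect_error(make_junction_queries(m, strrep("A", 10), strrep("C", 40)),
               "5' side")
  expect_error(make_junction_queries(m, strrep("A", 40), strrep("C", 10)),
               "3' side")
})

test_that("missplicing always shifts the frame; 3n retention does not", {
  m <- toy_model()
  for (ph in 0:2) expect_true(assess_frameshift(m, ph))
  expect_false(assess_frameshift(m, 0, retained = 3))
  expect_false(assess_frameshift(m, 1, retained = 0))
  expect_error(assess_frameshift(m, 3), "phase")
})

test_that("missplice arithmetic holds over many random models", {
  # randomized lengths; a modest corpus here, the acceptance suite
  # quantifies over a larger one
  set.seed(77)
  for (i in 1:25) {
    tpl <- build_stwintron(internal_len = sample(40:100, 1),
                           external_len = sample(45:150, 1),
                           ntire = NULL, external_bp_dist = sample(2:20, 1))
    g <- paste0(strrep("A", 35), tpl$seq, strrep("C", 35))
    hits <- detect_stwintrons(g)
    tr <- Filter(function(m) m$plus_start == 36L &&
                   m$plus_end == 35L + nchar(tpl$seq), hits)
    expect_true(length(tr) >= 1)
    pr <- splice_products(tr[[1]], strrep("A", 35), strrep("C", 35), phase = 0)
    expect_identical(nchar(pr$pre_mRNA$sequence) - nchar(pr$misspliced$sequence),
                     nchar(tpl$seq) - 1L)
    expect_true(pr$misspliced$frameshift)
  }
})
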