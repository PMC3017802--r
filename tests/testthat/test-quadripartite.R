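plant_ir <- function(lsc_len, ir_len, ssc_len, divergence = 0, seed = 1L) {
  set.seed(seed)
  lsc <- random_dna(lsc_len)
  ir <- random_dna(ir_len)
  ssc <- random_dna(ssc_len)
  arm_a <- ir
  if (divergence > 0) {
    ch <- strsplit(arm_a, NULL)[[1L]]
    hit <- sample(ir_len, round(divergence * ir_len))
    for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    arm_a <- paste(ch, collapse = "")
  }
  list(seq = paste0(lsc, arm_a, ssc, revcomp(ir)), ir = ir)
}

test_that("a planted exact inverted repeat is recovered with its regions", {
  g <- plant_ir(5000L, 2000L, 3000L, seed = 3L)
  m <- find_inverted_repeat(g$seq, min_len = 1000L)
  expect_false(is.null(m))
  expect_equal(m$ir_length, 2000L)
  expect_equal(m$lsc_length, 5000L)
  expect_equal(m$ssc_length, 3000L)
  expect_equal(m$mismatches, 0)
  ## intervals tile the circle
  n <- nchar(g$seq)
  total <- 2L * m$ir_length + m$lsc_length + m$ssc_length
  expect_equal(total, n)
  ## arm A equals revcomp of arm B
  a <- substring(g$seq, m$ir_a$start, m$ir_a$end)
  b <- substring(g$seq, m$ir_b$start, m$ir_b$end)
  expect_equal(a, revcomp(b))
})

test_that("recovery is rotation-invariant", {
  g <- plant_ir(5000L, 2000L, 3000L, seed = 4L)
  m0 <- find_inverted_repeat(g$seq, min_len = 1000L)
  for (off in c(1L, 2500L, 7123L)) {
    rot <- paste0(substring(g$seq, off + 1L), substring(g$seq, 1L, off))
    m <- find_inverted_repeat(rot, min_len = 1000L)
    expect_equal(m$ir_length, m0$ir_length)
    expect_equal(m$lsc_length, m0$lsc_length)
    expect_equal(m$ssc_length, m0$ssc_length)
  }
})

test_that("random sequence without a planted IR yields none", {
  set.seed(19)
  expect_null(find_inverted_repeat(random_dna(20000L), min_len = 1000L))
})

test_that("planted IRs of 1-5 kb with 0-1% divergence are recovered within tolerance", {
  cases <- expand.grid(len = c(1000L, 2000L, 5000L), div = c(0, 0.01))
  for (r in seq_len(nrow(cases))) {
    len <- cases$len[r]; div <- cases$div[r]
    g <- plant_ir(6000L, len, 4000L, divergence = div, seed = 100L + r)
    m <- find_inverted_repeat(g$seq, min_len = 900L)
    expect_false(is.null(m), info = sprintf("len=%d div=%g", len, div))
    expect_lte(abs(m$ir_length - len), div * len + 10,
               label = sprintf("arm error (len=%d, div=%g)", len, div))
  }
})

test_that("detection is strand-symmetric", {
  g <- plant_ir(4000L, 1500L, 2500L, seed = 8L)
  m <- find_inverted_repeat(g$seq, min_len = 1000L)
  mr <- find_inverted_repeat(revcomp(g$seq), min_len = 1000L)
  expect_equal(mr$ir_length, m$ir_length)
  expect_equal(mr$lsc_length, m$lsc_length)
  expect_equal(mr$ssc_length, m$ssc_length)
})

test_that("per-region partition tiles the genome and recombines to whole-genome GC", {
  spec <- pt_genome_spec(seed = 21L, length = 269000L)
  g <- generate_genome(spec)
  m <- find_inverted_repeat(g)
  expect_false(is.null(m))
  expect_lte(abs(m$ir_length - spec$ir$length), 10)
  pq <- partition_quadripartite(g, m)
  expect_equal(sum(pq$length), genome_length(g))
  whole <- sum(pq$gc * pq$length) / sum(pq$length)
  expect_lt(abs(whole - gc_content(g)), 1e-6)
  ## the IR arms carry the duplicated genes, the single-copy regions the rest
  expect_equal(pq$genes[pq$region == "IRA"], pq$genes[pq$region == "IRB"])
  expect_equal(sum(pq$genes), 102L)
  expect_gt(pq$genes[pq$region == "LSC"], pq$genes[pq$region == "SSC"] - 20L)
})
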