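test_that("planted forward and reverse-complement repeats are found", {
  set.seed(1)
  motif <- "GATTACAGATTA"
  s <- paste0(random_dna(150, .4), motif, random_dna(120, .4), motif,
              random_dna(100, .4))
  m <- find_maximal_repeats(s, min_len = 12L, hamming_k = 0L, types = "F")
  expect_gte(nrow(m), 1L)
  expect_true(any(m$length >= 12L & m$mismatches == 0L))
  s2 <- paste0(random_dna(120), "GGATCCGTTAACGGA", random_dna(90),
               revcomp("GGATCCGTTAACGGA"), random_dna(60))
  m2 <- find_maximal_repeats(s2, min_len = 12L, hamming_k = 0L, types = "RC")
  expect_gte(nrow(m2), 1L)
  expect_true(any(m2$length >= 15L))
  ## every reported pair re-verifies under its type's transform
  for (r in seq_len(nrow(m2))) {
    a <- substring(s2, m2$start_a[r], m2$end_a[r])
    b <- substring(s2, m2$start_b[r], m2$end_b[r])
    d <- sum(strsplit(a, NULL)[[1L]] != strsplit(revcomp(b), NULL)[[1L]])
    expect_lte(d, m2$mismatches[r])
  }
})

test_that("finder equals the exhaustive oracle on random sequences (all types, k <= 1)", {
  for (seed in 1:3) {
    set.seed(seed * 101L)
    s <- random_dna(300L, gc = 0.35)
    for (k in 0:1) {
      got <- repeat_keys(find_maximal_repeats(s, min_len = 12L,
                                              hamming_k = k))
      want <- oracle_repeats(s, min_len = 12L, k = k)
      expect_equal(got, want, info = sprintf("seed=%d k=%d", seed, k))
    }
  }
})

test_that("repeat finding is strand-consistent under reverse complement", {
  set.seed(77)
  s <- paste0(random_dna(100), "CCTTAAGGCCTTA", random_dna(80),
              "CCTTAAGGCCTTA", random_dna(60))
  m <- find_maximal_repeats(s, min_len = 12L, hamming_k = 0L)
  mr <- find_maximal_repeats(revcomp(s), min_len = 12L, hamming_k = 0L)
  expect_equal(table(m$type), table(mr$type))
  n <- nchar(s)
  mirrored <- sort(paste(n - mr$end_b + 1L, n - mr$start_b + 1L,
                         n - mr$end_a + 1L, n - mr$start_a + 1L)[mr$type == "F"])
  original <- sort(paste(m$start_a, m$end_a, m$start_b, m$end_b)[m$type == "F"])
  expect_equal(mirrored, original)
})

test_that("min_len below seeding feasibility errors", {
  expect_error(find_maximal_repeats("ACGTACGTACGT", min_len = 3L), "min_len")
})

test_that("repeat clustering groups planted families with their statistics", {
  set.seed(12)
  fam1 <- random_dna(40, gc = 0.2)
  fam2 <- random_dna(50, gc = 0.25)
  pieces <- character(0)
  for (i in 1:5) pieces <- c(pieces, random_dna(80, .5), fam1)
  for (i in 1:5) pieces <- c(pieces, random_dna(80, .5), fam2)
  s <- paste0(paste(pieces, collapse = ""), random_dna(80, .5))
  m <- find_maximal_repeats(s, min_len = 30L, hamming_k = 0L, types = "F")
  fams <- cluster_repeats(m, s, identity = 0.8)
  expect_equal(length(fams), 2L)
  ## each family's instances cover exactly the five planted copy sites
  ## (maximal matches of variable extent multiply the instance count)
  planted1 <- which(vapply(1:(nchar(s) - 39L), function(p)
    substring(s, p, p + 39L) == fam1, NA))
  planted2 <- which(vapply(1:(nchar(s) - 49L), function(p)
    substring(s, p, p + 49L) == fam2, NA))
  site_cover <- function(f, sites, w) {
    vapply(sites, function(p)
      any(f$members$start <= p & f$members$end >= p + w - 1L), NA)
  }
  covered <- vapply(fams, function(f) {
    all(site_cover(f, planted1, 40L)) || all(site_cover(f, planted2, 50L))
  }, NA)
  expect_true(all(covered))
  expect_true(all(vapply(fams, `[[`, 0L, "size") >= 5L))
  for (f in fams) {
    ats <- 1 - vapply(f$members$seq, gc_content, 0)
    expect_equal(f$at_fraction, mean(ats))
  }
})

test_that("dotplot has a maximal self diagonal, transposes, and sees planted runs", {
  set.seed(31)
  a <- random_dna(300)
  dp <- dotplot(a, a, window = 50L)
  expect_true(all(diag(dp) == 50L))
  b <- random_dna(250)
  expect_equal(dotplot(a, b, window = 50L), t(dotplot(b, a, window = 50L)),
               ignore_attr = TRUE)
  shared <- random_dna(200)
  x <- paste0(random_dna(60), shared, random_dna(40))
  y <- paste0(random_dna(30), shared, random_dna(70))
  dxy <- dotplot(x, y, window = 50L)
  expect_gte(sum(dxy == 50L), 200L - 50L + 1L)
  expect_error(dotplot("ACGT", "ACGT", window = 50L), "window")
})
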