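test_that("hand-foldable hairpin is found; degenerate inputs yield none", {
  h <- find_hairpins("GGGAAATTTCCC", min_stem = 3L, loop_range = c(3L, 6L),
                     max_arm_mismatch = 0L)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 1L)
  expect_equal(h$end, 12L)
  expect_gte(h$stem_len, 3L)
  expect_equal(2L * h$stem_len + h$loop_len, 12L)
  ## brute-force agreement: no qualifying stem-loop in these sequences
  expect_false(oracle_has_hairpin("ACGTACGT", 3L, 3L, 6L))
  expect_equal(nrow(find_hairpins("ACGTACGT", min_stem = 3L,
                                  loop_range = c(3L, 6L),
                                  max_arm_mismatch = 0L)), 0L)
  expect_equal(nrow(find_hairpins(strrep("A", 60))), 0L)
})

test_that("every reported hairpin re-verifies its arm pairing independently", {
  set.seed(23)
  s <- random_dna(3000, .5)
  h <- find_hairpins(s, min_stem = 5L, loop_range = c(3L, 8L),
                     max_arm_mismatch = 1L)
  expect_gte(nrow(h), 1L)
  for (r in seq_len(nrow(h))) {
    left <- substring(s, h$start[r], h$start[r] + h$stem_len[r] - 1L)
    right <- substring(s, h$end[r] - h$stem_len[r] + 1L, h$end[r])
    mis <- sum(strsplit(revcomp(left), NULL)[[1L]] !=
                 strsplit(right, NULL)[[1L]])
    expect_lte(mis, 1L)
    expect_equal(mis, h$arm_mismatches[r])
    expect_equal(h$loop[r],
                 substring(s, h$start[r] + h$stem_len[r],
                           h$end[r] - h$stem_len[r]))
  }
})

## build one synthetic cluster like those in intergenic mtDNA: ~3 elements
## of 23-38 nt, ~110-nt span, ~50% GC, loops carrying TTTA/TTT
make_cluster <- function(seed) {
  set.seed(seed)
  parts <- character(0)
  truth <- 0L
  for (i in 1:3) {
    stem <- sample(8:12, 1L)
    loop <- paste0("TTTA", random_dna(sample(0:3, 1L), .5))
    arm <- random_dna(stem, .5)
    parts <- c(parts, paste0(arm, loop, revcomp(arm)))
    truth <- truth + 1L
    if (i < 3) parts <- c(parts, random_dna(sample(8:20, 1L), .5))
  }
  paste(parts, collapse = "")
}

test_that("planted clusters are recovered with correct hairpin counts at defaults", {
  set.seed(99)
  clusters <- vapply(1:4, make_cluster, "")
  gaps <- vapply(1:5, function(i) random_dna(450, .3), "")
  s <- paste0(gaps[1], clusters[1], gaps[2], clusters[2], gaps[3],
              clusters[3], gaps[4], clusters[4], gaps[5])
  ## planted spans
  pos <- 0L; spans <- list()
  for (i in 1:4) {
    pos <- pos + nchar(gaps[i])
    spans[[i]] <- c(pos + 1L, pos + nchar(clusters[i]))
    pos <- pos + nchar(clusters[i])
  }
  h <- find_hairpins(s)                      # defaults: stem 8, loop 3-12
  cl <- cluster_hairpins(h, seq = s)
  ## each planted region is recovered as one cluster holding its three
  ## elements (spurious background hairpins in the random flanks may add
  ## extra clusters and are not asserted against)
  for (sp in spans) {
    hit <- which(cl$start <= sp[2L] & cl$end >= sp[1L])
    expect_equal(length(hit), 1L)
    expect_gte(cl$n_hairpins[hit], 3L)
    expect_lte(cl$n_hairpins[hit], 5L)
    expect_lt(abs(cl$gc[hit] - 0.5), 0.2)
    expect_lt(cl$length[hit], 200L)
  }
  tally <- loop_motif_tally(h)
  expect_gte(tally[["TTTA"]] + tally[["TTT"]], 10L)
  expect_lte(sum(tally), nrow(h))
})

test_that("hairpin gap chaining follows max_gap", {
  hp <- data.frame(start = c(1L, 40L, 90L, 700L),
                   end = c(30L, 70L, 120L, 730L),
                   stem_len = 8L, loop_len = 4L, loop = "TTTA",
                   arm_mismatches = 0L, gc = 0.5)
  cl <- cluster_hairpins(hp, max_gap = 30L)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$n_hairpins, c(3L, 1L))
  expect_equal(cl$length[1L], 120L)          # span first start to last end
})

test_that("cluster consensus groups families across strands and copies", {
  set.seed(55)
  proto <- make_cluster(123)
  s <- paste0(random_dna(200, .5), proto, random_dna(200, .5), proto,
              random_dna(200, .5), revcomp(proto), random_dna(150, .5),
              proto, random_dna(100, .5))
  h <- find_hairpins(s)
  cl <- cluster_hairpins(h, seq = s)
  expect_gte(nrow(cl), 4L)
  cons <- build_consensus(cl, s, identity = 0.7)
  ## the dominant family holds the four planted copies (both strands);
  ## chance background hairpins may contribute extra singleton families
  expect_equal(cons[[1L]]$occurrences, 4L)
  ## boundary hairpin stems may extend a few bases into the flanks, so the
  ## family consensus contains the planted prototype's core on one strand
  core <- substring(proto, 4L, nchar(proto) - 3L)
  cc <- cons[[1L]]$consensus
  expect_true(grepl(core, cc, fixed = TRUE) ||
                grepl(revcomp(core), cc, fixed = TRUE))
})

test_that("a single-column difference produces the IUPAC ambiguity code", {
  a <- "GGGGAAATTTCCCC"
  b <- sub("AAA", "ACA", a)
  cl <- data.frame(start = c(1L, 21L), end = c(14L, 34L))
  s <- paste0(a, "AATTAA", b, "AATT")
  cons <- build_consensus(cl, s, identity = 0.7)
  expect_equal(length(cons), 1L)
  cc <- cons[[1L]]$consensus
  expect_equal(nchar(cc), 14L)
  expect_true(grepl("M", cc) || grepl("K", cc))   # A/C tie (either strand)
})

test_that("loop motif tally prefers the longest motif and never double counts", {
  hp <- data.frame(loop = c("TTTA", "GGG", "TTTC"))
  tl <- loop_motif_tally(hp)
  expect_equal(unname(tl["TTTA"]), 1L)
  expect_equal(unname(tl["TTT"]), 1L)
  expect_equal(unname(sum(loop_motif_tally(data.frame(loop = character(0))))),
               0L)
})
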