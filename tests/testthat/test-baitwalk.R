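test_that("recruitment recovers planted fragments, both strands, archive-order invariant", {
  set.seed(41)
  bait <- random_dna(3000, .4)
  frags <- vapply(1:20, function(i) {
    st <- sample(1:(3000 - 800), 1L)
    substring(bait, st, st + 799L)
  }, "")
  frags[seq(2, 20, 2)] <- vapply(frags[seq(2, 20, 2)], revcomp, "",
                                 USE.NAMES = FALSE)
  noise <- vapply(1:20, function(i) random_dna(800, .4), "")
  ar <- trace_archive(stats::setNames(c(frags, noise),
                                      sprintf("t%02d", 1:40)))
  hits <- recruit_traces(ar, c(b = bait))
  expect_equal(sort(hits$trace_id), sprintf("t%02d", 1:20))
  expect_true(all(hits$identity > 0.99))
  expect_setequal(unique(hits$strand), c("+", "-"))
  ## shuffled archive gives the same hit set
  hits2 <- recruit_traces(ar[rev(seq_len(nrow(ar))), ], c(b = bait))
  expect_equal(sort(hits2$trace_id), sort(hits$trace_id))
})

test_that("recruitment threshold separates 15% from 25% diverged traces", {
  set.seed(43)
  bait <- random_dna(2000, .4)
  mutate_at <- function(s, rate) {
    ch <- strsplit(s, NULL)[[1L]]
    hit <- which(runif(length(ch)) < rate)
    for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    paste(ch, collapse = "")
  }
  t15 <- vapply(1:5, function(i)
    mutate_at(substring(bait, 301, 1100), 0.15), "")
  t25 <- vapply(1:5, function(i)
    mutate_at(substring(bait, 301, 1100), 0.25), "")
  ar <- trace_archive(stats::setNames(c(t15, t25),
                                      c(paste0("lo", 1:5), paste0("hi", 1:5))))
  hits <- recruit_traces(ar, c(b = bait))
  expect_true(all(paste0("lo", 1:5) %in% hits$trace_id))
  expect_false(any(paste0("hi", 1:5) %in% hits$trace_id))
})

test_that("error-free tiling traces assemble into the exact source", {
  set.seed(47)
  src <- random_dna(5000, .4)
  starts <- seq(1L, 4001L, by = 500L)      # 1100-nt reads, 600-nt overlaps
  reads <- substring(src, starts, pmin(starts + 1099L, 5000L))
  names(reads) <- sprintf("r%02d", seq_along(reads))
  ctgs <- assemble(trace_archive(reads))
  expect_equal(length(ctgs), 1L)
  expect_equal(ctgs[[1L]]$consensus, src)
  expect_equal(nrow(ctgs[[1L]]$layout), length(reads))
  cov <- colSums(ctgs[[1L]]$counts[1:4, ])
  expect_true(all(cov >= 1L))
})

test_that("overlaps below min_overlap are not merged", {
  set.seed(48)
  src <- random_dna(1600, .4)
  a <- substring(src, 1, 1000)
  b <- substring(src, 601, 1600)           # 400-nt overlap < 500
  ctgs <- assemble(trace_archive(c(x = a, y = b)))
  expect_equal(length(ctgs), 2L)
})

test_that("noisy deep coverage assembles to a near-perfect consensus", {
  g <- annotated_genome("src", random_dna(10000, .4), circular = FALSE)
  ar <- shred_traces(g, shred_spec(coverage = 20, error_rate = 0.01,
                                   read_length_mean = 900,
                                   read_length_sd = 50, seed = 50L))
  ## linear source: use the whole archive directly
  ctgs <- suppressWarnings(assemble(ar))
  best <- ctgs[[1L]]
  ev <- evaluate_assembly(best, g, ar)
  ## the uncovered extreme ends of a linear source bound identity slightly
  ## below the consensus accuracy of the deep-coverage interior
  expect_gte(ev$identity, 0.99)
  expect_equal(ev$purity, 1)
  expect_gt(ev$mean_coverage, 15)
})

test_that("circular closure trims, canonicalizes, and respects thresholds", {
  set.seed(53)
  src <- random_dna(10000, .4)
  ctg <- organellarch:::new_contig("c1", paste0(src, substring(src, 1, 600)))
  cc <- detect_circularity(ctg)
  expect_true(cc$circular)
  expect_equal(nchar(cc$consensus), 10000L)
  ## short end overlap stays linear
  ctg2 <- organellarch:::new_contig("c2", paste0(src, substring(src, 1, 300)))
  expect_false(detect_circularity(ctg2)$circular)
  ## canonical rotation is invariant to where the circle was cut
  refs <- vapply(sample(1:9999, 5L), function(cut) {
    rot <- paste0(substring(src, cut + 1L), substring(src, 1L, cut))
    ct <- organellarch:::new_contig("c", paste0(rot, substring(rot, 1, 600)))
    detect_circularity(ct)$consensus
  }, "")
  expect_equal(length(unique(refs)), 1L)
  expect_equal(refs[1L], detect_circularity(ctg)$consensus)
})

test_that("walk with max_rounds = 0 returns contigs unchanged and fixpoints hold", {
  set.seed(59)
  src <- random_dna(6000, .4)
  reads <- substring(src, seq(1L, 3001L, 600L), seq(1L, 3001L, 600L) + 999L)
  names(reads) <- sprintf("w%02d", seq_along(reads))
  ar <- trace_archive(reads)
  ctgs <- assemble(ar)
  expect_identical(walk(ar, ctgs, max_rounds = 0L), ctgs)
  ## nothing recruitable beyond the already-used reads: unchanged after one round
  w1 <- walk(ar, ctgs, max_rounds = 3L)
  expect_equal(nchar(w1[[1L]]$consensus), nchar(ctgs[[1L]]$consensus))
})

test_that("mean coverage is total trace length over consensus length and purity drops with numt-like decoys", {
  set.seed(61)
  src <- random_dna(4000, .4)
  reads <- substring(src, seq(1L, 3001L, 500L), seq(1L, 3001L, 500L) + 999L)
  names(reads) <- sprintf("v%02d", seq_along(reads))
  ctgs <- assemble(trace_archive(reads))
  ev <- evaluate_assembly(ctgs[[1L]], src)
  expect_equal(ev$mean_coverage, sum(nchar(reads)) / nchar(ctgs[[1L]]$consensus))
  ## a nuclear decoy carrying an organelle-like insertion gets recruited
  g <- annotated_genome("t", random_dna(8000, .4), circular = TRUE)
  ins <- substring(g$sequence, 2001, 2800)
  ar <- shred_traces(g, shred_spec(coverage = 15, error_rate = 0.01,
                                   nuclear_background = 4,
                                   decoy_length = 4000L,
                                   decoy_insert = ins, seed = 62L))
  hits <- recruit_traces(ar, c(b = substring(g$sequence, 1501, 3500)))
  rec <- ar[ar$id %in% hits$trace_id, ]
  expect_true(any(rec$origin == "nuclear"))
  purity <- mean(rec$origin == "organelle")
  expect_lt(purity, 1)
  expect_gt(purity, 0.5)
})
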