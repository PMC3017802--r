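test_that("identical specs generate byte-identical genomes", {
  g1 <- generate_genome(mt_genome_spec(seed = 7L, length = 12000L,
                                       gene_introns = 6L,
                                       palindromes = list(regions = 4L)))
  g2 <- generate_genome(mt_genome_spec(seed = 7L, length = 12000L,
                                       gene_introns = 6L,
                                       palindromes = list(regions = 4L)))
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$features, g2$features)
  g3 <- generate_genome(mt_genome_spec(seed = 8L, length = 12000L,
                                       gene_introns = 6L,
                                       palindromes = list(regions = 4L)))
  expect_false(identical(g1$sequence, g3$sequence))
})

test_that("generated architecture matches the requested fractions and counts", {
  spec <- mt_genome_spec(seed = 15L)
  g <- generate_genome(spec)
  expect_equal(genome_length(g), spec$length)
  p <- partition_genome(g)
  expect_lt(abs(p$fractions[["coding"]] - spec$coding_frac), 0.01)
  expect_lt(abs(p$fractions[["intronic"]] - spec$intronic_frac), 0.01)
  expect_lt(abs(p$fractions[["noncoding"]] - 0.58), 0.01)
  expect_equal(intron_gene_ratio(g), 18 / 12)
  inv <- gene_inventory(g)
  expect_equal(inv$counts$dedup, c(7L, 2L, 3L))
  expect_equal(unname(inv$fragments[c("rrns", "rrnl")]), c(3L, 6L))
  ## all genes on one strand
  strands <- vapply(Filter(function(f) f$kind == "gene", g$features),
                    function(f) f$strand, "")
  expect_true(all(strands == "+"))
})

test_that("category GC follows the spec targets", {
  g <- generate_genome(mt_genome_spec(seed = 16L))
  gc <- gc_by_category(g)
  expect_lt(abs(gc[["intron"]] - 0.34), 0.03)
  expect_lt(abs(gc[["intergenic"]] - 0.37), 0.03)
  expect_lt(abs(gc[["overall"]] - 0.344), 0.02)
  codon <- gc_by_codon_position(g)
  expect_lt(max(abs(codon - c(0.38, 0.38, 0.19))), 0.03)
})

test_that("a requested inverted repeat is planted and detectable", {
  spec <- genome_spec(length = 24000L, seed = 33L, coding_frac = 0.3,
                      intronic_frac = 0.1,
                      genes = data.frame(
                        name = c(paste0("g", 1:8), "rrs", "trnA"),
                        class = c(rep("protein", 8L), "rRNA", "tRNA"),
                        strand = "+", fragments = 1L,
                        length = c(rep(NA_real_, 8L), 900, 75)),
                      gene_introns = 4L,
                      ir = list(length = 2000L, genes = c("rrs", "trnA"),
                                introns = 0L))
  g <- generate_genome(spec)
  m <- find_inverted_repeat(g, min_len = 1000L)
  expect_false(is.null(m))
  expect_lte(abs(m$ir_length - 2000L), 10)
  ## duplicated genes appear twice, once per arm
  inv <- gene_inventory(g)
  expect_equal(sum(inv$counts$with_dup) - sum(inv$counts$dedup), 2L)
})

test_that("infeasible packing fails with a budget error", {
  spec <- genome_spec(length = 2000L, seed = 1L, coding_frac = 0.9,
                      intronic_frac = 0.05,
                      genes = data.frame(name = c("a", "b"),
                                         class = "rRNA", strand = "+",
                                         fragments = 1L, length = 1500))
  expect_error(generate_genome(spec), "infeasible|budget")
})

test_that("shredding honours coverage, wraps the origin, and is exact at zero error", {
  g <- generate_genome(mt_genome_spec(seed = 9L, length = 15000L,
                                      gene_introns = 8L,
                                      palindromes = list(regions = 6L)))
  ar <- shred_traces(g, shred_spec(coverage = 30, error_rate = 0,
                                   read_length_mean = 750, seed = 10L))
  realized <- sum(nchar(ar$sequence)) / genome_length(g)
  expect_lt(abs(realized - 30) / 30, 0.1)
  dbl <- paste0(g$sequence, g$sequence)
  dbl_rc <- revcomp(dbl)
  hits <- vapply(ar$sequence[1:100], function(s) {
    grepl(s, dbl, fixed = TRUE) || grepl(s, dbl_rc, fixed = TRUE)
  }, NA)
  expect_true(all(hits))
  ## some read spans the origin
  tail_hit <- vapply(ar$sequence, function(s) {
    (grepl(s, dbl, fixed = TRUE) && !grepl(s, g$sequence, fixed = TRUE)) ||
      (grepl(s, dbl_rc, fixed = TRUE) &&
         !grepl(s, revcomp(g$sequence), fixed = TRUE))
  }, NA)
  expect_gte(sum(tail_hit), 1L)
})

test_that("toy fixture matches its hand-computed statistics and survives round trip", {
  tf <- toy_fixture()
  p <- partition_genome(tf$genome)
  expect_equal(p$coding_nt, tf$partition$coding_nt)
  expect_equal(p$noncoding_nt, tf$partition$noncoding_nt)
  expect_equal(p$intergenic_nt, tf$partition$intergenic_nt)
  expect_equal(p$intronic_nt, tf$partition$intronic_nt)
  expect_equal(intron_gene_ratio(tf$genome), tf$intron_gene_ratio)
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(tf$genome, path)
  g2 <- read_genbank(path)
  p2 <- partition_genome(g2)
  expect_equal(p2$coding_nt, p$coding_nt)
  expect_equal(p2$intronic_nt, p$intronic_nt)
})
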