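test_that("toy partition follows the accounting definitions exactly", {
  tf <- toy_fixture()
  p <- partition_genome(tf$genome)
  expect_equal(p$coding_nt, 750L)
  expect_equal(p$noncoding_nt, 750L)
  expect_equal(p$intergenic_nt, 630L)
  expect_equal(p$intronic_nt, 120L)
  expect_equal(p$coding_nt + p$noncoding_nt, p$genome_length)
  expect_equal(p$intergenic_nt + p$intronic_nt, p$noncoding_nt)
})

test_that("overlapping coding annotations are not double counted", {
  s <- random_dna(1000, .5)
  g <- annotated_genome("ov", s, circular = FALSE, features = list(
    feature("gene", "g1", "+", feature_parts(101L, 400L)),
    feature("CDS", "g1", "+", feature_parts(101L, 400L)),
    feature("gene", "g2", "+", feature_parts(351L, 650L)),
    feature("CDS", "g2", "+", feature_parts(351L, 650L))))
  p <- partition_genome(g)
  o <- oracle_partition(g)
  expect_equal(p$coding_nt, o$coding_nt)
  expect_equal(p$coding_nt, 550L)          # union, overlap counted once
  expect_equal(p$intergenic_nt, o$intergenic_nt)
})

test_that("partition agrees with the per-position oracle and is rotation-invariant", {
  for (seed in 1:5) {
    g <- random_annotated_genome(L = 4000L, n_genes = 4L, seed = seed)
    p <- partition_genome(g)
    o <- oracle_partition(g)
    expect_equal(p$coding_nt, o$coding_nt)
    expect_equal(p$intergenic_nt, o$intergenic_nt)
    expect_equal(p$intronic_nt, o$intronic_nt)
    g2 <- rotate_genome(g, 1234L)
    p2 <- partition_genome(g2)
    expect_equal(p2$coding_nt, p$coding_nt)
    expect_equal(p2$intronic_nt, p$intronic_nt)
  }
})

test_that("gc_content handles simple cases, N bases, and revcomp symmetry", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("AAAA"), 0)
  expect_equal(gc_content("GCNN"), 1)        # N excluded both sides
  expect_error(gc_content("NNNN"), "undefined|all-N")
  set.seed(7)
  for (i in 1:10) {
    s <- random_dna(200, runif(1))
    expect_equal(gc_content(s), gc_content(revcomp(s)))
  }
})

test_that("codon-position GC is hand-countable and strand/order invariant", {
  g <- annotated_genome("c", "ATGGCC", features = list(
    feature("CDS", "x", "+", feature_parts(1L, 6L))))
  expect_equal(unname(gc_by_codon_position(g)), c(0.5, 0.5, 1.0))
  ## minus-strand CDS equals the same CDS on the revcomp genome's plus strand
  set.seed(3)
  cds <- random_dna(300, .45)
  pad <- random_dna(50, .3)
  gp <- annotated_genome("p", paste0(pad, cds, pad), features = list(
    feature("CDS", "x", "+", feature_parts(51L, 350L))))
  gm <- annotated_genome("m", paste0(revcomp(pad), revcomp(cds), revcomp(pad)),
                         features = list(
    feature("CDS", "x", "-", feature_parts(51L, 350L))))
  expect_equal(gc_by_codon_position(gm), gc_by_codon_position(gp))
  ## concatenation order of two CDSs does not matter
  g2 <- annotated_genome("o", paste0(pad, cds, pad, cds, pad), features = list(
    feature("CDS", "a", "+", feature_parts(51L, 350L)),
    feature("CDS", "b", "+", feature_parts(401L, 700L))))
  expect_equal(gc_by_codon_position(g2), gc_by_codon_position(gp))
})

test_that("cumulative GC-skew matches hand computation and symmetry", {
  s <- cumulative_gc_skew("GGGGCCCC", window = 4L, step = 4L)
  expect_equal(s$skew, c(1, -1))
  expect_equal(s$cumulative, c(1, 0))
  z <- cumulative_gc_skew(strrep("A", 100), window = 10L, step = 10L)
  expect_true(all(z$skew == 0) && all(z$cumulative == 0))
  ## windows of the reverse complement, read back-to-front, negate
  set.seed(11)
  x <- random_dna(400, .5)
  a <- cumulative_gc_skew(x, window = 50L, step = 50L)
  b <- cumulative_gc_skew(revcomp(x), window = 50L, step = 50L)
  expect_equal(rev(-b$skew), a$skew)
})

test_that("intron/gene ratio counts fragments once and handles edge cases", {
  tf <- toy_fixture()
  expect_equal(intron_gene_ratio(tf$genome), 2 / 3)
  ## excluding intergenic introns drops the free-standing one
  expect_equal(intron_gene_ratio(tf$genome,
                                 include_intergenic_introns = FALSE), 1 / 3)
  nogene <- annotated_genome("n", random_dna(500))
  expect_error(intron_gene_ratio(nogene), "no genes")
})

test_that("gene inventory reports duplicates and fragments", {
  s <- random_dna(2000, .4)
  g <- annotated_genome("inv", s, features = list(
    feature("CDS", "cob", "+", feature_parts(1L, 300L)),
    feature("CDS", "nad4", "+", feature_parts(401L, 700L)),
    feature("tRNA", "trnM", "+", feature_parts(801L, 870L)),
    feature("tRNA", "trnM", "+", feature_parts(901L, 970L)),
    feature("rRNA", "rrnl_L1", "+", feature_parts(1001L, 1100L)),
    feature("rRNA", "rrnl_L2", "+", feature_parts(1201L, 1300L)),
    feature("rRNA", "rrnl_L3", "+", feature_parts(1401L, 1500L))))
  inv <- gene_inventory(g)
  cts <- inv$counts
  expect_equal(cts$with_dup[cts$class == "protein"], 2L)
  expect_equal(cts$with_dup[cts$class == "tRNA"], 2L)
  expect_equal(cts$dedup[cts$class == "tRNA"], 1L)
  expect_equal(cts$with_dup[cts$class == "rRNA"], 1L)   # one fragmented gene
  expect_equal(unname(inv$fragments["rrnl"]), 3L)
})

test_that("gene-set comparison partitions the name universe", {
  cells <- gene_set_compare(list(A = c("cob", "nad4"), B = c("cob", "trnM")))
  expect_equal(cells[["A+B"]], "cob")
  expect_equal(cells[["A"]], "nad4")
  expect_equal(cells[["B"]], "trnM")
  same <- gene_set_compare(list(X = c("a", "b"), Y = c("a", "b")))
  expect_equal(names(same), "X+Y")
  ## disjoint cells unioning to the universe, on random inputs
  set.seed(5)
  universe <- paste0("gene", 1:20)
  invs <- lapply(1:3, function(i) sample(universe, 12))
  names(invs) <- c("P", "Q", "R")
  cells <- gene_set_compare(invs)
  all_names <- unname(unlist(cells))
  expect_equal(sort(all_names), sort(unique(unlist(invs))))
  expect_equal(anyDuplicated(all_names), 0L)
})
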