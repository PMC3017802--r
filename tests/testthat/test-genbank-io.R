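fixture_path <- system.file("extdata", "toy_mt_synthetic.gb",
                            package = "organellarch")

test_that("GenBank fixture parses with typed features, strands and wraps", {
  g <- read_genbank(fixture_path)
  expect_s3_class(g, "AnnotatedGenome")
  expect_true(g$circular)
  expect_equal(genome_length(g), 1500L)
  kinds <- vapply(g$features, function(f) f$kind, "")
  expect_equal(sum(kinds == "gene"), 4L)       # orfX is typed pseudogene
  expect_equal(sum(kinds == "pseudogene"), 1L)
  expect_equal(sum(kinds == "intron"), 2L)
  expect_equal(sum(kinds == "repeat_region"), 1L)
  cds <- Filter(function(f) f$kind == "CDS", g$features)[[1L]]
  expect_equal(cds$parts$start, c(101L, 401L))
  expect_equal(cds$parts$end, c(280L, 700L))
  trn <- Filter(function(f) f$kind == "tRNA", g$features)[[1L]]
  expect_equal(trn$strand, "-")
  ## join(1451..1500,1..40) on a circular record becomes one wrapping part
  psi <- Filter(function(f) f$kind == "pseudogene", g$features)[[1L]]
  expect_equal(nrow(psi$parts), 1L)
  expect_true(psi$parts$wraps[1L])
  expect_equal(nchar(extract_seq(g, psi$parts$start[1L], psi$parts$end[1L],
                                 wraps = TRUE)), 90L)
})

test_that("fixture sequence and accounting match the in-code toy genome", {
  g <- read_genbank(fixture_path)
  tf <- toy_fixture()
  expect_equal(g$sequence, tf$genome$sequence)
  p <- partition_genome(g)
  expect_equal(p$coding_nt, tf$partition$coding_nt)
  expect_equal(p$intergenic_nt, tf$partition$intergenic_nt)
  expect_equal(p$intronic_nt, tf$partition$intronic_nt)
  expect_equal(intron_gene_ratio(g), tf$intron_gene_ratio)
})

test_that("write_genbank/read_genbank round-trips features exactly", {
  g <- toy_fixture()$genome
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, path)
  g2 <- read_genbank(path)
  expect_equal(g2$sequence, g$sequence)
  expect_equal(g2$circular, g$circular)
  expect_equal(length(g2$features), length(g$features))
  for (i in seq_along(g$features)) {
    expect_equal(g2$features[[i]]$kind, g$features[[i]]$kind)
    expect_equal(g2$features[[i]]$strand, g$features[[i]]$strand)
    expect_equal(g2$features[[i]]$parts$start, g$features[[i]]$parts$start)
    expect_equal(g2$features[[i]]$parts$end, g$features[[i]]$parts$end)
  }
})

test_that("coordinates beyond the sequence raise a named error", {
  bad <- c("LOCUS       X 100 bp DNA circular",
           "FEATURES             Location/Qualifiers",
           "     gene            50..150",
           '                     /gene="oops"',
           "ORIGIN",
           paste0("        1 ", paste(rep("acgtacgtac", 10), collapse = " ")),
           "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(bad, path)
  expect_error(read_genbank(path), "oops|beyond")
})

test_that("FASTA reading enforces the alphabet and preserves order", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">b", "acgta", ">a", "GGGTT"), path)
  s <- read_fasta(path)
  expect_equal(names(s), c("b", "a"))
  expect_equal(unname(s[1L]), "ACGTA")
  writeLines(c(">u", "ACGU"), path)
  expect_error(read_fasta(path), "non-ACGTN")
  expect_equal(unname(read_fasta(path, map_to_N = TRUE)), "ACGN")
})

test_that("extract_seq handles strand and circular wrap", {
  g <- annotated_genome("x", "ACGTAC", circular = TRUE)
  expect_equal(extract_seq(g, 2, 4), "CGT")
  expect_equal(extract_seq(g, 2, 4, strand = "-"), "ACG")
  expect_equal(extract_seq(g, 5, 2, wraps = TRUE), "ACAC")
  lin <- annotated_genome("y", "ACGTAC", circular = FALSE)
  expect_error(extract_seq(lin, 5, 2, wraps = TRUE), "linear")
})

test_that("minus-strand extraction is the reverse complement of plus", {
  set.seed(42)
  for (rep_i in 1:10) {
    s <- random_dna(80)
    g <- annotated_genome("r", s, circular = TRUE)
    st <- sample(1:70, 1L); en <- st + sample(1:9, 1L)
    expect_equal(extract_seq(g, st, en, strand = "-"),
                 revcomp(extract_seq(g, st, en, strand = "+")))
  }
})

test_that("GFF3 and BED writers split wrapping parts at the origin", {
  g <- read_genbank(fixture_path)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(g, gff)
  lines <- readLines(gff)
  expect_equal(lines[1L], "##gff-version 3")
  body <- lines[!startsWith(lines, "#")]
  expect_gte(length(body), length(g$features))
  ## the wrapping pseudogene emits two segments
  psi <- grep("orfX", body, value = TRUE)
  expect_equal(length(psi), 2L)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(data.frame(start = c(10L, 1451L), end = c(20L, 40L),
                       wraps = c(FALSE, TRUE), name = c("a", "b")),
            "toy", bed, L = 1500L)
  rows <- read.table(bed, sep = "\t")
  expect_equal(rows$V2[1L], 9L)        # 0-based half-open at the boundary
  expect_equal(rows$V3[1L], 20L)
  expect_equal(nrow(rows), 3L)
})
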