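## Synthetic annotated organelle genomes and simulated trace archives.
##
## The generator plants, with exact length budgeting, the architectural
## features the analysis modules measure: single-strand or mixed-strand gene
## sets (optionally fragmented into coding modules), group-I/II-like introns
## inside genes (optionally hosting intronic ORFs) and between genes, a
## large inverted repeat duplicating its genes and introns, AT-rich
## dispersed repeat families, GC-balanced palindromic hairpin clusters, and
## pseudogene fragments. Coding and intronic nucleotide totals are met by
## construction, so the accounting statistics recover the spec fractions up
## to rounding; intergenic filler GC is solved so the category GC targets
## are met in expectation. All randomness flows from the spec seed.

#' Construct a synthetic genome specification
#'
#' @param length Genome length in nt.
#' @param seed Mandatory RNG seed; identical specs generate byte-identical
#'   genomes.
#' @param id Genome identifier.
#' @param circular Mapping conformation (default `TRUE`).
#' @param coding_frac,intronic_frac Target fractions of genome length for
#'   coding and (genic) intronic DNA; intergenic is the remainder.
#' @param genes Data frame with columns `name`, `class`
#'   (`protein`/`rRNA`/`tRNA`), `strand`, `fragments` (coding modules, 1 =
#'   unfragmented) and `length` (`NA` for protein genes, whose length is
#'   solved from the coding budget).
#' @param gene_introns Number of introns distributed over non-IR protein
#'   genes.
#' @param intronic_orfs Number of genic introns that host an intronic ORF.
#' @param intergenic_introns Number of free-standing introns planted between
#'   genes.
#' @param intergenic_intron_len Length of each intergenic intron (drawn from
#'   the intergenic budget).
#' @param ir `list(length, genes, introns, lsc_length, ssc_length)`: inverted
#'   repeat arm length (0 = none), the gene names duplicated in the arm, the
#'   number of introns per arm, and the two single-copy region lengths.
#' @param palindromes `list(regions, per_cluster, stem, loop, gap, gc,
#'   families)` describing planted hairpin clusters.
#' @param repeats `list(families, copies, len, at)` describing dispersed
#'   repeat families.
#' @param pseudogenes Number of pseudogene fragments planted in intergenic
#'   DNA.
#' @param gc `list(codon, rna, intron, intergenic)`: GC targets — per codon
#'   position for protein genes, and per category otherwise.
#' @return A `GenomeSpec` list.
#' @export
genome_spec <- function(length, seed, id = "synth", circular = TRUE,
                        coding_frac = 0.42, intronic_frac = 0.285,
                        genes = NULL,
                        gene_introns = 0L, intronic_orfs = 0L,
                        intergenic_introns = 0L,
                        intergenic_intron_len = 800L,
                        ir = list(length = 0L),
                        palindromes = list(regions = 0L),
                        repeats = list(families = 0L),
                        pseudogenes = 0L,
                        gc = list(codon = c(0.38, 0.38, 0.19), rna = 0.33,
                                  intron = 0.34, intergenic = 0.37)) {
  stopifnot(!missing(seed), length > 0)
  if (is.null(genes)) {
    genes <- data.frame(name = c("geneA", "geneB"),
                        class = "protein", strand = "+",
                        fragments = 1L, length = NA_real_)
  }
  defaults_pal <- list(regions = 0L, per_cluster = 3L, stem = c(8L, 12L),
                       loop = c(4L, 7L), gap = c(5L, 25L), gc = 0.5,
                       families = 6L)
  defaults_rep <- list(families = 0L, copies = 10L, len = c(30L, 60L),
                       at = c(0.7, 0.9))
  defaults_ir <- list(length = 0L, genes = character(0), introns = 0L,
                      lsc_length = NULL, ssc_length = NULL)
  spec <- list(id = id, length = as.integer(length), circular = circular,
               seed = as.integer(seed),
               coding_frac = coding_frac, intronic_frac = intronic_frac,
               genes = genes, gene_introns = as.integer(gene_introns),
               intronic_orfs = as.integer(intronic_orfs),
               intergenic_introns = as.integer(intergenic_introns),
               intergenic_intron_len = as.integer(intergenic_intron_len),
               ir = utils::modifyList(defaults_ir, ir),
               palindromes = utils::modifyList(defaults_pal, palindromes),
               repeats = utils::modifyList(defaults_rep, repeats),
               pseudogenes = as.integer(pseudogenes), gc = gc)
  class(spec) <- "GenomeSpec"
  spec
}

#' Mitochondrial-style genome specification
#'
#' Defaults emulate a compact circular chlamydomonadalean-type mtDNA:
#' 28.3 kb, 12 genes on one strand (7 protein, 2 fragmented rRNAs with 3 and
#' 6 coding modules, 3 tRNAs), 18 group-I-like introns (2 with intronic
#' ORFs), 58% noncoding (28.5% intronic, 29.5% intergenic), 18 palindromic
#' hairpin cluster regions, sparse dispersed repeats, and the region/codon
#' GC structure of such genomes (coding 33%, introns 34%, intergenic 37%;
#' codon positions 38/38/19%).
#'
#' @param seed RNG seed.
#' @param length Genome length (default 28300).
#' @param ... Overrides passed to [genome_spec()].
#' @return A `GenomeSpec`.
#' @export
mt_genome_spec <- function(seed, length = 28300L, ...) {
  genes <- data.frame(
    name = c("cob", "cox1", "nad1", "nad2", "nad4", "nad5", "nad6",
             "rrns", "rrnl", "trnM", "trnQ", "trnW"),
    class = c(rep("protein", 7L), "rRNA", "rRNA", rep("tRNA", 3L)),
    strand = "+",
    fragments = c(rep(1L, 7L), 3L, 6L, rep(1L, 3L)),
    length = c(rep(NA_real_, 7L), 1200, 2400, 75, 75, 75))
  args <- list(length = length, seed = seed, id = "synth_mt",
               coding_frac = 0.42, intronic_frac = 0.285,
               genes = genes, gene_introns = 18L, intronic_orfs = 2L,
               palindromes = list(regions = 18L, per_cluster = 3L,
                                  families = 6L, gc = 0.5),
               repeats = list(families = 2L, copies = 3L),
               gc = list(codon = c(0.38, 0.38, 0.19), rna = 0.33,
                         intron = 0.34, intergenic = 0.37))
  do.call(genome_spec, utils::modifyList(args, list(...)))
}

#' Plastid-style genome specification
#'
#' Defaults emulate an inflated circular chlamydomonadalean-type ptDNA:
#' 269 kb with a 14.4-kb inverted repeat pair separating 127.3-kb and
#' 112.9-kb single-copy regions, 97 unique genes (66 protein, 3 rRNA, 28
#' tRNA; 5 duplicated in the IR for 102 total), 43 introns (11 duplicated in
#' the IR, 7 intergenic), 17 intronic ORFs, 3 pseudogene fragments, ~100
#' AT-rich dispersed repeat families, 65.5% noncoding (13.5% genic-intronic,
#' 52% intergenic), and codon GC 42/52/13%.
#'
#' @param seed RNG seed.
#' @param length Genome length (default 269000); single-copy region lengths
#'   scale when overridden.
#' @param ... Overrides passed to [genome_spec()].
#' @return A `GenomeSpec`.
#' @export
pt_genome_spec <- function(seed, length = 269000L, ...) {
  protein_names <- c("psaA", "psbA", "psbB", "psbC", "psbD", "rbcL", "atpA",
                     "atpB", "atpE", "atpF", "atpH", "atpI", "petA", "petB",
                     "petD", "rpoA", "rpoB", "rpoC1", "rpoC2", "rps2",
                     "rps3", "rps4", "rps7", "rps8", "rps9", "rps11",
                     "rps12", "rps14", "rps18", "rps19", "rpl2", "rpl5",
                     "rpl14", "rpl16", "rpl20", "rpl23", "rpl36", "ycf1",
                     "ycf3", "ycf4", "cemA", "ccsA", "chlB", "chlL", "chlN",
                     "clpP", "ftsH", "tufA", "infA", "psaB", "psaC", "psaJ",
                     "psbE", "psbF", "psbH", "psbI", "psbJ", "psbK", "psbL",
                     "psbM", "psbN", "psbT", "psbZ", "petG", "petL", "minD")
  stopifnot(length(protein_names) == 66L)
  trna <- paste0("trn", c("A", "C", "D", "E1", "E2", "F", "G", "H", "I1",
                          "I2", "I3", "K", "L1", "L2", "M1", "M2", "N", "P",
                          "Q", "R1", "R2", "S1", "S2", "T", "V", "W", "Y",
                          "fM"))
  stopifnot(length(trna) == 28L)
  genes <- rbind(
    data.frame(name = protein_names, class = "protein", strand = NA,
               fragments = 1L, length = NA_real_),
    data.frame(name = c("rrs", "rrl", "rrn5"), class = "rRNA", strand = NA,
               fragments = 1L, length = c(1500, 2900, 120)),
    data.frame(name = trna, class = "tRNA", strand = NA, fragments = 1L,
               length = 75))
  scale <- length / 269000
  args <- list(length = length, seed = seed, id = "synth_pt",
               coding_frac = 0.345, intronic_frac = 0.135,
               genes = genes, gene_introns = 14L, intronic_orfs = 17L,
               intergenic_introns = 7L, intergenic_intron_len = 800L,
               ir = list(length = as.integer(round(14400 * scale)),
                         genes = c("rrs", "rrn5", "trnI1", "trnA", "chlN"),
                         introns = 11L,
                         lsc_length = as.integer(round(127300 * scale)),
                         ssc_length = NULL),
               palindromes = list(regions = 0L),
               repeats = list(families = 100L, copies = 10L,
                              len = c(30L, 60L), at = c(0.7, 0.9)),
               pseudogenes = 3L,
               gc = list(codon = c(0.42, 0.52, 0.13), rna = 0.34,
                         intron = 0.32, intergenic = 0.31))
  do.call(genome_spec, utils::modifyList(args, list(...)))
}

## random DNA with per-codon-position GC (length must be multiple of 3)
random_cds <- function(n_codons, codon_gc) {
  pos_seq <- function(p) random_dna(n_codons, codon_gc[p])
  cols <- lapply(1:3, function(p) dna_chars(pos_seq(p)))
  paste(c(rbind(cols[[1L]], cols[[2L]], cols[[3L]])), collapse = "")
}

## shift local features by an offset
shift_features <- function(features, offset) {
  lapply(features, function(f) {
    f$parts$start <- as.integer(f$parts$start + offset)
    f$parts$end <- as.integer(f$parts$end + offset)
    f
  })
}

## mirror local features of a block of length n (strand flip)
flip_features <- function(features, n) {
  lapply(features, function(f) {
    s <- n - f$parts$end + 1L
    e <- n - f$parts$start + 1L
    ord <- order(s)
    f$parts <- feature_parts(s[ord], e[ord])
    f$strand <- if (f$strand == "+") "-" else "+"
    f
  })
}

## one gene block: list(seq, features (local 1-based), coding_len)
build_gene_block <- function(name, class, strand, coding_len, intron_lens,
                             orf_flags, gc) {
  feats <- list()
  if (class == "protein") {
    n_codons <- coding_len %/% 3L
    cds <- random_cds(n_codons, gc$codon)
    k <- length(intron_lens)
    if (k > 0L) {
      ## cut between codons, keeping >= 30 nt terminal exons
      lo <- max(10L, 10L); hi <- n_codons - 10L
      cuts <- sort(sample(lo:hi, k)) * 3L
      exon_seqs <- substring(cds, c(1L, cuts + 1L),
                             c(cuts, nchar(cds)))
      pieces <- character(0)
      pos <- 0L
      exon_parts <- NULL
      for (e in seq_along(exon_seqs)) {
        pieces <- c(pieces, exon_seqs[e])
        exon_parts <- rbind(exon_parts,
                            c(pos + 1L, pos + nchar(exon_seqs[e])))
        pos <- pos + nchar(exon_seqs[e])
        if (e <= k) {
          ilen <- intron_lens[e]
          iseq <- random_dna(ilen, gc$intron)
          feats[[length(feats) + 1L]] <-
            feature("intron", paste0(name, "_i", e), "+",
                    feature_parts(pos + 1L, pos + ilen))
          if (orf_flags[e]) {
            olen <- min(300L, ilen - 60L)
            if (olen >= 90L) {
              olen <- (olen %/% 3L) * 3L
              feats[[length(feats) + 1L]] <-
                feature("intronic_ORF", paste0(name, "_orf", e), "+",
                        feature_parts(pos + 31L, pos + 30L + olen),
                        qualifiers = list(product = "maturase-like"))
            }
          }
          pieces <- c(pieces, iseq)
          pos <- pos + ilen
        }
      }
      blk <- paste(pieces, collapse = "")
      cds_f <- feature("CDS", name, "+",
                       feature_parts(exon_parts[, 1L], exon_parts[, 2L]),
                       qualifiers = list(codon_start = "1"))
    } else {
      blk <- cds
      cds_f <- feature("CDS", name, "+", feature_parts(1L, nchar(cds)),
                       qualifiers = list(codon_start = "1"))
    }
    feats <- c(list(cds_f), feats)
  } else {
    blk <- random_dna(coding_len, gc$rna)
    feats <- list(feature(class, name, "+", feature_parts(1L, coding_len)))
  }
  n <- nchar(blk)
  feats <- c(list(feature("gene", name, "+", feature_parts(1L, n))), feats)
  if (strand == "-") {
    blk <- revcomp(blk)
    feats <- flip_features(feats, n)
  }
  list(seq = blk, features = feats, len = n)
}

## one palindromic hairpin cluster prototype: list(seq, n_hairpins)
build_palindrome_cluster <- function(per_cluster, stem_rng, loop_rng,
                                     gap_rng, gc) {
  pieces <- character(0)
  for (h in seq_len(per_cluster)) {
    s <- sample(stem_rng[1L]:stem_rng[2L], 1L)
    l <- sample(loop_rng[1L]:loop_rng[2L], 1L)
    motif <- sample(c("TTTA", "TTT"), 1L)
    pad <- l - nchar(motif)
    loop <- if (pad >= 0L) {
      paste0(motif, random_dna(pad, gc))
    } else substring(motif, 1L, l)
    arm <- random_dna(s, gc)
    pieces <- c(pieces, paste0(arm, loop, revcomp(arm)))
    if (h < per_cluster) {
      pieces <- c(pieces, random_dna(sample(gap_rng[1L]:gap_rng[2L], 1L),
                                     gc))
    }
  }
  list(seq = paste(pieces, collapse = ""), n_hairpins = per_cluster)
}

#' Generate an annotated synthetic organelle genome
#'
#' See [genome_spec()], [mt_genome_spec()] and [pt_genome_spec()] for the
#' controllable architecture. All planted truth is returned as annotation;
#' identical specs give byte-identical output.
#'
#' @param spec A `GenomeSpec`.
#' @return An `AnnotatedGenome`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "GenomeSpec"))
  set.seed(spec$seed)
  L <- spec$length
  gc <- spec$gc
  genes <- spec$genes
  if (any(is.na(genes$strand))) {
    genes$strand[is.na(genes$strand)] <- sample(c("+", "-"),
                                                sum(is.na(genes$strand)),
                                                replace = TRUE)
  }
  ir_len <- spec$ir$length %||% 0L
  ir_genes <- spec$ir$genes %||% character(0)
  if (!all(ir_genes %in% genes$name)) {
    stop("ir$genes must name genes present in the gene table")
  }

  ## --- coding budget ------------------------------------------------------
  coding_target <- round(spec$coding_frac * L)
  dup <- genes$name %in% ir_genes
  fixed <- !is.na(genes$length)
  fixed_pos <- sum(genes$length[fixed] * ifelse(dup[fixed], 2L, 1L))
  n_prot_units <- sum(ifelse(dup[!fixed], 2L, 1L))
  if (any(!fixed) && coding_target <= fixed_pos) {
    stop("infeasible spec: coding budget too small for the fixed-length genes")
  }
  prot_len <- if (any(!fixed)) {
    max(90L, (((coding_target - fixed_pos) / n_prot_units) %/% 3L) * 3L)
  } else 0L
  genes$length[!fixed] <- prot_len

  ## --- intron budget ------------------------------------------------------
  intron_target <- round(spec$intronic_frac * L)
  n_ir_intr <- if (ir_len > 0L) spec$ir$introns else 0L
  intron_units <- spec$gene_introns + 2L * n_ir_intr
  intron_len <- if (intron_units > 0L) intron_target %/% intron_units else 0L
  if (intron_units > 0L && intron_len < 80L) {
    stop("infeasible spec: intronic budget leaves introns shorter than 80 nt")
  }

  ## assign introns: IR introns to IR protein genes (or any IR gene slot on
  ## its protein member), other introns round-robin over non-IR proteins
  prot_non_ir <- which(genes$class == "protein" & !dup)
  prot_ir <- which(genes$class == "protein" & dup)
  gene_intr <- stats::setNames(rep(0L, nrow(genes)), genes$name)
  if (spec$gene_introns > 0L) {
    if (!length(prot_non_ir)) stop("introns requested but no protein genes")
    tgt <- rep(prot_non_ir, length.out = spec$gene_introns)
    for (t in tgt) gene_intr[t] <- gene_intr[t] + 1L
  }
  if (n_ir_intr > 0L) {
    if (!length(prot_ir)) stop("IR introns requested but no IR protein gene")
    tgt <- rep(prot_ir, length.out = n_ir_intr)
    for (t in tgt) gene_intr[t] <- gene_intr[t] + 1L
  }
  ## which introns carry ORFs (first `intronic_orfs` genic introns)
  orf_budget <- spec$intronic_orfs

  ## --- build gene blocks --------------------------------------------------
  blocks <- list()
  for (gi in seq_len(nrow(genes))) {
    nm <- genes$name[gi]; cls <- genes$class[gi]
    frag <- genes$fragments[gi]
    glen <- as.integer(genes$length[gi])
    ni <- gene_intr[gi]
    if (frag > 1L) {
      piece <- glen %/% frag
      frag_letter <- if (grepl("l$", nm)) "L" else "S"   # rrnl L1.., rrns S1..
      for (fg in seq_len(frag)) {
        plen <- if (fg < frag) piece else glen - piece * (frag - 1L)
        blocks[[length(blocks) + 1L]] <- c(
          build_gene_block(sprintf("%s_%s%d", nm, frag_letter, fg),
                           cls, genes$strand[gi], plen, integer(0),
                           logical(0), gc),
          list(gene = nm, dup = dup[gi]))
      }
    } else {
      ilens <- integer(0); orfs <- logical(0)
      if (ni > 0L) {
        ilens <- rep(intron_len, ni)
        orfs <- rep(FALSE, ni)
        take <- min(ni, orf_budget)
        if (take > 0L) {
          orfs[seq_len(take)] <- TRUE
          orf_budget <- orf_budget - take
        }
      }
      blocks[[length(blocks) + 1L]] <- c(
        build_gene_block(nm, cls, genes$strand[gi], glen, ilens, orfs, gc),
        list(gene = nm, dup = dup[gi]))
    }
  }

  ## --- intergenic elements ------------------------------------------------
  elements <- list()
  pal <- spec$palindromes
  if (pal$regions > 0L) {
    protos <- lapply(seq_len(pal$families), function(f) {
      build_palindrome_cluster(pal$per_cluster, pal$stem, pal$loop,
                               pal$gap, pal$gc)
    })
    for (rgn in seq_len(pal$regions)) {
      fam <- ((rgn - 1L) %% pal$families) + 1L
      p <- protos[[fam]]
      elements[[length(elements) + 1L]] <- list(
        seq = p$seq,
        features = list(feature("repeat_region",
                                sprintf("palcluster_%d", rgn), "+",
                                feature_parts(1L, nchar(p$seq)),
                                qualifiers = list(rpt_type = "palindromic_cluster",
                                                  family = as.character(fam),
                                                  n_hairpins = as.character(p$n_hairpins)))),
        len = nchar(p$seq))
    }
  }
  rpt <- spec$repeats
  if (rpt$families > 0L) {
    for (fam in seq_len(rpt$families)) {
      rl <- sample(rpt$len[1L]:rpt$len[2L], 1L)
      at <- stats::runif(1L, rpt$at[1L], rpt$at[2L])
      proto <- random_dna(rl, gc = 1 - at)
      for (cp in seq_len(rpt$copies)) {
        elements[[length(elements) + 1L]] <- list(
          seq = proto,
          features = list(feature("repeat_region",
                                  sprintf("dr%d", fam), "+",
                                  feature_parts(1L, rl),
                                  qualifiers = list(rpt_type = "dispersed",
                                                    family = as.character(fam)))),
          len = rl)
      }
    }
  }
  if (spec$intergenic_introns > 0L) {
    for (q in seq_len(spec$intergenic_introns)) {
      il <- spec$intergenic_intron_len
      elements[[length(elements) + 1L]] <- list(
        seq = random_dna(il, gc$intron),
        features = list(feature("intron", sprintf("igi%d", q), "+",
                                feature_parts(1L, il),
                                qualifiers = list(note = "intergenic group-II-like intron"))),
        len = il)
    }
  }
  if (spec$pseudogenes > 0L) {
    donors <- genes$name[genes$class == "protein"]
    for (q in seq_len(spec$pseudogenes)) {
      plen <- max(150L, as.integer(prot_len) %/% 2L)
      elements[[length(elements) + 1L]] <- list(
        seq = random_cds(plen %/% 3L, gc$codon),
        features = list(feature("pseudogene",
                                paste0(donors[((q - 1L) %% length(donors)) + 1L],
                                       "_psi"), "+",
                                feature_parts(1L, (plen %/% 3L) * 3L),
                                qualifiers = list(pseudo = TRUE))),
        len = (plen %/% 3L) * 3L)
    }
  }

  ## --- region assembly ----------------------------------------------------
  ir_blocks <- Filter(function(b) isTRUE(b$dup), blocks)
  sc_blocks <- Filter(function(b) !isTRUE(b$dup), blocks)

  pack_region <- function(blks, elems, target_len, filler_gc) {
    content <- sum(vapply(blks, `[[`, 0, "len")) +
      sum(vapply(elems, `[[`, 0, "len"))
    filler <- target_len - content
    if (filler < 0L) {
      stop(sprintf("infeasible spec: region content %d nt exceeds its %d-nt budget",
                   content, target_len))
    }
    items <- c(blks, elems)
    items <- items[sample.int(length(items))]
    nslots <- length(items) + 1L
    cuts <- if (filler > 0L) {
      as.vector(stats::rmultinom(1L, filler, rep(1 / nslots, nslots)))
    } else rep(0L, nslots)
    seqs <- character(0)
    feats <- list()
    pos <- 0L
    for (ii in seq_along(items)) {
      if (cuts[ii] > 0L) {
        seqs <- c(seqs, random_dna(cuts[ii], filler_gc))
        pos <- pos + cuts[ii]
      }
      seqs <- c(seqs, items[[ii]]$seq)
      feats <- c(feats, shift_features(items[[ii]]$features, pos))
      pos <- pos + items[[ii]]$len
    }
    if (cuts[nslots] > 0L) {
      seqs <- c(seqs, random_dna(cuts[nslots], filler_gc))
      pos <- pos + cuts[nslots]
    }
    stopifnot(pos == target_len)
    list(seq = paste(seqs, collapse = ""), features = feats)
  }

  ## filler GC solved so intergenic-category GC meets its target on average
  elem_gc_len <- vapply(elements, function(e) {
    c(gc_fraction(e$seq) * e$len, e$len)
  }, c(0, 0))
  elem_gc_nt <- if (length(elements)) sum(elem_gc_len[1L, ]) else 0
  elem_nt <- if (length(elements)) sum(elem_gc_len[2L, ]) else 0
  intergenic_total <- L - coding_target - intron_target
  fg_num <- gc$intergenic * intergenic_total - elem_gc_nt
  filler_den <- intergenic_total - elem_nt
  filler_gc <- if (filler_den > 0) min(0.8, max(0.05, fg_num / filler_den)) else gc$intergenic

  if (ir_len > 0L) {
    lsc_len <- as.integer(spec$ir$lsc_length %||%
                            round((L - 2L * ir_len) * 0.53))
    ssc_len <- as.integer(spec$ir$ssc_length %||% (L - 2L * ir_len - lsc_len))
    stopifnot(lsc_len + ssc_len + 2L * ir_len == L)
    ## split single-copy blocks and elements between LSC and SSC by length
    arm <- pack_region(ir_blocks, list(), ir_len, filler_gc)
    ord <- sample.int(length(sc_blocks))
    lens <- vapply(sc_blocks, `[[`, 0, "len")[ord]
    csum <- cumsum(lens)
    sc_content_target <- lsc_len * (sum(lens) / (lsc_len + ssc_len))
    in_lsc <- csum <= sc_content_target
    lsc_blocks <- sc_blocks[ord[in_lsc]]
    ssc_blocks <- sc_blocks[ord[!in_lsc]]
    e_ord <- sample.int(length(elements))
    e_half <- elements[e_ord] # alternate elements between the regions
    lsc_elems <- e_half[seq_along(e_half) %% 2L == 1L]
    ssc_elems <- e_half[seq_along(e_half) %% 2L == 0L]
    lsc <- pack_region(lsc_blocks, lsc_elems, lsc_len, filler_gc)
    ssc <- pack_region(ssc_blocks, ssc_elems, ssc_len, filler_gc)
    ## genome = LSC + IR_A + SSC + IR_B(revcomp)
    seqs <- c(lsc$seq, arm$seq, ssc$seq, revcomp(arm$seq))
    feats <- c(lsc$features,
               shift_features(arm$features, lsc_len),
               shift_features(ssc$features, lsc_len + ir_len),
               shift_features(flip_features(arm$features, ir_len),
                              lsc_len + ir_len + ssc_len))
    genome_seq <- paste(seqs, collapse = "")
  } else {
    packed <- pack_region(blocks, elements, L, filler_gc)
    genome_seq <- packed$seq
    feats <- packed$features
  }
  ord <- order(vapply(feats, function(f) as.numeric(f$parts$start[1L]), 0),
               vapply(feats, function(f) match(f$kind, FEATURE_KINDS), 0L))
  annotated_genome(spec$id, genome_seq, circular = spec$circular,
                   features = feats[ord])
}

#' Construct a shredding specification
#'
#' @param coverage Fold coverage of the source genome.
#' @param read_length_mean,read_length_sd Read length distribution in nt.
#' @param error_rate Per-base substitution probability (0-0.2; indels are
#'   not simulated).
#' @param nuclear_background Fold coverage of a random decoy "nuclear"
#'   sequence appended to the archive (0 = none).
#' @param decoy_length Length of the decoy sequence (default: genome
#'   length).
#' @param decoy_insert Optional organelle-like fragment (character) planted
#'   in the decoy to mimic a numt/nupt.
#' @param seed Mandatory RNG seed.
#' @return A `ShredSpec` list.
#' @export
shred_spec <- function(coverage = 30, read_length_mean = 750,
                       read_length_sd = 80, error_rate = 0.01,
                       nuclear_background = 0, decoy_length = NULL,
                       decoy_insert = NULL, seed) {
  stopifnot(!missing(seed), coverage > 0, error_rate >= 0, error_rate <= 0.2)
  structure(list(coverage = coverage, read_length_mean = read_length_mean,
                 read_length_sd = read_length_sd, error_rate = error_rate,
                 nuclear_background = nuclear_background,
                 decoy_length = decoy_length, decoy_insert = decoy_insert,
                 seed = as.integer(seed)),
            class = "ShredSpec")
}

## apply i.i.d. substitutions to a sequence
mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- dna_chars(s)
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit)) {
    for (i in hit) {
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    }
  }
  paste(ch, collapse = "")
}

#' Shred a genome into a simulated trace archive
#'
#' Reads are drawn uniformly over the (possibly circular) genome with random
#' strands and i.i.d. substitution errors; decoy reads from a random
#' GC-matched nuclear-background sequence are appended. Origin tags
#' (`organelle`/`nuclear`) are attached for downstream evaluation.
#'
#' @param genome An `AnnotatedGenome` (or DNA string, treated as circular).
#' @param spec A `ShredSpec`.
#' @return A `TraceArchive`.
#' @export
shred_traces <- function(genome, spec) {
  stopifnot(inherits(spec, "ShredSpec"))
  set.seed(spec$seed)
  s <- if (inherits(genome, "AnnotatedGenome")) genome$sequence else genome
  circular <- if (inherits(genome, "AnnotatedGenome")) genome$circular else TRUE
  L <- nchar(s)
  if (spec$read_length_mean > L) stop("read length exceeds genome length")
  draw_reads <- function(src, circ, fold, tag, prefix) {
    n <- nchar(src)
    nreads <- ceiling(fold * n / spec$read_length_mean)
    if (nreads < 1L) return(NULL)
    lens <- pmax(100L, pmin(round(stats::rnorm(nreads, spec$read_length_mean,
                                               spec$read_length_sd)),
                            n))
    starts <- if (circ) {
      sample.int(n, nreads, replace = TRUE)
    } else {
      vapply(lens, function(l) sample.int(n - l + 1L, 1L), 0L)
    }
    src2 <- if (circ) paste0(src, src) else src
    seqs <- substring(src2, starts, starts + lens - 1L)
    flip <- sample(c(TRUE, FALSE), nreads, replace = TRUE)
    seqs[flip] <- vapply(seqs[flip], revcomp, "", USE.NAMES = FALSE)
    seqs <- vapply(seqs, mutate_seq, "", rate = spec$error_rate,
                   USE.NAMES = FALSE)
    data.frame(id = sprintf("%s%05d", prefix, seq_len(nreads)),
               sequence = seqs, origin = tag)
  }
  out <- draw_reads(s, circular, spec$coverage, "organelle", "org")
  if (spec$nuclear_background > 0) {
    dl <- spec$decoy_length %||% L
    decoy <- random_dna(dl, gc_fraction(s))
    if (!is.null(spec$decoy_insert)) {
      ins <- spec$decoy_insert
      at <- max(1L, dl %/% 3L)
      decoy <- paste0(substring(decoy, 1L, at), ins,
                      substring(decoy, at + 1L, dl))
    }
    out <- rbind(out, draw_reads(decoy, FALSE, spec$nuclear_background,
                                 "nuclear", "nuc"))
  }
  trace_archive(out)
}

#' Hand-checked toy genome fixture
#'
#' A fixed 1.5-kb circular genome with one intron-bearing protein gene, a
#' minus-strand tRNA, a fragmented rRNA (2 modules), one intergenic intron
#' and one palindromic-cluster region, together with its hand-computed
#' accounting: coding 750 nt, noncoding 750 nt, intergenic 630 nt, intronic
#' 120 nt, and intron/gene ratio 2/3.
#'
#' @return A list: `genome` (`AnnotatedGenome`), `partition` (named list of
#'   expected totals), `intron_gene_ratio`.
#' @export
toy_fixture <- function() {
  base <- strrep("ACGTTGCA", 188L)            # 1504 nt, deterministic
  sequence <- substring(base, 1L, 1500L)
  features <- list(
    feature("gene", "cob", "+", feature_parts(101L, 700L)),
    feature("CDS", "cob", "+",
            feature_parts(c(101L, 401L), c(280L, 700L)),
            qualifiers = list(codon_start = "1")),
    feature("intron", "cob_i1", "+", feature_parts(281L, 400L)),
    feature("gene", "trnM", "-", feature_parts(801L, 870L)),
    feature("tRNA", "trnM", "-", feature_parts(801L, 870L)),
    feature("gene", "rrns_S1", "+", feature_parts(901L, 1000L)),
    feature("rRNA", "rrns_S1", "+", feature_parts(901L, 1000L)),
    feature("gene", "rrns_S2", "+", feature_parts(1051L, 1150L)),
    feature("rRNA", "rrns_S2", "+", feature_parts(1051L, 1150L)),
    feature("intron", "igi1", "+", feature_parts(1201L, 1280L),
            qualifiers = list(note = "intergenic intron")),
    feature("repeat_region", "palcluster_1", "+",
            feature_parts(1301L, 1400L),
            qualifiers = list(rpt_type = "palindromic_cluster")))
  genome <- annotated_genome("toy_synthetic", sequence, circular = TRUE,
                             features = features)
  list(genome = genome,
       partition = list(genome_length = 1500L, coding_nt = 750L,
                        noncoding_nt = 750L, intergenic_nt = 630L,
                        intronic_nt = 120L),
       intron_gene_ratio = 2 / 3)
}
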