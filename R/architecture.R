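## Genome-accounting and composition statistics.
##
## The coding/noncoding accounting follows four interlocking definitions:
##   i)   coding nt   = union length of annotated protein-, rRNA- and
##        tRNA-coding regions, minus positions also annotated as introns
##        (intronic ORFs count with the introns, not the coding total;
##        pseudogenes are excluded);
##   ii)  noncoding nt = genome length - coding nt;
##   iii) intergenic nt = genome length - union length of gene regions
##        (gene spans including their introns and intronic ORFs);
##   iv)  intronic nt  = noncoding nt - intergenic nt.
## Both conservation identities (i+ii and iii+iv) hold by construction and
## are re-checked against a per-position classifier in the test suite.

coding_kinds <- c("CDS", "rRNA", "tRNA")
intronic_kinds <- c("intron", "intronic_ORF")

# linear IRanges of all parts of features of the given kinds
kind_iranges <- function(genome, kinds) {
  fs <- features_of_kind(genome, kinds)
  if (!length(fs)) return(IRanges::IRanges())
  do.call(c, lapply(fs, function(f) parts_to_iranges(f$parts, genome_length(genome))))
}

# union of gene-region spans: gene features plus coding-feature spans plus
# intron/intronic-ORF parts overlapping those spans
gene_union_iranges <- function(genome) {
  L <- genome_length(genome)
  span_ir <- function(fs) {
    if (!length(fs)) return(IRanges::IRanges())
    do.call(c, lapply(fs, function(f) parts_to_iranges(feature_span(f, L), L)))
  }
  u0 <- IRanges::reduce(c(span_ir(features_of_kind(genome, "gene")),
                          span_ir(features_of_kind(genome, coding_kinds))))
  intr <- kind_iranges(genome, intronic_kinds)
  if (length(intr) && length(u0)) {
    hit <- IRanges::overlapsAny(intr, u0)
    u0 <- IRanges::reduce(c(u0, intr[hit]))
  }
  u0
}

#' Partition a genome into coding, intronic and intergenic nucleotides
#'
#' Applies the annotation-driven accounting described above. The report is
#' rotation-invariant for circular genomes and conserves both identities
#' `coding + noncoding = length` and `intergenic + intronic = noncoding`.
#'
#' @param genome An `AnnotatedGenome`.
#' @return A `PartitionReport`: genome length, the four nucleotide totals and
#'   their fractions of genome length.
#' @export
partition_genome <- function(genome) {
  validate_genome(genome)
  L <- genome_length(genome)
  if (!length(genome$features)) {
    warning("genome has no features; coding content is zero")
  }
  coding_ir <- IRanges::reduce(kind_iranges(genome, coding_kinds))
  intron_ir <- IRanges::reduce(kind_iranges(genome, intronic_kinds))
  coding_nt <- sum(IRanges::width(IRanges::setdiff(coding_ir, intron_ir)))
  noncoding_nt <- L - coding_nt
  intergenic_nt <- L - sum(IRanges::width(gene_union_iranges(genome)))
  intronic_nt <- noncoding_nt - intergenic_nt
  structure(list(genome_length = L,
                 coding_nt = coding_nt,
                 noncoding_nt = noncoding_nt,
                 intergenic_nt = intergenic_nt,
                 intronic_nt = intronic_nt,
                 fractions = c(coding = coding_nt / L,
                               noncoding = noncoding_nt / L,
                               intergenic = intergenic_nt / L,
                               intronic = intronic_nt / L)),
            class = "PartitionReport")
}

#' @export
print.PartitionReport <- function(x, ...) {
  cat(sprintf("PartitionReport: %d nt\n", x$genome_length))
  cat(sprintf("  coding     %8d nt  (%.1f%%)\n", x$coding_nt,
              100 * x$fractions[["coding"]]))
  cat(sprintf("  noncoding  %8d nt  (%.1f%%)\n", x$noncoding_nt,
              100 * x$fractions[["noncoding"]]))
  cat(sprintf("   intergenic %7d nt  (%.1f%%)\n", x$intergenic_nt,
              100 * x$fractions[["intergenic"]]))
  cat(sprintf("   intronic   %7d nt  (%.1f%%)\n", x$intronic_nt,
              100 * x$fractions[["intronic"]]))
  invisible(x)
}

#' GC content of a sequence, genome, or region set
#'
#' `(G + C) / (A + C + G + T)`; `N` positions are excluded from numerator and
#' denominator. A character vector is treated as a region set and pooled.
#'
#' @param x A DNA string, character vector of strings, or `AnnotatedGenome`.
#' @return GC fraction in `[0, 1]`.
#' @export
gc_content <- function(x) {
  if (inherits(x, "AnnotatedGenome")) x <- x$sequence
  stopifnot(is.character(x), length(x) >= 1L)
  gc_fraction(paste(x, collapse = ""))
}

#' GC content by genomic category
#'
#' Returns the overall GC fraction plus the fractions over the coding,
#' intron (introns and intronic ORFs, as annotated), and intergenic
#' partitions of the genome.
#'
#' @param genome An `AnnotatedGenome`.
#' @return Named numeric vector `overall`, `coding`, `intron`, `intergenic`
#'   (categories absent from the genome are `NA`).
#' @export
gc_by_category <- function(genome) {
  L <- genome_length(genome)
  coding_m <- coverage_mask(kind_iranges(genome, coding_kinds), L)
  intron_m <- coverage_mask(kind_iranges(genome, intronic_kinds), L)
  gene_m <- coverage_mask(gene_union_iranges(genome), L)
  chars <- dna_chars(genome$sequence)
  cat_gc <- function(mask) {
    if (!any(mask)) return(NA_real_)
    gc_fraction(paste(chars[mask], collapse = ""))
  }
  c(overall = gc_fraction(genome$sequence),
    coding = cat_gc(coding_m & !intron_m),
    intron = cat_gc(intron_m),
    intergenic = cat_gc(!gene_m & !intron_m))
}

#' GC content by codon position
#'
#' Pools all annotated protein-coding sequences (spliced, strand-resolved,
#' frame from the `codon_start` qualifier) and tallies GC at codon sites 1,
#' 2 and 3. Partial trailing codons are dropped with a warning unless the
#' feature is flagged fragmented/pseudo.
#'
#' @param genome An `AnnotatedGenome`.
#' @return Numeric vector `c(pos1, pos2, pos3)` of GC fractions.
#' @export
gc_by_codon_position <- function(genome) {
  cds <- Filter(function(f) !is_pseudo(f),
                features_of_kind(genome, "CDS"))
  if (!length(cds)) stop("no protein-coding (CDS) features annotated")
  counts <- matrix(0, nrow = 3L, ncol = 2L,
                   dimnames = list(NULL, c("gc", "tot")))
  for (f in cds) {
    s <- feature_seq(genome, f)
    cs <- suppressWarnings(as.integer(f$qualifiers$codon_start %||% 1L))
    if (!is.na(cs) && cs > 1L) s <- substring(s, cs)
    n <- nchar(s)
    if (n %% 3L != 0L) {
      flagged <- isTRUE(f$qualifiers$fragment) || !is.null(f$qualifiers$fragment_of)
      if (!flagged) {
        warning(sprintf("CDS '%s' length %d is not a multiple of 3; truncating",
                        f$name, n))
      }
      s <- substring(s, 1L, n - n %% 3L)
      n <- nchar(s)
    }
    if (n == 0L) next
    ch <- dna_chars(s)
    posidx <- rep_len(1:3, n)
    for (p in 1:3) {
      cp <- ch[posidx == p]
      cp <- cp[cp != "N"]
      counts[p, "gc"] <- counts[p, "gc"] + sum(cp %in% c("G", "C"))
      counts[p, "tot"] <- counts[p, "tot"] + length(cp)
    }
  }
  out <- counts[, "gc"] / counts[, "tot"]
  names(out) <- c("pos1", "pos2", "pos3")
  out
}

#' Cumulative GC-skew series
#'
#' Per-window skew `(G - C) / (G + C)` accumulated by running sum; often used
#' to pinpoint replication origins and shifts in transcriptional polarity.
#' Circular genomes wrap the final windows; a window with `G + C = 0`
#' contributes skew 0.
#'
#' @param genome An `AnnotatedGenome` or DNA string (treated as linear).
#' @param window Window size in nt (default 1000).
#' @param step Step size in nt (default 1000).
#' @return A `SkewSeries` data frame with columns `position` (window
#'   midpoint), `skew` (per-window) and `cumulative`; attributes `window`,
#'   `step`.
#' @export
cumulative_gc_skew <- function(genome, window = 1000L, step = 1000L) {
  circular <- FALSE
  s <- genome
  if (inherits(genome, "AnnotatedGenome")) {
    s <- genome$sequence
    circular <- genome$circular
  }
  L <- nchar(s)
  stopifnot(window >= 1L, step >= 1L, window <= L)
  starts <- seq(1L, L, by = step)
  if (!circular) starts <- starts[starts + window - 1L <= L]
  if (!length(starts)) stop("no complete windows at this window/step")
  src <- if (circular) paste0(s, substring(s, 1L, window)) else s
  x <- Biostrings::DNAString(src)
  v <- Biostrings::letterFrequencyInSlidingView(x, window, c("G", "C"))
  g <- v[starts, "G"]; c_ <- v[starts, "C"]
  den <- g + c_
  skew <- ifelse(den == 0, 0, (g - c_) / den)
  out <- data.frame(position = starts + (window - 1) / 2,
                    skew = skew, cumulative = cumsum(skew))
  attr(out, "window") <- window
  attr(out, "step") <- step
  class(out) <- c("SkewSeries", "data.frame")
  out
}

# base gene name: fragment qualifier wins, else strip _S1/_L2/-a style
# fragment suffixes (editable via the fragment_map argument of the callers)
base_gene_name <- function(name, qualifiers = list(), fragment_map = NULL) {
  if (!is.null(qualifiers$fragment_of)) return(qualifiers$fragment_of)
  if (!is.null(fragment_map) && name %in% names(fragment_map)) {
    return(fragment_map[[name]])
  }
  sub("_[SL]?[0-9]+$", "", name)
}

# gene-level features: gene wrappers when present, else coding features
gene_level_features <- function(genome) {
  genes <- features_of_kind(genome, "gene")
  if (length(genes)) return(genes)
  Filter(function(f) !is_pseudo(f), features_of_kind(genome, coding_kinds))
}

#' Intron/gene ratio
#'
#' Number of annotated introns divided by the number of genes. Defaults keep
#' duplicate genes/introns inside an inverted repeat (both copies count) and
#' include intergenic introns; fragmented genes (e.g. rRNA coding modules)
#' count once per locus.
#'
#' @param genome An `AnnotatedGenome`.
#' @param include_intergenic_introns Count introns lying outside every gene
#'   region (default `TRUE`).
#' @param dedupe_ir Collapse genes and introns duplicated by an inverted
#'   repeat, matching by name/sequence (default `FALSE`).
#' @param fragment_map Optional named character vector mapping fragment
#'   labels to their locus name.
#' @return The ratio as a plain number.
#' @export
intron_gene_ratio <- function(genome, include_intergenic_introns = TRUE,
                              dedupe_ir = FALSE, fragment_map = NULL) {
  L <- genome_length(genome)
  genes <- gene_level_features(genome)
  n_genes <- count_loci(genes, L, fragment_map, dedupe = dedupe_ir)
  if (n_genes == 0L) stop("genome has no genes; intron/gene ratio undefined")
  introns <- features_of_kind(genome, "intron")
  if (!include_intergenic_introns && length(introns)) {
    gu <- gene_union_iranges(genome)
    introns <- Filter(function(f)
      any(IRanges::overlapsAny(parts_to_iranges(f$parts, L), gu)), introns)
  }
  n_introns <- length(introns)
  if (dedupe_ir && n_introns > 0L) {
    sigs <- vapply(introns, function(f) feature_seq(genome, f), "")
    n_introns <- length(unique(sigs))
  }
  n_introns / n_genes
}

# number of gene loci: fragments (shared base name, near one another)
# collapse to one locus; IR duplicates optionally collapse by name
count_loci <- function(genes, L, fragment_map = NULL, dedupe = FALSE) {
  if (!length(genes)) return(0L)
  base <- vapply(genes, function(f)
    base_gene_name(f$name, f$qualifiers, fragment_map), "")
  frag <- vapply(genes, function(f)
    !is.null(f$qualifiers$fragment_of) ||
      grepl("_[SL]?[0-9]+$", f$name), NA)
  if (dedupe) return(length(unique(base)))
  # group fragments of the same base name into one locus; distinct loci of
  # the same name (IR duplicates) are separated by > half the genome? No:
  # fragments collapse globally per base name, duplicates of whole genes
  # (identical full names, frag = FALSE) each count.
  n_frag_loci <- length(unique(base[frag]))
  n_whole <- sum(!frag)
  n_frag_loci + n_whole
}

#' Gene inventory of a genome
#'
#' Counts genes by class (protein, rRNA, tRNA), both keeping and collapsing
#' duplicates, with fragment counts for genes split into coding modules.
#'
#' @param genome An `AnnotatedGenome`.
#' @param fragment_map Optional named character vector mapping fragment
#'   labels to their locus name.
#' @return A `GeneInventory`: per-class counts with/without duplicates,
#'   the gene-name multiset, and per-gene fragment counts.
#' @export
gene_inventory <- function(genome, fragment_map = NULL) {
  feats <- Filter(function(f) !is_pseudo(f) && f$kind != "intronic_ORF",
                  features_of_kind(genome, coding_kinds))
  cls <- vapply(feats, function(f)
    switch(f$kind, CDS = "protein", rRNA = "rRNA", tRNA = "tRNA"), "")
  base <- vapply(feats, function(f)
    base_gene_name(f$name, f$qualifiers, fragment_map), "")
  frag <- vapply(feats, function(f)
    !is.null(f$qualifiers$fragment_of) || grepl("_[SL]?[0-9]+$", f$name), NA)
  counts <- data.frame(class = c("protein", "rRNA", "tRNA"),
                       with_dup = 0L, dedup = 0L)
  names_multiset <- character(0)
  fragments <- integer(0)
  for (k in counts$class) {
    sel <- cls == k
    b <- base[sel]; fr <- frag[sel]
    # fragmented loci count once (with fragment count); whole genes count
    # per copy in the with-duplicates variant
    with_dup <- length(unique(b[fr])) + sum(!fr)
    dedup <- length(unique(b))
    counts$with_dup[counts$class == k] <- with_dup
    counts$dedup[counts$class == k] <- dedup
    names_multiset <- c(names_multiset, b[!fr], unique(b[fr]))
    for (bn in unique(b[fr])) fragments[bn] <- sum(b == bn)
  }
  structure(list(counts = counts, names = names_multiset,
                 fragments = fragments),
            class = "GeneInventory")
}

#' @export
print.GeneInventory <- function(x, ...) {
  cat("GeneInventory\n")
  for (i in seq_len(nrow(x$counts))) {
    cat(sprintf("  %-8s with duplicates %3d, deduplicated %3d\n",
                x$counts$class[i], x$counts$with_dup[i], x$counts$dedup[i]))
  }
  if (length(x$fragments)) {
    cat("  fragmented:",
        paste(sprintf("%s (%d modules)", names(x$fragments), x$fragments),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compare gene repertoires across genomes (Venn partition)
#'
#' For every non-empty subset of the inputs, reports the genes exclusive to
#' exactly that subset of genomes (deduplicated names, optional synonym map).
#'
#' @param inventories Named list of `GeneInventory` objects or character
#'   vectors of gene names.
#' @param synonyms Optional named character vector mapping alternate names
#'   onto canonical ones.
#' @return A named list: each element, keyed `"A+B"`-style by the sorted
#'   member genomes, holds the gene names exclusive to that subset. Cells
#'   are disjoint and union to the full name universe.
#' @export
gene_set_compare <- function(inventories, synonyms = NULL) {
  stopifnot(length(inventories) >= 2L)
  if (is.null(names(inventories))) {
    names(inventories) <- paste0("G", seq_along(inventories))
  }
  sets <- lapply(inventories, function(inv) {
    nm <- if (inherits(inv, "GeneInventory")) inv$names else inv
    nm <- unique(nm)
    if (!is.null(synonyms)) {
      hit <- nm %in% names(synonyms)
      nm[hit] <- synonyms[nm[hit]]
    }
    unique(nm)
  })
  universe <- sort(unique(unlist(sets)))
  sig <- vapply(universe, function(g) {
    paste(sort(names(sets)[vapply(sets, function(s) g %in% s, NA)]),
          collapse = "+")
  }, "")
  split(universe, sig)
}
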