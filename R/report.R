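## Composite per-genome reports and multi-genome comparison tables.

#' Composite architecture report for one genome
#'
#' One document with size, mapping conformation, the coding/noncoding
#' accounting, GC statistics (overall, by category, by codon position),
#' intron/gene ratio, gene inventory, the inverted-repeat map (when one is
#' detected), and palindrome/repeat summaries. Values are also formatted at
#' reporting precision: kb and percentages to 1 decimal, ratios to 2
#' decimals.
#'
#' @param x An `AnnotatedGenome` or path to a GenBank flat file.
#' @param find_ir Attempt inverted-repeat detection (default `TRUE`;
#'   automatically skipped for genomes under 10 kb).
#' @param scan_repeats Run the hairpin/cluster scan and a dispersed-repeat
#'   scan (default `TRUE`; the repeat scan is skipped above `max_repeat_nt`).
#' @param min_ir_len Minimum IR arm length passed to
#'   [find_inverted_repeat()].
#' @param max_repeat_nt Upper sequence size for the dispersed-repeat scan
#'   (default 50000).
#' @return A `GenomeReport` list.
#' @export
report_genome <- function(x, find_ir = TRUE, scan_repeats = TRUE,
                          min_ir_len = 1000L, max_repeat_nt = 50000L) {
  genome <- if (inherits(x, "AnnotatedGenome")) x else read_genbank(x)
  L <- genome_length(genome)
  part <- partition_genome(genome)
  gc_cat <- gc_by_category(genome)
  codon <- tryCatch(gc_by_codon_position(genome),
                    error = function(e) c(pos1 = NA, pos2 = NA, pos3 = NA))
  ratio <- tryCatch(intron_gene_ratio(genome), error = function(e) NA_real_)
  inv <- gene_inventory(genome)
  irmap <- NULL
  if (find_ir && genome$circular && L >= 10000L) {
    irmap <- find_inverted_repeat(genome, min_len = min_ir_len)
  }
  pal <- NULL
  if (scan_repeats) {
    hp <- find_hairpins(genome$sequence)
    cl <- cluster_hairpins(hp, seq = genome$sequence, genome = genome)
    pal <- list(n_hairpins = nrow(hp), n_clusters = nrow(cl),
                mean_cluster_length = if (nrow(cl)) mean(cl$length) else NA,
                mean_cluster_gc = if (nrow(cl)) mean(cl$gc) else NA,
                mean_hairpins_per_cluster =
                  if (nrow(cl)) mean(cl$n_hairpins) else NA,
                loop_motifs = loop_motif_tally(hp))
  }
  reps <- NULL
  if (scan_repeats && L <= max_repeat_nt) {
    rm_ <- find_maximal_repeats(genome$sequence, min_len = 12L,
                                hamming_k = 0L)
    reps <- list(n_matches = nrow(rm_),
                 n_families = if (nrow(rm_)) {
                   length(cluster_repeats(rm_, genome$sequence))
                 } else 0L)
  }
  out <- list(id = genome$id,
              size_nt = L,
              size_kb = round(L / 1000, 1),
              conformation = if (genome$circular) "circular" else "linear",
              percent_coding = round(100 * part$fractions[["coding"]], 1),
              percent_noncoding = round(100 * part$fractions[["noncoding"]], 1),
              percent_intergenic = round(100 * part$fractions[["intergenic"]], 1),
              percent_intronic = round(100 * part$fractions[["intronic"]], 1),
              percent_gc = round(100 * gc_cat[["overall"]], 1),
              gc_by_category = gc_cat,
              gc_by_codon_position = codon,
              intron_gene_ratio = if (is.na(ratio)) NA else round(ratio, 2),
              partition = part,
              inventory = inv,
              ir = irmap,
              palindromes = pal,
              repeats = reps)
  class(out) <- "GenomeReport"
  out
}

#' @export
print.GenomeReport <- function(x, ...) {
  cat(sprintf("GenomeReport %s: %.1f kb, %s\n", x$id, x$size_kb,
              x$conformation))
  cat(sprintf("  %%coding %.1f | %%noncoding %.1f (intergenic %.1f, intronic %.1f) | %%GC %.1f\n",
              x$percent_coding, x$percent_noncoding, x$percent_intergenic,
              x$percent_intronic, x$percent_gc))
  if (!is.na(x$intron_gene_ratio)) {
    cat(sprintf("  intron/gene ratio %.2f\n", x$intron_gene_ratio))
  }
  if (!is.null(x$ir)) {
    cat(sprintf("  IR %.1f kb, LSC %.1f kb, SSC %.1f kb\n",
                x$ir$ir_length / 1000, x$ir$lsc_length / 1000,
                x$ir$ssc_length / 1000))
  }
  if (!is.null(x$palindromes) && x$palindromes$n_clusters > 0) {
    cat(sprintf("  palindrome clusters: %d (mean %.0f nt, GC %.0f%%, %.1f hairpins each)\n",
                x$palindromes$n_clusters, x$palindromes$mean_cluster_length,
                100 * x$palindromes$mean_cluster_gc,
                x$palindromes$mean_hairpins_per_cluster))
  }
  invisible(x)
}

#' Serialize a genome report to JSON
#'
#' @param report A `GenomeReport`.
#' @param path Optional output path; when omitted the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
report_to_json <- function(report, path = NULL) {
  x <- report
  x$partition <- unclass(x$partition)
  x$inventory <- unclass(x$inventory)
  if (!is.null(x$ir)) x$ir <- unclass(x$ir)
  class(x) <- NULL
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Compare several genomes
#'
#' Per-genome architecture rows (size, %noncoding, %intergenic, %intronic,
#' %GC) plus size-versus-%noncoding scatter data; per-file failures are
#' reported in the `error` column and the run continues.
#'
#' @param xs List of `AnnotatedGenome` objects and/or GenBank file paths.
#' @param ... Passed to [report_genome()].
#' @return A data frame, one row per input, in input order.
#' @export
compare_genomes <- function(xs, ...) {
  stopifnot(length(xs) >= 1L)
  rows <- lapply(xs, function(x) {
    tryCatch({
      r <- report_genome(x, find_ir = FALSE, scan_repeats = FALSE, ...)
      data.frame(id = r$id, size_kb = r$size_kb,
                 percent_coding = r$percent_coding,
                 percent_noncoding = r$percent_noncoding,
                 percent_intergenic = r$percent_intergenic,
                 percent_intronic = r$percent_intronic,
                 percent_gc = r$percent_gc, error = NA_character_)
    }, error = function(e) {
      data.frame(id = if (is.character(x)) basename(x) else "?",
                 size_kb = NA_real_, percent_coding = NA_real_,
                 percent_noncoding = NA_real_, percent_intergenic = NA_real_,
                 percent_intronic = NA_real_, percent_gc = NA_real_,
                 error = conditionMessage(e))
    })
  })
  do.call(rbind, rows)
}
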