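## FASTA/FASTQ reading and GFF3/BED writing.

#' Read a (multi-record) FASTA file
#'
#' @param path Path to a FASTA file.
#' @param map_to_N Map non-ACGTN characters (e.g. `U`, IUPAC ambiguity) to
#'   `N` instead of raising an error.
#' @return A named character vector of uppercase sequences, in file order.
#' @export
read_fasta <- function(path, map_to_N = FALSE) {
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  seqs <- vapply(seq_along(seqs), function(i) {
    normalize_dna(seqs[i], map_to_N = map_to_N, what = paste0("record ", ids[i]))
  }, "")
  stats::setNames(seqs, ids)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a FASTQ file as sequences
#'
#' Quality strings are discarded (the assembler's consensus caller is
#' coverage-weighted majority and ignores Phred values).
#'
#' @param path Path to a FASTQ file.
#' @return A named character vector of uppercase sequences.
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  if (!length(set)) stop("empty FASTQ file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  stats::setNames(toupper(as.character(set)), ids)
}

#' Write genome features as GFF3
#'
#' 1-based inclusive coordinates; wrapping parts are split at the origin.
#'
#' @param genome An `AnnotatedGenome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genome, path) {
  L <- genome_length(genome)
  rows <- c("##gff-version 3",
            sprintf("##sequence-region %s 1 %d", genome$id, L))
  for (f in genome$features) {
    p <- f$parts
    for (i in seq_len(nrow(p))) {
      segs <- if (p$wraps[i]) {
        list(c(p$start[i], L), c(1L, p$end[i]))
      } else list(c(p$start[i], p$end[i]))
      for (sg in segs) {
        rows <- c(rows, paste(genome$id, "organellarch", f$kind, sg[1L], sg[2L],
                              ".", f$strand, ".",
                              sprintf("Name=%s", f$name), sep = "\t"))
      }
    }
  }
  writeLines(rows, path)
  invisible(path)
}

#' Write intervals as BED
#'
#' BED is 0-based half-open; the conversion happens here, at the boundary.
#'
#' @param intervals Data frame with columns `start`, `end` (1-based
#'   inclusive) and optionally `name`, `strand`, `wraps`.
#' @param chrom Chromosome/sequence name.
#' @param path Output path.
#' @param L Sequence length (required when wrapping intervals are present).
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, chrom, path, L = NULL) {
  rows <- character(0)
  for (i in seq_len(nrow(intervals))) {
    nm <- if ("name" %in% names(intervals)) intervals$name[i] else "."
    strand <- if ("strand" %in% names(intervals)) intervals$strand[i] else "+"
    wraps <- isTRUE(intervals$wraps[i])
    segs <- if (wraps) {
      stopifnot(!is.null(L))
      list(c(intervals$start[i], L), c(1L, intervals$end[i]))
    } else list(c(intervals$start[i], intervals$end[i]))
    for (sg in segs) {
      rows <- c(rows, paste(chrom, sg[1L] - 1L, sg[2L], nm, 0L, strand,
                            sep = "\t"))
    }
  }
  writeLines(rows, path)
  invisible(path)
}
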