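## AnnotatedGenome / Feature containers and coordinate arithmetic.
##
## Coordinates are 1-based inclusive throughout (the GenBank and IRanges
## convention). A feature part that crosses the origin of a circular genome is
## kept as a single wrapping interval (start > end, wraps = TRUE) rather than
## being silently linearized; interval arithmetic resolves the wrap on demand.

FEATURE_KINDS <- c("gene", "CDS", "tRNA", "rRNA", "intron", "intronic_ORF",
                   "pseudogene", "repeat_region", "misc")

#' Construct a feature part table
#'
#' @param start,end 1-based inclusive coordinates (vectors of equal length).
#' @param wraps Logical; `TRUE` where the part crosses the circular origin
#'   (in which case `end < start`).
#' @return A `data.frame` with columns `start`, `end`, `wraps`.
#' @export
feature_parts <- function(start, end, wraps = FALSE) {
  wraps <- rep_len(wraps, length(start))
  stopifnot(length(start) == length(end))
  data.frame(start = as.integer(start), end = as.integer(end), wraps = wraps)
}

#' Construct a genome feature
#'
#' @param kind One of `gene`, `CDS`, `tRNA`, `rRNA`, `intron`, `intronic_ORF`,
#'   `pseudogene`, `repeat_region`, `misc`.
#' @param name Label, e.g. `"cob"` or `"trnM"`.
#' @param strand `"+"` or `"-"`.
#' @param parts A parts table from [feature_parts()], ordered along the
#'   feature.
#' @param qualifiers Named list of free-form annotations.
#' @return An object of class `Feature`.
#' @export
feature <- function(kind, name, strand = "+", parts, qualifiers = list()) {
  kind <- match.arg(kind, FEATURE_KINDS)
  stopifnot(strand %in% c("+", "-"), nrow(parts) >= 1L)
  structure(list(kind = kind, name = name, strand = strand,
                 parts = parts, qualifiers = qualifiers),
            class = "Feature")
}

#' Construct an annotated genome
#'
#' The substrate of every statistic in the package: a DNA sequence, its
#' mapping conformation (circular or linear), and a typed feature list.
#'
#' @param id Accession-like identifier.
#' @param sequence DNA string over `A,C,G,T,N` (uppercased on input).
#' @param circular Logical mapping conformation.
#' @param features List of [feature()] objects.
#' @return An object of class `AnnotatedGenome`.
#' @export
annotated_genome <- function(id, sequence, circular = FALSE,
                             features = list()) {
  sequence <- normalize_dna(sequence, what = paste0("genome ", id))
  if (nchar(sequence) == 0L) stop("genome sequence must be non-empty")
  g <- structure(list(id = id, sequence = sequence,
                      circular = isTRUE(circular), features = features),
                 class = "AnnotatedGenome")
  validate_genome(g)
  g
}

#' @export
print.AnnotatedGenome <- function(x, ...) {
  kinds <- vapply(x$features, function(f) f$kind, "")
  cat(sprintf("AnnotatedGenome %s: %d nt, %s, %d features\n", x$id,
              nchar(x$sequence), if (x$circular) "circular" else "linear",
              length(x$features)))
  if (length(kinds)) {
    tab <- table(factor(kinds, levels = FEATURE_KINDS))
    tab <- tab[tab > 0]
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Genome length in nucleotides
#' @param genome An `AnnotatedGenome`.
#' @return Integer length.
#' @export
genome_length <- function(genome) nchar(genome$sequence)

# width of each part, wrap-aware
part_widths <- function(parts, L) {
  ifelse(parts$wraps, (L - parts$start + 1L) + parts$end,
         parts$end - parts$start + 1L)
}

validate_genome <- function(g) {
  L <- genome_length(g)
  for (f in g$features) {
    p <- f$parts
    if (any(p$start < 1L | p$start > L | p$end < 1L | p$end > L)) {
      stop(sprintf("feature '%s' has coordinates outside [1, %d]", f$name, L),
           call. = FALSE)
    }
    if (any(p$wraps & !g$circular)) {
      stop(sprintf("feature '%s' wraps the origin of a linear genome", f$name),
           call. = FALSE)
    }
    if (any(!p$wraps & p$end < p$start)) {
      stop(sprintf("feature '%s' has end < start without wraps", f$name),
           call. = FALSE)
    }
  }
  invisible(g)
}

# feature parts as a linear IRanges, wrapped parts split at the origin
parts_to_iranges <- function(parts, L) {
  st <- integer(0); en <- integer(0)
  for (i in seq_len(nrow(parts))) {
    if (parts$wraps[i]) {
      st <- c(st, parts$start[i], 1L); en <- c(en, L, parts$end[i])
    } else {
      st <- c(st, parts$start[i]); en <- c(en, parts$end[i])
    }
  }
  IRanges::IRanges(start = st, end = en)
}

# span of a feature (min start to max end along the feature's reading
# direction), as a single (possibly wrapping) interval
feature_span <- function(f, L) {
  p <- f$parts
  if (any(p$wraps)) {
    # canonical span of a wrapping feature: from the first part's start
    # around the origin to the last part's end
    return(feature_parts(p$start[1L], p$end[nrow(p)], wraps = TRUE))
  }
  feature_parts(min(p$start), max(p$end))
}

#' Extract a subsequence from a genome
#'
#' Wrapping intervals concatenate the suffix and prefix of a circular genome;
#' `strand = "-"` returns the reverse complement.
#'
#' @param genome An `AnnotatedGenome`, or a plain character sequence.
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` or `"-"`.
#' @param wraps Whether the interval crosses the origin (`end < start`).
#' @return Character scalar.
#' @export
extract_seq <- function(genome, start, end, strand = "+", wraps = FALSE) {
  s <- if (inherits(genome, "AnnotatedGenome")) genome$sequence else genome
  circ <- if (inherits(genome, "AnnotatedGenome")) genome$circular else TRUE
  L <- nchar(s)
  stopifnot(start >= 1L, start <= L, end >= 1L, end <= L)
  if (wraps) {
    if (!circ) stop("wrapping extraction requested on a linear genome")
    out <- paste0(substring(s, start, L), substring(s, 1L, end))
  } else {
    stopifnot(end >= start)
    out <- substring(s, start, end)
  }
  if (strand == "-") out <- revcomp(out)
  out
}

# spliced, strand-resolved sequence of a feature (parts in genome order;
# minus strand reverse-complements the concatenation)
feature_seq <- function(genome, f) {
  pieces <- vapply(seq_len(nrow(f$parts)), function(i) {
    extract_seq(genome, f$parts$start[i], f$parts$end[i],
                strand = "+", wraps = f$parts$wraps[i])
  }, "")
  out <- paste(pieces, collapse = "")
  if (f$strand == "-") out <- revcomp(out)
  out
}

#' Rotate a circular genome to a new origin
#'
#' Position `offset + 1` of the input becomes position 1 of the output;
#' features are remapped, acquiring or losing wrap flags as needed. Every
#' statistic in the package is invariant under this operation.
#'
#' @param genome A circular `AnnotatedGenome`.
#' @param offset Number of nucleotides to rotate by (0 to length-1).
#' @return The rotated `AnnotatedGenome`.
#' @export
rotate_genome <- function(genome, offset) {
  if (!genome$circular) stop("only circular genomes can be rotated")
  L <- genome_length(genome)
  offset <- ((offset %% L) + L) %% L
  if (offset == 0L) return(genome)
  s <- genome$sequence
  newseq <- paste0(substring(s, offset + 1L, L), substring(s, 1L, offset))
  map1 <- function(x) ((x - offset - 1L) %% L) + 1L
  feats <- lapply(genome$features, function(f) {
    p <- f$parts
    ns <- map1(p$start); ne <- map1(p$end)
    w <- ne < ns
    # a formerly wrapping part may become linear and vice versa
    f$parts <- feature_parts(ns, ne, wraps = w)
    f
  })
  annotated_genome(genome$id, newseq, circular = TRUE, features = feats)
}

# per-position logical mask covered by any of the given IRanges
coverage_mask <- function(ir, L) {
  m <- logical(L)
  if (length(ir)) {
    red <- IRanges::reduce(ir)
    for (i in seq_along(red)) {
      m[IRanges::start(red)[i]:IRanges::end(red)[i]] <- TRUE
    }
  }
  m
}

# select features by kind
features_of_kind <- function(genome, kinds) {
  Filter(function(f) f$kind %in% kinds, genome$features)
}

# is a feature flagged pseudo (qualifier or psi label)?
is_pseudo <- function(f) {
  f$kind == "pseudogene" ||
    isTRUE(f$qualifiers$pseudo) || "pseudo" %in% names(f$qualifiers) &&
      !identical(f$qualifiers$pseudo, FALSE) ||
    grepl("psi|ψ", f$name, ignore.case = TRUE)
}
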