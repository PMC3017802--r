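## Low-level sequence utilities shared across modules.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Reverse complement of a DNA string
#'
#' @param s A character scalar over `A,C,G,T,N`.
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  if (nchar(s) == 0L) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Complement (without reversal) of a DNA string
#' @param s A character scalar over `A,C,G,T,N`.
#' @return The complement as a character scalar.
#' @export
complement_seq <- function(s) chartr("ACGTN", "TGCAN", s)

#' Reverse (without complementation) of a DNA string
#' @param s A character scalar.
#' @return The reversed string.
#' @export
reverse_seq <- function(s) {
  if (nchar(s) == 0L) return(s)
  paste(rev(strsplit(s, NULL, fixed = TRUE)[[1L]]), collapse = "")
}

# split into single characters
dna_chars <- function(s) strsplit(s, NULL, fixed = TRUE)[[1L]]

# byte representation; raw comparisons are the fast path for Hamming scans
dna_raw <- function(s) charToRaw(s)

# raw-level complement lookup (A<->T, C<->G, N->N)
raw_complement <- function(r) {
  lut <- raw(256L)
  lut[as.integer(charToRaw("A")) + 1L] <- charToRaw("T")
  lut[as.integer(charToRaw("C")) + 1L] <- charToRaw("G")
  lut[as.integer(charToRaw("G")) + 1L] <- charToRaw("C")
  lut[as.integer(charToRaw("T")) + 1L] <- charToRaw("A")
  lut[as.integer(charToRaw("N")) + 1L] <- charToRaw("N")
  lut[as.integer(r) + 1L]
}

#' Random DNA sequence
#'
#' Draws an i.i.d. sequence with a given GC content (A/T and G/C split evenly).
#' Randomness comes from the session RNG; callers seed it.
#'
#' @param n Length in nucleotides.
#' @param gc Target GC fraction in `[0, 1]`.
#' @return Character scalar of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# k-mer start positions table; data.table with columns kmer, pos
kmer_table <- function(s, k) {
  n <- nchar(s)
  if (n < k) {
    return(data.table::data.table(kmer = character(0), pos = integer(0)))
  }
  pos <- seq_len(n - k + 1L)
  data.table::data.table(kmer = substring(s, pos, pos + k - 1L), pos = pos)
}

# Hamming distance between equal-length strings
hamming <- function(a, b) {
  ra <- dna_raw(a); rb <- dna_raw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}

# identity fraction of equal-length strings
seq_identity <- function(a, b) {
  ra <- dna_raw(a); rb <- dna_raw(b)
  stopifnot(length(ra) == length(rb))
  if (length(ra) == 0L) return(NA_real_)
  mean(ra == rb)
}

# sanitize/validate a DNA string: uppercase, optionally map non-ACGTN to N
normalize_dna <- function(s, map_to_N = FALSE, what = "sequence") {
  s <- toupper(s)
  bad <- gsub("[ACGTN]", "", s)
  if (nchar(bad) > 0L) {
    if (map_to_N) {
      s <- gsub("[^ACGTN]", "N", s)
    } else {
      stop(sprintf("%s contains non-ACGTN characters (e.g. '%s')",
                   what, substr(bad, 1L, 1L)), call. = FALSE)
    }
  }
  s
}

# lexicographically minimal rotation of a circular string (vectorized
# candidate-elimination; adequate for non-degenerate genomic sequence)
minimal_rotation <- function(s) {
  n <- nchar(s)
  if (n <= 1L) return(s)
  r <- as.integer(dna_raw(paste0(s, s)))
  cand <- which(r[seq_len(n)] == min(r[seq_len(n)]))
  depth <- 1L
  while (length(cand) > 1L && depth < n) {
    ch <- r[cand + depth]
    cand <- cand[ch == min(ch)]
    depth <- depth + 1L
  }
  i <- cand[1L]
  substring(paste0(s, s), i, i + n - 1L)
}

# canonical strand + rotation for a circular sequence: the lexicographically
# smaller of the minimal rotations of the sequence and its reverse complement
canonical_circular <- function(s) {
  a <- minimal_rotation(s)
  b <- minimal_rotation(revcomp(s))
  if (a <= b) a else b
}

# GC fraction of a string, N-aware
gc_fraction <- function(s) {
  if (!nzchar(s)) stop("empty sequence has no GC content", call. = FALSE)
  x <- Biostrings::DNAString(s)
  f <- Biostrings::letterFrequency(x, c("G", "C", "A", "T"))
  den <- sum(f)
  if (den == 0) stop("all-N sequence has undefined GC content", call. = FALSE)
  unname((f[["G"]] + f[["C"]]) / den)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
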