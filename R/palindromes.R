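## Palindromic (hairpin-capable) element detection, genomic clustering,
## family consensus, and loop-motif tallies.
##
## Detection is a combinatorial stem-loop scan, not thermodynamic folding:
## an element is a left arm, a loop of bounded length, and a right arm that
## is the reverse complement of the left arm within a small mismatch budget.
## The innermost and outermost arm pairs must pair (a mismatched innermost
## pair is the same structure with a longer loop; a mismatched outermost
## pair is not a maximal stem). G:T wobble pairs do not count as pairing.

#' Find hairpin-capable palindromic elements
#'
#' Reports all maximal stem-loops with stem length at least `min_stem`, loop
#' length within `loop_range`, and at most `max_arm_mismatch` internal
#' mismatched pairs; overlapping calls are resolved to the longest stem,
#' then leftmost element.
#'
#' @param seq DNA string.
#' @param min_stem Minimum stem (arm) length in nt (default 8).
#' @param loop_range Length-2 vector of allowed loop lengths (default
#'   `c(3, 12)`).
#' @param max_arm_mismatch Maximum mismatched pairs in the stem (default 1).
#' @param max_stem Scan depth cap for the arm extension (default 40).
#' @return A data frame of `Hairpin` rows: `start`, `end`, `stem_len`,
#'   `loop_len`, `loop`, `arm_mismatches`, `gc`.
#' @export
find_hairpins <- function(seq, min_stem = 8L, loop_range = c(3L, 12L),
                          max_arm_mismatch = 1L, max_stem = 40L) {
  n <- nchar(seq)
  stopifnot(loop_range[1L] >= 1L, loop_range[2L] >= loop_range[1L])
  if (n < 2L * min_stem + loop_range[1L]) {
    return(empty_hairpins())
  }
  r <- dna_raw(seq)
  rc <- raw_complement(r)
  J <- max_stem
  cands <- list()
  for (l in loop_range[1L]:loop_range[2L]) {
    ## p = position of the innermost left-arm base; loop = p+1 .. p+l
    p <- seq_len(n)
    M <- matrix(FALSE, n, J)
    for (jj in seq_len(J)) {
      li <- p - jj + 1L          # left partner of pair jj
      ri <- p + l + jj           # right partner
      ok <- li >= 1L & ri <= n
      M[ok, jj] <- r[li[ok]] == rc[ri[ok]]
    }
    ## cumulative mismatches over pair depth
    UT <- upper.tri(matrix(0, J, J), diag = TRUE) * 1
    C <- (!M) %*% UT
    valid <- (C <= max_arm_mismatch) & M & M[, 1L]
    V <- valid * matrix(seq_len(J), n, J, byrow = TRUE)
    s <- max.col(V, ties.method = "last")
    s[rowSums(valid) == 0L] <- 0L
    ## out-of-bounds pairs were filled FALSE, so s never exceeds the bounds
    sel <- which(s >= min_stem)
    if (!length(sel)) next
    mism <- C[cbind(sel, s[sel])]
    cands[[length(cands) + 1L]] <- data.frame(
      start = sel - s[sel] + 1L, end = sel + l + s[sel],
      stem_len = s[sel], loop_len = l, arm_mismatches = mism)
  }
  if (!length(cands)) return(empty_hairpins())
  cand <- do.call(rbind, cands)
  ## overlap resolution: longest stem, then leftmost, then shortest loop
  cand <- cand[order(-cand$stem_len, cand$start, cand$loop_len), ]
  taken <- logical(n)
  keep <- logical(nrow(cand))
  for (q in seq_len(nrow(cand))) {
    span <- cand$start[q]:cand$end[q]
    if (!any(taken[span])) {
      keep[q] <- TRUE
      taken[span] <- TRUE
    }
  }
  hp <- cand[keep, ]
  hp <- hp[order(hp$start), ]
  rownames(hp) <- NULL
  hp$loop <- substring(seq, hp$start + hp$stem_len,
                       hp$start + hp$stem_len + hp$loop_len - 1L)
  hp$gc <- vapply(seq_len(nrow(hp)), function(q)
    gc_fraction(substring(seq, hp$start[q], hp$end[q])), 0)
  hp[, c("start", "end", "stem_len", "loop_len", "loop",
         "arm_mismatches", "gc")]
}

empty_hairpins <- function() {
  data.frame(start = integer(0), end = integer(0), stem_len = integer(0),
             loop_len = integer(0), loop = character(0),
             arm_mismatches = integer(0), gc = numeric(0))
}

#' Group hairpins into genomic clusters
#'
#' Single-linkage chaining of hairpins whose gap does not exceed `max_gap`.
#' When the source sequence (and optionally an annotated genome) is given,
#' per-cluster GC and annotation context are reported.
#'
#' @param hairpins A hairpin data frame from [find_hairpins()], sorted by
#'   position.
#' @param seq Optional source sequence for GC computation.
#' @param genome Optional `AnnotatedGenome` for context classification
#'   (`intergenic`, `intronic`, or `coding`, by majority of cluster span).
#' @param max_gap Maximum gap between adjacent cluster members in nt
#'   (default 30).
#' @return A data frame of `PalindromeCluster` rows: `start`, `end`,
#'   `length`, `n_hairpins`, `gc`, `context`.
#' @export
cluster_hairpins <- function(hairpins, max_gap = 30L, seq = NULL,
                             genome = NULL) {
  if (!nrow(hairpins)) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), n_hairpins = integer(0),
                      gc = numeric(0), context = character(0)))
  }
  hairpins <- hairpins[order(hairpins$start), ]
  gap <- hairpins$start[-1L] - hairpins$end[-nrow(hairpins)] - 1L
  cl <- cumsum(c(1L, as.integer(gap > max_gap)))
  if (is.null(seq) && !is.null(genome)) seq <- genome$sequence
  ctx_masks <- NULL
  if (!is.null(genome)) {
    L <- genome_length(genome)
    coding_m <- coverage_mask(kind_iranges(genome, coding_kinds), L)
    intron_m <- coverage_mask(kind_iranges(genome, intronic_kinds), L)
    gene_m <- coverage_mask(gene_union_iranges(genome), L)
    ctx_masks <- list(coding = coding_m & !intron_m,
                      intronic = (gene_m & !(coding_m & !intron_m)) | intron_m,
                      intergenic = !gene_m & !intron_m)
  }
  out <- lapply(split(seq_len(nrow(hairpins)), cl), function(idx) {
    st <- min(hairpins$start[idx]); en <- max(hairpins$end[idx])
    gc <- if (!is.null(seq)) gc_fraction(substring(seq, st, en)) else NA_real_
    ctx <- NA_character_
    if (!is.null(ctx_masks)) {
      span <- st:en
      votes <- vapply(ctx_masks, function(m) sum(m[span]), 0)
      ctx <- names(votes)[which.max(votes)]
    }
    data.frame(start = st, end = en, length = en - st + 1L,
               n_hairpins = length(idx), gc = gc, context = ctx)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## IUPAC code for a set of bases
iupac_code <- local({
  map <- Biostrings::IUPAC_CODE_MAP
  rev_map <- stats::setNames(names(map),
                             vapply(strsplit(map, ""), function(x)
                               paste(sort(x), collapse = ""), ""))
  function(bases) {
    key <- paste(sort(unique(bases)), collapse = "")
    unname(rev_map[key])
  }
})

#' Build family consensus sequences for palindrome clusters
#'
#' Clusters are grouped into families by pairwise identity of their
#' strand-canonicalized sequences (a cluster and its reverse complement are
#' the same object; the lexicographically smaller of sequence/revcomp is the
#' family key). Each family gets a column-majority IUPAC consensus (ties
#' produce the ambiguity code of the tied bases) and an occurrence count.
#'
#' @param clusters A cluster data frame from [cluster_hairpins()].
#' @param seq The source sequence.
#' @param identity Family-membership identity threshold (default 0.7).
#' @return A list of `ClusterConsensus` objects: `consensus` (IUPAC string),
#'   `occurrences`, `members` (start positions).
#' @export
build_consensus <- function(clusters, seq, identity = 0.7) {
  stopifnot(nrow(clusters) >= 1L)
  seqs <- substring(seq, clusters$start, clusters$end)
  rcs <- vapply(seqs, revcomp, "", USE.NAMES = FALSE)
  nu <- length(seqs)
  parent <- seq_len(nu)
  findr <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  ## strand-agnostic pairwise identity: a cluster and its reverse
  ## complement are the same object
  pid2 <- function(i, j) {
    max(pair_identity(seqs[i], seqs[j]), pair_identity(seqs[i], rcs[j]))
  }
  if (nu > 1L) {
    for (i in 1:(nu - 1L)) {
      for (j in (i + 1L):nu) {
        if (pid2(i, j) >= identity) {
          ri <- findr(i); rj <- findr(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  comp <- vapply(seq_len(nu), findr, 0L)
  fams <- lapply(split(seq_len(nu), comp), function(idx) {
    ## orient every member to the family representative (longest, then
    ## lexicographically smallest member)
    lens <- nchar(seqs[idx])
    rep_i <- idx[order(-lens, seqs[idx])][1L]
    members <- vapply(idx, function(i) {
      if (pair_identity(seqs[i], seqs[rep_i]) >=
          pair_identity(rcs[i], seqs[rep_i])) seqs[i] else rcs[i]
    }, "")
    cons <- column_majority_consensus(members)
    ## canonical strand for reporting (reverse complement is IUPAC-aware)
    crc <- revcomp(cons)
    if (crc < cons) {
      members <- vapply(members, revcomp, "", USE.NAMES = FALSE)
      cons <- column_majority_consensus(members)
    }
    structure(list(consensus = cons, occurrences = length(idx),
                   members = clusters$start[idx]),
              class = "ClusterConsensus")
  })
  names(fams) <- NULL
  fams[order(-vapply(fams, `[[`, 0L, "occurrences"))]
}

# column-majority IUPAC consensus; unequal-length members are aligned to the
# longest member by global alignment, member insertions dropped
column_majority_consensus <- function(members) {
  lens <- nchar(members)
  ref <- members[order(-lens, members)][1L]
  cols <- lapply(members, function(m) {
    if (nchar(m) == nchar(ref)) return(dna_chars(m))
    al <- Biostrings::pairwiseAlignment(m, ref, type = "global",
                                        substitutionMatrix =
                                          Biostrings::nucleotideSubstitutionMatrix(1, -1),
                                        gapOpening = 2, gapExtension = 1)
    pat <- dna_chars(as.character(Biostrings::alignedPattern(al)))
    sub <- dna_chars(as.character(Biostrings::alignedSubject(al)))
    keep <- sub != "-"
    out <- pat[keep]
    out[out == "-"] <- NA_character_
    length(out) <- nchar(ref)
    out
  })
  mat <- do.call(rbind, cols)
  cons <- vapply(seq_len(ncol(mat)), function(cc) {
    col <- mat[, cc]
    col <- col[!is.na(col) & col %in% c("A", "C", "G", "T")]
    if (!length(col)) return("N")
    tab <- table(col)
    iupac_code(names(tab)[tab == max(tab)])
  }, "")
  paste(cons, collapse = "")
}

#' @export
print.ClusterConsensus <- function(x, ...) {
  cat(sprintf("ClusterConsensus: %d occurrence(s), %s\n", x$occurrences,
              x$consensus))
  invisible(x)
}

#' Tally loop motifs across hairpins
#'
#' Counts hairpins whose loop contains each motif; motifs are tried longest
#' first and a hairpin counts towards at most one motif.
#'
#' @param hairpins A hairpin data frame from [find_hairpins()].
#' @param motifs Character vector of motifs (default `c("TTTA", "TTT")`).
#' @return Named integer vector of counts.
#' @export
loop_motif_tally <- function(hairpins, motifs = c("TTTA", "TTT")) {
  motifs <- motifs[order(-nchar(motifs))]
  counts <- stats::setNames(integer(length(motifs)), motifs)
  for (loop in hairpins$loop) {
    for (m in motifs) {
      if (grepl(m, loop, fixed = TRUE)) {
        counts[m] <- counts[m] + 1L
        break
      }
    }
  }
  counts
}
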