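## Maximal repeat finding (forward / reverse / complement / reverse-
## complement; exact or Hamming-approximate), repeat-family clustering, and
## sliding-window dotplot matrices.
##
## The finder is seed-and-extend: exact seeds of pigeonhole-guaranteed length
## floor((min_len - k) / (k + 1)) locate candidate diagonals between the
## sequence and its per-type transform; around each seed, the maximal
## intervals holding at most k mismatches are enumerated from the positions
## of the flanking mismatches, which is provably complete for the configured
## (min_len, k).

REPEAT_TYPES <- c("F", "R", "C", "RC")

# transform of the subject sequence for each repeat type
type_transform <- function(s, type) {
  switch(type, F = s, R = reverse_seq(s), C = complement_seq(s),
         RC = revcomp(s))
}

# map an instance interval in transform coordinates back to the genome
type_backmap <- function(j, len, n, type) {
  switch(type,
         F = c(j, j + len - 1L),
         C = c(j, j + len - 1L),
         R = c(n - j - len + 2L, n - j + 1L),
         RC = c(n - j - len + 2L, n - j + 1L))
}

#' Find maximal repeat pairs in a sequence
#'
#' Reports every maximal pair (not extendable in either direction within the
#' mismatch budget) of length at least `min_len` under the requested repeat
#' types, each once under a canonical ordering (`start_a`, `end_a`) <
#' (`start_b`, `end_b`); the trivial full-length self match is excluded.
#'
#' @param seq DNA string.
#' @param min_len Minimal repeat size in nt (default 12).
#' @param hamming_k Mismatch budget per pair, 0-3 (default 0).
#' @param types Subset of `c("F", "R", "C", "RC")` (forward, reverse,
#'   complement, reverse complement).
#' @return A data frame of `RepeatMatch` rows: `type`, `start_a`, `end_a`,
#'   `start_b`, `end_b`, `length`, `mismatches`, `at_fraction`.
#' @export
find_maximal_repeats <- function(seq, min_len = 12L, hamming_k = 0L,
                                 types = REPEAT_TYPES) {
  stopifnot(hamming_k >= 0L, hamming_k <= 3L)
  if (min_len < 4L) stop("min_len below 4 makes seeding infeasible")
  n <- nchar(seq)
  if (n < min_len) stop("sequence shorter than min_len")
  types <- match.arg(types, REPEAT_TYPES, several.ok = TRUE)
  w <- max(4L, (min_len - hamming_k) %/% (hamming_k + 1L))
  out <- list()
  xr <- dna_raw(seq)
  kx <- kmer_table(seq, w)
  data.table::setkey(kx, kmer)
  for (type in types) {
    y <- type_transform(seq, type)
    yr <- dna_raw(y)
    ky <- kmer_table(y, w)
    hits <- kx[ky, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (!nrow(hits)) next
    data.table::setnames(hits, c("kmer", "pos", "i.pos"), c("kmer", "i", "j"))
    if (type == "F") hits <- hits[hits$i != hits$j, ]
    if (!nrow(hits)) next
    hits[, diag := j - i]
    data.table::setorder(hits, diag, i)
    seen <- new.env(hash = TRUE)
    res <- list()
    last_diag <- NA_integer_; last_skip <- -Inf
    for (r in seq_len(nrow(hits))) {
      d <- hits$diag[r]; i <- hits$i[r]
      ## seeds within the exact run already enumerated yield the same
      ## intervals and are skipped
      if (!is.na(last_diag) && d == last_diag && i <= last_skip) next
      found <- maximal_intervals_at(xr, yr, i, i + d, w, hamming_k, min_len)
      ivs <- found$ivs
      last_diag <- d
      last_skip <- found$run_hi - w + 1L
      if (is.null(ivs)) next
      for (q in seq_len(nrow(ivs))) {
        a <- c(ivs$i_start[q], ivs$i_end[q])
        len <- a[2L] - a[1L] + 1L
        b <- type_backmap(ivs$j_start[q], len, n, type)
        inst <- rbind(c(a[1L], a[2L]), c(b[1L], b[2L]))
        inst <- inst[order(inst[, 1L], inst[, 2L]), , drop = FALSE]
        if (all(inst[1L, ] == inst[2L, ])) next   # degenerate self pair
        key <- paste(type, inst[1L, 1L], inst[1L, 2L], inst[2L, 1L], inst[2L, 2L])
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        res[[length(res) + 1L]] <-
          data.frame(type = type,
                     start_a = inst[1L, 1L], end_a = inst[1L, 2L],
                     start_b = inst[2L, 1L], end_b = inst[2L, 2L],
                     length = len, mismatches = ivs$mis[q])
      }
    }
    if (length(res)) out[[type]] <- do.call(rbind, res)
  }
  if (!length(out)) {
    return(data.frame(type = character(0), start_a = integer(0),
                      end_a = integer(0), start_b = integer(0),
                      end_b = integer(0), length = integer(0),
                      mismatches = integer(0), at_fraction = numeric(0)))
  }
  m <- do.call(rbind, out)
  rownames(m) <- NULL
  m$at_fraction <- vapply(seq_len(nrow(m)), function(r) {
    1 - gc_fraction(substring(seq, m$start_a[r], m$end_a[r]))
  }, 0)
  m[order(m$type, m$start_a, m$start_b), ]
}

# Enumerate the maximal <=k-mismatch intervals on the diagonal through seed
# (i, j); i/j are coordinates into xr/yr. Returns list(ivs, run_hi) where
# ivs is NULL or a data frame (i_start, i_end, j_start, mis) and run_hi is
# the end (in i coordinates) of the seed's exact run.
maximal_intervals_at <- function(xr, yr, i, j, w, k, min_len) {
  nx <- length(xr); ny <- length(yr)
  ## walk right collecting up to k+1 mismatch offsets (0-based from i)
  right_m <- integer(0)
  t <- w   # seed occupies offsets 0..w-1 and is exact
  while (length(right_m) <= k) {
    if (i + t > nx || j + t > ny) { right_m <- c(right_m, t); break }
    if (xr[i + t] != yr[j + t]) right_m <- c(right_m, t)
    t <- t + 1L
  }
  while (length(right_m) <= k) right_m <- c(right_m, t)  # boundary sentinel
  ## walk left collecting up to k+1 mismatch offsets (negative)
  left_m <- integer(0)
  t <- -1L
  while (length(left_m) <= k) {
    if (i + t < 1L || j + t < 1L) { left_m <- c(left_m, t); break }
    if (xr[i + t] != yr[j + t]) left_m <- c(left_m, t)
    t <- t - 1L
  }
  while (length(left_m) <= k) left_m <- c(left_m, t)
  at_boundary_r <- (i + right_m > nx) | (j + right_m > ny)
  at_boundary_l <- (i + left_m < 1L) | (j + left_m < 1L)
  run_hi <- i + right_m[1L] - 1L
  rows <- list()
  for (a in 0:k) {        # a mismatches taken on the left, k - a on the right
    b <- k - a
    lo <- left_m[a + 1L] + 1L     # one right of the (a+1)-th left mismatch
    hi <- right_m[b + 1L] - 1L    # one left of the (b+1)-th right mismatch
    len <- hi - lo + 1L
    if (len < min_len) next
    ## boundary sentinels among the chosen flanks are not real mismatches
    nmis <- a + b -
      sum(at_boundary_l[seq_len(a)]) - sum(at_boundary_r[seq_len(b)])
    rows[[length(rows) + 1L]] <- c(i + lo, i + hi, j + lo, nmis)
  }
  if (!length(rows)) return(list(ivs = NULL, run_hi = run_hi))
  m <- do.call(rbind, rows)
  m <- m[!duplicated(m[, 1:2, drop = FALSE]), , drop = FALSE]
  list(ivs = data.frame(i_start = m[, 1L], i_end = m[, 2L],
                        j_start = m[, 3L], mis = m[, 4L]),
       run_hi = run_hi)
}

#' Cluster repeat instances into families
#'
#' Single-linkage clustering of the repeat instances of a match list on
#' pairwise sequence identity. Links come from the matches themselves (two
#' sides of a match within the mismatch budget are near-identical), from
#' genomic co-location of overlapping instances, and from alignment of the
#' remaining family representatives, which keeps the linkage complete
#' without aligning every instance pair. Each family reports its members, a
#' representative (the most frequent instance sequence), length range, and
#' mean AT fraction.
#'
#' @param matches A match data frame from [find_maximal_repeats()].
#' @param seq The sequence the matches were found in.
#' @param identity Single-linkage identity threshold (default 0.8).
#' @return A list of `RepeatFamily` objects (members, representative, size,
#'   length_range, at_fraction).
#' @export
cluster_repeats <- function(matches, seq, identity = 0.8) {
  if (!nrow(matches)) stop("no repeat matches to cluster")
  inst <- unique(rbind(
    data.frame(start = matches$start_a, end = matches$end_a),
    data.frame(start = matches$start_b, end = matches$end_b)))
  inst <- inst[order(inst$start, inst$end), ]
  rownames(inst) <- NULL
  inst$seq <- substring(seq, inst$start, inst$end)
  ni <- nrow(inst)
  parent <- seq_len(ni)
  findr <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  unite <- function(i, j) {
    ri <- findr(i); rj <- findr(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  key <- paste(inst$start, inst$end)
  idx_of <- stats::setNames(seq_len(ni), key)
  ## the matches themselves certify near-identity of their two instances
  for (r in seq_len(nrow(matches))) {
    if (matches$mismatches[r] / matches$length[r] <= 1 - identity) {
      unite(idx_of[[paste(matches$start_a[r], matches$end_a[r])]],
            idx_of[[paste(matches$start_b[r], matches$end_b[r])]])
    }
  }
  ## genomic co-location: instances sharing most of their span
  for (i in seq_len(ni - 1L)) {
    j <- i + 1L
    while (j <= ni && inst$start[j] <= inst$end[i]) {
      ov <- min(inst$end[i], inst$end[j]) - inst$start[j] + 1L
      if (ov >= identity * max(nchar(inst$seq[i]), nchar(inst$seq[j]))) {
        unite(i, j)
      }
      j <- j + 1L
    }
  }
  ## merge remaining components whose representatives align at >= identity
  comp <- vapply(seq_len(ni), findr, 0L)
  reps <- vapply(split(seq_len(ni), comp), function(ii) {
    tab <- sort(table(inst$seq[ii]), decreasing = TRUE)
    names(tab)[1L]
  }, "")
  rep_idx <- vapply(split(seq_len(ni), comp), `[`, 0L, 1L)
  nr <- length(reps)
  if (nr > 1L && nr <= 400L) {
    for (i in 1:(nr - 1L)) {
      for (j in (i + 1L):nr) {
        if (findr(rep_idx[i]) != findr(rep_idx[j]) &&
            pair_identity(reps[i], reps[j]) >= identity) {
          unite(rep_idx[i], rep_idx[j])
        }
      }
    }
  }
  comp <- vapply(seq_len(ni), findr, 0L)
  fams <- lapply(split(inst, comp), function(mem) {
    tab <- sort(table(mem$seq), decreasing = TRUE)
    structure(list(members = mem[, c("start", "end", "seq")],
                   representative = names(tab)[1L],
                   size = nrow(mem),
                   length_range = range(nchar(mem$seq)),
                   at_fraction = mean(1 - vapply(mem$seq, gc_fraction, 0))),
              class = "RepeatFamily")
  })
  names(fams) <- NULL
  fams[order(-vapply(fams, `[[`, 0L, "size"))]
}

# identity of two (possibly unequal-length) instance sequences: global
# alignment identities over the longer length
pair_identity <- function(a, b) {
  if (a == b) return(1)
  if (nchar(a) == nchar(b)) return(seq_identity(a, b))
  al <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix =
                                        Biostrings::nucleotideSubstitutionMatrix(1, -1),
                                      gapOpening = 1, gapExtension = 1)
  Biostrings::nmatch(al) / max(nchar(a), nchar(b))
}

#' @export
print.RepeatFamily <- function(x, ...) {
  cat(sprintf("RepeatFamily: %d members, %d-%d nt, %.0f%% AT, rep %s\n",
              x$size, x$length_range[1L], x$length_range[2L],
              100 * x$at_fraction,
              if (nchar(x$representative) > 30)
                paste0(substr(x$representative, 1, 27), "...")
              else x$representative))
  invisible(x)
}

#' Sliding-window dotplot matrix
#'
#' `score[i, j]` is the number of identities between
#' `seq_a[i..i+window-1]` and `seq_b[j..j+window-1]`. A self-plot has a
#' maximal main diagonal; `dotplot(a, b)` is the transpose of
#' `dotplot(b, a)`.
#'
#' @param seq_a,seq_b DNA strings (both at least `window` long).
#' @param window Window size in nt (default 50).
#' @return A `DotplotMatrix`: integer matrix with attributes `window` and
#'   `axes`.
#' @export
dotplot <- function(seq_a, seq_b = seq_a, window = 50L) {
  na <- nchar(seq_a); nb <- nchar(seq_b)
  if (window > min(na, nb)) stop("window exceeds a sequence length")
  ra <- dna_raw(seq_a); rb <- dna_raw(seq_b)
  nr <- na - window + 1L; nc <- nb - window + 1L
  if (as.double(nr) * nc > 3e7) {
    stop("dotplot matrix would exceed 3e7 cells; use shorter sequences")
  }
  E <- outer(ra, rb, `==`)
  S <- matrix(0L, nr, nc)
  for (o in 0:(window - 1L)) {
    S <- S + E[(1L + o):(nr + o), (1L + o):(nc + o)]
  }
  structure(S, window = window, axes = c("seq_a", "seq_b"),
            class = c("DotplotMatrix", class(S)))
}

#' Write above-threshold dotplot cells as sparse TSV
#'
#' @param dp A `DotplotMatrix`.
#' @param path Output path.
#' @param min_score Minimum window identities to report (default 80% of the
#'   window).
#' @return `path`, invisibly.
#' @export
dotplot_sparse <- function(dp, path, min_score = NULL) {
  w <- attr(dp, "window")
  if (is.null(min_score)) min_score <- ceiling(0.8 * w)
  idx <- which(dp >= min_score, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1L], j = idx[, 2L], score = dp[idx])
  df <- df[order(df$i, df$j), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
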