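## Bait-and-walk assembly: seeded recruitment of organelle-like traces from
## a mixed archive, greedy overlap-layout-consensus assembly, iterative
## contig walking, and circular closure detection.
##
## Overlap placement and the consensus caller are substitution-only: an
## overlap is evaluated on the best shared-seed diagonal between two
## sequences and scored under the configured match/mismatch scores, and the
## consensus is a coverage-weighted per-column majority. Recruitment falls
## back to a gapped local alignment (under the recruitment scoring scheme)
## when the diagonal evaluation fails.

#' Construct a trace archive
#'
#' @param sequences Named character vector of read sequences (names are
#'   trace ids), or a data frame with columns `id` and `sequence`.
#' @param origin Optional per-trace origin tags (`organelle`, `nuclear`,
#'   `unknown`), used only for evaluation of synthetic data.
#' @return A `TraceArchive` data frame with columns `id`, `sequence`,
#'   `origin`.
#' @export
trace_archive <- function(sequences, origin = NULL) {
  if (is.data.frame(sequences)) {
    df <- as.data.frame(sequences)
    if (!"origin" %in% names(df)) df$origin <- origin %||% "unknown"
  } else {
    ids <- names(sequences) %||% paste0("trace", seq_along(sequences))
    df <- data.frame(id = ids, sequence = unname(sequences),
                     origin = origin %||% "unknown")
  }
  stopifnot(all(nchar(df$sequence) > 0L))
  class(df) <- c("TraceArchive", "data.frame")
  df
}

## gapless evaluation of sequence b placed at diagonal offset d relative to
## a (b[t] pairs a[t + d]); returns matches/mismatches/overlap/identity
evaluate_diagonal <- function(ra, rb, d) {
  lo <- max(1L, 1L + d); hi <- min(length(ra), length(rb) + d)
  if (hi < lo) return(NULL)
  av <- ra[lo:hi]; bv <- rb[(lo - d):(hi - d)]
  matches <- sum(av == bv)
  ovl <- hi - lo + 1L
  list(offset = d, matches = matches, mismatches = ovl - matches,
       overlap = ovl, identity = matches / ovl)
}

## best-scoring local segment along a diagonal (maximum-subarray over the
## per-position match/mismatch scores): an ungapped local alignment
diagonal_best_segment <- function(ra, rb, d, match = 2, mismatch = -3) {
  lo <- max(1L, 1L + d); hi <- min(length(ra), length(rb) + d)
  if (hi < lo) return(NULL)
  eq <- ra[lo:hi] == rb[(lo - d):(hi - d)]
  sc <- ifelse(eq, match, mismatch)
  ## maximum subarray via prefix sums
  cs <- cumsum(sc)
  pref <- c(0, cs[-length(cs)])
  pm <- cummin(pref)
  gain <- cs - pm
  best_e <- which.max(gain)
  best <- gain[best_e]
  if (best <= 0) return(NULL)
  best_s <- max(which(pref[seq_len(best_e)] == pm[best_e]))
  span <- best_e - best_s + 1L
  m <- sum(eq[best_s:best_e])
  list(offset = d, matches = m, mismatches = span - m, span = span,
       identity = m / span, score = best)
}

#' Recruit traces similar to bait sequences
#'
#' For each trace, the best match to any bait (either strand) is located by
#' exact seed sharing (default 11-mers) and evaluated on the best shared
#' diagonal; when the diagonal evaluation fails, a gapped local alignment
#' under the recruitment scoring scheme (match 2, mismatch -3, gap open 5,
#' gap extend 2) is tried. A trace is recruited when its identity over the
#' aligned span exceeds `min_similarity` and the span reaches `min_span`.
#'
#' @param archive A `TraceArchive` (or named character vector of reads).
#' @param baits Character vector of bait sequences.
#' @param min_similarity Identity threshold over the aligned span
#'   (default 0.80).
#' @param min_span Minimum aligned span in nt (default 100).
#' @param seed_k Exact seed length (default 11).
#' @param min_seeds_fallback Minimum shared-seed count before the gapped
#'   fallback alignment is attempted for a candidate that fails the
#'   ungapped evaluation (default 20).
#' @return A data frame of `RecruitmentHit` rows: `trace_id`, `bait_id`,
#'   `strand`, `aligned_length`, `identity`, `score`.
#' @export
recruit_traces <- function(archive, baits, min_similarity = 0.80,
                           min_span = 100L, seed_k = 11L,
                           min_seeds_fallback = 20L) {
  prep <- prepare_archive(archive, seed_k)
  recruit_core(prep, baits, min_similarity = min_similarity,
               min_span = min_span, min_seeds_fallback = min_seeds_fallback)
}

## precompute per-archive structures reused across walking rounds
prepare_archive <- function(archive, seed_k = 11L) {
  archive <- trace_archive(archive)
  tr_fwd <- archive$sequence
  tr_rc <- vapply(tr_fwd, revcomp, "", USE.NAMES = FALSE)
  tr_tab <- NULL
  if (nrow(archive)) {
    tr_tab <- data.table::rbindlist(lapply(seq_len(nrow(archive)),
                                           function(t) {
      f <- kmer_table(tr_fwd[t], seed_k)
      f[, `:=`(tix = t, strand = "+")]
      r <- kmer_table(tr_rc[t], seed_k)
      r[, `:=`(tix = t, strand = "-")]
      rbind(f, r)
    }))
    data.table::setkey(tr_tab, kmer)
  }
  list(archive = archive, tr_fwd = tr_fwd, tr_rc = tr_rc,
       raw_fwd = lapply(tr_fwd, dna_raw), raw_rc = lapply(tr_rc, dna_raw),
       tr_tab = tr_tab, seed_k = seed_k)
}

recruit_core <- function(prep, baits, min_similarity = 0.80,
                         min_span = 100L, min_seeds_fallback = 20L,
                         exclude = character(0)) {
  stopifnot(length(baits) >= 1L)
  archive <- prep$archive
  empty <- data.frame(trace_id = character(0), bait_id = character(0),
                      strand = character(0), aligned_length = integer(0),
                      identity = numeric(0), score = numeric(0))
  if (!nrow(archive)) return(empty)
  if (is.null(names(baits))) names(baits) <- paste0("bait", seq_along(baits))
  baits <- baits[!duplicated(baits)]
  bait_raw <- lapply(baits, dna_raw)
  raw_fwd <- prep$raw_fwd; raw_rc <- prep$raw_rc
  tr_fwd <- prep$tr_fwd; tr_rc <- prep$tr_rc
  excluded_tix <- which(archive$id %in% exclude)
  ## candidate (trace, strand, bait): modal shared diagonal + seed count
  cands <- list()
  for (bi in seq_along(baits)) {
    bt <- kmer_table(baits[[bi]], prep$seed_k)
    jn <- prep$tr_tab[bt, on = "kmer", nomatch = NULL,
                      allow.cartesian = TRUE]
    if (length(excluded_tix)) jn <- jn[!tix %in% excluded_tix]
    if (!nrow(jn)) next
    ## jn: pos = trace pos, i.pos = bait pos; trace placed at diagonal
    ## offset d in bait coordinates
    g <- jn[, .N, by = .(tix, strand, d = i.pos - pos)]
    g <- g[, .(d = d[which.max(N)], n_d = max(N), seeds = sum(N)),
           by = .(tix, strand)]
    g[, bait := bi]
    cands[[length(cands) + 1L]] <- g
  }
  if (!length(cands)) return(empty)
  cand <- as.data.frame(data.table::rbindlist(cands))
  hits <- list()
  for (idx in split(seq_len(nrow(cand)), cand$tix)) {
    rows <- cand[idx, , drop = FALSE]
    tix <- rows$tix[1L]
    best <- NULL
    for (r in seq_len(nrow(rows))) {
      strand <- rows$strand[r]; bi <- rows$bait[r]
      rs <- if (strand == "+") raw_fwd[[tix]] else raw_rc[[tix]]
      dg <- diagonal_best_segment(bait_raw[[bi]], rs, rows$d[r])
      cand_hit <- NULL
      if (!is.null(dg) && dg$identity > min_similarity &&
          dg$span >= min_span) {
        cand_hit <- list(bait = names(baits)[bi], strand = strand,
                         span = dg$span, identity = dg$identity,
                         score = dg$score)
      } else if (rows$seeds[r] >= min_seeds_fallback) {
        ## gapped fallback under the recruitment scoring scheme
        s <- if (strand == "+") tr_fwd[tix] else tr_rc[tix]
        al <- Biostrings::pairwiseAlignment(
          s, baits[[bi]], type = "local",
          substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(2, -3),
          gapOpening = 5, gapExtension = 2)
        ni <- Biostrings::nindel(al)
        span <- Biostrings::nmatch(al) + Biostrings::nmismatch(al) +
          sum(Biostrings::insertion(ni)[, "WidthSum"]) +
          sum(Biostrings::deletion(ni)[, "WidthSum"])
        idn <- if (span > 0L) Biostrings::nmatch(al) / span else 0
        if (idn > min_similarity && span >= min_span) {
          cand_hit <- list(bait = names(baits)[bi], strand = strand,
                           span = span, identity = idn,
                           score = Biostrings::score(al))
        }
      }
      if (!is.null(cand_hit) &&
          (is.null(best) || cand_hit$score > best$score ||
           (cand_hit$score == best$score && cand_hit$span > best$span))) {
        best <- cand_hit
      }
    }
    if (!is.null(best)) {
      hits[[length(hits) + 1L]] <-
        data.frame(trace_id = archive$id[tix], bait_id = best$bait,
                   strand = best$strand, aligned_length = best$span,
                   identity = best$identity, score = best$score)
    }
  }
  if (!length(hits)) return(empty)
  do.call(rbind, hits)
}

## ---- contig machinery -----------------------------------------------------

BASE_IDX <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)

seq_to_counts <- function(s) {
  n <- nchar(s)
  m <- matrix(0L, 5L, n, dimnames = list(names(BASE_IDX), NULL))
  m[cbind(BASE_IDX[dna_chars(s)], seq_len(n))] <- 1L
  m
}

counts_to_consensus <- function(counts) {
  ## majority over A,C,G,T; ties break in A<C<G<T order (deterministic)
  acgt <- counts[1:4, , drop = FALSE]
  idx <- max.col(t(acgt), ties.method = "first")
  out <- names(BASE_IDX)[idx]
  out[colSums(acgt) == 0L] <- "N"
  paste(out, collapse = "")
}

# reverse-complement a counts matrix (flip columns, swap A/T and C/G rows)
rc_counts <- function(counts) {
  counts[c("T", "G", "C", "A", "N"), rev(seq_len(ncol(counts))), drop = FALSE]
}

new_contig <- function(id, sequence, trace_id = id) {
  structure(list(id = id, consensus = sequence,
                 counts = seq_to_counts(sequence),
                 layout = data.frame(trace_id = trace_id, offset = 0L,
                                     strand = "+",
                                     length = nchar(sequence)),
                 circular = FALSE),
            class = "Contig")
}

#' @export
print.Contig <- function(x, ...) {
  cov <- colSums(x$counts[1:4, , drop = FALSE])
  cat(sprintf("Contig %s: %d nt, %s, %d traces, coverage %.1fx (min %d)\n",
              x$id, nchar(x$consensus),
              if (x$circular) "circular" else "linear",
              nrow(x$layout), mean(cov), min(cov)))
  invisible(x)
}

# merge contig B into contig A; o is the 1-based position in A coordinates
# of B's first base after strand resolution (may be <= 0)
merge_contigs <- function(A, B, o, strand) {
  if (strand == "-") {
    Lb0 <- nchar(B$consensus)
    B$counts <- rc_counts(B$counts)
    B$consensus <- revcomp(B$consensus)
    B$layout$offset <- Lb0 - (B$layout$offset + B$layout$length)
    B$layout$strand <- ifelse(B$layout$strand == "+", "-", "+")
  }
  La <- nchar(A$consensus); Lb <- nchar(B$consensus)
  new_lo <- min(1L, o)
  new_hi <- max(La, o + Lb - 1L)
  shift <- 1L - new_lo
  L <- new_hi - new_lo + 1L
  counts <- matrix(0L, 5L, L, dimnames = list(names(BASE_IDX), NULL))
  counts[, (1L + shift):(La + shift)] <- A$counts
  bcols <- (o + shift):(o + Lb - 1L + shift)
  counts[, bcols] <- counts[, bcols] + B$counts
  la <- A$layout; la$offset <- la$offset + shift
  lb <- B$layout; lb$offset <- lb$offset + o - 1L + shift
  structure(list(id = A$id, consensus = counts_to_consensus(counts),
                 counts = counts, layout = rbind(la, lb), circular = FALSE),
            class = "Contig")
}

## per-contig stacked k-mer table (forward and reverse-complement strands)
contig_kmer_rows <- function(id, consensus, rc_consensus, k) {
  f <- kmer_table(consensus, k)
  f[, `:=`(cid = id, strand = "+")]
  r <- kmer_table(rc_consensus, k)
  r[, `:=`(cid = id, strand = "-")]
  rbind(f, r)
}

## candidate edges of the query contigs against the master table; the query
## side is strided (any true >= min_overlap overlap shares many seeds)
edge_candidates <- function(master, query_tab, stride = 4L) {
  q <- query_tab[query_tab$strand == "+" & (query_tab$pos - 1L) %% stride == 0L, ]
  j <- master[q, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  ## j: pos/cid/strand = subject, i.pos/i.cid = query
  j <- j[cid != i.cid]
  if (!nrow(j)) return(NULL)
  g <- j[, .N, by = .(a = i.cid, b = cid, strand, d = i.pos - pos)]
  g[g[, .I[which.max(N)], by = .(a, b, strand)]$V1]
}

## evaluate candidate rows into accepted edges
evaluate_edges <- function(g, raw_fwd, raw_rc, min_overlap, min_identity,
                          scores) {
  rows <- list()
  for (r in seq_len(nrow(g))) {
    a <- g$a[r]; b <- g$b[r]; strand <- g$strand[r]
    rb <- if (strand == "+") raw_fwd[[b]] else raw_rc[[b]]
    dg <- evaluate_diagonal(raw_fwd[[a]], rb, g$d[r])
    if (is.null(dg)) next
    if (dg$overlap < min_overlap || dg$identity < min_identity) next
    rows[[length(rows) + 1L]] <-
      data.frame(a = a, b = b, strand = strand, offset = dg$offset + 1L,
                 overlap = dg$overlap, identity = dg$identity,
                 score = scores[["match"]] * dg$matches +
                   scores[["mismatch"]] * dg$mismatches)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Assemble traces by greedy overlap-layout-consensus
#'
#' Repeatedly merges the pair of contigs with the highest-scoring overlap
#' satisfying the identity and length thresholds (either strand), with a
#' coverage-weighted majority consensus. Remaining singletons are returned
#' as one-trace contigs. Deterministic given input order: ties break by
#' score, then overlap length, then lexicographically smallest id pair.
#'
#' @param traces A `TraceArchive`, named character vector, or list of
#'   `Contig` objects (allowing re-assembly with existing contigs).
#' @param min_identity Minimum overlap identity (default 0.98).
#' @param min_overlap Minimum overlap length in nt (default 500; lowered
#'   with a warning when it exceeds the shortest usable input).
#' @param scores Overlap scoring scheme, `c(match = 1, mismatch = -2,
#'   gap = -2, first_gap = -3)`; the gap terms apply in gapped evaluations
#'   (recruitment fallback), the overlap score itself is gapless.
#' @param seed_k Seed length for overlap candidate detection (default 16).
#' @return A list of `Contig` objects, longest first.
#' @export
assemble <- function(traces, min_identity = 0.98, min_overlap = 500L,
                     scores = c(match = 1, mismatch = -2, gap = -2,
                                first_gap = -3),
                     seed_k = 16L) {
  if (is.list(traces) && length(traces) &&
      all(vapply(traces, inherits, NA, "Contig"))) {
    contigs <- traces
  } else {
    archive <- trace_archive(traces)
    stopifnot(nrow(archive) >= 1L)
    contigs <- lapply(seq_len(nrow(archive)), function(i) {
      new_contig(archive$id[i], archive$sequence[i])
    })
  }
  names(contigs) <- vapply(contigs, `[[`, "", "id")
  stopifnot(!anyDuplicated(names(contigs)))
  shortest <- min(vapply(contigs, function(ct) nchar(ct$consensus), 0L))
  if (min_overlap > shortest) {
    warning(sprintf("min_overlap %d exceeds shortest input (%d nt); lowering",
                    min_overlap, shortest))
    min_overlap <- shortest
  }
  ## cached raw strands; the master k-mer table over the input contigs is
  ## built and keyed once — contigs created by merging keep their own keyed
  ## tables, and stale master rows are filtered out after each join
  raw_fwd <- lapply(contigs, function(ct) dna_raw(ct$consensus))
  rc_cons <- lapply(contigs, function(ct) revcomp(ct$consensus))
  raw_rc <- lapply(rc_cons, dna_raw)
  tabs <- lapply(names(contigs), function(id) {
    contig_kmer_rows(id, contigs[[id]]$consensus, rc_cons[[id]], seed_k)
  })
  master <- data.table::rbindlist(tabs)
  data.table::setkey(master, kmer)
  merged_tabs <- list()   # id -> keyed k-mer table of merge-created contigs
  edges <- NULL
  if (length(contigs) > 1L) {
    g <- edge_candidates(master, master)
    if (!is.null(g)) {
      ## each unordered pair appears from both sides; keep a < b
      g <- g[g$a < g$b, ]
      edges <- evaluate_edges(g, raw_fwd, raw_rc, min_overlap, min_identity,
                              scores)
    }
  }
  while (!is.null(edges) && nrow(edges)) {
    key <- paste(pmin(edges$a, edges$b), pmax(edges$a, edges$b))
    ord <- order(-edges$score, -edges$overlap, key)
    e <- edges[ord[1L], ]
    merged <- merge_contigs(contigs[[e$a]], contigs[[e$b]],
                            e$offset, e$strand)
    contigs[[e$b]] <- NULL
    contigs[[e$a]] <- merged
    raw_fwd[[e$b]] <- NULL; raw_rc[[e$b]] <- NULL
    raw_fwd[[e$a]] <- dna_raw(merged$consensus)
    rc_merged <- revcomp(merged$consensus)
    raw_rc[[e$a]] <- dna_raw(rc_merged)
    merged_tabs[[e$a]] <- NULL; merged_tabs[[e$b]] <- NULL
    edges <- edges[edges$a != e$a & edges$b != e$a &
                     edges$a != e$b & edges$b != e$b, , drop = FALSE]
    ## edges of the merged contig against every other active contig
    new_tab <- contig_kmer_rows(e$a, merged$consensus, rc_merged, seed_k)
    others <- setdiff(names(contigs), e$a)
    g <- edge_candidates(master, new_tab)
    if (!is.null(g)) g <- g[g$b %in% others, ]
    glist <- if (!is.null(g) && nrow(g)) list(g) else list()
    for (mid in intersect(names(merged_tabs), others)) {
      gm <- edge_candidates(merged_tabs[[mid]], new_tab)
      if (!is.null(gm) && nrow(gm)) glist[[length(glist) + 1L]] <- gm
    }
    merged_tabs[[e$a]] <- data.table::setkey(new_tab, kmer)
    if (length(glist)) {
      new_edges <- evaluate_edges(do.call(rbind, glist), raw_fwd, raw_rc,
                                  min_overlap, min_identity, scores)
      if (!is.null(new_edges)) {
        edges <- if (is.null(edges) || !nrow(edges)) new_edges else
          rbind(edges, new_edges)
      }
    }
    if (is.null(edges) || !nrow(edges)) break
  }
  contigs <- unname(contigs)
  contigs[order(-vapply(contigs, function(ct) nchar(ct$consensus), 0L),
                vapply(contigs, `[[`, "", "id"))]
}

#' Walk a trace archive to extend contigs
#'
#' Each round uses the terminal windows of every linear contig as baits for
#' [recruit_traces()] over the not-yet-used part of the archive, then
#' re-assembles the newly recruited traces with the current contigs. Stops
#' when no contig grows or after `max_rounds`. Total assembled length is
#' non-decreasing across rounds.
#'
#' @param archive A `TraceArchive`.
#' @param contigs A list of `Contig` objects from [assemble()].
#' @param max_rounds Maximum walking rounds (default 50).
#' @param bait_window Terminal window length used as bait (default 1000).
#' @param min_similarity,min_span Recruitment thresholds (see
#'   [recruit_traces()]).
#' @param min_identity,min_overlap,scores,seed_k Assembly parameters (see
#'   [assemble()]).
#' @return A list of `Contig` objects.
#' @export
walk <- function(archive, contigs, max_rounds = 50L, bait_window = 1000L,
                 min_similarity = 0.80, min_span = 100L,
                 min_identity = 0.98, min_overlap = 500L,
                 scores = c(match = 1, mismatch = -2, gap = -2,
                            first_gap = -3),
                 seed_k = 16L) {
  archive <- trace_archive(archive)
  used <- unique(unlist(lapply(contigs, function(ct) ct$layout$trace_id)))
  if (max_rounds < 1L) return(contigs)
  prep <- prepare_archive(archive)
  longest <- function(cs) max(vapply(cs, function(ct) nchar(ct$consensus), 0L))
  for (round in seq_len(max_rounds)) {
    if (all(archive$id %in% used)) break
    baits <- character(0)
    for (ct in contigs) {
      if (ct$circular) next
      L <- nchar(ct$consensus)
      w <- min(bait_window, L)
      baits <- c(baits, substring(ct$consensus, 1L, w),
                 substring(ct$consensus, L - w + 1L, L))
    }
    if (!length(baits)) break
    baits <- unique(baits)
    names(baits) <- paste0("end", seq_along(baits))
    hits <- recruit_core(prep, baits, min_similarity = min_similarity,
                         min_span = min_span, exclude = used)
    if (!nrow(hits)) break
    new_tr <- archive[archive$id %in% hits$trace_id, , drop = FALSE]
    new_contigs <- lapply(seq_len(nrow(new_tr)), function(i) {
      new_contig(new_tr$id[i], new_tr$sequence[i])
    })
    before <- longest(contigs)
    core_traces <- unique(unlist(lapply(contigs, function(ct)
      ct$layout$trace_id)))
    contigs <- assemble(c(contigs, new_contigs),
                        min_identity = min_identity,
                        min_overlap = min_overlap, scores = scores,
                        seed_k = seed_k)
    ## walk extends the existing contigs; recruited traces that did not
    ## merge into any of them are returned to the archive rather than
    ## promoted to new contigs (singletons would otherwise bait unrelated
    ## repeat neighbourhoods)
    contigs <- Filter(function(ct)
      any(ct$layout$trace_id %in% core_traces), contigs)
    used <- unique(unlist(lapply(contigs, function(ct) ct$layout$trace_id)))
    if (longest(contigs) <= before) break
  }
  contigs
}

#' Detect and close a circular contig
#'
#' If the two ends of a linear contig overlap at `min_identity` over at
#' least `min_end_overlap` nt, one copy of the overlap is trimmed (its
#' coverage folded onto the retained copy), the contig is marked circular,
#' and it is rotated to a canonical origin (the lexicographically minimal
#' rotation of the canonical strand), making the result invariant to where
#' the source circle was cut. An ambiguous double closure (tandem end
#' repeat) leaves the contig linear with a warning.
#'
#' @param contig A linear `Contig`.
#' @param min_end_overlap Minimum end-overlap length in nt (default 500).
#' @param min_identity Minimum end-overlap identity (default 0.98).
#' @param seed_k Seed length (default 16).
#' @return The (possibly circularized) `Contig`.
#' @export
detect_circularity <- function(contig, min_end_overlap = 500L,
                               min_identity = 0.98, seed_k = 16L) {
  stopifnot(inherits(contig, "Contig"), !contig$circular)
  s <- contig$consensus
  L <- nchar(s)
  if (L < 2L * min_end_overlap) return(contig)
  W <- min(L %/% 2L, max(4L * min_end_overlap, 5000L))
  kp <- kmer_table(substring(s, 1L, W), seed_k)
  data.table::setkey(kp, kmer)
  ks <- kmer_table(substring(s, L - W + 1L, L), seed_k)
  hits <- kp[ks, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (!nrow(hits)) return(contig)
  data.table::setnames(hits, c("kmer", "pos", "i.pos"), c("kmer", "j", "i"))
  ## suffix position i (suffix coords) matching prefix position j implies an
  ## end overlap of v = W - i + j nucleotides
  vs <- hits[, .N, by = .(v = W - i + j)]
  vs <- vs[vs$v >= min_end_overlap & vs$v < L, ]
  if (!nrow(vs)) return(contig)
  ok_v <- integer(0)
  for (v in sort(vs$v, decreasing = TRUE)) {
    if (seq_identity(substring(s, L - v + 1L, L),
                     substring(s, 1L, v)) >= min_identity) {
      ok_v <- c(ok_v, v)
    }
  }
  if (!length(ok_v)) return(contig)
  if (diff(range(ok_v)) > max(10L, 0.05 * max(ok_v))) {
    warning("ambiguous double closure (tandem end repeat); leaving linear")
    return(contig)
  }
  v <- max(ok_v)
  keepL <- L - v
  counts <- contig$counts[, seq_len(keepL), drop = FALSE]
  counts[, seq_len(v)] <- counts[, seq_len(v)] +
    contig$counts[, (keepL + 1L):L, drop = FALSE]
  cons <- counts_to_consensus(counts)
  layout <- contig$layout
  layout$offset <- layout$offset %% keepL
  ## canonical strand, then canonical rotation
  a <- minimal_rotation(cons)
  b <- minimal_rotation(revcomp(cons))
  if (b < a) {
    counts <- rc_counts(counts)
    cons <- revcomp(cons)
    layout$offset <- (keepL - (layout$offset + layout$length)) %% keepL
    layout$strand <- ifelse(layout$strand == "+", "-", "+")
    target <- b
  } else target <- a
  rot <- regexpr(substring(target, 1L, min(keepL, 200L)),
                 paste0(cons, cons), fixed = TRUE)[[1L]] - 1L
  if (rot > 0L) {
    counts <- counts[, c((rot + 1L):keepL, 1L:rot), drop = FALSE]
    layout$offset <- (layout$offset - rot) %% keepL
  }
  contig$consensus <- counts_to_consensus(counts)
  contig$counts <- counts
  contig$layout <- layout
  contig$circular <- TRUE
  contig
}

#' Evaluate an assembly against a known truth genome
#'
#' Reports rotation- and strand-aware identity to the truth sequence, mean
#' and minimum coverage, and recruitment purity (fraction of traces in the
#' layout whose origin tag is `organelle`).
#'
#' @param contig A `Contig`.
#' @param truth An `AnnotatedGenome` (or DNA string) of known truth.
#' @param archive Optional `TraceArchive` carrying origin tags.
#' @return A list: `identity`, `length`, `truth_length`, `mean_coverage`,
#'   `min_coverage`, `purity`, `circular`.
#' @export
evaluate_assembly <- function(contig, truth, archive = NULL) {
  tr <- if (inherits(truth, "AnnotatedGenome")) truth$sequence else truth
  truth_circ <- if (inherits(truth, "AnnotatedGenome")) truth$circular else TRUE
  idn <- aligned_circular_identity(contig$consensus, tr,
                                   circular = contig$circular && truth_circ)
  cov <- colSums(contig$counts[1:4, , drop = FALSE])
  purity <- NA_real_
  if (!is.null(archive)) {
    archive <- trace_archive(archive)
    org <- archive$origin[match(contig$layout$trace_id, archive$id)]
    purity <- mean(org == "organelle", na.rm = TRUE)
  }
  list(identity = idn, length = nchar(contig$consensus),
       truth_length = nchar(tr),
       mean_coverage = sum(contig$layout$length) / nchar(contig$consensus),
       min_coverage = min(cov), purity = purity,
       circular = contig$circular)
}

# rotation/strand-aware identity of an assembled sequence to a truth
# sequence: the truth is anchored in the (doubled) assembly by exact
# anchors and compared position-wise along the implied rotation
aligned_circular_identity <- function(cons, truth, circular = TRUE,
                                      anchor_k = 50L) {
  Lt <- nchar(truth); Lc <- nchar(cons)
  if (Lt == 0L || Lc == 0L) return(0)
  rt <- dna_raw(truth)
  best <- 0
  for (s in list(cons, revcomp(cons))) {
    rs <- dna_raw(s)
    dbl <- if (circular) paste0(s, s) else s
    for (astart in unique(as.integer(seq(1L, max(1L, Lt - anchor_k),
                                         length.out = 8L)))) {
      anchor <- substring(truth, astart, min(astart + anchor_k - 1L, Lt))
      hit <- regexpr(anchor, dbl, fixed = TRUE)[[1L]]
      if (hit < 0L) next
      off <- hit - astart   # assembly position = truth position + off
      dpos <- seq_len(Lt) + off
      if (circular) {
        dpos <- ((dpos - 1L) %% Lc) + 1L
        idn <- mean(rt == rs[dpos])
      } else {
        keep <- dpos >= 1L & dpos <= Lc
        idn <- sum(rt[keep] == rs[dpos[keep]]) / Lt
      }
      best <- max(best, idn)
      if (best > 0.9999) return(best)
    }
  }
  best
}
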