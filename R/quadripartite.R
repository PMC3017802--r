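## Large inverted repeat detection and IR/LSC/SSC partitioning of circular
## plastid genomes.
##
## Candidate arms are generated by exact 25-mer seed matching between the
## (doubled) forward strand and its reverse complement, grouped by diagonal,
## then extended outwards while the cumulative mismatch fraction stays within
## budget (with a local-density stop so the boundary does not creep into
## unrelated sequence); the boundary always ends on a matching position.

#' Detect the large inverted repeat of a circular genome
#'
#' Finds the maximal-length pair of disjoint, reverse-complementary segments
#' of at least `min_len` nt and partitions the circle into the two arms
#' (IR\eqn{_A}/IR\eqn{_B}) and the large and small single-copy regions
#' (LSC/SSC, named by size).
#'
#' @param genome A circular `AnnotatedGenome` or DNA string (assumed
#'   circular).
#' @param min_len Minimum arm length in nt (default 1000).
#' @param max_mismatch_frac Arm divergence budget as a mismatch fraction
#'   (default 0.01).
#' @param seed_k Exact seed length (default 25).
#' @return A `QuadripartiteMap` (intervals `ir_a`, `ir_b`, `lsc`, `ssc`,
#'   plus `ir_length` and `mismatches`), or `NULL` when no inverted repeat
#'   of at least `min_len` exists.
#' @export
find_inverted_repeat <- function(genome, min_len = 1000L,
                                 max_mismatch_frac = 0.01, seed_k = 25L) {
  s <- if (inherits(genome, "AnnotatedGenome")) genome$sequence else genome
  n <- nchar(s)
  if (n < 2L * min_len) return(NULL)
  D <- paste0(s, s)
  E <- revcomp(D)
  m <- nchar(D)
  Dr <- dna_raw(D); Er <- dna_raw(E)

  kd <- kmer_table(D, seed_k)
  ke <- kmer_table(E, seed_k)
  data.table::setkey(kd, kmer)
  hits <- kd[ke, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (!nrow(hits)) return(NULL)
  data.table::setnames(hits, c("kmer", "pos", "i.pos"), c("kmer", "i", "j"))
  hits[, diag := j - i]
  ## split each diagonal's seeds into runs (the doubled sequence places
  ## both copies of a repeat on the same diagonal, far apart)
  data.table::setorder(hits, diag, i)
  hits[, run := cumsum(c(1L, diff(i) > 200L)), by = diag]
  diags <- hits[, .(seed_lo = min(i), seed_hi = max(i), nseed = .N),
                by = .(diag, run)]

  cands <- list()
  for (r in seq_len(nrow(diags))) {
    d <- diags$diag[r]
    i0 <- diags$seed_lo[r]
    i1 <- min(diags$seed_hi[r] + seed_k - 1L, m, m - d)
    ## valid range of i along this diagonal
    ilo_min <- max(1L, 1L - d)
    ihi_max <- min(m, m - d)
    ## mismatch vector over a horizon around the seed span (cap work at n)
    lo <- max(ilo_min, i0 - n)
    hi <- min(ihi_max, i1 + n)
    idx <- lo:hi
    mis <- Dr[idx] != Er[idx + d]
    ## extend left of the first seed and right of the last seed: the
    ## seed-covered span is well-matching by construction
    ext <- extend_with_budget(mis, i0 - lo + 1L, i1 - lo + 1L,
                              max_mismatch_frac)
    if (is.null(ext)) next
    i_lo <- lo + ext[1L] - 1L
    i_hi <- lo + ext[2L] - 1L
    len <- i_hi - i_lo + 1L
    if (len < min_len || len > n) next
    nmis <- sum(mis[ext[1L]:ext[2L]])
    j_lo <- i_lo + d; j_hi <- i_hi + d
    b_lo <- m - j_hi + 1L; b_hi <- m - j_lo + 1L
    a0 <- ((i_lo - 1L) %% n) + 1L
    b0 <- ((b_lo - 1L) %% n) + 1L
    key <- paste(min(a0, b0), max(a0, b0), len)
    cands[[key]] <- list(a0 = a0, b0 = b0, len = len, nmis = nmis)
  }
  if (!length(cands)) return(NULL)

  cl <- data.frame(a0 = vapply(cands, `[[`, 0, "a0"),
                   b0 = vapply(cands, `[[`, 0, "b0"),
                   len = vapply(cands, `[[`, 0L, "len"),
                   nmis = vapply(cands, `[[`, 0, "nmis"))
  ## canonical unordered arm pair; reject overlapping arms
  keep <- logical(nrow(cl))
  for (r in seq_len(nrow(cl))) {
    keep[r] <- arms_disjoint(cl$a0[r], cl$b0[r], cl$len[r], n)
  }
  cl <- cl[keep, , drop = FALSE]
  if (!nrow(cl)) return(NULL)
  cl <- cl[order(-cl$len, pmin(cl$a0, cl$b0)), , drop = FALSE]
  best <- cl[1L, ]
  build_quadripartite_map(best$a0, best$b0, best$len, best$nmis, n)
}

# greedy two-sided extension of an exact seed along a mismatch vector:
# cumulative mismatch fraction <= frac, stop when 3 of the last 10 positions
# mismatch (far above any plausible arm divergence, reached almost
# immediately in unrelated flanking sequence), and trim back so both
# boundaries sit on matches
extend_with_budget <- function(mis, seed_lo, seed_hi, frac) {
  T_ <- length(mis)
  right_limit <- function(side_mis, base_len) {
    if (!length(side_mis)) return(0L)
    cm <- cumsum(side_mis)
    t <- seq_along(side_mis)
    roll <- cm - c(rep(0L, min(10L, length(cm))),
                   utils::head(cm, -10L))[seq_along(cm)]
    ## scan up to the density stop, then take the farthest extent whose
    ## cumulative mismatch fraction stays within budget
    stop_at <- which(roll >= 3L)[1L]
    lim_max <- if (is.na(stop_at)) length(side_mis) else stop_at
    ok <- which(cm[seq_len(lim_max)] <= frac * (base_len + t[seq_len(lim_max)]))
    lim <- if (length(ok)) max(ok) else 0L
    ## end on a match
    while (lim > 0L && side_mis[lim]) lim <- lim - 1L
    lim
  }
  seed_len <- seed_hi - seed_lo + 1L
  r <- if (seed_hi < T_) {
    right_limit(mis[(seed_hi + 1L):T_], seed_len)
  } else 0L
  l <- if (seed_lo > 1L) {
    right_limit(rev(mis[1:(seed_lo - 1L)]), seed_len)
  } else 0L
  c(seed_lo - l, seed_hi + r)
}

# positions (mod n) of an interval starting at a0 with given length
circ_positions <- function(a0, len, n) (((a0 - 1L) + 0:(len - 1L)) %% n) + 1L

arms_disjoint <- function(a0, b0, len, n) {
  if (2L * len > n) return(FALSE)
  pa <- circ_positions(a0, len, n)
  pb <- circ_positions(b0, len, n)
  !any(pa %in% pb)
}

interval_from_start <- function(a0, len, n) {
  e <- ((a0 - 1L + len - 1L) %% n) + 1L
  feature_parts(a0, e, wraps = e < a0)
}

build_quadripartite_map <- function(a0, b0, len, nmis, n) {
  if (b0 < a0) { tmp <- a0; a0 <- b0; b0 <- tmp }
  ir_a <- interval_from_start(a0, len, n)
  ir_b <- interval_from_start(b0, len, n)
  ## gaps between arm ends and next arm start (circular)
  gap_after <- function(end_pos, next_start) {
    glen <- ((next_start - end_pos - 1L) %% n + n) %% n
    list(start = (end_pos %% n) + 1L, len = glen)
  }
  endA <- ((a0 - 1L + len - 1L) %% n) + 1L
  endB <- ((b0 - 1L + len - 1L) %% n) + 1L
  g1 <- gap_after(endA, b0)   # between arm A and arm B
  g2 <- gap_after(endB, a0)   # between arm B and arm A
  iv <- function(g) if (g$len > 0L) interval_from_start(g$start, g$len, n) else NULL
  if (g1$len >= g2$len) {
    lsc <- iv(g1); ssc <- iv(g2); lsc_len <- g1$len; ssc_len <- g2$len
  } else {
    lsc <- iv(g2); ssc <- iv(g1); lsc_len <- g2$len; ssc_len <- g1$len
  }
  structure(list(ir_a = ir_a, ir_b = ir_b, lsc = lsc, ssc = ssc,
                 ir_length = len, mismatches = nmis,
                 lsc_length = lsc_len, ssc_length = ssc_len,
                 genome_length = n),
            class = "QuadripartiteMap")
}

#' @export
print.QuadripartiteMap <- function(x, ...) {
  cat(sprintf("QuadripartiteMap (%d nt circle)\n", x$genome_length))
  cat(sprintf("  IR arms: %d nt each (%d mismatches), at %d and %d\n",
              x$ir_length, x$mismatches, x$ir_a$start, x$ir_b$start))
  cat(sprintf("  LSC: %d nt, SSC: %d nt\n", x$lsc_length, x$ssc_length))
  invisible(x)
}

# per-position region labels (IRA/IRB/LSC/SSC) for a map
region_masks <- function(map) {
  n <- map$genome_length
  lab <- character(n)
  assign_iv <- function(iv, name) {
    if (is.null(iv)) return()
    lab[circ_positions(iv$start, part_widths(iv, n), n)] <<- name
  }
  assign_iv(map$ir_a, "IRA"); assign_iv(map$ir_b, "IRB")
  assign_iv(map$lsc, "LSC"); assign_iv(map$ssc, "SSC")
  lab
}

#' Per-region architecture statistics for a quadripartite genome
#'
#' Computes, for each of IR\eqn{_A}, IR\eqn{_B}, LSC and SSC: region length,
#' GC content, a coding/intronic/intergenic partition, and the number of
#' gene loci assigned to the region (genes assigned by the majority of their
#' span; boundary-spanning genes are reported).
#'
#' @param genome A circular `AnnotatedGenome`.
#' @param map A `QuadripartiteMap` from [find_inverted_repeat()].
#' @return A data frame with one row per region.
#' @export
partition_quadripartite <- function(genome, map) {
  n <- genome_length(genome)
  stopifnot(n == map$genome_length)
  lab <- region_masks(map)
  ## per-position accounting labels
  coding_m <- coverage_mask(kind_iranges(genome, coding_kinds), n)
  intron_m <- coverage_mask(kind_iranges(genome, intronic_kinds), n)
  gene_m <- coverage_mask(gene_union_iranges(genome), n)
  chars <- dna_chars(genome$sequence)
  genes <- gene_level_features(genome)
  gene_region <- vapply(genes, function(f) {
    pos <- unlist(lapply(seq_len(nrow(f$parts)), function(i) {
      p <- f$parts[i, ]
      circ_positions(p$start, part_widths(p, n), n)
    }))
    tab <- table(lab[pos])
    names(tab)[which.max(tab)]
  }, "")
  regions <- c("IRA", "IRB", "LSC", "SSC")
  out <- lapply(regions, function(rg) {
    sel <- lab == rg
    if (!any(sel)) {
      return(data.frame(region = rg, length = 0L, gc = NA_real_,
                        coding_nt = 0L, intronic_nt = 0L, intergenic_nt = 0L,
                        genes = 0L))
    }
    coding <- sum(sel & coding_m & !intron_m)
    intergenic <- sum(sel & !gene_m)
    intronic <- sum(sel) - coding - intergenic
    data.frame(region = rg, length = sum(sel),
               gc = gc_fraction(paste(chars[sel], collapse = "")),
               coding_nt = coding, intronic_nt = intronic,
               intergenic_nt = intergenic,
               genes = sum(gene_region == rg))
  })
  do.call(rbind, out)
}
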