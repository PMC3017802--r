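## Independent brute-force oracles and small random-genome builders used
## across the suite. These deliberately avoid the package's interval
## arithmetic and seed-and-extend machinery: positions are labelled one by
## one and substring pairs are enumerated exhaustively.

rc <- function(s) revcomp(s)

## per-position classifier implementing the coding/noncoding definitions by
## marking individual nucleotides (wrap-aware via modular arithmetic)
oracle_partition <- function(genome) {
  L <- genome_length(genome)
  mark <- function(parts) {
    m <- logical(L)
    for (i in seq_len(nrow(parts))) {
      if (parts$wraps[i]) {
        pos <- c(parts$start[i]:L, 1:parts$end[i])
      } else {
        pos <- parts$start[i]:parts$end[i]
      }
      m[pos] <- TRUE
    }
    m
  }
  coding_m <- logical(L); intron_m <- logical(L); gene_m <- logical(L)
  for (f in genome$features) {
    if (f$kind %in% c("CDS", "rRNA", "tRNA")) {
      coding_m <- coding_m | mark(f$parts)
      sp <- data.frame(start = min(f$parts$start), end = max(f$parts$end),
                       wraps = any(f$parts$wraps))
      if (sp$wraps) sp <- data.frame(start = f$parts$start[1],
                                     end = f$parts$end[nrow(f$parts)],
                                     wraps = TRUE)
      gene_m <- gene_m | mark(sp)
    }
    if (f$kind == "gene") {
      sp <- if (any(f$parts$wraps)) {
        data.frame(start = f$parts$start[1], end = f$parts$end[nrow(f$parts)],
                   wraps = TRUE)
      } else {
        data.frame(start = min(f$parts$start), end = max(f$parts$end),
                   wraps = FALSE)
      }
      gene_m <- gene_m | mark(sp)
    }
    if (f$kind %in% c("intron", "intronic_ORF")) {
      intron_m <- intron_m | mark(f$parts)
    }
  }
  ## introns sharing a position with a gene region extend the gene region
  for (f in genome$features) {
    if (f$kind %in% c("intron", "intronic_ORF")) {
      m <- mark(f$parts)
      if (any(m & gene_m)) gene_m <- gene_m | m
    }
  }
  coding <- sum(coding_m & !intron_m)
  intergenic <- sum(!gene_m)
  list(coding_nt = coding, noncoding_nt = L - coding,
       intergenic_nt = intergenic,
       intronic_nt = (L - coding) - intergenic)
}

## random annotated genome: non-overlapping genes, some with an intron,
## plus an intergenic intron, on a circular sequence
random_annotated_genome <- function(L = 5000L, n_genes = 5L, seed = 1L) {
  set.seed(seed)
  seqn <- random_dna(L, 0.4)
  slots <- sort(sample(seq(50L, L - 500L, by = 450L), n_genes))
  feats <- list()
  for (gi in seq_along(slots)) {
    st <- slots[gi]
    glen <- sample(c(150L, 240L, 330L), 1L)
    strand <- sample(c("+", "-"), 1L)
    nm <- paste0("g", gi)
    has_intron <- gi %% 2L == 0L
    feats[[length(feats) + 1L]] <-
      feature("gene", nm, strand, feature_parts(st, st + glen - 1L))
    if (has_intron) {
      i_st <- st + 60L; i_en <- i_st + 59L
      feats[[length(feats) + 1L]] <-
        feature("CDS", nm, strand,
                feature_parts(c(st, i_en + 1L), c(i_st - 1L, st + glen - 1L)))
      feats[[length(feats) + 1L]] <-
        feature("intron", paste0(nm, "_i1"), strand,
                feature_parts(i_st, i_en))
    } else {
      feats[[length(feats) + 1L]] <-
        feature("CDS", nm, strand, feature_parts(st, st + glen - 1L))
    }
  }
  ## a free-standing intron between the last gene and the origin
  ig_st <- L - 220L
  feats[[length(feats) + 1L]] <-
    feature("intron", "igi", "+", feature_parts(ig_st, ig_st + 99L))
  annotated_genome(paste0("rand", seed), seqn, circular = TRUE,
                   features = feats)
}

## exhaustive maximal-repeat oracle: every diagonal of the sequence against
## its per-type transform, maximal <= k intervals from mismatch positions
oracle_repeats <- function(seqn, min_len, k, types = c("F", "R", "C", "RC")) {
  n <- nchar(seqn)
  x <- strsplit(seqn, NULL)[[1L]]
  transform <- list(
    F = x,
    R = rev(x),
    C = strsplit(chartr("ACGT", "TGCA", seqn), NULL)[[1L]],
    RC = strsplit(rc(seqn), NULL)[[1L]])
  out <- list()
  for (type in types) {
    y <- transform[[type]]
    for (d in (-(n - min_len)):(n - min_len)) {
      ilo <- max(1L, 1L - d); ihi <- min(n, n - d)
      if (ihi - ilo + 1L < min_len) next
      idx <- ilo:ihi
      mis <- x[idx] != y[idx + d]
      m <- c(0L, which(mis), length(idx) + 1L)
      if (length(m) < k + 2L) {
        ## fewer mismatches than budget: single maximal interval
        starts <- 1L; ends <- length(idx)
        nm <- sum(mis)
      } else {
        ii <- seq_len(length(m) - k - 1L)
        starts <- m[ii] + 1L
        ends <- m[ii + k + 1L] - 1L
        nm <- vapply(ii, function(q) sum(mis[starts[q]:ends[q]]), 0L)
      }
      lens <- ends - starts + 1L
      keep <- lens >= min_len
      for (q in which(keep)) {
        i1 <- idx[1L] + starts[q] - 1L
        i2 <- idx[1L] + ends[q] - 1L
        j1 <- i1 + d
        len <- i2 - i1 + 1L
        ab <- switch(type,
                     F = c(j1, j1 + len - 1L),
                     C = c(j1, j1 + len - 1L),
                     R = c(n - j1 - len + 2L, n - j1 + 1L),
                     RC = c(n - j1 - len + 2L, n - j1 + 1L))
        inst <- rbind(c(i1, i2), ab)
        inst <- inst[order(inst[, 1L], inst[, 2L]), , drop = FALSE]
        if (all(inst[1L, ] == inst[2L, ])) next
        if (type == "F" && d == 0L) next
        key <- paste(type, inst[1L, 1L], inst[1L, 2L],
                     inst[2L, 1L], inst[2L, 2L], sep = ":")
        out[[key]] <- c(len = len, mis = nm[q])
      }
    }
  }
  if (is.null(names(out))) character(0) else sort(names(out))
}

repeat_keys <- function(matches) {
  if (!nrow(matches)) return(character(0))
  sort(paste(matches$type, matches$start_a, matches$end_a,
             matches$start_b, matches$end_b, sep = ":"))
}

## brute-force hairpin existence check over all (start, stem, loop)
oracle_has_hairpin <- function(seqn, min_stem, loop_min, loop_max,
                               max_mismatch = 0L) {
  n <- nchar(seqn)
  x <- strsplit(seqn, NULL)[[1L]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  for (p in seq_len(n)) {          # innermost left-arm base
    for (l in loop_min:loop_max) {
      s <- 0L; mm <- 0L
      while (TRUE) {
        li <- p - s; ri <- p + l + 1L + s
        if (li < 1L || ri > n) break
        if (comp[[x[li]]] != x[ri]) {
          if (s == 0L) break       # innermost pair must pair
          mm <- mm + 1L
          if (mm > max_mismatch) break
        }
        s <- s + 1L
      }
      if (s >= min_stem) return(TRUE)
    }
  }
  FALSE
}
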