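## GenBank flat-file reading and writing.
##
## GenBank coordinates are 1-based inclusive, identical to the package's
## internal convention, so locations pass through unchanged; join/complement/
## order location strings are resolved into ordered part tables, and a join
## whose consecutive parts abut across the origin of a circular record is
## merged into a single wrapping part.

#' Read a GenBank flat file
#'
#' Parses the LOCUS line (length, circular/linear), the FEATURES table
#' (including `join`, `order`, and `complement` locations) and the ORIGIN
#' sequence into an [annotated_genome()]. Unknown feature keys are kept with
#' kind `misc`; a CDS fully contained in an annotated intron is typed
#' `intronic_ORF`; features with a `/pseudo` qualifier (or a psi label) are
#' typed `pseudogene`.
#'
#' @param path Path to a single-record GenBank flat file.
#' @return An `AnnotatedGenome`.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty GenBank file: ", path)

  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) stop("no LOCUS line in ", path)
  locus <- lines[locus_i[1L]]
  circular <- grepl("\\bcircular\\b", locus, ignore.case = TRUE)
  id <- strsplit(trimws(sub("^LOCUS\\s+", "", locus)), "\\s+")[[1L]][1L]
  acc_i <- grep("^ACCESSION\\s+\\S", lines)
  if (length(acc_i)) {
    acc <- strsplit(trimws(sub("^ACCESSION\\s+", "", lines[acc_i[1L]])),
                    "\\s+")[[1L]][1L]
    if (nzchar(acc) && acc != ".") id <- acc
  }

  ## ORIGIN sequence
  orig_i <- grep("^ORIGIN", lines)
  if (!length(orig_i)) stop("no ORIGIN/sequence section in ", path)
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > orig_i[1L]][1L] else length(lines) + 1L
  if (is.na(end_i)) end_i <- length(lines) + 1L
  seq_lines <- lines[(orig_i[1L] + 1L):(end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("missing sequence in ", path)
  L <- nchar(sequence)

  ## FEATURES table
  feats <- list()
  feat_i <- grep("^FEATURES", lines)
  if (length(feat_i)) {
    body <- lines[(feat_i[1L] + 1L):(orig_i[1L] - 1L)]
    body <- body[!grepl("^\\S", body)]          # stop at next top-level keyword
    key_rows <- grep("^ {5}\\S", body)
    for (ki in seq_along(key_rows)) {
      first <- key_rows[ki]
      last <- if (ki < length(key_rows)) key_rows[ki + 1L] - 1L else length(body)
      block <- body[first:last]
      key <- sub("^ {5}(\\S+).*$", "\\1", block[1L])
      if (key == "source") next
      rest <- trimws(sub("^ {5}\\S+\\s*", "", block[1L]))
      cont <- if (length(block) > 1L) trimws(block[-1L]) else character(0)
      ## location may continue over lines until the first qualifier line
      qual_start <- which(startsWith(cont, "/"))
      loc_extra <- if (length(qual_start)) {
        utils::head(cont, qual_start[1L] - 1L)
      } else cont
      loc_str <- paste(c(rest, loc_extra), collapse = "")
      qual_lines <- if (length(qual_start)) {
        cont[qual_start[1L]:length(cont)]
      } else character(0)
      quals <- parse_qualifiers(qual_lines)
      loc <- parse_location(loc_str, L, circular,
                            feature_label = paste0(key, " ",
                                                   quals$gene %||% quals$label %||% ""))
      feats[[length(feats) + 1L]] <- list(key = key, strand = loc$strand,
                                          parts = loc$parts, qualifiers = quals)
    }
  }

  features <- lapply(feats, genbank_feature_to_typed)
  features <- infer_intronic_orfs(features, L)
  annotated_genome(id, sequence, circular = circular, features = features)
}

parse_qualifiers <- function(qlines) {
  if (!length(qlines)) return(list())
  ## re-join continuation lines (lines not starting with /key=)
  joined <- character(0)
  for (l in qlines) {
    if (grepl("^/[A-Za-z_]+(=|$)", l) || !length(joined)) {
      joined <- c(joined, l)
    } else {
      joined[length(joined)] <- paste(joined[length(joined)], l)
    }
  }
  out <- list()
  for (l in joined) {
    m <- regmatches(l, regexec("^/([A-Za-z_]+)(=(.*))?$", l))[[1L]]
    if (length(m) < 2L) next
    key <- m[2L]
    val <- if (length(m) >= 4L && nzchar(m[3L])) gsub('^"|"$', "", m[4L]) else TRUE
    out[[key]] <- val
  }
  out
}

# Parse a GenBank location string into strand + ordered parts.
parse_location <- function(loc, L, circular, feature_label = "") {
  loc <- gsub("[<>\\s]", "", loc)
  strand <- "+"
  # strip (possibly nested once) complement
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc)) {
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  }
  pieces <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  st <- integer(0); en <- integer(0)
  for (p in pieces) {
    p2 <- p
    neg <- FALSE
    if (grepl("^complement\\(", p2)) {  # per-part complement
      neg <- TRUE
      p2 <- sub("^complement\\((.*)\\)$", "\\1", p2)
    }
    if (neg) strand <- "-"
    if (grepl("\\.\\.", p2)) {
      ab <- as.integer(strsplit(p2, "..", fixed = TRUE)[[1L]])
    } else {
      ab <- rep(as.integer(p2), 2L)
    }
    if (any(is.na(ab)) || ab[1L] < 1L || ab[2L] < 1L ||
        ab[1L] > L || ab[2L] > L) {
      stop(sprintf("location of feature %s references coordinates beyond the %d-nt sequence: '%s'",
                   feature_label, L, p), call. = FALSE)
    }
    st <- c(st, ab[1L]); en <- c(en, ab[2L])
  }
  parts <- feature_parts(st, en, wraps = FALSE)
  ## merge consecutive parts abutting across the origin into one wrapping part
  if (circular && nrow(parts) >= 2L) {
    i <- 1L
    while (i < nrow(parts)) {
      if (parts$end[i] == L && parts$start[i + 1L] == 1L) {
        parts$end[i] <- parts$end[i + 1L]
        parts$wraps[i] <- TRUE
        parts <- parts[-(i + 1L), , drop = FALSE]
      } else i <- i + 1L
    }
    rownames(parts) <- NULL
  }
  list(strand = strand, parts = parts)
}

# map a raw GenBank feature to a typed Feature
genbank_feature_to_typed <- function(x) {
  q <- x$qualifiers
  name <- q$gene %||% q$label %||% q$product %||% q$note %||% x$key
  kind <- switch(x$key,
                 gene = "gene", CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                 intron = "intron", repeat_region = "repeat_region",
                 misc_feature = "misc", "misc")
  if (!is.null(q$pseudo) || grepl("psi|ψ", name, ignore.case = FALSE)) {
    if (kind %in% c("gene", "CDS", "tRNA", "rRNA")) kind <- "pseudogene"
  }
  feature(kind, name, strand = x$strand, parts = x$parts, qualifiers = q)
}

# A CDS fully contained in an intron feature is an intronic ORF (the
# accounting groups it with noncoding DNA). Containment is tested on the
# linear IRanges projection, so wrapping features work too.
infer_intronic_orfs <- function(features, L) {
  intr <- Filter(function(f) f$kind == "intron", features)
  if (!length(intr)) return(features)
  intron_ir <- IRanges::reduce(do.call(c, lapply(intr, function(f)
    parts_to_iranges(f$parts, L))))
  lapply(features, function(f) {
    if (f$kind != "CDS") return(f)
    fir <- parts_to_iranges(f$parts, L)
    ov <- IRanges::width(IRanges::intersect(fir, intron_ir))
    if (sum(ov) == sum(IRanges::width(fir))) f$kind <- "intronic_ORF"
    f
  })
}

#' Write a GenBank flat file
#'
#' Emits the genome and its typed features back as a minimal GenBank record.
#' Round-trips through [read_genbank()] preserve feature count, kinds,
#' strands and part coordinates exactly.
#'
#' @param genome An `AnnotatedGenome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  L <- genome_length(genome)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   UNA %s",
                     genome$id, L,
                     if (genome$circular) "circular" else "linear",
                     format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(sprintf("DEFINITION  %s.", genome$id), con)
  writeLines(sprintf("ACCESSION   %s", genome$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  kind_to_key <- c(gene = "gene", CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                   intron = "intron", intronic_ORF = "CDS",
                   pseudogene = "gene", repeat_region = "repeat_region",
                   misc = "misc_feature")
  for (f in genome$features) {
    key <- kind_to_key[[f$kind]]
    loc <- format_location(f, L)
    writeLines(sprintf("     %-15s %s", key, loc), con)
    writeLines(sprintf('                     /gene="%s"', f$name), con)
    if (f$kind == "pseudogene" || is_pseudo(f)) {
      writeLines("                     /pseudo", con)
    }
    for (qn in setdiff(names(f$qualifiers), c("gene", "pseudo"))) {
      qv <- f$qualifiers[[qn]]
      if (isTRUE(qv)) {
        writeLines(sprintf("                     /%s", qn), con)
      } else {
        writeLines(sprintf('                     /%s="%s"', qn, qv), con)
      }
    }
  }
  writeLines("ORIGIN", con)
  s <- genome$sequence
  starts <- seq(1L, L, by = 60L)
  for (st in starts) {
    chunk <- substring(s, st, min(st + 59L, L))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", st, tolower(paste(tens, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

format_location <- function(f, L) {
  p <- f$parts
  spans <- character(0)
  for (i in seq_len(nrow(p))) {
    if (p$wraps[i]) {
      spans <- c(spans, sprintf("%d..%d", p$start[i], L),
                 sprintf("1..%d", p$end[i]))
    } else if (p$start[i] == p$end[i]) {
      spans <- c(spans, sprintf("%d", p$start[i]))
    } else {
      spans <- c(spans, sprintf("%d..%d", p$start[i], p$end[i]))
    }
  }
  loc <- if (length(spans) > 1L) {
    sprintf("join(%s)", paste(spans, collapse = ","))
  } else spans
  if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
  loc
}
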