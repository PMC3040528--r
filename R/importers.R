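# Loaders: classic SAMtools pileup (variants + per-base coverage), BED and
# GFF features, key-value consequence annotations, and a plugin registry so
# new annotation formats can be added without touching the package. All
# loaders persist through the generic store interface.

#' Parse one classic pileup line
#'
#' Classic 6-column single-sample pileup (chrom, 1-based position, reference
#' base, depth, read bases, base qualities). Multi-sample and mpileup
#' extensions are rejected. The read-bases string is captured raw; no
#' interpretation happens here — see [count_alleles()].
#'
#' @param line A single line of text (CR/LF stripped).
#' @param line_number Optional line number used in error messages.
#' @return An object of class `qe_pileup_record`.
#' @export
parse_pileup_line <- function(line, line_number = NA_integer_) {
  line <- sub("\r$", "", line)
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) != 6L) {
    stop("pileup line ", line_number, ": expected 6 tab-separated columns ",
         "(classic single-sample pileup), got ", length(f), call. = FALSE)
  }
  pos <- suppressWarnings(as.numeric(f[2]))
  depth <- suppressWarnings(as.integer(f[4]))
  if (is.na(pos) || pos < 1 || pos != floor(pos)) {
    stop("pileup line ", line_number, ": position is not a positive integer",
         call. = FALSE)
  }
  if (is.na(depth) || depth < 0) {
    stop("pileup line ", line_number, ": depth is not a non-negative integer",
         call. = FALSE)
  }
  structure(list(contig = f[1], position = pos, ref_base = f[3],
                 depth = depth, read_bases = f[5], base_qualities = f[6]),
            class = "qe_pileup_record")
}

#' Tokenize a pileup read-bases string into allele counts
#'
#' Applies the standard pileup grammar: `.`/`,` are reference calls,
#' `ACGTN`/`acgtn` alternate calls, `^X` consumes the following
#' mapping-quality character, `$` marks a read end, `+n<seq>`/`-n<seq>`
#' attach an insertion/deletion to the preceding call, and `*` is a
#' deletion placeholder (a call token, but tracked separately and never a
#' variant itself). Token conservation — call tokens consumed equals the
#' depth column — is enforced and is the line-level integrity check.
#'
#' @param rec A [parse_pileup_line()] record.
#' @return An object of class `qe_allele_counts`: `ref_count`, named
#'   `snv_counts` (upper-cased alt base), `insertion_counts` and
#'   `deletion_counts` (sequences as written), `deletion_placeholders`.
#' @export
count_alleles <- function(rec) {
  res <- pileup_tokenize_cpp(rec$read_bases, rec$ref_base)[[1]]
  if (isTRUE(res$malformed)) {
    stop("malformed read-bases string at ", rec$contig, ":", rec$position,
         ": '", rec$read_bases, "'", call. = FALSE)
  }
  if (res$tokens != rec$depth) {
    stop("token conservation violated at ", rec$contig, ":", rec$position,
         ": ", res$tokens, " call tokens for depth ", rec$depth, call. = FALSE)
  }
  structure(list(ref_count = res$ref_count,
                 snv_counts = res$snv_counts,
                 insertion_counts = res$insertion_counts,
                 deletion_counts = res$deletion_counts,
                 deletion_placeholders = res$deletion_placeholders),
            class = "qe_allele_counts")
}

#' Call variants from the allele counts of one pileup line
#'
#' One variant per alternate allele whose observation count meets
#' `min_observations` ("observed once or more" loading corresponds to the
#' default threshold of 1). The 1-based pileup position becomes the internal
#' 0-based locus. Versions are assigned deterministically per locus: SNVs by
#' alternate base, then insertions, then deletions, each lexicographic.
#' Deletions are anchored at the pileup base that carries the `-n<seq>`
#' token; their `stop` extends over the deleted bases.
#'
#' @param rec A [parse_pileup_line()] record.
#' @param counts The matching [count_alleles()] result.
#' @param min_observations Minimum supporting reads (default 1).
#' @param genome_label Genome the calls belong to.
#' @return A list of `qe_variant` with versions `1..k` in calling order.
#' @export
call_variants <- function(rec, counts, min_observations = 1L, genome_label) {
  pos0 <- rec$position - 1
  refb <- toupper(rec$ref_base)
  out <- list()
  sc <- counts$snv_counts
  for (b in sort(names(sc))) {
    if (sc[[b]] >= min_observations) {
      out[[length(out) + 1L]] <- variant(
        contig = rec$contig, position = pos0, stop = pos0 + 1, type = "SNV",
        ref_allele = refb, alt_allele = b, observation_count = sc[[b]],
        depth = rec$depth, genome_label = genome_label,
        version = length(out) + 1L)
    }
  }
  ic <- counts$insertion_counts
  for (s in sort(names(ic))) {
    if (ic[[s]] >= min_observations) {
      out[[length(out) + 1L]] <- variant(
        contig = rec$contig, position = pos0, stop = pos0 + 1,
        type = "INSERTION", ref_allele = "", alt_allele = toupper(s),
        observation_count = ic[[s]], depth = rec$depth,
        genome_label = genome_label, version = length(out) + 1L)
    }
  }
  dc <- counts$deletion_counts
  for (s in sort(names(dc))) {
    if (dc[[s]] >= min_observations) {
      out[[length(out) + 1L]] <- variant(
        contig = rec$contig, position = pos0, stop = pos0 + 1 + nchar(s),
        type = "DELETION", ref_allele = toupper(s), alt_allele = "",
        observation_count = dc[[s]], depth = rec$depth,
        genome_label = genome_label, version = length(out) + 1L)
    }
  }
  out
}

read_input_lines <- function(input) {
  if (is.character(input) && length(input) == 1L && file.exists(input)) {
    readLines(input)     # file() decompresses gzip transparently
  } else if (inherits(input, "connection")) {
    readLines(input)
  } else if (is.character(input)) {
    input
  } else {
    stop("input must be a file path, connection, or character vector of lines",
         call. = FALSE)
  }
}

#' Load a pileup stream: variants and per-base coverage
#'
#' Streams a classic pileup sorted by (contig, position): every alternate
#' allele observed at least `min_observations` times becomes a stored,
#' tag-indexed variant, and every base with depth >= 1 is recorded in a
#' coverage block of the store's block width. Unsorted input and grammar
#' violations abort with the offending line identified.
#'
#' @param store A `qe_store`.
#' @param input File path (optionally gzipped), connection, or character
#'   vector of pileup lines.
#' @param genome_label Genome label to load under.
#' @param min_observations Minimum supporting reads for a call (default 1).
#' @return A load report: `list(variants_written, blocks_written, lines_read)`.
#' @export
load_pileup <- function(store, input, genome_label, min_observations = 1L) {
  check_label(genome_label)
  lines <- read_input_lines(input)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  report <- list(variants_written = 0L, blocks_written = 0L, lines_read = n)
  register_genome(store, genome_label)
  if (n == 0L) return(report)

  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf != 6L)) {
    bad <- which(nf != 6L)[1]
    stop("pileup line ", bad, ": expected 6 tab-separated columns (classic ",
         "single-sample pileup), got ", nf[bad], call. = FALSE)
  }
  m <- matrix(unlist(f, use.names = FALSE), nrow = 6L)
  contig <- m[1, ]; pos <- suppressWarnings(as.numeric(m[2, ]))
  refb <- m[3, ]; depth <- suppressWarnings(as.integer(m[4, ]))
  bases <- m[5, ]
  if (anyNA(pos) || any(pos < 1)) {
    stop("pileup line ", which(is.na(pos) | pos < 1)[1],
         ": position is not a positive integer", call. = FALSE)
  }
  if (anyNA(depth) || any(depth < 0)) {
    stop("pileup line ", which(is.na(depth) | depth < 0)[1],
         ": depth is not a non-negative integer", call. = FALSE)
  }

  # sort-order check: contigs must be grouped, positions strictly increasing
  newc <- c(TRUE, contig[-1] != contig[-n])
  if (anyDuplicated(contig[newc])) {
    stop("unsorted pileup: contig '", contig[newc][anyDuplicated(contig[newc])],
         "' appears in more than one run of lines", call. = FALSE)
  }
  bad_order <- which(!newc & c(FALSE, diff(pos) <= 0))
  if (length(bad_order)) {
    stop("unsorted pileup at line ", bad_order[1], " (", contig[bad_order[1]],
         ":", format_pos(pos[bad_order[1]]), ")", call. = FALSE)
  }

  toks <- pileup_tokenize_cpp(bases, refb)
  tokens <- vapply(toks, `[[`, 0L, "tokens")
  malformed <- vapply(toks, function(x) isTRUE(x$malformed), FALSE)
  if (any(malformed)) {
    bad <- which(malformed)[1]
    stop("pileup line ", bad, ": malformed read-bases string '", bases[bad],
         "'", call. = FALSE)
  }
  if (any(tokens != depth)) {
    bad <- which(tokens != depth)[1]
    stop("pileup line ", bad, ": token conservation violated (", tokens[bad],
         " call tokens for depth ", depth[bad], ")", call. = FALSE)
  }

  # variant calls (alt-bearing lines are sparse; per-line handling is fine)
  has_alt <- vapply(toks, function(x) {
    length(x$snv_counts) > 0L || length(x$insertion_counts) > 0L ||
      length(x$deletion_counts) > 0L
  }, FALSE)
  for (i in which(has_alt)) {
    rec <- structure(list(contig = contig[i], position = pos[i],
                          ref_base = refb[i], depth = depth[i],
                          read_bases = bases[i], base_qualities = m[6, i]),
                     class = "qe_pileup_record")
    cts <- structure(list(ref_count = toks[[i]]$ref_count,
                          snv_counts = toks[[i]]$snv_counts,
                          insertion_counts = toks[[i]]$insertion_counts,
                          deletion_counts = toks[[i]]$deletion_counts,
                          deletion_placeholders = toks[[i]]$deletion_placeholders),
                     class = "qe_allele_counts")
    for (v in call_variants(rec, cts, min_observations, genome_label)) {
      write_variant(store, v, auto_version = TRUE)
      report$variants_written <- report$variants_written + 1L
    }
  }

  # coverage blocks (sorted input lets each (contig, block) be built once)
  bs <- store$block_size
  pos0 <- pos - 1
  covered <- depth >= 1L
  block_start <- (pos0 %/% bs) * bs
  grp <- paste0(contig, "\r", format_pos(block_start))
  for (g in split(which(covered), grp[covered])) {
    i1 <- g[1]
    cb <- coverage_block(contig = contig[i1], block_start = block_start[i1],
                         block_size = bs, offsets = pos0[g] - block_start[i1],
                         depths = depth[g], genome_label = genome_label)
    write_coverage_block(store, cb)
    report$blocks_written <- report$blocks_written + 1L
  }
  report
}

#' Load BED intervals as features
#'
#' BED3+ lines become features; BED's 0-based half-open coordinates are the
#' internal convention and are kept as-is. Column 4 (name), 5 (score) and
#' 6 (strand) are captured when present, and the name is also recorded as a
#' `name` tag so features are reachable through the tag index. `track`,
#' `browser` and `#` header lines are skipped.
#'
#' @inheritParams load_pileup
#' @return Number of features written, invisibly.
#' @export
load_bed_features <- function(store, input, genome_label) {
  check_label(genome_label)
  register_genome(store, genome_label)
  lines <- sub("\r$", "", read_input_lines(input))
  lines <- lines[nzchar(lines)]
  skip <- grepl("^(track|browser|#)", lines)
  lines <- lines[!skip]
  count <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop("BED line ", i, ": fewer than 3 columns", call. = FALSE)
    }
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end) || start < 0 || end <= start) {
      stop("BED line ", i, ": malformed coordinates '", f[2], "-", f[3], "'",
           call. = FALSE)
    }
    name <- if (length(f) >= 4L) f[4] else ""
    score <- if (length(f) >= 5L) suppressWarnings(as.numeric(f[5])) else NA_real_
    strand <- if (length(f) >= 6L && f[6] %in% c("+", "-")) f[6] else "."
    tags <- if (nzchar(name)) c(name = name) else character(0)
    write_feature(store, feature(contig = f[1], position = start, stop = end,
                                 name = name, score = score, strand = strand,
                                 tags = tags, genome_label = genome_label))
    count <- count + 1L
  }
  invisible(count)
}

#' Load GFF records as features
#'
#' GFF's 9 tab-separated columns with 1-based inclusive coordinates are
#' converted to the internal 0-based half-open convention
#' (`start-1, end`). The attributes column (`key=value` pairs separated by
#' `;`) is parsed into tags. Comment lines are skipped.
#'
#' @inheritParams load_pileup
#' @return Number of features written, invisibly.
#' @export
load_gff_features <- function(store, input, genome_label) {
  check_label(genome_label)
  register_genome(store, genome_label)
  lines <- sub("\r$", "", read_input_lines(input))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  count <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L) {
      stop("GFF line ", i, ": expected 9 tab-separated columns, got ",
           length(f), call. = FALSE)
    }
    start <- suppressWarnings(as.numeric(f[4]))
    end <- suppressWarnings(as.numeric(f[5]))
    if (is.na(start) || is.na(end) || start < 1 || end < start) {
      stop("GFF line ", i, ": malformed coordinates", call. = FALSE)
    }
    tags <- parse_gff_attributes(f[9])
    score <- if (f[6] == ".") NA_real_ else suppressWarnings(as.numeric(f[6]))
    strand <- if (f[7] %in% c("+", "-")) f[7] else "."
    name <- if ("ID" %in% names(tags)) tags[["ID"]] else f[3]
    write_feature(store, feature(contig = f[1], position = start - 1,
                                 stop = end, name = name, score = score,
                                 strand = strand, tags = tags,
                                 genome_label = genome_label))
    count <- count + 1L
  }
  invisible(count)
}

parse_gff_attributes <- function(s) {
  if (is.na(s) || !nzchar(s) || s == ".") return(character(0))
  parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  eq <- regexpr("=", parts, fixed = TRUE)
  keys <- ifelse(eq > 0, substr(parts, 1L, eq - 1L), parts)
  vals <- ifelse(eq > 0, substr(parts, eq + 1L, nchar(parts)), "")
  structure(vals, names = trimws(keys))
}

#' Load key-value consequence annotations
#'
#' A simple tab-separated key-value format linking coding consequences to
#' already-loaded variants: columns `contig`, `position` (1-based),
#' `variant_version`, `effect`, `gene` (`.` for none), and an optional
#' `key=value;key=value` tag column. Consequence *prediction* is out of
#' scope; this loads annotations produced elsewhere.
#'
#' @inheritParams load_pileup
#' @param check_ref Require each back-reference to resolve to a stored
#'   variant.
#' @return Number of consequences written, invisibly.
#' @export
load_consequences_kv <- function(store, input, genome_label, check_ref = TRUE) {
  check_label(genome_label)
  register_genome(store, genome_label)
  lines <- sub("\r$", "", read_input_lines(input))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  count <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4L) {
      stop("consequence line ", i, ": expected at least 4 columns", call. = FALSE)
    }
    pos <- suppressWarnings(as.numeric(f[2]))
    if (is.na(pos) || pos < 1) {
      stop("consequence line ", i, ": malformed position", call. = FALSE)
    }
    tags <- if (length(f) >= 6L) parse_gff_attributes(f[6]) else character(0)
    cq <- consequence(contig = f[1], position = pos - 1, effect = f[4],
                      gene = if (length(f) >= 5L && f[5] != ".") f[5] else NA_character_,
                      variant_version = as.integer(f[3]), tags = tags,
                      genome_label = genome_label)
    write_consequence(store, cq, check_ref = check_ref)
    count <- count + 1L
  }
  invisible(count)
}

# ---- plugin registry -------------------------------------------------------

the_loaders <- new.env(parent = emptyenv())

#' Register a loader plugin
#'
#' A loader is a function `function(store, input, genome_label, ...)` that
#' persists records through the generic store interface. Built-in formats
#' (`pileup`, `bed`, `gff`, `consequence-kv`) are pre-registered.
#'
#' @param format_name Name the loader is dispatched under.
#' @param loader The loader function.
#' @param overwrite Allow replacing an existing registration (default FALSE;
#'   a duplicate registration without it is an error).
#' @return Invisibly, the format name.
#' @export
register_loader <- function(format_name, loader, overwrite = FALSE) {
  if (!is.function(loader)) stop("loader must be a function", call. = FALSE)
  if (!overwrite && exists(format_name, envir = the_loaders, inherits = FALSE)) {
    stop("a loader for format '", format_name, "' is already registered",
         call. = FALSE)
  }
  assign(format_name, loader, envir = the_loaders)
  invisible(format_name)
}

#' Registered loader formats
#' @return Sorted character vector of format names.
#' @export
loader_formats <- function() sort(ls(the_loaders))

#' Dispatch a load to a registered plugin
#'
#' @inheritParams load_pileup
#' @param format_name Registered format name.
#' @param ... Passed through to the loader.
#' @return Whatever the loader returns.
#' @export
load_with_plugin <- function(format_name, store, input, genome_label, ...) {
  loader <- the_loaders[[format_name]]
  if (is.null(loader)) {
    stop("no loader registered for format '", format_name, "'; known formats: ",
         paste(loader_formats(), collapse = ", "), call. = FALSE)
  }
  loader(store, input, genome_label, ...)
}

register_builtin_loaders <- function() {
  for (fmt in c("pileup", "bed", "gff", "consequence-kv")) {
    if (!exists(fmt, envir = the_loaders, inherits = FALSE)) {
      loader <- switch(fmt, pileup = load_pileup, bed = load_bed_features,
                       gff = load_gff_features,
                       `consequence-kv` = load_consequences_kv)
      assign(fmt, loader, envir = the_loaders)
    }
  }
}

.onLoad <- function(libname, pkgname) {
  register_builtin_loaders()
}
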