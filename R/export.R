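# Track serialisation: BED for variants, WIG (per-base fixedStep or
# block-averaged) for coverage, and the non-redundant tag listing.

#' Serialise variants as BED
#'
#' One BED4 line per variant: chrom, chromStart (0-based), chromEnd
#' (exclusive) and a name field that encodes the variant's metadata as
#' `type|ref>alt|obs:<n>|depth:<n>|v:<version>` (a `-` stands for an empty
#' allele). The name encoding is this package's own, stable convention.
#' Output is deterministic byte-for-byte for a fixed input.
#'
#' @param variants A list of `qe_variant` in genomic order (as returned by
#'   [query_variants()]).
#' @param con A connection or file path; omit for a character vector return.
#' @return Invisibly, the number of lines written (or the lines themselves
#'   when `con` is `NULL`).
#' @export
export_bed <- function(variants, con = NULL) {
  lines <- vapply(variants, function(v) {
    sprintf("%s\t%s\t%s\t%s", v$contig, format_pos(v$position),
            format_pos(v$stop), bed_name(v))
  }, "")
  emit_lines(lines, con)
}

bed_name <- function(v) {
  sprintf("%s|%s>%s|obs:%d|depth:%d|v:%d", v$type,
          if (nzchar(v$ref_allele)) v$ref_allele else "-",
          if (nzchar(v$alt_allele)) v$alt_allele else "-",
          v$observation_count, v$depth, v$version)
}

emit_lines <- function(lines, con) {
  if (is.null(con)) return(invisible(lines))
  if (is.character(con)) {
    writeLines(lines, con)
  } else {
    writeLines(lines, con)
  }
  invisible(length(lines))
}

#' Serialise per-base coverage as WIG
#'
#' `mode = "per_base"` emits contiguous covered runs as `fixedStep` sections
#' with `step=1`; WIG is 1-based, so section starts are internal positions
#' plus one. `mode = "block_average"` emits one value per coverage block:
#' the arithmetic mean of the depths over the *covered* bases of the block
#' (uncovered bases are unstored and do not enter the mean — dividing by the
#' block width instead would change every value), as `fixedStep` with
#' `step=span=block_size`.
#'
#' @param coverage Data frame from [query_coverage()] (`contig`, `position`,
#'   `depth`), ascending in position.
#' @param con Connection, path, or `NULL` to return the lines.
#' @param mode `"per_base"` or `"block_average"`.
#' @param block_size Block width; required for `block_average`.
#' @return Invisibly, lines written (or the lines when `con` is `NULL`).
#' @export
export_wig <- function(coverage, con = NULL,
                       mode = c("per_base", "block_average"),
                       block_size = NULL) {
  mode <- match.arg(mode)
  if (nrow(coverage) == 0L) return(emit_lines(character(0), con))
  if (length(unique(coverage$contig)) > 1L) {
    o <- order(match(coverage$contig, unique(coverage$contig)), coverage$position)
    if (!identical(o, seq_len(nrow(coverage)))) {
      stop("coverage input must be sorted by (contig, position)", call. = FALSE)
    }
  } else if (is.unsorted(coverage$position, strictly = TRUE)) {
    stop("coverage input must be sorted by ascending position", call. = FALSE)
  }
  lines <- character(0)
  if (mode == "per_base") {
    for (ct in unique(coverage$contig)) {
      sub <- coverage[coverage$contig == ct, , drop = FALSE]
      run <- cumsum(c(TRUE, diff(sub$position) != 1))
      for (r in split(seq_len(nrow(sub)), run)) {
        lines <- c(lines,
                   sprintf("fixedStep chrom=%s start=%s step=1", ct,
                           format_pos(sub$position[r[1]] + 1)),
                   as.character(sub$depth[r]))
      }
    }
  } else {
    if (is.null(block_size)) {
      stop("block_average mode requires block_size", call. = FALSE)
    }
    for (ct in unique(coverage$contig)) {
      sub <- coverage[coverage$contig == ct, , drop = FALSE]
      blk <- (sub$position %/% block_size) * block_size
      means <- vapply(split(sub$depth, blk), mean, 0)
      starts <- as.numeric(names(means))
      o <- order(starts)
      starts <- starts[o]; means <- means[o]
      run <- cumsum(c(TRUE, diff(starts) != block_size))
      for (r in split(seq_along(starts), run)) {
        lines <- c(lines,
                   sprintf("fixedStep chrom=%s start=%s step=%d span=%d", ct,
                           format_pos(starts[r[1]] + 1), block_size,
                           block_size),
                   sprintf("%.6g", means[r]))
      }
    }
  }
  emit_lines(lines, con)
}

#' Non-redundant tags of a variant result set
#'
#' The set union of all tag key/value pairs across the result, sorted
#' lexicographically by key then value.
#'
#' @param variants A list of `qe_variant`.
#' @return A data frame with columns `tag` and `value` (value may be `""`).
#' @export
nonredundant_tags <- function(variants) {
  keys <- character(0); vals <- character(0)
  for (v in variants) {
    if (length(v$tags)) {
      keys <- c(keys, names(v$tags)); vals <- c(vals, unname(v$tags))
    }
  }
  if (length(keys) == 0L) {
    return(data.frame(tag = character(0), value = character(0)))
  }
  pair <- paste0(keys, "\x01", vals)
  keep <- !duplicated(pair)
  keys <- keys[keep]; vals <- vals[keep]
  o <- order(keys, vals, method = "radix")
  data.frame(tag = keys[o], value = vals[o])
}

# body form used by the CLI/web service: "tag=value", bare tags plain
format_tags_body <- function(tags_df) {
  ifelse(nzchar(tags_df$value), paste0(tags_df$tag, "=", tags_df$value),
         tags_df$tag)
}

#' Full-table BED export of a genome's variants
#'
#' Streams every stored variant of one genome (optionally restricted to a
#' region) straight from a primary-table scan to BED lines, decoding
#' records column-wise in bulk. Produces exactly the same bytes as
#' [export_bed()] over [query_variants()] with an empty filter, and is the
#' path to use for whole-genome exports at millions of variants, where
#' per-object construction would dominate.
#'
#' @param store A `qe_store`.
#' @param genome_label Genome to export.
#' @param con Connection, path, or `NULL` to return the lines.
#' @param region Optional region string.
#' @return Invisibly, lines written (or the lines when `con` is `NULL`).
#' @export
export_genome_bed <- function(store, genome_label, con = NULL,
                              region = NULL) {
  assert_open(store)
  assert_genome(store, genome_label)
  reg <- parse_region(region)
  keys <- if (is.null(reg)) {
    scan_group_keys(store, "primary", NULL, NULL, family = "variant")$keys
  } else {
    rk <- region_keys(store, reg)
    if (is.null(rk)) character(0) else
      scan_group_keys(store, "primary", rk$start, rk$end,
                      family = "variant")$keys
  }
  if (length(keys) == 0L) return(emit_lines(character(0), con))
  te <- table_env(store, "primary")
  slots <- mget(keys, envir = te$cells)
  values <- character(0)
  # common case: one cell per slot; fall back to flattening otherwise
  nper <- lengths(slots)
  if (all(nper == 1L)) {
    cl <- lapply(slots, `[[`, 1L)
    labs <- vapply(cl, `[[`, "", "label")
    values <- vapply(cl, `[[`, "", "value")[labs == genome_label]
  } else {
    values <- unlist(lapply(slots, function(cells) {
      out <- character(0)
      for (cell in cells) {
        if (cell$label == genome_label) out <- c(out, cell$value)
      }
      out
    }), use.names = FALSE)
  }
  if (length(values) == 0L) return(emit_lines(character(0), con))
  d <- decode_variant_cols(values)
  ref <- ifelse(nzchar(d$ref_allele), d$ref_allele, "-")
  alt <- ifelse(nzchar(d$alt_allele), d$alt_allele, "-")
  lines <- sprintf("%s\t%s\t%s\t%s|%s>%s|obs:%d|depth:%d|v:%d",
                   d$contig, format_pos(d$position), format_pos(d$stop),
                   d$type, ref, alt, d$observation_count, d$depth, d$version)
  emit_lines(lines, con)
}
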