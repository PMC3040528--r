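# Query layer: region/field/tag queries over variants, consequence reports
# joined to their variants, and per-base coverage reconstruction.

#' Build a variant filter
#'
#' Clauses combine by conjunction (AND); an empty filter passes everything.
#' When `tag` is set, query execution routes through the secondary tag
#' index instead of a primary-table scan; `tag_value` additionally requires
#' the tag to carry that value (checked client-side after index lookup).
#' A `max_p_value` clause rejects variants with no stored p-value.
#'
#' @param min_observations,min_depth Integer lower bounds, or `NULL`.
#' @param max_p_value Upper bound on the call p-value, or `NULL`.
#' @param variant_types Subset of
#'   `r paste(VARIANT_TYPES, collapse = ", ")`, or `NULL`.
#' @param tag,tag_value Tag key (and optionally value) the variant must
#'   carry, or `NULL`.
#' @return A `qe_variant_filter`.
#' @export
variant_filter <- function(min_observations = NULL, min_depth = NULL,
                           max_p_value = NULL, variant_types = NULL,
                           tag = NULL, tag_value = NULL) {
  num_ok <- function(x) is.null(x) || (is.numeric(x) && length(x) == 1L && is.finite(x))
  if (!num_ok(min_observations) || !num_ok(min_depth) || !num_ok(max_p_value)) {
    stop("filter bounds must be single finite numbers (or NULL)", call. = FALSE)
  }
  if (!is.null(variant_types)) {
    if (!all(variant_types %in% VARIANT_TYPES)) {
      stop("unknown variant type(s): ",
           paste(setdiff(variant_types, VARIANT_TYPES), collapse = ", "),
           call. = FALSE)
    }
  }
  if (!is.null(tag_value) && is.null(tag)) {
    stop("tag_value requires tag", call. = FALSE)
  }
  structure(list(min_observations = min_observations, min_depth = min_depth,
                 max_p_value = max_p_value, variant_types = variant_types,
                 tag = tag, tag_value = tag_value),
            class = "qe_variant_filter")
}

variant_passes <- function(v, filter, skip_tag = FALSE) {
  if (!is.null(filter$min_observations) &&
      v$observation_count < filter$min_observations) return(FALSE)
  if (!is.null(filter$min_depth) && v$depth < filter$min_depth) return(FALSE)
  if (!is.null(filter$max_p_value) &&
      (is.na(v$p_value) || v$p_value > filter$max_p_value)) return(FALSE)
  if (!is.null(filter$variant_types) && !(v$type %in% filter$variant_types)) {
    return(FALSE)
  }
  if (!skip_tag && !is.null(filter$tag)) {
    if (!(filter$tag %in% names(v$tags))) return(FALSE)
    if (!is.null(filter$tag_value) &&
        v$tags[[filter$tag]] != filter$tag_value) return(FALSE)
  }
  TRUE
}

#' Parse a region string
#'
#' `"contig:start-stop"` with 0-based half-open coordinates, or a bare
#' contig name for the whole contig. With `one_based = TRUE` the string is
#' read as 1-based inclusive (browser convention) and converted.
#'
#' @param region Region string, or `NULL` for whole genome.
#' @param one_based Interpret coordinates as 1-based inclusive.
#' @return `NULL`, or a list `(contig, start, stop)` (`stop` may be `Inf`).
#' @export
parse_region <- function(region, one_based = FALSE) {
  if (is.null(region)) return(NULL)
  if (!is.character(region) || length(region) != 1L || !nzchar(region)) {
    stop("malformed region: must be 'contig' or 'contig:start-stop'",
         call. = FALSE)
  }
  if (!grepl(":", region, fixed = TRUE)) {
    return(list(contig = region, start = 0, stop = Inf))
  }
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L) {
    stop("malformed region '", region, "': expected contig:start-stop",
         call. = FALSE)
  }
  start <- as.numeric(m[3]); stop_ <- as.numeric(m[4])
  if (one_based) { start <- start - 1 }
  if (start > stop_) stop("malformed region '", region, "': start > stop",
                          call. = FALSE)
  list(contig = m[2], start = start, stop = stop_)
}

region_keys <- function(store, region) {
  ci <- store$contigs[[region$contig]]
  if (is.null(ci)) return(NULL)   # valid region, but contig holds no data
  start_key <- row_key_hex(ci, region$start)
  end_key <- if (is.finite(region$stop)) row_key_hex(ci, region$stop)
             else row_key_hex(ci + 1L, 0)
  list(start = start_key, end = end_key)
}

in_region <- function(contig, position, region) {
  if (is.null(region)) return(rep(TRUE, length(position)))
  contig == region$contig & position >= region$start & position < region$stop
}

#' Query variants by region, fields and tags
#'
#' Yields exactly the stored variants of a genome whose locus falls in the
#' region and which pass every filter clause, in (contig, position, version)
#' order. With a tag clause present, execution routes through the secondary
#' index ([lookup_by_tag()]) and applies the remaining clauses afterwards;
#' otherwise a primary-table range scan is used. Both routes return
#' identical results by construction.
#'
#' @param store A `qe_store`.
#' @param genome_label Genome to query.
#' @param region Region string (see [parse_region()]), or `NULL` for whole
#'   genome.
#' @param filter A [variant_filter()].
#' @param one_based Interpret the region as 1-based inclusive.
#' @return A list of `qe_variant` in genomic order.
#' @export
query_variants <- function(store, genome_label, region = NULL,
                           filter = variant_filter(), one_based = FALSE) {
  assert_open(store)
  assert_genome(store, genome_label)
  reg <- parse_region(region, one_based = one_based)
  out <- if (is.null(filter$tag)) {
    scan_route_variants(store, genome_label, reg, filter)
  } else {
    tag_route_variants(store, genome_label, reg, filter)
  }
  sort_variants(out, contig_order = store$contig_names)
}

scan_route_variants <- function(store, genome_label, reg, filter) {
  keys <- if (is.null(reg)) {
    scan_group_keys(store, "primary", NULL, NULL, family = "variant")$keys
  } else {
    rk <- region_keys(store, reg)
    if (is.null(rk)) return(list())
    scan_group_keys(store, "primary", rk$start, rk$end, family = "variant")$keys
  }
  te <- table_env(store, "primary")
  out <- list()
  for (k in keys) {
    for (cell in te$cells[[k]]) {
      if (cell$label != genome_label) next
      v <- decode_variant(cell$value)
      if (variant_passes(v, filter)) out[[length(out) + 1L]] <- v
    }
  }
  out
}

tag_route_variants <- function(store, genome_label, reg, filter) {
  hits <- lookup_by_tag(store, filter$tag, genome_label)
  out <- list()
  seen <- new.env(parent = emptyenv())
  for (h in hits) {
    rhex <- raw_to_hex(h$target_row_key)
    if (exists(rhex, envir = seen, inherits = FALSE)) next
    assign(rhex, TRUE, envir = seen)
    cells <- get_cells(store, h$target_table, rhex, "variant",
                       label = genome_label)
    for (cell in cells) {
      v <- decode_variant(cell$value)
      # soundness: the row may hold variants without the tag; re-check all
      # clauses including the tag (and tag value, which the index ignores)
      if (!variant_passes(v, filter)) next
      if (!is.null(reg) && !in_region(v$contig, v$position, reg)) next
      out[[length(out) + 1L]] <- v
    }
  }
  out
}

# (contig, position, version) order; contigs rank by the store's dictionary
# when given, else by first appearance
sort_variants <- function(vs, contig_order = NULL) {
  if (length(vs) <= 1L) return(vs)
  contigs <- vapply(vs, `[[`, "", "contig")
  rank <- if (is.null(contig_order)) match(contigs, unique(contigs))
          else match(contigs, contig_order)
  vs[order(rank, vapply(vs, `[[`, 0, "position"),
           vapply(vs, `[[`, 0L, "version"))]
}

#' Query consequences joined to their variants
#'
#' Each consequence in the region is joined to the variant its
#' `variant_version` back-reference names; consequences whose variant fails
#' the filter are suppressed, and dangling back-references are skipped with
#' a warning.
#'
#' @inheritParams query_variants
#' @return A list of pairs `list(consequence = , variant = )` in genomic
#'   order.
#' @export
query_consequences <- function(store, genome_label, region = NULL,
                               filter = variant_filter(), one_based = FALSE) {
  assert_open(store)
  assert_genome(store, genome_label)
  reg <- parse_region(region, one_based = one_based)
  keys <- if (is.null(reg)) {
    scan_group_keys(store, "primary", NULL, NULL, family = "consequence")$keys
  } else {
    rk <- region_keys(store, reg)
    if (is.null(rk)) return(list())
    scan_group_keys(store, "primary", rk$start, rk$end, family = "consequence")$keys
  }
  te <- table_env(store, "primary")
  out <- list()
  for (k in keys) {
    rhex <- substr(k, 1L, ROW_KEY_HEX)
    for (cell in te$cells[[k]]) {
      if (cell$label != genome_label) next
      cq <- decode_consequence(cell$value)
      vcells <- get_cells(store, "primary", rhex, "variant", label = genome_label)
      hit <- NULL
      for (vc in vcells) {
        if (vc$version == cq$variant_version) { hit <- vc; break }
      }
      if (is.null(hit)) {
        warning("dangling consequence back-reference at ", cq$contig, ":",
                format_pos(cq$position), " (v", cq$variant_version,
                ", genome ", genome_label, "); skipped", call. = FALSE)
        next
      }
      v <- decode_variant(hit$value)
      if (!variant_passes(v, filter)) next
      out[[length(out) + 1L]] <- list(consequence = cq, variant = v)
    }
  }
  out
}

#' Query per-base coverage in a region
#'
#' Reconstructs per-base depths from the coverage blocks overlapping the
#' region, clipped to it. Coverage is queryable only by location; a region
#' is required (there is no whole-genome per-base stream). Uncovered bases
#' are omitted. When a block was loaded more than once, the highest cell
#' version wins.
#'
#' @inheritParams query_variants
#' @param region Region string (required).
#' @return A data frame with columns `contig`, `position` (0-based),
#'   `depth`, ascending in position.
#' @export
query_coverage <- function(store, genome_label, region, one_based = FALSE) {
  assert_open(store)
  assert_genome(store, genome_label)
  if (is.null(region)) stop("coverage queries require a region", call. = FALSE)
  reg <- parse_region(region, one_based = one_based)
  empty <- data.frame(contig = character(0), position = numeric(0),
                      depth = integer(0))
  ci <- store$contigs[[reg$contig]]
  if (is.null(ci)) return(empty)
  bs <- store$block_size
  lo <- (reg$start %/% bs) * bs
  hi <- if (is.finite(reg$stop)) reg$stop else NULL
  start_key <- row_key_hex(ci, lo)
  end_key <- if (is.null(hi)) row_key_hex(ci + 1L, 0) else row_key_hex(ci, hi)
  keys <- scan_group_keys(store, "primary", start_key, end_key,
                          family = "coverage")$keys
  te <- table_env(store, "primary")
  pieces <- list()
  for (k in keys) {
    best <- NULL
    for (cell in te$cells[[k]]) {
      if (cell$label != genome_label) next
      if (is.null(best) || cell$version > best$version) best <- cell
    }
    if (is.null(best)) next
    cb <- decode_coverage(best$value)
    posn <- cb$block_start + cb$offsets
    keep <- posn >= reg$start & posn < reg$stop
    if (any(keep)) {
      pieces[[length(pieces) + 1L]] <-
        data.frame(contig = cb$contig, position = posn[keep],
                   depth = cb$depths[keep])
    }
  }
  if (length(pieces) == 0L) return(empty)
  out <- do.call(rbind, pieces)
  out[order(out$position), , drop = FALSE]
}
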